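# Published reference statistics for the eight deposited Bulbophyllum
# plastomes (GenBank MN604054-MN604059, MN737573, MN580547), bundled as
# plain TSV under inst/extdata.  These printed tables are inputs to the
# length-arithmetic and rate computations; the sequences themselves are not
# shipped.

read_extdata <- function(name) {
  path <- system.file("extdata", name, package = "plastocomp")
  if (!nzchar(path)) stop(sprintf("bundled table %s not found", name), call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published per-genome characteristics of the eight deposited plastomes
#'
#' @return data.frame: species, accession, total/LSC/SSC/IR lengths (bp) and
#'   total GC percentage
#' @export
published_plastome_stats <- function() read_extdata("bulbophyllum_plastome_stats.tsv")

#' Published pooled mutation/indel counts per region class
#'
#' @return data.frame: class, mutations, indels, total_length
#' @export
published_region_counts <- function() read_extdata("bulbophyllum_region_counts.tsv")

#' Published parsimony-informative-site counts of the phylogenetic matrices
#'
#' @return data.frame: matrix, pis, sites
#' @export
published_matrix_stats <- function() read_extdata("bulbophyllum_matrix_stats.tsv")

#' Length arithmetic over the published genome table
#'
#' Reconstructs each total as LSC + SSC + 2 x IR and summarizes the range
#' relationships: the SSC length range across genomes and its share of the
#' total-length range.
#'
#' @param stats data.frame as [published_plastome_stats()]
#' @return list with `reconstructed_totals`, `max_total`, `min_total`,
#'   `ssc_range`, `total_range`, `ssc_share_pct` (nearest integer)
#' @export
length_arithmetic <- function(stats = published_plastome_stats()) {
  recon <- stats$lsc_bp + stats$ssc_bp + 2 * stats$ir_bp
  ssc_range <- max(stats$ssc_bp) - min(stats$ssc_bp)
  total_range <- max(recon) - min(recon)
  list(reconstructed_totals = stats::setNames(recon, stats$species),
       max_total = max(recon), min_total = min(recon),
       ssc_range = ssc_range, total_range = total_range,
       ssc_share_pct = round_half_up(100 * ssc_range / total_range, 0))
}
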