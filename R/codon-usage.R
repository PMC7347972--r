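# Codon usage: raw counts, RSCU, and start-codon audit over the intact CDS
# complement of each genome (pseudogenes excluded).

#' Count codons over a set of in-frame CDS sequences
#'
#' Codons containing `N` are skipped; internal stop codons are counted but
#' flagged; each sequence must be in frame (length divisible by 3).
#'
#' @param cds_sequences list/character vector of in-frame DNA strings
#' @param names optional CDS names used in error messages
#' @return object of class `codon_usage_table`: data.frame with one row per
#'   codon (codon, amino acid, count, RSCU placeholder), plus attributes
#'   `total_sense`, `skipped_ambiguous`, `internal_stops`
#' @export
count_codons <- function(cds_sequences, names = NULL) {
  cds_sequences <- as.character(cds_sequences)
  if (is.null(names)) names <- paste0("cds", seq_along(cds_sequences))
  counts <- stats::setNames(integer(64), CODONS)
  skipped <- 0L
  internal_stops <- 0L
  for (i in seq_along(cds_sequences)) {
    s <- toupper(cds_sequences[[i]])
    if (nchar(s) %% 3 != 0) {
      stop(sprintf("CDS '%s' length %d is not divisible by 3", names[i], nchar(s)),
           call. = FALSE)
    }
    cod <- split_codons(s)
    amb <- grepl("N", cod, fixed = TRUE)
    skipped <- skipped + sum(amb)
    cod <- cod[!amb]
    if (!length(cod)) next
    if (length(cod) > 1) {
      internal_stops <- internal_stops + sum(cod[-length(cod)] %in% STOP_CODONS)
    }
    tab <- table(factor(cod, levels = CODONS))
    counts <- counts + as.integer(tab)
  }
  out <- data.frame(codon = CODONS, aa = unname(CODON_AA[CODONS]),
                    count = unname(counts), rscu = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("codon_usage_table", "data.frame"),
            total_sense = sum(counts[names(counts) %in% SENSE_CODONS]),
            skipped_ambiguous = skipped, internal_stops = internal_stops)
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = n_c * k_aa / sum of counts over the codons synonymous with c,
#' where k_aa is the degeneracy of the amino acid under the standard genetic
#' code.  Stop codons carry no RSCU; amino acids with zero observations are
#' reported as missing (0/0).
#'
#' @param table a `codon_usage_table` from [count_codons()]
#' @return the table with the `rscu` column filled
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  for (a in unique(table$aa)) {
    if (a == "*") next
    idx <- which(table$aa == a)
    tot <- sum(table$count[idx])
    table$rscu[idx] <- if (tot == 0) NA_real_ else table$count[idx] * length(idx) / tot
  }
  table
}

#' Per-genome codon usage over intact CDSs
#'
#' Pools all features of kind CDS (pseudogenes excluded), extracts their
#' in-frame sequences and returns the RSCU-filled usage table.
#'
#' @param record a [plastome_record()]
#' @return a `codon_usage_table`
#' @export
genome_codon_usage <- function(record) {
  f <- record$features
  ids <- unique(f$feature_id[f$kind == "CDS"])
  seqs <- lapply(ids, function(fid) extract_feature_sequence(record, fid))
  nms <- vapply(ids, function(fid) feature_parts(record, fid)$name[1], character(1))
  seqs <- unlist(seqs) %||% character(0)
  keep <- nchar(seqs) %% 3 == 0
  rscu(count_codons(seqs[keep], names = nms[keep]))
}

#' Audit non-ATG initiation codons
#'
#' Reports the first codon of every CDS feature whose observed start codon is
#' not ATG (e.g. the GTG/ACG initiators of rps19 and rpl2 reported in
#' plastomes, putative RNA-editing or pseudogenization signals).
#'
#' @param records list of [plastome_record()]
#' @return data.frame with columns `genome`, `gene`, `start_codon`
#' @export
start_codon_audit <- function(records) {
  rows <- list()
  for (rec in records) {
    f <- rec$features
    ids <- unique(f$feature_id[f$kind == "CDS"])
    for (fid in ids) {
      s <- extract_feature_sequence(rec, fid)
      start <- substr(s, 1, 3)
      if (start != "ATG") {
        rows[[length(rows) + 1]] <- data.frame(
          genome = rec$id, gene = feature_parts(rec, fid)$name[1],
          start_codon = start, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(genome = character(0), gene = character(0),
                      start_codon = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Genomes-by-codons RSCU matrix
#'
#' Heatmap-ready cross-genome matrix of RSCU values.
#'
#' @param records list of [plastome_record()]
#' @return numeric matrix, rows = genomes, columns = the 61 sense codons
#' @export
rscu_matrix <- function(records) {
  m <- t(vapply(records, function(rec) {
    tab <- genome_codon_usage(rec)
    stats::setNames(tab$rscu, tab$codon)[SENSE_CODONS]
  }, numeric(length(SENSE_CODONS))))
  rownames(m) <- vapply(records, function(r) r$id, character(1))
  m
}
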