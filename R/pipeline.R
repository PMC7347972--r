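# Configuration-driven pipeline: simulate (or load) genomes, then run the
# structure / codon / repeat / SSR / variability / selection stages in
# dependency order, writing stage TSVs plus one JSON summary.  All
# randomness flows from a single root seed through named per-stage
# substreams, so toggling stages does not shift other stages' draws.

PIPELINE_STAGES <- c("structure", "codon", "repeats", "ssrs", "variability",
                     "selection")

#' Validate a pipeline configuration
#'
#' @param config list with any of: `simulate` (logical or list of
#'   [build_ancestor()] / [evolution_config()] overrides), `genomes`
#'   (character paths), `alignment` (path or `"from-truth"`), `reference`
#'   (genome id), `stages` (subset of the stage names), `out_dir`, `seed`,
#'   `ssr_thresholds`, `repeat_min_len`, `repeat_max_mismatch`, `top_k`
#' @return the config with resolved defaults
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(simulate = TRUE, genomes = NULL, alignment = "from-truth",
                   reference = NULL, stages = PIPELINE_STAGES,
                   out_dir = tempfile("plastocomp_"), seed = 1,
                   ssr_thresholds = c(10, 5, 3, 3, 3, 3),
                   repeat_min_len = 30, repeat_max_mismatch = 3, top_k = 10)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, config)
  bad <- setdiff(out$stages, PIPELINE_STAGES)
  if (length(bad)) stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  out
}

tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative-plastome pipeline
#'
#' @param config list, see [pipeline_config()]
#' @param quiet suppress progress messages
#' @return invisibly, a list with the per-stage results and the summary
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  # ---- inputs -------------------------------------------------------------
  truth <- NULL
  if (isTRUE(cfg$simulate) || is.list(cfg$simulate)) {
    say("simulate: building ancestor and evolving %s", "clade")
    anc <- build_ancestor(seed = cfg$seed)
    evc <- default_evolution_config(seed = cfg$seed)
    sim <- evolve(anc, evc)
    records <- sim$records
    truth <- sim$truth
    aln <- truth$true_alignment[setdiff(rownames(truth$true_alignment), "ancestor"), ]
    reference <- names(records)[1]
    for (id in names(records)) {
      write_genbank(records[[id]], file.path(cfg$out_dir, paste0(id, ".gb")),
                    date = "01-JAN-2026")
    }
    write_fasta(apply(truth$true_alignment, 1, paste, collapse = ""),
                file.path(cfg$out_dir, "true_alignment.fasta"))
  } else {
    if (is.null(cfg$genomes)) stop("either simulate or genomes must be given", call. = FALSE)
    records <- lapply(cfg$genomes, read_annotated_genome)
    names(records) <- vapply(records, function(r) r$id, character(1))
    aln <- if (!is.null(cfg$alignment) && cfg$alignment != "from-truth") {
      read_alignment(cfg$alignment)
    } else NULL
    reference <- cfg$reference %||% names(records)[1]
  }

  results <- list()

  # ---- structure ----------------------------------------------------------
  if ("structure" %in% cfg$stages) {
    say("structure: quadripartite partitions and junctions")
    partitions <- lapply(records, function(r) {
      attr(r, "partition") %||% detect_inverted_repeat(r)
    })
    st <- structure_table(records, partitions)
    junc <- do.call(rbind, lapply(names(records), function(id) {
      cbind(id = id, junction_report(records[[id]], partitions[[id]]))
    }))
    types <- vapply(names(records), function(id) {
      classify_ir_ssc_type(records[[id]], partitions[[id]])
    }, character(1))
    st$junction_type <- types
    ref_rec <- if (!is.null(truth)) truth$ancestor else records[[reference]]
    ndh_ids <- unique(ref_rec$features$feature_id[
      ref_rec$features$name %in% NDH_GENES & ref_rec$features$kind == "CDS"])
    ref_lens <- vapply(ndh_ids, function(fid) {
      nchar(extract_feature_sequence(ref_rec, fid))
    }, numeric(1))
    names(ref_lens) <- vapply(ndh_ids, function(fid) {
      feature_parts(ref_rec, fid)$name[1]
    }, character(1))
    ref_lens <- ref_lens[!duplicated(names(ref_lens))]
    audit <- ndh_audit(records, ref_lens)
    reg <- length_regression(st$ssc_bp, st$total_bp)
    corr <- tryCatch(ndh_ssc_correlation(records, partitions),
                     error = function(e) list(r = NA, p_value = NA))
    tsv(st, cfg$out_dir, "structure_table")
    tsv(junc, cfg$out_dir, "junction_table")
    tsv(cbind(id = rownames(audit), as.data.frame(audit)), cfg$out_dir, "ndh_status")
    results$structure <- list(table = st, junctions = junc, types = types,
                              ndh = audit, ssc_total_regression = reg,
                              ndh_ssc_correlation = corr,
                              partitions = partitions)
  }

  # ---- codon usage --------------------------------------------------------
  if ("codon" %in% cfg$stages) {
    say("codon: usage tables and RSCU")
    usage <- lapply(records, genome_codon_usage)
    mat <- rscu_matrix(records)
    audit <- start_codon_audit(records)
    for (id in names(usage)) tsv(usage[[id]], cfg$out_dir, paste0("codon_usage_", id))
    tsv(cbind(id = rownames(mat), as.data.frame(mat)), cfg$out_dir, "rscu_matrix")
    tsv(audit, cfg$out_dir, "start_codon_audit")
    results$codon <- list(usage = usage, rscu_matrix = mat, start_codons = audit)
  }

  # ---- repeats ------------------------------------------------------------
  if ("repeats" %in% cfg$stages) {
    say("repeats: dispersed repeat scan")
    reps <- lapply(names(records), function(id) {
      r <- find_long_repeats(records[[id]]$sequence, cfg$repeat_min_len,
                             cfg$repeat_max_mismatch)
      part <- results$structure$partitions[[id]] %||% detect_inverted_repeat(records[[id]])
      ann <- classify_hits(r, part, region_class_map(records[[id]]))
      cbind(id = id, ann$hits)
    })
    reps <- do.call(rbind, reps)
    tsv(reps, cfg$out_dir, "repeat_table")
    results$repeats <- reps
  }

  # ---- SSRs ---------------------------------------------------------------
  if ("ssrs" %in% cfg$stages) {
    say("ssrs: microsatellite scan and polymorphism calling")
    loci <- lapply(records, function(r) scan_ssrs(r$sequence, cfg$ssr_thresholds))
    ann <- lapply(names(records), function(id) {
      part <- results$structure$partitions[[id]] %||% detect_inverted_repeat(records[[id]])
      cl <- classify_hits(loci[[id]], part, region_class_map(records[[id]]))
      cbind(id = id, cl$hits)
    })
    ssr_tab <- do.call(rbind, ann)
    poly <- polymorphic_ssrs(loci)
    tsv(ssr_tab, cfg$out_dir, "ssr_table")
    tsv(poly, cfg$out_dir, "polymorphic_ssrs")
    results$ssrs <- list(loci = ssr_tab, polymorphic = poly)
  }

  # ---- variability --------------------------------------------------------
  if ("variability" %in% cfg$stages && !is.null(aln)) {
    say("variability: segment statistics and marker ranking")
    ref_map <- region_class_map(records[[reference]])
    segs <- segment_alignment(aln, ref_map, reference)
    rates <- rate_table(segs)
    top <- rank_segments(segs, cfg$top_k)
    corr <- tryCatch(sv_at_correlation(segs), error = function(e) list(r = NA, p_value = NA))
    tsv(segs, cfg$out_dir, "segments")
    tsv(rates, cfg$out_dir, "rate_table")
    tsv(top, cfg$out_dir, "top_markers")
    results$variability <- list(segments = segs, rates = rates, top = top,
                                sv_at = corr)
  }

  # ---- selection ----------------------------------------------------------
  if ("selection" %in% cfg$stages) {
    say("selection: codon-model scan")
    genes <- if (!is.null(truth) && length(truth$selection)) {
      names(truth$selection)
    } else {
      shared <- Reduce(intersect, lapply(records, function(r) {
        unique(r$features$name[r$features$kind == "CDS"])
      }))
      utils::head(shared, 2)
    }
    gene_alns <- lapply(genes, function(g) {
      seqs <- vapply(records, function(r) {
        tryCatch(extract_feature_sequence(r, g), error = function(e) NA_character_)
      }, character(1))
      seqs <- seqs[!is.na(seqs)]
      seqs[nchar(seqs) == max(nchar(seqs))]
    })
    names(gene_alns) <- genes
    keep <- vapply(gene_alns, function(s) length(s) >= 3 &&
                     length(unique(nchar(s))) == 1, logical(1))
    scan <- selection_scan(gene_alns[keep])
    if (!is.null(scan$summary)) tsv(scan$summary, cfg$out_dir, "selection_summary")
    results$selection <- scan
  }

  # ---- summary ------------------------------------------------------------
  summary <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_genomes = length(records),
    genome_lengths = vapply(records, genome_length, numeric(1)))
  if (!is.null(results$structure)) {
    st <- results$structure$table
    summary$structure <- list(
      totals_check = all(st$lsc_bp + st$ssc_bp + 2 * st$ir_bp == st$total_bp),
      junction_types = as.list(results$structure$types),
      ssc_total_r_squared = results$structure$ssc_total_regression$r_squared,
      ndh_ssc_r = results$structure$ndh_ssc_correlation$r)
  }
  if (!is.null(results$ssrs)) {
    summary$ssrs <- list(total = nrow(results$ssrs$loci),
                         polymorphic_groups =
                           length(unique(results$ssrs$polymorphic$locus_group)))
  }
  if (!is.null(results$variability)) {
    summary$variability <- list(n_segments = nrow(results$variability$segments),
                                top_markers = results$variability$top$name)
  }
  if (!is.null(results$selection) && !is.null(results$selection$summary)) {
    s <- results$selection$summary
    summary$selection <- list(genes = s$gene, lrt_p = s$lrt_p,
                              n_positive_sites = s$n_positive_sites)
  }
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(results = results, summary = summary, out_dir = cfg$out_dir,
                 records = records, truth = truth))
}
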