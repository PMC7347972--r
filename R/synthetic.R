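# Synthetic plastome generator: a quadripartite ancestor with a plastid-like
# gene map (ndh family, junction-spanning ycf1, trnH-rps19 cluster in the
# IR), evolved along a tree under HKY substitutions with per-region-class
# rates, geometric-length indels restricted to non-coding single-copy
# sequence, SSR slippage, ndh deletions/truncations, and IR mutation
# mirroring.  Every run emits the true alignment and a machine-readable
# truth log so downstream stages can be validated offline.

#' Default region length plan
#'
#' Desk-scale lengths in the LSC > IR > SSC proportions of sequenced
#' Bulbophyllum plastomes (roughly 0.55 : 0.17 : 0.09 of the total).
#'
#' @return list with `LSC`, `SSC`, `IR` lengths in bp
#' @export
default_length_plan <- function() list(LSC = 33000, SSC = 5600, IR = 10300)

#' Default plastid-like gene plan
#'
#' Ordered gene map covering the 11-gene ndh family (seven members in the
#' SSC), rpl22 adjacent to the LSC/IRb junction, the trnH-rps19 cluster and
#' rRNA operon inside the IR, two intron-bearing genes, and the GTG/ACG
#' alternative initiators of rps19/rpl2.
#'
#' @return data.frame with columns `name`, `kind`, `region`, `len`,
#'   `strand`, `intron_len`, `start_codon`
#' @export
default_gene_plan <- function() {
  g <- function(name, kind, region, len, strand = "+", intron_len = 0,
                start_codon = "ATG") {
    data.frame(name = name, kind = kind, region = region, len = len,
               strand = strand, intron_len = intron_len,
               start_codon = start_codon, stringsAsFactors = FALSE)
  }
  rbind(
    g("psbA", "CDS", "LSC", 1062, "-"),
    g("matK", "CDS", "LSC", 1500),
    g("trnR", "tRNA", "LSC", 72),
    g("atpA", "CDS", "LSC", 1524, "-"),
    g("atpF", "CDS", "LSC", 555, "-", intron_len = 700),
    g("atpH", "CDS", "LSC", 246, "-"),
    g("atpI", "CDS", "LSC", 744, "-"),
    g("rpoB", "CDS", "LSC", 2100, "-"),
    g("ndhC", "CDS", "LSC", 363, "-"),
    g("ndhJ", "CDS", "LSC", 477, "-"),
    g("ndhK", "CDS", "LSC", 678, "-"),
    g("trnS", "tRNA", "LSC", 87),
    g("psbB", "CDS", "LSC", 1527),
    g("psbT", "CDS", "LSC", 108),
    g("clpP", "CDS", "LSC", 591, "-", intron_len = 600),
    g("petB", "CDS", "LSC", 648),
    g("rpl22", "CDS", "LSC", 363),
    g("rps19", "CDS", "IR", 279, "-", start_codon = "GTG"),
    g("trnH", "tRNA", "IR", 74, "-"),
    g("rpl2", "CDS", "IR", 822, "-", start_codon = "ACG"),
    g("ycf2", "CDS", "IR", 1800),
    g("ndhB", "CDS", "IR", 1533, "-"),
    g("rrn16", "rRNA", "IR", 1490),
    g("trnI", "tRNA", "IR", 72),
    g("trnA", "tRNA", "IR", 73),
    g("rrn23", "rRNA", "IR", 1500),
    g("ndhF", "CDS", "SSC", 450, "-"),
    g("rpl32", "CDS", "SSC", 120),
    g("ccsA", "CDS", "SSC", 450),
    g("ndhD", "CDS", "SSC", 450, "-"),
    g("ndhE", "CDS", "SSC", 210, "-"),
    g("ndhG", "CDS", "SSC", 270, "-"),
    g("ndhI", "CDS", "SSC", 240, "-"),
    g("ndhA", "CDS", "SSC", 450, "-", intron_len = 300),
    g("ndhH", "CDS", "SSC", 450, "-"),
    g("rps15", "CDS", "SSC", 150))
}

#' Default planted SSR loci
#' @return data.frame with `motif` and `count`
#' @export
default_ssr_plan <- function() {
  data.frame(motif = c("A", "T", "A", "AT", "TA", "AAT", "AATT", "AATAG", "AATAGC"),
             count = c(12, 11, 13, 6, 7, 4, 4, 4, 3),
             stringsAsFactors = FALSE)
}

random_cds <- function(n_codons, start_codon = "ATG") {
  # AT-rich codon usage, as in plastid CDSs
  pi <- default_codon_pi()
  body <- sample(SENSE_CODONS, n_codons - 2, replace = TRUE, prob = pi)
  paste(c(start_codon, body, "TAA"), collapse = "")
}

# distribute genes along a region; returns start offsets (0-based, region
# relative).  first_gap/last_gap may be fixed; remaining space is split
# evenly over the free gaps.
place_genes <- function(region_len, total_lens, first_gap = NA, last_gap = NA) {
  n <- length(total_lens)
  free <- region_len - sum(total_lens) -
    (if (is.na(first_gap)) 0 else first_gap) - (if (is.na(last_gap)) 0 else last_gap)
  n_free <- n + 1 - (!is.na(first_gap)) - (!is.na(last_gap))
  if (free < n_free * 2) stop("gene plan overflows the region", call. = FALSE)
  base <- free %/% max(n_free, 1)
  gaps <- rep(base, n + 1)
  if (!is.na(first_gap)) gaps[1] <- first_gap
  if (!is.na(last_gap)) gaps[n + 1] <- last_gap
  # absorb the remainder into the first free gap
  spent <- sum(gaps[-(n + 1)]) + gaps[n + 1]
  slack <- region_len - sum(total_lens) - spent
  idx_free <- which(if (is.na(first_gap)) rep(TRUE, n + 1) else c(FALSE, rep(TRUE, n)))
  gaps[idx_free[1]] <- gaps[idx_free[1]] + slack
  if (n == 1) return(gaps[1])
  cumsum(c(gaps[1], total_lens[-n] + gaps[2:n]))
}

splice_in <- function(chars, at0, piece) {
  pc <- strsplit(piece, "", fixed = TRUE)[[1]]
  chars[(at0 + 1):(at0 + length(pc))] <- pc
  chars
}

#' Build a synthetic quadripartite ancestor plastome
#'
#' Constructs a circular record LSC | IRb | SSC | IRa with
#' IRa = reverse complement of IRb exactly, ycf1 spanning the SSC/IRa
#' junction with its truncated mirror copy at the IRb/SSC junction, seven
#' ndh genes in the SSC, and planted SSR loci.  IR boundaries are made
#' sharp (the flanking bases break complementarity) so the planted
#' partition is the maximal inverted-repeat pair.
#'
#' @param length_plan list with `LSC`, `SSC`, `IR` (see
#'   [default_length_plan()])
#' @param gene_plan data.frame as [default_gene_plan()]
#' @param seed integer seed
#' @param ycf1_ir_overlap bp of ycf1 extending into the IRa (and mirrored as
#'   the ycf1 pseudogene fragment at the IRb/SSC junction)
#' @param ndhF_ir_overlap when > 0, annotate ndhF as a pseudogene spanning
#'   the IRb/SSC junction by this many bp (junction type 2)
#' @param ssr_plan data.frame of SSR loci to plant (see
#'   [default_ssr_plan()]); `NULL` for none
#' @return a [plastome_record()] with attributes `partition`
#'   (a [quadripartite_partition()]) and `ssr_truth` (planted loci)
#' @export
build_ancestor <- function(length_plan = default_length_plan(),
                           gene_plan = default_gene_plan(), seed = 1,
                           ycf1_ir_overlap = 300, ndhF_ir_overlap = 0,
                           ssr_plan = default_ssr_plan()) {
  stopifnot(length_plan$IR >= 1000, length_plan$LSC > 0, length_plan$SSC > 0)
  set.seed(stage_seed(seed, "ancestor"))
  lsc_len <- length_plan$LSC; ssc_len <- length_plan$SSC; ir_len <- length_plan$IR
  ov <- ycf1_ir_overlap
  ycf1_len <- 1200
  ycf1_ssc <- ycf1_len - ov
  L <- lsc_len + ssc_len + 2 * ir_len
  lsc_off <- 0; irb_off <- lsc_len; ssc_off <- lsc_len + ir_len
  ira_off <- ssc_off + ssc_len

  build_gene_seq <- function(row) {
    core <- if (row$kind == "CDS") random_cds(row$len / 3, row$start_codon)
            else random_dna(row$len, gc = 0.5)
    if (row$intron_len > 0) {
      e1 <- 3 * ((row$len / 3) %/% 2)
      list(seq = paste0(substr(core, 1, e1), random_dna(row$intron_len, gc = 0.3),
                        substr(core, e1 + 1, row$len)),
           exon1 = e1)
    } else {
      list(seq = core, exon1 = NA)
    }
  }

  features <- feature_table()
  chars_region <- function(len, gc = 0.3) strsplit(random_dna(len, gc), "", fixed = TRUE)[[1]]

  add_gene <- function(features, row, abs_start, gene, mirror = FALSE,
                       ir_bounds = NULL) {
    total <- row$len + row$intron_len
    s <- abs_start; e <- abs_start + total
    kind <- row$kind
    if (is.na(gene$exon1)) {
      parts <- matrix(c(s, e), ncol = 2)
    } else if (row$strand == "+") {
      i1 <- s + gene$exon1; i2 <- i1 + row$intron_len
      parts <- matrix(c(s, i1, i2, e), ncol = 2, byrow = TRUE)
    } else {
      # genome layout is revcomp(exon1 | intron | exon2): the reading-first
      # exon sits at the high-coordinate end
      i1 <- s + (row$len - gene$exon1); i2 <- i1 + row$intron_len
      parts <- matrix(c(i2, e, s, i1), ncol = 2, byrow = TRUE)
    }
    add_feature(features, row$name, kind, row$strand, parts, codon_start = 0L)
  }

  # background GC mirrors the observed region ordering (IR richest, SSC
  # poorest) so per-region GC summaries behave like real plastomes
  region_gc <- c(LSC = 0.31, IR = 0.42, SSC = 0.26)

  assemble_region <- function(plan, region_len, offset, first_gap = NA, last_gap = NA,
                              gc = 0.3) {
    chars <- chars_region(region_len, gc = gc)
    if (!nrow(plan)) return(list(chars = chars, placed = NULL))
    totals <- plan$len + plan$intron_len
    starts <- place_genes(region_len, totals, first_gap, last_gap)
    placed <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      gene <- build_gene_seq(plan[i, ])
      gseq <- if (plan$strand[i] == "-") revcomp(gene$seq) else gene$seq
      chars <- splice_in(chars, starts[i], gseq)
      placed[[i]] <- list(row = plan[i, ], start = offset + starts[i], gene = gene)
    }
    list(chars = chars, placed = placed)
  }

  # ycf1 first (its tail defines the IRb end)
  ycf1_seq <- random_cds(ycf1_len / 3)

  lsc_plan <- gene_plan[gene_plan$region == "LSC", ]
  lsc <- assemble_region(lsc_plan, lsc_len, lsc_off, last_gap = 20,
                         gc = region_gc[["LSC"]])

  ir_plan <- gene_plan[gene_plan$region == "IR", ]
  irb <- assemble_region(ir_plan, ir_len, irb_off, first_gap = 60, last_gap = ov + 40,
                         gc = region_gc[["IR"]])
  irb$chars <- splice_in(irb$chars, ir_len - ov, revcomp(substr(ycf1_seq, ycf1_ssc + 1, ycf1_len)))

  ssc_plan <- gene_plan[gene_plan$region == "SSC", ]
  type2 <- ndhF_ir_overlap > 0
  first_gap <- 80
  if (type2) {
    ndhF_row <- ssc_plan[ssc_plan$name == "ndhF", ]
    first_gap <- 80 + (ndhF_row$len - ndhF_ir_overlap)
    ssc_plan <- ssc_plan[ssc_plan$name != "ndhF", ]
  }
  ssc <- assemble_region(ssc_plan, ssc_len - ycf1_ssc, ssc_off,
                         first_gap = first_gap, last_gap = NA,
                         gc = region_gc[["SSC"]])
  ssc$chars <- c(ssc$chars, strsplit(substr(ycf1_seq, 1, ycf1_ssc), "", fixed = TRUE)[[1]])

  # features: LSC + SSC genes directly, IR genes in both copies
  for (p in c(lsc$placed, ssc$placed)) {
    features <- add_gene(features, p$row, p$start, p$gene)
  }
  for (p in irb$placed) {
    features <- add_gene(features, p$row, p$start, p$gene)
    total <- p$row$len + p$row$intron_len
    rel <- p$start - irb_off
    mir <- p$row
    mir$strand <- if (p$row$strand == "+") "-" else "+"
    mir_start <- ira_off + ir_len - rel - total
    features <- add_gene(features, mir, mir_start, p$gene)
  }
  # ycf1 spanning SSC end into IRa; pseudo fragment at IRb end
  features <- add_feature(features, "ycf1", "CDS", "+",
                          matrix(c(ira_off - ycf1_ssc, ira_off + ov), ncol = 2))
  features <- add_feature(features, "ycf1", "pseudogene", "-",
                          matrix(c(irb_off + ir_len - ov, irb_off + ir_len), ncol = 2))
  if (type2) {
    ndhF_row <- gene_plan[gene_plan$region == "SSC" & gene_plan$name == "ndhF", ]
    features <- add_feature(features, "ndhF", "pseudogene", "-",
                            matrix(c(ssc_off - ndhF_ir_overlap,
                                     ssc_off - ndhF_ir_overlap + ndhF_row$len), ncol = 2))
  }

  chars <- c(lsc$chars, irb$chars, ssc$chars)
  chars <- c(chars, revcomp_chars(chars[(irb_off + 1):(irb_off + ir_len)]))
  stopifnot(length(chars) == L)

  # sharpen IR boundaries so the planted pair is maximal:
  # leftward growth pairs S[irb_off - 1] with comp(S[0]); rightward growth
  # pairs S[irb_off + ir_len] with comp(S[ira_off - 1])
  comp1 <- chartr("ACGTN", "TGCAN", chars[1])
  if (chars[irb_off] == comp1) {
    chars[irb_off] <- setdiff(DNA_BASES, comp1)[1]
  }
  comp2 <- chartr("ACGTN", "TGCAN", chars[ira_off])
  if (chars[irb_off + ir_len + 1] == comp2) {
    chars[irb_off + ir_len + 1] <- setdiff(DNA_BASES, comp2)[1]
  }

  # plant SSR loci into LSC intergenic gaps
  ssr_truth <- data.frame(motif = character(0), unit = integer(0),
                          count = integer(0), start = integer(0),
                          stringsAsFactors = FALSE)
  if (!is.null(ssr_plan) && nrow(ssr_plan)) {
    spans <- lapply(lsc$placed, function(p) {
      c(p$start, p$start + p$row$len + p$row$intron_len)
    })
    gap_starts <- vapply(spans[-length(spans)], function(s) s[2], numeric(1))
    gap_ends <- vapply(spans[-1], function(s) s[1], numeric(1))
    big <- which(gap_ends - gap_starts >= 120)
    stopifnot(length(big) >= nrow(ssr_plan))
    for (i in seq_len(nrow(ssr_plan))) {
      motif <- ssr_plan$motif[i]; count <- ssr_plan$count[i]
      u <- nchar(motif)
      pos <- gap_starts[big[i]] + 40                 # 0-based locus start
      run <- strsplit(paste(rep(motif, count), collapse = ""), "", fixed = TRUE)[[1]]
      chars[(pos + 1):(pos + length(run))] <- run
      # maximality guards: left boundary must not extend the period
      chars[pos] <- setdiff(DNA_BASES, substr(motif, u, u))[1]
      chars[pos + length(run) + 1] <- setdiff(DNA_BASES, substr(motif, 1, 1))[1]
      ssr_truth <- rbind(ssr_truth, data.frame(
        motif = canonical_motif(motif), unit = u, count = count, start = pos,
        stringsAsFactors = FALSE))
    }
  }

  rec <- plastome_record(id = "ancestor", sequence = paste(chars, collapse = ""),
                         circular = TRUE, features = features,
                         source = "synthetic ancestor")
  attr(rec, "partition") <- quadripartite_partition(
    LSC = c(lsc_off, lsc_off + lsc_len), IRb = c(irb_off, irb_off + ir_len),
    SSC = c(ssc_off, ssc_off + ssc_len), IRa = c(ira_off, ira_off + ir_len),
    genome_length = L)
  attr(rec, "ssr_truth") <- ssr_truth
  rec
}
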