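# Hypervariable-marker screen: segment a multi-genome alignment by the
# reference genome's CDS/intron/IGS map, count mutations (Eta), indel events
# (simple indel coding), conserved sites and parsimony-informative sites, and
# rank candidate markers by the sequence-variability (SV) statistic
#   SV = 100 * (mutations + indel events) /
#        (conserved sites + mutations + indel events).

segment_stats <- function(m) {
  nc <- ncol(m)
  gapfree <- colSums(m == "-") == 0
  present <- vapply(DNA_BASES, function(b) colSums(m == b), numeric(nc))
  if (nc == 1) present <- matrix(present, nrow = 1)
  nstates <- rowSums(present > 0)
  mutations <- sum(pmax(nstates[gapfree] - 1, 0))
  conserved <- sum(gapfree & nstates <= 1)
  pis <- sum(gapfree & rowSums(present >= 2) >= 2)
  # indel events: one per distinct gap span (start, end) in any sequence
  spans <- character(0)
  for (r in seq_len(nrow(m))) {
    rl <- rle(m[r, ] == "-")
    ends <- cumsum(rl$lengths); starts <- c(1L, ends[-length(ends)] + 1L)
    g <- which(rl$values)
    if (length(g)) spans <- c(spans, paste(starts[g], ends[g], sep = ":"))
  }
  indel_events <- length(unique(spans))
  at <- sum(m %in% c("A", "T"))
  acgt <- sum(m %in% DNA_BASES)
  denom <- conserved + mutations + indel_events
  list(mutations = mutations, indel_events = indel_events, conserved = conserved,
       pis = pis, aligned_length = nc,
       at_fraction = if (acgt > 0) at / acgt else NA_real_,
       sv = if (denom > 0) 100 * (mutations + indel_events) / denom else NA_real_)
}

#' Minimum number of mutations (Eta) in an aligned segment
#'
#' Sum over gap-free columns of (number of distinct A/C/G/T states - 1);
#' ambiguous bases are excluded from the state set, gap-containing columns
#' are handled solely by indel events.
#'
#' @param m character matrix (sequences x columns)
#' @return integer mutation count
#' @export
count_mutations <- function(m) {
  stopifnot(nrow(m) >= 2)
  segment_stats(m)$mutations
}

#' Indel events under simple indel coding
#'
#' One event per distinct gap span (start, end) observed in at least one
#' sequence; spans sharing both endpoints across sequences count once;
#' nested or overlapping spans with different endpoints count separately.
#'
#' @inheritParams count_mutations
#' @return integer event count
#' @export
count_indel_events <- function(m) {
  stopifnot(nrow(m) >= 2)
  segment_stats(m)$indel_events
}

#' Potentially parsimony-informative sites
#'
#' Gap-free columns with at least two states each carried by at least two
#' sequences.
#'
#' @inheritParams count_mutations
#' @return integer PIS count
#' @export
count_pis <- function(m) {
  segment_stats(m)$pis
}

#' Sequence variability of a segment
#'
#' @param mutations,indel_events,conserved the segment's counts
#' @return SV percentage, `NA` when the denominator is zero
#' @export
sequence_variability <- function(mutations, indel_events, conserved) {
  denom <- conserved + mutations + indel_events
  if (denom <= 0) return(NA_real_)
  100 * (mutations + indel_events) / denom
}

#' Slice a multi-genome alignment into CDS/intron/IGS segments
#'
#' Projects the reference genome's region map onto alignment columns and
#' keeps segments whose ungapped reference length is at least `min_len`.
#' Statistics are computed over all sequences; the reference fixes segment
#' coordinates and names only.
#'
#' @param alignment character matrix from [read_alignment()] (rows named by
#'   genome id, gaps as `-`)
#' @param reference_map [region_class_map()] of the reference genome
#' @param reference row name of the reference sequence
#' @param min_len minimum ungapped reference length (default 150 bp)
#' @param sequences optional subset of row names to use for statistics
#' @param min_presence minimum non-gap fraction required of every sequence
#'   in a segment (default 0.5); segments failing it — typically loci
#'   deleted or rearranged in some genome, which the same-flanking-region
#'   rule excludes — are dropped
#' @return data.frame, one row per segment: `name`, `class`, `col_start`,
#'   `col_end`, `ref_length`, plus the segment statistics
#' @export
segment_alignment <- function(alignment, reference_map, reference,
                              min_len = 150, sequences = NULL,
                              min_presence = 0.5) {
  if (!reference %in% rownames(alignment)) {
    stop(sprintf("reference '%s' absent from the alignment", reference), call. = FALSE)
  }
  use <- sequences %||% rownames(alignment)
  ref <- alignment[reference, ]
  base_cols <- which(ref != "-")
  rows <- list()
  for (i in seq_len(nrow(reference_map))) {
    s <- reference_map$start[i]; e <- reference_map$end[i]
    if (e - s < min_len) next
    c1 <- base_cols[s + 1]; c2 <- base_cols[e]
    m <- alignment[use, c1:c2, drop = FALSE]
    if (min(rowMeans(m != "-")) < min_presence) next
    st <- segment_stats(m)
    rows[[length(rows) + 1]] <- data.frame(
      name = reference_map$locus[i], class = reference_map$class[i],
      col_start = c1, col_end = c2, ref_length = e - s,
      mutations = st$mutations, indel_events = st$indel_events,
      conserved = st$conserved, pis = st$pis,
      aligned_length = st$aligned_length, at_fraction = st$at_fraction,
      sv = st$sv, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no segment meets the minimum length", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pooled mutation/indel rates per region class
#'
#' @param segments data.frame from [segment_alignment()]
#' @param digits presentation rounding for the per-100-bp rates (default 2,
#'   `NULL` for full precision)
#' @return data.frame per class: pooled mutations, indels, total length, and
#'   rates per 100 bp
#' @export
rate_table <- function(segments, digits = 2) {
  cls <- sort(unique(segments$class))
  rows <- lapply(cls, function(cl) {
    s <- segments[segments$class == cl, , drop = FALSE]
    mut <- sum(s$mutations); ind <- sum(s$indel_events); len <- sum(s$ref_length)
    data.frame(class = cl, mutations = mut, indels = ind, total_length = len,
               mut_per_100bp = rate_per_100bp(mut, len, digits),
               indel_per_100bp = rate_per_100bp(ind, len, digits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank segments by sequence variability
#'
#' Descending SV; ties broken by higher PIS, then longer reference length,
#' then name.
#'
#' @param segments data.frame from [segment_alignment()]
#' @param k number of top segments to return (default 10)
#' @return the top-k rows in rank order
#' @export
rank_segments <- function(segments, k = 10) {
  if (k > nrow(segments)) {
    warning(sprintf("k = %d exceeds the %d available segments; returning all",
                    k, nrow(segments)))
    k <- nrow(segments)
  }
  sv <- ifelse(is.na(segments$sv), -Inf, segments$sv)
  o <- order(-sv, -segments$pis, -segments$ref_length, segments$name)
  segments[o[seq_len(k)], , drop = FALSE]
}

#' Correlation of SV with AT content across segments
#'
#' @param segments data.frame from [segment_alignment()]
#' @return list with Pearson `r` and `p_value`
#' @export
sv_at_correlation <- function(segments) {
  ok <- !is.na(segments$sv) & !is.na(segments$at_fraction)
  if (sum(ok) < 3) stop("need at least 3 segments", call. = FALSE)
  if (stats::sd(segments$sv[ok]) == 0 || stats::sd(segments$at_fraction[ok]) == 0) {
    stop("zero variance in SV or AT content", call. = FALSE)
  }
  ct <- stats::cor.test(segments$sv[ok], segments$at_fraction[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
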