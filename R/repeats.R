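# Dispersed long repeats (forward / reverse / palindromic, mismatch-bounded
# maximal pairs) and microsatellite (SSR) scanning with cross-species
# polymorphism calling.
#
# Repeat-pair semantics, shared with the brute-force oracle used in tests:
# on every (anti)diagonal a window is admissible when it carries at most
# `max_mismatch` mismatches and both endpoints are matches; all admissible
# windows not contained in a longer admissible window on the same diagonal
# are reported.  On anti-diagonals mirror-duplicates are collapsed and a
# window symmetric about the center (a perfect self-palindrome / self-mirror)
# is reported once as its two half-intervals.

# maximal admissible windows from the positions of mismatches in a match
# vector of length n; returns matrix cols (lo, hi), 1-based inclusive
max_mismatch_windows <- function(mism_pos, n, k) {
  if (n <= 0) return(matrix(integer(0), ncol = 2))
  mp <- c(0L, mism_pos, n + 1L)
  t <- length(mism_pos)
  nwin <- t - k + 1L
  if (nwin < 1L) {                      # whole vector admissible
    lo <- 1L; hi <- n
  } else {
    j <- seq_len(nwin)
    lo <- mp[j] + 1L
    hi <- mp[j + k + 1L] - 1L
  }
  # trim edges to matches
  win <- cbind(lo, hi)
  win <- win[win[, 1] <= win[, 2], , drop = FALSE]
  if (!nrow(win)) return(matrix(integer(0), ncol = 2))
  for (r in seq_len(nrow(win))) {
    while (win[r, 1] <= win[r, 2] && win[r, 1] %in% mism_pos) win[r, 1] <- win[r, 1] + 1L
    while (win[r, 2] >= win[r, 1] && win[r, 2] %in% mism_pos) win[r, 2] <- win[r, 2] - 1L
  }
  win <- win[win[, 1] <= win[, 2], , drop = FALSE]
  if (!nrow(win)) return(win)
  win <- unique(win)
  # drop windows contained in another window
  keep <- rep(TRUE, nrow(win))
  for (r in seq_len(nrow(win))) {
    keep[r] <- !any(win[, 1] <= win[r, 1] & win[, 2] >= win[r, 2] &
                      (win[, 1] != win[r, 1] | win[, 2] != win[r, 2]))
  }
  win[keep, , drop = FALSE]
}

count_mismatches_chars <- function(a, b) sum(a != b)

#' Find long dispersed repeats
#'
#' Reports all maximal repeat pairs of length at least `min_len` with at most
#' `max_mismatch` mismatches (Hamming distance), in three classes: `forward`
#' (substring vs substring), `reverse` (vs the reversed, non-complemented
#' substring) and `palindromic` (vs the reverse-complemented substring).
#'
#' @param seq DNA string
#' @param min_len minimum repeat length (default 30 bp)
#' @param max_mismatch maximum Hamming distance (default 3)
#' @param classes subset of `c("forward", "reverse", "palindromic")`
#' @return data.frame with columns `class`, `length`, `mismatches`,
#'   `start1`, `end1`, `start2`, `end2` (0-based half-open intervals)
#' @export
find_long_repeats <- function(seq, min_len = 30, max_mismatch = 3,
                              classes = c("forward", "reverse", "palindromic")) {
  classes <- match.arg(classes, several.ok = TRUE)
  seq <- toupper(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  if (L < min_len) return(empty_repeat_df())
  out <- list()

  if ("forward" %in% classes) {
    win <- seeded_diag_windows(x, x, min_len, max_mismatch,
                               offsets = function(e) e >= 1L)
    out <- c(out, repeat_rows_from_windows(win, "forward", x, x, L, min_len))
  }
  for (cl in intersect(classes, c("reverse", "palindromic"))) {
    w <- if (cl == "palindromic") rev(complement_chars(x)) else rev(x)
    win <- seeded_diag_windows(x, w, min_len, max_mismatch)
    out <- c(out, repeat_rows_from_windows(win, cl, x, w, L, min_len))
  }
  if (!length(out)) return(empty_repeat_df())
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$class, res$start1, res$start2), , drop = FALSE]
}

empty_repeat_df <- function() {
  data.frame(class = character(0), length = integer(0), mismatches = integer(0),
             start1 = integer(0), end1 = integer(0), start2 = integer(0),
             end2 = integer(0), stringsAsFactors = FALSE)
}

# lexicographically minimal rotation of motif over both strands
canonical_motif <- function(motif) {
  rot <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n) - 1L, function(i) {
      paste0(substr(s, i + 1, n), substr(s, 1, i))
    }, character(1))
  }
  min(c(rot(motif), rot(revcomp(motif))))
}

is_primitive_motif <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(TRUE)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 &&
        motif == paste(rep(substr(motif, 1, d), n / d), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

#' Scan microsatellites (SSRs)
#'
#' Maximal perfect tandem runs of 1-6 bp motifs meeting per-unit-length
#' repeat-count thresholds (defaults: mono >= 10, di >= 5, tri- through
#' hexa- >= 3, the MISA-style configuration of plastome surveys).  Runs are
#' canonicalized: a poly-A run is reported once as a mononucleotide locus,
#' never again as (AA)n etc.; motifs are reported as the lexicographically
#' minimal rotation over both strands.
#'
#' @param seq DNA string
#' @param thresholds named/positional vector of minimum repeat counts for
#'   unit lengths 1..6
#' @param flank_len flanking sequence length attached to each locus (for
#'   cross-species locus grouping and primer design export)
#' @return data.frame with columns `motif` (canonical), `unit`, `count`,
#'   `start`, `end` (0-based half-open), `flank_left`, `flank_right`
#' @export
scan_ssrs <- function(seq, thresholds = c(10, 5, 3, 3, 3, 3), flank_len = 20) {
  stopifnot(length(thresholds) == 6)
  seq <- toupper(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(x)
  rows <- list()
  for (u in 1:6) {
    if (L < u * thresholds[u]) next
    same <- x[seq_len(L - u)] == x[seq_len(L - u) + u] & x[seq_len(L - u)] != "N"
    r <- rle(same)
    ends <- cumsum(r$lengths); starts <- c(1L, ends[-length(ends)] + 1L)
    for (i in which(r$values & r$lengths >= u)) {
      q <- r$lengths[i]
      count <- q %/% u + 1L
      if (count < thresholds[u]) next
      a <- starts[i]                       # run of matches starts here
      motif <- paste(x[a:(a + u - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next # covered at a smaller unit length
      span <- u * count
      rows[[length(rows) + 1]] <- data.frame(
        motif = canonical_motif(motif), unit = u, count = count,
        start = a - 1L, end = a - 1L + span, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(0), unit = integer(0), count = integer(0),
                      start = integer(0), end = integer(0),
                      flank_left = character(0), flank_right = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit), , drop = FALSE]
  out$flank_left <- substr(rep(seq, nrow(out)),
                           pmax(1L, out$start - flank_len + 1L), out$start)
  out$flank_right <- substr(rep(seq, nrow(out)), out$end + 1L,
                            pmin(L, out$end + flank_len))
  rownames(out) <- NULL
  out
}

majority_region <- function(iv, partition) {
  L <- partition$genome_length
  regs <- c("LSC", "IRb", "SSC", "IRa")
  ov <- vapply(regs, function(r) circ_intersect_len(iv, partition[[r]], L), numeric(1))
  starts <- vapply(regs, function(r) partition[[r]][1] %% L, numeric(1))
  best <- which(ov == max(ov))
  regs[best[which.min(starts[best])]]     # tie -> lower-coordinate region
}

majority_class <- function(iv, map) {
  ov <- pmax(0, pmin(iv[2], map$end) - pmax(iv[1], map$start))
  cls <- tapply(ov, map$class, sum)
  names(cls)[which.max(cls)]
}

#' Annotate repeat hits / SSR loci with genomic regions
#'
#' Labels every record with its quadripartite region (majority overlap; exact
#' ties resolved toward the lower-coordinate region) and its CDS/intron/IGS
#' class, and returns summary cross-tabulations.
#'
#' @param hits data.frame from [find_long_repeats()] or [scan_ssrs()]
#' @param partition a [quadripartite_partition()]
#' @param map a [region_class_map()] of the same genome
#' @return list with `hits` (annotated) and `summary` (region x class counts)
#' @export
classify_hits <- function(hits, partition, map) {
  if (!nrow(hits)) {
    return(list(hits = hits, summary = table(region = character(0), class = character(0))))
  }
  is_repeat <- "start1" %in% names(hits)
  iv_cols <- if (is_repeat) c("start1", "end1") else c("start", "end")
  ivs <- lapply(seq_len(nrow(hits)), function(i) as.numeric(hits[i, iv_cols]))
  hits$region <- vapply(ivs, majority_region, character(1), partition = partition)
  hits$region_class <- vapply(ivs, majority_class, character(1), map = map)
  if (is_repeat) {
    ivs2 <- lapply(seq_len(nrow(hits)), function(i) as.numeric(hits[i, c("start2", "end2")]))
    hits$region2 <- vapply(ivs2, majority_region, character(1), partition = partition)
    hits$region_class2 <- vapply(ivs2, majority_class, character(1), map = map)
  }
  list(hits = hits, summary = table(region = hits$region, class = hits$region_class))
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Call polymorphic SSR locus groups across species
#'
#' Loci from different genomes are grouped when their canonical motif matches
#' and either flanking sequence matches with at most `max_flank_mismatch`
#' mismatches.  A group is polymorphic when present in at least `k` species
#' with at least two distinct repeat counts.
#'
#' @param per_species_loci named list of [scan_ssrs()] data.frames, one per
#'   genome
#' @param k minimum number of species carrying the locus (default 4)
#' @param max_flank_mismatch flank tolerance (default 2)
#' @return data.frame of polymorphic loci: `locus_group`, `species`, `motif`,
#'   `count`, `start`, `end`
#' @export
polymorphic_ssrs <- function(per_species_loci, k = 4, max_flank_mismatch = 2) {
  stopifnot(length(per_species_loci) >= 2)
  sp_names <- names(per_species_loci) %||% paste0("sp", seq_along(per_species_loci))
  groups <- list()   # each: list(motif, fl, fr, rows = df)
  for (s in seq_along(per_species_loci)) {
    loci <- per_species_loci[[s]]
    for (i in seq_len(nrow(loci))) {
      row <- cbind(species = sp_names[s], loci[i, , drop = FALSE])
      placed <- FALSE
      for (g in seq_along(groups)) {
        gr <- groups[[g]]
        if (gr$motif != row$motif) next
        if (hamming(gr$fl, row$flank_left) <= max_flank_mismatch ||
            hamming(gr$fr, row$flank_right) <= max_flank_mismatch) {
          groups[[g]]$rows <- rbind(gr$rows, row)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        groups[[length(groups) + 1]] <- list(motif = row$motif, fl = row$flank_left,
                                             fr = row$flank_right, rows = row)
      }
    }
  }
  out <- list()
  gid <- 0L
  for (gr in groups) {
    sp <- unique(gr$rows$species)
    if (length(sp) < k) next
    if (length(unique(gr$rows$count)) < 2) next    # monomorphic
    gid <- gid + 1L
    out[[gid]] <- cbind(locus_group = gid, gr$rows)
  }
  if (!length(out)) {
    return(data.frame(locus_group = integer(0), species = character(0),
                      motif = character(0), unit = integer(0), count = integer(0),
                      start = integer(0), end = integer(0),
                      flank_left = character(0), flank_right = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("locus_group", "species", "motif", "unit", "count", "start", "end",
          "flank_left", "flank_right")]
}

primer_gc <- function(p) {
  n <- nchar(p)
  (n - nchar(gsub("[GC]", "", p))) / n
}

#' Primer melting temperature (simple salt-free approximation)
#'
#' Tm = 64.9 + 41 * (GC_count - 16.4) / length.
#'
#' @param primer DNA string
#' @return Tm in degrees Celsius
#' @export
primer_tm <- function(primer) {
  n <- nchar(primer)
  gc <- n - nchar(gsub("[GC]", "", toupper(primer)))
  64.9 + 41 * (gc - 16.4) / n
}

#' Validate a primer pair against amplification constraints
#'
#' Rules (defaults follow common plastome-marker design practice): product
#' length 100-500 bp, primer length 18-27 bp, GC content 40-60%, melting
#' temperature difference at most 1 degree C.
#'
#' @param forward,reverse primer sequences
#' @param product_length expected amplicon length in bp
#' @param rules list with `product`, `primer_len`, `gc` (each `c(min, max)`)
#'   and `max_tm_diff`
#' @return list of per-rule logicals plus `pass` (all rules) and the two Tm
#'   values
#' @export
check_primer_constraints <- function(forward, reverse, product_length,
                                     rules = list(product = c(100, 500),
                                                  primer_len = c(18, 27),
                                                  gc = c(0.40, 0.60),
                                                  max_tm_diff = 1)) {
  if (!nzchar(forward) || !nzchar(reverse)) stop("empty primer", call. = FALSE)
  forward <- toupper(forward); reverse <- toupper(reverse)
  lens <- c(nchar(forward), nchar(reverse))
  gcs <- c(primer_gc(forward), primer_gc(reverse))
  tms <- c(primer_tm(forward), primer_tm(reverse))
  res <- list(
    product_ok = product_length >= rules$product[1] && product_length <= rules$product[2],
    length_ok = all(lens >= rules$primer_len[1] & lens <= rules$primer_len[2]),
    gc_ok = all(gcs >= rules$gc[1] & gcs <= rules$gc[2]),
    tm_ok = abs(diff(tms)) <= rules$max_tm_diff,
    tm = tms)
  res$pass <- res$product_ok && res$length_ok && res$gc_ok && res$tm_ok
  res
}
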