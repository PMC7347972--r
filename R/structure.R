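# Quadripartite structure: IR detection, junction context, IR/SSC junction
# typology, ndh-gene audit, and the length-relationship statistics.

NDH_GENES <- c("ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF",
               "ndhG", "ndhH", "ndhI", "ndhJ", "ndhK")

# --- circular interval helpers (intervals are c(start, end), 0-based
# half-open; end may exceed L to express wrapping the origin) ---------------

interval_len <- function(iv) iv[2] - iv[1]

norm_interval <- function(iv, L) {
  s <- iv[1] %% L
  c(s, s + interval_len(iv))
}

circ_intersect_len <- function(iv1, iv2, L) {
  iv1 <- norm_interval(iv1, L); iv2 <- norm_interval(iv2, L)
  tot <- 0
  for (shift in c(-L, 0, L)) {
    a <- max(iv1[1], iv2[1] + shift)
    b <- min(iv1[2], iv2[2] + shift)
    if (b > a) tot <- tot + (b - a)
  }
  tot
}

circ_contains <- function(iv, p, L) {
  iv <- norm_interval(iv, L)
  p <- p %% L
  any(vapply(c(-L, 0, L), function(shift) {
    q <- p + shift
    q >= iv[1] && q < iv[2]
  }, logical(1)))
}

# minimal circular distance from point p to the arc iv (0 when inside)
circ_point_dist <- function(iv, p, L) {
  iv <- norm_interval(iv, L)
  p <- p %% L
  for (shift in c(-L, 0, L)) {
    q <- p + shift
    if (q >= iv[1] && q < iv[2]) return(0)
  }
  d <- c(abs(p - iv[1]), abs(p - iv[2]), abs(p + L - iv[1]), abs(p - L - iv[1]),
         abs(p + L - iv[2]), abs(p - L - iv[2]))
  min(d)
}

#' Quadripartite partition constructor
#'
#' @param LSC,IRb,SSC,IRa `[start, end)` intervals (end may exceed the genome
#'   length to express an origin-wrapping region)
#' @param genome_length genome length in bp
#' @return object of class `quadripartite_partition`
#' @export
quadripartite_partition <- function(LSC, IRb, SSC, IRa, genome_length) {
  p <- structure(list(LSC = LSC, IRb = IRb, SSC = SSC, IRa = IRa,
                      genome_length = genome_length),
                 class = "quadripartite_partition")
  lens <- partition_lengths(p)
  if (sum(lens) != genome_length) {
    stop("partition intervals do not tile the genome", call. = FALSE)
  }
  if (abs(lens[["IRa"]] - lens[["IRb"]]) > 10) {
    stop("IRa and IRb lengths differ by more than the 10 bp tolerance", call. = FALSE)
  }
  if (lens[["LSC"]] < lens[["SSC"]]) {
    stop("LSC must be the longer single-copy region", call. = FALSE)
  }
  p
}

#' Region lengths of a partition
#' @param partition a `quadripartite_partition`
#' @return named numeric vector (LSC, IRb, SSC, IRa)
#' @export
partition_lengths <- function(partition) {
  vapply(partition[c("LSC", "IRb", "SSC", "IRa")], interval_len, numeric(1))
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  l <- partition_lengths(x)
  cat(sprintf("quadripartite partition of %s bp: LSC %s | IRb %s | SSC %s | IRa %s\n",
              format(x$genome_length, big.mark = ","),
              l["LSC"], l["IRb"], l["SSC"], l["IRa"]))
  invisible(x)
}

#' Detect the inverted-repeat pair and quadripartite structure
#'
#' Seed-and-extend search for the maximal pair of disjoint intervals in which
#' one interval matches the reverse complement of the other within a mismatch
#' tolerance.  Exact 25-mer matches between the (doubled, for circular
#' records) sequence and its reverse complement seed candidate anti-diagonals;
#' the best diagonal is extended outward while the running mismatch fraction
#' stays within `max_mismatch_frac`.  Single-copy regions are labeled LSC/SSC
#' by length; IRb is the repeat copy that follows the LSC in genome order.
#'
#' @param record a [plastome_record()]
#' @param min_len minimum IR length in bp (default 10,000)
#' @param max_mismatch_frac maximum mismatch fraction inside each IR copy
#' @return a [quadripartite_partition()]
#' @export
detect_inverted_repeat <- function(record, min_len = 10000, max_mismatch_frac = 0.01) {
  L <- genome_length(record)
  if (L < 2 * min_len) stop("genome shorter than twice min_len", call. = FALSE)
  k <- 25L
  D <- if (record$circular) paste0(record$sequence, record$sequence) else record$sequence
  nD <- nchar(D)
  dvec <- strsplit(D, "", fixed = TRUE)[[1]]
  cvec <- complement_chars(dvec)

  kmers <- substring(D, 1:(nD - k + 1), k:nD)
  rc <- revcomp(D)
  rkmers <- substring(rc, 1:(nD - k + 1), k:nD)
  # match S k-mer at x with revcomp k-mer at r  =>  partner interval starts at
  # y0 = nD - r - k + 1 (1-based); anti-diagonal constant m = x + (y0 + k - 1)
  common <- intersect(unique(kmers), unique(rkmers))
  common <- setdiff(common, common[grepl("N", common, fixed = TRUE)])
  if (!length(common)) stop("no quadripartite structure found", call. = FALSE)
  xs <- split(seq_along(kmers), kmers)[common]
  rs <- split(seq_along(rkmers), rkmers)[common]
  seeds_m <- integer(0); seeds_x <- integer(0)
  for (i in seq_along(common)) {
    x <- xs[[i]]; y0 <- nD - rs[[i]] - k + 2L
    grid <- expand.grid(x = x, y0 = y0)
    seeds_m <- c(seeds_m, grid$x + grid$y0 + k - 1L)
    seeds_x <- c(seeds_x, grid$x)
  }
  # per anti-diagonal seed counts; inspect the most seed-dense diagonals
  tab <- sort(table(seeds_m), decreasing = TRUE)
  cand <- as.integer(names(tab))[seq_len(min(length(tab), 20L))]
  best <- NULL
  for (m in cand) {
    # each pair is seeded from both copies; keep the left-copy seeds only
    sx <- seeds_x[seeds_m == m & seeds_x < m / 2]
    if (!length(sx)) next
    xr <- range(sx)
    hit <- extend_antidiagonal(dvec, cvec, m, xr[1], xr[2] + k - 1L, max_mismatch_frac)
    if (is.null(hit)) next
    s1 <- hit[1]; e1 <- hit[2]             # 1-based inclusive copy1
    len <- e1 - s1 + 1L
    s2 <- m - e1; e2 <- m - s1
    if (len < min_len) next
    if (s2 <= e1) next                     # copies must be disjoint
    # map to original circular coordinates and require circular disjointness
    iv1 <- c(s1 - 1L, e1); iv2 <- c(s2 - 1L, e2)
    if (record$circular) {
      if (iv1[1] >= L) { iv1 <- iv1 - L; iv2 <- iv2 - L }
      if (interval_len(iv1) + interval_len(iv2) > L) next
      if (circ_intersect_len(iv1, iv2, L) > 0) next
    }
    if (is.null(best) || len > best$len) best <- list(len = len, iv1 = iv1, iv2 = iv2)
  }
  if (is.null(best)) stop("no quadripartite structure found", call. = FALSE)
  partition_from_ir_pair(best$iv1, best$iv2, L)
}

# extend [x1, x2] (1-based, all-match seed span) on anti-diagonal m outward,
# keeping mismatches <= frac * length; returns c(start, end) or NULL
extend_antidiagonal <- function(dvec, cvec, m, x1, x2, frac) {
  nD <- length(dvec)
  lo_bound <- max(1L, m - nD)
  hi_bound <- min(nD, m - 1L)
  mism <- sum(dvec[x1:x2] != cvec[m - (x1:x2)])
  repeat {
    len <- x2 - x1 + 1L
    budget <- floor(frac * (len + 1L))
    moved <- FALSE
    if (x1 > lo_bound) {
      add <- dvec[x1 - 1L] != cvec[m - x1 + 1L]
      if (mism + add <= max(budget, 0)) { x1 <- x1 - 1L; mism <- mism + add; moved <- TRUE }
    }
    if (x2 < hi_bound && (x2 + 1L) < (m - x2 - 1L)) {  # keep copies disjoint
      add <- dvec[x2 + 1L] != cvec[m - x2 - 1L]
      if (mism + add <= max(floor(frac * (x2 - x1 + 2L)), 0)) {
        x2 <- x2 + 1L; mism <- mism + add; moved <- TRUE
      }
    }
    if (!moved) break
  }
  # trim the ends back until each terminates in a 10 bp exact-match run, so
  # near-random junction overshoot (allowed by the global mismatch budget)
  # cannot displace the reported boundary
  w <- 10L
  repeat {
    if (x2 - x1 + 1L < w) return(NULL)
    mm <- which(dvec[x1:(x1 + w - 1L)] != cvec[m - (x1:(x1 + w - 1L))])
    if (!length(mm)) break
    x1 <- x1 + max(mm)
  }
  repeat {
    if (x2 - x1 + 1L < w) return(NULL)
    mm <- which(dvec[(x2 - w + 1L):x2] != cvec[m - ((x2 - w + 1L):x2)])
    if (!length(mm)) break
    x2 <- x2 - (w - min(mm) + 1L)
  }
  c(x1, x2)
}

# build the partition from two disjoint IR copy intervals on the circle
partition_from_ir_pair <- function(iv1, iv2, L) {
  iv1 <- norm_interval(iv1, L); iv2 <- norm_interval(iv2, L)
  # order copies along the circle starting from iv1
  gap_a <- (iv2[1] - iv1[2]) %% L      # gap following iv1
  gap_b <- (iv1[1] - iv2[2]) %% L      # gap following iv2
  if (gap_a >= gap_b) {
    # longer gap (LSC) follows iv1: order iv1 -> LSC -> iv2 -> SSC
    lsc <- c(iv1[2] %% L, iv1[2] %% L + gap_a)
    ssc <- c(iv2[2] %% L, iv2[2] %% L + gap_b)
    irb <- iv2; ira <- iv1
  } else {
    lsc <- c(iv2[2] %% L, iv2[2] %% L + gap_b)
    ssc <- c(iv1[2] %% L, iv1[2] %% L + gap_a)
    irb <- iv1; ira <- iv2
  }
  quadripartite_partition(LSC = lsc, IRb = irb, SSC = ssc, IRa = ira,
                          genome_length = L)
}

#' Junction gene context
#'
#' For each of the four junctions (J_LB = LSC/IRb, J_SB = IRb/SSC,
#' J_SA = SSC/IRa, J_LA = IRa/LSC), reports the feature spanning the junction
#' point (or the nearest feature within 1 kb) and its signed overlap: bp of
#' the feature inside the adjacent IR, negative values giving the distance
#' from the junction for non-overlapping features.
#'
#' @param record a [plastome_record()]
#' @param partition a [quadripartite_partition()]
#' @return data.frame with columns `junction`, `feature`, `kind`, `overlap`
#' @export
junction_report <- function(record, partition) {
  L <- partition$genome_length
  juncs <- list(
    J_LB = list(pos = partition$IRb[1] %% L, ir = partition$IRb),
    J_SB = list(pos = partition$IRb[2] %% L, ir = partition$IRb),
    J_SA = list(pos = partition$IRa[1] %% L, ir = partition$IRa),
    J_LA = list(pos = partition$IRa[2] %% L, ir = partition$IRa))
  f <- record$features
  fids <- unique(f$feature_id)
  spans <- lapply(fids, function(fid) feature_span(record, fid))
  nms <- vapply(fids, function(fid) feature_parts(record, fid)$name[1], character(1))
  kinds <- vapply(fids, function(fid) feature_parts(record, fid)$kind[1], character(1))
  out <- data.frame(junction = names(juncs), feature = NA_character_,
                    kind = NA_character_, overlap = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(juncs)) {
    pos <- juncs[[j]]$pos; ir <- juncs[[j]]$ir
    if (!length(fids)) next
    dist <- vapply(spans, circ_point_dist, numeric(1), p = pos, L = L)
    spanning <- which(vapply(spans, function(sp) {
      circ_contains(sp, (pos - 1) %% L, L) && circ_contains(sp, pos %% L, L)
    }, logical(1)))
    if (length(spanning)) {
      ov <- vapply(spans[spanning], circ_intersect_len, numeric(1), iv2 = ir, L = L)
      pick <- spanning[which.max(ov)]
      out$overlap[j] <- max(ov)
    } else {
      near <- which(dist <= 1000 & dist > 0)
      near <- c(near, which(dist == 0))    # features touching but not spanning
      if (!length(near)) next
      pick <- near[which.min(dist[near])]
      inside <- circ_intersect_len(spans[[pick]], ir, L)
      out$overlap[j] <- if (inside > 0) inside else -dist[pick]
    }
    out$feature[j] <- nms[pick]
    out$kind[j] <- kinds[pick]
  }
  out
}

#' Classify the IR/SSC junction type
#'
#' Typology driven by the ndhF gene at the IRb/SSC junction: `TYPE1` when an
#' ndhF feature lies wholly in the SSC, `TYPE2` when ndhF overlaps the
#' junction (extends into the IRb), `TYPE3` when ndhF has been lost and the
#' IR expands toward ycf1.
#'
#' @inheritParams junction_report
#' @return one of `"TYPE1"`, `"TYPE2"`, `"TYPE3"`
#' @export
classify_ir_ssc_type <- function(record, partition) {
  L <- partition$genome_length
  f <- record$features
  ndhf_ids <- unique(f$feature_id[f$name == "ndhF"])
  if (!length(ndhf_ids)) return("TYPE3")
  for (fid in ndhf_ids) {
    sp <- feature_span(record, fid)
    if (circ_intersect_len(sp, partition$IRb, L) > 0) return("TYPE2")
  }
  "TYPE1"
}

#' Audit ndh-gene intactness across genomes
#'
#' A gene is `intact` when annotated as a CDS with a valid initiation codon
#' (ATG, or the GTG/ACG alternatives seen in plastomes), no internal stop
#' codon, and length at least 90% of the supplied reference; `truncated` when
#' a feature is present but fails those checks (including pseudogene
#' annotations); `lost` when no feature exists.
#'
#' @param records list of [plastome_record()]
#' @param reference_lengths named numeric vector of intact CDS lengths for the
#'   11 ndh genes (bp)
#' @return character matrix genomes x genes with entries
#'   intact/truncated/lost
#' @export
ndh_audit <- function(records, reference_lengths) {
  genes <- intersect(NDH_GENES, names(reference_lengths))
  if (!length(genes)) stop("reference_lengths must name ndh genes", call. = FALSE)
  out <- matrix("lost", nrow = length(records), ncol = length(genes),
                dimnames = list(vapply(records, function(r) r$id, character(1)), genes))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    for (g in genes) {
      ids <- unique(rec$features$feature_id[rec$features$name == g])
      if (!length(ids)) next
      kinds <- vapply(ids, function(fid) feature_parts(rec, fid)$kind[1], character(1))
      fid <- if (any(kinds == "CDS")) ids[kinds == "CDS"][1] else ids[1]
      if (feature_parts(rec, fid)$kind[1] != "CDS") { out[i, g] <- "truncated"; next }
      s <- extract_feature_sequence(rec, fid)
      cod <- split_codons(substr(s, 1, 3 * (nchar(s) %/% 3)))
      ok_start <- substr(s, 1, 3) %in% c("ATG", "GTG", "ACG")
      internal_stop <- length(cod) > 1 && any(cod[-length(cod)] %in% STOP_CODONS)
      ok_len <- nchar(s) >= 0.9 * reference_lengths[[g]]
      out[i, g] <- if (ok_start && !internal_stop && ok_len) "intact" else "truncated"
    }
  }
  out
}

#' Ordinary least-squares length regression
#'
#' Fits `y ~ x` and reports the slope, intercept, r-squared, the F statistic
#' on (1, n-2) degrees of freedom and its two-sided p-value; used for the
#' SSC-length versus total-genome-length relationship.
#'
#' @param x,y numeric vectors of equal length (n >= 3)
#' @return list with `slope`, `intercept`, `r_squared`, `F_statistic`, `df`,
#'   `p_value`
#' @export
length_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  Fst <- r2 * (n - 2) / (1 - r2)
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, F_statistic = Fst, df = c(1, n - 2),
       p_value = stats::pf(Fst, 1, n - 2, lower.tail = FALSE))
}

#' Correlation of residual ndh length in the SSC with SSC length
#'
#' Pearson correlation between the summed residual ndh-gene sequence length
#' located in the SSC and the SSC length, across genomes.
#'
#' @param records list of [plastome_record()]
#' @param partitions list of matching [quadripartite_partition()]
#' @return list with `r` and `p_value`
#' @export
ndh_ssc_correlation <- function(records, partitions) {
  stopifnot(length(records) == length(partitions))
  if (length(records) < 3) stop("need at least 3 genomes", call. = FALSE)
  ssc <- vapply(partitions, function(p) interval_len(p$SSC), numeric(1))
  ndh <- vapply(seq_along(records), function(i) {
    rec <- records[[i]]; L <- partitions[[i]]$genome_length
    ids <- unique(rec$features$feature_id[rec$features$name %in% NDH_GENES])
    if (!length(ids)) return(0)
    sum(vapply(ids, function(fid) {
      circ_intersect_len(feature_span(rec, fid), partitions[[i]]$SSC, L)
    }, numeric(1)))
  }, numeric(1))
  if (stats::sd(ssc) == 0 || stats::sd(ndh) == 0) {
    stop("zero variance: ndh/SSC lengths are constant across genomes", call. = FALSE)
  }
  ct <- stats::cor.test(ndh, ssc, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Table of per-genome structural characteristics
#'
#' @param records list of [plastome_record()]
#' @param partitions list of matching partitions
#' @return data.frame, one row per genome (lengths, GC contents, feature
#'   counts by kind)
#' @export
structure_table <- function(records, partitions) {
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]; p <- partitions[[i]]
    l <- partition_lengths(p)
    kinds <- vapply(unique(rec$features$feature_id),
                    function(fid) feature_parts(rec, fid)$kind[1], character(1))
    data.frame(id = rec$id, total_bp = genome_length(rec),
               lsc_bp = l[["LSC"]], ssc_bp = l[["SSC"]], ir_bp = l[["IRb"]],
               gc_total = gc_content(rec),
               gc_lsc = gc_content(rec, p$LSC), gc_ssc = gc_content(rec, p$SSC),
               gc_ir = gc_content(rec, p$IRb),
               n_cds = sum(kinds == "CDS"), n_trna = sum(kinds == "tRNA"),
               n_rrna = sum(kinds == "rRNA"), n_pseudo = sum(kinds == "pseudogene"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
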