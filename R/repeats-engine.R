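# Seed-and-extend engine behind find_long_repeats().
#
# All three repeat classes reduce to plain diagonal matching between the
# sequence x and a transformed copy w (forward: w = x; reverse: w = rev(x);
# palindromic: w = revcomp(x)): x[i] is compared with w[i + e] on diagonal
# offset e.  Any admissible window of length >= min_len with <= k mismatches
# contains an exact seed of length floor(min_len / (k + 1)) (pigeonhole), so
# exact seed matches enumerate every diagonal neighborhood that can hold a
# hit; local mismatch walks then recover the maximal admissible windows.

kmer_codes <- function(chars, k) {
  b <- match(chars, DNA_BASES) - 1L          # N -> NA
  n <- length(chars)
  if (n < k) return(numeric(0))
  codes <- numeric(n - k + 1L)
  for (o in 0:(k - 1L)) codes <- codes * 4 + b[(1L + o):(n - k + 1L + o)]
  codes                                       # NA wherever the k-mer holds an N
}

# the (kmax + 1) mismatch positions nearest to `from`, walking in chunks in
# one direction along diagonal e; returns sorted positions (may be fewer
# when the diagonal boundary intervenes)
walk_mismatches <- function(xs, ws, e, from, bound, dir, kmax) {
  found <- integer(0)
  cur <- from
  chunk <- 64L
  while (length(found) <= kmax) {
    if (dir < 0) {
      if (cur < bound) break
      nxt <- max(bound, cur - chunk + 1L)
      idx <- nxt:cur
      mm <- idx[xs[idx] != ws[idx + e]]
      found <- c(mm, found)
      cur <- nxt - 1L
    } else {
      if (cur > bound) break
      nxt <- min(bound, cur + chunk - 1L)
      idx <- cur:nxt
      mm <- idx[xs[idx] != ws[idx + e]]
      found <- c(found, mm)
      cur <- nxt + 1L
    }
  }
  n <- length(found)
  if (n <= kmax + 1L) return(found)
  if (dir < 0) found[(n - kmax):n] else found[1:(kmax + 1L)]
}

# maximal admissible windows (<= kmax mismatches, match endpoints) in the
# local environment of one exact run on one diagonal.
# xs, ws: full char vectors; e: offset; run = c(lo, hi) exact-match run
# (1-based x indices); bounds = c(min_i, max_i) valid i range on the diagonal
local_windows <- function(xs, ws, e, run, bounds, kmax, min_len) {
  # one vectorized probe of min_len flanking positions resolves the
  # (kmax+1)-mismatch bounds in almost every case; walk further only when a
  # side stays unsaturated inside the probe
  seg_lo <- max(bounds[1], run[1] - min_len)
  seg_hi <- min(bounds[2], run[2] + min_len)
  idx <- seg_lo:seg_hi
  mm_seg <- idx[xs[idx] != ws[idx + e]]
  mm_left <- mm_seg[mm_seg < run[1]]
  mm_right <- mm_seg[mm_seg > run[2]]
  nl <- length(mm_left)
  if (nl > kmax) {
    mm_left <- mm_left[(nl - kmax):nl]
  } else if (seg_lo > bounds[1]) {
    mm_left <- walk_mismatches(xs, ws, e, run[1] - 1L, bounds[1], -1L, kmax)
  }
  nr <- length(mm_right)
  if (nr > kmax) {
    mm_right <- mm_right[1:(kmax + 1L)]
  } else if (seg_hi < bounds[2]) {
    mm_right <- walk_mismatches(xs, ws, e, run[2] + 1L, bounds[2], 1L, kmax)
  }
  lo_bound <- if (length(mm_left) > kmax) mm_left[1] else bounds[1]
  hi_bound <- if (length(mm_right) > kmax) mm_right[length(mm_right)] else bounds[2]
  if (hi_bound - lo_bound + 1L < min_len) {
    return(matrix(integer(0), ncol = 2))
  }
  mm <- c(mm_left[mm_left >= lo_bound], mm_right[mm_right <= hi_bound])
  n_local <- hi_bound - lo_bound + 1L
  win <- max_mismatch_windows(mm - lo_bound + 1L, n_local, kmax)
  if (!nrow(win)) return(win)
  win <- win + lo_bound - 1L
  win[win[, 2] - win[, 1] + 1L >= min_len, , drop = FALSE]
}

# enumerate maximal admissible windows across all diagonals with >= 1 seed
seeded_diag_windows <- function(xs, ws, min_len, kmax, offsets = NULL) {
  n <- length(xs); nw <- length(ws)
  k <- max(4L, min_len %/% (kmax + 1L))
  cx <- kmer_codes(xs, k)
  cw <- kmer_codes(ws, k)
  ix <- which(!is.na(cx)); iw <- which(!is.na(cw))
  sx <- split(ix, cx[ix]); sw <- split(iw, cw[iw])
  shared <- intersect(names(sx), names(sw))
  if (!length(shared)) return(cbind(e = integer(0), lo = integer(0), hi = integer(0)))
  pe_l <- vector("list", length(shared)); pi_l <- vector("list", length(shared))
  for (ci in seq_along(shared)) {
    x <- sx[[shared[ci]]]; j <- sw[[shared[ci]]]
    xi <- rep(x, each = length(j))
    ji <- rep(j, length(x))
    pe_l[[ci]] <- ji - xi
    pi_l[[ci]] <- xi
  }
  pe <- unlist(pe_l); pi <- unlist(pi_l)
  if (!is.null(offsets)) {
    keep <- offsets(pe)
    pe <- pe[keep]; pi <- pi[keep]
  }
  if (!length(pe)) return(cbind(e = integer(0), lo = integer(0), hi = integer(0)))
  o <- order(pe, pi)
  pe <- pe[o]; pi <- pi[o]
  res <- list()
  idx <- 1L
  N <- length(pe)
  while (idx <= N) {
    e <- pe[idx]
    bounds <- c(max(1L, 1L - e), min(n, nw - e))
    last_cov <- -1L
    while (idx <= N && pe[idx] == e) {
      i <- pi[idx]
      idx <- idx + 1L
      if (i <= last_cov) next
      # exact run around the seed
      lo <- i
      while (lo - 1L >= bounds[1] && xs[lo - 1L] == ws[lo - 1L + e]) lo <- lo - 1L
      hi <- i + k - 1L
      while (hi + 1L <= bounds[2] && xs[hi + 1L] == ws[hi + 1L + e]) hi <- hi + 1L
      last_cov <- hi
      win <- local_windows(xs, ws, e, c(lo, hi), bounds, kmax, min_len)
      for (r in seq_len(nrow(win))) {
        res[[length(res) + 1L]] <- c(e, win[r, 1], win[r, 2])
      }
    }
  }
  if (!length(res)) return(cbind(e = integer(0), lo = integer(0), hi = integer(0)))
  m <- unique(do.call(rbind, res))
  colnames(m) <- c("e", "lo", "hi")
  m
}

repeat_rows_from_windows <- function(win, class, xs, ws, n, min_len) {
  rows <- list()
  for (r in seq_len(nrow(win))) {
    e <- win[r, "e"]; lo <- win[r, "lo"]; hi <- win[r, "hi"]
    nmis <- sum(xs[lo:hi] != ws[(lo:hi) + e])
    if (class == "forward") {
      rows[[length(rows) + 1L]] <- data.frame(
        class = class, length = hi - lo + 1L, mismatches = nmis,
        start1 = lo - 1L, end1 = hi, start2 = lo + e - 1L, end2 = hi + e,
        stringsAsFactors = FALSE)
    } else {
      # w index j pairs with original index m - i where m = n + 1 - e
      m <- n + 1L - e
      lo2 <- m - hi; hi2 <- m - lo
      if (lo > lo2) next                       # mirror duplicate
      if (lo == lo2) {                         # self-symmetric: report halves
        len <- hi - lo + 1L
        half <- len %/% 2L
        if (half < min_len) next
        h1 <- c(lo, lo + half - 1L)
        h2 <- c(hi - half + 1L, hi)
        nmis <- sum(xs[h1[1]:h1[2]] != ws[(h1[1]:h1[2]) + e])
        rows[[length(rows) + 1L]] <- data.frame(
          class = class, length = half, mismatches = nmis,
          start1 = h1[1] - 1L, end1 = h1[2], start2 = h2[1] - 1L, end2 = h2[2],
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          class = class, length = hi - lo + 1L, mismatches = nmis,
          start1 = lo - 1L, end1 = hi, start2 = lo2 - 1L, end2 = hi2,
          stringsAsFactors = FALSE)
      }
    }
  }
  rows
}
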