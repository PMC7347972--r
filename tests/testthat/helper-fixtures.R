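# Shared fixtures (memoized across test files) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

# reduced-scale plans for fast structural simulations
small_length_plan <- function() list(LSC = 9000, SSC = 2400, IR = 3000)

small_gene_plan <- function() {
  g <- function(name, kind, region, len, strand = "+", intron_len = 0,
                start_codon = "ATG") {
    data.frame(name = name, kind = kind, region = region, len = len,
               strand = strand, intron_len = intron_len,
               start_codon = start_codon, stringsAsFactors = FALSE)
  }
  rbind(
    g("psbA", "CDS", "LSC", 600, "-"),
    g("matK", "CDS", "LSC", 900),
    g("trnR", "tRNA", "LSC", 72),
    g("atpF", "CDS", "LSC", 450, "-", intron_len = 400),
    g("rpl22", "CDS", "LSC", 300),
    g("rps19", "CDS", "IR", 279, "-", start_codon = "GTG"),
    g("rrn16", "rRNA", "IR", 900),
    g("ndhF", "CDS", "SSC", 450, "-"),
    g("ndhG", "CDS", "SSC", 270, "-"),
    g("rps15", "CDS", "SSC", 150))
}

small_ancestor <- function(seed = 1, ...) {
  build_ancestor(length_plan = small_length_plan(),
                 gene_plan = small_gene_plan(), seed = seed,
                 ssr_plan = utils::head(default_ssr_plan(), 4), ...)
}

# the default eight-taxon study simulation, built once
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    anc <- build_ancestor(seed = 1)
    .fixture_env$sim <- evolve(anc, default_evolution_config(seed = 1))
  }
  .fixture_env$sim
}

quick_tree4 <- function() {
  ape::read.tree(text = "((a:0.1,b:0.12):0.05,c:0.1,d:0.15);")
}

quick_tree8 <- function() {
  ape::read.tree(text = paste0("((a:0.15,b:0.18):0.08,((c:0.12,d:0.15):0.06,",
                               "(e:0.15,f:0.13):0.08):0.05,(g:0.18,h:0.12):0.06);"))
}

random_seq <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- brute-force repeat oracle -------------------------------------------
# Independent enumeration: for every match position lo on a diagonal, the
# right-maximal admissible window is computed from cumulative mismatch
# counts; left-maximality is then verified explicitly.  Mirrors the
# reported-pair semantics (mirror dedup, self-symmetric halving) but shares
# no code with the engine.
oracle_diag_windows <- function(is_mismatch, kmax, min_len) {
  n <- length(is_mismatch)
  if (n < min_len) return(NULL)
  cs <- cumsum(is_mismatch)
  cs0 <- c(0L, cs)
  pm <- cummax(ifelse(!is_mismatch, seq_len(n), 0L))   # last match <= j
  lo <- which(!is_mismatch)
  hi_raw <- findInterval(cs0[lo] + kmax, cs)           # largest hi, <= kmax mism
  hi <- ifelse(hi_raw >= 1, pm[pmax(hi_raw, 1)], 0L)   # trim to a match
  keep <- hi - lo + 1L >= min_len
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(NULL)
  pl <- ifelse(lo > 1, pm[pmax(lo - 1L, 1)], 0L)       # previous match < lo
  extendable <- pl > 0 & (cs[hi] - cs0[pmax(pl, 1)]) <= kmax
  out <- cbind(lo[!extendable], hi[!extendable])
  unique(out)
}

oracle_repeats <- function(seq, min_len = 30, max_mismatch = 3,
                           classes = c("forward", "reverse", "palindromic")) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  rows <- list()
  if ("forward" %in% classes) {
    for (d in seq_len(L - min_len)) {
      mm <- x[seq_len(L - d)] != x[seq_len(L - d) + d]
      win <- oracle_diag_windows(mm, max_mismatch, min_len)
      for (r in seq_len(NROW(win))) {
        lo <- win[r, 1]; hi <- win[r, 2]
        rows[[length(rows) + 1]] <- data.frame(
          class = "forward", length = hi - lo + 1L,
          mismatches = sum(mm[lo:hi]),
          start1 = lo - 1L, end1 = hi, start2 = lo + d - 1L, end2 = hi + d,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (cl in intersect(classes, c("reverse", "palindromic"))) {
    y <- if (cl == "palindromic") comp else x
    for (m in seq(2L, 2L * L)) {
      ilo <- max(1L, m - L); ihi <- min(L, m - 1L)
      if (ihi - ilo + 1L < min_len) next
      idx <- ilo:ihi
      mm <- x[idx] != y[m - idx]
      win <- oracle_diag_windows(mm, max_mismatch, min_len)
      for (r in seq_len(NROW(win))) {
        lo <- win[r, 1] + ilo - 1L; hi <- win[r, 2] + ilo - 1L
        lo2 <- m - hi; hi2 <- m - lo
        if (lo > lo2) next
        nm <- sum(mm[(lo:hi) - ilo + 1L])
        if (lo == lo2) {
          half <- (hi - lo + 1L) %/% 2L
          if (half < min_len) next
          h1 <- c(lo, lo + half - 1L); h2 <- c(hi - half + 1L, hi)
          nm <- sum(mm[(h1[1]:h1[2]) - ilo + 1L])
          rows[[length(rows) + 1]] <- data.frame(
            class = cl, length = half, mismatches = nm,
            start1 = h1[1] - 1L, end1 = h1[2], start2 = h2[1] - 1L, end2 = h2[2],
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            class = cl, length = hi - lo + 1L, mismatches = nm,
            start1 = lo - 1L, end1 = hi, start2 = lo2 - 1L, end2 = hi2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(plastocomp:::empty_repeat_df())
  res <- unique(do.call(rbind, rows))
  res <- res[order(res$class, res$start1, res$start2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

repeat_key <- function(df) {
  apply(df[, c("class", "start1", "end1", "start2", "end2")], 1, paste,
        collapse = "|")
}

# ---- exhaustive codon-likelihood oracle ----------------------------------
# Sums over all ancestral-state assignments; R-side eigen path, independent
# of the compiled pruning kernel.
oracle_codon_lnl <- function(states, tree, pi, kappa, omegas, weights) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  states <- states[tr$tip.label, , drop = FALSE]
  internal <- sort(unique(tr$edge[, 1]))
  stopifnot(length(internal) <= 2)
  mu <- plastocomp:::codon_mixture_mu(pi, kappa, omegas, weights)
  root <- ntip + 1L
  n <- ncol(states)
  total <- 0
  site_lik <- rep(0, n)
  for (k in seq_along(omegas)) {
    Ps <- lapply(seq_len(nrow(tr$edge)), function(e) {
      plastocomp:::codon_Pmat(pi, kappa, omegas[k], tr$edge.length[e], mu)
    })
    combos <- if (length(internal) == 2) {
      expand.grid(r = 1:61, v = 1:61)
    } else {
      data.frame(r = 1:61, v = NA)
    }
    for (s in seq_len(n)) {
      acc <- 0
      for (ci in seq_len(nrow(combos))) {
        assign_state <- function(node) {
          if (node <= ntip) return(states[node, s])
          if (node == root) combos$r[ci] else combos$v[ci]
        }
        pr <- pi[combos$r[ci]]
        for (e in seq_len(nrow(tr$edge))) {
          pr <- pr * Ps[[e]][assign_state(tr$edge[e, 1]), assign_state(tr$edge[e, 2])]
        }
        acc <- acc + pr
      }
      site_lik[s] <- site_lik[s] + weights[k] * acc
    }
  }
  sum(log(site_lik))
}

# per-column recount oracles for alignment statistics
oracle_eta <- function(m) {
  tot <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) next
    st <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(st) >= 1) tot <- tot + length(st) - 1L
  }
  tot
}

oracle_pis <- function(m) {
  tot <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) next
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    if (sum(tab >= 2) >= 2) tot <- tot + 1L
  }
  tot
}

oracle_indel_events <- function(m) {
  spans <- character(0)
  for (i in seq_len(nrow(m))) {
    gap <- m[i, ] == "-"
    j <- 1
    while (j <= length(gap)) {
      if (gap[j]) {
        k <- j
        while (k < length(gap) && gap[k + 1]) k <- k + 1
        spans <- c(spans, paste(j, k))
        j <- k + 1
      } else j <- j + 1
    }
  }
  length(unique(spans))
}

oracle_conserved <- function(m) {
  tot <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) next
    st <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(st) <= 1) tot <- tot + 1L
  }
  tot
}
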