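# Evolution of a synthetic ancestor along a tree, with a complete truth log
# (true alignment via stable column keys, per-branch event lists, SSR and
# planted-repeat coordinates, true site classes for genes under selection).

#' Evolution configuration
#'
#' @param tree newick string or `ape::phylo` with branch lengths
#'   (substitutions per site at the CDS-class rate)
#' @param region_rates named multipliers per region class
#' @param indel_rate indel events per eligible site per unit branch length
#' @param indel_length geometric length parameter in (0, 1]
#' @param ssr_slippage_rate per-locus per-branch probability of a one-unit
#'   slippage
#' @param ndh_loss_events data.frame with `branch` (tip label), `gene`,
#'   `action` (`"delete"` or `"truncate"`), or `NULL`
#' @param planted_repeats data.frame with `class`, `length`, `mismatches`,
#'   or `NULL`
#' @param selection_genes data.frame with `gene`, `p0`, `p`, `q`, `omega_s`,
#'   or `NULL`
#' @param kappa HKY transition/transversion rate ratio
#' @param seed integer seed
#' @return list of class `evolution_config`
#' @export
evolution_config <- function(tree,
                             region_rates = c(CDS = 1, intron = 1.38, IGS = 2.02),
                             indel_rate = 0.4, indel_length = 0.35,
                             ssr_slippage_rate = 0.3,
                             ndh_loss_events = NULL, planted_repeats = NULL,
                             selection_genes = NULL, kappa = 2, seed = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(region_rates < 0) || indel_rate < 0 || ssr_slippage_rate < 0 ||
      ssr_slippage_rate > 1) {
    stop("rates must be nonnegative (slippage in [0,1])", call. = FALSE)
  }
  if (indel_length <= 0 || indel_length > 1) {
    stop("geometric length parameter must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(all(c("CDS", "intron", "IGS") %in% names(region_rates)))
  if (!is.null(ndh_loss_events)) {
    stopifnot(all(c("branch", "gene", "action") %in% names(ndh_loss_events)))
    if (!all(ndh_loss_events$branch %in% tree$tip.label)) {
      stop("ndh_loss_events name unknown branches", call. = FALSE)
    }
    if (!all(ndh_loss_events$action %in% c("delete", "truncate"))) {
      stop("ndh_loss_events action must be delete/truncate", call. = FALSE)
    }
  }
  structure(list(tree = tree, region_rates = region_rates,
                 indel_rate = indel_rate, indel_length = indel_length,
                 ssr_slippage_rate = ssr_slippage_rate,
                 ndh_loss_events = ndh_loss_events,
                 planted_repeats = planted_repeats,
                 selection_genes = selection_genes,
                 kappa = kappa, seed = as.integer(seed)),
            class = "evolution_config")
}

#' Default eight-taxon study configuration
#'
#' An eight-leaf tree at plastome-scale divergence with independent ndh
#' losses on several lineages (ndhF lost twice independently, other ndh
#' genes truncated), mirroring the structural variation the analysis
#' pipeline is meant to detect.
#'
#' @param seed integer seed
#' @return an [evolution_config()]
#' @export
default_evolution_config <- function(seed = 1) {
  tree <- paste0("((sp1:0.004,sp2:0.006):0.003,(sp3:0.005,(sp4:0.004,",
                 "sp5:0.007):0.004):0.002,(sp6:0.006,(sp7:0.005,sp8:0.004)",
                 ":0.003):0.002);")
  ndh <- data.frame(
    branch = c("sp3", "sp3", "sp6", "sp6", "sp6", "sp2", "sp7", "sp8", "sp4"),
    gene = c("ndhF", "ndhD", "ndhF", "ndhA", "ndhH", "ndhK", "ndhI", "ndhE", "ndhG"),
    action = c("delete", "delete", "delete", "delete", "truncate", "truncate",
               "truncate", "truncate", "truncate"),
    stringsAsFactors = FALSE)
  evolution_config(tree = tree, ndh_loss_events = ndh,
                   planted_repeats = data.frame(
                     class = c("forward", "palindromic", "reverse"),
                     length = c(42, 36, 34), mismatches = c(2, 0, 1),
                     stringsAsFactors = FALSE),
                   selection_genes = data.frame(
                     gene = "matK", p0 = 0.9, p = 0.4, q = 1.8, omega_s = 3,
                     stringsAsFactors = FALSE),
                   seed = seed)
}

# ---- node-state helpers ---------------------------------------------------

class_vec_from_features <- function(features, L) {
  cls <- integer(L)
  for (fid in unique(features$feature_id)) {
    p <- features[features$feature_id == fid, , drop = FALSE]
    p <- p[order(p$part), , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      idx <- (p$start[i] + 1):p$end[i]
      cls[idx][cls[idx] < 2L] <- 2L
    }
    if (nrow(p) > 1 && !p$wrap[1]) {
      o <- order(p$start)
      for (i in seq_len(nrow(p) - 1)) {
        if (p$end[o][i] < p$start[o][i + 1]) {
          gap <- (p$end[o][i] + 1):p$start[o][i + 1]
          cls[gap][cls[gap] < 1L] <- 1L
        }
      }
    }
  }
  cls
}

shift_coords <- function(state, at, delta) {
  f <- state$features
  f$start <- ifelse(f$start >= at, f$start + delta, f$start)
  f$end <- ifelse(f$end >= at, f$end + delta, f$end)
  state$features <- f
  state$partition <- lapply(state$partition, function(iv) {
    ifelse(iv >= at, iv + delta, iv)
  })
  if (nrow(state$ssr)) {
    state$ssr$start <- ifelse(state$ssr$start >= at, state$ssr$start + delta,
                              state$ssr$start)
  }
  state
}

# delete 0-based [d0, d0 + len)
apply_deletion <- function(state, d0, len) {
  idx <- (d0 + 1):(d0 + len)
  if (nrow(state$ssr)) {
    hit <- state$ssr$start < d0 + len &
      (state$ssr$start + state$ssr$unit * state$ssr$count) > d0
    state$ssr <- state$ssr[!hit, , drop = FALSE]
  }
  for (fld in c("seq", "keys", "class_vec", "sub_excl", "indel_excl")) {
    state[[fld]] <- state[[fld]][-idx]
  }
  shift_coords(state, d0 + len, -len)
}

# insert after 0-based point p0 (inserted bases occupy [p0, p0 + len))
apply_insertion <- function(state, p0, bases, new_keys, class_val,
                            excl = FALSE) {
  len <- length(bases)
  ins <- function(v, vals) append(v, vals, after = p0)
  state$seq <- ins(state$seq, bases)
  state$keys <- ins(state$keys, new_keys)
  state$class_vec <- ins(state$class_vec, rep(class_val, len))
  state$sub_excl <- ins(state$sub_excl, rep(excl, len))
  state$indel_excl <- ins(state$indel_excl, rep(excl, len))
  shift_coords(state, p0, len)
}

region_of <- function(partition, pos0) {
  for (r in c("LSC", "IRb", "SSC", "IRa")) {
    iv <- partition[[r]]
    if (pos0 >= iv[1] && pos0 < iv[2]) return(r)
  }
  NA_character_
}

hky_jump <- function(old, kappa, freqs) {
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  others <- setdiff(DNA_BASES, old)
  w <- freqs[others] * ifelse(others == partner[[old]], kappa, 1)
  others[sample.int(3, 1, prob = w)]
}

set_reading_bases <- function(state, fid, offset0, bases) {
  p <- state$features[state$features$feature_id == fid, , drop = FALSE]
  p <- p[order(p$part), , drop = FALSE]
  nb <- length(bases)
  acc <- 0L
  for (i in seq_len(nrow(p))) {
    pl <- p$end[i] - p$start[i]
    r0 <- max(offset0, acc); r1 <- min(offset0 + nb, acc + pl)
    if (r1 > r0) {
      rr <- r0:(r1 - 1)
      if (p$strand[i] == "+") {
        g <- p$start[i] + (rr - acc)
        state$seq[g + 1] <- bases[rr - offset0 + 1]
      } else {
        g <- p$end[i] - 1 - (rr - acc)
        state$seq[g + 1] <- chartr("ACGTN", "TGCAN", bases[rr - offset0 + 1])
      }
    }
    acc <- acc + pl
  }
  state
}

reading_positions <- function(state, fid) {
  p <- state$features[state$features$feature_id == fid, , drop = FALSE]
  p <- p[order(p$part), , drop = FALSE]
  out <- integer(0)
  for (i in seq_len(nrow(p))) {
    g <- if (p$strand[i] == "+") p$start[i]:(p$end[i] - 1) else (p$end[i] - 1):p$start[i]
    out <- c(out, g)
  }
  out                                     # 0-based genome position per reading index
}

feature_id_by_name <- function(features, name, kind = NULL) {
  sel <- features$name == name
  if (!is.null(kind)) sel <- sel & features$kind %in% kind
  ids <- unique(features$feature_id[sel])
  if (!length(ids)) return(NA_integer_)
  ids[1]
}

# plant one dispersed repeat pair into LSC intergenic sequence of the root
# state; returns the updated state plus the truth row
plant_one_repeat <- function(state, class, len, mismatches) {
  cls <- state$class_vec
  lsc <- state$partition$LSC
  ok <- which(cls == 0L & !state$indel_excl & !state$sub_excl &
                seq_along(cls) - 1 >= lsc[1] & seq_along(cls) - 1 < lsc[2])
  runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  runs <- runs[vapply(runs, length, integer(1)) >= len + 4]
  if (length(runs) < 2) stop("no room to plant repeats", call. = FALSE)
  pick <- sample(length(runs), 2)
  src_run <- runs[[pick[1]]]; tgt_run <- runs[[pick[2]]]
  s1 <- src_run[2]                          # 1-based vector index
  s2 <- tgt_run[2]
  if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
  piece <- state$seq[s1:(s1 + len - 1)]
  copy <- switch(class,
                 forward = piece,
                 reverse = rev(piece),
                 palindromic = revcomp_chars(piece))
  if (mismatches > 0) {
    mpos <- sample(2:(len - 1), mismatches)
    for (m in mpos) copy[m] <- sample(setdiff(DNA_BASES, copy[m]), 1)
  }
  state$seq[s2:(s2 + len - 1)] <- copy
  # sharpen flanks so the planted pair is maximal at its stated length
  if (class == "forward") {
    if (state$seq[s1 - 1] == state$seq[s2 - 1]) {
      state$seq[s2 - 1] <- sample(setdiff(DNA_BASES, state$seq[s1 - 1]), 1)
    }
    if (state$seq[s1 + len] == state$seq[s2 + len]) {
      state$seq[s2 + len] <- sample(setdiff(DNA_BASES, state$seq[s1 + len]), 1)
    }
  } else {
    tf <- if (class == "palindromic") function(b) chartr("ACGTN", "TGCAN", b) else identity
    if (state$seq[s1 - 1] == tf(state$seq[s2 + len])) {
      state$seq[s2 + len] <- sample(setdiff(DNA_BASES, state$seq[s2 + len]), 1)
      if (state$seq[s1 - 1] == tf(state$seq[s2 + len])) {
        state$seq[s2 + len] <- sample(setdiff(DNA_BASES, c(state$seq[s2 + len],
          ifelse(class == "palindromic", chartr("ACGTN", "TGCAN", state$seq[s1 - 1]),
                 state$seq[s1 - 1]))), 1)
      }
    }
    if (state$seq[s1 + len] == tf(state$seq[s2 - 1])) {
      state$seq[s2 - 1] <- sample(setdiff(DNA_BASES, c(state$seq[s2 - 1],
        ifelse(class == "palindromic", chartr("ACGTN", "TGCAN", state$seq[s1 + len]),
               state$seq[s1 + len]))), 1)
    }
  }
  mark <- c((s1 - 1):(s1 + len), (s2 - 1):(s2 + len))
  state$sub_excl[mark] <- TRUE
  state$indel_excl[mark] <- TRUE
  list(state = state,
       truth = data.frame(class = class, length = len, mismatches = mismatches,
                          start1 = s1 - 1, end1 = s1 - 1 + len,
                          start2 = s2 - 1, end2 = s2 - 1 + len,
                          stringsAsFactors = FALSE))
}

#' Evolve a synthetic ancestor along a tree
#'
#' Substitutions follow HKY with per-region-class rate multipliers (events
#' sampled as Poisson counts per class and branch); indels have geometric
#' lengths and are restricted to non-coding single-copy sequence; mutations
#' sampled in the IRb are mirrored into the IRa so the inverted repeats stay
#' identical; ndh loss events delete or truncate their gene on the named
#' terminal branch (deletions shrink the SSC); planted SSR loci undergo
#' one-unit slippage.  Genes listed in `selection_genes` evolve under the
#' M8 codon mixture via [simulate_codon_gene()] on the same tree and are
#' spliced in with their per-branch substitutions logged.
#'
#' @param ancestor a [build_ancestor()] record (attributes `partition` and
#'   `ssr_truth` are used)
#' @param config an [evolution_config()]
#' @return list with `records` (named list of leaf [plastome_record()]s,
#'   each carrying its `partition` attribute) and `truth` (a `truth_log`:
#'   `true_alignment`, `events`, `ssr`, `planted_repeats`, `selection`,
#'   `config`)
#' @export
evolve <- function(ancestor, config) {
  stopifnot(inherits(config, "evolution_config"))
  set.seed(stage_seed(config$seed, "evolve"))
  tree <- stats::reorder(config$tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  part0 <- attr(ancestor, "partition")
  if (is.null(part0)) part0 <- detect_inverted_repeat(ancestor)
  ssr0 <- attr(ancestor, "ssr_truth") %||%
    data.frame(motif = character(0), unit = integer(0), count = integer(0),
               start = integer(0), stringsAsFactors = FALSE)
  L0 <- genome_length(ancestor)
  freqs <- stats::setNames(rep(0, 4), DNA_BASES)
  tab <- table(factor(strsplit(ancestor$sequence, "")[[1]], levels = DNA_BASES))
  freqs[] <- as.numeric(tab) / sum(tab)

  state <- list(seq = strsplit(ancestor$sequence, "", fixed = TRUE)[[1]],
                keys = as.numeric(seq_len(L0)),
                features = ancestor$features,
                partition = list(LSC = part0$LSC, IRb = part0$IRb,
                                 SSC = part0$SSC, IRa = part0$IRa),
                ssr = ssr0,
                sub_excl = logical(L0), indel_excl = logical(L0))
  state$class_vec <- class_vec_from_features(state$features, L0)
  # shield planted SSR loci from substitutions/indels (slippage handles them)
  if (nrow(ssr0)) {
    for (i in seq_len(nrow(ssr0))) {
      span <- (ssr0$start[i]):(ssr0$start[i] + ssr0$unit[i] * ssr0$count[i] + 1)
      state$sub_excl[span] <- TRUE
      state$indel_excl[span] <- TRUE
    }
  }
  # selection genes: shield from HKY substitutions (codon process instead)
  sel <- config$selection_genes
  if (!is.null(sel)) {
    for (g in sel$gene) {
      fid <- feature_id_by_name(state$features, g, kind = "CDS")
      if (is.na(fid)) stop(sprintf("selection gene '%s' not in ancestor", g), call. = FALSE)
      sp <- feature_span(list(features = state$features), fid)
      if (region_of(state$partition, sp[1]) %in% c("IRb", "IRa")) {
        stop("selection genes must lie in single-copy regions", call. = FALSE)
      }
      state$sub_excl[(sp[1] + 1):sp[2]] <- TRUE
    }
  }

  truth_repeats <- NULL
  if (!is.null(config$planted_repeats)) {
    for (i in seq_len(nrow(config$planted_repeats))) {
      pr <- config$planted_repeats[i, ]
      res <- plant_one_repeat(state, pr$class, pr$length, pr$mismatches)
      state <- res$state
      truth_repeats <- rbind(truth_repeats, res$truth)
    }
    # planted repeats change the ancestor sequence
    ancestor$sequence <- paste(state$seq, collapse = "")
  }

  # events accumulate as chunks of parallel vectors; one concatenation at
  # the end keeps logging O(1) per event
  ev <- new.env(parent = emptyenv())
  ev$chunks <- list()
  log_event <- function(branch, type, class, key, length = 1L,
                        gene = NA_character_, from = NA_character_,
                        to = NA_character_) {
    k <- base::length(ev$chunks) + 1L
    n <- base::length(key)
    ev$chunks[[k]] <- list(branch = rep_len(branch, n), type = rep_len(type, n),
                           class = rep_len(class, n), key = key,
                           len = rep_len(as.integer(length), n),
                           gene = rep_len(gene, n), from = rep_len(from, n),
                           to = rep_len(to, n))
  }
  class_names <- c("IGS", "intron", "CDS")

  evolve_branch <- function(state, b, branch) {
    L <- length(state$seq)
    # 1. ndh loss events
    ev <- config$ndh_loss_events
    if (!is.null(ev)) {
      mine <- ev[ev$branch == branch, , drop = FALSE]
      for (i in seq_len(nrow(mine))) {
        fid <- feature_id_by_name(state$features, mine$gene[i], kind = "CDS")
        if (is.na(fid)) stop(sprintf("gene '%s' absent on branch %s",
                                     mine$gene[i], branch), call. = FALSE)
        if (mine$action[i] == "delete") {
          sp <- feature_span(list(features = state$features), fid)
          log_event(branch, "ndh_del", "CDS", state$keys[sp[1] + 1],
                    length = sp[2] - sp[1], gene = mine$gene[i])
          state$features <- state$features[state$features$feature_id != fid, , drop = FALSE]
          state <- apply_deletion(state, sp[1], sp[2] - sp[1])
          state$class_vec <- class_vec_from_features(state$features, length(state$seq))
        } else {
          rp <- reading_positions(state, fid)
          ncod <- length(rp) %/% 3
          mid <- (ncod %/% 2)                     # 0-based codon index
          state <- set_reading_bases(state, fid, 3 * mid, c("T", "A", "A"))
          log_event(branch, "ndh_trunc", "CDS", state$keys[rp[3 * mid + 1] + 1],
                    length = 3L, gene = mine$gene[i])
        }
      }
      L <- length(state$seq)
    }
    ira <- state$partition$IRa
    irb <- state$partition$IRb
    pos0 <- seq_len(L) - 1L
    in_ira <- pos0 >= ira[1] & pos0 < ira[2]
    # 2. substitutions, Poisson event counts per class
    for (code in 0:2) {
      mult <- config$region_rates[[class_names[code + 1]]]
      elig <- which(state$class_vec == code & !state$sub_excl & !in_ira)
      if (!length(elig) || mult == 0) next
      n <- stats::rpois(1, b * mult * length(elig))
      if (n == 0) next
      hits <- elig[sample.int(length(elig), n, replace = TRUE)]
      olds <- character(0); news <- character(0); keys <- numeric(0)
      molds <- character(0); mnews <- character(0); mkeys <- numeric(0)
      for (i in hits) {
        old <- state$seq[i]
        if (old == "N") next
        new <- hky_jump(old, config$kappa, freqs)
        state$seq[i] <- new
        olds[length(olds) + 1L] <- old
        news[length(news) + 1L] <- new
        keys[length(keys) + 1L] <- state$keys[i]
        p0 <- i - 1L
        if (p0 >= irb[1] && p0 < irb[2]) {       # mirror into IRa
          mp <- ira[1] + (irb[2] - 1 - p0)
          state$seq[mp + 1] <- chartr("ACGT", "TGCA", new)
          molds[length(molds) + 1L] <- old
          mnews[length(mnews) + 1L] <- new
          mkeys[length(mkeys) + 1L] <- state$keys[mp + 1]
        }
      }
      if (length(keys)) {
        log_event(branch, "sub", class_names[code + 1], keys,
                  from = olds, to = news)
      }
      if (length(mkeys)) {
        log_event(branch, "sub_mirror", class_names[code + 1], mkeys,
                  from = molds, to = mnews)
      }
    }
    # 3. indels (non-coding, single-copy only)
    lsc <- state$partition$LSC; ssc <- state$partition$SSC
    insc <- (pos0 >= lsc[1] & pos0 < lsc[2]) | (pos0 >= ssc[1] & pos0 < ssc[2])
    elig <- which(state$class_vec <= 1L & !state$indel_excl & insc)
    if (length(elig) && config$indel_rate > 0) {
      n <- stats::rpois(1, b * config$indel_rate * length(elig))
      for (k in seq_len(n)) {
        L <- length(state$seq)
        i <- elig[sample.int(length(elig), 1)]
        if (i > L) next                          # coordinates moved; skip
        len <- min(stats::rgeom(1, config$indel_length) + 1L, 30L)
        if (stats::runif(1) < 0.5) {             # insertion after i
          if (i >= L || state$class_vec[i + 1] != state$class_vec[i] ||
              state$indel_excl[i + 1] || state$indel_excl[i]) next
          bases <- sample(DNA_BASES, len, replace = TRUE, prob = freqs)
          a <- state$keys[i]; nxt <- if (i < L) state$keys[i + 1] else a + 1
          step <- (nxt - a) / (len + 1)
          nk <- a + (1:len) * step + stats::runif(len, 0, step * 1e-3)
          nk <- sort(nk)
          state <- apply_insertion(state, i, bases, nk, state$class_vec[i])
          log_event(branch, "ins", class_names[state$class_vec[i] + 1], a,
                    length = len)
          elig <- which(state$class_vec <= 1L & !state$indel_excl &
                          {p <- seq_along(state$seq) - 1L
                           (p >= state$partition$LSC[1] & p < state$partition$LSC[2]) |
                             (p >= state$partition$SSC[1] & p < state$partition$SSC[2])})
        } else {                                 # deletion from i
          j <- i
          while (j - i + 1L < len && j + 1L <= length(state$seq) &&
                 state$class_vec[j + 1] == state$class_vec[i] &&
                 !state$indel_excl[j + 1] &&
                 identical(region_of(state$partition, j), region_of(state$partition, i - 1L))) {
            j <- j + 1L
          }
          dlen <- j - i + 1L
          log_event(branch, "del", class_names[state$class_vec[i] + 1],
                    state$keys[i], length = dlen)
          state <- apply_deletion(state, i - 1L, dlen)
          elig <- which(state$class_vec <= 1L & !state$indel_excl &
                          {p <- seq_along(state$seq) - 1L
                           (p >= state$partition$LSC[1] & p < state$partition$LSC[2]) |
                             (p >= state$partition$SSC[1] & p < state$partition$SSC[2])})
        }
      }
    }
    # 4. SSR slippage
    if (nrow(state$ssr) && config$ssr_slippage_rate > 0) {
      for (r in seq_len(nrow(state$ssr))) {
        if (stats::runif(1) >= config$ssr_slippage_rate) next
        u <- state$ssr$unit[r]; cnt <- state$ssr$count[r]
        s0 <- state$ssr$start[r]
        dir <- sample(c(-1L, 1L), 1)
        if (cnt + dir < 2L) dir <- 1L
        if (dir == 1L) {
          p0 <- s0 + u
          bases <- state$seq[(s0 + 1):(s0 + u)]
          a <- state$keys[p0]; nxt <- state$keys[p0 + 1]
          step <- (nxt - a) / (u + 1)
          nk <- sort(a + (1:u) * step + stats::runif(u, 0, step * 1e-3))
          state <- apply_insertion(state, p0, bases, nk, 0L, excl = TRUE)
          # insertion shifted this locus' own start; restore it
          state$ssr$start[r] <- s0
        } else {
          state$ssr$count[r] <- cnt - 1L         # keep the row: deletion drops overlaps
          saved <- state$ssr[r, , drop = FALSE]
          state$ssr <- state$ssr[-r, , drop = FALSE]
          log_dummy <- NULL
          state <- apply_deletion(state, s0, u)
          saved$start <- s0
          state$ssr <- rbind(state$ssr, saved)
          state$ssr <- state$ssr[order(state$ssr$start), , drop = FALSE]
        }
        if (dir == 1L) state$ssr$count[r] <- cnt + 1L
        log_event(branch, "ssr", "IGS", state$keys[s0 + 1], length = u * dir,
                  gene = state$ssr$motif[pmin(r, nrow(state$ssr))])
      }
    }
    state
  }

  node_states <- vector("list", ntip + tree$Nnode)
  node_states[[root]] <- state
  labels <- c(tree$tip.label, paste0("node", (ntip + 1):(ntip + tree$Nnode)))
  for (e in rev(seq_len(nrow(tree$edge)))) {     # preorder
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    node_states[[child]] <- evolve_branch(node_states[[parent]],
                                          tree$edge.length[e], labels[child])
  }

  # selection genes: codon-mixture evolution spliced over the HKY background
  selection_truth <- list()
  if (!is.null(sel)) {
    for (i in seq_len(nrow(sel))) {
      g <- sel$gene[i]
      fid0 <- feature_id_by_name(state$features, g, kind = "CDS")
      rlen <- length(reading_positions(state, fid0))
      n_sim <- rlen %/% 3 - 2L
      # genome branch lengths are per nucleotide site; the codon process is
      # normalized per codon site, so scale by 3 to keep divergence comparable
      ctree <- tree
      ctree$edge.length <- 3 * tree$edge.length
      sim <- simulate_codon_gene(ctree, list(p0 = sel$p0[i], p = sel$p[i],
                                            q = sel$q[i], omega_s = sel$omega_s[i],
                                            kappa = config$kappa),
                                 n_sim, seed = stage_seed(config$seed, paste0("sel_", g)),
                                 return_all_nodes = TRUE)
      for (nd in seq_along(node_states)) {
        st <- node_states[[nd]]
        fid <- feature_id_by_name(st$features, g, kind = "CDS")
        bases <- strsplit(sim$node_sequences[nd], "", fixed = TRUE)[[1]]
        node_states[[nd]] <- set_reading_bases(st, fid, 3L, bases)
      }
      # log per-branch substitutions of the codon process
      for (e in seq_len(nrow(tree$edge))) {
        pseq <- strsplit(sim$node_sequences[tree$edge[e, 1]], "", fixed = TRUE)[[1]]
        cseq <- strsplit(sim$node_sequences[tree$edge[e, 2]], "", fixed = TRUE)[[1]]
        d <- which(pseq != cseq)
        if (!length(d)) next
        cst <- node_states[[tree$edge[e, 2]]]
        fid <- feature_id_by_name(cst$features, g, kind = "CDS")
        rp <- reading_positions(cst, fid)
        gpos <- rp[3L + d]                       # reading offset 3 + (pos-1) + 1
        log_event(labels[tree$edge[e, 2]], "sub", "CDS",
                  cst$keys[gpos + 1], gene = g, from = pseq[d], to = cseq[d])
      }
      selection_truth[[g]] <- list(site_class = sim$site_class,
                                   site_omega = sim$site_omega,
                                   codon_alignment = sim$alignment)
    }
    # splicing rewrote gene bases at every node, including the root
    ancestor$sequence <- paste(node_states[[root]]$seq, collapse = "")
  }

  # leaf records and the true alignment
  records <- list()
  for (t in seq_len(ntip)) {
    st <- node_states[[t]]
    rec <- plastome_record(id = tree$tip.label[t],
                           sequence = paste(st$seq, collapse = ""),
                           circular = TRUE, features = st$features,
                           source = "synthetic leaf")
    attr(rec, "partition") <- quadripartite_partition(
      LSC = st$partition$LSC, IRb = st$partition$IRb,
      SSC = st$partition$SSC, IRa = st$partition$IRa,
      genome_length = length(st$seq))
    attr(rec, "ssr_truth") <- st$ssr
    records[[tree$tip.label[t]]] <- rec
  }
  anc_state <- node_states[[root]]
  all_keys <- sort(unique(c(unlist(lapply(node_states[seq_len(ntip)],
                                          function(s) s$keys)),
                            anc_state$keys)))
  aln <- matrix("-", nrow = ntip + 1, ncol = length(all_keys),
                dimnames = list(c(tree$tip.label, "ancestor"), NULL))
  for (t in seq_len(ntip)) {
    st <- node_states[[t]]
    aln[t, match(st$keys, all_keys)] <- st$seq
  }
  aln[ntip + 1, match(anc_state$keys, all_keys)] <- anc_state$seq

  grab <- function(fld) unlist(lapply(ev$chunks, `[[`, fld), use.names = FALSE)
  ev_df <- data.frame(branch = as.character(grab("branch")),
                      type = as.character(grab("type")),
                      class = as.character(grab("class")),
                      key = as.numeric(grab("key")),
                      length = as.integer(grab("len")),
                      gene = as.character(grab("gene")),
                      from = as.character(grab("from")),
                      to = as.character(grab("to")),
                      stringsAsFactors = FALSE)
  truth <- structure(list(true_alignment = aln, events = ev_df,
                          ssr = lapply(records, attr, "ssr_truth"),
                          planted_repeats = truth_repeats,
                          selection = selection_truth,
                          ancestor = ancestor, config = config),
                     class = "truth_log")
  list(records = records, truth = truth)
}

#' @export
print.truth_log <- function(x, ...) {
  cat(sprintf("truth_log: %d x %d true alignment, %d events, %d planted repeats\n",
              nrow(x$true_alignment), ncol(x$true_alignment), nrow(x$events),
              if (is.null(x$planted_repeats)) 0L else nrow(x$planted_repeats)))
  invisible(x)
}
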