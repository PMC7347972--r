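# Site-level positive-selection scan: codon alignments, NJ guide trees,
# M8-vs-M8a likelihood-ratio tests, naive empirical-Bayes site posteriors,
# gene divergence, and the NG86 counting method as an independent check.

#' Build a codon alignment from aligned CDS sequences
#'
#' @param seqs named character vector of aligned, in-frame CDS sequences
#'   (equal lengths divisible by 3; gaps as `-`)
#' @return character matrix of codon strings (taxa x codon sites) with
#'   columns containing gaps, stops or ambiguity removed; attribute
#'   `removed_columns` reports how many
#' @export
build_codon_alignment <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences have unequal aligned lengths", call. = FALSE)
  if (lens[1] %% 3 != 0) stop("aligned length not divisible by 3", call. = FALSE)
  m <- do.call(rbind, lapply(seqs, split_codons))
  rownames(m) <- names(seqs)
  ok <- apply(m, 2, function(col) all(col %in% SENSE_CODONS))
  out <- m[, ok, drop = FALSE]
  attr(out, "removed_columns") <- sum(!ok)
  out
}

#' Neighbor-joining tree from ungapped sequences
#'
#' Kimura two-parameter distances with a p-distance fallback when K2P is
#' undefined (saturation); negative NJ branch lengths are clamped to zero.
#'
#' @param seqs named character vector of equal-length DNA sequences
#' @return `ape::phylo`
#' @export
nj_tree <- function(seqs) {
  if (length(seqs) < 3) stop("need at least 3 sequences", call. = FALSE)
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  dna <- ape::as.DNAbin(m)
  d <- ape::dist.dna(dna, model = "K80")
  if (any(!is.finite(d))) {
    warning("K2P distances undefined (saturation); falling back to p-distance")
    d <- ape::dist.dna(dna, model = "raw")
  }
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' M8 vs M8a likelihood-ratio test
#'
#' Statistic 2(lnL_M8 - lnL_M8a) clamped at zero; p-value from chi-squared
#' with 1 degree of freedom (a deliberately conservative reference
#' distribution for this boundary case).
#'
#' @param fit_null an M8a [fit_codon_model()] fit
#' @param fit_alt an M8 fit on the same alignment and tree
#' @return list with `statistic` and `p_value`
#' @export
lrt_m8_vs_m8a <- function(fit_null, fit_alt) {
  if (fit_null$model != "M8a" || fit_alt$model != "M8") {
    stop("expected an M8a null fit and an M8 alternative fit", call. = FALSE)
  }
  if (fit_null$n_sites != fit_alt$n_sites ||
      !setequal(fit_null$tree$tip.label, fit_alt$tree$tip.label)) {
    stop("fits are not on the same alignment/tree", call. = FALSE)
  }
  stat <- max(0, 2 * (fit_alt$lnl - fit_null$lnl))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Empirical-Bayes site posteriors and positive-selection calls
#'
#' Naive empirical Bayes at the MLEs: per-site class posteriors are
#' proportional to class weight times the site likelihood under that class.
#' A site is called positively selected when the M8-vs-M8a LRT is
#' significant at `alpha`, the posterior probability of the omega_s class is
#' at least `posterior_cutoff`, and the posterior mean omega exceeds 1.
#'
#' @param fit_alt an M8 [fit_codon_model()] fit
#' @param codon_aln the codon alignment the fit was computed on
#' @param lrt_p p-value of the M8-vs-M8a LRT; `NA` disables the gate (calls
#'   on posterior alone)
#' @param posterior_cutoff posterior threshold for the omega_s class
#' @param alpha LRT significance level
#' @return data.frame per site: `site`, `posterior_ws` (posterior of the
#'   omega_s class), `mean_omega`, `positive`
#' @export
site_posteriors <- function(fit_alt, codon_aln, lrt_p = NA,
                            posterior_cutoff = 0.95, alpha = 0.05) {
  stopifnot(fit_alt$model == "M8")
  cls <- fit_site_classes(fit_alt)
  states <- codon_state_matrix(codon_aln)
  res <- codon_loglik(states, fit_alt$tree, fit_alt$pi, fit_alt$kappa,
                      cls$omegas, cls$weights, per_site = TRUE)
  lw <- log(pmax(cls$weights, 1e-300)) + res$site_class_loglik
  post <- apply(lw, 2, function(v) {
    v <- v - max(v)
    e <- exp(v)
    e / sum(e)
  })
  ws_idx <- length(cls$omegas)
  mean_omega <- as.numeric(cls$omegas %*% post)
  gate <- if (is.na(lrt_p)) TRUE else lrt_p <= alpha
  data.frame(site = seq_len(ncol(codon_aln)),
             posterior_ws = post[ws_idx, ],
             mean_omega = mean_omega,
             positive = gate & post[ws_idx, ] >= posterior_cutoff & mean_omega > 1)
}

#' Gene divergence as average branch length
#'
#' @param fit a [fit_codon_model()] fit (conventionally the M0 fit)
#' @return arithmetic mean of the branch lengths
#' @export
gene_divergence <- function(fit) {
  mean(fit$tree$edge.length)
}

# --- NG86 counting method --------------------------------------------------

ng86_site_counts <- function(codon) {
  sp <- strsplit(codon, "", fixed = TRUE)[[1]]
  syn <- 0
  for (k in 1:3) {
    for (b in setdiff(DNA_BASES, sp[k])) {
      mut <- sp; mut[k] <- b
      mut <- paste(mut, collapse = "")
      if (!mut %in% STOP_CODONS && CODON_AA[[mut]] == CODON_AA[[codon]]) {
        syn <- syn + 1 / 3
      }
    }
  }
  c(S = syn, N = 3 - syn)
}

ng86_pair_diffs <- function(a, b) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  d <- which(sa != sb)
  if (!length(d)) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(length(d)),
                  "1" = list(d),
                  "2" = list(d, rev(d)),
                  "3" = {
                    o <- list()
                    for (i in 1:3) for (j in setdiff(1:3, i)) {
                      o[[length(o) + 1]] <- d[c(i, j, setdiff(1:3, c(i, j)))]
                    }
                    o
                  })
  step_counts <- function(path, allow_stop) {
    cur <- sa
    sd <- 0; nd <- 0
    for (pos in path) {
      nxt <- cur; nxt[pos] <- sb[pos]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (!allow_stop && c2 %in% STOP_CODONS && c2 != b) return(NULL)
      if (c2 %in% STOP_CODONS || c1 %in% STOP_CODONS) {
        nd <- nd + 1                     # change via stop counted nonsynonymous
      } else if (CODON_AA[[c1]] == CODON_AA[[c2]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, step_counts, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) res <- lapply(perms, step_counts, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Pathway counting with all orderings of multi-difference codons averaged
#' (orderings through stop codons are skipped unless all are blocked), and
#' Jukes-Cantor multiple-hit correction.  Serves as an independent oracle
#' for the maximum-likelihood omega estimates.
#'
#' @param seq_a,seq_b in-frame, equal-length, stop-free codon sequences
#' @return list with `dN`, `dS`, `omega`, and the raw proportions
#' @export
ng86_dnds <- function(seq_a, seq_b) {
  ca <- split_codons(toupper(seq_a)); cb <- split_codons(toupper(seq_b))
  if (length(ca) != length(cb)) stop("sequences differ in codon length", call. = FALSE)
  if (any(c(ca, cb) %in% STOP_CODONS)) stop("stop codon in input", call. = FALSE)
  ok <- ca %in% SENSE_CODONS & cb %in% SENSE_CODONS
  ca <- ca[ok]; cb <- cb[ok]
  sites_a <- rowSums(vapply(ca, ng86_site_counts, numeric(2)))
  sites_b <- rowSums(vapply(cb, ng86_site_counts, numeric(2)))
  S <- (sites_a[["S"]] + sites_b[["S"]]) / 2
  N <- (sites_a[["N"]] + sites_b[["N"]]) / 2
  diffs <- rowSums(vapply(seq_along(ca), function(i) ng86_pair_diffs(ca[i], cb[i]),
                          numeric(2)))
  pS <- if (S > 0) diffs[["sd"]] / S else 0
  pN <- if (N > 0) diffs[["nd"]] / N else 0
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(Inf)
    -3 / 4 * log(arg)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (is.finite(dS) && dS > 0) dN / dS else if (dN == 0) NA_real_ else Inf
  list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
       sd = diffs[["sd"]], nd = diffs[["nd"]], S = S, N = N)
}

#' Selection scan over a set of gene alignments
#'
#' For each gene: M0/M8a/M8 fits on a fixed tree (per-gene NJ unless a tree
#' is supplied), the M8-vs-M8a LRT, positive-site calls, and divergence as
#' the mean M0 branch length.
#'
#' @param gene_alignments named list of aligned, in-frame CDS sequence sets
#'   (named character vectors)
#' @param tree optional `ape::phylo` used for every gene
#' @param posterior_cutoff,alpha site-call thresholds (see
#'   [site_posteriors()])
#' @return list with `summary` (one row per gene) and `sites` (per-gene
#'   site tables)
#' @export
selection_scan <- function(gene_alignments, tree = NULL,
                           posterior_cutoff = 0.95, alpha = 0.05) {
  rows <- list(); sites <- list()
  for (g in names(gene_alignments)) {
    seqs <- gene_alignments[[g]]
    aln <- build_codon_alignment(seqs)
    if (ncol(aln) < 10 || nrow(aln) < 3) next
    tr <- tree %||% nj_tree(gsub("-", "", seqs))
    m0 <- fit_codon_model(aln, tr, "M0")
    m8a <- fit_codon_model(aln, tr, "M8a", m0_fit = m0)
    m8 <- fit_codon_model(aln, tr, "M8", m0_fit = m0)
    lrt <- lrt_m8_vs_m8a(m8a, m8)
    st <- site_posteriors(m8, aln, lrt_p = lrt$p_value,
                          posterior_cutoff = posterior_cutoff, alpha = alpha)
    sites[[g]] <- st
    rows[[g]] <- data.frame(
      gene = g, n_codons = ncol(aln), lnl_m0 = m0$lnl, lnl_m8a = m8a$lnl,
      lnl_m8 = m8$lnl, kappa = m8$kappa, p0 = m8$p0, p = m8$p, q = m8$q,
      omega_s = m8$omega_s, lrt_stat = lrt$statistic, lrt_p = lrt$p_value,
      n_positive_sites = sum(st$positive), divergence = gene_divergence(m0),
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, rows), sites = sites)
}
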