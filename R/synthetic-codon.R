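# Codon-alignment simulator under the M8 site-class mixture; used both as a
# standalone generator for the selection-scan calibration studies and to
# splice genes under selection into evolved synthetic plastomes.

default_codon_pi <- function(freqs = c(A = 0.315, C = 0.185, G = 0.185, T = 0.315)) {
  pi <- vapply(SENSE_CODONS, function(cd) {
    freqs[[substr(cd, 1, 1)]] * freqs[[substr(cd, 2, 2)]] * freqs[[substr(cd, 3, 3)]]
  }, numeric(1))
  pi / sum(pi)
}

#' Simulate a codon alignment under the M8 mixture
#'
#' Each site's omega is the mean of one of 10 equal-probability discretized
#' Beta(p, q) categories with probability `p0`, otherwise `omega_s`;
#' sequences evolve along the tree under the same GY94-style rate matrix
#' used for fitting (branch lengths in expected substitutions per codon
#' site, averaged over site classes).
#'
#' @param tree `ape::phylo` or newick string with branch lengths
#' @param m8_params list with `p0`, `p`, `q`, `omega_s` (>= 1) and `kappa`
#' @param n_codons number of codon sites (>= 1)
#' @param seed integer seed
#' @param pi sense-codon frequencies (default: AT-rich plastome-like F3x4)
#' @param return_all_nodes also return internal-node and root sequences
#' @return list with `alignment` (character matrix of codon strings, tips as
#'   rows), `sequences` (collapsed strings), `site_class` (`"beta"` or
#'   `"positive"` per site), `site_omega`, and optionally `node_sequences`
#' @export
simulate_codon_gene <- function(tree, m8_params, n_codons, seed = 1,
                                pi = default_codon_pi(),
                                return_all_nodes = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(n_codons >= 1)
  p0 <- m8_params$p0; p <- m8_params$p; q <- m8_params$q
  ws <- m8_params$omega_s; kappa <- m8_params$kappa %||% 2
  if (ws < 1) stop("omega_s must be >= 1", call. = FALSE)
  if (p <= 0 || q <= 0) stop("invalid beta parameters", call. = FALSE)
  set.seed(seed)

  ncat <- 10
  betas <- beta_class_means(p, q, ncat)
  omegas <- c(betas, ws)
  weights <- c(rep(p0 / ncat, ncat), 1 - p0)
  mu <- codon_mixture_mu(pi, kappa, omegas, weights)

  is_pos <- stats::runif(n_codons) >= p0
  cls <- ifelse(is_pos, ncat + 1L, sample.int(ncat, n_codons, replace = TRUE))
  site_omega <- omegas[cls]

  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nnode_total <- ntip + tr$Nnode
  node_states <- vector("list", nnode_total)
  node_states[[root]] <- sample.int(61, n_codons, replace = TRUE, prob = pi)

  # unique branch (class, length) transition matrices
  for (e in rev(seq_len(nrow(tr$edge)))) {      # preorder: root-side first
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t_e <- tr$edge.length[e]
    st <- node_states[[parent]]
    out <- integer(n_codons)
    for (k in sort(unique(cls))) {
      idx <- which(cls == k)
      if (!length(idx)) next
      P <- codon_Pmat(pi, kappa, omegas[k], t_e, mu)
      for (i in idx) out[i] <- sample.int(61, 1, prob = P[st[i], ])
    }
    node_states[[child]] <- out
  }

  tip_mat <- do.call(rbind, lapply(seq_len(ntip), function(i) {
    SENSE_CODONS[node_states[[i]]]
  }))
  rownames(tip_mat) <- tr$tip.label
  res <- list(alignment = tip_mat,
              sequences = apply(tip_mat, 1, paste, collapse = ""),
              site_class = ifelse(cls == ncat + 1L, "positive", "beta"),
              site_omega = site_omega)
  if (return_all_nodes) {
    res$node_sequences <- vapply(node_states, function(s) {
      paste(SENSE_CODONS[s], collapse = "")
    }, character(1))
    res$tree <- tr
    res$root <- root
  }
  res
}
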