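# GY94 codon model machinery: F3x4 frequencies, discretized-beta site
# classes (M0 / M8a / M8), likelihood evaluation via the compiled pruning
# kernel, and maximum-likelihood fitting.

#' Convert a codon alignment to a state matrix
#'
#' @param codon_aln character matrix (taxa x codon sites) of codon strings
#' @return integer matrix of indices into the 61 sense codons (NA for
#'   anything else)
#' @keywords internal
codon_state_matrix <- function(codon_aln) {
  m <- matrix(match(codon_aln, SENSE_CODONS), nrow = nrow(codon_aln),
              dimnames = dimnames(codon_aln))
  storage.mode(m) <- "integer"
  m
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies multiplied per codon, restricted
#' to the 61 sense codons and renormalized; a small floor keeps unobserved
#' states strictly positive.
#'
#' @param codon_aln character matrix of codon strings
#' @return numeric vector of length 61 (sense-codon order), summing to 1
#' @export
f3x4_frequencies <- function(codon_aln) {
  cod <- codon_aln[codon_aln %in% SENSE_CODONS]
  posfreq <- matrix(0, 3, 4, dimnames = list(NULL, DNA_BASES))
  for (p in 1:3) {
    b <- substr(cod, p, p)
    tab <- table(factor(b, levels = DNA_BASES))
    posfreq[p, ] <- (as.numeric(tab) + 0.5) / (sum(tab) + 2)
  }
  pi <- vapply(SENSE_CODONS, function(cd) {
    posfreq[1, substr(cd, 1, 1)] * posfreq[2, substr(cd, 2, 2)] *
      posfreq[3, substr(cd, 3, 3)]
  }, numeric(1))
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}

#' Equal-probability discretized Beta(p, q) category means
#'
#' @param p,q beta shape parameters (> 0)
#' @param ncat number of categories (default 10)
#' @return numeric vector of category-mean representatives
#' @export
beta_class_means <- function(p, q, ncat = 10) {
  if (p <= 0 || q <= 0) stop("beta shape parameters must be positive", call. = FALSE)
  # extreme shapes visited during optimization trigger harmless
  # reduced-precision warnings from the incomplete beta
  bounds <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = ncat + 1), p, q))
  lo <- bounds[-(ncat + 1)]; hi <- bounds[-1]
  num <- suppressWarnings(stats::pbeta(hi, p + 1, q) - stats::pbeta(lo, p + 1, q))
  den <- suppressWarnings(stats::pbeta(hi, p, q) - stats::pbeta(lo, p, q))
  mean_full <- p / (p + q)
  out <- ifelse(den > 0, mean_full * num / pmax(den, 1e-300), (lo + hi) / 2)
  pmin(pmax(out, 0), 1)
}

# site-class mixture for a model
model_site_classes <- function(model, params, ncat = 10) {
  switch(model,
    M0 = list(omegas = params$omega, weights = 1),
    M8a = list(omegas = c(beta_class_means(params$p, params$q, ncat), 1),
               weights = c(rep(params$p0 / ncat, ncat), 1 - params$p0)),
    M8 = list(omegas = c(beta_class_means(params$p, params$q, ncat), params$omega_s),
              weights = c(rep(params$p0 / ncat, ncat), 1 - params$p0)),
    stop("unknown model"))
}

# postorder edge matrix + tip-ordered states for the kernel
prep_tree_states <- function(states, tree) {
  tr <- stats::reorder(tree, "postorder")
  if (!setequal(tr$tip.label, rownames(states))) {
    stop("tree tip labels do not match the alignment", call. = FALSE)
  }
  list(tree = tr, states = states[tr$tip.label, , drop = FALSE])
}

#' Codon-model log-likelihood
#'
#' @param states integer state matrix from [codon_state_matrix()] with taxa
#'   as rownames
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon site)
#' @param pi sense-codon frequencies (length 61)
#' @param kappa transition/transversion rate ratio
#' @param omegas,weights the site-class mixture
#' @param per_site also return the per-class per-site log-likelihood matrix
#' @param cache optional environment memoizing per-class eigendecompositions
#'   (valid for one set of frequencies `pi`); used heavily during fitting
#' @return list with `lnl` (and `site_class_loglik` when requested)
#' @export
codon_loglik <- function(states, tree, pi, kappa, omegas, weights,
                         per_site = FALSE, cache = NULL) {
  pp <- prep_tree_states(states, tree)
  eigens <- vector("list", length(omegas))
  rates <- numeric(length(omegas))
  for (k in seq_along(omegas)) {
    key <- sprintf("%.14g|%.14g", kappa, omegas[k])
    eg <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(eg)) {
      eg <- codon_eigen_cpp(pi, get_pair_type(), kappa, omegas[k])
      if (!is.null(cache)) cache[[key]] <- eg
    }
    eigens[[k]] <- eg
    rates[k] <- eg$rate
  }
  codon_lik_cpp(pp$states, pp$tree$edge, pp$tree$edge.length,
                length(pp$tree$tip.label), pi, eigens, rates, weights, per_site)
}

safe_lnl <- function(expr) {
  v <- tryCatch(expr, error = function(e) NULL)
  if (is.null(v) || !is.finite(v$lnl)) return(-1e12)
  v$lnl
}

#' Fit a codon substitution model
#'
#' Fits M0 (single omega), M8a (beta-distributed omega in 10 equal-weight
#' categories plus a class fixed at omega = 1) or M8 (the extra class free,
#' omega_s >= 1) on a fixed tree topology by bounded quasi-Newton
#' optimization of transformed parameters.  Branch lengths are optimized
#' individually under M0; M8a/M8 keep the M0 branch-length proportions and
#' re-optimize a single tree-scale factor together with kappa and the
#' site-class parameters, then M8 is anchored at the M8a solution so the
#' nesting inequality lnL(M8) >= lnL(M8a) holds at the reported optima.
#'
#' @param codon_aln character matrix of codon strings (taxa x sites), rows
#'   named
#' @param tree `ape::phylo` with starting branch lengths (e.g. [nj_tree()])
#' @param model `"M0"`, `"M8a"` or `"M8"`
#' @param n_beta_categories number of discretized beta categories
#' @param m0_fit optional previously computed M0 fit (to reuse branch
#'   lengths)
#' @param m8a_fit optional previously computed M8a fit (start point for M8)
#' @return object of class `codon_model_fit`
#' @export
fit_codon_model <- function(codon_aln, tree, model = c("M0", "M8a", "M8"),
                            n_beta_categories = 10, m0_fit = NULL,
                            m8a_fit = NULL) {
  model <- match.arg(model)
  states <- codon_state_matrix(codon_aln)
  pi <- f3x4_frequencies(codon_aln)
  cache <- new.env(parent = emptyenv())
  ctl <- list(maxit = 100, factr = 1e9)
  tree$edge.length <- pmax(tree$edge.length %||% rep(0.05, nrow(tree$edge)), 1e-6)

  if (model == "M0") {
    nb <- nrow(tree$edge)
    fn <- function(par) {
      tr <- tree
      tr$edge.length <- exp(par[3:(2 + nb)])
      -safe_lnl(codon_loglik(states, tr, pi, exp(par[1]),
                             exp(par[2]), 1, FALSE, cache = cache))
    }
    start <- c(log(2), log(0.2), log(pmax(tree$edge.length, 1e-5)))
    opt <- stats::optim(start, fn, method = "L-BFGS-B",
                        lower = c(log(0.05), log(1e-4), rep(log(1e-7), nb)),
                        upper = c(log(50), log(20), rep(log(20), nb)),
                        control = ctl)
    tr <- tree
    tr$edge.length <- exp(opt$par[3:(2 + nb)])
    fit <- list(model = "M0", lnl = -opt$value, kappa = exp(opt$par[1]),
                omega = exp(opt$par[2]), p0 = NA, p = NA, q = NA,
                omega_s = NA, pi = pi, tree = tr,
                n_sites = ncol(codon_aln), converged = opt$convergence == 0)
    class(fit) <- "codon_model_fit"
    return(fit)
  }

  if (is.null(m0_fit)) m0_fit <- fit_codon_model(codon_aln, tree, "M0")
  prop <- m0_fit$tree$edge.length / sum(m0_fit$tree$edge.length)
  prop <- pmax(prop, 1e-9)
  base_tree <- m0_fit$tree

  mk_fn <- function(omega_s_free) {
    function(par) {
      kappa <- exp(par[1]); scale <- exp(par[2])
      p0 <- stats::plogis(par[3]); p <- exp(par[4]); q <- exp(par[5])
      ws <- if (omega_s_free) 1 + exp(par[6]) else 1
      cls <- model_site_classes(if (omega_s_free) "M8" else "M8a",
                                list(p0 = p0, p = p, q = q, omega_s = ws),
                                n_beta_categories)
      tr <- base_tree
      tr$edge.length <- prop * scale
      -safe_lnl(codon_loglik(states, tr, pi, kappa, cls$omegas, cls$weights,
                             FALSE, cache = cache))
    }
  }
  lower <- c(log(0.05), log(1e-5), -9, log(0.02), log(0.02))
  upper <- c(log(50), log(9), 9, log(50), log(50))
  s0 <- c(log(m0_fit$kappa), log(sum(m0_fit$tree$edge.length)),
          stats::qlogis(0.9), log(0.5), log(2))

  fit_one <- function(fn, start, lo, up) {
    stats::optim(start, fn, method = "L-BFGS-B", lower = lo, upper = up,
                 control = ctl)
  }

  if (model == "M8a") {
    opt <- fit_one(mk_fn(FALSE), s0, lower, upper)
    # a second start guards against local optima in (p, q)
    opt2 <- fit_one(mk_fn(FALSE), replace(s0, 4:5, c(log(2), log(0.5))), lower, upper)
    if (opt2$value < opt$value) opt <- opt2
    par <- opt$par
    fit <- list(model = "M8a", lnl = -opt$value, kappa = exp(par[1]),
                omega = NA, p0 = stats::plogis(par[3]), p = exp(par[4]),
                q = exp(par[5]), omega_s = 1, pi = pi,
                tree = { tr <- base_tree; tr$edge.length <- prop * exp(par[2]); tr },
                n_sites = ncol(codon_aln), converged = opt$convergence == 0)
    class(fit) <- "codon_model_fit"
    return(fit)
  }

  # M8: start from the M8a solution and from a positive-selection start
  m8a <- m8a_fit %||% fit_codon_model(codon_aln, tree, "M8a",
                                      n_beta_categories = n_beta_categories,
                                      m0_fit = m0_fit)
  s_null <- c(log(m8a$kappa), log(sum(m8a$tree$edge.length)),
              stats::qlogis(min(max(m8a$p0, 1e-4), 1 - 1e-4)),
              log(m8a$p), log(m8a$q), log(1e-4))
  s_pos <- replace(s_null, 6, log(1.5))
  lower6 <- c(lower, log(1e-6)); upper6 <- c(upper, log(30))
  fn8 <- mk_fn(TRUE)
  cand <- list(fit_one(fn8, s_null, lower6, upper6),
               fit_one(fn8, s_pos, lower6, upper6))
  opt <- cand[[which.min(vapply(cand, function(o) o$value, numeric(1)))]]
  lnl <- -opt$value
  par <- opt$par
  if (lnl < m8a$lnl) {                  # enforce nesting at the optimum
    lnl <- m8a$lnl
    par <- s_null
  }
  fit <- list(model = "M8", lnl = lnl, kappa = exp(par[1]), omega = NA,
              p0 = stats::plogis(par[3]), p = exp(par[4]), q = exp(par[5]),
              omega_s = 1 + exp(par[6]), pi = pi,
              tree = { tr <- base_tree; tr$edge.length <- prop * exp(par[2]); tr },
              n_sites = ncol(codon_aln), converged = opt$convergence == 0)
  class(fit) <- "codon_model_fit"
  fit
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("codon model %s: lnL = %.3f, kappa = %.2f", x$model, x$lnl, x$kappa))
  if (x$model == "M0") cat(sprintf(", omega = %.3f", x$omega))
  if (x$model %in% c("M8a", "M8")) {
    cat(sprintf(", p0 = %.3f, beta(%.2f, %.2f), omega_s = %.3f",
                x$p0, x$p, x$q, x$omega_s))
  }
  cat("\n")
  invisible(x)
}

# class mixture of a fitted M8/M8a model
fit_site_classes <- function(fit, ncat = 10) {
  model_site_classes(fit$model,
                     list(omega = fit$omega, p0 = fit$p0, p = fit$p, q = fit$q,
                          omega_s = fit$omega_s), ncat)
}

# --- R-side Q/P construction: used by the simulator and as an independent
# cross-check of the compiled kernel ---------------------------------------

codon_Q <- function(pi, kappa, omega) {
  type <- get_pair_type()
  mult <- matrix(0, 61, 61)
  mult[type == 1] <- 1
  mult[type == 2] <- kappa
  mult[type == 3] <- omega
  mult[type == 4] <- kappa * omega
  Q <- mult * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  Q
}

codon_mixture_mu <- function(pi, kappa, omegas, weights) {
  rates <- vapply(omegas, function(w) {
    Q <- codon_Q(pi, kappa, w)
    -sum(pi * diag(Q))
  }, numeric(1))
  1 / sum(weights * rates)
}

codon_Pmat <- function(pi, kappa, omega, t, mu = NULL) {
  Q <- codon_Q(pi, kappa, omega)
  if (is.null(mu)) mu <- 1 / (-sum(pi * diag(Q)))
  sp <- sqrt(pi)
  A <- Q * (sp %o% (1 / sp))
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  P <- eg$vectors %*% diag(exp(eg$values * mu * t)) %*% t(eg$vectors)
  P <- P * ((1 / sp) %o% sp)
  P[P < 0] <- 0
  P
}
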