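test_that("codon alignments drop gap/stop columns and keep frame", {
  seqs <- c(a = "ATGAAACCC", b = "ATGAAACCC", c = "ATG---CCC")
  aln <- build_codon_alignment(seqs)
  expect_equal(ncol(aln), 2)
  expect_equal(attr(aln, "removed_columns"), 1)
  stops <- c(a = "ATGTAACCC", b = "ATGAAACCC", c = "ATGAAACCC")
  expect_equal(ncol(build_codon_alignment(stops)), 2)
  expect_error(build_codon_alignment(c(a = "ATGA", b = "ATGA")), "divisible")
  expect_error(build_codon_alignment(c(a = "ATGAAA", b = "ATG")), "unequal")
})

test_that("NJ trees satisfy closed-form and additive expectations", {
  # identical sequences -> star tree with zero branches
  same <- setNames(rep(strrep("ACGT", 60), 3), c("a", "b", "c"))
  tr <- nj_tree(same)
  expect_equal(sum(tr$edge.length), 0)

  # 3 taxa: branch lengths solve the three-point equations
  set.seed(4)
  seqs <- simulate_codon_gene(ape::read.tree(text = "(a:0.08,b:0.12,c:0.2);"),
                              list(p0 = 1, p = 1, q = 1, omega_s = 1, kappa = 2),
                              400, seed = 8)$sequences
  tr3 <- nj_tree(seqs)
  m <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(m) <- names(seqs)
  d <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(bl["a"]), (d["a", "b"] + d["a", "c"] - d["b", "c"]) / 2,
               tolerance = 1e-8)
  expect_equal(unname(bl["b"]), (d["a", "b"] + d["b", "c"] - d["a", "c"]) / 2,
               tolerance = 1e-8)

  # 4 taxa with additive distances recover the generating topology
  tr4 <- quick_tree4()
  sim4 <- simulate_codon_gene(tr4, list(p0 = 1, p = 1, q = 1, omega_s = 1,
                                        kappa = 2), 500, seed = 10)
  est <- nj_tree(sim4$sequences)
  expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(tr4)), 0,
               ignore_attr = TRUE)
  expect_true(all(est$edge.length >= 0))
  expect_error(nj_tree(same[1:2]), "at least 3")
})

test_that("pruning likelihood matches exhaustive ancestral-state summation", {
  for (sd in 1:3) {
    ntax <- if (sd == 1) 3 else 4
    tr <- if (ntax == 3) ape::read.tree(text = "(a:0.2,b:0.1,c:0.3);") else quick_tree4()
    sim <- simulate_codon_gene(tr, list(p0 = 0.9, p = 0.6, q = 1.4, omega_s = 2,
                                        kappa = 1.8), 30, seed = 60 + sd)
    states <- plastocomp:::codon_state_matrix(sim$alignment)
    pi <- f3x4_frequencies(sim$alignment)
    omegas <- c(0.2, 1, 3)
    weights <- c(0.5, 0.3, 0.2)
    got <- codon_loglik(states, tr, pi, 2.1, omegas, weights)$lnl
    want <- oracle_codon_lnl(states, tr, pi, 2.1, omegas, weights)
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("two identical sequences collapse to zero branch length", {
  seqs <- simulate_codon_gene(ape::read.tree(text = "(a:0,b:0);"),
                              list(p0 = 1, p = 1, q = 1, omega_s = 1, kappa = 2),
                              60, seed = 5)
  tr2 <- ape::read.tree(text = "(a:0.1,b:0.1);")
  aln <- build_codon_alignment(seqs$sequences)
  fit <- fit_codon_model(aln, tr2, "M0")
  expect_lt(sum(fit$tree$edge.length), 1e-4)
  pi <- fit$pi
  states <- plastocomp:::codon_state_matrix(aln)
  expect_equal(fit$lnl, sum(log(pi[states["a", ]])), tolerance = 1e-4)
})

test_that("the LRT is clamped at zero and nested fits are ordered", {
  tr <- quick_tree8()
  sim <- simulate_codon_gene(tr, list(p0 = 0.95, p = 0.5, q = 1.5, omega_s = 1,
                                      kappa = 2), 120, seed = 31)
  m0 <- fit_codon_model(sim$alignment, tr, "M0")
  m8a <- fit_codon_model(sim$alignment, tr, "M8a", m0_fit = m0)
  m8 <- fit_codon_model(sim$alignment, tr, "M8", m0_fit = m0, m8a_fit = m8a)
  expect_gte(m8$lnl, m8a$lnl)
  lrt <- lrt_m8_vs_m8a(m8a, m8)
  expect_gte(lrt$statistic, 0)
  expect_lte(lrt$p_value, 1)
  same <- lrt_m8_vs_m8a(m8a, local({ x <- m8; x$lnl <- m8a$lnl; x }))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt_m8_vs_m8a(m8, m8a), "M8a null")
})

test_that("site posteriors are proper probabilities and gate on the LRT", {
  tr <- quick_tree8()
  sim <- simulate_codon_gene(tr, list(p0 = 0.8, p = 0.5, q = 1.5, omega_s = 4,
                                      kappa = 2), 150, seed = 17)
  m0 <- fit_codon_model(sim$alignment, tr, "M0")
  m8 <- fit_codon_model(sim$alignment, tr, "M8", m0_fit = m0)
  st <- site_posteriors(m8, sim$alignment, lrt_p = 0.001)
  expect_true(all(st$posterior_ws >= 0 & st$posterior_ws <= 1))
  # full class posteriors sum to one per site
  cls <- plastocomp:::fit_site_classes(m8)
  res <- codon_loglik(plastocomp:::codon_state_matrix(sim$alignment), m8$tree,
                      m8$pi, m8$kappa, cls$omegas, cls$weights, per_site = TRUE)
  lw <- log(pmax(cls$weights, 1e-300)) + res$site_class_loglik
  post <- apply(lw, 2, function(v) { e <- exp(v - max(v)); e / sum(e) })
  expect_equal(colSums(post), rep(1, ncol(post)), tolerance = 1e-12)
  # flagged sites always have posterior mean omega > 1
  expect_true(all(st$mean_omega[st$positive] > 1))
  # gating: identical table with a non-significant LRT flags nothing
  st0 <- site_posteriors(m8, sim$alignment, lrt_p = 0.5)
  expect_equal(sum(st0$positive), 0)
  # under strong simulated selection, calls are enriched in true positives
  if (sum(st$positive) >= 5) {
    expect_gte(mean(sim$site_class[st$positive] == "positive"), 0.8)
  }
  # an invariant alignment yields no positive calls
  same <- matrix("ATG", nrow = 8, ncol = 30,
                 dimnames = list(tr$tip.label, NULL))
  m0s <- fit_codon_model(same, tr, "M0")
  m8s <- fit_codon_model(same, tr, "M8", m0_fit = m0s)
  sts <- site_posteriors(m8s, same, lrt_p = 1)
  expect_equal(sum(sts$positive), 0)
})

test_that("gene divergence is the arithmetic mean branch length", {
  tr <- quick_tree4()
  fit <- list(tree = tr)
  expect_equal(gene_divergence(fit), mean(tr$edge.length))
  tz <- tr; tz$edge.length[] <- 0
  expect_equal(gene_divergence(list(tree = tz)), 0)
})

test_that("NG86 counting matches direct expectations and its pathway oracle", {
  same <- strrep("ATGAAACCC", 3)
  r <- ng86_dnds(same, same)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)

  # one synonymous difference only: TTT -> TTC
  a <- "ATGTTTAAA"; b <- "ATGTTCAAA"
  r2 <- ng86_dnds(a, b)
  expect_equal(r2$dN, 0)
  expect_gt(r2$dS, 0)
  expect_equal(r2$sd, 1)
  expect_equal(r2$nd, 0)

  # pathway averaging equals an independent permutation enumeration
  set.seed(23)
  gc_code <- plastocomp:::CODON_AA
  stops <- plastocomp:::STOP_CODONS
  for (rep in 1:25) {
    ca <- sample(plastocomp:::SENSE_CODONS, 1)
    cb <- sample(plastocomp:::SENSE_CODONS, 1)
    got <- plastocomp:::ng86_pair_diffs(ca, cb)
    sa <- strsplit(ca, "")[[1]]; sb <- strsplit(cb, "")[[1]]
    d <- which(sa != sb)
    if (!length(d)) { expect_equal(unname(got), c(0, 0)); next }
    perms <- switch(length(d), list(d),
                    list(d, d[2:1]),
                    {
                      p <- list(); for (i in 1:3) for (j in setdiff(1:3, i))
                        p[[length(p) + 1]] <- c(d[i], d[j], d[setdiff(1:3, c(i, j))])
                      p
                    })
    tallies <- list()
    for (pm in perms) {
      cur <- sa; sd_ <- 0; nd_ <- 0; blocked <- FALSE
      for (pos in pm) {
        nxt <- cur; nxt[pos] <- sb[pos]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (c2 %in% stops && c2 != cb) { blocked <- TRUE; break }
        if (gc_code[[c1]] == gc_code[[c2]]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
        cur <- nxt
      }
      if (!blocked) tallies[[length(tallies) + 1]] <- c(sd_, nd_)
    }
    if (length(tallies)) {
      want <- colMeans(do.call(rbind, tallies))
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("M0 omega tracks NG86 pairwise omega across genes", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.2,c:0.25);")
  ml <- ng <- numeric(0)
  set.seed(6)
  for (g in 1:16) {
    w_true <- runif(1, 0.05, 0.95)
    sim <- simulate_codon_gene(tr, list(p0 = 1, p = 30 * w_true,
                                        q = 30 * (1 - w_true),
                                        omega_s = 1, kappa = 2),
                               150, seed = 700 + g)
    m0 <- fit_codon_model(sim$alignment, tr, "M0")
    pair <- ng86_dnds(sim$sequences[["a"]], sim$sequences[["b"]])
    if (is.finite(pair$omega) && !is.na(pair$omega)) {
      ml <- c(ml, m0$omega); ng <- c(ng, pair$omega)
    }
  }
  expect_gte(length(ml), 12)
  expect_gte(cor(ml, ng, method = "spearman"), 0.8)
})
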