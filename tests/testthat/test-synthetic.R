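test_that("ancestor construction satisfies the quadripartite invariants", {
  anc <- small_ancestor(seed = 4)
  p <- attr(anc, "partition")
  S <- anc$sequence
  irb <- substr(S, p$IRb[1] + 1, p$IRb[2])
  ira <- substr(S, p$IRa[1] + 1, p$IRa[2])
  expect_identical(irb, plastocomp:::revcomp(ira))
  lens <- partition_lengths(p)
  expect_equal(sum(lens), genome_length(anc))

  # default plan ordering LSC > IR > SSC, as in sequenced plastomes
  full <- default_length_plan()
  expect_true(full$LSC > full$IR && full$IR > full$SSC)

  # ycf1 spans the SSC/IRa junction; its pseudogene fragment ends at IRb/SSC
  f <- anc$features
  ycf1 <- f[f$name == "ycf1" & f$kind == "CDS", ]
  expect_true(ycf1$start < p$IRa[1] && ycf1$end > p$IRa[1])
  psi <- f[f$name == "ycf1" & f$kind == "pseudogene", ]
  expect_equal(psi$end, p$IRb[2])

  # determinism
  expect_identical(small_ancestor(seed = 4)$sequence, S)

  # overflow
  expect_error(build_ancestor(length_plan = list(LSC = 4000, SSC = 1200, IR = 1100),
                              seed = 1),
               "overflow")
})

test_that("all-zero rates leave every leaf identical to the ancestor", {
  anc <- small_ancestor(seed = 7)
  cfg <- evolution_config(tree = quick_tree4(),
                          region_rates = c(CDS = 0, intron = 0, IGS = 0),
                          indel_rate = 0, ssr_slippage_rate = 0, seed = 7)
  sim <- evolve(anc, cfg)
  for (rec in sim$records) expect_identical(rec$sequence, anc$sequence)
  expect_equal(nrow(sim$truth$events), 0)
  expect_true(all(sim$truth$true_alignment != "-"))
})

test_that("degapping the true alignment reproduces each leaf byte-for-byte", {
  sim <- shared_sim()
  aln <- sim$truth$true_alignment
  for (id in names(sim$records)) {
    expect_identical(paste(aln[id, aln[id, ] != "-"], collapse = ""),
                     sim$records[[id]]$sequence)
  }
  anc <- sim$truth$ancestor
  expect_identical(paste(aln["ancestor", aln["ancestor", ] != "-"], collapse = ""),
                   anc$sequence)
})

test_that("realized substitution counts track the Poisson expectation per class", {
  anc <- small_ancestor(seed = 11)
  cls <- plastocomp:::class_vec_from_features(anc$features, genome_length(anc))
  part <- attr(anc, "partition")
  pos0 <- seq_along(cls) - 1
  in_ira <- pos0 >= part$IRa[1] & pos0 < part$IRa[2]
  tree <- quick_tree4()
  tlen <- sum(tree$edge.length)
  rates <- c(CDS = 1, intron = 1.38, IGS = 2.02)
  for (sd in 1:10) {
    cfg <- evolution_config(tree = tree, region_rates = rates, indel_rate = 0,
                            ssr_slippage_rate = 0, seed = 100 + sd)
    sim <- evolve(anc, cfg)
    ev <- sim$truth$events
    for (cl in names(rates)) {
      code <- c(IGS = 0, intron = 1, CDS = 2)[[cl]]
      n_elig <- sum(cls == code & !in_ira) -
        if (cl == "IGS") sum(attr(anc, "ssr_truth")$unit *
                               attr(anc, "ssr_truth")$count + 2) else 0
      lambda <- tlen * rates[[cl]] * n_elig
      observed <- sum(ev$type == "sub" & ev$class == cl)
      expect_lt(abs(observed - lambda), 4 * sqrt(lambda) + 1)
    }
  }
})

test_that("IGS accumulates more substitutions per site than CDS", {
  anc <- small_ancestor(seed = 13)
  cls <- plastocomp:::class_vec_from_features(anc$features, genome_length(anc))
  wins <- 0
  for (sd in 1:8) {
    cfg <- evolution_config(tree = quick_tree4(),
                            region_rates = c(CDS = 1, intron = 1, IGS = 2),
                            indel_rate = 0, ssr_slippage_rate = 0, seed = 200 + sd)
    sim <- evolve(anc, cfg)
    ev <- sim$truth$events
    igs_rate <- sum(ev$type == "sub" & ev$class == "IGS") / sum(cls == 0)
    cds_rate <- sum(ev$type == "sub" & ev$class == "CDS") / sum(cls == 2)
    if (igs_rate > cds_rate) wins <- wins + 1
  }
  expect_gte(wins, 7)    # sign test at a 2x rate ratio
})

test_that("ndh deletions shrink the SSC and the total length by the deleted span", {
  anc <- small_ancestor(seed = 9)
  fid <- anc$features$feature_id[anc$features$name == "ndhG"][1]
  span <- plastocomp:::feature_span(anc, fid)
  cfg <- evolution_config(tree = quick_tree4(),
                          region_rates = c(CDS = 0, intron = 0, IGS = 0),
                          indel_rate = 0, ssr_slippage_rate = 0,
                          ndh_loss_events = data.frame(branch = "a", gene = "ndhG",
                                                       action = "delete"),
                          seed = 3)
  sim <- evolve(anc, cfg)
  dspan <- span[2] - span[1]
  p0 <- attr(anc, "partition")
  pa <- attr(sim$records[["a"]], "partition")
  expect_equal(genome_length(sim$records[["a"]]), genome_length(anc) - dspan)
  expect_equal(plastocomp:::interval_len(pa$SSC),
               plastocomp:::interval_len(p0$SSC) - dspan)
  expect_equal(genome_length(sim$records[["b"]]), genome_length(anc))
  expect_false("ndhG" %in% sim$records[["a"]]$features$name)

  # truncation introduces an internal stop without changing length
  cfg2 <- evolution_config(tree = quick_tree4(),
                           region_rates = c(CDS = 0, intron = 0, IGS = 0),
                           indel_rate = 0, ssr_slippage_rate = 0,
                           ndh_loss_events = data.frame(branch = "b", gene = "ndhF",
                                                        action = "truncate"),
                           seed = 3)
  sim2 <- evolve(anc, cfg2)
  s <- extract_feature_sequence(sim2$records[["b"]], "ndhF")
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  expect_true(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  expect_equal(genome_length(sim2$records[["b"]]), genome_length(anc))
})

test_that("unknown branches or genes in loss events are rejected", {
  expect_error(evolution_config(tree = quick_tree4(),
                                ndh_loss_events = data.frame(branch = "zz",
                                                             gene = "ndhF",
                                                             action = "delete")),
               "unknown branches")
  anc <- small_ancestor(seed = 2)
  cfg <- evolution_config(tree = quick_tree4(),
                          ndh_loss_events = data.frame(branch = "a", gene = "ndhD",
                                                       action = "delete"),
                          seed = 1)
  expect_error(evolve(anc, cfg), "absent")   # ndhD not in the reduced gene map
})

test_that("planted SSR loci and repeats are recoverable from the truth log", {
  sim <- shared_sim()
  thresholds <- c(10, 5, 3, 3, 3, 3)
  for (id in c("sp2", "sp7")) {
    rec <- sim$records[[id]]
    truth <- sim$truth$ssr[[id]]
    truth <- truth[truth$count >= thresholds[truth$unit], ]   # detectable loci
    found <- scan_ssrs(rec$sequence)
    hit <- merge(truth, found, by = c("motif", "unit", "start"))
    expect_equal(nrow(hit), nrow(truth))
    expect_equal(hit$count.x, hit$count.y)
  }
  pr <- sim$truth$planted_repeats
  reps <- find_long_repeats(sim$truth$ancestor$sequence)
  for (i in seq_len(nrow(pr))) {
    containing <- reps[reps$class == pr$class[i] &
                         reps$start1 <= pr$start1[i] & reps$end1 >= pr$end1[i] &
                         reps$start2 <= pr$start2[i] & reps$end2 >= pr$end2[i], ]
    expect_gte(nrow(containing), 1)
  }
})

test_that("codon-gene simulation honors site classes and degenerate settings", {
  tr <- quick_tree4()
  none <- simulate_codon_gene(tr, list(p0 = 1, p = 0.5, q = 1.5, omega_s = 1,
                                       kappa = 2), 50, seed = 1)
  expect_false(any(none$site_class == "positive"))

  sim <- simulate_codon_gene(tr, list(p0 = 0.9, p = 0.5, q = 1.5, omega_s = 3,
                                      kappa = 2), 300, seed = 42)
  n_pos <- sum(sim$site_class == "positive")
  expect_lt(abs(n_pos - 30), 3 * sqrt(300 * 0.1 * 0.9) + 1)

  tz <- tr
  tz$edge.length[] <- 0
  frozen <- simulate_codon_gene(tz, list(p0 = 0.9, p = 0.5, q = 1.5, omega_s = 3,
                                         kappa = 2), 60, seed = 3)
  expect_equal(length(unique(frozen$sequences)), 1)

  expect_error(simulate_codon_gene(tr, list(p0 = 0.9, p = -1, q = 1.5,
                                            omega_s = 3, kappa = 2), 10),
               "beta")
  expect_error(simulate_codon_gene(tr, list(p0 = 0.9, p = 0.5, q = 1.5,
                                            omega_s = 0.5, kappa = 2), 10),
               "omega_s")
})

test_that("evolution is deterministic for a fixed seed", {
  anc <- small_ancestor(seed = 21)
  cfg <- evolution_config(tree = quick_tree4(), seed = 77)
  s1 <- evolve(anc, cfg)
  s2 <- evolve(anc, cfg)
  expect_identical(lapply(s1$records, `[[`, "sequence"),
                   lapply(s2$records, `[[`, "sequence"))
  expect_identical(s1$truth$true_alignment, s2$truth$true_alignment)
})
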