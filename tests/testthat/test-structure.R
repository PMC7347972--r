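rotate_record <- function(rec, offset) {
  L <- genome_length(rec)
  s <- rec$sequence
  seq_rot <- paste0(substr(s, offset + 1, L), substr(s, 1, offset))
  f <- rec$features
  f2 <- feature_table()
  for (fid in unique(f$feature_id)) {
    p <- f[f$feature_id == fid, , drop = FALSE]
    p <- p[order(p$part), ]
    s2 <- (p$start - offset) %% L
    e2 <- s2 + (p$end - p$start)
    if (any(e2 > L)) next                      # would wrap; drop for this test
    f2 <- add_feature(f2, p$name[1], p$kind[1], p$strand[1],
                      cbind(s2, e2), p$codon_start[1])
  }
  plastome_record(rec$id, seq_rot, circular = TRUE, features = f2)
}

test_that("planted inverted repeats are recovered exactly", {
  for (sd in c(3, 8, 15)) {
    anc <- small_ancestor(seed = sd)
    p <- attr(anc, "partition")
    d <- detect_inverted_repeat(anc, min_len = 2500)
    expect_equal(unname(d$IRb), unname(p$IRb))
    expect_equal(unname(d$IRa), unname(p$IRa))
    expect_equal(sum(partition_lengths(d)), genome_length(anc))
  }
})

test_that("sequences without an IR raise a structure error", {
  s <- random_seq(20000, seed = 5)
  rec <- plastome_record("flat", s)
  expect_error(detect_inverted_repeat(rec, min_len = 2000),
               "no quadripartite structure")
  expect_error(detect_inverted_repeat(plastome_record("tiny", random_seq(3000, 1)),
                                      min_len = 2000),
               "shorter")
})

test_that("IR/SSC junction classification is invariant to genome rotation", {
  anc <- small_ancestor(seed = 6)
  base <- classify_ir_ssc_type(anc, detect_inverted_repeat(anc, min_len = 2500))
  for (offset in c(2000, 7000, 12000)) {
    rot <- rotate_record(anc, offset)
    expect_true("ndhF" %in% rot$features$name)
    d <- detect_inverted_repeat(rot, min_len = 2500)
    expect_equal(sum(partition_lengths(d)), genome_length(rot))
    expect_identical(classify_ir_ssc_type(rot, d), base)
  }
})

test_that("junction context reports signed overlaps with the documented convention", {
  # rpl22 in the small ancestor ends 20 bp before the LSC/IRb junction
  anc <- small_ancestor(seed = 2)
  d <- detect_inverted_repeat(anc, min_len = 2500)
  jr <- junction_report(anc, d)
  expect_equal(jr$overlap[jr$junction == "J_LB"], -20)
  expect_equal(jr$feature[jr$junction == "J_LB"], "rpl22")
  # ycf1 extends its configured overlap into the IRa
  expect_equal(jr$overlap[jr$junction == "J_SA"], 300)
  expect_equal(jr$feature[jr$junction == "J_SA"], "ycf1")

  # an ndhF annotated across the IRb/SSC junction is reported with its
  # in-IR overlap and drives the type-2 call
  anc2 <- small_ancestor(seed = 2, ndhF_ir_overlap = 16)
  d2 <- detect_inverted_repeat(anc2, min_len = 2500)
  jr2 <- junction_report(anc2, d2)
  expect_equal(jr2$feature[jr2$junction == "J_SB"], "ndhF")
  expect_equal(jr2$overlap[jr2$junction == "J_SB"], 16)
  expect_identical(classify_ir_ssc_type(anc2, d2), "TYPE2")
})

test_that("the three junction types are assigned from the ndhF configuration", {
  anc <- small_ancestor(seed = 10)
  d <- detect_inverted_repeat(anc, min_len = 2500)
  expect_identical(classify_ir_ssc_type(anc, d), "TYPE1")
  no_ndhf <- anc
  no_ndhf$features <- anc$features[anc$features$name != "ndhF", ]
  expect_identical(classify_ir_ssc_type(no_ndhf, d), "TYPE3")
})

test_that("ndh audit distinguishes intact, truncated, and lost genes", {
  sim <- shared_sim()
  anc <- sim$truth$ancestor
  ref <- sapply(c("ndhF", "ndhG", "ndhA"), function(g) {
    nchar(extract_feature_sequence(anc, g))
  })
  audit <- ndh_audit(sim$records, ref)
  # deletions configured on sp3/sp6 (ndhF), truncation on sp4 (ndhG)
  expect_equal(unname(audit["sp3", "ndhF"]), "lost")
  expect_equal(unname(audit["sp6", "ndhF"]), "lost")
  expect_equal(unname(audit["sp4", "ndhG"]), "truncated")
  expect_equal(unname(audit["sp1", "ndhF"]), "intact")
  expect_equal(unname(audit["sp5", "ndhG"]), "intact")
})

test_that("length regression matches closed-form identities", {
  x <- c(1, 2, 3, 4)
  reg <- suppressWarnings(length_regression(x, 2 * x + 5))  # exact fit intended
  expect_equal(reg$r_squared, 1)
  expect_equal(reg$slope, 2)

  set.seed(8)
  x <- rnorm(8); y <- x + rnorm(8)
  reg <- length_regression(x, y)
  expect_equal(reg$F_statistic, reg$r_squared * 6 / (1 - reg$r_squared))
  # against the standard linear-model F
  expect_equal(reg$F_statistic,
               unname(summary(lm(y ~ x))$fstatistic["value"]))
  expect_error(length_regression(rep(1, 5), rnorm(5)), "variance")
})

test_that("ndh/SSC correlation is driven by deletions and errors on constants", {
  sim <- shared_sim()
  parts <- lapply(sim$records, function(r) attr(r, "partition"))
  res <- ndh_ssc_correlation(sim$records, parts)
  expect_gt(res$r, 0.9)
  # identical genomes -> zero variance
  same <- rep(sim$records[1], 3)
  psame <- rep(parts[1], 3)
  expect_error(ndh_ssc_correlation(same, psame), "zero variance")
  # independent lengths are uncorrelated
  set.seed(5)
  far <- replicate(50, cor(rnorm(100), rnorm(100)))
  expect_gt(mean(abs(far) < 0.3), 0.95)
})

test_that("structure table satisfies the quadripartite length identity", {
  sim <- shared_sim()
  parts <- lapply(sim$records, function(r) attr(r, "partition"))
  st <- structure_table(sim$records, parts)
  expect_true(all(st$lsc_bp + st$ssc_bp + 2 * st$ir_bp == st$total_bp))
  expect_true(all(st$gc_ir > st$gc_ssc))    # rRNA-rich IR is GC-richest
})
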