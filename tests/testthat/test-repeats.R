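test_that("repeat finding equals the brute-force oracle on random sequences", {
  # many short sequences at a permissive length (hits arise by chance), a
  # few larger ones at the field's 30 bp / 3 mismatch setting with plants
  for (sd in 1:8) {
    n <- c(300, 500, 800, 1500)[(sd %% 4) + 1]
    s <- random_seq(n, seed = 400 + sd, gc = 0.45)
    a <- find_long_repeats(s, min_len = 12, max_mismatch = 2)
    b <- oracle_repeats(s, min_len = 12, max_mismatch = 2)
    expect_setequal(repeat_key(a), repeat_key(b))
    expect_equal(nrow(a), nrow(b))
  }
})

test_that("planted 35 bp duplicates with mismatches are found at genome defaults", {
  set.seed(77)
  for (sd in 1:4) {
    base <- random_seq(3000, seed = 500 + sd)
    piece <- substr(base, 101, 135)
    mutated <- strsplit(piece, "")[[1]]
    for (pos in c(10, 25)) {
      mutated[pos] <- setdiff(c("A", "C", "G", "T"), mutated[pos])[1]
    }
    s <- paste0(substr(base, 1, 2000), paste(mutated, collapse = ""),
                substr(base, 2036, 3000))
    hits <- find_long_repeats(s, min_len = 30, max_mismatch = 3,
                              classes = "forward")
    planted <- hits[hits$start1 <= 100 & hits$end1 >= 135 &
                      hits$start2 <= 2000 & hits$end2 >= 2035, ]
    expect_gte(nrow(planted), 1)
    expect_true(any(planted$mismatches >= 2))
    # and the full output still equals the oracle at these settings
    b <- oracle_repeats(s, min_len = 30, max_mismatch = 3)
    a <- find_long_repeats(s, min_len = 30, max_mismatch = 3)
    expect_setequal(repeat_key(a), repeat_key(b))
  }
})

test_that("sequences without self-similarity yield an empty result", {
  expect_equal(nrow(find_long_repeats(random_seq(200, 3), min_len = 30)), 0)
  expect_equal(nrow(find_long_repeats(random_seq(500, 1), min_len = 60)), 0)
})

test_that("SSR scanning applies thresholds and canonical motifs", {
  expect_equal(nrow(scan_ssrs(paste0("GG", strrep("A", 10), "GG"))), 1)
  got <- scan_ssrs(paste0("GG", strrep("A", 10), "GG"))
  expect_equal(got$motif, "A")
  expect_equal(got$count, 10)
  expect_equal(nrow(scan_ssrs(paste0("GG", strrep("A", 9), "GG"))), 0)

  di <- scan_ssrs(paste0("GGC", strrep("AT", 5), "GGC"))
  expect_equal(nrow(di), 1)
  expect_equal(di$motif, "AT")
  expect_equal(di$unit, 2)
  expect_equal(di$count, 5)

  # a poly-A run is never additionally reported as (AA)n or (AAA)n
  poly <- scan_ssrs(paste0("CC", strrep("A", 24), "CC"))
  expect_equal(nrow(poly), 1)
  expect_equal(poly$unit, 1)
})

test_that("SSR locus counts are invariant to reverse complementation", {
  for (sd in 1:5) {
    anc <- small_ancestor(seed = 30 + sd)
    s <- anc$sequence
    a <- scan_ssrs(s)
    b <- scan_ssrs(plastocomp:::revcomp(s))
    expect_equal(nrow(a), nrow(b))
    expect_equal(sort(table(a$motif)), sort(table(b$motif)))
  }
})

test_that("every reported SSR span re-validates as a perfect tandem", {
  anc <- small_ancestor(seed = 44)
  loci <- scan_ssrs(anc$sequence)
  expect_gt(nrow(loci), 0)
  for (i in seq_len(nrow(loci))) {
    span <- substr(anc$sequence, loci$start[i] + 1, loci$end[i])
    unit1 <- substr(span, 1, loci$unit[i])
    expect_identical(span, strrep(unit1, loci$count[i]))
  }
})

test_that("hits are classified by region with the majority/tie rule", {
  anc <- small_ancestor(seed = 3)
  part <- attr(anc, "partition")
  map <- region_class_map(anc)
  loci <- scan_ssrs(anc$sequence)
  cl <- classify_hits(loci, part, map)
  planted <- merge(cl$hits, attr(anc, "ssr_truth"),
                   by = c("motif", "unit", "start"))
  expect_equal(nrow(planted), nrow(attr(anc, "ssr_truth")))
  expect_true(all(planted$region == "LSC"))        # planted in LSC gaps
  expect_true(all(planted$region_class == "IGS"))

  # junction-spanning interval: majority overlap, tie to lower coordinate
  fake <- data.frame(motif = "A", unit = 1, count = 10,
                     start = part$IRb[1] - 4, end = part$IRb[1] + 6)
  got <- classify_hits(fake, part, map)
  expect_equal(got$hits$region, "IRb")             # 6 bp in IRb vs 4 in LSC
  fake2 <- data.frame(motif = "A", unit = 1, count = 10,
                      start = part$IRb[1] - 5, end = part$IRb[1] + 5)
  got2 <- classify_hits(fake2, part, map)
  expect_equal(got2$hits$region, "LSC")            # exact tie -> lower region
})

test_that("polymorphic SSR groups require presence in k species and variation", {
  sim <- shared_sim()
  loci <- lapply(sim$records, function(r) scan_ssrs(r$sequence))
  poly <- polymorphic_ssrs(loci, k = 4)
  expect_gt(length(unique(poly$locus_group)), 0)
  # every reported group is present in >= 4 species with >= 2 counts
  for (g in unique(poly$locus_group)) {
    rows <- poly[poly$locus_group == g, ]
    expect_gte(length(unique(rows$species)), 4)
    expect_gte(length(unique(rows$count)), 2)
  }
  # slipped planted loci are among the polymorphic groups
  truth_counts <- sapply(sim$truth$ssr, function(d) d$count[d$motif == "A"][1])
  if (length(unique(truth_counts)) >= 2) {
    expect_true("A" %in% poly$motif)
  }

  # three species only -> excluded at k = 4; monomorphic -> excluded
  mk <- function(count) data.frame(motif = "AT", unit = 2, count = count,
                                   start = 100, end = 100 + 2 * count,
                                   flank_left = strrep("C", 20),
                                   flank_right = strrep("G", 20),
                                   stringsAsFactors = FALSE)
  three <- list(a = mk(5), b = mk(6), c = mk(7))
  expect_equal(nrow(polymorphic_ssrs(three, k = 4)), 0)
  five_same <- list(a = mk(5), b = mk(5), c = mk(5), d = mk(5), e = mk(5))
  expect_equal(nrow(polymorphic_ssrs(five_same, k = 4)), 0)
  five_var <- list(a = mk(5), b = mk(5), c = mk(6), d = mk(7), e = mk(5))
  expect_equal(length(unique(polymorphic_ssrs(five_var, k = 4)$locus_group)), 1)
})

test_that("primer constraint checks evaluate each rule", {
  fwd <- strrep("AC", 10)            # 20-mer, 50% GC
  rev <- strrep("GT", 10)
  pass <- check_primer_constraints(fwd, rev, 300)
  expect_true(pass$pass)
  expect_false(check_primer_constraints(fwd, rev, 600)$product_ok)
  expect_false(check_primer_constraints(substr(fwd, 1, 17), rev, 300)$length_ok)
  expect_false(check_primer_constraints(strrep("AT", 10), rev, 300)$gc_ok)
  expect_error(check_primer_constraints("", rev, 300), "empty")
  # documented melting-temperature approximation
  expect_equal(primer_tm(fwd), 64.9 + 41 * (10 - 16.4) / 20)
})
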