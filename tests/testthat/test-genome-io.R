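test_that("GenBank coordinates convert to 0-based half-open and round-trip", {
  gb <- c(
    "LOCUS       toy 100 bp    DNA     circular PLN 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             11..40",
    "                     /gene=\"psbA\"",
    "                     /codon_start=1",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  rec <- read_annotated_genome(path, "genbank")
  expect_equal(genome_length(rec), 100)
  expect_true(rec$circular)
  f <- rec$features
  expect_equal(nrow(f), 1)
  expect_equal(f$start, 10)
  expect_equal(f$end, 40)
  expect_equal(f$strand, "+")

  # full round trip on a feature-rich synthetic record
  anc <- small_ancestor(seed = 2)
  out <- withr::local_tempfile(fileext = ".gb")
  write_genbank(anc, out, date = "01-JAN-2026")
  back <- read_annotated_genome(out, "genbank")
  expect_equal(back$sequence, anc$sequence)
  a <- anc$features[order(anc$features$feature_id, anc$features$part), ]
  b <- back$features[order(back$features$feature_id, back$features$part), ]
  for (col in c("name", "kind", "strand", "codon_start", "start", "end")) {
    expect_equal(unname(b[[col]]), unname(a[[col]]), label = col)
  }
})

test_that("malformed or non-DNA input is rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not a genbank file"), path)
  expect_error(read_annotated_genome(path, "genbank"), "LOCUS")
  expect_error(plastome_record("x", "ACGRT"), "alphabet")
  expect_error(plastome_record("x", ""), "nonempty")
})

test_that("gc_content handles intervals, wraps, N exclusion and degenerate input", {
  r <- plastome_record("t", "ATGC", circular = TRUE)
  expect_equal(gc_content(r), 0.5)
  expect_equal(gc_content(plastome_record("t", "AAAA")), 0)
  expect_equal(gc_content(plastome_record("t", "AANGC")), 2 / 4)
  # wrapped interval on circular record: last 2 + first 2 bases
  expect_equal(gc_content(r, c(2, 1)), 2 / 3)  # "GC" + "A"
  expect_error(gc_content(r, c(1, 1)), "empty")
  expect_error(gc_content(plastome_record("t", "NNNN")), "unambiguous")
})

test_that("gc_content of the whole equals the length-weighted partition mean", {
  anc <- small_ancestor(seed = 5)
  L <- genome_length(anc)
  cuts <- sort(sample(seq(100, L - 100), 4))
  bounds <- rbind(c(0, cuts[1]), cbind(cuts[-4], cuts[-1]), c(cuts[4], L))
  parts <- apply(bounds, 1, function(iv) {
    gc_content(anc, iv) * (iv[2] - iv[1])
  })
  expect_equal(sum(parts) / L, gc_content(anc), tolerance = 1e-12)
})

test_that("region classification labels exons, introns and IGS and tiles the genome", {
  feats <- add_feature(feature_table(), "X", "CDS", "+",
                       rbind(c(10, 22), c(50, 62)), codon_start = 0)
  seq100 <- strrep("ACGT", 25)
  rec <- plastome_record("t", seq100, features = feats)
  map <- region_class_map(rec)
  expect_equal(map$class[map$start == 10], "CDS")
  intron <- map[map$class == "intron", ]
  expect_equal(c(intron$start, intron$end), c(22, 50))
  expect_equal(intron$locus, "X")
  igs <- map[map$class == "IGS", ]
  expect_equal(sort(igs$start), c(0, 62))   # wraps around the origin
  expect_equal(sum(map$end - map$start), 100)

  # zero features -> one genome-wide IGS
  bare <- plastome_record("t", seq100)
  map0 <- region_class_map(bare)
  expect_equal(nrow(map0), 1)
  expect_equal(map0$class, "IGS")

  # tiling holds across random synthetic records
  for (sd in 1:40) {
    f <- feature_table()
    pos <- 0
    set.seed(sd)
    for (i in seq_len(sample(1:6, 1))) {
      s <- pos + sample(5:30, 1)
      e <- s + 3 * sample(4:20, 1)
      if (e > 960) break
      f <- add_feature(f, paste0("g", i), "CDS", sample(c("+", "-"), 1),
                       rbind(c(s, e)))
      pos <- e
    }
    rec <- plastome_record("t", random_seq(1000, sd), features = f)
    m <- region_class_map(rec)
    expect_equal(sum(m$end - m$start), 1000)
    expect_true(all(m$start[-1] == m$end[-nrow(m)]))
  }
})

test_that("feature extraction follows strand and multi-part reading order", {
  seq <- "ATGAAATAAGGGCCCTTTACGTACGTACGT"
  f <- add_feature(feature_table(), "g1", "CDS", "+", rbind(c(0, 9)))
  rec <- plastome_record("t", seq, features = f)
  expect_equal(extract_feature_sequence(rec, "g1"), "ATGAAATAA")
  f2 <- add_feature(feature_table(), "g2", "CDS", "-", rbind(c(0, 9)))
  rec2 <- plastome_record("t", seq, features = f2)
  expect_equal(extract_feature_sequence(rec2, "g2"), "TTATTTCAT")

  # two-part minus-strand feature vs slice+revcomp composition
  fm <- add_feature(feature_table(), "g3", "CDS", "-",
                    rbind(c(20, 26), c(3, 9)))      # reading order parts
  rec3 <- plastome_record("t", seq, features = fm)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  manual <- paste0(rc(substr(seq, 21, 26)), rc(substr(seq, 4, 9)))
  expect_equal(extract_feature_sequence(rec3, "g3"), manual)
})

test_that("aligned FASTA round-trips through write_fasta/read_alignment", {
  seqs <- c(s1 = "ACGT-ACGT", s2 = "ACGTTAC-T")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  m <- read_alignment(path)
  expect_equal(dim(m), c(2, 9))
  expect_equal(paste(m["s2", ], collapse = ""), seqs[["s2"]])
})
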