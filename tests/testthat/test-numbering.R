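test_that("conservation profiles count exactly", {
  # single sequence: every non-gap column is 100% its residue
  p1 <- build_profile(c(s1 = "MKT-A"))
  expect_equal(p1$summary$percent[c(1, 2, 3, 5)], rep(100, 4))
  expect_equal(p1$summary$top_residue[1:3], c("M", "K", "T"))

  # two sequences differing at one column: 50/50 there, 100 elsewhere
  p2 <- build_profile(c(a = "MKTA", b = "MKSA"))
  expect_equal(p2$summary$percent, c(100, 100, 50, 100))

  # planted 9/10 lysine column
  seqs <- c(rep("AKG", 9), "ARG")
  p3 <- build_profile(seqs)
  expect_equal(p3$summary$percent[2], 90)
  expect_equal(p3$summary$top_residue[2], "K")

  # per-column counts always sum to n_sequences
  counts <- p3$counts
  sums <- tapply(counts$count, counts$column, sum)
  expect_true(all(sums == 10))
})

test_that("profiles are permutation-invariant and validate their input", {
  seqs <- make_synthetic_msa(20, c(0.9, 0.5, 0.7), seed = 5)
  p <- build_profile(seqs)
  p_rev <- build_profile(rev(seqs))
  expect_equal(p$summary, p_rev$summary)
  expect_equal(p$counts, p_rev$counts)

  expect_error(build_profile(c("MKT", "MK")), class = "dsa_data_error")
  expect_error(build_profile(character()), class = "dsa_data_error")
  expect_error(build_profile(c("MZT")), class = "dsa_data_error")
})

test_that("gap handling in the denominator is switchable", {
  seqs <- c("A-", "A-", "AK", "AK")
  incl <- build_profile(seqs)                      # gaps count in denominator
  excl <- build_profile(seqs, exclude_gaps = TRUE)
  expect_equal(incl$summary$percent[2], 50)
  expect_equal(excl$summary$percent[2], 100)
})

test_that("anchor assignment picks the most conserved column with documented ties", {
  seqs <- make_synthetic_msa(50, c(0.5, 0.6, 1.0, 0.55, 0.4), seed = 9)
  prof <- build_profile(seqs)
  a <- assign_anchor(prof, c(1, 5), helix = "B")
  expect_equal(a$column, 3L)
  expect_equal(a$percent, 100)
  expect_equal(a$helix, 2L)

  # exact tie: lowest column index wins, with a warning
  tie <- build_profile(c("AKKk", "AKKA", "AKKA", "GKKG"))
  expect_warning(at <- assign_anchor(tie, c(2, 3)), regexp = "tie")
  expect_equal(at$column, 2L)

  # all-gap window errors
  gappy <- build_profile(c("A--K", "A--K"))
  expect_error(assign_anchor(gappy, c(2, 3)), class = "dsa_data_error")
})

test_that("helix numbering spans the window around its .50 anchor", {
  # a 24-column window whose anchor sits 17 positions in: labels 2.33-2.56
  win <- c(2, 25)
  labels <- number_helix(win[1] + 17L, win, "2.50")
  expect_equal(nrow(labels), 24L)
  expect_equal(labels$label[1], "2.33")
  expect_equal(labels$label[24], "2.56")
  expect_equal(labels$label[labels$column == win[1] + 17L], "2.50")

  # single-column window: that column is the anchor
  one <- number_helix(4L, c(4, 4), "5.50")
  expect_equal(one$label, "5.50")

  # the +3 column after a 6.50 anchor is 6.53
  f <- number_helix(10L, c(1, 20), "6.50")
  expect_equal(f$label[f$column == 13L], "6.53")
  expect_equal(f$label[f$column == 14L], "6.54")

  # bijection between columns and labels
  expect_equal(anyDuplicated(f$label), 0L)
  expect_equal(f$column, seq.int(1, 20))

  # windows running past h.0 are rejected
  expect_error(number_helix(60L, c(1, 70), "3.50"), class = "dsa_range_error")
  expect_error(number_helix(5L, c(1, 10), "3.49"), class = "dsa_config_error")
})

test_that("planted anchors are recovered at family-like conservation levels", {
  # seven 10-column helix windows; anchor column 6 of each window planted at
  # the reference family's anchor conservation, background at 30%
  anchor_levels <- c(0.64, 0.95, 0.98, 0.95, 0.70, 0.98, 1.00)
  levels <- unlist(lapply(anchor_levels, function(a) c(rep(0.30, 5), a, rep(0.30, 4))))
  seqs <- make_synthetic_msa(603, levels, seed = 12)
  prof <- build_profile(seqs)
  for (h in 1:7) {
    win <- c((h - 1) * 10 + 1, h * 10)
    a <- assign_anchor(prof, win, helix = h)
    expect_equal(a$column, (h - 1L) * 10L + 6L)
    lab <- number_helix(a$column, win, render_label(h, 50L))
    expect_equal(lab$label[lab$column == a$column], render_label(h, 50L))
  }
})

test_that("synthetic alignments are reproducible with calibrated conservation", {
  s1 <- make_synthetic_msa(100, c(1, 0.64, 0.2), seed = 3)
  s2 <- make_synthetic_msa(100, c(1, 0.64, 0.2), seed = 3)
  expect_identical(s1, s2)

  # level-1 column is invariant
  expect_equal(length(unique(substr(s1, 1, 1))), 1L)

  # a 0.64-level column over 603 sequences lands inside the binomial 99% CI
  big <- make_synthetic_msa(603, 0.64, seed = 8)
  prof <- build_profile(big)
  half_width <- 2.576 * sqrt(0.64 * 0.36 / 603) * 100
  expect_lt(abs(prof$summary$percent[1] - 64), half_width)
})

test_that("alignments round-trip through FASTA and Clustal readers", {
  seqs <- make_synthetic_msa(8, c(0.9, 1, 0.5, 0.7), seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(seqs, fa)
  back <- read_msa(fa)
  expect_equal(unname(back), unname(seqs))
  expect_equal(names(back), names(seqs))

  # hand-written Clustal block
  aln <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "sp1             MKT-A",
               "sp2             MKSGA",
               "                ** .*", ""), aln)
  cl <- read_msa(aln)
  expect_equal(unname(cl), c("MKT-A", "MKSGA"))
})
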