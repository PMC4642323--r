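test_that("identical rows give zero distances and an undefined ratio", {
  row <- c("ATG", "AAA", "GGC", "TTT")
  e <- nei_gojobori(row, row)
  expect_equal(e$Sd, 0); expect_equal(e$Nd, 0)
  expect_equal(e$Ks, 0); expect_equal(e$Ka, 0)
  expect_true(e$undefined)
  expect_true(is.na(e$ratio))
})

test_that("the single-codon worked example is reproduced exactly", {
  # TTT (Phe) vs TTA (Leu): one nonsynonymous difference; averaged sites
  # S = (1/3 + 2/3)/2 = 0.5 (TTA's position 2 has both stop changes
  # excluded from the possible-change count)
  e <- nei_gojobori("TTT", "TTA")
  expect_equal(e$S, 0.5, tolerance = 1e-12)
  expect_equal(e$N, 2.5, tolerance = 1e-12)
  expect_equal(e$Sd, 0); expect_equal(e$Nd, 1)
  expect_equal(e$pN, 0.4, tolerance = 1e-12)
  expect_equal(e$Ks, 0)
  expect_true(is.na(e$ratio))
})

test_that("estimates are symmetric and conserve sites", {
  set.seed(51)
  for (rep in 1:5) {
    a <- random_sense_codons(60)
    b <- random_sense_codons(60)
    # bring b close enough to avoid saturation
    keep <- sample(60, 45)
    b[keep] <- a[keep]
    e1 <- nei_gojobori(a, b)
    e2 <- nei_gojobori(b, a)
    expect_equal(e1$Ks, e2$Ks, tolerance = 1e-12)
    expect_equal(e1$Ka, e2$Ka, tolerance = 1e-12)
    expect_equal(e1$S + e1$N, 3 * 60, tolerance = 1e-9)
  }
})

test_that("pairwise estimates equal the brute-force pathway oracle", {
  set.seed(52)
  a <- random_sense_codons(500)
  b <- a
  flip <- sample(500, 120)
  b[flip] <- random_sense_codons(120)
  ours <- nei_gojobori(a, b)
  oracle <- oracle_nei_gojobori(a, b)
  expect_equal(ours$S, oracle$S, tolerance = 1e-9)
  expect_equal(ours$N, oracle$N, tolerance = 1e-9)
  expect_equal(ours$Sd, oracle$Sd, tolerance = 1e-9)
  expect_equal(ours$Nd, oracle$Nd, tolerance = 1e-9)
  expect_equal(ours$Ks, oracle$Ks, tolerance = 1e-9)
  expect_equal(ours$Ka, oracle$Ka, tolerance = 1e-9)
})

test_that("gapped columns are dropped pairwise", {
  a <- c("ATG", "---", "GGC")
  b <- c("ATG", "AAA", "GGC")
  e <- nei_gojobori(a, b)
  expect_equal(e$n_codons, 2)
  expect_equal(e$S + e$N, 6, tolerance = 1e-9)
})

test_that("saturation and degenerate inputs raise the documented errors", {
  expect_error(jukes_cantor(0.8), class = "nbsevol_saturated")
  expect_equal(jukes_cantor(0), 0)
  # strictly increasing on [0, 3/4)
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jukes_cantor(p)) > 0))
  expect_error(nei_gojobori(c("---"), c("---")), "zero comparable")
  expect_error(nei_gojobori(c("ATG", "AAA"), c("ATG")), "equal length")
})

test_that("back-translation maps residues to codons and gaps to ---", {
  aln <- rbind(a = c("M", "-", "A"), b = c("M", "K", "A"))
  cds <- c(a = "ATGGCT", b = "ATGAAAGCT")
  caln <- backtranslate_alignment(aln, cds)
  expect_identical(unname(caln["a", ]), c("ATG", "---", "GCT"))
  expect_identical(unname(caln["b", ]), c("ATG", "AAA", "GCT"))

  # gap-free alignment is the codon concatenation
  aln2 <- rbind(x = c("M", "K"))
  caln2 <- backtranslate_alignment(aln2, c(x = "ATGAAA"))
  expect_identical(unname(caln2["x", ]), c("ATG", "AAA"))

  expect_error(backtranslate_alignment(aln, c(a = "ATGTAAGCT",
                                              b = "ATGAAAGCT")),
               "internal stop")
  expect_error(backtranslate_alignment(aln, c(a = "ATGGCT",
                                              b = "ATGAATGCT")),
               "mismatch")
})

test_that("family summaries average pairwise estimates", {
  # two-member family equals its single pairwise estimate
  caln <- rbind(a = c("ATG", "AAA", "CTT", "GGC", "TAT", "CAA", "GAC"),
                b = c("ATG", "AAG", "CTT", "GGC", "TAT", "CAA", "GAT"))
  fam <- family_kaks(caln)
  single <- nei_gojobori(caln["a", ], caln["b", ])
  expect_equal(fam$Ka, single$Ka)
  expect_equal(fam$Ks, single$Ks)
  expect_equal(fam$n_pairs, 1)

  # identical members: defined Ks = 0, ratio flagged undefined
  caln2 <- rbind(a = c("ATG", "AAA"), b = c("ATG", "AAA"),
                 c = c("ATG", "AAA"))
  fam2 <- family_kaks(caln2)
  expect_equal(fam2$Ks, 0)
  expect_true(is.na(fam2$ratio))
})

test_that("Ks profile bins are half-open with a separate overflow tally", {
  est <- data.frame(Ks = c(0.45, 0.42, 0.13, 1.2, 0.1),
                    ratio = c(0.5, 0.7, 0.2, 0.1, NA))
  prof <- ks_profile(est)
  expect_equal(prof$count[prof$bin_lo == 0.4], 2)
  expect_equal(prof$count[prof$bin_lo == 0.1], 2)  # 0.1 falls in [0.1, 0.2)
  expect_equal(attr(prof, "n_above"), 1)
  expect_equal(sum(prof$frequency), 4 / 5)
  expect_equal(prof$mean_ratio[prof$bin_lo == 0.4], 0.6)
  # all-identical values land in a single bin
  prof2 <- ks_profile(data.frame(Ks = rep(0.05, 4), ratio = rep(1, 4)))
  expect_equal(prof2$count[1], 4)
  expect_equal(sum(prof2$count), 4)
})
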