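test_that("promoter extraction does the strand-aware coordinate arithmetic", {
  genome <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 500), collapse = ""))
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1001, 101, 200),
                             end = c(1300, 400, 340)),
    strand = c("+", "-", "+"))
  gr$gene_id <- c("plus", "minus", "short")
  prom <- extract_promoters(genome, gr, length = 1000)

  # + gene at 1001: promoter is bases 1..1000
  expect_identical(unname(prom["plus"]), substr(genome[[1]], 1, 1000))
  # - gene ending at 400: promoter is revcomp of bases 401..1400
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(genome[[1]], 401, 1400))))
  expect_identical(unname(prom["minus"]), expected)
  # + gene 200 bp from the contig start: truncated to 199 bp and flagged
  expect_equal(nchar(prom[["short"]]), 199)
  trunc <- attr(prom, "truncated")
  expect_true(trunc[["short"]])
  expect_false(trunc[["plus"]])

  bad <- GenomicRanges::GRanges("chrX", IRanges::IRanges(10, 20),
                                strand = "+")
  bad$gene_id <- "x"
  expect_error(extract_promoters(genome, bad, 100), "absent")
})

test_that("scanning reports overlapping hits on both strands", {
  hits <- scan_motifs(c(g = "AAAGCTTT"), c(M = "AAAG"))
  fwd <- hits[hits$strand == "+", ]
  rev_ <- hits[hits$strand == "-", ]
  expect_equal(fwd$start, 1)
  expect_equal(rev_$start, 5)  # CTTT at 5..8 is AAAG on the minus strand

  # degenerate codes: W = A/T
  expect_equal(nrow(scan_motifs(c(g = "TAAAG"),
                                c(M = "WAAAG"))[
                                  scan_motifs(c(g = "TAAAG"),
                                              c(M = "WAAAG"))$strand == "+", ]),
               1)
  # overlapping occurrences all counted
  h2 <- scan_motifs(c(g = "AAAAA"), c(M = "AA"))
  expect_equal(sum(h2$strand == "+"), 4)
  # palindrome: one hit per strand at the same site
  h3 <- scan_motifs(c(g = "GGTACC"), c(M = "GTAC"))
  expect_equal(nrow(h3), 2)
  expect_setequal(h3$strand, c("+", "-"))
})

test_that("N in the subject only matches a motif N", {
  expect_equal(nrow(scan_motifs(c(g = "ANAG"), c(M = "AAAG"))), 0)
  h <- scan_motifs(c(g = "ANAG"), c(M = "ANAG"))
  expect_true(any(h$strand == "+"))
  expect_error(scan_motifs(c(g = "AAAA"), c(M = "AAZG")), "invalid IUPAC")
})

test_that("scanner matches the naive sliding-window oracle", {
  set.seed(91)
  motifs <- c(DOF = "AAAG", W = "TTGAC", DEG = "CANNTG", GT1 = "GRWAAW")
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
    hits <- scan_motifs(stats::setNames(seq, "g"), motifs)
    for (mn in names(motifs)) {
      fwd <- sort(hits$start[hits$motif == mn & hits$strand == "+"])
      rev_ <- sort(hits$start[hits$motif == mn & hits$strand == "-"])
      expect_identical(fwd, oracle_scan_one_strand(seq, motifs[[mn]]),
                       label = paste(mn, "+"))
      expect_identical(rev_,
                       oracle_scan_one_strand(seq,
                                              oracle_revcomp(motifs[[mn]])),
                       label = paste(mn, "-"))
    }
  }
})

test_that("reverse-complementing the promoter swaps strand counts", {
  set.seed(92)
  motifs <- c(DOF = "AAAG", BOX = "TGACT")
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_motifs(c(g = seq), motifs)
  h2 <- scan_motifs(c(g = rc), motifs)
  for (mn in names(motifs)) {
    expect_equal(sum(h1$motif == mn & h1$strand == "+"),
                 sum(h2$motif == mn & h2$strand == "-"))
    expect_equal(sum(h1$motif == mn & h1$strand == "-"),
                 sum(h2$motif == mn & h2$strand == "+"))
  }
})

test_that("the census reports occurrences and genes with conservation", {
  hits <- data.frame(
    gene_id = c(rep(paste0("g", 1:10), each = 3), "g1"),
    motif = c(rep("DOF", 30), "W"),
    strand = "+", start = 1)
  cen <- motif_census(hits, paste0("g", 1:12), c("DOF", "W", "NONE"))
  expect_equal(cen$occurrences[cen$motif == "DOF"], 30)
  expect_equal(cen$genes_with_hit[cen$motif == "DOF"], 10)
  expect_equal(cen$occurrences[cen$motif == "W"], 1)
  expect_equal(cen$occurrences[cen$motif == "NONE"], 0)
  expect_equal(cen$genes_with_hit[cen$motif == "NONE"], 0)
  expect_equal(sum(cen$occurrences), nrow(hits))
  expect_identical(cen$motif[1], "DOF")  # sorted by gene count
})

test_that("IUPAC reverse complement round-trips", {
  expect_identical(revcomp_iupac("AAAG"), "CTTT")
  expect_identical(revcomp_iupac("CANNTG"), "CANNTG")  # palindromic pattern
  expect_identical(revcomp_iupac(revcomp_iupac("GRWAAW")), "GRWAAW")
  expect_error(revcomp_iupac("AXG"), "invalid IUPAC")
})
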