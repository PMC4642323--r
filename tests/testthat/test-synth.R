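small_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    species_names = c("speciesA", "speciesB"),
    family_specs = list(
      family_spec(4, "TNL", target_ks = 0.2, omega = 0.3, cds_codons = 80),
      family_spec(3, "CNL", target_ks = 0.4, omega = 0.3, cds_codons = 80,
                  rnl = TRUE),
      family_spec(2, "XN", target_ks = 0.1, omega = 0.2, cds_codons = 80,
                  species = "speciesB")
    ),
    singleton_count = 3, singleton_codons = 80,
    promoter_length = 300,
    motifs = c(DOFCOREZM = "AAAG", WBOXATNPR1 = "TTGAC"),
    planted_motifs = c(DOFCOREZM = 3L),
    genome_gene_total = 500, ...)
}

test_that("evolution along a zero branch is the identity", {
  p <- codon_params(2, 0.3)
  root <- c("ATG", "AAA", "GGG")
  expect_identical(evolve_codon_sequence(root, 0, p), root)
})

test_that("omega = 0 forbids nonsynonymous change", {
  p <- codon_params(kappa = 2, omega = 0)
  set.seed(3)
  root <- sample_root_codons(400, p)
  tip <- evolve_codon_sequence(root, 5, p)
  aa <- codon_amino_acids()
  expect_identical(unname(aa[tip]), unname(aa[root]))
  expect_gt(sum(tip != root), 0)  # synonymous change did happen
})

test_that("long evolution converges to the stationary distribution", {
  pi <- rep(1 / 61, 61)
  p <- codon_params(kappa = 2, omega = 0.5, pi = pi)
  set.seed(11)
  root <- rep("ATG", 6000)  # far from stationarity
  tip <- evolve_codon_sequence(root, 60, p)
  freq <- tabulate(match(tip, sense_codons()), 61) / length(tip)
  expect_lt(max(abs(freq - pi)), 4 * sqrt(max(pi * (1 - pi)) / length(tip)) + 0.005)
})

test_that("stop codons and invalid codons are rejected", {
  p <- codon_params(2, 0.3)
  expect_error(evolve_codon_sequence(c("ATG", "TAA"), 0.1, p), "invalid codon")
  expect_error(evolve_codon_sequence(c("ATG", "NNN"), 0.1, p), "invalid codon")
})

test_that("simulated dataset conserves gene counts across outputs", {
  dir <- withr::local_tempdir()
  man <- simulate_dataset(small_config(seed = 7), dir)
  expect_equal(nrow(man$genes), 4 + 3 + 2 + 3)
  expect_equal(sum(!is.na(man$genes$family)), 9)
  expect_equal(length(unique(stats::na.omit(man$genes$family))), 3)
  prot <- read_fasta(file.path(dir, "proteins.faa"), "AA")
  cds <- read_fasta(file.path(dir, "cds.fna"), "DNA")
  gff <- read_gff_genes(file.path(dir, "genes.gff3"))
  expect_setequal(names(prot), man$genes$gene_id)
  expect_setequal(names(cds), man$genes$gene_id)
  expect_setequal(gff$gene_id, man$genes$gene_id)
  # in-frame CDS translating to the protein, no stops
  for (id in names(prot)) {
    expect_identical(translate_cds(cds[[id]]), unname(prot[id]))
  }
  # exon counts recovered from the GFF match the manifest
  expect_equal(
    stats::setNames(gff$exon_count, gff$gene_id)[man$genes$gene_id],
    stats::setNames(man$genes$exon_count, man$genes$gene_id))
})

test_that("identical configurations reproduce byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(small_config(seed = 5), d1)
  simulate_dataset(small_config(seed = 5), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  simulate_dataset(small_config(seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "cds.fna")),
                         readLines(file.path(d3, "cds.fna"))))
})

test_that("planted motif counts are exactly recoverable on the forward strand", {
  for (seed in c(13, 14, 15)) {
    dir <- withr::local_tempdir()
    cfg <- small_config(seed = seed)
    cfg$planted_motifs <- c(DOFCOREZM = 3L, WBOXATNPR1 = 2L)
    man <- simulate_dataset(cfg, dir)
    prom <- read_fasta(file.path(dir, "promoters.fna"), "DNA")
    hits <- scan_motifs(prom, cfg$motifs)
    fwd <- hits[hits$strand == "+", ]
    for (mn in names(cfg$planted_motifs)) {
      counts <- table(factor(fwd$gene_id[fwd$motif == mn],
                             levels = names(prom)))
      expect_true(all(counts == cfg$planted_motifs[[mn]]),
                  label = sprintf("seed %d motif %s", seed, mn))
    }
  }
})

test_that("configuration invariants are enforced", {
  expect_error(
    sim_config(family_specs = list(family_spec(10)), singleton_count = 5,
               genome_gene_total = 12),
    "exceeds genome_gene_total")
  expect_error(family_spec(0), "size")
  expect_error(
    sim_config(planted_motifs = c(NOSUCH = 1L),
               motifs = c(DOFCOREZM = "AAAG")))
})
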