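test_that("protein distances follow their definitions", {
  msa <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
               b = strsplit("AAAAAAAAAC", "")[[1]],
               c = strsplit("AAAAAAAAAA", "")[[1]])
  Dp <- protein_distance(msa, "p")
  expect_equal(Dp["a", "b"], 0.1)
  expect_equal(Dp["a", "c"], 0)
  Dpois <- protein_distance(msa, "poisson")
  expect_equal(Dpois["a", "b"], -log(1 - 0.1))
  # gap columns are excluded pairwise
  msa2 <- rbind(a = c("A", "-", "C", "D"), b = c("A", "K", "C", "E"),
                c = c("A", "K", "C", "D"))
  expect_equal(protein_distance(msa2, "p")["a", "b"], 1 / 3)
  expect_equal(protein_distance(msa2, "p")["b", "c"], 1 / 4)
  # saturation errors under the poisson model
  msa3 <- rbind(a = c("A", "A"), b = c("C", "C"), c = c("A", "C"))
  expect_error(protein_distance(msa3, "poisson"),
               class = "nbsevol_saturated")
})

test_that("three-taxon branch lengths follow the closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (2 + 3 - 4) / 2)
  expect_equal(unname(bl["B"]), (2 + 4 - 3) / 2)
  expect_equal(unname(bl["C"]), (3 + 4 - 2) / 2)
})

test_that("additive distances are recovered exactly", {
  set.seed(81)
  for (rep in 1:3) {
    tr <- ape::rtree(6)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 1)
    D <- stats::cophenetic(tr)
    est <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(est, ape::unroot(tr)), 0)
    expect_equal(sort(stats::cophenetic(est)[rownames(D), colnames(D)]),
                 sort(D), tolerance = 1e-8)
  }
})

test_that("random matrices give the same topology as the independent ape NJ", {
  set.seed(82)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    D <- random_distance_matrix(n)
    t1 <- neighbor_joining(D)
    t2 <- ape::nj(D)
    expect_equal(phangorn::RF.dist(t1, t2), 0)
  }
})

test_that("input validation rejects malformed matrices", {
  D <- random_distance_matrix(4)
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 0.5
  expect_error(neighbor_joining(Dbad), "symmetric")
  expect_error(neighbor_joining(D[1:2, 1:2]))
})

test_that("invariantly supported bipartitions get bootstrap support 100", {
  # every column separates {a, b} from {c, d, e}
  col1 <- c(a = "A", b = "A", c = "C", d = "C", e = "D")
  col2 <- c(a = "K", b = "K", c = "E", d = "D", e = "D")
  msa <- cbind(matrix(rep(col1, 10), ncol = 10),
               matrix(rep(col2, 8), ncol = 8))
  rownames(msa) <- names(col1)
  tr <- bootstrap_nj(msa, replicates = 50, seed = 4, model = "p")
  mono <- clade_monophyly(tr, c("a", "b"))
  expect_true(mono$is_monophyletic)
  expect_equal(mono$support, 100)
})

test_that("a single replicate yields supports of 0 or 100 and seeds reproduce", {
  set.seed(83)
  msa <- matrix(sample(c("A", "C", "D", "E"), 6 * 40, replace = TRUE),
                nrow = 6, dimnames = list(paste0("t", 1:6), NULL))
  tr1 <- bootstrap_nj(msa, replicates = 1, seed = 9, model = "p")
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  tr2 <- bootstrap_nj(msa, replicates = 25, seed = 9, model = "p")
  tr3 <- bootstrap_nj(msa, replicates = 25, seed = 9, model = "p")
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr3))
})

test_that("species-specific clades respect the strict support threshold", {
  txt <- "((a1:1,a2:1)45:1,(a3:1,a4:1)80:1,(b1:1,b2:1)90:1);"
  tr <- ape::read.tree(text = txt)
  spp <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A", b1 = "B", b2 = "B")
  rep_all <- species_specific_clades(tr, spp, support_threshold = 50)
  found <- lapply(rep_all$clades, paste, collapse = ",")
  expect_true("a3,a4" %in% found)
  expect_true("b1,b2" %in% found)
  expect_false("a1,a2" %in% found)  # support 45 not counted at threshold 50
  expect_equal(rep_all$n_genes, sum(lengths(rep_all$clades)))

  # focal species restriction
  rep_a <- species_specific_clades(tr, spp, support_threshold = 50,
                                   focal = "A")
  expect_equal(rep_a$n_clades, 1)
  expect_equal(rep_a$proportion, proportion_pct(2, 4))
  expect_error(species_specific_clades(tr, spp[-1]), "species unknown")
})

test_that("maximality prevents counting nested clades", {
  txt <- "(((a1:1,a2:1)100:1,(a3:1,a4:1)100:1)100:1,(a5:1,a6:1)100:1,o1:4);"
  tr <- ape::read.tree(text = txt)
  spp <- c(a1 = "A", a2 = "A", a3 = "A", a4 = "A", a5 = "A", a6 = "A",
           o1 = "B")
  rep <- species_specific_clades(tr, spp, support_threshold = 50,
                                 focal = "A")
  # clades must be disjoint and none nested inside another counted clade
  all_genes <- unlist(rep$clades)
  expect_equal(length(all_genes), length(unique(all_genes)))
  expect_equal(rep$n_genes, 6)
})

test_that("monophyly is an exact bipartition test", {
  tr <- ape::read.tree(text = "((a:1,b:1)90:1,(c:1,d:1)80:1,e:1);")
  expect_true(clade_monophyly(tr, c("a", "b"))$is_monophyletic)
  expect_equal(clade_monophyly(tr, c("a", "b"))$support, 90)
  expect_false(clade_monophyly(tr, c("a", "c"))$is_monophyletic)
  expect_true(clade_monophyly(tr, c("a", "b", "c", "d"))$is_monophyletic)
  expect_true(clade_monophyly(tr, "a")$is_monophyletic)  # trivial
})
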