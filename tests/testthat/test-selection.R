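# a tiny shared fixture: 4 sequences, 60 codons, simulated under M0
sim_family <- function(seed, omega = 0.3, n_codons = 60, n_taxa = 4,
                       t_tip = 0.15) {
  p <- codon_params(kappa = 2, omega = omega)
  set.seed(seed)
  root <- sample_root_codons(n_codons, p)
  rows <- t(vapply(seq_len(n_taxa), function(i) {
    evolve_codon_sequence(root, t_tip, p)
  }, character(n_codons)))
  rownames(rows) <- paste0("t", seq_len(n_taxa))
  rows
}

star_tree <- function(labels, bl = 0.15) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%g", labels, bl), collapse = ","), ");"))
}

test_that("pruning equals brute-force ancestral-state summation", {
  sm <- site_model("M0", kappa = 2, omega = 0.4)
  Q <- gy94_rate_matrix(codon_params(2, 0.4))

  # 3 taxa x 2 codons on a star tree
  aln3 <- sim_family(61, n_codons = 2, n_taxa = 3)
  tr3 <- star_tree(rownames(aln3), c(0.1, 0.25, 0.4))
  tr3$edge.length <- c(0.1, 0.25, 0.4)
  ours <- site_loglik(aln3, tr3, sm)
  states <- matrix(match(aln3, sense_codons()), nrow = 3,
                   dimnames = dimnames(aln3))
  oracle <- oracle_star_loglik(states[tr3$tip.label, , drop = FALSE],
                               tr3$edge.length, Q, sm$pi)
  expect_equal(ours$lnL, oracle, tolerance = 1e-8)

  # 4 taxa x 3 codons with an internal edge
  aln4 <- sim_family(62, n_codons = 3, n_taxa = 4)
  tr4 <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.15,t3:0.3,t4:0.05);")
  ours4 <- site_loglik(aln4, tr4, sm)
  states4 <- matrix(match(aln4, sense_codons()), nrow = 4,
                    dimnames = dimnames(aln4))
  oracle4 <- oracle_twoclade_loglik(
    states4[c("t1", "t2", "t3", "t4"), , drop = FALSE],
    c(0.1, 0.2, 0.3, 0.05), 0.15, Q, sm$pi)
  expect_equal(ours4$lnL, oracle4, tolerance = 1e-8)
})

test_that("zero branch lengths with identical sequences give sum log pi", {
  aln <- rbind(t1 = c("ATG", "AAA"), t2 = c("ATG", "AAA"),
               t3 = c("ATG", "AAA"))
  tr <- star_tree(rownames(aln), 0)
  sm <- site_model("M0", kappa = 2, omega = 0.3)
  ll <- site_loglik(aln, tr, sm)
  idx <- match(c("ATG", "AAA"), sense_codons())
  expect_equal(ll$lnL, sum(log(sm$pi[idx])), tolerance = 1e-9)
})

test_that("M8 with p1 = 0 reduces to M7 at the same beta shape", {
  aln <- sim_family(63)
  tr <- star_tree(rownames(aln))
  m7 <- site_model("M7", kappa = 2, p = 0.8, q = 2.1)
  m8 <- site_model("M8", kappa = 2, p = 0.8, q = 2.1, p0 = 1, omega_s = 3)
  l7 <- site_loglik(aln, tr, m7)
  l8 <- site_loglik(aln, tr, m8)
  expect_equal(l7$lnL, l8$lnL, tolerance = 1e-9)
})

test_that("beta discretization uses K equal-weight category medians", {
  sm <- site_model("M7", p = 2, q = 3, K = 10)
  expect_length(sm$omegas, 10)
  expect_equal(sm$weights, rep(0.1, 10))
  expect_equal(sm$omegas, stats::qbeta((1:10 - 0.5) / 10, 2, 3))
  sm8 <- site_model("M8", p = 2, q = 3, p0 = 0.8, omega_s = 2.5, K = 10)
  expect_length(sm8$omegas, 11)
  expect_equal(sum(sm8$weights), 1)
  expect_equal(sm8$weights[11], 0.2)
  expect_equal(sm8$omegas[11], 2.5)
})

test_that("chi-square critical values and validation", {
  expect_equal(chi2_critical(0.05, 2), 5.991, tolerance = 5e-4)
  expect_equal(chi2_critical(0.01, 2), 9.210, tolerance = 5e-4)
  expect_equal(chi2_critical(0.05, 2), -2 * log(0.05), tolerance = 1e-10)
  expect_error(chi2_critical(1.0, 2), "alpha")
  expect_error(chi2_critical(0, 2), "alpha")
})

test_that("LRT statistic and stars follow the thresholds", {
  mk <- function(model, lnl) {
    structure(list(model = model, lnL = lnl, fingerprint = "x"),
              class = "site_model_fit")
  }
  r1 <- lrt_m7_m8(mk("M7", -1000), mk("M8", -996))
  expect_equal(r1$two_delta_lnl, 8)
  expect_identical(r1$significance, "*")
  r2 <- lrt_m7_m8(mk("M7", -500), mk("M8", -495))
  expect_equal(r2$two_delta_lnl, 10)
  expect_identical(r2$significance, "**")
  r3 <- lrt_m7_m8(mk("M7", -500), mk("M8", -500))
  expect_equal(r3$two_delta_lnl, 0)
  expect_identical(r3$significance, "ns")
  # tiny negative values are optimizer noise, clamped
  r4 <- lrt_m7_m8(mk("M7", -500), mk("M8", -500.00004))
  expect_equal(r4$two_delta_lnl, 0)
  b <- mk("M8", -499); b$fingerprint <- "y"
  expect_error(lrt_m7_m8(mk("M7", -500), b), "different data")
})

test_that("fits recover omega and respect model nesting", {
  aln <- sim_family(64, omega = 0.25, n_codons = 120)
  tr <- star_tree(rownames(aln))
  m0 <- fit_site_model(aln, tr, "M0", seed = 1)
  expect_gt(m0$params$omega, 0.1)
  expect_lt(m0$params$omega, 0.5)
  m7 <- fit_site_model(aln, tr, "M7", seed = 1, m0_fit = m0, restarts = 1)
  m8 <- fit_site_model(aln, tr, "M8", seed = 1, m0_fit = m0, m7_fit = m7,
                       restarts = 1)
  expect_gte(m8$lnL, m7$lnL - 1e-4)
  lrt <- lrt_m7_m8(m7, m8)
  expect_gte(lrt$two_delta_lnl, 0)

  sites <- positive_sites(m8)
  expect_true(all(sites$p_positive >= 0 & sites$p_positive <= 1))
  expect_equal(nrow(sites), 120)
})

test_that("per-site class posteriors are normalized and degenerate cases flag", {
  aln <- sim_family(65, omega = 0.2, n_codons = 50)
  tr <- star_tree(rownames(aln))
  sm8 <- site_model("M8", kappa = 2, p = 1, q = 3, p0 = 0.85, omega_s = 2)
  ll <- site_loglik(aln, tr, sm8)
  lp <- sweep(ll$class_loglik, 2, log(sm8$weights), "+")
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx) / rowSums(exp(lp - mx))
  expect_lt(max(abs(rowSums(post) - 1)), 1e-9)

  # an alignment of identical sequences is flagged as unidentifiable
  aln_id <- matrix(rep(c("ATG", "AAA", "CTT"), each = 3), nrow = 3,
                   dimnames = list(paste0("t", 1:3), NULL))
  fit <- fit_site_model(aln_id, star_tree(paste0("t", 1:3)), "M0", seed = 1)
  expect_true("no_variable_sites" %in% fit$flags)
})

test_that("p1 = 0 gives zero positive-site posteriors", {
  aln <- sim_family(66, n_codons = 30)
  tr <- star_tree(rownames(aln))
  sm <- site_model("M8", kappa = 2, p = 1, q = 2, p0 = 1, omega_s = 2)
  ll <- site_loglik(aln, tr, sm)
  fake_fit <- structure(list(model = "M8", sm = sm,
                             class_loglik = ll$class_loglik,
                             patterns = ll$patterns),
                        class = "site_model_fit")
  sites <- positive_sites(fake_fit)
  expect_true(all(sites$p_positive == 0))
})
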