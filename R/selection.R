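# Codon site models of positive selection: GY94 likelihood computed by
# Felsenstein pruning over the 61 sense codons, site-class mixtures M7
# (beta-distributed omega on (0,1), K equal-probability categories at their
# quantile medians) and M8 (beta plus one class with omega >= 1), the
# M7-vs-M8 likelihood-ratio test, and empirical-Bayes identification of
# sites in the positive-selection class.
#
# Site posteriors are computed at the maximum-likelihood estimates (naive
# empirical Bayes); integration over parameter uncertainty (full BEB) is not
# performed, and outputs are labelled accordingly.

#' Site-class structure of a codon model
#'
#' @param model `"M0"`, `"M7"` or `"M8"`.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (61 values or `"equal"`).
#' @param omega M0's single dN/dS ratio.
#' @param p,q Beta shape parameters (M7/M8), both > 0.
#' @param p0 M8: weight of the beta component (in `[0, 1]`).
#' @param omega_s M8: dN/dS of the extra class (>= 1).
#' @param K Number of beta discretization categories (default 10).
#' @return List of class `codon_site_model` with `omegas`, `weights`,
#'   `kappa`, `pi` and the model id.
#' @export
site_model <- function(model = c("M0", "M7", "M8"), kappa = 2,
                       pi = "equal", omega = 0.3, p = 1, q = 1,
                       p0 = 0.9, omega_s = 2, K = 10) {
  model <- match.arg(model)
  if (identical(pi, "equal")) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61L, abs(sum(pi) - 1) < 1e-8, kappa > 0)
  if (model == "M0") {
    stopifnot(omega >= 0)
    omegas <- omega; weights <- 1
    pars <- list(omega = omega)
  } else {
    stopifnot(p > 0, q > 0)
    # extreme shapes make qbeta warn about quantile accuracy; category
    # medians are still the right discretization points
    omegas <- suppressWarnings(stats::qbeta((seq_len(K) - 0.5) / K, p, q))
    weights <- rep(1 / K, K)
    pars <- list(p = p, q = q)
    if (model == "M8") {
      stopifnot(p0 >= 0, p0 <= 1, omega_s >= 1)
      omegas <- c(omegas, omega_s)
      weights <- c(p0 * weights, 1 - p0)
      pars <- c(pars, list(p0 = p0, omega_s = omega_s))
    }
  }
  structure(list(model = model, kappa = kappa, pi = as.numeric(pi),
                 omegas = omegas, weights = weights, params = pars, K = K),
            class = "codon_site_model")
}

# Per-class eigendecompositions with the mixture normalized so the expected
# substitution rate (weighted over classes) is 1.
.class_decomps <- function(sm) {
  Qs <- lapply(sm$omegas, function(w) {
    gy94_rate_matrix(codon_params(sm$kappa, w, sm$pi), normalize = FALSE)
  })
  rates <- vapply(Qs, attr, numeric(1), "rate")
  scale <- sum(sm$weights * rates)
  if (scale <= 0) stop("degenerate model: zero mean substitution rate")
  lapply(Qs, function(Q) rev_eigen(Q / scale, sm$pi))
}

# Compress a gap-free codon index matrix into unique site patterns.
# codon_aln: character matrix of codons; columns containing any gap are
# dropped before analysis.
codon_patterns <- function(codon_aln) {
  stopifnot(is.matrix(codon_aln), !is.null(rownames(codon_aln)))
  gapped <- apply(codon_aln == "---", 2, any)
  aln <- codon_aln[, !gapped, drop = FALSE]
  if (ncol(aln) == 0L) stop("no gap-free codon columns to analyze")
  idx <- matrix(codon_index(aln), nrow = nrow(aln),
                dimnames = list(rownames(aln), NULL))
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  map <- match(key, uk)
  pat <- idx[, match(uk, key), drop = FALSE]
  list(patterns = pat, map = map, weights = tabulate(map, length(uk)),
       n_sites = ncol(aln), n_dropped = sum(gapped))
}

# Per-class per-pattern log-likelihoods by pruning with per-pattern scaling.
# tree must be an ape phylo with edge.length set; its tip labels must match
# the pattern matrix row names.
.class_site_logliks <- function(pat, tree, decomps, pi) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  tip_idx <- pat$patterns[tree$tip.label, , drop = FALSE]
  npat <- ncol(tip_idx)
  n_node <- n_tip + tree$Nnode
  root <- tree$edge[nrow(tree$edge), 1]
  out <- matrix(NA_real_, npat, length(decomps))
  for (k in seq_along(decomps)) {
    Ps <- lapply(tree$edge.length, function(t) prob_matrix(decomps[[k]], t))
    partial <- vector("list", n_node)
    logscale <- numeric(npat)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      term <- if (child <= n_tip) {
        Ps[[e]][, tip_idx[child, ], drop = FALSE]
      } else {
        Ps[[e]] %*% partial[[child]]
      }
      if (is.null(partial[[parent]])) {
        partial[[parent]] <- term
      } else {
        partial[[parent]] <- partial[[parent]] * term
      }
      if (child > n_tip) {
        # rescale the freshly combined child contribution lazily at parent
        m <- apply(partial[[parent]], 2, max)
        low <- m < 1e-80
        if (any(m <= 0)) stop("numerical underflow in pruning")
        partial[[parent]] <- sweep(partial[[parent]], 2, m, "/")
        logscale <- logscale + log(m)
      }
    }
    site_l <- colSums(pi * partial[[root]])
    out[, k] <- log(site_l) + logscale
  }
  out
}

#' Log-likelihood of a codon alignment under a site model
#'
#' Felsenstein pruning over the 61 sense codons; for mixture models the
#' per-site likelihood averages the class likelihoods with the class
#' weights. Columns containing gaps are dropped.
#'
#' @param codon_aln Codon alignment matrix (as from
#'   [backtranslate_alignment()]).
#' @param tree `ape::phylo` with branch lengths; tips = alignment rows.
#' @param sm A [site_model()].
#' @return List with `lnL`, `site_lnl` (per analyzed site, alignment
#'   order), `class_loglik` (pattern x class matrix), `patterns`.
#' @export
site_loglik <- function(codon_aln, tree, sm) {
  stopifnot(setequal(tree$tip.label, rownames(codon_aln)))
  pat <- codon_patterns(codon_aln)
  decomps <- .class_decomps(sm)
  cls <- .class_site_logliks(pat, tree, decomps, sm$pi)
  site_pat <- .logsumexp_rows(sweep(cls, 2, log(sm$weights), "+"))
  lnL <- sum(site_pat * pat$weights)
  list(lnL = lnL, site_lnl = site_pat[pat$map], class_loglik = cls,
       patterns = pat)
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  keep <- is.finite(mx)
  out <- rep(-Inf, nrow(m))
  out[keep] <- mx[keep] +
    log(rowSums(exp(m[keep, , drop = FALSE] - mx[keep])))
  out
}

#' Fit a codon site model by maximum likelihood
#'
#' M0 jointly estimates kappa, omega and the branch lengths (Nelder-Mead on
#' log-transformed parameters, seeded random restarts). M7 and M8 hold the
#' branch lengths and kappa fixed at the M0 estimates and maximize their
#' site-class parameters.
#'
#' @param codon_aln Codon alignment matrix.
#' @param tree `ape::phylo` with starting branch lengths (tips = rows of the
#'   alignment; e.g. a neighbor-joining tree).
#' @param model `"M0"`, `"M7"` or `"M8"`.
#' @param pi `"f3x4"` (default; position-specific frequencies estimated from
#'   the alignment), `"equal"`, or a 61-vector.
#' @param K Beta discretization categories (default 10).
#' @param restarts Random restarts for the site-class optimization
#'   (default 3).
#' @param seed Seed making the restarts reproducible.
#' @param m0_fit A previous M0 fit (required for M7/M8; computed on the fly
#'   when omitted).
#' @param m7_fit For M8 only: a previous M7 fit on the same data. Its MLEs
#'   seed one M8 start (at the p0 -> 1 boundary), which both speeds the
#'   search and enforces the nesting lnL(M8) >= lnL(M7).
#' @return List of class `site_model_fit`: `model`, `params`, `kappa`,
#'   `lnL`, `site_lnl`, `tree` (fitted branch lengths), `sm` (the fitted
#'   [site_model()]), `class_loglik`, `patterns`, `fingerprint`,
#'   `convergence`, `flags`.
#' @export
fit_site_model <- function(codon_aln, tree, model = c("M0", "M7", "M8"),
                           pi = "f3x4", K = 10, restarts = 3, seed = 1,
                           m0_fit = NULL, m7_fit = NULL) {
  model <- match.arg(model)
  stopifnot(nrow(codon_aln) >= 3L)
  if (identical(pi, "f3x4")) {
    pi <- f3x4_frequencies(codon_aln)
  } else if (identical(pi, "equal")) {
    pi <- rep(1 / 61, 61)
  }
  pat <- codon_patterns(codon_aln)
  fingerprint <- paste(nrow(codon_aln), pat$n_sites,
                       sum(pat$patterns * seq_len(length(pat$patterns))),
                       sep = ":")
  flags <- character(0)
  if (ncol(pat$patterns) == 1L ||
      all(apply(pat$patterns, 2, function(col) length(unique(col)) == 1L))) {
    flags <- c(flags, "no_variable_sites")
  }

  if (model == "M0") {
    fit <- .fit_m0(codon_aln, tree, pi, pat, seed)
  } else {
    if (is.null(m0_fit)) {
      m0_fit <- fit_site_model(codon_aln, tree, "M0", pi = pi, seed = seed)
    }
    fit <- .fit_beta_model(codon_aln, m0_fit, model, pi, K, restarts, seed,
                           m7_fit)
  }
  fit$fingerprint <- fingerprint
  fit$flags <- c(flags, fit$flags)
  class(fit) <- "site_model_fit"
  fit
}

.neg_loglik_factory <- function(pat, pi) {
  function(tree, sm) {
    cls <- .class_site_logliks(pat, tree, .class_decomps(sm), sm$pi)
    site_pat <- .logsumexp_rows(sweep(cls, 2, log(sm$weights), "+"))
    -sum(site_pat * pat$weights)
  }
}

# M0: one Nelder-Mead search over (log kappa, log omega, log branch
# lengths) from a neutral-ish start; this is the branch-length estimation
# step, held fixed by the site-class models.
.fit_m0 <- function(codon_aln, tree, pi, pat, seed) {
  tree <- ape::unroot(tree)
  bl0 <- pmax(tree$edge.length, 1e-4)
  nb <- length(bl0)
  nll <- .neg_loglik_factory(pat, pi)
  obj <- function(theta) {
    kappa <- exp(theta[1]); omega <- exp(theta[2])
    if (kappa > 100 || omega > 50) return(1e10)
    tr <- tree
    tr$edge.length <- exp(theta[2 + seq_len(nb)])
    if (any(tr$edge.length > 50)) return(1e10)
    nll(tr, site_model("M0", kappa = kappa, pi = pi, omega = omega))
  }
  set.seed(seed)
  best <- stats::optim(c(log(2), log(0.4), log(bl0)), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-9))
  theta <- best$par
  tr <- tree
  tr$edge.length <- exp(theta[2 + seq_len(nb)])
  sm <- site_model("M0", kappa = exp(theta[1]), pi = pi,
                   omega = exp(theta[2]))
  ll <- site_loglik(codon_aln, tr, sm)
  list(model = "M0",
       params = list(omega = exp(theta[2])), kappa = exp(theta[1]),
       lnL = ll$lnL, site_lnl = ll$site_lnl, tree = tr, sm = sm,
       class_loglik = ll$class_loglik, patterns = ll$patterns,
       convergence = best$convergence,
       flags = if (best$convergence != 0) "optim_not_converged" else character(0))
}

.fit_beta_model <- function(codon_aln, m0_fit, model, pi, K, restarts, seed,
                            m7_fit = NULL) {
  tree <- m0_fit$tree
  kappa <- m0_fit$kappa
  pat <- m0_fit$patterns
  nll <- .neg_loglik_factory(pat, pi)
  make_sm <- function(theta) {
    p <- exp(theta[1]); q <- exp(theta[2])
    if (model == "M7") {
      site_model("M7", kappa = kappa, pi = pi, p = p, q = q, K = K)
    } else {
      p0 <- stats::plogis(theta[3]); omega_s <- 1 + exp(theta[4])
      site_model("M8", kappa = kappa, pi = pi, p = p, q = q, p0 = p0,
                 omega_s = omega_s, K = K)
    }
  }
  obj <- function(theta) {
    if (any(abs(theta[1:2]) > log(50))) return(1e10)
    if (model == "M8" && theta[4] > log(49)) return(1e10)
    nll(tree, make_sm(theta))
  }
  set.seed(seed + 17L)
  starts <- if (model == "M7") {
    list(c(log(0.5), log(1.5)))
  } else {
    list(c(log(0.5), log(1.5), stats::qlogis(0.9), log(1)))
  }
  if (model == "M8" && !is.null(m7_fit)) {
    stopifnot(m7_fit$model == "M7")
    # the M7 solution at the p0 -> 1 boundary (beta-only) and a variant
    # with a modest positive class
    starts <- c(list(
      c(log(m7_fit$params$p), log(m7_fit$params$q), stats::qlogis(1 - 1e-8),
        log(1e-6)),
      c(log(m7_fit$params$p), log(m7_fit$params$q), stats::qlogis(0.9),
        log(1))), starts)
  }
  for (r in seq_len(max(0, restarts - 1))) {
    base <- c(log(stats::runif(1, 0.2, 2)), log(stats::runif(1, 0.2, 3)))
    starts[[length(starts) + 1]] <-
      if (model == "M7") base
      else c(base, stats::qlogis(stats::runif(1, 0.5, 0.99)),
             log(stats::runif(1, 0.2, 3)))
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-9))
    if (is.null(best) || o$value < best$value) best <- o
  }
  sm <- make_sm(best$par)
  ll <- site_loglik(codon_aln, tree, sm)
  list(model = model, params = sm$params, kappa = kappa,
       lnL = ll$lnL, site_lnl = ll$site_lnl, tree = tree, sm = sm,
       class_loglik = ll$class_loglik, patterns = ll$patterns,
       convergence = best$convergence,
       flags = if (best$convergence != 0) "optim_not_converged" else character(0))
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f\n", x$model, x$lnL))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params),
                                 unlist(x$params)), collapse = " "),
      sprintf(" kappa=%.3g\n", x$kappa))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square critical value
#'
#' Upper-tail quantile of the chi-square distribution; for `df = 2` this is
#' `-2 ln(alpha)` (5.991 at alpha 0.05, 9.210 at 0.01).
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df Degrees of freedom (default 2).
#' @return The critical value.
#' @export
chi2_critical <- function(alpha, df = 2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be strictly inside (0, 1)")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test between M7 and M8
#'
#' `2 * (lnL_M8 - lnL_M7)` compared to chi-square critical values with 2
#' degrees of freedom: `"*"` beyond the 5% critical value (5.991), `"**"`
#' beyond the 1% one (9.210), `"ns"` otherwise.
#'
#' @param fit7,fit8 Fits from [fit_site_model()] on the same alignment and
#'   tree.
#' @param tol Negative statistics within `tol` of zero (optimizer noise) are
#'   clamped to 0.
#' @return List of class `lrt_result`: `two_delta_lnl`, `df`,
#'   `significance`.
#' @export
lrt_m7_m8 <- function(fit7, fit8, tol = 1e-4) {
  stopifnot(fit7$model == "M7", fit8$model == "M8")
  if (!identical(fit7$fingerprint, fit8$fingerprint)) {
    stop("fits were computed on different data")
  }
  stat <- 2 * (fit8$lnL - fit7$lnL)
  if (stat < 0 && stat > -tol) stat <- 0
  if (stat < 0) {
    warning("M8 log-likelihood below M7 beyond tolerance (", stat,
            "); clamping to 0")
    stat <- 0
  }
  sig <- if (stat > chi2_critical(0.01, 2)) "**"
         else if (stat > chi2_critical(0.05, 2)) "*"
         else "ns"
  structure(list(two_delta_lnl = stat, df = 2L, significance = sig),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT (df = %d): 2*delta lnL = %.4f [%s]\n", x$df,
              x$two_delta_lnl, x$significance))
  invisible(x)
}

#' Empirical-Bayes detection of positively selected sites
#'
#' For each analyzed site, the posterior probability of the M8
#' positive-selection class at the maximum-likelihood estimates:
#' `P(class k | site) = w_k L_k(site) / sum_j w_j L_j(site)`, with
#' `P(omega > 1)` the mass of the omega_s class. Sites are starred at
#' posterior >= 0.95 (`*`) and >= 0.99 (`**`).
#'
#' @param fit8 An M8 fit from [fit_site_model()].
#' @return Data frame with one row per analyzed site: `site`,
#'   `p_positive`, `flag`.
#' @export
positive_sites <- function(fit8) {
  stopifnot(fit8$model == "M8")
  cls <- fit8$class_loglik
  logw <- log(fit8$sm$weights)
  lp <- sweep(cls, 2, logw, "+")
  denom <- .logsumexp_rows(lp)
  post <- exp(lp - denom)   # patterns x classes, rows sum to 1
  p1 <- fit8$sm$weights[ncol(post)]
  p_pos <- if (p1 == 0) rep(0, nrow(post)) else post[, ncol(post)]
  per_site <- p_pos[fit8$patterns$map]
  flag <- ifelse(per_site >= 0.99, "**",
                 ifelse(per_site >= 0.95, "*", ""))
  out <- data.frame(site = seq_along(per_site), p_positive = per_site,
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "posterior_method") <-
    "NEB (posteriors at the MLEs; no integration over parameter uncertainty)"
  out
}
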