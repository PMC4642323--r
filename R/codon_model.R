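# Core machinery for codon substitution models (GY94 family).
#
# Codons are indexed 1..61 over the sense codons of the standard genetic code
# (alphabetical order, stops TAA/TAG/TGA excluded). All rate matrices are
# reversible with respect to the supplied codon frequencies pi.

NUC <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (alphabetical order).
#' @export
sense_codons <- function() {
  if (is.null(.codon_env$codons)) .init_codon_tables()
  .codon_env$codons
}

#' Amino acid translation of the sense codons
#'
#' @return Named character vector mapping each sense codon to its one-letter
#'   amino acid.
#' @export
codon_amino_acids <- function() {
  if (is.null(.codon_env$aa)) .init_codon_tables()
  .codon_env$aa
}

.init_codon_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc)[gc != "*"])
  stopifnot(length(codons) == 61L)
  aa <- gc[codons]
  .codon_env$codons <- codons
  .codon_env$aa <- aa
  .codon_env$index <- stats::setNames(seq_along(codons), codons)

  # Single-nucleotide neighbour table: for each ordered sense-codon pair (i,j)
  # differing at one position, record position, whether the change is a
  # transition (A<->G, C<->T) and whether it is synonymous.
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  from <- integer(0); to <- integer(0); ts <- logical(0); syn <- logical(0)
  split_codons <- strsplit(codons, "")
  for (i in seq_along(codons)) {
    ci <- split_codons[[i]]
    for (pos in 1:3) {
      for (b in NUC[NUC != ci[pos]]) {
        cj <- ci; cj[pos] <- b
        codon_j <- paste(cj, collapse = "")
        j <- unname(.codon_env$index[codon_j])
        if (is.na(j)) next  # change to a stop codon
        from <- c(from, i); to <- c(to, j)
        ts <- c(ts, is_transition(ci[pos], b))
        syn <- c(syn, aa[[i]] == aa[[j]])
      }
    }
  }
  .codon_env$neighbors <- data.frame(from = from, to = to,
                                     transition = ts, synonymous = syn)

  # Nei-Gojobori synonymous-site fraction per codon: at each position, the
  # fraction of the possible (non-stop) single-nucleotide changes that are
  # synonymous, summed over the three positions.
  s_sites <- numeric(61)
  for (i in seq_along(codons)) {
    ci <- split_codons[[i]]
    s <- 0
    for (pos in 1:3) {
      n_valid <- 0L; n_syn <- 0L
      for (b in NUC[NUC != ci[pos]]) {
        cj <- ci; cj[pos] <- b
        codon_j <- paste(cj, collapse = "")
        if (codon_j %in% STOP_CODONS) next
        n_valid <- n_valid + 1L
        if (gc[[codon_j]] == aa[[i]]) n_syn <- n_syn + 1L
      }
      s <- s + n_syn / n_valid
    }
    s_sites[i] <- s
  }
  .codon_env$ng_s_sites <- s_sites
  invisible(NULL)
}

codon_index <- function(codons) {
  if (is.null(.codon_env$index)) .init_codon_tables()
  idx <- .codon_env$index[codons]
  if (anyNA(idx)) {
    bad <- codons[is.na(idx)]
    stop("invalid codon(s): ", paste(unique(bad), collapse = ", "),
         " (stop codons and non-ACGT codons are not allowed)")
  }
  unname(idx)
}

#' Nei-Gojobori synonymous-site counts per codon
#'
#' For each sense codon, the number of synonymous sites: at each of the three
#' positions, the fraction of possible single-nucleotide changes (changes to
#' stop codons excluded from the possible-change count) that preserve the
#' amino acid, summed over positions. Nonsynonymous sites are `3 - S`.
#'
#' @return Numeric vector of length 61, named by codon.
#' @export
ng_synonymous_sites <- function() {
  if (is.null(.codon_env$ng_s_sites)) .init_codon_tables()
  stats::setNames(.codon_env$ng_s_sites, sense_codons())
}

#' Codon model parameter set
#'
#' Bundles the parameters of a GY94-style codon substitution model: the
#' transition/transversion rate ratio kappa, the nonsynonymous/synonymous
#' rate ratio omega, and the equilibrium codon frequencies.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS rate ratio (>= 0).
#' @param pi Codon frequencies over the 61 sense codons (summing to 1), or
#'   `"equal"` for uniform frequencies.
#' @return A list of class `codon_params`.
#' @export
codon_params <- function(kappa = 2, omega = 0.3, pi = "equal") {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(omega), length(omega) == 1L, omega >= 0)
  if (identical(pi, "equal")) {
    pi <- rep(1 / 61, 61)
  }
  stopifnot(is.numeric(pi), length(pi) == 61L, all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("codon frequencies must sum to 1")
  structure(list(kappa = kappa, omega = omega, pi = as.numeric(pi)),
            class = "codon_params")
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61x61 rate matrix with `q_ij = pi_j * kappa^[transition] *
#' omega^[nonsynonymous]` for single-nucleotide changes and 0 otherwise.
#'
#' @param params A [codon_params()] object.
#' @param normalize If `TRUE` (default), scale so the expected substitution
#'   rate at stationarity is 1 per codon site per unit branch length.
#' @return The rate matrix, with attributes `pi` (frequencies) and `rate`
#'   (the pre-normalization mean rate, useful for mixture-model scaling).
#' @export
gy94_rate_matrix <- function(params, normalize = TRUE) {
  nb <- .codon_env$neighbors
  if (is.null(nb)) { .init_codon_tables(); nb <- .codon_env$neighbors }
  Q <- matrix(0, 61, 61, dimnames = list(sense_codons(), sense_codons()))
  q <- params$pi[nb$to] *
    ifelse(nb$transition, params$kappa, 1) *
    ifelse(nb$synonymous, 1, params$omega)
  Q[cbind(nb$from, nb$to)] <- q
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(params$pi * diag(Q))
  if (normalize) {
    if (mean_rate <= 0) stop("degenerate rate matrix (zero mean rate)")
    Q <- Q / mean_rate
  }
  attr(Q, "pi") <- params$pi
  attr(Q, "rate") <- mean_rate
  Q
}

# Symmetrized eigendecomposition of a pi-reversible rate matrix. Returns a
# closure-friendly list from which P(t) = exp(Qt) is assembled cheaply.
rev_eigen <- function(Q, pi = attr(Q, "pi")) {
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))          # diag(sp) Q diag(1/sp), symmetric
  S <- (S + t(S)) / 2                  # clean round-off asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sp = sp)
}

# Transition probability matrix P(t) from a rev_eigen() decomposition.
prob_matrix <- function(decomp, t) {
  if (t < 0) stop("branch length must be >= 0")
  E <- decomp$U %*% (exp(decomp$lambda * t) * t(decomp$U))
  P <- (1 / decomp$sp) * E * rep(decomp$sp, each = length(decomp$sp))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Expected fraction of substitutions that are synonymous
#'
#' Under the model's stationary distribution, the proportion of the total
#' substitution rate carried by synonymous changes. Used to calibrate branch
#' lengths to a target Ks in the simulator.
#'
#' @param params A [codon_params()] object.
#' @return A single number in (0, 1].
#' @export
synonymous_rate_fraction <- function(params) {
  Q <- gy94_rate_matrix(params, normalize = TRUE)
  nb <- .codon_env$neighbors
  syn_rate <- sum(params$pi[nb$from[nb$synonymous]] *
                    Q[cbind(nb$from[nb$synonymous], nb$to[nb$synonymous])])
  syn_rate  # Q is normalized: total rate is 1, so this is already a fraction
}

#' Pairwise divergence time for a target Ks
#'
#' Converts a target synonymous divergence (substitutions per synonymous
#' site) into total branch length separating a pair of sequences, using the
#' model's synonymous rate fraction and the expected Nei-Gojobori synonymous
#' site count at stationarity.
#'
#' @param target_ks Desired pairwise Ks.
#' @param params A [codon_params()] object.
#' @return Total pairwise divergence in expected substitutions per codon site.
#' @export
divergence_for_ks <- function(target_ks, params) {
  stopifnot(target_ks >= 0)
  s_bar <- sum(params$pi * ng_synonymous_sites()) / 3  # per nucleotide site
  rho_s <- synonymous_rate_fraction(params)
  # Ks ~= (t * rho_s) / (3 * s_bar) per synonymous site, with t in expected
  # substitutions per codon site; invert for t.
  target_ks * 3 * s_bar / rho_s
}

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies estimated from codon sequences,
#' multiplied across the three codon positions, with stop codons removed and
#' the remainder renormalized over the 61 sense codons.
#'
#' @param codon_rows Character matrix (or vector) of codons.
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(codon_rows) {
  codons <- as.vector(codon_rows)
  codons <- codons[!is.na(codons) & codons != "---"]
  if (!length(codons)) stop("no codons supplied")
  m <- do.call(rbind, strsplit(codons, ""))
  freqs <- lapply(1:3, function(p) {
    f <- table(factor(m[, p], levels = NUC))
    f <- as.numeric(f)
    if (sum(f) == 0) stop("no valid nucleotides at codon position ", p)
    # add a small pseudocount so no sense codon gets probability zero
    f <- f + 0.5
    f / sum(f)
  })
  sc <- strsplit(sense_codons(), "")
  pi <- vapply(sc, function(c3) {
    freqs[[1]][match(c3[1], NUC)] * freqs[[2]][match(c3[2], NUC)] *
      freqs[[3]][match(c3[3], NUC)]
  }, numeric(1))
  pi / sum(pi)
}

# Split an in-frame CDS string into codons; validates alphabet and frame.
split_codons <- function(cds) {
  cds <- toupper(gsub("U", "T", cds))
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3 (got ", n, ")")
  }
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Translate an in-frame CDS
#'
#' @param cds A nucleotide string whose length is a multiple of 3, containing
#'   no internal stop codons (a single trailing stop is tolerated and removed).
#' @return The amino-acid string.
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(cds)
  if (codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% STOP_CODONS)) {
    stop("internal stop codon at codon position ",
         which(codons %in% STOP_CODONS)[1])
  }
  paste(codon_amino_acids()[codons], collapse = "")
}
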