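# Independent brute-force oracles used to validate the package's
# implementations on small random instances. These deliberately take the
# most naive route (explicit loops, full enumeration) and share as little
# code as possible with the package.

GC_TABLE <- Biostrings::GENETIC_CODE

# --- Nei-Gojobori oracle ----------------------------------------------

# synonymous-site count of one codon: loop over the 9 single-base changes,
# skip changes to stops, fraction synonymous per position
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[pos]) next
      alt <- chars; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (GC_TABLE[[alt]] == "*") next
      valid <- valid + 1
      if (GC_TABLE[[alt]] == GC_TABLE[[codon]]) syn <- syn + 1
    }
    total <- total + if (valid > 0) syn / valid else 0
  }
  total
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# average syn/nonsyn differences between two codons over stop-free
# mutational pathways
oracle_codon_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(0, 0))
  res <- NULL
  for (order in oracle_permutations(pos)) {
    cur <- a; s <- 0; n <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- GC_TABLE[[paste(cur, collapse = "")]]
      aa2 <- GC_TABLE[[paste(nxt, collapse = "")]]
      if (aa2 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) res <- rbind(res, c(s, n))
  }
  stopifnot(!is.null(res))
  colMeans(res)
}

oracle_nei_gojobori <- function(codons_a, codons_b) {
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    S <- S + (oracle_syn_sites(codons_a[i]) + oracle_syn_sites(codons_b[i])) / 2
    d <- oracle_codon_diffs(codons_a[i], codons_b[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * length(codons_a) - S
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# random sense-codon sequence (uniform over the 61 codons)
random_sense_codons <- function(n) {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  sample(sense, n, replace = TRUE)
}

# --- pruning-likelihood oracle ----------------------------------------

# transition matrix by a series-expansion matrix exponential (independent
# of the package's eigendecomposition route)
oracle_pmatrix <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# total log-likelihood by explicit summation over all ancestral codon
# assignments, for a star tree with one internal node (3+ tips hanging off
# the root) or the 4-taxon tree ((A,B),C,D) with two internal nodes.
oracle_star_loglik <- function(tip_states, branch_lengths, Q, pi) {
  Ps <- lapply(branch_lengths, function(t) oracle_pmatrix(Q, t))
  n_sites <- ncol(tip_states)
  total <- 0
  for (s in seq_len(n_sites)) {
    like <- 0
    for (a in 1:61) {
      term <- pi[a]
      for (k in seq_along(Ps)) term <- term * Ps[[k]][a, tip_states[k, s]]
      like <- like + term
    }
    total <- total + log(like)
  }
  total
}

oracle_twoclade_loglik <- function(tip_states, bl_tips, bl_internal, Q, pi) {
  # tree (((1,2)m,3,4)root); bl_tips = lengths of tips 1..4, bl_internal =
  # root-to-m length
  Ps <- lapply(bl_tips, function(t) oracle_pmatrix(Q, t))
  Pm <- oracle_pmatrix(Q, bl_internal)
  total <- 0
  for (s in seq_len(ncol(tip_states))) {
    like <- 0
    for (a in 1:61) {
      inner <- 0
      for (b in 1:61) {
        inner <- inner + Pm[a, b] * Ps[[1]][b, tip_states[1, s]] *
          Ps[[2]][b, tip_states[2, s]]
      }
      like <- like + pi[a] * inner * Ps[[3]][a, tip_states[3, s]] *
        Ps[[4]][a, tip_states[4, s]]
    }
    total <- total + log(like)
  }
  total
}

# --- motif-scan oracle -------------------------------------------------

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T", "N"))

oracle_scan_one_strand <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(s) < length(p)) return(hits)
  for (start in 1:(length(s) - length(p) + 1)) {
    ok <- TRUE
    for (k in seq_along(p)) {
      if (!(s[start + k - 1] %in% ORACLE_IUPAC[[p[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# --- transitive-closure oracle for single-linkage families -------------

oracle_components <- function(ids, edges) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  rownames(adj) <- colnames(adj) <- ids
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[edges$gene_a[r], edges$gene_b[r]] <- TRUE
      adj[edges$gene_b[r], edges$gene_a[r]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[adj[i, ]] <- cid
    }
  }
  stats::setNames(comp, ids)
}

# --- misc helpers -------------------------------------------------------

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_distance_matrix <- function(n) {
  labs <- paste0("t", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  D + t(D)
}
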