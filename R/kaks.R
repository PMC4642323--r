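# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor multiple-hit correction, on
# codon alignments back-translated from protein alignments. Gapped columns
# are removed pairwise (pairwise deletion); mutations and mutational
# pathways through stop codons are excluded from both site and difference
# counting.

.ng_env <- new.env(parent = emptyenv())

# All orderings of 1..k, k <= 3 (minimal mutational pathways).
.perms <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Average synonymous / nonsynonymous difference counts between two sense
# codons: pathways (orderings of the differing positions) that pass through
# a stop codon are excluded; remaining pathways weighted equally. In the
# degenerate case where every pathway is blocked, all pathways are used with
# steps into/out of stops counted as nonsynonymous.
codon_pair_differences <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng_env[[key]]
  if (!is.null(hit)) return(hit)
  aa <- Biostrings::GENETIC_CODE
  a1 <- strsplit(c1, "")[[1]]
  a2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(a1 != a2)
  k <- length(diff_pos)
  if (k == 0L) {
    out <- c(syn = 0, nonsyn = 0)
    .ng_env[[key]] <- out
    return(out)
  }
  perms <- .perms[[k]]
  path_syn <- numeric(0); path_non <- numeric(0)
  all_syn <- numeric(0); all_non <- numeric(0)
  for (r in seq_len(nrow(perms))) {
    cur <- a1
    s <- 0; n <- 0; blocked <- FALSE
    for (pos in diff_pos[perms[r, ]]) {
      nxt <- cur
      nxt[pos] <- a2[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (aa[[to]] == "*" || aa[[from]] == "*") {
        blocked <- TRUE
        n <- n + 1  # fallback accounting only
      } else if (aa[[from]] == aa[[to]]) {
        s <- s + 1
      } else {
        n <- n + 1
      }
      cur <- nxt
    }
    all_syn <- c(all_syn, s); all_non <- c(all_non, n)
    if (!blocked) { path_syn <- c(path_syn, s); path_non <- c(path_non, n) }
  }
  out <- if (length(path_syn)) {
    c(syn = mean(path_syn), nonsyn = mean(path_non))
  } else {
    c(syn = mean(all_syn), nonsyn = mean(all_non))
  }
  .ng_env[[key]] <- out
  out
}

#' Jukes-Cantor distance
#'
#' Multiple-hit correction `d = -(3/4) ln(1 - (4/3) p)` of an observed
#' proportion of differences.
#'
#' @param p Proportion of observed differences (0 <= p < 3/4).
#' @return Corrected distance.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("proportion must be >= 0")
  if (any(p >= 0.75)) {
    stop(errorCondition("distance saturated (p >= 3/4)",
                        class = c("nbsevol_saturated", "error", "condition")))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka/Ks for one codon-row pair
#'
#' Synonymous/nonsynonymous site counts come from exhaustive enumeration of
#' single-nucleotide changes per codon (changes to stop codons excluded from
#' the possible-change count), averaged over the two sequences. Differences
#' are averaged over all orderings of minimal mutational pathways, pathways
#' through stop codons excluded. Proportions are Jukes-Cantor corrected.
#'
#' @param row_a,row_b Character vectors of codons (`"---"` for a gap) of
#'   equal length, or in-frame CDS strings. Columns with a gap in either row
#'   are dropped pairwise.
#' @return List of class `kaks_estimate`: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka`, `ratio` (`NA` with `undefined = TRUE` when `Ks = 0`),
#'   `n_codons`.
#' @export
nei_gojobori <- function(row_a, row_b) {
  if (length(row_a) == 1L && nchar(row_a[1]) > 3L) row_a <- split_codons(row_a)
  if (length(row_b) == 1L && nchar(row_b[1]) > 3L) row_b <- split_codons(row_b)
  if (length(row_a) != length(row_b)) {
    stop("codon rows must have equal length")
  }
  keep <- row_a != "---" & row_b != "---"
  a <- row_a[keep]; b <- row_b[keep]
  if (!length(a)) stop("zero comparable codons after gap removal")
  ia <- codon_index(a); ib <- codon_index(b)
  s_sites <- ng_synonymous_sites()
  S <- (sum(s_sites[ia]) + sum(s_sites[ib])) / 2
  N <- 3 * length(a) - S
  diffs <- vapply(seq_along(a), function(i) {
    codon_pair_differences(a[i], b[i])
  }, numeric(2))
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  undefined <- Ks == 0
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 ratio = if (undefined) NA_real_ else Ka / Ks,
                 undefined = undefined, n_codons = length(a)),
            class = "kaks_estimate")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' @param protein_aln Character matrix of aligned residues (rows =
#'   sequences, rownames = gene ids) as from [align_star()].
#' @param cds_map Named character vector of in-frame CDS strings (no
#'   internal stops; trailing stop tolerated).
#' @return Character matrix of codons (`"---"` for gaps), same dimnames.
#' @export
backtranslate_alignment <- function(protein_aln, cds_map) {
  stopifnot(is.matrix(protein_aln), !is.null(rownames(protein_aln)))
  ids <- rownames(protein_aln)
  missing <- setdiff(ids, names(cds_map))
  if (length(missing)) {
    stop("CDS missing for: ", paste(missing, collapse = ", "))
  }
  out <- matrix("---", nrow(protein_aln), ncol(protein_aln),
                dimnames = dimnames(protein_aln))
  for (id in ids) {
    codons <- split_codons(cds_map[[id]])
    if (codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    prot <- translate_cds(paste(codons, collapse = ""))
    row <- protein_aln[id, ]
    residues <- which(row != "-")
    ungapped <- paste(row[residues], collapse = "")
    if (nchar(prot) != length(residues)) {
      stop("CDS/protein length mismatch for ", id, ": ", nchar(prot),
           " codons vs ", length(residues), " aligned residues")
    }
    obs <- strsplit(ungapped, "")[[1]]
    exp <- strsplit(prot, "")[[1]]
    bad <- which(obs != exp)
    if (length(bad)) {
      stop("translation mismatch for ", id, " at residue ", bad[1],
           ": alignment has '", obs[bad[1]], "', CDS encodes '",
           exp[bad[1]], "'")
    }
    out[id, residues] <- codons
  }
  out
}

#' Family-level Ka/Ks
#'
#' Computes Nei-Gojobori estimates for every within-family pair and
#' summarizes: family Ka and Ks are arithmetic means over pairs, and the
#' family ratio is mean(Ka)/mean(Ks) (robust to pairs with undefined
#' ratios). Saturated pairs are dropped with a note; a family whose pairs
#' are all saturated is flagged.
#'
#' @param codon_aln Codon alignment matrix from [backtranslate_alignment()].
#' @return List of class `family_kaks`: `pairs` (data frame), `Ka`, `Ks`,
#'   `ratio`, `n_pairs`, `n_saturated`, `all_saturated`.
#' @export
family_kaks <- function(codon_aln) {
  ids <- rownames(codon_aln)
  stopifnot(length(ids) >= 2L)
  rows <- list(); k <- 0L; n_sat <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      est <- tryCatch(nei_gojobori(codon_aln[i, ], codon_aln[j, ]),
                      nbsevol_saturated = function(e) NULL)
      if (is.null(est)) { n_sat <- n_sat + 1L; next }
      k <- k + 1L
      rows[[k]] <- data.frame(gene_a = ids[i], gene_b = ids[j],
                              S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
                              Ks = est$Ks, Ka = est$Ka, ratio = est$ratio,
                              stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    return(structure(list(pairs = NULL, Ka = NA_real_, Ks = NA_real_,
                          ratio = NA_real_, n_pairs = 0L,
                          n_saturated = n_sat, all_saturated = TRUE),
                     class = "family_kaks"))
  }
  pairs <- do.call(rbind, rows)
  Ka <- mean(pairs$Ka); Ks <- mean(pairs$Ks)
  structure(list(pairs = pairs, Ka = Ka, Ks = Ks,
                 ratio = if (Ks > 0) Ka / Ks else NA_real_,
                 n_pairs = k, n_saturated = n_sat, all_saturated = FALSE),
            class = "family_kaks")
}

#' Ks-bin frequency and Ka/Ks profile
#'
#' Histogram of pairwise Ks over [0, 1) in half-open bins of the given
#' width, with the mean Ka/Ks of the pairs in each bin. Pairs with Ks >= 1
#' are tallied separately.
#'
#' @param estimates Data frame with columns `Ks` and `ratio` (e.g. the
#'   row-bound `pairs` tables of [family_kaks()] results).
#' @param width Bin width (default 0.1).
#' @return Data frame with `bin_lo`, `bin_hi`, `count`, `frequency`
#'   (proportion of all pairs), `mean_ratio`; attribute `n_above` counts
#'   pairs with Ks >= 1 and `n_total` all pairs.
#' @export
ks_profile <- function(estimates, width = 0.1) {
  stopifnot(nrow(estimates) > 0)
  edges <- seq(0, 1, by = width)
  lo <- utils::head(edges, -1); hi <- edges[-1]
  ks <- estimates$Ks
  idx <- findInterval(ks, edges, rightmost.closed = FALSE)
  count <- vapply(seq_along(lo), function(b) sum(idx == b & ks < 1),
                  numeric(1))
  mean_ratio <- vapply(seq_along(lo), function(b) {
    r <- estimates$ratio[idx == b & ks < 1 & !is.na(estimates$ratio)]
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  out <- data.frame(bin_lo = lo, bin_hi = hi, count = count,
                    frequency = count / length(ks), mean_ratio = mean_ratio)
  attr(out, "n_above") <- sum(ks >= 1)
  attr(out, "n_total") <- length(ks)
  out
}
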