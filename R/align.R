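# Protein alignment: pairwise global (Gotoh, compiled) and a center-star
# progressive multiple alignment built on it. Scoring is BLOSUM62 with affine
# gaps (open 10, extend 0.5; a length-L gap costs 10 + 0.5 L), recorded in
# output metadata by the pipeline for reproducibility.

.align_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' @return The BLOSUM62 matrix shipped with Biostrings.
#' @export
blosum62 <- function() {
  if (is.null(.align_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_env$blosum62 <- e$BLOSUM62
  }
  .align_env$blosum62
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (Gotoh
#' algorithm), end gaps penalized.
#'
#' @param a,b Protein sequences (single strings, standard amino-acid
#'   alphabet; `X` tolerated).
#' @param submat Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_ext Positive gap penalties; a gap of length L costs
#'   `gap_open + gap_ext * L`.
#' @return List with `score`, `aligned_a`, `aligned_b`.
#' @export
align_global <- function(a, b, submat = blosum62(), gap_open = 10,
                         gap_ext = 0.5) {
  stopifnot(is.character(a), length(a) == 1L, nzchar(a),
            is.character(b), length(b) == 1L, nzchar(b))
  .gotoh_align(toupper(a), toupper(b), submat, gap_open, gap_ext)
}

#' Coverage and identity of a gene pair
#'
#' Aligns two protein sequences globally and reports the family-clustering
#' metrics: `aligned_length` is the number of alignment columns with a
#' residue in both sequences; `identity` is the fraction of those columns
#' with identical residues (`X` never counts as identical); `coverage` is
#' `aligned_length` divided by the longer sequence's length, which makes the
#' metric symmetric and conservative.
#'
#' @inheritParams align_global
#' @return List with `aligned_length`, `coverage`, `identity`, `score`, and
#'   the aligned strings.
#' @export
pairwise_metrics <- function(a, b, submat = blosum62(), gap_open = 10,
                             gap_ext = 0.5) {
  aln <- align_global(a, b, submat, gap_open, gap_ext)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  aligned_length <- sum(both)
  ident <- sum(both & ca == cb & ca != "X")
  list(aligned_length = aligned_length,
       coverage = aligned_length / max(nchar(a), nchar(b)),
       identity = if (aligned_length > 0) ident / aligned_length else 0,
       score = aln$score,
       aligned_a = aln$aligned_a, aligned_b = aln$aligned_b)
}

#' Center-star progressive multiple alignment
#'
#' Aligns every sequence to a center sequence (the one with the greatest
#' summed pairwise alignment score to all others) and merges the pairwise
#' alignments under the once-a-gap-always-a-gap rule.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @inheritParams align_global
#' @return Character matrix of single characters, rows = sequences (input
#'   order), columns = alignment columns.
#' @export
align_star <- function(seqs, submat = blosum62(), gap_open = 10,
                       gap_ext = 0.5) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  n <- length(seqs)
  if (n == 2L) {
    aln <- align_global(seqs[[1]], seqs[[2]], submat, gap_open, gap_ext)
    m <- rbind(strsplit(aln$aligned_a, "")[[1]],
               strsplit(aln$aligned_b, "")[[1]])
    rownames(m) <- names(seqs)
    return(m)
  }
  # pick the center by total pairwise score
  scores <- matrix(0, n, n)
  pair_cache <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- align_global(seqs[[i]], seqs[[j]], submat, gap_open, gap_ext)
      scores[i, j] <- scores[j, i] <- aln$score
      pair_cache[[(i - 1) * n + j]] <- aln
    }
  }
  center <- which.max(rowSums(scores))

  master <- matrix(strsplit(seqs[[center]], "")[[1]], nrow = 1)
  row_ids <- center
  for (k in seq_len(n)[-center]) {
    aln <- if (k > center) pair_cache[[(center - 1) * n + k]] else NULL
    if (is.null(aln)) {
      # cached orientation is (k, center); realign for a stable orientation
      aln <- align_global(seqs[[center]], seqs[[k]], submat, gap_open,
                          gap_ext)
      ac <- strsplit(aln$aligned_a, "")[[1]]
      as_ <- strsplit(aln$aligned_b, "")[[1]]
    } else {
      ac <- strsplit(aln$aligned_a, "")[[1]]
      as_ <- strsplit(aln$aligned_b, "")[[1]]
    }
    master <- .merge_into_master(master, ac, as_)
    row_ids <- c(row_ids, k)
  }
  out <- master[order(match(row_ids, seq_len(n))), , drop = FALSE]
  rownames(out) <- names(seqs)[sort(row_ids)]
  out
}

# Merge a (center, new) pairwise alignment into the running master alignment
# whose first row is the (gapped) center. Gap columns already in the master
# are consumed before pairwise insertions at the same point (deterministic).
.merge_into_master <- function(master, ac, as_) {
  mc <- master[1, ]
  i <- 1L; j <- 1L
  nm <- length(mc); np <- length(ac)
  keep_cols <- integer(0)   # master column index, or 0L for a fresh gap col
  new_row <- character(0)
  while (i <= nm || j <= np) {
    mi <- if (i <= nm) mc[i] else NA_character_
    pj <- if (j <= np) ac[j] else NA_character_
    if (!is.na(mi) && mi == "-") {
      keep_cols <- c(keep_cols, i); new_row <- c(new_row, "-"); i <- i + 1L
    } else if (!is.na(pj) && pj == "-") {
      keep_cols <- c(keep_cols, 0L); new_row <- c(new_row, as_[j]); j <- j + 1L
    } else if (!is.na(mi) && !is.na(pj)) {
      stopifnot(mi == pj)
      keep_cols <- c(keep_cols, i); new_row <- c(new_row, as_[j])
      i <- i + 1L; j <- j + 1L
    } else {
      stop("internal error: center rows out of sync in center-star merge")
    }
  }
  out <- matrix("-", nrow = nrow(master) + 1L, ncol = length(keep_cols))
  nonzero <- keep_cols != 0L
  out[seq_len(nrow(master)), nonzero] <- master[, keep_cols[nonzero],
                                                drop = FALSE]
  out[nrow(out), ] <- new_row
  out
}
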