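# Gene-family clustering from pairwise global-alignment coverage and
# identity. Two genes are joined when BOTH coverage and identity reach the
# threshold (70/80/90% in the standard protocol); families are the connected
# components of the resulting graph (single linkage), restricted to
# components of size >= 2 — size-1 components are reported as singletons.

#' All-vs-all alignment metrics
#'
#' @param seqs Named character vector of protein sequences.
#' @inheritParams align_global
#' @return Data frame with one row per unordered pair: `gene_a`, `gene_b`,
#'   `aligned_length`, `coverage`, `identity`, `score`.
#' @export
all_pairs_metrics <- function(seqs, submat = blosum62(), gap_open = 10,
                              gap_ext = 0.5) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  rows <- list()
  k <- 0L
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      m <- pairwise_metrics(seqs[[i]], seqs[[j]], submat, gap_open, gap_ext)
      k <- k + 1L
      rows[[k]] <- data.frame(gene_a = names(seqs)[i],
                              gene_b = names(seqs)[j],
                              aligned_length = m$aligned_length,
                              coverage = m$coverage,
                              identity = m$identity,
                              score = m$score,
                              stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      aligned_length = integer(0), coverage = numeric(0),
                      identity = numeric(0), score = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Cluster genes into families at a coverage/identity threshold
#'
#' @param pairs Data frame from [all_pairs_metrics()] (or any table with
#'   `gene_a`, `gene_b`, `coverage`, `identity`).
#' @param gene_ids All gene ids under consideration (singletons included).
#' @param threshold Fraction in (0, 1]; an edge requires `coverage >=
#'   threshold` AND `identity >= threshold`.
#' @return List of class `gene_family_set`: `threshold`, `families` (list of
#'   character vectors, each of size >= 2, ordered by decreasing size then
#'   first member), `singletons`, `membership` (named family id per gene, NA
#'   for singletons).
#' @export
build_families <- function(pairs, gene_ids, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  stopifnot(!anyDuplicated(gene_ids))
  pass <- pairs$coverage >= threshold & pairs$identity >= threshold
  g <- igraph::graph_from_data_frame(
    pairs[pass, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = gene_ids)
  )
  comp <- igraph::components(g)
  groups <- split(gene_ids, comp$membership)
  fams <- Filter(function(x) length(x) >= 2L, groups)
  singles <- unlist(Filter(function(x) length(x) == 1L, groups),
                    use.names = FALSE)
  ord <- order(-vapply(fams, length, integer(1)),
               vapply(fams, function(x) sort(x)[1], character(1)))
  fams <- unname(fams[ord])
  membership <- stats::setNames(rep(NA_integer_, length(gene_ids)), gene_ids)
  for (fi in seq_along(fams)) membership[fams[[fi]]] <- fi
  structure(list(threshold = threshold, families = fams,
                 singletons = sort(as.character(singles)),
                 membership = membership),
            class = "gene_family_set")
}

#' @export
print.gene_family_set <- function(x, ...) {
  cat(sprintf(
    "gene_family_set: threshold %.0f%%, %d families (%d genes), %d singletons\n",
    100 * x$threshold, length(x$families),
    sum(lengths(x$families)), length(x$singletons)))
  invisible(x)
}

#' Family census at one threshold
#'
#' Multi-gene/singleton counts, proportion of genes in multi-gene families,
#' family count, mean and maximal family size — overall and restricted to
#' TIR and non-TIR genes (a TIR gene is one whose architecture code is TNL
#' or TN).
#'
#' @param fs A [build_families()] result.
#' @param tir_flags Named logical vector over all genes in `fs` (`TRUE` =
#'   TIR-type).
#' @return List of class `family_census`.
#' @export
family_census <- function(fs, tir_flags) {
  all_genes <- c(unlist(fs$families, use.names = FALSE), fs$singletons)
  missing <- setdiff(all_genes, names(tir_flags))
  if (length(missing)) {
    stop("tir_flags missing for: ", paste(missing, collapse = ", "))
  }
  stats_for <- function(keep) {
    # restrict the partition to a gene subset; family structure is kept,
    # families reduced below 2 members by the restriction stay families for
    # the subgroup census only if >= 2 members remain
    fams <- lapply(fs$families, function(f) f[f %in% keep])
    fams <- Filter(function(f) length(f) >= 2L, fams)
    multi <- sum(lengths(fams))
    total <- sum(all_genes %in% keep)
    list(multi = multi,
         single = total - multi,
         proportion_multi = proportion_pct(multi, total),
         n_families = length(fams),
         mean_members = if (length(fams)) {
           round_half_up(multi / length(fams), 2)
         } else NA_real_,
         max_members = if (length(fams)) max(lengths(fams)) else 0L)
  }
  tir_genes <- names(tir_flags)[tir_flags]
  structure(list(threshold = fs$threshold,
                 overall = stats_for(all_genes),
                 tir = stats_for(intersect(all_genes, tir_genes)),
                 non_tir = stats_for(setdiff(all_genes, tir_genes))),
            class = "family_census")
}

#' @export
print.family_census <- function(x, ...) {
  o <- x$overall
  cat(sprintf("family census at %.0f%%:\n", 100 * x$threshold))
  cat(sprintf("  multi-gene %d, singletons %d (%.2f%% multiple)\n",
              o$multi, o$single, o$proportion_multi))
  cat(sprintf("  %d families, mean %.2f members, max %d\n",
              o$n_families, o$mean_members, o$max_members))
  invisible(x)
}
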