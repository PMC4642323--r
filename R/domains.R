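# Architecture classification of NBS-encoding genes from domain annotations,
# and the genome census (counts, proportions, exon statistics).
#
# Letter codes follow the field's convention: an NBS (NB-ARC) domain is
# required; a TIR N-terminus gives TNL/TN (with/without LRR), a coiled-coil
# gives CNL/CN, no recognized N-terminal domain gives XNL/XN. The RPW8
# powdery-mildew-resistance domain is flagged orthogonally (it co-occurs with
# TIR or CC architectures), not as a seventh code.

DOMAIN_LABELS <- c("NBS", "TIR", "CC", "LRR", "RPW8")
ARCH_CODES <- c("TNL", "TN", "CNL", "CN", "XNL", "XN")

#' Classify a gene's domain architecture
#'
#' Presence/absence of domains determines the letter code; multiple hits of
#' one domain collapse to presence. Genes without an NBS domain are not
#' NBS-encoding and receive an `NA` code.
#'
#' @param hits Character vector of domain labels observed in the gene
#'   (subset of `NBS, TIR, CC, LRR, RPW8`; may be empty).
#' @return List with `code` (one of TNL/TN/CNL/CN/XNL/XN, or `NA` if the
#'   gene is not NBS-encoding), `nbs` (logical) and `rnl` (logical RPW8
#'   flag).
#' @export
classify_architecture <- function(hits) {
  hits <- unique(as.character(hits))
  bad <- setdiff(hits, DOMAIN_LABELS)
  if (length(bad)) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  }
  rnl <- "RPW8" %in% hits
  if (!"NBS" %in% hits) {
    return(list(code = NA_character_, nbs = FALSE, rnl = rnl))
  }
  lrr <- "LRR" %in% hits
  code <- if ("TIR" %in% hits) {
    if (lrr) "TNL" else "TN"
  } else if ("CC" %in% hits) {
    if (lrr) "CNL" else "CN"
  } else {
    if (lrr) "XNL" else "XN"
  }
  list(code = code, nbs = TRUE, rnl = rnl)
}

#' Classify a table of domain hits
#'
#' @param domain_hits Data frame with columns `gene_id` and `domain` (extra
#'   columns such as coordinates are ignored for classification).
#' @param gene_ids Optional vector of gene ids to classify (genes with no
#'   hits get `NA` code); defaults to the ids present in `domain_hits`.
#' @return Data frame with columns `gene_id`, `code`, `nbs`, `rnl`.
#' @export
classify_genes <- function(domain_hits, gene_ids = NULL) {
  stopifnot(all(c("gene_id", "domain") %in% names(domain_hits)))
  if (is.null(gene_ids)) gene_ids <- unique(domain_hits$gene_id)
  by_gene <- split(as.character(domain_hits$domain),
                   factor(domain_hits$gene_id, levels = gene_ids))
  res <- lapply(gene_ids, function(g) classify_architecture(by_gene[[g]]))
  data.frame(gene_id = gene_ids,
             code = vapply(res, `[[`, character(1), "code"),
             nbs = vapply(res, `[[`, logical(1), "nbs"),
             rnl = vapply(res, `[[`, logical(1), "rnl"),
             stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Display rounding for percentages and means (2 decimals by default),
#' half-up rather than R's default round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean exon count of a gene subset
#'
#' @param exon_counts Named integer vector (per-gene exon counts, e.g. from
#'   [read_gff_genes()]).
#' @param subset Gene ids to average over.
#' @return Arithmetic mean exon count (`NaN` for an empty subset).
#' @export
exon_stats <- function(exon_counts, subset) {
  missing <- setdiff(subset, names(exon_counts))
  if (length(missing)) {
    stop("genes absent from the gene models: ",
         paste(missing, collapse = ", "))
  }
  mean(exon_counts[subset])
}

#' Architecture census of NBS-encoding genes
#'
#' Counts per letter code, aggregate counts (NBS-encoding, NBS-LRR,
#' NBS-only, TIR and non-TIR), genome proportions against a supplied
#' genome-wide gene total, and mean exon counts per aggregate.
#'
#' @param classes Data frame from [classify_genes()]; rows with `nbs = FALSE`
#'   are excluded from the census.
#' @param genome_gene_total Number of genes in the whole genome (the
#'   denominator for proportions). Must be >= the number of NBS genes.
#' @param exon_counts Optional named vector of per-gene exon counts.
#' @return List of class `nbs_census` with `counts`, `aggregates`,
#'   `proportions` (percent, rounded to 2 decimals half-up) and
#'   `mean_exons`.
#' @export
architecture_census <- function(classes, genome_gene_total,
                                exon_counts = NULL) {
  stopifnot(is.numeric(genome_gene_total), length(genome_gene_total) == 1L)
  if (genome_gene_total <= 0) {
    stop("genome_gene_total must be a positive count")
  }
  cl <- classes[classes$nbs, , drop = FALSE]
  if (genome_gene_total < nrow(cl)) {
    stop("genome_gene_total is smaller than the number of NBS genes")
  }
  counts <- vapply(ARCH_CODES, function(cd) sum(cl$code == cd), integer(1))
  agg <- c(
    nbs_encoding = sum(counts),
    nbs_lrr = counts[["TNL"]] + counts[["CNL"]] + counts[["XNL"]],
    nbs_only = counts[["TN"]] + counts[["CN"]] + counts[["XN"]],
    tir = counts[["TNL"]] + counts[["TN"]],
    non_tir = sum(counts) - counts[["TNL"]] - counts[["TN"]],
    tnl = counts[["TNL"]],
    non_tnl = counts[["CNL"]] + counts[["XNL"]],
    rnl = sum(cl$rnl)
  )
  pct <- function(x) proportion_pct(x, genome_gene_total)
  proportions <- c(
    nbs_encoding = pct(agg[["nbs_encoding"]]),
    nbs_lrr = pct(agg[["nbs_lrr"]]),
    tnl = pct(agg[["tnl"]]),
    non_tnl = pct(agg[["non_tnl"]])
  )
  mean_exons <- NULL
  if (!is.null(exon_counts)) {
    subsets <- list(
      nbs_encoding = cl$gene_id,
      nbs_lrr = cl$gene_id[cl$code %in% c("TNL", "CNL", "XNL")],
      tnl = cl$gene_id[cl$code == "TNL"],
      non_tnl = cl$gene_id[cl$code %in% c("CNL", "XNL")],
      cnl = cl$gene_id[cl$code == "CNL"]
    )
    mean_exons <- vapply(subsets, function(s) {
      if (!length(s)) return(NA_real_)
      round_half_up(exon_stats(exon_counts, s), 2)
    }, numeric(1))
  }
  structure(list(counts = counts, aggregates = agg,
                 proportions = proportions, mean_exons = mean_exons,
                 genome_gene_total = genome_gene_total),
            class = "nbs_census")
}

#' Percentage with 2-decimal half-up rounding
#'
#' @param x Numerator count.
#' @param total Denominator count.
#' @return `100 * x / total` rounded half-up to 2 decimals (0 if total is 0).
#' @export
proportion_pct <- function(x, total) {
  if (total == 0) return(0)
  round_half_up(100 * x / total, 2)
}

#' @export
print.nbs_census <- function(x, ...) {
  cat("NBS-encoding gene census\n")
  cat("  total NBS-encoding:", x$aggregates[["nbs_encoding"]],
      sprintf("(%.2f%% of %d genome genes)\n",
              x$proportions[["nbs_encoding"]], as.integer(x$genome_gene_total)))
  cat("  per code:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                           collapse = " "), "\n")
  cat("  NBS-LRR:", x$aggregates[["nbs_lrr"]],
      " TIR:", x$aggregates[["tir"]],
      " non-TIR:", x$aggregates[["non_tir"]],
      " RPW8-flagged:", x$aggregates[["rnl"]], "\n")
  if (!is.null(x$mean_exons)) {
    cat("  mean exons:",
        paste(sprintf("%s=%.2f", names(x$mean_exons), x$mean_exons),
              collapse = " "), "\n")
  }
  invisible(x)
}
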