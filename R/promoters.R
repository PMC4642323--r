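# Promoter extraction (~1 kb upstream of the gene feature, strand-aware)
# and exact IUPAC-degenerate cis-element scanning on both strands, with a
# per-motif census. Overlapping matches are counted and a palindromic site
# yields one hit per strand (SIGNALSCAN-like behaviour).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Reverse complement of an IUPAC pattern or DNA sequence
#'
#' @param x A single string over the IUPAC nucleotide alphabet.
#' @return The reverse complement string.
#' @export
revcomp_iupac <- function(x) {
  chars <- rev(strsplit(toupper(x), "")[[1]])
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("invalid IUPAC code(s): ",
         paste(unique(chars[is.na(comp)]), collapse = ", "))
  }
  paste(comp, collapse = "")
}

# Translate an IUPAC pattern into a PCRE character-class regex. Subject N is
# unknown sequence: it matches only a motif N (which accepts any base or N).
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!length(chars)) stop("empty motif pattern")
  cls <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC code: ", ch)
    if (ch == "N") "[ACGTN]" else if (length(set) == 1) set
    else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste(cls, collapse = "")
}

#' Extract promoter regions from a genome
#'
#' For a plus-strand gene the promoter is the `length` bases ending
#' immediately before the gene start; for a minus-strand gene, the reverse
#' complement of the `length` bases starting immediately after the gene
#' end. Promoters running off a contig edge are truncated and flagged.
#'
#' @param genome A named `Biostrings::DNAStringSet` (or named character
#'   vector) of contigs.
#' @param genes A `GenomicRanges::GRanges` of gene features with a
#'   `gene_id` metadata column (e.g. from [read_gff_genes()]).
#' @param length Promoter length in bp (default 1000).
#' @return Named character vector of promoter sequences (5' to 3'), with a
#'   logical `truncated` attribute.
#' @export
extract_promoters <- function(genome, genes, length = 1000) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  ids <- genes$gene_id
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  missing <- setdiff(as.character(GenomicRanges::seqnames(genes)),
                     names(genome))
  if (length(missing)) {
    stop("contig(s) absent from the genome: ",
         paste(unique(missing), collapse = ", "))
  }
  prom <- GenomicRanges::promoters(genes, upstream = length, downstream = 0)
  out <- character(base::length(genes))
  truncated <- logical(base::length(genes))
  for (i in seq_along(genes)) {
    contig <- as.character(GenomicRanges::seqnames(prom)[i])
    contig_len <- base::length(genome[[contig]])
    s <- max(1L, GenomicRanges::start(prom)[i])
    e <- min(contig_len, GenomicRanges::end(prom)[i])
    truncated[i] <- (e - s + 1L) < length
    if (e < s) { out[i] <- ""; truncated[i] <- TRUE; next }
    seq <- Biostrings::subseq(genome[[contig]], s, e)
    if (as.character(GenomicRanges::strand(genes)[i]) == "-") {
      seq <- Biostrings::reverseComplement(seq)
    }
    out[i] <- as.character(seq)
  }
  names(out) <- ids
  attr(out, "truncated") <- stats::setNames(truncated, ids)
  out
}

#' Scan promoters for IUPAC motifs
#'
#' Exact degenerate matching of each motif against each promoter, both
#' strands, all overlapping occurrences. A minus-strand hit is reported at
#' the forward-coordinate start of the site (the position where the
#' reverse complement of the motif matches the forward strand).
#'
#' @param promoters Named character vector of promoter sequences (alphabet
#'   `A, C, G, T, N`; `N` matches only a motif `N`).
#' @param motifs Named character vector of IUPAC patterns (names = motif
#'   names), or a data frame with `name` and `pattern` columns.
#' @return Data frame of hits: `gene_id`, `motif`, `strand`, `start`.
#' @export
scan_motifs <- function(promoters, motifs) {
  if (is.data.frame(motifs)) {
    motifs <- stats::setNames(motifs$pattern, motifs$name)
  }
  stopifnot(!is.null(names(motifs)), !is.null(names(promoters)))
  hits <- list(); k <- 0L
  for (mi in seq_along(motifs)) {
    fwd <- paste0("(?=", iupac_regex(motifs[[mi]]), ")")
    rev_ <- paste0("(?=", iupac_regex(revcomp_iupac(motifs[[mi]])), ")")
    for (gi in seq_along(promoters)) {
      seq <- toupper(promoters[[gi]])
      if (!nzchar(seq)) next
      for (strand in c("+", "-")) {
        rx <- if (strand == "+") fwd else rev_
        m <- gregexpr(rx, seq, perl = TRUE)[[1]]
        starts <- m[m > 0]
        if (!length(starts)) next
        k <- k + 1L
        hits[[k]] <- data.frame(gene_id = names(promoters)[gi],
                                motif = names(motifs)[mi],
                                strand = strand, start = as.integer(starts),
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) {
    return(data.frame(gene_id = character(0), motif = character(0),
                      strand = character(0), start = integer(0)))
  }
  do.call(rbind, hits)
}

#' Per-motif occurrence census
#'
#' Both interpretations of a motif count are reported: total occurrences
#' and the number of genes with at least one hit; rows are sorted by
#' decreasing gene count (ties by occurrences, then name).
#'
#' @param hits Hit table from [scan_motifs()].
#' @param gene_ids All scanned gene ids (to report zeros).
#' @param motif_names All motif names (to report zeros).
#' @return Data frame with `motif`, `occurrences`, `genes_with_hit`.
#' @export
motif_census <- function(hits, gene_ids, motif_names) {
  occurrences <- vapply(motif_names, function(m) {
    sum(hits$motif == m)
  }, integer(1))
  genes_with_hit <- vapply(motif_names, function(m) {
    length(unique(hits$gene_id[hits$motif == m]))
  }, integer(1))
  out <- data.frame(motif = motif_names, occurrences = occurrences,
                    genes_with_hit = genes_with_hit,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$genes_with_hit, -out$occurrences, out$motif), ,
      drop = FALSE]
}
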