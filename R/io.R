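# Readers and writers for the dataset formats: FASTA via Biostrings, GFF3
# via rtracklayer, and the simple TSV tables (domain hits, species map,
# motif file). All writers emit deterministic, plain-text output.

#' Read a protein or nucleotide FASTA into a named character vector
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs)
       else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Returns the gene features as a `GRanges` with a `gene_id` column and a
#' per-gene exon count. When a gene has several mRNAs, the exon count of
#' the mRNA with the longest total CDS is used (ties broken by mRNA id).
#'
#' @param path GFF3 file.
#' @return `GRanges` of genes with metadata columns `gene_id` and
#'   `exon_count`.
#' @export
read_gff_genes <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  genes$gene_id <- genes$ID
  mrna <- gff[type == "mRNA"]
  exons <- gff[type == "exon"]
  cds <- gff[type == "CDS"]
  parent1 <- function(x) vapply(x$Parent, function(p) p[1], character(1))
  mrna_parent <- parent1(mrna)
  exon_parent <- parent1(exons)
  cds_parent <- parent1(cds)
  exon_count <- integer(length(genes))
  for (i in seq_along(genes)) {
    g <- genes$gene_id[i]
    m_ids <- mrna$ID[mrna_parent == g]
    if (!length(m_ids)) { exon_count[i] <- NA_integer_; next }
    cds_len <- vapply(m_ids, function(m) {
      sum(GenomicRanges::width(cds[cds_parent == m]))
    }, numeric(1))
    canon <- m_ids[order(-cds_len, m_ids)][1]
    exon_count[i] <- sum(exon_parent == canon)
  }
  genes$exon_count <- exon_count
  genes
}

#' Read a domain-hit table
#'
#' @param path TSV with columns `gene_id`, `domain`, `start`, `end`.
#' @return Data frame.
#' @export
read_domain_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "domain", "start", "end") %in% names(d)))
  d
}

#' Read a species-map table
#'
#' @param path TSV with columns `gene_id`, `species`.
#' @return Named character vector gene id -> species.
#' @export
read_species_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "species") %in% names(d)))
  stats::setNames(d$species, d$gene_id)
}

#' Read a motif file
#'
#' @param path TSV with columns `name`, `pattern` (IUPAC codes).
#' @return Named character vector of patterns.
#' @export
read_motif_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "pattern") %in% names(d)))
  stats::setNames(d$pattern, d$name)
}

#' Write a data frame as TSV
#'
#' @param d Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
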