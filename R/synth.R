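# Seeded synthetic-data generator. Emits a miniature genome/proteome/
# annotation/promoter dataset with the statistical structure the analysis
# assumes — multi-member gene families diverged to target Ks under chosen
# omega, planted domain architectures, two species labels, promoters with
# planted motif occurrences — plus a ground-truth manifest.
#
# Families evolve on a star topology: one root codon sequence drawn from
# the model's stationary distribution, each member evolved independently
# along a branch of half the pairwise divergence calibrated to the target
# Ks. Domain architectures are emitted as annotation rows (the pipeline
# consumes domain tables, mirroring the use of upstream domain scanners),
# not as sequence motifs.

ARCH_DOMAINS <- list(
  TNL = c("TIR", "NBS", "LRR"), TN = c("TIR", "NBS"),
  CNL = c("CC", "NBS", "LRR"), CN = c("CC", "NBS"),
  XNL = c("NBS", "LRR"), XN = "NBS"
)

#' Evolve a codon sequence along a branch
#'
#' Each codon site evolves independently under the GY94 process of the
#' selection module: transition probabilities are the matrix exponential of
#' the normalized rate matrix at the given branch length. The process is
#' restricted to the 61 sense codons, so no stop codon can arise.
#'
#' @param root Codon sequence: character vector of codons or an in-frame
#'   CDS string (sense codons only).
#' @param branch_length Expected substitutions per codon site (>= 0).
#' @param params A [codon_params()] object.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Character vector of evolved codons.
#' @export
evolve_codon_sequence <- function(root, branch_length, params, seed = NULL) {
  if (length(root) == 1L && nchar(root[1]) > 3L) root <- split_codons(root)
  idx <- codon_index(root)
  stopifnot(branch_length >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (branch_length == 0) return(sense_codons()[idx])
  P <- prob_matrix(rev_eigen(gy94_rate_matrix(params)), branch_length)
  out <- integer(length(idx))
  for (state in unique(idx)) {
    at <- which(idx == state)
    out[at] <- sample.int(61L, length(at), replace = TRUE, prob = P[state, ])
  }
  sense_codons()[out]
}

#' Sample a codon sequence from stationary frequencies
#'
#' @param n_codons Number of codons.
#' @param params A [codon_params()] object.
#' @return Character vector of codons.
#' @export
sample_root_codons <- function(n_codons, params) {
  sense_codons()[sample.int(61L, n_codons, replace = TRUE,
                            prob = params$pi)]
}

#' Specification of one simulated gene family
#'
#' @param size Number of members (>= 1).
#' @param architecture Letter code (TNL/TN/CNL/CN/XNL/XN).
#' @param target_ks Pairwise synonymous divergence the members should
#'   attain (substitutions per synonymous site, >= 0).
#' @param omega dN/dS of the simulating process (>= 0).
#' @param kappa Transition/transversion ratio (> 0).
#' @param cds_codons CDS length in codons (>= 40 so planted domain
#'   cassettes fit).
#' @param rnl Whether members carry the RPW8 domain.
#' @param species Species label (default: the configuration's first
#'   species).
#' @return A `family_spec` list.
#' @export
family_spec <- function(size, architecture = "CNL", target_ks = 0.3,
                        omega = 0.3, kappa = 2, cds_codons = 150,
                        rnl = FALSE, species = NULL) {
  stopifnot(size >= 1, target_ks >= 0, omega >= 0, kappa > 0,
            cds_codons >= 40,
            architecture %in% names(ARCH_DOMAINS))
  structure(list(size = as.integer(size), architecture = architecture,
                 target_ks = target_ks, omega = omega, kappa = kappa,
                 cds_codons = as.integer(cds_codons), rnl = isTRUE(rnl),
                 species = species),
            class = "family_spec")
}

#' Simulation configuration
#'
#' @param seed Integer seed; a single RNG stream drives the whole dataset.
#' @param species_names Species labels (first = focal species).
#' @param family_specs List of [family_spec()] objects.
#' @param singleton_count Number of unrelated single-copy genes.
#' @param singleton_codons CDS length of singletons.
#' @param promoter_length Promoter length in bp (default 1000).
#' @param motifs Named character vector of IUPAC motif patterns (the motif
#'   file written alongside the dataset).
#' @param planted_motifs Named integer vector: occurrences to plant per
#'   promoter for each named motif (names must appear in `motifs`).
#' @param genome_gene_total Genome-wide gene count used as the census
#'   denominator (>= number of simulated genes).
#' @param deep_divergence Branch length (expected substitutions per codon
#'   site) from the shared superfamily ancestor to each family root and
#'   each singleton. All simulated genes are homologous — as real NBS
#'   genes are — but between-family divergence is deep enough (default 1.0
#'   per lineage) that only within-family pairs pass the clustering
#'   thresholds.
#' @param provable_promoters When `TRUE` (default) promoter background is
#'   drawn from the 3-letter alphabet A/C/T so that planted counts of
#'   G-containing motifs are exactly recoverable on the forward strand;
#'   otherwise the background is uniform over A/C/G/T.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, species_names = c("speciesA", "speciesB"),
                       family_specs = list(), singleton_count = 0,
                       singleton_codons = 150, promoter_length = 1000,
                       motifs = c(DOFCOREZM = "AAAG"),
                       planted_motifs = c(DOFCOREZM = 2L),
                       genome_gene_total = 2000,
                       provable_promoters = TRUE,
                       deep_divergence = 1.0) {
  stopifnot(length(species_names) >= 1, !anyDuplicated(species_names),
            singleton_count >= 0, promoter_length >= 10)
  for (fs in family_specs) stopifnot(inherits(fs, "family_spec"))
  n_genes <- sum(vapply(family_specs, `[[`, integer(1), "size")) +
    singleton_count
  if (n_genes > genome_gene_total) {
    stop("sum of family sizes plus singletons (", n_genes,
         ") exceeds genome_gene_total (", genome_gene_total, ")")
  }
  if (length(planted_motifs)) {
    stopifnot(!is.null(names(planted_motifs)),
              all(names(planted_motifs) %in% names(motifs)))
  }
  structure(list(seed = as.integer(seed), species_names = species_names,
                 family_specs = family_specs,
                 singleton_count = as.integer(singleton_count),
                 singleton_codons = as.integer(singleton_codons),
                 promoter_length = as.integer(promoter_length),
                 motifs = motifs, planted_motifs = planted_motifs,
                 genome_gene_total = as.integer(genome_gene_total),
                 provable_promoters = isTRUE(provable_promoters),
                 deep_divergence = deep_divergence),
            class = "sim_config")
}

#' Default simulation configuration
#'
#' A desk-scale dataset emulating the structure of a two-species NBS-gene
#' survey: a focal species carrying several multi-member families whose Ks
#' targets cluster around the 0.4-0.5 duplication peak with a minority of
#' recent (Ks 0.1-0.2) duplications, mostly purifying omega with one family
#' under positive selection, an RPW8-flagged family, a TIR family, and a
#' handful of singletons split across both species.
#'
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1) {
  fams <- list(
    family_spec(6, "XNL", target_ks = 0.45, omega = 0.20),
    family_spec(5, "CNL", target_ks = 0.42, omega = 0.30),
    family_spec(4, "CN",  target_ks = 0.48, omega = 0.20),
    family_spec(4, "TNL", target_ks = 0.16, omega = 0.40),
    family_spec(3, "XNL", target_ks = 0.10, omega = 1.20),
    family_spec(3, "XNL", target_ks = 0.30, omega = 0.30, rnl = TRUE),
    family_spec(3, "CNL", target_ks = 0.06, omega = 0.40),
    family_spec(4, "XNL", target_ks = 0.45, omega = 0.25,
                species = "speciesB"),
    family_spec(2, "TN",  target_ks = 0.35, omega = 0.30)
  )
  sim_config(
    seed = seed,
    species_names = c("speciesA", "speciesB"),
    family_specs = fams,
    singleton_count = 8,
    motifs = default_motifs(),
    planted_motifs = c(DOFCOREZM = 2L, WBOXATNPR1 = 1L),
    genome_gene_total = 2000
  )
}

#' Built-in motif fixture
#'
#' A small set of named IUPAC cis-element patterns in the style of the
#' PLACE collection, shipped as `inst/extdata/motifs_place_subset.tsv`.
#'
#' @return Named character vector of patterns.
#' @export
default_motifs <- function() {
  read_motif_tsv(system.file("extdata", "motifs_place_subset.tsv",
                             package = "nbsevol", mustWork = TRUE))
}

# Plant non-overlapping motif instances into a promoter-oriented character
# vector; `taken` carries positions already occupied by other motifs so
# instances of different motifs never overwrite each other. Returns the
# modified vector, the chosen start positions and the updated `taken`.
.plant_motifs <- function(prom, pattern, count, taken = integer(0)) {
  w <- nchar(pattern)
  L <- length(prom)
  stopifnot(count * (w + 1) < L)
  sets <- IUPAC_SETS[strsplit(toupper(pattern), "")[[1]]]
  starts <- integer(0)
  guard <- 0L
  while (length(starts) < count) {
    guard <- guard + 1L
    if (guard > 1000L) stop("could not place motifs without overlap")
    p <- sample.int(L - w + 1L, 1L)
    if (any(seq.int(p, p + w - 1L) %in% taken)) next
    inst <- vapply(sets, function(s) s[sample.int(length(s), 1L)],
                   character(1))
    prom[seq.int(p, p + w - 1L)] <- inst
    taken <- c(taken, seq.int(p, p + w - 1L))
    starts <- c(starts, p)
  }
  list(prom = prom, starts = sort(starts), taken = taken)
}

# Domain cassette rows for one gene, coordinates as fractions of protein
# length.
.domain_rows <- function(gene_id, code, rnl, prot_len) {
  seg <- function(lo, hi) c(max(1L, round(lo * prot_len)),
                            min(prot_len, round(hi * prot_len)))
  spans <- list(TIR = seg(0.05, 0.25), CC = seg(0.05, 0.20),
                RPW8 = seg(0.05, 0.15), NBS = seg(0.30, 0.65),
                LRR = seg(0.70, 0.95))
  labels <- ARCH_DOMAINS[[code]]
  if (rnl) labels <- c(labels, "RPW8")
  do.call(rbind, lapply(labels, function(d) {
    data.frame(gene_id = gene_id, domain = d, start = spans[[d]][1],
               end = spans[[d]][2], stringsAsFactors = FALSE)
  }))
}

#' Simulate a dataset
#'
#' Writes protein FASTA, CDS FASTA, genome FASTA, GFF3 gene models (gene/
#' mRNA/exon/CDS), domain TSV, species map TSV, promoter FASTA, the motif
#' file, and a ground-truth manifest JSON into `out_dir`. Re-running with
#' the same configuration reproduces the files byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  genes <- list()      # per-gene records
  fam_rows <- list()
  counter <- stats::setNames(rep(0L, length(config$species_names)),
                             config$species_names)
  new_id <- function(species) {
    counter[species] <<- counter[species] + 1L
    sprintf("%s_g%03d", species, counter[species])
  }

  # One ancestral sequence for the whole superfamily: every family root and
  # singleton is a deeply diverged descendant, so all genes are homologous
  # but only within-family pairs pass the clustering thresholds.
  anc_params <- codon_params(kappa = 2, omega = 0.3, pi = "equal")
  max_codons <- max(c(config$singleton_codons,
                      vapply(config$family_specs, `[[`, integer(1),
                             "cds_codons"), 1L))
  ancestor <- sample_root_codons(max_codons, anc_params)

  for (fi in seq_along(config$family_specs)) {
    fs <- config$family_specs[[fi]]
    species <- if (is.null(fs$species)) config$species_names[1] else fs$species
    stopifnot(species %in% config$species_names)
    params <- codon_params(fs$kappa, fs$omega, "equal")
    t_pair <- divergence_for_ks(fs$target_ks, params)
    root <- evolve_codon_sequence(ancestor[seq_len(fs$cds_codons)],
                                  config$deep_divergence, anc_params)
    for (m in seq_len(fs$size)) {
      codons <- evolve_codon_sequence(root, t_pair / 2, params)
      genes[[length(genes) + 1L]] <- list(
        gene_id = new_id(species), species = species,
        code = fs$architecture, rnl = fs$rnl, family = fi,
        cds = paste(codons, collapse = ""))
    }
    fam_rows[[fi]] <- data.frame(
      family = fi, size = fs$size, architecture = fs$architecture,
      rnl = fs$rnl, species = species, target_ks = fs$target_ks,
      omega = fs$omega, kappa = fs$kappa, cds_codons = fs$cds_codons,
      stringsAsFactors = FALSE)
  }
  for (s in seq_len(config$singleton_count)) {
    species <- config$species_names[(s - 1L) %%
                                      length(config$species_names) + 1L]
    codons <- evolve_codon_sequence(
      ancestor[seq_len(config$singleton_codons)],
      config$deep_divergence, anc_params)
    # singleton architectures rotate over the letter codes
    code <- names(ARCH_DOMAINS)[(s - 1L) %% length(ARCH_DOMAINS) + 1L]
    genes[[length(genes) + 1L]] <- list(
      gene_id = new_id(species), species = species, code = code,
      rnl = FALSE, family = NA_integer_,
      cds = paste(codons, collapse = ""))
  }

  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  cds_map <- stats::setNames(vapply(genes, `[[`, character(1), "cds"),
                             gene_ids)
  prot_map <- vapply(cds_map, translate_cds, character(1))
  exon_counts <- stats::setNames(sample(1:6, length(genes), replace = TRUE),
                                 gene_ids)

  # --- genome layout: per-species contig, one block per gene ------------
  L <- config$promoter_length
  bg_alpha <- if (config$provable_promoters) c("A", "C", "T") else NUC
  contigs <- list()
  gff <- c("##gff-version 3")
  prom_truth <- list()
  gene_meta <- list()
  for (species in config$species_names) {
    idx <- which(vapply(genes, `[[`, character(1), "species") == species)
    if (!length(idx)) next
    contig <- paste0("chr_", species)
    blocks <- list()
    cursor <- 0L
    for (k in idx) {
      g <- genes[[k]]
      cds_chars <- strsplit(g$cds, "")[[1]]
      glen <- length(cds_chars)
      block_len <- L + glen + L
      block <- sample(bg_alpha, block_len, replace = TRUE)
      strand <- if (match(k, idx) %% 2L == 1L) "+" else "-"
      gstart <- cursor + L + 1L
      gend <- gstart + glen - 1L
      # gene body
      body <- if (strand == "+") cds_chars else
        rev(unname(IUPAC_COMPLEMENT[cds_chars]))
      block[seq.int(L + 1L, L + glen)] <- body
      # promoter, authored in promoter orientation then placed
      prom <- sample(bg_alpha, L, replace = TRUE)
      counts <- list()
      occupied <- integer(0)
      for (mn in names(config$planted_motifs)) {
        planted <- .plant_motifs(prom, config$motifs[[mn]],
                                 config$planted_motifs[[mn]], occupied)
        prom <- planted$prom
        occupied <- planted$taken
        counts[[mn]] <- length(planted$starts)
      }
      if (strand == "+") {
        block[seq_len(L)] <- prom
      } else {
        block[seq.int(L + glen + 1L, block_len)] <-
          rev(unname(IUPAC_COMPLEMENT[prom]))
      }
      prom_truth[[g$gene_id]] <- counts
      blocks[[length(blocks) + 1L]] <- block
      # gff records (exons split the gene span contiguously)
      mid <- paste0(g$gene_id, ".m1")
      gff <- c(gff,
               sprintf("%s\tnbsevol_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       contig, gstart, gend, strand, g$gene_id),
               sprintf("%s\tnbsevol_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       contig, gstart, gend, strand, mid, g$gene_id))
      ne <- exon_counts[[g$gene_id]]
      bounds <- unique(round(seq(gstart - 1L, gend, length.out = ne + 1L)))
      ne <- length(bounds) - 1L
      exon_counts[g$gene_id] <- ne
      phase <- 0L
      for (e in seq_len(ne)) {
        es <- bounds[e] + 1L; ee <- bounds[e + 1L]
        gff <- c(gff,
                 sprintf("%s\tnbsevol_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                         contig, es, ee, strand, mid, e, mid),
                 sprintf("%s\tnbsevol_sim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         contig, es, ee, strand, phase, mid, mid))
        phase <- (3L - (ee - es + 1L - phase) %% 3L) %% 3L
      }
      gene_meta[[length(gene_meta) + 1L]] <- data.frame(
        gene_id = g$gene_id, species = species, code = g$code,
        rnl = g$rnl, family = g$family, exon_count = ne,
        strand = strand, contig = contig, start = gstart, end = gend,
        stringsAsFactors = FALSE)
      cursor <- cursor + block_len
    }
    contigs[[contig]] <- paste(unlist(blocks), collapse = "")
  }

  # --- domain table -----------------------------------------------------
  dom <- do.call(rbind, lapply(genes, function(g) {
    .domain_rows(g$gene_id, g$code, g$rnl, nchar(prot_map[[g$gene_id]]))
  }))

  # --- write files ------------------------------------------------------
  paths <- list(
    proteins = file.path(out_dir, "proteins.faa"),
    cds = file.path(out_dir, "cds.fna"),
    genome = file.path(out_dir, "genome.fna"),
    gff = file.path(out_dir, "genes.gff3"),
    domains = file.path(out_dir, "domains.tsv"),
    species = file.path(out_dir, "species.tsv"),
    promoters = file.path(out_dir, "promoters.fna"),
    motifs = file.path(out_dir, "motifs.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_fasta(prot_map, paths$proteins, "AA")
  write_fasta(cds_map, paths$cds, "DNA")
  write_fasta(unlist(contigs), paths$genome, "DNA")
  writeLines(gff, paths$gff)
  write_tsv(dom, paths$domains)
  meta <- do.call(rbind, gene_meta)
  write_tsv(meta[, c("gene_id", "species")], paths$species)
  write_tsv(data.frame(name = names(config$motifs),
                       pattern = unname(config$motifs)), paths$motifs)
  genome <- Biostrings::DNAStringSet(unlist(contigs))
  gr <- read_gff_genes(paths$gff)
  proms <- extract_promoters(genome, gr, L)
  write_fasta(stats::setNames(as.character(proms), names(proms)),
              paths$promoters, "DNA")

  manifest <- list(
    seed = config$seed,
    genome_gene_total = config$genome_gene_total,
    promoter_length = L,
    provable_promoters = config$provable_promoters,
    genes = meta,
    families = if (length(fam_rows)) do.call(rbind, fam_rows) else NULL,
    planted_motifs = as.list(config$planted_motifs),
    planted_per_gene = prom_truth,
    paths = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
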