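# Stage orchestration: read a dataset directory, run classification,
# family clustering (three thresholds), Ka/Ks, phylogeny + clade reports,
# site-model selection tests and promoter scanning, and write per-stage
# TSVs plus a Markdown summary report. All randomness (bootstrap, optimizer
# restarts) flows from one seed.

#' Read and cross-validate a dataset directory
#'
#' Expects the file layout written by [simulate_dataset()]: `proteins.faa`,
#' `cds.fna`, `genes.gff3`, `domains.tsv`, `species.tsv`, plus either
#' `genome.fna` or `promoters.fna`, and optionally `motifs.tsv` and
#' `manifest.json`.
#'
#' @param dir Dataset directory.
#' @return List of parsed inputs.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  proteins <- read_fasta(p("proteins.faa"), "AA")
  cds <- read_fasta(p("cds.fna"), "DNA")
  genes <- read_gff_genes(p("genes.gff3"))
  domains <- read_domain_tsv(p("domains.tsv"))
  species <- read_species_tsv(p("species.tsv"))
  motifs <- if (file.exists(p("motifs.tsv"))) read_motif_tsv(p("motifs.tsv"))
            else default_motifs()
  genome <- if (file.exists(p("genome.fna"))) {
    Biostrings::readDNAStringSet(p("genome.fna"))
  } else NULL
  promoters <- if (file.exists(p("promoters.fna"))) {
    read_fasta(p("promoters.fna"), "DNA")
  } else NULL
  manifest <- if (file.exists(p("manifest.json"))) {
    jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  } else NULL

  ids <- names(proteins)
  problems <- c(
    if (length(miss <- setdiff(ids, names(cds))))
      paste("CDS missing for:", paste(miss, collapse = ", ")),
    if (length(miss <- setdiff(ids, genes$gene_id)))
      paste("gene models missing for:", paste(miss, collapse = ", ")),
    if (length(miss <- setdiff(ids, names(species))))
      paste("species missing for:", paste(miss, collapse = ", ")),
    if (length(orphan <- setdiff(unique(domains$gene_id), ids)))
      paste("domain rows for unknown genes:", paste(orphan, collapse = ", "))
  )
  if (length(problems)) stop(paste(problems, collapse = "\n"))
  for (id in ids) {
    if (3L * nchar(proteins[[id]]) != nchar(cds[[id]])) {
      stop("CDS/protein length mismatch for ", id)
    }
  }
  list(dir = dir, proteins = proteins, cds = cds, genes = genes,
       domains = domains, species = species, motifs = motifs,
       genome = genome, promoters = promoters, manifest = manifest)
}

# NBS-domain subsequences (first NBS hit per gene).
nbs_domain_seqs <- function(proteins, domains) {
  nbs <- domains[domains$domain == "NBS", , drop = FALSE]
  nbs <- nbs[!duplicated(nbs$gene_id), , drop = FALSE]
  out <- stats::setNames(
    substr(proteins[nbs$gene_id], nbs$start, nbs$end), nbs$gene_id)
  out[nzchar(out)]
}

#' Run the full analysis pipeline
#'
#' @param dataset A directory path or the result of [read_dataset()].
#' @param out_dir Output directory for stage TSVs and the report.
#' @param thresholds Family coverage/identity thresholds.
#' @param replicates Bootstrap replicates for the phylogeny.
#' @param support_threshold Species-specific clades require support
#'   strictly above this percentage.
#' @param seed Seed driving bootstrap resampling and optimizer restarts.
#' @param genome_gene_total Census denominator; defaults to the manifest's
#'   value when the dataset carries one.
#' @param promoter_length Promoter length for extraction when a genome is
#'   present.
#' @param run_selection Fit M0/M7/M8 per family (the slowest stage).
#' @param restarts Random restarts for the site-class optimizations.
#' @return List of class `nbs_pipeline_result` with every stage's outputs.
#' @export
run_pipeline <- function(dataset, out_dir = NULL,
                         thresholds = c(0.70, 0.80, 0.90),
                         replicates = 1000, support_threshold = 50,
                         seed = 1, genome_gene_total = NULL,
                         promoter_length = 1000, run_selection = TRUE,
                         restarts = 2) {
  ds <- if (is.character(dataset)) read_dataset(dataset) else dataset
  if (is.null(genome_gene_total)) {
    genome_gene_total <- ds$manifest$genome_gene_total
    if (is.null(genome_gene_total)) {
      stop("genome_gene_total must be given when the dataset has no manifest")
    }
  }

  # --- classification and census ---------------------------------------
  classes <- classify_genes(ds$domains, names(ds$proteins))
  exon_counts <- stats::setNames(ds$genes$exon_count, ds$genes$gene_id)
  census <- architecture_census(classes, genome_gene_total, exon_counts)
  nbs_ids <- classes$gene_id[classes$nbs]

  # --- families at each threshold --------------------------------------
  pairs <- all_pairs_metrics(ds$proteins[nbs_ids])
  tir_flags <- stats::setNames(classes$code %in% c("TNL", "TN"),
                               classes$gene_id)[nbs_ids]
  family_sets <- lapply(thresholds, function(th) {
    build_families(pairs, nbs_ids, th)
  })
  names(family_sets) <- sprintf("%.0f%%", 100 * thresholds)
  family_censuses <- lapply(family_sets, family_census, tir_flags = tir_flags)

  # --- Ka/Ks per family at the loosest threshold -----------------------
  fs <- family_sets[[1]]
  codon_alns <- lapply(fs$families, function(members) {
    aln <- align_star(ds$proteins[members])
    backtranslate_alignment(aln, ds$cds)
  })
  kaks <- lapply(codon_alns, family_kaks)
  pair_tables <- Filter(Negate(is.null), lapply(kaks, `[[`, "pairs"))
  all_pairs <- if (length(pair_tables)) do.call(rbind, pair_tables) else NULL
  non_tir_pairs <- if (!is.null(all_pairs)) {
    all_pairs[!tir_flags[all_pairs$gene_a], , drop = FALSE]
  } else NULL
  profile <- if (!is.null(non_tir_pairs) && nrow(non_tir_pairs)) {
    ks_profile(non_tir_pairs)
  } else NULL

  # --- phylogeny on NBS domains ----------------------------------------
  tree <- NULL; clade_report <- NULL; rnl_mono <- NULL
  nbs_seqs <- nbs_domain_seqs(ds$proteins[nbs_ids], ds$domains)
  if (length(nbs_seqs) >= 4L) {
    msa <- align_star(nbs_seqs)
    tree <- bootstrap_nj(msa, replicates = replicates, seed = seed)
    clade_report <- species_specific_clades(
      tree, ds$species, support_threshold = support_threshold,
      focal = ds$species[[nbs_ids[1]]])
    rnl_ids <- classes$gene_id[classes$nbs & classes$rnl]
    rnl_ids <- intersect(rnl_ids, tree$tip.label)
    if (length(rnl_ids) >= 2L) {
      rnl_mono <- clade_monophyly(tree, rnl_ids)
    }
  }

  # --- site-model selection tests --------------------------------------
  selection <- NULL
  if (run_selection) {
    big <- which(lengths(fs$families) >= 3L)
    selection <- lapply(big, function(fi) {
      aln <- codon_alns[[fi]]
      start_tree <- selection_start_tree(aln)
      m0 <- fit_site_model(aln, start_tree, "M0", seed = seed)
      m7 <- fit_site_model(aln, start_tree, "M7", seed = seed, m0_fit = m0,
                           restarts = restarts)
      m8 <- fit_site_model(aln, start_tree, "M8", seed = seed, m0_fit = m0,
                           m7_fit = m7, restarts = restarts)
      lrt <- lrt_m7_m8(m7, m8)
      list(family = fi, members = fs$families[[fi]], m0 = m0, m7 = m7,
           m8 = m8, lrt = lrt, sites = positive_sites(m8))
    })
  }

  # --- promoters --------------------------------------------------------
  promoters <- ds$promoters
  if (is.null(promoters) && !is.null(ds$genome)) {
    promoters <- extract_promoters(ds$genome, ds$genes, promoter_length)
  }
  motif_hits <- motif_tab <- NULL
  if (!is.null(promoters)) {
    promoters <- promoters[intersect(names(promoters), nbs_ids)]
    motif_hits <- scan_motifs(promoters, ds$motifs)
    motif_tab <- motif_census(motif_hits, names(promoters),
                              names(ds$motifs))
  }

  result <- structure(list(
    classes = classes, census = census, pairs = pairs,
    family_sets = family_sets, family_censuses = family_censuses,
    codon_alignments = codon_alns, kaks = kaks, kaks_pairs = all_pairs,
    ks_profile = profile, tree = tree, clade_report = clade_report,
    rnl_monophyly = rnl_mono, selection = selection,
    promoters = promoters, motif_hits = motif_hits,
    motif_census = motif_tab,
    settings = list(thresholds = thresholds, replicates = replicates,
                    support_threshold = support_threshold, seed = seed,
                    genome_gene_total = genome_gene_total,
                    alignment = "BLOSUM62, gap open 10, extend 0.5",
                    kaks = "Nei-Gojobori (1986) with Jukes-Cantor correction",
                    distance = "Poisson-corrected protein distance",
                    posterior = "NEB at MLEs")),
    class = "nbs_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Starting tree for the selection stage: NJ on the family's protein
# p-distances, or the unique 3-taxon topology.
selection_start_tree <- function(codon_aln) {
  prot <- apply(codon_aln, 1, function(row) {
    paste(ifelse(row == "---", "-",
                 codon_amino_acids()[row]), collapse = "")
  })
  msa <- do.call(rbind, strsplit(prot, ""))
  rownames(msa) <- rownames(codon_aln)
  D <- protein_distance(msa, "p")
  D[D == 0] <- 1e-4
  diag(D) <- 0
  neighbor_joining(D)
}

#' Formatted summary tables of a pipeline run
#'
#' Assembles the census-style tables (architecture counts and proportions,
#' family statistics at every threshold, clade summary, per-family
#' selection results, motif counts) as character matrices with percentages
#' and means displayed at 2 decimals, half-up.
#'
#' @param result A [run_pipeline()] result.
#' @return Named list of data frames.
#' @export
report_summaries <- function(result) {
  cs <- result$census
  arch <- data.frame(
    quantity = c("NBS-encoding genes", "NBS-LRR genes",
                 sprintf("%s genes", names(cs$counts)),
                 "genome genes", "proportion NBS-encoding (%)",
                 "proportion NBS-LRR (%)"),
    value = c(cs$aggregates[["nbs_encoding"]], cs$aggregates[["nbs_lrr"]],
              unname(cs$counts), cs$genome_gene_total,
              cs$proportions[["nbs_encoding"]],
              cs$proportions[["nbs_lrr"]]))
  fam <- do.call(rbind, lapply(names(result$family_censuses), function(nm) {
    o <- result$family_censuses[[nm]]$overall
    data.frame(threshold = nm, multi = o$multi, single = o$single,
               proportion_multi = o$proportion_multi,
               n_families = o$n_families, mean_members = o$mean_members,
               max_members = o$max_members)
  }))
  clades <- if (!is.null(result$clade_report)) {
    cr <- result$clade_report
    data.frame(n_clades = cr$n_clades, n_genes = cr$n_genes,
               mean_paralogs = cr$mean_paralogs,
               proportion = cr$proportion)
  } else NULL
  sel <- if (!is.null(result$selection)) {
    do.call(rbind, lapply(result$selection, function(s) {
      data.frame(family = s$family, n_members = length(s$members),
                 omega_m0 = round_half_up(s$m0$params$omega, 4),
                 lnL_m0 = round(s$m0$lnL, 4), lnL_m7 = round(s$m7$lnL, 4),
                 lnL_m8 = round(s$m8$lnL, 4),
                 two_delta_lnl = round(s$lrt$two_delta_lnl, 4),
                 significance = s$lrt$significance,
                 n_sites_95 = sum(s$sites$p_positive >= 0.95),
                 n_sites_99 = sum(s$sites$p_positive >= 0.99))
    }))
  } else NULL
  list(architecture = arch, families = fam, clades = clades,
       selection = sel, motifs = result$motif_census)
}

#' Write pipeline outputs to disk
#'
#' Stage TSVs plus a Markdown report; deterministic for a fixed seed.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sums <- report_summaries(result)
  write_tsv(result$classes, file.path(out_dir, "classes.tsv"))
  write_tsv(result$pairs, file.path(out_dir, "alignment_pairs.tsv"))
  for (nm in names(result$family_sets)) {
    fs <- result$family_sets[[nm]]
    tab <- data.frame(
      family_id = rep(seq_along(fs$families), lengths(fs$families)),
      gene_id = unlist(fs$families))
    write_tsv(tab, file.path(out_dir, sprintf(
      "families_%s.tsv", sub("%", "", nm))))
  }
  if (!is.null(result$kaks_pairs)) {
    write_tsv(result$kaks_pairs, file.path(out_dir, "kaks_pairs.tsv"))
  }
  if (!is.null(result$ks_profile)) {
    write_tsv(result$ks_profile, file.path(out_dir, "ks_profile.tsv"))
  }
  if (!is.null(result$tree)) {
    ape::write.tree(result$tree, file.path(out_dir, "nbs_tree.nwk"))
  }
  if (!is.null(sums$selection)) {
    write_tsv(sums$selection, file.path(out_dir, "selection.tsv"))
  }
  if (!is.null(result$motif_census)) {
    write_tsv(result$motif_census, file.path(out_dir, "motif_census.tsv"))
  }

  md <- c("# NBS-encoding gene analysis report", "",
          sprintf("settings: %s",
                  paste(sprintf("%s=%s", names(result$settings),
                                vapply(result$settings, function(x)
                                  paste(format(x), collapse = ","),
                                  character(1))), collapse = "; ")),
          "", "## Architecture census", "",
          .md_table(sums$architecture),
          "", "## Gene families", "",
          .md_table(sums$families))
  if (!is.null(result$ks_profile)) {
    md <- c(md, "", "## Ks profile (non-TIR pairs)", "",
            .md_table(cbind(result$ks_profile,
                            frequency = round(result$ks_profile$frequency, 4))[,
                              c("bin_lo", "bin_hi", "count", "mean_ratio")]))
  }
  if (!is.null(sums$clades)) {
    md <- c(md, "", "## Species-specific duplication clades", "",
            .md_table(sums$clades))
  }
  if (!is.null(result$rnl_monophyly)) {
    md <- c(md, "", sprintf(
      "RPW8-flagged genes monophyletic: %s (support %s)",
      result$rnl_monophyly$is_monophyletic,
      format(result$rnl_monophyly$support)))
  }
  if (!is.null(sums$selection)) {
    md <- c(md, "", "## Site-model selection tests", "",
            .md_table(sums$selection))
  }
  if (!is.null(sums$motifs)) {
    md <- c(md, "", "## Promoter cis-element census", "",
            .md_table(utils::head(sums$motifs, 30)))
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

.md_table <- function(d) {
  d[] <- lapply(d, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE) else as.character(col)
  })
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  rows <- apply(d, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                         " |"))
  c(header, sep, rows)
}

#' @export
print.nbs_pipeline_result <- function(x, ...) {
  cat("nbs_pipeline_result\n")
  print(x$census)
  for (fc in x$family_censuses) print(fc)
  if (!is.null(x$clade_report)) print(x$clade_report)
  invisible(x)
}
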