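# Whole-genome synthesis: two receptor families with independent gene
# trees, reference ("other species") sequences, confounders, clustered
# placement on scaffolds, and a repeat landscape enriched near one family.

#' Default simulation configuration
#'
#' The defaults encode the study conditions: a large T2R-like family (24
#' focal genes, mixed-omega codon evolution with 15% of sites at omega = 5,
#' 60% at 0.1, 25% at 1, kappa = 4, total tree length 8
#' substitutions/codon), a smaller V1R-like family under mild purifying
#' selection, lognormal intergenic gaps with medians 31 kb (T2R) and 16 kb
#' (V1R), a pseudogene fraction of 6/80 for the T2R-like family, class-I
#' repeat background of 0.36 elements/kb (about 7.2 per 20-kb window) and a
#' 2.0-fold class-I enrichment within 20 kb of T2R-like genes only.
#'
#' @param seed master RNG seed; per-stage seeds are derived from it.
#' @return nested configuration list (see vignette for key meanings).
#' @export
default_sim_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    gc = 0.42,
    kappa = 4,
    families = list(
      T2R = list(
        n_genes = 24, n_refs = 6, n_codons = 300, tree_length = 8,
        site_class_mix = list(c(0.60, 0.1), c(0.25, 1), c(0.15, 5)),
        scaffold_lengths = rep(1000000L, 4),
        genes_per_cluster = list(min = 5, max = 7),
        intergenic_gap = list(meanlog = log(31000), sdlog = 0.5),
        pseudogene_fraction = 6 / 80, allele_fraction = 0,
        near_gene_multiplier = 2.0),
      V1R = list(
        n_genes = 12, n_refs = 6, n_codons = 300, tree_length = 8,
        site_class_mix = list(c(0.70, 0.2), c(0.30, 1)),
        scaffold_lengths = rep(400000L, 2),
        genes_per_cluster = list(min = 3, max = 6),
        intergenic_gap = list(meanlog = log(16000), sdlog = 0.5),
        pseudogene_fraction = 0, allele_fraction = 0,
        near_gene_multiplier = 1.0)),
    background_scaffolds = list(n = 12, length = 150000L),
    repeat_background_density = c(
      SINE = 0.15, LINE = 0.15, LTR = 0.06, DNA = 0.08, SmallRNA = 0.01,
      "Satellite/simple/low" = 0.05),
    enrichment_window = 20000)
}

#' Validate a simulation configuration
#' @param config list as returned by [default_sim_config()].
#' @return the config, invisibly; errors on violated invariants.
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_config <- function(config) {
  stopifnot(is.numeric(config$seed), config$gc > 0, config$gc < 1,
            config$kappa > 0)
  for (fam in names(config$families)) {
    f <- config$families[[fam]]
    normalize_mix(f$site_class_mix)
    if (any(f$scaffold_lengths <= 0)) stop("scaffold lengths must be positive")
    if (f$pseudogene_fraction < 0 || f$pseudogene_fraction > 1 ||
        f$allele_fraction < 0 || f$allele_fraction > 1)
      stop("fractions must lie in [0,1]")
    if (f$near_gene_multiplier < 0) stop("multiplier must be >= 0")
  }
  if (any(config$repeat_background_density < 0))
    stop("repeat densities must be >= 0")
  ncod <- vapply(config$families, function(f) f$n_codons, numeric(1))
  if (length(unique(ncod)) != 1)
    stop("sister families must share n_codons (one ancestral gene)")
  invisible(config)
}

#' Simulate a complete synthetic genome with ground truth
#'
#' Runs the full generator: per family, a gene tree over focal + reference
#' genes, codon evolution with site-class omega truth, confounder
#' injection, clustered placement; then background scaffolds and the
#' repeat landscape.  Reference leaves model sequences from other species
#' and are not planted on scaffolds.
#'
#' @param config configuration list (see [default_sim_config()]).
#' @param out_dir optional directory; when given, writes scaffolds (FASTA),
#'   truth loci (GFF3), repeat truth (.out dialect and BED), gene trees
#'   (Newick), site-class truth (TSV) and protein/CDS/reference FASTA.
#' @return list with scaffolds, loci, elements, and per-family truth
#'   (tree, cds, proteins, refs, site classes, confounder meta).
#' @export
simulate_genome <- function(config = default_sim_config(), out_dir = NULL) {
  validate_sim_config(config)
  seed <- config$seed
  fams <- list()
  all_scaffolds <- character()
  all_loci <- list()
  enriched_ids <- character()
  fam_names <- names(config$families)
  specs <- lapply(fam_names, function(fam) {
    f <- config$families[[fam]]
    list(n = f$n_genes + f$n_refs, n_codons = f$n_codons,
         mix = f$site_class_mix, tree_length = f$tree_length,
         prefix = paste0(fam, "_"))
  })
  pair <- simulate_family_pair(specs[[1]], specs[[2]], kappa = config$kappa,
                               seed = seed + 7L,
                               stem_length = config$stem_length %||% 0.8)
  for (fi in seq_along(config$families)) {
    fam <- names(config$families)[fi]
    f <- config$families[[fam]]
    ev <- pair[[paste0(fam, "_")]]
    tree <- ev$tree
    ref_ids <- with_seed(seed + 11L * fi + 2L,
                         sample(names(ev$alignment), f$n_refs))
    focal_ids <- setdiff(names(ev$alignment), ref_ids)
    # focal genes keep the family prefix; references get a species tag
    refs <- ev$alignment[ref_ids]
    names(refs) <- sub(paste0("^", fam, "_"), paste0("Ref_", fam, "_"),
                       names(refs))
    genes <- ev$alignment[focal_ids]
    names(genes) <- sub(paste0("^", fam, "_"), paste0("Lc_", fam, "_"),
                        names(genes))
    conf <- inject_confounders(genes, f$pseudogene_fraction,
                               f$allele_fraction,
                               seed = seed + 11L * fi + 3L)
    names(f$scaffold_lengths) <- sprintf("%s_scf%02d", fam,
                                         seq_along(f$scaffold_lengths))
    planted <- plant_family(conf$genes, f$scaffold_lengths,
                            f$genes_per_cluster, f$intergenic_gap,
                            seed = seed + 11L * fi + 4L, gc = config$gc,
                            meta = conf$meta, family = fam)
    if (f$near_gene_multiplier != 1)
      enriched_ids <- c(enriched_ids, conf$meta$gene_id)
    intact <- conf$meta$gene_id[!conf$meta$is_pseudogene]
    fams[[fam]] <- list(
      tree = tree, site_class = ev$site_class, site_omega = ev$site_omega,
      cds = conf$genes, meta = conf$meta, refs = refs,
      ref_proteins = vapply(refs, translate_cds, character(1)),
      proteins = vapply(conf$genes[intact], translate_cds, character(1)),
      multiplier = f$near_gene_multiplier)
    all_scaffolds <- c(all_scaffolds, planted$scaffolds)
    all_loci[[fam]] <- planted$loci
  }
  bg <- config$background_scaffolds
  bg_seqs <- with_seed(seed + 101L, {
    setNames(vapply(seq_len(bg$n), function(i)
      random_background(bg$length, config$gc), character(1)),
      sprintf("bg_scf%02d", seq_len(bg$n)))
  })
  all_scaffolds <- c(all_scaffolds, bg_seqs)
  loci <- do.call(rbind, all_loci)
  rownames(loci) <- NULL
  # multiplier applies to the enriched family only; others see background
  mult <- max(vapply(fams, function(x) x$multiplier, numeric(1)))
  rep_out <- sprinkle_repeats(all_scaffolds, loci,
                              config$repeat_background_density,
                              near_gene_multiplier = mult,
                              enrichment_window = config$enrichment_window,
                              seed = seed + 202L,
                              enriched_gene_ids = enriched_ids)
  result <- list(scaffolds = rep_out$scaffolds, loci = loci,
                 elements = rep_out$elements, families = fams,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(result$scaffolds, file.path(out_dir, "scaffolds.fasta"),
                type = "DNA")
    write_gff3(loci, file.path(out_dir, "truth_loci.gff3"))
    write_repeatmasker_out(result$elements,
                           file.path(out_dir, "repeats_truth.out"))
    bed <- result$elements
    if (nrow(bed))
      writeLines(paste(bed$scaffold_id, bed$start, bed$end,
                       paste0(bed$class, ":", bed$family), 0, bed$strand,
                       sep = "\t"),
                 file.path(out_dir, "repeats_truth.bed"))
    else writeLines(character(), file.path(out_dir, "repeats_truth.bed"))
    for (fam in names(fams)) {
      x <- fams[[fam]]
      if (!is.null(x$tree$edge) && nrow(x$tree$edge))
        ape::write.tree(x$tree, file.path(out_dir,
                                          paste0("gene_tree_", fam, ".nwk")))
      write_tsv(data.frame(codon_index = seq_along(x$site_class),
                           class = x$site_class, omega = x$site_omega),
                file.path(out_dir, paste0("site_classes_", fam, ".tsv")))
      write_fasta(x$cds, file.path(out_dir, paste0("cds_", fam, ".fasta")),
                  type = "DNA")
      write_fasta(x$proteins,
                  file.path(out_dir, paste0("proteins_", fam, ".fasta")))
      write_fasta(x$ref_proteins,
                  file.path(out_dir, paste0("refs_", fam, ".fasta")))
    }
  }
  result
}
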