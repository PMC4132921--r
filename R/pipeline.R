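# End-to-end orchestration: simulate -> mine -> phylo -> motifs ->
# selection -> repeats, plus scoring of results against simulation truth.

#' Default end-to-end pipeline configuration
#'
#' Every analysis threshold is a named key with the study value as the
#' default: 200-aa minimum homology region, 98% allele identity, 2%
#' minimum distributed divergence, 80% branch support, 45% conservation,
#' 90% gap-column stripping, p < 0.1 selection cutoff, 20-kb density
#' windows, 1-kb profile bins, and cluster minima of 3 (T2R coverage
#' regions) and 2 (V1R).
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    sim = default_sim_config(seed),
    mine = list(word_len = 4, min_region_len = 200, min_score = 100,
                max_edits = 2, allele_identity = 98, min_divergence = 2,
                max_rounds = 20),
    phylo = list(n_reps = 100, min_support = 80),
    motif = list(conservation = 0.45, gap_strip = 0.9),
    selection = list(p_threshold = 0.1, ds_ceiling = 2),
    repeats = list(window = 20000, bin = 1000,
                   cluster_min = c(T2R = 3, V1R = 2), max_gap = 100000,
                   n_reference = 10, flank = 10000))
}

#' Read / write pipeline configuration (YAML)
#' @param path YAML file.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Agreement of a candidate with a family's conserved motifs
#'
#' Aligns the candidate into the family reference set and measures the
#' fraction of family-conserved columns (frequency > threshold) at which
#' the candidate carries the consensus residue.
#'
#' @param candidate protein string.
#' @param refs named protein vector of family references.
#' @param threshold conservation threshold.
#' @return fraction in `[0, 1]` (NA when no column is conserved).
#' @export
motif_agreement <- function(candidate, refs, threshold = 0.45) {
  aln <- progressive_align(c(refs, cand = candidate))
  prof <- conservation_profile(aln[names(aln) != "cand"], threshold)
  cv <- strsplit(aln[["cand"]], "")[[1]]
  cons <- which(prof$conserved)
  if (!length(cons)) return(NA_real_)
  mean(cv[cons] == prof$consensus[cons])
}

#' Run the full synthetic-study pipeline
#'
#' @param config configuration list from [default_pipeline_config()].
#' @param out_dir output directory; stage outputs are written under it
#'   with stable file names.
#' @return RunReport list (stage outputs, metrics, seeds, config hash).
#' @export
run_full_pipeline <- function(config = default_pipeline_config(),
                              out_dir = tempfile("chemomine_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[chemomine] stage %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))

  if (!is.null(config$user_data)) {
    ud <- config$user_data
    if (is.null(ud$genome) || is.null(ud$queries))
      stop("configuration error: user-data mode requires both a genome and seed queries")
    scaffolds <- read_fasta(ud$genome, type = "DNA")
    queries <- read_fasta(ud$queries, type = "AA")
    mc <- config$mine
    closure <- stage("mine", recursive_closure(
      queries, scaffolds, word_len = mc$word_len,
      min_region_len = mc$min_region_len, min_score = mc$min_score,
      max_rounds = mc$max_rounds))
    candidates <- closure$candidates
    cur <- lapply(seq_len(nrow(candidates)), function(i)
      repair_orf(candidates[i, ], scaffolds[[candidates$scaffold_id[i]]],
                 queries = queries, max_edits = mc$max_edits))
    accepted <- cur[!vapply(cur, function(x) x$rejected, logical(1))]
    col <- collapse_alleles(accepted, id_threshold = mc$allele_identity)
    mine_dir <- file.path(out_dir, "mine")
    dir.create(mine_dir, showWarnings = FALSE)
    if (length(col$genes))
      write_fasta(setNames(vapply(col$genes, `[[`, character(1), "protein"),
                           vapply(col$genes, `[[`, character(1), "gene_id")),
                  file.path(mine_dir, "curated_proteins.fasta"))
    return(list(out_dir = out_dir, config_hash = config_hash,
                seed = config$seed, mode = "user_data", closure = closure,
                curated = col))
  }

  sim <- stage("simulate",
               simulate_genome(config$sim, file.path(out_dir, "sim")))

  mine_dir <- file.path(out_dir, "mine")
  dir.create(mine_dir, showWarnings = FALSE)
  mc <- config$mine
  queries <- c(sim$families$T2R$ref_proteins, sim$families$V1R$ref_proteins)
  closure <- stage("mine", recursive_closure(
    queries, sim$scaffolds, word_len = mc$word_len,
    min_region_len = mc$min_region_len, min_score = mc$min_score,
    max_rounds = mc$max_rounds))
  candidates <- closure$candidates
  curated <- stage("curate", {
    cur <- lapply(seq_len(nrow(candidates)), function(i)
      repair_orf(candidates[i, ], sim$scaffolds[[candidates$scaffold_id[i]]],
                 queries = queries, max_edits = mc$max_edits))
    accepted <- cur[!vapply(cur, function(x) x$rejected, logical(1))]
    col <- collapse_alleles(accepted, id_threshold = mc$allele_identity)
    list(genes = col$genes, merged = col$merged,
         rejected = cur[vapply(cur, function(x) x$rejected, logical(1))])
  })
  cur_loci <- do.call(rbind, lapply(curated$genes, function(g)
    data.frame(scaffold_id = g$scaffold_id, start = g$start, end = g$end,
               strand = g$strand, gene_id = g$gene_id,
               is_pseudogene = g$is_pseudogene_candidate,
               n_edits = g$n_edits, stringsAsFactors = FALSE)))
  write_tsv(cur_loci, file.path(mine_dir, "curated_loci.tsv"))
  write_fasta(setNames(vapply(curated$genes, `[[`, character(1), "protein"),
                       cur_loci$gene_id),
              file.path(mine_dir, "curated_proteins.fasta"))

  phylo_dir <- file.path(out_dir, "phylo")
  dir.create(phylo_dir, showWarnings = FALSE)
  refs <- c(sim$families$T2R$ref_proteins, sim$families$V1R$ref_proteins)
  ref_family <- c(rep("T2R", length(sim$families$T2R$ref_proteins)),
                  rep("V1R", length(sim$families$V1R$ref_proteins)))
  cand_prot <- setNames(vapply(curated$genes, `[[`, character(1), "protein"),
                        cur_loci$gene_id)
  assign <- stage("phylo", assign_family(
    cand_prot, refs, ref_family, n_reps = config$phylo$n_reps,
    seed = config$seed + 7L, min_support = config$phylo$min_support))
  write_tsv(assign$assignments, file.path(phylo_dir, "assignments.tsv"))
  ape::write.tree(assign$tree, file.path(phylo_dir, "support_tree.nwk"))
  cur_loci$family <- assign$assignments$family[
    match(cur_loci$gene_id, assign$assignments$gene_id)]

  motif_dir <- file.path(out_dir, "motifs")
  dir.create(motif_dir, showWarnings = FALSE)
  motifs <- stage("motifs", {
    groups_seqs <- c(cand_prot, refs)
    grp <- list(
      Lc_T2R = cur_loci$gene_id[cur_loci$family == "T2R"],
      Lc_V1R = cur_loci$gene_id[cur_loci$family == "V1R"],
      Ref_T2R = names(refs)[ref_family == "T2R"],
      Ref_V1R = names(refs)[ref_family == "V1R"])
    master <- progressive_align(groups_seqs)
    master <- strip_gap_columns(master, config$motif$gap_strip)
    tab <- cross_family_motif_table(
      master, grp,
      group_family = c(Lc_T2R = "T2R", Lc_V1R = "V1R",
                       Ref_T2R = "T2R", Ref_V1R = "V1R"),
      threshold = config$motif$conservation)
    write_tsv(tab, file.path(motif_dir, "motif_table.tsv"))
    cons_t2r <- conservation_profile(master[grp$Lc_T2R],
                                     config$motif$conservation)
    consensus <- paste(ifelse(is.na(cons_t2r$consensus), "A",
                              cons_t2r$consensus), collapse = "")
    tm <- predict_tm_regions(consensus)
    write_tsv(tm, file.path(motif_dir, "tm_intervals.tsv"))
    list(table = tab, tm = tm, master = master, groups = grp)
  })

  sel_dir <- file.path(out_dir, "selection")
  dir.create(sel_dir, showWarnings = FALSE)
  selection <- stage("selection", {
    out <- list()
    for (fam in c("T2R", "V1R")) {
      ids <- cur_loci$gene_id[cur_loci$family == fam &
                                !cur_loci$is_pseudogene]
      if (length(ids) < 3) next
      prots <- cand_prot[ids]
      cds <- setNames(vapply(curated$genes, `[[`, character(1), "cds"),
                      cur_loci$gene_id)[ids]
      paln <- progressive_align(prots)
      caln <- codon_backthread(paln, cds)
      tr <- nj_tree(protein_distance(paln))
      fit <- global_codon_fit(caln, tr)
      anc <- ml_joint_ancestors(fit$tree, caln, kappa = fit$kappa,
                                omega = fit$omega)
      slac <- slac_site_test(fit$tree, caln, anc, kappa = fit$kappa)
      fel <- fel_site_fit(caln, fit)
      cons <- consensus_calls(slac, fel, config$selection$p_threshold)
      dsok <- ds_saturation_check(caln, config$selection$ds_ceiling)
      region <- if (fam == "T2R" && nrow(motifs$tm))
        site_region_map(cons$calls, motifs$tm) else NULL
      calls <- if (is.null(region)) cons$calls else region$calls
      write_tsv(calls, file.path(sel_dir, paste0("site_calls_", fam, ".tsv")))
      out[[fam]] <- list(calls = calls, summary = cons$summary,
                         fit = fit, ds = dsok,
                         region_table = if (is.null(region)) NULL
                                        else region$table)
    }
    jsonlite::write_json(
      lapply(out, function(x) as.list(x$summary)),
      file.path(sel_dir, "selection_summary.json"), auto_unbox = TRUE)
    out
  })

  rep_dir <- file.path(out_dir, "repeats")
  dir.create(rep_dir, showWarnings = FALSE)
  rc <- config$repeats
  repeats <- stage("repeats", {
    elements <- parse_repeatmasker(file.path(out_dir, "sim",
                                             "repeats_truth.out"))
    slen <- vapply(sim$scaffolds, nchar, numeric(1))
    clusters <- detect_clusters(cur_loci, min_genes = 2,
                                max_gap = rc$max_gap)
    refs_sample <- sample_reference_regions(
      slen, n = rc$n_reference, seed = config$seed + 13L, loci = sim$loci,
      exclude_gene_scaffolds = TRUE)
    ref_counts <- reference_window_counts(refs_sample$regions, elements,
                                          window = rc$window)
    out <- list(elements = elements, clusters = clusters,
                reference = refs_sample, ref_counts = ref_counts)
    for (fam in c("T2R", "V1R")) {
      ming <- unname(rc$cluster_min[fam])
      cl <- clusters[clusters$family == fam & clusters$n_genes >= 2, ,
                     drop = FALSE]
      ids <- unlist(strsplit(cl$gene_ids, ","))
      genes <- cur_loci[cur_loci$gene_id %in% ids, , drop = FALSE]
      if (!nrow(genes)) next
      wc <- gene_window_counts(genes, elements, slen, window = rc$window)
      cmp <- compare_densities(wc$count, ref_counts)
      cov_cl <- clusters[clusters$family == fam &
                           clusters$n_genes >= ming, , drop = FALSE]
      coverage <- if (nrow(cov_cl)) {
        t(vapply(seq_len(nrow(cov_cl)), function(i) {
          reg <- list(scaffold_id = cov_cl$scaffold_id[i],
                      start = max(0, cov_cl$start[i] - rc$flank),
                      end = min(slen[[cov_cl$scaffold_id[i]]],
                                cov_cl$end[i] + rc$flank))
          class_coverage(reg, elements)
        }, numeric(7)))
      } else NULL
      profiles <- lapply(unique(cl$scaffold_id), function(scf)
        binned_frequency(slen[[scf]], elements[elements$scaffold_id == scf, ],
                         bin = rc$bin))
      names(profiles) <- unique(cl$scaffold_id)
      write_tsv(wc, file.path(rep_dir, paste0("window_counts_", fam, ".tsv")))
      out[[fam]] <- list(window_counts = wc, comparison = cmp,
                         coverage = coverage, profiles = profiles)
    }
    ref_cov <- t(vapply(seq_len(nrow(refs_sample$regions)), function(i)
      class_coverage(refs_sample$regions[i, ], elements), numeric(7)))
    out$reference_coverage <- ref_cov
    out
  })

  report <- list(out_dir = out_dir, config_hash = config_hash,
                 seed = config$seed, sim = sim, closure = closure,
                 curated = curated, loci = cur_loci, assign = assign,
                 motifs = motifs, selection = selection, repeats = repeats)
  report$metrics <- score_against_truth(report, sim)
  jsonlite::write_json(report$metrics,
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

# >= 50% reciprocal-overlap matching between predicted and truth loci.
match_loci <- function(pred, truth) {
  if (!nrow(pred) || !nrow(truth)) return(integer(nrow(pred)))
  vapply(seq_len(nrow(pred)), function(i) {
    same <- which(truth$scaffold_id == pred$scaffold_id[i] &
                    truth$strand == pred$strand[i])
    for (j in same) {
      ov <- min(truth$end[j], pred$end[i]) - max(truth$start[j], pred$start[i])
      if (ov > 0 && ov >= 0.5 * (truth$end[j] - truth$start[j]) &&
          ov >= 0.5 * (pred$end[i] - pred$start[i])) return(j)
    }
    0L
  }, integer(1))
}

#' Score pipeline results against simulation truth
#'
#' Gene-level matching by >= 50% reciprocal coordinate overlap;
#' family-assignment accuracy on matched genes; site-level confusion of
#' consensus calls against omega-class truth (the curated ORF's start
#' codon offsets truth codon indices by one); repeat-enrichment ratio and
#' p-value.
#'
#' @param report RunReport from [run_full_pipeline()].
#' @param sim simulation truth from [simulate_genome()].
#' @return metrics list.
#' @export
score_against_truth <- function(report, sim) {
  truth <- sim$loci
  pred <- report$loci
  m <- match_loci(pred, truth)
  truth_nonps <- which(!truth$is_pseudogene)
  recall <- if (length(truth_nonps))
    mean(truth_nonps %in% m) else NA_real_
  precision <- if (nrow(pred)) mean(m > 0) else 0
  fam_ok <- sum(m > 0 & pred$family == truth$family[pmax(m, 1)])
  fam_acc <- if (any(m > 0)) fam_ok / sum(m > 0) else NA_real_
  site_conf <- list()
  for (fam in names(report$selection)) {
    sel <- report$selection[[fam]]
    truth_omega <- sim$families[[fam]]$site_omega
    calls <- sel$calls
    idx <- calls$site - 1L  # leading ATG codon added at planting
    ok <- idx >= 1 & idx <= length(truth_omega)
    truth_cls <- ifelse(truth_omega[idx[ok]] > 1, "positive",
                        ifelse(truth_omega[idx[ok]] < 1, "negative",
                               "neutral"))
    site_conf[[fam]] <- table(truth = truth_cls,
                              called = calls$consensus[ok])
  }
  enr <- NULL
  if (!is.null(report$repeats$T2R)) {
    cmp <- report$repeats$T2R$comparison
    enr <- list(ratio = cmp$mean_group / cmp$mean_ref, p = cmp$p)
  }
  list(recall = recall, precision = precision,
       family_accuracy = fam_acc,
       n_candidates = nrow(pred),
       n_truth_genes = nrow(truth),
       site_confusion = lapply(site_conf, function(x)
         as.data.frame.matrix(unclass(x))),
       enrichment = enr)
}

#' Validate a repertoire protein FASTA
#'
#' Reports sequence count and length range, for checking a downloaded
#' repertoire file (e.g. a published supplementary protein set) against
#' its documented size and length bounds.
#'
#' @param path protein FASTA.
#' @param pattern optional regex restricting to a subset of ids.
#' @return list(n, min_len, max_len, lengths).
#' @export
validate_repertoire_fasta <- function(path, pattern = NULL) {
  seqs <- read_fasta(path, type = "AA")
  if (!is.null(pattern)) seqs <- seqs[grepl(pattern, names(seqs))]
  lens <- nchar(seqs)
  list(n = length(seqs), min_len = if (length(lens)) min(lens) else NA,
       max_len = if (length(lens)) max(lens) else NA, lengths = lens)
}
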