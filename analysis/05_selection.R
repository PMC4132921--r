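#!/usr/bin/env Rscript
# Stage 5: per-codon selection inference.
#
# For each family: codon alignment (back-threading the curated CDS
# through the protein alignment), NJ tree, global MG94xHKY85 fit, joint
# ML ancestors, SLAC counting test and FEL likelihood-ratio test, and
# the two-method consensus at p < 0.1; the dS-saturation guard and the
# TM/loop site map are reported alongside.

library(chemomine)

cand <- read_fasta("results/mine/curated_proteins.fasta")
cds <- read_fasta("results/mine/curated_cds.fasta", type = "DNA")
loci <- chemomine:::read_tsv("results/mine/curated_loci.tsv")
asg <- chemomine:::read_tsv("results/phylo/assignments.tsv")
tm <- chemomine:::read_tsv("results/motifs/tm_intervals.tsv")
dir.create("results/selection", showWarnings = FALSE, recursive = TRUE)

summary_out <- list()
for (fam in c("T2R", "V1R")) {
  ids <- asg$gene_id[asg$family == fam]
  ids <- setdiff(ids, loci$gene_id[loci$is_pseudogene])
  if (length(ids) < 3) next
  paln <- progressive_align(cand[ids])
  caln <- codon_backthread(paln, cds[ids])
  tr <- nj_tree(protein_distance(paln))
  fit <- global_codon_fit(caln, tr)
  anc <- ml_joint_ancestors(fit$tree, caln, kappa = fit$kappa, omega = 1)
  slac <- slac_site_test(fit$tree, caln, anc, kappa = fit$kappa)
  fel <- fel_site_fit(caln, fit)
  cons <- consensus_calls(slac, fel)
  ds <- ds_saturation_check(caln)
  calls <- cons$calls
  if (fam == "T2R" && nrow(tm)) calls <- site_region_map(calls, tm)$calls
  chemomine:::write_tsv(calls,
                        sprintf("results/selection/site_calls_%s.tsv", fam))
  cat(sprintf("%s: kappa=%.2f mean omega=%.2f; %d positive, %d negative sites; max dS %.2f (%s)\n",
              fam, fit$kappa, fit$omega,
              cons$summary["positive"], cons$summary["negative"],
              ds$max_dS, if (ds$pass) "below ceiling" else "saturated"))
  summary_out[[fam]] <- as.list(cons$summary)
}
jsonlite::write_json(summary_out, "results/selection/summary.json",
                     auto_unbox = TRUE)
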