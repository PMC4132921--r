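#!/usr/bin/env Rscript
# Stage 6: transposable-element landscape at three scales.
#
# Class-I (SINE/LINE/LTR) accounting around gene clusters: percent
# coverage of cluster regions (10-kb flanks), 20-kb gene-centered window
# densities with Student's t-test against sampled reference scaffolds,
# and 1-kb binned profiles per cluster contig; intergenic distances and
# orientation patterns are tabulated as well.

library(chemomine)

seed <- as.integer(Sys.getenv("CHEMOMINE_SEED", "1"))
scaffolds <- read_fasta("results/sim/scaffolds.fasta", type = "DNA")
slen <- vapply(scaffolds, nchar, numeric(1))
elements <- parse_repeatmasker("results/sim/repeats_truth.out")
loci <- chemomine:::read_tsv("results/mine/curated_loci.tsv")
asg <- chemomine:::read_tsv("results/phylo/assignments.tsv")
loci$family <- asg$family[match(loci$gene_id, asg$gene_id)]
dir.create("results/repeats", showWarnings = FALSE, recursive = TRUE)

clusters <- detect_clusters(loci)
refs <- sample_reference_regions(slen, n = 10, seed = seed + 13,
                                 loci = loci,
                                 exclude_gene_scaffolds = TRUE)
cat(sprintf("reference: %d scaffolds, %.1f Mb\n", nrow(refs$regions),
            refs$total_bp / 1e6))
ref_counts <- chemomine:::reference_window_counts(refs$regions, elements)

for (fam in c("T2R", "V1R")) {
  cl <- clusters[clusters$family == fam, ]
  if (!nrow(cl)) next
  ids <- unlist(strsplit(cl$gene_ids, ","))
  genes <- loci[loci$gene_id %in% ids, ]
  wc <- gene_window_counts(genes, elements, slen)
  cmp <- compare_densities(wc$count, ref_counts)
  cat(sprintf("%s: %.1f +/- %.1f vs %.1f +/- %.1f elements/20 kb (t=%.2f, p=%.2g)\n",
              fam, cmp$mean_group, cmp$sem_group, cmp$mean_ref,
              cmp$sem_ref, cmp$t, cmp$p))
  chemomine:::write_tsv(wc,
                        sprintf("results/repeats/window_counts_%s.tsv", fam))
  profs <- lapply(unique(cl$scaffold_id), function(scf)
    cbind(scaffold_id = scf,
          binned_frequency(slen[[scf]],
                           elements[elements$scaffold_id == scf, ])))
  chemomine:::write_tsv(do.call(rbind, profs),
                        sprintf("results/repeats/profiles_1kb_%s.tsv", fam))
}

med <- intergenic_median(loci, clusters)
cat("intergenic medians (kb):",
    paste(names(med), round(med / 1000, 1), collapse = ", "), "\n")

# orientation of adjacent within-cluster pairs
ori <- list()
for (i in seq_len(nrow(clusters))) {
  ids <- strsplit(clusters$gene_ids[i], ",")[[1]]
  g <- loci[match(ids, loci$gene_id), ]
  g <- g[order(g$start), ]
  if (nrow(g) < 2) next
  for (j in seq_len(nrow(g) - 1))
    ori[[length(ori) + 1]] <- data.frame(
      family = clusters$family[i], left = g$gene_id[j],
      right = g$gene_id[j + 1],
      pattern = orientation_pattern(g[j, ], g[j + 1, ]))
}
ori <- do.call(rbind, ori)
chemomine:::write_tsv(ori, "results/repeats/orientation.tsv")
print(table(ori$family, ori$pattern))
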