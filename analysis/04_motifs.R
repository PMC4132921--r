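#!/usr/bin/env Rscript
# Stage 4: motif conservation across families.
#
# Builds a master alignment of candidates and references, strips
# gap-dominated columns (> 90% gaps), computes per-group conservation at
# the 45% threshold, classifies columns (shared / differential /
# family- / group-specific), and annotates transmembrane regions from
# Kyte-Doolittle hydropathy on the T2R consensus.

library(chemomine)

cand <- read_fasta("results/mine/curated_proteins.fasta")
asg <- chemomine:::read_tsv("results/phylo/assignments.tsv")
refs_t <- read_fasta("results/sim/refs_T2R.fasta")
refs_v <- read_fasta("results/sim/refs_V1R.fasta")

groups <- list(
  Lc_T2R = asg$gene_id[asg$family == "T2R"],
  Lc_V1R = asg$gene_id[asg$family == "V1R"],
  Ref_T2R = names(refs_t),
  Ref_V1R = names(refs_v))
master <- progressive_align(c(cand, refs_t, refs_v))
master <- strip_gap_columns(master)
tab <- cross_family_motif_table(
  master, groups,
  group_family = c(Lc_T2R = "T2R", Lc_V1R = "V1R",
                   Ref_T2R = "T2R", Ref_V1R = "V1R"))
dir.create("results/motifs", showWarnings = FALSE, recursive = TRUE)
chemomine:::write_tsv(tab, "results/motifs/motif_table.tsv")
print(attr(tab, "class_counts"))

prof <- conservation_profile(master[groups$Lc_T2R])
consensus <- paste(ifelse(is.na(prof$consensus), "A", prof$consensus),
                   collapse = "")
tm <- predict_tm_regions(consensus)
chemomine:::write_tsv(tm, "results/motifs/tm_intervals.tsv")
cat(sprintf("%d transmembrane intervals on the T2R consensus\n", nrow(tm)))

# per-column logo matrix (letter heights) for downstream plotting
m <- do.call(rbind, strsplit(master[groups$Lc_T2R], ""))
ic <- vapply(seq_len(ncol(m)), function(j) logo_information(m[, j])$ic,
             numeric(1))
chemomine:::write_tsv(data.frame(column = seq_along(ic), ic = ic),
                      "results/motifs/logo_ic.tsv")
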