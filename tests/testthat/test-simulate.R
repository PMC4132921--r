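# Synthetic-genome generator: tree shape, codon evolution truth,
# planting round trips, repeat landscape, confounders.

test_that("simulate_gene_tree produces binary trees and is deterministic", {
  t1 <- simulate_gene_tree(1, seed = 1)
  expect_equal(length(t1$tip.label), 1L)
  expect_equal(t1$Nnode, 0L)

  t5 <- simulate_gene_tree(5, seed = 2)
  expect_equal(length(t5$tip.label), 5L)
  expect_equal(t5$Nnode, 4L)  # binary-tree identity: n - 1 internal nodes
  expect_true(all(t5$edge.length > 0))

  expect_identical(ape::write.tree(simulate_gene_tree(7, seed = 9)),
                   ape::write.tree(simulate_gene_tree(7, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_gene_tree(7, seed = 9)),
                         ape::write.tree(simulate_gene_tree(7, seed = 10))))
  expect_error(simulate_gene_tree(0, seed = 1), "invalid parameter")
})

test_that("evolve_codons respects site-class constraints", {
  expect_error(evolve_codons(simulate_gene_tree(3, 1), 10, list(), 4, 1),
               "invalid parameter")

  tr <- simulate_gene_tree(6, seed = 3, total_length = 3)
  ev <- evolve_codons(tr, 120, list(c(0.5, 0), c(0.5, 5)), kappa = 4,
                      seed = 5)
  expect_equal(unique(nchar(ev$alignment)), 360L)
  # omega = 0 forbids nonsynonymous changes: identical amino acids at
  # those sites across all leaves
  prots <- vapply(ev$alignment, chemomine:::translate_cds, character(1))
  pm <- do.call(rbind, strsplit(prots, ""))
  w0 <- which(ev$site_omega == 0)
  expect_true(all(apply(pm[, w0, drop = FALSE], 2,
                        function(x) length(unique(x)) == 1)))
  expect_false(all(apply(pm[, ev$site_omega == 5, drop = FALSE], 2,
                         function(x) length(unique(x)) == 1)))

  # zero branch lengths: all leaves identical to each other
  tr0 <- tr
  tr0$edge.length[] <- 0
  ev0 <- evolve_codons(tr0, 50, list(c(1, 1)), kappa = 4, seed = 2)
  expect_equal(length(unique(ev0$alignment)), 1L)

  # no stop codons anywhere
  tb <- chemomine:::codon_tables()
  for (s in ev$alignment)
    expect_false(any(chemomine:::split_codons(s) %in% tb$stop_codons))
})

test_that("counting-oracle dN/dS recovers the omega ordering of site classes", {
  tr <- simulate_gene_tree(12, seed = 21, total_length = 5)
  ev <- evolve_codons(tr, 200, list(c(0.5, 0.1), c(0.35, 1), c(0.15, 5)),
                      kappa = 4, seed = 22)
  sub_aln <- function(omega) {
    idx <- which(ev$site_omega == omega)
    vapply(ev$alignment, function(s) {
      cods <- chemomine:::split_codons(s)
      paste(cods[idx], collapse = "")
    }, character(1))
  }
  mean_ratio <- function(aln) {
    ids <- names(aln)
    r <- c()
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      x <- ng_pair_dnds(aln[[i]], aln[[j]])
      if (is.finite(x[["dS"]]) && x[["dS"]] > 0)
        r <- c(r, x[["dN"]] / x[["dS"]])
    }
    mean(r)
  }
  r5 <- mean_ratio(sub_aln(5))
  r01 <- mean_ratio(sub_aln(0.1))
  expect_gt(r5, r01)
  expect_gt(r5, 1)
  expect_lt(r01, 1)
})

test_that("plant_family round-trips proteins and respects geometry", {
  g <- small_genome()
  for (i in seq_len(nrow(g$loci))) {
    l <- g$loci[i, ]
    seg <- substr(g$scaffolds[[l$scaffold_id]], l$start + 1, l$end)
    if (l$strand == "-") seg <- chemomine:::revcomp(seg)
    prot <- chemomine:::translate_cds(seg)
    expect_identical(sub("\\*$", "", prot), g$family$proteins[[l$gene_id]])
  }

  # genes_per_cluster = 1 with enough scaffolds: one gene per scaffold
  fam <- small_family()
  pl1 <- plant_family(fam$genes[1:3],
                      scaffold_lengths = c(a = 30000, b = 30000, c = 30000),
                      genes_per_cluster = list(min = 1, max = 1),
                      intergenic_gap = list(meanlog = log(5000), sdlog = 0.3),
                      seed = 4)
  expect_equal(length(unique(pl1$loci$scaffold_id)), 3L)

  expect_error(plant_family(fam$genes, scaffold_lengths = c(tiny = 2000),
                            genes_per_cluster = list(min = 6, max = 6),
                            intergenic_gap = list(meanlog = log(5000),
                                                  sdlog = 0.3), seed = 1),
               "tiny")
})

test_that("planted intergenic gaps reproduce the configured 31-kb median", {
  fam <- small_family(n = 40, codons = 150, seed = 31, total_length = 2)
  pl <- plant_family(fam$genes,
                     scaffold_lengths = setNames(rep(500000, 6),
                                                 paste0("s", 1:6)),
                     genes_per_cluster = list(min = 6, max = 8),
                     intergenic_gap = list(meanlog = log(31000), sdlog = 0.5),
                     seed = 33)
  cl <- detect_clusters(pl$loci, min_genes = 2, max_gap = 1e9)
  med <- intergenic_median(pl$loci, cl)
  expect_lt(abs(med[["T2R"]] - 31000) / 31000, 0.2)
})

test_that("sprinkle_repeats matches configured densities and enrichment", {
  # all densities zero: empty annotation
  g <- small_genome()
  r0 <- sprinkle_repeats(g$scaffolds, g$loci,
                         background_density = c(SINE = 0, LINE = 0, LTR = 0,
                                                DNA = 0, SmallRNA = 0,
                                                "Satellite/simple/low" = 0),
                         seed = 1)
  expect_equal(nrow(r0$elements), 0L)

  # enrichment ratio via the window-count oracle, 50+ genes
  fam <- small_family(n = 54, codons = 150, seed = 41, total_length = 2)
  pl <- plant_family(fam$genes,
                     scaffold_lengths = setNames(rep(600000, 6),
                                                 paste0("s", 1:6)),
                     genes_per_cluster = list(min = 9, max = 9),
                     intergenic_gap = list(meanlog = log(31000), sdlog = 0.4),
                     seed = 42)
  bg <- setNames(vapply(1:6, function(i)
    chemomine:::with_seed(500 + i,
                          chemomine:::random_background(200000)),
    character(1)), paste0("bg", 1:6))
  for (mult in c(1, 2)) {
    rs <- sprinkle_repeats(c(pl$scaffolds, bg), pl$loci,
                           near_gene_multiplier = mult,
                           enrichment_window = 20000, seed = 77,
                           enriched_gene_ids = pl$loci$gene_id)
    slen <- vapply(rs$scaffolds, nchar, numeric(1))
    wc <- gene_window_counts(pl$loci, rs$elements, slen)
    ref <- chemomine:::reference_window_counts(
      data.frame(scaffold_id = names(bg), start = 0, end = 200000),
      rs$elements)
    ratio <- mean(wc$count) / mean(ref)
    tol <- if (mult == 1) 0.2 else 0.3
    expect_lt(abs(ratio - mult), mult * tol)
  }
})

test_that("inject_confounders plants detectable pseudogenes and alleles", {
  fam <- small_family()
  c0 <- inject_confounders(fam$genes, 0, 0, seed = 1)
  expect_identical(c0$genes, fam$genes)

  cp <- inject_confounders(fam$genes, pseudogene_fraction = 0.5,
                           allele_fraction = 0, seed = 3)
  ps <- cp$meta$gene_id[cp$meta$is_pseudogene]
  expect_gt(length(ps), 0)
  for (g in ps) {
    prot <- chemomine:::translate_cds(cp$genes[[g]])
    # at least one premature stop in the annotated frame
    expect_true(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }

  ca <- inject_confounders(fam$genes, 0, allele_fraction = 0.4, seed = 5)
  al <- ca$meta[!is.na(ca$meta$is_allele_of), ]
  expect_gt(nrow(al), 0)
  for (i in seq_len(nrow(al))) {
    pair <- c(a = chemomine:::translate_cds(ca$genes[[al$gene_id[i]]]),
              b = chemomine:::translate_cds(ca$genes[[al$is_allele_of[i]]]))
    expect_gt(identity_matrix(pair)$identity[1, 2], 98)
  }
})

test_that("simulate_genome writes consistent truth artifacts", {
  cfg <- default_sim_config(5)
  cfg$families$T2R$n_genes <- 6
  cfg$families$T2R$n_refs <- 3
  cfg$families$T2R$scaffold_lengths <- rep(300000L, 2)
  cfg$families$T2R$genes_per_cluster <- list(min = 3, max = 3)
  cfg$families$V1R$n_genes <- 4
  cfg$families$V1R$n_refs <- 3
  cfg$families$V1R$scaffold_lengths <- 250000L
  cfg$families$V1R$genes_per_cluster <- list(min = 4, max = 4)
  cfg$background_scaffolds$n <- 2
  out <- tempfile("sim_")
  sim <- simulate_genome(cfg, out)
  expect_true(file.exists(file.path(out, "scaffolds.fasta")))
  gff <- read_gff3(file.path(out, "truth_loci.gff3"))
  expect_equal(nrow(gff), nrow(sim$loci))
  expect_setequal(gff$gene_id, sim$loci$gene_id)
  # loci never overlap on a scaffold
  for (scf in unique(sim$loci$scaffold_id)) {
    l <- sim$loci[sim$loci$scaffold_id == scf, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1) expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
  }
  # .out round trip preserves element classes
  parsed <- parse_repeatmasker(file.path(out, "repeats_truth.out"))
  expect_equal(nrow(parsed), nrow(sim$elements))
  expect_equal(sort(unique(parsed$class)), sort(unique(sim$elements$class)))
  unlink(out, recursive = TRUE)
})
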