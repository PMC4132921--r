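# Shared fixture builders.  Everything is generated in code under fixed
# seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

# A small evolved family: tree, CDS alignment, proteins.
small_family <- function(n = 6, codons = 250, seed = 11, total_length = 2,
                         mix = list(c(1, 0.5))) {
  key <- paste("fam", n, codons, seed, total_length, sep = "_")
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  tr <- simulate_gene_tree(n, seed = seed, total_length = total_length)
  ev <- evolve_codons(tr, codons, mix, kappa = 4, seed = seed + 1)
  genes <- setNames(paste0("ATG", ev$alignment),
                    paste0("G", seq_len(n)))
  prot <- vapply(genes, chemomine:::translate_cds, character(1))
  out <- list(tree = tr, ev = ev, genes = genes, proteins = prot)
  .fx[[key]] <- out
  out
}

# A small planted genome with two 3-gene clusters.
small_genome <- function(seed = 7) {
  key <- paste0("genome_", seed)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  fam <- small_family()
  pl <- plant_family(setNames(paste0(fam$genes, "TAA"), names(fam$genes)),
                     scaffold_lengths = c(s1 = 60000, s2 = 60000),
                     genes_per_cluster = list(min = 3, max = 3),
                     intergenic_gap = list(meanlog = log(5000), sdlog = 0.3),
                     seed = seed)
  out <- list(family = fam, scaffolds = pl$scaffolds, loci = pl$loci)
  .fx[[key]] <- out
  out
}

# Random protein string (uniform residues).
random_protein <- function(n, seed) {
  with_seed <- chemomine:::with_seed
  with_seed(seed, paste(sample(chemomine:::AA20, n, replace = TRUE),
                        collapse = ""))
}

# Mutate a fraction of residues of a protein (never to the same residue).
mutate_protein <- function(prot, rate, seed) {
  chemomine:::with_seed(seed, {
    v <- strsplit(prot, "")[[1]]
    k <- round(rate * length(v))
    at <- sample(seq_along(v), k)
    for (i in at) v[i] <- sample(setdiff(chemomine:::AA20, v[i]), 1)
    paste(v, collapse = "")
  })
}

# The full-scale synthetic genome shared by acceptance tests (built once).
acceptance_sim <- function(seed = 101) {
  if (!is.null(.fx$acc_sim)) return(.fx$acc_sim)
  .fx$acc_sim <- simulate_genome(default_sim_config(seed))
  .fx$acc_sim
}
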