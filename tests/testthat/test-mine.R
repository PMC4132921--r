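# Translated homology search, recursive closure, ORF curation, allele
# collapsing and the distributed-divergence rule.

test_that("translate_six_frames follows the frame conventions", {
  fr <- translate_six_frames("ATGAAA")
  expect_identical(fr[["+1"]], "MK")
  s <- "ATGAAACCCGGGTTTACG"
  fr <- translate_six_frames(s)
  rc <- chemomine:::revcomp(s)
  expect_identical(fr[["-1"]], translate_six_frames(rc)[["+1"]])
  n <- nchar(s)
  for (f in 0:2)
    expect_equal(nchar(fr[[paste0("+", f + 1)]]), (n - f) %/% 3)
  expect_identical(translate_six_frames("ATGNNNAAA")[["+1"]], "MXK")
  expect_error(translate_six_frames("ATGR"), "alphabet")
})

test_that("seeded search recovers planted genes and filters short regions", {
  g <- small_genome()
  prot <- g$family$proteins
  hits <- seeded_translated_search(prot[1], g$scaffolds)
  # every planted gene found with exact strand and near-exact boundaries
  expect_equal(nrow(hits), nrow(g$loci))
  for (i in seq_len(nrow(g$loci))) {
    l <- g$loci[i, ]
    h <- hits[hits$scaffold_id == l$scaffold_id &
                abs(hits$start - l$start) <= 30, ]
    expect_equal(nrow(h), 1L)
    expect_identical(h$strand, l$strand)
    expect_lte(abs(h$end - l$end), 30)
  }

  # a 150-residue fragment of a query is below the 200-aa region filter
  frag <- substr(prot[[1]], 1, 150)
  frag_dna <- g$family$genes[[1]]
  scf_frag <- c(f1 = paste0(
    chemomine:::random_background(5000, 0.42),
    substr(frag_dna, 1, 450),
    chemomine:::random_background(5000, 0.42)))
  expect_equal(nrow(seeded_translated_search(prot[1], scf_frag)), 0L)
  expect_false(nrow(seeded_translated_search(prot[1], scf_frag,
                                             min_region_len = 100)) == 0)

  # pure background scaffold: zero hits (precision invariant)
  bg <- c(b1 = chemomine:::with_seed(99,
                                     chemomine:::random_background(80000)))
  expect_equal(nrow(seeded_translated_search(prot, bg)), 0L)

  expect_error(seeded_translated_search(character(), bg), "non-empty")
  expect_equal(nrow(seeded_translated_search(prot[1],
                                             character())), 0L)
})

test_that("recursive closure reaches chained homologs and is stable", {
  g <- small_genome()
  prot <- g$family$proteins
  cl <- recursive_closure(prot, g$scaffolds)
  expect_equal(nrow(cl$candidates), nrow(g$loci))
  expect_equal(cl$rounds, 2L)  # fixed point after one productive round

  # chain A -> B -> C, mutated stepwise so that pairwise alignment
  # scores straddle the score threshold: A finds B but not C, and C
  # becomes reachable only once B has joined the query set.
  A <- random_protein(250, seed = 61)
  B <- mutate_protein(A, 0.5, seed = 62)
  C <- mutate_protein(B, 0.5, seed = 63)
  s_ab <- align_pair(A, B, type = "local")$score
  s_bc <- align_pair(B, C, type = "local")$score
  s_ac <- align_pair(A, C, type = "local")$score
  expect_gt(min(s_ab, s_bc), s_ac)  # the construction is a true chain
  thr <- ceiling((s_ac + min(s_ab, s_bc)) / 2)
  revtrans <- function(p) {
    tb <- chemomine:::codon_tables()
    paste(vapply(strsplit(p, "")[[1]], function(a) {
      cands <- tb$codons[tb$aa == a]
      cands[1]
    }, character(1)), collapse = "")
  }
  scf <- c(chain = paste0(
    chemomine:::with_seed(64, chemomine:::random_background(3000)),
    "ATG", revtrans(B), "TAA",
    chemomine:::with_seed(65, chemomine:::random_background(3000)),
    "ATG", revtrans(C), "TAA",
    chemomine:::with_seed(66, chemomine:::random_background(3000))))
  round1 <- seeded_translated_search(c(A = A), scf, min_score = thr)
  expect_equal(nrow(round1), 1L)  # only B is reachable from A
  cl2 <- recursive_closure(c(A = A), scf, min_score = thr)
  expect_equal(nrow(cl2$candidates), 2L)  # C joined via B

  # query order does not change the closure
  cl3 <- recursive_closure(rev(prot), g$scaffolds)
  key <- function(x) sort(paste(x$scaffold_id, x$start, x$end, x$strand))
  expect_identical(key(cl$candidates), key(cl3$candidates))
})

test_that("repair_orf applies the two-edit curation boundary", {
  g <- small_genome()
  prot <- g$family$proteins
  hits <- seeded_translated_search(prot, g$scaffolds)
  cur <- repair_orf(hits[1, ], g$scaffolds[[hits$scaffold_id[1]]])
  expect_false(cur$rejected)
  expect_equal(cur$n_edits, 0L)
  expect_false(cur$is_pseudogene_candidate)
  truth <- g$loci[g$loci$scaffold_id == cur$scaffold_id &
                    abs(g$loci$start - cur$start) <= 3, ]
  expect_identical(cur$protein, g$family$proteins[[truth$gene_id[1]]])

  # plant copies with 2 and 3 internal stops
  tb <- chemomine:::codon_tables()
  make_stopped <- function(nstop) {
    cds <- g$family$genes[[1]]
    for (k in seq_len(nstop))
      substr(cds, (40 + 30 * k) * 3 + 1, (40 + 30 * k) * 3 + 3) <- "TAA"
    c(ps = paste0(chemomine:::with_seed(70 + nstop,
                                        chemomine:::random_background(4000)),
                  cds, "TAA",
                  chemomine:::with_seed(80 + nstop,
                                        chemomine:::random_background(4000))))
  }
  scf2 <- make_stopped(2)
  h2 <- seeded_translated_search(prot[1], scf2)
  expect_equal(nrow(h2), 1L)
  r2 <- repair_orf(h2[1, ], scf2[[1]])
  expect_false(r2$rejected)
  expect_equal(r2$n_edits, 2L)
  expect_true(r2$is_pseudogene_candidate)
  expect_equal(nchar(r2$cds) %% 3, 0L)

  scf3 <- make_stopped(3)
  h3 <- seeded_translated_search(prot[1], scf3)
  r3 <- repair_orf(h3[1, ], scf3[[1]])
  expect_true(r3$rejected)  # > 2 disruptions is the acceptance boundary
})

test_that("collapse_alleles applies the adjacency and threshold rules", {
  p <- random_protein(300, seed = 90)
  mk <- function(id, scf, start, prot, edits = 0) {
    list(gene_id = id, scaffold_id = scf, start = start,
         end = start + 3 * nchar(prot), strand = "+", cds = "",
         protein = prot, n_edits = edits,
         is_pseudogene_candidate = edits > 0)
  }
  p99 <- mutate_protein(p, 0.01, seed = 91)   # > 98% identical
  p97 <- mutate_protein(p, 0.03, seed = 92)   # below the threshold

  # identical sequence at overlapping coordinates: one gene
  r <- collapse_alleles(list(mk("a", "s1", 100, p), mk("b", "s1", 400, p)))
  expect_equal(length(r$genes), 1L)

  # 99%-identical pair adjacent in one cluster: both retained
  r <- collapse_alleles(list(mk("a", "s1", 1000, p),
                             mk("b", "s1", 30000, p99)))
  expect_equal(length(r$genes), 2L)

  # 99%-identical pair on different scaffolds without anchors: merged
  r <- collapse_alleles(list(mk("a", "s1", 1000, p),
                             mk("b", "s2", 1000, p99)))
  expect_equal(length(r$genes), 1L)

  # anchored on both scaffolds: unambiguously different location, kept
  q <- random_protein(300, seed = 93)
  q2 <- mutate_protein(q, 0.3, seed = 94)
  r <- collapse_alleles(list(mk("a", "s1", 1000, p),
                             mk("a2", "s1", 40000, q),
                             mk("b", "s2", 1000, p99),
                             mk("b2", "s2", 40000, q2)))
  expect_equal(length(r$genes), 4L)

  # 97%-identical pair anywhere: two genes
  r <- collapse_alleles(list(mk("a", "s1", 1000, p),
                             mk("b", "s2", 1000, p97)))
  expect_equal(length(r$genes), 2L)
})

test_that("divergence must be distributed across alignment quarters", {
  base <- strsplit(random_protein(80, seed = 95), "")[[1]]
  clustered <- base
  clustered[2:7] <- vapply(clustered[2:7], function(a)
    setdiff(chemomine:::AA20, a)[1], character(1))
  expect_false(divergence_distribution_check(paste(base, collapse = ""),
                                             paste(clustered, collapse = "")))
  spread <- base
  for (i in c(5, 25, 75)) spread[i] <- setdiff(chemomine:::AA20, spread[i])[1]
  expect_true(divergence_distribution_check(paste(base, collapse = ""),
                                            paste(spread, collapse = "")))
  expect_false(divergence_distribution_check(paste(base, collapse = ""),
                                             paste(base, collapse = "")))
  expect_error(divergence_distribution_check("MKVL", "MKVL"), "invalid")
})
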