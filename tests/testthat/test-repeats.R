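# Repeat parsing, scanning, coverage, window densities, binning,
# clusters, distances, orientation, intron checks.

test_that("parse_repeatmasker maps classes and handles edge cases", {
  f <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query  position in query  matching repeat",
    "score   div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
    "",
    " 1000 10.0 0.5 0.5 scfA 101 250 (0) + tRNA-Core SINE/tRNA-Core 1 150 (0) 1",
    "  900 12.0 0.5 0.5 scfA 501 700 (0) C L2 LINE/L2 1 200 (0) 2",
    "  800  8.0 0.5 0.5 scfB 11 90 (0) + lowc Low_complexity 1 80 (0) 3"),
    f)
  el <- parse_repeatmasker(f)
  expect_equal(nrow(el), 3L)
  expect_identical(el$class, c("SINE", "LINE", "Satellite/simple/low"))
  expect_equal(el$start[1], 100L)  # 1-based inclusive -> 0-based half-open
  expect_equal(el$end[1], 250L)
  expect_identical(el$strand, c("+", "-", "+"))

  writeLines(readLines(f)[1:3], f)
  expect_equal(nrow(parse_repeatmasker(f)), 0L)

  writeLines(c(readLines(f), "garbage line without coordinates"), f)
  expect_error(parse_repeatmasker(f), "line 4")
})

test_that("naive_repeat_scan finds motifs on both strands and truth", {
  lib <- repeat_motif_library()
  motif <- lib$seq[lib$family == "LINE_A"]
  bg <- chemomine:::with_seed(3, chemomine:::random_background(20000))
  scf <- c(x = paste0(substr(bg, 1, 5000), motif,
                      substr(bg, 5001, 12000),
                      chemomine:::revcomp(motif),
                      substr(bg, 12001, 20000)))
  el <- naive_repeat_scan(scf)
  li <- el[el$family == "LINE_A" | el$class == "LINE", ]
  expect_equal(nrow(li), 2L)
  expect_equal(li$start[1], 5000)
  expect_equal(li$end[1], 5000 + nchar(motif))
  expect_error(naive_repeat_scan(scf, library = lib[0, ]), "empty")

  # recovery of sprinkled truth
  g <- small_genome()
  rs <- sprinkle_repeats(g$scaffolds, g$loci, seed = 5,
                         near_gene_multiplier = 1)
  found <- naive_repeat_scan(rs$scaffolds)
  truth <- rs$elements
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    f <- found[found$scaffold_id == truth$scaffold_id[i] &
                 found$class == truth$class[i], ]
    any(pmin(f$end, truth$end[i]) - pmax(f$start, truth$start[i]) >
          0.9 * (truth$end[i] - truth$start[i]))
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("class_coverage merges and clips correctly", {
  reg <- list(scaffold_id = "s", start = 0, end = 1000)
  el <- data.frame(scaffold_id = "s", start = 100, end = 200, strand = "+",
                   family = "SINE_A", class = "SINE")
  expect_equal(class_coverage(reg, el)[["SINE"]], 10)
  two <- data.frame(scaffold_id = "s", start = c(0, 50), end = c(100, 150),
                    strand = "+", family = "LINE_A", class = "LINE")
  expect_equal(class_coverage(reg, two)[["LINE"]], 15)  # 150 bp once
  expect_true(all(class_coverage(reg, el[0, ]) == 0))
  expect_error(class_coverage(list(scaffold_id = "s", start = 5, end = 5),
                              el), "positive")
})

test_that("gene windows count overlaps with half-open boundaries", {
  slen <- c(s = 100000)
  genes <- data.frame(scaffold_id = "s", start = 49000, end = 51000,
                      gene_id = "g1")
  # window is [40000, 60000)
  el <- data.frame(scaffold_id = "s",
                   start = c(39900, 60000, 41000, 59999),
                   end = c(40000, 60100, 41200, 60050),
                   strand = "+", family = "SINE_A", class = "SINE")
  wc <- gene_window_counts(genes, el, slen)
  expect_equal(wc$count, 2)  # abutting elements at the edges not counted

  expect_equal(gene_window_counts(genes, el[0, ], slen)$count, 0)

  # translation invariance
  sh <- 12345
  el2 <- transform(el, start = start + sh, end = end + sh)
  genes2 <- transform(genes, start = start + sh, end = end + sh)
  wc2 <- gene_window_counts(genes2, el2, c(s = 100000 + sh))
  expect_equal(wc2$count, wc$count)

  bad <- data.frame(scaffold_id = "s", start = 99000, end = 101000,
                    gene_id = "off")
  expect_error(gene_window_counts(bad, el, slen), "off scaffold")
})

test_that("compare_densities matches the closed-form two-sample t", {
  x <- c(1, 2, 3, 4, 5)
  self <- compare_densities(x, x)
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)

  y <- c(2, 3, 4, 5, 6)
  r <- compare_densities(x, y)
  # hand computation: pooled variance t with n1 = n2 = 5
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(abs(t_hand), df = 8, lower.tail = FALSE)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  expect_equal(r$sem_group, sd(x) / sqrt(5))
})

test_that("binned_frequency assigns by start and conserves counts", {
  el <- data.frame(scaffold_id = "s", start = c(1500, 10, 2999),
                   end = c(1600, 100, 3100), strand = "+",
                   family = "SINE_A", class = "SINE")
  bf <- binned_frequency(3500, el)
  expect_equal(bf$count[2], 1)  # start 1500 -> bin index 1 (0-based)
  expect_equal(sum(bf$count), 3)
  expect_equal(nrow(bf), 4L)
  expect_equal(bf$end[4], 3500)
  empty <- binned_frequency(2500, el[0, ])
  expect_equal(nrow(empty), 3L)
  expect_true(all(empty$count == 0))
})

test_that("reference sampling is deterministic and filters", {
  slen <- setNames(seq(50000, 140000, by = 10000), paste0("s", 1:10))
  a <- sample_reference_regions(slen, n = 4, seed = 9)
  b <- sample_reference_regions(slen, n = 4, seed = 9)
  expect_identical(a$regions, b$regions)
  expect_equal(a$total_bp, sum(a$regions$end))
  loci <- data.frame(scaffold_id = c("s1", "s2"), gene_id = c("g1", "g2"))
  c2 <- sample_reference_regions(slen, n = 8, seed = 2, loci = loci,
                                 exclude_gene_scaffolds = TRUE)
  expect_false(any(c2$regions$scaffold_id %in% c("s1", "s2")))
  expect_error(sample_reference_regions(slen, n = 11, seed = 1),
               "eligible")
})

test_that("cluster detection and intergenic medians follow the gap rule", {
  loci <- data.frame(
    scaffold_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    start = c(0, 11000, 32000, 0, 151000, 5000),
    end = c(1000, 12000, 33000, 1000, 152000, 6000),
    strand = "+",
    gene_id = paste0("g", 1:6),
    family = "T2R")
  cl <- detect_clusters(loci)
  expect_equal(nrow(cl), 1L)  # s2 pair is 150 kb apart; s3 is a singleton
  expect_equal(cl$n_genes, 3L)
  med <- intergenic_median(loci, cl)
  expect_equal(unname(med["T2R"]), median(c(10000, 20000)))

  pair <- loci[1:2, ]
  clp <- detect_clusters(pair)
  expect_equal(unname(intergenic_median(pair, clp)["T2R"]), 10000)
})

test_that("orientation patterns follow strand geometry", {
  g <- function(start, end, strand)
    list(start = start, end = end, strand = strand)
  expect_identical(orientation_pattern(g(0, 10, "+"), g(20, 30, "+")),
                   "head-to-tail")
  expect_identical(orientation_pattern(g(0, 10, "-"), g(20, 30, "+")),
                   "head-to-head")
  expect_identical(orientation_pattern(g(0, 10, "+"), g(20, 30, "-")),
                   "tail-to-tail")
  expect_error(orientation_pattern(g(0, 10, "+"), g(5, 30, "-")), "overlap")
})

test_that("monoexonic check tolerates short indels but not intron-size inserts", {
  g <- small_genome()
  l <- g$loci[1, ]
  gene <- list(scaffold_id = l$scaffold_id, start = l$start, end = l$end - 3,
               strand = l$strand,
               cds = g$family$genes[[l$gene_id]])
  expect_true(check_monoexonic(gene, g$scaffolds[[l$scaffold_id]]))

  insert_at <- function(cds, insert) {
    paste0(substr(cds, 1, 300), insert, substr(cds, 301, nchar(cds)))
  }
  mk_scf <- function(insert) {
    body <- insert_at(g$family$genes[[l$gene_id]], insert)
    paste0(chemomine:::with_seed(1, chemomine:::random_background(2000)),
           body,
           chemomine:::with_seed(2, chemomine:::random_background(2000)))
  }
  intron <- chemomine:::with_seed(8, chemomine:::random_background(500))
  scf_i <- mk_scf(intron)
  gene_i <- list(scaffold_id = "x", start = 2000,
                 end = 2000 + nchar(g$family$genes[[l$gene_id]]) + 500,
                 strand = "+", cds = g$family$genes[[l$gene_id]])
  expect_false(check_monoexonic(gene_i, scf_i))

  small <- chemomine:::with_seed(9, chemomine:::random_background(29))
  scf_s <- mk_scf(small)
  gene_s <- list(scaffold_id = "x", start = 2000,
                 end = 2000 + nchar(g$family$genes[[l$gene_id]]) + 29,
                 strand = "+", cds = g$family$genes[[l$gene_id]])
  expect_true(check_monoexonic(gene_s, scf_s))
})
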