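# Transposable-element accounting at three scales: percent coverage of
# cluster regions, 20-kb gene-centered window densities with a t-test
# against reference regions, and 1-kb binned profiles; plus cluster
# detection, intergenic distances, orientation patterns and intron checks.

CLASS1 <- c("SINE", "LINE", "LTR")

rm_class_of <- function(classfam) {
  prefix <- sub("/.*$", "", classfam)
  ifelse(prefix %in% c("SINE", "LINE", "LTR", "DNA"), prefix,
  ifelse(prefix %in% c("Low_complexity", "Simple_repeat", "Satellite"),
         "Satellite/simple/low",
  ifelse(grepl("RNA$", prefix) | prefix == "Small_RNA", "SmallRNA",
         "Other")))
}

#' Parse a RepeatMasker .out file
#'
#' Expects the standard dialect: three header lines, whitespace-separated
#' columns, 1-based inclusive coordinates, a `C` strand flag for the
#' minus strand, and a class/family column like `LINE/L2`.
#'
#' @param path file path.
#' @return RepeatElement data.frame (0-based half-open coordinates).
#' @export
parse_repeatmasker <- function(path) {
  ln <- readLines(path)
  body <- ln[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), class = character()))
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11 || is.na(suppressWarnings(as.integer(f[6]))) ||
        is.na(suppressWarnings(as.integer(f[7]))))
      stop(sprintf("malformed RepeatMasker line %d", i + 3L))
    data.frame(scaffold_id = f[5],
               start = as.integer(f[6]) - 1L, end = as.integer(f[7]),
               strand = if (f[9] == "C") "-" else "+",
               family = f[10], class = rm_class_of(f[11]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Naive repeat scan against a motif library
#'
#' Approximate full-motif matching (both strands) of labeled library
#' motifs; overlapping same-class matches are merged.  An in-package
#' stand-in for an external repeat annotator so the synthetic pipeline is
#' self-contained.
#'
#' @param scaffolds named character vector.
#' @param library data.frame(family, class, seq); default the bundled one.
#' @param min_len discard matches shorter than this.
#' @param max_mismatch_rate allowed mismatches per motif length.
#' @return RepeatElement data.frame.
#' @export
naive_repeat_scan <- function(scaffolds, library = repeat_motif_library(),
                              min_len = 50, max_mismatch_rate = 0.05) {
  if (is.null(library) || !nrow(library)) stop("empty motif library")
  out <- list()
  for (scf in names(scaffolds)) {
    subj <- Biostrings::DNAString(scaffolds[[scf]])
    for (r in seq_len(nrow(library))) {
      if (nchar(library$seq[r]) < min_len) next
      mm <- floor(max_mismatch_rate * nchar(library$seq[r]))
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") library$seq[r]
               else revcomp(library$seq[r])
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = mm)
        if (!length(m)) next
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = scf, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = strand,
          family = library$family[r], class = library$class[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), class = character()))
  el <- do.call(rbind, out)
  # merge overlapping same-class matches
  merged <- list()
  for (scf in unique(el$scaffold_id)) for (cls in unique(el$class)) {
    e <- el[el$scaffold_id == scf & el$class == cls, ]
    if (!nrow(e)) next
    red <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    merged[[length(merged) + 1L]] <- data.frame(
      scaffold_id = scf, start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      strand = e$strand[match(IRanges::start(red) - 1L, e$start)],
      family = e$family[match(IRanges::start(red) - 1L, e$start)],
      class = cls, stringsAsFactors = FALSE)
  }
  el <- do.call(rbind, merged)
  el$strand[is.na(el$strand)] <- "+"
  el$family[is.na(el$family)] <- "merged"
  rownames(el) <- NULL
  el
}

#' Percent coverage of a region by repeat class
#'
#' Overlapping element intervals are merged per class, clipped to the
#' region, summed and divided by the region length.
#'
#' @param region list or one-row data.frame with scaffold_id, start, end
#'   (0-based half-open).
#' @param elements RepeatElement data.frame.
#' @return named numeric, percent of region bases per class.
#' @export
class_coverage <- function(region, elements) {
  rlen <- region$end - region$start
  if (rlen <= 0) stop("region length must be positive")
  classes <- c(CLASS1, "DNA", "SmallRNA", "Satellite/simple/low", "Other")
  out <- setNames(numeric(length(classes)), classes)
  e <- elements[elements$scaffold_id == region$scaffold_id, , drop = FALSE]
  for (cls in classes) {
    ec <- e[e$class == cls, , drop = FALSE]
    if (!nrow(ec)) next
    red <- IRanges::reduce(IRanges::IRanges(ec$start + 1L, ec$end))
    clipped <- IRanges::restrict(red, start = region$start + 1L,
                                 end = region$end)
    out[cls] <- 100 * sum(IRanges::width(clipped)) / rlen
  }
  out
}

#' Class-I element counts in fixed windows centered on genes
#'
#' A window of `window` bp is centered on each gene midpoint and clipped
#' at scaffold ends (counts then normalized to elements per full window);
#' an element is counted once if it overlaps the window (half-open
#' boundary convention).
#'
#' @param genes loci data.frame (scaffold_id, start, end, gene_id).
#' @param elements RepeatElement data.frame.
#' @param scaffold_lengths named lengths of the scaffolds.
#' @param window window width in bp (even).
#' @param classes element classes counted (default class I).
#' @return data.frame(gene_id, count) with mean and SEM attributes.
#' @export
gene_window_counts <- function(genes, elements, scaffold_lengths,
                               window = 20000, classes = CLASS1) {
  stopifnot(window %% 2 == 0)
  el <- elements[elements$class %in% classes, , drop = FALSE]
  counts <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    slen <- scaffold_lengths[[g$scaffold_id]]
    if (is.null(slen) || g$end > slen || g$start < 0)
      stop(sprintf("gene %s lies off scaffold %s", g$gene_id, g$scaffold_id))
    mid <- floor((g$start + g$end) / 2)
    a <- max(0, mid - window %/% 2)
    b <- min(slen, mid + window %/% 2)
    e <- el[el$scaffold_id == g$scaffold_id, , drop = FALSE]
    n <- sum(e$start < b & e$end > a)
    n * window / (b - a)  # normalize when clipped
  }, numeric(1))
  out <- data.frame(gene_id = genes$gene_id, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "mean") <- mean(counts)
  attr(out, "sem") <- sd(counts) / sqrt(length(counts))
  out
}

# Counts in a non-overlapping window tiling of whole reference regions.
reference_window_counts <- function(regions, elements, window = 20000,
                                    classes = CLASS1) {
  el <- elements[elements$class %in% classes, , drop = FALSE]
  counts <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    starts <- seq(r$start, r$end - window, by = window)
    e <- el[el$scaffold_id == r$scaffold_id, , drop = FALSE]
    counts <- c(counts, vapply(starts, function(a)
      sum(e$start < a + window & e$end > a), numeric(1)))
  }
  counts
}

#' Two-sample comparison of window densities
#'
#' Student's two-sample t-test (equal variance, two-sided, as printed in
#' the source figure legends; Welch switchable).
#'
#' @param group,reference numeric count vectors (n >= 2 each).
#' @param var_equal use the equal-variance statistic (default TRUE).
#' @return list(t, p, mean_group, sem_group, mean_ref, sem_ref).
#' @export
compare_densities <- function(group, reference, var_equal = TRUE) {
  stopifnot(length(group) >= 2, length(reference) >= 2)
  sem <- function(x) sd(x) / sqrt(length(x))
  res <- tryCatch(t.test(group, reference, var.equal = var_equal),
                  error = function(e) NULL)
  if (is.null(res)) {  # both groups constant
    t <- 0; p <- if (mean(group) == mean(reference)) 1 else 0
  } else { t <- unname(res$statistic); p <- res$p.value }
  list(t = t, p = p, mean_group = mean(group), sem_group = sem(group),
       mean_ref = mean(reference), sem_ref = sem(reference))
}

#' Per-bin element frequency profile of a contig
#'
#' Elements are assigned to the bin containing their start; the final
#' partial bin is normalized by its true width.
#'
#' @param contig_length contig length in bp.
#' @param elements RepeatElement data.frame (one scaffold).
#' @param bin bin width in bp.
#' @param classes element classes counted.
#' @return data.frame(bin, start, end, count, per_kb).
#' @export
binned_frequency <- function(contig_length, elements, bin = 1000,
                             classes = CLASS1) {
  stopifnot(bin > 0)
  nb <- ceiling(contig_length / bin)
  starts <- (seq_len(nb) - 1L) * bin
  ends <- pmin(starts + bin, contig_length)
  el <- elements[elements$class %in% classes, , drop = FALSE]
  counts <- tabulate(pmin(el$start %/% bin + 1L, nb), nbins = nb)
  data.frame(bin = seq_len(nb) - 1L, start = starts, end = ends,
             count = counts, per_kb = counts / ((ends - starts) / 1000))
}

#' Sample reference regions (whole scaffolds)
#'
#' Uniform sample without replacement among scaffolds at least
#' `min_length` long, optionally excluding gene-bearing scaffolds.
#'
#' @param scaffold_lengths named lengths.
#' @param n number of scaffolds to draw.
#' @param seed RNG seed.
#' @param loci truth/predicted loci used by the exclusion filter.
#' @param exclude_gene_scaffolds drop scaffolds carrying genes.
#' @param min_length minimum scaffold length.
#' @return list(regions = data.frame(scaffold_id, start, end), total_bp).
#' @export
sample_reference_regions <- function(scaffold_lengths, n = 10, seed = 1,
                                     loci = NULL,
                                     exclude_gene_scaffolds = FALSE,
                                     min_length = 0) {
  elig <- names(scaffold_lengths)[scaffold_lengths >= min_length]
  if (exclude_gene_scaffolds && !is.null(loci))
    elig <- setdiff(elig, unique(loci$scaffold_id))
  if (n > length(elig))
    stop(sprintf("only %d eligible scaffolds for a sample of %d",
                 length(elig), n))
  chosen <- with_seed(seed, sample(elig, n))
  regions <- data.frame(scaffold_id = chosen, start = 0L,
                        end = as.integer(scaffold_lengths[chosen]),
                        stringsAsFactors = FALSE)
  list(regions = regions, total_bp = sum(regions$end))
}

#' Detect same-family gene clusters on scaffolds
#'
#' Maximal runs of same-family genes on one scaffold with successive
#' end-to-start gaps at most `max_gap`; runs below `min_genes` are
#' dropped.
#'
#' @param loci loci data.frame.
#' @param min_genes minimum cluster size retained (family minima applied
#'   at the analysis site: 3 for T2R coverage regions, 2 otherwise).
#' @param max_gap maximum intra-cluster gap in bp.
#' @return GeneCluster data.frame (cluster_id, scaffold_id, family,
#'   n_genes, start, end, gene_ids comma-joined in order).
#' @export
detect_clusters <- function(loci, min_genes = 2, max_gap = 100000) {
  out <- list()
  for (scf in unique(loci$scaffold_id)) for (fam in unique(loci$family)) {
    g <- loci[loci$scaffold_id == scf & loci$family == fam, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$start), ]
    gap <- c(Inf, g$start[-1] - g$end[-nrow(g)])
    run <- cumsum(gap > max_gap)
    for (rr in unique(run)) {
      gg <- g[run == rr, , drop = FALSE]
      if (nrow(gg) < min_genes) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = scf, family = fam, n_genes = nrow(gg),
        start = min(gg$start), end = max(gg$end),
        gene_ids = paste(gg$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold_id = character(), family = character(),
                      n_genes = integer(), start = integer(),
                      end = integer(), gene_ids = character()))
  res <- do.call(rbind, out)
  res$cluster_id <- sprintf("cl%02d", seq_len(nrow(res)))
  res
}

#' Median intergenic distance within clusters, per family
#'
#' Distance is the end-to-start gap between coordinate-adjacent genes of
#' a cluster.
#'
#' @param loci loci data.frame.
#' @param clusters result of [detect_clusters()].
#' @return named numeric of per-family medians; families without adjacent
#'   pairs are NA with a warning.
#' @export
intergenic_median <- function(loci, clusters) {
  fams <- unique(clusters$family)
  out <- setNames(rep(NA_real_, length(fams)), fams)
  for (fam in fams) {
    d <- numeric(0)
    for (i in which(clusters$family == fam)) {
      ids <- strsplit(clusters$gene_ids[i], ",")[[1]]
      g <- loci[match(ids, loci$gene_id), ]
      g <- g[order(g$start), ]
      if (nrow(g) > 1) d <- c(d, g$start[-1] - g$end[-nrow(g)])
    }
    if (!length(d)) warning(sprintf("no adjacent pairs for family %s", fam))
    else out[fam] <- median(d)
  }
  out
}

#' Relative orientation of an adjacent gene pair
#'
#' @param g1,g2 one-row loci (start, end, strand) on one scaffold.
#' @return "head-to-tail", "head-to-head" or "tail-to-tail".
#' @export
orientation_pattern <- function(g1, g2) {
  if (g1$start < g2$end && g2$start < g1$end) stop("genes overlap")
  left <- if (g1$start <= g2$start) g1 else g2
  right <- if (g1$start <= g2$start) g2 else g1
  if (left$strand == right$strand) return("head-to-tail")
  if (left$strand == "-" && right$strand == "+") return("head-to-head")
  "tail-to-tail"
}

#' Check that a curated gene is monoexonic on its scaffold
#'
#' Aligns the coding sequence against the genomic interval (strand
#' oriented, free end gaps in the genomic side); TRUE iff the alignment
#' is colinear with no gap of `max_gap_bp` or more.
#'
#' @param gene CuratedGene list (scaffold_id, start, end, strand, cds).
#' @param scaffold the scaffold sequence.
#' @param max_gap_bp intron-calling threshold (default 30).
#' @return logical.
#' @export
check_monoexonic <- function(gene, scaffold, max_gap_bp = 30) {
  if (gene$end > nchar(scaffold) || gene$start < 0)
    stop("locus does not lie on the scaffold")
  ss <- strand_space(gene, scaffold)
  genomic <- substr(ss$seq, ss$start + 1, ss$end)
  al <- align_pair(gene$cds, genomic, type = "overlap", alphabet = "dna",
                   gap_open = 5, gap_extend = 0.5, match = 2, mismatch = -3)
  gaps <- al$ai == 0L | al$bi == 0L
  if (!any(gaps)) return(TRUE)
  r <- rle(gaps)
  max(r$lengths[r$values]) < max_gap_bp
}
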