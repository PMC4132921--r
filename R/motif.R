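# Motif conservation: gap-column stripping, per-column conservation at the
# 45% threshold, sequence-logo information content, cross-family motif
# classification over a master alignment, and hydropathy-based
# transmembrane annotation.

aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  m
}

#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` (strictly) are
#' deleted; the mapping from kept columns to original columns is retained
#' as the `"provenance"` attribute.
#'
#' @param alignment named character vector of gapped rows.
#' @param max_gap_fraction threshold (default 0.9).
#' @return stripped alignment with a `provenance` attribute.
#' @export
strip_gap_columns <- function(alignment, max_gap_fraction = 0.9) {
  m <- aln_matrix(alignment)
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= max_gap_fraction)
  if (!length(keep)) stop("all columns removed by the gap filter")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- setNames(out, names(alignment))
  attr(out, "provenance") <- keep
  out
}

#' Per-column conservation profile
#'
#' Consensus is the most frequent non-gap residue (ties broken
#' alphabetically); its frequency is taken over non-gap rows; a column is
#' conserved iff that frequency strictly exceeds `threshold`.
#'
#' @param alignment named character vector (>= 2 rows).
#' @param threshold conservation threshold (default 0.45).
#' @return data.frame(column, consensus, frequency, conserved).
#' @export
conservation_profile <- function(alignment, threshold = 0.45) {
  if (length(alignment) < 2) stop("need at least two rows")
  m <- aln_matrix(alignment)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col))
      return(data.frame(column = j, consensus = NA_character_,
                        frequency = 0, conserved = FALSE))
    tab <- table(col)
    top <- sort(names(tab)[tab == max(tab)])[1]
    f <- as.numeric(max(tab)) / length(col)
    data.frame(column = j, consensus = top, frequency = f,
               conserved = f > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sequence-logo information content of one column
#'
#' IC = log2(20) - H where H is the Shannon entropy of the residue
#' frequencies over non-gap rows (no small-sample correction); letter
#' heights are frequency x IC.
#'
#' @param column character vector of residues (possibly with gaps).
#' @return list(ic = bits, heights = named numeric).
#' @export
logo_information <- function(column) {
  if (!length(column)) stop("empty column")
  col <- column[column != "-"]
  if (!length(col)) return(list(ic = 0, heights = numeric(0)))
  f <- table(col) / length(col)
  h <- -sum(f * log2(f))
  ic <- log2(20) - h
  list(ic = ic, heights = setNames(as.numeric(f) * ic, names(f)))
}

#' Cross-family motif comparison over a master alignment
#'
#' Classifies every master-alignment column by where it is conserved:
#' `shared` (the same residue conserved in at least one group of each
#' family), `differential` (both families conserved but with different
#' residues), `family-specific` (>= 2 groups of one family only),
#' `group-specific` (exactly one group), or `none`.
#'
#' @param master named character vector, the master alignment.
#' @param groups named list: group name -> row names belonging to it.
#' @param group_family named character vector: family of each group.
#' @param threshold conservation threshold.
#' @return data.frame with one row per column: per-group conserved flags
#'   and consensus residues, and `class`; summary counts in the
#'   `"class_counts"` attribute.
#' @export
cross_family_motif_table <- function(master, groups, group_family,
                                     threshold = 0.45) {
  keep <- vapply(groups, function(g) length(g) >= 2, logical(1))
  if (any(!keep))
    warning(sprintf("groups excluded (fewer than 2 sequences): %s",
                    paste(names(groups)[!keep], collapse = ", ")))
  groups <- groups[keep]
  group_family <- group_family[names(groups)]
  profs <- lapply(groups, function(ids)
    conservation_profile(master[ids], threshold))
  ncols <- nrow(profs[[1]])
  fams <- unique(group_family)
  rows <- lapply(seq_len(ncols), function(j) {
    cons <- vapply(profs, function(p) p$conserved[j], logical(1))
    res <- vapply(profs, function(p)
      if (is.na(p$consensus[j])) "" else p$consensus[j], character(1))
    res_by_fam <- lapply(fams, function(f)
      unique(res[cons & group_family == f]))
    names(res_by_fam) <- fams
    nonempty <- vapply(res_by_fam, length, integer(1)) > 0
    cls <- if (sum(cons) == 0) "none"
      else if (all(nonempty)) {
        if (length(intersect(res_by_fam[[1]], res_by_fam[[2]]))) "shared"
        else "differential"
      } else if (sum(cons) >= 2) "family-specific" else "group-specific"
    out <- data.frame(column = j, class = cls, stringsAsFactors = FALSE)
    for (g in names(groups)) {
      out[[paste0("conserved_", g)]] <- cons[[g]]
      out[[paste0("consensus_", g)]] <- res[[g]]
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "class_counts") <- table(out$class)
  out
}

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Predict transmembrane regions from hydropathy
#'
#' Sliding Kyte-Doolittle hydropathy (window 19); maximal runs of window
#' centers whose mean hydropathy exceeds the threshold become candidate
#' intervals; runs shorter than `min_len` residues are discarded.  For a
#' 7-transmembrane receptor consensus this yields the canonical seven
#' intervals.
#'
#' @param consensus ungapped residue string.
#' @param window sliding window length (odd).
#' @param threshold mean-hydropathy threshold.
#' @param min_len minimum run length (residues).
#' @return data.frame(start, end) of 1-based inclusive intervals.
#' @export
predict_tm_regions <- function(consensus, window = 19, threshold = 1.6,
                               min_len = 15) {
  v <- strsplit(consensus, "")[[1]]
  n <- length(v)
  if (n < window) stop("sequence shorter than the hydropathy window")
  h <- KYTE_DOOLITTLE[v]
  h[is.na(h)] <- 0
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  score <- vapply(centers, function(i) mean(h[(i - half):(i + half)]),
                  numeric(1))
  above <- score > threshold
  if (!any(above)) return(data.frame(start = integer(), end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = centers[starts[r$values]],
                   end = centers[ends[r$values]])
  iv <- iv[iv$end - iv$start + 1L >= min_len, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}
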