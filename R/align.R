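# Thin wrappers around the package's affine-gap dynamic-programming kernel.

blosum62 <- function() {
  if (is.null(.cm_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cm_cache$BLOSUM62 <- e$BLOSUM62
  }
  .cm_cache$BLOSUM62
}

# Residue-residue score matrix for two character vectors.
protein_score_matrix <- function(a, b, mat = blosum62()) {
  a[!a %in% rownames(mat)] <- "X"
  b[!b %in% rownames(mat)] <- "X"
  mat[a, b, drop = FALSE]
}

#' Pairwise sequence alignment with affine gap costs
#'
#' @param a,b sequences (single character strings).
#' @param type one of "global", "local", "overlap" (free end gaps in `b`).
#' @param gap_open,gap_extend gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param alphabet "protein" (BLOSUM62) or "dna" (match/mismatch scores).
#' @param match,mismatch scores used when `alphabet = "dna"`.
#' @return list with `score`, aligned strings `a_aln`/`b_aln`, and the
#'   1-based aligned index vectors `ai`/`bi` (0 = gap).
#' @export
align_pair <- function(a, b, type = c("global", "local", "overlap"),
                       gap_open = 11, gap_extend = 1,
                       alphabet = c("protein", "dna"),
                       match = 2, mismatch = -3) {
  type <- match.arg(type)
  alphabet <- match.arg(alphabet)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (alphabet == "protein") {
    S <- protein_score_matrix(av, bv)
  } else {
    S <- matrix(ifelse(outer(av, bv, "=="), match, mismatch),
                nrow = length(av))
  }
  code <- c(global = 0L, local = 1L, overlap = 2L)[[type]]
  r <- align_affine_cpp(S, gap_open, gap_extend, code)
  a_aln <- ifelse(r$ai == 0L, "-", av[pmax(r$ai, 1L)])
  b_aln <- ifelse(r$bi == 0L, "-", bv[pmax(r$bi, 1L)])
  list(score = r$score,
       a_aln = paste(a_aln, collapse = ""),
       b_aln = paste(b_aln, collapse = ""),
       ai = r$ai, bi = r$bi)
}
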