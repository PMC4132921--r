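# Codon-level machinery shared by the simulator and the selection module:
# sense-codon tables, single-nucleotide neighborhoods, and the MG94xHKY85
# rate matrix with uniform codon frequencies (which makes Q symmetric, so
# likelihood code can use a symmetric eigendecomposition).

NUC <- c("A", "C", "G", "T")

#' Genetic-code tables for the 61 sense codons
#'
#' @return list with `codons` (61 sense codons, alphabetical), `aa` (amino
#'   acid per codon), `stop_codons`, and `neighbors` (61 x 9 matrix of
#'   single-nucleotide neighbor indices into the full 64-codon table, with
#'   the codon strings as dimnames).
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.cm_cache$codon_tables)) return(.cm_cache$codon_tables)
  gc64 <- Biostrings::GENETIC_CODE
  all64 <- names(gc64)
  stops <- all64[gc64 == "*"]
  sense <- all64[gc64 != "*"]
  # 9 single-nt neighbors of every codon (as codon strings)
  nb <- matrix("", nrow = length(all64), ncol = 9,
               dimnames = list(all64, NULL))
  for (cd in all64) {
    ch <- strsplit(cd, "")[[1]]
    k <- 0L
    for (pos in 1:3) for (n in NUC) {
      if (n == ch[pos]) next
      alt <- ch; alt[pos] <- n
      k <- k + 1L
      nb[cd, k] <- paste(alt, collapse = "")
    }
  }
  out <- list(codons = sense, aa = gc64[sense], stop_codons = stops,
              aa64 = gc64, neighbors = nb)
  .cm_cache$codon_tables <- out
  out
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' MG94xHKY85 codon rate matrix with uniform codon frequencies
#'
#' Off-diagonal rate for a single-nucleotide change i -> j is
#' `kappa` for transitions (1 for transversions), multiplied by `omega`
#' when the change is nonsynonymous; changes into stop codons and
#' multi-nucleotide changes have rate 0.  The matrix is scaled by a
#' kappa-dependent constant chosen once so that the expected number of
#' substitutions per codon per unit branch length equals 1 at omega = 1
#' under uniform codon frequencies; branch lengths are therefore expected
#' substitutions/codon on the neutral scale.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @return 61 x 61 rate matrix over the sense codons (symmetric).
#' @export
mg94_rate_matrix <- function(kappa, omega) {
  stopifnot(kappa > 0, omega >= 0)
  tb <- codon_tables()
  base <- .cm_cache$mg94_base
  if (is.null(base)) {
    n <- length(tb$codons)
    zero <- matrix(0, n, n, dimnames = list(tb$codons, tb$codons))
    base <- list(syn_ts = zero, syn_tv = zero, non_ts = zero, non_tv = zero)
    for (i in seq_len(n)) {
      ci <- tb$codons[i]
      chi <- strsplit(ci, "")[[1]]
      for (cj in tb$neighbors[ci, ]) {
        if (!(cj %in% tb$codons)) next  # stop codon target
        chj <- strsplit(cj, "")[[1]]
        pos <- which(chi != chj)
        ts <- is_transition(chi[pos], chj[pos])
        syn <- tb$aa[ci] == tb$aa[cj]
        slot <- paste0(if (syn) "syn" else "non", if (ts) "_ts" else "_tv")
        base[[slot]][ci, cj] <- 1
      }
    }
    .cm_cache$mg94_base <- base
  }
  syn <- kappa * base$syn_ts + base$syn_tv
  nonsyn <- kappa * base$non_ts + base$non_tv
  # neutral-scale normalization: mean total leave rate at omega = 1 is 1
  rho <- 1 / mean(rowSums(syn) + rowSums(nonsyn))
  q <- rho * (syn + omega * nonsyn)
  diag(q) <- -rowSums(q)
  q
}

# Symmetric eigendecomposition of the MG94 matrix, cached per (kappa, omega).
mg94_eigen <- function(kappa, omega) {
  key <- paste0("eig_", format(kappa, digits = 10), "_",
                format(omega, digits = 10))
  e <- .cm_cache[[key]]
  if (is.null(e)) {
    e <- eigen(mg94_rate_matrix(kappa, omega), symmetric = TRUE)
    if (is.null(.cm_cache$eig_keys)) .cm_cache$eig_keys <- character()
    if (length(.cm_cache$eig_keys) > 400) {  # bound the cache
      rm(list = .cm_cache$eig_keys, envir = .cm_cache)
      .cm_cache$eig_keys <- character()
    }
    .cm_cache[[key]] <- e
    .cm_cache$eig_keys <- c(.cm_cache$eig_keys, key)
  }
  e
}

# Transition probability matrix P(t) = U exp(L t) U' from a cached eigen.
mg94_pmat <- function(eig, t) {
  p <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  p[p < 0] <- 0
  p / rowSums(p)
}

# Split an in-frame nucleotide string into codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

translate_cds <- function(cds) {
  tb <- codon_tables()
  cods <- split_codons(cds)
  aa <- tb$aa64[cods]
  aa[is.na(aa)] <- "X"  # codons containing N or gaps
  paste(aa, collapse = "")
}
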