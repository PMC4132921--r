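# Protein phylogenetics: deterministic progressive alignment, identity and
# similarity matrices, Poisson-corrected distances, neighbor joining with
# negative-branch clamping, nonparametric bootstrap support, reciprocal
# outgroup family assignment, and ancestral-lineage counting.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# 20 x L residue-frequency profile of a set of gapped rows (gap mass
# dropped so gaps score zero against everything).
profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  p <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (a in AA20) p[a, ] <- colSums(m == a)
  p / length(rows)
}

merge_profiles <- function(rows_a, rows_b, gap_open = 11, gap_extend = 1) {
  B <- blosum62()[AA20, AA20]
  pa <- profile_of(rows_a)
  pb <- profile_of(rows_b)
  S <- t(pa) %*% B %*% pb
  r <- align_affine_cpp(S, gap_open, gap_extend, 0L)
  expand <- function(rows, idx, other_len) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow = nrow(m), ncol = length(idx))
    take <- idx != 0L
    out[, take] <- m[, idx[take], drop = FALSE]
    rownames(out) <- names(rows)
    apply(out, 1, paste, collapse = "")
  }
  c(expand(rows_a, r$ai), expand(rows_b, r$bi))
}

# Shared k-mer distance used only for the guide tree.
kmer_distance <- function(seqs, k = 3) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(character()))
    table(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- sum(pmin(km[[i]][names(km[[j]])], km[[j]]), na.rm = TRUE)
    denom <- max(1, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1)
    d[i, j] <- d[j, i] <- 1 - common / denom
  }
  d
}

#' Deterministic progressive multiple alignment
#'
#' Average-linkage guide tree on shared k-mer distances, then
#' profile-profile merges with BLOSUM62 expected scores and affine gaps.
#'
#' @param proteins named character vector (>= 1 sequence).
#' @param gap_open,gap_extend affine gap penalties.
#' @return named character vector of equal-length gapped rows.
#' @export
progressive_align <- function(proteins, gap_open = 11, gap_extend = 1) {
  if (!length(proteins)) stop("no sequences")
  if (any(!nzchar(proteins))) stop("invalid input: empty sequence")
  if (length(proteins) == 1) return(proteins)
  if (length(proteins) == 2) {
    al <- align_pair(proteins[[1]], proteins[[2]], type = "global",
                     gap_open = gap_open, gap_extend = gap_extend)
    return(setNames(c(al$a_aln, al$b_aln), names(proteins)))
  }
  d <- kmer_distance(proteins)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- lapply(seq_along(proteins), function(i) proteins[i])
  merged <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) groups[[-x]] else merged[[x]]
    merged[[s]] <- merge_profiles(pick(hc$merge[s, 1]),
                                  pick(hc$merge[s, 2]),
                                  gap_open, gap_extend)
  }
  out <- merged[[length(merged)]]
  out[names(proteins)]
}

#' Pairwise identity and similarity matrices
#'
#' Global pairwise alignment (BLOSUM62, affine gaps); identity is the
#' percentage of matching positions over the length of the shorter
#' sequence, similarity counts BLOSUM62-positive pairs the same way.
#'
#' @param sequences named character vector (>= 2).
#' @return list(identity, similarity): symmetric percent matrices with
#'   diagonal 100.
#' @export
identity_matrix <- function(sequences) {
  if (length(sequences) < 2) stop("need at least two sequences")
  if (any(!nzchar(sequences))) stop("invalid input: empty sequence")
  n <- length(sequences)
  B <- blosum62()
  idm <- sim <- matrix(100, n, n,
                       dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- align_pair(sequences[[i]], sequences[[j]], type = "global")
    av <- strsplit(al$a_aln, "")[[1]]
    bv <- strsplit(al$b_aln, "")[[1]]
    both <- av != "-" & bv != "-"
    shorter <- min(nchar(sequences[[i]]), nchar(sequences[[j]]))
    idm[i, j] <- idm[j, i] <- 100 * sum(av == bv & both) / shorter
    pos <- both & mapply(function(a, b) B[a, b] > 0,
                         ifelse(av %in% rownames(B), av, "X"),
                         ifelse(bv %in% rownames(B), bv, "X"))
    sim[i, j] <- sim[j, i] <- 100 * sum(pos) / shorter
  }
  list(identity = idm, similarity = sim)
}

#' Poisson-corrected protein distance matrix
#'
#' p-distance over mutually ungapped columns with the Poisson correction
#' d = -ln(1 - p).
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @return symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(alignment) {
  if (length(alignment) < 2) stop("need at least two rows")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  ng <- m != "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- ng[i, ] & ng[j, ]
    if (!any(shared))
      stop(sprintf("no shared ungapped columns for pair %s, %s",
                   names(alignment)[i], names(alignment)[j]))
    p <- sum(m[i, shared] != m[j, shared]) / sum(shared)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree with negative-branch clamping
#'
#' Standard neighbor joining; any negative branch length is set to zero
#' and the (negative) amount transferred to its sibling branch.
#'
#' @param d square symmetric distance matrix, n >= 3.
#' @return unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < -1e-12)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent)
    sib <- setdiff(sib, e)
    if (length(sib)) {
      amt <- tr$edge.length[e]
      tr$edge.length[sib[1]] <- max(0, tr$edge.length[sib[1]] + amt)
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap branch support for the NJ tree of an alignment
#'
#' Nonparametric bootstrap: alignment columns are resampled with
#' replacement, the NJ tree rebuilt, and each internal branch of the
#' full-data tree is annotated with the percentage of replicates
#' containing its bipartition.
#'
#' @param alignment named character vector of gapped rows.
#' @param n_reps number of replicates (default 100).
#' @param seed RNG seed.
#' @return `ape::phylo` with `node.label` holding support percentages.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1) {
  if (n_reps < 1) stop("invalid parameter: n_reps must be >= 1")
  full <- nj_tree(protein_distance(alignment))
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), replace = TRUE)
      aln_r <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                              collapse = ""), names(alignment))
      tryCatch(nj_tree(protein_distance(aln_r)), error = function(e) NULL)
    })
  })
  reps <- reps[!vapply(reps, is.null, logical(1))]
  cnt <- ape::prop.clades(full, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  full$node.label <- round(100 * cnt / length(reps), 1)
  full
}

# Tips descending from each node (internal node numbering per ape).
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Assign candidate genes to families by phylogenetic position
#'
#' Candidates and labeled references of two families are aligned and an
#' NJ tree with bootstrap support built; the tree is rooted between the
#' two reference families (reciprocal outgroups).  A candidate is
#' assigned to a family iff the smallest reference-containing clade
#' around its leaf contains references of that family only and has
#' support strictly above `min_support`.
#'
#' @param candidates named protein vector.
#' @param refs named protein vector of references.
#' @param ref_family character vector, family per reference (two levels).
#' @param n_reps,seed bootstrap parameters.
#' @param min_support percent support threshold ("above 80" is strict).
#' @return list(assignments = data.frame(gene_id, family, support, note),
#'   tree = supported rooted tree).
#' @export
assign_family <- function(candidates, refs, ref_family, n_reps = 100,
                          seed = 1, min_support = 80) {
  stopifnot(length(refs) == length(ref_family))
  fams <- unique(ref_family)
  if (length(fams) != 2)
    stop("reference set must contain exactly two families")
  aln <- progressive_align(c(refs, candidates))
  tr <- nj_tree(protein_distance(aln))
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), replace = TRUE)
      aln_r <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                              collapse = ""), names(aln))
      tryCatch(nj_tree(protein_distance(aln_r)), error = function(e) NULL)
    })
  })
  reps <- reps[!vapply(reps, is.null, logical(1))]
  cnt <- ape::prop.clades(tr, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  tr$node.label <- round(100 * cnt / length(reps), 1)
  ntip <- length(tr$tip.label)
  refs1 <- names(refs)[ref_family == fams[1]]
  refs2 <- names(refs)[ref_family == fams[2]]
  # the two families are reciprocal outgroups: membership is decided by
  # the edge whose bipartition cleanly separates the two reference sets
  # (the branch between the monophyletic family groups); among such
  # edges the best-supported one is used, and its support gates every
  # assignment
  internal <- (ntip + 1):(ntip + tr$Nnode)
  sep <- lapply(internal, function(v) {
    side <- tr$tip.label[tips_under(tr, v)]
    has1 <- all(refs1 %in% side); no2 <- !any(refs2 %in% side)
    has2 <- all(refs2 %in% side); no1 <- !any(refs1 %in% side)
    if (has1 && no2) list(node = v, fam_inside = fams[1], side = side)
    else if (has2 && no1) list(node = v, fam_inside = fams[2], side = side)
    else NULL
  })
  sep <- sep[!vapply(sep, is.null, logical(1))]
  miss <- setdiff(names(candidates), tr$tip.label)
  if (length(miss))
    stop(sprintf("candidate %s missing from tree", miss[1]))
  if (!length(sep)) {
    res <- data.frame(gene_id = names(candidates), family = "unassigned",
                      support = NA_real_,
                      note = "reference families not separable",
                      stringsAsFactors = FALSE)
    return(list(assignments = res, tree = tr))
  }
  supp <- vapply(sep, function(s) {
    x <- tr$node.label[s$node - ntip]
    if (is.na(x)) 0 else x
  }, numeric(1))
  best <- sep[[which.max(supp)]]
  split_support <- max(supp)
  res <- lapply(names(candidates), function(cd) {
    fam <- if (cd %in% best$side) best$fam_inside
           else setdiff(fams, best$fam_inside)
    if (split_support > min_support)
      data.frame(gene_id = cd, family = fam, support = split_support,
                 note = "inside family clade", stringsAsFactors = FALSE)
    else
      data.frame(gene_id = cd, family = "unassigned",
                 support = split_support,
                 note = sprintf("split support %.1f <= %d", split_support,
                                min_support),
                 stringsAsFactors = FALSE)
  })
  rooted <- tryCatch(ape::root(tr, node = best$node, resolve.root = TRUE),
                     error = function(e) tr)
  list(assignments = do.call(rbind, res), tree = rooted)
}

#' Count ancestral gene lineages of a focal species
#'
#' Given a rooted tree with species-tagged leaves, counts the maximal
#' subtrees whose leaves all belong to the focal species; each such
#' subtree corresponds to one gene already present when the focal lineage
#' diverged from the references.
#'
#' @param tree rooted `ape::phylo`.
#' @param is_focal logical vector along `tree$tip.label`, or a predicate
#'   applied to the labels.
#' @return integer count (0 when no focal leaves).
#' @export
count_ancestral_lineages <- function(tree, is_focal) {
  if (is.function(is_focal)) is_focal <- vapply(tree$tip.label, is_focal,
                                                logical(1))
  ntip <- length(tree$tip.label)
  if (!any(is_focal)) return(0L)
  if (all(is_focal)) return(1L)
  all_focal <- function(node) all(is_focal[tips_under(tree, node)])
  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p)) p else NA_integer_
  }
  nodes <- seq_len(ntip + tree$Nnode)
  cnt <- 0L
  for (v in nodes) {
    if (!all_focal(v)) next
    p <- parent_of(v)
    if (is.na(p) || !all_focal(p)) cnt <- cnt + 1L
  }
  cnt
}
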