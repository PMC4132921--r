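# Per-codon selection inference: codon back-threading, Nei-Gojobori site
# and difference counting, codon-level Fitch ancestors, the SLAC counting
# test, the MG94xHKY85 global fit, the FEL per-site likelihood-ratio test,
# the two-method consensus at p < 0.1, and the dS-saturation guard.

#' Back-thread coding sequences through a protein alignment
#'
#' Every protein gap becomes a gap triplet, giving a codon alignment with
#' 3x the protein column count.  Each CDS must translate to its ungapped
#' protein row (X tolerated at repaired positions).
#'
#' @param protein_alignment named character vector of gapped rows.
#' @param cds named character vector of in-frame coding sequences.
#' @return named character vector of gapped codon rows.
#' @export
codon_backthread <- function(protein_alignment, cds) {
  out <- vapply(names(protein_alignment), function(id) {
    row <- protein_alignment[[id]]
    if (is.null(cds[[id]])) stop(sprintf("no cds for %s", id))
    cods <- split_codons(cds[[id]])
    prot <- translate_cds(cds[[id]])
    ungapped <- gsub("-", "", row)
    if (nchar(ungapped) != length(cods))
      stop(sprintf("translation mismatch for %s at position %d",
                   id, min(nchar(ungapped), length(cods)) + 1L))
    pv <- strsplit(prot, "")[[1]]
    uv <- strsplit(ungapped, "")[[1]]
    bad <- which(pv != uv & pv != "X" & uv != "X")
    if (length(bad))
      stop(sprintf("translation mismatch for %s at position %d", id, bad[1]))
    rv <- strsplit(row, "")[[1]]
    res <- character(length(rv))
    k <- 0L
    for (i in seq_along(rv)) {
      if (rv[i] == "-") res[i] <- "---"
      else { k <- k + 1L; res[i] <- cods[k] }
    }
    paste(res, collapse = "")
  }, character(1))
  setNames(out, names(protein_alignment))
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous fraction is computed over the
#' non-stop single-nucleotide neighbors at that position; positions whose
#' neighbors are all stops contribute nothing, so s + n equals the number
#' of accounted positions.
#'
#' @param codon sense codon string.
#' @return c(s = synonymous sites, n = nonsynonymous sites).
#' @export
ng_site_counts <- function(codon) {
  tb <- codon_tables()
  if (!(codon %in% tb$codons))
    stop(sprintf("undefined for stop or invalid codon %s", codon))
  ch <- strsplit(codon, "")[[1]]
  s <- n <- 0
  for (pos in 1:3) {
    syn <- 0L; tot <- 0L
    for (nt in setdiff(NUC, ch[pos])) {
      alt <- ch; alt[pos] <- nt
      altc <- paste(alt, collapse = "")
      if (!(altc %in% tb$codons)) next  # stop neighbor excluded
      tot <- tot + 1L
      if (tb$aa[altc] == tb$aa[codon]) syn <- syn + 1L
    }
    if (tot > 0) {
      s <- s + syn / tot
      n <- n + (tot - syn) / tot
    }
  }
  c(s = s, n = n)
}

# Transition/transversion-weighted variant used for SLAC's expected-site
# fractions: neighbor contributions are weighted kappa (transitions) or 1
# (transversions), matching the mutation model the ancestors were evolved
# under; kappa = 1 reduces to plain NG counting.
ng_site_counts_weighted <- function(codon, kappa = 1) {
  key <- paste0("ngw_", codon, "_", format(kappa, digits = 8))
  hit <- .cm_cache[[key]]
  if (!is.null(hit)) return(hit)
  tb <- codon_tables()
  ch <- strsplit(codon, "")[[1]]
  s <- n <- 0
  for (pos in 1:3) {
    wsyn <- 0; wtot <- 0
    for (nt in setdiff(NUC, ch[pos])) {
      alt <- ch; alt[pos] <- nt
      altc <- paste(alt, collapse = "")
      if (!(altc %in% tb$codons)) next
      w <- if (is_transition(ch[pos], nt)) kappa else 1
      wtot <- wtot + w
      if (tb$aa[altc] == tb$aa[codon]) wsyn <- wsyn + w
    }
    if (wtot > 0) {
      s <- s + wsyn / wtot
      n <- n + (wtot - wsyn) / wtot
    }
  }
  out <- c(s = s, n = n)
  .cm_cache[[key]] <- out
  out
}

# Average synonymous/nonsynonymous step counts over all minimal mutation
# paths between two sense codons, excluding paths through stop codons
# (falling back to all paths when every path hits a stop).  Cached.
codon_path_counts <- function(a, b) {
  key <- paste0("path_", a, "_", b)
  hit <- .cm_cache[[key]]
  if (!is.null(hit)) return(hit)
  tb <- codon_tables()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  diff <- which(av != bv)
  count_path <- function(order) {
    cur <- av
    syn <- 0; non <- 0; valid <- TRUE
    for (pos in order) {
      nxt <- cur; nxt[pos] <- bv[pos]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (!(c2 %in% tb$codons) && c2 != b) valid <- FALSE
      if (!(c2 %in% tb$codons)) { cur <- nxt; next }
      if (!(c1 %in% tb$codons)) { cur <- nxt; next }
      if (tb$aa[c1] == tb$aa[c2]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    list(syn = syn, non = non, valid = valid)
  }
  orders <- if (length(diff) <= 1) list(diff) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    perms(diff)
  }
  res <- lapply(orders, count_path)
  valid <- vapply(res, function(r) r$valid, logical(1))
  use <- if (any(valid)) res[valid] else res
  out <- c(syn = mean(vapply(use, function(r) r$syn, numeric(1))),
           non = mean(vapply(use, function(r) r$non, numeric(1))))
  .cm_cache[[key]] <- out
  out
}

# One-sided binomial p-value of the SLAC counting test for a site with
# observed (NN, NS) changes and expected (EN, ES) sites; counts are
# rounded to integers for the exact test.
slac_binom_p <- function(NN, NS, EN, ES) {
  x <- round(NN); ntr <- round(NN + NS)
  if (ntr == 0) return(1)
  if (EN + ES == 0) return(NA_real_)
  p0 <- EN / (EN + ES)
  dN <- if (EN > 0) NN / EN else 0
  dS <- if (ES > 0) NS / ES else 0
  if (dN >= dS) pbinom(x - 1, ntr, p0, lower.tail = FALSE)
  else pbinom(x, ntr, p0)
}

# --- codon-level Fitch parsimony ------------------------------------------

# Per-site ancestral codon states by Fitch sets (missing data = full set),
# top-down resolution preferring the parent state, then the state implying
# the fewest nonsynonymous changes, then lexicographic codon order.
#' Ancestral codon states by Fitch parsimony
#'
#' @param tree `ape::phylo`; leaves must match the alignment names.
#' @param codon_alignment named character vector of gapped codon rows.
#' @return list(states = (tips + internal nodes) x sites matrix of codon
#'   strings, score = per-site minimal change count).
#' @export
parsimony_ancestors <- function(tree, codon_alignment) {
  tb <- codon_tables()
  ids <- names(codon_alignment)
  if (!setequal(ids, tree$tip.label))
    stop("tree leaves do not match alignment ids")
  rows <- lapply(codon_alignment, split_codons)
  nsite <- length(rows[[1]])
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  post <- reorder(tree, "postorder")
  states <- matrix(NA_character_, nrow = nnode, ncol = nsite)
  score <- integer(nsite)
  children_of <- split(post$edge[, 2], post$edge[, 1])
  parent_order <- unique(post$edge[, 1])  # postorder over internal nodes
  root <- parent_order[length(parent_order)]
  aa_of <- function(cod) unname(tb$aa[cod])
  for (s in seq_len(nsite)) {
    sets <- vector("list", nnode)
    for (i in seq_len(ntip)) {
      cod <- rows[[tree$tip.label[i]]][s]
      sets[[i]] <- if (cod %in% tb$codons) cod else tb$codons  # missing
    }
    nchanges <- 0L
    for (v in parent_order) {
      kids <- children_of[[as.character(v)]]
      cur <- sets[[kids[1]]]
      for (k in kids[-1]) {
        inter <- intersect(cur, sets[[k]])
        if (length(inter)) cur <- inter
        else { cur <- union(cur, sets[[k]]); nchanges <- nchanges + 1L }
      }
      sets[[v]] <- cur
    }
    score[s] <- nchanges
    # top-down resolution
    pick <- function(cands, target_aa) {
      if (length(cands) == 1) return(cands)
      nons <- vapply(cands, function(c) as.integer(aa_of(c) != target_aa),
                     integer(1))
      sort(cands[nons == min(nons)])[1]
    }
    root_set <- sets[[root]]
    states[root, s] <- if (length(root_set) == 1) root_set
      else sort(root_set)[1]
    for (e in rev(seq_len(nrow(post$edge)))) {  # preorder
      par <- post$edge[e, 1]; child <- post$edge[e, 2]
      pst <- states[par, s]
      states[child, s] <- if (pst %in% sets[[child]]) pst
        else pick(sets[[child]], aa_of(pst))
    }
  }
  rownames(states) <- c(tree$tip.label,
                        paste0("node", (ntip + 1):nnode))
  list(states = states, score = score)
}

#' Joint maximum-likelihood ancestral codon states
#'
#' Pupko-style max-product dynamic programming under the MG94xHKY85
#' model with the given kappa/omega and the tree's branch lengths; this
#' is the ancestor reconstruction the counting method is built on
#' ("likelihood ancestor counting").  Deterministic.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param codon_alignment named gapped codon rows.
#' @param kappa,omega model parameters (typically from the global fit).
#' @return list(states = node x site codon matrix, score = NA) in the
#'   same layout as [parsimony_ancestors()].
#' @export
ml_joint_ancestors <- function(tree, codon_alignment, kappa, omega = 1) {
  tb <- codon_tables()
  ids <- names(codon_alignment)
  if (!setequal(ids, tree$tip.label))
    stop("tree leaves do not match alignment ids")
  tips <- tip_states(codon_alignment)
  rownames(tips) <- names(codon_alignment)
  tips <- tips[tree$tip.label, , drop = FALSE]
  nsite <- ncol(tips)
  ntip <- nrow(tips)
  post <- reorder(tree, "postorder")
  nnode <- ntip + post$Nnode
  eig <- mg94_eigen(kappa, omega)
  logP <- lapply(seq_len(nrow(post$edge)), function(e) {
    P <- mg94_pmat(eig, max(post$edge.length[e], 1e-8))
    log(pmax(P, 1e-300))
  })
  root <- post$edge[nrow(post$edge), 1]
  states <- matrix(NA_character_, nrow = nnode, ncol = nsite)
  child_edges <- split(seq_len(nrow(post$edge)), post$edge[, 1])
  for (s in seq_len(nsite)) {
    M <- matrix(0, nnode, 61)     # best log-prob of subtree given parent state
    BP <- matrix(NA_integer_, nnode, 61)
    acc <- matrix(0, nnode, 61)   # sum over processed children, by own state
    for (e in seq_len(nrow(post$edge))) {
      child <- post$edge[e, 2]; par <- post$edge[e, 1]
      if (child <= ntip) {
        obs <- tips[child, s]
        if (is.na(obs)) {
          M[child, ] <- 0
          BP[child, ] <- NA_integer_
        } else {
          M[child, ] <- logP[[e]][, obs]
          BP[child, ] <- obs
        }
      } else {
        tmp <- sweep(logP[[e]], 2, acc[child, ], "+")
        BP[child, ] <- max.col(tmp, ties.method = "first")
        M[child, ] <- tmp[cbind(seq_len(61), BP[child, ])]
      }
      acc[par, ] <- acc[par, ] + M[child, ]
    }
    rs <- which.max(acc[root, ])
    states[root, s] <- tb$codons[rs]
    # top-down backtrack (preorder over edges)
    chosen <- integer(nnode)
    chosen[root] <- rs
    for (e in rev(seq_len(nrow(post$edge)))) {
      par <- post$edge[e, 1]; child <- post$edge[e, 2]
      cs <- BP[child, chosen[par]]
      if (is.na(cs)) cs <- chosen[par]  # missing tip: inherit
      chosen[child] <- cs
      states[child, s] <- tb$codons[cs]
    }
  }
  rownames(states) <- c(post$tip.label, paste0("node", (ntip + 1):nnode))
  list(states = states, score = rep(NA_integer_, nsite))
}

#' SLAC per-site counting test
#'
#' Observed synonymous/nonsynonymous changes are summed over all branches
#' of the ancestral labeling (multi-step codon changes averaged over
#' minimal stop-free paths); expected sites are summed from
#' [ng_site_counts()] over all node states.  Following the counting
#' method's convention, the reported p-value is the one-sided binomial
#' tail for the direction the site leans to: P(X >= NN) when dN > dS
#' (excess nonsynonymous changes), P(X <= NN) when dN < dS, with success
#' probability EN / (EN + ES); the direction is the sign of dN - dS.
#'
#' @param tree `ape::phylo` over the alignment ids.
#' @param codon_alignment named gapped codon rows.
#' @param ancestors result of [parsimony_ancestors()] (computed if NULL).
#' @param kappa transition/transversion ratio used to weight the expected
#'   site fractions (1 = unweighted NG counting); pass the globally
#'   fitted kappa for model-consistent expectations.
#' @return data.frame(site, slac_dN, slac_dS, slac_p, slac_direction, NN,
#'   NS, EN, ES).
#' @export
slac_site_test <- function(tree, codon_alignment, ancestors = NULL,
                           kappa = 1) {
  tb <- codon_tables()
  if (is.null(ancestors)) ancestors <- parsimony_ancestors(tree, codon_alignment)
  st <- ancestors$states
  nsite <- ncol(st)
  edges <- tree$edge
  res <- lapply(seq_len(nsite), function(s) {
    NN <- NS <- 0
    for (e in seq_len(nrow(edges))) {
      a <- st[edges[e, 1], s]; b <- st[edges[e, 2], s]
      if (is.na(a) || is.na(b) || a == b) next
      pc <- codon_path_counts(a, b)
      NS <- NS + pc[["syn"]]; NN <- NN + pc[["non"]]
    }
    site_counts <- vapply(st[, s], function(c)
      if (c %in% tb$codons) ng_site_counts_weighted(c, kappa)
      else c(s = 0, n = 0),
      numeric(2))
    ES <- sum(site_counts["s", ]); EN <- sum(site_counts["n", ])
    dS <- if (ES > 0) NS / ES else 0
    dN <- if (EN > 0) NN / EN else 0
    dir <- sign(dN - dS)
    p <- slac_binom_p(NN, NS, EN, ES)
    data.frame(site = s, slac_dN = dN, slac_dS = dS, slac_p = p,
               slac_direction = dir, NN = NN, NS = NS,
               EN = EN, ES = ES)
  })
  do.call(rbind, res)
}

# --- MG94 likelihood machinery --------------------------------------------

# Tip codon-state indices (NA for gaps/ambiguous codons).
tip_states <- function(codon_alignment) {
  tb <- codon_tables()
  t(vapply(codon_alignment, function(r) {
    cods <- split_codons(r)
    match(cods, tb$codons)
  }, integer(nchar(codon_alignment[[1]]) / 3)))
}

# Log-likelihood of the whole alignment under MG94(kappa, omega) with the
# given branch lengths.  Pruning with 61 x nsites partial matrices.
codon_loglik_alignment <- function(tree, tips, kappa, omega, edge_len) {
  eig <- mg94_eigen(kappa, omega)
  nsite <- ncol(tips)
  ntip <- nrow(tips)
  nnode <- ntip + tree$Nnode
  post <- reorder(tree, "postorder")
  partial <- vector("list", nnode)
  scale_log <- 0
  order_nodes <- unique(post$edge[, 1])
  # children messages: process edges in postorder
  msg <- vector("list", nnode)
  for (e in seq_len(nrow(post$edge))) {
    child <- post$edge[e, 2]
    t <- edge_len[e]
    P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
    P[P < 1e-300] <- 1e-300
    if (child <= ntip) {
      L <- matrix(0, 61, nsite)
      idx <- tips[child, ]
      known <- !is.na(idx)
      L[cbind(idx[known], which(known))] <- 1
      L[, !known] <- 1
    } else {
      L <- partial[[child]]
    }
    msg[[child]] <- P %*% L
    par <- post$edge[e, 1]
    partial[[par]] <- if (is.null(partial[[par]])) msg[[child]]
      else partial[[par]] * msg[[child]]
    # rescale to avoid underflow once the node is complete
  }
  root <- order_nodes[length(order_nodes)]
  lik <- colMeans(partial[[root]])  # uniform root frequencies
  sum(log(pmax(lik, 1e-300))) + scale_log
}

#' Global MG94xHKY85 fit of branch lengths, kappa and mean omega
#'
#' Maximizes the codon likelihood jointly over log branch lengths, log
#' kappa and a single global log omega (L-BFGS-B), starting from
#' NJ-derived branch lengths.
#'
#' @param codon_alignment named gapped codon rows (>= 3 sequences).
#' @param tree topology (`ape::phylo`); branch lengths used as a start if
#'   present.
#' @param max_iter optimizer iteration cap.
#' @return list(tree with fitted lengths, kappa, omega, loglik,
#'   convergence).
#' @export
global_codon_fit <- function(codon_alignment, tree, max_iter = 300) {
  if (length(codon_alignment) < 3) stop("need at least 3 sequences")
  tips <- tip_states(codon_alignment)
  rownames(tips) <- names(codon_alignment)
  post <- reorder(tree, "postorder")
  tips <- tips[tree$tip.label, , drop = FALSE]
  nedge <- nrow(post$edge)
  el0 <- if (!is.null(post$edge.length)) pmax(post$edge.length, 1e-4)
         else rep(0.1, nedge)
  obj <- function(par) {
    el <- exp(par[seq_len(nedge)])
    kappa <- exp(par[nedge + 1])
    omega <- exp(par[nedge + 2])
    -codon_loglik_alignment(post, tips, kappa, omega, el)
  }
  fit <- optim(c(log(el0), log(2), log(0.5)), obj, method = "L-BFGS-B",
               lower = c(rep(log(1e-6), nedge), log(0.1), log(1e-4)),
               upper = c(rep(log(20), nedge), log(50), log(50)),
               control = list(maxit = max_iter))
  out_tree <- post
  out_tree$edge.length <- exp(fit$par[seq_len(nedge)])
  list(tree = out_tree, kappa = exp(fit$par[nedge + 1]),
       omega = exp(fit$par[nedge + 2]), loglik = -fit$value,
       convergence = fit$convergence)
}

# Per-site log-likelihood using cached eigensystem messages (vectors, not
# full P matrices): edge message = U (exp(lambda * t) * (U' L_child)).
site_loglik <- function(post, tipcol, eig, edge_len, ntip) {
  nnode <- ntip + post$Nnode
  partial <- vector("list", nnode)
  U <- eig$vectors; lam <- eig$values
  for (e in seq_len(nrow(post$edge))) {
    child <- post$edge[e, 2]
    if (child <= ntip) {
      L <- numeric(61)
      if (is.na(tipcol[child])) L[] <- 1 else L[tipcol[child]] <- 1
    } else L <- partial[[child]]
    m <- U %*% (exp(lam * edge_len[e]) * crossprod(U, L))
    m[m < 1e-300] <- 1e-300
    par <- post$edge[e, 1]
    partial[[par]] <- if (is.null(partial[[par]])) m else partial[[par]] * m
  }
  root <- post$edge[nrow(post$edge), 1]
  log(max(mean(partial[[root]]), 1e-300))
}

#' FEL per-site likelihood-ratio test
#'
#' With branch lengths and kappa fixed from the global fit, each site's
#' synonymous rate alpha and nonsynonymous rate beta are estimated by
#' maximum likelihood; the null constrains alpha = beta and the p-value
#' comes from a chi-squared test with 1 degree of freedom on 2*deltaLnL.
#'
#' @param codon_alignment named gapped codon rows.
#' @param fit result of [global_codon_fit()] (tree + kappa reused).
#' @return data.frame(site, fel_alpha, fel_beta, fel_p, fel_direction).
#' @export
fel_site_fit <- function(codon_alignment, fit) {
  tips <- tip_states(codon_alignment)
  rownames(tips) <- names(codon_alignment)
  post <- fit$tree  # already postorder with fitted lengths
  tips <- tips[post$tip.label, , drop = FALSE]
  ntip <- nrow(tips)
  el <- post$edge.length
  kappa <- fit$kappa
  eig1 <- mg94_eigen(kappa, 1)
  nsite <- ncol(tips)
  res <- lapply(seq_len(nsite), function(s) {
    col <- tips[, s]
    obs <- unique(col[!is.na(col)])
    if (length(obs) <= 1) {
      return(data.frame(site = s, fel_alpha = 0, fel_beta = 0, fel_p = 1,
                        fel_direction = 0))
    }
    # null: alpha = beta = r, a pure rescaling of the neutral matrix
    null_ll <- function(logr)
      -site_loglik(post, col, eig1, exp(logr) * el, ntip)
    n0 <- optimize(null_ll, c(log(1e-4), log(50)))
    # alternative: overall scale alpha, ratio omega = beta/alpha
    alt_ll <- function(p) {
      a <- exp(p[1]); w <- exp(p[2])
      -site_loglik(post, col, mg94_eigen(kappa, w), a * el, ntip)
    }
    a0 <- optim(c(n0$minimum, 0), alt_ll, method = "Nelder-Mead",
                control = list(maxit = 150, reltol = 1e-7))
    lrt <- max(0, 2 * (n0$objective - a0$value))
    alpha <- exp(a0$par[1])
    beta <- alpha * exp(a0$par[2])
    data.frame(site = s, fel_alpha = alpha, fel_beta = beta,
               fel_p = pchisq(lrt, df = 1, lower.tail = FALSE),
               fel_direction = sign(beta - alpha))
  })
  do.call(rbind, res)
}

#' Consensus selection calls from SLAC and FEL
#'
#' A site is called positively (negatively) selected iff both methods
#' agree on the direction with p below the threshold; everything else is
#' neutral.
#'
#' @param slac result of [slac_site_test()].
#' @param fel result of [fel_site_fit()].
#' @param p_threshold significance cutoff (default 0.1).
#' @return list(calls = per-site data.frame with `consensus`, summary =
#'   c(positive =, negative =)).
#' @export
consensus_calls <- function(slac, fel, p_threshold = 0.1) {
  if (nrow(slac) != nrow(fel)) stop("site-call length mismatch")
  calls <- merge(slac, fel, by = "site")
  calls <- calls[order(calls$site), ]
  pos <- !is.na(calls$slac_p) & calls$slac_p < p_threshold &
    calls$slac_direction > 0 & calls$fel_p < p_threshold &
    calls$fel_direction > 0
  neg <- !is.na(calls$slac_p) & calls$slac_p < p_threshold &
    calls$slac_direction < 0 & calls$fel_p < p_threshold &
    calls$fel_direction < 0
  calls$consensus <- ifelse(pos, "positive", ifelse(neg, "negative",
                                                    "neutral"))
  list(calls = calls,
       summary = c(positive = sum(pos), negative = sum(neg)))
}

# Pairwise Nei-Gojobori counts for two gapped codon rows.
ng_pairwise <- function(row_a, row_b) {
  tb <- codon_tables()
  ca <- split_codons(row_a); cb <- split_codons(row_b)
  ok <- ca %in% tb$codons & cb %in% tb$codons
  S <- N <- Sd <- Nd <- 0
  for (i in which(ok)) {
    sa <- ng_site_counts(ca[i]); sb <- ng_site_counts(cb[i])
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    if (ca[i] != cb[i]) {
      pc <- codon_path_counts(ca[i], cb[i])
      Sd <- Sd + pc[["syn"]]; Nd <- Nd + pc[["non"]]
    }
  }
  c(S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Pairwise dN and dS by Nei-Gojobori counting with Jukes-Cantor correction
#' @param row_a,row_b gapped codon rows of equal length.
#' @return c(dS, dN, pS, pN); saturated proportions give Inf.
#' @export
ng_pair_dnds <- function(row_a, row_b) {
  x <- ng_pairwise(row_a, row_b)
  jc <- function(p) if (p >= 3 / 4) Inf else -3 / 4 * log(1 - 4 * p / 3)
  pS <- if (x[["S"]] > 0) x[["Sd"]] / x[["S"]] else 0
  pN <- if (x[["N"]] > 0) x[["Nd"]] / x[["N"]] else 0
  c(dS = jc(pS), dN = jc(pN), pS = pS, pN = pN)
}

#' dS-saturation guard
#'
#' Maximum pairwise Nei-Gojobori dS (Jukes-Cantor corrected) across the
#' alignment; the analysis passes iff it stays below the ceiling (beyond
#' which synonymous saturation distorts dN/dS).
#'
#' @param codon_alignment named gapped codon rows (>= 2).
#' @param threshold dS ceiling (default 2).
#' @return list(max_dS, pass, dS = pairwise matrix).
#' @export
ds_saturation_check <- function(codon_alignment, threshold = 2) {
  n <- length(codon_alignment)
  if (n < 2) stop("need at least two sequences")
  ids <- names(codon_alignment)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- ng_pair_dnds(codon_alignment[[i]],
                                       codon_alignment[[j]])[["dS"]]
  }
  mx <- max(d)
  list(max_dS = mx, pass = is.finite(mx) && mx < threshold, dS = d)
}

#' Closed-form 2x2 chi-squared test (no continuity correction)
#' @param tab 2x2 matrix of counts.
#' @return list(statistic, p_value).
#' @export
chisq2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Map site calls onto transmembrane intervals
#'
#' Assigns each site to TM or non-TM by the given intervals (alignment
#' coordinates) and tabulates positive/negative consensus calls per
#' region class.
#'
#' @param calls per-site data.frame with `site` and `consensus`.
#' @param tm_intervals data.frame(start, end), non-overlapping.
#' @return list(table = counts matrix, calls = input with `region`).
#' @export
site_region_map <- function(calls, tm_intervals) {
  if (nrow(tm_intervals) > 1) {
    iv <- tm_intervals[order(tm_intervals$start), ]
    if (any(iv$start[-1] <= iv$end[-nrow(iv)]))
      stop("overlapping TM intervals")
  }
  in_tm <- vapply(calls$site, function(s)
    any(s >= tm_intervals$start & s <= tm_intervals$end), logical(1))
  calls$region <- ifelse(in_tm, "TM", "non-TM")
  tab <- table(factor(calls$region, c("TM", "non-TM")),
               factor(calls$consensus, c("positive", "negative", "neutral")))
  list(table = unclass(tab), calls = calls)
}

#' Chi-squared comparison of TM-site fractions between two families
#'
#' Compares the fraction of positively selected sites falling in
#' transmembrane regions between two site sets (e.g. 13 of 28 vs 4 of 14)
#' with the closed-form 2x2 chi-squared test.
#'
#' @param tm1,total1 TM-positive and total positive sites, family 1.
#' @param tm2,total2 same for family 2.
#' @return list(statistic, p_value).
#' @export
tm_fraction_chisq <- function(tm1, total1, tm2, total2) {
  chisq2x2(matrix(c(tm1, total1 - tm1, tm2, total2 - tm2), 2, 2,
                  byrow = TRUE))
}
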