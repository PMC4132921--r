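# Synthetic-genome generator.  Produces scaffolds carrying clustered,
# intronless, single-exon receptor genes born by duplication, codon
# alignments with site-class-heterogeneous omega truth, pseudogene and
# allelic confounders, and a class-I transposable-element landscape with
# configurable enrichment near one family's genes.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Simulate a bifurcating gene-family tree
#'
#' A random bifurcating topology with uniform random branch lengths,
#' rescaled to a fixed total tree length (expected substitutions per
#' codon on the neutral scale).  This emulates a family born from a
#' single ancestral gene by repeated duplications spread through time;
#' the true duplication tempo is unknown, so length is distributed
#' roughly evenly over branches rather than concentrated in deep
#' coalescent intervals.
#'
#' @param n_extant number of extant genes (>= 1).
#' @param seed RNG seed.
#' @param total_length total branch length after rescaling.
#' @param tip_prefix label prefix for the leaves.
#' @return an `ape::phylo` tree (degenerate single-leaf structure for
#'   `n_extant = 1`).
#' @export
simulate_gene_tree <- function(n_extant, seed, total_length = 6,
                               tip_prefix = "g") {
  if (!is.numeric(n_extant) || n_extant < 1)
    stop("invalid parameter: n_extant must be >= 1")
  n_extant <- as.integer(n_extant)
  labels <- sprintf("%s%02d", tip_prefix, seq_len(n_extant))
  if (n_extant == 1L) {
    return(structure(list(edge = matrix(integer(), 0, 2),
                          tip.label = labels, Nnode = 0L,
                          edge.length = numeric(0)), class = "phylo"))
  }
  with_seed(seed, {
    tr <- ape::rtree(n_extant, tip.label = labels)
    tr$edge.length <- tr$edge.length * total_length / sum(tr$edge.length)
    tr
  })
}

# Normalize a site_class_mix given as list of c(prop, omega) pairs (or a
# 2-column matrix / data.frame with columns prop, omega).
normalize_mix <- function(site_class_mix) {
  if (is.null(site_class_mix) || !length(site_class_mix))
    stop("invalid parameter: empty site_class_mix")
  if (is.data.frame(site_class_mix)) {
    m <- cbind(site_class_mix[[1]], site_class_mix[[2]])
  } else if (is.matrix(site_class_mix)) {
    m <- site_class_mix
  } else {
    m <- do.call(rbind, site_class_mix)
  }
  colnames(m) <- c("prop", "omega")
  if (any(m[, "prop"] < 0 | m[, "prop"] > 1) ||
      abs(sum(m[, "prop"]) - 1) > 1e-9)
    stop("invalid parameter: site-class proportions must lie in [0,1] and sum to 1")
  if (any(m[, "omega"] < 0)) stop("invalid parameter: omega must be >= 0")
  m
}

#' Evolve codon sequences along a gene tree with site-class omega
#'
#' MG94-style codon substitution with HKY mutation (`kappa`) and a
#' per-site omega multiplier on nonsynonymous rates; substitutions into
#' stop codons have rate zero; the root sequence is stop-free by
#' construction.  Site classes are assigned in exact proportions and
#' shuffled over positions.
#'
#' @param tree `ape::phylo` with branch lengths (expected subst./codon).
#' @param n_codons number of codons.
#' @param site_class_mix list of `c(proportion, omega)` pairs summing to 1.
#' @param kappa transition/transversion ratio.
#' @param seed RNG seed.
#' @param root_seq optional root codon sequence (in-frame string); drawn
#'   uniformly over sense codons when NULL.
#' @param site_class optional per-codon class assignment to reuse.
#' @return list with `alignment` (named in-frame CDS per leaf, no gaps),
#'   `site_class` (class index per codon), `site_omega` (omega per codon)
#'   and `class_omega` (omega per class).
#' @export
evolve_codons <- function(tree, n_codons, site_class_mix, kappa, seed,
                          root_seq = NULL, site_class = NULL) {
  mix <- normalize_mix(site_class_mix)
  tb <- codon_tables()
  nclass <- nrow(mix)
  # exact class counts: floor + largest-remainder
  raw <- mix[, "prop"] * n_codons
  cnt <- floor(raw)
  rem <- n_codons - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    if (is.null(site_class))
      site_class <- sample(rep.int(seq_len(nclass), cnt))
    root <- if (is.null(root_seq))
      sample(seq_along(tb$codons), n_codons, replace = TRUE)
    else match(split_codons(root_seq), tb$codons)
    if (anyNA(root)) stop("root_seq contains stop or invalid codons")
    eigs <- lapply(mix[, "omega"], function(w) mg94_eigen(kappa, w))
    if (is.null(tree$edge) || nrow(tree$edge) == 0) {  # single leaf
      aln <- setNames(paste(tb$codons[root], collapse = ""), tree$tip.label)
      return(list(alignment = aln, site_class = site_class,
                  site_omega = mix[site_class, "omega"],
                  class_omega = mix[, "omega"]))
    }
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nrow = nnode, ncol = n_codons)
    states[ntip + 1L, ] <- root
    ord <- reorder(tree, "cladewise")  # parents before children
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      t <- ord$edge.length[e]
      cur <- states[par, ]
      nxt <- integer(n_codons)
      for (k in seq_len(nclass)) {
        idx <- which(site_class == k)
        if (!length(idx)) next
        P <- mg94_pmat(eigs[[k]], t)
        # sample endpoint states for all sites of this class on this branch
        for (s in idx) nxt[s] <- sample.int(61L, 1L, prob = P[cur[s], ])
      }
      states[child, ] <- nxt
    }
    aln <- vapply(seq_len(ntip), function(i)
      paste(tb$codons[states[i, ]], collapse = ""), character(1))
    names(aln) <- tree$tip.label
    list(alignment = aln, site_class = site_class,
         site_omega = mix[site_class, "omega"], class_omega = mix[, "omega"])
  })
}

# Evolve codon indices along a single branch of length t, per site class.
evolve_branch <- function(states, site_class, eigs, t) {
  out <- states
  for (k in seq_along(eigs)) {
    idx <- which(site_class == k)
    if (!length(idx)) next
    P <- mg94_pmat(eigs[[k]], t)
    for (s in idx) out[s] <- sample.int(61L, 1L, prob = P[states[s], ])
  }
  out
}

#' Simulate two sister receptor families from a shared ancestor
#'
#' The two families are the closest relatives of one another (as T2R and
#' V1R/ORA are), so they must be simulated as sister clades: a shared
#' ancestral gene evolves along two stem branches, then each family
#' radiates under its own site-class omega mix.  This keeps all
#' sequences homologous, making cross-family alignment, reciprocal
#' outgroup rooting and family assignment meaningful.
#'
#' @param spec1,spec2 per-family lists: n (leaves), n_codons, mix
#'   (site_class_mix), tree_length, prefix.
#' @param kappa transition/transversion ratio.
#' @param seed RNG seed.
#' @param stem_length branch length from the shared ancestor to each
#'   family ancestor (expected substitutions/codon).
#' @return list of two family results (as [evolve_codons()], plus
#'   `tree`), named by the prefixes.
#' @export
simulate_family_pair <- function(spec1, spec2, kappa = 4, seed = 1,
                                 stem_length = 0.8) {
  tb <- codon_tables()
  n_codons <- spec1$n_codons
  stopifnot(n_codons == spec2$n_codons)
  root <- with_seed(seed, sample(seq_along(tb$codons), n_codons,
                                 replace = TRUE))
  out <- list()
  for (i in 1:2) {
    spec <- list(spec1, spec2)[[i]]
    mix <- normalize_mix(spec$mix)
    raw <- mix[, "prop"] * n_codons
    cnt <- floor(raw)
    rem <- n_codons - sum(cnt)
    if (rem > 0) {
      o <- order(raw - cnt, decreasing = TRUE)
      cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
    }
    fam <- with_seed(seed + 31L * i, {
      site_class <- sample(rep.int(seq_len(nrow(mix)), cnt))
      eigs <- lapply(mix[, "omega"], function(w) mg94_eigen(kappa, w))
      anc <- evolve_branch(root, site_class, eigs, stem_length)
      list(site_class = site_class,
           anc = paste(tb$codons[anc], collapse = ""))
    })
    tree <- simulate_gene_tree(spec$n, seed = seed + 31L * i + 1L,
                               total_length = spec$tree_length,
                               tip_prefix = spec$prefix)
    ev <- evolve_codons(tree, n_codons, spec$mix, kappa,
                        seed = seed + 31L * i + 2L,
                        root_seq = fam$anc, site_class = fam$site_class)
    ev$tree <- tree
    out[[spec$prefix]] <- ev
  }
  out
}

random_background <- function(n, gc = 0.42) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Plant coding sequences on synthetic scaffolds in clusters
#'
#' Genes are grouped into clusters of sampled size, clusters assigned to
#' scaffolds (one cluster per scaffold while scaffolds last, then cycling
#' with a large separating gap), placed on random strands with lognormal
#' intergenic gaps, and embedded in i.i.d. background sequence of the
#' stated GC content.
#'
#' @param genes named character vector of in-frame CDS.
#' @param scaffold_lengths named (or unnamed) vector of scaffold lengths (bp).
#' @param genes_per_cluster list(min=, max=) uniform integer cluster size.
#' @param intergenic_gap list(meanlog=, sdlog=) lognormal gap (bp).
#' @param seed RNG seed.
#' @param gc background GC content.
#' @param meta optional data.frame with gene_id, is_pseudogene, is_allele_of.
#' @param family family label recorded in the truth table.
#' @return list(scaffolds = named character, loci = truth data.frame with
#'   0-based half-open coordinates).
#' @export
plant_family <- function(genes, scaffold_lengths,
                         genes_per_cluster = list(min = 3, max = 8),
                         intergenic_gap = list(meanlog = log(31000), sdlog = 0.5),
                         seed = 1, gc = 0.42, meta = NULL, family = "T2R") {
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("%s_scf%02d", family,
                                       seq_along(scaffold_lengths))
  with_seed(seed, {
    ids <- names(genes)
    ord <- sample(ids)
    size_range <- genes_per_cluster$min:genes_per_cluster$max
    sizes <- integer(0)
    while (sum(sizes) < length(ord)) {
      sizes <- c(sizes, if (length(size_range) == 1) size_range
                 else sample(size_range, 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - length(ord))
    sizes <- sizes[sizes > 0]
    clusters <- split(ord, rep(seq_along(sizes), sizes))
    nscf <- length(scaffold_lengths)
    scf_of_cluster <- ((seq_along(clusters) - 1) %% nscf) + 1
    loci <- list()
    cursor <- setNames(rep(NA_real_, nscf), names(scaffold_lengths))
    for (ci in seq_along(clusters)) {
      scf <- names(scaffold_lengths)[scf_of_cluster[ci]]
      len <- scaffold_lengths[[scf_of_cluster[ci]]]
      pos <- if (is.na(cursor[scf])) runif(1, 5000, 20000)
             else cursor[scf] + 150000  # separate co-resident clusters
      for (g in clusters[[ci]]) {
        glen <- nchar(genes[[g]])
        if (pos + glen > len)
          stop(sprintf("placement error: genes do not fit on scaffold %s", scf))
        loci[[length(loci) + 1L]] <- data.frame(
          scaffold_id = scf, start = round(pos), end = round(pos) + glen,
          strand = sample(c("+", "-"), 1), gene_id = g,
          stringsAsFactors = FALSE)
        pos <- round(pos) + glen +
          rlnorm(1, intergenic_gap$meanlog, intergenic_gap$sdlog)
      }
      cursor[scf] <- pos
    }
    loci <- do.call(rbind, loci)
    loci$family <- family
    if (!is.null(meta)) {
      m <- meta[match(loci$gene_id, meta$gene_id), ]
      loci$is_pseudogene <- m$is_pseudogene
      loci$is_allele_of <- m$is_allele_of
    } else {
      loci$is_pseudogene <- FALSE
      loci$is_allele_of <- NA_character_
    }
    scaffolds <- vapply(seq_len(nscf), function(i) {
      s <- strsplit(random_background(scaffold_lengths[[i]], gc), "")[[1]]
      here <- loci[loci$scaffold_id == names(scaffold_lengths)[i], ]
      for (r in seq_len(nrow(here))) {
        cds <- genes[[here$gene_id[r]]]
        if (here$strand[r] == "-") cds <- revcomp(cds)
        s[(here$start[r] + 1):here$end[r]] <- strsplit(cds, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    names(scaffolds) <- names(scaffold_lengths)
    list(scaffolds = scaffolds, loci = loci)
  })
}

#' Bundled repeat motif library
#'
#' A small fixed library of synthetic repeat-element consensus motifs, a
#' few per class, generated deterministically.  These are emitted both as
#' annotation intervals and as literal sequence insertions so that a
#' .out-parsing path and a naive sequence-scanner path can both be tested.
#' @return data.frame with family, class, seq.
#' @export
repeat_motif_library <- function() {
  if (!is.null(.cm_cache$motif_lib)) return(.cm_cache$motif_lib)
  spec <- list(
    c("SINE_A", "SINE", 180), c("SINE_B", "SINE", 150),
    c("LINE_A", "LINE", 300), c("LINE_B", "LINE", 250),
    c("LTR_A", "LTR", 220),
    c("DNA_A", "DNA", 200),
    c("SRNA_A", "SmallRNA", 90),
    c("SAT_A", "Satellite/simple/low", 120))
  lib <- with_seed(920731, {
    do.call(rbind, lapply(spec, function(x) data.frame(
      family = x[1], class = x[2],
      seq = random_background(as.integer(x[3]), gc = 0.5),
      stringsAsFactors = FALSE)))
  })
  .cm_cache$motif_lib <- lib
  lib
}

#' Sprinkle repeat elements over scaffolds
#'
#' Elements of each class are placed by a Poisson process at the stated
#' background density (elements per kb); within `enrichment_window`-wide
#' regions centered on flagged genes, class-I (SINE/LINE/LTR) density is
#' multiplied by `near_gene_multiplier`.  Elements avoid gene bodies and
#' one another; each is a lightly mutated copy of a library motif written
#' into the scaffold sequence.
#'
#' @param scaffolds named character vector.
#' @param loci truth loci data.frame (or NULL for plain background).
#' @param background_density named numeric, elements/kb per class.
#' @param near_gene_multiplier dimensionless factor for class I near
#'   enriched genes.
#' @param enrichment_window window width (bp) centered on gene midpoints.
#' @param seed RNG seed.
#' @param enriched_gene_ids gene ids whose neighborhoods are enriched.
#' @return list(scaffolds = sequences with elements written in,
#'   elements = annotation data.frame).
#' @export
sprinkle_repeats <- function(scaffolds, loci = NULL,
                             background_density = c(
                               SINE = 0.15, LINE = 0.15, LTR = 0.06,
                               DNA = 0.08, SmallRNA = 0.01,
                               "Satellite/simple/low" = 0.05),
                             near_gene_multiplier = 1,
                             enrichment_window = 20000, seed = 1,
                             enriched_gene_ids = character()) {
  stopifnot(all(background_density >= 0), near_gene_multiplier >= 0)
  lib <- repeat_motif_library()
  class1 <- c("SINE", "LINE", "LTR")
  with_seed(seed, {
    out_elems <- list()
    for (scf in names(scaffolds)) {
      slen <- nchar(scaffolds[[scf]])
      schars <- NULL
      gene_iv <- if (!is.null(loci)) loci[loci$scaffold_id == scf, ] else NULL
      occupied <- if (!is.null(gene_iv) && nrow(gene_iv))
        IRanges::IRanges(gene_iv$start + 1L, gene_iv$end)
      else IRanges::IRanges()
      enr <- if (!is.null(gene_iv) && nrow(gene_iv)) {
        g <- gene_iv[gene_iv$gene_id %in% enriched_gene_ids, ]
        if (nrow(g)) {
          mid <- floor((g$start + g$end) / 2)
          IRanges::reduce(IRanges::IRanges(
            pmax(1L, mid - enrichment_window %/% 2L + 1L),
            pmin(slen, mid + enrichment_window %/% 2L)))
        } else IRanges::IRanges()
      } else IRanges::IRanges()
      enr_len <- sum(IRanges::width(enr))
      bg_len <- slen - enr_len
      for (cls in names(background_density)) {
        dens <- background_density[[cls]] / 1000
        mult <- if (cls %in% class1) near_gene_multiplier else 1
        n_bg <- rpois(1, dens * bg_len)
        n_enr <- rpois(1, dens * mult * enr_len)
        motifs <- lib[lib$class == cls, , drop = FALSE]
        place_one <- function(in_enriched) {
          m <- motifs[sample.int(nrow(motifs), 1), ]
          mlen <- nchar(m$seq)
          for (try in 1:40) {
            if (in_enriched) {
              w <- IRanges::width(enr)
              k <- sample.int(length(enr), 1, prob = w)
              lo <- IRanges::start(enr)[k]; hi <- IRanges::end(enr)[k]
            } else { lo <- 1L; hi <- slen }
            st <- floor(runif(1, lo, max(lo + 1, hi - mlen)))
            iv <- IRanges::IRanges(st, st + mlen - 1L)
            if (IRanges::end(iv) > slen) next
            if (!in_enriched && length(enr) &&
                sum(IRanges::countOverlaps(iv, enr))) next
            if (sum(IRanges::countOverlaps(iv, occupied))) next
            occupied <<- c(occupied, iv)
            return(data.frame(scaffold_id = scf, start = st - 1L,
                              end = st - 1L + mlen,
                              strand = sample(c("+", "-"), 1),
                              family = m$family, class = m$class,
                              stringsAsFactors = FALSE))
          }
          NULL
        }
        placed <- c(lapply(seq_len(n_bg), function(i) place_one(FALSE)),
                    if (enr_len > 0)
                      lapply(seq_len(n_enr), function(i) place_one(TRUE)))
        placed <- placed[!vapply(placed, is.null, logical(1))]
        if (length(placed)) out_elems <- c(out_elems, placed)
      }
    }
    elements <- if (length(out_elems)) do.call(rbind, out_elems)
      else data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), class = character())
    # write the element sequences into the scaffolds (2% point mutations)
    if (nrow(elements)) {
      seqs <- lapply(scaffolds, function(s) strsplit(s, "")[[1]])
      for (r in seq_len(nrow(elements))) {
        m <- lib$seq[lib$family == elements$family[r]][1]
        mv <- strsplit(m, "")[[1]]
        nm <- rbinom(1, length(mv), 0.02)
        if (nm > 0) {
          at <- sample.int(length(mv), nm)
          mv[at] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
        }
        if (elements$strand[r] == "-")
          mv <- rev(chartr("ACGT", "TGCA", mv))
        seqs[[elements$scaffold_id[r]]][
          (elements$start[r] + 1):elements$end[r]] <- mv
      }
      scaffolds <- vapply(seqs, paste, character(1), collapse = "")
    }
    list(scaffolds = scaffolds, elements = elements)
  })
}

#' Inject pseudogene and allelic-variant confounders
#'
#' A fraction of genes is pseudogenized in place (1-2 in-frame disruptions:
#' premature stop codons, or a single-base deletion whose frame is restored
#' by a compensating insertion within 30 bp); a fraction gains a
#' near-identical allelic copy (< 2% amino-acid divergence) to be planted
#' at a second locus.
#'
#' @param genes named character vector of in-frame CDS.
#' @param pseudogene_fraction,allele_fraction fractions in `[0, 1]`.
#' @param seed RNG seed.
#' @return list(genes = modified/extended gene set, meta = data.frame with
#'   gene_id, is_pseudogene, n_disruptions, is_allele_of).
#' @export
inject_confounders <- function(genes, pseudogene_fraction = 0,
                               allele_fraction = 0, seed = 1) {
  stopifnot(pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            allele_fraction >= 0, allele_fraction <= 1)
  tb <- codon_tables()
  with_seed(seed, {
    ids <- names(genes)
    meta <- data.frame(gene_id = ids, is_pseudogene = FALSE,
                       n_disruptions = 0L, is_allele_of = NA_character_,
                       stringsAsFactors = FALSE)
    n_ps <- round(pseudogene_fraction * length(ids))
    ps_ids <- if (n_ps > 0) sample(ids, n_ps) else character()
    for (g in ps_ids) {
      ndis <- sample(1:2, 1)
      cds <- genes[[g]]
      for (d in seq_len(ndis)) {
        ncod <- nchar(cds) %/% 3
        at <- sample(seq(10, ncod - 10), 1)
        if (d == 1 || runif(1) < 0.5) {  # always >= 1 premature stop
          stopc <- sample(tb$stop_codons, 1)
          substr(cds, (at - 1) * 3 + 1, at * 3) <- stopc
        } else {               # compensated frameshift
          del_at <- (at - 1) * 3 + sample(1:3, 1)
          ins_at <- del_at + sample(3:29, 1)
          v <- strsplit(cds, "")[[1]]
          v <- v[-del_at]
          v <- append(v, sample(c("A", "C", "G", "T"), 1),
                      after = min(ins_at, length(v)))
          cds <- paste(v, collapse = "")
        }
      }
      genes[[g]] <- cds
      meta$is_pseudogene[meta$gene_id == g] <- TRUE
      meta$n_disruptions[meta$gene_id == g] <- ndis
    }
    n_al <- round(allele_fraction * length(ids))
    al_src <- if (n_al > 0) sample(setdiff(ids, ps_ids),
                                   min(n_al, length(ids) - n_ps))
              else character()
    for (g in al_src) {
      cds <- genes[[g]]
      ncod <- nchar(cds) %/% 3
      nmut <- max(1L, floor(0.01 * ncod))  # < 2% aa divergence
      at <- sample(seq(2, ncod - 1), nmut)
      for (a in at) {
        repeat {
          newc <- sample(tb$codons, 1)
          old <- substr(cds, (a - 1) * 3 + 1, a * 3)
          if (tb$aa[newc] != tb$aa64[old]) break
        }
        substr(cds, (a - 1) * 3 + 1, a * 3) <- newc
      }
      nid <- paste0(g, "a")
      genes[[nid]] <- cds
      meta <- rbind(meta, data.frame(gene_id = nid, is_pseudogene = FALSE,
                                     n_disruptions = 0L, is_allele_of = g,
                                     stringsAsFactors = FALSE))
    }
    list(genes = genes, meta = meta)
  })
}
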