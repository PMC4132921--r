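# Repertoire mining: a deterministic seeded translated homology search
# (exact protein k-mer seeds, affine-gap Smith-Waterman extension with
# BLOSUM62), recursive query closure, ORF repair under the <= 2
# stop/frameshift rule, allele collapsing at > 98% identity, and the
# distributed-divergence acceptance check.

#' Translate a nucleotide sequence in all six reading frames
#'
#' @param dna nucleotide string over A/C/G/T/N.
#' @return named character vector with frames `+1,+2,+3,-1,-2,-3`; stops
#'   are `*`, codons containing N translate to `X`.
#' @export
translate_six_frames <- function(dna) {
  if (grepl("[^ACGTN]", dna))
    stop("alphabet error: sequence contains characters outside {A,C,G,T,N}")
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  tr1 <- function(s, f) {
    n <- length(s) - f
    n <- n - n %% 3
    if (n <= 0) return("")
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(s, f + 1, f + n), if.fuzzy.codon = "solve")))
  }
  setNames(c(vapply(0:2, function(f) tr1(fwd, f), character(1)),
             vapply(0:2, function(f) tr1(rev, f), character(1))),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# Integer codes of all protein k-mers of a string ('A'..'Z' base 26);
# windows containing non-letters (gaps, stops) are NA.
encode_kmers <- function(s, k) {
  v <- utf8ToInt(s) - 65L
  n <- length(v)
  if (n < k) return(integer(0))
  ok <- v >= 0L & v <= 25L
  code <- integer(n - k + 1L)
  good <- rep(TRUE, n - k + 1L)
  for (i in seq_len(k)) {
    idx <- i:(n - k + i)
    code <- code * 26L + v[idx]
    good <- good & ok[idx]
  }
  code[!good] <- NA_integer_
  code
}

# Precompute six-frame translations and k-mer codes for every scaffold.
build_search_index <- function(scaffolds, word_len = 4) {
  lapply(scaffolds, function(s) {
    fr <- translate_six_frames(s)
    list(frames = fr,
         codes = lapply(fr, encode_kmers, k = word_len),
         length = nchar(s))
  })
}

# Convert a frame-coordinate hit [t_lo, t_hi] (1-based aa positions in the
# frame translation) to 0-based half-open genomic coordinates.
frame_to_genomic <- function(frame_name, t_lo, t_hi, scaffold_len) {
  f <- as.integer(substr(frame_name, 2, 2)) - 1L
  if (startsWith(frame_name, "+")) {
    list(start = f + 3L * (t_lo - 1L), end = f + 3L * t_hi, strand = "+")
  } else {
    list(start = scaffold_len - (f + 3L * t_hi),
         end = scaffold_len - (f + 3L * (t_lo - 1L)), strand = "-")
  }
}

# Best ungapped max-subarray (Kadane) BLOSUM score of a query against a
# frame translation along the given diagonals; a cheap prefilter that
# spares full alignments for windows that cannot reach the score floor.
diag_prefilter <- function(query_chars, frame_str, diags, B) {
  flen <- nchar(frame_str)
  qlen <- length(query_chars)
  best <- -Inf
  for (d in diags) {
    i1 <- max(1L, 1L - d); i2 <- min(qlen, flen - d)
    if (i2 - i1 < 30L) next
    tv <- strsplit(substr(frame_str, i1 + d, i2 + d), "")[[1]]
    qv <- query_chars[i1:i2]
    qv[!qv %in% rownames(B)] <- "X"
    tv[!tv %in% rownames(B)] <- "X"
    s <- B[cbind(qv, tv)]
    cs <- cumsum(s)
    best <- max(best, max(cs - cummin(c(0, cs[-length(cs)]))))
  }
  best
}

# Greedy merge: same scaffold + strand with > `frac` mutual overlap keeps
# only the higher-scoring hit.
merge_hits <- function(hits, frac = 0.5) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(-hits$raw_score), ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- hits[keep, ]
      same <- prev$scaffold_id == hits$scaffold_id[i] &
        prev$strand == hits$strand[i]
      if (any(same)) {
        p <- prev[same, ]
        ov <- pmax(0, pmin(p$end, hits$end[i]) - pmax(p$start, hits$start[i]))
        mut <- ov > frac * (p$end - p$start) &
          ov > frac * (hits$end[i] - hits$start[i])
        if (any(mut)) ok <- FALSE
      }
    }
    keep[i] <- ok
  }
  out <- hits[keep, ]
  rownames(out) <- NULL
  out
}

#' Seeded translated homology search
#'
#' Finds locally optimal gapped alignments (BLOSUM62, affine gaps) between
#' protein queries and the six-frame translations of genomic scaffolds,
#' extended from exact k-mer seeds.  Overlapping same-strand hits are
#' merged keeping the best score; hits whose aligned genomic region is
#' shorter than `min_region_len` residues are discarded.
#'
#' @param queries named character vector of protein queries.
#' @param scaffolds named character vector of genomic sequences.
#' @param word_len exact-seed length (residues).
#' @param min_region_len minimum aligned region length (residues).
#' @param min_score minimum raw alignment score.
#' @param index optional precomputed [build_search_index()] result.
#' @return CandidateLocus data.frame: scaffold_id, start, end (0-based
#'   half-open), strand, frame, protein, raw_score, query_id.
#' @export
seeded_translated_search <- function(queries, scaffolds, word_len = 4,
                                     min_region_len = 200, min_score = 100,
                                     index = NULL) {
  if (!length(queries)) stop("queries must be non-empty")
  empty <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = character(), protein = character(),
                      raw_score = numeric(), query_id = character(),
                      stringsAsFactors = FALSE)
  if (!length(scaffolds)) return(empty)
  if (is.null(index)) index <- build_search_index(scaffolds, word_len)
  qtab <- data.table::rbindlist(lapply(names(queries), function(q) {
    cd <- encode_kmers(queries[[q]], word_len)
    ok <- !is.na(cd)
    data.table::data.table(code = cd[ok], qid = q, qpos = which(ok))
  }))
  if (!nrow(qtab)) return(empty)
  qtab <- unique(qtab)
  data.table::setkey(qtab, code)
  qset <- unique(qtab$code)
  hits <- list()
  for (scf in names(index)) {
    ix <- index[[scf]]
    for (fr in names(ix$frames)) {
      codes <- ix$codes[[fr]]
      pos <- which(codes %in% qset)
      if (!length(pos)) next
      mt <- qtab[data.table::data.table(code = codes[pos], tpos = pos),
                 on = "code", allow.cartesian = TRUE]
      frame_windows <- list()
      for (q in unique(mt$qid)) {
        sub <- mt[mt$qid == q, ]
        qlen <- nchar(queries[[q]])
        flen <- nchar(ix$frames[[fr]])
        # cluster seeds by target position, then require diagonal
        # coherence (true homologies share a narrow diagonal band;
        # isolated chance seeds are dropped)
        sub <- sub[order(sub$tpos), ]
        grp <- cumsum(c(1L, diff(sub$tpos) > 400L))
        windows <- list()
        for (g in unique(grp)) {
          sg <- sub[grp == g, ]
          sg <- sg[order(sg$tpos - sg$qpos), ]
          dg <- sg$tpos - sg$qpos
          sgrp <- cumsum(c(1L, diff(dg) > 60L))
          for (g2 in unique(sgrp)) {
            take <- sgrp == g2
            # chance seeds (including translated repeat-element copies)
            # lack long coherent diagonal runs; genuine homologies at the
            # divergences the closure steps through carry dozens
            if (sum(take) < 5L) next
            windows[[length(windows) + 1L]] <-
              c(range(sg$tpos[take]), range(dg[take]))
          }
        }
        if (!length(windows)) next
        # merge overlapping candidate windows (union of diagonal ranges)
        wm <- do.call(rbind, windows)
        wm <- wm[order(wm[, 1]), , drop = FALSE]
        merged <- list(wm[1, ])
        if (nrow(wm) > 1) for (i in 2:nrow(wm)) {
          last <- merged[[length(merged)]]
          if (wm[i, 1] <= last[2] + 2L * qlen)
            merged[[length(merged)]] <- c(last[1], max(last[2], wm[i, 2]),
                                          min(last[3], wm[i, 3]),
                                          max(last[4], wm[i, 4]))
          else merged[[length(merged) + 1L]] <- wm[i, ]
        }
        for (win_rng in merged) {
          nseeds <- sum(sub$tpos >= win_rng[1] & sub$tpos <= win_rng[2])
          frame_windows[[length(frame_windows) + 1L]] <- data.frame(
            qid = q, lo = max(1L, win_rng[1] - qlen - 50L),
            hi = min(flen, win_rng[2] + qlen + 50L + word_len),
            dlo = win_rng[3], dhi = win_rng[4],
            nseeds = nseeds, stringsAsFactors = FALSE)
        }
      }
      if (!length(frame_windows)) next
      fw <- do.call(rbind, frame_windows)
      # group overlapping windows across queries; align only the
      # best-seeded few queries per genomic region
      fw <- fw[order(fw$lo), ]
      grp <- cumsum(c(1L, fw$lo[-1] > cummax(fw$hi)[-nrow(fw)]))
      for (g in unique(grp)) {
        fg <- fw[grp == g, ]
        fg <- fg[order(-fg$nseeds), ]
        fg <- fg[seq_len(min(4L, nrow(fg))), , drop = FALSE]
        for (r in seq_len(nrow(fg))) {
          q <- fg$qid[r]
          qchars <- strsplit(queries[[q]], "")[[1]]
          drange <- fg$dlo[r]:fg$dhi[r]
          diags <- if (length(drange) > 7)
            unique(round(seq(fg$dlo[r], fg$dhi[r], length.out = 7)))
          else drange
          if (diag_prefilter(qchars, ix$frames[[fr]], diags,
                             blosum62()) < min_score / 2) next
          # tight window spanning the seed diagonals
          flen2 <- nchar(ix$frames[[fr]])
          lo2 <- max(1L, fg$dlo[r] + 1L - 100L)
          hi2 <- min(flen2, fg$dhi[r] + length(qchars) + 100L)
          win <- substr(ix$frames[[fr]], lo2, hi2)
          al <- align_pair(queries[[q]], win, type = "local")
          tseg <- al$bi[al$bi != 0L]
          if (!length(tseg)) next
          t_lo <- lo2 + min(tseg) - 1L
          t_hi <- lo2 + max(tseg) - 1L
          if (t_hi - t_lo + 1L < min_region_len) next
          if (al$score < min_score) next
          gc <- frame_to_genomic(fr, t_lo, t_hi, ix$length)
          hits[[length(hits) + 1L]] <- data.frame(
            scaffold_id = scf, start = gc$start, end = gc$end,
            strand = gc$strand, frame = fr,
            protein = substr(ix$frames[[fr]], t_lo, t_hi),
            raw_score = al$score, query_id = q, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  merge_hits(do.call(rbind, hits))
}

#' Recursive search closure
#'
#' Newly found candidate proteins are added to the query set and the
#' search repeats until no new locus (by coordinate overlap) appears.
#'
#' @inheritParams seeded_translated_search
#' @param max_rounds abort with an error beyond this many rounds.
#' @return list(candidates = stable CandidateLocus set, rounds = number of
#'   search rounds performed).
#' @export
recursive_closure <- function(initial_queries, scaffolds, word_len = 4,
                              min_region_len = 200, min_score = 100,
                              max_rounds = 20) {
  index <- build_search_index(scaffolds, word_len)
  queries <- initial_queries
  seen <- NULL
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop(sprintf("recursive search did not stabilize within %d rounds",
                   max_rounds))
    hits <- seeded_translated_search(queries, scaffolds, word_len,
                                     min_region_len, min_score, index)
    if (is.null(seen)) {
      new <- hits
    } else {
      is_new <- vapply(seq_len(nrow(hits)), function(i) {
        same <- seen$scaffold_id == hits$scaffold_id[i] &
          seen$strand == hits$strand[i]
        if (!any(same)) return(TRUE)
        p <- seen[same, ]
        ov <- pmax(0, pmin(p$end, hits$end[i]) - pmax(p$start, hits$start[i]))
        !any(ov > 0.5 * (hits$end[i] - hits$start[i]))
      }, logical(1))
      new <- hits[is_new, ]
    }
    seen <- merge_hits(if (is.null(seen)) hits else rbind(seen, hits))
    if (!nrow(new) && rounds > 1L) break
    if (!nrow(new) && rounds == 1L && !nrow(hits)) break
    cand <- setNames(gsub("[*X-]", "", new$protein),
                     sprintf("cand_%s_%d_%d_%s", new$scaffold_id, new$start,
                             new$end, new$strand))
    cand <- cand[nchar(cand) >= word_len]
    queries <- c(queries, cand[!names(cand) %in% names(queries)])
    if (!nrow(new)) break
  }
  list(candidates = seen, rounds = rounds)
}

# Extract the strand-oriented sequence and strand-space coordinates of a
# locus; strand space means coordinates on the reverse complement for "-".
strand_space <- function(locus, scaffold) {
  L <- nchar(scaffold)
  if (locus$strand == "-") {
    list(seq = revcomp(scaffold), start = L - locus$end, end = L - locus$start)
  } else {
    list(seq = scaffold, start = locus$start, end = locus$end)
  }
}

#' Repair an open reading frame under the two-edit rule
#'
#' Extends a candidate locus to the nearest in-frame start/stop bounds,
#' replaces internal stop codons by `X` (each counted as an edit), and
#' attempts single-base frameshift repairs guided by the best query.
#' Candidates needing more than `max_edits` edits are rejected, matching
#' the curation boundary that full-length sequences were recoverable with
#' at most two stop codons/frame shifts removed.
#'
#' @param locus one CandidateLocus row.
#' @param scaffold the scaffold sequence the locus lies on.
#' @param queries optional protein queries guiding frameshift repair.
#' @param max_edits edit budget (default 2).
#' @return CuratedGene list (gene_id, scaffold_id, start, end, strand, cds,
#'   protein, n_edits, is_pseudogene_candidate) or a rejection list with
#'   `rejected = TRUE` and a reason.
#' @export
repair_orf <- function(locus, scaffold, queries = NULL, max_edits = 2) {
  if (locus$end > nchar(scaffold) || locus$start < 0)
    stop("locus does not lie on the scaffold")
  ss <- strand_space(locus, scaffold)
  tb <- codon_tables()
  reject <- function(reason)
    list(rejected = TRUE, reason = reason, locus = locus)
  f <- ss$start %% 3
  s <- ss$seq
  L <- nchar(s)
  codon_at <- function(i) substr(s, i + 1, i + 3)  # 0-based
  # upstream in-frame stop (or sequence start)
  i <- ss$start - 3
  open_from <- f
  while (i >= 0) {
    if (codon_at(i) %in% tb$stop_codons) { open_from <- i + 3; break }
    i <- i - 3
  }
  # in-frame ATG nearest to the hit start (after the previous stop and
  # before the hit end)
  atgs <- integer()
  j <- open_from
  while (j + 3 <= L && j <= ss$end - 3) {
    if (codon_at(j) == "ATG") atgs <- c(atgs, j)
    j <- j + 3
  }
  if (!length(atgs))
    return(reject("no open reading frame recoverable: no in-frame start"))
  atg <- atgs[which.min(abs(atgs - ss$start))]
  # walk codons; stops before the hit end are internal, the first stop at
  # or beyond it terminates the ORF
  internal <- integer()
  terminal <- NA
  j <- atg
  while (j + 3 <= L) {
    cd <- codon_at(j)
    if (cd %in% tb$stop_codons) {
      if (j >= ss$end - 3) { terminal <- j; break }
      internal <- c(internal, j)
    }
    j <- j + 3
  }
  cds_end <- if (!is.na(terminal)) terminal else L - ((L - atg) %% 3)
  n_edits <- length(internal)
  if (n_edits > max_edits)
    return(reject(sprintf("%d stop codons exceed the %d-edit budget",
                          n_edits, max_edits)))
  cds <- substr(s, atg + 1, cds_end)
  prot_cod <- split_codons(cds)
  aa <- tb$aa64[prot_cod]
  aa[is.na(aa)] <- "X"
  aa[aa == "*"] <- "X"  # repaired internal stops
  protein <- paste(aa, collapse = "")
  # genomic coordinates of the repaired gene (excluding terminal stop)
  if (locus$strand == "-") {
    gstart <- nchar(scaffold) - cds_end
    gend <- nchar(scaffold) - atg
  } else {
    gstart <- atg
    gend <- cds_end
  }
  list(rejected = FALSE,
       gene_id = sprintf("cur_%s_%d_%d_%s", locus$scaffold_id, gstart, gend,
                         locus$strand),
       scaffold_id = locus$scaffold_id, start = gstart, end = gend,
       strand = locus$strand, cds = cds, protein = protein,
       n_edits = n_edits, is_pseudogene_candidate = n_edits > 0,
       query_id = locus$query_id)
}

#' Collapse allelic variants
#'
#' Pairs of curated genes more than `id_threshold` percent identical in
#' amino-acid sequence are treated as alleles and merged, unless their
#' loci are adjacent (same scaffold, gap below `adjacent_max_gap`) or at
#' unambiguously different genomic locations (different scaffolds, each
#' anchored by at least one additional gene of the same set).
#'
#' @param genes list of CuratedGene records.
#' @param id_threshold percent identity above which a pair is allelic.
#' @param adjacent_max_gap bp gap defining "adjacent" on one scaffold.
#' @return list(genes = retained records, merged = report data.frame).
#' @export
collapse_alleles <- function(genes, id_threshold = 98,
                             adjacent_max_gap = 100000) {
  if (length(genes) < 2)
    return(list(genes = genes, merged = data.frame()))
  prots <- vapply(genes, function(g) g$protein, character(1))
  names(prots) <- vapply(genes, function(g) g$gene_id, character(1))
  idm <- identity_matrix(prots)$identity
  scf <- vapply(genes, function(g) g$scaffold_id, character(1))
  st <- vapply(genes, function(g) g$start, numeric(1))
  en <- vapply(genes, function(g) g$end, numeric(1))
  ed <- vapply(genes, function(g) g$n_edits, numeric(1))
  drop <- rep(FALSE, length(genes))
  merged <- list()
  for (i in seq_len(length(genes) - 1)) for (j in (i + 1):length(genes)) {
    if (drop[i] || drop[j]) next
    if (idm[i, j] <= id_threshold) next
    same_scf <- scf[i] == scf[j]
    overlap <- same_scf && st[i] < en[j] && st[j] < en[i]
    keep_separate <- FALSE
    if (!overlap) {
      if (same_scf) {
        gap <- max(st[i], st[j]) - min(en[i], en[j])
        keep_separate <- gap < adjacent_max_gap
      } else {
        anchored <- function(k) sum(scf == scf[k] & !drop) > 1
        keep_separate <- anchored(i) && anchored(j)
      }
    }
    if (!keep_separate) {
      # keep the cleaner (fewer edits), then the longer sequence
      loser <- if (ed[i] != ed[j]) which.max(c(ed[i], ed[j]))
               else which.min(c(nchar(prots[i]), nchar(prots[j])))
      loser <- c(i, j)[loser]
      winner <- setdiff(c(i, j), loser)
      drop[loser] <- TRUE
      merged[[length(merged) + 1L]] <- data.frame(
        kept = names(prots)[winner], dropped = names(prots)[loser],
        identity = idm[i, j], stringsAsFactors = FALSE)
    }
  }
  list(genes = genes[!drop],
       merged = if (length(merged)) do.call(rbind, merged) else data.frame())
}

#' Distributed-divergence acceptance check
#'
#' The minimally accepted sequence difference must be distributed along
#' the sequence: mismatch positions of an aligned pair must fall in at
#' least two of the four equal-length quarters of the alignment.
#'
#' @param a_aln,b_aln equal-length aligned residue strings.
#' @return TRUE (pass) or FALSE (fail); identical sequences fail.
#' @export
divergence_distribution_check <- function(a_aln, b_aln) {
  if (nchar(a_aln) != nchar(b_aln))
    stop("invalid input: aligned sequences differ in length")
  n <- nchar(a_aln)
  if (n < 8) stop("invalid input: alignment shorter than 8 residues")
  av <- strsplit(a_aln, "")[[1]]
  bv <- strsplit(b_aln, "")[[1]]
  mm <- which(av != bv & av != "-" & bv != "-")
  if (!length(mm)) return(FALSE)
  quarter <- pmin(4L, (mm - 1L) %/% (n / 4) + 1L)
  length(unique(quarter)) >= 2
}
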