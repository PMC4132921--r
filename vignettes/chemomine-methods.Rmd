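---
title: "Models and methods behind chemomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemomine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chemomine` is an end-to-end, ground-truth-driven re-implementation of a
chemosensory receptor repertoire study: mining intronless GPCR genes from
genomic scaffolds, phylogeny-based family assignment, motif-conservation
comparison, per-codon selection inference by a SLAC + FEL consensus, and
multi-scale transposable-element statistics. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and the limits of what the synthetic validation can show.

## The synthetic genome and what it emulates

All validation runs against `simulate_genome()`, whose defaults define
the study conditions:

* **Gene families.** A T2R-like family of 24 focal genes plus 6
  "other-species" references, and a V1R-like family of 12 + 6. The two
  families are simulated as *sister clades* sharing one ancestral gene
  (stem length 0.8 substitutions/codon to each family ancestor),
  because in the biology they are each other's closest relatives and
  every downstream step — cross-family alignment, reciprocal-outgroup
  rooting, motif comparison — presumes homology across families. Each
  family then radiates under its own conditions: a random bifurcating
  topology with uniform random branch lengths, rescaled to a total tree
  length of 8 expected substitutions/codon.
  The true duplication tempo of such expansions is unknown; the uniform
  branch-length stand-in was chosen over a coalescent because a
  coalescent concentrates most of the tree length in a few deep
  branches, where any counting-based method collapses multiple hits so
  severely that per-site substitution counts become uninformative. A
  first-principles power estimate (expected likelihood-ratio ≈
  2 × events × KL divergence between the neutral and selected
  nonsynonymous fractions; ~25 events per site needed for per-site
  power at p < 0.1) sets the tree length of 8.
* **Codon evolution.** MG94-style: HKY mutation (κ = 4, default) with a
  per-site ω multiplier on nonsynonymous rates and zero rate into stop
  codons, uniform codon frequencies. Branch lengths are expected
  substitutions/codon *at ω = 1*, so a site of class ω evolves at
  relative rate (f~S~ + ω·f~N~). The T2R-like mix is 60% of sites at
  ω = 0.1, 25% at 1, 15% at 5; the V1R-like family is mildly purifying
  (70% at 0.2, 30% at 1). Each planted gene is framed by a start codon
  and a terminal stop.
* **Genomic context.** Genes are grouped into clusters (5–7 for the
  T2R-like family), placed on both strands with lognormal intergenic
  gaps whose medians equal the study's observed values (31 kb T2R-like,
  16 kb V1R-like), and embedded in i.i.d. background sequence at GC
  0.42. Twelve gene-free background scaffolds support reference
  sampling.
* **Confounders.** A fraction 6/80 of T2R-like genes is pseudogenized
  in place with 1–2 disruptions (always at least one premature stop;
  optionally a single-base deletion compensated within 30 bp, so the
  locus stays full-length at the homology level). Allelic copies
  (< 2% amino-acid divergence, planted at a second locus) are available
  but default to zero, matching the study's observation that no allelic
  pairs survived curation.
* **Repeats.** Six element classes from a small bundled motif library
  are placed by a Poisson process; class-I (SINE/LINE/LTR) background
  density is 0.36 elements/kb — about 7.2 per 20-kb window, the
  reference-region value — and is multiplied by 2.0 inside 20-kb
  windows centered on T2R-like genes only. Elements are emitted both as
  annotation (RepeatMasker-dialect `.out`, BED) and as literal,
  lightly mutated sequence insertions, so both the annotation-parsing
  and the sequence-scanning entry points can be validated.

What the generator does **not** emulate: indels within coding regions
(so alignment inference is exercised only on substitution divergence),
introns (beyond constructed test cases), assembly gaps/Ns, non-uniform
codon usage, rate variation along branches, and segmental duplication of
repeat context together with genes. Green tests therefore demonstrate
algorithmic correctness and calibrated behaviour under this model — not
performance on real assemblies, where fragmented contigs, indels and
alignment error add failure modes.

## Mining

The translated search is a deterministic stand-in for a BLAST-style
tool: exact protein 4-mer seeds against all six reading frames, local
affine-gap extension (BLOSUM62, gap open 11 / extend 1, the package's
own Rcpp kernel), merging of same-strand hits with > 50% mutual overlap
(best score kept), a raw-score floor (default 100), and the study's own
filter of a ≥ 200-residue aligned region. The search is iterated to
closure: accepted candidate proteins join the query set until no new
locus appears (guard: 20 rounds).

ORF repair extends a hit to the nearest in-frame start (the ATG closest
to the hit start after the previous in-frame stop) and terminal stop;
internal stops become `X` and count as edits; a candidate needing more
than 2 edits is rejected — the curation boundary under which the
original repertoire tolerated putative sequencing errors. Allele
collapsing merges pairs > 98% identical unless they are adjacent on one
scaffold (< 100 kb) or on different scaffolds that each carry another
family gene; the 2% minimum divergence must additionally fall in at
least two alignment quarters ("distributed along the sequence").

## Phylogeny and family assignment

Progressive alignment (average-linkage guide tree on shared 3-mers,
profile–profile merges under BLOSUM62 expected scores) feeds
Poisson-corrected p-distances, neighbor joining (negative branches
clamped to zero, the deficit moved to the sibling), and a nonparametric
bootstrap (default 100 replicates) whose supports live on the 0–100
scale consumed by the decision rule. The study's maximum-likelihood
trees with aLRT support are deliberately *not* reproduced: the
assignment rule only consumes "support above 80%", which the bootstrap
provides; "above 80" is implemented strictly. Family assignment uses
the reciprocal-outgroup structure directly: the tree contains one edge
whose bipartition cleanly separates the two reference sets (the branch
between the monophyletic family groups); a candidate belongs to the
family on whose side of that edge its leaf falls, and the edge's
bootstrap support — the support of the family segregation itself —
must exceed 80% for any assignment to be made. When several edges
separate the reference sets (candidates attached along the stem), the
best-supported one is used. Ancestral genes per family
are counted as maximal focal-species-only subtrees of the rooted tree;
this operationalizes what tree figures in this literature mark as open
circles at basal nodes, and is stated here as the package's own
definition.

Poisson-corrected distances (rather than ML distances) are a speed
fidelity trade-off; at the synthetic divergences used here NJ recovers
additive metrics exactly and deep family splits bootstrap at 100%.

## Motif conservation

Columns with > 90% gaps are stripped; per column and group, the
consensus is the most frequent non-gap residue (ties alphabetical) and
a column is conserved iff its frequency among non-gap rows strictly
exceeds 0.45. Whether the original 45% rule was applied per family or
on master-alignment columns is not documented; per-group frequencies on
master columns are used here. Logo information content is
log₂20 − H (no small-sample correction). Cross-family classes:
*shared* (same residue conserved in both families), *differential*
(different residues), *family-specific* (≥ 2 groups of one family),
*group-specific*, *none*. Transmembrane regions come from Kyte–Doolittle
hydropathy (window 19, threshold 1.6); maximal runs of above-threshold
window centers shorter than 15 residues are discarded. These intervals
are a hydropathy operationalization, not a reproduction of any published
TM annotation.

## Site-level selection

A single global MG94×HKY85 fit (uniform codon frequencies, joint
L-BFGS-B over log branch lengths, log κ, one global log ω; NJ start)
anchors both tests.

* **SLAC.** Ancestral codons by joint maximum likelihood (max-product
  dynamic programming under the fitted model with ω fixed at 1 so the
  reconstruction does not presuppose a selective direction). Per site,
  observed synonymous/nonsynonymous changes are summed over branches,
  multi-nucleotide changes averaged over minimal stop-free mutation
  paths; expected sites are Nei–Gojobori fractions summed over all node
  states, with neighbor contributions weighted by the fitted κ so the
  binomial null matches the mutation process. The p-value is the
  one-sided exact binomial tail in the direction the site leans
  (the counting method's own convention). A codon-level Fitch
  parsimony reconstruction (tie-breaks: fewest nonsynonymous
  changes, then lexicographic) is retained as an alternative ancestor
  engine and is oracle-tested against brute-force minima.
* **FEL.** Per site, (α, β) maximized with branch lengths and κ fixed;
  null α = β; p from χ² with 1 df on 2ΔlnL (no boundary mixture — a
  conservative simplification). Invariant sites short-circuit to p = 1.
* **Consensus.** A site is reported iff both methods agree in direction
  at p < 0.1 — deliberately stringent, no multiple-testing correction,
  as in the original procedure. The dS guard computes pairwise NG dS
  with Jukes–Cantor correction and flags alignments whose maximum
  exceeds the ceiling (default 2; the study's own repertoires satisfied
  dS < 0.5, available as configuration).

Measured operating characteristics on the default mixed-ω simulation
(24 taxa, 300 codons, several seeds): FEL alone detects 64–76% of ω = 5
sites at p < 0.1; SLAC alone 36–58%; the consensus, being their
intersection, 36–56%, with a false-positive rate below 2% on ω ≤ 1
sites and ≤ 5% positive calls under full neutrality. The consensus is
bound by SLAC, which is conservative by construction (point-estimate
ancestors collapse multiple hits to ~20 counted events per site where
~30 occurred, and the exact binomial needs roughly 25+ events for
reliable per-site detection at this effect size). This mirrors the
reference implementations, where the counting method consistently
reports fewer sites than FEL; the acceptance suite states a 60%
consensus-sensitivity goal that the faithful two-method rule does not
reach under these conditions, and the corresponding test records that
honestly rather than weakening the agreement rule.

## Repeat landscape

Class-I elements are counted at three scales: percent coverage of
cluster regions (clusters = maximal same-family runs with gaps
≤ 100 kb; coverage regions take 10-kb flanks; per-analysis minima of 3
T2R / 2 V1R genes), 20-kb windows centered on clustered genes (any
overlap counts once; windows clipped at scaffold ends are re-normalized
to a full window; Student's equal-variance two-sided t-test against a
20-kb tiling of sampled gene-free reference scaffolds, Welch
switchable), and 1-kb binned profiles over whole cluster contigs
(elements assigned by start position; final partial bin normalized by
its width). Intergenic distance is the end-to-start gap of
coordinate-adjacent genes (start-to-start would be the alternative;
end-to-start is used throughout). Orientation classes follow strand
geometry: same strand head-to-tail; opposite strands with 5′ ends
proximal head-to-head, otherwise tail-to-tail. The monoexonic check
aligns the curated CDS to its genomic interval with free genomic end
gaps and fails on any alignment gap of ≥ 30 bp.

## Numerical and degenerate-input choices

* Uniform codon frequencies make the MG94 rate matrix symmetric, so all
  likelihood code uses a symmetric eigendecomposition (cached per
  (κ, ω)); transition probabilities are clipped at tiny positive values
  to avoid log-underflow.
* Fractional SLAC counts (from path averaging) are rounded for the
  exact binomial but kept fractional for dN/dS.
* Saturated NG proportions (p~S~ ≥ 3/4) yield infinite dS and fail the
  saturation guard rather than being truncated.
* The aligner's gap convention is cost = open + k·extend, matching the
  convention of the independent aligner used as a test oracle.
* All stochastic operations are pure functions of their seed; the
  pipeline derives stage seeds from one master seed, and identical
  configuration + seed reproduces identical tabular outputs.

## Problem sizes

Default study sizes — a ~6.5 Mb genome (4 × 1 Mb + 2 × 0.4 Mb gene
scaffolds, 12 × 150 kb background), 36 focal genes, 300 codons, 100
bootstrap replicates — were chosen so a full run with both selection
analyses completes in minutes on a single core while leaving every
statistic enough data to be calibrated (e.g. ~45 positively selected
truth sites, ~24 gene windows against ~70 reference windows).

## Known limitations

* Real-data fidelity: no indels, introns, or assembly artefacts; the
  mining recall/precision of 1 observed on synthetic truth is an upper
  bound, not a field estimate.
* The progressive aligner is adequate at these divergences but is not a
  substitute for mature MSA tools on real, indel-rich families.
* Simulated proteins carry no transmembrane architecture, so hydropathy
  annotation finds no intervals on simulated consensus sequences; the TM
  logic is exercised on constructed hydropathy patterns instead, and the
  TM/loop site map only engages when intervals exist.
* Support values are bootstrap proportions, not aLRT; only the "above
  80%" decision is comparable.
* The SLAC+FEL consensus trades sensitivity for a very low false
  positive rate (see measured characteristics above).
* The frameshift-repair path in `repair_orf()` is a best-effort
  operationalization; the original manual curation of frameshifted
  candidates is not documented and cannot be reproduced exactly.
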