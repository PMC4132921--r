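# chemomine

`chemomine` re-implements, end to end and at desk scale, the analysis
workflow used to characterize the chemosensory receptor gene repertoires of
a slowly-evolving fish genome: mining intronless bitter-taste (T2R-like)
and vomeronasal (V1R-like) GPCR genes from genomic scaffolds, assigning
them to families by phylogeny, comparing conserved sequence motifs,
calling per-codon positive/negative selection by a SLAC + FEL consensus,
and quantifying transposable-element enrichment around gene clusters.
Because the original analyses depend on a multi-gigabase genome and
external web services, every stage here runs against a **synthetic-genome
generator with known ground truth**, so each step of the pipeline is
testable offline, on one CPU, in minutes.

It is aimed at molecular evolution researchers who want a transparent,
scriptable version of this class of study — or a calibrated sandbox for
the individual methods.

## The methods in brief

* **dN/dS per codon.** For each codon site, the synonymous rate α and
  nonsynonymous rate β are contrasted: ω = β/α < 1 indicates purifying
  selection, ω > 1 positive (diversifying) selection. Two independent
  methods are run per site and a site is reported only when both agree at
  p < 0.1:
  * **SLAC** — ancestral codon states are reconstructed (joint maximum
    likelihood under MG94×HKY85), observed synonymous/nonsynonymous
    changes counted over all branches (multi-step changes averaged over
    minimal stop-free paths), and the nonsynonymous count tested against
    its neutral expectation with a one-sided exact binomial test.
  * **FEL** — with branch lengths and κ fixed from a global MG94×HKY85
    fit, per-site (α, β) are estimated by maximum likelihood and α = β is
    tested by a likelihood-ratio test (χ², 1 df).
  A dS ceiling guards against synonymous saturation.
* **Mining.** A deterministic translated homology search (exact protein
  k-mer seeds, affine-gap Smith–Waterman extension with BLOSUM62, 200-aa
  minimum region) is iterated to closure, ORFs are repaired under a
  two-edit rule (stop codons/frameshifts), and >98%-identical sequences
  are collapsed as alleles unless their loci are distinct.
* **Phylogeny.** Progressive alignment, Poisson-corrected distances,
  neighbor joining, nonparametric bootstrap; a candidate is assigned to a
  family iff the smallest reference-containing clade around it is pure
  and supported above 80%.
* **Repeats.** Class-I transposable elements (SINE/LINE/LTR) are counted
  in 20-kb windows centered on clustered genes and compared with sampled
  reference scaffolds by Student's t-test, alongside cluster-region
  percent coverage and 1-kb binned profiles.

## Worked example

```r
library(chemomine)

report <- run_full_pipeline(default_pipeline_config(seed = 1), "run1")
report$metrics$recall        # 1
report$metrics$precision     # 1
report$metrics$enrichment    # $ratio 1.886, $p 1.4e-15
report$selection$T2R$summary # positive 13, negative 45
report$selection$V1R$summary # positive  2, negative 39
```

On the default synthetic conditions (seed 1) this prints a gene-level
recall and precision of 1 — every planted intact gene recovered at its
true locus, no false loci — a class-I repeat enrichment ratio of 1.89
(simulated: 2.0) at p = 1.4e-15 for the T2R-like family with a
non-significant contrast for the V1R-like family (p = 0.75), and 13
positively / 45 negatively selected consensus sites in the T2R-like
family (whose simulation placed 15% of codons at ω = 5) versus 2 / 39
in the mildly purifying V1R-like family.

The same stages can be run piecewise as numbered scripts:

```sh
for s in analysis/0*_*.R; do Rscript "$s"; done   # writes results/
```

(Scripts read `CHEMOMINE_SEED` from the environment; default 1.)

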