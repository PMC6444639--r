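---
title: "Prioritizing predicted biosynthetic gene clusters with metabolite QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing predicted biosynthetic gene clusters with metabolite QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcqtl)
```

## The problem

Plant specialized-metabolite pathways are sometimes encoded by physically
adjacent genes — biosynthetic gene clusters (BGCs) — and several tools
predict such clusters from genome sequence alone.  A substantial fraction of
predictions, however, are not bona fide pathways: neighbouring enzyme genes
need not catalyse successive steps of one route, and many predicted clusters
show no coexpression.  Before investing in heterologous expression, the
candidate list needs pruning.

bgcqtl implements a genetical-metabolomics prioritization: map untargeted
LC–MS metabolite features as quantitative traits across a segregating or
natural population, superimpose the resulting metabolite QTL (mQTL)
intervals on the predicted clusters, and grade every superposition by
independent evidence layers.  A cluster overlapped by several mQTLs whose
metabolites are connected by defined biotransformation mass differences, and
whose enzyme genes are coexpressed, is a far stronger candidate than a
cluster grazed by a single association.  Clusters linked only to
*unannotated* metabolites are the discovery pool; clusters linked to
well-known metabolites whose pathways are incompatible with the cluster's
enzyme content are likely false-positive predictions.

## Mapping models

**RIL populations.**  For a recombinant inbred line (RIL) panel with
homozygous `{0,1}` genotypes, each trait is scanned marker by marker with
the least-squares LOD statistic

$$\mathrm{LOD}_j = \frac{n}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1(j)},$$

the log10 likelihood ratio of the one-QTL model at marker $j$ against the
intercept-only model.  Missing calls are dropped pairwise; monomorphic
markers score 0; $\mathrm{RSS}_1$ is floored at $10^{-12}$ so a perfectly
heritable trait yields a large finite score.  Genome-wide significance uses
the classical permutation scheme: the trait is permuted across lines
(1000 times by default), the genome-wide maximum LOD recorded each time,
and the empirical 95th percentile taken as the threshold.  One mQTL is
emitted per chromosome whose local peak exceeds the threshold, delimited by
the 1.5-LOD drop rule: walk out from the peak to the first marker whose LOD
falls below peak − 1.5 and include that boundary marker.  1.5 is the
classical convention for support intervals; widening the drop can only
widen the interval.

**Association panels.**  For natural accessions with dosage `{0,1,2}`
genotypes, the package fits per-marker fixed-effect regressions with the
leading principal components of the centered genotype matrix (3 by default)
as structure covariates, reporting the two-sided p-value of the additive
genotype coefficient.  This is an explicit approximation to a kinship mixed
model: it preserves the structure-correction logic at a fraction of the
machinery, and the divergence is recorded in the run metadata.  Per trait,
Benjamini–Hochberg control at q = 0.05 selects significant markers;
significant markers within 10 kb of each other merge into one mQTL whose
interval is padded by half the merge window and whose peak is the most
significant member.  Multiple-testing control is per trait, matching how
mQTL counts are conventionally reported; a `global_fdr` switch applies BH
across all traits jointly instead.

## The evidence layers

Each (mQTL, cluster) superposition — any positive overlap of the 1-based
closed intervals counts, since the superposition itself is the
candidate-generating event — feeds five boolean evidence flags per cluster:

* **multi_mqtl** — two or more mQTLs overlap the cluster;
* **multi_gene** — member markers (association mQTLs only) resolve, with a
  2 kb flank, to two or more distinct cluster genes;
* **massdiff** — two or more of the cluster's metabolite features are
  connected in the mass-difference network: a pair is joined when its m/z
  difference matches a biotransformation delta within
  max(0.005 Da, 10 ppm).  The shipped table (methylation, hydroxylation,
  acetylation, malonylation, rhamnosylation, glycosylation, sinapoylation)
  is computed from monoisotopic atomic masses at call time, e.g. hexose
  condensation C6H10O5 = `r sprintf("%.5f", monoisotopic_mass("C6H10O5"))` Da.
  Feature m/z is treated as a neutral-mass proxy: adduct and isotope
  deconvolution are out of scope, a documented caveat;
* **coexpression** — the maximum pairwise Pearson correlation among the
  cluster's class-bearing genes in an expression matrix reaches 0.79, the
  level at which coexpression of cluster enzymes is conventionally called
  strong.  Only enzyme-class-bearing members enter by default;
* **compatibility** — at least one overlapping annotated metabolite has a
  compound class compatible with the cluster's enzyme classes (the shipped
  map: lignan ↔ dirigent/dioxygenase, flavonoid ↔ chalcone-stilbene
  synthase/glycosyltransferase/acyltransferase, terpene ↔ terpene
  synthase/oxidosqualene cyclase; fully user-overridable).

The classification partitions linked clusters: `discovery_candidate` (all
traits unannotated), `known_compatible`, `mixed` (compatible annotated
traits alongside unknowns — implied but unnamed in qualitative treatments,
so it gets its own label here), and
`known_incompatible_or_false_positive`.  The score is the weighted sum of
satisfied flags with unit default weights: no principled exchange rate
between genetic and coexpression evidence exists, so the weighting is left
explicit and configurable rather than hidden in a heuristic.  Ranking is a
strict total order: score, then number of supporting mQTLs, then genomic
coordinate, then cluster id.

## Cluster detection

When no external cluster predictions are supplied, `detect_bgcs()` applies
a deliberately simple chaining rule: enzyme-class-bearing genes chain while
consecutive enzyme-gene intervals lie ≤ 10 kb apart; a chain is a cluster
iff it has ≥ 3 enzyme genes of ≥ 2 distinct classes.  Class-free genes
inside the span are members but never break the chain.  This is an explicit
proxy for full plant-cluster predictors (which add redundancy filtering and
per-class rules); real predictions can always be injected through
`read_cluster_table()`, and the prioritization logic is agnostic to their
origin.  Enzyme classes come from a tabular domain-hit interface
(`assign_enzyme_classes()`), so any profile-HMM scanner can feed it; which
domain families count as scaffold-forming is configurable because no
canonical enumeration exists.

## What the simulator emulates

`simulate_study()` builds a complete, fully seeded study so every stage is
testable without external data:

* **Genome** — 5 chromosomes × 50 genes in 100 kb slots; planted clusters
  compress `cluster_size` consecutive genes to 3 kb gaps and cycle ≥ 2
  enzyme classes over them.  Background gene spacing (~100 kb) exceeds the
  10 kb chaining gap, so spurious chains cannot arise from the lone-enzyme
  background fraction (2%) alone.
* **RIL population** — RIL-by-selfing: homozygous lines whose genotype
  switches between adjacent markers with probability $R = 2r/(1+2r)$, with
  $r$ from Haldane's map function; the most common RIL design, chosen
  because population-type details beyond "RIL" are rarely available.
* **Association panel** — Balding–Nichols-style subpopulation divergence:
  ancestral frequencies uniform on [0.05, 0.95], Beta-perturbed per
  subpopulation, binomial dosages.
* **Traits** — one causal locus per trait at the marker nearest the causal
  cluster's midpoint (making the locus recoverable by a support interval in
  expectation), effect scaled against the realized genotype variance so the
  requested heritability is met in expectation.  The default h² = 0.3 is a
  calibration choice — typical for mid-sized metabolite QTL effects — not an
  empirical estimate; end-to-end recovery checks use h² = 0.5.
* **Features** — causal traits form one biotransformation chain per causal
  cluster (base mass plus exact monoisotopic deltas); other traits get
  unrelated masses; an `annotation_fraction` of features carries compound
  annotations.
* **Expression** — planted-cluster genes share a latent profile scaled so
  expected pairwise correlation equals the 0.8 target; background genes are
  independent.

What it deliberately does *not* emulate: linkage disequilibrium beyond
subpopulation divergence, epistasis, multi-QTL traits, adducts/isotopes,
retention-time structure, or realistic mQTL interval provenance from
genetic-map coordinates (all positions here are physical).  Passing
recovery tests therefore demonstrate the method's internal correctness and
calibration, not its field performance on real populations.

## Numerical choices and degenerate inputs

* Intervals are 1-based closed throughout, the R/Bioconductor and GFF3
  convention; overlap length is `min(end) − max(start) + 1`.  BED export
  converts to 0-based half-open at the boundary.
* Peak ties break to the lowest genomic coordinate; chromosome ordering is
  plain character sort — determinism, not karyotype aesthetics, is the
  contract.
* RSS values are floored at 1e-12; monomorphic or covariate-collinear
  markers report LOD 0 / p 1 rather than erroring.
* Constant or all-missing traits, unsorted annotations or maps, > 10%
  missing calls at a marker, and cluster tables citing unknown genes are
  validation errors with dedicated condition classes.
* One global seed drives fixed per-stage child seeds, so any stage can be
  re-run independently and the whole pipeline is byte-reproducible;
  per-trait permutation seeds derive from (seed, trait index).

## Problem sizes

The recovery and calibration analyses in the test suite and acceptance
script use study sizes chosen as the smallest that make the statistical
properties sharp: n = 200 lines, 5 × 50 markers, 1000 permutations, 100–200
replicate seeds for rate estimates.  These match the package's default
simulated-study conditions.

## Limitations

The GWAS model is not a kinship mixed model; strong family structure beyond
a few principal components will inflate associations.  Mass-difference
linkage on raw m/z conflates adducts with biotransformations.  The chaining
detector is a proxy, tuned for clarity over sensitivity.  And, as for any
association evidence, an mQTL over a cluster may reflect indirect effects
(e.g. precursor-pool genetics) rather than biosynthesis within the cluster
— the ranking guides follow-up, it does not replace it.
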