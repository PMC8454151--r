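---
title: "Methods: drug similarity and MoA inference on drug-target-pathway networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug similarity and MoA inference on drug-target-pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathfp)
```

# The problem

Natural-product drugs are usually found by phenotype, not by target, so
their mechanism of action (MoA) is unclear. A practical way to
characterize such a drug is to compare it against approved reference
drugs with known MoA. `pathfp` supports two complementary comparisons
on a drug-target-pathway heterogeneous information network (HIN):

* **Target-profile similarity** — do two drugs bind the same proteins?
* **Pathway-fingerprint similarity** — do two drugs act on the same
  pathways, possibly through *different* proteins?

The interesting case is when the two views disagree: a drug can share
targets with one reference class yet share pathways with another,
pointing at an MoA that target lists alone would mislabel.

# Evidence integration

Per-source drug-target interaction probabilities (e.g. a literature-
mining channel, a bioassay channel where outcomes map as active = 1,
inactive = 0, inconclusive/unspecific = 0.5, and a structure-based
prediction channel) are combined by noisy-OR:

$$CS = 1 - \prod_s (1 - P_s)$$

A source with no record contributes $P_s = 0$, the identity factor.
The score is monotone in each $P_s$, permutation-invariant, and equals
1 as soon as any source is certain. Duplicate records within one source
keep the maximum probability. For a multi-composition preparation, the
per-composition scores are computed first and then collapsed per target
by the **maximum** over compositions (sources unioned); the retention
filter $CS > 0.4$ (strict, boundary excluded) is applied only *after*
that merge — the order matters and is asserted by a construction test.

# The heterogeneous network and PathSim

The HIN has drugs, targets and pathways, with unweighted drug-target
edges (interactions surviving the filter; $CS$ is kept as metadata
only) and target-pathway membership edges from GMT gene sets. The
*pathway fingerprint* of drug $x$ is the vector
$F_x[p] = |T_x \cap \mathrm{genes}(p)|$. The number of metapath
instances drug → target → pathway → target → drug between $x$ and $y$
is the inner product $c(x,y) = \sum_p F_x[p]\,F_y[p]$; a walk through a
single shared target ($t_1 = t_2$) is a valid instance (standard
commuting-matrix semantics). PathSim is

$$s(x, y) = \frac{2\,c(x, y)}{c(x, x) + c(y, y)} \in [0, 1],$$

with $s(x,x) = 1$ whenever $c(x,x) > 0$. The test suite checks the
fingerprint formulation against an independent exhaustive enumeration
of all 4-edge walks on hundreds of random networks, exactly.

Target-pathway incidence is restricted by default to genes that are a
target of at least one drug: non-target genes cannot mediate any
metapath instance, so fingerprints are unchanged and memory is saved;
the full gene sets stay on the object for display and regulation
scoring.

**Target similarity.** The upstream formula for target-space similarity
is printed with the intersection in both numerator and denominator,
which is identically 1 and cannot produce the non-trivial clusterings
it is credited with. This package reads it as the Jaccard index
$|T_a \cap T_b| / |T_a \cup T_b|$ — the only reading under which the
method is non-degenerate — and records that choice here deliberately.

**Degenerate drugs.** A drug with no targets (or none inside any
pathway) has no defined similarity; it is scored 0 against everything,
including itself, with a warning, rather than being dropped or given
invented similarity.

# Clustering

Drugs are clustered on $d = 1 - s$ by agglomerative clustering.
Linkage is configurable (`complete`, `average`, `single`); the default
is **complete**, the default of the R clustering routine the original
workflow names. The linkage loop is implemented in the package (with
ties in the minimum inter-cluster distance broken by the
lexicographically smallest pair of original leaf indices, for
cross-platform determinism) so that `stats::hclust` remains available
as an *independent* reference: the suite checks merge heights against
it to 1e-9 on random matrices. Flat cuts at explicit `k` are nested by
construction; `k` cuts only — reading clusters visually off a figure
is not reproducible and is not supported.

# MoA inference for a query drug

Given a query and its most similar reference (by PathSim), the shared
metapath subgraph collects every pathway containing targets of both,
partitions each pathway's mediating targets into common / query-only /
reference-only, and ranks pathways by their path-instance contribution
$F_q[p] F_r[p]$ (ties by pathway id). The contributions provably sum
to $c(q, r)$, which the tests assert on random networks.

**Regulation direction.** From an external differential-expression
table (e.g. an edgeR result), genes are classified with inclusive
thresholds FDR $\le$ 0.1 and linear fold change $\ge$ 1.5 (up) or
$\le$ 1/1.5 (down). Fold-change convention is declared by column name
(`fc` linear, `log2fc` signed log2), never sniffed from values. The
direction statistic for a pathway is the up-regulated ratio. The
upstream report prints ratios like "61/91 genes upregulated" without
stating whether 91 counts DE genes in the pathway or all measured
pathway genes; both policies are implemented — default `"de"`
($n_{up}/(n_{up}+n_{down})$, comparable across pathways with different
expression coverage), alternative `"measured"` — and every report
carries its policy label. Two contrasts are compared with a neutral
band, default $[0.4, 0.6]$ (closed): ratios inside the band carry no
directional signal, so such comparisons are indeterminate rather than
forced.

# The synthetic world

The generator states one fixed world; its defaults were chosen once
and are not tuned against test outcomes.

* **Structure.** Two drug classes of 6 drugs each (echoing a
  six-glucocorticoid versus seven-NSAID comparison), 6 targets per drug
  from class pools of 20 private targets, 6 pathways per class of 10
  member genes plus 5 never-targeted filler genes. Classes are disjoint
  in targets; within a class, drugs overlap through the shared pool.
* **The confounder.** One extra drug draws its 6 targets from an
  8-gene *bridge* slice counted in class 1's pool, while exactly the
  bridge genes are pathway members only on class 2's side. Jaccard
  therefore pulls the confounder toward class 1 and PathSim toward
  class 2 — the dissociation the pipeline must recover.
* **Evidence.** Each observed edge is detected independently per
  channel (defaults 0.9 / 0.7 / 0.8); true records draw probabilities
  uniformly on $[0.5, 1]$ and spurious ones on $[0, 0.5]$, which makes
  the 0.4 threshold meaningful without calibration.
* **Noise.** `noise_missing` deletes true edges; `noise_spurious`
  activates false pairs (at rate $\times$ 0.05 per candidate pair).
  Draws are coupled across rates by uniform thresholding, so for a
  fixed seed the perturbation at rate 0.3 contains the one at 0.1 —
  common random numbers, decided at design time.
* **Expression.** Planted pathways give members FC
  $\approx$ `effect_fc` (default 2) with lognormal jitter (sd 0.1) and
  FDR $\sim U[0, 0.05]$; everything else sits near FC 1 and/or FDR
  $\ge$ 0.2. A gene in several planted pathways takes the first listed
  direction.

What a green test establishes: the pipeline recovers planted structure
under its stated noise. What it does not: realistic count-level RNA-seq
noise, correlated evidence channels, ontology structure among gene
sets, or anything about the original study's database snapshots.

# Numerical and format choices

* All randomness flows through explicit seeds; generators restore the
  caller's RNG state.
* Pipeline floats are written with 6 significant digits so text
  outputs are byte-stable across platforms; reruns with the same
  config are bit-identical.
* Run configuration is a plain `key: value` file (round-trip
  tested) — no YAML dependency.
* Gene symbols are upper-cased at every ingestion point to absorb case
  drift between sources; gene sets are taken as given (no ontology
  propagation).

# Known limitations

* Only the drug-target-pathway-target-drug metapath is counted; no
  PPI-mediated metapaths, no weighted PathSim.
* The up-ratio is reported without multiple-testing control across
  pathways — it is a descriptive direction statistic, not a test.
* Reference regulation directions must be supplied as DE tables; no
  signature-database retrieval is performed.
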