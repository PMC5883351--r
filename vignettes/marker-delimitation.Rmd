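---
title: "SNP-density marker discovery and PTP species delimitation"
author: "markerptp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-density marker discovery and PTP species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerptp)
```

## The problem

Closely related plant species — recently diverged congeners such as the
ginsengs — are routinely misidentified by the standard short barcoding loci,
whose per-site variation is simply too low.  Whole-plastome alignments carry
enough signal, but a practical barcode must be short and amplifiable.  This
package implements the workflow that bridges the two: scan a plastome
alignment for windows of unusually high SNP density, extract those windows as
candidate markers, and then ask the question that actually matters for
identification — *does a tree built from this marker alone delimit the
species correctly?* — using Poisson Tree Processes (PTP) species delimitation
as the scoring engine.

Throughout, a companion simulator generates alignments, trees and ground
truth with exactly the statistical structure the delimitation model assumes,
so every stage can be validated end to end without any external data.

## Windowed SNP density

A column of the alignment is a SNP iff at least two distinct unambiguous
nucleotides (A/C/G/T) occur in it.  Gaps, `N` and IUPAC ambiguity codes are
never counted as states: this is the conservative reading, and it makes the
counts deterministic.  A consequence worth knowing is that a column whose
variation exists only under ambiguity codes is invisible to the scan.

SNP positions are binned into fixed windows of `window_size` columns
(default 800, chosen to be long enough to design an amplicon in and short
enough to localize hotspots; the final partial window is kept and classified
like any other, and its count is *not* length-normalized — a deliberate,
documented bias that makes the last window look slightly cold).  Each
window's count is then standardized against the mean and sample (n−1)
standard deviation of all window counts, and classified:

* `low` — z < 1 (including negative z),
* `moderate` — 1 ≤ z < 2,
* `high` — z ≥ 2.

If the counts have zero variance every window is `low`.  Since the z-score
is location/scale-invariant, adding a constant to every window's count
changes no class.

Candidate marker regions are maximal runs of windows at or above a minimum
class (default `moderate`), bridging up to `merge_gap` quieter windows
(default 1 — real intergenic hotspots span several windows with dips, and
the named plastid markers of interest are 2–4 kb, i.e. multiple windows).
Regions are ranked by total SNP count.  Auto-proposed regions are named
`R<start>-<end>`; gene-anchored names (e.g. *trnC-rps16*) can only come from
a user-supplied region table, because genome annotation is out of scope here.

## Trees

The built-in tree engine is distance-based: p-distances or JC69 distances
(`-3/4·ln(1 − 4/3·p)`) with pairwise deletion of sites that are not plain
A/C/G/T in both sequences, followed by neighbor joining.  NJ is exact on
additive matrices — which is precisely what the test suite exploits as an
oracle — and negative estimated branch lengths are clamped to zero with the
deficit moved onto the sister branch.  Bootstrap supports are bipartition
frequencies over column-resampled replicates, seeded and reproducible.

This engine keeps the package self-sufficient; it is *not* a substitute
claim about ML inference.  Externally built maximum-likelihood trees can be
imported as Newick at every stage (`read_newick()`, the `trees` argument of
`evaluate_markers()`, `engine = "external"` in `run_config()`) so the exact
published workflow — RAxML trees fed into delimitation — can be reproduced.

Delimitation needs a rooted tree.  With an outgroup, the tree is rooted on
it and the outgroup is then pruned before delimitation (the delimitation
model describes the ingroup's branching process; keeping a distant outgroup
would pollute the speciation rate class).  Without one, midpoint rooting is
used.

## The PTP delimitation model

A *delimitation* is a set of "species root" nodes of the rooted tree,
pairwise non-ancestral, whose subtrees cover all tips.  Edges strictly
inside a species subtree are *coalescent* edges; all other edges — including
the stem edge leading into each species root — are *speciation* edges.
Each class is modeled as a Poisson process on branch length: edge lengths
are independent Exponential(λ) draws, with one λ for the speciation class
and either a shared coalescent λ (`single` model) or one per species
(`multi` model, the default).  For a class with n edges totalling S
substitutions/site, the profile log-likelihood at the MLE λ = n/S is
n·ln(n/S) − n.  The null model — one rate for every edge — is exactly the
single-entity delimitation.

Numerical choices:

* Edges shorter than `minbr = 1e-9` substitutions/site are excluded from
  every likelihood; zero-length branches would otherwise force infinite rate
  estimates.  A class with no included edges contributes nothing and owns no
  identifiable rate.
* Ties in the likelihood are always broken toward *fewer* entities
  (lumping), the conservative direction for identification claims.

### Finding the ML delimitation

Internally a delimitation is carried as the parent-closed set S of
"speciation nodes" above the species roots, which makes the state space (an
antichain lattice) easy to enumerate, perturb and sample.  `brute_force_ml()`
enumerates every valid delimitation (feasible to ~12 tips) and is the
correctness anchor.  `ml_delimitation()` is the production search:

1. an exact dynamic program that finds the optimal partition for *fixed*
   class rates (with rates fixed, the objective is edge-additive), iterated
   with profile-ML rate updates, started from a grid of rate pairs derived
   from branch-length quantiles — in both orientations, since nothing forces
   the short-edge class to be the coalescent one at a local optimum;
2. best-improvement hill climbing over single split/merge toggles, with
   whole-subtree collapse/shatter macro moves and a depth-2 pair rescue for
   ridge points;
3. zero-loss merge polishing to enforce the lumping tie-break.

The search is required by the test suite to reproduce the enumeration oracle
exactly (partition and log-likelihood to 1e-9) on hundreds of random
mixed-regime trees; on the trees used in the analyses (≤ ~60 tips) it runs
in milliseconds to seconds.

### The likelihood ratio test

The fitted delimitation is tested against the one-rate null.  The PTP
alternative is inherently one-sided: it claims that within-species
(coalescent) branching is *faster* than between-species branching.  The test
statistic therefore uses the order-constrained MLE of the fitted partition:
any coalescent class whose unconstrained rate falls at or below the
speciation rate is pooled into the speciation class (iterated until
consistent) — a fully pooled partition reproduces the null exactly.  The
statistic is referred to χ² with df = 1 for the single model and
df = number of entities for the multi model (each entity owns a
coalescent-rate parameter).  If p ≥ α (default 0.01) the single-entity
delimitation is returned.

Two caveats are documented rather than corrected.  First, the statistic is a
*maximum* over delimitations, so the χ² reference is approximate; with the
one-sided constraint the multi-rate test measures slightly conservative at
α = 0.01 on simulated single-rate trees (the package's type-I study), which
is the right direction for identification claims.  Second, the single-rate
model's test remains anticonservative under the same study (its df = 1
cannot absorb the selection effect); the multi model is the default for
exactly this reason, and single-model p-values should be read qualitatively.

### MCMC supports and the ASV

`mcmc_delimitation()` runs Metropolis sampling over delimitations under a
uniform prior: each step proposes toggling a uniformly chosen internal node
of S — adding a node splits the entity rooted there into its children's
entities, removing one merges its children's entities — and invalid toggles
are rejected in place, keeping the proposal symmetric.  Acceptance is
min(1, exp(Δ log-likelihood)).  Two chains are run (one from the
single-entity state, one from all-singletons), the first 10% of each is
discarded, and the rest are pooled into per-node supports: the fraction of
samples in which a node is a species root.  The between-chain support
correlation is reported as a minimal convergence signal; no further
diagnostic is applied.  On 4-tip trees the sampler is required to reproduce
the exactly enumerated likelihood-weighted distribution (χ² goodness of
fit), which pins down both the proposal and the acceptance rule.

The **Average Support Value (ASV)** is the mean support of the ML
delimitation's species roots — how strongly the sampler agrees with the
point estimate.  A single-entity ML delimitation takes the root's support.
Note that on data with no structure the posterior over delimitations is
nearly flat, so the ASV is legitimately low even though the LRT correctly
retains a single entity: ASV measures congruence, not correctness.

## Scoring markers by species discrimination

A species is *identified* by a marker iff some delimited entity's tip set
equals exactly that species' accession set — monophyletic and exclusive.
The paper-of-record workflow never defines "successful identification"
operationally; exact-entity match is the strictest reading and the default.
A looser rule ("neither split nor lumped": all accessions in one entity and
no *complete* foreign species in that entity) is available via
`mode = "loose"`.  `evaluate_markers()` applies the whole cascade — extract,
(concatenate), distance, NJ, root, delimit, optionally MCMC — to every
region and every requested combination, and reports percent variable sites,
entity count, discrimination and ASV per row.  Concatenation order follows
the user's combo list; NJ distances are invariant to column order, so the
order is cosmetic.

## The simulator: what it emulates, and what it does not

`simulate_tree()` draws a Yule topology over species (uniform random tip
splitting), a random coalescent join within each species, and *independent
exponential* branch lengths: every between-species edge (species-tree edges
and each species' stem) from Exp(λ_sp), every within-species edge from
Exp(λ_coal).  This matches the generative assumption of the PTP likelihood
exactly — deliberately so, because it makes parameter recovery a well-posed
test of the estimator rather than of model misspecification.
`simulate_alignment()` evolves sites independently under Jukes–Cantor along
that tree, with per-site rate multipliers inside hotspot regions and a
uniform root sequence.

Default study conditions (the `end_to_end_fixture()` profiles):

* **easy** — 5 species × 4 accessions, λ_sp = 1, λ_coal = 50 (rate
  ratio 50), L = 4000, base rate 0.002, one ×20 hotspot on columns
  801–1600.  The base rate is chosen so that between-species divergence is
  of order 0.5–1% and the hotspot ~10–20× that — the regime of real plastome
  alignments of recently diverged congeners, far from JC saturation.
* **hard** — 6 species × 3 accessions at rate ratio 5, with two sister
  species pairs whose stem edges are redrawn at the coalescent scale: two
  barely diverged pairs that markers should struggle to separate.
* **null** — a single species of 20 accessions: one exponential regime, the
  negative control.

What the simulator does *not* emulate: indels and alignment error (synthetic
alignments are gap-free, so gap handling is exercised by hand-built
fixtures, not by simulation), rate variation beyond hotspots (no Γ-rates),
base composition bias, recombination-free-but-linked marker correlation, and
any form of sequencing error.  Passing the simulation studies therefore
demonstrates that the estimators work where their assumptions hold; it does
not certify performance on real, messy alignments.

Known limitations worth repeating: exact identification at high rate ratios
still fails in a few percent of replicates for *inherent* reasons — a
speciation stem drawn near zero makes two species genuinely inseparable
(lumping), and a long coalescent tail edge mimics a speciation event
(oversplitting); both phenomena have direct analogues in the real data this
workflow targets.  ML delimitation on *estimated* (NJ) trees inherits the
tree's topological errors within species, which mostly perturbs entity
boundaries rather than species-level splits.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and is bit-exactly
reproducible from it.  The stage runner (`run_config()` / `run_stage()`)
validates its settings (800-column windows, α = 0.01, 2 chains, 10% burn-in
as defaults), writes artifacts plus a JSON manifest (config, seed, input
checksums, package/R versions, timing) per stage, and composes the full
workflow; the numbered scripts under `analysis/` are thin narrative drivers
over it.  The validation studies are sized for a desk machine: oracle
equivalence on 200 random ≤12-tip trees, recovery over 50 easy and 100 null
replicates, 50,000-step chains for the exact-distribution check, and a
20-seed hotspot-vs-cold marker study — together a few minutes of single-core
compute.
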