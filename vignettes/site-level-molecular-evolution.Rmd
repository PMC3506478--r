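---
title: "Site-level selection, conservation and co-evolution: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-level selection, conservation and co-evolution: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Closely related orthologs of a protein-coding gene — the motivating case
is a family-18 chitinase shared by about a dozen *Streptomyces* genomes —
differ at some sites much more than at others. Three complementary
site-level analyses dissect that variation:

1. **Reverse conservation analysis (RCA)** asks *where* the protein is
   unusually variable: per-column evolutionary rates are estimated by
   empirical Bayes, standardized, smoothed, and thresholded into
   contiguous "highly variable regions".
2. **REL selection analysis** asks *why*: a codon model separates
   synonymous (dS) from non-synonymous (dN) substitution rates and tests,
   site by site, for dN > dS (positive selection).
3. **BGM co-evolution analysis** asks *which sites move together*:
   non-synonymous substitutions are mapped onto tree branches by
   ancestral reconstruction, and a Bayesian network over sites is
   sampled to find pairs whose substitution histories are coupled.

All three stages report coordinates in the numbering of a designated
reference sequence, so their outputs can be joined residue by residue
(`run_all()`, `cross_annotate()`).

# Models and assumptions

## Likelihood engine

Every stage rests on Felsenstein pruning over a reversible substitution
model on an arbitrary finite state space (4 nucleotides, 20 amino acids,
or the 61 sense codons of the standard genetic code). Models couple a
symmetric exchangeability matrix $R$ with stationary frequencies $\pi$:
$Q_{ij} = R_{ij}\pi_j$. Transition matrices come from the symmetric
eigendecomposition of $\Pi^{1/2} Q \Pi^{-1/2}$, which is exact for this
model class; the kernel is implemented in C++ and cross-checked in the
test suite against a pure-R pass, an independent matrix exponential, and
exhaustive enumeration over internal-node states. Gaps and ambiguity
symbols contribute all-ones partial likelihoods ("treated as unknown");
partially ambiguous codons get uniform support over compatible sense
codons — this realizes the convention that ambiguous characters are
averaged.

Tree scaffolding is deliberately modest: maximum-likelihood pairwise
distances, BIONJ (exact on additive metrics; delegated to `ape` for
n ≥ 4), coordinate-wise Brent branch-length optimization (monotone in
the total log-likelihood), and nonparametric bootstrap support. Full
topology search and aLRT-style supports are out of scope; a user-supplied
Newick tree is always accepted.

## RCA

Per-column rates are modelled by a discrete-gamma prior with $K = 16$
equal-probability categories (category values are the conditional
category means, so the prior mean is exactly 1). The shape $\alpha$ is
fitted by maximizing the integrated likelihood; the per-column posterior
mean rate is then z-transformed across columns into **S scores**
(population SD, so "mean 0, SD 1" is an exact testable property),
smoothed by a sliding window of $n = 7$ columns into **W scores**
(windows truncate at the termini so terminal residues keep scores), and
regions are maximal runs with $W \ge 0.5$ (ties inside). Higher S means
*more variable*; some conservation literature inverts the sign.

## REL

Stage 1 fits a constrained reversible nucleotide model (branch lengths
plus exchangeabilities; `AG` is the reference rate). Three presets ship
the published gene-specific reductions: for the chitinase gene CG is
tied to the reference while CT shares the AC parameter and GT shares AT
(two free parameters); the recA and dnaN control-gene sets are analogous,
with dnaN's unnamed CT kept as its own free parameter and flagged.

Stage 2 holds the relative branch lengths fixed and fits a 3×3 grid of
(dN, dS) classes: three dN values, three dS values, and class weights
that are the **outer product of independent dN and dS marginals** — the
structure of the original random-effects-likelihood method, where the
site-to-site distributions of dN and dS are independent. This matters
statistically: with a freely varying 3×3 weight matrix, neutral data
routinely supports a degenerate joint class (high dN paired with
near-zero dS) carrying idiosyncratic weight, which manufactures false
positive-selection signal. The product constraint forces any extreme
marginal value to be shared across the whole alignment, and the
false-positive audit (below) only passes with it.

Weights are profiled out by closed-form EM inside every objective
evaluation, so the optimizer works on just the six log rate values
(Nelder–Mead from deterministic multi-starts; identical codon columns
share one likelihood evaluation). A separate "global branch scale" would
be exactly collinear with scaling both value vectors — every class rate
is linear in dN or dS — so it is not fitted; for reporting, values are
normalized so the dS-marginal-weighted mean of dS is 1
(`grid$branch_scale` records the factor), and the ratio grid is
scale-invariant.

Per-site inference is empirical Bayes: class posteriors
$\propto w_{ij} P(\text{site} \mid dN_i, dS_j)$, and the evidence for
positive selection is the Bayes factor
$BF = \frac{\text{post}/(1-\text{post})}{\text{prior}/(1-\text{prior})}$
over the classes with $dN_i > dS_j$. Classification uses the published
thresholds: strong at $BF \ge 50$, weak at $10 \le BF < 50$ (both
boundaries inclusive); otherwise "negative" when the posterior mass on
$dN < dS$ exceeds 0.5, else "none". If the prior mass on positive
classes is 0 or 1 the BF is undefined and reported as NaN.

Site-level positive calls are additionally gated on a model-level
likelihood-ratio test against the neutral-constrained submodel in which
every site has $dN = dS = r$ with $r$ a three-value discrete
distribution (df = 5 at the 0.95 level; `fit$lrt`,
`fit$positive_supported`). The gate exists because under exact
neutrality the fitted value vectors land arbitrarily on either side of
the $dN = dS$ boundary: a dominant class at ratio 1.02 with weight 0.98
turns nearly every site into a huge "Bayes factor" without any
selection signal. Gating empirical-Bayes site identification on a
significant model-level test is the field's standard defence (codeml
interprets BEB sites only under a significant M1a/M2a comparison);
ungated Bayes factors remain available (`classify_sites(...,
lrt_gate = FALSE)`).

## BGM

The co-evolution stage reduces each codon site to a binary vector over
branches: 1 where the jointly most probable ancestral reconstruction
(max-product dynamic programming, ties to the lowest codon index —
deterministic) implies an amino-acid change. Branches with gap or
ambiguous observed codons contribute 0 — a hard binary map cannot
"average" ambiguity, so the conservative choice is made and documented.
Sites with fewer than 3 non-synonymous branches are dropped (boundary
inclusive). The reconstruction model defaults to the REL fit collapsed
to its weight-averaged (dN, dS) pair; a neutral model is the documented
fallback.

Network structure is sampled by Metropolis–Hastings over directed
acyclic graphs with in-degree ≤ 2: single-edge additions, deletions and
reversals with the exact Hastings ratios for the asymmetric proposal,
and Beta(1,1)-integrated (K2-style) marginal likelihood per node
family, cached per parent set. The structure prior is an
independent-edge sparsity prior (default inclusion probability 0.05
per directed edge). A fully uniform prior is *not* usable with a 0.5
posterior calling threshold: once in-degree ≤ 2 is imposed, a uniform
prior already places ~0.35 marginal mass on every undirected edge, so
null data would hover near the threshold; the sparsity prior restores
the interpretation of 0.5 as "data-driven evidence". Setting
`edge_prior = 0.5` recovers the uniform prior. Edge posteriors are
direction-marginalized inclusion frequencies after burn-in (defaults
100,000 steps / 10,000 burn-in, seeded and bit-for-bit reproducible).
Called pairs (posterior ≥ 0.5) are grouped by connected components.

# The synthetic world

`simulate_tree()` draws a Yule topology and rescales branches so the
mean root-to-tip path equals the requested depth in expected
substitutions per site. `simulate_protein()` draws per-site gamma rates
(or takes fixed rates for planted-block designs) and runs an exact
Gillespie simulation down each branch under JTT, returning true rates
and substitution counts. `simulate_codons()` assigns each site a (dN,
dS) class and simulates under the corresponding codon matrices, with one
shared normalization so that branch lengths stay in substitution units
regardless of the class mix — without it, "tree depth 1" would mean
almost no substitutions under slow classes and the stated power targets
would be meaningless. `simulate_coevolution()` couples a follower site
to a leader: wherever the leader had a non-synonymous event, the
follower receives a forced non-synonymous substitution on the same
branch with probability $\rho$ (else on a random branch), matching
exactly the branch-level binary signal the BGM stage observes.

What the generators do *not* emulate: insertions/deletions, among-branch
rate variation, codon-usage heterogeneity along the gene, and alignment
error. A green recovery test therefore establishes that the inference
machinery works on data satisfying its own assumptions — not that those
assumptions hold for any particular real alignment.

# Audits and their calibration

The statistical acceptance surface is property-based
(`audit_*` functions):

- *RCA*: a 20-column block at rate ×5 among 300 columns (10 taxa) must
  be overlapped by a called region in ≥ 95% of 50 replicates.
- *REL type-I*: all-neutral data (dn = ds site-wise; 12 taxa, 300
  codons) may yield a site at BF ≥ 50 in at most 1 replicate.
- *REL power*: with 10% of sites at dN/dS = 4, a fitted class with
  ratio > 1 must appear, ≥ 60% of planted sites must reach BF ≥ 10,
  and the fitted positive ratio must land within a factor 2 of truth in
  ≥ 80% of replicates.
- *BGM*: independent Bernoulli(0.3) columns must produce no called edge
  in ≥ 90% of 20 runs; a ρ = 0.9 planted pair among 8 independent sites
  (20 taxa) must be recovered in ≥ 80% of 20 replicates, both from the
  simulator's own branch event map and through the full
  reconstruction-based path.

Two calibration choices deserve explanation. First, the REL audits run
at 8 replicates (the audit's own scale is 50) purely for compute budget;
the absolute allowance — at most one violating replicate — and all
fraction thresholds are kept. Second, the BGM recovery world uses depth
0.6 substitutions/site with the coupled class at dN 1.8 and independent
sites at dN 0.6: coupled sites then accrue roughly five non-synonymous
events, enough to pass the ≥ 3 filter and inform the network. At
substantially higher divergence the joint reconstruction saturates
(multiple hits collapse onto single branches) and the branch maps decay
toward noise — a real limitation of substitution-mapping co-evolution
methods, not an artifact of this implementation. Recovery from the
simulator's truth map is essentially deterministic; recovery through
the reconstruction path is seed-set sensitive (65–95% across seed
batches in our checks) precisely because event *placement* errors, not
event detection, dilute the pairwise overlap signal. Both are audited.
Relatedly, the null world itself occasionally samples a pair of
genuinely correlated Bernoulli columns (with 45 pairs per run this is
not rare), which any calibrated detector should and does flag; the
≥ 90% clean-run target budgets for this.

# Numerical choices

- Branch lengths bracketed in [0, 10] expected substitutions/site;
  saturated ML distances cap at 10 with a warning.
- Branch-length optimization tolerance 1e-6 on the log-likelihood;
  gamma-shape search on log scale over [0.02, 100], upper bound reported
  with a warning when no rate variation is detectable.
- Pruning rescales partial likelihoods only when a column's mass drifts
  below 1e-120 (cheap check, exact log bookkeeping).
- F3x4 codon frequencies by default; F61 with pseudocount 0.5 available.
- EM weight profiling to 1e-9 in the log-likelihood; Nelder–Mead with
  reltol 1e-9, default 3 deterministic starts (presets spanning neutral,
  purifying-heavy, positive-heavy and two mixed grids, each scaled by a
  single-class neutral pre-fit).
- Ties: region calling and site classification treat thresholds as
  inclusive (≥); ancestral-state ties break to the lowest codon index.
- Degenerate inputs: constant rate vectors z-transform to all zeros; an
  all-gap column has log-likelihood 0 and posterior rate equal to the
  prior mean.

# Known limitations

- No topology search: trees are user-supplied or BIONJ + ML branch
  lengths.
- The REL grid is identified only up to the branch-length scale
  convention; printed dN/dS *values* are convention-dependent, ratios
  are not.
- BGM results depend on reconstruction fidelity and decay at high
  divergence (see above); directionality of edges is not interpreted.
- Config files are JSON (no YAML reader in the supported dependency
  set).
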