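---
title: "Comparing cycle-removal strategies for pathway Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cycle-removal strategies for pathway Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaybn)
```

## The problem

Curated signalling pathways are directed graphs over genes, and they are
cyclic: negative feedback (an inhibitor induced by the pathway's own output),
mutual regulation, and self-loops are everywhere. A Bayesian network requires
a DAG, so any pathway-as-BN analysis starts by deleting (or rewiring) edges
until no directed cycle remains. That step is not innocent — which edges are
sacrificed determines which causal relationships the downstream model can
represent — and published methods make very different choices. This package
implements five of those choices behind one interface so their consequences
can be measured on data with known ground truth.

## The model

Every reconstructed pathway is a linear-Gaussian BN: each gene `Y` with
parents `X1..Xk` follows

```
Y = b0 + sum_i bi * Xi + eps,   eps ~ N(0, sigma^2)
```

Parameters are ordinary least squares per node — the maximum-likelihood
estimator under Gaussian noise — fitted **only on control (non-tumor)
training samples**, so the network describes unperturbed regulation. The
residual variance is the MLE (divide by n) and is floored at `1e-8` so a
zero-residual fit keeps a finite density. A sample's score under a pathway is
its joint log-density, which factorises over the DAG as the sum of
conditional Gaussian log-densities (natural log). `bn_joint_mvn()` exposes
the closed-form joint normal implied by the system,
`mu = (I - B)^-T b0`, `Sigma = (I - B)^-T D (I - B)^-1`; the test suite
checks the factorised score against it to 1e-8.

Per-sample, per-pathway log-likelihoods form the feature table of a Random
Forest classifying tumor vs control. Feature importance (mean decrease in
Gini impurity, averaged over the repeated splits) ranks pathways; accuracy,
precision, recall and F1 are reported at the threshold maximising the
Matthews correlation coefficient over midpoints of the sorted unique test
scores, plus threshold-free AUC. BIC = `k ln(n) - 2 logL` with
`k = sum(|parents| + 2)` compares reconstructions as penalized fits (lower is
better; the package reports average per-pathway ranks).

## The five strategies and their knobs

* **props** — seed-shuffled edge re-insertion, skipping cycle-creators. The
  only knob is the seed. Every rejected edge re-creates a cycle if put back
  (the result is a maximal acyclic edge subset in insertion order).
* **clipper** — per-edge simple regression of child on parent on control
  training samples; two-sided slope-test p-value; insertion in ascending-p
  order (ties broken by stable input edge order). One parent per regression,
  not multivariate. Zero-variance genes get p = 1 with a warning.
* **bnrich** — stage 1 applies ordered rules to edges inside nontrivial
  strongly connected components only, recomputing SCCs between rules:
  R1 removes edges whose source compartment is strictly deeper than the
  target on extracellular < membrane < cytoplasm < nucleus; R2 removes
  `expression`/`state_transition` edges leaving the nucleus backwards; R3
  removes `inhibition` edges still inside an SCC. Residual cycles either
  raise an error (default) or are delegated to the clipper criterion
  (`fallback = "clipper"`). Stage 2 fits one LASSO per child per condition
  (both conditions' training samples) and removes edges whose coefficient is
  exactly zero in **both** fits.
* **bpa** — each cyclegroup (nontrivial SCC) loses all internal edges,
  gains a complete random-order tournament (`k(k-1)/2` added edges,
  provenance `"added"`), and every external parent is connected to every
  member. The expansive reading (all ordered pairs; fan-out to all members)
  was chosen because the published edge-addition counts are of that
  magnitude, far above a Hamiltonian-chain reading.
* **ensemble** — node hierarchies by TrueSkill (mu = 25, sigma = 25/3,
  beta = sigma/2, no draws, one seed-shuffled pass; each edge is a match won
  by its target) and by social agony (integer labels minimising
  `sum max(0, r(u) - r(v) + 1)`); three heuristics (forward / backward /
  greedy scans over hierarchy-violating edges) per ranking give six methods;
  each votes to remove edges; the final DAG inserts edges in ascending vote
  order, skipping cycle-creators. Rankings are computed on the whole graph
  and decycling runs per SCC: the upstream/downstream context outside an SCC
  is what identifies which of its edges are feedbacks (an isolated two-cycle
  is perfectly symmetric).

## Numerical and design choices

* **LASSO penalty selection.** The penalty is chosen by 5-fold
  cross-validation with the one-standard-error rule (largest penalty within
  one SE of the minimal CV error), on a 100-point log grid down to
  `1e-4 * lambda_max`. The exact CV minimum was tried first and rejected: at
  the CV minimum an independent (true-zero) parent retains a nonzero
  coefficient roughly half the time, so the documented behaviour — weak
  edges shrink to *exactly* zero — would be a coin flip. The 1-SE rule
  restores it (verified against glmnet: 30/30 null-edge removals, 30/30
  retention of true effects down to coefficient 0.5). The path itself is an
  in-package coordinate-descent solver (covariance updates, warm starts,
  objective-based stopping for near-collinear designs); glmnet serves as the
  independent cross-check in the tests, not as the implementation.
* **Agony ties.** Agony minima are often non-unique (an isolated 2-cycle can
  be labelled either way at equal agony). Among minimal labelings the
  implementation prefers the one with the most strictly-forward edges — the
  hierarchy that explains the most of the graph. Exact search is exhaustive
  for components of up to 5 nodes (k^k labelings); above that a seeded
  coordinate-descent relabeling with local scoring is used.
* **TrueSkill fallback.** The standard update uses `v(t) = phi(t)/Phi(t)`;
  in the extreme tail where `Phi(t)` underflows, `v(t)` is replaced by its
  asymptote `-t`.
* **Determinism.** Clipper, the BNrich rule stage and all reports are
  deterministic given data; props, bpa and ensemble are deterministic given
  `(input, seed)`. Every internal random draw derives from one master seed
  via salted derivation (`derive_seed`), so pipelines are bit-reproducible.
* **Degenerate inputs.** Self-loops are stripped and ledgered before every
  strategy; duplicate edges collapse to the first occurrence with a warning;
  rank-deficient parent matrices fall back to the pseudo-inverse; zero
  variances yield p = 1 (clipper) or edge retention (LASSO) with warnings.

## What the synthetic generator does and does not emulate

`gen_scenario()` builds a random DAG on a fixed topological order
(the "truth"), annotates compartments by depth (membrane → cytoplasm →
nucleus), and adds feedback edges that run strictly against that axis
(interaction `inhibition` or `expression`) to create the observed cyclic
graph — so, by construction, the anti-flux edges are exactly the planted
feedbacks, and the rule-based strategy can recover the truth exactly.
Expression is ancestral-sampled from the truth: coefficients uniform on
±[0.5, 2], residual sd 1, root means around 5–9, and a deterministic
per-gene shift (computed from the implied means and variances of both
condition models, identical across conditions) keeps values on a nonnegative
log2(n+1)-like scale without clamping, so the closed-form covariance holds
exactly and is testable. The tumor condition adds a fixed delta to a chosen
subset of coefficients; delta 0 is the null world. Defaults (60 pairs, 12
pathways, delta 1.5 on 3 edges, ten 75/25 paired splits) are the scale at
which the comparison is run.

Not emulated: RNA-seq count noise (negative binomial), library-size and
batch effects, FPKM computation, and non-linear regulation. A green test
therefore establishes that the pipeline behaves correctly under its own
linear-Gaussian assumptions — not that any strategy is superior on real
tumor cohorts.

## Leakage and the repeated-split protocol

An early version fitted each pathway's BN once and then re-randomized the
train/test split per repeat. That inflates the null scenario to AUC ≈ 0.7:
control samples that the network saw during fitting carry inflated in-sample
log-likelihoods into later test sets, and the forest learns to read that
artifact. `run_enrichment()` therefore redraws the paired split per repeat,
refits every network on that split's control training samples, and rebuilds
the feature table before training the forest; with it the null scenario sits
at AUC 0.45–0.56 while the perturbed scenario is unaffected.
`train_eval_rf()` keeps the simpler fixed-feature-table contract for
features that are already leak-free with respect to each resplit. Graph
reconstruction itself is still performed once per pathway — a desk-scale
simplification; reconstruction depends on expression only through clipper
p-values and LASSO zero patterns, and its output is a graph, not a fitted
score, so its leakage pathway is far weaker.

## Known limitations

* The agony heuristic above 5 nodes is a local search; it matches the
  exhaustive optimum on small components but carries no global guarantee.
* The BNrich rule inventory is a three-rule reconstruction of prose
  guidance; rule ids are ledgered per removal so alternative rule sets can
  be swapped in.
* BIC ranks on synthetic data should be read qualitatively: they depend on
  the generator's density and noise scale.
* The Random Forest grows unpruned CART trees with bootstrap sampling and
  vote-fraction probabilities; it is intentionally minimal (binary
  classification, Gini importance) rather than a general-purpose forest.

```{r example}
g <- fixture_fig2()
find_sccs(g)
tidy(bnrich_rules(g))[, c("source", "target", "status", "reason")]
```
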