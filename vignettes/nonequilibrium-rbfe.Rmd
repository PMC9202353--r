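---
title: "Bidirectional nonequilibrium estimation of relative binding free energies"
author: "nebar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional nonequilibrium estimation of relative binding free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nebar)
```

## The problem and the model

Relative binding free energies (RBFE) rank a series of candidate ligands
against a common receptor: RBFE(A→B) = ΔG_B − ΔG_A, the difference of the
two absolute binding free energies. In the dual-topology nonequilibrium
(NE) formulation both compounds are present simultaneously; a coupling
parameter λ is driven over a *finite* time so that A's interaction with
its environment switches off while B's switches on, once in the bound
state of the receptor and once in bulk solvent. Each driven trajectory,
started from an equilibrium configuration of the initial end-state,
yields one work value W. Over a swarm of independent trajectories W is a
random variable whose distribution encodes both the free-energy change
and the dissipation of the protocol.

Three identities connect the work samples to free energies:

* **Jarzynski**: ⟨exp(−βW)⟩ = exp(−βΔG) over the forward (or reverse)
  sample alone, with β = 1/k_BT.
* **Crooks**: P_f(W)/P_r(−W) = exp[β(W − ΔG)]; the forward and
  (negated) reverse work densities cross exactly at W = ΔG.
* **Bennett acceptance ratio (BAR)**: the minimum-variance combination of
  both directions, obtained by solving a self-consistent equation in ΔG.

An edge estimate ΔΔG(A→B) is the bound-leg ΔG minus the unbound-leg ΔG,
plus a per-edge finite-size correction δG_fs supplied as a constant
(needed when the transmutation changes the ligand's net charge under
periodic boundaries; its derivation is outside this package's scope).

The package computes eight estimators per edge (`edge_estimate()`):
two-arm BAR; BAR\* on the *convolution* of bound-forward with
unbound-reverse work (and vice versa), the virtual
double-system-single-box construction that yields the edge ΔΔG in one
shot; per-arm Jarzynski differences J(FF)/J(RR); Jarzynski on the
convolved sets J\*(FR)/J\*(RF); and per-arm second-cumulant Gaussian
estimates G(FF)/G(RR).

## Conventions that matter

* **Units**: work and free energies in kcal/mol; k_B fixed at
  1.98720425864083e−3 kcal mol⁻¹ K⁻¹; default temperature 298.15 K
  (k_BT = 0.59249 kcal/mol).
* **Sign convention**: a reverse work set stores the work of the B→A
  process *as performed*, never pre-negated; estimators do all
  negations. Work files therefore go verbatim from simulation output to
  disk to analysis.
* **Population variance**: every estimator formula uses the
  maximum-likelihood (population) variance. This makes the convolution
  moment identities exact — the mean and population variance of the
  Cartesian sum set {W_i + W_j} are exactly the sums of the per-set
  means and population variances — and makes the per-arm Gaussian
  difference algebraically identical to the convolution-based Gaussian
  estimate. This identity is why the per-arm-then-difference convention
  was adopted for G(FF)/G(RR), a point on which the two readings of the
  estimator family are otherwise indistinguishable.
* **Bennett equation**: solved with the ln(n_f/n_r) sample-size offset
  (unequal direction counts are the norm: the reference study used 196
  bound and 96 unbound trajectories per direction). The solver runs
  Newton iteration from the symmetric guess (⟨W_f⟩ − ⟨W_r⟩)/2 and falls
  back to bracketed root finding on
  [min(−W_r) − pad, max(W_f) + pad] with the padding doubled up to four
  times. The residual at the returned root is below the solver tolerance
  (default 1e−8) and is exposed in the diagnostics. When the two work
  distributions are catastrophically disjoint the Bennett function is
  numerically flat at zero over a wide window, any root is meaningless,
  and the solver refuses with a "bracket failure" error rather than
  returning an arbitrary number.
* **Convolution cap**: the full Cartesian product is used up to 10⁶
  pairs (the in-study case is 196 × 96 ≈ 1.9 × 10⁴); beyond that a
  seeded uniform subsample of pairs guards pathological inputs.
* **Bootstrap**: uncertainties resample the *original per-leg* work sets
  with replacement and re-run the whole estimator (re-convolving inside
  each resample) — convolved points are not independent, so resampling
  them directly would understate the error. The resample count is a free
  choice (the reference study does not state one); the default is 1000,
  and the replicate studies in the test suite use 64–200 to keep the
  suite fast.
* **Normality screen**: Gaussian estimates carry a Jarque–Bera-type
  statistic (n/6·[skew² + (kurt−3)²/4], flagged above the χ²₂ 95% point
  5.99). Markedly non-normal work (e.g. a ligand starting as a ghost
  with several metastable poses) invalidates the second-cumulant
  formula; the estimate is *flagged, never suppressed*, so a table
  renders it with a marker instead of a hole.
* **Crossing-point diagnostic**: kernel densities (Gaussian kernel,
  Silverman bandwidth) of W_f and −W_r on a 512-point grid over the
  overlap window; the intersection nearest the midpoint of the two
  means is reported. It is a visual check on BAR, not an estimator.

## Network validation

`build_network()` / `network_from_table()` assemble edges into an RBFE
network; each unordered compound pair is stored once, in a declared
orientation, and queries in the opposite sense transparently negate the
value. Two self-consistency instruments:

* **Cycle closure** (`enumerate_cycles()`, `cycle_sum()`): the sum of
  edge values around any closed cycle must vanish within the quadrature
  sum of the edge errors. Both the signed and the absolute sum are
  reported: recomputing published closure tables showed that traversal
  conventions for longer cycles are not always recoverable from a
  printed table, and the absolute sum is convention-free.
* **Indirect RBFEs** (`indirect_rbfe()`): between non-adjacent
  compounds the estimate is summed along the path with the fewest
  edges (ties broken by lexicographically smallest node sequence), with
  quadrature errors; the transmutation count N_t is reported because the
  confidence interval widens with it. Routing is deliberately by edge
  count, not by error weight: it matches how indirect estimates are
  counted in the field's correlation plots.

`compare_stats()` gives MUE, mean signed error, Pearson r and the
best-fit line, dropping incomplete pairs with an explicit count;
`deviation_correlation()` correlates per-edge deviations between two
estimators with a chemical-dissimilarity metric (Tanimoto coefficient,
volume or charge change) stored on the edges. The relative charge- and
volume-change metrics have no canonical definition here and are
accepted as user-supplied fields.

## What the synthetic generators emulate

The package is testable end-to-end without molecular dynamics because
every estimator can be fed synthetic work with a known answer:

* `crooks_gaussian_sampler()` draws the unique Gaussian pair consistent
  with the Crooks relation at a given ΔG and σ (μ_f = ΔG + βσ²/2,
  μ_r = −ΔG + βσ²/2, equal variances) — the near-equilibrium limit of a
  real NE protocol.
* `bimodal_sampler()` mixes such components with exponentially
  reweighted reverse weights, remaining exactly Crooks-consistent with
  ΔG = −(1/β) ln Σ w_i exp(−βΔG_i); it emulates ligands with several
  metastable poses, whose work distributions are visibly multimodal.
* `dragged_trap_simulator()` is an overdamped Langevin particle in a
  trap translated at speed v: ΔF = 0 exactly, so the entire mean work
  is dissipation, growing ∝ v² at fixed duration, while the Jarzynski
  average must stay at 1.
* `alchemical_toy_switch()` is a 1D alchemical annihilation/growth
  process: a Langevin particle coupled to a fixed partner through
  either the *shifted* pair potential — a (1−λ) prefactor with the
  electrostatic and Lennard-Jones origins moved outward by λα (α =
  0.35 Å) and λβ (β = 4.0 Å), finite at contact for any λ > 0 — or a
  naive λ-scaled unshifted potential. The printed form of the shifted
  potential in the source material is not fully legible; the form
  implemented here is the package's own reconstruction that satisfies
  every stated property (pure end-states, shifted origins, finite at
  contact) and is isolated behind `shifted_potential_params()` so it
  can be swapped. A λ-independent harmonic confinement
  (1 kcal mol⁻¹ Å⁻², a stand-in for the surrounding medium) makes the
  ghost state normalisable; it is identical in both coupling modes, so
  the exact free-energy difference — computed by grid quadrature of the
  two 1D configuration integrals, the ground truth for all toy tests —
  is mode-independent. Initial configurations are drawn exactly by
  inverse-CDF sampling on a fine grid; work uses the switch-then-measure
  convention W = Σ[V(x_i; λ_{i+1}) − V(x_i; λ_i)], which makes the
  one-step (instantaneous) protocol identity exact. The deterministic
  drift per step is capped at 1 Å so that the intentionally singular
  linear-coupling mode remains integrable; work values are unaffected
  (work is a potential difference at frozen positions).

What these generators do *not* emulate: correlated trajectories, slow
orthogonal degrees of freedom, water reorganisation, protocol-dependent
work autocorrelation — so green tests demonstrate estimator
correctness, not MD convergence on real systems.

* `hrem_ladder()` reproduces the solute-tempering scaling protocol
  S_m = S^((m−1)/n). Note a quirk of the protocol as printed: for
  S = 0.1 and n = 16 the smallest factor is 0.1^(15/16) ≈ 0.115, not
  0.1 itself; the helper implements the formula literally.

## Problem sizes used by the shipped studies

The test-suite and acceptance-script studies run at the reference
study's per-edge sample sizes (196 bound / 96 unbound trajectories per
direction), 100 seeded replicates for the coverage study with 64
bootstrap resamples, 5000 trajectories for the trap identity, and
150–800 trajectories with 50–400 Langevin steps for the alchemical toy.
These sizes are the package's choice of a desk-scale experiment that
still leaves the statistical bands (≥95/100 within 3 SE, Jarzynski
average in [0.9, 1.1], ≥90% dissipation orderings) comfortably
resolvable.

## Known limitations

* The finite-size correction δG_fs is consumed, never derived; users
  must supply it per edge when the net charge changes.
* Values-only networks (built from a published table) support closure,
  indirect estimates and statistics, but estimators cannot run without
  the work samples.
* The Gaussian estimators are exact only for normal work distributions;
  the normality flag is advisory and conservative.
* The shortest-path rule is fewest-edges; on networks where a longer
  path has a much smaller quadrature error the reported indirect
  estimate is not the minimum-variance one.
* The 1D toy has a single alchemical site and no centre-of-mass tether
  between two ligands (the tether provably cancels at the end-states in
  the full method, so its omission does not bias the toy's free
  energies).

## A worked example

```{r example}
path <- system.file("extdata", "wp6_sampl9_rbfe.tsv", package = "nebar")
net <- read_network(path)
net

# primary cycle closure, bidirectional estimates
cycle_sum(net, c("g01", "g03", "g04", "g01"), "BAR")

# indirect estimate four compounds away from the reference
indirect_rbfe(net, "g03", "g09", "BAR")

# how far does a convolution-based unidirectional estimate drift from BAR?
long <- read_estimate_table(path)
bar_col <- long[long$method == "BAR", ]
jfr_col <- long[long$method == "J*(FR)", ]
m <- merge(bar_col, jfr_col, by = c("source", "target"))
compare_stats(m$value.y, m$value.x)
```

And a fully synthetic edge with known truth:

```{r synthetic}
b <- crooks_gaussian_sampler(3.0, 2, 196, 196, seed = 1, leg = "bound")
u <- crooks_gaussian_sampler(1.0, 1, 96, 96, seed = 2, leg = "unbound")
e <- edge_data("A", "B", works = list(
  bound_forward = b$forward, bound_reverse = b$reverse,
  unbound_forward = u$forward, unbound_reverse = u$reverse))
edge_estimate(e, "BAR", boot_set = bootstrap_settings(200, seed = 3))
edge_estimate(e, "BAR*", boot_set = bootstrap_settings(200, seed = 3))
```
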