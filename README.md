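# nebar — bidirectional nonequilibrium RBFE analysis

`nebar` analyses dual-topology **nonequilibrium alchemical** relative
binding free energy (RBFE) calculations. It is aimed at computational
chemists who already have nonequilibrium work samples — one work value
per driven alchemical trajectory, for the bound and unbound legs of a
thermodynamic cycle, in the forward and/or reverse direction — and need
the full estimator family, honest uncertainties, and network-level
validation, without touching an MD engine.

## The statistics at the core

For a process driven over finite time, the work W is a random variable
linked to the free-energy change ΔG by

* the Jarzynski identity ⟨e^(−βW)⟩ = e^(−βΔG),
* the Crooks relation P_f(W)/P_r(−W) = e^(β(W−ΔG)), and
* the Bennett acceptance ratio (BAR), the minimum-variance bidirectional
  estimator, solved self-consistently with the ln(n_f/n_r) offset for
  unequal sample sizes.

Per edge A→B the package computes ΔΔG = ΔG_bound − ΔG_unbound (plus a
supplied finite-size correction) with eight estimators: `BAR` (two-arm),
`BAR*` (BAR on the *convolution* of bound-forward with unbound-reverse
work — the virtual double-system-single-box construction), `J(FF)`,
`J(RR)`, `J*(FR)`, `J*(RF)` (Jarzynski, per-arm or convolved), and
`G(FF)`, `G(RR)` (second-cumulant Gaussian, ΔG = ⟨W⟩ − βσ²/2 with
population variance). Errors come from bootstrap resampling of the
original per-leg work sets. Networks of edges are validated by cycle
closure (Σ around any cycle ≈ 0 within quadrature error) and by
shortest-path indirect estimates against a reference compound.

A synthetic-data module (Crooks-consistent Gaussian/bimodal samplers, a
dragged-trap Langevin process with ΔF = 0, and a 1D alchemical switching
toy with a shifted-origin pair potential and exact grid-quadrature free
energies) provides ground truth for every test.

## Worked example

The package ships the published per-edge estimates for the 18
transmutations of the SAMPL9 WP6 host–guest network as a values-only
table:

```r
library(nebar)
path <- system.file("extdata", "wp6_sampl9_rbfe.tsv", package = "nebar")
net <- read_network(path)
net
#> <rbfe_network> 13 compounds, 18 edges, methods: BAR, BAR*, J(FF), J(RR),
#>   J*(FR), J*(RF), G(FF), G(RR) (values-only)

cycle_sum(net, c("g01", "g03", "g04", "g01"), "BAR")
#> <cycle> g01 -> g03 -> g04 -> g01 [BAR]: sum = -0.1 +/- 0.9 kcal/mol

indirect_rbfe(net, "g03", "g09", "BAR")
#> <estimate> BAR: 0.4 +/- 1.2 kcal/mol
```

The cycle sum −0.1 kcal/mol is well inside its 0.9 kcal/mol quadrature
error: the network is self-consistent around that triangle. The
indirect estimate reaches g09 three edges away from the reference g03,
its error widened by quadrature over the path.

A fully synthetic edge with known truth ΔΔG = 3.0 − 1.0 = 2.0:

```r
b <- crooks_gaussian_sampler(3.0, 2, 196, 196, seed = 1, leg = "bound")
u <- crooks_gaussian_sampler(1.0, 1, 96, 96, seed = 2, leg = "unbound")
e <- edge_data("A", "B", works = list(
  bound_forward = b$forward, bound_reverse = b$reverse,
  unbound_forward = u$forward, unbound_reverse = u$reverse))
edge_estimate(e, "BAR",  boot_set = bootstrap_settings(200, seed = 3))
#> <estimate> BAR: 2.3 +/- 0.2 kcal/mol
edge_estimate(e, "BAR*", boot_set = bootstrap_settings(200, seed = 3))
#> <estimate> BAR*: 2.3 +/- 0.2 kcal/mol
```

Both bidirectional estimators land within two standard errors of the
truth, and agree with each other — the expected behaviour when the work
distributions are Gaussian and overlapping.

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "nebar.R", package = "nebar")`:

```sh
Rscript nebar.R estimate --manifest edges.yaml --methods BAR,BAR* --out results
Rscript nebar.R cycles   --manifest wp6_sampl9_rbfe.tsv --methods BAR --max-edges 6
Rscript nebar.R network  --manifest wp6_sampl9_rbfe.tsv --reference g03
Rscript nebar.R simulate --kind crooks-gaussian --n 196 --delta-g 2 --seed 7
Rscript nebar.R compare  --table-a calc.tsv --table-b expt.tsv
```

Manifests are YAML (see `?read_edge_manifest`); work files are plain
text, one value per line, kcal/mol (see `?read_work_file`). Human-readable
tables are rounded to 0.1 kcal/mol; machine outputs keep full precision
and embed the seed, package version and input digests.

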