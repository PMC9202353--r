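# Synthetic nonequilibrium work generation with known ground truth:
# analytic Crooks-consistent samplers, driven overdamped Langevin toys,
# a shifted-potential 1D alchemical switch, and the solute-tempering
# scaling-ladder helper.

#' Protocol parameters for a synthetic switching process
#'
#' @param tau Protocol duration (reduced time units).
#' @param dt Integration timestep; must satisfy `0 < dt < tau`.
#' @param n_trajectories Number of independent switching trajectories.
#' @param temperature Temperature in kelvin (default 298.15, i.e.
#'   kT = 0.59249 kcal/mol so all outputs are in kcal/mol).
#' @param seed Integer seed; generators are bit-reproducible given it.
#' @param schedule Only `"linear"`: `lambda(t) = t/tau` forward,
#'   `1 - t/tau` reverse.
#' @return A list of class `toy_protocol`.
#' @export
toy_protocol <- function(tau, dt, n_trajectories, temperature = 298.15,
                         seed = 1L, schedule = "linear") {
  stopifnot(dt > 0, dt <= tau, n_trajectories >= 1)
  schedule <- match.arg(schedule, "linear")
  structure(list(tau = tau, dt = dt,
                 n_trajectories = as.integer(n_trajectories),
                 temperature = temperature, seed = as.integer(seed),
                 schedule = schedule),
            class = "toy_protocol")
}

#' Parameters of the shifted pair potential
#'
#' Describes a single Lennard-Jones plus Coulomb pair interaction whose
#' electrostatic and LJ origins are shifted outward during alchemical
#' switching, keeping the energy finite at contact without reshaping the
#' potential (as soft-core regularization would).
#'
#' @param epsilon LJ well depth, kcal/mol.
#' @param sigma_lj LJ diameter, Angstrom.
#' @param charge_product Product of the charges premultiplied by the
#'   Coulomb constant, kcal Angstrom / mol.
#' @param alpha_shift Electrostatic origin shift, Angstrom (default 0.35).
#' @param beta_shift LJ origin shift, Angstrom (default 4.0).  These are
#'   length shifts, unrelated to the thermodynamic beta.
#' @return A list of class `shifted_potential_params`.
#' @export
shifted_potential_params <- function(epsilon = 0.25, sigma_lj = 1.8,
                                     charge_product = 0,
                                     alpha_shift = 0.35, beta_shift = 4.0) {
  stopifnot(epsilon >= 0, sigma_lj > 0, alpha_shift >= 0, beta_shift >= 0)
  structure(list(epsilon = epsilon, sigma_lj = sigma_lj,
                 charge_product = charge_product,
                 alpha_shift = alpha_shift, beta_shift = beta_shift),
            class = "shifted_potential_params")
}

#' Crooks-consistent Gaussian work sampler
#'
#' Draws forward and reverse work samples from the unique pair of Gaussian
#' distributions with common variance `sigma^2` satisfying the Crooks
#' relation for a process of free-energy change `delta_g`:
#' forward ~ N(delta_g + beta sigma^2 / 2, sigma^2) and
#' reverse ~ N(-delta_g + beta sigma^2 / 2, sigma^2).
#'
#' @param delta_g Ground-truth free-energy change, kcal/mol.
#' @param sigma Work standard deviation, kcal/mol (>= 0).
#' @param n_forward,n_reverse Sample sizes.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @param leg Leg tag for the returned sets (default `"bound"`).
#' @return List with elements `forward` and `reverse` ([work_set()]s).
#' @export
crooks_gaussian_sampler <- function(delta_g, sigma, n_forward, n_reverse,
                                    temperature = 298.15, seed = 1L,
                                    leg = "bound") {
  stopifnot(sigma >= 0, n_forward >= 1, n_reverse >= 1)
  b <- thermal_beta(temperature)
  wd <- b * sigma^2 / 2
  vals <- withr::with_seed(seed, list(
    f = stats::rnorm(n_forward, delta_g + wd, sigma),
    r = stats::rnorm(n_reverse, -delta_g + wd, sigma)))
  list(forward = work_set(vals$f, "forward", leg, temperature,
                          label = sprintf("crooks-gaussian dG=%.4g", delta_g)),
       reverse = work_set(vals$r, "reverse", leg, temperature,
                          label = sprintf("crooks-gaussian dG=%.4g", delta_g)))
}

#' Crooks-consistent bimodal (Gaussian-mixture) work sampler
#'
#' Emulates the work distribution of a ligand with several metastable
#' binding poses: a mixture of Crooks-consistent Gaussian components.
#' Component `i` has weight `weights[i]` in the forward direction; in the
#' reverse direction the weights are exponentially reweighted to
#' `weights[i] * exp(-beta * delta_gs[i])` (renormalised), which keeps the
#' overall pair Crooks-consistent with ground truth
#' `DG = -(1/beta) log( sum_i w_i exp(-beta DG_i) )`.
#'
#' @param weights Mixture weights summing to 1.
#' @param delta_gs Component free-energy changes, kcal/mol (one per weight).
#' @param sigma Common component standard deviation, kcal/mol.
#' @param n_forward,n_reverse Sample sizes.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @param leg Leg tag (default `"bound"`).
#' @return List with `forward`, `reverse` ([work_set()]s) and the implied
#'   overall `delta_g`.
#' @export
bimodal_sampler <- function(weights, delta_gs, sigma, n_forward, n_reverse,
                            temperature = 298.15, seed = 1L, leg = "bound") {
  if (length(weights) != length(delta_gs))
    stop("bimodal_sampler: one delta_g per weight required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("bimodal_sampler: weights must sum to 1")
  b <- thermal_beta(temperature)
  wd <- b * sigma^2 / 2
  # overall free energy of the mixture (log-sum-exp for stability)
  x <- log(weights) - b * delta_gs
  m <- max(x)
  dg_tot <- -(1 / b) * (m + log(sum(exp(x - m))))
  wr <- exp(x - m); wr <- wr / sum(wr)
  vals <- withr::with_seed(seed, {
    cf <- sample.int(length(weights), n_forward, replace = TRUE,
                     prob = weights)
    cr <- sample.int(length(weights), n_reverse, replace = TRUE, prob = wr)
    list(f = stats::rnorm(n_forward, delta_gs[cf] + wd, sigma),
         r = stats::rnorm(n_reverse, -delta_gs[cr] + wd, sigma))
  })
  list(forward = work_set(vals$f, "forward", leg, temperature,
                          label = sprintf("bimodal dG=%.4g", dg_tot)),
       reverse = work_set(vals$r, "reverse", leg, temperature,
                          label = sprintf("bimodal dG=%.4g", dg_tot)),
       delta_g = dg_tot)
}

#' Dragged harmonic trap: a minimal dissipative switching process
#'
#' Overdamped Langevin particle in a harmonic trap whose centre moves at
#' constant speed `v` for the protocol duration.  The free-energy change
#' is exactly zero (the trap merely translates), so every work sample is
#' pure dissipation and the Jarzynski average `<exp(-beta W)>` must equal
#' 1.  The mean dissipation grows with the driving speed.
#'
#' The particle starts from thermal equilibrium in the resting trap; work
#' is accumulated per step as the energy change under the trap
#' displacement at frozen particle position,
#' `W = sum_i [V(x_i; c_{i+1}) - V(x_i; c_i)]`.
#'
#' @param stiffness Trap force constant k, kcal/mol/Angstrom^2 (> 0).
#' @param speed Trap speed v, Angstrom per reduced time.
#' @param friction Friction gamma (> 0); the free diffusion constant is
#'   `kT/gamma`.
#' @param protocol A [toy_protocol()].
#' @return A [work_set()] (forward, bound-leg tag) of per-trajectory works.
#' @export
dragged_trap_simulator <- function(stiffness, speed, friction, protocol) {
  stopifnot(inherits(protocol, "toy_protocol"), stiffness > 0, friction > 0)
  dt <- protocol$dt
  if (stiffness * dt / friction > 0.1)
    stop("integrator unstable: require stiffness * dt / friction <= 0.1")
  n <- protocol$n_trajectories
  kT <- .kB * protocol$temperature
  nstep <- max(1L, round(protocol$tau / dt))
  work <- withr::with_seed(protocol$seed, {
    x <- stats::rnorm(n, 0, sqrt(kT / stiffness))  # equilibrium start
    w <- numeric(n)
    noise_sd <- sqrt(2 * kT * dt / friction)
    for (i in seq_len(nstep)) {
      c_old <- speed * (i - 1L) * dt
      c_new <- speed * i * dt
      # switch-then-measure: move the trap, pay the energy difference
      w <- w + 0.5 * stiffness * ((x - c_new)^2 - (x - c_old)^2)
      x <- x - (stiffness / friction) * (x - c_new) * dt +
        stats::rnorm(n, 0, noise_sd)
    }
    w
  })
  work_set(work, "forward", "bound", protocol$temperature,
           label = sprintf("dragged-trap v=%.3g", speed))
}

#' Shifted Lennard-Jones + Coulomb pair energy
#'
#' Alchemically attenuated pair interaction
#' `(1 - lambda) * [ q/(r + lambda a) + 4 eps ((s/(r + lambda b))^12 -
#' (s/(r + lambda b))^6) ]` with electrostatic origin shift `a` and LJ
#' origin shift `b`.  At `lambda = 0` this is the exact unshifted pair
#' energy; at `lambda = 1` it vanishes for every `r` (ghost state); for
#' any `lambda > 0` it stays finite down to contact (`r -> 0`), which is
#' the point of the regularization: the origin is moved instead of the
#' potential being softened.
#'
#' @param r Interparticle distance, Angstrom (> 0); vectorised.
#' @param lam Coupling parameter in `[0, 1]`; 1 is the ghost state.
#' @param params A [shifted_potential_params()].
#' @return Energy in kcal/mol.
#' @export
shifted_pair_potential <- function(r, lam, params = shifted_potential_params()) {
  if (any(r <= 0)) stop("shifted_pair_potential: r must be > 0")
  stopifnot(lam >= 0, lam <= 1)
  re <- r + lam * params$alpha_shift
  rl <- r + lam * params$beta_shift
  s6 <- (params$sigma_lj / rl)^6
  (1 - lam) * (params$charge_product / re +
                 4 * params$epsilon * (s6^2 - s6))
}

# naive lambda-scaled unshifted coupling (diverges at contact for lam < 1)
.linear_pair_potential <- function(r, lam, params) {
  s6 <- (params$sigma_lj / r)^6
  (1 - lam) * (params$charge_product / r +
                 4 * params$epsilon * (s6^2 - s6))
}

.pair_potential <- function(r, lam, params, mode) {
  if (mode == "shifted") shifted_pair_potential(r, lam, params)
  else .linear_pair_potential(r, lam, params)
}

# d/dr of the pair potential (vectorised)
.pair_force <- function(r, lam, params, mode) {
  if (mode == "shifted") {
    re <- r + lam * params$alpha_shift
    rl <- r + lam * params$beta_shift
    s6 <- (params$sigma_lj / rl)^6
    (1 - lam) * (-params$charge_product / re^2 +
                   4 * params$epsilon * (-12 * s6^2 + 6 * s6) / rl)
  } else {
    s6 <- (params$sigma_lj / r)^6
    (1 - lam) * (-params$charge_product / r^2 +
                   4 * params$epsilon * (-12 * s6^2 + 6 * s6) / r)
  }
}

# total toy potential: pair coupling at distance |x| from a fixed partner
# at the origin, plus a lambda-independent harmonic confinement (a solvent
# cage proxy) that makes the ghost state normalisable.
.toy_potential <- function(x, lam, params, mode, k_conf) {
  r <- pmax(abs(x), 1e-9)   # grid points may sit exactly at contact
  .pair_potential(r, lam, params, mode) + 0.5 * k_conf * x^2
}

.toy_dvdx <- function(x, lam, params, mode, k_conf) {
  r <- pmax(abs(x), 1e-9)
  sign(x) * .pair_force(r, lam, params, mode) + k_conf * x
}

# exact free-energy difference F(lam_b) - F(lam_a) of the 1D toy by grid
# quadrature of the configuration integrals.
toy_free_energy <- function(params, mode, k_conf, temperature,
                            lam_a = 0, lam_b = 1, half_width = NULL,
                            n_grid = 20001L) {
  kT <- .kB * temperature
  if (is.null(half_width)) half_width <- 8 * sqrt(kT / k_conf)
  x <- seq(-half_width, half_width, length.out = n_grid)
  ua <- .toy_potential(x, lam_a, params, mode, k_conf)
  ub <- .toy_potential(x, lam_b, params, mode, k_conf)
  logz <- function(u) {       # log of the configuration integral, stable
    m <- min(u)
    -m / kT + log(sum(exp(-(u - m) / kT)) * (x[2] - x[1]))
  }
  -kT * (logz(ub) - logz(ua))
}

# inverse-CDF sampling from the 1D Boltzmann density at fixed lambda
.sample_toy_equilibrium <- function(n, lam, params, mode, k_conf,
                                    temperature) {
  kT <- .kB * temperature
  half_width <- 8 * sqrt(kT / k_conf)
  x <- seq(-half_width, half_width, length.out = 8192L)
  u <- .toy_potential(x, lam, params, mode, k_conf)
  p <- exp(-(u - min(u)) / kT)
  cdf <- cumsum(p); cdf <- cdf / cdf[length(cdf)]
  u01 <- stats::runif(n)
  x[findInterval(u01, cdf) + 1L]
}

#' 1D alchemical switching toy (shifted vs linear coupling)
#'
#' A single overdamped Langevin particle interacts with a fixed partner at
#' the origin through either the shifted pair coupling
#' ([shifted_pair_potential()]) or a naive lambda-scaled unshifted
#' coupling, plus a lambda-independent harmonic confinement that stands in
#' for the surrounding medium and makes the decoupled (ghost) state
#' normalisable.  Lambda is driven linearly from 0 to 1 (forward,
#' annihilation) and from 1 to 0 (reverse, growth), starting each
#' trajectory from exact equilibrium at the initial state.  Work is
#' accumulated with the switch-then-measure convention
#' `W = sum_i [V(x_i; lambda_{i+1}) - V(x_i; lambda_i)]`, which makes the
#' instantaneous-protocol identity `W = V(x_0; 1) - V(x_0; 0)` exact.
#'
#' Because the end-states of the two coupling modes are identical, their
#' free energies agree; only the dissipation along the path differs, which
#' is what the shifted form is designed to reduce during growth.
#'
#' @param params A [shifted_potential_params()].
#' @param protocol A [toy_protocol()].
#' @param mode `"shifted"` or `"linear"` coupling.
#' @param friction Langevin friction gamma (default 1).
#' @param k_conf Confinement force constant, kcal/mol/Angstrom^2
#'   (default 1).
#' @return List with `forward` and `reverse` [work_set()]s (bound leg) and
#'   `delta_g`, the exact forward free-energy change computed by grid
#'   quadrature of the two configuration integrals.
#' @export
alchemical_toy_switch <- function(params, protocol,
                                  mode = c("shifted", "linear"),
                                  friction = 1, k_conf = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "toy_protocol"), friction > 0, k_conf > 0)
  dt <- protocol$dt
  if (k_conf * dt / friction > 0.1)
    stop("integrator unstable: require k_conf * dt / friction <= 0.1")
  n <- protocol$n_trajectories
  kT <- .kB * protocol$temperature
  nstep <- max(1L, round(protocol$tau / dt))
  noise_sd <- sqrt(2 * kT * dt / friction)
  max_step <- 1.0   # cap on the deterministic drift per step, Angstrom

  run_leg <- function(lam_seq, seed_off) {
    withr::with_seed(protocol$seed + seed_off, {
      x <- .sample_toy_equilibrium(n, lam_seq[1], params, mode, k_conf,
                                   protocol$temperature)
      w <- numeric(n)
      for (i in seq_len(nstep)) {
        w <- w + .toy_potential(x, lam_seq[i + 1L], params, mode, k_conf) -
          .toy_potential(x, lam_seq[i], params, mode, k_conf)
        drift <- -.toy_dvdx(x, lam_seq[i + 1L], params, mode, k_conf) *
          dt / friction
        drift <- pmax(pmin(drift, max_step), -max_step)
        x <- x + drift + stats::rnorm(n, 0, noise_sd)
      }
      w
    })
  }
  lam <- seq(0, 1, length.out = nstep + 1L)
  wf <- run_leg(lam, 0L)
  wr <- run_leg(rev(lam), 1L)
  dg <- toy_free_energy(params, mode, k_conf, protocol$temperature)
  list(forward = work_set(wf, "forward", "bound", protocol$temperature,
                          label = sprintf("toy-switch %s annihilation", mode)),
       reverse = work_set(wr, "reverse", "bound", protocol$temperature,
                          label = sprintf("toy-switch %s growth", mode)),
       delta_g = dg)
}

#' Solute-tempering scaling ladder
#'
#' Scaling factors along a Hamiltonian replica-exchange ladder,
#' `S_m = s_min^((m - 1) / n)` for `m = 1, ..., n`: the first replica is
#' unscaled (factor exactly 1) and the factors decrease geometrically
#' toward (but not reaching) `s_min`.
#'
#' @param s_min Maximum (smallest) scaling factor, in `(0, 1]`.
#' @param n_replicas Number of replicas (>= 1).
#' @return Numeric vector of length `n_replicas`.
#' @examples
#' hrem_ladder(0.1, 16)[16]   # 0.1^(15/16) = 0.11548
#' @export
hrem_ladder <- function(s_min, n_replicas) {
  stopifnot(s_min > 0, s_min <= 1, n_replicas >= 1)
  s_min^((seq_len(n_replicas) - 1) / n_replicas)
}

#' Linear-regression Crooks diagnostic
#'
#' By the Crooks relation, `(1/beta) * log( P_f(W) / P_r(-W) )` is linear
#' in `W` with unit slope (in beta units) and crosses zero at `W = DG`.
#' This estimates the log-ratio on a common histogram of the forward works
#' and negated reverse works, keeps bins where both samples have at least
#' `min_count` entries, and regresses the log-ratio (in kcal/mol) on `W`.
#'
#' @param forward,reverse [work_set()] objects.
#' @param n_bins Number of histogram bins over the joint range.
#' @param min_count Minimum per-sample bin occupancy (default 50).
#' @return List with `slope` (should be ~1), `delta_g` (the x-intercept,
#'   should be ~DG) and `n_bins_used`.
#' @export
crooks_diagnostic <- function(forward, reverse, n_bins = 40, min_count = 50) {
  wf <- forward$values; wr <- -reverse$values
  b <- beta_of(forward)
  lo <- max(min(wf), min(wr)); hi <- min(max(wf), max(wr))
  if (!(lo < hi)) stop("crooks_diagnostic: no overlap")
  brk <- seq(lo, hi, length.out = n_bins + 1L)
  cf <- tabulate(findInterval(wf, brk, rightmost.closed = TRUE,
                              all.inside = FALSE), n_bins + 1L)[seq_len(n_bins)]
  cr <- tabulate(findInterval(wr, brk, rightmost.closed = TRUE,
                              all.inside = FALSE), n_bins + 1L)[seq_len(n_bins)]
  keep <- cf >= min_count & cr >= min_count
  if (sum(keep) < 3) stop("crooks_diagnostic: fewer than 3 well-populated bins")
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  # densities normalised over their own sample size
  y <- (1 / b) * log((cf[keep] / length(wf)) / (cr[keep] / length(wr)))
  fit <- stats::lm(y ~ mid[keep])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(slope = slope, delta_g = -intercept / slope, n_bins_used = sum(keep))
}

#' Write generated work sets and their ground truth to disk
#'
#' Writes each work set as a standard plain-text work file plus a YAML
#' sidecar recording the ground-truth free energy, the generator
#' parameters and the seed: the fixture format used throughout the test
#' suite.
#'
#' @param sets Named list of [work_set()] objects; names become file stems.
#' @param dir Output directory (created if needed).
#' @param ground_truth Ground-truth free energy, kcal/mol (may be `NA`).
#' @param parameters Named list of generator parameters for the sidecar.
#' @return Character vector of the file paths written, invisibly.
#' @export
write_toy_fixture <- function(sets, dir, ground_truth = NA_real_,
                              parameters = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sets)) {
    p <- file.path(dir, paste0(nm, ".work"))
    write_work_file(sets[[nm]], p,
                    header = sprintf("%s %s work, kcal/mol",
                                     sets[[nm]]$leg, sets[[nm]]$direction))
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "ground_truth.yaml")
  yaml::write_yaml(c(list(delta_g_kcal_mol = ground_truth), parameters),
                   meta)
  invisible(c(paths, meta))
}
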