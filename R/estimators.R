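# Free-energy estimators for bidirectional nonequilibrium alchemy.
#
# All estimators take work in kcal/mol and return free energies in kcal/mol.
# Population (maximum-likelihood) variances are used throughout so that the
# moment-additivity identities of the work-convolution construction hold
# exactly.

#' Numerical settings for the Bennett acceptance ratio solver
#'
#' @param tolerance Convergence tolerance on the free energy, kcal/mol.
#' @param max_iterations Maximum Newton iterations before falling back to
#'   bracketed root finding.
#' @param bracket_padding Padding (kcal/mol) added to the work range when
#'   bracketing the root; escalated by doubling up to 4 times.
#' @return A list of class `bar_settings`.
#' @export
bar_settings <- function(tolerance = 1e-8, max_iterations = 200,
                         bracket_padding = 50) {
  stopifnot(tolerance > 0, max_iterations >= 1, bracket_padding > 0)
  structure(list(tolerance = tolerance, max_iterations = max_iterations,
                 bracket_padding = bracket_padding),
            class = "bar_settings")
}

#' Settings for bootstrap uncertainty estimation
#'
#' @param n_resamples Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; all bootstrap randomness flows from it.
#' @param confidence Confidence level; the default 0.68 reports the plain
#'   standard error (standard deviation of the resampled estimates).
#' @return A list of class `bootstrap_settings`.
#' @export
bootstrap_settings <- function(n_resamples = 1000, seed = 1L,
                               confidence = 0.68) {
  stopifnot(n_resamples >= 2, confidence > 0, confidence < 1)
  structure(list(n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), confidence = confidence),
            class = "bootstrap_settings")
}

# Estimate container --------------------------------------------------------

fe_estimate <- function(value, stderr = NA_real_, method,
                        n_forward = NA_integer_, n_reverse = NA_integer_,
                        diagnostics = list()) {
  if (!is.finite(value)) stop("estimate value is not finite")
  if (!is.na(stderr) && stderr < 0) stop("stderr must be >= 0")
  structure(list(value = value, stderr = stderr, method = method,
                 n_forward = n_forward, n_reverse = n_reverse,
                 diagnostics = diagnostics),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  se <- if (is.na(x$stderr)) "" else sprintf(" +/- %.1f", x$stderr)
  cat(sprintf("<estimate> %s: %.1f%s kcal/mol\n", x$method, x$value, se))
  if (!is.null(x$diagnostics$nonnormal) && isTRUE(x$diagnostics$nonnormal))
    cat("  [!] work distribution flagged as non-normal\n")
  invisible(x)
}

# log( mean( exp(x) ) ), stable
.logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# population (ML) variance
.popvar <- function(x) mean((x - mean(x))^2)

#' Jarzynski exponential-average free-energy estimate
#'
#' Computes `DG = -(1/beta) * log( mean( exp(-beta * W) ) )` over the work
#' sample, using a log-sum-exp formulation stable for very large `|beta W|`.
#' By Jensen's inequality the estimate never exceeds the mean work.
#'
#' The estimate refers to the process that produced the sample: applied to a
#' reverse-direction work set it estimates the free-energy change of the
#' reverse process (i.e. minus that of the forward one).
#'
#' @param ws A [work_set()].
#' @return An [fe_estimate] with `method = "J"`, and the per-sample
#'   dissipation `mean(W) - DG` in `diagnostics$dissipation`.
#' @examples
#' ws <- work_set(c(1, 1, 1), "forward", "bound")
#' jarzynski(ws)$value   # 1
#' @export
jarzynski <- function(ws) {
  stopifnot(inherits(ws, "work_set"))
  b <- beta_of(ws)
  val <- -(1 / b) * .logmeanexp(-b * ws$values)
  fe_estimate(val, method = "J",
              n_forward = if (ws$direction == "forward") length(ws$values)
                          else NA_integer_,
              n_reverse = if (ws$direction == "reverse") length(ws$values)
                          else NA_integer_,
              diagnostics = list(dissipation = mean(ws$values) - val))
}

#' Composite normality screen for a work sample
#'
#' Jarque-Bera-type statistic `n/6 * (skew^2 + (kurt - 3)^2 / 4)` built from
#' the sample skewness and kurtosis, with an advisory flag at the chi-square
#' 95% point (5.99, 2 df).  Used to annotate Gaussian estimates on markedly
#' non-normal work distributions; estimates are flagged, never suppressed.
#'
#' @param values Numeric vector (n >= 4 for a meaningful statistic).
#' @return List with `statistic`, `skewness`, `kurtosis` and logical
#'   `nonnormal`.
#' @export
normality_screen <- function(values) {
  n <- length(values)
  m <- mean(values)
  s2 <- .popvar(values)
  if (s2 == 0 || n < 4)
    return(list(statistic = 0, skewness = 0, kurtosis = 3, nonnormal = FALSE))
  skew <- mean((values - m)^3) / s2^1.5
  kurt <- mean((values - m)^4) / s2^2
  stat <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = stat, skewness = skew, kurtosis = kurt,
       nonnormal = stat > stats::qchisq(0.95, df = 2))
}

#' Second-cumulant (Gaussian) free-energy estimate
#'
#' `DG = mean(W) - beta * sigma^2 / 2`, with `sigma^2` the population
#' (maximum-likelihood) variance.  Exact for Gaussian work distributions;
#' the returned diagnostics carry a normality screen ([normality_screen()])
#' whose flag is advisory only.
#'
#' @param ws A [work_set()] with at least 2 values.
#' @return An [fe_estimate] with `method = "G"`.
#' @export
gaussian_estimate <- function(ws) {
  stopifnot(inherits(ws, "work_set"))
  if (length(ws$values) < 2) stop("gaussian_estimate: variance undefined (n < 2)")
  b <- beta_of(ws)
  s2 <- .popvar(ws$values)
  val <- mean(ws$values) - b * s2 / 2
  scr <- normality_screen(ws$values)
  fe_estimate(val, method = "G",
              n_forward = if (ws$direction == "forward") length(ws$values)
                          else NA_integer_,
              n_reverse = if (ws$direction == "reverse") length(ws$values)
                          else NA_integer_,
              diagnostics = c(scr, list(dissipation = b * s2 / 2)))
}

# Bennett implicit function: monotone increasing in dg.
# wf: forward works; wr: reverse works (as performed); all in kcal/mol.
# g(dg) = sum_F fermi(M + b(Wf - dg)) - sum_R fermi(-M + b(Wr + dg))
# with M = log(nf/nr) and fermi(x) = 1/(1+exp(x)) ... note fermi is
# decreasing, so g is increasing in dg.
.bar_fn <- function(dg, wf, wr, b, M) {
  sum(stats::plogis(-(M + b * (wf - dg)))) -
    sum(stats::plogis(-(-M + b * (wr + dg))))
}

.bar_grad <- function(dg, wf, wr, b, M) {
  pf <- stats::plogis(-(M + b * (wf - dg)))
  pr <- stats::plogis(-(-M + b * (wr + dg)))
  b * sum(pf * (1 - pf)) + b * sum(pr * (1 - pr))
}

#' Bennett acceptance ratio (BAR) from forward and reverse work samples
#'
#' Solves the self-consistent Bennett equation, including the
#' `log(n_f / n_r)` offset for unequal sample sizes, for the free-energy
#' change of the forward process.  The reverse sample holds the work of the
#' reverse process as performed (not pre-negated).  The root is found by
#' Newton iteration from a second-cumulant initial guess, guarded by
#' bracketed root finding over
#' `[min(-W_r) - pad, max(W_f) + pad]` with padding escalation.
#'
#' @param forward,reverse [work_set()] objects at the same temperature.
#' @param settings A [bar_settings()].
#' @return An [fe_estimate] with `method = "BAR"`; diagnostics carry the
#'   per-direction dissipations `mean(W_f) - DG` and `mean(W_r) + DG`, a
#'   kernel-density overlap measure of the forward and negated-reverse work
#'   distributions, the Bennett residual, and a convergence flag.
#' @examples
#' f <- work_set(2.5, "forward", "bound"); r <- work_set(-2.5, "reverse", "bound")
#' bar(f, r)$value   # 2.5, zero-dissipation symmetric case
#' @export
bar <- function(forward, reverse, settings = bar_settings()) {
  stopifnot(inherits(forward, "work_set"), inherits(reverse, "work_set"))
  if (abs(forward$temperature - reverse$temperature) > 1e-9)
    stop("bar: temperature mismatch between forward and reverse sets")
  wf <- forward$values; wr <- reverse$values
  b <- beta_of(forward)
  M <- log(length(wf) / length(wr))
  fn <- function(dg) .bar_fn(dg, wf, wr, b, M)

  # Newton from the symmetric crude guess
  dg <- (mean(wf) - mean(wr)) / 2
  converged <- FALSE
  for (it in seq_len(settings$max_iterations)) {
    g <- fn(dg)
    dgr <- .bar_grad(dg, wf, wr, b, M)
    if (dgr <= 0) break
    step <- g / dgr
    dg_new <- dg - step
    if (!is.finite(dg_new)) break
    if (abs(dg_new - dg) < settings$tolerance) {
      dg <- dg_new; converged <- TRUE; break
    }
    dg <- dg_new
  }
  if (!converged) {
    # bracketed fallback with padding escalation
    pad <- settings$bracket_padding
    lo <- min(-wr); hi <- max(wf)
    ok <- FALSE
    for (esc in 0:4) {
      lo_p <- lo - pad; hi_p <- hi + pad
      if (fn(lo_p) < 0 && fn(hi_p) > 0) { ok <- TRUE; break }
      pad <- pad * 2
    }
    if (!ok) stop("BAR bracket failure: forward and reverse work ",
                  "distributions do not overlap")
    dg <- stats::uniroot(fn, c(lo_p, hi_p),
                         tol = min(settings$tolerance, 1e-10))$root
    converged <- TRUE
  }
  res <- fn(dg)
  # a catastrophically non-overlapping pair leaves the Bennett function
  # numerically flat at zero over a wide window around the root: the
  # "solution" is then arbitrary and must be refused
  n_tot <- length(wf) + length(wr)
  if (abs(res) < 1e-8 * n_tot &&
      abs(fn(dg - 1)) < 1e-8 * n_tot && abs(fn(dg + 1)) < 1e-8 * n_tot)
    stop("BAR bracket failure: forward and reverse work distributions ",
         "do not overlap")
  fe_estimate(dg, method = "BAR",
              n_forward = length(wf), n_reverse = length(wr),
              diagnostics = list(
                dissipation_forward = mean(wf) - dg,
                dissipation_reverse = mean(wr) + dg,
                overlap = work_overlap(wf, -wr),
                residual = res,
                converged = converged))
}

# integral of min(p, q) for two KDEs on a common grid; 0..1
work_overlap <- function(x, y) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(1)
  dx <- stats::density(x, from = rng[1], to = rng[2], n = 256)
  dy <- stats::density(y, from = rng[1], to = rng[2], n = 256)
  sum(pmin(dx$y, dy$y)) * diff(dx$x[1:2])
}

#' Convolve two work samples (virtual double-system construction)
#'
#' Returns the set of pairwise sums `{W_i + W_j}`: the empirical analogue of
#' convolving the two work distributions.  Used to combine the bound-leg
#' work with the opposite-direction unbound-leg work so that an edge RBFE
#' can be estimated in a single shot.  When `length(a) * length(b)` exceeds
#' `max_products` a seeded uniform random subsample of `max_products` pairs
#' is drawn instead of the full Cartesian product.
#'
#' In the full-product regime the mean of the result is exactly
#' `mean(a) + mean(b)` and its population variance is exactly the sum of
#' the population variances.
#'
#' @param a,b [work_set()] objects at the same temperature.
#' @param max_products Cap on the number of pairwise sums (default 1e6).
#' @param seed Integer seed for the subsampling branch.
#' @return A [work_set()] with `leg = "combined"` and the direction of `a`.
#' @export
convolve_work <- function(a, b, max_products = 1e6, seed = 1L) {
  stopifnot(inherits(a, "work_set"), inherits(b, "work_set"))
  if (abs(a$temperature - b$temperature) > 1e-9)
    stop("convolve_work: temperature mismatch")
  na <- length(a$values); nb <- length(b$values)
  if (as.double(na) * nb <= max_products) {
    vals <- as.vector(outer(a$values, b$values, `+`))
  } else {
    vals <- withr::with_seed(seed, {
      i <- sample.int(na, max_products, replace = TRUE)
      j <- sample.int(nb, max_products, replace = TRUE)
      a$values[i] + b$values[j]
    })
  }
  work_set(vals, direction = a$direction, leg = "combined",
           temperature = a$temperature,
           label = paste(a$label, "(*)", b$label))
}

#' Apply a finite-size correction to a free-energy value
#'
#' The correction for periodic-boundary/charge artifacts is supplied as a
#' per-edge constant (kcal/mol) and simply added to the RBFE.
#'
#' @param value Free energy, kcal/mol.
#' @param delta_fs Correction, kcal/mol.
#' @return `value + delta_fs`.
#' @export
apply_fs_correction <- function(value, delta_fs) value + delta_fs

#' Dissipated work of a nonequilibrium process
#'
#' `W_diss = mean(W) - DG`: the excess of the mean work over the underlying
#' free-energy change.  Non-negative in expectation by the second law.
#'
#' @param ws A [work_set()].
#' @param delta_g Free-energy change of the process that produced `ws`,
#'   kcal/mol.
#' @return Dissipation in kcal/mol.
#' @export
dissipation <- function(ws, delta_g) {
  stopifnot(inherits(ws, "work_set"))
  mean(ws$values) - delta_g
}

#' Crossing point of the forward and reverse work densities
#'
#' Estimates where the forward density of `W` and the reverse density of
#' `-W` intersect: by the Crooks relation the two densities cross at
#' `W = DG`, so this is a visual/diagnostic estimate of the free energy.
#' Gaussian kernel densities (Silverman bandwidth) are evaluated on a
#' common grid restricted to the overlap window of the two supports, and
#' the intersection is located by sign change of the density difference
#' (linear interpolation; when several crossings exist the one closest to
#' the midpoint of the two density means is returned).  If the densities
#' are numerically indistinguishable the common mode is returned.
#'
#' @param forward,reverse [work_set()] objects.
#' @param n_grid Number of grid points (default 512).
#' @return The crossing work value, kcal/mol.
#' @export
crossing_point <- function(forward, reverse, n_grid = 512) {
  stopifnot(inherits(forward, "work_set"), inherits(reverse, "work_set"))
  wf <- forward$values
  wr <- -reverse$values    # reverse works mapped onto the forward axis
  lo <- max(min(wf), min(wr)); hi <- min(max(wf), max(wr))
  if (!(lo < hi)) stop("crossing_point: no overlap between the forward and ",
                       "negated reverse work supports")
  df <- stats::density(wf, from = lo, to = hi, n = n_grid)
  dr <- stats::density(wr, from = lo, to = hi, n = n_grid)
  dd <- df$y - dr$y
  scale <- max(df$y, dr$y)
  if (max(abs(dd)) < 1e-3 * scale) {
    # identical densities: report the common mode
    return(df$x[which.max(df$y + dr$y)])
  }
  sgn <- sign(dd)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  if (!length(idx)) {
    # supports overlap but densities do not cross inside the window;
    # report the point of closest approach
    return(df$x[which.min(abs(dd))])
  }
  xc <- df$x[idx] - dd[idx] * diff(df$x[1:2]) / (dd[idx + 1L] - dd[idx])
  target <- (mean(wf) + mean(wr)) / 2
  xc[which.min(abs(xc - target))]
}

#' Bootstrap standard error of an arbitrary work-based estimator
#'
#' Resamples each work set independently with replacement (same size),
#' re-evaluates the estimator on each resample and returns the standard
#' deviation of the resampled estimates.  Fully reproducible given the
#' seed in `settings`.  If the estimator fails on more than 10% of the
#' resamples the bootstrap is declared unstable and an error is raised;
#' occasional failures below that fraction are dropped.
#'
#' @param estimator A function taking a list of [work_set()] objects and
#'   returning a numeric scalar.
#' @param worksets List of [work_set()] objects to resample.
#' @param settings A [bootstrap_settings()].
#' @return The bootstrap standard error (kcal/mol).
#' @export
bootstrap_error <- function(estimator, worksets, settings = bootstrap_settings()) {
  stopifnot(is.function(estimator), length(worksets) >= 1)
  vals <- withr::with_seed(settings$seed, {
    vapply(seq_len(settings$n_resamples), function(r) {
      res <- lapply(worksets, function(ws) {
        ws$values <- ws$values[sample.int(length(ws$values),
                                          replace = TRUE)]
        ws
      })
      tryCatch(as.numeric(estimator(res)), error = function(e) NA_real_)
    }, numeric(1))
  })
  nfail <- sum(is.na(vals))
  if (nfail > 0.1 * settings$n_resamples)
    stop("unstable bootstrap: estimator failed on ", nfail, " of ",
         settings$n_resamples, " resamples")
  stats::sd(vals[!is.na(vals)])
}

# method requirements: which work keys each edge estimator needs
.all_work_keys <- c("bound_forward", "bound_reverse",
                    "unbound_forward", "unbound_reverse")
.method_needs <- list(
  "BAR"    = .all_work_keys,
  "BAR*"   = .all_work_keys,
  "J(FF)"  = c("bound_forward", "unbound_forward"),
  "J(RR)"  = c("bound_reverse", "unbound_reverse"),
  "J*(FR)" = c("bound_forward", "unbound_reverse"),
  "J*(RF)" = c("bound_reverse", "unbound_forward"),
  "G(FF)"  = c("bound_forward", "unbound_forward"),
  "G(RR)"  = c("bound_reverse", "unbound_reverse"))

#' Supported edge-estimator method tags
#' @return Character vector of the eight method tags.
#' @export
estimator_methods <- function() names(.method_needs)

# point estimate of the edge RBFE (before fs correction) from a named list
# of work sets; conv_seed feeds the convolution subsampler.
.edge_point <- function(w, method, bar_set, max_products = 1e6,
                        conv_seed = 1L) {
  switch(method,
    "BAR" = bar(w$bound_forward, w$bound_reverse, bar_set)$value -
            bar(w$unbound_forward, w$unbound_reverse, bar_set)$value,
    "BAR*" = {
      f <- convolve_work(w$bound_forward, w$unbound_reverse,
                         max_products = max_products, seed = conv_seed)
      r <- convolve_work(w$bound_reverse, w$unbound_forward,
                         max_products = max_products, seed = conv_seed + 1L)
      bar(f, r, bar_set)$value
    },
    "J(FF)" = jarzynski(w$bound_forward)$value -
              jarzynski(w$unbound_forward)$value,
    "J(RR)" = -(jarzynski(w$bound_reverse)$value -
                jarzynski(w$unbound_reverse)$value),
    "J*(FR)" = jarzynski(convolve_work(w$bound_forward, w$unbound_reverse,
                                       max_products = max_products,
                                       seed = conv_seed))$value,
    "J*(RF)" = -jarzynski(convolve_work(w$bound_reverse, w$unbound_forward,
                                        max_products = max_products,
                                        seed = conv_seed))$value,
    "G(FF)" = gaussian_estimate(w$bound_forward)$value -
              gaussian_estimate(w$unbound_forward)$value,
    "G(RR)" = -(gaussian_estimate(w$bound_reverse)$value -
                gaussian_estimate(w$unbound_reverse)$value),
    stop("unknown method tag: ", method))
}

#' Edge-level RBFE estimate
#'
#' Combines the bound- and unbound-leg work samples of an edge into the
#' relative binding free energy of the `source -> target` transmutation,
#' using one of the eight supported estimators, and applies the edge's
#' finite-size correction.  The bidirectional estimators are `BAR` (two-arm
#' Bennett, bound minus unbound) and `BAR*` (Bennett on the convolved
#' forward = bound-forward (+) unbound-reverse and reverse = bound-reverse
#' (+) unbound-forward work sets).  `J(FF)`, `J(RR)` are per-arm Jarzynski
#' differences; `J*(FR)`, `J*(RF)` are Jarzynski estimates on the convolved
#' sets; `G(FF)`, `G(RR)` are per-arm Gaussian (second-cumulant)
#' differences.
#'
#' The bootstrap standard error resamples the original per-leg work sets
#' (never the convolved points, which are not independent) and re-convolves
#' inside each resample.
#'
#' @param edge An [edge_data()] carrying the work sets the method needs.
#' @param method One of [estimator_methods()].
#' @param bar_set A [bar_settings()].
#' @param boot_set A [bootstrap_settings()], or `NULL` to skip the
#'   bootstrap (stderr `NA`).
#' @param max_products Convolution cap, see [convolve_work()].
#' @return An [fe_estimate]; `diagnostics` include the normality screens of
#'   the work sets used (for Gaussian methods).
#' @export
edge_estimate <- function(edge, method, bar_set = bar_settings(),
                          boot_set = bootstrap_settings(),
                          max_products = 1e6) {
  stopifnot(inherits(edge, "edge_data"))
  method <- match.arg(method, estimator_methods())
  need <- .method_needs[[method]]
  missing <- setdiff(need, names(edge$works))
  if (length(missing))
    stop("edge_estimate: edge ", edge$source, " -> ", edge$target,
         " lacks work set(s) required by ", method, ": ",
         paste(missing, collapse = ", "))
  w <- edge$works[need]
  value <- .edge_point(w, method, bar_set, max_products) + edge$fs_correction
  stderr <- NA_real_
  if (!is.null(boot_set)) {
    est_fun <- local({
      keys <- need
      function(resampled) {
        names(resampled) <- keys
        .edge_point(resampled, method, bar_set, max_products,
                    conv_seed = sample.int(.Machine$integer.max - 2L, 1L))
      }
    })
    stderr <- bootstrap_error(est_fun, w, boot_set)
  }
  diag <- list()
  if (method %in% c("G(FF)", "G(RR)"))
    diag$normality <- lapply(w, function(ws) normality_screen(ws$values))
  nf <- if (!is.null(w$bound_forward)) length(w$bound_forward$values)
        else length(w$bound_reverse$values)
  nr <- if (!is.null(w$unbound_forward)) length(w$unbound_forward$values)
        else length(w$unbound_reverse$values)
  fe_estimate(value, stderr = stderr, method = method,
              n_forward = nf, n_reverse = nr, diagnostics = diag)
}
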