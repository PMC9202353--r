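kT298 <- 1.98720425864083e-3 * 298.15

test_that("jarzynski reduces to the work value on dissipationless samples", {
  expect_equal(jarzynski(work_set(c(2.5, 2.5, 2.5), "forward", "bound"))$value,
               2.5)
  expect_equal(jarzynski(work_set(c(0, 0), "forward", "bound"))$value, 0)
  # numerically stable far into the exponential tails
  big <- work_set(c(5000, 6000), "forward", "bound")
  expect_true(is.finite(jarzynski(big)$value))
})

test_that("jarzynski converges to the Gaussian cumulant limit", {
  # population limit mu - beta sigma^2 / 2; at sigma = 1 kcal/mol the
  # estimator's sampling spread at n = 2e5 is well inside 0.05
  s <- crooks_gaussian_sampler(delta_g = 5 - 1 / (2 * kT298), sigma = 1,
                               n_forward = 200000, n_reverse = 1, seed = 101)
  expect_equal(jarzynski(s$forward)$value, 5 - 1 / (2 * kT298),
               tolerance = 0.05 / abs(5 - 1 / (2 * kT298)))
  # at sigma = 2 the spread is larger: check against a bootstrap interval
  s2 <- crooks_gaussian_sampler(delta_g = 1.6245, sigma = 2,
                                n_forward = 200000, n_reverse = 1, seed = 7)
  se <- bootstrap_error(function(w) jarzynski(w[[1]])$value,
                        list(s2$forward),
                        bootstrap_settings(n_resamples = 50, seed = 1))
  expect_lt(abs(jarzynski(s2$forward)$value - 1.6245), 4 * se)
})

test_that("gaussian estimate matches hand arithmetic and flags nothing odd", {
  expect_equal(gaussian_estimate(work_set(c(3, 3), "forward", "bound"))$value,
               3)
  est <- gaussian_estimate(work_set(c(4, 6), "forward", "bound"))
  expect_equal(est$value, 5 - 1 / (2 * kT298), tolerance = 1e-12)
  expect_error(gaussian_estimate(work_set(1, "forward", "bound")),
               "variance undefined")
  g <- gaussian_estimate(random_work_set(5000, seed = 2))
  expect_false(g$diagnostics$nonnormal)
})

test_that("normality screen flags a markedly bimodal work distribution", {
  bim <- bimodal_sampler(c(0.5, 0.5), c(-4, 4), 0.5, 2000, 10, seed = 8)
  expect_true(normality_screen(bim$forward$values)$nonnormal)
  expect_false(normality_screen(rnorm(2000))$nonnormal)
})

test_that("gaussian and jarzynski agree increasingly well on Gaussian work", {
  med_gap <- vapply(c(1e2, 1e3, 1e4, 1e5), function(n) {
    gaps <- vapply(1:20, function(s) {
      ws <- crooks_gaussian_sampler(1.2, 1.5, n, 1, seed = 1000 + s)$forward
      abs(gaussian_estimate(ws)$value - jarzynski(ws)$value)
    }, numeric(1))
    median(gaps)
  }, numeric(1))
  expect_true(all(diff(med_gap) < 0))
  expect_lt(med_gap[4], 0.05)
})

test_that("BAR solves the symmetric singleton and is antisymmetric", {
  f <- work_set(1.75, "forward", "bound")
  r <- work_set(-1.75, "reverse", "bound")
  expect_equal(bar(f, r)$value, 1.75, tolerance = 1e-7)

  for (s in 1:10) {
    fw <- random_work_set(50, seed = 300 + s, direction = "forward")
    rv <- random_work_set(30, seed = 400 + s, direction = "reverse")
    ab <- bar(fw, rv)$value
    ba <- bar(work_set(rv$values, "forward", "bound"),
              work_set(fw$values, "reverse", "bound"))$value
    expect_equal(ab, -ba, tolerance = 1e-6)
  }
})

test_that("BAR recovers the free energy of a Crooks Gaussian pair", {
  truth <- 1.6244
  s <- crooks_gaussian_sampler(truth, 2, 2000, 2000, seed = 3)
  est <- bar(s$forward, s$reverse)
  se <- bootstrap_error(function(w) bar(w[[1]], w[[2]])$value,
                        list(s$forward, s$reverse),
                        bootstrap_settings(n_resamples = 200, seed = 5))
  expect_lt(abs(est$value - truth), 3 * se)
  # the Bennett residual vanishes at the solution
  expect_lt(abs(est$diagnostics$residual), 1e-6)
  # per-direction dissipations are both positive here and sum consistently
  expect_gt(est$diagnostics$dissipation_forward, 0)
  expect_gt(est$diagnostics$dissipation_reverse, 0)
})

test_that("BAR reports a bracket failure on catastrophically disjoint work", {
  f <- work_set(rep(1000, 5), "forward", "bound")
  r <- work_set(rep(900, 5), "reverse", "bound")
  expect_error(bar(f, r), "bracket failure")
})

test_that("BAR stays unbiased with strongly unequal sample sizes", {
  # the log(n_f/n_r) offset keeps the estimator centred when one
  # direction has ten times the trajectories of the other
  s <- crooks_gaussian_sampler(0.9, 1.2, 2000, 200, seed = 12)
  est <- bar(s$forward, s$reverse)
  se <- bootstrap_error(function(w) bar(w[[1]], w[[2]])$value,
                        list(s$forward, s$reverse),
                        bootstrap_settings(n_resamples = 200, seed = 13))
  expect_lt(abs(est$value - 0.9), 3 * se)
})

test_that("work convolution enumerates pair sums and is moment-additive", {
  a <- work_set(c(1, 2), "forward", "bound")
  b <- work_set(c(10, 20), "reverse", "unbound")
  cv <- convolve_work(a, b)
  expect_setequal(cv$values, c(11, 21, 12, 22))
  expect_equal(cv$leg, "combined")
  expect_equal(cv$direction, "forward")

  popvar <- function(x) mean((x - mean(x))^2)
  for (s in 1:5) {
    x <- random_work_set(37, seed = 500 + s)
    y <- random_work_set(23, seed = 600 + s)
    cz <- convolve_work(x, y)
    # brute-force oracle over all pairs
    all_sums <- as.numeric(sapply(x$values, function(v) v + y$values))
    expect_equal(mean(cz$values), mean(x$values) + mean(y$values))
    expect_equal(sort(cz$values), sort(all_sums))
    expect_equal(popvar(cz$values), popvar(x$values) + popvar(y$values),
                 tolerance = 1e-10)
  }
})

test_that("convolution caps the product set with seeded subsampling", {
  x <- random_work_set(2000, seed = 21)
  y <- random_work_set(2000, seed = 22)
  c1 <- convolve_work(x, y, max_products = 5000, seed = 99)
  c2 <- convolve_work(x, y, max_products = 5000, seed = 99)
  c3 <- convolve_work(x, y, max_products = 5000, seed = 100)
  expect_length(c1$values, 5000)
  expect_identical(c1$values, c2$values)
  expect_false(identical(c1$values, c3$values))
})

test_that("all eight estimators agree on a zero-dissipation edge", {
  wb <- 3.2; wu <- 1.1; fs <- -2.0
  mk <- function(v, d, l) work_set(rep(v, 2), d, l)
  e <- edge_data("A", "B",
                 works = list(bound_forward = mk(wb, "forward", "bound"),
                              bound_reverse = mk(-wb, "reverse", "bound"),
                              unbound_forward = mk(wu, "forward", "unbound"),
                              unbound_reverse = mk(-wu, "reverse", "unbound")),
                 fs_correction = fs)
  for (m in estimator_methods()) {
    est <- edge_estimate(e, m, boot_set = NULL)
    expect_equal(est$value, wb - wu + fs, tolerance = 1e-6, label = m)
  }
})

test_that("per-arm Gaussian difference equals the convolution-based form", {
  # the Crooks-reversed image of the unbound forward sample is the proper
  # convolution partner; with ML variances the identity is exact
  e <- synthetic_edge(2.5, 0.7, 1.5, 1.0, seed = 31)
  b <- 1 / kT298
  per_arm <- edge_estimate(e, "G(FF)", boot_set = NULL)$value
  uf <- e$works$unbound_forward
  s2u <- mean((uf$values - mean(uf$values))^2)
  rev_img <- work_set(-(uf$values - b * s2u), "forward", "unbound")
  conv <- convolve_work(e$works$bound_forward, rev_img)
  expect_equal(gaussian_estimate(conv)$value, per_arm, tolerance = 1e-9)
})

test_that("edge_estimate names the missing work set", {
  e <- synthetic_edge(1, 0, 1, 1, seed = 40)
  e$works$unbound_reverse <- NULL
  expect_error(edge_estimate(e, "BAR"), "unbound_reverse")
  expect_error(edge_estimate(e, "J*(FR)"), "unbound_reverse")
  expect_silent(edge_estimate(e, "J(FF)", boot_set = NULL))
})

test_that("finite-size correction is additive and invertible", {
  expect_equal(apply_fs_correction(1.23, 0), 1.23)
  x <- apply_fs_correction(4.2, -2.3)
  expect_equal(apply_fs_correction(x, 2.3), 4.2)
  # corrections shipped with the reference network survive the round trip
  meta <- attr(read_estimate_table(wp6_table_path()), "edge_meta")
  expect_true(all(meta$fs %in% c(0, 2.0, -2.0, -2.3, -4.3)))
})

test_that("dissipation matches its definition and the Gaussian identity", {
  expect_equal(dissipation(work_set(c(2, 2), "forward", "bound"), 2), 0)
  s <- crooks_gaussian_sampler(1.6245, 2, 100000, 1, seed = 55)
  d <- dissipation(s$forward, 1.6245)
  expect_equal(d, 4 / (2 * kT298), tolerance = 0.02)
  # second law, in expectation, on independent large samples
  for (s2 in 1:5) {
    dg <- runif(1, -3, 3)
    smp <- crooks_gaussian_sampler(dg, runif(1, 0.5, 2.5), 20000, 1,
                                   seed = 700 + s2)
    expect_gt(dissipation(smp$forward, dg), 0)
  }
})

test_that("crossing point locates the Crooks intersection", {
  # reverse works drawn as exact negatives: densities coincide, the
  # crossing is reported at the common mode
  f <- work_set(withr::with_seed(61, rnorm(5000, 2, 0.5)),
                "forward", "bound")
  r <- work_set(-f$values, "reverse", "bound")
  cp <- crossing_point(f, r)
  expect_lt(abs(cp - 2), 0.15)

  s <- crooks_gaussian_sampler(1.6244, 2, 20000, 20000, seed = 62)
  expect_lt(abs(crossing_point(s$forward, s$reverse) - 1.6244), 0.2)
  # consistency with BAR on well-overlapped data
  est <- bar(s$forward, s$reverse)
  expect_lt(abs(crossing_point(s$forward, s$reverse) - est$value), 0.25)

  disjoint_f <- work_set(rnorm(100, 100, 0.1), "forward", "bound")
  disjoint_r <- work_set(rnorm(100, 100, 0.1), "reverse", "bound")
  expect_error(crossing_point(disjoint_f, disjoint_r), "no overlap")
})

test_that("bootstrap errors are reproducible, sane and second-order exact", {
  const <- work_set(rep(2, 50), "forward", "bound")
  expect_equal(bootstrap_error(function(w) mean(w[[1]]$values), list(const),
                               bootstrap_settings(50, seed = 1)), 0)

  ws <- random_work_set(500, seed = 71)
  f <- function(w) mean(w[[1]]$values)
  s1 <- bootstrap_error(f, list(ws), bootstrap_settings(200, seed = 9))
  s2 <- bootstrap_error(f, list(ws), bootstrap_settings(200, seed = 9))
  expect_identical(s1, s2)

  # ~1/sqrt(n) scaling of the mean's bootstrap error, 20 replicates
  ratios <- vapply(1:20, function(s) {
    full <- random_work_set(800, seed = 800 + s)
    half <- work_set(full$values[1:400], "forward", "bound")
    bootstrap_error(f, list(half), bootstrap_settings(200, seed = s)) /
      bootstrap_error(f, list(full), bootstrap_settings(200, seed = s))
  }, numeric(1))
  expect_gt(mean(ratios >= 1.25 & ratios <= 1.60), 0.7)

  # an estimator that fails on most resamples is reported as unstable
  flaky <- function(w) if (runif(1) < 0.5) stop("boom") else 1
  expect_error(bootstrap_error(flaky, list(ws),
                               bootstrap_settings(100, seed = 2)),
               "unstable bootstrap")
})
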