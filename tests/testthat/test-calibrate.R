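test_that("KS comparison: identity, exact small-sample p, and input checks", {
  k0 <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k0$statistic, 0)
  expect_equal(k0$p_value, 1)
  # disjoint 3-vs-3: D = 1 and exact p = 2 / choose(6, 3) = 0.1
  k <- ks_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(k$statistic, 1)
  expect_equal(k$p_value, 0.1)
  expect_true(k$exact)
  expect_error(ks_compare(1, c(1, 2)), ">= 2 values")
  # published panel groups separate significantly
  panel <- liver_reference_panel()
  p <- ks_compare(panel$ba_mean[panel$group == "basolateral"],
                  panel$ba_mean[panel$group == "apical" &
                                  panel$panel_only == "no"])
  expect_lt(p$p_value, 0.05)
})

test_that("group fitting on both scales, with normality check", {
  expect_error(fit_group(c(1, 1, 1)), "zero variance")
  expect_error(fit_group(c(1, 2)), ">= 3 values")
  expect_error(fit_group(c(1, 2, -3, 4)), "non-positive")
  f <- fit_group(c(exp(1), exp(1), exp(3), exp(3)), scale = "log")
  expect_equal(f$mu, 2)
  expect_equal(f$sigma, sqrt(4 / 3), tolerance = 1e-12)
  fr <- fit_group(c(1.5, 2, 2.5), scale = "raw")
  expect_equal(fr$mu, 2)
  expect_equal(fr$sigma, 0.5)
  # logged ratios of the published basolateral panel pass normality
  b <- liver_reference_panel()
  f23 <- fit_group(b$ba_mean[b$group == "basolateral"], "basolateral")
  expect_equal(f23$n, 23L)
  expect_gt(f23$shapiro_p, 0.05)
})

test_that("log-normal moment matching inverts raw moments", {
  expect_equal(unname(moment_match_lognormal(1, 0)), c(0, 0))
  mm <- moment_match_lognormal(1.04, 0.0227)
  expect_equal(unname(mm["mu_log"]), 0.0288356, tolerance = 1e-6)
  expect_equal(unname(mm["sigma_log"]), 0.1441188, tolerance = 1e-6)
  expect_error(moment_match_lognormal(1, -0.1), ">= 0")
  set.seed(41)
  for (i in 1:25) {
    m <- runif(1, 0.2, 5); v <- runif(1, 0, 2)
    p <- moment_match_lognormal(m, v)
    # regenerate the raw moments of a log-normal with those parameters
    m_back <- exp(p["mu_log"] + p["sigma_log"]^2 / 2)
    v_back <- m_back^2 * (exp(p["sigma_log"]^2) - 1)
    expect_equal(unname(m_back), m, tolerance = 1e-12)
    expect_equal(unname(v_back), v, tolerance = 1e-12)
  }
})

test_that("density intersection: midpoint, quadratic root, symmetry", {
  # exact-moment samples let us build fits with prescribed (mu, sigma)
  logfit <- function(mu, sigma, n = 24, label = "g") {
    fit_group(exp(synthesize_sample(mu, sigma, n)), label, scale = "log")
  }
  f1 <- logfit(0, 0.5); f2 <- logfit(1, 0.5)
  expect_equal(density_intersection(f1, f2), exp(0.5), tolerance = 1e-12)
  # unequal variances: frozen 1e-6 grid-search value for N(0,1) vs N(4,4)
  f3 <- logfit(0, 1); f4 <- logfit(4, 2)
  expect_equal(density_intersection(f3, f4), exp(1.659910), tolerance = 1e-5)
  expect_equal(density_intersection(f4, f3), density_intersection(f3, f4))
  expect_error(density_intersection(f1, f1), "coincide|distinct")
  rawfit <- function(mu, sigma, n = 24) {
    fit_group(synthesize_sample(mu, sigma, n), scale = "raw")
  }
  expect_error(density_intersection(rawfit(1, 0.2), logfit(1, 0.2)),
               "same scale")
})

test_that("density intersection agrees with a grid-search oracle", {
  set.seed(42)
  for (i in 1:100) {
    mu1 <- runif(1, -2, 0); mu2 <- runif(1, 0.5, 3)
    s1 <- runif(1, 0.1, 1); s2 <- runif(1, 0.1, 1)
    f1 <- fit_group(exp(synthesize_sample(mu1, s1, 12)), scale = "log")
    f2 <- fit_group(exp(synthesize_sample(mu2, s2, 12)), scale = "log")
    got <- tryCatch(log(density_intersection(f1, f2)), error = function(e) NA)
    if (is.na(got)) next  # pathological sigma ratio without interior root
    expect_lt(abs(got - grid_intersection(mu1, s1, mu2, s2)), 1e-5)
  }
})

test_that("thresholds rescale with the ratios (equivariance)", {
  vals <- list(apical = synthesize_sample(0.5, 0.08, 11),
               both = synthesize_sample(1.02, 0.15, 7),
               baso = synthesize_sample(2.4, 0.5, 23))
  for (scale in c("raw", "log")) {
    f <- lapply(vals, fit_group, scale = scale)
    lo <- density_intersection(f$apical, f$both)
    hi <- density_intersection(f$both, f$baso)
    fc <- lapply(vals, function(v) fit_group(3 * v, scale = scale))
    expect_equal(density_intersection(fc$apical, fc$both), 3 * lo,
                 tolerance = 1e-9)
    expect_equal(density_intersection(fc$both, fc$baso), 3 * hi,
                 tolerance = 1e-9)
  }
})

test_that("pooled t-test matches direct evaluation and its conventions", {
  # frozen from the direct pooled-variance formula
  tt <- protein_vs_group_ttest(c(2.0, 2.1, 1.9, 2.0),
                               c(1.0, 0.9, 1.1, 1.0, 1.05, 0.95, 1.1))
  expect_equal(tt$t, 20.3839509062, tolerance = 1e-9)
  expect_equal(tt$df, 9)
  expect_lt(tt$p_value, 1e-7)
  # constant protein at the group mean
  g <- synthesize_sample(1.04, 0.2, 7)
  t0 <- protein_vs_group_ttest(rep(1.04, 4), g)
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)
  # sign anti-symmetry
  set.seed(43)
  for (i in 1:20) {
    x <- rnorm(4, 2, 0.3); y <- rnorm(7, 1, 0.2)
    a <- protein_vs_group_ttest(x, y)
    b <- protein_vs_group_ttest(y, x)
    expect_equal(a$t, -b$t, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    o <- pooled_t_oracle(x, y)
    expect_equal(a$t, o$t, tolerance = 1e-12)
    expect_equal(a$p_value, o$p, tolerance = 1e-12)
  }
  # zero pooled variance conventions
  expect_equal(protein_vs_group_ttest(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(protein_vs_group_ttest(c(2, 2), c(1, 1))$p_value, 0)
})

test_that("Bonferroni adjustment caps, scales and is monotone", {
  expect_equal(bonferroni(0.01, 279), 1)
  expect_equal(bonferroni(1e-5, 100), 1e-3)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni(p, 7)) >= 0))
})

test_that("calibration separates a noise-free synthetic panel perfectly", {
  p <- noise_free_params(n_apical = 12, n_both = 8, n_basolateral = 24,
                         ref_sizes = c(apical = 11, both = 7,
                                       basolateral = 23),
                         seed = 55)
  sim <- generate_dataset(p)
  ratios <- compute_ba_ratios(quantify_transitions(sim$transitions))
  cal <- calibrate(ratios, sim$panel)
  expect_s3_class(cal, "ba_calibration")
  expect_lt(cal$thresholds$lower, cal$thresholds$upper)
  members <- dplyr::inner_join(sim$panel, ratios, by = "accession")
  ap <- members$mean[members$group == "apical"]
  bo <- members$mean[members$group == "both"]
  ba <- members$mean[members$group == "basolateral"]
  expect_true(all(ap < cal$thresholds$lower))
  expect_true(all(bo > cal$thresholds$lower & bo < cal$thresholds$upper))
  expect_true(all(ba > cal$thresholds$upper))
  expect_true(all(cal$ks$p_value < 0.05))
  expect_equal(nrow(cal$model_tests), length(ap) + length(ba))
})

test_that("degenerate and incomplete panels raise errors with context", {
  vals <- synthesize_sample(1, 0.1, 10)
  ratios <- tibble::tibble(accession = sprintf("P%d", 1:20),
                           mean = rep(vals, 2), sem = 0.01, n = 4L)
  panel_same <- tibble::tibble(
    accession = sprintf("P%d", 1:20),
    group = rep(c("apical", "both"), each = 10))
  expect_error(suppressWarnings(calibrate(ratios, panel_same)),
               "basolateral")
  panel_identical <- tibble::tibble(
    accession = c(sprintf("P%d", 1:10), sprintf("P%d", 11:20),
                  sprintf("P%d", 1:10)),
    group = rep(c("apical", "both", "basolateral"), each = 10))
  # apical and basolateral groups share identical values -> no border
  expect_error(suppressWarnings(calibrate(ratios, panel_identical)),
               "coincide|intersection|distinct")
})

test_that("calibration with published moments reproduces the printed border", {
  panel <- liver_reference_panel()
  ratios <- tibble::tibble(accession = panel$accession, mean = panel$ba_mean,
                           sem = panel$ba_sem, n = 4L)
  cal <- calibrate(ratios[!is.na(ratios$mean), ], panel,
                   both_moments = both_group_moments())
  expect_equal(cal$thresholds$upper, 1.42, tolerance = 0.05 / 1.42)
  expect_equal(cal$fits$basolateral$n, 23L)
})
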