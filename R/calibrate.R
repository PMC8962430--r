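#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test. The exact small-sample p-value
#' (enumeration over label assignments) is used whenever `n * m <= 1e4`
#' and the pooled sample is tie-free; with ties or larger samples the
#' asymptotic p-value is reported and flagged, the convention also used by
#' `stats::ks.test`.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with `statistic` (D), `p_value`, and `exact` (logical).
#' @export
ks_compare <- function(group_a, group_b) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs >= 2 values")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) * length(group_b) <= 1e4
  kt <- suppressWarnings(ks.test(group_a, group_b, exact = exact))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       exact = exact)
}

#' Fit a reference group's density model
#'
#' Fits the normal density used for the border-line calibration to one
#' reference group's per-protein mean B/A ratios. With `scale = "raw"`
#' (the default) the normal is fitted to the ratios themselves (group mean
#' and sample SD on the ratio scale); with `scale = "log"` it is fitted to
#' their natural logs, i.e. a log-normal model of the ratios. Both scales
#' are reported along with a Shapiro-Wilk normality check of the logged
#' ratios (the log-normality justification for modeling positive ratios).
#'
#' @param values positive per-protein mean B/A ratios, at least 3.
#' @param label group label, e.g. `"apical"`, `"both"`, `"basolateral"`.
#' @param scale `"raw"` or `"log"`: the scale on which the normal density
#'   is fitted and intersected.
#' @return object of class `group_fit`: label, n, `mu`/`sigma` (fit-scale
#'   parameters), `scale`, `mu_log`/`sigma_log`, `raw_mean`/`raw_variance`,
#'   `shapiro_p`, and `values`.
#' @export
fit_group <- function(values, label = "group", scale = c("raw", "log")) {
  scale <- match.arg(scale)
  assert_that(is.numeric(values) && length(values) >= 3,
              "need >= 3 values for density fitting")
  if (any(!is.finite(values) | values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)[1]
    abort(sprintf("non-positive B/A ratio in group '%s' (member %s)", label,
                  names(values)[bad] %||% as.character(bad)))
  }
  if (sd(values) == 0) {
    abort(sprintf("zero variance in group '%s': density fit is degenerate",
                  label))
  }
  lv <- log(values)
  fit <- list(
    label = label, n = length(values), scale = scale,
    mu = if (scale == "raw") mean(values) else mean(lv),
    sigma = if (scale == "raw") sd(values) else sd(lv),
    mu_log = mean(lv), sigma_log = sd(lv),
    raw_mean = mean(values), raw_variance = var(values),
    shapiro_p = shapiro.test(lv)$p.value,
    values = values
  )
  structure(fit, class = "group_fit")
}

#' Fit a reference group from published raw moments
#'
#' When a group's member values are unavailable but its raw-scale mean and
#' variance are published, the density model is reconstructed from those
#' moments: directly for `scale = "raw"`, via log-normal moment matching
#' ([moment_match_lognormal()]) for `scale = "log"`. No normality check is
#' possible (`shapiro_p = NA`).
#'
#' @param raw_mean,raw_variance published mean and variance of the ratios.
#' @param n group size (used for reporting and member reconstruction).
#' @inheritParams fit_group
#' @return a `group_fit` object without member `values`.
#' @export
fit_group_moments <- function(raw_mean, raw_variance, n, label = "group",
                              scale = c("raw", "log")) {
  scale <- match.arg(scale)
  assert_that(raw_mean > 0, "`raw_mean` must be > 0")
  assert_that(raw_variance > 0, "`raw_variance` must be > 0 for a density fit")
  mm <- moment_match_lognormal(raw_mean, raw_variance)
  structure(list(
    label = label, n = n, scale = scale,
    mu = if (scale == "raw") raw_mean else mm[["mu_log"]],
    sigma = if (scale == "raw") sqrt(raw_variance) else mm[["sigma_log"]],
    mu_log = mm[["mu_log"]], sigma_log = mm[["sigma_log"]],
    raw_mean = raw_mean, raw_variance = raw_variance,
    shapiro_p = NA_real_, values = NULL
  ), class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit> %s (n = %d, %s scale): mu = %.4g, sigma = %.4g\n",
              x$label, x$n, x$scale, x$mu, x$sigma))
  invisible(x)
}

#' Log-normal parameters from raw mean and variance
#'
#' Standard moment inversion: a log-normal with parameters
#' `sigma_log^2 = log(1 + v / m^2)` and `mu_log = log(m) - sigma_log^2 / 2`
#' has raw mean `m` and raw variance `v`.
#'
#' @param m raw mean, `> 0`.
#' @param v raw variance, `>= 0`.
#' @return named numeric vector `c(mu_log, sigma_log)`.
#' @examples
#' moment_match_lognormal(1.04, 0.0227)
#' @export
moment_match_lognormal <- function(m, v) {
  assert_that(m > 0, "`m` must be > 0")
  if (v < 0) abort("`v` must be >= 0")
  s2 <- log(1 + v / m^2)
  c(mu_log = log(m) - s2 / 2, sigma_log = sqrt(s2))
}

# unique intersection of two normal densities strictly between their means;
# quadratic in x (linear when the sigmas are equal)
normal_intersection <- function(mu1, sigma1, mu2, sigma2) {
  assert_that(sigma1 > 0 && sigma2 > 0, "sigmas must be > 0")
  if (mu1 == mu2 && sigma1 == sigma2) abort("densities coincide")
  assert_that(mu1 != mu2, "means must be distinct")
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  if (sigma1 == sigma2) return((mu1 + mu2) / 2)
  a <- 1 / sigma1^2 - 1 / sigma2^2
  b <- -2 * (mu1 / sigma1^2 - mu2 / sigma2^2)
  cc <- mu1^2 / sigma1^2 - mu2^2 / sigma2^2 - 2 * log(sigma2 / sigma1)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) abort("normal densities do not intersect between the means")
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  inside <- roots[roots > lo & roots < hi]
  if (length(inside) != 1) {
    abort(sprintf(
      "no unique density intersection between the means (roots: %s)",
      paste(signif(roots, 6), collapse = ", ")))
  }
  inside
}

#' Decision border between two reference groups
#'
#' Solves for the point where the two fitted group densities are equal,
#' restricted to the unique root strictly between the two group means, and
#' returns it on the B/A-ratio scale. For `"log"`-scale fits the normal
#' densities are intersected on the log axis and the root exponentiated
#' back (the 1/x Jacobian of the log-normal densities cancels, so this is
#' also the ratio-scale log-normal intersection). The operation is
#' symmetric in its arguments. When the sigmas differ the density equation
#' is quadratic; both roots exist but only the one between the means is a
#' decision border, and an error reporting both roots is raised if neither
#' (or both) lie there.
#'
#' @param fit1,fit2 `group_fit` objects on the same scale.
#' @return the border on the ratio scale (a positive scalar).
#' @examples
#' both <- fit_group_moments(1.04, 0.0227, n = 7, label = "both")
#' baso <- fit_group(c(1.69, 1.71, 1.86, 2.2, 2.5, 3.02, 3.72), "basolateral")
#' density_intersection(both, baso)
#' @export
density_intersection <- function(fit1, fit2) {
  assert_that(inherits(fit1, "group_fit") && inherits(fit2, "group_fit"),
              "need two group_fit objects")
  assert_that(identical(fit1$scale, fit2$scale),
              "fits must be on the same scale")
  root <- normal_intersection(fit1$mu, fit1$sigma, fit2$mu, fit2$sigma)
  if (fit1$scale == "log") exp(root) else root
}

#' Pooled-variance Student's t-test of one protein against a reference group
#'
#' Compares a protein's per-animal B/A ratios with the member mean ratios
#' of a reference group using the classical two-sample pooled-variance
#' Student's t-test (`df = n1 + n2 - 2`), on the raw ratio scale. Welch's
#' unequal-variance form is available behind `var_equal = FALSE`.
#' Degenerate conventions: both samples constant and equal means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means gives
#' `t = +/-Inf, p = 0`.
#'
#' @param protein_ratios numeric vector of the protein's per-animal ratios
#'   (n >= 2).
#' @param group_values numeric vector of the group's member mean ratios
#'   (n >= 2).
#' @param var_equal pooled-variance Student (default) or Welch.
#' @return list with `t`, `df`, `p_value`.
#' @export
protein_vs_group_ttest <- function(protein_ratios, group_values,
                                   var_equal = TRUE) {
  x <- protein_ratios; y <- group_values
  assert_that(length(x) >= 2 && length(y) >= 2,
              "both samples need >= 2 values")
  n1 <- length(x); n2 <- length(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(var(x) / n1 + var(y) / n2)
    df <- (var(x) / n1 + var(y) / n2)^2 /
      ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  }
  d <- mean(x) - mean(y)
  if (se == 0) {
    if (d == 0) return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(d) * Inf, df = df, p_value = 0))
  }
  t <- d / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)`, monotone in both arguments.
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m number of comparisons, `>= 1`.
#' @return adjusted p-value(s), capped at 1.
#' @export
bonferroni <- function(p, m) {
  assert_that(all(p >= 0 & p <= 1), "`p` must be in [0, 1]")
  assert_that(m >= 1, "`m` must be >= 1")
  pmin(1, m * p)
}

#' Calibrate the apical/both/basolateral decision borders
#'
#' Runs the full reference-panel validation: pairwise KS tests between the
#' three groups' mean ratios, per-group density fits with Shapiro-Wilk
#' normality checks of the logged ratios, the two density-intersection
#' borders (lower = apical/both, upper = both/basolateral), and a
#' per-model-protein pooled t-test against the both group with Bonferroni
#' correction over the panel. A Shapiro-Wilk p below 0.05 warns but does
#' not fail. When the both group's member values are unavailable, supply
#' its published raw moments via `both_moments`; its members are then
#' reconstructed at exactly those moments ([synthesize_sample()]) for the
#' KS and t comparisons.
#'
#' @param ratios B/A ratio tibble from [compute_ba_ratios()], or any tibble
#'   with `accession`, `mean` and optionally `ratios`/`sem`/`n` columns.
#' @param panel reference panel tibble (`accession`, `group` with values
#'   apical/both/basolateral).
#' @param scale fit scale, `"raw"` (default) or `"log"`; see [fit_group()].
#' @param both_moments optional `list(mean =, variance =, n =)` replacing
#'   the both group's member values.
#' @param var_equal passed to [protein_vs_group_ttest()].
#' @return object of class `ba_calibration`: `fits` (named list of
#'   `group_fit`), `thresholds` ([ba_thresholds()]), `ks` tibble,
#'   `model_tests` tibble, `scale`.
#' @export
calibrate <- function(ratios, panel, scale = c("raw", "log"),
                      both_moments = NULL, var_equal = TRUE) {
  scale <- match.arg(scale)
  ratios <- as_tibble(ratios)
  panel <- as_tibble(panel)
  assert_that(all(c("accession", "group") %in% names(panel)),
              "panel needs `accession` and `group` columns")
  bad <- setdiff(unique(panel$group), c("apical", "both", "basolateral"))
  assert_that(length(bad) == 0,
              paste("unknown panel group(s):", paste(bad, collapse = ", ")))

  members <- panel %>%
    left_join(select(ratios, "accession", "mean"), by = "accession")
  get_values <- function(g) {
    v <- members %>% filter(.data$group == g, is.finite(.data$mean))
    setNames(v$mean, v$accession)
  }
  fits <- list()
  for (g in c("apical", "both", "basolateral")) {
    vals <- get_values(g)
    if (g == "both" && !is.null(both_moments)) {
      fits[[g]] <- fit_group_moments(both_moments$mean, both_moments$variance,
                                     n = both_moments$n %||% 7,
                                     label = g, scale = scale)
    } else {
      if (length(vals) < 3) {
        abort(sprintf(
          "reference group '%s' has %d member(s) with ratios; need >= 3",
          g, length(vals)))
      }
      fits[[g]] <- fit_group(vals, label = g, scale = scale)
    }
  }
  for (g in names(fits)) {
    p <- fits[[g]]$shapiro_p
    if (is.finite(p) && p < 0.05) {
      warn(sprintf(
        "Shapiro-Wilk on logged '%s' ratios rejects normality (p = %.3g)",
        g, p))
    }
  }
  both_values <- if (!is.null(fits$both$values)) {
    fits$both$values
  } else {
    synthesize_sample(fits$both$raw_mean, sqrt(fits$both$raw_variance),
                      fits$both$n)
  }
  group_values <- list(apical = get_values("apical"), both = both_values,
                       basolateral = get_values("basolateral"))

  pairs <- list(c("basolateral", "both"), c("both", "apical"),
                c("basolateral", "apical"))
  ks <- bind_rows(lapply(pairs, function(p) {
    k <- ks_compare(group_values[[p[1]]], group_values[[p[2]]])
    tibble(group_a = p[1], group_b = p[2], statistic = k$statistic,
           p_value = k$p_value, exact = k$exact)
  }))

  thresholds <- ba_thresholds(
    lower = density_intersection(fits$apical, fits$both),
    upper = density_intersection(fits$both, fits$basolateral)
  )

  tested <- members %>% filter(.data$group != "both", is.finite(.data$mean))
  m <- nrow(tested)
  model_tests <- bind_rows(lapply(seq_len(nrow(tested)), function(i) {
    acc <- tested$accession[i]
    pr <- protein_ratio_values(ratios, acc)
    tt <- protein_vs_group_ttest(pr, both_values, var_equal = var_equal)
    tibble(accession = acc, group = tested$group[i], t = tt$t, df = tt$df,
           p_value = tt$p_value)
  }))
  if (nrow(model_tests) > 0) {
    model_tests <- model_tests %>%
      mutate(p_adjusted = bonferroni(.data$p_value, m),
             significant = .data$p_adjusted < 0.05)
  }

  structure(list(fits = fits, thresholds = thresholds, ks = ks,
                 model_tests = model_tests, scale = scale, n_tested = m),
            class = "ba_calibration")
}

# per-animal ratios for one accession: stored values if present, otherwise
# reconstructed at the protein's printed mean and SEM
protein_ratio_values <- function(ratios, accession) {
  row <- ratios[ratios$accession == accession, ]
  assert_that(nrow(row) == 1, sprintf("accession %s not found", accession))
  if ("ratios" %in% names(row) && !is.null(row$ratios[[1]])) {
    return(row$ratios[[1]])
  }
  n <- if ("n" %in% names(row)) row$n[1] else 4L
  sem <- if ("sem" %in% names(row)) row$sem[1] else 0
  synthesize_sample(row$mean[1], sem * sqrt(n), n)
}

#' Decision thresholds on the B/A-ratio scale
#'
#' @param lower apical/both border; `upper` both/basolateral border.
#' @param upper see `lower`.
#' @return object of class `ba_thresholds`.
#' @export
ba_thresholds <- function(lower, upper) {
  assert_that(is.numeric(lower) && is.numeric(upper) && 0 < lower &&
                lower < upper, "need 0 < lower < upper")
  structure(list(lower = lower, upper = upper), class = "ba_thresholds")
}

#' @export
print.ba_thresholds <- function(x, ...) {
  cat(sprintf("<ba_thresholds> apical < %.4g <= both <= %.4g < basolateral\n",
              x$lower, x$upper))
  invisible(x)
}

#' @export
print.ba_calibration <- function(x, ...) {
  cat("B/A ratio calibration (", x$scale, "-scale density fits)\n", sep = "")
  for (f in x$fits) {
    cat(sprintf("  %-12s n = %2d  mu = %7.4f  sigma = %6.4f  shapiro p = %s\n",
                f$label, f$n, f$mu, f$sigma,
                ifelse(is.na(f$shapiro_p), "-",
                       sprintf("%.3f", f$shapiro_p))))
  }
  cat(sprintf("  borders: lower = %.4g, upper = %.4g\n",
              x$thresholds$lower, x$thresholds$upper))
  cat("  KS tests:\n")
  for (i in seq_len(nrow(x$ks))) {
    cat(sprintf("    %s vs %s: D = %.3f, p = %.3g%s\n", x$ks$group_a[i],
                x$ks$group_b[i], x$ks$statistic[i], x$ks$p_value[i],
                ifelse(x$ks$exact[i], " (exact)", "")))
  }
  if (nrow(x$model_tests) > 0) {
    cat(sprintf("  model proteins Bonferroni-significant vs both: %d / %d\n",
                sum(x$model_tests$significant), nrow(x$model_tests)))
  }
  invisible(x)
}
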