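# shared helpers: independent oracles and canned parameter sets

suppressPackageStartupMessages(library(dplyr))

# noise-free simulation: every stochastic layer switched off except the
# per-protein true-ratio draw
noise_free_params <- function(..., seed = 11) {
  simulation_params(
    replicate_cv = 0, transition_efficiency_sd = 0,
    peptide_ionization_sd = 0, dropout_prob = 0, seed = seed, ...)
}

# grid-search oracle for the intersection of two normal densities between
# their means: coarse pass at 1e-3 then refinement to a 1e-6 grid, fully
# independent of the closed-form quadratic in the package
grid_intersection <- function(mu1, s1, mu2, s2) {
  f <- function(x) abs(dnorm(x, mu1, s1) - dnorm(x, mu2, s2))
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  g <- seq(lo, hi, by = 1e-3)
  x0 <- g[which.min(f(g))]
  g <- seq(max(lo, x0 - 2e-3), min(hi, x0 + 2e-3), by = 1e-6)
  g[which.min(f(g))]
}

# direct evaluation of the pooled-variance two-sample t
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# random protein sequence over the canonical alphabet
random_sequence <- function(n, seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# published per-class category counts of the packaged liver call table
liver_expected_categories <- function() {
  list(
    apical = c(
      receptor = 17, `GPCR-related` = 3, `CD antigen` = 11, integrin = 4,
      adhesion = 2, transporter = 16, channel = 2, pump = 6, scaffold = 2,
      proteoglycan = 1, enzyme = 42, Rho = 3, `Ras-related` = 9, other = 32,
      uncharacterized = 4),
    basolateral = c(
      receptor = 11, `GPCR-related` = 1, `CD antigen` = 2, adhesion = 7,
      transporter = 34, channel = 2, pump = 4, scaffold = 10, enzyme = 11,
      Rho = 1, other = 41, uncharacterized = 1)
  )
}
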