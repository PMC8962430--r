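make_transitions <- function(areas, transition_ids = seq_along(areas),
                             animal = "M1", fraction = "apical",
                             peptide = "LLDVAGHK", accession = "P1") {
  tibble::tibble(accession = accession, peptide = peptide,
                 transition_id = as.character(transition_ids),
                 animal_id = animal, fraction = fraction, area = areas)
}

test_that("transition filtering enforces the floor and the cell minimum", {
  crit <- selection_criteria(min_valid_transitions = 3, min_area = 10)
  full <- make_transitions(c(20, 30, 40, 50, 60, 70))
  expect_equal(nrow(filter_transitions(full, crit)), 6)
  sparse <- make_transitions(c(20, 30, 1, 2, 3, 4))
  expect_equal(nrow(filter_transitions(sparse, crit)), 0)  # cell dropped
  # min_area = 0 with positive areas is the identity
  crit0 <- selection_criteria(min_valid_transitions = 1, min_area = 0)
  expect_equal(filter_transitions(full, crit0), full)
  # zero and negative areas are invalid regardless of the floor
  bad <- make_transitions(c(0, -5, 10, 20, 30))
  expect_equal(nrow(filter_transitions(bad, crit0)), 3)
})

test_that("normalization removes a pure transition-efficiency artifact", {
  base <- c(100, 150, 80, 120)  # four samples
  rec <- dplyr::bind_rows(
    make_transitions(base, 1, animal = c("M1", "M2", "M3", "M4")),
    make_transitions(3 * base, 2, animal = c("M1", "M2", "M3", "M4")))
  norm <- normalize_transitions(rec)
  w <- tidyr::pivot_wider(norm, id_cols = "animal_id",
                          names_from = "transition_id",
                          values_from = "area")
  expect_equal(w$`1`, w$`2`, tolerance = 1e-12)
})

test_that("single-transition peptides are returned unchanged", {
  rec <- make_transitions(c(5, 10), 1, animal = c("M1", "M2"))
  norm <- normalize_transitions(rec)
  expect_equal(norm$area, rec$area, tolerance = 1e-12)
  expect_equal(norm$efficiency, c(1, 1), tolerance = 1e-12)
})

test_that("known injected efficiency factors are recovered", {
  set.seed(21)
  truth <- c(0.5, 1, 2)  # geometric mean 1
  base <- stats::rlnorm(8, log(100), 0.4)
  rec <- dplyr::bind_rows(lapply(1:3, function(t) {
    make_transitions(truth[t] * base, t,
                     animal = rep(sprintf("M%d", 1:4), 2),
                     fraction = rep(c("apical", "basolateral"), each = 4))
  }))
  norm <- normalize_transitions(rec)
  eff <- norm %>% dplyr::distinct(transition_id, efficiency) %>%
    dplyr::arrange(transition_id)
  expect_equal(eff$efficiency, truth, tolerance = 1e-9)
  expect_equal(exp(mean(log(eff$efficiency))), 1, tolerance = 1e-12)
})

test_that("normalization is idempotent on random complete matrices", {
  set.seed(22)
  for (i in 1:5) {
    n_t <- sample(2:6, 1)
    rec <- dplyr::bind_rows(lapply(seq_len(n_t), function(t) {
      make_transitions(stats::rlnorm(8, log(50), 1), t,
                       animal = rep(sprintf("M%d", 1:4), 2),
                       fraction = rep(c("apical", "basolateral"), each = 4))
    }))
    once <- normalize_transitions(rec)
    twice <- normalize_transitions(dplyr::select(once, -efficiency))
    expect_equal(twice$area, once$area, tolerance = 1e-12)
    expect_equal(twice$efficiency, rep(1, nrow(twice)), tolerance = 1e-12)
  }
})

test_that("roll-up averages transitions then peptides arithmetically", {
  rec <- make_transitions(c(2, 4, 6))
  r <- rollup(rec)
  expect_equal(r$peptides$area, 4)
  two_peps <- dplyr::bind_rows(
    make_transitions(10, 1, peptide = "AAAAAK"),
    make_transitions(20, 1, peptide = "CCCCCK"))
  r2 <- rollup(two_peps)
  expect_equal(r2$proteins$area, 15)
  expect_equal(r2$proteins$n_peptides, 2L)
})

test_that("roll-up commutes with uniform rescaling of all areas", {
  set.seed(23)
  rec <- dplyr::bind_rows(lapply(1:3, function(t) {
    make_transitions(stats::rlnorm(4, log(100), 0.5), t,
                     animal = sprintf("M%d", 1:4))
  }))
  a <- quantify_transitions(rec)$proteins
  rec2 <- dplyr::mutate(rec, area = area * 7.5)
  b <- quantify_transitions(rec2)$proteins
  expect_equal(b$area, 7.5 * a$area, tolerance = 1e-12)
})

test_that("noise-free synthetic areas reproduce generator abundances exactly", {
  p <- noise_free_params(n_apical = 4, n_both = 4, n_basolateral = 4,
                         ref_sizes = c(apical = 3, both = 3, basolateral = 3))
  sim <- generate_dataset(p)
  quant <- quantify_transitions(sim$transitions)
  ap <- quant$proteins %>% dplyr::filter(fraction == "apical") %>%
    dplyr::left_join(sim$truth, by = "accession")
  expect_equal(ap$area, ap$abundance, tolerance = 1e-9)
  ba <- quant$proteins %>% dplyr::filter(fraction == "basolateral") %>%
    dplyr::left_join(sim$truth, by = "accession")
  expect_equal(ba$area, ba$abundance * ba$true_ba, tolerance = 1e-9)
})

test_that("quantify applies sequence-based selection and logs rejections", {
  gs <- generate_sequences(n_proteins = 2, n_clean = 2, seed = 3)
  pep <- gs$peptides[gs$peptides$role == "clean", ]
  rejects <- gs$peptides[gs$peptides$role == "met_cys", ]
  rec <- dplyr::bind_rows(lapply(seq_len(nrow(gs$peptides)), function(i) {
    make_transitions(c(10, 20, 30), 1:3,
                     peptide = gs$peptides$peptide[i],
                     accession = gs$peptides$accession[i])
  }))
  q <- suppressMessages(quantify_transitions(
    rec, sequences = gs$sequences, tm_intervals = gs$tm_intervals))
  expect_true(all(pep$peptide %in% q$peptides$peptide))
  expect_false(any(rejects$peptide %in% q$peptides$peptide))
  expect_true(all(rejects$peptide %in% q$rejected_peptides$peptide))
  expect_true(all(nzchar(q$rejected_peptides$reasons)))
})
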