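#' Per-protein basolateral/apical ratios across paired animals
#'
#' For every protein, the B/A ratio is computed per animal as the
#' basolateral-fraction protein area divided by the paired apical-fraction
#' area, and then summarized over animals: arithmetic mean, SEM
#' (sample SD / sqrt(n), n - 1 denominator) and sample variance. Animals
#' missing either fraction do not contribute; proteins with fewer than two
#' complete pairs are excluded and recorded in the `excluded` attribute
#' with a reason.
#'
#' @param protein_quant a `protein_quant` object from
#'   [quantify_transitions()], or its `proteins` tibble (`accession`,
#'   `animal_id`, `fraction`, `area`).
#' @param min_pairs minimum complete animal pairs (default 2).
#' @return tibble with columns `accession`, `n`, `mean`, `sem`, `variance`
#'   and a list-column `ratios` of the per-animal ratios (named by animal);
#'   excluded proteins in `attr(, "excluded")`.
#' @export
compute_ba_ratios <- function(protein_quant, min_pairs = 2) {
  prot <- if (inherits(protein_quant, "protein_quant")) {
    protein_quant$proteins
  } else {
    as_tibble(protein_quant)
  }
  assert_that(all(c("accession", "animal_id", "fraction", "area") %in%
                    names(prot)), "protein quant table misses columns")
  bad <- setdiff(unique(prot$fraction), .fractions)
  if (length(bad) > 0) {
    abort(sprintf("unknown fraction label(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(.fractions, collapse = ", ")))
  }
  wide <- prot %>%
    select("accession", "animal_id", "fraction", "area") %>%
    tidyr::pivot_wider(names_from = "fraction", values_from = "area")
  for (f in .fractions) if (!f %in% names(wide)) wide[[f]] <- NA_real_
  wide <- wide %>%
    mutate(ratio = .data$basolateral / .data$apical) %>%
    filter(is.finite(.data$ratio))

  res <- wide %>%
    group_by(.data$accession) %>%
    summarise(
      n = n(),
      mean = mean(.data$ratio),
      sem = if (n() > 1) sd(.data$ratio) / sqrt(n()) else NA_real_,
      variance = if (n() > 1) var(.data$ratio) else NA_real_,
      ratios = list(setNames(.data$ratio, .data$animal_id)),
      .groups = "drop"
    )
  excluded <- res %>%
    filter(.data$n < min_pairs) %>%
    mutate(reason = sprintf("only %d complete animal pair(s), need >= %d",
                            .data$n, min_pairs)) %>%
    select("accession", "reason")
  never_paired <- setdiff(unique(prot$accession), res$accession)
  if (length(never_paired) > 0) {
    excluded <- bind_rows(excluded, tibble(
      accession = never_paired,
      reason = "no animal with both apical and basolateral areas"
    ))
  }
  res <- filter(res, .data$n >= min_pairs)
  if (nrow(res) == 0) {
    abort(paste("no protein has two complete apical/basolateral animal",
                "pairs; is one fraction entirely missing?"))
  }
  if (nrow(excluded) > 0) {
    inform(sprintf("%d protein(s) excluded from ratio statistics",
                   nrow(excluded)))
  }
  attr(res, "excluded") <- excluded
  res
}
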