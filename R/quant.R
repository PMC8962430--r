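#' Remove unreliable transition peaks
#'
#' Drops transition records whose area is missing, non-positive (zero and
#' negative areas are invalid extraction output, never quantified), or
#' below the detection floor `min_area`, then drops every
#' (accession, peptide, animal, fraction) cell in which fewer than
#' `min_valid_transitions` transitions survive. Dropped cells are simply
#' absent from the output (missingness is encoded as an absent row
#' throughout the package).
#'
#' @param records transition tibble (`accession`, `peptide`,
#'   `transition_id`, `animal_id`, `fraction`, `area`).
#' @param criteria a [selection_criteria()] object; only `min_area` and
#'   `min_valid_transitions` are used here.
#' @return filtered transition tibble.
#' @export
filter_transitions <- function(records, criteria = selection_criteria()) {
  rec <- as_tibble(records)
  rec <- rec %>%
    filter(is.finite(.data$area), .data$area > 0,
           .data$area >= criteria$min_area)
  rec %>%
    group_by(.data$accession, .data$peptide, .data$animal_id, .data$fraction) %>%
    filter(n() >= criteria$min_valid_transitions) %>%
    ungroup()
}

#' Normalize transition-to-transition signal-intensity differences
#'
#' Different transitions of one peptide have systematically different
#' ionization/fragmentation efficiencies, so their raw areas differ by a
#' roughly constant multiplicative factor across samples. For each peptide
#' the per-transition efficiency factor is estimated as the geometric mean,
#' over samples, of the transition's area divided by that sample's
#' geometric mean over transitions; each area is then divided by its
#' transition's factor. On a complete transition-by-sample matrix the
#' factors have geometric mean 1, the operation is idempotent, and a pure
#' multiplicative transition artifact is removed exactly. A transition
#' observed in fewer samples gets its factor from the samples where it is
#' present.
#'
#' @param records transition tibble with positive areas (run
#'   [filter_transitions()] first).
#' @return the tibble with `area` replaced by the normalized area and an
#'   added `efficiency` column holding each transition's estimated factor.
#' @export
normalize_transitions <- function(records) {
  rec <- as_tibble(records)
  if (nrow(rec) == 0) return(mutate(rec, efficiency = numeric(0)))
  assert_that(all(rec$area > 0), "areas must be strictly positive")
  rec %>%
    group_by(.data$accession, .data$peptide, .data$animal_id, .data$fraction) %>%
    mutate(.log_sample = mean(log(.data$area))) %>%
    group_by(.data$accession, .data$peptide, .data$transition_id) %>%
    mutate(efficiency = exp(mean(log(.data$area) - .data$.log_sample))) %>%
    ungroup() %>%
    mutate(area = .data$area / .data$efficiency) %>%
    select(-".log_sample")
}

#' Roll transition areas up to peptide- and protein-level areas
#'
#' The peptide-level area of each (animal, fraction) cell is the arithmetic
#' mean of its surviving normalized transition areas; the protein-level
#' area is the arithmetic mean of its retained peptides' areas. A
#' protein/fraction/animal cell is missing iff all of its peptides are
#' missing there. Geometric averaging is available for sensitivity
#' analysis, arithmetic is the default.
#'
#' @param records normalized transition tibble.
#' @param average `"arithmetic"` (default) or `"geometric"`.
#' @return list with `peptides` (accession, peptide, animal_id, fraction,
#'   area, n_transitions) and `proteins` (accession, animal_id, fraction,
#'   area, n_peptides) tibbles.
#' @export
rollup <- function(records, average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  avg <- if (average == "arithmetic") {
    function(x) mean(x)
  } else {
    function(x) exp(mean(log(x)))
  }
  pep <- as_tibble(records) %>%
    group_by(.data$accession, .data$peptide, .data$animal_id, .data$fraction) %>%
    summarise(area = avg(.data$area), n_transitions = n(), .groups = "drop")
  prot <- pep %>%
    group_by(.data$accession, .data$animal_id, .data$fraction) %>%
    summarise(area = avg(.data$area), n_peptides = n(), .groups = "drop")
  list(peptides = pep, proteins = prot)
}

#' Transition table to protein-level peak areas
#'
#' Full quantification stage: sequence-based peptide selection (when
#' protein sequences and/or transmembrane intervals are supplied),
#' transition filtering, transition-efficiency normalization, and roll-up
#' to per-animal per-fraction protein areas. Proteins losing all of their
#' peptides are excluded and recorded in the rejection ledger.
#'
#' @param transitions transition tibble (`accession`, `peptide`,
#'   `transition_id`, `animal_id`, `fraction`, `area`).
#' @param criteria a [selection_criteria()] object.
#' @param sequences optional named character vector of protein sequences
#'   (names = accessions); enables miscleavage/ragged-end/transmembrane
#'   rules via in-silico digestion.
#' @param tm_intervals optional tibble (`accession`, `start`, `end`).
#' @param average passed to [rollup()].
#' @return object of class `protein_quant`: a list with `proteins`,
#'   `peptides`, and `rejected_peptides` (the rejection ledger) tibbles.
#' @export
quantify_transitions <- function(transitions, criteria = selection_criteria(),
                                 sequences = NULL, tm_intervals = NULL,
                                 average = "arithmetic") {
  rec <- as_tibble(transitions)
  observed <- distinct(rec, .data$accession, .data$peptide)
  ledger <- tibble(accession = character(), peptide = character(),
                   reasons = character())

  if (!is.null(sequences)) {
    dig <- bind_rows(lapply(names(sequences), function(acc) {
      mutate(digest_protein(sequences[[acc]]), accession = acc)
    }))
    observed <- observed %>%
      left_join(dig, by = c("accession", "peptide"))
  }
  sel <- select_peptides(observed, tm_intervals = tm_intervals,
                         criteria = criteria)
  ledger <- sel %>%
    filter(!.data$retained) %>%
    select("accession", "peptide", "reasons")
  rec <- rec %>%
    semi_join(filter(sel, .data$retained), by = c("accession", "peptide"))

  rec <- filter_transitions(rec, criteria)
  rec <- normalize_transitions(rec)
  rolled <- rollup(rec, average = average)

  lost <- setdiff(unique(as_tibble(transitions)$accession),
                  unique(rolled$proteins$accession))
  if (length(lost) > 0) {
    inform(sprintf("%d protein(s) excluded with no peptide surviving selection",
                   length(lost)))
  }
  structure(list(proteins = rolled$proteins, peptides = rolled$peptides,
                 rejected_peptides = ledger, excluded_proteins = lost),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("<protein_quant>", n_distinct(x$proteins$accession), "proteins,",
      n_distinct(x$peptides$peptide), "peptides;",
      nrow(x$rejected_peptides), "peptide(s) rejected\n")
  invisible(x)
}
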