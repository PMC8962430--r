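#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves a protein sequence after lysine (K) or arginine (R) except when
#' the following residue is proline (P), the standard trypsin specificity
#' rule. Peptides are returned in N-to-C order together with their 1-based
#' start/end coordinates, the number of internal missed cleavage sites, and
#' the flanking residues on either side (`-` at the protein termini). With
#' `miscleavage_allowance = 0` only fully cleaved peptides are returned;
#' larger allowances additionally return every run of up to
#' `miscleavage_allowance + 1` consecutive fully cleaved peptides.
#'
#' @param sequence single amino-acid string over the 20 canonical residues.
#' @param miscleavage_allowance maximum number of internal missed cleavages
#'   (default 0).
#' @return tibble with columns `peptide`, `start`, `end`, `n_missed`,
#'   `prev_aa`, `next_aa`.
#' @examples
#' digest_protein("MAKRSTPKLLR")$peptide # "MAK" "R" "STPK" "LLR"
#' digest_protein("AKPG")$peptide        # "AKPG": K before P is not cleaved
#' @export
digest_protein <- function(sequence, miscleavage_allowance = 0) {
  assert_that(is.character(sequence) && length(sequence) == 1 &&
                nzchar(sequence), "`sequence` must be a non-empty string")
  assert_that(miscleavage_allowance >= 0,
              "`miscleavage_allowance` must be >= 0")
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% .canonical_aa)
  if (length(bad) > 0) {
    abort(sprintf("non-canonical residue '%s' at position %d", aa[bad[1]],
                  bad[1]))
  }
  n <- length(aa)
  # cleavage after position i: K/R not followed by P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[cut_after + 1] != "P"]
  starts <- c(1, cut_after[cut_after < n] + 1)
  ends <- c(cut_after[cut_after < n], n)
  base <- tibble(
    start = starts, end = ends, n_missed = 0L,
    peptide = vapply(seq_along(starts),
                     function(i) substr(sequence, starts[i], ends[i]), "")
  )
  out <- base
  if (miscleavage_allowance > 0 && nrow(base) > 1) {
    for (k in seq_len(min(miscleavage_allowance, nrow(base) - 1))) {
      i <- seq_len(nrow(base) - k)
      out <- bind_rows(out, tibble(
        start = base$start[i], end = base$end[i + k], n_missed = as.integer(k),
        peptide = vapply(seq_along(i), function(j) {
          substr(sequence, base$start[j], base$end[j + k])
        }, "")
      ))
    }
  }
  out %>%
    mutate(
      prev_aa = ifelse(.data$start == 1, "-",
                       substring(sequence, .data$start - 1, .data$start - 1)),
      next_aa = ifelse(.data$end == n, "-",
                       substring(sequence, .data$end + 1, .data$end + 1))
    ) %>%
    arrange(.data$start, .data$end) %>%
    select("peptide", "start", "end", "n_missed", "prev_aa", "next_aa")
}

#' Peptide selection criteria
#'
#' Bundles the data-selection and amino-acid-sequence-based peptide
#' selection rules applied before quantification roll-up. The defaults
#' implement the usual criteria for reliable surrogate peptides in targeted
#' and DIA quantification: a workable length range, no methionine or
#' cysteine (oxidation / alkylation artifacts), fully cleaved peptides
#' without ragged ends (KK/RR/KR/RK junctions digest poorly), no overlap
#' with a transmembrane segment, and at least `min_valid_transitions`
#' surviving transitions per (peptide, animal, fraction) cell.
#'
#' @param min_length,max_length allowed peptide length in residues.
#' @param forbid_residues residues whose presence rejects a peptide.
#' @param forbid_miscleavage reject peptides with internal missed cleavages.
#' @param forbid_ragged_ends reject peptides flanked by K/R (KK/RR/KR/RK
#'   junctions).
#' @param forbid_tm_overlap reject peptides sharing any residue with a
#'   transmembrane interval.
#' @param min_valid_transitions minimum surviving transitions for a
#'   (peptide, animal, fraction) cell to be quantified.
#' @param min_area detection floor; transition areas below it are dropped.
#' @return object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_length = 6, max_length = 16,
                               forbid_residues = c("M", "C"),
                               forbid_miscleavage = TRUE,
                               forbid_ragged_ends = TRUE,
                               forbid_tm_overlap = TRUE,
                               min_valid_transitions = 3,
                               min_area = 0) {
  assert_that(min_length <= max_length, "`min_length` must be <= `max_length`")
  assert_that(min_valid_transitions >= 1, "`min_valid_transitions` must be >= 1")
  structure(list(
    min_length = min_length, max_length = max_length,
    forbid_residues = forbid_residues,
    forbid_miscleavage = forbid_miscleavage,
    forbid_ragged_ends = forbid_ragged_ends,
    forbid_tm_overlap = forbid_tm_overlap,
    min_valid_transitions = min_valid_transitions,
    min_area = min_area
  ), class = "selection_criteria")
}

#' Apply sequence-based peptide selection rules
#'
#' Retains a peptide iff it violates none of the enabled rules, and returns
#' an exhaustive rejection ledger: every rejected peptide lists every rule
#' it violates (`length`, `residue`, `miscleavage`, `ragged_end`,
#' `transmembrane`). Context rules (`miscleavage`, `ragged_end`,
#' `transmembrane`) are only evaluated when the corresponding columns
#' (`n_missed`, `prev_aa`/`next_aa`, `start`/`end`) are available, so the
#' function also works on bare peptide strings observed in a transition
#' table without a protein database.
#'
#' Peptide and transmembrane coordinates are 1-based closed intervals on
#' the same protein; overlap means any shared residue.
#'
#' @param peptides tibble with at least a `peptide` column; optionally
#'   `accession`, `start`, `end`, `n_missed`, `prev_aa`, `next_aa` as
#'   produced by [digest_protein()].
#' @param tm_intervals optional tibble (`accession`, `start`, `end`) of
#'   transmembrane segments.
#' @param criteria a [selection_criteria()] object.
#' @return the input tibble with logical `retained` and character `reasons`
#'   (`;`-separated, `""` when retained) columns.
#' @export
select_peptides <- function(peptides, tm_intervals = NULL,
                            criteria = selection_criteria()) {
  assert_that(inherits(criteria, "selection_criteria"),
              "`criteria` must be a selection_criteria object")
  pep <- as_tibble(peptides)
  assert_that("peptide" %in% names(pep), "`peptides` needs a `peptide` column")
  if (nrow(pep) == 0) {
    return(mutate(pep, retained = logical(0), reasons = character(0)))
  }
  len <- nchar(pep$peptide)
  viol <- list()
  viol$length <- len < criteria$min_length | len > criteria$max_length
  if (length(criteria$forbid_residues) > 0) {
    pat <- paste0("[", paste(criteria$forbid_residues, collapse = ""), "]")
    viol$residue <- grepl(pat, pep$peptide)
  }
  if (criteria$forbid_miscleavage && "n_missed" %in% names(pep)) {
    viol$miscleavage <- pep$n_missed > 0
  }
  if (criteria$forbid_ragged_ends && all(c("prev_aa", "next_aa") %in% names(pep))) {
    # a terminus is ragged when its cleavage site lies inside a K/R
    # dipeptide (KK/RR/KR/RK): such junctions digest variably. Every
    # tryptic peptide is preceded by K/R, so the N-side condition also
    # requires the peptide's own first residue to be K/R.
    kr <- c("K", "R")
    first <- substring(pep$peptide, 1, 1)
    last <- substring(pep$peptide, len, len)
    viol$ragged_end <- (pep$prev_aa %in% kr & first %in% kr) |
      (pep$next_aa %in% kr & last %in% kr)
  }
  if (criteria$forbid_tm_overlap && !is.null(tm_intervals) &&
      nrow(tm_intervals) > 0 && all(c("start", "end") %in% names(pep))) {
    tm <- as_tibble(tm_intervals)
    by_acc <- "accession" %in% names(pep) && "accession" %in% names(tm)
    viol$transmembrane <- vapply(seq_len(nrow(pep)), function(i) {
      t <- if (by_acc) tm[tm$accession == pep$accession[i], ] else tm
      any(t$start <= pep$end[i] & t$end >= pep$start[i])
    }, logical(1))
  }
  reason_mat <- do.call(cbind, viol)
  reasons <- apply(reason_mat, 1, function(v) {
    paste(names(viol)[which(v)], collapse = ";")
  })
  pep %>% mutate(retained = reasons == "", reasons = reasons)
}
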