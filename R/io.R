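# Tables are tab-separated UTF-8 with a header row and "." decimals.

.read_tsv <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

#' Read and write the transition-level peak-area table
#'
#' Columns: `accession`, `peptide`, `transition_id`, `animal_id`,
#' `fraction`, `area`. Fraction labels may use the hepatocyte terminology
#' (`canalicular` = apical, `sinusoidal` = basolateral); the alias map is
#' applied on read and any other label is an error naming the allowed
#' values. Reading a written table restores identical content.
#'
#' @param path file path.
#' @param aliases named character vector mapping alternative fraction
#'   labels to canonical ones.
#' @return transition tibble.
#' @export
read_transition_table <- function(path, aliases = .fraction_aliases) {
  tab <- .read_tsv(path, readr::cols(
    accession = "c", peptide = "c", transition_id = "c", animal_id = "c",
    fraction = "c", area = "d"))
  if (nrow(tab) > 0) {
    tab$fraction <- ifelse(tab$fraction %in% names(aliases),
                           unname(aliases[tab$fraction]), tab$fraction)
    bad <- which(!tab$fraction %in% .fractions)
    if (length(bad) > 0) {
      abort(sprintf(
        "line %d: unknown fraction label '%s' (allowed: %s)",
        bad[1] + 1, tab$fraction[bad[1]],
        paste(c(.fractions, names(aliases)), collapse = ", ")))
    }
    if (any(!is.finite(tab$area))) {
      abort(sprintf("line %d: malformed or missing area",
                    which(!is.finite(tab$area))[1] + 1))
    }
  }
  tab
}

#' @rdname read_transition_table
#' @param transitions transition tibble to write.
#' @export
write_transition_table <- function(transitions, path) {
  readr::write_tsv(as_tibble(transitions), path, progress = FALSE)
  invisible(path)
}

#' Read an annotation table
#'
#' Columns: `accession`, optional `gene`, `keywords` (a `;`-separated
#' subcellular-location keyword list), optional `category`.
#'
#' @param path file path.
#' @return annotation tibble.
#' @export
read_annotation_table <- function(path) {
  tab <- .read_tsv(path, readr::cols(.default = "c"))
  assert_that(all(c("accession", "keywords") %in% names(tab)),
              "annotation table needs `accession` and `keywords` columns")
  tab
}

#' Read a reference-panel table
#'
#' Columns: `accession`, `group` (apical/both/basolateral), optional
#' `ba_mean`, `ba_sem`, `panel_only`.
#'
#' @param path file path.
#' @return panel tibble.
#' @export
read_reference_panel <- function(path) {
  tab <- .read_tsv(path, readr::cols(.default = "c"))
  assert_that(all(c("accession", "group") %in% names(tab)),
              "panel table needs `accession` and `group` columns")
  bad <- setdiff(unique(tab$group), c("apical", "both", "basolateral"))
  assert_that(length(bad) == 0,
              paste("unknown panel group(s):", paste(bad, collapse = ", ")))
  for (col in c("ba_mean", "ba_sem")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write the localization call table
#'
#' @param calls call table from [build_call_table()].
#' @param path file path.
#' @export
write_call_table <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path, progress = FALSE)
  invisible(path)
}

#' Read/write protein sequences as FASTA
#'
#' Thin wrappers over Biostrings; sequences are plain named character
#' vectors inside the package.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  rlang::check_installed("Biostrings")
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of protein sequences.
#' @export
write_fasta <- function(sequences, path) {
  rlang::check_installed("Biostrings")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Curated mouse-liver membrane-protein call table
#'
#' The packaged table of 279 mouse-liver plasma-membrane(-candidate)
#' proteins with their measured basolateral/apical ratio summaries
#' (mean +/- SEM over 4 animals), UniProt-derived membrane status
#' (`yes` = annotated cell membrane, `potentially` = membrane without an
#' organelle-membrane keyword), curated functional category, and the
#' membrane side each protein is enriched on (154 apical, 125
#' basolateral). Used as the desk-scale acceptance fixture for the
#' classification stage.
#'
#' @return tibble with columns `accession`, `gene`, `ba_mean`, `ba_sem`,
#'   `membrane_status`, `category`, `side`.
#' @export
liver_membrane_calls <- function() {
  path <- system.file("extdata", "liver_membrane_calls.tsv",
                      package = "swathloc", mustWork = TRUE)
  .read_tsv(path, readr::cols(
    accession = "c", gene = "c", ba_mean = "d", ba_sem = "d",
    membrane_status = "c", category = "c", side = "c"))
}

#' Literature-validated liver reference panel
#'
#' The 41-protein reference panel with immunohistochemically established
#' localization: 23 basolateral and 11 apical model proteins (B/A means
#' present where published; two apical members, Atp8b1 and Atp9a, are
#' panel-only without published ratios) and the both-localized group,
#' whose member-level ratios were never published and which is therefore
#' carried by its published raw moments (see [both_group_moments()]).
#'
#' @return tibble with columns `accession`, `gene`, `group`, `ba_mean`,
#'   `ba_sem`, `panel_only`.
#' @export
liver_reference_panel <- function() {
  path <- system.file("extdata", "liver_reference_panel.tsv",
                      package = "swathloc", mustWork = TRUE)
  .read_tsv(path, readr::cols(
    accession = "c", gene = "c", group = "c", ba_mean = "d", ba_sem = "d",
    panel_only = "c"))
}

#' Published raw moments of the both-localized reference group
#'
#' Mean 1.04 and variance 0.0227 of the 7 both-localized model proteins'
#' mean B/A ratios (one value per protein, not per animal).
#'
#' @return `list(mean = 1.04, variance = 0.0227, n = 7)`.
#' @export
both_group_moments <- function() {
  list(mean = 1.04, variance = 0.0227, n = 7)
}
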