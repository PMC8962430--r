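#' Organelle-membrane keyword blacklist
#'
#' Reads the editable blacklist of organelle-membrane keywords shipped in
#' `inst/extdata/organelle_membranes.txt` (one lower-case term per line,
#' `#` comments). A protein whose only membrane keywords match this list
#' is excluded from plasma-membrane candidacy.
#'
#' @param path optional path to an alternative blacklist file.
#' @return character vector of lower-case terms.
#' @export
organelle_blacklist <- function(path = NULL) {
  path <- path %||% system.file("extdata", "organelle_membranes.txt",
                                package = "swathloc", mustWork = TRUE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  tolower(x[nzchar(x)])
}

#' Plasma-membrane candidacy from subcellular-location keywords
#'
#' Implements the keyword filter used to restrict calls to plasma-membrane
#' proteins. A protein is `"yes"` if any keyword contains "cell membrane"
#' (an explicit cell-membrane annotation wins regardless of additional
#' organelle keywords); otherwise `"potentially"` if some keyword contains
#' "membrane" and none of its membrane keywords is on the
#' organelle-membrane blacklist (e.g. mitochondrial membrane); otherwise
#' `"excluded"`. Matching is case-insensitive and trimmed; the result is a
#' pure function of the keyword set (order does not matter). An empty
#' keyword set is `"excluded"`.
#'
#' @param keywords character vector of keywords, or a single `;`-separated
#'   string.
#' @param blacklist organelle-membrane terms, default
#'   [organelle_blacklist()].
#' @return one of `"yes"`, `"potentially"`, `"excluded"`.
#' @examples
#' membrane_status(c("Cell membrane", "Lysosome membrane")) # "yes"
#' membrane_status("Membrane")                              # "potentially"
#' membrane_status("Mitochondrion inner membrane")          # "excluded"
#' @export
membrane_status <- function(keywords, blacklist = organelle_blacklist()) {
  kw <- unlist(strsplit(as.character(keywords), ";"), use.names = FALSE)
  kw <- tolower(trimws(kw))
  kw <- kw[nzchar(kw)]
  if (length(kw) == 0) return("excluded")
  if (any(grepl("cell membrane", kw, fixed = TRUE))) return("yes")
  memb <- kw[grepl("membrane", kw, fixed = TRUE)]
  if (length(memb) == 0) return("excluded")
  on_blacklist <- vapply(memb, function(k) {
    any(vapply(blacklist, function(b) grepl(b, k, fixed = TRUE), logical(1)))
  }, logical(1))
  if (any(on_blacklist)) "excluded" else "potentially"
}

#' Classify a B/A ratio against the calibrated borders
#'
#' Strict inequalities, following the wording "less than" / "more than":
#' apical iff `ba_mean < lower`, basolateral iff `ba_mean > upper`, both
#' otherwise (a mean exactly on a border is "both"). Vectorized and
#' monotone in `ba_mean`.
#'
#' @param ba_mean positive mean B/A ratio(s).
#' @param thresholds a [ba_thresholds()] object.
#' @return character vector in `{"apical", "both", "basolateral"}`.
#' @export
classify_ratio <- function(ba_mean, thresholds) {
  assert_that(inherits(thresholds, "ba_thresholds"),
              "`thresholds` must be a ba_thresholds object")
  assert_that(all(ba_mean > 0), "`ba_mean` must be > 0")
  ifelse(ba_mean < thresholds$lower, "apical",
         ifelse(ba_mean > thresholds$upper, "basolateral", "both"))
}

#' Build the final localization call table
#'
#' Joins quantified B/A ratios with annotations, applies the
#' plasma-membrane keyword filter, classifies every candidate against the
#' calibrated borders, and tests each candidate's per-animal ratios
#' against the both-localized reference group (pooled Student's t,
#' Bonferroni-corrected over the number of called proteins by default).
#' Proteins without annotation, or with `membrane_status = "excluded"`,
#' are returned in the `excluded` attribute with a reason and carry no
#' class.
#'
#' @param ratios tibble from [compute_ba_ratios()] (or a summary table
#'   with `accession`, `mean`, `sem`, `n`; per-animal values are then
#'   reconstructed at those moments).
#' @param annotations tibble with `accession`, `keywords`, and optionally
#'   `gene`, `category`.
#' @param thresholds a [ba_thresholds()] object (calibrated or overridden).
#' @param both the both-localized reference: a numeric vector of member
#'   mean ratios, or `list(mean =, variance =, n =)` published moments.
#' @param m Bonferroni denominator; default: number of called proteins.
#' @param blacklist passed to [membrane_status()].
#' @param var_equal passed to [protein_vs_group_ttest()].
#' @return tibble of calls: `accession`, `gene`, `ba_mean`, `ba_sem`,
#'   `membrane_status`, `class`, `p_value`, `p_adjusted`, `significant`,
#'   `category`; excluded proteins in `attr(, "excluded")`.
#' @export
build_call_table <- function(ratios, annotations, thresholds, both,
                             m = NULL, blacklist = organelle_blacklist(),
                             var_equal = TRUE) {
  ratios <- as_tibble(ratios)
  ann <- as_tibble(annotations)
  assert_that(all(c("accession", "keywords") %in% names(ann)),
              "annotations need `accession` and `keywords` columns")
  if (!"gene" %in% names(ann)) ann$gene <- NA_character_
  if (!"category" %in% names(ann)) ann$category <- NA_character_

  both_values <- if (is.list(both) && !is.null(both$mean)) {
    synthesize_sample(both$mean, sqrt(both$variance), both$n %||% 7)
  } else {
    as.numeric(both)
  }
  assert_that(length(both_values) >= 2,
              "both group needs >= 2 member values")

  tab <- ratios %>%
    left_join(select(ann, "accession", "gene", "keywords", "category"),
              by = "accession")
  no_ann <- is.na(tab$keywords)
  if (any(no_ann)) {
    warn(sprintf("%d quantified protein(s) have no annotation; excluded",
                 sum(no_ann)))
  }
  tab$membrane_status <- ifelse(
    no_ann, "excluded",
    vapply(tab$keywords, membrane_status, "", blacklist = blacklist)
  )
  excluded <- tab %>%
    filter(.data$membrane_status == "excluded") %>%
    mutate(reason = ifelse(is.na(.data$keywords), "no annotation",
                           "keyword filter")) %>%
    select("accession", "gene", "reason")

  calls <- tab %>% filter(.data$membrane_status != "excluded")
  if (nrow(calls) == 0) {
    res <- tibble(accession = character(), gene = character(),
                  ba_mean = numeric(), ba_sem = numeric(),
                  membrane_status = character(), class = character(),
                  p_value = numeric(), p_adjusted = numeric(),
                  significant = logical(), category = character())
    attr(res, "excluded") <- excluded
    return(res)
  }
  calls$class <- classify_ratio(calls$mean, thresholds)
  m <- m %||% nrow(calls)
  tests <- vapply(calls$accession, function(acc) {
    protein_vs_group_ttest(protein_ratio_values(ratios, acc), both_values,
                           var_equal = var_equal)$p_value
  }, numeric(1))
  res <- calls %>%
    mutate(p_value = unname(tests),
           p_adjusted = bonferroni(.data$p_value, m),
           significant = .data$p_adjusted < 0.05) %>%
    rename(ba_mean = "mean", ba_sem = "sem") %>%
    select("accession", "gene", "ba_mean", "ba_sem", "membrane_status",
           "class", "p_value", "p_adjusted", "significant", "category")
  attr(res, "excluded") <- excluded
  attr(res, "bonferroni_m") <- m
  res
}

#' Functional-category composition of the calls
#'
#' Contingency table of class by functional category, with per-class
#' totals. Totals equal the number of called proteins.
#'
#' @param calls call table from [build_call_table()] (needs `class` and
#'   `category` columns).
#' @return tibble `category` x one column per class, plus a `total` row.
#' @export
summarize_categories <- function(calls) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(tibble(category = "total", apical = 0L, both = 0L,
                  basolateral = 0L))
  }
  wide <- calls %>%
    mutate(category = ifelse(is.na(.data$category), "uncategorized",
                             .data$category)) %>%
    count(.data$category, .data$class) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("apical", "both", "basolateral")) {
    if (!cl %in% names(wide)) wide[[cl]] <- 0L
  }
  wide <- wide %>% select("category", "apical", "both", "basolateral")
  totals <- tibble(category = "total",
                   apical = sum(wide$apical), both = sum(wide$both),
                   basolateral = sum(wide$basolateral))
  bind_rows(wide, totals)
}
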