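#' Parameters of the synthetic two-fraction SWATH experiment
#'
#' Describes the simulated world: per-class log-normal true B/A ratios,
#' paired animals, peptides and transitions per protein, and a
#' multiplicative noise model at three levels (per-animal replicate noise,
#' per-peptide ionization efficiency, per-transition fragmentation
#' efficiency), matching the ratio-and-averaging arithmetic of the
#' quantification stage. Class defaults are read from the observed ranges
#' of the liver reference panel: apical ratios cluster around 0.3-0.77,
#' both-localized around 1 (raw variance ~0.023, i.e. sigma_log ~0.14),
#' basolateral around 1.7-5.7. Replicate CV defaults to 2%, the magnitude
#' of the published per-protein SEMs (~0.5-3% of the means). Dropout is
#' encoded as an absent transition row, mirroring real extraction output.
#'
#' @param n_apical,n_both,n_basolateral protein counts per true class.
#' @param class_log_mean,class_log_sd named numeric (apical/both/
#'   basolateral): mean and SD of `ln`(true B/A) per class.
#' @param n_animals paired animals (>= 2, default 4).
#' @param peptides_per_protein inclusive integer range, default `c(1, 5)`.
#' @param transitions_per_peptide transitions per peptide, default 6.
#' @param transition_efficiency_sd SD of `ln`(per-transition multiplicative
#'   efficiency).
#' @param peptide_ionization_sd SD of `ln`(per-peptide ionization factor).
#' @param replicate_cv coefficient of variation of the per-animal,
#'   per-fraction multiplicative replicate noise (biological + technical).
#' @param dropout_prob probability a transition row is missing; scalar or
#'   named length-2 vector `c(apical =, basolateral =)`.
#' @param frac_nonmembrane,frac_potential,frac_organelle annotation
#'   keyword mixture: fraction of proteins annotated with no membrane
#'   keyword, with a bare "Membrane" keyword, and with an
#'   organelle-membrane keyword; the remainder get "Cell membrane".
#' @param ref_sizes named integer vector: reference-panel members drawn
#'   per class (capped at the class size), default `c(apical = 11,
#'   both = 7, basolateral = 23)` as in the liver panel.
#' @param abundance_log_mean,abundance_log_sd `ln`-scale parameters of the
#'   true apical-fraction protein abundance.
#' @param seed integer random seed; identical seeds reproduce identical
#'   datasets.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(
    n_apical = 30, n_both = 30, n_basolateral = 30,
    class_log_mean = c(apical = log(0.5), both = log(1), basolateral = log(2.4)),
    class_log_sd = c(apical = 0.2, both = 0.14, basolateral = 0.21),
    n_animals = 4,
    peptides_per_protein = c(1, 5),
    transitions_per_peptide = 6,
    transition_efficiency_sd = 0.5,
    peptide_ionization_sd = 0.8,
    replicate_cv = 0.02,
    dropout_prob = 0.05,
    frac_nonmembrane = 0.10, frac_potential = 0.25, frac_organelle = 0.05,
    ref_sizes = c(apical = 11, both = 7, basolateral = 23),
    abundance_log_mean = log(1e5), abundance_log_sd = 1,
    seed = 1) {
  p <- list(
    n_apical = n_apical, n_both = n_both, n_basolateral = n_basolateral,
    class_log_mean = class_log_mean, class_log_sd = class_log_sd,
    n_animals = n_animals, peptides_per_protein = peptides_per_protein,
    transitions_per_peptide = transitions_per_peptide,
    transition_efficiency_sd = transition_efficiency_sd,
    peptide_ionization_sd = peptide_ionization_sd,
    replicate_cv = replicate_cv, dropout_prob = dropout_prob,
    frac_nonmembrane = frac_nonmembrane, frac_potential = frac_potential,
    frac_organelle = frac_organelle, ref_sizes = ref_sizes,
    abundance_log_mean = abundance_log_mean,
    abundance_log_sd = abundance_log_sd, seed = seed
  )
  counts <- c(n_apical, n_both, n_basolateral)
  assert_that(all(counts >= 0), "class counts must be >= 0")
  assert_that(all(class_log_sd >= 0) && transition_efficiency_sd >= 0 &&
                peptide_ionization_sd >= 0 && replicate_cv >= 0 &&
                abundance_log_sd >= 0, "all SDs must be >= 0")
  probs <- c(dropout_prob, frac_nonmembrane, frac_potential, frac_organelle)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0, 1]")
  assert_that(frac_nonmembrane + frac_potential + frac_organelle <= 1,
              "annotation fractions must sum to <= 1")
  assert_that(n_animals >= 2, "`n_animals` must be >= 2")
  assert_that(length(peptides_per_protein) == 2 &&
                peptides_per_protein[1] >= 1 &&
                peptides_per_protein[1] <= peptides_per_protein[2],
              "`peptides_per_protein` must be an increasing range >= 1")
  assert_that(transitions_per_peptide >= 1,
              "`transitions_per_peptide` must be >= 1")
  assert_that(all(c("apical", "both", "basolateral") %in%
                    names(class_log_mean)) &&
                all(c("apical", "both", "basolateral") %in%
                      names(class_log_sd)),
              "class parameter vectors must be named apical/both/basolateral")
  structure(p, class = "simulation_params")
}

.dropout_for <- function(dropout_prob, fraction) {
  if (length(dropout_prob) == 1) return(unname(dropout_prob))
  unname(dropout_prob[[fraction]])
}

#' Generate a complete synthetic two-fraction experiment
#'
#' Draws per-protein true B/A ratios from the class-specific log-normal
#' distributions and emits everything the downstream pipeline consumes:
#' the transition-level peak-area table, an annotation table with
#' realistic subcellular-location keywords, a labelled reference panel,
#' and the ground truth. The expected apical-fraction area of a transition
#' equals the protein's true abundance (times its peptide/transition
#' efficiency factors, which have unit median and cancel in the B/A
#' ratio); the expected basolateral area is that times the true B/A ratio.
#' Replicate noise is multiplicative log-normal with mean 1 and the
#' requested CV. Identical seeds reproduce identical outputs.
#'
#' @param params a [simulation_params()] object.
#' @return object of class `swath_simulation`: list with `transitions`,
#'   `annotations`, `panel`, `truth` tibbles and `params`.
#' @export
generate_dataset <- function(params = simulation_params()) {
  assert_that(inherits(params, "simulation_params"),
              "`params` must come from simulation_params()")
  for (g in c("apical", "both", "basolateral")) {
    ref_n <- params$ref_sizes[[g]] %||% 0
    n_g <- switch(g, apical = params$n_apical, both = params$n_both,
                  basolateral = params$n_basolateral)
    if (ref_n > 0 && n_g == 0) {
      abort(sprintf(
        "reference panel requests %d '%s' protein(s) but the class is empty",
        ref_n, g))
    }
  }
  withr::with_seed(params$seed, .generate_dataset_impl(params))
}

.generate_dataset_impl <- function(p) {
  classes <- rep(c("apical", "both", "basolateral"),
                 c(p$n_apical, p$n_both, p$n_basolateral))
  n_prot <- length(classes)
  assert_that(n_prot > 0, "no proteins requested")
  accession <- sprintf("SYN%s%04d", toupper(substr(classes, 1, 2)),
                       seq_len(n_prot))
  gene <- sprintf("Gene%04d", seq_len(n_prot))

  true_ba <- rlnorm(n_prot, p$class_log_mean[classes], p$class_log_sd[classes])
  abundance <- rlnorm(n_prot, p$abundance_log_mean, p$abundance_log_sd)
  truth <- tibble(accession = accession, gene = gene, class = classes,
                  true_ba = true_ba, abundance = abundance)

  # annotation keyword mixture
  kw_class <- sample(
    c("none", "potential", "organelle", "cell"), n_prot, replace = TRUE,
    prob = c(p$frac_nonmembrane, p$frac_potential, p$frac_organelle,
             1 - p$frac_nonmembrane - p$frac_potential - p$frac_organelle))
  organelle_kw <- c("Mitochondrion inner membrane", "Mitochondrion outer membrane",
                    "Endoplasmic reticulum membrane", "Golgi apparatus membrane",
                    "Lysosome membrane", "Peroxisome membrane")
  keywords <- vapply(seq_len(n_prot), function(i) {
    switch(kw_class[i],
           none = sample(c("Cytoplasm", "Secreted", "Nucleus"), 1),
           potential = "Membrane",
           organelle = sample(organelle_kw, 1),
           cell = if (runif(1) < 0.2) {
             paste("Cell membrane", sample(organelle_kw, 1), sep = "; ")
           } else {
             "Cell membrane"
           })
  }, "")
  categories <- c("receptor", "GPCR-related", "CD antigen", "integrin",
                  "adhesion", "transporter", "channel", "pump", "scaffold",
                  "proteoglycan", "enzyme", "Rho", "Ras-related", "other",
                  "uncharacterized")
  annotations <- tibble(
    accession = accession, gene = gene, keywords = keywords,
    category = sample(categories, n_prot, replace = TRUE),
    intended_status = unname(c(none = "excluded", potential = "potentially",
                               organelle = "excluded", cell = "yes")[kw_class])
  )

  panel <- bind_rows(lapply(c("apical", "both", "basolateral"), function(g) {
    members <- accession[classes == g]
    k <- min(p$ref_sizes[[g]] %||% 0, length(members))
    if (k == 0) return(NULL)
    tibble(accession = sample(members, k), group = g)
  }))

  # per-protein peptide counts and per-peptide/transition efficiencies
  n_pep <- sample(seq(p$peptides_per_protein[1], p$peptides_per_protein[2]),
                  n_prot, replace = TRUE)
  pep <- tibble(
    accession = rep(accession, n_pep),
    true_ba = rep(true_ba, n_pep),
    abundance = rep(abundance, n_pep),
    peptide = unlist(lapply(n_pep, function(k) {
      vapply(seq_len(k), function(j) .random_peptide(), "")
    })),
    pep_eff = rlnorm(sum(n_pep), 0, p$peptide_ionization_sd)
  )
  trans <- pep[rep(seq_len(nrow(pep)), each = p$transitions_per_peptide), ]
  trans$transition_id <- sprintf("y%d", rep(seq_len(p$transitions_per_peptide),
                                            nrow(pep)))
  trans$trans_eff <- rlnorm(nrow(trans), 0, p$transition_efficiency_sd)

  animals <- sprintf("M%d", seq_len(p$n_animals))
  cells <- tidyr::expand_grid(trans, animal_id = animals,
                              fraction = .fractions)
  cv <- p$replicate_cv
  sdlog <- sqrt(log(1 + cv^2))
  # replicate noise shared across transitions within a (protein, animal,
  # fraction) cell so the protein-level CV matches `replicate_cv`
  noise_key <- cells %>%
    distinct(.data$accession, .data$animal_id, .data$fraction) %>%
    mutate(noise = if (cv == 0) 1 else
      rlnorm(n(), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  cells <- cells %>%
    left_join(noise_key, by = c("accession", "animal_id", "fraction")) %>%
    mutate(area = .data$abundance *
             ifelse(.data$fraction == "basolateral", .data$true_ba, 1) *
             .data$pep_eff * .data$trans_eff * .data$noise)

  drop_p <- if (length(p$dropout_prob) == 1) {
    rep(unname(p$dropout_prob), nrow(cells))
  } else {
    unname(p$dropout_prob[cells$fraction])
  }
  keep <- runif(nrow(cells)) >= drop_p
  transitions <- cells[keep, ] %>%
    select("accession", "peptide", "transition_id", "animal_id", "fraction",
           "area")

  structure(list(transitions = transitions, annotations = annotations,
                 panel = panel, truth = truth, params = p),
            class = "swath_simulation")
}

# random clean tryptic peptide: interior residues avoid K/R/M/C, first
# residue avoids P (would suppress the upstream cleavage), ends in K/R
.random_peptide <- function(min_len = 7, max_len = 14) {
  len <- sample(min_len:max_len, 1)
  interior <- setdiff(.canonical_aa, c("K", "R", "M", "C"))
  first <- setdiff(interior, "P")
  paste0(paste(c(sample(first, 1),
                 sample(interior, len - 2, replace = TRUE)), collapse = ""),
         sample(c("K", "R"), 1))
}

#' @export
print.swath_simulation <- function(x, ...) {
  cat("<swath_simulation>", nrow(x$truth), "proteins (",
      x$params$n_apical, "apical /", x$params$n_both, "both /",
      x$params$n_basolateral, "basolateral ),",
      nrow(x$transitions), "transition rows\n")
  invisible(x)
}

#' Generate synthetic protein sequences with engineered rule violations
#'
#' Emits protein sequences built as concatenations of tryptic units, so
#' that in-silico digestion exactly inverts the construction, together
#' with transmembrane-interval annotations and a per-peptide truth table.
#' A stated number of peptides per protein is engineered to violate each
#' selection rule so the selection stage can be exercised: peptides
#' containing Met/Cys, peptides overlapping a transmembrane interval,
#' too-short and too-long peptides, and ragged (K|K-type) junctions (the
#' junction also emits a stray single-residue peptide, itself rejected on
#' length).
#'
#' @param n_proteins number of proteins.
#' @param n_clean clean rule-passing peptides per protein.
#' @param n_met_cys,n_tm,n_short,n_long,n_ragged engineered violations per
#'   protein (counts).
#' @param clean_length inclusive length range of clean peptides; must fit
#'   inside the default selection length window.
#' @param seed random seed.
#' @return list with `sequences` (named character), `tm_intervals` tibble
#'   (`accession`, `start`, `end`) and `peptides` truth tibble
#'   (`accession`, `peptide`, `start`, `end`, `role`).
#' @export
generate_sequences <- function(n_proteins = 5, n_clean = 3, n_met_cys = 1,
                               n_tm = 1, n_short = 1, n_long = 1,
                               n_ragged = 1, clean_length = c(7, 14),
                               seed = 1) {
  assert_that(n_proteins >= 1, "`n_proteins` must be >= 1")
  counts <- c(n_clean, n_met_cys, n_tm, n_short, n_long, n_ragged)
  assert_that(all(counts >= 0) && sum(counts) >= 1,
              "need at least one peptide per protein")
  assert_that(clean_length[1] >= 3 && clean_length[1] <= clean_length[2],
              "impossible `clean_length` range")
  withr::with_seed(seed, {
    seqs <- character(0); tm <- list(); peps <- list()
    for (i in seq_len(n_proteins)) {
      acc <- sprintf("SEQ%04d", i)
      units <- character(0); roles <- character(0)
      add <- function(u, r) {
        units <<- c(units, u); roles <<- c(roles, r)
      }
      for (j in seq_len(n_clean)) {
        add(.random_peptide(clean_length[1], clean_length[2]), "clean")
      }
      for (j in seq_len(n_met_cys)) {
        u <- .random_peptide(clean_length[1], clean_length[2])
        k <- sample(seq_len(nchar(u) - 1), 1)
        substr(u, k, k) <- sample(c("M", "C"), 1)
        add(u, "met_cys")
      }
      for (j in seq_len(n_tm)) {
        add(.random_peptide(clean_length[1], clean_length[2]), "tm")
      }
      for (j in seq_len(n_short)) add(.random_peptide(3, 5), "short")
      for (j in seq_len(n_long)) add(.random_peptide(18, 24), "long")
      # ragged blocks go last: a unit followed by a lone K/R creates the
      # ragged K|K junction without contaminating the flanks of clean units
      for (j in seq_len(n_ragged)) {
        add(.random_peptide(clean_length[1], clean_length[2]), "ragged")
        add(sample(c("K", "R"), 1), "ragged_spacer")
      }
      ends <- cumsum(nchar(units))
      starts <- ends - nchar(units) + 1
      tm_rows <- which(roles == "tm")
      if (length(tm_rows) > 0) {
        tm[[acc]] <- tibble(accession = acc, start = starts[tm_rows],
                            end = ends[tm_rows])
      }
      seqs[[acc]] <- paste(units, collapse = "")
      peps[[acc]] <- tibble(accession = acc, peptide = units,
                            start = starts, end = ends, role = roles)
    }
    list(sequences = seqs, tm_intervals = bind_rows(tm),
         peptides = bind_rows(peps))
  })
}
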