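#' Configuration for the synthetic linked-cohort generator
#'
#' Bundles the generative parameters for [simulate_cohort()]: cohort size
#' and composition, and the observation model linking each patient's true
#' etiology to what the administrative extract records. Defaults mirror a
#' single-centre hepatology-clinic validation cohort: 442 patients seen
#' May-August 2013, 53% with cirrhosis, and a gold-standard etiology mix
#' of 45% HCV, 9% HBV, 10% alcohol-related, 26% NAFLD/cryptogenic, 9%
#' autoimmune and 1% hemochromatosis. Observation events (a qualifying
#' positive lab recorded, a matching code recorded) are independent given
#' the true label.
#'
#' @param n Cohort size (default 442).
#' @param p_cirrhosis Probability a patient has cirrhosis (default
#'   233/442).
#' @param etiology_prevalence Named probability vector over
#'   [etiology_levels()], summing to 1; the true-label distribution when
#'   `stratified = FALSE`.
#' @param stratified Draw true labels from per-stratum prevalence vectors
#'   instead of the overall one (default `FALSE`).
#' @param prevalence_cirrhosis,prevalence_no_cirrhosis Per-stratum
#'   prevalence vectors used when `stratified = TRUE`. Defaults follow the
#'   published per-stratum counts where printed; the two privacy-suppressed
#'   cells (alcohol, hemochromatosis) are filled by allocating the overall
#'   counts proportionally across strata (cirrhosis 36/5 and no-cirrhosis
#'   9/1 of the overall 45/6), which respects every printed bound.
#' @param lab_sensitivity Named vector `c(HCV = , HBV = )`: probability a
#'   true viral-hepatitis case has a qualifying positive lab (HCV RNA /
#'   HBV surface antigen) recorded on or before the index date.
#' @param lab_fpr Named vector `c(HCV = , HBV = )`: probability a
#'   non-case has a spurious qualifying positive lab.
#' @param p_antibody Probability a true HCV case additionally has a
#'   positive HCV antibody record (never used by the classifier).
#' @param code_sensitivity Named vector over `AUTOIMMUNE`,
#'   `HEMOCHROMATOSIS`, `ALCOHOL`: probability a true case of that
#'   etiology has at least one matching diagnosis code recorded strictly
#'   before the index date.
#' @param code_background Same shape: probability a non-case carries at
#'   least one matching code.
#' @param filler_lab_rate Probability a patient gets a negative filler
#'   serology record.
#' @param filler_code_rate Probability a patient gets a non-matching
#'   filler diagnosis code (common chronic-disease codes).
#' @param index_start,index_end Window the index (clinic-visit) dates are
#'   drawn from, uniformly.
#' @param lookback_years How far before the index date diagnosis-code
#'   service dates may fall; codes dated before 2002 are emitted as ICD-9,
#'   later ones as ICD-10, matching when each revision was in use.
#' @param seed Integer RNG seed; same config and seed give bit-identical
#'   output. `NULL` uses the current RNG state.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n = 442,
                       p_cirrhosis = 233 / 442,
                       etiology_prevalence = c(
                         HCV = 0.45, HBV = 0.09, ALCOHOL = 0.10,
                         NAFLD_CRYPTOGENIC = 0.26, AUTOIMMUNE = 0.09,
                         HEMOCHROMATOSIS = 0.01),
                       stratified = FALSE,
                       prevalence_cirrhosis = c(
                         HCV = 115, HBV = 13, ALCOHOL = 36,
                         NAFLD_CRYPTOGENIC = 40, AUTOIMMUNE = 24,
                         HEMOCHROMATOSIS = 5) / 233,
                       prevalence_no_cirrhosis = c(
                         HCV = 84, HBV = 24, ALCOHOL = 9,
                         NAFLD_CRYPTOGENIC = 75, AUTOIMMUNE = 16,
                         HEMOCHROMATOSIS = 1) / 209,
                       lab_sensitivity = c(HCV = 0.95, HBV = 0.94),
                       lab_fpr = c(HCV = 0.002, HBV = 0.002),
                       p_antibody = 0.98,
                       code_sensitivity = c(AUTOIMMUNE = 0.70,
                                            HEMOCHROMATOSIS = 0.40,
                                            ALCOHOL = 0.85),
                       code_background = c(AUTOIMMUNE = 0.01,
                                           HEMOCHROMATOSIS = 0.005,
                                           ALCOHOL = 0.03),
                       filler_lab_rate = 0.3,
                       filler_code_rate = 0.5,
                       index_start = as.Date("2013-05-01"),
                       index_end = as.Date("2013-08-31"),
                       lookback_years = 25,
                       seed = NULL) {
  cfg <- list(n = n, p_cirrhosis = p_cirrhosis,
              etiology_prevalence = etiology_prevalence,
              stratified = stratified,
              prevalence_cirrhosis = prevalence_cirrhosis,
              prevalence_no_cirrhosis = prevalence_no_cirrhosis,
              lab_sensitivity = lab_sensitivity, lab_fpr = lab_fpr,
              p_antibody = p_antibody,
              code_sensitivity = code_sensitivity,
              code_background = code_background,
              filler_lab_rate = filler_lab_rate,
              filler_code_rate = filler_code_rate,
              index_start = as.Date(index_start),
              index_end = as.Date(index_end),
              lookback_years = lookback_years, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "hepetio_validation_error")
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || is.na(cfg$n) ||
      cfg$n < 0 || cfg$n != round(cfg$n)) {
    stop_cfg("`n` must be a single non-negative integer.")
  }
  probs <- c(p_cirrhosis = cfg$p_cirrhosis, cfg$lab_sensitivity,
             cfg$lab_fpr, p_antibody = cfg$p_antibody,
             cfg$code_sensitivity, cfg$code_background,
             filler_lab_rate = cfg$filler_lab_rate,
             filler_code_rate = cfg$filler_code_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_cfg("All probabilities must lie in [0, 1].")
  }
  for (nm in c("etiology_prevalence", "prevalence_cirrhosis",
               "prevalence_no_cirrhosis")) {
    p <- cfg[[nm]]
    if (!setequal(names(p), etiology_levels())) {
      stop_cfg(paste0("`", nm, "` must be named by the six etiologies."))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_cfg(paste0("`", nm, "` must be non-negative and sum to 1."))
    }
  }
  for (nm in c("lab_sensitivity", "lab_fpr")) {
    if (!all(c("HCV", "HBV") %in% names(cfg[[nm]]))) {
      stop_cfg(paste0("`", nm, "` must be named with HCV and HBV."))
    }
  }
  for (nm in c("code_sensitivity", "code_background")) {
    if (!all(c("AUTOIMMUNE", "HEMOCHROMATOSIS", "ALCOHOL") %in%
             names(cfg[[nm]]))) {
      stop_cfg(paste0("`", nm,
                      "` must be named with the three code lists."))
    }
  }
  if (cfg$index_end < cfg$index_start) {
    stop_cfg("`index_end` must not precede `index_start`.")
  }
  invisible(cfg)
}

filler_code_pool <- list(
  ICD9 = c("4019", "25000", "53081", "496", "5849", "V700"),
  ICD10 = c("I10", "E119", "K219", "J449", "N179", "Z511"))

draw_codes <- function(ids, index_dates, patterns, lookback_years) {
  k <- length(ids)
  if (k == 0) return(empty_diagnoses())
  max_off <- max(1L, round(lookback_years * 365.25))
  off <- sample.int(max_off, k, replace = TRUE)
  service_on <- index_dates - off
  system <- ifelse(as.integer(format(service_on, "%Y")) < 2002,
                   "ICD9", "ICD10")
  # a custom list may cover only one system; fall back to the one it has
  for (sys in c("ICD9", "ICD10")) {
    if (is.null(patterns[[sys]]) || length(patterns[[sys]]) == 0) {
      system[system == sys] <- setdiff(c("ICD9", "ICD10"), sys)
    }
  }
  code <- character(k)
  for (sys in unique(system)) {
    i <- which(system == sys)
    code[i] <- sample(patterns[[sys]], length(i), replace = TRUE)
  }
  tibble::tibble(patient_id = ids, system = system, code = code,
                 service_on = service_on,
                 source = sample(source_db_levels(), k, replace = TRUE))
}

generate_cohort_impl <- function(cfg, code_lists) {
  n <- cfg$n
  lev <- etiology_levels()
  if (n == 0) {
    cohort <- cld_cohort(tibble::tibble(
      patient_id = character(), index_date = as.Date(character()),
      cirrhosis = logical(), gold_label = character()),
      provenance = "simulation (n = 0)")
    return(list(cohort = cohort,
                truth = tibble::tibble(patient_id = character(),
                                       true_label = character(),
                                       cirrhosis = logical()),
                config = cfg))
  }
  ids <- sprintf("P%05d", seq_len(n))
  cirrhosis <- runif(n) < cfg$p_cirrhosis
  labels <- character(n)
  if (cfg$stratified) {
    for (grp in list(list(cirrhosis, cfg$prevalence_cirrhosis),
                     list(!cirrhosis, cfg$prevalence_no_cirrhosis))) {
      k <- sum(grp[[1]])
      if (k > 0) {
        labels[grp[[1]]] <- sample(lev, k, replace = TRUE,
                                   prob = grp[[2]][lev])
      }
    }
  } else {
    labels <- sample(lev, n, replace = TRUE,
                     prob = cfg$etiology_prevalence[lev])
  }
  span <- as.integer(cfg$index_end - cfg$index_start)
  index_date <- cfg$index_start +
    sample.int(span + 1L, n, replace = TRUE) - 1L

  lab_rows <- list()
  lab_window <- 5L * 365L  # serology drawn within five years up to index
  add_labs <- function(which_pat, test, result) {
    k <- sum(which_pat)
    if (k == 0) return()
    off <- sample.int(lab_window + 1L, k, replace = TRUE) - 1L
    lab_rows[[length(lab_rows) + 1]] <<- tibble::tibble(
      patient_id = ids[which_pat], test = test, result = result,
      collected_on = index_date[which_pat] - off)
  }
  is_hcv <- labels == "HCV"
  is_hbv <- labels == "HBV"
  add_labs(runif(n) < ifelse(is_hcv, cfg$lab_sensitivity[["HCV"]],
                             cfg$lab_fpr[["HCV"]]),
           "HCV_RNA", "POSITIVE")
  add_labs(is_hcv & runif(n) < cfg$p_antibody, "HCV_ANTIBODY", "POSITIVE")
  add_labs(runif(n) < ifelse(is_hbv, cfg$lab_sensitivity[["HBV"]],
                             cfg$lab_fpr[["HBV"]]),
           "HBV_SURFACE_ANTIGEN", "POSITIVE")
  add_labs(!is_hcv & runif(n) < cfg$filler_lab_rate,
           "HCV_ANTIBODY", "NEGATIVE")
  labs <- if (length(lab_rows) > 0) dplyr::bind_rows(lab_rows)
          else empty_labs()

  dx_rows <- list()
  for (ln in c("AUTOIMMUNE", "HEMOCHROMATOSIS", "ALCOHOL")) {
    is_case <- labels == ln
    hit <- runif(n) < ifelse(is_case, cfg$code_sensitivity[[ln]],
                             cfg$code_background[[ln]])
    pats <- split(code_lists$pattern[code_lists$list == ln],
                  code_lists$system[code_lists$list == ln])
    dx_rows[[ln]] <- draw_codes(ids[hit], index_date[hit], pats,
                                cfg$lookback_years)
  }
  filler <- runif(n) < cfg$filler_code_rate
  dx_rows[["filler"]] <- draw_codes(ids[filler], index_date[filler],
                                    filler_code_pool, cfg$lookback_years)
  diagnoses <- dplyr::bind_rows(dx_rows)

  patients <- tibble::tibble(patient_id = ids, index_date = index_date,
                             cirrhosis = cirrhosis, gold_label = labels)
  cohort <- cld_cohort(patients, labs, diagnoses,
                       provenance = paste0(
                         "simulation (n = ", n, ", seed = ",
                         cfg$seed %||% "unset", ")"))
  list(cohort = cohort,
       truth = tibble::tibble(patient_id = ids, true_label = labels,
                              cirrhosis = cirrhosis),
       config = cfg)
}

#' Simulate a linked administrative cohort with known truth
#'
#' Generates a cohort, lab table and diagnosis table from the generative
#' model described in [sim_config()]: each patient draws a cirrhosis
#' status and a true etiology; true viral-hepatitis cases have qualifying
#' positive serology recorded with the configured sensitivity (non-cases
#' with the configured false-positive rate); true autoimmune,
#' hemochromatosis and alcohol cases receive at least one matching
#' diagnosis code (drawn uniformly from the corresponding list, dated
#' strictly before the index date) with the configured code sensitivity
#' (non-cases with the background rate); negative serology and
#' non-matching filler codes are sprinkled in. The true label is copied
#' into the cohort's `gold_label`, so the simulated cohort feeds directly
#' into [classify_cohort()] and [validate_etiology()].
#'
#' @param config A [sim_config()].
#' @param code_lists Code lists the generator draws matching codes from;
#'   defaults to [default_code_lists()]. Using the same lists for
#'   generation and classification guarantees generated case codes are
#'   matchable.
#' @return A list: `cohort` (a [cld_cohort()] with `gold_label` set),
#'   `truth` (tibble `patient_id`, `true_label`, `cirrhosis`) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            code_lists = default_code_lists()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed,
                     generate_cohort_impl(config, code_lists))
  } else {
    generate_cohort_impl(config, code_lists)
  }
}

#' Expected true-label by assigned-label probability matrix
#'
#' The analytic counterpart of [simulate_cohort()] composed with the
#' hierarchy: because the observation events (qualifying HCV evidence,
#' qualifying HBV evidence, and one match indicator per code list) are
#' independent given the true label, the probability that a patient with
#' true label `t` is assigned label `a` follows in closed form from the
#' first-satisfied-rule structure. Rows sum to 1. With perfect observation
#' (sensitivities 1, false-positive and background rates 0) the matrix is
#' the identity.
#'
#' @param config A [sim_config()].
#' @return A 6x6 numeric matrix, rows true labels, columns assigned
#'   labels, in [etiology_levels()] order.
#' @export
expected_classification_matrix <- function(config = sim_config()) {
  validate_sim_config(config)
  lev <- etiology_levels()
  m <- matrix(0, 6, 6, dimnames = list(true = lev, assigned = lev))
  for (t in lev) {
    pH <- if (t == "HCV") config$lab_sensitivity[["HCV"]]
          else config$lab_fpr[["HCV"]]
    pB <- if (t == "HBV") config$lab_sensitivity[["HBV"]]
          else config$lab_fpr[["HBV"]]
    pcode <- function(list_name) {
      if (t == list_name) config$code_sensitivity[[list_name]]
      else config$code_background[[list_name]]
    }
    pA <- pcode("AUTOIMMUNE")
    pM <- pcode("HEMOCHROMATOSIS")
    pL <- pcode("ALCOHOL")
    m[t, "HCV"] <- pH
    m[t, "HBV"] <- (1 - pH) * pB
    m[t, "AUTOIMMUNE"] <- (1 - pH) * (1 - pB) * pA
    m[t, "HEMOCHROMATOSIS"] <- (1 - pH) * (1 - pB) * (1 - pA) * pM
    m[t, "ALCOHOL"] <- (1 - pH) * (1 - pB) * (1 - pA) * (1 - pM) * pL
    m[t, "NAFLD_CRYPTOGENIC"] <-
      (1 - pH) * (1 - pB) * (1 - pA) * (1 - pM) * (1 - pL)
  }
  m
}

#' Write a simulated cohort (and its truth table) to disk
#'
#' Convenience wrapper writing `cohort.csv`, `labs.csv`, `diagnoses.csv`
#' (via [write_cohort()]) plus `truth.csv` into `dir`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the four file paths.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_cohort(sim$cohort, dir)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(sim$truth, truth_path, progress = FALSE)
  invisible(c(paths, truth_path))
}
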