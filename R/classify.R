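#' Positive chronic-hepatitis-C serology on or before an index date
#'
#' A patient counts as serologically HCV-positive only on a positive HCV
#' RNA or HCV genotype result; a positive HCV antibody in isolation is not
#' diagnostic (it persists after viral clearance) and never contributes.
#' Lab results collected on the index date itself are eligible: same-day
#' serology at the clinic visit is informative, unlike coded diagnoses
#' which are restricted to strictly before the visit.
#'
#' @param labs One patient's lab results (`test`, `result`, `collected_on`).
#' @param index_date The patient's index date.
#' @return A list with `positive` (logical) and `evidence` (the qualifying
#'   lab rows).
#' @export
has_positive_hcv <- function(labs, index_date) {
  positive_lab(labs, c("HCV_RNA", "HCV_GENOTYPE"), index_date)
}

#' Positive chronic-hepatitis-B serology on or before an index date
#'
#' Requires a positive HBV DNA or HBV surface antigen result; indeterminate
#' results count as non-positive.
#'
#' @inheritParams has_positive_hcv
#' @return A list with `positive` and `evidence`, as [has_positive_hcv()].
#' @export
has_positive_hbv <- function(labs, index_date) {
  positive_lab(labs, c("HBV_DNA", "HBV_SURFACE_ANTIGEN"), index_date)
}

positive_lab <- function(labs, tests, index_date) {
  if (is.null(labs) || nrow(labs) == 0) {
    return(list(positive = FALSE, evidence = empty_labs()[, -1]))
  }
  keep <- labs$test %in% tests & labs$result == "POSITIVE" &
    labs$collected_on <= index_date
  list(positive = any(keep), evidence = labs[keep, , drop = FALSE])
}

#' The default hierarchy of assignment steps
#'
#' The order encodes clinical plausibility: viral hepatitis is established
#' from serology first (HCV, then HBV); failing that, coded diagnoses are
#' searched for autoimmune liver disease and hereditary hemochromatosis,
#' then for alcohol-related conditions; a patient matching nothing is
#' assigned NAFLD/cryptogenic. Autoimmune is evaluated before
#' hemochromatosis within the combined code step; when both code sets
#' match, an ambiguity flag records it. Alternative orders can be passed to
#' [classify_patient()] for sensitivity analyses.
#'
#' @return Named character vector mapping step names to output labels.
#' @export
etiology_hierarchy <- function() {
  c(HCV_LAB = "HCV",
    HBV_LAB = "HBV",
    AUTOIMMUNE_CODE = "AUTOIMMUNE",
    HEMOCHROMATOSIS_CODE = "HEMOCHROMATOSIS",
    ALCOHOL_CODE = "ALCOHOL",
    DEFAULT_NAFLD = "NAFLD_CRYPTOGENIC")
}

step_list_name <- c(AUTOIMMUNE_CODE = "AUTOIMMUNE",
                    HEMOCHROMATOSIS_CODE = "HEMOCHROMATOSIS",
                    ALCOHOL_CODE = "ALCOHOL")

#' Assign an etiology to a single patient
#'
#' Runs the hierarchy over one patient's lab results and diagnosis records:
#' the first satisfied rule determines the label, and only that rule's
#' evidence is returned. The hierarchy always terminates — a patient with
#' no qualifying serology and no matching codes is NAFLD/cryptogenic, with
#' empty evidence.
#'
#' @param labs One patient's lab results (may be empty or `NULL`).
#' @param diagnoses One patient's diagnosis records, codes normalized.
#' @param index_date The patient's index (clinic-visit) date.
#' @param code_lists Code-list tibble; defaults to [default_code_lists()].
#' @param hierarchy Ordered named vector of steps to labels; the
#'   `DEFAULT_NAFLD` fallthrough is always appended if missing.
#' @return A list: `label`, `step`, `evidence` (tibble of the triggering
#'   lab or diagnosis rows; empty for the default step), and
#'   `ambiguity_flags` (character; notes such as both autoimmune and
#'   hemochromatosis codes being present at the code-evaluation step).
#' @export
classify_patient <- function(labs, diagnoses, index_date,
                             code_lists = default_code_lists(),
                             hierarchy = etiology_hierarchy()) {
  if (length(index_date) != 1 || is.na(index_date)) {
    abort("`index_date` must be a single non-missing date.",
          class = "hepetio_validation_error")
  }
  steps <- hierarchy[names(hierarchy) != "DEFAULT_NAFLD"]
  code_evidence <- list()
  for (step in names(steps)) {
    ev <- switch(step,
      HCV_LAB = has_positive_hcv(labs, index_date)$evidence,
      HBV_LAB = has_positive_hbv(labs, index_date)$evidence,
      {
        ln <- step_list_name[[step]]
        any_match(diagnoses, code_lists, ln, index_date)
      })
    if (step %in% names(step_list_name)) code_evidence[[step]] <- ev
    if (nrow(ev) > 0) {
      flags <- character()
      both <- c("AUTOIMMUNE_CODE", "HEMOCHROMATOSIS_CODE")
      if (step %in% both) {
        other <- setdiff(both, step)
        other_ev <- code_evidence[[other]]
        if (is.null(other_ev)) {
          other_ev <- any_match(diagnoses, code_lists,
                                step_list_name[[other]], index_date)
        }
        if (nrow(other_ev) > 0) {
          flags <- "autoimmune_and_hemochromatosis_codes"
        }
      }
      return(list(label = unname(steps[[step]]), step = step,
                  evidence = ev, ambiguity_flags = flags))
    }
  }
  list(label = "NAFLD_CRYPTOGENIC", step = "DEFAULT_NAFLD",
       evidence = empty_diagnoses()[, -1], ambiguity_flags = character())
}

#' Classify every patient in a cohort
#'
#' Applies [classify_patient()] to each row of a [cld_cohort()], in cohort
#' order. The classification is a pure function of the cohort and code
#' lists: repeat calls are identical.
#'
#' @param cohort A `cld_cohort`.
#' @param code_lists Code-list tibble; defaults to [default_code_lists()].
#' @param hierarchy Step order, as in [classify_patient()].
#' @return A tibble with one row per patient: `patient_id`, `label`,
#'   `step`, `evidence_count`, `ambiguity_flags` (comma-separated, `""` if
#'   none) and `evidence` (list-column of the triggering rows).
#' @export
classify_cohort <- function(cohort, code_lists = default_code_lists(),
                            hierarchy = etiology_hierarchy()) {
  n <- nrow(cohort)
  if (n == 0) {
    return(tibble::tibble(patient_id = character(), label = character(),
                          step = character(), evidence_count = integer(),
                          ambiguity_flags = character(), evidence = list()))
  }
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- tryCatch(
      classify_patient(cohort$labs[[i]], cohort$diagnoses[[i]],
                       cohort$index_date[[i]], code_lists, hierarchy),
      error = function(e) {
        abort(paste0("Patient '", cohort$patient_id[[i]], "': ",
                     conditionMessage(e)),
              class = "hepetio_validation_error")
      })
  }
  tibble::tibble(
    patient_id = cohort$patient_id,
    label = vapply(res, `[[`, "", "label"),
    step = vapply(res, `[[`, "", "step"),
    evidence_count = vapply(res, function(r) nrow(r$evidence), 0L),
    ambiguity_flags = vapply(res, function(r)
      paste(r$ambiguity_flags, collapse = ","), ""),
    evidence = lapply(res, `[[`, "evidence"))
}

#' Distribution of assigned etiologies
#'
#' Bar chart of assignment counts by label, optionally filled by the
#' hierarchy step that produced each assignment — useful for spotting a
#' cohort where most labels come from the default fallthrough.
#'
#' @param assignments Output of [classify_cohort()].
#' @param by_step Fill bars by assignment step (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_etiology_distribution <- function(assignments, by_step = TRUE) {
  df <- dplyr::mutate(assignments,
                      label = factor(.data$label, etiology_levels()))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label)) +
    ggplot2::labs(x = NULL, y = "Patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (by_step) {
    p + ggplot2::geom_bar(ggplot2::aes(fill = .data$step)) +
      ggplot2::scale_fill_brewer(palette = "Set2", name = "Step")
  } else {
    p + ggplot2::geom_bar(fill = "grey30")
  }
}
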