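empty_labs <- function() {
  tibble::tibble(patient_id = character(), test = character(),
                 result = character(), collected_on = as.Date(character()))
}

empty_diagnoses <- function() {
  tibble::tibble(patient_id = character(), system = character(),
                 code = character(), service_on = as.Date(character()),
                 source = character())
}

#' Assemble a linked cohort from its three component tables
#'
#' A cohort is stored as a nested tibble: one row per patient with the
#' patient's lab results and diagnosis records as list-columns, so the
#' whole object pipes through [classify_cohort()] and
#' [validate_etiology()]. Lab and diagnosis rows are attached to patients
#' by `patient_id`; rows referencing a patient absent from `patients` are
#' rejected. Diagnosis codes are normalized on construction. Diagnosis rows
#' dated after a patient's index date are retained here and filtered at
#' classification time, so one cohort supports multiple index-date
#' analyses.
#'
#' @param patients Data frame with columns `patient_id`, `index_date`
#'   (Date), `cirrhosis` (logical), and optionally `gold_label` (one of
#'   [etiology_levels()] or `NA`).
#' @param labs Data frame with columns `patient_id`, `test`, `result`,
#'   `collected_on` (Date). May be empty.
#' @param diagnoses Data frame with columns `patient_id`, `system`, `code`,
#'   `service_on` (Date), `source`. May be empty.
#' @param provenance Free-text description of where the cohort came from
#'   (source files or a simulation seed).
#' @return A `cld_cohort`: a tibble with columns `patient_id`,
#'   `index_date`, `cirrhosis`, `gold_label`, `labs`, `diagnoses`.
#' @export
cld_cohort <- function(patients, labs = empty_labs(),
                       diagnoses = empty_diagnoses(),
                       provenance = "in-memory") {
  patients <- tibble::as_tibble(patients)
  labs <- tibble::as_tibble(labs)
  diagnoses <- tibble::as_tibble(diagnoses)
  if (!"gold_label" %in% names(patients)) {
    patients$gold_label <- NA_character_
  }
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate patient_id in cohort: ",
                 paste(unique(dup), collapse = ", ")),
          class = "hepetio_validation_error")
  }
  orphan_labs <- setdiff(labs$patient_id, patients$patient_id)
  orphan_dx <- setdiff(diagnoses$patient_id, patients$patient_id)
  if (length(orphan_labs) > 0 || length(orphan_dx) > 0) {
    abort(paste0("Records reference patient_ids absent from the cohort: ",
                 paste(unique(c(orphan_labs, orphan_dx)), collapse = ", ")),
          class = "hepetio_validation_error")
  }
  bad_gold <- !is.na(patients$gold_label) &
    !patients$gold_label %in% etiology_levels()
  if (any(bad_gold)) {
    abort(paste0("Invalid gold_label for patient(s): ",
                 paste(patients$patient_id[bad_gold], collapse = ", ")),
          class = "hepetio_validation_error")
  }
  if (nrow(diagnoses) > 0) {
    diagnoses$code <- normalize_code(diagnoses$code)
  }
  out <- patients[, c("patient_id", "index_date", "cirrhosis", "gold_label")]
  out <- dplyr::nest_join(out, labs, by = "patient_id", name = "labs")
  out <- dplyr::nest_join(out, diagnoses, by = "patient_id",
                          name = "diagnoses")
  attr(out, "provenance") <- provenance
  class(out) <- c("cld_cohort", class(out))
  out
}

#' @export
print.cld_cohort <- function(x, ...) {
  n_lab <- sum(vapply(x$labs, nrow, 0L))
  n_dx <- sum(vapply(x$diagnoses, nrow, 0L))
  cat(sprintf(
    "<cld_cohort> %d patients, %d lab results, %d diagnosis records\n",
    nrow(x), n_lab, n_dx))
  cat("provenance:", attr(x, "provenance") %||% "unknown", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_field <- function(x, file, lines, field, parser, allowed = NULL) {
  if (!is.null(allowed)) {
    bad <- !x %in% allowed
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "%s line %d: field '%s' has value '%s' (expected one of %s).",
        file, lines[i], field, x[i], paste(allowed, collapse = ", ")),
        class = "hepetio_parse_error")
    }
    return(x)
  }
  parser(x, file, lines, field)
}

parse_iso_date <- function(x, file, lines, field) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(rep(NA_character_, length(x)))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- !ok | is.na(d)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "%s line %d: field '%s' has value '%s' (expected ISO date YYYY-MM-DD).",
      file, lines[i], field, x[i]),
      class = "hepetio_parse_error")
  }
  d
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(paste0("Input file not found: ", path),
          class = "hepetio_input_error")
  }
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hepetio_parse_error")
  }
  tab
}

#' Read a linked cohort from three delimited text files
#'
#' Reads the three tables that emulate a linked administrative extract
#' (cohort/index dates, viral-serology lab results, coded diagnoses),
#' validates every field, normalizes diagnosis codes, and assembles them
#' into a [cld_cohort()]. All dates must be ISO-8601 (`YYYY-MM-DD`).
#' Expected schemas:
#' * `cohort.csv`: `patient_id,index_date,cirrhosis,gold_label` with
#'   `cirrhosis` coded 0/1 and `gold_label` blank or one of
#'   [etiology_levels()].
#' * `labs.csv`: `patient_id,test,result,collected_on` with `test` in
#'   [lab_test_levels()] and `result` in POSITIVE/NEGATIVE/INDETERMINATE.
#' * `diagnoses.csv`: `patient_id,system,code,service_on,source` with
#'   `system` ICD9/ICD10 and `source` DAD/NACRS/OHIP.
#'
#' @param cohort_path,labs_path,diagnoses_path Paths to the three CSVs.
#' @return A `cld_cohort`.
#' @export
read_cohort <- function(cohort_path, labs_path, diagnoses_path) {
  co <- read_table_checked(cohort_path,
                           c("patient_id", "index_date", "cirrhosis"))
  lines <- seq_len(nrow(co)) + 1L
  if (!"gold_label" %in% names(co)) co$gold_label <- NA_character_
  co$gold_label[!is.na(co$gold_label) & co$gold_label == ""] <- NA_character_
  patients <- tibble::tibble(
    patient_id = co$patient_id,
    index_date = parse_iso_date(co$index_date, cohort_path, lines,
                                "index_date"),
    cirrhosis = parse_field(co$cirrhosis, cohort_path, lines, "cirrhosis",
                            NULL, allowed = c("0", "1")) == "1",
    gold_label = {
      gl <- co$gold_label
      bad <- !is.na(gl) & !gl %in% etiology_levels()
      if (any(bad)) {
        i <- which(bad)[1]
        abort(sprintf(
          "%s line %d: field 'gold_label' has value '%s'.",
          cohort_path, lines[i], gl[i]), class = "hepetio_parse_error")
      }
      gl
    })

  lb <- read_table_checked(labs_path,
                           c("patient_id", "test", "result", "collected_on"))
  lines <- seq_len(nrow(lb)) + 1L
  labs <- tibble::tibble(
    patient_id = lb$patient_id,
    test = parse_field(lb$test, labs_path, lines, "test", NULL,
                       allowed = lab_test_levels()),
    result = parse_field(lb$result, labs_path, lines, "result", NULL,
                         allowed = lab_result_levels()),
    collected_on = parse_iso_date(lb$collected_on, labs_path, lines,
                                  "collected_on"))
  orphan <- !labs$patient_id %in% patients$patient_id
  if (any(orphan)) {
    i <- which(orphan)[1]
    abort(sprintf(
      "%s line %d: patient_id '%s' not present in cohort table.",
      labs_path, lines[i], labs$patient_id[i]),
      class = "hepetio_parse_error")
  }

  dx <- read_table_checked(diagnoses_path,
                           c("patient_id", "system", "code", "service_on",
                             "source"))
  lines <- seq_len(nrow(dx)) + 1L
  diagnoses <- tibble::tibble(
    patient_id = dx$patient_id,
    system = parse_field(dx$system, diagnoses_path, lines, "system", NULL,
                         allowed = code_system_levels()),
    code = {
      blank <- is.na(dx$code) | trimws(dx$code) == ""
      if (any(blank)) {
        i <- which(blank)[1]
        abort(sprintf("%s line %d: field 'code' is blank.",
                      diagnoses_path, lines[i]),
              class = "hepetio_parse_error")
      }
      dx$code
    },
    service_on = parse_iso_date(dx$service_on, diagnoses_path, lines,
                                "service_on"),
    source = parse_field(dx$source, diagnoses_path, lines, "source", NULL,
                         allowed = source_db_levels()))
  orphan <- !diagnoses$patient_id %in% patients$patient_id
  if (any(orphan)) {
    i <- which(orphan)[1]
    abort(sprintf(
      "%s line %d: patient_id '%s' not present in cohort table.",
      diagnoses_path, lines[i], diagnoses$patient_id[i]),
      class = "hepetio_parse_error")
  }

  cld_cohort(patients, labs, diagnoses,
             provenance = paste0("files: ", cohort_path, ", ", labs_path,
                                 ", ", diagnoses_path))
}

#' Flatten a cohort back into its three component tables
#'
#' @param cohort A `cld_cohort`.
#' @return A list of tibbles `patients`, `labs`, `diagnoses`.
#' @export
cohort_tables <- function(cohort) {
  patients <- tibble::tibble(patient_id = cohort$patient_id,
                             index_date = cohort$index_date,
                             cirrhosis = cohort$cirrhosis,
                             gold_label = cohort$gold_label)
  bind_part <- function(col, empty) {
    parts <- cohort[[col]][vapply(cohort[[col]], nrow, 0L) > 0]
    if (length(parts) == 0) return(empty)
    out <- dplyr::bind_rows(parts)
    # nest_join drops the join key from the nested tables
    if (!"patient_id" %in% names(out)) {
      out$patient_id <- rep(cohort$patient_id,
                            vapply(cohort[[col]], nrow, 0L))
    }
    out
  }
  list(patients = patients,
       labs = bind_part("labs", empty_labs()),
       diagnoses = bind_part("diagnoses", empty_diagnoses()))
}

#' Write a cohort to the three-file delimited layout
#'
#' Writes `cohort.csv`, `labs.csv` and `diagnoses.csv` into `dir` in the
#' schemas read by [read_cohort()]; a written cohort round-trips exactly.
#'
#' @param cohort A `cld_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- cohort_tables(cohort)
  paths <- file.path(dir, c("cohort.csv", "labs.csv", "diagnoses.csv"))
  pat <- tabs$patients
  pat$cirrhosis <- as.integer(pat$cirrhosis)
  readr::write_csv(pat, paths[1], na = "", progress = FALSE)
  readr::write_csv(
    tabs$labs[, c("patient_id", "test", "result", "collected_on")],
    paths[2], na = "", progress = FALSE)
  readr::write_csv(
    tabs$diagnoses[, c("patient_id", "system", "code", "service_on",
                       "source")],
    paths[3], na = "", progress = FALSE)
  invisible(paths)
}

#' Cohort composition summary
#'
#' Tabulates the cohort overall and stratified by cirrhosis status:
#' stratum sizes (as a percentage of the whole cohort) and, where gold
#' labels are present, per-etiology counts with percentages of the stratum
#' size. This reproduces the descriptive arithmetic of a validation-study
#' demographics table (e.g. percent with cirrhosis, percent HCV overall
#' and within the cirrhotic stratum).
#'
#' @param cohort A `cld_cohort` (or any data frame with `cirrhosis` and
#'   optionally `gold_label` columns).
#' @param digits Decimal places for percentages (default 0, matching how
#'   such tables are usually printed).
#' @return A tibble with columns `stratum`, `etiology` (`NA` for the
#'   stratum-size rows), `n`, `pct`.
#' @export
summarize_cohort <- function(cohort, digits = 0) {
  df <- tibble::as_tibble(cohort)
  n_total <- nrow(df)
  strata <- list(OVERALL = rep(TRUE, n_total),
                 CIRRHOSIS = df$cirrhosis,
                 NO_CIRRHOSIS = !df$cirrhosis)
  rows <- purrr::imap(strata, function(keep, name) {
    sub <- df[keep, , drop = FALSE]
    size <- tibble::tibble(stratum = name, etiology = NA_character_,
                           n = nrow(sub),
                           pct = round(100 * nrow(sub) / n_total, digits))
    if (all(is.na(sub$gold_label))) return(size)
    et <- sub |>
      dplyr::filter(!is.na(.data$gold_label)) |>
      dplyr::count(etiology = .data$gold_label) |>
      dplyr::mutate(stratum = name,
                    pct = round(100 * .data$n / nrow(sub), digits))
    dplyr::bind_rows(size, et[, c("stratum", "etiology", "n", "pct")])
  })
  dplyr::bind_rows(rows)
}
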