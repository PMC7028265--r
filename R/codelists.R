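#' Normalize an ICD-9 or ICD-10 diagnosis code
#'
#' Administrative extracts and published code lists mix dotted ("K74.3",
#' "571.42") and undotted ("K700") code styles. All matching in this package
#' happens on a normalized form: upper-case, with dots and whitespace
#' removed. Normalization is idempotent.
#'
#' @param raw Character vector of raw codes. Must be non-blank after
#'   trimming.
#' @param system Code system, `"ICD9"` or `"ICD10"`. Both systems share the
#'   same normalization; the argument documents intent and is validated.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code("K74.3", "ICD10")
#' normalize_code("571.42", "ICD9")
#' @export
normalize_code <- function(raw, system = c("ICD9", "ICD10")) {
  system <- match.arg(system)
  if (!is.character(raw) || length(raw) == 0) {
    abort("`raw` must be a non-empty character vector.",
          class = "hepetio_validation_error")
  }
  out <- toupper(gsub("[.[:space:]]", "", raw))
  if (any(is.na(out) | out == "")) {
    bad <- which(is.na(out) | out == "")
    abort(paste0("Blank diagnosis code at position ",
                 paste(bad, collapse = ", "), "."),
          class = "hepetio_validation_error")
  }
  out
}

#' Does a normalized code match a code pattern?
#'
#' Matching is by prefix on normalized strings: pattern `"303"` (alcohol
#' dependence, an ICD-9 three-digit category) matches any of its subcodes
#' such as `"30390"`, while `"3050"` does not match `"30510"` (tobacco use
#' disorder). Prefix semantics are needed because the published lists mix
#' category-level codes with fully specific five-character codes, and
#' administrative records usually carry the fuller form.
#'
#' @param code Character vector of normalized codes.
#' @param pattern A single normalized pattern.
#' @param code_system Code system of `code` (vectorized or scalar).
#' @param pattern_system Code system of `pattern`. A system mismatch is not
#'   an error; it simply never matches.
#' @return Logical vector, `TRUE` where `pattern` is a leading substring of
#'   `code` and the systems agree.
#' @export
code_matches <- function(code, pattern, code_system = "ICD10",
                         pattern_system = code_system) {
  startsWith(code, pattern) & (code_system == pattern_system)
}

# Table of built-in diagnosis-code patterns: one row per (list, system,
# pattern). The alcohol list deliberately keeps both the category-level and
# the more specific entries (e.g. ICD-9 291 and 291.0) exactly as published;
# under prefix matching the category code subsumes the specific one.
default_pattern_table <- function() {
  row <- function(list, system, codes, description) {
    tibble::tibble(list = list, system = system,
                   pattern = normalize_code(codes, system),
                   description = description)
  }
  dplyr::bind_rows(
    # Autoimmune liver disease: PBC, PSC, AIH
    row("AUTOIMMUNE", "ICD9", "571.6",
        "Primary biliary cholangitis or biliary cirrhosis"),
    row("AUTOIMMUNE", "ICD9", "576.1", "Primary sclerosing cholangitis"),
    row("AUTOIMMUNE", "ICD9", "571.42", "Autoimmune hepatitis"),
    row("AUTOIMMUNE", "ICD10", "K74.3",
        "Primary biliary cholangitis or biliary cirrhosis"),
    row("AUTOIMMUNE", "ICD10", "K83.0", "Primary sclerosing cholangitis"),
    row("AUTOIMMUNE", "ICD10", "K75.4", "Autoimmune hepatitis"),
    row("HEMOCHROMATOSIS", "ICD9", "275.0", "Hereditary hemochromatosis"),
    row("HEMOCHROMATOSIS", "ICD10", "E83.10", "Hereditary hemochromatosis"),
    row("ALCOHOL", "ICD9", "305.0",
        "Acute intoxication / harmful alcohol use"),
    row("ALCOHOL", "ICD9", "303", "Alcohol dependence"),
    row("ALCOHOL", "ICD9", "291.0", "Alcohol withdrawal"),
    row("ALCOHOL", "ICD9", "291", "Other alcohol-related psychoses"),
    row("ALCOHOL", "ICD9", "571.0", "Alcoholic fatty liver"),
    row("ALCOHOL", "ICD9", "571.1", "Alcoholic hepatitis"),
    row("ALCOHOL", "ICD9", "571.2",
        "Alcoholic fibrosis, sclerosis or cirrhosis of liver"),
    row("ALCOHOL", "ICD9", "571.3", "Alcoholic liver disease, unspecified"),
    row("ALCOHOL", "ICD9", "535.3", "Alcoholic gastritis"),
    row("ALCOHOL", "ICD9", "357.5", "Alcoholic polyneuropathy"),
    row("ALCOHOL", "ICD9", "425.5", "Alcoholic cardiomyopathy"),
    row("ALCOHOL", "ICD9", c("980.0", "980.9"), "Toxic effect of alcohol"),
    row("ALCOHOL", "ICD9", "790.3", "Finding of alcohol in blood"),
    row("ALCOHOL", "ICD9", "760.71",
        "Maternal care for damage to fetus from alcohol"),
    row("ALCOHOL", "ICD10", "F100", "Acute intoxication"),
    row("ALCOHOL", "ICD10", "F101", "Harmful alcohol use"),
    row("ALCOHOL", "ICD10", "F102", "Alcohol dependence"),
    row("ALCOHOL", "ICD10", c("F103", "F104"), "Alcohol withdrawal"),
    row("ALCOHOL", "ICD10", paste0("F10", 5:9),
        "Other alcohol-related psychoses"),
    row("ALCOHOL", "ICD10", c("X45", "Y15", "X65"),
        "Accidental or intentional poisoning by alcohol"),
    row("ALCOHOL", "ICD10", "K700", "Alcoholic fatty liver"),
    row("ALCOHOL", "ICD10", "K701", "Alcoholic hepatitis"),
    row("ALCOHOL", "ICD10", "K702",
        "Alcoholic fibrosis and sclerosis of liver"),
    row("ALCOHOL", "ICD10", "K703", "Alcoholic cirrhosis"),
    row("ALCOHOL", "ICD10", "K704", "Alcoholic hepatic failure"),
    row("ALCOHOL", "ICD10", "K709", "Alcoholic liver disease, unspecified"),
    row("ALCOHOL", "ICD10", "K292", "Alcoholic gastritis"),
    row("ALCOHOL", "ICD10", "G312",
        "Degeneration of nervous system due to alcohol"),
    row("ALCOHOL", "ICD10", "G621", "Alcoholic polyneuropathy"),
    row("ALCOHOL", "ICD10", "G721", "Alcoholic myopathy"),
    row("ALCOHOL", "ICD10", "I426", "Alcoholic cardiomyopathy"),
    row("ALCOHOL", "ICD10", c("K852", "K860"),
        "Alcohol-induced pancreatitis"),
    row("ALCOHOL", "ICD10", "E244",
        "Alcohol-induced pseudo-Cushing's syndrome"),
    row("ALCOHOL", "ICD10", c("T510", "T519"), "Toxic effect of alcohol"),
    row("ALCOHOL", "ICD10", "R780", "Finding of alcohol in blood"),
    row("ALCOHOL", "ICD10", c("O354", "Q860", "P043"),
        "Maternal care for damage to fetus from alcohol")
  )
}

#' Built-in diagnosis-code lists for etiology assignment
#'
#' Returns the three named code lists used by the code-evaluation steps of
#' the hierarchy: `AUTOIMMUNE` (autoimmune hepatitis, primary biliary
#' cholangitis, primary sclerosing cholangitis), `HEMOCHROMATOSIS`
#' (hereditary hemochromatosis), and `ALCOHOL` (alcohol-related conditions
#' spanning liver disease, dependence/withdrawal, poisoning and
#' alcohol-attributed organ damage). Patterns are stored normalized (no
#' dots, upper-case) and deduplicated: where a source table repeats a code
#' across clinical rows (ICD-9 305.0, 571.2) it appears here once.
#'
#' @return A tibble with columns `list`, `system`, `pattern`, `description`,
#'   one row per unique `(list, system, pattern)`.
#' @seealso [read_code_lists()] to load replacement lists from a config
#'   file, [code_matches()] for the prefix-match semantics.
#' @export
default_code_lists <- function() {
  default_pattern_table() |>
    dplyr::distinct(.data$list, .data$system, .data$pattern,
                    .keep_all = TRUE)
}

#' Load diagnosis-code lists from a YAML or JSON config file
#'
#' The file maps list names to per-system code vectors, e.g.
#' ```yaml
#' AUTOIMMUNE:
#'   icd9: ["571.6", "576.1", "571.42"]
#'   icd10: ["K74.3", "K83.0", "K75.4"]
#' ```
#' Codes may be dotted or undotted; they are normalized on load. This lets
#' the same classifier run with jurisdiction-specific lists.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A tibble in the same shape as [default_code_lists()].
#' @export
read_code_lists <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Code-list config not found: ", path),
          class = "hepetio_input_error")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    abort("Code-list config must map list names to {icd9, icd10} blocks.",
          class = "hepetio_validation_error")
  }
  rows <- purrr::imap(raw, function(block, name) {
    sys_key <- c(icd9 = "ICD9", icd10 = "ICD10")
    purrr::imap(block, function(codes, key) {
      key <- tolower(key)
      if (!key %in% names(sys_key)) {
        abort(paste0("Unknown code system '", key, "' in list '", name,
                     "' (expected icd9/icd10)."),
              class = "hepetio_validation_error")
      }
      codes <- as.character(unlist(codes))
      tibble::tibble(list = toupper(name), system = sys_key[[key]],
                     pattern = normalize_code(codes, sys_key[[key]]),
                     description = NA_character_)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$list, .data$system, .data$pattern,
                    .keep_all = TRUE)
}

#' Diagnosis records matching a code list before an index date
#'
#' Returns exactly the diagnosis records whose service date falls strictly
#' before `index_date` and whose normalized code prefix-matches at least one
#' pattern of the named list in the record's code system. The strict window
#' reflects that coded diagnoses are evaluated prior to the clinic visit
#' that anchors each patient. An empty result signals no match.
#'
#' @param diagnoses A data frame of diagnosis records with columns
#'   `code` (normalized), `system`, `service_on` (Date); typically one
#'   patient's records.
#' @param code_lists A code-list tibble ([default_code_lists()] shape).
#' @param list_name Which list to match (`"AUTOIMMUNE"`,
#'   `"HEMOCHROMATOSIS"`, `"ALCOHOL"`, or any name present in `code_lists`).
#' @param index_date The patient's index (clinic-visit) date.
#' @return The matching rows of `diagnoses` (possibly zero rows), in input
#'   order.
#' @export
any_match <- function(diagnoses, code_lists, list_name, index_date) {
  pats <- code_lists[code_lists$list == list_name, , drop = FALSE]
  if (is.null(diagnoses) || nrow(diagnoses) == 0) {
    return(empty_diagnoses()[, -1])
  }
  if (nrow(pats) == 0) {
    return(diagnoses[integer(0), , drop = FALSE])
  }
  in_window <- diagnoses$service_on < index_date
  hit <- rep(FALSE, nrow(diagnoses))
  for (sys in unique(pats$system)) {
    p <- pats$pattern[pats$system == sys]
    idx <- which(in_window & diagnoses$system == sys & !hit)
    for (i in idx) {
      if (any(startsWith(diagnoses$code[i], p))) hit[i] <- TRUE
    }
  }
  diagnoses[hit, , drop = FALSE]
}
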