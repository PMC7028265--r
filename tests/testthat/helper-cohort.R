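# Builders and independent brute-force oracles shared across test files.
# The oracles deliberately re-derive everything from first principles
# (regex prefix matching, explicit rule enumeration, loop-based counting)
# so they share no code with the package implementation.

d <- function(x) as.Date(x)

lab_row <- function(test, result, collected_on, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, test = test, result = result,
                 collected_on = d(collected_on))
}

dx_row <- function(system, code, service_on, source = "DAD",
                   patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, system = system, code = code,
                 service_on = d(service_on), source = source)
}

one_patient_cohort <- function(labs = NULL, diagnoses = NULL,
                               index_date = "2013-06-15",
                               cirrhosis = TRUE, gold_label = NA) {
  patients <- tibble::tibble(patient_id = "P1", index_date = d(index_date),
                             cirrhosis = cirrhosis,
                             gold_label = as.character(gold_label))
  cld_cohort(patients,
             labs %||% hepetio:::empty_labs(),
             diagnoses %||% hepetio:::empty_diagnoses())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent classifier oracle -----------------------------------------

oracle_normalize <- function(x) toupper(gsub("[. ]", "", x))

oracle_table1 <- list(
  AUTOIMMUNE = list(ICD9 = c("5716", "5761", "57142"),
                    ICD10 = c("K743", "K830", "K754")),
  HEMOCHROMATOSIS = list(ICD9 = "2750", ICD10 = "E8310"),
  ALCOHOL = list(
    ICD9 = c("3050", "303", "2910", "291", "5710", "5711", "5712", "5713",
             "5353", "3575", "4255", "9800", "9809", "7903", "76071"),
    ICD10 = c(paste0("F10", 0:9), "X45", "Y15", "X65",
              paste0("K70", c(0:4, 9)), "K292", "G312", "G621", "G721",
              "I426", "K852", "K860", "E244", "T510", "T519", "R780",
              "O354", "Q860", "P043")))

oracle_code_hit <- function(diagnoses, list_name, index_date) {
  if (is.null(diagnoses) || nrow(diagnoses) == 0) return(FALSE)
  pats <- oracle_table1[[list_name]]
  for (i in seq_len(nrow(diagnoses))) {
    if (!(diagnoses$service_on[i] < index_date)) next
    for (p in pats[[diagnoses$system[i]]]) {
      if (grepl(paste0("^", p), diagnoses$code[i])) return(TRUE)
    }
  }
  FALSE
}

oracle_classify <- function(labs, diagnoses, index_date) {
  pos <- function(tests) {
    !is.null(labs) && nrow(labs) > 0 &&
      any(labs$test %in% tests & labs$result == "POSITIVE" &
            labs$collected_on <= index_date)
  }
  rules <- list(
    list("HCV", pos(c("HCV_RNA", "HCV_GENOTYPE"))),
    list("HBV", pos(c("HBV_DNA", "HBV_SURFACE_ANTIGEN"))),
    list("AUTOIMMUNE", oracle_code_hit(diagnoses, "AUTOIMMUNE",
                                       index_date)),
    list("HEMOCHROMATOSIS", oracle_code_hit(diagnoses, "HEMOCHROMATOSIS",
                                            index_date)),
    list("ALCOHOL", oracle_code_hit(diagnoses, "ALCOHOL", index_date)))
  for (r in rules) if (r[[2]]) return(r[[1]])
  "NAFLD_CRYPTOGENIC"
}

# --- independent accuracy oracles ------------------------------------------

oracle_confusion <- function(pred, gold, target) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == target && gold[i] == target) tp <- tp + 1
    else if (pred[i] == target) fp <- fp + 1
    else if (gold[i] == target) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# --- random-record generator for property tests -----------------------------

random_code_pool <- local({
  defaults <- default_code_lists()
  rbind(
    data.frame(system = defaults$system, code = defaults$pattern),
    data.frame(
      system = c("ICD9", "ICD9", "ICD9", "ICD10", "ICD10", "ICD10",
                 "ICD9", "ICD10"),
      # near-misses and subcodes: 30510 must NOT match 3050; 30390,
      # F1020, 5716X must match their category patterns
      code = c("30510", "30390", "5716X", "F1020", "K219", "I10",
               "4019", "E8311")))
})

random_patient_records <- function(index_date = d("2013-06-15")) {
  n_labs <- sample(0:3, 1)
  labs <- if (n_labs == 0) NULL else tibble::tibble(
    patient_id = "P1",
    test = sample(lab_test_levels(), n_labs, replace = TRUE),
    result = sample(c("POSITIVE", "NEGATIVE", "INDETERMINATE"), n_labs,
                    replace = TRUE),
    collected_on = index_date + sample(-400:100, n_labs, replace = TRUE))
  n_dx <- sample(0:3, 1)
  diagnoses <- if (n_dx == 0) NULL else {
    k <- sample(nrow(random_code_pool), n_dx, replace = TRUE)
    tibble::tibble(patient_id = "P1",
                   system = random_code_pool$system[k],
                   code = random_code_pool$code[k],
                   service_on = index_date + sample(-400:100, n_dx,
                                                    replace = TRUE),
                   source = sample(c("DAD", "NACRS", "OHIP"), n_dx,
                                   replace = TRUE))
  }
  list(labs = labs, diagnoses = diagnoses, index_date = index_date)
}

write_cohort_fixture <- function(dir, cohort_lines, labs_lines,
                                 dx_lines) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("patient_id,index_date,cirrhosis,gold_label",
               cohort_lines), file.path(dir, "cohort.csv"))
  writeLines(c("patient_id,test,result,collected_on", labs_lines),
             file.path(dir, "labs.csv"))
  writeLines(c("patient_id,system,code,service_on,source", dx_lines),
             file.path(dir, "diagnoses.csv"))
  file.path(dir, c("cohort.csv", "labs.csv", "diagnoses.csv"))
}
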