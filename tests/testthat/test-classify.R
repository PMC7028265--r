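idx <- as.Date("2013-06-15")

test_that("HCV serology requires RNA or genotype, not antibody alone", {
  rna <- lab_row("HCV_RNA", "POSITIVE", "2013-01-10")
  expect_true(has_positive_hcv(rna, idx)$positive)
  ab <- lab_row("HCV_ANTIBODY", "POSITIVE", "2013-01-10")
  expect_false(has_positive_hcv(ab, idx)$positive)
  late <- lab_row("HCV_RNA", "POSITIVE", "2013-09-01")
  expect_false(has_positive_hcv(late, idx)$positive)
  # same-day serology at the clinic visit is eligible
  same_day <- lab_row("HCV_GENOTYPE", "POSITIVE", "2013-06-15")
  res <- has_positive_hcv(same_day, idx)
  expect_true(res$positive)
  expect_equal(nrow(res$evidence), 1)
})

test_that("HBV serology requires a positive DNA or surface antigen", {
  sag <- lab_row("HBV_SURFACE_ANTIGEN", "POSITIVE", "2012-01-01")
  expect_true(has_positive_hbv(sag, idx)$positive)
  neg <- lab_row("HBV_DNA", "NEGATIVE", "2012-01-01")
  expect_false(has_positive_hbv(neg, idx)$positive)
  indet <- lab_row("HBV_DNA", "INDETERMINATE", "2012-01-01")
  expect_false(has_positive_hbv(indet, idx)$positive)
  expect_false(has_positive_hbv(NULL, idx)$positive)
})

test_that("the hierarchy assigns the first satisfied rule", {
  # viral serology outranks alcohol codes
  a <- classify_patient(lab_row("HCV_GENOTYPE", "POSITIVE", "2013-01-01"),
                        dx_row("ICD10", "F102", "2012-01-01"), idx)
  expect_equal(a$label, "HCV")
  expect_equal(a$step, "HCV_LAB")

  # antibody alone does not block fall-through to HBV
  labs <- dplyr::bind_rows(
    lab_row("HCV_ANTIBODY", "POSITIVE", "2013-01-01"),
    lab_row("HBV_SURFACE_ANTIGEN", "POSITIVE", "2013-01-01"))
  b <- classify_patient(labs, NULL, idx)
  expect_equal(b$label, "HBV")
  expect_equal(b$step, "HBV_LAB")

  # hemochromatosis codes outrank alcohol codes
  dx <- dplyr::bind_rows(dx_row("ICD10", "E8310", "2010-05-05"),
                         dx_row("ICD10", "F102", "2010-05-05"))
  c1 <- classify_patient(NULL, dx, idx)
  expect_equal(c1$label, "HEMOCHROMATOSIS")
  expect_equal(c1$step, "HEMOCHROMATOSIS_CODE")
  expect_equal(c1$ambiguity_flags, character(0))

  # nothing matches: default NAFLD/cryptogenic with empty evidence
  d1 <- classify_patient(NULL, dx_row("ICD10", "I10", "2010-05-05"), idx)
  expect_equal(d1$label, "NAFLD_CRYPTOGENIC")
  expect_equal(d1$step, "DEFAULT_NAFLD")
  expect_equal(nrow(d1$evidence), 0)
})

test_that("autoimmune precedes hemochromatosis and flags the ambiguity", {
  dx <- dplyr::bind_rows(dx_row("ICD10", "K743", "2010-05-05"),
                         dx_row("ICD10", "E8310", "2011-06-06"))
  a <- classify_patient(NULL, dx, idx)
  expect_equal(a$label, "AUTOIMMUNE")
  expect_equal(a$step, "AUTOIMMUNE_CODE")
  expect_equal(a$ambiguity_flags, "autoimmune_and_hemochromatosis_codes")
  # the flag also fires when a reordered hierarchy puts HH first
  rev_h <- c(HCV_LAB = "HCV", HBV_LAB = "HBV",
             HEMOCHROMATOSIS_CODE = "HEMOCHROMATOSIS",
             AUTOIMMUNE_CODE = "AUTOIMMUNE", ALCOHOL_CODE = "ALCOHOL")
  b <- classify_patient(NULL, dx, idx, hierarchy = rev_h)
  expect_equal(b$label, "HEMOCHROMATOSIS")
  expect_equal(b$ambiguity_flags, "autoimmune_and_hemochromatosis_codes")
})

test_that("classify_cohort is order-stable, pure, and matches per-patient calls", {
  expect_equal(nrow(classify_cohort(one_patient_cohort()[0, ])), 0)
  sim <- simulate_cohort(sim_config(n = 40, seed = 9))
  a1 <- classify_cohort(sim$cohort)
  a2 <- classify_cohort(sim$cohort)
  expect_identical(a1, a2)
  expect_equal(a1$patient_id, sim$cohort$patient_id)
  per_patient <- vapply(seq_len(nrow(sim$cohort)), function(i)
    classify_patient(sim$cohort$labs[[i]], sim$cohort$diagnoses[[i]],
                     sim$cohort$index_date[[i]])$label, "")
  expect_equal(a1$label, per_patient)
})

test_that("classification matches the brute-force first-rule oracle", {
  withr::with_seed(303, {
    for (rep in 1:200) {
      rec <- random_patient_records()
      got <- classify_patient(rec$labs, rec$diagnoses, rec$index_date)
      expect_equal(got$label,
                   oracle_classify(rec$labs, rec$diagnoses,
                                   rec$index_date))
      # step/label/evidence consistency invariants
      expect_equal(got$step == "DEFAULT_NAFLD",
                   got$label == "NAFLD_CRYPTOGENIC")
      expect_equal(got$step == "DEFAULT_NAFLD", nrow(got$evidence) == 0)
    }
  })
})

test_that("evidence is monotone under record addition and deletion", {
  rank_of <- function(label) match(label, unname(etiology_hierarchy()))
  withr::with_seed(404, {
    for (rep in 1:60) {
      rec <- random_patient_records()
      base <- classify_patient(rec$labs, rec$diagnoses, rec$index_date)
      # adding alcohol codes never changes an earlier-step label
      extra <- dplyr::bind_rows(rec$diagnoses,
                                dx_row("ICD10", "F102", "2010-01-01"))
      with_alc <- classify_patient(rec$labs, extra, rec$index_date)
      if (rank_of(base$label) < rank_of("ALCOHOL")) {
        expect_equal(with_alc$label, base$label)
      }
      # deleting records never promotes a label up the hierarchy
      if (!is.null(rec$diagnoses) && nrow(rec$diagnoses) > 0) {
        fewer <- rec$diagnoses[-1, ]
        sub <- classify_patient(rec$labs, fewer, rec$index_date)
        expect_gte(rank_of(sub$label), rank_of(base$label))
      }
      if (!is.null(rec$labs) && nrow(rec$labs) > 0) {
        sub <- classify_patient(rec$labs[-1, ], rec$diagnoses,
                                rec$index_date)
        expect_gte(rank_of(sub$label), rank_of(base$label))
      }
    }
  })
})

test_that("invalid index dates are rejected with patient context", {
  expect_error(classify_patient(NULL, NULL, as.Date(NA)),
               class = "hepetio_validation_error")
  cohort <- one_patient_cohort()
  cohort$index_date[1] <- NA
  err <- expect_error(classify_cohort(cohort),
                      class = "hepetio_validation_error")
  expect_match(conditionMessage(err), "P1")
})
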