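test_that("binary_confusion counts one-vs-rest cells", {
  ct <- binary_confusion(c("HCV", "HCV", "HBV"), c("HCV", "HBV", "HBV"),
                         "HCV")
  expect_equal(unlist(ct), c(tp = 1, fp = 1, fn = 0, tn = 1))
  # perfect agreement has no off-diagonal cells for any target
  pred <- c("HCV", "HBV", "ALCOHOL", "HCV")
  for (target in unique(pred)) {
    ct <- binary_confusion(pred, pred, target)
    expect_equal(ct$fp + ct$fn, 0)
  }
  expect_error(binary_confusion("HCV", c("HCV", "HBV"), "HCV"),
               class = "hepetio_validation_error")
  expect_error(binary_confusion(character(0), character(0), "HCV"),
               class = "hepetio_validation_error")
})

test_that("binary_confusion agrees with a loop-based count", {
  withr::with_seed(21, {
    for (rep in 1:50) {
      n <- sample(1:30, 1)
      pred <- sample(etiology_levels(), n, replace = TRUE)
      gold <- sample(etiology_levels(), n, replace = TRUE)
      target <- sample(etiology_levels(), 1)
      expect_equal(unlist(binary_confusion(pred, gold, target)),
                   oracle_confusion(pred, gold, target))
    }
  })
})

test_that("proportion metrics and exact intervals behave as published", {
  ct <- tibble::tibble(tp = 9, fp = 0, fn = 1, tn = 10)
  pm <- proportion_metrics(ct)
  sens <- pm[pm$metric == "sensitivity", ]
  expect_equal(sens$estimate, 0.9)
  expect_equal(sens$denominator, 10)

  # Clopper-Pearson at k = n: upper bound 1, lower bound (alpha/2)^(1/n)
  full <- proportion_metrics(tibble::tibble(tp = 10, fp = 0, fn = 0,
                                            tn = 0), alpha = 0.05)
  sens <- full[full$metric == "sensitivity", ]
  expect_equal(sens$conf_high, 1)
  expect_equal(sens$conf_low, 0.025^(1 / 10), tolerance = 1e-8)

  # zero denominator: undefined, never 0 or 1
  none <- proportion_metrics(tibble::tibble(tp = 0, fp = 2, fn = 0,
                                            tn = 8))
  expect_true(is.na(none$estimate[none$metric == "sensitivity"]))
  expect_equal(none$estimate[none$metric == "specificity"], 0.8)

  expect_error(proportion_metrics(ct, alpha = 1.2),
               class = "hepetio_validation_error")

  # Wilson is selectable and matches the score interval
  w <- proportion_metrics(ct, method = "wilson")
  ref <- suppressWarnings(prop.test(9, 10, correct = FALSE)$conf.int)
  expect_equal(w$conf_low[w$metric == "sensitivity"], ref[1])
})

test_that("cohens_kappa matches hand-computed and degenerate cases", {
  v <- rep(c(TRUE, FALSE), c(6, 14))
  expect_equal(cohens_kappa(v, v)$estimate, 1)

  # tp=4 fp=1 fn=1 tn=4: p_o = 0.8, p_e = 0.5, kappa = 0.6
  pred <- rep(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1, 4))
  gold <- rep(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1, 4))
  k <- cohens_kappa(pred, gold)
  expect_equal(k$estimate, 0.6)
  # Fleiss-style asymptotic interval around the same point
  se <- sqrt(0.8 * 0.2 / (10 * 0.25))
  expect_equal(k$conf_low, 0.6 - qnorm(0.975) * se)

  expect_true(is.na(cohens_kappa(rep(TRUE, 5), rep(TRUE, 5))$estimate))
  expect_error(cohens_kappa(TRUE, c(TRUE, FALSE)),
               class = "hepetio_validation_error")
})

test_that("kappa is symmetric and agrees with e1071 to 1e-10", {
  skip_if_not_installed("e1071")
  withr::with_seed(33, {
    for (rep in 1:60) {
      n <- sample(5:60, 1)
      pred <- runif(n) < runif(1)
      gold <- runif(n) < runif(1)
      k1 <- cohens_kappa(pred, gold)$estimate
      expect_equal(cohens_kappa(gold, pred)$estimate, k1)
      tab <- table(factor(pred, c(FALSE, TRUE)),
                   factor(gold, c(FALSE, TRUE)))
      ref <- e1071::classAgreement(tab)$kappa
      if (!is.na(k1) && is.finite(ref)) {
        expect_equal(k1, ref, tolerance = 1e-10)
      }
    }
  })
})

make_validation_cohort <- function(gold, cirrhosis) {
  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_along(gold)),
    index_date = d("2013-06-01"), cirrhosis = cirrhosis,
    gold_label = gold)
  cld_cohort(patients)
}

fake_assignments <- function(cohort, labels) {
  tibble::tibble(patient_id = cohort$patient_id, label = labels,
                 step = "DEFAULT_NAFLD", evidence_count = 0L,
                 ambiguity_flags = "", evidence = list(NULL))
}

test_that("a perfect algorithm validates perfectly", {
  gold <- rep(c("HCV", "HBV", "ALCOHOL", "NAFLD_CRYPTOGENIC"), each = 8)
  cohort <- make_validation_cohort(gold, rep(c(TRUE, FALSE), 16))
  v <- validate_etiology(cohort, fake_assignments(cohort, gold))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "kappa")) {
    vals <- v$rows[[m]]
    expect_true(all(is.na(vals) | vals == 1))
  }
  expect_equal(glance(v)$agreement, 1)
  expect_equal(glance(v)$kappa_multiclass, 1)
})

test_that("validation rows compose the per-operation results", {
  # one stratum of 10 with the hand-computed kappa = 0.6 configuration
  gold <- rep(c("HCV", "HBV", "HCV", "HBV"), c(4, 1, 1, 4))
  pred <- rep(c("HCV", "HCV", "HBV", "HBV"), c(4, 1, 1, 4))
  cohort <- make_validation_cohort(gold, rep(TRUE, 10))
  v <- validate_etiology(cohort, fake_assignments(cohort, pred))
  row <- v$rows[v$rows$stratum == "CIRRHOSIS" & v$rows$etiology == "HCV", ]
  expect_equal(unlist(row[, c("tp", "fp", "fn", "tn")]),
               c(tp = 4, fp = 1, fn = 1, tn = 4))
  expect_equal(row$sensitivity, 4 / 5)
  expect_equal(row$kappa, 0.6)
  ref <- proportion_metrics(tibble::tibble(tp = 4, fp = 1, fn = 1,
                                           tn = 4))
  expect_equal(row$ppv_low,
               ref$conf_low[ref$metric == "ppv"])
  # no-cirrhosis stratum is absent; OVERALL mirrors CIRRHOSIS here
  expect_false("NO_CIRRHOSIS" %in% v$rows$stratum)
})

test_that("validation invariants hold on random label sets", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      gold <- sample(etiology_levels(), n, replace = TRUE)
      pred <- sample(etiology_levels(), n, replace = TRUE)
      cirr <- runif(n) < 0.5
      cohort <- make_validation_cohort(gold, cirr)
      v <- validate_etiology(cohort, fake_assignments(cohort, pred))
      for (st in unique(v$rows$stratum)) {
        rows <- v$rows[v$rows$stratum == st, ]
        n_st <- rows$n[1]
        # confusion margins partition the stratum
        expect_true(all(rows$tp + rows$fn + rows$fp + rows$tn == n_st))
        keep <- switch(st, OVERALL = rep(TRUE, n), CIRRHOSIS = cirr,
                       NO_CIRRHOSIS = !cirr)
        expect_equal(sum(rows$tp), sum(pred[keep] == gold[keep]))
      }
      # swapping pred and gold: kappa fixed, sens<->ppv, spec<->npv
      v2 <- validate_etiology(make_validation_cohort(pred, cirr),
                              fake_assignments(cohort, gold))
      ov <- v$rows[v$rows$stratum == "OVERALL", ]
      ov2 <- v2$rows[v2$rows$stratum == "OVERALL", ]
      ov2 <- ov2[match(ov$etiology, ov2$etiology), ]
      expect_equal(ov2$kappa, ov$kappa)
      expect_equal(ov2$sensitivity, ov$ppv)
      expect_equal(ov2$npv, ov$specificity)
    }
  })
})

test_that("validation demands gold labels and full assignment coverage", {
  cohort <- make_validation_cohort(c("HCV", NA), c(TRUE, FALSE))
  asg <- fake_assignments(cohort, c("HCV", "HCV"))
  err <- expect_error(validate_etiology(cohort, asg),
                      class = "hepetio_validation_error")
  expect_match(conditionMessage(err), "P002")
  cohort2 <- make_validation_cohort(c("HCV", "HBV"), c(TRUE, FALSE))
  expect_error(validate_etiology(cohort2, asg[1, ]),
               class = "hepetio_validation_error")
})

test_that("tidy and glance expose the validation in broom shapes", {
  gold <- sample(rep(etiology_levels(), 4))
  cohort <- make_validation_cohort(gold, rep(c(TRUE, FALSE), 12))
  v <- validate_etiology(cohort, fake_assignments(cohort, gold))
  td <- tidy(v)
  expect_setequal(names(td), c("stratum", "etiology", "metric",
                               "estimate", "conf_low", "conf_high"))
  expect_equal(nrow(td), 5 * nrow(v$rows))
  gl <- glance(v)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 24)
  p <- autoplot(v)
  expect_s3_class(p, "ggplot")
})
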