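#' One-vs-rest confusion table for a target etiology
#'
#' Dichotomizes aligned predicted and gold-standard label vectors against a
#' single target etiology and counts the four confusion cells.
#'
#' @param pred,gold Aligned character vectors of labels, same length >= 1.
#' @param target The etiology treated as positive.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
binary_confusion <- function(pred, gold, target) {
  if (length(pred) != length(gold)) {
    abort("`pred` and `gold` must have the same length.",
          class = "hepetio_validation_error")
  }
  if (length(pred) == 0) {
    abort("Cannot build a confusion table from empty label vectors.",
          class = "hepetio_validation_error")
  }
  p <- pred == target
  g <- gold == target
  tibble::tibble(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g))
}

binom_ci <- function(x, n, alpha, method) {
  if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
  ci <- if (method == "wilson") {
    # suppressWarnings: chi-squared approximation warning is irrelevant,
    # only the Wilson interval is extracted
    suppressWarnings(
      prop.test(x, n, conf.level = 1 - alpha, correct = FALSE)$conf.int)
  } else {
    binom.test(x, n, conf.level = 1 - alpha)$conf.int
  }
  c(x / n, ci[1], ci[2])
}

#' Sensitivity, specificity, PPV and NPV with binomial intervals
#'
#' Computes the four standard diagnostic-accuracy proportions from a
#' one-vs-rest confusion table, each with a two-sided `1 - alpha` binomial
#' confidence interval. The default is the exact Clopper-Pearson interval,
#' the conservative choice customary in validation studies with small
#' cells; the Wilson score interval is selectable. A metric whose
#' denominator is zero (e.g. sensitivity in a stratum with no
#' gold-positive patients) is undefined and reported as `NA`, never as 0
#' or 1.
#'
#' @param ct A confusion table as returned by [binary_confusion()].
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return A tibble with one row per metric: `metric`, `estimate`,
#'   `conf_low`, `conf_high`, `denominator`.
#' @export
proportion_metrics <- function(ct, alpha = 0.05,
                               method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).",
          class = "hepetio_validation_error")
  }
  cells <- list(sensitivity = c(ct$tp, ct$tp + ct$fn),
                specificity = c(ct$tn, ct$tn + ct$fp),
                ppv = c(ct$tp, ct$tp + ct$fp),
                npv = c(ct$tn, ct$tn + ct$fn))
  purrr::imap(cells, function(xn, name) {
    est <- binom_ci(xn[1], xn[2], alpha, method)
    tibble::tibble(metric = name, estimate = est[1], conf_low = est[2],
                   conf_high = est[3], denominator = xn[2])
  }) |> dplyr::bind_rows()
}

#' Cohen's kappa for two aligned binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, where `p_o` is the
#' observed agreement proportion and `p_e` the chance agreement from the
#' product of the marginal positive/negative rates. The confidence
#' interval uses the asymptotic standard error
#' `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` with a normal approximation,
#' truncated to `[-1, 1]`. When both raters are constant (`p_e = 1`) kappa
#' is undefined and `NA` is returned. By convention kappa > 0.60 indicates
#' substantial and > 0.80 almost perfect agreement.
#'
#' @param pred_binary,gold_binary Aligned logical (or 0/1) vectors,
#'   length >= 1.
#' @param alpha Two-sided significance level; default 0.05.
#' @return A one-row tibble: `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
cohens_kappa <- function(pred_binary, gold_binary, alpha = 0.05) {
  if (length(pred_binary) != length(gold_binary)) {
    abort("Rating vectors must have the same length.",
          class = "hepetio_validation_error")
  }
  if (length(pred_binary) == 0) {
    abort("Rating vectors must be non-empty.",
          class = "hepetio_validation_error")
  }
  p <- as.logical(pred_binary)
  g <- as.logical(gold_binary)
  n <- length(p)
  po <- mean(p == g)
  p1 <- mean(p)
  g1 <- mean(g)
  pe <- p1 * g1 + (1 - p1) * (1 - g1)
  if (pe >= 1) {
    return(tibble::tibble(estimate = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(estimate = kappa,
                 conf_low = max(-1, kappa - z * se),
                 conf_high = min(1, kappa + z * se),
                 n = n)
}

# Multi-category Cohen's kappa over the full label set; supplementary to
# the per-etiology one-vs-rest kappas reported in the validation rows.
multiclass_kappa <- function(pred, gold) {
  n <- length(pred)
  po <- mean(pred == gold)
  lev <- union(pred, gold)
  pe <- sum(vapply(lev, function(l) mean(pred == l) * mean(gold == l), 0))
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

validation_row <- function(pred, gold, etiology, stratum, alpha, method) {
  ct <- binary_confusion(pred, gold, etiology)
  pm <- proportion_metrics(ct, alpha, method)
  kp <- cohens_kappa(pred == etiology, gold == etiology, alpha)
  wide <- purrr::map(seq_len(nrow(pm)), function(i) {
    stats::setNames(
      list(pm$estimate[i], pm$conf_low[i], pm$conf_high[i]),
      paste0(pm$metric[i], c("", "_low", "_high")))
  })
  tibble::as_tibble(c(
    list(stratum = stratum, etiology = etiology, n = length(pred)),
    as.list(ct), purrr::flatten(wide),
    list(kappa = kp$estimate, kappa_low = kp$conf_low,
         kappa_high = kp$conf_high)))
}

#' Validate etiology assignments against gold-standard labels
#'
#' Compares algorithm assignments with chart-abstracted gold-standard
#' etiologies, stratified by cirrhosis status (plus an overall stratum).
#' For each stratum and each etiology present in either the gold or the
#' predicted labels of that stratum, a one-vs-rest confusion table is built
#' and sensitivity, specificity, PPV, NPV and Cohen's kappa are computed
#' with `1 - alpha` intervals. Etiologies entirely absent from a stratum
#' are omitted, mirroring how validation studies decline to validate an
#' etiology with no cases.
#'
#' @param cohort A `cld_cohort`; every patient must carry a `gold_label`.
#' @param assignments Output of [classify_cohort()] covering the cohort.
#' @param alpha Two-sided significance level for all intervals.
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return An `etiology_validation` object; see [tidy.etiology_validation()]
#'   and [autoplot.etiology_validation()]. `$rows` holds one tibble row per
#'   (stratum, etiology) with confusion counts and all metrics.
#' @export
validate_etiology <- function(cohort, assignments, alpha = 0.05,
                              ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  missing_gold <- cohort$patient_id[is.na(cohort$gold_label)]
  if (length(missing_gold) > 0) {
    abort(paste0("Patients missing gold_label: ",
                 paste(missing_gold, collapse = ", ")),
          class = "hepetio_validation_error")
  }
  idx <- match(cohort$patient_id, assignments$patient_id)
  if (anyNA(idx)) {
    abort(paste0("Assignments missing for patient(s): ",
                 paste(cohort$patient_id[is.na(idx)], collapse = ", ")),
          class = "hepetio_validation_error")
  }
  pred <- assignments$label[idx]
  gold <- cohort$gold_label
  strata <- list(OVERALL = rep(TRUE, nrow(cohort)),
                 CIRRHOSIS = cohort$cirrhosis,
                 NO_CIRRHOSIS = !cohort$cirrhosis)
  rows <- purrr::imap(strata, function(keep, name) {
    if (!any(keep)) return(NULL)
    p <- pred[keep]
    g <- gold[keep]
    ets <- intersect(etiology_levels(), union(p, g))
    purrr::map(ets, validation_row, pred = p, gold = g, stratum = name,
               alpha = alpha, method = ci_method) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  mk <- purrr::imap(strata, function(keep, name) {
    tibble::tibble(stratum = name, n = sum(keep),
                   kappa_multiclass = if (any(keep))
                     multiclass_kappa(pred[keep], gold[keep]) else NA_real_)
  }) |> dplyr::bind_rows()
  structure(list(rows = rows, strata = mk, alpha = alpha,
                 ci_method = ci_method, n = nrow(cohort)),
            class = "etiology_validation")
}

#' @export
print.etiology_validation <- function(x, ...) {
  cat(sprintf(
    "<etiology_validation> %d patients, %d (stratum x etiology) rows\n",
    x$n, nrow(x$rows)))
  cat(sprintf("intervals: %d%% %s\n", round(100 * (1 - x$alpha)),
              x$ci_method))
  print(x$rows, ...)
  invisible(x)
}

#' Tidy an etiology validation into long form
#'
#' @param x An `etiology_validation`.
#' @param ... Unused.
#' @return A tibble with columns `stratum`, `etiology`, `metric`,
#'   `estimate`, `conf_low`, `conf_high`.
#' @method tidy etiology_validation
#' @export
tidy.etiology_validation <- function(x, ...) {
  purrr::map(c("sensitivity", "specificity", "ppv", "npv", "kappa"),
             function(m) {
               tibble::tibble(stratum = x$rows$stratum,
                              etiology = x$rows$etiology,
                              metric = m,
                              estimate = x$rows[[m]],
                              conf_low = x$rows[[paste0(m, "_low")]],
                              conf_high = x$rows[[paste0(m, "_high")]])
             }) |> dplyr::bind_rows() |>
    dplyr::arrange(match(.data$stratum, stratum_levels()),
                   match(.data$etiology, etiology_levels()))
}

#' One-line summary of an etiology validation
#'
#' @param x An `etiology_validation`.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, per-stratum sizes, overall
#'   label agreement, multi-class kappa, interval settings.
#' @method glance etiology_validation
#' @export
glance.etiology_validation <- function(x, ...) {
  ov <- x$rows[x$rows$stratum == "OVERALL", ]
  tibble::tibble(
    n = x$n,
    n_cirrhosis = x$strata$n[x$strata$stratum == "CIRRHOSIS"],
    n_no_cirrhosis = x$strata$n[x$strata$stratum == "NO_CIRRHOSIS"],
    agreement = sum(ov$tp) / x$n,
    kappa_multiclass = x$strata$kappa_multiclass[
      x$strata$stratum == "OVERALL"],
    alpha = x$alpha,
    ci_method = x$ci_method)
}

#' Forest plot of validation metrics
#'
#' Point estimates with confidence intervals for every (stratum, etiology)
#' row, faceted by metric — the graphical analogue of a printed validation
#' table.
#'
#' @param object An `etiology_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot etiology_validation
#' @export
autoplot.etiology_validation <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(!is.na(.data$estimate)) |>
    dplyr::mutate(etiology = factor(.data$etiology,
                                    rev(etiology_levels())),
                  metric = factor(.data$metric,
                                  c("sensitivity", "specificity", "ppv",
                                    "npv", "kappa")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$etiology,
                                   color = .data$stratum)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.25, position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::scale_color_brewer(palette = "Dark2", name = "Stratum") +
    ggplot2::labs(x = "Estimate (with CI)", y = NULL) +
    ggplot2::theme_minimal()
}
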