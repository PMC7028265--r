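# Which confusion cells each reported statistic is computed from; a
# statistic is suppressed whenever any of its defining cells is a small
# cell.
metric_cells <- list(
  sensitivity = c("tp", "fn"),
  specificity = c("tn", "fp"),
  ppv = c("tp", "fp"),
  npv = c("tn", "fn"),
  kappa = c("tp", "fp", "fn", "tn"))

#' Write a validation report with optional small-cell suppression
#'
#' Writes one CSV row per (stratum, etiology) with the confusion counts
#' and each accuracy statistic with its interval bounds — the layout of a
#' published validation table plus a stratum column. Privacy rules for
#' administrative data holdings commonly forbid reporting small cells
#' (counts of 5 or fewer) because of re-identification risk; with
#' `suppress = TRUE` any confusion count at or below `threshold` is
#' rendered as `marker`, as is every statistic (point and interval) whose
#' defining cells include such a count. Suppression is applied at
#' reporting time only — the validation object itself always holds full
#' precision.
#'
#' @param report An `etiology_validation` (or its `$rows` tibble).
#' @param path Output CSV path.
#' @param suppress Apply small-cell suppression (default `TRUE`).
#' @param threshold Counts less than or equal to this are suppressed;
#'   default 5.
#' @param marker String written in place of suppressed values; default
#'   `"NR"` (not reportable).
#' @param digits Decimal places for displayed statistics; default 2.
#' @return Invisibly, the formatted tibble that was written.
#' @export
write_report <- function(report, path, suppress = TRUE, threshold = 5,
                         marker = "NR", digits = 2) {
  rows <- if (inherits(report, "etiology_validation")) report$rows
          else tibble::as_tibble(report)
  fmt_num <- function(x) {
    ifelse(is.na(x), "", formatC(round(x, digits), format = "f",
                                 digits = digits))
  }
  out <- tibble::tibble(stratum = rows$stratum, etiology = rows$etiology,
                        n = as.character(rows$n))
  small <- list()
  for (cell in c("tp", "fp", "fn", "tn")) {
    small[[cell]] <- suppress & rows[[cell]] <= threshold
    out[[cell]] <- ifelse(small[[cell]], marker,
                          as.character(rows[[cell]]))
  }
  for (m in names(metric_cells)) {
    hit <- Reduce(`|`, small[metric_cells[[m]]])
    for (suffix in c("", "_low", "_high")) {
      col <- paste0(m, suffix)
      out[[col]] <- ifelse(hit, marker, fmt_num(rows[[col]]))
    }
  }
  tryCatch(readr::write_csv(out, path, progress = FALSE),
           error = function(e) {
             abort(paste0("Cannot write report to '", path, "': ",
                          conditionMessage(e)),
                   class = "hepetio_io_error")
           })
  invisible(out)
}
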