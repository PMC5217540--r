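# End-to-end comparison pipeline binding the modules together.

#' Compare GP-derived smoking status against survey self-report
#'
#' Runs the full pipeline for one classification variant: classifies every
#' surveyed patient's GP record at that patient's survey date, collapses to
#' the four-level scale, cross-tabulates against the survey self-report,
#' and computes Cohen's kappa for the three-status (smoker/ex/never) and
#' two-status (smoker/non-smoker) solutions over complete pairs, together
#' with the discordance summary.
#'
#' @param events Coded events: a data frame or a CSV path (see
#'   [read_events()]).
#' @param registry A \code{code_registry} or a codelist CSV path.
#' @param survey Survey responses: a data frame with \code{patient_id},
#'   \code{survey_date}, \code{status} (collapsed scale), or a CSV path
#'   (see [read_survey()]).
#' @param variant \code{"full"}, \code{"no-temporal"} or \code{"nearest"}.
#' @param verbose Log patient counts at each filter stage (surveyed, with
#'   any GP data, with informative codes, classified non-missing).
#' @return A \code{smoking_comparison}: list with \code{table}
#'   (\code{agreement_table}), \code{kappa_two}, \code{kappa_three}
#'   (\code{kappa_result}), \code{discordance} (data frame), and
#'   \code{variant}.
#' @export
run_comparison <- function(events, registry, survey,
                           variant = c("full", "no-temporal", "nearest"),
                           verbose = FALSE) {
  variant <- match.arg(variant)
  if (is.character(events)) events <- read_events(events)
  if (is.character(registry)) registry <- read_codelist(registry)
  if (is.character(survey)) survey <- read_survey(survey)
  events <- normalize_events(events)
  census <- data.frame(patient_id = survey$patient_id,
                       census_date = as.Date(survey$survey_date))
  gp <- classify_cohort(events, registry, census, variant = variant,
                        collapse = TRUE)
  if (verbose) {
    inf <- informative_events(events, registry,
                              status_only = variant == "nearest")
    message(sprintf(
      paste0("surveyed: %d | with GP events: %d | with informative codes:",
             " %d | classified non-missing: %d"),
      nrow(survey),
      length(intersect(survey$patient_id, unique(events$patient_id))),
      length(intersect(survey$patient_id, unique(inf$patient_id))),
      sum(gp$status != "MISSING")))
  }
  tab <- build_agreement_table(gp, survey)
  grid3 <- complete_pairs(tab)
  # kappa is undefined without complete pairs; leave it absent rather than fail
  out <- list(table = tab,
              kappa_three = if (sum(grid3) > 0) cohen_kappa(grid3),
              kappa_two = if (sum(grid3) > 0)
                cohen_kappa(collapse_two_status(grid3)),
              discordance = discordance_summary(tab),
              variant = variant)
  class(out) <- "smoking_comparison"
  out
}

#' @export
print.smoking_comparison <- function(x, ...) {
  cat("GP vs survey smoking-status comparison (variant:", x$variant, ")\n\n")
  print(x$table)
  if (is.null(x$kappa_two)) {
    cat("\nKappa undefined: no complete GP/survey pairs\n")
  } else {
    cat("\nTwo-status  "); print(x$kappa_two)
    cat("Three-status "); print(x$kappa_three)
  }
  cat("\nDiscordance:\n")
  d <- x$discordance
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-22s %5.0f / %5.0f = %s\n", d$measure[i],
                d$numerator[i], d$denominator[i],
                format_percent(d$percent[i])))
  }
  invisible(x)
}

#' Write per-patient classifications to CSV
#'
#' @param statuses Data frame \code{patient_id,status}.
#' @param path Output path; rows are written in lexicographic patient
#'   order so runs diff cleanly.
#' @return \code{path}, invisibly.
#' @export
write_statuses <- function(statuses, path) {
  statuses <- statuses[order(statuses$patient_id), , drop = FALSE]
  utils::write.csv(statuses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
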