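# Annual smoking prevalence from classified GP records.

#' Annual smoking prevalence from GP records
#'
#' For each requested year, classifies every patient aged 16 or over at the
#' within-year census date with the full life-course algorithm, collapses
#' relapsed and likely smokers into smokers, and reports the proportion of
#' smokers. By default the denominator is patients with a non-missing
#' collapsed status; set \code{include_missing = TRUE} to use all patients
#' aged 16+ instead (the denominator policy is recorded in the output).
#'
#' @param events Coded events (see [read_events()]).
#' @param demographics Data frame \code{patient_id,birth_date,sex}
#'   (\code{sex} optional; any labels are accepted as strata).
#' @param registry A \code{code_registry}.
#' @param years Integer vector of calendar years.
#' @param census_md Within-year census date as \code{"MM-DD"}; mid-year
#'   (July 1) by default.
#' @param include_missing Count patients with missing status in the
#'   denominator.
#' @return Data frame \code{year,sex,n_smokers,n_classified,prevalence,
#'   denominator} with one row per stratum (each sex level plus
#'   \code{"all"}) and year; \code{prevalence} is \code{NA} when nobody is
#'   classified (flagging years outside event coverage).
#' @export
annual_prevalence <- function(events, demographics, registry, years,
                              census_md = "07-01",
                              include_missing = FALSE) {
  stopifnot(all(c("patient_id", "birth_date") %in% names(demographics)))
  demographics$patient_id <- as.character(demographics$patient_id)
  if (anyDuplicated(demographics$patient_id)) {
    stop("duplicate patient_id in demographics", call. = FALSE)
  }
  birth <- as.Date(demographics$birth_date)
  sex <- if ("sex" %in% names(demographics)) {
    as.character(demographics$sex)
  } else {
    rep("all", nrow(demographics))
  }
  denom_label <- if (include_missing) "all_aged_16_plus" else "classified"
  out <- list()
  for (year in years) {
    census <- as.Date(sprintf("%d-%s", year, census_md))
    age <- floor(as.numeric(census - birth) / 365.25)
    eligible <- !is.na(age) & age >= 16
    ids <- demographics$patient_id[eligible]
    cls <- classify_cohort(events[events$patient_id %in% ids, , drop = FALSE],
                           registry, census, variant = "full",
                           collapse = TRUE)
    status <- cls$status[match(ids, cls$patient_id)]
    status[is.na(status)] <- "MISSING"  # eligible patients with no events
    strata <- split(status, factor(sex[eligible]))
    strata[["all"]] <- status
    for (s in names(strata)) {
      st <- strata[[s]]
      n_classified <- if (include_missing) length(st) else
        sum(st != "MISSING")
      n_smokers <- sum(st == "SMOKER")
      out[[length(out) + 1L]] <- data.frame(
        year = year, sex = s,
        n_smokers = n_smokers, n_classified = n_classified,
        prevalence = if (n_classified > 0) n_smokers / n_classified else
          NA_real_,
        denominator = denom_label,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
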