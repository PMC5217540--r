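# Census-date smoking-status classification over a patient's life course.

# tie-break priority when boundary dates are equidistant from the census:
# conservative toward smoking (therapy evidence is treated as smoking)
CATEGORY_PRIORITY <- c(SMOKER = 1L, EX = 2L, NEVER = 3L)

# "prior to the census" is read as on-or-before: a code recorded on the
# census day reflects status on that day. Isolated here so the strict
# (<) reading is a one-line change.
on_or_before <- function(date, census) date <= census

#' Classify smoking status at a census date (full algorithm)
#'
#' Assigns one of seven statuses from a patient's per-category first/last
#' summary and the dated informative events, evaluated in this order:
#' \enumerate{
#'   \item no informative events in the whole record:
#'     \code{NO_INFORMATION};
#'   \item no informative event on or before the census: if every
#'     informative event in the record is smoker-category,
#'     \code{LIKELY_SMOKER} (smoking typically starts years before it is
#'     first recorded), otherwise \code{UNKNOWN_SMOKING_STATUS};
#'   \item containment — category \emph{x} contains the census when
#'     \code{first_x <= census <= last_x}: smoker span overlapping an ex
#'     and/or never span gives \code{RELAPSED_SMOKER}; otherwise a
#'     containing smoker span gives \code{SMOKER}, then ex gives
#'     \code{EX_SMOKER}; a containing never span gives \code{EX_SMOKER}
#'     when ex or smoker evidence starts on or before the census (a
#'     never-smoker designation after evidence of smoking is a coding
#'     conflict, not a biography) and \code{NEVER_SMOKER} otherwise;
#'   \item no containing span: the category of the boundary date
#'     (first/last value) nearest the census in absolute days is taken
#'     (ties prefer the boundary on or before the census, then smoker over
#'     ex over never); a provisional \code{NEVER} is overridden to
#'     \code{EX_SMOKER} when any ex/smoker evidence lies on or before the
#'     census.
#' }
#'
#' @param summary A \code{category_summary} for the patient.
#' @param events The patient's informative events: data frame with
#'   \code{event_date} and \code{category}, as produced by
#'   [informative_events()]. Must be the events the summary was derived
#'   from.
#' @param census Census date (\code{Date} or ISO-8601 string).
#' @param temporal_check Set \code{FALSE} for the comparison variant that
#'   does not check for previous smoking status: a never-smoker span (or
#'   nearest never boundary) then stands regardless of earlier ex/smoker
#'   evidence. Relapse (overlap) detection is unaffected.
#' @return A single status string.
#' @export
#' @examples
#' reg <- default_codelist()
#' ev <- data.frame(patient_id = "p",
#'                  event_date = as.Date(c("2000-05-01", "2010-05-01")),
#'                  code = c("137R.", "137F."))
#' s <- summarize_patient(ev, reg)
#' ie <- informative_events(ev, reg)
#' classify_full(s, ie, as.Date("2005-01-01"))
classify_full <- function(summary, events, census, temporal_check = TRUE) {
  census <- as.Date(census)
  stopifnot(inherits(summary, "category_summary"))
  dates <- events$event_date
  cats <- events$category
  if (length(dates) == 0) {
    return("NO_INFORMATION")
  }
  if (!any(on_or_before(dates, census))) {
    if (all(cats == "SMOKER")) return("LIKELY_SMOKER")
    return("UNKNOWN_SMOKING_STATUS")
  }
  contains <- function(first, last) {
    !is.na(first) && first <= census && census <= last
  }
  in_never <- contains(summary$first_never, summary$last_never)
  in_ex <- contains(summary$first_ex, summary$last_ex)
  in_smok <- contains(summary$first_smok, summary$last_smok)
  prior_smoking <- (!is.na(summary$first_ex) &&
                      on_or_before(summary$first_ex, census)) ||
                   (!is.na(summary$first_smok) &&
                      on_or_before(summary$first_smok, census))
  if (in_smok && (in_ex || in_never)) return("RELAPSED_SMOKER")
  if (in_smok) return("SMOKER")
  if (in_ex) return("EX_SMOKER")
  if (in_never) {
    if (temporal_check && prior_smoking) return("EX_SMOKER")
    return("NEVER_SMOKER")
  }
  provisional <- nearest_boundary_category(summary, census)
  if (provisional == "NEVER" && temporal_check && prior_smoking) {
    return("EX_SMOKER")
  }
  c(NEVER = "NEVER_SMOKER", EX = "EX_SMOKER", SMOKER = "SMOKER")[[provisional]]
}

#' Variant without temporal checking
#'
#' Identical to [classify_full()] except that a never-smoker designation is
#' never overridden by earlier ex/smoker evidence.
#'
#' @inheritParams classify_full
#' @return A single status string.
#' @export
classify_no_temporal <- function(summary, events, census) {
  classify_full(summary, events, census, temporal_check = FALSE)
}

# Category of the first/last boundary date nearest the census.
# Assumes at least one category present and the census inside no span.
nearest_boundary_category <- function(summary, census) {
  bdates <- as.Date(character(0))
  bcats <- character(0)
  for (spec in list(c("NEVER", "never"), c("EX", "ex"), c("SMOKER", "smok"))) {
    f <- summary[[paste0("first_", spec[2])]]
    l <- summary[[paste0("last_", spec[2])]]
    if (!is.na(f)) {
      bdates <- c(bdates, f, l)
      bcats <- c(bcats, spec[1], spec[1])
    }
  }
  dist <- abs(as.integer(bdates - census))
  cand <- which(dist == min(dist))
  if (length(cand) > 1) {
    before <- cand[on_or_before(bdates[cand], census)]
    if (length(before) > 0) cand <- before
    cand <- cand[order(CATEGORY_PRIORITY[bcats[cand]])]
  }
  bcats[cand[1]]
}

#' Nearest-status-code classification
#'
#' The simplest comparison variant: taking status codes only (no therapy,
#' administration or advice codes), the patient's status is the base
#' category of the single status code dated nearest the census in absolute
#' days. Ties prefer the code on or before the census, then smoker over ex
#' over never. A patient with no status codes is missing.
#'
#' @param status_events Informative events produced with
#'   \code{status_only = TRUE}: data frame with \code{event_date},
#'   \code{category}.
#' @param census Census date.
#' @return One of \code{MISSING}, \code{SMOKER}, \code{EX_SMOKER},
#'   \code{NEVER_SMOKER}.
#' @export
classify_nearest <- function(status_events, census) {
  census <- as.Date(census)
  dates <- status_events$event_date
  cats <- status_events$category
  if (length(dates) == 0) return("MISSING")
  dist <- abs(as.integer(dates - census))
  cand <- which(dist == min(dist))
  if (length(cand) > 1) {
    before <- cand[on_or_before(dates[cand], census)]
    if (length(before) > 0) cand <- before
    cand <- cand[order(CATEGORY_PRIORITY[cats[cand]])]
  }
  c(NEVER = "NEVER_SMOKER", EX = "EX_SMOKER",
    SMOKER = "SMOKER")[[cats[cand[1]]]]
}

#' Collapse the seven statuses to the four-level comparison scale
#'
#' Relapsed and likely smokers count as smokers; records with no usable
#' information at the census (no information at all, or status codes only
#' after the census) are missing.
#'
#' @param status Character vector of seven-level statuses.
#' @return Character vector over \code{MISSING}, \code{SMOKER},
#'   \code{EX_SMOKER}, \code{NEVER_SMOKER}.
#' @export
collapse_status <- function(status) {
  map <- c(NO_INFORMATION = "MISSING",
           UNKNOWN_SMOKING_STATUS = "MISSING",
           NEVER_SMOKER = "NEVER_SMOKER",
           EX_SMOKER = "EX_SMOKER",
           RELAPSED_SMOKER = "SMOKER",
           LIKELY_SMOKER = "SMOKER",
           SMOKER = "SMOKER")
  bad <- setdiff(unique(status), names(map))
  if (length(bad) > 0) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[status])
}

#' Classify every patient in a cohort at a census date
#'
#' Runs the whole pipeline — event classification, per-patient first/last
#' summaries, census-date classification — for all patients at once.
#'
#' @param events Coded events for any number of patients (see
#'   [read_events()] for the column contract).
#' @param registry A \code{code_registry}.
#' @param census Either a single census date applied to every patient, or a
#'   data frame \code{patient_id,census_date} giving per-patient census
#'   dates (e.g. each patient's survey date); patients in \code{census} with
#'   no events are classified from an empty record.
#' @param variant \code{"full"}, \code{"no-temporal"} or \code{"nearest"}.
#' @param collapse Return the four-level collapsed scale instead of the
#'   seven-level one. The \code{"nearest"} variant is always four-level.
#' @return Data frame \code{patient_id,status}, ordered by patient id.
#' @export
classify_cohort <- function(events, registry, census,
                            variant = c("full", "no-temporal", "nearest"),
                            collapse = FALSE) {
  variant <- match.arg(variant)
  events <- normalize_events(events)
  per_patient <- is.data.frame(census)
  if (per_patient) {
    stopifnot(all(c("patient_id", "census_date") %in% names(census)))
    census_ids <- as.character(census$patient_id)
    if (anyDuplicated(census_ids)) {
      stop("duplicate patient_id in census table", call. = FALSE)
    }
    census_dates <- as.Date(census$census_date)
    ids <- sort(census_ids)
  } else {
    census <- as.Date(census)
    stopifnot(length(census) == 1, !is.na(census))
    ids <- sort(unique(events$patient_id))
  }
  cat_events <- informative_events(events, registry,
                                   status_only = variant == "nearest")
  by_patient <- split_by_patient(cat_events)
  empty <- data.frame(event_date = as.Date(character(0)),
                      category = character(0))
  status <- vapply(ids, function(id) {
    ev <- by_patient[[id]]
    if (is.null(ev)) ev <- empty
    cen <- if (per_patient) census_dates[match(id, census_ids)] else census
    if (is.na(cen)) return(NA_character_)
    if (variant == "nearest") {
      classify_nearest(ev, cen)
    } else {
      s <- category_summary(ev$event_date, ev$category)
      classify_full(s, ev, cen, temporal_check = variant == "full")
    }
  }, character(1))
  if (collapse && variant != "nearest") status <- collapse_status(status)
  out <- data.frame(patient_id = ids, status = unname(status),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
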