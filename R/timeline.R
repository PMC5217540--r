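# Patient timelines: reduce coded events to per-category first/last dates.

CATEGORY_FIELDS <- c("first_never", "last_never", "first_ex", "last_ex",
                     "first_smok", "last_smok")

#' Read a coded-event table
#'
#' @param path CSV with header columns \code{patient_id,event_date,code,value};
#'   dates ISO-8601 (\code{YYYY-MM-DD}); \code{value} may be blank.
#' @return Data frame with \code{patient_id} (character), \code{event_date}
#'   (\code{Date}), \code{code} (character), \code{value} (numeric, \code{NA}
#'   when blank).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("patient_id", "event_date", "code")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("events file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"value" %in% names(df)) df$value <- ""
  dates <- as.Date(df$event_date, format = "%Y-%m-%d")
  if (anyNA(dates) && nrow(df) > 0) {
    bad <- which(is.na(dates))[1]
    stop("unparseable event_date at data row ", bad, ": '",
         df$event_date[bad], "'", call. = FALSE)
  }
  data.frame(patient_id = df$patient_id,
             event_date = dates,
             code = df$code,
             value = suppressWarnings(as.numeric(df$value)),
             stringsAsFactors = FALSE)
}

#' Reduce coded events to dated smoking categories
#'
#' Classifies every event through the registry and keeps the informative
#' ones as (patient, date, category) rows. With \code{status_only = TRUE},
#' events whose code kind is therapy, cessation administration or advice are
#' dropped before classification — the event universe of the
#' nearest-status-code variant.
#'
#' @param events Data frame as returned by [read_events()] (the \code{value}
#'   column is optional).
#' @param registry A \code{code_registry}.
#' @param status_only Drop therapy/admin/advice-coded events first.
#' @return Data frame with columns \code{patient_id}, \code{event_date},
#'   \code{category} (one of \code{NEVER}, \code{EX}, \code{SMOKER}).
#' @export
informative_events <- function(events, registry, status_only = FALSE) {
  stopifnot(inherits(registry, "code_registry"))
  events <- normalize_events(events)
  if (status_only) {
    excluded <- registry$code[registry$kind %in% STATUS_EXCLUDED_KINDS]
    events <- events[!(events$code %in% excluded), , drop = FALSE]
  }
  cat <- classify_code(registry, events$code, events$value)
  keep <- cat != UNINFORMATIVE
  out <- data.frame(patient_id = events$patient_id[keep],
                    event_date = events$event_date[keep],
                    category = cat[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

normalize_events <- function(events) {
  stopifnot(is.data.frame(events))
  required <- c("patient_id", "event_date", "code")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    stop("events need column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"value" %in% names(events)) {
    events$value <- rep(NA_real_, nrow(events))
  }
  if (!inherits(events$event_date, "Date")) {
    events$event_date <- as.Date(events$event_date)
  }
  events$patient_id <- as.character(events$patient_id)
  events
}

#' Summarise one patient's record into per-category first/last dates
#'
#' The entire state the classification algorithm needs: for each of the
#' never-smoker, ex-smoker and smoker categories, the earliest and latest
#' dates on which an informative code of that category was recorded
#' (\code{FIRST_NEVER}/\code{LAST_NEVER}, \code{FIRST_EX}/\code{LAST_EX},
#' \code{FIRST_SMOK}/\code{LAST_SMOK}). Uninformative events contribute
#' nothing; the result does not depend on input order.
#'
#' @param events Coded events for a single patient.
#' @param registry A \code{code_registry}.
#' @return A \code{category_summary}: named list of six \code{Date} scalars
#'   (\code{NA} when the category never occurs).
#' @export
#' @examples
#' reg <- default_codelist()
#' ev <- data.frame(patient_id = "p1",
#'                  event_date = as.Date(c("2001-03-01", "2005-07-09")),
#'                  code = "137F.")
#' summarize_patient(ev, reg)
summarize_patient <- function(events, registry) {
  events <- normalize_events(events)
  if (length(unique(events$patient_id)) > 1) {
    stop("summarize_patient expects events for a single patient; got ",
         length(unique(events$patient_id)), call. = FALSE)
  }
  cat_events <- informative_events(events, registry)
  category_summary(cat_events$event_date, cat_events$category)
}

# Build a category_summary from parallel date/category vectors.
category_summary <- function(dates, categories) {
  out <- stats::setNames(rep(as.Date(NA), 6L), CATEGORY_FIELDS)
  for (spec in list(c("NEVER", "never"), c("EX", "ex"), c("SMOKER", "smok"))) {
    sel <- categories == spec[1]
    if (any(sel)) {
      out[[paste0("first_", spec[2])]] <- min(dates[sel])
      out[[paste0("last_", spec[2])]] <- max(dates[sel])
    }
  }
  out <- as.list(out)
  class(out) <- "category_summary"
  out
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Category summary (first/last informative code dates):\n")
  for (spec in list(c("NEVER", "never"), c("EX", "ex"), c("SMOKER", "smok"))) {
    f <- x[[paste0("first_", spec[2])]]
    l <- x[[paste0("last_", spec[2])]]
    cat(sprintf("  %-6s %s .. %s\n", spec[1],
                if (is.na(f)) "-" else format(f),
                if (is.na(l)) "-" else format(l)))
  }
  invisible(x)
}

# Split informative events by patient into a list of (event_date, category)
# data frames; used by the cohort-level classifier.
split_by_patient <- function(cat_events) {
  split(cat_events[c("event_date", "category")],
        factor(cat_events$patient_id))
}
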