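# Synthetic cohort generator: life-course smoking trajectories and their
# imperfect GP/survey observations.

#' Parameters for the synthetic cohort generator
#'
#' Defaults describe a plausible adult primary-care population: just under
#' half ever smoke, starting in the mid-teens to early twenties; current
#' smokers quit at a few percent per year and ex-smokers occasionally
#' relapse; patients see the GP a few times a year and a visit records a
#' smoking code roughly a quarter of the time (recording is sporadic);
#' a fifth of recorded smoker events are cessation-therapy or
#' administration codes rather than plain status codes; one in ten
#' ex-smokers self-reports "never smoked" at survey. Smoker under-report at
#' survey is not modelled (the corresponding probability is fixed at zero).
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer root seed; per-patient sub-streams are derived from
#'   it, so the same seed and parameters reproduce the cohort exactly and
#'   per-patient regeneration is stable.
#' @param initiation_prob Probability a patient ever starts smoking.
#' @param initiation_age Two-element integer range of starting ages, years.
#' @param annual_quit_prob Per-year probability a current smoker quits.
#' @param annual_relapse_prob Per-year probability an ex-smoker relapses.
#' @param visit_rate Expected GP visits per year (Poisson).
#' @param record_prob Probability a visit records a smoking code.
#' @param therapy_code_prob Probability a recorded smoker event is a
#'   therapy/administration/advice code rather than a status code.
#' @param never_misreport_prob Probability an ex-smoker self-reports never
#'   smoked at survey.
#' @param survey_year Calendar year of the survey.
#' @param birth_year_range Two-element range of birth years.
#' @param records_from First calendar year in which GP visits generate
#'   coded events (electronic records do not cover early life for older
#'   patients).
#' @param end_year Last calendar year of the observation window; the GP
#'   extract closes at the end of this year (defaults to the survey year).
#' @return A validated \code{cohort_params} list.
#' @export
cohort_params <- function(n_patients = 1000L, seed = 1L,
                          initiation_prob = 0.45,
                          initiation_age = c(14L, 22L),
                          annual_quit_prob = 0.04,
                          annual_relapse_prob = 0.02,
                          visit_rate = 4,
                          record_prob = 0.25,
                          therapy_code_prob = 0.2,
                          never_misreport_prob = 0.1,
                          survey_year = 2013L,
                          birth_year_range = c(1940L, 1995L),
                          records_from = 1990L,
                          end_year = survey_year) {
  p <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
            initiation_prob = initiation_prob,
            initiation_age = as.integer(initiation_age),
            annual_quit_prob = annual_quit_prob,
            annual_relapse_prob = annual_relapse_prob,
            visit_rate = visit_rate, record_prob = record_prob,
            therapy_code_prob = therapy_code_prob,
            never_misreport_prob = never_misreport_prob,
            survey_year = as.integer(survey_year),
            birth_year_range = as.integer(birth_year_range),
            records_from = as.integer(records_from),
            end_year = as.integer(end_year))
  probs <- c("initiation_prob", "annual_quit_prob", "annual_relapse_prob",
             "record_prob", "therapy_code_prob", "never_misreport_prob")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (p$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (p$visit_rate < 0) stop("visit_rate must be >= 0", call. = FALSE)
  if (length(p$initiation_age) != 2L ||
      p$initiation_age[1] > p$initiation_age[2]) {
    stop("initiation_age must be an increasing range", call. = FALSE)
  }
  if (length(p$birth_year_range) != 2L ||
      p$birth_year_range[1] > p$birth_year_range[2]) {
    stop("birth_year_range must be an increasing range", call. = FALSE)
  }
  if (p$end_year < p$survey_year) {
    stop("end_year must not precede survey_year", call. = FALSE)
  }
  class(p) <- "cohort_params"
  p
}

#' Generate a synthetic cohort with GP events, survey responses and truth
#'
#' Each patient follows a yearly two-state smoking chain: never-smoker
#' until a Bernoulli initiation at a random starting age, then alternating
#' current-smoker/ex-smoker spells driven by the annual quit and relapse
#' probabilities (a never-smoker state never recurs after initiation). GP
#' visits arrive at \code{visit_rate} per year from \code{records_from}
#' onwards; each visit records, with probability \code{record_prob}, a code
#' consistent with the patient's true state that year — smokers emit
#' therapy/administration codes with probability \code{therapy_code_prob}
#' and otherwise status or intensity codes (occasionally the bare parent
#' code with a cigarettes-per-day value), ex-smokers emit ex codes,
#' never-smokers emit never codes. Patients aged 16+ in the survey year
#' answer the survey with their true state, except that ex-smokers report
#' never having smoked with probability \code{never_misreport_prob}.
#'
#' @param params A \code{cohort_params} object.
#' @param registry Code registry supplying the emitted codes; the default
#'   codelist by default.
#' @return List with \code{events} (coded events), \code{surveys} (survey
#'   responses with items and derived status), \code{truth} (long data
#'   frame \code{patient_id,year,status} of true yearly states) and
#'   \code{demographics} (\code{patient_id,birth_date,sex}). Deterministic
#'   given the seed.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_patients = 50, seed = 42))
#' head(cohort$events)
generate_cohort <- function(params, registry = default_codelist()) {
  stopifnot(inherits(params, "cohort_params"),
            inherits(registry, "code_registry"))
  pools <- code_pools(registry)
  events <- vector("list", params$n_patients)
  surveys <- vector("list", params$n_patients)
  truths <- vector("list", params$n_patients)
  demo <- vector("list", params$n_patients)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  width <- nchar(as.character(params$n_patients))
  for (i in seq_len(params$n_patients)) {
    set.seed((params$seed * 69821 + i * 10007) %% 2147483647L)
    id <- sprintf("P%0*d", width, i)
    pat <- simulate_patient(id, params, pools)
    events[[i]] <- pat$events
    surveys[[i]] <- pat$survey
    truths[[i]] <- pat$truth
    demo[[i]] <- pat$demo
  }
  list(events = do.call(rbind, events),
       surveys = do.call(rbind, surveys[!vapply(surveys, is.null,
                                                logical(1))]),
       truth = do.call(rbind, truths),
       demographics = do.call(rbind, demo))
}

# partition registry codes into sampling pools
code_pools <- function(registry) {
  therapy <- registry$kind %in% STATUS_EXCLUDED_KINDS
  list(never = registry$code[registry$base_category == "NEVER"],
       ex = registry$code[registry$base_category == "EX" & !therapy],
       smoker_status = registry$code[registry$base_category == "SMOKER" &
                                       !therapy],
       smoker_therapy = registry$code[registry$base_category == "SMOKER" &
                                        therapy],
       parent = registry$code[registry$kind == "parent"])
}

simulate_patient <- function(id, params, pools) {
  birth_year <- sample(params$birth_year_range[1]:params$birth_year_range[2],
                       1L)
  ever <- stats::runif(1) < params$initiation_prob
  init_age <- sample(params$initiation_age[1]:params$initiation_age[2], 1L)
  init_year <- if (ever) birth_year + init_age else NA_integer_
  years <- birth_year:params$end_year
  state <- character(length(years))
  cur <- "NEVER"
  for (k in seq_along(years)) {
    y <- years[k]
    if (cur == "NEVER") {
      if (!is.na(init_year) && y >= init_year) cur <- "SMOKER"
    } else if (cur == "SMOKER") {
      if (stats::runif(1) < params$annual_quit_prob) cur <- "EX"
    } else if (stats::runif(1) < params$annual_relapse_prob) {
      cur <- "SMOKER"
    }
    state[k] <- cur
  }
  truth <- data.frame(patient_id = id, year = years, status = state,
                      stringsAsFactors = FALSE)

  ev_dates <- as.Date(character(0)); ev_codes <- character(0)
  ev_values <- numeric(0)
  rec_years <- years[years >= params$records_from]
  for (y in rec_years) {
    n_visits <- stats::rpois(1, params$visit_rate)
    if (n_visits == 0) next
    days <- sort(sample.int(365L, n_visits, replace = TRUE))
    recorded <- stats::runif(n_visits) < params$record_prob
    st <- state[match(y, years)]
    for (v in which(recorded)) {
      date <- as.Date(sprintf("%d-01-01", y)) + days[v] - 1L
      if (st == "NEVER") {
        code <- sample(pools$never, 1L); val <- NA_real_
      } else if (st == "EX") {
        code <- sample(pools$ex, 1L); val <- NA_real_
      } else if (stats::runif(1) < params$therapy_code_prob &&
                 length(pools$smoker_therapy) > 0) {
        code <- sample(pools$smoker_therapy, 1L); val <- NA_real_
      } else if (stats::runif(1) < 0.1 && length(pools$parent) > 0) {
        # bare hierarchy parent recorded with a cigarettes/day value
        code <- pools$parent[1L]; val <- sample(5:30, 1L)
      } else {
        code <- sample(pools$smoker_status, 1L); val <- NA_real_
      }
      ev_dates <- c(ev_dates, date); ev_codes <- c(ev_codes, code)
      ev_values <- c(ev_values, val)
    }
  }
  events <- data.frame(patient_id = rep(id, length(ev_dates)),
                       event_date = ev_dates, code = ev_codes,
                       value = ev_values, stringsAsFactors = FALSE)

  survey <- NULL
  age_at_survey <- params$survey_year - birth_year
  if (age_at_survey >= 16) {
    sdate <- as.Date(sprintf("%d-01-01", params$survey_year)) +
      sample.int(365L, 1L) - 1L
    st <- state[match(params$survey_year, years)]
    reported <- st
    if (st == "EX" && stats::runif(1) < params$never_misreport_prob) {
      reported <- "NEVER"
    }
    item <- switch(reported,
                   SMOKER = sample(1:2, 1L),
                   EX = sample(3:4, 1L),
                   NEVER = 5L)
    survey <- data.frame(patient_id = id, survey_date = sdate,
                         item = item,
                         status = c(SMOKER = "SMOKER", EX = "EX_SMOKER",
                                    NEVER = "NEVER_SMOKER")[[reported]],
                         stringsAsFactors = FALSE)
  }
  demo <- data.frame(patient_id = id,
                     birth_date = as.Date(sprintf("%d-07-01", birth_year)),
                     sex = sample(c("F", "M"), 1L),
                     stringsAsFactors = FALSE)
  list(events = events, survey = survey, truth = truth, demo = demo)
}

#' True smoking state of a synthetic patient at a date
#'
#' @param truth The \code{truth} data frame from [generate_cohort()].
#' @param patient_id Patient identifier.
#' @param date Calendar date.
#' @return \code{"NEVER"}, \code{"SMOKER"} or \code{"EX"}; \code{NA} outside
#'   the patient's simulated years.
#' @export
true_status_at <- function(truth, patient_id, date) {
  year <- as.integer(format(as.Date(date), "%Y"))
  hit <- truth$patient_id == patient_id & truth$year == year
  if (!any(hit)) return(NA_character_)
  truth$status[which(hit)[1]]
}

#' Write a synthetic cohort to CSV files
#'
#' Writes \code{events.csv}, \code{surveys.csv}, \code{truth.csv} and
#' \code{demographics.csv} under \code{dir} in the package's standard
#' formats (ISO-8601 dates, headers, deterministic row order).
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE,
                     na = "")
  }
  ev <- cohort$events[order(cohort$events$patient_id,
                            cohort$events$event_date), ]
  wr(ev, "events.csv")
  wr(cohort$surveys[order(cohort$surveys$patient_id), ], "surveys.csv")
  wr(cohort$truth, "truth.csv")
  wr(cohort$demographics, "demographics.csv")
  invisible(dir)
}
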