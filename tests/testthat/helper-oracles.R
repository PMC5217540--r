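# Independent oracles and scenario builders used across test files.

# Brute-force classifier: a literal enumeration of the census-scenario
# rules, written directly against the raw (date, category) events — no
# shared code with the package's classifier.
oracle_classify <- function(ev, census, temporal = TRUE) {
  if (nrow(ev) == 0) return("NO_INFORMATION")
  if (all(ev$event_date > census)) {
    if (all(ev$category == "SMOKER")) return("LIKELY_SMOKER")
    return("UNKNOWN_SMOKING_STATUS")
  }
  span <- lapply(split(ev$event_date, ev$category), range)
  inside <- names(span)[vapply(span, function(r) {
    r[1] <= census && census <= r[2]
  }, logical(1))]
  hist_smoke <- any(ev$event_date <= census &
                      ev$category %in% c("EX", "SMOKER"))
  as_status <- c(NEVER = "NEVER_SMOKER", EX = "EX_SMOKER",
                 SMOKER = "SMOKER")
  if ("SMOKER" %in% inside && length(inside) > 1) return("RELAPSED_SMOKER")
  if ("SMOKER" %in% inside) return("SMOKER")
  if ("EX" %in% inside) return("EX_SMOKER")
  if ("NEVER" %in% inside) {
    if (temporal && hist_smoke) return("EX_SMOKER")
    return("NEVER_SMOKER")
  }
  b <- do.call(rbind, lapply(names(span), function(cat) {
    data.frame(cat = cat, date = span[[cat]], stringsAsFactors = FALSE)
  }))
  b$dist <- abs(as.numeric(b$date - census))
  b <- b[order(b$dist, b$date > census,
               match(b$cat, c("SMOKER", "EX", "NEVER"))), ]
  provisional <- b$cat[1]
  if (provisional == "NEVER" && temporal && hist_smoke) return("EX_SMOKER")
  as_status[[provisional]]
}

# Brute-force Cohen's kappa: explicit double loop over cells.
oracle_kappa <- function(g) {
  n <- sum(g)
  po <- 0
  pe <- 0
  for (i in seq_len(nrow(g))) {
    po <- po + g[i, i] / n
    ri <- 0
    ci <- 0
    for (j in seq_len(ncol(g))) {
      ri <- ri + g[i, j]
      ci <- ci + g[j, i]
    }
    pe <- pe + (ri / n) * (ci / n)
  }
  (po - pe) / (1 - pe)
}

# Random dated-category event sets for property tests.
random_events <- function(n_events) {
  if (n_events == 0) {
    return(data.frame(event_date = as.Date(character(0)),
                      category = character(0)))
  }
  data.frame(
    event_date = as.Date("2000-01-01") + sample.int(5500L, n_events,
                                                    replace = TRUE),
    category = sample(c("NEVER", "EX", "SMOKER"), n_events, replace = TRUE),
    stringsAsFactors = FALSE)
}

random_census <- function() {
  as.Date("1999-01-01") + sample.int(6500L, 1L)
}

# Single-patient timeline realising all seven census scenarios:
# an ex spell, an overlapping smoker spell, then a late never spell.
scenario_timeline <- function() {
  data.frame(
    patient_id = "scenario",
    event_date = as.Date(c("2000-01-01", "2006-01-01",   # ex span
                           "2003-01-01", "2009-01-01",   # smoker span
                           "2010-01-01", "2012-01-01")), # never span
    code = c("137F.", "137F.", "137R.", "137R.", "1371.", "1371."),
    stringsAsFactors = FALSE)
}

scenario_censuses <- function() {
  as.Date(c(A = "1999-06-01",  # before every recorded date
            B = "2001-06-01",  # inside the ex span only
            C = "2004-06-01",  # ex and smoker spans overlap
            D = "2007-06-01",  # smoker span only
            E = "2009-06-01",  # between spans, last smoker date nearest
            F = "2011-06-01",  # inside the never span, smoking history
            G = "2013-06-01")) # after every recorded date
}

classify_at <- function(events, registry, census, temporal = TRUE) {
  ie <- informative_events(events, registry)
  s <- summarize_patient(events, registry)
  classify_full(s, ie, census, temporal_check = temporal)
}
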