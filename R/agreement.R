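# GP-versus-survey agreement: contingency tables, Cohen's kappa, discordance.

TABLE_LABELS <- c("missing", "smoker", "ex_smoker", "never_smoker")
LABEL_TO_STATUS <- stats::setNames(COLLAPSED_STATUSES, TABLE_LABELS)
STATUS_TO_LABEL <- stats::setNames(TABLE_LABELS, COLLAPSED_STATUSES)

#' Derive survey smoking status from the five-item survey question
#'
#' The survey question offers five responses: daily smoker (1), occasional
#' smoker (2), former daily smoker (3), former occasional smoker (4), never
#' smoked (5). Items 1-2 map to smoker, 3-4 to ex-smoker, 5 to never
#' smoker; a missing item is missing status.
#'
#' @param item Integer vector in 1..5, \code{NA} allowed.
#' @return Character vector over the four collapsed statuses.
#' @export
survey_status_from_item <- function(item) {
  item <- as.integer(item)
  if (any(!is.na(item) & (item < 1L | item > 5L))) {
    stop("survey item must be in 1..5 or NA", call. = FALSE)
  }
  out <- rep("MISSING", length(item))
  out[!is.na(item) & item <= 2L] <- "SMOKER"
  out[!is.na(item) & item %in% c(3L, 4L)] <- "EX_SMOKER"
  out[!is.na(item) & item == 5L] <- "NEVER_SMOKER"
  out
}

#' Read a survey-response table
#'
#' @param path CSV with columns \code{patient_id,survey_date} and either
#'   \code{item} (1..5, blank allowed) or \code{status} (one of
#'   \code{missing,smoker,ex_smoker,never_smoker}); when both are present
#'   and the item is non-missing, the status must agree with the item
#'   mapping.
#' @return Data frame \code{patient_id,survey_date,item,status} with
#'   \code{status} on the collapsed scale.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("patient_id", "survey_date")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("survey file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("item" %in% names(df)) && !("status" %in% names(df))) {
    stop("survey file needs an 'item' or 'status' column", call. = FALSE)
  }
  item <- if ("item" %in% names(df)) {
    suppressWarnings(as.integer(df$item))
  } else {
    rep(NA_integer_, nrow(df))
  }
  status <- if ("status" %in% names(df)) {
    lab <- tolower(df$status)
    bad <- !(lab %in% c(TABLE_LABELS, ""))
    if (any(bad)) {
      stop("unknown survey status label(s): ",
           paste(unique(df$status[bad]), collapse = ", "), call. = FALSE)
    }
    ifelse(lab == "", "MISSING", unname(LABEL_TO_STATUS[lab]))
  } else {
    survey_status_from_item(item)
  }
  if ("item" %in% names(df) && "status" %in% names(df)) {
    derived <- survey_status_from_item(item)
    clash <- !is.na(item) & derived != status
    if (any(clash)) {
      stop("survey item and status disagree at data row ",
           which(clash)[1], call. = FALSE)
    }
  }
  data.frame(patient_id = df$patient_id,
             survey_date = as.Date(df$survey_date),
             item = item,
             status = status,
             stringsAsFactors = FALSE)
}

#' Build a GP-versus-survey agreement table
#'
#' Cross-tabulates each surveyed person's GP-derived collapsed status (rows)
#' against their survey self-report (columns) on the four levels missing,
#' smoker, ex-smoker, never smoker. Surveyed patients absent from the GP
#' status table count in the GP-missing row, mirroring survey respondents
#' with no usable GP record.
#'
#' @param gp_statuses Data frame \code{patient_id,status} of collapsed GP
#'   statuses (e.g. from [classify_cohort()] with \code{collapse = TRUE}).
#' @param survey Data frame with \code{patient_id} and \code{status} on the
#'   collapsed scale (see [read_survey()]); one row per surveyed person.
#' @return An \code{agreement_table}: 4x4 integer matrix with
#'   row/column dimnames \code{missing,smoker,ex_smoker,never_smoker}.
#' @export
build_agreement_table <- function(gp_statuses, survey) {
  if (anyDuplicated(survey$patient_id)) {
    stop("duplicate patient_id in survey table: ",
         survey$patient_id[duplicated(survey$patient_id)][1], call. = FALSE)
  }
  idx <- match(survey$patient_id, gp_statuses$patient_id)
  gp <- ifelse(is.na(idx), "MISSING", gp_statuses$status[idx])
  gp[is.na(gp)] <- "MISSING"
  stopifnot(all(gp %in% COLLAPSED_STATUSES),
            all(survey$status %in% COLLAPSED_STATUSES))
  counts <- table(factor(unname(STATUS_TO_LABEL[gp]), levels = TABLE_LABELS),
                  factor(unname(STATUS_TO_LABEL[survey$status]),
                         levels = TABLE_LABELS))
  as_agreement_table(matrix(as.integer(counts), 4, 4,
                            dimnames = list(GP = TABLE_LABELS,
                                            survey = TABLE_LABELS)))
}

#' Construct an agreement table from a 4x4 count matrix
#'
#' @param counts 4x4 nonnegative matrix, rows GP, columns survey, in the
#'   order missing, smoker, ex-smoker, never smoker.
#' @param suppressed Optional logical 4x4 matrix flagging cells whose true
#'   small count was disclosure-suppressed at source and has been stored at
#'   its marginal-implied value.
#' @return An \code{agreement_table}.
#' @export
as_agreement_table <- function(counts, suppressed = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) == 4,
            all(counts >= 0), all(counts == round(counts)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(GP = TABLE_LABELS, survey = TABLE_LABELS)
  if (!is.null(suppressed)) {
    stopifnot(is.logical(suppressed), all(dim(suppressed) == c(4, 4)))
    attr(counts, "suppressed") <- unname(suppressed)
  }
  class(counts) <- c("agreement_table", class(counts))
  counts
}

#' @export
print.agreement_table <- function(x, suppress_small = FALSE, ...) {
  cat("GP vs survey agreement table (rows GP, columns survey)\n")
  m <- format_table_cells(x, suppress_small)
  full <- rbind(cbind(m, Totals = format(rowSums(unclass(x)))),
                Totals = c(format(colSums(unclass(x))), format(sum(x))))
  print(full, quote = FALSE, right = TRUE)
  invisible(x)
}

format_table_cells <- function(x, suppress_small) {
  m <- matrix(format(unclass(x)), 4, 4, dimnames = dimnames(x))
  if (suppress_small) m[unclass(x) < 5] <- "<5"
  m
}

#' Write an agreement table to CSV
#'
#' @param table An \code{agreement_table}.
#' @param path Output path.
#' @param suppress_small Render cells with counts under 5 as \code{"<5"}
#'   (small-number disclosure control); totals are not written, so no
#'   derived quantity is distorted.
#' @return \code{path}, invisibly.
#' @export
write_agreement_table <- function(table, path, suppress_small = FALSE) {
  m <- format_table_cells(table, suppress_small)
  df <- data.frame(GP = TABLE_LABELS, m, check.names = FALSE)
  names(df) <- c("", TABLE_LABELS)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an agreement table from CSV
#'
#' Cells rendered \code{"<5"} by disclosure control are read as \code{NA}
#' and flagged in the \code{suppressed} attribute.
#'
#' @param path CSV written by [write_agreement_table()] (or hand-built with
#'   the same 4-row/4-column labelled layout).
#' @return An \code{agreement_table}.
#' @export
read_agreement_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (ncol(df) != 5 || !all(tolower(df[[1]]) == TABLE_LABELS) ||
      !all(tolower(names(df)[-1]) == TABLE_LABELS)) {
    stop("agreement-table CSV must have rows/columns labelled ",
         paste(TABLE_LABELS, collapse = ","), call. = FALSE)
  }
  cells <- as.matrix(df[, -1])
  supp <- cells == "<5"
  cells[supp] <- NA
  counts <- matrix(as.integer(cells), 4, 4)
  if (any(supp)) {
    counts[supp] <- 0L  # placeholder; flagged below
    as_agreement_table(counts, suppressed = supp)
  } else {
    as_agreement_table(counts)
  }
}

#' Drop the missing row and column (complete pairs)
#'
#' Agreement statistics are computed over people with a known status in both
#' sources; this removes the missing row and column, leaving the 3x3 grid
#' over smoker, ex-smoker, never smoker.
#'
#' @param table An \code{agreement_table}.
#' @return 3x3 integer matrix.
#' @export
complete_pairs <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  m <- unclass(table)[2:4, 2:4]
  attr(m, "suppressed") <- NULL
  m
}

#' Amalgamate ex-smokers and never-smokers into non-smokers
#'
#' Collapses a 3x3 smoker/ex/never grid to the two-status solution
#' (current smoker versus current non-smoker) on both axes.
#'
#' @param grid 3x3 count matrix in the order smoker, ex-smoker, never
#'   smoker.
#' @return 2x2 matrix with levels \code{smoker}, \code{non_smoker}.
#' @export
collapse_two_status <- function(grid) {
  grid <- as.matrix(grid)
  stopifnot(nrow(grid) == 3, ncol(grid) == 3)
  out <- matrix(c(grid[1, 1], sum(grid[1, 2:3]),
                  sum(grid[2:3, 1]), sum(grid[2:3, 2:3])),
                2, 2, byrow = TRUE,
                dimnames = list(GP = c("smoker", "non_smoker"),
                                survey = c("smoker", "non_smoker")))
  out
}

#' Cohen's kappa with large-sample confidence interval
#'
#' Unweighted kappa \eqn{\kappa = (P_o - P_e)/(1 - P_e)} on a square count
#' grid, where \eqn{P_o} is the observed proportion of agreement (diagonal
#' sum over the grand total) and \eqn{P_e = \sum_i r_i c_i / N^2} the
#' agreement expected by chance from the marginals. The standard error is
#' the large-sample form \eqn{se = \sqrt{P_o (1 - P_o) / (N (1 - P_e)^2)}}
#' with a normal 95\% interval, and the point estimate is labelled with the
#' conventional agreement bands: up to 0.20 poor, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 good, 0.81-1.00 very good.
#'
#' @param grid Square nonnegative count matrix (any number of categories
#'   >= 2) with raters in the same category order on both axes.
#' @param conf_level Confidence level for the normal interval.
#' @return A \code{kappa_result}: list with \code{kappa}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{n}, \code{po}, \code{pe},
#'   \code{band}.
#' @export
#' @examples
#' g <- matrix(c(20, 5, 5, 20), 2, 2)
#' cohen_kappa(g)
cohen_kappa <- function(grid, conf_level = 0.95) {
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid) || nrow(grid) < 2) {
    stop("kappa needs a square grid with at least two categories",
         call. = FALSE)
  }
  if (any(grid < 0) || anyNA(grid)) {
    stop("kappa grid must be nonnegative and complete", call. = FALSE)
  }
  n <- sum(grid)
  if (n <= 0) stop("kappa grid is empty", call. = FALSE)
  po <- sum(diag(grid)) / n
  pe <- sum(rowSums(grid) * colSums(grid)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    stop("kappa undefined: chance agreement is 1 (degenerate marginals)",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(kappa = kappa, se = se,
              ci_low = kappa - z * se, ci_high = kappa + z * se,
              n = n, po = po, pe = pe, band = altman_band(kappa))
  class(out) <- "kappa_result"
  out
}

#' Agreement band for a kappa value
#'
#' @param kappa Numeric kappa in [-1, 1].
#' @return One of \code{poor}, \code{fair}, \code{moderate}, \code{good},
#'   \code{very good}.
#' @export
altman_band <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa >= -1, kappa <= 1 + 1e-12)
  if (kappa <= 0.20) "poor"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "good"
  else "very good"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.2f (95%% CI %.2f, %.2f)  n = %d  [%s]\n",
              x$kappa, x$ci_low, x$ci_high, x$n, x$band))
  invisible(x)
}

#' Discordance summary of an agreement table
#'
#' The headline disagreement rates between the two sources, each reported
#' with its numerator and denominator: the share of survey never-smokers the
#' GP record classifies as ex-smokers (the signature of past smoking
#' evidence overriding a never self-report), the shares of survey ex-smokers
#' classified never-smoker and smoker, the relative excess of GP-classified
#' smokers over survey smokers, and the proportion missing in each source.
#' Survey-column denominators are the full column totals (including
#' GP-missing rows).
#'
#' @param table An \code{agreement_table}.
#' @return Data frame \code{measure,numerator,denominator,percent}; a zero
#'   denominator yields \code{NA} percent rather than an error.
#' @export
discordance_summary <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  m <- unclass(table)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rows <- list(
    c("survey_never_gp_ex", m["ex_smoker", "never_smoker"],
      cs[["never_smoker"]]),
    c("survey_ex_gp_never", m["never_smoker", "ex_smoker"],
      cs[["ex_smoker"]]),
    c("survey_ex_gp_smoker", m["smoker", "ex_smoker"], cs[["ex_smoker"]]),
    c("gp_excess_smokers", rs[["smoker"]] - cs[["smoker"]], cs[["smoker"]]),
    c("missing_gp", rs[["missing"]], n),
    c("missing_survey", cs[["missing"]], n))
  out <- data.frame(
    measure = vapply(rows, `[[`, "", 1),
    numerator = as.numeric(vapply(rows, `[[`, "", 2)),
    denominator = as.numeric(vapply(rows, `[[`, "", 3)),
    stringsAsFactors = FALSE)
  out$percent <- mapply(pct, out$numerator, out$denominator)
  out
}

# report percentages at the source's printed precision:
# whole numbers, one decimal below 5%
format_percent <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 5, sprintf("%.1f%%", p), sprintf("%.0f%%", round(p))))
}
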