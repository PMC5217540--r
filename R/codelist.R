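# Code registry: maps clinical (Read V2 style) codes to smoking categories.

#' Read a smoking codelist into a code registry
#'
#' A codelist maps each clinical code to a base smoking category
#' (\code{NEVER}, \code{EX} or \code{SMOKER}), a descriptive sub-group, a
#' kind (plain status code, intensity code, cessation-therapy prescription,
#' cessation administration, advice, or the bare hierarchy parent code) and,
#' for intensity codes, an intensity class. The parent code carries no
#' category of its own: it is informative only when recorded with a positive
#' numeric value (cigarettes per day), in which case it indicates a current
#' smoker.
#'
#' @param path Path to a CSV file with header columns
#'   \code{code,base_category,subgroup,kind,intensity_class}.
#'   \code{base_category} may be blank only for \code{kind = "parent"};
#'   \code{intensity_class} may be blank except for \code{kind = "intensity"}.
#' @return An object of class \code{code_registry}: a data frame with one row
#'   per code, plus the attribute carrying the status-only subset (codes whose
#'   kind is not therapy, cessation administration or advice).
#' @seealso [default_codelist()] for the representative codelist shipped with
#'   the package, [classify_code()] for per-code classification.
#' @export
#' @examples
#' reg <- default_codelist()
#' nrow(reg)
#' classify_code(reg, "1371.")
read_codelist <- function(path) {
  if (!file.exists(path)) {
    stop("codelist file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  as_code_registry(df)
}

#' Construct a code registry from a data frame
#'
#' @param df Data frame with columns \code{code}, \code{base_category},
#'   \code{subgroup}, \code{kind} and optionally \code{intensity_class}.
#' @return A \code{code_registry}.
#' @export
as_code_registry <- function(df) {
  required <- c("code", "base_category", "subgroup", "kind")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("codelist is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"intensity_class" %in% names(df)) df$intensity_class <- ""
  df <- df[required_cols_order(df)]
  for (nm in names(df)) df[[nm]] <- trimws(as.character(df[[nm]]))

  dup <- df$code[duplicated(df$code)]
  if (length(dup) > 0) {
    stop("duplicate code(s) in codelist: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$kind), CODE_KINDS)
  if (length(bad_kind) > 0) {
    stop("unknown code kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  is_parent <- df$kind == "parent"
  bad_cat <- !is_parent & !(df$base_category %in% BASE_CATEGORIES)
  if (any(bad_cat)) {
    stop("invalid base_category for code(s): ",
         paste(df$code[bad_cat], collapse = ", "), call. = FALSE)
  }
  if (any(is_parent & df$base_category != "")) {
    stop("parent codes must not carry a base_category", call. = FALSE)
  }
  ta <- df$kind %in% c("therapy", "cessation_admin")
  if (any(ta & !(df$base_category %in% c("SMOKER", "EX")))) {
    stop("therapy/cessation_admin codes must map to SMOKER or EX",
         call. = FALSE)
  }
  has_int <- df$intensity_class != ""
  bad_int <- has_int & !(df$intensity_class %in% INTENSITY_CLASSES)
  if (any(bad_int)) {
    stop("invalid intensity_class for code(s): ",
         paste(df$code[bad_int], collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("code_registry", "data.frame")
  df
}

required_cols_order <- function(df) {
  c("code", "base_category", "subgroup", "kind", "intensity_class")
}

#' Representative default codelist
#'
#' A synthetic, representative codelist mirroring the group and sub-group
#' structure of the smoking Read-code hierarchy (never-smoked codes,
#' ex-smoker general/intensity/type/admin codes, current-smoker status and
#' intensity codes, nicotine-replacement and other cessation-therapy
#' prescription codes, cessation administration and advice codes, and the
#' bare parent code). It is a stand-in for a full production codelist: code
#' strings are illustrative, and large sub-groups (e.g. the many NRT product
#' codes) are collapsed to a few representative entries. User-supplied
#' codelists loaded with [read_codelist()] are first-class everywhere a
#' registry is accepted.
#'
#' @return A \code{code_registry}.
#' @export
default_codelist <- function() {
  path <- system.file("extdata", "codelist-synthetic.csv",
                      package = "readsmoke", mustWork = TRUE)
  read_codelist(path)
}

#' Subset a registry to status codes only
#'
#' Drops therapy, cessation-administration and advice codes, leaving plain
#' status/intensity codes and the parent code. This is the code universe used
#' by the nearest-status-code comparison variant.
#'
#' @param registry A \code{code_registry}.
#' @return A \code{code_registry} restricted to status-type codes.
#' @export
status_only_registry <- function(registry) {
  stopifnot(inherits(registry, "code_registry"))
  out <- registry[!(registry$kind %in% STATUS_EXCLUDED_KINDS), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("code_registry", "data.frame")
  out
}

#' Classify clinical codes to a base smoking category
#'
#' Resolves each code against the registry. Non-parent codes return their
#' base category. The parent code returns \code{SMOKER} when recorded with a
#' positive numeric value (a cigarettes-per-day count) and is uninformative
#' with a zero or absent value, since a zero may have been entered for either
#' a non-smoker or a smoker. Codes absent from the registry (ordinary
#' non-smoking clinical codes in a real extract) are uninformative, not
#' errors.
#'
#' @param registry A \code{code_registry}.
#' @param code Character vector of clinical codes.
#' @param value Optional numeric vector of recorded values (recycled);
#'   \code{NA} means no value recorded. Negative values are rejected.
#' @return Character vector over \code{c("NEVER","EX","SMOKER",
#'   "UNINFORMATIVE")}.
#' @export
classify_code <- function(registry, code, value = NA_real_) {
  stopifnot(inherits(registry, "code_registry"))
  n <- length(code)
  value <- rep_len(as.numeric(value), n)
  if (any(!is.na(value) & value < 0)) {
    stop("negative recorded value", call. = FALSE)
  }
  idx <- match(code, registry$code)
  out <- rep(UNINFORMATIVE, n)
  known <- !is.na(idx)
  kind <- registry$kind[idx[known]]
  cat <- registry$base_category[idx[known]]
  res <- ifelse(kind == "parent",
                ifelse(!is.na(value[known]) & value[known] > 0,
                       "SMOKER", UNINFORMATIVE),
                cat)
  out[known] <- res
  out
}

#' Classify smoking intensity from consumption or time to first cigarette
#'
#' Maps a daily cigarette/tobacco consumption count and/or the number of
#' minutes before the first cigarette on waking to an intensity class.
#' Consumption bands are half-open and escalate: 1-9 light, 10-19 medium,
#' 20-39 heavy, 40+ very heavy. Time-to-first-cigarette bands: over 60
#' minutes light, over 30 (up to 60) medium, over 5 (up to 30) heavy, 5
#' minutes or under very heavy. When both measures are supplied the heavier
#' class wins. A consumption count of zero is uninformative (a recorded zero
#' may describe a non-smoker or a smoker). The trivial-smoker class has no
#' numeric band; it is assignable only via explicit trivial-smoker codes.
#'
#' @param cigs_per_day Optional nonnegative count (vectorised).
#' @param minutes_to_first Optional nonnegative minutes (vectorised).
#' @return Character vector of intensity classes or \code{"UNINFORMATIVE"}.
#' @export
#' @examples
#' classify_intensity(cigs_per_day = 5)
#' classify_intensity(minutes_to_first = 4)
#' classify_intensity(cigs_per_day = 15, minutes_to_first = 4)
classify_intensity <- function(cigs_per_day = NULL, minutes_to_first = NULL) {
  if (is.null(cigs_per_day) && is.null(minutes_to_first)) {
    stop("supply cigs_per_day and/or minutes_to_first", call. = FALSE)
  }
  n <- max(length(cigs_per_day), length(minutes_to_first), 1L)
  cigs <- if (is.null(cigs_per_day)) rep(NA_real_, n) else
    rep_len(as.numeric(cigs_per_day), n)
  mins <- if (is.null(minutes_to_first)) rep(NA_real_, n) else
    rep_len(as.numeric(minutes_to_first), n)
  if (any(!is.na(cigs) & cigs < 0) || any(!is.na(mins) & mins < 0)) {
    stop("intensity inputs must be nonnegative", call. = FALSE)
  }
  if (any(is.na(cigs) & is.na(mins))) {
    stop("each case needs cigs_per_day or minutes_to_first", call. = FALSE)
  }
  # rank 0 = uninformative; 1..4 = light..very_heavy
  rank_cigs <- ifelse(is.na(cigs) | cigs == 0, 0,
               ifelse(cigs < 10, 1, ifelse(cigs < 20, 2,
               ifelse(cigs < 40, 3, 4))))
  rank_mins <- ifelse(is.na(mins), 0,
               ifelse(mins > 60, 1, ifelse(mins > 30, 2,
               ifelse(mins > 5, 3, 4))))
  rank <- pmax(rank_cigs, rank_mins)
  ifelse(rank == 0, UNINFORMATIVE,
         c("light", "medium", "heavy", "very_heavy")[rank])
}

#' Write a code registry back to CSV
#'
#' @param registry A \code{code_registry}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_codelist <- function(registry, path) {
  stopifnot(inherits(registry, "code_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @export
print.code_registry <- function(x, ...) {
  cat("Code registry:", nrow(x), "codes;",
      sum(x$kind == "parent"), "parent,",
      sum(x$kind %in% STATUS_EXCLUDED_KINDS), "therapy/admin/advice\n")
  tab <- table(factor(x$base_category,
                      levels = c(BASE_CATEGORIES, "")))
  cat("  base categories: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n", sep = "")
  invisible(x)
}
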