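# Published GP-versus-survey contingency tables shipped as fixtures.

#' Published GP-versus-survey reference tables
#'
#' The three contingency tables from the national person-level linkage
#' comparison of GP-derived smoking status against Welsh Health Survey
#' (2013/2014) self-report, one per classification variant: the full
#' life-course algorithm, the variant without temporal checking, and the
#' nearest-status-code variant. Each is a 4x4 grid (GP rows, survey
#' columns) over missing, smoker, ex-smoker, never smoker, with grand total
#' 6836 linked respondents.
#'
#' Two source-level details are resolved cell-consistently:
#' \itemize{
#'   \item the missing/missing cell of every table was
#'     disclosure-suppressed at source (rendered "<5"); it is stored at its
#'     marginal-implied value, 5, and flagged in the \code{suppressed}
#'     attribute;
#'   \item the nearest-status table's published missing-row total (423) is
#'     inconsistent with its column marginals, which imply 432; the cells
#'     stored here are the marginal-consistent ones (see the \code{erratum}
#'     attribute on that table).
#' }
#'
#' @param variant Optionally a single variant name; by default all three
#'   tables are returned.
#' @return A named list of \code{agreement_table} objects (\code{full},
#'   \code{no_temporal}, \code{nearest}), or a single table when
#'   \code{variant} is given.
#' @export
#' @examples
#' tabs <- reference_tables()
#' sum(tabs$full)
#' cohen_kappa(complete_pairs(tabs$full))
reference_tables <- function(variant = c("all", "full", "no_temporal",
                                         "nearest")) {
  variant <- match.arg(variant)
  files <- c(full = "gp-whs-full.csv",
             no_temporal = "gp-whs-no-temporal.csv",
             nearest = "gp-whs-nearest.csv")
  supp <- matrix(FALSE, 4, 4)
  supp[1, 1] <- TRUE  # "<5" at source; stored at marginal-implied value
  load_one <- function(file) {
    path <- system.file("extdata", file, package = "readsmoke",
                        mustWork = TRUE)
    tab <- read_agreement_table(path)
    as_agreement_table(unclass(tab), suppressed = supp)
  }
  tabs <- lapply(files, load_one)
  attr(tabs$nearest, "erratum") <-
    "published missing-row total 423; cells imply 432 (stored)"
  if (variant == "all") tabs else tabs[[variant]]
}
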