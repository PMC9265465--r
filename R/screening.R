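#' Percent change of a predicted property versus a reference
#'
#' Signed relative change `100 * (new - reference) / reference`. The sign
#' convention follows tabulated derivative-evaluation practice: a property
#' that decreases gives a negative change even when prose would quote the
#' magnitude as a "reduction".
#'
#' @param new numeric vector of new (derivative) values.
#' @param reference scalar reference (parent) value; must be nonzero.
#' @param digits decimal places for the reported value (default 2,
#'   half-up); use `NULL` for no rounding.
#' @return numeric vector of percent changes.
#' @export
#' @examples
#' property_change(4.623, 3.696)  # +25.08
property_change <- function(new, reference, digits = 2) {
  check_number(reference, "reference")
  if (reference == 0) stop_fq("reference value is zero: percent change undefined")
  if (any(!is.finite(new))) stop_fq("new values must be finite")
  pct <- 100 * (new - reference) / reference
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Bioconcentration red-line screen
#'
#' Persistent-pollutant convention: a chemical with logKow strictly greater
#' than 5 crosses the bioconcentration red line.
#'
#' @param logkow numeric octanol-water partition coefficient(s), log10.
#' @return logical vector, `TRUE` = passes (logKow <= 5).
#' @export
screen_bioconcentration <- function(logkow) {
  if (any(!is.finite(logkow))) stop_fq("logKow must be finite")
  !(logkow > 5)
}

#' Rank antibiotic derivatives against their parent compound
#'
#' For each derivative, computes the signed percent change versus the parent
#' for the composite biodegradability value (cv), the per-receptor predicted
#' activities, genotoxicity (ploec), bioconcentration (logkow), and
#' photodegradability (logt12); applies the bioconcentration red-line
#' screen; and sorts by cv improvement, largest first (ties broken by name).
#'
#' @param records data frame with columns `name`, `cv`, `g1gkq`, `g1ob0`,
#'   `g5m0k`, `ploec`, `logkow`, `logt12`, `is_parent` (exactly one row with
#'   `is_parent == 1`). Extra columns are carried through.
#' @param digits decimal places for the change columns (default 2).
#' @return data frame of the derivatives (parent excluded) with added
#'   `*_change` columns, `redline_pass`, and a `parent` attribute.
#' @export
#' @examples
#' recs <- read.csv(fq_example("mox_derivatives.csv"))
#' head(rank_derivatives(recs))
rank_derivatives <- function(records, digits = 2) {
  needed <- c("name", "cv", "g1gkq", "g1ob0", "g5m0k", "ploec", "logkow",
              "logt12", "is_parent")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop_fq(sprintf("records are missing column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  }
  ip <- which(records$is_parent == 1)
  if (length(ip) != 1L) stop_fq("exactly one record must be flagged as parent")
  parent <- records[ip, , drop = FALSE]
  der <- records[-ip, , drop = FALSE]
  props <- c("cv", "g1gkq", "g1ob0", "g5m0k", "ploec", "logkow", "logt12")
  for (pr in props) {
    der[[paste0(pr, "_change")]] <-
      property_change(der[[pr]], parent[[pr]], digits = digits)
  }
  der$redline_pass <- screen_bioconcentration(der$logkow)
  ord <- order(-der$cv_change, der$name)
  out <- der[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parent") <- parent
  out
}

#' Summarize a soil nutrient survey
#'
#' Arithmetic mean of each nutrient content column across sampling sites,
#' rounded half-up to match printed survey conventions. The suggested
#' amendment levels are downstream simulation configuration, not derivable
#' from the means; they are carried through as metadata.
#'
#' @param survey data frame with numeric columns `c`, `n`, `p` (g/kg),
#'   one row per site.
#' @param rounding decimal places for the means (default 2).
#' @param additions optional named numeric vector of amendment levels
#'   (g/kg) stored alongside the means.
#' @return list with `means` (named vector), `n_sites`, and `additions`.
#' @export
#' @examples
#' summarize_survey(read.csv(fq_example("soil_survey.csv")))
summarize_survey <- function(survey, rounding = 2,
                             additions = c(c = 2, n = 1, p = 2)) {
  cols <- c("c", "n", "p")
  if (!all(cols %in% names(survey))) {
    stop_fq("survey needs columns 'c', 'n', 'p'")
  }
  if (nrow(survey) < 1L) stop_fq("survey has no rows")
  vals <- as.matrix(survey[, cols])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_fq("nutrient contents must be finite and nonnegative")
  }
  means <- round_half_up(colMeans(vals), rounding)
  list(means = means, n_sites = nrow(survey), additions = additions)
}
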