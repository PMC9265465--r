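#' Paths to packaged example data
#'
#' The package ships small plain-text reference tables from a published
#' docking and composting-simulation study of 49 fluoroquinolones:
#' LibDock score matrices against three thermophilic degradation enzymes
#' (1GKQ, 1OB0, 5M0K), the published composite-biodegradability values,
#' the moxifloxacin derivative evaluation tables, a soil nutrient survey,
#' the composting amendment design, and the MM/PBSA binding energies of
#' the composting scenarios and agricultural field-measure trials.
#'
#' @param file name of a file under `extdata`; `NULL` lists available files.
#' @return a file path, or a character vector of file names.
#' @export
#' @examples
#' fq_example()
#' head(read.csv(fq_example("fq_docking_scores.csv"), check.names = FALSE))
fq_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "fqbiodeg"))
  } else {
    path <- system.file("extdata", file, package = "fqbiodeg")
    if (identical(path, "")) stop_fq(sprintf("no packaged file '%s'", file))
    path
  }
}

#' Read a compounds-by-receptors docking score matrix from CSV
#'
#' Expects a header `compound,<receptor>,...` with one row per compound.
#' Typographic minus signs (U+2212) are normalized on read.
#'
#' @param path CSV file path.
#' @return a validated [score_matrix()].
#' @export
read_score_matrix <- function(path) {
  df <- read_fq_csv(path)
  if (ncol(df) < 2L) stop_fq("score CSV needs a compound column plus at least one receptor column")
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  score_matrix(values, compound_ids = as.character(df[[1L]]))
}

#' Read a two-level design table from CSV
#'
#' Expects `group,<factor>,...,<response>` columns; every factor column must
#' be coded 0/1.
#'
#' @param path CSV file path.
#' @param response name of the response column (default `"energy"`).
#' @return a data frame with a `"factors"` attribute naming the 0/1 columns.
#' @export
read_design_table <- function(path, response = "energy") {
  df <- read_fq_csv(path)
  if (!response %in% names(df)) {
    stop_fq(sprintf("design CSV has no response column '%s'", response))
  }
  factors <- setdiff(names(df), c(names(df)[1L], response))
  for (f in factors) {
    if (!all(df[[f]] %in% c(0, 1))) {
      stop_fq(sprintf("factor column '%s' must be coded 0/1", f))
    }
  }
  attr(df, "factors") <- factors
  df
}

# internal: CSV reader with U+2212 normalization and no name mangling
read_fq_csv <- function(path) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  df <- utils::read.csv(text = normalize_minus(raw), check.names = FALSE,
                        stringsAsFactors = FALSE)
  df
}
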