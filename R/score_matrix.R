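#' Construct a compounds-by-receptors docking score matrix
#'
#' The score matrix holds one docking score (e.g., a LibDock score) per
#' compound and receptor. Scores enter the entropy-weight pipeline as
#' positive quantities: the influence proportions of
#' [compute_proportions()] are ratios of column sums, so nonpositive or
#' nonfinite entries are rejected at construction, naming the offending
#' cell.
#'
#' @param values numeric m x n matrix of scores (m compounds, n receptors).
#' @param compound_ids character vector of m compound identifiers
#'   (default: rownames, else `C1..Cm`).
#' @param receptor_ids character vector of n receptor identifiers
#'   (default: colnames, else `R1..Rn`).
#' @return a numeric matrix of class `"score_matrix"` with dimnames set.
#' @export
#' @examples
#' sm <- score_matrix(matrix(c(80, 90, 100, 110, 70, 75), 3, 2),
#'                    compound_ids = c("a", "b", "c"),
#'                    receptor_ids = c("r1", "r2"))
score_matrix <- function(values, compound_ids = NULL, receptor_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_ids)) {
    compound_ids <- rownames(values)
    if (is.null(compound_ids)) compound_ids <- paste0("C", seq_len(nrow(values)))
  }
  if (is.null(receptor_ids)) {
    receptor_ids <- colnames(values)
    if (is.null(receptor_ids)) receptor_ids <- paste0("R", seq_len(ncol(values)))
  }
  if (length(compound_ids) != nrow(values) || anyDuplicated(compound_ids)) {
    stop_fq("`compound_ids` must be unique and match the number of rows")
  }
  if (length(receptor_ids) != ncol(values) || anyDuplicated(receptor_ids)) {
    stop_fq("`receptor_ids` must be unique and match the number of columns")
  }
  dimnames(values) <- list(compound_ids, receptor_ids)
  if (nrow(values) < 2L) stop_fq("a score matrix needs at least 2 compounds")
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_fq(sprintf(
      "score for compound '%s', receptor '%s' is nonpositive or nonfinite",
      compound_ids[bad[1L, 1L]], receptor_ids[bad[1L, 2L]]))
  }
  structure(values, class = c("score_matrix", "matrix", "array"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Docking score matrix: %d compounds x %d receptors\n",
              nrow(x), ncol(x)))
  cat("Per-receptor range:\n")
  rng <- apply(unclass(x), 2L, range)
  print(data.frame(receptor = colnames(x), min = rng[1L, ], max = rng[2L, ],
                   row.names = NULL))
  invisible(x)
}

# internal: accept a score_matrix or coercible matrix
as_score_matrix <- function(x) {
  if (inherits(x, "score_matrix")) x else score_matrix(x)
}
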