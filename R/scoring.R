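#' Influence proportions of each receptor on each compound
#'
#' Divides every score by its receptor's column total, giving the share of
#' compound i in receptor j's score mass: `P[i, j] = v[i, j] / sum_i v[i, j]`.
#' These proportions are the distributions whose Shannon entropy drives the
#' entropy weights.
#'
#' @param scores a [score_matrix()] (or coercible positive matrix).
#' @return an m x n matrix with each column summing to 1.
#' @export
compute_proportions <- function(scores) {
  scores <- as_score_matrix(scores)
  sweep(unclass(scores), 2L, colSums(scores), "/")
}

#' Normalized Shannon entropy of a proportion column
#'
#' `e = -(1/log m) * sum_i p_i log p_i`, with the convention `0 * log 0 = 0`.
#' A uniform column attains the maximum e = 1; a one-hot column gives e = 0.
#' Entropy close to 1 means the receptor barely discriminates among the
#' compounds, so it will receive a small weight.
#'
#' @param p a proportion vector summing to 1 (entries >= 0), or a matrix
#'   whose columns are proportion vectors.
#' @return scalar entropy in `[0, 1]`, or one value per column for a matrix.
#' @export
compute_entropy <- function(p) {
  if (is.matrix(p)) return(apply(p, 2L, compute_entropy))
  m <- length(p)
  if (m < 2L) stop_fq("entropy needs at least 2 compounds (log m = 0 for m = 1)")
  if (any(!is.finite(p)) || any(p < 0)) stop_fq("proportions must be finite and >= 0")
  if (abs(sum(p) - 1) > 1e-8) stop_fq("proportions must sum to 1")
  terms <- ifelse(p > 0, p * log(p), 0)
  -sum(terms) / log(m)
}

#' Entropy weights of the receptors
#'
#' Each receptor's weight is its information content `1 - e_j`, normalized
#' to sum to one: `w_j = (1 - e_j) / sum_j (1 - e_j)`. Receptors whose score
#' distribution is nearly uniform contribute little information and are
#' down-weighted.
#'
#' @param entropies vector of per-receptor entropies in `[0, 1]`.
#' @return weight vector summing to 1.
#' @export
compute_weights <- function(entropies) {
  if (any(!is.finite(entropies)) || any(entropies < 0 | entropies > 1)) {
    stop_fq("entropies must lie in [0, 1]")
  }
  info <- 1 - entropies
  if (sum(info) <= 0) {
    stop_fq("all entropies equal 1: weights are undefined (no information)")
  }
  info / sum(info)
}

#' Affine rescaling of a score column onto a fixed scale
#'
#' Range ("index") normalization: the column minimum maps to `low`, the
#' maximum to `high` (defaults 1 and 9), and intermediate values are placed
#' proportionally: `a = low + (v - vmin) * (high - low) / (vmax - vmin)`.
#'
#' @param v numeric score column.
#' @param low,high scale anchors (defaults 1 and 9).
#' @param name optional receptor name used in the constant-column error.
#' @return vector of normalized values in `[low, high]`.
#' @export
normalize_column <- function(v, low = 1, high = 9, name = NULL) {
  if (any(!is.finite(v))) stop_fq("scores must be finite")
  vmin <- min(v)
  vmax <- max(v)
  if (vmax <= vmin) {
    stop_fq(sprintf("constant score column%s: range normalization undefined",
                    if (is.null(name)) "" else sprintf(" '%s'", name)))
  }
  low + (v - vmin) * (high - low) / (vmax - vmin)
}

#' Entropy-weighted composite biodegradability scores
#'
#' Runs the full composite-scoring pipeline on a docking score matrix:
#' influence proportions per receptor, normalized Shannon entropies, entropy
#' weights, range normalization of each receptor column onto the
#' `[low, high]` scale, and the weighted sum
#' `b_i = sum_j w_j * a[i, j]` — the composite biodegradability value of
#' compound i under the joint receptor (thermophilic-community) system.
#' All intermediates are retained for audit.
#'
#' @param scores a [score_matrix()] (or coercible positive matrix).
#' @param low,high composite scale anchors (defaults 1 and 9).
#' @return an object of class `"fq_composite"`: a list with elements
#'   `composite` (named m-vector), `weights`, `entropies` (named n-vectors),
#'   `proportions`, `normalized` (m x n matrices), `column_range` (per-
#'   receptor min/max used for the affine map), and `scale_low`/`scale_high`.
#' @export
#' @examples
#' sm <- read_score_matrix(fq_example("fq_docking_scores.csv"))
#' cs <- composite_scores(sm)
#' cs$weights
#' head(sort(cs$composite, decreasing = TRUE))
composite_scores <- function(scores, low = 1, high = 9) {
  scores <- as_score_matrix(scores)
  check_number(low, "low")
  check_number(high, "high")
  if (high <= low) stop_fq("`high` must exceed `low`")
  p <- compute_proportions(scores)
  e <- compute_entropy(p)
  w <- compute_weights(e)
  a <- unclass(scores)
  for (j in seq_len(ncol(a))) {
    a[, j] <- normalize_column(unclass(scores)[, j], low, high,
                               name = colnames(scores)[j])
  }
  b <- drop(a %*% w)
  stopifnot(abs(sum(w) - 1) < 1e-12,
            all(b >= low - 1e-9), all(b <= high + 1e-9))
  structure(list(
    composite = b,
    weights = stats::setNames(w, colnames(scores)),
    entropies = stats::setNames(e, colnames(scores)),
    proportions = p,
    normalized = a,
    column_range = apply(unclass(scores), 2L, range),
    scale_low = low,
    scale_high = high
  ), class = "fq_composite")
}

#' @export
print.fq_composite <- function(x, digits = 4, ...) {
  cat(sprintf("Entropy-weighted composite scores (%d compounds, %d receptors)\n",
              length(x$composite), length(x$weights)))
  cat(sprintf("Scale: [%g, %g]\n", x$scale_low, x$scale_high))
  cat("Receptor audit (entropy, weight, column min/max):\n")
  print(data.frame(receptor = names(x$weights),
                   entropy = round(x$entropies, digits),
                   weight = round(x$weights, digits),
                   vmin = x$column_range[1L, ],
                   vmax = x$column_range[2L, ],
                   row.names = NULL))
  top <- utils::head(sort(x$composite, decreasing = TRUE), 5L)
  cat("Top composite values:\n")
  print(round(top, digits))
  invisible(x)
}

#' Deviation of computed composites from a reference column
#'
#' Diagnostic comparison between composites computed from a score matrix and
#' an externally published composite column for the same compounds. The
#' published composite values shipped with the package are not exactly
#' recoverable from the shipped score matrix under the documented pipeline,
#' so this report is a diagnostic, not a correctness gate.
#'
#' @param result an `"fq_composite"` object.
#' @param reference data frame with columns `compound` and `cv`.
#' @return list with `table` (per-compound computed/reference/deviation),
#'   `max_abs_dev`, `mean_abs_dev`, and `cor` (Pearson correlation).
#' @export
composite_deviation <- function(result, reference) {
  stopifnot(inherits(result, "fq_composite"))
  if (!all(c("compound", "cv") %in% names(reference))) {
    stop_fq("`reference` needs columns 'compound' and 'cv'")
  }
  common <- intersect(names(result$composite), reference$compound)
  if (length(common) == 0L) stop_fq("no compounds in common with the reference")
  ref <- reference$cv[match(common, reference$compound)]
  comp <- result$composite[common]
  dev <- comp - ref
  list(
    table = data.frame(compound = common, computed = unname(comp),
                       reference = ref, deviation = unname(dev)),
    max_abs_dev = max(abs(dev)),
    mean_abs_dev = mean(abs(dev)),
    cor = stats::cor(comp, ref)
  )
}
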