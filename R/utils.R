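#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when comparing against published
#' tables. Base [round()] uses round-half-to-even, which turns a mean of
#' exactly 0.605 into 0.60 rather than the conventionally printed 0.61.
#' A small epsilon guards against values such as 0.605 that have no exact
#' binary representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.605, 2)  # 0.61, where round() gives 0.6
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# internal: consistent error with a data context
stop_fq <- function(...) stop(..., call. = FALSE)

# internal: check a numeric scalar
check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_fq(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

# internal: U+2212 (minus sign) -> ASCII hyphen-minus, as printed tables
# frequently use the typographic minus
normalize_minus <- function(x) gsub("−", "-", x)

# internal: evaluate `code` under a fixed seed, restoring the global RNG
# state afterwards so seeded generators leave no footprint in the session
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_fq("`seed` must be a single finite number")
  }
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
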