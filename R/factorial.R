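#' Percent improvement of a binding energy over a blank
#'
#' Binding energies are negative; stronger binding means larger magnitude.
#' The improvement is the relative gain in magnitude,
#' `100 * (|group| - |blank|) / |blank|`; positive values mean the group
#' binds more strongly than the blank.
#'
#' @param blank_energy blank-group binding energy (kJ/mol, must be < 0).
#' @param group_energy experimental-group binding energy (kJ/mol); may be a
#'   vector.
#' @param digits decimal places for the reported percentage (default 2,
#'   half-up); `NULL` for no rounding.
#' @return numeric percent improvement(s).
#' @export
#' @examples
#' binding_improvement(-102.160, -113.825)  # 11.42
binding_improvement <- function(blank_energy, group_energy, digits = 2) {
  check_number(blank_energy, "blank_energy")
  if (blank_energy >= 0) stop_fq("blank energy must be negative (binding)")
  if (any(!is.finite(group_energy))) stop_fq("group energies must be finite")
  pct <- 100 * (abs(group_energy) - abs(blank_energy)) / abs(blank_energy)
  if (is.null(digits)) pct else round_half_up(pct, digits)
}

#' Scenario report: per-group improvements and beneficial additives
#'
#' Compares every experimental group's binding energy with the blank group
#' and flags the groups with a positive improvement as beneficial. When a
#' design table mapping groups to additives is supplied, the beneficial
#' additive names are reported as well (for one-factor-at-a-time designs
#' where each group switches on a single additive).
#'
#' @param energies data frame with columns `group` and `energy` (kJ/mol).
#' @param blank id of the blank group (default `"G0"`); must be present.
#' @param design optional data frame with a `group` column and 0/1 additive
#'   columns (e.g. the packaged `compost_design.csv`).
#' @param digits decimal places for percentages (default 2).
#' @return object of class `"scenario_report"`: list with `table` (group,
#'   energy, improvement, beneficial), `beneficial` (group ids),
#'   `beneficial_additives` (or `NULL`), `blank_energy`, and `range`
#'   (min/max improvement among beneficial groups, `c(0, 0)` when none).
#' @export
scenario_report <- function(energies, blank = "G0", design = NULL, digits = 2) {
  if (!all(c("group", "energy") %in% names(energies))) {
    stop_fq("`energies` needs columns 'group' and 'energy'")
  }
  ib <- which(energies$group == blank)
  if (length(ib) != 1L) stop_fq(sprintf("blank group '%s' not found", blank))
  blank_energy <- energies$energy[ib]
  exp_rows <- energies[-ib, , drop = FALSE]
  imp <- binding_improvement(blank_energy, exp_rows$energy, digits = digits)
  tab <- data.frame(group = exp_rows$group, energy = exp_rows$energy,
                    improvement = imp, beneficial = imp > 0)
  beneficial <- tab$group[tab$beneficial]
  additives <- NULL
  if (!is.null(design) && length(beneficial) > 0L) {
    fac <- setdiff(names(design), "group")
    rows <- design[match(beneficial, design$group), fac, drop = FALSE]
    additives <- unique(unlist(lapply(seq_len(nrow(rows)), function(i) {
      names(rows)[which(rows[i, ] == 1)]
    })))
  }
  rng <- if (any(tab$beneficial)) {
    range(tab$improvement[tab$beneficial])
  } else {
    c(0, 0)
  }
  structure(list(table = tab, beneficial = beneficial,
                 beneficial_additives = additives,
                 blank_energy = blank_energy, range = rng),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario report (blank energy %.3f kJ/mol)\n", x$blank_energy))
  print(x$table, row.names = FALSE)
  if (length(x$beneficial) > 0L) {
    cat(sprintf("Beneficial groups: %s (improvement %.2f-%.2f%%)\n",
                paste(x$beneficial, collapse = ", "), x$range[1L], x$range[2L]))
    if (!is.null(x$beneficial_additives)) {
      cat(sprintf("Beneficial additives: %s\n",
                  paste(x$beneficial_additives, collapse = ", ")))
    }
  } else {
    cat("No group improved on the blank.\n")
  }
  invisible(x)
}

# internal: validate a two-level design data frame and return pieces
design_pieces <- function(design, response, factors = NULL) {
  if (is.null(factors)) factors <- attr(design, "factors")
  if (is.null(factors)) {
    factors <- setdiff(names(design), c("group", response))
  }
  if (!response %in% names(design)) {
    stop_fq(sprintf("no response column '%s'", response))
  }
  lv <- as.matrix(design[, factors, drop = FALSE])
  if (!all(lv %in% c(0, 1))) stop_fq("factor levels must be 0/1")
  list(levels = lv, y = as.numeric(design[[response]]), factors = factors)
}

#' Marginal mean response at one level of a factor
#'
#' Arithmetic mean of the response over all runs where `factor` sits at
#' `level`, reported to 3 decimals by default (kJ/mol convention).
#'
#' @param design data frame with 0/1 factor columns and a response column.
#' @param factor name of the factor column.
#' @param level 0 or 1.
#' @param response name of the response column (default `"energy"`).
#' @param digits decimal places (default 3); `NULL` for no rounding.
#' @return scalar mean response.
#' @export
#' @examples
#' fm <- read_design_table(fq_example("field_measures.csv"))
#' marginal_mean(fm, "organic_fertilizer", 1)  # -93.266
marginal_mean <- function(design, factor, level, response = "energy",
                          digits = 3) {
  dp <- design_pieces(design, response)
  if (!factor %in% dp$factors) stop_fq(sprintf("no factor '%s'", factor))
  sel <- dp$levels[, factor] == level
  if (!any(sel)) stop_fq(sprintf("no runs with %s = %s", factor, level))
  m <- mean(dp$y[sel])
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Main and interaction effects of a complete two-level factorial
#'
#' Estimates Yates-convention effects on a complete 2^k design: levels 0/1
#' are coded -1/+1 and the effect of a term T is the average of the coded
#' contrast, `effect(T) = (1 / 2^(k-1)) * sum_cells prod(signs) * ybar`,
#' so a main effect equals the difference of marginal means between the
#' high and the low level. Replicate runs of the same cell are averaged
#' first. Incomplete factorials are an error: one-factor-at-a-time
#' amendment designs do not support interaction estimation.
#'
#' @param design data frame with 0/1 factor columns and a response column;
#'   every one of the 2^k level combinations must be present.
#' @param max_order highest interaction order to report (default k).
#' @param response name of the response column (default `"energy"`).
#' @return data frame of class `"factorial_effects"` with columns `term`
#'   (factors joined by `:`), `order`, and `estimate`, plus attributes
#'   `factors` and `k`.
#' @export
#' @examples
#' fm <- read_design_table(fq_example("field_measures.csv"))
#' factorial_effects(fm, max_order = 1)
factorial_effects <- function(design, max_order = NULL, response = "energy") {
  dp <- design_pieces(design, response)
  k <- length(dp$factors)
  if (anyDuplicated(dp$factors)) stop_fq("duplicate factor names")
  if (is.null(max_order)) max_order <- k
  cell <- apply(dp$levels, 1L, paste, collapse = "")
  ybar <- tapply(dp$y, cell, mean)
  if (length(ybar) != 2^k) {
    stop_fq(sprintf(
      "incomplete 2^%d factorial: %d of %d level combinations present",
      k, length(ybar), 2^k))
  }
  lv <- dp$levels[!duplicated(cell), , drop = FALSE]
  ybar <- as.numeric(ybar[apply(lv, 1L, paste, collapse = "")])
  coded <- 2 * lv - 1
  terms <- unlist(lapply(seq_len(min(max_order, k)), function(o) {
    utils::combn(dp$factors, o, simplify = FALSE)
  }), recursive = FALSE)
  est <- vapply(terms, function(tm) {
    signs <- apply(coded[, tm, drop = FALSE], 1L, prod)
    sum(signs * ybar) / 2^(k - 1)
  }, numeric(1))
  out <- data.frame(term = vapply(terms, paste, "", collapse = ":"),
                    order = lengths(terms), estimate = est)
  structure(out, factors = dp$factors, k = k,
            class = c("factorial_effects", "data.frame"))
}

#' Significance screen for factorial effect estimates
#'
#' Flags effects significant at `alpha` with a method suited to the data:
#' \describe{
#'   \item{`"lenth"`}{Lenth's pseudo-standard-error for unreplicated 2^k
#'     designs: `s0 = 1.5 * median|effect|`,
#'     `PSE = 1.5 * median(|effect| : |effect| < 2.5 s0)`, margin of error
#'     `t(1 - alpha/2; m/3) * PSE`.}
#'   \item{`"pool-high-order"`}{pools the highest-order interaction effects
#'     as pure error and t-tests the rest against it.}
#'   \item{`"replicated-anova"`}{fixed-effects ANOVA on the raw replicated
#'     runs (requires >= 2 replicates per cell); p-values from [stats::aov()]
#'     style linear-model F tests.}
#' }
#'
#' @param effects a `"factorial_effects"` data frame.
#' @param method one of `"lenth"`, `"pool-high-order"`,
#'   `"replicated-anova"`.
#' @param alpha significance level (default 0.05).
#' @param design,response raw design data, required only for
#'   `"replicated-anova"`.
#' @return the effects data frame with added `significant` (logical; NA
#'   where not testable) and `method` columns; Lenth adds attributes `pse`,
#'   `margin` (individual), and `sme` (simultaneous margin, for family-wise
#'   statements about all effects at once).
#' @export
significance_screen <- function(effects,
                                method = c("lenth", "pool-high-order",
                                           "replicated-anova"),
                                alpha = 0.05, design = NULL,
                                response = "energy") {
  method <- match.arg(method)
  stopifnot(inherits(effects, "factorial_effects"))
  est <- effects$estimate
  out <- effects
  if (method == "lenth") {
    m <- length(est)
    if (m < 3L) stop_fq("Lenth's method needs at least 3 effect estimates")
    s0 <- 1.5 * stats::median(abs(est))
    trimmed <- abs(est)[abs(est) < 2.5 * s0]
    pse <- 1.5 * stats::median(if (length(trimmed) > 0L) trimmed else abs(est))
    if (pse <= 0) {
      # all effects zero: nothing distinguishable from noise
      out$significant <- rep(FALSE, m)
      margin <- sme <- 0
    } else {
      margin <- stats::qt(1 - alpha / 2, df = m / 3) * pse
      # simultaneous margin for family-wise statements
      gamma <- (1 + (1 - alpha)^(1 / m)) / 2
      sme <- stats::qt(gamma, df = m / 3) * pse
      out$significant <- abs(est) > margin
    }
    out$method <- "lenth"
    attr(out, "pse") <- pse
    attr(out, "margin") <- margin
    attr(out, "sme") <- sme
  } else if (method == "pool-high-order") {
    hi <- max(effects$order)
    pool <- est[effects$order == hi]
    if (hi < 2L || length(pool) < 1L) {
      stop_fq("no higher-order interactions available to pool as error")
    }
    s2 <- mean(pool^2)
    df <- length(pool)
    tstat <- est / sqrt(s2)
    signif <- 2 * stats::pt(-abs(tstat), df = df) < alpha
    signif[effects$order == hi] <- NA
    out$significant <- signif
    out$method <- "pool-high-order"
  } else {
    if (is.null(design)) {
      stop_fq("`design` with raw runs is required for replicated-anova")
    }
    dp <- design_pieces(design, response)
    cell <- apply(dp$levels, 1L, paste, collapse = "")
    if (min(table(cell)) < 2L) {
      stop_fq("replicated-anova needs at least 2 replicates per cell")
    }
    coded <- as.data.frame(2 * dp$levels - 1)
    dat <- cbind(coded, .y = dp$y)
    max_order <- max(effects$order)
    form <- stats::as.formula(paste(
      ".y ~ (", paste(dp$factors, collapse = " + "), ")^", max_order))
    fit <- stats::lm(form, data = dat)
    sm <- summary(fit)$coefficients
    rn <- rownames(sm)[-1L]
    pvals <- sm[-1L, "Pr(>|t|)"]
    key <- gsub(":", ":", rn)
    out$significant <- pvals[match(out$term, key)] < alpha
    out$method <- "replicated-anova"
  }
  out
}
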