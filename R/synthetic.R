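#' Simulate a docking score matrix
#'
#' Draws positive scores per receptor column from a truncated normal with
#' configurable column means and standard deviations. Defaults emulate
#' LibDock-style score tables: column means spread over roughly 70-120 with
#' a spread of about 10, giving matrices in the ~40-150 range. Fully
#' deterministic under `seed`; the session RNG state is untouched.
#'
#' @param m number of compounds (>= 2).
#' @param n number of receptors (>= 1).
#' @param seed integer seed.
#' @param col_means per-column means (recycled to n; default spread over
#'   `[70, 120]`).
#' @param col_sds per-column standard deviations (recycled; default 10).
#' @return a [score_matrix()].
#' @export
sim_score_matrix <- function(m = 49, n = 3, seed = 1,
                             col_means = seq(70, 120, length.out = n),
                             col_sds = 10) {
  if (m < 2L || n < 1L) stop_fq("need m >= 2 compounds and n >= 1 receptors")
  col_means <- rep_len(col_means, n)
  col_sds <- rep_len(col_sds, n)
  with_seed(seed, {
    vals <- vapply(seq_len(n), function(j) {
      x <- stats::rnorm(m, col_means[j], col_sds[j])
      while (any(x <= 0)) {  # truncate at zero by redraw
        x[x <= 0] <- stats::rnorm(sum(x <= 0), col_means[j], col_sds[j])
      }
      x
    }, numeric(m))
    score_matrix(vals,
                 compound_ids = sprintf("cmpd%02d", seq_len(m)),
                 receptor_ids = sprintf("rec%d", seq_len(n)))
  })
}

#' Simulate a QSAR dataset with low-rank latent structure
#'
#' Generates descriptors `X = T P' + noise` from `k` latent components with
#' a decaying variance spectrum (component j has score standard deviation
#' `2^(k - j)`, mimicking the dominant-to-minor factor structure of
#' molecular-field blocks) and a response `y = T q + noise` in which every
#' latent component contributes a comparable share of response variance
#' (`|q_j|` drawn from `[0.5, 1.5]` on the unit-scaled scores, with random
#' sign), so that the response genuinely requires all `k` components. The
#' generating truth — including the implied regression coefficient vector
#' `beta` with `y = X beta` in the noiseless limit — is returned for
#' recovery tests.
#'
#' @param s number of samples (> k).
#' @param p number of descriptors.
#' @param k number of latent components (>= 1).
#' @param noise_x,noise_y Gaussian noise standard deviations (defaults 0.05).
#' @param n_test number of additional test samples generated from the same
#'   model (default 0).
#' @param seed integer seed.
#' @return list with `X`, `y`, `X_test`, `y_test` (NULL when `n_test` = 0),
#'   and `truth` (list with `k`, `beta`, loadings `P`, score sds `sds`,
#'   response loadings `q`).
#' @export
sim_qsar_dataset <- function(s = 30, p = 60, k = 3, noise_x = 0.05,
                             noise_y = 0.05, n_test = 0, seed = 1) {
  if (k < 1L || s <= k) stop_fq("need s > k >= 1")
  with_seed(seed, {
    sds <- 2^(k - seq_len(k))
    P <- matrix(stats::rnorm(p * k), p, k)
    q <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.5, 1.5)
    qs <- q / sds  # loadings on the unscaled scores
    beta <- drop(P %*% solve(crossprod(P), qs))
    gen <- function(nn) {
      Tm <- sweep(matrix(stats::rnorm(nn * k), nn, k), 2L, sds, "*")
      X <- tcrossprod(Tm, P) + matrix(stats::rnorm(nn * p, 0, noise_x), nn, p)
      y <- drop(Tm %*% qs) + stats::rnorm(nn, 0, noise_y)
      list(X = X, y = y)
    }
    tr <- gen(s)
    te <- if (n_test > 0) gen(n_test) else list(X = NULL, y = NULL)
    list(X = tr$X, y = tr$y, X_test = te$X, y_test = te$y,
         truth = list(k = k, beta = beta, P = P, sds = sds, q = q))
  })
}

#' Simulate responses of a complete two-level factorial
#'
#' Enumerates the full 2^k design for the given factors and draws
#' `y = intercept + sum_T effect_T * coded_T / 2 + N(0, sigma)` per run,
#' with 0/1 levels coded -1/+1, so [factorial_effects()] recovers the
#' effect map exactly at `sigma = 0`. Interaction terms are named with
#' `:` (e.g. `"A:B"`).
#'
#' @param factors character vector of factor names (unique).
#' @param effects named numeric vector/list of true effects; names are
#'   factor names or `:`-joined interactions. Unnamed terms default to 0.
#' @param intercept grand mean (default 0).
#' @param sigma response noise standard deviation (default 0).
#' @param replicates runs per cell (default 1).
#' @param seed integer seed.
#' @return data frame `group,<factors>,energy` with attributes `factors`
#'   and `truth` (the complete effect map).
#' @export
sim_factorial_response <- function(factors, effects = NULL, intercept = 0,
                                   sigma = 0, replicates = 1, seed = 1) {
  k <- length(factors)
  if (k < 1L || anyDuplicated(factors)) {
    stop_fq("`factors` must be non-empty and unique")
  }
  effects <- unlist(effects)
  grid <- expand.grid(rep(list(c(0, 1)), k), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- factors
  grid <- grid[rep(seq_len(nrow(grid)), each = replicates), , drop = FALSE]
  coded <- 2 * as.matrix(grid) - 1
  mu <- rep(intercept, nrow(grid))
  for (tm in names(effects)) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (!all(parts %in% factors)) {
      stop_fq(sprintf("effect term '%s' names unknown factors", tm))
    }
    mu <- mu + effects[[tm]] * apply(coded[, parts, drop = FALSE], 1L, prod) / 2
  }
  y <- with_seed(seed, mu + stats::rnorm(nrow(grid), 0, sigma))
  out <- data.frame(group = sprintf("run%02d", seq_len(nrow(grid))),
                    grid, energy = y, row.names = NULL)
  attr(out, "factors") <- factors
  attr(out, "truth") <- effects
  out
}

#' Simulate internally consistent MM/PBSA energy records
#'
#' Draws component energies per species and computes the totals from them,
#' so the free-energy decomposition identities hold exactly by
#' construction. An optional perturbation injects a known residual into the
#' complex polar term after the total is fixed, for detector tests.
#'
#' @param count number of records (>= 1).
#' @param temperature simulation temperature in K (default 308; the
#'   thermophilic presets are 308 and 328).
#' @param mean_gas,sd_gas gas-phase energy distribution per species.
#' @param perturb additive residual injected into each record's complex
#'   polar component (default 0 = consistent records).
#' @param seed integer seed.
#' @return list of [energy_record()] objects.
#' @export
sim_energy_records <- function(count = 1, temperature = 308,
                               mean_gas = -300, sd_gas = 50, perturb = 0,
                               seed = 1) {
  if (count < 1L) stop_fq("`count` must be at least 1")
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      comp <- data.frame(
        species = c("complex", "protein", "ligand"),
        e_gas = stats::rnorm(3, mean_gas, sd_gas),
        temperature = temperature,
        s_gas = stats::runif(3, 0.05, 0.3),
        g_polar = stats::rnorm(3, -40, 10),
        g_nonpolar = stats::rnorm(3, 5, 2)
      )
      comp$g_total <- mapply(species_free_energy, comp$e_gas,
                             comp$temperature, comp$s_gas, comp$g_polar,
                             comp$g_nonpolar)
      comp$g_polar[1L] <- comp$g_polar[1L] + perturb
      energy_record(comp)
    })
  })
}
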