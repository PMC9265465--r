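#' Default van der Waals parameters by element
#'
#' Radii (in Angstrom) and Lennard-Jones well depths (kJ/mol) for the
#' elements common in drug-like molecules, in the style of the Tripos force
#' field used by classical CoMFA implementations. Users may supply their own
#' table to [conformer()].
#'
#' @return data frame with columns `element`, `radius`, `epsilon`.
#' @export
vdw_defaults <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    radius  = c(1.50, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
    epsilon = c(0.042, 0.457, 0.209, 0.486, 0.457, 1.674, 1.436, 1.172,
                1.297, 1.672)
  )
}

#' Construct a molecular conformer for field evaluation
#'
#' Holds atoms of one pre-aligned conformer: element symbols, 3D coordinates
#' in Angstrom, partial charges in units of e, and per-atom van der Waals
#' parameters. Charges are input metadata (e.g., Gasteiger-Huckel charges
#' assigned upstream); the package does not compute them. Alignment is an
#' input condition: all conformers entering one descriptor block must share
#' a common frame.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric natoms x 3 matrix (Angstrom).
#' @param charges numeric partial charges (e); required for electrostatic
#'   fields.
#' @param vdw optional data frame `element,radius,epsilon` overriding
#'   [vdw_defaults()]; may also contain per-atom rows matched by position
#'   via an `atom` column.
#' @return object of class `"conformer"`.
#' @export
conformer <- function(elements, coords, charges = NULL, vdw = vdw_defaults()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop_fq("`coords` must be an natoms x 3 matrix matching `elements`")
  }
  if (any(!is.finite(coords))) stop_fq("coordinates must be finite")
  if (is.null(charges)) charges <- rep(NA_real_, n)
  if (length(charges) != n) stop_fq("`charges` must have one value per atom")
  idx <- match(elements, vdw$element)
  if (anyNA(idx)) {
    stop_fq(sprintf("no van der Waals parameters for element '%s'",
                    elements[which(is.na(idx))[1L]]))
  }
  structure(list(
    elements = as.character(elements),
    coords = coords,
    charges = as.numeric(charges),
    radius = vdw$radius[idx],
    epsilon = vdw$epsilon[idx]
  ), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("Conformer: %d atoms (%s)\n", length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a conformer from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()`. PDB files carry no partial
#' charges; supply them via `charges` (e.g., from a sidecar CSV).
#'
#' @param path PDB file path.
#' @param charges optional numeric vector of per-atom partial charges.
#' @param vdw van der Waals parameter table (see [conformer()]).
#' @return a [conformer()].
#' @export
conformer_from_pdb <- function(path, charges = NULL, vdw = vdw_defaults()) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_fq("reading PDB files requires the 'bio3d' package")
  }
  pdb <- bio3d::read.pdb(path)
  elements <- trimws(pdb$atom$elesy)
  elements <- paste0(toupper(substr(elements, 1, 1)),
                     tolower(substr(elements, 2, 2)))
  coords <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  conformer(elements, coords, charges = charges, vdw = vdw)
}

#' Build a rectangular lattice enclosing a set of conformers
#'
#' The grid is axis-aligned with the given spacing; every atom of every
#' conformer lies at least `margin` inside the box. The origin is the
#' minimum corner; points are laid out with x varying fastest, then y,
#' then z (raster order).
#'
#' @param conformers list of [conformer()] objects (or a single one).
#' @param spacing lattice spacing in Angstrom (default 2.0).
#' @param margin clearance around the atoms in Angstrom (default 4.0).
#' @return object of class `"field_grid"` with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(conformers, spacing = 2.0, margin = 4.0) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (length(conformers) == 0L) stop_fq("at least one conformer is required")
  check_number(spacing, "spacing")
  check_number(margin, "margin")
  if (spacing <= 0) stop_fq("`spacing` must be positive")
  all_xyz <- do.call(rbind, lapply(conformers, `[[`, "coords"))
  lo <- apply(all_xyz, 2L, min) - margin
  hi <- apply(all_xyz, 2L, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("Field grid: %d x %d x %d points, spacing %g A, origin (%s)\n",
              x$dims[1L], x$dims[2L], x$dims[3L], x$spacing,
              paste(sprintf("%.2f", x$origin), collapse = ", ")))
  invisible(x)
}

#' Coordinates of all lattice points of a grid
#'
#' @param grid a `"field_grid"`.
#' @return numeric (nx*ny*nz) x 3 matrix in raster order (x fastest).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  ax <- lapply(1:3, function(d) {
    grid$origin[d] + grid$spacing * (seq_len(grid$dims[d]) - 1L)
  })
  pts <- expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]],
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

# internal: squared distances from every grid point to every atom
point_atom_dist <- function(grid, conf) {
  pts <- grid_points(grid)
  d2 <- outer(rowSums(pts^2), rowSums(conf$coords^2), "+") -
    2 * tcrossprod(pts, conf$coords)
  sqrt(pmax(d2, 0))
}

#' Default CoMFA probe
#'
#' An sp3 carbon probe carrying +1 e: van der Waals radius 1.7 Angstrom,
#' well depth 0.457 kJ/mol — the de-facto standard probe of classical
#' molecular-field analysis. All parameters are overridable.
#'
#' @param radius probe van der Waals radius (Angstrom).
#' @param epsilon probe well depth (kJ/mol).
#' @param charge probe charge (e).
#' @return list with `radius`, `epsilon`, `charge`.
#' @export
comfa_probe <- function(radius = 1.7, epsilon = 0.457, charge = 1) {
  list(radius = radius, epsilon = epsilon, charge = charge)
}

#' Steric (Lennard-Jones) field of a conformer on a grid
#'
#' At every lattice point the 6-12 Lennard-Jones interaction energy between
#' the probe and all atoms is summed:
#' `E = sum_a eps_a * ((r0_a / r)^12 - 2 (r0_a / r)^6)` with
#' `r0_a = radius_atom + radius_probe` and
#' `eps_a = sqrt(epsilon_atom * epsilon_probe)`. Values are clamped to
#' `[-cutoff, +cutoff]`; lattice points coincident with an atom therefore
#' yield the cutoff, never an infinity.
#'
#' @param conf a [conformer()].
#' @param grid a `"field_grid"`.
#' @param probe probe parameters, see [comfa_probe()].
#' @param cutoff clamp magnitude in kJ/mol (default 125.4, i.e. 30 kcal/mol).
#' @return numeric vector of energies, one per grid point (raster order).
#' @export
steric_field <- function(conf, grid, probe = comfa_probe(), cutoff = 125.4) {
  stopifnot(inherits(conf, "conformer"), inherits(grid, "field_grid"))
  r <- point_atom_dist(grid, conf)
  r0 <- conf$radius + probe$radius
  eps <- sqrt(conf$epsilon * probe$epsilon)
  rel6 <- sweep(1 / pmax(r, 1e-12), 2L, r0, "*")^6
  e <- sweep(rel6^2 - 2 * rel6, 2L, eps, "*")
  pmin(pmax(rowSums(e), -cutoff), cutoff)
}

# Coulomb constant in kJ/mol * Angstrom / e^2
.coulomb_k <- 1389.35458

#' Electrostatic (Coulomb) field of a conformer on a grid
#'
#' Coulomb interaction between the probe charge and the atomic partial
#' charges under a linear distance-dependent dielectric, eps(r) = r, so the
#' pair energy falls off as `k q_a q_probe / r^2`. Values are clamped to
#' `[-cutoff, +cutoff]`.
#'
#' @inheritParams steric_field
#' @return numeric vector of energies, one per grid point (raster order).
#' @export
electrostatic_field <- function(conf, grid, probe = comfa_probe(),
                                cutoff = 125.4) {
  stopifnot(inherits(conf, "conformer"), inherits(grid, "field_grid"))
  if (anyNA(conf$charges)) {
    stop_fq(sprintf("atom %d ('%s') has no partial charge",
                    which(is.na(conf$charges))[1L],
                    conf$elements[which(is.na(conf$charges))[1L]]))
  }
  r <- point_atom_dist(grid, conf)
  e <- .coulomb_k * probe$charge *
    sweep(1 / pmax(r, 1e-12)^2, 2L, conf$charges, "*")
  pmin(pmax(rowSums(e), -cutoff), cutoff)
}

#' Assemble a molecular-field descriptor matrix
#'
#' Evaluates the steric and electrostatic fields of every conformer on a
#' shared grid and binds them into one descriptor matrix: the steric block
#' first, then the electrostatic block, each in grid raster order.
#' Electrostatic values at sterically excluded points (where the steric
#' energy hit the clamp) are replaced by the per-column mean over the
#' non-excluded molecules — the classical CoMFA convention — unless
#' `excluded = "clamp"`. Near-constant columns (sd below `drop_sd`) are
#' dropped; the count is recorded in attributes.
#'
#' @param conformers list of [conformer()] objects sharing one alignment.
#' @param grid optional `"field_grid"`; built with defaults when `NULL`.
#' @param probe probe parameters, see [comfa_probe()].
#' @param cutoff clamp magnitude in kJ/mol.
#' @param excluded `"mean"` (default) or `"clamp"` handling of
#'   electrostatic values at sterically excluded points.
#' @param drop_sd threshold below which a column counts as constant.
#' @return numeric matrix (molecules x descriptors) with attributes
#'   `grid`, `n_dropped`, `kept` (column index into the unfiltered block),
#'   and `block` (factor `"S"`/`"E"` per kept column).
#' @export
field_descriptors <- function(conformers, grid = NULL, probe = comfa_probe(),
                              cutoff = 125.4, excluded = c("mean", "clamp"),
                              drop_sd = 1e-6) {
  excluded <- match.arg(excluded)
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (is.null(grid)) grid <- build_grid(conformers)
  S <- t(vapply(conformers, steric_field, numeric(prod(grid$dims)),
                grid = grid, probe = probe, cutoff = cutoff))
  E <- t(vapply(conformers, electrostatic_field, numeric(prod(grid$dims)),
                grid = grid, probe = probe, cutoff = cutoff))
  if (excluded == "mean" && nrow(S) > 1L) {
    excl <- S >= cutoff
    for (j in which(colSums(excl) > 0L)) {
      keep <- !excl[, j]
      fill <- if (any(keep)) mean(E[keep, j]) else 0
      E[!keep, j] <- fill
    }
  }
  X <- cbind(S, E)
  block <- rep(c("S", "E"), each = ncol(S))
  sds <- apply(X, 2L, stats::sd)
  if (nrow(X) == 1L) sds <- rep(Inf, ncol(X))  # single molecule: keep all
  keep <- sds >= drop_sd
  out <- X[, keep, drop = FALSE]
  mol_ids <- names(conformers)
  if (is.null(mol_ids)) mol_ids <- paste0("mol", seq_along(conformers))
  rownames(out) <- mol_ids
  colnames(out) <- paste0(block[keep], which(keep))
  structure(out, grid = grid, n_dropped = sum(!keep), kept = which(keep),
            block = block[keep])
}
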