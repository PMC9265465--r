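# small rigid "molecules" built in code
toy_mol <- function(shift = c(0, 0, 0)) {
  conformer(c("C", "O", "H"),
            rbind(c(0, 0, 0), c(1.2, 0, 0), c(-0.6, 0.9, 0)) +
              rep(shift, each = 3),
            charges = c(0.2, -0.4, 0.2))
}

test_that("grid construction encloses atoms with margin and is equivariant", {
  single <- conformer("C", matrix(0, 1, 3), charges = 0)
  g <- build_grid(single, spacing = 2, margin = 4)
  expect_true(all(g$origin <= -4))
  pts <- grid_points(g)
  expect_true(all(apply(pts, 2, max) >= 4))
  # translation shifts the origin exactly
  t_vec <- c(3.2, -1.5, 0.7)
  g2 <- build_grid(toy_mol(t_vec), spacing = 2, margin = 4)
  g1 <- build_grid(toy_mol(), spacing = 2, margin = 4)
  expect_equal(g2$origin, g1$origin + t_vec)
  expect_equal(g2$dims, g1$dims)
  # dims match an independent bounding-box computation for two molecules
  mols <- list(toy_mol(), toy_mol(c(2, 2, 2)))
  gb <- build_grid(mols, spacing = 1.5, margin = 3)
  xyz <- rbind(mols[[1]]$coords, mols[[2]]$coords)
  span <- apply(xyz, 2, max) + 3 - (apply(xyz, 2, min) - 3)
  expect_equal(gb$dims, as.integer(ceiling(span / 1.5)) + 1L)
})

test_that("steric field follows the 6-12 form, clamps, and decays", {
  atom <- conformer("C", matrix(0, 1, 3), charges = 0)
  probe <- comfa_probe()
  # scalar oracle at 4 Angstrom: single-pair Lennard-Jones energy
  g <- structure(list(origin = c(4, 0, 0), spacing = 1, dims = c(1L, 1L, 1L)),
                 class = "field_grid")
  r0 <- 1.7 + probe$radius
  eps <- sqrt(0.457 * probe$epsilon)
  expect_equal(steric_field(atom, g, probe),
               eps * ((r0 / 4)^12 - 2 * (r0 / 4)^6), tolerance = 1e-12)
  # deep overlap hits the clamp exactly; coincident point stays finite
  g0 <- structure(list(origin = c(0.3, 0, 0), spacing = 1,
                       dims = c(1L, 1L, 1L)), class = "field_grid")
  expect_equal(steric_field(atom, g0, probe), 125.4)
  gc <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(1L, 1L, 1L)),
                  class = "field_grid")
  expect_true(is.finite(steric_field(atom, gc, probe)))
  # decay to zero far away
  gfar <- structure(list(origin = c(80, 0, 0), spacing = 1,
                         dims = c(1L, 1L, 1L)), class = "field_grid")
  expect_lt(abs(steric_field(atom, gfar, probe)), 1e-6)
})

test_that("electrostatic field is Coulomb with distance dielectric", {
  atom <- conformer("N", matrix(0, 1, 3), charges = 0.5)
  g2 <- structure(list(origin = c(3, 0, 0), spacing = 1, dims = c(1L, 1L, 1L)),
                  class = "field_grid")
  # eps(r) = r gives q_i q_p k / r^2
  expect_equal(electrostatic_field(atom, g2), 1389.35458 * 0.5 / 9,
               tolerance = 1e-6)
  # very close to the charge the Coulomb energy hits the clamp
  gnear <- structure(list(origin = c(0.5, 0, 0), spacing = 1,
                          dims = c(1L, 1L, 1L)), class = "field_grid")
  expect_equal(electrostatic_field(atom, gnear), 125.4)
  # neutral molecule gives zero everywhere
  neutral <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                       charges = c(0, 0))
  g <- build_grid(neutral)
  expect_equal(electrostatic_field(neutral, g), rep(0, prod(g$dims)))
  # sign flip negates the field (before any mean replacement)
  mol <- toy_mol()
  flipped <- conformer(mol$elements, mol$coords, charges = -mol$charges)
  gm <- build_grid(mol)
  expect_equal(electrostatic_field(flipped, gm), -electrostatic_field(mol, gm))
  # missing charge errors with the atom named
  nochg <- conformer(c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)),
                     charges = c(0.1, NA))
  expect_error(electrostatic_field(nochg, gm), "atom 2")
})

test_that("descriptor assembly has deterministic shape and filtering", {
  mol <- toy_mol()
  g <- build_grid(mol, spacing = 2, margin = 4)
  X1 <- field_descriptors(list(only = mol), grid = g)
  expect_equal(nrow(X1), 1L)
  expect_equal(ncol(X1), 2L * prod(g$dims))  # single molecule: no filtering
  # duplicate molecules give identical rows
  X2 <- field_descriptors(list(a = mol, b = mol), grid = g, excluded = "clamp")
  expect_equal(unname(X2[1, ]), unname(X2[2, ]))
  # filtered column count equals a brute-force recount of varying columns
  mols <- list(a = toy_mol(), b = toy_mol(c(1, 0.5, 0)))
  gm <- build_grid(mols, spacing = 2, margin = 4)
  Xf <- field_descriptors(mols, grid = gm, excluded = "clamp")
  S <- rbind(steric_field(mols$a, gm), steric_field(mols$b, gm))
  E <- rbind(electrostatic_field(mols$a, gm), electrostatic_field(mols$b, gm))
  full <- cbind(S, E)
  n_varying <- sum(apply(full, 2, sd) >= 1e-6)
  expect_equal(ncol(Xf), n_varying)
  expect_equal(attr(Xf, "n_dropped"), ncol(full) - n_varying)
})

test_that("clamp bound holds everywhere and is stable under widening", {
  mols <- list(a = toy_mol(), b = toy_mol(c(0.8, 0, 0)))
  g <- build_grid(mols, spacing = 1.5, margin = 3)
  for (mol in mols) {
    s <- steric_field(mol, g)
    e <- electrostatic_field(mol, g)
    expect_true(all(is.finite(s)) && all(abs(s) <= 125.4))
    expect_true(all(is.finite(e)) && all(abs(e) <= 125.4))
    # doubling the cutoff never changes sub-cutoff values
    s2 <- steric_field(mol, g, cutoff = 250.8)
    below <- abs(s) < 125.4
    expect_equal(s[below], s2[below])
  }
})

test_that("rigid translation of molecules and grid leaves descriptors fixed", {
  t_vec <- c(5.1, -2.2, 3.3)
  mols <- list(a = toy_mol(), b = toy_mol(c(1, 1, 0)))
  shifted <- list(a = toy_mol(t_vec), b = toy_mol(c(1, 1, 0) + t_vec))
  X0 <- field_descriptors(mols)
  X1 <- field_descriptors(shifted)
  expect_equal(dim(X0), dim(X1))
  expect_equal(as.vector(X0), as.vector(X1), tolerance = 1e-9)
})
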