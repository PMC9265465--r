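#' Binding free energy from species totals
#'
#' End-point MM/PBSA bookkeeping: the binding free energy is the difference
#' between the complex total and the free species totals,
#' `G_bind = G_complex - G_free_protein - G_free_ligand` (kJ/mol).
#'
#' @param g_complex,g_protein,g_ligand species free-energy totals (kJ/mol).
#' @return scalar G_bind in kJ/mol.
#' @export
#' @examples
#' binding_free_energy(-200, -150, -30)  # -20
binding_free_energy <- function(g_complex, g_protein, g_ligand) {
  check_number(g_complex, "g_complex")
  check_number(g_protein, "g_protein")
  check_number(g_ligand, "g_ligand")
  g_complex - g_protein - g_ligand
}

#' Free energy of one species from its MM/PBSA components
#'
#' `G = E_gas - T * S_gas + G_polar + G_nonpolar`, where the last two terms
#' decompose the solvation free energy into its polar
#' (Poisson-Boltzmann) and nonpolar (surface-area) parts. Units: energies
#' kJ/mol, temperature K, entropy kJ/mol/K so that `T * S` is kJ/mol.
#' Composting-stage simulations conventionally run at 308 K or 328 K.
#'
#' @param e_gas gas-phase molecular-mechanics energy (kJ/mol).
#' @param temperature absolute temperature (K, nonnegative).
#' @param s_gas gas-phase entropy (kJ/mol/K).
#' @param g_polar,g_nonpolar polar and nonpolar solvation terms (kJ/mol).
#' @return scalar free energy (kJ/mol).
#' @export
#' @examples
#' species_free_energy(-100, 308, 0.1, -20, 5)  # -145.8
species_free_energy <- function(e_gas, temperature, s_gas, g_polar,
                                g_nonpolar) {
  for (nm in c("e_gas", "temperature", "s_gas", "g_polar", "g_nonpolar")) {
    check_number(get(nm), nm)
  }
  if (temperature < 0) stop_fq("temperature must be nonnegative")
  e_gas - temperature * s_gas + g_polar + g_nonpolar
}

#' Assemble an MM/PBSA energy record
#'
#' A record holds the component table for the three species of one binding
#' calculation (complex, free protein, free ligand). Totals may be supplied
#' or derived from components via [species_free_energy()].
#'
#' @param components data frame with columns `species` (must contain
#'   `"complex"`, `"protein"`, `"ligand"`), `e_gas`, `temperature`, `s_gas`,
#'   `g_polar`, `g_nonpolar`, and optionally `g_total`.
#' @return object of class `"energy_record"`: the components with `g_total`
#'   filled in, plus a `g_bind` attribute.
#' @export
energy_record <- function(components) {
  needed <- c("species", "e_gas", "temperature", "s_gas", "g_polar",
              "g_nonpolar")
  if (!all(needed %in% names(components))) {
    stop_fq(sprintf("components need columns: %s",
                    paste(needed, collapse = ", ")))
  }
  if (!all(c("complex", "protein", "ligand") %in% components$species)) {
    stop_fq("species must include 'complex', 'protein', and 'ligand'")
  }
  derived <- mapply(species_free_energy, components$e_gas,
                    components$temperature, components$s_gas,
                    components$g_polar, components$g_nonpolar)
  if (is.null(components$g_total)) components$g_total <- derived
  g <- function(sp) components$g_total[components$species == sp][1L]
  gb <- binding_free_energy(g("complex"), g("protein"), g("ligand"))
  structure(components, g_bind = gb, class = c("energy_record", "data.frame"))
}

#' Validate the internal identities of an energy record
#'
#' Checks, per species, that the stored total matches
#' `E_gas - T * S_gas + G_polar + G_nonpolar`, and that the stored binding
#' energy matches the species-total difference. A reporting operation:
#' failures are listed with residuals, never raised.
#'
#' @param record an [energy_record()].
#' @param tol absolute tolerance in kJ/mol (default 1e-6).
#' @return list with `table` (check, residual, pass per identity) and
#'   `all_pass`.
#' @export
validate_energy_record <- function(record, tol = 1e-6) {
  stopifnot(inherits(record, "energy_record"))
  derived <- mapply(species_free_energy, record$e_gas, record$temperature,
                    record$s_gas, record$g_polar, record$g_nonpolar)
  res_species <- record$g_total - derived
  g <- function(sp) record$g_total[record$species == sp][1L]
  res_bind <- attr(record, "g_bind") -
    binding_free_energy(g("complex"), g("protein"), g("ligand"))
  tab <- data.frame(
    check = c(paste0("total[", record$species, "]"), "g_bind"),
    residual = c(res_species, res_bind)
  )
  tab$pass <- abs(tab$residual) <= tol
  list(table = tab, all_pass = all(tab$pass))
}
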