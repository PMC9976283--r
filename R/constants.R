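#' Physical constants and unit conversions
#'
#' Returns the read-only constant registry used throughout the package.
#' Internal units are Angstrom for length, nanosecond for time, elementary
#' charges for charge and electron density in e/A^3. Energies are expressed
#' in units of kT at the configured temperature, with conversions to kJ/mol.
#'
#' @param temperature Simulation temperature in Kelvin (default 303).
#' @return A list with components:
#'   \describe{
#'     \item{temperature}{K}
#'     \item{kB_kJmol}{Boltzmann constant in kJ/(mol K)}
#'     \item{kT_kJmol}{kT at \code{temperature}, kJ/mol}
#'     \item{kT_J}{kT at \code{temperature}, Joule (per particle)}
#'     \item{elementary_charge}{Coulomb}
#'     \item{avogadro}{1/mol}
#'     \item{debye_per_eA}{Debye per e*Angstrom (4.80320)}
#'     \item{bohr_A}{Bohr radius in Angstrom}
#'     \item{eV_kT}{1 eV expressed in kT units at \code{temperature}}
#'   }
#' @export
#' @examples
#' k <- permeonics_constants()
#' k$kT_kJmol            # ~2.52 kJ/mol at 303 K
permeonics_constants <- function(temperature = 303) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  kB_J <- 1.380649e-23
  e_C <- 1.602176634e-19
  NA_mol <- 6.02214076e23
  kT_J <- kB_J * temperature
  structure(list(
    temperature = temperature,
    kB_kJmol = kB_J * NA_mol / 1000,
    kT_kJmol = kT_J * NA_mol / 1000,
    kT_J = kT_J,
    elementary_charge = e_C,
    avogadro = NA_mol,
    debye_per_eA = 4.80320,
    bohr_A = 0.529177210903,
    eV_kT = e_C / kT_J
  ), class = "permeonics_constants")
}

#' @export
print.permeonics_constants <- function(x, ...) {
  cat("permeonics constants @", x$temperature, "K\n")
  cat(sprintf("  kT = %.6g kJ/mol = %.6g J\n", x$kT_kJmol, x$kT_J))
  cat(sprintf("  e = %.9e C, N_A = %.8e /mol\n", x$elementary_charge, x$avogadro))
  cat(sprintf("  1 e*A = %.5f D, 1 Bohr = %.6f A\n", x$debye_per_eA, x$bohr_A))
  invisible(x)
}

# concentration (mol/L) from number density (1/A^3):
# n [A^-3] * 1e27 [A^3/L] / N_A
.density_to_molar <- function(density_A3) {
  density_A3 * 1e27 / 6.02214076e23
}

# element symbols by atomic number (through Ba; superset of what the
# analyses encounter) and the standard amino-acid residue names
ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg",
              "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V",
              "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Br", "Rb", "Sr", "I",
              "Cs", "Ba")

ATOMIC_NUMBERS <- stats::setNames(seq_along(ELEMENTS), ELEMENTS)

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
            "SER", "THR", "TRP", "TYR", "VAL")
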