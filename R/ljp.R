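# Limiting molar conductivities at 25 C (S cm^2 mol^-1, per mole of ion),
# from standard electrochemistry tables (CRC Handbook; Ng & Barry 1995,
# J Neurosci Methods 56:37, for gluconate, HEPES and methanesulfonate).
# The relative electrophoretic mobility used by the Henderson equation is
# (lambda/|z|) / lambda_K.
.ion_table <- data.frame(
  species = c("K", "Na", "Li", "Cs", "Rb", "H", "NH4", "TEA", "TrisH",
              "Mg", "Ca", "Ba",
              "Cl", "Br", "F", "I", "NO3", "HCO3", "OH", "acetate",
              "gluconate", "methanesulfonate", "HEPES", "H2PO4", "SO4"),
  charge = c(1, 1, 1, 1, 1, 1, 1, 1, 1,
             2, 2, 2,
             -1, -1, -1, -1, -1, -1, -1, -1,
             -1, -1, -1, -1, -2),
  lambda = c(73.48, 50.08, 38.66, 77.2, 77.8, 349.65, 73.5, 32.6, 29.5,
             106.0, 119.0, 127.2,
             76.31, 78.1, 55.4, 76.8, 71.42, 44.5, 198.0, 40.9,
             24.3, 48.9, 22.0, 33.0, 160.0),
  stringsAsFactors = FALSE)

#' Bundled ionic mobility table
#'
#' Species, charge, limiting molar conductivity (25 C), and the resulting
#' electrophoretic mobility relative to K+ used by [ljp_henderson()].
#' Note that tables expressed JPCalc-style as mobility per unit charge list
#' half these values for divalents.
#'
#' @return Data.frame with columns `species`, `charge`, `lambda_S_cm2_mol`,
#'   `mobility_rel_K`.
#' @export
ion_mobilities <- function() {
  data.frame(species = .ion_table$species, charge = .ion_table$charge,
             lambda_S_cm2_mol = .ion_table$lambda,
             mobility_rel_K =
               (.ion_table$lambda / abs(.ion_table$charge)) / 73.48,
             stringsAsFactors = FALSE)
}

#' Define a solution composition for junction-potential calculations
#'
#' @param species Character vector of species names; must appear in
#'   [ion_mobilities()] unless both `charge` and `mobility` are supplied.
#' @param conc_mM Concentrations in mM (same length).
#' @param charge Optional integer charges overriding the table.
#' @param mobility Optional electrophoretic mobilities relative to K+
#'   overriding the table.
#' @return Data.frame of class `solution_composition`.
#' @export
solution_composition <- function(species, conc_mM, charge = NULL,
                                 mobility = NULL) {
  if (length(species) != length(conc_mM))
    stop("species and conc_mM lengths differ")
  if (any(conc_mM < 0)) stop("concentrations must be >= 0")
  tab <- ion_mobilities()
  idx <- match(species, tab$species)
  if (is.null(charge) || is.null(mobility)) {
    unknown <- species[is.na(idx)]
    if (length(unknown))
      stop("species not in the bundled mobility table: ",
           paste(unknown, collapse = ", "),
           "; supply charge= and mobility= explicitly")
  }
  out <- data.frame(species = species,
                    charge = if (is.null(charge)) tab$charge[idx] else charge,
                    conc_mM = conc_mM,
                    mobility = if (is.null(mobility))
                      tab$mobility_rel_K[idx] else mobility,
                    stringsAsFactors = FALSE)
  class(out) <- c("solution_composition", "data.frame")
  out
}

#' Liquid junction potential by the generalized Henderson equation
#'
#' Computes the junction potential between the pipette and bath solutions
#' over all ionic species, using the bundled relative-mobility table.
#' The returned value is the potential of the bath relative to the pipette
#' solution, i.e. the number to be subtracted from command potentials when
#' correcting offline (positive for typical low-mobility-anion pipette
#' solutions such as gluconate).
#'
#' Species present in only one solution are treated as having zero
#' concentration in the other.
#'
#' @param pipette,bath [solution_composition()] objects.
#' @param temperature_K Temperature (default 305.15 K).
#' @return Junction potential in mV.
#' @export
ljp_henderson <- function(pipette, bath, temperature_K = 305.15) {
  if (!nrow(pipette) || !nrow(bath)) stop("solutions must be non-empty")
  sp <- union(pipette$species, bath$species)
  get <- function(sol, what) {
    v <- sol[[what]][match(sp, sol$species)]
    v
  }
  cp <- pipette$conc_mM[match(sp, pipette$species)]
  cb <- bath$conc_mM[match(sp, bath$species)]
  cp[is.na(cp)] <- 0; cb[is.na(cb)] <- 0
  z <- ifelse(is.na(match(sp, pipette$species)),
              bath$charge[match(sp, bath$species)],
              pipette$charge[match(sp, pipette$species)])
  u <- ifelse(is.na(match(sp, pipette$species)),
              bath$mobility[match(sp, bath$species)],
              pipette$mobility[match(sp, pipette$species)])
  dc <- cb - cp
  s_num <- sum(sign(z) * u * dc)
  s_den <- sum(abs(z) * u * dc)
  s_p <- sum(abs(z) * u * cp)
  s_b <- sum(abs(z) * u * cb)
  if (s_p <= 0 || s_b <= 0) stop("each solution must contain charged species")
  if (abs(s_den) < 1e-12) {
    # equal equivalent-conductance sums: Henderson limit via L'Hopital not
    # needed at our tolerance; identical solutions return exactly 0
    if (max(abs(dc)) < 1e-12) return(0)
    s_den <- sign(s_den + 1e-300) * 1e-12
  }
  rt_over_f_mV(temperature_K) * (s_num / s_den) * log(s_p / s_b)
}
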