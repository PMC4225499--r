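# Saline composition, ionic strength and Debye-Hueckel activity corrections.
#
# Solutions are described by their recipe components (salts and buffers), the
# working pH and the liquid-junction potential measured against the pipette
# saline. Ionic strength bookkeeping resolves each component into charged
# species: fully dissociated salts, the pH-dependent anionic fraction of
# sulfonate buffers (HEPES, TAPS, MES), EGTA carried at net charge -2
# (H2EGTA2- / CaEGTA2- are isovalent at physiological pH), and the titrant
# counter-cations those anions require. Ca2+ delivered alongside an excess of
# EGTA is treated as fully chelated (zero free concentration).

# Kielland ion-size parameters (Angstrom) for the extended Debye-Hueckel form
.kielland_a <- c(
  Na = 4.5, Li = 6, K = 3, Rb = 2.5, Cs = 2.5,
  Mg = 8, Ca = 6, Sr = 5, Ba = 5, NMDG = 4.5, H = 9, Cl = 3
)

.ion_valence <- c(
  Na = 1, Li = 1, K = 1, Rb = 1, Cs = 1,
  Mg = 2, Ca = 2, Sr = 2, Ba = 2, NMDG = 1, H = 1, Cl = -1
)

# buffer acid dissociation constants (sulfonic acid group)
.buffer_pka <- c(HEPES = 7.5, TAPS = 8.4, MES = 6.15)

#' Ionic valence lookup
#'
#' @param ion Ion name, e.g. `"Na"`, `"Ca"`.
#' @return Integer valence.
#' @export
ion_valence <- function(ion) {
  z <- .ion_valence[ion]
  if (any(is.na(z))) {
    stop("unknown ion(s): ", paste(ion[is.na(z)], collapse = ", "))
  }
  unname(z)
}

#' Define a bath or pipette saline
#'
#' @param components Named numeric vector of component concentrations in mM.
#'   Recognised components: the chloride salts `NaCl`, `KCl`, `LiCl`, `RbCl`,
#'   `CsCl`, `MgCl2`, `CaCl2`, `SrCl2`, `BaCl2`, the organic salt pair
#'   `NMDG` (N-methyl-D-glucamine titrated with HCl) and `CsMES`, the buffers
#'   `HEPES`, `TAPS`, `MES`, the chelator `EGTA`, and neutral `mannitol`.
#' @param pH Solution pH (5 to 12).
#' @param ljp Liquid-junction potential in mV assigned to this solution when
#'   paired against the pipette (-15 to 15 mV).
#' @param titrant Cation used to adjust pH (supplies counter-ions for buffer
#'   and chelator anions). Defaults to the most abundant cation in the recipe.
#' @return Object of class `solution_composition`.
#' @export
#' @examples
#' bath <- solution_composition(c(NaCl = 150, HEPES = 10, EGTA = 5, CaCl2 = 0.5))
#' ionic_strength(bath)
solution_composition <- function(components, pH = 7.4, ljp = 0, titrant = NULL) {
  stopifnot(is.numeric(components), length(components) > 0,
            !is.null(names(components)), all(components >= 0))
  if (pH < 5 || pH > 12) stop("pH must lie in [5, 12]")
  if (ljp < -15 || ljp > 15) stop("ljp must lie in [-15, 15] mV")
  if (anyDuplicated(names(components))) {
    components <- tapply(components, names(components), sum)
    components <- stats::setNames(as.numeric(components), names(components))
  }
  known <- c("NaCl", "KCl", "LiCl", "RbCl", "CsCl", "MgCl2", "CaCl2", "SrCl2",
             "BaCl2", "NMDG", "CsMES", "HEPES", "TAPS", "MES", "EGTA",
             "mannitol")
  bad <- setdiff(names(components), known)
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "))
  sol <- structure(
    list(components = components, pH = pH, ljp = ljp, titrant = titrant),
    class = "solution_composition"
  )
  if (is.null(titrant)) {
    cat_tab <- cation_concentrations(sol, free = FALSE)
    sol$titrant <- names(cat_tab)[which.max(cat_tab)]
  }
  sol
}

# cation name carried by each salt component
.salt_cation <- c(
  NaCl = "Na", KCl = "K", LiCl = "Li", RbCl = "Rb", CsCl = "Cs",
  MgCl2 = "Mg", CaCl2 = "Ca", SrCl2 = "Sr", BaCl2 = "Ba",
  NMDG = "NMDG", CsMES = "Cs"
)

# total (not free) cation concentrations from the salt components, mM
cation_concentrations <- function(solution, free = TRUE) {
  comp <- solution$components
  out <- numeric(0)
  for (nm in names(comp)) {
    if (!nm %in% names(.salt_cation)) next
    ion <- .salt_cation[[nm]]
    out[ion] <- (if (ion %in% names(out)) out[[ion]] else 0) + comp[[nm]]
  }
  if (free && "Ca" %in% names(out)) {
    egta <- if ("EGTA" %in% names(comp)) comp[["EGTA"]] else 0
    out[["Ca"]] <- max(0, out[["Ca"]] - egta)
  }
  out
}

#' Free concentration of an ion in a solution
#'
#' Ca2+ co-dissolved with excess EGTA is counted as fully chelated.
#'
#' @param solution A [solution_composition()].
#' @param ion Cation name.
#' @return Free concentration in mM (0 when the ion is absent).
#' @export
ion_conc <- function(solution, ion) {
  tab <- cation_concentrations(solution, free = TRUE)
  if (ion %in% names(tab)) tab[[ion]] else 0
}

# resolve a solution into charged species for the ionic-strength sum:
# data.frame(species, z, conc_mM)
dissociate <- function(solution) {
  comp <- solution$components
  pH <- solution$pH
  rows <- list()
  add <- function(species, z, conc) {
    if (conc > 0) rows[[length(rows) + 1]] <<- data.frame(
      species = species, z = z, conc_mM = conc, stringsAsFactors = FALSE)
  }
  cl <- 0
  titrant_eq <- 0 # mEq of titrant cation required by buffer/chelator anions
  for (nm in names(comp)) {
    c_mM <- comp[[nm]]
    if (c_mM == 0) next
    if (nm %in% c("NaCl", "KCl", "LiCl", "RbCl", "CsCl", "NMDG")) {
      add(.salt_cation[[nm]], 1, c_mM)
      cl <- cl + c_mM
    } else if (nm %in% c("MgCl2", "SrCl2", "BaCl2")) {
      add(.salt_cation[[nm]], 2, c_mM)
      cl <- cl + 2 * c_mM
    } else if (nm == "CaCl2") {
      egta <- if ("EGTA" %in% names(comp)) comp[["EGTA"]] else 0
      add("Ca", 2, max(0, c_mM - egta))
      cl <- cl + 2 * c_mM
    } else if (nm == "CsMES") {
      add("Cs", 1, c_mM)
      add("MES-", -1, c_mM)
    } else if (nm %in% names(.buffer_pka)) {
      frac <- 1 / (1 + 10^(.buffer_pka[[nm]] - pH))
      add(paste0(nm, "-"), -1, frac * c_mM)
      titrant_eq <- titrant_eq + frac * c_mM
    } else if (nm == "EGTA") {
      add("EGTA2-", -2, c_mM)
      titrant_eq <- titrant_eq + 2 * c_mM
    } else if (nm == "mannitol") {
      # neutral osmolyte, no charge contribution
    }
  }
  add("Cl", -1, cl)
  if (titrant_eq > 0) {
    zt <- ion_valence(solution$titrant)
    add(paste0(solution$titrant, "(titrant)"), zt, titrant_eq / zt)
  }
  do.call(rbind, rows)
}

#' Ionic strength of a saline
#'
#' \eqn{I = \frac{1}{2}\sum_i c_i z_i^2} over all charged species, including
#' the pH-dependent buffer anions, EGTA (net charge -2) and their titrant
#' counter-cations.
#'
#' @param solution A [solution_composition()].
#' @return Ionic strength in mol/L.
#' @export
#' @examples
#' ionic_strength(solution_composition(c(NaCl = 150))) # 0.150
ionic_strength <- function(solution) {
  tab <- dissociate(solution)
  if (is.null(tab) || nrow(tab) == 0) stop("solution has no charged species")
  sum(tab$conc_mM / 1000 * tab$z^2) / 2
}

#' Extended Debye-Hueckel activity coefficient
#'
#' \eqn{\log_{10}\gamma = -A z^2 \sqrt{I} / (1 + B a \sqrt{I})} with
#' A = 0.509 (mol/L)^-1/2, B = 0.328 1/(Angstrom (mol/L)^1/2) and the Kielland
#' ion-size parameter \eqn{a}.
#'
#' @param ion Ion name (supplies valence and ion size when not given).
#' @param I Ionic strength in mol/L.
#' @param z Valence override.
#' @param a_angstrom Ion-size parameter override in Angstrom.
#' @param A,B Debye-Hueckel constants.
#' @return Activity coefficient in (0, 1].
#' @export
#' @examples
#' debye_huckel_gamma("Na", 0.17) # ~0.74
debye_huckel_gamma <- function(ion, I, z = NULL, a_angstrom = NULL,
                               A = 0.509, B = 0.328) {
  if (I < 0) stop("ionic strength must be >= 0")
  if (is.null(z)) z <- ion_valence(ion)
  if (is.null(a_angstrom)) {
    if (!ion %in% names(.kielland_a)) {
      stop("no ion-size parameter for ion: ", ion)
    }
    a_angstrom <- .kielland_a[[ion]]
  }
  10^(-A * z^2 * sqrt(I) / (1 + B * a_angstrom * sqrt(I)))
}

#' Effective activity of an ion in a solution
#'
#' \eqn{\alpha_x = \gamma_x [X]} with the activity coefficient evaluated at
#' the solution's own ionic strength.
#'
#' @param ion Cation name.
#' @param solution A [solution_composition()].
#' @return Effective activity in mM.
#' @export
#' @examples
#' effective_activity("Na", bath_monovalent("Na")) # ~111 mM
effective_activity <- function(ion, solution) {
  conc <- ion_conc(solution, ion)
  if (conc == 0) stop("ion ", ion, " is absent from the solution")
  debye_huckel_gamma(ion, ionic_strength(solution)) * conc
}

#' Standard monovalent-substitution bath saline
#'
#' X-Cl (150), HEPES (10), EGTA (5), CaCl2 (0.5) in mM, pH 7.4 titrated with
#' X-OH, where X is the test cation.
#'
#' @param ion Test monovalent cation (`"Na"`, `"Li"`, `"K"`, `"Rb"`, `"Cs"`).
#' @param ljp Measured liquid-junction potential for this bath, mV.
#' @param pH Bath pH.
#' @return A [solution_composition()].
#' @export
bath_monovalent <- function(ion = "Na", ljp = 0, pH = 7.4) {
  stopifnot(ion %in% c("Na", "Li", "K", "Rb", "Cs"))
  comp <- c(150, 10, 5, 0.5)
  names(comp) <- c(paste0(ion, "Cl"), "HEPES", "EGTA", "CaCl2")
  solution_composition(comp, pH = pH, ljp = ljp, titrant = ion)
}

#' Standard divalent-substitution bath saline
#'
#' X-Cl2 (110), HEPES (10), EGTA (5), CaCl2 (0.5) in mM, pH 7.4 titrated with
#' X-(OH)2, where X is the test cation.
#'
#' @param ion Test divalent cation (`"Mg"`, `"Ca"`, `"Sr"`, `"Ba"`).
#' @inheritParams bath_monovalent
#' @return A [solution_composition()].
#' @export
bath_divalent <- function(ion = "Ca", ljp = 0, pH = 7.4) {
  stopifnot(ion %in% c("Mg", "Ca", "Sr", "Ba"))
  comp <- c(110, 10, 5, 0.5)
  names(comp) <- c(paste0(ion, "Cl2"), "HEPES", "EGTA", "CaCl2")
  solution_composition(comp, pH = pH, ljp = ljp, titrant = ion)
}

#' Standard pipette saline for selectivity experiments
#'
#' NMDG (90, titrated with HCl), NaCl (20), HEPES (10), EGTA (5), CaCl2 (0.5)
#' in mM at pH 7.4. NMDG+ is impermeant, so Na+ (20 mM) is the only permeant
#' internal cation: the pseudo-bi-ionic configuration.
#'
#' @return A [solution_composition()].
#' @export
pipette_standard <- function() {
  solution_composition(
    c(NMDG = 90, NaCl = 20, HEPES = 10, EGTA = 5, CaCl2 = 0.5),
    pH = 7.4, titrant = "NMDG"
  )
}

#' Pipette saline for temperature/pH modulation experiments
#'
#' CsMES (100), HEPES (10), NaCl (15), EGTA (6), TAPS (5), MgCl2 (2),
#' CaCl2 (3) in mM.
#'
#' @param pH Pipette pH (6.4 to 9.4).
#' @return A [solution_composition()].
#' @export
pipette_thermo <- function(pH = 7.4) {
  solution_composition(
    c(CsMES = 100, HEPES = 10, NaCl = 15, EGTA = 6, TAPS = 5,
      MgCl2 = 2, CaCl2 = 3),
    pH = pH, titrant = "Cs"
  )
}

#' @export
print.solution_composition <- function(x, ...) {
  cat("<solution_composition> pH", x$pH, " LJP", x$ljp, "mV\n")
  comp <- x$components
  cat(paste0("  ", names(comp), " ", comp, " mM", collapse = "\n"), "\n")
  cat("  ionic strength:", signif(ionic_strength(x), 4), "mol/L\n")
  invisible(x)
}
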