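# Periodic-table constants used across the workflow. Covalent radii follow
# Cordero et al. (2008); masses are standard atomic weights (CIAAW, abridged).

.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Mn = 1.39, Fe = 1.32, Co = 1.26,
  Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19,
  Se = 1.20, Br = 1.20, Kr = 1.16, Rb = 2.20, Sr = 1.95, Mo = 1.54,
  Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44, In = 1.42,
  Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40, Cs = 2.44,
  Ba = 2.15, W = 1.62, Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45,
  Pb = 1.46, Bi = 1.48
)

.atomic_masses <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Ga = 69.723, Ge = 72.630,
  As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798, Rb = 85.468,
  Sr = 87.62, Mo = 95.95, Ru = 101.07, Rh = 102.906, Pd = 106.42,
  Ag = 107.868, Cd = 112.414, In = 114.818, Sn = 118.710, Sb = 121.760,
  Te = 127.60, I = 126.904, Xe = 131.293, Cs = 132.905, Ba = 137.327,
  W = 183.84, Pt = 195.084, Au = 196.967, Hg = 200.592, Tl = 204.38,
  Pb = 207.2, Bi = 208.980
)

#' Covalent radius of an element
#'
#' @param element character vector of element symbols (case-sensitive,
#'   e.g. `"Cl"`).
#' @return numeric vector of covalent radii in angstroms.
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Standard atomic mass of an element
#'
#' @inheritParams covalent_radius
#' @return numeric vector of masses in daltons.
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

is_known_element <- function(element) {
  element %in% names(.covalent_radii)
}

# Normalize PDB-style element strings ("FE", " C") to symbols ("Fe", "C").
normalize_element <- function(x) {
  x <- trimws(x)
  bad <- nchar(x) == 0L
  x <- paste0(toupper(substring(x, 1, 1)), tolower(substring(x, 2)))
  x[bad] <- ""
  x
}
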