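## Periodic-table data used throughout the package.
##
## Covalent radii (Angstrom) follow Cordero et al. (2008); for transition
## metals with spin-state-dependent radii the low-spin value is used. The
## table covers the elements that occur in organometallic functionalization
## work; unknown symbols raise an error at the point of use.

.covalentRadii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Ar = 1.06,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22,
  Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
  Cs = 2.44, Ba = 2.15, La = 2.07, Hf = 1.75, Ta = 1.70, W = 1.62,
  Re = 1.51, Os = 1.44, Ir = 1.41, Pt = 1.36, Au = 1.36, Hg = 1.32,
  Tl = 1.45, Pb = 1.46, Bi = 1.48
)

.atomicNumbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Hf = 72,
  Ta = 73, W = 74, Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80,
  Tl = 81, Pb = 82, Bi = 83
)

#' Covalent radius of an element
#'
#' Looks up the covalent radius (in Angstrom) used for bond perception and
#' for the default new-bond length when a substituent is attached to a
#' scaffold.
#'
#' @param symbol Character vector of element symbols (e.g. `"C"`, `"Ru"`).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' covalentRadius(c("H", "C"))
#' @export
covalentRadius <- function(symbol) {
  r <- .covalentRadii[symbol]
  if (anyNA(r)) {
    bad <- unique(symbol[is.na(r)])
    stop("no covalent radius for element symbol(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Atomic number of an element
#'
#' @param symbol Character vector of element symbols.
#' @return Integer vector of nuclear charges.
#' @examples
#' atomicNumber("Mn")
#' @export
atomicNumber <- function(symbol) {
  z <- .atomicNumbers[symbol]
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(as.integer(z))
}

#' Known element symbols
#'
#' @return Character vector of element symbols covered by the bundled
#'   periodic-table data.
#' @export
knownElements <- function() names(.covalentRadii)

.isKnownElement <- function(symbol) symbol %in% names(.covalentRadii)
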