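#' Emission-line registry
#'
#' The package identifies XRF channels by emission-line ids of the form
#' `"<element>.Ka"`. This registry holds the Ka line energies (keV) and atomic
#' masses (g/mol) of the elements handled by the wall model and the
#' quantification module.
#'
#' @return A data frame with columns `line`, `element`, `energy_keV`, and
#'   `atomic_mass`.
#' @export
#' @examples
#' xrf_lines()
xrf_lines <- function() {
  data.frame(
    line = c("Ca.Ka", "Mn.Ka", "Zn.Ka", "Sr.Ka", "Mg.Ka", "S.Ka", "P.Ka"),
    element = c("Ca", "Mn", "Zn", "Sr", "Mg", "S", "P"),
    energy_keV = c(3.6917, 5.8988, 8.6389, 14.165, 1.2536, 2.3078, 2.0137),
    atomic_mass = c(40.078, 54.938, 65.380, 87.620, 24.305, 32.060, 30.974),
    stringsAsFactors = FALSE
  )
}

# atomic masses used for chemical-formula mass fractions (matrix + traces)
.atomic_masses <- c(
  H = 1.008, C = 12.011, O = 15.999, Mg = 24.305, P = 30.974, S = 32.060,
  Ca = 40.078, Mn = 54.938, Zn = 65.380, Sr = 87.620
)

#' Line energy lookup
#'
#' @param line Emission-line id, e.g. `"Mn.Ka"`.
#' @return Line energy in keV.
#' @export
line_energy <- function(line) {
  reg <- xrf_lines()
  i <- match(line, reg$line)
  if (anyNA(i)) stop("unknown emission line: ", paste(line[is.na(i)], collapse = ", "))
  reg$energy_keV[i]
}

#' @rdname line_energy
#' @return `line_element()` returns the element symbol of a line id.
#' @export
line_element <- function(line) {
  reg <- xrf_lines()
  i <- match(line, reg$line)
  if (anyNA(i)) stop("unknown emission line: ", paste(line[is.na(i)], collapse = ", "))
  reg$element[i]
}

# Parse a simple chemical formula like "CaCO3" into element counts.
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.numeric(sub("^[A-Za-z]+", "", parts))
  n[is.na(n)] <- 1
  counts <- tapply(n, el, sum)
  out <- as.numeric(counts)
  names(out) <- names(counts)
  unknown <- setdiff(names(out), names(.atomic_masses))
  if (length(unknown)) stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "))
  out
}

# Mass fractions of the elements in a formula (named numeric, sums to 1).
formula_mass_fractions <- function(formula) {
  counts <- parse_formula(formula)
  w <- counts * .atomic_masses[names(counts)]
  w / sum(w)
}
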