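# Isotope masses (Da) and natural abundances: IUPAC-CIAAW 2021 atomic masses,
# CODATA electron mass. Enough elements for lipid-panel work in positive mode.

.ELECTRON_MASS <- 0.000548579909065

.ELEMENT_TABLE <- list(
  H  = list(mass = c(1.00782503207, 2.01410177812),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.00307400443, 15.00010889888),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
            abundance = c(0.99757, 0.00038, 0.00205)),
  Na = list(mass = 22.9897692820, abundance = 1.0),
  P  = list(mass = 30.97376199842, abundance = 1.0),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F  = list(mass = 18.99840316273, abundance = 1.0),
  Cl = list(mass = c(34.968852682, 36.965902602),
            abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
            abundance = c(0.932581, 0.000117, 0.067302))
)

#' Supported chemical elements
#'
#' Element symbols for which isotope masses and natural abundances are
#' built in.
#'
#' @return Character vector of element symbols.
#' @export
supportedElements <- function() names(.ELEMENT_TABLE)

#' Mass of the electron
#'
#' @return Electron rest mass in Da (CODATA).
#' @export
electronMass <- function() .ELECTRON_MASS

# monoisotopic = most abundant isotope; for every element in the table this is
# also the lightest, so entry 1 doubles as the envelope base peak
.monoMass <- function(element) {
  e <- .ELEMENT_TABLE[[element]]
  if (is.null(e)) stop("unknown element symbol: ", element)
  e$mass[which.max(e$abundance)]
}
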