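#' @import methods
NULL

#' Molecular formula
#'
#' An elemental composition: a named integer vector of element counts.
#' Zero-count entries are dropped, so two formulas are equal iff their count
#' maps are equal. The empty formula (no atoms) is legal and has mass 0.
#'
#' @slot counts Named integer vector, element symbol -> count (> 0).
#' @seealso [parseFormula()], [monoisotopicMass()]
#' @export
setClass("Formula", representation(counts = "integer"))

setValidity("Formula", function(object) {
  cnt <- object@counts
  if (length(cnt) == 0L) return(TRUE)
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    return("all counts must be named by element symbol")
  if (anyDuplicated(names(cnt))) return("duplicate element symbols")
  if (any(is.na(cnt)) || any(cnt <= 0L))
    return("counts must be positive (zero-count entries are dropped)")
  bad <- setdiff(names(cnt), supportedElements())
  if (length(bad)) return(paste("unknown element symbol:", bad[1]))
  TRUE
})

.formula <- function(counts) {
  counts <- counts[counts != 0]
  storage.mode(counts) <- "integer"
  new("Formula", counts = counts)
}

#' Parse a Hill-notation molecular formula
#'
#' Accepts element-symbol + optional-count tokens without parentheses, e.g.
#' `"C24H47NO7"`. An omitted count means 1.
#'
#' @param text Formula string.
#' @return A [Formula-class] object.
#' @examples
#' parseFormula("C24H47NO7")   # psychosine
#' parseFormula("H2O")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse formula: ", text)
  sym <- sub("[0-9]*$", "", tokens)
  bad <- setdiff(sym, supportedElements())
  if (length(bad))
    stop("unknown element symbol '", bad[1], "' in formula: ", text)
  n <- sub("^[A-Za-z]+", "", tokens)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  counts <- tapply(n, sym, sum)
  .formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Canonical Hill string of a formula
#'
#' Carbon first, hydrogen second, remaining elements alphabetically (all
#' alphabetical when no carbon is present).
#'
#' @param f A [Formula-class].
#' @return Character scalar ("" for the empty formula).
#' @export
hillFormula <- function(f) {
  cnt <- f@counts
  if (!length(cnt)) return("")
  syms <- sort(names(cnt))
  if ("C" %in% syms) syms <- c("C", intersect("H", syms), setdiff(syms, c("C", "H")))
  paste0(vapply(syms, function(s)
    paste0(s, if (cnt[[s]] > 1L) cnt[[s]] else ""), ""), collapse = "")
}

setMethod("show", "Formula", function(object) {
  cat("Formula: ", if (length(object@counts)) hillFormula(object) else "(empty)",
      "  (monoisotopic ", format(monoisotopicMass(object), nsmall = 6), " Da)\n",
      sep = "")
})

.addCounts <- function(a, b, sign = 1L) {
  syms <- union(names(a), names(b))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + sign * b
  out
}

#' Combine formulas
#'
#' `addFormulas` merges compositions; `subtractFormulas` removes one from the
#' other and errors if any element count would go negative.
#'
#' @param a,b [Formula-class] objects.
#' @return A [Formula-class].
#' @export
addFormulas <- function(a, b) .formula(.addCounts(a@counts, b@counts))

#' @rdname addFormulas
#' @export
subtractFormulas <- function(a, b) {
  out <- .addCounts(a@counts, b@counts, sign = -1L)
  if (any(out < 0L))
    stop("composition error: cannot remove ",
         hillFormula(b), " from ", hillFormula(a))
  .formula(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope masses times element counts; the empty
#' formula has mass 0.
#'
#' @param f A [Formula-class] or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")        # 18.010565
#' monoisotopicMass("C24H47NO7")  # psychosine, 461.335253
#' @export
monoisotopicMass <- function(f) {
  f <- .asFormula(f)
  cnt <- f@counts
  if (!length(cnt)) return(0)
  sum(vapply(names(cnt), .monoMass, 0) * as.numeric(cnt))
}

.asFormula <- function(f) {
  if (is(f, "Formula")) f else parseFormula(f)
}

#' Ionization adduct specification
#'
#' Describes how a neutral molecule M becomes an observed ion: atoms added,
#' atoms removed, the signed charge, and the number of electrons removed
#' (one per positive charge in positive mode; 1 for a radical cation formed
#' by electron loss alone).
#'
#' @slot name Display label, e.g. `"[M+H]+"`.
#' @slot added,removed [Formula-class] compositions.
#' @slot charge Signed integer charge (never 0).
#' @slot electronDelta Integer count of electrons removed.
#' @export
setClass("Adduct", representation(name = "character", added = "Formula",
                                  removed = "Formula", charge = "integer",
                                  electronDelta = "integer"))

setValidity("Adduct", function(object) {
  if (object@charge == 0L) return("adduct charge must be nonzero")
  TRUE
})

setMethod("show", "Adduct", function(object) {
  cat("Adduct ", object@name, ": +", hillFormula(object@added),
      if (length(object@removed@counts)) paste0(" -", hillFormula(object@removed)) else "",
      ", charge ", object@charge, ", e- removed ", object@electronDelta, "\n", sep = "")
})

.mkAdduct <- function(name, added = "", removed = "", charge = 1L,
                      electronDelta = charge) {
  new("Adduct", name = name,
      added = if (nzchar(added)) parseFormula(added) else .formula(integer(0)),
      removed = if (nzchar(removed)) parseFormula(removed) else .formula(integer(0)),
      charge = as.integer(charge), electronDelta = as.integer(electronDelta))
}

#' Built-in positive-mode adducts
#'
#' The protonated ion, its water loss, the ammonium and sodium adducts, and
#' the radical cation (the fluoranthene lock-mass species).
#'
#' @return Named list of [Adduct-class] objects with names `"M+H"`,
#'   `"M+H-H2O"`, `"M+NH4"`, `"M+Na"`, `"M+."`.
#' @export
builtinAdducts <- function() {
  list(
    "M+H"     = .mkAdduct("[M+H]+", added = "H"),
    "M+H-H2O" = .mkAdduct("[M+H-H2O]+", added = "H", removed = "H2O"),
    "M+NH4"   = .mkAdduct("[M+NH4]+", added = "NH4"),
    "M+Na"    = .mkAdduct("[M+Na]+", added = "Na"),
    "M+."     = .mkAdduct("[M]+.", added = "")
  )
}

.asAdduct <- function(a) {
  if (is(a, "Adduct")) return(a)
  ad <- builtinAdducts()[[a]]
  if (is.null(ad)) stop("unknown adduct name: ", a,
                        " (built in: ", paste(names(builtinAdducts()), collapse = ", "), ")")
  ad
}

#' Theoretical m/z of an adduct ion
#'
#' `(m(M) + m(added) - m(removed) - electronDelta * m_e) / |charge|`, with
#' monoisotopic masses throughout. Values are never rounded internally;
#' round to 4 decimals only for display.
#'
#' @param f Neutral molecule, [Formula-class] or string.
#' @param adduct An [Adduct-class] or a built-in adduct name.
#' @return m/z in Th.
#' @examples
#' adductMz("C24H47NO7", "M+H")   # psychosine [M+H]+ -> 462.3425
#' adductMz("C27H46O", "M+Na")    # cholesterol [M+Na]+ -> 409.3441
#' adductMz("C16H10", "M+.")      # fluoranthene lock mass -> 202.0777
#' @export
adductMz <- function(f, adduct) {
  f <- .asFormula(f)
  a <- .asAdduct(adduct)
  ion <- subtractFormulas(addFormulas(f, a@added), a@removed)
  (monoisotopicMass(ion) - a@electronDelta * .ELECTRON_MASS) / abs(a@charge)
}

# ion composition after applying an adduct (electron bookkeeping separate)
.ionFormula <- function(f, adduct) {
  a <- .asAdduct(adduct)
  subtractFormulas(addFormulas(.asFormula(f), a@added), a@removed)
}

#' Fragment m/z after a neutral loss
#'
#' Subtracts the monoisotopic mass of the lost neutral from a singly charged
#' precursor m/z; the charge is assumed unchanged.
#'
#' @param precursorMz Precursor m/z in Th.
#' @param loss Neutral-loss composition, [Formula-class] or string.
#' @return Fragment m/z in Th.
#' @examples
#' mh <- adductMz("C24H47NO7", "M+H")
#' neutralLossMz(mh, "C6H12O6")  # galactose loss -> 282.2791
#' @export
neutralLossMz <- function(precursorMz, loss) {
  out <- precursorMz - monoisotopicMass(loss)
  if (any(out <= 0)) stop("neutral loss exceeds precursor m/z")
  out
}

#' Signed relative mass error in ppm
#'
#' @param observed,theoretical m/z values in Th; `theoretical` must be > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Isotope envelope
#'
#' Relative isotopologue abundances aggregated by nucleon-number offset
#' (M, M+1, M+2, ...), i.e. fine structure merged — the envelope an Orbitrap
#' displays at lipid masses. Entries are truncated to `nPeaks` and
#' renormalized to sum to 1.
#'
#' @slot mz Peak m/z values (strictly increasing; entry 1 is monoisotopic).
#' @slot abundance Relative abundances summing to 1.
#' @export
setClass("IsotopePattern", representation(mz = "numeric", abundance = "numeric"))

setValidity("IsotopePattern", function(object) {
  if (length(object@mz) != length(object@abundance)) return("length mismatch")
  if (length(object@mz) == 0) return("empty pattern")
  if (any(diff(object@mz) <= 0)) return("m/z must be strictly increasing")
  if (abs(sum(object@abundance) - 1) > 1e-9) return("abundances must sum to 1")
  TRUE
})

setMethod("show", "IsotopePattern", function(object) {
  cat("IsotopePattern with", length(object@mz), "peaks\n")
  print(data.frame(mz = round(object@mz, 4),
                   abundance = signif(object@abundance, 6)))
})

# single-element n-atom distribution over nucleon offsets, by binary-power
# convolution of the one-atom distribution; tracks abundance-weighted mass
.atomDist <- function(element) {
  e <- .ELEMENT_TABLE[[element]]
  base <- round(min(e$mass))
  off <- round(e$mass) - base
  list(offset = as.integer(off), p = e$abundance, mass = e$mass)
}

.convolveDist <- function(a, b, tol = 1e-12) {
  off <- as.vector(outer(a$offset, b$offset, "+"))
  p <- as.vector(outer(a$p, b$p))
  m <- as.vector(outer(a$mass, b$mass, "+"))
  key <- factor(off)
  ps <- tapply(p, key, sum)
  ms <- tapply(p * m, key, sum) / ps
  keep <- ps > tol
  o <- as.integer(names(ps))[keep]
  ord <- order(o)
  list(offset = o[ord], p = as.numeric(ps[keep])[ord], mass = as.numeric(ms[keep])[ord])
}

.powDist <- function(d, n) {
  res <- NULL
  while (n > 0) {
    if (n %% 2 == 1) res <- if (is.null(res)) d else .convolveDist(res, d)
    n <- n %/% 2
    if (n > 0) d <- .convolveDist(d, d)
  }
  if (is.null(res)) list(offset = 0L, p = 1, mass = 0) else res
}

#' Theoretical isotope pattern of a formula or adduct ion
#'
#' Per-element isotope distributions are convolved, aggregated by integer
#' nucleon offset, truncated to `nPeaks` and renormalized. With `adduct`
#' given, the pattern of the ion composition is returned on the m/z scale
#' (electron mass and charge applied).
#'
#' @param f Neutral molecule, [Formula-class] or string.
#' @param nPeaks Number of envelope peaks to keep (>= 1).
#' @param adduct Optional [Adduct-class] or built-in adduct name.
#' @return An [IsotopePattern-class].
#' @examples
#' isotopePattern("C", 2)                        # ~ 0.9893 / 0.0107
#' isotopePattern("C24H47NO7", 4, adduct = "M+H")
#' @export
isotopePattern <- function(f, nPeaks = 4L, adduct = NULL) {
  if (nPeaks < 1L) stop("nPeaks must be >= 1")
  charge <- 1L; edelta <- 0L
  if (!is.null(adduct)) {
    a <- .asAdduct(adduct)
    f <- .ionFormula(f, a)
    charge <- abs(a@charge); edelta <- a@electronDelta
  } else f <- .asFormula(f)
  cnt <- f@counts
  if (!length(cnt)) stop("cannot compute an isotope pattern of the empty formula")
  dist <- NULL
  for (el in names(cnt)) {
    d <- .powDist(.atomDist(el), cnt[[el]])
    dist <- if (is.null(dist)) d else .convolveDist(dist, d)
  }
  keep <- seq_len(min(nPeaks, length(dist$offset)))
  p <- dist$p[keep] / sum(dist$p[keep])
  mz <- (dist$mass[keep] - edelta * .ELECTRON_MASS) / charge
  new("IsotopePattern", mz = mz, abundance = p)
}

#' Adduct m/z table for a lipid panel
#'
#' Computes, for each molecule, the theoretical m/z of the requested adducts
#' — the table a practitioner checks against annotation software output.
#'
#' @param formulas Character vector of formulas (named by species, optional).
#' @param adducts Character vector of built-in adduct names or list of
#'   [Adduct-class] objects.
#' @param digits Display rounding (half-even), default 4 decimals.
#' @return data.frame with columns species, formula, adduct, mz.
#' @export
adductTable <- function(formulas, adducts = c("M+H", "M+H-H2O", "M+NH4", "M+Na"),
                        digits = 4) {
  species <- if (is.null(names(formulas))) formulas else names(formulas)
  rows <- lapply(seq_along(formulas), function(i) {
    data.frame(species = species[i], formula = formulas[[i]],
               adduct = vapply(adducts, function(a) .asAdduct(a)@name, ""),
               mz = round(vapply(adducts, function(a)
                 adductMz(formulas[[i]], a), 0), digits),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
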