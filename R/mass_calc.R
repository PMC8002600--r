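# Theoretical protein masses on the monoisotopic and average scales.
#
# Residue masses are derived at load time from elemental compositions and a
# single table of atomic masses, so the two scales cannot drift apart.

# Atomic masses: average = IUPAC standard atomic weights; monoisotopic =
# lightest-isotope masses.
.element_masses <- local({
  m <- rbind(
    H = c(monoisotopic = 1.00782503207, average = 1.00794),
    C = c(monoisotopic = 12.0,          average = 12.0107),
    N = c(monoisotopic = 14.0030740048, average = 14.0067),
    O = c(monoisotopic = 15.9949146196, average = 15.9994),
    S = c(monoisotopic = 31.97207100,   average = 32.065)
  )
  m
})

.proton_mass <- 1.007276466879

# Elemental composition (H, C, N, O, S) of each amino-acid residue, i.e. the
# amino acid minus one water.
.residue_formulas <- local({
  f <- rbind(
    G = c(3, 2, 1, 1, 0),
    A = c(5, 3, 1, 1, 0),
    S = c(5, 3, 1, 2, 0),
    P = c(7, 5, 1, 1, 0),
    V = c(9, 5, 1, 1, 0),
    T = c(7, 4, 1, 2, 0),
    C = c(5, 3, 1, 1, 1),
    L = c(11, 6, 1, 1, 0),
    I = c(11, 6, 1, 1, 0),
    N = c(6, 4, 2, 2, 0),
    D = c(5, 4, 1, 3, 0),
    Q = c(8, 5, 2, 2, 0),
    K = c(12, 6, 2, 1, 0),
    E = c(7, 5, 1, 3, 0),
    M = c(9, 5, 1, 1, 1),
    H = c(7, 6, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(12, 6, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(10, 11, 2, 1, 0)
  )
  colnames(f) <- c("H", "C", "N", "O", "S")
  f
})

# residue masses (rows: residue, cols: monoisotopic / average)
.residue_masses <- .residue_formulas[, rownames(.element_masses)] %*% .element_masses

.water_mass <- c(
  monoisotopic = 2 * .element_masses["H", "monoisotopic"] + .element_masses["O", "monoisotopic"],
  average      = 2 * .element_masses["H", "average"] + .element_masses["O", "average"]
)

#' Theoretical molecular mass of a protein sequence
#'
#' Computes the neutral molecular mass of an unmodified, full-length
#' polypeptide chain as the sum of residue masses plus one water, on both the
#' monoisotopic and the average (isotope-abundance-weighted) scale. Intact-cell
#' biotyping peaks above ~1 kDa are matched on the average scale; the
#' monoisotopic value is reported alongside for completeness.
#'
#' @param sequence Character scalar over the 20 standard one-letter amino-acid
#'   codes (case-insensitive).
#' @param met_excised If \code{TRUE}, also return the masses of the chain with
#'   the initiator methionine removed (only when the sequence starts with M).
#'   Off by default: masses are computed from the full-length deposited chain.
#' @return A list of class \code{"mass_pair"} with elements
#'   \code{monoisotopic} and \code{average} (Da), and, when requested and
#'   applicable, \code{monoisotopic_met_excised} / \code{average_met_excised}.
#' @examples
#' protein_mass("GG")
#' @export
protein_mass <- function(sequence, met_excised = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("'sequence' must be a single non-empty character string")
  }
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% rownames(.residue_masses)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-standard residue '%s' at position %d; mass defined only for the 20 standard amino acids",
      residues[bad[1L]], bad[1L]
    ))
  }
  counts <- table(factor(residues, levels = rownames(.residue_masses)))
  total <- as.numeric(counts) %*% .residue_masses
  out <- list(
    monoisotopic = unname(total[1L, "monoisotopic"] + .water_mass[["monoisotopic"]]),
    average      = unname(total[1L, "average"] + .water_mass[["average"]])
  )
  if (isTRUE(met_excised) && residues[1L] == "M" && length(residues) > 1L) {
    out$monoisotopic_met_excised <- out$monoisotopic - .residue_masses["M", "monoisotopic"]
    out$average_met_excised <- out$average - .residue_masses["M", "average"]
  }
  class(out) <- "mass_pair"
  out
}

#' @export
print.mass_pair <- function(x, ...) {
  cat(sprintf("molecular mass: monoisotopic %.4f Da, average %.3f Da\n",
              x$monoisotopic, x$average))
  invisible(x)
}

#' Singly protonated ([M+H]+) mass
#'
#' Converts a neutral molecular mass to the m/z of its singly protonated ion.
#' On the average scale the hydrogen atomic weight (1.00794) is added; on the
#' monoisotopic scale the proton mass (1.007276). At the +/- 2 Da matching
#' tolerance used for intact-cell profiles the electron-mass distinction is
#' immaterial, but the convention is fixed here so results are reproducible.
#'
#' @param mass Neutral mass in Da (> 0); vectorised.
#' @param scale \code{"average"} or \code{"monoisotopic"}.
#' @return m/z of \code{[M+H]+} in Da.
#' @examples
#' protonated_mass(1000, "average")
#' @export
protonated_mass <- function(mass, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("'mass' must be positive and finite")
  }
  shift <- if (scale == "average") .element_masses["H", "average"] else .proton_mass
  mass + shift
}
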