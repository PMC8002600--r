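# Peak annotation by theoretical protein mass within a tolerance window.

#' Build a sorted theoretical-mass index from a proteome
#'
#' Computes the theoretical mass of every computable protein record on the
#' chosen scale and adduct convention and returns them sorted ascending, ready
#' for window queries. Records flagged non-computable (non-standard residues)
#' are skipped with a warning giving their count.
#'
#' @param proteome A \code{\link{read_proteome}} data.frame (or any data.frame
#'   with \code{accession}, \code{description}, \code{sequence} columns; a
#'   missing \code{computable} column is derived).
#' @param scale Mass scale: \code{"average"} (default; the scale intact-cell
#'   biotyping peaks are matched on) or \code{"monoisotopic"}.
#' @param adduct \code{"MH"} (default) for singly protonated \code{[M+H]+}
#'   masses, matching the m/z axis of positive-mode spectra, or
#'   \code{"neutral"}.
#' @return An object of class \code{"mass_index"}: list with \code{entries}
#'   (data.frame \code{mass}, \code{accession}, \code{description}, sorted by
#'   mass), \code{scale} and \code{adduct}.
#' @export
build_mass_index <- function(proteome, scale = c("average", "monoisotopic"),
                             adduct = c("MH", "neutral")) {
  scale <- match.arg(scale)
  adduct <- match.arg(adduct)
  stopifnot(is.data.frame(proteome),
            all(c("accession", "sequence") %in% names(proteome)))
  computable <- if ("computable" %in% names(proteome)) {
    proteome$computable
  } else {
    !grepl(sprintf("[^%s]", paste(.standard_aa, collapse = "")),
           toupper(proteome$sequence))
  }
  n_skip <- sum(!computable)
  if (n_skip > 0) {
    warning(sprintf("%d record(s) with non-standard residues skipped", n_skip))
  }
  keep <- proteome[computable, , drop = FALSE]
  if (nrow(keep) == 0L) stop("no computable protein records")
  mass <- vapply(keep$sequence, function(s) protein_mass(s)[[scale]], 0,
                 USE.NAMES = FALSE)
  if (adduct == "MH") mass <- protonated_mass(mass, scale)
  entries <- data.frame(
    mass = mass,
    accession = keep$accession,
    description = if ("description" %in% names(keep)) keep$description else "",
    stringsAsFactors = FALSE
  )
  entries <- entries[order(entries$mass, entries$accession), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, scale = scale, adduct = adduct),
            class = "mass_index")
}

#' @export
print.mass_index <- function(x, ...) {
  cat(sprintf("mass index: %d entries, %s %s masses %.1f-%.1f Da\n",
              nrow(x$entries), x$scale,
              if (x$adduct == "MH") "[M+H]+" else "neutral",
              min(x$entries$mass), max(x$entries$mass)))
  invisible(x)
}

#' Annotate peaks by theoretical protein mass
#'
#' For each peak, reports every index entry whose theoretical mass lies within
#' \code{peak m/z +/- tol}, ranked by absolute mass difference (rank 1 =
#' closest). The assignment is deliberately many-to-many: one peak can match
#' several proteins and one protein several peaks. Peaks with no candidate are
#' reported with an explicit unassigned row; peaks with more than
#' \code{ambiguity_cap} candidates are flagged low-specificity — mass-only
#' assignment at these densities should be taken with caution.
#'
#' @param x A \code{\link{peaklist}} or \code{consensus_profile}.
#' @param index A \code{\link{build_mass_index}} object.
#' @param tol Tolerance window in Da (> 0); default 2 Da.
#' @param ambiguity_cap Candidate count above which a peak is flagged
#'   low-specificity; default 5.
#' @return A data.frame of class \code{"annotation"} with one row per
#'   (peak, candidate) and columns \code{peak_mz}, \code{intensity},
#'   \code{accession}, \code{description}, \code{theoretical_mass},
#'   \code{delta} (peak m/z minus theoretical mass), \code{rank},
#'   \code{n_candidates}, \code{low_specificity}. Unassigned peaks carry NA
#'   accession and 0 candidates.
#' @export
annotate_peaks <- function(x, index, tol = 2, ambiguity_cap = 5) {
  stopifnot(inherits(index, "mass_index"))
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  if (nrow(index$entries) == 0L) stop("empty mass index")
  pt <- .peak_table(x)
  ent <- index$entries
  res <- vector("list", nrow(pt))
  for (i in seq_len(nrow(pt))) {
    mz <- pt$mz[i]
    lo <- findInterval(mz - tol, ent$mass, left.open = TRUE) + 1L
    hi <- findInterval(mz + tol, ent$mass)
    if (hi >= lo) {
      cand <- ent[lo:hi, , drop = FALSE]
      delta <- mz - cand$mass
      o <- order(abs(delta), cand$accession)
      nc <- length(o)
      res[[i]] <- data.frame(
        peak_mz = mz, intensity = pt$intensity[i],
        accession = cand$accession[o], description = cand$description[o],
        theoretical_mass = cand$mass[o], delta = delta[o],
        rank = seq_len(nc), n_candidates = nc,
        low_specificity = nc > ambiguity_cap,
        stringsAsFactors = FALSE
      )
    } else {
      res[[i]] <- data.frame(
        peak_mz = mz, intensity = pt$intensity[i],
        accession = NA_character_, description = NA_character_,
        theoretical_mass = NA_real_, delta = NA_real_,
        rank = NA_integer_, n_candidates = 0L, low_specificity = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("annotation", "data.frame")
  out
}

#' Export annotations as CSV
#'
#' Deterministic, byte-stable output for identical inputs.
#'
#' @param x An \code{annotation} data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "annotation"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
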