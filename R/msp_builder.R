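# Consensus profile (main spectra projection, MSP) construction.

#' Build a consensus profile (MSP) from replicate peak lists
#'
#' Merges replicate spectra of one sample into a consensus peak profile, the
#' unit compared in biotyping. Peaks pooled across all replicates are grouped
#' by single-linkage chaining within \code{tol} on the sorted m/z union; a
#' chain spanning more than \code{2 * tol} is split at its largest internal
#' gap so consensus peak width stays bounded. Each group present in at least
#' \code{min_frequency} of the source spectra becomes one consensus peak with
#' m/z the intensity-weighted mean of its members and intensity the mean over
#' the spectra that contain it (absent spectra are excluded, not zero-filled).
#' If more than \code{max_peaks} groups survive, the \code{max_peaks} most
#' intense are kept.
#'
#' @param spectra Non-empty list of \code{\link{peaklist}} objects.
#' @param tol Grouping tolerance in Da (> 0). Default 2 Da, the tolerance
#'   used throughout for peak matching.
#' @param min_frequency Minimum fraction of source spectra a group must occur
#'   in, in (0, 1]. Default 0.25.
#' @param max_peaks Cap on the number of consensus peaks; default 100,
#'   matching the ~100 species-characteristic peaks a typical intact-cell
#'   profile carries.
#' @param profile_id Identifier for the profile; defaults to the first
#'   spectrum's id with a \code{"_msp"} suffix.
#' @param meta Metadata list; defaults to the first spectrum's metadata.
#' @return An object of class \code{"consensus_profile"}: list with
#'   \code{profile_id}, \code{peaks} (data.frame \code{mz},
#'   \code{mean_intensity}, \code{frequency}), \code{n_source_spectra},
#'   \code{meta} and \code{params}.
#' @export
build_msp <- function(spectra, tol = 2, min_frequency = 0.25, max_peaks = 100,
                      profile_id = NULL, meta = NULL) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("'spectra' must be a non-empty list of peaklist objects")
  }
  if (!all(vapply(spectra, inherits, TRUE, "peaklist"))) {
    stop("every element of 'spectra' must be a peaklist")
  }
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  if (!is.numeric(min_frequency) || min_frequency <= 0 || min_frequency > 1) {
    stop("'min_frequency' must be in (0, 1]")
  }
  n_spec <- length(spectra)
  if (is.null(profile_id)) profile_id <- paste0(spectra[[1L]]$spectrum_id, "_msp")
  if (is.null(meta)) meta <- spectra[[1L]]$meta

  pool <- do.call(rbind, lapply(seq_len(n_spec), function(i) {
    p <- spectra[[i]]$peaks
    if (nrow(p) == 0L) return(NULL)
    data.frame(mz = p$mz, intensity = p$intensity, source = i)
  }))
  if (is.null(pool) || nrow(pool) == 0L) stop("no peaks in any input spectrum")
  pool <- pool[order(pool$mz), , drop = FALSE]

  groups <- .group_peaks(pool$mz, tol)

  cons <- lapply(groups, function(ix) {
    mzs <- pool$mz[ix]; ints <- pool$intensity[ix]; src <- pool$source[ix]
    # per-spectrum intensity: a spectrum contributing several pooled peaks to
    # one group counts once, with its intensities summed
    per_spec <- tapply(ints, factor(src, levels = unique(src)), sum)
    freq <- length(unique(src)) / n_spec
    w <- if (sum(ints) > 0) ints / sum(ints) else rep(1 / length(ints), length(ints))
    c(mz = sum(w * mzs), mean_intensity = mean(as.numeric(per_spec)), frequency = freq)
  })
  cons <- as.data.frame(do.call(rbind, cons))
  cons <- cons[cons$frequency >= min_frequency, , drop = FALSE]
  if (nrow(cons) > max_peaks) {
    keep <- order(cons$mean_intensity, decreasing = TRUE)[seq_len(max_peaks)]
    cons <- cons[sort(keep), , drop = FALSE]
  }
  cons <- cons[order(cons$mz), , drop = FALSE]
  rownames(cons) <- NULL

  structure(
    list(
      profile_id = profile_id,
      peaks = cons,
      n_source_spectra = n_spec,
      meta = meta,
      params = list(tol = tol, min_frequency = min_frequency, max_peaks = max_peaks)
    ),
    class = "consensus_profile"
  )
}

# Single-linkage grouping on sorted m/z: chains break at gaps > tol; a chain
# whose span exceeds 2*tol is split recursively at its largest internal gap.
.group_peaks <- function(mz_sorted, tol) {
  n <- length(mz_sorted)
  if (n == 0L) return(list())
  gap <- diff(mz_sorted)
  breaks <- which(gap > tol)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- list()
  for (k in seq_along(starts)) {
    out <- c(out, .split_wide(mz_sorted, starts[k]:ends[k], tol))
  }
  out
}

.split_wide <- function(mz, ix, tol) {
  if (mz[ix[length(ix)]] - mz[ix[1L]] <= 2 * tol || length(ix) < 2L) {
    return(list(ix))
  }
  gaps <- diff(mz[ix])
  cut <- which.max(gaps)
  c(.split_wide(mz, ix[seq_len(cut)], tol),
    .split_wide(mz, ix[(cut + 1L):length(ix)], tol))
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus profile '%s': %d peaks from %d spectra",
              x$profile_id, nrow(x$peaks), x$n_source_spectra))
  if (nrow(x$peaks) > 0) {
    cat(sprintf(", m/z %.1f-%.1f", min(x$peaks$mz), max(x$peaks$mz)))
  }
  cat("\n")
  invisible(x)
}

#' @method plot consensus_profile
#' @export
plot.consensus_profile <- function(x, ...) {
  p <- x$peaks
  graphics::plot(p$mz, p$mean_intensity, type = "h",
                 xlab = "m/z (Da)", ylab = "mean intensity (a.u.)",
                 main = x$profile_id, ...)
  invisible(x)
}

#' Normalize peak intensities
#'
#' Explicit intensity normalization for a peak list or consensus profile.
#' \code{"base-peak"} scales the most intense peak to 100; \code{"tic"}
#' scales intensities to sum to 1. Normalization is idempotent and never
#' applied implicitly on read.
#'
#' @param x A \code{\link{peaklist}} or \code{consensus_profile}.
#' @param mode \code{"base-peak"} (default) or \code{"tic"}.
#' @return An object of the same class with rescaled intensities.
#' @export
normalize_intensities <- function(x, mode = c("base-peak", "tic")) {
  mode <- match.arg(mode)
  UseMethod("normalize_intensities")
}

#' @export
normalize_intensities.peaklist <- function(x, mode = c("base-peak", "tic")) {
  mode <- match.arg(mode)
  x$peaks$intensity <- .rescale(x$peaks$intensity, mode)
  x
}

#' @export
normalize_intensities.consensus_profile <- function(x, mode = c("base-peak", "tic")) {
  mode <- match.arg(mode)
  x$peaks$mean_intensity <- .rescale(x$peaks$mean_intensity, mode)
  x
}

.rescale <- function(v, mode) {
  if (length(v) == 0L || all(v == 0)) stop("cannot normalize all-zero intensities")
  if (mode == "base-peak") 100 * v / max(v) else v / sum(v)
}

#' Write a consensus profile as CSV (plus a JSON-like metadata sidecar)
#'
#' The peak table goes to \code{path} as CSV with columns \code{mz},
#' \code{mean_intensity}, \code{frequency}; build parameters and metadata go
#' to \code{<path>.meta.yaml}.
#'
#' @param x A \code{consensus_profile}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_msp <- function(x, path) {
  stopifnot(inherits(x, "consensus_profile"))
  utils::write.csv(x$peaks, path, row.names = FALSE)
  side <- list(profile_id = x$profile_id, n_source_spectra = x$n_source_spectra,
               params = x$params, meta = x$meta)
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a consensus profile written by \code{write_msp}
#'
#' @param path CSV path previously written by \code{\link{write_msp}}.
#' @return A \code{consensus_profile}.
#' @export
read_msp <- function(path) {
  peaks <- utils::read.csv(path)
  stopifnot(all(c("mz", "mean_intensity", "frequency") %in% names(peaks)))
  side_path <- paste0(path, ".meta.yaml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  structure(
    list(
      profile_id = side$profile_id %||% sub("\\.[^.]*$", "", basename(path)),
      peaks = peaks[order(peaks$mz), , drop = FALSE],
      n_source_spectra = side$n_source_spectra %||% 1L,
      meta = side$meta %||% list(),
      params = side$params %||% list()
    ),
    class = "consensus_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: make a consensus_profile directly from mz/intensity vectors
.profile_from_peaks <- function(mz, intensity, profile_id, meta = list(),
                                frequency = 1, n_source = 1L) {
  o <- order(mz)
  structure(
    list(
      profile_id = profile_id,
      peaks = data.frame(mz = mz[o], mean_intensity = intensity[o],
                         frequency = rep_len(frequency, length(mz))[o]),
      n_source_spectra = n_source,
      meta = meta,
      params = list()
    ),
    class = "consensus_profile"
  )
}
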