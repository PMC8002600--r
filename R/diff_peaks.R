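# Differential peak detection between a treated profile and its control.

.peak_table <- function(x) {
  if (inherits(x, "consensus_profile")) {
    data.frame(mz = x$peaks$mz,
               intensity = x$peaks$mean_intensity,
               frequency = x$peaks$frequency)
  } else if (inherits(x, "peaklist")) {
    data.frame(mz = x$peaks$mz, intensity = x$peaks$intensity,
               frequency = NA_real_)
  } else {
    stop("expected a peaklist or consensus_profile")
  }
}

.profile_label <- function(x) {
  if (inherits(x, "consensus_profile")) x$profile_id else x$spectrum_id
}

#' Differential peaks between a sample profile and its control
#'
#' Matches sample peaks to control peaks one-to-one, greedily by ascending
#' absolute m/z difference over all cross pairs within \code{tol} (ties broken
#' toward the lower control m/z), each peak used at most once. Unmatched
#' sample peaks are the newly appeared peaks; unmatched control peaks are the
#' missing peaks. Presence/absence only: intensities are carried through for
#' reporting but play no role in the matching.
#'
#' @param sample,control \code{consensus_profile} (or \code{peaklist})
#'   objects; both non-empty.
#' @param tol Matching tolerance in Da (> 0); default 2 Da.
#' @return An object of class \code{"diff_report"}: list with data.frames
#'   \code{new_peaks}, \code{missing_peaks} (columns \code{mz},
#'   \code{intensity}, \code{frequency}) and \code{shared} (columns
#'   \code{sample_mz}, \code{control_mz}, \code{delta}), plus \code{tol} and
#'   the two profile ids.
#' @export
diff_profiles <- function(sample, control, tol = 2) {
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  s <- .peak_table(sample)
  c_ <- .peak_table(control)
  if (nrow(s) == 0L || nrow(c_) == 0L) stop("both profiles must be non-empty")

  # candidate cross pairs within tol
  pairs <- NULL
  for (i in seq_len(nrow(s))) {
    j <- which(abs(c_$mz - s$mz[i]) <= tol)
    if (length(j)) {
      pairs <- rbind(pairs, data.frame(
        si = i, cj = j, delta = s$mz[i] - c_$mz[j]
      ))
    }
  }
  s_used <- logical(nrow(s)); c_used <- logical(nrow(c_))
  matched <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    pairs <- pairs[order(abs(pairs$delta), c_$mz[pairs$cj]), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$si[k]; j <- pairs$cj[k]
      if (!s_used[i] && !c_used[j]) {
        s_used[i] <- TRUE; c_used[j] <- TRUE
        matched <- rbind(matched, data.frame(
          sample_mz = s$mz[i], control_mz = c_$mz[j], delta = pairs$delta[k]
        ))
      }
    }
  }
  if (is.null(matched)) {
    matched <- data.frame(sample_mz = numeric(0), control_mz = numeric(0),
                          delta = numeric(0))
  } else {
    matched <- matched[order(matched$sample_mz), , drop = FALSE]
    rownames(matched) <- NULL
  }
  new_peaks <- s[!s_used, , drop = FALSE]; rownames(new_peaks) <- NULL
  missing_peaks <- c_[!c_used, , drop = FALSE]; rownames(missing_peaks) <- NULL

  structure(
    list(
      sample_id = .profile_label(sample),
      control_id = .profile_label(control),
      new_peaks = new_peaks,
      missing_peaks = missing_peaks,
      shared = matched,
      tol = tol
    ),
    class = "diff_report"
  )
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf("diff '%s' vs control '%s' (tol %.2g Da):\n",
              x$sample_id, x$control_id, x$tol))
  cat(sprintf("  %d newly appeared, %d missing, %d shared\n",
              nrow(x$new_peaks), nrow(x$missing_peaks), nrow(x$shared)))
  invisible(x)
}

#' Export a diff report as a long CSV
#'
#' One row per peak, with a \code{category} column (\code{new},
#' \code{missing}, \code{shared}).
#'
#' @param x A \code{diff_report}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_diff_report <- function(x, path) {
  stopifnot(inherits(x, "diff_report"))
  rows <- rbind(
    if (nrow(x$new_peaks)) data.frame(category = "new", mz = x$new_peaks$mz,
                                      intensity = x$new_peaks$intensity,
                                      frequency = x$new_peaks$frequency,
                                      matched_mz = NA_real_, delta = NA_real_),
    if (nrow(x$missing_peaks)) data.frame(category = "missing",
                                          mz = x$missing_peaks$mz,
                                          intensity = x$missing_peaks$intensity,
                                          frequency = x$missing_peaks$frequency,
                                          matched_mz = NA_real_, delta = NA_real_),
    if (nrow(x$shared)) data.frame(category = "shared", mz = x$shared$sample_mz,
                                   intensity = NA_real_, frequency = NA_real_,
                                   matched_mz = x$shared$control_mz,
                                   delta = x$shared$delta)
  )
  if (is.null(rows)) rows <- data.frame(category = character(0), mz = numeric(0),
                                        intensity = numeric(0), frequency = numeric(0),
                                        matched_mz = numeric(0), delta = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Tabulate diff reports into a treatment-by-condition count matrix
#'
#' Aggregates per-condition diff reports into the matrix behind the usual
#' summary heat maps: rows are treatments, columns are (dose, time)
#' conditions, each cell carries the number of newly appeared and of missing
#' peaks.
#'
#' @param reports List of \code{diff_report}s.
#' @param conditions data.frame with one row per report and columns
#'   \code{treatment}, \code{dose_uM}, \code{time_days}. Condition keys must
#'   be unique.
#' @return An object of class \code{"diff_matrix"}: list with the long-format
#'   \code{counts} data.frame and matrices \code{n_new} and \code{n_missing}
#'   (rows treatments, columns dose x time).
#' @export
diff_matrix <- function(reports, conditions) {
  if (length(reports) == 0L) stop("'reports' must be non-empty")
  if (!is.data.frame(conditions) || nrow(conditions) != length(reports) ||
      !all(c("treatment", "dose_uM", "time_days") %in% names(conditions))) {
    stop("'conditions' must have one row per report with treatment, dose_uM, time_days")
  }
  key <- paste(conditions$treatment, conditions$dose_uM, conditions$time_days)
  if (anyDuplicated(key)) stop("duplicate condition keys in 'conditions'")

  counts <- data.frame(
    treatment = conditions$treatment,
    dose_uM = conditions$dose_uM,
    time_days = conditions$time_days,
    n_new = vapply(reports, function(r) nrow(r$new_peaks), 0L),
    n_missing = vapply(reports, function(r) nrow(r$missing_peaks), 0L)
  )
  treatments <- unique(counts$treatment)
  cond <- unique(counts[order(counts$dose_uM, counts$time_days),
                        c("dose_uM", "time_days")])
  col_lab <- sprintf("%guM_%gd", cond$dose_uM, cond$time_days)
  mk <- function(field) {
    m <- matrix(NA_real_, nrow = length(treatments), ncol = nrow(cond),
                dimnames = list(treatments, col_lab))
    for (r in seq_len(nrow(counts))) {
      i <- match(counts$treatment[r], treatments)
      j <- which(cond$dose_uM == counts$dose_uM[r] &
                   cond$time_days == counts$time_days[r])
      m[i, j] <- counts[[field]][r]
    }
    m
  }
  structure(
    list(counts = counts, n_new = mk("n_new"), n_missing = mk("n_missing")),
    class = "diff_matrix"
  )
}

#' @export
print.diff_matrix <- function(x, ...) {
  cat(sprintf("diff matrix: %d treatments x %d conditions\n",
              nrow(x$n_new), ncol(x$n_new)))
  cat("newly appeared peaks:\n"); print(x$n_new)
  cat("missing peaks:\n"); print(x$n_missing)
  invisible(x)
}

#' Heat map of differential peak counts
#'
#' Renders the newly-appeared or missing count matrix as a heat map (rows:
#' treatments, columns: dose x time conditions), in the style of the summary
#' figures used for treatment screens.
#'
#' @param x A \code{diff_matrix}.
#' @param which \code{"new"}, \code{"missing"} or \code{"both"} (default,
#'   drawn side by side).
#' @param filename Optional file to write the figure to (extension decides
#'   the device, as in \code{pheatmap}).
#' @param ... Further arguments to \code{pheatmap::pheatmap}.
#' @return The pheatmap object(s), invisibly.
#' @method plot diff_matrix
#' @export
plot.diff_matrix <- function(x, which = c("both", "new", "missing"),
                             filename = NA, ...) {
  which <- match.arg(which)
  draw <- function(m, title, fn) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = title, display_numbers = TRUE,
                       number_format = "%.0f", filename = fn, ...)
  }
  out <- list()
  if (which %in% c("both", "new")) {
    out$new <- draw(x$n_new, "newly appeared peaks", filename)
  }
  if (which %in% c("both", "missing")) {
    fn2 <- if (which == "both" && !is.na(filename)) {
      sub("(\\.[^.]+)$", "_missing\\1", filename)
    } else filename
    out$missing <- draw(x$n_missing, "missing peaks", fn2)
  }
  invisible(out)
}

#' Export a diff matrix as CSV (long format)
#'
#' @param x A \code{diff_matrix}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_diff_matrix <- function(x, path) {
  stopifnot(inherits(x, "diff_matrix"))
  utils::write.csv(x$counts, path, row.names = FALSE)
  invisible(path)
}
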