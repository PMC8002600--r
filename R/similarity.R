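# Spectral similarity, correlation distance, UPGMA trees and library
# identification.

#' Align two profiles into paired intensity vectors
#'
#' Base-peak normalizes both profiles, matches their peaks one-to-one as in
#' \code{\link{diff_profiles}}, and returns the union of peaks as two paired
#' intensity vectors with 0 standing for absence. This is the common carrier
#' for correlation distance and identification scoring.
#'
#' @param a,b \code{consensus_profile} (or \code{peaklist}) objects,
#'   non-empty.
#' @param tol Matching tolerance in Da (> 0); default 2 Da.
#' @return A data.frame with columns \code{mz} (representative m/z),
#'   \code{intensity_a}, \code{intensity_b} and \code{shared} (logical).
#' @export
align_profiles <- function(a, b, tol = 2) {
  a <- normalize_intensities(a, "base-peak")
  b <- normalize_intensities(b, "base-peak")
  d <- diff_profiles(a, b, tol = tol)
  ta <- .peak_table(a); tb <- .peak_table(b)
  ia <- ta$intensity[match(d$shared$sample_mz, ta$mz)]
  ib <- tb$intensity[match(d$shared$control_mz, tb$mz)]
  out <- rbind(
    if (nrow(d$shared)) data.frame(mz = d$shared$sample_mz, intensity_a = ia,
                                   intensity_b = ib, shared = TRUE),
    if (nrow(d$new_peaks)) data.frame(mz = d$new_peaks$mz,
                                      intensity_a = d$new_peaks$intensity,
                                      intensity_b = 0, shared = FALSE),
    if (nrow(d$missing_peaks)) data.frame(mz = d$missing_peaks$mz,
                                          intensity_a = 0,
                                          intensity_b = d$missing_peaks$intensity,
                                          shared = FALSE)
  )
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation distance between two profiles
#'
#' One minus the correlation of the aligned, base-peak-normalized and
#' square-root-transformed intensity vectors (square root as variance
#' stabilization for peak intensities). Ranges over [0, 2]: identical
#' profiles give 0, anti-correlated ones approach 2.
#'
#' @param a,b Profiles as in \code{\link{align_profiles}}.
#' @param tol Matching tolerance in Da; default 2.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Distance in [0, 2].
#' @export
correlation_distance <- function(a, b, tol = 2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- align_profiles(a, b, tol = tol)
  if (nrow(al) < 3L) stop("aligned vectors need at least 3 positions")
  va <- sqrt(al$intensity_a); vb <- sqrt(al$intensity_b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("degenerate profile: zero intensity variance after alignment")
  }
  1 - stats::cor(va, vb, method = method)
}

#' Pairwise correlation-distance matrix
#'
#' @param profiles Named (or id-labelled) list of profiles, n >= 2.
#' @param tol Matching tolerance in Da; default 2.
#' @param method Correlation type, as in \code{\link{correlation_distance}}.
#' @return A symmetric numeric matrix with zero diagonal and profile ids as
#'   dimnames.
#' @export
distance_matrix <- function(profiles, tol = 2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  labels <- names(profiles)
  if (is.null(labels)) labels <- vapply(profiles, .profile_label, "")
  if (anyDuplicated(labels)) stop("profile labels must be unique")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- correlation_distance(profiles[[i]], profiles[[j]],
                                                 tol = tol, method = method)
    }
  }
  d
}

#' UPGMA (average-linkage) dendrogram from a distance matrix
#'
#' Standard unweighted pair-group agglomeration: the distance between two
#' clusters is the mean over all cross pairs; each merge creates a node at
#' half the merge distance, so root-to-leaf path lengths are equal
#' (ultrametric). Ties are broken by lexicographic order of the smallest leaf
#' label in each cluster, which makes the tree reproducible even on
#' all-equal distance matrices.
#'
#' @param d Symmetric distance matrix with labelled rows/columns, zero
#'   diagonal, finite entries, n >= 2.
#' @return An ultrametric \code{ape::phylo} tree with branch lengths.
#' @export
upgma <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L) {
    stop("'d' must be a square matrix with n >= 2")
  }
  if (any(!is.finite(d))) stop("'d' contains non-finite entries")
  if (max(abs(d - t(d))) > 1e-12) stop("'d' must be symmetric")
  if (any(diag(d) != 0)) stop("'d' must have a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(d)))
  n <- nrow(d)

  # active clusters: newick fragment, height, size, lexicographically
  # smallest member label (the tie-break key)
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  key <- labels
  dd <- d
  active <- rep(TRUE, n)

  for (step in seq_len(n - 1L)) {
    ia <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (p in seq_along(ia)) {
      for (q in seq_len(p - 1L)) {
        i <- ia[q]; j <- ia[p]  # ensure i before j in active order
        dij <- dd[i, j]
        k1 <- sort(c(key[i], key[j]))
        better <- dij < best_d - 1e-15 ||
          (abs(dij - best_d) <= 1e-15 &&
             (is.null(best_key) || k1[1L] < best_key[1L] ||
                (k1[1L] == best_key[1L] && k1[2L] < best_key[2L])))
        if (better) {
          best <- c(i, j); best_d <- dij; best_key <- k1
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    h <- best_d / 2
    bl_i <- h - height[i]; bl_j <- h - height[j]
    # order children lexicographically by key for byte-stable newick
    if (key[i] <= key[j]) {
      frag <- sprintf("(%s:%.12g,%s:%.12g)", newick[i], bl_i, newick[j], bl_j)
    } else {
      frag <- sprintf("(%s:%.12g,%s:%.12g)", newick[j], bl_j, newick[i], bl_i)
    }
    # UPGMA update: size-weighted mean keeps cluster distance = mean over
    # all cross pairs of leaves
    for (k in ia) {
      if (k != i && k != j) {
        dd[i, k] <- dd[k, i] <- (size[i] * dd[i, k] + size[j] * dd[j, k]) /
          (size[i] + size[j])
      }
    }
    newick[i] <- frag
    height[i] <- h
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    active[j] <- FALSE
  }
  tree_str <- paste0(newick[which(active)], ";")
  ape::read.tree(text = tree_str)
}

#' Write a dendrogram as Newick
#'
#' @param tree An \code{ape::phylo} tree.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Cluster profiles into a dendrogram
#'
#' Convenience wrapper: pairwise correlation distances, then UPGMA.
#'
#' @inheritParams distance_matrix
#' @return An \code{ape::phylo} tree.
#' @export
cluster_profiles <- function(profiles, tol = 2, method = c("pearson", "spearman")) {
  upgma(distance_matrix(profiles, tol = tol, method = method))
}

#' Score a query profile against a reference library
#'
#' A transparent composite similarity score on a 0-3 scale: with f_qr the
#' fraction of query peaks matched in the reference, f_rq the reverse
#' fraction, and r the Pearson correlation of matched (base-peak-normalized,
#' square-root-transformed) intensities, the score is
#' \code{(f_qr * f_rq * max(r, 0))^(1/3) * 3}. The 0-3 range imitates the
#' familiar commercial biotyping scale, but the score is NOT numerically
#' comparable to proprietary scores or their >= 2.0 species-level convention.
#'
#' @param query A \code{consensus_profile} (or \code{peaklist}).
#' @param library Non-empty named list of reference profiles.
#' @param tol Matching tolerance in Da; default 2.
#' @return An object of class \code{"identification"}: data.frame with one
#'   row per reference (columns \code{reference}, \code{score}, \code{f_qr},
#'   \code{f_rq}, \code{intensity_cor}), sorted by decreasing score (ties by
#'   label), with the best match first.
#' @export
identify_profile <- function(query, library, tol = 2) {
  if (!is.list(library) || length(library) == 0L) stop("'library' must be non-empty")
  labels <- names(library)
  if (is.null(labels)) labels <- vapply(library, .profile_label, "")
  rows <- lapply(seq_along(library), function(k) {
    ref <- library[[k]]
    al <- align_profiles(query, ref, tol = tol)
    nq <- sum(al$intensity_a > 0)
    nr <- sum(al$intensity_b > 0)
    nsh <- sum(al$shared)
    f_qr <- if (nq > 0) nsh / nq else 0
    f_rq <- if (nr > 0) nsh / nr else 0
    sh <- al[al$shared, , drop = FALSE]
    r <- if (nrow(sh) >= 2L) {
      va <- sqrt(sh$intensity_a); vb <- sqrt(sh$intensity_b)
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        # flat matched intensities: perfect agreement if identical, else no signal
        if (isTRUE(all.equal(va, vb))) 1 else 0
      } else {
        stats::cor(va, vb)
      }
    } else 0
    data.frame(reference = labels[k], score = (f_qr * f_rq * max(r, 0))^(1 / 3) * 3,
               f_qr = f_qr, f_rq = f_rq, intensity_cor = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$reference), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("identification", "data.frame")
  out
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("best match: '%s' (score %.2f of 3)\n",
              x$reference[1L], x$score[1L]))
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}
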