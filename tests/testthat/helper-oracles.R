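# Independent oracles used across the suite. These deliberately re-derive
# quantities through a different route than the package (molecular formula
# first, exhaustive search, ...) so agreement is evidence, not tautology.

# --- formula-based mass oracle ---------------------------------------------
# Counts atoms of the whole molecule first (residue formulas + one water),
# then takes a single dot product with atomic masses.

.oracle_atoms <- list(
  # residue formulas as c(C, H, N, O, S)
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
.oracle_mono <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, S = 31.97207100)
.oracle_avg <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
                 S = 32.065)

oracle_formula <- function(sequence) {
  res <- strsplit(sequence, "")[[1L]]
  atoms <- Reduce(`+`, .oracle_atoms[res])
  atoms <- atoms + c(0, 2, 0, 1, 0)  # one water
  names(atoms) <- c("C", "H", "N", "O", "S")
  atoms
}

oracle_mass <- function(sequence, scale = "average") {
  atoms <- oracle_formula(sequence)
  tab <- if (scale == "average") .oracle_avg else .oracle_mono
  sum(atoms * tab[names(atoms)])
}

random_sequence <- function(len) {
  paste(sample(names(.oracle_atoms), len, replace = TRUE), collapse = "")
}

# --- brute-force diff matching oracle --------------------------------------
# Exhaustively maximises the number of matched sample/control pairs within
# tol and, among maximal matchings, minimises total |delta|. Returns
# c(n_matched, total_delta).

oracle_match <- function(s_mz, c_mz, tol) {
  best <- c(-1, Inf)
  recurse <- function(i, c_free, n_matched, total) {
    if (i > length(s_mz)) {
      if (n_matched > best[1L] ||
          (n_matched == best[1L] && total < best[2L] - 1e-12)) {
        best <<- c(n_matched, total)
      }
      return(invisible())
    }
    # prune: even matching everything remaining cannot beat best
    remaining <- length(s_mz) - i + 1L
    if (n_matched + remaining < best[1L]) return(invisible())
    cand <- which(c_free & abs(c_mz - s_mz[i]) <= tol)
    for (j in cand) {
      c_free[j] <- FALSE
      recurse(i + 1L, c_free, n_matched + 1L, total + abs(s_mz[i] - c_mz[j]))
      c_free[j] <- TRUE
    }
    recurse(i + 1L, c_free, n_matched, total)  # leave peak i unmatched
  }
  recurse(1L, rep(TRUE, length(c_mz)), 0L, 0)
  best
}

# random peak positions where every within-tol candidate pair is unambiguous:
# at most one sample and one control peak per group, groups separated by
# > 2*tol — the regime where greedy matching is provably optimal
random_unambiguous_instance <- function(n_groups, tol) {
  centers <- cumsum(stats::runif(n_groups, 3.1 * tol, 20 * tol)) + 1000
  s_mz <- c(); c_mz <- c()
  for (ct in centers) {
    ns <- sample(0:1, 1L); nc <- sample(0:1, 1L)
    s_mz <- c(s_mz, ct + stats::runif(ns, -tol / 2, tol / 2))
    c_mz <- c(c_mz, ct + stats::runif(nc, -tol / 2, tol / 2))
  }
  list(s = sort(s_mz), c = sort(c_mz))
}

# ambiguous instances (clusters of up to 2 per side) for invariant checks
# that hold regardless of matching optimality
random_clustered_instance <- function(n_groups, tol) {
  centers <- cumsum(stats::runif(n_groups, 3 * tol, 20 * tol)) + 1000
  s_mz <- c(); c_mz <- c()
  for (ct in centers) {
    ns <- sample(0:2, 1L); nc <- sample(0:2, 1L)
    s_mz <- c(s_mz, ct + stats::runif(ns, -tol / 2, tol / 2))
    c_mz <- c(c_mz, ct + stats::runif(nc, -tol / 2, tol / 2))
  }
  list(s = sort(s_mz), c = sort(c_mz))
}

# --- small object builders --------------------------------------------------

make_profile <- function(mz, intensity = NULL, id = "p") {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  icmaldi:::.profile_from_peaks(mz, intensity, profile_id = id)
}

make_peaklist <- function(mz, intensity = NULL, id = "s") {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  peaklist(mz, intensity, spectrum_id = id)
}
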