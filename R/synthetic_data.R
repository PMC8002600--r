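# Synthetic proteomes, control profiles, replicate spectra and dose/time
# treatment effects, with ground truth for parameter-recovery tests.
#
# The generator emulates the statistical structure the analysis assumes:
# ~100-peak control profiles in m/z 1000-25000, replicate-to-replicate peak
# dropout, and treatments that delete template peaks and induce novel
# ("stress") peaks as functions of concentration and incubation time.

#' Treatment-effect configuration
#'
#' Generative parameters of the dose/time treatment model. Each template peak
#' is deleted independently with probability
#' \code{p_loss = plogis(loss_steepness * (log(dose / loss_midpoint_dose) +
#' time / time_scale))}, so loss escalates both with concentration and with
#' incubation time; an untreated culture (dose 0) is never perturbed. Novel
#' stress peaks appear with Poisson rate \code{gain_rate * p_loss}, drawn
#' from proteome members absent from the control template so annotation of
#' new peaks remains meaningful.
#'
#' @param loss_midpoint_dose Dose (micromolar) at which, at time 0, a peak is
#'   lost with probability 1/2; default 20. Together with the defaults below
#'   this grades the 1-10 micromolar, 1-3 week screening window from ~1% peak
#'   loss at the mildest condition to ~93% at the harshest.
#' @param loss_steepness Dimensionless logistic steepness; default 2.
#' @param time_scale Days per unit logit increase; default 10.5 (1.5 weeks).
#' @param gain_rate Expected number of novel peaks at maximal severity;
#'   default 35, matching the largest newly-appeared counts seen after harsh
#'   3-week treatments.
#' @param mz_jitter_sd Replicate-to-replicate m/z jitter SD in Da; default
#'   0.5 (well inside the 2 Da grouping tolerance).
#' @param replicate_dropout Per-peak, per-replicate dropout probability;
#'   default 0.2.
#' @param intensity_cv Log-normal intensity coefficient of variation across
#'   replicates; default 0.3.
#' @return A list of class \code{"treatment_config"}.
#' @export
treatment_config <- function(loss_midpoint_dose = 20, loss_steepness = 2,
                             time_scale = 10.5, gain_rate = 35,
                             mz_jitter_sd = 0.5, replicate_dropout = 0.2,
                             intensity_cv = 0.3) {
  stopifnot(loss_midpoint_dose > 0, loss_steepness > 0, time_scale > 0,
            gain_rate >= 0, mz_jitter_sd >= 0,
            replicate_dropout >= 0, replicate_dropout <= 1, intensity_cv >= 0)
  structure(
    list(loss_midpoint_dose = loss_midpoint_dose,
         loss_steepness = loss_steepness, time_scale = time_scale,
         gain_rate = gain_rate, mz_jitter_sd = mz_jitter_sd,
         replicate_dropout = replicate_dropout, intensity_cv = intensity_cv),
    class = "treatment_config"
  )
}

#' Expected per-peak loss probability of the treatment model
#'
#' @param dose Concentration in micromolar (>= 0).
#' @param time_days Incubation time in days (>= 0).
#' @param cfg A \code{\link{treatment_config}}.
#' @return Probability in [0, 1]; 0 whenever \code{dose} is 0.
#' @export
loss_probability <- function(dose, time_days, cfg = treatment_config()) {
  if (any(dose < 0) || any(time_days < 0)) stop("dose and time must be >= 0")
  logit <- cfg$loss_steepness *
    (log(dose / cfg$loss_midpoint_dose) + time_days / cfg$time_scale)
  p <- stats::plogis(logit)
  p[dose == 0] <- 0
  p
}

#' Generate a random synthetic proteome
#'
#' Random sequences over the 20 standard amino acids with accessions
#' \code{SYN0001...}. Lengths are drawn uniformly from \code{length_range};
#' at the default range the average protein mass spans roughly the m/z
#' 1000-25000 examination window of intact-cell spectra.
#'
#' @param n_proteins Number of records (>= 1).
#' @param length_range Integer range of sequence lengths; default
#'   \code{c(9, 230)} (~1-25 kDa at ~108 Da mean residue mass).
#' @param seed Integer seed; fixed seed gives identical records (and
#'   identical FASTA bytes via \code{\link{write_proteome}}).
#' @param path Optional FASTA path to write the proteome to.
#' @return A \code{proteome} data.frame as from \code{\link{read_proteome}}.
#' @export
generate_proteome <- function(n_proteins, length_range = c(9, 230),
                              seed = 1L, path = NULL) {
  if (!is.numeric(n_proteins) || n_proteins < 1) stop("'n_proteins' must be >= 1")
  if (length(length_range) != 2L || length_range[1L] < 1 ||
      length_range[2L] < length_range[1L]) {
    stop("'length_range' must be an increasing pair of lengths >= 1")
  }
  set.seed(seed)
  lens <- sample(length_range[1L]:length_range[2L], n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(.standard_aa, L, replace = TRUE), collapse = "")
  }, "")
  out <- data.frame(
    accession = sprintf("SYN%04d", seq_len(n_proteins)),
    description = sprintf("synthetic protein %d (length %d)",
                          seq_len(n_proteins), lens),
    sequence = seqs,
    computable = TRUE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("proteome", "data.frame")
  if (!is.null(path)) write_proteome(out, path)
  out
}

#' Generate a control template profile from a proteome
#'
#' Selects \code{n_peaks} proteins whose average [M+H]+ masses fall in
#' \code{mz_window} and are mutually separated by at least \code{min_gap} Da
#' (so every template peak annotates back to its source protein at rank 1),
#' and assigns log-normal intensities. The template is the noise-free ground
#' truth a control culture's replicates are emitted from.
#'
#' @param proteome A \code{proteome} data.frame.
#' @param n_peaks Number of template peaks; default 100, a typical count of
#'   species-characteristic peaks in an intact-cell profile.
#' @param mz_window Examination window in Da; default \code{c(1000, 25000)}.
#' @param min_gap Minimum m/z separation between selected proteins; default 5.
#' @param seed Integer seed.
#' @return A list of class \code{"template_profile"}: \code{profile}
#'   (a \code{consensus_profile}), and \code{truth} (data.frame
#'   \code{accession}, \code{mz}, \code{intensity} for every template peak).
#' @export
generate_control_template <- function(proteome, n_peaks = 100,
                                      mz_window = c(1000, 25000),
                                      min_gap = 5, seed = 1L) {
  stopifnot(is.data.frame(proteome), n_peaks >= 1)
  idx <- build_mass_index(proteome, scale = "average", adduct = "MH")
  ent <- idx$entries
  ent <- ent[ent$mass >= mz_window[1L] & ent$mass <= mz_window[2L], , drop = FALSE]
  # greedy left-to-right thinning to enforce the min_gap spacing
  keep <- logical(nrow(ent))
  last <- -Inf
  for (i in seq_len(nrow(ent))) {
    if (ent$mass[i] - last >= min_gap) { keep[i] <- TRUE; last <- ent$mass[i] }
  }
  ent <- ent[keep, , drop = FALSE]
  if (nrow(ent) < n_peaks) {
    stop(sprintf(
      "window too narrow: only %d proteins with mass in [%g, %g] at >= %g Da spacing (need %d)",
      nrow(ent), mz_window[1L], mz_window[2L], min_gap, n_peaks))
  }
  set.seed(seed)
  pick <- sort(sample(nrow(ent), n_peaks))
  sel <- ent[pick, , drop = FALSE]
  intensity <- stats::rlnorm(n_peaks, meanlog = log(1000), sdlog = 1)
  truth <- data.frame(accession = sel$accession, mz = sel$mass,
                      intensity = intensity, stringsAsFactors = FALSE)
  truth <- truth[order(truth$mz), , drop = FALSE]
  rownames(truth) <- NULL
  profile <- .profile_from_peaks(truth$mz, truth$intensity,
                                 profile_id = "control_template",
                                 meta = list(treatment = "control", dose_uM = 0,
                                             time_days = 0, is_control = TRUE))
  structure(list(profile = profile, truth = truth), class = "template_profile")
}

#' Apply a dose/time treatment to a template profile
#'
#' Deletes each template peak independently with the model's
#' \code{\link{loss_probability}} and adds \code{rpois(1, gain_rate * p_loss)}
#' novel "stress" peaks at the [M+H]+ masses of proteome members not
#' expressed in the control template (at least 5 Da away from every template
#' peak and from each other, so new peaks annotate unambiguously). Novel
#' peaks are taken from the front of a treatment-specific priority order over
#' the candidate stress proteins: the same compound induces the same proteins
#' across its dose/time grid, only more of them as severity grows — so
#' profiles of harsh conditions of one treatment resemble each other, as
#' compound-specific stress responses do. Returns the perturbed template and
#' the exact ground truth of deletions and additions.
#'
#' @param template A \code{\link{generate_control_template}} object.
#' @param proteome The proteome the template was generated from.
#' @param dose Concentration in micromolar (>= 0).
#' @param time_days Incubation time in days (>= 0).
#' @param cfg A \code{\link{treatment_config}}.
#' @param treatment Treatment name recorded in the metadata.
#' @param seed Integer seed.
#' @param stress_rank Optional character vector of candidate accessions in
#'   induction priority order (the treatment's stress signature); by default
#'   a permutation drawn deterministically from \code{seed} and
#'   \code{treatment}, so one treatment shares its signature across
#'   conditions when the same seed is used.
#' @param loss_u Optional numeric vector of per-template-peak uniform
#'   variates coupling deletions across the treatment's grid: peak i is
#'   deleted when \code{loss_u[i] < p_loss}, so a harsher condition destroys
#'   a superset of what a milder one destroys, while each condition's
#'   deletion count stays Binomial(n_peaks, p_loss). Drawn from the same
#'   (seed, treatment)-derived stream by default.
#' @return A list of class \code{"treated_profile"}: \code{profile} (the
#'   perturbed \code{consensus_profile}), \code{truth} (list with
#'   \code{deleted} and \code{added} data.frames and \code{p_loss}).
#' @export
apply_treatment <- function(template, proteome, dose, time_days,
                            cfg = treatment_config(), treatment = "treatment",
                            seed = 1L, stress_rank = NULL, loss_u = NULL) {
  stopifnot(inherits(template, "template_profile"))
  if (dose < 0 || time_days < 0) stop("dose and time must be >= 0")
  p_loss <- loss_probability(dose, time_days, cfg)
  tr <- template$truth
  cand <- .stress_candidates(template, proteome)
  if (is.null(stress_rank) || is.null(loss_u)) {
    # treatment-level draws: deterministic in (seed, treatment) only
    tseed <- (as.integer(seed) + sum(utf8ToInt(treatment))) %% .Machine$integer.max
    set.seed(tseed)
    if (is.null(stress_rank)) stress_rank <- sample(cand$accession)
    if (is.null(loss_u)) loss_u <- stats::runif(nrow(tr))
  }
  if (length(loss_u) != nrow(tr)) stop("'loss_u' must have one variate per template peak")
  set.seed(seed)
  del <- loss_u < p_loss
  kept <- tr[!del, , drop = FALSE]

  n_new <- stats::rpois(1L, cfg$gain_rate * p_loss)
  added <- tr[0, , drop = FALSE]
  if (n_new > 0) {
    picks <- stress_rank[stress_rank %in% cand$accession]
    picks <- picks[seq_len(min(n_new, length(picks)))]
    n_new <- length(picks)
    if (n_new > 0) {
      sel <- cand[match(picks, cand$accession), , drop = FALSE]
      added <- data.frame(accession = sel$accession,
                          mz = sel$mass,
                          intensity = sel$intensity,
                          stringsAsFactors = FALSE)
      added <- added[order(added$mz), , drop = FALSE]
    }
  }
  all_peaks <- rbind(kept, added)
  all_peaks <- all_peaks[order(all_peaks$mz), , drop = FALSE]
  if (nrow(all_peaks) == 0L) {
    # a floor of one residual peak keeps downstream profiles non-degenerate
    all_peaks <- tr[which.max(tr$intensity), , drop = FALSE]
    kept <- all_peaks
  }
  profile <- .profile_from_peaks(
    all_peaks$mz, all_peaks$intensity,
    profile_id = sprintf("%s_%guM_%gd", treatment, dose, time_days),
    meta = list(treatment = treatment, dose_uM = dose, time_days = time_days,
                is_control = dose == 0)
  )
  structure(
    list(profile = profile,
         truth = list(deleted = tr[del, , drop = FALSE], added = added,
                      p_loss = p_loss)),
    class = "treated_profile"
  )
}

# Stress-peak candidate pool: unexpressed proteome members inside the
# template's m/z span, >= 5 Da from every template peak and from each other.
# Deterministic in (template, proteome).
.stress_candidates <- function(template, proteome) {
  tr <- template$truth
  idx <- build_mass_index(proteome, scale = "average", adduct = "MH")
  ent <- idx$entries
  cand <- ent[!(ent$accession %in% tr$accession), , drop = FALSE]
  ok <- vapply(cand$mass, function(m) all(abs(m - tr$mz) >= 5), TRUE)
  cand <- cand[ok, , drop = FALSE]
  cand <- cand[cand$mass >= min(tr$mz) & cand$mass <= max(tr$mz), , drop = FALSE]
  thinned <- logical(nrow(cand)); last <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$mass[i] - last >= 5) { thinned[i] <- TRUE; last <- cand$mass[i] }
  }
  cand <- cand[thinned, , drop = FALSE]
  # expression level is a property of the protein, not of the condition:
  # draw it once, deterministically per accession, so conditions sharing a
  # stress protein show it at a correlated intensity
  cand$intensity <- vapply(cand$accession, function(a) {
    codes <- utf8ToInt(a)
    h <- sum(codes * 131^(seq_along(codes) %% 5)) %% .Machine$integer.max
    set.seed(h)
    stats::rlnorm(1L, meanlog = log(1000), sdlog = 1)
  }, 0, USE.NAMES = FALSE)
  cand
}

#' Emit noisy replicate peak lists from a profile
#'
#' Each replicate drops every peak independently with probability
#' \code{replicate_dropout}, jitters m/z by \code{Normal(0, mz_jitter_sd)}
#' and multiplies intensities by log-normal noise with the configured CV.
#'
#' @param profile A \code{consensus_profile} (template or perturbed).
#' @param n_replicates Number of replicate spectra (>= 1); 20 is the usual
#'   count an MSP is built from.
#' @param cfg A \code{\link{treatment_config}}.
#' @param seed Integer seed.
#' @param dir Optional directory: replicates are additionally written as
#'   two-column text files \code{rep<k>.txt}.
#' @return List of \code{\link{peaklist}} objects.
#' @export
emit_replicates <- function(profile, n_replicates = 20,
                            cfg = treatment_config(), seed = 1L, dir = NULL) {
  stopifnot(inherits(profile, "consensus_profile"), n_replicates >= 1)
  sdlog <- sqrt(log(1 + cfg$intensity_cv^2))
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(k) {
    p <- profile$peaks
    keep <- stats::runif(nrow(p)) >= cfg$replicate_dropout
    # never emit an empty spectrum: keep the base peak
    if (!any(keep)) keep[which.max(p$mean_intensity)] <- TRUE
    p <- p[keep, , drop = FALSE]
    mz <- p$mz + stats::rnorm(nrow(p), 0, cfg$mz_jitter_sd)
    mz <- pmax(mz, 1e-6)
    ints <- p$mean_intensity *
      stats::rlnorm(nrow(p), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    peaklist(mz, ints, spectrum_id = sprintf("%s_rep%02d", profile$profile_id, k),
             meta = c(profile$meta, list(replicate = k)))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(reps)) {
      write_peaklist(reps[[k]], file.path(dir, sprintf("rep%02d.txt", k)))
    }
  }
  reps
}

#' Simulate a full treatment experiment
#'
#' Generates a proteome, a control template, and for every treatment x dose x
#' time condition a perturbed profile with replicate spectra, under a single
#' seed hierarchy (seed -> per-condition -> per-replicate) for exact
#' reproducibility.
#'
#' @param treatments Character vector of treatment names.
#' @param doses Concentrations in micromolar; default \code{c(1, 2, 5, 10)}.
#' @param times_days Incubation times; default \code{c(7, 14, 21)} (1-3
#'   weeks).
#' @param n_replicates Replicates per condition; default 8.
#' @param n_proteins Proteome size; default 400.
#' @param n_peaks Template peaks; default 100.
#' @param cfg A \code{\link{treatment_config}}.
#' @param seed Master integer seed.
#' @param dir Optional output directory; when given, writes
#'   \code{proteome.fasta}, \code{conditions/<treatment>_<dose>_<time>/rep<k>.txt}
#'   and \code{config.yaml}.
#' @return A list of class \code{"synthetic_experiment"} with
#'   \code{proteome}, \code{template}, \code{control_replicates},
#'   \code{conditions} (list with \code{profile}, \code{truth},
#'   \code{replicates}, and the condition descriptors) and \code{cfg}.
#' @export
simulate_experiment <- function(treatments = "treatment",
                                doses = c(1, 2, 5, 10),
                                times_days = c(7, 14, 21),
                                n_replicates = 8, n_proteins = 400,
                                n_peaks = 100, cfg = treatment_config(),
                                seed = 1L, dir = NULL) {
  seed <- as.integer(seed)
  proteome <- generate_proteome(n_proteins, seed = seed)
  template <- generate_control_template(proteome, n_peaks = n_peaks,
                                        seed = seed + 1L)
  control_reps <- emit_replicates(template$profile, n_replicates, cfg,
                                  seed = seed + 2L)
  grid <- expand.grid(treatment = treatments, dose = doses, time = times_days,
                      stringsAsFactors = FALSE)
  # one stress signature per treatment, shared across its dose/time grid
  cand <- .stress_candidates(template, proteome)
  signatures <- lapply(treatments, function(tn) {
    set.seed((seed + sum(utf8ToInt(tn))) %% .Machine$integer.max)
    list(stress_rank = sample(cand$accession),
         loss_u = stats::runif(nrow(template$truth)))
  })
  names(signatures) <- treatments
  conditions <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cseed <- (seed + 1000L * g) %% .Machine$integer.max
    treated <- apply_treatment(template, proteome, grid$dose[g], grid$time[g],
                               cfg, treatment = grid$treatment[g],
                               seed = cseed,
                               stress_rank = signatures[[grid$treatment[g]]]$stress_rank,
                               loss_u = signatures[[grid$treatment[g]]]$loss_u)
    reps <- emit_replicates(treated$profile, n_replicates, cfg,
                            seed = (cseed + 1L) %% .Machine$integer.max)
    conditions[[g]] <- list(treatment = grid$treatment[g], dose = grid$dose[g],
                            time_days = grid$time[g], profile = treated$profile,
                            truth = treated$truth, replicates = reps)
  }
  out <- structure(
    list(proteome = proteome, template = template,
         control_replicates = control_reps, conditions = conditions,
         cfg = cfg, seed = seed),
    class = "synthetic_experiment"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_proteome(proteome, file.path(dir, "proteome.fasta"))
    cdir <- file.path(dir, "conditions")
    for (cond in conditions) {
      sub <- file.path(cdir, sprintf("%s_%g_%g", cond$treatment, cond$dose,
                                     cond$time_days))
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_along(cond$replicates)) {
        write_peaklist(cond$replicates[[k]],
                       file.path(sub, sprintf("rep%02d.txt", k)))
      }
    }
    ctl <- file.path(cdir, "control_0_0")
    dir.create(ctl, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(control_reps)) {
      write_peaklist(control_reps[[k]], file.path(ctl, sprintf("rep%02d.txt", k)))
    }
    yaml::write_yaml(c(list(treatments = treatments, doses = doses,
                            times_days = times_days,
                            n_replicates = n_replicates,
                            n_proteins = n_proteins, n_peaks = n_peaks,
                            seed = seed), unclass(cfg)),
                     file.path(dir, "config.yaml"))
  }
  out
}
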