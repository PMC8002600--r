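# End-to-end pipeline: simulate (or read) -> MSPs -> diff -> annotate ->
# heat map -> cluster, driven by a single config.

#' Default pipeline configuration
#'
#' A run configuration is a plain named list, serializable to YAML. With
#' \code{input_dir = NULL} the pipeline generates its own synthetic
#' experiment; otherwise it expects the directory layout written by
#' \code{\link{simulate_experiment}} (\code{proteome.fasta},
#' \code{conditions/<treatment>_<dose>_<time>/rep<k>.txt}, the control under
#' \code{conditions/control_0_0}).
#'
#' @param input_dir Optional input directory; \code{NULL} to simulate.
#' @param output_dir Run output directory.
#' @param seed Integer seed used for every source of randomness.
#' @param tol Matching/grouping tolerance in Da.
#' @param min_frequency,max_peaks Consensus-profile build parameters.
#' @param treatments,doses,times_days,n_replicates,n_proteins,n_peaks
#'   Synthetic experiment layout (ignored when \code{input_dir} is given).
#' @return A named list of class \code{"run_config"}.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "icmaldi_run",
                            seed = 1L, tol = 2, min_frequency = 0.25,
                            max_peaks = 100, treatments = "treatment",
                            doses = c(1, 2, 5, 10), times_days = c(7, 14, 21),
                            n_replicates = 8, n_proteins = 400, n_peaks = 100) {
  if (tol <= 0) stop("'tol' must be > 0")
  if (min_frequency <= 0 || min_frequency > 1) stop("'min_frequency' must be in (0, 1]")
  structure(
    list(input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
         tol = tol, min_frequency = min_frequency, max_peaks = max_peaks,
         treatments = treatments, doses = doses, times_days = times_days,
         n_replicates = n_replicates, n_proteins = n_proteins,
         n_peaks = n_peaks),
    class = "run_config"
  )
}

.read_condition_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(txt|csv)$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no peak-list files in '%s'", dir))
  lapply(files, read_peaklist)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (synthetic generation or reading of
#' peak-list directories), consensus-profile construction per condition,
#' differential peak detection of every treated condition against the
#' control, tabulation and heat-map rendering of the differential counts,
#' mass-based annotation of every differential peak against the proteome,
#' and correlation-distance UPGMA clustering of all consensus profiles. No
#' stage mutates its inputs; all artifacts are written under
#' \code{config$output_dir}, alongside an echoed \code{config.yaml} and a
#' \code{MANIFEST.yaml} carrying the config's MD5 hash. Identical config and
#' seed give byte-identical text outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the consensus profiles, diff reports, diff
#'   matrix, annotations, distance matrix and tree.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  # --- stage 1: inputs ------------------------------------------------------
  if (is.null(config$input_dir)) {
    exp <- simulate_experiment(
      treatments = config$treatments, doses = config$doses,
      times_days = config$times_days, n_replicates = config$n_replicates,
      n_proteins = config$n_proteins, n_peaks = config$n_peaks,
      seed = config$seed
    )
    proteome <- exp$proteome
    cond_spectra <- lapply(exp$conditions, function(cond) {
      list(treatment = cond$treatment, dose = cond$dose,
           time_days = cond$time_days, spectra = cond$replicates)
    })
    control_spectra <- exp$control_replicates
  } else {
    fasta <- file.path(config$input_dir, "proteome.fasta")
    if (!file.exists(fasta)) stop(sprintf("missing proteome FASTA: '%s'", fasta))
    proteome <- read_proteome(fasta)
    cdirs <- list.dirs(file.path(config$input_dir, "conditions"),
                       recursive = FALSE)
    if (length(cdirs) == 0L) stop("no condition directories found")
    is_ctl <- grepl("^control_", basename(cdirs))
    if (!any(is_ctl)) stop("no control_* condition directory found")
    control_spectra <- .read_condition_dir(cdirs[is_ctl][1L])
    cond_spectra <- lapply(cdirs[!is_ctl], function(d) {
      parts <- strsplit(basename(d), "_", fixed = TRUE)[[1L]]
      if (length(parts) < 3L) stop(sprintf("cannot parse condition dir '%s'", d))
      list(treatment = paste(parts[seq_len(length(parts) - 2L)], collapse = "_"),
           dose = as.numeric(parts[length(parts) - 1L]),
           time_days = as.numeric(parts[length(parts)]),
           spectra = .read_condition_dir(d))
    })
  }

  # --- stage 2: consensus profiles -----------------------------------------
  msp_dir <- file.path(out_dir, "msp")
  dir.create(msp_dir, showWarnings = FALSE)
  control_msp <- build_msp(control_spectra, tol = config$tol,
                           min_frequency = config$min_frequency,
                           max_peaks = config$max_peaks,
                           profile_id = "control")
  write_msp(control_msp, file.path(msp_dir, "control.csv"))
  msps <- list()
  for (cond in cond_spectra) {
    id <- sprintf("%s_%guM_%gd", cond$treatment, cond$dose, cond$time_days)
    m <- build_msp(cond$spectra, tol = config$tol,
                   min_frequency = config$min_frequency,
                   max_peaks = config$max_peaks, profile_id = id)
    m$meta <- list(treatment = cond$treatment, dose_uM = cond$dose,
                   time_days = cond$time_days, is_control = FALSE)
    write_msp(m, file.path(msp_dir, paste0(id, ".csv")))
    msps[[id]] <- m
  }

  # --- stage 3: differential peaks -----------------------------------------
  diff_dir <- file.path(out_dir, "diff")
  dir.create(diff_dir, showWarnings = FALSE)
  reports <- lapply(msps, diff_profiles, control = control_msp,
                    tol = config$tol)
  for (id in names(reports)) {
    write_diff_report(reports[[id]], file.path(diff_dir, paste0(id, ".csv")))
  }
  conditions_df <- do.call(rbind, lapply(cond_spectra, function(cond) {
    data.frame(treatment = cond$treatment, dose_uM = cond$dose,
               time_days = cond$time_days)
  }))
  dm <- diff_matrix(unname(reports), conditions_df)
  write_diff_matrix(dm, file.path(out_dir, "diff_matrix.csv"))
  grDevices::pdf(NULL)  # pheatmap must not leave a device open on screen
  try(plot(dm, which = "both",
           filename = file.path(out_dir, "diff_heatmap.pdf")), silent = TRUE)
  grDevices::dev.off()

  # --- stage 4: annotation --------------------------------------------------
  index <- build_mass_index(proteome, scale = "average", adduct = "MH")
  ann_dir <- file.path(out_dir, "annotation")
  dir.create(ann_dir, showWarnings = FALSE)
  annotations <- list()
  for (id in names(msps)) {
    ann <- annotate_peaks(msps[[id]], index, tol = config$tol)
    write_annotation(ann, file.path(ann_dir, paste0(id, ".csv")))
    annotations[[id]] <- ann
  }

  # --- stage 5: clustering --------------------------------------------------
  all_profiles <- c(list(control = control_msp), msps)
  dmat <- distance_matrix(all_profiles, tol = config$tol)
  utils::write.csv(round(dmat, 10), file.path(out_dir, "distance_matrix.csv"))
  tree <- upgma(dmat)
  write_dendrogram(tree, file.path(out_dir, "dendrogram.nwk"))

  manifest <- list(
    config_md5 = cfg_hash,
    outputs = sort(list.files(out_dir, recursive = TRUE))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "MANIFEST.yaml"))

  invisible(list(control_msp = control_msp, msps = msps, reports = reports,
                 diff_matrix = dm, annotations = annotations,
                 distance_matrix = dmat, tree = tree,
                 config_md5 = cfg_hash))
}
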