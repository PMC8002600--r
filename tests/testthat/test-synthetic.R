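test_that("proteome generation is deterministic and spans the mass window", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  p1 <- generate_proteome(40, seed = 1, path = f1)
  p2 <- generate_proteome(40, seed = 1, path = f2)
  expect_identical(p1, p2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_proteome(0), ">= 1")

  p <- generate_proteome(500, seed = 2)
  masses <- vapply(p$sequence, function(s) protein_mass(s)$average, 0,
                   USE.NAMES = FALSE)
  expect_lt(min(masses), 2500)
  expect_gt(max(masses), 20000)
})

test_that("control templates respect window, spacing and reproducibility", {
  p <- generate_proteome(400, seed = 3)
  tpl <- generate_control_template(p, n_peaks = 100, seed = 4)
  expect_equal(nrow(tpl$profile$peaks), 100L)
  expect_true(all(tpl$profile$peaks$mz >= 1000 & tpl$profile$peaks$mz <= 25000))
  expect_true(all(diff(tpl$profile$peaks$mz) >= 5))
  tpl2 <- generate_control_template(p, n_peaks = 100, seed = 4)
  expect_identical(tpl$truth, tpl2$truth)
  # template m/z equal average [M+H]+ of the source proteins
  seqs <- p$sequence[match(tpl$truth$accession, p$accession)]
  expect_equal(tpl$truth$mz,
               protonated_mass(vapply(seqs, function(s) protein_mass(s)$average,
                                      0, USE.NAMES = FALSE), "average"),
               tolerance = 1e-9)
  expect_error(generate_control_template(p, n_peaks = 5000, seed = 1),
               "window too narrow")
})

test_that("null treatment leaves the template unchanged", {
  p <- generate_proteome(300, seed = 5)
  tpl <- generate_control_template(p, n_peaks = 50, seed = 6)
  tr <- apply_treatment(tpl, p, dose = 0, time_days = 0, seed = 7)
  expect_equal(tr$profile$peaks$mz, tpl$profile$peaks$mz)
  expect_equal(nrow(tr$truth$deleted), 0L)
  expect_equal(nrow(tr$truth$added), 0L)
  expect_equal(tr$truth$p_loss, 0)
  tr2 <- apply_treatment(tpl, p, dose = 0, time_days = 21, seed = 7)
  expect_equal(tr2$truth$p_loss, 0)
  expect_error(apply_treatment(tpl, p, dose = -1, time_days = 0), ">= 0")
})

test_that("loss probability is monotone in dose and time", {
  cfg <- treatment_config()
  doses <- c(0, 1, 2, 5, 10, 20)
  times <- c(0, 7, 14, 21)
  for (t in times) {
    expect_true(all(diff(loss_probability(doses, t, cfg)) >= 0))
  }
  for (d in doses) {
    expect_true(all(diff(loss_probability(d, times, cfg)) >= 0))
  }
})

test_that("deletion counts follow the binomial model", {
  # mean over 60 independent simulations within 3 SD of n * p_loss
  p <- generate_proteome(400, seed = 8)
  tpl <- generate_control_template(p, n_peaks = 100, seed = 9)
  cfg <- treatment_config()
  p_loss <- loss_probability(5, 14, cfg)
  n_sim <- 60
  dels <- vapply(seq_len(n_sim), function(r) {
    tr <- apply_treatment(tpl, p, 5, 14, cfg, seed = 1000 + r)
    nrow(tr$truth$deleted)
  }, 0L)
  se <- sqrt(100 * p_loss * (1 - p_loss) / n_sim)
  expect_lt(abs(mean(dels) - 100 * p_loss), 3 * se)
})

test_that("diff against the control recovers the exact ground truth", {
  p <- generate_proteome(400, seed = 10)
  tpl <- generate_control_template(p, n_peaks = 80, seed = 11)
  tr <- apply_treatment(tpl, p, dose = 5, time_days = 21, seed = 12)
  d <- diff_profiles(tr$profile, tpl$profile, tol = 2)
  expect_equal(sort(d$missing_peaks$mz), sort(tr$truth$deleted$mz))
  expect_equal(sort(d$new_peaks$mz), sort(tr$truth$added$mz))
})

test_that("replicates without noise are identical to the profile; with seed, reproducible", {
  tpl <- make_profile(seq(1000, 5000, by = 500))
  cfg0 <- treatment_config(mz_jitter_sd = 0, replicate_dropout = 0,
                           intensity_cv = 0)
  reps <- emit_replicates(tpl, 5, cfg0, seed = 13)
  for (r in reps) {
    expect_equal(r$peaks$mz, tpl$peaks$mz)
    expect_equal(r$peaks$intensity, tpl$peaks$mean_intensity)
  }
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  emit_replicates(tpl, 3, treatment_config(), seed = 14, dir = dir1)
  emit_replicates(tpl, 3, treatment_config(), seed = 14, dir = dir2)
  for (fn in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, fn)),
                     readLines(file.path(dir2, fn)))
  }
})

test_that("a treatment's stress signature is nested across severities", {
  exp <- simulate_experiment(doses = c(2, 10), times_days = c(7, 21),
                             n_replicates = 1, n_proteins = 300,
                             n_peaks = 60, seed = 15)
  added <- lapply(exp$conditions, function(cc) cc$truth$added$accession)
  sizes <- vapply(added, length, 0L)
  o <- order(sizes)
  for (k in seq_len(length(o) - 1L)) {
    expect_true(all(added[[o[k]]] %in% added[[o[k + 1L]]]))
  }
})

test_that("experiment simulation writes the documented directory layout", {
  dir <- withr::local_tempdir()
  exp <- simulate_experiment(doses = c(1, 10), times_days = 7,
                             n_replicates = 2, n_proteins = 150,
                             n_peaks = 30, seed = 16, dir = dir)
  expect_true(file.exists(file.path(dir, "proteome.fasta")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(dir.exists(file.path(dir, "conditions", "control_0_0")))
  expect_true(file.exists(file.path(dir, "conditions", "treatment_1_7",
                                    "rep01.txt")))
  pl <- read_peaklist(file.path(dir, "conditions", "treatment_10_7", "rep02.txt"))
  expect_s3_class(pl, "peaklist")
  expect_gt(nrow(pl$peaks), 0)
})
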