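test_that("a single spectrum's MSP is the spectrum itself", {
  pl <- make_peaklist(c(1000, 2000, 3000), c(5, 10, 2))
  msp <- build_msp(list(pl), tol = 2, min_frequency = 1)
  expect_equal(msp$peaks$mz, pl$peaks$mz)
  expect_equal(msp$peaks$mean_intensity, pl$peaks$intensity)
  expect_equal(msp$peaks$frequency, rep(1, 3))
})

test_that("MSP of identical replicates reproduces the spectrum with frequency 1", {
  pl <- make_peaklist(c(1200.5, 4000, 9999.9), c(3, 8, 1))
  msp <- build_msp(replicate(7, pl, simplify = FALSE))
  expect_equal(msp$peaks$mz, pl$peaks$mz, tolerance = 1e-12)
  expect_equal(msp$peaks$frequency, rep(1, 3))
  expect_equal(msp$n_source_spectra, 7L)
})

test_that("occupancy threshold separates consistent from sporadic peaks", {
  # peak near 5000 in all 4 replicates, peak near 6000 in exactly 1
  reps <- lapply(1:4, function(k) {
    mz <- 5000 + 0.1 * k
    if (k == 1) mz <- c(mz, 6000)
    make_peaklist(mz)
  })
  msp <- build_msp(reps, tol = 2, min_frequency = 0.5)
  expect_equal(nrow(msp$peaks), 1L)
  expect_true(abs(msp$peaks$mz - 5000.25) < 0.5)
  expect_equal(msp$peaks$frequency, 1)
  # lowering the threshold admits the sporadic peak too
  msp2 <- build_msp(reps, tol = 2, min_frequency = 0.25)
  expect_equal(nrow(msp2$peaks), 2L)
})

test_that("raising min_frequency never increases the number of consensus peaks", {
  set.seed(21)
  template <- make_profile(sort(1000 + runif(40, 0, 20000)),
                           rlnorm(40, log(100), 1))
  reps <- emit_replicates(template, 10, treatment_config(), seed = 5)
  sizes <- vapply(c(0.1, 0.25, 0.5, 0.75, 1),
                  function(f) nrow(build_msp(reps, min_frequency = f)$peaks), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("consensus peaks are separated and lie within their group span", {
  set.seed(22)
  template <- make_profile(seq(2000, 22000, by = 250))
  reps <- emit_replicates(template, 12, treatment_config(), seed = 9)
  msp <- build_msp(reps, tol = 2, min_frequency = 0.25, max_peaks = 1000)
  expect_true(all(diff(msp$peaks$mz) > 2))
  # every consensus mz is close to one template position (span containment)
  nearest <- vapply(msp$peaks$mz,
                    function(m) min(abs(m - template$peaks$mz)), 0)
  expect_true(all(nearest < 2))
})

test_that("max_peaks keeps the most intense groups", {
  reps <- list(make_peaklist(c(1000, 2000, 3000, 4000), c(1, 100, 50, 2)))
  msp <- build_msp(reps, max_peaks = 2)
  expect_equal(msp$peaks$mz, c(2000, 3000))
})

test_that("template recovery from 20 noisy replicates at dropout 0.2", {
  # P(Bin(20, 0.8) < 5) < 1e-6 per peak, so all 100 template peaks must
  # reappear in the consensus at min_frequency 0.25
  set.seed(33)
  p <- generate_proteome(400, seed = 13)
  tpl <- generate_control_template(p, n_peaks = 100, seed = 14)
  reps <- emit_replicates(tpl$profile, 20, treatment_config(), seed = 15)
  msp <- build_msp(reps, tol = 2, min_frequency = 0.25, max_peaks = 100)
  expect_equal(nrow(msp$peaks), 100L)
  d <- vapply(tpl$profile$peaks$mz, function(m) min(abs(m - msp$peaks$mz)), 0)
  expect_true(all(d < 2))
})

test_that("degenerate inputs are rejected", {
  expect_error(build_msp(list()), "non-empty")
  expect_error(build_msp(list(make_peaklist(1000)), tol = 0), "tol")
  expect_error(build_msp(list(make_peaklist(1000)), min_frequency = 0), "min_frequency")
})

test_that("normalization modes scale as documented and are idempotent", {
  pl <- make_peaklist(c(1000, 2000, 3000), c(1, 2, 4))
  bp <- normalize_intensities(pl, "base-peak")
  expect_equal(bp$peaks$intensity, c(25, 50, 100))
  tic <- normalize_intensities(make_peaklist(c(1000, 2000), c(1, 1)), "tic")
  expect_equal(tic$peaks$intensity, c(0.5, 0.5))
  expect_equal(normalize_intensities(bp, "base-peak"), bp)
  expect_equal(normalize_intensities(tic, "tic"), tic)
  expect_error(normalize_intensities(make_peaklist(1000, 0)), "all-zero")
})

test_that("MSP CSV round-trip preserves the profile", {
  f <- withr::local_tempfile(fileext = ".csv")
  msp <- build_msp(list(make_peaklist(c(1000, 2000), c(5, 10))))
  write_msp(msp, f)
  back <- read_msp(f)
  expect_equal(back$peaks$mz, msp$peaks$mz)
  expect_equal(back$profile_id, msp$profile_id)
  expect_equal(back$n_source_spectra, msp$n_source_spectra)
})
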