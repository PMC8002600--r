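test_that("aligned vectors carry identity, disjointness and diff consistency", {
  p <- make_profile(c(1000, 2000, 3000), c(10, 20, 40))
  al <- align_profiles(p, p)
  expect_equal(al$intensity_a, al$intensity_b)
  expect_equal(max(al$intensity_a), 100)  # base-peak normalized

  q <- make_profile(c(10000, 11000, 12000), c(1, 2, 3))
  al2 <- align_profiles(p, q, tol = 2)
  expect_true(all(al2$intensity_a * al2$intensity_b == 0))

  set.seed(5)
  a <- make_profile(sort(runif(25, 1000, 20000)), rlnorm(25, log(50), 1))
  b <- make_profile(sort(runif(30, 1000, 20000)), rlnorm(30, log(50), 1))
  al3 <- align_profiles(a, b, tol = 2)
  d <- diff_profiles(a, b, tol = 2)
  expect_equal(nrow(al3),
               nrow(d$new_peaks) + nrow(d$missing_peaks) + nrow(d$shared))
})

test_that("correlation distance is zero on identity, symmetric, and matches the textbook formula", {
  p <- make_profile(c(1000, 2000, 3000, 4000), c(10, 20, 30, 40))
  expect_equal(correlation_distance(p, p), 0, tolerance = 1e-12)

  set.seed(6)
  a <- make_profile(sort(runif(20, 1000, 20000)), rlnorm(20, log(50), 1))
  b <- make_profile(sort(runif(20, 1000, 20000)), rlnorm(20, log(50), 1))
  expect_equal(correlation_distance(a, b), correlation_distance(b, a))

  # hand-computed 4-position instance: disjoint beyond-tol peaks so the
  # aligned vectors are exactly the normalized intensities and zeros
  x <- make_profile(c(1000, 2000), c(100, 25))
  y <- make_profile(c(5000, 6000), c(50, 50))
  al <- align_profiles(x, y, tol = 2)
  r <- stats::cor(sqrt(al$intensity_a), sqrt(al$intensity_b))
  expect_equal(correlation_distance(x, y), 1 - r, tolerance = 1e-12)
  # textbook Pearson on the same vectors
  va <- sqrt(al$intensity_a); vb <- sqrt(al$intensity_b)
  r_hand <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(r, r_hand, tolerance = 1e-12)
})

test_that("degenerate correlation inputs error", {
  a <- make_profile(c(1000, 2000), c(1, 1))
  expect_error(correlation_distance(a, a), "at least 3|variance")
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(8)
  profs <- lapply(1:5, function(k) {
    make_profile(sort(runif(30, 1000, 20000)), rlnorm(30, log(50), 1),
                 id = paste0("p", k))
  })
  names(profs) <- paste0("p", 1:5)
  d <- distance_matrix(profs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("upgma handles textbook instances", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(d)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))

  d3 <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma(d3)
  expect_true(ape::is.monophyletic(tr3, c("A", "B")))
  expect_false(ape::is.monophyletic(tr3, c("A", "C")))
})

test_that("upgma trees are ultrametric and agree with average-linkage hclust", {
  set.seed(9)
  for (k in 1:10) {
    n <- sample(4:9, 1L)
    m <- matrix(runif(n * n, 0.1, 2), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tr <- upgma(m)
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
    # independent route: stats::hclust average linkage cophenetic distances
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    coph_hc <- as.matrix(stats::cophenetic(hc))
    coph_tr <- ape::cophenetic.phylo(tr)
    ord <- rownames(coph_hc)
    expect_equal(coph_tr[ord, ord], coph_hc, tolerance = 1e-8)
  }
})

test_that("all-equal distances give the documented deterministic tie-break", {
  n <- 5
  m <- matrix(1, n, n); diag(m) <- 0
  labs <- c("delta", "alpha", "echo", "bravo", "charlie")
  dimnames(m) <- list(labs, labs)
  t1 <- ape::write.tree(upgma(m))
  t2 <- ape::write.tree(upgma(m[rev(labs), rev(labs)]))
  expect_identical(t1, t2)  # label order in the matrix is immaterial
  expect_true(ape::is.ultrametric(upgma(m), tol = 1e-9))
})

test_that("upgma validates its input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(m), "symmetric")
  m2 <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(upgma(m2), "non-finite")
})

test_that("identification scores identity at 3, disjoint at 0, and is order-invariant", {
  set.seed(10)
  lib <- lapply(1:5, function(k) {
    make_profile(sort(runif(40, 1000, 20000)), rlnorm(40, log(50), 1),
                 id = paste0("ref", k))
  })
  names(lib) <- paste0("ref", 1:5)
  q <- lib[[3]]
  res <- identify_profile(q, lib)
  expect_equal(res$reference[1], "ref3")
  expect_equal(res$score[1], 3, tolerance = 1e-9)

  disjoint <- make_profile(c(30000, 31000, 32000))
  res0 <- identify_profile(disjoint, lib)
  expect_equal(res0$score, rep(0, 5))

  perm <- sample(5)
  res_p <- identify_profile(q, lib[perm])
  expect_equal(res_p$reference[1], "ref3")
  expect_equal(res_p$score, res$score)
})

test_that("the generating template is recovered from noisy replicates", {
  set.seed(12)
  p <- generate_proteome(600, seed = 101)
  hits <- 0; n_runs <- 20
  lib_tpl <- lapply(1:5, function(k) {
    generate_control_template(p, n_peaks = 60, seed = 200 + k)
  })
  lib <- lapply(lib_tpl, function(t) t$profile)
  names(lib) <- paste0("species", 1:5)
  for (r in 1:n_runs) {
    k <- sample(5, 1)
    reps <- emit_replicates(lib_tpl[[k]]$profile, 6, treatment_config(),
                            seed = 300 + r)
    msp <- build_msp(reps)
    res <- identify_profile(msp, lib)
    hits <- hits + (res$reference[1] == paste0("species", k))
  }
  expect_equal(hits, n_runs)
})
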