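test_that("Kirchhoff matrix follows the spring-network definition", {
  g <- build_kirchhoff(path3_map())
  expect_equal(g$matrix,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3))
  M <- matrix(0, 3, 3); M[1, 2] <- M[2, 1] <- 5; M[2, 3] <- M[3, 2] <- 1
  g2 <- build_kirchhoff(contact_map(M))
  expect_equal(g2$matrix[1, 2], -5)
  expect_equal(g2$matrix[1, 1], 5)
  expect_equal(rowSums(g2$matrix), rep(0, 3))
  ## self-contacts on the diagonal contribute nothing
  Md <- M; diag(Md) <- c(9, 9, 9)
  expect_equal(build_kirchhoff(contact_map(Md))$matrix, g2$matrix)
})

test_that("decompose recovers known Laplacian spectra and zero modes", {
  g <- build_kirchhoff(path3_map())
  ms <- decompose(g, m = 2)
  expect_equal(ms$values, c(1, 3))
  expect_equal(ms$n_zero, 1L)
  ## complete graph on 4 nodes with unit weights: eigenvalues 4, 4, 4
  K4 <- contact_map(matrix(1, 4, 4) - diag(4))
  expect_equal(decompose(build_kirchhoff(K4), m = 3)$values, rep(4, 3))
  ## eigenvectors orthonormal, deterministic signs
  m5 <- random_connected_map(20, seed = 7)
  ms5 <- decompose(build_kirchhoff(m5), m = 10)
  expect_equal(crossprod(ms5$vectors), diag(10), tolerance = 1e-8)
  for (k in 1:10)
    expect_gt(ms5$vectors[which.max(abs(ms5$vectors[, k])), k], 0)
  ## connected graph: exactly one zero mode discarded
  expect_equal(ms5$n_zero, 1L)
})

test_that("disconnected graphs error unless explicitly allowed", {
  M <- matrix(0, 6, 6)
  M[1, 2] <- M[2, 1] <- 1; M[2, 3] <- M[3, 2] <- 1
  M[4, 5] <- M[5, 4] <- 1; M[5, 6] <- M[6, 5] <- 1
  g <- build_kirchhoff(contact_map(M))
  expect_error(decompose(g, m = 2), "disconnected")
  ms <- decompose(g, m = 2, allow_disconnected = TRUE)
  expect_equal(ms$n_zero, 2L)
  expect_warning(decompose(build_kirchhoff(path3_map()), m = 10),
                 "clamped")
})

test_that("MSF matches the pseudoinverse oracle on the 3-bin path", {
  fit <- gnm(path3_map(), n_modes = 2)
  expect_equal(as.numeric(fluctuations(fit)), c(5, 2, 5) / 9,
               tolerance = 1e-10)
  ## single softest mode only: (1/lambda_1) u_1i^2 with u_1 = (1,0,-1)/sqrt(2)
  fit1 <- gnm(path3_map(), n_modes = 1)
  expect_equal(as.numeric(fluctuations(fit1)), c(0.5, 0, 0.5),
               tolerance = 1e-10)
  ## trace identity: sum_i msf_i = sum_k 1/lambda_k
  m <- random_connected_map(15, seed = 3)
  f <- gnm(m, n_modes = 8)
  expect_equal(sum(f$msf), sum(1 / coef(f)), tolerance = 1e-10)
})

test_that("full-mode covariance equals the Moore-Penrose pseudoinverse", {
  for (seed in 1:5) {
    n <- sample(10:40, 1)
    m <- random_connected_map(n, seed = seed)
    fit <- gnm(m, n_modes = n - 1)
    C <- vcov(fit)
    C_oracle <- MASS::ginv(build_kirchhoff(m)$matrix)
    expect_equal(C, C_oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("MSF grows monotonically with the number of modes", {
  m <- random_connected_map(25, seed = 9)
  f_small <- gnm(m, n_modes = 5)
  f_big <- gnm(m, n_modes = 20)
  expect_true(all(f_big$msf - f_small$msf >= -1e-12))
})

test_that("directional cross-correlations are correlation cosines", {
  fit <- gnm(path3_map(), n_modes = 2)
  D <- cross_correlation(fit)
  expect_equal(D[1, 2], -1 / sqrt(10), tolerance = 1e-10)
  expect_equal(diag(D), rep(1, 3))
  expect_true(all(D >= -1 & D <= 1))
  ## rank-1 covariance: all correlations have |D| = 1 where defined
  f1 <- manual_fit(matrix(c(1, 1, -2) / sqrt(6), 3), values = 2)
  D1 <- cross_correlation(vcov(f1))
  expect_equal(abs(D1), matrix(1, 3, 3))
  ## zero-variance locus is a diagnosable error
  f0 <- manual_fit(matrix(c(1, 0, -1) / sqrt(2), 3), values = 1)
  expect_error(cross_correlation(vcov(f0)), "zero-variance")
})

test_that("collectivity measures mode delocalization", {
  n <- 8
  uniform <- manual_fit(matrix(1 / sqrt(n), n, 1), values = 1)
  expect_equal(collectivity(uniform), 1)
  spike <- manual_fit(matrix(c(1, rep(0, n - 1)), n, 1), values = 1)
  expect_equal(collectivity(spike), 1 / n)
  half <- manual_fit(matrix(c(rep(sqrt(2 / n), n / 2), rep(0, n / 2)),
                            n, 1), values = 1)
  expect_equal(collectivity(half), 0.5)
  ## always in (0, 1]
  f <- gnm(random_connected_map(12, seed = 5), n_modes = 6)
  k <- collectivity(f)
  expect_true(all(k > 0 & k <= 1))
})

test_that("normalize_profile scales to mean 1 and preserves correlations", {
  p <- structure(c(1, 2, 3), mask = rep(TRUE, 3),
                 class = "mobility_profile")
  expect_equal(as.numeric(normalize_profile(p)), c(0.5, 1, 1.5))
  const <- structure(c(2, 2, 2), mask = rep(TRUE, 3),
                     class = "mobility_profile")
  expect_equal(as.numeric(normalize_profile(const)), c(1, 1, 1))
  expect_equal(as.numeric(normalize_profile(normalize_profile(p))),
               as.numeric(normalize_profile(p)))
  expect_error(normalize_profile(structure(c(0, 0), mask = rep(TRUE, 2),
                                           class = "mobility_profile")),
               "all-zero")
  q <- gnm(random_connected_map(10, seed = 2), n_modes = 5)
  r <- gnm(random_connected_map(10, seed = 3), n_modes = 5)
  expect_equal(
    profile_correlation(fluctuations(q), fluctuations(r)),
    profile_correlation(fluctuations(q, normalized = TRUE),
                        fluctuations(r, normalized = TRUE)))
})

test_that("genome scope restricted per chromosome equals chromosome scope when trans is zero", {
  M <- matrix(0, 12, 12)
  blocks <- list(1:6, 7:12)
  set.seed(21)
  for (b in blocks) {
    for (i in head(b, -1)) M[i, i + 1] <- M[i + 1, i] <- runif(1, 0.5, 2)
    M[b[1], b[length(b)]] <- M[b[length(b)], b[1]] <- 0.3
  }
  bins <- data.frame(chrom = rep(c("chr1", "chr2"), each = 6),
                     start = rep(0:5, 2) * 50000,
                     end = rep(1:6, 2) * 50000)
  map <- contact_map(M, bins = bins)
  per_chr <- chromosome_gnms(map, n_modes = 5)
  for (ch in c("chr1", "chr2")) {
    b <- blocks[[match(ch, c("chr1", "chr2"))]]
    sub <- contact_map(M[b, b], bins = bins[b, ])
    full_block <- gnm(sub, n_modes = 5)
    expect_equal(per_chr[[ch]]$msf, full_block$msf, tolerance = 1e-8)
  }
})

test_that("sparse partial eigensolution agrees with the dense path", {
  m <- random_connected_map(120, seed = 13, density = 0.1)
  g <- build_kirchhoff(m)
  dense <- decompose(g, m = 10, dense_below = 2000)
  sparse <- decompose(g, m = 10, dense_below = 10)
  expect_equal(sparse$values, dense$values, tolerance = 1e-7)
  expect_equal(abs(colSums(sparse$vectors * dense$vectors)),
               rep(1, 10), tolerance = 1e-6)
})

test_that("model methods behave like a fitted-model object", {
  m <- random_connected_map(15, seed = 4)
  fit <- gnm(m, n_modes = 6, label = "demo")
  expect_output(print(fit), "Gaussian network model")
  expect_output(print(summary(fit)), "Collectivity")
  expect_length(coef(fit), 6)
  expect_equal(dim(vcov(fit)), c(15, 15))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(3, 15))
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-10)
})
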