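test_that("depth profile is flat in the topsoil and exponential below", {
  expect_equal(depth_mean_profile(0.1), 12.21)
  expect_equal(depth_mean_profile(0.3), 12.21)  # continuity at the interface
  expect_equal(depth_mean_profile(0.9, gamma = 3), 12.21 * exp(-1.8))
  expect_equal(depth_mean_profile(0.9, gamma = 3), 2.0183, tolerance = 1e-4)
  expect_error(depth_mean_profile(-0.1))
})

test_that("gene-to-biomass conversion matches the tabulated anchor", {
  expect_equal(genes_to_biomass(1.11e8, 1.10e-7), 12.21)
  expect_equal(genes_to_biomass(0), 0)
  x <- c(1e6, 3e7, 1.11e8)
  expect_equal(biomass_to_genes(genes_to_biomass(x)), x)
})

test_that("areal intensity follows from the thin-section geometry", {
  lg <- lgcp_params(1, 0.009)
  expect_equal(mean_intensity(0.1, lg), 6.882e6, tolerance = 1e-3)
  # expected genes per 5 mm x 5 mm topsoil cell
  expect_equal(mean_intensity(0.1, lg) * (5e-3)^2, 172.05, tolerance = 1e-3)
  lg2 <- lgcp_params(1, 0.009, d_v_sts = 2 * lg$d_v_sts)
  expect_equal(mean_intensity(0.1, lg2), 2 * mean_intensity(0.1, lg))
})

test_that("sigma2 = 0 reduces to an inhomogeneous Poisson process", {
  lg <- lgcp_params(0, 0.009, res = 1e-3)
  f <- sample_field(lg, 0.3, 0.3, seed = 42)
  counts <- as.vector(f$gene_count)
  mu <- mean_intensity(0.1, lg) * (5e-3)^2
  expect_equal(mean(counts), mu, tolerance = 0.02)
  # Poisson: variance equals mean (index of dispersion near 1)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.08)
  # ensemble CV is the Poisson-only CV, about 100/sqrt(172)
  expect_equal(compute_cv(f, "topsoil"), 100 / sqrt(mu), tolerance = 0.06)
  expect_equal(colonization_ratio(f, "topsoil"), 100, tolerance = 1e-6)
})

test_that("field sampling is reproducible and unbiased", {
  lg <- default_lgcp("HIGH")
  f1 <- sample_field(lg, 0.15, 0.15, seed = 7)
  f2 <- sample_field(lg, 0.15, 0.15, seed = 7)
  expect_identical(f1$B, f2$B)
  f3 <- sample_field(lg, 0.15, 0.15, seed = 8)
  expect_false(identical(f1$B, f3$B))
  # ensemble mean of cell biomass matches the depth profile (within 2 SEM)
  means <- vapply(1:40, function(k)
    mean(sample_field(lg, 0.15, 0.15, seed = 100 + k)$B), 0)
  sem <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 12.21), 2 * sem + 1e-9)
})

test_that("subsoil is more heterogeneous and less colonized than topsoil", {
  lg <- default_lgcp("EXTR")
  cvs <- matrix(0, 8, 2); crs <- matrix(0, 8, 2)
  for (k in 1:8) {
    f <- sample_field(lg, 0.15, 0.9, seed = 300 + k)
    cvs[k, ] <- c(compute_cv(f, "topsoil"), compute_cv(f, "subsoil"))
    crs[k, ] <- c(colonization_ratio(f, "topsoil"),
                  colonization_ratio(f, "subsoil"))
  }
  expect_gt(mean(cvs[, 2]), mean(cvs[, 1]))
  expect_lt(mean(crs[, 2]), mean(crs[, 1]))
})

test_that("CV is a closed-form population statistic", {
  B <- matrix(c(rep(1, 18), rep(3, 18)), 6, 6)
  f <- field_from_B(B)
  expect_equal(compute_cv(f, "topsoil"), 50)  # sd/mean of {1,3} = 1/2
  expect_equal(compute_cv(field_from_B(matrix(5, 4, 4))), 0)
  expect_error(compute_cv(field_from_B(matrix(0, 4, 4))), "zero mean")
})

test_that("colonization ratio applies the 100 genes/g threshold", {
  expect_equal(colonization_ratio(field_from_B(matrix(0, 4, 4))), 0)
  # one gene in a 5 mm cell is ~645 genes/g, far above the threshold:
  # CR equals the fraction of cells holding at least one gene
  f <- sample_field(lgcp_params(2, 0.009, res = 1e-3), 0.2, 0.2, seed = 5)
  expect_equal(colonization_ratio(f, "topsoil"),
               100 * mean(f$gene_count >= 1))
})

test_that("semivariogram of uniform and white-noise fields", {
  vg0 <- empirical_semivariogram(field_from_B(matrix(4, 20, 20)))
  expect_true(all(vg0$gamma == 0))
  set.seed(11)
  Z <- matrix(rnorm(60 * 60, 10, 2), 60, 60)
  vg <- empirical_semivariogram(field_from_B(Z))
  s2 <- mean((Z - mean(Z))^2)
  # i.i.d. field: E(Z_i - Z_j)^2 / 2 = variance at every lag
  expect_true(all(abs(vg$gamma - s2) / s2 < 0.1))
})

test_that("exponential variogram fit recovers known parameters", {
  h <- seq(1.65e-3, 50e-3, by = 3.3e-3)
  vario <- data.frame(dist = h, gamma = 7 * (1 - exp(-h / 0.009)),
                      npairs = rep(1000, length(h)))
  ft <- fit_exponential_variogram(vario)
  expect_true(ft$converged)
  expect_equal(ft$sill, 7, tolerance = 0.01)
  expect_equal(ft$range_a, 0.009, tolerance = 0.01)
  expect_equal(ft$practical_range, 0.027, tolerance = 0.01)
  # scale equivariance: distances scaled by k scale the fitted range by k
  vario2 <- transform(vario, dist = dist * 2.5,
                      gamma = 7 * (1 - exp(-dist * 2.5 / (2.5 * 0.009))))
  ft2 <- fit_exponential_variogram(vario2)
  expect_equal(ft2$range_a, 2.5 * 0.009, tolerance = 0.01)
})

test_that("acceptance rule applies the CV and range bands", {
  hom <- hom_field(0.3, 0.3)
  expect_true(accept_field(hom, target_cv = 0)$accepted)
  expect_false(accept_field(hom, target_cv = 400)$accepted)
  lg <- default_lgcp("EXTR")
  for (k in 1:5) {
    f <- sample_field(lg, 0.3, 0.3, seed = 600 + k)
    m <- field_metrics(f)
    want <- abs(m$cv - 400) <= 40 &&
      !is.na(m$practical_range) && abs(m$practical_range - 27e-3) <= 2e-3
    expect_identical(accept_field(f, 400)$accepted, want)
  }
})

test_that("scenario CV targets are bound to the labels", {
  expect_equal(scenario_cv_target("HOM"), 0)
  expect_equal(scenario_cv_target("LOW"), 16)
  expect_equal(scenario_cv_target("HIGH"), 161)
  expect_equal(scenario_cv_target("EXTR"), 400)
  expect_error(scenario_cv_target("MEGA"))
})
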