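test_that("cohort generation is deterministic and respects basic bounds", {
  cfg <- quick_cfg(n = 400, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(quick_cfg(n = 400, seed = 10))
  expect_false(identical(c1$bmi, c3$bmi))

  expect_true(all(c1$crp > 0))
  expect_true(all(c1$bmi > 0))
  expect_true(all(c1$at_score > 0))
  expect_true(all(c1$cm_score >= 0 & c1$cm_score <= 25))
  expect_true(all(c1$cm_score == round(c1$cm_score)))
  expect_false(anyNA(c1))
  expect_true(all(c1$age >= 40 & c1$age <= 70))
})

test_that("zero residual SDs give the exact noise-free structural limit", {
  cfg <- plain_cfg(n = 300, seed = 4,
                   residual_sds = c(bmi = 0, at = 0, crp = 0))
  coh <- generate_cohort(cfg)
  lat <- attr(coh, "latents")
  a <- cfg$struct_coeffs
  expect_equal(lat$crp,
               a[["a2"]] * lat$cm + a[["b1"]] * lat$bmi + a[["b2"]] * lat$at,
               tolerance = 1e-12)
  expect_equal(lat$bmi, a[["a1"]] * lat$cm, tolerance = 1e-12)
  # raw CRP is an exact monotone (lognormal) transform of the latent
  expect_equal(cor(log(coh$crp), lat$crp), 1, tolerance = 1e-12)
})

test_that("CM-AT correlation matches the published value at study scale", {
  coh <- generate_cohort(quick_cfg(n = 21738, seed = 31))
  r <- cor(coh$cm_score, coh$at_score, method = "spearman")
  expect_lt(abs(r - 0.31), 0.02)
})

test_that("raw BMI and CRP marginals are calibrated within Monte-Carlo error", {
  coh <- generate_cohort(quick_cfg(n = 50000, seed = 12))
  n <- nrow(coh)
  for (v in list(list("bmi", 26.5, 4.2), list("crp", 2.03, 3.53))) {
    x <- coh[[v[[1]]]]
    # SEs from the theoretical moments of the calibrated lognormal
    s2 <- log(1 + (v[[3]] / v[[2]])^2)
    kurt <- exp(4 * s2) + 2 * exp(3 * s2) + 3 * exp(2 * s2) - 3
    se_mean <- v[[3]] / sqrt(n)
    se_sd <- v[[3]] * sqrt((kurt - 1) / (4 * n))
    expect_lt(abs(mean(x) - v[[2]]), 3 * se_mean)
    expect_lt(abs(sd(x) - v[[3]]), 3 * se_sd)
  }
})

test_that("standardized latents converge to the model-implied covariance", {
  cfg <- quick_cfg(n = 100000, seed = 21)
  coh <- generate_cohort(cfg)
  lat <- attr(coh, "latents")
  S_emp <- cov(scale(as.matrix(lat)))
  a <- cfg$struct_coeffs
  th <- c(a, v_cm = 1, v_bmi = unname(cfg$residual_sds["bmi"]^2),
          v_at = unname(cfg$residual_sds["at"]^2),
          v_crp = unname(cfg$residual_sds["crp"]^2))
  S_mod <- implied_covariance(h1_model(), th)
  expect_lt(max(abs(S_emp[colnames(S_mod), colnames(S_mod)] - S_mod)), 0.01)
})

test_that("cortical centroids form a quasi-uniform unit-sphere lattice", {
  geo <- generate_geometry(quick_cfg())
  cort <- geo[geo$structure_class == "cortical", ]
  expect_identical(nrow(cort), 180L)
  norms <- sqrt(cort$x^2 + cort$y^2 + cort$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_identical(anyDuplicated(cort[, c("x", "y", "z")]), 0L)
  D <- as.matrix(dist(cort[, c("x", "y", "z")]))
  diag(D) <- Inf
  expect_gt(min(D), 0)
  expect_true(all(!geo$spin_eligible[geo$structure_class == "subcortical"]))

  # nearest-neighbour spacing regularity at finer resolution (brute force)
  geo2 <- generate_geometry(quick_cfg(n_cortical = 1000))
  c2 <- as.matrix(geo2[geo2$structure_class == "cortical", c("x", "y", "z")])
  D2 <- as.matrix(dist(c2))
  diag(D2) <- Inf
  nn <- apply(D2, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.2)
})

test_that("null brain maps give reference-distribution t statistics", {
  cfg <- plain_cfg(n = 5000, seed = 8, spatial_kernel_length = 0,
                   regional_effects = list(c1 = 0, c2 = 0, c3 = 0))
  coh <- generate_cohort(cfg)
  br <- generate_brain(coh, generate_geometry(cfg), cfg)
  lat <- attr(coh, "latents")
  sm <- regionwise_regression(lat$crp, unclass(br))
  ks <- suppressWarnings(
    ks.test(sm$t, function(q) pt(q, df = nrow(coh) - 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted regional CRP effect is recovered with |t| > 2", {
  m <- 12 + 7
  c2v <- rep(0, m); c2v[5] <- -0.1
  hits <- vapply(1:10, function(s) {
    cfg <- plain_cfg(n = 20000, seed = 500 + s, n_cortical = 12,
                     regional_effects = list(c1 = 0, c2 = c2v, c3 = 0))
    coh <- generate_cohort(cfg)
    br <- generate_brain(coh, generate_geometry(cfg), cfg)
    sm <- regionwise_regression(attr(coh, "latents")$crp, unclass(br))
    sm$beta[5] < 0 && abs(sm$t[5]) > 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("spatially correlated noise has positive Moran's I", {
  cfg <- plain_cfg(n = 50, seed = 3, spatial_kernel_length = 0.4,
                   regional_effects = list(c1 = 0, c2 = 0, c3 = 0))
  geo <- generate_geometry(cfg)
  br <- generate_brain(generate_cohort(cfg), geo, cfg)
  cent <- as.matrix(geo[geo$structure_class == "cortical", c("x", "y", "z")])
  I <- moran_i(as.numeric(br[1, 1:180]), cent, k = 6)
  expect_gt(I, 0)

  cfg0 <- plain_cfg(n = 50, seed = 3, spatial_kernel_length = 0,
                    regional_effects = list(c1 = 0, c2 = 0, c3 = 0))
  br0 <- generate_brain(generate_cohort(cfg0), generate_geometry(cfg0), cfg0)
  I0 <- moran_i(as.numeric(br0[1, 1:180]), cent, k = 6)
  expect_lt(abs(I0), abs(I))
})

test_that("brain generation is deterministic and shape-checked", {
  cfg <- quick_cfg(n = 60, seed = 5, n_cortical = 20)
  coh <- generate_cohort(cfg)
  geo <- generate_geometry(cfg)
  b1 <- generate_brain(coh, geo, cfg)
  b2 <- generate_brain(coh, geo, cfg)
  expect_identical(b1, b2)
  expect_identical(dim(b1), c(60L, 27L))
  expect_error(generate_brain(as.data.frame(coh[1:10, ]), geo, cfg),
               "latents")
  cfg2 <- quick_cfg(n = 60, seed = 5, n_cortical = 30)
  expect_error(generate_brain(coh, geo, cfg2), "region counts")
})

test_that("outlier injection plants exactly what the MAD filter detects", {
  cfg <- quick_cfg(n = 200, seed = 6, n_cortical = 10)
  coh <- generate_cohort(cfg)
  br <- generate_brain(coh, generate_geometry(cfg), cfg)

  same <- inject_outliers(br, rate = 0, magnitude = 10)
  expect_identical(same$matrix, br)
  expect_identical(nrow(same$planted), 0L)

  expect_error(inject_outliers(br, 0.01, magnitude = 4), "undetectable")
  expect_error(inject_outliers(br, rate = 1.5, magnitude = 10), "rate")

  out <- inject_outliers(br, rate = 0.01, magnitude = 10, seed = 2)
  expect_equal(nrow(out$planted), round(0.01 * length(br)))
  flagged <- vapply(seq_len(nrow(out$planted)), function(i) {
    keep <- mad_filter(out$matrix[, out$planted$col[i]])
    !keep[out$planted$row[i]]
  }, logical(1))
  expect_true(all(flagged))
})

test_that("completely-at-random masking hits the requested rate", {
  cfg <- quick_cfg(n = 500, seed = 2, n_cortical = 40, mcar_rate = 0.05)
  coh <- generate_cohort(cfg)
  br <- generate_brain(coh, generate_geometry(cfg), cfg)
  rate <- mean(is.na(br))
  expect_lt(abs(rate - 0.05), 0.01)
})
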