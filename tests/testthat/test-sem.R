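test_that("the model text syntax parses, labels and validates", {
  m <- path_model(c("crp <- bmi : b1", "bmi <- cm"))
  expect_identical(m$edges$label, c("b1", "bmi~cm"))
  expect_identical(count_parameters(m), 2L)
  expect_error(path_model("a <~ b"), "cannot parse")
  expect_error(path_model(c("b <- a : x", "c <- b : x")), "duplicate")
  expect_error(path_model(c("b <- a", "a <- b")), "cycle")

  expect_identical(count_parameters(h3_full_model()), 8L)
  expect_identical(count_parameters(h3_sparse_model()), 6L)
  expect_identical(count_parameters(h1_model()), 5L)
})

test_that("implied covariance follows the path-tracing closed forms", {
  m0 <- independence_model(c("x", "y"))
  expect_equal(implied_covariance(m0, c(v_x = 2, v_y = 3)),
               diag(c(2, 3)), ignore_attr = TRUE)

  m1 <- path_model("y <- x : a", variables = c("x", "y"))
  S <- implied_covariance(m1, c(a = 0.5, v_x = 1, v_y = 0.3))
  expect_equal(S["x", "y"], 0.5)
  expect_equal(S["y", "y"], 0.5^2 + 0.3)

  # four-variable model at the published point estimates
  th <- c(a1 = 0.072, a2 = 0.008, a3 = 0.315, b1 = 0.434, b2 = 0.019,
          v_cm = 1, v_bmi = 1 - 0.072^2, v_at = 1 - 0.315^2, v_crp = 0.81)
  S4 <- implied_covariance(h1_model(), th)
  expect_equal(S4["cm", "crp"], 0.008 + 0.072 * 0.434 + 0.315 * 0.019,
               tolerance = 1e-12)
  expect_error(implied_covariance(h1_model(), th[1:4]), "free parameters")
})

test_that("ML estimation equals the least-squares oracle on random models", {
  set.seed(42)
  for (rep in 1:5) {
    sim <- sim_random_recursive(p = sample(3:5, 1), n = 400)
    fit <- fit_path_model(sim$model, sample_moments(sim$data))
    oracle <- ols_oracle(sim$model, sim$data)
    if (length(oracle))
      expect_equal(fit$estimates[names(oracle)], oracle, tolerance = 1e-8)
    # true minimum: random perturbations never decrease the discrepancy
    S <- fit$S
    logdetS <- determinant(S)$modulus
    Fhat <- brainpath:::bp_F_ml(S, fit$Sigma, logdetS)
    for (k in 1:5) {
      thp <- fit$estimates + rnorm(length(fit$estimates), sd = 0.05)
      Sp <- implied_covariance(sim$model, thp)
      expect_gte(brainpath:::bp_F_ml(S, Sp, logdetS), Fhat - 1e-10)
    }
  }
})

test_that("saturated models reproduce the sample moments exactly", {
  set.seed(5)
  d <- sim_h1(300)
  msat <- path_model(c("bmi <- cm", "at <- cm", "at <- bmi", "crp <- cm",
                       "crp <- bmi", "crp <- at"),
                     variables = c("cm", "bmi", "at", "crp"))
  fit <- fit_path_model(msat, sample_moments(d))
  expect_identical(fit$df, 0)
  expect_equal(fit$F_min, 0)
  expect_equal(fit$T_ml, 0)
  expect_equal(fit$Sigma, fit$S, tolerance = 1e-8)
})

test_that("growing the edge set never increases the ML discrepancy", {
  set.seed(6)
  d <- sim_h1(500)
  edges <- c("bmi <- cm", "at <- cm", "crp <- bmi", "crp <- at", "crp <- cm",
             "at <- bmi")
  Fs <- vapply(seq_along(edges), function(k) {
    m <- path_model(edges[1:k], variables = c("cm", "bmi", "at", "crp"))
    fit_path_model(m, sample_moments(d))$F_min
  }, numeric(1))
  expect_true(all(diff(Fs) <= 1e-10))
  expect_equal(Fs[length(Fs)], 0, tolerance = 1e-12)
})

test_that("parameter estimates are consistent at large n", {
  set.seed(88)
  d <- sim_h1(100000)
  fit <- fit_path_model(h1_model(), sample_moments(d, standardize = TRUE))
  truth <- c(a1 = 0.072, a2 = 0.008, a3 = 0.315, b1 = 0.434, b2 = 0.019)
  expect_lt(max(abs(fit$estimates[names(truth)] - truth)), 0.01)
})

test_that("estimation guards its preconditions", {
  d <- sim_h1(50)
  S_bad <- matrix(1, 4, 4, dimnames = list(names(d), names(d)))
  mom <- structure(list(S = S_bad, n = 50, means = rep(0, 4)),
                   class = "brainpath_moments")
  expect_error(fit_path_model(h1_model(), mom), "positive definite")
  mom2 <- sample_moments(d); mom2$n <- 3
  expect_error(fit_path_model(h1_model(), mom2), "sample size")
})

test_that("sandwich errors agree with naive errors for normal data", {
  set.seed(9)
  d <- sim_h1(100000)
  fit <- fit_sem(h1_model(), d)
  expect_true(all(fit$se_robust / fit$se_naive > 0.95))
  expect_true(all(fit$se_robust / fit$se_naive < 1.05))
  expect_equal(unname(fit$scaling), 1, tolerance = 0.05)
  # Wald z is exactly estimate / robust SE
  expect_identical(fit$z, fit$estimates / fit$se_robust)
})

test_that("heavy-tailed residuals inflate the scaling factor", {
  # jointly heavy-tailed (elliptical t3) residuals: every residual moment
  # direction carries excess kurtosis, so the mean scaling must exceed 1
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    n <- 5000
    w <- sqrt(3 / rchisq(n, 3))
    cm <- rnorm(n)
    d <- data.frame(cm = cm,
                    bmi = 0.1 * cm + w * rnorm(n),
                    at = 0.3 * cm + w * rnorm(n))
    d$crp <- 0.4 * d$bmi + w * rnorm(n)
    fit_sem(h1_model(), d)$scaling > 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a saturated model reports zero scaled statistic with a warning", {
  set.seed(10)
  d <- sim_h1(300)
  msat <- path_model(c("bmi <- cm", "at <- cm", "at <- bmi", "crp <- cm",
                       "crp <- bmi", "crp <- at"),
                     variables = c("cm", "bmi", "at", "crp"))
  fit <- fit_path_model(msat, sample_moments(d))
  expect_warning(fit <- robust_errors(fit, d), "saturated")
  expect_equal(fit$T_sb, 0)
  expect_equal(fit$scaling, 1)
})

test_that("fit indices hit their degenerate anchors and bands", {
  set.seed(11)
  d <- sim_h1(2000)
  base <- fit_sem(independence_model(names(d)), d)
  msat <- path_model(c("bmi <- cm", "at <- cm", "at <- bmi", "crp <- cm",
                       "crp <- bmi", "crp <- at"),
                     variables = c("cm", "bmi", "at", "crp"))
  sat <- suppressWarnings(fit_sem(msat, d))
  ix <- fit_indices(sat, base)
  expect_equal(ix$cfi, 1)
  expect_equal(ix$rmsea, 0)
  expect_equal(ix$srmr, 0, tolerance = 1e-8)

  ix0 <- fit_indices(base, base)         # baseline scored against itself
  expect_equal(ix0$cfi, 0)
  expect_identical(unname(ix0$bands["cfi"]), "poor")

  fit <- fit_sem(h1_model(), d)
  expect_error(fit_indices(fit, fit), "independence")

  # a well-specified model on a calibrated cohort sits in the good band
  coh <- generate_cohort(quick_cfg(n = 21738, seed = 19))
  r <- preprocess_phenotypes(coh)
  f2 <- fit_sem(h1_model(), r)
  b2 <- fit_sem(independence_model(names(r)), r)
  ix2 <- fit_indices(f2, b2)
  expect_lt(ix2$srmr, 0.05)
  expect_identical(unname(ix2$bands["srmr"]), "good")
  expect_true(ix2$rmsea_ci["lower"] <= ix2$rmsea + 1e-12)
})

test_that("indirect effects are literal products with delta-method errors", {
  set.seed(12)
  d <- sim_h1(5000)
  fit <- fit_sem(h1_model(), d)
  ind <- indirect_effects(fit, list(c("cm", "bmi", "crp"), c("a3", "b2")))
  expect_equal(ind$estimate[1],
               unname(fit$estimates["a1"] * fit$estimates["b1"]))
  expect_equal(ind$estimate[2],
               unname(fit$estimates["a3"] * fit$estimates["b2"]))

  # Sobel identity when the parameter covariance is diagonal
  fit2 <- fit
  fit2$acov_robust <- diag(diag(fit$acov_robust))
  dimnames(fit2$acov_robust) <- dimnames(fit$acov_robust)
  ind2 <- indirect_effects(fit2, list(c("a1", "b1")))
  a <- fit$estimates["a1"]; b <- fit$estimates["b1"]
  sea <- fit$se_robust["a1"]; seb <- fit$se_robust["b1"]
  expect_equal(ind2$se, unname(sqrt(b^2 * sea^2 + a^2 * seb^2)),
               tolerance = 1e-12)

  # zero coefficient in the chain: estimate 0 and z 0
  fit3 <- fit
  fit3$estimates["a1"] <- 0
  ind3 <- indirect_effects(fit3, list(c("a1", "b1")))
  expect_identical(ind3$estimate, 0)

  expect_error(indirect_effects(fit, list(c("cm", "crp", "bmi"))), "no edge")
  expect_error(indirect_effects(fit, list(c("b1", "a1"))), "directed path")
})

test_that("nested comparison uses k = p1 - p2 and checks nesting", {
  set.seed(13)
  d <- sim_h1(2000)
  d$region <- 0.05 * d$crp + rnorm(2000)
  ff <- fit_sem(h3_full_model(), d)
  fs <- fit_sem(h3_sparse_model(), d)
  cmp <- lr_compare(ff, fs)
  expect_identical(cmp$df, 2L)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  expect_error(lr_compare(ff, ff), "k = 0")
  m_alt <- path_model(c("bmi <- cm : a1", "at <- bmi : q"),
                      variables = c("cm", "bmi", "at", "crp", "region"))
  fa <- fit_sem(m_alt, d)
  expect_error(lr_compare(ff, fa), "not nested")
})

test_that("parameter recovery from the calibrated generator is unbiased", {
  est <- vapply(1:50, function(s) {
    coh <- generate_cohort(quick_cfg(n = 5000, seed = 6000 + s))
    fit <- fit_path_model(h1_model(),
                          sample_moments(preprocess_phenotypes(coh),
                                         standardize = TRUE))
    fit$estimates[c("a1", "a2", "a3", "b1", "b2")]
  }, numeric(5))
  truth <- c(a1 = 0.072, a2 = 0.008, a3 = 0.315, b1 = 0.434, b2 = 0.019)
  bias <- abs(rowMeans(est) - truth)
  expect_true(all(bias < 0.01))
})
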