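#' Configuration for the synthetic cohort and brain-map generator
#'
#' Builds and validates the full parameter set of the synthetic population:
#' structural (standardized) path coefficients between childhood maltreatment
#' (CM), adult trauma (AT), body-mass index (BMI) and C-reactive protein
#' (CRP); per-region effects of BMI/CRP/AT on brain structure; raw-scale
#' marginal calibration targets; nuisance-covariate effects; the spatial
#' kernel for regional noise; and the master seed.
#'
#' The structural model is defined between the *analysis-scale* variables
#' (standardized log-transformed scores), so that fitting the path model to a
#' generated cohort recovers `struct_coeffs` as standardized coefficients:
#' \deqn{BMI = a1 CM + e_1,\quad AT = a3 CM + e_3,\quad
#'       CRP = a2 CM + b1 BMI + b2 AT + e_2.}
#' Raw-scale BMI, CRP and AT are lognormal transforms of these latents with
#' mean/SD matched to `marginal_calibration`; CM is an integer questionnaire
#' sum in `[0, 25]` produced by a calibrated zero-inflated lognormal count
#' map. Covariate effects are injected on the log scale before
#' exponentiation, so nuisance regression after log transformation removes
#' them exactly.
#'
#' @param n_participants Cohort size (>= 10).
#' @param variant `"mri"` (default) calibrates marginals and sample size to
#'   the imaging subsample (n = 21,738; direct CM->CRP effect 0.008);
#'   `"ukb"` to the full-cohort replication (n = 116,887; CM->CRP 0.0095).
#' @param struct_coeffs Named vector with elements `a1` (CM->BMI), `a2`
#'   (CM->CRP), `a3` (CM->AT), `b1` (BMI->CRP), `b2` (AT->CRP).
#' @param residual_sds Optional named vector (`bmi`, `at`, `crp`) of latent
#'   residual SDs; `NULL` (default) solves them so every latent has unit
#'   variance and `struct_coeffs` are exactly the standardized coefficients.
#'   Zero is allowed (noise-free limit).
#' @param marginal_calibration Optional list overriding raw-scale targets;
#'   elements `bmi`, `crp`, `cm`, `at`, `age`, `ses` are `c(mean, sd)`
#'   pairs, `sex_p` the proportion of females, `site_probs` site
#'   probabilities.
#' @param covariate_effects Optional list of named coefficient vectors (per
#'   variable: `cm`, `bmi`, `at`, `crp`, `region`) on standardized covariate
#'   columns (`age`, `sex`, `age_sex`, `ses`, `site2`, `site3`, ...). The CM
#'   vector defaults to zero.
#' @param regional_effects Optional list of per-region coefficient vectors
#'   `c1` (BMI), `c2` (CRP), `c3` (AT), each of length
#'   `n_cortical + n_subcortical`; `NULL` (default) generates smooth cortical
#'   effect maps at simulation time (`c1`/`c2` as noisy copies of one shared
#'   map, reproducing the observed high BMI-CRP map correlation regime).
#' @param regional_params Optional list overriding the regional-map
#'   hyperparameters (see Details in the methods vignette).
#' @param spatial_kernel_length Squared-exponential kernel scale in chordal
#'   distance on the unit sphere (>= 0; 0 = spatially independent noise).
#' @param n_cortical,n_subcortical Region counts (defaults 180 and 7).
#' @param mcar_rate Completely-at-random missingness rate for regional cells.
#' @param seed Integer master seed; all generator randomness derives from it.
#'
#' @return An object of class `brainpath_config`.
#' @examples
#' cfg <- generator_config(n_participants = 500, seed = 1)
#' cfg$struct_coeffs
#' @export
generator_config <- function(n_participants = NULL,
                             variant = c("mri", "ukb"),
                             struct_coeffs = NULL,
                             residual_sds = NULL,
                             marginal_calibration = NULL,
                             covariate_effects = NULL,
                             regional_effects = NULL,
                             regional_params = NULL,
                             spatial_kernel_length = 0.3,
                             n_cortical = 180,
                             n_subcortical = 7,
                             mcar_rate = 0,
                             seed = 1L) {
  variant <- match.arg(variant)

  defaults <- bp_variant_defaults(variant)
  if (is.null(n_participants)) n_participants <- defaults$n
  if (is.null(struct_coeffs)) struct_coeffs <- defaults$coeffs
  cal <- utils::modifyList(defaults$marginals, as.list(marginal_calibration %||% list()))

  cov_def <- list(
    cm     = c(),
    bmi    = c(age = 0.10, sex = -0.05),
    at     = c(ses = 0.10),
    crp    = c(age = 0.10, sex = 0.08),
    region = c(age = -0.20, site2 = 0.05, site3 = -0.05)
  )
  cov_eff <- utils::modifyList(cov_def, as.list(covariate_effects %||% list()))
  cov_eff <- Filter(length, cov_eff)

  rp_def <- list(
    map_sd = 0.04, mix_noise = 0.3, w3 = -0.4, map_sd3 = 0.008,
    sub_c1 = 0.02, sub_c2 = -0.025, sub_c3 = -0.03, sub_jitter = 0.005,
    cortical_mean = 2.6, cortical_sd = 0.16,
    subcortical_mean = 5000, subcortical_sd = 450
  )
  rp <- utils::modifyList(rp_def, as.list(regional_params %||% list()))

  ## -- validation -----------------------------------------------------------
  if (!is.numeric(n_participants) || n_participants < 10)
    stop("n_participants must be >= 10", call. = FALSE)
  need <- c("a1", "a2", "a3", "b1", "b2")
  if (!all(need %in% names(struct_coeffs)))
    stop("struct_coeffs must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  struct_coeffs <- struct_coeffs[need]
  if (spatial_kernel_length < 0)
    stop("spatial_kernel_length must be >= 0", call. = FALSE)
  if (mcar_rate < 0 || mcar_rate > 1)
    stop("mcar_rate must be in [0, 1]", call. = FALSE)
  if (n_cortical < 2) stop("n_cortical must be >= 2", call. = FALSE)
  for (v in c("bmi", "crp", "cm", "at", "age", "ses")) {
    if (cal[[v]][2] <= 0)
      stop("marginal calibration for '", v, "' has non-positive SD: ",
           "configuration not invertible", call. = FALSE)
  }
  if (!is.null(residual_sds)) {
    if (!all(c("bmi", "at", "crp") %in% names(residual_sds)))
      stop("residual_sds must name bmi, at and crp", call. = FALSE)
    if (any(residual_sds < 0))
      stop("residual SDs must be >= 0", call. = FALSE)
  }
  if (!is.null(regional_effects)) {
    m <- n_cortical + n_subcortical
    for (ci in c("c1", "c2", "c3")) {
      if (length(regional_effects[[ci]]) == 1L)
        regional_effects[[ci]] <- rep(regional_effects[[ci]], m)
      if (length(regional_effects[[ci]]) != m)
        stop("regional_effects$", ci, " must have length 1 or ", m,
             call. = FALSE)
    }
  }

  ## -- derived calibration --------------------------------------------------
  a <- struct_coeffs
  if (is.null(residual_sds)) {
    v_bmi <- 1 - a["a1"]^2
    v_at  <- 1 - a["a3"]^2
    rho_ba <- a["a1"] * a["a3"]
    expl <- a["a2"]^2 + a["b1"]^2 + a["b2"]^2 +
      2 * (a["a2"] * a["b1"] * a["a1"] + a["a2"] * a["b2"] * a["a3"] +
             a["b1"] * a["b2"] * rho_ba)
    v_crp <- 1 - expl
    if (v_bmi < 0 || v_at < 0 || v_crp < 0)
      stop("struct_coeffs imply explained variance > 1; ",
           "supply residual_sds explicitly", call. = FALSE)
    residual_sds <- c(bmi = sqrt(unname(v_bmi)), at = sqrt(unname(v_at)),
                      crp = sqrt(unname(v_crp)))
  }

  cm_map <- bp_calibrate_count_map(cal$cm[1], cal$cm[2], cap = 25)

  lognorm <- list(
    bmi = bp_lognormal_params(cal$bmi[1], cal$bmi[2]),
    crp = bp_lognormal_params(cal$crp[1], cal$crp[2]),
    at  = bp_lognormal_params(cal$at[1], cal$at[2])
  )

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    variant = variant,
    struct_coeffs = struct_coeffs,
    residual_sds = residual_sds,
    marginal_calibration = cal,
    covariate_effects = cov_eff,
    regional_effects = regional_effects,
    regional_params = rp,
    spatial_kernel_length = spatial_kernel_length,
    n_cortical = as.integer(n_cortical),
    n_subcortical = as.integer(n_subcortical),
    mcar_rate = mcar_rate,
    seed = as.integer(seed),
    cm_map = cm_map,
    lognormal = lognorm
  ), class = "brainpath_config")
  cfg$hash <- bp_hash(cfg)
  cfg
}

## Variant-specific defaults: sample size, structural coefficients and raw
## marginal targets for the imaging subsample vs the full-cohort replication.
bp_variant_defaults <- function(variant) {
  if (variant == "mri") {
    list(
      n = 21738L,
      coeffs = c(a1 = 0.072, a2 = 0.008, a3 = 0.315, b1 = 0.434, b2 = 0.019),
      marginals = list(
        bmi = c(26.5, 4.2), crp = c(2.03, 3.53),
        cm = c(1.70, 2.31), at = c(1.93, 2.37),
        age = c(55, 7), ses = c(-1.94, 2.69),
        sex_p = 0.54, site_probs = c(0.5, 0.3, 0.2)
      )
    )
  } else {
    list(
      n = 116887L,
      coeffs = c(a1 = 0.072, a2 = 0.0095, a3 = 0.315, b1 = 0.434, b2 = 0.019),
      marginals = list(
        bmi = c(26.8, 4.6), crp = c(2.29, 4.02),
        cm = c(1.76, 2.41), at = c(2.09, 2.51),
        age = c(56, 8), ses = c(-1.68, 2.85),
        sex_p = 0.56, site_probs = c(0.5, 0.3, 0.2)
      )
    )
  }
}

#' Lognormal parameters matching a raw-scale mean and SD
#'
#' Solves `meanlog`/`sdlog` so that `exp(meanlog + sdlog * Z)` has the target
#' moments for standard-normal `Z`.
#' @param mean,sd Target raw-scale mean (> 0) and SD (> 0).
#' @return Named vector `c(meanlog, sdlog)`.
#' @keywords internal
bp_lognormal_params <- function(mean, sd) {
  if (sd <= 0 || mean <= 0)
    stop("lognormal calibration requires positive mean and SD", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Zero-inflated lognormal-to-count map for questionnaire sum scores:
##   count(z) = min(cap, round(expm1(max(0, mu + sigma * z)))),  z ~ N(0,1).
## The ramp at zero produces the zero inflation; (mu, sigma) are solved by
## quadrature so the count matches the target raw mean/SD.
bp_calibrate_count_map <- function(mean, sd, cap = 25) {
  z <- seq(-6, 6, length.out = 4001)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  moments <- function(mu, sigma) {
    cnt <- bp_count_map(z, mu, sigma, cap)
    m <- sum(w * cnt)
    c(m = m, s = sqrt(max(sum(w * cnt^2) - m^2, 0)))
  }
  obj <- function(par) {
    mo <- moments(par[1], exp(par[2]))
    (mo["m"] - mean)^2 + (mo["s"] - sd)^2
  }
  fit <- stats::optim(c(0, log(1.3)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  mo <- moments(mu, sigma)
  if (abs(mo["m"] - mean) > 0.05 * sd || abs(mo["s"] - sd) > 0.1 * sd)
    stop("count-map calibration failed for mean=", mean, " sd=", sd,
         call. = FALSE)
  lp <- log1p(bp_count_map(z, mu, sigma, cap))
  m0 <- sum(w * lp)
  s0 <- sqrt(sum(w * lp^2) - m0^2)
  list(mu = mu, sigma = sigma, cap = cap,
       log1p_mean = m0, log1p_sd = s0,
       raw_mean = unname(mo["m"]), raw_sd = unname(mo["s"]))
}

bp_count_map <- function(z, mu, sigma, cap) {
  pmin(cap, round(expm1(pmax(0, mu + sigma * z))))
}

## Standardized log1p score implied by the count map for latent z.
bp_cm_analysis_scale <- function(count, cm_map) {
  (log1p(count) - cm_map$log1p_mean) / cm_map$log1p_sd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Small deterministic content hash (djb2 over the serialized text); used to
## stamp outputs with the provenance of the generating configuration.
bp_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 12,
                                               list.len = 1000)),
               collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.brainpath_config <- function(x, ...) {
  cat("<brainpath_config>", x$variant, "variant, n =", x$n_participants,
      ", seed =", x$seed, "\n")
  cat("  structural coefficients:",
      paste(names(x$struct_coeffs), signif(x$struct_coeffs, 4),
            sep = "=", collapse = ", "), "\n")
  cat("  regions:", x$n_cortical, "cortical +", x$n_subcortical,
      "subcortical; kernel length", x$spatial_kernel_length, "\n")
  cat("  hash:", x$hash, "\n")
  invisible(x)
}
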