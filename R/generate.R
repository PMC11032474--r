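#' Generate a synthetic phenotype cohort
#'
#' Draws one cohort from the structural population described by a
#' [generator_config()]: an integer childhood-maltreatment (CM) sum score with
#' a zero-inflated right-skewed marginal, and adult trauma (AT), BMI and CRP
#' generated on the standardized log scale from the recursive linear model
#' \eqn{BMI = a1\,CM + e}, \eqn{AT = a3\,CM + e},
#' \eqn{CRP = a2\,CM + b1\,BMI + b2\,AT + e}, then mapped to the raw scale by
#' inverting the log transform. Nuisance-covariate effects (age, sex,
#' age-by-sex, SES, site) are injected on the log scale before
#' exponentiation. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()] object.
#' @return A `data.frame` (class `brainpath_cohort`) with columns `id`,
#'   `cm_score`, `at_score`, `bmi`, `crp`, `age`, `sex` (1 = female), `ses`,
#'   `site`. The standardized structural latents are attached as
#'   `attr(, "latents")` for diagnostics; the seed and configuration hash are
#'   attached as attributes and embedded in file headers on write.
#' @examples
#' coh <- generate_cohort(generator_config(n_participants = 200, seed = 7))
#' head(coh)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "brainpath_config"))
  n <- config$n_participants
  cal <- config$marginal_calibration
  a <- config$struct_coeffs
  rs <- config$residual_sds

  withr::with_seed(config$seed, {
    age <- bp_rtruncnorm(n, cal$age[1], cal$age[2], 40, 70)
    ses <- bp_rtruncnorm(n, cal$ses[1], cal$ses[2], -6, 10)
    sex <- stats::rbinom(n, 1, cal$sex_p)
    site <- sample(paste0("site", seq_along(cal$site_probs)), n,
                   replace = TRUE, prob = cal$site_probs)

    C <- bp_covariate_columns(age, sex, ses, site, cal)

    z_cm <- stats::rnorm(n)
    z_cm <- bp_mix_covariates(z_cm, C, config$covariate_effects$cm)
    cm_score <- bp_count_map(z_cm, config$cm_map$mu, config$cm_map$sigma,
                             config$cm_map$cap)
    cm_a <- bp_cm_analysis_scale(cm_score, config$cm_map)

    u_bmi <- a["a1"] * cm_a + rs["bmi"] * stats::rnorm(n)
    u_at  <- a["a3"] * cm_a + rs["at"] * stats::rnorm(n)
    u_crp <- a["a2"] * cm_a + a["b1"] * u_bmi + a["b2"] * u_at +
      rs["crp"] * stats::rnorm(n)

    z_bmi <- bp_mix_covariates(u_bmi, C, config$covariate_effects$bmi)
    z_at  <- bp_mix_covariates(u_at,  C, config$covariate_effects$at)
    z_crp <- bp_mix_covariates(u_crp, C, config$covariate_effects$crp)

    ln <- config$lognormal
    out <- data.frame(
      id = sprintf("P%06d", seq_len(n)),
      cm_score = as.numeric(cm_score),
      at_score = exp(ln$at["meanlog"] + ln$at["sdlog"] * z_at),
      bmi = exp(ln$bmi["meanlog"] + ln$bmi["sdlog"] * z_bmi),
      crp = exp(ln$crp["meanlog"] + ln$crp["sdlog"] * z_crp),
      age = age, sex = sex, ses = ses, site = site,
      stringsAsFactors = FALSE
    )
    attr(out, "latents") <- data.frame(cm = as.numeric(cm_a),
                                       bmi = as.numeric(u_bmi),
                                       at = as.numeric(u_at),
                                       crp = as.numeric(u_crp))
    attr(out, "covariate_columns") <- C
    attr(out, "seed") <- config$seed
    attr(out, "config_hash") <- config$hash
    class(out) <- c("brainpath_cohort", "data.frame")
    out
  })
}

## Truncated normal via inverse-CDF (exact, vectorized).
bp_rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

## Standardized nuisance columns shared by all generated variables.
bp_covariate_columns <- function(age, sex, ses, site, cal) {
  age_z <- (age - cal$age[1]) / cal$age[2]
  sex_c <- sex - cal$sex_p
  ses_z <- (ses - cal$ses[1]) / cal$ses[2]
  C <- cbind(age = age_z, sex = sex_c, age_sex = age_z * sex_c, ses = ses_z)
  lev <- paste0("site", seq_along(cal$site_probs))
  for (k in seq_along(lev)[-1]) {
    C <- cbind(C, (site == lev[k]) - cal$site_probs[k])
    colnames(C)[ncol(C)] <- lev[k]
  }
  C
}

## z* = sqrt(1 - var(gamma'C)) * u + gamma'C : covariate effects enter the
## log scale while preserving (approximately) unit total variance, so the
## lognormal marginal calibration stays on target.
bp_mix_covariates <- function(u, C, gamma) {
  if (is.null(gamma) || length(gamma) == 0) return(u)
  bad <- setdiff(names(gamma), colnames(C))
  if (length(bad))
    stop("unknown covariate effect name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  part <- as.numeric(C[, names(gamma), drop = FALSE] %*% gamma)
  v <- stats::var(part)
  if (v >= 1)
    stop("covariate effects explain >= 100% of a latent's variance",
         call. = FALSE)
  sqrt(1 - v) * u + part
}

#' Generate parcel geometry on the unit sphere
#'
#' Places `n_cortical` parcel centroids quasi-uniformly on the unit sphere
#' with a Fibonacci lattice (a stand-in for a symmetrized single-hemisphere
#' cortical parcellation) and appends `n_subcortical` named subcortical
#' structures that carry no centroid and are exempt from spin tests.
#' Deterministic; uses no random numbers.
#'
#' @param config A [generator_config()] object.
#' @return A `data.frame` (class `brainpath_geometry`) with columns
#'   `region_id`, `structure_class` (`"cortical"`/`"subcortical"`),
#'   `hemisphere_merged`, `spin_eligible` and unit-norm centroid coordinates
#'   `x`, `y`, `z` (NA for subcortical rows).
#' @export
generate_geometry <- function(config) {
  stopifnot(inherits(config, "brainpath_config"))
  nc <- config$n_cortical
  ns <- config$n_subcortical
  i <- seq_len(nc) - 1
  zc <- 1 - (2 * i + 1) / nc
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - zc^2))
  sub_names <- c("thalamus", "caudate", "putamen", "pallidum",
                 "hippocampus", "amygdala", "accumbens")
  sub_ids <- if (ns <= length(sub_names)) sub_names[seq_len(ns)] else
    c(sub_names, sprintf("sub%02d", seq_len(ns - length(sub_names))))
  out <- data.frame(
    region_id = c(sprintf("ctx%03d", seq_len(nc)), sub_ids),
    structure_class = rep(c("cortical", "subcortical"), c(nc, ns)),
    hemisphere_merged = TRUE,
    spin_eligible = rep(c(TRUE, FALSE), c(nc, ns)),
    x = c(r * cos(phi), rep(NA_real_, ns)),
    y = c(r * sin(phi), rep(NA_real_, ns)),
    z = c(zc, rep(NA_real_, ns)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("brainpath_geometry", "data.frame")
  out
}

#' Generate a participants-by-regions brain measurement matrix
#'
#' Each region's standardized value is
#' \eqn{c_1 BMI + c_2 CRP + c_3 AT + \epsilon}, where the per-region effect
#' maps (`c1`, `c2`, `c3`) and the noise field \eqn{\epsilon} are smooth over
#' cortical centroids under a squared-exponential kernel in chordal distance
#' (scale `config$spatial_kernel_length`; 0 gives independent noise), and
#' subcortical noise is independent. `c1` and `c2` default to two noisy
#' copies of one shared smooth map. Values are mapped to thickness-like
#' (cortical) or volume-like (subcortical) raw units. Deterministic given the
#' configuration seed.
#'
#' @param phenotypes A cohort from [generate_cohort()] (its structural
#'   latents drive the regional effects).
#' @param geometry A [generate_geometry()] table from the same config.
#' @param config The shared [generator_config()].
#' @return A numeric matrix (class `brainpath_regional`), participants in
#'   rows, regions in columns, with `NA` for masked cells and the geometry,
#'   effect maps, seed and config hash as attributes.
#' @export
generate_brain <- function(phenotypes, geometry, config) {
  stopifnot(inherits(config, "brainpath_config"),
            inherits(geometry, "brainpath_geometry"))
  lat <- attr(phenotypes, "latents")
  if (is.null(lat))
    stop("phenotypes must come from generate_cohort() (missing latents)",
         call. = FALSE)
  n <- nrow(phenotypes)
  if (nrow(lat) != n)
    stop("mismatched participant counts between phenotypes and latents",
         call. = FALSE)
  nc <- sum(geometry$structure_class == "cortical")
  ns <- sum(geometry$structure_class == "subcortical")
  if (nc != config$n_cortical || ns != config$n_subcortical)
    stop("geometry region counts do not match config", call. = FALSE)
  m <- nc + ns
  rp <- config$regional_params

  cent <- as.matrix(geometry[geometry$structure_class == "cortical",
                             c("x", "y", "z")])
  Kc <- bp_sphere_kernel(cent, config$spatial_kernel_length)
  L <- chol(Kc)

  withr::with_seed(config$seed + 1L, {
    eff <- config$regional_effects
    if (is.null(eff)) {
      base <- as.numeric(crossprod(L, stats::rnorm(nc)))
      m3 <- as.numeric(crossprod(L, stats::rnorm(nc)))
      c1 <- rp$map_sd * base + rp$map_sd * rp$mix_noise * stats::rnorm(nc)
      c2 <- rp$map_sd * base + rp$map_sd * rp$mix_noise * stats::rnorm(nc)
      c3 <- rp$map_sd3 * (rp$w3 * base + sqrt(1 - rp$w3^2) * m3)
      eff <- list(
        c1 = c(c1, rp$sub_c1 + rp$sub_jitter * stats::rnorm(ns)),
        c2 = c(c2, rp$sub_c2 + rp$sub_jitter * stats::rnorm(ns)),
        c3 = c(c3, rp$sub_c3 + rp$sub_jitter * stats::rnorm(ns))
      )
    }

    X <- cbind(lat$bmi, lat$crp, lat$at)
    Cmat <- rbind(eff$c1, eff$c2, eff$c3)      # 3 x m
    struct <- X %*% Cmat                        # n x m
    S3 <- stats::cov(X)
    var_struct <- colSums(Cmat * (S3 %*% Cmat))
    noise_sd <- sqrt(pmax(1 - var_struct, 0.05))

    noise <- matrix(stats::rnorm(n * m), n, m)
    if (nc > 0) noise[, seq_len(nc)] <- noise[, seq_len(nc)] %*% L
    noise <- sweep(noise, 2, noise_sd, `*`)

    C <- attr(phenotypes, "covariate_columns")
    covpart <- 0
    gamma <- config$covariate_effects$region
    if (!is.null(gamma) && length(gamma) > 0 && !is.null(C))
      covpart <- as.numeric(C[, names(gamma), drop = FALSE] %*% gamma)

    zmat <- struct + covpart + noise
    mu <- rep(c(rp$cortical_mean, rp$subcortical_mean), c(nc, ns))
    sdv <- rep(c(rp$cortical_sd, rp$subcortical_sd), c(nc, ns))
    out <- sweep(sweep(zmat, 2, sdv, `*`), 2, mu, `+`)

    if (config$mcar_rate > 0) {
      mask <- stats::runif(n * m) < config$mcar_rate
      out[mask] <- NA_real_
    }
    dimnames(out) <- list(phenotypes$id, geometry$region_id)
    attr(out, "geometry") <- geometry
    attr(out, "effect_maps") <- eff
    attr(out, "seed") <- config$seed
    attr(out, "config_hash") <- config$hash
    class(out) <- c("brainpath_regional", class(out))
    out
  })
}

## Squared-exponential kernel in chordal (straight-line) distance between
## unit-sphere centroids; length 0 degenerates to independent regions.
bp_sphere_kernel <- function(cent, len, jitter = 1e-8) {
  n <- nrow(cent)
  if (len <= 0) return(diag(n))
  G <- tcrossprod(cent)
  d2 <- pmax(0, outer(rep(1, n), rep(1, n)) * 2 - 2 * G)
  K <- exp(-d2 / (2 * len^2))
  K + diag(jitter, n)
}

#' Plant detectable outliers into a regional matrix
#'
#' Displaces randomly chosen cells to `median +/- magnitude * MAD` of their
#' region (raw MAD, no consistency constant), providing ground truth for the
#' 5-MAD exclusion filter.
#'
#' @param matrix A `brainpath_regional` matrix (or plain numeric matrix).
#' @param rate Fraction of cells to displace, in `[0, 1]`.
#' @param magnitude Displacement in MAD multiples; must exceed 5, otherwise
#'   the planted outliers would be undetectable by design.
#' @param seed Integer seed for cell selection and displacement signs.
#' @return A list with elements `matrix` (the contaminated copy) and
#'   `planted` (a data.frame of `row`, `col` indices).
#' @export
inject_outliers <- function(matrix, rate, magnitude, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (magnitude <= 5)
    stop("magnitude must exceed 5 (a smaller displacement would be ",
         "undetectable by the 5-MAD filter)", call. = FALSE)
  ncell <- length(matrix)
  k <- round(rate * ncell)
  if (k == 0)
    return(list(matrix = matrix, planted = data.frame(row = integer(),
                                                      col = integer())))
  withr::with_seed(seed, {
    ok <- which(!is.na(matrix))
    cells <- sample(ok, min(k, length(ok)))
    sgn <- sample(c(-1, 1), length(cells), replace = TRUE)
    rows <- ((cells - 1) %% nrow(matrix)) + 1
    cols <- ((cells - 1) %/% nrow(matrix)) + 1
    for (j in unique(cols)) {
      v <- matrix[, j]
      med <- stats::median(v, na.rm = TRUE)
      mad0 <- stats::median(abs(v - med), na.rm = TRUE)
      sel <- cols == j
      matrix[cbind(rows[sel], j)] <- med + sgn[sel] * magnitude * mad0
    }
    list(matrix = matrix,
         planted = data.frame(row = rows, col = cols))
  })
}
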