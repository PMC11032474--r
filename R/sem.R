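#' Model-implied covariance matrix
#'
#' For a recursive path model with path matrix `B` and diagonal variance
#' matrix `Psi` (exogenous variances plus residual variances),
#' \deqn{\Sigma(\theta) = (I - B)^{-1} \Psi (I - B)^{-T}.}
#'
#' @param model A [path_model()].
#' @param theta Named parameter vector: one element per edge label followed
#'   by one variance `v_<name>` per variable (any order; matched by name).
#' @return Symmetric covariance matrix with variable dimnames.
#' @examples
#' m <- path_model("y <- x : a", variables = c("x", "y"))
#' implied_covariance(m, c(a = 0.5, v_x = 1, v_y = 0.75))
#' @export
implied_covariance <- function(model, theta) {
  stopifnot(inherits(model, "brainpath_model"))
  pn <- bp_param_names(model)
  if (!all(pn %in% names(theta)))
    stop("theta must name all free parameters: ",
         paste(setdiff(pn, names(theta)), collapse = ", "), call. = FALSE)
  theta <- theta[pn]
  p <- length(model$vars)
  B <- matrix(0, p, p, dimnames = list(model$vars, model$vars))
  if (nrow(model$edges))
    B[cbind(model$edges$to, model$edges$from)] <- theta[model$edges$label]
  A <- solve(diag(p) - B)     # invertible for any acyclic B
  Psi <- diag(theta[paste0("v_", model$vars)], p)
  Sigma <- A %*% Psi %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(model$vars, model$vars)
  Sigma
}

bp_param_names <- function(model) {
  c(model$edges$label, paste0("v_", model$vars))
}

#' Sample moments for path-model estimation
#'
#' @param data Numeric matrix or data.frame of observed variables.
#' @param standardize If `TRUE` the covariance is replaced by the
#'   correlation matrix, so fitted path coefficients are standardized.
#' @return List of class `brainpath_moments` with elements `S`, `n`, `means`.
#' @export
sample_moments <- function(data, standardize = FALSE) {
  X <- as.matrix(data)
  S <- stats::cov(X)
  if (standardize) S <- stats::cov2cor(S)
  structure(list(S = S, n = nrow(X), means = colMeans(X),
                 vars = colnames(X)),
            class = "brainpath_moments")
}

## vech (column-major lower triangle incl. diagonal) and its duplication
## matrix; p is at most 6 here so dense construction is fine.
bp_vech <- function(M) M[lower.tri(M, diag = TRUE)]

bp_duplication <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  D <- matrix(0, p * p, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

## Derivatives of Sigma wrt each free parameter, as a list of p x p matrices.
bp_dSigma <- function(model, theta) {
  p <- length(model$vars)
  B <- matrix(0, p, p, dimnames = list(model$vars, model$vars))
  if (nrow(model$edges))
    B[cbind(model$edges$to, model$edges$from)] <- theta[model$edges$label]
  A <- solve(diag(p) - B)
  Psi <- diag(theta[paste0("v_", model$vars)], p)
  Sigma <- A %*% Psi %*% t(A)
  out <- vector("list", nrow(model$edges) + p)
  names(out) <- bp_param_names(model)
  for (k in seq_len(nrow(model$edges))) {
    i <- match(model$edges$to[k], model$vars)
    j <- match(model$edges$from[k], model$vars)
    M <- A[, i, drop = FALSE] %*% Sigma[j, , drop = FALSE]  # A E_ij Sigma
    out[[k]] <- M + t(M)
  }
  for (k in seq_len(p)) {
    Ak <- A[, k, drop = FALSE]
    out[[nrow(model$edges) + k]] <- Ak %*% t(Ak)
  }
  out
}

bp_F_ml <- function(S, Sigma, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  logdet + sum(diag(chol2inv(ch) %*% S)) - logdetS - nrow(S)
}

#' Fit a recursive path model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' \deqn{F_{ML}(\theta) = \ln|\Sigma(\theta)| + tr(S\,\Sigma(\theta)^{-1})
#'  - \ln|S| - p}
#' by quasi-Newton iteration with analytic gradient, warm-started at the
#' per-equation least-squares solution (which is exact for this model class,
#' so iteration counts are typically zero or one). Naive (normal-theory)
#' standard errors come from the inverse Fisher information; call
#' [robust_errors()] to add sandwich errors and the scaled test statistic.
#'
#' @param model A [path_model()].
#' @param moments A [sample_moments()] object (S positive definite, n greater
#'   than the number of variables).
#' @param grad_tol Gradient-norm target (default 1e-10).
#' @param max_iter Maximum quasi-Newton iterations (default 500).
#' @return An object of class `brainpath_fit`; see [parameter_table()].
#' @export
fit_path_model <- function(model, moments, grad_tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(model, "brainpath_model"),
            inherits(moments, "brainpath_moments"))
  vars <- model$vars
  if (!all(vars %in% colnames(moments$S)))
    stop("moments lack model variable(s): ",
         paste(setdiff(vars, colnames(moments$S)), collapse = ", "),
         call. = FALSE)
  S <- moments$S[vars, vars]
  n <- moments$n
  p <- length(vars)
  if (n <= p) stop("sample size must exceed the number of variables",
                   call. = FALSE)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance matrix is not positive definite", call. = FALSE))
  logdetS <- 2 * sum(log(diag(chS)))

  ## exact warm start: per-equation least squares in topological order
  theta0 <- numeric(0)
  for (v in vars) {
    par <- model$edges$from[model$edges$to == v]
    if (length(par) == 0) {
      theta0[paste0("v_", v)] <- S[v, v]
    } else {
      beta <- solve(S[par, par, drop = FALSE], S[par, v])
      lab <- model$edges$label[model$edges$to == v]
      theta0[lab] <- beta
      theta0[paste0("v_", v)] <- S[v, v] - sum(S[v, par] * beta)
    }
  }
  theta0 <- theta0[bp_param_names(model)]

  fn <- function(th) {
    names(th) <- names(theta0)
    bp_F_ml(S, implied_covariance(model, th), logdetS)
  }
  gr <- function(th) {
    names(th) <- names(theta0)
    Sigma <- implied_covariance(model, th)
    Sinv <- chol2inv(chol(Sigma))
    W <- Sinv - Sinv %*% S %*% Sinv
    vapply(bp_dSigma(model, th), function(dS) sum(W * dS), numeric(1))
  }

  g0 <- gr(theta0)
  iter <- 0L
  theta <- theta0
  if (sqrt(sum(g0^2)) > grad_tol) {
    opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
    theta <- opt$par
    names(theta) <- names(theta0)
    iter <- opt$counts[["function"]]
  }
  gfin <- gr(theta)
  gnorm <- sqrt(sum(gfin^2))
  if (!is.finite(gnorm) || gnorm > 1e-6)
    stop("path model estimation did not converge (gradient norm ",
         format(gnorm), " after ", iter, " evaluations)", call. = FALSE)

  Sigma <- implied_covariance(model, theta)
  Fmin <- max(0, bp_F_ml(S, Sigma, logdetS))
  npar <- length(theta)
  df <- p * (p + 1) / 2 - npar
  Tml <- (n - 1) * Fmin
  if (df == 0) { Fmin <- 0; Tml <- 0 }

  ## normal-theory information: Delta' V Delta with V the ML weight matrix
  dS <- bp_dSigma(model, theta)
  Delta <- vapply(dS, bp_vech, numeric(p * (p + 1) / 2))
  D <- bp_duplication(p)
  Sinv <- chol2inv(chol(Sigma))
  V <- 0.5 * t(D) %*% (Sinv %x% Sinv) %*% D
  AtVA <- crossprod(Delta, V %*% Delta)
  acov_naive <- solve(AtVA) / (n - 1)
  se_naive <- sqrt(pmax(diag(acov_naive), 0))
  names(se_naive) <- names(theta)

  structure(list(
    model = model, estimates = theta, se_naive = se_naive,
    acov_naive = acov_naive, Sigma = Sigma, S = S, n = n,
    F_min = Fmin, T_ml = Tml, df = df,
    converged = TRUE, iterations = iter, grad_norm = gnorm,
    Delta = Delta, V = V,
    robust = FALSE, se_robust = NULL, acov_robust = NULL,
    T_sb = NA_real_, scaling = NA_real_, z = NULL, p_value = NULL
  ), class = "brainpath_fit")
}

#' Add Huber-White (sandwich) errors and the scaled test statistic
#'
#' Computes the empirical fourth-moment matrix \eqn{\Gamma} (the asymptotic
#' covariance of the unique elements of S) from per-row data, the sandwich
#' covariance of the estimates, Wald z statistics (estimate / robust SE) with
#' two-sided normal p-values, and the mean-scaled (Satorra-Bentler) test
#' statistic \eqn{T_{SB} = T_{ML}/c} with \eqn{c = tr(U\Gamma)/df} for the
#' standard residual weight matrix \eqn{U}.
#'
#' @param fit A converged [fit_path_model()] result.
#' @param data Per-row data for the model variables (moments alone are not
#'   sufficient for \eqn{\Gamma}). If the fit used a correlation matrix,
#'   supply the standardized data.
#' @return The fit, augmented with `se_robust`, `acov_robust`, `z`,
#'   `p_value`, `T_sb` and `scaling`.
#' @export
robust_errors <- function(fit, data) {
  stopifnot(inherits(fit, "brainpath_fit"))
  vars <- fit$model$vars
  X <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  if (nrow(X) != fit$n)
    stop("data rows do not match the fitted sample size", call. = FALSE)
  n <- fit$n
  p <- length(vars)
  xc <- sweep(X, 2, colMeans(X))
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Dmat <- xc[, idx[, 1], drop = FALSE] * xc[, idx[, 2], drop = FALSE]
  Dc <- sweep(Dmat, 2, colMeans(Dmat))
  Gamma <- crossprod(Dc) / n

  Delta <- fit$Delta; V <- fit$V
  AtVA <- crossprod(Delta, V %*% Delta)
  Ainv <- solve(AtVA)
  mid <- crossprod(Delta, V %*% Gamma %*% V %*% Delta)
  acov_rob <- Ainv %*% mid %*% Ainv / (n - 1)
  se_rob <- sqrt(pmax(diag(acov_rob), 0))
  names(se_rob) <- names(fit$estimates)

  if (fit$df == 0) {
    warning("saturated model: scaling undefined, reporting T_sb = 0, c = 1")
    cfac <- 1
    Tsb <- 0
  } else {
    U <- V - V %*% Delta %*% Ainv %*% t(Delta) %*% V
    cfac <- sum(U * Gamma) / fit$df     # tr(U Gamma), both symmetric
    Tsb <- fit$T_ml / cfac
  }
  z <- ifelse(se_rob > 0, fit$estimates / se_rob, 0)
  fit$se_robust <- se_rob
  fit$acov_robust <- acov_rob
  fit$Gamma <- Gamma
  fit$z <- z
  fit$p_value <- 2 * stats::pnorm(-abs(z))
  fit$T_sb <- Tsb
  fit$scaling <- cfac
  fit$robust <- TRUE
  fit
}

#' Convenience wrapper: fit with robust errors from raw data
#'
#' Standardizes the data columns (so coefficients are standardized betas,
#' i.e. the model is fit to the correlation matrix), fits the model and adds
#' sandwich errors.
#'
#' @param model A [path_model()].
#' @param data data.frame or matrix holding the model variables.
#' @param standardize Fit to the correlation matrix (default `TRUE`).
#' @param robust Add sandwich errors and scaled statistic (default `TRUE`).
#' @return A `brainpath_fit`.
#' @export
fit_sem <- function(model, data, standardize = TRUE, robust = TRUE) {
  X <- as.matrix(as.data.frame(data)[, model$vars, drop = FALSE])
  if (standardize) X <- scale(X)
  fit <- fit_path_model(model, sample_moments(X))
  if (robust) fit <- robust_errors(fit, X)
  fit
}

#' Parameter table of a fitted path model
#'
#' @param fit A `brainpath_fit`.
#' @return data.frame with one row per free parameter: label, type, from/to,
#'   estimate, naive SE, robust SE, Wald z and two-sided p (robust columns
#'   are `NA` until [robust_errors()] has been applied).
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "brainpath_fit"))
  ne <- nrow(fit$model$edges)
  lab <- names(fit$estimates)
  data.frame(
    parameter = lab,
    type = rep(c("path", "variance"), c(ne, length(lab) - ne)),
    from = c(fit$model$edges$from, rep(NA, length(lab) - ne)),
    to = c(fit$model$edges$to, sub("^v_", "", lab[-seq_len(ne)])),
    estimate = unname(fit$estimates),
    se_naive = unname(fit$se_naive),
    se_robust = if (fit$robust) unname(fit$se_robust) else NA_real_,
    z = if (fit$robust) unname(fit$z) else NA_real_,
    p = if (fit$robust) unname(fit$p_value) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @export
print.brainpath_fit <- function(x, digits = 4, ...) {
  cat("<brainpath_fit>", x$model$label, " n =", x$n, " df =", x$df, "\n")
  cat("  F_ml =", signif(x$F_min, digits), " T_ml =", signif(x$T_ml, digits))
  if (x$robust)
    cat("  T_sb =", signif(x$T_sb, digits),
        " scaling c =", signif(x$scaling, digits))
  cat("\n")
  pt <- parameter_table(x)
  pt[, 5:9] <- lapply(pt[, 5:9], function(v) signif(v, digits))
  print(pt, row.names = FALSE)
  invisible(x)
}

#' Fit indices relative to an independence baseline
#'
#' CFI, RMSEA (with a 90% noncentral-chi-square confidence interval) and
#' SRMR, plus robust variants computed by plugging the scaled statistics into
#' the same formulas when both fits carry them. Qualitative bands follow the
#' conventional cutoffs: CFI acceptable 0.95-0.97, good > 0.97; SRMR
#' acceptable 0.05-0.10, good < 0.05; RMSEA acceptable 0.05-0.08,
#' good < 0.05.
#'
#' @param fit A fitted target model.
#' @param baseline The independence model (same variables, no paths) fitted
#'   to the same moments.
#' @return List of class `brainpath_indices`.
#' @export
fit_indices <- function(fit, baseline) {
  stopifnot(inherits(fit, "brainpath_fit"), inherits(baseline, "brainpath_fit"))
  if (!setequal(fit$model$vars, baseline$model$vars) ||
      nrow(baseline$model$edges) != 0)
    stop("baseline must be the independence model on the same variables",
         call. = FALSE)
  n <- fit$n
  cfi_f <- function(T1, df1, T0, df0)
    1 - max(T1 - df1, 0) / max(T0 - df0, T1 - df1, 0, .Machine$double.eps)
  rmsea_f <- function(T1, df1)
    if (df1 == 0) 0 else sqrt(max(T1 - df1, 0) / (df1 * n))

  cfi <- min(1, max(0, cfi_f(fit$T_ml, fit$df, baseline$T_ml, baseline$df)))
  rmsea <- rmsea_f(fit$T_ml, fit$df)
  ci <- bp_rmsea_ci(fit$T_ml, fit$df, n)

  ## SRMR: RMS of standardized residual moments over unique elements
  Sc <- fit$S; Sg <- fit$Sigma
  d <- sqrt(diag(Sc))
  Rz <- (Sc - Sg) / tcrossprod(d)
  srmr <- sqrt(mean(bp_vech(Rz)^2))

  rob <- NULL
  if (fit$robust && baseline$robust && !is.na(fit$T_sb)) {
    rob <- list(
      cfi = min(1, max(0, cfi_f(fit$T_sb, fit$df, baseline$T_sb,
                                baseline$df))),
      rmsea = rmsea_f(fit$T_sb, fit$df),
      rmsea_ci = bp_rmsea_ci(fit$T_sb, fit$df, n)
    )
  }
  band <- function(x, good, acc, larger_is_better) {
    if (larger_is_better) {
      if (x > good) "good" else if (x >= acc) "acceptable" else "poor"
    } else {
      if (x < good) "good" else if (x <= acc) "acceptable" else "poor"
    }
  }
  structure(list(
    cfi = cfi, rmsea = rmsea, rmsea_ci = ci, srmr = srmr, robust = rob,
    bands = c(cfi = band(cfi, 0.97, 0.95, TRUE),
              srmr = band(srmr, 0.05, 0.10, FALSE),
              rmsea = band(rmsea, 0.05, 0.08, FALSE)),
    n = n, T_ml = fit$T_ml, df = fit$df
  ), class = "brainpath_indices")
}

## 90% CI for RMSEA from the noncentral chi-square distribution of T.
bp_rmsea_ci <- function(T1, df1, n, level = 0.90) {
  if (df1 == 0 || !is.finite(T1)) return(c(lower = 0, upper = 0))
  a <- (1 - level) / 2
  ncp_for <- function(target) {
    f <- function(l) stats::pchisq(T1, df1, ncp = l) - target
    if (f(0) < 0) return(0)
    hi <- max(T1 * 2, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lo <- ncp_for(1 - a)
  hi <- ncp_for(a)
  c(lower = sqrt(lo / (df1 * n)), upper = sqrt(hi / (df1 * n)))
}

#' @export
print.brainpath_indices <- function(x, digits = 4, ...) {
  cat("CFI =", signif(x$cfi, digits),
      " RMSEA =", signif(x$rmsea, digits),
      sprintf("[%.4f, %.4f]", x$rmsea_ci[1], x$rmsea_ci[2]),
      " SRMR =", signif(x$srmr, digits), "\n")
  if (!is.null(x$robust))
    cat("robust: CFI =", signif(x$robust$cfi, digits),
        " RMSEA =", signif(x$robust$rmsea, digits), "\n")
  cat("bands:", paste(names(x$bands), x$bands, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Indirect (mediation) effects as products of chained coefficients
#'
#' For each chain of directed edges, the point estimate is the literal
#' product of the component estimates and the standard error comes from the
#' multivariate delta method on the (robust, if available) parameter
#' covariance; for a two-edge chain with independent components this reduces
#' to the Sobel formula \eqn{\sqrt{b^2 SE_a^2 + a^2 SE_b^2}}.
#'
#' @param fit A `brainpath_fit` (robust errors recommended).
#' @param chains List of chains; each chain is either a vector of edge labels
#'   (e.g. `c("a1", "b1")`) or a variable sequence (e.g.
#'   `c("cm", "bmi", "crp")`).
#' @return data.frame with chain label, estimate, SE, Wald z and two-sided p.
#' @export
indirect_effects <- function(fit, chains) {
  stopifnot(inherits(fit, "brainpath_fit"))
  edges <- fit$model$edges
  acov <- fit$acov_robust %||% fit$acov_naive
  one <- function(chain) {
    if (all(chain %in% edges$label) && !all(chain %in% fit$model$vars)) {
      labs <- chain
      for (k in seq_along(labs)[-1]) {
        prev_to <- edges$to[edges$label == labs[k - 1]]
        nxt_from <- edges$from[edges$label == labs[k]]
        if (prev_to != nxt_from)
          stop("chain edges do not form a directed path: ",
               paste(chain, collapse = " -> "), call. = FALSE)
      }
    } else if (all(chain %in% fit$model$vars) && length(chain) >= 2) {
      labs <- character(length(chain) - 1)
      for (k in seq_len(length(chain) - 1)) {
        hit <- edges$label[edges$from == chain[k] & edges$to == chain[k + 1]]
        if (length(hit) != 1)
          stop("no edge ", chain[k], " -> ", chain[k + 1], " in the model",
               call. = FALSE)
        labs[k] <- hit
      }
    } else {
      stop("chain must be edge labels or a variable sequence of the model: ",
           paste(chain, collapse = ", "), call. = FALSE)
    }
    th <- fit$estimates[labs]
    est <- prod(th)
    grad <- vapply(seq_along(th), function(j) prod(th[-j]), numeric(1))
    Vsub <- acov[labs, labs, drop = FALSE]
    se <- sqrt(max(0, as.numeric(t(grad) %*% Vsub %*% grad)))
    z <- if (se > 0) est / se else 0
    data.frame(chain = paste(labs, collapse = "*"),
               estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(chains, one))
  rownames(out) <- NULL
  out
}

#' Scaled likelihood-ratio comparison of nested path models
#'
#' Tests a sparse model against a full model fitted to the same moments with
#' the difference statistic on `k = p1 - p2` degrees of freedom. When both
#' fits carry scaled statistics, the Satorra-Bentler difference correction
#' `cd = (df0*c0 - df1*c1) / (df0 - df1)` is applied; a non-positive `cd`
#' falls back to the unscaled difference with a warning.
#'
#' @param full,sparse `brainpath_fit` objects; `sparse`'s edge set must be a
#'   strict subset of `full`'s.
#' @return List of class `brainpath_lrcomp`: `statistic`, `df`, `p`,
#'   `scaling`, `unscaled`.
#' @export
lr_compare <- function(full, sparse) {
  stopifnot(inherits(full, "brainpath_fit"), inherits(sparse, "brainpath_fit"))
  if (!identical(full$model$vars, sparse$model$vars))
    stop("models are defined over different variables", call. = FALSE)
  key <- function(m) paste(m$edges$from, m$edges$to)
  if (!all(key(sparse$model) %in% key(full$model)))
    stop("sparse model is not nested in the full model", call. = FALSE)
  k <- nrow(full$model$edges) - nrow(sparse$model$edges)
  if (k <= 0)
    stop("degenerate comparison: models have the same number of paths (k = 0)",
         call. = FALSE)
  if (full$n != sparse$n)
    stop("fits are based on different sample sizes", call. = FALSE)
  dT <- max(0, sparse$T_ml - full$T_ml)
  cd <- NA_real_
  stat <- dT
  if (full$robust && sparse$robust &&
      is.finite(full$scaling) && is.finite(sparse$scaling)) {
    cd <- (sparse$df * sparse$scaling - full$df * full$scaling) /
      (sparse$df - full$df)
    if (is.finite(cd) && cd > 0) {
      stat <- dT / cd
    } else {
      warning("non-positive scaled-difference correction; ",
              "falling back to the unscaled statistic")
      cd <- NA_real_
    }
  }
  structure(list(statistic = stat, df = k,
                 p = stats::pchisq(stat, k, lower.tail = FALSE),
                 scaling = cd, unscaled = dT,
                 T_full = full$T_ml, T_sparse = sparse$T_ml),
            class = "brainpath_lrcomp")
}

#' @export
print.brainpath_lrcomp <- function(x, digits = 4, ...) {
  cat("scaled LR difference:", signif(x$statistic, digits),
      "on", x$df, "df, p =", signif(x$p, digits), "\n")
  if (is.finite(x$scaling %||% NA))
    cat("difference scaling cd =", signif(x$scaling, digits), "\n")
  invisible(x)
}
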