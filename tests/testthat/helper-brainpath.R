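# Shared fixtures and independent oracles used across the suite.

# A quick, small configuration; override anything via ...
quick_cfg <- function(n = 500, seed = 1, ...) {
  generator_config(n_participants = n, seed = seed, ...)
}

# Configuration with no covariate effects anywhere (pure structural draws).
plain_cfg <- function(n = 500, seed = 1, ...) {
  generator_config(
    n_participants = n, seed = seed,
    covariate_effects = list(cm = c(), bmi = c(), at = c(), crp = c(),
                             region = c()),
    ...
  )
}

# Direct simulator of the four-variable structural model on the standardized
# scale -- an oracle independent of the package's cohort generator.
sim_h1 <- function(n, a1 = 0.072, a2 = 0.008, a3 = 0.315, b1 = 0.434,
                   b2 = 0.019) {
  cm <- rnorm(n)
  bmi <- a1 * cm + sqrt(1 - a1^2) * rnorm(n)
  at <- a3 * cm + sqrt(1 - a3^2) * rnorm(n)
  v <- a2^2 + b1^2 + b2^2 +
    2 * (a2 * b1 * a1 + a2 * b2 * a3 + b1 * b2 * a1 * a3)
  crp <- a2 * cm + b1 * bmi + b2 * at + sqrt(1 - v) * rnorm(n)
  data.frame(cm = cm, bmi = bmi, at = at, crp = crp)
}

# Simulate a random recursive model: random DAG over p variables (edges only
# from earlier to later in a fixed order), random coefficients, unit noise.
sim_random_recursive <- function(p = 4, n = 400, edge_prob = 0.6) {
  vars <- paste0("v", seq_len(p))
  lines <- character(0)
  for (j in 2:p) {
    for (i in 1:(j - 1)) {
      if (runif(1) < edge_prob)
        lines <- c(lines, paste0(vars[j], " <- ", vars[i]))
    }
  }
  model <- path_model(lines, variables = vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  if (nrow(model$edges))
    B[cbind(model$edges$to, model$edges$from)] <-
      runif(nrow(model$edges), -0.6, 0.6)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
  for (j in seq_len(p))
    X[, j] <- X[, seq_len(j - 1), drop = FALSE] %*% B[j, seq_len(j - 1)] +
      rnorm(n)
  list(model = model, data = as.data.frame(X))
}

# Per-equation least-squares oracle via lm(), independent of the SEM code.
ols_oracle <- function(model, data) {
  out <- numeric(0)
  for (v in model$vars) {
    par <- model$edges$from[model$edges$to == v]
    if (length(par) == 0) next
    fml <- stats::reformulate(par, response = v)
    cf <- coef(lm(fml, data = data))[par]
    names(cf) <- model$edges$label[model$edges$to == v]
    out <- c(out, cf)
  }
  out
}

# Brute-force Moran's I over a k-nearest-neighbour graph on sphere centroids.
moran_i <- function(x, cent, k = 6) {
  n <- length(x)
  D <- as.matrix(dist(cent))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1)]
    W[i, nb] <- 1
  }
  xc <- x - mean(x)
  (n / sum(W)) * sum(W * tcrossprod(xc)) / sum(xc^2)
}

# Naive Spearman with average ranks, from the definition.
naive_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Smooth random cortical map under the package's kernel (for spin tests).
smooth_map <- function(cent, len = 0.4) {
  K <- brainpath:::bp_sphere_kernel(cent, len)
  as.numeric(crossprod(chol(K), rnorm(nrow(cent))))
}
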