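#' Generate spin permutations of a cortical parcellation
#'
#' For each spin a uniformly random 3D rotation (orthonormalized Gaussian
#' matrix with determinant correction) is applied to all cortical centroids,
#' and each rotated centroid is assigned the region of its nearest original
#' centroid (ties broken by lowest region index). The resulting assignments
#' may be non-bijective (duplicates allowed), as is standard for
#' centroid-based spin tests on parcellated maps. Subcortical regions carry
#' no centroid and are exempt.
#'
#' @param geometry A [generate_geometry()] table with cortical centroids.
#' @param n_spins Number of spins (>= 100; default 10000).
#' @param seed Integer seed for the rotation batch.
#' @return Integer matrix `n_spins x n_cortical`; row `s`, column `j` gives
#'   the original region index whose value region `j` receives under spin
#'   `s`. Cortical region ids and the seed are attached as attributes.
#' @export
generate_spins <- function(geometry, n_spins = 10000, seed = 1L) {
  stopifnot(inherits(geometry, "brainpath_geometry") ||
              is.data.frame(geometry))
  cort <- geometry$structure_class == "cortical"
  if (!any(cort))
    stop("spin test undefined: geometry has no cortical centroids",
         call. = FALSE)
  if (n_spins < 100) stop("n_spins must be >= 100", call. = FALSE)
  cent <- as.matrix(geometry[cort, c("x", "y", "z")])
  nc <- nrow(cent)
  out <- matrix(NA_integer_, n_spins, nc)
  withr::with_seed(seed, {
    for (s in seq_len(n_spins)) {
      R <- bp_random_rotation()
      rot <- cent %*% t(R)
      ## nearest original centroid = max inner product on the unit sphere;
      ## max.col with ties.method "first" takes the lowest region index
      out[s, ] <- max.col(rot %*% t(cent), ties.method = "first")
    }
  })
  attr(out, "region_id") <- geometry$region_id[cort]
  attr(out, "seed") <- seed
  out
}

## Uniform (Haar) random rotation: QR of a Gaussian matrix with the sign
## convention R = Q diag(sign(diag(Rq))) and a determinant flip to SO(3).
bp_random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin permutation p-value for a correlation between two cortical maps
#'
#' The observed statistic is computed on the original maps; the null
#' distribution rearranges `map1` by each spin assignment while `map2` stays
#' fixed, and the two-sided p-value is
#' \eqn{p_{spin} = (1 + \#\{|null| \ge |observed|\}) / (S + 1)}.
#'
#' @param map1,map2 Numeric vectors on the spin geometry (cortical regions,
#'   same order as the spin columns).
#' @param spins A [generate_spins()] matrix.
#' @param statistic `"spearman"` (default) or `"pearson"`.
#' @return List of class `brainpath_spin`: `observed`, `null` (length S),
#'   `p_spin`, `n_spins`, `statistic`.
#' @export
spin_pvalue <- function(map1, map2, spins,
                        statistic = c("spearman", "pearson")) {
  statistic <- match.arg(statistic)
  nc <- ncol(spins)
  if (length(map1) != nc || length(map2) != nc)
    stop("map length does not match the spin geometry (", nc, " regions)",
         call. = FALSE)
  observed <- stats::cor(map1, map2, method = statistic)
  perm <- matrix(map1[t(spins)], nrow = nc)   # regions x S
  nulls <- as.numeric(stats::cor(map2, perm, method = statistic))
  S <- nrow(spins)
  p <- (1 + sum(abs(nulls) >= abs(observed))) / (S + 1)
  structure(list(observed = observed, null = nulls, p_spin = p,
                 n_spins = S, statistic = statistic,
                 seed = attr(spins, "seed")),
            class = "brainpath_spin")
}

#' @export
print.brainpath_spin <- function(x, digits = 4, ...) {
  cat("spin test (", x$statistic, ", S = ", x$n_spins, "): observed = ",
      signif(x$observed, digits), ", p_spin = ", signif(x$p_spin, digits),
      "\n", sep = "")
  invisible(x)
}
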