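#' Region-wise simple regressions of brain structure on one predictor
#'
#' Fits `region ~ predictor` separately at every region (one predictor at a
#' time; the three phenotype maps deliberately do not correct for each
#' other). Inputs are expected to be residualized upstream; masked cells are
#' dropped per region. Regions with fewer than `min_cases` complete cases or
#' zero variance are reported as missing, not zero.
#'
#' @param predictor Residualized numeric vector (one value per participant).
#' @param brain Participants-by-regions matrix (NA = masked).
#' @param adjust Multiplicity correction applied to the map: `"BH"`
#'   (default), `"holm"` or `"none"`.
#' @param alpha Significance level for the flags (default 0.05).
#' @param family_size Number of tests in the family; defaults to the number
#'   of analysed (non-missing) regions.
#' @param min_cases Minimum complete cases per region (default 10).
#' @param label Predictor label stored in the map.
#' @return A data.frame (class `brainpath_statmap`) with one row per region:
#'   `region_id`, `n`, `beta`, `se`, `t`, `p`, `p_adj`, `sig`.
#' @export
regionwise_regression <- function(predictor, brain, adjust = c("BH", "holm",
                                                               "none"),
                                  alpha = 0.05, family_size = NULL,
                                  min_cases = 10, label = "predictor") {
  adjust <- match.arg(adjust)
  if (length(predictor) != nrow(brain))
    stop("predictor length does not match brain rows", call. = FALSE)
  m <- ncol(brain)
  out <- data.frame(
    region_id = colnames(brain) %||% sprintf("r%03d", seq_len(m)),
    n = NA_integer_, beta = NA_real_, se = NA_real_, t = NA_real_,
    p = NA_real_, p_adj = NA_real_, sig = NA, stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    y <- brain[, j]
    ok <- is.finite(y) & is.finite(predictor)
    nj <- sum(ok)
    if (nj < min_cases) next
    x <- predictor[ok]; yj <- y[ok]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0 || stats::var(yj) == 0) next
    beta <- sum((x - mean(x)) * (yj - mean(yj))) / sxx
    res <- yj - mean(yj) - beta * (x - mean(x))
    s2 <- sum(res^2) / (nj - 2)
    se <- sqrt(s2 / sxx)
    tt <- beta / se
    out$n[j] <- nj; out$beta[j] <- beta; out$se[j] <- se; out$t[j] <- tt
    out$p[j] <- 2 * stats::pt(-abs(tt), nj - 2)
  }
  done <- !is.na(out$p)
  if (any(done)) {
    adj <- adjust_pvalues(out$p[done],
                          method = if (adjust == "none") "none" else adjust,
                          alpha = alpha, family_size = family_size)
    out$p_adj[done] <- adj$p_adj
    out$sig[done] <- adj$flag
  }
  attr(out, "predictor") <- label
  attr(out, "m") <- sum(done)
  attr(out, "adjust") <- adjust
  class(out) <- c("brainpath_statmap", "data.frame")
  out
}

#' Multiple-testing adjustment with significance flags
#'
#' Benjamini-Hochberg step-up FDR or Holm step-down FWER adjustment (via
#' [stats::p.adjust()]), with flags at `alpha`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"`, `"holm"` or `"none"`.
#' @param alpha Flagging level (default 0.05).
#' @param family_size Optional family size `>= length(pvals)` (e.g. the full
#'   region count when some regions dropped out of the analysis).
#' @return List with `p_adj` and logical `flag`.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "holm", "none"),
                           alpha = 0.05, family_size = NULL) {
  method <- match.arg(method)
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  nfam <- max(family_size %||% length(pvals), length(pvals))
  p_adj <- stats::p.adjust(pvals, method = method, n = nfam)
  list(p_adj = p_adj, flag = !is.na(p_adj) & p_adj <= alpha)
}

#' Rank correlation between two regional statistic maps
#'
#' Spearman correlation (average ranks for ties) of the t-statistic vectors
#' of two maps over their shared, non-missing regions.
#'
#' @param map1,map2 `brainpath_statmap` objects (or data.frames with
#'   `region_id` and `t`).
#' @param statistic Map column to correlate (default `"t"`).
#' @return Numeric correlation.
#' @export
map_correlation <- function(map1, map2, statistic = "t") {
  shared <- intersect(map1$region_id, map2$region_id)
  v1 <- map1[[statistic]][match(shared, map1$region_id)]
  v2 <- map2[[statistic]][match(shared, map2$region_id)]
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(ok) < 3)
    stop("fewer than 3 shared regions with finite statistics", call. = FALSE)
  stats::cor(v1[ok], v2[ok], method = "spearman")
}
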