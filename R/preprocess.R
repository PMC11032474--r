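#' Log-transform a phenotype vector
#'
#' Applies the natural logarithm elementwise under one of two conventions:
#' `"log"` for strictly positive measures (CRP, BMI) or `"log1p"` for
#' non-negative questionnaire sums that contain zeros.
#'
#' @param values Numeric vector.
#' @param convention `"log"` or `"log1p"`.
#' @return Transformed vector with the convention recorded as an attribute.
#' @examples
#' log_transform(c(1, 2.03), "log")
#' @export
log_transform <- function(values, convention = c("log", "log1p")) {
  convention <- match.arg(convention)
  if (convention == "log") {
    bad <- which(values <= 0)
    if (length(bad))
      stop("log transform undefined for non-positive values at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    out <- log(values)
  } else {
    bad <- which(values < 0)
    if (length(bad))
      stop("log1p transform undefined for negative values at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    out <- log1p(values)
  }
  attr(out, "convention") <- convention
  out
}

#' Remove nuisance covariate effects by least squares
#'
#' Regresses the response on an intercept plus the covariate design and
#' returns the residuals, which are exactly orthogonal to every design
#' column. Categorical covariates must already be expanded to indicator
#' columns (see [preprocess_phenotypes()] for the standard design).
#'
#' @param response Numeric vector, or a matrix whose columns are residualized
#'   against the same design (no missing values; regional data with masks is
#'   handled column-wise by [preprocess_brain()]).
#' @param covariates Numeric matrix or data.frame of covariate columns.
#' @return Residuals with the same shape as `response`.
#' @export
residualize <- function(response, covariates) {
  X <- as.matrix(cbind(`(Intercept)` = 1, covariates))
  storage.mode(X) <- "double"
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  qr.resid(qx, as.matrix(response))[, , drop = !is.matrix(response)]
}

#' Median-absolute-deviation outlier mask
#'
#' Flags values more than `multiplier` raw median absolute deviations from
#' the median. The MAD is computed without a normal-consistency constant
#' (`constant = 1` reproduces a literal "five median absolute deviations"
#' rule); if the MAD is zero nothing is excluded.
#'
#' @param values Numeric vector with at least 3 finite values.
#' @param multiplier Exclusion threshold in MAD multiples (default 5).
#' @param constant Scale constant applied to the MAD (default 1; 1.4826 gives
#'   the normal-consistent estimator).
#' @return Logical inclusion mask (`TRUE` = keep, `FALSE` = excluded
#'   outlier, `NA` where the input was missing).
#' @export
mad_filter <- function(values, multiplier = 5, constant = 1) {
  fin <- is.finite(values)
  if (sum(fin) == 0) stop("all values missing", call. = FALSE)
  if (sum(fin) < 3)
    stop("mad_filter needs at least 3 finite values", call. = FALSE)
  med <- stats::median(values[fin])
  mad0 <- constant * stats::median(abs(values[fin] - med))
  keep <- rep(NA, length(values))
  keep[fin] <- if (mad0 == 0) TRUE else
    abs(values[fin] - med) <= multiplier * mad0
  keep
}

#' Average bilaterally homologous regions
#'
#' Collapses left/right homologous columns to their participant-wise mean.
#' If one side of a pair is missing (e.g. excluded by the MAD filter) the
#' other side's value is used alone.
#'
#' @param matrix Participants-by-regions matrix with hemisphere-specific
#'   columns.
#' @param pairs data.frame with columns `left`, `right`, `name` giving the
#'   homolog pairing and the merged region label.
#' @return Matrix with one column per pair.
#' @export
symmetrize <- function(matrix, pairs) {
  stopifnot(all(c("left", "right", "name") %in% names(pairs)))
  missing_lab <- setdiff(c(pairs$left, pairs$right), colnames(matrix))
  if (length(missing_lab))
    stop("unpaired region label(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(colnames(matrix), c(pairs$left, pairs$right))
  if (length(extra))
    stop("unpaired region label(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  out <- sapply(seq_len(nrow(pairs)), function(i) {
    l <- matrix[, pairs$left[i]]
    r <- matrix[, pairs$right[i]]
    m <- rowMeans(cbind(l, r), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  })
  colnames(out) <- pairs$name
  rownames(out) <- rownames(matrix)
  out
}

## Standard nuisance design: age, sex, age-by-sex, Townsend SES, plus site
## indicator contrasts for regional (imaging) data.
bp_design <- function(cohort, site = FALSE) {
  X <- cbind(age = cohort$age, sex = cohort$sex,
             age_sex = cohort$age * cohort$sex, ses = cohort$ses)
  if (site && !is.null(cohort$site)) {
    f <- factor(cohort$site)
    if (nlevels(f) > 1) {
      M <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(M) <- paste0("site_", levels(f)[-1])
      X <- cbind(X, M)
    }
  }
  X
}

#' Residualize and standardize the four model phenotypes
#'
#' Applies the analysis-scale transform to each phenotype (log1p for the CM
#' sum score, natural log for AT, BMI and CRP by default), nuisance-regresses
#' age, sex, age-by-sex and SES, and z-scores the residuals so that path
#' coefficients fitted downstream are directly standardized.
#'
#' @param cohort A [generate_cohort()] table (or any data.frame with columns
#'   `cm_score`, `at_score`, `bmi`, `crp`, `age`, `sex`, `ses`).
#' @param conventions Named character vector of log conventions per variable.
#' @return A data.frame (class `brainpath_resid`) with standardized residual
#'   columns `cm`, `bmi`, `at`, `crp`; the covariate design used is attached
#'   as `attr(, "design")`.
#' @export
preprocess_phenotypes <- function(cohort,
                                  conventions = c(cm = "log1p", at = "log",
                                                  bmi = "log", crp = "log")) {
  raw <- list(cm = cohort$cm_score, at = cohort$at_score,
              bmi = cohort$bmi, crp = cohort$crp)
  X <- bp_design(cohort, site = FALSE)
  out <- lapply(names(raw), function(v) {
    tr <- log_transform(raw[[v]], conventions[[v]])
    r <- residualize(as.numeric(tr), X)
    as.numeric(scale(r))
  })
  names(out) <- names(raw)
  out <- as.data.frame(out)
  attr(out, "design") <- X
  attr(out, "conventions") <- conventions
  attr(out, "config_hash") <- attr(cohort, "config_hash")
  class(out) <- c("brainpath_resid", "data.frame")
  out
}

#' MAD-filter, residualize and standardize a regional matrix
#'
#' Per region: masks values more than `mad_multiplier` raw MADs from the
#' regional median, nuisance-regresses age, sex, age-by-sex, SES and site on
#' the complete cases, and z-scores the residuals. Masked cells stay `NA`
#' (absent, not zero); regions with fewer than `min_cases` complete cases are
#' returned all-`NA`.
#'
#' @param brain A `brainpath_regional` matrix (participants x regions).
#' @param cohort The matching cohort table (covariate source).
#' @param mad_multiplier MAD exclusion threshold (default 5).
#' @param mad_constant MAD scale constant (default 1, the raw MAD).
#' @param min_cases Minimum complete cases per region (default 10).
#' @return A list with `matrix` (standardized residual matrix with `NA`
#'   masks), `exclusions` (audit table: participant, region, value,
#'   threshold) and `geometry`.
#' @export
preprocess_brain <- function(brain, cohort, mad_multiplier = 5,
                             mad_constant = 1, min_cases = 10) {
  X <- bp_design(cohort, site = TRUE)
  m <- ncol(brain)
  out <- matrix(NA_real_, nrow(brain), m, dimnames = dimnames(brain))
  excl <- vector("list", m)
  for (j in seq_len(m)) {
    v <- brain[, j]
    keep <- mad_filter(v, multiplier = mad_multiplier, constant = mad_constant)
    flagged <- which(!is.na(keep) & !keep)
    if (length(flagged)) {
      fin <- is.finite(v)
      med <- stats::median(v[fin])
      thr <- mad_multiplier * mad_constant * stats::median(abs(v[fin] - med))
      excl[[j]] <- data.frame(
        participant = if (is.null(rownames(brain))) as.character(flagged) else
          rownames(brain)[flagged],
        region = colnames(brain)[j], value = v[flagged], threshold = thr,
        stringsAsFactors = FALSE)
    }
    use <- which(!is.na(keep) & keep)
    if (length(use) < min_cases) next
    r <- residualize(v[use], X[use, , drop = FALSE])
    s <- stats::sd(r)
    if (s > 0) out[use, j] <- r / s
  }
  exclusions <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
  if (is.null(exclusions))
    exclusions <- data.frame(participant = character(), region = character(),
                             value = numeric(), threshold = numeric())
  list(matrix = out, exclusions = exclusions,
       geometry = attr(brain, "geometry"))
}
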