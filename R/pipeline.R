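#' Cohort-level path analysis (H1)
#'
#' Fits the four-variable model (CM -> BMI/AT/CRP with BMI/AT -> CRP) to
#' residualized, standardized phenotypes with robust errors; reports fit
#' indices against the independence baseline, the two indirect effects of CM
#' on CRP (through BMI and through AT), the Spearman correlation matrix of
#' the four variables, and the simple regression of CRP on CM used to check
#' that the direct effect is absorbed by the indirect paths.
#'
#' @param resid A [preprocess_phenotypes()] table (columns `cm`, `bmi`,
#'   `at`, `crp`).
#' @return List of class `brainpath_h1`: `fit`, `indices`, `indirect`,
#'   `spearman`, `simple_lm` (CRP-on-CM slope, SE, t, p), `n`.
#' @export
run_h1 <- function(resid) {
  need <- c("cm", "bmi", "at", "crp")
  if (!all(need %in% names(resid)))
    stop("resid must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(resid)
  if (n < 100)
    stop("n = ", n, " is too small for path-model asymptotics; ",
         "use at least 100 participants", call. = FALSE)
  fit <- fit_sem(h1_model(), resid)
  baseline <- fit_sem(independence_model(need), resid)
  indices <- fit_indices(fit, baseline)
  indirect <- indirect_effects(fit, list(c("cm", "bmi", "crp"),
                                         c("cm", "at", "crp")))
  rownames(indirect) <- c("cm_bmi_crp", "cm_at_crp")
  sp <- stats::cor(as.matrix(resid[, need]), method = "spearman")
  sl <- stats::summary.lm(stats::lm(crp ~ cm, data = resid))$coefficients
  simple_lm <- c(beta = sl["cm", 1], se = sl["cm", 2], t = sl["cm", 3],
                 p = sl["cm", 4])
  structure(list(fit = fit, indices = indices, indirect = indirect,
                 spearman = sp, simple_lm = simple_lm, n = n),
            class = "brainpath_h1")
}

#' @export
print.brainpath_h1 <- function(x, digits = 4, ...) {
  cat("== H1: four-variable path model (n =", x$n, ") ==\n")
  print(x$fit, digits = digits)
  print(x$indices, digits = digits)
  cat("indirect effects of cm on crp:\n")
  print(signif(x$indirect[, -1], digits))
  cat("simple regression crp ~ cm: beta =", signif(x$simple_lm[1], digits),
      "(SE", paste0(signif(x$simple_lm[2], digits), ","),
      "p =", signif(x$simple_lm[4], digits), ")\n")
  invisible(x)
}

#' Region-wise effect maps of BMI, CRP and AT (H2)
#'
#' Builds one simple-regression statistic map per predictor (BMI, CRP, AT,
#' plus CM as the expected-null check), each with BH-FDR flags, and compares
#' the cortical t-maps pairwise with Spearman correlations whose p-values are
#' corrected for spatial autocorrelation by spin tests.
#'
#' @param resid A [preprocess_phenotypes()] table.
#' @param brain A [preprocess_brain()] result (or a standardized
#'   participants-by-regions matrix).
#' @param geometry The parcel geometry (needed for the spin tests; taken
#'   from `brain` if available).
#' @param n_spins Number of spins (default 10000).
#' @param spin_seed Seed for the rotation batch.
#' @param alpha FDR level for the flags (default 0.05).
#' @return List of class `brainpath_h2`: `maps` (named list of statmaps),
#'   `map_comparisons` (data.frame with rho and p_spin per predictor pair),
#'   `spin_nulls` (per-pair null statistics for audit).
#' @export
run_h2 <- function(resid, brain, geometry = NULL, n_spins = 10000,
                   spin_seed = 1L, alpha = 0.05) {
  if (is.list(brain) && !is.matrix(brain)) {
    geometry <- geometry %||% brain$geometry
    brain <- brain$matrix
  }
  if (is.null(geometry))
    stop("geometry is required for the spin-corrected map comparisons",
         call. = FALSE)
  preds <- c("bmi", "crp", "at", "cm")
  maps <- lapply(preds, function(v)
    regionwise_regression(resid[[v]], brain, adjust = "BH", alpha = alpha,
                          label = v))
  names(maps) <- preds

  cort_id <- geometry$region_id[geometry$structure_class == "cortical"]
  spins <- generate_spins(geometry, n_spins = n_spins, seed = spin_seed)
  pairs <- list(c("bmi", "crp"), c("bmi", "at"), c("crp", "at"))
  nulls <- list()
  cmp <- do.call(rbind, lapply(pairs, function(pr) {
    t1 <- maps[[pr[1]]]$t[match(cort_id, maps[[pr[1]]]$region_id)]
    t2 <- maps[[pr[2]]]$t[match(cort_id, maps[[pr[2]]]$region_id)]
    sp <- spin_pvalue(t1, t2, spins, statistic = "spearman")
    nulls[[paste(pr, collapse = "_")]] <<- sp$null
    data.frame(map1 = pr[1], map2 = pr[2], rho = sp$observed,
               p_spin = sp$p_spin, n_spins = sp$n_spins,
               stringsAsFactors = FALSE)
  }))
  structure(list(maps = maps, map_comparisons = cmp, spin_nulls = nulls,
                 alpha = alpha),
            class = "brainpath_h2")
}

#' @export
print.brainpath_h2 <- function(x, digits = 4, ...) {
  cat("== H2: region-wise effect maps ==\n")
  for (v in names(x$maps)) {
    m <- x$maps[[v]]
    cat(sprintf("  %-4s: %d regions analysed, %d significant (FDR <= %g)\n",
                v, attr(m, "m"), sum(m$sig, na.rm = TRUE), x$alpha))
  }
  cat("cortical map comparisons (spin-corrected):\n")
  cmp <- x$map_comparisons
  cmp$rho <- signif(cmp$rho, digits)
  print(cmp, row.names = FALSE)
  invisible(x)
}

#' Region-wise full-versus-sparse mediation models (H3)
#'
#' At every region, fits the full (eight-path) and sparse (six-path)
#' region-inclusive models with robust errors, compares them with the scaled
#' likelihood-ratio difference test (k = 2), applies the chosen multiplicity
#' correction across regions, assigns the winning model per region, and
#' estimates the indirect-effect chains of CM on the region exclusively
#' within the region set where each chain's host model won. Regions where
#' either model fails to converge are reported as unevaluated.
#'
#' @param resid A [preprocess_phenotypes()] table.
#' @param brain A [preprocess_brain()] result or standardized matrix.
#' @param contrast_correction `"BH"` (FDR, default) or `"holm"` (FWER) for
#'   the model contrasts.
#' @param alpha Level for contrasts and for the chain-wise FDR (default 0.05).
#' @param min_cases Minimum complete cases per region.
#' @param keep_fits Keep the per-region fit objects (default `FALSE`).
#' @return List of class `brainpath_h3`: `regions` (per-region comparison
#'   table with winner labels), `chains` (named list of indirect-effect maps,
#'   each FDR-adjusted within its evaluated set), `correction`, and
#'   optionally `fits`.
#' @export
run_h3 <- function(resid, brain, contrast_correction = c("BH", "holm"),
                   alpha = 0.05, min_cases = 100, keep_fits = FALSE) {
  contrast_correction <- match.arg(contrast_correction)
  if (is.list(brain) && !is.matrix(brain)) brain <- brain$matrix
  m <- ncol(brain)
  ids <- colnames(brain) %||% sprintf("r%03d", seq_len(m))
  full_m <- h3_full_model()
  sparse_m <- h3_sparse_model()
  regions <- data.frame(region_id = ids, n = NA_integer_,
                        lr_stat = NA_real_, lr_df = NA_integer_,
                        lr_p = NA_real_, lr_p_adj = NA_real_,
                        winner = NA_character_, stringsAsFactors = FALSE)
  fits <- if (keep_fits) vector("list", m) else NULL
  chain_defs <- list(
    cm_bmi_region     = c("a1", "c1"),
    cm_at_region      = c("a3", "c3"),
    cm_crp_region     = c("a2", "c2"),
    cm_bmi_crp_region = c("a1", "b1", "c2"),
    cm_at_crp_region  = c("a3", "b2", "c2")
  )
  full_only <- c("cm_bmi_region", "cm_at_region")
  chain_rows <- lapply(chain_defs, function(x) list())

  for (j in seq_len(m)) {
    y <- brain[, j]
    ok <- is.finite(y)
    for (v in c("cm", "bmi", "at", "crp")) ok <- ok & is.finite(resid[[v]])
    if (sum(ok) < min_cases) next
    dat <- data.frame(cm = resid$cm[ok], bmi = resid$bmi[ok],
                      at = resid$at[ok], crp = resid$crp[ok],
                      region = y[ok])
    res <- tryCatch({
      ff <- fit_sem(full_m, dat)
      fs <- fit_sem(sparse_m, dat)
      list(ff = ff, fs = fs, lr = lr_compare(ff, fs))
    }, error = function(e) NULL)
    if (is.null(res)) next   # unevaluated region
    regions$n[j] <- nrow(dat)
    regions$lr_stat[j] <- res$lr$statistic
    regions$lr_df[j] <- res$lr$df
    regions$lr_p[j] <- res$lr$p
    if (keep_fits) fits[[j]] <- res[c("ff", "fs")]
    for (ch in names(chain_defs)) {
      host <- if (ch %in% full_only) "full" else "either"
      chain_rows[[ch]][[length(chain_rows[[ch]]) + 1L]] <-
        list(j = j, full = indirect_effects(res$ff, chain_defs[ch]),
             sparse = if (host == "either")
               indirect_effects(res$fs, chain_defs[ch]) else NULL)
    }
  }

  done <- !is.na(regions$lr_p)
  if (any(done)) {
    adj <- adjust_pvalues(regions$lr_p[done], method = contrast_correction,
                          alpha = alpha)
    regions$lr_p_adj[done] <- adj$p_adj
    regions$winner[done] <- ifelse(adj$flag, "full", "sparse")
  }

  ## chain maps, evaluated only where the chain's host model won
  chains <- lapply(names(chain_defs), function(ch) {
    rows <- lapply(chain_rows[[ch]], function(r) {
      w <- regions$winner[r$j]
      if (is.na(w)) return(NULL)
      if (ch %in% full_only && w != "full") return(NULL)
      est <- if (w == "full") r$full else r$sparse
      cbind(data.frame(region_id = regions$region_id[r$j], model = w,
                       stringsAsFactors = FALSE), est)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0) return(NULL)
    adj <- adjust_pvalues(out$p, method = "BH", alpha = alpha)
    out$p_adj <- adj$p_adj
    out$sig <- adj$flag
    rownames(out) <- NULL
    out
  })
  names(chains) <- names(chain_defs)

  structure(list(regions = regions, chains = chains,
                 correction = contrast_correction, alpha = alpha,
                 fits = fits),
            class = "brainpath_h3")
}

#' @export
print.brainpath_h3 <- function(x, digits = 4, ...) {
  cat("== H3: full vs sparse mediation models (", x$correction,
      "correction ) ==\n")
  tab <- table(factor(x$regions$winner, levels = c("full", "sparse")),
               useNA = "ifany")
  cat("winners: full =", tab[["full"]], ", sparse =", tab[["sparse"]],
      ", unevaluated =", sum(is.na(x$regions$winner)), "\n")
  for (ch in names(x$chains)) {
    cm <- x$chains[[ch]]
    if (is.null(cm)) {
      cat(sprintf("  %-18s: not evaluated\n", ch))
    } else {
      cat(sprintf("  %-18s: %3d regions, %3d significant (FDR <= %g)\n",
                  ch, nrow(cm), sum(cm$sig), x$alpha))
    }
  }
  invisible(x)
}
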