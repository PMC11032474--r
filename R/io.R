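## Tab-separated I/O with a '#'-prefixed provenance header (seed and config
## hash), plus schema validation for the pipeline input bundle.

bp_header <- function(x) {
  c(paste0("# seed: ", attr(x, "seed") %||% NA),
    paste0("# config: ", attr(x, "config_hash") %||% NA))
}

bp_write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bp_read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

bp_read_header <- function(path) {
  lines <- readLines(path, n = 10)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) out[[kv[1]]] <- kv[2]
  }
  out
}

#' Write / read a phenotype cohort as tab-separated text
#'
#' The file carries a comment header (`# seed: ...`, `# config: ...`) so
#' every output records its provenance.
#' @param cohort A [generate_cohort()] table.
#' @param path Output file path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_phenotypes <- function(cohort, path) {
  bp_write_tsv(as.data.frame(cohort), path, bp_header(cohort))
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- bp_read_tsv(path)
  bp_check_columns(out, c("id", "cm_score", "at_score", "bmi", "crp",
                          "age", "sex", "ses", "site"), "phenotype table")
  h <- bp_read_header(path)
  attr(out, "seed") <- as.integer(h$seed)
  attr(out, "config_hash") <- h$config
  class(out) <- c("brainpath_cohort", "data.frame")
  out
}

#' Write / read parcel geometry as tab-separated text
#' @param geometry A [generate_geometry()] table.
#' @param path File path.
#' @return `path` (write) or the geometry table (read).
#' @export
write_geometry <- function(geometry, path) {
  bp_write_tsv(as.data.frame(geometry), path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  out <- bp_read_tsv(path)
  bp_check_columns(out, c("region_id", "structure_class", "x", "y", "z"),
                   "geometry table")
  class(out) <- c("brainpath_geometry", "data.frame")
  out
}

#' Write / read a regional measurement matrix as tab-separated text
#'
#' Rows are participants (first column `id`), remaining columns regions.
#' @param brain A `brainpath_regional` matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_regional <- function(brain, path) {
  df <- data.frame(id = rownames(brain), as.data.frame(unclass(brain)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  bp_write_tsv(df, path, bp_header(brain))
}

#' @rdname write_regional
#' @export
read_regional <- function(path) {
  df <- bp_read_tsv(path)
  bp_check_columns(df, "id", "regional matrix")
  out <- as.matrix(df[, -1, drop = FALSE])
  rownames(out) <- df$id
  h <- bp_read_header(path)
  attr(out, "seed") <- as.integer(h$seed)
  attr(out, "config_hash") <- h$config
  class(out) <- c("brainpath_regional", class(out))
  out
}

#' Write / read a generator configuration as a structured key-value file
#'
#' Only the user-level parameters are stored; derived calibration constants
#' are re-solved on read so the file stays small and readable.
#' @param config A [generator_config()] object.
#' @param path YAML file path.
#' @return `path` (write) or a rebuilt `brainpath_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "brainpath_config"))
  keep <- list(
    n_participants = config$n_participants, variant = config$variant,
    struct_coeffs = as.list(config$struct_coeffs),
    residual_sds = as.list(config$residual_sds),
    marginal_calibration = config$marginal_calibration,
    covariate_effects = lapply(config$covariate_effects, as.list),
    regional_effects = config$regional_effects,
    regional_params = config$regional_params,
    spatial_kernel_length = config$spatial_kernel_length,
    n_cortical = config$n_cortical, n_subcortical = config$n_subcortical,
    mcar_rate = config$mcar_rate, seed = config$seed, hash = config$hash
  )
  yaml::write_yaml(keep, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- generator_config(
    n_participants = y$n_participants, variant = y$variant,
    struct_coeffs = unlist(y$struct_coeffs),
    residual_sds = unlist(y$residual_sds),
    marginal_calibration = y$marginal_calibration,
    covariate_effects = lapply(y$covariate_effects, unlist),
    regional_effects = y$regional_effects,
    regional_params = y$regional_params,
    spatial_kernel_length = y$spatial_kernel_length,
    n_cortical = y$n_cortical, n_subcortical = y$n_subcortical,
    mcar_rate = y$mcar_rate, seed = y$seed
  )
  cfg
}

bp_check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read and validate a pipeline input bundle
#'
#' @param paths Named list with elements `phenotypes`, and optionally
#'   `brain` and `geometry`, each a file path written by the corresponding
#'   `write_*` function.
#' @return List with the validated tables; schema violations are reported
#'   column by column.
#' @export
read_inputs <- function(paths) {
  out <- list(phenotypes = read_phenotypes(paths$phenotypes))
  if (!is.null(paths$geometry)) out$geometry <- read_geometry(paths$geometry)
  if (!is.null(paths$brain)) {
    out$brain <- read_regional(paths$brain)
    if (!is.null(out$geometry) &&
        ncol(out$brain) != nrow(out$geometry))
      stop("brain matrix has ", ncol(out$brain), " regions but geometry has ",
           nrow(out$geometry), call. = FALSE)
    if (nrow(out$brain) != nrow(out$phenotypes))
      stop("brain matrix and phenotype table disagree on participant count",
           call. = FALSE)
  }
  out
}

#' Write analysis results as tab-separated tables
#'
#' Serializes `brainpath_h1` / `brainpath_h2` / `brainpath_h3` results (and
#' the generating config hash, when available) under `out_dir`.
#' @param results A result object from [run_h1()], [run_h2()] or [run_h3()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (defaults to the hypothesis label).
#' @return Character vector of files written.
#' @export
write_results <- function(results, out_dir, prefix = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    bp_write_tsv(df, p)
    files <<- c(files, p)
  }
  if (inherits(results, "brainpath_h1")) {
    prefix <- prefix %||% "h1"
    w(parameter_table(results$fit), paste0(prefix, "_parameters.tsv"))
    w(results$indirect, paste0(prefix, "_indirect.tsv"))
    ix <- results$indices
    w(data.frame(index = c("cfi", "rmsea", "rmsea_lo", "rmsea_hi", "srmr"),
                 value = c(ix$cfi, ix$rmsea, ix$rmsea_ci[1], ix$rmsea_ci[2],
                           ix$srmr)),
      paste0(prefix, "_fit_indices.tsv"))
  } else if (inherits(results, "brainpath_h2")) {
    prefix <- prefix %||% "h2"
    for (v in names(results$maps))
      w(as.data.frame(results$maps[[v]]), paste0(prefix, "_map_", v, ".tsv"))
    w(results$map_comparisons, paste0(prefix, "_map_comparisons.tsv"))
    for (nm in names(results$spin_nulls))
      w(data.frame(spin_index = seq_along(results$spin_nulls[[nm]]),
                   statistic = results$spin_nulls[[nm]]),
        paste0(prefix, "_spin_null_", nm, ".tsv"))
  } else if (inherits(results, "brainpath_h3")) {
    prefix <- prefix %||% "h3"
    w(results$regions, paste0(prefix, "_model_contrasts.tsv"))
    for (ch in names(results$chains))
      if (!is.null(results$chains[[ch]]))
        w(results$chains[[ch]], paste0(prefix, "_chain_", ch, ".tsv"))
  } else {
    stop("unsupported results object of class ", class(results)[1],
         call. = FALSE)
  }
  files
}
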