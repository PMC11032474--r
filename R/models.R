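#' Specify a recursive observed-variable path model
#'
#' Parses a small text syntax with one directed edge per line,
#' `"lhs <- rhs : label"` (the label is optional), into a path model over
#' named observed variables. The edge graph must be acyclic (recursive) and
#' residual variances are strictly diagonal; every labelled coefficient maps
#' to exactly one edge. Exogenous variances and residual variances are
#' implicit free parameters.
#'
#' @param spec Character vector of edge lines (a single string may hold
#'   several lines separated by newlines or `;`).
#' @param variables Optional character vector fixing the variable order;
#'   defaults to order of first appearance.
#' @param label Optional model label.
#' @return An object of class `brainpath_model` with elements `vars`,
#'   `edges` (data.frame `from`, `to`, `label`) and `label`.
#' @examples
#' m <- path_model(c("bmi <- cm : a1", "crp <- bmi : b1"))
#' count_parameters(m)
#' @export
path_model <- function(spec, variables = NULL, label = NULL) {
  lines <- unlist(strsplit(spec, "[\n;]"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse1 <- function(ln) {
    m <- regmatches(ln, regexec(
      "^([A-Za-z0-9_.]+)\\s*<-\\s*([A-Za-z0-9_.]+)\\s*(?::\\s*([A-Za-z0-9_.]+))?$",
      ln))[[1]]
    if (length(m) == 0)
      stop("cannot parse model line: '", ln, "'", call. = FALSE)
    c(to = m[2], from = m[3], label = if (nzchar(m[4])) m[4] else
      paste0(m[2], "~", m[3]))
  }
  if (length(lines) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        label = character(), stringsAsFactors = FALSE)
  } else {
    parsed <- t(vapply(lines, parse1, character(3)))
    edges <- data.frame(from = parsed[, "from"], to = parsed[, "to"],
                        label = parsed[, "label"], stringsAsFactors = FALSE,
                        row.names = NULL)
  }
  vars <- variables %||% unique(c(rbind(edges$from, edges$to)))
  if (!all(c(edges$from, edges$to) %in% vars))
    stop("edge variables missing from 'variables'", call. = FALSE)
  if (anyDuplicated(edges$label))
    stop("duplicate coefficient label(s): ",
         paste(unique(edges$label[duplicated(edges$label)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop("duplicate edge(s)", call. = FALSE)
  ord <- bp_topo_order(vars, edges)    # errors on cycles
  structure(list(vars = vars, edges = edges, order = ord,
                 label = label %||% "path model"),
            class = "brainpath_model")
}

## Topological order of the directed edge graph; errors if cyclic.
bp_topo_order <- function(vars, edges) {
  remaining <- vars
  ord <- character(0)
  while (length(remaining)) {
    ## a variable is emittable once all its parents are emitted
    free <- remaining[vapply(remaining, function(v) {
      all(edges$from[edges$to == v] %in% ord)
    }, logical(1))]
    if (length(free) == 0)
      stop("path model is not recursive (directed cycle detected)",
           call. = FALSE)
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
  }
  ord
}

#' Number of free directed path coefficients
#'
#' Counts directed-edge coefficients only; variances are excluded, matching
#' the convention under which the brain-region models have eight (full) and
#' six (sparse) parameters.
#' @param model A [path_model()].
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "brainpath_model"))
  nrow(model$edges)
}

#' Canonical four-variable model: CM -> {BMI, AT, CRP} with BMI/AT -> CRP
#'
#' The cohort-level hypothesis model: childhood maltreatment has direct
#' effects on BMI (`a1`), AT (`a3`) and CRP (`a2`); BMI (`b1`) and AT (`b2`)
#' have direct effects on CRP. No BMI-AT residual covariance, so the model
#' has one degree of freedom.
#' @return A `brainpath_model` over variables `cm`, `bmi`, `at`, `crp`.
#' @export
h1_model <- function() {
  path_model(c("bmi <- cm : a1",
               "at  <- cm : a3",
               "crp <- cm : a2",
               "crp <- bmi : b1",
               "crp <- at : b2"),
             variables = c("cm", "bmi", "at", "crp"),
             label = "four-variable model")
}

#' Region-inclusive full model (eight path parameters)
#'
#' Extends [h1_model()] with direct effects of BMI (`c1`), CRP (`c2`) and AT
#' (`c3`) on one brain region.
#' @param region Name of the region variable (default `"region"`).
#' @return A `brainpath_model` over `cm`, `bmi`, `at`, `crp`, `region`.
#' @export
h3_full_model <- function(region = "region") {
  path_model(c("bmi <- cm : a1",
               "at  <- cm : a3",
               "crp <- cm : a2",
               "crp <- bmi : b1",
               "crp <- at : b2",
               paste0(region, " <- bmi : c1"),
               paste0(region, " <- crp : c2"),
               paste0(region, " <- at : c3")),
             variables = c("cm", "bmi", "at", "crp", region),
             label = "full model")
}

#' Region-inclusive sparse model (six path parameters)
#'
#' As [h3_full_model()] but only CRP has a direct effect on the region; BMI
#' and AT can act on the region only through CRP.
#' @inheritParams h3_full_model
#' @return A `brainpath_model`.
#' @export
h3_sparse_model <- function(region = "region") {
  path_model(c("bmi <- cm : a1",
               "at  <- cm : a3",
               "crp <- cm : a2",
               "crp <- bmi : b1",
               "crp <- at : b2",
               paste0(region, " <- crp : c2")),
             variables = c("cm", "bmi", "at", "crp", region),
             label = "sparse model")
}

#' Independence (baseline) model over a variable set
#'
#' All paths removed; only variances are estimated. Used as the incremental
#' baseline for the CFI.
#' @param variables Character vector of variable names.
#' @return A `brainpath_model` with no edges.
#' @export
independence_model <- function(variables) {
  path_model(character(0), variables = variables, label = "independence model")
}

#' @export
print.brainpath_model <- function(x, ...) {
  cat("<brainpath_model>", x$label, "-", length(x$vars), "variables,",
      nrow(x$edges), "paths, df =",
      length(x$vars) * (length(x$vars) + 1) / 2 -
        (nrow(x$edges) + length(x$vars)), "\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$to, " <- ", x$edges$from, " : ", x$edges$label,
               collapse = "\n"), "\n")
  invisible(x)
}
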