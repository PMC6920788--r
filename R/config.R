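# YAML configuration: top-level keys `params`, `geometry`, `scan`.
# Unknown keys anywhere are rejected; `--set key.path=value` overrides.

.scan_fields <- c("mode", "grid_step", "L_min", "L_max", "dL", "L_u_fixed",
                  "Rp_min", "Rp_max", "Rp_step", "n_out", "L_d", "L_u")
.geometry_fields <- c("conformation", "Rp", "Hp", "n1", "n2")
.param_fields <- c("B", "K", "sigma", "h_r", "h_s", "a_qm", "Delta", "kT")

.default_scan <- function() {
  list(grid_step = 0.1, L_min = 2, L_max = 14, dL = 0.5, L_u_fixed = 7,
       Rp_min = 1, Rp_max = 40, Rp_step = 0.5, n_out = 40, L_d = 0, L_u = 0)
}

#' Read and resolve a model configuration
#'
#' @param path YAML file with optional top-level maps `params`, `geometry`
#'   and `scan`.  `geometry` takes either `conformation: closed|open` or an
#'   explicit `Rp` (with optional `Hp`, defaulting to `2*h_r`), plus `n1`,
#'   `n2`.
#' @param overrides character vector of `key.path=value` strings (e.g.
#'   `params.Delta=0.02`, `geometry.n1=0.5`).
#' @return list with elements `params` (`membrane_params`), `geometry`
#'   (`protein_geometry`) and `scan` (named list).
#' @export
read_config <- function(path = NULL, overrides = character()) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) {
      stop("configuration error: file not found: ", path, call. = FALSE)
    }
    tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("configuration parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("params", "geometry", "scan"))
  if (length(bad)) {
    stop("configuration error: unknown top-level key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([a-z]+)\\.([A-Za-z_0-9]+)=(.*)$", ov))[[1]]
    if (length(m) != 4L) {
      stop("configuration error: malformed --set override: ", ov, call. = FALSE)
    }
    val <- if (m[2] == "geometry" && m[3] == "conformation") m[4] else {
      v <- suppressWarnings(as.numeric(m[4]))
      if (is.na(v)) stop("configuration error: non-numeric value in ", ov,
                         call. = FALSE)
      v
    }
    raw[[m[2]]][[m[3]]] <- val
  }
  pov <- raw$params
  if (!is.null(pov)) {
    bad <- setdiff(names(pov), .param_fields)
    if (length(bad)) stop("configuration error: unknown params field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  params <- make_params(if (is.null(pov)) list() else pov)
  g <- raw$geometry
  if (!is.null(g)) {
    bad <- setdiff(names(g), .geometry_fields)
    if (length(bad)) stop("configuration error: unknown geometry field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  n1 <- g$n1 %||% 0; n2 <- g$n2 %||% 0
  geometry <- if (!is.null(g$conformation)) {
    egfr_geometry(g$conformation, n1, n2, params)
  } else {
    protein_geometry(g$Rp %||% 1.6, g$Hp %||% (2 * params$h_r), n1, n2)
  }
  sc <- raw$scan
  if (!is.null(sc)) {
    bad <- setdiff(names(sc), .scan_fields)
    if (length(bad)) stop("configuration error: unknown scan field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  scan <- utils::modifyList(.default_scan(), if (is.null(sc)) list() else sc)
  if (!scan$grid_step %in% c(0.05, 0.1, 0.2)) {
    stop("validation error: field 'grid_step' must be one of 0.05, 0.1, 0.2",
         call. = FALSE)
  }
  list(params = params, geometry = geometry, scan = scan)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a resolved configuration back to YAML
#'
#' The written file reloads to identical values with [read_config()].
#'
#' @param config a list as returned by [read_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(
    params = config$params[.param_fields],
    geometry = config$geometry[c("Rp", "Hp", "n1", "n2")],
    scan = config$scan
  ), path)
  invisible(path)
}

#' Validate a configuration file without running anything
#'
#' @param path YAML configuration file.
#' @return list with `valid` (logical) and `issues` (character vector of
#'   violated constraints, with field names).
#' @export
validate_config <- function(path) {
  issues <- character()
  res <- tryCatch(read_config(path), error = function(e) {
    issues <<- c(issues, conditionMessage(e)); NULL
  })
  list(valid = is.null(res) == FALSE && length(issues) == 0L, issues = issues)
}
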