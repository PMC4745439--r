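## Recognized flat parameter names and the reference defaults (the figure
## defaults of the source configuration: coupling number 0.75, micropolar
## parameter 50, stenosis occupying half a two-unit artery, catheter 0.1,
## 1% wall slip, unit flux, converging taper).
sf_param_names <- c("phi", "zeta", "eps", "gamma", "Gamma", "rc",
                    "N", "m", "Q", "u")

sf_defaults <- list(phi = -0.05, zeta = NULL, eps = 0.1, gamma = 0.5,
                    Gamma = 0.5, rc = 0.1, N = 0.75, m = 50, Q = 1, u = 0.01)

## build the three model objects from a flat named list of values
params_from_values <- function(vals) {
  unknown <- setdiff(names(vals), sf_param_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  v <- sf_defaults
  v[names(vals)] <- vals
  if (!is.null(vals$zeta) && is.null(vals$phi)) v$phi <- NULL
  if (!is.null(vals$zeta) && !is.null(vals$phi))
    stop("`phi` and `zeta` both given: the taper is overdetermined")
  geom <- geometry_params(eps = v$eps, gamma = v$gamma, Gamma = v$Gamma,
                          rc = v$rc, phi = v$phi, zeta = v$zeta)
  list(geom = geom,
       fluid = fluid_params(N = v$N, m = v$m),
       flow = flow_conditions(Q = v$Q, u = v$u),
       values = v)
}

#' Read model parameters from a flat key-value config file
#'
#' The file holds one `key = value` pair per line (`#` comments and blank
#' lines ignored); recognized keys are `phi`, `zeta`, `eps`, `gamma`,
#' `Gamma`, `rc`, `N`, `m`, `Q`, `u`.  Missing keys take the reference
#' defaults (`N = 0.75`, `m = 50`, `Gamma = 0.5`, `gamma = 0.5`, `rc = 0.1`,
#' `u = 0.01`, `eps = 0.1`, `Q = 1`, `phi = -0.05`).  Unknown keys, a taper
#' given both as `phi` and `zeta`, and constraint violations (e.g. `N >= 1`)
#' are rejected with an error naming the key.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied on top of the file (CLI
#'   `--set` flags).
#' @return A list with elements `geom`, `fluid`, `flow` (validated model
#'   objects) and `values` (the resolved flat parameter list).
#' @examples
#' p <- load_config(NULL)        # reference defaults
#' p$fluid
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("cannot parse config line: ", ln)
      key <- trimws(kv[1L])
      val <- suppressWarnings(as.numeric(trimws(kv[2L])))
      if (is.na(val))
        stop("non-numeric value for key `", key, "`")
      vals[[key]] <- val
    }
  }
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    vals[names(overrides)] <- overrides
  }
  params_from_values(vals)
}

#' Run a parameter sweep
#'
#' Evaluates the model over the cartesian product of one or more parameter
#' axes and records the requested outputs, one row per combination.  Rows
#' are emitted in deterministic axis order (last axis varies fastest, as in
#' [expand.grid()]); a failing combination is recorded in its `error`
#' column rather than aborting the sweep.
#'
#' @param base A parameter set from [load_config()] (or its `values` list).
#' @param axes Named list of numeric vectors to vary; every name must be a
#'   recognized parameter.  An empty list runs the base case once.
#' @param outputs Character subset of `"lambda"` (impedance), `"tw"` (wall
#'   shear stress at the stenosis extrema), `"extrema"` (locations and
#'   radii).
#' @param method Slip convention for `lambda`/`tw`, see
#'   [pressure_gradient_at()].
#' @param max_rows Cap on the product size (sweeps are desk-scale).
#' @param verbose Emit one message per row.
#' @return A data.frame: one row per combination with the axis values, the
#'   requested outputs and an `error` column (`NA` on success).  Errors in
#'   every row raise after the sweep completes.
#' @examples
#' sw <- run_sweep(load_config(NULL), list(rc = c(0.05, 0.1)),
#'                 outputs = "lambda")
#' sw$lambda
#' @export
run_sweep <- function(base, axes = list(), outputs = c("lambda", "tw"),
                      method = "affine", max_rows = 1e5, verbose = FALSE) {
  if (!is.null(base$values)) base <- base$values
  outputs <- match.arg(outputs, c("lambda", "tw", "extrema"),
                       several.ok = TRUE)
  if (length(axes)) {
    bad <- setdiff(names(axes), sf_param_names)
    if (length(bad))
      stop("unknown sweep axis name(s): ", paste(bad, collapse = ", "))
    grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_along(axes)), drop = FALSE]
  } else {
    grid <- data.frame(row.names = 1L)
  }
  if (nrow(grid) > max_rows)
    stop(sprintf("sweep size %d exceeds cap %d", nrow(grid), max_rows))
  rows <- vector("list", max(nrow(grid), 1L))
  for (i in seq_along(rows)) {
    vals <- base
    if (ncol(grid)) vals[names(grid)] <- as.list(grid[i, , drop = FALSE])
    ## an axis on one taper representation silences the base default of the
    ## other, mirroring the mutual exclusion in the constructor
    if ("zeta" %in% names(grid)) vals$phi <- NULL
    if ("phi" %in% names(grid)) vals$zeta <- NULL
    out <- if (ncol(grid)) as.list(grid[i, , drop = FALSE]) else list()
    res <- tryCatch({
      p <- params_from_values(vals[!vapply(vals, is.null, logical(1L))])
      o <- list()
      if ("extrema" %in% outputs || "tw" %in% outputs)
        ex <- stenosis_extrema(p$geom)
      if ("extrema" %in% outputs)
        o <- c(o, list(zL = ex$zL, zC = ex$zC, zR = ex$zR,
                       hL = ex$hL, hC = ex$hC, hR = ex$hR))
      if ("lambda" %in% outputs)
        o$lambda <- impedance(p$geom, p$fluid, p$flow, method = method)$lam
      if ("tw" %in% outputs) {
        o$tw_zL <- wall_shear_stress_at(ex$zL, p$geom, p$fluid, p$flow,
                                        method = method)
        o$tw_zC <- wall_shear_stress_at(ex$zC, p$geom, p$fluid, p$flow,
                                        method = method)
        o$tw_zR <- wall_shear_stress_at(ex$zR, p$geom, p$fluid, p$flow,
                                        method = method)
      }
      c(o, list(error = NA_character_))
    }, error = function(e) list(error = conditionMessage(e)))
    rows[[i]] <- c(out, res)
    if (verbose)
      message(sprintf("sweep row %d/%d: %s", i, length(rows),
                      if (is.na(rows[[i]]$error)) "ok" else rows[[i]]$error))
  }
  cols <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(cols, function(cn)
    vapply(rows, function(r) if (is.null(r[[cn]])) NA_real_ else
      if (cn == "error") NA_real_ else as.numeric(r[[cn]]),
      numeric(1L))), col.names = cols)
  df$error <- vapply(rows, function(r) r$error %||% NA_character_,
                     character(1L))
  if (all(!is.na(df$error)))
    stop("all sweep rows failed; first error: ", df$error[1L])
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table as reproducible CSV
#'
#' Numeric columns are formatted with 10 significant digits so re-running
#' the same configuration byte-reproduces the file.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]]))
      out[[cn]] <- sprintf("%.10g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run-metadata sidecar
#'
#' Records the resolved parameters, computation options and package version
#' next to a result file, so the pair suffices to re-run the computation.
#'
#' @param path Sidecar path (conventionally `<result>.json`).
#' @param values Resolved flat parameter list (see [load_config()]).
#' @param extra Optional named list of additional fields (tolerances,
#'   sweep axes, ...).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, values, extra = list()) {
  meta <- c(list(package = "stenoflow",
                 version = as.character(utils::packageVersion("stenoflow")),
                 parameters = values[!vapply(values, is.null, logical(1L))]),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
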