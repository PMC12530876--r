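# Delimited-text I/O
#
# All tabular artifacts are plain delimited text so runs stay diffable.
# Datasets round-trip losslessly at better than 12 significant digits.

.dataset_cols <- c("sigma_C", "sigma_H", "eps_C", "eps_H", "density", "valid")

fmt_num <- function(x) sprintf("%.15g", x)

#' Write / read a parameter sample set
#'
#' Plain CSV with the header `sigma_C,sigma_H,eps_C,eps_H` in units of
#' nm, nm, kJ/mol, kJ/mol.
#'
#' @param points data frame of parameter points.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   the data frame of points.
#' @export
write_params <- function(points, path) {
  stopifnot(all(.param_cols %in% names(points)))
  df <- points[, .param_cols, drop = FALSE]
  lines <- c(paste(.param_cols, collapse = ","),
             do.call(paste, c(lapply(df, fmt_num), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  read_checked_csv(path, .param_cols)[, .param_cols, drop = FALSE]
}

# strict CSV reader: exact column set, numeric fields, line-numbered errors
read_checked_csv <- function(path, cols) {
  lines <- readLines(path)
  if (!length(lines))
    stop("'", path, "' is empty (expected a header row)", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing <- setdiff(cols, header)
  extra <- setdiff(header, cols)
  if (length(missing))
    stop("'", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(extra))
    stop("'", path, "' has unexpected column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                             length(header)), header))
    return(out)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  n_bad <- which(lengths(parts) != length(header))
  if (length(n_bad))
    stop("'", path, "' line ", n_bad[1] + 1L, ": expected ",
         length(header), " fields, found ", lengths(parts)[n_bad[1]],
         call. = FALSE)
  out <- as.data.frame(lapply(seq_along(header), function(j) {
    vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), j)))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("'", path, "' line ", bad[1] + 1L, ": malformed value in column '",
           header[j], "'", call. = FALSE)
    vals
  }))
  names(out) <- header
  out
}

#' Write / read a density dataset
#'
#' CSV schema `sigma_C,sigma_H,eps_C,eps_H,density,valid` (units nm, nm,
#' kJ/mol, kJ/mol, kg/m^3; `valid` coded 0/1).  Numeric values round-trip
#' at 15 significant digits.
#'
#' @param ds a `density_dataset`.
#' @param path file path.
#' @param name dataset label used on read; defaults to the file stem.
#' @return `write_density_dataset` returns `path` invisibly;
#'   `read_density_dataset` returns the `density_dataset`.
#' @export
write_density_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "density_dataset"))
  lines <- c(paste(.dataset_cols, collapse = ","),
             paste(fmt_num(ds$sigma_C), fmt_num(ds$sigma_H),
                   fmt_num(ds$eps_C), fmt_num(ds$eps_H),
                   fmt_num(ds$density), as.integer(ds$valid), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_density_dataset
#' @export
read_density_dataset <- function(path,
                                 name = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_checked_csv(path, .dataset_cols)
  bad <- which(!df$valid %in% c(0, 1))
  if (length(bad))
    stop("'", path, "' line ", bad[1] + 1L,
         ": 'valid' must be 0 or 1", call. = FALSE)
  df$valid <- df$valid == 1
  density_dataset(df, name = name)
}

#' Read a pipeline run configuration
#'
#' Structured YAML with one block per stage (`space`, `sampling`,
#' `oracle`, `preprocess`, `conformers`, `harness`, `selection`,
#' `optimizer`, `verify`) plus a global `seed` from which every
#' stochastic stage derives its own stream unless that stage overrides
#' it.  Two presets ship with the package: `"desk"` (reduced scale, the
#' default working setup) and `"paper"` (full-scale plan bookkeeping).
#'
#' @param path YAML file path, or a preset name.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    preset <- system.file("extdata", paste0(path, ".yaml"),
                          package = "smaopt")
    if (nzchar(preset)) path <- preset
    else stop("config file or preset '", path, "' not found", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  for (block in c("space", "sampling", "harness", "optimizer"))
    if (is.null(cfg[[block]]))
      stop("config is missing the '", block, "' block", call. = FALSE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$space <- parameter_space(cfg$space$names, cfg$space$lower,
                               cfg$space$upper)
  class(cfg) <- "run_config"
  cfg
}

#' Build the sample sets declared in a config
#'
#' @param cfg a `run_config`.
#' @return Named list of parameter data frames, one per declared dataset.
#' @export
config_samples <- function(cfg) {
  out <- list()
  for (d in cfg$sampling$datasets) {
    pts <- switch(d$strategy,
      grid = make_grid(grid_spec(d$min, d$step, d$max,
                                 names = cfg$space$names)),
      sobol = {
        sp <- if (!is.null(d$lower))
          parameter_space(cfg$space$names, d$lower, d$upper) else cfg$space
        make_sobol(sp, d$m,
                   scramble_seed = d$scramble_seed)
      },
      stop("unknown sampling strategy '", d$strategy, "'", call. = FALSE))
    out[[d$name]] <- pts
  }
  out
}
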