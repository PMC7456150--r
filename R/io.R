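#' Write / read a landscape grid as self-describing text
#'
#' Grids are serialised as a CSV long table (one row per cell, column-major
#' order) preceded by `#`-comment header lines carrying the grid shape and
#' cell area. Missing cells (e.g. masked ocean) are written as `NA` and
#' preserved on read. Values round-trip at full double precision.
#'
#' @param grid a [landscape_grid] object.
#' @param path output file path.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns a
#'   [landscape_grid].
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "landscape_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# landscape_grid nrow=%d ncol=%d cell_area=%.10g",
            grid$nrow, grid$ncol, grid$cell_area)), con)
  df <- data.frame(maat = grid$maat,
                   peat_fraction = grid$peat_fraction,
                   permafrost_fraction = grid$permafrost_fraction,
                   peat_depth = grid$peat_depth,
                   c_storage = grid$c_storage,
                   n_storage = grid$n_storage,
                   biome_class = grid$biome_class,
                   minero_frac = grid$minero_frac,
                   ombro_frac = grid$ombro_frac)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# landscape_grid"))
    stop("unknown grid format: ", path)
  get_num <- function(key) {
    m <- regmatches(header, regexpr(paste0(key, "=[-0-9.eE+]+"), header))
    if (!length(m)) stop("grid header missing required field '", key, "'")
    as.numeric(sub(paste0(key, "="), "", m))
  }
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("maat", "peat_fraction", "permafrost_fraction", "peat_depth",
            "c_storage", "n_storage", "biome_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("grid file missing required variable(s): ",
         paste(miss, collapse = ", "))
  structure(list(nrow = as.integer(get_num("nrow")),
                 ncol = as.integer(get_num("ncol")),
                 cell_area = get_num("cell_area"),
                 maat = df$maat, peat_fraction = df$peat_fraction,
                 permafrost_fraction = df$permafrost_fraction,
                 peat_depth = df$peat_depth, c_storage = df$c_storage,
                 n_storage = df$n_storage, biome_class = df$biome_class,
                 minero_frac = if (is.null(df$minero_frac))
                   rep(NA_real_, nrow(df)) else df$minero_frac,
                 ombro_frac = if (is.null(df$ombro_frac))
                   rep(NA_real_, nrow(df)) else df$ombro_frac),
            class = "landscape_grid")
}

#' Write / read peat cores as CSV
#'
#' Header: `site_id,depth_cm,oc_pct,bulk_density,n_pct,c_storage,
#' n_storage,maat,permafrost`.
#'
#' @param cores a `peat_cores` data frame.
#' @param path file path.
#' @export
write_cores <- function(cores, path) {
  stopifnot(is.data.frame(cores))
  utils::write.csv(cores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cores
#' @export
read_cores <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("peat_cores", "data.frame")
  out
}

#' Write a stock summary as CSV
#'
#' One row per peatland class, mirroring the standard inventory table
#' layout.
#'
#' @param summary a `stock_summary` object.
#' @param path file path.
#' @export
write_stock_summary <- function(summary, path) {
  df <- cbind(class = rownames(summary), as.data.frame(summary))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a thaw scenario as tidy CSV
#'
#' Writes the annual series in long form (`year`, `variable`, `value`)
#' plus a one-row cumulative summary CSV alongside (suffix
#' `_summary.csv`). Flux sign convention (positive = emission) is recorded
#' in a comment header.
#'
#' @param scenario a `thaw_scenario` object.
#' @param path file path for the annual series.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "thaw_scenario"))
  s <- scenario$series
  long <- do.call(rbind, lapply(setdiff(names(s), "year"), function(v)
    data.frame(year = s$year, variable = v, value = s[[v]])))
  con <- file(path, "w")
  writeLines(sprintf(
    "# thaw scenario +%.1fC; sign convention: positive = emission",
    scenario$warming), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  close(con)
  sm <- as.data.frame(scenario$totals)
  utils::write.csv(cbind(warming = scenario$warming, sm),
                   sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The full parameter tree of the pipeline as a named list, mirroring the
#' shipped YAML (`system.file("extdata", "default_config.yml", package =
#' "peatthaw")`), which documents the provenance of every default.
#'
#' @return nested named list with sections `synth`, `stocks`, `curve`,
#'   `fluxes`, `thaw`, `forcing`, `seeds`.
#' @export
default_run_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yml",
                              package = "peatthaw"))
}

#' Read and validate a run configuration
#'
#' Unknown keys (at any nesting level present in the default schema) are
#' rejected with an error naming the offending key; recognised keys
#' override the defaults.
#'
#' @param path path to a YAML file.
#' @return validated nested list merged over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_checked(default_run_config(), user, "config")
}

merge_checked <- function(def, user, where) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key '", where, "$", unknown[1], "'")
  for (nm in names(user))
    def[[nm]] <- if (is.list(def[[nm]]))
      merge_checked(def[[nm]], user[[nm]], paste0(where, "$", nm))
    else user[[nm]]
  def
}
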