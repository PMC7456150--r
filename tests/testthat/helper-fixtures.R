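# Shared fixtures: built in code, cached per test file.

.fixture_env <- new.env(parent = emptyenv())

# The default study landscape (500x500, seed 1); generated once per file.
default_landscape <- function() {
  if (is.null(.fixture_env$grid))
    .fixture_env$grid <- generate_landscape(synth_config())
  .fixture_env$grid
}

# A small, fast landscape for structural tests.
small_config <- function(seed = 7, ...) {
  synth_config(nrow = 40, ncol = 30, cell_area = 100, seed = seed, ...)
}

small_landscape <- function(seed = 7, ...) {
  generate_landscape(small_config(seed = seed, ...))
}

# Hand-built grid with fully controlled fields.
make_grid <- function(maat, peat_fraction, permafrost_fraction = 0,
                      peat_depth = 100, c_storage = 100, n_storage = 3,
                      cell_area = 100, biome_class = "boreal",
                      minero_frac = 0.5) {
  n <- length(maat)
  rep_n <- function(x) rep_len(x, n)
  structure(list(
    nrow = n, ncol = 1L, cell_area = cell_area,
    maat = maat, peat_fraction = rep_n(peat_fraction),
    permafrost_fraction = rep_n(permafrost_fraction),
    peat_depth = rep_n(peat_depth), c_storage = rep_n(c_storage),
    n_storage = rep_n(n_storage), biome_class = rep_n(biome_class),
    minero_frac = rep_n(minero_frac),
    ombro_frac = rep_n(1 - minero_frac)),
    class = "landscape_grid")
}

# Restrict a landscape to a subset of cells (for partition properties).
subset_grid <- function(grid, idx) {
  fields <- c("maat", "peat_fraction", "permafrost_fraction",
              "peat_depth", "c_storage", "n_storage", "biome_class",
              "minero_frac", "ombro_frac")
  for (f in fields) grid[[f]] <- grid[[f]][idx]
  grid$nrow <- length(idx); grid$ncol <- 1L
  grid
}

# Uniform flux table: every stage/type cell carries the same values.
uniform_flux_table <- function(co2 = 0, ch4 = 0, n2o = 0,
                               lateral_c = 0, lateral_n = 0) {
  tab <- default_stage_flux_table()
  tab$co2 <- co2; tab$ch4 <- ch4; tab$n2o <- n2o
  tab$lateral_c <- lateral_c; tab$lateral_n <- lateral_n
  validate_flux_table(tab)
}
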