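# Shared fixtures.  Models and grid runs are expensive enough to build
# once per test session; everything here is deterministic.

model_cache <- new.env(parent = emptyenv())

cached_model <- function(ih_mode) {
  key <- paste0("model_", ih_mode)
  if (is.null(model_cache[[key]]))
    model_cache[[key]] <- build_model(ih_mode)
  model_cache[[key]]
}

cached_rest <- function(ih_mode) {
  key <- paste0("rest_", ih_mode)
  if (is.null(model_cache[[key]]))
    model_cache[[key]] <- resting_state(cached_model(ih_mode))
  model_cache[[key]]
}

# A passive, electrically isolated cell: active densities zeroed and the
# axial resistivity made effectively infinite, so each compartment is an
# independent RC circuit with known R and C.
isolated_passive_model <- function(g_leak = 0.1, e_leak = -70) {
  build_model("none", passive = list(density_scale = 0, g_leak = g_leak,
                                     e_leak = e_leak, ra = 1e9))
}

# The full 18-run grid at reduced duration (4 theta cycles analyzed),
# computed once.
cached_grid <- function() {
  if (is.null(model_cache$grid))
    model_cache$grid <- run_grid(cycles = 4)
  model_cache$grid
}
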