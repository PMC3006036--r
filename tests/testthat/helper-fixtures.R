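# Shared fixture cache: expensive scenes and maps are built once per suite
# run and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_fixture <- function(name, ...) {
  cached(paste0("fx_", name), make_fixture(name, ...))
}

# full pipeline result on the clean b8mer fixture (used by several files)
get_b8_pipeline <- function() {
  cached("b8_pipeline", {
    fx <- get_fixture("b8mer")
    run_pipeline(fx$map, reference = fx$ref)
  })
}

# a small noise-free map with a single isotropic Gaussian peak
gaussian_peak_map <- function(centre = c(5, 5, 5), cell_len = 10,
                              spacing = 0.5, sd_atom = 0.9, height = 5) {
  cell <- unit_cell(cell_len)
  n <- as.integer(round(cell_len / spacing))
  ax <- (seq_len(n) - 1) * spacing
  gx <- outer(outer(exp(-(ax - centre[1])^2 / (2 * sd_atom^2)),
                    exp(-(ax - centre[2])^2 / (2 * sd_atom^2))),
              exp(-(ax - centre[3])^2 / (2 * sd_atom^2)))
  m <- density_grid(array(height * gx, c(n, n, n)), cell, normalized = TRUE)
  m
}

expect_within <- function(x, lo, hi) {
  expect_true(x >= lo && x <= hi,
              label = sprintf("%.4g in [%.4g, %.4g]", x, lo, hi))
}
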