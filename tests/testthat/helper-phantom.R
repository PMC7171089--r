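# shared fixtures, built once per test run

# default-geometry phantom base (no deformation applied)
base_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- devbrainmap:::phantom_base(phantom_spec())
    cache
  }
})

# small phantom for geometry-light tests
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(24, 24, 12), deformation_um = 0,
               age_scale = 1, ...)
}

# light registration settings for unit tests (full defaults are exercised in
# the acceptance suite)
light_reg <- function(...) {
  registration_config(affine_levels = 2, bspline_levels = 2,
                      iterations = c(40, 15), ...)
}

# brute-force step-up BH oracle, independent of the package path
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
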