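# Shared fixtures: the baseline homeostatic vessel is expensive enough to
# build once per test run.
test_baseline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- init_homeostatic(vessel_params())
    cache
  }
})

# Finite-difference derivative of f at x with a centred stencil.
fd_central <- function(f, x, h = 1e-6 * max(abs(x), 1)) {
  (f(x + h) - f(x - h)) / (2 * h)
}
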