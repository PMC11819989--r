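# shared fixtures for the test suite

# the half-and-half unit material used in worked examples:
# equal phases, unit stress scales, I1-exponents only
unit_params <- function() {
  material_params(c1 = 1, c2 = 1, c3 = 1, c4 = 0, c5 = 1, c6 = 0, vf = 0.5)
}

# a random admissible parameter set; coefficient magnitudes bounded so the
# exponents stay representable on the tested stretch range
draw_params <- function(cmax = 50) {
  material_params(
    c1 = stats::runif(1, -cmax, cmax), c2 = stats::runif(1, -cmax, cmax),
    c3 = stats::runif(1, -cmax, cmax), c4 = stats::runif(1, -cmax, cmax),
    c5 = stats::runif(1, -cmax, cmax), c6 = stats::runif(1, -cmax, cmax),
    vf = stats::runif(1, 0.3, 0.8)
  )
}

draw_stretch <- function(n = 1) stats::runif(n, 1.001, 1.25)
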