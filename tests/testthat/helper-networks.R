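## Shared builders for small test networks and designs.

slow_rates <- function() rate_preset("multilipoplex_slow")

ref_net <- function(variant = "multilipoplex",
                    preset = "multilipoplex_slow", ...) {
  r <- rate_preset(preset)
  build_network(variant, r, reference_design(r, ...))
}

## rates with everything switched off except the named ones
only_rates <- function(...) {
  on <- list(...)
  args <- list(k_A = 0, k_E = 0, k_L = 0, d_E = 0, k_M = 0, k_TL = 0,
               d_M = 0, d_G = 0, k_U = 0, d_L = 0, k_W = 0)
  args[names(on)] <- on
  do.call(rate_constants, args)
}

## independent ODE oracle for the expression cascade (stiff integration)
cascade_ode <- function(m0, t0, rates, times, maturation = TRUE) {
  rhs <- if (maturation) function(t, x, p)
    list(c(-rates$d_M * x[1],
           rates$k_TL * x[1] - (rates$k_M + rates$d_G) * x[2],
           rates$k_M * x[2] - rates$d_G * x[3]))
  else function(t, x, p)
    list(c(-rates$d_M * x[1], 0, rates$k_TL * x[1] - rates$d_G * x[3]))
  out <- deSolve::lsoda(c(M = m0, G = 0, Gs = 0), c(t0, times[times > t0]),
                        rhs, NULL, rtol = 1e-10, atol = 1e-8)
  approx(out[, 1], out[, "Gs"], xout = times, yleft = 0, rule = 2)$y
}
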