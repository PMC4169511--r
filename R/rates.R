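#' Kinetic rate constants of the transfection model
#'
#' Bundles the eleven first-order rate constants of the delivery and
#' expression chain.  All rates are per hour.  Five of them (`k_A`, `k_E`,
#' `k_L`, `d_E`, `k_M`) are the free parameters of the model; the remainder
#' are fixed, either to literature values (`k_TL`, `d_M`, `d_G`) or to
#' limiting values that make unpacking effectively immediate (`k_U` large)
#' and internal lipoplex degradation negligible (`d_L` small).
#'
#' @param k_A attachment rate of external lipoplexes to the cell surface (1/h).
#' @param k_E endocytosis rate of clathrin-coated pits (1/h).
#' @param k_L endosomal lysis rate (1/h).
#' @param d_E endosome degradation rate (1/h); a catch-all for endosomes that
#'   are never observed to lyse, including intra-endosomal mRNA decay.
#' @param k_M GFP maturation (folding + oxidation) rate (1/h).
#' @param k_TL translation rate per mRNA (proteins/(mRNA h)).
#' @param d_M mRNA degradation rate (1/h).
#' @param d_G degradation rate of both immature and mature GFP (1/h).
#' @param k_U lipoplex unpacking rate (1/h); large by default so release of
#'   mRNA from a cytosolic lipoplex is effectively instantaneous.
#' @param d_L degradation rate of internal (cytosolic) lipoplexes (1/h).
#' @param k_W washing rate applied to external lipoplexes after the
#'   incubation time (1/h); zero before `t_inc`, `k_W` afterwards.
#'
#' @return An object of class `rate_constants` (a named list).
#' @seealso [rate_preset()] for the published parameter sets.
#' @export
#' @examples
#' rate_constants(k_A = 0.27, k_E = 0.81, k_L = 0.11, d_E = 0.67, k_M = 5.5)
rate_constants <- function(k_A, k_E, k_L, d_E, k_M,
                           k_TL = 170, d_M = 0.062, d_G = 0.056,
                           k_U = 1e6, d_L = 1e-6, k_W = 1e6) {
  r <- list(k_A = k_A, k_E = k_E, k_L = k_L, d_E = d_E, k_M = k_M,
            k_TL = k_TL, d_M = d_M, d_G = d_G, k_U = k_U, d_L = d_L,
            k_W = k_W)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate constant '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  structure(r, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Transfection rate constants (1/h; k_TL in proteins/(mRNA h)):\n")
  print(unlist(x))
  invisible(x)
}

.preset_table <- list(
  streamlined_slow =
    list(k_A = 0.03, k_E = 0.8,  k_L = 0.065, d_E = 0.65, k_M = 5.5),
  multilipoplex_fast =
    list(k_A = 0.26, k_E = 0.73, k_L = 0.10,  d_E = 0.60, k_M = 9.23),
  multilipoplex_slow =
    list(k_A = 0.27, k_E = 0.81, k_L = 0.11,  d_E = 0.67, k_M = 5.5)
)

#' Published rate-constant presets
#'
#' Returns one of the three published parameter columns: the streamlined
#' model with slow maturation, the multiple-lipoplex model with the fast
#' (literature) maturation rate, or the multiple-lipoplex model with the
#' slow (optimised) maturation rate.  The fixed rates (`k_TL = 170`,
#' `d_M = 0.062`, `d_G = 0.056`, `k_U = 1e6`, `d_L = 1e-6`) are shared by
#' all presets.
#'
#' @param name one of `"streamlined_slow"`, `"multilipoplex_fast"`,
#'   `"multilipoplex_slow"`.
#' @return A [rate_constants] object.
#' @export
rate_preset <- function(name = c("multilipoplex_slow", "multilipoplex_fast",
                                 "streamlined_slow")) {
  name <- match.arg(name)
  do.call(rate_constants, .preset_table[[name]])
}

#' Experiment design: dose, incubation, lipoplex size, capacity, horizon
#'
#' @param L_ex0 initial number of external lipoplexes per cell (a
#'   dimensionless count acting as the dose proxy).
#' @param t_inc incubation time before the wash (h).
#' @param t_end simulation horizon (h).
#' @param S number of mRNA molecules per lipoplex.
#' @param N_max maximum number of lipoplexes per pit/endosome.
#' @param dt_out output sampling interval (h).
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design(L_ex0 = 25, t_inc = 1, t_end = 30)
experiment_design <- function(L_ex0, t_inc = 1, t_end = 30, S = 350,
                              N_max = 10, dt_out = 0.1) {
  d <- list(L_ex0 = L_ex0, t_inc = t_inc, t_end = t_end, S = S,
            N_max = N_max, dt_out = dt_out)
  for (nm in names(d))
    if (!is.numeric(d[[nm]]) || length(d[[nm]]) != 1L || is.na(d[[nm]]))
      stop("design field '", nm, "' must be a single number", call. = FALSE)
  if (L_ex0 < 0) stop("L_ex0 must be >= 0", call. = FALSE)
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  if (N_max < 1) stop("N_max must be >= 1", call. = FALSE)
  if (t_inc < 0 || t_inc > t_end)
    stop("need 0 <= t_inc <= t_end", call. = FALSE)
  if (dt_out <= 0) stop("dt_out must be > 0", call. = FALSE)
  d$S <- as.integer(round(S)); d$N_max <- as.integer(round(N_max))
  structure(d, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Experiment design: L_ex0 = %g, t_inc = %g h, t_end = %g h, S = %d,\n",
    x$L_ex0, x$t_inc, x$t_end, x$S))
  cat(sprintf("  N_max = %d, dt_out = %g h\n", x$N_max, x$dt_out))
  invisible(x)
}

#' Calibrate the reference dose to a target mean number of attachments
#'
#' The total attachment propensity is `k_A * L_ex` independently of the pit
#' population, so the expected cumulative number of attachments over the
#' incubation is `L_ex0 * (1 - exp(-k_A * t_inc))`.  This solves for the
#' initial external lipoplex count that yields a given mean number of
#' lipoplexes adhering to each cell (6 for the reference design).
#'
#' @param rates a [rate_constants] object (only `k_A` is used).
#' @param target_attached desired mean number of attached lipoplexes per cell.
#' @param t_inc incubation time (h).
#' @return The calibrated `L_ex0` (not rounded; per-cell initial counts are
#'   rounded by the simulation engines).
#' @export
#' @examples
#' calibrate_dose(rate_preset("multilipoplex_slow"))
calibrate_dose <- function(rates, target_attached = 6, t_inc = 1) {
  stopifnot(inherits(rates, "rate_constants"), target_attached >= 0)
  p <- 1 - exp(-rates$k_A * t_inc)
  if (p <= 0) stop("k_A * t_inc must be positive to calibrate a dose",
                   call. = FALSE)
  target_attached / p
}

#' Reference design for a preset: dose calibrated to 6 attached lipoplexes
#'
#' Convenience wrapper combining [calibrate_dose()] and
#' [experiment_design()] with the default incubation (1 h), horizon (30 h),
#' lipoplex size (350 mRNA) and pit capacity (10).
#'
#' @inheritParams calibrate_dose
#' @param ... passed on to [experiment_design()].
#' @export
reference_design <- function(rates, target_attached = 6, ...) {
  args <- list(...)
  t_inc <- if (!is.null(args$t_inc)) args$t_inc else 1
  do.call(experiment_design,
          c(list(L_ex0 = calibrate_dose(rates, target_attached, t_inc)),
            args))
}
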