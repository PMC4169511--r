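## Simulated-annealing estimation of the five free rates against the five
## experimental determinants: mean number of attached lipoplexes, the
## dose-response curve, the mean and width of the onset-time distribution,
## and the mean maximum GFP level.

.free_params <- c("k_A", "k_E", "k_L", "d_E", "k_M")

#' Compute the five optimisation determinants for a parameter set
#'
#' Builds the multiple-lipoplex network for the given free rates, runs a
#' hybrid ensemble at the reference dose and a delivery-only dose sweep,
#' fits every transfected cell's GFP trace, and summarises.
#'
#' @param params named vector with `k_A`, `k_E`, `k_L`, `d_E`, `k_M` (1/h).
#' @param design an [experiment_design]; `L_ex0` is the experimentally fixed
#'   reference dose and is *not* recalibrated per candidate.
#' @param n_cells cells for the reference ensemble; each dose point of the
#'   sweep uses `ceiling(n_cells * dose_n_frac)` cells.
#' @param seed master seed.
#' @param dose_grid relative doses of the sweep.
#' @param dose_n_frac fraction of `n_cells` per dose point.
#' @param fixed a [rate_constants]-style list supplying the fixed rates.
#' @param maturation passed to [fit_onset_batch()]; the default mirrors the
#'   single-cell analysis convention (maturation absorbed into onset).
#' @return A list of class `goal_summary` with `mean_attached`,
#'   `dose_response` (TE per grid point), `onset_mean`, `onset_width`,
#'   `mean_maxgfp`, plus `te_ref` and `converged_fraction` diagnostics.
#' @export
compute_goals <- function(params, design, n_cells = 1000, seed = 1,
                          dose_grid = c(0.25, 0.5, 1, 2, 4),
                          dose_n_frac = 0.4, fixed = NULL,
                          maturation = FALSE) {
  params <- params[.free_params]
  if (anyNA(params)) stop("params must name ", paste(.free_params,
                                                     collapse = ", "),
                          call. = FALSE)
  args <- as.list(params)
  if (!is.null(fixed))
    args <- c(args, fixed[setdiff(names(fixed), c(.free_params, "k_W"))])
  rates <- do.call(rate_constants, args)
  net <- build_network("multilipoplex", rates, design)
  ens <- simulate_ensemble(net, n_cells, seed, engine = "hybrid")

  tf <- ens$cells$transfected
  onset_mean <- onset_width <- mean_maxgfp <- NA_real_
  convf <- 0
  if (sum(tf) >= 2) {
    fits <- fit_onset_batch(ens$gfp[, tf, drop = FALSE], ens$times,
                            rates, maturation = maturation)
    convf <- mean(fits$converged)
    if (sum(fits$converged) >= 2) {
      od <- onset_distribution(fits)
      onset_mean <- od$location; onset_width <- od$width
      mean_maxgfp <- mean(fits$maxgfp[fits$converged])
    }
  }
  dr <- dose_response(rates, design, dose_grid,
                      n_cells = ceiling(n_cells * dose_n_frac),
                      seed = derive_seeds(seed, 1, stream = 11),
                      variant = "multilipoplex")
  structure(list(mean_attached = mean(ens$cells$n_attached),
                 dose_response = setNames(dr$TE, paste0("d", dr$dose)),
                 onset_mean = onset_mean, onset_width = onset_width,
                 mean_maxgfp = mean_maxgfp,
                 te_ref = transfection_efficiency(ens),
                 converged_fraction = convf,
                 dose_grid = dose_grid, params = params),
            class = "goal_summary")
}

#' @export
print.goal_summary <- function(x, ...) {
  cat(sprintf(
    "Goals: mean attached %.2f | onset %.2f +/- %.2f h | mean maxGFP %.4g\n",
    x$mean_attached, x$onset_mean, x$onset_width, x$mean_maxgfp))
  cat("  TE(dose):", paste(sprintf("%s=%.3f", names(x$dose_response),
                                   x$dose_response), collapse = " "), "\n")
  invisible(x)
}

#' Weighted squared-relative-deviation objective
#'
#' Equal-weight sum of squared relative deviations over the five
#' determinants; the dose-response term is the mean squared TE deviation
#' across the grid (TE is already dimensionless and bounded).  Zero if and
#' only if all determinants match.
#'
#' @param goals,targets `goal_summary` objects (or plain lists with the same
#'   five fields).
#' @param weights named weights for `mean_attached`, `dose_response`,
#'   `onset_mean`, `onset_width`, `mean_maxgfp`.
#' @return Non-negative score.
#' @export
objective <- function(goals, targets,
                      weights = c(mean_attached = 1, dose_response = 1,
                                  onset_mean = 1, onset_width = 1,
                                  mean_maxgfp = 1)) {
  need <- c("mean_attached", "dose_response", "onset_mean", "onset_width",
            "mean_maxgfp")
  if (!all(need %in% names(targets)) || any(vapply(targets[need], is.null,
                                                   TRUE)))
    stop("targets must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(goals$dose_response) != length(targets$dose_response))
    stop("dose grids of goals and targets differ", call. = FALSE)
  rel2 <- function(g, t) if (is.na(g)) 10 else ((g - t) / t)^2
  s <- weights[["mean_attached"]] * rel2(goals$mean_attached,
                                         targets$mean_attached) +
    weights[["dose_response"]] *
      mean((goals$dose_response - targets$dose_response)^2) +
    weights[["onset_mean"]] * rel2(goals$onset_mean, targets$onset_mean) +
    weights[["onset_width"]] * rel2(goals$onset_width,
                                    targets$onset_width) +
    weights[["mean_maxgfp"]] * rel2(goals$mean_maxgfp,
                                    targets$mean_maxgfp)
  unname(s)
}

#' Configuration for simulated annealing
#'
#' @param init named start values for the five free rates (1/h).
#' @param lower,upper named bounds; defaults span the literature ranges
#'   (1e-3–10/h for the delivery rates, 0.5–20/h for `k_M`).
#' @param t0 initial temperature; `NULL` sets it to the median absolute
#'   score change of 20 pilot proposals.
#' @param cooling geometric cooling factor per step, in (0, 1).
#' @param steps number of annealing steps.
#' @param sigma log-space Gaussian proposal SD.
#' @param n_cells ensemble size per evaluation (>= 100).
#' @param seed master seed.
#' @param design experiment design (reference dose fixed).
#' @param dose_grid relative doses used by [compute_goals()].
#' @export
anneal_config <- function(init, lower = NULL, upper = NULL, t0 = NULL,
                          cooling = 0.95, steps = 300, sigma = 0.2,
                          n_cells = 1000, seed = 1, design,
                          dose_grid = c(0.25, 0.5, 1, 2, 4)) {
  if (is.null(lower))
    lower <- c(k_A = 1e-3, k_E = 1e-3, k_L = 1e-3, d_E = 1e-3, k_M = 0.5)
  if (is.null(upper))
    upper <- c(k_A = 10, k_E = 10, k_L = 10, d_E = 10, k_M = 20)
  init <- init[.free_params]; lower <- lower[.free_params]
  upper <- upper[.free_params]
  stopifnot(!anyNA(init), all(lower > 0), all(init >= lower),
            all(init <= upper), cooling > 0, cooling < 1, n_cells >= 100)
  list(init = init, lower = lower, upper = upper, t0 = t0,
       cooling = cooling, steps = steps, sigma = sigma, n_cells = n_cells,
       seed = seed, design = design, dose_grid = dose_grid)
}

## Boltzmann acceptance rule: always accept improvements, accept a
## worsening of size delta with probability exp(-delta/temp).
.metropolis_accept <- function(delta, temp) {
  delta <= 0 || (temp > 0 && runif(1) < exp(-delta / temp))
}

## Reflecting log-space Gaussian proposal inside [lower, upper].
.propose <- function(par, sigma, lower, upper) {
  lp <- log(par) + rnorm(length(par), 0, sigma)
  lo <- log(lower); up <- log(upper)
  for (i in seq_along(lp)) {
    w <- up[i] - lo[i]
    x <- (lp[i] - lo[i]) %% (2 * w)
    lp[i] <- lo[i] + if (x > w) 2 * w - x else x
  }
  setNames(exp(lp), names(par))
}

#' Simulated-annealing estimation of the five free rates
#'
#' Metropolis acceptance with probability `min(1, exp(-delta/T))`, geometric
#' cooling, log-space Gaussian proposals reflected at the bounds.  Every
#' evaluation uses a fresh sub-seed so the optimiser cannot overfit one
#' stochastic realisation; the returned best candidate is re-evaluated at
#' `final_n_cells`.
#'
#' @param config an [anneal_config()].
#' @param targets target determinants (a `goal_summary` or a list with the
#'   same five fields).
#' @param final_n_cells ensemble size for the final re-evaluation of the
#'   best candidate.
#' @param verbose print progress every 25 steps.
#' @return An object of class `anneal_result`: `best_params`, `best_score`,
#'   `final_goals`, `trace` (step, temperature, score, accepted),
#'   `n_evaluations`.
#' @export
anneal <- function(config, targets, final_n_cells = 5000, verbose = FALSE) {
  cf <- config
  set.seed(cf$seed)
  eval_seed <- function(k) derive_seeds(cf$seed, 1, stream = 100 + k)
  score_of <- function(par, k) {
    g <- compute_goals(par, cf$design, n_cells = cf$n_cells,
                       seed = eval_seed(k), dose_grid = cf$dose_grid)
    objective(g, targets)
  }
  par <- cf$init
  s_cur <- score_of(par, 0)
  n_eval <- 1L

  t0 <- cf$t0
  if (is.null(t0)) {
    pil <- numeric(20)
    for (k in 1:20) {
      pp <- .propose(par, cf$sigma, cf$lower, cf$upper)
      pil[k] <- abs(score_of(pp, 1000 + k) - s_cur)
      n_eval <- n_eval + 1L
    }
    t0 <- max(stats::median(pil), 1e-8)
  }

  best_par <- par; best_s <- s_cur
  temp <- t0
  tr <- data.frame(step = integer(cf$steps), temperature = numeric(cf$steps),
                   score = numeric(cf$steps), accepted = logical(cf$steps))
  for (k in seq_len(cf$steps)) {
    prop <- .propose(par, cf$sigma, cf$lower, cf$upper)
    s_new <- score_of(prop, k)
    n_eval <- n_eval + 1L
    accept <- .metropolis_accept(s_new - s_cur, temp)
    if (accept) { par <- prop; s_cur <- s_new }
    if (s_cur < best_s) { best_s <- s_cur; best_par <- par }
    tr[k, ] <- list(k, temp, s_cur, accept)
    temp <- temp * cf$cooling
    if (verbose && k %% 25 == 0)
      message(sprintf("step %d  T=%.3g  score=%.4g  best=%.4g", k, temp,
                      s_cur, best_s))
  }
  final <- compute_goals(best_par, cf$design, n_cells = final_n_cells,
                         seed = eval_seed(-1), dose_grid = cf$dose_grid)
  structure(list(best_params = best_par, best_score = best_s,
                 final_goals = final, trace = tr, n_evaluations = n_eval,
                 t0 = t0, config = cf),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat("Simulated-annealing fit of the five free rates (1/h):\n")
  print(signif(x$best_params, 4))
  cat(sprintf("  best score %.4g after %d evaluations (T0 = %.3g)\n",
              x$best_score, x$n_evaluations, x$t0))
  invisible(x)
}
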