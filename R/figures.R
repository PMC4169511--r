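## Figure-reproduction pipelines.  Every command first computes the
## underlying tables (so everything runs headless); plotting is a
## convenience layer on top.

.fig_ens <- function(variant, preset, n_cells, seed, stream = 0,
                     expression = TRUE, design = NULL) {
  rates <- rate_preset(preset)
  if (is.null(design)) design <- reference_design(rates)
  net <- build_network(variant, rates, design)
  simulate_ensemble(net, n_cells, seed, expression = expression,
                    stream = stream)
}

.mean_maxgfp <- function(ens) {
  tf <- ens$cells$transfected
  if (sum(tf) < 2) return(NA_real_)
  fits <- fit_onset_batch(ens$gfp[, tf, drop = FALSE], ens$times, ens$rates)
  mean(fits$maxgfp[fits$converged])
}

#' Reproduce the published result figures at configurable scale
#'
#' Runs the pipeline behind each result figure and returns its underlying
#' tables: deterministic-vs-stochastic time courses (`fig3`), an ensemble
#' of GFP traces (`fig4`), onset-time distributions for the slow and fast
#' maturation presets (`fig5`), maximum-GFP lognormal summaries for both
#' model variants (`fig6a`), the dose-response sweep with single- and
#' double-Poissonian fits (`fig6b`), and the predictive sweeps over
#' incubation time (`fig7a`), endosome degradation rate (`fig7b`), lysis
#' rate (`fig7c`) and lipoplex size at constant total mRNA (`fig7d`).
#'
#' @param which one of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6a"`, `"fig6b"`,
#'   `"fig7a"`, `"fig7b"`, `"fig7c"`, `"fig7d"`.
#' @param n_cells ensemble size per condition.
#' @param seed master seed.
#' @param plot draw a base-graphics rendition as a side effect.
#' @return A list with the computed tables (and fit objects where
#'   relevant).
#' @export
reproduce_figures <- function(which = c("fig3", "fig4", "fig5", "fig6a",
                                        "fig6b", "fig7a", "fig7b", "fig7c",
                                        "fig7d"),
                              n_cells = 500, seed = 1, plot = FALSE) {
  which <- match.arg(which)
  rates <- rate_preset("multilipoplex_slow")
  design <- reference_design(rates)
  out <- switch(which,
    fig3 = {
      net <- build_network("multilipoplex", rates, design)
      ode <- simulate_deterministic(net)
      ssa <- simulate_ssa(net, seed = derive_seeds(seed, 1), budget = 1e8)
      list(ode = data.frame(time_h = ode$times, ode$observables),
           ssa = data.frame(time_h = ssa$times, ssa$observables))
    },
    fig4 = {
      ens <- .fig_ens("multilipoplex", "multilipoplex_slow",
                      min(n_cells, 100), seed)
      list(times = ens$times, gfp = ens$gfp)
    },
    fig5 = {
      res <- lapply(c(slow = "multilipoplex_slow",
                      fast = "multilipoplex_fast"), function(p) {
        ens <- .fig_ens("multilipoplex", p, n_cells, seed,
                        stream = if (p == "multilipoplex_slow") 1 else 2)
        tf <- ens$cells$transfected
        fits <- fit_onset_batch(ens$gfp[, tf, drop = FALSE], ens$times,
                                ens$rates)
        list(t0 = fits$t0[fits$converged],
             summary = onset_distribution(fits))
      })
      res
    },
    fig6a = {
      res <- lapply(c(streamlined = "streamlined_slow",
                      multilipoplex = "multilipoplex_slow"), function(p) {
        variant <- if (p == "streamlined_slow") "streamlined" else
          "multilipoplex"
        ens <- .fig_ens(variant, p, n_cells, seed,
                        stream = if (variant == "streamlined") 3 else 4)
        tf <- ens$cells$transfected
        fits <- fit_onset_batch(ens$gfp[, tf, drop = FALSE], ens$times,
                                ens$rates)
        list(maxgfp = fits$maxgfp[fits$converged],
             summary = maxgfp_distribution(fits))
      })
      res
    },
    fig6b = {
      grid <- c(0.125, 0.25, 0.5, 1, 2, 4, 8)
      res <- lapply(c(streamlined = "streamlined_slow",
                      multilipoplex = "multilipoplex_slow"), function(p) {
        variant <- if (p == "streamlined_slow") "streamlined" else
          "multilipoplex"
        r <- rate_preset(p)
        dr <- dose_response(r, reference_design(r), grid, n_cells,
                            derive_seeds(seed, 1,
                                         stream = if (variant ==
                                                      "streamlined") 5 else 6),
                            variant = variant)
        list(dose_response = dr,
             single = fit_poissonian(dr, "single"),
             double = fit_poissonian(dr, "double"))
      })
      res
    },
    fig7a = {
      grid <- c(0.25, 0.5, 0.75, 1, 1.5, 2)
      rows <- lapply(seq_along(grid), function(k) {
        des <- design; des$t_inc <- grid[k]
        ens <- .fig_ens("multilipoplex", "multilipoplex_slow", n_cells,
                        seed, stream = 20 + k, design = des)
        data.frame(t_inc = grid[k],
                   TE = transfection_efficiency(ens),
                   mean_maxgfp = .mean_maxgfp(ens))
      })
      df <- do.call(rbind, rows)
      fit <- stats::lm(TE ~ t_inc, df)
      list(data = df, linear_fit = fit,
           r_squared = summary(fit)$r.squared)
    },
    fig7b = ,
    fig7c = {
      par_name <- if (which == "fig7b") "d_E" else "k_L"
      base <- rates[[par_name]]
      grid <- base * c(0.25, 0.5, 1, 2, 4)
      rows <- lapply(seq_along(grid), function(k) {
        r <- rates; r[[par_name]] <- grid[k]
        net <- build_network("multilipoplex", r, design)
        ens <- simulate_ensemble(net, n_cells, seed, stream = 40 + k)
        data.frame(value = grid[k], TE = transfection_efficiency(ens),
                   mean_maxgfp = .mean_maxgfp(ens))
      })
      df <- do.call(rbind, rows)
      names(df)[1] <- par_name
      pos <- df$TE > 0
      xx <- df[[par_name]][pos]; ly <- log(df$TE[pos])
      efit <- stats::lm(ly ~ xx)
      list(data = df, exp_fit_r_squared = summary(efit)$r.squared,
           exp_slope = unname(coef(efit)[2]))
    },
    fig7d = {
      sizes <- c(88, 175, 350, 700, 1400)
      rows <- lapply(seq_along(sizes), function(k) {
        des <- design
        des$S <- as.integer(sizes[k])
        des$L_ex0 <- design$L_ex0 * 350 / sizes[k]  # constant total mRNA
        ens <- .fig_ens("multilipoplex", "multilipoplex_slow", n_cells,
                        seed, stream = 60 + k, design = des)
        data.frame(S = sizes[k], TE = transfection_efficiency(ens),
                   mean_maxgfp = .mean_maxgfp(ens))
      })
      list(data = do.call(rbind, rows))
    })
  if (plot) .plot_figure(which, out)
  invisible(out)
}

.plot_figure <- function(which, res) {
  if (which == "fig3") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    for (w in c("attached", "in_endosomes", "mRNA", "mature_gfp")) {
      graphics::plot(res$ode$time_h, res$ode[[w]], type = "l", lty = 3,
                     col = "darkgreen", xlab = "time (h)", ylab = w,
                     ylim = range(res$ode[[w]], res$ssa[[w]]))
      graphics::lines(res$ssa$time_h, res$ssa[[w]], col = "red")
    }
  } else if (which == "fig4") {
    graphics::matplot(res$times, res$gfp, type = "l", lty = 1,
                      col = grDevices::adjustcolor("darkgreen", 0.3),
                      xlab = "time (h)", ylab = "mature GFP")
  } else if (which == "fig5") {
    graphics::hist(res$slow$t0, breaks = 20, freq = FALSE, col = "mistyrose",
                   xlab = "onset time (h)", main = "")
    xx <- seq(0, 12, 0.05)
    graphics::lines(xx, stats::dnorm(xx, res$slow$summary$location,
                                     res$slow$summary$width), col = "red")
    graphics::lines(xx, stats::dnorm(xx, res$fast$summary$location,
                                     res$fast$summary$width), col = "darkgreen",
                    lty = 2)
  } else if (which == "fig6a") {
    graphics::hist(log10(res$multilipoplex$maxgfp), breaks = 20,
                   col = "mistyrose", xlab = "log10 max GFP", main = "")
  } else if (which == "fig6b") {
    m <- res$multilipoplex$dose_response
    graphics::plot(m$dose, m$TE, log = "x", col = "red",
                   xlab = "relative dose", ylab = "TE", ylim = c(0, 1))
    s <- res$streamlined$dose_response
    graphics::points(s$dose, s$TE, pch = 2, col = "darkgreen")
    dd <- exp(seq(log(min(m$dose)), log(max(m$dose)), length.out = 80))
    graphics::lines(dd, predict(res$multilipoplex$double, dd), col = "red")
    graphics::lines(dd, predict(res$streamlined$single, dd),
                    col = "darkgreen", lty = 2)
  } else {
    df <- res$data
    graphics::plot(df[[1]], df$TE, type = "b", col = "red",
                   xlab = names(df)[1], ylab = "TE")
  }
  invisible(NULL)
}
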