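## Ensembles of independent single-cell simulations.

#' Counter-based per-cell seed derivation
#'
#' Maps a master seed and a stream/cell index to a 31-bit seed so that
#' ensembles are reproducible and independent of evaluation order.
#'
#' @param master master seed (integer).
#' @param n number of seeds.
#' @param stream optional stream offset, to decouple different ensembles
#'   driven by the same master seed.
#' @export
derive_seeds <- function(master, n, stream = 0) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m + stream * 97003 +
                seq_len(n) * 1000003) %% m)
}

#' Simulate an ensemble of cells
#'
#' Runs `n_cells` independent single-cell simulations with per-cell seeds
#' derived from the master seed ([derive_seeds()]), and collects per-cell
#' delivery records, mRNA release schedules and mature-GFP traces.
#'
#' @param network a [build_network()] network.
#' @param n_cells number of cells.
#' @param seed master seed.
#' @param engine `"hybrid"` (default) or `"ssa"`.  Full SSA of the
#'   expression phase at the published translation rate fires millions of
#'   events per cell and is intended for validation at reduced rates.
#' @param expression keep mature-GFP traces (hybrid only; delivery-only
#'   ensembles are much cheaper and sufficient for transfection efficiency).
#' @param keep_trajectories keep the full `cell_trajectory` objects.
#' @param stream seed stream offset (see [derive_seeds()]).
#' @inheritParams simulate_ssa
#' @return A `transfection_ensemble`: per-cell summaries (`$cells`), release
#'   events (`$releases`), a time-by-cell mature-GFP matrix (`$gfp`) and the
#'   output grid (`$times`).
#' @export
#' @examples
#' net <- build_network("multilipoplex", rate_preset("multilipoplex_slow"),
#'                      reference_design(rate_preset("multilipoplex_slow")))
#' ens <- simulate_ensemble(net, n_cells = 20, seed = 1)
#' ens
simulate_ensemble <- function(network, n_cells, seed,
                              engine = c("hybrid", "ssa"),
                              expression = TRUE, keep_trajectories = FALSE,
                              init = c("round", "fractional", "poisson"),
                              wash = c("truncate", "explicit"),
                              budget = 5e6, stream = 0) {
  engine <- match.arg(engine)
  init <- match.arg(init); wash <- match.arg(wash)
  stopifnot(n_cells >= 1)
  net <- network
  seeds <- derive_seeds(seed, n_cells, stream = stream)
  times <- .out_times(net$design)
  gfp <- if (expression) matrix(0, length(times), n_cells) else NULL
  rel <- vector("list", n_cells)
  trajs <- if (keep_trajectories) vector("list", n_cells) else NULL

  # the SSA argument set is identical for every cell: build it once
  sim_net <- if (engine == "hybrid") delivery_subnetwork(net) else net
  a <- .ssa_args(sim_net)
  des <- net$design
  wash_mode <- if (wash == "truncate") 0L else 1L
  gs_idx <- match("G*", net$species)

  cols <- c("L_ex0", "n_attached", "n_endocytosed", "n_lysed_endosomes",
            "n_degraded_endosomes", "n_delivered", "first_release")
  cs <- matrix(NA_real_, n_cells, length(cols),
               dimnames = list(NULL, cols))
  any_over <- FALSE

  for (i in seq_len(n_cells)) {
    set.seed(seeds[i])
    x0 <- .init_state(sim_net, init = init)
    res <- ssa_core(x0 = as.integer(x0), stoich = a$stoich, kind = a$kind,
                    rate = a$rate, ridx = a$ridx, lex = a$lex,
                    pits = a$pits, cargo = a$cargo, eclass = a$eclass,
                    release_size = a$release_size, t_inc = des$t_inc,
                    wash_mode = wash_mode, out_times = times,
                    log_events = FALSE, budget = budget)
    any_over <- any_over || isTRUE(res$over_budget)
    tal <- res$tallies
    nrel <- length(res$release_times)
    cs[i, ] <- c(x0[["L_ex"]], tal[["attached"]],
                 tal[["endocytosed_lipoplexes"]], tal[["lysis_events"]],
                 tal[["degradation_events"]], tal[["unpack_events"]],
                 if (nrel) min(res$release_times) else NA_real_)
    if (nrel)
      rel[[i]] <- data.frame(cell = i, time = res$release_times,
                             size = res$release_sizes)
    if (expression && engine == "hybrid" && nrel) {
      g <- numeric(length(times))
      for (k in seq_len(nrel))
        g <- g + res$release_sizes[k] *
          expr_unit(times - res$release_times[k], net$rates,
                    component = "Gs")
      gfp[, i] <- g
    } else if (expression && engine == "ssa") {
      gfp[, i] <- res$counts[, gs_idx]
    }
    if (keep_trajectories)
      trajs[[i]] <- if (engine == "hybrid")
        simulate_hybrid(net, seed = seeds[i], init = init, wash = wash,
                        budget = budget, expression = expression)
      else simulate_ssa(net, seed = seeds[i], init = init, wash = wash,
                        budget = budget)
  }
  if (any_over)
    warning("SSA event budget exceeded in at least one cell", call. = FALSE)

  cells <- data.frame(cell = seq_len(n_cells), seed = seeds, cs)
  cells$transfected <- cells$n_delivered > 0

  structure(list(
    variant = net$variant, rates = net$rates, design = net$design,
    engine = engine, n_cells = n_cells, seed = seed, stream = stream,
    cells = cells,
    releases = if (length(rl <- rel[!vapply(rel, is.null, TRUE)]))
      do.call(rbind, rl) else
        data.frame(cell = integer(), time = numeric(), size = numeric()),
    gfp = gfp, times = times, trajectories = trajs),
    class = "transfection_ensemble")
}

#' @export
print.transfection_ensemble <- function(x, ...) {
  cat(sprintf("Transfection ensemble: %d cells, '%s' network, %s engine, seed %s\n",
              x$n_cells, x$variant, x$engine, format(x$seed)))
  cat(sprintf("  mean attached: %.2f   mean delivered lipoplexes: %.2f   TE: %.3f\n",
              mean(x$cells$n_attached), mean(x$cells$n_delivered),
              mean(x$cells$transfected)))
  invisible(x)
}

#' @export
summary.transfection_ensemble <- function(object, ...) {
  ce <- object$cells
  out <- list(
    n_cells = object$n_cells,
    mean_attached = mean(ce$n_attached),
    mean_endocytosed = mean(ce$n_endocytosed),
    mean_delivered = mean(ce$n_delivered),
    lysed_fraction = with(ce, sum(n_lysed_endosomes) /
                            max(1, sum(n_lysed_endosomes) +
                                  sum(n_degraded_endosomes))),
    transfection_efficiency = mean(ce$transfected),
    mean_first_release = mean(ce$first_release, na.rm = TRUE))
  class(out) <- "summary.transfection_ensemble"
  out
}

#' @export
print.summary.transfection_ensemble <- function(x, ...) {
  cat(sprintf(
    "cells: %d\nmean attached: %.3f\nmean endocytosed: %.3f\nmean delivered: %.3f\nlysed endosome fraction: %.3f\ntransfection efficiency: %.3f\nmean first release (transfected cells): %.3f h\n",
    x$n_cells, x$mean_attached, x$mean_endocytosed, x$mean_delivered,
    x$lysed_fraction, x$transfection_efficiency, x$mean_first_release))
  invisible(x)
}

#' @export
plot.transfection_ensemble <- function(x, max_cells = 50, ...) {
  if (is.null(x$gfp)) stop("ensemble was run without expression traces")
  idx <- seq_len(min(max_cells, x$n_cells))
  graphics::matplot(x$times, x$gfp[, idx, drop = FALSE], type = "l",
                    lty = 1, col = grDevices::adjustcolor("darkgreen", 0.35),
                    xlab = "time (h)", ylab = "mature GFP (molecules)", ...)
  invisible(x)
}
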