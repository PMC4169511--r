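## Simulation engines: deterministic (ODE), exact stochastic (SSA) and
## hybrid (stochastic delivery + analytic expression).

.traj <- function(times, counts, net, engine, release = NULL, tallies = NULL,
                  events = NULL, n_events = NA_real_, seed = NA_integer_) {
  obs <- sapply(net$observables, function(w) drop(counts %*% w))
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1,
                                       dimnames = list(NULL, names(net$observables)))
  structure(list(times = times, counts = counts, observables = obs,
                 release = release, tallies = tallies, events = events,
                 n_events = n_events, engine = engine, seed = seed,
                 variant = net$variant, species = net$species,
                 design = net$design, rates = net$rates),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("Cell trajectory (%s engine, '%s' network): %d time points to %g h\n",
              x$engine, x$variant, length(x$times), max(x$times)))
  if (!is.null(x$release) && nrow(x$release))
    cat(sprintf("  %d mRNA release event(s), first at %.2f h\n",
                nrow(x$release), min(x$release$time)))
  cat(sprintf("  final mature GFP: %.4g\n",
              x$observables[nrow(x$observables), "mature_gfp"]))
  invisible(x)
}

#' @export
as.data.frame.cell_trajectory <- function(x, ...) {
  d <- data.frame(time_h = x$times, x$counts, check.names = FALSE)
  cbind(d, x$observables)
}

#' @export
plot.cell_trajectory <- function(x, what = c("attached", "in_endosomes",
                                             "mRNA", "mature_gfp"), ...) {
  what <- match.arg(what, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(what), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (w in what)
    graphics::plot(x$times, x$observables[, w], type = "l",
                   xlab = "time (h)", ylab = w, ...)
  invisible(x)
}

.out_times <- function(design, times = NULL) {
  if (!is.null(times)) return(times)
  tt <- seq(0, design$t_end, by = design$dt_out)
  if (tail(tt, 1) < design$t_end) tt <- c(tt, design$t_end)
  tt
}

## Initial species counts; how L_ex0 becomes an integer per-cell count is a
## modelling choice ("round" by default; attachment itself already
## Poissonises the delivered number).
.init_state <- function(net, init = c("round", "fractional", "poisson"),
                        integer_state = TRUE) {
  init <- match.arg(init)
  x0 <- setNames(numeric(length(net$species)), net$species)
  L0 <- net$design$L_ex0
  if (!integer_state) { x0["L_ex"] <- L0; return(x0) }
  x0["L_ex"] <- switch(init,
    round = round(L0),
    fractional = floor(L0) + (runif(1) < (L0 - floor(L0))),
    poisson = rpois(1, L0))
  x0
}

#' Deterministic (ODE) simulation of a transfection network
#'
#' Integrates the mass-action rate equations with the stiff-capable `lsoda`
#' solver from \pkg{deSolve}.  The wash is applied either as an event that
#' removes the remaining external lipoplexes at `t_inc` (the large-`k_W`
#' limit, default) or as an explicit first-order wash reaction switching on
#' at `t_inc`.
#'
#' @param network a [build_network()] object.
#' @param tolerances named vector with `rtol` and `atol`.
#' @param wash `"truncate"` or `"explicit"`.
#' @param times optional output time grid (h); defaults to the design grid.
#' @return A `cell_trajectory` with continuous species amounts.
#' @export
simulate_deterministic <- function(network,
                                   tolerances = c(rtol = 1e-8, atol = 1e-8),
                                   wash = c("truncate", "explicit"),
                                   times = NULL) {
  wash <- match.arg(wash)
  net <- network
  des <- net$design
  times <- .out_times(des, times)
  Smat <- network_stoich(net)
  ridx <- network_reactant_index(net)
  kindv <- vapply(net$reactions, `[[`, "", "rate_kind")
  rolev <- vapply(net$reactions, `[[`, "", "role")
  ratev <- vapply(net$reactions, `[[`, 0, "rate_constant")
  lex <- match("L_ex", net$species)
  pit_idx <- grep("^P(_\\d+)?$", net$species)
  is_new <- kindv == "attach_channel" & rolev == "attach_new"
  is_join <- kindv == "attach_channel" & rolev == "attach_join"
  is_wash <- kindv == "wash"
  is_mass <- kindv == "mass_action_first_order"

  rhs <- function(t, x, p) {
    x <- pmax(x, 0)
    npits <- sum(x[pit_idx])
    v <- numeric(length(ratev))
    v[is_mass] <- ratev[is_mass] * x[ridx[is_mass]]
    kAX_L <- x[lex] / (npits + 1)
    v[is_new] <- ratev[is_new] * kAX_L
    v[is_join] <- ratev[is_join] * kAX_L * x[ridx[is_join]]
    if (wash == "explicit")
      v[is_wash] <- wash_rate(t, des$t_inc, ratev[is_wash]) * x[lex]
    list(drop(crossprod(Smat, v)))
  }

  x0 <- .init_state(net, integer_state = FALSE)
  ev <- NULL
  if (wash == "truncate" && des$t_inc > 0 && des$t_inc < max(times))
    ev <- list(data = data.frame(var = "L_ex", time = des$t_inc, value = 0,
                                 method = "rep"))
  sol <- tryCatch(
    deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                   rtol = tolerances[["rtol"]], atol = tolerances[["atol"]],
                   events = ev, maxsteps = 50000),
    warning = function(w) stop("ODE integration problem: ",
                               conditionMessage(w), call. = FALSE))
  counts <- pmax(unname(as.matrix(sol[, -1, drop = FALSE])), 0)
  colnames(counts) <- net$species
  .traj(times = sol[, 1], counts = counts, net = net, engine = "ode")
}

## Map a network to the argument set of the compiled SSA kernel.
.ssa_args <- function(net) {
  kindv <- vapply(net$reactions, `[[`, "", "rate_kind")
  rolev <- vapply(net$reactions, `[[`, "", "role")
  kind <- integer(length(kindv))
  kind[kindv == "mass_action_first_order"] <- 0L
  kind[rolev == "attach_new"] <- 1L
  kind[rolev == "attach_join"] <- 2L
  kind[kindv == "wash"] <- 3L
  eclass <- c(attach = 1L, attach_new = 1L, attach_join = 1L,
              endocytosis = 2L, lysis = 3L, endosome_degradation = 4L,
              unpack = 5L, wash = 6L)[rolev]
  eclass[is.na(eclass)] <- 0L
  list(stoich = network_stoich(net),
       kind = kind,
       rate = vapply(net$reactions, `[[`, 0, "rate_constant"),
       ridx = network_reactant_index(net) - 1L,
       lex = match("L_ex", net$species) - 1L,
       pits = grep("^P(_\\d+)?$", net$species) - 1L,
       cargo = vapply(net$reactions, `[[`, 0, "cargo"),
       eclass = unname(eclass),
       release_size = vapply(net$reactions, `[[`, 0, "release_size"))
  }

#' Exact stochastic (Gillespie) simulation of a transfection network
#'
#' Runs the direct-method SSA with per-state attach-channel propensities
#' (`k_A / (n_pits + 1)` per channel) and the wash handled at `t_inc` either
#' as instantaneous removal of the remaining external lipoplexes
#' (`"truncate"`, the large-`k_W` limit) or as an explicit wash reaction
#' (`"explicit"`).  Identical seeds give identical trajectories.
#'
#' @inheritParams simulate_deterministic
#' @param seed optional integer seed (uses R's RNG; `set.seed` semantics).
#' @param init how the possibly fractional design dose `L_ex0` becomes an
#'   integer initial count: deterministic rounding (default), a Bernoulli
#'   split of the fractional part, or a Poisson draw.
#' @param log_events keep the full (time, reaction) event log.
#' @param budget soft cap on the number of reaction events; a warning is
#'   issued when it is exceeded (full SSA of the expression phase at
#'   `k_TL = 170`, `S = 350` fires millions of events per cell) and the run
#'   aborts at 100 times the budget.
#' @param x0 optional named vector of initial copy numbers overriding the
#'   default (dose in `L_ex`, zero elsewhere); species not named keep 0.
#' @return A `cell_trajectory` with integer copy numbers, mRNA release
#'   events (`$release`) and delivery bookkeeping tallies (`$tallies`).
#' @export
simulate_ssa <- function(network, seed = NULL,
                         init = c("round", "fractional", "poisson"),
                         wash = c("truncate", "explicit"),
                         log_events = FALSE, budget = 5e6, times = NULL,
                         x0 = NULL) {
  wash <- match.arg(wash); init <- match.arg(init)
  net <- network
  des <- net$design
  times <- .out_times(des, times)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    x0 <- .init_state(net, init = init)
  } else {
    xx <- setNames(numeric(length(net$species)), net$species)
    stopifnot(all(names(x0) %in% net$species))
    xx[names(x0)] <- x0
    x0 <- xx
  }
  a <- .ssa_args(net)
  res <- ssa_core(x0 = as.integer(x0), stoich = a$stoich, kind = a$kind,
                  rate = a$rate, ridx = a$ridx, lex = a$lex, pits = a$pits,
                  cargo = a$cargo, eclass = a$eclass,
                  release_size = a$release_size,
                  t_inc = des$t_inc,
                  wash_mode = if (wash == "truncate") 0L else 1L,
                  out_times = times, log_events = log_events,
                  budget = budget)
  if (isTRUE(res$over_budget))
    warning("SSA event count exceeded the configured budget (", budget,
            "); consider the hybrid engine", call. = FALSE)
  counts <- res$counts
  colnames(counts) <- net$species
  release <- data.frame(time = res$release_times, size = res$release_sizes)
  events <- NULL
  if (log_events) {
    labs <- vapply(net$reactions, `[[`, "", "label")
    events <- data.frame(time = res$event_times,
                         reaction = res$event_reaction,
                         label = labs[res$event_reaction])
  }
  tal <- res$tallies
  tal["initial_L_ex"] <- x0[["L_ex"]]
  .traj(times = times, counts = counts, net = net, engine = "ssa",
        release = release, tallies = tal, events = events,
        n_events = res$n_events,
        seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Reduce a network to its stochastic delivery chain
#'
#' Keeps the low-copy species (`L_ex`, pits, endosomes, `L_in`) and their
#' reactions and strips the mRNA product from the unpacking reaction, whose
#' firings are instead recorded as release events.  Used by the hybrid
#' engine, which reconstructs the expression phase analytically.
#'
#' @param network a full [build_network()] network.
#' @export
delivery_subnetwork <- function(network) {
  net <- network
  keep_sp <- grep("^(L_ex|P(_\\d+)?|E(_\\d+)?|L_in)$", net$species,
                  value = TRUE)
  keep <- vapply(net$reactions, function(r)
    all(names(r$reactants) %in% keep_sp) &&
      (r$role == "unpack" || all(names(r$products) %in% keep_sp)),
    logical(1))
  rx <- lapply(net$reactions[keep], function(r) {
    if (r$role == "unpack") r$products <- NULL
    r
  })
  obs <- lapply(net$observables[c("attached", "in_endosomes")],
                function(w) w[keep_sp])
  structure(list(variant = net$variant, species = keep_sp, reactions = rx,
                 observables = obs, rates = net$rates, design = net$design),
            class = "lipoplex_network")
}

#' Hybrid simulation: stochastic delivery, analytic expression
#'
#' The delivery chain (external lipoplexes, pits, endosomes, internal
#' lipoplexes) runs by exact SSA; every unpacking event releases a packet of
#' `S` mRNA whose contribution to mRNA, immature and mature GFP is added
#' analytically through the linear expression cascade.  Because the
#' expression phase is linear and high-copy, the hybrid trace equals the
#' conditional expectation of the full SSA given the delivery history, and
#' ensemble statistics agree with full SSA up to Monte-Carlo error.
#'
#' @inheritParams simulate_ssa
#' @param expression compute the expression-phase columns (set to `FALSE`
#'   when only delivery statistics are needed).
#' @return A `cell_trajectory` whose delivery species are integer counts and
#'   whose `M`, `G`, `G*` columns are continuous superpositions.
#' @export
simulate_hybrid <- function(network, seed = NULL,
                            init = c("round", "fractional", "poisson"),
                            wash = c("truncate", "explicit"),
                            log_events = FALSE, budget = 5e6, times = NULL,
                            expression = TRUE) {
  net <- network
  sub <- delivery_subnetwork(net)
  tr <- simulate_ssa(sub, seed = seed, init = init, wash = wash,
                     log_events = log_events, budget = budget, times = times)
  tt <- tr$times
  M <- Gi <- Gs <- numeric(length(tt))
  if (expression && nrow(tr$release)) {
    for (k in seq_len(nrow(tr$release))) {
      tau <- tt - tr$release$time[k]
      m0 <- tr$release$size[k]
      M <- M + m0 * expr_unit(tau, net$rates, component = "M")
      Gi <- Gi + m0 * expr_unit(tau, net$rates, component = "G")
      Gs <- Gs + m0 * expr_unit(tau, net$rates, component = "Gs")
    }
  }
  counts <- cbind(tr$counts, M = M, G = Gi, `G*` = Gs)
  colnames(counts) <- net$species
  out <- .traj(times = tt, counts = counts, net = net, engine = "hybrid",
               release = tr$release, tallies = tr$tallies,
               events = tr$events, n_events = tr$n_events, seed = tr$seed)
  out
}
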