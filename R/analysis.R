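## Single-cell observables: onset time and maximum expression by fitting the
## analytic expression solution, distribution summaries, transfection
## efficiency and dose-response Poissonian fits.

## Vectorised profile fit: for every candidate onset time the amplitude
## enters linearly, so the optimal m0 and residual follow from two inner
## products.  Y is a time-by-cell matrix.
.onset_profile <- function(Y, times, rates, maturation, t0_grid) {
  B <- vapply(t0_grid, function(t0)
    expr_unit(times - t0, rates, maturation), numeric(length(times)))
  bb <- colSums(B * B)                    # per t0
  NUM <- crossprod(B, Y)                  # t0 x cells
  yy <- colSums(Y * Y)
  m0 <- sweep(pmax(NUM, 0), 1, bb, "/")
  rss <- outer(rep(1, length(t0_grid)), yy) - pmax(NUM, 0)^2 / bb
  list(m0 = m0, rss = rss)
}

.onset_refine <- function(y, times, rates, maturation, t0, half_width) {
  yy <- sum(y * y)
  f <- function(t0) {
    b <- expr_unit(times - t0, rates, maturation)
    num <- max(sum(b * y), 0)
    yy - num^2 / sum(b * b)
  }
  op <- optimize(f, c(max(0, t0 - half_width), t0 + half_width), tol = 1e-7)
  b <- expr_unit(times - op$minimum, rates, maturation)
  m0 <- max(sum(b * y), 0) / sum(b * b)
  list(t0 = op$minimum, m0 = m0, rss = op$objective)
}

#' Fit onset time and maximum GFP of a batch of traces
#'
#' Least-squares fit of the analytic expression solution over free
#' `(t0, m0)` with all rates fixed, applied column-wise to a time-by-cell
#' matrix of mature-GFP traces.  A coarse grid over the onset time (with the
#' amplitude profiled out analytically) is refined per cell by 1-d
#' optimisation.
#'
#' @param gfp numeric matrix, time points in rows, cells in columns (a
#'   single trace may be given as a vector).
#' @param times output grid (h).
#' @param rates [rate_constants] used for the fixed rates of the fit curve.
#' @param maturation logical; `FALSE` (default) fits the two-stage
#'   translation + degradation solution of the original single-cell
#'   analysis, in which the maturation delay is absorbed into the onset
#'   time.  `TRUE` fits the full three-stage cascade.
#' @param t0_grid candidate onset grid (h); defaults to
#'   `seq(0, 0.8 * max(times), 0.1)`.
#' @return A data.frame with one row per cell: `t0`, `m0_eff`, `maxgfp`
#'   (maximum of the fitted curve), `rss`, `converged`.
#' @export
fit_onset_batch <- function(gfp, times, rates, maturation = FALSE,
                            t0_grid = NULL) {
  if (is.null(dim(gfp))) gfp <- matrix(gfp, ncol = 1)
  stopifnot(nrow(gfp) == length(times))
  if (is.null(t0_grid))
    t0_grid <- seq(0, 0.8 * max(times), by = 0.1)
  prof <- .onset_profile(gfp, times, rates, maturation, t0_grid)
  best <- apply(prof$rss, 2, which.min)
  pk <- curve_peak(rates, maturation)
  n <- ncol(gfp)
  out <- data.frame(cell = seq_len(n), t0 = NA_real_, m0_eff = NA_real_,
                    maxgfp = NA_real_, rss = NA_real_, converged = FALSE)
  step <- if (length(t0_grid) > 1) diff(t0_grid[1:2]) else 0.1
  for (i in seq_len(n)) {
    y <- gfp[, i]
    if (!any(y > 0) || sd(y) == 0) next
    r <- .onset_refine(y, times, rates, maturation, t0_grid[best[i]],
                       half_width = 1.5 * step)
    ok <- r$m0 > 0 && is.finite(r$rss)
    out$t0[i] <- r$t0; out$m0_eff[i] <- r$m0
    out$maxgfp[i] <- r$m0 * pk[["height"]]
    out$rss[i] <- r$rss; out$converged[i] <- ok
  }
  out
}

#' Fit the expression-onset time and maximum GFP of one trace
#'
#' @inheritParams fit_onset_batch
#' @param gfp a single mature-GFP trace on `times`.
#' @return An object of class `onset_fit` with elements `t0`, `m0_eff`,
#'   `maxgfp`, `rss`, `converged`; `coef()` and `predict()` methods are
#'   provided.  Non-convergence (flat or zero traces) is flagged, never
#'   silently zeroed.
#' @export
#' @examples
#' r <- rate_preset("multilipoplex_slow")
#' tt <- seq(0, 30, 0.1)
#' y <- expression_curve(700, 4, r, maturation = TRUE)(tt)
#' fit_onset_maxgfp(y, tt, r, maturation = TRUE)
fit_onset_maxgfp <- function(gfp, times, rates, maturation = FALSE,
                             t0_grid = NULL) {
  d <- fit_onset_batch(matrix(gfp, ncol = 1), times, rates, maturation,
                       t0_grid)
  structure(list(t0 = d$t0, m0_eff = d$m0_eff, maxgfp = d$maxgfp,
                 rss = d$rss, converged = d$converged,
                 maturation = maturation, rates = rates, times = times),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Onset fit: did not converge (flat or empty trace)\n")
    return(invisible(x))
  }
  cat(sprintf("Onset fit: t0 = %.3f h, m0_eff = %.1f mRNA, maxGFP = %.4g (rss %.3g)\n",
              x$t0, x$m0_eff, x$maxgfp, x$rss))
  invisible(x)
}

#' @export
coef.onset_fit <- function(object, ...)
  c(t0 = object$t0, m0_eff = object$m0_eff)

#' @export
predict.onset_fit <- function(object, times = object$times, ...) {
  if (!isTRUE(object$converged)) return(rep(NA_real_, length(times)))
  object$m0_eff * expr_unit(times - object$t0, object$rates,
                            object$maturation)
}

## Collect converged fits from a fits data.frame / onset_fit / numeric vector
.fit_values <- function(fits, col) {
  if (inherits(fits, "onset_fit"))
    fits <- data.frame(t0 = fits$t0, maxgfp = fits$maxgfp,
                       converged = fits$converged)
  if (is.numeric(fits)) return(fits)
  fits[[col]][fits$converged]
}

#' Gaussian summary of expression-onset times
#'
#' @param fits a data.frame from [fit_onset_batch()] (only converged rows
#'   are used) or a numeric vector of onset times.
#' @return A `distribution_summary` with `kind = "gaussian"`, `location`
#'   (sample mean, h), `width` (sample SD, h) and `n`.
#' @export
onset_distribution <- function(fits) {
  t0 <- .fit_values(fits, "t0")
  if (length(t0) < 2)
    stop("need at least 2 converged onset fits", call. = FALSE)
  structure(list(kind = "gaussian", location = mean(t0), width = sd(t0),
                 n = length(t0)), class = "distribution_summary")
}

#' Lognormal summary of maximum-GFP levels
#'
#' Two-parameter lognormal summary fitted by moments on the log scale:
#' the location is `exp(mean(log x))` and the width is `sd(log x)`.
#' Non-positive values are excluded and counted.
#'
#' @param fits a data.frame from [fit_onset_batch()] or a numeric vector of
#'   per-cell maximum GFP values.
#' @return A `distribution_summary` with `kind = "lognormal"`, `location`
#'   (molecules), `width` (dimensionless), `n` and `n_excluded`.
#' @export
maxgfp_distribution <- function(fits) {
  x <- .fit_values(fits, "maxgfp")
  pos <- x > 0 & is.finite(x)
  if (sum(pos) < 2)
    stop("need at least 2 positive maximum-GFP values", call. = FALSE)
  lx <- log(x[pos])
  structure(list(kind = "lognormal", location = exp(mean(lx)),
                 width = sd(lx), n = sum(pos), n_excluded = sum(!pos)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("%s summary: location %.4g, width %.4g (n = %d%s)\n",
              x$kind, x$location, x$width, x$n,
              if (!is.null(x$n_excluded) && x$n_excluded)
                paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}

#' Transfection efficiency of an ensemble
#'
#' Fraction of cells that express GFP.  With the simulation ground truth
#' (`method = "release"`) a cell counts as transfected when at least one
#' mRNA packet was released; for trace-only data (`method = "fit"`) a cell
#' counts when its onset fit converged with a fitted maximum above the
#' detection floor (default 1e3 molecules, far below the ~1e5 single-packet
#' amplitude).
#'
#' @param x a `transfection_ensemble`, or a fits data.frame from
#'   [fit_onset_batch()] (which forces `method = "fit"`).
#' @param method `"release"` or `"fit"`.
#' @param rates,maturation used to fit traces when `x` is an ensemble and
#'   `method = "fit"`.
#' @param floor detection floor on the fitted maximum GFP (molecules).
#' @return A fraction in `[0, 1]`.
#' @export
transfection_efficiency <- function(x, method = c("release", "fit"),
                                    rates = NULL, maturation = FALSE,
                                    floor = 1e3) {
  method <- match.arg(method)
  if (is.data.frame(x) && !is.null(x$maxgfp))
    return(mean(x$converged & !is.na(x$maxgfp) & x$maxgfp >= floor))
  stopifnot(inherits(x, "transfection_ensemble"))
  if (method == "release") return(mean(x$cells$transfected))
  if (is.null(x$gfp)) stop("ensemble has no GFP traces", call. = FALSE)
  if (is.null(rates)) rates <- x$rates
  fits <- fit_onset_batch(x$gfp, x$times, rates, maturation)
  mean(fits$converged & !is.na(fits$maxgfp) & fits$maxgfp >= floor)
}

#' Dose-response curve of transfection efficiency
#'
#' Runs an independent ensemble at every relative dose (multiples of the
#' design's reference `L_ex0`) and records the transfection efficiency.
#'
#' @param rates a [rate_constants] object.
#' @param design an [experiment_design]; its `L_ex0` is the reference dose.
#' @param dose_grid relative dose multipliers.
#' @param n_cells cells per dose point.
#' @param seed master seed; each dose uses its own stream.
#' @param variant network variant.
#' @param engine simulation engine (delivery statistics only are needed, so
#'   expression traces are skipped).
#' @return A data.frame of class `dose_response` with columns `dose`
#'   (relative), `L_ex0`, `TE`, `n_cells`.
#' @export
dose_response <- function(rates, design, dose_grid, n_cells, seed,
                          variant = c("multilipoplex", "streamlined"),
                          engine = "hybrid") {
  variant <- match.arg(variant)
  out <- vector("list", length(dose_grid))
  for (k in seq_along(dose_grid)) {
    d <- dose_grid[k]
    if (d < 0) stop("doses must be >= 0", call. = FALSE)
    des <- design
    des$L_ex0 <- design$L_ex0 * d
    if (des$L_ex0 == 0) {
      out[[k]] <- data.frame(dose = d, L_ex0 = 0, TE = 0, n_cells = n_cells)
      next
    }
    net <- build_network(variant, rates, des)
    ens <- simulate_ensemble(net, n_cells, seed, engine = engine,
                             expression = FALSE, stream = k)
    out[[k]] <- data.frame(dose = d, L_ex0 = des$L_ex0,
                           TE = transfection_efficiency(ens),
                           n_cells = n_cells)
  }
  structure(do.call(rbind, out), class = c("dose_response", "data.frame"))
}

## Poissonian dose-response forms.  The single form is the zero class of one
## Poisson delivery process whose mean scales with dose.  The double form
## nests two Poisson processes: endosomal delivery events (mean N) times
## lipoplex occupancy per endosome (mean L, scaling with dose), giving
## TE(d) = 1 - exp(-N (1 - exp(-L d))).  As L -> 0 at fixed N*L it reduces
## to the single form with a = N*L.
.pois_te <- function(form, par, d) {
  if (form == "single") 1 - exp(-par[["a"]] * d)
  else 1 - exp(-par[["N"]] * (1 - exp(-par[["L"]] * d)))
}

#' Fit a single- or double-Poissonian dose-response model
#'
#' Least squares on the transfection efficiencies.  The single form
#' `TE(d) = 1 - exp(-a d)` is the zero-class of one Poisson delivery
#' process; the double form `TE(d) = 1 - exp(-N (1 - exp(-L d)))` nests a
#' Poisson number of endosomal delivery events (mean `N`) each carrying a
#' Poisson number of lipoplexes (mean `L` at the reference dose, scaling
#' with dose), and captures the sub-exponential bend that multi-lipoplex
#' packing produces.  On data without that bend the double fit is
#' non-identifiable (`L` collapses towards 0 with `N*L` fixed) and is
#' flagged.
#'
#' @param dr a [dose_response()] data.frame (or any data.frame with `dose`
#'   and `TE`); at least 3 dose points.
#' @param form `"single"` or `"double"`.
#' @return A list of class `poisson_fit`: `form`, `par`, `rss`, `fitted`,
#'   `flagged` (non-identifiability), `converged`.
#' @export
fit_poissonian <- function(dr, form = c("single", "double")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(dr), all(c("dose", "TE") %in% names(dr)))
  if (nrow(dr) < 3) stop("need at least 3 dose points", call. = FALSE)
  d <- dr$dose; te <- dr$TE
  rssf <- function(par) sum((te - .pois_te(form, par, d))^2)
  if (form == "single") {
    op <- optimize(function(la) rssf(c(a = exp(la))), c(log(1e-4), log(1e3)),
                   tol = 1e-10)
    par <- c(a = exp(op$minimum))
    rss <- op$objective
    flagged <- FALSE
    conv <- TRUE
  } else {
    starts <- list(c(0, 0), c(log(2), log(0.5)), c(log(0.5), log(2)),
                   c(log(5), log(0.2)))
    best <- NULL
    for (s in starts) {
      op <- optim(s, function(p) rssf(c(N = exp(p[1]), L = exp(p[2]))),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || op$value < best$value) best <- op
    }
    par <- c(N = exp(best$par[1]), L = exp(best$par[2]))
    rss <- best$value
    conv <- best$convergence == 0
    # L -> 0 (or N exploding) with N*L finite means the data carry no
    # second-Poisson curvature
    flagged <- par[["L"]] < 0.02 || par[["N"]] > 100
  }
  structure(list(form = form, par = par, rss = rss,
                 fitted = .pois_te(form, par, d), dose = d,
                 flagged = flagged, converged = conv),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf("%s-Poissonian dose-response fit: %s (rss %.3g%s)\n",
              x$form,
              paste(names(x$par), signif(x$par, 3), sep = " = ",
                    collapse = ", "),
              x$rss, if (x$flagged) ", flagged non-identifiable" else ""))
  invisible(x)
}

#' @export
predict.poisson_fit <- function(object, dose = object$dose, ...)
  .pois_te(object$form, object$par, dose)
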