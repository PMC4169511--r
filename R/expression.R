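## Analytic solution of the linear expression cascade
##   dM/dt  = -d_M M
##   dG/dt  =  k_TL M - (k_M + d_G) G
##   dG*/dt =  k_M G - d_G G*
## with M(t0) = m0, G(t0) = G*(t0) = 0.  All stages are first order, so the
## solution is a sum of exponentials and is linear in m0; traces of cells
## that received several mRNA packets are superpositions of shifted copies.

## Nudge nearly-coincident decay rates apart so the distinct-root formulas
## stay well conditioned; the perturbation (1 part in 1e7) is far below any
## measurable effect.
.distinct3 <- function(a, b, c) {
  eps <- 1e-7
  for (i in 1:4) {
    m <- max(a, b, c, 1e-12)
    if (abs(a - b) < eps * m) b <- b * (1 + 3 * eps) + eps * m * 1e-3
    if (abs(a - c) < eps * m) c <- c * (1 - 3 * eps) - eps * m * 1e-3
    if (abs(b - c) < eps * m) c <- c * (1 - 7 * eps) - eps * m * 1e-3
  }
  c(a = a, b = b, c = c)
}

## Unit-amplitude (m0 = 1) cascade components at lag tau >= 0.
## maturation = FALSE drops the maturation stage and treats translated GFP
## as directly fluorescent (the convention of the single-cell analysis the
## onset-time fitting mirrors; the maturation delay is then absorbed into
## the fitted onset time).
expr_unit <- function(tau, rates, maturation = TRUE,
                      component = c("Gs", "M", "G")) {
  component <- match.arg(component)
  a <- rates$d_M
  pos <- tau > 0
  out <- numeric(length(tau))
  tp <- tau[pos]
  if (component == "M") {
    out[pos] <- exp(-a * tp)
    return(out)
  }
  if (!maturation) {
    if (component == "G") stop("no immature-GFP pool without maturation")
    cc <- rates$d_G
    r <- .distinct3(a, a + 1, cc)  # only a vs c must be distinct here
    a <- r["a"]; cc <- r["c"]
    out[pos] <- rates$k_TL * (exp(-cc * tp) - exp(-a * tp)) / (a - cc)
    return(out)
  }
  b <- rates$k_M + rates$d_G
  cc <- rates$d_G
  r <- .distinct3(a, b, cc)
  a <- r["a"]; b <- r["b"]; cc <- r["c"]
  if (component == "G") {
    out[pos] <- rates$k_TL * (exp(-a * tp) - exp(-b * tp)) / (b - a)
    return(out)
  }
  out[pos] <- rates$k_TL * rates$k_M *
    (exp(-a * tp) / ((b - a) * (cc - a)) +
     exp(-b * tp) / ((a - b) * (cc - b)) +
     exp(-cc * tp) / ((a - cc) * (b - cc)))
  out
}

#' Analytic mature-GFP expression curve
#'
#' Closed-form solution of the expression cascade for a packet of `m0` mRNA
#' molecules released at time `t0`: translation at `k_TL`, mRNA decay at
#' `d_M`, maturation at `k_M` (optional) and GFP decay at `d_G` on both the
#' immature and mature pools.  The curve is linear in `m0`, so multi-packet
#' cells are superpositions of shifted copies.
#'
#' @param m0 released mRNA molecules.
#' @param t0 release (onset) time, h.
#' @param rates a [rate_constants] object (only `k_TL`, `d_M`, `k_M`, `d_G`
#'   are used).
#' @param maturation include the maturation stage (`TRUE`) or use the
#'   two-stage translation + degradation solution in which maturation is
#'   absorbed into the onset time (`FALSE`).
#' @return A function of time (h) returning mature-GFP molecule counts.
#' @export
#' @examples
#' r <- rate_preset("multilipoplex_slow")
#' f <- expression_curve(350, 3, r)
#' f(c(0, 5, 20))
expression_curve <- function(m0, t0, rates, maturation = TRUE) {
  stopifnot(m0 >= 0, inherits(rates, "rate_constants"))
  force(m0); force(t0); force(maturation)
  function(t) m0 * expr_unit(t - t0, rates, maturation)
}

## Lag and height of the unit-curve maximum.
curve_peak <- function(rates, maturation = TRUE) {
  if (!maturation) {
    a <- rates$d_M; cc <- rates$d_G
    if (abs(a - cc) < 1e-9 * max(a, cc)) a <- a * (1 + 1e-6)
    tau <- log(a / cc) / (a - cc)
    return(c(tau = tau, height = expr_unit(tau, rates, FALSE)))
  }
  op <- optimize(function(tau) expr_unit(tau, rates, TRUE),
                 interval = c(1e-6, 60 / max(rates$d_G, 1e-3)),
                 maximum = TRUE, tol = 1e-8)
  c(tau = op$maximum, height = op$objective)
}
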