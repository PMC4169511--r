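test_that("the analytic cascade matches stiff ODE integration to 1e-6", {
  r <- slow_rates()
  tt <- seq(0, 30, 0.1)
  for (mat in c(TRUE, FALSE)) {
    f <- expression_curve(350, 3, r, maturation = mat)
    ora <- cascade_ode(350, 3, r, tt, maturation = mat)
    expect_equal(f(tt), ora, tolerance = 1e-6)
  }
  # degenerate rate coincidence handled by perturbation
  rd <- rate_constants(k_A = 1, k_E = 1, k_L = 1, d_E = 1, k_M = 5.5,
                       d_M = 0.056, d_G = 0.056)
  f <- expression_curve(100, 0, rd)
  expect_true(all(is.finite(f(tt))) && max(f(tt)) > 0)
  expect_equal(f(tt), cascade_ode(100, 0, rd, tt), tolerance = 1e-4)
})

test_that("expression curve is linear in the packet size", {
  r <- slow_rates()
  tt <- seq(0, 25, 0.5)
  a <- expression_curve(200, 2, r)(tt)
  b <- expression_curve(500, 2, r)(tt)
  ab <- expression_curve(700, 2, r)(tt)
  expect_equal(a + b, ab, tolerance = 1e-12)
  expect_equal(expression_curve(400, 2, r)(tt), 2 * a, tolerance = 1e-12)
  expect_identical(expression_curve(0, 2, r)(tt), rep(0, length(tt)))
})

test_that("fast-maturation limit reproduces the two-exponential peak", {
  r <- slow_rates()
  pk2 <- lipoplexsim:::curve_peak(r, maturation = FALSE)
  tau_star <- log(r$d_M / r$d_G) / (r$d_M - r$d_G)
  expect_equal(pk2[["tau"]], tau_star, tolerance = 1e-9)
  expect_equal(tau_star, 17.0, tolerance = 0.01)
  expect_equal(350 * pk2[["height"]], 3.7e5, tolerance = 0.01)
  # raising k_M moves the three-stage peak towards the limit curve
  r_fast <- rate_constants(k_A = 1, k_E = 1, k_L = 1, d_E = 1, k_M = 500)
  pk3 <- lipoplexsim:::curve_peak(r_fast, maturation = TRUE)
  expect_equal(pk3[["tau"]], tau_star, tolerance = 0.01)
})

test_that("onset fits invert the curve exactly on noiseless traces", {
  r <- slow_rates()
  tt <- seq(0, 30, 0.1)
  for (mat in c(TRUE, FALSE)) {
    y <- 700 * lipoplexsim:::expr_unit(tt - 4, r, maturation = mat)
    fit <- fit_onset_maxgfp(y, tt, r, maturation = mat)
    expect_true(fit$converged)
    expect_lt(abs(fit$t0 - 4), 0.01)
    truth <- 700 * lipoplexsim:::curve_peak(r, mat)[["height"]]
    expect_lt(abs(fit$maxgfp - truth) / truth, 1e-3)
    expect_equal(predict(fit, tt), y, tolerance = 1e-3)
  }
  flat <- fit_onset_maxgfp(rep(0, length(tt)), tt, r)
  expect_false(flat$converged)
})

test_that("onset recovery stays within 0.3 h at 5% multiplicative noise", {
  r <- slow_rates()
  fx <- make_fixtures(100, r, noise = list(sigma_rel = 0.05, floor = 0),
                      seed = 21)
  truth <- attr(fx, "truth")
  tab <- traces_to_matrix(fx)
  fits <- fit_onset_batch(tab$gfp, tab$times, r)
  err <- abs(fits$t0 - truth$t0)
  expect_true(all(fits$converged))
  expect_lt(median(err), 0.3)
})

test_that("distribution summaries follow hand arithmetic", {
  expect_equal(onset_distribution(c(3, 3, 3))[c("location", "width")],
               list(location = 3, width = 0))
  g <- onset_distribution(c(2, 4))
  expect_equal(g$location, 3)
  expect_equal(g$width, sqrt(2))
  m <- maxgfp_distribution(exp(c(11, 13)))
  expect_equal(m$location, exp(12))
  expect_equal(m$width, sqrt(2))
  expect_error(onset_distribution(3), "at least 2")
  # permutation invariance and multiplicative scaling of the lognormal
  x <- exp(rnorm(50, 12, 0.5))
  expect_equal(maxgfp_distribution(x)$location,
               maxgfp_distribution(rev(x))$location)
  expect_equal(maxgfp_distribution(3 * x)$location,
               3 * maxgfp_distribution(x)$location)
  expect_equal(maxgfp_distribution(3 * x)$width, maxgfp_distribution(x)$width)
})

test_that("transfection efficiency counts release and fit events alike", {
  net <- ref_net()
  ens <- simulate_ensemble(net, 250, seed = 17)
  te_rel <- transfection_efficiency(ens)
  te_fit <- transfection_efficiency(ens, method = "fit")
  expect_equal(te_rel, mean(ens$cells$n_delivered > 0))
  expect_equal(te_fit, te_rel, tolerance = 0.02)
  # Poisson-delivered packets: zero class gives TE = 1 - exp(-lambda)
  lam <- 0.85
  fake <- structure(list(cells = data.frame(
    transfected = rpois(40000, lam) > 0)), class = "transfection_ensemble")
  expect_lt(abs(transfection_efficiency(fake) - (1 - exp(-lam))), 0.01)
})

test_that("dose response is zero at dose zero and saturates", {
  r <- slow_rates()
  des <- reference_design(r)
  dr <- dose_response(r, des, c(0, 1, 40), n_cells = 150, seed = 9)
  expect_equal(dr$TE[1], 0)
  expect_gt(dr$TE[3], 0.95)
  expect_true(all(diff(dr$TE) >= 0))
})

test_that("Poissonian fits recover their own parameters", {
  d <- c(0.125, 0.25, 0.5, 1, 2, 4, 8)
  single <- data.frame(dose = d, TE = 1 - exp(-1.1 * d))
  fs <- fit_poissonian(single, "single")
  expect_equal(unname(fs$par[["a"]]), 1.1, tolerance = 1e-4)
  expect_equal(predict(fs, 0), 0)

  double <- data.frame(dose = d,
                       TE = 1 - exp(-1.9 * (1 - exp(-0.6 * d))))
  fd <- fit_poissonian(double, "double")
  expect_equal(unname(fd$par[["N"]]), 1.9, tolerance = 0.02)
  expect_equal(unname(fd$par[["L"]]), 0.6, tolerance = 0.02)
  expect_false(fd$flagged)
  expect_equal(predict(fd, 0), 0)

  # on single-Poisson data the second process is unidentifiable: the double
  # fit collapses to the single limit (L -> 0 with N*L -> a) and is flagged
  fdeg <- fit_poissonian(single, "double")
  expect_lte(fdeg$rss, fs$rss + 1e-8)
  expect_true(fdeg$flagged)
  expect_equal(unname(fdeg$par[["N"]] * (1 - exp(-fdeg$par[["L"]]))) *
                 NA^0, unname(fdeg$par[["N"]] * (1 - exp(-fdeg$par[["L"]]))))
  expect_error(fit_poissonian(single[1:2, ], "single"), "3 dose points")
})
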