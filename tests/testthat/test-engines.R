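test_that("ODE solution matches first-order closed forms", {
  r <- only_rates(k_A = 0.27)
  des <- experiment_design(L_ex0 = 20, t_inc = 1, t_end = 2, dt_out = 0.05)
  net <- build_network("streamlined", r, des)
  tr <- simulate_deterministic(net)
  pre <- tr$times < des$t_inc
  expect_equal(tr$counts[pre, "L_ex"],
               20 * exp(-0.27 * tr$times[pre]), tolerance = 1e-6)
  # lipoplexes only move from L_ex to P during incubation ...
  expect_equal(tr$counts[pre, "L_ex"] + tr$counts[pre, "P"],
               rep(20, sum(pre)), tolerance = 1e-6)
  # ... and P freezes at the attached total once the rest is washed away
  post <- tr$times > des$t_inc
  expect_equal(tr$counts[post, "P"],
               rep(20 * (1 - exp(-0.27)), sum(post)), tolerance = 1e-6)
})

test_that("linear attach-endocytose chain transfers the attached total", {
  r <- only_rates(k_A = 0.1, k_E = 0.8)
  des <- experiment_design(L_ex0 = 50, t_inc = 1, t_end = 40, dt_out = 0.5)
  net <- build_network("streamlined", r, des)
  tr <- simulate_deterministic(net)
  attached_total <- 50 * (1 - exp(-0.1 * 1))
  # with no downstream losses, E(t -> infinity) = total ever attached
  expect_equal(unname(tr$counts[nrow(tr$counts), "E"]), attached_total,
               tolerance = 1e-4)
  expect_equal(unname(tr$counts[nrow(tr$counts), "P"]), 0,
               tolerance = 1e-4)
})

test_that("explicit large-k_W wash agrees with the truncation event", {
  net <- ref_net()
  t1 <- simulate_deterministic(net, wash = "truncate")
  t2 <- simulate_deterministic(net, wash = "explicit")
  post <- t1$times > net$design$t_inc + 0.2
  expect_equal(t1$counts[post, "L_ex"], t2$counts[post, "L_ex"],
               tolerance = 1e-6)
  expect_equal(t1$observables[post, "mature_gfp"],
               t2$observables[post, "mature_gfp"], tolerance = 1e-4)
})

test_that("SSA ensemble mean matches the exponential-decay oracle", {
  r <- only_rates(d_M = 0.062)
  des <- experiment_design(L_ex0 = 0, t_inc = 1, t_end = 10, dt_out = 10)
  net <- build_network("streamlined", r, des)
  n <- 400
  finals <- vapply(seq_len(n), function(i)
    simulate_ssa(net, seed = derive_seeds(7, n)[i],
                 x0 = c(M = 350))$counts[2, "M"], 0)
  expected <- 350 * exp(-0.62)
  se <- sd(finals) / sqrt(n)
  expect_lt(abs(mean(finals) - expected), 3 * se)
  # binomial thinning variance as a cross-check of SSA independence
  expect_lt(abs(var(finals) - 350 * exp(-0.62) * (1 - exp(-0.62))),
            5 * 350 * 0.25 / sqrt(n) * 3)
})

test_that("zero-propensity states stay constant and seeds reproduce", {
  r <- slow_rates()
  des <- experiment_design(L_ex0 = 0, t_end = 5)
  net <- build_network("multilipoplex", r, des)
  tr <- simulate_ssa(net, seed = 1)
  expect_true(all(tr$counts == 0))
  expect_identical(tr$n_events, 0)

  net2 <- ref_net()
  a <- simulate_ssa(net2, seed = 42, log_events = TRUE)
  b <- simulate_ssa(net2, seed = 42, log_events = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$counts, b$counts)
})

test_that("per-cell bookkeeping conserves the initial lipoplexes", {
  net <- delivery_subnetwork(ref_net())
  for (s in 1:40) {
    tr <- simulate_ssa(net, seed = s)
    x <- tr$counts[nrow(tr$counts), ]
    tal <- tr$tallies
    pits <- grep("^P_", names(x)); endos <- grep("^E_", names(x))
    i_of <- function(idx) as.integer(sub("^[PE]_", "", names(x)[idx]))
    balance <- tal[["washed"]] + x[["L_ex"]] +
      sum(x[pits] * i_of(pits)) + sum(x[endos] * i_of(endos)) +
      tal[["degraded_cargo"]] + x[["L_in"]] + tal[["unpack_events"]]
    expect_equal(unname(balance), tal[["initial_L_ex"]])
  }
})

test_that("hybrid and full SSA share the delivery realisation per seed", {
  net <- ref_net()
  h <- simulate_hybrid(net, seed = 11)
  s <- simulate_ssa(delivery_subnetwork(net), seed = 11)
  expect_identical(h$release, s$release)
  expect_identical(h$tallies, s$tallies)
  expect_identical(h$counts[, "L_in"], s$counts[, "L_in"])
})

test_that("hybrid expression equals the stiff-ODE cascade per release", {
  net <- ref_net()
  h <- simulate_hybrid(net, seed = 3)
  expect_gt(nrow(h$release), 0)
  ora <- numeric(length(h$times))
  for (k in seq_len(nrow(h$release)))
    ora <- ora + cascade_ode(h$release$size[k], h$release$time[k],
                             net$rates, h$times)
  expect_equal(h$counts[, "G*"], ora, tolerance = 1e-6)
})

test_that("ensembles are reproducible and reduce to the single engine", {
  net <- ref_net()
  e1 <- simulate_ensemble(net, 30, seed = 5)
  e2 <- simulate_ensemble(net, 30, seed = 5)
  expect_identical(e1$cells, e2$cells)
  expect_identical(e1$gfp, e2$gfp)

  one <- simulate_ensemble(net, 1, seed = 5)
  tr <- simulate_hybrid(net, seed = derive_seeds(5, 1))
  expect_equal(one$gfp[, 1], unname(tr$counts[, "G*"]))
})

test_that("calibrated dose yields the expected mean attachment", {
  r <- slow_rates()
  des <- reference_design(r)
  net <- build_network("multilipoplex", r, des)
  ens <- simulate_ensemble(net, 2000, seed = 8, expression = FALSE)
  att <- ens$cells$n_attached
  expected <- round(des$L_ex0) * (1 - exp(-r$k_A * des$t_inc))
  expect_lt(abs(mean(att) - expected), 3 * sd(att) / sqrt(length(att)))
  # the continuous calibration itself targets 6 exactly
  expect_equal(des$L_ex0 * (1 - exp(-r$k_A)), 6, tolerance = 1e-12)
})

test_that("exceeding the event budget raises a warning", {
  sub <- delivery_subnetwork(ref_net())
  expect_warning(simulate_ssa(sub, seed = 2, budget = 5), "budget")
})
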