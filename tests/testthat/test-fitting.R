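test_that("objective is zero at match and additive in relative errors", {
  g <- list(mean_attached = 6, dose_response = c(0.2, 0.4, 0.6),
            onset_mean = 3.2, onset_width = 1.6, mean_maxgfp = 5.4e5)
  expect_identical(objective(g, g), 0)
  g2 <- g; g2$onset_mean <- 3.2 * 1.1
  expect_equal(objective(g2, g), 0.01, tolerance = 1e-12)
  # field order is irrelevant
  expect_identical(objective(g2, rev(g)), objective(g2, g))
  expect_error(objective(g, g[-3]), "targets must provide")
  g3 <- g; g3$dose_response <- c(0.2, 0.4)
  expect_error(objective(g3, g), "dose grids")
})

test_that("Boltzmann acceptance matches exp(-delta/T) empirically", {
  set.seed(1)
  delta <- 0.7; temp <- 1.3
  acc <- vapply(seq_len(1e4), function(i)
    lipoplexsim:::.metropolis_accept(delta, temp), logical(1))
  p <- exp(-delta / temp)
  expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 1e4))
  # greedy limit: only improving moves pass at T = 0
  expect_true(lipoplexsim:::.metropolis_accept(-0.1, 0))
  expect_false(any(vapply(seq_len(100), function(i)
    lipoplexsim:::.metropolis_accept(1e-9, 0), logical(1))))
})

test_that("proposals stay inside the bounds", {
  set.seed(2)
  lo <- c(k_A = 1e-3, k_E = 1e-3, k_L = 1e-3, d_E = 1e-3, k_M = 0.5)
  up <- c(k_A = 10, k_E = 10, k_L = 10, d_E = 10, k_M = 20)
  par <- c(k_A = 0.27, k_E = 0.81, k_L = 0.11, d_E = 0.67, k_M = 5.5)
  for (i in 1:200) {
    par <- lipoplexsim:::.propose(par, 0.6, lo, up)
    expect_true(all(par >= lo & par <= up))
  }
})

test_that("compute_goals responds to the rates as the kinetics dictate", {
  des <- reference_design(slow_rates())
  dead <- c(k_A = 0, k_E = 0.8, k_L = 0.1, d_E = 0.6, k_M = 5.5)
  # zero attachment: nothing is delivered at any dose
  g0 <- compute_goals(dead, des, n_cells = 120, seed = 3,
                      dose_grid = c(0.5, 1))
  expect_equal(g0$mean_attached, 0, tolerance = 1e-6)
  expect_equal(unname(g0$dose_response), c(0, 0))

  true <- c(k_A = 0.27, k_E = 0.81, k_L = 0.11, d_E = 0.67, k_M = 5.5)
  g1 <- compute_goals(true, des, n_cells = 400, seed = 3,
                      dose_grid = c(0.5, 1))
  # doubling the lysis rate raises TE at every dose (competing risks)
  g2 <- compute_goals(replace(true, "k_L", 0.22), des, n_cells = 400,
                      seed = 3, dose_grid = c(0.5, 1))
  expect_true(all(g2$dose_response > g1$dose_response))
  expect_equal(g1$onset_mean, 3.2, tolerance = 0.15)
})

test_that("annealing is reproducible for a fixed seed", {
  des <- reference_design(slow_rates())
  true <- c(k_A = 0.27, k_E = 0.81, k_L = 0.11, d_E = 0.67, k_M = 5.5)
  tg <- compute_goals(true, des, n_cells = 300, seed = 77,
                      dose_grid = c(0.5, 1))
  cf <- anneal_config(init = true * c(1.3, 0.8, 1.2, 0.9, 1.1),
                      t0 = 0.05, cooling = 0.9, steps = 4, n_cells = 100,
                      seed = 5, design = des, dose_grid = c(0.5, 1))
  a <- anneal(cf, tg, final_n_cells = 100)
  b <- anneal(cf, tg, final_n_cells = 100)
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$trace, b$trace)
  expect_equal(a$best_score, min(a$trace$score))
})
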