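test_that("species and reaction counts follow the closed forms", {
  net <- ref_net("streamlined", "streamlined_slow")
  expect_identical(length(net$species), 7L)
  expect_identical(length(net$reactions), 12L)
  expect_setequal(net$species, c("L_ex", "P", "E", "L_in", "M", "G", "G*"))

  r <- slow_rates()
  for (N in c(1L, 2L, 5L, 10L)) {
    des <- reference_design(r, N_max = N)
    net <- build_network("multilipoplex", r, des)
    expect_identical(length(net$species), 2L * N + 5L)
    # 1 wash + 1 new-pit + (N-1) join + N endocytosis + N lysis +
    # N degradation + 7 downstream
    expect_identical(length(net$reactions), 4L * N + 8L)
  }
})

test_that("capacity-1 multilipoplex reduces to the streamlined topology", {
  r <- slow_rates()
  net1 <- build_network("multilipoplex", r, reference_design(r, N_max = 1))
  roles <- vapply(net1$reactions, `[[`, "", "role")
  expect_false(any(roles == "attach_join"))
  net_s <- build_network("streamlined", r, reference_design(r))
  roles_s <- vapply(net_s$reactions, `[[`, "", "role")
  # same chain up to the attach-channel naming
  roles_s[roles_s == "attach"] <- "attach_new"
  expect_setequal(roles, roles_s)
  expect_identical(length(net1$species), 7L)
})

test_that("invalid variants and designs are rejected", {
  r <- slow_rates()
  expect_error(build_network("nested", r, reference_design(r)),
               "unknown variant")
  expect_error(experiment_design(L_ex0 = 10, N_max = 0), "N_max")
  expect_error(experiment_design(L_ex0 = -1), "L_ex0")
  expect_error(experiment_design(L_ex0 = 10, t_inc = 5, t_end = 2), "t_inc")
  expect_error(rate_constants(k_A = -0.1, k_E = 1, k_L = 1, d_E = 1,
                              k_M = 1), "k_A")
})

test_that("attachment propensity is pit-normalised with constant total", {
  a <- attach_propensity(0.27, 10, 0)
  expect_identical(a$n_channels, 1)
  expect_equal(a$total, 2.7)

  a <- attach_propensity(0.27, 10, 2)
  expect_identical(a$n_channels, 3)
  expect_equal(a$per_channel, rep(0.9, 3))
  expect_equal(a$total, 2.7)

  expect_equal(attach_propensity(1.23, 0, 7)$total, 0)
  # invariance of the total in the number of occupied pits
  tot <- vapply(0:9, function(n) attach_propensity(0.27, 5, n)$total, 0)
  expect_equal(tot, rep(0.27 * 5, 10))
})

test_that("wash rate is zero before and high from the incubation time", {
  expect_identical(wash_rate(0.5, 1, 1e6), 0)
  expect_identical(wash_rate(1.0, 1, 1e6), 1e6)  # boundary inclusive
  expect_identical(wash_rate(2, 1, 0), 0)
  expect_error(wash_rate(-1, 1, 1e6))
})

test_that("every reaction conserves mRNA equivalents except the sinks", {
  for (variant in c("streamlined", "multilipoplex")) {
    net <- ref_net(variant,
                   if (variant == "streamlined") "streamlined_slow"
                   else "multilipoplex_slow")
    S <- net$design$S
    eq <- setNames(numeric(length(net$species)), net$species)
    eq["L_ex"] <- S; eq["L_in"] <- S; eq["M"] <- 1
    pits <- grep("^P(_\\d+)?$", net$species)
    endos <- grep("^E(_\\d+)?$", net$species)
    i_of <- function(nm) {
      n <- suppressWarnings(as.integer(sub("^[PE]_?", "", nm)))
      ifelse(is.na(n), 1L, n)
    }
    eq[pits] <- S * i_of(net$species[pits])
    eq[endos] <- S * i_of(net$species[endos])
    delta <- lipoplexsim:::network_stoich(net) %*% eq
    roles <- vapply(net$reactions, `[[`, "", "role")
    conserving <- roles %in% c("attach", "attach_new", "attach_join",
                               "endocytosis", "lysis", "unpack")
    expect_equal(unname(delta[conserving]), rep(0, sum(conserving)),
                 info = variant)
    sinks <- roles %in% c("wash", "endosome_degradation",
                          "lipoplex_degradation", "mRNA_degradation")
    expect_true(all(delta[sinks] < 0), info = variant)
  }
})

test_that("nested-species count is exact and monotone", {
  x <- count_full_nested_species(175, 10)
  # frozen from an exact big-integer oracle
  expect_identical(x$string, "26938938999176025390625")
  expect_equal(x$log10, 10 * log10(175))
  expect_identical(count_full_nested_species(1, 10)$string, "1")
  y <- count_full_nested_species(176, 10)
  expect_identical(y$string, "28518499943362777317376")
  expect_identical(lipoplexsim:::compare_big_count(y, x), 1L)
  expect_error(count_full_nested_species(0, 10))
})

test_that("dose calibration hits the target mean attachment exactly", {
  r <- slow_rates()
  L0 <- calibrate_dose(r, target_attached = 6, t_inc = 1)
  expect_equal(L0 * (1 - exp(-r$k_A)), 6, tolerance = 1e-12)
  expect_error(calibrate_dose(only_rates(), 6))
})
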