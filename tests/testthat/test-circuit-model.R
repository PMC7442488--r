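test_that("steady-state synaptic currents match the model equations", {
  net <- default_nonplastic()
  ph <- tibble::tibble(kind = "baseline", v = 0, m = 0, duration = 3000)
  sim <- simulate_protocol(net, ph, record_every = 0)
  # soma: x_E - w_EP r_P = 27.339 - 2.8*2 = 21.739; rates settle at target
  expect_equal(unname(drop(sim$avg$i_e_syn)),
               rep(net$background$x_e - 2.8 * 2, 70), tolerance = 1e-4)
  # dendrite: 0 - 3.5*2 + 0.42*1 = -6.58
  expect_equal(unname(drop(sim$avg$i_d_syn)), rep(-6.58, 70),
               tolerance = 1e-3)
  # dendritic bracket rectified away; no calcium event at baseline
  expect_true(all(sim$avg$dend == 0))
  expect_true(all(sim$avg$ca == 0))
  # total somatic input 0.69 * 21.739 = 15 sustains r_E = 1 above
  # rheobase 14
  expect_equal(unname(drop(sim$avg$r_e)), rep(1, 70), tolerance = 1e-3)
})

test_that("disabling dendritic rectification passes inhibition to soma", {
  pc_norect <- pc_params(dend_rect = FALSE)
  net <- build_network(seed = 4, pc = pc_norect)
  # backgrounds were solved assuming the bracket silences the negative
  # dendritic current; without the bracket that inhibition reaches the
  # soma and the operating point drops below the (1, 2, 2, 4) target
  ss <- steady_state_rates(net, duration = 2000)
  expect_lt(mean(ss$r_e), 0.8)
  # and the piecewise-linear oracle agrees with the simulation
  lin <- linear_steady_state(net, route_inputs(net, 0, 0))
  expect_true(lin$consistent)
  expect_equal(drop(ss$r_e), lin$r_e, tolerance = 1e-4)
  expect_equal(drop(ss$r_p), lin$r_p, tolerance = 1e-4)
})

test_that("calcium events require strictly suprathreshold dendritic input", {
  # isolated PCs: zero weights, background only; I_D0 = lam_e * I_E +
  # (1 - lam_d) * x_D crosses theta_c = 28 as x_D grows
  zero <- setNames(rep(0, 11), pathway_table()$pathway)
  iso <- build_network(sizes = small_sizes(), mean_weights = zero,
                       seed = 3)
  x_e <- iso$background$x_e            # (1 + 14)/0.69, dendrite silent
  i_d0 <- function(x_d) 0.31 * x_e + 0.73 * x_d
  x_cross <- (28 - 0.31 * x_e) / 0.73
  r_of <- function(x_d, ca) {
    max(0.27 * max(x_d + ca, 0) + 0.69 * x_e - 14, 0)
  }
  just_below <- x_cross - 1e-4
  just_above <- x_cross + 1e-4
  net_b <- iso; net_b$background$x_d <- just_below
  net_a <- iso; net_a$background$x_d <- just_above
  ss_b <- steady_state_rates(net_b, duration = 1500)
  ss_a <- steady_state_rates(net_a, duration = 1500)
  expect_equal(mean(ss_b$r_e), r_of(just_below, 0), tolerance = 1e-4)
  expect_equal(mean(ss_a$r_e), r_of(just_above, 7), tolerance = 1e-4)
  # the event adds c = 7 (1/s) of dendritic current, lam_d * 7 somatic
  expect_equal(mean(ss_a$r_e) - mean(ss_b$r_e), 0.27 * 7,
               tolerance = 1e-3)
})

test_that("uncoupled units settle at their rectified fixed points", {
  zero <- setNames(rep(0, 11), pathway_table()$pathway)
  iso <- build_network(sizes = small_sizes(), mean_weights = zero,
                       seed = 3)
  iso$background <- list(x_e = 10, x_d = 0, x_p = 4, x_s = 0.5, x_v = 4)
  ss <- steady_state_rates(iso, duration = 1500)
  # PC input 0.69*10 = 6.9 below rheobase: silent
  expect_true(all(ss$r_e == 0))
  expect_equal(unique(ss$r_p), 4, tolerance = 1e-6)
  expect_equal(unique(ss$r_s), 0.5, tolerance = 1e-6)
  expect_equal(unique(ss$r_v), 4, tolerance = 1e-6)
})

test_that("integration converges at second order in the time step", {
  zero <- setNames(rep(0, 11), pathway_table()$pathway)
  iso <- build_network(sizes = small_sizes(), mean_weights = zero,
                       seed = 3)
  iso$background <- list(x_e = 40, x_d = 0, x_p = 2, x_s = 2, x_v = 2)
  ph <- tibble::tibble(kind = "baseline", v = 0, m = 0, duration = 30)
  # analytic transient from r(0) = 0: r(t) = r_inf (1 - exp(-t/tau_E))
  r_inf <- 0.69 * 40 - 14
  exact <- r_inf * (1 - exp(-30 / 60))
  err <- vapply(c(2, 1, 0.5), function(dt) {
    sim <- simulate_protocol(iso, ph, dt = dt, record_every = 0,
                             avg_window = 0)
    abs(mean(sim$state$r_e) - exact)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)   # halving dt cuts the error ~4x
  expect_lt(err[1] / err[2], 5)
  expect_gt(err[2] / err[3], 3)
  expect_lt(err[2] / err[3], 5)

  # steady states are step-size independent
  net <- default_nonplastic()
  ss1 <- steady_state_rates(net, duration = 3000, dt = 0.2)
  ss2 <- steady_state_rates(net, duration = 3000, dt = 0.1)
  expect_equal(ss1$r_e, ss2$r_e, tolerance = 1e-6)
})

test_that("rates stay nonnegative under strong inhibition", {
  net <- default_nonplastic()
  sim <- simulate_protocol(net, test_triplet(3.5), record_every = 1,
                           opto = list(population = "som",
                                       mode = "activate"))
  expect_true(all(sim$traces$rate >= 0))
  sim2 <- simulate_protocol(net, test_triplet(3.5), record_every = 1,
                            opto = list(population = "vip",
                                        mode = "inactivate"))
  expect_true(all(sim2$traces$rate >= 0))
  # the dendritic contribution to the soma is never negative
  expect_true(all(sim$avg$dend >= 0))
})

test_that("time steps outside the supported window are rejected", {
  net <- default_nonplastic()
  ph <- tibble::tibble(kind = "baseline", v = 0, m = 0, duration = 10)
  expect_error(simulate_protocol(net, ph, dt = 0.01), "0.05-2 ms")
  expect_error(simulate_protocol(net, ph, dt = 5), "0.05-2 ms")
  expect_no_error(simulate_protocol(net, ph, dt = 5, force_dt = TRUE,
                                    record_every = 0))
})
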