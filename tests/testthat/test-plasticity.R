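# direct single-phase C++ driver used to probe individual rules
run_plastic_phase <- function(net, v, m, duration, plast_over = list(),
                              rho_e = NULL, rho_p = NULL, dt = 1) {
  par <- npecircuit:::sim_par_list(net$pc, net$inter)
  sz <- net$sizes
  bl <- steady_state_rates(net, duration = 2000, dt = dt)
  n_post <- colSums(net$masks$ep)
  plast <- modifyList(list(
    variant = 1L, eta_ep = 0, eta_ds = 0, eta_px = 0, eta_pe = 0,
    epsilon = 0.1, do_ep = TRUE, do_ds = TRUE, do_ps = TRUE,
    do_pv = TRUE, do_pe = FALSE,
    rho_e = if (is.null(rho_e)) bl$r_e else rho_e,
    rho_p = if (is.null(rho_p)) bl$r_p else rho_p,
    m_ep = net$masks$ep, m_ds = net$masks$ds, m_ps = net$masks$ps,
    m_pv = net$masks$pv, m_pe = net$masks$pe,
    inv_npost = ifelse(n_post > 0, 1 / n_post, 0)), plast_over)
  drv <- route_inputs(net, v, m)
  res <- npecircuit:::cpp_simulate_phase(net$weights, bl, drv, par, dt,
                                         duration, 0, 0, plast)
  res$start <- bl
  res
}

eff <- function(w) mean(rowSums(w))

test_that("zero learning rates leave all weights unchanged", {
  net <- build_network(sizes = small_sizes(), plastic = TRUE, seed = 6)
  seqq <- training_sequence("qt", 3, seed = 1)
  tr <- train_network(net, seqq,
                      plasticity_config(eta_ep = 0, eta_ds = 0,
                                        eta_px = 0, eta_pe = 0),
                      dt = 1)
  expect_equal(tr$weights, net$weights, tolerance = 1e-12)
})

test_that("the somatic inhibitory rule is driven by the rate deviation", {
  net <- build_network(sizes = small_sizes(), plastic = TRUE, seed = 6)
  # PCs pushed above target by a mismatch stimulus: inhibition strengthens
  res_up <- run_plastic_phase(net, v = 0, m = 5, duration = 500,
                              plast_over = list(eta_ep = 1e-4))
  expect_gt(eff(res_up$weights$ep), eff(net$weights$ep))
  # targets far above any reachable rate: inhibition weakens, floored at 0
  res_dn <- run_plastic_phase(net, v = 0, m = 0, duration = 500,
                              plast_over = list(eta_ep = 1e-3),
                              rho_e = rep(50, net$sizes$n_pc))
  expect_lt(eff(res_dn$weights$ep), eff(net$weights$ep))
  expect_true(all(res_dn$weights$ep >= 0))
  # silent presynaptic PV neurons gate the update off
  net_sil <- net
  net_sil$background$x_p <- -30        # drives PV rates to zero
  res0 <- run_plastic_phase(net_sil, v = 0, m = 3, duration = 300,
                            plast_over = list(eta_ep = 1e-3))
  expect_equal(res0$weights$ep, net$weights$ep, tolerance = 1e-12)
})

test_that("the dendritic rule tracks rectified dendritic activity", {
  net <- build_network(sizes = small_sizes(), plastic = TRUE, seed = 6)
  # feedback drives the dendrite (motor input uncancelled early on)
  res_up <- run_plastic_phase(net, v = 5, m = 5, duration = 500,
                              plast_over = list(eta_ds = 1e-4))
  expect_gt(eff(res_up$weights$ds), eff(net$weights$ds))
  # with strong dendritic inhibition the dendrite is rectified-silent at
  # baseline and the activity-gated rule leaves the weights untouched
  net_bal <- default_nonplastic()
  res_dn <- run_plastic_phase(net_bal, v = 0, m = 0, duration = 500,
                              plast_over = list(eta_ds = 1e-2))
  expect_equal(res_dn$weights$ds, net_bal$weights$ds, tolerance = 1e-10)
  # while a weakly inhibited dendrite is active at baseline and recruits
  # more SOM inhibition
  res_up2 <- run_plastic_phase(net, v = 0, m = 0, duration = 500,
                               plast_over = list(eta_ds = 1e-3))
  expect_gte(eff(res_up2$weights$ds), eff(net$weights$ds))
})

test_that("backprop and PV-homeostatic rules push their targets", {
  net <- build_network(sizes = small_sizes(), plastic = TRUE, seed = 6)
  # PCs above baseline: SOM/VIP->PV inhibition is released (deltas < 0)
  res <- run_plastic_phase(net, v = 0, m = 5, duration = 500,
                           plast_over = list(eta_px = 1e-4))
  expect_lt(eff(res$weights$ps), eff(net$weights$ps))
  expect_lt(eff(res$weights$pv), eff(net$weights$pv))
  # PV-homeostatic: PV above its target strengthens SOM/VIP->PV and
  # weakens PC->PV, both pushing the PV rate down
  res_h <- run_plastic_phase(net, v = 5, m = 0, duration = 500,
                             plast_over = list(variant = 3L,
                                               eta_px = 1e-4,
                                               eta_pe = 1e-4,
                                               do_pe = TRUE),
                             rho_p = rep(0.5, net$sizes$n_pv))
  expect_gt(eff(res_h$weights$ps), eff(net$weights$ps))
  expect_gt(eff(res_h$weights$pv), eff(net$weights$pv))
  expect_lt(eff(res_h$weights$pe), eff(net$weights$pe))
})

test_that("rules vanish when every neuron sits at its target", {
  # at the analytic solution with targets equal to the realized baseline,
  # a baseline phase produces no updates at all
  net <- default_nonplastic()
  res <- run_plastic_phase(net, v = 0, m = 0, duration = 300,
                           plast_over = list(eta_ep = 1e-3,
                                             eta_px = 1e-3),
                           rho_e = rep(1, net$sizes$n_pc),
                           rho_p = rep(2, net$sizes$n_pv))
  expect_equal(eff(res$weights$ep), eff(net$weights$ep),
               tolerance = 1e-4)
  expect_equal(eff(res$weights$ps), eff(net$weights$ps),
               tolerance = 1e-4)
})

test_that("analytically balanced weights are a plasticity fixed point", {
  # feedback/playback-averaged updates stay negligible when training
  # starts from the constraint solution: weights drift by far less than
  # they would from an unbalanced start
  net <- default_nonplastic()
  seqq <- training_sequence("qt", 30, stim_max = 3.5, seed = 9)
  cfg <- plasticity_config(eta_ep = 1e-6, eta_ds = 2e-6, eta_px = 1e-6,
                           convergence_tol = 0,
                           rho_e = rep(1, net$sizes$n_pc),
                           rho_p = rep(2, net$sizes$n_pv))
  tr <- suppressWarnings(train_network(net, seqq, cfg, dt = 1))
  ew0 <- effective_weights(net); ew1 <- effective_weights(tr)
  expect_lt(abs(ew1[["ep"]] - ew0[["ep"]]) / ew0[["ep"]], 0.05)
  expect_lt(abs(ew1[["ps"]] - ew0[["ps"]]) / ew0[["ps"]], 0.10)
  expect_lt(abs(ew1[["pv"]] - ew0[["pv"]]) / ew0[["pv"]], 0.10)
})

test_that("local rule parallels backprop on dense connectivity", {
  net <- dense_network()
  common <- list(eta_px = 1e-5)
  res_bp <- run_plastic_phase(net, v = 4, m = 1, duration = 200,
                              plast_over = c(common, variant = 1L))
  res_lo <- run_plastic_phase(net, v = 4, m = 1, duration = 200,
                              plast_over = c(common, variant = 2L))
  d_bp <- c(res_bp$weights$ps - net$weights$ps,
            res_bp$weights$pv - net$weights$pv)
  d_lo <- c(res_lo$weights$ps - net$weights$ps,
            res_lo$weights$pv - net$weights$pv)
  cosine <- sum(d_bp * d_lo) / sqrt(sum(d_bp^2) * sum(d_lo^2))
  expect_gt(cosine, 0.99)
})

test_that("Dale's principle survives aggressive training", {
  net <- build_network(sizes = small_sizes(), plastic = TRUE, seed = 12)
  seqq <- training_sequence("qt", 40, seed = 13)
  cfg <- plasticity_config(eta_ep = 1e-4, eta_ds = 1e-4, eta_px = 1e-4,
                           convergence_tol = 0)
  tr <- train_network(net, seqq, cfg, dt = 1)
  for (pw in names(tr$weights)) {
    expect_true(all(tr$weights[[pw]] >= 0), label = paste("Dale", pw))
    # structural zeros never regrow
    expect_true(all(tr$weights[[pw]][net$masks[[pw]] == 0] == 0),
                label = paste("mask", pw))
  }
})

test_that("training history tracks convergence statistics", {
  net <- build_network(sizes = small_sizes(), plastic = TRUE, seed = 12)
  seqq <- training_sequence("qt", 30, seed = 13)
  tr <- train_network(net, seqq, plasticity_config(convergence_tol = 0),
                      dt = 1, checkpoint_every = 5)
  h <- tr$training$history
  expect_true(all(c("stimulus", "mean_abs_drr", "w_ep", "w_ds", "w_ps",
                    "w_pv") %in% names(h)))
  expect_equal(tr$training$n_stimuli, 30)
  expect_false(tr$training$converged)
  expect_equal(length(tr$training$rho_e), net$sizes$n_pc)
})
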