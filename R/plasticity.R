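#' Plasticity configuration
#'
#' Selects the learning-rule variant and its hyperparameters. All variants
#' share the inhibitory Hebbian rules onto PCs,
#' \deqn{\Delta w_{EP,ij} \propto (r_{E,i} - \rho_{E,0,i})\, r_{P,j}, \qquad
#'       \Delta w_{DS,ij} \propto (A_i - \epsilon)\, r_{S,j},}
#' with \eqn{A_i = [I^{syn}_{D,i} + c_i]_+} the rectified dendritic
#' activity. They differ in how the SOM-to-PV and VIP-to-PV synapses learn:
#'
#' * `"backprop"`: \eqn{\Delta w_{ij} \propto \frac{1}{N_{E,i}}
#'   \sum_{k \in S^{post}_i} (\rho_{E,0,k} - r_{E,k})\, r^{pre}_j} — the
#'   averaged deviation of the PCs each PV neuron inhibits
#'   (an approximated backpropagation of error).
#' * `"local"`: \eqn{\Delta w_{ij} \propto \Delta E_{rec,i}\, r^{pre}_j}
#'   with \eqn{\Delta E_{rec,i} = \sum_k w_{PE,ik} (\rho_{E,0,k} -
#'   r_{E,k})} — the PV neuron's own excitatory recurrent drive relative to
#'   target, a biologically plausible local approximation (feedback
#'   alignment regime).
#' * `"pv_homeostatic"`: \eqn{\Delta w_{PX,ij} \propto (r_{P,i} -
#'   \rho_{P,0,i})\, r_{X,j}} for X in \{SOM, VIP\}, plus the anti-Hebbian
#'   \eqn{\Delta w_{PE,ij} \propto (\rho_{P,0,i} - r_{P,i})\, r_{E,j}} that
#'   establishes the PV target rate; intended for configurations in which
#'   PCs receive no direct visual input.
#'
#' Weight updates are applied every integration step (Euler on
#' \eqn{\dot w}), masked to the structural connectivity, and clipped at
#' zero so Dale's principle holds at all times. Learning rates are per
#' connection and per ms, chosen so the weight change per stimulus stays
#' small against the weight scale (plasticity must integrate over many
#' stimuli, not track single phases).
#'
#' @param variant `"backprop"`, `"local"` or `"pv_homeostatic"`.
#' @param eta_ep,eta_ds Learning rates of the PV-to-soma and
#'   SOM-to-dendrite rules (1/ms per unit pre*post).
#' @param eta_px Learning rate of the SOM/VIP-to-PV rules; `NULL` picks
#'   2e-6 (backprop, homeostatic) or 8e-7 (local — its error signal is
#'   amplified by the summed recurrent drive).
#' @param eta_pe Learning rate of the anti-Hebbian PC-to-PV rule
#'   (`pv_homeostatic` only).
#' @param epsilon Dendritic correction (1/s) easing strong onset
#'   responses.
#' @param rho_e,rho_p Target rates (1/s), scalars recycled per neuron;
#'   defaults are the circuit's baseline operating-point rates of 1 (PC)
#'   and 2 (PV). `NULL` measures each neuron's own pre-training baseline
#'   instead (note the measured initial baseline of the default plastic
#'   network lies too high for a Dale-feasible balanced solution).
#' @param plastic_ep,plastic_ds,plastic_ps,plastic_pv Per-pathway plastic
#'   switches (e.g. set `plastic_pv = FALSE` to freeze VIP-to-PV synapses).
#' @param baseline_settle Pre-training baseline simulation length (ms) used
#'   to measure \eqn{\rho_{E,0}}, \eqn{\rho_{P,0}}.
#' @param convergence_tol,convergence_window Every `convergence_window`
#'   stimuli, training pauses for a frozen-weight probe (baseline,
#'   feedback and playback at the top stimulus strength, plasticity off)
#'   and stops once the mean absolute PC response relative to the probe
#'   baseline is below `convergence_tol` in both probe phases. Probing
#'   with plasticity frozen avoids the rate deviations being masked by
#'   within-phase weight adaptation.
#' @param rate_cap Divergence guard: abort if any population mean rate
#'   exceeds this (1/s).
#' @return A list of class `plasticity_config`.
#' @export
plasticity_config <- function(variant = c("backprop", "local",
                                          "pv_homeostatic"),
                              eta_ep = 2e-6, eta_ds = 2e-5,
                              eta_px = NULL, eta_pe = 2e-6,
                              epsilon = 0.1, rho_e = 1, rho_p = 2,
                              plastic_ep = TRUE, plastic_ds = TRUE,
                              plastic_ps = TRUE, plastic_pv = TRUE,
                              baseline_settle = 5000,
                              convergence_tol = 0.05,
                              convergence_window = 50,
                              rate_cap = 500) {
  variant <- match.arg(variant)
  # the local rule's error signal is scaled by the summed PC->PV drive
  # (eff. w_PE ~ 2.5), so its rate is reduced to match the backprop gain
  eta_px <- eta_px %||% (if (variant == "local") 8e-7 else 2e-6)
  stopifnot(eta_ep >= 0, eta_ds >= 0, eta_px >= 0, eta_pe >= 0,
            epsilon >= 0, baseline_settle > 0, rate_cap > 0)
  structure(list(variant = variant, eta_ep = eta_ep, eta_ds = eta_ds,
                 eta_px = eta_px, eta_pe = eta_pe, epsilon = epsilon,
                 rho_e = rho_e, rho_p = rho_p,
                 plastic_ep = plastic_ep, plastic_ds = plastic_ds,
                 plastic_ps = plastic_ps, plastic_pv = plastic_pv,
                 baseline_settle = baseline_settle,
                 convergence_tol = convergence_tol,
                 convergence_window = convergence_window,
                 rate_cap = rate_cap),
            class = "plasticity_config")
}

variant_code <- function(variant) {
  switch(variant, backprop = 1L, local = 2L, pv_homeostatic = 3L)
}

#' Train a plastic network on a stimulus sequence
#'
#' Runs the experience-dependent learning loop: measure each neuron's
#' pre-training baseline rate (the plasticity target), then integrate the
#' dynamics through the training sequence while the selected inhibitory
#' plasticity rules update the synapses every step. Training stops at the
#' end of the sequence or once the convergence criterion of the
#' [plasticity_config()] is met.
#'
#' @param network A plastic `npe_network` (see [build_network()]).
#' @param sequence Phase tibble from [training_sequence()].
#' @param config A [plasticity_config()].
#' @param dt Integration step during training (ms); 1 ms trades accuracy
#'   for speed inside the supported window.
#' @param checkpoint_every Record effective plastic weights every this many
#'   stimuli in the history.
#' @return The trained `npe_network`; `$training` holds the baseline
#'   targets, convergence flag, number of stimuli used and a per-stimulus
#'   `history` tibble (mean |dR/R| of PCs and effective plastic weights).
#' @export
#' @examples
#' \donttest{
#' net <- build_network(plastic = TRUE, seed = 1)
#' trained <- train_network(net, training_sequence("qt", 300, seed = 2))
#' glance(trained)
#' }
train_network <- function(network, sequence, config = plasticity_config(),
                          dt = 1, checkpoint_every = 10) {
  stopifnot(inherits(network, "npe_network"),
            inherits(config, "plasticity_config"))
  if (!network$plastic)
    warning("training a network built with plastic = FALSE; ",
            "initial weights are the fixed non-plastic strengths")
  validate_phases(sequence)
  check_dt(dt)
  sz <- network$sizes
  par <- sim_par_list(network$pc, network$inter)

  # target rates: the baseline operating point the rules should restore;
  # NULL means each neuron's own measured pre-training baseline
  bl <- steady_state_rates(network, v = 0, m = 0,
                           duration = config$baseline_settle, dt = dt)
  rho_e <- if (is.null(config$rho_e)) bl$r_e else
    rep_len(config$rho_e, sz$n_pc)
  rho_p <- if (is.null(config$rho_p)) bl$r_p else
    rep_len(config$rho_p, sz$n_pv)

  n_post <- colSums(network$masks$ep)   # PCs inhibited per PV neuron
  if (any(n_post == 0) && config$variant == "backprop")
    warning("PV neuron(s) without postsynaptic PCs: ",
            paste(which(n_post == 0), collapse = ", "),
            "; their incoming SOM/VIP weights stay frozen")
  plast <- list(
    variant = variant_code(config$variant),
    eta_ep = config$eta_ep, eta_ds = config$eta_ds,
    eta_px = config$eta_px, eta_pe = config$eta_pe,
    epsilon = config$epsilon,
    do_ep = isTRUE(config$plastic_ep), do_ds = isTRUE(config$plastic_ds),
    do_ps = isTRUE(config$plastic_ps), do_pv = isTRUE(config$plastic_pv),
    do_pe = config$variant == "pv_homeostatic",
    rho_e = rho_e, rho_p = rho_p,
    m_ep = network$masks$ep, m_ds = network$masks$ds,
    m_ps = network$masks$ps, m_pv = network$masks$pv,
    m_pe = network$masks$pe,
    inv_npost = ifelse(n_post > 0, 1 / n_post, 0))

  weights <- network$weights
  state <- list(r_e = bl$r_e, r_p = bl$r_p, r_s = bl$r_s, r_v = bl$r_v)
  history <- list()
  stim_i <- 0
  converged <- FALSE
  stim_max <- max(sequence$v, sequence$m)
  # frozen-weight convergence probe: feedback and playback at the top
  # stimulus strength with plasticity off, responses measured against the
  # probe's own baseline phase
  probe_ok <- function(w, st) {
    if (config$convergence_tol <= 0) return(FALSE)
    net_p <- network
    net_p$weights <- w
    probe <- tibble::tibble(
      kind = c("baseline", "feedback", "baseline", "playback"),
      v = c(0, stim_max, 0, stim_max), m = c(0, stim_max, 0, 0),
      duration = 1000)
    sim <- simulate_protocol(net_p, probe, dt = dt, record_every = 0,
                             init_state = st)
    r_bl <- colMeans(sim$avg$r_e[c(1, 3), , drop = FALSE])
    dev_fb <- abs(sim$avg$r_e[2, ] - r_bl) / pmax(r_bl, 0.1)
    dev_pb <- abs(sim$avg$r_e[4, ] - r_bl) / pmax(r_bl, 0.1)
    # population mean within tol and every single PC within 1.6 tol,
    # i.e. balance must hold cell by cell, not just on average
    mean(dev_fb) < config$convergence_tol &&
      mean(dev_pb) < config$convergence_tol &&
      max(dev_fb, dev_pb) < 1.6 * config$convergence_tol
  }

  for (i in seq_len(nrow(sequence))) {
    ph <- sequence[i, ]
    net_i <- network; net_i$weights <- weights
    drives <- route_inputs(net_i, v = ph$v, m = ph$m)
    res <- cpp_simulate_phase(weights, state, drives, par, dt, ph$duration,
                              0, max(ph$duration - 500, 0), plast)
    weights <- res$weights
    state <- res$state
    means <- c(mean(res$avg$r_e), mean(res$avg$r_p), mean(res$avg$r_s),
               mean(res$avg$r_v))
    if (any(!is.finite(means)) || any(means > config$rate_cap))
      stop("training diverged at phase ", i, " (population mean rates ",
           paste(signif(means, 3), collapse = ", "),
           " 1/s); reduce the learning rates", call. = FALSE)
    if (ph$kind != "baseline") {
      stim_i <- stim_i + 1
      drr <- mean(abs(res$avg$r_e - rho_e) / pmax(rho_e, 0.1))
      if (stim_i %% checkpoint_every == 0 || stim_i == 1) {
        ew <- vapply(weights[c("ep", "ds", "ps", "pv", "pe")],
                     function(w) mean(rowSums(w)), numeric(1))
        history[[length(history) + 1]] <- tibble::tibble(
          stimulus = stim_i, kind = ph$kind, mean_abs_drr = drr,
          w_ep = ew[["ep"]], w_ds = ew[["ds"]], w_ps = ew[["ps"]],
          w_pv = ew[["pv"]], w_pe = ew[["pe"]])
      }
      if (stim_i %% config$convergence_window == 0 &&
          probe_ok(weights, state)) {
        converged <- TRUE
        break
      }
    }
  }

  network$weights <- enforce_dale(weights)
  network$training <- list(
    config = config, rho_e = rho_e, rho_p = rho_p,
    converged = converged, n_stimuli = stim_i,
    history = dplyr::bind_rows(history), final_state = state)
  network
}
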