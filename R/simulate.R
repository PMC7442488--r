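#' Simulate a stimulus protocol
#'
#' Integrates the network dynamics through an ordered sequence of phases
#' with a 2nd-order Runge-Kutta (Heun) scheme, rates clamped nonnegative
#' after every step. Unless an initial state is supplied, all rates start
#' at zero. For every phase, per-neuron rates and synaptic/dendritic
#' currents are averaged over the last `avg_window` ms of the phase (the
#' tail average excludes onset transients).
#'
#' @param network An `npe_network`.
#' @param phases A phase tibble (`kind`, `v`, `m`, `duration`), e.g. from
#'   [test_triplet()] or [training_sequence()].
#' @param dt Integration step (ms). The scheme is accurate and stable for
#'   steps between 0.05 and 2 ms; values outside that window are rejected
#'   unless `force_dt = TRUE`.
#' @param record_every Trace sampling interval (ms); 0 disables trace
#'   recording (phase averages are always computed).
#' @param opto Optional list `list(population =, mode =)` applied to every
#'   phase, see [apply_opto()].
#' @param avg_window Tail-averaging window per phase (ms), capped at the
#'   phase duration.
#' @param init_state Optional list of rate vectors `r_e`, `r_p`, `r_s`,
#'   `r_v`; defaults to all zeros.
#' @param force_dt Allow `dt` outside \[0.05, 2\] ms.
#' @return An object of class `npe_sim` with elements `phases` (the input
#'   tibble plus a phase id), `avg` (list of phase-by-neuron matrices:
#'   rates `r_e` ... `r_v`, currents `i_e_syn`, `i_d_syn`, `i_d0`, `ca`,
#'   `exc`, `inh`, `dend`), `traces` (long tibble of rates, or `NULL`),
#'   `current_traces` (PC-mean current traces) and the final `state`.
#' @export
#' @examples
#' net <- build_network(seed = 1)
#' sim <- simulate_protocol(net, test_triplet(3.5))
#' phase_responses(sim)
simulate_protocol <- function(network, phases, dt = 0.1, record_every = 1,
                              opto = NULL, avg_window = 500,
                              init_state = NULL, force_dt = FALSE) {
  stopifnot(inherits(network, "npe_network"))
  validate_phases(phases)
  check_dt(dt, force_dt)
  sz <- network$sizes
  state <- init_state %||% list(r_e = numeric(sz$n_pc),
                                r_p = numeric(sz$n_pv),
                                r_s = numeric(sz$n_som),
                                r_v = numeric(sz$n_vip))
  par <- sim_par_list(network$pc, network$inter)
  no_plast <- list(variant = 0L)

  n_phase <- nrow(phases)
  avg_names <- c("r_e", "r_p", "r_s", "r_v", "i_e_syn", "i_d_syn", "i_d0",
                 "ca", "exc", "inh", "dend")
  avg <- lapply(setNames(avg_names, avg_names), function(nm) {
    n <- if (nm %in% c("r_p")) sz$n_pv else if (nm == "r_s") sz$n_som
         else if (nm == "r_v") sz$n_vip else sz$n_pc
    matrix(NA_real_, n_phase, n)
  })
  traces <- vector("list", n_phase)
  cur_traces <- vector("list", n_phase)
  t0 <- 0
  for (i in seq_len(n_phase)) {
    ph <- phases[i, ]
    drives <- route_inputs(network, v = ph$v, m = ph$m)
    if (!is.null(opto))
      drives <- apply_opto(drives, population = opto$population,
                           mode = opto$mode)
    res <- cpp_simulate_phase(network$weights, state, drives, par, dt,
                              ph$duration, record_every,
                              max(ph$duration - avg_window, 0), no_plast)
    state <- res$state
    for (nm in avg_names) avg[[nm]][i, ] <- res$avg[[nm]]
    if (record_every > 0) {
      tr <- res$traces
      # drop each phase's t = 0 sample (duplicate of the previous end)
      keep <- if (i == 1) rep(TRUE, length(tr$time)) else tr$time > 0
      traces[[i]] <- tibble::tibble(
        time = rep(t0 + tr$time[keep], times = 4),
        population = rep(c("PC", "PV", "SOM", "VIP"),
                         each = sum(keep)),
        phase = i,
        rate = c(rowMeans(tr$r_e[keep, , drop = FALSE]),
                 rowMeans(tr$r_p[keep, , drop = FALSE]),
                 rowMeans(tr$r_s[keep, , drop = FALSE]),
                 rowMeans(tr$r_v[keep, , drop = FALSE])))
      cur_traces[[i]] <- tibble::tibble(
        time = t0 + tr$time[keep], phase = i,
        exc = tr$currents[keep, 1], inh = tr$currents[keep, 2],
        dend = tr$currents[keep, 3], ca = tr$currents[keep, 4])
    }
    t0 <- t0 + ph$duration
  }
  phases$phase <- seq_len(n_phase)
  structure(list(network = network, phases = phases, avg = avg,
                 traces = if (record_every > 0) dplyr::bind_rows(traces),
                 current_traces = if (record_every > 0)
                   dplyr::bind_rows(cur_traces),
                 state = state, dt = dt, avg_window = avg_window,
                 opto = opto),
            class = "npe_sim")
}

check_dt <- function(dt, force = FALSE) {
  if (!force && (dt < 0.05 || dt > 2))
    stop("dt = ", dt, " ms is outside the supported 0.05-2 ms window; ",
         "pass force_dt = TRUE to override", call. = FALSE)
  invisible(dt)
}

#' @export
print.npe_sim <- function(x, ...) {
  cat("<npe_sim> ", nrow(x$phases), " phases, ",
      sum(x$phases$duration) / 1000, " s simulated\n", sep = "")
  print(dplyr::count(x$phases, .data$kind))
  invisible(x)
}

#' Steady state by direct simulation
#'
#' Convenience wrapper: holds the drives constant and integrates long
#' enough for the rates to settle, returning the tail-averaged rates.
#'
#' @param network An `npe_network`.
#' @param v,m Visual and motor drives (1/s).
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @return Named list of rate vectors `r_e`, `r_p`, `r_s`, `r_v`.
#' @export
steady_state_rates <- function(network, v = 0, m = 0, duration = 5000,
                               dt = 0.1) {
  kind <- if (v == 0 && m == 0) "baseline" else if (v == m) "feedback"
    else if (m > v) "mismatch" else "playback"
  ph <- tibble::tibble(kind = kind, v = v, m = m, duration = duration)
  sim <- simulate_protocol(network, ph, dt = dt, record_every = 0,
                           avg_window = min(500, duration / 2))
  list(r_e = drop(sim$avg$r_e), r_p = drop(sim$avg$r_p),
       r_s = drop(sim$avg$r_s), r_v = drop(sim$avg$r_v))
}
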