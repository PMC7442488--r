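#' Analytic balance constraints on the interneuron circuit
#'
#' For a linearized, homogeneous network whose PC dendrites are
#' sufficiently inhibited during feedback and playback, requiring that PCs
#' stay at baseline in both phases (the defining property of nPE neurons)
#' fixes the SOM-to-PV and VIP-to-PV strengths:
#' \deqn{w_{PS} = V_P + w_{VS} M_P - \frac{1 + w_{PP}}{w_{EP}} V_E}
#' \deqn{w_{PV} = M_P + w_{SV} V_P - w_{SV}\frac{1 + w_{PP}}{w_{EP}} V_E
#'       = w_{SV} w_{PS} + (1 - w_{SV} w_{VS}) M_P}
#' where \eqn{V_X, M_X \in \{0, 1\}} indicate whether population X receives
#' visual and motor input. The two printed forms of the second constraint
#' are verified to agree to machine precision.
#'
#' @param v_e,v_p,m_p Binary input flags: visual input to PC somata, visual
#'   and motor input to PV neurons.
#' @param w_pp,w_ep,w_sv,w_vs Population-summed strengths of the PV-to-PV,
#'   PV-to-PC, VIP-to-SOM and SOM-to-VIP pathways. `w_pp = NULL` picks the
#'   non-plastic default (0.1 if `v_e`, else 1.5).
#' @param check_dale Error if a solution is negative (it could not be
#'   realized by an inhibitory synapse); set `FALSE` to inspect infeasible
#'   configurations.
#' @return A one-row tibble with the configuration and `w_ps`, `w_pv`.
#' @export
#' @examples
#' solve_constraints(v_e = 1, v_p = 1, m_p = 0)
solve_constraints <- function(v_e = 1, v_p = 1, m_p = 0, w_pp = NULL,
                              w_ep = 2.8, w_sv = 0.61, w_vs = 0.5,
                              check_dale = TRUE) {
  stopifnot(v_e %in% 0:1, v_p %in% 0:1, m_p %in% 0:1, w_ep > 0)
  w_pp <- w_pp %||% (if (v_e) 0.1 else 1.5)
  q <- (1 + w_pp) / w_ep
  w_ps <- v_p + w_vs * m_p - q * v_e
  w_pv <- m_p + w_sv * v_p - w_sv * q * v_e
  alt <- w_sv * w_ps + (1 - w_sv * w_vs) * m_p
  if (abs(w_pv - alt) > 1e-12 * max(1, abs(w_pv)))
    stop("internal error: the two forms of the w_PV constraint disagree")
  if (check_dale && (w_ps < 0 || w_pv < 0))
    stop(sprintf(paste0(
      "configuration V_E=%d V_P=%d M_P=%d with w_PP=%.3g, w_EP=%.3g gives ",
      "a negative inhibitory strength (w_PS=%.4g, w_PV=%.4g); ",
      "it violates Dale's principle"), v_e, v_p, m_p, w_pp, w_ep,
      w_ps, w_pv), call. = FALSE)
  tibble::tibble(v_e = v_e, v_p = v_p, m_p = m_p, w_pp = w_pp,
                 w_ep = w_ep, w_ps = w_ps, w_pv = w_pv)
}

#' Constraint table over all input configurations
#'
#' Evaluates [solve_constraints()] for all eight combinations of the
#' `(V_E, V_P, M_P)` flags; infeasible (Dale-violating) configurations are
#' kept with `feasible = FALSE`.
#'
#' @inheritParams solve_constraints
#' @return A tibble with eight rows.
#' @export
constraint_table <- function(w_ep = 2.8, w_sv = 0.61, w_vs = 0.5) {
  grid <- expand.grid(v_e = 0:1, v_p = 0:1, m_p = 0:1)
  purrr::pmap_dfr(grid, function(v_e, v_p, m_p) {
    res <- solve_constraints(v_e, v_p, m_p, w_ep = w_ep, w_sv = w_sv,
                             w_vs = w_vs, check_dale = FALSE)
    res$feasible <- res$w_ps >= 0 & res$w_pv >= 0
    res
  })
}

#' Background drives realizing a target baseline operating point
#'
#' Inverts the linear fixed-point equations of the circuit at `v = m = 0`
#' for the constant background inputs `(x_E, x_P, x_S, x_V)` (with
#' `x_D = 0`) that make the population rates settle at `target_rates`.
#' Assumes the PC dendrite is rectified-silent and subthreshold for calcium
#' events at baseline; both assumptions are verified at the solution and an
#' error is raised if either fails.
#'
#' @param weights Named vector of population-summed effective weights (as
#'   from [effective_weights()]), or an `npe_network`.
#' @param input Unused routing information, accepted for interface symmetry.
#' @param target_rates Baseline rates (PC, PV, SOM, VIP) in 1/s, all > 0.
#' @param pc A [pc_params()].
#' @return Named list `x_e`, `x_d`, `x_p`, `x_s`, `x_v` (1/s) plus the
#'   diagnostic dendritic currents `i_d_syn` and `i_d0` at the fixed point.
#' @export
#' @examples
#' net <- build_network(seed = 1)
#' solve_background_inputs(effective_weights(net))
solve_background_inputs <- function(weights, input = NULL,
                                    target_rates = c(1, 2, 2, 4),
                                    pc = pc_params()) {
  if (inherits(weights, "npe_network")) {
    pc <- weights$pc
    weights <- effective_weights(weights)
  }
  stopifnot(length(target_rates) == 4, all(target_rates > 0))
  r_e <- target_rates[1]; r_p <- target_rates[2]
  r_s <- target_rates[3]; r_v <- target_rates[4]
  w <- as.list(weights)

  x_v <- r_v - w$ve * r_e + w$vs * r_s
  x_s <- r_s - w$se * r_e + w$sv * r_v
  x_p <- r_p - w$pe * r_e + w$pp * r_p + w$ps * r_s + w$pv * r_v
  # PC soma: r_e = (1 - lambda_e) * I_E - theta, dendritic bracket at zero
  i_e_syn <- (r_e + pc$theta) / (1 - pc$lambda_e)
  x_e <- i_e_syn + w$ep * r_p

  i_d_syn <- -w$ds * r_s + w$de * r_e
  i_d0 <- pc$lambda_e * i_e_syn + (1 - pc$lambda_d) * i_d_syn
  if (i_d_syn > 0)
    stop("solved baseline has a positive dendritic synaptic input (",
         signif(i_d_syn, 4), " 1/s); the rectified-silent dendrite ",
         "assumption fails - re-solve with the dendritic branch active",
         call. = FALSE)
  if (i_d0 >= pc$theta_c)
    stop("solved baseline crosses the dendritic calcium threshold",
         call. = FALSE)
  list(x_e = x_e, x_d = 0, x_p = x_p, x_s = x_s, x_v = x_v,
       i_d_syn = i_d_syn, i_d0 = i_d0)
}

#' Piecewise-linear steady state of the full network
#'
#' Independent fixed-point oracle for the simulated dynamics. The network
#' is piecewise linear: each PC is either above rheobase or silent, its
#' dendritic bracket active or rectified away, its calcium event on or off,
#' and each interneuron either active or silent. Given drives, the solver
#' iterates branch assignments: solve the linear system implied by the
#' current assignment, recompute every unit's branch from the solution, and
#' repeat until self-consistent.
#'
#' @param network An `npe_network`.
#' @param drives Named list of per-neuron drive vectors `x_e`, `x_d`,
#'   `x_p`, `x_s`, `x_v` (scalars recycled), e.g. from [route_inputs()].
#' @param max_iter Maximum branch-refinement iterations.
#' @return List with rate vectors `r_e`, `r_p`, `r_s`, `r_v`, the final
#'   branch assignment, `iterations` and `consistent` (logical; `FALSE`
#'   means the assignment cycled without settling, e.g. exactly on a
#'   rectification boundary).
#' @export
linear_steady_state <- function(network, drives, max_iter = 50) {
  sz <- network$sizes
  ne <- sz$n_pc; np <- sz$n_pv; ns <- sz$n_som; nv <- sz$n_vip
  W <- network$weights
  pc <- network$pc
  x_e <- rep_len(drives$x_e, ne); x_d <- rep_len(drives$x_d, ne)
  x_p <- rep_len(drives$x_p, np); x_s <- rep_len(drives$x_s, ns)
  x_v <- rep_len(drives$x_v, nv)
  lam_d <- pc$lambda_d; lam_e <- pc$lambda_e

  ie <- seq_len(ne); ip <- ne + seq_len(np)
  is <- ne + np + seq_len(ns); iv <- ne + np + ns + seq_len(nv)
  n_tot <- ne + np + ns + nv

  branch <- list(e_on = rep(TRUE, ne), dend_on = rep(FALSE, ne),
                 ca_on = rep(FALSE, ne), p_on = rep(TRUE, np),
                 s_on = rep(TRUE, ns), v_on = rep(TRUE, nv))

  solve_for <- function(b) {
    A <- diag(n_tot)
    rhs <- numeric(n_tot)
    Bd <- b$dend_on * lam_d          # per-PC dendritic gain
    ca <- b$ca_on * pc$c_amp
    # PC rows
    A[ie, ip] <- (1 - lam_e) * W$ep
    A[ie, is] <- Bd * W$ds
    A[ie, ie] <- A[ie, ie] - Bd * W$de
    rhs[ie] <- (1 - lam_e) * x_e + Bd * (x_d + ca) - pc$theta
    # PV rows
    A[ip, ie] <- -W$pe
    A[ip, ip] <- A[ip, ip] + W$pp
    A[ip, is] <- W$ps
    A[ip, iv] <- W$pv
    rhs[ip] <- x_p
    # SOM rows
    A[is, ie] <- -W$se
    A[is, iv] <- W$sv
    rhs[is] <- x_s
    # VIP rows
    A[iv, ie] <- -W$ve
    A[iv, is] <- W$vs
    rhs[iv] <- x_v
    off <- c(!b$e_on, !b$p_on, !b$s_on, !b$v_on)
    if (any(off)) {
      A[off, ] <- 0
      A[cbind(which(off), which(off))] <- 1
      rhs[off] <- 0
    }
    r <- solve(A, rhs)
    list(r_e = r[ie], r_p = r[ip], r_s = r[is], r_v = r[iv])
  }

  recompute_branch <- function(r) {
    i_e_syn <- x_e - drop(W$ep %*% r$r_p)
    i_d_syn <- x_d - drop(W$ds %*% r$r_s) + drop(W$de %*% r$r_e)
    i_d0 <- lam_e * i_e_syn + (1 - lam_d) * i_d_syn
    ca_on <- if (pc$ca_at_threshold) i_d0 >= pc$theta_c else i_d0 > pc$theta_c
    dend <- i_d_syn + ca_on * pc$c_amp
    dend_on <- if (pc$dend_rect) dend > 0 else rep(TRUE, ne)
    i_tot <- lam_d * (if (pc$dend_rect) pmax(dend, 0) else dend) +
      (1 - lam_e) * i_e_syn
    list(e_on = i_tot > pc$theta,
         dend_on = dend_on, ca_on = ca_on,
         p_on = (x_p + drop(W$pe %*% r$r_e) - drop(W$pp %*% r$r_p) -
                   drop(W$ps %*% r$r_s) - drop(W$pv %*% r$r_v)) > 0,
         s_on = (x_s + drop(W$se %*% r$r_e) - drop(W$sv %*% r$r_v)) > 0,
         v_on = (x_v + drop(W$ve %*% r$r_e) - drop(W$vs %*% r$r_s)) > 0)
  }

  consistent <- FALSE
  r <- NULL
  for (it in seq_len(max_iter)) {
    r <- solve_for(branch)
    nb <- recompute_branch(r)
    if (identical(lapply(nb, unname), lapply(branch, unname))) {
      consistent <- TRUE
      break
    }
    branch <- nb
  }
  c(r, list(branch = branch, iterations = it, consistent = consistent))
}

#' Compare learned weights with the analytic balance solution
#'
#' Collapses a (typically trained) network to population-summed effective
#' weights and reports the relative deviation of the learned SOM-to-PV and
#' VIP-to-PV strengths from the constraint solution evaluated at the
#' network's own effective `w_PP` and `w_EP`. Additionally quantifies the
#' dendritic cancellation: the residual rectified dendritic activity during
#' a feedback phase, relative to the motor drive that had to be canceled.
#'
#' @param network An `npe_network`.
#' @param fb_strength Feedback stimulus (1/s) used for the dendritic
#'   residual; defaults to 7 for plastic and 3.5 for non-plastic networks.
#' @param dt Integration step (ms).
#' @return A tibble with rows `w_ps`, `w_pv` (learned vs analytic,
#'   relative deviation) and `dendrite` (residual fraction).
#' @export
check_balance <- function(network, fb_strength = NULL, dt = 0.1) {
  fb_strength <- fb_strength %||% (if (network$plastic) 7 else 3.5)
  ew <- effective_weights(network)
  cons <- solve_constraints(v_e = network$input$v_e,
                            v_p = network$input$v_p,
                            m_p = network$input$m_p,
                            w_pp = ew[["pp"]], w_ep = ew[["ep"]],
                            w_sv = ew[["sv"]], w_vs = ew[["vs"]],
                            check_dale = FALSE)
  phases <- tibble::tibble(kind = c("baseline", "feedback"),
                           v = c(0, fb_strength), m = c(0, fb_strength),
                           duration = c(1000, 1000))
  sim <- simulate_protocol(network, phases, dt = dt, record_every = 0)
  dend_fb <- mean(sim$avg$i_d_syn[2, ] + sim$avg$ca[2, ])
  tibble::tibble(
    quantity = c("w_ps", "w_pv", "dendrite"),
    learned = c(ew[["ps"]], ew[["pv"]], max(dend_fb, 0)),
    analytic = c(cons$w_ps, cons$w_pv, 0),
    reference = c(abs(cons$w_ps), abs(cons$w_pv), fb_strength),
    rel_deviation = c(
      abs(ew[["ps"]] - cons$w_ps) / max(abs(cons$w_ps), 1e-12),
      abs(ew[["pv"]] - cons$w_pv) / max(abs(cons$w_pv), 1e-12),
      max(dend_fb, 0) / fb_strength))
}
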