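#' Pyramidal-cell parameters
#'
#' Parameters of the two-compartment pyramidal-cell (PC) rate model. The
#' somatic rate follows \eqn{\tau_E \dot r = -r + [I - \Theta]_+} where the
#' total somatic input \eqn{I} combines the somatic synaptic current and the
#' (rectified) dendritic current, including a threshold-triggered calcium
#' event of amplitude `c_amp` elicited when the total dendritic input exceeds
#' `theta_c`.
#'
#' @param tau_e Somatic rate time constant (ms).
#' @param theta Rheobase \eqn{\Theta} (1/s); input below it yields zero rate.
#' @param lambda_d,lambda_e Fractions of current leaking away from dendrite
#'   and soma respectively (dimensionless, in \[0, 1\]).
#' @param c_amp Calcium-event amplitude (1/s).
#' @param theta_c Calcium threshold \eqn{\Theta_c} (1/s) on the total
#'   synaptically generated dendritic input.
#' @param gain Rate-to-current gain \eqn{g} (1/(pA s)); used only when
#'   converting rate-unit currents to pA in analyses, never in the dynamics.
#' @param dend_rect Logical; rectify the dendritic contribution to the soma
#'   so that an excess of dendritic inhibition cannot reach the soma.
#'   Disable to study the variant without the dendritic nonlinearity.
#' @param ca_at_threshold Heaviside convention at the calcium threshold:
#'   `FALSE` (default) means `H(0) = 0`, i.e. an event requires strictly
#'   suprathreshold drive.
#' @return A list of class `pc_params`.
#' @export
#' @examples
#' pc_params()
pc_params <- function(tau_e = 60, theta = 14, lambda_d = 0.27,
                      lambda_e = 0.31, c_amp = 7, theta_c = 28,
                      gain = 0.07, dend_rect = TRUE,
                      ca_at_threshold = FALSE) {
  stopifnot(tau_e > 0, lambda_d >= 0, lambda_d <= 1, lambda_e >= 0,
            lambda_e <= 1, c_amp >= 0, theta_c > 0, gain > 0)
  structure(list(tau_e = tau_e, theta = theta, lambda_d = lambda_d,
                 lambda_e = lambda_e, c_amp = c_amp, theta_c = theta_c,
                 gain = gain, dend_rect = isTRUE(dend_rect),
                 ca_at_threshold = isTRUE(ca_at_threshold)),
            class = "pc_params")
}

#' Interneuron parameters
#'
#' @param tau_i Rate time constant (ms) shared by PV, SOM and VIP units,
#'   chosen to resemble a fast GABA-A time constant.
#' @return A list of class `interneuron_params`.
#' @export
interneuron_params <- function(tau_i = 2) {
  stopifnot(tau_i > 0)
  structure(list(tau_i = tau_i), class = "interneuron_params")
}

#' Population sizes
#'
#' @param n_pc Number of pyramidal cells.
#' @param n_pv,n_som,n_vip Numbers of PV, SOM and VIP interneurons.
#' @return A list of class `population_sizes`.
#' @export
population_sizes <- function(n_pc = 70, n_pv = 10, n_som = 10, n_vip = 10) {
  stopifnot(n_pc > 0, n_pv > 0, n_som > 0, n_vip > 0)
  structure(list(n_pc = as.integer(n_pc), n_pv = as.integer(n_pv),
                 n_som = as.integer(n_som), n_vip = as.integer(n_vip)),
            class = "population_sizes")
}

# flat parameter list handed to the C++ integrator
sim_par_list <- function(pc, inter) {
  list(tau_e = pc$tau_e, tau_i = inter$tau_i, theta = pc$theta,
       lambda_d = pc$lambda_d, lambda_e = pc$lambda_e, c_amp = pc$c_amp,
       theta_c = pc$theta_c, dend_rect = pc$dend_rect,
       ca_at_eq = pc$ca_at_threshold)
}
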