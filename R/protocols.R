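#' Input configuration: routing of visual and motor drives
#'
#' Binary flags route the scalar visual drive `v` and motor-prediction
#' drive `m` to the populations: `v_e` (visual to PC somata), `v_p` /
#' `m_p` (visual / motor to PV neurons), and `dendrite_motor` (motor to PC
#' apical dendrites, on by default). A fraction `f_som` of SOM neurons
#' receives `v` (the rest `m`), and a fraction `f_vip` of VIP neurons
#' receives `v` (the rest `m`); by default `f_vip = 1 - f_som` so that at
#' `f_som = 1` all SOM neurons are visual and all VIP neurons carry the
#' motor prediction, the canonical configuration.
#'
#' @param v_e,v_p,m_p Binary flags (0/1).
#' @param f_som Fraction of SOM neurons receiving visual input, in \[0, 1\].
#' @param f_vip Fraction of VIP neurons receiving visual input;
#'   `NULL` means `1 - f_som`.
#' @param dendrite_motor Logical; PC dendrites receive the motor drive.
#' @return A list of class `input_config`.
#' @export
#' @examples
#' input_config()                      # canonical nPE configuration
#' input_config(v_e = 0, m_p = 1)      # PCs without visual, PV with motor
input_config <- function(v_e = 1, v_p = 1, m_p = 0, f_som = 1,
                         f_vip = NULL, dendrite_motor = TRUE) {
  stopifnot(v_e %in% 0:1, v_p %in% 0:1, m_p %in% 0:1,
            f_som >= 0, f_som <= 1)
  f_vip <- f_vip %||% (1 - f_som)
  stopifnot(f_vip >= 0, f_vip <= 1)
  structure(list(v_e = as.integer(v_e), v_p = as.integer(v_p),
                 m_p = as.integer(m_p), f_som = f_som, f_vip = f_vip,
                 dendrite_motor = isTRUE(dendrite_motor)),
            class = "input_config")
}

phase_kinds <- c("baseline", "feedback", "mismatch", "playback",
                 "independent")

validate_phases <- function(phases) {
  stopifnot(is.data.frame(phases),
            all(c("kind", "v", "m", "duration") %in% names(phases)))
  stopifnot(all(phases$kind %in% phase_kinds), all(phases$duration > 0),
            all(phases$v >= 0), all(phases$m >= 0))
  bad <- (phases$kind == "baseline" & (phases$v != 0 | phases$m != 0)) |
    (phases$kind == "feedback" & (phases$v != phases$m | phases$v <= 0)) |
    (phases$kind == "mismatch" & phases$m <= phases$v) |
    (phases$kind == "playback" & phases$v <= phases$m)
  if (any(bad))
    stop("phase ", which(bad)[1], " violates its kind invariant ",
         "(baseline: v=m=0; feedback: v=m>0; mismatch: m>v; playback: v>m)",
         call. = FALSE)
  invisible(phases)
}

#' Generate a training stimulus sequence
#'
#' Builds the phase sequence a plastic network is exposed to during
#' learning. All stimulus and baseline phases last 1 s by default.
#'
#' * `"qt"` (quasi-natural training): alternating feedback (`v = m = s`)
#'   and playback (`v = s`, `m = playback_m`) stimuli, each preceded by a
#'   baseline phase; `s` is drawn fresh per stimulus from
#'   \eqn{U(0, \mathrm{stim\_max})}.
#' * `"rt"` (random gain training): baselines alternating with phases in
#'   which `v` and `m` are independent \eqn{U(0, \mathrm{stim\_max})}
#'   draws (kind `"independent"`).
#' * `"ct"` (coupled training): baselines alternating with feedback phases
#'   only — perfectly coupled sensorimotor experience.
#'
#' @param paradigm `"qt"`, `"rt"` or `"ct"`.
#' @param n_stimuli Number of stimulus (non-baseline) phases.
#' @param stim_max Upper end of the uniform stimulus distribution (1/s).
#' @param playback_m Motor drive during training playback phases (the
#'   playback stimulus is visual input not predicted by motor commands;
#'   default 0).
#' @param stim_dur,baseline_dur Phase durations (ms).
#' @param seed Integer seed for the stimulus random stream.
#' @return A tibble of phases (`kind`, `v`, `m`, `duration`).
#' @export
#' @examples
#' training_sequence("qt", n_stimuli = 4, seed = 1)
training_sequence <- function(paradigm = c("qt", "rt", "ct"),
                              n_stimuli = 500, stim_max = 7,
                              playback_m = 0, stim_dur = 1000,
                              baseline_dur = 1000, seed = NULL) {
  paradigm <- match.arg(paradigm)
  stopifnot(n_stimuli > 0, stim_max > 0)
  gen <- function() {
    stim <- switch(
      paradigm,
      qt = {
        s <- runif(n_stimuli, 0, stim_max)
        pb <- seq_len(n_stimuli) %% 2 == 0   # FB, PB, FB, PB, ...
        tibble::tibble(kind = ifelse(pb, "playback", "feedback"),
                       v = s, m = ifelse(pb, playback_m, s))
      },
      rt = tibble::tibble(kind = "independent",
                          v = runif(n_stimuli, 0, stim_max),
                          m = runif(n_stimuli, 0, stim_max)),
      ct = {
        s <- runif(n_stimuli, 0, stim_max)
        tibble::tibble(kind = "feedback", v = s, m = s)
      })
    stim$duration <- stim_dur
    bl <- tibble::tibble(kind = "baseline", v = 0, m = 0,
                         duration = baseline_dur)
    out <- vector("list", 2L * n_stimuli)
    out[seq(1, 2 * n_stimuli, by = 2)] <- list(bl)
    out[seq(2, 2 * n_stimuli, by = 2)] <-
      lapply(seq_len(n_stimuli), function(i) stim[i, ])
    dplyr::bind_rows(out)
  }
  phases <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  # feedback phases with a zero draw degenerate to baseline; relabel them
  phases$kind[phases$kind %in% c("feedback", "playback") &
                phases$v == 0 & phases$m == 0] <- "baseline"
  validate_phases(phases)
}

#' Feedback / mismatch / playback test triplet
#'
#' The canonical post-learning probe: baseline, feedback (`v = m = s`),
#' baseline, mismatch (`v = 0`, `m = s`), baseline, playback (`v = s`,
#' `m = 0`), each 1 s. Stimulus strength is 7 (1/s) for plastic and 3.5 for
#' non-plastic networks by convention.
#'
#' @param strength Stimulus strength `s` (1/s), > 0.
#' @param mismatch_v,playback_m Visual drive during mismatch and motor
#'   drive during playback; nonzero values probe partial mismatches.
#' @param duration Phase duration (ms).
#' @return A tibble of six phases.
#' @export
test_triplet <- function(strength, mismatch_v = 0, playback_m = 0,
                         duration = 1000) {
  stopifnot(length(strength) == 1, strength > 0)
  bl <- tibble::tibble(kind = "baseline", v = 0, m = 0, duration = duration)
  tt <- dplyr::bind_rows(
    bl,
    tibble::tibble(kind = "feedback", v = strength, m = strength,
                   duration = duration),
    bl,
    tibble::tibble(kind = "mismatch", v = mismatch_v, m = strength,
                   duration = duration),
    bl,
    tibble::tibble(kind = "playback", v = strength, m = playback_m,
                   duration = duration))
  validate_phases(tt)
}

# which SOM / VIP units receive the visual drive (the rest receive motor);
# deterministic first-ceil(f * N) assignment, fixed for the run
routing_groups <- function(network) {
  ns <- network$sizes$n_som; nv <- network$sizes$n_vip
  som_vis <- seq_len(ns) <= ceiling(network$input$f_som * ns)
  vip_vis <- seq_len(nv) <= ceiling(network$input$f_vip * nv)
  list(som_visual = som_vis, vip_visual = vip_vis)
}

#' Route stimulus drives to per-neuron external inputs
#'
#' Combines the network's constant background inputs with the visual drive
#' `v` and motor drive `m` of one phase according to the network's
#' [input_config()]: PC somata receive `V_E v`, PC dendrites receive `m`
#' (if `dendrite_motor`), PV neurons receive `V_P v + M_P m`, the first
#' `ceil(f_som N_SOM)` SOM units receive `v` and the rest `m`, and
#' likewise for VIP units with `f_vip`.
#'
#' @param network An `npe_network`.
#' @param v,m Visual and motor drive (1/s), both >= 0.
#' @return Named list of per-neuron drive vectors `x_e`, `x_d`, `x_p`,
#'   `x_s`, `x_v`.
#' @export
route_inputs <- function(network, v = 0, m = 0) {
  stopifnot(v >= 0, m >= 0)
  cfg <- network$input
  sz <- network$sizes
  bg <- network$background
  grp <- routing_groups(network)
  list(
    x_e = rep_len(bg$x_e, sz$n_pc) + cfg$v_e * v,
    x_d = rep_len(bg$x_d, sz$n_pc) + if (cfg$dendrite_motor) m else 0,
    x_p = rep_len(bg$x_p, sz$n_pv) + cfg$v_p * v + cfg$m_p * m,
    x_s = rep_len(bg$x_s, sz$n_som) + ifelse(grp$som_visual, v, m),
    x_v = rep_len(bg$x_v, sz$n_vip) + ifelse(grp$vip_visual, v, m))
}

#' Apply a simulated optogenetic manipulation
#'
#' Adds a constant offset to the external drive of every unit of one
#' interneuron population: -8 (1/s) for inactivation and +5 (1/s) for
#' activation. The offset enters the rate equation before rectification, so
#' partial inactivation is possible.
#'
#' @param drives Drive list as returned by [route_inputs()].
#' @param population `"pv"`, `"som"` or `"vip"`.
#' @param mode `"inactivate"`, `"activate"` or `"none"` (identity).
#' @param inactivate_input,activate_input Offsets (1/s).
#' @return The modified drive list.
#' @export
apply_opto <- function(drives, population = c("pv", "som", "vip"),
                       mode = c("inactivate", "activate", "none"),
                       inactivate_input = -8, activate_input = 5) {
  mode <- match.arg(mode)
  if (mode == "none") return(drives)
  population <- match.arg(population)
  off <- if (mode == "inactivate") inactivate_input else activate_input
  slot <- switch(population, pv = "x_p", som = "x_s", vip = "x_v")
  drives[[slot]] <- drives[[slot]] + off
  drives
}
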