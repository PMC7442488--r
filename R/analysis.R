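#' Per-neuron phase responses relative to baseline
#'
#' Computes \eqn{\Delta R/R = (r - r_{BL})/r_{BL}} for every neuron and
#' every non-baseline phase of a simulated protocol. The phase rate `r` is
#' the tail average stored by [simulate_protocol()] (the last `avg_window`
#' ms of each phase, excluding onset transients); the baseline rate
#' \eqn{r_{BL}} is the mean tail-averaged rate over the protocol's baseline
#' phases. Neurons with (numerically) zero baseline get `NA` responses and
#' are excluded from classification.
#'
#' @param sim An `npe_sim` from [simulate_protocol()].
#' @param zero_tol Baseline rates below this (1/s) are treated as zero.
#' @return A tibble with columns `population`, `unit`, `phase`, `kind`,
#'   `v`, `m`, `rate`, `baseline_rate`, `drr`.
#' @export
phase_responses <- function(sim, zero_tol = 1e-6) {
  stopifnot(inherits(sim, "npe_sim"))
  bl_idx <- which(sim$phases$kind == "baseline")
  if (length(bl_idx) == 0)
    stop("protocol contains no baseline phase; dR/R is undefined",
         call. = FALSE)
  stim_idx <- which(sim$phases$kind != "baseline")
  pops <- c(PC = "r_e", PV = "r_p", SOM = "r_s", VIP = "r_v")
  purrr::imap_dfr(pops, function(slot, pop) {
    rates <- sim$avg[[slot]]
    r_bl <- colMeans(rates[bl_idx, , drop = FALSE])
    purrr::map_dfr(stim_idx, function(i) {
      ph <- sim$phases[i, ]
      tibble::tibble(
        population = pop, unit = seq_along(r_bl), phase = i,
        kind = ph$kind, v = ph$v, m = ph$m, rate = rates[i, ],
        baseline_rate = r_bl,
        drr = ifelse(r_bl > zero_tol, (rates[i, ] - r_bl) / r_bl,
                     NA_real_))
    })
  })
}

#' Classify pyramidal cells into prediction-error types
#'
#' Applies the rate-based classification to the feedback / mismatch /
#' playback responses of each PC:
#' * `nPE` — \eqn{\Delta R/R > } `mm_threshold` in mismatch, within
#'   `band` in feedback and playback;
#' * `pPE` — symmetric: above threshold in playback only;
#' * `baseline` — within the band in all three phases;
#' * `suppressed_MM` — below `-mm_threshold` in mismatch, in-band
#'   elsewhere;
#' * `other` — the remainder;
#' * `undefined` — zero baseline rate, excluded from labeling.
#'
#' @param x An `npe_sim` containing one feedback, one mismatch and one
#'   playback phase (e.g. a simulated [test_triplet()]), or a tibble from
#'   [phase_responses()].
#' @param mm_threshold Response threshold (default 0.20, i.e. 20%).
#' @param band Tolerated absolute response elsewhere (default 0.10).
#' @return A tibble with one row per PC: `unit`, `fb`, `mm`, `pb`,
#'   `baseline_rate` and `label` (factor with the levels above).
#' @export
classify_pcs <- function(x, mm_threshold = 0.2, band = 0.1) {
  resp <- if (inherits(x, "npe_sim")) phase_responses(x) else x
  pc <- dplyr::filter(resp, .data$population == "PC",
                      .data$kind %in% c("feedback", "mismatch", "playback"))
  missing_kinds <- setdiff(c("feedback", "mismatch", "playback"), pc$kind)
  if (length(missing_kinds) > 0)
    stop("classification needs feedback, mismatch and playback phases; ",
         "missing: ", paste(missing_kinds, collapse = ", "), call. = FALSE)
  wide <- pc |>
    dplyr::group_by(.data$unit, .data$kind) |>
    dplyr::summarise(drr = mean(.data$drr),
                     baseline_rate = .data$baseline_rate[1],
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "drr") |>
    dplyr::rename(fb = "feedback", mm = "mismatch", pb = "playback")
  lab <- function(fb, mm, pb) {
    if (anyNA(c(fb, mm, pb))) return("undefined")
    in_band <- function(z) abs(z) < band
    if (mm > mm_threshold && in_band(fb) && in_band(pb)) return("nPE")
    if (pb > mm_threshold && in_band(fb) && in_band(mm)) return("pPE")
    if (in_band(fb) && in_band(mm) && in_band(pb)) return("baseline")
    if (mm < -mm_threshold && in_band(fb) && in_band(pb))
      return("suppressed_MM")
    "other"
  }
  wide$label <- factor(
    mapply(lab, wide$fb, wide$mm, wide$pb),
    levels = c("nPE", "pPE", "baseline", "suppressed_MM", "other",
               "undefined"))
  dplyr::arrange(wide, dplyr::desc(.data$mm))
}

#' Normalize responses to \[-1, 1\] with baseline at zero
#'
#' Divides each neuron's phase responses by its maximum absolute response,
#' the normalization used to display population response heatmaps.
#' All-zero response sets are left at zero.
#'
#' @param responses A tibble from [phase_responses()] (or any tibble with
#'   `unit`, `population` and `drr` columns).
#' @return The tibble with an added `drr_norm` column.
#' @export
normalize_responses <- function(responses) {
  responses |>
    dplyr::group_by(.data$population, .data$unit) |>
    dplyr::mutate(drr_norm = {
      peak <- max(abs(.data$drr), na.rm = TRUE)
      if (is.finite(peak) && peak > 0) .data$drr / peak else
        .data$drr * 0
    }) |>
    dplyr::ungroup()
}

#' Somatic current decomposition in pA
#'
#' Splits each PC's tail-averaged somatic input per phase into an
#' excitatory part \eqn{(1-\lambda_E) x_E + \lambda_D [I^{syn}_D + c]_+}
#' and an inhibitory (PV-mediated) part \eqn{(1-\lambda_E) w_{EP} r_P},
#' converted from rate units to pA by dividing by the gain `g`.
#'
#' @param sim An `npe_sim`.
#' @param gain Rate-to-current gain `g` in 1/(pA s); defaults to the
#'   network's [pc_params()] value.
#' @return A tibble per PC and phase: `exc_pa`, `inh_pa`,
#'   `net_pa = exc_pa - inh_pa` and the dendritic contribution `dend_pa`.
#' @export
current_decomposition <- function(sim, gain = NULL) {
  stopifnot(inherits(sim, "npe_sim"))
  g <- gain %||% sim$network$pc$gain
  n_pc <- ncol(sim$avg$exc)
  purrr::map_dfr(seq_len(nrow(sim$phases)), function(i) {
    tibble::tibble(
      phase = i, kind = sim$phases$kind[i], unit = seq_len(n_pc),
      exc_pa = sim$avg$exc[i, ] / g, inh_pa = sim$avg$inh[i, ] / g,
      net_pa = (sim$avg$exc[i, ] - sim$avg$inh[i, ]) / g,
      dend_pa = sim$avg$dend[i, ] / g)
  })
}

#' Optogenetic fingerprint of a prediction-error circuit
#'
#' Runs the feedback / mismatch / playback test triplet under a control
#' condition and under all six optogenetic manipulations (inactivation and
#' activation of PV, SOM, VIP), and tabulates how the mean response of the
#' control-classified nPE population changes in each phase. A change
#' smaller than `dead_band` (in \eqn{\Delta R/R}) counts as `"none"`.
#'
#' @param network An `npe_network` (trained, or non-plastic with the
#'   analytic constraint weights).
#' @param strength Test stimulus strength (1/s); defaults to 7 for plastic
#'   and 3.5 for non-plastic networks.
#' @param units PC units to aggregate; `NULL` uses the control-condition
#'   nPE cells (all PCs if none classify as nPE).
#' @param dead_band Categorical dead-band on the \eqn{\Delta R/R} change.
#' @param dt Integration step (ms).
#' @return A tibble: `population`, `mode`, `kind`, mean control and
#'   manipulated responses, `delta` and `change`
#'   (increase/decrease/none).
#' @export
opto_fingerprint <- function(network, strength = NULL, units = NULL,
                             dead_band = 0.1, dt = 0.1) {
  strength <- strength %||% (if (network$plastic) 7 else 3.5)
  triplet <- test_triplet(strength)
  ctrl_sim <- simulate_protocol(network, triplet, dt = dt,
                                record_every = 0)
  ctrl_cls <- classify_pcs(ctrl_sim)
  if (is.null(units)) {
    units <- ctrl_cls$unit[ctrl_cls$label == "nPE"]
    if (length(units) == 0) units <- ctrl_cls$unit
  }
  pop_mean <- function(sim) {
    phase_responses(sim) |>
      dplyr::filter(.data$population == "PC", .data$unit %in% units) |>
      dplyr::group_by(.data$kind) |>
      dplyr::summarise(drr = mean(.data$drr), .groups = "drop")
  }
  ctrl <- pop_mean(ctrl_sim)
  grid <- expand.grid(population = c("pv", "som", "vip"),
                      mode = c("inactivate", "activate"),
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(population, mode) {
    sim <- simulate_protocol(network, triplet, dt = dt, record_every = 0,
                             opto = list(population = population,
                                         mode = mode))
    dplyr::inner_join(ctrl, pop_mean(sim), by = "kind",
                      suffix = c("_ctrl", "_opto")) |>
      dplyr::mutate(
        population = population, mode = mode,
        delta = .data$drr_opto - .data$drr_ctrl,
        change = dplyr::case_when(
          is.na(delta) ~ "undefined",
          delta > dead_band ~ "increase",
          delta < -dead_band ~ "decrease",
          TRUE ~ "none"),
        .before = 1)
  })
}
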