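#' Connection probabilities and pathway table
#'
#' The circuit has eleven structural pathways. Postsynaptic targets are the
#' PC soma (`e`), the PC apical dendrite (`d`) and the PV/SOM/VIP
#' populations (`p`, `s`, `v`); presynaptic sources are the PC (`e`), PV
#' (`p`), SOM (`s`) and VIP (`v`) populations. Pathway codes concatenate
#' post- then presynaptic population (`"ep"` = PV onto PC soma, `"ds"` =
#' SOM onto PC dendrite, ...).
#'
#' @return A tibble with one row per pathway: `pathway`, `post`, `pre`,
#'   `prob` (connection probability), `sign` (+1 excitatory, -1 inhibitory)
#'   and `self` (whether the source and target population coincide, in which
#'   case autapses are excluded).
#' @export
pathway_table <- function() {
  tibble::tibble(
    pathway = c("ep", "ds", "de", "pe", "pp", "ps", "pv",
                "se", "sv", "ve", "vs"),
    post = c("e", "d", "d", "p", "p", "p", "p", "s", "s", "v", "v"),
    pre  = c("p", "s", "e", "e", "p", "s", "v", "e", "v", "e", "s"),
    prob = c(0.6, 0.55, 0.1, 0.45, 0.5, 0.6, 0.5, 0.35, 0.5, 0.1, 0.45),
    sign = c(-1, -1, +1, +1, -1, -1, -1, +1, -1, +1, -1),
    self = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE)
  )
}

#' Mean connection strengths for a given input configuration
#'
#' Non-plastic networks use the fixed strengths `w_EP = 2.8`, `w_DS = 3.5`,
#' `w_PE = 1.5` and `w_PP = 0.1` (if PCs receive visual input) or `1.5`
#' (otherwise), with `w_PS` and `w_PV` computed from the analytic
#' excitation-inhibition balance constraints ([solve_constraints()]).
#' Plastic networks start from `w_EP = 1.75`, `w_DS = 0.35`,
#' `w_PE = 2.5`/`1.2`, `w_PP = 0.5`/`1.5`, `w_PS = 0.3`, `w_PV = 0.6`.
#' Shared non-plastic strengths are `w_DE = 0.42`, `w_SE = 1`,
#' `w_SV = 0.61`, `w_VS = 0.5` and `w_VE = w_ve`.
#'
#' @param input An [input_config()].
#' @param plastic Logical; initial strengths for a plastic network?
#' @param w_ve PC-to-VIP strength (set to 1 by symmetry with `w_SE`).
#' @return Named numeric vector of population-summed mean strengths, one per
#'   pathway of [pathway_table()].
#' @export
default_mean_weights <- function(input = input_config(), plastic = FALSE,
                                 w_ve = 1) {
  v_e <- input$v_e
  base <- c(de = 0.42, se = 1, sv = 0.61, ve = w_ve, vs = 0.5)
  if (plastic) {
    w <- c(ep = 1.75, ds = 0.35,
           pe = if (v_e) 2.5 else 1.2,
           pp = if (v_e) 0.5 else 1.5,
           ps = 0.3, pv = 0.6, base)
  } else {
    w <- c(ep = 2.8, ds = 3.5, pe = 1.5,
           pp = if (v_e) 0.1 else 1.5, base)
    cons <- solve_constraints(v_e = input$v_e, v_p = input$v_p,
                              m_p = input$m_p, w_pp = w[["pp"]],
                              w_ep = w[["ep"]], w_sv = w[["sv"]],
                              w_vs = w[["vs"]])
    w <- c(w, ps = cons$w_ps, pv = cons$w_pv)
  }
  w[pathway_table()$pathway]
}

round_half_up <- function(x) floor(x + 0.5)

# exact in-degree for one pathway
pathway_indegree <- function(n_pre, prob) {
  as.integer(round_half_up(n_pre * prob))
}

pop_n <- function(sizes, code) {
  switch(code, e = sizes$n_pc, d = sizes$n_pc, p = sizes$n_pv,
         s = sizes$n_som, v = sizes$n_vip)
}

# one pathway's weight matrix (n_post x n_pre) with exactly k nonzero
# entries per row, each mean_w / k (non-plastic) or U(0.5, 1.5) * mean_w / k
sample_pathway <- function(n_post, n_pre, k, mean_w, self, plastic) {
  w <- matrix(0, n_post, n_pre)
  if (mean_w == 0 || k == 0) return(w)
  for (i in seq_len(n_post)) {
    pool <- seq_len(n_pre)
    if (self) pool <- pool[pool != i]
    idx <- sample(pool, k, replace = FALSE)
    w[i, idx] <- if (plastic) runif(k, 0.5, 1.5) * mean_w / k else mean_w / k
  }
  w
}

#' Build a randomly connected microcircuit
#'
#' Constructs the full network: random connectivity with fixed in-degree per
#' pathway (every neuron of a type receives exactly
#' `round(N_pre * p)` connections, autapses excluded), connection weights
#' scaled by the in-degree so that the summed afferent weight of each neuron
#' equals the configured population mean regardless of population size, and
#' constant background drives. For non-plastic networks the background
#' inputs are solved analytically so that the baseline operating point is
#' `baseline_rates`; plastic networks use the fixed backgrounds
#' `x_E = 28`, `x_D = 0`, `x_P = x_S = x_V = 2` (1/s).
#'
#' @param sizes A [population_sizes()].
#' @param input An [input_config()] describing how visual (`v`) and motor
#'   (`m`) drives are routed.
#' @param plastic Logical; draw initial weights from
#'   \eqn{U(0.5 w, 1.5 w)/k} for subsequent training instead of using the
#'   fixed non-plastic strengths.
#' @param seed Integer seed for the connectivity random stream (kept
#'   separate from stimulus seeds so structure can be held fixed while
#'   stimuli vary). `NULL` uses the current RNG state.
#' @param pc,inter Neuron parameter sets ([pc_params()],
#'   [interneuron_params()]).
#' @param baseline_rates Target baseline rates (PC, PV, SOM, VIP) in 1/s
#'   used to solve non-plastic background drives.
#' @param w_ve See [default_mean_weights()].
#' @param mean_weights Optional named vector overriding
#'   [default_mean_weights()].
#' @param prob_overrides Optional named vector overriding individual
#'   connection probabilities of [pathway_table()] (e.g.
#'   `c(pe = 0.9)` for dense PC-to-PV connectivity, the regime in which
#'   the local recurrent-drive plasticity rule approximates
#'   backpropagation well).
#' @return An object of class `npe_network`: weight matrices, structural
#'   masks, parameters, background drives and the realized input routing.
#' @export
#' @examples
#' net <- build_network(seed = 1)
#' tidy(net)
build_network <- function(sizes = population_sizes(),
                          input = input_config(),
                          plastic = FALSE, seed = NULL,
                          pc = pc_params(), inter = interneuron_params(),
                          baseline_rates = c(1, 2, 2, 4), w_ve = 1,
                          mean_weights = NULL, prob_overrides = NULL) {
  stopifnot(inherits(sizes, "population_sizes"),
            inherits(input, "input_config"))
  means <- mean_weights %||%
    default_mean_weights(input = input, plastic = plastic, w_ve = w_ve)
  pt <- pathway_table()
  if (!is.null(prob_overrides)) {
    stopifnot(all(names(prob_overrides) %in% pt$pathway),
              all(prob_overrides >= 0), all(prob_overrides <= 1))
    pt$prob[match(names(prob_overrides), pt$pathway)] <- prob_overrides
  }
  stopifnot(all(pt$pathway %in% names(means)))

  draw <- function() {
    weights <- list()
    for (r in seq_len(nrow(pt))) {
      pw <- pt$pathway[r]
      n_post <- pop_n(sizes, pt$post[r])
      n_pre <- pop_n(sizes, pt$pre[r])
      k <- pathway_indegree(n_pre, pt$prob[r])
      if (k == 0 && means[[pw]] > 0)
        stop("pathway '", pw, "': in-degree 0 with nonzero mean strength; ",
             "increase the presynaptic population", call. = FALSE)
      if (pt$self[r] && k > n_pre - 1)
        stop("pathway '", pw, "': in-degree exceeds available partners",
             call. = FALSE)
      weights[[pw]] <- sample_pathway(n_post, n_pre, k, means[[pw]],
                                      pt$self[r], plastic)
    }
    weights
  }
  weights <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  masks <- lapply(weights, function(w) (w > 0) * 1)

  net <- structure(
    list(sizes = sizes, input = input, pc = pc, inter = inter,
         weights = weights, masks = masks, means = means,
         plastic = plastic, seed = seed, training = NULL),
    class = "npe_network")

  if (plastic) {
    net$background <- list(x_e = 28, x_d = 0, x_p = 2, x_s = 2, x_v = 2)
  } else {
    bg <- solve_background_inputs(effective_weights(net), input = input,
                                  target_rates = baseline_rates, pc = pc)
    net$background <- bg[c("x_e", "x_d", "x_p", "x_s", "x_v")]
  }
  net
}

#' Population-summed effective weights
#'
#' Collapses a network's weight matrices to mean-field scalars: the summed
#' afferent weight per postsynaptic neuron, averaged over the population.
#' At initialization this equals the configured mean strengths exactly for
#' non-plastic networks and in expectation for plastic ones.
#'
#' @param network An `npe_network`.
#' @return Named numeric vector, one entry per pathway.
#' @export
effective_weights <- function(network) {
  vapply(network$weights, function(w) mean(rowSums(w)), numeric(1))
}

#' Clip weight magnitudes at zero (Dale's principle)
#'
#' All weights are stored as nonnegative magnitudes whose sign is applied
#' structurally (inhibitory pathways enter the dynamics with a minus sign).
#' This helper clips any negative magnitude at zero while preserving the
#' structural zero pattern, and is applied after every plasticity step.
#'
#' @param weights A named list of weight matrices (or an `npe_network`).
#' @return The clipped object, same shape as the input.
#' @export
enforce_dale <- function(weights) {
  if (inherits(weights, "npe_network")) {
    weights$weights <- enforce_dale(weights$weights)
    return(weights)
  }
  lapply(weights, function(w) pmax(w, 0))
}

#' @export
print.npe_network <- function(x, ...) {
  s <- x$sizes
  cat("<npe_network> ", if (x$plastic) "plastic" else "non-plastic",
      if (!is.null(x$training)) " (trained)", "\n", sep = "")
  cat(sprintf("  populations: %d PC, %d PV, %d SOM, %d VIP\n",
              s$n_pc, s$n_pv, s$n_som, s$n_vip))
  cat(sprintf("  input routing: V_E=%d V_P=%d M_P=%d f_SOM=%.2f f_VIP=%.2f\n",
              x$input$v_e, x$input$v_p, x$input$m_p, x$input$f_som,
              x$input$f_vip))
  ew <- effective_weights(x)
  cat("  effective weights: ",
      paste(sprintf("%s=%.3g", names(ew), ew), collapse = " "), "\n")
  invisible(x)
}
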