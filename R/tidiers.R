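#' Tidy a network into a pathway summary
#'
#' @param x An `npe_network`.
#' @param ... Unused.
#' @return A tibble with one row per pathway: structural properties,
#'   configured mean strength and realized effective (population-summed)
#'   strength.
#' @export
tidy.npe_network <- function(x, ...) {
  pt <- pathway_table()
  ew <- effective_weights(x)
  pt$mean_strength <- unname(x$means[pt$pathway])
  pt$effective <- unname(ew[pt$pathway])
  pt$in_degree <- vapply(x$weights[pt$pathway],
                         function(w) as.integer(sum(w[1, ] > 0)),
                         integer(1))
  pt
}

#' One-row summary of a network
#'
#' @param x An `npe_network`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, input flags, plastic/trained status and
#'   (if trained) convergence information.
#' @export
glance.npe_network <- function(x, ...) {
  tr <- x$training
  tibble::tibble(
    n_pc = x$sizes$n_pc, n_pv = x$sizes$n_pv, n_som = x$sizes$n_som,
    n_vip = x$sizes$n_vip, v_e = x$input$v_e, v_p = x$input$v_p,
    m_p = x$input$m_p, f_som = x$input$f_som, plastic = x$plastic,
    trained = !is.null(tr),
    converged = if (!is.null(tr)) tr$converged else NA,
    n_stimuli = if (!is.null(tr)) tr$n_stimuli else NA_integer_)
}

#' Tidy a simulation into its phase-averaged rates
#'
#' @param x An `npe_sim`.
#' @param ... Unused.
#' @return A long tibble: `phase`, `kind`, `population`, `unit`, `rate`.
#' @export
tidy.npe_sim <- function(x, ...) {
  pops <- c(PC = "r_e", PV = "r_p", SOM = "r_s", VIP = "r_v")
  purrr::imap_dfr(pops, function(slot, pop) {
    m <- x$avg[[slot]]
    purrr::map_dfr(seq_len(nrow(m)), function(i) {
      tibble::tibble(phase = i, kind = x$phases$kind[i], population = pop,
                     unit = seq_len(ncol(m)), rate = m[i, ])
    })
  })
}
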