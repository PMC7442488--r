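# Shared fixtures, built in code at test time.

# default non-plastic network with analytically balanced weights
default_nonplastic <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(seed = 101)
    net
  }
})

# small sizes for cheap dynamical tests
small_sizes <- function() population_sizes(n_pc = 12, n_pv = 4,
                                           n_som = 4, n_vip = 4)

# a fully connected homogeneous network, built by hand (used to compare
# plasticity rule variants where dense PC<->PV connectivity matters)
dense_network <- function(n_pc = 8, n_in = 4, seed = 1) {
  sizes <- population_sizes(n_pc, n_in, n_in, n_in)
  means <- default_mean_weights(input_config(), plastic = TRUE)
  full <- function(n_post, n_pre, w) matrix(w / n_pre, n_post, n_pre)
  pt <- pathway_table()
  weights <- lapply(seq_len(nrow(pt)), function(r) {
    full(pop_n_test(sizes, pt$post[r]), pop_n_test(sizes, pt$pre[r]),
         means[[pt$pathway[r]]])
  })
  names(weights) <- pt$pathway
  net <- build_network(sizes = sizes, input = input_config(),
                       plastic = TRUE, seed = seed)
  net$weights <- weights
  net$masks <- lapply(weights, function(w) (w > 0) * 1)
  net
}

pop_n_test <- function(sizes, code) {
  switch(code, e = sizes$n_pc, d = sizes$n_pc, p = sizes$n_pv,
         s = sizes$n_som, v = sizes$n_vip)
}

# random non-plastic networks in the linear regime: modest weights, all
# units interior, used for oracle-equivalence checks
random_linear_network <- function(seed) {
  withr::with_seed(seed, {
    means <- c(ep = runif(1, 1.5, 3), ds = runif(1, 2, 4),
               de = runif(1, 0, 0.3), pe = runif(1, 0.5, 1.5),
               pp = runif(1, 0, 0.3), ps = runif(1, 0.2, 0.8),
               pv = runif(1, 0.2, 0.8), se = runif(1, 0.5, 1.2),
               sv = runif(1, 0.2, 0.7), ve = runif(1, 0.5, 1.2),
               vs = runif(1, 0.2, 0.6))
    build_network(sizes = small_sizes(), seed = seed + 1000,
                  mean_weights = means,
                  baseline_rates = runif(4, 1, 4))
  })
}

# a quasi-natural-trained default network, trained once per session and
# reused by the slower integration tests
trained_default <- local({
  net <- NULL
  function() {
    if (is.null(net)) {
      plastic <- build_network(plastic = TRUE, seed = 7)
      net <<- train_network(plastic,
                            training_sequence("qt", 4000, seed = 17),
                            plasticity_config(), dt = 1)
    }
    net
  }
})
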