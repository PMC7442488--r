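# build a minimal npe_sim by hand: a triplet protocol with prescribed
# phase-average rates, for exercising the analysis layer in isolation
fake_sim <- function(rates_pc, baseline = 1, n_phase_kinds =
                       c("baseline", "feedback", "mismatch", "playback")) {
  n_pc <- ncol(rates_pc)
  phases <- tibble::tibble(
    kind = n_phase_kinds,
    v = c(0, 7, 0, 7), m = c(0, 7, 7, 0), duration = 1000,
    phase = seq_along(n_phase_kinds))
  one <- function(n, val = baseline)
    matrix(val, length(n_phase_kinds), n)
  avg <- list(r_e = rbind(rep(baseline, n_pc), rates_pc),
              r_p = one(4), r_s = one(4), r_v = one(4),
              i_e_syn = one(n_pc), i_d_syn = one(n_pc, 0),
              i_d0 = one(n_pc, 0), ca = one(n_pc, 0),
              exc = one(n_pc, 14), inh = one(n_pc, 0),
              dend = one(n_pc, 0))
  structure(list(network = default_nonplastic(), phases = phases,
                 avg = avg, traces = NULL, current_traces = NULL),
            class = "npe_sim")
}

test_that("dR/R is computed against the baseline-phase average", {
  # one PC at 1.3 in mismatch (dR/R = 0.30), flat elsewhere
  sim <- fake_sim(rbind(c(1, 1), c(1.3, 1), c(1, 0.5)))
  resp <- phase_responses(sim)
  pc <- resp[resp$population == "PC", ]
  expect_equal(pc$drr[pc$kind == "mismatch" & pc$unit == 1], 0.3)
  expect_equal(pc$drr[pc$kind == "feedback" & pc$unit == 1], 0)
  expect_equal(pc$drr[pc$kind == "playback" & pc$unit == 2], -0.5)
})

test_that("zero-baseline neurons are flagged undefined", {
  sim <- fake_sim(rbind(c(1, 1), c(1.5, 1), c(1, 1)))
  sim$avg$r_e[, 2] <- 0     # second PC silent everywhere
  resp <- phase_responses(sim)
  expect_true(all(is.na(resp$drr[resp$population == "PC" &
                                   resp$unit == 2])))
  cls <- classify_pcs(sim)
  expect_equal(as.character(cls$label[cls$unit == 2]), "undefined")
})

test_that("classification thresholds implement the published rule", {
  cases <- list(
    list(fb = 0.05, mm = 0.50, pb = -0.02, lab = "nPE"),
    list(fb = 0, mm = 0, pb = 0, lab = "baseline"),
    list(fb = 0.02, mm = -0.01, pb = 0.45, lab = "pPE"),
    list(fb = 0.01, mm = -0.35, pb = 0.03, lab = "suppressed_MM"),
    list(fb = 0.25, mm = 0.50, pb = 0.02, lab = "other"),   # FB off-band
    list(fb = 0.05, mm = 0.15, pb = 0.05, lab = "other"))   # over band,
  # under threshold
  rates <- vapply(cases, function(cc) 1 + c(cc$fb, cc$mm, cc$pb),
                  numeric(3))
  sim <- fake_sim(rates)
  cls <- classify_pcs(sim)
  got <- as.character(cls$label[order(cls$unit)])
  expect_equal(got, vapply(cases, `[[`, "", "lab"))
})

test_that("labels are exclusive and exhaustive over random responses", {
  withr::with_seed(31, {
    rates <- 1 + matrix(runif(3 * 200, -0.6, 0.6), 3, 200)
    cls <- classify_pcs(fake_sim(rates))
    expect_equal(nrow(cls), 200)
    expect_false(anyNA(cls$label))
  })
})

test_that("response normalization scales by the maximum magnitude", {
  sim <- fake_sim(rbind(c(1.5, 1, 1), c(2, 1, 0.5), c(0.75, 1, 1)))
  resp <- normalize_responses(phase_responses(sim))
  pc1 <- resp[resp$population == "PC" & resp$unit == 1, ]
  expect_equal(sort(pc1$drr_norm), sort(c(0.5, 1, -0.25)))
  # all-zero responses stay at zero
  pc2 <- resp[resp$population == "PC" & resp$unit == 2, ]
  expect_true(all(pc2$drr_norm == 0))
  # (-2, 1, 0) scales to (-1, 0.5, 0)
  sim3 <- fake_sim(rbind(c(1, 1, 1), c(-1, 1, 1), c(2, 1, 1))) # unit 1:
  # fb 0, mm -2, pb 1 after dR/R
  sim3$avg$r_e[2:4, 1] <- c(1, -1, 2)
  resp3 <- normalize_responses(phase_responses(sim3))
  u1 <- resp3[resp3$population == "PC" & resp3$unit == 1, ]
  expect_equal(u1$drr_norm[u1$kind == "mismatch"], -1)
  expect_equal(u1$drr_norm[u1$kind == "playback"], 0.5)
  expect_equal(u1$drr_norm[u1$kind == "feedback"], 0)
})

test_that("current decomposition converts rate units to pA by the gain", {
  sim <- fake_sim(rbind(c(1, 1), c(1, 1), c(1, 1)))
  dec <- current_decomposition(sim)
  # excitation fixed at 14 rate units = 14 / 0.07 = 200 pA
  expect_equal(dec$exc_pa, rep(200, nrow(dec)))
  expect_equal(dec$net_pa, dec$exc_pa - dec$inh_pa)
})

test_that("the balanced network keeps net somatic current flat", {
  net <- default_nonplastic()
  sim <- simulate_protocol(net, test_triplet(3.5), record_every = 0)
  dec <- current_decomposition(sim)
  by_phase <- dec |>
    dplyr::group_by(.data$phase, .data$kind) |>
    dplyr::summarise(net = mean(.data$net_pa), exc = mean(.data$exc_pa),
                     .groups = "drop")
  net_bl <- mean(by_phase$net[by_phase$kind == "baseline"])
  fb <- by_phase[by_phase$kind == "feedback", ]
  expect_lt(abs(fb$net - net_bl), 0.05 * fb$exc)
})

test_that("fingerprints are deterministic and well-formed", {
  net <- default_nonplastic()
  fp1 <- opto_fingerprint(net)
  expect_equal(nrow(fp1), 6 * 3)      # 6 manipulations x 3 phases
  expect_true(all(fp1$change %in% c("increase", "decrease", "none",
                                    "undefined")))
  fp2 <- opto_fingerprint(net)
  expect_identical(fp1, fp2)
})
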