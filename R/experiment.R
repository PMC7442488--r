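#' Default experiment configuration
#'
#' A fully serializable description of one experiment: network sizes,
#' input routing, training paradigm, plasticity settings, integration
#' steps and the two independent random seeds (connectivity vs. stimuli,
#' so structure can be held fixed while stimuli vary).
#'
#' @param preset Optional preset name filling in a recipe:
#'   `"npe_emergence"` (quasi-natural training of the default plastic
#'   network, report the nPE count), `"opto_grid"` (optogenetic fingerprint
#'   grid over the four PC/PV input configurations) or `"som_vip_sweep"`
#'   (sweep of the SOM/VIP visual fraction `f`).
#' @return A named list of class `experiment_config`.
#' @export
experiment_config <- function(preset = NULL) {
  cfg <- list(
    preset = preset %||% "custom",
    sizes = list(n_pc = 70, n_pv = 10, n_som = 10, n_vip = 10),
    input = list(v_e = 1, v_p = 1, m_p = 0, f_som = 1, f_vip = NULL),
    plastic = TRUE,
    paradigm = "qt", n_stimuli = 3000, stim_max = 7,
    plasticity = list(variant = "backprop"),
    test_strength = NULL,
    dt_test = 0.1, dt_train = 1,
    seed_connectivity = 1L, seed_stimuli = 2L,
    opto_grid = FALSE,
    f_sweep = NULL)
  if (!is.null(preset)) {
    cfg <- switch(
      preset,
      npe_emergence = cfg,
      opto_grid = modifyList(cfg, list(opto_grid = TRUE)),
      som_vip_sweep = modifyList(
        cfg, list(f_sweep = c(1, 0.75, 0.5, 0.25, 0))),
      stop("unknown preset '", preset, "'", call. = FALSE))
  }
  structure(cfg, class = "experiment_config")
}

config_keys <- function() names(unclass(experiment_config()))

#' Load an experiment configuration from YAML
#'
#' Unknown keys are rejected with the offending key path; a missing seed is
#' auto-generated and recorded in the manifest when the experiment runs.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
#' @examples
#' cfg <- load_experiment_config(
#'   system.file("extdata", "example-config.yaml",
#'               package = "npecircuit"))
#' cfg$paradigm
load_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (blk in c("sizes", "input", "plasticity")) {
    if (!is.null(raw[[blk]])) {
      tmpl <- experiment_config()[[blk]]
      bad <- setdiff(names(raw[[blk]]),
                     union(names(tmpl),
                           names(formals(plasticity_config))))
      if (length(bad) > 0)
        stop("unknown configuration key(s): ",
             paste(paste0(blk, "$", bad), collapse = ", "), call. = FALSE)
    }
  }
  num_keys <- c("n_stimuli", "stim_max", "dt_test", "dt_train",
                "seed_connectivity", "seed_stimuli")
  for (k in intersect(num_keys, names(raw)))
    if (!is.numeric(raw[[k]]))
      stop("configuration key '", k, "' must be numeric, got '",
           raw[[k]], "'", call. = FALSE)
  cfg <- modifyList(unclass(experiment_config()), raw)
  # reinstate NULL-valued keys dropped by YAML / modifyList
  missing <- setdiff(config_keys(), names(cfg))
  cfg[missing] <- list(NULL)
  if (!"f_vip" %in% names(cfg$input)) cfg$input["f_vip"] <- list(NULL)
  cfg <- cfg[config_keys()]
  structure(cfg, class = "experiment_config")
}

#' Save an experiment configuration to YAML
#'
#' @param config An `experiment_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

build_from_config <- function(cfg, f_som = NULL) {
  inp <- cfg$input
  input <- input_config(v_e = inp$v_e, v_p = inp$v_p, m_p = inp$m_p,
                        f_som = f_som %||% inp$f_som,
                        f_vip = if (is.null(f_som)) inp$f_vip else NULL)
  build_network(sizes = do.call(population_sizes, cfg$sizes),
                input = input, plastic = isTRUE(cfg$plastic),
                seed = cfg$seed_connectivity)
}

#' Run a configured experiment end-to-end
#'
#' Executes build, (optionally) train, test, classify and (optionally) the
#' optogenetic grid or the SOM/VIP input-fraction sweep, then writes all
#' artifacts (weights, response table, classification, summary) as
#' CSV/JSON files plus a manifest with checksums, seeds and the package
#' version.
#'
#' @param config An `experiment_config` (or path to a YAML file).
#' @param outdir Output directory (created if missing); `NULL` skips
#'   writing and only returns the results.
#' @return A list with the trained network, classification tibble, summary
#'   list, and any sweep/fingerprint tables.
#' @export
run_experiment <- function(config = experiment_config(), outdir = NULL) {
  if (is.character(config)) config <- load_experiment_config(config)
  cfg <- config
  if (is.null(cfg$seed_connectivity)) {
    cfg$seed_connectivity <- sample.int(.Machine$integer.max, 1)
  }
  if (is.null(cfg$seed_stimuli)) {
    cfg$seed_stimuli <- sample.int(.Machine$integer.max, 1)
  }

  run_one <- function(f_som = NULL) {
    net <- build_from_config(cfg, f_som = f_som)
    if (isTRUE(cfg$plastic)) {
      seq <- training_sequence(cfg$paradigm, cfg$n_stimuli,
                               stim_max = cfg$stim_max,
                               seed = cfg$seed_stimuli)
      pcfg <- do.call(plasticity_config, cfg$plasticity)
      net <- train_network(net, seq, pcfg, dt = cfg$dt_train)
    }
    strength <- cfg$test_strength %||% (if (isTRUE(cfg$plastic)) 7 else 3.5)
    sim <- simulate_protocol(net, test_triplet(strength),
                             dt = cfg$dt_test, record_every = 0)
    list(network = net, sim = sim, classification = classify_pcs(sim))
  }

  if (!is.null(cfg$f_sweep)) {
    runs <- lapply(cfg$f_sweep, function(f) run_one(f_som = f))
    sweep <- purrr::map2_dfr(cfg$f_sweep, runs, function(f, r) {
      dplyr::count(r$classification, .data$label, .drop = FALSE) |>
        dplyr::mutate(f_som = f, fraction = .data$n / sum(.data$n))
    })
    main <- runs[[1]]
    extra <- list(f_sweep = sweep)
  } else {
    main <- run_one()
    extra <- list()
    if (isTRUE(cfg$opto_grid)) {
      extra$fingerprint <- opto_fingerprint(main$network)
    }
  }

  counts <- table(main$classification$label)
  summary <- list(
    preset = cfg$preset,
    seeds = list(connectivity = cfg$seed_connectivity,
                 stimuli = cfg$seed_stimuli),
    n_pc = main$network$sizes$n_pc,
    n_npe = unname(counts[["nPE"]]),
    label_counts = as.list(counts),
    converged = if (!is.null(main$network$training))
      main$network$training$converged else NA)

  results <- c(list(network = main$network,
                    classification = main$classification,
                    summary = summary, config = cfg), extra)
  if (!is.null(outdir)) save_results(results, outdir)
  results
}

#' Persist experiment results
#'
#' Writes the classification table, effective weights, any sweep or
#' fingerprint tables (CSV), the summary (JSON), the configuration (YAML)
#' and a manifest JSON that lists every written file with its MD5 checksum.
#'
#' @param results List from [run_experiment()].
#' @param outdir Output directory.
#' @return Path of the manifest file, invisibly.
#' @export
save_results <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr_csv <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr_csv(results$classification, "classification.csv")
  wr_csv(tidy(results$network), "weights.csv")
  if (!is.null(results$f_sweep)) wr_csv(results$f_sweep, "f_sweep.csv")
  if (!is.null(results$fingerprint))
    wr_csv(results$fingerprint, "fingerprint.csv")
  if (!is.null(results$network$training) &&
      nrow(results$network$training$history) > 0)
    wr_csv(results$network$training$history, "training_history.csv")
  p <- file.path(outdir, "summary.json")
  jsonlite::write_json(results$summary, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  p <- file.path(outdir, "config.yaml")
  save_experiment_config(results$config, p)
  files <- c(files, p)
  manifest <- list(
    package = "npecircuit",
    version = as.character(utils::packageVersion("npecircuit")),
    created = format(Sys.time(), tz = "UTC"),
    seeds = results$summary$seeds,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  invisible(mp)
}
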