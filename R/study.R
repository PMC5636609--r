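study_defaults <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    out_dir = NULL,
    groups = c("control", "treated"),
    n_neurons = 16L,
    scaling_factor = 1.51,
    mepsc = list(duration = 60, sampling_rate = 1e5, event_rate = 1.5,
                 amp_median = 18, amp_sigma = 0.45, rise_tau = 1,
                 decay_tau = 8, noise_sd = 2),
    analysis = list(threshold = 7.5, n_per_neuron = 50L, alpha = 0.05),
    fi = list(enabled = TRUE, n_neurons = 16L, R_in_mean = 100, R_in_sd = 10,
              tau_m = 10, noise_sd = 0.3, sampling_rate = 1e4),
    bursts = list(enabled = TRUE, n_preps = 4L, epoch_dur = 600,
                  burst_rate_per_min = 10,
                  control_amp_factor = 1.0, treated_amp_factor = 0.6,
                  freq_factor = 0.2, washout_amp_factor = 0.9,
                  washout_freq_factor = 0.8),
    ingest = list(control_events = NULL, treated_events = NULL)
  )
}

#' Validate and normalize a study configuration
#'
#' Accepts a YAML file path or a list; fills every missing key with its
#' default (detection threshold 7.5 pA, 50 events per neuron, 16 neurons
#' per group, alpha 0.05, 10-minute epochs — the out-of-the-box design
#' matches the study the pipeline models), rejects unknown keys with their
#' key path, and enforces the structural invariants: exactly two groups, a
#' non-negative seed, and (in ingest mode) existing input paths.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Normalized list of class `study_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config),
            class = "synscale_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- study_defaults()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown key: %s", unknown))
  }
  for (blk in c("mepsc", "analysis", "fi", "bursts", "ingest")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(bad)) {
        errors <- c(errors, sprintf("unknown key: %s.%s", blk, bad))
      }
      defaults[[blk]] <- utils::modifyList(defaults[[blk]],
                                           config[[blk]][setdiff(names(config[[blk]]), bad)])
    }
  }
  for (k in setdiff(names(defaults),
                    c("mepsc", "analysis", "fi", "bursts", "ingest"))) {
    if (!is.null(config[[k]])) defaults[[k]] <- config[[k]]
  }
  if (length(defaults$groups) != 2L) {
    errors <- c(errors, "groups: exactly two groups required")
  }
  if (!is.numeric(defaults$seed) || defaults$seed < 0 ||
      defaults$seed != round(defaults$seed)) {
    errors <- c(errors, "seed: must be a non-negative integer")
  }
  if (!defaults$mode %in% c("simulate", "ingest")) {
    errors <- c(errors, "mode: must be 'simulate' or 'ingest'")
  }
  if (identical(defaults$mode, "ingest")) {
    for (k in c("control_events", "treated_events")) {
      p <- defaults$ingest[[k]]
      if (is.null(p) || !file.exists(p)) {
        errors <- c(errors, sprintf("ingest.%s: path missing or not found", k))
      }
    }
  }
  if (defaults$scaling_factor <= 0) {
    errors <- c(errors, "scaling_factor: must be positive")
  }
  if (length(errors)) {
    abort(paste0("Invalid study config:\n",
                 paste0("  - ", errors, collapse = "\n")),
          class = "synscale_config_error")
  }
  defaults$seed <- as.integer(defaults$seed)
  structure(defaults, class = "study_config")
}

#' Run the full desk-scale study
#'
#' Orchestrates the complete analysis from one configuration. In simulate
#' mode: generate two mEPSC cohorts (the treated cohort multiplicatively
#' scaled), run event detection and per-neuron summaries, run the
#' rank-order scaling analysis, simulate and analyze step families for
#' intrinsic excitability (per-neuron input-resistance heterogeneity plus
#' membrane noise provides biological variability), simulate two-channel
#' neurograms per preparation and compare drug epochs to baseline, and
#' collect the statistical battery. In ingest mode the per-neuron event
#' tables are read from CSV and only the scaling analysis is run.
#' Everything is deterministic given the seed; when `out_dir` is set, all
#' tables are written there as CSV plus a human-readable `summary.txt`.
#'
#' @param config A `study_config` (or anything [validate_config()] accepts).
#' @return A `study_report`: list with `neurons`, `scaling` (the
#'   `scaling_result`), `scaling_summary`, `fi`, `bursts`, `stats`,
#'   `provenance`.
#' @export
run_study <- function(config = list()) {
  cfg <- if (inherits(config, "study_config")) config else
    validate_config(config)
  set.seed(cfg$seed)
  thr <- cfg$analysis$threshold
  dc <- detection_config(threshold = thr)
  stats_rows <- list()

  if (cfg$mode == "simulate") {
    mp <- do.call(mepsc_params, c(cfg$mepsc, list(seed = NULL)))
    cohorts <- generate_scaled_cohorts(mp, cfg$scaling_factor,
                                       n_neurons = cfg$n_neurons,
                                       seed = cfg$seed)
    detect_group <- function(lst, label) {
      purrr::imap(lst, function(x, i) {
        ev <- detect_events(x$trace, dc)
        list(events = ev,
             record = summarize_neuron(ev, window = cfg$mepsc$duration,
                                       neuron_id = paste0(label, "_", i),
                                       group = label))
      })
    }
    ctrl <- detect_group(cohorts$control, cfg$groups[1])
    trt <- detect_group(cohorts$treated, cfg$groups[2])
    ctrl_amps <- lapply(ctrl, function(x) x$events$amplitude_pA)
    trt_amps <- lapply(trt, function(x) x$events$amplitude_pA)
    neurons <- dplyr::bind_rows(c(lapply(ctrl, `[[`, "record"),
                                  lapply(trt, `[[`, "record")))
  } else {
    ctrl_tab <- read_table_file(cfg$ingest$control_events)
    trt_tab <- read_table_file(cfg$ingest$treated_events)
    split_amps <- function(tab) {
      lapply(split(tab, tab$neuron_id),
             function(d) d$amplitude_pA[order(d$onset_s)])
    }
    ctrl_amps <- split_amps(ctrl_tab)
    trt_amps <- split_amps(trt_tab)
    neurons <- dplyr::bind_rows(
      purrr::imap_dfr(ctrl_amps, ~ tibble(neuron_id = .y,
                                          group = cfg$groups[1],
                                          n_events = length(.x),
                                          mean_amplitude_pA = mean(.x))),
      purrr::imap_dfr(trt_amps, ~ tibble(neuron_id = .y,
                                         group = cfg$groups[2],
                                         n_events = length(.x),
                                         mean_amplitude_pA = mean(.x)))
    )
  }

  scaling <- scaling_pipeline(ctrl_amps, trt_amps,
                              n_per_neuron = cfg$analysis$n_per_neuron,
                              threshold = thr, alpha = cfg$analysis$alpha)
  amp_means <- split(neurons$mean_amplitude_pA, neurons$group)
  stats_rows$amplitude <- unpaired_t(amp_means[[cfg$groups[1]]],
                                     amp_means[[cfg$groups[2]]])

  fi_out <- NULL
  if (cfg$mode == "simulate" && isTRUE(cfg$fi$enabled)) {
    gen_group <- function(offset) {
      lapply(seq_len(cfg$fi$n_neurons), function(i) {
        rin <- max(10, stats::rnorm(1, cfg$fi$R_in_mean, cfg$fi$R_in_sd))
        generate_fi_sweeps(
          lif_params(R_in = rin, tau_m = cfg$fi$tau_m),
          sampling_rate = cfg$fi$sampling_rate,
          noise_sd = cfg$fi$noise_sd,
          seed = (cfg$seed + offset + i) %% 2147483587L)
      })
    }
    fam_a <- gen_group(1000L)
    fam_b <- gen_group(2000L)
    cmp <- compare_fi_slopes(fam_a, fam_b, labels = cfg$groups)
    rin_tab <- tibble(
      group = rep(cfg$groups, each = cfg$fi$n_neurons),
      R_in_MOhm = c(vapply(fam_a, input_resistance, numeric(1)),
                    vapply(fam_b, input_resistance, numeric(1))))
    stats_rows$fi_ancova <- cmp$ancova
    stats_rows$fi_gain_t <- cmp$t_gains
    fi_out <- list(comparison = cmp, input_resistance = rin_tab)
  }

  burst_out <- NULL
  if (cfg$mode == "simulate" && isTRUE(cfg$bursts$enabled)) {
    bcfg <- cfg$bursts
    run_prep <- function(amp_factor, offset, i) {
      ng <- generate_neurogram(
        burst_rate_per_min = bcfg$burst_rate_per_min,
        epochs = default_epochs(
          epoch_dur = bcfg$epoch_dur,
          amp_factors = c(1, amp_factor, bcfg$washout_amp_factor),
          freq_factors = c(1, bcfg$freq_factor, bcfg$washout_freq_factor)),
        seed = (cfg$seed + offset + i) %% 2147483587L)
      eb <- detect_bursts(ng$cnx, ng$snii)
      epoch_compare(eb, ng$truth$epochs)
    }
    prep_tab <- dplyr::bind_rows(
      lapply(seq_len(bcfg$n_preps), function(i)
        dplyr::mutate(run_prep(bcfg$control_amp_factor, 3000L, i),
                      group = cfg$groups[1], prep = i)),
      lapply(seq_len(bcfg$n_preps), function(i)
        dplyr::mutate(run_prep(bcfg$treated_amp_factor, 4000L, i),
                      group = cfg$groups[2], prep = i))
    )
    drug <- prep_tab[prep_tab$epoch == "drug", , drop = FALSE]
    pct <- split(drug$pct_amplitude, drug$group)
    stats_rows$burst_amp_pct <- mann_whitney(pct[[cfg$groups[1]]],
                                             pct[[cfg$groups[2]]])
    burst_out <- prep_tab
  }

  stats_tab <- dplyr::bind_rows(stats_rows, .id = "comparison")
  report <- structure(list(
    neurons = neurons,
    scaling = scaling,
    scaling_summary = glance(scaling),
    fi = fi_out,
    bursts = burst_out,
    stats = stats_tab,
    provenance = list(seed = cfg$seed, mode = cfg$mode,
                      threshold = thr,
                      n_per_neuron = cfg$analysis$n_per_neuron,
                      alpha = cfg$analysis$alpha,
                      package_version = as.character(utils::packageVersion("synscale")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "study_report")

  if (!is.null(cfg$out_dir)) write_study_report(report, cfg$out_dir)
  report
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(report$neurons, file.path(out_dir, "neurons.csv"))
  write_table(report$scaling_summary, file.path(out_dir, "scaling.csv"))
  if (!is.null(report$bursts)) {
    write_table(report$bursts, file.path(out_dir, "burst_epochs.csv"))
  }
  if (!is.null(report$fi)) {
    write_table(report$fi$input_resistance,
                file.path(out_dir, "input_resistance.csv"))
    write_table(report$fi$comparison$mean_gains,
                file.path(out_dir, "fi_gains.csv"))
  }
  write_table(report$stats, file.path(out_dir, "stats.csv"))
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con)
  cat("Study summary\n=============\n\n")
  print(report$scaling)
  cat("\nPer-comparison statistics:\n")
  print(as.data.frame(report$stats))
  cat(sprintf("\nSeed: %d  threshold: %g pA  n/neuron: %d  alpha: %g\n",
              report$provenance$seed, report$provenance$threshold,
              report$provenance$n_per_neuron, report$provenance$alpha))
  sink()
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$scaling)
  cat(sprintf("  %d neuron records; %d statistical comparisons\n",
              nrow(x$neurons), nrow(x$stats)))
  invisible(x)
}
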