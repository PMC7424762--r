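#' Configuration for a synthetic glutamate-imaging or survival experiment
#'
#' Bundles per-condition simulation parameters, detection settings and seeds
#' into one validated object that the experiment runners consume. Every
#' stage derives its RNG stream from `seed` plus fixed offsets, so a config
#' is a complete, reproducible description of a run.
#'
#' @param conditions named list; each element is a list of
#'   [trace_sim_params()] overrides for that condition (e.g.
#'   `list(amplitude_mean = 1)`). At least 2 conditions for comparative
#'   stages.
#' @param n_animals animals per condition.
#' @param n_rois traces (ROIs) recorded per animal.
#' @param event_threshold,offset_band detection parameters (dF/F).
#' @param survival a [survival_sim_params()] list for the lifespan stage.
#' @param climbing named list of per-genotype [climbing_sim_params()]
#'   overrides keyed by genotype label; `climbing_timepoints` gives the
#'   assay days.
#' @param climbing_timepoints numeric vector of assay timepoints (days).
#' @param n_perm permutations for the interaction test.
#' @param seed master integer seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(conditions = list(control = list(),
                                                ab42 = list()),
                              n_animals = 5L, n_rois = 2L,
                              event_threshold = 0.1, offset_band = 0.2,
                              survival = survival_sim_params(),
                              climbing = NULL,
                              climbing_timepoints = c(7, 14, 21),
                              n_perm = 1000L, seed = 1L) {
  cfg <- list(conditions = conditions, n_animals = as.integer(n_animals),
              n_rois = as.integer(n_rois),
              event_threshold = event_threshold, offset_band = offset_band,
              survival = survival, climbing = climbing,
              climbing_timepoints = climbing_timepoints,
              n_perm = as.integer(n_perm), seed = as.integer(seed))
  if (length(cfg$conditions) < 1L || is.null(names(cfg$conditions))) {
    stop("conditions must be a named list", call. = FALSE)
  }
  if (cfg$n_animals < 1L || cfg$n_rois < 1L) {
    stop("n_animals and n_rois must be >= 1", call. = FALSE)
  }
  class(cfg) <- "experiment_config"
  cfg
}

# deterministic per-stage seed derivation, kept well below 2^31
.derive_seed <- function(base, ...) {
  s <- as.double(base) %% 1000003
  for (x in c(...)) s <- (s * 7919 + as.double(x) + 1) %% 2000003
  as.integer(s)
}

.log_line <- function(log_path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  invisible(msg)
}

# md5 over the sorted data files of a run directory; file-content based so
# two runs agree iff their outputs are bit-identical
.run_hash <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(csv|yaml|txt)$",
                           recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("report\\.yaml$|log\\.txt$", files)]
  sums <- tools::md5sum(files)
  unname(tools::md5sum(
    {
      tmp <- tempfile()
      writeLines(paste(basename(names(sums)), sums), tmp)
      tmp
    }
  ))
}

#' Run a synthetic glutamate-imaging experiment end to end
#'
#' For each condition and animal, simulates iGluSnFR traces, converts them
#' to dF/F, detects transients, summarizes per ROI and aggregates per
#' animal, then compares conditions by one-way ANOVA with Tukey HSD on both
#' the per-animal mean amplitude and the event rate. All intermediates are
#' written as CSV into `out_dir`; a rerun with the same config is
#' bit-identical (verified by the report's provenance hash).
#'
#' @param config an [experiment_config()].
#' @param out_dir run directory (created; stage files are overwritten).
#' @return Object of class `experiment_report`: per-animal table, ANOVA
#'   results, file manifest and provenance (`seed`, `run_hash`, package
#'   version).
#' @export
run_glutamate_experiment <- function(config, out_dir = tempfile("glurun")) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$conditions) < 2L) {
    stop("comparative analysis needs >= 2 conditions", call. = FALSE)
  }
  if (config$n_animals < 3L) {
    warning("underpowered design: fewer than 3 animals per condition",
            call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("glutamate experiment, seed %d\n", config$seed),
      file = log_path)

  traces <- list()
  summaries <- list()
  transient_rows <- list()
  cond_names <- names(config$conditions)
  for (ci in seq_along(cond_names)) {
    cond <- cond_names[ci]
    for (a in seq_len(config$n_animals)) {
      animal <- sprintf("%s_a%02d", cond, a)
      for (r in seq_len(config$n_rois)) {
        sp <- do.call(trace_sim_params, c(
          config$conditions[[ci]],
          list(seed = .derive_seed(config$seed, ci, a, r))))
        sim <- simulate_trace(sp, roi_id = sprintf("roi%d", r),
                              animal_id = animal, condition = cond)
        traces[[length(traces) + 1L]] <- sim$trace
        dff <- compute_dff(sim$trace)
        tr <- detect_transients(dff, config$event_threshold,
                                config$offset_band)
        if (nrow(tr) > 0L) {
          lab <- as.data.frame(tr)
          lab$roi_id <- sprintf("roi%d", r)
          lab$animal_id <- animal
          lab$condition <- cond
          transient_rows[[length(transient_rows) + 1L]] <- lab
        }
        summaries[[length(summaries) + 1L]] <- summarize_trace(
          tr, dff, roi_id = sprintf("roi%d", r), animal_id = animal,
          condition = cond)
      }
    }
    .log_line(log_path, "condition %s: %d animals x %d ROIs simulated",
              cond, config$n_animals, config$n_rois)
  }
  summaries <- do.call(rbind, summaries)
  animals <- aggregate_by_animal(summaries)
  .log_line(log_path, "detected %d transients over %d traces",
            sum(summaries$n_transients), nrow(summaries))

  write_traces_csv(traces, file.path(out_dir, "traces.csv"))
  if (length(transient_rows)) {
    write_transients_csv(do.call(rbind, transient_rows),
                         file.path(out_dir, "transients.csv"))
  }
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(animals, file.path(out_dir, "animals.csv"),
                   row.names = FALSE)

  anova_amp <- one_way_anova(split(animals$mean_amplitude,
                                   factor(animals$condition,
                                          levels = cond_names)))
  anova_rate <- one_way_anova(split(animals$events_per_min,
                                    factor(animals$condition,
                                           levels = cond_names)))
  stats_txt <- file.path(out_dir, "anova.txt")
  sink(stats_txt)
  cat("Per-animal mean amplitude:\n")
  print(anova_amp)
  cat("\nPer-animal event rate (events/min):\n")
  print(anova_rate)
  sink()
  .log_line(log_path, "ANOVA amplitude F(%d,%d)=%.4g p=%.4g",
            anova_amp$df_between, anova_amp$df_within, anova_amp$f_stat,
            anova_amp$p_value)

  report <- structure(
    list(kind = "glutamate", animals = animals,
         anova_amplitude = anova_amp, anova_rate = anova_rate,
         out_dir = out_dir,
         provenance = list(seed = config$seed,
                           run_hash = .run_hash(out_dir),
                           package_version =
                             as.character(utils::packageVersion("synapseflux")))),
    class = "experiment_report")
  yaml::write_yaml(list(kind = report$kind,
                        provenance = report$provenance),
                   file.path(out_dir, "report.yaml"))
  report
}

#' Run a synthetic survival and climbing experiment end to end
#'
#' Simulates a 2x2 genotype-by-induction cohort, estimates Kaplan-Meier
#' curves per cell, computes all pairwise log-rank tests, tests the
#' genotype-by-induction interaction by the stratified permutation test,
#' and simulates climbing trials per genotype at each timepoint with their
#' performance indices. Deterministic under the config seed.
#'
#' @param config an [experiment_config()]; the `survival`, `climbing`,
#'   `climbing_timepoints` and `n_perm` fields drive this runner.
#' @param out_dir run directory.
#' @return Object of class `experiment_report` with `records`, `km` (named
#'   list of curves), `pairwise_logrank`, `interaction`, `pi_table` and
#'   provenance.
#' @export
run_survival_experiment <- function(config, out_dir = tempfile("survrun")) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("survival experiment, seed %d\n", config$seed),
      file = log_path)

  sp <- config$survival
  sp$seed <- .derive_seed(config$seed, 101L)
  records <- simulate_survival(sp)
  write_survival_csv(records, file.path(out_dir, "survival.csv"))
  .log_line(log_path, "simulated %d flies in %d cells", nrow(records), 4L)

  cell <- interaction(records$genotype, records$induction, sep = ":")
  km <- lapply(split(records, cell), kaplan_meier)
  km_tab <- do.call(rbind, lapply(names(km), function(nm) {
    cbind(group = nm, as.data.frame(km[[nm]]))
  }))
  utils::write.csv(km_tab, file.path(out_dir, "km_curves.csv"),
                   row.names = FALSE)

  cells <- levels(cell)
  pairs <- utils::combn(cells, 2L)
  pw <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    chi_square = NA_real_, p_value = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    lr <- logrank_test(records[cell == pairs[1L, i], ],
                       records[cell == pairs[2L, i], ])
    pw$chi_square[i] <- lr$chi_square
    pw$p_value[i] <- lr$p_value
  }
  utils::write.csv(pw, file.path(out_dir, "pairwise_logrank.csv"),
                   row.names = FALSE)

  interaction_res <- permutation_interaction_test(
    records, n_perm = config$n_perm,
    seed = .derive_seed(config$seed, 202L))
  .log_line(log_path, "interaction p = %.4g (%d perms)",
            interaction_res$p_value, interaction_res$n_perm)

  genos <- unique(records$genotype)
  pi_rows <- list()
  for (gi in seq_along(genos)) {
    over <- if (!is.null(config$climbing)) config$climbing[[genos[gi]]]
    for (ti in seq_along(config$climbing_timepoints)) {
      cp <- do.call(climbing_sim_params, c(
        over, list(seed = .derive_seed(config$seed, 303L, gi, ti))))
      counts <- simulate_climbing(cp)
      pi_rows[[length(pi_rows) + 1L]] <- data.frame(
        genotype = genos[gi],
        timepoint = config$climbing_timepoints[ti],
        trial = counts$trial, n_top = counts$n_top,
        n_middle = counts$n_middle, n_bottom = counts$n_bottom,
        pi = performance_index(counts))
    }
  }
  pi_table <- do.call(rbind, pi_rows)
  utils::write.csv(pi_table, file.path(out_dir, "climbing_pi.csv"),
                   row.names = FALSE)
  .log_line(log_path, "climbing: %d PI values", nrow(pi_table))

  report <- structure(
    list(kind = "survival", records = records, km = km,
         pairwise_logrank = pw, interaction = interaction_res,
         pi_table = pi_table, out_dir = out_dir,
         provenance = list(seed = config$seed,
                           run_hash = .run_hash(out_dir),
                           package_version =
                             as.character(utils::packageVersion("synapseflux")))),
    class = "experiment_report")
  yaml::write_yaml(list(kind = report$kind,
                        interaction_p = interaction_res$p_value,
                        provenance = report$provenance),
                   file.path(out_dir, "report.yaml"))
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report:%s> run dir %s\n", x$kind, x$out_dir))
  if (x$kind == "glutamate") {
    cat(sprintf("  %d animals; amplitude ANOVA F(%d,%d)=%.4g p=%.4g\n",
                nrow(x$animals), x$anova_amplitude$df_between,
                x$anova_amplitude$df_within, x$anova_amplitude$f_stat,
                x$anova_amplitude$p_value))
  } else {
    cat(sprintf("  %d flies; interaction p = %.4g\n", nrow(x$records),
                x$interaction$p_value))
  }
  cat(sprintf("  provenance hash %s\n", x$provenance$run_hash))
  invisible(x)
}

#' Read or write an experiment config as YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$survival <- unclass(cfg$survival)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  surv <- if (!is.null(raw$survival)) do.call(survival_sim_params, raw$survival)
          else survival_sim_params()
  experiment_config(
    conditions = lapply(raw$conditions, function(x) if (is.null(x)) list() else x),
    n_animals = raw$n_animals, n_rois = raw$n_rois,
    event_threshold = raw$event_threshold, offset_band = raw$offset_band,
    survival = surv, climbing = raw$climbing,
    climbing_timepoints = unlist(raw$climbing_timepoints),
    n_perm = raw$n_perm, seed = raw$seed)
}
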