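# Pipeline orchestration: simulate -> write -> gate -> quantify -> report,
# deterministically from one seed, with file-based and in-memory entry
# points.

resolve_populations <- function(x) {
  if (is.list(x) && length(x) > 0L &&
      all(vapply(x, inherits, TRUE, "population_spec"))) return(x)
  if (inherits(x, "population_spec")) return(list(x))
  if (is.character(x) && length(x) == 1L) {
    if (x == "bead_mix") return(bead_mix_populations())
    if (x == "blood") return(blood_populations())
    if (file.exists(x)) return(read_population_config(x))
    stop("unknown population preset or file: ", x, call. = FALSE)
  }
  stop("cannot interpret `populations`", call. = FALSE)
}

resolve_scenario <- function(x) {
  if (inherits(x, "device_scenario")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^flow_", x))
      return(flow_rate_scenario(as.numeric(sub("^flow_", "", x))))
    if (x %in% c("zigzag", "spiral")) return(blood_scenario(x))
    if (file.exists(x)) return(read_scenario_config(x))
    stop("unknown scenario preset or file: ", x, call. = FALSE)
  }
  stop("cannot interpret `scenario`", call. = FALSE)
}

resolve_strategy <- function(x) {
  if (inherits(x, "gating_tree")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x == "beads") return(build_bead_strategy())
    if (x == "blood") return(build_blood_strategy())
    if (file.exists(x)) return(read_gating_strategy(x))
    stop("gating strategy not found: ", x, call. = FALSE)
  }
  stop("cannot interpret gating strategy", call. = FALSE)
}

#' Run the full evaluation pipeline in memory
#'
#' Simulates a sorted sample (sample draw, probabilistic sorting,
#' counting-bead spike-in, acquisition), gates it and computes the
#' performance report, all from a single seed.
#'
#' @param populations Population set: list of \code{population_spec},
#'   preset name (\code{"bead_mix"}, \code{"blood"}) or YAML path.
#' @param scenario Device scenario: \code{device_scenario}, preset
#'   (\code{"flow_0.7"}, ..., \code{"zigzag"}, \code{"spiral"}) or YAML
#'   path.
#' @param volume_ml Processed sample volume (mL).
#' @param seed Integer run seed.
#' @param strategy Gating strategy: \code{gating_tree}, preset
#'   (\code{"beads"}, \code{"blood"}) or YAML path.
#' @param accudrop_per_tube Expected counting beads spiked per tube.
#' @param acquired_fraction Per-outlet recorded fractions in (0,1].
#' @param correction_mode,purity_definition,qc_expected,qc_tolerance See
#'   \code{\link{performance_report}}.
#' @param ground_truth_bypass Quantify from simulator labels instead of
#'   gating (oracle mode).
#' @return List with \code{report} (\code{performance_report}),
#'   \code{counts} (\code{count_matrix}), \code{acquisition} (two
#'   \code{acquisition_record}s) and \code{volumes}.
#' @export
run_pipeline <- function(populations, scenario, volume_ml, seed = 1L,
                         strategy = "beads",
                         accudrop_per_tube = 50000,
                         acquired_fraction = c(inner = 1, outer = 1),
                         correction_mode = "volume_consistent",
                         purity_definition = "freq_total",
                         qc_expected = 1 / 3, qc_tolerance = 0.05,
                         ground_truth_bypass = FALSE) {
  populations <- resolve_populations(populations)
  scenario <- resolve_scenario(scenario)
  tree <- resolve_strategy(strategy)
  pre <- sample_events(populations, volume_ml, seed = seed)
  sorted <- sort_events(pre, scenario, seed = seed)
  acq <- spike_and_acquire(sorted$inner, sorted$outer, sorted$volumes,
                           accudrop_per_tube = accudrop_per_tube,
                           acquired_fraction = acquired_fraction,
                           seed = seed)
  cm <- count_populations(acq, tree, ground_truth_bypass = ground_truth_bypass)
  accudrop_counts <- if (ground_truth_bypass) {
    c(inner = acq$inner$accudrop_recorded,
      outer = acq$outer$accudrop_recorded)
  } else NULL
  report <- performance_report(
    cm, volumes = sorted$volumes,
    correction_mode = correction_mode,
    purity_definition = purity_definition,
    accudrop_counts = accudrop_counts,
    qc_expected = qc_expected, qc_tolerance = qc_tolerance)
  list(report = report, counts = cm, acquisition = acq,
       volumes = sorted$volumes)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a list or a YAML/JSON path", call. = FALSE)
}

#' Simulate a sorted run and write per-outlet event files
#'
#' Writes \code{inner.<fmt>} and \code{outer.<fmt>} event files, row-aligned
#' ground-truth sidecars (\code{inner_truth.tsv}, \code{outer_truth.tsv})
#' and a \code{manifest.json} recording every parameter; re-running from
#' the manifest alone reproduces the outputs byte for byte.
#'
#' @param config List, or path to a YAML/JSON config, with fields
#'   \code{populations}, \code{scenario}, \code{volume_ml}, \code{seed},
#'   \code{outdir} and optional \code{accudrop_per_tube},
#'   \code{acquired_fraction}, \code{format} (\code{"fcs"} or
#'   \code{"tsv"}).
#' @return Invisibly, a list of written file paths plus the per-outlet
#'   collected volumes.
#' @export
run_simulate <- function(config) {
  cfg <- read_run_config(config)
  for (f in c("populations", "scenario", "volume_ml", "outdir")) {
    if (is.null(cfg[[f]]))
      stop("config field '", f, "' is required", call. = FALSE)
  }
  seed <- as.integer(cfg$seed %||% 1L)
  fmt <- cfg$format %||% "fcs"
  accudrop_per_tube <- cfg$accudrop_per_tube %||% 50000
  af <- unlist(cfg$acquired_fraction %||% c(inner = 1, outer = 1))
  populations <- resolve_populations(cfg$populations)
  scenario <- resolve_scenario(cfg$scenario)

  pre <- sample_events(populations, cfg$volume_ml, seed = seed)
  sorted <- sort_events(pre, scenario, seed = seed)
  acq <- spike_and_acquire(sorted$inner, sorted$outer, sorted$volumes,
                           accudrop_per_tube = accudrop_per_tube,
                           acquired_fraction = af, seed = seed)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (outlet in c("inner", "outer")) {
    ev <- acq[[outlet]]$events
    f_ev <- file.path(cfg$outdir, paste0(outlet, ".", fmt))
    write_events(ev, f_ev, format = fmt)
    f_truth <- file.path(cfg$outdir, paste0(outlet, "_truth.tsv"))
    write_truth_sidecar(ev, f_truth)
    paths[[outlet]] <- f_ev
    paths[[paste0(outlet, "_truth")]] <- f_truth
  }
  manifest <- list(
    populations = if (is.character(cfg$populations)) cfg$populations
    else lapply(unname(populations), function(p) p[
      c("name", "kind", "diameter", "concentration", "doublet_fraction",
        "doublet_area_scale", "doublet_height_scale", "channels")]),
    scenario = if (is.character(cfg$scenario)) cfg$scenario
    else list(flow_rate_ml_min = scenario$flow_rate,
              f_inner = scenario$f_inner,
              p_inner = scenario$p_inner),
    volume_ml = cfg$volume_ml, seed = seed, format = fmt,
    accudrop_per_tube = accudrop_per_tube,
    acquired_fraction = as.list(af),
    outdir = cfg$outdir,
    volumes_ul = as.list(sorted$volumes),
    accudrop_spiked = list(inner = acq$inner$accudrop_spiked,
                           outer = acq$outer$accudrop_spiked),
    accudrop_recorded = list(inner = acq$inner$accudrop_recorded,
                             outer = acq$outer$accudrop_recorded))
  f_manifest <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- f_manifest
  paths$volumes <- sorted$volumes
  invisible(paths)
}

manifest_config <- function(manifest) {
  cfg <- manifest
  if (is.list(cfg$populations) && !is.character(cfg$populations)) {
    cfg$populations <- lapply(cfg$populations, function(p) {
      population_spec(p$name, p$kind, p$diameter, p$concentration,
                      p$channels, p$doublet_fraction,
                      p$doublet_area_scale, p$doublet_height_scale)
    })
  }
  if (is.list(cfg$scenario) && !is.character(cfg$scenario)) {
    s <- cfg$scenario
    cfg$scenario <- device_scenario(s$flow_rate_ml_min,
                                    as.data.frame(s$p_inner), s$f_inner)
  }
  cfg
}

#' Evaluate written event files into a performance report
#'
#' Reads the per-outlet event files of a simulated (or instrument-exported)
#' run, applies a gating strategy, normalizes with the gated counting-bead
#' counts and writes the report as long-format TSV and JSON. A QC failure
#' is recorded in the report but does not abort evaluation.
#'
#' @param outdir Directory holding \code{manifest.json} plus the event
#'   files written by \code{\link{run_simulate}}.
#' @param strategy Gating strategy (object, preset or YAML path); must
#'   resolve, otherwise evaluation stops before writing anything.
#' @param correction_mode,purity_definition,qc_tolerance See
#'   \code{\link{performance_report}}.
#' @param ground_truth_bypass Use the truth sidecars instead of gating.
#' @return The \code{performance_report}, invisibly; files
#'   \code{report.tsv} and \code{report.json} are written into
#'   \code{outdir}.
#' @export
run_evaluate <- function(outdir, strategy = "beads",
                         correction_mode = "volume_consistent",
                         purity_definition = "freq_total",
                         qc_tolerance = 0.05,
                         ground_truth_bypass = FALSE) {
  tree <- resolve_strategy(strategy)
  f_manifest <- file.path(outdir, "manifest.json")
  if (!file.exists(f_manifest))
    stop("no manifest.json in ", outdir, call. = FALSE)
  manifest <- jsonlite::read_json(f_manifest, simplifyVector = TRUE)
  fmt <- manifest$format %||% "fcs"
  tubes <- lapply(c(inner = "inner", outer = "outer"), function(outlet) {
    ev <- read_events(file.path(outdir, paste0(outlet, ".", fmt)))
    f_truth <- file.path(outdir, paste0(outlet, "_truth.tsv"))
    if (file.exists(f_truth)) {
      truth <- utils::read.delim(f_truth, stringsAsFactors = FALSE)
      if (nrow(truth) != nrow(ev))
        stop("truth sidecar of '", outlet, "' is not row-aligned",
             call. = FALSE)
      ev <- cbind(ev, truth)
    }
    ev
  })
  volumes <- unlist(manifest$volumes_ul)
  cm <- count_populations(tubes, tree,
                          ground_truth_bypass = ground_truth_bypass)
  accudrop_counts <- if (ground_truth_bypass)
    unlist(manifest$accudrop_recorded) else NULL
  report <- performance_report(cm, volumes = volumes,
                               correction_mode = correction_mode,
                               purity_definition = purity_definition,
                               accudrop_counts = accudrop_counts,
                               qc_tolerance = qc_tolerance)
  write_report(report, file.path(outdir, "report.tsv"),
               file.path(outdir, "report.json"))
  invisible(report)
}

#' Write a performance report to TSV and/or JSON
#'
#' The TSV is long format (\code{population}, \code{class}, \code{metric},
#' \code{value}); the JSON mirrors the report object.
#'
#' @param report A \code{\link{performance_report}}.
#' @param path_tsv,path_json Output paths (\code{NULL} to skip).
#' @return The report, invisibly.
#' @export
write_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    long <- rbind(
      data.frame(population = report$se$population,
                 class = report$se$class, metric = "SE",
                 value = report$se$se, stringsAsFactors = FALSE),
      data.frame(population = report$purity$population, class = "total",
                 metric = "purity", value = report$purity$purity,
                 stringsAsFactors = FALSE))
    utils::write.table(long, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Parameter-recovery experiment for one bead size at one flow rate
#'
#' Simulates a single bead population through the named flow-rate scenario
#' (full acquisition, counting-bead spike-in), runs gating, normalization
#' and the efficiency metric, and returns the estimated singlet and doublet
#' Separation Efficiency together with the simulated ground-truth class
#' sizes. This is the package's standard check that the pipeline recovers
#' the capture probabilities the virtual sorter was configured with.
#'
#' @param flow_rate Flow rate (mL/min) of a shipped scenario fixture.
#' @param population Bead population name (e.g. \code{"bead_15um"}).
#' @param n_objects Expected number of simulated objects of that
#'   population.
#' @param doublet_fraction Cluster prevalence; raise it to obtain enough
#'   doublets for a stable doublet-class estimate.
#' @param seed Integer run seed.
#' @param accudrop_per_tube Expected counting beads spiked per tube.
#' @return List with \code{se_singlet}, \code{se_doublet} (percent,
#'   pipeline estimates), \code{n_singlets}, \code{n_doublets} (ground
#'   truth), \code{p_singlet}, \code{p_doublet} (configured capture
#'   probabilities) and the full \code{report}.
#' @export
capture_recovery_run <- function(flow_rate, population = "bead_15um",
                                 n_objects = 26000, doublet_fraction = 0.2,
                                 seed = 1L, accudrop_per_tube = 50000) {
  pops <- bead_mix_populations(doublet_fraction)[population]
  if (anyNA(names(pops)))
    stop("unknown bead population '", population, "'", call. = FALSE)
  scenario <- flow_rate_scenario(flow_rate)
  volume <- n_objects / pops[[1]]$concentration
  res <- run_pipeline(pops, scenario, volume_ml = volume, seed = seed,
                      strategy = "beads",
                      accudrop_per_tube = accudrop_per_tube)
  ev <- rbind(res$acquisition$inner$events, res$acquisition$outer$events)
  is_pop <- ev$population_id == population
  list(se_singlet = se_value(res$report, population, "singlet"),
       se_doublet = se_value(res$report, population, "doublet"),
       n_singlets = sum(is_pop & ev$cluster_size == 1L),
       n_doublets = sum(is_pop & ev$cluster_size == 2L),
       p_singlet = scenario_p(scenario, population, "singlet"),
       p_doublet = scenario_p(scenario, population, "doublet"),
       report = res$report)
}
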