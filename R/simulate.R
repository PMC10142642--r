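# Labeled synthetic event generation: sample draw, probabilistic two-outlet
# sorting, counting-bead spike-in and partial cytometer acquisition.

# Draw channel intensities for n singlet objects of one population.
draw_singlet_channels <- function(pop, n) {
  out <- vector("list", length(SORTGAUGE_CHANNELS))
  names(out) <- SORTGAUGE_CHANNELS
  for (ch in AREA_CHANNELS) {
    m <- pop$channels[[ch]]
    out[[ch]] <- stats::rlnorm(n, meanlog = log(m$median),
                               sdlog = sqrt(log(1 + m$cv^2)))
  }
  # Heights ride on their area draw: the pulse shape varies far less than the
  # particle-to-particle intensity, so area/height is tight around 1.
  for (hch in names(HEIGHT_PAIR)) {
    ach <- HEIGHT_PAIR[[hch]]
    m <- pop$channels[[hch]]
    ratio <- m$median / pop$channels[[ach]]$median
    out[[hch]] <- out[[ach]] * ratio *
      stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + m$cv^2)))
  }
  as.data.frame(out, check.names = FALSE)
}

#' Simulate a pre-sort labeled event table
#'
#' Draws a Poisson number of objects for each population (its concentration
#' times the processed volume), marks each object as a two-particle cluster
#' with the population's doublet fraction, and draws the eight-channel signal
#' from the population's log-normal model. Cluster signals are a singlet draw
#' with pulse-area channels scaled by the population's
#' \code{doublet_area_scale} and pulse-height channels by
#' \code{doublet_height_scale}, so the area/height ratio separates clusters
#' from singlets by construction.
#'
#' @param populations List of \code{\link{population_spec}} objects.
#' @param volume Processed sample volume in mL.
#' @param seed Integer seed; all randomness in this call derives from it.
#' @return An event table: one row per object, the eight channel columns plus
#'   ground-truth \code{population_id} and \code{cluster_size} (1 or 2). The
#'   processed volume is attached as attribute \code{"volume_ml"}.
#' @export
sample_events <- function(populations, volume, seed = 1L) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("volume must be a single positive number (mL)", call. = FALSE)
  if (length(populations) == 0L)
    stop("at least one population is required", call. = FALSE)
  if (inherits(populations, "population_spec"))
    populations <- list(populations)
  with_seed(derive_seed(seed, "sample_events"), {
    parts <- lapply(populations, function(pop) {
      n <- stats::rpois(1L, pop$concentration * volume)
      if (n == 0L) {
        ev <- draw_singlet_channels(pop, 0L)
        ev$population_id <- character(0)
        ev$cluster_size <- integer(0)
        return(ev)
      }
      cluster <- 1L + stats::rbinom(n, 1L, pop$doublet_fraction)
      ev <- draw_singlet_channels(pop, n)
      dbl <- cluster == 2L
      if (any(dbl)) {
        ev[dbl, AREA_CHANNELS] <- ev[dbl, AREA_CHANNELS] *
          pop$doublet_area_scale
        ev[dbl, names(HEIGHT_PAIR)] <- ev[dbl, names(HEIGHT_PAIR)] *
          pop$doublet_height_scale
      }
      ev$population_id <- rep(pop$name, n)
      ev$cluster_size <- cluster
      ev
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "volume_ml") <- volume
    out
  })
}

#' Sort events through a probabilistic two-outlet device
#'
#' Each event is independently routed to the inner (target) outlet with the
#' scenario probability for its (population, cluster class); collected
#' volumes split as (\code{f_inner}, \code{1 - f_inner}) of the processed
#' volume. Event totals are conserved.
#'
#' @param events Labeled event table from \code{\link{sample_events}}.
#' @param scenario A \code{\link{device_scenario}}.
#' @param seed Integer seed.
#' @param volume Processed volume in mL; defaults to the table's
#'   \code{"volume_ml"} attribute.
#' @return List with elements \code{inner} and \code{outer} (event tables
#'   with a ground-truth \code{outlet} column) and \code{volumes}, the
#'   per-outlet collected volumes in microlitres.
#' @export
sort_events <- function(events, scenario, seed = 1L,
                        volume = attr(events, "volume_ml")) {
  stopifnot(inherits(scenario, "device_scenario"))
  assert_event_table(events)
  if (!all(c("population_id", "cluster_size") %in% names(events)))
    stop("events must carry ground-truth population_id and cluster_size",
         call. = FALSE)
  if (is.null(volume))
    stop("processed volume unknown: supply `volume` (mL)", call. = FALSE)
  cls <- ifelse(events$cluster_size >= 2L, "doublet", "singlet")
  p <- scenario_p(scenario, events$population_id, cls)
  if (anyNA(p)) {
    missing <- unique(paste(events$population_id, cls)[is.na(p)])
    stop("scenario lacks p_inner for: ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  with_seed(derive_seed(seed, "sort_events"), {
    to_inner <- stats::runif(nrow(events)) < p
    inner <- events[to_inner, , drop = FALSE]
    outer <- events[!to_inner, , drop = FALSE]
    if (nrow(inner)) inner$outlet <- "inner"
    else inner$outlet <- character(0)
    if (nrow(outer)) outer$outlet <- "outer"
    else outer$outlet <- character(0)
    rownames(inner) <- rownames(outer) <- NULL
    list(inner = inner, outer = outer,
         volumes = c(inner = scenario$f_inner * volume * 1000,
                     outer = (1 - scenario$f_inner) * volume * 1000))
  })
}

#' Spike counting beads and emulate partial acquisition
#'
#' Appends accudrop-style counting-bead events to each collection tube in
#' equal expected number (the spike count is Poisson-distributed around
#' \code{accudrop_per_tube}, as when pipetting an equal volume of bead
#' stock), then independently subsamples each tube at its acquired fraction
#' to emulate recording only part of the tube on the cytometer. Recorded
#' counting-bead numbers then report each file's acquired volume.
#'
#' @param inner,outer Post-sort event tables.
#' @param volumes Named per-outlet collected volumes (uL) from
#'   \code{\link{sort_events}}.
#' @param accudrop_per_tube Expected counting beads spiked per tube (> 0).
#' @param acquired_fraction Length-2 (inner, outer) fractions in (0,1] of
#'   each tube recorded during acquisition.
#' @param seed Integer seed.
#' @param accudrop \code{population_spec} of the counting bead.
#' @return List of two acquisition records (\code{inner}, \code{outer});
#'   each holds \code{events}, \code{collected_volume} (uL),
#'   \code{accudrop_spiked}, \code{acquired_fraction} and
#'   \code{accudrop_recorded} (ground truth).
#' @export
spike_and_acquire <- function(inner, outer, volumes, accudrop_per_tube,
                              acquired_fraction = c(inner = 1, outer = 1),
                              seed = 1L, accudrop = accudrop_population()) {
  if (!is.numeric(accudrop_per_tube) || accudrop_per_tube <= 0)
    stop("accudrop_per_tube must be > 0", call. = FALSE)
  acquired_fraction <- rep_len(acquired_fraction, 2L)
  if (any(acquired_fraction <= 0 | acquired_fraction > 1))
    stop("acquired fractions must lie in (0, 1]", call. = FALSE)
  tubes <- list(inner = inner, outer = outer)
  with_seed(derive_seed(seed, "spike_and_acquire"), {
    out <- vector("list", 2L)
    names(out) <- names(tubes)
    for (i in seq_along(tubes)) {
      tube <- tubes[[i]]
      n_spike <- stats::rpois(1L, accudrop_per_tube)
      spike <- draw_singlet_channels(accudrop, n_spike)
      if (accudrop$doublet_fraction > 0 && n_spike > 0L) {
        dbl <- stats::rbinom(n_spike, 1L, accudrop$doublet_fraction) == 1L
        spike[dbl, AREA_CHANNELS] <- spike[dbl, AREA_CHANNELS] *
          accudrop$doublet_area_scale
        spike[dbl, names(HEIGHT_PAIR)] <- spike[dbl, names(HEIGHT_PAIR)] *
          accudrop$doublet_height_scale
        spike$cluster_size <- 1L + as.integer(dbl)
      } else {
        spike$cluster_size <- rep(1L, n_spike)
      }
      spike$population_id <- rep(accudrop$name, n_spike)
      spike$outlet <- rep(names(tubes)[i], n_spike)
      full <- rbind(tube[, names(spike), drop = FALSE], spike)
      keep <- stats::runif(nrow(full)) < acquired_fraction[i]
      rec <- full[keep, , drop = FALSE]
      rownames(rec) <- NULL
      out[[i]] <- structure(
        list(events = rec,
             collected_volume = unname(volumes[names(tubes)[i]]),
             accudrop_spiked = n_spike,
             acquired_fraction = unname(acquired_fraction[i]),
             accudrop_recorded = sum(rec$population_id == accudrop$name)),
        class = "acquisition_record")
    }
    out
  })
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf(
    "<acquisition_record> %d events recorded (%.0f%% of tube), %.4g uL collected, %d/%d accudrop recorded\n",
    nrow(x$events), 100 * x$acquired_fraction, x$collected_volume,
    x$accudrop_recorded, x$accudrop_spiked))
  invisible(x)
}
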