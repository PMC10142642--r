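# Population specifications: the statistical description of one particle or
# cell type as the cytometer sees it.

#' Define a particle/cell population
#'
#' A population couples a physical description (diameter, concentration) to a
#' per-channel log-normal signal model. Each channel is parameterised by its
#' median intensity and coefficient of variation; pulse-height channels
#' (FSC-H, SSC-H) are drawn correlated with their area channel so the
#' area/height pulse ratio is tight around 1 for single particles. A fraction
#' \code{doublet_fraction} of emitted objects are two-particle clusters whose
#' area signals are scaled by \code{doublet_area_scale} and height signals by
#' \code{doublet_height_scale} relative to a singlet draw (pulse elongation:
#' a cluster roughly doubles the integrated pulse but stretches, rather than
#' doubles, its peak).
#'
#' @param name Population label (e.g. \code{"bead_15um"}).
#' @param kind One of \code{"bead"}, \code{"RBC"}, \code{"WBC"},
#'   \code{"accudrop"}.
#' @param diameter Particle diameter in micrometres.
#' @param concentration Particles per mL of sample.
#' @param channels Named list over the eight panel channels; each element a
#'   list with \code{median} (arbitrary intensity units) and \code{cv}.
#' @param doublet_fraction Probability in [0,1] that an emitted object is a
#'   two-particle cluster.
#' @param doublet_area_scale,doublet_height_scale Multiplicative signal scale
#'   of a cluster relative to a singlet draw, for pulse-area and pulse-height
#'   channels respectively.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(name, kind, diameter, concentration, channels,
                            doublet_fraction = 0.05,
                            doublet_area_scale = 2,
                            doublet_height_scale = 1.2) {
  kind <- match.arg(kind, c("bead", "RBC", "WBC", "accudrop"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(diameter) || diameter <= 0)
    stop("diameter must be > 0 for population '", name, "'", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be > 0 for population '", name, "'",
         call. = FALSE)
  if (!is.numeric(doublet_fraction) || doublet_fraction < 0 ||
      doublet_fraction > 1)
    stop("doublet_fraction must lie in [0,1] for population '", name, "'",
         call. = FALSE)
  missing <- setdiff(SORTGAUGE_CHANNELS, names(channels))
  if (length(missing) > 0L)
    stop("channel model for '", name, "' lacks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (ch in names(channels)) {
    m <- channels[[ch]]
    if (!is.numeric(m$median) || m$median <= 0 ||
        !is.numeric(m$cv) || m$cv <= 0)
      stop("channel '", ch, "' of '", name,
           "' needs positive median and cv", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, diameter = diameter,
         concentration = concentration,
         channels = channels[SORTGAUGE_CHANNELS],
         doublet_fraction = doublet_fraction,
         doublet_area_scale = doublet_area_scale,
         doublet_height_scale = doublet_height_scale),
    class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s (%s), %.3g um, %.4g /mL, doublets %.1f%%\n",
              x$name, x$kind, x$diameter, x$concentration,
              100 * x$doublet_fraction))
  invisible(x)
}

# Build the eight-channel model from a compact description. Scatter medians
# scale with diameter^2 (geometric cross-section); heights share the area
# median and carry only the small pulse-shape cv.
channel_model <- function(diameter, fluor, scatter_cv = 0.35,
                          fluor_cv = 0.25, height_cv = 0.05,
                          fsc_per_um2 = 500, ssc_per_um2 = NULL) {
  ssc_per_um2 <- ssc_per_um2 %||% (fsc_per_um2 * 0.3)
  fsc <- fsc_per_um2 * diameter^2
  ssc <- ssc_per_um2 * diameter^2
  mods <- list(
    `FSC-A` = list(median = fsc, cv = scatter_cv),
    `FSC-H` = list(median = fsc, cv = height_cv),
    `SSC-A` = list(median = ssc, cv = scatter_cv),
    `SSC-H` = list(median = ssc, cv = height_cv))
  for (ch in c("B530", "YG610", "B610", "R670")) {
    mods[[ch]] <- list(median = fluor[[ch]], cv = fluor_cv)
  }
  mods
}

#' Reference bead-mixture populations
#'
#' The five-size validation bead mixture (3, 7, 10, 15, 20 um) at the stock
#' concentrations used to exercise a size-based sorter: small sizes at
#' blood-like high concentrations, large CTC-surrogate sizes rare. Sizes are
#' resolved by fluorescence (B530 increasing with size; YG610 distinguishes
#' the 7 um dye) rather than by forward scatter alone, whose population CVs
#' are wide enough that adjacent sizes overlap.
#'
#' @param doublet_fraction Cluster prevalence applied to every bead size.
#' @return Named list of \code{population_spec} objects.
#' @export
bead_mix_populations <- function(doublet_fraction = 0.05) {
  mk <- function(name, d, conc, fluor) {
    population_spec(name, "bead", d, conc,
                    channel_model(d, fluor),
                    doublet_fraction = doublet_fraction)
  }
  pops <- list(
    mk("bead_3um", 3, 4.13e6,
       list(B530 = 400,    YG610 = 250,   B610 = 200, R670 = 150)),
    mk("bead_7um", 7, 286e3,
       list(B530 = 400,    YG610 = 30000, B610 = 200, R670 = 150)),
    mk("bead_10um", 10, 161e3,
       list(B530 = 8000,   YG610 = 800,   B610 = 200, R670 = 150)),
    mk("bead_15um", 15, 51e3,
       list(B530 = 80000,  YG610 = 800,   B610 = 200, R670 = 150)),
    mk("bead_20um", 20, 25e3,
       list(B530 = 600000, YG610 = 800,   B610 = 200, R670 = 150)))
  names(pops) <- vapply(pops, `[[`, "", "name")
  pops
}

#' Accudrop-style counting-bead population
#'
#' Counting beads spiked in equal quantity into each equal-volume collection
#' tube; identified by their high B610 emission and low B530, far from every
#' sample population. Concentration is nominal (spiking is by count, not by
#' sampled volume) and the doublet fraction defaults to zero.
#'
#' @param doublet_fraction Cluster prevalence among the counting beads.
#' @return A \code{population_spec}.
#' @export
accudrop_population <- function(doublet_fraction = 0) {
  population_spec(
    "accudrop", "accudrop", diameter = 3.2, concentration = 1e6,
    channel_model(3.2, list(B530 = 200, YG610 = 200, B610 = 3e5, R670 = 150)),
    doublet_fraction = doublet_fraction)
}

#' Diluted-blood populations with spiked sizing beads
#'
#' Emulates CD45-stained whole blood diluted 1:20, spiked with 10/15/20 um
#' beads at the bead-mixture concentrations. RBCs are CD45-negative and
#' low-granularity; WBCs carry a high R670 (CD45-APC) signal. Platelets and
#' debris are not modeled. Concentrations refer to the diluted suspension;
#' keep the simulated volume small (default 0.002 mL in the shipped scenario)
#' to stay at desk-scale event counts.
#'
#' @param dilution Extra dilution factor applied to the blood cells on top of
#'   the 1:20 baseline (beads are spiked post-dilution and are unaffected).
#' @param doublet_fraction Cluster prevalence applied to all populations.
#' @return Named list of \code{population_spec} objects.
#' @export
blood_populations <- function(dilution = 1, doublet_fraction = 0.05) {
  stopifnot(dilution >= 1)
  beads <- bead_mix_populations(doublet_fraction)
  rbc <- population_spec(
    "RBC", "RBC", diameter = 7, concentration = 2.5e8 / dilution,
    channel_model(7, list(B530 = 150, YG610 = 150, B610 = 200, R670 = 150),
                  ssc_per_um2 = 40),
    doublet_fraction = doublet_fraction)
  wbc <- population_spec(
    "WBC", "WBC", diameter = 10, concentration = 3.3e5 / dilution,
    channel_model(10, list(B530 = 300, YG610 = 300, B610 = 250, R670 = 20000)),
    doublet_fraction = doublet_fraction)
  c(list(RBC = rbc, WBC = wbc),
    beads[c("bead_10um", "bead_15um", "bead_20um")])
}

#' Read or write population configurations as YAML
#'
#' The YAML schema mirrors \code{\link{population_spec}}: a top-level
#' \code{populations} sequence whose entries carry \code{name}, \code{kind},
#' \code{diameter_um}, \code{concentration_per_ml}, \code{doublet_fraction},
#' optional doublet scales, and a \code{channels} map of
#' \code{\{median, cv\}} pairs.
#'
#' @param path File path.
#' @param populations Named list of \code{population_spec} objects.
#' @return \code{read_population_config}: named list of
#'   \code{population_spec}; \code{write_population_config}: \code{path},
#'   invisibly.
#' @export
read_population_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$populations))
    stop("population config lacks a 'populations' entry: ", path,
         call. = FALSE)
  pops <- lapply(cfg$populations, function(p) {
    population_spec(
      name = p$name, kind = p$kind, diameter = p$diameter_um,
      concentration = p$concentration_per_ml,
      channels = p$channels,
      doublet_fraction = p$doublet_fraction %||% 0.05,
      doublet_area_scale = p$doublet_area_scale %||% 2,
      doublet_height_scale = p$doublet_height_scale %||% 1.2)
  })
  names(pops) <- vapply(pops, `[[`, "", "name")
  pops
}

#' @rdname read_population_config
#' @export
write_population_config <- function(populations, path) {
  entries <- lapply(unname(populations), function(p) {
    list(name = p$name, kind = p$kind, diameter_um = p$diameter,
         concentration_per_ml = p$concentration,
         doublet_fraction = p$doublet_fraction,
         doublet_area_scale = p$doublet_area_scale,
         doublet_height_scale = p$doublet_height_scale,
         channels = p$channels)
  })
  yaml::write_yaml(list(populations = entries), path)
  invisible(path)
}
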