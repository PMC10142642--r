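# Device scenarios: the probabilistic surrogate for a two-outlet
# continuous-flow sorter. Inertial focusing is not modeled mechanistically;
# the device is summarised by per-population, per-cluster-class probabilities
# of exiting through the inner (target) outlet at a named flow rate.

#' Define a two-outlet sorter scenario
#'
#' @param flow_rate Sample flow rate in mL/min (a label for the operating
#'   point; it does not enter the sampling).
#' @param p_inner Data frame with columns \code{population}, \code{class}
#'   (\code{"singlet"} or \code{"doublet"}) and \code{p_inner}, the
#'   probability that such an object exits via the inner outlet.
#' @param f_inner Fraction of the processed volume collected at the inner
#'   outlet; the devices characterised here collect about one third centrally.
#' @return An object of class \code{device_scenario}.
#' @export
device_scenario <- function(flow_rate, p_inner, f_inner = 1 / 3) {
  stopifnot(is.data.frame(p_inner),
            all(c("population", "class", "p_inner") %in% names(p_inner)))
  if (any(p_inner$p_inner < 0 | p_inner$p_inner > 1))
    stop("all p_inner values must lie in [0,1]", call. = FALSE)
  if (!is.numeric(f_inner) || f_inner <= 0 || f_inner >= 1)
    stop("f_inner must lie in (0,1)", call. = FALSE)
  bad <- setdiff(p_inner$class, c("singlet", "doublet"))
  if (length(bad) > 0L)
    stop("unknown cluster class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(flow_rate = flow_rate,
                 p_inner = p_inner[, c("population", "class", "p_inner")],
                 f_inner = f_inner),
            class = "device_scenario")
}

#' @export
print.device_scenario <- function(x, ...) {
  cat(sprintf("<device_scenario> %.2g mL/min, f_inner = %.3f\n",
              x$flow_rate, x$f_inner))
  print(x$p_inner, row.names = FALSE)
  invisible(x)
}

# Look up p_inner for (population, class) pairs; NA where absent.
scenario_p <- function(scenario, population, class) {
  key <- paste(scenario$p_inner$population, scenario$p_inner$class)
  scenario$p_inner$p_inner[match(paste(population, class), key)]
}

p_inner_table <- function(...) {
  # rows of population -> c(singlet, doublet)
  rows <- list(...)
  do.call(rbind, lapply(names(rows), function(pop) {
    data.frame(population = pop, class = c("singlet", "doublet"),
               p_inner = as.numeric(rows[[pop]]))
  }))
}

#' Flow-rate titration scenarios for the bead mixture
#'
#' Inner-outlet capture probabilities for the five bead sizes at sample flow
#' rates 0.6 to 1.0 mL/min on a size-selective inertial device. The measured
#' operating points carried by these fixtures: at 0.7 mL/min the 20 um beads
#' are almost fully captured while only 50.7% of 15 um singlets and 24.7% of
#' 15 um doublets reach the inner outlet; at 0.9 mL/min 15 um capture exceeds
#' 98% (doublet capture peaks) but 46.3% of 10 um singlets and 54.5% of 10 um
#' doublets are co-captured; at 0.6 mL/min large particles are not focused
#' centrally. Values without a measured anchor are fixture constants chosen
#' to follow that titration shape.
#'
#' @param flow_rate One of 0.6, 0.7, 0.8, 0.9, 1.0 (mL/min).
#' @return A \code{device_scenario}.
#' @export
flow_rate_scenario <- function(flow_rate) {
  tabs <- list(
    "0.6" = p_inner_table(bead_3um = c(0.02, 0.02), bead_7um = c(0.03, 0.03),
                          bead_10um = c(0.05, 0.06), bead_15um = c(0.02, 0.02),
                          bead_20um = c(0.05, 0.05)),
    "0.7" = p_inner_table(bead_3um = c(0.03, 0.03), bead_7um = c(0.05, 0.05),
                          bead_10um = c(0.15, 0.20),
                          bead_15um = c(0.507, 0.247),
                          bead_20um = c(0.995, 0.995)),
    "0.8" = p_inner_table(bead_3um = c(0.05, 0.05), bead_7um = c(0.08, 0.08),
                          bead_10um = c(0.20, 0.25),
                          bead_15um = c(0.985, 0.85),
                          bead_20um = c(0.995, 0.995)),
    "0.9" = p_inner_table(bead_3um = c(0.08, 0.08), bead_7um = c(0.12, 0.12),
                          bead_10um = c(0.463, 0.545),
                          bead_15um = c(0.985, 0.92),
                          bead_20um = c(0.995, 0.995)),
    "1.0" = p_inner_table(bead_3um = c(0.10, 0.10), bead_7um = c(0.15, 0.15),
                          bead_10um = c(0.55, 0.60),
                          bead_15um = c(0.98, 0.88),
                          bead_20um = c(0.995, 0.995)))
  key <- sprintf("%.1f", flow_rate)
  if (!key %in% names(tabs))
    stop("no fixture scenario at flow rate ", flow_rate,
         " mL/min (available: ", paste(names(tabs), collapse = ", "), ")",
         call. = FALSE)
  device_scenario(flow_rate, tabs[[key]])
}

#' Beads-in-blood scenarios at each chip's optimal flow rate
#'
#' Capture probabilities for diluted blood spiked with 10/15/20 um beads, for
#' a 3D-printed zigzag chip (0.8 mL/min) and a PDMS spiral chip (1.7 mL/min).
#' Both enrich particles above ~12-15 um: low capture of RBCs (~4%), WBCs
#' (~7%) and 10 um singlets (~4%), high capture of 15 and 20 um beads. The
#' chips differ mainly in 10 um doublet capture (>10% zigzag vs ~2% spiral).
#'
#' @param chip \code{"zigzag"} or \code{"spiral"}.
#' @return A \code{device_scenario}.
#' @export
blood_scenario <- function(chip = c("zigzag", "spiral")) {
  chip <- match.arg(chip)
  if (chip == "zigzag") {
    device_scenario(0.8, p_inner_table(
      RBC = c(0.04, 0.04), WBC = c(0.07, 0.07),
      bead_10um = c(0.04, 0.12), bead_15um = c(0.98, 0.95),
      bead_20um = c(0.995, 0.995)))
  } else {
    device_scenario(1.7, p_inner_table(
      RBC = c(0.04, 0.04), WBC = c(0.07, 0.07),
      bead_10um = c(0.04, 0.02), bead_15um = c(0.98, 0.90),
      bead_20um = c(0.995, 0.995)))
  }
}

#' Read or write device scenarios as YAML
#'
#' Schema: \code{flow_rate_ml_min}, \code{f_inner}, and a \code{p_inner}
#' sequence of \code{\{population, class, p_inner\}} entries.
#'
#' @param path File path.
#' @param scenario A \code{device_scenario}.
#' @return \code{read_scenario_config}: a \code{device_scenario};
#'   \code{write_scenario_config}: \code{path}, invisibly.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(cfg$p_inner, function(e) {
    data.frame(population = e$population, class = e$class,
               p_inner = e$p_inner)
  }))
  device_scenario(cfg$flow_rate_ml_min, tab, cfg$f_inner %||% (1 / 3))
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(scenario, path) {
  entries <- lapply(seq_len(nrow(scenario$p_inner)), function(i) {
    as.list(scenario$p_inner[i, ])
  })
  yaml::write_yaml(list(flow_rate_ml_min = scenario$flow_rate,
                        f_inner = scenario$f_inner,
                        p_inner = entries), path)
  invisible(path)
}
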