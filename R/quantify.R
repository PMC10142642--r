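# Quantification: counting-bead volume normalization, Separation Efficiency,
# Purity, collection-ratio QC and replicate aggregation.

#' Counts indexed by outlet, population and cluster class
#'
#' A long-format count container with columns \code{outlet},
#' \code{population}, \code{class} (\code{singlet}/\code{doublet}/
#' \code{total}) and \code{count}; \code{\link{correct_counts}} adds a
#' \code{corrected} column. Raw counts are integers; corrected counts may be
#' fractional.
#'
#' @param counts Data frame with the four columns above, counts >= 0.
#' @return An object of classes \code{count_matrix} and \code{data.frame}.
#' @export
count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("outlet", "population", "class", "count") %in%
                  names(counts)))
  if (any(counts$count < 0))
    stop("counts must be non-negative", call. = FALSE)
  bad <- setdiff(counts$class, c("singlet", "doublet", "total"))
  if (length(bad) > 0L)
    stop("unknown cluster class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(counts) <- c("count_matrix", "data.frame")
  counts
}

get_count <- function(cm, outlet, population, class,
                      corrected = "corrected" %in% names(cm)) {
  col <- if (corrected) "corrected" else "count"
  idx <- cm$outlet == outlet & cm$population == population &
    cm$class == class
  if (!any(idx)) return(NA_real_)
  sum(cm[[col]][idx])
}

#' Per-outlet count-correction factors from recorded counting beads
#'
#' Equal counting-bead spikes into equal-volume tubes mean the recorded bead
#' count of each FCS file is proportional to the fraction of that tube
#' acquired. Two correction conventions are provided. The default,
#' \code{"volume_consistent"}, scales each outlet by
#' \code{A_ref / A_outlet}, which equalises the effective acquired volume
#' across tubes (an outlet that recorded twice the beads had twice the
#' volume acquired, so its counts are halved relative to the reference).
#' \code{"paper_literal"} scales by \code{A_outlet / A_ref}, reproducing the
#' worked-example arithmetic in which the tube with 10,000 recorded beads
#' against 5,000 in the reference tube has its counts doubled. The reference
#' outlet's factor is 1 in both modes.
#'
#' @param A_inner,A_outer Recorded counting-bead counts per tube (> 0).
#' @param reference Reference outlet (conventionally the one collecting the
#'   non-target population, i.e. \code{"outer"}).
#' @param mode \code{"volume_consistent"} (default) or
#'   \code{"paper_literal"}.
#' @return Named numeric vector of factors \code{c(inner =, outer =)}.
#' @export
accudrop_factors <- function(A_inner, A_outer,
                             reference = c("outer", "inner"),
                             mode = c("volume_consistent",
                                      "paper_literal")) {
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  A <- c(inner = A_inner, outer = A_outer)
  if (any(!is.finite(A)) || any(A <= 0))
    stop("counting-bead counts must be positive in every tube; ",
         "normalization is impossible otherwise", call. = FALSE)
  if (mode == "paper_literal") A / A[reference] else A[reference] / A
}

#' Apply per-outlet correction factors to a count matrix
#'
#' @param cm A \code{\link{count_matrix}} of raw counts.
#' @param factors Named per-outlet factors, e.g. from
#'   \code{\link{accudrop_factors}}.
#' @return The count matrix with a \code{corrected} column.
#' @export
correct_counts <- function(cm, factors) {
  stopifnot(inherits(cm, "count_matrix"))
  missing <- setdiff(unique(cm$outlet), names(factors))
  if (length(missing) > 0L)
    stop("no correction factor for outlet(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cm$corrected <- cm$count * unname(factors[cm$outlet])
  cm
}

#' Separation Efficiency
#'
#' The percentage of a population (within one cluster class) that was
#' collected in the target outlet:
#' \code{SE = 100 * c_target / (c_target + c_other)}, computed on
#' volume-corrected counts in both terms. When the population was seen in
#' neither outlet the metric is undefined and \code{NA} is returned —
#' deliberately distinct from 0, which would mean perfect depletion.
#'
#' @param cm A corrected \code{\link{count_matrix}}.
#' @param population Population label.
#' @param class \code{"singlet"}, \code{"doublet"} or \code{"total"}.
#' @param target_outlet The outlet the device is meant to enrich into.
#' @return SE in percent, or \code{NA_real_} when undefined.
#' @export
separation_efficiency <- function(cm, population, class = "total",
                                  target_outlet = "inner") {
  stopifnot(inherits(cm, "count_matrix"))
  if (!"corrected" %in% names(cm))
    stop("counts are uncorrected; apply correct_counts() first",
         call. = FALSE)
  outlets <- unique(cm$outlet)
  if (!target_outlet %in% outlets)
    stop("unknown target outlet '", target_outlet, "'", call. = FALSE)
  c_t <- get_count(cm, target_outlet, population, class)
  c_o <- sum(vapply(setdiff(outlets, target_outlet), function(o) {
    v <- get_count(cm, o, population, class)
    if (is.na(v)) 0 else v
  }, 0))
  if (is.na(c_t)) return(NA_real_)
  if (c_t + c_o <= 0) return(NA_real_)
  100 * c_t / (c_t + c_o)
}

#' Purity of the target outlet
#'
#' Default \code{"freq_total"}: the population's percentage of all events in
#' the target outlet (the "Freq. total" convention), so purities across
#' populations sum to 100. \code{"ratio"}: the target/non-target count
#' ratio. Counting beads are an added reagent, not sample, and are excluded
#' from the composition by default. Undefined (empty target outlet) yields
#' \code{NA}.
#'
#' @param cm A corrected \code{\link{count_matrix}}.
#' @param population Population label.
#' @param target_outlet Outlet whose composition is assessed.
#' @param definition \code{"freq_total"} or \code{"ratio"}.
#' @param exclude Populations excluded from the composition.
#' @return Percent (freq_total) or unitless ratio, or \code{NA_real_}.
#' @export
purity <- function(cm, population, target_outlet = "inner",
                   definition = c("freq_total", "ratio"),
                   exclude = "accudrop") {
  stopifnot(inherits(cm, "count_matrix"))
  definition <- match.arg(definition)
  if (!"corrected" %in% names(cm))
    stop("counts are uncorrected; apply correct_counts() first",
         call. = FALSE)
  pops <- setdiff(unique(cm$population), exclude)
  if (!population %in% pops)
    stop("population '", population, "' not present (or excluded)",
         call. = FALSE)
  tot <- vapply(pops, function(p) {
    v <- get_count(cm, target_outlet, p, "total")
    if (is.na(v)) 0 else v
  }, 0)
  denom <- sum(tot)
  if (denom <= 0) return(NA_real_)
  c_pop <- tot[[population]]
  if (definition == "freq_total") 100 * c_pop / denom
  else {
    non_target <- denom - c_pop
    if (non_target <= 0) return(NA_real_)
    c_pop / non_target
  }
}

#' Collection-ratio quality control
#'
#' The devices characterised here collect approximately one third of the
#' sample volume at the inner outlet regardless of flow rate; runs whose
#' collected-volume split deviates from that expectation indicate a
#' collection problem and are flagged for exclusion.
#'
#' @param volumes Named per-outlet collected volumes (any consistent unit),
#'   with an \code{inner} element.
#' @param expected_fraction Expected inner-volume fraction.
#' @param tolerance Absolute tolerance on the fraction.
#' @return List with \code{ratio} (inner/total) and logical \code{pass}.
#' @export
collection_ratio_qc <- function(volumes, expected_fraction = 1 / 3,
                                tolerance = 0.05) {
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  if (!"inner" %in% names(volumes))
    stop("volumes must name an 'inner' outlet", call. = FALSE)
  ratio <- unname(volumes[["inner"]] / sum(volumes))
  list(ratio = ratio, pass = abs(ratio - expected_fraction) <= tolerance)
}

#' Build a device performance report
#'
#' Applies counting-bead normalization to raw per-outlet counts, computes
#' Separation Efficiency for every population and cluster class, Purity of
#' the target outlet for every population, and the collection-ratio QC.
#'
#' @param cm Raw \code{\link{count_matrix}} including an \code{accudrop}
#'   population (or explicit \code{accudrop_counts}).
#' @param volumes Named per-outlet collected volumes (uL) for QC; omit with
#'   \code{NULL} to skip QC.
#' @param target_outlet Target outlet.
#' @param correction_mode Passed to \code{\link{accudrop_factors}}.
#' @param purity_definition Passed to \code{\link{purity}}.
#' @param accudrop_counts Optional named vector \code{c(inner=, outer=)} of
#'   recorded counting beads overriding the gated \code{accudrop} totals.
#' @param qc_expected,qc_tolerance Collection-ratio QC parameters.
#' @return An object of class \code{performance_report}: list with
#'   \code{se} (population x class data frame, percent), \code{purity}
#'   (per population), \code{factors}, \code{accudrop},
#'   \code{collection_ratio}, \code{qc_pass} and the modes used.
#' @export
performance_report <- function(cm, volumes = NULL, target_outlet = "inner",
                               correction_mode = c("volume_consistent",
                                                   "paper_literal"),
                               purity_definition = c("freq_total", "ratio"),
                               accudrop_counts = NULL,
                               qc_expected = 1 / 3, qc_tolerance = 0.05) {
  correction_mode <- match.arg(correction_mode)
  purity_definition <- match.arg(purity_definition)
  if (is.null(accudrop_counts)) {
    accudrop_counts <- c(
      inner = get_count(cm, "inner", "accudrop", "total", corrected = FALSE),
      outer = get_count(cm, "outer", "accudrop", "total", corrected = FALSE))
    if (anyNA(accudrop_counts))
      stop("no accudrop counts available; gate them or pass ",
           "accudrop_counts", call. = FALSE)
  }
  reference <- setdiff(c("inner", "outer"), target_outlet)[1]
  factors <- accudrop_factors(accudrop_counts[["inner"]],
                              accudrop_counts[["outer"]],
                              reference = reference, mode = correction_mode)
  ccm <- correct_counts(cm, factors)
  pops <- setdiff(unique(cm$population), "accudrop")
  se <- do.call(rbind, lapply(pops, function(p) {
    data.frame(population = p, class = c("singlet", "doublet", "total"),
               se = vapply(c("singlet", "doublet", "total"), function(cl) {
                 separation_efficiency(ccm, p, cl, target_outlet)
               }, 0), stringsAsFactors = FALSE, row.names = NULL)
  }))
  pur <- data.frame(population = pops,
                    purity = vapply(pops, function(p) {
                      purity(ccm, p, target_outlet, purity_definition)
                    }, 0), stringsAsFactors = FALSE, row.names = NULL)
  qc <- if (is.null(volumes)) list(ratio = NA_real_, pass = NA)
  else collection_ratio_qc(volumes, qc_expected, qc_tolerance)
  structure(list(se = se, purity = pur, factors = factors,
                 accudrop = accudrop_counts,
                 collection_ratio = qc$ratio, qc_pass = qc$pass,
                 target_outlet = target_outlet,
                 correction_mode = correction_mode,
                 purity_definition = purity_definition),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "<performance_report> target '%s', correction '%s', purity '%s'\n",
    x$target_outlet, x$correction_mode, x$purity_definition))
  if (!is.na(x$collection_ratio))
    cat(sprintf("collection ratio %.3f (QC %s)\n", x$collection_ratio,
                if (isTRUE(x$qc_pass)) "pass" else "FAIL"))
  cat("Separation Efficiency (%):\n")
  print(x$se, row.names = FALSE, digits = 4)
  cat("Purity of target outlet:\n")
  print(x$purity, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract one Separation Efficiency value from a report
#'
#' @param report A \code{\link{performance_report}}.
#' @param population Population label.
#' @param class Cluster class.
#' @return SE in percent (or \code{NA_real_}).
#' @export
se_value <- function(report, population, class = "total") {
  idx <- report$se$population == population & report$se$class == class
  if (!any(idx)) NA_real_ else report$se$se[idx]
}

#' Aggregate replicate performance reports
#'
#' Replicates failing the collection-ratio QC are excluded (and listed);
#' the rest are summarised by per-metric mean and sample standard
#' deviation.
#'
#' @param reports List of \code{\link{performance_report}} objects over the
#'   same populations and classes.
#' @return List with \code{se_summary} (population, class, mean, sd, n),
#'   \code{purity_summary}, \code{n_replicates} and \code{excluded}
#'   (indices of QC-failed replicates).
#' @export
aggregate_replicates <- function(reports) {
  stopifnot(length(reports) >= 1L)
  keysets <- lapply(reports, function(r)
    paste(r$se$population, r$se$class))
  for (i in seq_along(reports)) {
    if (!setequal(keysets[[1]], keysets[[i]]))
      stop("replicate ", i, " covers a different population/class set",
           call. = FALSE)
  }
  failed <- which(vapply(reports, function(r) isFALSE(r$qc_pass), TRUE))
  kept <- setdiff(seq_along(reports), failed)
  if (length(kept) == 0L)
    stop("all replicates failed collection-ratio QC", call. = FALSE)
  use <- reports[kept]
  key <- keysets[[1]]
  se_mat <- vapply(use, function(r) {
    r$se$se[match(key, paste(r$se$population, r$se$class))]
  }, numeric(length(key)))
  se_mat <- matrix(se_mat, nrow = length(key))
  se_summary <- data.frame(
    population = reports[[1]]$se$population,
    class = reports[[1]]$se$class,
    mean = rowMeans(se_mat, na.rm = TRUE),
    sd = apply(se_mat, 1L, stats::sd, na.rm = TRUE),
    n = rowSums(!is.na(se_mat)), stringsAsFactors = FALSE)
  pops <- reports[[1]]$purity$population
  p_mat <- vapply(use, function(r) {
    r$purity$purity[match(pops, r$purity$population)]
  }, numeric(length(pops)))
  p_mat <- matrix(p_mat, nrow = length(pops))
  purity_summary <- data.frame(
    population = pops,
    mean = rowMeans(p_mat, na.rm = TRUE),
    sd = apply(p_mat, 1L, stats::sd, na.rm = TRUE),
    n = rowSums(!is.na(p_mat)), stringsAsFactors = FALSE)
  list(se_summary = se_summary, purity_summary = purity_summary,
       n_replicates = length(kept), excluded = failed)
}
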