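# Hierarchical gating: geometric gates on channel pairs, a gating tree
# yielding population labels, and pulse-processing singlet/doublet
# classification on the area/height ratio.

#' Define a rectangular or polygonal gate
#'
#' Gates live on a 2-D channel pair with an axis transform of
#' \code{"linear"} or \code{"log10"}. Region coordinates are given in raw
#' data units; with a log axis, events (and vertices) at values <= 0 fall
#' outside every gate on that axis. Boundary points count as inside.
#'
#' @param id Gate identifier.
#' @param channel_x,channel_y Channel names.
#' @param xmin,xmax,ymin,ymax Rectangle corners (raw units), ordered.
#' @param x,y Polygon vertex coordinates (raw units); the polygon must be
#'   simple (non-self-intersecting).
#' @param transform_x,transform_y Axis transforms.
#' @return An object of class \code{gate}.
#' @export
rectangle_gate <- function(id, channel_x, channel_y,
                           xmin, xmax, ymin, ymax,
                           transform_x = "linear", transform_y = "linear") {
  if (xmin > xmax || ymin > ymax)
    stop("rectangle corners must be ordered (min <= max) in gate '", id, "'",
         call. = FALSE)
  structure(list(id = id, type = "rectangle",
                 channel_x = channel_x, channel_y = channel_y,
                 transform_x = match.arg(transform_x, c("linear", "log10")),
                 transform_y = match.arg(transform_y, c("linear", "log10")),
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "gate")
}

#' @rdname rectangle_gate
#' @export
polygon_gate <- function(id, channel_x, channel_y, x, y,
                         transform_x = "linear", transform_y = "linear") {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (polygon_self_intersects(x, y))
    stop("polygon gate '", id, "' is self-intersecting", call. = FALSE)
  structure(list(id = id, type = "polygon",
                 channel_x = channel_x, channel_y = channel_y,
                 transform_x = match.arg(transform_x, c("linear", "log10")),
                 transform_y = match.arg(transform_y, c("linear", "log10")),
                 x = as.numeric(x), y = as.numeric(y)),
            class = "gate")
}

# Segment-intersection test over non-adjacent polygon edges.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4L) return(FALSE)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return(TRUE)
    }
  }
  FALSE
}

gate_axis <- function(values, transform) {
  if (transform == "log10") {
    out <- rep(NA_real_, length(values))
    ok <- is.finite(values) & values > 0
    out[ok] <- log10(values[ok])
    out
  } else {
    values
  }
}

# Even-odd point-in-polygon with an explicit on-edge check (boundary points
# are members). Vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- pmin(xi, xj) - 1e-12 <= px & px <= pmax(xi, xj) + 1e-12 &
      pmin(yi, yj) - 1e-12 <= py & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) <= 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a gate to an event table
#'
#' @param events Event table.
#' @param gate A \code{\link{rectangle_gate}} or \code{\link{polygon_gate}}.
#' @return Logical membership mask, one element per event. Events with
#'   non-positive values on a log-transformed axis are never members.
#' @export
apply_gate <- function(events, gate) {
  stopifnot(inherits(gate, "gate"))
  missing <- setdiff(c(gate$channel_x, gate$channel_y), names(events))
  if (length(missing) > 0L)
    stop("gate '", gate$id, "' needs missing channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- gate_axis(events[[gate$channel_x]], gate$transform_x)
  y <- gate_axis(events[[gate$channel_y]], gate$transform_y)
  ok <- !is.na(x) & !is.na(y)
  mask <- rep(FALSE, nrow(events))
  if (!any(ok)) return(mask)
  if (gate$type == "rectangle") {
    lim <- c(gate_axis(c(gate$xmin, gate$xmax), gate$transform_x),
             gate_axis(c(gate$ymin, gate$ymax), gate$transform_y))
    mask[ok] <- x[ok] >= lim[1] & x[ok] <= lim[2] &
      y[ok] >= lim[3] & y[ok] <= lim[4]
  } else {
    vx <- gate_axis(gate$x, gate$transform_x)
    vy <- gate_axis(gate$y, gate$transform_y)
    if (anyNA(vx) || anyNA(vy))
      stop("polygon gate '", gate$id,
           "' has non-positive vertices on a log axis", call. = FALSE)
    mask[ok] <- point_in_polygon(x[ok], y[ok], vx, vy)
  }
  mask
}

#' Assemble a hierarchical gating tree
#'
#' Nodes apply a gate to their parent's members; leaves carry population
#' labels. Leaf regions within a parent are expected to be disjoint — use
#' \code{\link{validate_tree}} on fixture data to verify; labeling assigns
#' each event to at most one leaf (first match in node order).
#'
#' @param gates List of \code{gate} objects (named by their ids or not).
#' @param nodes Data frame with columns \code{id}, \code{parent}
#'   (\code{"root"} for top level), \code{gate} (gate id) and \code{label}
#'   (population label for leaves, \code{NA} for internal nodes).
#' @return An object of class \code{gating_tree}.
#' @export
gating_tree <- function(gates, nodes) {
  names(gates) <- vapply(gates, `[[`, "", "id")
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent", "gate", "label") %in% names(nodes)))
  if (anyDuplicated(nodes$id))
    stop("node ids must be unique", call. = FALSE)
  labs <- nodes$label[!is.na(nodes$label)]
  if (anyDuplicated(labs))
    stop("leaf labels must be unique", call. = FALSE)
  missing <- setdiff(nodes$gate, names(gates))
  if (length(missing) > 0L)
    stop("nodes reference unknown gate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(setdiff(nodes$parent, "root"), nodes$id)
  if (length(bad) > 0L)
    stop("nodes reference unknown parent(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(gates = gates, nodes = nodes), class = "gating_tree")
}

#' @export
print.gating_tree <- function(x, ...) {
  cat("<gating_tree> with", nrow(x$nodes), "nodes,",
      sum(!is.na(x$nodes$label)), "leaves:",
      paste(stats::na.omit(x$nodes$label), collapse = ", "), "\n")
  invisible(x)
}

tree_leaves <- function(tree) tree$nodes$label[!is.na(tree$nodes$label)]

# Membership mask of every node, computed top-down.
tree_masks <- function(events, tree) {
  masks <- list(root = rep(TRUE, nrow(events)))
  for (i in seq_len(nrow(tree$nodes))) {
    node <- tree$nodes[i, ]
    parent <- masks[[node$parent]]
    if (is.null(parent))
      stop("node '", node$id, "' appears before its parent '",
           node$parent, "'", call. = FALSE)
    masks[[node$id]] <- parent & apply_gate(events, tree$gates[[node$gate]])
  }
  masks
}

#' Label events with a gating tree
#'
#' @param events Event table.
#' @param tree A \code{\link{gating_tree}}.
#' @return Character vector of leaf labels, \code{NA} for ungated events.
#'   The number of events matching more than one leaf (which a valid
#'   strategy should keep at zero) is attached as attribute
#'   \code{"n_multi_leaf"}.
#' @export
label_events <- function(events, tree) {
  masks <- tree_masks(events, tree)
  labels <- rep(NA_character_, nrow(events))
  hits <- rep(0L, nrow(events))
  for (i in seq_len(nrow(tree$nodes))) {
    node <- tree$nodes[i, ]
    if (is.na(node$label)) next
    m <- masks[[node$id]]
    hits <- hits + as.integer(m)
    assign_now <- m & is.na(labels)
    labels[assign_now] <- node$label
  }
  attr(labels, "n_multi_leaf") <- sum(hits > 1L)
  labels
}

#' Validate a gating tree against (fixture) data
#'
#' Checks that no event reaches more than one leaf and, when ground truth is
#' present, reports per-leaf recovery and contamination.
#'
#' @param events Event table, ideally with ground-truth labels.
#' @param tree A \code{\link{gating_tree}}.
#' @return List with \code{n_multi_leaf}, \code{n_ungated} and (with ground
#'   truth) a per-leaf \code{recovery}/\code{contamination} data frame.
#' @export
validate_tree <- function(events, tree) {
  labels <- label_events(events, tree)
  out <- list(n_multi_leaf = attr(labels, "n_multi_leaf"),
              n_ungated = sum(is.na(labels)))
  if ("population_id" %in% names(events)) {
    leaves <- tree_leaves(tree)
    stats <- do.call(rbind, lapply(leaves, function(lf) {
      truth <- events$population_id == lf
      got <- !is.na(labels) & labels == lf
      data.frame(
        leaf = lf,
        recovery = if (any(truth)) sum(got & truth) / sum(truth) else NA_real_,
        contamination = if (any(got)) sum(got & !truth) / sum(got) else NA_real_)
    }))
    out$leaf_stats <- stats
  }
  out
}

#' Pulse-processing singlet/doublet classification
#'
#' Particles traveling as a cluster elongate the cytometer pulse, raising
#' integrated area relative to peak height; thresholding the area/height
#' ratio separates singlets from doublets/larger clusters (all clusters are
#' classed \code{"doublet"}). With \code{threshold = NULL} the cut is placed
#' automatically at the valley between the two modes of the log-ratio
#' density; if no clear second mode exists, a fixed default at the geometric
#' midpoint of the singlet (1) and doublet (area-scale/height-scale) ratios
#' is used.
#'
#' @param events Event table.
#' @param area_channel,height_channel Pulse channels, default forward
#'   scatter area/height.
#' @param threshold Ratio cut; doublet iff area/height > threshold.
#' @return Character vector in \code{\{"singlet", "doublet",
#'   "unclassifiable"\}} (the latter for non-positive or non-finite pulse
#'   heights, never silently dropped), with the threshold used attached as
#'   attribute \code{"threshold"}.
#' @export
classify_cluster <- function(events, area_channel = "FSC-A",
                             height_channel = "FSC-H", threshold = NULL) {
  assert_event_table(events, c(area_channel, height_channel))
  if (!is.null(threshold) && threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  a <- events[[area_channel]]
  h <- events[[height_channel]]
  ratio <- ifelse(is.finite(a) & is.finite(h) & h > 0, a / h, NA_real_)
  if (is.null(threshold)) threshold <- auto_ratio_threshold(ratio)
  out <- rep("unclassifiable", length(ratio))
  out[!is.na(ratio) & ratio <= threshold] <- "singlet"
  out[!is.na(ratio) & ratio > threshold] <- "doublet"
  attr(out, "threshold") <- threshold
  out
}

#' Automatic area/height threshold by valley finding
#'
#' Locates the density valley between the two dominant modes of
#' \code{log(ratio)}. Falls back to \code{default} when fewer than
#' \code{min_n} ratios are available or the distribution is effectively
#' unimodal (secondary mode below 1% of the main mode).
#'
#' @param ratio Numeric area/height ratios (NAs ignored).
#' @param default Fallback threshold; the geometric midpoint between a
#'   singlet ratio of 1 and the default doublet ratio 2/1.2.
#' @param min_n Minimum number of ratios for valley finding.
#' @return A single threshold on the ratio scale.
#' @export
auto_ratio_threshold <- function(ratio, default = sqrt(2 / 1.2),
                                 min_n = 50L) {
  r <- ratio[is.finite(ratio) & ratio > 0]
  if (length(r) < min_n) return(default)
  d <- stats::density(log(r), n = 512)
  y <- d$y
  is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  peaks <- which(is_max)
  peaks <- peaks[order(y[peaks], decreasing = TRUE)]
  # prune shoulder maxima: keep peaks carrying at least 1% of the top peak
  peaks <- peaks[y[peaks] >= 0.01 * y[peaks[1]]]
  if (length(peaks) < 2L) return(default)
  p1 <- min(peaks[1:2]); p2 <- max(peaks[1:2])
  valley <- p1 + which.min(y[p1:p2]) - 1L
  if (y[valley] > 0.5 * min(y[p1], y[p2])) return(default)
  exp(d$x[valley])
}

# --- shipped strategies ------------------------------------------------------

#' Gating strategy for the five-size bead mixture
#'
#' Hierarchy: (I) counting beads split from sizing beads on their high B610
#' emission; (II) among low-B530 ("small") beads, YG610 separates 3 um from
#' 7 um — the channel needed because 3 um doublets overlap 7 um singlets in
#' B530 alone; (III) 10/15/20 um resolved on B530 vs forward scatter; (IV) a
#' low-B530 clean-up gate refines the counting-bead leaf. Each size leaf is
#' further split into singlets and doublets by pulse processing at counting
#' time. Gate coordinates are fixture constants tuned once against the
#' default simulator signal models and versioned with them.
#'
#' @return A \code{\link{gating_tree}} with leaves \code{bead_3um},
#'   \code{bead_7um}, \code{bead_10um}, \code{bead_15um}, \code{bead_20um}
#'   and \code{accudrop}.
#' @export
build_bead_strategy <- function() {
  HI <- 1e9
  gates <- list(
    rectangle_gate("g_accudrop_hi_b610", "B610", "B530",
                   xmin = 3e4, xmax = HI, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_size_beads", "B610", "B530",
                   xmin = 1e-3, xmax = 3e4, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_accudrop_cleanup", "B530", "SSC-A",
                   xmin = 1e-3, xmax = 3e3, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_small_beads", "B530", "YG610",
                   xmin = 1e-3, xmax = 3e3, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_3um", "YG610", "B530",
                   xmin = 1e-3, xmax = 3e3, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_7um", "YG610", "B530",
                   xmin = 3e3, xmax = HI, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_large_beads", "B530", "YG610",
                   xmin = 3e3, xmax = HI, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_10um", "B530", "FSC-A",
                   xmin = 3e3, xmax = 3e4, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_15um", "B530", "FSC-A",
                   xmin = 3e4, xmax = 2.6e5, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_20um", "B530", "FSC-A",
                   xmin = 2.6e5, xmax = HI, ymin = 0, ymax = HI,
                   transform_x = "log10"))
  nodes <- data.frame(
    id = c("accudrop_hi", "accudrop", "beads", "small", "bead_3um",
           "bead_7um", "large", "bead_10um", "bead_15um", "bead_20um"),
    parent = c("root", "accudrop_hi", "root", "beads", "small", "small",
               "beads", "large", "large", "large"),
    gate = c("g_accudrop_hi_b610", "g_accudrop_cleanup", "g_size_beads",
             "g_small_beads", "g_3um", "g_7um", "g_large_beads",
             "g_10um", "g_15um", "g_20um"),
    label = c(NA, "accudrop", NA, NA, "bead_3um", "bead_7um", NA,
              "bead_10um", "bead_15um", "bead_20um"),
    stringsAsFactors = FALSE)
  gating_tree(gates, nodes)
}

#' Gating strategy for bead-spiked diluted blood
#'
#' Hierarchy: (I) counting beads out on high B610; (II) WBCs split from
#' everything else on R670 (CD45-APC) vs side scatter; (III) among
#' CD45-negative events, B530 separates unstained blood cells (RBC leaf)
#' from the fluorescent sizing beads, which are then resolved into 10/15/20
#' um exactly as in the bead-only strategy.
#'
#' @return A \code{\link{gating_tree}} with leaves \code{RBC}, \code{WBC},
#'   \code{bead_10um}, \code{bead_15um}, \code{bead_20um}, \code{accudrop}.
#' @export
build_blood_strategy <- function() {
  HI <- 1e9
  gates <- list(
    rectangle_gate("g_accudrop_hi_b610", "B610", "B530",
                   xmin = 3e4, xmax = HI, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_accudrop_cleanup", "B530", "SSC-A",
                   xmin = 1e-3, xmax = 3e3, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_not_accudrop", "B610", "B530",
                   xmin = 1e-3, xmax = 3e4, ymin = 1e-3, ymax = HI,
                   transform_x = "log10", transform_y = "log10"),
    rectangle_gate("g_wbc", "R670", "SSC-A",
                   xmin = 3e3, xmax = HI, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_cd45_neg", "R670", "SSC-A",
                   xmin = 1e-3, xmax = 3e3, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_rbc", "B530", "SSC-A",
                   xmin = 1e-3, xmax = 3e3, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_spiked_beads", "B530", "SSC-A",
                   xmin = 3e3, xmax = HI, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_10um", "B530", "FSC-A",
                   xmin = 3e3, xmax = 3e4, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_15um", "B530", "FSC-A",
                   xmin = 3e4, xmax = 2.6e5, ymin = 0, ymax = HI,
                   transform_x = "log10"),
    rectangle_gate("g_20um", "B530", "FSC-A",
                   xmin = 2.6e5, xmax = HI, ymin = 0, ymax = HI,
                   transform_x = "log10"))
  nodes <- data.frame(
    id = c("accudrop_hi", "accudrop", "cells_beads", "WBC", "cd45neg",
           "RBC", "beads", "bead_10um", "bead_15um", "bead_20um"),
    parent = c("root", "accudrop_hi", "root", "cells_beads", "cells_beads",
               "cd45neg", "cd45neg", "beads", "beads", "beads"),
    gate = c("g_accudrop_hi_b610", "g_accudrop_cleanup", "g_not_accudrop",
             "g_wbc", "g_cd45_neg", "g_rbc", "g_spiked_beads",
             "g_10um", "g_15um", "g_20um"),
    label = c(NA, "accudrop", NA, "WBC", NA, "RBC", NA,
              "bead_10um", "bead_15um", "bead_20um"),
    stringsAsFactors = FALSE)
  gating_tree(gates, nodes)
}

#' Count gated populations per outlet and cluster class
#'
#' Labels the events of each outlet with the gating tree and splits every
#' population leaf into singlets and doublets by pulse processing (per-leaf
#' automatic threshold unless one is given). \code{total} counts are
#' singlets + doublets + unclassifiable events (non-positive pulse heights),
#' so nothing is silently dropped. With \code{ground_truth_bypass = TRUE}
#' the simulator's labels replace gating entirely, providing the oracle
#' path.
#'
#' @param events_by_outlet Named list (\code{inner}, \code{outer}) of event
#'   tables, or of \code{acquisition_record}s.
#' @param tree A \code{\link{gating_tree}}.
#' @param area_channel,height_channel Pulse channels for the cluster split.
#' @param threshold Fixed area/height threshold; \code{NULL} for per-leaf
#'   automatic placement.
#' @param ground_truth_bypass Use simulator labels instead of gating.
#' @return A \code{count_matrix} (see \code{\link{count_matrix}}); ungated
#'   event counts per outlet are attached as attribute \code{"ungated"}.
#' @export
count_populations <- function(events_by_outlet, tree,
                              area_channel = "FSC-A",
                              height_channel = "FSC-H",
                              threshold = NULL,
                              ground_truth_bypass = FALSE) {
  events_by_outlet <- lapply(events_by_outlet, function(x) {
    if (inherits(x, "acquisition_record")) x$events else x
  })
  stopifnot(!is.null(names(events_by_outlet)))
  leaves <- tree_leaves(tree)
  rows <- list()
  ungated <- integer(length(events_by_outlet))
  names(ungated) <- names(events_by_outlet)
  for (outlet in names(events_by_outlet)) {
    ev <- events_by_outlet[[outlet]]
    if (ground_truth_bypass) {
      if (!all(c("population_id", "cluster_size") %in% names(ev)))
        stop("ground-truth bypass needs population_id and cluster_size",
             call. = FALSE)
      labels <- ifelse(ev$population_id %in% leaves, ev$population_id,
                       NA_character_)
    } else {
      labels <- label_events(ev, tree)
    }
    ungated[outlet] <- sum(is.na(labels))
    for (lf in leaves) {
      idx <- !is.na(labels) & labels == lf
      if (ground_truth_bypass) {
        cls <- ifelse(ev$cluster_size[idx] >= 2L, "doublet", "singlet")
        n_uncls <- 0L
      } else {
        cls <- classify_cluster(ev[idx, , drop = FALSE], area_channel,
                                height_channel, threshold)
        n_uncls <- sum(cls == "unclassifiable")
      }
      n_s <- sum(cls == "singlet")
      n_d <- sum(cls == "doublet")
      rows[[length(rows) + 1L]] <- data.frame(
        outlet = outlet, population = lf,
        class = c("singlet", "doublet", "total"),
        count = c(n_s, n_d, n_s + n_d + n_uncls),
        stringsAsFactors = FALSE)
    }
  }
  cm <- count_matrix(do.call(rbind, rows))
  attr(cm, "ungated") <- ungated
  cm
}

# --- gating strategy YAML ----------------------------------------------------

#' Read or write a gating strategy as YAML
#'
#' Schema: a \code{gates} sequence (id, type, channels, transforms and
#' either rectangle bounds or polygon vertices, all in raw units) and a
#' \code{tree} sequence of \code{\{id, parent, gate, label\}} nodes in
#' top-down order.
#'
#' @param path File path.
#' @param tree A \code{\link{gating_tree}}.
#' @return \code{read_gating_strategy}: a \code{gating_tree};
#'   \code{write_gating_strategy}: \code{path}, invisibly.
#' @export
read_gating_strategy <- function(path) {
  cfg <- yaml::read_yaml(path)
  gates <- lapply(cfg$gates, function(g) {
    if (g$type == "rectangle") {
      rectangle_gate(g$id, g$channel_x, g$channel_y,
                     g$xmin, g$xmax, g$ymin, g$ymax,
                     g$transform_x %||% "linear", g$transform_y %||% "linear")
    } else if (g$type == "polygon") {
      polygon_gate(g$id, g$channel_x, g$channel_y,
                   as.numeric(g$x), as.numeric(g$y),
                   g$transform_x %||% "linear", g$transform_y %||% "linear")
    } else {
      stop("unknown gate type '", g$type, "' in ", path, call. = FALSE)
    }
  })
  nodes <- do.call(rbind, lapply(cfg$tree, function(n) {
    data.frame(id = n$id, parent = n$parent, gate = n$gate,
               label = n$label %||% NA_character_, stringsAsFactors = FALSE)
  }))
  gating_tree(gates, nodes)
}

#' @rdname read_gating_strategy
#' @export
write_gating_strategy <- function(tree, path) {
  gates <- lapply(unname(tree$gates), function(g) {
    base <- list(id = g$id, type = g$type,
                 channel_x = g$channel_x, channel_y = g$channel_y,
                 transform_x = g$transform_x, transform_y = g$transform_y)
    if (g$type == "rectangle")
      c(base, list(xmin = g$xmin, xmax = g$xmax,
                   ymin = g$ymin, ymax = g$ymax))
    else c(base, list(x = g$x, y = g$y))
  })
  nodes <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    n <- as.list(tree$nodes[i, ])
    if (is.na(n$label)) n$label <- NULL
    n
  })
  yaml::write_yaml(list(gates = gates, tree = nodes), path)
  invisible(path)
}
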