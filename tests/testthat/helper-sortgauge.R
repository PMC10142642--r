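# Shared fixtures and independent oracles for the test suite.

# A single bead population with a simple channel model, handy for unit tests.
test_population <- function(name = "bead_15um", diameter = 15,
                            concentration = 5e4, doublet_fraction = 0.05,
                            b530 = 80000) {
  population_spec(
    name, "bead", diameter, concentration,
    sortgauge:::channel_model(
      diameter, list(B530 = b530, YG610 = 800, B610 = 200, R670 = 150)),
    doublet_fraction = doublet_fraction)
}

# Two-population mini mixture used for fast pipeline-level checks.
mini_mix <- function(doublet_fraction = 0.1, concentration = 2e4) {
  pops <- bead_mix_populations(doublet_fraction)[c("bead_10um", "bead_15um")]
  for (i in seq_along(pops)) pops[[i]]$concentration <- concentration
  pops
}

mini_scenario <- function() {
  device_scenario(0.9, data.frame(
    population = rep(c("bead_10um", "bead_15um"), each = 2),
    class = rep(c("singlet", "doublet"), 2),
    p_inner = c(0.463, 0.545, 0.507, 0.247)))
}

# Independent scalar point-in-polygon oracle: crossing number computed one
# point at a time, boundary points counted inside via segment distance.
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  point_on_segment <- function(x, y, x1, y1, x2, y2, eps = 1e-9) {
    d12 <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    d <- abs((x2 - x1) * (y1 - y) - (x1 - x) * (y2 - y1)) / max(d12, eps)
    within <- x >= min(x1, x2) - eps & x <= max(x1, x2) + eps &
      y >= min(y1, y2) - eps & y <= max(y1, y2) + eps
    d <= eps * (1 + d12) & within
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (point_on_segment(x, y, vx[i], vy[i], vx[j], vy[j])) return(TRUE)
      if ((vy[i] > y) != (vy[j] > y)) {
        xint <- vx[i] + (y - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, TRUE)
}

# Ground-truth SE tally straight from labeled events (bypasses counting and
# correction code entirely).
truth_se <- function(inner, outer, population, class) {
  pick <- function(ev) {
    cls <- ifelse(ev$cluster_size >= 2L, "doublet", "singlet")
    if (class == "total") sum(ev$population_id == population)
    else sum(ev$population_id == population & cls == class)
  }
  n_i <- pick(inner); n_o <- pick(outer)
  if (n_i + n_o == 0) return(NA_real_)
  100 * n_i / (n_i + n_o)
}

# 3-standard-error binomial tolerance, in percent, around proportion p.
binom_tol <- function(p, n) 3 * 100 * sqrt(p * (1 - p) / n)
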