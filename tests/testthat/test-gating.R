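# Geometric gates, the hierarchical strategies and pulse-processing
# singlet/doublet classification.

test_that("a rectangle covering the data range keeps every event", {
  ev <- sample_events(list(test_population()), volume = 0.01, seed = 1)
  g <- rectangle_gate("all", "FSC-A", "SSC-A", 0, 1e12, 0, 1e12)
  expect_true(all(apply_gate(ev, g)))
})

test_that("polygon membership matches a brute-force oracle", {
  withr::local_seed(42)
  # a concave, irregular polygon
  vx <- c(0.1, 0.9, 0.8, 0.5, 0.6, 0.2)
  vy <- c(0.1, 0.2, 0.9, 0.4, 0.8, 0.7)
  ev <- data.frame(`FSC-A` = runif(1000), `SSC-A` = runif(1000),
                   check.names = FALSE)
  g <- polygon_gate("poly", "FSC-A", "SSC-A", vx, vy)
  expect_identical(apply_gate(ev, g),
                   pip_oracle(ev$`FSC-A`, ev$`SSC-A`, vx, vy))
  # and for the unit square specifically, including boundary points
  sq <- polygon_gate("sq", "FSC-A", "SSC-A", c(0, 1, 1, 0), c(0, 0, 1, 1))
  pts <- data.frame(`FSC-A` = c(runif(500), 0, 1, 0.5, 0.5),
                    `SSC-A` = c(runif(500), 0, 1, 0, 1),
                    check.names = FALSE)
  expect_identical(apply_gate(pts, sq),
                   pip_oracle(pts$`FSC-A`, pts$`SSC-A`,
                              c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_true(all(tail(apply_gate(pts, sq), 4)))  # boundary is inside
})

test_that("gate edge cases: boundaries inside, log axis drops <= 0", {
  ev <- data.frame(B530 = c(10, 100, 0, -5, 1000),
                   `SSC-A` = c(5, 5, 5, 5, 5), check.names = FALSE)
  g <- rectangle_gate("r", "B530", "SSC-A", 10, 1000, 0, 10,
                      transform_x = "log10")
  expect_identical(apply_gate(ev, g), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_error(apply_gate(ev, rectangle_gate("r2", "YG610", "SSC-A",
                                             0, 1, 0, 1)), "YG610")
  expect_error(rectangle_gate("bad", "B530", "SSC-A", 10, 1, 0, 1),
               "ordered")
  expect_error(polygon_gate("selfx", "B530", "SSC-A",
                            c(0, 1, 1, 0), c(0, 1, 0, 1)),
               "self-intersecting")
})

test_that("gate masks are permutation invariant", {
  ev <- sample_events(bead_mix_populations(), volume = 5e-4, seed = 14)
  g <- rectangle_gate("r", "B530", "YG610", 3e3, 1e9, 1e-3, 1e9,
                      transform_x = "log10", transform_y = "log10")
  m <- apply_gate(ev, g)
  perm <- sample(nrow(ev))
  expect_identical(apply_gate(ev[perm, ], g), m[perm])
})

test_that("area = height means singlet for any threshold above 1", {
  ev <- data.frame(`FSC-A` = c(5, 10, 20), `FSC-H` = c(5, 10, 20),
                   check.names = FALSE)
  cls <- classify_cluster(ev, threshold = 1.05)
  expect_true(all(cls == "singlet"))
})

test_that("zero pulse heights are flagged unclassifiable, not dropped", {
  ev <- data.frame(`FSC-A` = c(10, 10), `FSC-H` = c(0, 10),
                   check.names = FALSE)
  cls <- classify_cluster(ev, threshold = 1.3)
  expect_identical(as.character(cls), c("unclassifiable", "singlet"))
})

test_that("pulse processing separates simulated doublets at >= 99% accuracy", {
  ev <- sample_events(list(test_population(doublet_fraction = 0.05,
                                           concentration = 2e5)),
                      volume = 0.05, seed = 23)
  cls <- classify_cluster(ev)
  truth <- ifelse(ev$cluster_size == 2L, "doublet", "singlet")
  expect_gt(mean(cls == truth), 0.99)
  expect_gt(attr(cls, "threshold"), 1.05)
  expect_lt(attr(cls, "threshold"), 1.6)
})

test_that("the automatic threshold falls back sensibly when unimodal", {
  ev <- sample_events(list(test_population(doublet_fraction = 0)),
                      volume = 0.05, seed = 24)
  thr <- auto_ratio_threshold(ev$`FSC-A` / ev$`FSC-H`)
  expect_equal(thr, sqrt(2 / 1.2))
})

test_that("doublet gating works for every size in the five-bead mixture", {
  ev <- sample_events(bead_mix_populations(0.05), volume = 5e-3, seed = 25)
  tree <- build_bead_strategy()
  labels <- label_events(ev, tree)
  for (leaf in c("bead_3um", "bead_7um", "bead_10um", "bead_15um",
                 "bead_20um")) {
    sub <- ev[!is.na(labels) & labels == leaf, ]
    cls <- classify_cluster(sub)
    truth <- ifelse(sub$cluster_size == 2L, "doublet", "singlet")
    expect_gt(mean(cls == truth), 0.98)
  }
})

test_that("bead strategy recovers every population on the mixture fixture", {
  ev <- sample_events(bead_mix_populations(), volume = 0.01, seed = 26)
  srt <- sort_events(ev, flow_rate_scenario(0.8), seed = 26)
  acq <- spike_and_acquire(srt$inner, srt$outer, srt$volumes, 20000,
                           seed = 26)
  all_events <- rbind(acq$inner$events, acq$outer$events)
  tree <- build_bead_strategy()
  v <- validate_tree(all_events, tree)
  expect_equal(v$n_multi_leaf, 0L)
  expect_true(all(v$leaf_stats$recovery >= 0.95))
  expect_true(all(v$leaf_stats$contamination <= 0.02))
  # counting-bead capture through the gate hierarchy
  acc <- v$leaf_stats[v$leaf_stats$leaf == "accudrop", ]
  expect_gte(acc$recovery, 0.99)
})

test_that("an empty event table yields zero counts in every leaf", {
  ev <- sample_events(bead_mix_populations(), volume = 1e-4, seed = 1)[0, ]
  cm <- count_populations(list(inner = ev, outer = ev),
                          build_bead_strategy())
  expect_true(all(cm$count == 0))
  expect_equal(nrow(cm), 2 * 6 * 3)
})

test_that("blood strategy separates cells, beads and counting beads", {
  pops <- blood_populations(dilution = 25)  # desk-scale blood fixture
  ev <- sample_events(pops, volume = 0.01, seed = 27)
  srt <- sort_events(ev, blood_scenario("zigzag"), seed = 27)
  acq <- spike_and_acquire(srt$inner, srt$outer, srt$volumes, 10000,
                           seed = 27)
  all_events <- rbind(acq$inner$events, acq$outer$events)
  tree <- build_blood_strategy()
  v <- validate_tree(all_events, tree)
  wbc <- v$leaf_stats[v$leaf_stats$leaf == "WBC", ]
  expect_lte(wbc$contamination, 0.02)  # WBC leaf purity >= 98%
  expect_gte(wbc$recovery, 0.95)
  # rare 15 um beads recovered from the cell background
  b15 <- v$leaf_stats[v$leaf_stats$leaf == "bead_15um", ]
  expect_gte(b15$recovery, 0.95)
  expect_gt(sum(all_events$population_id == "bead_15um"), 30)
})

test_that("bead leaves stay empty when no beads are present", {
  pops <- blood_populations(dilution = 100)[c("RBC", "WBC")]
  ev <- sample_events(pops, volume = 0.005, seed = 28)
  cm <- count_populations(list(inner = ev[0, ], outer = ev),
                          build_blood_strategy())
  bead_rows <- grepl("^bead_", cm$population)
  expect_true(all(cm$count[bead_rows] == 0))
})

test_that("counts equal brute-force recomposition of each gate chain", {
  ev <- sample_events(bead_mix_populations(), volume = 2e-3, seed = 29)
  tree <- build_bead_strategy()
  cm <- count_populations(list(inner = ev, outer = ev[0, ]), tree)
  # recompose root-to-leaf chains by hand
  chain_mask <- function(leaf_id) {
    mask <- rep(TRUE, nrow(ev))
    id <- leaf_id
    while (id != "root") {
      node <- tree$nodes[tree$nodes$id == id, ]
      mask <- mask & apply_gate(ev, tree$gates[[node$gate]])
      id <- node$parent
    }
    mask
  }
  for (i in which(!is.na(tree$nodes$label))) {
    leaf <- tree$nodes$label[i]
    n_leaf <- sum(chain_mask(tree$nodes$id[i]))
    tot <- cm$count[cm$outlet == "inner" & cm$population == leaf &
                      cm$class == "total"]
    expect_equal(tot, n_leaf)
  }
  # conservation: gated events never exceed the total
  tot_gated <- sum(cm$count[cm$outlet == "inner" & cm$class == "total"])
  expect_lte(tot_gated, nrow(ev))
  expect_equal(tot_gated + attr(cm, "ungated")[["inner"]], nrow(ev))
  # and the per-population counts track ground truth within 5%
  truth <- table(ev$population_id)
  for (p in names(truth)) {
    tot <- cm$count[cm$outlet == "inner" & cm$population == p &
                      cm$class == "total"]
    expect_lt(abs(tot - truth[[p]]) / truth[[p]], 0.05)
  }
})

test_that("gating strategies survive a YAML round trip", {
  tree <- build_bead_strategy()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gating_strategy(tree, path)
  back <- read_gating_strategy(path)
  ev <- sample_events(bead_mix_populations(), volume = 5e-4, seed = 30)
  expect_identical(label_events(ev, back), label_events(ev, tree))
})
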