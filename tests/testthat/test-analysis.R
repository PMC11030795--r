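# Post-run statistics: cytotoxicity, growth fits, neighborhood analysis,
# event-log reconciliation, snapshot rendering.

fakeTraj <- function(time_h, neg, pos = 0 * neg) {
  structure(list(summary = data.frame(time_h = time_h, tumor_PDL1neg = neg,
                                      tumor_PDL1pos = pos),
                 events = data.frame(time_h = numeric(), kind = character(),
                                     class = character(), id = numeric(),
                                     parent = numeric(), cause = character())),
            class = "simTrajectory")
}

test_that("cytotoxicity is an alive-count ratio: zero against itself, scale-invariant", {
  tt <- seq(0, 12, by = 3)
  ctrl <- fakeTraj(tt, c(1000, 1200, 1500, 1800, 2000))
  expect_true(all(cytotoxicity(ctrl, ctrl)$cytotoxicity == 0))
  trt <- fakeTraj(tt, c(1000, 900, 850, 820, 800))
  cs <- cytotoxicity(trt, ctrl)
  expect_equal(cs$cytotoxicity[5], 1 - 800 / 2000)  # A_C 2000, A_T 800 -> 0.6
  scaled <- cytotoxicity(fakeTraj(tt, 3 * trt$summary$tumor_PDL1neg),
                         fakeTraj(tt, 3 * ctrl$summary$tumor_PDL1neg))
  expect_equal(scaled$cytotoxicity, cs$cytotoxicity)
  # replicate averaging and grid checks
  cs2 <- cytotoxicity(list(trt, trt), list(ctrl, ctrl))
  expect_equal(cs2$cytotoxicity, cs$cytotoxicity)
  expect_error(cytotoxicity(trt, fakeTraj(tt + 1, ctrl$summary$tumor_PDL1neg)),
               "mismatched emit grids")
})

test_that("growth-rate fit recovers an exact exponential and the quiescent decay", {
  tt <- seq(0, 48, by = 1.5)
  r <- 0.0238
  d <- data.frame(time_h = tt, count = 1200 * exp(r * tt))
  expect_lt(abs(fitGrowthRate(d) - r), 1e-6)
  expect_lt(abs(fitGrowthRate(d, window = c(12, 36)) - r), 1e-6)
  # quiescent-only population decays at about the intrinsic death hazard
  cfg <- tinyConfig()
  cfg$experiment$n_tcell <- 0
  cfg$experiment$n_tumor <- 500
  cfg$experiment$frac_pdl1_pos <- 1
  tr <- runExperiment(cfg, seed = 8, duration_h = 36)
  expect_lt(abs(fitGrowthRate(tr) - (-cfg$tumor$intrinsic_death_per_h)),
            1.5e-3)
})

test_that("knn windows: one-hot for uniform labels; equals brute-force oracle", {
  set.seed(21)
  x <- runif(60, 0, 100); y <- runif(60, 0, 100)
  one <- knnWindows(x, y, rep("a", 60), k = 10)
  expect_true(all(one[, "a"] == 1))
  # 12-point hand-constructed configuration on a grid
  gx <- rep(1:4, 3) * 10; gy <- rep(1:3, each = 4) * 10
  lab <- rep(c("t", "u"), 6)
  expect_equal(knnWindows(gx, gy, lab, k = 5),
               bruteKnn(gx, gy, lab, k = 5))
  expect_equal(knnWindows(gx, gy, lab, k = 5, include_self = FALSE),
               bruteKnn(gx, gy, lab, k = 5, include_self = FALSE))
  expect_error(knnWindows(1:3, 1:3, c("a", "a", "b"), k = 10),
               "fewer than k")
})

test_that("knn windows equal the brute-force oracle on random instances up to n = 500", {
  set.seed(33)
  for (n in c(60, 200, 500)) {
    x <- runif(n, 0, 300); y <- runif(n, 0, 300)
    lab <- sample(c("tumor_neg", "tumor_pos", "tcell"), n, replace = TRUE)
    expect_equal(knnWindows(x, y, lab, k = 10), bruteKnn(x, y, lab, k = 10))
  }
  # rows are fractions over the label alphabet summing to one
  comp <- knnWindows(runif(50), runif(50), sample(letters[1:4], 50, TRUE),
                     k = 10)
  expect_true(all(abs(rowSums(comp) - 1) < 1e-12))
})

test_that("two separated pure-label blobs give two distinct window patterns", {
  x <- c(runif(30, 0, 10), runif(30, 100, 110))
  y <- runif(60, 0, 10)
  lab <- rep(c("a", "b"), each = 30)
  comp <- knnWindows(x, y, lab, k = 10)
  expect_true(all(comp[1:30, "a"] == 1))
  expect_true(all(comp[31:60, "b"] == 1))
})

test_that("neighborhood clustering recovers well-separated composition groups exactly", {
  set.seed(12)
  centers <- diag(5)
  comp <- do.call(rbind, lapply(1:5, function(k)
    matrix(rep(centers[k, ], 40), 40, byrow = TRUE) +
      matrix(runif(200, 0, 0.02), 40)))
  truth <- rep(1:5, each = 40)
  res <- clusterNeighborhoods(comp, n_clusters = 5, seed = 3)
  expect_equal(adjustedRand(res$labels, truth), 1)
  # duplicate rows share labels
  dup <- rbind(comp, comp[1, , drop = FALSE])
  res2 <- clusterNeighborhoods(dup, n_clusters = 5, seed = 3)
  expect_equal(res2$labels[nrow(dup)], res2$labels[1])
  expect_error(clusterNeighborhoods(comp[1:3, ], n_clusters = 5), "fewer rows")
})

test_that("alive counts reconcile with the event log (births minus deaths)", {
  cfg <- tinyConfig()
  tr <- runExperiment(cfg, seed = 6, duration_h = 6)
  s <- tr$summary
  for (cls in c("tumors", "tcells")) {
    alive <- if (cls == "tumors") s$tumor_PDL1neg + s$tumor_PDL1pos
             else s$tcell_PD1neg + s$tcell_PD1pos
    for (i in seq_len(nrow(s))) {
      ev <- tr$events[tr$events$class == cls &
                        tr$events$time_h <= s$time_h[i] + 1e-9, ]
      expect_equal(alive[i],
                   alive[1] + sum(ev$kind == "division") -
                     sum(ev$kind == "death"))
    }
  }
  # death accounting by cause is non-negative and cumulative
  cbp <- countsByPhenotype(tr)
  expect_true(all(cbp$alive >= 0))
  expect_true(all(diff(cbp$deaths_cytotoxic[cbp$class == "tumors" &
                                            cbp$phenotype == "PDL1neg"]) >= 0))
})

test_that("phenotype transitions are one-way in simulation output", {
  cfg <- tinyConfig()
  cfg$tcell$p_max <- 1            # provoke engagements and transitions
  tr <- runExperiment(cfg, seed = 9, duration_h = 6, emit_interval_h = 0.5,
                      record_agents = TRUE)
  track <- function(store, pos) {
    seen <- list()
    for (snap in tr$snapshots) {
      tab <- snap$stores[[store]]
      for (i in seq_along(tab$id)) {
        id <- as.character(tab$id[i])
        now <- tab$phenotype[i] == pos
        if (!is.null(seen[[id]]) && seen[[id]] && !now) return(FALSE)
        seen[[id]] <- now
      }
    }
    TRUE
  }
  expect_true(track("agents/tumors", "PDL1pos"))
  expect_true(track("agents/tcells", "PD1pos"))
})

test_that("snapshot rendering reports counts and a full color key", {
  cfg <- tinyConfig()
  tr <- runExperiment(cfg, seed = 2, duration_h = 1, emit_interval_h = 0.5)
  png_path <- file.path(tempdir(), "snap.png")
  meta <- renderSnapshot(tr$final_state, file = png_path)
  expect_true(file.exists(png_path))
  expect_equal(meta$n_agents, length(tr$final_state$space$id))
  expect_length(meta$colors, 5L)  # 2 T cell + 2 tumor phenotypes + DC
})
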