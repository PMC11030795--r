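# Initializers, synthetic imaging tables, configuration, reproducibility.

test_that("tumor-bed initialization places classes, phenotypes, and positions as configured", {
  cfg <- tinyConfig()
  cfg$experiment$n_tumor <- 1200 / 8
  cfg$experiment$n_tcell <- 12
  cfg$experiment$frac_pd1_pos <- 0.25
  set.seed(1)
  st <- initTumorBed(cfg)
  tc <- st$agents$tcells
  expect_length(tc$id, 12L)
  expect_equal(sum(tc$phenotype == "PD1pos"), 3L)   # nearest-integer rounding
  expect_equal(sum(tc$phenotype == "PD1neg"), 9L)
  expect_length(st$agents$tumors$id, 150L)
  # all tumors inside the bed (up to relaxation slack)
  sp <- st$space
  ctr <- cfg$environment$bed_center_um
  d <- sqrt((sp$x - ctr[1])^2 + (sp$y - ctr[2])^2)
  tum <- sp$class == "tumors"
  expect_true(all(d[tum] <= cfg$environment$bed_radius_um + 25))
  # outside placement: zero T cells inside the bed at t = 0
  cfg$experiment$placement <- "outside"
  set.seed(1)
  st2 <- initTumorBed(cfg)
  sp2 <- st2$space
  d2 <- sqrt((sp2$x - ctr[1])^2 + (sp2$y - ctr[2])^2)
  expect_true(all(d2[sp2$class == "tcells"] > cfg$environment$bed_radius_um))
  # over-packed bed is rejected
  cfg$experiment$n_tumor <- 5000
  expect_error(initTumorBed(cfg), "packing limit")
})

test_that("in vitro initialization preserves the effector:target ratio and phenotype mix", {
  cfg <- tinyConfig()
  cfg$experiment$mode <- "in_vitro"
  cfg$experiment$n_tumor <- 120
  cfg$experiment$n_tcell <- 120
  cfg$experiment$frac_pdl1_pos <- 1
  set.seed(2)
  st <- initInVitro(cfg)
  expect_length(st$agents$tcells$id, 120L)
  expect_length(st$agents$tumors$id, 120L)
  expect_true(all(st$agents$tumors$phenotype == "PDL1pos"))
  expect_true(all(st$agents$tumors$mhc == cfg$tumor$levels$pos$mhc))
  cfg$experiment$frac_pdl1_pos <- 0
  set.seed(2)
  expect_true(all(initInVitro(cfg)$agents$tumors$phenotype == "PDL1neg"))
})

test_that("synthetic imaging tables honor fractions and are seed-reproducible", {
  t1 <- synthCodex(2000, tumor_fraction = 0.95, frac_pd1_pos = 0.25, seed = 5)
  t2 <- synthCodex(2000, tumor_fraction = 0.95, frac_pd1_pos = 0.25, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, synthCodex(2000, seed = 6)))
  expect_true(all(synthCodex(300, tumor_fraction = 1,
                             other_fraction = 0)$cell_type == "tumor"))
})

test_that("imaging import round-trips the synthetic table within sampling error", {
  tab <- synthCodex(2000, tumor_fraction = 0.9, frac_pd1_pos = 0.25,
                    frac_pdl1_pos = 0.3, seed = 7)
  cfg <- defaultParams()
  ini <- suppressMessages(initFromCodex(tab, cfg))
  st <- ini$state
  n_t <- sum(tab$cell_type == "tcell")
  n_m <- sum(tab$cell_type == "tumor")
  expect_length(st$agents$tcells$id, n_t)
  expect_length(st$agents$tumors$id, n_m)
  expect_equal(attr(st, "dropped"), sum(tab$cell_type == "stroma"))
  gated_pd1 <- mean(st$agents$tcells$phenotype == "PD1pos")
  expect_lt(abs(gated_pd1 - 0.25), 3 * sqrt(0.25 * 0.75 / n_t))
  gated_pdl1 <- mean(st$agents$tumors$phenotype == "PDL1pos")
  expect_lt(abs(gated_pdl1 - 0.3), 3 * sqrt(0.3 * 0.7 / n_m))
})

test_that("imaging import validates inputs and defaults below-gate cells to negative", {
  cfg <- defaultParams()
  tab <- data.frame(cell_id = 1, x = 10, y = 20, cell_type = "tcell",
                    PD1 = 50, PDL1 = 0, MHCI = 0, Ki67 = 0)
  ini <- initFromCodex(tab, cfg, gates = list(PD1 = 5, PDL1 = 5, MHCI = 5))
  expect_equal(ini$state$agents$tcells$phenotype, "PD1pos")
  expect_equal(ini$state$space$x[1], 0)  # translated to the region origin
  expect_error(initFromCodex(tab[, -5], cfg), "missing required columns")
  expect_error(initFromCodex(tab, cfg, region = c(100, 200, 100, 200)),
               "empty region")
  zero <- synthCodex(400, seed = 1)
  zero$PD1 <- 0; zero$PDL1 <- 0; zero$MHCI <- 0
  st0 <- suppressMessages(initFromCodex(zero, cfg))$state
  expect_true(all(st0$agents$tcells$phenotype == "PD1neg"))
  expect_true(all(st0$agents$tumors$phenotype == "PDL1neg"))
})

test_that("configuration validation names the missing block and rejects bad values", {
  expect_error(validateConfig(list(engine = list())), "tcell|environment")
  cfg <- defaultParams()
  cfg$experiment$frac_pd1_pos <- 1.5
  expect_error(validateConfig(cfg), "frac_pd1_pos")
  cfg <- defaultParams()
  cfg$tcell$pd1neg$ifng_ng_per_h <- 0
  expect_error(validateConfig(cfg), "secretion")
  expect_error(loadConfig("no-such-config"), "not found")
})

test_that("packaged experiment configs load, validate, and cover the canonical designs", {
  dir <- system.file("configs", package = "tmesim")
  files <- list.files(dir, pattern = "[.]yaml$")
  expect_true(length(files) >= 8)
  for (f in files) {
    cfg <- loadConfig(file.path(dir, f))
    expect_true(is.list(cfg$experiment))
  }
  c25 <- loadConfig("adoptive_25pd1")
  expect_equal(c25$experiment$n_tumor, 1200)
  expect_equal(c25$experiment$n_tcell, 12)
  expect_equal(c25$experiment$frac_pd1_pos, 0.25)
  expect_false(loadConfig("no_ln_25pd1")$lymph_node$enabled)
  expect_true(loadConfig("ln_25pd1")$lymph_node$enabled)
  expect_equal(loadConfig("outside_bed_25pd1")$experiment$placement, "outside")
  expect_equal(loadConfig("invitro_pretreated")$experiment$frac_pdl1_pos, 1)
})

test_that("identical seeds give identical trajectories; different seeds differ", {
  cfg <- tinyConfig()
  cfg$experiment$duration_h <- 2
  a <- runExperiment(cfg, seed = 4, duration_h = 2)
  b <- runExperiment(cfg, seed = 4, duration_h = 2)
  expect_identical(a$summary, b$summary)
  expect_identical(a$events, b$events)
  expect_identical(a$final_state$space, b$final_state$space)
  d <- runExperiment(cfg, seed = 5, duration_h = 2)
  expect_false(identical(a$summary, d$summary))
})

test_that("sweeps produce one trajectory per seed and serialize round-trip", {
  cfg <- tinyConfig()
  cfg$experiment$replicates <- 3
  trs <- runSweep(cfg, duration_h = 0.5, emit_interval_h = 0.25)
  expect_length(trs, 3L)
  expect_equal(sapply(trs, function(t) t$seed), cfg$experiment$seed + 0:2)
  dir <- file.path(tempdir(), "tmesim-io-test")
  paths <- writeTrajectory(trs[[1]], dir, prefix = "rep1")
  expect_true(all(file.exists(paths)))
  counts <- readTrajectoryCounts(file.path(dir, "rep1_counts.csv"))
  expect_equal(sort(unique(counts$class)), c("tcells", "tumors"))
  expect_equal(nrow(counts), 3 * 4)  # 3 emit times x 4 class-phenotypes
})

test_that("the full wiring composes 5 processes with the LN, 4 without", {
  cfg <- tinyConfig()
  set.seed(1)
  comp4 <- buildComposite(cfg, initTumorBed(cfg), run_seed = 1)
  expect_named(comp4$processes, c("neighbors", "tcell", "tumor", "diffusion"))
  cfg$lymph_node$enabled <- TRUE
  set.seed(1)
  comp5 <- buildComposite(cfg, initTumorBed(cfg), run_seed = 1)
  expect_length(comp5$processes, 5L)
  expect_true("lymph_node" %in% names(comp5$processes))
  # every port of every process resolves in the state tree
  for (nm in names(comp5$processes)) {
    for (port in comp5$processes[[nm]]$ports) {
      path <- comp5$topology[[nm]][[port]]
      expect_false(is.null(tmesim:::getPath(comp5$state, path)))
    }
  }
})
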