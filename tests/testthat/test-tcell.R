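# T cell process: engagement, secretion, packets, exhaustion, checkpoint
# apoptosis, phenotype one-wayness.

# construct a minimal view for the T cell process: one T cell, optionally in
# contact with one tumor cell
tcellView <- function(cfg, phen = "PD1neg", tumor_phen = "PDL1pos",
                      contact = TRUE, engaged = FALSE, tcr = 1) {
  tc <- tmesim:::newTcellTable(1, phen)
  tc$tcr <- tcr
  tum <- tmesim:::newTumorTable(2, tumor_phen, cfg)
  if (engaged) {
    tc$engaged_with <- 2
    tc$act_clock_h <- cfg$tcell$activation_h
  }
  field <- makeField(cfg$environment)
  list(tcells = tc, tumors = tum,
       contacts = if (contact) list(i_id = 1, j_id = 2, dist = 15)
                  else list(i_id = numeric(0), j_id = numeric(0),
                            dist = numeric(0)),
       space = list(id = c(1, 2), class = c("tcells", "tumors"),
                    x = c(100, 114), y = c(100, 100), radius = c(5, 10),
                    heading = c(0, 0), speed = c(0, 0), mv_count = c(0, 0)),
       field = field)
}

test_that("no contacts: no packets, no secretion without activation", {
  cfg <- defaultParams()
  p <- tcellProcess(cfg, run_seed = 1)
  upd <- p$update(tcellView(cfg, contact = FALSE), 60)
  expect_null(upd$packets)
  expect_null(upd$secretion)
  expect_true(is.na(upd$tcells$x$engaged_with))
})

test_that("engaged cell delivers rate*dt packets and secretes rate*dt IFNg locally", {
  cfg <- defaultParams()
  p <- tcellProcess(cfg, run_seed = 1)
  v <- tcellView(cfg, engaged = TRUE, tumor_phen = "PDL1neg")
  upd <- p$update(v, 60)
  expect_equal(upd$packets$x$id, 2)
  expect_equal(upd$packets$x$n, cfg$tcell$pd1neg$packets_per_min * 1)
  m <- upd$secretion$x
  expect_equal(sum(m), cfg$tcell$pd1neg$ifng_ng_per_h / 60)
  expect_equal(which(m > 0), posToBin(100, 100, v$field))
  expect_equal(upd$tcells$x$cum_eng_h, 1 / 60)
})

test_that("PD-1/PD-L1 inhibition needs both receptor and ligand", {
  cfg <- defaultParams()
  p <- tcellProcess(cfg, run_seed = 1)
  inh <- cfg$tcell$pd1_pdl1$inhibition
  pk <- function(phen, tum)
    p$update(tcellView(cfg, phen = phen, tumor_phen = tum,
                       engaged = TRUE), 60)$packets$x$n
  expect_equal(pk("PD1neg", "PDL1pos"), 4)          # receptor absent
  expect_equal(pk("PD1pos", "PDL1neg"), 3)          # ligand absent
  expect_equal(pk("PD1pos", "PDL1pos"), 3 * inh)    # both present
})

test_that("engagement probability: mhc and tcr gate recognition", {
  expect_equal(engagementProbability(0, 1, 1), 0)
  expect_equal(engagementProbability(1, 0, 1), 0)
  expect_equal(engagementProbability(1, 1, 1), 1)
  cfg <- defaultParams()
  cfg$tcell$p_max <- 1
  p <- tcellProcess(cfg, run_seed = 1)
  # p = 1, mhc = 1, tcr = 1: always engage on contact
  upd <- p$update(tcellView(cfg, tumor_phen = "PDL1pos"), 60)
  expect_equal(upd$tcells$x$engaged_with, 2)
  # activation window opened this step (already decremented by one step)
  expect_equal(upd$tcells$x$act_clock_h, cfg$tcell$activation_h - 1 / 60)
  # fully downregulated TCR: never engage
  upd <- p$update(tcellView(cfg, tumor_phen = "PDL1pos", tcr = 0), 60)
  expect_true(is.na(upd$tcells$x$engaged_with))
})

test_that("completed kill increments stimulation, downregulates TCR, starts refractory", {
  cfg <- defaultParams()
  p <- tcellProcess(cfg, run_seed = 1)
  v <- tcellView(cfg, engaged = TRUE)
  v$tumors <- tmesim:::emptyTbl(c(id = "numeric"))  # target died
  v$tumors <- tmesim:::newTumorTable(numeric(0), character(0), cfg)
  upd <- p$update(v, 60)
  t1 <- upd$tcells$x
  expect_true(is.na(t1$engaged_with))
  expect_equal(t1$stim_count, 1L)
  expect_equal(t1$tcr, 1 - cfg$tcell$tcr_down_frac, tolerance = 1e-3)
  expect_equal(t1$refr_clock_h, cfg$tcell$refractory_h)
})

test_that("stale contact force-ends engagement without reward", {
  cfg <- defaultParams()
  p <- tcellProcess(cfg, run_seed = 1)
  v <- tcellView(cfg, engaged = TRUE, contact = FALSE)  # target alive, apart
  upd <- p$update(v, 60)
  t1 <- upd$tcells$x
  expect_true(is.na(t1$engaged_with))
  expect_equal(t1$stim_count, 0L)
  expect_equal(t1$stale_count, 1L)
})

test_that("exhaustion: timer fires exactly at the threshold and is one-way", {
  th <- 8
  expect_false(any(checkExhaustion(c(0, 7.99), engaged = c(TRUE, TRUE),
                                   dt_h = 1 / 60, threshold_h = th)))
  expect_true(all(checkExhaustion(c(8, 9), engaged = c(FALSE, TRUE),
                                  dt_h = 1 / 60, threshold_h = th)))
})

test_that("probabilistic exhaustion: mean engaged time to transition ~ threshold", {
  th <- 8; dt <- 1 / 60; n <- 10000
  p <- 1 - exp(-dt / th)
  set.seed(1)
  # geometric waiting time oracle for the per-step hazard
  steps <- rgeom(n, p) + 1
  t_mc <- mean(steps) * dt
  se <- sd(steps * dt) / sqrt(n)
  expect_lt(abs(t_mc - (th + dt / 2)), 2 * se + dt)
  # and the per-step rule itself fires with the right probability
  u <- runif(1e5)
  frac <- mean(checkExhaustion(rep(0, 1e5), rep(TRUE, 1e5), dt, th,
                               mode = "probabilistic", u = u))
  expect_lt(abs(frac - p), 3 * sqrt(p / 1e5))
})

test_that("checkpoint apoptosis matches the exponential survival oracle", {
  h <- 0.05; dt_h <- 1 / 60; t_end <- 10; n <- 10000
  p_step <- 1 - exp(-h * dt_h)
  set.seed(2)
  alive <- rep(TRUE, n)
  for (s in seq_len(t_end / dt_h)) {
    die <- alive & runif(n) < p_step
    alive[die] <- FALSE
  }
  frac <- 1 - mean(alive)
  expected <- 1 - exp(-h * t_end)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 2 * se + 1e-3)
})

test_that("secretion ordering: PD-1- output exceeds PD-1+ under identical engagement", {
  cfg <- defaultParams()
  p <- tcellProcess(cfg, run_seed = 1)
  s_neg <- sum(p$update(tcellView(cfg, "PD1neg", "PDL1neg",
                                  engaged = TRUE), 60)$secretion$x)
  s_pos <- sum(p$update(tcellView(cfg, "PD1pos", "PDL1neg",
                                  engaged = TRUE), 60)$secretion$x)
  expect_gt(s_neg, s_pos)
})

test_that("probabilistic refractory mode yields a smoother exhaustion curve", {
  th <- 8; dt <- 1 / 60; n <- 2000
  # timer: all continuously engaged cells flip in the same step
  flips_timer <- rep(th, n)
  set.seed(5)
  flips_prob <- (rgeom(n, 1 - exp(-dt / th)) + 1) * dt
  per_hour <- function(t) max(tabulate(floor(t) + 1))
  expect_lt(per_hour(flips_prob), per_hour(flips_timer))
})
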