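# Initializers for the canonical experiment designs, imaging-table import,
# synthetic fixture generation, composite wiring, and run drivers.

# ---- placement helpers -----------------------------------------------------

#' @keywords internal
uniformDisc <- function(n, center, R) {
  r <- R * sqrt(stats::runif(n))
  a <- 2 * pi * stats::runif(n)
  list(x = center[1] + r * cos(a), y = center[2] + r * sin(a))
}

#' @keywords internal
uniformOutsideDisc <- function(n, env, center, R) {
  x <- y <- numeric(n)
  got <- 0L
  while (got < n) {
    cx <- stats::runif(n, 0, env$width_um)
    cy <- stats::runif(n, 0, env$height_um)
    ok <- (cx - center[1])^2 + (cy - center[2])^2 > R^2
    take <- min(n - got, sum(ok))
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      x[got + seq_len(take)] <- cx[idx]
      y[got + seq_len(take)] <- cy[idx]
      got <- got + take
    }
  }
  list(x = x, y = y)
}

#' Blue-noise (Poisson-disc) sampling in a disc
#'
#' Dart throwing with a spatial grid at `min_dist`, followed by collision
#' relaxation in the caller. Errors when the requested density exceeds the
#' packing limit.
#' @keywords internal
dartDisc <- function(n, center, R, min_dist) {
  if (n * (min_dist / 2)^2 > 0.9 * R^2)
    stop("requested density exceeds packing limit")
  cs <- min_dist / sqrt(2)
  ng <- ceiling(2 * R / cs)
  grid <- matrix(NA_integer_, ng, ng)
  x <- y <- numeric(n)
  got <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  while (got < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- R * sqrt(stats::runif(1))
    a <- 2 * pi * stats::runif(1)
    px <- center[1] + r * cos(a); py <- center[2] + r * sin(a)
    gx <- floor((px - center[1] + R) / cs) + 1L
    gy <- floor((py - center[2] + R) / cs) + 1L
    ok <- TRUE
    for (ix in max(1L, gx - 2L):min(ng, gx + 2L)) {
      for (iy in max(1L, gy - 2L):min(ng, gy + 2L)) {
        k <- grid[ix, iy]
        if (!is.na(k) && (x[k] - px)^2 + (y[k] - py)^2 < min_dist^2) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) {
      got <- got + 1L
      x[got] <- px; y[got] <- py
      grid[gx, gy] <- got
    }
  }
  if (got < n)  # dense regime: fill remainder uniformly; relaxation separates
    within <- uniformDisc(n - got, center, R)
  else within <- NULL
  if (!is.null(within)) {
    x[(got + 1L):n] <- within$x
    y[(got + 1L):n] <- within$y
  }
  list(x = x, y = y)
}

# ---- agent-table constructors ---------------------------------------------

#' @keywords internal
newTcellTable <- function(ids, phenotype) {
  list(id = as.numeric(ids), phenotype = phenotype,
       engaged_with = rep(NA_real_, length(ids)),
       cum_eng_h = numeric(length(ids)), stim_count = integer(length(ids)),
       act_clock_h = numeric(length(ids)),
       refr_clock_h = numeric(length(ids)),
       tcr = rep(1, length(ids)), div_clock_h = numeric(length(ids)),
       age_h = numeric(length(ids)), stale_count = integer(length(ids)),
       cnt = numeric(length(ids)))
}

#' @keywords internal
newTumorTable <- function(ids, phenotype, params) {
  n <- length(ids)
  tm <- params$tumor
  thr <- conversionThreshold(stats::runif(n), tm$conversion)
  pos <- phenotype == "PDL1pos"
  list(id = as.numeric(ids), phenotype = phenotype,
       packets = numeric(n), exposure = numeric(n), threshold_ng = thr,
       pdl1 = ifelse(pos, tm$levels$pos$pdl1, tm$levels$neg$pdl1),
       mhc = ifelse(pos, tm$levels$pos$mhc, tm$levels$neg$mhc),
       age_h = numeric(n), cnt = numeric(n))
}

#' @keywords internal
phenotypeDraw <- function(n, frac_pos, pos, neg) {
  n_pos <- round(frac_pos * n)
  sample(c(rep(pos, n_pos), rep(neg, n - n_pos)))
}

#' @keywords internal
assembleState <- function(tcells, tumors, tc_xy, tum_xy, params) {
  env <- params$environment
  n_tc <- tblN(tcells); n_tm <- tblN(tumors)
  field <- makeField(env)
  space <- list(
    id = c(tcells$id, tumors$id),
    class = c(rep("tcells", n_tc), rep("tumors", n_tm)),
    x = c(tc_xy$x, tum_xy$x), y = c(tc_xy$y, tum_xy$y),
    radius = c(rep(params$tcell$diameter_um / 2, n_tc),
               rep(params$tumor$diameter_um / 2, n_tm)),
    heading = stats::runif(n_tc + n_tm, 0, 2 * pi),
    speed = numeric(n_tc + n_tm), mv_count = numeric(n_tc + n_tm))
  rc <- resolveCollisions(space$x, space$y, space$radius,
                          c(0, env$width_um, 0, env$height_um), iters = 30)
  space$x <- rc$x; space$y <- rc$y
  list(
    agents = list(tcells = tcells, tumors = tumors),
    space = space,
    contacts = list(i_id = numeric(0), j_id = numeric(0), dist = numeric(0)),
    fields = list(ifng = field),
    mail = list(
      secretion = matrix(0, nrow(field), ncol(field)),
      packets = emptyTbl(c(id = "numeric", n = "numeric")),
      uptake = emptyTbl(c(id = "numeric", bin = "integer", ng = "numeric")),
      grant = emptyTbl(c(id = "numeric", ng = "numeric")),
      death_notices = emptyTbl(c(id = "numeric", x = "numeric",
                                 y = "numeric"))),
    lymph_node = emptyLymphNode())
}

#' @keywords internal
routeToLymphNode <- function(state, params) {
  lp <- params$lymph_node
  tc <- state$agents$tcells
  n_route <- round(lp$ln_fraction * tblN(tc))
  if (n_route > 0) {
    pick <- sample(tblN(tc), n_route)
    routed <- tblFilter(tc, seq_len(tblN(tc)) %in% pick)
    state$agents$tcells <- tblFilter(tc, !(seq_len(tblN(tc)) %in% pick))
    sp <- state$space
    state$space <- tblFilter(sp, !(sp$id %in% routed$id))
    state$lymph_node$residents <- list(
      id = routed$id, phenotype = routed$phenotype,
      licensed = rep(FALSE, n_route), divs_done = numeric(n_route),
      next_div_h = rep(Inf, n_route), cnt = numeric(n_route))
  }
  # dendritic cells start in the tumor arena (inside the bed)
  env <- params$environment
  dc_xy <- uniformDisc(lp$n_dc, env$bed_center_um, env$bed_radius_um)
  base <- max(c(0, state$agents$tcells$id, state$agents$tumors$id,
                state$lymph_node$residents$id))
  state$lymph_node$dcs <- list(
    id = base + seq_len(lp$n_dc), x = dc_xy$x, y = dc_xy$y,
    activated = rep(FALSE, lp$n_dc), antigen = numeric(lp$n_dc),
    migration_clock_h = numeric(lp$n_dc),
    location = rep("tumor", lp$n_dc), cnt = numeric(lp$n_dc))
  state
}

# ---- initializers ----------------------------------------------------------

#' Initialize a tumor-bed experiment
#'
#' Tumor cells are placed in the tumor-bed disc by blue-noise sampling plus
#' collision relaxation, with phenotypes drawn from `frac_pdl1_pos`; T cells
#' are placed uniformly inside the bed (`placement = "inside"`) or uniformly
#' in the region outside it (`"outside"`), with phenotypes from
#' `frac_pd1_pos` (nearest-integer rounding). The field starts at zero.
#' Uses R's RNG: seed beforehand (see [runExperiment()]).
#'
#' @param config full configuration (see [defaultParams()]).
#' @return initial state tree.
#' @export
initTumorBed <- function(config) {
  ex <- config$experiment
  env <- config$environment
  n_tm <- ex$n_tumor; n_tc <- ex$n_tcell
  tum_xy <- dartDisc(n_tm, env$bed_center_um, env$bed_radius_um,
                     min_dist = 0.75 * config$tumor$diameter_um)
  tc_xy <- if (identical(ex$placement, "outside"))
    uniformOutsideDisc(n_tc, env, env$bed_center_um, env$bed_radius_um)
  else uniformDisc(n_tc, env$bed_center_um, env$bed_radius_um)
  tcells <- newTcellTable(seq_len(n_tc),
                          phenotypeDraw(n_tc, ex$frac_pd1_pos,
                                        "PD1pos", "PD1neg"))
  tumors <- newTumorTable(n_tc + seq_len(n_tm),
                          phenotypeDraw(n_tm, ex$frac_pdl1_pos,
                                        "PDL1pos", "PDL1neg"), config)
  state <- assembleState(tcells, tumors, tc_xy, tum_xy, config)
  if (isTRUE(config$lymph_node$enabled))
    state <- routeToLymphNode(state, config)
  state
}

#' Initialize an in vitro-mirror experiment
#'
#' Tumor and T cells interleaved uniformly over the full arena (no tumor
#' bed), mirroring a well-mixed killing assay at the configured
#' effector-to-target ratio. `frac_pdl1_pos = 1` models IFNg-pretreated
#' (fully converted, quiescent) tumor cells; `0` models untreated cells.
#'
#' @param config full configuration.
#' @return initial state tree.
#' @export
initInVitro <- function(config) {
  ex <- config$experiment
  env <- config$environment
  n_tm <- ex$n_tumor; n_tc <- ex$n_tcell
  xy <- list(x = stats::runif(n_tc + n_tm, 0, env$width_um),
             y = stats::runif(n_tc + n_tm, 0, env$height_um))
  tc_xy <- list(x = xy$x[seq_len(n_tc)], y = xy$y[seq_len(n_tc)])
  tum_xy <- list(x = xy$x[n_tc + seq_len(n_tm)],
                 y = xy$y[n_tc + seq_len(n_tm)])
  tcells <- newTcellTable(seq_len(n_tc),
                          phenotypeDraw(n_tc, ex$frac_pd1_pos,
                                        "PD1pos", "PD1neg"))
  tumors <- newTumorTable(n_tc + seq_len(n_tm),
                          phenotypeDraw(n_tm, ex$frac_pdl1_pos,
                                        "PDL1pos", "PDL1neg"), config)
  state <- assembleState(tcells, tumors, tc_xy, tum_xy, config)
  if (isTRUE(config$lymph_node$enabled))
    state <- routeToLymphNode(state, config)
  state
}

# ---- imaging-table import and synthesis -----------------------------------

#' Estimate a gating threshold from a bimodal marker distribution
#'
#' Midpoint between the two mixture modes on the log scale (2-means on
#' log1p intensities). Degenerate (unimodal near zero) markers gate
#' everything negative.
#'
#' @param v non-negative marker intensities.
#' @return threshold on the original scale.
#' @export
gateThreshold <- function(v) {
  lv <- log1p(v)
  if (stats::sd(lv) < 1e-6) return(Inf)
  km <- stats::kmeans(lv, centers = range(lv), iter.max = 50)
  expm1(mean(km$centers))
}

#' Initialize from a single-cell imaging table
#'
#' Crops cells to `region`, translates coordinates to the arena frame,
#' assigns T cell phenotype from the PD1 gate and tumor phenotype from the
#' joint PDL1-and-MHCI gate, and drops non-tumor/non-T rows (count reported
#' via a message and the `dropped` attribute). The arena is resized to the
#' cropped region.
#'
#' @param table data.frame with columns `cell_id`, `x`, `y`, `cell_type`
#'   (labels containing "tumor" or "t" cell classes) and marker columns
#'   `PD1`, `PDL1`, `MHCI`.
#' @param config full configuration; environment geometry is overridden to
#'   the region size.
#' @param region `c(xmin, xmax, ymin, ymax)` crop (default: full table).
#' @param gates optional named list of thresholds for `PD1`, `PDL1`, `MHCI`;
#'   missing gates are estimated with [gateThreshold()].
#' @return list with the initial `state` and the adjusted `config`.
#' @export
initFromCodex <- function(table, config, region = NULL, gates = NULL) {
  need <- c("cell_id", "x", "y", "cell_type", "PD1", "PDL1", "MHCI")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(region))
    region <- c(min(table$x), max(table$x), min(table$y), max(table$y))
  keep <- table$x >= region[1] & table$x <= region[2] &
          table$y >= region[3] & table$y <= region[4]
  if (!any(keep)) stop("empty region")
  tab <- table[keep, , drop = FALSE]
  tab$x <- tab$x - region[1]
  tab$y <- tab$y - region[3]
  type <- tolower(tab$cell_type)
  is_tum <- grepl("tumou?r", type)
  is_t <- !is_tum & grepl("^t[ _-]?cell|^cd8|^t$", type)
  dropped <- sum(!is_t & !is_tum)
  if (dropped > 0)
    message("dropped ", dropped, " non-tumor/non-T cells")
  if (is.null(gates)) gates <- list()
  for (m in c("PD1", "PDL1", "MHCI"))
    if (is.null(gates[[m]])) gates[[m]] <- gateThreshold(tab[[m]])
  env <- config$environment
  env$width_um <- max(region[2] - region[1], env$bin_um)
  env$height_um <- max(region[4] - region[3], env$bin_um)
  env$bed_center_um <- c(env$width_um / 2, env$height_um / 2)
  config$environment <- env
  tct <- tab[is_t, , drop = FALSE]
  tmt <- tab[is_tum, , drop = FALSE]
  tcells <- newTcellTable(seq_len(nrow(tct)),
                          ifelse(tct$PD1 > gates$PD1, "PD1pos", "PD1neg"))
  tumors <- newTumorTable(nrow(tct) + seq_len(nrow(tmt)),
                          ifelse(tmt$PDL1 > gates$PDL1 &
                                 tmt$MHCI > gates$MHCI,
                                 "PDL1pos", "PDL1neg"), config)
  state <- assembleState(tcells, tumors,
                         list(x = tct$x, y = tct$y),
                         list(x = tmt$x, y = tmt$y), config)
  if (isTRUE(config$lymph_node$enabled))
    state <- routeToLymphNode(state, config)
  attr(state, "dropped") <- dropped
  attr(state, "gates") <- gates
  list(state = state, config = config)
}

#' Generate a synthetic single-cell imaging table
#'
#' Emulates a multiplexed-imaging single-cell table: a spatially clustered
#' tumor bed with T cells biased to the periphery, and marker intensities
#' drawn from two-component lognormal mixtures so that gating recovers the
#' configured phenotype fractions.
#'
#' @param n_cells total number of cells.
#' @param tumor_fraction fraction of cells that are tumor cells.
#' @param frac_pd1_pos,frac_pdl1_pos phenotype-positive fractions for T and
#'   tumor cells.
#' @param other_fraction fraction of unrelated ("stroma") cells.
#' @param bed_radius_um tumor-bed radius of the synthetic tissue.
#' @param seed RNG seed (same seed, identical table).
#' @return data.frame with columns `cell_id`, `x`, `y`, `cell_type`, `PD1`,
#'   `PDL1`, `MHCI`, `Ki67`.
#' @export
synthCodex <- function(n_cells, tumor_fraction = 0.95, frac_pd1_pos = 0.25,
                       frac_pdl1_pos = 0.3, other_fraction = 0.02,
                       bed_radius_um = 450, seed = 1) {
  stopifnot(n_cells > 0)
  set.seed(seed)
  n_other <- round(other_fraction * n_cells)
  n_tum <- round(tumor_fraction * (n_cells - n_other))
  n_tc <- n_cells - n_other - n_tum
  ctr <- c(bed_radius_um * 1.3, bed_radius_um * 1.3)
  mix_lnorm <- function(n, pos, lo = 1, hi = 25, sd = 0.35)
    stats::rlnorm(n, meanlog = log(ifelse(pos, hi, lo)), sdlog = sd)
  tum_xy <- uniformDisc(n_tum, ctr, bed_radius_um)
  # T cells biased to the tumor periphery
  r <- bed_radius_um * (0.85 + 0.3 * stats::runif(n_tc))
  a <- 2 * pi * stats::runif(n_tc)
  tc_xy <- list(x = ctr[1] + r * cos(a), y = ctr[2] + r * sin(a))
  oth_xy <- list(x = stats::runif(n_other, 0, 2 * ctr[1]),
                 y = stats::runif(n_other, 0, 2 * ctr[2]))
  tum_pos <- stats::runif(n_tum) < frac_pdl1_pos
  tc_pos <- stats::runif(n_tc) < frac_pd1_pos
  df <- data.frame(
    cell_id = seq_len(n_tum + n_tc + n_other),
    x = c(tum_xy$x, tc_xy$x, oth_xy$x),
    y = c(tum_xy$y, tc_xy$y, oth_xy$y),
    cell_type = c(rep("tumor", n_tum), rep("tcell", n_tc),
                  rep("stroma", n_other)),
    PD1 = c(mix_lnorm(n_tum, FALSE), mix_lnorm(n_tc, tc_pos),
            mix_lnorm(n_other, FALSE)),
    PDL1 = c(mix_lnorm(n_tum, tum_pos), mix_lnorm(n_tc, FALSE),
             mix_lnorm(n_other, FALSE)),
    MHCI = c(mix_lnorm(n_tum, tum_pos), mix_lnorm(n_tc, FALSE),
             mix_lnorm(n_other, FALSE)),
    Ki67 = c(mix_lnorm(n_tum, !tum_pos), mix_lnorm(n_tc, FALSE),
             mix_lnorm(n_other, FALSE)))
  df[c("x", "y")] <- lapply(df[c("x", "y")], round, digits = 2)
  df
}

# ---- composite wiring and run drivers -------------------------------------

#' Wire the full tumor-microenvironment composite
#'
#' Connects the movement/collision/contact process, the T cell and tumor
#' processes, the IFNg field process and (optionally) the dendritic-cell /
#' lymph-node process over the shared state tree.
#'
#' @param config full configuration.
#' @param state initial state tree from an initializer.
#' @param run_seed integer run seed driving all agent substreams.
#' @return a `simComposite` ready for [runComposite()].
#' @export
buildComposite <- function(config, state, run_seed) {
  procs <- list(
    neighborsProcess(config, run_seed),
    tcellProcess(config, run_seed),
    tumorProcess(config, run_seed),
    fieldProcess(config))
  topology <- list(
    neighbors = list(space = "space", tcells = "agents/tcells",
                     contacts = "contacts"),
    tcell = list(tcells = "agents/tcells", tumors = "agents/tumors",
                 contacts = "contacts", space = "space",
                 field = "fields/ifng", secretion = "mail/secretion",
                 packets = "mail/packets"),
    tumor = list(tumors = "agents/tumors", space = "space",
                 field = "fields/ifng", packets = "mail/packets",
                 grant = "mail/grant", uptake = "mail/uptake",
                 death_notices = "mail/death_notices"),
    diffusion = list(field = "fields/ifng", secretion = "mail/secretion",
                     uptake = "mail/uptake", grant = "mail/grant"))
  if (isTRUE(config$lymph_node$enabled)) {
    procs <- c(procs, list(lymphNodeProcess(config, run_seed)))
    topology$lymph_node <- list(ln = "lymph_node",
                                death_notices = "mail/death_notices")
  }
  ids <- c(state$agents$tcells$id, state$agents$tumors$id,
           state$lymph_node$residents$id, state$lymph_node$dcs$id)
  vol <- attr(state$fields$ifng, "bin_vol_mL")
  summarize <- function(s, clock_h) {
    tc <- s$agents$tcells; tum <- s$agents$tumors; ln <- s$lymph_node
    list(
      tumor_PDL1neg = sum(tum$phenotype == "PDL1neg"),
      tumor_PDL1pos = sum(tum$phenotype == "PDL1pos"),
      tcell_PD1neg = sum(tc$phenotype == "PD1neg"),
      tcell_PD1pos = sum(tc$phenotype == "PD1pos"),
      tcell_engaged = sum(!is.na(tc$engaged_with)),
      tcell_LN = tblN(ln$residents),
      tcell_queue = tblN(ln$queue),
      dc_tumor = sum(ln$dcs$location == "tumor"),
      dc_LN = sum(ln$dcs$location == "LN"),
      ifng_total_ng = sum(s$fields$ifng) * vol)
  }
  compose(procs, topology, state, dt_s = config$engine$dt_s,
          agent_stores = c("agents/tcells", "agents/tumors"),
          space_store = "space",
          next_id = max(c(0, ids)) + 1L,
          summarize = summarize)
}

#' Run one experiment replicate
#'
#' Seeds the RNG, builds the initial state for the configured mode
#' (`tumor_bed`, `in_vitro`, or `codex_init`), wires the composite, and runs
#' it for the configured duration.
#'
#' @param config full configuration (see [loadConfig()] /
#'   [defaultParams()]).
#' @param seed integer seed (defaults to `config$experiment$seed`).
#' @param duration_h,emit_interval_h override the configured duration /
#'   emit interval.
#' @param record_agents,record_field forwarded to [runComposite()].
#' @param codex_table optional single-cell table for `codex_init` mode.
#' @return a `simTrajectory` with `config` and `seed` attached.
#' @export
runExperiment <- function(config, seed = config$experiment$seed,
                          duration_h = config$experiment$duration_h,
                          emit_interval_h = config$engine$emit_interval_h,
                          record_agents = FALSE, record_field = FALSE,
                          codex_table = NULL) {
  validateConfig(config)
  set.seed(seed)
  state <- switch(config$experiment$mode,
    tumor_bed = initTumorBed(config),
    in_vitro = initInVitro(config),
    codex_init = {
      if (is.null(codex_table))
        stop("codex_init mode requires a codex_table")
      ini <- initFromCodex(codex_table, config)
      config <- ini$config
      ini$state
    })
  comp <- buildComposite(config, state, run_seed = seed)
  traj <- runComposite(comp, duration_h, emit_interval_h,
                       record_agents = record_agents,
                       record_field = record_field)
  traj$config <- config
  traj$seed <- seed
  traj
}

#' Run a replicate sweep over seeds
#'
#' @param config full configuration.
#' @param seeds integer seeds, one per replicate (default
#'   `seq_len(config$experiment$replicates)` offset by the configured seed).
#' @param ... forwarded to [runExperiment()].
#' @return list of `simTrajectory` objects.
#' @export
runSweep <- function(config, seeds = NULL, ...) {
  if (is.null(seeds))
    seeds <- config$experiment$seed + seq_len(config$experiment$replicates) - 1
  lapply(seeds, function(s) runExperiment(config, seed = s, ...))
}
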