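# All tunable model parameters live here (and in the YAML configs); none are
# hard-coded in process code. Units are stated per field.

#' Default model parameters
#'
#' Returns the full nested parameter list. Key defaults: T cells secrete IFNg
#' only while activated (activation window opened by TCR engagement); PD-1-
#' cells secrete 4-fold more IFNg and cytotoxic packets than PD-1+ cells,
#' divide while activated, and die at a lower baseline hazard. Tumor cells
#' double every 29.1 h while proliferative (calibrated against exponential
#' growth of 1,200 to ~5,000 cells in 60 h), convert one-way to a quiescent
#' PD-L1+/MHC-I+ phenotype once cumulative IFNg uptake crosses a per-cell
#' lognormal threshold, and die after accumulating 128 cytotoxic packets.
#' The conversion threshold median equals the exposure accumulated in an
#' 18 h bath at 10 ng/mL, so that bath converts ~50% of cells.
#'
#' @return nested named list of parameters.
#' @export
defaultParams <- function() {
  k_up <- 3e-6   # mL per cell per h; IFNg uptake rate constant
  list(
    engine = list(dt_s = 60, emit_interval_h = 1.5),
    environment = list(
      width_um = 1600, height_um = 1600,
      bed_center_um = c(800, 800), bed_radius_um = 500,
      bin_um = 30, depth_um = 15,          # grid bin edge and nominal depth
      D_um2_s = 2, decay_per_h = 3,        # effective IFNg diffusivity/decay
      contact_tol_um = 3,                  # contact = gap <= tolerance
      collision_iters = 2, overlap_tol_frac = 0.05,
      turn_sd_rad = 2                      # heading noise per sqrt(min); confined walk
    ),
    tcell = list(
      diameter_um = 10,
      pd1neg = list(
        ifng_ng_per_h = 1.2e-2,    # secreted while activated
        packets_per_min = 4,       # delivered while engaged
        speed_free_um_min = 10, speed_engaged_um_min = 1,
        death_per_h = 0.002, division_interval_h = 8
      ),
      pd1pos = list(
        ifng_ng_per_h = 4e-3,      # 3-fold lower IFNg secretion
        packets_per_min = 3,
        speed_free_um_min = 5, speed_engaged_um_min = 1,
        death_per_h = 0.01, division_interval_h = Inf
      ),
      exhaustion_threshold_h = 14, # lifetime engaged hours to PD-1+ switch
      activation_h = 3, refractory_h = 1,
      refractory_mode = "timer",   # or "probabilistic"
      tcr_down_frac = 0.15, tcr_recovery_per_h = 0.3,
      p_max = 0.5,                 # engagement prob = p_max * mhc * tcr (per 60 s contact step)
      pd1_pdl1 = list(inhibition = 0.3, extra_death_per_h = 0.05)
    ),
    tumor = list(
      diameter_um = 20,
      doubling_h = 28.0,  # division schedule; net growth (with the 0.001/h
                          # intrinsic death) doubles every ~29.1 h
      intrinsic_death_per_h = 0.001,
      k_up_mL_per_h = k_up,
      packet_threshold = 128,
      conversion = list(median_ng = k_up * 10 * 18, sigma_log = 0.5),
      levels = list(neg = list(pdl1 = 0.1, mhc = 0.05),
                    pos = list(pdl1 = 1, mhc = 1))
    ),
    lymph_node = list(
      enabled = FALSE, n_dc = 12, dc_uptake_radius_um = 40,
      dc_transit_h = 4, ln_fraction = 0.25,
      licensing_rate_per_h = 0.2, n_div = 3,
      division_interval_h = 6, egress_delay_h = 6
    ),
    experiment = list(
      mode = "tumor_bed",          # tumor_bed | in_vitro | codex_init
      n_tumor = 1200, n_tcell = 12,
      frac_pd1_pos = 0.25, frac_pdl1_pos = 0,
      placement = "inside",        # inside | outside (tumor bed)
      duration_h = 72, replicates = 4, seed = 1
    )
  )
}

#' Recursively merge a configuration override into defaults
#' @param base,override nested lists; leaves in `override` win.
#' @return merged list.
#' @export
mergeConfig <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base)) return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(override[[nm]]) && is.list(base[[nm]]))
      mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Validate a full configuration
#'
#' @param config nested list as returned by [defaultParams()] /
#'   [loadConfig()].
#' @return the config, invisibly; stops with a message naming the offending
#'   block or field otherwise.
#' @export
validateConfig <- function(config) {
  required <- c("engine", "environment", "tcell", "tumor", "lymph_node",
                "experiment")
  for (blk in required)
    if (is.null(config[[blk]]))
      stop("configuration is missing required block '", blk, "'",
           call. = FALSE)
  ex <- config$experiment
  if (!is.null(ex$n_tumor) && ex$n_tumor <= 0) stop("n_tumor must be > 0")
  if (ex$frac_pd1_pos < 0 || ex$frac_pd1_pos > 1)
    stop("frac_pd1_pos must lie in [0, 1]")
  if (ex$frac_pdl1_pos < 0 || ex$frac_pdl1_pos > 1)
    stop("frac_pdl1_pos must lie in [0, 1]")
  if (!ex$mode %in% c("tumor_bed", "in_vitro", "codex_init"))
    stop("unknown experiment mode: ", ex$mode)
  if (!ex$placement %in% c("inside", "outside"))
    stop("unknown placement: ", ex$placement)
  if (ex$duration_h <= 0) stop("duration_h must be > 0")
  tc <- config$tcell
  if (tc$pd1neg$ifng_ng_per_h <= tc$pd1pos$ifng_ng_per_h)
    stop("PD-1- secretion rates must exceed PD-1+ rates")
  if (tc$pd1neg$death_per_h >= tc$pd1pos$death_per_h)
    stop("PD-1- death hazard must be lower than PD-1+")
  if (tc$pd1neg$speed_engaged_um_min >= tc$pd1neg$speed_free_um_min)
    stop("engaged speed must be below unengaged speed")
  if (config$tumor$packet_threshold <= 0) stop("packet_threshold must be > 0")
  invisible(config)
}

#' Load a YAML experiment configuration
#'
#' Reads a YAML file whose top-level keys override [defaultParams()]
#' (`experiment`, `tcell`, `tumor`, `environment`, `lymph_node`, `engine`),
#' merges it into the defaults and validates the result.
#'
#' @param path YAML file path, or the name of a packaged config (see
#'   `list.files(system.file("configs", package = "tmesim"))`).
#' @return validated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) {
    pkgd <- system.file("configs", paste0(path, ".yaml"), package = "tmesim")
    if (nzchar(pkgd)) path <- pkgd
  }
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- mergeConfig(defaultParams(), raw)
  validateConfig(cfg)
  cfg
}
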