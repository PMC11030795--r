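# Tumor cell agent process: proliferative PD-L1-/MHC-I-low vs. quiescent
# PD-L1+/MHC-I+ phenotypes, IFNg-exposure-driven one-way conversion, death by
# accumulated cytotoxic packets or intrinsic hazard. Tumor cells do not
# migrate; they move only through collision resolution.

#' Draw per-cell IFNg conversion thresholds
#'
#' Thresholds on cumulative IFNg exposure (ng) are lognormal with the
#' configured median and log-scale sigma; each cell draws its threshold at
#' birth, which produces the partial, smooth population conversion seen when
#' a population is bathed in IFNg.
#'
#' @param u uniform draws in (0, 1).
#' @param conversion list with `median_ng` and `sigma_log`.
#' @return numeric thresholds (ng); `median_ng = Inf` disables conversion.
#' @export
conversionThreshold <- function(u, conversion) {
  if (!is.finite(conversion$median_ng)) return(rep(Inf, length(u)))
  stats::qlnorm(u, meanlog = log(conversion$median_ng),
                sdlog = conversion$sigma_log)
}

#' Fraction of cells converted at a given cumulative exposure
#'
#' Analytic lognormal CDF companion to [conversionThreshold()]; an 18 h bath
#' at 10 ng/mL with default parameters sits at the threshold median, i.e.
#' converts 50% of cells.
#'
#' @param exposure_ng cumulative uptaken IFNg (ng).
#' @param conversion list with `median_ng` and `sigma_log`.
#' @return converted fraction in \[0, 1\].
#' @export
convertedFraction <- function(exposure_ng, conversion) {
  if (!is.finite(conversion$median_ng)) return(rep(0, length(exposure_ng)))
  stats::plnorm(exposure_ng, meanlog = log(conversion$median_ng),
                sdlog = conversion$sigma_log)
}

#' Cytotoxic-packet death check
#'
#' A tumor cell dies (cause "cytotoxic") once cumulative received packets
#' reach the threshold; both phenotypes are killable.
#'
#' @param packets_received cumulative packets per cell.
#' @param threshold packet death threshold.
#' @return logical death trigger.
#' @export
packetDeathCheck <- function(packets_received, threshold) {
  packets_received >= threshold
}

#' Tumor cell process
#'
#' Consumes the packet and uptake-grant mailboxes, posts IFNg uptake requests
#' (`k_up * C_local * dt`, granted up to bin content by the field process),
#' evaluates the one-way conversion to the quiescent PD-L1+/MHC-I+ phenotype,
#' and triggers division (proliferative phenotype only, exponential schedule
#' calibrated to the configured doubling time) and death (cytotoxic packets
#' or intrinsic hazard).
#'
#' @param params full parameter list.
#' @param run_seed integer run seed.
#' @return a [processSpec()].
#' @export
tumorProcess <- function(params, run_seed) {
  tm <- params$tumor
  div_rate <- log(2) / tm$doubling_h
  processSpec("tumor",
              ports = c("tumors", "space", "field", "packets", "grant",
                        "uptake", "death_notices"),
              timestep_s = params$engine$dt_s,
              update = function(view, dt_s) {
    tum <- view$tumors
    n <- tblN(tum)
    empty_pk <- emptyTbl(c(id = "numeric", n = "numeric"))
    empty_gr <- emptyTbl(c(id = "numeric", ng = "numeric"))
    empty_dn <- emptyTbl(c(id = "numeric", x = "numeric", y = "numeric"))
    out <- list(tumors = updReplace(tum),
                packets = updReplace(empty_pk),
                grant = updReplace(empty_gr),
                death_notices = updReplace(empty_dn))
    if (n == 0L) return(out)
    dt_h <- dt_s / 3600
    u <- agentRunif(run_seed, 3L, tum$id, tum$cnt, 3L)
    tum$cnt <- tum$cnt + 3
    tum$age_h <- tum$age_h + dt_h

    # consume mailboxes (frozen values; mailboxes reset by replacement above,
    # same-step producer deltas land on top for the next step)
    pk <- view$packets
    if (length(pk$id)) {
      agg <- rowsum(pk$n, pk$id)
      row <- match(as.numeric(rownames(agg)), tum$id)
      ok <- !is.na(row)
      tum$packets[row[ok]] <- tum$packets[row[ok]] + agg[ok, 1L]
    }
    gr <- view$grant
    if (length(gr$id)) {
      agg <- rowsum(gr$ng, gr$id)
      row <- match(as.numeric(rownames(agg)), tum$id)
      ok <- !is.na(row)
      tum$exposure[row[ok]] <- tum$exposure[row[ok]] + agg[ok, 1L]
    }

    # uptake requests against the local field concentration
    sp <- view$space
    rows <- match(tum$id, sp$id)
    bins <- posToBin(sp$x[rows], sp$y[rows], view$field)
    cloc <- view$field[bins]
    req <- tm$k_up_mL_per_h * cloc * dt_h
    has <- req > 1e-12   # skip negligible requests (< 1e-12 ng per step)
    if (any(has))
      out$uptake <- updAppend(list(id = tum$id[has],
                                   bin = bins[has], ng = req[has]))

    # one-way conversion once cumulative exposure crosses the cell threshold
    conv <- tum$phenotype == "PDL1neg" & tum$exposure >= tum$threshold_ng
    if (any(conv)) {
      tum$phenotype[conv] <- "PDL1pos"
      tum$pdl1[conv] <- tm$levels$pos$pdl1
      tum$mhc[conv] <- tm$levels$pos$mhc
    }

    # death: cytotoxic packets, else intrinsic hazard
    cyto <- packetDeathCheck(tum$packets, tm$packet_threshold)
    intr <- !cyto & u[, 1L] < 1 - exp(-tm$intrinsic_death_per_h * dt_h)
    die <- cyto | intr
    rem <- list()
    if (any(die)) {
      if (any(cyto)) rem[[length(rem) + 1L]] <-
        list(store = "agents/tumors", ids = tum$id[cyto], cause = "cytotoxic")
      if (any(intr)) rem[[length(rem) + 1L]] <-
        list(store = "agents/tumors", ids = tum$id[intr], cause = "intrinsic")
      out$death_notices <- updReplace(list(id = tum$id[die],
                                           x = sp$x[rows][die],
                                           y = sp$y[rows][die]))
    }

    # division: proliferative phenotype only, exponential schedule
    divide <- tum$phenotype == "PDL1neg" & !die &
      u[, 2L] < 1 - exp(-div_rate * dt_h)
    adds <- list()
    if (any(divide)) {
      di <- which(divide)
      ang <- 2 * pi * u[di, 3L]
      thr <- conversionThreshold(
        agentRunif(run_seed, 4L, tum$id[di], tum$cnt[di], 1L)[, 1L],
        tm$conversion)
      tum$cnt[di] <- tum$cnt[di] + 1
      for (k in seq_along(di)) {
        i <- di[k]
        adds[[length(adds) + 1L]] <- list(
          store = "agents/tumors", parent = tum$id[i],
          x = sp$x[rows[i]] + sp$radius[rows[i]] * cos(ang[k]),
          y = sp$y[rows[i]] + sp$radius[rows[i]] * sin(ang[k]),
          radius = sp$radius[rows[i]],
          state = list(phenotype = "PDL1neg", packets = 0, exposure = 0,
                       threshold_ng = thr[k], pdl1 = tm$levels$neg$pdl1,
                       mhc = tm$levels$neg$mhc, age_h = 0, cnt = 0))
      }
    }
    if (any(die)) tum <- tblFilter(tum, !die)
    out$tumors <- updReplace(tum)
    if (length(adds) || length(rem))
      out$.agents <- list(add = adds, remove = rem)
    out
  })
}
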