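# T cell agent process: two phenotypes (PD-1- effector-like, PD-1+
# exhausted-like), engagement-driven activation, IFNg and cytotoxic packet
# secretion, exhaustion transition, PD-1/PD-L1 induced apoptosis, division
# and death triggers. One engaged tumor target per T cell at a time;
# tie-break among contacts: nearest center, then lowest agent id.

#' Engagement probability
#'
#' A T cell in contact with a tumor cell engages with probability
#' `p_max * mhc_level * tcr_level`; MHC-I-low tumors are recognizable at
#' reduced probability, and TCR downregulation (after completed engagements)
#' suppresses re-engagement until recovery.
#'
#' @param mhc_level tumor MHC-I level in \[0, 1\].
#' @param tcr_level T cell surface TCR level in \[0, 1\].
#' @param p_max maximal engagement probability per contact opportunity.
#' @return engagement probability vector.
#' @export
engagementProbability <- function(mhc_level, tcr_level, p_max = 1) {
  p_max * mhc_level * tcr_level
}

#' Exhaustion transition (PD-1- to PD-1+)
#'
#' Timer mode: the switch fires exactly when cumulative engaged time reaches
#' the threshold. Probabilistic mode: while engaged, the switch fires with a
#' per-step hazard of `1 / threshold` per engaged hour, so the expected
#' engaged time to transition equals the same threshold. PD-1+ is absorbing.
#'
#' @param cum_eng_h cumulative engaged hours (per cell).
#' @param engaged logical: engaged during this step.
#' @param dt_h step length (h).
#' @param threshold_h exhaustion threshold (engaged hours).
#' @param mode `"timer"` or `"probabilistic"`.
#' @param u uniform draws (used in probabilistic mode).
#' @return logical vector: transition fires this step.
#' @export
checkExhaustion <- function(cum_eng_h, engaged, dt_h, threshold_h,
                            mode = "timer", u = NULL) {
  if (mode == "timer") {
    cum_eng_h >= threshold_h
  } else {
    p <- 1 - exp(-dt_h / threshold_h)
    engaged & !is.null(u) & u < p
  }
}

#' T cell process
#'
#' Builds the process updating every T cell agent in the tumor compartment:
#' engagement begin/continue/end decisions, IFNg secretion into the local
#' field bin (only while activated), cytotoxic packet delivery to the engaged
#' tumor cell, the one-way exhaustion transition, PD-1/PD-L1 inhibition and
#' apoptosis, division (PD-1- only, while activated) and death triggers.
#'
#' @param params full parameter list.
#' @param run_seed integer run seed.
#' @return a [processSpec()].
#' @export
tcellProcess <- function(params, run_seed) {
  tp <- params$tcell
  th <- tp$exhaustion_threshold_h
  prob_mode <- identical(tp$refractory_mode, "probabilistic")
  processSpec("tcell",
              ports = c("tcells", "tumors", "contacts", "space", "field",
                        "secretion", "packets"),
              timestep_s = params$engine$dt_s,
              update = function(view, dt_s) {
    t <- view$tcells
    n <- tblN(t)
    out <- list(tcells = updReplace(t))
    if (n == 0L) return(out)
    dt_h <- dt_s / 3600
    dt_min <- dt_s / 60
    tum <- view$tumors
    sp <- view$space
    u <- agentRunif(run_seed, 1L, t$id, t$cnt, 6L)
    t$cnt <- t$cnt + 6
    t$age_h <- t$age_h + dt_h
    t$tcr <- 1 - (1 - t$tcr) * exp(-tp$tcr_recovery_per_h * dt_h)

    # refractory countdown / stochastic exit
    if (prob_mode) {
      exit <- t$refr_clock_h > 0 & u[, 5L] < 1 - exp(-dt_h / tp$refractory_h)
      t$refr_clock_h[exit] <- 0
    } else {
      t$refr_clock_h <- pmax(0, t$refr_clock_h - dt_h)
    }

    # resolve ongoing engagements against the frozen tumor store
    engaged <- !is.na(t$engaged_with)
    target_row <- match(t$engaged_with, tum$id)
    completed <- engaged & is.na(target_row)      # target died: kill completed
    if (any(completed)) {
      t$stim_count[completed] <- t$stim_count[completed] + 1L
      t$tcr[completed] <- t$tcr[completed] * (1 - tp$tcr_down_frac)
      t$refr_clock_h[completed] <- tp$refractory_h
      t$engaged_with[completed] <- NA_real_
    }
    still <- engaged & !is.na(target_row)
    if (any(still)) {                             # stale-contact check
      ck <- t$id[still] * 2^26 + t$engaged_with[still]
      have <- c(view$contacts$i_id * 2^26 + view$contacts$j_id,
                view$contacts$j_id * 2^26 + view$contacts$i_id)
      stale <- !(ck %in% have)
      if (any(stale)) {
        si <- which(still)[stale]
        t$stale_count[si] <- t$stale_count[si] + 1L
        t$engaged_with[si] <- NA_real_
      }
    }
    eng_now <- !is.na(t$engaged_with)
    tgt <- match(t$engaged_with, tum$id)
    pn <- t$phenotype == "PD1neg"

    # PD-1/PD-L1 checkpoint: inhibition + extra apoptosis hazard applies to
    # PD-1+ cells engaged with a PD-L1+ tumor
    ckpt <- eng_now & !pn & tum$phenotype[ifelse(is.na(tgt), 1L, tgt)] ==
      "PDL1pos" & !is.na(tgt)
    inhib <- ifelse(ckpt, tp$pd1_pdl1$inhibition, 1)

    # cytotoxic packet delivery while engaged
    if (any(eng_now)) {
      t$cum_eng_h[eng_now] <- t$cum_eng_h[eng_now] + dt_h
      rate <- ifelse(pn, tp$pd1neg$packets_per_min, tp$pd1pos$packets_per_min)
      pk <- rate[eng_now] * inhib[eng_now] * dt_min
      out$packets <- updAppend(list(id = t$engaged_with[eng_now], n = pk))
    }

    # exhaustion (one-way)
    flip <- pn & checkExhaustion(t$cum_eng_h, eng_now, dt_h, th,
                                 if (prob_mode) "probabilistic" else "timer",
                                 u[, 4L])
    t$phenotype[flip] <- "PD1pos"
    pn <- t$phenotype == "PD1neg"

    # new engagements from the contact graph
    free <- !eng_now & t$refr_clock_h <= 0
    ct <- view$contacts
    if (any(free) && length(ct$i_id)) {
      ti <- match(ct$i_id, t$id); tj <- match(ct$j_id, t$id)
      # orient pairs as (tcell, tumor)
      a_id <- c(ct$i_id[!is.na(ti)], ct$j_id[!is.na(tj)])
      b_id <- c(ct$j_id[!is.na(ti)], ct$i_id[!is.na(tj)])
      dd <- c(ct$dist[!is.na(ti)], ct$dist[!is.na(tj)])
      brow <- match(b_id, tum$id)
      ok <- !is.na(brow) & a_id %in% t$id[free]
      if (any(ok)) {
        a_id <- a_id[ok]; brow <- brow[ok]; dd <- dd[ok]
        o <- order(a_id, dd, tum$id[brow])
        first <- !duplicated(a_id[o])
        a_sel <- a_id[o][first]; b_sel <- brow[o][first]
        arow <- match(a_sel, t$id)
        p <- engagementProbability(tum$mhc[b_sel], t$tcr[arow], tp$p_max)
        accept <- u[arow, 1L] < p
        if (any(accept)) {
          ar <- arow[accept]
          t$engaged_with[ar] <- tum$id[b_sel[accept]]
          t$act_clock_h[ar] <- tp$activation_h
        }
      }
    }

    # IFNg secretion while activated, into the local field bin
    act <- t$act_clock_h > 0
    if (any(act)) {
      srate <- ifelse(pn, tp$pd1neg$ifng_ng_per_h, tp$pd1pos$ifng_ng_per_h)
      mass <- srate[act] * inhib[act] * dt_h
      rows <- match(t$id[act], sp$id)
      bins <- posToBin(sp$x[rows], sp$y[rows], view$field)
      dm <- matrix(0, nrow(view$field), ncol(view$field))
      agg <- rowsum(mass, bins)
      dm[as.integer(rownames(agg))] <- agg[, 1L]
      out$secretion <- updDelta(dm)
    }

    # death: baseline hazard by phenotype + checkpoint apoptosis hazard
    base_h <- ifelse(pn, tp$pd1neg$death_per_h, tp$pd1pos$death_per_h)
    extra_h <- ifelse(ckpt, tp$pd1_pdl1$extra_death_per_h, 0)
    h_tot <- base_h + extra_h
    die <- u[, 2L] < 1 - exp(-h_tot * dt_h)
    cause <- ifelse(extra_h > 0 & u[, 3L] < extra_h / h_tot,
                    "pd1_apoptosis", "intrinsic")

    # division: PD-1- cells accumulate activated time toward the interval
    t$div_clock_h <- t$div_clock_h + ifelse(act & pn, dt_h, 0)
    divide <- pn & !die & t$div_clock_h >=
      tp$pd1neg$division_interval_h
    adds <- list()
    if (any(divide)) {
      t$div_clock_h[divide] <- 0
      rows <- match(t$id[divide], sp$id)
      ang <- 2 * pi * u[divide, 6L]
      r0 <- sp$radius[rows]
      for (k in seq_along(rows)) {
        i <- which(divide)[k]
        adds[[length(adds) + 1L]] <- list(
          store = "agents/tcells", parent = t$id[i],
          x = sp$x[rows[k]] + r0[k] * cos(ang[k]),
          y = sp$y[rows[k]] + r0[k] * sin(ang[k]),
          radius = r0[k],
          # daughters inherit the lineage's engagement history (exhaustion
          # odometer); only operational clocks reset
          state = list(phenotype = t$phenotype[i], engaged_with = NA_real_,
                       cum_eng_h = t$cum_eng_h[i],
                       stim_count = t$stim_count[i], act_clock_h = 0,
                       refr_clock_h = 0, tcr = t$tcr[i], div_clock_h = 0,
                       age_h = 0, stale_count = 0L, cnt = 0))
      }
    }
    t$act_clock_h <- pmax(0, t$act_clock_h - dt_h)

    rem <- list()
    if (any(die)) {
      for (cz in unique(cause[die]))
        rem[[length(rem) + 1L]] <- list(store = "agents/tcells",
                                        ids = t$id[die & cause == cz],
                                        cause = cz)
      keep <- !die
      t <- tblFilter(t, keep)
    }
    out$tcells <- updReplace(t)
    if (length(adds) || length(rem))
      out$.agents <- list(add = adds, remove = rem)
    out
  })
}
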