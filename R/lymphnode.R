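# Optional dendritic-cell / lymph-node compartment: DCs in the tumor arena
# acquire antigen from dying tumor cells, migrate to the tumor-draining
# lymph node (fixed transit delay), and license resident T cells there to
# proliferate; daughters egress to the tumor arena boundary after a delay.
# The LN is a well-mixed (non-spatial) store; LN residence never advances
# TCR engagement, so resident founders cannot exhaust.

#' Empty lymph-node store
#' @return nested list used as the `lymph_node` store.
#' @keywords internal
emptyLymphNode <- function() {
  list(
    dcs = emptyTbl(c(id = "numeric", x = "numeric", y = "numeric",
                     activated = "logical", antigen = "numeric",
                     migration_clock_h = "numeric", location = "character",
                     cnt = "numeric")),
    residents = emptyTbl(c(id = "numeric", phenotype = "character",
                           licensed = "logical", divs_done = "numeric",
                           next_div_h = "numeric", cnt = "numeric")),
    queue = emptyTbl(c(arrival_h = "numeric", phenotype = "character",
                       founder = "numeric")),
    clock_h = 0, draw_cnt = 0, cum_ln_divisions = 0
  )
}

#' Dendritic-cell / lymph-node process
#'
#' Dendritic cells located in the tumor arena become activated when a tumor
#' death occurs within the uptake radius during a step (antigen load
#' increases, migration clock starts); they then transit to the LN over the
#' configured delay. In the LN, a resident PD-1- T cell encounters activated
#' antigen-bearing DCs with a well-mixed probability per step; a licensing
#' event triggers a proliferation burst (`n_div` doublings at the LN division
#' interval), after which the `2^n_div - 1` daughters enter the egress queue
#' and arrive at a uniformly random position on the arena boundary after the
#' egress delay.
#'
#' @param params full parameter list.
#' @param run_seed integer run seed.
#' @return a [processSpec()].
#' @export
lymphNodeProcess <- function(params, run_seed) {
  lp <- params$lymph_node
  env <- params$environment
  processSpec("lymph_node", ports = c("ln", "death_notices"),
              timestep_s = params$engine$dt_s,
              update = function(view, dt_s) {
    ln <- view$ln
    dt_h <- dt_s / 3600
    ln$clock_h <- ln$clock_h + dt_h
    dn <- view$death_notices
    dc <- ln$dcs

    # DC antigen uptake and activation in the tumor arena
    if (tblN(dc) && length(dn$id)) {
      in_tumor <- which(dc$location == "tumor")
      if (length(in_tumor)) {
        d2 <- outer(dc$x[in_tumor], dn$x, `-`)^2 +
              outer(dc$y[in_tumor], dn$y, `-`)^2
        hits <- rowSums(d2 <= lp$dc_uptake_radius_um^2)
        got <- hits > 0
        if (any(got)) {
          i <- in_tumor[got]
          dc$antigen[i] <- pmin(1, dc$antigen[i] + 0.25 * hits[got])
          dc$activated[i] <- TRUE
          dc$location[i] <- "in_transit"
          dc$migration_clock_h[i] <- lp$dc_transit_h
        }
      }
    }
    # transit countdown
    tr <- dc$location == "in_transit"
    if (any(tr)) {
      dc$migration_clock_h[tr] <- dc$migration_clock_h[tr] - dt_h
      arr <- tr & dc$migration_clock_h <= 1e-9
      dc$location[arr] <- "LN"
      dc$migration_clock_h[arr] <- 0
    }
    ln$dcs <- dc

    # licensing of resident PD-1- founders by activated DCs in the LN
    res <- ln$residents
    n_act <- sum(dc$location == "LN" & dc$activated & dc$antigen > 0)
    if (tblN(res)) {
      u <- agentRunif(run_seed, 5L, res$id, res$cnt, 1L)
      res$cnt <- res$cnt + 1
      eligible <- !res$licensed & res$phenotype == "PD1neg" & n_act > 0
      lic <- eligible & u[, 1L] < 1 - exp(-lp$licensing_rate_per_h *
                                          n_act * dt_h)
      if (any(lic)) {
        res$licensed[lic] <- TRUE
        res$divs_done[lic] <- 0
        res$next_div_h[lic] <- ln$clock_h + lp$division_interval_h
      }
      # division bursts: cohort doubles n_div times, then daughters egress
      due <- res$licensed & ln$clock_h >= res$next_div_h
      if (any(due)) {
        res$divs_done[due] <- res$divs_done[due] + 1
        done <- due & res$divs_done >= lp$n_div
        cont <- due & !done
        res$next_div_h[cont] <- res$next_div_h[cont] + lp$division_interval_h
        if (any(done)) {
          n_d <- 2^lp$n_div - 1
          for (i in which(done)) {
            ln$queue <- tblBind(ln$queue, list(
              arrival_h = rep(ln$clock_h + lp$egress_delay_h, n_d),
              phenotype = rep(res$phenotype[i], n_d),
              founder = rep(res$id[i], n_d)))
          }
          res$licensed[done] <- FALSE
          ln$cum_ln_divisions <- ln$cum_ln_divisions + sum(done) * n_d
        }
      }
      ln$residents <- res
    }

    # egress arrivals: add T cells on the arena boundary
    adds <- list()
    q <- ln$queue
    if (tblN(q)) {
      arrive <- q$arrival_h <= ln$clock_h + 1e-9
      if (any(arrive)) {
        na <- sum(arrive)
        u <- agentRunif(run_seed, 6L, seq_len(na), rep(ln$draw_cnt, na), 1L)
        ln$draw_cnt <- ln$draw_cnt + na
        # arrivals extravasate on the tumor-bed boundary (uniform angle)
        ang <- u[, 1L] * 2 * pi
        px <- pmin(pmax(env$bed_center_um[1] +
                          env$bed_radius_um * cos(ang), 0), env$width_um)
        py <- pmin(pmax(env$bed_center_um[2] +
                          env$bed_radius_um * sin(ang), 0), env$height_um)
        fi <- which(arrive)
        for (k in seq_len(na)) {
          adds[[length(adds) + 1L]] <- list(
            store = "agents/tcells", parent = q$founder[fi[k]],
            x = px[k], y = py[k], radius = params$tcell$diameter_um / 2,
            state = list(phenotype = q$phenotype[fi[k]],
                         engaged_with = NA_real_, cum_eng_h = 0,
                         stim_count = 0L, act_clock_h = 0, refr_clock_h = 0,
                         tcr = 1, div_clock_h = 0, age_h = 0,
                         stale_count = 0L, cnt = 0))
        }
        ln$queue <- tblFilter(q, !arrive)
      }
    }
    out <- list(ln = updReplace(ln))
    if (length(adds)) out$.agents <- list(add = adds)
    out
  })
}
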