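# Shared 2D spatial environment: rigid-body positions and collisions,
# state-dependent motility, contact detection, and the gridded IFNg field
# with per-agent secretion/uptake exchange.
#
# Coordinates are continuous 2D in micrometres, origin at the lower-left
# corner; field bins are half-open [i*h, (i+1)*h). Concentrations are ng/mL;
# a bin of edge h um and nominal depth d um has volume h*h*d * 1e-12 mL.

#' Create an empty IFNg concentration field
#'
#' @param env environment parameter block (see [defaultParams()]).
#' @return matrix of zeros, `nx x ny` bins, with attributes `bin_um`,
#'   `depth_um`, and `bin_vol_mL`.
#' @export
makeField <- function(env) {
  nx <- ceiling(env$width_um / env$bin_um)
  ny <- ceiling(env$height_um / env$bin_um)
  f <- matrix(0, nx, ny)
  attr(f, "bin_um") <- env$bin_um
  attr(f, "depth_um") <- env$depth_um
  attr(f, "bin_vol_mL") <- env$bin_um^2 * env$depth_um * 1e-12
  f
}

#' Map positions to field bin indices
#' @param x,y coordinates (um).
#' @param field field matrix from [makeField()].
#' @return integer vector of linear bin indices.
#' @export
posToBin <- function(x, y, field) {
  h <- attr(field, "bin_um")
  ix <- pmin(pmax(floor(x / h), 0), nrow(field) - 1L)
  iy <- pmin(pmax(floor(y / h), 0), ncol(field) - 1L)
  as.integer(iy * nrow(field) + ix + 1L)
}

#' Diffuse and decay the IFNg field
#'
#' Explicit 5-point diffusion with zero-flux boundaries, substepped so that
#' `D * dt_sub / h^2 <= 0.25`, followed by first-order decay. With zero decay
#' total mass is conserved to floating-point accuracy. Aborts if a negative
#' concentration appears (scheme bug guard).
#'
#' @param field field matrix ([makeField()]).
#' @param dt_s timestep (s).
#' @param D_um2_s diffusion coefficient (um^2/s).
#' @param decay_per_h first-order decay rate (1/h).
#' @return updated field (attributes preserved).
#' @export
diffuseField <- function(field, dt_s, D_um2_s, decay_per_h = 0) {
  out <- diffuse_field(field, D_um2_s, attr(field, "bin_um"), dt_s,
                       decay_per_h)
  if (any(out < 0)) stop("negative concentration after diffusion")
  attributes(out) <- attributes(field)
  out
}

#' Exchange mass between agents and the field
#'
#' Secretion adds mass to the bin containing each position; uptake removes
#' `min(requested, available)` per bin (simultaneous requests within a bin
#' share the available mass proportionally) and reports granted amounts.
#'
#' @param field field matrix.
#' @param secretions table with columns `bin` (or `x`,`y`) and `ng`.
#' @param uptakes table with columns `id`, `bin` (or `x`,`y`), `ng`.
#' @return `list(field =, grants = list(id =, ng =))`.
#' @export
exchangeField <- function(field, secretions = NULL, uptakes = NULL) {
  vol <- attr(field, "bin_vol_mL")
  conc <- field
  if (!is.null(secretions) && length(secretions$ng)) {
    bin <- secretions$bin %||% posToBin(secretions$x, secretions$y, field)
    if (any(secretions$ng < 0)) stop("negative secretion amount")
    add <- numeric(length(conc))
    agg <- rowsum(secretions$ng, bin)
    add[as.integer(rownames(agg))] <- agg[, 1L]
    conc <- conc + add / vol
  }
  grants <- list(id = numeric(0), ng = numeric(0))
  if (!is.null(uptakes) && length(uptakes$ng)) {
    bin <- uptakes$bin %||% posToBin(uptakes$x, uptakes$y, field)
    if (any(uptakes$ng < 0)) stop("negative uptake request")
    req_by_bin <- rowsum(uptakes$ng, bin)
    bins <- as.integer(rownames(req_by_bin))
    avail <- conc[bins] * vol
    frac <- ifelse(req_by_bin[, 1L] > 0,
                   pmin(1, avail / req_by_bin[, 1L]), 0)
    granted <- uptakes$ng * frac[match(bin, bins)]
    take <- numeric(length(conc))
    agg <- rowsum(granted, bin)
    take[as.integer(rownames(agg))] <- agg[, 1L]
    conc <- conc - take / vol
    # grants never exceed bin content analytically; clamp rounding residue
    tol <- 1e-9 * max(conc, 1e-300)
    if (any(conc < -tol)) stop("uptake exceeded bin content")
    conc[conc < 0] <- 0
    grants <- list(id = uptakes$id, ng = unname(granted))
  }
  attributes(conc) <- attributes(field)
  list(field = conc, grants = grants)
}

#' Persistent random walk step with reflecting boundaries
#'
#' Free agents turn by Gaussian heading noise and advance `speed * dt` along
#' their heading; agents with speed 0 do not move.
#'
#' @param x,y,heading current positions (um) and headings (rad).
#' @param speed_um_min target speeds (um/min).
#' @param dt_s timestep (s).
#' @param turn_sd_rad heading noise SD per sqrt(minute).
#' @param bounds `c(xmin, xmax, ymin, ymax)`.
#' @param u uniform draw matrix (n x 2) driving the turn noise (see
#'   [agentRunif()]).
#' @return list with updated `x`, `y`, `heading`.
#' @export
moveAgents <- function(x, y, heading, speed_um_min, dt_s, turn_sd_rad,
                       bounds, u) {
  dt_min <- dt_s / 60
  n <- length(x)
  if (n == 0L) return(list(x = x, y = y, heading = heading))
  z <- boxMuller(u[, 1L], u[, 2L])
  heading <- heading + turn_sd_rad * sqrt(dt_min) * z
  step <- speed_um_min * dt_min
  nx <- x + step * cos(heading)
  ny <- y + step * sin(heading)
  refl <- function(v, lo, hi) {
    v <- ifelse(v < lo, 2 * lo - v, v)
    ifelse(v > hi, 2 * hi - v, v)
  }
  nx2 <- pmin(pmax(refl(nx, bounds[1], bounds[2]), bounds[1]), bounds[2])
  ny2 <- pmin(pmax(refl(ny, bounds[3], bounds[4]), bounds[3]), bounds[4])
  heading <- ifelse(nx != nx2, pi - heading, heading)
  heading <- ifelse(ny != ny2, -heading, heading)
  list(x = nx2, y = ny2, heading = heading)
}

#' Resolve overlaps between circular rigid bodies
#'
#' Iterative pairwise separation: overlapping pairs are pushed apart along
#' the center line, half each. After the configured iterations, residual
#' overlap above the tolerance triggers a warning (positions still returned).
#'
#' @param x,y,r circle centers and radii (um).
#' @param bounds `c(xmin, xmax, ymin, ymax)`.
#' @param iters relaxation sweeps.
#' @param overlap_tol_frac accepted residual overlap as a fraction of the
#'   smallest radius.
#' @param warn warn on non-convergence.
#' @return list with `x`, `y`, `max_overlap`.
#' @export
resolveCollisions <- function(x, y, r, bounds, iters = 4,
                              overlap_tol_frac = 0.05, warn = FALSE,
                              residual_scan = TRUE) {
  if (length(x) < 2L)
    return(list(x = x, y = y, max_overlap = 0))
  out <- relax_collisions(x, y, r, as.integer(iters),
                          bounds[1], bounds[2], bounds[3], bounds[4],
                          residual_scan)
  if (warn && out$max_overlap > overlap_tol_frac * min(r))
    warning("collision relaxation did not converge; residual overlap ",
            signif(out$max_overlap, 3), " um")
  out
}

#' Contact graph between circular agents
#'
#' Exact pairwise contacts (`distance <= r_i + r_j + tolerance`) computed
#' with a spatial hash; matches the brute-force O(n^2) scan exactly.
#'
#' @param x,y,r centers and radii (um).
#' @param tol contact tolerance (um).
#' @param focal optional integer indices: only pairs touching a focal agent
#'   are returned (pairs of two focal agents appear once).
#' @return list with `i`, `j` (indices) and `dist`; symmetric by
#'   construction, no self pairs.
#' @export
contactPairs <- function(x, y, r, tol = 0, focal = NULL) {
  m <- grid_contacts(x, y, r, tol,
                     if (is.null(focal)) integer(0) else as.integer(focal))
  list(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]), dist = m[, 3L])
}

# ---- processes -------------------------------------------------------------

#' Movement / collision / contact process ("neighbors")
#'
#' Moves motile agents (free cells: persistent random walk; engaged T cells:
#' directed toward their target so engagement is maintained), resolves
#' collisions, and publishes the T-cell contact graph.
#'
#' @param params full parameter list.
#' @param run_seed integer run seed (drives heading noise substreams).
#' @return a [processSpec()].
#' @export
neighborsProcess <- function(params, run_seed) {
  env <- params$environment
  bounds <- c(0, env$width_um, 0, env$height_um)
  processSpec("neighbors", ports = c("space", "tcells", "contacts"),
              timestep_s = params$engine$dt_s,
              update = function(view, dt_s) {
    sp <- view$space
    tc <- view$tcells
    n <- tblN(sp)
    if (n == 0L) return(list(space = updReplace(sp)))
    # target speeds: tumors 0; T cells by phenotype/engagement
    speed <- numeric(n)
    row_of <- match(tc$id, sp$id)
    if (length(row_of)) {
      eng <- !is.na(tc$engaged_with)
      pn <- tc$phenotype == "PD1neg"
      speed[row_of] <- ifelse(eng,
        ifelse(pn, params$tcell$pd1neg$speed_engaged_um_min,
                   params$tcell$pd1pos$speed_engaged_um_min),
        ifelse(pn, params$tcell$pd1neg$speed_free_um_min,
                   params$tcell$pd1pos$speed_free_um_min))
    }
    x <- sp$x; y <- sp$y; heading <- sp$heading
    mob <- which(speed > 0)
    if (length(mob)) {
      u <- agentRunif(run_seed, 2L, sp$id[mob], sp$mv_count[mob], 2L)
      mv <- moveAgents(sp$x[mob], sp$y[mob], sp$heading[mob], speed[mob],
                       dt_s, env$turn_sd_rad, bounds, u)
      x[mob] <- mv$x; y[mob] <- mv$y; heading[mob] <- mv$heading
      sp$mv_count[mob] <- sp$mv_count[mob] + 2
    }
    # engaged T cells head straight for their target (contact maintenance)
    if (length(row_of)) {
      eng_i <- which(!is.na(tc$engaged_with))
      if (length(eng_i)) {
        trow <- match(tc$engaged_with[eng_i], sp$id)
        ok <- !is.na(trow)
        ei <- row_of[eng_i[ok]]; ti <- trow[ok]
        dx <- sp$x[ti] - sp$x[ei]; dy <- sp$y[ti] - sp$y[ei]
        d <- sqrt(dx^2 + dy^2)
        gap <- d - (sp$radius[ei] + sp$radius[ti])
        step <- pmin(pmax(gap, 0), speed[ei] * dt_s / 60)
        mvx <- ifelse(d > 1e-9, dx / d, 0) * step
        mvy <- ifelse(d > 1e-9, dy / d, 0) * step
        x[ei] <- sp$x[ei] + mvx
        y[ei] <- sp$y[ei] + mvy
        heading[ei] <- atan2(dy, dx)
      }
    }
    rc <- resolveCollisions(x, y, sp$radius, bounds,
                            iters = env$collision_iters,
                            overlap_tol_frac = env$overlap_tol_frac,
                            residual_scan = FALSE)
    sp$x <- rc$x; sp$y <- rc$y; sp$heading <- heading
    sp$speed <- speed
    focal <- which(sp$class != "tumor")
    ct <- if (length(focal))
      contactPairs(sp$x, sp$y, sp$radius, env$contact_tol_um, focal)
    else list(i = integer(0), j = integer(0), dist = numeric(0))
    contacts <- list(i_id = sp$id[ct$i], j_id = sp$id[ct$j], dist = ct$dist)
    list(space = updReplace(sp), contacts = updReplace(contacts))
  })
}

#' IFNg field process (exchange + diffusion + decay)
#'
#' Consumes the secretion and uptake-request mailboxes, performs the
#' exchange (uptake capped at bin content, shared proportionally), grants
#' uptaken mass back to the requesting agents, then diffuses and decays the
#' field. Mass is exactly conserved: field(t+dt) = field(t) + secreted -
#' granted - decayed (diffusion is conservative).
#'
#' @param params full parameter list.
#' @return a [processSpec()].
#' @export
fieldProcess <- function(params) {
  env <- params$environment
  processSpec("diffusion",
              ports = c("field", "secretion", "uptake", "grant"),
              timestep_s = params$engine$dt_s,
              update = function(view, dt_s) {
    f <- view$field
    vol <- attr(f, "bin_vol_mL")
    # secretion mailbox: matrix of ng per bin
    if (any(view$secretion != 0)) f <- f + view$secretion / vol
    grants <- list(id = numeric(0), ng = numeric(0))
    if (length(view$uptake$ng)) {
      ex <- exchangeField(f, uptakes = view$uptake)
      f <- ex$field
      grants <- ex$grants
    }
    f <- diffuseField(f, dt_s, env$D_um2_s, env$decay_per_h)
    list(field = updReplace(f),
         secretion = updReplace(view$secretion * 0),
         uptake = updReplace(emptyTbl(c(id = "numeric", bin = "integer",
                                        ng = "numeric"))),
         grant = updAppend(grants))
  })
}
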