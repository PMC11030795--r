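# Post-run statistics: cytotoxicity against a no-T-cell control, phenotype
# time courses, death accounting, exponential growth fits, k-NN multicellular
# neighborhood analysis, and simple snapshot rendering.

#' @keywords internal
aliveTumor <- function(traj) traj$summary$tumor_PDL1neg +
  traj$summary$tumor_PDL1pos

#' Cytotoxicity relative to a no-T-cell control
#'
#' `cytotoxicity(t) = 1 - A_T(t) / A_C(t)` where `A` is the mean alive tumor
#' count across replicates; an alive-count ratio, invariant to proportional
#' scaling of both arms, defined only where the control count is positive.
#'
#' @param treated,control `simTrajectory` objects or lists of replicates
#'   sharing the emit grid and initial tumor count.
#' @return data.frame with `time_h` and `cytotoxicity`.
#' @export
cytotoxicity <- function(treated, control) {
  as_list <- function(x) if (inherits(x, "simTrajectory")) list(x) else x
  treated <- as_list(treated); control <- as_list(control)
  tt <- treated[[1]]$summary$time_h
  for (tr in c(treated, control))
    if (!isTRUE(all.equal(tr$summary$time_h, tt)))
      stop("mismatched emit grids")
  a_t <- rowMeans(sapply(treated, aliveTumor))
  a_c <- rowMeans(sapply(control, aliveTumor))
  ok <- a_c > 0
  data.frame(time_h = tt[ok], cytotoxicity = 1 - a_t[ok] / a_c[ok])
}

#' Alive counts and cumulative deaths by phenotype over time
#'
#' @param traj a `simTrajectory`.
#' @return data.frame in long format: `time_h`, `class`, `phenotype`,
#'   `alive`, plus cumulative deaths by cause (`deaths_<cause>` columns,
#'   per class, repeated across that class's phenotypes).
#' @export
countsByPhenotype <- function(traj) {
  s <- traj$summary
  long <- rbind(
    data.frame(time_h = s$time_h, class = "tumors", phenotype = "PDL1neg",
               alive = s$tumor_PDL1neg),
    data.frame(time_h = s$time_h, class = "tumors", phenotype = "PDL1pos",
               alive = s$tumor_PDL1pos),
    data.frame(time_h = s$time_h, class = "tcells", phenotype = "PD1neg",
               alive = s$tcell_PD1neg),
    data.frame(time_h = s$time_h, class = "tcells", phenotype = "PD1pos",
               alive = s$tcell_PD1pos))
  ev <- traj$events[traj$events$kind == "death", , drop = FALSE]
  for (cz in c("cytotoxic", "intrinsic", "pd1_apoptosis")) {
    col <- paste0("deaths_", cz)
    long[[col]] <- vapply(seq_len(nrow(long)), function(i)
      sum(ev$class == long$class[i] & ev$cause == cz &
            ev$time_h <= long$time_h[i] + 1e-9), 0)
  }
  long
}

#' Cumulative death counts by class and cause at a time point
#' @param traj a `simTrajectory`.
#' @param time_h evaluation time (default: end of run).
#' @param class agent class (`"tumors"` or `"tcells"`).
#' @return named vector of cumulative deaths by cause.
#' @export
deathCounts <- function(traj, time_h = Inf, class = "tumors") {
  ev <- traj$events
  ev <- ev[ev$kind == "death" & ev$class == class &
             ev$time_h <= time_h + 1e-9, , drop = FALSE]
  if (!nrow(ev)) return(stats::setNames(numeric(0), character(0)))
  tapply(rep(1, nrow(ev)), ev$cause, sum)
}

#' Fit an exponential growth rate
#'
#' Least-squares slope of `log(count)` against time over a window.
#'
#' @param traj a `simTrajectory`, or a data.frame with `time_h` and `count`.
#' @param window `c(t0, t1)` in hours (default: full range).
#' @return growth rate in 1/h.
#' @export
fitGrowthRate <- function(traj, window = NULL) {
  d <- if (inherits(traj, "simTrajectory"))
    data.frame(time_h = traj$summary$time_h, count = aliveTumor(traj))
  else traj
  if (!is.null(window))
    d <- d[d$time_h >= window[1] & d$time_h <= window[2], , drop = FALSE]
  if (any(d$count <= 0)) stop("counts must be positive over the fit window")
  unname(stats::coef(stats::lm(log(count) ~ time_h, data = d))[2])
}

#' k-nearest-neighbor window composition
#'
#' For each cell, the window is the index cell plus its `k - 1` nearest
#' neighbors (Euclidean distance, ties broken by lower agent id/index;
#' `include_self = FALSE` uses the `k` nearest neighbors excluding the index
#' cell). Rows are label fractions summing to 1.
#'
#' @param x,y coordinates.
#' @param labels cell labels (factor or character).
#' @param k window size (default 10).
#' @param include_self include the index cell in its window.
#' @return matrix `n x nlevels` of fractions; rownames are cell indices.
#' @export
knnWindows <- function(x, y, labels, k = 10, include_self = TRUE) {
  n <- length(x)
  if (n < k) stop("fewer than k cells")
  labels <- factor(labels)
  lev <- levels(labels)
  out <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  take <- if (include_self) k else k + 1L  # self then dropped
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- outer(x[idx], x, `-`)^2 + outer(y[idx], y, `-`)^2
    for (r in seq_along(idx)) {
      i <- idx[r]
      dd <- d2[r, ]
      ord <- order(dd, seq_len(n))          # ties -> lower index
      sel <- ord[seq_len(take)]
      if (!include_self) sel <- setdiff(sel, i)[seq_len(k)]
      tab <- tabulate(as.integer(labels[sel]), nbins = length(lev))
      out[i, ] <- tab / k
    }
  }
  out
}

#' @keywords internal
kmeansPlusPlus <- function(xm, k) {
  n <- nrow(xm)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((xm - xm[rep(centers[1], n), , drop = FALSE])^2)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = p)
    nd <- rowSums((xm - xm[rep(centers[j], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  xm[centers, , drop = FALSE]
}

#' Cluster neighborhood compositions
#'
#' k-means over window composition vectors (k-means++ initialization, 10
#' restarts, fixed seed); labels are arbitrary up to permutation and should
#' be compared across runs with a permutation-invariant index.
#'
#' @param compositions matrix from [knnWindows()].
#' @param n_clusters number of neighborhoods (default 5).
#' @param seed RNG seed.
#' @param nstart restarts.
#' @return `neighborhoodResult`: list with `labels` (1-based), `centroids`,
#'   and `composition`.
#' @export
clusterNeighborhoods <- function(compositions, n_clusters = 5, seed = 1,
                                 nstart = 10) {
  if (nrow(compositions) < n_clusters) stop("fewer rows than clusters")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    km <- stats::kmeans(compositions,
                        centers = kmeansPlusPlus(unique(compositions),
                                                 n_clusters),
                        iter.max = 100)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(labels = unname(best$cluster), centroids = best$centers,
                 composition = compositions),
            class = "neighborhoodResult")
}

#' @export
print.neighborhoodResult <- function(x, ...) {
  cat("neighborhoodResult:", nrow(x$composition), "cells,",
      nrow(x$centroids), "neighborhoods\n")
  invisible(x)
}

#' Render a simulation snapshot
#'
#' Circles colored by class and phenotype over a heat layer of the IFNg
#' field; larger circles are tumor cells, smaller circles are T cells.
#' Purely for inspection; no quantities should be read from the image.
#'
#' @param state state tree (e.g. `traj$final_state`).
#' @param file optional PNG path; if `NULL`, draws on the current device.
#' @param width_px,height_px PNG size.
#' @return (invisibly) metadata: agent counts by class and phenotype and the
#'   color key covering all five phenotype classes.
#' @export
renderSnapshot <- function(state, file = NULL, width_px = 800,
                           height_px = 800) {
  cols <- c(tumors.PDL1neg = "salmon", tumors.PDL1pos = "lightblue3",
            tcells.PD1neg = "blue3", tcells.PD1pos = "green3",
            dc = "orange")
  f <- state$fields$ifng
  h <- attr(f, "bin_um")
  sp <- state$space
  if (!is.null(file)) grDevices::png(file, width_px, height_px)
  graphics::image(x = (seq_len(nrow(f)) - 0.5) * h,
                  y = (seq_len(ncol(f)) - 0.5) * h, z = f,
                  col = grDevices::hcl.colors(32, "Reds", rev = TRUE),
                  xlab = "x (um)", ylab = "y (um)", useRaster = TRUE)
  if (tblN(sp)) {
    key <- paste(sp$class, c(state$agents$tcells$phenotype,
                             state$agents$tumors$phenotype)[
                   match(sp$id, c(state$agents$tcells$id,
                                  state$agents$tumors$id))], sep = ".")
    graphics::symbols(sp$x, sp$y, circles = sp$radius, inches = FALSE,
                      add = TRUE, fg = "grey30", bg = cols[key])
  }
  dcs <- state$lymph_node$dcs
  if (tblN(dcs) && any(dcs$location == "tumor")) {
    i <- dcs$location == "tumor"
    graphics::symbols(dcs$x[i], dcs$y[i], circles = rep(6, sum(i)),
                      inches = FALSE, add = TRUE, bg = cols["dc"])
  }
  graphics::legend("topright", legend = names(cols), pt.bg = cols,
                   pch = 21, cex = 0.7, bg = "white")
  if (!is.null(file)) grDevices::dev.off()
  meta <- list(
    n_agents = tblN(sp),
    counts = c(table(c(paste("tcells", state$agents$tcells$phenotype),
                       paste("tumors", state$agents$tumors$phenotype)))),
    colors = cols)
  invisible(meta)
}
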