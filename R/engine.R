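# Minimal compositional simulation kernel: "processes" compute updates against
# shared "stores" through declared ports; updates are computed synchronously
# against a frozen pre-step snapshot and then applied (replacements first, then
# additive/append deltas, then agent removals, then agent additions). Agents
# can be added (division, egress) and removed (death) mid-simulation.

# ---- agent tables (plain lists of equal-length column vectors) -------------

#' Number of rows in an agent table
#' @param t agent table (named list of equal-length vectors).
#' @keywords internal
tblN <- function(t) if (length(t) == 0L) 0L else length(t[[1L]])

#' @keywords internal
tblFilter <- function(t, keep) lapply(t, function(col) col[keep])

#' @keywords internal
tblBind <- function(a, b) {
  if (tblN(a) == 0L) return(b)
  if (tblN(b) == 0L) return(a)
  mapply(function(x, y) c(x, y), a, b[names(a)], SIMPLIFY = FALSE)
}

#' @keywords internal
emptyTbl <- function(cols) {
  out <- lapply(cols, function(cl) vector(cl, 0L))
  names(out) <- names(cols)
  out
}

# ---- store paths -----------------------------------------------------------

#' @keywords internal
getPath <- function(state, path) {
  for (p in strsplit(path, "/", fixed = TRUE)[[1L]]) {
    if (is.null(state) || is.null(state[[p]])) return(NULL)
    state <- state[[p]]
  }
  state
}

#' @keywords internal
setPath <- function(state, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  rec <- function(node, i) {
    if (i > length(parts)) return(value)
    node[[parts[i]]] <- rec(node[[parts[i]]], i + 1L)
    node
  }
  rec(state, 1L)
}

# ---- updates ---------------------------------------------------------------

#' Update constructors
#'
#' A process update maps each of its ports to either an additive delta
#' (numeric vectors/matrices, added elementwise), an append delta (rows bound
#' onto a table store), or a replacement. Deltas from different processes on
#' the same variable are additive; at most one process may replace a given
#' variable per step. Replacements are applied before deltas, which is what
#' lets a consumer reset a "mailbox" store in the same step that producers
#' append to it.
#'
#' @param x delta or replacement value; for [updAppend()] a table of rows.
#' @return a tagged update component.
#' @export
updDelta <- function(x) structure(list(x = x), class = "upd_delta")

#' @rdname updDelta
#' @export
updReplace <- function(x) structure(list(x = x), class = "upd_replace")

#' @rdname updDelta
#' @export
updAppend <- function(x) structure(list(x = x), class = "upd_append")

# ---- process / composite ---------------------------------------------------

#' Declare a simulation process
#'
#' @param name identifier.
#' @param ports character vector of port names; each must be wired to a store
#'   path by the topology passed to [compose()].
#' @param update function `(view, dt_s)` returning a named list of update
#'   components (see [updDelta()]) over declared ports, plus an optional
#'   `.agents` element: `list(add = list(...), remove = list(...))` where each
#'   `add` is `list(store =, parent =, x =, y =, radius =, state = list(...))`
#'   and each `remove` is `list(store =, ids =, cause =)`.
#' @param timestep_s preferred update interval in seconds; must be a multiple
#'   of the composite's global step.
#' @return a `processSpec` object.
#' @export
processSpec <- function(name, ports, update, timestep_s = 60) {
  stopifnot(is.character(name), length(name) == 1L, is.function(update),
            timestep_s > 0)
  structure(list(name = name, ports = ports, update = update,
                 timestep_s = timestep_s),
            class = "processSpec")
}

#' Wire processes and stores into a runnable composite
#'
#' @param processes list of [processSpec()] objects.
#' @param topology named list: `topology[[process]][[port]]` is a `/`-separated
#'   store path into the state tree.
#' @param initial initial state tree (nested named list).
#' @param dt_s global timestep in seconds (default 60).
#' @param agent_stores character vector of store paths holding agent tables
#'   (each with an `id` column) that participate in engine-level add/remove.
#' @param space_store optional path of the shared spatial store whose rows
#'   (id, class, x, y, radius, ...) mirror the agent stores.
#' @param next_id first id handed to newly added agents.
#' @param summarize optional function `(state, clock_h)` returning a named
#'   list of scalars recorded at every emit.
#' @return a `simComposite` environment.
#' @export
compose <- function(processes, topology, initial, dt_s = 60,
                    agent_stores = character(), space_store = NULL,
                    next_id = 1L, summarize = NULL) {
  names(processes) <- vapply(processes, function(p) p$name, "")
  unbound <- character()
  for (p in processes) {
    top <- topology[[p$name]]
    for (port in p$ports) {
      path <- top[[port]]
      if (is.null(path)) {
        unbound <- c(unbound, paste0(p$name, ":", port))
      } else if (is.null(getPath(initial, path))) {
        stop("topology path does not resolve: ", p$name, ":", port,
             " -> ", path)
      }
    }
    if (p$timestep_s < dt_s || abs(p$timestep_s / dt_s -
                                   round(p$timestep_s / dt_s)) > 1e-9)
      stop("process timestep must be a multiple of the global step: ", p$name)
  }
  if (length(unbound))
    stop("unbound ports: ", paste(unbound, collapse = ", "))
  ids <- unlist(lapply(agent_stores, function(s) getPath(initial, s)$id))
  if (anyDuplicated(ids)) stop("duplicate agent id in initial state")
  comp <- new.env(parent = emptyenv())
  comp$processes <- processes
  comp$topology <- topology
  comp$state <- initial
  comp$dt_s <- dt_s
  comp$acc <- stats::setNames(rep(0, length(processes)), names(processes))
  comp$clock_h <- 0
  comp$agent_stores <- agent_stores
  comp$space_store <- space_store
  comp$next_id <- next_id
  comp$events <- list()
  comp$summarize <- summarize
  class(comp) <- "simComposite"
  comp
}

#' @export
print.simComposite <- function(x, ...) {
  cat("simComposite:", length(x$processes), "process(es), clock",
      round(x$clock_h, 3), "h,", x$next_id - 1L, "ids assigned\n")
  invisible(x)
}

#' Advance a composite by one global step
#'
#' All processes whose timers elapse compute updates against the frozen
#' pre-step state; updates are then applied synchronously and the clock
#' advances by `dt_s`.
#'
#' @param comp a `simComposite`.
#' @param dt_s step in seconds (default the composite's global step).
#' @return the composite, invisibly (state mutated in place).
#' @export
stepComposite <- function(comp, dt_s = comp$dt_s) {
  stopifnot(dt_s > 0)
  snap <- comp$state
  updates <- list()
  for (nm in names(comp$processes)) {
    p <- comp$processes[[nm]]
    comp$acc[[nm]] <- comp$acc[[nm]] + dt_s
    if (comp$acc[[nm]] + 1e-9 >= p$timestep_s) {
      comp$acc[[nm]] <- comp$acc[[nm]] - p$timestep_s
      view <- lapply(comp$topology[[nm]][p$ports], function(path)
        getPath(snap, path))
      names(view) <- p$ports
      upd <- p$update(view, p$timestep_s)
      extra <- setdiff(setdiff(names(upd), ".agents"), p$ports)
      if (length(extra))
        stop("process '", nm, "' updated undeclared port(s): ",
             paste(extra, collapse = ", "))
      updates[[nm]] <- upd
    }
  }
  state <- snap
  # replacements (unique per variable)
  replaced <- character()
  for (nm in names(updates)) {
    upd <- updates[[nm]]
    for (port in setdiff(names(upd), ".agents")) {
      u <- upd[[port]]
      if (inherits(u, "upd_replace")) {
        path <- comp$topology[[nm]][[port]]
        if (path %in% replaced)
          stop("conflicting replacements on variable: ", path)
        replaced <- c(replaced, path)
        state <- setPath(state, path, u$x)
      }
    }
  }
  # additive / append deltas
  for (nm in names(updates)) {
    upd <- updates[[nm]]
    for (port in setdiff(names(upd), ".agents")) {
      u <- upd[[port]]
      path <- comp$topology[[nm]][[port]]
      if (inherits(u, "upd_delta")) {
        state <- setPath(state, path, getPath(state, path) + u$x)
      } else if (inherits(u, "upd_append")) {
        state <- setPath(state, path, tblBind(getPath(state, path), u$x))
      }
    }
  }
  t_now <- comp$clock_h + dt_s / 3600
  # removals
  for (nm in names(updates)) {
    ag <- updates[[nm]][[".agents"]]
    for (rm in ag$remove) {
      store <- getPath(state, rm$store)
      keep <- !(store$id %in% rm$ids)
      state <- setPath(state, rm$store, tblFilter(store, keep))
      if (!is.null(comp$space_store)) {
        sp <- getPath(state, comp$space_store)
        state <- setPath(state, comp$space_store,
                         tblFilter(sp, !(sp$id %in% rm$ids)))
      }
      comp$events[[length(comp$events) + 1L]] <- list(
        time_h = rep(t_now, length(rm$ids)), kind = rep("death", length(rm$ids)),
        class = rep(basename(rm$store), length(rm$ids)), id = rm$ids,
        parent = rep(NA_real_, length(rm$ids)),
        cause = rep(rm$cause, length.out = length(rm$ids)))
    }
  }
  # additions (deterministic order independent of process evaluation order)
  adds <- list()
  for (nm in names(updates)) adds <- c(adds, updates[[nm]][[".agents"]]$add)
  if (length(adds)) {
    key <- order(vapply(adds, function(a) a$store, ""),
                 vapply(adds, function(a) as.numeric(a$parent %||% 0), 0))
    for (a in adds[key]) {
      id <- comp$next_id
      comp$next_id <- comp$next_id + 1L
      store <- getPath(state, a$store)
      row <- c(list(id = id), a$state)
      state <- setPath(state, a$store, tblBind(store, row[names(store)]))
      if (!is.null(comp$space_store)) {
        sp <- getPath(state, comp$space_store)
        sprow <- list(id = id, class = basename(a$store), x = a$x, y = a$y,
                      radius = a$radius, heading = 0, speed = 0, mv_count = 0)
        state <- setPath(state, comp$space_store, tblBind(sp, sprow[names(sp)]))
      }
      comp$events[[length(comp$events) + 1L]] <- list(
        time_h = t_now, kind = "division", class = basename(a$store), id = id,
        parent = as.numeric(a$parent %||% NA_real_), cause = NA_character_)
    }
  }
  comp$state <- state
  comp$clock_h <- t_now
  invisible(comp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a composite and record a trajectory
#'
#' @param comp a `simComposite`.
#' @param duration_h simulated duration in hours.
#' @param emit_interval_h interval between recorded snapshots (hours); the
#'   trajectory contains records at t = 0 and every emit interval.
#' @param record_agents if `TRUE`, keep full agent-table snapshots at each
#'   emit time (memory-heavy on long runs).
#' @param record_field if `TRUE`, keep the concentration grid at each emit.
#' @return a `simTrajectory`: summary table, event log, optional snapshots.
#' @export
runComposite <- function(comp, duration_h, emit_interval_h = 1.5,
                         record_agents = FALSE, record_field = FALSE) {
  stopifnot(duration_h > 0, emit_interval_h <= duration_h)
  dt_s <- comp$dt_s
  n_steps <- round(duration_h * 3600 / dt_s)
  emit_every <- max(1L, round(emit_interval_h * 3600 / dt_s))
  summaries <- list()
  snapshots <- list()
  fields <- list()
  emit <- function() {
    k <- length(summaries) + 1L
    if (!is.null(comp$summarize))
      summaries[[k]] <<- c(list(time_h = comp$clock_h),
                           comp$summarize(comp$state, comp$clock_h))
    else summaries[[k]] <<- list(time_h = comp$clock_h)
    if (record_agents)
      snapshots[[k]] <<- list(
        stores = stats::setNames(lapply(comp$agent_stores, function(s)
          getPath(comp$state, s)), comp$agent_stores),
        space = if (!is.null(comp$space_store))
          getPath(comp$state, comp$space_store))
    if (record_field) fields[[k]] <<- getPath(comp$state, "fields/ifng")
  }
  emit()
  for (s in seq_len(n_steps)) {
    stepComposite(comp, dt_s)
    # emit on the grid, and always record the final state
    if (s %% emit_every == 0L || s == n_steps) emit()
  }
  ev <- comp$events
  events <- if (length(ev)) {
    as.data.frame(lapply(stats::setNames(nm = names(ev[[1L]])), function(cn)
      unlist(lapply(ev, `[[`, cn), use.names = FALSE)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(time_h = numeric(), kind = character(), class = character(),
               id = numeric(), parent = numeric(), cause = character(),
               stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(s, stringsAsFactors = FALSE)))
  structure(list(summary = summary, events = events, snapshots = snapshots,
                 fields = fields, final_state = comp$state,
                 dt_s = dt_s, duration_h = duration_h,
                 emit_interval_h = emit_interval_h),
            class = "simTrajectory")
}

#' @export
print.simTrajectory <- function(x, ...) {
  cat("simTrajectory:", nrow(x$summary), "snapshots over",
      round(x$duration_h, 2), "h;", nrow(x$events), "events\n")
  invisible(x)
}
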