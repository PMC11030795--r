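#' Per-agent counter-based random numbers
#'
#' Deterministic uniform draws keyed by `(run_seed, stream, id, counter)`.
#' Every agent owns an independent substream, so creating or removing agents
#' never perturbs any other agent's randomness, and process evaluation order
#' cannot change the result. `stream` separates the consumers (e.g. the T cell
#' process vs. the movement process) drawing for the same agent.
#'
#' @param run_seed integer run seed.
#' @param stream integer stream id (one per consuming process).
#' @param id numeric vector of agent ids.
#' @param counter numeric vector of per-agent draw counters (advanced by the
#'   caller after use, by at least `k`).
#' @param k number of draws per agent.
#' @return an `n x k` matrix of uniforms in (0, 1).
#' @export
agentRunif <- function(run_seed, stream, id, counter, k = 1L) {
  if (length(id) == 0L) return(matrix(numeric(0), 0L, k))
  hash_runif(as.numeric(run_seed), as.numeric(stream), as.numeric(id),
             as.numeric(counter), as.integer(k))
}

#' Standard normal draws from two uniform columns (Box-Muller)
#' @param u1,u2 uniform vectors in (0, 1).
#' @return numeric vector of standard normals.
#' @keywords internal
boxMuller <- function(u1, u2) {
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}
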