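#' Update the current vector with a step displacement
#'
#' The path integrator continuously accumulates the agent's displacements
#' into a "current vector" referenced to the nest. It keeps running during
#' search and landmark-guided walking and is reset to zero exactly and only
#' when the agent enters the nest. Passive displacement (capture and
#' transport by the experimenter) does not pass through this function, so a
#' transported agent keeps its pre-capture current vector.
#'
#' @param current the current vector, a [polar_vector()].
#' @param displacement the step displacement, a [polar_vector()] (10 length
#'   units per step for an actively walking agent).
#' @return the updated current vector.
#' @export
update_current <- function(current, displacement) {
  stopifnot(inherits(current, "polar_vector"),
            inherits(displacement, "polar_vector"))
  pv_add(current, displacement)
}

#' Create an empty bank of reference-vector memories
#'
#' One slot per known food source. A slot holds the nest-to-food vector
#' stored the moment food was found there ("reference vector") or `NULL`
#' before any successful visit.
#'
#' @param source_ids character vector of food-source ids.
#' @return a named list of class `reference_memories`.
#' @export
reference_memories <- function(source_ids) {
  stopifnot(is.character(source_ids), !anyDuplicated(source_ids))
  m <- stats::setNames(vector("list", length(source_ids)), source_ids)
  structure(m, class = "reference_memories")
}

#' Store the current vector as a reference vector
#'
#' Triggered by finding food at a rewarding source: the momentary current
#' vector is copied into that source's long-term slot, overwriting any
#' earlier value. No reward, no store.
#'
#' @param memories a [reference_memories()] bank.
#' @param source_id id of the source where food was found.
#' @param current the current vector at the moment of the find.
#' @return the updated bank.
#' @export
store_reference <- function(memories, source_id, current) {
  stopifnot(inherits(memories, "reference_memories"),
            inherits(current, "polar_vector"))
  if (!source_id %in% names(memories))
    stop(sprintf("unknown food source id '%s'", source_id))
  memories[[source_id]] <- polar_vector(current$angle, current$length)
  memories
}

#' Gated reference-vector output
#'
#' Reference memories are gated by the motivation network: a memory emits
#' its stored vector only while both the outbound motivation and the
#' motivation for its own source are above the gate threshold. In every
#' other state (notably the whole inbound leg) the gated output is the zero
#' vector, which makes the nest the goal; this is how the sign reversal of
#' the home vector is realized.
#'
#' @param memories a [reference_memories()] bank.
#' @param motivation named activation vector (see [motivation_state()]).
#' @param threshold gate threshold on activations (default 0.5).
#' @return a [polar_vector()]: the active source's reference vector, or the
#'   zero vector.
#' @export
gated_reference <- function(memories, motivation, threshold = 0.5) {
  stopifnot(inherits(memories, "reference_memories"))
  if (motivation[["outbound"]] < threshold) return(polar_vector(0, 0))
  for (id in names(memories)) {
    unit <- paste0("source", id)
    if (unit %in% names(motivation) &&
        motivation[[unit]] >= threshold &&
        !is.null(memories[[id]]))
      return(memories[[id]])
  }
  polar_vector(0, 0)
}

#' Path-integrator procedure output
#'
#' Subtracts the current vector from the (gated) reference vector. The
#' direction of the difference is the proposed walking direction; the
#' emitted length is normalized to 1, except that when the difference is
#' shorter than `eps_pi` the output length is 0: the integrator is in its
#' zero state ("zero-vector" agent) and proposes no direction, letting the
#' search generator take over.
#'
#' @param reference the gated reference vector (zero vector when inbound).
#' @param current the current vector.
#' @param eps_pi zero-state radius in length units (default 1, a tenth of a
#'   step: below this the difference direction is noise-dominated).
#' @return a [polar_vector()] with length 1 or 0.
#' @export
#' @examples
#' # inbound agent 100 units east of the nest points home (west):
#' pi_output(polar_vector(0, 0), polar_vector(0, 100))
pi_output <- function(reference, current, eps_pi = 1.0) {
  stopifnot(inherits(reference, "polar_vector"),
            inherits(current, "polar_vector"))
  diff <- pv_sub(reference, current)
  if (diff$length < eps_pi) return(polar_vector(diff$angle, 0))
  polar_vector(diff$angle, 1)
}
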