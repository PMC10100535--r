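#' Partition the system into QM and MM regions
#'
#' Validates a two-region split of the coordinate vector: the QM (solute)
#' indices and their complement, the MM (environment) indices.  Indices are
#' 1-based positions in the flat coordinate vector.
#'
#' @param total_dof Total number of degrees of freedom.
#' @param qm_indices Integer vector of QM degrees of freedom; non-empty,
#'   in range, duplicate-free.
#' @return An object of class `region_partition` with `qm_indices`,
#'   `mm_indices`, `total_dof`.
#' @export
#' @examples
#' partition_system(9, 1:3)
partition_system <- function(total_dof, qm_indices) {
  total_dof <- as.integer(total_dof)
  qm_indices <- as.integer(qm_indices)
  if (length(qm_indices) == 0) stop("QM region must be non-empty")
  bad <- qm_indices[qm_indices < 1L | qm_indices > total_dof]
  if (length(bad) > 0)
    stop("QM index out of range [1, ", total_dof, "]: ", bad[1])
  dup <- qm_indices[duplicated(qm_indices)]
  if (length(dup) > 0)
    stop("duplicate QM index: ", dup[1])
  structure(list(qm_indices = qm_indices,
                 mm_indices = setdiff(seq_len(total_dof), qm_indices),
                 total_dof = total_dof),
            class = "region_partition")
}

#' Subtractive QM/MM energy and gradient
#'
#' Combines a high-level engine on the QM region with a low-level engine on
#' the full system by the subtractive scheme:
#' `E = E(full, low) - E(QM, low) + E(QM, high)`,
#' with the gradient combined by the same signs (low-level full-system
#' gradient over all DOFs; the QM-region terms scattered onto the QM
#' indices).  Forces are the negative of the combined gradient.
#'
#' Engines are closures `function(positions) -> list(energy, gradient)`
#' evaluable both on the full coordinate vector and on the QM subvector;
#' the high-level engine is typically state-specific (an excited-state
#' surface closure built with [qm_state_engine()]).  Embedding is
#' mechanical: the high-level engine never sees the environment.
#'
#' @param partition A `region_partition`.
#' @param high_engine High-level engine, called on the QM subvector.
#' @param low_engine Low-level engine, called on the full vector and on the
#'   QM subvector.
#' @param state A phase-space state (see [phase_space_state()]) carrying the
#'   current positions, or a bare numeric position vector of length
#'   `partition$total_dof`.
#' @return An object of class `subtractive_energy`: `e_full_low`,
#'   `e_qm_low`, `e_qm_high`, `e_total` (eV) and `gradient_total`
#'   (eV/A, length `total_dof`).
#' @export
subtractive_energy_and_gradient <- function(partition, high_engine,
                                            low_engine, state) {
  stopifnot(inherits(partition, "region_partition"))
  x <- if (is.list(state)) state$positions else as.numeric(state)
  if (length(x) != partition$total_dof)
    stop("state has ", length(x), " coordinates; partition expects ",
         partition$total_dof)
  qm <- partition$qm_indices

  full_low <- .eval_engine(low_engine, x, "low level, full system")
  qm_low <- .eval_engine(low_engine, x[qm], "low level, QM region")
  qm_high <- .eval_engine(high_engine, x[qm], "high level, QM region")

  g <- full_low$gradient
  g[qm] <- g[qm] - qm_low$gradient + qm_high$gradient

  structure(list(
    e_full_low = full_low$energy,
    e_qm_low = qm_low$energy,
    e_qm_high = qm_high$energy,
    e_total = full_low$energy - qm_low$energy + qm_high$energy,
    gradient_total = g
  ), class = "subtractive_energy")
}

.eval_engine <- function(engine, x, what) {
  res <- tryCatch(engine(x), error = function(e)
    stop("engine failure (", what, "): ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(res) || is.null(res$energy) || is.null(res$gradient))
    stop("engine (", what, ") must return list(energy, gradient)")
  if (length(res$gradient) != length(x))
    stop("engine (", what, ") returned gradient of length ",
         length(res$gradient), ", expected ", length(x))
  res
}

#' State-specific high-level engine from a model surface
#'
#' Wraps a `model_surface` as an engine closure returning the adiabatic
#' energy and gradient of one electronic state, for use as the high-level
#' side of [subtractive_energy_and_gradient()].
#'
#' @param model A `model_surface`.
#' @param surface 0-based electronic state label (0 = ground state).
#' @return A function `(positions) -> list(energy, gradient)`.
#' @export
qm_state_engine <- function(model, surface = 0L) {
  stopifnot(inherits(model, "model_surface"),
            surface >= 0, surface < model$n_states)
  i <- as.integer(surface) + 1L
  function(positions) {
    es <- evaluate_surface(model, positions)
    list(energy = es$energies[i], gradient = es$gradients[i, ])
  }
}

#' Zero engine
#'
#' An engine returning zero energy and gradient for any input; the vacuum
#' (gas-phase) limit of the low level.
#'
#' @return A function `(positions) -> list(energy, gradient)`.
#' @export
zero_engine <- function() {
  function(positions) list(energy = 0,
                           gradient = numeric(length(positions)))
}
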