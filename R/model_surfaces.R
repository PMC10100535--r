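#' Analytic multi-state diabatic model surfaces
#'
#' Constructs an avoided-crossing model: a smooth real symmetric diabatic
#' potential matrix V(R) whose eigendecomposition yields adiabatic surfaces,
#' exact adiabatic gradients, and exact nonadiabatic coupling vectors via the
#' Hellmann-Feynman expression.  Diagonal elements are
#' linear-plus-harmonic in each nuclear degree of freedom,
#' `V_dd(R) = e0 + sum_i a_i (R_i - r0_i) + 0.5 k_i (R_i - r0_i)^2`,
#' and off-diagonal couplings are Gaussians
#' `V_de(R) = amp * exp(-sum_i (R_i - rc_i)^2 / (2 w_i^2))`,
#' a Tully-style form for which every downstream quantity is analytic.
#'
#' Electronic states are labelled 0-based throughout the package (S0 is
#' state 0, the second excited state is state 2), matching the usual
#' photochemistry notation.
#'
#' @param n_states Number of adiabatic states, 2 or 3.
#' @param params Optional list overriding the built-in default model:
#'   `n_dof`, `masses` (amu, recycled to `n_dof`), `states` (one list per
#'   diabatic state with `e0` eV, `a` eV/A, `k` eV/A^2, `r0` A), `couplings`
#'   (each with `states` = 0-based pair, `amp` eV, `rc` A, `w` A), and
#'   `f_diab` (surrogate oscillator strength per diabatic state).
#' @param seed Optional integer; when given, well depths and coupling centres
#'   receive a small reproducible jitter, for generating model families in
#'   property tests.
#' @return An object of class `model_surface`.
#' @export
#' @examples
#' m <- make_avoided_crossing_model(2)
#' es <- evaluate_surface(m, 0.3)
#' es$energies
make_avoided_crossing_model <- function(n_states = 2, params = NULL,
                                        seed = NULL) {
  stopifnot(n_states %in% c(2L, 3L))
  p <- .default_model_params(n_states)
  if (!is.null(params)) p[names(params)] <- params
  n_dof <- as.integer(p$n_dof)
  if (length(p$states) != n_states)
    stop("params$states must have one entry per diabatic state")

  states <- lapply(p$states, function(s) {
    list(e0 = s$e0,
         a  = rep_len(if (is.null(s$a)) 0 else s$a, n_dof),
         k  = rep_len(if (is.null(s$k)) 0 else s$k, n_dof),
         r0 = rep_len(if (is.null(s$r0)) 0 else s$r0, n_dof))
  })
  couplings <- lapply(p$couplings, function(cp) {
    list(states = as.integer(cp$states),
         amp = cp$amp,
         rc = rep_len(cp$rc, n_dof),
         w  = rep_len(cp$w, n_dof))
  })
  if (length(couplings) == 0 || all(vapply(couplings, function(cp) cp$amp,
                                           0) == 0))
    stop("degenerate model: all diabatic couplings are identically zero, ",
         "so no nonadiabatic transition is possible anywhere")
  for (cp in couplings) {
    if (any(cp$states < 0 | cp$states >= n_states) ||
        cp$states[1] == cp$states[2])
      stop("coupling refers to invalid state pair: ",
           paste(cp$states, collapse = ","))
    if (any(cp$w <= 0)) stop("coupling widths must be positive")
  }

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (i in seq_along(states))
      states[[i]]$e0 <- states[[i]]$e0 + stats::rnorm(1, 0, 0.02)
    for (i in seq_along(couplings))
      couplings[[i]]$rc <- couplings[[i]]$rc + stats::rnorm(n_dof, 0, 0.02)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }

  structure(list(
    n_states = as.integer(n_states),
    n_dof = n_dof,
    masses = rep_len(p$masses, n_dof),
    states = states,
    couplings = couplings,
    f_diab = rep_len(p$f_diab, n_states)
  ), class = "model_surface")
}

# Built-in defaults: a bound harmonic ground diabat crossed by one (2-state)
# or two staggered (3-state) dissociative-like linear diabats, couplings
# centred on the diabatic crossing seams.
.default_model_params <- function(n_states) {
  if (n_states == 2L) {
    # V00 = 2 R^2 crosses V11 = 2 - R at R = (-1 + sqrt(17))/4
    rc <- (-1 + sqrt(17)) / 4
    list(n_dof = 1L, masses = 12,
         states = list(list(e0 = 0, a = 0, k = 4, r0 = 0),
                       list(e0 = 2, a = -1, k = 0, r0 = 0)),
         couplings = list(list(states = c(0L, 1L), amp = 0.08,
                               rc = rc, w = 0.25)),
         f_diab = c(0, 0.7))
  } else {
    rc01 <- (-1 + sqrt(17)) / 4     # V00 x V11 seam
    rc12 <- 0.5                     # (3 - 3R) = (2 - R) seam
    list(n_dof = 1L, masses = 12,
         states = list(list(e0 = 0, a = 0, k = 4, r0 = 0),
                       list(e0 = 2, a = -1, k = 0, r0 = 0),
                       list(e0 = 3, a = -3, k = 0, r0 = 0)),
         couplings = list(list(states = c(0L, 1L), amp = 0.05,
                               rc = rc01, w = 0.3),
                          list(states = c(1L, 2L), amp = 0.05,
                               rc = rc12, w = 0.3)),
         f_diab = c(0, 0.1, 0.7))
  }
}

# Diabatic matrix and its gradient at geometry R.
# Returns list(V = n x n, dV = n x n x n_dof).
.diabatic_matrix <- function(model, R) {
  n <- model$n_states
  nd <- model$n_dof
  V <- matrix(0, n, n)
  dV <- array(0, c(n, n, nd))
  for (d in seq_len(n)) {
    s <- model$states[[d]]
    x <- R - s$r0
    V[d, d] <- s$e0 + sum(s$a * x) + 0.5 * sum(s$k * x^2)
    dV[d, d, ] <- s$a + s$k * x
  }
  for (cp in model$couplings) {
    i <- cp$states[1] + 1L
    j <- cp$states[2] + 1L
    z <- (R - cp$rc) / cp$w
    v <- cp$amp * exp(-0.5 * sum(z^2))
    g <- -v * z / cp$w
    V[i, j] <- V[i, j] + v
    V[j, i] <- V[i, j]
    dV[i, j, ] <- dV[i, j, ] + g
    dV[j, i, ] <- dV[i, j, ]
  }
  list(V = V, dV = dV)
}

#' Adiabatic energies, gradients and couplings at one geometry
#'
#' Diagonalizes the diabatic matrix at `R` and returns the full electronic
#' structure a hopping step needs: adiabatic energies in ascending order,
#' their analytic gradients `<a|dV/dR|a>`, nonadiabatic coupling vectors
#' `d_ba = <b|dV/dR|a> / (E_a - E_b)` (Hellmann-Feynman; exactly
#' antisymmetric), and surrogate oscillator strengths obtained by projecting
#' per-diabat strengths through the adiabatic mixing,
#' `f_a = sum_d C[d,a]^2 f_diab[d]`.
#'
#' If any adiabatic gap falls below `1e-10` eV the couplings of that pair are
#' undefined; the result is returned with `degenerate = TRUE` and `NA`
#' couplings for the affected pair, and the caller must handle it (the
#' hopping propagator reuses the previous step's couplings).
#'
#' @param model A `model_surface`.
#' @param R Numeric geometry vector of length `model$n_dof` (angstrom).
#' @return An object of class `el_structure` with elements `energies` (eV,
#'   ascending, one per state 0..n-1), `gradients` (n_states x n_dof, eV/A),
#'   `nac` (n_states x n_states x n_dof array, 1/A), `f`, `vectors`
#'   (diabatic-to-adiabatic eigenvector columns), `degenerate`, `R`.
#' @export
evaluate_surface <- function(model, R) {
  stopifnot(inherits(model, "model_surface"))
  R <- as.numeric(R)
  if (length(R) != model$n_dof)
    stop("geometry has ", length(R), " components; model expects ",
         model$n_dof)
  dm <- .diabatic_matrix(model, R)
  eig <- eigen(dm$V, symmetric = TRUE)
  ord <- order(eig$values)            # ascending: S0 first
  E <- eig$values[ord]
  C <- eig$vectors[, ord, drop = FALSE]

  n <- model$n_states
  nd <- model$n_dof
  grad <- matrix(0, n, nd)
  nac <- array(0, c(n, n, nd))
  # M[, , d] = C' dV_d C gives all Hellmann-Feynman matrix elements at once
  degenerate <- FALSE
  for (d in seq_len(nd)) {
    M <- crossprod(C, dm$dV[, , d] %*% C)
    grad[, d] <- diag(M)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      gap <- E[a] - E[b]
      if (abs(gap) < 1e-10) {
        nac[b, a, d] <- NA_real_
        degenerate <- TRUE
      } else {
        nac[b, a, d] <- M[b, a] / gap
      }
    }
  }
  f <- as.numeric(crossprod(C^2, model$f_diab))

  structure(list(energies = E, gradients = grad, nac = nac, f = f,
                 vectors = C, degenerate = degenerate, R = R),
            class = "el_structure")
}

#' @export
print.model_surface <- function(x, ...) {
  cat("Diabatic model surface:", x$n_states, "states,", x$n_dof,
      "nuclear DOF\n")
  cat("  masses (amu):", paste(format(x$masses), collapse = ", "), "\n")
  cat("  couplings:\n")
  for (cp in x$couplings)
    cat(sprintf("    S%d-S%d  amp %.3f eV, centre (%s) A, width (%s) A\n",
                cp$states[1], cp$states[2], cp$amp,
                paste(format(cp$rc, digits = 3), collapse = ","),
                paste(format(cp$w, digits = 3), collapse = ",")))
  invisible(x)
}
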