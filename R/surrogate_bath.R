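#' Surrogate classical solvent bath
#'
#' Builds an ensemble of soft spherical particles standing in for an
#' explicit-water MM shell: water-like masses and alternating partial
#' charges, packed without overlap in a sphere around the solute region at
#' liquid-water number density, with Maxwell-Boltzmann velocities at the
#' target temperature.  The bath interacts through a flat-bottom spherical
#' confinement, pairwise Gaussian repulsion, and a smooth charge-weighted
#' Gaussian coupling to a solute site (see [bath_low_engine()]); all terms
#' have analytic gradients.  This is a surrogate environment, not a water
#' force field: it produces realistic thermal forces and a well-defined
#' low-level energy, nothing more.
#'
#' @param n_particles Number of bath particles (>= 0).
#' @param temperature Target temperature in K (> 0).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   configuration exactly.
#' @param coupling_strength Solute-bath interaction scale in eV.
#' @param mass Per-particle mass in amu (default 18, water-like).
#' @return An object of class `solvent_bath` with `positions`/`velocities`
#'   (`n x 3` matrices, A and A/fs), `masses`, `charges`,
#'   `coupling_strength`, `temperature_target`, and the confinement radius
#'   `r_wall`.
#' @export
#' @examples
#' b <- make_solvent_bath(20, 298, seed = 1)
#' nrow(b$positions)
make_solvent_bath <- function(n_particles, temperature = 298, seed = NULL,
                              coupling_strength = 0.05, mass = 18) {
  stopifnot(n_particles >= 0, temperature > 0, mass > 0)
  n_particles <- as.integer(n_particles)
  if (!is.null(seed)) set.seed(seed)

  # water number density 0.0334 / A^3 sets the confinement radius
  r_wall <- if (n_particles > 0)
    max(4, (3 * n_particles / (4 * pi * 0.0334))^(1 / 3) + 1.3) else 4
  r_core <- 2.5      # exclusion zone around the solute site at the origin
  d_min <- 2.6       # minimum pair distance during packing

  pos <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(pos) < n_particles) {
    tries <- tries + 1L
    if (tries > 2000L * max(1L, n_particles))
      stop("bath packing failure: could not place ", n_particles,
           " particles at minimum distance ", d_min, " A within radius ",
           round(r_wall, 2), " A")
    x <- stats::runif(3, -r_wall, r_wall)
    r <- sqrt(sum(x^2))
    if (r > r_wall - 1.3 || r < r_core) next
    if (nrow(pos) > 0 &&
        min(sqrt(rowSums(sweep(pos, 2, x)^2))) < d_min) next
    pos <- rbind(pos, x)
  }
  dimnames(pos) <- NULL

  masses <- rep(mass, n_particles)
  vel <- matrix(0, n_particles, 3)
  if (n_particles > 0)
    vel[] <- .mb_velocities(rep(masses, each = 3), temperature)

  structure(list(
    n_particles = n_particles,
    positions = pos,
    velocities = vel,
    masses = masses,
    charges = if (n_particles > 0)
      rep_len(c(0.4, -0.4), n_particles) else numeric(0),
    coupling_strength = coupling_strength,
    temperature_target = temperature,
    r_wall = r_wall
  ), class = "solvent_bath")
}

#' Low-level (MM) energy engine for the surrogate bath
#'
#' Returns an engine closure `function(positions) -> list(energy, gradient)`
#' suitable as the low-level side of the subtractive QM/MM combination.
#' Given the full coordinate vector (QM degrees of freedom first, then bath
#' particles flattened row-wise) it evaluates, in eV:
#' flat-bottom confinement `0.5 k (|r_i| - r_wall)^2` outside the wall,
#' pairwise Gaussian repulsion `A exp(-|r_ij|^2 / 2 w^2)`, and solute-bath
#' coupling `c q_i exp(-|r_i - P|^2 / 2 w_c^2)` where the solute site `P` is
#' built from the first up-to-3 QM coordinates.  Given a QM-region-only
#' vector it returns zero: the low level carries no intramolecular solute
#' terms, so the subtractive scheme's QM-region low-level energy vanishes.
#'
#' @param bath A `solvent_bath`.
#' @param n_qm_dof Number of QM degrees of freedom preceding the bath block.
#' @param k_conf Confinement stiffness, eV/A^2.
#' @param a_rep,w_rep Gaussian pair repulsion amplitude (eV) and width (A).
#' @param w_coup Width of the solute-bath coupling Gaussian (A).
#' @return A function `(positions) -> list(energy, gradient)`.
#' @export
bath_low_engine <- function(bath, n_qm_dof, k_conf = 2, a_rep = 0.15,
                            w_rep = 1.2, w_coup = 2.5) {
  stopifnot(inherits(bath, "solvent_bath"))
  n_b <- bath$n_particles
  q <- bath$charges
  cs <- bath$coupling_strength
  r_wall <- bath$r_wall
  n_qm_dof <- as.integer(n_qm_dof)
  n_site <- min(3L, n_qm_dof)

  function(positions) {
    positions <- as.numeric(positions)
    if (length(positions) == n_qm_dof)   # QM region alone at the low level
      return(list(energy = 0, gradient = numeric(n_qm_dof)))
    if (length(positions) != n_qm_dof + 3L * n_b)
      stop("bath engine: expected ", n_qm_dof, " or ", n_qm_dof + 3L * n_b,
           " coordinates, got ", length(positions))
    g <- numeric(length(positions))
    if (n_b == 0) return(list(energy = 0, gradient = g))

    xb <- matrix(positions[-seq_len(n_qm_dof)], n_b, 3, byrow = TRUE)
    e <- 0

    # confinement (flat bottom inside r_wall)
    r <- sqrt(rowSums(xb^2))
    out <- r > r_wall
    if (any(out)) {
      d <- r[out] - r_wall
      e <- e + 0.5 * k_conf * sum(d^2)
      gb <- matrix(0, n_b, 3)
      gb[out, ] <- k_conf * d / r[out] * xb[out, , drop = FALSE]
      g[-seq_len(n_qm_dof)] <- g[-seq_len(n_qm_dof)] + as.numeric(t(gb))
    }

    # pairwise Gaussian repulsion
    if (n_b > 1) {
      gb <- matrix(0, n_b, 3)
      for (i in seq_len(n_b - 1L)) {
        dx <- sweep(xb[(i + 1L):n_b, , drop = FALSE], 2, xb[i, ])
        r2 <- rowSums(dx^2)
        v <- a_rep * exp(-0.5 * r2 / w_rep^2)
        e <- e + sum(v)
        gpair <- -(v / w_rep^2) * dx          # dE/d(x_j), j > i
        gb[(i + 1L):n_b, ] <- gb[(i + 1L):n_b, ] + gpair
        gb[i, ] <- gb[i, ] - colSums(gpair)
      }
      g[-seq_len(n_qm_dof)] <- g[-seq_len(n_qm_dof)] + as.numeric(t(gb))
    }

    # solute-bath coupling through the solute site P
    if (n_site > 0 && cs != 0) {
      P <- c(positions[seq_len(n_site)], numeric(3L - n_site))
      dx <- sweep(xb, 2, P)
      r2 <- rowSums(dx^2)
      v <- cs * q * exp(-0.5 * r2 / w_coup^2)
      e <- e + sum(v)
      gbath <- -(v / w_coup^2) * dx
      g[-seq_len(n_qm_dof)] <- g[-seq_len(n_qm_dof)] + as.numeric(t(gbath))
      gsite <- -colSums(gbath)
      g[seq_len(n_site)] <- g[seq_len(n_site)] + gsite[seq_len(n_site)]
    }

    list(energy = e, gradient = g)
  }
}
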