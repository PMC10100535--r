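# shared fixtures: small analytic models and engines built in code

# two linear diabats crossing at rc with a Gaussian coupling of amplitude amp
linear_crossing_params <- function(amp = 0.07, rc = 0.5, w = 0.3,
                                   mass = 10) {
  list(n_dof = 1, masses = mass,
       states = list(list(e0 = 0, a = 1, k = 0, r0 = 0),
                     list(e0 = 1, a = -1, k = 0, r0 = 0)),
       couplings = list(list(states = c(0, 1), amp = amp, rc = rc, w = w)),
       f_diab = c(0, 1))
}

# 3-state, 2-DOF model exercising multi-dimensional gradients and couplings
model_2dof <- function() {
  make_avoided_crossing_model(3, list(
    n_dof = 2, masses = c(12, 14),
    states = list(list(e0 = 0, a = c(0, 0.2), k = c(4, 3), r0 = c(0, 0)),
                  list(e0 = 2, a = c(-1, 0.5), k = c(0, 1), r0 = c(0, 0.2)),
                  list(e0 = 3, a = c(-3, -0.3), k = c(0, 0.5),
                       r0 = c(0.1, 0))),
    couplings = list(list(states = c(0, 1), amp = 0.05, rc = c(0.78, 0),
                          w = c(0.3, 0.5)),
                     list(states = c(1, 2), amp = 0.05, rc = c(0.5, 0.1),
                          w = c(0.3, 0.4))),
    f_diab = c(0, 0.1, 0.7)))
}

# smooth anharmonic analytic engine evaluable at any dimension
sine_engine <- function(a = 0.3, b = 0.7) {
  function(x) list(energy = a * sum(sin(x)) + b * sum(x^2),
                   gradient = a * cos(x) + 2 * b * x)
}

# a constant-coefficient coupling snapshot (no geometry attached)
const_snapshot <- function(energies, sigma12, n_dof = 1) {
  n <- length(energies)
  sg <- matrix(0, n, n)
  sg[1, 2] <- sigma12
  sg[2, 1] <- -sigma12
  structure(list(energies = energies, sigma = sg,
                 nac = array(0, c(n, n, n_dof))),
            class = "coupling_snapshot")
}

# hop-time frame built by hand
hop_frame <- function(t21, t10, t_max) {
  structure(data.frame(trajectory_id = seq_along(t21), t_hop_21 = t21,
                       t_hop_10 = t10,
                       t_max = rep(t_max, length(t21))),
            class = c("hop_times", "data.frame"))
}

# independent complex ODE oracle for the amplitude equations:
# dc/dt = -i/hbar diag(E) c - sigma c, integrated with deSolve at tight
# tolerance (real/imaginary split)
ode_amplitude_oracle <- function(c0, energies, sigma, t_end) {
  hbar <- surfhop_constants()$hbar_evfs
  n <- length(c0)
  f <- function(t, y, p) {
    cc <- complex(real = y[seq_len(n)], imaginary = y[n + seq_len(n)])
    dc <- -1i / hbar * energies * cc - as.vector(sigma %*% cc)
    list(c(Re(dc), Im(dc)))
  }
  out <- deSolve::ode(c(Re(c0), Im(c0)), c(0, t_end), f, NULL,
                      rtol = 1e-12, atol = 1e-12)
  complex(real = out[2, 1 + seq_len(n)],
          imaginary = out[2, 1 + n + seq_len(n)])
}
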