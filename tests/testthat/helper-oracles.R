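# Independent oracles used by the tests. These deliberately avoid the
# package's closed forms and optimiser.

# Classical fixed-step RK4 integration of dR/dt = f(R), reporting R at the
# requested times (times[1] is the initial condition's time).
rk4_integrate <- function(f, r0, times, dt = 0.02) {
  out <- numeric(length(times))
  out[1L] <- r0
  r <- r0
  for (i in seq_along(times)[-1L]) {
    span <- times[i] - times[i - 1L]
    n_sub <- max(1L, ceiling(span / dt))
    h <- span / n_sub
    for (s in seq_len(n_sub)) {
      k1 <- f(r)
      k2 <- f(r + h / 2 * k1)
      k3 <- f(r + h / 2 * k2)
      k4 <- f(r + h * k3)
      r <- r + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i] <- r
  }
  out
}

# ODE oracle for the 1:1 model phases.
ode_association <- function(ka, kd, rmax, conc, times, dt = 0.02)
  rk4_integrate(function(r) ka * conc * (rmax - r) - kd * r, 0, times, dt)

ode_dissociation <- function(kd, r0, times, dt = 0.02)
  rk4_integrate(function(r) -kd * r, r0, times, dt)

# Complement-table oracle for duplex scanning, independent of the package's
# vectorised implementation: explicit per-position loop.
oracle_pair_counts <- function(p_seq, t_seq) {
  comp <- list(A = "T", T = "A", C = "G", G = "C")
  p <- strsplit(p_seq, "")[[1]]; t <- strsplit(t_seq, "")[[1]]
  stopifnot(length(p) == length(t))
  n_match <- n_mm <- n_gob <- n_gog <- 0L
  for (i in seq_along(p)) {
    if (p[i] == "-" && t[i] == "-") n_gog <- n_gog + 1L
    else if (p[i] == "-" || t[i] == "-") n_gob <- n_gob + 1L
    else if (identical(comp[[p[i]]], t[i])) n_match <- n_match + 1L
    else n_mm <- n_mm + 1L
  }
  list(n_match = n_match, n_mismatch = n_mm,
       n_gap_opposite_base = n_gob, n_gap = n_gob + n_gog)
}

# Brute-force two-segment segmentation oracle: tries every admissible
# breakpoint with lm() fits.
oracle_seg2 <- function(x, y, min_seg = 5) {
  n <- length(x)
  sse <- function(idx) {
    if (length(unique(x[idx])) < 2) return(sum((y[idx] - mean(y[idx]))^2))
    sum(stats::resid(stats::lm(y[idx] ~ x[idx]))^2)
  }
  best <- NULL; best_sse <- Inf
  for (b in (min_seg + 1L):(n - min_seg + 1L)) {
    s <- sse(1:(b - 1L)) + sse(b:n)
    if (s < best_sse) { best_sse <- s; best <- b }
  }
  slope <- function(idx) unname(stats::coef(stats::lm(y[idx] ~ x[idx]))[2])
  list(breakpoint = best, slopes = c(slope(1:(best - 1L)), slope(best:n)),
       sse = best_sse)
}

# Build a bare qcmd_trace from explicit series (single overtone n3).
make_qcmd_trace <- function(delta_f, delta_D, time = seq_along(delta_f) - 1) {
  structure(list(time = time,
                 delta_f = matrix(delta_f, ncol = 1,
                                  dimnames = list(NULL, "n3")),
                 delta_D = matrix(delta_D, ncol = 1,
                                  dimnames = list(NULL, "n3")),
                 overtones = 3, phase = rep(NA_character_, length(time)),
                 fundamental_frequency = 4.95e6,
                 sample_id = "synthetic", seed = NA_integer_),
            class = "qcmd_trace")
}

default_params <- function() kinetic_params(1e6, 1e-3, 100)
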