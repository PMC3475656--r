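#' Wang-Buzsaki model parameters
#'
#' Single-compartment Hodgkin-Huxley-type neuron with fast sodium (activation
#' slaved to its asymptotic value), delayed-rectifier potassium and leak
#' currents, plus an optional slow potassium current gated by a variable `z`
#' that charges towards 1 during an action potential (time constant
#' `tau_z_fast`) and decays to 0 near rest (time constant `tau_z_slow`).
#' Reversal potentials in mV, conductances in mS/cm², capacitance in µF/cm².
#' `zeta` is the dimensionless gate-speed (temperature) factor.
#'
#' @param E_L,E_Na,E_K reversal potentials, mV.
#' @param g_L,g_Na,g_K maximal conductances, mS/cm².
#' @param C_m membrane capacitance, µF/cm².
#' @param zeta gate-speed factor.
#' @param g_slow slow-K maximal conductance, mS/cm² (0 disables).
#' @param tau_z_fast,tau_z_slow slow-gate time constants, ms.
#' @param V_z voltage above which the slow gate charges, mV.
#' @return a named list of class `wb_params`.
#' @export
wb_params <- function(E_L = -65, E_Na = 55, E_K = -90,
                      g_L = 0.1, g_Na = 35, g_K = 9, C_m = 1, zeta = 5,
                      g_slow = 0, tau_z_fast = 10, tau_z_slow = 500,
                      V_z = -20) {
  stopifnot(g_L >= 0, g_Na >= 0, g_K >= 0, g_slow >= 0, C_m > 0,
            tau_z_fast > 0, tau_z_slow > 0)
  structure(list(E_L = E_L, E_Na = E_Na, E_K = E_K, g_L = g_L, g_Na = g_Na,
                 g_K = g_K, C_m = C_m, zeta = zeta, g_slow = g_slow,
                 tau_z_fast = tau_z_fast, tau_z_slow = tau_z_slow, V_z = V_z),
            class = "wb_params")
}

#' Voltage-gated channel rate constants
#'
#' The Wang-Buzsaki (1996) opening/closing rates (1/ms) for the sodium
#' activation `m`, sodium inactivation `h` and potassium activation `n`
#' gates. The removable singularities of `alpha_m` (V = -35 mV) and
#' `alpha_n` (V = -34 mV) are evaluated by their analytic limits.
#'
#' @param V membrane potential(s), mV.
#' @return a tibble with columns `V`, `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @export
wb_rate_constants <- function(V) {
  stopifnot(all(is.finite(V)))
  m <- .wb_rates_cpp(as.numeric(V))
  dplyr::bind_cols(tibble::tibble(V = as.numeric(V)), tibble::as_tibble(m))
}

#' Asymptotic gate values x_inf(V) = alpha/(alpha + beta)
#'
#' @param V membrane potential(s), mV.
#' @return a tibble with columns `V`, `m_inf`, `h_inf`, `n_inf`.
#' @export
wb_gate_inf <- function(V) {
  r <- wb_rate_constants(V)
  tibble::tibble(
    V = r$V,
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n)
  )
}

#' Time derivatives of the Wang-Buzsaki state
#'
#' The membrane equation is
#' `C_m dV/dt = -I_L - I_Na - I_K - I_slow + I_inj` with
#' `I_L = g_L (V - E_L)`, `I_Na = g_Na m_inf^3 h (V - E_Na)`,
#' `I_K = g_K n^4 (V - E_K)` and `I_slow = g_slow z (V - E_K)`;
#' `h` and `n` follow `zeta * (alpha (1 - x) - beta x)` and the slow gate
#' relaxes to 1 (above `V_z`) or 0 (below) with its respective time constant.
#'
#' @param V membrane potential, mV.
#' @param h,n,z gate values in \[0, 1\].
#' @param I_inj injected current, µA/cm².
#' @param params a [wb_params()] list.
#' @return a named list `dV`, `dh`, `dn`, `dz` (per ms).
#' @export
wb_derivatives <- function(V, h, n, z = 0, I_inj = 0, params = wb_params()) {
  stopifnot(h >= 0, h <= 1, n >= 0, n <= 1, z >= 0, z <= 1)
  r <- wb_rate_constants(V)
  m_inf <- r$alpha_m / (r$alpha_m + r$beta_m)
  I_L <- params$g_L * (V - params$E_L)
  I_Na <- params$g_Na * m_inf^3 * h * (V - params$E_Na)
  I_K <- params$g_K * n^4 * (V - params$E_K)
  I_slow <- params$g_slow * z * (V - params$E_K)
  z_inf <- as.numeric(V >= params$V_z)
  tau_z <- ifelse(V >= params$V_z, params$tau_z_fast, params$tau_z_slow)
  list(
    dV = (-I_L - I_Na - I_K - I_slow + I_inj) / params$C_m,
    dh = params$zeta * (r$alpha_h * (1 - h) - r$beta_h * h),
    dn = params$zeta * (r$alpha_n * (1 - n) - r$beta_n * n),
    dz = (z_inf - z) / tau_z
  )
}

#' Half-width of the per-step uniform noise draw
#'
#' The intrinsic noise current has autocorrelation `2 lambda delta(t - t')`.
#' Drawn once per integration step and held constant for `dt`, a uniform
#' variate on `(-A, A)` delivers the required discrete variance `2 lambda/dt`
#' when `A = sqrt(6 lambda/dt)` (dialect `"contract"`, the default). Dialect
#' `"literal"` uses `A = 12 lambda/dt` instead, a historical convention kept
#' for comparison.
#'
#' @param lam noise intensity lambda, mV²/ms.
#' @param dt integration step, ms.
#' @param dialect `"contract"` or `"literal"`.
#' @return half-width A (mV/ms).
#' @export
noise_half_width <- function(lam, dt, dialect = c("contract", "literal")) {
  dialect <- match.arg(dialect)
  stopifnot(lam >= 0, dt > 0)
  if (lam == 0) return(0)
  switch(dialect, contract = sqrt(6 * lam / dt), literal = 12 * lam / dt)
}

#' Simulate one trial of the Wang-Buzsaki neuron
#'
#' Integrates the model with a second-order (midpoint) Runge-Kutta scheme at
#' step `dt`. The injected current is the stimulus held by zero-order hold on
#' the integration grid; the intrinsic noise is drawn once per step and
#' shared between both RK stages. Gates start at their asymptotic values for
#' `V0`.
#'
#' @param params a [wb_params()] list.
#' @param stimulus a [stim_waveform()] of injected current, µA/cm².
#' @param dt integration step, ms.
#' @param lam noise intensity, mV²/ms.
#' @param V0 initial membrane potential, mV.
#' @param z0 initial slow-gate value.
#' @param seed integer seed for the noise draw (`NULL` leaves the RNG state
#'   alone).
#' @param noise_dialect see [noise_half_width()].
#' @param record_gates keep the gate trajectories.
#' @return a `wb_trace` tibble with columns `t_ms`, `V` (and `h`, `n`, `z`
#'   when recorded); attribute `dt_ms`.
#' @export
simulate_trial <- function(params, stimulus, dt = 0.05, lam = 0, V0 = -70,
                           z0 = 0, seed = NULL,
                           noise_dialect = c("contract", "literal"),
                           record_gates = FALSE) {
  stopifnot(inherits(params, "wb_params"), inherits(stimulus, "stim_waveform"))
  noise_dialect <- match.arg(noise_dialect)
  I_inj <- resample_zoh(stimulus$current, stim_dt(stimulus), dt)
  if (!is.null(seed)) set.seed(seed)
  half <- noise_half_width(lam, dt, noise_dialect)
  res <- .wb_simulate_cpp(I_inj, dt, unclass(params), half, V0, z0,
                          record_gates)
  out <- tibble::tibble(t_ms = stimulus$t_ms[1] + (seq_along(res$V) - 1) * dt,
                        V = res$V)
  if (record_gates) {
    out$h <- res$h; out$n <- res$n; out$z <- res$z
  }
  attr(out, "dt_ms") <- dt
  class(out) <- c("wb_trace", class(out))
  out
}

# zero-order hold resampling of a stimulus onto the integration grid
resample_zoh <- function(x, dt_from, dt_to) {
  if (isTRUE(all.equal(dt_from, dt_to))) return(x)
  n_to <- floor(length(x) * dt_from / dt_to)
  idx <- pmin(floor((seq_len(n_to) - 1) * dt_to / dt_from) + 1, length(x))
  x[idx]
}

#' Detect spike times from a voltage trace
#'
#' A spike is the time of the first sample at which the membrane potential
#' reaches 0 mV from below (V >= 0 preceded by V < 0). No sub-sample
#' interpolation is applied.
#'
#' @param trace a `wb_trace` (or any data frame with `t_ms` and `V`).
#' @return numeric vector of spike times, ms, strictly increasing.
#' @export
detect_spikes <- function(trace) {
  V <- trace$V
  stopifnot(all(is.finite(V)))
  idx <- which(V >= 0 & dplyr::lag(V) < 0)
  as.numeric(trace$t_ms[idx])
}

#' Simulate an ensemble of trials
#'
#' One trial per seed; each trial shares the frozen stimulus but draws its
#' own intrinsic noise. Condition metadata (`a`, `b`, `nu`, `lam`, `seed`)
#' is stored in the trial table.
#'
#' @inheritParams simulate_trial
#' @param seeds integer vector of distinct per-trial seeds.
#' @param condition optional named list of condition values (e.g. `a`, `b`,
#'   `nu`) copied into the trial table.
#' @return a [spike_ensemble()].
#' @export
simulate_ensemble <- function(params, stimulus, seeds, dt = 0.05, lam = 0,
                              V0 = -70, z0 = 0,
                              noise_dialect = c("contract", "literal"),
                              condition = list()) {
  noise_dialect <- match.arg(noise_dialect)
  if (anyDuplicated(seeds)) stop("per-trial seeds must be distinct",
                                 call. = FALSE)
  trains <- purrr::map(seeds, function(s) {
    tr <- simulate_trial(params, stimulus, dt = dt, lam = lam, V0 = V0,
                         z0 = z0, seed = s, noise_dialect = noise_dialect)
    detect_spikes(tr)
  })
  spikes <- tibble::tibble(
    trial = rep(seq_along(seeds), lengths(trains)),
    time = unlist(trains, use.names = FALSE) %||% numeric()
  )
  trials <- tibble::tibble(trial = seq_along(seeds), seed = as.integer(seeds),
                           lam = lam)
  for (nm in names(condition)) trials[[nm]] <- condition[[nm]]
  dur <- nrow(stimulus) * stim_dt(stimulus)
  spike_ensemble(spikes, trials = trials, duration_ms = dur,
                 t0_ms = stimulus$t_ms[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
autoplot.wb_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$V)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)")
}
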