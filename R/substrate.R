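#' Substrate configuration for the virtual analog compartment chain
#'
#' Describes the fixed constants of the emulated substrate: chain size,
#' passive membrane parameters, the conductance ranges spanned by the two
#' 10-bit DACs, the synaptic input kernel, the integration/sampling step, the
#' ADC quantizer, and the noise model.  All quantities are in dimensionless
#' model units (capacitance 1, voltages of order 1, time in units where the
#' mid-range membrane time constant is about 1).
#'
#' The default conductance ranges are documented calibration constants: with
#' both DAC genes at mid-range (511, 511) the chain operates at an empirical
#' length constant of about one compartment and a first-compartment EPSP of
#' order 150 ADC bits, the regime the measurement protocol is designed for.
#'
#' @param n_compartments number of compartments in the linear chain (>= 2).
#' @param c_m membrane capacitance per compartment.
#' @param e_l leak reversal potential (model volts).
#' @param g_l_range length-2 numeric, `(min, max)` leak conductance reached at
#'   DAC codes 0 and 1022.
#' @param g_ic_range length-2 numeric, `(min, max)` inter-compartment
#'   conductance reached at DAC codes 0 and 1022.
#' @param syn_amplitude peak synaptic current of one input event.
#' @param tau_syn decay time constant of the synaptic current kernel.
#' @param dt integration and sampling step (model time).
#' @param adc_range length-2 numeric `(v_lo, v_hi)`, the quantizer span.
#' @param adc_bits ADC resolution in bits (default 10, i.e. 1024 codes).
#' @param noise_sigma SD of the Gaussian voltage noise added to every
#'   recorded sample (model volts); trial-to-trial variation of observables
#'   arises from this term.
#' @param noise_filter_tau correlation time of the recording noise (model
#'   time).  0, the default, gives iid per-sample noise; a positive value
#'   low-pass filters the noise (AR(1) with the stationary SD kept at
#'   `noise_sigma`), emulating membrane-filtered noise.
#' @param mismatch_sigma relative SD of the per-circuit fixed-pattern
#'   (fabrication) mismatch factors; 0 disables mismatch.
#' @return an object of class `substrate_config` (a validated list).
#' @examples
#' cfg <- substrate_config()
#' cfg$n_compartments
#' @export
substrate_config <- function(n_compartments = 5L,
                             c_m = 1.0,
                             e_l = 0.0,
                             g_l_range = c(0.5, 2.0),
                             g_ic_range = c(0.2, 4.2),
                             syn_amplitude = 1.9,
                             tau_syn = 0.5,
                             dt = 0.01,
                             adc_range = c(-0.2, 1.8),
                             adc_bits = 10L,
                             noise_sigma = 0.008,
                             noise_filter_tau = 0.0,
                             mismatch_sigma = 0.0) {
  cfg <- list(n_compartments = as.integer(n_compartments), c_m = c_m,
              e_l = e_l, g_l_range = as.numeric(g_l_range),
              g_ic_range = as.numeric(g_ic_range),
              syn_amplitude = syn_amplitude, tau_syn = tau_syn, dt = dt,
              adc_range = as.numeric(adc_range),
              adc_bits = as.integer(adc_bits),
              noise_sigma = noise_sigma,
              noise_filter_tau = noise_filter_tau,
              mismatch_sigma = mismatch_sigma)
  validate_substrate_config(cfg)
  structure(cfg, class = "substrate_config")
}

validate_substrate_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) config_error(msg)
  check(cfg$n_compartments >= 2, "n_compartments must be >= 2")
  check(cfg$c_m > 0, "c_m must be strictly positive")
  for (fld in c("g_l_range", "g_ic_range")) {
    r <- cfg[[fld]]
    check(length(r) == 2 && all(r > 0) && r[1] < r[2],
          paste0(fld, " must be strictly positive with min < max"))
  }
  check(cfg$tau_syn > 0, "tau_syn must be strictly positive")
  check(cfg$dt > 0, "dt must be strictly positive")
  check(length(cfg$adc_range) == 2 && cfg$adc_range[1] < cfg$adc_range[2],
        "adc_range must satisfy v_lo < v_hi")
  check(cfg$adc_bits >= 1, "adc_bits must be >= 1")
  check(cfg$noise_sigma >= 0, "noise_sigma must be >= 0")
  check(cfg$noise_filter_tau >= 0, "noise_filter_tau must be >= 0")
  check(cfg$mismatch_sigma >= 0, "mismatch_sigma must be >= 0")
  # The propagator is exact, but dt is also the sampling step: peaks and
  # event times are only resolved to dt, so demand several samples per
  # relevant time constant.
  tau_min <- min(cfg$c_m / (cfg$g_l_range[2] + 2 * cfg$g_ic_range[2]),
                 cfg$tau_syn)
  check(cfg$dt <= tau_min / 2,
        sprintf(paste0("dt = %g is too coarse for this substrate: the ",
                       "fastest time constant is %g and peaks would be ",
                       "under-sampled; choose dt <= %g"),
                cfg$dt, tau_min, tau_min / 2))
  invisible(cfg)
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("evochain_config_error", "evochain_error")))
}

#' Map a DAC code to a conductance
#'
#' The substrate exposes conductances through 10-bit DACs.  The transfer
#' function is a strictly increasing affine map from the shared code range
#' `[0, 1022]` onto the configured conductance range:
#' `g = min + (d / 1022) * (max - min)`.
#'
#' @param d integer DAC code(s) in `[0, 1022]`.
#' @param range length-2 numeric `(min, max)` conductance range.
#' @return conductance value(s), same length as `d`.
#' @examples
#' dac_to_conductance(0, c(0.05, 2))    # lower bound
#' dac_to_conductance(1022, c(0.05, 2)) # upper bound
#' @export
dac_to_conductance <- function(d, range) {
  stopifnot(length(range) == 2, range[1] < range[2])
  if (any(!is.finite(d)) || any(d < 0) || any(d > DAC_MAX) || any(d != round(d)))
    stop(errorCondition(
      sprintf("DAC codes must be integers in [0, %d]", DAC_MAX),
      class = c("evochain_bounds_error", "evochain_error")))
  range[1] + (as.numeric(d) / DAC_MAX) * (range[2] - range[1])
}

#' Realize a compartment chain from DAC genes
#'
#' Turns an integer genome into a concrete [chain_model()].  Two gene layouts
#' are supported, matching the two search problems:
#' \describe{
#'   \item{2 genes}{homogeneous chain: gene 1 sets the leak conductance of
#'     every compartment, gene 2 the conductance of every inter-compartment
#'     connection.}
#'   \item{2n-1 genes}{heterogeneous chain: the first `n` genes set the `n`
#'     per-compartment leak conductances, the remaining `n - 1` the per-edge
#'     inter-compartment conductances.}
#' }
#' When `mismatch_sigma > 0`, every conductance is additionally multiplied by
#' a per-circuit fixed-pattern factor (lognormal with mean 1 and relative SD
#' `mismatch_sigma`), drawn once from `mismatch_seed` — static fabrication
#' mismatch, as opposed to trial-to-trial noise.
#'
#' @param genes integer vector of DAC codes, length 2 or `2 * n - 1`.
#' @param config a [substrate_config()].
#' @param mismatch_seed seed for the fixed-pattern stream (ignored when
#'   `mismatch_sigma = 0`).
#' @return a [chain_model()].
#' @examples
#' make_chain(c(511, 511), substrate_config())
#' @export
make_chain <- function(genes, config, mismatch_seed = 0L) {
  n <- config$n_compartments
  if (!(length(genes) %in% c(2L, 2L * n - 1L)))
    stop(errorCondition(
      sprintf("gene vector must have length 2 or %d (= 2n-1), got %d",
              2L * n - 1L, length(genes)),
      class = c("evochain_shape_error", "evochain_error")))
  if (length(genes) == 2L) {
    g_l <- rep(dac_to_conductance(genes[1], config$g_l_range), n)
    g_ic <- rep(dac_to_conductance(genes[2], config$g_ic_range), n - 1L)
  } else {
    g_l <- dac_to_conductance(genes[seq_len(n)], config$g_l_range)
    g_ic <- dac_to_conductance(genes[n + seq_len(n - 1L)], config$g_ic_range)
  }
  factors <- rep(1, 2L * n - 1L)
  if (config$mismatch_sigma > 0) {
    sdlog <- sqrt(log1p(config$mismatch_sigma^2))
    factors <- with_stream(derive_seed(mismatch_seed, "mismatch"),
                           exp(rnorm(2L * n - 1L, -sdlog^2 / 2, sdlog)))
  }
  chain_model(g_l = g_l * factors[seq_len(n)],
              g_ic = g_ic * factors[n + seq_len(n - 1L)],
              c_m = rep(config$c_m, n),
              e_l = rep(config$e_l, n),
              mismatch_factors = factors,
              genes = as.integer(genes))
}

#' Construct a compartment chain model
#'
#' The concrete passive parameters of one chain: per-compartment leak
#' conductances, capacitances and leak reversals, and per-edge
#' inter-compartment conductances.  The membrane dynamics are
#' `C_i dU_i/dt = -g_l_i (U_i - E_l_i) + sum_j g_ic_ij (U_j - U_i) + I_i`,
#' the second-order central-difference discretization of the passive cable
#' equation on a line.
#'
#' @param g_l leak conductances, one per compartment (>= 0; strictly positive
#'   chains are required for a well-posed steady state).
#' @param g_ic inter-compartment conductances, one per edge (length `n - 1`).
#' @param c_m capacitances, one per compartment (> 0).
#' @param e_l leak reversal potentials, one per compartment.
#' @param mismatch_factors fixed-pattern factors recorded at realization.
#' @param genes the DAC genome the chain was realized from (may be NULL for
#'   manually constructed chains).
#' @return an object of class `chain_model`.
#' @export
chain_model <- function(g_l, g_ic, c_m, e_l,
                        mismatch_factors = rep(1, length(g_l) + length(g_ic)),
                        genes = NULL) {
  n <- length(g_l)
  stopifnot(n >= 1, length(g_ic) == n - 1, length(c_m) == n, length(e_l) == n)
  if (any(g_l < 0) || any(g_ic <= 0 & n > 1) || any(c_m <= 0))
    stop(errorCondition(
      "conductances must be non-negative and capacitances strictly positive",
      class = c("evochain_config_error", "evochain_error")))
  structure(list(g_l = as.numeric(g_l), g_ic = as.numeric(g_ic),
                 c_m = as.numeric(c_m), e_l = as.numeric(e_l),
                 mismatch_factors = as.numeric(mismatch_factors),
                 genes = genes),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %d compartments\n", length(x$g_l)))
  cat("  g_l :", signif(x$g_l, 4), "\n")
  cat("  g_ic:", signif(x$g_ic, 4), "\n")
  if (!is.null(x$genes)) cat("  genes:", x$genes, "\n")
  invisible(x)
}

# Conductance matrix G = diag(g_l) + graph Laplacian of the chain weighted
# by g_ic.  G U = g_l * e_l + I at steady state.
conductance_matrix <- function(chain) {
  n <- length(chain$g_l)
  G <- diag(chain$g_l, n, n)
  for (i in seq_len(n - 1)) {
    g <- chain$g_ic[i]
    G[i, i] <- G[i, i] + g
    G[i + 1, i + 1] <- G[i + 1, i + 1] + g
    G[i, i + 1] <- G[i, i + 1] - g
    G[i + 1, i] <- G[i + 1, i] - g
  }
  G
}

#' Steady-state voltages of a chain under constant input currents
#'
#' Solves the stationary form of the chain dynamics,
#' `(diag(g_l) + L_ic) U = g_l * E_l + I`, where `L_ic` is the chain
#' Laplacian weighted by the inter-compartment conductances.  The system is
#' tridiagonal and is solved exactly with the Thomas algorithm; with strictly
#' positive leak conductances the matrix is an irreducibly diagonally
#' dominant M-matrix, hence nonsingular.
#'
#' @param chain a [chain_model()].
#' @param currents numeric vector of constant external currents, one per
#'   compartment (a scalar is recycled).
#' @return numeric vector of steady-state membrane voltages.
#' @examples
#' ch <- make_chain(c(511, 511), substrate_config())
#' steady_state(ch, c(0.5, 0, 0, 0, 0))
#' @export
steady_state <- function(chain, currents = 0) {
  n <- length(chain$g_l)
  currents <- rep_len(as.numeric(currents), n)
  if (all(chain$g_l <= 0))
    stop(errorCondition("steady state requires at least one positive leak",
                        class = c("evochain_config_error", "evochain_error")))
  gi <- c(chain$g_ic, 0)
  diag_main <- chain$g_l + c(0, chain$g_ic) + gi
  lower <- -chain$g_ic
  upper <- -chain$g_ic
  rhs <- chain$g_l * chain$e_l + currents
  # Thomas forward sweep
  cp <- numeric(n - 1)
  dp <- numeric(n)
  denom <- diag_main[1]
  if (n > 1) cp[1] <- upper[1] / denom
  dp[1] <- rhs[1] / denom
  if (n > 1) {
    for (i in 2:n) {
      denom <- diag_main[i] - lower[i - 1] * cp[i - 1]
      if (i < n) cp[i] <- upper[i] / denom
      dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
    }
  }
  u <- numeric(n)
  u[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  u
}

#' Define a stimulation program
#'
#' A stimulus is a list of synaptic input events, each an input spike landing
#' on one compartment at one time, plus an optional constant current per
#' compartment.  Each event triggers a current-based exponential kernel
#' `I(t) = syn_amplitude * exp(-(t - t_spike) / tau_syn)` on its target.
#'
#' @param spike_times numeric vector of event times, sorted ascending, all in
#'   `[0, total_duration)`.
#' @param targets integer vector of 0-based target compartments (a scalar is
#'   recycled).
#' @param total_duration model time covered by the recording.
#' @param constant_current optional numeric vector of per-compartment constant
#'   currents (default 0).
#' @param n_compartments chain size used to validate targets.
#' @return an object of class `stimulus_program`.
#' @export
stimulus_program <- function(spike_times, targets = 0L, total_duration,
                             constant_current = 0, n_compartments = 5L) {
  spike_times <- as.numeric(spike_times)
  targets <- rep_len(as.integer(targets), length(spike_times))
  if (is.unsorted(spike_times))
    stop(errorCondition("spike times must be sorted ascending",
                        class = c("evochain_protocol_error", "evochain_error")))
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) >= total_duration))
    stop(errorCondition("spike times must lie within [0, total_duration)",
                        class = c("evochain_protocol_error", "evochain_error")))
  if (length(targets) && (min(targets) < 0 || max(targets) >= n_compartments))
    stop(errorCondition("target compartment out of range",
                        class = c("evochain_protocol_error", "evochain_error")))
  structure(list(spike_times = spike_times, targets = targets,
                 total_duration = total_duration,
                 constant_current = rep_len(as.numeric(constant_current),
                                            n_compartments)),
            class = "stimulus_program")
}

# Exact one-step propagator of the augmented linear system
# z = (v, s, 1): v' = A v + C^{-1} s + C^{-1} I_const, s' = -s / tau_syn,
# where v is the voltage deviation from the zero-input resting state.
build_propagator <- function(chain, tau_syn, dt, constant_current) {
  n <- length(chain$g_l)
  A <- -conductance_matrix(chain) / chain$c_m
  m <- 2L * n + 1L
  M <- matrix(0, m, m)
  M[seq_len(n), seq_len(n)] <- A
  M[cbind(seq_len(n), n + seq_len(n))] <- 1 / chain$c_m
  M[seq_len(n), m] <- constant_current / chain$c_m
  M[cbind(n + seq_len(n), n + seq_len(n))] <- -1 / tau_syn
  as.matrix(Matrix::expm(Matrix::Matrix(M * dt)))
}

# Noiseless membrane voltages of a chain under a stimulus program, sampled
# every config$dt.  Returns a list with the voltage matrix
# [compartment x sample] (absolute volts) and the resting voltages.
simulate_clean <- function(chain, stim, config) {
  n <- length(chain$g_l)
  dt <- config$dt
  n_samples <- as.integer(ceiling(stim$total_duration / dt)) + 1L
  P <- build_propagator(chain, config$tau_syn, dt, stim$constant_current)
  # zero-leak chains (diagnostic only) have no unique rest; use e_l
  rest <- if (all(chain$g_l == 0)) chain$e_l else steady_state(chain, 0)
  spike_steps <- as.integer(round(stim$spike_times / dt))
  v <- propagate_chain_cpp(P, n, n_samples, spike_steps,
                           as.integer(stim$targets), config$syn_amplitude)
  list(voltages = v + rest, rest = rest, dt = dt)
}

# ADC quantizer: clip to [v_lo, v_hi], uniform mid-tread rounding onto
# 2^adc_bits integer codes.
quantize_voltage <- function(v, config) {
  n_codes <- 2L^config$adc_bits
  lo <- config$adc_range[1]
  hi <- config$adc_range[2]
  code <- round((v - lo) / (hi - lo) * (n_codes - 1))
  code[code < 0] <- 0
  code[code > n_codes - 1] <- n_codes - 1
  storage.mode(code) <- "integer"
  code
}

# Volts represented by one ADC bit (code step).
bit_step <- function(config) {
  diff(config$adc_range) / (2L^config$adc_bits - 1)
}

# Recording stage shared by simulate_chain() and the trial-repeat fast path:
# add per-sample Gaussian noise (iid, or AR(1)-filtered when the config asks
# for membrane-filtered noise) and quantize.
record_traces <- function(clean_voltages, config, noise_sigma, seed) {
  v <- clean_voltages
  if (noise_sigma > 0) {
    noise <- with_stream(derive_seed(seed, "noise"), {
      eps <- matrix(rnorm(length(v)), nrow(v), ncol(v))
      if (config$noise_filter_tau > 0) {
        # AR(1) along time per compartment, stationary SD = noise_sigma
        rho <- exp(-config$dt / config$noise_filter_tau)
        t(apply(eps, 1, function(e)
          as.numeric(stats::filter(e * sqrt(1 - rho^2), rho,
                                   method = "recursive",
                                   init = e[1])))) * noise_sigma
      } else {
        eps * noise_sigma
      }
    })
    v <- v + noise
  }
  quantize_voltage(v, config)
}

#' Emulate one recording of a compartment chain
#'
#' Integrates the passive chain dynamics under a stimulus program with the
#' exact exponential propagator of the linear system (membrane voltages plus
#' exponentially decaying synaptic currents), samples every `config$dt`, adds
#' iid Gaussian voltage noise to every recorded sample, and quantizes to the
#' ADC code range.  Noise enters at the recording stage only, emulating read
#' noise of the analog substrate: the underlying dynamics of a fixed chain
#' and stimulus are deterministic.
#'
#' @param chain a [chain_model()].
#' @param stim a [stimulus_program()].
#' @param config a [substrate_config()].
#' @param noise_sigma per-sample noise SD (model volts); defaults to the
#'   config value.
#' @param seed master seed for the recording-noise stream.
#' @return an object of class `recording_set`: integer `traces`
#'   (compartment x sample, ADC codes), the noiseless `clean` voltage matrix
#'   (model volts, for diagnostics), `dt`, and a `meta` list with seed, genes
#'   and a config hash.
#' @examples
#' cfg <- substrate_config()
#' ch <- make_chain(c(511, 511), cfg)
#' st <- stimulus_program(2, 0L, 10, n_compartments = cfg$n_compartments)
#' rec <- simulate_chain(ch, st, cfg, seed = 1)
#' dim(rec$traces)
#' @export
simulate_chain <- function(chain, stim, config,
                           noise_sigma = config$noise_sigma, seed = 0L) {
  if (noise_sigma < 0)
    config_error("noise_sigma must be >= 0")
  clean <- simulate_clean(chain, stim, config)
  traces <- record_traces(clean$voltages, config, noise_sigma, seed)
  recording_set(traces, clean$voltages, config$dt,
                meta = list(seed = seed, genes = chain$genes,
                            noise_sigma = noise_sigma,
                            config_hash = config_hash(config)))
}

recording_set <- function(traces, clean, dt, meta = list()) {
  stopifnot(is.matrix(traces), is.integer(traces))
  structure(list(traces = traces, clean = clean, dt = dt, meta = meta),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d compartments x %d samples, dt = %g\n",
              nrow(x$traces), ncol(x$traces), x$dt))
  invisible(x)
}

config_hash <- function(config) {
  v <- unlist(unclass(config), use.names = TRUE)
  paste0("cfg-", sum(utf8ToInt(paste(names(v), format(v, digits = 15),
                                     collapse = ";"))))
}

#' Export a recording to CSV with a JSON metadata sidecar
#'
#' Writes one column per compartment of quantized ADC codes; the sample
#' interval, seed and genes go to `<path>.json`.
#'
#' @param rec a `recording_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(t(rec$traces))
  names(df) <- paste0("compartment_", seq_len(nrow(rec$traces)) - 1L)
  write.csv(df, path, row.names = FALSE)
  meta <- c(list(dt = rec$dt, n_samples = ncol(rec$traces)), rec$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
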