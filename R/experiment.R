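#' Measurement protocol configuration
#'
#' Describes the EPSP attenuation protocol: a train of `n_spikes` synaptic
#' input events is injected into one compartment, spaced widely enough that
#' the membrane returns to rest between events, and every compartment's
#' voltage is recorded.  Window lengths left `NULL` are resolved per chain:
#' the inter-spike interval defaults to 10 times the slowest membrane time
#' constant `max(c_m / g_l)` (residual deflection below `exp(-10)`), the
#' baseline window to 20% of the interval (ending one sample before the
#' spike) and the response window to 60% of the interval.
#'
#' @param n_spikes number of input spikes per run (default 10, the
#'   spike-triggered-average mode; 1 gives the single-measurement mode).
#' @param inter_spike_interval model time between spikes, or `NULL` to resolve
#'   per chain.
#' @param pre_window baseline window length before each spike, or `NULL`.
#' @param post_window response window length after each spike, or `NULL`.
#' @param input_compartment 0-based index receiving the input (default 0).
#' @return an object of class `protocol_config`.
#' @examples
#' protocol_config(n_spikes = 1)
#' @export
protocol_config <- function(n_spikes = 10L, inter_spike_interval = NULL,
                            pre_window = NULL, post_window = NULL,
                            input_compartment = 0L) {
  if (n_spikes < 1) config_error("n_spikes must be >= 1")
  if (!is.null(inter_spike_interval)) {
    if (inter_spike_interval <= 0)
      config_error("inter_spike_interval must be > 0")
    if (!is.null(pre_window) && !is.null(post_window) &&
        inter_spike_interval < pre_window + post_window)
      config_error("inter_spike_interval must be >= pre_window + post_window")
  }
  structure(list(n_spikes = as.integer(n_spikes),
                 inter_spike_interval = inter_spike_interval,
                 pre_window = pre_window, post_window = post_window,
                 input_compartment = as.integer(input_compartment)),
            class = "protocol_config")
}

# Resolve NULL protocol windows for a concrete chain.
resolve_protocol <- function(protocol, chain, config) {
  tau_slow <- max(chain$c_m / pmax(chain$g_l, .Machine$double.eps),
                  config$tau_syn)
  isi <- protocol$inter_spike_interval
  if (is.null(isi)) isi <- 10 * tau_slow
  pre <- protocol$pre_window
  if (is.null(pre)) pre <- 0.2 * isi
  post <- protocol$post_window
  if (is.null(post)) post <- 0.6 * isi
  if (isi < pre + post)
    config_error("inter_spike_interval must be >= pre_window + post_window")
  list(n_spikes = protocol$n_spikes, isi = isi, pre = pre, post = post,
       input_compartment = protocol$input_compartment)
}

#' Spike-triggered average of a recording
#'
#' For each compartment, cuts a window `[t - pre_window, t + post_window]`
#' around every input spike time, subtracts that window's pre-spike baseline
#' mean (so the resting potential sits at zero), and averages the
#' baseline-subtracted windows across spikes.  With iid per-sample noise the
#' residual noise SD of the average falls as `1/sqrt(n_spikes)`.
#'
#' @param rec a `recording_set` from [simulate_chain()].
#' @param spike_times numeric vector of input spike times (model time).
#' @param pre_window baseline window length before each spike.
#' @param post_window response window length after each spike.
#' @return an object of class `sta_traces`: matrix `traces`
#'   (compartment x window sample, ADC bits relative to baseline), the window
#'   sample index `spike_index` at which the spike occurs, `dt`, and
#'   `n_spikes`.
#' @export
sta <- function(rec, spike_times, pre_window, post_window) {
  traces <- rec$traces
  if (!is.matrix(traces)) traces <- rec # allow raw matrices internally
  sta_from_traces(traces, rec$dt, spike_times, pre_window, post_window)
}

sta_from_traces <- function(traces, dt, spike_times, pre_window, post_window) {
  n_samples <- ncol(traces)
  spike_idx <- as.integer(round(spike_times / dt)) + 1L
  n_pre <- as.integer(round(pre_window / dt))
  n_post <- as.integer(round(post_window / dt))
  if (any(spike_idx - n_pre < 1L) || any(spike_idx + n_post > n_samples))
    stop(errorCondition(
      "an STA window extends past the recording",
      class = c("evochain_protocol_error", "evochain_error")))
  w_len <- n_pre + n_post + 1L
  acc <- matrix(0, nrow(traces), w_len)
  for (s in spike_idx) {
    win <- traces[, (s - n_pre):(s + n_post), drop = FALSE]
    # baseline: mean over the pre-spike part, ending one sample before the spike
    baseline <- rowMeans(win[, seq_len(n_pre), drop = FALSE])
    acc <- acc + (win - baseline)
  }
  structure(list(traces = acc / length(spike_idx), spike_index = n_pre + 1L,
                 dt = dt, n_spikes = length(spike_idx)),
            class = "sta_traces")
}

#' Extract EPSP peak amplitudes from averaged traces
#'
#' The amplitude per compartment is the maximum of the baseline-subtracted
#' average trace over the post-spike window, in ADC bits.
#'
#' @param avg an `sta_traces` object from [sta()].
#' @return numeric vector of peak amplitudes (bits), one per compartment.
#' @export
extract_amplitudes <- function(avg) {
  post <- avg$traces[, avg$spike_index:ncol(avg$traces), drop = FALSE]
  apply(post, 1, max)
}

degenerate_fit_error <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("evochain_degenerate_fit", "evochain_fit_error",
                                "evochain_error")))
}

#' Fit an exponential attenuation profile
#'
#' Fits `U_max(x) = a * exp(-x / lambda) + c` to the EPSP peak amplitudes,
#' with `x` the 0-based compartment index, by Levenberg-Marquardt nonlinear
#' least squares with `lambda` constrained positive.  `lambda` is the
#' empirical length constant of the chain in units of compartments.
#'
#' @param amplitudes numeric vector of peak amplitudes (bits), one per
#'   compartment; at least 4 points are required for the 3-parameter fit.
#' @return an object of class `attenuation_fit` with elements `a`,
#'   `lambda_emp`, `c`, and `residual` (RMS fit error).
#' @examples
#' amps <- 100 * exp(-(0:4) / 1.07) + 5
#' fit_attenuation(amps)
#' @export
fit_attenuation <- function(amplitudes) {
  y <- as.numeric(amplitudes)
  if (any(!is.finite(y)))
    stop(errorCondition("amplitudes must be finite",
                        class = c("evochain_fit_error", "evochain_error")))
  if (length(y) < 4)
    stop(errorCondition("need at least 4 amplitudes for the 3-parameter fit",
                        class = c("evochain_fit_error", "evochain_error")))
  if (diff(range(y)) == 0)
    degenerate_fit_error(
      "flat amplitude profile: length constant is unidentifiable",
      diagnostics = list(amplitudes = y))
  x <- seq_along(y) - 1
  n <- length(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-x / lambda) + c,
      data = data.frame(x = x, y = y),
      start = list(a = y[1] - y[n], lambda = 1, c = y[n]),
      lower = c(a = -Inf, lambda = 1e-6, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    degenerate_fit_error(
      paste0("attenuation fit failed to converge: ", conditionMessage(fit)),
      diagnostics = list(amplitudes = y))
  p <- coef(fit)
  if (!is.finite(p[["lambda"]]) || p[["lambda"]] <= 0)
    degenerate_fit_error("fitted length constant is not positive",
                         diagnostics = list(amplitudes = y, coef = p))
  structure(list(a = unname(p[["a"]]), lambda_emp = unname(p[["lambda"]]),
                 c = unname(p[["c"]]),
                 residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("<attenuation_fit> a = %.3f bits, lambda_emp = %.4f compartments, c = %.3f bits (RMS %.3g)\n",
              x$a, x$lambda_emp, x$c, x$residual))
  invisible(x)
}

observation <- function(amplitudes, fit) {
  structure(list(amplitudes = amplitudes, lambda_emp = fit$lambda_emp,
                 h0 = amplitudes[1], fit = fit),
            class = "observation")
}

#' @export
print.observation <- function(x, ...) {
  cat(sprintf("<observation> lambda_emp = %.4f compartments, h0 = %.2f bits\n",
              x$lambda_emp, x$h0))
  cat("  amplitudes (bits):", sprintf("%.2f", x$amplitudes), "\n")
  invisible(x)
}

# Build the chain, stimulus, and noiseless dynamics for one attenuation run.
# Shared by run_attenuation_experiment() and the trial-repeat fast path:
# because recording noise is applied after integration, the expensive
# noiseless dynamics can be computed once and re-recorded many times.
prepare_attenuation_run <- function(genes, substrate_cfg, protocol_cfg,
                                    mismatch_seed = 0L) {
  chain <- make_chain(genes, substrate_cfg, mismatch_seed = mismatch_seed)
  p <- resolve_protocol(protocol_cfg, chain, substrate_cfg)
  spike_times <- p$pre + p$isi * (seq_len(p$n_spikes) - 1)
  total <- p$pre + p$isi * (p$n_spikes - 1) + p$post + 2 * substrate_cfg$dt
  stim <- stimulus_program(spike_times, p$input_compartment, total,
                           n_compartments = substrate_cfg$n_compartments)
  clean <- simulate_clean(chain, stim, substrate_cfg)
  list(chain = chain, stim = stim, clean = clean, protocol = p)
}

# Recording + analysis stage of one attenuation run.
measure_observation <- function(run, substrate_cfg, noise_sigma, seed) {
  traces <- record_traces(run$clean$voltages, substrate_cfg, noise_sigma, seed)
  avg <- sta_from_traces(traces, run$clean$dt, run$stim$spike_times,
                         run$protocol$pre, run$protocol$post)
  amps <- extract_amplitudes(avg)
  observation(amps, fit_attenuation(amps))
}

#' Run one EPSP attenuation experiment
#'
#' Realizes a chain from the DAC genes, injects `n_spikes` input spikes into
#' the input compartment with enough spacing for the membrane to return to
#' rest, records all compartments in one emulation run, computes the
#' spike-triggered average, extracts peak amplitudes, and fits the
#' exponential attenuation profile.
#'
#' @param genes integer DAC genome (length 2 or `2n - 1`).
#' @param substrate_cfg a [substrate_config()].
#' @param protocol_cfg a [protocol_config()].
#' @param seed master seed; the recording-noise and mismatch streams are
#'   derived from it.
#' @param noise_sigma recording noise SD; defaults to the substrate config.
#' @return an `observation`: per-compartment `amplitudes` (bits), the fitted
#'   `lambda_emp` (compartments), `h0` (= `amplitudes[1]`), and the full
#'   `attenuation_fit`.
#' @examples
#' obs <- run_attenuation_experiment(c(511, 511), substrate_config(),
#'                                   protocol_config(), seed = 1)
#' obs$lambda_emp
#' @export
run_attenuation_experiment <- function(genes, substrate_cfg = substrate_config(),
                                       protocol_cfg = protocol_config(),
                                       seed = 0L,
                                       noise_sigma = substrate_cfg$noise_sigma) {
  run <- prepare_attenuation_run(genes, substrate_cfg, protocol_cfg,
                                 mismatch_seed = seed)
  measure_observation(run, substrate_cfg, noise_sigma, seed)
}

#' Record the multi-site EPSP amplitude matrix
#'
#' For the nine-dimensional search, every compartment is connected to a
#' pre-synaptic partner: a spike is injected into one compartment after
#' another and the EPSP amplitudes are recorded in all compartments, giving
#' the matrix `h[i, j]` = amplitude recorded in compartment `i` for an input
#' to compartment `j` (0-based, stored 1-based).
#'
#' @param genes integer DAC genome of length `2n - 1`.
#' @param substrate_cfg a [substrate_config()].
#' @param protocol_cfg a [protocol_config()]; its `input_compartment` is
#'   overridden per input site.
#' @param seed master seed; site `j` uses the derived stream `"site<j>"`.
#' @param noise_sigma recording noise SD; defaults to the substrate config.
#' @return an `amplitude_matrix`: numeric `n x n` matrix of EPSP peak
#'   amplitudes in bits.
#' @export
run_multisite_experiment <- function(genes, substrate_cfg = substrate_config(),
                                     protocol_cfg = protocol_config(),
                                     seed = 0L,
                                     noise_sigma = substrate_cfg$noise_sigma) {
  n <- substrate_cfg$n_compartments
  if (length(genes) != 2L * n - 1L)
    stop(errorCondition(
      sprintf("multi-site experiment needs %d genes (2n-1), got %d",
              2L * n - 1L, length(genes)),
      class = c("evochain_shape_error", "evochain_error")))
  h <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    pc <- protocol_cfg
    pc$input_compartment <- j - 1L
    site_seed <- derive_seed(seed, paste0("site", j - 1L))
    run <- prepare_attenuation_run(genes, substrate_cfg, pc,
                                   mismatch_seed = seed)
    traces <- record_traces(run$clean$voltages, substrate_cfg, noise_sigma,
                            site_seed)
    avg <- sta_from_traces(traces, run$clean$dt, run$stim$spike_times,
                           run$protocol$pre, run$protocol$post)
    h[, j] <- extract_amplitudes(avg)
  }
  structure(h, class = c("amplitude_matrix", "matrix"))
}

#' Trial-to-trial variation of the attenuation observables
#'
#' Repeats the attenuation experiment with independent recording-noise draws
#' at a fixed parameterization, in both the single-measurement mode
#' (`n_spikes = 1`) and the spike-triggered-average mode (`n_spikes` from
#' `protocol_cfg`, default 10), and summarizes the run-to-run spread of the
#' length constant and the first-compartment amplitude.
#'
#' @param genes integer DAC genome.
#' @param substrate_cfg a [substrate_config()].
#' @param protocol_cfg a [protocol_config()] describing the STA mode.
#' @param n_repeats number of independent repeats per mode (>= 2).
#' @param seed master seed; repeat `i` of mode `m` uses stream `"<m>-rep<i>"`.
#' @return a list of class `trial_to_trial`: `runs`, a tidy data frame with
#'   one row per repeat per mode (`mode`, `rep`, `lambda_emp`, `h0`), and
#'   `summary`, a data frame of per-mode means and SDs.
#' @export
trial_to_trial <- function(genes, substrate_cfg = substrate_config(),
                           protocol_cfg = protocol_config(),
                           n_repeats = 100L, seed = 0L) {
  if (n_repeats < 2) config_error("n_repeats must be >= 2")
  modes <- list(single = { p <- protocol_cfg; p$n_spikes <- 1L; p },
                sta = protocol_cfg)
  rows <- list()
  for (mode in names(modes)) {
    run <- prepare_attenuation_run(genes, substrate_cfg, modes[[mode]],
                                   mismatch_seed = seed)
    for (i in seq_len(n_repeats)) {
      obs <- measure_observation(run, substrate_cfg,
                                 substrate_cfg$noise_sigma,
                                 derive_seed(seed, paste0(mode, "-rep", i)))
      rows[[length(rows) + 1L]] <-
        data.frame(mode = mode, rep = i, lambda_emp = obs$lambda_emp,
                   h0 = obs$h0)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$mode), function(d) {
    data.frame(mode = d$mode[1],
               lambda_mean = mean(d$lambda_emp), lambda_sd = sd(d$lambda_emp),
               h0_mean = mean(d$h0), h0_sd = sd(d$h0))
  }))
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg, genes = genes, seed = seed),
            class = "trial_to_trial")
}

#' @export
print.trial_to_trial <- function(x, ...) {
  cat(sprintf("<trial_to_trial> genes (%s), %d repeats per mode\n",
              paste(x$genes, collapse = ", "), max(x$runs$rep)))
  print(x$summary)
  invisible(x)
}

#' Bundle target observables for the optimization
#'
#' @param lambda_hat target length constant (compartments).
#' @param h0_hat target first-compartment amplitude (bits), for the
#'   multi-objective fitness.
#' @param h_hat target amplitude matrix, for the nine-dimensional fitness.
#' @return an object of class `target_observation`.
#' @export
target_observation <- function(lambda_hat = NULL, h0_hat = NULL, h_hat = NULL) {
  if (!is.null(lambda_hat) && lambda_hat <= 0)
    config_error("lambda_hat must be > 0")
  if (!is.null(h0_hat) && h0_hat <= 0)
    config_error("h0_hat must be > 0")
  structure(list(lambda_hat = lambda_hat, h0_hat = h0_hat, h_hat = h_hat),
            class = "target_observation")
}

#' Export an observation as CSV/JSON
#'
#' @param obs an `observation` from [run_attenuation_experiment()].
#' @param path output path stem; writes `<path>.csv` (amplitudes) and
#'   `<path>.json` (fit parameters).
#' @return `path`, invisibly.
#' @export
write_observation <- function(obs, path) {
  write.csv(data.frame(compartment = seq_along(obs$amplitudes) - 1L,
                       amplitude_bits = obs$amplitudes),
            paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(lambda_emp = obs$lambda_emp, h0 = obs$h0,
                            a = obs$fit$a, c = obs$fit$c,
                            residual = obs$fit$residual),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
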