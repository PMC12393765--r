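## Information-transmission protocols: signal fidelity, consistency across
## realizations, and single-pulse perturbation encoding.

pathway_input_rate <- function(res, spec, pathway, dt_ms = 1) {
  if (pathway == "theta") {
    th <- generate_theta_spike_packets(res$duration_s, spec$theta,
                                       res$seeds$theta)
    spikes_to_rate(th$times_ms, res$duration_s * 1000, dt_ms = dt_ms)
  } else {
    spikes_to_rate(res$parallel_times_ms, res$duration_s * 1000, dt_ms = dt_ms)
  }
}

pc_output_rate <- function(res, dt_ms = 1) {
  spikes_to_rate(res$pc_raster$t_ms, res$duration_s * 1000, dt_ms = dt_ms)
}

#' Signal fidelity of a pathway: lagged MI between input and PC output
#'
#' For each realization, converts the chosen pathway's spike train and the
#' pooled PC output to 5 ms-kernel rate series and computes the kNN mutual
#' information as a function of the output lag; fidelity is summarised by
#' the maximum of each curve.
#'
#' @param spec a [motif_spec()] containing a parallel pathway.
#' @param pathway `"theta"` or `"parallel"`.
#' @param plan a [run_plan()].
#' @param lags_ms lag grid (ms).
#' @param dt_ms integration step of the simulations (ms).
#' @param runs optional precomputed list of `simulation_result`s from the
#'   same spec/plan (reused across pathways to avoid re-simulating).
#' @return list of class `"protocol_result"` with per-realization curves,
#'   `max_mi` (mean over realizations), `max_mi_sd`, `max_lag_ms`.
#' @export
fidelity_protocol <- function(spec, pathway = c("theta", "parallel"),
                              plan = run_plan(duration_s = 30,
                                              n_realizations = 5),
                              lags_ms = seq(-40, 40, by = 4), dt_ms = 0.025,
                              runs = NULL) {
  pathway <- match.arg(pathway)
  stopifnot(inherits(spec, "motif_spec"))
  if (pathway == "parallel" && is.null(spec$parallel)) {
    stop("spec has no parallel pathway", call. = FALSE)
  }
  if (is.null(runs)) {
    net <- build_motif(spec, seed = plan$seed)
    runs <- run_realizations(net, plan, dt_ms = dt_ms)
  }
  curves <- lapply(runs, function(res) {
    lagged_mi(pathway_input_rate(res, spec, pathway), pc_output_rate(res),
              lags_ms = lags_ms)
  })
  mx <- vapply(curves, function(cv) cv$max_mi, 0)
  structure(list(pathway = pathway, curves = curves, lags_ms = lags_ms,
                 max_mi = mean(mx), max_mi_sd = sd(mx),
                 max_lag_ms = vapply(curves, function(cv) cv$max_lag_ms, 0)),
            class = "protocol_result")
}

#' Consistency of the response to a repeated input
#'
#' Runs realizations in which the chosen pathway's input stream is held
#' bit-identical while all other inputs vary, then measures the MI between
#' the PC outputs of every pair of realizations. High values mean the
#' response is reliably determined by that pathway.
#'
#' @inheritParams fidelity_protocol
#' @return list of class `"protocol_result"` with `pair_mi`, `mean_mi`,
#'   `sd_mi`.
#' @export
consistency_protocol <- function(spec, pathway = c("theta", "parallel"),
                                 plan = run_plan(duration_s = 30,
                                                 n_realizations = 5),
                                 dt_ms = 0.025, runs = NULL) {
  pathway <- match.arg(pathway)
  if (plan$n_realizations < 2) stop("need at least 2 realizations", call. = FALSE)
  plan$fixed_inputs <- union(plan$fixed_inputs, pathway)
  if (is.null(runs)) {
    net <- build_motif(spec, seed = plan$seed)
    runs <- run_realizations(net, plan, dt_ms = dt_ms)
  }
  outs <- lapply(runs, pc_output_rate)
  pairs <- utils::combn(length(outs), 2)
  stride <- 5L
  pair_mi <- apply(pairs, 2, function(pr) {
    a <- outs[[pr[1]]]$values; b <- outs[[pr[2]]]$values
    idx <- seq(1L, min(length(a), length(b)), by = stride)
    mutual_information(a[idx], b[idx])
  })
  structure(list(pathway = pathway, pair_mi = pair_mi,
                 mean_mi = mean(pair_mi), sd_mi = sd(pair_mi)),
            class = "protocol_result")
}

#' Single-pulse perturbation protocol
#'
#' Per trial, runs paired simulations with and without one synaptic volley
#' delivered to every PC's proximal dendrite at a random time inside
#' `pulse_window_s`, under identical input streams. The encoding value is
#' the normalised difference between the perturbed and unperturbed PC
#' population rates in a window after the pulse; each trial is tagged with
#' the theta phase (from the theta-input synaptic current) and the gamma
#' phase (from the > 20 Hz high-passed mean PC potential) at pulse time.
#'
#' @param spec a [motif_spec()].
#' @param pulse_window_s interval (s) from which pulse times are drawn.
#' @param n_trials number of trials.
#' @param weight_uS pulse weight; default tenfold the PC noise weight (the
#'   parallel-pathway strength).
#' @param duration_s simulated duration per run (s).
#' @param response_window_ms window after the pulse scored for a response.
#' @param dt_ms integration step (ms).
#' @param seed global seed.
#' @return data.frame with one row per trial: `t_pulse_ms`,
#'   `theta_phase_deg`, `gamma_phase_deg`, `encoding`.
#' @export
perturbation_protocol <- function(spec, pulse_window_s = c(1, 1.5),
                                  n_trials = 20,
                                  weight_uS = 10 * spec$noise$weight_pc_uS,
                                  duration_s = 2, response_window_ms = 50,
                                  dt_ms = 0.025, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  if (pulse_window_s[2] + response_window_ms / 1000 > duration_s) {
    stop("pulse window exceeds the simulated duration", call. = FALSE)
  }
  net <- build_motif(spec, seed = seed)
  prox_slots <- net$slot_index$prox
  set.seed(derive_seed(seed, "perturbation-times"))
  t_pulse <- runif(n_trials, pulse_window_s[1], pulse_window_s[2]) * 1000
  out <- data.frame()
  for (tr in seq_len(n_trials)) {
    seeds <- list(theta = derive_seed(seed, "theta", tr),
                  noise = derive_seed(seed, "noise", tr),
                  parallel = derive_seed(seed, "parallel", tr))
    base <- run_simulation(net, duration_s, dt_ms = dt_ms, seeds = seeds)
    pert <- run_simulation(net, duration_s, dt_ms = dt_ms, seeds = seeds,
                           extra_events = data.frame(
                             t_ms = t_pulse[tr], slot = prox_slots,
                             w = weight_uS))
    rb <- pc_output_rate(base); rp <- pc_output_rate(pert)
    win <- which(seq_along(rb$values) * rb$dt_ms > t_pulse[tr] &
                 seq_along(rb$values) * rb$dt_ms <= t_pulse[tr] + response_window_ms)
    ## approximate number of added/displaced output spikes in the window
    enc <- sum(abs(rp$values[win] - rb$values[win])) * rb$dt_ms /
      rb$timescale_ms
    it <- round(t_pulse[tr] / base$dt_ms)
    thph <- extract_phase(-base$i_theta, base$fs, 8, 4)[it]
    hp <- base$v_pc - as.numeric(band_filter(base$v_pc, base$fs, 0.5, 20))
    gph <- Arg(analytic_signal(hp))[it]
    out <- rbind(out, data.frame(t_pulse_ms = t_pulse[tr],
                                 theta_phase_deg = thph * 180 / pi,
                                 gamma_phase_deg = gph * 180 / pi,
                                 encoding = enc))
  }
  out
}

#' Circular concentration of encoding over gamma phase
#'
#' Length of the encoding-weighted resultant vector of the gamma phases: 1
#' when responses occur at a single gamma phase, 0 when they are spread
#' uniformly over the cycle.
#'
#' @param trials result of [perturbation_protocol()].
#' @return scalar in `[0, 1]`.
#' @export
encoding_phase_concentration <- function(trials) {
  w <- trials$encoding
  if (sum(w) <= 0) return(0)
  Mod(sum(w * exp(1i * trials$gamma_phase_deg * pi / 180)) / sum(w))
}
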