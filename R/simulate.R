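## Network integration front-end, run plans, and spike-train observables.

#' Plan for a batch of simulation realizations
#'
#' @param duration_s simulated duration per realization (s).
#' @param n_realizations number of realizations.
#' @param fixed_inputs subset of `c("theta", "noise", "parallel")` whose
#'   random streams are held identical across realizations (the remaining
#'   streams get fresh seeds per realization).
#' @param seed global seed; per-stream, per-realization seeds are derived
#'   deterministically from it.
#' @return list of class `"run_plan"`.
#' @export
run_plan <- function(duration_s = 60, n_realizations = 20,
                     fixed_inputs = character(), seed = 1L) {
  stopifnot(all(fixed_inputs %in% c("theta", "noise", "parallel")))
  structure(list(duration_s = duration_s,
                 n_realizations = as.integer(n_realizations),
                 fixed_inputs = fixed_inputs, seed = as.integer(seed)),
            class = "run_plan")
}

csr_by_group <- function(group, n_groups, ...) {
  ord <- order(group)
  cols <- lapply(list(...), function(v) v[ord])
  counts <- tabulate(group, nbins = n_groups)
  ptr <- c(0L, cumsum(counts))
  c(list(ptr = as.integer(ptr)), cols)
}

#' Integrate one realization of a network
#'
#' Runs the conductance-based model with the exponential-Euler scheme at
#' fixed step `dt_ms`, delivering delayed spikes through an event queue.
#' Records spike rasters plus, at `record_dt_ms` resolution, the mean PC
#' somatic membrane potential `v_pc`, the mean somatic transmembrane current
#' `i_transm` (outward positive; theta troughs correspond to minima), the
#' mean theta-input synaptic current in the PC dendrites `i_theta`, and the
#' mean BC potential `v_bc`.
#'
#' @param network a [build_motif()] result.
#' @param duration_s simulated time (s).
#' @param dt_ms integration step (ms).
#' @param seeds list with integer seeds `theta`, `noise`, `parallel`
#'   (defaults derived from `seed`).
#' @param seed global seed used when `seeds` entries are missing.
#' @param record_dt_ms resolution of the recorded series (ms).
#' @param theta_spikes optional precomputed
#'   [generate_theta_spike_packets()] result (overrides `seeds$theta`).
#' @param extra_events optional data.frame with `t_ms`, `slot` (0-based),
#'   `w` (uS) delivering additional synaptic events (e.g. perturbations).
#' @param spike_threshold_mV,refractory_ms somatic spike detection.
#' @return list of class `"simulation_result"`.
#' @export
run_simulation <- function(network, duration_s, dt_ms = 0.025, seeds = list(),
                           seed = 1L, record_dt_ms = 1,
                           theta_spikes = NULL, extra_events = NULL,
                           spike_threshold_mV = -10, refractory_ms = 2) {
  stopifnot(inherits(network, "network"))
  assert_positive(duration_s, "duration_s")
  seeds <- utils::modifyList(
    list(theta = derive_seed(seed, "theta"),
         noise = derive_seed(seed, "noise"),
         parallel = derive_seed(seed, "parallel")), seeds)
  spec <- network$spec
  if (is.null(theta_spikes)) {
    theta_spikes <- if (length(network$theta_conn$pre)) {
      generate_theta_spike_packets(duration_s, spec$theta, seeds$theta)
    } else list(times_ms = numeric(0), unit = integer(0))
  }
  rec_every <- max(1L, round(record_dt_ms / dt_ms))
  n_steps <- as.integer(round(duration_s * 1000 / dt_ms / rec_every) * rec_every)

  tc <- network$theta_conn
  th_csr <- csr_by_group(tc$pre, spec$theta$n_driver_units,
                         slot = tc$slot, w = tc$w,
                         delay_steps = pmax(1L, as.integer(round(tc$delay_ms / dt_ms))))
  nc <- network$net_conn
  net_csr <- csr_by_group(nc$pre, network$n_pc + network$n_bc,
                          slot = nc$slot, w = nc$w,
                          delay_steps = pmax(1L, as.integer(round(nc$delay_ms / dt_ms))))
  if (is.null(extra_events)) {
    extra_events <- data.frame(t_ms = numeric(0), slot = integer(0),
                               w = numeric(0))
  }
  ev <- extra_events[order(extra_events$t_ms), , drop = FALSE]

  out <- .run_network_cpp(
    nodes = network$nodes, edges = network$edges, slots = network$slots,
    net_syn = net_csr,
    theta_in = c(list(t = theta_spikes$times_ms,
                      unit = as.integer(theta_spikes$unit - 1L)),
                 list(ptr = th_csr$ptr, slot = th_csr$slot, w = th_csr$w,
                      delay_steps = th_csr$delay_steps)),
    poisson_in = network$poisson,
    extra_in = list(t = ev$t_ms, slot = as.integer(ev$slot), w = ev$w),
    opts = list(dt = dt_ms, n_steps = n_steps, rec_every = rec_every,
                v_init = -65, spike_threshold = spike_threshold_mV,
                refractory_ms = refractory_ms, mg = 1,
                noise_seed = as.double(seeds$noise),
                parallel_seed = as.double(seeds$parallel),
                theta_current_slots = as.integer(network$theta_current_slots)))

  is_pc <- out$spike_cell <= network$n_pc
  structure(list(
    pc_raster = data.frame(unit = out$spike_cell[is_pc],
                           t_ms = out$spike_t[is_pc]),
    bc_raster = data.frame(unit = out$spike_cell[!is_pc] - network$n_pc,
                           t_ms = out$spike_t[!is_pc]),
    v_pc = out$v_pc, i_transm = out$i_transm, i_theta = out$i_theta,
    v_bc = out$v_bc, i_dend = out$i_dend,
    parallel_times_ms = sort(out$parallel_t),
    dt_ms = record_dt_ms * 1, fs = 1000 / record_dt_ms,
    duration_s = n_steps * dt_ms / 1000, integration_dt_ms = dt_ms,
    seeds = seeds, theta_peaks_ms = theta_spikes$peaks_ms %||% numeric(0),
    n_pc = network$n_pc, n_bc = network$n_bc),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %.1f s, %d PC / %d BC\n",
              x$duration_s, x$n_pc, x$n_bc))
  cat(sprintf("  PC rate %.3f Hz, BC rate %.2f Hz\n",
              firing_rate(x$pc_raster, x$n_pc, x$duration_s),
              firing_rate(x$bc_raster, x$n_bc, x$duration_s)))
  invisible(x)
}

#' Run a batch of realizations of a network
#'
#' Per realization, each input stream (theta packets, background noise,
#' parallel pathway) gets a seed derived from the plan seed; streams listed
#' in `fixed_inputs` reuse the realization-0 seed so their event times are
#' bit-identical across realizations.
#'
#' @param network a [build_motif()] result.
#' @param plan a [run_plan()].
#' @param dt_ms integration step (ms).
#' @param ... passed to [run_simulation()].
#' @return list of `simulation_result`s.
#' @export
run_realizations <- function(network, plan = run_plan(), dt_ms = 0.025, ...) {
  stopifnot(inherits(plan, "run_plan"))
  lapply(seq_len(plan$n_realizations), function(r) {
    idx <- function(stream) if (stream %in% plan$fixed_inputs) 0L else r
    seeds <- list(theta = derive_seed(plan$seed, "theta", idx("theta")),
                  noise = derive_seed(plan$seed, "noise", idx("noise")),
                  parallel = derive_seed(plan$seed, "parallel", idx("parallel")))
    run_simulation(network, plan$duration_s, dt_ms = dt_ms, seeds = seeds, ...)
  })
}

#' Mean firing rate per unit
#'
#' @param raster data.frame with a spike time per row (columns `unit`,
#'   `t_ms`).
#' @param n_units population size.
#' @param duration_s recording duration (s).
#' @return rate in Hz per unit.
#' @export
firing_rate <- function(raster, n_units, duration_s) {
  assert_positive(duration_s, "duration_s")
  nrow(raster) / (n_units * duration_s)
}

#' Theta-phase spiking distribution
#'
#' Assigns each spike the instantaneous phase of the band-filtered reference
#' series and returns the spike density over phase, normalised so the
#' integral over one cycle equals 1. Phase 0 is the reference peak; +/-180
#' degrees its trough.
#'
#' @param spike_times_ms spike times (ms).
#' @param reference numeric reference series (e.g. the theta-input synaptic
#'   current in the PC dendrites).
#' @param fs sampling rate of `reference` (Hz).
#' @param band filter passband (Hz).
#' @param n_bins number of phase bins.
#' @return list with `phase_deg` (bin centres), `density` (per radian),
#'   `circular_mean_deg`.
#' @export
phase_binned_spiking <- function(spike_times_ms, reference, fs,
                                 band = c(4, 12), n_bins = 24) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[2] <= band[1]) {
    stop("invalid phase band", call. = FALSE)
  }
  n <- length(reference)
  idx <- round(spike_times_ms * fs / 1000) + 1L
  if (any(idx < 1 | idx > n)) {
    stop("reference series does not cover all spike times", call. = FALSE)
  }
  ph <- extract_phase(reference, fs, mean(band), diff(band) / 2)
  sp <- ph[idx]
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(sp, breaks, all.inside = TRUE),
                     nbins = n_bins)
  density <- counts / sum(counts) / diff(breaks)[1]
  list(phase_deg = (breaks[-1] - diff(breaks)[1] / 2) * 180 / pi,
       density = density,
       circular_mean_deg = Arg(mean(exp(1i * sp))) * 180 / pi)
}

#' Latency from dendritic synaptic input to somatic depolarisation
#'
#' Places a single subthreshold synaptic event on the chosen compartment of
#' an isolated pyramidal cell and measures the delay until the somatic
#' depolarisation rate first exceeds a fraction of its peak.
#'
#' @param cell a [pyramidal_cell_params()].
#' @param stimulus_compartment `"soma"`, `"proximal"` or `"distal"`.
#' @param weight_uS AMPA weight of the test event.
#' @param onset_fraction fraction of the peak somatic dV/dt defining onset.
#' @return delay in ms.
#' @export
measure_dendritic_delay <- function(cell = pyramidal_cell_params(),
                                    stimulus_compartment = c("distal",
                                                             "proximal",
                                                             "soma"),
                                    weight_uS = 5e-4, onset_fraction = 0.05) {
  stimulus_compartment <- match.arg(stimulus_compartment)
  spec <- motif_spec("theta_ing", n_pc = 1, n_bc = 1,
                     noise = noise_spec(weight_pc_uS = 0, weight_bc_uS = 0),
                     theta_target = if (stimulus_compartment == "proximal")
                       "proximal" else "distal", pc = cell)
  net <- build_motif(spec, seed = 1L)
  slot <- switch(stimulus_compartment,
                 soma = net$slot_index$soma_noise[1],
                 proximal = if (spec$theta_target == "proximal")
                   net$slot_index$th_a[1] else net$slot_index$prox[1],
                 distal = net$slot_index$th_a[1])
  t_stim <- 100
  res <- run_simulation(net, duration_s = 0.15, record_dt_ms = 0.025,
                        theta_spikes = list(times_ms = numeric(0),
                                            unit = integer(0)),
                        extra_events = data.frame(t_ms = t_stim, slot = slot,
                                                  w = weight_uS))
  v <- res$v_pc
  t <- seq_along(v) * res$dt_ms
  post <- t > t_stim + 0.1
  dv <- c(0, diff(v)) / res$dt_ms
  dv[!post] <- 0
  pk <- max(dv)
  if (pk < 1e-4) stop("stimulus evoked no measurable somatic deflection",
                      call. = FALSE)
  t[which(dv > onset_fraction * pk)[1]] - t_stim
}
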