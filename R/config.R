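## Configuration round-trip, experiment orchestration (sweeps), and
## reproducibility bookkeeping.

#' Serialise a motif specification to YAML
#'
#' @param spec a [motif_spec()].
#' @param path optional file path; when omitted the YAML string is returned.
#' @return the YAML string, invisibly when written to a file.
#' @export
motif_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "motif_spec"))
  lst <- unclass(spec)
  d <- lst$pc$densities
  lst$pc$densities <- stats::setNames(
    lapply(seq_len(nrow(d)), function(i) as.list(d[i, ])), rownames(d))
  lst$bc$densities <- as.list(lst$bc$densities)
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  txt <- yaml::as.yaml(strip(lst))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Rebuild a motif specification from YAML
#'
#' @param x a YAML string or a file path produced by [motif_to_yaml()].
#' @return a validated [motif_spec()].
#' @export
motif_from_yaml <- function(x) {
  lst <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  pc <- lst$pc
  geometry <- lapply(pc$geometry, function(g) do.call(compartment_geometry, g))
  dens <- do.call(rbind, lapply(pc$densities, unlist))
  ## the stored spec is already resolved (populations, fan-ins and weights
  ## at their realized scale), so it is rebuilt at scale 1
  out <- motif_spec(kind = lst$kind,
             n_pc = lst$n_pc, n_bc = lst$n_bc,
             weights = lst$weights,
             fan_in = lst$fan_in, delays = lst$delays,
             theta = do.call(theta_drive_spec, lst$theta),
             noise = do.call(noise_spec, lst$noise),
             parallel = if (!is.null(lst$parallel))
               do.call(parallel_spec, lst$parallel),
             theta_target = lst$theta_target,
             inhibition_target = lst$inhibition_target,
             pc = pyramidal_cell_params(geometry = geometry, densities = dens,
                                        e_leak = pc$e_leak, e_na = pc$e_na,
                                        e_k = pc$e_k, e_h = pc$e_h),
             bc = basket_cell_params(
               geometry = do.call(compartment_geometry, lst$bc$geometry),
               densities = unlist(lst$bc$densities),
               e_leak = lst$bc$e_leak, e_na = lst$bc$e_na, e_k = lst$bc$e_k,
               input_delay_ms = lst$bc$input_delay_ms))
  out$scale_factor <- lst$scale_factor
  out
}

#' Reduced-size motif preserving per-neuron input statistics
#'
#' A 50 PC / 10 BC configuration of the calibrated motifs used for
#' sign-based analyses: fan-ins are clamped at the available population
#' sizes, the affected convergent weights are rescaled so every neuron
#' receives a comparable total synaptic drive to the full-size network
#' (20 -> 10 inhibitory inputs per PC at twice the weight, 20 -> 9 BC->BC
#' at 2.2x), and the two motif-defining weights (theta->BC, PC->BC) are
#' re-matched at this size so both motifs fire at ~0.5 Hz per PC.
#'
#' @param kind motif kind, see [motif_spec()].
#' @param ... further arguments passed to [motif_spec()] (e.g. `parallel`,
#'   `theta`, weight overrides, which take precedence).
#' @return a [motif_spec()].
#' @export
desk_scale_motif <- function(kind = c("theta_ing", "theta_ping", "mixed"),
                             ...) {
  args <- list(...)
  w <- list(bc_pc = 6e-3, pc_bc = 2.6e-3, bc_bc = 1.1e-3, theta_bc = 3.2e-6)
  if (!is.null(args$weights)) w <- utils::modifyList(w, args$weights)
  args$weights <- w
  do.call(motif_spec, c(list(kind = match.arg(kind), n_pc = 50, n_bc = 10),
                        args))
}

#' Motif configuration for the information-transmission protocols
#'
#' Reduced-size motifs with the parallel pathway enabled, re-balanced so
#' both motifs keep sparse (~0.5 Hz) PC firing under the extra drive: the
#' background noise is weakened (the parallel strength is tied to it
#' tenfold), the parallel pathway fires at a 5 ms mean interval, and the
#' motif-defining weights are re-matched. Used by the fidelity, consistency
#' and perturbation protocols.
#'
#' @param kind `"theta_ing"` or `"theta_ping"`.
#' @param parallel_interval_ms mean interval of the parallel input (1-5 ms).
#' @return a [motif_spec()].
#' @export
protocol_motif <- function(kind = c("theta_ing", "theta_ping"),
                           parallel_interval_ms = 5) {
  kind <- match.arg(kind)
  w <- if (kind == "theta_ing") list(theta_bc = 1.6e-6) else list(pc_bc = 2e-3)
  desk_scale_motif(kind, weights = w,
                   parallel = parallel_spec(parallel_interval_ms),
                   noise = noise_spec(weight_pc_uS = 2e-5,
                                      weight_bc_uS = 1e-5))
}

#' Amplitude frequency at the comodulogram's global maximum
#'
#' @param cfc a CFC `comodulogram`.
#' @return the amplitude-axis frequency (Hz) of the global maximum.
#' @export
summarize_peak_gamma <- function(cfc) {
  stopifnot(inherits(cfc, "comodulogram"))
  pk <- comodulogram_peak(cfc)
  cfc$amp_freqs[pk[2]]
}

#' Run a parameter sweep over motif configurations
#'
#' Executes the full pipeline (build, simulate, CFC, CFD) over the cartesian
#' product of the sweep axes. Each axis is a named list entry whose name is
#' a parameter path inside the motif spec (e.g. `"weights.theta_bc"`) and
#' whose value is the vector of values to sweep. Every cell derives its
#' seeds deterministically from the global seed and the cell index, and is
#' summarised by PC/BC firing rates, CFD_avg and the peak-CFC gamma
#' frequency.
#'
#' @param base_spec the base [motif_spec()]; `kind` is re-derived per cell
#'   from the swept weights (pure motifs at the axes' zeros, mixed inside).
#' @param axes named list of parameter paths to value vectors.
#' @param duration_s simulated duration per cell (s).
#' @param n_realizations realizations per cell (averaged).
#' @param seed global seed.
#' @param signal which recorded series to analyse.
#' @param phase_freqs,amp_freqs comodulogram grids.
#' @param dt_ms integration step (ms).
#' @return data.frame with one row per cell: axis values, `pc_rate`,
#'   `bc_rate`, `cfd_avg`, `peak_gamma`.
#' @export
run_sweep <- function(base_spec, axes, duration_s = 30, n_realizations = 1,
                      seed = 1L, signal = c("i_transm", "v_pc", "i_dend"),
                      phase_freqs = model_phase_freqs(),
                      amp_freqs = model_amp_freqs(), dt_ms = 0.025) {
  signal <- match.arg(signal)
  stopifnot(inherits(base_spec, "motif_spec"), length(axes) >= 1)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(axes)
  out <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    spec <- base_spec
    for (ax in names(axes)) {
      path <- strsplit(ax, ".", fixed = TRUE)[[1]]
      spec[[path]] <- grid[cell, ax]
    }
    ## re-derive the motif kind from the realized weights
    spec$kind <- if (spec$weights$theta_bc > 0 && spec$weights$pc_bc > 0) {
      "mixed"
    } else if (spec$weights$pc_bc > 0) "theta_ping" else "theta_ing"
    acc <- data.frame()
    for (r in seq_len(n_realizations)) {
      s <- derive_seed(seed, sprintf("sweep-cell-%d", cell), r)
      net <- build_motif(spec, s)
      res <- run_simulation(net, duration_s, seed = s, dt_ms = dt_ms)
      x <- res[[signal]]
      cfc <- cfc_comodulogram(x, res$fs, phase_freqs, amp_freqs)
      cfd <- cfd_map(x, res$fs, phase_freqs, amp_freqs, cfc = cfc)
      acc <- rbind(acc, data.frame(
        pc_rate = firing_rate(res$pc_raster, res$n_pc, res$duration_s),
        bc_rate = firing_rate(res$bc_raster, res$n_bc, res$duration_s),
        cfd_avg = cfd_avg(cfd, cfc),
        peak_gamma = summarize_peak_gamma(cfc)))
    }
    out[[cell]] <- cbind(grid[cell, , drop = FALSE], as.data.frame(t(colMeans(acc))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
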