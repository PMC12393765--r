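## theta-ING / theta-PING / mixed motifs: populations, random connectivity,
## delay distributions, theta drive, Poisson noise, parallel pathway.

#' Theta-drive specification
#'
#' An external population of driver units emits spike packets: the interval
#' between consecutive packet peaks is Gaussian `N(mu_T, sigma_T^2)` and
#' each cycle contributes `spikes_per_cycle` spikes at times Gaussian around
#' the peak with sd `w`, assigned uniformly at random to driver units. The
#' inter- and intra-cycle jitter is what makes the theta-gamma directionality
#' measurable.
#'
#' @param mu_T_ms,sigma_T_ms inter-peak interval mean and sd (ms).
#' @param w_ms intra-cycle spike-time sd (ms).
#' @param spikes_per_cycle spikes per theta cycle.
#' @param n_driver_units number of driver units.
#' @param delay_pc_ms,delay_bc_ms transmission delay means to PC dendrites
#'   and to BCs (ms).
#' @param bc_dendritic_delay_ms fixed extra delay to BCs standing in for
#'   their fast dendritic transmission (ms).
#' @return list of class `"theta_drive_spec"`.
#' @export
theta_drive_spec <- function(mu_T_ms = 125, sigma_T_ms = 16, w_ms = 25,
                             spikes_per_cycle = 10000, n_driver_units = 500,
                             delay_pc_ms = 20, delay_bc_ms = 20,
                             bc_dendritic_delay_ms = 1) {
  if (mu_T_ms <= 3 * sigma_T_ms) {
    stop("mu_T must exceed 3 x sigma_T", call. = FALSE)
  }
  assert_positive(w_ms, "w_ms")
  assert_positive(spikes_per_cycle, "spikes_per_cycle")
  assert_positive(n_driver_units, "n_driver_units")
  structure(list(mu_T_ms = mu_T_ms, sigma_T_ms = sigma_T_ms, w_ms = w_ms,
                 spikes_per_cycle = as.integer(spikes_per_cycle),
                 n_driver_units = as.integer(n_driver_units),
                 delay_pc_ms = delay_pc_ms, delay_bc_ms = delay_bc_ms,
                 bc_dendritic_delay_ms = bc_dendritic_delay_ms),
            class = "theta_drive_spec")
}

#' Background-noise specification
#'
#' Independent Poisson sources (default mean interval 1 ms, i.e. 1000
#' events/s) target the PC soma, the PC proximal dendrite, and the BCs.
#'
#' @param mean_interval_ms mean inter-event interval (ms).
#' @param weight_pc_uS,weight_bc_uS AMPA weights of single noise events (uS).
#' @export
noise_spec <- function(mean_interval_ms = 1, weight_pc_uS = 5e-5,
                       weight_bc_uS = 1e-5) {
  assert_positive(mean_interval_ms, "mean_interval_ms")
  structure(list(mean_interval_ms = mean_interval_ms,
                 weight_pc_uS = weight_pc_uS, weight_bc_uS = weight_bc_uS),
            class = "noise_spec")
}

#' Parallel-pathway specification
#'
#' A second Poisson input onto the PC proximal dendrite competing with the
#' theta pathway; its synaptic strength is tenfold the background noise.
#'
#' @param mean_interval_ms mean inter-event interval (1-5 ms).
#' @param weight_factor weight relative to the PC noise weight (fixed 10).
#' @export
parallel_spec <- function(mean_interval_ms = 3, weight_factor = 10) {
  assert_positive(mean_interval_ms, "mean_interval_ms")
  if (weight_factor != 10) {
    stop("parallel-pathway weight is tenfold the background noise", call. = FALSE)
  }
  structure(list(mean_interval_ms = mean_interval_ms,
                 weight_factor = weight_factor), class = "parallel_spec")
}

#' Calibrated synaptic weights (uS) and fan-ins of the default motifs
#'
#' Peak conductances of single synapses and convergent connection counts,
#' calibrated so that the full-size motifs reproduce sparse in-vivo-like PC
#' firing (~0.5 Hz) with theta-nested gamma in the 30-100 Hz band, a higher
#' gamma frequency in the feedforward (ING) than the feedback (PING) motif,
#' and dendritic delays of 2-5 ms. `pc_bc` applies to the theta-PING and
#' mixed motifs, `theta_bc` to the theta-ING and mixed motifs.
#'
#' @return named list with `weights` (uS) and `fan_in` (counts).
#' @export
motif_defaults <- function() {
  list(
    weights = list(theta_pc = 4.5e-6, theta_bc = 3.75e-6,
                   bc_pc = 3e-3, bc_bc = 5e-4, pc_bc = 1.1e-3,
                   nmda_ratio = 0.1),
    fan_in = list(theta_pc = 20L, theta_bc = 20L,
                  bc_pc = 20L, bc_bc = 20L, pc_bc = 80L),
    delays = list(theta_pc = 20, theta_bc = 20, bc_pc = 1.5,
                  pc_bc = 1.5, bc_bc = 1.5, sd = 0.2)
  )
}

#' Network-motif specification
#'
#' Assembles the full parameterisation of a theta-ING, theta-PING or mixed
#' motif: population sizes, synaptic weights and fan-ins, delay
#' distributions, theta drive, background noise and the optional parallel
#' pathway. The theta-ING motif has no PC->BC connection (feedforward
#' inhibition only); the theta-PING has no theta->BC connection (BCs are
#' recruited by PC feedback); mixed motifs have both. BC->BC self-inhibition
#' is present in all motifs.
#'
#' @param kind `"theta_ing"`, `"theta_ping"` or `"mixed"`.
#' @param n_pc,n_bc population sizes (defaults 200 and 40 at scale 1).
#' @param weights,fan_in,delays overrides of [motif_defaults()] entries.
#' @param theta a [theta_drive_spec()].
#' @param noise a [noise_spec()].
#' @param parallel optional [parallel_spec()].
#' @param theta_target PC compartment receiving the theta drive
#'   (`"distal"` or `"proximal"`).
#' @param inhibition_target PC compartment receiving BC inhibition
#'   (default `"soma"`).
#' @param scale_factor network scaling k: multiplies population sizes and
#'   projection counts, divides projection weights (noise is per-neuron and
#'   does not scale).
#' @param pc,bc cell parameter sets.
#' @return list of class `"motif_spec"`.
#' @export
motif_spec <- function(kind = c("theta_ing", "theta_ping", "mixed"),
                       n_pc = 200, n_bc = 40,
                       weights = list(), fan_in = list(), delays = list(),
                       theta = theta_drive_spec(), noise = noise_spec(),
                       parallel = NULL, theta_target = c("distal", "proximal"),
                       inhibition_target = c("soma", "proximal", "distal"),
                       scale_factor = 1,
                       pc = pyramidal_cell_params(),
                       bc = basket_cell_params()) {
  kind <- match.arg(kind)
  theta_target <- match.arg(theta_target)
  inhibition_target <- match.arg(inhibition_target)
  assert_positive(scale_factor, "scale_factor")
  def <- motif_defaults()
  w <- utils::modifyList(def$weights, weights)
  fi <- utils::modifyList(def$fan_in, fan_in)
  dl <- utils::modifyList(def$delays, delays)

  if (kind == "theta_ing") w$pc_bc <- 0
  if (kind == "theta_ping") w$theta_bc <- 0
  if (kind == "mixed" && (w$pc_bc <= 0 || w$theta_bc <= 0)) {
    stop("mixed motif needs both pc_bc and theta_bc weights > 0", call. = FALSE)
  }
  if (w$bc_bc <= 0) stop("BC->BC self-inhibition must be present", call. = FALSE)
  for (nm in names(w)) if (w[[nm]] < 0) stop("negative weight: ", nm, call. = FALSE)

  k <- scale_factor
  n_pc <- max(1L, as.integer(round(n_pc * k)))
  n_bc <- max(1L, as.integer(round(n_bc * k)))
  if (k != 1) {
    for (nm in c("theta_pc", "theta_bc", "bc_pc", "bc_bc", "pc_bc")) {
      fi[[nm]] <- max(1L, as.integer(round(fi[[nm]] * k)))
      w[[nm]] <- w[[nm]] / k
    }
  }
  fi$theta_pc <- min(fi$theta_pc, theta$n_driver_units)
  fi$theta_bc <- min(fi$theta_bc, theta$n_driver_units)
  fi$bc_pc <- min(fi$bc_pc, n_bc)
  fi$bc_bc <- min(fi$bc_bc, n_bc - 1L)
  fi$pc_bc <- min(fi$pc_bc, n_pc)

  structure(list(kind = kind, n_pc = n_pc, n_bc = n_bc, weights = w,
                 fan_in = fi, delays = dl, theta = theta, noise = noise,
                 parallel = parallel, theta_target = theta_target,
                 inhibition_target = inhibition_target,
                 scale_factor = scale_factor, pc = pc, bc = bc),
            class = "motif_spec")
}

#' Theta-modulated spike packets of the external driver population
#'
#' Cycle peak times form a renewal process with Gaussian intervals
#' `N(mu_T, sigma_T^2)` (non-positive intervals are resampled, up to 100
#' attempts); each cycle contributes `spikes_per_cycle` spike times drawn
#' `N(peak, w^2)`, assigned uniformly at random to driver units.
#'
#' @param duration_s simulated duration (s).
#' @param spec a [theta_drive_spec()].
#' @param seed integer seed.
#' @return list with sorted `times_ms`, `unit` (1-based driver ids), and
#'   `peaks_ms`.
#' @export
generate_theta_spike_packets <- function(duration_s, spec = theta_drive_spec(),
                                         seed = 1L) {
  assert_positive(duration_s, "duration_s")
  set.seed(seed)
  dur <- duration_s * 1000
  peaks <- numeric(0)
  t <- 0
  while (t < dur + 3 * spec$w_ms) {
    iv <- rnorm(1, spec$mu_T_ms, spec$sigma_T_ms)
    tries <- 0
    while (iv <= 0) {
      tries <- tries + 1
      if (tries > 100) stop("could not sample a positive theta interval",
                            call. = FALSE)
      iv <- rnorm(1, spec$mu_T_ms, spec$sigma_T_ms)
    }
    t <- t + iv
    peaks <- c(peaks, t)
  }
  times <- rep(peaks, each = spec$spikes_per_cycle) +
    rnorm(length(peaks) * spec$spikes_per_cycle, 0, spec$w_ms)
  unit <- sample.int(spec$n_driver_units, length(times), replace = TRUE)
  keep <- times >= 0 & times < dur
  ord <- order(times[keep])
  list(times_ms = times[keep][ord], unit = unit[keep][ord],
       peaks_ms = peaks[peaks < dur])
}

#' Homogeneous Poisson spike train
#'
#' @param duration_s duration (s).
#' @param mean_interval_ms mean inter-event interval (ms).
#' @param seed integer seed.
#' @return sorted spike times (ms).
#' @export
generate_poisson_spikes <- function(duration_s, mean_interval_ms = 1,
                                    seed = 1L) {
  if (duration_s < 0) stop("duration must be non-negative", call. = FALSE)
  assert_positive(mean_interval_ms, "mean_interval_ms")
  set.seed(seed)
  dur <- duration_s * 1000
  n_guess <- max(10, ceiling(dur / mean_interval_ms * 1.2 + 50))
  t <- cumsum(rexp(n_guess, rate = 1 / mean_interval_ms))
  while (length(t) && t[length(t)] < dur) {
    t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate = 1 / mean_interval_ms)))
  }
  t[t < dur]
}

## Gaussian delays truncated to be strictly positive (resample up to 100x).
sample_delays <- function(n, mean, sd) {
  d <- rnorm(n, mean, sd)
  for (tries in seq_len(100)) {
    bad <- d <= 0
    if (!any(bad)) return(d)
    d[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("could not sample positive delays", call. = FALSE)
}

#' Specs for a sweep over the theta -> PC transmission delay
#'
#' Returns motif specs differing only in `delay_pc_ms`, so the relative
#' transmission delay `Delta t = t_theta,BC - t_theta,PC` is swept while the
#' theta -> BC delay stays fixed.
#'
#' @param spec base [motif_spec()].
#' @param delay_pc_values_ms positive delays (ms); e.g. `c(30, 20, 10)` for
#'   `Delta t = -10, 0, +10` ms.
#' @return named list of motif specs (`dt_<value>`).
#' @export
relative_delay_sweep <- function(spec, delay_pc_values_ms = c(30, 20, 10)) {
  stopifnot(inherits(spec, "motif_spec"))
  if (any(delay_pc_values_ms <= 0)) stop("delays must be positive", call. = FALSE)
  out <- lapply(delay_pc_values_ms, function(d) {
    s <- spec
    s$theta$delay_pc_ms <- d
    s
  })
  names(out) <- sprintf("dt_%+g", spec$theta$delay_bc_ms - delay_pc_values_ms)
  out
}

## -- network realization ----------------------------------------------------

## Node layout per PC: 5 compartments x 3 segments in a chain
## (basal1..3, soma1..3, prox1..3, mid1..3, dist1..3); BCs are single nodes.
pc_segment_offset <- function(compartment, segment = 2L) {
  comp <- match(compartment, pc_compartment_names())
  (comp - 1L) * 3L + segment - 1L       # 0-based within-cell offset
}

#' Build a motif into a simulatable network realization
#'
#' Resolves cells into nodes, samples the random connectivity and Gaussian
#' transmission delays, and lays out synaptic conductance slots. The result
#' is deterministic given the seed and fully serialisable.
#'
#' @param spec a [motif_spec()].
#' @param seed integer seed for the connectivity realization.
#' @return list of class `"network"` consumed by [run_simulation()].
#' @export
build_motif <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  set.seed(seed)
  n_pc <- spec$n_pc; n_bc <- spec$n_bc
  pcp <- spec$pc; bcp <- spec$bc
  nodes_per_pc <- 15L
  nn <- n_pc * nodes_per_pc + n_bc

  cm <- gl <- el <- gna <- gk <- ghv <- numeric(nn)
  kin <- integer(nn); cell <- integer(nn)

  geom <- pcp$geometry; dens <- pcp$densities
  seg_area <- vapply(geom, segment_area_cm2, 0)          # cm^2 per segment
  seg_half <- vapply(geom, segment_half_axial_Mohm, 0)   # MOhm

  for (p in seq_len(n_pc)) {
    base <- (p - 1L) * nodes_per_pc
    for (c5 in 1:5) for (s3 in 1:3) {
      i <- base + (c5 - 1L) * 3L + s3
      a <- seg_area[c5]
      cm[i] <- geom[[c5]]$specific_capacitance_uF_cm2 * a * 1000  # nF
      gl[i] <- dens[c5, "gL"] * a * 1000                          # uS
      gna[i] <- dens[c5, "gNa"] * a * 1000
      gk[i] <- dens[c5, "gK"] * a * 1000
      ghv[i] <- dens[c5, "gH"] * a * 1000
      el[i] <- pcp$e_leak
      kin[i] <- 0L
      cell[i] <- p - 1L
    }
  }
  bc_area <- segment_area_cm2(bcp$geometry)
  for (b in seq_len(n_bc)) {
    i <- n_pc * nodes_per_pc + b
    cm[i] <- bcp$geometry$specific_capacitance_uF_cm2 * bc_area * 1000
    gl[i] <- bcp$densities["gL"] * bc_area * 1000
    gna[i] <- bcp$densities["gNa"] * bc_area * 1000
    gk[i] <- bcp$densities["gK"] * bc_area * 1000
    el[i] <- bcp$e_leak
    kin[i] <- 1L
    cell[i] <- n_pc + b - 1L
  }

  ## axial chain edges within each PC
  ne_pc <- nodes_per_pc - 1L
  ea <- eb <- integer(n_pc * ne_pc); eg <- numeric(n_pc * ne_pc)
  half_of_offset <- rep(seg_half, each = 3L)   # MOhm per 0-based offset + 1
  idx <- 0L
  for (p in seq_len(n_pc)) {
    base <- (p - 1L) * nodes_per_pc
    for (o in seq_len(ne_pc)) {
      idx <- idx + 1L
      ea[idx] <- base + o - 1L; eb[idx] <- base + o
      r <- half_of_offset[o] + half_of_offset[o + 1L]   # MOhm
      eg[idx] <- 1 / r                                  # uS
    }
  }

  ## conductance slots
  syn_def <- list(AMPA = synapse_params("AMPA"), NMDA = synapse_params("NMDA"),
                  GABA = synapse_params("GABA_A"))
  kind_code <- c(AMPA = 0L, NMDA = 1L, GABA = 2L)
  slot_node <- integer(0); slot_kind <- integer(0)
  slot_erev <- slot_taur <- slot_taud <- numeric(0)
  add_slot <- function(node0, kind) {
    p <- syn_def[[kind]]
    slot_node <<- c(slot_node, node0)
    slot_kind <<- c(slot_kind, kind_code[[kind]])
    slot_erev <<- c(slot_erev, p$reversal_mV)
    slot_taur <<- c(slot_taur, p$tau_rise_ms)
    slot_taud <<- c(slot_taud, p$tau_decay_ms)
    length(slot_node) - 1L                               # 0-based slot id
  }
  th_off <- pc_segment_offset(spec$theta_target)
  inh_off <- pc_segment_offset(spec$inhibition_target)
  soma_off <- pc_segment_offset("soma")
  prox_off <- pc_segment_offset("proximal")
  pc_base <- function(p) (p - 1L) * nodes_per_pc
  sl <- list(th_a = integer(n_pc), th_n = integer(n_pc),
             inh = integer(n_pc), soma_noise = integer(n_pc),
             prox = integer(n_pc),
             bc_a = integer(n_bc), bc_n = integer(n_bc), bc_g = integer(n_bc))
  for (p in seq_len(n_pc)) {
    sl$th_a[p] <- add_slot(pc_base(p) + th_off, "AMPA")
    sl$th_n[p] <- add_slot(pc_base(p) + th_off, "NMDA")
    sl$inh[p] <- add_slot(pc_base(p) + inh_off, "GABA")
    sl$soma_noise[p] <- add_slot(pc_base(p) + soma_off, "AMPA")
    sl$prox[p] <- add_slot(pc_base(p) + prox_off, "AMPA")
  }
  for (b in seq_len(n_bc)) {
    i <- n_pc * nodes_per_pc + b - 1L
    sl$bc_a[b] <- add_slot(i, "AMPA")
    sl$bc_n[b] <- add_slot(i, "NMDA")
    sl$bc_g[b] <- add_slot(i, "GABA")
  }

  ## synapse tables
  w <- spec$weights; fi <- spec$fan_in; dl <- spec$delays
  th <- spec$theta
  ## theta -> PC / BC, grouped by presynaptic driver unit
  th_pre <- integer(0); th_slot <- integer(0)
  th_w <- th_delay <- numeric(0)
  add_theta <- function(targets_slots_a, targets_slots_n, fan_in, weight,
                        delay_mean) {
    for (tgt in seq_along(targets_slots_a)) {
      units <- sample.int(th$n_driver_units, fan_in)
      d <- sample_delays(fan_in, delay_mean, dl$sd)
      th_pre <<- c(th_pre, units, units)
      th_slot <<- c(th_slot, rep(targets_slots_a[tgt], fan_in),
                    rep(targets_slots_n[tgt], fan_in))
      th_w <<- c(th_w, rep(weight, fan_in),
                 rep(weight * w$nmda_ratio, fan_in))
      th_delay <<- c(th_delay, d, d)
    }
  }
  add_theta(sl$th_a, sl$th_n, fi$theta_pc, w$theta_pc, th$delay_pc_ms)
  if (w$theta_bc > 0) {
    add_theta(sl$bc_a, sl$bc_n, fi$theta_bc, w$theta_bc,
              th$delay_bc_ms + th$bc_dendritic_delay_ms)
  }

  ## network synapses, grouped by presynaptic cell (1-based cells)
  net_pre <- integer(0); net_slot <- integer(0)
  net_w <- net_delay <- numeric(0)
  add_net <- function(pre_cells, slot, weight, delay_mean) {
    n <- length(pre_cells)
    net_pre <<- c(net_pre, pre_cells)
    net_slot <<- c(net_slot, rep(slot, n))
    net_w <<- c(net_w, rep(weight, n))
    net_delay <<- c(net_delay, sample_delays(n, delay_mean, dl$sd))
  }
  for (p in seq_len(n_pc)) {          # BC -> PC (always present)
    pre <- n_pc + sample.int(n_bc, fi$bc_pc)
    add_net(pre, sl$inh[p], w$bc_pc, dl$bc_pc)
  }
  for (b in seq_len(n_bc)) {          # BC -> BC (excluding self)
    pre <- n_pc + sample(setdiff(seq_len(n_bc), b), fi$bc_bc)
    add_net(pre, sl$bc_g[b], w$bc_bc, dl$bc_bc)
  }
  if (w$pc_bc > 0) {                  # PC -> BC (feedback, AMPA + NMDA)
    for (b in seq_len(n_bc)) {
      pre <- sample.int(n_pc, fi$pc_bc)
      d <- sample_delays(fi$pc_bc, dl$pc_bc, dl$sd)
      net_pre <- c(net_pre, pre, pre)
      net_slot <- c(net_slot, rep(sl$bc_a[b], fi$pc_bc),
                    rep(sl$bc_n[b], fi$pc_bc))
      net_w <- c(net_w, rep(w$pc_bc, fi$pc_bc),
                 rep(w$pc_bc * w$nmda_ratio, fi$pc_bc))
      net_delay <- c(net_delay, d, d)
    }
  }

  ## Poisson sources (stream 0 = background noise, 1 = parallel pathway)
  po_slot <- c(sl$soma_noise, sl$prox, sl$bc_a)
  po_w <- c(rep(spec$noise$weight_pc_uS, 2 * n_pc),
            rep(spec$noise$weight_bc_uS, n_bc))
  po_interval <- rep(spec$noise$mean_interval_ms, 2 * n_pc + n_bc)
  po_stream <- rep(0L, 2 * n_pc + n_bc)
  if (!is.null(spec$parallel)) {
    po_slot <- c(po_slot, sl$prox)
    po_w <- c(po_w, rep(spec$parallel$weight_factor * spec$noise$weight_pc_uS,
                        n_pc))
    po_interval <- c(po_interval, rep(spec$parallel$mean_interval_ms, n_pc))
    po_stream <- c(po_stream, rep(1L, n_pc))
  }

  detect_node <- c(vapply(seq_len(n_pc),
                          function(p) pc_base(p) + soma_off, 0L),
                   n_pc * nodes_per_pc + seq_len(n_bc) - 1L)
  pc_soma_nodes <- as.integer(unlist(lapply(seq_len(n_pc), function(p)
    pc_base(p) + (soma_off - 1L):(soma_off + 1L))))
  pc_dend_nodes <- as.integer(unlist(lapply(seq_len(n_pc), function(p)
    pc_base(p) + (th_off - 1L):(th_off + 1L))))

  structure(list(
    spec = spec, seed = as.integer(seed), n_pc = n_pc, n_bc = n_bc,
    nodes = list(cm = cm, gl = gl, el = el, gna = gna, gk = gk, gh = ghv,
                 ena_pc = pcp$e_na, ek_pc = pcp$e_k, eh = pcp$e_h,
                 ena_bc = bcp$e_na, ek_bc = bcp$e_k,
                 kin = kin, cell = cell, detect_node = detect_node,
                 pc_soma_nodes = pc_soma_nodes,
                 pc_dend_nodes = pc_dend_nodes, n_pc = n_pc),
    edges = list(a = ea, b = eb, g = eg),
    slots = list(node = slot_node, kind = slot_kind, erev = slot_erev,
                 taur = slot_taur, taud = slot_taud),
    slot_index = sl,
    theta_conn = list(pre = th_pre, slot = th_slot, w = th_w,
                      delay_ms = th_delay),
    net_conn = list(pre = net_pre, slot = net_slot, w = net_w,
                    delay_ms = net_delay),
    poisson = list(slot = po_slot, w = po_w, interval = po_interval,
                   stream = po_stream),
    theta_current_slots = c(sl$th_a, sl$th_n)
  ), class = "network")
}

#' Count synapse instances between two populations of a realized network
#'
#' @param network a [build_motif()] result.
#' @param projection one of `"theta_pc"`, `"theta_bc"`, `"pc_bc"`,
#'   `"bc_pc"`, `"bc_bc"`.
#' @return integer count of synapse instances (AMPA + NMDA pairs count once).
#' @export
count_synapses <- function(network,
                           projection = c("theta_pc", "theta_bc", "pc_bc",
                                          "bc_pc", "bc_bc")) {
  projection <- match.arg(projection)
  sl <- network$slot_index
  in_set <- function(slots, set) sum(slots %in% set)
  switch(projection,
    theta_pc = in_set(network$theta_conn$slot, sl$th_a),
    theta_bc = in_set(network$theta_conn$slot, sl$bc_a),
    pc_bc = in_set(network$net_conn$slot[network$net_conn$pre <= network$n_pc],
                   sl$bc_a),
    bc_pc = in_set(network$net_conn$slot, sl$inh),
    bc_bc = in_set(network$net_conn$slot, sl$bc_g))
}
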