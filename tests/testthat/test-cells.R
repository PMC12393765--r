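test_that("NMDA magnesium block follows the voltage-dependent factor", {
  expect_equal(nmda_block_factor(-40, mg = 0), 1.0)
  expect_equal(nmda_block_factor(37.2, mg = 0), 1.0)
  expect_equal(nmda_block_factor(0, mg = 1), 1 / 1.28)
  ## independent evaluation of the printed formula at -70 mV
  V <- -70
  expect_equal(nmda_block_factor(V, 1), 1 / (1 + 0.28 * 1 * exp(-0.062 * V)),
               tolerance = 1e-12)
  ## strictly increasing and bounded in (0, 1] on a dense grid
  v <- seq(-120, 60, length.out = 1000)
  b <- nmda_block_factor(v)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
})

test_that("double-exponential conductance peaks at the closed-form time", {
  p <- synapse_params("AMPA", weight_uS = 2e-3)
  expect_equal(double_exp_conductance(0, p), 0)
  expect_equal(double_exp_conductance(-1, p), 0)
  tr <- p$tau_rise_ms; td <- p$tau_decay_ms
  tp <- tr * td / (td - tr) * log(td / tr)
  expect_equal(double_exp_peak_time(p), tp)
  ## dense grid search confirms the stationary point and the normalisation
  tt <- seq(0, 30, by = 1e-3)
  g <- double_exp_conductance(tt, p)
  expect_equal(tt[which.max(g)], tp, tolerance = 1e-2)
  expect_equal(max(g), p$weight_uS, tolerance = 1e-6)
  ## numerical integral matches the closed form w * (td - tr) / norm
  nrm <- exp(-tp / td) - exp(-tp / tr)
  expect_equal(sum(g) * 1e-3, p$weight_uS * (td - tr) / nrm,
               tolerance = 1e-3)
})

test_that("synapse parameter validation enforces kinetics invariants", {
  expect_error(synapse_params("AMPA", tau_rise_ms = 3, tau_decay_ms = 3),
               "degenerate")
  expect_error(synapse_params("AMPA", tau_rise_ms = 5, tau_decay_ms = 3),
               "exceed")
  expect_error(synapse_params("GABA_A", weight_uS = -1))
  nmda <- synapse_params("NMDA")
  expect_gt(nmda$tau_decay_ms, nmda$tau_rise_ms)
  expect_lt(synapse_params("GABA_A")$reversal_mV, -60)
})

test_that("pyramidal cell geometry has five three-segment compartments", {
  pc <- pyramidal_cell_params()
  expect_length(pc$geometry, 5)
  for (g in pc$geometry) expect_equal(g$n_segments, 3L)
  expect_error(pyramidal_cell_params(
    geometry = list(basal = compartment_geometry(100, 2, n_segments = 1))))
  ## cylinder areas follow from length and diameter
  g <- compartment_geometry(300, 2)
  expect_equal(segment_area_cm2(g), pi * 2e-4 * 0.03 / 3)
})

test_that("calibrated PC is quiescent at rest and has 2-5 ms dendritic delays", {
  net <- quiet_single_cell()
  r <- run_simulation(net, duration_s = 10, theta_spikes = no_theta)
  expect_equal(nrow(r$pc_raster), 0L)

  d_soma <- measure_dendritic_delay(stimulus_compartment = "soma")
  d_prox <- measure_dendritic_delay(stimulus_compartment = "proximal")
  d_dist <- measure_dendritic_delay(stimulus_compartment = "distal")
  expect_lt(d_soma, 0.5)
  expect_gte(d_dist, 2); expect_lte(d_dist, 5)
  expect_gte(d_dist, d_prox)
})

test_that("basket cells fire faster than pyramidal cells to a strong step", {
  ## quiet BC variant (hyperpolarised leak) so the latency is input-evoked
  spec <- motif_spec("theta_ing", n_pc = 1, n_bc = 1,
                     noise = noise_spec(weight_pc_uS = 0, weight_bc_uS = 0),
                     bc = basket_cell_params(e_leak = -67))
  net <- build_motif(spec, seed = 1)
  lat <- function(slot) {
    r <- run_simulation(net, duration_s = 0.1, record_dt_ms = 0.025,
                        theta_spikes = no_theta,
                        extra_events = data.frame(t_ms = 50, slot = slot,
                                                  w = 3e-3))
    raster <- rbind(r$pc_raster,
                    transform(r$bc_raster, unit = unit + r$n_pc))
    after <- raster$t_ms[raster$t_ms > 50]
    if (length(after) == 0) Inf else min(after) - 50
  }
  bc_latency <- lat(net$slot_index$bc_a[1])
  pc_latency <- lat(net$slot_index$soma_noise[1])
  expect_lt(bc_latency, pc_latency)
})
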