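test_that("theta spike packets follow the renewal-packet construction", {
  ## degenerate jitter: exactly periodic delta packets
  sp0 <- theta_drive_spec(sigma_T_ms = 1e-9, w_ms = 1e-9,
                          spikes_per_cycle = 5, n_driver_units = 3)
  pk <- generate_theta_spike_packets(2, sp0, seed = 1)
  expect_equal(diff(pk$peaks_ms), rep(125, length(pk$peaks_ms) - 1),
               tolerance = 1e-6)
  expect_equal(sd(pk$times_ms - rep(pk$peaks_ms,
                                    each = 5)[seq_along(pk$times_ms)]) < 1e-6,
               TRUE)

  ## inter-peak statistics over ~1000 cycles
  sp <- theta_drive_spec(spikes_per_cycle = 10)
  pk2 <- generate_theta_spike_packets(130, sp, seed = 2)
  iv <- diff(pk2$peaks_ms)
  expect_equal(mean(iv), 125, tolerance = 2)
  expect_equal(sd(iv), 16, tolerance = 2)

  ## total count within 3 standard errors of duration/mu * spikes_per_cycle
  expect_equal(length(pk2$times_ms) / length(pk2$peaks_ms), 10, tolerance = 0.5)
})

test_that("Poisson noise trains have the right rate and irregularity", {
  t1 <- generate_poisson_spikes(10, mean_interval_ms = 1, seed = 3)
  expect_lt(abs(length(t1) - 10000), 3 * sqrt(10000))
  isi <- diff(t1)
  expect_equal(sd(isi) / mean(isi), 1, tolerance = 0.05)
  expect_length(generate_poisson_spikes(0, 1, seed = 1), 0)
})

test_that("motif construction respects the feedforward/feedback structure", {
  ing <- build_motif(motif_spec("theta_ing", n_pc = 20, n_bc = 5), seed = 4)
  ping <- build_motif(motif_spec("theta_ping", n_pc = 20, n_bc = 5), seed = 4)
  expect_equal(count_synapses(ing, "pc_bc"), 0L)
  expect_gt(count_synapses(ing, "theta_bc"), 0L)
  expect_equal(count_synapses(ping, "theta_bc"), 0L)
  expect_gt(count_synapses(ping, "pc_bc"), 0L)
  expect_gt(count_synapses(ing, "bc_bc"), 0L)  # self-inhibition always present
  expect_gt(count_synapses(ping, "bc_bc"), 0L)

  ## determinism: same seed gives identical realizations
  ing2 <- build_motif(motif_spec("theta_ing", n_pc = 20, n_bc = 5), seed = 4)
  expect_identical(ing$net_conn, ing2$net_conn)
  expect_identical(ing$theta_conn, ing2$theta_conn)

  expect_error(motif_spec("mixed", weights = list(theta_bc = 0)), "mixed")
  expect_error(motif_spec("theta_ing", weights = list(bc_pc = -1)), "negative")
})

test_that("sampled transmission delays match the Gaussian specification", {
  spec <- motif_spec("theta_ing", n_pc = 500, n_bc = 50)
  net <- build_motif(spec, seed = 5)
  ## BC -> PC delays: mean 1.5 ms, sd 0.2 ms
  inh <- net$net_conn$slot %in% net$slot_index$inh
  d <- net$net_conn$delay_ms[inh]
  expect_gte(length(d), 1e4)
  expect_lt(abs(mean(d) - 1.5), 0.05)
  expect_lt(abs(sd(d) - 0.2), 0.05)
  expect_true(all(net$net_conn$delay_ms > 0))
  expect_true(all(net$theta_conn$delay_ms > 0))
})

test_that("relative delay sweep only changes the theta->PC delay", {
  base <- motif_spec("theta_ing")
  sw <- relative_delay_sweep(base, c(30, 20, 10))
  expect_named(sw, c("dt_-10", "dt_+0", "dt_+10"))
  expect_equal(vapply(sw, function(s) s$theta$delay_pc_ms, 0),
               c(`dt_-10` = 30, `dt_+0` = 20, `dt_+10` = 10))
  for (s in sw) {
    expect_s3_class(s, "motif_spec")
    expect_equal(s$theta$delay_bc_ms, 20)
    s$theta$delay_pc_ms <- base$theta$delay_pc_ms
    expect_identical(s, base)
  }
  expect_error(relative_delay_sweep(base, c(0, 10)), "positive")
})

test_that("scaling up multiplies counts, divides weights, and keeps rates", {
  base <- motif_spec("theta_ing", n_pc = 50, n_bc = 10,
                     weights = list(bc_pc = 6e-3, bc_bc = 1.1e-3,
                                    theta_bc = 3.2e-6))
  up <- motif_spec("theta_ing", n_pc = 50, n_bc = 10,
                   weights = list(bc_pc = 6e-3, bc_bc = 1.1e-3,
                                  theta_bc = 3.2e-6),
                   scale_factor = 2)
  expect_equal(up$n_pc, 100); expect_equal(up$n_bc, 20)
  expect_equal(up$weights$bc_pc, base$weights$bc_pc / 2)
  expect_equal(up$fan_in$bc_pc, min(2 * base$fan_in$bc_pc, up$n_bc))

  r0 <- run_simulation(build_motif(base, 1), duration_s = 8, seed = 1)
  r1 <- run_simulation(build_motif(up, 1), duration_s = 8, seed = 1)
  f0 <- firing_rate(r0$pc_raster, r0$n_pc, r0$duration_s)
  f1 <- firing_rate(r1$pc_raster, r1$n_pc, r1$duration_s)
  expect_lt(abs(f1 - f0) / f0, 0.2)
  ## BC population rhythm also carries over
  b0 <- firing_rate(r0$bc_raster, r0$n_bc, r0$duration_s)
  b1 <- firing_rate(r1$bc_raster, r1$n_bc, r1$duration_s)
  expect_lt(abs(b1 - b0) / b0, 0.2)
})
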