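test_that("pathway rate series and protocol plumbing behave", {
  spec <- protocol_motif("theta_ing")
  net <- build_motif(spec, seed = 1)
  r <- run_simulation(net, duration_s = 5, seed = 1)
  ## parallel event times are recorded and Poisson-like at the set rate
  expect_gt(length(r$parallel_times_ms),
            0.8 * r$n_pc * 5000 / spec$parallel$mean_interval_ms)
  inp <- thetagamma:::pathway_input_rate(r, spec, "parallel")
  expect_s3_class(inp, "rate_series")
  expect_true(all(inp$values >= 0))
  expect_error(consistency_protocol(spec, "theta",
                                    run_plan(n_realizations = 1)), "2")
  expect_error(fidelity_protocol(desk_scale_motif("theta_ing"), "parallel"),
               "parallel")
})

test_that("a zero-amplitude pulse leaves the network untouched", {
  spec <- protocol_motif("theta_ing")
  net <- build_motif(spec, seed = 2)
  seeds <- list(theta = 1L, noise = 2L, parallel = 3L)
  base <- run_simulation(net, 1.2, seeds = seeds)
  pert <- run_simulation(net, 1.2, seeds = seeds,
                         extra_events = data.frame(
                           t_ms = 1000, slot = net$slot_index$prox, w = 0))
  expect_identical(base$pc_raster, pert$pc_raster)
  expect_identical(base$v_pc, pert$v_pc)
})

test_that("a disconnected pathway carries no information", {
  ## parallel weight is tied to the noise weight; silencing the noise
  ## stream's weight would silence the network, so instead compare the MI
  ## of the true parallel input against a surrogate independent train
  spec <- protocol_motif("theta_ping")
  net <- build_motif(spec, seed = 3)
  r <- run_simulation(net, duration_s = 10, seed = 3)
  out <- thetagamma:::pc_output_rate(r)
  fake <- spikes_to_rate(generate_poisson_spikes(10, 0.2, seed = 99),
                         10000, dt_ms = 1)
  mi_fake <- lagged_mi(fake, out, lags_ms = seq(-20, 20, 10))$max_mi
  mi_true <- lagged_mi(thetagamma:::pathway_input_rate(r, spec, "theta"), out,
                       lags_ms = seq(0, 40, 10))$max_mi
  expect_lt(mi_fake, 0.03)
  expect_gt(mi_true, mi_fake)
})

test_that("perturbation trials report phases and a bounded concentration", {
  spec <- protocol_motif("theta_ing")
  tr <- perturbation_protocol(spec, n_trials = 4, duration_s = 1.6, seed = 4)
  expect_equal(nrow(tr), 4L)
  expect_true(all(tr$encoding >= 0))
  expect_true(all(abs(tr$theta_phase_deg) <= 180))
  expect_true(all(abs(tr$gamma_phase_deg) <= 180))
  conc <- encoding_phase_concentration(tr)
  expect_gte(conc, 0); expect_lte(conc, 1)
  expect_error(perturbation_protocol(spec, pulse_window_s = c(1, 3),
                                     duration_s = 2), "window")
})
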