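test_that("a drive-free network stays silent and reproducible", {
  spec <- motif_spec("theta_ing", n_pc = 3, n_bc = 2,
                     weights = list(theta_pc = 0, theta_bc = 0),
                     noise = noise_spec(weight_pc_uS = 0, weight_bc_uS = 0))
  net <- build_motif(spec, seed = 1)
  r <- run_simulation(net, duration_s = 2, seed = 1)
  ## PCs are silent without synaptic drive; BCs are intrinsically tonic
  ## pacemakers, so their drive-free spiking must be metronome-regular
  expect_equal(nrow(r$pc_raster), 0L)
  isi <- diff(r$bc_raster$t_ms[r$bc_raster$unit == 1])
  if (length(isi) > 3) expect_lt(sd(isi) / mean(isi), 0.01)
  ## series lengths match duration / record step
  expect_length(r$v_pc, 2000)
  expect_true(all(r$pc_raster$t_ms >= 0 & r$pc_raster$t_ms <= 2000))
})

test_that("identical seeds reproduce a run bit-identically", {
  spec <- desk_scale_motif("theta_ing")
  net <- build_motif(spec, seed = 2)
  r1 <- run_simulation(net, duration_s = 3, seed = 9)
  r2 <- run_simulation(net, duration_s = 3, seed = 9)
  expect_identical(r1$pc_raster, r2$pc_raster)
  expect_identical(r1$bc_raster, r2$bc_raster)
  expect_identical(r1$v_pc, r2$v_pc)
  r3 <- run_simulation(net, duration_s = 3, seed = 10)
  expect_false(identical(r1$pc_raster, r3$pc_raster))
})

test_that("fixed theta input is bit-identical across realizations", {
  spec <- desk_scale_motif("theta_ing")
  net <- build_motif(spec, seed = 3)
  plan <- run_plan(duration_s = 3, n_realizations = 2,
                   fixed_inputs = "theta", seed = 11)
  runs <- run_realizations(net, plan)
  expect_identical(runs[[1]]$seeds$theta, runs[[2]]$seeds$theta)
  expect_identical(runs[[1]]$theta_peaks_ms, runs[[2]]$theta_peaks_ms)
  expect_false(identical(runs[[1]]$seeds$noise, runs[[2]]$seeds$noise))
  expect_false(identical(runs[[1]]$v_pc, runs[[2]]$v_pc))
})

test_that("firing rate is spikes per unit per second", {
  expect_equal(firing_rate(data.frame(unit = integer(0), t_ms = numeric(0)),
                           10, 5), 0)
  raster <- data.frame(unit = rep(1:4, 30), t_ms = runif(120, 0, 60000))
  expect_equal(firing_rate(raster, 200, 60), 0.01)
})

test_that("halving the integration step barely changes spike counts", {
  spec <- desk_scale_motif("theta_ing")
  net <- build_motif(spec, seed = 5)
  r1 <- run_simulation(net, 8, dt_ms = 0.025, seed = 5)
  r2 <- run_simulation(net, 8, dt_ms = 0.0125, seed = 5)
  n1 <- nrow(r1$pc_raster) + nrow(r1$bc_raster)
  n2 <- nrow(r2$pc_raster) + nrow(r2$bc_raster)
  expect_lt(abs(n1 - n2) / n1, 0.02)
})

test_that("phase-binned spiking normalises to unit cycle integral", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  ref <- sin(2 * pi * 8 * t)
  ## spikes exactly at reference troughs -> mass concentrated at +-180 deg
  troughs <- (which(diff(sign(diff(ref))) > 0) + 1)
  troughs <- troughs[ref[troughs] < -0.99]
  pb <- phase_binned_spiking(troughs / fs * 1000, ref, fs, n_bins = 24)
  expect_equal(sum(pb$density) * (2 * pi / 24), 1, tolerance = 1e-9)
  expect_gt(abs(pb$circular_mean_deg), 150)

  ## uniform random spikes -> flat histogram within multinomial noise
  set.seed(8)
  pb2 <- phase_binned_spiking(runif(5000, 100, 19900), ref, fs, n_bins = 12)
  expect_lt(max(abs(pb2$density - 1 / (2 * pi))), 4 / sqrt(5000 / 12) / (2 * pi))
  expect_error(phase_binned_spiking(25000, ref, fs), "cover")
  expect_error(phase_binned_spiking(100, ref, fs, band = c(0, 600)), "band")
})

test_that("feedforward inhibition advances PC firing; feedback delays it", {
  ## push-pull contract: with fast feedforward BC recruitment (theta-ING)
  ## the PCs fire before the theta drive peaks (phase precession); with
  ## feedback recruitment (theta-PING) the inhibition lags the PCs and
  ## their firing sits at/after the drive peak (phase recession)
  med_offset <- function(r) {
    pk <- r$theta_peaks_ms + 21   # packet centre + transmission delay
    d <- vapply(r$pc_raster$t_ms,
                function(ti) ti - pk[which.min(abs(pk - ti))], 0)
    median(d[abs(d) < 60])
  }
  o_ing <- med_offset(cached_desk_run("theta_ing"))
  o_ping <- med_offset(cached_desk_run("theta_ping"))
  expect_lt(o_ing, 0)
  expect_gt(o_ping, 0)
  expect_lt(o_ing, o_ping)
})
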