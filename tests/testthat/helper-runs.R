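# Shared simulation cache: several test files analyse the same reduced-size
# motif runs, so they are simulated once per session.
.run_cache <- new.env(parent = emptyenv())

cached_desk_run <- function(kind, duration_s = 25, seed = 1) {
  key <- sprintf("%s/%g/%d", kind, duration_s, seed)
  if (!exists(key, envir = .run_cache)) {
    net <- build_motif(desk_scale_motif(kind), seed = seed)
    assign(key, run_simulation(net, duration_s = duration_s, seed = seed,
                               dt_ms = 0.05),
           envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# tiny single-cell network with silent noise, used by cell-level tests
quiet_single_cell <- function(pc = pyramidal_cell_params()) {
  spec <- motif_spec("theta_ing", n_pc = 1, n_bc = 1,
                     noise = noise_spec(weight_pc_uS = 0, weight_bc_uS = 0),
                     pc = pc)
  build_motif(spec, seed = 1)
}

no_theta <- list(times_ms = numeric(0), unit = integer(0))
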