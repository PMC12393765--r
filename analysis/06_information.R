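#!/usr/bin/env Rscript
## Functional comparison of the motifs as communication channels. Two
## external inputs compete: the theta drive (distal dendrites) and a
## Poissonian parallel pathway (proximal dendrites, tenfold the background
## noise). Fidelity = lagged MI between an input and the PC output;
## consistency = MI between outputs of realizations sharing that input.
## A single-pulse perturbation protocol probes when, within the gamma
## cycle, each motif is responsive.
suppressPackageStartupMessages(library(thetagamma))
dir.create("results", showWarnings = FALSE)
seed <- 42L

rows <- list()
for (kind in c("theta_ing", "theta_ping")) {
  spec <- protocol_motif(kind)
  for (pw in c("theta", "parallel")) {
    dur <- if (pw == "theta") 15 else 25
    plan <- run_plan(duration_s = dur, n_realizations = 5, seed = seed,
                     fixed_inputs = pw)
    net <- build_motif(spec, seed = plan$seed)
    runs <- run_realizations(net, plan)
    fid <- fidelity_protocol(spec, pw, plan, runs = runs)
    con <- consistency_protocol(spec, pw, plan, runs = runs)
    rows[[paste(kind, pw)]] <- data.frame(
      motif = kind, pathway = pw,
      fidelity_mi = fid$max_mi, fidelity_sd = fid$max_mi_sd,
      consistency_mi = con$mean_mi, consistency_sd = con$sd_mi)
    cat(sprintf("%s / %-8s: fidelity %.4f (sd %.4f), consistency %.4f (sd %.4f)\n",
                kind, pw, fid$max_mi, fid$max_mi_sd, con$mean_mi, con$sd_mi))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/06_information.csv", row.names = FALSE)

cat("\nsingle-pulse perturbation protocol:\n")
pert <- list()
for (kind in c("theta_ing", "theta_ping")) {
  tr <- perturbation_protocol(protocol_motif(kind), n_trials = 30,
                              duration_s = 1.6,
                              seed = derive_seed(seed, paste0("pert-", kind)))
  tr$motif <- kind
  pert[[kind]] <- tr
  dep <- abs(tr$theta_phase_deg) < 90
  cat(sprintf("%s: mean encoding %.2f, gamma-phase concentration %.3f (depolarised half: %.3f)\n",
              kind, mean(tr$encoding), encoding_phase_concentration(tr),
              encoding_phase_concentration(tr[dep, ])))
}
write.csv(do.call(rbind, pert), "results/06_perturbation_trials.csv",
          row.names = FALSE)
cat("-> feedback (PING) motifs favour the theta pathway; feedforward (ING)\n")
cat("   motifs favour the parallel pathway and respond more broadly in phase.\n")
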