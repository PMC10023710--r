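# Shared campaign fixtures, simulated once per test run. Seed 1 is the
# package's default campaign; the noise-free twin is used for controller
# invariants that sensor noise would blur.
.fixtures <- new.env(parent = emptyenv())

campaign_noisy <- function() {
  if (is.null(.fixtures$noisy))
    .fixtures$noisy <- simulate_campaign(seed = 1)
  .fixtures$noisy
}

campaign_clean <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- simulate_campaign(seed = 1, noise = FALSE)
  .fixtures$clean
}

report_noisy <- function() {
  if (is.null(.fixtures$report))
    .fixtures$report <- evaluate_campaign(campaign_noisy())
  .fixtures$report
}

# a perfect-tracking stub trace: PV identical to SP, constant everything else
stub_trace <- function(protocol = "abduction", specimen = "stub", rep = 1L) {
  prof <- build_profile(protocol, dt_s = 0.05)
  tr <- data.frame(time_s = prof$time_s, phase = prof$phase,
                   sp_abd = prof$sp_abd, sp_fe = prof$sp_fe,
                   sp_rot = prof$sp_rot, pv_abd = prof$sp_abd,
                   pv_fe = prof$sp_fe, pv_rot = prof$sp_rot,
                   t_ap = 0, t_si = 0, t_ml = 0)
  for (m in c("MD", "AD", "PD", "ISP_TM", "SSC", "SSP"))
    tr[[paste0("F_", m)]] <- 50
  tr$share_fe <- 0.5; tr$share_ir <- 0.5
  tr$tot_fe_raw <- 60; tr$tot_ir_raw <- 100; tr$sat_flags <- 0
  attr(tr, "protocol") <- protocol
  attr(tr, "primary") <- attr(prof, "primary")
  attr(tr, "specimen") <- specimen
  attr(tr, "repeat") <- rep
  class(tr) <- c("trial_trace", "data.frame")
  tr
}
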