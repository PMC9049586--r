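## Named experiments covering the model's canonical stimulation protocols.
## Every scenario runs from the shipped default parameterization; condition
## sets (amplitudes, times, durations, multipliers, blocking fractions) are
## part of each scenario's definition and are asserted in the tests.

.SYNTH <- function() list(pulse(0, 10))
.FIG2_AMPS <- c(0.0005, 0.005, 0.05, 0.5)

.finalTotal <- function(traj, window = 20, slope_tol = 0.02) {
  s <- totalPkcSeries(traj)
  t1 <- max(s$time)
  plateauValue(s, c(t1 - window, t1), slope_tol = slope_tol)
}

.scenarioResult <- function(id, conditions, trajectories, metrics) {
  structure(list(id = id, conditions = conditions,
                 trajectories = trajectories, metrics = metrics),
            class = "pkc_scenario_result")
}

#' @export
print.pkc_scenario_result <- function(x, ...) {
  cat("PKC scenario:", x$id, "\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Activator dose--response
#'
#' Four runs with a 10-min synthesis pulse and a 15-min activator pulse at
#' 50 min, at amplitudes 0.0005, 0.005, 0.05 and 0.5 nM, plus the
#' activator-free control. Down-regulation is quantified as the final total
#' relative to the time-matched control run, which isolates the activator
#' effect from the slow intrinsic turnover of the mature pool.
#'
#' @param params parameterization (default: shipped defaults)
#' @param amplitudes activator pulse amplitudes, nM
#' @param t_end run length, minutes
#' @return a `pkc_scenario_result` with per-amplitude final totals, losses
#'   and peak active-species levels
#' @export
runDoseResponse <- function(params = defaultParams(),
                            amplitudes = .FIG2_AMPS, t_end = 185) {
  ctrl <- simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(), t_end = t_end),
                      params = params)
  ctrl_final <- .finalTotal(ctrl)
  trajs <- lapply(amplitudes, function(a)
    simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                            activator_pulses = list(pulse(50, 15, a)),
                            t_end = t_end), params = params))
  fin <- vapply(trajs, .finalTotal, numeric(1))
  metrics <- data.frame(
    amplitude_nM = amplitudes,
    plateau_pre = vapply(trajs, function(tr)
      plateauValue(totalPkcSeries(tr), c(40, 50)), numeric(1)),
    final_total = fin,
    control_final = ctrl_final,
    loss_fraction = 1 - fin / ctrl_final,
    peak_active = vapply(trajs, function(tr)
      max(tr$states[, "PKC_PAPHPT_act"]), numeric(1)),
    peak_dephospho = vapply(trajs, function(tr)
      max(tr$states[, "PKC_A"]), numeric(1)))
  .scenarioResult("fig2_dose", amplitudes, c(trajs, list(control = ctrl)),
                  metrics)
}

#' Activator pulse-duration sweep
#'
#' Five runs at the lowest amplitude (0.0005 nM) with pulse durations of
#' 15, 100, 150, 200 and 316.66 min.
#'
#' @inheritParams runDoseResponse
#' @param durations pulse durations in minutes
#' @param amplitude activator level, nM
#' @return a `pkc_scenario_result` with final totals and loss fractions
#' @export
runDurationSweep <- function(params = defaultParams(),
                             durations = c(15, 100, 150, 200, 316.66),
                             amplitude = 0.0005) {
  run1 <- function(dur, act) {
    t_end <- 50 + dur + 120
    ap <- if (act) list(pulse(50, dur, amplitude)) else list()
    simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                            activator_pulses = ap, t_end = t_end),
                params = params)
  }
  trajs <- lapply(durations, run1, act = TRUE)
  ctrls <- lapply(durations, run1, act = FALSE)
  fin <- vapply(trajs, .finalTotal, numeric(1))
  ctrl_fin <- vapply(ctrls, .finalTotal, numeric(1))
  metrics <- data.frame(duration_min = durations, final_total = fin,
                        control_final = ctrl_fin,
                        loss_fraction = 1 - fin / ctrl_fin)
  .scenarioResult("fig3_duration", durations, trajs, metrics)
}

#' Dephosphorylation blocking during high-intensity pulses
#'
#' Three identical 0.5 nM, 15-min activator pulses at 4000, 12000 and
#' 20000 s, with the dephosphorylation rate `k17` fully blocked during each
#' pulse, plus the unblocked contrast run and the activator-free control.
#'
#' @inheritParams runDoseResponse
#' @return a `pkc_scenario_result`; metrics include final-total retention
#'   relative to the control for the blocked and unblocked runs
#' @export
runBlockDephosphorylation <- function(params = defaultParams()) {
  onsets <- c(4000, 12000, 20000) / 60
  acts <- lapply(onsets, pulse, duration = 15, amplitude = 0.5)
  blocks <- lapply(onsets, pulse, duration = 15)
  t_end <- max(onsets) + 15 + 120
  blocked <- simulatePkc(pkcProtocol(
    synthesis_pulses = .SYNTH(), activator_pulses = acts,
    k17_blocks = blocks, t_end = t_end), params = params)
  unblocked <- simulatePkc(pkcProtocol(
    synthesis_pulses = .SYNTH(), activator_pulses = acts,
    t_end = t_end), params = params)
  ctrl <- simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                                  t_end = t_end), params = params)
  ctrl_final <- .finalTotal(ctrl)
  pre <- plateauValue(totalPkcSeries(blocked), c(40, onsets[1]))
  mature_min <- vapply(seq_along(onsets), function(i) {
    sel <- blocked$times >= onsets[i] & blocked$times <= onsets[i] + 15
    min(blocked$states[sel, "CPKC_PAPHPT"])
  }, numeric(1))
  metrics <- data.frame(
    run = c("blocked", "unblocked"),
    plateau_pre = pre,
    final_total = c(.finalTotal(blocked), .finalTotal(unblocked)),
    control_final = ctrl_final)
  metrics$retention <- metrics$final_total / metrics$control_final
  .scenarioResult("fig4_block_k17", c("blocked", "unblocked"),
                  list(blocked = blocked, unblocked = unblocked,
                       control = ctrl),
                  cbind(metrics,
                        mature_dip = rep(min(mature_min), 2)))
}

#' Sequential intermediate-strength pulses
#'
#' Three 15-min activator pulses of 0.005 nM at 50, 220 and 360 min; the
#' per-pulse stabilized drop of total PKC is measured as the difference of
#' the plateaus bracketing each pulse.
#'
#' @inheritParams runDoseResponse
#' @param amplitude activator level, nM
#' @param onsets pulse onset times, minutes
#' @param t_end run length, minutes
#' @return a `pkc_scenario_result` with one drop per pulse
#' @export
runSequentialPulses <- function(params = defaultParams(), amplitude = 0.005,
                                onsets = c(50, 220, 360), t_end = 500) {
  pulses <- lapply(onsets, pulse, duration = 15, amplitude = amplitude)
  traj <- simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                                  activator_pulses = pulses, t_end = t_end),
                      params = params)
  s <- totalPkcSeries(traj)
  nxt <- c(onsets[-1], t_end)
  drops <- vapply(seq_along(pulses), function(i)
    dropAfterPulse(s, pulses[[i]], next_event = nxt[i]), numeric(1))
  metrics <- data.frame(pulse = seq_along(onsets), onset_min = onsets,
                        drop = drops)
  .scenarioResult("fig5_sequential", onsets, list(traj), metrics)
}

#' HSP70 overexpression sweep
#'
#' Wild-type and 10x/40x/100x/200x HSP70 overexpression under a 0.5 nM,
#' 15-min activator pulse. Each condition is compared with its own
#' activator-free control.
#'
#' @inheritParams runDoseResponse
#' @param multipliers HSP70 overexpression factors
#' @return a `pkc_scenario_result` with final totals, retention, and peak /
#'   exposure (time-integral) of the dephosphorylated active species
#' @export
runHsp70Sweep <- function(params = defaultParams(),
                          multipliers = c(1, 10, 40, 100, 200),
                          t_end = 185) {
  run1 <- function(m, act) {
    ap <- if (act) list(pulse(50, 15, 0.5)) else list()
    simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                            activator_pulses = ap, hsp70_multiplier = m,
                            t_end = t_end), params = params)
  }
  trajs <- lapply(multipliers, run1, act = TRUE)
  ctrl_fin <- vapply(multipliers, function(m) .finalTotal(run1(m, FALSE)),
                     numeric(1))
  fin <- vapply(trajs, .finalTotal, numeric(1))
  auc <- function(tr, sp) {
    s <- speciesSeries(tr, sp)
    sum(diff(s$time) * (head(s$value, -1) + tail(s$value, -1)) / 2)
  }
  metrics <- data.frame(
    multiplier = multipliers, final_total = fin, control_final = ctrl_fin,
    retention = fin / ctrl_fin,
    peak_dephospho = vapply(trajs, function(tr)
      max(tr$states[, "PKC_A"]), numeric(1)),
    dephospho_exposure = vapply(trajs, auc, numeric(1), sp = "PKC_A"))
  .scenarioResult("fig6_hsp70", multipliers, trajs, metrics)
}

#' PHLPP blocking sweep
#'
#' 0, 50, 90, 95 and 100 percent fractional PHLPP inhibition under a
#' 0.5 nM, 15-min activator pulse.
#'
#' @inheritParams runDoseResponse
#' @param fractions blocking fractions in [0, 1]
#' @return a `pkc_scenario_result` with final totals and retention
#' @export
runPhlppBlockSweep <- function(params = defaultParams(),
                               fractions = c(0, 0.5, 0.9, 0.95, 1),
                               t_end = 185) {
  ctrl <- simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                                  t_end = t_end), params = params)
  ctrl_final <- .finalTotal(ctrl)
  trajs <- lapply(fractions, function(b)
    simulatePkc(pkcProtocol(synthesis_pulses = .SYNTH(),
                            activator_pulses = list(pulse(50, 15, 0.5)),
                            phlpp_block = b, t_end = t_end),
                params = params))
  fin <- vapply(trajs, .finalTotal, numeric(1))
  auc_act <- vapply(trajs, function(tr) {
    s <- speciesSeries(tr, "PKC_PAPHPT_act")
    sum(diff(s$time) * (head(s$value, -1) + tail(s$value, -1)) / 2)
  }, numeric(1))
  metrics <- data.frame(block_fraction = fractions, final_total = fin,
                        control_final = ctrl_final,
                        retention = fin / ctrl_final,
                        active_exposure = auc_act)
  .scenarioResult("fig7_phlpp", fractions, c(trajs, list(control = ctrl)),
                  metrics)
}

#' Rescue by a second protein-synthesis pulse
#'
#' The dose--response protocol per amplitude plus a second 10-min synthesis
#' pulse at 83.33 min. The reversal of down-regulation is reported both as
#' the absolute final-total gain and as a recovery index: gain divided by
#' the amount lost to the activator without the second pulse.
#'
#' @inheritParams runDoseResponse
#' @param second_onset onset of the second synthesis pulse, minutes
#' @return a `pkc_scenario_result`
#' @export
runSecondSynthesisPulse <- function(params = defaultParams(),
                                    amplitudes = .FIG2_AMPS,
                                    second_onset = 83.33, t_end = 250) {
  synth2 <- list(pulse(0, 10), pulse(second_onset, 10))
  run1 <- function(a, synth) {
    ap <- if (a > 0) list(pulse(50, 15, a)) else list()
    simulatePkc(pkcProtocol(synthesis_pulses = synth, activator_pulses = ap,
                            t_end = t_end), params = params)
  }
  ctrl_final <- .finalTotal(run1(0, .SYNTH()))
  base_fin <- vapply(amplitudes, function(a) .finalTotal(run1(a, .SYNTH())),
                     numeric(1))
  with_fin <- vapply(amplitudes, function(a) .finalTotal(run1(a, synth2)),
                     numeric(1))
  metrics <- data.frame(
    amplitude_nM = amplitudes, final_without = base_fin,
    final_with = with_fin, reversal = with_fin - base_fin,
    recovery_index = (with_fin - base_fin) / (ctrl_final - base_fin))
  .scenarioResult("s7_second_synthesis", amplitudes, NULL, metrics)
}

#' Dual-degradation variant dose--response
#'
#' The dose--response protocol under the two-competing-pathway variant in
#' which the membrane-bound active phospho form also degrades directly
#' (`lambda5 > 0`).
#'
#' @inheritParams runDoseResponse
#' @param lambda5 degradation rate of the membrane-active form, per second
#' @return a `pkc_scenario_result` with the same metrics as
#'   [runDoseResponse()]
#' @export
runDualDegradationVariant <- function(params = defaultParams(),
                                      lambda5 = 5e-4,
                                      amplitudes = .FIG2_AMPS, t_end = 185) {
  params$lambda5 <- lambda5
  out <- runDoseResponse(params = params, amplitudes = amplitudes,
                         t_end = t_end)
  out$id <- "s8_dual_degradation"
  out
}

#' Names of the shipped scenarios
#' @return character vector of scenario ids
#' @export
scenarioList <- function() {
  c("fig2_dose", "fig3_duration", "fig4_block_k17", "fig5_sequential",
    "fig6_hsp70", "fig7_phlpp", "s7_second_synthesis",
    "s8_dual_degradation")
}

#' Run a named scenario
#' @param name one of [scenarioList()]
#' @param params parameterization (default: shipped defaults)
#' @return a `pkc_scenario_result`
#' @export
runScenario <- function(name, params = defaultParams()) {
  switch(match.arg(name, scenarioList()),
    fig2_dose = runDoseResponse(params),
    fig3_duration = runDurationSweep(params),
    fig4_block_k17 = runBlockDephosphorylation(params),
    fig5_sequential = runSequentialPulses(params),
    fig6_hsp70 = runHsp70Sweep(params),
    fig7_phlpp = runPhlppBlockSweep(params),
    s7_second_synthesis = runSecondSynthesisPulse(params),
    s8_dual_degradation = runDualDegradationVariant(params))
}
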