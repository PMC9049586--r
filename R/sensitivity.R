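#' Parameters included in the one-at-a-time sensitivity sweep
#'
#' All twenty kinetic constants, the four degradation rates of the base
#' model, and the clamped polyribosome (`T`) and `PDK1` levels.
#'
#' @return character vector of parameter ids
#' @export
sensitivityParameters <- function() {
  c(paste0("k", 1:20), paste0("lambda", 1:4), "T", "PDK1")
}

#' Classify a sensitivity effect
#'
#' Thresholds on the normalized effect metric: `high` at or above
#' `high_cut`, `insensitive` below `low_cut`, `moderate` in between. The
#' cuts are tunable; the reference grouping is qualitative only.
#'
#' @param effect non-negative effect value(s)
#' @param high_cut,low_cut class boundaries
#' @return character vector of classes
#' @export
classifySensitivity <- function(effect, high_cut = 0.5, low_cut = 0.05) {
  ifelse(effect >= high_cut, "high",
         ifelse(effect >= low_cut, "moderate", "insensitive"))
}

.sens_protocol <- function(amplitude, t_end = 185) {
  pkcProtocol(synthesis_pulses = list(pulse(0, 10)),
              activator_pulses = list(pulse(50, 15, amplitude)),
              t_end = t_end)
}

#' Local one-at-a-time parameter-sensitivity map
#'
#' Effect of a 5-fold increase and a 90 percent reduction of each parameter
#' on total PKC, under low-intensity (0.0005 nM) and high-intensity
#' (0.5 nM) stimulation, all other parameters held at baseline. The effect
#' metric is the maximum over time of the absolute deviation of total PKC
#' from the baseline run, normalized by the baseline maximum; each
#' parameter's class is the maximum class over its four perturbation runs.
#'
#' @param params baseline parameterization
#' @param parameter_ids parameters to perturb
#' @param factors perturbation factors
#' @param scenarios named activator amplitudes (nM) for the two baselines
#' @param output_dt output grid, minutes
#' @return list with `records` (one row per parameter x scenario x factor,
#'   columns `parameter`, `scenario`, `factor`, `effect`, `class`, `status`)
#'   and `summary` (per-parameter overall effect and class)
#' @export
sensitivityMap <- function(params = defaultParams(),
                           parameter_ids = sensitivityParameters(),
                           factors = c(5, 0.1),
                           scenarios = c(low = 0.0005, high = 0.5),
                           output_dt = 1) {
  baselines <- lapply(scenarios, function(a)
    totalPkcSeries(simulatePkc(.sens_protocol(a), params = params,
                               output_dt = output_dt)))
  rows <- list()
  for (pid in parameter_ids) for (sc in names(scenarios)) for (f in factors) {
    pert <- params
    pert[[pid]] <- pert[[pid]] * f
    eff <- NA_real_; status <- "ok"
    res <- tryCatch(
      totalPkcSeries(simulatePkc(.sens_protocol(scenarios[[sc]]),
                                 params = pert, output_dt = output_dt)),
      error = function(e) e)
    if (inherits(res, "error")) {
      status <- conditionMessage(res)
    } else {
      base <- baselines[[sc]]
      eff <- max(abs(res$value - base$value)) / max(base$value)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = pid, scenario = sc, factor = f, effect = eff,
      status = status, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  records$class <- ifelse(is.na(records$effect), NA_character_,
                          classifySensitivity(records$effect))
  agg <- vapply(split(records$effect, records$parameter),
                function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE),
                numeric(1))
  summary <- data.frame(parameter = names(agg), effect = unname(agg),
                        class = classifySensitivity(unname(agg)),
                        stringsAsFactors = FALSE)
  summary <- summary[match(parameter_ids, summary$parameter), ]
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' PDK1 expression sweep
#'
#' Runs the low- and high-intensity stimulation protocols across scaled
#' PDK1 clamp levels and reports total-PKC plateaus and final totals,
#' together with the trajectories of the mature, membrane-active and
#' dephosphorylated-active states.
#'
#' @param params baseline parameterization
#' @param levels PDK1 levels as multiples of the baseline clamp
#' @param amplitudes named activator amplitudes, nM
#' @return list with `metrics` and per-level trajectories
#' @export
pdk1ExpressionSweep <- function(params = defaultParams(),
                                levels = c(0, 0.1, 0.25, 0.5, 1),
                                amplitudes = c(low = 0.0005, high = 0.5)) {
  rows <- list(); trajs <- list()
  for (lv in levels) for (sc in names(amplitudes)) {
    p <- params
    p$PDK1 <- p$PDK1 * lv
    tr <- simulatePkc(.sens_protocol(amplitudes[[sc]]), params = p)
    s <- totalPkcSeries(tr)
    rows[[length(rows) + 1L]] <- data.frame(
      pdk1_level = lv, scenario = sc,
      plateau_pre = mean(s$value[s$time >= 40 & s$time <= 50]),
      final_total = mean(s$value[s$time >= max(s$time) - 20]),
      mature_peak = max(tr$states[, "CPKC_PAPHPT"]),
      stringsAsFactors = FALSE)
    trajs[[paste(lv, sc, sep = "_")]] <- tr
  }
  list(metrics = do.call(rbind, rows), trajectories = trajs)
}
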