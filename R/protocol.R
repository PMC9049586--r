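#' Square stimulation pulse
#'
#' A half-open square pulse `[t_on, t_on + duration)`. Times are in minutes;
#' the amplitude is in the unit of the quantity it sets (nM for the
#' activator, dimensionless gating for synthesis).
#'
#' @param t_on onset time, minutes (>= 0)
#' @param duration pulse length, minutes (> 0)
#' @param amplitude pulse level (>= 0); for synthesis pulses the gate is
#'   binary and the amplitude is ignored
#' @return a `pkc_pulse` list
#' @export
pulse <- function(t_on, duration, amplitude = 1) {
  stopifnot(t_on >= 0, duration > 0, amplitude >= 0)
  structure(list(t_on = t_on, duration = duration, amplitude = amplitude),
            class = "pkc_pulse")
}

.in_pulse <- function(t, p) t >= p$t_on & t < p$t_on + p$duration

#' Stimulation and intervention protocol
#'
#' A timeline of square pulses and interventions resolved piecewise-constant
#' in time: protein-synthesis pulses gate the translation signal `k3`;
#' activator pulses set the clamped second-messenger level; `k17_blocks`
#' are windows during which the dephosphorylation rate is fully blocked
#' (as in the dephosphorylation-blocking experiment); `phlpp_block` is a
#' constant fractional PHLPP inhibition in [0, 1] scaling `k17`;
#' `hsp70_multiplier` scales the clamped HSP70 level for the whole run.
#'
#' @param synthesis_pulses list of [pulse()]s gating `k3`
#' @param activator_pulses list of [pulse()]s setting the activator (nM);
#'   overlapping activator pulses are rejected
#' @param k17_blocks list of [pulse()]s; inside any of them `k17` is 0
#' @param phlpp_block fraction of PHLPP activity blocked, in [0, 1]
#' @param hsp70_multiplier non-negative scaling of the HSP70 baseline
#' @param t_end end of the simulated time span, minutes
#' @return a `pkc_protocol`
#' @export
pkcProtocol <- function(synthesis_pulses = list(), activator_pulses = list(),
                        k17_blocks = list(), phlpp_block = 0,
                        hsp70_multiplier = 1, t_end) {
  stopifnot(t_end > 0, hsp70_multiplier >= 0)
  if (phlpp_block < 0 || phlpp_block > 1)
    stop("phlpp_block must lie in [0, 1]")
  as_pulses <- function(x) {
    if (inherits(x, "pkc_pulse")) x <- list(x)
    x[order(vapply(x, `[[`, numeric(1), "t_on"))]
  }
  activator_pulses <- as_pulses(activator_pulses)
  if (length(activator_pulses) > 1) {
    on <- vapply(activator_pulses, `[[`, numeric(1), "t_on")
    off <- on + vapply(activator_pulses, `[[`, numeric(1), "duration")
    if (any(on[-1] < off[-length(off)]))
      stop("overlapping activator pulses")
  }
  structure(list(
    synthesis_pulses = as_pulses(synthesis_pulses),
    activator_pulses = activator_pulses,
    k17_blocks = as_pulses(k17_blocks),
    phlpp_block = phlpp_block,
    hsp70_multiplier = hsp70_multiplier,
    t_end = t_end
  ), class = "pkc_protocol")
}

#' Translation signal at a time point
#'
#' `params$k3` inside any synthesis pulse (half-open windows), else 0.
#' @param t time in minutes
#' @param protocol a `pkc_protocol`
#' @param params a parameterization
#' @return effective k3 in per second
#' @export
k3At <- function(t, protocol, params) {
  on <- any(vapply(protocol$synthesis_pulses, .in_pulse, logical(1), t = t))
  if (on) params$k3 else 0
}

#' Activator (second-messenger) level at a time point
#' @inheritParams k3At
#' @return activator concentration in nM (0 outside all pulses)
#' @export
activatorAt <- function(t, protocol) {
  for (p in protocol$activator_pulses) if (.in_pulse(t, p)) return(p$amplitude)
  0
}

#' Effective dephosphorylation rate at a time point
#'
#' `k17 x (1 - phlpp_block)`, set to zero inside any blocking window. The
#' PHLPP concentration is folded into `k17`, so fractional PHLPP inhibition
#' and transient full blocking both act through this one effective constant.
#'
#' @inheritParams k3At
#' @return effective k17 in per second
#' @export
k17EffAt <- function(t, protocol, params) {
  blocked <- any(vapply(protocol$k17_blocks, .in_pulse, logical(1), t = t))
  if (blocked) 0 else params$k17 * (1 - protocol$phlpp_block)
}

#' Effective HSP70 level for a protocol
#'
#' Baseline level times the overexpression multiplier; constant over the run.
#' @param protocol a `pkc_protocol`
#' @param params a parameterization
#' @return clamped HSP70 level
#' @export
hsp70At <- function(protocol, params) {
  params$HSP70 * protocol$hsp70_multiplier
}

#' Discontinuity times of a protocol
#'
#' The sorted union of all pulse and blocking-window edges within
#' `[0, t_end]`; integration is restarted at each of them.
#'
#' @param protocol a `pkc_protocol`
#' @return numeric vector of times in minutes, including 0 and `t_end`
#' @export
breakTimes <- function(protocol) {
  edges <- unlist(lapply(
    c(protocol$synthesis_pulses, protocol$activator_pulses,
      protocol$k17_blocks),
    function(p) c(p$t_on, p$t_on + p$duration)))
  ts <- sort(unique(c(0, protocol$t_end, edges)))
  ts[ts >= 0 & ts <= protocol$t_end]
}

#' @export
print.pkc_protocol <- function(x, ...) {
  fmt <- function(ps) paste(vapply(ps, function(p)
    sprintf("[%g, %g) min @ %g", p$t_on, p$t_on + p$duration, p$amplitude),
    ""), collapse = ", ")
  cat("PKC stimulation protocol (t_end =", x$t_end, "min)\n")
  if (length(x$synthesis_pulses))
    cat("  synthesis pulses: ", fmt(x$synthesis_pulses), "\n")
  if (length(x$activator_pulses))
    cat("  activator pulses: ", fmt(x$activator_pulses), "\n")
  if (length(x$k17_blocks))
    cat("  k17 blocking windows: ", fmt(x$k17_blocks), "\n")
  if (x$phlpp_block > 0) cat("  PHLPP block fraction:", x$phlpp_block, "\n")
  if (x$hsp70_multiplier != 1)
    cat("  HSP70 multiplier:", x$hsp70_multiplier, "\n")
  invisible(x)
}
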