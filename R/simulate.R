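#' Simulate the PKC life cycle over a protocol
#'
#' Integrates the mass-action ODE system with a stiff BDF integrator
#' (deSolve), restarting the integration at every protocol discontinuity so
#' that no solver step straddles a parameter jump. Within each segment the
#' protocol-resolved effective constants (gated `k3`, activator level,
#' effective `k17`, HSP70 level) are constant.
#'
#' @param protocol a [pkcProtocol()]
#' @param params a parameterization (default: shipped defaults)
#' @param network a `pkc_network`; the base network unless the
#'   parameterization enables the dual-degradation variant (`lambda5 > 0`)
#' @param y0 initial state; defaults to the basal state ([initialState()])
#' @param output_dt output grid spacing in minutes
#' @param rtol,atol relative and absolute integration tolerances
#' @return a `pkc_trajectory`: `times` (minutes, includes every protocol
#'   edge), `states` (matrix, one named column per species), and provenance
#'   (`params`, `protocol`)
#' @export
simulatePkc <- function(protocol, params = defaultParams(),
                        network = buildDefaultNetwork(params$lambda5 > 0),
                        y0 = initialState(params),
                        output_dt = 0.5, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(protocol, "pkc_protocol"), output_dt > 0)
  params <- validateParams(params)
  if (!network$dual_degradation) params$lambda5 <- 0

  rhs <- function(t, y, p) list(pkcDerivatives(y, p$eff, p$clamped))

  edges <- breakTimes(protocol)
  times_out <- numeric(0)
  states <- NULL
  y <- unname(y0)
  for (i in seq_len(length(edges) - 1L)) {
    t0 <- edges[i]; t1 <- edges[i + 1L]
    mid <- (t0 + t1) / 2
    eff <- params
    eff$k3 <- k3At(mid, protocol, params)
    eff$k17 <- k17EffAt(mid, protocol, params)
    clamped <- c(T = params$T, PDK1 = params$PDK1, mTORC2 = params$mTORC2,
                 ACT = activatorAt(mid, protocol),
                 HSP70 = hsp70At(protocol, params))
    grid_min <- unique(c(seq(t0, t1, by = output_dt), t1))
    sol <- deSolve::ode(y = y, times = grid_min * 60, func = rhs,
                        parms = list(eff = eff, clamped = clamped),
                        method = "bdf", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
      stop(sprintf("integration failed on segment [%g, %g] min", t0, t1))
    seg <- unclass(sol)[, -1, drop = FALSE]
    if (any(!is.finite(seg)))
      stop(sprintf("non-finite state on segment [%g, %g] min", t0, t1))
    if (any(seg < -1e-6))
      stop(sprintf("negative concentrations beyond tolerance on [%g, %g] min",
                   t0, t1))
    keep <- if (i == 1L) seq_len(nrow(seg)) else -1L
    times_out <- c(times_out, grid_min[keep])
    states <- rbind(states, seg[keep, , drop = FALSE])
    y <- seg[nrow(seg), ]
    y[y < 0] <- 0  # absorb integrator round-off before the restart
  }
  colnames(states) <- .pkc_species$name
  structure(list(times = times_out, states = states, params = params,
                 protocol = protocol, rtol = rtol, atol = atol),
            class = "pkc_trajectory")
}

#' @export
print.pkc_trajectory <- function(x, ...) {
  cat(sprintf("PKC trajectory: %d time points over [0, %g] min, %d species\n",
              length(x$times), max(x$times), ncol(x$states)))
  tot <- conservedMoietyTotal(x$states)
  cat(sprintf("  total PKC: start %.3g, max %.3g, final %.3g ng/ml\n",
              tot[1], max(tot), tot[length(tot)]))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#' @param x a `pkc_trajectory`
#' @param ... unused
#' @return data.frame with columns `time_min`, `species`, `concentration`
#' @export
as.data.frame.pkc_trajectory <- function(x, ...) {
  data.frame(
    time_min = rep(x$times, times = ncol(x$states)),
    species = rep(colnames(x$states), each = length(x$times)),
    concentration = as.vector(x$states),
    stringsAsFactors = FALSE)
}

#' Time series of total PKC
#' @param trajectory a `pkc_trajectory`
#' @return data.frame with columns `time` (minutes) and `value` (ng/ml)
#' @export
totalPkcSeries <- function(trajectory) {
  data.frame(time = trajectory$times,
             value = conservedMoietyTotal(trajectory$states))
}

#' Time series of one species
#' @param trajectory a `pkc_trajectory`
#' @param species species name (see [pkcSpecies()])
#' @return data.frame with columns `time` and `value`
#' @export
speciesSeries <- function(trajectory, species) {
  data.frame(time = trajectory$times,
             value = trajectory$states[, species])
}

#' Plateau value of a series over a window
#'
#' Mean of the series over `window`, validated as stabilized: every local
#' finite-difference slope inside the window must stay below `slope_tol`.
#' The default tolerance sits above the intrinsic turnover drift of the
#' mature pool (about 0.006 ng/ml per minute at the 73 ng/ml plateau) and
#' far below stimulation transients.
#'
#' @param series data.frame with `time` (minutes) and `value`
#' @param window length-2 numeric, minutes
#' @param slope_tol maximum |slope| in value units per minute
#' @return plateau level (mean over the window)
#' @export
plateauValue <- function(series, window, slope_tol = 0.02) {
  sel <- series$time >= window[1] & series$time <= window[2]
  if (sum(sel) < 3) stop("plateau window contains fewer than 3 points")
  tt <- series$time[sel]; vv <- series$value[sel]
  slopes <- diff(vv) / diff(tt)
  if (any(abs(slopes) > slope_tol))
    stop(sprintf(paste0("series not stabilized in [%g, %g] min ",
                        "(max |slope| %.3g per min > %.3g)"),
                 window[1], window[2], max(abs(slopes)), slope_tol))
  mean(vv)
}

#' First crossing time of a fraction of the plateau
#'
#' First time at which the series reaches `fraction` times its plateau,
#' linearly interpolated between grid points. Used for maturation and
#' autophosphorylation half-times.
#'
#' @param series data.frame with `time` and `value`
#' @param fraction target fraction of the plateau (default one half)
#' @param plateau plateau level; defaults to the mean of the last tenth of
#'   the series
#' @return crossing time in minutes
#' @export
halfTime <- function(series, fraction = 0.5, plateau = NULL) {
  if (is.null(plateau)) {
    n <- nrow(series)
    plateau <- mean(series$value[series$time >=
      series$time[n] - 0.1 * (series$time[n] - series$time[1])])
  }
  target <- fraction * plateau
  if (series$value[1] >= target)
    stop("series starts at or above the target fraction of its plateau")
  above <- which(series$value >= target)
  if (!length(above)) stop("series never reaches the target fraction")
  i <- above[1]
  t0 <- series$time[i - 1]; t1 <- series$time[i]
  v0 <- series$value[i - 1]; v1 <- series$value[i]
  t0 + (target - v0) / (v1 - v0) * (t1 - t0)
}

#' Stabilized drop caused by one pulse
#'
#' Pre-pulse plateau minus post-pulse plateau: the pre-pulse plateau is
#' taken over `pre_window` minutes ending at pulse onset, the post-pulse
#' plateau from `settle_delay` minutes after pulse end up to `next_event`
#' (default: end of the series).
#'
#' @param series data.frame with `time` and `value`
#' @param pulse the [pulse()] whose effect is measured
#' @param next_event time bounding the post-pulse window, minutes
#' @param settle_delay minutes allowed for post-pulse relaxation (long enough for the dephosphorylated pool, half-life about 12 min, to clear)
#' @param pre_window length of the pre-pulse plateau window, minutes
#' @param slope_tol passed to [plateauValue()]
#' @return drop in series units (positive = net loss)
#' @export
dropAfterPulse <- function(series, pulse, next_event = NULL,
                           settle_delay = 60, pre_window = 10,
                           slope_tol = 0.02) {
  if (is.null(next_event)) next_event <- max(series$time)
  t_off <- pulse$t_on + pulse$duration
  pre <- plateauValue(series, c(pulse$t_on - pre_window, pulse$t_on),
                      slope_tol = slope_tol)
  post <- plateauValue(series, c(t_off + settle_delay, next_event),
                       slope_tol = slope_tol)
  pre - post
}
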