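# Simplified two-variable Izhikevich simulator and the canonical catalog of
# twenty firing behaviors used as ground truth throughout the package.

#' Constant-current stimulus protocol
#'
#' A stimulus is a baseline current plus an ordered set of non-overlapping
#' segments.  Each segment holds `amplitude` (optionally with a linear
#' `slope` in pA/ms so current ramps can be expressed) over `[start, end)`.
#'
#' @param segments data.frame with columns `start`, `end` (ms), `amplitude`
#'   and optionally `slope` (defaults to 0).
#' @param baseline current outside all segments.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(segments = NULL, baseline = 0) {
  if (is.null(segments)) {
    segments <- data.frame(start = numeric(), end = numeric(),
                           amplitude = numeric(), slope = numeric())
  }
  segments <- as.data.frame(segments)
  if (is.null(segments$slope)) segments$slope <- rep(0, nrow(segments))
  segments <- segments[segments$end > segments$start, , drop = FALSE]
  if (nrow(segments) > 1) {
    segments <- segments[order(segments$start), , drop = FALSE]
    if (any(segments$start[-1] < segments$end[-nrow(segments)]))
      stop("stimulus segments overlap")
  }
  rownames(segments) <- NULL
  structure(list(segments = segments, baseline = baseline),
            class = "stimulus_protocol")
}

#' Evaluate a stimulus protocol on a time grid
#'
#' @param protocol a [stimulus_protocol()].
#' @param t numeric vector of times (ms).
#' @return numeric vector of injected current, same length as `t`.
#' @export
stimulus_current <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  I <- rep(protocol$baseline, length(t))
  seg <- protocol$segments
  for (i in seq_len(nrow(seg))) {
    idx <- t >= seg$start[i] & t < seg$end[i]
    I[idx] <- seg$amplitude[i] + seg$slope[i] * (t[idx] - seg$start[i])
  }
  I
}

#' Single firing-behavior specification
#'
#' Bundles the Izhikevich hyperparameters `(a, b, c, d)`, the initial state,
#' the integration grid and the stimulus protocol for one behavior.  The
#' quadratic nullcline coefficients default to the cortical-neuron fit
#' `0.04 v^2 + 5 v + 140`; two behaviors (class 1 excitable and integrator)
#' use the published variant `0.04 v^2 + 4.1 v + 108`.  The accommodation
#' behavior integrates the recovery variable from the depolarization
#' `v + 65` without leak, `du = a b (v + 65)` (`u_rule = "shifted"`),
#' again following the published protocol set.
#'
#' @param name short behavior key, one of `"a"`..`"t"` in the default catalog.
#' @param label human-readable behavior name.
#' @param a,b,c,d Izhikevich hyperparameters (dimensionless).
#' @param v0,u0 initial membrane potential (mV) and recovery value.
#' @param dt integration step (ms).
#' @param n_steps number of samples (>= 2).
#' @param stimulus a [stimulus_protocol()].
#' @param quad length-3 numeric `(k2, k1, k0)` of the quadratic rate
#'   `k2 v^2 + k1 v + k0`.
#' @param u_rule `"standard"` (`du = a (b v - u)`) or `"shifted"`
#'   (`du = a b (v + 65)`, the leak-free accommodation rule).
#' @param target_params target pruned-coefficient count carried along for the
#'   benchmark's parameter-parity protocol.
#' @return object of class `behavior_spec`.
#' @export
behavior_spec <- function(name, label = name, a, b, c, d, v0, u0 = b * v0,
                          dt = 0.25, n_steps, stimulus = stimulus_protocol(),
                          quad = c(0.04, 5, 140), u_rule = c("standard", "shifted"),
                          target_params = NA_integer_) {
  u_rule <- match.arg(u_rule)
  stopifnot(dt > 0, n_steps >= 2, length(quad) == 3)
  duration <- n_steps * dt
  seg <- stimulus$segments
  if (nrow(seg) && (min(seg$start) < 0 || max(seg$end) > duration + 1e-9))
    stop("stimulus segments fall outside [0, n_steps * dt] for behavior ", name)
  structure(list(name = name, label = label, a = a, b = b, c = c, d = d,
                 v0 = v0, u0 = u0, dt = dt, n_steps = as.integer(n_steps),
                 stimulus = stimulus, quad = quad, u_rule = u_rule,
                 target_params = target_params),
            class = "behavior_spec")
}

#' @export
print.behavior_spec <- function(x, ...) {
  cat(sprintf("behavior_spec '%s' (%s): a=%g b=%g c=%g d=%g, v0=%g, dt=%g ms, n=%d (%g ms)\n",
              x$name, x$label, x$a, x$b, x$c, x$d, x$v0, x$dt, x$n_steps,
              x$n_steps * x$dt))
  invisible(x)
}

# Per-behavior defaults.  n_default is the sample count at scale = 1 with
# dt = 0.25 ms; protocols are expressed relative to the total duration D,
# with pulse widths and resonance-critical gaps kept absolute so the firing
# pattern survives rescaling.  target_params is the pruned-model coefficient
# budget shared by RSRM/RSSRM/PCR/RCR at scale 1.
.behavior_defaults <- function() {
  seg <- function(start, end, amplitude, slope = 0)
    data.frame(start = start, end = end, amplitude = amplitude, slope = slope)
  list(
    a = list(label = "tonic spiking", a = 0.02, b = 0.2, c = -65, d = 6,
             v0 = -70, n = 20000, target = 95,
             stim = function(D) stimulus_protocol(seg(0.1 * D, D, 14))),
    b = list(label = "phasic spiking", a = 0.02, b = 0.25, c = -65, d = 6,
             v0 = -64, n = 9000, target = 109,
             stim = function(D) stimulus_protocol(seg(0.55 * D, D, 0.5))),
    c = list(label = "tonic bursting", a = 0.02, b = 0.2, c = -50, d = 2,
             v0 = -70, n = 19000, target = 100,
             stim = function(D) stimulus_protocol(seg(0.1 * D, D, 15))),
    d = list(label = "phasic bursting", a = 0.02, b = 0.25, c = -55, d = 0.05,
             v0 = -64, n = 20000, target = 101,
             stim = function(D) stimulus_protocol(seg(0.55 * D, D, 0.6))),
    e = list(label = "mixed mode", a = 0.02, b = 0.2, c = -55, d = 4,
             v0 = -70, n = 20000, target = 137,
             stim = function(D) stimulus_protocol(seg(0.1 * D, D, 10))),
    f = list(label = "spike frequency adaptation", a = 0.01, b = 0.2, c = -65,
             d = 8, v0 = -70, n = 20000, target = 127,
             stim = function(D) stimulus_protocol(seg(0.1 * D, D, 30))),
    g = list(label = "class 1 excitable", a = 0.02, b = -0.1, c = -55, d = 6,
             v0 = -60, n = 20000, target = 200, quad = c(0.04, 4.1, 108),
             stim = function(D) {
               t0 <- 0.3 * D; t1 <- min(t0 + 270, D)
               stimulus_protocol(rbind(
                 seg(t0, t1, 0, slope = 0.075),
                 seg(t1, D, 0.075 * (t1 - t0))))
             }),
    h = list(label = "class 2 excitable", a = 0.2, b = 0.26, c = -65, d = 0,
             v0 = -64, n = 20000, target = 201,
             stim = function(D) {
               t0 <- 0.3 * D; t1 <- min(t0 + 270, D)
               stimulus_protocol(rbind(
                 seg(t0, t1, -0.5, slope = 0.015),
                 seg(t1, D, -0.5 + 0.015 * (t1 - t0))),
                 baseline = -0.5)
             }),
    i = list(label = "spike latency", a = 0.02, b = 0.2, c = -65, d = 6,
             v0 = -70, n = 20000, target = 102,
             stim = function(D) stimulus_protocol(seg(0.55 * D, 0.55 * D + 3, 7.04))),
    j = list(label = "subthreshold oscillations", a = 0.05, b = 0.26, c = -60,
             d = 0, v0 = -62, n = 15100, target = 97, min_D = 16,
             stim = function(D) stimulus_protocol(seg(0.55 * D, 0.55 * D + 5, 2))),
    k = list(label = "resonator", a = 0.1, b = 0.26, c = -60, d = -1,
             v0 = -62.5, n = 4000, target = 10, min_D = 64,
             stim = function(D) {
               # resonant pair: gap 40 ms matches the subthreshold
               # eigenperiod; an off-resonance 20 ms pair follows when the
               # recording is long enough to hold it
               r1 <- 0.25 * D
               pulses <- rbind(seg(r1, r1 + 4, 0.65),
                               seg(r1 + 40, r1 + 44, 0.65))
               if (D >= 185) {
                 p1 <- 0.65 * D
                 pulses <- rbind(pulses, seg(p1, p1 + 4, 0.65),
                                 seg(p1 + 20, p1 + 24, 0.65))
               }
               stimulus_protocol(pulses)
             }),
    l = list(label = "integrator", a = 0.02, b = -0.1, c = -55, d = 6,
             v0 = -60, n = 5300, target = 20, quad = c(0.04, 4.1, 108),
             min_D = 44,
             stim = function(D) {
               p1 <- 0.55 * D; p2 <- 0.1 * D
               stimulus_protocol(rbind(
                 seg(p1, p1 + 2, 9), seg(p1 + 5, p1 + 7, 9),
                 seg(p2, p2 + 2, 9), seg(p2 + 15, p2 + 17, 9)))
             }),
    m = list(label = "rebound spike", a = 0.03, b = 0.25, c = -60, d = 4,
             v0 = -64, n = 3500, target = 22,
             stim = function(D) stimulus_protocol(seg(0.55 * D, 0.55 * D + 5, -15))),
    n = list(label = "rebound burst", a = 0.03, b = 0.25, c = -52, d = 0,
             v0 = -64, n = 25000, target = 105,
             stim = function(D) stimulus_protocol(seg(0.55 * D, 0.55 * D + 5, -15))),
    o = list(label = "threshold variability", a = 0.03, b = 0.25, c = -60,
             d = 4, v0 = -64, n = 6200, target = 30, min_D = 64,
             stim = function(D) {
               t1 <- 0.55 * D; t2 <- 0.75 * D
               stimulus_protocol(rbind(
                 seg(t1, t1 + 5, 1),          # suprathreshold alone -> spike
                 seg(t2, t2 + 5, -6),         # brief inhibition
                 seg(t2 + 10, t2 + 15, 1)))   # same pulse, now subthreshold
             }),
    p = list(label = "bistability", a = 0.1, b = 0.26, c = -60, d = 0,
             v0 = -61, n = 20000, target = 172,
             stim = function(D) stimulus_protocol(rbind(
               seg(D / 8, D / 8 + 5, 1.24),
               seg(0.72 * D, 0.72 * D + 5, 1.24)), baseline = 0.24)),
    q = list(label = "depolarizing after-potential", a = 1, b = 0.2, c = -60,
             d = -21, v0 = -70, n = 1646, target = 10,
             stim = function(D) stimulus_protocol(seg(0.55 * D - 1, 0.55 * D + 1, 20))),
    r = list(label = "accommodation", a = 0.02, b = 1, c = -55, d = 4,
             v0 = -65, u0 = -16, n = 9500, target = 51, u_rule = "shifted",
             min_D = 32,
             stim = function(D) {
               ramp_end <- min(200, 0.5 * D)
               t1 <- 0.75 * D
               stimulus_protocol(rbind(
                 seg(0, ramp_end, 0, slope = 0.04),  # slow ramp: accommodated
                 seg(t1, t1 + 6, 4)))                # fast step -> one spike
             }),
    s = list(label = "inhibition-induced spiking", a = -0.02, b = -1, c = -60,
             d = 8, v0 = -63.8, n = 20000, target = 160,
             stim = function(D) stimulus_protocol(seg(0.3 * D, 0.85 * D, 75),
                                                  baseline = 80)),
    t = list(label = "inhibition-induced bursting", a = -0.026, b = -1,
             c = -45, d = 0, v0 = -63.8, n = 20000, target = 156,
             stim = function(D) stimulus_protocol(seg(0.3 * D, 0.85 * D, 75),
                                                  baseline = 80))
  )
}

#' Catalog of the twenty canonical firing behaviors
#'
#' Builds [behavior_spec()] objects for behaviors `"a"` through `"t"`
#' (tonic spiking ... inhibition-induced bursting) with the published
#' Izhikevich hyperparameters and stimulus protocols.  Durations default to
#' several seconds per behavior; `scale` shrinks (or stretches) every
#' behavior's sample count proportionally while keeping stimulus timing
#' relative to the recording length, so the firing classes are preserved.
#'
#' @param dt integration step in ms (default 0.25).  Changing `dt` keeps the
#'   physical duration fixed and adjusts `n_steps` accordingly.
#' @param scale duration scale factor (> 0); `scale = 0.1` gives recordings
#'   ten times shorter than the defaults.
#' @param names optional subset of behavior keys to build.
#' @return named list of `behavior_spec` objects.
#' @export
behavior_catalog <- function(dt = 0.25, scale = 1, names = NULL) {
  stopifnot(dt > 0, scale > 0)
  defs <- .behavior_defaults()
  if (is.null(names)) names <- base::names(defs)
  unknown <- setdiff(names, base::names(defs))
  if (length(unknown))
    stop("unknown behavior name(s): ", paste(unknown, collapse = ", "))
  out <- lapply(names, function(nm) {
    def <- defs[[nm]]
    n_steps <- max(2L, as.integer(round(def$n * scale * 0.25 / dt)))
    # durations never shrink below the behavior's protocol window (absolute
    # pulse gaps, e.g. the resonator's 40 ms resonant pair, must still fit)
    if (!is.null(def$min_D))
      n_steps <- max(n_steps, as.integer(ceiling(def$min_D / dt)))
    D <- n_steps * dt
    behavior_spec(name = nm, label = def$label,
                  a = def$a, b = def$b, c = def$c, d = def$d,
                  v0 = def$v0,
                  u0 = if (is.null(def$u0)) def$b * def$v0 else def$u0,
                  dt = dt, n_steps = n_steps, stimulus = def$stim(D),
                  quad = if (is.null(def$quad)) c(0.04, 5, 140) else def$quad,
                  u_rule = if (is.null(def$u_rule)) "standard" else def$u_rule,
                  target_params = max(2L, as.integer(round(def$target * scale))))
  })
  stats::setNames(out, names)
}

#' Simulate one behavior by forward Euler integration
#'
#' Integrates `dv/dt = k2 v^2 + k1 v + k0 - u + I`, `du/dt = a (b v - u)`
#' with step `dt`, updating `v` and `u` simultaneously from the previous
#' state.  Whenever the updated `v` reaches 30 mV the stored sample is
#' clamped to 30 mV, the spike time is recorded, and the state resets to
#' `(c, u + d)` before the next step.  The simulation is deterministic.
#'
#' @param spec a [behavior_spec()].
#' @return object of class `neuron_trace`: list with `t`, `I`, `v`, `u`
#'   (length `n_steps`), `spike_times` (ms), `dt`, `name`.
#' @export
simulate_behavior <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  n <- spec$n_steps
  dt <- spec$dt
  t <- (seq_len(n) - 1) * dt
  I <- stimulus_current(spec$stimulus, t)
  v <- numeric(n); u <- numeric(n)
  k2 <- spec$quad[1]; k1 <- spec$quad[2]; k0 <- spec$quad[3]
  shifted <- spec$u_rule == "shifted"
  vi <- spec$v0; ui <- spec$u0
  v[1] <- vi; u[1] <- ui
  spike_idx <- integer(0)
  # the first stored sample is the initial condition; it can itself be a
  # spike only if v0 >= 30, which valid specs exclude
  for (i in seq_len(n - 1)) {
    dv <- k2 * vi * vi + k1 * vi + k0 - ui + I[i]
    v_new <- vi + dt * dv
    if (!is.finite(v_new))
      stop(sprintf("numerical overflow in behavior '%s' at step %d", spec$name, i + 1))
    # on firing steps the recovery update sees the action-potential peak
    # (the pre-clamp overshoot), matching the canonical reset bookkeeping;
    # on subthreshold steps both variables advance from the previous state
    vref <- if (v_new >= 30) v_new else vi
    du <- if (shifted) spec$a * spec$b * (vref + 65)
          else spec$a * (spec$b * vref - ui)
    u_new <- ui + dt * du
    if (!is.finite(u_new))
      stop(sprintf("numerical overflow in behavior '%s' at step %d", spec$name, i + 1))
    if (v_new >= 30) {
      v[i + 1] <- 30
      u[i + 1] <- u_new
      spike_idx <- c(spike_idx, i + 1L)
      vi <- spec$c
      ui <- u_new + spec$d
    } else {
      v[i + 1] <- v_new
      u[i + 1] <- u_new
      vi <- v_new
      ui <- u_new
    }
  }
  structure(list(t = t, I = I, v = v, u = u,
                 spike_times = t[spike_idx], dt = dt, name = spec$name),
            class = "neuron_trace")
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat(sprintf("neuron_trace '%s': %d samples, dt=%g ms (%g ms), %d spikes\n",
              x$name, length(x$v), x$dt, length(x$v) * x$dt,
              length(x$spike_times)))
  invisible(x)
}

#' Spike train on a sample grid
#'
#' Represents a spike train both as a 0/1 indicator over samples and as the
#' equivalent spike-time stamps; `r` is the firing proportion
#' (spike count / sample count).
#'
#' @param times spike times (ms), strictly increasing, aligned to the grid.
#' @param n_steps number of samples on the grid.
#' @param dt grid step (ms).
#' @param t0 time of the first sample (ms).
#' @return object of class `spike_train` with fields `times`, `indicator`,
#'   `r`, `n_steps`, `dt`, `t0`.
#' @export
spike_train <- function(times, n_steps, dt, t0 = 0) {
  times <- sort(as.numeric(times))
  idx <- as.integer(round((times - t0) / dt)) + 1L
  if (length(idx) && (any(idx < 1) || any(idx > n_steps)))
    stop("spike times fall outside the sample grid")
  indicator <- integer(n_steps)
  indicator[idx] <- 1L
  structure(list(times = t0 + (idx - 1L) * dt, indicator = indicator,
                 r = length(idx) / n_steps, n_steps = as.integer(n_steps),
                 dt = dt, t0 = t0),
            class = "spike_train")
}

#' Extract the ground-truth spike train from a trace
#'
#' @param trace a `neuron_trace`.
#' @return a [spike_train()] on the trace's grid.
#' @export
extract_spike_train <- function(trace) {
  stopifnot(inherits(trace, "neuron_trace"))
  spike_train(trace$spike_times, n_steps = length(trace$v), dt = trace$dt,
              t0 = trace$t[1])
}

#' Classify a trace as one-spike or multiple-spike
#'
#' The twenty canonical behaviors split into nine that fire exactly one
#' spike and eleven that fire repeatedly.  Traces with no spikes are
#' degenerate for benchmarking and return `NA` with a warning.
#'
#' @param trace a `neuron_trace`.
#' @return `"one-spike"`, `"multiple-spike"`, or `NA` for zero spikes.
#' @export
classify_behavior <- function(trace) {
  stopifnot(inherits(trace, "neuron_trace"))
  k <- length(trace$spike_times)
  if (k == 0) {
    warning(sprintf("trace '%s' has no spikes: degenerate, excluded from both classes",
                    trace$name))
    return(NA_character_)
  }
  if (k == 1) "one-spike" else "multiple-spike"
}
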