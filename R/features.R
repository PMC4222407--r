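# Excitability feature extraction from current-clamp trace families:
# spike detection, F-I fit (rheobase and gain), input resistance, post-train
# AHP amplitude and action-potential voltage threshold.

#' Detect action potentials in a current-clamp trace
#'
#' Spikes are upward crossings of the detection threshold separated by at
#' least the refractory period; crossing times are linearly interpolated.
#'
#' @param trace an `ephys_trace` (current clamp)
#' @param threshold detection threshold, mV
#' @param refractory minimum inter-spike interval, ms
#' @param window optional `c(t0, t1)` restricting detection, ms
#' @return numeric vector of spike times, ms
#' @export
detect_spikes <- function(trace, threshold = -10, refractory = 2,
                          window = NULL) {
  if (trace$mode != "current_clamp")
    stop("spike detection requires a current-clamp trace")
  v <- trace$values
  t <- trace_time(trace)
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  times <- t[up] + frac * trace$dt
  keep <- c(TRUE, diff(times) >= refractory)
  # enforce refractory sequentially (diff-based pass can readmit bursts)
  times <- times[keep]
  if (length(times) > 1) {
    out <- times[1]
    for (tt in times[-1]) if (tt - out[length(out)] >= refractory) out <- c(out, tt)
    times <- out
  }
  if (!is.null(window)) times <- times[times >= window[1] & times <= window[2]]
  times
}

#' Spike counts per amplitude for a trace family
#'
#' Counts spikes inside each trace's stimulus window.
#'
#' @param traceset a `trace_family`
#' @param ... passed to [detect_spikes()]
#' @return data.frame with `amplitude` (pA) and `count`
#' @export
spike_counts <- function(traceset, ...) {
  data.frame(
    amplitude = family_amplitudes(traceset),
    count = vapply(traceset$traces, function(tr) {
      win <- if (!is.na(tr$t_on)) c(tr$t_on, tr$t_off) else NULL
      length(detect_spikes(tr, window = win, ...))
    }, 0L))
}

# Select the first linear portion of the F-I relation: start at the first
# suprathreshold amplitude, extend while the fit stays linear (R^2 >= r2_min)
# and the incremental slope keeps at least half of the initial pairwise
# slope; between 2 and max_points points.
select_fi_points <- function(amps, rates, r2_min = 0.95, slope_keep = 0.5,
                             max_points = 5, min_points = 3) {
  supra <- which(rates > 0)
  if (length(supra) < 2) stop("need at least 2 suprathreshold amplitudes")
  start <- supra[1]
  # a flat low-rate shelf before the rising limb is not part of the linear
  # portion; advance to the last point of the shelf
  while (start < length(rates) - 1 && rates[start + 1] <= rates[start])
    start <- start + 1
  idx <- start:(start + 1)
  if (idx[2] > length(amps)) stop("need at least 2 suprathreshold amplitudes")
  slope0 <- (rates[idx[2]] - rates[idx[1]]) / (amps[idx[2]] - amps[idx[1]])
  while (length(idx) < max_points && max(idx) < length(amps)) {
    cand <- c(idx, max(idx) + 1)
    fit <- lm(rates[cand] ~ amps[cand])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    inc <- (rates[max(cand)] - rates[max(idx)]) / (amps[max(cand)] - amps[max(idx)])
    keep_linear <- r2 >= r2_min || length(cand) <= min_points
    keep_slope <- inc >= slope_keep * slope0 || slope0 == 0
    if (keep_linear && keep_slope) idx <- cand else break
  }
  idx
}

#' Rheobase and F-I slope from a step family
#'
#' Fits a least-squares line through the first linear portion of the
#' firing-rate vs injected-current relation. The slope is the F-I gain
#' (Hz/nA); the rheobase is the abscissa intercept of the fit (pA), which
#' may fall between tested amplitudes.
#'
#' @param traceset a `trace_family`, or a data.frame with `amplitude` (pA)
#'   and `count` columns plus a known step duration
#' @param duration stimulus duration used for rate conversion, ms (taken from
#'   the traces when available)
#' @param ... selection-rule tuning passed to the internal point selector
#' @return list with `rheobase` (pA), `fi_slope` (Hz/nA), `fit_points_used`
#'   (amplitudes, pA) and `spike_counts`
#' @export
fi_features <- function(traceset, duration = NULL, ...) {
  if (inherits(traceset, "trace_family")) {
    counts <- spike_counts(traceset)
    if (is.null(duration)) {
      tr <- traceset$traces[[1]]
      duration <- tr$t_off - tr$t_on
    }
  } else {
    counts <- traceset
    if (is.null(duration)) stop("duration required with bare count tables")
  }
  counts <- counts[order(counts$amplitude), ]
  rates <- counts$count / (duration / 1000) # Hz
  amps_nA <- counts$amplitude / 1000
  idx <- select_fi_points(counts$amplitude, rates, ...)
  fit <- lm(rates[idx] ~ amps_nA[idx])
  slope <- unname(coef(fit)[2]) # Hz/nA
  rheo <- -unname(coef(fit)[1]) / slope * 1000 # pA
  list(rheobase = rheo, fi_slope = slope,
       fit_points_used = counts$amplitude[idx], spike_counts = counts)
}

#' Input resistance from subthreshold steps
#'
#' Least-squares slope of the steady-state voltage-current relation using
#' the -50, 0 and +50 pA traces; steady-state voltage is the mean over the
#' last part of the step.
#'
#' @param traceset a `trace_family` containing (at least) -50, 0 and +50 pA
#'   steps
#' @param amplitudes which amplitudes to use, pA
#' @param steady_window averaging window before stimulus offset, ms
#' @return input resistance, MOhm
#' @export
input_resistance <- function(traceset, amplitudes = c(-50, 0, 50),
                             steady_window = 200) {
  amps <- family_amplitudes(traceset)
  sel <- match(amplitudes, amps)
  if (anyNA(sel)) stop("trace family lacks the required amplitudes: ",
                       paste(amplitudes[is.na(sel)], collapse = ", "))
  vss <- vapply(traceset$traces[sel], function(tr) {
    if (length(detect_spikes(tr)))
      stop("input resistance requires subthreshold traces (spike detected)")
    t <- trace_time(tr)
    mean(tr$values[t > tr$t_off - steady_window & t <= tr$t_off])
  }, 0)
  fit <- lm(vss ~ amplitudes)
  unname(coef(fit)[2]) * 1000 # mV/pA -> MOhm
}

#' Post-train after-hyperpolarization amplitude
#'
#' The difference between the settled post-stimulus potential (mean of the
#' last `steady_window` ms of the trace) and the deepest hyperpolarization
#' within `search_window` ms after stimulus offset, reported as a positive
#' magnitude; 0 when the relaxation has no undershoot.
#'
#' @param trace an `ephys_trace` with >= 1 s of post-stimulus recording
#' @param search_window ms after stimulus offset searched for the trough
#' @param steady_window ms at the trace end defining the settled potential
#' @return AHP amplitude, mV (>= 0)
#' @export
ahp_amplitude <- function(trace, search_window = 500, steady_window = 100) {
  t <- trace_time(trace)
  if (is.na(trace$t_off) || trace$t_off > max(t))
    stop("stimulus offset not contained in the trace")
  if (max(t) - trace$t_off < 1000)
    stop("need >= 1 s of post-stimulus recording")
  steady <- mean(trace$values[t > max(t) - steady_window])
  trough <- min(trace$values[t > trace$t_off & t <= trace$t_off + search_window])
  max(steady - trough, 0)
}

#' Action-potential voltage threshold (third-derivative method)
#'
#' The membrane potential at the time of the first local maximum of the
#' third time-derivative of the voltage preceding the first spike peak.
#' Derivatives are estimated on a locally smoothed trace (quartic
#' Savitzky-Golay polynomial over a 1-ms window) and the search is limited
#' to a short pre-peak window.
#'
#' @param trace an `ephys_trace` sampled at 0.1 ms or faster
#' @param spike_time optional first spike time (defaults to the first
#'   detected spike)
#' @param smooth_window smoothing window, ms
#' @param search_span window before the spike peak searched for the
#'   derivative peak, ms
#' @return voltage threshold, mV
#' @export
ap_voltage_threshold <- function(trace, spike_time = NULL, smooth_window = 1,
                                 search_span = 3) {
  if (trace$dt > 0.1)
    stop("sampling interval above 0.1 ms: third derivative unreliable")
  if (is.null(spike_time)) {
    st <- detect_spikes(trace)
    if (!length(st)) stop("no spike detected")
    spike_time <- st[1]
  }
  t <- trace_time(trace)
  v <- trace$values
  np <- max(5, 2 * floor(smooth_window / trace$dt / 2) + 1)
  vs <- signal::sgolayfilt(v, p = 4, n = np)
  # spike peak after the detection crossing
  peak_region <- which(t >= spike_time & t <= spike_time + 2)
  i_peak <- peak_region[which.max(vs[peak_region])]
  d3 <- diff(vs, differences = 3) / trace$dt^3
  t3 <- t[seq_along(d3)] + 1.5 * trace$dt # centre of the difference stencil
  sel <- which(t3 >= t[i_peak] - search_span & t3 <= t[i_peak])
  if (length(sel) < 5) stop("search window too short for threshold estimation")
  d3w <- d3[sel]
  locmax <- which(diff(sign(diff(d3w))) < 0) + 1
  locmax <- locmax[d3w[locmax] > 0.05 * max(d3w)] # ignore numerical ripple
  i3 <- if (length(locmax)) sel[locmax[1]] else sel[which.max(d3w)]
  approx(t, vs, xout = t3[i3])$y
}

#' Extract the full excitability feature set
#'
#' Convenience wrapper running all extractors on a step family (plus an
#' optional dedicated AHP trace).
#'
#' @param traceset a `trace_family` covering subthreshold (-50..50 pA) and
#'   suprathreshold steps
#' @param ahp_trace optional long-post-window trace for the AHP
#' @return list of class `feature_set`: rheobase (pA), fi_slope (Hz/nA),
#'   input_resistance (MOhm), ahp_amplitude (mV or NA), ap_threshold (mV or
#'   NA), spike_counts, fit_points_used
#' @export
extract_features <- function(traceset, ahp_trace = NULL) {
  fi <- fi_features(traceset)
  rin <- tryCatch(input_resistance(traceset), error = function(e) NA_real_)
  ahp <- if (!is.null(ahp_trace)) ahp_amplitude(ahp_trace) else NA_real_
  thr <- tryCatch({
    counts <- fi$spike_counts
    first_supra <- counts$amplitude[which(counts$count > 0)[1]]
    tr <- traceset$traces[[match(first_supra, family_amplitudes(traceset))]]
    ap_voltage_threshold(tr)
  }, error = function(e) NA_real_)
  structure(list(rheobase = fi$rheobase, fi_slope = fi$fi_slope,
                 input_resistance = rin, ahp_amplitude = ahp,
                 ap_threshold = thr, spike_counts = fi$spike_counts,
                 fit_points_used = fi$fit_points_used),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>\n")
  cat(sprintf("  rheobase         %8.1f pA\n", x$rheobase))
  cat(sprintf("  F-I slope        %8.1f Hz/nA\n", x$fi_slope))
  cat(sprintf("  input resistance %8.1f MOhm\n", x$input_resistance))
  if (!is.na(x$ahp_amplitude))
    cat(sprintf("  AHP amplitude    %8.2f mV\n", x$ahp_amplitude))
  if (!is.na(x$ap_threshold))
    cat(sprintf("  AP threshold     %8.1f mV\n", x$ap_threshold))
  invisible(x)
}
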