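# Trace containers: uniformly sampled recordings from simulations or
# external sources, plus delimited-table I/O.

#' Construct an electrophysiology trace
#'
#' @param values numeric vector, mV (current clamp) or pA (voltage clamp)
#' @param dt sampling interval, ms
#' @param amplitude stimulus amplitude, pA (current clamp) or mV (voltage
#'   clamp command)
#' @param mode "current_clamp" or "voltage_clamp"
#' @param t_on,t_off stimulus onset/offset times, ms from trace start
#' @param metadata free-form list (protocol and model identifiers)
#' @return object of class `ephys_trace`
#' @export
ephys_trace <- function(values, dt, amplitude = NA_real_,
                        mode = c("current_clamp", "voltage_clamp"),
                        t_on = NA_real_, t_off = NA_real_, metadata = list()) {
  mode <- match.arg(mode)
  if (!all(is.finite(values))) stop("trace contains non-finite values")
  if (dt <= 0) stop("sampling interval must be positive")
  structure(list(values = as.numeric(values), dt = dt, amplitude = amplitude,
                 mode = mode, t_on = t_on, t_off = t_off, metadata = metadata),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s, %d samples @ %.3g ms (%.0f ms), amplitude %s\n",
              x$mode, length(x$values), x$dt, length(x$values) * x$dt,
              if (is.na(x$amplitude)) "?" else
                paste0(x$amplitude, if (x$mode == "current_clamp") " pA" else " mV")))
  invisible(x)
}

trace_time <- function(trace) seq_along(trace$values) * trace$dt

#' @export
as.data.frame.ephys_trace <- function(x, ...) {
  data.frame(time = trace_time(x), value = x$values, amplitude = x$amplitude)
}

#' Bundle traces from one protocol into a family
#'
#' @param traces list of `ephys_trace`
#' @param protocol free-form protocol description list
#' @return object of class `trace_family`
#' @export
trace_family <- function(traces, protocol = list()) {
  stopifnot(all(vapply(traces, inherits, TRUE, "ephys_trace")))
  amps <- vapply(traces, `[[`, 0, "amplitude")
  structure(list(traces = traces[order(amps)], protocol = protocol),
            class = "trace_family")
}

#' @export
print.trace_family <- function(x, ...) {
  amps <- family_amplitudes(x)
  cat(sprintf("<trace_family> %d traces, amplitudes %s\n", length(x$traces),
              paste(range(amps), collapse = "..")))
  invisible(x)
}

#' @export
length.trace_family <- function(x) length(x$traces)

family_amplitudes <- function(family) vapply(family$traces, `[[`, 0, "amplitude")

#' Write a trace family as a delimited long-format table
#'
#' Columns: time (ms), value (mV or pA), amplitude (pA or mV).
#'
#' @param family a `trace_family` (or single `ephys_trace`)
#' @param path output file
#' @export
write_trace_table <- function(family, path) {
  if (inherits(family, "ephys_trace")) family <- trace_family(list(family))
  df <- do.call(rbind, lapply(family$traces, as.data.frame))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace family from a delimited table
#'
#' Expects the long format written by [write_trace_table()]: time, value,
#' amplitude. The sampling interval is inferred from the time column;
#' stimulus timing can be supplied since external tables need not carry it.
#'
#' @param path input file
#' @param mode recording mode of the stored traces
#' @param t_on,t_off stimulus onset/offset, ms
#' @return a `trace_family`
#' @export
read_trace_table <- function(path, mode = "current_clamp",
                             t_on = NA_real_, t_off = NA_real_) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time", "value", "amplitude") %in% names(df)))
  traces <- lapply(split(df, df$amplitude), function(d) {
    d <- d[order(d$time), ]
    ephys_trace(d$value, dt = stats::median(diff(d$time)),
                amplitude = d$amplitude[1], mode = mode,
                t_on = t_on, t_off = t_off)
  })
  trace_family(unname(traces))
}

#' Describe a stimulation protocol
#'
#' @param mode "current_clamp" or "voltage_clamp"
#' @param steps list of `list(amplitude = , duration = )` entries (pA and ms
#'   for current clamp, mV and ms for voltage clamp)
#' @param inter_step_interval ms between steps of a family (modelled as full
#'   re-equilibration)
#' @param step_increment pA, for step families
#' @param injection_site compartment id (default: the soma root)
#' @param holding holding level between/before steps (pA or mV)
#' @return object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(mode = c("current_clamp", "voltage_clamp"),
                              steps, inter_step_interval = 5000,
                              step_increment = NA_real_, injection_site = NULL,
                              holding = 0) {
  mode <- match.arg(mode)
  durs <- vapply(steps, `[[`, 0, "duration")
  if (any(durs <= 0)) stop("step durations must be positive")
  structure(list(mode = mode, steps = steps,
                 inter_step_interval = inter_step_interval,
                 step_increment = step_increment,
                 injection_site = injection_site, holding = holding),
            class = "stimulus_protocol")
}
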