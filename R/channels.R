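# Hodgkin-Huxley-style channel kinetics library.
#
# A channel is a set of gates; each gate has a steady-state curve inf(v[,ca])
# and a time constant tau(v) (per-ms kinetics), plus an integer exponent.
# Channel current: i = gbar * prod(gate^exponent) * (v - erev).

# trap(x, q) = x / (1 - exp(-x/q)), the linear-exponential rate kernel,
# continuous at x = 0 where its limit is q.
trap <- function(x, q) ifelse(abs(x / q) < 1e-6, q * (1 + x / (2 * q)),
                              x / (1 - exp(-x / q)))

new_gate <- function(label, exponent, inf, tau, ca_dependent = FALSE) {
  stopifnot(exponent >= 1, exponent == round(exponent))
  list(label = label, exponent = as.integer(exponent), inf = inf, tau = tau,
       ca_dependent = ca_dependent)
}

new_channel <- function(name, ion, erev, gates, ca_source = FALSE,
                        params = list()) {
  structure(list(name = name, ion = ion, erev = erev, gates = gates,
                 ca_source = ca_source, v_half_shift = 0, params = params),
            class = "channel_kinetics")
}

#' @export
print.channel_kinetics <- function(x, ...) {
  cat(sprintf("<channel_kinetics> %s (ion %s, Erev %+.0f mV, %d gate%s%s%s)\n",
              x$name, x$ion, x$erev, length(x$gates),
              if (length(x$gates) > 1) "s" else "",
              if (x$v_half_shift != 0) sprintf(", V1/2 shift %+g mV", x$v_half_shift) else "",
              if (x$ca_source) ", Ca source" else ""))
  invisible(x)
}

q10_factor <- function(q10, source_temp, temperature)
  q10^((temperature - source_temp) / 10)

# --- kinetic forms ---------------------------------------------------------

form_trap_na <- function(p, tadj) {
  force(p); force(tadj)
  m_inf <- function(v) {
    v <- v + p$vshift
    a <- p$Ra * trap(v - p$tha, p$qa); b <- p$Rb * trap(-(v - p$tha), p$qa)
    a / (a + b)
  }
  m_tau <- function(v) {
    v <- v + p$vshift
    a <- p$Ra * trap(v - p$tha, p$qa); b <- p$Rb * trap(-(v - p$tha), p$qa)
    1 / ((a + b) * tadj)
  }
  h_inf <- function(v) {
    v <- v + p$vshift
    1 / (1 + exp((v - p$thinf) / p$qinf))
  }
  h_tau <- function(v) {
    v <- v + p$vshift
    a <- p$Rd * trap(v - p$thi1, p$qi); b <- p$Rg * trap(-(v - p$thi2), p$qi)
    1 / ((a + b) * tadj)
  }
  list(new_gate("m", 3, m_inf, m_tau), new_gate("h", 1, h_inf, h_tau))
}

form_trap_k <- function(p, tadj) {
  force(p); force(tadj)
  n_inf <- function(v) {
    a <- p$Ra * trap(v - p$tha, p$qa); b <- p$Rb * trap(-(v - p$tha), p$qa)
    a / (a + b)
  }
  n_tau <- function(v) {
    a <- p$Ra * trap(v - p$tha, p$qa); b <- p$Rb * trap(-(v - p$tha), p$qa)
    1 / ((a + b) * tadj)
  }
  list(new_gate("n", 1, n_inf, n_tau))
}

form_boltzmann_act <- function(p, tadj) {
  force(p); force(tadj)
  list(new_gate("m", 1,
                function(v) 1 / (1 + exp(-(v - p$vhalf) / p$k)),
                function(v) rep(p$tau_const / tadj, length(v))))
}

# Thermodynamic (Borg-Graham) A-type kinetics: voltage-dependent activation
# with a voltage-dependent effective valence, slow linear inactivation.
form_borg_graham_ka <- function(p, tadj, temperature) {
  force(p); force(tadj); force(temperature)
  FRT <- 96480 / (8.315 * (273.16 + temperature)) # 1/V, i.e. 1e-3 per mV
  zeta <- function(v) p$zetan + p$pw / (1 + exp((v - p$tq) / p$qq))
  alpn <- function(v) exp(1e-3 * zeta(v) * (v - p$vhalfn) * FRT)
  betn <- function(v) exp(1e-3 * zeta(v) * p$gmn * (v - p$vhalfn) * FRT)
  n_inf <- function(v) 1 / (1 + alpn(v))
  n_tau <- function(v) pmax(betn(v) / (tadj * p$a0n * (1 + alpn(v))), p$nmin / tadj)
  alpl <- function(v) exp(1e-3 * p$zetal * (v - p$vhalfl) * FRT)
  l_inf <- function(v) 1 / (1 + alpl(v))
  l_tau <- function(v) pmax(0.26 * (v + 50), p$lmin) # rate q10 applies to activation only
  list(new_gate("n", 1, n_inf, n_tau), new_gate("l", 1, l_inf, l_tau))
}

form_hva_ca <- function(p, tadj) {
  force(p); force(tadj)
  m_a <- function(v) 0.055 * trap(v + 27, 3.8)
  m_b <- function(v) 0.94 * exp((-75 - v) / 17)
  h_a <- function(v) 4.57e-4 * exp((-13 - v) / 50)
  h_b <- function(v) 0.0065 / (exp((-v - 15) / 28) + 1)
  list(new_gate("m", 2, function(v) m_a(v) / (m_a(v) + m_b(v)),
                function(v) 1 / ((m_a(v) + m_b(v)) * tadj)),
       new_gate("h", 1, function(v) h_a(v) / (h_a(v) + h_b(v)),
                function(v) 1 / ((h_a(v) + h_b(v)) * tadj)))
}

form_it2 <- function(p, tadj) {
  force(p); force(tadj)
  m_inf <- function(v) 1 / (1 + exp(-(v + 57) / 6.2))
  m_tau <- function(v) (0.612 + 1 / (exp(-(v + 132) / 16.7) + exp((v + 16.8) / 18.2))) / tadj
  h_inf <- function(v) 1 / (1 + exp((v + 81) / 4))
  h_tau <- function(v) ifelse(v < -80, exp((v + 467) / 66.6),
                              28 + exp(-(v + 22) / 10.5)) / tadj
  list(new_gate("m", 2, m_inf, m_tau), new_gate("h", 1, h_inf, h_tau))
}

form_hcn <- function(p, tadj) {
  force(p); force(tadj)
  list(new_gate("n", 1,
                function(v) 1 / (1 + exp((v - p$vhalf) / p$k)),
                function(v) (p$tau_min + p$tau_amp /
                               (exp((v - p$vpeak) / p$sigma) +
                                  exp(-(v - p$vpeak) / p$sigma))) / tadj))
}

# Joint voltage-calcium BK gating: the activation midpoint slides to more
# hyperpolarized voltages as [Ca]i rises (shift_per_decade mV per tenfold Ca).
form_bk <- function(p, tadj) {
  force(p); force(tadj)
  w_inf <- function(v, ca) {
    if (any(ca <= 0)) stop("BK gating requires calcium concentration > 0")
    vh <- p$vh_base - p$shift_per_decade * log10(ca / p$ca_ref)
    1 / (1 + exp(-(v - vh) / p$kw))
  }
  w_tau <- function(v) rep(p$tau_w / tadj, length(v))
  list(new_gate("w", 1, w_inf, w_tau, ca_dependent = TRUE))
}

# --- library ---------------------------------------------------------------

#' Load the channel kinetics library
#'
#' Builds every channel defined in the configuration file (by default the
#' shipped `channels.yaml`), with gating rates temperature-adjusted to
#' `temperature` via each channel's Q10.
#'
#' @param temperature simulation temperature, deg C
#' @param config path to a channel configuration YAML
#' @return named list of `channel_kinetics`, with the reversal potential map
#'   and calcium pool defaults attached as attributes
#' @export
channel_library <- function(temperature = 32, config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "channels.yaml", package = "l5sim")
  cfg <- yaml::read_yaml(config)
  erev_map <- cfg$reversal_potentials
  lib <- list()
  for (name in names(cfg$channels)) {
    ch <- cfg$channels[[name]]
    p <- ch$params
    tadj <- q10_factor(p$q10 %||% 1, p$source_temp %||% temperature, temperature)
    gates <- switch(ch$form,
      trap_na = form_trap_na(p, tadj),
      trap_k = form_trap_k(p, tadj),
      boltzmann_act = form_boltzmann_act(p, tadj),
      borg_graham_ka = form_borg_graham_ka(p, tadj, temperature),
      hva_ca = form_hva_ca(p, tadj),
      it2 = form_it2(p, tadj),
      hcn = form_hcn(p, tadj),
      bk = form_bk(p, tadj),
      stop("unknown kinetic form: ", ch$form))
    lib[[name]] <- new_channel(name, ch$ion, erev_map[[ch$ion]], gates,
                               ca_source = isTRUE(ch$ca_source), params = p)
  }
  attr(lib, "reversal_potentials") <- erev_map
  attr(lib, "calcium_pool") <- cfg$calcium_pool
  attr(lib, "temperature") <- temperature
  lib
}

# Evaluate a gate's steady state / time constant with the channel's V1/2
# shift applied to the voltage argument.
gate_inf <- function(channel, gate, v, ca = NULL) {
  veff <- v - channel$v_half_shift
  if (gate$ca_dependent) {
    if (is.null(ca)) stop(channel$name, ": calcium concentration required")
    gate$inf(veff, ca)
  } else gate$inf(veff)
}

gate_tau <- function(channel, gate, v) gate$tau(v - channel$v_half_shift)

#' First-order gate dynamics
#'
#' Returns the time-derivative `(inf - x) / tau` for every gate of a channel
#' at membrane potential `v` (mV) and, for calcium-dependent gates,
#' intracellular calcium `ca` (mM). The channel's half-activation shift is
#' applied to the voltage argument.
#'
#' @param channel a `channel_kinetics`
#' @param v membrane potential, mV
#' @param ca intracellular calcium, mM (required for BK)
#' @param state named numeric vector of gate values in `[0, 1]`
#' @return named numeric vector of derivatives, per ms
#' @export
gate_dynamics <- function(channel, v, ca = NULL, state) {
  labels <- vapply(channel$gates, `[[`, "", "label")
  if (is.null(names(state))) names(state) <- labels
  if (any(state < 0 | state > 1)) stop("gate state must lie in [0, 1]")
  out <- numeric(length(channel$gates))
  for (i in seq_along(channel$gates)) {
    g <- channel$gates[[i]]
    out[i] <- (gate_inf(channel, g, v, ca) - state[[g$label]]) /
      gate_tau(channel, g, v)
  }
  setNames(out, labels)
}

#' Steady-state open fraction of the BK channel
#'
#' The joint voltage-calcium activation surface: monotonically non-decreasing
#' in `v` at fixed `ca` and in `ca` at fixed `v`, bounded in `[0, 1]`.
#'
#' @param v membrane potential, mV
#' @param ca intracellular calcium concentration, mM (> 0)
#' @param library optional channel library to take the BK model from
#' @return open fraction in `[0, 1]`
#' @export
bk_open_fraction <- function(v, ca, library = NULL) {
  if (any(ca <= 0)) stop("calcium concentration must be > 0")
  lib <- library %||% channel_library()
  bk <- lib$K_BK
  gate_inf(bk, bk$gates[[1]], v, ca)
}

#' Shift a channel's half-activation voltage
#'
#' Returns a copy of the channel whose activation (and any other
#' voltage-dependent) curves equal the originals evaluated at `v - delta`;
#' shifts compose additively. A negative `delta` is a hyperpolarizing shift,
#' which for an activating gate increases the open fraction at any fixed
#' voltage.
#'
#' @param channel a `channel_kinetics`
#' @param delta shift in mV
#' @return shifted `channel_kinetics`
#' @export
shift_half_activation <- function(channel, delta) {
  has_vdep <- length(channel$gates) > 0
  if (!has_vdep) stop("channel has no voltage-dependent gate")
  channel$v_half_shift <- channel$v_half_shift + delta
  channel
}

#' Create a calcium pool
#'
#' Single sub-membrane shell with first-order decay back to the resting
#' concentration, driven by the magnitude of inward calcium current density.
#'
#' @param resting_concentration mM
#' @param decay_time_constant ms
#' @param influx_scale mM cm^2 / (ms mA)
#' @param concentration initial concentration, mM
#' @return object of class `calcium_pool`
#' @export
calcium_pool <- function(resting_concentration = 1e-4, decay_time_constant = 80,
                         influx_scale = 0.05,
                         concentration = resting_concentration) {
  stopifnot(resting_concentration >= 0, concentration >= resting_concentration,
            decay_time_constant > 0)
  structure(list(concentration = concentration,
                 resting_concentration = resting_concentration,
                 decay_time_constant = decay_time_constant,
                 influx_scale = influx_scale),
            class = "calcium_pool")
}

#' Advance a calcium pool by one time step
#'
#' `conc' = conc + dt * (influx_scale * |i_ca| - (conc - rest) / tau)`,
#' floored at the resting concentration.
#'
#' @param pool a `calcium_pool`
#' @param i_ca calcium current density, mA/cm^2 (inward; magnitude used)
#' @param dt time step, ms
#' @return updated `calcium_pool`
#' @export
update_calcium <- function(pool, i_ca, dt) {
  if (dt <= 0) stop("dt must be positive")
  conc <- pool$concentration +
    dt * (pool$influx_scale * abs(i_ca) -
            (pool$concentration - pool$resting_concentration) / pool$decay_time_constant)
  pool$concentration <- max(conc, pool$resting_concentration)
  pool
}

#' Split a total HCN density into HCN1 and HCN2 components
#'
#' The h-conductance is carried two-thirds by the HCN1 subtype and one-third
#' by the HCN2 subtype; the parts sum exactly to the input.
#'
#' @param total_density pS/um^2
#' @return named numeric vector `c(HCN1 = ..., HCN2 = ...)`
#' @export
hcn_split <- function(total_density) {
  if (any(total_density < 0)) stop("total density must be non-negative")
  h1 <- total_density * 2 / 3
  c(HCN1 = h1, HCN2 = total_density - h1)
}
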