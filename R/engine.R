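# Simulation engine: R-side assembly of the compartmental model and the
# current-/voltage-clamp protocols, with integration delegated to the
# compiled implicit cable solver.

V_GRID <- list(vmin = -120, dv = 0.05, nv = 3601) # mV
CA_GRID <- list(lcmin = -6, dlc = 0.05, nlc = 121) # log10([Ca] / mM)

# Convert the membrane model into the flat arrays the compiled solver takes.
# Conductance tables are rebuilt here so any half-activation shift or density
# scaling present on the model is honoured.
build_sim_arrays <- function(model, dt) {
  nodes <- model$tree$nodes
  n <- nrow(nodes)
  parent_idx <- match(nodes$parent_id, nodes$id) # NA for root
  if (any(!is.na(parent_idx) & parent_idx >= seq_len(n)))
    stop("tree must be ordered parent-before-child")
  area_cm2 <- nodes$area * 1e-8 # um^2 -> cm^2
  cm_nF <- nodes$cm * area_cm2 * 1e3 # uF -> nF
  g_leak <- area_cm2 * 1e3 / nodes$rm # 1/kOhm cm^2 -> uS
  # axial coupling: half-cylinder resistances in series, Ohm -> uS
  ax_res_half <- nodes$ra * (nodes$length * 1e-4 / 2) /
    (pi * (nodes$diam * 1e-4 / 2)^2)
  g_ax <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- parent_idx[i]
    g_ax[i] <- 1e6 / (ax_res_half[i] + ax_res_half[p])
  }

  vgrid_v <- V_GRID$vmin + V_GRID$dv * (seq_len(V_GRID$nv) - 1)
  ca_vals <- 10^(CA_GRID$lcmin + CA_GRID$dlc * (seq_len(CA_GRID$nlc) - 1))

  dens <- effective_densities(model)
  chans <- list()
  for (name in colnames(dens)) {
    gbar_all <- dens[, name] * nodes$area * 1e-6 # pS -> uS
    comp <- which(gbar_all > 0)
    if (!length(comp)) next
    kin <- model$kinetics[[name]]
    gates <- lapply(kin$gates, function(g) {
      if (g$ca_dependent) {
        inf <- outer(vgrid_v - kin$v_half_shift, ca_vals,
                     function(v, ca) g$inf(v, ca))
        list(exponent = g$exponent, ca_dep = TRUE, inf = as.numeric(inf),
             tau = gate_tau(kin, g, vgrid_v))
      } else {
        list(exponent = g$exponent, ca_dep = FALSE,
             inf = gate_inf(kin, g, vgrid_v),
             tau = gate_tau(kin, g, vgrid_v))
      }
    })
    chans[[name]] <- list(erev = kin$erev, ca_source = kin$ca_source,
                          comp = comp - 1L, gbar = gbar_all[comp], gates = gates)
  }
  capool <- model$calcium
  list(parent = ifelse(is.na(parent_idx), -1L, parent_idx - 1L),
       g_ax = g_ax, cm = cm_nF, g_leak = g_leak, e_leak = model$e_leak,
       channels = unname(chans),
       capool = list(rest = capool$resting_concentration,
                     tau = capool$decay_time_constant,
                     phi = capool$influx_scale,
                     eca = attr(model$kinetics, "reversal_potentials")$ca %||% 140,
                     area_cm2 = area_cm2))
}

soma_index <- function(model) which(is.na(model$tree$nodes$parent_id))

run_engine <- function(arrays, dt, stim_value, stim_mode = 0L, stim_comp = 1L,
                       state = NULL, record_comp = 1L, stride = 2L,
                       record_current = FALSE) {
  nsteps <- length(stim_value)
  init <- if (is.null(state)) {
    list(v = rep(-70, length(arrays$cm)), gates = NULL, ca = NULL)
  } else state
  .engine_run(arrays$parent, arrays$g_ax, arrays$cm, arrays$g_leak,
              arrays$e_leak, arrays$channels, V_GRID, CA_GRID, arrays$capool,
              dt, as.integer(nsteps),
              list(mode = as.integer(stim_mode), comp = as.integer(stim_comp) - 1L,
                   value = stim_value),
              init,
              list(comp = as.integer(record_comp) - 1L, stride = as.integer(stride),
                   current = record_current))
}

#' Relax the model to its resting steady state
#'
#' Integrates the model with zero injected current until the membrane settles
#' (2 s by default), starting from a uniform -70 mV with gates at their
#' steady state for that voltage. The returned state seeds subsequent
#' protocol runs; inter-step recovery in step families is modelled as this
#' full re-equilibration.
#'
#' @param model a `membrane_model`
#' @param dt integration step, ms
#' @param duration settling time, ms
#' @param v_init initial membrane potential, mV
#' @return list with `v`, `gates`, `ca` (solver state) and `v_rest` (somatic
#'   resting potential, mV)
#' @export
steady_state <- function(model, dt = 0.025, duration = 2000, v_init = -70) {
  arrays <- build_sim_arrays(model, dt)
  nsteps <- round(duration / dt)
  out <- run_engine(arrays, dt, numeric(nsteps),
                    state = list(v = rep(v_init, length(arrays$cm))),
                    record_comp = soma_index(model), stride = nsteps)
  list(v = out$v, gates = out$gates, ca = out$ca, v_rest = out$v[soma_index(model)],
       arrays = arrays, dt = dt)
}

# Internal single-step current-clamp run from a settled state.
simulate_step_trace <- function(model, amplitude, duration = 1000, pre = 100,
                                post = 300, dt = 0.025, state = NULL,
                                stride = 2L, arrays = NULL) {
  if (is.null(arrays)) arrays <- build_sim_arrays(model, dt)
  if (is.null(state)) state <- steady_state(model, dt = dt)
  soma <- soma_index(model)
  n_pre <- round(pre / dt); n_on <- round(duration / dt); n_post <- round(post / dt)
  stim <- c(numeric(n_pre), rep(amplitude / 1000, n_on), numeric(n_post)) # pA -> nA
  out <- run_engine(arrays, dt, stim, stim_comp = soma,
                    state = state[c("v", "gates", "ca")],
                    record_comp = soma, stride = stride)
  ephys_trace(out$rec[, 1], dt = dt * stride, amplitude = amplitude,
              mode = "current_clamp", t_on = pre, t_off = pre + duration,
              metadata = list(dt_solver = dt, v_rest = state$v_rest))
}

#' Integrate a stimulation protocol
#'
#' Runs the model through the steps of a [stimulus_protocol()] as one
#' continuous integration after a settle-to-steady-state period, recording
#' the somatic membrane potential (current clamp) or the clamp current
#' (voltage clamp).
#'
#' @param model a `membrane_model`
#' @param clamp a `stimulus_protocol`
#' @param dt integration step, ms (<= 0.025 recommended for production
#'   current-clamp runs)
#' @param duration optional total duration override, ms
#' @param settle settle time before the protocol, ms
#' @param stride recording stride (samples every `stride * dt` ms)
#' @return an `ephys_trace`
#' @export
integrate_model <- function(model, clamp, dt = 0.025, duration = NULL,
                            settle = 2000, stride = 2L) {
  arrays <- build_sim_arrays(model, dt)
  soma <- soma_index(model)
  site <- clamp$injection_site %||% soma
  vc <- clamp$mode == "voltage_clamp"
  amp_scale <- if (vc) 1 else 1e-3 # pA -> nA
  segs <- lapply(clamp$steps, function(s)
    rep(s$amplitude * amp_scale, round(s$duration / dt)))
  stim <- unlist(segs)
  if (!is.null(duration)) stim <- stim[seq_len(round(duration / dt))]
  state <- if (vc) {
    st <- steady_state(model, dt = dt)
    st$v[site] <- clamp$holding
    st
  } else steady_state(model, dt = dt)
  out <- run_engine(arrays, dt, stim, stim_mode = if (vc) 1L else 0L,
                    stim_comp = site, state = state[c("v", "gates", "ca")],
                    record_comp = soma, stride = stride,
                    record_current = vc)
  t_bounds <- cumsum(vapply(clamp$steps, `[[`, 0, "duration"))
  if (vc) {
    ephys_trace(out$i_rec * 1000, dt = dt * stride, # nA -> pA
                amplitude = clamp$steps[[1]]$amplitude, mode = "voltage_clamp",
                t_on = 0, t_off = t_bounds[length(t_bounds)],
                metadata = list(protocol = clamp, v_rest = state$v_rest))
  } else {
    ephys_trace(out$rec[, 1], dt = dt * stride, amplitude = clamp$steps[[1]]$amplitude,
                mode = "current_clamp", t_on = 0, t_off = t_bounds[length(t_bounds)],
                metadata = list(protocol = clamp, v_rest = state$v_rest))
  }
}

#' Run a family of rectangular current steps (F-I protocol)
#'
#' One-second somatic current injections at increasing amplitude, each run
#' from the fully re-equilibrated resting state (the inter-step interval of
#' the experimental protocol is modelled as complete recovery).
#'
#' @param model a `membrane_model`
#' @param max_amplitude largest step, pA
#' @param increment step increment, pA
#' @param duration step duration, ms
#' @param amplitudes optional explicit amplitude vector, pA (overrides
#'   max/increment)
#' @param dt integration step, ms
#' @param pre,post baseline before / recording after the step, ms
#' @param state optional pre-computed [steady_state()] result
#' @return a `trace_family`
#' @export
run_fi_protocol <- function(model, max_amplitude = 600, increment = 50,
                            duration = 1000, amplitudes = NULL, dt = 0.025,
                            pre = 100, post = 300, state = NULL) {
  if (is.null(amplitudes)) {
    if (increment <= 0) stop("increment must be positive")
    amplitudes <- seq(0, max_amplitude, by = increment)
  }
  arrays <- build_sim_arrays(model, dt)
  if (is.null(state)) state <- steady_state(model, dt = dt)
  traces <- lapply(amplitudes, function(a)
    simulate_step_trace(model, a, duration = duration, dt = dt, pre = pre,
                        post = post, state = state, arrays = arrays))
  trace_family(traces, protocol = list(type = "fi", increment = increment,
                                       duration = duration, dt = dt,
                                       v_rest = state$v_rest))
}

#' Current-clamp protocol for post-train after-hyperpolarization
#'
#' A single suprathreshold step with a long (>= 1 s) post-stimulus recording
#' window, for [ahp_amplitude()].
#'
#' @inheritParams run_fi_protocol
#' @param amplitude step amplitude, pA
#' @param post post-stimulus window, ms
#' @return an `ephys_trace`
#' @export
run_ahp_protocol <- function(model, amplitude = 350, duration = 1000,
                             post = 1500, dt = 0.025, state = NULL) {
  if (is.null(state)) state <- steady_state(model, dt = dt)
  simulate_step_trace(model, amplitude, duration = duration, pre = 100,
                      post = post, dt = dt, state = state)
}

#' Zero out channels (pharmacological mask)
#'
#' Returns a model in which the listed channels carry no conductance,
#' mirroring bath application of blockers.
#'
#' @param model a `membrane_model`
#' @param drop channel names to silence
#' @return modified `membrane_model`
#' @export
mask_channels <- function(model, drop) {
  unknown <- setdiff(drop, names(model$scale))
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  model$scale[drop] <- 0
  model
}

#' M-current deactivation (tail current) protocol
#'
#' Somatic ideal voltage clamp: hold, depolarize for `depol_duration`, then
#' step to the deactivating voltage. The tail amplitude is the instantaneous
#' current just after the deactivating step minus the steady-state current at
#' that voltage. Confounding conductances (sodium, calcium and h-current by
#' default, mirroring their pharmacological block) are masked.
#'
#' @param model a `membrane_model`
#' @param depol depolarized command, mV
#' @param depol_duration ms
#' @param deactivation deactivating command, mV
#' @param holding holding potential, mV
#' @param tail_duration recording window after the deactivating step, ms
#' @param mask channels silenced during the measurement (NULL for none)
#' @param dt integration step, ms
#' @param blank time skipped after the step before reading the
#'   "instantaneous" current (clamp transient), ms
#' @return list with `tail_trace` (an `ephys_trace` of the tail window, pA)
#'   and `tail_amplitude` (pA)
#' @export
run_im_tail_protocol <- function(model, depol = -30, depol_duration = 30000,
                                 deactivation = -50, holding = -50,
                                 tail_duration = 2000,
                                 mask = c("Na", "Na_x", "Na_P", "Ca_HVA",
                                          "Ca_IT2", "HCN1", "HCN2"),
                                 dt = 0.1, blank = 1) {
  mask <- intersect(mask, names(model$scale))
  if (length(mask)) model <- mask_channels(model, mask)
  proto <- stimulus_protocol("voltage_clamp", steps = list(
    list(amplitude = holding, duration = 1000),
    list(amplitude = depol, duration = depol_duration),
    list(amplitude = deactivation, duration = tail_duration)),
    holding = holding)
  trace <- integrate_model(model, proto, dt = dt, settle = 1000, stride = 1L)
  # leak subtraction: the same command sequence on the passive cell removes
  # capacitive/axial clamp transients from the unclamped neighbourhood
  passive <- mask_channels(model, names(model$scale))
  base <- integrate_model(passive, proto, dt = dt, settle = 1000, stride = 1L)
  trace$values <- trace$values - base$values
  t <- trace_time(trace)
  t_step <- 1000 + depol_duration
  tail_idx <- t > t_step + blank
  tail_vals <- trace$values[tail_idx]
  i_instant <- tail_vals[1]
  i_steady <- mean(tail_vals[seq(from = round(0.9 * length(tail_vals)),
                                 to = length(tail_vals))])
  tail_trace <- ephys_trace(tail_vals, dt = trace$dt, amplitude = deactivation,
                            mode = "voltage_clamp", t_on = 0,
                            t_off = tail_duration - blank,
                            metadata = list(depol = depol, holding = holding))
  list(tail_trace = tail_trace, tail_amplitude = i_instant - i_steady)
}

#' Analytic input resistance of the passive tree
#'
#' Steady-state cable solution: solves the passive conductance system
#' `G v = i` for a unit somatic current injection and returns the somatic
#' voltage deflection per current, independent of the time-stepping engine.
#'
#' @param tree a `compartment_tree` with passive properties
#' @return input resistance at the soma, MOhm
#' @export
passive_input_resistance <- function(tree) {
  nodes <- tree$nodes
  if (is.null(nodes$rm)) stop("tree needs passive properties")
  n <- nrow(nodes)
  parent_idx <- match(nodes$parent_id, nodes$id)
  area_cm2 <- nodes$area * 1e-8
  g_leak <- area_cm2 * 1e3 / nodes$rm # uS
  ax_res_half <- nodes$ra * (nodes$length * 1e-4 / 2) /
    (pi * (nodes$diam * 1e-4 / 2)^2)
  G <- diag(g_leak, n)
  for (i in seq_len(n)[-1]) {
    p <- parent_idx[i]
    g <- 1e6 / (ax_res_half[i] + ax_res_half[p])
    G[i, i] <- G[i, i] + g
    G[p, p] <- G[p, p] + g
    G[i, p] <- G[i, p] - g
    G[p, i] <- G[p, i] - g
  }
  soma <- which(is.na(nodes$parent_id))
  i_vec <- numeric(n)
  i_vec[soma] <- 1 # nA
  v <- solve(G, i_vec)
  v[soma] # mV per nA = MOhm
}
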