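# Synthetic paired "ex vivo" cohorts and analytic trace fixtures: stand-ins
# with the statistical structure the paired comparisons assume, so the
# feature-extraction and statistics stages are fully testable without
# recordings.

#' Specify a synthetic paired cohort
#'
#' Per-feature control means/SEMs and multiplicative treatment effects, with
#' between-cell dispersion and per-measurement noise. By default the group
#' variance implied by the SEM is split 90/10 into between-cell (biological)
#' and measurement components.
#'
#' @param features named list; each entry a list with `mean`, `sem` and
#'   either `effect` (multiplicative) or `treatment_mean`
#' @param n_cells number of paired cells (>= 3)
#' @param sem_n number of cells at which the stated SEMs were measured
#'   (defaults to `n_cells`); lets a preset cohort be scaled up without
#'   inflating the per-cell dispersion
#' @param dispersion_cv optional named coefficient-of-variation override for
#'   the between-cell spread (default: derived from the SEM)
#' @param noise_sd optional named measurement-noise override per feature
#' @param age_range postnatal-day range, inclusive
#' @param age_effect relative effect change per day of age (0 = no age
#'   dependence)
#' @param biological_share share of the SEM-implied variance attributed to
#'   between-cell dispersion
#' @param seed RNG seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(features, n_cells, sem_n = NULL, dispersion_cv = NULL,
                        noise_sd = NULL, age_range = c(11, 27),
                        age_effect = 0, biological_share = 0.9, seed = 1) {
  sem_n <- sem_n %||% n_cells
  if (n_cells < 3) stop("n_cells must be at least 3")
  spec_feats <- list()
  for (f in names(features)) {
    ft <- features[[f]]
    if (is.null(ft$mean) || ft$mean <= 0) stop("feature means must be positive: ", f)
    effect <- ft$effect %||% (ft$treatment_mean / ft$mean)
    sd_total <- ft$sem * sqrt(sem_n)
    cv <- dispersion_cv[[f]] %||% (sd_total * sqrt(biological_share) / ft$mean)
    nsd <- noise_sd[[f]] %||% (sd_total * sqrt(1 - biological_share))
    # SEM consistency: the implied dispersion/noise must reproduce the SEM
    implied_sem <- sqrt((cv * ft$mean)^2 + nsd^2) / sqrt(sem_n)
    if (abs(implied_sem - ft$sem) > 0.25 * ft$sem)
      warning("dispersion/noise inconsistent with stated SEM for ", f)
    spec_feats[[f]] <- list(mean = ft$mean, sem = ft$sem, effect = effect,
                            cv = cv, noise_sd = nsd)
  }
  structure(list(features = spec_feats, n_cells = n_cells,
                 age_range = age_range, age_effect = age_effect, seed = seed),
            class = "cohort_spec")
}

#' Load a shipped cohort preset
#'
#' Presets encode the paired group comparisons of the study (PKC activators,
#' IFN-beta, and the PKC-block controls) as generator specifications.
#'
#' @param name preset name (e.g. "pma", "bryostatin", "ifn", "gf_ifn",
#'   "calphostin_ifn")
#' @param n_cells optional override of the cohort size
#' @param age_scenario optional named age-dependence scenario from the preset
#'   file
#' @param seed RNG seed
#' @return a `cohort_spec`
#' @export
cohort_preset <- function(name, n_cells = NULL, age_scenario = NULL, seed = 1) {
  cfg <- yaml::read_yaml(system.file("extdata", "cohort_presets.yaml",
                                     package = "l5sim"))
  if (!name %in% names(cfg$presets)) stop("unknown preset: ", name)
  p <- cfg$presets[[name]]
  age_effect <- 0
  if (!is.null(age_scenario)) {
    sc <- cfg$age_scenarios[[age_scenario]]
    if (is.null(sc)) stop("unknown age scenario: ", age_scenario)
    age_effect <- sc$age_effect
  }
  cohort_spec(p$features, n_cells = n_cells %||% p$n_cells, sem_n = p$n_cells,
              age_range = unlist(cfg$age_range),
              age_effect = age_effect,
              biological_share = cfg$variance_split_biological, seed = seed)
}

#' Generate a synthetic paired cohort
#'
#' Per cell, baseline features are drawn log-normally around the control
#' means with the spec's between-cell dispersion; treatment values are the
#' baseline times the multiplicative effect (optionally age-modulated), and
#' both arms receive independent Gaussian measurement noise. Fully
#' reproducible from the spec seed.
#'
#' @param spec a `cohort_spec`
#' @return object of class `paired_cohort` with `age`, `control` and
#'   `treatment` data frames (one row per cell, pairing preserved)
#' @export
generate_paired_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_cells
  ages <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  mean_age <- mean(spec$age_range)
  ctrl <- data.frame(cell = seq_len(n), age = ages)
  trt <- data.frame(cell = seq_len(n), age = ages)
  for (f in names(spec$features)) {
    ft <- spec$features[[f]]
    # feasibility: P(value < 0) under the log-normal-plus-noise model,
    # averaged over baseline quantiles (the baseline itself is positive)
    sdlog <- sqrt(log(1 + ft$cv^2))
    meanlog <- log(ft$mean) - sdlog^2 / 2
    qs <- stats::qlnorm(stats::ppoints(199), meanlog, sdlog)
    worst_effect <- min(1, ft$effect *
                          (1 + spec$age_effect * (spec$age_range - mean_age)))
    p_neg <- mean(stats::pnorm(0, qs * worst_effect, ft$noise_sd))
    if (p_neg > 0.01)
      stop("spec rejected: feature ", f,
           " would go negative at > 1% rate (P = ", signif(p_neg, 2), ")")
    base <- stats::rlnorm(n, meanlog = log(ft$mean) - sdlog^2 / 2, sdlog = sdlog)
    eff <- ft$effect * (1 + spec$age_effect * (ages - mean_age))
    draw_noise <- function(values) {
      out <- values + stats::rnorm(n, 0, ft$noise_sd)
      for (k in 1:100) {
        neg <- out <= 0
        if (!any(neg)) break
        out[neg] <- values[neg] + stats::rnorm(sum(neg), 0, ft$noise_sd)
      }
      out
    }
    ctrl[[f]] <- draw_noise(base)
    trt[[f]] <- draw_noise(base * eff)
  }
  structure(list(control = ctrl, treatment = trt, spec = spec),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d cells, features: %s\n",
              nrow(x$control),
              paste(setdiff(names(x$control), c("cell", "age")), collapse = ", ")))
  invisible(x)
}

#' Write a cohort as a per-cell table
#'
#' Long format: cell, age, arm, one column per feature.
#'
#' @param cohort a `paired_cohort`
#' @param path output file
#' @export
write_cohort_table <- function(cohort, path) {
  ctrl <- cbind(arm = "control", cohort$control)
  trt <- cbind(arm = "treatment", cohort$treatment)
  write.table(rbind(ctrl, trt), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#'
#' @param path input file
#' @return a `paired_cohort`
#' @export
read_cohort_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  ctrl <- df[df$arm == "control", setdiff(names(df), "arm")]
  trt <- df[df$arm == "treatment", setdiff(names(df), "arm")]
  ctrl <- ctrl[order(ctrl$cell), ]; rownames(ctrl) <- NULL
  trt <- trt[order(trt$cell), ]; rownames(trt) <- NULL
  structure(list(control = ctrl, treatment = trt, spec = NULL),
            class = "paired_cohort")
}

# Stereotyped action-potential waveform added on top of the subthreshold
# response: smooth upstroke to a fixed overshoot, downstroke below baseline,
# recovery; total footprint ~3 ms.
ap_waveform <- function(t_rel, base) {
  up <- 38 - base
  w <- numeric(length(t_rel))
  inside <- t_rel >= 0 & t_rel <= 3
  x <- t_rel[inside]
  w[inside] <- up * exp(-((x - 0.7) / 0.28)^2) - 12 * exp(-((x - 1.7) / 0.5)^2)
  w
}

#' Generate an analytic current-clamp trace family with known features
#'
#' Piecewise-analytic membrane responses: RC subthreshold charging with the
#' target input resistance and membrane time constant, stereotyped spikes at
#' the rate implied by the target F-I line (evenly spaced within the step),
#' a post-train undershoot of the target AHP depth, and optional Gaussian
#' noise. Running the feature extractor on the output recovers the targets
#' (exactly for zero noise, within documented tolerances otherwise).
#'
#' @param targets list with `rheobase` (pA), `fi_slope` (Hz/nA),
#'   `input_resistance` (MOhm, default 100), `ahp` (mV, default 5),
#'   `v_rest` (default -70 mV), `tau_m` (default 20 ms)
#' @param noise_sd Gaussian noise, mV
#' @param seed RNG seed
#' @param amplitudes step amplitudes, pA
#' @param duration step duration, ms
#' @param post post-stimulus window, ms
#' @param dt sampling interval, ms
#' @return a `trace_family`
#' @export
generate_trace_fixture <- function(targets, noise_sd = 0, seed = 1,
                                   amplitudes = seq(-50, 400, by = 25),
                                   duration = 1000, post = 1500, dt = 0.05) {
  set.seed(seed)
  rheo <- targets$rheobase
  slope <- targets$fi_slope
  rin <- targets$input_resistance %||% 100
  ahp <- targets$ahp %||% 5
  v0 <- targets$v_rest %||% -70
  tau <- targets$tau_m %||% 20
  if (rheo >= max(amplitudes))
    stop("target rheobase outside the amplitude grid")
  pre <- 100
  t <- seq(dt, pre + duration + post, by = dt)
  traces <- lapply(amplitudes, function(amp) {
    v <- rep(v0, length(t))
    on <- t > pre & t <= pre + duration
    post_idx <- t > pre + duration
    # subthreshold RC response; suprathreshold steps ride on a depolarized
    # plateau clipped near threshold
    vss_amp <- min(amp, rheo) * rin / 1000 # mV deflection, clipped
    v[on] <- v0 + vss_amp * (1 - exp(-(t[on] - pre) / tau))
    n_spk <- 0
    if (amp > rheo) {
      rate <- slope * (amp - rheo) / 1000 # Hz
      n_spk <- round(rate * duration / 1000)
    }
    if (n_spk > 0) {
      spk_times <- pre + (seq_len(n_spk) - 0.5) / n_spk * duration
      base <- v0 + vss_amp
      for (ts in spk_times) v <- v + ap_waveform(t - ts, base)
    }
    # post-stimulus relaxation; undershoot only after spike trains
    v_off <- v0 + vss_amp * (1 - exp(-duration / tau))
    v[post_idx] <- v0 + (v_off - v0) * exp(-(t[post_idx] - pre - duration) / tau)
    if (n_spk > 0 && ahp > 0) {
      x <- (t[post_idx] - pre - duration) / 100
      v[post_idx] <- v[post_idx] - ahp * x * exp(1 - x)
    }
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    ephys_trace(v, dt = dt, amplitude = amp, mode = "current_clamp",
                t_on = pre, t_off = pre + duration,
                metadata = list(synthetic = TRUE, targets = targets))
  })
  trace_family(traces, protocol = list(type = "synthetic_fi", duration = duration,
                                       noise_sd = noise_sd, seed = seed))
}
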