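# In-silico modulation experiments: apply channel modulation sets, screen
# single-channel density changes, and run the 2^4 subset-necessity analysis
# of the PKC-linked modulations.

#' Define a channel modulation set
#'
#' Per-channel conductance scale factors and half-activation shifts,
#' representing a pharmacological or kinase-mediated modulation.
#'
#' @param scale_factors named numeric vector of density factors (> 0)
#' @param v_half_shifts named numeric vector of V1/2 shifts, mV
#' @param label description
#' @return object of class `modulation_set`
#' @export
modulation_set <- function(scale_factors = numeric(0),
                           v_half_shifts = numeric(0), label = "") {
  if (any(scale_factors <= 0)) stop("scale factors must be positive")
  structure(list(scale_factors = scale_factors, v_half_shifts = v_half_shifts,
                 label = label), class = "modulation_set")
}

#' @export
print.modulation_set <- function(x, ...) {
  parts <- c(sprintf("%s x%g", names(x$scale_factors), x$scale_factors),
             sprintf("%s V1/2 %+g mV", names(x$v_half_shifts), x$v_half_shifts))
  cat("<modulation_set>", if (nzchar(x$label)) paste0(x$label, ":") else "",
      if (length(parts)) paste(parts, collapse = ", ") else "identity", "\n")
  invisible(x)
}

#' The four PKC-linked channel modulations
#'
#' HCN1 conductance to 42.5%, M-type potassium conductance to 76%, BK
#' conductance to 50%, and a -2 mV shift of the persistent sodium
#' half-activation.
#'
#' @param components subset of `c("HCN1", "K_M", "K_BK", "Na_P")` to include
#' @return a `modulation_set`
#' @export
pkc_modulation_set <- function(components = c("HCN1", "K_M", "K_BK", "Na_P")) {
  scales <- c(HCN1 = 0.425, K_M = 0.76, K_BK = 0.50)
  shifts <- c(Na_P = -2)
  modulation_set(scale_factors = scales[intersect(components, names(scales))],
                 v_half_shifts = shifts[intersect(components, names(shifts))],
                 label = paste(components, collapse = "+"))
}

#' Apply a modulation set to a membrane model
#'
#' Density factors multiply the channel's conductance everywhere it is
#' expressed (an HCN1 factor touches only the HCN1 share of the HCN split);
#' V1/2 shifts are applied to the channel kinetics. The input model is not
#' modified; factors compose multiplicatively and shifts additively.
#'
#' @param model a `membrane_model`
#' @param mset a `modulation_set`
#' @return modulated `membrane_model`
#' @export
apply_modulation <- function(model, mset) {
  all_named <- c(names(mset$scale_factors), names(mset$v_half_shifts))
  unknown <- setdiff(all_named, names(model$kinetics))
  if (length(unknown)) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  for (ch in names(mset$scale_factors))
    model$scale[[ch]] <- model$scale[[ch]] * mset$scale_factors[[ch]]
  for (ch in names(mset$v_half_shifts))
    model$kinetics[[ch]] <- shift_half_activation(model$kinetics[[ch]],
                                                  mset$v_half_shifts[[ch]])
  model
}

model_fi_features <- function(model, amplitudes, duration = 1000, dt = 0.025,
                              post = 300) {
  fam <- run_fi_protocol(model, amplitudes = amplitudes, duration = duration,
                         dt = dt, post = post)
  fi_features(fam)
}

#' Screen single-channel modulations
#'
#' Runs the F-I protocol for every (channel, factor) pair, extracts rheobase
#' and F-I slope, and tabulates ratios against the unmodulated control row
#' (always present, labelled "control").
#'
#' @param model a `membrane_model` (the calibrated control)
#' @param channels channel names to screen (default: all expressed channels)
#' @param factors density factors to test
#' @param amplitudes F-I amplitudes, pA
#' @param dt integration step, ms
#' @return data.frame of class `screen_result`
#' @export
screen_single_modulations <- function(model, channels = NULL,
                                      factors = c(0.5, 0.75, 1.25, 1.5),
                                      amplitudes = seq(0, 600, by = 50),
                                      dt = 0.025) {
  channels <- channels %||% colnames(model$densities)
  rows <- list()
  ctrl <- model_fi_features(model, amplitudes, dt = dt)
  rows[[1]] <- data.frame(label = "control", channel = NA, factor = 1,
                          rheobase = ctrl$rheobase, fi_slope = ctrl$fi_slope)
  for (ch in channels) for (f in factors) {
    m <- apply_modulation(model, modulation_set(setNames(f, ch)))
    feats <- tryCatch(model_fi_features(m, amplitudes, dt = dt),
                      error = function(e) list(rheobase = NA, fi_slope = NA))
    rows[[length(rows) + 1]] <- data.frame(
      label = sprintf("%s x%g", ch, f), channel = ch, factor = f,
      rheobase = feats$rheobase, fi_slope = feats$fi_slope)
  }
  out <- do.call(rbind, rows)
  out$rheobase_ratio <- out$rheobase / ctrl$rheobase
  out$slope_ratio <- out$fi_slope / ctrl$fi_slope
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Subset-necessity analysis of the PKC modulations
#'
#' Evaluates all 16 subsets of the four PKC-linked modulations. A subset
#' fails the joint criterion when it achieves less than `necessity_fraction`
#' of the full set's F-I slope increase or of its rheobase decrease.
#'
#' @param model calibrated control `membrane_model`
#' @param amplitudes F-I amplitudes, pA
#' @param dt integration step, ms
#' @param necessity_fraction fraction of the full effect a subset must reach
#' @return data.frame of class `screen_result` with one row per subset,
#'   including `meets_joint_criterion`
#' @export
pkc_subset_analysis <- function(model, amplitudes = seq(0, 600, by = 50),
                                dt = 0.025, necessity_fraction = 0.8) {
  comps <- c("HCN1", "K_M", "K_BK", "Na_P")
  subsets <- unlist(lapply(0:4, function(k)
    combn(comps, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(s) {
    m <- if (length(s)) apply_modulation(model, pkc_modulation_set(s)) else model
    feats <- model_fi_features(m, amplitudes, dt = dt)
    data.frame(label = if (length(s)) paste(s, collapse = "+") else "control",
               n_components = length(s),
               rheobase = feats$rheobase, fi_slope = feats$fi_slope)
  })
  out <- do.call(rbind, rows)
  ctrl <- out[out$label == "control", ]
  out$rheobase_ratio <- out$rheobase / ctrl$rheobase
  out$slope_ratio <- out$fi_slope / ctrl$fi_slope
  full <- out[out$n_components == 4, ]
  slope_gain_full <- full$slope_ratio - 1
  rheo_drop_full <- 1 - full$rheobase_ratio
  out$meets_joint_criterion <-
    (out$slope_ratio - 1) >= necessity_fraction * slope_gain_full &
    (1 - out$rheobase_ratio) >= necessity_fraction * rheo_drop_full
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Joint effect size of a screen row
#'
#' Scalar summary combining the gain increase and rheobase reduction:
#' `(slope_ratio - 1) + (1 - rheobase_ratio)`.
#'
#' @param screen a `screen_result`
#' @return numeric vector aligned with the screen rows
#' @export
joint_effect_size <- function(screen) {
  (screen$slope_ratio - 1) + (1 - screen$rheobase_ratio)
}

#' Check invariance of the spike voltage threshold under modulation
#'
#' Extracts the AP voltage threshold of the first spike at the first
#' suprathreshold amplitude for the control and the modulated model.
#'
#' @param model control `membrane_model`
#' @param mset a `modulation_set`
#' @param amplitudes candidate amplitudes, pA
#' @param dt integration step, ms
#' @return list with `control_threshold` and `modulated_threshold`, mV
#' @export
threshold_invariance_check <- function(model, mset,
                                       amplitudes = seq(0, 600, by = 50),
                                       dt = 0.025) {
  thr_of <- function(m) {
    fam <- run_fi_protocol(m, amplitudes = amplitudes, dt = dt, post = 100)
    counts <- spike_counts(fam)
    first <- which(counts$count > 0)[1]
    if (is.na(first)) stop("model does not fire within the tested amplitudes")
    ap_voltage_threshold(fam$traces[[first]])
  }
  list(control_threshold = thr_of(model),
       modulated_threshold = thr_of(apply_modulation(model, mset)))
}

#' Build the calibrated control layer 5 model
#'
#' Assembles the full control model: stylized morphology, passive properties
#' with spine correction, the shipped density rules (including the
#' calibration factors) and the channel library.
#'
#' @param temperature deg C
#' @param max_segment spatial discretization limit, um
#' @return a `membrane_model`
#' @export
build_l5_model <- function(temperature = 32, max_segment = 20) {
  tree <- make_reference_morphology(max_segment = max_segment)
  tree <- assign_passive(tree)
  tree <- apply_spine_correction(tree)
  build_membrane_model(tree, rules = default_density_rules(),
                       kinetics = channel_library(temperature = temperature))
}
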