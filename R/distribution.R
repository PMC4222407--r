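# Spatial conductance-density rules: map channels to density profiles per
# region and assemble the simulation-ready membrane model.

PROFILES <- c("uniform", "linear", "exponential", "linear_exchange")

#' Create a density rule
#'
#' @param channel channel identifier (K_A and HCN are composite: K_A is split
#'   into proximal/distal A-type variants, HCN into HCN1/HCN2)
#' @param region one of soma/axon/apical/basal
#' @param profile one of uniform, linear, exponential, linear_exchange
#' @param start density at the region origin, pS/um^2
#' @param end density at the region's maximal path distance (linear profiles);
#'   alternatively `end_factor` scales `start`
#' @param end_factor multiplicative endpoint factor (alternative to `end`)
#' @param length_constant e-fold distance for exponential profiles, um
#' @param direction "growth" or "decay" for exponential profiles
#' @param cap_factor density cap (multiple of `start`) for exponential growth
#' @param span exchange span for `linear_exchange`, um
#' @param min_distance,max_distance extent limits, um (density is 0 outside)
#' @return object of class `density_rule`
#' @export
density_rule <- function(channel, region, profile, start, end = NULL,
                         end_factor = NULL, length_constant = NULL,
                         direction = "decay", cap_factor = NULL, span = 300,
                         min_distance = 0, max_distance = Inf) {
  stopifnot(profile %in% PROFILES, start >= 0, region %in% REGIONS)
  if (profile == "exponential" && (is.null(length_constant) || length_constant <= 0))
    stop("exponential profile needs a positive length constant")
  if (!is.null(cap_factor) && cap_factor < 1) stop("cap_factor must be >= 1")
  if (is.null(end)) end <- if (!is.null(end_factor)) start * end_factor else start
  structure(list(channel = channel, region = region, profile = profile,
                 start = start, end = end, length_constant = length_constant,
                 direction = direction, cap_factor = cap_factor, span = span,
                 min_distance = min_distance,
                 max_distance = if (is.null(max_distance)) Inf else max_distance),
            class = "density_rule")
}

#' Load the shipped density-rule set
#'
#' @param config path to a YAML rule file (defaults to the shipped table)
#' @return list with `rules` (list of `density_rule`) and `calibration`
#'   (named per-channel scale factors)
#' @export
default_density_rules <- function(config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "density_rules.yaml", package = "l5sim")
  cfg <- yaml::read_yaml(config)
  rules <- lapply(cfg$rules, function(r) do.call(density_rule, r))
  calibration <- unlist(cfg$calibration %||% list())
  list(rules = rules, calibration = calibration)
}

#' Evaluate a density rule at a path distance
#'
#' Uniform profiles return the start density; linear profiles interpolate
#' from the start at the region origin to the endpoint at `region_max`;
#' exponential profiles grow (capped at `cap_factor * start`) or decay with
#' the rule's length constant. Outside a stated extent the density is 0.
#' `linear_exchange` returns the total A-type density (the proximal/distal
#' split is applied by [ka_exchange_fraction()] at assembly).
#'
#' @param rule a `density_rule`
#' @param path_distance um from the soma centre (vectorized)
#' @param region_max maximal path distance of the rule's region, um (needed
#'   for linear profiles)
#' @return density in pS/um^2
#' @export
density_at <- function(rule, path_distance, region_max = NULL) {
  d <- path_distance
  dens <- switch(rule$profile,
    uniform = rep(rule$start, length(d)),
    linear = ,
    linear_exchange = {
      if (rule$start == rule$end) rep(rule$start, length(d))
      else {
        if (is.null(region_max) || !is.finite(region_max))
          stop("linear profile needs region_max")
        rule$start + (rule$end - rule$start) * pmin(d / region_max, 1)
      }
    },
    exponential = {
      if (rule$direction == "growth") {
        cap <- if (is.null(rule$cap_factor)) Inf else rule$cap_factor * rule$start
        pmin(rule$start * exp(d / rule$length_constant), cap)
      } else {
        rule$start * exp(-d / rule$length_constant)
      }
    })
  dens[d < rule$min_distance | d > rule$max_distance] <- 0
  dens
}

#' Proximal-to-distal A-type channel exchange
#'
#' Fraction of the distal A-type variant at a given path distance: the
#' exchange is linear over the first `span` micrometres of the dendrites and
#' complete beyond it.
#'
#' @param path_distance um (vectorized)
#' @param span exchange span, um
#' @return fraction of the distal variant in `[0, 1]`
#' @export
ka_exchange_fraction <- function(path_distance, span = 300) {
  pmin(pmax(path_distance / span, 0), 1)
}

#' Assemble the simulation-ready membrane model
#'
#' Resolves every density rule on every compartment (applying the spine
#' factor), splits composite channels (A-type proximal/distal exchange, HCN1/
#' HCN2 2/3:1/3), applies the calibration scale factors, and validates that
#' each region expresses at least one sodium and one potassium conductance.
#'
#' @param tree a `compartment_tree` with passive properties (and normally the
#'   spine correction) applied
#' @param rules list as returned by [default_density_rules()], or a bare list
#'   of `density_rule` objects
#' @param kinetics a channel library from [channel_library()]
#' @param e_leak leak reversal potential, mV
#' @return object of class `membrane_model`
#' @export
build_membrane_model <- function(tree, rules = default_density_rules(),
                                 kinetics = channel_library(), e_leak = -72) {
  if (is.null(tree$nodes$rm))
    stop("tree needs passive properties (assign_passive) before model assembly")
  if (is.null(rules$rules)) rules <- list(rules = rules, calibration = NULL)
  rule_list <- rules$rules
  if (!length(rule_list)) stop("empty rule list")
  calibration <- rules$calibration
  nodes <- tree$nodes
  ncomp <- nrow(nodes)
  region_max <- vapply(REGIONS, function(r) {
    d <- nodes$path_distance[nodes$region == r]
    if (length(d)) max(d) else 0
  }, 0)

  known <- c(names(kinetics), "K_A", "HCN")
  for (r in rule_list)
    if (!r$channel %in% known) stop("rule references unknown channel: ", r$channel)

  dens <- matrix(0, ncomp, 0)
  add_density <- function(dens, name, values) {
    if (!name %in% colnames(dens))
      dens <- cbind(dens, matrix(0, ncomp, 1, dimnames = list(NULL, name)))
    dens[, name] <- dens[, name] + values
    dens
  }
  for (r in rule_list) {
    in_region <- nodes$region == r$region
    if (!any(in_region)) next
    d <- nodes$path_distance
    base <- density_at(r, d, region_max = region_max[[r$region]])
    base[!in_region] <- 0
    base <- base * nodes$spine_factor
    if (r$channel == "K_A") {
      frac <- ka_exchange_fraction(d, span = r$span)
      if (r$region == "soma") frac <- 0
      dens <- add_density(dens, "K_AD", base * frac)
      dens <- add_density(dens, "K_AP", base * (1 - frac))
    } else if (r$channel == "HCN") {
      split <- hcn_split(base)
      dens <- add_density(dens, "HCN1", split[seq_len(ncomp)])
      dens <- add_density(dens, "HCN2", split[ncomp + seq_len(ncomp)])
    } else {
      dens <- add_density(dens, r$channel, base)
    }
  }
  for (ch in intersect(names(calibration), colnames(dens)))
    dens[, ch] <- dens[, ch] * calibration[[ch]]

  ions <- vapply(kinetics, `[[`, "", "ion")
  for (reg in unique(nodes$region)) {
    rows <- nodes$region == reg
    expressed <- colnames(dens)[colSums(dens[rows, , drop = FALSE]) > 0]
    if (!length(expressed)) {
      warning("region with no channels: ", reg)
      next
    }
    if (!any(ions[expressed] == "na") || !any(ions[expressed] == "k"))
      stop("region ", reg, " must express at least one Na and one K conductance")
  }

  structure(list(
    tree = tree,
    densities = dens, # pS/um^2, spine-corrected and calibrated
    kinetics = kinetics[colnames(dens)],
    scale = setNames(rep(1, ncol(dens)), colnames(dens)),
    e_leak = e_leak,
    calcium = attr(kinetics, "calcium_pool"),
    temperature = attr(kinetics, "temperature")
  ), class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat("<membrane_model> ", nrow(x$tree$nodes), " compartments, ",
      ncol(x$densities), " channels\n", sep = "")
  mod <- x$scale[x$scale != 1]
  shifts <- vapply(x$kinetics, `[[`, 0, "v_half_shift")
  shifts <- shifts[shifts != 0]
  if (length(mod))
    cat("  density scaling:", paste(sprintf("%s x%.3g", names(mod), mod), collapse = ", "), "\n")
  if (length(shifts))
    cat("  V1/2 shifts:", paste(sprintf("%s %+g mV", names(shifts), shifts), collapse = ", "), "\n")
  invisible(x)
}

#' Per-compartment effective channel densities
#'
#' The assembled densities with any modulation scale factors applied.
#'
#' @param model a `membrane_model`
#' @return matrix, compartments x channels, pS/um^2
#' @export
effective_densities <- function(model) {
  sweep(model$densities, 2, model$scale[colnames(model$densities)], `*`)
}

#' Report resolved densities at sampled distances
#'
#' Tabulates the effective density of every channel at a set of path
#' distances per region - a validation view of the density rules.
#'
#' @param model a `membrane_model`
#' @param distances path distances to sample, um
#' @return data.frame with region, path_distance and one column per channel
#' @export
density_report <- function(model, distances = c(0, 50, 100, 200, 400, 800)) {
  nodes <- model$tree$nodes
  dens <- effective_densities(model)
  out <- NULL
  for (reg in unique(nodes$region)) {
    rows <- which(nodes$region == reg)
    for (d in distances) {
      i <- rows[which.min(abs(nodes$path_distance[rows] - d))]
      if (abs(nodes$path_distance[i] - d) > 30) next
      out <- rbind(out, data.frame(region = reg, path_distance = nodes$path_distance[i],
                                   as.list(round(dens[i, ], 4)), check.names = FALSE))
    }
  }
  unique(out)
}
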