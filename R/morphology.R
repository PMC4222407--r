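#' @useDynLib l5sim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx lm coef sd setNames
#' @importFrom utils read.table write.table head tail combn
NULL

REGIONS <- c("soma", "axon", "basal", "apical")
SWC_TYPE_MAP <- c("1" = "soma", "2" = "axon", "3" = "basal", "4" = "apical")

#' Construct a compartmental tree
#'
#' A `compartment_tree` holds one row per electrical compartment: identity,
#' topology (parent), region, geometry and - once assigned - passive membrane
#' properties. Path distances are measured along the tree from the soma
#' centre, in micrometres, at the distal end of each compartment.
#'
#' @param nodes data.frame with columns `id`, `parent_id` (NA for the soma
#'   root), `region` (one of soma/axon/basal/apical), `length` and `diam`
#'   (um), `path_distance` (um) and optionally `x`, `y`, `z` endpoint
#'   coordinates.
#' @param swc optional data.frame of raw SWC samples kept for lossless
#'   round-tripping.
#' @return object of class `compartment_tree`
#' @keywords internal
new_compartment_tree <- function(nodes, swc = NULL) {
  nodes$area <- pi * nodes$diam * nodes$length # lateral cylinder area, um^2
  tree <- structure(list(nodes = nodes, swc = swc), class = "compartment_tree")
  validate_tree(tree)
  tree
}

#' Validate the structural invariants of a compartment tree
#'
#' Checks connectivity, acyclicity (parents precede children), positive
#' geometry and the single-soma-root property.
#'
#' @param tree a `compartment_tree`
#' @return the tree, invisibly; errors on violation
#' @export
validate_tree <- function(tree) {
  n <- tree$nodes
  stopifnot(is.data.frame(n), nrow(n) >= 1)
  if (any(n$length <= 0)) stop("all compartment lengths must be > 0")
  if (any(n$diam <= 0)) stop("all compartment diameters must be > 0")
  if (any(n$path_distance < 0)) stop("path distances must be >= 0")
  if (!all(n$region %in% REGIONS)) stop("unknown region label")
  root <- which(is.na(n$parent_id))
  if (length(root) != 1L) stop("exactly one root compartment required")
  if (n$region[root] != "soma") stop("root compartment must be the soma")
  idx <- match(n$parent_id, n$id)
  bad <- which(!is.na(n$parent_id) & is.na(idx))
  if (length(bad)) stop("parent id not found for compartment ", n$id[bad[1]])
  # parents must precede children in storage order -> acyclic by construction
  if (any(idx >= seq_len(nrow(n)), na.rm = TRUE))
    stop("parent must precede child (cycle or bad ordering)")
  invisible(tree)
}

#' @export
print.compartment_tree <- function(x, ...) {
  n <- x$nodes
  cat("<compartment_tree> ", nrow(n), " compartments\n", sep = "")
  tab <- table(n$region)
  for (r in names(tab)) {
    d <- n$path_distance[n$region == r]
    cat(sprintf("  %-7s n=%3d  max path distance %.1f um\n", r, tab[[r]], max(d)))
  }
  if (!is.null(n$rm)) cat(sprintf("  passive: cm %.2f uF/cm2, ra %.1f Ohm cm, rm %.1f..%.1f kOhm cm2\n",
                                  n$cm[1], n$ra[1], max(n$rm), min(n$rm)))
  invisible(x)
}

#' Read a morphology from SWC text
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent). All soma (type 1) samples are merged into a single equivalent
#' soma compartment; every other sample becomes one compartment spanning from
#' its parent sample to itself. Path distances are cumulative 3-D
#' point-to-point distances from the soma centre.
#'
#' @param swc_text character scalar (whole file) or vector of lines, or a
#'   path to an SWC file.
#' @return a `compartment_tree`
#' @export
load_swc <- function(swc_text) {
  if (length(swc_text) == 1 && !grepl("\n", swc_text) && file.exists(swc_text))
    swc_text <- readLines(swc_text)
  lines <- unlist(strsplit(swc_text, "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (!length(body)) stop("SWC input contains no samples")
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) != 7))
    stop("malformed SWC line (need 7 columns): ", body[which(lengths(fields) != 7)[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in SWC line: ", body[which(is.na(rowSums(m)))[1]])
  swc <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                    parent = as.integer(m[, 7]))
  unknown <- !as.character(swc$type) %in% names(SWC_TYPE_MAP)
  if (any(unknown))
    stop("unknown SWC type code in line: ", body[which(unknown)[1]])
  seen <- integer(0)
  for (i in seq_len(nrow(swc))) {
    p <- swc$parent[i]
    if (p != -1 && !(p %in% seen))
      stop("SWC structural error: parent ", p, " referenced before definition (line: ",
           body[i], ")")
    if (p == swc$id[i]) stop("SWC structural error: sample is its own parent")
    seen <- c(seen, swc$id[i])
  }
  soma_rows <- swc[swc$type == 1L, , drop = FALSE]
  if (nrow(soma_rows) == 0L) stop("SWC has no soma (type 1) sample")
  soma_id <- soma_rows$id[1]
  soma_centre <- c(mean(soma_rows$x), mean(soma_rows$y), mean(soma_rows$z))
  # Equivalent-area soma: sphere for a single sample, otherwise the summed
  # frustum path; represented as one cylinder with L = diam conserving area.
  if (nrow(soma_rows) == 1L) {
    soma_area <- 4 * pi * soma_rows$radius[1]^2
  } else {
    o <- order(soma_rows$id)
    sr <- soma_rows[o, ]
    seg <- sqrt(diff(sr$x)^2 + diff(sr$y)^2 + diff(sr$z)^2)
    rmid <- (sr$radius[-1] + sr$radius[-nrow(sr)]) / 2
    soma_area <- sum(2 * pi * rmid * pmax(seg, .Machine$double.eps))
    if (soma_area <= 0) soma_area <- 4 * pi * max(sr$radius)^2
  }
  soma_dim <- sqrt(soma_area / pi) # L = diam = sqrt(A/pi)
  nodes <- data.frame(id = soma_id, parent_id = NA_integer_, region = "soma",
                      length = soma_dim, diam = soma_dim, path_distance = 0,
                      x = soma_centre[1], y = soma_centre[2], z = soma_centre[3])
  coords <- swc[, c("x", "y", "z")]
  rownames(coords) <- swc$id
  pd <- setNames(rep(0, nrow(swc)), swc$id)
  for (i in seq_len(nrow(swc))) {
    row <- swc[i, ]
    if (row$type == 1L) next
    if (row$parent == -1L) stop("non-soma sample without parent: id ", row$id)
    pidx <- match(row$parent, swc$id)
    pcoord <- if (swc$type[pidx] == 1L) soma_centre else
      as.numeric(coords[as.character(row$parent), ])
    len <- sqrt(sum((c(row$x, row$y, row$z) - pcoord)^2))
    if (len <= 0) stop("zero-length SWC segment at sample ", row$id)
    parent_id <- if (swc$type[pidx] == 1L) soma_id else row$parent
    ppd <- if (swc$type[pidx] == 1L) 0 else pd[[as.character(row$parent)]]
    pd[[as.character(row$id)]] <- ppd + len
    nodes <- rbind(nodes, data.frame(
      id = row$id, parent_id = parent_id,
      region = SWC_TYPE_MAP[[as.character(row$type)]],
      length = len, diam = 2 * row$radius, path_distance = ppd + len,
      x = row$x, y = row$y, z = row$z))
  }
  new_compartment_tree(nodes, swc = swc)
}

#' Serialize a tree back to SWC text
#'
#' When the tree was loaded from SWC the original samples are reproduced at
#' full printed precision; otherwise samples are reconstructed from the
#' compartment endpoints.
#'
#' @param tree a `compartment_tree`
#' @return character vector of SWC lines
#' @export
write_swc <- function(tree) {
  if (!is.null(tree$swc)) {
    s <- tree$swc
    return(sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   s$id, s$type, s$x, s$y, s$z, s$radius, s$parent))
  }
  n <- tree$nodes
  type <- match(n$region, SWC_TYPE_MAP)
  parent <- ifelse(is.na(n$parent_id), -1L, n$parent_id)
  sprintf("%d %d %.17g %.17g %.17g %.17g %d",
          n$id, type, n$x, n$y, n$z, n$diam / 2, parent)
}

#' Built-in stylized layer 5 pyramidal morphology
#'
#' Deterministically constructs the reduced layer 5 cell shipped with the
#' package: a soma, an axon initial segment plus main axon, a long apical
#' trunk carrying a two-branch tuft, and two basal dendrites. Section
#' dimensions live in `inst/extdata/reference_morphology.yaml`; sections are
#' discretized so no electrical compartment exceeds `max_segment` micrometres.
#'
#' @param config path to the YAML geometry description (defaults to the
#'   shipped file).
#' @param max_segment maximum compartment length, um.
#' @return a `compartment_tree`
#' @export
make_reference_morphology <- function(config = NULL, max_segment = 20) {
  if (is.null(config))
    config <- system.file("extdata", "reference_morphology.yaml", package = "l5sim")
  spec <- yaml::read_yaml(config)
  secs <- spec$sections
  nodes <- NULL
  next_id <- 1L
  sec_end <- list() # section name -> list(id, pos, pd)
  for (s in secs) {
    dir <- as.numeric(unlist(s$direction))
    dir <- dir / sqrt(sum(dir^2))
    if (identical(s$name, "soma")) {
      nodes <- data.frame(id = next_id, parent_id = NA_integer_, region = "soma",
                          length = s$length, diam = s$diam_start,
                          path_distance = 0, x = 0, y = 0, z = 0)
      sec_end[[s$name]] <- list(id = next_id, pos = c(0, 0, 0), pd = 0)
      next_id <- next_id + 1L
      next
    }
    at <- sec_end[[s$parent]]
    if (is.null(at)) stop("section parent not defined: ", s$parent)
    nseg <- max(1L, ceiling(s$length / max_segment))
    seg_len <- s$length / nseg
    pos <- at$pos; pd <- at$pd; pid <- at$id
    d_end <- if (is.null(s$diam_end)) s$diam_start else s$diam_end
    for (k in seq_len(nseg)) {
      pos <- pos + dir * seg_len
      pd <- pd + seg_len
      frac <- (k - 0.5) / nseg
      diam <- s$diam_start + frac * (d_end - s$diam_start)
      nodes <- rbind(nodes, data.frame(
        id = next_id, parent_id = pid, region = s$region,
        length = seg_len, diam = diam, path_distance = pd,
        x = pos[1], y = pos[2], z = pos[3]))
      pid <- next_id
      next_id <- next_id + 1L
    }
    sec_end[[s$name]] <- list(id = pid, pos = pos, pd = pd)
  }
  new_compartment_tree(nodes)
}

#' Subdivide long compartments
#'
#' Splits any compartment longer than `max_segment` um into equal parts so
#' spatial discretization error stays controlled. Region, diameter and
#' passive properties (if assigned) are inherited; total membrane area is
#' conserved.
#'
#' @param tree a `compartment_tree`
#' @param max_segment maximum electrical segment length, um
#' @return a `compartment_tree`
#' @export
subdivide_tree <- function(tree, max_segment = 20) {
  n <- tree$nodes
  out <- NULL
  next_id <- 1L
  id_map <- integer(0) # old id -> new id of its distal piece
  extra_cols <- setdiff(names(n), c("id", "parent_id", "region", "length",
                                    "diam", "path_distance", "x", "y", "z", "area"))
  for (i in seq_len(nrow(n))) {
    row <- n[i, ]
    parent_new <- if (is.na(row$parent_id)) NA_integer_ else id_map[[as.character(row$parent_id)]]
    nseg <- if (row$region == "soma") 1L else max(1L, ceiling(row$length / max_segment))
    seg_len <- row$length / nseg
    base_pd <- row$path_distance - row$length
    pid <- parent_new
    for (k in seq_len(nseg)) {
      piece <- row
      piece$id <- next_id
      piece$parent_id <- pid
      piece$length <- seg_len
      piece$path_distance <- base_pd + k * seg_len
      for (cc in extra_cols) piece[[cc]] <- row[[cc]]
      out <- rbind(out, piece)
      pid <- next_id
      next_id <- next_id + 1L
    }
    id_map[[as.character(row$id)]] <- pid
  }
  rownames(out) <- NULL
  new_compartment_tree(out[, setdiff(names(out), "area")])
}

#' Assign passive membrane properties
#'
#' Applies uniform specific capacitance and axial resistivity, and a
#' sigmoidal specific membrane resistance profile over the dendrites: `rm`
#' follows a logistic curve of path distance with its midpoint at half the
#' maximal dendritic path distance, rescaled so the soma value and the distal
#' tip value are met exactly. Soma and axon take `rm_soma`.
#'
#' @param tree a `compartment_tree`
#' @param cm specific membrane capacitance, uF/cm^2
#' @param ra specific axial (intracellular) resistivity, Ohm cm
#' @param rm_soma specific membrane resistance at the soma, kOhm cm^2
#' @param rm_tip specific membrane resistance at the most distal dendritic
#'   tip, kOhm cm^2
#' @param rm_profile list with `span_coverage`: the fraction of the
#'   soma-to-tip `rm` range that the raw logistic spans over the dendritic
#'   extent (steepness parameter; the curve is affinely rescaled to hit the
#'   endpoints exactly).
#' @return the tree with `cm`, `ra`, `rm` columns and `spine_factor = 1`
#' @export
assign_passive <- function(tree, cm = 1.5, ra = 68.0, rm_soma = 36.0,
                           rm_tip = 5.4, rm_profile = list(span_coverage = 0.99)) {
  if (cm <= 0 || ra <= 0) stop("cm and ra must be positive")
  if (!(rm_soma > rm_tip && rm_tip > 0)) stop("need rm_soma > rm_tip > 0")
  n <- tree$nodes
  dend <- n$region %in% c("apical", "basal")
  if (!any(dend)) { # no dendrites: uniform rm_soma
    n$cm <- cm; n$ra <- ra; n$rm <- rm_soma
    n$spine_factor <- 1; n$spine_corrected <- FALSE
    tree$nodes <- n
    return(tree)
  }
  dmax <- max(n$path_distance[dend])
  d0 <- dmax / 2
  cov <- rm_profile$span_coverage %||% 0.99
  k <- 2 * log((1 + cov) / (1 - cov)) / dmax # logistic steepness
  f <- function(d) 1 / (1 + exp(k * (d - d0)))
  scale01 <- function(d) (f(d) - f(dmax)) / (f(0) - f(dmax))
  n$cm <- cm
  n$ra <- ra
  n$rm <- rm_soma
  n$rm[dend] <- rm_tip + (rm_soma - rm_tip) * scale01(n$path_distance[dend])
  n$spine_factor <- 1
  n$spine_corrected <- FALSE
  tree$nodes <- n
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the dendritic spine correction
#'
#' Compensates unmodelled spines by doubling specific capacitance, halving
#' specific membrane resistance, and recording a spine factor of 2 that later
#' doubles active channel densities - for basal compartments at or beyond
#' `basal_onset` and apical compartments at or beyond `apical_onset` path
#' distance. Soma and axon are never corrected; the call is idempotent.
#'
#' @param tree a `compartment_tree` with passive properties assigned
#' @param basal_onset onset distance for basal dendrites, um
#' @param apical_onset onset distance for the apical dendrite, um
#' @return the corrected tree
#' @export
apply_spine_correction <- function(tree, basal_onset = 20, apical_onset = 100) {
  n <- tree$nodes
  if (is.null(n$rm)) stop("assign_passive() must run before the spine correction")
  sel <- (!n$spine_corrected) &
    ((n$region == "basal" & n$path_distance >= basal_onset) |
       (n$region == "apical" & n$path_distance >= apical_onset))
  n$cm[sel] <- n$cm[sel] * 2
  n$rm[sel] <- n$rm[sel] / 2
  n$spine_factor[sel] <- n$spine_factor[sel] * 2
  n$spine_corrected[sel] <- TRUE
  tree$nodes <- n
  tree
}
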