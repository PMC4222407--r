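# Shared fixtures, built lazily and cached for the whole run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# SWC text helpers -----------------------------------------------------------
swc_line <- function(id, type, x, y, z, r, parent)
  sprintf("%d %d %g %g %g %g %d", id, type, x, y, z, r, parent)

swc_single_soma <- function() swc_line(1, 1, 0, 0, 0, 5, -1)

# soma at origin plus three collinear apical samples 100 um apart
swc_collinear_apical <- function() c(
  swc_line(1, 1, 0, 0, 0, 5, -1),
  swc_line(2, 4, 0, 100, 0, 1, 1),
  swc_line(3, 4, 0, 200, 0, 1, 2),
  swc_line(4, 4, 0, 300, 0, 1, 3))

# single somatic compartment carrying the somatic channel complement
soma_only_model <- function() cached("soma_only_model", {
  tree <- load_swc(swc_single_soma())
  tree <- assign_passive(tree)
  tree <- apply_spine_correction(tree)
  rules <- default_density_rules()
  rules$rules <- Filter(function(r) r$region == "soma", rules$rules)
  build_membrane_model(tree, rules = rules)
})

full_model <- function() cached("full_model", build_l5_model())

full_steady <- function() cached("full_steady", steady_state(full_model()))

passive_soma_model <- function() cached("passive_soma_model", {
  m <- soma_only_model()
  mask_channels(m, names(m$scale))
})
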