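rules <- default_density_rules()
rule_for <- function(channel, region)
  Filter(function(r) r$channel == channel && r$region == region, rules$rules)[[1]]

test_that("density profiles reproduce the printed membrane composition", {
  # uniform axonal sodium
  expect_equal(density_at(rule_for("Na_x", "axon"), c(0, 10, 100)),
               rep(3500, 3))
  # exponential dendritic delayed rectifier: 20 * exp(-80/80) at 80 um
  expect_equal(density_at(rule_for("K_V", "apical"), 80), 20 * exp(-1))
  # HCN growth from 0.95 with lambda 323, hard-capped at 40x
  hcn <- rule_for("HCN", "apical")
  expect_equal(density_at(hcn, 0), 0.95)
  expect_equal(density_at(hcn, 323 * log(40) + 50), 38.0)
  expect_equal(density_at(hcn, 2000), 38.0)
  # M-channels restricted to the proximal apical 100 um
  km <- rule_for("K_M", "apical")
  expect_equal(density_at(km, 50), 5)
  expect_equal(density_at(km, 150), 0)
  # T-type calcium only beyond 300 um
  it2 <- rule_for("Ca_IT2", "apical")
  expect_equal(density_at(it2, 200), 0)
  expect_equal(density_at(it2, 400), 0.5)
  # basal sodium decreases linearly to half its proximal value at the tip
  na_b <- rule_for("Na", "basal")
  expect_equal(density_at(na_b, 0, region_max = 200), 150)
  expect_equal(density_at(na_b, 200, region_max = 200), 75)
  expect_equal(density_at(na_b, 100, region_max = 200), 112.5)
})

test_that("the A-type proximal/distal exchange is linear over 300 um", {
  expect_equal(ka_exchange_fraction(0), 0)
  expect_equal(ka_exchange_fraction(150), 0.5)
  expect_equal(ka_exchange_fraction(450), 1)
  d <- seq(0, 600, by = 10)
  f <- ka_exchange_fraction(d)
  expect_true(all(diff(f) >= 0) && all(f >= 0 & f <= 1))
})

test_that("density profiles are continuous within a region", {
  for (r in rules$rules) {
    if (r$profile == "uniform") next
    d <- seq(r$min_distance, min(r$max_distance, 1000), length.out = 400)
    dens <- density_at(r, d, region_max = 900)
    expect_true(all(abs(diff(dens)) < 2), label = paste(r$channel, r$region))
  }
})

test_that("pS/um^2 converts to S/cm^2 and back without loss", {
  dens_ps_um2 <- c(0.6, 20, 3500)
  s_cm2 <- dens_ps_um2 * 1e-4 # 1 pS/um^2 == 1e-4 S/cm^2
  expect_equal(s_cm2 / 1e-4, dens_ps_um2)
  # engine unit path: density * area gives the same conductance either way
  area_um2 <- 1257
  g_uS <- dens_ps_um2 * area_um2 * 1e-6
  g_uS2 <- s_cm2 * (area_um2 * 1e-8) * 1e6
  expect_equal(g_uS, g_uS2)
})

test_that("membrane assembly places the printed somatic densities", {
  model <- full_model()
  nodes <- model$tree$nodes
  dens <- effective_densities(model)
  soma <- which(nodes$region == "soma")
  # calibration is restricted to Na-family/K_V, so these are the raw values
  expect_equal(unname(dens[soma, "K_AP"]), 150)
  expect_equal(unname(dens[soma, "K_BK"]), 0.6)
  expect_equal(unname(dens[soma, "Na_P"]), 10)
  expect_equal(unname(dens[soma, "Ca_HVA"]), 2)
  expect_equal(unname(dens[soma, "HCN1"] + dens[soma, "HCN2"]), 0.95)
  expect_equal(unname(dens[soma, "HCN1"] / dens[soma, "HCN2"]), 2)
  # spine-corrected compartments carry exactly twice the rule density
  basal_far <- which(nodes$region == "basal" & nodes$path_distance >= 20)
  i <- basal_far[1]
  raw <- density_at(rule_for("K_BK", "basal"), nodes$path_distance[i])
  expect_equal(unname(dens[i, "K_BK"]), 2 * raw)
  # A-type total: proximal + distal = printed total x spine factor
  apical <- which(nodes$region == "apical")
  total <- dens[apical, "K_AP"] + dens[apical, "K_AD"]
  expect_equal(unname(total), 300 * nodes$spine_factor[apical])
})

test_that("assembly rejects bad inputs and validates coverage", {
  tree <- assign_passive(make_reference_morphology())
  expect_error(build_membrane_model(tree, rules = list(rules = list())), "empty")
  bad <- list(rules = list(density_rule("K_Qux", "soma", "uniform", 5)))
  expect_error(build_membrane_model(tree, rules = bad), "unknown channel")
  # a region lacking any sodium conductance is rejected
  na_free <- list(rules = Filter(function(r)
    !(r$region == "axon" && r$channel == "Na_x"), rules$rules))
  expect_error(build_membrane_model(tree, rules = na_free), "at least one Na")
})
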