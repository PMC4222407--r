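lib <- channel_library()

test_that("gate dynamics vanish at steady state and follow first-order kinetics", {
  na <- lib$Na
  v <- -40
  inf <- l5sim:::gate_inf(na, na$gates[[1]], v)
  d <- gate_dynamics(na, v, state = c(m = inf, h = 0.5))
  expect_equal(unname(d["m"]), 0, tolerance = 1e-12)
  expect_error(gate_dynamics(na, v, state = c(m = 1.5, h = 0.5)), "\\[0, 1\\]")
  # Boltzmann gate at its half-activation voltage opens to exactly 1/2
  nap <- lib$Na_P
  vhalf <- nap$params$vhalf
  expect_equal(l5sim:::gate_inf(nap, nap$gates[[1]], vhalf), 0.5)
})

test_that("gate relaxation matches the analytic exponential solution", {
  # oracle: x(t) = inf + (x0 - inf) exp(-t/tau) for fixed voltage
  nap <- lib$Na_P
  g <- nap$gates[[1]]
  v <- -50
  inf <- l5sim:::gate_inf(nap, g, v)
  tau <- l5sim:::gate_tau(nap, g, v)
  t_end <- 2 * tau
  sol <- deSolve::ode(
    y = c(m = 0.05), times = c(0, t_end),
    func = function(t, y, p) list(gate_dynamics(nap, v, state = y)),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  analytic <- inf + (0.05 - inf) * exp(-t_end / tau)
  expect_lt(abs(sol[2, "m"] - analytic), 1e-6)
})

test_that("every steady state is bounded and every time constant positive", {
  v <- seq(-120, 60, by = 1)
  for (ch in lib) {
    for (g in ch$gates) {
      inf <- if (g$ca_dependent) l5sim:::gate_inf(ch, g, v, ca = 1e-3) else
        l5sim:::gate_inf(ch, g, v)
      expect_true(all(inf >= 0 & inf <= 1), label = paste(ch$name, g$label, "inf"))
      tau <- l5sim:::gate_tau(ch, g, v)
      expect_true(all(tau > 0), label = paste(ch$name, g$label, "tau"))
    }
  }
})

test_that("the BK activation surface is bounded and jointly monotone", {
  v <- seq(-100, 100, length.out = 20)
  ca <- 10^seq(-5, -1, length.out = 20)
  surf <- outer(v, ca, function(vv, cc) bk_open_fraction(vv, cc, library = lib))
  expect_true(all(surf >= 0 & surf <= 1))
  # brute-force monotonicity scan over the grid
  expect_true(all(apply(surf, 2, diff) >= 0)) # in v at fixed ca
  expect_true(all(apply(surf, 1, diff) >= 0)) # in ca at fixed v
  # halving calcium never increases the open fraction
  expect_true(all(bk_open_fraction(v, 2e-3, lib) >= bk_open_fraction(v, 1e-3, lib)))
  # saturation at strong depolarization and high calcium
  expect_gt(bk_open_fraction(100, 1e-2, lib), 0.95)
  expect_error(bk_open_fraction(-50, 0), "> 0")
})

test_that("half-activation shifts compose additively and invert exactly", {
  nap <- lib$Na_P
  v <- seq(-80, 0, by = 5)
  unshifted <- l5sim:::gate_inf(nap, nap$gates[[1]], v)
  same <- shift_half_activation(nap, 0)
  expect_equal(l5sim:::gate_inf(same, same$gates[[1]], v), unshifted)
  # hyperpolarizing shift increases activation at any fixed voltage
  shifted <- shift_half_activation(nap, -2)
  expect_true(all(l5sim:::gate_inf(shifted, shifted$gates[[1]], v) >= unshifted))
  # +2 then -2 restores the original curve to machine precision
  back <- shift_half_activation(shift_half_activation(nap, 2), -2)
  expect_identical(l5sim:::gate_inf(back, back$gates[[1]], v), unshifted)
})

test_that("the calcium pool has the stated equilibria and floor", {
  pool <- calcium_pool()
  # zero influx from rest: concentration stays at rest
  expect_equal(update_calcium(pool, 0, dt = 1)$concentration,
               pool$resting_concentration)
  # constant influx converges to rest + phi * |i| * tau (closed form)
  i_ca <- 0.01
  p <- pool
  for (k in 1:20000) p <- update_calcium(p, i_ca, dt = 0.1)
  expect_equal(p$concentration,
               pool$resting_concentration +
                 pool$influx_scale * i_ca * pool$decay_time_constant,
               tolerance = 1e-6)
  # never drops below rest
  p2 <- update_calcium(calcium_pool(concentration = 1.2e-4), 0, dt = 1000)
  expect_gte(p2$concentration, p2$resting_concentration)
  expect_error(update_calcium(pool, 0, dt = -1), "positive")
})

test_that("the HCN density split is exactly 2/3 : 1/3 and conservative", {
  s <- hcn_split(0.95)
  expect_equal(unname(s["HCN1"]), 0.95 * 2 / 3)
  expect_equal(unname(sum(s)), 0.95)
  expect_equal(unname(hcn_split(0)), c(0, 0))
  totals <- runif(50, 0, 50)
  splits <- vapply(totals, function(x) sum(hcn_split(x)), 0)
  expect_equal(splits, totals)
  expect_error(hcn_split(-1), "non-negative")
})

test_that("HCN1 activates at less hyperpolarized potentials than HCN2", {
  v <- seq(-120, -40, by = 1)
  inf1 <- l5sim:::gate_inf(lib$HCN1, lib$HCN1$gates[[1]], v)
  inf2 <- l5sim:::gate_inf(lib$HCN2, lib$HCN2$gates[[1]], v)
  mid1 <- v[which.min(abs(inf1 - 0.5))]
  mid2 <- v[which.min(abs(inf2 - 0.5))]
  expect_gt(mid1, mid2)
  # HCN1 is also the faster isoform over the activation range
  expect_true(all(l5sim:::gate_tau(lib$HCN1, lib$HCN1$gates[[1]], v) <
                    l5sim:::gate_tau(lib$HCN2, lib$HCN2$gates[[1]], v)))
})
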