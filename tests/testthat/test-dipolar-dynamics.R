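test_that("closed-form MAS phase agrees with the quadrature oracle", {
  # frozen oracle value computed by direct quadrature of the modulated
  # dipolar frequency (1e4+ step equivalent accuracy)
  expect_equal(mas_dipolar_phase(10000, pi / 4, pi / 3, 1e-4, 5000),
               2.449489742783, tolerance = 1e-10)
  # random sweep against the live oracle
  set.seed(101)
  for (i in 1:25) {
    d <- runif(1, 0, 30000); b <- runif(1, 0, pi); g <- runif(1, 0, 2 * pi)
    t1 <- runif(1, 0, 2e-4)
    expect_lt(abs(mas_dipolar_phase(d, b, g, t1, 5000) -
                  phase_quadrature(d, b, g, t1, 5000)), 1e-8)
  }
  # zero coupling and full-rotor refocusing null the phase exactly
  expect_equal(mas_dipolar_phase(0, 1, 1, 1e-4, 5000), 0)
  expect_equal(mas_dipolar_phase(15000, 0.7, 2.1, 2e-4, 5000), 0,
               tolerance = 1e-12)
  expect_error(mas_dipolar_phase(1000, 1, 1, 3e-4, 5000), "rotor period")
})

test_that("dephasing curves refocus, are symmetric, and deepen with coupling", {
  dp <- dipolar_params()
  flat <- simulate_dipshift(0, dp)
  expect_equal(flat$amplitude, rep(1, 16))
  cv <- simulate_dipshift(10000, dp, n_t1 = 17L)   # odd count samples tau_r/2
  expect_equal(cv$amplitude[1], 1, tolerance = 1e-6)
  expect_equal(cv$amplitude[17], 1, tolerance = 1e-6)
  # gamma-averaged symmetry about half a rotor period
  expect_equal(cv$amplitude, rev(cv$amplitude), tolerance = 1e-6)
  # minimum at tau_r/2
  expect_equal(which.min(cv$amplitude), 9L)
  # minimum depth decreases monotonically with d_eff up to 2 * mas_rate
  depths <- vapply(seq(500, 10000, length.out = 8), function(d)
    min(simulate_dipshift(d, dp, n_t1 = 17L)$amplitude), numeric(1))
  expect_true(all(diff(depths) < 0))
  # sign invariance: the amplitude depends on |d_eff| only
  expect_equal(simulate_dipshift(-8000, dp)$amplitude,
               simulate_dipshift(8000, dp)$amplitude, tolerance = 1e-12)
})

test_that("weak-coupling dephasing matches the quadratic series expansion", {
  # to second order, 1 - A(t1) = <Phi^2>/2: compute the powder-mean squared
  # phase directly as the independent small-coupling oracle
  dp <- dipolar_params()
  d <- 200   # d_eff << mas_rate
  sch <- powder_scheme(256L, 32L)
  ori <- expand.grid(beta = acos(sch$cos_beta), gamma = sch$gamma)
  cv <- simulate_dipshift(d, dp, sch)
  for (k in c(5L, 9L, 13L)) {
    phi2 <- mean(mas_dipolar_phase(d, ori$beta, ori$gamma, cv$t1[k],
                                   dp$mas_rate)^2)
    expect_equal(1 - cv$amplitude[k], phi2 / 2, tolerance = 1e-3)
  }
})

test_that("coupling fit inverts the dephasing simulation across the S range", {
  dp <- dipolar_params()
  for (S in c(0.05, 0.2, 0.56, 0.65, 0.84, 1.0)) {
    cv <- simulate_dipshift(S * dp$seq_scaling * dp$d_rigid, dp)
    fit <- fit_dipshift(cv, dp)
    expect_equal(fit$order_parameter, S, tolerance = 0.005 / S)
    expect_false(fit$at_bound && S < 1)
  }
  # flat curve means no residual coupling
  flat <- dephasing_curve(seq(0, 2e-4, length.out = 16), rep(1, 16), 5000)
  expect_equal(fit_dipshift(flat, dp)$order_parameter, 0, tolerance = 1e-3)
})

test_that("noisy dephasing curves recover S within the Monte-Carlo tolerance", {
  dp <- dipolar_params()
  clean <- simulate_dipshift(0.8 * dp$seq_scaling * dp$d_rigid, dp)
  set.seed(7)
  for (i in 1:5) {
    a <- clean$amplitude + rnorm(16, sd = 0.02)
    a[1] <- 1
    fit <- fit_dipshift(dephasing_curve(clean$t1, a, 5000), dp)
    expect_equal(fit$order_parameter, 0.8, tolerance = 0.03 / 0.8)
  }
})

test_that("order parameter is the scaled coupling ratio with clipping", {
  dp <- dipolar_params(d_rigid = 21500, seq_scaling = 0.577)
  expect_equal(order_parameter(0.577 * 21500, dp), 1)
  expect_equal(order_parameter(0, dp), 0)
  expect_equal(order_parameter(0.577 * 21500 * 0.56, dp), 0.56)
  expect_warning(s <- order_parameter(0.577 * 21500 * 1.05, dp), "clipped")
  expect_equal(s, 1)
  expect_error(order_parameter(-10, dp), "d_eff")
})

test_that("cone conversion matches the analytic root and is strictly decreasing", {
  expect_equal(cone_angle(1)$cone_semi_angle, 0)
  expect_equal(cone_angle(0.56)$cone_semi_angle, 47.9, tolerance = 1e-3)
  expect_equal(cone_angle(0.09)$cone_semi_angle, 81.0, tolerance = 1e-3)
  ss <- seq(0.02, 1, by = 0.02)
  th <- vapply(ss, function(s) cone_angle(s)$cone_semi_angle, numeric(1))
  expect_true(all(diff(th) < 0))
  # forward model round trip: S = cos(theta)(1+cos(theta))/2
  ct <- cos(th * pi / 180)
  expect_equal(ct * (1 + ct) / 2, ss, tolerance = 1e-10)
  expect_error(cone_angle(0), "S > 0")
  expect_error(cone_angle(1.2), "exceed")
})

test_that("r-PDLF splittings convert to order parameters and round-trip", {
  dpr <- dipolar_params(seq_scaling = 0.315)
  expect_equal(rpdlf_order_parameter(0, dpr), 0)
  expect_equal(rpdlf_order_parameter(0.09 * 0.315 * 21500, dpr), 0.09)
  expect_equal(rpdlf_order_parameter(0.05 * 0.315 * 21500, dpr), 0.05)
  # construction: maxima at +/- splitting/2
  db <- simulate_rpdlf(600 / (0.315 * 21500), dpr, linewidth = 50)
  expect_equal(rpdlf_splitting(db), 600, tolerance = 5 / 600)
  # S = 0 collapses to a single line at zero
  d0 <- simulate_rpdlf(0, dpr)
  expect_equal(d0$freq_axis[which.max(d0$intensity)], 0)
  expect_equal(rpdlf_splitting(d0), 0)
  # simulate -> peak-pick -> convert recovers S for the mobile-termini range
  for (S in c(0.05, 0.07, 0.09, 0.12)) {
    dd <- simulate_rpdlf(S, dpr, linewidth = 50)
    expect_equal(rpdlf_order_parameter(rpdlf_splitting(dd), dpr), S,
                 tolerance = 0.005 / S)
  }
  expect_error(simulate_rpdlf(0.9, dpr, axis = seq(-500, 500, by = 5)),
               "axis")
})

test_that("condition labels enforce the contact-time rule", {
  expect_error(condition_label("CP", "DMPC", "apo"), "contact")
  expect_error(condition_label("direct", "DMPC", "apo", contact_us = 700),
               "contact_us")
  cl <- condition_label("CP", "POPC", "ghrelin", site = "CH2",
                        contact_us = 700)
  expect_match(format(cl), "CP 700")
})

test_that("condition table aggregates duplicates as mean +/- half-range", {
  dp <- dipolar_params()
  mk <- function(S, lipid, ligand) {
    structure(list(d_eff = S * dp$seq_scaling * dp$d_rigid,
                   order_parameter = S, residual = 0, at_bound = FALSE,
                   damping_rate = NA_real_,
                   condition = condition_label("direct", lipid, ligand),
                   params = dp), class = "order_parameter_result")
  }
  res <- list(mk(0.60, "DMPC", "apo"), mk(0.64, "DMPC", "apo"),
              mk(0.65, "POPC", "apo"), mk(0.67, "POPC", "ghrelin"),
              mk(0.66, "POPC", "inverse_agonist"),
              mk(0.62, "DMPC", "ghrelin"),
              mk(0.61, "DMPC", "inverse_agonist"))
  tab <- tabulate_conditions(res)
  row <- tab[tab$lipid == "DMPC" & tab$ligand == "apo", ]
  expect_equal(row$S, 0.62)
  expect_equal(row$S_uncertainty, 0.02)
  expect_equal(row$n, 2L)
  # 3 ligand states x 2 lipids
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$ligand), c("apo", "ghrelin", "inverse_agonist"))
  # empty input gives an empty table with the full schema
  empty <- tabulate_conditions(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("site", "lipid", "ligand", "S", "S_uncertainty") %in%
                  names(empty)))
})
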