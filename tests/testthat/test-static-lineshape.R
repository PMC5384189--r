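test_that("orientation-dependent shift matches the axial closed form", {
  t133 <- amide_tensor(133)
  # parallel edge: iso + 2*span/3
  expect_equal(csa_shift(t133, 1), 119 + 2 * 133 / 3, tolerance = 1e-12)
  expect_equal(csa_shift(t133, 1), 207.67, tolerance = 1e-4)
  # magic angle nulls the anisotropic term
  expect_equal(csa_shift(t133, cos(54.7356 * pi / 180)), 119,
               tolerance = 1e-6)
  # zero span: identity at any orientation
  t0 <- csa_tensor(119, 0)
  expect_equal(csa_shift(t0, c(-1, -0.3, 0, 0.8, 1)), rep(119, 5))
  # eta = 0 output independent of gamma
  expect_equal(csa_shift(t133, 0.4, 0), csa_shift(t133, 0.4, 1.7))
  # eta > 0 brings in the azimuthal term with the documented sign
  te <- csa_tensor(119, 133, asymmetry = 0.5)
  expect_equal(csa_shift(te, 0, 0),
               119 + 133 / 3 * (-1 - 0.5), tolerance = 1e-12)
  expect_error(csa_shift(t133, 1.2), "cos_beta")
})

test_that("isotropic average of the shift over uniform cos(beta) recovers iso_shift", {
  tns <- amide_tensor(133)
  cb <- powder_scheme(4096L)$cos_beta
  expect_equal(mean(csa_shift(tns, cb)), 119, tolerance = 1e-3)
})

test_that("powder pattern has unit area, edge maximum and mirror symmetry", {
  tns <- amide_tensor(133)
  ax <- amide_axis(133)
  pp <- powder_pattern(tns, ax, broadening = 2)
  expect_s3_class(pp, "spectrum1d")
  expect_equal(spectrum_area(pp), 1, tolerance = 1e-6)
  # maximum at the perpendicular edge iso - span/3 (within broadening + grid)
  expect_equal(ax[which.max(pp$intensity)], 119 - 133 / 3, tolerance = 2.5)
  # zero span degenerates to a single symmetric line at iso_shift
  pp0 <- powder_pattern(csa_tensor(119, 0), ax, broadening = 2)
  expect_equal(ax[which.max(pp0$intensity)], 119, tolerance = 0.5)
  i_left <- approx(ax, pp0$intensity, 119 - 5)$y
  i_right <- approx(ax, pp0$intensity, 119 + 5)$y
  expect_equal(i_left, i_right, tolerance = 1e-8)
  # span sign flip mirrors the spectrum about iso_shift
  axs <- seq(119 - 140, 119 + 140, by = 0.5)   # symmetric axis about iso
  pn <- powder_pattern(csa_tensor(119, -133), axs, broadening = 2)
  pf <- powder_pattern(csa_tensor(119, 133), axs, broadening = 2)
  expect_equal(pn$intensity, rev(pf$intensity), tolerance = 1e-9)
  expect_error(powder_pattern(tns, numeric(0), 2), "axis")
  expect_error(powder_pattern(tns, ax, -1), "broadening")
})

test_that("powder average reproduces the analytic eta=0 frequency density", {
  tns <- amide_tensor(133)
  ax <- amide_axis(133, pad = 30, by = 0.25)
  pp <- powder_pattern(tns, ax, broadening = 0.8, powder_scheme(8192L))
  dens <- powder_density_axial(tns, ax)
  # compare away from the integrable singularity and the step edge, where
  # the finite broadening kernel dominates the difference
  sel <- ax > 119 - 133 / 3 + 12 & ax < 119 + 2 * 133 / 3 - 12
  expect_lt(max(abs(pp$intensity[sel] - dens[sel]) / dens[sel]), 0.01)
  # the analytic density integrates to one over the support (adaptive
  # quadrature handles the integrable inverse-square-root edge singularity)
  area_dens <- integrate(function(s) powder_density_axial(tns, s),
                         119 - 133 / 3, 119 + 2 * 133 / 3,
                         rel.tol = 1e-9)$value
  expect_equal(area_dens, 1, tolerance = 1e-6)
})

test_that("composite synthesis adds unit-area components with weight-areas", {
  model <- lineshape_model(
    aniso_components = list(list(tensor = amide_tensor(), broadening = 5,
                                 weight = 0.75)),
    iso_components = list(list(center = 108, width = 2, weight = 0.10),
                          list(center = 116, width = 2, weight = 0.08),
                          list(center = 124, width = 2, weight = 0.07)))
  ax <- amide_axis()
  sp <- synthesize_composite(model, ax)
  expect_equal(spectrum_area(sp), 1, tolerance = 1e-3)    # sum of weights
  # iso/total weight ratio is 25% by construction
  expect_equal(mobile_fraction(model)$fraction_mobile, 0.25)
  # dropping the isotropic lines reproduces the pure powder pattern
  pure <- lineshape_model(aniso_components = model$aniso_components)
  expect_equal(synthesize_composite(pure, ax)$intensity,
               powder_pattern(amide_tensor(), ax, 5)$intensity * 0.75,
               tolerance = 1e-12)
})

test_that("lineshape fit recovers span, centers and weights from noiseless data", {
  for (case in list(list(span = 128, frac = 0),
                    list(span = 133, frac = 0.25),
                    list(span = 60, frac = 0.4),
                    list(span = 180, frac = 0.1))) {
    truth <- lineshape_model(
      aniso_components = list(list(tensor = amide_tensor(case$span),
                                   broadening = 5, weight = 1 - case$frac)),
      iso_components = if (case$frac > 0)
        list(list(center = 116, width = 2, weight = case$frac)) else list())
    ax <- amide_axis(case$span)
    sp <- synthesize_composite(truth, ax)
    fit <- fit_lineshape(sp, perturb_model(truth, 1.1),
                         scheme = powder_scheme(128L))
    expect_true(fit$converged)
    expect_equal(fit$model$aniso_components[[1]]$tensor$span, case$span,
                 tolerance = 1 / case$span)          # within 1 ppm
    expect_equal(fit$model$aniso_components[[1]]$tensor$iso_shift, 119,
                 tolerance = 0.5 / 119)
    expect_equal(mobile_fraction(fit$model)$fraction_mobile, case$frac,
                 tolerance = 0.01)
  }
})

test_that("degenerate flat spectrum yields a non-convergence flag, not an error", {
  ax <- amide_axis()
  flat <- spectrum1d(ax, rep(0, length(ax)))
  fit <- fit_lineshape(flat, pure_aniso_model())
  expect_false(fit$converged)
})

test_that("mobile fraction is pure weight arithmetic and scale-invariant", {
  m <- lineshape_model(
    aniso_components = list(list(tensor = amide_tensor(), broadening = 5,
                                 weight = 3)),
    iso_components = list(list(center = 116, width = 2, weight = 1)))
  expect_equal(mobile_fraction(m)$fraction_mobile, 0.25)
  expect_equal(mobile_fraction(pure_aniso_model())$fraction_mobile, 0)
  # invariance under global intensity rescaling of the input spectrum
  cfg <- fixture_scenarios(11L)$dmpc_cp8ms
  g <- gen_static_spectrum(cfg)
  f1 <- fit_lineshape(g$spectrum, perturb_model(g$truth, 1.05),
                      scheme = powder_scheme(128L))
  sp10 <- spectrum1d(g$spectrum$axis, 10 * g$spectrum$intensity)
  init10 <- perturb_model(g$truth, 1.05)
  for (k in seq_along(init10$aniso_components))
    init10$aniso_components[[k]]$weight <- init10$aniso_components[[k]]$weight * 10
  for (k in seq_along(init10$iso_components))
    init10$iso_components[[k]]$weight <- init10$iso_components[[k]]$weight * 10
  f10 <- fit_lineshape(sp10, init10, scheme = powder_scheme(128L))
  expect_equal(mobile_fraction(f1$model)$fraction_mobile,
               mobile_fraction(f10$model)$fraction_mobile, tolerance = 1e-3)
  # all-zero weights rejected
  bad <- m
  bad$aniso_components[[1]]$weight <- 0
  bad$iso_components[[1]]$weight <- 0
  expect_error(mobile_fraction(bad), "zero")
})

test_that("type invariants are enforced", {
  expect_error(csa_tensor(119, 133, asymmetry = 1.2), "asymmetry")
  expect_error(spectrum1d(c(1, 2, 2), c(0, 0, 0)), "monotone")
  expect_error(spectrum1d(c(1, 2), c(0, NA)), "finite")
  expect_error(lineshape_model(), "component")
  expect_error(lineshape_model(iso_components =
    list(list(center = 116, width = -1, weight = 1))), "width")
})
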