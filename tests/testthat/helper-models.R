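# shared fixture builders for the test suite

amide_tensor <- function(span = 133) csa_tensor(iso_shift = 119, span = span)

# single axially symmetric component, unit weight
pure_aniso_model <- function(span = 133, broadening = 5, weight = 1) {
  lineshape_model(aniso_components = list(
    list(tensor = amide_tensor(span), broadening = broadening,
         weight = weight)))
}

# axis generously covering the pattern support for a given span
amide_axis <- function(span = 133, pad = 40, by = 0.5)
  seq(119 - abs(span) / 3 - pad, 119 + 2 * abs(span) / 3 + pad, by = by)

# multiplicative perturbation of every fitted lineshape parameter
perturb_model <- function(model, factor = 1.1) {
  for (k in seq_along(model$aniso_components)) {
    model$aniso_components[[k]]$tensor$span <-
      model$aniso_components[[k]]$tensor$span * factor
    model$aniso_components[[k]]$tensor$iso_shift <-
      model$aniso_components[[k]]$tensor$iso_shift * (1 + (factor - 1) / 5)
    model$aniso_components[[k]]$broadening <-
      model$aniso_components[[k]]$broadening * factor
    model$aniso_components[[k]]$weight <-
      model$aniso_components[[k]]$weight / factor
  }
  for (k in seq_along(model$iso_components)) {
    model$iso_components[[k]]$weight <-
      model$iso_components[[k]]$weight * factor
  }
  model
}

# direct numerical quadrature of the MAS dipolar frequency: the independent
# oracle for the closed-form accumulated phase
phase_quadrature <- function(d_eff, beta, gamma, t1, mas_rate) {
  wr <- 2 * pi * mas_rate
  stats::integrate(function(t)
    pi * d_eff * (sin(beta)^2 * cos(2 * (wr * t + gamma)) -
                  sqrt(2) * sin(2 * beta) * cos(wr * t + gamma)),
    0, t1, rel.tol = 1e-12, abs.tol = 1e-12, subdivisions = 2000L)$value
}
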