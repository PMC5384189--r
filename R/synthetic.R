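#' Fixture configuration for synthetic data generation
#'
#' A named, seeded parameter bundle for one synthetic dataset. Every
#' generator consumes one of these and returns a `(data, truth)` pair, so
#' recovery tests can compare fitted parameters against the generating
#' truth. The seed is mandatory: regeneration from an identical config is
#' bit-identical. Configs serialize losslessly to JSON via
#' [save_fixture_config()] / [load_fixture_config()].
#'
#' @param scenario scenario name (free text; see [fixture_scenarios()] for
#'   the packaged set).
#' @param params named list of physical generator parameters.
#' @param noise named list describing the noise model (e.g. `list(snr =
#'   50)` for additive noise relative to the signal maximum, `list(sd =
#'   0.02)` for absolute additive noise, `list(cv = 0.05)` for
#'   multiplicative noise).
#' @param replicates replicate count (>= 1).
#' @param seed RNG seed (mandatory integer).
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(scenario, params = list(), noise = list(),
                           replicates = 1L, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory for every fixture config")
  stopifnot(is.character(scenario), length(scenario) == 1L, replicates >= 1L)
  structure(list(scenario = scenario, params = params, noise = noise,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Packaged fixture scenarios
#'
#' Named configs emulating the study conditions: a static amide powder
#' spectrum in DMPC at long (8 ms) CP contact time with a quarter of the
#' intensity in narrow isotropic lines; DipShift dephasing curves per lipid
#' and ligand state at order parameters spanning the directly excited
#' backbone range; r-PDLF doublets for the highly mobile termini; and
#' saturation, competition and negative-control binding assays.
#'
#' @param seed base seed; each scenario derives its own sub-seed from it.
#' @return Named list of [fixture_config()] objects.
#' @export
fixture_scenarios <- function(seed = 1L) {
  sc <- function(name, params, noise, reps = 1L, off = 0L)
    fixture_config(name, params, noise, reps, seed + off)
  # directly excited backbone order parameters: lipid-dependent ranges, with
  # ligand states statistically indistinguishable from apo
  s_vals <- list(popc = c(apo = 0.65, ghrelin = 0.67, inverse = 0.66),
                 dmpc = c(apo = 0.60, ghrelin = 0.62, inverse = 0.61))
  out <- list(
    dmpc_cp8ms = sc("dmpc_cp8ms",
      params = list(iso_shift = 119, span = 133, broadening = 5,
                    aniso_weight = 0.75,
                    iso_centers = c(108, 116, 124, 72, 33),
                    iso_widths  = c(2, 2, 2, 1.5, 1.5),
                    iso_weights = c(0.06, 0.06, 0.06, 0.04, 0.03),
                    axis = seq(-20, 250, by = 0.5)),
      noise = list(snr = 50), off = 1L),
    rpdlf_termini = sc("rpdlf_termini",
      params = list(S = c(peak_23ppm = 0.09, peak_40ppm = 0.05),
                    d_rigid = 21500, seq_scaling = 0.315, linewidth = 50),
      noise = list(sd = 0.01), off = 2L),
    binding_saturation = sc("binding_saturation",
      params = list(k_d = 0.15, l_total = 100, f_unbound = 100,
                    f_enhance = 1,
                    r_grid = 10^seq(-1, 3.5, length.out = 12)),
      noise = list(cv = 0.05), reps = 9L, off = 3L),
    binding_competition = sc("binding_competition",
      params = list(k_d = 0.15, l_total = 100, r_total = 3160, k_i = 10,
                    f_unbound = 100, f_enhance = 1,
                    i_grid = 10^seq(0, 8, length.out = 13)),
      noise = list(cv = 0.05), reps = 9L, off = 4L),
    npy_control = sc("npy_control",
      params = list(k_d = 0.15, l_total = 100, f_unbound = 100,
                    f_enhance = 0,
                    r_grid = 10^seq(-1, 3.5, length.out = 12)),
      noise = list(cv = 0.05), reps = 9L, off = 5L))
  off <- 6L
  for (lip in c("popc", "dmpc")) {
    for (lig in c("apo", "ghrelin", "inverse")) {
      nm <- sprintf("dipshift_%s_%s", lip, lig)
      out[[nm]] <- sc(nm,
        params = list(S = unname(s_vals[[lip]][lig]),
                      lipid = toupper(lip),
                      ligand = if (lig == "inverse") "inverse_agonist" else lig,
                      d_rigid = 21500, seq_scaling = 1 / sqrt(3),
                      mas_rate = 5000, n_t1 = 16L),
        noise = list(sd = 0.02), reps = 2L, off = off)
      off <- off + 1L
    }
  }
  out
}

#' Generate a noisy static powder spectrum with known truth
#'
#' Builds the composite lineshape (one axially symmetric anisotropic
#' component plus narrow isotropic lines) through
#' [synthesize_composite()] — the generator shares the analysis module's
#' forward model, so recovery tests probe inversion, not model mismatch —
#' and adds additive Gaussian noise with standard deviation
#' `max(signal)/snr`.
#'
#' @param config a [fixture_config()]; see the `dmpc_cp8ms` entry of
#'   [fixture_scenarios()] for the expected parameter fields.
#' @return List with `spectrum` (a [spectrum1d()]) and `truth` (the
#'   generating [lineshape_model()]).
#' @export
gen_static_spectrum <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  p <- config$params
  iso <- Map(function(cc, w, wt) list(center = cc, width = w, weight = wt),
             p$iso_centers, p$iso_widths, p$iso_weights)
  truth <- lineshape_model(
    aniso_components = list(list(tensor = csa_tensor(p$iso_shift, p$span),
                                 broadening = p$broadening,
                                 weight = p$aniso_weight)),
    iso_components = iso)
  clean <- synthesize_composite(truth, p$axis)
  snr <- config$noise$snr
  y <- clean$intensity
  if (!is.null(snr) && snr > 0) {
    sdn <- max(y) / snr
    y <- y + with_seed(config$seed, stats::rnorm(length(y), sd = sdn))
  }
  list(spectrum = spectrum1d(clean$axis, y), truth = truth)
}

#' Generate a noisy DipShift dephasing curve with known truth
#'
#' Simulates the powder-averaged dephasing via [simulate_dipshift()] at
#' `d_eff = S * seq_scaling * d_rigid` and adds additive Gaussian noise.
#' `replicates > 1` emulates independent sample preparations (distinct
#' derived seeds per replicate).
#'
#' @param config a [fixture_config()] with params `S`, `d_rigid`,
#'   `seq_scaling`, `mas_rate`, `n_t1` and noise `sd`.
#' @return List with `curves` (list of [dephasing_curve()], one per
#'   replicate), `truth` (the generating order parameter S) and `params`
#'   (the [dipolar_params()]).
#' @export
gen_dipshift_curve <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  p <- config$params
  dp <- dipolar_params(d_rigid = p$d_rigid, seq_scaling = p$seq_scaling,
                       mas_rate = p$mas_rate)
  d_eff <- p$S * dp$seq_scaling * dp$d_rigid
  clean <- simulate_dipshift(d_eff, dp, n_t1 = p$n_t1)
  sdn <- if (is.null(config$noise$sd)) 0 else config$noise$sd
  curves <- lapply(seq_len(config$replicates), function(r) {
    a <- clean$amplitude
    if (sdn > 0)
      a <- a + with_seed(config$seed + 1000L * r,
                         stats::rnorm(length(a), sd = sdn))
    a[1] <- 1  # normalization reference point is noise-free by construction
    dephasing_curve(clean$t1, a, dp$mas_rate)
  })
  list(curves = curves, truth = p$S, params = dp)
}

#' Generate a noisy r-PDLF doublet with known truth
#'
#' Simulates the doublet via [simulate_rpdlf()] and adds additive Gaussian
#' noise (`noise$sd`, in units of the unit-peak-height profile).
#'
#' @param config a [fixture_config()] with params `S` (may be a named
#'   vector; the first element is used unless `which` selects another),
#'   `d_rigid`, `seq_scaling`, `linewidth`.
#' @param which index or name into `params$S` (default 1).
#' @return List with `doublet` (an `rpdlf_doublet`), `truth` (S) and
#'   `params`.
#' @export
gen_rpdlf <- function(config, which = 1L) {
  stopifnot(inherits(config, "fixture_config"))
  p <- config$params
  S <- unname(p$S[which])
  dp <- dipolar_params(d_rigid = p$d_rigid, seq_scaling = p$seq_scaling)
  clean <- simulate_rpdlf(S, dp, linewidth = p$linewidth)
  sdn <- if (is.null(config$noise$sd)) 0 else config$noise$sd
  y <- clean$intensity
  if (sdn > 0)
    y <- y + with_seed(config$seed, stats::rnorm(length(y), sd = sdn))
  doublet <- structure(list(freq_axis = clean$freq_axis, intensity = y,
                            splitting = clean$splitting),
                       class = "rpdlf_doublet")
  list(doublet = doublet, truth = S, params = dp)
}

#' Generate a noisy fluorescence binding dataset with known truth
#'
#' Saturation mode (params contain `r_grid`): bound tracer along a receptor
#' concentration grid from the quadratic depletion model, converted to a
#' fluorescence signal normalized to the unbound baseline. Competition mode
#' (params contain `i_grid` plus `r_total` and `k_i`): bound tracer along a
#' competitor grid from the exact ternary equilibrium. Replicate columns
#' carry independent multiplicative Gaussian noise (`noise$cv`).
#'
#' @param config a [fixture_config()].
#' @return List with `data` (a [dose_response()]), `truth` (the generating
#'   [binding_model()]) and `mode` (`"saturation"` or `"competition"`).
#' @export
gen_binding <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  p <- config$params
  competition <- !is.null(p$i_grid)
  model <- binding_model(k_d = p$k_d, l_total = p$l_total,
                         r_total = if (competition) p$r_total else 0,
                         k_i = if (competition) p$k_i else NA_real_,
                         f_unbound = p$f_unbound, f_enhance = p$f_enhance)
  if (competition) {
    x <- p$i_grid
    rl <- vapply(x, function(i)
      competitive_equilibrium(p$r_total, p$l_total, i, p$k_d, p$k_i)$RL,
      numeric(1))
  } else {
    x <- p$r_grid
    rl <- bound_tracer(x, p$l_total, p$k_d)
  }
  f <- fluorescence_signal(rl, model)
  cv <- if (is.null(config$noise$cv)) 0 else config$noise$cv
  y <- with_seed(config$seed, {
    sapply(seq_len(config$replicates), function(r)
      f * (1 + if (cv > 0) stats::rnorm(length(f), sd = cv) else 0))
  })
  list(data = dose_response(x, y), truth = model,
       mode = if (competition) "competition" else "saturation")
}
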