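#' Equilibrium binding model
#'
#' Parameters of the 1:1 receptor-tracer (and optionally competitor)
#' equilibrium used throughout the fluorescence-binding analyses. The model
#' is depletion-aware: bound tracer is computed from the exact quadratic
#' mass-balance solution, not the free-ligand hyperbola, which matters
#' whenever the tracer concentration is comparable to or above its K_d.
#'
#' @param k_d tracer dissociation constant (nM), > 0.
#' @param l_total total tracer concentration (nM), >= 0. Default 100, a
#'   typical fluorescent-tracer working concentration far above a
#'   sub-nanomolar K_d.
#' @param r_total total (active) receptor concentration (nM), >= 0.
#' @param k_i competitor dissociation constant (nM), > 0, or `NA` when no
#'   competitor is modelled.
#' @param f_unbound baseline fluorescence of the unbound tracer (percent,
#'   default 100).
#' @param f_enhance maximal fractional fluorescence enhancement at full
#'   tracer occupancy (dimensionless, default 1).
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(k_d = 0.15, l_total = 100, r_total = 0,
                          k_i = NA_real_, f_unbound = 100, f_enhance = 1) {
  stopifnot(is.numeric(k_d), k_d > 0, l_total >= 0, r_total >= 0,
            f_unbound >= 0)
  if (!is.na(k_i) && k_i <= 0) stop("k_i must be > 0 when supplied")
  structure(list(k_d = k_d, l_total = l_total, r_total = r_total, k_i = k_i,
                 f_unbound = f_unbound, f_enhance = f_enhance),
            class = "binding_model")
}

#' Bound tracer under ligand depletion
#'
#' Exact 1:1 equilibrium complex concentration from the quadratic
#' mass-balance solution
#' \deqn{[RL] = \frac{(R+L+K_d) - \sqrt{(R+L+K_d)^2 - 4RL}}{2}}
#' evaluated in the numerically stable product form. Always within
#' `[0, min(R, L)]`; the `k_d = 0` limit returns the stoichiometric bound
#' `min(R, L)`.
#'
#' @param r_total total receptor (nM), >= 0; vectorized.
#' @param l_total total tracer (nM), >= 0.
#' @param k_d dissociation constant (nM), >= 0.
#' @return Complex concentration `[RL]` (nM).
#' @export
bound_tracer <- function(r_total, l_total, k_d) {
  if (any(r_total < 0) || any(l_total < 0) || any(k_d < 0))
    stop("concentrations and k_d must be >= 0")
  s <- r_total + l_total + k_d
  disc <- pmax(s^2 - 4 * r_total * l_total, 0)
  # stable form avoids cancellation when 4RL << s^2
  2 * r_total * l_total / (s + sqrt(disc))
}

#' Half-maximal receptor concentration of a depletion-limited assay
#'
#' Receptor concentration at which the bound-tracer signal reaches half its
#' maximum: `l_total/2 + k_d`. For high-affinity systems (k_d -> 0) this
#' tends to `l_total/2`, the resolution limit of a saturation assay run at
#' tracer concentrations far above K_d.
#'
#' @param l_total total tracer concentration (nM), > 0.
#' @param k_d tracer dissociation constant (nM), >= 0 (0 gives the
#'   high-affinity limit).
#' @return Half-maximal receptor concentration (nM).
#' @export
assay_limit <- function(l_total, k_d = 0) {
  if (l_total <= 0) stop("l_total must be > 0")
  if (k_d < 0) stop("k_d must be >= 0")
  l_total / 2 + k_d
}

#' Fluorescence readout of the binding model
#'
#' `F = f_unbound * (1 + f_enhance * [RL]/l_total)`: baseline fluorescence
#' of the free tracer scaled by the fractional occupancy-driven
#' enhancement. Normalizing to the unbound state (100%) leaves the curve
#' shape invariant under rescaling of `f_unbound`.
#'
#' @param rl bound tracer concentration (nM).
#' @param model a [binding_model()].
#' @return Fluorescence (same units as `f_unbound`, percent by default).
#' @export
fluorescence_signal <- function(rl, model) {
  stopifnot(inherits(model, "binding_model"))
  if (model$l_total <= 0) stop("l_total must be > 0 for a fluorescence signal")
  model$f_unbound * (1 + model$f_enhance * rl / model$l_total)
}

#' Dose-response table
#'
#' Concentration grid with one or more replicate response columns.
#'
#' @param x concentrations (nM), > 0 and strictly increasing.
#' @param y numeric matrix (or vector) of responses, rows matching `x`.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(x, y) {
  x <- as.numeric(x)
  y <- as.matrix(y)
  stopifnot(nrow(y) == length(x), ncol(y) >= 1L)
  if (any(x <= 0)) stop("concentrations must be > 0")
  if (any(diff(x) <= 0)) stop("concentrations must be strictly increasing")
  structure(list(x = x, y = y), class = "dose_response")
}

#' Fit the Hill equation to dose-response data
#'
#' Least-squares fit of
#' \deqn{y = y_{min} + \frac{y_{max} - y_{min}}{1 + (ec_{50}/x)^{n}}}
#' with the concentration handled internally on a log10 scale (the Hill
#' curve is symmetric there, which conditions the fit well). Replicates are
#' fitted jointly, not averaged first. Standard errors come from the
#' Jacobian at the optimum. Degenerate data (constant response) yield a
#' `converged = FALSE` flag, not an error.
#'
#' @param data a [dose_response()] with at least 5 distinct concentrations.
#' @param hill_fixed optional fixed Hill slope (e.g. 1); default `NULL`
#'   fits the slope freely.
#' @return List of class `hill_fit` with `ec50`, `hill_n`, `y_min`,
#'   `y_max`, standard errors `se` (named vector), `converged`, `residual_norm`.
#' @export
fit_hill <- function(data, hill_fixed = NULL) {
  stopifnot(inherits(data, "dose_response"))
  if (length(unique(data$x)) < 5L)
    stop("need at least 5 distinct concentrations")
  lx <- log10(data$x)
  yv <- as.vector(data$y)
  lxv <- rep(lx, times = ncol(data$y))
  if (stats::sd(yv) == 0 || !all(is.finite(yv))) {
    return(structure(list(ec50 = NA_real_, hill_n = NA_real_,
                          y_min = NA_real_, y_max = NA_real_, se = NULL,
                          converged = FALSE, residual_norm = NA_real_),
                     class = "hill_fit"))
  }
  ymn <- min(yv); ymx <- max(yv)
  mid <- (ymn + ymx) / 2
  lec0 <- lx[which.min(abs(rowMeans(data$y) - mid))]
  p0 <- list(y_min = ymn, y_max = ymx, lec50 = lec0)
  if (is.null(hill_fixed)) p0$hill_n <- 1
  resid_fn <- function(p) {
    n <- if (is.null(hill_fixed)) p$hill_n else hill_fixed
    p$y_min + (p$y_max - p$y_min) / (1 + 10^((p$lec50 - lxv) * n)) - yv
  }
  fit <- try(minpack.lm::nls.lm(par = p0, fn = resid_fn,
             control = minpack.lm::nls.lm.control(maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) {
    return(structure(list(ec50 = NA_real_, hill_n = NA_real_,
                          y_min = NA_real_, y_max = NA_real_, se = NULL,
                          converged = FALSE, residual_norm = NA_real_),
                     class = "hill_fit"))
  }
  p <- fit$par
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  structure(list(ec50 = 10^p$lec50,
                 hill_n = if (is.null(hill_fixed)) p$hill_n else hill_fixed,
                 y_min = p$y_min, y_max = p$y_max, se = se,
                 converged = TRUE, residual_norm = sqrt(fit$deviance)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) { cat("Hill fit: NOT converged\n"); return(invisible(x)) }
  cat(sprintf("Hill fit: EC50 = %.3g nM, n = %.2f, plateaus %.1f..%.1f\n",
              x$ec50, x$hill_n, x$y_min, x$y_max))
  invisible(x)
}

#' Cheng-Prusoff conversion of an IC50 to a K_i
#'
#' `K_i = IC50 / (1 + l_total/k_d)`: corrects a competition IC50 for the
#' occupancy shift caused by the tracer. Valid when receptor depletion is
#' negligible; see [ki_from_ic50()] for the exact depletion-aware
#' inversion.
#'
#' @param ic50 half-maximal displacement concentration (nM), > 0.
#' @param l_total total tracer concentration (nM), > 0.
#' @param k_d tracer dissociation constant (nM), > 0.
#' @return K_i (nM).
#' @export
cheng_prusoff <- function(ic50, l_total, k_d) {
  stopifnot(ic50 > 0, l_total > 0, k_d > 0)
  ic50 / (1 + l_total / k_d)
}

#' Exact ternary competition equilibrium
#'
#' Solves the coupled mass balances of receptor R, tracer L and competitor
#' I with `[RL] = [R][L]/K_d` and `[RI] = [R][I]/K_i` by a bracketed
#' one-dimensional root in free `[R]`, followed by Newton polishing until
#' the receptor mass balance closes to better than 1e-10 relative. This is
#' the exact arithmetic behind depletion-corrected competition analysis: it
#' subsumes both the Cheng-Prusoff occupancy shift and tracer/receptor
#' depletion.
#'
#' @param r_total,l_total,i_total total concentrations (nM), >= 0.
#' @param k_d,k_i dissociation constants (nM), > 0 (`k_i = Inf` switches
#'   the competitor off).
#' @return List with free `R`, `L`, `I` and complexes `RL`, `RI` (nM), plus
#'   `residual` (worst relative mass-balance error).
#' @export
competitive_equilibrium <- function(r_total, l_total, i_total, k_d, k_i) {
  stopifnot(r_total >= 0, l_total >= 0, i_total >= 0, k_d > 0, k_i > 0)
  if (r_total == 0) {
    return(list(R = 0, L = l_total, I = i_total, RL = 0, RI = 0, residual = 0))
  }
  comp <- is.finite(k_i)
  # receptor mass balance as a function of free R (strictly increasing)
  f <- function(R) {
    R + l_total * (R / k_d) / (1 + R / k_d) +
      (if (comp) i_total * (R / k_i) / (1 + R / k_i) else 0) - r_total
  }
  fprime <- function(R) {
    1 + l_total / k_d / (1 + R / k_d)^2 +
      (if (comp) i_total / k_i / (1 + R / k_i)^2 else 0)
  }
  root <- stats::uniroot(f, c(0, r_total), tol = .Machine$double.eps^0.75)$root
  for (it in 1:8) {                         # Newton polish
    step <- f(root) / fprime(root)
    root <- max(root - step, 0)
    if (abs(step) < 1e-14 * max(root, 1)) break
  }
  R <- root
  L <- l_total / (1 + R / k_d)
  I <- if (comp) i_total / (1 + R / k_i) else i_total
  RL <- R * L / k_d
  RI <- if (comp) R * I / k_i else 0
  res <- max(abs(R + RL + RI - r_total) / max(r_total, 1e-300),
             abs(L + RL - l_total) / max(l_total, 1e-300),
             if (i_total > 0) abs(I + RI - i_total) / i_total else 0)
  if (res > 1e-10)
    stop(sprintf("equilibrium solver failed: relative mass-balance residual %.3g (R=%g, L=%g, I=%g)",
                 res, r_total, l_total, i_total))
  list(R = R, L = L, I = I, RL = RL, RI = RI, residual = res)
}

#' IC50 predicted by the depletion-aware competition model
#'
#' Competitor concentration at which bound tracer `[RL]` falls to half its
#' competitor-free value, found by a monotone bracketed root on a log
#' concentration scale over `[1e-6, 1e9]` nM. `[RL]` is strictly
#' decreasing in `i_total`, so the crossing (when the competitor is potent
#' enough to reach it within the search range) is unique.
#'
#' @param model a [binding_model()] with finite `k_i` and `r_total > 0`.
#' @return IC50 (nM).
#' @export
ic50_from_model <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  if (!is.finite(model$k_i)) stop("model needs a finite k_i")
  if (model$r_total <= 0 || model$l_total <= 0)
    stop("model needs r_total > 0 and l_total > 0")
  rl0 <- competitive_equilibrium(model$r_total, model$l_total, 0,
                                 model$k_d, model$k_i)$RL
  g <- function(log_i) {
    competitive_equilibrium(model$r_total, model$l_total, 10^log_i,
                            model$k_d, model$k_i)$RL - rl0 / 2
  }
  lo <- -6; hi <- 9
  if (g(hi) > 0)
    stop("bound tracer never falls to half-maximum within the search range ",
         "[1e-6, 1e9] nM; competitor too weak")
  10^stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' IC50 measured directly from displacement data
#'
#' Half-displacement concentration of a measured competition curve: the
#' point where the replicate-mean response crosses midway between its upper
#' plateau (lowest competitor concentration) and lower plateau (highest
#' concentration), located by monotone linear interpolation on a log10
#' concentration scale. Under strong receptor/tracer depletion the
#' displacement curve is not Hill-shaped, so this direct estimator is
#' preferred over a Hill-fit EC50 for feeding [ki_from_ic50()].
#'
#' @param data a [dose_response()] competition dataset whose concentration
#'   range covers both plateaus.
#' @return IC50 (nM).
#' @export
ic50_from_data <- function(data) {
  stopifnot(inherits(data, "dose_response"))
  ym <- rowMeans(data$y)
  mid <- (ym[1] + ym[length(ym)]) / 2
  below <- which(ym <= mid)
  if (length(below) == 0L || below[1] == 1L)
    stop("response never crosses half-displacement within the data range")
  j <- below[1]; i <- j - 1L
  lx <- log10(data$x)
  10^(lx[i] + (mid - ym[i]) / (ym[j] - ym[i]) * (lx[j] - lx[i]))
}

#' Fit the depletion-aware competition model to displacement data
#'
#' Least-squares fit of the exact ternary-equilibrium fluorescence curve to
#' measured displacement replicates, over `log10(k_i)` and (optionally) the
#' maximal fluorescence enhancement. Because every data point constrains
#' the fit — not just the half-displacement crossing — this estimator is
#' far more precise than converting a single interpolated IC50, especially
#' under strong depletion where the curve is not Hill-shaped.
#'
#' @param data a [dose_response()] competition dataset (x = competitor
#'   concentration, nM).
#' @param model a [binding_model()] fixing `k_d`, `l_total`, `r_total`,
#'   `f_unbound`; its `k_i` (if finite) seeds the optimizer.
#' @param fit_enhance also fit `f_enhance` (default `TRUE`).
#' @return List of class `competition_fit` with `k_i`, `f_enhance`,
#'   `converged`, `residual_norm` and the implied model `ic50`.
#' @export
fit_competition <- function(data, model, fit_enhance = TRUE) {
  stopifnot(inherits(data, "dose_response"), inherits(model, "binding_model"))
  yv <- as.vector(data$y)
  xrep <- rep(data$x, times = ncol(data$y))
  pred <- function(ki, fe) {
    rl <- vapply(data$x, function(i)
      competitive_equilibrium(model$r_total, model$l_total, i,
                              model$k_d, ki)$RL, numeric(1))
    m <- model; m$f_enhance <- fe
    rep(fluorescence_signal(rl, m), times = ncol(data$y))
  }
  p0 <- list(lki = log10(if (is.finite(model$k_i)) model$k_i else 10))
  if (fit_enhance) p0$fe <- model$f_enhance
  fit <- minpack.lm::nls.lm(par = p0, fn = function(p)
    pred(10^p$lki, if (fit_enhance) p$fe else model$f_enhance) - yv,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  ki <- 10^fit$par$lki
  fe <- if (fit_enhance) fit$par$fe else model$f_enhance
  m2 <- model; m2$k_i <- ki; m2$f_enhance <- fe
  ic50 <- tryCatch(ic50_from_model(m2), error = function(e) NA_real_)
  structure(list(k_i = ki, f_enhance = fe,
                 converged = fit$info %in% 1:4,
                 residual_norm = sqrt(fit$deviance), ic50 = ic50),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Competition fit: K_i = %.4g nM (model IC50 %.4g nM)%s\n",
              x$k_i, x$ic50, if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' K_i from a measured IC50 under the exact depletion model
#'
#' Inverts [ic50_from_model()] by a bracketed root in `log10(k_i)`: the
#' returned `k_i` is the competitor affinity whose depletion-aware
#' competition curve crosses half-maximal bound tracer at the observed
#' IC50. The simple [cheng_prusoff()] value is reported alongside for
#' comparison; the two agree in the no-depletion regime and diverge when
#' receptor consumes a significant fraction of tracer or competitor.
#'
#' @param ic50 measured half-displacement concentration (nM), > 0.
#' @param model a [binding_model()] supplying `k_d`, `l_total`, `r_total`.
#' @return List of class `ki_result` with `k_i` (depletion-corrected, nM)
#'   and `k_i_cheng_prusoff` (nM).
#' @export
ki_from_ic50 <- function(ic50, model) {
  stopifnot(inherits(model, "binding_model"), ic50 > 0)
  h <- function(log_ki) {
    m <- model; m$k_i <- 10^log_ki
    log10(ic50_from_model(m)) - log10(ic50)
  }
  # IC50 >= k_i always (the occupancy shift and depletion only inflate it),
  # so k_i = ic50 is a safe upper bracket; a k_i too weak to reach
  # half-displacement within the model's search range sits above the root,
  # so such failures count as a (large) positive sign
  h_safe <- function(log_ki) tryCatch(h(log_ki), error = function(e) 1e6)
  lo <- -6; hi <- log10(ic50)
  flo <- tryCatch(h(lo), error = function(e) NA_real_)
  if (!is.finite(flo) || flo > 0 || h_safe(hi) < 0)
    stop("could not bracket k_i in [1e-6, ", signif(ic50, 3),
         "] nM for IC50 = ", ic50, " nM")
  ki <- 10^stats::uniroot(h_safe, c(lo, hi), tol = 1e-12)$root
  structure(list(k_i = ki,
                 k_i_cheng_prusoff = cheng_prusoff(ic50, model$l_total,
                                                   model$k_d)),
            class = "ki_result")
}

#' @export
print.ki_result <- function(x, ...) {
  cat(sprintf("K_i (depletion-corrected): %.4g nM\nK_i (Cheng-Prusoff):       %.4g nM\n",
              x$k_i, x$k_i_cheng_prusoff))
  invisible(x)
}
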