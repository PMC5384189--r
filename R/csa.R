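#' Motionally averaged chemical-shift tensor
#'
#' Container for the parameters of a (possibly motionally averaged)
#' chemical-shift-anisotropy tensor in the axial convention used throughout
#' the package: the observable shift at polar angle beta between the tensor
#' symmetry axis and the magnetic field is
#' \deqn{\sigma(\beta) = \sigma_{iso} + \Delta\sigma (3\cos^2\beta - 1)/3}
#' where `span` is \eqn{\Delta\sigma = \sigma_\parallel - \sigma_\perp}.
#' For `asymmetry != 0` the standard secular expression with the azimuthal
#' term is used (see [csa_shift()]).
#'
#' A positive span puts the parallel edge downfield of the isotropic shift;
#' negative spans are allowed and mirror the powder pattern about
#' `iso_shift`.
#'
#' @param iso_shift isotropic chemical shift (ppm), finite.
#' @param span tensor span \eqn{\Delta\sigma = \sigma_\parallel -
#'   \sigma_\perp} (ppm); may be negative.
#' @param asymmetry asymmetry parameter \eqn{\eta \in [0, 1]}; 0 for an
#'   axially symmetric tensor, as produced by fast axial rotational
#'   diffusion of a membrane protein.
#' @return An object of class `csa_tensor`.
#' @examples
#' csa_tensor(iso_shift = 119, span = 133)
#' @export
csa_tensor <- function(iso_shift, span, asymmetry = 0) {
  stopifnot(is.numeric(iso_shift), length(iso_shift) == 1L, is.finite(iso_shift),
            is.numeric(span), length(span) == 1L, is.finite(span),
            is.numeric(asymmetry), length(asymmetry) == 1L)
  if (asymmetry < 0 || asymmetry > 1)
    stop("asymmetry (eta) must lie in [0, 1], got ", asymmetry)
  structure(list(iso_shift = iso_shift, span = span, asymmetry = asymmetry),
            class = "csa_tensor")
}

#' @export
print.csa_tensor <- function(x, ...) {
  cat(sprintf("CSA tensor: iso %.2f ppm, span %.2f ppm, eta %.3f\n",
              x$iso_shift, x$span, x$asymmetry))
  invisible(x)
}

#' One-dimensional spectrum
#'
#' A chemical-shift axis (ppm) with matching intensities. The axis is stored
#' in its given (strictly monotone) order; integration via [spectrum_area()]
#' always uses the stored order. NMR-style display with the axis reversed is
#' a plotting concern only.
#'
#' @param axis chemical-shift grid (ppm), strictly monotone.
#' @param intensity intensities (a.u.), same length as `axis`, finite.
#' @return An object of class `spectrum1d` (a list with `axis`, `intensity`).
#' @export
spectrum1d <- function(axis, intensity) {
  axis <- as.numeric(axis); intensity <- as.numeric(intensity)
  if (length(axis) < 2L) stop("axis must have at least two points")
  if (length(axis) != length(intensity))
    stop("axis and intensity lengths differ")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("axis must be strictly monotone")
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  structure(list(axis = axis, intensity = intensity), class = "spectrum1d")
}

#' Trapezoidal area of a spectrum
#'
#' @param spectrum a [spectrum1d()] object.
#' @return Trapezoidal integral over the stored axis order (positive for an
#'   ascending axis).
#' @export
spectrum_area <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  trapz_area(spectrum$axis, spectrum$intensity)
}

trapz_area <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Deterministic powder-orientation grid
#'
#' Orientation grid uniform in cos(beta) (equal solid-angle weights) crossed
#' with a uniform azimuth grid. Deterministic by construction so powder
#' averages are exactly reproducible and checkable against analytic
#' densities. Midpoint placement avoids the beta = 0 and beta = 90 degree
#' singular orientations.
#'
#' @param n_beta number of cos(beta) points (default 512).
#' @param n_gamma number of azimuth points (default 64); only consulted by
#'   operations whose integrand depends on gamma.
#' @return List with `cos_beta`, `gamma` and the constructor arguments.
#' @export
powder_scheme <- function(n_beta = 512L, n_gamma = 64L) {
  stopifnot(n_beta >= 1L, n_gamma >= 1L)
  list(cos_beta = (seq_len(n_beta) - 0.5) / n_beta,
       gamma = 2 * pi * (seq_len(n_gamma) - 0.5) / n_gamma,
       n_beta = as.integer(n_beta), n_gamma = as.integer(n_gamma))
}

#' Orientation-dependent chemical shift
#'
#' Secular chemical shift of a tensor at orientation (beta, gamma):
#' \deqn{\sigma = \sigma_{iso} + \frac{\Delta\sigma}{3}\left[(3\cos^2\beta -
#' 1) - \eta \sin^2\beta \cos 2\gamma\right]}
#' For an axially symmetric tensor (eta = 0) the result is independent of
#' `gamma` and reduces to \eqn{\sigma_{iso} + \Delta\sigma(3\cos^2\beta-1)/3}.
#'
#' @param tensor a [csa_tensor()].
#' @param cos_beta cosine of the polar angle; must satisfy `|cos_beta| <= 1`.
#' @param gamma azimuthal angle (rad); ignored when eta = 0.
#' @return Chemical shift(s) in ppm, recycled over the longer of the two
#'   orientation arguments.
#' @export
csa_shift <- function(tensor, cos_beta, gamma = 0) {
  stopifnot(inherits(tensor, "csa_tensor"))
  if (any(abs(cos_beta) > 1)) stop("|cos_beta| must not exceed 1")
  c2 <- cos_beta^2
  out <- tensor$iso_shift + tensor$span / 3 *
    ((3 * c2 - 1) - tensor$asymmetry * (1 - c2) * cos(2 * gamma))
  out
}

#' Powder-averaged CSA lineshape
#'
#' Averages [csa_shift()] over the orientation grid of `scheme`, bins the
#' resulting shift distribution onto `axis` (linear weight splitting between
#' neighbouring grid points) and convolves with a broadening kernel. The
#' output is normalized to unit trapezoidal area. For eta = 0 and small
#' broadening the maximum sits at the perpendicular edge
#' `iso_shift - span/3`, where the analytic frequency density
#' \eqn{p(\sigma) \propto [\Delta\sigma(\sigma-\sigma_\perp)]^{-1/2}}
#' diverges.
#'
#' @param tensor a [csa_tensor()].
#' @param axis shift grid (ppm), strictly monotone; should cover the full
#'   pattern support plus a few broadening widths.
#' @param broadening kernel width (ppm, Gaussian standard deviation or
#'   Lorentzian half-width at half-maximum), > 0.
#' @param scheme a [powder_scheme()]; the azimuth grid is only used when
#'   eta != 0.
#' @param kernel broadening kernel: Gaussian (default, typical for rigid
#'   inhomogeneously broadened sites) or Lorentzian.
#' @return A [spectrum1d()] of unit area.
#' @export
powder_pattern <- function(tensor, axis, broadening,
                           scheme = powder_scheme(),
                           kernel = c("gaussian", "lorentzian")) {
  stopifnot(inherits(tensor, "csa_tensor"))
  kernel <- match.arg(kernel)
  if (length(axis) < 2L) stop("axis must have at least two points")
  if (!is.numeric(broadening) || broadening <= 0)
    stop("broadening must be > 0")
  if (length(scheme$cos_beta) < 1L) stop("powder scheme must be non-empty")
  asc <- axis[1] < axis[length(axis)]
  ax <- if (asc) axis else rev(axis)

  if (tensor$asymmetry == 0) {
    shifts <- csa_shift(tensor, scheme$cos_beta)
    w <- rep(1 / length(shifts), length(shifts))
  } else {
    ori <- expand.grid(cb = scheme$cos_beta, g = scheme$gamma)
    shifts <- csa_shift(tensor, ori$cb, ori$g)
    w <- rep(1 / length(shifts), length(shifts))
  }
  hist_w <- bin_linear(shifts, w, ax)
  y <- convolve_kernel(ax, hist_w, broadening, kernel)
  a <- trapz_area(ax, y)
  if (a <= 0) stop("powder pattern has zero area on the supplied axis; ",
                   "axis does not cover the pattern support")
  y <- y / a
  spectrum1d(axis, if (asc) y else rev(y))
}

# Split each sample's weight linearly between the two bracketing axis points.
bin_linear <- function(x, w, ax) {
  n <- length(ax)
  out <- numeric(n)
  idx <- findInterval(x, ax)
  for (k in seq_along(x)) {
    i <- idx[k]
    if (i < 1L || i >= n) {
      # clamp onto end bins so no intensity is silently lost at the edges
      j <- max(1L, min(n, i))
      if (i >= 1L && i <= n) out[j] <- out[j] + w[k]
      next
    }
    f <- (x[k] - ax[i]) / (ax[i + 1L] - ax[i])
    out[i] <- out[i] + w[k] * (1 - f)
    out[i + 1L] <- out[i + 1L] + w[k] * f
  }
  out
}

convolve_kernel <- function(ax, hist_w, width, kernel) {
  nz <- which(hist_w > 0)
  y <- numeric(length(ax))
  for (i in nz) {
    d <- ax - ax[i]
    y <- y + hist_w[i] * switch(kernel,
      gaussian   = exp(-d^2 / (2 * width^2)),
      lorentzian = 1 / (1 + (d / width)^2))
  }
  y
}

#' Analytic powder density for an axially symmetric tensor
#'
#' Closed-form frequency density of the eta = 0 powder average,
#' \eqn{p(\sigma) = [4\Delta\sigma(\sigma - \sigma_\perp)]^{-1/2} \cdot 2}
#' on the support between the perpendicular edge
#' \eqn{\sigma_\perp = \sigma_{iso} - \Delta\sigma/3} and the parallel edge
#' \eqn{\sigma_\parallel = \sigma_{iso} + 2\Delta\sigma/3}, zero outside.
#' Serves as the independent oracle for [powder_pattern()].
#'
#' @param tensor a [csa_tensor()] with `asymmetry == 0`.
#' @param sigma shift values (ppm) at which to evaluate the density.
#' @return Density values (1/ppm), normalized to unit integral over the
#'   support.
#' @export
powder_density_axial <- function(tensor, sigma) {
  stopifnot(inherits(tensor, "csa_tensor"))
  if (tensor$asymmetry != 0) stop("analytic density requires eta = 0")
  if (tensor$span == 0) stop("analytic density undefined for zero span")
  s_perp <- tensor$iso_shift - tensor$span / 3
  u <- (sigma - s_perp) / tensor$span       # = cos^2(beta) on the support
  p <- numeric(length(sigma))
  ok <- u > 0 & u <= 1
  p[ok] <- 1 / (2 * abs(tensor$span) * sqrt(u[ok]))
  p
}
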