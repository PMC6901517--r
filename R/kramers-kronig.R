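#' Kramers-Kronig reconstruction of the real part
#'
#' Causality ties the two quadratures of any response spectrum together:
#' \deqn{\tilde R'(\omega) = \frac{2}{\pi} \,\mathrm{P}\!\!\int_0^\infty
#'   \tilde R''(\omega_1)\, \frac{\omega_1}{\omega_1^2 - \omega^2}\,
#'   \mathrm{d}\omega_1.}
#' The principal value is handled by singularity subtraction: with
#' \eqn{g(\omega_1) = \omega_1 \tilde R''(\omega_1)}, the integrand is split
#' into the regular part \eqn{(g(\omega_1)-g(\omega))/(\omega_1^2-\omega^2)}
#' (trapezoid quadrature, removable singularity filled by the derivative of
#' \eqn{g}) and \eqn{g(\omega)\,\mathrm{P}\!\int \mathrm{d}\omega_1/
#' (\omega_1^2-\omega^2)}, which integrates in closed form.  A node at
#' \eqn{\omega_1 = 0} with \eqn{g = 0} is prepended (the imaginary part is
#' odd).  Beyond the grid the imaginary part is extrapolated as a power-law
#' decay fitted to the trailing decade; if no decaying power law fits, the
#' tail is dropped and the result flagged.
#'
#' @param omega positive increasing grid.
#' @param imag_part \eqn{\tilde R''} on the grid (or a
#'   [response_spectrum()], in which case its imaginary part is used).
#' @param tail_factor extend the grid geometrically up to
#'   `tail_factor * max(omega)` for the fitted tail (default 50).
#' @return list with `omega`, `real` (the reconstruction), `err` (half-grid
#'   refinement estimate) and `tail_ok` (FALSE flags an accuracy warning:
#'   undecayed imaginary part with no usable power-law tail).
#' @export
kramers_kronig <- function(omega, imag_part, tail_factor = 50) {
  if (inherits(omega, "dqs_spectrum")) {
    imag_part <- Im(omega$value); omega <- omega$omega
  }
  n <- length(omega)
  if (n < 8) stop_config("grid too coarse for Kramers-Kronig quadrature")

  # power-law tail fit on the trailing decade
  tail_ok <- TRUE
  itail <- which(omega >= max(omega) / 3)
  if (length(itail) < 4) itail <- seq(n - 3, n)
  yt <- imag_part[itail]
  w_ext <- numeric(0); im_ext <- numeric(0)
  decayed <- abs(imag_part[n]) <= 0.01 * max(abs(imag_part))
  if (all(yt > 0) || all(yt < 0)) {
    fit <- stats::lm(log(abs(yt)) ~ log(omega[itail]))
    p <- coef(fit)[2]
    if (is.finite(p) && p < -0.5) {
      w_ext <- max(omega) * exp(seq(0.01, log(tail_factor), length.out = 200))
      im_ext <- sign(yt[1]) * exp(coef(fit)[1]) * w_ext^p
    } else if (!decayed) tail_ok <- FALSE
  } else if (!decayed) tail_ok <- FALSE

  wq <- c(0, omega, w_ext)
  gq <- c(0, omega * imag_part, w_ext * im_ext)
  # derivative of g on the quadrature grid (for the removable singularity)
  dg <- c(diff(gq) / diff(wq), 0)

  eval_at <- function(w, wqs, gqs, dgs) {
    denom <- wqs^2 - w^2
    gw <- stats::approx(wqs, gqs, w, rule = 2)$y
    reg <- (gqs - gw) / denom
    # nodes coinciding with w: removable singularity, fill with g'(w)/(2w)
    i <- which(abs(wqs - w) < 1e-9 * max(w, 1e-300))
    if (length(i)) reg[i] <- dgs[pmax(1, i - 1)] / (2 * w)
    wmax <- max(wqs)
    pv <- if (gw == 0) 0 else
      (1 / (2 * w)) * (log(abs((wmax - w) / (wmax + w))) -
                         log(abs((0 - w) / (0 + w))))
    out <- (2 / pi) * (trapz(wqs, reg) + gw * pv)
    if (!is.finite(out)) NA_real_ else out
  }

  interior <- omega > min(omega) & omega < max(omega)
  real_part <- vapply(omega, eval_at, numeric(1), wqs = wq, gqs = gq, dgs = dg)

  # half-resolution refinement error estimate
  keep <- unique(c(seq(1, length(wq), by = 2), length(wq)))
  dgh <- c(diff(gq[keep]) / diff(wq[keep]), 0)
  real_half <- vapply(omega, eval_at, numeric(1),
                      wqs = wq[keep], gqs = gq[keep], dgs = dgh)
  list(omega = omega, real = real_part, err = abs(real_part - real_half),
       interior = interior, tail_ok = tail_ok)
}
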