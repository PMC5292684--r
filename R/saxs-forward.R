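#' Bead (pseudo-residue) model
#'
#' A dummy-atom representation of a particle: bead coordinates in Angstrom
#' with optional per-bead scattering weights (point scatterers, no form
#' factors or hydration layer).
#'
#' @param coords numeric matrix, one row per bead, columns x/y/z in Angstrom
#' @param weights per-bead scattering weight (recycled); default 1
#' @return an object of class `bead_model`
#' @export
bead_model <- function(coords, weights = 1) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  weights <- rep_len(weights, nrow(coords))
  structure(list(coords = coords, weights = weights), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead model: %d beads, total weight %.3g\n",
              nrow(x$coords), sum(x$weights)))
  invisible(x)
}

pairwise_dw <- function(model) {
  n <- nrow(model$coords)
  d <- as.numeric(stats::dist(model$coords))
  w <- model$weights
  # dist() pair order: j = 1..n-1, i = (j+1)..n
  j <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  i <- sequence((n - 1L):1L, from = 2L:n)
  list(d = d, ww = w[i] * w[j])
}

#' Scattering intensity of a bead model by the Debye formula
#'
#' \deqn{I(q) = \sum_i \sum_j w_i w_j \frac{\sin(q d_{ij})}{q d_{ij}}}
#' with the \eqn{q \to 0} limit handled analytically
#' (\eqn{I(0) = (\sum_i w_i)^2}).
#'
#' @param model a [bead_model()]
#' @param q scattering-vector grid, 1/Angstrom (`q = 4 pi sin(theta)/lambda`)
#' @return a data frame of class `scattering_curve`: `q`, `I`, `sigma` (NA)
#' @export
debye_curve <- function(model, q = seq(0.008, 0.5, length.out = 200)) {
  stopifnot(inherits(model, "bead_model"), all(q >= 0), !is.unsorted(q, strictly = TRUE))
  n <- nrow(model$coords)
  wtot2 <- sum(model$weights)^2
  if (n < 2L) {
    warning("single-bead model: flat scattering curve")
    return(scattering_curve(q, rep(wtot2, length(q))))
  }
  pw <- pairwise_dw(model)
  self <- sum(model$weights^2)
  I <- vapply(q, function(qi) {
    if (qi == 0) return(wtot2)
    x <- qi * pw$d
    self + 2 * sum(pw$ww * sin(x) / x)
  }, numeric(1))
  scattering_curve(q, I)
}

#' Construct a scattering curve
#'
#' @param q scattering vector, 1/Angstrom, strictly increasing, >= 0
#' @param I intensity, arbitrary units
#' @param sigma per-point error (NA if unknown)
#' @return a data frame of class `scattering_curve`
#' @export
scattering_curve <- function(q, I, sigma = NA_real_) {
  stopifnot(length(q) == length(I), all(q >= 0),
            !is.unsorted(q, strictly = TRUE))
  structure(data.frame(q = q, I = I, sigma = rep_len(sigma, length(q))),
            class = c("scattering_curve", "data.frame"))
}

#' Pair-distance distribution of a bead model
#'
#' Histogram of all weighted pairwise distances. `Dmax` is the exact maximum
#' pairwise distance (no smoothing or extrapolation); the radius of gyration
#' follows from \eqn{R_g^2 = \int r^2 P(r) dr / (2 \int P(r) dr)}.
#'
#' @param model a [bead_model()]
#' @param bin_width histogram bin width, Angstrom
#' @return an object of class `pair_distribution`: `r` (bin midpoints), `p`,
#'   plus `rg` and `dmax`
#' @export
pr_from_beads <- function(model, bin_width = 1) {
  stopifnot(inherits(model, "bead_model"), bin_width > 0,
            nrow(model$coords) >= 2L)
  pw <- pairwise_dw(model)
  dmax <- max(pw$d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  bin <- findInterval(pw$d, breaks, rightmost.closed = TRUE)
  p <- vapply(seq_len(length(breaks) - 1L),
              function(b) sum(pw$ww[bin == b]), numeric(1))
  r <- breaks[-length(breaks)] + bin_width / 2
  # Rg^2 = sum_{i<j} w_i w_j d_ij^2 / W^2, the discrete form of
  # int r^2 P dr / (2 int P dr) with the self-pair weight in the norm
  rg <- sqrt(sum(r^2 * p)) / sum(model$weights)
  structure(list(r = r, p = p, rg = rg, dmax = dmax, bin_width = bin_width),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("P(r): %d bins of %.2g A, Rg = %.2f A, Dmax = %.2f A\n",
              length(x$r), x$bin_width, x$rg, x$dmax))
  invisible(x)
}

#' Rg and Dmax of a pair distribution
#'
#' @param pr a [pr_from_beads()] result
#' @return named vector `c(rg =, dmax =)` in Angstrom
#' @export
rg_dmax <- function(pr) {
  stopifnot(inherits(pr, "pair_distribution"))
  c(rg = pr$rg, dmax = pr$dmax)
}

#' Radius of gyration directly from coordinates
#'
#' Weighted root-mean-square distance from the centroid; the reference
#' definition against which the P(r)-derived Rg is checked.
#'
#' @param model a [bead_model()]
#' @return Rg in Angstrom
#' @export
rg_from_coords <- function(model) {
  w <- model$weights / sum(model$weights)
  ctr <- colSums(model$coords * w)
  sq <- rowSums(sweep(model$coords, 2L, ctr)^2)
  sqrt(sum(w * sq))
}

#' Chi agreement score between an experimental and a calculated curve
#'
#' \deqn{\chi = \sqrt{\frac{1}{N}\sum_q \left(\frac{I_{exp}(q) -
#'   I_{calc}(q)}{\sigma(q)}\right)^2}}
#' The calculated curve is interpolated onto the experimental q grid. With
#' `fit_scale = TRUE` (the convention of the standard scoring tools) a single
#' multiplicative factor on `I_calc` minimising chi is applied first and
#' reported in the `"scale"` attribute.
#'
#' @param exp_curve,calc_curve `scattering_curve` objects; `exp_curve` must
#'   carry positive `sigma` everywhere
#' @param fit_scale fit a multiplicative scale factor on the calculated curve
#' @return chi (dimensionless), with attribute `scale`
#' @export
chi_score <- function(exp_curve, calc_curve, fit_scale = TRUE) {
  stopifnot(inherits(exp_curve, "scattering_curve"),
            inherits(calc_curve, "scattering_curve"))
  bad <- which(is.na(exp_curve$sigma) | exp_curve$sigma <= 0)
  if (length(bad))
    stop("non-positive sigma at q = ",
         paste(signif(exp_curve$q[bad[seq_len(min(3, length(bad)))]], 3),
               collapse = ", "))
  if (min(calc_curve$q) > min(exp_curve$q) ||
      max(calc_curve$q) < max(exp_curve$q))
    stop("calculated curve does not cover the experimental q range")
  ic <- stats::approx(calc_curve$q, calc_curve$I, xout = exp_curve$q)$y
  s <- 1
  if (fit_scale) {
    w <- 1 / exp_curve$sigma^2
    s <- sum(w * exp_curve$I * ic) / sum(w * ic^2)
  }
  chi <- sqrt(mean(((exp_curve$I - s * ic) / exp_curve$sigma)^2))
  attr(chi, "scale") <- s
  chi
}

#' Guinier estimate of the radius of gyration
#'
#' Linear fit of \eqn{\ln I} versus \eqn{q^2} over the region
#' \eqn{q R_g < } `qmax_rg` (determined iteratively);
#' \eqn{R_g = \sqrt{-3 \times slope}}.
#'
#' @param curve a `scattering_curve`
#' @param qmax_rg upper limit of the dimensionless product `q * Rg`
#' @param min_points minimum usable points in the Guinier region
#' @return list: `rg`, `i0`, `q_range`, `n_points`, `nonlinear` flag (set
#'   when the region shows systematic curvature)
#' @export
guinier_rg <- function(curve, qmax_rg = 1.3, min_points = 5) {
  stopifnot(inherits(curve, "scattering_curve"))
  pos <- curve$I > 0
  q <- curve$q[pos]; I <- curve$I[pos]
  # initial slope from the first few points, then iterate the q*Rg cut
  use <- seq_len(min(10L, length(q)))
  rg <- NA_real_
  for (it in 1:20) {
    fit <- stats::lm(log(I[use]) ~ I(q[use]^2))
    slope <- stats::coef(fit)[[2L]]
    if (slope >= 0) stop("no Guinier decay: non-negative slope")
    rg_new <- sqrt(-3 * slope)
    use_new <- which(q * rg_new < qmax_rg)
    if (length(use_new) < min_points)
      stop("fewer than ", min_points, " points with q*Rg < ", qmax_rg)
    if (!is.na(rg) && abs(rg_new - rg) < 1e-6 * rg) { rg <- rg_new; use <- use_new; break }
    rg <- rg_new; use <- use_new
  }
  fit <- stats::lm(log(I[use]) ~ I(q[use]^2))
  res <- stats::residuals(fit)
  # systematic curvature: residuals correlated with q^4
  nonlinear <- length(use) > 6 &&
    abs(stats::cor(res, q[use]^4)) > 0.9 && stats::sd(res) > 5e-3
  if (nonlinear) warning("Guinier region shows systematic curvature")
  list(rg = rg, i0 = exp(stats::coef(fit)[[1L]]),
       q_range = range(q[use]), n_points = length(use),
       nonlinear = nonlinear)
}
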