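#' Kinetic parameters of the 1:1 transport-limited binding model
#'
#' Container for the parameters of the two-compartment mass-transport-limited
#' Langmuir model used throughout the SPR module:
#' \deqn{dR/dt = \frac{k_{on} C (R_{max} - R) - k_{off} R}{1 + k_{on}(R_{max} - R)/k_t}}
#' During dissociation the same equation applies with \eqn{C = 0}; a finite
#' transport coefficient \eqn{k_t} then slows the apparent release (rebinding).
#' \eqn{k_t = Inf} recovers the ideal Langmuir model.
#'
#' @param k_on association rate constant, 1/(M s); must be > 0
#' @param k_off dissociation rate constant, 1/s; must be >= 0
#' @param r_max surface capacity, resonance units (RU); must be > 0
#' @param k_t mass-transport coefficient, RU/(M s); > 0, `Inf` = no
#'   transport limitation
#' @return an object of class `kinetic_params`
#' @export
kinetic_params <- function(k_on, k_off = 2e-4, r_max = 1000, k_t = Inf) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L, is.finite(k_on), k_on > 0)
  stopifnot(is.numeric(k_off), length(k_off) == 1L, is.finite(k_off), k_off >= 0)
  stopifnot(is.numeric(r_max), length(r_max) == 1L, is.finite(r_max), r_max > 0)
  stopifnot(is.numeric(k_t), length(k_t) == 1L, k_t > 0)
  structure(list(k_on = k_on, k_off = k_off, r_max = r_max, k_t = k_t),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("1:1 transport-limited kinetic parameters\n")
  cat(sprintf("  k_on  = %.4g /M/s\n  k_off = %.4g /s\n  R_max = %.4g RU\n  k_t   = %.4g RU/M/s\n",
              x$k_on, x$k_off, x$r_max, x$k_t))
  invisible(x)
}

#' Injection phase schedule of an SPR cycle
#'
#' @param baseline seconds of buffer flow before the injection (response 0)
#' @param association seconds of analyte injection; must be > 0
#' @param dissociation seconds of buffer flow after the injection
#' @return an object of class `phase_schedule`
#' @export
phase_schedule <- function(baseline = 0, association = 200, dissociation = 600) {
  stopifnot(baseline >= 0, association > 0, dissociation >= 0)
  structure(list(baseline = baseline, association = association,
                 dissociation = dissociation),
            class = "phase_schedule")
}

new_sensorgram <- function(time, response, phase, conc) {
  stopifnot(length(time) == length(response), length(time) == length(phase))
  stopifnot(all(diff(time) > 0))
  structure(data.frame(time = time, response = response, phase = phase,
                       stringsAsFactors = FALSE),
            analyte_conc = conc, class = c("sensorgram", "data.frame"))
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("sensorgram: %d points, analyte %.3g M, phases: %s\n",
              nrow(x), attr(x, "analyte_conc"),
              paste(unique(x$phase), collapse = "/")))
  invisible(x)
}

#' Analyte concentration of a sensorgram
#' @param sg a `sensorgram`
#' @return concentration in M
#' @export
analyte_conc <- function(sg) attr(sg, "analyte_conc")

# Closed-form Langmuir association/dissociation (k_t = Inf).
langmuir_association <- function(t, k_on, k_off, r_max, conc, r0 = 0) {
  kobs <- k_on * conc + k_off
  req <- if (kobs > 0) r_max * k_on * conc / kobs else 0
  req + (r0 - req) * exp(-kobs * t)
}

spr_ode_solve <- function(times, r0, k_on, k_off, r_max, k_t, conc) {
  out <- deSolve::lsoda(
    y = c(R = r0), times = times, func = "spr_derivs",
    parms = c(k_on, k_off, r_max, k_t, conc),
    dllname = "decorakin", initfunc = "spr_initmod",
    rtol = 1e-8, atol = 1e-6)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration of the transport-limited binding model failed ",
         "(tolerances unmet); check parameter magnitudes")
  as.numeric(out[, "R"])
}

#' Simulate a noise-free sensorgram under the transport-limited 1:1 model
#'
#' Integrates the two-compartment model (see [kinetic_params()]) through the
#' baseline, association and dissociation phases. With `k_t = Inf` the exact
#' Langmuir closed form is used; otherwise a stiff-capable adaptive integrator
#' (lsoda, rtol 1e-8, atol 1e-6 RU) integrates the ODE.
#'
#' @param kin a [kinetic_params()] object
#' @param conc analyte concentration, M; >= 0
#' @param schedule a [phase_schedule()]
#' @param dt sampling interval, s
#' @return a `sensorgram` data frame (time, response, phase) with the analyte
#'   concentration attached as an attribute
#' @export
simulate_sensorgram <- function(kin, conc, schedule = phase_schedule(),
                                dt = 1) {
  stopifnot(inherits(kin, "kinetic_params"), inherits(schedule, "phase_schedule"))
  stopifnot(is.numeric(conc), length(conc) == 1L, conc >= 0)

  t_base <- if (schedule$baseline > 0) seq(0, schedule$baseline - dt, by = dt) else numeric(0)
  t0 <- schedule$baseline
  t_assoc <- seq(0, schedule$association, by = dt)
  t_diss <- if (schedule$dissociation > 0)
    seq(dt, schedule$dissociation, by = dt) else numeric(0)

  if (is.infinite(kin$k_t)) {
    r_assoc <- langmuir_association(t_assoc, kin$k_on, kin$k_off, kin$r_max, conc)
    r_end <- r_assoc[length(r_assoc)]
    r_diss <- r_end * exp(-kin$k_off * t_diss)
  } else {
    r_assoc <- spr_ode_solve(t_assoc, 0, kin$k_on, kin$k_off, kin$r_max,
                             kin$k_t, conc)
    r_end <- r_assoc[length(r_assoc)]
    r_diss <- if (length(t_diss))
      spr_ode_solve(c(0, t_diss), r_end, kin$k_on, kin$k_off, kin$r_max,
                    kin$k_t, 0)[-1L] else numeric(0)
  }

  time <- c(t_base, t0 + t_assoc, t0 + schedule$association + t_diss)
  response <- c(rep(0, length(t_base)), r_assoc, r_diss)
  phase <- c(rep("baseline", length(t_base)),
             rep("association", length(t_assoc)),
             rep("dissociation", length(t_diss)))
  new_sensorgram(time, response, phase, conc)
}

#' Double-reference a sensorgram
#'
#' Subtracts the response of the ligand on a reference surface (no capsid
#' captured) and the buffer response on the active surface, then re-zeroes the
#' trace to the mean of its baseline phase. References are interpolated onto
#' the time grid of `raw`; their time ranges must cover it.
#'
#' @param raw,surface_ref,buffer_ref `sensorgram` objects
#' @return the double-referenced `sensorgram`
#' @export
double_reference <- function(raw, surface_ref, buffer_ref) {
  stopifnot(inherits(raw, "sensorgram"))
  interp_onto <- function(ref, t) {
    if (min(ref$time) > min(t) || max(ref$time) < max(t))
      stop("reference trace does not cover the time range of the raw trace")
    stats::approx(ref$time, ref$response, xout = t)$y
  }
  resp <- raw$response -
    interp_onto(surface_ref, raw$time) -
    interp_onto(buffer_ref, raw$time)
  base <- resp[raw$phase == "baseline"]
  if (length(base)) resp <- resp - mean(base)
  new_sensorgram(raw$time, resp, raw$phase, analyte_conc(raw))
}

#' Correct the dissociation phase for slow loss of the captured surface
#'
#' When the binding surface is itself captured non-covalently (e.g. capsids
#' held by an antibody), its slow release multiplies the ligand dissociation
#' signal by \eqn{e^{-k_{off,capture} t}}. This correction divides the
#' dissociation-phase response by that factor so the remaining decay reflects
#' ligand release only.
#'
#' @param sg a `sensorgram`
#' @param capture_koff dissociation rate of the capture interaction, 1/s
#' @param max_amplification correction factors beyond this are flagged with a
#'   warning (noise amplification)
#' @return the corrected `sensorgram`
#' @export
correct_capture_drift <- function(sg, capture_koff, max_amplification = 10) {
  stopifnot(inherits(sg, "sensorgram"), capture_koff >= 0)
  resp <- sg$response
  i <- sg$phase == "dissociation"
  if (any(i)) {
    t_rel <- sg$time[i] - min(sg$time[sg$phase == "dissociation"]) +
      diff(sg$time)[1L]
    fac <- exp(capture_koff * t_rel)
    if (max(fac) > max_amplification)
      warning(sprintf(
        "capture-drift correction amplifies the late dissociation signal %.1f-fold; treat corrected k_off with caution",
        max(fac)))
    resp[i] <- resp[i] * fac
  }
  new_sensorgram(sg$time, resp, sg$phase, analyte_conc(sg))
}

#' Fit the dissociation rate from the dissociation phases of a sensorgram set
#'
#' Fits a single exponential \eqn{R(t) = A e^{-k_{off} t}} to the
#' dissociation phase of each curve and averages the per-curve estimates; the
#' reported error is the scatter (sd) across curves. Curves whose dissociation
#' phase does not decay yield a lower-bound estimate of 0 with a warning.
#'
#' @param sgs a list of `sensorgram` objects
#' @param min_points minimum number of dissociation points per curve
#' @return list with elements `k_off`, `k_off_sd`, `per_curve`
#' @export
fit_dissociation_koff <- function(sgs, min_points = 100) {
  stopifnot(is.list(sgs), length(sgs) >= 1L)
  per_curve <- vapply(sgs, function(sg) {
    i <- sg$phase == "dissociation"
    if (sum(i) <= min_points)
      stop("dissociation phase must have more than ", min_points, " points")
    t <- sg$time[i] - sg$time[i][1L]
    r <- sg$response[i]
    slope <- stats::coef(stats::lm(r ~ t))[2L]
    if (r[1L] <= 0 || slope >= -1e-9 * abs(r[1L]) / max(t)) {
      warning("non-decaying dissociation phase; returning lower bound 0")
      return(0)
    }
    a0 <- r[1L]
    pos <- r > 0
    loglin <- stats::lm(log(r[pos]) ~ t[pos])
    k0 <- max(1e-8, -stats::coef(loglin)[2L])
    if (stats::sd(stats::residuals(loglin)) < 1e-10)
      return(k0)  # exact exponential: nls has no residual to minimise
    fit <- stats::nls(r ~ a * exp(-k * t), start = list(a = a0, k = k0),
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
    max(0, stats::coef(fit)[["k"]])
  }, numeric(1))
  list(k_off = mean(per_curve),
       k_off_sd = if (length(per_curve) > 1L) stats::sd(per_curve) else NA_real_,
       per_curve = per_curve)
}

# Residuals of a parameter vector against a set of sensorgrams.
# theta is on log scale: (log k_on, log r_max, log k_t[, log k_off]).
spr_global_residuals <- function(theta, sgs, koff_fixed, dt_hint = NULL) {
  k_on <- exp(theta[[1L]])
  r_max <- exp(theta[[2L]])
  k_t <- exp(theta[[3L]])
  k_off <- if (is.null(koff_fixed)) exp(theta[[4L]]) else koff_fixed
  unlist(lapply(sgs, function(sg) {
    sched <- schedule_of(sg)
    kin <- kinetic_params(k_on, k_off, r_max, k_t)
    pred <- simulate_sensorgram(kin, analyte_conc(sg), sched,
                                dt = diff(sg$time)[1L])
    stats::approx(pred$time, pred$response, xout = sg$time)$y - sg$response
  }), use.names = FALSE)
}

# Recover the phase schedule implied by a sensorgram's phase labels.
schedule_of <- function(sg) {
  dt <- diff(sg$time)[1L]
  nb <- sum(sg$phase == "baseline")
  na <- sum(sg$phase == "association")
  nd <- sum(sg$phase == "dissociation")
  phase_schedule(baseline = nb * dt, association = (na - 1L) * dt,
                 dissociation = nd * dt)
}

#' Globally fit the transport-limited 1:1 model to a multi-concentration series
#'
#' One shared parameter set (`k_on`, `R_max`, `k_t`, and `k_off` unless fixed)
#' is fitted by unweighted least squares over all phases of all curves
#' simultaneously (Levenberg-Marquardt on log-scale parameters, multi-start).
#' Fixing `k_off` at an independently determined value mirrors the common
#' practice for very slow dissociation, where the association phases alone do
#' not constrain it. \eqn{K_D = k_{off}/k_{on}} is reported from the fit.
#'
#' @param sgs list of `sensorgram` objects at known analyte concentrations
#'   (at least 2 distinct concentrations)
#' @param koff_fixed a rate in 1/s to hold `k_off` fixed, or `"free"` to fit it
#' @param n_starts number of seeded multi-start initialisations
#' @param seed integer seed for the multi-start perturbations
#' @param kt_unbounded_factor fitted `k_t` above this multiple of
#'   `k_on * R_max` is reported as unidentifiable (`k_t = Inf`,
#'   `kt_unbounded = TRUE`): the data carry no transport signature
#' @return an object of class `kinetic_fit`: estimates, standard errors,
#'   `K_D`, residual standard deviation, per-curve residuals
#' @export
fit_global <- function(sgs, koff_fixed = 2e-4, n_starts = 10, seed = 1,
                       kt_unbounded_factor = 1e3) {
  stopifnot(is.list(sgs), length(sgs) >= 2L)
  concs <- vapply(sgs, analyte_conc, numeric(1))
  if (length(unique(concs)) < 2L)
    stop("global fit requires at least 2 distinct analyte concentrations; ",
         "a single concentration does not identify (k_on, R_max, k_t)")
  free_koff <- identical(koff_fixed, "free")
  koff_val <- if (free_koff) NULL else koff_fixed

  rmax0 <- max(vapply(sgs, function(s) max(s$response), numeric(1))) * 1.05
  cmid <- stats::median(concs)
  # crude k_obs from the time to half-max of the highest-concentration curve
  hi <- sgs[[which.max(concs)]]
  ia <- hi$phase == "association"
  th <- hi$time[ia] - hi$time[ia][1L]
  rh <- hi$response[ia]
  t_half <- th[which.min(abs(rh - 0.5 * max(rh)))]
  kon0 <- max(log(2) / max(t_half, 1) / max(concs), 1e3)

  base <- c(log(kon0), log(rmax0), log(kon0 * rmax0))
  if (free_koff) base <- c(base, log(1e-3))

  n_starts <- max(1L, n_starts)
  starts <- with_seed(seed, {
    m <- matrix(rep(base, n_starts), nrow = n_starts, byrow = TRUE)
    if (n_starts > 1L)
      m[-1L, ] <- m[-1L, ] + stats::rnorm((n_starts - 1L) * length(base), sd = 1.0)
    m
  })
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- starts[s, ]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = spr_global_residuals, sgs = sgs,
                         koff_fixed = koff_val,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("global fit failed from every start")

  theta <- best$par
  npar <- length(theta)
  nobs <- sum(vapply(sgs, nrow, integer(1)))
  sigma <- sqrt(best$deviance / max(1, nobs - npar))
  covm <- tryCatch(sigma^2 * solve(best$hessian), error = function(e) NULL)
  se_log <- if (is.null(covm)) rep(NA_real_, npar) else sqrt(pmax(0, diag(covm)))

  k_on <- exp(theta[[1L]]); r_max <- exp(theta[[2L]]); k_t <- exp(theta[[3L]])
  k_off <- if (free_koff) exp(theta[[4L]]) else koff_fixed
  kt_unbounded <- k_t > kt_unbounded_factor * k_on * r_max
  if (kt_unbounded) k_t <- Inf

  res <- spr_global_residuals(theta, sgs, koff_val)
  structure(list(
    k_on = k_on, k_on_se = k_on * se_log[1L],
    r_max = r_max, r_max_se = r_max * se_log[2L],
    k_t = k_t, k_t_se = if (kt_unbounded) NA_real_ else k_t * se_log[3L],
    kt_unbounded = kt_unbounded,
    k_off = k_off, koff_fixed = !free_koff,
    k_off_se = if (free_koff) k_off * se_log[4L] else NA_real_,
    K_D = compute_kd(k_on, k_off),
    sigma = sigma, n_obs = nobs, residuals = res,
    concentrations = concs), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Global 1:1 transport-limited fit\n")
  cat(sprintf("  k_on  = %.4g +/- %.2g /M/s\n", x$k_on, x$k_on_se))
  cat(sprintf("  k_off = %.4g /s%s\n", x$k_off,
              if (x$koff_fixed) " (fixed)" else sprintf(" +/- %.2g", x$k_off_se)))
  cat(sprintf("  R_max = %.4g RU\n", x$r_max))
  cat(sprintf("  k_t   = %s\n",
              if (x$kt_unbounded) "unbounded above (no transport signature)"
              else sprintf("%.4g RU/M/s", x$k_t)))
  cat(sprintf("  K_D   = %.4g M%s\n", x$K_D,
              if (x$koff_fixed) "  (no error: k_off forced)" else ""))
  cat(sprintf("  residual sd = %.3g RU over %d points\n", x$sigma, x$n_obs))
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param k_on association rate constant, 1/(M s); must be > 0
#' @param k_off dissociation rate constant, 1/s
#' @return \eqn{K_D = k_{off}/k_{on}} in M
#' @export
compute_kd <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), is.numeric(k_off), all(k_on > 0), all(k_off >= 0))
  k_off / k_on
}

#' Expected relative mass increase upon full decoration
#'
#' @param n_copies number of bound ligand copies per particle
#' @param ligand_mass ligand mass, Da
#' @param particle_mass particle mass, Da
#' @return percent mass increase, `100 * n_copies * ligand_mass / particle_mass`
#' @export
expected_mass_fraction <- function(n_copies, ligand_mass, particle_mass) {
  stopifnot(n_copies >= 0, ligand_mass > 0, particle_mass > 0)
  100 * n_copies * ligand_mass / particle_mass
}
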