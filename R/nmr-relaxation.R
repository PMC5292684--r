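# Physical constants for the 15N-1H spin pair (SI units). Bond length and
# CSA are the conventional model-free defaults; both are overridable through
# options("decorakin.r_nh"), options("decorakin.csa_n").
nmr_const <- function() {
  list(
    gamma_h = 2.6752218744e8,   # 1H gyromagnetic ratio, rad/s/T
    gamma_n = -2.7126e7,        # 15N gyromagnetic ratio, rad/s/T
    hbar = 1.054571817e-34,     # J s
    mu0 = 4 * pi * 1e-7,
    r_nh = getOption("decorakin.r_nh", 1.02e-10),  # N-H bond length, m
    csa_n = getOption("decorakin.csa_n", -160e-6)  # 15N CSA, dimensionless
  )
}

#' Per-residue Lipari-Szabo motional parameters
#'
#' The model-free description of internal backbone motion: a generalised
#' order parameter `s2` (amplitude of sub-tumbling motion), an effective
#' internal correlation time `tau_e` (ps), and a chemical-exchange
#' contribution `rex` (1/s, added to R2 only, referenced to `rex_field` MHz).
#' The extended (two-timescale) form adds a fast-motion order parameter
#' `sf2` and a slow internal time `tau_s` (ps), with `s2 = sf2 * ss2`.
#'
#' Model ids follow the conventional ladder: M1 (s2), M2 (s2, tau_e),
#' M3 (s2, rex), M4 (s2, tau_e, rex), M5 (sf2, s2, tau_s).
#'
#' @param s2 order parameter in `[0, 1]`
#' @param tau_e internal correlation time, ps; >= 0
#' @param rex exchange contribution to R2, 1/s; >= 0
#' @param sf2 fast-timescale order parameter for the extended model (M5);
#'   `NULL` for single-timescale models; requires `sf2 >= s2`
#' @param tau_s slow internal correlation time, ps (M5 only)
#' @param rex_field 1H field (MHz) at which `rex` is quoted
#' @return an object of class `motion_params`
#' @export
motion_params <- function(s2, tau_e = 0, rex = 0, sf2 = NULL, tau_s = 0,
                          rex_field = 600) {
  stopifnot(s2 >= 0, s2 <= 1, tau_e >= 0, rex >= 0, tau_s >= 0)
  if (!is.null(sf2)) stopifnot(sf2 >= s2, sf2 <= 1)
  model <- if (!is.null(sf2)) "M5"
  else if (tau_e > 0 && rex > 0) "M4"
  else if (rex > 0) "M3"
  else if (tau_e > 0) "M2"
  else "M1"
  structure(list(s2 = s2, tau_e = tau_e, rex = rex, sf2 = sf2,
                 tau_s = tau_s, rex_field = rex_field, model = model),
            class = "motion_params")
}

#' Overall rotational tumbling
#'
#' @param tau_m isotropic rotational correlation time, ns; > 0
#' @param scope label: the whole molecule or one domain
#' @return an object of class `global_tumbling`
#' @export
global_tumbling <- function(tau_m, scope = "molecule") {
  stopifnot(is.numeric(tau_m), length(tau_m) == 1L, tau_m > 0)
  structure(list(tau_m = tau_m, scope = scope), class = "global_tumbling")
}

#' Lipari-Szabo spectral density function
#'
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
#'   \frac{(1-S^2)\tau}{1+(\omega\tau)^2}\right],\quad
#'   \tau^{-1} = \tau_m^{-1} + \tau_e^{-1}}
#' For the extended model (M5) the second term becomes
#' \eqn{(S_f^2 - S^2)\tau'/(1+(\omega\tau')^2)} with
#' \eqn{\tau'^{-1} = \tau_m^{-1} + \tau_s^{-1}}.
#'
#' @param m a [motion_params()]
#' @param tumbling a [global_tumbling()]
#' @param omega angular frequency or vector thereof, rad/s
#' @return J(omega) in s/rad, same length as `omega`
#' @export
spectral_density <- function(m, tumbling, omega) {
  stopifnot(inherits(m, "motion_params"), inherits(tumbling, "global_tumbling"))
  tm <- tumbling$tau_m * 1e-9
  w2 <- omega^2
  if (m$model == "M5") {
    ts <- m$tau_s * 1e-12
    tp <- if (ts > 0) 1 / (1 / tm + 1 / ts) else 0
    amp2 <- m$sf2 - m$s2
  } else {
    te <- m$tau_e * 1e-12
    tp <- if (te > 0) 1 / (1 / tm + 1 / te) else 0
    amp2 <- 1 - m$s2
  }
  j <- m$s2 * tm / (1 + w2 * tm^2)
  if (tp > 0) j <- j + amp2 * tp / (1 + w2 * tp^2)
  0.4 * j
}

#' Predict 15N R1, R2 and heteronuclear NOE
#'
#' Standard expressions for 15N relaxation by the N-H dipolar interaction and
#' 15N chemical-shift anisotropy, evaluated from the spectral density at the
#' five canonical frequencies (0, omega_N, omega_H +/- omega_N, omega_H).
#' `rex` is added to R2 only, scaled by `(field/rex_field)^2` (exchange
#' broadening grows with the square of the static field).
#'
#' @inheritParams spectral_density
#' @param field 1H spectrometer frequency, MHz; > 0
#' @return named numeric vector `c(R1 =, R2 =, NOE =)` (R in 1/s)
#' @export
predict_rates <- function(m, tumbling, field) {
  stopifnot(field > 0)
  k <- nmr_const()
  wh <- 2 * pi * field * 1e6
  wn <- wh * k$gamma_n / k$gamma_h
  d <- k$mu0 * k$hbar * k$gamma_h * k$gamma_n / (4 * pi * k$r_nh^3)
  d2 <- d^2
  c2 <- (wn * k$csa_n)^2 / 3
  J <- function(w) spectral_density(m, tumbling, abs(w))

  j0 <- J(0); jn <- J(wn); jh <- J(wh)
  jhmn <- J(wh - wn); jhpn <- J(wh + wn)

  r1 <- d2 / 4 * (jhmn + 3 * jn + 6 * jhpn) + c2 * jn
  r2 <- d2 / 8 * (4 * j0 + jhmn + 3 * jn + 6 * jh + 6 * jhpn) +
    c2 / 6 * (4 * j0 + 3 * jn) +
    m$rex * (field / m$rex_field)^2
  noe <- if (r1 > 0)
    1 + d2 / 4 * (k$gamma_h / k$gamma_n) * (6 * jhpn - jhmn) / r1
  else NA_real_  # degenerate: no dipolar relaxation (J identically 0)
  c(R1 = unname(r1), R2 = unname(r2), NOE = unname(noe))
}

rigid_r2r1 <- function(tau_m, field) {
  r <- predict_rates(motion_params(s2 = 1), global_tumbling(tau_m), field)
  r[["R2"]] / r[["R1"]]
}

#' Rotational correlation time giving a target rigid-limit T1/T2 ratio
#'
#' Inverts the rigid-limit R2/R1 relation numerically (the ratio is strictly
#' increasing in `tau_m` beyond its minimum, which lies below 1 ns for the
#' fields considered here).
#'
#' @param ratio target T1/T2 (= R2/R1)
#' @param field 1H frequency, MHz
#' @param interval search interval for `tau_m`, ns
#' @return tau_m in ns
#' @export
tau_m_for_ratio <- function(ratio, field, interval = c(1, 60)) {
  stopifnot(ratio > 0)
  stats::uniroot(function(tm) rigid_r2r1(tm, field) - ratio,
                 interval = interval, tol = 1e-10)$root
}

#' Estimate per-domain tumbling times from trimmed T1/T2 ratios
#'
#' Residues with heteronuclear NOE below `noe_min` (flexible) are excluded,
#' the top and bottom `trim` fraction of the remaining R2/R1 ratios are
#' discarded (exchange and residual-flexibility outliers), and the rigid-limit
#' R2/R1(tau_m) relation is inverted on the trimmed mean.
#'
#' @param records relaxation data frame with columns `residue`, `domain`,
#'   `field`, `R1`, `R2`, `NOE`
#' @param trim fraction trimmed from each tail of the ratio distribution
#' @param noe_min NOE rigidity cutoff (residues below are excluded)
#' @param field which field's data to use (MHz); default the lowest present
#' @param min_residues minimum usable residues per domain after filtering
#' @return named list of [global_tumbling()] objects, one per domain
#' @export
estimate_tm_from_ratio <- function(records, trim = 0.1, noe_min = 0.6,
                                   field = NULL, min_residues = 5) {
  stopifnot(is.data.frame(records))
  if (is.null(field)) field <- min(records$field)
  rec <- records[records$field == field, ]
  out <- list()
  for (dom in unique(rec$domain)) {
    d <- rec[rec$domain == dom & !is.na(rec$NOE) & rec$NOE >= noe_min, ]
    ratio <- d$R2 / d$R1
    if (trim > 0 && length(ratio) > 0) {
      qs <- stats::quantile(ratio, c(trim, 1 - trim), names = FALSE)
      ratio <- ratio[ratio >= qs[1L] & ratio <= qs[2L]]
    }
    if (length(ratio) < min_residues)
      stop("domain '", dom, "': fewer than ", min_residues,
           " usable residues after NOE filtering and trimming")
    out[[dom]] <- global_tumbling(
      tau_m_for_ratio(mean(ratio), field), scope = dom)
  }
  out
}

# chi-square of a motion-parameter candidate against observed rates.
# Zero/absent errors fall back to unit weights (unweighted fit).
residue_chi2 <- function(m, tumbling, obs) {
  err <- c(obs$R1_err, obs$R2_err, obs$NOE_err)
  unw <- all(is.na(err) | err == 0)
  tot <- 0
  for (i in seq_len(nrow(obs))) {
    p <- predict_rates(m, tumbling, obs$field[i])
    res <- c(p[["R1"]] - obs$R1[i], p[["R2"]] - obs$R2[i],
             p[["NOE"]] - obs$NOE[i])
    w <- if (unw) c(1, 1, 1) else c(obs$R1_err[i], obs$R2_err[i], obs$NOE_err[i])
    tot <- tot + sum((res / w)^2)
  }
  if (!is.finite(tot)) 1e12 else tot
}

mf_model_pars <- list(
  M1 = c("s2"), M2 = c("s2", "tau_e"), M3 = c("s2", "rex"),
  M4 = c("s2", "tau_e", "rex"), M5 = c("sf2", "s2", "tau_s"))

mf_build <- function(model, par, rex_field) {
  p <- as.list(par)
  names(p) <- mf_model_pars[[model]]
  if (model == "M5")
    motion_params(s2 = min(p$s2, p$sf2), sf2 = p$sf2, tau_s = p$tau_s,
                  rex_field = rex_field)
  else
    motion_params(s2 = p$s2,
                  tau_e = if ("tau_e" %in% names(p)) p$tau_e else 0,
                  rex = if ("rex" %in% names(p)) p$rex else 0,
                  rex_field = rex_field)
}

#' Model-free fit of one residue's relaxation data
#'
#' Fits the candidate models M1 (S2), M2 (S2, tau_e), M3 (S2, Rex),
#' M4 (S2, tau_e, Rex) and M5 (Sf2, S2, tau_s) by (weighted) least squares
#' and selects among those with positive residual degrees of freedom by the
#' corrected Akaike criterion
#' \eqn{AICc = \chi^2 + 2k + 2k(k+1)/(n-k-1)} (or by a chi-square threshold
#' when `selection = "chi2"`). If the winning model still fails the
#' goodness-of-fit cut, the best-effort fit is returned flagged
#' `"unmodelled"`; records whose stated errors span the physical range of the
#' observable are flagged `"uninformative"`.
#'
#' @param obs data frame with one row per field: columns `field`, `R1`,
#'   `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err`
#' @param tumbling a [global_tumbling()] for the residue's domain
#' @param models candidate model ids
#' @param selection `"aicc"` or `"chi2"` (alpha-level chi-square test ladder)
#' @param gof_alpha significance level of the goodness-of-fit cut
#' @param rex_field field (MHz) at which fitted Rex is quoted
#' @return the winning [motion_params()] with attributes `chi2`, `df`,
#'   `model`, `flag` (`"ok"`, `"unmodelled"` or `"uninformative"`) and
#'   `selection_table`
#' @export
fit_residue <- function(obs, tumbling, models = names(mf_model_pars),
                        selection = c("aicc", "chi2"), gof_alpha = 1e-3,
                        rex_field = 600) {
  selection <- match.arg(selection)
  stopifnot(is.data.frame(obs), nrow(obs) >= 1L,
            inherits(tumbling, "global_tumbling"))
  n <- 3L * nrow(obs)
  tm_ps <- tumbling$tau_m * 1e3

  lower <- list(s2 = 0, tau_e = 0, rex = 0, sf2 = 0, tau_s = 0)
  upper <- list(s2 = 1, tau_e = tm_ps, rex = 200, sf2 = 1, tau_s = tm_ps)
  start <- list(s2 = 0.85, tau_e = 50, rex = 2, sf2 = 0.95, tau_s = 1000)

  rows <- list()
  for (mod in models) {
    pn <- mf_model_pars[[mod]]
    k <- length(pn)
    if (n - k < 1L) next  # not enough observables to fit this model
    obj <- function(par) {
      m <- tryCatch(mf_build(mod, par, rex_field), error = function(e) NULL)
      if (is.null(m)) return(1e12)
      residue_chi2(m, tumbling, obs)
    }
    p0 <- unlist(start[pn])
    fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                        lower = unlist(lower[pn]), upper = unlist(upper[pn]))
    # a second start guards against the tau_e/rex trade-off local minimum
    p1 <- p0; p1[] <- (unlist(lower[pn]) + unlist(upper[pn])) / 4
    fit2 <- stats::optim(p1, obj, method = "L-BFGS-B",
                         lower = unlist(lower[pn]), upper = unlist(upper[pn]))
    if (fit2$value < fit$value) fit <- fit2
    chi2 <- fit$value
    aicc <- if (n - k - 1L >= 1L) chi2 + 2 * k + 2 * k * (k + 1) / (n - k - 1)
            else NA_real_
    rows[[mod]] <- list(model = mod, k = k, chi2 = chi2, df = n - k,
                        aicc = aicc, par = fit$par)
  }
  if (!length(rows)) stop("no candidate model has positive degrees of freedom")

  tab <- data.frame(model = vapply(rows, `[[`, "", "model"),
                    k = vapply(rows, `[[`, 0L, "k"),
                    chi2 = vapply(rows, `[[`, 0, "chi2"),
                    df = vapply(rows, `[[`, 0L, "df"),
                    aicc = vapply(rows, `[[`, 0, "aicc"))
  win <- if (selection == "aicc") {
    cand <- tab[!is.na(tab$aicc), ]
    if (!nrow(cand)) tab$model[which.min(tab$chi2)]
    else cand$model[which.min(cand$aicc)]
  } else {
    # chi2 ladder: simplest model whose fit is not rejected
    w <- NULL
    for (mod in tab$model[order(tab$k)]) {
      r <- rows[[mod]]
      if (r$df < 1L || stats::pchisq(r$chi2, r$df, lower.tail = FALSE) >= gof_alpha) {
        w <- mod; break
      }
    }
    if (is.null(w)) tab$model[which.min(tab$chi2)] else w
  }

  r <- rows[[win]]
  m <- mf_build(win, r$par, rex_field)
  flag <- "ok"
  err_informative <- !(all(is.na(c(obs$R1_err, obs$R2_err, obs$NOE_err))) ||
                         all(c(obs$R1_err, obs$R2_err, obs$NOE_err) == 0))
  if (err_informative && any(obs$NOE_err >= 1 |
                             obs$R1_err / obs$R1 > 0.5 |
                             obs$R2_err / obs$R2 > 0.5, na.rm = TRUE))
    flag <- "uninformative"
  else if (err_informative && r$df >= 1L &&
           stats::pchisq(r$chi2, r$df, lower.tail = FALSE) < gof_alpha)
    flag <- "unmodelled"
  attr(m, "model") <- win
  attr(m, "chi2") <- r$chi2
  attr(m, "df") <- r$df
  attr(m, "flag") <- flag
  attr(m, "selection_table") <- tab
  m
}

#' Monte-Carlo confidence intervals for a model-free fit
#'
#' Resamples the observables from Gaussians centred on the measured values
#' with the measured standard deviations, refits the selected model, and
#' reports percentile intervals.
#'
#' @param fit a fitted [motion_params()] from [fit_residue()]
#' @param obs the observation data frame the fit was made from
#' @param tumbling the [global_tumbling()] used in the fit
#' @param n_mc number of Monte-Carlo resamples (>= 100)
#' @param seed integer seed
#' @param level central interval mass (default 0.68, approximately 1 sigma)
#' @return data frame with one row per parameter: `estimate`, `lower`,
#'   `upper`; zero measurement errors yield zero-width intervals with a warning
#' @export
mc_errors <- function(fit, obs, tumbling, n_mc = 200, seed = 1, level = 0.68) {
  stopifnot(n_mc >= 100)
  model <- attr(fit, "model")
  pn <- mf_model_pars[[model]]
  errs <- c(obs$R1_err, obs$R2_err, obs$NOE_err)
  if (all(is.na(errs) | errs == 0))
    warning("all measurement errors are zero; Monte-Carlo intervals collapse to points")
  draws <- with_seed(seed, {
    replicate(n_mc, {
      o <- obs
      o$R1 <- stats::rnorm(nrow(o), obs$R1, obs$R1_err)
      o$R2 <- stats::rnorm(nrow(o), obs$R2, obs$R2_err)
      o$NOE <- stats::rnorm(nrow(o), obs$NOE, obs$NOE_err)
      f <- fit_residue(o, tumbling, models = model,
                       rex_field = fit$rex_field)
      vapply(pn, function(p) f[[p]], numeric(1))
    })
  })
  draws <- matrix(draws, nrow = length(pn))
  a <- (1 - level) / 2
  data.frame(
    parameter = pn,
    estimate = vapply(pn, function(p) fit[[p]], numeric(1)),
    lower = apply(draws, 1L, stats::quantile, probs = a),
    upper = apply(draws, 1L, stats::quantile, probs = 1 - a),
    row.names = NULL)
}

#' Fit every residue of a relaxation dataset
#'
#' Convenience wrapper: per-domain tumbling (given or estimated via
#' [estimate_tm_from_ratio()]), then [fit_residue()] per residue, optionally
#' with Monte-Carlo intervals for Rex.
#'
#' @param records relaxation data frame (see [gen_relaxation_dataset()])
#' @param tumbling_by_domain named list of [global_tumbling()]; `NULL` to
#'   estimate from the data
#' @param mc_n Monte-Carlo resamples for Rex intervals; 0 disables
#' @param seed seed for the Monte-Carlo resampling
#' @param ... passed to [fit_residue()]
#' @return data frame: residue, domain, model, s2, tau_e, rex, chi2, flag,
#'   and (if `mc_n > 0`) `rex_lower`, `rex_upper`
#' @export
fit_dataset <- function(records, tumbling_by_domain = NULL, mc_n = 0,
                        seed = 1, ...) {
  if (is.null(tumbling_by_domain))
    tumbling_by_domain <- estimate_tm_from_ratio(records)
  res <- unique(records[, c("residue", "domain")])
  out <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    obs <- records[records$residue == res$residue[i], ]
    tmb <- tumbling_by_domain[[as.character(res$domain[i])]]
    f <- fit_residue(obs, tmb, ...)
    row <- data.frame(residue = res$residue[i], domain = res$domain[i],
                      model = attr(f, "model"), s2 = f$s2, tau_e = f$tau_e,
                      rex = f$rex, chi2 = attr(f, "chi2"),
                      flag = attr(f, "flag"))
    if (mc_n > 0 && f$rex > 0) {
      ci <- mc_errors(f, obs, tmb, n_mc = mc_n, seed = seed + i)
      row$rex_lower <- ci$lower[ci$parameter == "rex"]
      row$rex_upper <- ci$upper[ci$parameter == "rex"]
    } else {
      row$rex_lower <- NA_real_; row$rex_upper <- NA_real_
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Mean T1/T2 per domain
#'
#' Arithmetic mean of the per-residue R2/R1 ratio over residues with complete
#' data in each domain, at one field.
#'
#' @param records relaxation data frame
#' @param domains optional named list of residue-id vectors defining the
#'   domains (must be disjoint); default: the `domain` column
#' @param field field to evaluate (MHz); default the lowest present
#' @return named numeric vector of mean T1/T2 per domain
#' @export
domain_average_t1t2 <- function(records, domains = NULL, field = NULL) {
  if (is.null(field)) field <- min(records$field)
  rec <- records[records$field == field, ]
  if (is.null(domains)) {
    domains <- split(rec$residue, rec$domain)
  } else {
    ids <- unlist(domains)
    if (anyDuplicated(ids)) stop("domain residue ranges must be disjoint")
  }
  vapply(domains, function(ids) {
    d <- rec[rec$residue %in% ids & stats::complete.cases(rec[, c("R1", "R2")]), ]
    if (!nrow(d)) stop("empty domain residue range")
    mean(d$R2 / d$R1)
  }, numeric(1))
}

#' Flag residues undergoing chemical exchange
#'
#' @param fits data frame from [fit_dataset()]
#' @param min_rex minimum Rex (1/s) for inclusion; the threshold is closed
#'   (`rex == min_rex` is included)
#' @param require_significance also require the Monte-Carlo interval for Rex
#'   to exclude 0 (needs `mc_n > 0` in [fit_dataset()])
#' @return vector of residue ids whose selected model carries Rex
#' @export
flag_exchange <- function(fits, min_rex = 0, require_significance = FALSE) {
  sel <- fits$model %in% c("M3", "M4") & fits$rex >= min_rex
  if (require_significance) {
    if (all(is.na(fits$rex_lower[sel])))
      stop("significance filtering requires Monte-Carlo intervals (mc_n > 0)")
    sel <- sel & !is.na(fits$rex_lower) & fits$rex_lower > 0
  }
  fits$residue[sel]
}
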