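#' Generate a multi-concentration synthetic sensorgram series
#'
#' One noise-free trace per concentration from [simulate_sensorgram()], plus
#' additive i.i.d. Gaussian noise in response units (the declared instrument
#' noise model; default sd 0.5 RU).
#'
#' @param kin a [kinetic_params()]
#' @param concentrations analyte concentrations, M; all >= 0
#' @param schedule a [phase_schedule()]
#' @param noise a [noise_spec()] (sd in RU)
#' @param dt sampling interval, s
#' @return list of `sensorgram` objects (class `sensorgram_set`)
#' @export
gen_sensorgram_series <- function(kin,
                                  concentrations = c(0.312, 0.625, 1.25,
                                                     2.5, 5, 10, 20) * 1e-9,
                                  schedule = phase_schedule(),
                                  noise = noise_spec(sd = 0.5),
                                  dt = 1) {
  bad <- which(concentrations < 0)
  if (length(bad))
    stop("negative analyte concentration at position ", bad[1L], ": ",
         concentrations[bad[1L]])
  ideal <- lapply(concentrations, simulate_sensorgram, kin = kin,
                  schedule = schedule, dt = dt)
  sgs <- with_seed(noise$seed, lapply(ideal, function(sg) {
    if (noise$sd > 0)
      sg$response <- sg$response + stats::rnorm(nrow(sg), sd = noise$sd)
    sg
  }))
  structure(sgs, class = c("sensorgram_set", "list"))
}

#' Motional-parameter table of a synthetic two-domain protein
#'
#' A per-residue table mimicking a two-domain protein whose domains tumble
#' independently: mostly rigid backbones (S2 near 0.85 with small internal
#' times), a configurable number of residues carrying chemical exchange
#' (clustered at the end of each block, mirroring exchange that localises to
#' specific structural elements), and domain labels `NTD`/`CTD`.
#'
#' @param n_ntd,n_ctd residues per domain
#' @param n_rex number of exchange-bearing residues (split across domains)
#' @param rex_range range of Rex values drawn for those residues, 1/s
#' @param seed integer seed
#' @return data frame: residue, domain, s2, tau_e (ps), rex (1/s)
#' @export
synthetic_protein_motions <- function(n_ntd = 40, n_ctd = 45, n_rex = 16,
                                      rex_range = c(2, 6), seed = 1) {
  stopifnot(n_ntd >= 1, n_ctd >= 1, n_rex >= 0, n_rex <= n_ntd + n_ctd)
  n <- n_ntd + n_ctd
  with_seed(seed, {
    tab <- data.frame(
      residue = seq_len(n),
      domain = rep(c("NTD", "CTD"), c(n_ntd, n_ctd)),
      s2 = pmin(0.98, pmax(0.6, stats::rnorm(n, 0.85, 0.04))),
      tau_e = stats::runif(n, 10, 80),
      rex = 0)
    if (n_rex > 0) {
      n1 <- ceiling(n_rex / 2)
      idx <- c(seq(n_ntd - n1 + 1L, n_ntd),
               seq(n - (n_rex - n1) + 1L, n))[seq_len(n_rex)]
      tab$rex[idx] <- stats::runif(n_rex, rex_range[1L], rex_range[2L])
    }
    tab
  })
}

#' Tumbling time that gives a target mean T1/T2 for a residue set
#'
#' Inverts the mean R2/R1 of a motional-parameter table (internal motion and
#' exchange included) as a function of the shared tumbling time, so a
#' generated domain reproduces a configured average T1/T2 exactly in the
#' noise-free limit.
#'
#' @param motions data frame with columns `s2`, `tau_e`, `rex`
#' @param target_ratio desired mean R2/R1
#' @param field 1H frequency, MHz
#' @param interval search interval, ns
#' @return tau_m in ns
#' @export
calibrate_tm_to_ratio <- function(motions, target_ratio, field = 600,
                                  interval = c(1, 60)) {
  mean_ratio <- function(tm) {
    tmb <- global_tumbling(tm)
    mean(vapply(seq_len(nrow(motions)), function(i) {
      r <- predict_rates(motion_params(motions$s2[i], motions$tau_e[i],
                                       motions$rex[i]), tmb, field)
      r[["R2"]] / r[["R1"]]
    }, numeric(1)))
  }
  stats::uniroot(function(tm) mean_ratio(tm) - target_ratio,
                 interval = interval, tol = 1e-8)$root
}

#' Generate a synthetic 15N relaxation dataset
#'
#' For every residue, field and replicate, draws
#' `predict_rates(...) + noise`; the reported value is the replicate mean
#' and the reported error the standard error of that mean (so errors shrink
#' as `1/sqrt(replicates)`). Rate noise is fractional (`rel_sd` of the true
#' rate, matching the roughly constant relative precision of R1/R2
#' experiments); NOE noise is absolute (`noe_sd`).
#'
#' @param per_residue data frame: `residue`, `domain`, `s2`, `tau_e` (ps),
#'   `rex` (1/s); e.g. from [synthetic_protein_motions()]
#' @param tumbling_by_domain named numeric vector (ns) or named list of
#'   [global_tumbling()], one entry per domain present
#' @param fields 1H frequencies, MHz; all > 0
#' @param rel_sd fractional noise sd on R1 and R2
#' @param noe_sd absolute noise sd on the NOE
#' @param replicates replicate measurements per observable
#' @param seed integer seed
#' @return data frame: residue, domain, field, R1, R1_err, R2, R2_err, NOE,
#'   NOE_err
#' @export
gen_relaxation_dataset <- function(per_residue, tumbling_by_domain,
                                   fields = c(600, 700), rel_sd = 0.02,
                                   noe_sd = 0.02, replicates = 2, seed = 1) {
  stopifnot(all(fields > 0), replicates >= 1, rel_sd >= 0, noe_sd >= 0)
  if (!is.list(tumbling_by_domain))
    tumbling_by_domain <- lapply(tumbling_by_domain, global_tumbling)
  missing_dom <- setdiff(unique(per_residue$domain), names(tumbling_by_domain))
  if (length(missing_dom))
    stop("no tumbling assigned for domain(s): ",
         paste(missing_dom, collapse = ", "))

  grid <- expand.grid(i = seq_len(nrow(per_residue)), field = fields,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(g) {
      i <- grid$i[g]; fld <- grid$field[g]
      m <- motion_params(per_residue$s2[i], per_residue$tau_e[i],
                         per_residue$rex[i])
      tmb <- tumbling_by_domain[[as.character(per_residue$domain[i])]]
      tr <- predict_rates(m, tmb, fld)
      draw <- function(true, sd) {
        reps <- true + stats::rnorm(replicates, sd = sd)
        c(mean(reps),
          if (replicates > 1L) stats::sd(reps) / sqrt(replicates) else 0)
      }
      r1 <- draw(tr[["R1"]], rel_sd * tr[["R1"]])
      r2 <- draw(tr[["R2"]], rel_sd * tr[["R2"]])
      noe <- draw(tr[["NOE"]], noe_sd)
      data.frame(residue = per_residue$residue[i],
                 domain = per_residue$domain[i], field = fld,
                 R1 = r1[1L], R1_err = r1[2L],
                 R2 = r2[1L], R2_err = r2[2L],
                 NOE = noe[1L], NOE_err = noe[2L])
    })
    do.call(rbind, rows)
  })
}

#' Generate a two-lobe bead model of a two-domain protein
#'
#' Two compact lobes joined by a short straight linker along the x axis: a
#' globular lobe (sphere) and an elongated lobe (prolate ellipsoid,
#' immunoglobulin-like aspect), each sampled uniformly in its interior with
#' the first bead anchored at the lobe centre. The default geometry is
#' calibrated so that the model's P(r) gives Rg = 30 +/- 1 A and
#' Dmax = 110 +/- 5 A.
#'
#' Lobes are sampled uniformly in their interiors, then recentred on the
#' lobe centre and isotropically rescaled so each lobe's sampled radius of
#' gyration equals the analytic value for its solid (removing finite-sample
#' scatter), and the beads nearest the two outer axial extremities are
#' snapped onto them, pinning `Dmax` at
#' `separation + sphere_radius + ellipsoid_semiaxes[1]`.
#'
#' @param n_per_domain beads per lobe; >= 1
#' @param separation centre-to-centre lobe distance, A
#' @param linker_beads beads placed evenly on the inter-lobe segment
#' @param seed integer seed
#' @param sphere_radius radius of the globular lobe, A
#' @param ellipsoid_semiaxes semi-axes of the elongated lobe, A (long axis
#'   along x)
#' @return a [bead_model()]
#' @export
gen_two_domain_beads <- function(n_per_domain = 75, separation = 50,
                                 linker_beads = 6, seed = 1,
                                 sphere_radius = 14,
                                 ellipsoid_semiaxes = c(48, 8, 8)) {
  stopifnot(n_per_domain >= 1, separation >= 0, linker_beads >= 0,
            sphere_radius > 0, all(ellipsoid_semiaxes > 0))
  sample_lobe <- function(n, semi, centre) {
    pts <- matrix(0, 0, 3)
    while (nrow(pts) < n) {
      cand <- matrix(stats::runif(3 * 2 * n, -1, 1), ncol = 3)
      keep <- rowSums(cand^2) <= 1
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE] %*% diag(semi)
    if (n >= 3L) {
      pts <- sweep(pts, 2L, colMeans(pts))      # exact lobe centroid
      rg_solid <- sqrt(sum(semi^2) / 5)          # uniform solid ellipsoid
      rg_sample <- sqrt(mean(rowSums(pts^2)))
      if (rg_sample > 0) pts <- pts * (rg_solid / rg_sample)
    } else pts[] <- 0
    sweep(pts, 2L, centre, `+`)
  }
  c_a <- c(-separation / 2, 0, 0)
  c_b <- c(+separation / 2, 0, 0)
  coords <- with_seed(seed, {
    a <- sample_lobe(n_per_domain, rep(sphere_radius, 3), c_a)
    b <- sample_lobe(n_per_domain, ellipsoid_semiaxes, c_b)
    if (n_per_domain >= 3L) {
      a[which.min(a[, 1L]), ] <- c_a - c(sphere_radius, 0, 0)
      b[which.max(b[, 1L]), ] <- c_b + c(ellipsoid_semiaxes[1L], 0, 0)
    }
    lnk <- if (linker_beads > 0)
      cbind(seq(c_a[1L], c_b[1L],
                length.out = linker_beads + 2L)[-c(1L, linker_beads + 2L)],
            0, 0)
    else matrix(0, 0, 3)
    rbind(a, lnk, b)
  })
  bead_model(coords)
}

#' Generate a synthetic DNA-release melting curve
#'
#' Fluorescence model: `baseline(T) * (1 - L(T)) + amplitude * L(T)` where
#' the closed-particle baseline declines linearly with temperature (the
#' dye's own response) and the released fraction `L` is a logistic in
#' temperature centred at `tex_true`, so the analytic maximum of the release
#' derivative sits exactly at `tex_true`.
#'
#' @param tex_true true DNA-exit temperature, degrees C (within the grid)
#' @param release_width logistic scale of the transition, degrees C; > 0
#' @param probe_slope fractional baseline decline per degree C
#' @param amplitude fluorescence of the fully released state, a.u.
#' @param grid temperature grid, degrees C (default 4-99 in 0.5 steps)
#' @param noise a [noise_spec()] (sd in a.u.)
#' @param baseline closed-state fluorescence at the start of the ramp, a.u.
#' @param condition metadata list attached to the curve
#' @return a [melt_curve()]
#' @export
gen_melt_curve <- function(tex_true, release_width = 2, probe_slope = 0.005,
                           amplitude = 1000, grid = seq(4, 99, by = 0.5),
                           noise = noise_spec(), baseline = 400,
                           condition = list()) {
  stopifnot(release_width > 0, tex_true >= 4, tex_true <= 99)
  if (tex_true < min(grid) || tex_true > max(grid))
    stop("tex_true = ", tex_true, " lies outside the temperature grid [",
         min(grid), ", ", max(grid), "]")
  L <- stats::plogis((grid - tex_true) / release_width)
  base <- baseline * pmax(0, 1 - probe_slope * (grid - grid[1L]))
  f <- base * (1 - L) + amplitude * L
  f <- with_seed(noise$seed,
                 f + if (noise$sd > 0) stats::rnorm(length(f), sd = noise$sd)
                     else 0)
  melt_curve(grid, f, condition)
}

#' Particle concentration from absorbance at 260 nm
#'
#' The empirical quantitation rule for purified phage particles:
#' `particles/mL = 3.4e11 * OD260`.
#'
#' @param od260 absorbance at 260 nm; >= 0
#' @return particles per mL
#' @export
particles_from_od <- function(od260) {
  stopifnot(is.numeric(od260), all(od260 >= 0))
  3.4e11 * od260
}

#' Decoration-site concentration from capsid concentration
#'
#' 120 hexamer-centre binding sites per capsid.
#'
#' @param capsid_conc molar capsid concentration; >= 0
#' @param sites_per_capsid number of decoration sites per capsid
#' @return molar site concentration
#' @export
site_concentration <- function(capsid_conc, sites_per_capsid = 120) {
  stopifnot(is.numeric(capsid_conc), all(capsid_conc >= 0))
  sites_per_capsid * capsid_conc
}
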