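#' Build the 120-site capsid decoration lattice
#'
#' The decoration sites sit at the centres of the 120 hexamers of the
#' icosahedral shell. Two adjacency embodiments are provided:
#' `"icosa-net"` deterministically wraps a triangular (hexagonal-net) tiling
#' onto a closed 10 x 12 surface, giving every site exactly six neighbours;
#' `"k-regular"` draws a seeded random k-regular graph. The true T=13
#' lattice is non-uniform near the pentamers; both modes are uniform
#' approximations intended for sensitivity checks against each other.
#'
#' @param mode `"icosa-net"` (deterministic) or `"k-regular"` (seeded)
#' @param k degree for the k-regular mode (`k * 120` must be even)
#' @param seed integer seed (k-regular mode only)
#' @param n_sites number of sites (120 for the capsid studied here)
#' @return an object of class `capsid_lattice`: `n_sites`, `edges`
#'   (two-column matrix, 1-based, symmetric, no self-edges), `mode`
#' @export
build_capsid_graph <- function(mode = c("icosa-net", "k-regular"), k = 6,
                               seed = 1, n_sites = 120) {
  mode <- match.arg(mode)
  if (mode == "k-regular") {
    if ((k * n_sites) %% 2 != 0)
      stop("k * n_sites must be even for a k-regular graph")
    g <- with_seed(seed, igraph::sample_k_regular(n_sites, k))
    edges <- igraph::as_edgelist(g)
  } else {
    # wrap a triangular net on a torus-like closure: rows x cols grid,
    # neighbours E, W, N, S, NE, SW (each site degree 6), deterministic
    rows <- 10L; cols <- as.integer(n_sites / 10L)
    stopifnot(rows * cols == n_sites)
    id <- function(r, c) ((r - 1L) %% rows) * cols + ((c - 1L) %% cols) + 1L
    e <- list()
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      a <- id(r, c)
      e[[length(e) + 1L]] <- rbind(c(a, id(r, c + 1L)),
                                   c(a, id(r + 1L, c)),
                                   c(a, id(r + 1L, c + 1L)))
    }
    edges <- do.call(rbind, e)
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges)
  }
  storage.mode(edges) <- "integer"
  structure(list(n_sites = as.integer(n_sites), edges = edges, mode = mode),
            class = "capsid_lattice")
}

#' @export
print.capsid_lattice <- function(x, ...) {
  cat(sprintf("capsid lattice (%s): %d sites, %d edges, mean degree %.2f\n",
              x$mode, x$n_sites, nrow(x$edges),
              2 * nrow(x$edges) / x$n_sites))
  invisible(x)
}

#' Node degrees of a capsid lattice
#' @param lattice a [build_capsid_graph()] result
#' @return integer vector of length `n_sites`
#' @export
lattice_degrees <- function(lattice) {
  tabulate(c(lattice$edges[, 1L], lattice$edges[, 2L]), lattice$n_sites)
}

adjacency_flat <- function(lattice) {
  n <- lattice$n_sites
  nb <- vector("list", n)
  for (i in seq_len(nrow(lattice$edges))) {
    a <- lattice$edges[i, 1L]; b <- lattice$edges[i, 2L]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  lens <- lengths(nb)
  list(adj = as.integer(unlist(nb) - 1L),
       offsets = as.integer(c(0L, cumsum(lens))))
}

#' Thermodynamic model of cooperative decoration
#'
#' Lattice-gas energetics in thermal units (kT): each bound ligand
#' contributes `dg_bind` (negative = intrinsically favourable) and each pair
#' of occupied neighbouring sites contributes `eps_coop` (negative = binding
#' is stabilised by occupied neighbours, the cooperative case). `ratio` is
#' the total ligand-to-site molar ratio of the mixture.
#'
#' @param dg_bind intrinsic site binding free energy, kT
#' @param eps_coop nearest-neighbour coupling, kT per occupied pair
#' @param ratio ligand:site molar ratio; >= 0
#' @return an object of class `decoration_model`
#' @export
decoration_model <- function(dg_bind, eps_coop = 0, ratio = 1) {
  stopifnot(is.finite(dg_bind), is.finite(eps_coop), ratio >= 0)
  structure(list(dg_bind = dg_bind, eps_coop = eps_coop, ratio = ratio),
            class = "decoration_model")
}

#' Simulate the equilibrium occupancy distribution of a decorated population
#'
#' Metropolis exchange moves of ligands between one shared finite pool and
#' the sites of `n_capsids` identical capsids. The configuration weight is
#' \eqn{e^{-E} v^F / F!} with \eqn{E = \Delta G N_{bound} +
#' \epsilon N_{pairs}}, `F` the free-ligand count and `v` an activity volume
#' (default: the total number of sites), so detailed balance holds and at
#' `eps_coop = 0` the stationary state is the independent-site isotherm.
#' Total ligand (`ratio * n_sites * n_capsids`) is conserved exactly.
#'
#' The first `burnin_frac` of the sweeps are discarded; the occupancy
#' histogram is accumulated over all post-burn-in sweeps. Equilibration is
#' diagnosed by comparing the mean occupancy of the third and fourth
#' quarters of the run; drift beyond `drift_tol` (fractional) sets the
#' `equilibrated` flag to `FALSE` with a warning.
#'
#' @param lattice a [build_capsid_graph()] result
#' @param model a [decoration_model()]
#' @param n_capsids number of capsids sharing the pool
#' @param sweeps Monte-Carlo sweeps (1 sweep = one attempted move per site)
#' @param seed integer seed
#' @param v activity volume of the free pool (default: total site count)
#' @param burnin_frac fraction of sweeps discarded as burn-in
#' @param drift_tol equilibration drift tolerance (fraction of mean occupancy)
#' @return an object of class `population_distribution`: `counts` (final
#'   per-capsid occupancy), `histogram` (mean over post-burn-in sweeps,
#'   bins 0..n_sites), `free`, `total_ligand`, `traj`, `equilibrated`
#' @export
simulate_population <- function(lattice, model, n_capsids = 500,
                                sweeps = 2000, seed = 1, v = NULL,
                                burnin_frac = 0.5, drift_tol = 0.02) {
  stopifnot(inherits(lattice, "capsid_lattice"),
            inherits(model, "decoration_model"),
            n_capsids >= 1, sweeps >= 4)
  af <- adjacency_flat(lattice)
  total <- round(model$ratio * lattice$n_sites * n_capsids)
  if (is.null(v)) v <- lattice$n_sites * n_capsids
  burnin <- as.integer(floor(sweeps * burnin_frac))
  raw <- with_seed(seed, .Call(C_coop_mc, lattice$n_sites, af$adj,
                               af$offsets, as.integer(n_capsids),
                               as.double(total), as.double(model$dg_bind),
                               as.double(model$eps_coop), as.double(v),
                               as.integer(sweeps), burnin, 1L))
  hist_counts <- raw$hist / max(1, sum(raw$hist) / n_capsids)

  q <- floor(sweeps / 4)
  m3 <- mean(raw$traj[(2 * q + 1):(3 * q)])
  m4 <- mean(raw$traj[(3 * q + 1):(4 * q)])
  scale_ref <- max(mean(c(m3, m4)), 1e-8)
  equilibrated <- abs(m4 - m3) / scale_ref <= drift_tol
  if (!equilibrated)
    warning(sprintf(
      "possible non-equilibration: mean occupancy drifts %.1f%% between the 3rd and 4th quarter of the run",
      100 * abs(m4 - m3) / scale_ref))

  stopifnot(sum(raw$count) + raw$free == total)  # exact ligand conservation
  structure(list(counts = raw$count, histogram = hist_counts,
                 n_sites = lattice$n_sites, n_capsids = n_capsids,
                 free = raw$free, total_ligand = total, traj = raw$traj,
                 equilibrated = equilibrated, model = model),
            class = "population_distribution")
}

#' @export
print.population_distribution <- function(x, ...) {
  gp <- gel_pattern(x)
  cat(sprintf("decorated population: %d capsids x %d sites, ratio %.2f\n",
              x$n_capsids, x$n_sites, x$model$ratio))
  cat(sprintf("  mean occupancy %.1f/%d; bands: %.0f%% undecorated, %.0f%% partial, %.0f%% saturated\n",
              mean(x$counts), x$n_sites,
              100 * gp[["undecorated"]], 100 * gp[["partial"]],
              100 * gp[["saturated"]]))
  if (!x$equilibrated) cat("  WARNING: equilibration diagnostic failed\n")
  invisible(x)
}

# occupancy-fraction masses of a population (final-state counts)
occupancy_fractions <- function(dist) dist$counts / dist$n_sites

#' Bimodality score of an occupancy distribution
#'
#' `1 - (mass in the middle tercile of fractional occupancy)` when both
#' outer terciles carry mass; 0 otherwise (unimodal mid-centred, all-empty
#' or all-full populations score 0 by convention). A fully bimodal
#' empty-plus-saturated population scores 1.
#'
#' @param dist a [simulate_population()] result
#' @param min_capsids minimum population size
#' @return score in `[0, 1]`
#' @export
bimodality_score <- function(dist, min_capsids = 100) {
  stopifnot(inherits(dist, "population_distribution"),
            dist$n_capsids >= min_capsids)
  x <- occupancy_fractions(dist)
  lo <- mean(x < 1 / 3); mid <- mean(x >= 1 / 3 & x <= 2 / 3)
  hi <- mean(x > 2 / 3)
  if (lo > 0 && hi > 0) 1 - mid else 0
}

#' Classify a decorated population into native-gel band fractions
#'
#' Capsids below 10% occupancy co-migrate with the undecorated band, above
#' 90% with the fully decorated band; everything between would appear at
#' intermediate mobility.
#'
#' @param dist a [simulate_population()] result
#' @param thresholds fractional occupancy cutpoints `c(low, high)`
#' @return named vector of fractions `(undecorated, partial, saturated)`
#' @export
gel_pattern <- function(dist, thresholds = c(0.1, 0.9)) {
  stopifnot(inherits(dist, "population_distribution"))
  x <- occupancy_fractions(dist)
  c(undecorated = mean(x < thresholds[1L]),
    partial = mean(x >= thresholds[1L] & x <= thresholds[2L]),
    saturated = mean(x > thresholds[2L]))
}

#' Intrinsic binding energy giving a target independent-site occupancy
#'
#' At `eps_coop = 0` the stationary occupancy solves the mean-field balance
#' \eqn{p/(1-p) = (F/v) e^{-\Delta G}} with `F = (ratio - p) * n_sites_total`
#' and `v` the default activity volume (the total site count). This helper
#' inverts that relation; it is the closed-form oracle against which the
#' sampler is validated.
#'
#' @param p target single-site occupancy probability in (0, 1)
#' @param ratio ligand:site molar ratio (must exceed `p`)
#' @return `dg_bind` in kT
#' @export
dg_for_occupancy <- function(p, ratio) {
  stopifnot(p > 0, p < 1, ratio > p)
  log((ratio - p) * (1 - p) / p)
}
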