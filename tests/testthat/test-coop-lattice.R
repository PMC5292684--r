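test_that("lattice construction gives 120 six-coordinated sites, reproducibly", {
  kreg <- build_capsid_graph("k-regular", k = 6, seed = 3)
  expect_identical(kreg$n_sites, 120L)
  expect_true(all(lattice_degrees(kreg) == 6))
  expect_identical(build_capsid_graph("k-regular", seed = 3)$edges, kreg$edges)
  expect_false(identical(build_capsid_graph("k-regular", seed = 4)$edges,
                         kreg$edges))
  expect_error(build_capsid_graph("k-regular", k = 5, n_sites = 121))

  net <- build_capsid_graph("icosa-net")
  expect_identical(net$n_sites, 120L)
  deg <- lattice_degrees(net)
  expect_lt(abs(mean(deg) - 6), 0.5)
  expect_true(all(net$edges[, 1] != net$edges[, 2]))  # no self-edges
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)  # connected
})

test_that("ligand is conserved exactly and runs are seed-reproducible", {
  lat <- build_capsid_graph("icosa-net")
  mod <- decoration_model(2, -1, 0.6)
  p1 <- simulate_population(lat, mod, n_capsids = 150, sweeps = 300, seed = 8)
  p2 <- simulate_population(lat, mod, n_capsids = 150, sweeps = 300, seed = 8)
  expect_identical(p1$counts, p2$counts)
  expect_equal(sum(p1$counts) + p1$free, p1$total_ligand)
  expect_identical(p1$total_ligand, round(0.6 * 120 * 150))
})

test_that("independent sites reproduce the closed-form binomial isotherm", {
  lat <- build_capsid_graph("k-regular", seed = 1)
  p_target <- 0.5
  mod <- decoration_model(dg_for_occupancy(p_target, 50), eps_coop = 0,
                          ratio = 50)
  pop <- simulate_population(lat, mod, n_capsids = 400, sweeps = 400, seed = 2)
  counts <- pop$counts
  expect_equal(mean(counts) / 120, p_target, tolerance = 0.02)
  # chi-square against Binomial(120, p) with pooled tails
  brk <- c(-Inf, seq(48, 72, by = 4), Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(pbinom(c(-Inf, seq(48, 72, by = 4), Inf), 120, p_target))
  keep <- pr > 0
  chisq <- suppressWarnings(chisq.test(as.vector(obs[keep]), p = pr[keep],
                                       rescale.p = TRUE))
  expect_gt(chisq$p.value, 0.01)
})

test_that("strong nearest-neighbour coupling makes decoration all-or-none", {
  lat <- build_capsid_graph("icosa-net")
  sub <- simulate_population(lat, decoration_model(4, -2, 0.4),
                             n_capsids = 300, sweeps = 4000, seed = 5)
  gp <- gel_pattern(sub)
  expect_lt(gp[["partial"]], 0.15)      # intermediates scarce
  expect_gt(gp[["undecorated"]], 0.5)   # most capsids bare at ratio 0.4
  expect_gt(gp[["saturated"]], 0.02)    # but a minority already saturated
  expect_gt(bimodality_score(sub), 0.8)

  sup <- simulate_population(lat, decoration_model(4, -2, 1.2),
                             n_capsids = 300, sweeps = 4000, seed = 5)
  expect_gt(gel_pattern(sup)[["saturated"]], 0.9)
})

test_that("bimodality scoring follows its conventions", {
  fake <- function(counts) structure(
    list(counts = counts, n_sites = 120, n_capsids = length(counts)),
    class = "population_distribution")
  expect_identical(bimodality_score(fake(rep(c(0L, 120L), each = 60))), 1)
  expect_identical(bimodality_score(fake(rep(60L, 150))), 0)
  expect_identical(bimodality_score(fake(rep(0L, 150))), 0)    # all empty
  expect_identical(bimodality_score(fake(rep(120L, 150))), 0)  # all full
  mixed <- fake(c(rep(0L, 50), rep(60L, 30), rep(120L, 70)))
  expect_equal(bimodality_score(mixed), 1 - 30 / 150)
  # relabelling capsids changes nothing
  expect_identical(bimodality_score(fake(sample(mixed$counts))),
                   bimodality_score(mixed))
})

test_that("gel band classification matches occupancy thresholds", {
  fake <- function(counts) structure(
    list(counts = counts, n_sites = 120, n_capsids = length(counts)),
    class = "population_distribution")
  expect_equal(gel_pattern(fake(rep(120L, 10))),
               c(undecorated = 0, partial = 0, saturated = 1))
  # independent-site run at mean occupancy 0.4: nearly everything partial
  counts <- rbinom(500, 120, 0.4)
  expect_gt(gel_pattern(fake(counts))[["partial"]], 0.9)
})

test_that("mean occupancy grows with ligand ratio and bimodality with coupling strength", {
  lat <- build_capsid_graph("icosa-net")
  occ <- vapply(c(0.2, 0.6, 1.0), function(r) {
    mean(vapply(1:3, function(s)
      mean(simulate_population(lat, decoration_model(-1, -0.5, r),
                               n_capsids = 60, sweeps = 400,
                               seed = s)$counts), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(occ) > 0))

  # very favourable binding: all ligand bound, mean occupancy pinned at 0.4,
  # so the coupling strength isolates its effect on the population shape
  scores <- vapply(c(0, -0.8, -1.6, -2.4), function(eps)
    bimodality_score(simulate_population(
      lat, decoration_model(-6, eps, 0.4), n_capsids = 150, sweeps = 1500,
      seed = 4)), numeric(1))
  expect_gt(scores[4], scores[1])
  expect_gt(cor(seq_along(scores), scores), 0.8)
})
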