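test_that("pheromone initialisation maps PIC monotonically and reproducibly", {
  # equal PIC: include probability uniform across loci
  ph <- init_pheromones(5, "pic", pic_values = rep(0.6, 5))
  p_in <- ph$tau_in^0.7 / (ph$tau_in^0.7 + ph$tau_out^0.7)
  expect_true(all(abs(p_in - p_in[1]) < 1e-12))
  # higher PIC, strictly stronger include trail
  ph2 <- init_pheromones(2, "pic", pic_values = c(0.95, 0.12))
  expect_gt(ph2$tau_in[1], ph2$tau_in[2])
  expect_lt(ph2$tau_out[1], ph2$tau_out[2])
  expect_equal(ph2$tau_in, 0.01 + c(0.95, 0.12))
  # random mode reproducible under a seed, strictly positive
  r1 <- withr::with_seed(5, init_pheromones(8, "random"))
  r2 <- withr::with_seed(5, init_pheromones(8, "random"))
  expect_identical(r1, r2)
  expect_true(all(r1$tau_in > 0 & r1$tau_out > 0))
  expect_error(init_pheromones(3, "pic"), "pic_values")
})

test_that("free construction matches the tau^alpha inclusion law", {
  # k large enough that the >= 2-locus resampling correction is negligible
  withr::with_seed(8, {
    # equal trails: each locus in with probability 1/2
    ph <- structure(list(tau_in = rep(0.4, 12), tau_out = rep(0.4, 12)),
                    class = "pheromone_state")
    draws <- picaco:::construct_panels(ph, alpha = 0.7, n = NULL, m = 4000)
    freq <- rowMeans(draws)
    se <- sqrt(0.25 / 4000)
    expect_true(all(abs(freq - 0.5) < 3.5 * se))
    # skewed trails follow the closed form
    tau_in <- rep(c(0.9, 0.2, 0.5, 0.7), 2)
    tau_out <- rep(c(0.1, 0.7, 0.5, 0.3), 2)
    ph2 <- structure(list(tau_in = tau_in, tau_out = tau_out),
                     class = "pheromone_state")
    p_expect <- tau_in^0.7 / (tau_in^0.7 + tau_out^0.7)
    draws2 <- picaco:::construct_panels(ph2, alpha = 0.7, n = NULL, m = 10000)
    freq2 <- rowMeans(draws2)
    se2 <- sqrt(p_expect * (1 - p_expect) / 10000)
    expect_true(all(abs(freq2 - p_expect) < 3.5 * se2))
  })
})

test_that("fixed-size construction returns exact sizes; n = k forces the full set", {
  ph <- init_pheromones(5, "pic", pic_values = c(0.9, 0.8, 0.1, 0.2, 0.5))
  withr::with_seed(3, {
    draws <- picaco:::construct_panels(ph, alpha = 0.7, n = 3, m = 200)
    expect_true(all(colSums(draws) == 3))
    full <- construct_solution(ph, n = 5)
    expect_true(all(full))
  })
})

test_that("pheromone updates evaporate, deposit by rank, and stay positive", {
  ph <- structure(list(tau_in = rep(1, 4), tau_out = rep(1, 4)),
                  class = "pheromone_state")
  cfg <- aco_config(ants = 2, elite_frac = 0.5)  # one elite ant
  # a worthless solution (loss 100) deposits nothing: pure decay
  panels <- matrix(c(1, 1, 0, 0), ncol = 1)
  ph1 <- update_pheromones(ph, panels, losses = 100, cfg)
  expect_equal(ph1$tau_in, rep(0.9, 4))
  expect_equal(ph1$tau_out, rep(0.9, 4))
  # a zero-loss solution deposits exactly 1 on its traversed edges
  ph2 <- update_pheromones(ph, panels, losses = 0, cfg)
  expect_equal(ph2$tau_in, c(1.9, 1.9, 0.9, 0.9))
  expect_equal(ph2$tau_out, c(0.9, 0.9, 1.9, 1.9))
  # elite chosen by rank: better panel's edges end up stronger
  two <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  ph3 <- update_pheromones(ph, two, losses = c(10, 60), cfg)
  expect_gt(ph3$tau_in[1], ph3$tau_in[2])
  # trails never fall below the positive floor
  ph4 <- ph
  for (i in 1:200) ph4 <- update_pheromones(ph4, panels, losses = 100, cfg)
  expect_true(all(ph4$tau_in >= 0.01 & ph4$tau_out >= 0.01))
})

test_that("seeded ACO runs are deterministic with monotone best-loss traces", {
  g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 6, seed = 41)
  a1 <- aco_select(g, n = 3, config = fast_config(), seed = 7)
  a2 <- aco_select(g, n = 3, config = fast_config(), seed = 7)
  expect_identical(a1$trace, a2$trace)
  expect_identical(a1$panel, a2$panel)
  expect_true(all(diff(a1$trace$best_loss) <= 1e-12))
  expect_equal(a1$n, 3)
  # n = k short-circuits to the full panel at zero loss
  full <- aco_select(g, n = 6, config = fast_config(), seed = 1)
  expect_equal(full$loss, 0)
  expect_equal(full$panel, loci(g))
  expect_error(aco_select(g, n = 1, config = fast_config()), "2..k")
  expect_error(aco_select(g, n = 3, margin = 5), "exactly one")
})

test_that("fixed-size ACO finds the exhaustive optimum on small instances", {
  hits <- 0
  for (i in 1:5) {
    g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 8, seed = 50 + i)
    ex <- exhaustive_panel(g, n = 3)
    fit <- aco_select(g, n = 3, config = aco_config(ants = 20, epochs = 40),
                      seed = i)
    hits <- hits + (fit$loss <= ex$loss + 1e-9)
  }
  expect_gte(hits, 4)
})

test_that("margin mode reduces progressively and respects degenerate margins", {
  g <- planted_fixture()
  # an unreachably generous margin reduces to the floor of 2 loci
  fit <- aco_select(g, margin = 1e6, config = fast_config(), seed = 2)
  expect_equal(fit$n, 2)
  # margin <= 0 returns the full set with a warning
  expect_warning(fit0 <- aco_select(g, margin = 0, config = fast_config()),
                 "full marker set")
  expect_equal(fit0$n, n_loci(g))
  expect_equal(fit0$loss, 0)
})

test_that("the exhaustive oracle enumerates correctly and refuses large k", {
  g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 3,
                          missing_rate = 0, seed = 61)
  ex <- exhaustive_panel(g, n = 2)
  # brute force over the 3 possible pairs, computed independently
  losses <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ix) {
    accuracy_loss(g, loci(g)[ix])
  }, 0)
  expect_equal(ex$loss, min(losses))
  expect_equal(ex$panel, loci(g)[list(c(1, 2), c(1, 3), c(2, 3))[[which.min(losses)]]])
  # permutation of locus labels permutes the optimum consistently
  tb <- tibble::as_tibble(g)
  perm <- c(L03 = "A", L01 = "B", L02 = "C")
  tb$locus <- unname(perm[tb$locus])
  g2 <- genotype_tbl(tb, loci = c("B", "C", "A"))
  ex2 <- exhaustive_panel(g2, n = 2)
  expect_setequal(unname(perm[ex$panel]), ex2$panel)
  expect_equal(ex2$loss, ex$loss)
  expect_error(exhaustive_panel(g, n = 2, max_loci = 2), "refusing")
})
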