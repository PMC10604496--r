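test_that("the simulator honours its configuration", {
  g <- simulate_genotypes(n_pops = 3, n_per_pop = c(5, 7, 9), n_loci = 4,
                          allele_range = c(3, 6), missing_rate = 0, seed = 91)
  expect_equal(length(individuals(g)), 21)
  expect_equal(n_loci(g), 4)
  expect_equal(length(populations(g)), 3)
  tb <- tibble::as_tibble(g)
  expect_false(anyNA(tb$allele_1))                 # missing_rate = 0
  st <- locus_stats(g)
  expect_true(all(st$Na <= 6))                     # never above the cap
  # reproducibility
  g2 <- simulate_genotypes(n_pops = 3, n_per_pop = c(5, 7, 9), n_loci = 4,
                           allele_range = c(3, 6), missing_rate = 0, seed = 91)
  expect_identical(tibble::as_tibble(g), tibble::as_tibble(g2))
  expect_warning(simulate_genotypes(allele_range = c(1, 1), n_loci = 1,
                                    n_per_pop = 4, seed = 1),
                 "fewer than 2 alleles")
})

test_that("missing calls appear at roughly the configured rate", {
  g <- simulate_genotypes(n_pops = 1, n_per_pop = 400, n_loci = 5,
                          missing_rate = 0.2, seed = 93)
  tb <- tibble::as_tibble(g)
  rate <- mean(is.na(tb$allele_1))
  expect_lt(abs(rate - 0.2), 3.5 * sqrt(0.2 * 0.8 / nrow(tb)))
  # missing is genotype-level: allele_2 missing exactly where allele_1 is
  expect_identical(is.na(tb$allele_1), is.na(tb$allele_2))
})

test_that("Fst controls across-population frequency divergence", {
  spread_at <- function(fst) {
    g <- simulate_genotypes(n_pops = 6, n_per_pop = 60, n_loci = 6,
                            allele_range = c(4, 4), fst = fst,
                            missing_rate = 0, seed = 95)
    fr <- allele_freqs(g, "population")
    sd_by <- dplyr::summarise(
      dplyr::group_by(fr, locus, allele),
      s = sd(freq), n_pop = dplyr::n(), .groups = "drop")
    mean(sd_by$s[sd_by$n_pop == 6])
  }
  expect_lt(spread_at(0.001), spread_at(0.3) / 3)
})

test_that("a near-fixed ancestral p = 0.5 biallelic locus shows Ho around 0.5", {
  g <- simulate_genotypes(n_pops = 1, n_per_pop = 1000, n_loci = 1,
                          allele_range = c(2, 2), fst = 1e-3,
                          concentration = 1e6, missing_rate = 0, seed = 97)
  st <- locus_stats(g)
  expect_lt(abs(st$Ho - 0.5), 3 * sqrt(0.25 / 1000))
  # pooled frequencies converge on the (symmetric) ancestral vector
  fr <- allele_freqs(g, "pooled")
  expect_true(all(abs(fr$freq - 0.5) < 0.05))
})

test_that("the planted instance is reproducible with exact design frequencies", {
  g1 <- make_planted_instance(seed = 7)
  g2 <- make_planted_instance(seed = 7)
  expect_identical(tibble::as_tibble(g1), tibble::as_tibble(g2))
  expect_equal(attr(g1, "planted_loci"), c("L01", "L02", "L03", "L04"))
  # allele frequencies hit the designed profiles to rounding precision
  fr <- allele_freqs(g1, "population")
  prof <- picaco:::planted_profiles(10, 4, 1)
  f_l1_p1 <- fr$freq[fr$locus == "L01" & fr$group == "P1"]
  # largest-remainder rounding at 2000 alleles: within 1/2000 per allele
  expect_equal(length(f_l1_p1), 12)
  expect_true(all(abs(sort(f_l1_p1) - sort(prof[[1]][[1]])) <= 5e-4 + 1e-12))
})

test_that("the exhaustive oracle recovers the planted panel", {
  g <- planted_fixture()
  planted <- attr(g, "planted_loci")
  ex <- exhaustive_panel(g, n = attr(g, "n_best"))
  expect_setequal(ex$panel, planted)
  # and margin-mode enumeration gives the same panel at the stated margin
  exm <- exhaustive_panel(g, margin = attr(g, "margin"))
  expect_setequal(exm$panel, planted)
})

test_that("the planted panel is uniquely loss-preserving at its size", {
  g <- planted_fixture()
  planted <- attr(g, "planted_loci")
  margin <- attr(g, "margin")
  # the planted quartet reproduces the full-panel AGD within the margin ...
  expect_lt(accuracy_loss(g, planted), margin)
  # ... with a wide gap to the best competing panel of the same size
  ev <- picaco:::panel_evaluator(g)
  losses_at <- function(size) {
    combos <- utils::combn(ev$k, size)
    panels <- matrix(0, ev$k, ncol(combos))
    panels[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = size))] <- 1
    stats::setNames(as.numeric(ev$loss(panels)),
                    apply(combos, 2, function(ix) paste(ev$loci[ix], collapse = "+")))
  }
  at4 <- sort(losses_at(attr(g, "n_best")))
  expect_equal(names(at4)[1], paste(planted, collapse = "+"))
  expect_gt(at4[2], at4[1] + 4)          # wide gap to the runner-up
  # ... and every smaller panel overshoots the margin decisively
  expect_gt(min(losses_at(2)), margin)
  expect_gt(min(losses_at(3)), margin)
})

test_that("planted signal loci are the high-PIC loci", {
  st <- locus_stats(planted_fixture())
  sig <- st$PIC[st$locus %in% c("L01", "L02", "L03", "L04")]
  noise <- st$PIC[!st$locus %in% c("L01", "L02", "L03", "L04")]
  expect_gt(min(sig), max(noise))
})
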