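test_that("allele frequencies match hand counts under every grouping", {
  g <- gt_from_calls(list(i1 = c("p1", 1, 1), i2 = c("p1", 1, 2)), "L")
  fr <- allele_freqs(g, "pooled")
  expect_equal(fr$freq, c(0.75, 0.25))   # 3 of 4 alleles are '1'
  expect_equal(unique(fr$n_obs), 2L)

  fi <- allele_freqs(g, "individual")
  f2 <- fi[fi$group == "i2", ]
  expect_equal(f2$freq, c(0.5, 0.5))     # diploid identity

  # frequencies sum to 1 per (group, locus) on messy simulated data
  gs <- simulate_genotypes(n_pops = 3, n_per_pop = 12, n_loci = 5,
                           missing_rate = 0.15, seed = 5)
  fp <- allele_freqs(gs, "population")
  sums <- dplyr::summarise(dplyr::group_by(fp, group, locus),
                           s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("all-missing loci are flagged, not dropped", {
  tb <- tibble::as_tibble(toy_gt())
  tb$allele_1[tb$locus == "L2"] <- 0L
  g <- genotype_tbl(tb)
  expect_warning(fr <- allele_freqs(g, "population"), "zero observed")
  expect_true(all(attr(fr, "empty_groups")$locus == "L2"))
  expect_warning(st <- locus_stats(g), "zero observed")
  expect_true(is.na(st$PIC[st$locus == "L2"]))
  expect_equal(st$n_obs[st$locus == "L2"], 0L)
})

test_that("PIC follows the codominant two-term formula", {
  expect_equal(pic(1), 0)                                  # monomorphic
  expect_equal(pic(c(0.5, 0.5)), 0.375)                    # 1 - 1/2 - 2/16
  expect_equal(pic(c(0.9, 0.1)), 1 - 0.82 - 2 * 0.81 * 0.01)
  expect_error(pic(numeric(0)), "empty")
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
})

test_that("effective allele count is the inverse homozygosity", {
  expect_equal(n_effective(c(0.5, 0.5)), 2)
  expect_equal(n_effective(c(0.9, 0.1)), 1 / 0.82)
  expect_equal(n_effective(1), 1)
  expect_error(n_effective(numeric(0)), "empty")
})

test_that("PIC <= He and Nea <= Na on random frequency vectors", {
  withr::with_seed(7, {
    for (i in 1:200) {
      m <- sample(2:12, 1)
      p <- rgamma(m, 1); p <- p / sum(p)
      expect_lte(pic(p), expected_het(p) + 1e-12)
      expect_lte(n_effective(p), m)
      expect_gte(n_effective(p), 1)
    }
  })
  # equality cases: uniform frequencies reach Nea = Na
  expect_equal(n_effective(rep(0.25, 4)), 4)
})

test_that("heterozygosities count distinct-allele genotypes and pooled He", {
  g <- gt_from_calls(list(i1 = c("p", 1, 2), i2 = c("p", 1, 1),
                          i3 = c("p", 2, 2), i4 = c("p", 1, 2)), "L")
  h <- heterozygosities(g, "L")
  expect_equal(unname(h["Ho"]), 0.5)     # 2 of 4 genotypes heterozygous
  expect_equal(unname(h["He"]), 0.5)     # pooled p = (0.5, 0.5)

  mono <- gt_from_calls(list(i1 = c("p", 3, 3), i2 = c("p", 3, 3)), "L")
  expect_equal(unname(heterozygosities(mono, "L")), c(0, 0))
  expect_error(heterozygosities(g, "nope"), "unknown locus")
})

test_that("allele richness is alleles per genotyped individual", {
  # the ratios the statistic is defined to reproduce
  expect_equal(5 / 652, 0.00767, tolerance = 1e-3)
  expect_equal(82 / 652, 0.1258, tolerance = 1e-3)
  expect_equal(9 / 79, 0.1139, tolerance = 1e-3)
  g <- random_gt(n_ind = 20, k = 3, missing_rate = 0, seed = 11)
  st <- locus_stats(g)
  expect_equal(st$AR, st$Na / 20)
  expect_equal(allele_richness(g, "M1"), st$AR[1])
})

test_that("locus_stats satisfies its invariants and relabeling invariance", {
  g <- simulate_genotypes(n_pops = 2, n_per_pop = 25, n_loci = 6,
                          missing_rate = 0.05, seed = 9)
  st <- locus_stats(g)
  expect_equal(nrow(st), 6)
  expect_true(all(st$Nea >= 1 & st$Nea <= st$Na + 1e-12))
  expect_true(all(st$PIC >= 0 & st$PIC <= st$He & st$He <= 1))
  expect_true(all(st$Ho >= 0 & st$Ho <= 1))

  # relabeling allele codes and shuffling individuals changes nothing
  tb <- tibble::as_tibble(g)
  relabel <- function(a) ifelse(is.na(a), NA_integer_, a * 7L + 3L)
  tb$allele_1 <- relabel(tb$allele_1)
  tb$allele_2 <- relabel(tb$allele_2)
  tb <- tb[sample(nrow(tb)), ]
  tb <- dplyr::arrange(tb, match(individual, unique(individual)))
  st2 <- locus_stats(genotype_tbl(tb, loci = loci(g)))
  expect_equal(st2[c("Na", "Nea", "AR", "PIC", "Ho", "He")],
               st[c("Na", "Nea", "AR", "PIC", "Ho", "He")])
})

test_that("summary table reports min, max and mean per statistic", {
  g <- random_gt(n_ind = 30, k = 5, seed = 13)
  st <- locus_stats(g)
  sm <- locus_stats_summary(st)
  expect_equal(sm$statistic, c("Na", "Nea", "AR", "PIC", "Ho", "He"))
  expect_equal(sm$mean[sm$statistic == "PIC"], mean(st$PIC))
  expect_equal(sm$min[sm$statistic == "Na"], min(st$Na))
})

test_that("the unbiased He estimator applies the 2n/(2n-1) factor", {
  expect_equal(expected_het(c(0.5, 0.5), unbiased = TRUE, n_obs = 10),
               0.5 * 20 / 19)
  expect_error(expected_het(c(0.5, 0.5), unbiased = TRUE), "n_obs")
})
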