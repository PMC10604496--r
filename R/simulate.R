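#' Simulate multi-allelic genotypes under the Balding-Nichols model
#'
#' Per locus, an ancestral allele frequency vector is drawn from a symmetric
#' Dirichlet; each population's frequencies are then drawn from a Dirichlet
#' centred on the ancestral vector with concentration
#' \eqn{(1 - F_{st}) / F_{st}}, so `fst` tunes between-population divergence.
#' Genotypes are sampled under Hardy-Weinberg equilibrium within population,
#' and whole genotypes are masked to missing independently at `missing_rate`
#' (both alleles together, matching the missing-genotype convention of
#' [genotype_tbl()]).
#'
#' Defaults emulate a modest multi-population microsatellite survey: a few
#' subpopulations of tens of individuals, ten loci carrying 5-20 alleles
#' each, moderate structure and a low missing-call rate.
#'
#' @param n_pops Number of subpopulations.
#' @param n_per_pop Individuals per subpopulation (recycled to `n_pops`).
#' @param n_loci Number of loci.
#' @param allele_range Inclusive range of per-locus allele counts; drawn
#'   uniformly per locus. A locus may be requested with fewer than 2 alleles
#'   (monomorphic edge case), which is allowed but flagged with a warning.
#' @param fst Divergence parameter in (0, 1).
#' @param concentration Symmetric Dirichlet concentration for the ancestral
#'   frequencies (1 = uniform over the simplex).
#' @param missing_rate Per-genotype missing probability in \[0, 1).
#' @param seed Optional integer seed; the run is reproducible given it.
#' @return A [genotype_tbl] with populations `P1..P<n_pops>`, individuals
#'   `P<i>_<j>` and loci `L01..`.
#' @examples
#' g <- simulate_genotypes(seed = 1)
#' locus_stats(g)
#' @export
simulate_genotypes <- function(n_pops = 4, n_per_pop = 30, n_loci = 10,
                               allele_range = c(5, 20), fst = 0.15,
                               concentration = 1, missing_rate = 0.02,
                               seed = NULL) {
  stopifnot(n_pops >= 1, all(n_per_pop >= 1), n_loci >= 1,
            fst > 0, fst < 1, missing_rate >= 0, missing_rate < 1,
            concentration > 0)
  allele_range <- sort(as.integer(allele_range))
  if (length(allele_range) == 1) allele_range <- rep(allele_range, 2)
  if (allele_range[1] < 2) {
    warning("locus with fewer than 2 alleles requested; monomorphic loci allowed",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  pops <- paste0("P", seq_len(n_pops))
  lv <- sprintf("L%02d", seq_len(n_loci))
  kappa <- (1 - fst) / fst

  rdirichlet <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
    x / sum(x)
  }

  rows <- vector("list", n_loci)
  for (li in seq_len(n_loci)) {
    n_alleles <- if (allele_range[1] == allele_range[2]) allele_range[1] else
      sample(seq(allele_range[1], allele_range[2]), 1)
    anc <- rdirichlet(rep(concentration, n_alleles))
    per_pop <- lapply(seq_len(n_pops), function(p) rdirichlet(anc * kappa))
    a1 <- integer(0); a2 <- integer(0); ind <- character(0); pop <- character(0)
    for (p in seq_len(n_pops)) {
      n <- n_per_pop[p]
      draws <- sample.int(n_alleles, 2 * n, replace = TRUE, prob = per_pop[[p]])
      a1 <- c(a1, draws[seq_len(n)])
      a2 <- c(a2, draws[n + seq_len(n)])
      ind <- c(ind, sprintf("%s_%03d", pops[p], seq_len(n)))
      pop <- c(pop, rep(pops[p], n))
    }
    rows[[li]] <- tibble::tibble(individual = ind, population = pop,
                                 locus = lv[li], allele_1 = a1, allele_2 = a2)
  }
  out <- dplyr::bind_rows(rows)
  if (missing_rate > 0) {
    mask <- stats::runif(nrow(out)) < missing_rate
    out$allele_1[mask] <- NA_integer_
    out$allele_2[mask] <- NA_integer_
  }
  out <- dplyr::arrange(out, match(.data$individual, unique(.data$individual)),
                        match(.data$locus, lv))
  genotype_tbl(out, loci = lv)
}

#' Construct a genotype dataset with a known optimal marker panel
#'
#' Builds a two-population dataset in which `n_best` designated "signal"
#' loci (highly polymorphic, strongly and heterogeneously differentiated)
#' jointly reproduce the full-panel average genetic distance almost exactly,
#' while every smaller panel misses it by a wide margin. The remaining loci
#' are low-polymorphism background whose contributions are balanced so that
#' the signal panel is the unique loss-minimising panel of its size and the
#' smallest panel within a 5% accuracy-loss margin. The construction is
#' verified in the package tests with the exhaustive oracle
#' ([exhaustive_panel()]).
#'
#' Population allele profiles follow a fixed design (scaled by `separation`).
#' Allele counts are allocated to match the design frequencies exactly
#' (largest-remainder rounding at `2 * n_per_pop` alleles), then paired at
#' random into diploid genotypes: genotype-level statistics (e.g. Ho) are
#' stochastic while the allele frequencies - and hence the loss landscape
#' the panel search sees - are fixed by construction.
#'
#' @param k Total number of loci (>= `n_best` + 2).
#' @param n_best Size of the planted optimal panel.
#' @param n_per_pop Individuals sampled per population; large values keep
#'   the empirical loss landscape close to the designed one.
#' @param separation Scale in (0, 1] for the differentiation of the signal
#'   loci relative to the background; 1 (default) is the verified design.
#' @param seed Optional integer seed.
#' @return A [genotype_tbl] with attributes `planted_loci` (character),
#'   `margin` (the accuracy-loss margin, in percent, at which margin-mode
#'   selection recovers the planted panel) and `n_best`.
#' @examples
#' g <- make_planted_instance(seed = 1)
#' attr(g, "planted_loci")
#' @export
make_planted_instance <- function(k = 10, n_best = 4, n_per_pop = 1000,
                                  separation = 1, seed = NULL) {
  stopifnot(n_best >= 2, k >= n_best + 2, separation > 0, separation <= 1,
            n_per_pop >= 10)
  if (!is.null(seed)) set.seed(seed)
  prof <- planted_profiles(k, n_best, separation)
  lv <- sprintf("L%02d", seq_len(k))
  rows <- vector("list", k)
  for (li in seq_len(k)) {
    a1 <- integer(0); a2 <- integer(0); ind <- character(0); pop <- character(0)
    for (p in 1:2) {
      freqs <- prof[[li]][[p]]
      pool <- sample(rep.int(seq_along(freqs),
                             largest_remainder(freqs, 2 * n_per_pop)))
      a1 <- c(a1, pool[seq_len(n_per_pop)])
      a2 <- c(a2, pool[n_per_pop + seq_len(n_per_pop)])
      ind <- c(ind, sprintf("P%d_%04d", p, seq_len(n_per_pop)))
      pop <- c(pop, rep(paste0("P", p), n_per_pop))
    }
    rows[[li]] <- tibble::tibble(individual = ind, population = pop,
                                 locus = lv[li], allele_1 = a1, allele_2 = a2)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, match(.data$individual, unique(.data$individual)),
                        match(.data$locus, lv))
  g <- genotype_tbl(out, loci = lv)
  attr(g, "planted_loci") <- lv[seq_len(n_best)]
  attr(g, "n_best") <- n_best
  attr(g, "margin") <- 5
  g
}

# integer allele counts matching p as closely as possible at `total` draws
largest_remainder <- function(p, total) {
  raw <- p * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Fixed population frequency profiles behind make_planted_instance.
#
# Signal loci: 12 equally-spaced alleles; population 1 concentrates on the
# first six with skew s1, population 2 mirrors with its own skew s2; unequal
# skews make each locus's contribution to the Nei similarity sums
# asymmetric between populations, which is what prevents accidental
# cancellation among sub-panels. Background loci: biallelic with mirrored
# unequal skews x1 / x2. The numeric skews were chosen (and are verified by
# exhaustive enumeration in the tests) so that the signal panel reproduces
# the full-panel AGD while every 2- and 3-locus panel misses it widely.
planted_profiles <- function(k, n_best, separation = 1) {
  base <- planted_design_constants()
  s1 <- rep_len(base$s1, n_best) * separation
  s2 <- rep_len(base$s2, n_best) * separation
  x1 <- 0.5 + (rep_len(base$x1, k - n_best) - 0.5) * separation
  x2 <- 0.5 + (rep_len(base$x2, k - n_best) - 0.5) * separation
  prof <- vector("list", k)
  for (j in seq_len(k)) {
    if (j <= n_best) {
      p1 <- c(rep((1 + s1[j]) / 12, 6), rep((1 - s1[j]) / 12, 6))
      p2 <- rev(c(rep((1 + s2[j]) / 12, 6), rep((1 - s2[j]) / 12, 6)))
    } else {
      jj <- j - n_best
      p1 <- c(x1[jj], 1 - x1[jj])
      p2 <- c(1 - x2[jj], x2[jj])
    }
    prof[[j]] <- list(p1, p2)
  }
  prof
}

# Skew constants for the default (k = 10, n_best = 4) planted design; found
# by direct search over the skew space against exact enumeration of all
# panel losses, then validated on sampled genotypes.
planted_design_constants <- function() {
  list(
    s1 = c(0.8435, 0.1573, 0.0500, 0.2062),
    s2 = c(0.7373, 0.2916, 0.2858, 0.0500),
    x1 = c(0.5654, 0.2773, 0.3698, 0.9700, 0.5060, 0.8006),
    x2 = c(0.8881, 0.5769, 0.4459, 0.9586, 0.4123, 0.3514)
  )
}

#' Leave-one-locus-out influence on the average genetic distance
#'
#' A PIC-free measure of how much between-group differentiation each locus
#' carries under the panel cost: the accuracy loss (in percent) of the panel
#' that drops just that locus.
#'
#' @param g A [genotype_tbl].
#' @param grouping As in [genetic_dist()].
#' @return A tibble with columns `locus` and `influence`.
#' @export
locus_influence <- function(g, grouping = "auto") {
  ev <- panel_evaluator(g, grouping)
  panels <- 1 - diag(ev$k)
  tibble::tibble(locus = ev$loci, influence = as.numeric(ev$loss(panels)))
}
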