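#' Allele frequencies by population, pooled, or per individual
#'
#' Frequencies are computed from observed (non-missing) alleles only, so the
#' denominator varies by locus and group. Groups with no observed genotype at
#' a locus contribute no frequency rows; these gaps are recorded in the
#' `empty_groups` attribute rather than dropped silently.
#'
#' @param g A [genotype_tbl].
#' @param grouping `"population"` (one frequency vector per population and
#'   locus), `"pooled"` (all individuals together), or `"individual"` (each
#'   individual is its own group, so frequencies are 0, 0.5 or 1).
#' @return A tibble with columns `group`, `locus`, `allele`, `freq`, `n_obs`
#'   (`n_obs` counts non-missing genotypes behind the frequency vector).
#'   Attribute `empty_groups` is a tibble of (group, locus) pairs with no
#'   observations.
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 10, n_loci = 3, seed = 1)
#' allele_freqs(g, "pooled")
#' @export
allele_freqs <- function(g, grouping = c("population", "pooled", "individual")) {
  g <- as_genotype_tbl(g)
  grouping <- match.arg(grouping)
  x <- tibble::as_tibble(g)
  x$group <- switch(grouping,
    population = x$population,
    pooled = "pooled",
    individual = x$individual
  )
  lv <- loci(g)
  groups <- unique(x$group)

  obs <- x[!is.na(x$allele_1), c("group", "locus", "allele_1", "allele_2")]
  long <- tidyr::pivot_longer(obs, c("allele_1", "allele_2"),
                              values_to = "allele")
  counts <- dplyr::count(long, .data$group, .data$locus, .data$allele)
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$group, .data$locus),
    freq = .data$n / sum(.data$n),
    n_obs = as.integer(sum(.data$n) / 2)
  )
  counts <- dplyr::ungroup(counts)
  out <- dplyr::arrange(counts[c("group", "locus", "allele", "freq", "n_obs")],
                        match(.data$group, groups), match(.data$locus, lv),
                        .data$allele)

  full <- tidyr::expand_grid(group = groups, locus = lv)
  seen <- dplyr::distinct(out[c("group", "locus")])
  empty <- dplyr::anti_join(full, seen, by = c("group", "locus"))
  if (nrow(empty) > 0) {
    dead <- vapply(lv, function(l) {
      sum(empty$locus == l) == length(groups)
    }, logical(1))
    if (any(dead)) {
      warning("locus with zero observed alleles in every group: ",
              paste(lv[dead], collapse = ", "), call. = FALSE)
    }
  }
  attr(out, "empty_groups") <- empty
  attr(out, "grouping") <- grouping
  attr(out, "loci") <- lv
  out
}

#' Polymorphic information content of an allele frequency vector
#'
#' Uses the codominant-marker formula of Botstein et al.:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2}
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return PIC in \eqn{[0, 1)}; 0 for a monomorphic locus.
#' @examples
#' pic(c(0.5, 0.5)) # 0.375
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Effective number of alleles
#'
#' \eqn{Nea = 1 / \sum_i p_i^2}: the number of equifrequent alleles that
#' would give the same expected homozygosity.
#'
#' @inheritParams pic
#' @return A value in \eqn{[1, Na]}, reaching `Na` only for uniform
#'   frequencies.
#' @examples
#' n_effective(c(0.9, 0.1)) # 1 / 0.82
#' @export
n_effective <- function(freqs) {
  check_freqs(freqs)
  1 / sum(freqs^2)
}

#' Expected heterozygosity
#'
#' Plain expected heterozygosity \eqn{He = 1 - \sum_i p_i^2}. With
#' `unbiased = TRUE` and `n_obs` supplied, applies the small-sample
#' correction \eqn{2n/(2n-1)}.
#'
#' @inheritParams pic
#' @param unbiased Apply the small-sample correction?
#' @param n_obs Number of genotypes behind `freqs` (needed when
#'   `unbiased = TRUE`).
#' @export
expected_het <- function(freqs, unbiased = FALSE, n_obs = NULL) {
  check_freqs(freqs)
  he <- 1 - sum(freqs^2)
  if (unbiased) {
    if (is.null(n_obs)) stop("`n_obs` required for the unbiased estimator",
                             call. = FALSE)
    he <- he * 2 * n_obs / (2 * n_obs - 1)
  }
  he
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0) stop("empty allele frequency vector", call. = FALSE)
  if (any(freqs < 0)) stop("negative allele frequency", call. = FALSE)
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Observed and expected heterozygosity at one locus
#'
#' `Ho` is the fraction of observed (non-missing) genotypes with two distinct
#' alleles; `He` is computed from the pooled allele frequencies.
#'
#' @param g A [genotype_tbl].
#' @param locus Locus name.
#' @return Named numeric vector `c(Ho =, He =)`.
#' @export
heterozygosities <- function(g, locus) {
  g <- as_genotype_tbl(g)
  if (!locus %in% loci(g)) stop("unknown locus: ", locus, call. = FALSE)
  x <- tibble::as_tibble(g)
  x <- x[x$locus == locus & !is.na(x$allele_1), ]
  if (nrow(x) == 0) {
    stop("no observed genotypes at locus ", locus, call. = FALSE)
  }
  ho <- mean(x$allele_1 != x$allele_2)
  p <- table(c(x$allele_1, x$allele_2))
  he <- expected_het(as.numeric(p) / sum(p))
  c(Ho = ho, He = he)
}

#' Allele richness of one locus
#'
#' Defined as the observed allele count divided by the number of genotyped
#' individuals in the dataset, i.e. alleles per individual sampled. This is a
#' sample-size-normalised allele count, not rarefaction-based richness.
#'
#' @param g A [genotype_tbl].
#' @param locus Locus name.
#' @export
allele_richness <- function(g, locus) {
  g <- as_genotype_tbl(g)
  if (!locus %in% loci(g)) stop("unknown locus: ", locus, call. = FALSE)
  x <- tibble::as_tibble(g)
  x <- x[x$locus == locus & !is.na(x$allele_1), ]
  na <- length(unique(c(x$allele_1, x$allele_2)))
  na / length(individuals(g))
}

#' Per-locus diversity statistics table
#'
#' One row per locus with the standard microsatellite descriptors: observed
#' allele count (`Na`), effective allele count (`Nea`), allele richness
#' (`AR` = Na / individuals), polymorphic information content (`PIC`),
#' observed (`Ho`) and expected (`He`) heterozygosity, all on pooled allele
#' frequencies from non-missing genotypes. Loci with no observed genotypes
#' are kept as flagged `NA` rows.
#'
#' @param g A [genotype_tbl].
#' @return A tibble with columns `locus`, `Na`, `Nea`, `AR`, `PIC`, `Ho`,
#'   `He`, `n_obs`.
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 20, n_loci = 4, seed = 1)
#' locus_stats(g)
#' @export
locus_stats <- function(g) {
  g <- as_genotype_tbl(g)
  n_ind <- length(individuals(g))
  x <- tibble::as_tibble(g)
  per_locus <- function(l) {
    xi <- x[x$locus == l & !is.na(x$allele_1), ]
    if (nrow(xi) == 0) {
      return(tibble::tibble(locus = l, Na = NA_integer_, Nea = NA_real_,
                            AR = NA_real_, PIC = NA_real_, Ho = NA_real_,
                            He = NA_real_, n_obs = 0L))
    }
    tab <- table(c(xi$allele_1, xi$allele_2))
    p <- as.numeric(tab) / sum(tab)
    tibble::tibble(
      locus = l,
      Na = length(p),
      Nea = n_effective(p),
      AR = length(p) / n_ind,
      PIC = pic(p),
      Ho = mean(xi$allele_1 != xi$allele_2),
      He = expected_het(p),
      n_obs = nrow(xi)
    )
  }
  out <- dplyr::bind_rows(lapply(loci(g), per_locus))
  if (any(out$n_obs == 0)) {
    warning("locus with zero observed genotypes: ",
            paste(out$locus[out$n_obs == 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Summary (min, max, mean) of a per-locus statistics table
#'
#' @param stats A tibble from [locus_stats()].
#' @return A tibble with one row per statistic and columns `statistic`,
#'   `min`, `max`, `mean`.
#' @export
locus_stats_summary <- function(stats) {
  vars <- c("Na", "Nea", "AR", "PIC", "Ho", "He")
  long <- tidyr::pivot_longer(stats[c("locus", vars)], dplyr::all_of(vars),
                              names_to = "statistic")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$statistic),
    min = min(.data$value, na.rm = TRUE),
    max = max(.data$value, na.rm = TRUE),
    mean = mean(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  out[match(vars, out$statistic), ]
}
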