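#' Compare marker-selection schemes across panel sizes
#'
#' Runs each scheme at each requested panel size (stochastic schemes with
#' `replicates` independently seeded runs, deterministic ones once), records
#' the estimation accuracy `100 - loss`, and performs all pairwise scheme
#' contrasts per size with Tukey's honest significant difference test.
#' Groups that are exact ties (zero variance everywhere) are reported with
#' p = 1 rather than dropped.
#'
#' @param g A [genotype_tbl].
#' @param n_values Integer vector of panel sizes.
#' @param schemes Scheme names, see [select_panel()].
#' @param replicates Replicate runs per stochastic scheme per size.
#' @param config An [aco_config()] for the ACO-based schemes.
#' @param grouping As in [genetic_dist()].
#' @param seed Master seed; replicate seeds are derived from it
#'   deterministically so each run is individually reproducible.
#' @return An object of class `scheme_comparison`: list with `accuracies`
#'   (tibble: n, scheme, replicate, accuracy, seed), `contrasts` (tibble:
#'   n, scheme_a, scheme_b, diff, p_value), and `winners` (tibble: n,
#'   scheme, accuracy).
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 6, seed = 7)
#' cmp <- compare_schemes(g, n_values = c(3, 4), replicates = 3,
#'                        config = aco_config(ants = 10, epochs = 10), seed = 1)
#' cmp$winners
#' @export
compare_schemes <- function(g, n_values,
                            schemes = c("pic_aco", "aco", "pic", "random"),
                            replicates = 20, config = aco_config(),
                            grouping = "auto", seed = 1) {
  stopifnot(replicates >= 2)
  schemes <- match.arg(schemes, several.ok = TRUE)
  stochastic <- c("pic_aco", "aco", "random")
  rows <- list()
  for (n in n_values) {
    for (sc in schemes) {
      reps <- if (sc %in% stochastic) seq_len(replicates) else 1L
      for (r in reps) {
        run_seed <- derive_seed(seed, n, match(sc, schemes), r)
        fit <- select_panel(g, sc, n = n, config = config,
                            grouping = grouping, seed = run_seed)
        rows[[length(rows) + 1]] <- tibble::tibble(
          n = n, scheme = sc, replicate = r,
          accuracy = fit$accuracy, seed = run_seed)
      }
    }
  }
  acc <- dplyr::bind_rows(rows)
  contrasts <- dplyr::bind_rows(lapply(n_values, function(nn) {
    tukey_contrasts(acc[acc$n == nn, ], nn)
  }))
  winners <- dplyr::slice_max(dplyr::group_by(acc, .data$n),
                              .data$accuracy, n = 1, with_ties = FALSE)
  winners <- dplyr::ungroup(winners)[c("n", "scheme", "accuracy")]
  structure(list(accuracies = acc, contrasts = contrasts, winners = winners),
            class = "scheme_comparison")
}

# per-size Tukey HSD over scheme accuracy distributions (internal)
tukey_contrasts <- function(df, n) {
  pairs <- utils::combn(unique(df$scheme), 2)
  if (stats::var(df$accuracy) < 1e-24 || length(unique(df$scheme)) < 2) {
    # exact ties across the board: every contrast is a non-difference
    return(tibble::tibble(n = n, scheme_a = pairs[1, ], scheme_b = pairs[2, ],
                          diff = 0, p_value = 1))
  }
  fit <- stats::aov(accuracy ~ scheme, data = df)
  tk <- stats::TukeyHSD(fit)$scheme
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- tibble::tibble(
    n = n,
    scheme_a = vapply(nm, `[`, "", 1),
    scheme_b = vapply(nm, `[`, "", 2),
    diff = tk[, "diff"],
    p_value = tk[, "p adj"]
  )
  # zero residual variance makes p NaN although group means differ/tie;
  # report exact ties as p = 1 and exact separations as p ~ 0
  if (anyNA(out$p_value)) {
    out$p_value[is.na(out$p_value) & abs(out$diff) < 1e-12] <- 1
    out$p_value[is.na(out$p_value)] <- 0
  }
  out
}

derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  as.integer(sum(parts * 10007^(seq_along(parts) - 1)) %% 2147480000)
}

#' Full-versus-reduced panel discrepancy report
#'
#' For each diversity statistic (Na, Nea, AR, PIC, Ho, He), compares the
#' per-locus values on the reduced panel against the full marker set with a
#' two-sample t-test (pooled-variance Student form by default, Welch via
#' `welch = TRUE`), reporting the mean on each set, the mean difference,
#' the fold change (reduced / full) and a significance tier: `ns`
#' (p > 0.05), `*` (0.01 < p < 0.05), `**` (0.001 < p < 0.01), `***`
#' (p < 0.001). When the panel is the full set the report is emitted with
#' `NA` entries (there is nothing to compare).
#'
#' @param g A [genotype_tbl].
#' @param panel Panel specification (locus names, logical or integer).
#' @param welch Use the Welch (unequal-variance) t-test?
#' @return A tibble with columns `statistic`, `mean_panel`, `mean_full`,
#'   `mean_diff`, `fold`, `t_stat`, `p_value`, `significance`.
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 20, n_loci = 8, seed = 8)
#' panel_discrepancy(g, loci(g)[1:4])
#' @export
panel_discrepancy <- function(g, panel, welch = FALSE) {
  g <- as_genotype_tbl(g)
  sel <- resolve_panel(panel, loci(g))
  st <- locus_stats(g)
  vars <- c("Na", "Nea", "AR", "PIC", "Ho", "He")
  if (all(sel)) {
    return(tibble::tibble(statistic = vars, mean_panel = NA_real_,
                          mean_full = NA_real_, mean_diff = NA_real_,
                          fold = NA_real_, t_stat = NA_real_,
                          p_value = NA_real_, significance = NA_character_))
  }
  one <- function(v) {
    reduced <- st[[v]][sel]
    full <- st[[v]]
    # a statistic can be constant on both sets (e.g. Na when every allele is
    # seen at every locus): report an exact tie instead of failing
    if (stats::var(reduced) < 1e-24 && stats::var(full) < 1e-24) {
      tie <- abs(mean(reduced) - mean(full)) < 1e-12
      t_stat <- if (tie) 0 else Inf
      p <- if (tie) 1 else 0
    } else {
      tt <- stats::t.test(reduced, full, var.equal = !welch)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble::tibble(
      statistic = v,
      mean_panel = mean(reduced),
      mean_full = mean(full),
      mean_diff = mean(reduced) - mean(full),
      fold = mean(reduced) / mean(full),
      t_stat = t_stat,
      p_value = p,
      significance = significance_tier(p)
    )
  }
  dplyr::bind_rows(lapply(vars, one))
}

significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Progressive marker-reduction curve
#'
#' Reduces the panel size from k down to 2 under one selection scheme and
#' records the best-found accuracy loss plus the mean Ho, He and AR of the
#' selected loci at each size; the table autoplot()s as a reduction curve.
#'
#' @param g A [genotype_tbl].
#' @param scheme Scheme name, see [select_panel()].
#' @param config An [aco_config()] for ACO-based schemes.
#' @param grouping As in [genetic_dist()].
#' @param seed Master seed (per-size seeds are derived from it).
#' @return A tibble of class `reduction_curve` with columns `n`, `loss`,
#'   `Ho`, `He`, `AR` and a `panel` list-column.
#' @export
reduction_curve <- function(g, scheme = "pic_aco", config = aco_config(),
                            grouping = "auto", seed = 1) {
  g <- as_genotype_tbl(g)
  st <- locus_stats(g)
  k <- n_loci(g)
  rows <- lapply(seq(k, 2), function(n) {
    fit <- select_panel(g, scheme, n = n, config = config, grouping = grouping,
                        seed = derive_seed(seed, n))
    sel <- st$locus %in% fit$panel
    tibble::tibble(n = n, loss = fit$loss,
                   Ho = mean(st$Ho[sel]), He = mean(st$He[sel]),
                   AR = mean(st$AR[sel]), panel = list(fit$panel))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reduction_curve", class(out))
  attr(out, "scheme") <- scheme
  out
}
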