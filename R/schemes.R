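#' PIC-rank marker selection
#'
#' Ranks loci by polymorphic information content and keeps the most
#' informative ones. In fixed-size mode the top `n` loci are returned (ties
#' broken by locus order). In margin mode panel sizes are scanned upward
#' from 2 and the smallest top-PIC panel whose accuracy loss meets the
#' margin is returned (the full set if none does).
#'
#' @inheritParams aco_select
#' @return A `panel_selection` with scheme `"pic"`. Deterministic.
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 6, seed = 5)
#' pic_rank_select(g, n = 3)
#' @export
pic_rank_select <- function(g, n = NULL, margin = NULL, grouping = "auto") {
  ev <- panel_evaluator(g, grouping)
  pv <- locus_stats(g)$PIC
  if (anyNA(pv)) stop("PIC undefined for some locus", call. = FALSE)
  ranked <- order(-pv)                      # ties: earlier locus first
  top_panel <- function(size) {
    sel <- rep(FALSE, ev$k)
    sel[ranked[seq_len(size)]] <- TRUE
    sel
  }
  if (!is.null(n) && is.null(margin)) {
    if (n < 2 || n > ev$k) stop("`n` must be in 2..k", call. = FALSE)
    sel <- top_panel(n)
    res <- list(panel = sel, loss = as.numeric(ev$loss(as.numeric(sel))))
    return(new_panel_selection(res, ev, "pic", NULL, NULL, mode = "fixed_n"))
  }
  if (is.null(n) && !is.null(margin)) {
    if (margin <= 0) {
      warning("margin <= 0: returning the full marker set", call. = FALSE)
      res <- list(panel = rep(TRUE, ev$k), loss = 0)
      return(new_panel_selection(res, ev, "pic", NULL, NULL, mode = "margin",
                                 margin = margin))
    }
    for (size in 2:ev$k) {
      sel <- top_panel(size)
      loss <- as.numeric(ev$loss(as.numeric(sel)))
      if (loss <= margin) {
        res <- list(panel = sel, loss = loss)
        return(new_panel_selection(res, ev, "pic", NULL, NULL, mode = "margin",
                                   margin = margin))
      }
    }
    res <- list(panel = rep(TRUE, ev$k), loss = 0)
    return(new_panel_selection(res, ev, "pic", NULL, NULL, mode = "margin",
                               margin = margin))
  }
  stop("give exactly one of `n` and `margin`", call. = FALSE)
}

#' Random marker selection (control scheme)
#'
#' Draws a uniform panel of `n` loci without replacement; the baseline the
#' informed schemes are compared against.
#'
#' @inheritParams aco_select
#' @export
random_select <- function(g, n, grouping = "auto", seed = NULL) {
  ev <- panel_evaluator(g, grouping)
  if (n < 2 || n > ev$k) stop("`n` must be in 2..k", call. = FALSE)
  run_with_seed(seed, {
    sel <- rep(FALSE, ev$k)
    sel[sample.int(ev$k, n)] <- TRUE
    res <- list(panel = sel, loss = as.numeric(ev$loss(as.numeric(sel))))
    new_panel_selection(res, ev, "random", NULL, seed, mode = "fixed_n")
  })
}

#' PIC-seeded ACO marker selection
#'
#' The combined scheme: per-locus PIC values seed the initial pheromone
#' trails ([init_pheromones()] with `mode = "pic"`), after which the ACO
#' search proceeds exactly as [aco_select()]. The top-PIC locus is favoured,
#' not force-included: initialisation biases construction while the search
#' remains free to drop redundant high-PIC markers.
#'
#' @inheritParams aco_select
#' @export
pic_aco_select <- function(g, n = NULL, margin = NULL, config = aco_config(),
                           grouping = "auto", seed = NULL) {
  aco_select(g, n = n, margin = margin, config = config, init = "pic",
             grouping = grouping, seed = seed)
}

#' Run a marker-selection scheme by name
#'
#' Dispatch over the four selection schemes: `"pic_aco"` (PIC-seeded ACO),
#' `"aco"` (random-initialised ACO), `"pic"` (PIC rank) and `"random"`
#' (uniform control). The result records the scheme, mode and parameters
#' for provenance.
#'
#' @param g A [genotype_tbl].
#' @param scheme Scheme name.
#' @param n,margin Panel size or accuracy-loss margin (exactly one, except
#'   `"random"` which requires `n`).
#' @param config An [aco_config()] for the ACO-based schemes.
#' @param grouping As in [genetic_dist()].
#' @param seed Integer seed (required for reproducibility of the stochastic
#'   schemes).
#' @return A `panel_selection`.
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 6, seed = 6)
#' select_panel(g, "pic", n = 3)
#' @export
select_panel <- function(g, scheme = c("pic_aco", "aco", "pic", "random"),
                         n = NULL, margin = NULL, config = aco_config(),
                         grouping = "auto", seed = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    pic_aco = pic_aco_select(g, n = n, margin = margin, config = config,
                             grouping = grouping, seed = seed),
    aco = aco_select(g, n = n, margin = margin, config = config,
                     init = "random", grouping = grouping, seed = seed),
    pic = pic_rank_select(g, n = n, margin = margin, grouping = grouping),
    random = {
      if (is.null(n)) stop("the random control scheme needs a fixed `n`",
                           call. = FALSE)
      random_select(g, n = n, grouping = grouping, seed = seed)
    }
  )
}
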