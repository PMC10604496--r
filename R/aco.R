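#' Ant colony optimizer configuration
#'
#' Defaults follow the standard parameterisation for this marker-selection
#' task: 50 ants per epoch, 120 epochs, pheromone weight
#' \eqn{\alpha = 0.7} and per-epoch pheromone retention 0.9 (each epoch
#' trails are multiplied by `decay` before new deposits, so small values
#' forget quickly and explore more).
#'
#' @param ants Ants (candidate panels) constructed per epoch.
#' @param epochs Number of epochs (iterations).
#' @param alpha Pheromone weight exponent in the path-choice probabilities.
#' @param decay Pheromone retention factor per epoch, in (0, 1).
#' @param elite_frac Fraction of top-ranked ants depositing pheromone each
#'   epoch (rank-based update). The 0.5 default lets the better half of the
#'   colony deposit: on exhaustive-oracle benchmarks, stronger elitism (0.2)
#'   fixated prematurely in near-tie loss landscapes, while half-colony
#'   deposits preserved rank selection and recovered the true optimum.
#' @return A list of class `aco_config`.
#' @export
aco_config <- function(ants = 50, epochs = 120, alpha = 0.7, decay = 0.9,
                       elite_frac = 0.5) {
  stopifnot(ants >= 1, epochs >= 1, alpha > 0, decay > 0, decay < 1,
            elite_frac > 0, elite_frac <= 1)
  structure(list(ants = as.integer(ants), epochs = as.integer(epochs),
                 alpha = alpha, decay = decay, elite_frac = elite_frac),
            class = "aco_config")
}

# pheromone floor: keeps every edge reachable after evaporation
PHEROMONE_EPS <- 0.01

#' Initialise pheromone trails on the include/exclude graph
#'
#' The search graph has two nodes per locus (include / exclude); each
#' carries a strictly positive pheromone value. `"random"` draws every trail
#' from Uniform(eps, 1) using the current RNG state. `"pic"` seeds the
#' include trail of locus j with `eps + PIC_j` and its exclude trail with
#' `eps + (1 - PIC_j)`, biasing early epochs toward polymorphic markers.
#'
#' @param k Number of loci.
#' @param mode `"random"` or `"pic"`.
#' @param pic_values Per-locus PIC values (required for `mode = "pic"`).
#' @return A list of class `pheromone_state` with components `tau_in`,
#'   `tau_out` (length-k positive numerics).
#' @export
init_pheromones <- function(k, mode = c("random", "pic"), pic_values = NULL) {
  mode <- match.arg(mode)
  eps <- PHEROMONE_EPS
  if (mode == "random") {
    st <- list(tau_in = stats::runif(k, eps, 1), tau_out = stats::runif(k, eps, 1))
  } else {
    if (is.null(pic_values) || length(pic_values) != k || anyNA(pic_values)) {
      stop("`pic_values` (one PIC per locus) required for pic initialisation",
           call. = FALSE)
    }
    st <- list(tau_in = eps + pic_values, tau_out = eps + (1 - pic_values))
  }
  structure(st, class = "pheromone_state")
}

#' Construct one candidate panel from pheromone trails
#'
#' In free mode each locus is included independently with probability
#' \eqn{\tau_{in}^\alpha / (\tau_{in}^\alpha + \tau_{out}^\alpha)}; panels
#' with fewer than two loci are resampled (bounded retries, then a
#' deterministic top-up by pheromone rank). In fixed-size mode `n` loci are
#' drawn sequentially without replacement with probability proportional to
#' \eqn{\tau_{in}^\alpha} among the remaining loci.
#'
#' @param ph A [init_pheromones()] state.
#' @param alpha Pheromone weight exponent.
#' @param n Fixed panel size, or `NULL` for free mode.
#' @return Logical inclusion vector of length k.
#' @export
construct_solution <- function(ph, alpha = 0.7, n = NULL) {
  drop(construct_panels(ph, alpha, n, 1)) == 1
}

# batch construction: returns k x m 0/1 matrix
construct_panels <- function(ph, alpha, n, m) {
  k <- length(ph$tau_in)
  win <- ph$tau_in^alpha
  if (!is.null(n)) {
    stopifnot(n >= 2, n <= k)
    out <- matrix(0, k, m)
    for (j in seq_len(m)) {
      out[sample.int(k, n, prob = win), j] <- 1
    }
    return(out)
  }
  p_in <- win / (win + ph$tau_out^alpha)
  out <- matrix(as.numeric(stats::runif(k * m) < p_in), k, m)
  short <- which(colSums(out) < 2)
  for (j in short) {
    for (try in 1:20) {
      out[, j] <- as.numeric(stats::runif(k) < p_in)
      if (sum(out[, j]) >= 2) break
    }
    if (sum(out[, j]) < 2) {       # deterministic top-up by pheromone rank
      out[, j] <- 0
      out[order(win, decreasing = TRUE)[1:2], j] <- 1
    }
  }
  out
}

#' Rank-based pheromone update with evaporation
#'
#' Every trail first evaporates to `decay` times its value, then each of the
#' top `ceiling(elite_frac * ants)` ants (by accuracy loss) deposits
#' \eqn{\Delta = (100 - loss)/100} on the edges it traversed: the include
#' edge of each selected locus and the exclude edge of each unselected one.
#' Trails are floored at a small positive constant so every path stays
#' reachable.
#'
#' @param ph A `pheromone_state`.
#' @param panels k x m 0/1 matrix of constructed panels (columns are ants).
#' @param losses Accuracy loss of each panel, in percent.
#' @param config An [aco_config()].
#' @return The updated `pheromone_state`.
#' @export
update_pheromones <- function(ph, panels, losses, config) {
  if (is.vector(panels)) panels <- matrix(as.numeric(panels), ncol = 1)
  stopifnot(ncol(panels) == length(losses))
  tau_in <- ph$tau_in * config$decay
  tau_out <- ph$tau_out * config$decay
  n_elite <- min(ncol(panels), ceiling(config$elite_frac * config$ants))
  if (n_elite >= 1) {
    elite <- order(losses)[seq_len(n_elite)]
    delta <- pmax(0, (100 - losses[elite]) / 100)
    sel <- panels[, elite, drop = FALSE]
    tau_in <- tau_in + as.numeric(sel %*% delta)
    tau_out <- tau_out + as.numeric((1 - sel) %*% delta)
  }
  structure(list(tau_in = pmax(tau_in, PHEROMONE_EPS),
                 tau_out = pmax(tau_out, PHEROMONE_EPS)),
            class = "pheromone_state")
}

# core seeded ACO loop over a prepared evaluator (internal)
aco_run <- function(ev, n, config, init, pic_values = NULL) {
  k <- ev$k
  ph <- init_pheromones(k, init, pic_values)
  best_loss <- Inf
  best_panel <- NULL
  best_epoch <- NA_integer_
  trace <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    panels <- construct_panels(ph, config$alpha, n, config$ants)
    losses <- as.numeric(ev$loss(panels))
    b <- best_of_epoch(panels, losses)
    if (is_better(b$loss, b$panel, best_loss, best_panel)) {
      best_loss <- b$loss
      best_panel <- b$panel
      best_epoch <- e
    }
    ph <- update_pheromones(ph, panels, losses, config)
    trace[e] <- best_loss
  }
  list(panel = best_panel == 1, loss = best_loss, trace = trace,
       epochs_to_best = best_epoch, pheromones = ph)
}

# epoch winner under the deterministic tie-break (smaller panel, then
# lexicographically earliest inclusion vector)
best_of_epoch <- function(panels, losses) {
  o <- order(losses, colSums(panels))
  cand <- o[abs(losses[o] - losses[o[1]]) < 1e-12 &
              colSums(panels)[o] == sum(panels[, o[1]])]
  if (length(cand) > 1) {
    keys <- apply(panels[, cand, drop = FALSE], 2,
                  function(v) paste(v, collapse = ""))
    cand <- cand[order(keys, decreasing = TRUE)[1]]  # earliest loci first
  } else cand <- cand[1]
  list(panel = panels[, cand], loss = losses[cand])
}

is_better <- function(loss, panel, best_loss, best_panel) {
  if (is.null(best_panel)) return(TRUE)
  if (loss < best_loss - 1e-12) return(TRUE)
  if (loss > best_loss + 1e-12) return(FALSE)
  s <- sum(panel); bs <- sum(best_panel)
  if (s != bs) return(s < bs)
  paste(panel, collapse = "") > paste(best_panel, collapse = "")
}

#' ACO marker selection
#'
#' Runs the ant colony search for a reduced marker panel minimising the
#' accuracy loss of the average genetic distance. With `n` given, the search
#' is over panels of exactly `n` loci. With `margin` given, panel sizes are
#' reduced progressively from k-1 downwards, stopping at the first size
#' whose best-found loss exceeds the margin; the smallest qualifying panel
#' is returned (the full set if even size k-1 fails).
#'
#' @param g A [genotype_tbl].
#' @param n Fixed panel size (2..k), or `NULL`.
#' @param margin Accuracy-loss margin in percent, or `NULL`. Exactly one of
#'   `n` and `margin` must be given.
#' @param config An [aco_config()].
#' @param init Pheromone initialisation: `"random"` or `"pic"` (PIC-seeded).
#' @param grouping As in [genetic_dist()].
#' @param seed Integer seed; runs are deterministic given it.
#' @return A `panel_selection` object; see [select_panel()].
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 15, n_loci = 6, seed = 4)
#' aco_select(g, n = 3, config = aco_config(ants = 10, epochs = 10), seed = 1)
#' @export
aco_select <- function(g, n = NULL, margin = NULL, config = aco_config(),
                       init = c("random", "pic"), grouping = "auto",
                       seed = NULL) {
  init <- match.arg(init)
  scheme <- if (init == "pic") "pic_aco" else "aco"
  ev <- panel_evaluator(g, grouping)
  pic_values <- if (init == "pic") locus_stats(g)$PIC else NULL
  if (init == "pic" && anyNA(pic_values)) {
    stop("PIC undefined for some locus; cannot seed pheromones", call. = FALSE)
  }
  run_with_seed(seed, {
    if (!is.null(n) && is.null(margin)) {
      if (n < 2 || n > ev$k) stop("`n` must be in 2..k", call. = FALSE)
      if (n == ev$k) {
        res <- list(panel = rep(TRUE, ev$k), loss = 0,
                    trace = rep(0, config$epochs), epochs_to_best = 1L)
      } else {
        res <- aco_run(ev, n, config, init, pic_values)
      }
      new_panel_selection(res, ev, scheme, config, seed, mode = "fixed_n")
    } else if (is.null(n) && !is.null(margin)) {
      if (margin <= 0) {
        warning("margin <= 0: returning the full marker set", call. = FALSE)
        res <- list(panel = rep(TRUE, ev$k), loss = 0,
                    trace = rep(0, config$epochs), epochs_to_best = 1L)
        return(new_panel_selection(res, ev, scheme, config, seed,
                                   mode = "margin", margin = margin))
      }
      best <- NULL
      for (size in seq(ev$k - 1, 2)) {
        res <- aco_run(ev, size, config, init, pic_values)
        if (res$loss <= margin) best <- res else break
      }
      if (is.null(best)) {
        best <- list(panel = rep(TRUE, ev$k), loss = 0,
                     trace = rep(0, config$epochs), epochs_to_best = 1L)
      }
      new_panel_selection(best, ev, scheme, config, seed, mode = "margin",
                          margin = margin)
    } else {
      stop("give exactly one of `n` and `margin`", call. = FALSE)
    }
  })
}

# deterministic seeding helper: evaluates expr under set.seed(seed) without
# clobbering the caller's RNG stream when seed is NULL
run_with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

new_panel_selection <- function(res, ev, scheme, config, seed,
                                mode, margin = NULL) {
  structure(list(
    panel = ev$loci[res$panel],
    all_loci = ev$loci,
    loss = as.numeric(res$loss),
    accuracy = 100 - as.numeric(res$loss),
    n = sum(res$panel),
    k = ev$k,
    scheme = scheme,
    mode = mode,
    margin = margin,
    trace = if (!is.null(res$trace))
      tibble::tibble(epoch = seq_along(res$trace), best_loss = res$trace),
    epochs_to_best = res$epochs_to_best,
    full_agd = ev$full_agd,
    grouping = ev$grouping,
    config = config,
    seed = seed
  ), class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("# panel_selection: scheme %s (%s mode)\n", x$scheme, x$mode))
  cat(sprintf("#   %d of %d loci, accuracy loss %.4g%% (AGD reference %.4g)\n",
              x$n, x$k, x$loss, x$full_agd))
  cat("#   panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive optimal panel (test oracle)
#'
#' Enumerates candidate panels to find the true optimum: all
#' \eqn{\binom{k}{n}} panels in fixed-size mode, or every panel size
#' (smallest first) in margin mode, returning the smallest panel whose
#' minimal loss meets the margin. Guarded to small k: enumeration beyond
#' `max_loci` loci is refused.
#'
#' @inheritParams aco_select
#' @param max_loci Refusal guard on k (default 20).
#' @return A `panel_selection` with scheme `"exhaustive"`.
#' @export
exhaustive_panel <- function(g, n = NULL, margin = NULL, grouping = "auto",
                             max_loci = 20) {
  ev <- panel_evaluator(g, grouping)
  if (ev$k > max_loci) {
    stop("refusing exhaustive enumeration beyond ", max_loci, " loci",
         call. = FALSE)
  }
  best_at_size <- function(size) {
    combos <- utils::combn(ev$k, size)
    panels <- matrix(0, ev$k, ncol(combos))
    panels[cbind(as.vector(combos),
                 rep(seq_len(ncol(combos)), each = size))] <- 1
    losses <- as.numeric(ev$loss(panels))
    o <- order(losses)
    tied <- o[losses[o] - losses[o[1]] < 1e-12]
    if (length(tied) > 1) {
      keys <- apply(panels[, tied, drop = FALSE], 2,
                    function(v) paste(v, collapse = ""))
      tied <- tied[order(keys, decreasing = TRUE)[1]]
    } else tied <- tied[1]
    list(panel = panels[, tied] == 1, loss = losses[tied])
  }
  if (!is.null(n) && is.null(margin)) {
    if (n < 2 || n > ev$k) stop("`n` must be in 2..k", call. = FALSE)
    res <- best_at_size(n)
  } else if (is.null(n) && !is.null(margin)) {
    res <- NULL
    for (size in 2:ev$k) {
      cand <- best_at_size(size)
      if (cand$loss <= margin) { res <- cand; break }
    }
    if (is.null(res)) res <- list(panel = rep(TRUE, ev$k), loss = 0)
  } else {
    stop("give exactly one of `n` and `margin`", call. = FALSE)
  }
  res$trace <- NULL; res$epochs_to_best <- NA_integer_
  new_panel_selection(res, ev, "exhaustive", NULL, NULL,
                      mode = if (is.null(margin)) "fixed_n" else "margin",
                      margin = margin)
}
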