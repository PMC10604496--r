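#' Nei genetic distance between two groups over a marker panel
#'
#' Computes
#' \deqn{D_{a,b} = -\ln\left(\frac{\sum_k \sum_j p_{ajk} p_{bjk}}
#'  {\sqrt{\sum_k \sum_j p_{ajk}^2 \; \sum_k \sum_j p_{bjk}^2}}\right)}
#' with the locus sums taken inside the numerator and both denominator sums
#' (Nei's standard distance, not a per-locus average of ratios). When the
#' two groups share no alleles anywhere on the panel the numerator is zero
#' and the distance is `+Inf`; it is never capped.
#'
#' @param fa,fb Per-locus allele frequencies of the two groups: each a list
#'   of numeric vectors, one per locus, named by allele code (vectors are
#'   aligned by name; unnamed vectors are aligned by position).
#' @param panel Optional panel restricting the computation: locus names,
#'   logical or integer positions into `names(fa)`.
#' @return The distance (non-negative; possibly `Inf`).
#' @examples
#' nei_distance(list(L1 = c(a1 = 1, a2 = 0)), list(L1 = c(a1 = 0.5, a2 = 0.5)))
#' @export
nei_distance <- function(fa, fb, panel = NULL) {
  if (!is.list(fa)) fa <- list(fa)
  if (!is.list(fb)) fb <- list(fb)
  if (length(fa) != length(fb)) {
    stop("`fa` and `fb` must cover the same loci", call. = FALSE)
  }
  if (!is.null(panel)) {
    sel <- resolve_panel(panel, names(fa) %||% as.character(seq_along(fa)))
    fa <- fa[sel]; fb <- fb[sel]
  }
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(fa)) {
    pa <- fa[[i]]; pb <- fb[[i]]
    if (is.null(names(pa)) != is.null(names(pb))) {
      stop("frequency vectors must be consistently named", call. = FALSE)
    }
    if (!is.null(names(pa))) {
      alleles <- union(names(pa), names(pb))
      a <- stats::setNames(rep(0, length(alleles)), alleles)
      b <- a
      a[names(pa)] <- pa; b[names(pb)] <- pb
    } else {
      if (length(pa) != length(pb)) {
        stop("unnamed frequency vectors must have equal length", call. = FALSE)
      }
      a <- pa; b <- pb
    }
    num <- num + sum(a * b)
    da <- da + sum(a^2)
    db <- db + sum(b^2)
  }
  if (da == 0 || db == 0) stop("group with no observed frequencies on panel",
                               call. = FALSE)
  if (num == 0) return(Inf)
  ratio <- num / sqrt(da * db)
  # identical frequency sets can exceed 1 by rounding; distance floors at 0
  max(0, -log(ratio))
}

# ---------------------------------------------------------------------------
# internal fast machinery: per-locus cross-product terms
#
# For groups a, b and locus l define C[a,b,l] = sum_j p_ajl * p_bjl. Any
# panel's pairwise Nei distances follow from sums of C over included loci,
# so panels can be scored with one matrix product. This is what makes the
# ACO loop cheap: scoring an epoch of ant panels is a (G^2 x k) %*% (k x m)
# multiply.

cross_terms <- function(g, grouping = c("auto", "population", "individual",
                                        "pooled")) {
  grouping <- match.arg(grouping)
  g <- as_genotype_tbl(g)
  if (grouping == "auto") {
    grouping <- if (length(populations(g)) >= 2) "population" else "individual"
  }
  if (grouping == "pooled") {
    stop("distances need >= 2 groups; use grouping = 'individual' for a single population",
         call. = FALSE)
  }
  fr <- allele_freqs(g, grouping)
  lv <- attr(fr, "loci")
  groups <- unique(fr$group)
  if (length(groups) < 2) {
    stop("fewer than 2 groups under this grouping; use grouping = 'individual'",
         call. = FALSE)
  }
  P <- length(groups); k <- length(lv)
  cross <- matrix(0, nrow = P * P, ncol = k,
                  dimnames = list(NULL, lv))
  for (li in seq_len(k)) {
    fl <- fr[fr$locus == lv[li], ]
    if (nrow(fl) == 0) next
    alleles <- sort(unique(fl$allele))
    F <- matrix(0, nrow = P, ncol = length(alleles))
    F[cbind(match(fl$group, groups), match(fl$allele, alleles))] <- fl$freq
    cross[, li] <- as.vector(F %*% t(F))
  }
  list(cross = cross, groups = groups, loci = lv, grouping = grouping)
}

# distances for a batch of panels; panels: k x m matrix of 0/1
pair_index <- function(P) {
  ij <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  list(ij = ij,
       num = (ij[, 2] - 1) * P + ij[, 1],   # column-major [i, j]
       dia = (seq_len(P) - 1) * P + seq_len(P))
}

panel_distances <- function(ct, panels) {
  P <- length(ct$groups)
  S <- ct$cross %*% panels                       # (P*P) x m
  px <- pair_index(P)
  num <- S[px$num, , drop = FALSE]
  dia <- S[px$dia, , drop = FALSE]
  di <- dia[px$ij[, 1], , drop = FALSE]
  dj <- dia[px$ij[, 2], , drop = FALSE]
  D <- -log(num / sqrt(di * dj))
  D[num == 0] <- Inf
  D[D < 0] <- 0
  D                                              # n_pairs x m
}

# mean of finite pairwise distances per panel (+ count of infinite pairs)
panel_agd <- function(ct, panels) {
  D <- panel_distances(ct, panels)
  fin <- is.finite(D)
  n_inf <- colSums(!fin)
  agd <- colSums(ifelse(fin, D, 0)) / colSums(fin)
  agd[colSums(fin) == 0] <- NA_real_
  list(agd = agd, n_infinite = n_inf)
}

# closure scoring panels by accuracy loss against the cached full-panel AGD
panel_evaluator <- function(g, grouping = "auto") {
  ct <- cross_terms(g, grouping)
  k <- length(ct$loci)
  full <- panel_agd(ct, matrix(1, k, 1))
  if (is.na(full$agd) || full$agd <= 0) {
    stop("full-panel AGD is undefined or zero; accuracy loss has no reference",
         call. = FALSE)
  }
  loss_fn <- function(panels) {
    if (is.vector(panels)) panels <- matrix(as.numeric(panels), ncol = 1)
    res <- panel_agd(ct, panels)
    loss <- 100 * abs(res$agd - full$agd) / full$agd
    loss[is.na(res$agd)] <- Inf
    loss
  }
  list(loss = loss_fn, full_agd = full$agd, ct = ct, k = k, loci = ct$loci,
       grouping = ct$grouping)
}

# ---------------------------------------------------------------------------

#' Pairwise Nei distance matrix under a marker panel
#'
#' The grouping unit is the subpopulation when the data carry two or more
#' population labels, otherwise each individual is its own group (with
#' per-individual "frequencies" of 0, 0.5 or 1); both modes can be forced.
#'
#' @param g A [genotype_tbl].
#' @param panel Panel specification (locus names, logical or integer
#'   positions); `NULL` means the full marker set.
#' @param grouping `"auto"` (default), `"population"` or `"individual"`.
#' @return An object of class `nei_dist`: a symmetric distance matrix with a
#'   zero diagonal, plus `panel` and `grouping` attributes. Pairs with no
#'   shared alleles are `Inf` and flagged, never capped.
#' @examples
#' g <- simulate_genotypes(n_pops = 3, n_per_pop = 15, n_loci = 5, seed = 2)
#' genetic_dist(g)
#' @export
genetic_dist <- function(g, panel = NULL, grouping = "auto") {
  ct <- cross_terms(g, grouping)
  sel <- resolve_panel(panel, ct$loci)
  P <- length(ct$groups)
  D <- panel_distances(ct, matrix(as.numeric(sel), ncol = 1))
  m <- matrix(0, P, P, dimnames = list(ct$groups, ct$groups))
  px <- pair_index(P)
  m[px$ij] <- D[, 1]
  m[px$ij[, c(2, 1), drop = FALSE]] <- D[, 1]
  structure(m, class = c("nei_dist", "matrix"),
            panel = ct$loci[sel], grouping = ct$grouping,
            n_infinite = sum(!is.finite(D)))
}

#' @export
print.nei_dist <- function(x, ...) {
  cat(sprintf("# Nei distance matrix (%d groups, %d loci, grouping = %s)\n",
              nrow(x), length(attr(x, "panel")), attr(x, "grouping")))
  if (attr(x, "n_infinite") > 0) {
    cat(sprintf("# %d pair(s) with no shared alleles (Inf)\n",
                attr(x, "n_infinite")))
  }
  print(unclass(x)[,], ...)
  invisible(x)
}

#' Average genetic distance (AGD) of a marker panel
#'
#' Mean of the finite off-diagonal pairwise Nei distances; infinite pairs
#' (no shared alleles) are excluded from the mean and counted in the
#' `n_infinite` attribute.
#'
#' @inheritParams genetic_dist
#' @return The AGD as a single number with attribute `n_infinite`.
#' @export
agd <- function(g, panel = NULL, grouping = "auto") {
  ct <- cross_terms(g, grouping)
  sel <- resolve_panel(panel, ct$loci)
  res <- panel_agd(ct, matrix(as.numeric(sel), ncol = 1))
  if (is.na(res$agd)) {
    stop("all pairwise distances are infinite; AGD undefined", call. = FALSE)
  }
  structure(res$agd, n_infinite = res$n_infinite)
}

#' Accuracy loss of a reduced marker panel
#'
#' The panel cost used throughout the package:
#' \deqn{loss = 100 \cdot |AGD(panel) - AGD(full)| / AGD(full)}
#' so `100 - loss` is the panel's estimation accuracy.
#'
#' @inheritParams genetic_dist
#' @return Accuracy loss in percent (0 for the full panel).
#' @examples
#' g <- simulate_genotypes(n_pops = 2, n_per_pop = 20, n_loci = 6, seed = 3)
#' accuracy_loss(g, panel = loci(g)[1:3])
#' @export
accuracy_loss <- function(g, panel = NULL, grouping = "auto") {
  ev <- panel_evaluator(g, grouping)
  sel <- resolve_panel(panel, ev$loci)
  as.numeric(ev$loss(as.numeric(sel)))
}
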