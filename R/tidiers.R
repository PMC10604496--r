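#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a panel selection
#'
#' One row per locus with its inclusion flag, so selections join naturally
#' onto [locus_stats()] tables.
#'
#' @param x A `panel_selection`.
#' @param ... Unused.
#' @return A tibble with columns `locus`, `selected`.
#' @method tidy panel_selection
#' @export
tidy.panel_selection <- function(x, ...) {
  tibble::tibble(locus = x$all_loci, selected = x$all_loci %in% x$panel)
}

#' @method glance panel_selection
#' @export
glance.panel_selection <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, mode = x$mode, n = x$n, k = x$k,
    loss = x$loss, accuracy = x$accuracy,
    margin = x$margin %||% NA_real_,
    epochs_to_best = x$epochs_to_best %||% NA_integer_,
    full_agd = x$full_agd, grouping = x$grouping,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a Nei distance matrix
#'
#' @param x A `nei_dist` matrix from [genetic_dist()].
#' @param ... Unused.
#' @return A long tibble with columns `group_a`, `group_b`, `distance`
#'   (upper triangle only).
#' @method tidy nei_dist
#' @export
tidy.nei_dist <- function(x, ...) {
  m <- unclass(x)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(group_a = rownames(m)[ij[, 1]],
                 group_b = colnames(m)[ij[, 2]],
                 distance = m[ij])
}

#' @method tidy scheme_comparison
#' @export
tidy.scheme_comparison <- function(x, ...) x$contrasts

#' @method glance scheme_comparison
#' @export
glance.scheme_comparison <- function(x, ...) x$winners
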