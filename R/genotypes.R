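#' Diploid codominant genotype tables
#'
#' A `genotype_tbl` is an ordinary tibble in long format with one row per
#' individual-by-locus genotype and columns `individual`, `population`,
#' `locus`, `allele_1`, `allele_2`. Allele codes are opaque positive integers
#' (fragment sizes or labels); no ordering semantics are attached to them
#' anywhere downstream. A genotype is missing when either allele was scored
#' as 0; missing genotypes are stored as a pair of `NA`s and are excluded
#' from both numerator and denominator of every per-locus statistic.
#'
#' @param x A data frame with columns `individual`, `population`, `locus`,
#'   `allele_1`, `allele_2`. Allele code 0 (either position) marks a missing
#'   genotype and is converted to `NA` on both alleles.
#' @param loci Optional character vector fixing the locus order. Defaults to
#'   order of first appearance.
#' @return A tibble of class `genotype_tbl` with a `loci` attribute holding
#'   the ordered locus names.
#' @examples
#' g <- genotype_tbl(data.frame(
#'   individual = c("i1", "i1", "i2", "i2"),
#'   population = "P1",
#'   locus      = c("L1", "L2", "L1", "L2"),
#'   allele_1   = c(1L, 3L, 1L, 0L),
#'   allele_2   = c(1L, 4L, 2L, 2L)
#' ))
#' n_loci(g)
#' @export
genotype_tbl <- function(x, loci = NULL) {
  x <- tibble::as_tibble(x)
  needed <- c("individual", "population", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[needed]
  x$individual <- as.character(x$individual)
  x$population <- as.character(x$population)
  x$locus <- as.character(x$locus)
  for (col in c("allele_1", "allele_2")) {
    a <- x[[col]]
    if (!is.numeric(a)) {
      a_int <- suppressWarnings(as.integer(a))
      if (anyNA(a_int) && !all(is.na(a[is.na(a_int)]))) {
        bad <- which(is.na(a_int) & !is.na(a))[1]
        stop(sprintf("non-integer allele code '%s' in column %s, row %d",
                     a[bad], col, bad), call. = FALSE)
      }
      a <- a_int
    } else if (any(abs(a - round(a)) > 1e-9, na.rm = TRUE)) {
      bad <- which(abs(a - round(a)) > 1e-9)[1]
      stop(sprintf("non-integer allele code '%s' in column %s, row %d",
                   format(a[bad]), col, bad), call. = FALSE)
    }
    x[[col]] <- as.integer(round(as.numeric(a)))
  }
  if (any(x$allele_1 < 0 | x$allele_2 < 0, na.rm = TRUE)) {
    stop("negative allele codes are not allowed", call. = FALSE)
  }
  # whole-genotype missing rule: either allele 0 (or NA) blanks the pair
  miss <- is.na(x$allele_1) | is.na(x$allele_2) | x$allele_1 == 0L | x$allele_2 == 0L
  x$allele_1[miss] <- NA_integer_
  x$allele_2[miss] <- NA_integer_

  if (is.null(loci)) loci <- unique(x$locus)
  if (!setequal(loci, unique(x$locus))) {
    stop("`loci` must list exactly the loci present in the table", call. = FALSE)
  }
  dup <- x[duplicated(x[c("individual", "locus")]), ]
  if (nrow(dup) > 0) {
    stop(sprintf("duplicated genotype entry for individual '%s' at locus '%s'",
                 dup$individual[1], dup$locus[1]), call. = FALSE)
  }
  # every individual must be scored (possibly as missing) at every locus
  tab <- table(x$individual)
  if (length(unique(tab)) != 1L || unique(tab) != length(loci)) {
    off <- names(tab)[tab != length(loci)][1]
    stop(sprintf("individual '%s' has %d locus records, expected %d",
                 off, tab[[off]], length(loci)), call. = FALSE)
  }
  pop_of <- tapply(x$population, x$individual, function(p) length(unique(p)))
  if (any(pop_of != 1L)) {
    stop(sprintf("individual '%s' is assigned to more than one population",
                 names(pop_of)[pop_of != 1L][1]), call. = FALSE)
  }
  structure(x, loci = as.character(loci),
            class = c("genotype_tbl", class(tibble::tibble())))
}

#' @rdname genotype_tbl
#' @export
is_genotype_tbl <- function(x) inherits(x, "genotype_tbl")

#' @rdname genotype_tbl
#' @export
loci <- function(x) {
  stopifnot(is_genotype_tbl(x))
  attr(x, "loci")
}

#' @rdname genotype_tbl
#' @export
n_loci <- function(x) length(loci(x))

#' @rdname genotype_tbl
#' @export
individuals <- function(x) {
  stopifnot(is_genotype_tbl(x))
  unique(x$individual)
}

#' @rdname genotype_tbl
#' @export
populations <- function(x) {
  stopifnot(is_genotype_tbl(x))
  unique(x$population)
}

#' @export
print.genotype_tbl <- function(x, ...) {
  cat(sprintf("# genotype_tbl: %d individuals x %d loci, %d population(s)\n",
              length(individuals(x)), n_loci(x), length(populations(x))))
  NextMethod()
}

# subsetting drops the class (plain tibble comes back) which is fine for
# dplyr pipelines; genotype_tbl() revalidates when the structure is needed.

#' Coerce a wide two-columns-per-locus data frame to a genotype table
#'
#' Accepts the layout GenAlEx exports: an individual identifier column, a
#' population column, then two adjacent allele columns per locus.
#'
#' @param x Data frame whose first two columns are individual and population
#'   identifiers, followed by 2k allele columns.
#' @param loci Locus names, length k. Defaults to the odd allele column names.
#' @return A [genotype_tbl].
#' @export
as_genotype_tbl <- function(x, loci = NULL) {
  if (is_genotype_tbl(x)) return(x)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) < 4 || (ncol(x) - 2) %% 2 != 0) {
    stop("expected columns: individual, population, then 2 allele columns per locus",
         call. = FALSE)
  }
  k <- (ncol(x) - 2) / 2
  if (is.null(loci)) loci <- names(x)[2 + 2 * seq_len(k) - 1]
  if (length(loci) != k) stop("`loci` must have length ", k, call. = FALSE)
  if (anyDuplicated(loci)) stop("locus names must be unique", call. = FALSE)
  long <- lapply(seq_len(k), function(j) {
    tibble::tibble(
      individual = as.character(x[[1]]),
      population = as.character(x[[2]]),
      locus = loci[j],
      allele_1 = x[[2 + 2 * j - 1]],
      allele_2 = x[[2 + 2 * j]]
    )
  })
  out <- dplyr::bind_rows(long)
  out <- dplyr::arrange(out, match(individual, unique(as.character(x[[1]]))),
                        match(locus, loci))
  genotype_tbl(out, loci = loci)
}

# internal: wide matrix layout (individuals x 2k) used by writers
gt_wide <- function(g) {
  stopifnot(is_genotype_tbl(g))
  lv <- loci(g)
  ind <- individuals(g)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(g),
    id_cols = c("individual", "population"),
    names_from = "locus",
    values_from = c("allele_1", "allele_2"),
    names_glue = "{locus}.{ifelse(.value == 'allele_1', 1, 2)}"
  )
  ord <- as.vector(rbind(paste0(lv, ".1"), paste0(lv, ".2")))
  wide <- wide[match(ind, wide$individual), c("individual", "population", ord)]
  wide
}

#' Restrict a genotype table to a marker panel
#'
#' @param g A [genotype_tbl].
#' @param panel Panel specification: character locus names, logical inclusion
#'   vector over `loci(g)`, or integer locus positions.
#' @return A [genotype_tbl] containing only the panel loci.
#' @export
subset_loci <- function(g, panel) {
  sel <- resolve_panel(panel, loci(g))
  keep <- loci(g)[sel]
  genotype_tbl(dplyr::filter(tibble::as_tibble(g), .data$locus %in% keep),
               loci = keep)
}

# internal: normalize any panel representation to a logical vector over loci
resolve_panel <- function(panel, all_loci) {
  k <- length(all_loci)
  if (is.null(panel)) return(rep(TRUE, k))
  if (is.logical(panel)) {
    if (length(panel) != k) {
      stop("logical panel must have length ", k, call. = FALSE)
    }
    sel <- panel
  } else if (is.character(panel)) {
    unknown <- setdiff(panel, all_loci)
    if (length(unknown) > 0) {
      stop("unknown loci in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sel <- all_loci %in% panel
  } else if (is.numeric(panel)) {
    if (any(panel < 1 | panel > k)) stop("panel indices out of range", call. = FALSE)
    sel <- seq_len(k) %in% as.integer(panel)
  } else {
    stop("unsupported panel specification", call. = FALSE)
  }
  if (sum(sel) < 1) stop("panel must include at least one locus", call. = FALSE)
  sel
}
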