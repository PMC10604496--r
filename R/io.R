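#' Read a GenAlEx-style codominant genotype file
#'
#' Parses the standard GenAlEx codominant export: a first header row
#' `k, N, P, n1, ..., nP` (number of loci, individuals, populations and
#' per-population sizes), a second title row, a third row carrying locus
#' names over paired allele columns, then one row per individual with its
#' identifier, population label and two allele codes per locus. Allele code
#' 0 marks a missing allele; a genotype with either allele missing is
#' treated as wholly missing.
#'
#' @param path Path to a comma- or tab-delimited GenAlEx file.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header row.
#' @return A [genotype_tbl].
#' @seealso [write_genalex()], [read_csv_genotypes()]
#' @export
read_genalex <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 4) {
    stop("GenAlEx parse error: file has fewer than 4 non-empty rows", call. = FALSE)
  }
  if (is.null(delim)) {
    delim <- if (lengths(strsplit(lines[1], "\t"))[1] >
                 lengths(strsplit(lines[1], ","))[1]) "\t" else ","
  }
  cells <- strsplit(lines, delim, fixed = TRUE)
  hdr <- suppressWarnings(as.integer(cells[[1]]))
  if (length(hdr) < 3 || anyNA(hdr[1:3])) {
    stop("GenAlEx parse error: row 1 must start with integer counts 'loci, individuals, populations'",
         call. = FALSE)
  }
  k <- hdr[1]; n_ind <- hdr[2]; n_pop <- hdr[3]
  pop_sizes <- hdr[seq_len(n_pop) + 3]
  if (length(pop_sizes) == n_pop && !anyNA(pop_sizes) && sum(pop_sizes) != n_ind) {
    stop(sprintf("GenAlEx parse error: row 1 declares %d individuals but population sizes sum to %d",
                 n_ind, sum(pop_sizes)), call. = FALSE)
  }
  locus_row <- cells[[3]]
  locus_names <- locus_row[2 + 2 * seq_len(k) - 1]
  locus_names <- trimws(locus_names)
  if (anyNA(locus_names) || any(locus_names == "")) {
    stop("GenAlEx parse error: row 3 does not name all declared loci", call. = FALSE)
  }
  body <- cells[-(1:3)]
  if (length(body) != n_ind) {
    stop(sprintf("GenAlEx parse error: header declares %d individuals but body has %d data rows",
                 n_ind, length(body)), call. = FALSE)
  }
  parse_row <- function(row, i) {
    if (length(row) < 2 + 2 * k) {
      stop(sprintf("GenAlEx parse error: data row %d has %d fields, expected %d",
                   i, length(row), 2 + 2 * k), call. = FALSE)
    }
    al <- row[2 + seq_len(2 * k)]
    al_num <- suppressWarnings(as.integer(trimws(al)))
    blank <- trimws(al) == ""
    al_num[blank] <- 0L
    if (anyNA(al_num)) {
      j <- which(is.na(al_num))[1]
      stop(sprintf("GenAlEx parse error: non-integer allele cell '%s' at data row %d, column %d",
                   al[j], i, 2 + j), call. = FALSE)
    }
    c(trimws(row[1]), trimws(row[2]), al_num)
  }
  parsed <- t(vapply(seq_along(body), function(i) parse_row(body[[i]], i),
                     character(2 + 2 * k)))
  wide <- data.frame(individual = parsed[, 1], population = parsed[, 2],
                     stringsAsFactors = FALSE)
  al <- apply(parsed[, -(1:2), drop = FALSE], 2, as.integer)
  if (n_ind == 1) al <- matrix(al, nrow = 1)
  wide <- cbind(wide, as.data.frame(al))
  as_genotype_tbl(wide, loci = locus_names)
}

#' Write a genotype table as a GenAlEx codominant file
#'
#' Produces a file that [read_genalex()] reads back to an identical
#' genotype table (missing genotypes become `0 0` pairs).
#'
#' @param g A [genotype_tbl] with at least one individual.
#' @param path Output file path.
#' @param title Title placed on the second header row.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(g, path, title = "picaco export", delim = ",") {
  g <- as_genotype_tbl(g)
  if (length(individuals(g)) == 0) {
    stop("refusing to write a genotype table with zero individuals", call. = FALSE)
  }
  wide <- gt_wide(g)
  lv <- loci(g)
  pops <- populations(g)
  pop_sizes <- vapply(pops, function(p) sum(wide$population == p), 0L)
  row1 <- c(length(lv), nrow(wide), length(pops), pop_sizes)
  row2 <- title
  row3 <- c("Ind", "Pop", as.vector(rbind(lv, "")))
  mat <- as.matrix(wide[, -(1:2)])
  mat[is.na(mat)] <- 0L
  join <- function(x) paste(x, collapse = delim)
  body <- vapply(seq_len(nrow(wide)), function(i) {
    join(c(wide$individual[i], wide$population[i], mat[i, ]))
  }, character(1))
  writeLines(c(join(row1), row2, join(row3), body), path)
  invisible(path)
}

#' Read or write genotypes as a plain long CSV
#'
#' The long schema has one genotype per row with columns
#' `individual, population, locus, allele_1, allele_2`; allele code 0 (or an
#' empty cell) marks a missing genotype. This is a convenience alternative
#' to the GenAlEx layout; both round-trip exactly.
#'
#' @param path CSV file path.
#' @return A [genotype_tbl] (for the reader) or `path` invisibly (writer).
#' @export
read_csv_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("individual", "population", "locus", "allele_1", "allele_2")
  if (!all(needed %in% names(x))) {
    stop("CSV parse error: expected columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("allele_1", "allele_2")) {
    if (is.character(x[[col]])) {
      v <- trimws(x[[col]]); v[v == ""] <- "0"
      vi <- suppressWarnings(as.integer(v))
      if (anyNA(vi)) {
        bad <- which(is.na(vi))[1]
        stop(sprintf("CSV parse error: non-integer allele cell '%s' in column %s, row %d",
                     x[[col]][bad], col, bad), call. = FALSE)
      }
      x[[col]] <- vi
    }
  }
  genotype_tbl(x)
}

#' @rdname read_csv_genotypes
#' @param g A [genotype_tbl].
#' @export
write_csv_genotypes <- function(g, path) {
  g <- as_genotype_tbl(g)
  if (length(individuals(g)) == 0) {
    stop("refusing to write a genotype table with zero individuals", call. = FALSE)
  }
  out <- tibble::as_tibble(g)
  out$allele_1[is.na(out$allele_1)] <- 0L
  out$allele_2[is.na(out$allele_2)] <- 0L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
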