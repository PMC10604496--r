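# small deterministic genotype tables used across test files

toy_gt <- function() {
  # 2 populations x 2 individuals, 2 loci; one missing genotype
  genotype_tbl(tibble::tibble(
    individual = rep(c("a1", "a2", "b1", "b2"), each = 2),
    population = rep(c("A", "A", "B", "B"), each = 2),
    locus = rep(c("L1", "L2"), times = 4),
    allele_1 = c(1L, 3L, 1L, 0L, 2L, 3L, 2L, 4L),
    allele_2 = c(1L, 4L, 2L, 2L, 2L, 3L, 2L, 4L)
  ))
}

# wide builder: calls is a list ind -> c(pop, a1,a2, a1,a2, ...)
gt_from_calls <- function(calls, loci_names) {
  rows <- lapply(names(calls), function(id) {
    v <- calls[[id]]
    k <- (length(v) - 1) / 2
    tibble::tibble(individual = id, population = v[1], locus = loci_names,
                   allele_1 = as.integer(v[2 * seq_len(k)]),
                   allele_2 = as.integer(v[2 * seq_len(k) + 1]))
  })
  genotype_tbl(dplyr::bind_rows(rows), loci = loci_names)
}

# random valid genotype table for round-trip property tests
random_gt <- function(n_ind = 10, k = 4, n_pop = 2, missing_rate = 0.1,
                      seed = 1) {
  withr::with_seed(seed, {
    lv <- paste0("M", seq_len(k))
    pops <- paste0("pop", seq_len(n_pop))
    tb <- tidyr::expand_grid(individual = sprintf("ind%02d", seq_len(n_ind)),
                             locus = lv)
    tb$population <- pops[1 + (match(tb$individual, unique(tb$individual)) - 1) %%
                            n_pop]
    tb$allele_1 <- sample(1:9, nrow(tb), replace = TRUE)
    tb$allele_2 <- sample(1:9, nrow(tb), replace = TRUE)
    miss <- runif(nrow(tb)) < missing_rate
    tb$allele_1[miss] <- 0L
    genotype_tbl(tb, loci = lv)
  })
}

# cached expensive fixtures, shared across test files in one session
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) {
    assign(name, force(expr), .fixture_cache)
  }
  get(name, .fixture_cache)
}

planted_fixture <- function() cached("planted", make_planted_instance(seed = 42))

# a fast ACO configuration for unit tests (acceptance tests use defaults)
fast_config <- function() aco_config(ants = 15, epochs = 25)
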