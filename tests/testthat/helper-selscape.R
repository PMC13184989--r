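# Shared fixtures. Benchmarks are generated in code and cached per session so
# several test files can reuse the same simulated selection. Tests run the
# registered scenarios scaled down 5x from their defaults (2e4 genotypes /
# 2e5 reads instead of 1e5 / 1e6) to fit the suite's time budget; the mean
# reads-per-genotype (10x), and hence per-genotype sampling noise, is
# unchanged.
TEST_N <- 2e4
TEST_DEPTH <- 2e5

.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function(scenario, seed, n_distinct = TEST_N,
                          depth = TEST_DEPTH) {
  key <- paste(scenario, seed, n_distinct, depth, sep = "|")
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- make_benchmark(scenario, seed = seed,
                                          n_distinct = n_distinct,
                                          depth = depth)
  .bench_cache[[key]]
}

# A tiny 8-nt spec with one constrained pair and two free positions: small
# enough for exhaustive enumeration oracles.
tiny_spec <- function() {
  library_spec(core_length = 8L, variable_positions = c(2L, 4L, 5L, 7L),
               position_codes = c(`4` = "N", `5` = "R"),
               pair_constraints = list(pair_constraint(2L, 7L)),
               reference_core = "AXGXXTXC")
}

# Independent oracle: enumerate a spec by brute force over the full product
# space and filter by constraint membership (never calls library_size).
enumerate_oracle <- function(spec) {
  sets <- lapply(spec$variable_positions, function(p) {
    code <- spec$position_codes[as.character(p)]
    if (!is.na(code)) expand_iupac(code) else c("A", "C", "G", "T")
  })
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (con in spec$pair_constraints) {
    i5 <- match(con$pos5, spec$variable_positions)
    i3 <- match(con$pos3, spec$variable_positions)
    allowed <- selscape:::constraint_duplets(con)
    keep <- keep & paste0(grid[[i5]], grid[[i3]]) %in% allowed
  }
  sort(do.call(paste0, grid[keep, , drop = FALSE]))
}
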