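spec <- aurora_bulge_spec()

# A hand-checkable 4-position spec and landscape used by several oracles.
mini_spec <- library_spec(4L, 1:4, c(`1` = "N", `2` = "N", `3` = "N", `4` = "N"),
                          reference_core = "XXXX")
mini_landscape <- function(link = "logistic", intercept = 0) {
  eff <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  eff[1, "A"] <- 0.5; eff[2, "G"] <- -0.25
  epi <- data.frame(substrate = "S", pos_i = 1L, base_i = "A",
                    pos_j = 3L, base_j = "T", effect = 0.75)
  activity_landscape(mini_spec, "S", additive = list(S = eff), epistatic = epi,
                     intercept = c(S = intercept), link = link)
}

test_that("reacted_fraction matches hand computation and link limits", {
  tr <- mini_landscape()
  # hand oracle: AGCT scores 0.5 (1A) - 0.25 (2G); no epistatic hit (3 is C)
  expect_equal(reacted_fraction("AGCT", "S", tr), plogis(0.5 - 0.25))
  # ACTT: 0.5 (1A) + 0.75 (epistatic 1A & 3T)
  expect_equal(reacted_fraction("ACTT", "S", tr), plogis(0.5 + 0.75))
  expect_equal(reacted_fraction("CCCC", "S", tr), plogis(0))

  flat <- activity_landscape(mini_spec, "S",
                             additive = list(S = matrix(0, 4, 4)),
                             intercept = c(S = 0))
  expect_equal(reacted_fraction(c("AAAA", "GTCA"), "S", flat), c(0.5, 0.5))
  low <- activity_landscape(mini_spec, "S",
                            additive = list(S = matrix(0, 4, 4)),
                            intercept = c(S = -40))
  expect_lt(reacted_fraction("AAAA", "S", low), 1e-15)
  # linear link clamps to [0, 1]
  lin <- mini_landscape(link = "linear", intercept = -1)
  expect_equal(reacted_fraction("CCCC", "S", lin), 0)
})

test_that("pairing bonus applies per satisfied constraint", {
  eff <- matrix(0, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  tr <- activity_landscape(tiny_spec(), "S", additive = list(S = eff),
                           pairing_bonus = c(S = 1), intercept = c(S = 0))
  # tiny_spec constrains positions 2-7 (genotype indices 1 and 4)
  expect_equal(reacted_fraction("GAAC", "S", tr), plogis(1))  # G-C pairs
  expect_equal(reacted_fraction("AAAC", "S", tr), plogis(0))  # A-C does not
})

test_that("simulate_pool is seeded, normalised and tends to equimolar", {
  pool <- simulate_pool(spec, 500, concentration = 100, seed = 3)
  expect_identical(nrow(pool), 500L)
  expect_false(anyDuplicated(pool$genotype) > 0)
  expect_equal(sum(pool$freq), 1)
  expect_identical(pool, simulate_pool(spec, 500, concentration = 100, seed = 3))
  flat <- simulate_pool(spec, 500, concentration = 1e7, seed = 3)
  expect_lt(max(flat$freq) / min(flat$freq), 1.01)
  skewed <- simulate_pool(spec, 500, concentration = 1, seed = 3)
  expect_gt(max(skewed$freq) / min(skewed$freq),
            max(pool$freq) / min(pool$freq))
  expect_error(simulate_pool(mini_spec, 1000, seed = 1), "exceeds")
})

test_that("simulate_selection enriches proportionally to reacted fraction", {
  pool <- simulate_pool(spec, 100, seed = 5)
  tr <- activity_landscape(
    spec, "S",
    additive = list(S = matrix(stats::rnorm(56, sd = 0.4), 14, 4,
                               dimnames = list(NULL, c("A", "C", "G", "T")))),
    intercept = c(S = -1))
  post <- simulate_selection(pool, tr, "S")
  p <- reacted_fraction(pool$genotype, "S", tr)
  # brute-force oracle: post/pre ratio proportional to p, exactly
  ratio <- post$freq / pool$freq
  expect_equal(ratio / ratio[1], p / p[1])

  flat <- activity_landscape(spec, "S", additive = list(S = matrix(0, 14, 4)),
                             intercept = c(S = 1))
  expect_equal(simulate_selection(pool, flat, "S")$freq, pool$freq)

  two <- data.table::data.table(genotype = pool$genotype[1:2], freq = c(0.5, 0.5))
  # give the two genotypes reacted fractions 0.5 and 0.25 via a hand-built landscape
  eff <- matrix(0, 14, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  b1 <- substr(two$genotype[1], 1, 1); b2 <- substr(two$genotype[2], 1, 1)
  if (b1 == b2) {
    # fall back: distinguish at first differing position
    d <- which(strsplit(two$genotype[1], "")[[1]] != strsplit(two$genotype[2], "")[[1]])[1]
    eff[d, substr(two$genotype[1], d, d)] <- 0.5
    eff[d, substr(two$genotype[2], d, d)] <- 0.25
  } else {
    eff[1, b1] <- 0.5; eff[1, b2] <- 0.25
  }
  tr3 <- activity_landscape(spec, "S", additive = list(S = eff),
                            intercept = c(S = 0), link = "linear")
  post2 <- simulate_selection(two, tr3, "S")
  expect_equal(post2$freq, c(2, 1) / 3)

  zero <- activity_landscape(spec, "S", additive = list(S = matrix(0, 14, 4)),
                             intercept = c(S = -1), link = "linear")
  expect_error(simulate_selection(pool, zero, "S"), "degenerate")
})

test_that("sample_reads is multinomial, seeded and CPM-consistent", {
  single <- data.table::data.table(genotype = strrep("A", 14), freq = 1)
  t1 <- sample_reads(single, 1e4, seed = 1)
  expect_identical(t1$count, 10000L)
  expect_equal(t1$cpm, 1e6)

  pool <- simulate_pool(spec, 400, concentration = 5, seed = 6)
  t2 <- sample_reads(pool, 1e5, seed = 2)
  expect_identical(t2, sample_reads(pool, 1e5, seed = 2))
  expect_equal(sum(t2$cpm), 1e6)
  # counts within 5 binomial sd of expectation for all freq >= 1e-3
  idx <- pool$freq >= 1e-3
  expected <- pool$freq[idx] * 1e5
  obs <- t2$count[match(pool$genotype[idx], t2$genotype)]
  obs[is.na(obs)] <- 0L
  sds <- sqrt(1e5 * pool$freq[idx] * (1 - pool$freq[idx]))
  expect_true(all(abs(obs - expected) <= 5 * sds))
})

test_that("neutral selection leaves expected CPM unchanged", {
  pool <- simulate_pool(spec, 1000, seed = 8)
  flat <- activity_landscape(spec, "S", additive = list(S = matrix(0, 14, 4)),
                             intercept = c(S = -2))
  post <- simulate_selection(pool, flat, "S")
  pre_tab <- sample_reads(pool, 2e5, seed = 9)
  post_tab <- sample_reads(post, 2e5, seed = 10)
  m <- merge(pre_tab, post_tab, by = "genotype")
  # paired multinomial noise: mean CPM difference compatible with zero
  d <- m$cpm.y - m$cpm.x
  expect_lt(abs(mean(d)) / (sd(d) / sqrt(nrow(m))), 5)
})

test_that("enrichment correlates with reacted fraction at deep coverage", {
  # deep-coverage configuration so genotypes reach >= 100 reads
  sim <- get_benchmark("additive", seed = 31, n_distinct = 1000, depth = 2e5)
  tab <- sim$post_counts[["4MUP"]]
  m <- merge(sim$pool, data.table::as.data.table(tab), by = "genotype")
  m$pre_cpm <- m$freq * 1e6
  hi <- m[m$count >= 100, ]
  expect_gt(nrow(hi), 200)
  p <- reacted_fraction(hi$genotype, "4MUP", sim$truth)
  expect_gte(cor(log(hi$cpm / hi$pre_cpm), log(p), method = "spearman"), 0.95)
})

test_that("benchmark scenarios encode their registered structure", {
  expect_error(make_benchmark("nope", seed = 1), "should be one of|unknown")

  sim_a <- get_benchmark("additive", seed = 31, n_distinct = 300, depth = 5000)
  expect_null(sim_a$truth$epistatic)
  expect_identical(sim_a$truth$additive[["4MUP"]], sim_a$truth$additive[["diFMUP"]])

  sim_p <- get_benchmark("specificity-planted", seed = 41, n_distinct = 300,
                         depth = 5000)
  da <- sim_p$truth$additive[["4MUP"]] - sim_p$truth$additive[["diFMUP"]]
  differing <- spec$variable_positions[rowSums(abs(da)) > 1e-12]
  expect_setequal(differing, c(20, 21, 33, 34))

  sim_i <- get_benchmark("imbalanced", seed = 13)
  ea <- enrichment_summary(sim_i$post_counts[["4MUP"]], pool_size = TEST_N)
  eb <- enrichment_summary(sim_i$post_counts[["diFMUP"]], pool_size = TEST_N)
  expect_gt(ea$n_enriched, eb$n_enriched)

  # reproducibility: same seed, same tables
  s1 <- make_benchmark("additive", seed = 51, n_distinct = 200, depth = 2000)
  s2 <- make_benchmark("additive", seed = 51, n_distinct = 200, depth = 2000)
  expect_equal(s1$post_counts, s2$post_counts)
})

test_that("ground truth serialises to JSON", {
  sim <- get_benchmark("additive", seed = 31, n_distinct = 300, depth = 5000)
  path <- tempfile(fileext = ".json")
  write_truth_json(sim, path)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(truth$scenario, "additive")
  expect_equal(unlist(truth$additive[["4MUP"]][["A"]]),
               unname(sim$truth$additive[["4MUP"]][, "A"]))
})
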