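spec <- aurora_bulge_spec()

# small synthetic regression problem: exactly additive target over genotypes
additive_toy <- function(n, seed, noise_sd = 0) {
  set.seed(seed)
  g <- sample_genotypes(spec, n, seed = seed)
  eff <- matrix(stats::runif(56, 0, 2), 14, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  sym <- matrix(unlist(strsplit(g, "")), ncol = 14, byrow = TRUE)
  y <- rowSums(vapply(1:14, function(i) eff[cbind(i, match(sym[, i],
                                                           c("A", "C", "G", "T")))],
                      numeric(n)))
  list(genotypes = g, y = y + stats::rnorm(n, sd = noise_sd), eff = eff)
}

test_that("one-hot encoding follows the stated column convention", {
  X <- one_hot_encode(c("A", "C", "G", "T"))
  expect_identical(unname(X), diag(4))
  g <- sample_genotypes(spec, 20, seed = 2)
  Xg <- one_hot_encode(g, spec)
  expect_identical(dim(Xg), c(20L, 56L))
  expect_identical(colnames(Xg)[1:4], c("p16_A", "p16_C", "p16_G", "p16_T"))
  # each 4-column block sums to 1 per row
  block_sums <- sapply(seq(1, 56, 4), function(j) rowSums(Xg[, j:(j + 3)]))
  expect_true(all(block_sums == 1))
  expect_identical(rowSums(Xg), rep(14, 20))
  expect_identical(decode_one_hot(Xg), g)
  expect_error(one_hot_encode("ACGN"), "A,C,G,T")
})

test_that("make_split is seeded, disjoint, exhaustive and nested", {
  plan <- split_plan(test_fraction = 0.2, fractions = c(1, 0.5, 0.25),
                     seed = 11)
  sp <- make_split(10L, plan)
  expect_length(sp$test, 2L)
  expect_length(sp$train, 8L)
  expect_identical(sort(c(sp$test, sp$train)), 1:10)

  sp2 <- make_split(1000L, plan)
  expect_identical(sp2, make_split(1000L, plan))
  expect_true(all(sp2$downsamples[["0.50"]] %in% sp2$downsamples[["1.00"]]))
  expect_true(all(sp2$downsamples[["0.25"]] %in% sp2$downsamples[["0.50"]]))
  expect_length(intersect(sp2$test, unlist(sp2$downsamples)), 0L)
  expect_error(split_plan(fractions = c(0.5, 1)), "unsorted|decreasing|rev")
})

test_that("eval_metrics agrees with explicit definitions", {
  y <- c(3, 1, 4, 1, 5)
  m <- eval_metrics(y, y)
  expect_equal(m$spearman_rho, 1)
  expect_equal(m$r_squared, 1)
  expect_equal(m$mae, 0)

  shifted <- eval_metrics(y + 2.5, y)
  expect_equal(shifted$mae, 2.5)
  expect_equal(shifted$spearman_rho, 1)

  # oracle equivalence on random pairs: rho via explicit average ranks,
  # R^2 via its definition formula
  set.seed(99)
  for (i in 1:5) {
    p <- stats::rnorm(100); o <- stats::rnorm(100) + 0.5 * p
    p[1:3] <- p[4]  # introduce ties
    m <- eval_metrics(p, o)
    rp <- rank(p, ties.method = "average"); ro <- rank(o, ties.method = "average")
    rho_oracle <- sum((rp - mean(rp)) * (ro - mean(ro))) /
      sqrt(sum((rp - mean(rp))^2) * sum((ro - mean(ro))^2))
    expect_equal(m$spearman_rho, rho_oracle)
    expect_equal(m$r_squared, 1 - sum((o - p)^2) / sum((o - mean(o))^2))
    expect_equal(m$mae, mean(abs(o - p)))
  }
  expect_error(eval_metrics(1, 1), "length")
})

small_cfg <- function(...) network_config(hidden_layer_sizes = 32L,
                                          max_iter = 60L, ...)

test_that("fit_network fits, is seeded, and handles degenerate targets", {
  toy <- additive_toy(1500, seed = 3)
  X <- one_hot_encode(toy$genotypes)

  const <- fit_network(X[1:200, ], rep(2, 200), small_cfg(), seed = 1)
  expect_true(all(abs(stats::predict(const, X[201:210, ]) - 2) < 1e-2))

  f1 <- fit_network(X, toy$y, small_cfg(), seed = 5)
  f2 <- fit_network(X, toy$y, small_cfg(), seed = 5)
  expect_identical(stats::predict(f1, X), stats::predict(f2, X))
  expect_gt(eval_metrics(stats::predict(f1, X), toy$y)$r_squared, 0.9)
})

test_that("grid search scores by mean CV R^2 with deterministic tie-break", {
  toy <- additive_toy(800, seed = 4)
  X <- one_hot_encode(toy$genotypes)
  one <- list(small_cfg(alpha = 0.01))
  gs1 <- grid_search_cv(X, toy$y, one, folds = 3L, seed = 2)
  expect_identical(gs1$best_index, 1L)
  expect_identical(gs1$best_config, one[[1]])

  # a degenerate 1-unit network loses to an adequate one on additive truth
  grid <- list(network_config(hidden_layer_sizes = 1L, max_iter = 20L),
               small_cfg())
  gs2 <- grid_search_cv(X, toy$y, grid, folds = 3L, seed = 2)
  expect_identical(gs2$best_index, 2L)
  expect_identical(nrow(gs2$results), 2L)
})

test_that("train_model keeps test rows out of training", {
  toy <- additive_toy(600, seed = 6)
  plan <- split_plan(fractions = c(1, 0.5), seed = 3)
  run <- train_model(toy$genotypes, toy$y, plan, small_cfg(), seed = 1,
                     fraction = 0.5)
  expect_length(intersect(run$split$test, unlist(run$split$downsamples)), 0L)
  expect_identical(nrow(run$predictions), length(run$split$test))
  expect_error(train_model(toy$genotypes, toy$y, plan, small_cfg(),
                           fraction = 0.3), "fraction")
})

test_that("learning_curve is consistent with direct fits and improves with data", {
  toy <- additive_toy(2000, seed = 7, noise_sd = 1)
  plan <- split_plan(fractions = c(1, 0.25), seed = 5)
  lc <- learning_curve(toy$genotypes, toy$y, plan, small_cfg(), seed = 9)
  expect_identical(nrow(lc), 2L)
  expect_identical(lc$fraction, c(1, 0.25))
  # fraction-1 row equals a direct fit with the same derived seed
  direct <- train_model(toy$genotypes, toy$y, plan, small_cfg(),
                        seed = derive_seed(9, "lc1"))
  expect_equal(lc$r_squared[1], direct$metrics$r_squared)
  expect_gte(lc$r_squared[1], lc$r_squared[2] - 0.02)
})

test_that("positional baselines are exact on additive truth and blind to XOR", {
  toy <- additive_toy(3000, seed = 8)
  bl <- baseline_positional(toy$genotypes[1:2000], toy$y[1:2000])
  m <- eval_metrics(stats::predict(bl, toy$genotypes[2001:3000]),
                    toy$y[2001:3000])
  expect_gt(m$r_squared, 0.999)

  # purely epistatic target: XOR of bases at positions 1 and 2 (balanced)
  g <- sample_genotypes(spec, 4000, seed = 12)
  pur <- function(i) substr(g, i, i) %in% c("A", "G")
  y_xor <- as.numeric(xor(pur(3), pur(4)))
  bx <- baseline_positional(g[1:3000], y_xor[1:3000])
  mx <- eval_metrics(stats::predict(bx, g[3001:4000]), y_xor[3001:4000])
  expect_lt(abs(mx$r_squared), 0.05)

  # pair mode captures duplet structure at the constrained pair
  i16 <- 1L; i42 <- 14L
  dup <- paste0(substr(g, i16, i16), substr(g, i42, i42))
  y_pair <- as.numeric(dup %in% c("AT", "TA", "CG", "GC", "GT", "TG"))
  bp <- baseline_positional(g[1:3000], y_pair[1:3000], mode = "pair",
                            spec = spec)
  mp <- eval_metrics(stats::predict(bp, g[3001:4000]), y_pair[3001:4000])
  expect_gt(mp$r_squared, 0.999)
  bs <- baseline_positional(g[1:3000], y_pair[1:3000])
  ms <- eval_metrics(stats::predict(bs, g[3001:4000]), y_pair[3001:4000])
  expect_gt(mp$r_squared, ms$r_squared + 0.2)
})

test_that("specificity_regression reports a calibrated skew diagnostic", {
  # symmetric world: both arms drawn from one landscape at equal depth
  sim <- get_benchmark("additive", seed = 31, n_distinct = 2000, depth = 4e4)
  m <- merge_common(sim$post_counts[["4MUP"]], sim$post_counts[["diFMUP"]])
  run <- specificity_regression(m, split_plan(fractions = 1, seed = 2),
                                small_cfg(), seed = 3)
  expect_lt(abs(run$skew - 0.5), 0.05)
  expect_identical(nrow(run$predictions), length(run$split$test))
})

test_that("permutation importance ranks the planted positions first", {
  sim <- get_benchmark("specificity-planted", seed = 41)
  m <- merge_common(sim$post_counts[["4MUP"]], sim$post_counts[["diFMUP"]])
  plan <- split_plan(fractions = 1, seed = 4)
  run <- specificity_regression(m, plan, network_config(
    hidden_layer_sizes = c(64L, 64L), max_iter = 80L), seed = 5, spec = spec)
  expect_gte(run$metrics$r_squared, 0.5)
  X <- one_hot_encode(m$genotype, spec)[run$split$test, ]
  imp <- permutation_importance(run$fit, X, m$score[run$split$test],
                                n_repeats = 2L, seed = 6)
  top_feats <- imp$feature[1:8]
  top_pos <- as.integer(sub("^p(\\d+)_.*$", "\\1", top_feats))
  expect_true(all(top_pos %in% c(20L, 21L, 33L, 34L)))
})
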