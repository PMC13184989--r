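# Sequence -> activity/specificity regression workflow: one-hot encoding,
# seeded 80/20 split with nested downsampling, CV grid search, evaluation
# metrics, positional-frequency baselines and learning curves.

#' One-hot encode genotypes
#'
#' Position-major column order with bases ordered A,C,G,T: column
#' `4*(i-1)+j` is 1 iff position `i` carries base `j`. Each position block
#' sums to exactly 1 per row.
#'
#' @param genotypes Character vector of equal-length genotype strings over
#'   `{A,C,G,T}`.
#' @param spec Optional `library_spec`; if given, columns are named by core
#'   position (`p16_A`, ...), otherwise by genotype index (`x1_A`, ...).
#' @return Numeric matrix, `length(genotypes)` x `4 * k`.
#' @export
one_hot_encode <- function(genotypes, spec = NULL) {
  k <- nchar(genotypes[1L])
  if (any(nchar(genotypes) != k)) stop("genotypes must have equal length", call. = FALSE)
  if (any(grepl("[^ACGT]", genotypes)))
    stop("genotypes must be over {A,C,G,T}", call. = FALSE)
  sym <- genotype_matrix(genotypes, k)
  X <- matrix(0, nrow = length(genotypes), ncol = 4L * k)
  for (i in seq_len(k)) {
    j <- match(sym[, i], BASES)
    X[cbind(seq_len(nrow(X)), 4L * (i - 1L) + j)] <- 1
  }
  labels <- if (!is.null(spec)) paste0("p", spec$variable_positions)
            else paste0("x", seq_len(k))
  colnames(X) <- paste0(rep(labels, each = 4L), "_", rep(BASES, k))
  X
}

#' Decode a one-hot matrix back to genotype strings
#'
#' @param X Matrix produced by [one_hot_encode()].
#' @return Character vector of genotypes.
#' @export
decode_one_hot <- function(X) {
  k <- ncol(X) / 4L
  cols <- lapply(seq_len(k), function(i) {
    block <- X[, 4L * (i - 1L) + 1:4, drop = FALSE]
    BASES[max.col(block)]
  })
  do.call(paste0, cols)
}

#' Define a split / downsampling plan
#'
#' @param test_fraction Held-out test fraction (default 0.20).
#' @param fractions Training subsample fractions, sorted descending; nested so
#'   learning-curve points compare like with like. Default geometric halvings
#'   down to 1/32, which bracket the ~12.5% regime where predictive power
#'   typically degrades.
#' @param folds Cross-validation folds (default 3).
#' @param seed Integer seed.
#' @return A `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.2,
                       fractions = c(1, 1/2, 1/4, 1/8, 1/16, 1/32),
                       folds = 3L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            all(fractions > 0), all(fractions <= 1),
            !is.unsorted(rev(fractions)), folds >= 2L)
  structure(list(test_fraction = test_fraction, fractions = fractions,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "split_plan")
}

#' Seeded train/test split with nested downsampling indices
#'
#' Test rows are drawn once and never reused; the training remainder is
#' shuffled once and each downsampling fraction takes a prefix, so smaller
#' fractions are subsets of larger ones.
#'
#' @param n_rows Number of rows (>= 10).
#' @param plan A [split_plan()].
#' @return List with `test`, `train` (index vectors) and `downsamples`
#'   (named list of nested index vectors, one per fraction).
#' @export
make_split <- function(n_rows, plan = split_plan()) {
  stopifnot(n_rows >= 10L)
  set.seed(plan$seed)
  n_test <- round(plan$test_fraction * n_rows)
  test <- sort(sample.int(n_rows, n_test))
  train <- setdiff(seq_len(n_rows), test)
  shuffled <- sample(train)
  downs <- lapply(plan$fractions, function(f)
    shuffled[seq_len(max(1L, round(f * length(train))))])
  names(downs) <- format(plan$fractions, trim = TRUE)
  list(test = test, train = train, downsamples = downs)
}

#' Evaluate regression predictions
#'
#' Spearman rank correlation (average ranks for ties), coefficient of
#' determination about the test-set mean, and mean absolute error. Optional
#' per-row weights (e.g. read counts) weight R^2 and MAE; the rank
#' correlation is always unweighted.
#'
#' @param predicted,observed Numeric vectors (length >= 2).
#' @param weights Optional non-negative per-row weights.
#' @return An `eval_metrics` list: `spearman_rho`, `r_squared`, `mae`,
#'   `n_test`.
#' @export
eval_metrics <- function(predicted, observed, weights = NULL) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  w <- weights %||% rep(1, length(observed))
  stopifnot(length(w) == length(observed), all(w >= 0))
  ybar <- stats::weighted.mean(observed, w)
  ss_res <- sum(w * (observed - predicted)^2)
  ss_tot <- sum(w * (observed - ybar)^2)
  structure(list(
    spearman_rho = suppressWarnings(
      stats::cor(predicted, observed, method = "spearman")),
    r_squared = 1 - ss_res / ss_tot,
    mae = stats::weighted.mean(abs(observed - predicted), w),
    n_test = length(observed)), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("rho = %.3f, R^2 = %.3f, MAE = %.4g (n = %d)\n",
              x$spearman_rho, x$r_squared, x$mae, x$n_test))
  invisible(x)
}

#' Evaluate a fitted model on held-out data
#'
#' @param model An `mlp_fit` or `positional_baseline`.
#' @param X Feature matrix (`mlp_fit`) or genotype vector
#'   (`positional_baseline`).
#' @param y Observed targets.
#' @return An `eval_metrics`.
#' @export
evaluate <- function(model, X, y) {
  eval_metrics(stats::predict(model, X), y)
}

#' Default hyperparameter grid
#'
#' Covers hidden sizes, L2 penalty, initial learning rate and batch size;
#' the documented final configuration is one of its points.
#'
#' @return List of [network_config()] objects in grid order.
#' @export
default_grid <- function() {
  hidden <- list(100L, c(200L, 200L), c(200L, 200L, 200L))
  grid <- list()
  for (h in hidden) for (a in c(1e-4, 1e-3, 1e-2))
    for (lr in c(1e-3, 1e-2)) for (bs in c(100L, 200L))
      grid[[length(grid) + 1L]] <- network_config(
        hidden_layer_sizes = h, alpha = a, learning_rate_init = lr,
        batch_size = bs)
  grid
}

#' Grid search with k-fold cross-validation
#'
#' Exhaustively scores each candidate configuration by mean CV R^2 over
#' seeded folds of the supplied training rows (never the held-out test set);
#' ties break by grid order.
#'
#' @param X,y Training features and targets only.
#' @param grid List of [network_config()]s.
#' @param folds Number of folds (default 3).
#' @param seed Integer seed (fold assignment and fits).
#' @param sample_weight Optional loss weights.
#' @return List with `best_config`, `best_index`, `results` (`data.table` of
#'   grid index and mean/per-fold R^2).
#' @export
grid_search_cv <- function(X, y, grid, folds = 3L, seed = 1L,
                           sample_weight = NULL) {
  stopifnot(length(grid) >= 1L, folds >= 2L, nrow(X) >= folds)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(X)))
  res <- data.table::data.table(config = seq_along(grid), mean_r2 = NA_real_)
  fold_r2 <- matrix(NA_real_, length(grid), folds)
  for (gi in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_network(X[tr, , drop = FALSE], y[tr], grid[[gi]],
                         seed = derive_seed(seed, paste0("cv", gi, "-", f)),
                         sample_weight = sample_weight[tr])
      fold_r2[gi, f] <- eval_metrics(stats::predict(fit, X[!tr, , drop = FALSE]),
                                     y[!tr])$r_squared
    }
    res$mean_r2[gi] <- mean(fold_r2[gi, ])
  }
  for (f in seq_len(folds)) res[[paste0("fold", f)]] <- fold_r2[, f]
  best <- which.max(res$mean_r2)  # which.max takes the first maximum: grid order
  list(best_config = grid[[best]], best_index = best, results = res)
}

#' Positional-frequency baseline regressors
#'
#' `"single"` mode: a main-effects model of the per-position nucleotide
#' identities — least-squares fit of the target on one-hot position/base
#' indicators (equivalent to per-position mean deviations when positions are
#' independent, and correct when pair constraints make them correlated).
#' `"pair"` mode adds indicator blocks for the joint base identity (duplet)
#' at each pair constraint. Categories unseen in training fall back to the
#' reference prediction.
#'
#' @param genotypes Training genotype strings.
#' @param y Training targets.
#' @param mode `"single"` or `"pair"`.
#' @param spec A `library_spec` (required for `"pair"` mode).
#' @param sample_weight Optional non-negative least-squares weights.
#' @return A `positional_baseline` with a [predict()] method taking genotype
#'   strings.
#' @export
baseline_positional <- function(genotypes, y, mode = c("single", "pair"),
                                spec = NULL, sample_weight = NULL) {
  mode <- match.arg(mode)
  if (mode == "pair" && is.null(spec))
    stop("'pair' mode needs a library_spec for its pair constraints", call. = FALSE)
  k <- nchar(genotypes[1L])
  X <- baseline_design(genotypes, k, mode, spec)
  fit <- if (is.null(sample_weight)) stats::lm.fit(X, y)
         else stats::lm.wfit(X, y, w = sample_weight)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # aliased columns (block sums) drop out
  structure(list(coefs = coefs, mode = mode, k = k,
                 pair_idx = if (mode == "pair")
                   lapply(spec$pair_constraints, function(con)
                     genotype_index(spec, c(con$pos5, con$pos3)))),
            class = "positional_baseline")
}

# Design matrix: intercept + one-hot per position (+ duplet one-hot per pair
# constraint in "pair" mode).
baseline_design <- function(genotypes, k, mode, spec,
                            pair_idx = NULL) {
  X <- cbind(`(Intercept)` = 1, one_hot_encode(genotypes))
  if (mode == "pair") {
    idxs <- pair_idx %||% lapply(spec$pair_constraints, function(con)
      genotype_index(spec, c(con$pos5, con$pos3)))
    sym <- genotype_matrix(genotypes, k)
    duplets <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, b)))
    for (j in seq_along(idxs)) {
      dup <- paste0(sym[, idxs[[j]][1]], sym[, idxs[[j]][2]])
      D <- matrix(0, length(genotypes), length(duplets),
                  dimnames = list(NULL, paste0("pair", j, "_", duplets)))
      D[cbind(seq_along(dup), match(dup, duplets))] <- 1
      X <- cbind(X, D)
    }
  }
  X
}

#' @export
predict.positional_baseline <- function(object, newdata, ...) {
  X <- baseline_design(newdata, object$k, object$mode, spec = NULL,
                       pair_idx = object$pair_idx)
  as.vector(X %*% object$coefs)
}

#' Train and evaluate a sequence-to-target regression
#'
#' The standard workflow: one-hot encode, split per `plan`, fit the network on
#' the full training set (or a downsample), evaluate on the held-out test set.
#'
#' @param genotypes Genotype strings.
#' @param y Targets (e.g. CPM or specificity score).
#' @param plan A [split_plan()].
#' @param config A [network_config()].
#' @param seed Integer seed for the fit (the split uses `plan$seed`).
#' @param sample_weight Optional per-row weights (e.g. read counts for CPM
#'   regression).
#' @param fraction Training fraction to use (must be one of
#'   `plan$fractions`; default 1).
#' @param spec Optional `library_spec` for feature names.
#' @return List with `fit`, `metrics`, `predictions` (`data.table` of
#'   genotype, observed, predicted on the test set), `split`.
#' @export
train_model <- function(genotypes, y, plan = split_plan(),
                        config = network_config(), seed = 1L,
                        sample_weight = NULL, fraction = 1, spec = NULL) {
  X <- one_hot_encode(genotypes, spec)
  sp <- make_split(nrow(X), plan)
  fi <- which(abs(plan$fractions - fraction) < 1e-9)
  if (length(fi) != 1L) stop("fraction not in plan$fractions", call. = FALSE)
  tr <- sp$downsamples[[fi]]
  fit <- fit_network(X[tr, , drop = FALSE], y[tr], config, seed = seed,
                     sample_weight = sample_weight[tr])
  pred <- stats::predict(fit, X[sp$test, , drop = FALSE])
  metrics <- eval_metrics(pred, y[sp$test])
  list(fit = fit, metrics = metrics,
       predictions = data.table::data.table(genotype = genotypes[sp$test],
                                            observed = y[sp$test],
                                            predicted = pred),
       split = sp)
}

#' Learning curve over nested training-set downsamples
#'
#' One model per fraction in the plan, all evaluated on the same held-out
#' test set.
#'
#' @inheritParams train_model
#' @return `data.table` with `fraction`, `n_train`, `spearman_rho`,
#'   `r_squared`, `mae`, `seed`.
#' @export
learning_curve <- function(genotypes, y, plan = split_plan(),
                           config = network_config(), seed = 1L,
                           sample_weight = NULL, spec = NULL) {
  X <- one_hot_encode(genotypes, spec)
  sp <- make_split(nrow(X), plan)
  rows <- lapply(seq_along(plan$fractions), function(i) {
    tr <- sp$downsamples[[i]]
    fit <- fit_network(X[tr, , drop = FALSE], y[tr], config,
                       seed = derive_seed(seed, paste0("lc", i)),
                       sample_weight = sample_weight[tr])
    m <- eval_metrics(stats::predict(fit, X[sp$test, , drop = FALSE]), y[sp$test])
    data.table::data.table(fraction = plan$fractions[i], n_train = length(tr),
                           spearman_rho = m$spearman_rho,
                           r_squared = m$r_squared, mae = m$mae,
                           seed = derive_seed(seed, paste0("lc", i)))
  })
  data.table::rbindlist(rows)
}

#' Specificity-score regression with a skew diagnostic
#'
#' Runs the standard workflow with the merged table's specificity score as
#' target (unweighted by default) and reports the share of positive scores —
#' the imbalance mechanism that limits specificity models when one arm
#' dominates.
#'
#' @param merged A `merged_specificity`.
#' @param plan,config,seed,sample_weight As in [train_model()].
#' @param spec Optional `library_spec`.
#' @return List with `metrics`, `predictions`, `fit`, `skew` (share of
#'   positive scores in the full merged table).
#' @export
specificity_regression <- function(merged, plan = split_plan(),
                                   config = network_config(), seed = 1L,
                                   sample_weight = NULL, spec = NULL) {
  stopifnot(inherits(merged, "merged_specificity"), nrow(merged) > 0L)
  run <- train_model(merged$genotype, merged$score, plan, config, seed,
                     sample_weight = sample_weight, spec = spec)
  run$skew <- mean(merged$score > 0)
  run
}

#' CPM regression from a merged table
#'
#' Regresses one arm's raw CPM on sequence; rows are weighted by that arm's
#' read counts by default (abundant sequences carry more evidence).
#'
#' @param merged A `merged_specificity`.
#' @param arm `"a"` or `"b"`.
#' @param weight_by_counts Use the arm's read counts as loss weights
#'   (default `TRUE`).
#' @param plan,config,seed As in [train_model()].
#' @param spec Optional `library_spec`.
#' @return As [train_model()].
#' @export
cpm_regression <- function(merged, arm = c("a", "b"), plan = split_plan(),
                           config = network_config(), seed = 1L,
                           weight_by_counts = TRUE, spec = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(merged, "merged_specificity"), nrow(merged) > 0L)
  y <- merged[[paste0("cpm_", arm)]]
  w <- if (weight_by_counts) merged[[paste0("count_", arm)]] else NULL
  train_model(merged$genotype, y, plan, config, seed, sample_weight = w,
              spec = spec)
}

#' Permutation importance of one-hot feature columns
#'
#' Drop in held-out R^2 when one column is shuffled, averaged over repeats.
#'
#' @param model An `mlp_fit`.
#' @param X,y Held-out features and targets.
#' @param n_repeats Shuffles per column (default 3).
#' @param seed Integer seed.
#' @return `data.table` with `feature`, `importance`, sorted descending.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 3L, seed = 1L) {
  base_r2 <- eval_metrics(stats::predict(model, X), y)$r_squared
  set.seed(seed)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      base_r2 - eval_metrics(stats::predict(model, Xp), y)$r_squared
    }, 0)
    mean(drops)
  }, 0)
  out <- data.table::data.table(feature = colnames(X) %||%
                                  paste0("V", seq_len(ncol(X))),
                                importance = imp)
  data.table::setorderv(out, "importance", order = -1L)
  out[]
}
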