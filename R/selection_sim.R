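# Synthetic single-step selection: genotype -> reacted-fraction landscape,
# enrichment proportional to reacted fraction, multinomial read sampling.

BASES <- c("A", "C", "G", "T")

# genotype strings -> n x k matrix of single characters
genotype_matrix <- function(genotypes, k) {
  matrix(unlist(strsplit(genotypes, ""), use.names = FALSE),
         ncol = k, byrow = TRUE)
}

#' Construct a ground-truth activity landscape
#'
#' Maps genotypes to a per-substrate reacted fraction through a linear score
#' (additive per position/base effects, optional pairwise epistatic effects,
#' optional bonus per satisfied pair constraint) passed through a link, plus a
#' substrate-independent non-specific background:
#' `p = background + (1 - background) * link(intercept + score)`.
#'
#' @param spec A `library_spec`.
#' @param substrates Character vector of substrate names.
#' @param additive Named list (per substrate) of `k x 4` matrices (rows =
#'   variable positions in order, columns A,C,G,T) of additive effects.
#' @param epistatic Optional `data.frame` with columns `substrate`, `pos_i`,
#'   `base_i`, `pos_j`, `base_j`, `effect` (core coordinates).
#' @param pairing_bonus Named numeric per substrate: score bonus per satisfied
#'   pair constraint (under the default [pairing_rule()]).
#' @param intercept Named numeric per substrate.
#' @param background Non-specific reaction probability floor (scalar or named
#'   per substrate), e.g. background ligation.
#' @param link `"logistic"` or `"linear"` (identity clamped to `[0, 1]`).
#' @param rugged Optional named list (per substrate) of named numeric vectors:
#'   idiosyncratic per-genotype score deviations (activity cliffs) added on
#'   top of the additive/epistatic terms; genotypes not listed get 0. Part of
#'   the deterministic ground truth, but not a smooth function of sequence.
#' @return An `activity_landscape` object.
#' @export
activity_landscape <- function(spec, substrates, additive, epistatic = NULL,
                               pairing_bonus = NULL, intercept,
                               background = 0, link = c("logistic", "linear"),
                               rugged = NULL) {
  link <- match.arg(link)
  k <- length(spec$variable_positions)
  stopifnot(setequal(names(additive), substrates),
            all(vapply(additive, function(m) all(dim(m) == c(k, 4L)), TRUE)),
            setequal(names(intercept), substrates))
  if (is.null(pairing_bonus))
    pairing_bonus <- stats::setNames(rep(0, length(substrates)), substrates)
  if (length(background) == 1L && is.null(names(background)))
    background <- stats::setNames(rep(background, length(substrates)), substrates)
  structure(list(spec = spec, substrates = substrates, additive = additive,
                 epistatic = epistatic, pairing_bonus = pairing_bonus,
                 intercept = intercept, background = background, link = link,
                 rugged = rugged),
            class = "activity_landscape")
}

landscape_score <- function(genotypes, substrate, truth) {
  spec <- truth$spec
  k <- length(spec$variable_positions)
  sym <- genotype_matrix(genotypes, k)
  eff <- truth$additive[[substrate]]
  score <- rep(truth$intercept[[substrate]], length(genotypes))
  base_idx <- matrix(match(sym, BASES), nrow = nrow(sym))
  for (i in seq_len(k))
    score <- score + eff[cbind(i, base_idx[, i])]
  epi <- truth$epistatic
  if (!is.null(epi)) {
    epi <- epi[epi$substrate == substrate, , drop = FALSE]
    if (nrow(epi)) {
      ii <- genotype_index(spec, epi$pos_i)
      jj <- genotype_index(spec, epi$pos_j)
      for (r in seq_len(nrow(epi))) {
        hit <- sym[, ii[r]] == epi$base_i[r] & sym[, jj[r]] == epi$base_j[r]
        score <- score + epi$effect[r] * hit
      }
    }
  }
  bonus <- truth$pairing_bonus[[substrate]]
  if (bonus != 0) {
    rule <- pairing_rule()
    for (con in spec$pair_constraints) {
      idx <- genotype_index(spec, c(con$pos5, con$pos3))
      paired <- paste0(sym[, idx[1]], sym[, idx[2]]) %in% rule$paired_duplets
      score <- score + bonus * paired
    }
  }
  rug <- truth$rugged[[substrate]]
  if (!is.null(rug)) {
    dev <- rug[genotypes]
    dev[is.na(dev)] <- 0
    score <- score + unname(dev)
  }
  score
}

#' Reacted fraction of genotypes under a ground-truth landscape
#'
#' @param genotypes Character vector of genotype strings.
#' @param substrate Substrate name.
#' @param truth An [activity_landscape()].
#' @return Numeric vector of fractions in `[0, 1]`; deterministic.
#' @export
reacted_fraction <- function(genotypes, substrate, truth) {
  stopifnot(inherits(truth, "activity_landscape"),
            substrate %in% truth$substrates)
  validate_genotypes(genotypes, truth$spec)
  s <- landscape_score(genotypes, substrate, truth)
  p <- switch(truth$link,
              logistic = stats::plogis(s),
              linear = pmin(pmax(s, 0), 1))
  bg <- truth$background[[substrate]]
  bg + (1 - bg) * p
}

#' Simulate a pre-selection pool
#'
#' Draws `n_distinct` unique genotypes uniformly from the encoded space and
#' assigns them frequencies from a symmetric Dirichlet: larger `concentration`
#' means closer to equimolar.
#'
#' @param spec A `library_spec`.
#' @param n_distinct Number of distinct genotypes (must not exceed
#'   `library_size(spec)`).
#' @param concentration Dirichlet concentration parameter (default 100:
#'   modest synthesis skew around equimolar).
#' @param seed Integer seed.
#' @return `data.table` with columns `genotype`, `freq` (summing to 1).
#' @export
simulate_pool <- function(spec, n_distinct, concentration = 100, seed) {
  if (n_distinct > library_size(spec))
    stop("n_distinct exceeds the encoded space", call. = FALSE)
  gs <- unique(sample_genotypes(spec, n_distinct, seed = seed))
  tries <- 0L
  while (length(gs) < n_distinct && tries < 50L) {
    tries <- tries + 1L
    extra <- sample_genotypes(spec, 2L * (n_distinct - length(gs)),
                              seed = derive_seed(seed, paste0("pool-topup", tries)))
    gs <- unique(c(gs, extra))
  }
  gs <- gs[seq_len(n_distinct)]
  set.seed(derive_seed(seed, "pool-freqs"))
  w <- stats::rgamma(n_distinct, shape = concentration, rate = 1)
  data.table::data.table(genotype = gs, freq = w / sum(w))
}

#' Apply one round of selection to a pool
#'
#' Post-selection frequency is proportional to pre-selection frequency times
#' the genotype's reacted fraction (reacted members are tagged, purified and
#' amplified; everything downstream is proportional sampling).
#'
#' @param pool `data.table` with `genotype`, `freq` (summing to 1).
#' @param truth An [activity_landscape()].
#' @param substrate Substrate name.
#' @return `data.table` with `genotype`, `freq` (post-selection, summing to 1).
#' @export
simulate_selection <- function(pool, truth, substrate) {
  p <- reacted_fraction(pool$genotype, substrate, truth)
  w <- pool$freq * p
  if (sum(w) <= 0) stop("degenerate selection: all reacted fractions are zero",
                        call. = FALSE)
  data.table::data.table(genotype = pool$genotype, freq = w / sum(w))
}

#' Sample sequencing reads from a frequency map
#'
#' Multinomial draw of `depth` reads; genotypes drawn zero times are absent
#' from the resulting table (as in real sequencing).
#'
#' @param freqs `data.table` with `genotype`, `freq`.
#' @param depth Total number of reads (> 0).
#' @param seed Integer seed.
#' @param arm_label Arm label for the output table.
#' @return A `genotype_counts` table.
#' @export
sample_reads <- function(freqs, depth, seed, arm_label = "arm") {
  stopifnot(depth > 0)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, size = depth, prob = freqs$freq))
  count_and_normalize(counts = stats::setNames(counts, freqs$genotype),
                      arm_label = arm_label)
}

#' Write a count table as FASTQ reads embedded in the reference core
#'
#' Emits one record per read (a genotype with count c produces c records),
#' with constant maximal base qualities; inverse of [process_reads()].
#'
#' @param table A `genotype_counts`.
#' @param spec A `library_spec`.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(table, spec, path) {
  stopifnot(inherits(table, "genotype_counts"))
  seqs <- embed_in_core(rep(table$genotype, table$count), spec)
  qual <- strrep("I", spec$core_length)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

# ---- benchmark scenario registry ------------------------------------------

# Centred per-position additive effects, k x 4, iid N(0, sd) per cell.
random_additive <- function(k, sd) {
  m <- matrix(stats::rnorm(k * 4L, sd = sd), nrow = k,
              dimnames = list(NULL, BASES))
  m - rowMeans(m)
}

# Positive lognormal effect cells with a given mean and log-sd: summing such
# cells yields a reacted fraction that is exactly additive, strictly
# positive, and heavy-tailed (many weak, few strong contributions).
random_additive_positive <- function(k, mean_cell, sdlog = 1.5) {
  meanlog <- log(mean_cell) - sdlog^2 / 2
  matrix(stats::rlnorm(k * 4L, meanlog = meanlog, sdlog = sdlog), nrow = k,
         dimnames = list(NULL, BASES))
}

benchmark_scenarios <- c("additive", "epistatic", "specificity-planted",
                         "imbalanced")

# Positions whose substrate effects differ in the "specificity-planted"
# scenario (a known reference set recovered by the mutation-effect analysis).
PLANTED_POSITIONS <- c(20L, 21L, 33L, 34L)

build_landscape <- function(scenario, spec, seed) {
  k <- length(spec$variable_positions)
  subs <- c("4MUP", "diFMUP")
  set.seed(derive_seed(seed, paste0("landscape-", scenario)))
  if (scenario == "additive") {
    # reacted fraction = sum of positive per-position cells: exactly additive
    # in position/base indicators (the regime where a main-effects baseline
    # is correctly specified), strictly inside (0, 1), heavy-tailed
    eff <- random_additive_positive(k, mean_cell = 0.05 / k)
    activity_landscape(spec, subs,
                       additive = list(`4MUP` = eff, diFMUP = eff),
                       intercept = c(`4MUP` = 0, diFMUP = 0),
                       link = "linear")
  } else if (scenario == "epistatic") {
    # additive cells plus positive pairwise (duplet-specific) cells at six
    # position pairs: a main-effects model misses most of the signal
    eff <- random_additive_positive(k, mean_cell = 0.02 / k)
    n_pos <- as.integer(names(spec$position_codes))
    cmb <- utils::combn(n_pos, 2L)
    pairs <- t(cmb[, sample.int(ncol(cmb), 6L), drop = FALSE])
    mean_pair_cell <- 0.03 / nrow(pairs)
    epi <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      cells <- stats::rlnorm(16L, meanlog = log(mean_pair_cell) - 1.5^2 / 2,
                             sdlog = 1.5)
      data.frame(substrate = rep(subs, each = 16L),
                 pos_i = pairs[r, 1], base_i = rep(rep(BASES, each = 4L), 2L),
                 pos_j = pairs[r, 2], base_j = rep(rep(BASES, 4L), 2L),
                 effect = rep(cells, 2L))
    }))
    activity_landscape(spec, subs,
                       additive = list(`4MUP` = eff, diFMUP = eff),
                       epistatic = epi,
                       intercept = c(`4MUP` = 0, diFMUP = 0),
                       link = "linear")
  } else if (scenario == "specificity-planted") {
    eff_a <- random_additive(k, sd = 0.5)
    eff_b <- eff_a
    idx <- genotype_index(spec, PLANTED_POSITIONS)
    delta <- random_additive(length(idx), sd = 1.0)
    eff_b[idx, ] <- eff_b[idx, ] + delta
    activity_landscape(spec, subs,
                       additive = list(`4MUP` = eff_a, diFMUP = eff_b),
                       intercept = c(`4MUP` = -2, diFMUP = -2),
                       background = 1e-4,
                       link = "logistic")
  } else if (scenario == "imbalanced") {
    # arm A: heavy-tailed logistic landscape over a sizeable non-specific
    # background, giving a continuum of enriched genotypes (predictable raw
    # CPM) while most common genotypes carry only a few reads; arm B reacts
    # appreciably only through idiosyncratic per-genotype activity cliffs
    # (added in make_benchmark as the landscape's rugged component), so it
    # has few enriched genotypes, no smooth sequence signal, and its
    # background members shared with arm A sit at ~1 read. The log2
    # CPM-ratio of the common mass is then dominated by counting noise and
    # unlearnable cliffs (skewed positive), while raw CPM stays predictable
    # - the imbalance structure this scenario models.
    eff_a <- random_additive(k, sd = 1.5)
    eff_b <- 0.3 * eff_a
    activity_landscape(spec, subs,
                       additive = list(`4MUP` = eff_a, diFMUP = eff_b),
                       intercept = c(`4MUP` = -12, diFMUP = -16),
                       background = c(`4MUP` = 6e-3, diFMUP = 5e-5),
                       link = "logistic")
  } else {
    stop("unknown scenario: '", scenario, "'", call. = FALSE)
  }
}

#' Generate a registered benchmark selection
#'
#' Scenario registry:
#' * `"additive"` — purely additive reacted-fraction landscape, identical for
#'   both substrates (identity link).
#' * `"epistatic"` — adds pairwise interaction terms and a pairing bonus.
#' * `"specificity-planted"` — logistic landscape in which the two substrates
#'   differ only at positions 20, 21, 33 and 34.
#' * `"imbalanced"` — the second arm reacts appreciably only for genotypes
#'   carrying a 3-base motif, so it has far fewer enriched genotypes.
#'
#' @param scenario One of the registered scenario names.
#' @param seed Integer seed; all randomness (landscape draw, pool, read
#'   sampling) derives from it.
#' @param n_distinct Distinct genotypes in the pool (default 1e5).
#' @param depth Reads per arm (default 1e6).
#' @param concentration Pool Dirichlet concentration (default 100).
#' @return A `simulated_selection`: list with `spec`, `truth`, `pool`,
#'   `post_freqs` (per substrate), `pre_counts`, `post_counts` (per
#'   substrate), `scenario`, `seed`.
#' @export
make_benchmark <- function(scenario, seed, n_distinct = 1e5, depth = 1e6,
                           concentration = 100) {
  scenario <- match.arg(scenario, benchmark_scenarios)
  spec <- aurora_bulge_spec()
  truth <- build_landscape(scenario, spec, seed)
  pool <- simulate_pool(spec, n_distinct, concentration,
                        seed = derive_seed(seed, "pool"))
  if (scenario == "imbalanced") {
    # idiosyncratic arm-B activity cliffs over the pool's genotypes; the sd
    # puts the few saturated cliff genotypes in charge of most arm-B reads
    set.seed(derive_seed(seed, "rugged"))
    truth$rugged <- list(diFMUP = stats::setNames(
      stats::rnorm(n_distinct, sd = 5), pool$genotype))
  }
  post_freqs <- lapply(stats::setNames(truth$substrates, truth$substrates),
                       function(s) simulate_selection(pool, truth, s))
  pre_counts <- sample_reads(pool, depth, seed = derive_seed(seed, "reads-pre"),
                             arm_label = "round0")
  post_counts <- lapply(stats::setNames(truth$substrates, truth$substrates),
                        function(s) sample_reads(post_freqs[[s]], depth,
                                                 seed = derive_seed(seed, paste0("reads-", s)),
                                                 arm_label = s))
  structure(list(spec = spec, truth = truth, pool = pool,
                 post_freqs = post_freqs, pre_counts = pre_counts,
                 post_counts = post_counts, scenario = scenario, seed = seed,
                 n_distinct = n_distinct, depth = depth,
                 concentration = concentration),
            class = "simulated_selection")
}

#' Expected (noise-free) post-selection CPM for a benchmark
#'
#' With `equimolar = FALSE` (default) the expectation is taken over the
#' actual simulated pool, i.e. it includes the pool's synthesis skew. With
#' `equimolar = TRUE` it is the purely sequence-determined expectation under
#' an equimolar pool — the ground-truth function a sequence-to-activity model
#' can at best recover.
#'
#' @param sim A `simulated_selection`.
#' @param substrate Substrate name.
#' @param equimolar Ignore the pool's frequency skew.
#' @return Named numeric vector of expected CPM over pool genotypes.
#' @export
expected_cpm <- function(sim, substrate, equimolar = FALSE) {
  if (equimolar) {
    p <- reacted_fraction(sim$pool$genotype, substrate, sim$truth)
    return(stats::setNames(p / sum(p) * 1e6, sim$pool$genotype))
  }
  f <- sim$post_freqs[[substrate]]
  stats::setNames(f$freq * 1e6, f$genotype)
}

#' Serialize a benchmark's ground truth to JSON
#'
#' Records the landscape (additive/epistatic effects, intercepts, link,
#' background), scenario, seed and sizes so recovery tests never re-derive
#' the truth.
#'
#' @param sim A `simulated_selection`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(sim, path) {
  tr <- sim$truth
  obj <- list(
    scenario = sim$scenario, seed = sim$seed,
    n_distinct = sim$n_distinct, depth = sim$depth,
    concentration = sim$concentration,
    substrates = tr$substrates, link = tr$link,
    intercept = as.list(tr$intercept),
    background = as.list(tr$background),
    pairing_bonus = as.list(tr$pairing_bonus),
    variable_positions = tr$spec$variable_positions,
    additive = lapply(tr$additive, function(m) as.data.frame(m)),
    epistatic = tr$epistatic,
    # the full per-genotype rugged vectors live in memory / RDS-free reruns;
    # the JSON records their dispersion only
    rugged_sd = if (!is.null(tr$rugged)) lapply(tr$rugged, stats::sd)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
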