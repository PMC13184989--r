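# Per-position stratification of the specificity score and mutation-effect
# ranking against a permutation null.

base_at <- function(genotypes, spec, position) {
  i <- genotype_index(spec, position)
  substr(genotypes, i, i)
}

#' Partition a merged table by the base at one variable position
#'
#' @param m A `merged_specificity`.
#' @param spec A `library_spec`.
#' @param position A variable core position.
#' @return Named list (`A`, `C`, `G`, `T`) of disjoint, exhaustive row subsets
#'   (each a `data.table`; possibly 0-row).
#' @export
stratify_by_position <- function(m, spec, position) {
  stopifnot(inherits(m, "merged_specificity"))
  b <- base_at(m$genotype, spec, position)
  dt <- data.table::as.data.table(m)
  lapply(stats::setNames(BASES, BASES), function(x) dt[b == x, ])
}

position_effect_summary <- function(m, spec, position, min_n = 10L,
                                    scores = NULL) {
  scores <- scores %||% m$score
  b <- base_at(m$genotype, spec, position)
  w <- m$cpm_a + m$cpm_b
  per_base <- lapply(stats::setNames(BASES, BASES), function(x) {
    sel <- b == x
    list(n = sum(sel),
         median_score = if (any(sel)) stats::median(scores[sel]) else NA_real_,
         mean_score = if (any(sel)) mean(scores[sel]) else NA_real_,
         weighted_mean_score = if (any(sel))
           stats::weighted.mean(scores[sel], w[sel]) else NA_real_)
  })
  med <- vapply(per_base, function(x)
    if (x$n >= min_n) x$median_score else NA_real_, 0)
  effect_range <- if (sum(!is.na(med)) >= 2L) diff(range(med, na.rm = TRUE)) else NA_real_
  list(position = position, per_base = per_base, effect_range = effect_range)
}

#' Rank variable positions by their mutation effect on specificity
#'
#' For each variable position, rows (optionally filtered to high abundance)
#' are stratified by the base at that position; the effect statistic is the
#' range (max minus min) of per-base median specificity scores among bases
#' with at least `min_n` rows. Positions are returned sorted by effect range
#' descending, ties broken by position index. CPM-weighted means are reported
#' alongside, since abundant sequences carry more evidence.
#'
#' @param m A `merged_specificity`.
#' @param spec A `library_spec`.
#' @param min_cpm Keep rows with `max(cpm_a, cpm_b) >= min_cpm` (default 10,
#'   the conventional "high abundance" cut).
#' @param min_n Minimum rows per base for that base's median to count
#'   (default 10).
#' @return `data.table` with one row per (position, base): columns `position`,
#'   `base`, `n`, `median_score`, `mean_score`, `weighted_mean_score`,
#'   `effect_range`, `rank`; ordered by rank. Empty (0-row) result if the
#'   filter empties the table.
#' @export
rank_positions_by_effect <- function(m, spec, min_cpm = 10, min_n = 10L) {
  stopifnot(inherits(m, "merged_specificity"), min_cpm >= 0, min_n >= 0)
  keep <- pmax(m$cpm_a, m$cpm_b) >= min_cpm
  dt <- data.table::as.data.table(m)[keep, ]
  if (nrow(dt) == 0L) return(data.table::data.table())
  dt <- structure(dt, class = c("merged_specificity", class(dt)))
  rows <- list()
  for (p in spec$variable_positions) {
    s <- position_effect_summary(dt, spec, p, min_n = min_n)
    for (x in BASES) {
      pb <- s$per_base[[x]]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        position = p, base = x, n = pb$n, median_score = pb$median_score,
        mean_score = pb$mean_score,
        weighted_mean_score = pb$weighted_mean_score,
        effect_range = s$effect_range)
    }
  }
  out <- data.table::rbindlist(rows)
  pos_order <- unique(out[order(-out$effect_range, out$position),
                          c("position", "effect_range")])
  pos_order[, "rank" := seq_len(nrow(pos_order))]
  out <- merge(out, pos_order[, c("position", "rank")], by = "position")
  data.table::setorderv(out, c("rank", "base"))
  out[]
}

#' Report the specificity of designated variants
#'
#' @param m A `merged_specificity`.
#' @param variants Character vector of genotype strings.
#' @return `data.table` with `genotype`, `cpm_a`, `cpm_b`, `score`, `status`
#'   (`"common"`, `"a_only"`, `"b_only"`, `"absent"`); missing variants are
#'   flagged, not errors.
#' @export
variant_specificity <- function(m, variants) {
  stopifnot(inherits(m, "merged_specificity"))
  idx <- match(variants, m$genotype)
  a_only <- attr(m, "a_only"); b_only <- attr(m, "b_only")
  status <- ifelse(!is.na(idx), "common",
            ifelse(variants %in% a_only$genotype, "a_only",
            ifelse(variants %in% b_only$genotype, "b_only", "absent")))
  data.table::data.table(
    genotype = variants,
    cpm_a = ifelse(!is.na(idx), m$cpm_a[idx],
                   a_only$cpm_a[match(variants, a_only$genotype)]),
    cpm_b = ifelse(!is.na(idx), m$cpm_b[idx],
                   b_only$cpm_b[match(variants, b_only$genotype)]),
    score = ifelse(!is.na(idx), m$score[idx], NA_real_),
    status = status)
}

#' Permutation null distribution of a position's effect range
#'
#' Recomputes the effect range after random shuffles of the score column
#' (base assignments and per-base n are untouched), giving a calibrated
#' "no positional effect" reference for [rank_positions_by_effect()].
#'
#' @param m A `merged_specificity` (pre-filtered as desired).
#' @param spec A `library_spec`.
#' @param position Variable core position.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param min_n As in [rank_positions_by_effect()].
#' @return List with `observed`, `null` (numeric vector of permuted effect
#'   ranges), and `quantiles` (0.5, 0.9, 0.95, 0.99).
#' @export
permutation_null_effect_range <- function(m, spec, position, n_perm = 200L,
                                          seed = 1L, min_n = 10L) {
  stopifnot(n_perm >= 100L)
  observed <- position_effect_summary(m, spec, position, min_n)$effect_range
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    position_effect_summary(m, spec, position, min_n,
                            scores = sample(m$score))$effect_range
  }, 0)
  list(observed = observed, null = null,
       quantiles = stats::quantile(null, c(0.5, 0.9, 0.95, 0.99), na.rm = TRUE))
}
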