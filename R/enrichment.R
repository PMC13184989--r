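# Arm comparison: CPM distributions, inner merge on common genotypes, and the
# log2 CPM-ratio specificity score.

#' Specificity score: log2 of a CPM ratio
#'
#' Positive scores mean the genotype prefers arm A's substrate. Antisymmetric
#' under swapping the arms.
#'
#' @param cpm_a,cpm_b Strictly positive CPM values (vectorised).
#' @return `log2(cpm_a / cpm_b)`.
#' @export
specificity_score <- function(cpm_a, cpm_b) {
  if (any(cpm_a <= 0) || any(cpm_b <= 0))
    stop("CPM values must be strictly positive", call. = FALSE)
  log2(cpm_a / cpm_b)
}

#' Merge two selection arms on their common genotypes
#'
#' Inner join on genotype of two count tables; each common row gets both CPM
#' values and the specificity score `log2(cpm_a / cpm_b)`. Genotypes exclusive
#' to one arm are reported separately (they get no score; a display-only
#' pseudocount is available via [scatter_export()]).
#'
#' @param a,b `genotype_counts` tables for arms A and B.
#' @return A `merged_specificity` object: `data.table` with columns
#'   `genotype`, `cpm_a`, `cpm_b`, `count_a`, `count_b`, `score`; attributes
#'   `arm_a_label`, `arm_b_label`, `n_common`, `a_only`, `b_only`. An empty
#'   intersection gives an empty (0-row) table, not an error.
#' @export
merge_common <- function(a, b) {
  stopifnot(inherits(a, "genotype_counts"), inherits(b, "genotype_counts"),
            nrow(a) > 0L, nrow(b) > 0L)
  da <- data.table::as.data.table(a)[, c("genotype", "count", "cpm")]
  db <- data.table::as.data.table(b)[, c("genotype", "count", "cpm")]
  data.table::setnames(da, c("genotype", "count_a", "cpm_a"))
  data.table::setnames(db, c("genotype", "count_b", "cpm_b"))
  m <- merge(da, db, by = "genotype")
  m[, "score" := if (nrow(m)) specificity_score(m$cpm_a, m$cpm_b) else numeric(0)]
  data.table::setorderv(m, "genotype")
  data.table::setcolorder(m, c("genotype", "cpm_a", "cpm_b", "score",
                               "count_a", "count_b"))
  structure(m, class = c("merged_specificity", class(m)),
            arm_a_label = attr(a, "arm_label"), arm_b_label = attr(b, "arm_label"),
            n_common = nrow(m),
            a_only = da[!da$genotype %in% m$genotype, ],
            b_only = db[!db$genotype %in% m$genotype, ])
}

#' @export
print.merged_specificity <- function(x, ...) {
  cat(sprintf("merged_specificity [%s vs %s]: %d common genotypes (%d/%d exclusive)\n",
              attr(x, "arm_a_label"), attr(x, "arm_b_label"), attr(x, "n_common"),
              nrow(attr(x, "a_only")), nrow(attr(x, "b_only"))))
  NextMethod()
}

#' Export scatter coordinates for the two-arm CPM comparison
#'
#' Common genotypes at their observed CPM pairs; arm-exclusive genotypes are
#' placed using a display-only pseudocount (half the minimum observed CPM of
#' the missing arm) and flagged, mirroring how single-arm sequences are drawn
#' in two-arm scatter plots. Pseudocounted rows never enter score analyses.
#'
#' @param m A `merged_specificity`.
#' @return `data.table` with `genotype`, `cpm_a`, `cpm_b`, `exclusive`
#'   (`"none"`, `"a_only"`, `"b_only"`).
#' @export
scatter_export <- function(m) {
  stopifnot(inherits(m, "merged_specificity"))
  common <- data.table::data.table(genotype = m$genotype, cpm_a = m$cpm_a,
                                   cpm_b = m$cpm_b, exclusive = "none")
  a_only <- attr(m, "a_only"); b_only <- attr(m, "b_only")
  pseudo_a <- if (nrow(b_only)) min(m$cpm_a, a_only$cpm_a) / 2 else NA_real_
  pseudo_b <- if (nrow(a_only)) min(m$cpm_b, b_only$cpm_b) / 2 else NA_real_
  out <- list(common)
  if (nrow(a_only))
    out <- c(out, list(data.table::data.table(genotype = a_only$genotype,
                                              cpm_a = a_only$cpm_a,
                                              cpm_b = pseudo_b, exclusive = "a_only")))
  if (nrow(b_only))
    out <- c(out, list(data.table::data.table(genotype = b_only$genotype,
                                              cpm_a = pseudo_a,
                                              cpm_b = b_only$cpm_b, exclusive = "b_only")))
  data.table::rbindlist(out)
}

#' Summarise enrichment of a selection arm against the starting pool
#'
#' Computes per-arm CPM quantiles, counts of genotypes at or above CPM
#' thresholds, and the enriched set: genotypes whose post-selection CPM
#' exceeds their pre-selection CPM by more than `enrichment_factor`. When no
#' round-0 table is available the pre-selection CPM defaults to the equimolar
#' expectation `1e6 / pool_size`.
#'
#' @param post Post-selection `genotype_counts`.
#' @param pre Optional round-0 `genotype_counts`.
#' @param thresholds CPM thresholds for abundance counts.
#' @param enrichment_factor Fold-change defining "enriched" (default 2).
#' @param pool_size Number of distinct genotypes in the starting pool; used
#'   for the equimolar expectation when `pre` is `NULL` (defaults to the
#'   number of genotypes observed post-selection).
#' @return An `enrichment_summary` list: `quantiles`, `threshold_counts`,
#'   `n_enriched`, `enriched` (genotype vector), `n_exclusive` (genotypes
#'   absent from `pre`, when `pre` is given), `pre_mode`.
#' @export
enrichment_summary <- function(post, pre = NULL, thresholds = c(1, 10, 100),
                               enrichment_factor = 2, pool_size = NULL) {
  stopifnot(inherits(post, "genotype_counts"))
  qs <- stats::quantile(post$cpm, c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1))
  counts <- vapply(thresholds, function(th) sum(post$cpm >= th), 0L)
  names(counts) <- paste0("cpm>=", thresholds)
  if (is.null(pre)) {
    pool_size <- pool_size %||% nrow(post)
    pre_cpm <- rep(1e6 / pool_size, nrow(post))
    n_exclusive <- NA_integer_
    pre_mode <- sprintf("equimolar expectation (1e6 / %d)", pool_size)
  } else {
    idx <- match(post$genotype, pre$genotype)
    n_exclusive <- sum(is.na(idx))
    # genotypes unseen in round 0 fall back to the equimolar expectation
    fallback <- 1e6 / (pool_size %||% nrow(pre))
    pre_cpm <- ifelse(is.na(idx), fallback, pre$cpm[idx])
    pre_mode <- "round-0 table"
  }
  enriched <- post$genotype[post$cpm / pre_cpm > enrichment_factor]
  structure(list(arm_label = attr(post, "arm_label"), quantiles = qs,
                 threshold_counts = counts, n_enriched = length(enriched),
                 enriched = enriched, n_exclusive = n_exclusive,
                 pre_mode = pre_mode, enrichment_factor = enrichment_factor),
            class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("enrichment_summary [%s]: %d enriched (> %gx over %s)\n",
              x$arm_label, x$n_enriched, x$enrichment_factor, x$pre_mode))
  print(round(x$quantiles, 2))
  print(x$threshold_counts)
  invisible(x)
}

#' Most abundant genotype of a count table
#'
#' Highest read count; ties broken lexicographically by genotype.
#'
#' @param t A `genotype_counts`.
#' @return The genotype string.
#' @export
top_sequence <- function(t) {
  stopifnot(inherits(t, "genotype_counts"))
  if (nrow(t) == 0L) stop("empty count table", call. = FALSE)
  t$genotype[1L]  # table is sorted by count desc, genotype asc
}

#' Write / read a merged specificity table as TSV
#'
#' @param m A `merged_specificity`.
#' @param path TSV path.
#' @return `write_merged_table`: invisibly `path`; `read_merged_table`: a
#'   `merged_specificity` (exclusive-genotype attributes are not round-tripped).
#' @export
write_merged_table <- function(m, path) {
  stopifnot(inherits(m, "merged_specificity"))
  hdr <- sprintf("# arm_a=%s arm_b=%s score=log2(cpm_a/cpm_b)",
                 attr(m, "arm_a_label"), attr(m, "arm_b_label"))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_merged_table
#' @export
read_merged_table <- function(path) {
  first <- readLines(path, n = 1L)
  arm_a <- sub("^# arm_a=(\\S+).*$", "\\1", first)
  arm_b <- sub("^.* arm_b=(\\S+).*$", "\\1", first)
  m <- data.table::fread(path, sep = "\t", skip = 1L)
  structure(m, class = c("merged_specificity", class(m)),
            arm_a_label = arm_a, arm_b_label = arm_b, n_common = nrow(m),
            a_only = data.table::data.table(), b_only = data.table::data.table())
}
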