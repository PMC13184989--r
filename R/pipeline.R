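# Pipeline orchestration: one structured config, staged execution
# (simulate -> process-reads -> enrich -> mutscan -> train -> report),
# derived per-stage seeds and a hashed manifest.

#' Build a run configuration
#'
#' All pipeline defaults in one validated object. Either a simulation
#' `scenario` or two arm input files (FASTA/FASTQ) must be supplied.
#'
#' @param out_dir Output run directory.
#' @param seed Global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param scenario Registered benchmark scenario, or `NULL` when arm inputs
#'   are given.
#' @param arm_inputs Named list `list(a = path, b = path)` of read files, or
#'   `NULL` to simulate.
#' @param arm_labels Labels for the two arms.
#' @param n_distinct,depth,concentration Simulation sizes.
#' @param max_fixed_mismatches Scaffold mismatch budget for read processing.
#' @param min_cpm,min_n Mutation-effect thresholds.
#' @param plan A [split_plan()].
#' @param network A [network_config()].
#' @param run_learning_curve Also compute the downsampling learning curve.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, scenario = "specificity-planted",
                       arm_inputs = NULL, arm_labels = c("4MUP", "diFMUP"),
                       n_distinct = 2000L, depth = 50000L, concentration = 100,
                       max_fixed_mismatches = 0L, min_cpm = 10, min_n = 10L,
                       plan = split_plan(fractions = c(1, 0.5)),
                       network = network_config(), run_learning_curve = FALSE) {
  if (is.null(scenario) && is.null(arm_inputs))
    stop("either a scenario or arm inputs must be given", call. = FALSE)
  if (!is.null(arm_inputs)) {
    stopifnot(setequal(names(arm_inputs), c("a", "b")))
    missing <- !vapply(arm_inputs, file.exists, TRUE)
    if (any(missing))
      stop("arm input(s) not found: ",
           paste(unlist(arm_inputs[missing]), collapse = ", "), call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scenario = scenario, arm_inputs = arm_inputs,
                 arm_labels = arm_labels, n_distinct = as.integer(n_distinct),
                 depth = as.integer(depth), concentration = concentration,
                 max_fixed_mismatches = as.integer(max_fixed_mismatches),
                 min_cpm = min_cpm, min_n = as.integer(min_n), plan = plan,
                 network = network, run_learning_curve = run_learning_curve),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Unspecified fields take [run_config()] defaults; `plan` and `network`
#' sub-objects map to [split_plan()] and [network_config()] arguments.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[setdiff(names(raw), c("plan", "network"))]
  if (!is.null(raw$plan)) args$plan <- do.call(split_plan, as.list(raw$plan))
  if (!is.null(raw$network))
    args$network <- do.call(network_config, as.list(raw$network))
  do.call(run_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> process-reads -> enrich -> mutscan -> train
#' -> report in order, writing every artifact plus a `manifest.json` with
#' seeds and md5 hashes into the run directory. Rerunning with the same
#' config reproduces all deterministic artifacts bit for bit.
#'
#' @param config A [run_config()] or path to a JSON config.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  spec <- aurora_bulge_spec()
  artifacts <- character(0)
  add <- function(...) artifacts <<- c(artifacts, ...)

  if (!is.null(config$scenario)) {
    fastq <- run_stage("simulate", {
      sim <- make_benchmark(config$scenario, seed = derive_seed(config$seed, "simulate"),
                            n_distinct = config$n_distinct, depth = config$depth,
                            concentration = config$concentration)
      write_truth_json(sim, out("truth.json"))
      data.table::fwrite(sim$pool, out("pool.tsv"), sep = "\t")
      write_count_table(sim$pre_counts, out("round0.tsv"))
      paths <- list()
      for (i in 1:2) {
        s <- sim$truth$substrates[i]
        paths[[c("a", "b")[i]]] <- out(paste0("reads_", s, ".fastq"))
        write_reads_fastq(sim$post_counts[[s]], spec, paths[[c("a", "b")[i]]])
      }
      add("truth.json", "pool.tsv", "round0.tsv",
          basename(unlist(paths)))
      paths
    })
  } else {
    fastq <- config$arm_inputs
  }

  tables <- run_stage("process-reads", {
    tabs <- list()
    for (arm in c("a", "b")) {
      res <- process_reads(fastq[[arm]], spec,
                           arm_label = config$arm_labels[match(arm, c("a", "b"))],
                           max_fixed_mismatches = config$max_fixed_mismatches)
      tabs[[arm]] <- res$table
      write_count_table(res$table, out(paste0("table_", arm, ".tsv")))
      write_processing_report(res$report, out(paste0("report_", arm, ".json")))
      add(paste0("table_", arm, ".tsv"), paste0("report_", arm, ".json"))
    }
    tabs
  })

  merged <- run_stage("enrich", {
    merged <- merge_common(tables$a, tables$b)
    write_merged_table(merged, out("merged.tsv"))
    summ <- lapply(tables, enrichment_summary, pool_size = config$n_distinct)
    jsonlite::write_json(lapply(summ, function(s)
      s[c("arm_label", "quantiles", "threshold_counts", "n_enriched", "pre_mode")]),
      out("enrichment.json"), auto_unbox = TRUE, digits = NA)
    add("merged.tsv", "enrichment.json")
    merged
  })

  run_stage("mutscan", {
    eff <- rank_positions_by_effect(merged, spec, min_cpm = config$min_cpm,
                                    min_n = config$min_n)
    data.table::fwrite(eff, out("effects.tsv"), sep = "\t")
    variants <- unique(c(top_sequence(tables$a), top_sequence(tables$b)))
    vs <- variant_specificity(merged, variants)
    jsonlite::write_json(vs, out("variants.json"), auto_unbox = TRUE, digits = NA)
    add("effects.tsv", "variants.json")
  })

  run_stage("train", {
    runs <- list(
      cpm = cpm_regression(merged, "a", plan = config$plan,
                           config = config$network,
                           seed = derive_seed(config$seed, "train-cpm"),
                           spec = spec),
      score = specificity_regression(merged, plan = config$plan,
                                     config = config$network,
                                     seed = derive_seed(config$seed, "train-score"),
                                     spec = spec))
    metrics <- lapply(runs, function(r)
      c(unclass(r$metrics), skew = r$skew %||% NULL))
    jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    add("metrics.json")
    for (task in names(runs)) {
      data.table::fwrite(runs[[task]]$predictions,
                         out(paste0("predictions_", task, ".tsv")), sep = "\t")
      add(paste0("predictions_", task, ".tsv"))
    }
    if (config$run_learning_curve) {
      lc <- learning_curve(merged$genotype, merged$cpm_a, plan = config$plan,
                           config = config$network,
                           seed = derive_seed(config$seed, "train-lc"), spec = spec)
      data.table::fwrite(lc, out("learning_curve.tsv"), sep = "\t")
      add("learning_curve.tsv")
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("selscape")),
    seed = config$seed, scenario = config$scenario,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       train_cpm = derive_seed(config$seed, "train-cpm"),
                       train_score = derive_seed(config$seed, "train-score")),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(out(artifacts))), artifacts)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  run_stage("report", pipeline_report(config$out_dir))
  invisible(manifest)
}

#' Summarise a completed run directory
#'
#' Reads the run's artifacts and writes `report.txt`: CPM distribution
#' summaries per arm, top sequences, the position-effect ranking and model
#' metrics. Regeneration is idempotent. An incomplete run raises an error
#' listing the missing artifacts.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Invisibly, the report lines.
#' @export
pipeline_report <- function(run_dir) {
  need <- c("table_a.tsv", "table_b.tsv", "merged.tsv", "effects.tsv",
            "metrics.json")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing artifacts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ta <- read_count_table(file.path(run_dir, "table_a.tsv"))
  tb <- read_count_table(file.path(run_dir, "table_b.tsv"))
  merged <- read_merged_table(file.path(run_dir, "merged.tsv"))
  eff <- data.table::fread(file.path(run_dir, "effects.tsv"))
  metrics <- jsonlite::read_json(file.path(run_dir, "metrics.json"),
                                 simplifyVector = TRUE)
  fmt_arm <- function(t) {
    q <- stats::quantile(t$cpm, c(0.5, 0.9, 0.99, 1))
    sprintf("arm %-8s %7d genotypes  CPM median %.2f  p90 %.2f  p99 %.2f  max %.1f  top %s",
            attr(t, "arm_label"), nrow(t), q[1], q[2], q[3], q[4], top_sequence(t))
  }
  top_eff <- unique(eff[, c("position", "effect_range", "rank")])
  top_eff <- top_eff[order(top_eff$rank), ][1:min(5, nrow(top_eff)), ]
  lines <- c(
    "== selection run report ==",
    fmt_arm(ta), fmt_arm(tb),
    sprintf("common genotypes: %d; positive-score share: %.3f",
            nrow(merged), mean(merged$score > 0)),
    "-- position-effect ranking (top) --",
    sprintf("  rank %d: position %d (effect range %.3f)",
            top_eff$rank, top_eff$position, top_eff$effect_range),
    "-- model metrics --",
    vapply(names(metrics), function(k)
      sprintf("  %-6s rho=%.3f R2=%.3f MAE=%.4g (n=%d)", k,
              metrics[[k]]$spearman_rho, metrics[[k]]$r_squared,
              metrics[[k]]$mae, metrics[[k]]$n_test), ""))
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
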