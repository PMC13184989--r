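# Merged amplicon reads -> genotype count table (orientation, scaffold match,
# variable-position extraction, CPM normalisation).

# Positions of the fixed (non-variable) scaffold bases and their expected chars.
fixed_scaffold <- function(spec) {
  pos <- setdiff(seq_len(spec$core_length), spec$variable_positions)
  list(pos = pos, chars = substring(spec$reference_core, pos, pos))
}

# Vectorised mismatch count against the fixed scaffold positions.
# Reads must have nchar == core_length; others get NA.
fixed_mismatches <- function(reads, spec) {
  fx <- fixed_scaffold(spec)
  mm <- integer(length(reads))
  ok <- nchar(reads) == spec$core_length
  mm[!ok] <- NA_integer_
  if (any(ok)) {
    r <- reads[ok]
    acc <- integer(length(r))
    for (i in seq_along(fx$pos)) {
      p <- fx$pos[i]
      acc <- acc + (substr(r, p, p) != fx$chars[i])
    }
    mm[ok] <- acc
  }
  mm
}

reverse_complement <- function(reads) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
}

#' Orient reads against the reference scaffold
#'
#' Each read is compared, at the fixed (non-variable) positions, to the
#' reference core in both its given orientation and its reverse complement;
#' the orientation with fewer mismatches wins, provided it is within
#' `max_fixed_mismatches`. Ties and over-budget reads are rejected.
#'
#' @param reads Character vector over `{A,C,G,T,N}` (already primer-clipped,
#'   core length expected).
#' @param spec A `library_spec`.
#' @param max_fixed_mismatches Mismatch budget at fixed positions (default 0).
#' @return List with `oriented` (character, `NA` where rejected) and `reason`
#'   (character, `NA` where accepted; one of `"length"`, `"orientation_tie"`,
#'   `"orientation_budget"`).
#' @export
orient_reads <- function(reads, spec, max_fixed_mismatches = 0L) {
  n <- length(reads)
  oriented <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  len_ok <- nchar(reads) == spec$core_length
  reason[!len_ok] <- "length"
  if (any(len_ok)) {
    fwd <- reads[len_ok]
    rev <- reverse_complement(fwd)
    mm_f <- fixed_mismatches(fwd, spec)
    mm_r <- fixed_mismatches(rev, spec)
    best <- pmin(mm_f, mm_r)
    over <- best > max_fixed_mismatches
    tie <- !over & (mm_f == mm_r)
    take_f <- !over & !tie & (mm_f < mm_r)
    take_r <- !over & !tie & (mm_r < mm_f)
    out <- rep(NA_character_, length(fwd))
    out[take_f] <- fwd[take_f]
    out[take_r] <- rev[take_r]
    oriented[len_ok] <- out
    rsn <- rep(NA_character_, length(fwd))
    rsn[over] <- "orientation_budget"
    rsn[tie] <- "orientation_tie"
    reason[len_ok] <- rsn
  }
  list(oriented = oriented, reason = reason)
}

#' Match oriented reads to the scaffold and extract genotypes
#'
#' Compares the fixed positions to the reference core; reads within the
#' mismatch budget and without ambiguous bases at variable positions yield
#' their 14-symbol genotype (generally, one symbol per variable position).
#'
#' @param reads Oriented reads (character vector, core length).
#' @param spec A `library_spec`.
#' @param max_fixed_mismatches Mismatch budget at fixed positions (default 0,
#'   i.e. exact scaffold match).
#' @return List with `genotype` (character, `NA` where rejected) and `reason`
#'   (`"length"`, `"fixed_mismatch"`, `"ambiguous_variable"`).
#' @export
match_and_extract <- function(reads, spec, max_fixed_mismatches = 0L) {
  n <- length(reads)
  genotype <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  len_ok <- !is.na(reads) & nchar(reads) == spec$core_length
  reason[!len_ok] <- "length"
  if (any(len_ok)) {
    r <- reads[len_ok]
    mm <- fixed_mismatches(r, spec)
    g <- extract_variable_positions(r, spec)
    amb <- grepl("[^ACGT]", g)
    pass <- (mm <= max_fixed_mismatches) & !amb
    gg <- rep(NA_character_, length(r))
    gg[pass] <- g[pass]
    genotype[len_ok] <- gg
    rsn <- rep(NA_character_, length(r))
    rsn[amb] <- "ambiguous_variable"
    rsn[!amb & mm > max_fixed_mismatches] <- "fixed_mismatch"
    reason[len_ok] <- rsn
  }
  list(genotype = genotype, reason = reason)
}

# Mismatches between equal-length strings x (vector) and a scalar pattern.
pattern_mismatches <- function(x, pattern) {
  acc <- integer(length(x))
  for (i in seq_len(nchar(pattern)))
    acc <- acc + (substr(x, i, i) != substr(pattern, i, i))
  acc
}

#' Clip anchored 5' and 3' primers from reads
#'
#' Primers are matched anchored at the read ends within a per-primer mismatch
#' budget (no indels); the insert between them is returned. Reads whose ends
#' do not match are rejected.
#'
#' @param reads Character vector.
#' @param fwd_primer,rev_primer Non-empty primer strings as they appear on the
#'   read (5' prefix and 3' suffix).
#' @param max_mismatches Mismatch budget per primer (default 0).
#' @return List with `insert` (character, `NA` where rejected) and `reason`
#'   (`"too_short"`, `"fwd_primer"`, `"rev_primer"`).
#' @export
clip_primers <- function(reads, fwd_primer, rev_primer, max_mismatches = 0L) {
  stopifnot(nzchar(fwd_primer), nzchar(rev_primer))
  lf <- nchar(fwd_primer); lr <- nchar(rev_primer)
  n <- length(reads)
  insert <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  long_enough <- nchar(reads) >= lf + lr
  reason[!long_enough] <- "too_short"
  if (any(long_enough)) {
    r <- reads[long_enough]
    mm_f <- pattern_mismatches(substr(r, 1L, lf), fwd_primer)
    tails <- substr(r, nchar(r) - lr + 1L, nchar(r))
    mm_r <- pattern_mismatches(tails, rev_primer)
    ok <- mm_f <= max_mismatches & mm_r <= max_mismatches
    ins <- rep(NA_character_, length(r))
    ins[ok] <- substr(r[ok], lf + 1L, nchar(r[ok]) - lr)
    rsn <- rep(NA_character_, length(r))
    rsn[mm_f > max_mismatches] <- "fwd_primer"
    rsn[mm_f <= max_mismatches & mm_r > max_mismatches] <- "rev_primer"
    insert[long_enough] <- ins
    reason[long_enough] <- rsn
  }
  list(insert = insert, reason = reason)
}

#' Build a genotype count table with CPM normalisation
#'
#' Counts unique genotypes and normalises to counts per million: a genotype's
#' read count times 1e6 divided by the total number of reads in the table.
#' Rows are ordered by count descending, ties broken lexicographically by
#' genotype, so "most abundant" queries are deterministic.
#'
#' @param genotypes Character vector (a stream of observed genotypes), or a
#'   named integer vector of pre-tallied counts via `counts`.
#' @param arm_label Label of the selection arm (e.g. `"4-MUP"`).
#' @param counts Optional: named integer vector of counts (names = genotypes);
#'   used instead of tallying `genotypes`.
#' @return A `genotype_counts` object: a `data.table` with columns `genotype`,
#'   `count`, `cpm` and attributes `arm_label`, `total_reads`.
#' @export
count_and_normalize <- function(genotypes = NULL, arm_label = "arm",
                                counts = NULL) {
  if (is.null(counts)) {
    if (is.null(genotypes) || length(genotypes) == 0L)
      stop("empty genotype stream", call. = FALSE)
    dt <- data.table::data.table(genotype = genotypes)
    dt <- dt[, list(count = .N), by = "genotype"]
  } else {
    if (length(counts) == 0L) stop("empty counts", call. = FALSE)
    dt <- data.table::data.table(genotype = names(counts),
                                 count = as.integer(counts))
    dt <- dt[dt$count > 0L, ]
    if (nrow(dt) == 0L) stop("all counts are zero", call. = FALSE)
  }
  total <- sum(dt$count)
  dt[, "cpm" := dt$count * 1e6 / total]
  data.table::setorderv(dt, c("count", "genotype"), order = c(-1L, 1L))
  structure(dt, class = c("genotype_counts", class(dt)),
            arm_label = arm_label, total_reads = total)
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype_counts [%s]: %d unique genotypes, %d reads\n",
              attr(x, "arm_label"), nrow(x), attr(x, "total_reads")))
  NextMethod()
}

#' Read merged amplicon reads and produce a genotype count table
#'
#' The full processing chain: load FASTA/FASTQ, optionally clip anchored
#' primers, unify orientation against the reference scaffold, match the fixed
#' scaffold positions, extract variable positions, count unique genotypes and
#' normalise to CPM. Every rejected read is tallied by reason.
#'
#' @param input Path to a FASTA or FASTQ file, or a character vector of reads.
#' @param spec A `library_spec`.
#' @param arm_label Selection-arm label stored in the output table.
#' @param max_fixed_mismatches Scaffold mismatch budget (default 0).
#' @param fwd_primer,rev_primer Optional anchored primers to clip first.
#' @param primer_mismatches Mismatch budget per primer.
#' @param min_mean_q Optional mean Phred quality threshold (FASTQ only;
#'   default `NULL`, no quality filtering).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return A `processing_result`: list with `table` (a `genotype_counts`) and
#'   `report` (a `processing_report` of counters).
#' @export
process_reads <- function(input, spec, arm_label = "arm",
                          max_fixed_mismatches = 0L,
                          fwd_primer = NULL, rev_primer = NULL,
                          primer_mismatches = 0L,
                          min_mean_q = NULL, format = "auto") {
  mean_q <- NULL
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    if (format == "auto")
      format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", input)) "fastq" else "fasta"
    if (format == "fastq" && !is.null(min_mean_q)) {
      qs <- Biostrings::readQualityScaledDNAStringSet(input)
      reads <- as.character(qs)
      mean_q <- vapply(as(Biostrings::quality(qs), "IntegerList"), mean, 0)
    } else {
      reads <- as.character(Biostrings::readDNAStringSet(input, format = format))
    }
  } else {
    reads <- as.character(input)
  }
  n_input <- length(reads)
  reject <- c(quality = 0L, too_short = 0L, fwd_primer = 0L, rev_primer = 0L,
              length = 0L, orientation_tie = 0L, orientation_budget = 0L,
              fixed_mismatch = 0L, ambiguous_variable = 0L)
  tally <- function(reasons) {
    tb <- table(reasons)
    reject[names(tb)] <<- reject[names(tb)] + as.integer(tb)
  }
  if (!is.null(mean_q)) {
    drop <- mean_q < min_mean_q
    reject["quality"] <- sum(drop)
    reads <- reads[!drop]
  }
  if (!is.null(fwd_primer)) {
    cl <- clip_primers(reads, fwd_primer, rev_primer, primer_mismatches)
    tally(cl$reason[!is.na(cl$reason)])
    reads <- cl$insert[!is.na(cl$insert)]
  }
  n_primer_pass <- length(reads)
  ori <- orient_reads(reads, spec, max_fixed_mismatches)
  tally(ori$reason[!is.na(ori$reason)])
  reads <- ori$oriented[!is.na(ori$oriented)]
  n_oriented <- length(reads)
  mx <- match_and_extract(reads, spec, max_fixed_mismatches)
  tally(mx$reason[!is.na(mx$reason)])
  genotypes <- mx$genotype[!is.na(mx$genotype)]
  if (length(genotypes) == 0L)
    stop("no reads passed processing (", n_input, " input reads)", call. = FALSE)
  tab <- count_and_normalize(genotypes, arm_label = arm_label)
  report <- structure(list(
    n_input = n_input,
    n_primer_pass = n_primer_pass,
    n_oriented = n_oriented,
    n_scaffold_pass = length(genotypes),
    n_rejected_by_reason = reject[reject > 0L]
  ), class = "processing_report")
  structure(list(table = tab, report = report), class = "processing_result")
}

#' @export
print.processing_report <- function(x, ...) {
  cat(sprintf("processing_report: %d in, %d oriented, %d pass\n",
              x$n_input, x$n_oriented, x$n_scaffold_pass))
  if (length(x$n_rejected_by_reason))
    for (r in names(x$n_rejected_by_reason))
      cat(sprintf("  rejected %-20s %d\n", r, x$n_rejected_by_reason[[r]]))
  invisible(x)
}

#' Write / read a genotype count table as TSV
#'
#' Columns `genotype`, `count`, `cpm`; a `# arm=<label> total_reads=<n>`
#' comment line precedes the header.
#'
#' @param x A `genotype_counts`.
#' @param path Output TSV path.
#' @return `write_count_table`: invisibly, `path`; `read_count_table`: a
#'   `genotype_counts`.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "genotype_counts"))
  hdr <- sprintf("# arm=%s total_reads=%d", attr(x, "arm_label"),
                 attr(x, "total_reads"))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(x)[, c("genotype", "count", "cpm")],
                     path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  arm <- sub("^# arm=(\\S+).*$", "\\1", first)
  dt <- data.table::fread(path, sep = "\t", skip = 1L)
  count_and_normalize(counts = stats::setNames(dt$count, dt$genotype),
                      arm_label = arm)
}

#' Write a processing report as a JSON sidecar
#'
#' @param report A `processing_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_processing_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
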