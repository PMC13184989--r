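# Degenerate library model: IUPAC templates with paired-position constraints.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC degeneracy code to its base set
#'
#' @param code Single IUPAC symbol (e.g. `"N"`, `"R"`, `"A"`).
#' @return Character vector of bases in `{A,C,G,T}`.
#' @examples
#' expand_iupac("N")
#' expand_iupac("R")
#' @export
expand_iupac <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- toupper(code)
  bases <- IUPAC_MAP[[code]]
  if (is.null(bases)) stop("invalid IUPAC code: '", code, "'", call. = FALSE)
  bases
}

#' Define a paired-position constraint
#'
#' Two positions jointly encoded by purine/pyrimidine degeneracy: orientation
#' `"R-Y"` means the 5' position is R = {A,G} and the 3' position is Y = {C,T};
#' `"Y-R"` is the converse. Listing both orientations models the equimolar
#' mixture of orientation sublibraries.
#'
#' @param pos5,pos3 1-based core positions, `pos5 < pos3`.
#' @param orientations Non-empty subset of `c("R-Y", "Y-R")`.
#' @return A `pair_constraint` object.
#' @export
pair_constraint <- function(pos5, pos3, orientations = c("R-Y", "Y-R")) {
  stopifnot(length(pos5) == 1L, length(pos3) == 1L)
  pos5 <- as.integer(pos5); pos3 <- as.integer(pos3)
  if (!(pos5 < pos3)) stop("pos5 must be < pos3", call. = FALSE)
  orientations <- match.arg(orientations, c("R-Y", "Y-R"), several.ok = TRUE)
  structure(list(pos5 = pos5, pos3 = pos3, orientations = orientations),
            class = "pair_constraint")
}

# All (base5, base3) duplets consistent with any allowed orientation,
# as two-character strings, e.g. "AC".
constraint_duplets <- function(con) {
  out <- character(0)
  for (ori in con$orientations) {
    sets <- strsplit(ori, "-", fixed = TRUE)[[1]]
    b5 <- expand_iupac(sets[1]); b3 <- expand_iupac(sets[2])
    out <- c(out, as.vector(outer(b5, b3, paste0)))
  }
  sort(unique(out))
}

#' Construct a degenerate library specification
#'
#' Describes a fixed core sequence with degenerate (variable) positions, some
#' of which may be jointly constrained as encoded base pairs.
#'
#' @param core_length Length of the core sequence.
#' @param variable_positions Strictly increasing 1-based positions that vary.
#' @param position_codes Named character vector mapping unconstrained variable
#'   positions (names, as integers) to IUPAC codes.
#' @param pair_constraints List of [pair_constraint()] objects; every
#'   constrained position must appear in exactly one constraint and in
#'   `variable_positions`.
#' @param reference_core String of length `core_length` over `{A,C,G,T,X}`,
#'   `X` marking the variable positions.
#' @param wildtype Optional reference genotype (metadata only).
#' @return A `library_spec` object.
#' @seealso [aurora_bulge_spec()] for the default bulge library.
#' @export
library_spec <- function(core_length, variable_positions, position_codes,
                         pair_constraints = list(), reference_core,
                         wildtype = NULL) {
  core_length <- as.integer(core_length)
  variable_positions <- as.integer(variable_positions)
  if (any(diff(variable_positions) <= 0))
    stop("variable_positions must be strictly increasing", call. = FALSE)
  if (any(variable_positions < 1L | variable_positions > core_length))
    stop("variable_positions out of [1, core_length]", call. = FALSE)

  con_pos <- unlist(lapply(pair_constraints, function(x) c(x$pos5, x$pos3)))
  if (anyDuplicated(con_pos))
    stop("a position appears in more than one pair constraint", call. = FALSE)
  if (length(con_pos) && !all(con_pos %in% variable_positions))
    stop("pair-constrained positions must be variable positions", call. = FALSE)

  coded <- as.integer(names(position_codes))
  free_pos <- setdiff(variable_positions, con_pos)
  if (!setequal(coded, free_pos))
    stop("position_codes must cover exactly the unconstrained variable positions",
         call. = FALSE)
  for (code in position_codes) expand_iupac(code)  # validates

  if (nchar(reference_core) != core_length)
    stop("reference_core length != core_length", call. = FALSE)
  core_chars <- strsplit(reference_core, "")[[1]]
  if (!all(core_chars %in% c("A", "C", "G", "T", "X")))
    stop("reference_core must be over {A,C,G,T,X}", call. = FALSE)
  if (!identical(which(core_chars == "X"), variable_positions))
    stop("X positions in reference_core must equal variable_positions", call. = FALSE)

  spec <- structure(list(
    core_length = core_length,
    variable_positions = variable_positions,
    position_codes = position_codes[order(coded)],
    pair_constraints = pair_constraints,
    reference_core = reference_core,
    wildtype = wildtype
  ), class = "library_spec")
  if (!is.null(wildtype)) validate_genotypes(wildtype, spec)
  spec
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("library_spec: %d-nt core, %d variable positions, %d pair constraint(s)\n",
              x$core_length, length(x$variable_positions), length(x$pair_constraints)))
  cat("  positions:", paste(x$variable_positions, collapse = ", "), "\n")
  cat(sprintf("  encoded genotypes: %s\n", format(library_size(x), big.mark = ",")))
  invisible(x)
}

#' The default bulge library specification
#'
#' A 47-nt catalytic core with 14 variable positions: ten fully randomised (N)
#' positions (20-23, 33-37, 41 — nine bulge positions plus the bulged G at 41)
#' and two base pairs (16-42 and 17-40) encoded by R-Y or Y-R degeneracy.
#'
#' The true 47-nt core sequence is not redistributed here; the default
#' `reference_core` is a synthetic placeholder scaffold (all combinatorial
#' results are independent of the fixed bases). The bundled wild-type genotype
#' is likewise synthetic except at positions 20 (A), 21 (T), 33 (T), 34 (C)
#' and 41 (G), which follow the characterised reference variant.
#'
#' @param reference_core Optional replacement 47-nt core (with `X` at the 14
#'   variable positions), e.g. the real sequence if available.
#' @return A `library_spec`.
#' @examples
#' spec <- aurora_bulge_spec()
#' library_size(spec)        # 67108864
#' pairing_fraction(spec)    # 0.5625
#' @export
aurora_bulge_spec <- function(reference_core = NULL) {
  if (is.null(reference_core)) {
    # synthetic placeholder scaffold; X marks positions 16,17,20-23,33-37,40-42
    reference_core <- "GGATCGTCAGTGCATXXCAXXXXTCAGCGATCXXXXXGGXXXCCGAA"
  }
  n_pos <- c(20L, 21L, 22L, 23L, 33L, 34L, 35L, 36L, 37L, 41L)
  codes <- stats::setNames(rep("N", length(n_pos)), n_pos)
  library_spec(
    core_length = 47L,
    variable_positions = c(16L, 17L, 20L, 21L, 22L, 23L, 33L, 34L, 35L, 36L,
                           37L, 40L, 41L, 42L),
    position_codes = codes,
    pair_constraints = list(pair_constraint(16L, 42L), pair_constraint(17L, 40L)),
    reference_core = reference_core,
    wildtype = "GAATCATCAGTTGC"
  )
}

#' Base-pairing rule used when asking whether constrained duplets pair
#'
#' Defaults to the canonical Watson-Crick pairs plus G-T/T-G wobbles.
#'
#' @param paired_duplets Character vector of two-letter duplets (5' base then
#'   3' base) counted as paired.
#' @return A `pairing_rule` object.
#' @export
pairing_rule <- function(paired_duplets = c("AT", "TA", "CG", "GC", "GT", "TG")) {
  stopifnot(all(nchar(paired_duplets) == 2L),
            all(strsplit(paste(paired_duplets, collapse = ""), "")[[1]] %in%
                  c("A", "C", "G", "T")))
  structure(list(paired_duplets = sort(unique(paired_duplets))),
            class = "pairing_rule")
}

# Per-position candidate sets for unconstrained positions, named by position.
free_position_sets <- function(spec) {
  lapply(spec$position_codes, expand_iupac)
}

#' Exact number of distinct genotypes a library spec encodes
#'
#' Product of the base-set sizes of unconstrained positions times, per pair
#' constraint, the number of duplets consistent with any allowed orientation.
#' Exact as long as the count is below 2^53.
#'
#' @param spec A `library_spec`.
#' @return The count, as a double.
#' @export
library_size <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  sz <- prod(vapply(free_position_sets(spec), length, 1L))
  for (con in spec$pair_constraints) sz <- sz * length(constraint_duplets(con))
  sz
}

#' Fraction of encoded genotypes in which every constrained duplet pairs
#'
#' @param spec A `library_spec`.
#' @param rule A [pairing_rule()].
#' @return Fraction in `[0, 1]`. Unconstrained positions do not contribute.
#' @export
pairing_fraction <- function(spec, rule = pairing_rule()) {
  stopifnot(inherits(spec, "library_spec"), inherits(rule, "pairing_rule"))
  frac <- 1
  for (con in spec$pair_constraints) {
    dup <- constraint_duplets(con)
    frac <- frac * mean(dup %in% rule$paired_duplets)
  }
  frac
}

# Map core positions to indices within the genotype string.
genotype_index <- function(spec, positions) {
  idx <- match(as.integer(positions), spec$variable_positions)
  if (anyNA(idx)) stop("position(s) not variable: ",
                       paste(positions[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Deterministically enumerate the genotypes a spec encodes
#'
#' Genotypes are returned in lexicographic order of the genotype string. The
#' full space is materialised before sorting, so enumeration refuses to run
#' when `library_size(spec)` exceeds `safety_bound`; use [sample_genotypes()]
#' for larger spaces.
#'
#' @param spec A `library_spec`.
#' @param limit Optional truncation: return only the first `limit` genotypes.
#' @param safety_bound Refuse enumeration above this many genotypes.
#' @return Character vector of genotype strings.
#' @export
enumerate_genotypes <- function(spec, limit = NULL, safety_bound = 1e7) {
  stopifnot(inherits(spec, "library_spec"))
  if (!is.null(limit) && limit == 0) return(character(0))
  n <- library_size(spec)
  if (n > safety_bound)
    stop(sprintf("space of %.3g genotypes exceeds safety bound %.3g; use sample_genotypes()",
                 n, safety_bound), call. = FALSE)
  k <- length(spec$variable_positions)
  if (k == 0L) {
    out <- ""
  } else {
    # one block per unconstrained position, one joint block per constraint
    blocks <- list(); block_pos <- list()
    for (p in names(spec$position_codes)) {
      blocks[[length(blocks) + 1L]] <- expand_iupac(spec$position_codes[[p]])
      block_pos[[length(block_pos) + 1L]] <- as.integer(p)
    }
    for (con in spec$pair_constraints) {
      blocks[[length(blocks) + 1L]] <- constraint_duplets(con)
      block_pos[[length(block_pos) + 1L]] <- c(con$pos5, con$pos3)
    }
    grid <- expand.grid(blocks, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    sym <- matrix("", nrow = nrow(grid), ncol = k)
    for (b in seq_along(blocks)) {
      idx <- genotype_index(spec, block_pos[[b]])
      if (length(idx) == 1L) {
        sym[, idx] <- grid[[b]]
      } else {
        sym[, idx[1]] <- substr(grid[[b]], 1L, 1L)
        sym[, idx[2]] <- substr(grid[[b]], 2L, 2L)
      }
    }
    out <- sort(do.call(paste0, as.data.frame(sym, stringsAsFactors = FALSE)))
  }
  if (!is.null(limit)) out <- utils::head(out, limit)
  out
}

#' Sample genotypes i.i.d. uniformly over the encoded space
#'
#' @param spec A `library_spec`.
#' @param n Number of draws (with replacement).
#' @param seed Integer seed; the draw is reproducible.
#' @return Character vector of `n` genotype strings.
#' @export
sample_genotypes <- function(spec, n, seed) {
  stopifnot(inherits(spec, "library_spec"), n >= 0)
  if (n == 0) return(character(0))
  set.seed(seed)
  k <- length(spec$variable_positions)
  sym <- matrix("", nrow = n, ncol = k)
  for (p in names(spec$position_codes)) {
    bases <- expand_iupac(spec$position_codes[[p]])
    sym[, genotype_index(spec, as.integer(p))] <-
      bases[sample.int(length(bases), n, replace = TRUE)]
  }
  for (con in spec$pair_constraints) {
    dup <- constraint_duplets(con)
    pick <- dup[sample.int(length(dup), n, replace = TRUE)]
    idx <- genotype_index(spec, c(con$pos5, con$pos3))
    sym[, idx[1]] <- substr(pick, 1L, 1L)
    sym[, idx[2]] <- substr(pick, 2L, 2L)
  }
  do.call(paste0, as.data.frame(sym, stringsAsFactors = FALSE))
}

#' Validate genotype strings against a spec
#'
#' Checks length and alphabet only: count tables may legitimately contain
#' genotypes outside the encoded (constraint-consistent) space, e.g. from
#' sequencing errors.
#'
#' @param genotypes Character vector.
#' @param spec A `library_spec`.
#' @return Invisibly, `genotypes`.
#' @export
validate_genotypes <- function(genotypes, spec) {
  k <- length(spec$variable_positions)
  if (any(nchar(genotypes) != k))
    stop("genotype length must be ", k, call. = FALSE)
  if (any(grepl("[^ACGT]", genotypes)))
    stop("genotypes must be over {A,C,G,T}", call. = FALSE)
  invisible(genotypes)
}

#' Embed genotypes into the reference core
#'
#' Replaces the `X` positions of the spec's reference core with each
#' genotype's symbols; inverse of [extract_variable_positions()].
#'
#' @param genotypes Character vector of genotype strings.
#' @param spec A `library_spec`.
#' @return Character vector of full-length core sequences.
#' @export
embed_in_core <- function(genotypes, spec) {
  stopifnot(inherits(spec, "library_spec"))
  validate_genotypes(genotypes, spec)
  cores <- rep(spec$reference_core, length(genotypes))
  for (i in seq_along(spec$variable_positions)) {
    p <- spec$variable_positions[i]
    substr(cores, p, p) <- substr(genotypes, i, i)
  }
  cores
}

#' Extract the variable positions from full-length core sequences
#'
#' @param seqs Character vector of sequences at least `core_length` long.
#' @param spec A `library_spec`.
#' @return Character vector of genotype strings.
#' @export
extract_variable_positions <- function(seqs, spec) {
  stopifnot(inherits(spec, "library_spec"))
  if (any(nchar(seqs) < spec$core_length))
    stop("sequences shorter than core_length", call. = FALSE)
  cols <- lapply(spec$variable_positions, function(p) substr(seqs, p, p))
  do.call(paste0, cols)
}

#' Decompose a spec into its single-orientation sublibraries
#'
#' One sub-spec per combination of orientations across pair constraints (four
#' for the default bulge library, matching its four synthesised
#' oligonucleotide pools). The sublibraries partition the encoded space.
#'
#' @param spec A `library_spec`.
#' @return Named list of `library_spec`s; names like `"R-Y/Y-R"`.
#' @export
orientation_sublibraries <- function(spec) {
  stopifnot(inherits(spec, "library_spec"), length(spec$pair_constraints) > 0L)
  oris <- lapply(spec$pair_constraints, function(con) con$orientations)
  combos <- expand.grid(oris, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    cons <- spec$pair_constraints
    for (j in seq_along(cons))
      cons[[j]] <- pair_constraint(cons[[j]]$pos5, cons[[j]]$pos3,
                                   orientations = combos[r, j])
    sub <- spec
    sub$pair_constraints <- cons
    out[[paste(unlist(combos[r, ]), collapse = "/")]] <- sub
  }
  out
}

#' Write genotypes embedded in the reference core to FASTA
#'
#' @param genotypes Character vector of genotype strings.
#' @param spec A `library_spec`.
#' @param path Output FASTA path.
#' @param names Optional record names (default `g1..gn`).
#' @return Invisibly, `path`.
#' @export
write_genotypes_fasta <- function(genotypes, spec, path, names = NULL) {
  seqs <- embed_in_core(genotypes, spec)
  if (is.null(names)) names <- paste0("g", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(stats::setNames(seqs, names))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
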