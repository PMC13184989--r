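test_that("IUPAC codes expand to their exact base sets", {
  expect_setequal(expand_iupac("N"), c("A", "C", "G", "T"))
  expect_setequal(expand_iupac("R"), c("A", "G"))
  expect_setequal(expand_iupac("Y"), c("C", "T"))
  expect_identical(expand_iupac("A"), "A")
  expect_identical(expand_iupac("n"), expand_iupac("N"))
  expect_error(expand_iupac("Z"), "invalid IUPAC")
})

test_that("library_size is exact on the default bulge spec and degenerate specs", {
  spec <- aurora_bulge_spec()
  expect_identical(library_size(spec), 4^10 * 8 * 8)
  expect_identical(library_size(spec), 67108864)

  none <- library_spec(4L, integer(0), stats::setNames(character(0), integer(0)),
                       reference_core = "ACGT")
  expect_identical(library_size(none), 1)

  two_n <- library_spec(4L, c(1L, 3L), c(`1` = "N", `3` = "N"),
                        reference_core = "XCXT")
  expect_identical(library_size(two_n), 16)
})

test_that("pairing_fraction matches the encoded-duplet arithmetic", {
  expect_equal(pairing_fraction(aurora_bulge_spec()), 0.5625)
  # single pair restricted to R-Y: of {A,G} x {C,T}, AT / GC / GT pair, AC not
  ry <- library_spec(4L, c(1L, 4L), stats::setNames(character(0), integer(0)),
                     pair_constraints = list(pair_constraint(1L, 4L, "R-Y")),
                     reference_core = "XCGX")
  expect_equal(pairing_fraction(ry), 0.75)
  # no constrained positions at all: trivially 1
  gc_fixed <- library_spec(4L, c(1L, 4L), c(`1` = "G", `4` = "C"),
                           reference_core = "XCGX")
  expect_equal(pairing_fraction(gc_fixed), 1.0)
})

test_that("library_size and pairing_fraction agree with exhaustive enumeration", {
  rule <- pairing_rule()
  specs <- list(
    tiny_spec(),
    library_spec(6L, c(1L, 2L, 5L, 6L), c(`2` = "N", `5` = "Y"),
                 pair_constraints = list(pair_constraint(1L, 6L, "Y-R")),
                 reference_core = "XXCGXX"),
    library_spec(5L, c(1L, 3L, 5L), c(`3` = "B"),
                 pair_constraints = list(pair_constraint(1L, 5L)),
                 reference_core = "XAXAX"))
  for (spec in specs) {
    ref <- enumerate_oracle(spec)
    expect_identical(length(ref), as.integer(library_size(spec)))
    expect_identical(enumerate_genotypes(spec), ref)
    paired <- vapply(ref, function(g) {
      all(vapply(spec$pair_constraints, function(con) {
        i5 <- match(con$pos5, spec$variable_positions)
        i3 <- match(con$pos3, spec$variable_positions)
        paste0(substr(g, i5, i5), substr(g, i3, i3)) %in% rule$paired_duplets
      }, TRUE))
    }, TRUE)
    expect_equal(pairing_fraction(spec, rule), mean(paired))
  }
})

test_that("enumeration handles limits, safety bound, and trivial specs", {
  one_n <- library_spec(2L, 1L, c(`1` = "N"), reference_core = "XA")
  expect_identical(enumerate_genotypes(one_n), c("A", "C", "G", "T"))
  expect_identical(enumerate_genotypes(one_n, limit = 0), character(0))
  expect_identical(enumerate_genotypes(one_n, limit = 2), c("A", "C"))
  expect_error(enumerate_genotypes(aurora_bulge_spec()), "safety bound")
})

test_that("orientation sublibraries are disjoint and partition the space", {
  spec <- aurora_bulge_spec()
  subs <- orientation_sublibraries(spec)
  expect_length(subs, 4L)
  expect_setequal(names(subs), c("R-Y/R-Y", "R-Y/Y-R", "Y-R/R-Y", "Y-R/Y-R"))
  expect_equal(sum(vapply(subs, library_size, 0)), library_size(spec))
  # disjointness, checked exhaustively on the reduced spec
  tiny_subs <- orientation_sublibraries(tiny_spec())
  sets <- lapply(tiny_subs, enumerate_genotypes)
  expect_equal(sum(lengths(sets)), library_size(tiny_spec()))
  expect_identical(anyDuplicated(unlist(sets)), 0L)
})

test_that("sample_genotypes is seeded and uniform over the encoded space", {
  spec <- aurora_bulge_spec()
  expect_identical(sample_genotypes(spec, 0, seed = 1), character(0))
  g1 <- sample_genotypes(spec, 200, seed = 42)
  g2 <- sample_genotypes(spec, 200, seed = 42)
  expect_identical(g1, g2)
  expect_true(all(nchar(g1) == 14L))

  # chi-square of per-position base frequencies vs the encoded expectation
  n <- 1e5
  g <- sample_genotypes(spec, n, seed = 7)
  pvals <- c()
  for (p in as.integer(names(spec$position_codes))) {
    i <- match(p, spec$variable_positions)
    obs <- table(factor(substr(g, i, i), levels = c("A", "C", "G", "T")))
    pvals <- c(pvals, stats::chisq.test(obs)$p.value)
  }
  for (con in spec$pair_constraints) {
    i5 <- match(con$pos5, spec$variable_positions)
    i3 <- match(con$pos3, spec$variable_positions)
    dup <- paste0(substr(g, i5, i5), substr(g, i3, i3))
    obs <- table(factor(dup, levels = selscape:::constraint_duplets(con)))
    pvals <- c(pvals, stats::chisq.test(obs)$p.value)
  }
  expect_gt(min(pvals), 0.001)
})

test_that("embed_in_core and extract_variable_positions round-trip", {
  spec <- aurora_bulge_spec()
  g <- sample_genotypes(spec, 25, seed = 3)
  expect_identical(extract_variable_positions(embed_in_core(g, spec), spec), g)
  # embedding the wild type reproduces the reference core with X filled in
  wt_core <- embed_in_core(spec$wildtype, spec)
  expect_identical(nchar(wt_core), 47L)
  expect_false(grepl("X", wt_core))
  expect_identical(extract_variable_positions(wt_core, spec), spec$wildtype)
  # spec with no variable positions embeds to the bare reference core
  none <- library_spec(4L, integer(0), stats::setNames(character(0), integer(0)),
                       reference_core = "ACGT")
  expect_identical(embed_in_core("", none), "ACGT")
  expect_error(embed_in_core("ACG", spec), "length")
})

test_that("spec validation rejects malformed inputs", {
  expect_error(library_spec(4L, c(3L, 1L), c(`1` = "N", `3` = "N"),
                            reference_core = "XCXT"), "increasing")
  expect_error(library_spec(4L, c(1L, 3L), c(`1` = "N", `3` = "Q"),
                            reference_core = "XCXT"), "invalid IUPAC")
  expect_error(library_spec(4L, c(1L, 3L), c(`1` = "N", `3` = "N"),
                            reference_core = "XCTX"), "X positions")
  expect_error(pair_constraint(5L, 2L), "pos5")
  expect_error(pair_constraint(1L, 2L, character(0)))
})
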