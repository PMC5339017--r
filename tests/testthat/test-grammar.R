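test_that("spacer records validate name, alphabet and length", {
  sp <- spacer_record("s1", "ggtcgacctcgagtcagtca")
  expect_equal(sp$sequence, "GGUCGACCUCGAGUCAGUCA")
  expect_error(spacer_record("", "GGUCGACCUCGAGUCAGUCA"), "non-empty")
  expect_error(spacer_record("s", strrep("A", 21)), "\\[10, 20\\]")
  expect_error(spacer_record("s", strrep("A", 9)), "\\[10, 20\\]")
})

test_that("back-fold construction follows the coverage and bulge rules", {
  g20 <- spacer_record("g", strrep("G", 20))
  expect_equal(build_backfold(g20, 0L), strrep("C", 20))
  expect_equal(build_backfold(g20, 5L), strrep("C", 15))
  expect_equal(build_backfold(g20, 20L), "")
  expect_error(build_backfold(g20, 21L), "outside")
  expect_error(build_backfold(g20, -1L), "outside")
  # spacer-strand bulge: back-fold skips the bulged nucleotides
  sp <- fixture_spacer()
  bf <- build_backfold(sp, 0L, list(bulge_element(6L, 2L, "spacer")))
  expect_equal(nchar(bf), 18L)
  # re-align the back-fold to the spacer under the bulge map: every designed
  # pair must be Watson-Crick
  cons <- assemble_sbh(sp, cleaving_units()$basic_loop,
                       bulge_pattern = list(bulge_element(6L, 2L, "spacer")))
  expect_true(validate_construct(cons))
  expect_equal(stem_pair_count(cons), 18L)
  # backfold-strand bulge inserts extra nucleotides instead
  bf2 <- build_backfold(sp, 0L, list(bulge_element(6L, 2L, "backfold")))
  expect_equal(nchar(bf2), 22L)
  expect_error(build_backfold(sp, 0L, list(bulge_element(25L, 2L, "spacer"))),
               "beyond")
})

test_that("assembly produces consistent regions and degenerate cases", {
  sp <- fixture_spacer()
  cons <- assemble_sbh(sp, cleaving_units()$basic_loop)
  expect_equal(nchar(cons$full_sequence), 44L)  # 20 + 4 + 20
  expect_equal(region_sequence(cons, "spacer"), sp$sequence)
  expect_equal(region_sequence(cons, "loop"), "GAAA")
  # x = len(spacer), no loop: a native guide
  native <- assemble_sbh(sp, NULL, free_count_x = 20L)
  expect_equal(native$full_sequence, sp$sequence)
  # with scaffold appended
  sc <- assemble_sbh(sp, cleaving_units()$basic_loop, include_scaffold = TRUE)
  expect_equal(region_sequence(sc, "scaffold"), sgrna_scaffold("tracr"))
  expect_true(validate_construct(sc))
})

test_that("region slices and length law hold over random constructs", {
  set.seed(7)
  for (i in 1:50) {
    sp <- synth_spacers(1, gc_target = runif(1, 0.3, 0.7))[[1]]
    # the default two-bulge pattern needs at least 16 covered nucleotides
    pat <- if (i %% 2 == 0) default_bulge_pattern() else list()
    x <- if (length(pat)) sample(0:4, 1) else sample(0:10, 1)
    cons <- assemble_sbh(sp, cleaving_units()$basic_loop, free_count_x = x,
                         bulge_pattern = pat)
    expect_true(validate_construct(cons))
    expect_equal(region_sequence(cons, "spacer"), sp$sequence)
    # length law: |guide| = (L - x - skipped + inserted) + |loop| + L
    skipped <- sum(vapply(pat, function(b)
      if (b$strand == "spacer") b$length else 0L, integer(1)))
    inserted <- sum(vapply(pat, function(b)
      if (b$strand == "backfold") b$length else 0L, integer(1)))
    expect_equal(nchar(cons$full_sequence),
                 (20L - x - skipped + inserted) + 4L + 20L)
    # round-trip: reassembling region slices reproduces the guide
    parts <- vapply(names(cons$regions),
                    function(r) region_sequence(cons, r), character(1))
    expect_identical(paste(parts, collapse = ""), cons$full_sequence)
  }
})

test_that("default 0B pattern gives the 16-pair bulged stem", {
  cons <- assemble_sbh(fixture_spacer(), cleaving_units()$basic_loop,
                       bulge_pattern = default_bulge_pattern())
  expect_equal(stem_pair_count(cons), 16L)
  expect_equal(nchar(cons$backfold), 16L)
})

test_that("graft geometries shorten the stem monotonically", {
  cons <- assemble_sbh(fixture_spacer(), cleaving_units()$basic_loop,
                       bulge_pattern = default_bulge_pattern())
  unit <- cleaving_units()$csy4
  full <- graft_unit(cons, csy4_as("apex"))
  med <- graft_unit(cons, csy4_as("distal_bulge"))
  nano <- graft_unit(cons, csy4_as("proximal_bulge"))
  # apex graft: length bookkeeping (old loop out, unit in)
  expect_equal(nchar(full$full_sequence),
               nchar(cons$full_sequence) - 4L + nchar(unit$sequence))
  expect_gt(stem_pair_count(full), stem_pair_count(med))
  expect_gt(stem_pair_count(med), stem_pair_count(nano))
  for (g in list(full, med, nano)) expect_true(validate_construct(g))
  # bulge grafts on a bulge-free construct are a configuration error
  plain <- assemble_sbh(fixture_spacer(), cleaving_units()$basic_loop)
  expect_error(graft_unit(plain, csy4_as("distal_bulge")), "bulged")
})

test_that("residual 5' nucleotide accounting", {
  cons <- assemble_sbh(fixture_spacer(), cleaving_units()$basic_loop,
                       bulge_pattern = default_bulge_pattern())
  # cut exactly at the unit/spacer junction leaves nothing
  flush <- cleaving_unit("flush", "GAAA", cut_offset = 4L)
  expect_equal(residual_5p_nt(graft_unit(cons, flush)), 0L)
  # cut at unit start with a full-length spacer: the whole unit tail remains
  head_cut <- cleaving_unit("headcut", "GAAAGAAA", cut_offset = 0L)
  expect_equal(residual_5p_nt(graft_unit(cons, head_cut)), 8L)
  # geometry ordering for one spacer and one unit: full > medium > nano
  r_full <- residual_5p_nt(graft_unit(cons, csy4_as("apex")))
  r_med <- residual_5p_nt(graft_unit(cons, csy4_as("distal_bulge")))
  r_nano <- residual_5p_nt(graft_unit(cons, csy4_as("proximal_bulge")))
  expect_true(r_full > r_med && r_med > r_nano)
  # non-cleavable loop
  expect_error(residual_5p_nt(cons), "not cleavable|cut_offset")
})
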