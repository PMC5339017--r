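test_that("MFE prediction handles unstructured and hairpin sequences", {
  r <- predict_mfe("AAAAAAA")
  expect_equal(r$structure, ".......")
  expect_equal(r$mfe, 0)
  # engine-derived frozen fixture for a canonical GC hairpin
  h <- predict_mfe("GGGGAAAACCCC")
  expect_equal(h$structure, "((((....))))")
  expect_equal(h$mfe, -4.3, tolerance = 1e-9)
  expect_lt(h$mfe, 0)
})

test_that("MFE matches exhaustive enumeration on small random sequences", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_rna(sample(10:13, 1))
    pred <- predict_mfe(s)
    expect_equal(pred$mfe, oracle_mfe(s), tolerance = 1e-9, label = s)
    # the traced structure must evaluate to the reported energy
    if (pred$mfe < 0) {
      pt <- sbhdesign:::.pair_table(pred$structure)
      expect_equal(oracle_energy(s, pt), pred$mfe, tolerance = 1e-9, label = s)
    }
  }
  # GU-wobble-rich cases exercise the wobble rows of the stack table
  for (s in c("GGGUGAAAGUCCC", "UGUGAAAACACA", "GUGUGAAAACACAC")) {
    expect_equal(predict_mfe(s)$mfe, oracle_mfe(s), tolerance = 1e-9, label = s)
  }
})

test_that("pair probabilities match the Boltzmann ensemble on small cases", {
  set.seed(41)
  seqs <- c("GGGAAAACCC", "GCGCAAAAGCGC", replicate(6, random_rna(11)))
  for (s in seqs) {
    P <- pair_probabilities(s)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(as.matrix(P)), oracle_pair_probs(s), tolerance = 1e-8,
                 label = s)
  }
})

test_that("a bulge destabilizes a perfect duplex hairpin", {
  stem <- "GCGGAUCGACUGCGUACGAC"
  perfect <- paste0(stem, "GAAA", revcomp_rna(stem))
  bulged <- paste0(substr(stem, 1, 10), substr(stem, 13, 20), "GAAA",
                   revcomp_rna(stem))
  expect_lt(predict_mfe(perfect)$mfe, predict_mfe(bulged)$mfe)
})

test_that("expected-fold construction follows the grammar", {
  sp <- fixture_spacer()
  plain <- assemble_sbh(sp, cleaving_units()$basic_loop)
  tg <- target_structure(plain)
  expect_equal(tg$structure,
               paste0(strrep("(", 20), "....", strrep(")", 20)))
  expect_true(all(tg$constrained_mask))
  # bulged stem: 16 designed pairs; bulged spacer positions are dots
  bulged <- assemble_sbh(sp, cleaving_units()$basic_loop,
                         bulge_pattern = default_bulge_pattern())
  tb <- target_structure(bulged)
  ch <- strsplit(tb$structure, "")[[1]]
  expect_equal(sum(ch == "("), 16L)
  expect_equal(sum(ch == ")"), 16L)
  sp_region <- seq.int(bulged$regions$spacer[1] + 1L, bulged$regions$spacer[2])
  expect_equal(sum(ch[sp_region] == "."), 4L)
  # scaffold positions are unconstrained
  sc <- assemble_sbh(sp, cleaving_units()$basic_loop, include_scaffold = TRUE)
  tsc <- target_structure(sc)
  scaff <- seq.int(sc$regions$scaffold[1] + 1L, sc$regions$scaffold[2])
  expect_false(any(tsc$constrained_mask[scaff]))
  expect_true(all(tsc$constrained_mask[-scaff]))
  # free spacer nucleotides are unconstrained-state dots
  x5 <- target_structure(assemble_sbh(sp, cleaving_units()$basic_loop,
                                      free_count_x = 5L))
  expect_equal(substr(x5$structure, nchar(x5$structure) - 4L,
                      nchar(x5$structure)), ".....")
})

test_that("folding score measures positional agreement with the target", {
  sp <- fixture_spacer()
  cons <- assemble_sbh(sp, cleaving_units()$basic_loop)
  tg <- target_structure(cons)
  exact <- structure(list(sequence = cons$full_sequence,
                          structure = tg$structure, mfe = -1),
                     class = "fold_result")
  expect_equal(folding_score(exact, tg), 1)
  # all-unpaired prediction matches only the dot positions
  dots <- structure(list(sequence = cons$full_sequence,
                         structure = strrep(".", 44), mfe = 0),
                    class = "fold_result")
  expect_equal(folding_score(dots, tg), 4 / 44)
  # a 5-bp toy hairpin with one mispaired base pair: both partners miss
  toy_target <- structure(list(structure = "(((((.....)))))",
                               constrained_mask = rep(TRUE, 15)),
                          class = "target_structure")
  shifted <- structure(list(sequence = strrep("A", 15),
                            structure = "((((......)))).", mfe = -1),
                       class = "fold_result")
  expect_equal(folding_score(shifted, toy_target), 5 / 15)
  # dropping the outermost pair keeps the inner partners identical
  dropped <- structure(list(sequence = strrep("A", 15),
                            structure = ".((((.....)))).", mfe = -1),
                       class = "fold_result")
  expect_equal(folding_score(dropped, toy_target), 13 / 15)
  # length mismatch is a dimension error
  expect_error(folding_score(dots, toy_target), "lengths differ")
})

test_that("probability-mode scores are bounded and reward the designed fold", {
  sp <- spacer_record("gc", "GGCACUGCGGCUGGAGGUGG")
  cons <- assemble_sbh(sp, cleaving_units()$basic_loop,
                       bulge_pattern = default_bulge_pattern())
  tg <- target_structure(cons)
  pred <- predict_mfe(cons$full_sequence)
  s_mfe <- folding_score(pred, tg)
  s_prob <- folding_score(pred, tg, mode = "probability")
  expect_true(s_prob >= 0 && s_prob <= 1)
  # a strong designed stem dominates its ensemble in both modes
  expect_gt(s_prob, 0.5)
  expect_gt(s_mfe, 0.85)
})

test_that("combined score multiplies per-spacer folding scores", {
  set.seed(13)
  sps <- synth_spacers(2, gc_target = 0.7)
  a <- asl("AAUAAUAAUAAUAA")
  sc <- combined_score(a, sps)
  expect_equal(sc$product, prod(sc$per_spacer))
  expect_equal(combined_score(a, sps[1])$product,
               unname(sc$per_spacer[1]))
  # permutation invariance
  sc_rev <- combined_score(a, rev(sps))
  expect_equal(sc_rev$product, sc$product)
  # appending a spacer cannot increase the product
  sc3 <- combined_score(a, c(sps, synth_spacers(1, gc_target = 0.3)))
  expect_lte(sc3$product, sc$product + 1e-12)
  expect_error(combined_score(a, list()), "at least one")
})

test_that("stem free energy uses the hairpin region and is 0 for no stem", {
  weak <- structure(list(name = "a20", sequence = strrep("A", 20)),
                    class = "spacer_record")
  # an all-A spacer still pairs its U back-fold; use a loop-only construct
  native <- assemble_sbh(weak, cleaving_units()$basic_loop, free_count_x = 20L)
  expect_equal(stem_free_energy(native), 0)
  sp <- fixture_spacer()
  with_sc <- assemble_sbh(sp, cleaving_units()$basic_loop,
                          include_scaffold = TRUE)
  without_sc <- assemble_sbh(sp, cleaving_units()$basic_loop)
  expect_equal(stem_free_energy(with_sc), stem_free_energy(without_sc))
  expect_lt(stem_free_energy(with_sc, with_scaffold = TRUE),
            stem_free_energy(with_sc))
})

test_that("prediction is reproducible across calls", {
  s <- paste0(strrep("G", 8), "AAAA", strrep("C", 8))
  r1 <- predict_mfe(s)
  r2 <- predict_mfe(s)
  expect_identical(r1, r2)
})
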