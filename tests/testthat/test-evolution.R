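test_that("sensing loops carry forced complementary flanks", {
  a <- asl("AAUCAUAAUCAUAA")
  expect_equal(nchar(a$sequence), 20L)
  expect_equal(a$core, substr(a$sequence, 4, 17))
  expect_equal(a$flank3, revcomp_rna(a$flank5))
  expect_error(asl("ACGU", stem_context = "GGCC"), "3 nt")
})

test_that("random loop draws are seeded, uniform, and flank-constrained", {
  set.seed(99)
  a1 <- random_asl()
  set.seed(99)
  a2 <- random_asl()
  expect_identical(a1, a2)
  set.seed(100)
  draws <- replicate(10000, random_asl()$core)
  freq <- table(strsplit(paste(draws, collapse = ""), ""))
  freq <- freq / sum(freq)
  expect_true(all(abs(freq - 0.25) < 0.02))
  expect_true(all(vapply(replicate(20, random_asl(), simplify = FALSE),
                         function(a) a$flank3 == revcomp_rna(a$flank5),
                         logical(1))))
})

test_that("crossover conserves bases columnwise and respects flank repair", {
  set.seed(5)
  a <- asl(strrep("A", 14))
  b <- asl(strrep("C", 14))
  kids <- recombine(a, b)
  # constructed case: children are prefix/suffix mosaics of an all-A and an
  # all-C core (flanks are identical between parents and repaired)
  core1 <- strsplit(kids[[1]]$core, "")[[1]]
  expect_true(all(core1 %in% c("A", "C")))
  if (any(core1 == "A") && any(core1 == "C")) {
    expect_lt(max(which(core1 == "A")), min(which(core1 == "C")))
  }
  # identical parents give identical children
  same <- recombine(a, a)
  expect_identical(same[[1]]$sequence, a$sequence)
  expect_identical(same[[2]]$sequence, a$sequence)
  # columnwise conservation over many random crossovers
  for (i in 1:200) {
    p1 <- random_asl()
    p2 <- random_asl()
    ch <- recombine(p1, p2)
    m_par <- rbind(strsplit(p1$sequence, "")[[1]], strsplit(p2$sequence, "")[[1]])
    m_kid <- rbind(strsplit(ch[[1]]$sequence, "")[[1]],
                   strsplit(ch[[2]]$sequence, "")[[1]])
    for (j in seq_len(20)) {
      expect_setequal(m_kid[, j], m_par[, j])
    }
  }
})

test_that("mutation hits the expected number of core bases", {
  set.seed(8)
  a <- asl("ACGUACGUACGUAC")
  dist <- replicate(10000, {
    m <- mutate_asl(a, rate = 0.05)
    sum(strsplit(m$core, "")[[1]] != strsplit(a$core, "")[[1]])
  })
  expect_equal(mean(dist), 0.7, tolerance = 0.05 / 0.7)
  # substituted bases always differ from the original; flanks are untouched
  set.seed(9)
  m <- mutate_asl(a, rate = 0.99)
  expect_equal(m$flank5, a$flank5)
  expect_equal(m$flank3, a$flank3)
  hits <- strsplit(m$core, "")[[1]] != strsplit(a$core, "")[[1]]
  expect_gt(sum(hits), 0)
})

test_that("tie-break ranking is total and follows GC then run length", {
  recs <- data.frame(
    asl = c("GGGGGGGGGGGGGGGGGGGG", "GCGCAUAUGCGCAUAUGCAU",
            "GGCCAAUUGGCCAAUUGGAA", "AAAAUUUUAAAAUUUUAAAA"),
    product_score = c(0.5, 0.5, 0.5, 0.9),
    gc_fraction = c(1.0, 0.5, 0.5, 0.0),
    max_homopolymer_run = c(20L, 2L, 4L, 4L))
  ranked <- tiebreak_rank(recs)
  expect_equal(ranked$product_score[1], 0.9)     # score dominates
  expect_equal(ranked$asl[2], "GCGCAUAUGCGCAUAUGCAU")  # GC 0.5 before GC 1.0
  expect_equal(ranked$asl[3], "GGCCAAUUGGCCAAUUGGAA")  # run 2 before run 4
  # deterministic total order regardless of input order
  shuffled <- tiebreak_rank(recs[c(3, 1, 4, 2), ])
  rownames(shuffled) <- NULL
  rownames(ranked) <- NULL
  expect_identical(shuffled, ranked)
})

test_that("exhaustive evolution enumerates and ranks every variant", {
  sp <- fixture_spacer()
  cons <- assemble_sbh(sp, asl_unit(asl("A")),
                       bulge_pattern = default_bulge_pattern())
  lo <- cons$regions$loop
  one <- exhaustive_evolve(cons, c(lo[1] + 3L, lo[1] + 4L))
  expect_equal(nrow(one), 4L)
  expect_setequal(one$variable, c("A", "C", "G", "U"))
  expect_true(all(diff(one$score) <= 1e-12))      # ranked best-first
  # region guard
  cons4 <- assemble_sbh(sp, asl_unit(asl("AAAA")),
                        bulge_pattern = default_bulge_pattern())
  lo4 <- cons4$regions$loop
  expect_equal(nrow(exhaustive_evolve(cons4, c(lo4[1] + 3L, lo4[1] + 7L))), 256L)
  expect_error(exhaustive_evolve(cons, c(0L, 12L)), "ga_evolve")
})

test_that("the GA is elitist, seeded-deterministic and improves monotonically", {
  set.seed(21)
  sps <- synth_spacers(1, gc_target = 0.65)
  cfg <- ga_config(pool_size = 30L, max_generations = 5L, seed = 7L)
  r1 <- ga_evolve(sps, cfg)
  r2 <- ga_evolve(sps, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  traj <- attr(r1, "top_score_trajectory")
  expect_true(all(diff(traj) >= -1e-12))
  expect_gte(attr(r1, "generations"), cfg$max_generations)
  expect_lte(attr(r1, "generations"), 5L * cfg$max_generations)
  # reported products equal freshly recomputed per-spacer scores
  for (i in c(1L, nrow(r1))) {
    fresh <- combined_score(asl(r1$core[i]), sps)
    expect_equal(r1$product_score[i], fresh$product, tolerance = 1e-12)
  }
  expect_error(ga_evolve(list(), ga_config()), "at least one")
})

test_that("GA leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(ga_evolve(list(fixture_spacer()),
                      ga_config(pool_size = 10L, max_generations = 2L,
                                seed = 3L)))
  expect_identical(.Random.seed, before)
})
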