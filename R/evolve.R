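#' ASO-sensing loop (ASL)
#'
#' A 20-nt loop element (with the default 14-nt core) for ASO-responsive
#' hairpins: a single-stranded core available for antisense-oligonucleotide
#' hybridization, flanked on both sides by 3 stem-complementary nucleotides.
#' The flanks form a 3-bp apex clamp — `flank3` is the reverse complement of
#' `flank5` — extending the hairpin stem and leaving exactly the core open.
#' The clamp is a construct-level constant (the `stem_context`), so one loop
#' can be shared across spacers.
#'
#' @param core core sequence (single-stranded segment), default length 14.
#' @param stem_context 3-nt flank on the 5' side; the 3' flank is forced to
#'   its reverse complement.
#' @return an object of class `asl` with fields `sequence`, `core`, `flank5`,
#'   `flank3`.
#' @examples
#' asl("AAUCAUAAUCAUAA")
#' @export
asl <- function(core, stem_context = "GGC") {
  core <- normalize_rna(core, "ASL core")
  flank5 <- normalize_rna(stem_context, "stem context")
  if (nchar(flank5) != 3L) stop("stem_context must be 3 nt", call. = FALSE)
  if (nchar(core) < 1L) stop("ASL core must be non-empty", call. = FALSE)
  flank3 <- revcomp_rna(flank5)
  structure(list(sequence = paste0(flank5, core, flank3), core = core,
                 flank5 = flank5, flank3 = flank3),
            class = "asl")
}

#' @export
print.asl <- function(x, ...) {
  cat(sprintf("<asl> %s [%s|%s|%s]\n", x$sequence, x$flank5, x$core, x$flank3))
  invisible(x)
}

# rebuild an ASL from a full 20-mer, re-imposing the flank constraint
.asl_repair <- function(full_seq, stem_context) {
  n <- nchar(full_seq)
  asl(substr(full_seq, 4L, n - 3L), stem_context)
}

#' Loop unit wrapping a sensing loop
#'
#' Converts an [asl()] into a [cleaving_unit()] whose expected fold asserts
#' the 3-bp flank clamp as pairs and the core as unpaired (the open
#' conformation required for ASO access). Not protein-cleavable
#' (`cut_offset` NULL); induction is ASO/RNase-H mediated.
#'
#' @param x an [asl()].
#' @return a `cleaving_unit`.
#' @export
asl_unit <- function(x) {
  stopifnot(inherits(x, "asl"))
  n <- nchar(x$sequence)
  u <- cleaving_unit("asl", x$sequence, cut_offset = NULL, graft_mode = "apex")
  u$self_pairs <- data.frame(a = 0:2, b = (n - 1):(n - 3))
  u$asl <- x
  u
}

#' Draw a uniformly random sensing loop
#'
#' Uniform random core; flanks forced by the stem context. Uses R's RNG, so
#' it is reproducible under `set.seed()`.
#'
#' @param stem_context 3-nt apex clamp sequence.
#' @param core_length core length in nt (default 14).
#' @return an [asl()].
#' @export
random_asl <- function(stem_context = "GGC", core_length = 14L) {
  core <- paste(sample(c("A", "C", "G", "U"), core_length, replace = TRUE),
                collapse = "")
  asl(core, stem_context)
}

#' Recombine two sensing loops
#'
#' Single-point crossover at a uniform position along the full loop sequence;
#' both children are flank-repaired afterwards. At every position the two
#' children jointly carry the same bases as the two parents.
#'
#' @param a,b parent [asl()] objects of equal length and stem context.
#' @return list of two child `asl` objects.
#' @export
recombine <- function(a, b) {
  stopifnot(inherits(a, "asl"), inherits(b, "asl"),
            nchar(a$sequence) == nchar(b$sequence))
  n <- nchar(a$sequence)
  pos <- sample.int(n - 1L, 1L)  # crossover after position pos, in [1, n-1]
  c1 <- paste0(substr(a$sequence, 1L, pos), substr(b$sequence, pos + 1L, n))
  c2 <- paste0(substr(b$sequence, 1L, pos), substr(a$sequence, pos + 1L, n))
  list(.asl_repair(c1, a$flank5), .asl_repair(c2, a$flank5))
}

#' Mutate a sensing loop
#'
#' Each core position is independently substituted to a *different* base with
#' probability `rate`; flanks are left at their forced values. The expected
#' Hamming distance is `core_length * rate`.
#'
#' @param x an [asl()].
#' @param rate per-base substitution probability in (0, 1).
#' @return a mutated `asl`.
#' @export
mutate_asl <- function(x, rate = 0.05) {
  stopifnot(inherits(x, "asl"), rate > 0, rate < 1)
  ch <- strsplit(x$core, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "U"), ch[i]), 1L)
  }
  asl(paste(ch, collapse = ""), x$flank5)
}

#' Total tie-broken ordering of scored loop candidates
#'
#' Candidates are ranked by product score (descending), then GC content
#' closest to 50%, then smallest maximum homopolymer run, then
#' lexicographically — a deterministic total order.
#'
#' @param records data.frame with columns `asl`, `product_score`,
#'   `gc_fraction`, `max_homopolymer_run`.
#' @return the records reordered (best first).
#' @export
tiebreak_rank <- function(records) {
  stopifnot(all(c("asl", "product_score", "gc_fraction", "max_homopolymer_run")
                %in% names(records)))
  ord <- order(-records$product_score,
               abs(records$gc_fraction - 0.5),
               records$max_homopolymer_run,
               records$asl)
  records[ord, , drop = FALSE]
}

#' GA configuration
#'
#' Defaults follow the published run: a pool of N = 150 loops, an iteration
#' threshold of 20 generations and a 2-generation stall rule. Per-generation
#' additions (mutants and fresh random loops, N/2 each) and the 5% per-base
#' mutation rate are package defaults where no value is published.
#'
#' @param pool_size pool size N (>= 2).
#' @param max_generations iteration threshold before the stall rule may stop
#'   the run; a hard cap of `5 * max_generations` guarantees termination.
#' @param stall_generations consecutive generations with an unchanged top
#'   score required to stop.
#' @param mutated_added_per_gen mutated loops appended per generation
#'   (default `pool_size / 2`).
#' @param random_added_per_gen fresh random loops appended per generation
#'   (default `pool_size / 2`).
#' @param mutation_rate per-base substitution probability.
#' @param core_length ASL core length (14 for the standard design).
#' @param stem_context 3-nt apex clamp.
#' @param seed integer seed for a fully reproducible run, or NULL.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pool_size = 150L, max_generations = 20L,
                      stall_generations = 2L,
                      mutated_added_per_gen = NULL, random_added_per_gen = NULL,
                      mutation_rate = 0.05, core_length = 14L,
                      stem_context = "GGC", seed = NULL) {
  if (is.null(mutated_added_per_gen)) mutated_added_per_gen <- pool_size %/% 2L
  if (is.null(random_added_per_gen)) random_added_per_gen <- pool_size %/% 2L
  cfg <- list(pool_size = as.integer(pool_size),
              max_generations = as.integer(max_generations),
              stall_generations = as.integer(stall_generations),
              mutated_added_per_gen = as.integer(mutated_added_per_gen),
              random_added_per_gen = as.integer(random_added_per_gen),
              mutation_rate = mutation_rate,
              core_length = as.integer(core_length),
              stem_context = normalize_rna(stem_context),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$pool_size < 2L) stop("pool_size must be >= 2", call. = FALSE)
  if (cfg$mutation_rate <= 0 || cfg$mutation_rate >= 1) {
    stop("mutation_rate must be in (0, 1)", call. = FALSE)
  }
  if (cfg$mutated_added_per_gen < 0L || cfg$random_added_per_gen < 0L) {
    stop("per-generation addition counts must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "ga_config")
}

# run fn with a locally seeded RNG, leaving the caller's RNG state untouched
.with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# memoised product-fitness scorer over a fixed spacer panel; precomputes the
# per-spacer hairpin templates and target pair tables once (the target depends
# only on region lengths, not on the loop core) so each evaluation is a single
# paste + fold + positional match
.make_scorer <- function(spacers, engine, bulge_pattern, mode) {
  cache <- new.env(parent = emptyenv())
  probe <- NULL
  templates <- NULL
  init <- function(a) {
    templates <<- lapply(spacers, function(sp) {
      cons <- assemble_sbh(sp, asl_unit(a), free_count_x = 0L,
                           bulge_pattern = bulge_pattern)
      tg <- target_structure(cons)
      lo <- cons$regions$loop
      list(name = sp$name,
           pre = paste0(substr(cons$full_sequence, 1L, lo[1]), a$flank5),
           post = paste0(a$flank3,
                         substr(cons$full_sequence, lo[2] + 1L,
                                nchar(cons$full_sequence))),
           target = tg,
           tt = .pair_table(tg$structure),
           idx = which(tg$constrained_mask))
    })
    probe <<- nchar(a$core)
  }
  function(a) {
    key <- a$sequence
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (is.null(templates) || nchar(a$core) != probe) init(a)
    fs <- vapply(templates, function(tp) {
      seq <- paste0(tp$pre, a$core, tp$post)
      pred <- predict_mfe(seq, engine)
      if (mode == "mfe") .score_positional(pred$structure, tp$tt, tp$idx)
      else folding_score(pred, tp$target, mode = mode, engine = engine)
    }, numeric(1))
    names(fs) <- vapply(templates, `[[`, "", "name")
    sc <- list(per_spacer = fs, product = prod(fs))
    cache[[key]] <- sc
    sc
  }
}

.record_pool <- function(pool, scorer) {
  scs <- lapply(pool, scorer)
  per <- do.call(rbind, lapply(scs, function(s) s$per_spacer))
  colnames(per) <- paste0("FS_", colnames(per))
  df <- data.frame(asl = vapply(pool, function(a) a$sequence, character(1)),
                   core = vapply(pool, function(a) a$core, character(1)),
                   per, check.names = FALSE, row.names = NULL)
  df$product_score <- vapply(scs, function(s) s$product, numeric(1))
  df$gc_fraction <- vapply(df$asl, gc_fraction, numeric(1), USE.NAMES = FALSE)
  df$max_homopolymer_run <- vapply(df$asl, max_homopolymer_run, integer(1),
                                   USE.NAMES = FALSE)
  df
}

#' Evolve a shared sensing loop across spacers with a genetic algorithm
#'
#' Runs the elitist GA: each generation (1) every pool member is recombined
#' with a uniformly chosen partner and both offspring join the pool, (2)
#' mutated copies of pool members are appended, (3) fresh random loops are
#' appended, (4) all members are scored by the product of per-spacer folding
#' scores and only the fittest `pool_size` survive (tie-broken as in
#' [tiebreak_rank()]). The run stops once the generation count exceeds
#' `max_generations` *and* the top score has not changed for
#' `stall_generations` consecutive generations, or at the hard cap of
#' `5 * max_generations`. Fully reproducible under `config$seed`.
#'
#' @param spacers list of [spacer_record()] objects (p >= 1).
#' @param config a [ga_config()].
#' @param engine a [fold_engine()].
#' @param bulge_pattern stem bulge pattern of the host hairpin.
#' @param mode folding-score mode, see [folding_score()].
#' @return a `ga_result`: the ranked final pool as a data.frame (columns
#'   `asl`, `core`, per-spacer `FS_*`, `product_score`, `gc_fraction`,
#'   `max_homopolymer_run`), with attributes `generations`,
#'   `top_score_trajectory` and `config`.
#' @export
ga_evolve <- function(spacers, config = ga_config(), engine = fold_engine(),
                      bulge_pattern = default_bulge_pattern(), mode = "mfe") {
  if (inherits(spacers, "spacer_record")) spacers <- list(spacers)
  if (length(spacers) < 1L) stop("need at least one spacer", call. = FALSE)
  stopifnot(inherits(config, "ga_config"))
  .with_local_seed(config$seed, function() {
    scorer <- .make_scorer(spacers, engine, bulge_pattern, mode)
    new_asl <- function() random_asl(config$stem_context, config$core_length)
    pool <- replicate(config$pool_size, new_asl(), simplify = FALSE)
    traj <- numeric(0)
    stall <- 0L
    gen <- 0L
    hard_cap <- 5L * config$max_generations
    repeat {
      gen <- gen + 1L
      expanded <- pool
      for (a in pool) {
        partner <- pool[[sample.int(length(pool), 1L)]]
        expanded <- c(expanded, recombine(a, partner))
      }
      if (config$mutated_added_per_gen > 0L) {
        src <- pool[sample.int(length(pool), config$mutated_added_per_gen,
                               replace = TRUE)]
        expanded <- c(expanded, lapply(src, mutate_asl,
                                       rate = config$mutation_rate))
      }
      if (config$random_added_per_gen > 0L) {
        expanded <- c(expanded,
                      replicate(config$random_added_per_gen, new_asl(),
                                simplify = FALSE))
      }
      df <- .record_pool(expanded, scorer)
      df <- tiebreak_rank(df)
      df <- df[seq_len(min(config$pool_size, nrow(df))), , drop = FALSE]
      pool <- lapply(df$core, asl, stem_context = config$stem_context)
      top <- df$product_score[1]
      if (length(traj) > 0L && isTRUE(all.equal(top, traj[length(traj)]))) {
        stall <- stall + 1L
      } else {
        stall <- 0L
      }
      traj <- c(traj, top)
      if ((gen > config$max_generations && stall >= config$stall_generations) ||
          gen >= hard_cap) {
        break
      }
    }
    rownames(df) <- NULL
    attr(df, "generations") <- gen
    attr(df, "top_score_trajectory") <- traj
    attr(df, "config") <- config
    attr(df, "engine") <- c(name = engine$name, version = engine$version)
    class(df) <- c("ga_result", class(df))
    df
  })
}

#' Exhaustively evolve a variable region against a target fold
#'
#' Enumerates every sequence of the variable region (4^len candidates),
#' scores each full sequence against the target with [folding_score()], and
#' returns all candidates ranked by score and tie-break. The top entry is the
#' global optimum — the oracle against which the GA is checked.
#'
#' @param construct an `sbh_construct` serving as the template.
#' @param variable_region integer `c(start, end)`, 0-based half-open interval
#'   in full-sequence coordinates.
#' @param target a `target_structure` for the template (default derived from
#'   the construct).
#' @param engine a [fold_engine()].
#' @param max_len refuse regions longer than this (4^len blow-up); use the
#'   GA instead for longer regions.
#' @param mode folding-score mode.
#' @return data.frame with columns `variable`, `sequence`, `score`,
#'   `gc_fraction`, `max_homopolymer_run`, ranked best-first.
#' @export
exhaustive_evolve <- function(construct, variable_region,
                              target = target_structure(construct),
                              engine = fold_engine(), max_len = 8L,
                              mode = "mfe") {
  stopifnot(inherits(construct, "sbh_construct"), length(variable_region) == 2L)
  a <- variable_region[1]
  b <- variable_region[2]
  len <- b - a
  n <- nchar(construct$full_sequence)
  if (a < 0 || b > n || len < 1L) stop("invalid variable region", call. = FALSE)
  if (len > max_len) {
    stop("variable region of ", len, " nt gives 4^", len,
         " candidates; use ga_evolve() for regions longer than ", max_len,
         " nt", call. = FALSE)
  }
  bases <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid, rep(list(bases), len))
  variants <- apply(as.matrix(grid), 1L, paste, collapse = "")
  pre <- substr(construct$full_sequence, 1L, a)
  post <- substr(construct$full_sequence, b + 1L, n)
  score <- vapply(variants, function(v) {
    folding_score(predict_mfe(paste0(pre, v, post), engine), target,
                  mode = mode, engine = engine)
  }, numeric(1))
  df <- data.frame(variable = variants,
                   sequence = paste0(pre, variants, post),
                   product_score = score,
                   gc_fraction = vapply(variants, gc_fraction, numeric(1)),
                   max_homopolymer_run =
                     vapply(variants, max_homopolymer_run, integer(1)),
                   asl = variants,
                   row.names = NULL)
  df <- tiebreak_rank(df)
  names(df)[names(df) == "product_score"] <- "score"
  df$asl <- NULL
  rownames(df) <- NULL
  df
}

#' Construct a planted-solution instance for the loop-evolution problem
#'
#' Draws GC-rich random spacers and verifies (by folding) that a designated
#' sensing loop scores exactly 1 on every resulting hairpin, redrawing
#' spacers until it does. Used to test that the GA recovers a perfect loop
#' when one is known to exist.
#'
#' @param p number of spacers.
#' @param planted_core core of the planted loop (default an AU-rich 14-mer
#'   that cannot invade a GC-rich stem).
#' @param stem_context 3-nt apex clamp.
#' @param gc_target spacer GC content (high, for a dominant stem).
#' @param engine a [fold_engine()].
#' @param max_tries redraw limit per spacer.
#' @return list with `spacers` (list of [spacer_record()]) and `asl` (the
#'   planted [asl()], scoring 1 on every hairpin).
#' @export
synth_planted_instance <- function(p = 2L, planted_core = "AAUAAUAAUAAUAA",
                                   stem_context = "GGC", gc_target = 0.7,
                                   engine = fold_engine(), max_tries = 200L) {
  planted <- asl(planted_core, stem_context)
  spacers <- list()
  for (i in seq_len(p)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      sp <- synth_spacers(1L, gc_target = gc_target)[[1]]
      sp$name <- sprintf("planted_%d", i)
      fs <- combined_score(planted, list(sp), engine)$product
      if (fs == 1) { ok <- TRUE; break }
    }
    if (!ok) stop("could not plant a perfect-scoring spacer", call. = FALSE)
    spacers[[i]] <- sp
  }
  list(spacers = spacers, asl = planted)
}
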