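#' Folding engine handle
#'
#' The package folds RNA with its own built-in nearest-neighbour engine
#' (`"nnfold"`): Zuker-style minimum-free-energy dynamic programming plus a
#' McCaskill-style partition function for pair probabilities, at 37 degrees C
#' with a Turner-2004-style parameter set (see the methods vignette for the
#' exact model). The handle exists so an external thermodynamic engine can be
#' slotted in: any object with class `fold_engine` and a `$fold(seq)` function
#' returning `list(structure=, mfe=)` is accepted by [predict_mfe()].
#'
#' @param name engine name; only `"nnfold"` is built in.
#' @return an object of class `fold_engine`.
#' @export
fold_engine <- function(name = "nnfold") {
  if (!identical(name, "nnfold")) {
    stop("engine '", name, "' is not available; the built-in engine is ",
         "'nnfold'. Supply a custom fold_engine object with a $fold(seq) ",
         "function to use an external backend.", call. = FALSE)
  }
  structure(list(name = "nnfold", version = "0.1.0", temperature_c = 37,
                 fold = function(seq) .c_fold_mfe(seq),
                 pair_probs = function(seq) .c_pair_probs(seq)),
            class = "fold_engine")
}

#' @export
print.fold_engine <- function(x, ...) {
  cat(sprintf("<fold_engine> %s %s (%g C)\n", x$name, x$version, x$temperature_c))
  invisible(x)
}

#' Predict the minimum-free-energy structure of an RNA
#'
#' Deterministic for a fixed engine, parameter set and temperature. A sequence
#' with no stable pairing returns the all-unpaired structure with a free
#' energy of exactly 0.
#'
#' @param seq RNA (or DNA, transliterated) string, length >= 1.
#' @param engine a [fold_engine()].
#' @return an object of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0).
#' @examples
#' predict_mfe("GGGGAAAACCCC")
#' @export
predict_mfe <- function(seq, engine = fold_engine()) {
  stopifnot(inherits(engine, "fold_engine"))
  s <- normalize_rna(seq)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  r <- engine$fold(s)
  structure(list(sequence = s, structure = r$structure, mfe = r$mfe),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.2f", x$mfe), ")\n", sep = "")
  invisible(x)
}

#' Base-pair probability matrix
#'
#' Equilibrium pair probabilities from the engine's partition function,
#' used by the probability-weighted folding-score mode.
#'
#' @param seq RNA string.
#' @param engine a [fold_engine()].
#' @return symmetric numeric matrix, `P[i, j]` = probability that i pairs j.
#' @export
pair_probabilities <- function(seq, engine = fold_engine()) {
  stopifnot(inherits(engine, "fold_engine"))
  if (is.null(engine$pair_probs)) {
    stop("engine '", engine$name, "' provides no pair probabilities", call. = FALSE)
  }
  engine$pair_probs(normalize_rna(seq))
}

# positional-match folding score against a precomputed target pair table
.score_positional <- function(pred_structure, target_pt, idx) {
  pp <- .pair_table(pred_structure)
  mean(pp[idx] == target_pt[idx])
}

# pair table of a dot-bracket string: integer vector, 0 = unpaired,
# otherwise 1-based partner position
.pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      st <- c(st, i)
    } else if (ch[i] == ")") {
      if (length(st) == 0L) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- st[length(st)]
      st <- st[-length(st)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid dot-bracket character '", ch[i], "'", call. = FALSE)
    }
  }
  if (length(st) != 0L) stop("unbalanced dot-bracket string", call. = FALSE)
  pt
}

#' Expected fold of an SBH / iSBH construct
#'
#' Builds the designed dot-bracket target: back-fold positions paired to their
#' covered spacer partners, bulged and free spacer nucleotides unpaired, the
#' loop open (constrained for a basic loop or sensing loop, unconstrained for
#' units carrying their own internal structure), and scaffold positions
#' unconstrained. Sensing-loop flank pairs (the 3-bp apex clamp of an ASL) are
#' asserted as pairs.
#'
#' @param construct an `sbh_construct`.
#' @return an object of class `target_structure`: `structure` (dot-bracket)
#'   and `constrained_mask` (logical; TRUE positions are asserted).
#' @export
target_structure <- function(construct) {
  stopifnot(inherits(construct, "sbh_construct"))
  n <- nchar(construct$full_sequence)
  ch <- rep(".", n)
  mask <- rep(TRUE, n)
  pr <- .stem_pairs_full(construct)
  ch[pr$bf] <- "("
  ch[pr$sp] <- ")"
  lo <- construct$regions$loop
  if (!is.null(construct$loop_unit)) {
    u <- construct$loop_unit
    if (isTRUE(u$structured)) {
      mask[seq.int(lo[1] + 1L, length.out = lo[2] - lo[1])] <- FALSE
    } else if (!is.null(u$self_pairs) && nrow(u$self_pairs) > 0L) {
      ch[lo[1] + u$self_pairs$a + 1L] <- "("
      ch[lo[1] + u$self_pairs$b + 1L] <- ")"
    }
  }
  if (construct$scaffold_included) {
    sc <- construct$regions$scaffold
    mask[seq.int(sc[1] + 1L, length.out = sc[2] - sc[1])] <- FALSE
  }
  structure(list(structure = paste(ch, collapse = ""), constrained_mask = mask),
            class = "target_structure")
}

#' @export
print.target_structure <- function(x, ...) {
  cat(x$structure, "\n", sep = "")
  cat(sum(x$constrained_mask), "of", length(x$constrained_mask),
      "positions constrained\n")
  invisible(x)
}

#' Folding score of a prediction against an expected fold
#'
#' The per-hairpin similarity statistic FS in \[0, 1\]. Default `"mfe"` mode:
#' the fraction of constrained positions whose pairing state in the predicted
#' MFE structure matches the target — paired positions must have the identical
#' partner, dots must be unpaired. `"probability"` mode averages, over
#' constrained positions, the equilibrium probability of the target state
#' (pair probability for target pairs, unpaired probability for target dots).
#' The score is 1 exactly when every constrained position matches.
#'
#' @param pred a `fold_result` from [predict_mfe()].
#' @param target a `target_structure`.
#' @param mode `"mfe"` or `"probability"`.
#' @param engine engine used for `"probability"` mode.
#' @return numeric score in \[0, 1\].
#' @export
folding_score <- function(pred, target, mode = c("mfe", "probability"),
                          engine = fold_engine()) {
  mode <- match.arg(mode)
  stopifnot(inherits(pred, "fold_result"), inherits(target, "target_structure"))
  n <- nchar(pred$structure)
  if (n != nchar(target$structure) || n != length(target$constrained_mask)) {
    stop("prediction and target lengths differ", call. = FALSE)
  }
  tt <- .pair_table(target$structure)
  idx <- which(target$constrained_mask)
  if (length(idx) == 0L) stop("target constrains no positions", call. = FALSE)
  if (mode == "mfe") {
    .score_positional(pred$structure, tt, idx)
  } else {
    P <- pair_probabilities(pred$sequence, engine)
    unp <- 1 - pmin(1, rowSums(P))
    p <- ifelse(tt[idx] > 0L, P[cbind(idx, tt[idx])], unp[idx])
    mean(p)
  }
}

#' Product fitness of a sensing loop across spacers
#'
#' Builds the sensing-loop hairpin for each spacer, folds it and multiplies
#' the per-spacer folding scores FS1..FSp. Permutation-invariant in the spacer
#' list and non-increasing as spacers are appended; equals FS1 for a single
#' spacer; any zero score annihilates the product.
#'
#' @param asl an [asl()] sensing loop.
#' @param spacers list of [spacer_record()] objects, length >= 1.
#' @param engine a [fold_engine()].
#' @param bulge_pattern stem bulge pattern of the host hairpin.
#' @param mode folding-score mode, see [folding_score()].
#' @return list with `per_spacer` (named numeric vector) and `product`.
#' @export
combined_score <- function(asl, spacers, engine = fold_engine(),
                           bulge_pattern = default_bulge_pattern(),
                           mode = "mfe") {
  if (inherits(spacers, "spacer_record")) spacers <- list(spacers)
  if (length(spacers) < 1L) stop("need at least one spacer", call. = FALSE)
  fs <- vapply(spacers, function(sp) {
    cons <- assemble_sbh(sp, asl_unit(asl), free_count_x = 0L,
                         bulge_pattern = bulge_pattern)
    folding_score(predict_mfe(cons$full_sequence, engine),
                  target_structure(cons), mode = mode, engine = engine)
  }, numeric(1))
  names(fs) <- vapply(spacers, function(sp) sp$name, character(1))
  list(per_spacer = fs, product = prod(fs))
}

#' Stem free energy of a construct
#'
#' The minimum free energy (kcal/mol) of the hairpin region — back-fold, loop
#' and spacer, scaffold excluded by default — the stem-stability proxy used to
#' compare SBH designs. A construct with no stable stem returns 0.
#'
#' @param construct an `sbh_construct`.
#' @param engine a [fold_engine()].
#' @param with_scaffold fold the full guide including the scaffold instead.
#' @return numeric, kcal/mol.
#' @export
stem_free_energy <- function(construct, engine = fold_engine(),
                             with_scaffold = FALSE) {
  stopifnot(inherits(construct, "sbh_construct"))
  seq <- if (with_scaffold || !construct$scaffold_included) {
    construct$full_sequence
  } else {
    paste0(region_sequence(construct, "backfold"),
           region_sequence(construct, "loop"),
           region_sequence(construct, "spacer"))
  }
  predict_mfe(seq, engine)$mfe
}
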