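#' Generate the SBH(x) series for a spacer
#'
#' One entry for every back-fold coverage x in 0..len(spacer): x spacer
#' nucleotides are left free, the rest are covered by the back-fold. Each
#' entry carries the full hairpin sequence, its predicted structure and MFE
#' (the stem-stability proxy), and annealed cloning oligos. x = len(spacer)
#' degenerates to a back-fold-free guide.
#'
#' @param spacer a [spacer_record()].
#' @param loop_unit a [cleaving_unit()] (default the GAAA basic loop).
#' @param engine a [fold_engine()].
#' @param bulge_pattern bulge pattern applied at every x where it fits;
#'   entries where it does not fit fall back to a plain stem and are marked.
#' @param enforce_g1 apply the U6 +G1 rule to the cloning insert.
#' @param mfe_ceiling entries with MFE above this value (weaker stems) are
#'   flagged, not dropped; NULL disables flagging.
#' @return a `series_report` data.frame with columns `x_or_offset`,
#'   `sequence`, `structure`, `mfe_kcal_mol`, `top_oligo`, `bottom_oligo`,
#'   `flagged`; constructs in `attr(, "constructs")`.
#' @export
sbh_series <- function(spacer, loop_unit = cleaving_units()$basic_loop,
                       engine = fold_engine(), bulge_pattern = list(),
                       enforce_g1 = TRUE, mfe_ceiling = NULL) {
  stopifnot(inherits(spacer, "spacer_record"))
  L <- nchar(spacer$sequence)
  entries <- lapply(0:L, function(x) {
    cons <- tryCatch(
      assemble_sbh(spacer, loop_unit, free_count_x = x,
                   bulge_pattern = bulge_pattern),
      error = function(e) assemble_sbh(spacer, loop_unit, free_count_x = x)
    )
    fr <- predict_mfe(cons$full_sequence, engine)
    ol <- cloning_oligos(cons, enforce_g1 = enforce_g1)
    list(cons = cons,
         row = data.frame(x_or_offset = x, sequence = cons$full_sequence,
                          structure = fr$structure, mfe_kcal_mol = fr$mfe,
                          top_oligo = ol$top, bottom_oligo = ol$bottom))
  })
  .series_report(entries, list(kind = "sbh_series", spacer = spacer$name,
                               loop_unit = loop_unit$name,
                               x_range = c(0L, L)), mfe_ceiling)
}

#' Slide a bulge pattern along an SBH stem
#'
#' Starting from the full-coverage hairpin, translates a user-defined bulge
#' pattern (anchored by its loop-proximal element) along the stem in 1-nt
#' steps, producing one entry per offset at which the whole pattern fits.
#' Internal spacing of the pattern is preserved.
#'
#' @param spacer a [spacer_record()].
#' @param loop_unit a [cleaving_unit()].
#' @param pattern list of [bulge_element()] objects at their leftmost
#'   (loop-proximal) placement.
#' @param engine a [fold_engine()].
#' @param enforce_g1 apply the U6 +G1 rule to the cloning insert.
#' @param mfe_ceiling see [sbh_series()].
#' @return a `series_report` (columns as in [sbh_series()], `x_or_offset`
#'   holding the translation offset). A pattern that never fits returns an
#'   empty report with a warning.
#' @export
slide_bulges <- function(spacer, loop_unit = cleaving_units()$basic_loop,
                         pattern = default_bulge_pattern(),
                         engine = fold_engine(), enforce_g1 = TRUE,
                         mfe_ceiling = NULL) {
  stopifnot(inherits(spacer, "spacer_record"), length(pattern) >= 1L)
  pattern <- .sort_bulges(pattern)
  base <- pattern[[1]]$stem_index
  entries <- list()
  offset <- 0L
  repeat {
    shifted <- lapply(pattern, function(b) {
      bulge_element(b$stem_index - base + offset, b$length, b$strand, b$insert)
    })
    cons <- tryCatch(
      assemble_sbh(spacer, loop_unit, free_count_x = 0L,
                   bulge_pattern = shifted),
      error = function(e) NULL
    )
    if (is.null(cons)) break
    fr <- predict_mfe(cons$full_sequence, engine)
    ol <- cloning_oligos(cons, enforce_g1 = enforce_g1)
    entries[[length(entries) + 1L]] <-
      list(cons = cons,
           row = data.frame(x_or_offset = offset, sequence = cons$full_sequence,
                            structure = fr$structure, mfe_kcal_mol = fr$mfe,
                            top_oligo = ol$top, bottom_oligo = ol$bottom))
    offset <- offset + 1L
  }
  if (length(entries) == 0L) {
    warning("bulge pattern does not fit the stem at any offset")
  }
  .series_report(entries, list(kind = "slide_bulges", spacer = spacer$name,
                               loop_unit = loop_unit$name,
                               pattern_elements = length(pattern)),
                 mfe_ceiling)
}

.series_report <- function(entries, parameters, mfe_ceiling) {
  if (length(entries) == 0L) {
    df <- data.frame(x_or_offset = integer(0), sequence = character(0),
                     structure = character(0), mfe_kcal_mol = numeric(0),
                     top_oligo = character(0), bottom_oligo = character(0),
                     flagged = logical(0))
  } else {
    df <- do.call(rbind, lapply(entries, `[[`, "row"))
    df$flagged <- if (is.null(mfe_ceiling)) FALSE else df$mfe_kcal_mol > mfe_ceiling
  }
  rownames(df) <- NULL
  attr(df, "constructs") <- lapply(entries, `[[`, "cons")
  attr(df, "parameters") <- parameters
  class(df) <- c("series_report", class(df))
  df
}

#' @export
print.series_report <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf("<series_report> %s | spacer %s | loop %s | %d entries\n",
              p$kind, p$spacer, p$loop_unit, nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more entries\n")
  invisible(x)
}
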