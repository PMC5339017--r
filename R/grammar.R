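#' Spacer record
#'
#' A named guide spacer, the design target of every construct in the package.
#' Sequences are accepted as DNA or RNA and normalized to uppercase RNA at
#' ingestion. Lengths outside 10-20 nt are rejected: shorter guides lose
#' targeting specificity, longer ones are not SpCas9 spacers.
#'
#' @param name non-empty identifier.
#' @param sequence spacer sequence, DNA or RNA, 10-20 nt (typically 20).
#' @return an object of class `spacer_record` with fields `name`, `sequence`.
#' @examples
#' spacer_record("CTS1s", "GGTCGACCTCGAGTCAGTCA")
#' @export
spacer_record <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!nzchar(name)) stop("spacer name must be non-empty", call. = FALSE)
  seq <- normalize_rna(sequence, what = paste0("spacer '", name, "'"))
  n <- nchar(seq)
  if (n < 10L || n > 20L) {
    stop(sprintf("spacer '%s' is %d nt; must be within [10, 20]", name, n),
         call. = FALSE)
  }
  structure(list(name = name, sequence = seq), class = "spacer_record")
}

#' @export
print.spacer_record <- function(x, ...) {
  cat(sprintf("<spacer_record> %s: %s (%d nt)\n", x$name, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Bulge element of a hairpin stem
#'
#' A bulge is a run of unpaired nucleotides on one strand of the stem.
#' `stem_index` counts paired stem positions from the loop-proximal end
#' (0-based): a bulge at index `s` sits between the s-th and (s+1)-th base pair
#' counted from the loop. A `spacer`-strand bulge leaves spacer nucleotides
#' unpaired (the back-fold skips their complements, keeping the spacer sequence
#' intact for DNA targeting); a `backfold`-strand bulge inserts extra
#' nucleotides into the back-fold.
#'
#' @param stem_index 0-based position along the paired stem, from the loop end.
#' @param length number of bulged nucleotides (default 2).
#' @param strand `"spacer"` or `"backfold"`.
#' @param insert for backfold-strand bulges, the inserted nucleotides
#'   (default a run of A, which cannot extend the stem pairing).
#' @return an object of class `bulge_element`.
#' @export
bulge_element <- function(stem_index, length = 2L, strand = c("spacer", "backfold"),
                          insert = NULL) {
  strand <- match.arg(strand)
  stem_index <- as.integer(stem_index)
  length <- as.integer(length)
  if (length < 1L) stop("bulge length must be >= 1", call. = FALSE)
  if (stem_index < 0L) stop("bulge stem_index must be >= 0", call. = FALSE)
  if (is.null(insert)) insert <- strrep("A", length)
  insert <- normalize_rna(insert, "bulge insert")
  if (nchar(insert) != length) stop("bulge insert length mismatch", call. = FALSE)
  structure(list(stem_index = stem_index, length = length, strand = strand,
                 insert = insert),
            class = "bulge_element")
}

#' Default bulged-stem pattern of the SBH(0B) design
#'
#' Two 2-nt spacer-strand bulges. The exact positions in the published
#' prototype are configurable here; defaults place them at paired-stem indices
#' 5 and 12 from the loop end, which splits a 20-nt spacer stem into three
#' helices of 5, 7 and 4 bp.
#'
#' @param basal also append the basal destabilizing bulge of the 0B* variant:
#'   2 nt on the spacer strand at the very base of the stem (the two
#'   scaffold-proximal spacer nucleotides are left unpaired and the back-fold
#'   shortened accordingly). This realization never stabilizes the hairpin —
#'   the 0B* guide is a subsequence of the 0B guide, so every 0B* fold is
#'   available to 0B at equal or lower energy.
#' @return list of [bulge_element()] objects.
#' @export
default_bulge_pattern <- function(basal = FALSE) {
  p <- list(bulge_element(5L, 2L, "spacer"), bulge_element(12L, 2L, "spacer"))
  if (basal) p <- c(p, list(bulge_element(14L, 2L, "spacer")))
  p
}

.sort_bulges <- function(bulges) {
  if (length(bulges) == 0L) return(bulges)
  ord <- order(vapply(bulges, function(b) b$stem_index, integer(1)))
  bulges[ord]
}

#' RNA-cleaving / loop unit
#'
#' The interchangeable unit occupying the hairpin loop (or fused into a stem
#' bulge): a basic tetraloop, an endoribonuclease recognition motif (Csy4,
#' Cas6A), an ASO-sensing loop, or a ribozyme. `cut_offset` is the 0-based
#' position within the unit 5' of which cleavage occurs (NULL for
#' non-cleavable loops).
#'
#' @param name identifier.
#' @param sequence unit RNA sequence, non-empty.
#' @param cut_offset integer in \[0, nchar(sequence)\] or NULL.
#' @param graft_mode `"apex"`, `"distal_bulge"` or `"proximal_bulge"`.
#' @return an object of class `cleaving_unit`.
#' @export
cleaving_unit <- function(name, sequence, cut_offset = NULL,
                          graft_mode = c("apex", "distal_bulge", "proximal_bulge")) {
  graft_mode <- match.arg(graft_mode)
  seq <- normalize_rna(sequence, paste0("unit '", name, "'"))
  if (nchar(seq) == 0L) stop("cleaving unit sequence must be non-empty", call. = FALSE)
  if (!is.null(cut_offset)) {
    cut_offset <- as.integer(cut_offset)
    if (cut_offset < 0L || cut_offset > nchar(seq)) {
      stop("cut_offset outside [0, unit length]", call. = FALSE)
    }
  }
  structure(list(name = name, sequence = seq, cut_offset = cut_offset,
                 graft_mode = graft_mode),
            class = "cleaving_unit")
}

#' Registry of built-in loop / cleaving units
#'
#' * `basic_loop` — GAAA tetraloop for non-inducible SBH constructs.
#' * `csy4` — the 28-nt Pseudomonas aeruginosa Csy4 (Cas6f) repeat;
#'   cleavage 3' of the recognition hairpin (after position 20) leaves an
#'   8-nt tail on the downstream fragment.
#' * `cas6a_synthetic` — a SYNTHETIC stand-in hairpin with Cas6-like cut
#'   geometry (the published Thermus thermophilus motif is not bundled);
#'   substitute the real motif via [cleaving_unit()] for wet-lab use.
#' * `hhrz_synthetic` — a SYNTHETIC stand-in for a self-cleaving hammerhead
#'   ribozyme, treated purely as a graftable sequence unit.
#'
#' @return named list of [cleaving_unit()] objects.
#' @export
cleaving_units <- function() {
  structured <- function(u) { u$structured <- TRUE; u }
  list(
    basic_loop = cleaving_unit("basic_loop", "GAAA"),
    csy4 = structured(cleaving_unit("csy4", "GUUCACUGCCGUAUAGGCAGCUAAGAAA",
                                    cut_offset = 20L)),
    cas6a_synthetic = structured(cleaving_unit("cas6a_synthetic",
                                               "GGCAUCGCGAAAGCGAUGCCAAAG",
                                               cut_offset = 20L)),
    hhrz_synthetic = structured(cleaving_unit("hhrz_synthetic",
                                              "CUGAUGAGGCCGAAAGGCCGAAACAGGUC",
                                              cut_offset = 24L))
  )
}

#' Standard sgRNA scaffold constants
#'
#' `tracr` is the standard 76-nt SpCas9 sgRNA scaffold. `sam_2xms2` is a
#' SYNTHETIC stand-in for an MS2-aptamer-bearing scaffold (tetraloop and
#' stem-loop 2 replaced by the MS2 hairpin), selectable for designs aimed at
#' MCP-fusion recruitment; substitute the exact published scaffold for
#' wet-lab use. Scaffolds are excluded from folding by default.
#'
#' @param variant `"tracr"` or `"sam_2xms2"`.
#' @return scaffold RNA string.
#' @export
sgrna_scaffold <- function(variant = c("tracr", "sam_2xms2")) {
  variant <- match.arg(variant)
  ms2 <- "GGCCAACAUGAGGAUCACCCAUGUCUGCAGGGCC"
  switch(variant,
    tracr = paste0("GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCA",
                   "ACUUGAAAAAGUGGCACCGAGUCGGUGC"),
    sam_2xms2 = paste0("GUUUUAGAGCUAG", ms2, "CAAGUUAAAAUAAGGCUAGUCCGUUAUCA",
                       "ACUUGAAAAAGUGG", ms2, "CACCGAGUCGGUGC")
  )
}

# Walk the stem from the loop-proximal end and return the alignment between
# spacer and back-fold under a bulge pattern. Spacer position 1 is
# loop-proximal (the spacer 5' end adjoins the loop); the covered segment is
# the loop-proximal len-x nucleotides, leaving the x scaffold-proximal (3')
# spacer nucleotides free.
#
# Returns a list with:
#   pairs      data.frame(stem_index, sp_pos, bf_rank) — bf_rank counts
#              back-fold nucleotides from the back-fold 3' (loop-proximal) end
#   sp_bulged  spacer positions (1-based in spacer) left unpaired by bulges
#   bf_inserts data.frame(after_pair, insert) back-fold strand insertions
#   backfold   the back-fold sequence 5'->3'
.stem_alignment <- function(spacer_seq, free_count_x, bulges) {
  L <- nchar(spacer_seq)
  x <- as.integer(free_count_x)
  if (x < 0L || x > L) {
    stop(sprintf("free_count_x = %d outside [0, %d]", x, L), call. = FALSE)
  }
  covered <- L - x
  bulges <- .sort_bulges(bulges)
  idx <- vapply(bulges, function(b) b$stem_index, integer(1))
  if (anyDuplicated(idx)) stop("overlapping bulge elements", call. = FALSE)

  sp_chars <- strsplit(spacer_seq, "")[[1]]
  pairs <- list()
  sp_bulged <- integer(0)
  bf_rev <- character(0)   # back-fold built 3'->5' (loop end first)
  bf_inserts <- list()
  sp <- 1L                 # next spacer position to consume
  c <- 0L                  # paired positions placed so far
  bi <- 1L                 # next bulge to apply
  while (sp <= covered) {
    while (bi <= length(bulges) && bulges[[bi]]$stem_index == c) {
      b <- bulges[[bi]]
      if (b$strand == "spacer") {
        take <- seq.int(sp, length.out = b$length)
        if (max(take) > covered) {
          stop("bulge extends beyond covered spacer segment", call. = FALSE)
        }
        sp_bulged <- c(sp_bulged, take)
        sp <- sp + b$length
      } else {
        bf_rev <- c(bf_rev, rev(strsplit(b$insert, "")[[1]]))
        bf_inserts[[length(bf_inserts) + 1L]] <- list(after_pair = c, insert = b$insert)
      }
      bi <- bi + 1L
    }
    if (sp > covered) break
    bf_rev <- c(bf_rev, unname(.COMP_RNA[sp_chars[sp]]))
    pairs[[length(pairs) + 1L]] <- c(stem_index = c, sp_pos = sp,
                                     bf_rank = length(bf_rev))
    sp <- sp + 1L
    c <- c + 1L
  }
  if (bi <= length(bulges)) {
    b <- bulges[[bi]]
    if (b$stem_index == c && b$strand == "spacer" && x > 0L) {
      stop("bulge extends beyond covered spacer segment", call. = FALSE)
    }
    if (b$stem_index == c && b$strand == "spacer" && sp + b$length - 1L <= L) {
      # terminal (basal) bulge: trailing spacer nucleotides left unpaired
      sp_bulged <- c(sp_bulged, seq.int(sp, length.out = b$length))
      bi <- bi + 1L
    }
    if (bi <= length(bulges)) {
      stop(sprintf("bulge at stem_index %d beyond stem length %d",
                   bulges[[bi]]$stem_index, c), call. = FALSE)
    }
  }
  pairs <- if (length(pairs)) {
    as.data.frame(do.call(rbind, pairs))
  } else {
    data.frame(stem_index = integer(0), sp_pos = integer(0), bf_rank = integer(0))
  }
  list(pairs = pairs, sp_bulged = sp_bulged, bf_inserts = bf_inserts,
       backfold = paste(rev(bf_rev), collapse = ""))
}

#' Build the spacer-blocking back-fold strand
#'
#' Returns the 5' extension whose 3' end adjoins the hairpin loop: the reverse
#' complement of the loop-proximal `len - x` spacer nucleotides, with
#' backfold-strand bulges inserted as extra unpaired nucleotides and
#' spacer-strand bulges realized as skipped complements.
#'
#' @param spacer a [spacer_record()].
#' @param free_count_x number of scaffold-proximal spacer nucleotides left
#'   unpaired (the superscript x of the SBH(x) nomenclature).
#' @param bulge_pattern list of [bulge_element()] objects.
#' @return back-fold RNA string (5'->3').
#' @examples
#' build_backfold(spacer_record("s", strrep("G", 20)), 5)  # 15 C's
#' @export
build_backfold <- function(spacer, free_count_x = 0L, bulge_pattern = list()) {
  stopifnot(inherits(spacer, "spacer_record"))
  .stem_alignment(spacer$sequence, free_count_x, bulge_pattern)$backfold
}

#' Assemble an SBH / iSBH construct
#'
#' Concatenates back-fold, loop unit and spacer (optionally followed by the
#' sgRNA scaffold) into a full guide and records region coordinates (0-based,
#' half-open) and the stem pairing map used for expected-structure
#' construction.
#'
#' @param spacer a [spacer_record()].
#' @param loop_unit a [cleaving_unit()], or NULL for no loop (native guide
#'   when `free_count_x` equals the spacer length).
#' @param free_count_x free spacer nucleotides, see [build_backfold()].
#' @param bulge_pattern list of [bulge_element()] objects.
#' @param include_scaffold append the sgRNA scaffold.
#' @param scaffold scaffold sequence used when `include_scaffold` is TRUE.
#' @return an object of class `sbh_construct` with fields `spacer`,
#'   `free_count_x`, `bulge_pattern`, `loop_unit`, `backfold`, `full_sequence`,
#'   `regions`, `scaffold_included`, and the internal pairing map.
#' @examples
#' sp <- spacer_record("demo", "GGACGCAUAAAGAUGAGACG")
#' cons <- assemble_sbh(sp, cleaving_units()$basic_loop,
#'                      bulge_pattern = default_bulge_pattern())
#' cons$full_sequence
#' @export
assemble_sbh <- function(spacer, loop_unit = cleaving_units()$basic_loop,
                         free_count_x = 0L, bulge_pattern = list(),
                         include_scaffold = FALSE,
                         scaffold = sgrna_scaffold("tracr")) {
  stopifnot(inherits(spacer, "spacer_record"))
  if (!is.null(loop_unit)) stopifnot(inherits(loop_unit, "cleaving_unit"))
  aln <- .stem_alignment(spacer$sequence, free_count_x, bulge_pattern)
  loop_seq <- if (is.null(loop_unit)) "" else loop_unit$sequence
  nb <- nchar(aln$backfold)
  nl <- nchar(loop_seq)
  L <- nchar(spacer$sequence)
  scaffold <- if (include_scaffold) normalize_rna(scaffold, "scaffold") else ""
  full <- paste0(aln$backfold, loop_seq, spacer$sequence, scaffold)
  regions <- list(backfold = c(0L, nb), loop = c(nb, nb + nl),
                  spacer = c(nb + nl, nb + nl + L))
  if (include_scaffold) {
    regions$scaffold <- c(nb + nl + L, nb + nl + L + nchar(scaffold))
  }
  structure(list(
    spacer = spacer,
    free_count_x = as.integer(free_count_x),
    bulge_pattern = .sort_bulges(bulge_pattern),
    loop_unit = loop_unit,
    backfold = aln$backfold,
    full_sequence = full,
    regions = regions,
    scaffold_included = include_scaffold,
    native_spacer_len = L,
    alignment = aln
  ), class = "sbh_construct")
}

#' @export
print.sbh_construct <- function(x, ...) {
  cat(sprintf("<sbh_construct> SBH(%d%s)%s-%s\n", x$free_count_x,
              if (length(x$bulge_pattern)) "B" else "",
              if (is.null(x$loop_unit)) "" else paste0("^", x$loop_unit$name),
              x$spacer$name))
  cat("  ", x$full_sequence, "\n", sep = "")
  cat(sprintf("  backfold %d nt | loop %d nt | spacer %d nt | pairs %d%s\n",
              nchar(x$backfold), diff(x$regions$loop),
              diff(x$regions$spacer), stem_pair_count(x),
              if (x$scaffold_included) " | + scaffold" else ""))
  invisible(x)
}

#' Extract a region slice from a construct
#' @param construct an `sbh_construct`.
#' @param region region name (`"backfold"`, `"loop"`, `"spacer"`, `"scaffold"`).
#' @return RNA substring of `full_sequence`.
#' @export
region_sequence <- function(construct, region) {
  iv <- construct$regions[[region]]
  if (is.null(iv)) stop("no region '", region, "' in construct", call. = FALSE)
  substr(construct$full_sequence, iv[1] + 1L, iv[2])
}

#' Number of paired stem positions in a construct
#' @param construct an `sbh_construct`.
#' @return integer count of base pairs in the designed stem.
#' @export
stem_pair_count <- function(construct) nrow(construct$alignment$pairs)

# Stem pairs in full-sequence coordinates (1-based), loop-proximal first.
.stem_pairs_full <- function(construct) {
  p <- construct$alignment$pairs
  nb <- nchar(construct$backfold)
  sp0 <- construct$regions$spacer[1]            # 0-based start of spacer
  data.frame(stem_index = p$stem_index,
             bf = nb - p$bf_rank + 1L,          # bf_rank 1 = 3'-most backfold nt
             sp = sp0 + p$sp_pos)
}

#' Graft a cleaving unit onto a construct
#'
#' Apex grafts replace the loop with the unit. Bulge grafts (`distal_bulge` =
#' loop-proximal bulge, `proximal_bulge` = scaffold-proximal bulge) delete the
#' stem between the apex and the chosen bulge on both strands and bridge the
#' cut points with the unit — the "medium" and "nano" geometries. The chosen
#' bulge's unpaired nucleotides are retained at the junction; bulges inside the
#' deleted span are removed with it. Stem length strictly decreases for
#' non-apex modes.
#'
#' @param construct an `sbh_construct` (without scaffold for bulge grafts the
#'   spacer record is truncated accordingly).
#' @param unit a [cleaving_unit()]; its `graft_mode` selects the geometry.
#' @return a new `sbh_construct`.
#' @export
graft_unit <- function(construct, unit) {
  stopifnot(inherits(construct, "sbh_construct"), inherits(unit, "cleaving_unit"))
  if (unit$graft_mode == "apex") {
    return(assemble_sbh(construct$spacer, unit, construct$free_count_x,
                        construct$bulge_pattern,
                        include_scaffold = construct$scaffold_included))
  }
  bulges <- construct$bulge_pattern
  if (length(bulges) == 0L) {
    stop("bulge graft mode '", unit$graft_mode,
         "' requires a bulged construct", call. = FALSE)
  }
  idx <- vapply(bulges, function(b) b$stem_index, integer(1))
  chosen <- if (unit$graft_mode == "distal_bulge") which.min(idx) else which.max(idx)
  s_star <- bulges[[chosen]]$stem_index
  if (s_star == 0L) stop("chosen bulge already at the apex", call. = FALSE)

  aln <- construct$alignment
  L <- nchar(construct$spacer$sequence)
  # spacer positions removed: those paired at stem_index < s_star, plus bulged
  # positions of other bulges lying within the deleted span
  del_paired <- aln$pairs$sp_pos[aln$pairs$stem_index < s_star]
  del_bulged <- integer(0)
  for (k in seq_along(bulges)) {
    if (k != chosen && bulges[[k]]$stem_index < s_star &&
        bulges[[k]]$strand == "spacer") {
      del_bulged <- c(del_bulged, .bulge_spacer_positions(aln, bulges[[k]]))
    }
  }
  keep <- setdiff(seq_len(L), c(del_paired, del_bulged))
  keep <- sort(keep)
  new_seq <- paste(strsplit(construct$spacer$sequence, "")[[1]][keep], collapse = "")
  # truncated spacers may fall below the 10-nt ingestion minimum; build the
  # record directly (it is a derived region, not user input)
  new_spacer <- structure(list(name = construct$spacer$name, sequence = new_seq),
                          class = "spacer_record")

  # re-indexed bulge pattern: survivors shift left by s_star
  new_bulges <- list()
  for (k in seq_along(bulges)) {
    b <- bulges[[k]]
    if (k == chosen || b$stem_index >= s_star) {
      new_bulges[[length(new_bulges) + 1L]] <-
        bulge_element(b$stem_index - s_star, b$length, b$strand, b$insert)
    }
  }
  out <- assemble_sbh(new_spacer, unit, construct$free_count_x, new_bulges,
                      include_scaffold = construct$scaffold_included)
  out$native_spacer_len <- construct$native_spacer_len
  out
}

# spacer positions occupied by a given spacer-strand bulge
.bulge_spacer_positions <- function(aln, bulge) {
  all_b <- aln$sp_bulged
  # bulge at stem_index s sits after the s-th pair: its spacer positions are
  # the bulged run immediately following pair s (or the stem start)
  prev_sp <- if (bulge$stem_index == 0L) 0L else
    aln$pairs$sp_pos[match(bulge$stem_index - 1L, aln$pairs$stem_index)]
  sort(all_b[all_b > prev_sp])[seq_len(bulge$length)]
}

#' Residual 5' nucleotides after in-silico cleavage
#'
#' Counts the nucleotides left 5' of the targeting spacer on the guide strand
#' after cleaving at the loop unit's cut site, net of the guide segment the
#' Cas protein accommodates: the retained unit tail plus the construct's
#' spacer region, minus the native spacer length (floor 0). For a full-length
#' spacer this is simply the unit tail plus any junction nucleotides; for the
#' truncated medium/nano geometries the shortened spacer absorbs part or all
#' of the tail, reproducing the full > medium > nano residual ordering.
#'
#' @param construct an `sbh_construct` whose loop unit has a `cut_offset`.
#' @return integer residual nucleotide count.
#' @export
residual_5p_nt <- function(construct) {
  unit <- construct$loop_unit
  if (is.null(unit) || is.null(unit$cut_offset)) {
    stop("construct's loop unit is not cleavable (no cut_offset)", call. = FALSE)
  }
  tail_len <- nchar(unit$sequence) - unit$cut_offset
  spacer_len <- diff(construct$regions$spacer)
  max(0L, tail_len + spacer_len - construct$native_spacer_len)
}

#' Validate the internal consistency of a construct
#'
#' Checks the invariants of the construct grammar: region slices reassemble
#' the full sequence, and every designed stem pair is Watson-Crick
#' complementary.
#'
#' @param construct an `sbh_construct`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_construct <- function(construct) {
  parts <- vapply(names(construct$regions),
                  function(r) region_sequence(construct, r), character(1))
  if (paste(parts, collapse = "") != construct$full_sequence) {
    stop("region slices do not reassemble full_sequence", call. = FALSE)
  }
  pr <- .stem_pairs_full(construct)
  ch <- strsplit(construct$full_sequence, "")[[1]]
  ok <- .COMP_RNA[ch[pr$bf]] == ch[pr$sp]
  if (!all(ok)) stop("non-complementary designed stem pair", call. = FALSE)
  invisible(TRUE)
}
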