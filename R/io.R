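#' Annealed cloning oligos for a construct
#'
#' Emits the top/bottom DNA oligo pair for Golden-Gate-style (BbsI) insertion
#' of the back-fold-loop-spacer cassette: the insert transliterated to DNA
#' with the vector overhangs, `CACC` + insert on the top strand and `AAAC` +
#' reverse complement of the insert on the bottom strand, so the annealed
#' duplex leaves exactly the two 4-nt overhangs single-stranded. With
#' `enforce_g1` the U6 +G1 rule is applied to the insert first.
#'
#' @param construct an `sbh_construct`, or a character insert sequence
#'   (RNA or DNA).
#' @param enforce_g1 prepend G when the insert does not start with one.
#' @return an object of class `oligo_pair`: `top`, `bottom`, `insert`,
#'   `overhang_top` ("CACC"), `overhang_bottom` ("AAAC").
#' @examples
#' cloning_oligos("GACT", enforce_g1 = FALSE)  # top CACCGACT, bottom AAACAGTC
#' @export
cloning_oligos <- function(construct, enforce_g1 = TRUE) {
  insert_rna <- if (inherits(construct, "sbh_construct")) {
    paste0(region_sequence(construct, "backfold"),
           region_sequence(construct, "loop"),
           region_sequence(construct, "spacer"))
  } else {
    normalize_rna(as.character(construct), "insert")
  }
  if (nchar(insert_rna) == 0L) stop("empty cloning insert", call. = FALSE)
  if (enforce_g1) insert_rna <- apply_u6_g(insert_rna)
  insert <- rna_to_dna(insert_rna)
  structure(list(top = paste0("CACC", insert),
                 bottom = paste0("AAAC", revcomp_dna(insert)),
                 insert = insert,
                 overhang_top = "CACC", overhang_bottom = "AAAC"),
            class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat("<oligo_pair>\n  top:    5'-", x$top, "-3'\n  bottom: 5'-", x$bottom,
      "-3'\n", sep = "")
  invisible(x)
}

#' Antisense oligonucleotides against a sensing loop
#'
#' DNA ASOs complementary to the loop, at the footprints used for induction:
#' 14 nt (core only), 20 nt (full loop) and 25 nt (extended 3 nt into the
#' back-fold-side stem and 2 nt into the spacer-side stem to favour strand
#' separation).
#'
#' @param construct an `sbh_construct` whose loop unit wraps an [asl()].
#' @param lengths ASO lengths to emit (subset of 14/20/25).
#' @return named character vector of DNA ASOs (5'->3').
#' @export
design_asos <- function(construct, lengths = c(14L, 20L, 25L)) {
  stopifnot(inherits(construct, "sbh_construct"))
  u <- construct$loop_unit
  if (is.null(u) || is.null(u$asl)) {
    stop("construct's loop unit is not an ASO-sensing loop", call. = FALSE)
  }
  lo <- construct$regions$loop
  full <- construct$full_sequence
  target14 <- substr(full, lo[1] + 4L, lo[1] + 3L + nchar(u$asl$core))
  target20 <- substr(full, lo[1] + 1L, lo[2])
  target25 <- substr(full, max(1L, lo[1] - 2L), min(nchar(full), lo[2] + 2L))
  out <- c(`14` = revcomp_dna(rna_to_dna(target14)),
           `20` = revcomp_dna(rna_to_dna(target20)),
           `25` = revcomp_dna(rna_to_dna(target25)))
  out[as.character(lengths)]
}

#' Read spacers from FASTA or plain text
#'
#' FASTA input is detected by a leading `>`; otherwise the file is read as
#' one sequence per line (optionally `name<TAB>sequence`). DNA is
#' transliterated to RNA; duplicate names and out-of-range lengths are
#' rejected.
#'
#' @param path file path.
#' @return list of [spacer_record()] objects.
#' @export
read_spacers <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty spacer file: ", path, call. = FALSE)
  if (startsWith(first, ">")) {
    set <- Biostrings::readBStringSet(path)
    names_ <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    named <- lengths(parts) >= 2L
    names_ <- sprintf("spacer_%d", seq_along(lines))
    names_[named] <- vapply(parts[named], `[[`, "", 1L)
    seqs <- vapply(parts, `[[`, "", 1L)
    seqs[named] <- vapply(parts[named], `[[`, "", 2L)
  }
  if (anyDuplicated(names_)) {
    stop("duplicate spacer name: ", names_[duplicated(names_)][1], call. = FALSE)
  }
  mapply(spacer_record, names_, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Generate random spacers
#'
#' Fixture generator: independent random 20-mers with expected GC content
#' `gc_target` (G/C and A/U drawn evenly within their class). Reproducible
#' under `set.seed()`.
#'
#' @param n number of spacers (>= 1).
#' @param gc_target expected GC fraction in \[0, 1\].
#' @param length spacer length.
#' @param prefix name prefix.
#' @return list of [spacer_record()] objects.
#' @export
synth_spacers <- function(n, gc_target = 0.5, length = 20L, prefix = "synth") {
  stopifnot(n >= 1L, gc_target >= 0, gc_target <= 1)
  lapply(seq_len(n), function(i) {
    b <- sample(c("G", "C", "A", "U"), length, replace = TRUE,
                prob = c(gc_target / 2, gc_target / 2,
                         (1 - gc_target) / 2, (1 - gc_target) / 2))
    spacer_record(sprintf("%s_%d", prefix, i), paste(b, collapse = ""))
  })
}

#' Write a report to disk
#'
#' Serializes a `series_report` or `ga_result` (or any data.frame with the
#' corresponding columns). Formats: `tsv` (stable documented columns),
#' `json` (lossless round-trip of the table), `fasta` (entry sequences), and
#' `vienna` (sequence line, dot-bracket line, "(mfe)" suffix; requires
#' `structure` and `mfe_kcal_mol` columns).
#'
#' @param report data.frame-like report.
#' @param path output file.
#' @param format one of `"tsv"`, `"json"`, `"fasta"`, `"vienna"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json", "fasta", "vienna")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  switch(format,
    tsv = utils::write.table(df, path, sep = "\t", quote = FALSE,
                             row.names = FALSE),
    json = jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                                pretty = TRUE),
    fasta = {
      seqs <- if ("sequence" %in% names(df)) df$sequence else df$asl
      ids <- if ("x_or_offset" %in% names(df)) {
        sprintf("entry_%s", df$x_or_offset)
      } else {
        sprintf("entry_%d", seq_len(nrow(df)))
      }
      writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
    },
    vienna = {
      if (!all(c("sequence", "structure", "mfe_kcal_mol") %in% names(df))) {
        stop("vienna format needs sequence/structure/mfe_kcal_mol columns",
             call. = FALSE)
      }
      writeLines(as.vector(rbind(
        df$sequence,
        sprintf("%s (%.2f)", df$structure, df$mfe_kcal_mol))), path)
    }
  )
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path JSON file path.
#' @return data.frame.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Write constructs as annotated FASTA
#'
#' One record per construct; the description line carries the region
#' coordinates (0-based half-open) so the file round-trips the construct
#' anatomy.
#'
#' @param constructs list of `sbh_construct` objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_constructs_fasta <- function(constructs, path) {
  lines <- unlist(lapply(constructs, function(cons) {
    ann <- paste(vapply(names(cons$regions), function(r) {
      iv <- cons$regions[[r]]
      sprintf("%s=%d:%d", r, iv[1], iv[2])
    }, character(1)), collapse = " ")
    c(sprintf(">%s x=%d %s", cons$spacer$name, cons$free_count_x, ann),
      cons$full_sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' JSON dump of a construct record
#'
#' Serializes the construct anatomy — spacer, coverage, bulge pattern, loop
#' unit, back-fold, full sequence and region coordinates — as JSON.
#'
#' @param construct an `sbh_construct`.
#' @param path output file, or NULL to return the JSON string.
#' @return `path` invisibly, or the JSON string when `path` is NULL.
#' @export
construct_to_json <- function(construct, path = NULL) {
  stopifnot(inherits(construct, "sbh_construct"))
  rec <- list(
    spacer = list(name = construct$spacer$name,
                  sequence = construct$spacer$sequence),
    free_count_x = construct$free_count_x,
    bulge_pattern = lapply(construct$bulge_pattern, function(b) {
      list(stem_index = b$stem_index, length = b$length, strand = b$strand)
    }),
    loop_unit = if (is.null(construct$loop_unit)) NULL else
      list(name = construct$loop_unit$name,
           sequence = construct$loop_unit$sequence,
           cut_offset = construct$loop_unit$cut_offset,
           graft_mode = construct$loop_unit$graft_mode),
    backfold = construct$backfold,
    full_sequence = construct$full_sequence,
    regions = construct$regions,
    scaffold_included = construct$scaffold_included,
    stem_pairs = stem_pair_count(construct)
  )
  if (is.null(path)) {
    return(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                         digits = NA)))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' JSON snapshot of inputs, configuration, seed and engine version —
#' sufficient to regenerate a run's outputs byte-identically.
#'
#' @param path output JSON path.
#' @param config a [ga_config()] or any named list.
#' @param inputs named list describing inputs (e.g. spacer names/sequences).
#' @param engine a [fold_engine()].
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = list(),
                               engine = fold_engine()) {
  manifest <- list(
    package = "sbhdesign",
    package_version = as.character(utils::packageVersion("sbhdesign")),
    engine = list(name = engine$name, version = engine$version,
                  temperature_c = engine$temperature_c),
    config = unclass(config),
    inputs = inputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
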