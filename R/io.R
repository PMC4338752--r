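#' Read a phoneme alignment table
#'
#' Alignment files are UTF-8, tab-delimited with a header and columns
#' `phoneme`, `onset`, `offset`, `word` (times in seconds, word is the
#' 1-based index of the containing word). Rows must be sorted by onset with
#' `onset < offset`; symbols are validated against the inventory.
#'
#' @param path Path to a tab-delimited alignment file.
#' @param feature_table Feature table used to validate phoneme symbols.
#' @return A tibble with columns `phoneme`, `onset`, `offset`, `word`.
#' @export
read_alignments <- function(path, feature_table = build_feature_table()) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      phoneme = readr::col_character(),
      onset = readr::col_double(),
      offset = readr::col_double(),
      word = readr::col_integer()
    )
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop("malformed alignment file ", path, ": row ", probs$row[1],
         " (", probs$expected[1], ")")
  }
  validate_alignments(tab, feature_table)
  tab
}

validate_alignments <- function(tab, feature_table = build_feature_table()) {
  need <- c("phoneme", "onset", "offset", "word")
  if (!all(need %in% names(tab))) {
    stop("alignment table must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(tab$onset >= tab$offset)
  if (length(bad) > 0) {
    stop("alignment row ", bad[1], ": onset (", tab$onset[bad[1]],
         ") is not before offset (", tab$offset[bad[1]], ")")
  }
  if (is.unsorted(tab$onset)) stop("alignment rows must be sorted by onset")
  unknown <- which(!(tab$phoneme %in% feature_table$phoneme))
  if (length(unknown) > 0) {
    stop("unknown phoneme symbol(s) at row(s) ",
         paste(utils::head(unknown, 5), collapse = ", "), ": ",
         paste(unique(tab$phoneme[unknown]), collapse = ", "))
  }
  invisible(tab)
}

#' @rdname read_alignments
#' @param alignments Alignment tibble to write.
#' @export
write_alignments <- function(alignments, path) {
  validate_alignments(alignments)
  readr::write_tsv(alignments, path)
  invisible(path)
}

#' Read or write a word-boundary table
#'
#' Word files are tab-delimited with columns `word` (orthographic form or
#' placeholder), `onset`, `offset` in seconds. Used by the speech-vs-silence
#' screening to place word-locked and silence epochs.
#'
#' @param path File path.
#' @return A tibble with columns `word`, `onset`, `offset`.
#' @export
read_words <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      word = readr::col_character(),
      onset = readr::col_double(),
      offset = readr::col_double()
    )
  )
  if (any(tab$onset >= tab$offset)) stop("word boundaries must have onset < offset")
  tab
}

#' @rdname read_words
#' @param words Word-boundary tibble to write.
#' @export
write_words <- function(words, path) {
  readr::write_tsv(words, path)
  invisible(path)
}

#' Read or write a recording container
#'
#' A recording (channels-by-samples data with sampling rate, grid membership
#' and optional electrode coordinates) is stored as a single-file container
#' holding the named components `data`, `fs`, `grid`, `coords`. The reader
#' re-validates all invariants.
#'
#' @param path File path (`.rds`).
#' @return For `read_recording`, an `ecog_recording`.
#' @export
read_recording <- function(path) {
  obj <- readRDS(path)
  new_recording(obj$data, fs = obj$fs, grid = obj$grid, coords = obj$coords)
}

#' @rdname read_recording
#' @param rec An `ecog_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ecog_recording"))
  saveRDS(unclass(rec), path)
  invisible(path)
}
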