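#' Segmental-feature dimensions recognised by the pipeline
#'
#' Seven binary feature dimensions plus `"vowel"` (the complement of
#' `"consonant"`, offered so the phonological contrast can be run with the
#' vowel class as the positive class) and `"all"` (every phoneme positive;
#' used by the simulator for speech-locked effects that are not feature
#' specific).
#'
#' @format Character vector.
#' @export
feature_dimensions <- c(
  "labial", "coronal", "dorsal",
  "obstruent", "sonorant",
  "voiced", "consonant", "vowel"
)

# ARPAbet symbols with IPA display forms; the General American inventory:
# 24 consonants and 15 vowels.
.consonants <- c(
  p = "p", b = "b", t = "t", d = "d", k = "k", g = "g",
  ch = "tʃ", jh = "dʒ",
  f = "f", v = "v", th = "θ", dh = "ð",
  s = "s", z = "z", sh = "ʃ", zh = "ʒ", hh = "h",
  m = "m", n = "n", ng = "ŋ",
  l = "l", r = "r", w = "w", y = "j"
)
.vowels <- c(
  iy = "i", ih = "ɪ", eh = "ɛ", ae = "æ",
  aa = "ɑ", ah = "ə", ao = "ɔ",
  uw = "u", uh = "ʊ", er = "ɝ",
  ay = "aɪ", ey = "eɪ", aw = "aʊ",
  ow = "oʊ", oy = "ɔɪ"
)

#' Phoneme inventory
#'
#' The compiled General American phoneme inventory used throughout the
#' package: 24 consonants and 15 vowels, ARPAbet coded with IPA display
#' forms. A given recording or stimulus set may use any subset.
#'
#' @return A tibble with columns `phoneme` (ARPAbet code), `ipa` (display
#'   form) and `class` (`"consonant"` or `"vowel"`).
#' @export
#' @examples
#' phoneme_inventory()
phoneme_inventory <- function() {
  tibble::tibble(
    phoneme = c(names(.consonants), names(.vowels)),
    ipa = unname(c(.consonants, .vowels)),
    class = rep(c("consonant", "vowel"), c(length(.consonants), length(.vowels)))
  )
}

#' Per-phoneme segmental-feature table
#'
#' Binary (+/-) assignment of every inventory phoneme to the segmental
#' feature dimensions: place of articulation (labial, coronal, dorsal),
#' manner (obstruent vs. sonorant), voicing, and phonological class
#' (consonant vs. vowel). A phoneme may carry several "+" features at once
#' (e.g. /w/ is both labial and dorsal); vowels carry no place feature.
#'
#' Two printed-source inconsistencies are resolved by standard English
#' phonology: /z/ and /ʒ/ are voiced, /ʃ/ is voiceless. /h/ is
#' classed as a (voiceless) obstruent so that the obstruent/sonorant
#' partition is exhaustive.
#'
#' @return A tibble with one row per phoneme and logical columns `labial`,
#'   `coronal`, `dorsal`, `obstruent`, `sonorant`, `voiced`, `consonant`.
#' @export
#' @examples
#' ft <- build_feature_table()
#' sum(ft$consonant)   # 24
#' sum(!ft$consonant)  # 15
build_feature_table <- function() {
  inv <- phoneme_inventory()
  labial_set   <- c("b", "p", "f", "v", "m", "w")
  coronal_set  <- c("t", "d", "th", "dh", "s", "z", "sh", "zh", "n",
                    "ch", "jh", "r", "l", "y")
  dorsal_set   <- c("k", "g", "w")
  obstruent_set <- c("p", "b", "t", "d", "k", "g", "ch", "jh",
                     "f", "v", "th", "dh", "s", "z", "sh", "zh", "hh")
  voiced_cons <- c("b", "d", "g", "v", "dh", "z", "zh", "jh",
                   "m", "n", "ng", "l", "r", "w", "y")
  tibble::tibble(
    phoneme = inv$phoneme,
    ipa = inv$ipa,
    labial = inv$phoneme %in% labial_set,
    coronal = inv$phoneme %in% coronal_set,
    dorsal = inv$phoneme %in% dorsal_set,
    obstruent = inv$phoneme %in% obstruent_set,
    sonorant = !(inv$phoneme %in% obstruent_set),
    voiced = inv$class == "vowel" | inv$phoneme %in% voiced_cons,
    consonant = inv$class == "consonant"
  )
}

#' Label alignment rows along one feature dimension
#'
#' Tags every phoneme occurrence in an alignment table with "+" or "-"
#' according to whether the phoneme carries the requested segmental
#' feature. `"vowel"` is the complement of `"consonant"`; `"all"` labels
#' every row "+".
#'
#' @param alignments Alignment tibble as returned by [read_alignments()] or
#'   [sample_alignments()]: columns `phoneme`, `onset`, `offset`, `word`.
#' @param feature_table Feature table from [build_feature_table()].
#' @param dimension One of [feature_dimensions] or `"all"`.
#' @return The alignment tibble with an added `label` column, factor with
#'   levels `-`, `+` ("+" is the positive class throughout the package).
#' @export
label_for_feature <- function(alignments, feature_table = build_feature_table(),
                              dimension) {
  dimension <- match.arg(dimension, c(feature_dimensions, "all"))
  unknown <- setdiff(unique(alignments$phoneme), feature_table$phoneme)
  if (length(unknown) > 0) {
    stop("phonemes not in the feature table: ", paste(unknown, collapse = ", "))
  }
  pos <- if (dimension == "all") {
    rep(TRUE, nrow(alignments))
  } else if (dimension == "vowel") {
    !feature_table$consonant[match(alignments$phoneme, feature_table$phoneme)]
  } else {
    feature_table[[dimension]][match(alignments$phoneme, feature_table$phoneme)]
  }
  dplyr::mutate(
    alignments,
    label = factor(ifelse(pos, "+", "-"), levels = c("-", "+"))
  )
}
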