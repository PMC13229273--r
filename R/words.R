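#' The eight-word CVC stimulus set
#'
#' Returns the consonant-vowel-consonant word set used throughout the
#' paradigm, with the positional phoneme transcription of each word. The set
#' forms a factorial grid: initial consonant (/b/, /r/) is fully crossed with
#' vowel (/i:/, /u:/), and the final consonant is nested within the initial
#' (b-words end in /m/ or /t/, r-words in /l/ or /f/). Vowels are transcribed
#' as monophthongs so that vowel sharing is a clean 2 x 2 factor.
#'
#' @return A tibble with one row per word and columns `word`, `initial`,
#'   `vowel`, `final`.
#' @export
#' @examples
#' word_set()
word_set <- function() {
  tibble::tibble(
    word    = c("beam", "beat", "boom", "boot", "real", "reef", "rule", "roof"),
    initial = c("b", "b", "b", "b", "r", "r", "r", "r"),
    vowel   = c("i:", "i:", "u:", "u:", "i:", "i:", "u:", "u:"),
    final   = c("m", "t", "m", "t", "l", "f", "l", "f")
  )
}

phoneme_positions <- function() c("initial", "vowel", "final")

#' Count phonemes shared between two words, by position
#'
#' Compares two CVC words position by position (initial consonant, vowel,
#' final consonant) and counts the positions at which the phoneme labels are
#' identical. This is the similarity primitive behind the Shared Phonemes
#' dissimilarity model.
#'
#' @param word_a,word_b Word orthographies (character, vectorised and
#'   recycled).
#' @param words Word table with positional transcriptions, as returned by
#'   [word_set()].
#' @return Integer vector of counts in 0..3.
#' @export
#' @examples
#' shared_phoneme_count("beam", "beat")  # share /b/ and /i:/
#' shared_phoneme_count("beam", "rule")  # nothing shared
shared_phoneme_count <- function(word_a, word_b, words = word_set()) {
  ia <- match(word_a, words$word)
  ib <- match(word_b, words$word)
  if (anyNA(ia) || anyNA(ib)) {
    abort("unknown word: not in the supplied word set")
  }
  out <- (words$initial[ia] == words$initial[ib]) +
    (words$vowel[ia] == words$vowel[ib]) +
    (words$final[ia] == words$final[ib])
  as.integer(out)
}
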