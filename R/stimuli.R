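#' Default pseudoword stimulus set
#'
#' The four Dutch pseudowords crossing phonotactic probability (the medial
#' cluster *-ts-* is high-probability, *-tk-* low-probability) with syllable
#' stress (first vs. second syllable stressed, upper case marking the stressed
#' syllable). Every stimulus lasts 600 ms; for formal (cluster) deviants the
#' acoustic deviation begins at the /t/-onset 250 ms into the word, for
#' temporal (stress) deviants at word onset.
#'
#' @param duration_ms Stimulus duration in ms.
#' @param deviation_onset_formal_ms Onset of the formal (phonotactic)
#'   deviation relative to stimulus onset, ms.
#' @param deviation_onset_temporal_ms Onset of the temporal (stress)
#'   deviation relative to stimulus onset, ms.
#'
#' @return A tibble with one row per stimulus: `id`, `phonprob` (`"HPP"` /
#'   `"LPP"`), `sylstr` (`"SylStr1"` / `"SylStr2"`), `duration_ms`,
#'   `deviation_onset_formal_ms`, `deviation_onset_temporal_ms`.
#' @export
#' @examples
#' stimulus_set()
stimulus_set <- function(duration_ms = 600,
                         deviation_onset_formal_ms = 250,
                         deviation_onset_temporal_ms = 0) {
  stopifnot(duration_ms > 0,
            deviation_onset_formal_ms >= 0,
            deviation_onset_formal_ms < duration_ms,
            deviation_onset_temporal_ms >= 0,
            deviation_onset_temporal_ms < duration_ms)
  tibble::tibble(
    id = c("NOTsal", "NOTkal", "notSAL", "notKAL"),
    phonprob = c("HPP", "LPP", "HPP", "LPP"),
    sylstr = c("SylStr1", "SylStr1", "SylStr2", "SylStr2"),
    duration_ms = duration_ms,
    deviation_onset_formal_ms = deviation_onset_formal_ms,
    deviation_onset_temporal_ms = deviation_onset_temporal_ms
  )
}

check_stimulus_crossing <- function(stimuli) {
  if (!is.data.frame(stimuli) || nrow(stimuli) != 4L) {
    stop("`stimuli` must contain exactly 4 stimuli (full 2x2 crossing).",
         call. = FALSE)
  }
  cells <- paste(stimuli$phonprob, stimuli$sylstr)
  want <- c("HPP SylStr1", "LPP SylStr1", "HPP SylStr2", "LPP SylStr2")
  if (anyDuplicated(stimuli$id) || !setequal(cells, want) ||
      anyDuplicated(cells)) {
    stop("`stimuli` must form a full 2x2 phonprob x sylstr crossing ",
         "with unique ids.", call. = FALSE)
  }
  invisible(stimuli)
}

#' Corpus frequencies of the manipulated features
#'
#' Summed INL word-frequency counts for bisyllabic Dutch words containing the
#' medial consonant clusters *-ts-* / *-tk-* and the two stress patterns,
#' either over all bisyllabic words or restricted to a CVCCVC syllable
#' structure, together with ratios recomputed from the counts. These
#' frequencies motivate the high/low predictability labels: first-syllable
#' stress dominates bisyllabic Dutch (~80%), and second-syllable stress is
#' rare (~6%) among CVCCVC words.
#'
#' @return A tibble with columns `scope` (`"AllBiSyl"`, `"CVCCVC"`),
#'   `ts_freq`, `tk_freq`, `sylstr1_freq`, `sylstr2_freq`, and the recomputed
#'   `phonprob_ratio` (ts/tk), `stress_ratio` (SylStr1/SylStr2),
#'   `sylstr1_share` and `sylstr2_share` (proportions of the stress total).
#' @export
#' @examples
#' feature_frequency_table()
feature_frequency_table <- function() {
  tbl <- tibble::tibble(
    scope = c("AllBiSyl", "CVCCVC"),
    ts_freq = c(94061, 12270),
    tk_freq = c(7787, NA_real_),
    sylstr1_freq = c(7633058, 292794),
    sylstr2_freq = c(1926345, 18817)
  )
  dplyr::mutate(
    tbl,
    phonprob_ratio = .data$ts_freq / .data$tk_freq,
    stress_ratio = .data$sylstr1_freq / .data$sylstr2_freq,
    sylstr1_share = .data$sylstr1_freq /
      (.data$sylstr1_freq + .data$sylstr2_freq),
    sylstr2_share = .data$sylstr2_freq /
      (.data$sylstr1_freq + .data$sylstr2_freq)
  )
}

#' Cross-condition identity map for difference waves
#'
#' In the multi-feature oddball design every stimulus serves as the standard
#' of one condition and reappears as a formal deviant (other cluster, same
#' stress) and a temporal deviant (same cluster, other stress) in two other
#' conditions. Difference waves compare the *identical* stimulus across
#' conditions, so each (condition, deviant role) cell maps to the condition
#' in which that deviant stimulus is the standard.
#'
#' @param stimuli Stimulus table as from [stimulus_set()]; must be a full
#'   2x2 phonprob x sylstr crossing.
#'
#' @return A tibble with 8 rows: `condition` (standard stimulus id), `role`
#'   (`"FD"` / `"TD"`), `deviant` (deviant stimulus id) and `maps_to` (the
#'   condition whose standard is that identical stimulus; always equal to
#'   `deviant`).
#' @export
#' @examples
#' build_identity_map(stimulus_set())
build_identity_map <- function(stimuli = stimulus_set()) {
  check_stimulus_crossing(stimuli)
  other <- function(x, levels) levels[levels != x]
  rows <- purrr::map_dfr(seq_len(nrow(stimuli)), function(i) {
    std <- stimuli[i, ]
    fd <- stimuli$id[stimuli$phonprob == other(std$phonprob, c("HPP", "LPP")) &
                       stimuli$sylstr == std$sylstr]
    td <- stimuli$id[stimuli$phonprob == std$phonprob &
                       stimuli$sylstr == other(std$sylstr,
                                               c("SylStr1", "SylStr2"))]
    tibble::tibble(condition = std$id, role = c("FD", "TD"),
                   deviant = c(fd, td))
  })
  dplyr::mutate(rows, maps_to = .data$deviant)
}
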