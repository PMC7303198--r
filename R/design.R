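#' Default trial tallies for one oddball condition
#'
#' One condition block set comprises 1,620 trials: 1,332 standards plus 144
#' formal and 144 temporal deviants (8.9% per deviant type), presented over
#' 2 sessions x 3 runs x 4 blocks of 270 trials.
#'
#' @return Named integer vector with elements `SD`, `FD`, `TD`.
#' @export
design_counts <- function() {
  c(SD = 1332L, FD = 144L, TD = 144L)
}

#' Generate a pseudorandom oddball condition sequence
#'
#' Builds the ordered trial list for one condition: a frequent standard
#' stimulus interspersed with formal (FD) and temporal (TD) deviants, with
#' 1 to 8 standards between any two successive deviants. Under
#' `balanced = TRUE` each deviant type's inter-deviant separations are
#' allocated equally over `sep_range` (at the defaults, 144 deviants per type
#' / 8 separations = 18 per separation) and shuffled; otherwise separations
#' are drawn uniformly and repaired so the standard tally is met exactly.
#' Standards not consumed as separators are appended after the last deviant.
#'
#' @param standard Stimulus id used as the condition's standard.
#' @param deviants Named character vector `c(FD = , TD = )` giving the
#'   deviant stimulus ids (see [build_identity_map()]).
#' @param counts Named integer vector `c(SD = , FD = , TD = )`; defaults to
#'   [design_counts()]. A deviant type with count 0 is omitted.
#' @param sep_range Integer pair, minimum and maximum number of standards
#'   between successive deviants (default `c(1, 8)`).
#' @param trial_duration_ms Trial duration (stimulus onset asynchrony), ms.
#' @param seed Integer seed; the sequence is reproducible given the seed.
#' @param balanced Allocate separations equally over `sep_range` per deviant
#'   type (default `TRUE`).
#' @param n_tokens Number of recorded utterance variants per stimulus; a
#'   token is drawn uniformly per trial.
#'
#' @return A tibble of class `oddball_sequence` with columns `index`,
#'   `onset_ms`, `stimulus`, `role` (`"SD"`, `"FD"`, `"TD"`), `condition`,
#'   `token`, and attributes `condition`, `trial_duration_ms`, `seed`,
#'   `sep_range`.
#' @export
#' @examples
#' seq <- generate_condition_sequence("NOTsal",
#'   c(FD = "NOTkal", TD = "notSAL"), seed = 1)
#' table(seq$role)
generate_condition_sequence <- function(standard,
                                        deviants,
                                        counts = design_counts(),
                                        sep_range = c(1L, 8L),
                                        trial_duration_ms = 1200,
                                        seed = 1L,
                                        balanced = TRUE,
                                        n_tokens = 3L) {
  stopifnot(is.character(standard), length(standard) == 1L)
  counts <- counts[c("SD", "FD", "TD")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must supply non-negative SD, FD and TD tallies.",
         call. = FALSE)
  }
  if (sep_range[1] < 1L) {
    stop("Minimum deviant separation must be at least 1 standard.",
         call. = FALSE)
  }
  if (sep_range[2] < sep_range[1]) {
    stop("`sep_range` must be non-decreasing.", call. = FALSE)
  }
  n_dev <- sum(counts[c("FD", "TD")])
  if (n_dev > 0 && !all(deviants[names(counts[c("FD", "TD")])[
    counts[c("FD", "TD")] > 0]] != "")) {
    stop("Deviant stimulus ids missing.", call. = FALSE)
  }
  if (n_dev * sep_range[1] > counts[["SD"]]) {
    stop("Infeasible design: ", n_dev, " deviants need at least ",
         n_dev * sep_range[1], " separating standards but only ",
         counts[["SD"]], " standards are available.", call. = FALSE)
  }

  seps_for <- function(n, balanced) {
    if (n == 0L) return(integer(0))
    bins <- seq.int(sep_range[1], sep_range[2])
    if (balanced) {
      if (n %% length(bins) != 0L) {
        stop("Balanced separation allocation needs the deviant count (", n,
             ") to be a multiple of the number of separations (",
             length(bins), ").", call. = FALSE)
      }
      rep(bins, each = n %/% length(bins))
    } else {
      sample(bins, n, replace = TRUE)
    }
  }

  withr::with_seed(seed, {
    slots <- tibble::tibble(
      role = rep(c("FD", "TD"), times = counts[c("FD", "TD")]),
      sep = c(seps_for(counts[["FD"]], balanced),
              seps_for(counts[["TD"]], balanced))
    )
    if (nrow(slots) > 0) {
      slots <- slots[sample.int(nrow(slots)), ]
      if (balanced && sum(slots$sep) > counts[["SD"]]) {
        stop("Infeasible design: balanced separations need ",
             sum(slots$sep), " separating standards but only ",
             counts[["SD"]], " are available.", call. = FALSE)
      }
      if (!balanced) {
        # repair so separators never exceed the standard budget
        over <- sum(slots$sep) - counts[["SD"]]
        while (over > 0) {
          i <- sample(which(slots$sep > sep_range[1]), 1L)
          slots$sep[i] <- slots$sep[i] - 1L
          over <- over - 1L
        }
      }
    }
    roles <- character(0)
    for (i in seq_len(nrow(slots))) {
      roles <- c(roles, rep("SD", slots$sep[i]), slots$role[i])
    }
    roles <- c(roles, rep("SD", counts[["SD"]] - sum(slots$sep)))
    stim <- ifelse(roles == "SD", standard,
                   ifelse(roles == "FD", deviants[["FD"]], deviants[["TD"]]))
    out <- tibble::tibble(
      index = seq_along(roles),
      onset_ms = (seq_along(roles) - 1) * trial_duration_ms,
      stimulus = stim,
      role = roles,
      condition = standard,
      token = sample.int(n_tokens, length(roles), replace = TRUE)
    )
    out <- tibble::new_tibble(out, class = "oddball_sequence")
    attr(out, "condition") <- standard
    attr(out, "trial_duration_ms") <- trial_duration_ms
    attr(out, "seed") <- seed
    attr(out, "sep_range") <- as.integer(sep_range)
    out
  })
}

#' Inter-deviant separations of a sequence
#'
#' Number of standards between successive deviants (the first deviant is
#' preceded by the standards since block start).
#'
#' @param seq An `oddball_sequence` (or any tibble with `role`).
#' @param by_role Tally separations per deviant type rather than pooled.
#' @return A tibble with `role` (if `by_role`), `separation`, `n`.
#' @export
deviant_separations <- function(seq, by_role = FALSE) {
  dev_idx <- which(seq$role != "SD")
  prev <- c(0L, dev_idx[-length(dev_idx)])
  sep <- dev_idx - prev - 1L
  tbl <- tibble::tibble(role = seq$role[dev_idx], separation = sep)
  if (by_role) {
    dplyr::count(tbl, .data$role, .data$separation, name = "n")
  } else {
    dplyr::count(tbl, .data$separation, name = "n")
  }
}

#' Validate an oddball sequence against the design invariants
#'
#' Report-only checks: tallies match the requested counts, all inter-deviant
#' separations lie within `sep_range`, the block begins with at least one
#' standard, onsets fall on the trial grid, standards carry the condition's
#' standard stimulus, and the total is divisible into 270-trial blocks.
#'
#' @param seq An `oddball_sequence`.
#' @param counts Expected tallies (default [design_counts()]).
#' @param sep_range Allowed separation range (default taken from the
#'   sequence attribute, else `c(1, 8)`).
#' @param block_length Trials per block for the partition check (270; use
#'   `NA` to skip).
#'
#' @return A tibble with one row per check: `check`, `pass`,
#'   `first_fail_index` (NA when passing), `detail`.
#' @export
validate_sequence <- function(seq, counts = design_counts(),
                              sep_range = attr(seq, "sep_range") %||% c(1L, 8L),
                              block_length = 270L) {
  td <- attr(seq, "trial_duration_ms") %||%
    (if (nrow(seq) > 1) diff(seq$onset_ms[1:2]) else 1200)
  tal <- c(SD = sum(seq$role == "SD"), FD = sum(seq$role == "FD"),
           TD = sum(seq$role == "TD"))
  res <- list()
  add <- function(check, pass, first_fail = NA_integer_, detail = "") {
    res[[length(res) + 1L]] <<- tibble::tibble(
      check = check, pass = pass, first_fail_index = as.integer(first_fail),
      detail = detail)
  }

  bad_tal <- names(counts)[tal[names(counts)] != counts]
  add("tallies", length(bad_tal) == 0L,
      if (length(bad_tal)) which(seq$role == bad_tal[1])[1] else NA,
      paste0("SD=", tal[["SD"]], " FD=", tal[["FD"]], " TD=", tal[["TD"]]))

  seps <- deviant_separations(seq)
  dev_idx <- which(seq$role != "SD")
  if (length(dev_idx)) {
    prev <- c(0L, dev_idx[-length(dev_idx)])
    raw_sep <- dev_idx - prev - 1L
    bad <- which(raw_sep < sep_range[1] | raw_sep > sep_range[2])
    add("separations", length(bad) == 0L,
        if (length(bad)) dev_idx[bad[1]] else NA,
        paste0("range ", min(raw_sep), "-", max(raw_sep)))
    add("starts_with_standard", seq$role[1] == "SD",
        if (seq$role[1] != "SD") 1L else NA)
  } else {
    add("separations", TRUE, NA, "no deviants")
    add("starts_with_standard", nrow(seq) == 0L || seq$role[1] == "SD",
        if (nrow(seq) > 0 && seq$role[1] != "SD") 1L else NA)
  }

  off_grid <- which(seq$onset_ms %% td != 0)
  add("onsets_on_grid", length(off_grid) == 0L,
      if (length(off_grid)) off_grid[1] else NA)

  bad_std <- which(seq$role == "SD" & seq$stimulus != seq$condition)
  add("standard_stimulus", length(bad_std) == 0L,
      if (length(bad_std)) bad_std[1] else NA)

  if (!is.na(block_length)) {
    add("block_partition", nrow(seq) %% block_length == 0L, NA,
        paste0(nrow(seq), " trials / ", block_length, " per block"))
  }
  dplyr::bind_rows(res)
}

#' Generate the four condition sequences of one participant
#'
#' One sequence per condition, with deviant identities taken from the
#' identity map and per-condition seeds derived from `seed`.
#'
#' @inheritParams generate_condition_sequence
#' @param stimuli Stimulus table ([stimulus_set()]).
#' @return Named list of `oddball_sequence`, one per condition.
#' @export
generate_participant_sequences <- function(stimuli = stimulus_set(),
                                           counts = design_counts(),
                                           sep_range = c(1L, 8L),
                                           trial_duration_ms = 1200,
                                           seed = 1L,
                                           balanced = TRUE) {
  imap <- build_identity_map(stimuli)
  conds <- stimuli$id
  out <- purrr::map(seq_along(conds), function(i) {
    cond <- conds[i]
    dv <- imap[imap$condition == cond, ]
    generate_condition_sequence(
      standard = cond,
      deviants = c(FD = dv$deviant[dv$role == "FD"],
                   TD = dv$deviant[dv$role == "TD"]),
      counts = counts, sep_range = sep_range,
      trial_duration_ms = trial_duration_ms,
      seed = derive_seed(seed, i), balanced = balanced)
  })
  stats::setNames(out, conds)
}

#' Export a sequence as a TSV event table
#'
#' @param seq An `oddball_sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sequence_tsv <- function(seq, path) {
  utils::write.table(as.data.frame(seq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a sequence as a BrainVision-style marker file
#'
#' Writes a `.vmrk` text file with one `Stimulus` marker per trial at the
#' trial-onset sample.
#'
#' @param seq An `oddball_sequence`.
#' @param path Output `.vmrk` file.
#' @param srate_hz Sampling rate used to convert onsets to sample positions.
#' @param data_file Value for the `DataFile` header field.
#' @return `path`, invisibly.
#' @export
write_sequence_vmrk <- function(seq, path, srate_hz = 1000,
                                data_file = "") {
  lines <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", data_file),
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,S %s/%s/%d,%d,1,0",
            seq$index, seq$role, seq$stimulus, seq$token,
            round(seq$onset_ms / 1000 * srate_hz) + 1L)
  )
  writeLines(lines, path)
  invisible(path)
}
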