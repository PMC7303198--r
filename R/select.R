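#' Select analysis trials from an epoched condition block
#'
#' Applies the deviant/standard selection rules: a deviant is kept iff it
#' was preceded by at least two standards since the previous deviant and
#' survived artifact rejection; a standard is kept iff it immediately
#' precedes a kept deviant and itself survived rejection (if that standard
#' was rejected the deviant is retained and no replacement is sought).
#' Under the balanced default design with no artifact rejections this
#' retains 126 deviants per type and 252 standards per condition.
#'
#' @param ep An `eeg_epochs` object aligned to `seq` (same trial order).
#' @param seq The `oddball_sequence` the epochs were recorded for.
#' @return A selection tibble: `trial`, `condition`, `stimulus`, `role`,
#'   `selected`, `reason` (`"separation"`, `"artifact"`,
#'   `"not_preceding_deviant"`, or `NA` for selected trials).
#' @export
select_analysis_trials <- function(ep, seq) {
  if (nrow(ep$metadata) != nrow(seq)) {
    stop("Epochs (", nrow(ep$metadata), ") and sequence (", nrow(seq),
         ") have different trial counts.", call. = FALSE)
  }
  n <- nrow(seq)
  role <- seq$role
  kept_art <- ep$metadata$kept
  dev_idx <- which(role != "SD")
  prev_dev <- c(0L, dev_idx[-length(dev_idx)])
  separation <- dev_idx - prev_dev - 1L

  selected <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  reason[role == "SD"] <- "not_preceding_deviant"

  for (j in seq_along(dev_idx)) {
    i <- dev_idx[j]
    if (separation[j] < 2L) {
      reason[i] <- "separation"
    } else if (!kept_art[i]) {
      reason[i] <- "artifact"
    } else {
      selected[i] <- TRUE
      std <- i - 1L
      if (kept_art[std]) {
        selected[std] <- TRUE
        reason[std] <- NA_character_
      } else {
        reason[std] <- "artifact"
      }
    }
  }
  tibble::tibble(
    trial = seq_len(n),
    condition = seq$condition,
    stimulus = seq$stimulus,
    role = role,
    selected = selected,
    reason = dplyr::if_else(selected, NA_character_, reason)
  )
}

#' Equalize selected-trial counts across conditions
#'
#' Computes the participant's global minimum of kept-deviant counts over all
#' 8 deviant cells (4 conditions x FD/TD) and subsamples, without
#' replacement and seeded, every deviant cell to exactly that number and
#' every condition's standard pool to the same number. The standard subset
#' is drawn once per condition and shared between the FD and TD comparisons.
#'
#' @param selections Named list of selection tibbles (one per condition,
#'   from [select_analysis_trials()]), or a single bound tibble with a
#'   `condition` column.
#' @param seed Integer seed for the subsampling.
#' @return A tibble like the input (bound across conditions) with an
#'   `analysis` logical column marking the equalized final trial set, plus
#'   attribute `n_equalized`.
#' @export
equalize_counts <- function(selections, seed = 1L) {
  tbl <- if (is.data.frame(selections)) selections
         else dplyr::bind_rows(selections)
  dev <- dplyr::filter(tbl, .data$selected, .data$role != "SD")
  cells <- dplyr::count(dev, .data$condition, .data$role)
  all_cells <- tidyr::expand_grid(condition = unique(tbl$condition),
                                  role = c("FD", "TD"))
  cells <- dplyr::left_join(all_cells, cells,
                            by = c("condition", "role"))
  cells$n[is.na(cells$n)] <- 0L
  if (any(cells$n == 0L)) {
    bad <- cells[cells$n == 0L, ][1, ]
    stop("No selected trials in cell ", bad$condition, "/", bad$role,
         "; cannot equalize counts.", call. = FALSE)
  }
  n_eq <- min(cells$n)
  tbl$analysis <- FALSE
  withr::with_seed(seed, {
    for (cond in unique(tbl$condition)) {
      for (r in c("FD", "TD")) {
        idx <- which(tbl$condition == cond & tbl$role == r & tbl$selected)
        tbl$analysis[idx[sample.int(length(idx), n_eq)]] <- TRUE
      }
      std_idx <- which(tbl$condition == cond & tbl$role == "SD" &
                         tbl$selected)
      if (length(std_idx) < n_eq) {
        stop("Standard pool for condition ", cond, " (",
             length(std_idx), ") is smaller than the equalized count (",
             n_eq, ").", call. = FALSE)
      }
      tbl$analysis[std_idx[sample.int(length(std_idx), n_eq)]] <- TRUE
    }
  })
  attr(tbl, "n_equalized") <- n_eq
  tbl
}
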