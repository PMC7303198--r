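#' Electrode montages
#'
#' `default_montage()` returns the full 63-channel recording setup: 57 scalp
#' electrodes on 10%-system positions, left/right mastoids (M1, M2) for
#' offline re-referencing, and 4 EOG channels. `scaled_montage()` is the
#' reduced 16-channel profile used for fast simulation studies (10 scalp
#' channels covering the frontocentral and centroparietal rows, mastoids,
#' 4 EOG).
#'
#' Scalp positions are schematic 2D grid coordinates (`x` left-right in
#' 10%-steps, `y` anterior-posterior by row) sufficient to model the
#' frontocentral falloff of the mismatch response; they are not digitized
#' 3D locations.
#'
#' @return A tibble with columns `name`, `type` (`"scalp"`, `"mastoid"`,
#'   `"eog"`), `x`, `y`.
#' @export
default_montage <- function() {
  rows <- list(
    Fp = list(y = 4, ch = c("Fp1", "Fpz", "Fp2")),
    AF = list(y = 3, ch = c("AF3", "AFz", "AF4")),
    F  = list(y = 2, ch = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    FC = list(y = 1, ch = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
    C  = list(y = 0, ch = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    CP = list(y = -1, ch = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
    P  = list(y = -2, ch = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    PO = list(y = -3, ch = c("PO3", "POz", "PO4")),
    O  = list(y = -4, ch = c("O1", "Oz", "O2"))
  )
  scalp <- purrr::map_dfr(rows, function(r) {
    n <- length(r$ch)
    tibble::tibble(name = r$ch, type = "scalp",
                   x = seq(-(n - 1) / 2, (n - 1) / 2), y = r$y)
  })
  aux <- tibble::tibble(
    name = c("M1", "M2", "HEOG_L", "HEOG_R", "VEOG_U", "VEOG_D"),
    type = c("mastoid", "mastoid", "eog", "eog", "eog", "eog"),
    x = c(-5, 5, -5, 5, 0.5, 0.5),
    y = c(0, 0, 4, 4, 5, 5)
  )
  dplyr::bind_rows(scalp, aux)
}

#' @rdname default_montage
#' @export
scaled_montage <- function() {
  m <- default_montage()
  keep <- c("Fz", "F1", "F2", "FCz", "FC1", "FC2",
            "Cz", "CPz", "CP1", "CP2",
            "M1", "M2", "HEOG_L", "HEOG_R", "VEOG_U", "VEOG_D")
  m[match(keep, m$name), ]
}

#' Frontocentral topography weights
#'
#' Spatial weight map of the simulated event-related components: a Gaussian
#' radial falloff from a peak electrode (FCz for the MMN), normalized so the
#' peak has weight 1. Mastoid and EOG channels receive fixed weights
#' (default 0), making the average-mastoid reference neutral for the
#' simulated signal.
#'
#' @param montage Montage tibble ([default_montage()]).
#' @param peak Name of the peak electrode.
#' @param falloff Gaussian spatial scale in grid units (larger = flatter).
#' @param mastoid_weight,eog_weight Fixed weights for non-scalp channels.
#' @return Numeric vector of weights in `[-1, 1]`, named by channel.
#' @export
topography_weights <- function(montage = default_montage(), peak = "FCz",
                               falloff = 2.5, mastoid_weight = 0,
                               eog_weight = 0) {
  stopifnot(peak %in% montage$name)
  p <- montage[montage$name == peak, ]
  d2 <- (montage$x - p$x)^2 + (montage$y - p$y)^2
  w <- exp(-d2 / (2 * falloff^2))
  w[montage$type == "mastoid"] <- mastoid_weight
  w[montage$type == "eog"] <- eog_weight
  stats::setNames(w, montage$name)
}

#' Regions of interest for MMN amplitude measures
#'
#' Frontocentral and centroparietal electrode sets used for mean-amplitude
#' analysis. `scaled` returns the reduced sets matching [scaled_montage()].
#'
#' @param scaled Use the reduced 16-channel profile's ROIs.
#' @return Named list with character vectors `frontocentral` and
#'   `centroparietal`.
#' @export
mmn_rois <- function(scaled = FALSE) {
  if (scaled) {
    list(frontocentral = c("Fz", "F1", "F2", "FCz", "FC1", "FC2"),
         centroparietal = c("Cz", "CPz", "CP1", "CP2"))
  } else {
    list(
      frontocentral = c("Fz", "F1", "F2", "F3", "F4",
                        "FCz", "FC1", "FC2", "FC3", "FC4"),
      centroparietal = c("Cz", "C1", "C2", "C3", "C4",
                         "CPz", "CP1", "CP2", "CP3", "CP4")
    )
  }
}
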