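#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

ms_to_sample <- function(ms, srate_hz) {
  as.integer(round(ms / 1000 * srate_hz))
}

# derive a child seed from a master seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
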