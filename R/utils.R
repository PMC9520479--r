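#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

# trapezoidal integral over the axis
trapz_integral <- function(wavenumber, intensity) {
  pracma::trapz(wavenumber, intensity)
}

# derive a bounded sub-seed from a base seed and a stream label,
# so independent stages consume independent, reproducible streams
sub_seed <- function(seed, stream) {
  offsets <- c(design = 11L, amplitude = 23L, fluorescence = 41L,
               ambient = 59L, noise = 73L, saturation = 97L, split = 131L,
               gain = 151L)
  if (!stream %in% names(offsets)) rlang::abort(paste0("unknown RNG stream: ", stream))
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}
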