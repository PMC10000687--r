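# shared instrument profiles for tests

# ideal continuous detector: no noise, no background, no quantization
instr_noiseless <- function(image_size_px = 512, ...) {
  instrument_profile(photon_noise = FALSE, read_noise_sd = 0,
                     background_level = 0, image_size_px = image_size_px,
                     ...)
}

# noise off but 8-bit quantization forced on: isolates quantization error
instr_quantized <- function(image_size_px = 512, ...) {
  instrument_profile(photon_noise = FALSE, read_noise_sd = 0,
                     background_level = 0, image_size_px = image_size_px,
                     quantize = TRUE, ...)
}

all_valid <- function(pair) matrix(TRUE, nrow(pair$co), ncol(pair$co))
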