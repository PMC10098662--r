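# shared fixtures: small constructed images and scenes

const_image <- function(value, h = 8, w = 10, role = "calibrated",
                        bit_depth = NULL) {
  m <- matrix(value, h, w)
  multispectral_image(list(blue = m, green = m, red = m, nir = m),
                      role = role, bit_depth = bit_depth)
}

make_image <- function(blue, green, red, nir, role = "calibrated",
                       bit_depth = NULL) {
  multispectral_image(list(blue = blue, green = green, red = red, nir = nir),
                      role = role, bit_depth = bit_depth)
}

random_image <- function(h, w, seed = 1, role = "calibrated", scale = 1) {
  withr::with_seed(seed, {
    bands <- lapply(1:4, function(i) matrix(runif(h * w) * scale, h, w))
  })
  names(bands) <- c("blue", "green", "red", "nir")
  multispectral_image(bands, role = role)
}

# small fast scene for unit tests
quick_scene_params <- function(seed = 1, ...) {
  scene_params(height = 128, width = 160, seed = seed, ...)
}

# end-to-end condition: ~10% true thread occlusion at reduced resolution
e2e_scene_params <- function(seed = 1, ...) {
  scene_params(height = 256, width = 320, thread_spacing = 40, seed = seed, ...)
}
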