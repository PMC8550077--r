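# Shared tiny fixtures for fast tests.

tiny_spec <- function(variant = "res2net") {
  backbone_spec(variant, channels = c(8L, 8L, 16L, 16L, 32L),
                res2net_scale = 4L, res2net_width = 2L)
}

tiny_model <- function(variant = "res2net", seed = 42L) {
  set.seed(seed)
  ppa_unet(tiny_spec(variant), reduce = 8L)
}

# the single-sample overfit fixture: thick wide crescent on a 64-px canvas
overfit_params <- function() {
  synth_params(canvas_size = 64L, disc_radius_range = c(10, 12),
               ppa_width_fraction_range = c(0.5, 0.65),
               crescent_angular_span = c(300, 340),
               vessel_count = 3L, blur_sigma = 0.8)
}

overfit_config <- function(seed = 102L, out_dir = tempfile("fit_")) {
  train_config(input_size = 96L, backbone = tiny_spec(), epochs = 1000L,
               batch_size = 1L, learning_rate = 8e-3, seed = seed,
               reduce = 8L, weight_kernel = 7L, output_dir = out_dir)
}

rand_tensor <- function(h, w, c, sd = 1) {
  ppaseg:::pt_const(array(stats::rnorm(h * w * c, sd = sd), dim = c(h, w, c)))
}

random_binary_matrix <- function(h, w, p = 0.4) {
  matrix(stats::rbinom(h * w, 1, p), h, w)
}
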