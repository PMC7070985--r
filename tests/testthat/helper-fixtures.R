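# Shared fixtures: small deterministic objects built in code.

tiny_grid <- function() electrode_grid(2, 3)

random_recording <- function(grid = electrode_grid(8, 16), frames = 100,
                             fs = 1000, seed = 1, meta = list(gesture = 0L)) {
  set.seed(seed)
  recording(matrix(rnorm(grid$rows * grid$cols * frames),
                   grid$rows * grid$cols, frames),
            fs = fs, grid = grid, meta = meta)
}

# a [0,1] image sequence with a constant label, deterministic
unit_sequence <- function(len = 40, h = 4, w = 5, fs = 1000, label = 0L,
                          seed = 1) {
  set.seed(seed)
  image_sequence(array(runif(len * h * w), c(len, h, w)), fs, label = label)
}

# tiny trainable spec (temporal trace 10 -> 8 -> 6 -> 3 -> 1 -> 1)
tiny_spec <- function(G = 2) {
  build_3d_cnn(c(10, 5, 7), pool_s = 2, G = G, n_kernels = c(2, 4, 4),
               fc = c(12, 8))
}

new_spec_for_test <- function(layers, input_shape, G) {
  emg3d:::new_network_spec(input_shape, layers, G)
}

# two-class linearly separable cube dataset
separable_cubes <- function(n = 200, seed = 3) {
  set.seed(seed)
  cubes <- array(runif(10 * 5 * 7 * n) * 0.1, c(10, 5, 7, n))
  labels <- rep(0:1, each = n / 2)
  cubes[, 1:2, 1:2, labels == 1] <- cubes[, 1:2, 1:2, labels == 1] + 0.5
  cube_dataset(cubes, labels, 10L, 1L, 1000, "train")
}
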