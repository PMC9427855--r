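# Shared fixtures: tiny configurations that keep unit tests fast. The
# full-size desk cohort (n = 150, 32x40x32) is only built in the acceptance
# tests.

tiny_config <- function(n_subjects = 12L, seed = 101L, ...) {
  synthetic_config(grid_shape = c(16L, 20L, 16L), voxel_size_mm = 2,
                   n_subjects = n_subjects, seed = seed, ...)
}

tiny_atlas_regions <- function() {
  # two spheres inside the mask of a 16x20x16 grid
  data.frame(
    label = 1:2, name = c("a", "b"), role = c("reference", "effect_low"),
    cx = c(0.5, 0.5), cy = c(0.33, 0.66), cz = c(0.45, 0.55),
    r = c(0.12, 0.12), stringsAsFactors = FALSE
  )
}

# a small random volume on a given grid
random_volume <- function(dim = c(8L, 8L, 8L), seed = 1, voxel = 1) {
  set.seed(seed)
  new_volume(array(runif(prod(dim)), dim), voxel_size_mm = voxel)
}

# small random network for gradient checks
small_net_config <- function(seed, activation = "softplus") {
  cnn_config(channels = c(2L, 3L), dense = 4L, activation = activation,
             seed = seed)
}

random_instance <- function(seed, input_dim = c(8L, 8L, 8L),
                            activation = "softplus") {
  cfg <- small_net_config(seed, activation)
  net <- build_network(input_dim, cfg, seed = seed)
  structure(list(net = net, config = cfg, fold = 1L,
                 input_dim = input_dim, target_center = 0,
                 target_scale = 1),
            class = "taucl_instance")
}

# brute-force dense 3D convolution of the whole network is impractical;
# instead tests use finite differences and small closed-form cases.
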