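# Shared fixtures, all generated in code.

rand_fm <- function(n, c, h, w, seed = 1) {
  set.seed(seed)
  feature_map(rnorm(n * c * h * w), dim = c(n, c, h, w))
}

# a slimmed network for fast engine tests (identical wiring, fewer filters);
# double precision so finite-difference checks are meaningful
tiny_config <- function(precision = "double") {
  network_config(input_size = c(8L, 8L), stem_filters = c(4L, 4L),
                 branchA_filters = 4L, branchB_filters = c(4L, 4L),
                 fusion_head_filters = c(4L, 2L), sa_groups = 1L,
                 precision = precision)
}

small_phantom <- function(seed = 1, size = 96L, ...) {
  generate_phantom(phantom_config(size = c(size, size), seed = seed, ...))
}
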