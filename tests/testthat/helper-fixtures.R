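# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# A normal walker with a 20-frame cycle, masks and poses only.
walker_normal <- function() fixture("walker_normal", function() {
  generate_walker_sequence(walker_config("normal", frames_per_cycle = 20L,
                                         n_cycles = 3L, seed = 7L),
                           render_frames = FALSE)
})

# A short rendered sequence (RGB frames) for segmentation tests.
walker_rendered <- function() fixture("walker_rendered", function() {
  generate_walker_sequence(walker_config("normal", frames_per_cycle = 10L,
                                         n_cycles = 1L, frame_height = 160L,
                                         seed = 11L))
})

as_silhouettes <- function(sq) {
  gaitkit:::new_silhouette_sequence(sq$masks, fps = 10)
}

# Tiny five-conv-layer configuration for fast model tests; same topology,
# shrunk input and widths.
tiny_model_config <- function(seed = 1L, ...) {
  model_config(input_size = 16L, channels = 2L,
               conv_channels = c(2L, 2L, 2L, 3L, 3L),
               dense_units = c(8L, 3L), classes = c("a", "b", "c"),
               dropout = 0, batch_size = 4L, seed = seed, ...)
}

# A small separable 3-class image set for the tiny config: class-dependent
# bright quadrants plus noise.
tiny_image_set <- function(n_per_class = 6L, seed = 5L) {
  gaitkit:::with_seed(seed, {
    imgs <- list(); labels <- character(0)
    for (cl in 1:3) {
      for (i in seq_len(n_per_class)) {
        m <- matrix(stats::runif(256, 0, 0.2), 16L, 16L)
        rows <- ((cl - 1L) * 5L + 1L):((cl - 1L) * 5L + 5L)
        m[rows, 4:12] <- m[rows, 4:12] + 0.7
        imgs[[length(imgs) + 1L]] <- pmin(m, 1)
        labels <- c(labels, c("a", "b", "c")[cl])
      }
    }
    list(images = imgs, labels = labels)
  })
}

# A linear toy classifier: flatten + dense over a single-channel input.
linear_toy <- function(W, size = 8L, classes = c("a", "b", "c")) {
  dense <- gaitkit:::layer_dense(size * size, length(classes))
  dense$W <- W
  cfg <- model_config(input_size = size, channels = 1L,
                      conv_channels = c(1L, 1L, 1L, 1L, 1L),
                      dense_units = c(2L, length(classes)), classes = classes)
  structure(list(net = list(gaitkit:::layer_flatten(), dense),
                 config = cfg, classes = classes, history = NULL),
            class = "gait_classifier")
}

# Reduced-scale cross-validation sets: 56 x 56 energy images, 10 synthetic
# subjects per class (studio domain) and a noisier shifted-scale domain.
cv56_set <- function() fixture("cv56", function() {
  full <- synthetic_training_set(n_per_class = 10, seed = 77, n_cycles = 2L)
  full$representations <- lapply(full$representations, shrink_representation, 56L)
  full
})

cv56_noisy_set <- function() fixture("cv56_noisy", function() {
  full <- synthetic_training_set(n_per_class = 4, seed = 91, n_cycles = 2L,
                                 mask_noise = 0.01, scale_range = c(0.8, 0.95))
  full$representations <- lapply(full$representations, shrink_representation, 56L)
  full
})

# Downscale a gait representation to a smaller square (for reduced-scale
# classifier experiments).
shrink_representation <- function(rep, size) {
  px <- gaitkit:::from_ebimage(EBImage::resize(gaitkit:::as_ebimage(rep$pixels),
                                               w = size, h = size))
  px <- pmin(pmax(px, 0), 1)
  structure(list(kind = rep$kind, pixels = px, scope = rep$scope,
                 cycle = rep$cycle, n_frames = rep$n_frames),
            class = "gait_representation")
}
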