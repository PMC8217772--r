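# Shared in-code fixtures: ellipsoid masks, smooth blob images, tiny
# dynamic images. Everything is generated at test time.

ellipsoidMask <- function(n, semi, center = (n + 1) / 2) {
  if (length(n) == 1L) n <- rep(n, 3L)
  if (length(center) == 1L) center <- rep(center, 3L)
  idx <- which(array(TRUE, n), arr.ind = TRUE)
  el <- ((idx[, 1] - center[1]) / semi[1])^2 +
        ((idx[, 2] - center[2]) / semi[2])^2 +
        ((idx[, 3] - center[3]) / semi[3])^2 <= 1
  m <- array(FALSE, n)
  m[idx[el, , drop = FALSE]] <- TRUE
  m
}

# smooth two-bump image, good for intensity-based registration
blobImage <- function(n = 40, spacing = c(1000, 1000, 1000)) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  c1 <- n * c(0.5, 0.52, 0.5); c2 <- n * c(0.66, 0.42, 0.62)
  v <- exp(-(((g$x - c1[1]) / (n * 0.2))^2 + ((g$y - c1[2]) / (n * 0.14))^2 +
             ((g$z - c1[3]) / (n * 0.25))^2)) +
       0.5 * exp(-(((g$x - c2[1]) / (n * 0.08))^2 +
                   ((g$y - c2[2]) / (n * 0.08))^2 +
                   ((g$z - c2[3]) / (n * 0.08))^2))
  VolumeImage(array(v, c(n, n, n)), spacing)
}

# rotate/translate array content (thin wrapper over the package internal)
moveArray <- function(arr, angles = c(0, 0, 0), trans = c(0, 0, 0),
                      linear = TRUE) {
  petquant:::rotateTranslateArray(array(as.double(arr), dim(arr)), angles,
                                  trans, linear = linear)
}

smallDynamic <- function(dims = c(10, 10, 14), nframes = 2, value = 1,
                         spacing = c(1000, 1000, 1000)) {
  fs <- frameTable((seq_len(nframes) - 1) * 600, seq_len(nframes) * 600)
  DynamicImage(array(value, c(dims, nframes)), spacing, fs)
}

smallPipelineConfig <- function(outDir, seed = 11L) {
  list(output_dir = outDir, tracer_mode = "metabolic", seed = seed,
       mode = "phantom", n_animals = 3L, states = c("healthy", "stroke"),
       group_effects = list(stroke = list(cortex = 0.7)),
       pet_dim = c(48L, 48L, 60L), n_frames = 3L,
       intervals = list(c(0, 30), c(0, 10)),
       reference_region = "cerebellum",
       deformable_iterations = 40L, plots = FALSE)
}
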