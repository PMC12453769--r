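# Seed-reproducible synthetic peripheral-blood-smear generator.
#
# Each image holds one stained lymphoid cell of interest (plus anuclear
# red-cell distractors) on a pale background.  The class signal is
# cytological and measurable: the nucleus-to-cell area ratio is drawn
# from pairwise-disjoint per-class ranges, with class-specific chromatin
# texture amplitude and nucleolus count as secondary cues.  The nucleus
# mask is the ground truth for segmentation; benign cells (hematogones)
# also have nuclei, so their masks are non-empty too -- the class signal
# is morphology, not mask emptiness.

#' The four smear classes, in canonical order
#' @return Character vector c("Benign", "Early-B", "Pre-B", "Pro-B").
#' @export
smear_classes <- function() c("Benign", "Early-B", "Pre-B", "Pro-B")

#' Default synthetic-smear parameters
#'
#' @param image_size Pixels per side (square images).
#' @param cells_per_image Range (min, max) of cells per image: one
#'   lymphoid cell of interest plus red-cell distractors.
#' @param noise_sd Additive Gaussian pixel noise, clipped to [0, 1].
#' @param seed Integer seed; fully determines the generated data.
#' @param class_morphology Per-class list of `ratio` (nucleus-to-cell
#'   area ratio range, pairwise disjoint across classes), `chromatin`
#'   (texture amplitude) and `nucleoli` (count).
#' @return Parameter list accepted by [generate_dataset()].
#' @export
synthetic_params <- function(image_size = 224L,
                             cells_per_image = c(3L, 6L),
                             noise_sd = 0.02,
                             seed = 1L,
                             class_morphology = default_morphology()) {
  p <- list(image_size = as.integer(image_size),
            cells_per_image = as.integer(cells_per_image),
            noise_sd = noise_sd, seed = as.integer(seed),
            class_morphology = class_morphology)
  validate_synthetic_params(p)
  p
}

default_morphology <- function() {
  list(
    "Benign"  = list(ratio = c(0.20, 0.30), chromatin = 0.02, nucleoli = 0L),
    "Early-B" = list(ratio = c(0.38, 0.48), chromatin = 0.05, nucleoli = 1L),
    "Pre-B"   = list(ratio = c(0.56, 0.66), chromatin = 0.08, nucleoli = 2L),
    "Pro-B"   = list(ratio = c(0.74, 0.84), chromatin = 0.11, nucleoli = 3L)
  )
}

validate_synthetic_params <- function(p) {
  if (p$image_size < 16) stop_invalid("image_size must be >= 16")
  if (length(p$cells_per_image) != 2 || any(p$cells_per_image < 1) ||
      p$cells_per_image[1] > p$cells_per_image[2])
    stop_invalid("cells_per_image must be a valid (min, max) range")
  ranges <- lapply(p$class_morphology, `[[`, "ratio")
  for (r in ranges) {
    if (length(r) != 2 || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1)
      stop_invalid("degenerate nucleus-to-cell ratio range")
  }
  n <- length(ranges)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && ranges[[i]][1] < ranges[[j]][2] &&
        ranges[[j]][1] < ranges[[i]][2])
      stop_invalid("per-class ratio ranges must be pairwise disjoint")
  }
  invisible(p)
}

disc_mask <- function(S, cx, cy, r) {
  xs <- matrix(seq_len(S), S, S)
  ys <- matrix(seq_len(S), S, S, byrow = TRUE)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

paint <- function(img, mask, col) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask] <- col[ch]
    img[, , ch] <- pl
  }
  img
}

# one sample; consumes the current RNG stream
draw_sample <- function(label, params, sample_id) {
  S <- params$image_size
  morph <- params$class_morphology[[label]]
  # warm white-pink background; red dominance >> noise_sd so the
  # blue-dominant cell measurement is unambiguous
  img <- array(0, c(S, S, 3))
  img[, , 1] <- 0.97; img[, , 2] <- 0.92; img[, , 3] <- 0.87

  # anuclear red-cell distractors (pinkish, never blue-dominant)
  n_extra <- sample(params$cells_per_image[1]:params$cells_per_image[2], 1) - 1L
  for (k in seq_len(n_extra)) {
    r <- stats::runif(1, 0.05, 0.09) * S
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.30, 0.46) * S
    cx <- S / 2 + rad * cos(ang); cy <- S / 2 + rad * sin(ang)
    m <- disc_mask(S, cx, cy, r)
    shade <- stats::runif(1, -0.04, 0.04)
    img <- paint(img, m, c(0.93 + shade, 0.72 + shade, 0.76 + shade))
    inner <- disc_mask(S, cx, cy, r * 0.55)   # central pallor
    img <- paint(img, inner, c(0.96 + shade, 0.82 + shade, 0.84 + shade))
  }

  # the lymphoid cell of interest: blue-dominant cytoplasm + dark nucleus
  r_cell <- stats::runif(1, 0.16, 0.20) * S
  cx <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  cy <- S / 2 + stats::runif(1, -0.05, 0.05) * S
  cell <- disc_mask(S, cx, cy, r_cell)
  img <- paint(img, cell, c(0.62, 0.70, 0.90))

  ratio <- stats::runif(1, morph$ratio[1], morph$ratio[2])
  r_nuc <- r_cell * sqrt(ratio)
  nuc <- disc_mask(S, cx, cy, r_nuc)
  img <- paint(img, nuc, c(0.38, 0.25, 0.55))

  # chromatin texture inside the nucleus
  if (morph$chromatin > 0) {
    tex <- matrix(stats::rnorm(S * S, 0, morph$chromatin), S, S)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[nuc] <- pl[nuc] + tex[nuc]
      img[, , ch] <- pl
    }
  }
  # nucleoli: small pale spots within the nucleus
  for (k in seq_len(morph$nucleoli)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.5) * r_nuc
    m <- disc_mask(S, cx + rad * cos(ang), cy + rad * sin(ang),
                   max(1.5, 0.12 * r_nuc))
    m <- m & nuc
    img <- paint(img, m, c(0.55, 0.42, 0.68))
  }

  if (params$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
  img <- pmin(pmax(img, 0), 1)

  list(image = img, mask = nuc * 1, label = label, sample_id = sample_id)
}

#' Generate a balanced synthetic smear dataset
#'
#' Draws `n` samples with labels assigned round-robin over the four
#' classes.  Output is fully determined by `params$seed`.
#'
#' @param params Parameters from [synthetic_params()].
#' @param n Number of samples (>= 1).
#' @return list(samples = list of SmearSample, manifest = data.frame with
#'   sample_id and label).
#' @export
generate_dataset <- function(params, n) {
  if (n < 1) stop_invalid("n must be >= 1")
  validate_synthetic_params(params)
  cls <- smear_classes()
  samples <- with_seed(params$seed, {
    lapply(seq_len(n), function(i) {
      label <- cls[((i - 1L) %% 4L) + 1L]
      draw_sample(label, params, sprintf("s%04d", i))
    })
  })
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    label = vapply(samples, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}

#' Measured nucleus-to-cell area ratio of a sample
#'
#' Nucleus area is the mask foreground; cell area is the count of
#' blue-dominant pixels (blue channel exceeding red), which by
#' construction isolates the lymphoid cell from background and red-cell
#' distractors.
#'
#' @param sample SmearSample.
#' @return Scalar ratio in (0, 1).
#' @export
nucleus_area_ratio <- function(sample) {
  cell <- sum(sample$image[, , 3] > sample$image[, , 1])
  if (cell == 0) return(NA_real_)
  sum(sample$mask) / cell
}

#' Rescale and resize an 8-bit image into the model input range
#'
#' Divides pixel values by 255 into [0, 1] and, if needed, resizes to
#' `target_size` x `target_size` (bilinear, via EBImage).
#'
#' @param image H x W x 3 array with integer values in [0, 255].
#' @param target_size Output side length in pixels (default 224).
#' @return target_size x target_size x 3 array in [0, 1].
#' @export
preprocess <- function(image, target_size = 224L) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop_invalid("expected a 3-channel image, got dims %s",
                 paste(d, collapse = "x"))
  if (any(image < 0 | image > 255))
    stop_invalid("pixel values must lie in [0, 255]")
  img <- image / 255
  if (d[1] != target_size || d[2] != target_size) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("EBImage is required to resize images", call. = FALSE)
    img <- EBImage::imageData(
      EBImage::resize(EBImage::Image(img, colormode = "Color"),
                      w = target_size, h = target_size))
    img <- array(img, c(target_size, target_size, 3))
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

#' Spatially augment a sample
#'
#' Applies the same exact spatial map (no interpolation) to image and
#' mask; the label is unchanged.
#'
#' @param sample SmearSample.
#' @param op One of "rotate90", "rotate180", "rotate270", "hflip",
#'   "vflip".
#' @return Augmented SmearSample.
#' @export
augment <- function(sample, op) {
  f <- switch(op,
    rotate90 = function(m) {         # 90 degrees counter-clockwise
      if (length(dim(m)) == 3) aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE]
      else t(m)[ncol(m):1, , drop = FALSE]
    },
    rotate180 = function(m) {
      if (length(dim(m)) == 3) m[dim(m)[1]:1, dim(m)[2]:1, , drop = FALSE]
      else m[nrow(m):1, ncol(m):1, drop = FALSE]
    },
    rotate270 = function(m) {
      if (length(dim(m)) == 3) aperm(m, c(2, 1, 3))[, dim(m)[1]:1, , drop = FALSE]
      else t(m)[, nrow(m):1, drop = FALSE]
    },
    hflip = function(m) {
      if (length(dim(m)) == 3) m[, dim(m)[2]:1, , drop = FALSE]
      else m[, ncol(m):1, drop = FALSE]
    },
    vflip = function(m) {
      if (length(dim(m)) == 3) m[dim(m)[1]:1, , , drop = FALSE]
      else m[nrow(m):1, , drop = FALSE]
    },
    stop_invalid("unknown augmentation op '%s'", op))
  sample$image <- f(sample$image)
  sample$mask <- f(sample$mask)
  sample
}

#' Split sample ids into train / validation / test
#'
#' Sizes follow floor(f_val * n) and floor(f_test * n) with the remainder
#' assigned to training, after a seed-determined shuffle.
#'
#' @param ids Vector of sample ids (length >= 3).
#' @param fractions Length-3 (train, val, test) fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param seed Shuffle seed.
#' @return list(train_ids, val_ids, test_ids, fractions).
#' @export
split_dataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_invalid("fractions must sum to 1")
  if (any(fractions < 0)) stop_invalid("fractions must be non-negative")
  n <- length(ids)
  if (n < 3) stop_invalid("need at least 3 ids to split")
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  shuffled <- ids[perm]
  list(train_ids = shuffled[seq_len(n_train)],
       val_ids = shuffled[n_train + seq_len(n_val)],
       test_ids = shuffled[n_train + n_val + seq_len(n_test)],
       fractions = fractions)
}
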