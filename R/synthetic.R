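#' Generate a synthetic three-class lung-image fixture
#'
#' Emulates the structure of a small lung CT benchmark (default 35
#' normal / 32 benign / 33 malignant samples) with three visually
#' distinguishable low-level texture regimes on a shared smooth
#' background field:
#'
#' * **normal** — the smooth low-intensity field alone;
#' * **benign** — one bright isotropic Gaussian blob with a regular
#'   boundary near the image centre, plus a mild global intensity lift;
#' * **malignant** — several smaller anisotropic high-gradient blobs at
#'   random positions, plus a larger intensity lift.
#'
#' `separability` scales every class-specific term: at 0 the three
#' classes are statistically identical; at the default 1 a
#' nearest-centroid rule on raw pixels separates them comfortably.
#' Pixel noise is i.i.d. Gaussian with `noise_sd`; images are clipped to
#' \[0, 1\]. Per-class mean intensity is ordered normal < benign <
#' malignant for any seed (at positive separability). Deterministic
#' under `seed`.
#'
#' @param class_counts Integer triple (normal, benign, malignant);
#'   default `c(35, 32, 33)`.
#' @param image_size Side length in pixels (default 64).
#' @param separability Non-negative scalar, class-signal gain
#'   (default 1).
#' @param noise_sd Pixel noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `label` and the
#'   list-column `image` (matrices in \[0, 1\]).
#' @examples
#' d <- generate_lung_images(class_counts = c(4, 3, 3), image_size = 32, seed = 1)
#' table(d$label)
#' @export
generate_lung_images <- function(class_counts = c(35L, 32L, 33L),
                                 image_size = 64L,
                                 separability = 1,
                                 noise_sd = 0.05,
                                 seed = 1L) {
  if (length(class_counts) != 3L || any(class_counts < 1L)) {
    abort("`class_counts` must be three positive integers (normal, benign, malignant).")
  }
  if (separability < 0) abort("`separability` must be non-negative.")
  s <- as.integer(image_size)
  rng <- rng_stream(derive_seed(seed, "lung_images"))
  labels <- rep(c("normal", "benign", "malignant"), times = class_counts)
  xg <- matrix(rep(seq_len(s), each = s), nrow = s)        # column index
  yg <- matrix(rep(seq_len(s), times = s), nrow = s)       # row index

  base_field <- function() {
    # smooth low-frequency background shared by all classes
    fx <- rng$runif(1, 0.5, 1.5) * 2 * pi / s
    fy <- rng$runif(1, 0.5, 1.5) * 2 * pi / s
    px <- rng$runif(1, 0, 2 * pi)
    py <- rng$runif(1, 0, 2 * pi)
    0.25 + 0.04 * (sin(fx * xg + px) + cos(fy * yg + py))
  }
  gauss_blob <- function(cx, cy, sx, sy, amp) {
    amp * exp(-(((xg - cx)^2) / (2 * sx^2) + ((yg - cy)^2) / (2 * sy^2)))
  }

  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    img <- base_field()
    if (labels[i] == "benign") {
      cx <- s / 2 + rng$runif(1, -s / 8, s / 8)
      cy <- s / 2 + rng$runif(1, -s / 8, s / 8)
      sigma <- rng$runif(1, s / 10, s / 7)
      img <- img + separability * (0.04 + gauss_blob(cx, cy, sigma, sigma, 0.5))
    } else if (labels[i] == "malignant") {
      n_blobs <- 3L + rng$sample(0:2, 1L)
      for (b in seq_len(n_blobs)) {
        cx <- rng$runif(1, s / 6, 5 * s / 6)
        cy <- rng$runif(1, s / 6, 5 * s / 6)
        sx <- rng$runif(1, s / 24, s / 12)
        sy <- sx * rng$runif(1, 0.4, 2.5)       # irregular: anisotropic
        img <- img + separability * gauss_blob(cx, cy, sx, sy, rng$runif(1, 0.3, 0.5))
      }
      img <- img + separability * 0.10
    }
    img <- img + matrix(rng$rnorm(s * s, sd = noise_sd), nrow = s)
    images[[i]] <- clip(img, 0, 1)
  }

  tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(labels)),
    label = labels,
    image = images
  )
}

#' Stratified train/test split plan
#'
#' Allocates each class's samples to train and test by a per-class
#' shuffle so per-class proportions are within one sample of the global
#' fraction. A `table_matching` mode instead fixes the test-set class
#' counts to those implied by the published lungdb metric tables —
#' (8, 5, 7) at fraction 0.8 and (13, 9, 8) at fraction 0.7 for classes
#' (normal, benign, malignant) — so that worked-example evaluations
#' share those denominators.
#'
#' @param labels Vector of class labels.
#' @param train_fraction Fraction of samples in the training split,
#'   strictly inside (0, 1); conventional choices are 0.8 and 0.7.
#' @param seed Integer seed for the per-class shuffles.
#' @param table_matching Use the fixed lungdb test counts (default
#'   `FALSE`; requires labels normal/benign/malignant and
#'   `train_fraction` 0.8 or 0.7).
#' @return A `split_plan` list: integer vectors `train` and `test`
#'   (disjoint, exhaustive), `per_class` tibble, `train_fraction`,
#'   `seed`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L,
                             table_matching = FALSE) {
  labels <- as.character(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly inside (0, 1).")
  }
  counts <- table(labels)
  if (any(counts < 2L)) abort("Every class needs at least 2 samples to split.")
  classes <- names(counts)
  rng <- rng_stream(derive_seed(seed, "split"))

  test_counts <- if (table_matching) {
    if (!setequal(classes, c("normal", "benign", "malignant"))) {
      abort("Table-matching mode requires classes normal/benign/malignant.")
    }
    fixed <- if (isTRUE(all.equal(train_fraction, 0.8))) {
      c(normal = 8L, benign = 5L, malignant = 7L)
    } else if (isTRUE(all.equal(train_fraction, 0.7))) {
      c(normal = 13L, benign = 9L, malignant = 8L)
    } else {
      abort("Table-matching mode is defined for train fractions 0.8 and 0.7.")
    }
    if (any(fixed[classes] >= counts[classes])) {
      abort("Too few samples per class for table-matching test counts.")
    }
    fixed[classes]
  } else {
    n_train <- round_half_up(train_fraction * counts, 0)
    if (any(n_train >= counts) || any(n_train < 1L)) {
      abort("`train_fraction` leaves some class without both train and test samples.")
    }
    setNames(as.integer(counts - n_train), classes)
  }

  train_idx <- integer(0)
  test_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample(length(idx))]
    nt <- test_counts[[cl]]
    test_idx <- c(test_idx, idx[seq_len(nt)])
    train_idx <- c(train_idx, idx[-seq_len(nt)])
  }
  per_class <- tibble::tibble(
    class = classes,
    n_train = as.integer(counts[classes] - test_counts[classes]),
    n_test = as.integer(test_counts[classes])
  )
  structure(
    list(train = sort(train_idx), test = sort(test_idx),
         per_class = per_class, train_fraction = train_fraction,
         seed = as.integer(seed), table_matching = isTRUE(table_matching)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Stratified split (train fraction %.2f%s)\n", x$train_fraction,
              if (x$table_matching) ", table-matching" else ""))
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}

#' Write and read an image dataset as a class-directory tree
#'
#' `write_image_dataset()` lays the images out as
#' `<dir>/<label>/<sample_id>.png` plus a `manifest.csv` (sample_id,
#' path, label); `read_image_dataset()` loads either such a directory or
#' a manifest file back into the tibble layout produced by
#' [generate_lung_images()].
#'
#' @param dataset Tibble with `sample_id`, `label`, `image` columns.
#' @param dir Directory to create/read.
#' @return The manifest tibble (invisibly for the writer).
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    sub <- file.path(dir, dataset$label[i])
    dir.create(sub, showWarnings = FALSE)
    paths[i] <- file.path(sub, paste0(dataset$sample_id[i], ".png"))
    EBImage::writeImage(EBImage::Image(dataset$image[[i]]), paths[i])
  }
  manifest <- tibble::tibble(sample_id = dataset$sample_id,
                             path = paths, label = dataset$label)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_image_dataset
#' @export
read_image_dataset <- function(dir) {
  manifest_path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  if (file.exists(manifest_path)) {
    manifest <- tibble::as_tibble(utils::read.csv(manifest_path))
    if (dir.exists(dir)) {
      rel <- !file.exists(manifest$path)
      manifest$path[rel] <- file.path(dir, manifest$path[rel])
    }
  } else {
    files <- list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        recursive = TRUE, full.names = TRUE)
    if (length(files) == 0L) abort("No images found under `dir`.")
    manifest <- tibble::tibble(
      sample_id = sub("\\.[^.]+$", "", basename(files)),
      path = files,
      label = basename(dirname(files))
    )
  }
  imgs <- lapply(manifest$path, function(p) {
    im <- EBImage::imageData(EBImage::readImage(p))
    if (length(dim(im)) == 3L) im <- rowMeans(im, dims = 2L)
    im
  })
  tibble::tibble(sample_id = manifest$sample_id, label = manifest$label,
                 image = imgs)
}
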