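#' Define a synthetic crop class
#'
#' A class specification for the synthetic patch generator: a per-band mean
#' intensity signature, a patch count, and a texture scale controlling the
#' amount of smoothed within-patch spatial variation.
#'
#' @param name Class label (character scalar).
#' @param count Number of patches to generate for this class (>= 1).
#' @param signature Numeric vector of per-band mean intensities in `[0, 1]`;
#'   its length fixes the dataset band count.
#' @param texture_scale Non-negative scalar; amplitude of the smoothed spatial
#'   texture component added to every patch of this class. `0` gives flat
#'   patches (signature plus i.i.d. pixel noise only).
#' @return An object of class `class_spec`.
#' @examples
#' class_spec("Maize", 20, signature = c(0.2, 0.6, 0.3))
#' @export
class_spec <- function(name, count, signature, texture_scale = 0.05) {
  stopifnot(is.character(name), length(name) == 1L)
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop_config("count must be a positive integer")
  signature <- as.numeric(signature)
  if (any(!is.finite(signature)) || any(signature < 0) || any(signature > 1)) {
    stop_config("signature entries must lie in [0, 1]")
  }
  if (!is.finite(texture_scale) || texture_scale < 0) {
    stop_config("texture_scale must be non-negative")
  }
  structure(
    list(name = name, count = count, signature = signature,
         texture_scale = texture_scale),
    class = "class_spec"
  )
}

#' Six-class drone-imagery emulation profile
#'
#' Class specifications emulating a six-class drone crop-patch collection
#' (Maize, Banana, Forest, Other, Legume, Structure) with the characteristic
#' imbalance of per-class counts 2075, 1661, 1270, 750, 363 and 331 (6,450
#' patches in total). `scale` shrinks every count (ceiling-rounded) so test
#' runs stay fast; `scale = 1` reproduces the full counts.
#'
#' @param scale Multiplier applied to each class count (default 0.1).
#' @param bands Number of spectral bands (default 3); signatures are defined
#'   for up to 4 bands and recycled deterministically beyond that.
#' @return List of [class_spec()] objects.
#' @examples
#' sum(vapply(drone_crop_profile(scale = 1), function(s) s$count, integer(1)))
#' @export
drone_crop_profile <- function(scale = 0.1, bands = 3) {
  counts <- c(Maize = 2075, Banana = 1661, Forest = 1270,
              Other = 750, Legume = 363, Structure = 331)
  # Distinct, well-spread signatures: vegetation classes greener, Structure
  # bright and flat, Forest dark. Values are design choices, not measurements.
  sigs <- rbind(
    Maize     = c(0.35, 0.65, 0.30, 0.55),
    Banana    = c(0.45, 0.75, 0.40, 0.60),
    Forest    = c(0.15, 0.40, 0.20, 0.70),
    Other     = c(0.55, 0.50, 0.45, 0.40),
    Legume    = c(0.30, 0.55, 0.55, 0.50),
    Structure = c(0.80, 0.80, 0.75, 0.20)
  )
  tex <- c(0.06, 0.05, 0.10, 0.04, 0.05, 0.02)
  lapply(seq_along(counts), function(i) {
    sig <- rep_len(sigs[i, ], bands)
    class_spec(names(counts)[i], max(1L, as.integer(ceiling(counts[i] * scale))),
               signature = sig, texture_scale = tex[i])
  })
}

#' Generate a labeled synthetic image set
#'
#' Draws multi-band image patches around per-class spectral signatures:
#' each pixel is the class's per-band mean plus i.i.d. Gaussian noise
#' (`noise_sd`) plus, when a class's `texture_scale` is positive, a smoothed
#' random spatial field shared across bands, emulating within-patch texture.
#' Intensities are truncated to `[0, 1]`. Identical `(specs, seed)` give
#' bit-identical output.
#'
#' @param specs Non-empty list of [class_spec()] objects; all signatures must
#'   have length `bands`.
#' @param bands Number of bands (>= 1).
#' @param patch_size Patch side length in pixels (>= 4).
#' @param noise_sd Non-negative Gaussian pixel noise standard deviation.
#' @param seed Integer seed; all randomness is local to the call.
#' @return An object of class `imageset`: list with `patches` (4-d array,
#'   sample x band x height x width), `labels` (0-based integer vector) and
#'   `class_names`.
#' @examples
#' im <- generate_imageset(drone_crop_profile(scale = 0.01), seed = 1)
#' dim(im$patches)
#' @export
generate_imageset <- function(specs, bands = 3, patch_size = 32,
                              noise_sd = 0.05, seed = 1) {
  if (length(specs) == 0) stop_config("specs must be non-empty")
  if (patch_size < 4) stop_config("patch_size must be >= 4")
  if (bands < 1) stop_config("bands must be >= 1")
  if (!is.finite(noise_sd) || noise_sd < 0) stop_config("noise_sd must be non-negative")
  for (s in specs) {
    if (!inherits(s, "class_spec")) stop_config("specs must be class_spec objects")
    if (length(s$signature) != bands) {
      stop_config("signature length %d of class '%s' does not match bands = %d",
                  length(s$signature), s$name, bands)
    }
  }
  n <- sum(vapply(specs, function(s) s$count, integer(1)))
  patches <- array(0, dim = c(n, bands, patch_size, patch_size))
  labels <- integer(n)
  with_local_seed(seed, {
    row <- 1L
    for (k in seq_along(specs)) {
      s <- specs[[k]]
      for (i in seq_len(s$count)) {
        base <- array(rep(s$signature, each = 1),
                      dim = c(bands, patch_size, patch_size))
        for (b in seq_len(bands)) base[b, , ] <- s$signature[b]
        if (s$texture_scale > 0) {
          field <- smooth_field(patch_size)
          for (b in seq_len(bands)) {
            base[b, , ] <- base[b, , ] + s$texture_scale * field
          }
        }
        if (noise_sd > 0) {
          base <- base + array(stats::rnorm(length(base), sd = noise_sd), dim = dim(base))
        }
        patches[row, , , ] <- clip(base, 0, 1)
        labels[row] <- k - 1L
        row <- row + 1L
      }
    }
  })
  structure(
    list(patches = patches, labels = labels,
         class_names = vapply(specs, function(s) s$name, character(1))),
    class = "imageset"
  )
}

# Smoothed zero-mean random field on a patch_size^2 grid: i.i.d. normals
# blurred by a separable moving average, then centred. Gives spatially
# correlated texture at negligible cost.
smooth_field <- function(patch_size, window = 5L) {
  z <- matrix(stats::rnorm(patch_size^2), patch_size, patch_size)
  k <- rep(1 / window, window)
  pad <- (window - 1L) %/% 2L
  blur1 <- function(m) {
    mp <- rbind(m[rep(1L, pad), , drop = FALSE], m, m[rep(patch_size, pad), , drop = FALSE])
    out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    out[(pad + 1L):(pad + patch_size), , drop = FALSE]
  }
  z <- blur1(z)
  z <- t(blur1(t(z)))
  z <- z - mean(z)
  z / max(stats::sd(z), 1e-12)
}

#' @export
print.imageset <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("Labeled image set: %d patches, %d band(s), %dx%d pixels\n",
              d[1], d[2], d[3], d[4]))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Generate a Gaussian-cluster feature table
#'
#' Class-conditional spherical Gaussian clusters whose centroids are placed at
#' distance proportional to `class_sep` (centroids on scaled random unit
#' directions; unit within-class variance), for testing classifiers and
#' tuning loops without the image stage.
#'
#' @param n_per_class Integer vector of per-class sample counts (all >= 1).
#' @param n_features Feature dimension (>= 1).
#' @param class_sep Non-negative centroid separation scale. `0` collapses all
#'   classes onto one distribution.
#' @param seed Integer seed.
#' @return An object of class `feature_table`: list with `X` (numeric matrix,
#'   samples x features), `labels` (0-based integers) and `feature_names`.
#' @examples
#' ft <- generate_feature_table(c(20, 20), n_features = 4, class_sep = 3, seed = 1)
#' table(ft$labels)
#' @export
generate_feature_table <- function(n_per_class, n_features = 8,
                                   class_sep = 2, seed = 1) {
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 1L)) stop_config("all class counts must be >= 1")
  if (n_features < 1) stop_config("n_features must be >= 1")
  if (!is.finite(class_sep) || class_sep < 0) stop_config("class_sep must be non-negative")
  C <- length(n_per_class)
  n <- sum(n_per_class)
  with_local_seed(seed, {
    centers <- matrix(stats::rnorm(C * n_features), C, n_features)
    norms <- sqrt(rowSums(centers^2))
    centers <- centers / pmax(norms, 1e-12) * class_sep
    X <- matrix(stats::rnorm(n * n_features), n, n_features)
    labels <- rep(seq_len(C) - 1L, times = n_per_class)
    X <- X + centers[labels + 1L, , drop = FALSE]
    feature_table(X, labels, paste0("f", seq_len(n_features) - 1L))
  })
}

#' Construct a feature table
#'
#' @param X Numeric matrix, samples x features, all entries finite.
#' @param labels Integer class labels in `[0, C-1]`, one per row of `X`.
#' @param feature_names Optional character vector of column names.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, labels, feature_names = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_config("feature matrix contains non-finite entries")
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) {
    stop_config("row count of X (%d) does not match labels length (%d)",
                nrow(X), length(labels))
  }
  if (!is.null(feature_names)) {
    stopifnot(length(feature_names) == ncol(X))
    colnames(X) <- feature_names
  }
  structure(list(X = X, labels = labels, feature_names = colnames(X)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features, %d class(es)\n",
              nrow(x$X), ncol(x$X), length(unique(x$labels))))
  invisible(x)
}

#' Write an image set to a plain-text layout
#'
#' Writes `patches.csv` (one row per patch: flattened band-major pixel values),
#' `labels.csv` (`sample_id,class_name`) and `meta.csv` (dimensions and class
#' order) to `dir`. With `png = TRUE` additionally writes one false-colour PNG
#' per patch under `dir/png/<class>/`.
#'
#' @param imageset An [generate_imageset()] result.
#' @param dir Output directory (created if missing).
#' @param png Also export per-patch PNGs (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_imageset <- function(imageset, dir, png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(imageset$patches)
  flat <- matrix(aperm(imageset$patches, c(1, 2, 3, 4)), nrow = d[1])
  utils::write.table(round(flat, 6), file.path(dir, "patches.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  labs <- data.frame(
    sample_id = seq_len(d[1]) - 1L,
    class_name = imageset$class_names[imageset$labels + 1L]
  )
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- data.frame(key = c("n", "bands", "height", "width",
                             paste0("class", seq_along(imageset$class_names) - 1L)),
                     value = c(d, imageset$class_names))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  if (png) {
    for (k in seq_along(imageset$class_names)) {
      sub <- file.path(dir, "png", imageset$class_names[k])
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      idx <- which(imageset$labels == k - 1L)
      for (i in idx) {
        img <- patch_to_rgb(imageset$patches[i, , , ])
        png::writePNG(img, file.path(sub, sprintf("patch_%05d.png", i - 1L)))
      }
    }
  }
  invisible(dir)
}

# Map a band x h x w patch to an h x w x 3 array for PNG export: first three
# bands as RGB, fewer bands recycled.
patch_to_rgb <- function(patch) {
  if (length(dim(patch)) == 2L) patch <- array(patch, dim = c(1L, dim(patch)))
  b <- dim(patch)[1]
  idx <- rep_len(seq_len(b), 3L)
  aperm(patch[idx, , , drop = FALSE], c(2, 3, 1))
}

#' Read an image set written by [write_imageset()]
#'
#' Also accepts a directory-per-class layout of PNG (or TIFF, if the patches
#' were exported by other tools and re-encoded as PNG) files under `dir/png/`
#' or directly under `dir/<class>/`.
#'
#' @param dir Directory containing `patches.csv` + `labels.csv` + `meta.csv`,
#'   or class subdirectories of PNG files.
#' @return An `imageset` object.
#' @export
read_imageset <- function(dir) {
  if (file.exists(file.path(dir, "patches.csv"))) {
    meta <- utils::read.csv(file.path(dir, "meta.csv"), colClasses = "character")
    d <- as.integer(meta$value[1:4])
    class_names <- meta$value[-(1:4)]
    flat <- as.matrix(utils::read.table(file.path(dir, "patches.csv"), sep = ","))
    patches <- array(flat, dim = d)
    labs <- utils::read.csv(file.path(dir, "labels.csv"))
    labels <- match(labs$class_name, class_names) - 1L
    return(structure(list(patches = patches, labels = labels,
                          class_names = class_names), class = "imageset"))
  }
  root <- if (dir.exists(file.path(dir, "png"))) file.path(dir, "png") else dir
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop_config("no image layout found under '%s'", dir)
  imgs <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]),
                             pattern = "\\.(png|PNG)$", full.names = TRUE))
    for (f in files) {
      arr <- png::readPNG(f)
      if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
      imgs[[length(imgs) + 1L]] <- aperm(arr, c(3, 1, 2))
      labels <- c(labels, k - 1L)
    }
  }
  d1 <- dim(imgs[[1]])
  patches <- array(0, dim = c(length(imgs), d1))
  for (i in seq_along(imgs)) patches[i, , , ] <- imgs[[i]]
  structure(list(patches = patches, labels = labels, class_names = classes),
            class = "imageset")
}

#' Write / read a feature table as CSV
#'
#' Layout: `sample_id,label,f0..fK`.
#'
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @return `path` (writer) or a `feature_table` (reader).
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = seq_len(nrow(table$X)) - 1L, label = table$labels)
  fx <- as.data.frame(table$X)
  names(fx) <- if (!is.null(table$feature_names)) table$feature_names else
    paste0("f", seq_len(ncol(table$X)) - 1L)
  utils::write.csv(cbind(df, fx), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path)
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]), df$label,
                names(df)[-(1:2)])
}
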