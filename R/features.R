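#' Bounded search space
#'
#' A rectangular box over which the swarm optimizers operate, with named
#' coordinates.
#'
#' @param lower,upper Numeric vectors of equal length with `lower < upper`
#'   element-wise.
#' @param names Optional coordinate names.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower, upper, names = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) == 0) stop_config("search space must have at least one dimension")
  if (length(lower) != length(upper)) stop_config("lower/upper length mismatch")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop_config("need finite lower < upper element-wise")
  }
  if (is.null(names)) names <- paste0("x", seq_along(lower))
  stopifnot(length(names) == length(lower))
  structure(list(lower = lower, upper = upper, names = names),
            class = "search_space")
}

#' Default extractor hyperparameter search space
#'
#' Six coordinates decoded by [decode_hyperparams()]: number of filters
#' (2–64), kernel size (3, 5 or 7), pooling window (2 or 4), pooling stride
#' (1–4), number of conv/pool stages (1–3), and ReLU on/off.
#'
#' @return A [search_space()].
#' @export
extractor_space <- function() {
  search_space(
    lower = c(2, 0, 0, 1, 1, 0),
    upper = c(64.999, 2.999, 1.999, 4.999, 3.999, 1.999),
    names = c("n_filters", "kernel_idx", "pool_idx", "pool_stride",
              "n_stages", "use_relu")
  )
}

#' Decode a continuous position into extractor hyperparameters
#'
#' Total, deterministic decoding: positions are clipped into the box, then
#' floor-rounded onto each coordinate's discrete grid (kernel size over
#' \{3,5,7\}, pooling window over \{2,4\}), so any real vector of the right
#' dimension decodes without error and values below the rounding granularity
#' do not change the result.
#'
#' @param position Numeric vector, one entry per coordinate of `space`.
#' @param space A [search_space()] laid out as [extractor_space()].
#' @return An object of class `extractor_hyperparams` with fields `n_filters`,
#'   `kernel_size`, `pool_size`, `pool_stride`, `n_stages`, `use_relu`.
#' @examples
#' decode_hyperparams(extractor_space()$lower, extractor_space())
#' @export
decode_hyperparams <- function(position, space) {
  if (length(position) != length(space$lower)) {
    stop_config("position has %d coordinates but space has %d",
                length(position), length(space$lower))
  }
  p <- clip(as.numeric(position), space$lower, space$upper)
  structure(
    list(
      n_filters   = as.integer(floor(p[1])),
      kernel_size = c(3L, 5L, 7L)[1L + floor(p[2])],
      pool_size   = c(2L, 4L)[1L + floor(p[3])],
      pool_stride = as.integer(floor(p[4])),
      n_stages    = as.integer(floor(p[5])),
      use_relu    = floor(p[6]) >= 1
    ),
    class = "extractor_hyperparams"
  )
}

#' @export
print.extractor_hyperparams <- function(x, ...) {
  cat(sprintf(
    "Extractor: %d filters, %dx%d kernel, pool %d stride %d, %d stage(s), ReLU %s\n",
    x$n_filters, x$kernel_size, x$kernel_size, x$pool_size, x$pool_stride,
    x$n_stages, if (x$use_relu) "on" else "off"))
  invisible(x)
}

#' Extract features with the convolutional filter bank
#'
#' The built-in extractor: `n_stages` repetitions of (valid 2-d convolution
#' with a seeded random filter bank, optional ReLU, max-pooling), followed by
#' global average and standard-deviation pooling over each final filter map.
#' Filters are drawn once from `seed` (scaled Gaussian entries, zero-mean per
#' filter beyond stage one) and never trained, so extraction is a pure
#' function of `(images, hp, seed)`. Output dimensionality is
#' `2 * n_filters`.
#'
#' @param images An `imageset`.
#' @param hp An `extractor_hyperparams` object (see [decode_hyperparams()]).
#'   A `filters` list element (one `n_filters x channels x k x k` bank per
#'   stage) pins the filter bank instead of drawing it from `seed`.
#' @param seed Integer seed for the filter bank.
#' @return A [feature_table()] carrying the image labels.
#' @examples
#' im <- generate_imageset(drone_crop_profile(scale = 0.005), seed = 1)
#' hp <- decode_hyperparams(c(8, 0, 0, 2, 1, 1), extractor_space())
#' ft <- extract_features(im, hp, seed = 1)
#' dim(ft$X)
#' @export
extract_features <- function(images, hp, seed = 1) {
  d <- dim(images$patches)
  if (d[3] < hp$kernel_size || d[4] < hp$kernel_size) {
    stop_config("patch (%dx%d) smaller than kernel (%d) at stage 1",
                d[3], d[4], hp$kernel_size)
  }
  maps <- images$patches                      # n x channels x h x w
  with_local_seed(seed, {
    for (stage in seq_len(hp$n_stages)) {
      ch <- dim(maps)[2]
      hcur <- dim(maps)[3]; wcur <- dim(maps)[4]
      if (hcur < hp$kernel_size || wcur < hp$kernel_size) {
        stop_config("feature map (%dx%d) smaller than kernel (%d) at stage %d",
                    hcur, wcur, hp$kernel_size, stage)
      }
      W <- if (!is.null(hp$filters)) {
        hp$filters[[stage]]
      } else {
        filter_bank(hp$n_filters, ch, hp$kernel_size, zero_mean = stage > 1L)
      }
      maps <- conv2d_valid(maps, W)
      if (hp$use_relu) maps[maps < 0] <- 0
      if (dim(maps)[3] >= hp$pool_size && dim(maps)[4] >= hp$pool_size) {
        maps <- max_pool(maps, hp$pool_size, hp$pool_stride)
      }
    }
  })
  n <- dim(maps)[1]; nf <- dim(maps)[2]
  npix <- dim(maps)[3] * dim(maps)[4]
  flat <- matrix(maps, nrow = n * nf)         # rows index (sample, filter)
  m1 <- rowMeans(flat)
  v <- rowSums((flat - m1)^2) / max(1L, npix - 1L)
  mu <- matrix(m1, n, nf)
  sdv <- matrix(sqrt(pmax(v, 0)), n, nf)
  X <- cbind(mu, sdv)
  colnames(X) <- c(paste0("mean_f", seq_len(nf) - 1L),
                   paste0("sd_f", seq_len(nf) - 1L))
  feature_table(X, images$labels, colnames(X))
}

# Random filter bank: n_filters x channels x k x k, N(0, 1/sqrt(fan-in)).
# Later stages use per-filter zero-mean filters so deep responses stay
# centred; stage one keeps the raw draw so band means pass through.
filter_bank <- function(n_filters, channels, k, zero_mean = FALSE) {
  fan_in <- channels * k * k
  W <- array(stats::rnorm(n_filters * fan_in, sd = 1 / sqrt(fan_in)),
             dim = c(n_filters, channels, k, k))
  if (zero_mean) {
    for (f in seq_len(n_filters)) W[f, , , ] <- W[f, , , ] - mean(W[f, , , ])
  }
  W
}

# Valid 2-d convolution (correlation) of a batch: input n x c x h x w with a
# bank nf x c x k x k -> n x nf x (h-k+1) x (w-k+1). Implemented as im2col
# over shifted slices so the whole batch is one matrix product.
conv2d_valid <- function(input, W) {
  di <- dim(input); n <- di[1]; ch <- di[2]; h <- di[3]; w <- di[4]
  dw <- dim(W); nf <- dw[1]; k <- dw[3]
  oh <- h - k + 1L; ow <- w - k + 1L
  cols <- matrix(0, n * oh * ow, ch * k * k)
  col <- 1L
  for (c_i in seq_len(ch)) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        # slice: n x oh x ow
        s <- input[, c_i, dy:(dy + oh - 1L), dx:(dx + ow - 1L), drop = FALSE]
        cols[, col] <- as.vector(s)
        col <- col + 1L
      }
    }
  }
  Wm <- matrix(0, ch * k * k, nf)
  col <- 1L
  for (c_i in seq_len(ch)) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        Wm[col, ] <- W[, c_i, dy, dx]
        col <- col + 1L
      }
    }
  }
  out <- cols %*% Wm                           # (n*oh*ow) x nf
  aperm(array(out, dim = c(n, oh, ow, nf)), c(1, 4, 2, 3))
}

# Max pooling with window p and stride s over the two spatial axes.
max_pool <- function(input, p, s) {
  di <- dim(input); h <- di[3]; w <- di[4]
  oh <- max(1L, (h - p) %/% s + 1L); ow <- max(1L, (w - p) %/% s + 1L)
  out <- array(-Inf, dim = c(di[1], di[2], oh, ow))
  for (dy in seq_len(p)) {
    for (dx in seq_len(p)) {
      ys <- (seq_len(oh) - 1L) * s + dy
      xs <- (seq_len(ow) - 1L) * s + dx
      out <- pmax(out, input[, , ys, xs, drop = FALSE])
    }
  }
  out
}

# ---- extractor registry -----------------------------------------------------

.extractors <- new.env(parent = emptyenv())

#' Register a named feature extractor
#'
#' Extractors are functions `(images, hp, seed) -> feature_table` selectable
#' by name in pipeline configuration; the built-in convolutional bank is
#' pre-registered as `"convbank"`. The returned table is contract-checked:
#' its row count must equal the number of input patches.
#'
#' @param name Unused extractor name.
#' @param fn Function of `(images, hp, seed)` returning a [feature_table()].
#' @param overwrite Allow replacing an existing registration (default `FALSE`;
#'   registering a taken name is an error).
#' @return `name`, invisibly.
#' @export
register_extractor <- function(name, fn, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (!overwrite && !is.null(.extractors[[name]])) {
    stop_config("extractor '%s' is already registered", name)
  }
  assign(name, fn, envir = .extractors)
  invisible(name)
}

#' @rdname register_extractor
#' @export
list_extractors <- function() sort(ls(.extractors))

#' Look up a registered extractor and wrap it with contract checks
#' @param name Registered extractor name.
#' @return The checking wrapper function.
#' @export
get_extractor <- function(name) {
  fn <- .extractors[[name]]
  if (is.null(fn)) stop_config("no extractor registered under '%s'", name)
  function(images, hp, seed) {
    out <- fn(images, hp, seed)
    if (!inherits(out, "feature_table")) {
      stop_config("extractor '%s' did not return a feature_table", name)
    }
    n_in <- dim(images$patches)[1]
    if (nrow(out$X) != n_in) {
      stop_config("extractor '%s' returned %d feature rows for %d patches",
                  name, nrow(out$X), n_in)
    }
    out
  }
}

# Built-in registration happens at load time.
.onLoad <- function(libname, pkgname) {
  if (is.null(.extractors[["convbank"]])) {
    register_extractor("convbank", extract_features)
  }
}
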