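test_that("decoding is total, clipped and quantized on the discrete grids", {
  sp <- extractor_space()
  lo <- decode_hyperparams(sp$lower, sp)
  expect_equal(lo$n_filters, 2L)
  expect_equal(lo$kernel_size, 3L)
  expect_equal(lo$pool_size, 2L)
  expect_equal(lo$pool_stride, 1L)
  expect_equal(lo$n_stages, 1L)
  expect_false(lo$use_relu)

  # sub-granularity perturbations decode identically
  a <- decode_hyperparams(c(8.1, 1.2, 0.3, 2.4, 1.5, 1.6), sp)
  b <- decode_hyperparams(c(8.9, 1.9, 0.9, 2.9, 1.9, 1.9), sp)
  expect_identical(a, b)

  # out-of-range positions clip rather than error
  wild <- decode_hyperparams(c(-100, 100, -5, 99, 99, -3), sp)
  expect_equal(wild$n_filters, 2L)
  expect_equal(wild$kernel_size, 7L)
  expect_equal(wild$pool_stride, 4L)
  expect_error(decode_hyperparams(c(1, 2), sp), "coordinates")
})

test_that("1,000 random in-bounds positions decode and re-decode stably", {
  sp <- extractor_space()
  set.seed(42)
  for (rep in 1:1000) {
    pos <- runif(6, sp$lower, sp$upper)
    hp <- decode_hyperparams(pos, sp)
    expect_true(hp$n_filters >= 2 && hp$n_filters <= 64)
    expect_true(hp$kernel_size %in% c(3L, 5L, 7L))
    expect_true(hp$pool_size %in% c(2L, 4L))
    expect_true(hp$pool_stride >= 1 && hp$pool_stride <= 4)
    expect_true(hp$n_stages %in% 1:3)
    # decoding the decoded values (as a position) is idempotent
    pos2 <- c(hp$n_filters, match(hp$kernel_size, c(3, 5, 7)) - 1,
              match(hp$pool_size, c(2, 4)) - 1, hp$pool_stride,
              hp$n_stages, as.integer(hp$use_relu))
    expect_identical(decode_hyperparams(pos2, sp), hp)
  }
})

test_that("convolution matches a hand-computed oracle and identity kernels pass through", {
  # hand oracle on a single 4x4 patch, 3x3 kernel
  patch <- array(0, dim = c(1, 1, 4, 4))
  patch[1, 1, , ] <- matrix(1:16 / 16, 4, 4)
  W <- array(0, dim = c(1, 1, 3, 3))
  W[1, 1, 2, 2] <- 1                     # identity (centre tap)
  out <- dtocrop:::conv2d_valid(patch, W)
  expect_equal(dim(out), c(1, 1, 2, 2))
  expect_equal(out[1, 1, , ], patch[1, 1, 2:3, 2:3], tolerance = 1e-12)

  # random kernel vs scalar loop
  set.seed(1)
  patch[1, 1, , ] <- matrix(rnorm(16), 4, 4)
  W[1, 1, , ] <- matrix(rnorm(9), 3, 3)
  out <- dtocrop:::conv2d_valid(patch, W)
  for (y in 1:2) for (x in 1:2) {
    expect_equal(out[1, 1, y, x],
                 sum(patch[1, 1, y:(y + 2), x:(x + 2)] * W[1, 1, , ]),
                 tolerance = 1e-12)
  }

  # identity kernel, no pooling, no ReLU: features are the (cropped) patch
  # mean and standard deviation
  W_id <- array(0, dim = c(1, 1, 3, 3))
  W_id[1, 1, 2, 2] <- 1
  W <- W_id
  im <- structure(list(patches = patch, labels = 0L, class_names = "a"),
                  class = "imageset")
  hp <- decode_hyperparams(c(2, 0, 1, 1, 1, 0), extractor_space())
  hp$n_filters <- 1L
  hp$filters <- list(W)                  # pin the identity bank
  hp$pool_size <- 99L                    # larger than the map: pooling skipped
  ft <- extract_features(im, hp, seed = 1)
  inner <- patch[1, 1, 2:3, 2:3]
  expect_equal(unname(ft$X[1, ]), c(mean(inner), sd(inner)), tolerance = 1e-12)
})

test_that("extraction is a pure deterministic function of images, hp and seed", {
  im <- generate_imageset(drone_crop_profile(scale = 0.005), seed = 2)
  hp <- decode_hyperparams(c(6, 1, 0, 2, 2, 1), extractor_space())
  a <- extract_features(im, hp, seed = 9)
  b <- extract_features(im, hp, seed = 9)
  expect_identical(a$X, b$X)
  c <- extract_features(im, hp, seed = 10)
  expect_false(identical(a$X, c$X))

  # identical patches give identical feature rows
  im2 <- im
  im2$patches[2, , , ] <- im2$patches[1, , , ]
  ft <- extract_features(im2, hp, seed = 9)
  expect_equal(ft$X[1, ], ft$X[2, ], tolerance = 1e-12)

  # constant-zero patches give all-zero features (ReLU(0) = 0, sd = 0)
  im0 <- im
  im0$patches[] <- 0
  ft0 <- extract_features(im0, hp, seed = 9)
  expect_true(all(ft0$X == 0))
})

test_that("output dimensionality follows the 2 * n_filters rule over a grid", {
  im <- generate_imageset(list(class_spec("a", 2, c(0.4, 0.5, 0.3)),
                               class_spec("b", 2, c(0.6, 0.3, 0.5))),
                          patch_size = 16, seed = 1)
  for (nf in c(2, 5, 9)) {
    for (st in 1:2) {
      hp <- decode_hyperparams(c(nf, 0, 0, 2, st, 1), extractor_space())
      ft <- extract_features(im, hp, seed = 1)
      expect_equal(ncol(ft$X), 2L * nf)
      expect_equal(nrow(ft$X), 4L)
    }
  }
})

test_that("kernels larger than the shrinking map raise a stage-naming error", {
  im <- generate_imageset(list(class_spec("a", 2, 0.4), class_spec("b", 2, 0.6)),
                          bands = 1, patch_size = 8, seed = 1)
  hp <- decode_hyperparams(c(4, 2, 1, 4, 3, 0), extractor_space())  # 7x7 kernel, deep
  expect_error(extract_features(im, hp, seed = 1), "stage")
})

test_that("the extractor registry enforces names and contracts", {
  expect_true("convbank" %in% list_extractors())
  expect_error(register_extractor("convbank", function(im, hp, seed) NULL),
               "already registered")
  nm <- paste0("tmp_extractor_", sample.int(1e6, 1))
  register_extractor(nm, function(images, hp, seed) {
    feature_table(matrix(1, 2, 2), c(0L, 1L))   # wrong row count for most inputs
  })
  im <- generate_imageset(list(class_spec("a", 2, 0.4), class_spec("b", 2, 0.6)),
                          bands = 1, patch_size = 8, seed = 1)
  expect_error(get_extractor(nm)(im, NULL, 1), "4 patches")
  expect_error(get_extractor("no_such_extractor"), "no extractor")
})

test_that("a constant-feature extractor yields chance-level accuracy on balanced data", {
  im <- generate_imageset(list(class_spec("a", 30, c(0.3, 0.5, 0.4)),
                               class_spec("b", 30, c(0.6, 0.2, 0.5))),
                          patch_size = 8, seed = 3)
  const_ft <- feature_table(matrix(1, 60, 4), im$labels)
  fit <- suppressWarnings(elm(const_ft, L = 20, seed = 1))
  acc <- mean(predict(fit, const_ft$X) == const_ft$labels)
  expect_equal(acc, 0.5, tolerance = 0.05)   # chance level from class priors
})

test_that("best-of-grid hyperparameters never lose to worst-of-grid on separable data", {
  im <- generate_imageset(drone_crop_profile(scale = 0.008), seed = 6)
  sp <- extractor_space()
  grid <- list(c(2, 0, 0, 4, 1, 0), c(8, 0, 0, 2, 1, 1),
               c(16, 1, 0, 2, 2, 1), c(4, 2, 1, 2, 1, 0))
  split <- stratified_split(im$labels, 0.7, seed = 1)
  errs <- vapply(grid, function(pos) {
    hp <- decode_hyperparams(pos, sp)
    tr <- dtocrop:::subset_imageset(im, split$train)
    te <- dtocrop:::subset_imageset(im, split$test)
    ftr <- extract_features(tr, hp, seed = 4)
    fte <- extract_features(te, hp, seed = 4)
    fit <- suppressWarnings(elm(ftr, L = 40, lambda = 1e-4, seed = 2))
    error_rate_fitness(fte$labels, predict(fit, fte$X))
  }, numeric(1))
  expect_lte(min(errs), max(errs))
  expect_lt(min(errs), 50)                  # the good grid points genuinely work
})
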