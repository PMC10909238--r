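#' Stratified train/test split
#'
#' Splits indices class by class with largest-remainder rounding so per-class
#' proportions are preserved to within one sample; deterministic under a
#' fixed seed, disjoint and exhaustive.
#'
#' @param labels Integer class labels (0-based).
#' @param ratio Training fraction in (0, 1) (e.g. 0.8 for an 80:20 split).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (1-based).
#' @examples
#' s <- stratified_split(rep(0:1, each = 50), 0.8, seed = 1)
#' lengths(s)
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1) {
  if (ratio <= 0 || ratio >= 1) stop_config("ratio must lie in (0, 1)")
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 2)) {
    k <- names(counts)[which(counts < 2)[1]]
    stop_config("class %s has fewer than 2 samples and cannot be split", k)
  }
  # largest-remainder apportionment of the training quota across classes
  quota <- as.numeric(counts) * ratio
  n_train <- floor(quota)
  rem <- sum(round(sum(quota)) - sum(n_train))
  if (rem > 0) {
    order_rem <- order(quota - n_train, decreasing = TRUE)
    n_train[order_rem[seq_len(rem)]] <- n_train[order_rem[seq_len(rem)]] + 1L
  }
  # keep every class represented on both sides
  n_train <- pmax(1L, pmin(as.numeric(counts) - 1L, n_train))
  with_local_seed(seed, {
    train <- integer(0); test <- integer(0)
    for (k in seq_along(classes)) {
      idx <- which(labels == classes[k])
      idx <- sample(idx)
      train <- c(train, idx[seq_len(n_train[k])])
      test <- c(test, idx[-seq_len(n_train[k])])
    }
    list(train = sort(train), test = sort(test))
  })
}

subset_imageset <- function(images, idx) {
  structure(list(patches = images$patches[idx, , , , drop = FALSE],
                 labels = images$labels[idx],
                 class_names = images$class_names),
            class = "imageset")
}

subset_table <- function(table, idx) {
  feature_table(table$X[idx, , drop = FALSE], table$labels[idx],
                table$feature_names)
}

#' Pipeline configuration
#'
#' @param split_ratio Training fraction of the outer split (default 0.8,
#'   i.e. 80:20).
#' @param val_fraction Fraction of the training side held out as the inner
#'   validation set on which both tuning stages score candidates
#'   (default 0.2).
#' @param dto [dto_config()] for stage 1 (extractor hyperparameters).
#' @param msca [msca_config()] for stage 2 (ELM parameters).
#' @param extractor Registered extractor name (default `"convbank"`).
#' @param extractor_space [search_space()] for stage 1 (default
#'   [extractor_space()]).
#' @param elm_space [search_space()] for stage 2: hidden nodes `L`
#'   (integer-rounded), `log10(lambda)` and activation index; default
#'   L in [10, 300], lambda in [1e-8, 10], all three activations.
#' @param stage1_L,stage1_lambda ELM settings used inside the stage-1
#'   fitness (modest fixed classifier; defaults 60 and 1e-4).
#' @param decode_fn Function decoding a stage-1 position into the
#'   hyperparameter object handed to the extractor; defaults to
#'   [decode_hyperparams()]. Override it together with `extractor_space`
#'   when a registered extractor uses its own parameterization.
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(split_ratio = 0.8, val_fraction = 0.2,
                            dto = dto_config(m = 8, T = 10),
                            msca = msca_config(m = 10, T = 15),
                            extractor = "convbank",
                            extractor_space = dtocrop::extractor_space(),
                            elm_space = NULL,
                            stage1_L = 60, stage1_lambda = 1e-4,
                            decode_fn = decode_hyperparams,
                            seed = 1) {
  if (split_ratio <= 0 || split_ratio >= 1) stop_config("split_ratio in (0,1)")
  if (val_fraction <= 0 || val_fraction >= 1) stop_config("val_fraction in (0,1)")
  if (is.null(elm_space)) {
    elm_space <- search_space(c(10, -8, 0), c(300.999, 1, 2.999),
                             names = c("L", "log10_lambda", "activation_idx"))
  }
  structure(list(split_ratio = split_ratio, val_fraction = val_fraction,
                 dto = dto, msca = msca, extractor = extractor,
                 extractor_space = extractor_space, elm_space = elm_space,
                 stage1_L = stage1_L, stage1_lambda = stage1_lambda,
                 decode_fn = decode_fn, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Decode a stage-2 position into ELM settings
#'
#' `L` floors to an integer grid, `lambda` is log10-scaled, and the
#' activation index floors into `(sigmoid, relu, tanh)`; positions are
#' clipped into the box first, so decoding is total.
#'
#' @param position Length-3 numeric vector.
#' @param space The stage-2 [search_space()].
#' @return List with `L`, `lambda`, `activation`.
#' @export
decode_elm_params <- function(position, space) {
  if (length(position) != 3) stop_config("stage-2 position must have 3 coordinates")
  p <- clip(as.numeric(position), space$lower, space$upper)
  list(L = as.integer(floor(p[1])),
       lambda = 10^p[2],
       activation = c("sigmoid", "relu", "tanh")[1L + floor(p[3])])
}

# Inner train/validation split of the training side, shared by both stages.
inner_split <- function(labels, val_fraction, seed) {
  s <- stratified_split(labels, 1 - val_fraction, seed = seed)
  list(fit = s$train, val = s$test)
}

#' Stage 1: tune extractor hyperparameters with DTO
#'
#' DTO minimizes the classifier error rate (percent misclassified) of a
#' fixed modest ELM trained on the inner-training side and scored on the
#' inner-validation side, with features re-extracted for every candidate
#' position.
#'
#' @param train_images Training-side `imageset`.
#' @param cfg A [pipeline_config()].
#' @return List with `hp` (decoded best hyperparameters), `position`,
#'   `value` (best validation error, percent), `history`.
#' @export
stage1_tune_extractor <- function(train_images, cfg) {
  if (length(unique(train_images$labels)) < 2) {
    stop_config("stage 1 requires >= 2 classes in the training data")
  }
  inner <- inner_split(train_images$labels, cfg$val_fraction,
                       seed = cfg$seed + 101L)
  fit_im <- subset_imageset(train_images, inner$fit)
  val_im <- subset_imageset(train_images, inner$val)
  extractor <- get_extractor(cfg$extractor)
  space <- cfg$extractor_space
  objective <- function(pos) {
    hp <- cfg$decode_fn(pos, space)
    # infeasible candidates (e.g. a kernel larger than the pooled map)
    # receive an infinite error rather than aborting the search
    tryCatch({
      ft_fit <- extractor(fit_im, hp, seed = cfg$seed + 7L)
      ft_val <- extractor(val_im, hp, seed = cfg$seed + 7L)
      model <- suppressWarnings(
        elm(ft_fit, L = cfg$stage1_L, lambda = cfg$stage1_lambda,
            seed = cfg$seed + 13L))
      error_rate_fitness(ft_val$labels, predict(model, ft_val$X))
    }, error = function(e) Inf)
  }
  res <- swarm_optimize(objective, space, "dto", cfg$dto,
                        seed = cfg$seed + 1L)
  list(hp = cfg$decode_fn(res$best, space), position = res$best,
       value = res$value, history = res$history)
}

#' Stage 2: tune ELM parameters with MSCA
#'
#' MSCA minimizes the inner-validation error rate over
#' `(L, log10 lambda, activation)` on the stage-1 feature table.
#'
#' @param train_features Training-side [feature_table()].
#' @param cfg A [pipeline_config()].
#' @return List with `params` (decoded best), `position`, `value`,
#'   `history`.
#' @export
stage2_tune_elm <- function(train_features, cfg) {
  inner <- inner_split(train_features$labels, cfg$val_fraction,
                       seed = cfg$seed + 202L)
  ft_fit <- subset_table(train_features, inner$fit)
  ft_val <- subset_table(train_features, inner$val)
  space <- cfg$elm_space
  objective <- function(pos) {
    par <- decode_elm_params(pos, space)
    model <- elm(ft_fit, L = par$L, activation = par$activation,
                 lambda = par$lambda, seed = cfg$seed + 17L)
    error_rate_fitness(ft_val$labels, predict(model, ft_val$X))
  }
  res <- suppressWarnings(
    swarm_optimize(objective, space, "msca", cfg$msca, seed = cfg$seed + 2L))
  list(params = decode_elm_params(res$best, space), position = res$best,
       value = res$value, history = res$history)
}

#' Run the full tuned-classification pipeline
#'
#' Stratified outer split, DTO tuning of the feature extractor (stage 1),
#' MSCA tuning of the ELM (stage 2) on the winning features, a final ELM fit
#' on the full training side, and per-class evaluation reports for both
#' sides. The test side is never touched before the final evaluation. Fully
#' reproducible from `(config, seed)`.
#'
#' @param images An `imageset`.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory: reports, histories and a JSON run
#'   summary are written there.
#' @return An object of class `dtocc_run` with elements `hp`, `elm_params`,
#'   `model`, `report_train`, `report_test`, `history_stage1`,
#'   `history_stage2`, `split_sizes`, `config`.
#' @examples
#' \donttest{
#' im <- generate_imageset(drone_crop_profile(scale = 0.02), seed = 1)
#' cfg <- pipeline_config(dto = dto_config(m = 4, T = 3),
#'                        msca = msca_config(m = 4, T = 4), seed = 1)
#' run <- run_pipeline(im, cfg)
#' print(run)
#' }
#' @export
run_pipeline <- function(images, cfg = pipeline_config(), out_dir = NULL) {
  split <- stratified_split(images$labels, cfg$split_ratio,
                            seed = cfg$seed + 303L)
  train_im <- subset_imageset(images, split$train)
  s1 <- stage1_tune_extractor(train_im, cfg)
  extractor <- get_extractor(cfg$extractor)
  train_ft <- extractor(train_im, s1$hp, seed = cfg$seed + 7L)
  s2 <- stage2_tune_elm(train_ft, cfg)
  model <- suppressWarnings(
    elm(train_ft, L = s2$params$L, activation = s2$params$activation,
        lambda = s2$params$lambda, seed = cfg$seed + 17L))
  test_im <- subset_imageset(images, split$test)
  test_ft <- extractor(test_im, s1$hp, seed = cfg$seed + 7L)
  pct <- round(100 * cfg$split_ratio)
  rep_train <- evaluation_report(train_ft$labels, predict(model, train_ft$X),
                                 class_names = images$class_names,
                                 split_tag = sprintf("TR%d", pct))
  rep_test <- evaluation_report(test_ft$labels, predict(model, test_ft$X),
                                class_names = images$class_names,
                                split_tag = sprintf("TS%d", 100L - pct))
  run <- structure(
    list(hp = s1$hp, elm_params = s2$params, model = model,
         report_train = rep_train, report_test = rep_test,
         history_stage1 = s1$history, history_stage2 = s2$history,
         split_sizes = c(train = length(split$train), test = length(split$test)),
         config = cfg),
    class = "dtocc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.dtocc_run <- function(x, ...) {
  cat("Tuned crop-classification run\n")
  cat(sprintf("Split: %d train / %d test\n",
              x$split_sizes["train"], x$split_sizes["test"]))
  print(x$hp)
  cat(sprintf("ELM: L = %d, lambda = %.3g, activation = %s\n",
              x$elm_params$L, x$elm_params$lambda, x$elm_params$activation))
  cat(sprintf("Stage-1 best validation error: %.2f%% | Stage-2: %.2f%%\n",
              x$history_stage1[length(x$history_stage1)],
              x$history_stage2[length(x$history_stage2)]))
  cat("\n-- Train side --\n"); print(x$report_train)
  cat("\n-- Test side --\n"); print(x$report_test)
  invisible(x)
}

#' @export
summary.dtocc_run <- function(object, ...) {
  avg <- attr(object$report_test$averages, "display")
  cat(sprintf("Test macro metrics [%s]: accuracy %.2f, precision %.2f, recall %.2f, F %.2f, MCC %.2f\n",
              object$report_test$split_tag, avg["accuracy"], avg["precision"],
              avg["recall"], avg["f_score"], avg["mcc"]))
  invisible(object)
}

# Persist a run: reports, confusions, histories and a JSON summary.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report(run$report_train, file.path(out_dir, "report_train.csv"),
               confusion_path = file.path(out_dir, "confusion_train.csv"))
  write_report(run$report_test, file.path(out_dir, "report_test.csv"),
               confusion_path = file.path(out_dir, "confusion_test.csv"))
  utils::write.csv(data.frame(iteration = seq_along(run$history_stage1) - 1L,
                              f_gbest = run$history_stage1),
                   file.path(out_dir, "history_stage1.csv"), row.names = FALSE)
  utils::write.csv(data.frame(iteration = seq_along(run$history_stage2) - 1L,
                              f_gbest = run$history_stage2),
                   file.path(out_dir, "history_stage2.csv"), row.names = FALSE)
  summary_obj <- list(
    hp = unclass(run$hp),
    elm_params = run$elm_params,
    split_sizes = as.list(run$split_sizes),
    test_averages = as.list(run$report_test$averages),
    train_averages = as.list(run$report_train$averages),
    seed = run$config$seed
  )
  jsonlite::write_json(summary_obj, file.path(out_dir, "run.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
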