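# Training orchestration: the five training strategies (supervised with and
# without augmentation, transfer finetuning, layer freezing, self-supervised
# downstream) and the cross-validation schemes (threefold, leave-one-out).
# The segmentation loss is a soft-Dice over the background/foreground
# softmax; a cross-entropy alternative is config-selectable.

#' Training configuration
#'
#' @param strategy One of `"supervised"`, `"supervised_aug"`, `"finetune"`,
#'   `"layer_freeze"`, `"ssl"`.
#' @param model_spec A [unet_spec()] or [swin_spec()] used when a model is
#'   built from scratch.
#' @param epochs Full-training epoch budget.
#' @param finetune_epochs Epochs used by the finetune/layer-freeze
#'   strategies; one of 2, 4, 6, 8, 10 (default 6, the best-performing
#'   setting).
#' @param augmentation_rate One of 1, 4, 8, 16, 32.
#' @param loss `"soft_dice"` or `"cross_entropy"`.
#' @param lr Adam learning rate.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `train_config`.
#' @export
train_config <- function(strategy = c("supervised", "supervised_aug",
                                      "finetune", "layer_freeze", "ssl"),
                         model_spec = NULL, epochs = 10L,
                         finetune_epochs = 6L, augmentation_rate = 1L,
                         loss = c("soft_dice", "cross_entropy"),
                         lr = 1e-3, seed = 1L) {
  strategy <- match.arg(strategy)
  loss <- match.arg(loss)
  if (!finetune_epochs %in% c(2L, 4L, 6L, 8L, 10L)) {
    stop("finetune_epochs must be one of 2, 4, 6, 8, 10")
  }
  if (!augmentation_rate %in% c(1L, 4L, 8L, 16L, 32L)) {
    stop("augmentation_rate must be one of 1, 4, 8, 16, 32")
  }
  structure(list(strategy = strategy, model_spec = model_spec,
                 epochs = as.integer(epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 augmentation_rate = as.integer(augmentation_rate),
                 loss = loss, lr = lr, seed = as.integer(seed)),
            class = "train_config")
}

#' Build a cross-validation fold plan
#'
#' `threefold` shuffles the ids and splits them into three disjoint
#' near-equal subsets; `leave_one_out` makes one singleton test fold per id.
#'
#' @param case_ids Character vector of case identifiers.
#' @param scheme `"threefold"` or `"leave_one_out"`.
#' @param seed Shuffling seed.
#' @return A `fold_plan` with disjoint, covering `partitions`.
#' @export
make_folds <- function(case_ids, scheme = c("threefold", "leave_one_out"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(case_ids)
  if (scheme == "threefold" && n < 3) {
    stop("threefold cross-validation needs at least 3 cases, got ", n)
  }
  if (scheme == "leave_one_out" && n < 2) {
    stop("leave-one-out cross-validation needs at least 2 cases, got ", n)
  }
  set.seed(seed)
  ids <- sample(case_ids)
  partitions <- if (scheme == "threefold") {
    unname(split(ids, rep(1:3, length.out = n)))
  } else {
    as.list(ids)
  }
  structure(list(scheme = scheme, partitions = partitions),
            class = "fold_plan")
}

# ---- segmentation losses ---------------------------------------------------

soft_dice_loss <- function(logits, target, eps = 1) {
  p1 <- 1 / (1 + exp(logits[, , , 1] - logits[, , , 2]))
  s1 <- sum(p1 * target)
  s2 <- sum(p1)
  s3 <- sum(target)
  den <- s2 + s3 + eps
  loss <- 1 - (2 * s1 + eps) / den
  dp1 <- -(2 * target * den - (2 * s1 + eps)) / den^2
  dl1 <- dp1 * p1 * (1 - p1)
  dlogits <- array(0, dim(logits))
  dlogits[, , , 1] <- -dl1
  dlogits[, , , 2] <- dl1
  list(loss = loss, dlogits = dlogits)
}

cross_entropy_loss <- function(logits, target) {
  l0 <- logits[, , , 1]
  l1 <- logits[, , , 2]
  m <- pmax(l0, l1)
  lse <- m + log(exp(l0 - m) + exp(l1 - m))
  n <- length(target)
  loss <- sum(lse - ifelse(target > 0, l1, l0)) / n
  p1 <- exp(l1 - lse)
  dl1 <- (p1 - target) / n
  dlogits <- array(0, dim(logits))
  dlogits[, , , 1] <- -dl1
  dlogits[, , , 2] <- dl1
  list(loss = loss, dlogits = dlogits)
}

seg_loss <- function(kind) {
  switch(kind, soft_dice = soft_dice_loss, cross_entropy = cross_entropy_loss)
}

#' Train a segmentation model on labeled canonical cases
#'
#' Single-volume Adam steps with the chosen segmentation loss, honoring the
#' model's trainability flags (frozen groups stay bit-identical).
#'
#' @param model A `seg_model`.
#' @param cases Non-empty list of `canonical_case` objects.
#' @param epochs,lr Schedule.
#' @param loss `"soft_dice"` (default) or `"cross_entropy"`.
#' @param seed Shuffling seed.
#' @return A list of class `seg_fit` with the trained `model` and a
#'   per-epoch `history` tibble.
#' @export
train_model <- function(model, cases, epochs = 10L, lr = 1e-3,
                        loss = "soft_dice", seed = 1L) {
  stopifnot(inherits(model, "seg_model"))
  if (!length(cases)) stop("training needs a non-empty case list")
  lfun <- seg_loss(loss)
  state <- adam_init(model$params)
  history <- tibble::tibble(epoch = integer(), loss = numeric())
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, ep))
    ord <- sample(seq_along(cases))
    losses <- numeric(length(ord))
    for (q in seq_along(ord)) {
      cs <- cases[[ord[q]]]
      out <- model_forward(model, cs$image, cache = TRUE)
      lb <- lfun(out$y, cs$label)
      losses[q] <- lb$loss
      grads <- model_backward(model, out$cache, lb$dlogits)
      upd <- adam_step(model$params, grads, state, model$trainable, lr = lr)
      model$params <- upd$params
      state <- upd$state
    }
    history <- dplyr::bind_rows(history,
                                tibble::tibble(epoch = ep,
                                               loss = mean(losses)))
  }
  structure(list(model = model, history = history), class = "seg_fit")
}

resolve_pretrained <- function(pretrained, strategy) {
  if (is.null(pretrained)) {
    stop("strategy '", strategy,
         "' requires a pretrained checkpoint (model object or .rds path)")
  }
  if (is.character(pretrained)) {
    obj <- readRDS(pretrained)
    if (is.list(obj) && !is.null(obj$arch)) {
      return(load_checkpoint(pretrained))
    }
    return(obj)
  }
  pretrained
}

#' Run one training strategy and score held-out cases
#'
#' Implements the five studied strategies: `supervised` trains from scratch
#' on the unaugmented training cases; `supervised_aug` first expands them by
#' the configured augmentation rate; `finetune` loads a pretrained
#' segmentation model and retrains every parameter for `finetune_epochs` on
#' the augmented cases; `layer_freeze` does the same but only updates the
#' two decoder blocks nearest the output (plus head); `ssl` transplants a
#' pretrained pretext encoder, freezes it and trains the decoding path.
#'
#' @param train_cases,test_cases Lists of `canonical_case` objects; test
#'   cases are never augmented.
#' @param config A [train_config()].
#' @param pretrained Checkpoint (object or path) for the strategies that
#'   need one.
#' @return A list of class `strategy_fit` with `model`, per-test-case
#'   `scores` tibble and the `config`.
#' @export
run_strategy <- function(train_cases, test_cases, config, pretrained = NULL) {
  stopifnot(inherits(config, "train_config"))
  seed <- config$seed
  model <- switch(
    config$strategy,
    supervised = {
      m <- build_model_from_spec(config$model_spec, derive_seed(seed, 11L))
      train_model(m, train_cases, epochs = config$epochs, lr = config$lr,
                  loss = config$loss, seed = seed)$model
    },
    supervised_aug = {
      aug <- expand_training_set(train_cases, config$augmentation_rate,
                                 seed = derive_seed(seed, 21L))
      m <- build_model_from_spec(config$model_spec, derive_seed(seed, 11L))
      train_model(m, aug, epochs = config$epochs, lr = config$lr,
                  loss = config$loss, seed = seed)$model
    },
    finetune = {
      m <- resolve_pretrained(pretrained, "finetune")
      stopifnot(inherits(m, "seg_model"))
      m <- set_trainable(m, "all")
      aug <- expand_training_set(train_cases, config$augmentation_rate,
                                 seed = derive_seed(seed, 21L))
      train_model(m, aug, epochs = config$finetune_epochs, lr = config$lr,
                  loss = config$loss, seed = seed)$model
    },
    layer_freeze = {
      m <- resolve_pretrained(pretrained, "layer_freeze")
      stopifnot(inherits(m, "seg_model"))
      m <- set_trainable(m, "bottom_two_only")
      aug <- expand_training_set(train_cases, config$augmentation_rate,
                                 seed = derive_seed(seed, 21L))
      train_model(m, aug, epochs = config$finetune_epochs, lr = config$lr,
                  loss = config$loss, seed = seed)$model
    },
    ssl = {
      pm <- resolve_pretrained(pretrained, "ssl")
      if (is.list(pm) && !is.null(pm$model)) pm <- pm$model
      if (!inherits(pm, "pretext_model")) {
        stop("strategy 'ssl' requires a pretrained pretext encoder checkpoint")
      }
      aug <- expand_training_set(train_cases, config$augmentation_rate,
                                 seed = derive_seed(seed, 21L))
      downstream_train(pm, aug, epochs = config$epochs, lr = config$lr,
                       seed = seed)
    })
  scores <- score_cases(model, test_cases)
  structure(list(model = model, scores = scores, config = config),
            class = "strategy_fit")
}

build_model_from_spec <- function(spec, seed) {
  if (is.null(spec)) stop("config$model_spec is required to build a model")
  if (inherits(spec, "unet_spec")) build_unet(spec, seed = seed)
  else build_swin_unetr(spec, seed = seed)
}

score_cases <- function(model, cases, rule = detection_rule()) {
  purrr::map_dfr(cases, function(cs) {
    pred <- segment(model, cs$image)
    sc <- dice(pred, cs$label)
    tibble::tibble(case = cs$source_id,
                   size_class = cs$size_class,
                   dice = sc$dice,
                   detected = detect(pred, rule))
  })
}

#' Run a cross-validated experiment
#'
#' For every fold of the plan, trains the configured strategy on the tumor
#' cases outside the fold and scores the fold's cases.  Normal (tumor-free)
#' cases never enter any training fold; in detection mode they are scored
#' once, by a model trained on all tumor cases, and a detection table over
#' the groups is assembled.
#'
#' @param cases Named list of `canonical_case` objects (names are case ids).
#' @param plan A [make_folds()] plan over the tumor case ids.
#' @param config A [train_config()].
#' @param pretrained Optional checkpoint forwarded to [run_strategy()].
#' @param detection Score normal cases and build a detection table.
#' @param normal_cases Named list of normal cases with a `group` attribute
#'   (`normal_plain` / `normal_hyperintense`) when `detection = TRUE`.
#' @param rule A [detection_rule()].
#' @return An `experiment_report`: per-fold scores, mean Dice, and (in
#'   detection mode) the detection table and its metrics.
#' @export
run_experiment <- function(cases, plan, config, pretrained = NULL,
                           detection = FALSE, normal_cases = list(),
                           rule = detection_rule()) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- names(cases)
  fold_scores <- list()
  for (f in seq_along(plan$partitions)) {
    test_ids <- intersect(plan$partitions[[f]], ids)
    train_ids <- setdiff(ids, test_ids)
    if (!length(test_ids)) next
    fit <- run_strategy(cases[train_ids], cases[test_ids], config,
                        pretrained = pretrained)
    fold_scores[[length(fold_scores) + 1]] <-
      dplyr::mutate(fit$scores, fold = f)
  }
  per_case <- dplyr::bind_rows(fold_scores)
  report <- list(scheme = plan$scheme, strategy = config$strategy,
                 augmentation_rate = config$augmentation_rate,
                 per_case = per_case,
                 mean_dice = mean(per_case$dice))
  if (detection) {
    full_fit <- run_strategy(cases, normal_cases, config,
                             pretrained = pretrained)
    groups <- vapply(normal_cases, function(cs) cs$group %||% "normal_plain",
                     character(1))
    normal_scores <- dplyr::mutate(full_fit$scores, group = unname(groups))
    tumor_groups <- vapply(cases, function(cs) {
      paste0(cs$size_class, "_tumor")
    }, character(1))
    tumor_scores <- dplyr::mutate(per_case, group = unname(tumor_groups[case]))
    all_scores <- dplyr::bind_rows(tumor_scores, normal_scores)
    report$detection_table <- detection_table(all_scores)
    report$detection_metrics <- detection_metrics(report$detection_table)
    report$normal_scores <- normal_scores
  }
  structure(report, class = "experiment_report")
}

#' Serialize / deserialize an experiment report
#'
#' @param report An `experiment_report`.
#' @param path JSON file path.
#' @return `read_experiment_report` returns the report.
#' @export
write_experiment_report <- function(report, path) {
  obj <- unclass(report)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_experiment_report
#' @export
read_experiment_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_case <- tibble::as_tibble(obj$per_case)
  if (!is.null(obj$detection_table)) {
    obj$detection_table <- structure(tibble::as_tibble(obj$detection_table),
                                     class = c("detection_table",
                                               class(tibble::tibble())))
  }
  structure(obj, class = "experiment_report")
}

#' @export
tidy.experiment_report <- function(x, ...) x$per_case

#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, strategy = x$strategy,
                 augmentation_rate = x$augmentation_rate,
                 n_cases = nrow(x$per_case), mean_dice = x$mean_dice)
}

#' @export
tidy.seg_fit <- function(x, ...) x$history

#' @export
glance.seg_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 final_loss = utils::tail(x$history$loss, 1))
}
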