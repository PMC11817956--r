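test_that("fold plans are disjoint, covering, and sized as stated", {
  ids33 <- sprintf("c%02d", 1:33)
  plan <- make_folds(ids33, "threefold", seed = 1)
  expect_length(plan$partitions, 3)
  expect_equal(vapply(plan$partitions, length, integer(1)), rep(11L, 3))
  expect_setequal(unlist(plan$partitions), ids33)
  expect_equal(anyDuplicated(unlist(plan$partitions)), 0)
  ids15 <- sprintf("s%02d", 1:15)
  loo <- make_folds(ids15, "leave_one_out", seed = 2)
  expect_length(loo$partitions, 15)
  expect_true(all(vapply(loo$partitions, length, integer(1)) == 1))
  expect_setequal(unlist(loo$partitions), ids15)
  expect_error(make_folds("a", "threefold"), "at least 3")
  expect_error(make_folds("a", "leave_one_out"), "at least 2")
})

test_that("training configurations validate their domains", {
  expect_error(train_config(finetune_epochs = 5), "2, 4, 6, 8, 10")
  expect_error(train_config(augmentation_rate = 3), "1, 4, 8, 16, 32")
  expect_error(train_config(strategy = "magic"))
  cfg <- train_config("supervised", model_spec = tiny_unet_spec())
  expect_s3_class(cfg, "train_config")
})

test_that("strategies require their pretrained artifacts by name", {
  cases <- make_blob_cases(2, seed0 = 70)
  cfg <- train_config("ssl", model_spec = tiny_swin_spec(), epochs = 1)
  expect_error(run_strategy(cases, cases, cfg), "pretrained")
  cfg2 <- train_config("finetune", model_spec = tiny_unet_spec())
  expect_error(run_strategy(cases, cases, cfg2), "pretrained")
})

test_that("a strategy run is deterministic for a fixed seed", {
  cases <- make_blob_cases(3, seed0 = 80)
  cfg <- train_config("supervised", model_spec = tiny_unet_spec(),
                      epochs = 1, seed = 5)
  f1 <- run_strategy(cases[1:2], cases[3], cfg)
  f2 <- run_strategy(cases[1:2], cases[3], cfg)
  expect_identical(f1$scores$dice, f2$scores$dice)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("layer freezing keeps everything but the bottom two blocks and head", {
  cases <- make_blob_cases(2, seed0 = 90)
  pre <- build_unet(tiny_unet_spec(), seed = 11)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(pre, ck)
  cfg <- train_config("layer_freeze", finetune_epochs = 2,
                      augmentation_rate = 1, seed = 3)
  fit <- run_strategy(cases[1], cases[2], cfg, pretrained = ck)
  frozen <- names(pre$params)[!(pre$groups %in% c("bottom_two", "head"))]
  expect_identical(fit$model$params[frozen], pre$params[frozen])
})

test_that("leave-one-out experiments report one score per fold", {
  cases <- make_blob_cases(4, seed0 = 95)
  names(cases) <- vapply(cases, function(x) x$source_id, character(1))
  plan <- make_folds(names(cases), "leave_one_out", seed = 1)
  cfg <- train_config("supervised", model_spec = tiny_unet_spec(),
                      epochs = 1, seed = 2)
  rep <- run_experiment(cases, plan, cfg)
  expect_equal(nrow(rep$per_case), 4)
  expect_setequal(rep$per_case$case, names(cases))
  expect_equal(rep$mean_dice, mean(rep$per_case$dice))
  gl <- glance(rep)
  expect_equal(gl$n_cases, 4)
})

test_that("detection mode keeps normal cases out of training and tables them", {
  cases <- make_blob_cases(3, seed0 = 100)
  names(cases) <- vapply(cases, function(x) x$source_id, character(1))
  normals <- lapply(1:2, function(i) {
    set.seed(400 + i)
    shape <- c(32L, 32L, 32L)
    img <- array(stats::runif(prod(shape), 0, 0.3), shape)
    cs <- neuroseg:::new_canonical_case(img, array(0L, shape),
                                        paste0("normal", i), "none", 0,
                                        shape)
    cs$group <- if (i == 1) "normal_plain" else "normal_hyperintense"
    cs
  })
  names(normals) <- vapply(normals, function(x) x$source_id, character(1))
  plan <- make_folds(names(cases), "leave_one_out", seed = 1)
  cfg <- train_config("supervised", model_spec = tiny_unet_spec(),
                      epochs = 1, seed = 2)
  rep <- run_experiment(cases, plan, cfg, detection = TRUE,
                        normal_cases = normals)
  # normals never appear among the cross-validated (trained-on) cases
  expect_false(any(names(normals) %in% rep$per_case$case))
  expect_s3_class(rep$detection_table, "detection_table")
  expect_setequal(
    rep$detection_table$group[grepl("normal", rep$detection_table$group)],
    c("normal_plain", "normal_hyperintense"))
  expect_true(all(c("sensitivity", "specificity_all",
                    "specificity_excl_hyper") %in%
                    names(rep$detection_metrics)))
})

test_that("experiment reports round-trip through JSON", {
  per_case <- tibble::tibble(case = c("a", "b"), size_class = "small",
                             dice = c(0.5, 0.25), detected = c(TRUE, FALSE),
                             fold = 1:2)
  rep <- structure(list(scheme = "leave_one_out", strategy = "supervised",
                        augmentation_rate = 4L, per_case = per_case,
                        mean_dice = 0.375),
                   class = "experiment_report")
  p <- withr::local_tempfile(fileext = ".json")
  write_experiment_report(rep, p)
  rt <- read_experiment_report(p)
  expect_equal(rt$mean_dice, rep$mean_dice)
  expect_equal(rt$strategy, rep$strategy)
  expect_equal(as.data.frame(rt$per_case), as.data.frame(per_case))
})

test_that("augmented variants never cross onto the test side", {
  cases <- make_blob_cases(2, seed0 = 120)
  aug <- expand_training_set(cases, 4, seed = 1)
  test_ids <- "caseX"
  expect_false(any(vapply(aug, function(x) x$source_id, character(1)) %in%
                     test_ids))
  # expansion inherits only training source ids
  expect_setequal(unique(vapply(aug, function(x) x$source_id, character(1))),
                  vapply(cases, function(x) x$source_id, character(1)))
})
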