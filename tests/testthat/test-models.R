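test_that("the U-net shape ladder matches the closed form at desk scale", {
  sp <- unet_spec(base_channels = 4, input_shape = c(64, 64, 32))
  lad <- unet_ladder(sp)
  expect_equal(lad$channels, c(4, 8, 16, 32, 64))
  expect_equal(lad$x[5], 4)
  expect_equal(lad$z[5], 2)
  m <- build_unet(sp, seed = 1)
  out <- model_forward(m, array(0, c(64, 64, 32)))
  expect_equal(out$shapes$bottleneck, c(4, 4, 2, 64))
  expect_equal(out$shapes$out, c(64, 64, 32, 2))
  # every encoder stage shape agrees with the ladder oracle
  for (s in 1:4) {
    expect_equal(out$shapes[[paste0("enc", s)]],
                 c(lad$x[s + 1], lad$y[s + 1], lad$z[s + 1],
                   lad$channels[s + 1]))
  }
  expect_error(unet_spec(input_shape = c(60, 64, 32)), "multiples of 32")
})

test_that("the Swin-style ladder ends at 16x the embedding dimension", {
  sp <- tiny_swin_spec()
  lad <- swin_ladder(sp)
  expect_equal(lad$channels, c(6, 12, 24, 48, 96))
  m <- build_swin_unetr(sp, seed = 1)
  out <- model_forward(m, array(0, c(32, 32, 32)))
  expect_equal(out$shapes$bottleneck[4], 96)           # 16 * embed_dim
  expect_equal(out$shapes$dec5[4], sp$embed_dim)       # decoder feature
  expect_equal(out$shapes$out, c(32, 32, 32, 2))
  for (s in 0:4) {
    expect_equal(out$shapes[[paste0("stage", s)]][4], lad$channels[s + 1])
  }
  # defaults: ladder oracle for the full-scale configuration
  ld <- swin_ladder(swin_spec())
  expect_equal(ld$channels[5], 768)
  expect_equal(unlist(ld[5, c("x", "y", "z")], use.names = FALSE),
               c(4, 4, 2))
})

test_that("incompatible attention windows are rejected", {
  sp <- swin_spec(embed_dim = 6, input_shape = c(32, 32, 32),
                  window_size = 3)
  m <- build_swin_unetr(sp, seed = 1)
  expect_error(model_forward(m, array(0, c(32, 32, 32))), "window")
})

test_that("segmentation is an argmax with background winning ties", {
  y <- array(0, c(4, 4, 2, 2))
  y[, , , 1] <- 1
  expect_true(all(neuroseg:::logits_to_mask(y) == 0))
  y[2:3, 2:3, 1, 2] <- 5
  m <- neuroseg:::logits_to_mask(y)
  expect_equal(sum(m), 4)
  expect_equal(m[2, 2, 1], 1)
  ties <- array(0.7, c(4, 4, 2, 2))
  expect_true(all(neuroseg:::logits_to_mask(ties) == 0))
  model <- build_unet(tiny_unet_spec(), seed = 2)
  x <- array(stats::rnorm(32^3), c(32, 32, 32))
  expect_identical(segment(model, x), segment(model, x))
  expect_true(all(segment(model, x) %in% c(0, 1)))
  expect_error(model_forward(model, array(0, c(16, 16, 16))), "contract")
})

test_that("parameter groups partition the parameters", {
  for (m in list(build_unet(tiny_unet_spec(), seed = 1),
                 build_swin_unetr(tiny_swin_spec(), seed = 1))) {
    pg <- parameter_groups(m)
    expect_setequal(pg$parameter, names(m$params))
    expect_true(all(pg$group %in% c("encoder", "decoder", "bottom_two",
                                    "head")))
    expect_true(all(table(pg$parameter) == 1))
    expect_true(all(c("encoder", "decoder", "bottom_two", "head") %in%
                      pg$group))
  }
})

test_that("trainability policies freeze exactly the stated groups", {
  cases <- make_blob_cases(1, seed0 = 60)
  for (build in list(function() build_unet(tiny_unet_spec(), seed = 3),
                     function() build_swin_unetr(tiny_swin_spec(),
                                                 seed = 3))) {
    m0 <- build()
    for (policy in c("bottom_two_only", "decoder_only")) {
      m <- set_trainable(m0, policy)
      fit <- train_model(m, cases, epochs = 1, lr = 1e-2, seed = 5)
      on <- switch(policy,
                   bottom_two_only = c("bottom_two", "head"),
                   decoder_only = c("decoder", "bottom_two", "head"))
      frozen <- names(m0$params)[!(m0$groups %in% on)]
      live <- names(m0$params)[m0$groups %in% on]
      expect_identical(fit$model$params[frozen], m0$params[frozen])
      changed <- vapply(live, function(nm) {
        !identical(fit$model$params[[nm]], m0$params[[nm]])
      }, logical(1))
      expect_gt(mean(changed), 0.5)
    }
    m <- set_trainable(m0, "all")
    expect_true(all(m$trainable))
  }
})

test_that("checkpoints round-trip weights and spec", {
  m <- build_unet(tiny_unet_spec(), seed = 9)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$params, m$params)
  expect_equal(m2$spec, m$spec)
  x <- array(stats::rnorm(32^3), c(32, 32, 32))
  expect_identical(segment(m, x), segment(m2, x))
})

test_that("tidy and glance summarize fitted models", {
  m <- build_unet(tiny_unet_spec(), seed = 1)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(m$params))
  gl <- glance(m)
  expect_equal(gl$architecture, "unet")
  expect_gt(gl$n_parameters, 0)
})
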