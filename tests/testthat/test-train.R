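test_that("the learning-rate schedule matches its closed form", {
  expect_equal(lr_schedule(1.25e-3, 0.95, 0), 1.25e-3)
  expect_equal(lr_schedule(1.25e-3, 1, 17), 1.25e-3)
  expect_equal(lr_schedule(1.25e-3, 0.95, 20), 1.25e-3 * 0.95^20)
  expect_equal(lr_schedule(1.25e-3, 0.95, 20), 4.4811e-4, tolerance = 1e-4)
  lrs <- vapply(0:19, function(e) lr_schedule(1.25e-3, 0.95, e), numeric(1))
  expect_true(all(diff(lrs) < 0))
  expect_error(lr_schedule(1e-3, 0.95, -1), "epoch")
  expect_error(train_config(gamma = 1.5), "gamma")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("a one-epoch run trains, logs and checkpoints", {
  cfg <- synth_config(image_width_px = 96, image_height_px = 96,
                      n_stomata_range = c(1, 1), angle_range_deg = c(20, 160))
  samples <- lapply(1:4, function(i) generate_sample(cfg, 400 + i))
  out <- withr::local_tempdir()
  tc <- train_config(epochs = 1, batch_size = 2, seed = 1)
  m <- train_detector(samples, tc, out_dir = out)
  expect_s3_class(m, "rsd_model")
  expect_equal(nrow(m$history), 1)
  expect_true(file.exists(file.path(out, "training_log.csv")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  log <- read.csv(file.path(out, "training_log.csv"))
  expect_true(all(c("epoch", "lr", "train_total", "val_total", "LH", "Loff",
                    "Lsize", "Lang", "Lcon", "val_precision", "val_recall",
                    "val_f1") %in% names(log)))
  expect_true(is.finite(log$train_total))
  # 3:1 split of 4 samples
  expect_equal(m$n_train, 3)
  expect_equal(m$n_val, 1)
  # predict returns detection lists
  dets <- predict(m, samples[[4]]$image)
  expect_type(dets, "list")
})

test_that("training is reproducible: identical seeds give identical losses", {
  cfg <- synth_config(image_width_px = 96, image_height_px = 96,
                      n_stomata_range = c(1, 1))
  samples <- lapply(1:4, function(i) generate_sample(cfg, 500 + i))
  tc <- train_config(epochs = 1, batch_size = 2, seed = 9)
  m1 <- train_detector(samples, tc)
  m2 <- train_detector(samples, tc)
  expect_equal(m1$history$train_total, m2$history$train_total,
               tolerance = 1e-6)
  expect_identical(m1$history$val_f1, m2$history$val_f1)
})

test_that("the loss on a fixed batch decreases over the first steps", {
  set.seed(91)
  sk <- asNamespace("stomakit")
  cfg <- synth_config(image_width_px = 96, image_height_px = 96,
                      n_stomata_range = c(2, 2), angle_range_deg = c(20, 160))
  s <- generate_sample(cfg, 77)
  net <- sk$with_seed(5, build_network(net_config()))
  params <- sk$network_params(net)
  opt <- sk$adamw_state(params)
  tg <- encode_targets(s$annotations, 4, 24, 24)
  tc <- train_config()
  losses <- numeric(50)
  for (t in 1:50) {
    sk$zero_grads(params)
    tape <- sk$new_tape()
    il <- sk$image_losses(tape, net, s, tg, tc)
    losses[t] <- il$total_value
    sk$tape_backward(tape, il$total)
    opt <- sk$adamw_step(params, opt, 1.25e-3, t = t)
  }
  expect_lt(mean(losses[41:50]), mean(losses[1:10]))
  expect_lt(losses[50], losses[1])
})
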