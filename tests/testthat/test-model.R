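# Classifier architecture, parameter accounting, gradient correctness and
# the training loop.

test_that("feature maps halve per layer and the flattened width feeds the head", {
  cfg <- model_config()
  expect_equal(gaitkit:::conv_spatial_sizes(cfg), c(112L, 56L, 28L, 14L, 7L))
  clf <- build_classifier(cfg)
  dense1 <- Filter(function(l) l$type == "dense", clf$net)[[1]]
  expect_equal(dense1$nin, 7L * 7L * 64L)
})

test_that("layer-wise parameter accounting matches the closed form", {
  clf <- build_classifier(model_config())
  by_type <- c(conv = 0, bn = 0, dense = 0)
  for (l in clf$net) {
    if (l$type %in% c("conv", "dense"))
      by_type[l$type] <- by_type[l$type] + length(l$W) + length(l$b)
    if (l$type == "bn") by_type["bn"] <- by_type["bn"] + 4 * l$c
  }
  expect_equal(unname(by_type["conv"]), 74816)    # 9*Cin*Cout + Cout per layer
  expect_equal(unname(by_type["bn"]), 896)        # 4 per normalized channel
  expect_equal(unname(by_type["dense"]), 3136 * 512 + 512 + 512 * 5 + 5)
  expect_equal(count_parameters(clf), sum(by_type))

  # a single 1-unit dense layer on one input counts weight + bias
  toy <- structure(list(net = list(gaitkit:::layer_dense(1L, 1L))),
                   class = "gait_classifier")
  expect_equal(count_parameters(toy), 2L)
})

test_that("weight initialization is a deterministic function of the seed", {
  a <- build_classifier(tiny_model_config(seed = 5L))
  b <- build_classifier(tiny_model_config(seed = 5L))
  c <- build_classifier(tiny_model_config(seed = 6L))
  expect_identical(a$net, b$net)
  expect_false(identical(a$net[[1]]$W, c$net[[1]]$W))
})

test_that("softmax outputs form a probability simplex for arbitrary inputs", {
  clf <- build_classifier(tiny_model_config())
  set.seed(2)
  inputs <- list(matrix(stats::runif(256), 16, 16),
                 matrix(0, 16, 16), matrix(1, 16, 16))
  p <- predict(clf, inputs)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_error(predict(clf, matrix(0, 10, 10)))
})

test_that("analytic gradients match finite differences for every layer type", {
  cfg <- tiny_model_config(seed = 42L)
  clf <- build_classifier(cfg)
  # nudge biases/shifts off zero so no pre-activation sits exactly on the
  # rectifier kink (where the one-sided numerical derivative is undefined)
  set.seed(8)
  for (i in seq_along(clf$net)) {
    for (nm in intersect(names(clf$net[[i]]), c("b", "beta")))
      clf$net[[i]][[nm]] <- stats::rnorm(length(clf$net[[i]][[nm]]), 0, 0.3)
  }
  imgs <- lapply(1:4, function(i) matrix(stats::runif(256), 16, 16))
  tin <- gaitkit:::input_tensor(imgs, cfg)
  Y <- gaitkit:::onehot_labels(c("a", "b", "c", "a"), cfg$classes)
  loss_of <- function(net) {
    fw <- gaitkit:::net_forward(net, tin, training = TRUE)
    gaitkit:::softmax_ce(fw$out, Y)$loss
  }
  fw <- gaitkit:::net_forward(clf$net, tin, training = TRUE)
  r <- gaitkit:::softmax_ce(fw$out, Y)
  bw <- gaitkit:::net_backward(clf$net, fw$caches, r$dlogits)
  eps <- 1e-6
  for (i in seq_along(clf$net)) {
    fields <- gaitkit:::trainable_fields(clf$net[[i]])
    if (is.null(fields)) next
    for (nm in fields) {
      v <- clf$net[[i]][[nm]]
      for (p in sample(length(v), min(4L, length(v)))) {
        n1 <- clf$net; n1[[i]][[nm]][p] <- v[p] + eps
        n2 <- clf$net; n2[[i]][[nm]][p] <- v[p] - eps
        num <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
        ana <- bw$grads[[i]][[nm]][p]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = sprintf("grad %s/%s[%d] (layer %d)",
                                     clf$net[[i]]$type, nm, p, i))
      }
    }
  }
  # gradient with respect to the input (used by the saliency map)
  p <- 101L
  t1 <- tin; t1$x[1, p] <- t1$x[1, p] + eps
  t2 <- tin; t2$x[1, p] <- t2$x[1, p] - eps
  num <- (loss_of_input <- function(tt) {
    f <- gaitkit:::net_forward(clf$net, tt, training = TRUE)
    gaitkit:::softmax_ce(f$out, Y)$loss
  })(t1) - loss_of_input(t2)
  expect_equal(bw$dinput$x[1, p], num / (2 * eps), tolerance = 1e-4)
})

test_that("training reduces the loss and is reproducible for a fixed seed", {
  ds <- tiny_image_set()
  cfg <- tiny_model_config(seed = 3L)
  clf0 <- build_classifier(cfg)
  p0 <- predict(clf0, ds$images)
  init_loss <- -mean(log(p0[cbind(seq_along(ds$labels),
                                  match(ds$labels, cfg$classes))]))
  clf1 <- train_classifier(clf0, ds$images, ds$labels,
                           validation_fraction = 0, epochs = 10L)
  expect_lt(clf1$history$loss[1], init_loss + 0.05)
  expect_lt(clf1$history$loss[nrow(clf1$history)], init_loss)
  clf2 <- train_classifier(build_classifier(cfg), ds$images, ds$labels,
                           validation_fraction = 0, epochs = 10L)
  expect_identical(clf1$net, clf2$net)
})

test_that("training rejects degenerate label sets", {
  ds <- tiny_image_set(n_per_class = 2L)
  clf <- build_classifier(tiny_model_config())
  expect_error(train_classifier(clf, ds$images[1:2], c("a", "a")),
               "two classes")
  expect_error(train_classifier(clf, ds$images, rep(c("a", "b", "z"), each = 2)),
               "outside the class set")
})

test_that("classifiers round-trip through the checkpoint container", {
  clf <- build_classifier(tiny_model_config())
  path <- file.path(tempdir(), "clf.rds")
  save_classifier(clf, path)
  expect_true(file.exists(sub("\\.rds$", "_config.yaml", path)))
  back <- load_classifier(path)
  expect_identical(back$net, clf$net)
  set.seed(4)
  img <- matrix(stats::runif(256), 16, 16)
  expect_identical(predict(back, img), predict(clf, img))
})
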