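test_that("window labelling follows the pre-impact rule", {
  spec <- simulation_spec()
  sim <- simulate_fall("F11", spec, seed = 9)
  ds <- list(sim, list(rec = simulate_adl("D06", spec, seed = 9),
                       label = NULL))
  lw <- label_windows(ds, width = 50, stride = 5, max_adl_per_file = Inf)
  ends <- vapply(lw$windows, function(w) w$end_frame, 1L)
  onset <- sim$label$onset_frame
  impact <- sim$label$impact_frame
  fall_trial <- lw$file == 1L
  # no window of the fall trial extends past the impact frame
  expect_true(all(ends[fall_trial] <= impact))
  # fall iff the last frame lies in [onset, impact]
  expect_equal(lw$labels[fall_trial] == "fall", ends[fall_trial] >= onset)
  # ADL recordings contribute only adl windows
  expect_true(all(lw$labels[!fall_trial] == "adl"))
})

test_that("the SVM separates a linearly separable toy set exactly", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("adl", "fall"), each = 20), levels = c("adl", "fall"))
  m <- train_svm(x, y)
  expect_equal(mean(predict_windows(m, x) == y), 1)
  expect_error(train_svm(x, factor(rep("adl", 40),
                                   levels = c("adl", "fall"))), "both class")
  expect_error(train_svm(x[0, , drop = FALSE], y[0]), "empty")
  expect_error(predict_windows(m, x[, 1, drop = FALSE]), "expects 2 features")
})

test_that("both classifiers recover the fall class on held-out subjects", {
  lw <- recovery_windows()
  tr <- lw$train
  fm <- feature_matrix(lw$windows)
  nz <- fit_normalizer(fm[tr, ])
  svm <- train_svm(apply_normalizer(nz, fm[tr, ]), lw$labels[tr])
  acc_svm <- mean(predict_windows(svm, apply_normalizer(nz, fm[!tr, ])) ==
                    lw$labels[!tr])
  expect_gte(acc_svm, 0.95)

  X <- windows_to_array(lw$windows)
  cs <- convlstm_spec(n_filters = c(8L, 16L, 32L), lstm_hidden = 32L)
  m <- train_convlstm(X[tr, , ], lw$labels[tr], spec = cs, epochs = 5,
                      seed = 2026)
  acc_cl <- mean(predict_windows(m, X[!tr, , ]) == lw$labels[!tr])
  expect_gte(acc_cl, 0.95)
  expect_true(all(is.finite(m$history)))
  expect_lt(tail(m$history, 1), m$history[1])  # loss trends downward
})

test_that("convlstm outputs lie on the probability simplex", {
  cs <- convlstm_spec(n_filters = c(4L, 4L, 4L), lstm_hidden = 8L)
  m <- build_convlstm(cs, seed = 1)
  X <- array(rnorm(7 * 50 * 9), c(7, 50, 9))
  p <- predict(m, X)
  expect_equal(dim(p), c(7L, 2L))
  expect_equal(unname(rowSums(p)), rep(1, 7), tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_length(predict_windows(m, X[integer(0), , , drop = FALSE]), 0L)
  expect_error(predict_windows(m, matrix(0, 3, 40)), "raw")
  expect_error(convlstm_forward <- predict(m, array(0, c(2, 20, 9))),
               "input must be")
})

test_that("invalid architectures are rejected at construction", {
  expect_error(convlstm_spec(pool = 4L, input_width = 50L), "collapses")
  expect_error(convlstm_spec(kernel = 4L), "odd")
  expect_error(convlstm_spec(n_filters = c(8L, 8L)), "three")
  expect_error(convlstm_spec(dropout = 1), "dropout")
})

test_that("training is reproducible under a fixed seed and flags divergence", {
  set.seed(30)
  X <- array(rnorm(40 * 16 * 2), c(40, 16, 2))
  X[21:40, , 1] <- X[21:40, , 1] + 3
  y <- factor(rep(c("adl", "fall"), each = 20), levels = c("adl", "fall"))
  cs <- convlstm_spec(n_filters = c(2L, 3L, 3L), kernel = 3L,
                      lstm_hidden = 4L, input_width = 16L,
                      input_channels = 2L)
  m1 <- train_convlstm(X, y, spec = cs, epochs = 3, seed = 5)
  m2 <- train_convlstm(X, y, spec = cs, epochs = 3, seed = 5)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$history)))
  # non-finite activations surface as a training error naming the epoch
  Xbad <- X
  Xbad[1, 1, 1] <- NaN
  expect_error(train_convlstm(Xbad, y, spec = cs, epochs = 2, seed = 5),
               "diverged.*epoch 1")
  expect_error(train_convlstm(X, factor(rep("adl", 40),
                                        levels = c("adl", "fall")),
                              spec = cs), "both class")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(14)
  cs <- convlstm_spec(n_filters = c(2L, 3L, 3L), kernel = 3L, pool = 2L,
                      lstm_hidden = 4L, dropout = 0, input_width = 16L,
                      input_channels = 2L)
  model <- build_convlstm(cs, seed = 6)
  X <- array(rnorm(4 * 16 * 2), c(4, 16, 2))
  Y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  res <- preimpact:::convlstm_loss(model, X, Y, training = TRUE)
  loss_at <- function(m) preimpact:::convlstm_loss(m, X, Y, training = TRUE,
                                                   want_grads = FALSE)$loss
  eps <- 1e-5
  check_param <- function(getter, setter, grads) {
    g <- getter(model$params)
    ga <- getter(grads)
    for (i in sample(length(g), min(6L, length(g)))) {
      mp <- model; pp <- getter(mp$params); pp[i] <- pp[i] + eps
      mp$params <- setter(mp$params, pp)
      mm <- model; pm <- getter(mm$params); pm[i] <- pm[i] - eps
      mm$params <- setter(mm$params, pm)
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(ga[i], num, tolerance = 1e-4)
    }
  }
  paths <- list(
    list(get = function(p) p$conv[[1]]$W,
         set = function(p, v) { p$conv[[1]]$W <- v; p }),
    list(get = function(p) p$bn[[2]]$gamma,
         set = function(p, v) { p$bn[[2]]$gamma <- v; p }),
    list(get = function(p) p$lstm[[1]]$Wx,
         set = function(p, v) { p$lstm[[1]]$Wx <- v; p }),
    list(get = function(p) p$lstm[[2]]$Wh,
         set = function(p, v) { p$lstm[[2]]$Wh <- v; p }),
    list(get = function(p) p$fc$W,
         set = function(p, v) { p$fc$W <- v; p }))
  for (pth in paths) check_param(pth$get, pth$set, res$grads)
})

test_that("model archives round-trip with their normaliser", {
  lw <- recovery_windows()
  tr <- lw$train
  fm <- feature_matrix(lw$windows)
  nz <- fit_normalizer(fm[tr, ])
  svm <- train_svm(apply_normalizer(nz, fm[tr, ]), lw$labels[tr])
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(svm, path, normalizer = nz)
  arch <- load_model(path)
  expect_identical(
    predict_windows(arch$model, apply_normalizer(arch$normalizer, fm[!tr, ])),
    predict_windows(svm, apply_normalizer(nz, fm[!tr, ])))
})
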