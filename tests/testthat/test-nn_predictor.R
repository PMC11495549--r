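test_that("backpropagated gradients match central finite differences on
           every layer", {
  set.seed(31)
  sizes <- c(2, 4, 7, 4, 1)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l) {
    matrix(runif(sizes[l] * sizes[l + 1], -0.5, 0.5), sizes[l],
           sizes[l + 1])
  })
  B <- lapply(seq_len(L), function(l) runif(sizes[l + 1], -0.5, 0.5))
  X <- matrix(runif(16), 8, 2)
  y <- matrix(runif(8, 0.1, 0.9), ncol = 1)
  A <- soycdrisk:::nn_forward(W, B, X)
  g <- soycdrisk:::nn_gradient(W, A, y)
  h <- 1e-6
  worst <- 0
  for (l in seq_len(L)) {
    for (i in seq_along(W[[l]])) {
      Wp <- W; Wm <- W
      Wp[[l]][i] <- W[[l]][i] + h
      Wm[[l]][i] <- W[[l]][i] - h
      fd <- (soycdrisk:::nn_loss(soycdrisk:::nn_forward(Wp, B, X), y) -
             soycdrisk:::nn_loss(soycdrisk:::nn_forward(Wm, B, X), y)) /
            (2 * h)
      worst <- max(worst, abs(fd - g$W[[l]][i]))
    }
    for (i in seq_along(B[[l]])) {
      Bp <- B; Bm <- B
      Bp[[l]][i] <- B[[l]][i] + h
      Bm[[l]][i] <- B[[l]][i] - h
      fd <- (soycdrisk:::nn_loss(soycdrisk:::nn_forward(W, Bp, X), y) -
             soycdrisk:::nn_loss(soycdrisk:::nn_forward(W, Bm, X), y)) /
            (2 * h)
      worst <- max(worst, abs(fd - g$B[[l]][i]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training is deterministic per seed and monotone in loss", {
  coh <- generate_cohort(default_cohort_spec(seed = 4))
  cfg <- nn_config(seed = 4, max_iterations = 500)
  m1 <- train_nn(coh, cfg)
  m2 <- train_nn(coh, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$B, m2$B)
  expect_lte(m1$final_loss, m1$initial_loss)
  m3 <- train_nn(coh, nn_config(seed = 5, max_iterations = 500))
  expect_false(identical(m1$W, m3$W))
})

test_that("the network fits noiseless planar data to R >= 0.99", {
  set.seed(12)
  cd <- runif(36, 0.4, 3)
  ph <- runif(36, 4.5, 8)
  plane <- make_samples(cd, ph, 0.1 * cd - 0.05 * ph + 0.4)
  m <- train_nn(plane, nn_config(seed = 1))
  ev <- evaluate_nn(m, plane)
  expect_gte(as.numeric(ev$R), 0.99)
})

test_that("predictions are the inverse-scaled sigmoid output: zero weights
           give the output-range midpoint and all predictions stay in the
           inverse-scaled range", {
  coh <- generate_cohort(default_cohort_spec(seed = 6))
  m <- train_nn(coh, nn_config(seed = 6, max_iterations = 50))
  z <- m
  z$W <- lapply(z$W, function(w) w * 0)
  z$B <- lapply(z$B, function(b) b * 0)
  # sigmoid(0) = 0.5 maps back to the midpoint of the output range
  mid <- z$out_lo + (0.5 - 0.1) / 0.8 * (z$out_hi - z$out_lo)
  expect_equal(as.numeric(predict_nn(z, 1.0, 6.0)), mid,
               tolerance = 1e-12)

  # sigmoid output unit bounds every prediction
  grid <- expand.grid(cd = seq(0.1, 5, length.out = 7),
                      ph = seq(3.5, 9.5, length.out = 7))
  p <- as.numeric(predict_nn(m, grid$cd, grid$ph))
  lo_bound <- m$out_lo + (0 - 0.1) / 0.8 * (m$out_hi - m$out_lo)
  hi_bound <- m$out_lo + (1 - 0.1) / 0.8 * (m$out_hi - m$out_lo)
  expect_true(all(p > lo_bound & p < hi_bound))
})

test_that("prediction is continuous and batch predict equals single
           predicts; out-of-range inputs are flagged", {
  coh <- generate_cohort(default_cohort_spec(seed = 7))
  m <- train_nn(coh, nn_config(seed = 7, max_iterations = 200))
  base <- as.numeric(predict_nn(m, 1.5, 6.0))
  for (d in c(1e-4, 1e-6, 1e-8)) {
    expect_lt(abs(as.numeric(predict_nn(m, 1.5 + d, 6.0)) - base), 10 * d)
  }
  batch <- predict_nn(m, coh$soil_cd, coh$soil_ph)
  singles <- vapply(seq_len(nrow(coh)), function(i) {
    as.numeric(predict_nn(m, coh$soil_cd[i], coh$soil_ph[i]))
  }, numeric(1))
  expect_equal(as.numeric(batch), singles, tolerance = 1e-12)

  flagged <- predict_nn(m, max(coh$soil_cd) + 1, 6.0)
  expect_true(attr(flagged, "extrapolated"))
})

test_that("the trained network fits the cohort at least as well as the
           pooled linear model", {
  coh <- generate_cohort(default_cohort_spec(seed = 10))
  m <- train_nn(coh, nn_config(seed = 10))
  nn_r <- as.numeric(evaluate_nn(m, coh)$R)
  mlr <- fit_mlr(coh, "soybean_cd", "pooled")
  mlr_r <- sqrt(mlr$r_squared)
  expect_gt(nn_r, mlr_r)
})

test_that("a perfect predictor scores R = 1, RMSE = 0", {
  coh <- generate_cohort(default_cohort_spec(seed = 3))
  fake <- structure(list(sizes = c(2L, 1L)), class = "nn_model")
  # evaluate_nn only needs predict_nn; emulate perfection by evaluating a
  # trained model on data equal to its own predictions
  m <- train_nn(coh, nn_config(seed = 3, max_iterations = 100))
  pred <- as.numeric(predict_nn(m, coh$soil_cd, coh$soil_ph))
  mirrored <- coh
  mirrored$soybean_cd <- pmax(pred, 0)
  ev <- evaluate_nn(m, mirrored)
  expect_equal(as.numeric(ev$R), 1, tolerance = 1e-9)
  expect_equal(ev$RMSE, 0, tolerance = 1e-12)
})

test_that("JSON serialization round-trips the model and its predictions", {
  coh <- generate_cohort(default_cohort_spec(seed = 8))
  m <- train_nn(coh, nn_config(seed = 8, max_iterations = 300))
  path <- withr::local_tempfile(fileext = ".json")
  nn_to_json(m, path)
  back <- nn_from_json(path)
  expect_equal(back$sizes, m$sizes)
  expect_equal(back$W, m$W, tolerance = 1e-12)
  p1 <- as.numeric(predict_nn(m, coh$soil_cd, coh$soil_ph))
  p2 <- as.numeric(predict_nn(back, coh$soil_cd, coh$soil_ph))
  expect_equal(p1, p2, tolerance = 1e-12)
})
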