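#' Configuration of the sigmoid feed-forward network
#'
#' The predictor is a fully connected feed-forward network mapping
#' (soil Cd, soil pH) to grain Cd through three hidden layers of 4, 7 and
#' 4 neurons (architecture 2-4-7-4-1), logistic sigmoid activation
#' `f(x) = 1 / (1 + exp(-x))` on every layer including the output unit,
#' trained by full-batch gradient descent on the mean-squared error with a
#' base learning rate of 0.01 and at most 10000 iterations.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param learning_rate base gradient-descent step; a backtracking line
#'   search halves the step whenever it would increase the loss (and lets
#'   an accepted step expand again), so descent is monotone at any rate.
#' @param max_iterations iteration cap.
#' @param seed seed for the weight initialization stream.
#' @param tolerance stop early once the loss decrease in one iteration
#'   falls below this value.
#' @return object of class `nn_config`.
#' @export
nn_config <- function(hidden_sizes = c(4L, 7L, 4L), learning_rate = 0.01,
                      max_iterations = 10000L, seed = 1L,
                      tolerance = 1e-12) {
  stopifnot(all(hidden_sizes >= 1), learning_rate > 0,
            max_iterations >= 1, tolerance >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), tolerance = tolerance),
            class = "nn_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass: list of activation matrices, input included.
nn_forward <- function(W, B, X) {
  L <- length(W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    A[[l + 1]] <- sigmoid(sweep(A[[l]] %*% W[[l]], 2, B[[l]], "+"))
  }
  A
}

nn_loss <- function(A, y) mean((A[[length(A)]] - y)^2)

# Backpropagated gradient of the mean-squared error wrt all weights and
# biases. A is the activation list from nn_forward.
nn_gradient <- function(W, A, y) {
  L <- length(W)
  n <- nrow(A[[1]])
  out <- A[[L + 1]]
  delta <- (2 / n) * (out - y) * out * (1 - out)
  gW <- vector("list", L)
  gB <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(A[[l]]) %*% delta
    gB[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(W[[l]])) * A[[l]] * (1 - A[[l]])
  }
  list(W = gW, B = gB)
}

# min-max scaling helpers; targets go to [0.1, 0.9] so the sigmoid output
# unit keeps a live gradient at the extremes, inputs to [0, 1].
scale_minmax <- function(x, lo, hi, to = c(0, 1)) {
  to[1] + (x - lo) / (hi - lo) * (to[2] - to[1])
}
unscale_minmax <- function(s, lo, hi, to = c(0, 1)) {
  lo + (s - to[1]) / (to[2] - to[1]) * (hi - lo)
}

#' Train the neural-network accumulation predictor
#'
#' Inputs are min-max scaled to `[0, 1]` and targets to `[0.1, 0.9]`
#' (scaling bounds are stored in the model); weights and biases start
#' uniform on `(-0.5, 0.5)` from the seeded stream; optimization is
#' full-batch gradient descent with a step-halving line search, so the
#' training loss is non-increasing. Deterministic for a fixed
#' `config$seed`. There is no train/test split: with 36-sample surveys the
#' model is fit and evaluated on the same data, and reported metrics are
#' training metrics.
#'
#' @param samples validated sample data frame with >= 10 rows and
#'   non-constant soil Cd and pH.
#' @param config an [nn_config()].
#' @return object of class `nn_model`: weights, biases, scaling bounds,
#'   config and training metrics (`initial_loss`, `final_loss`,
#'   `iterations`).
#' @export
train_nn <- function(samples, config = nn_config()) {
  stopifnot(inherits(config, "nn_config"))
  validate_samples(samples)
  if (nrow(samples) < 10) stop("need at least 10 samples to train")
  X_raw <- cbind(soil_cd = samples$soil_cd, soil_ph = samples$soil_ph)
  if (any(apply(X_raw, 2, sd) == 0)) stop("inputs must be non-constant")
  in_lo <- apply(X_raw, 2, min)
  in_hi <- apply(X_raw, 2, max)
  out_lo <- min(samples$soybean_cd)
  out_hi <- max(samples$soybean_cd)
  if (out_lo == out_hi) stop("target is constant; nothing to fit")
  X <- sapply(seq_len(2), function(j) {
    scale_minmax(X_raw[, j], in_lo[j], in_hi[j])
  })
  y <- matrix(scale_minmax(samples$soybean_cd, out_lo, out_hi,
                           to = c(0.1, 0.9)), ncol = 1)

  sizes <- c(2L, config$hidden_sizes, 1L)
  L <- length(sizes) - 1
  set.seed(config$seed)
  W <- lapply(seq_len(L), function(l) {
    matrix(runif(sizes[l] * sizes[l + 1], -0.5, 0.5), sizes[l],
           sizes[l + 1])
  })
  B <- lapply(seq_len(L), function(l) runif(sizes[l + 1], -0.5, 0.5))

  A <- nn_forward(W, B, X)
  cur <- nn_loss(A, y)
  initial <- cur
  step <- config$learning_rate
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    g <- nn_gradient(W, A, y)
    repeat {
      W2 <- Map(function(w, gw) w - step * gw, W, g$W)
      B2 <- Map(function(b, gb) b - step * gb, B, g$B)
      A2 <- nn_forward(W2, B2, X)
      new <- nn_loss(A2, y)
      if (!is.finite(new)) {
        stop("training diverged (non-finite loss); use a smaller ",
             "learning rate")
      }
      if (new <= cur || step < 1e-14) break
      step <- step / 2
    }
    iters <- it
    if (new > cur) break          # line search exhausted; converged
    drop <- cur - new
    W <- W2; B <- B2; A <- A2; cur <- new
    step <- step * 2              # let accepted steps expand again
    if (drop < config$tolerance) break
  }
  structure(list(
    sizes = sizes, W = W, B = B,
    in_lo = in_lo, in_hi = in_hi,
    out_lo = out_lo, out_hi = out_hi,
    config = config,
    initial_loss = initial, final_loss = cur, iterations = iters
  ), class = "nn_model")
}

#' Predict grain Cd with the trained network
#'
#' Inputs are scaled with the stored training bounds, passed through the
#' network, and the sigmoid output is mapped back to mg/kg. Inputs outside
#' the training range are allowed (the scaling extrapolates linearly) but
#' flagged through the `extrapolated` attribute.
#'
#' @param model a trained [train_nn()] model.
#' @param soil_cd,soil_ph numeric vectors.
#' @return predicted grain Cd (mg/kg) with logical attribute
#'   `extrapolated`.
#' @export
predict_nn <- function(model, soil_cd, soil_ph) {
  stopifnot(inherits(model, "nn_model"),
            length(soil_cd) == length(soil_ph))
  X_raw <- cbind(soil_cd, soil_ph)
  extra <- X_raw[, 1] < model$in_lo[1] | X_raw[, 1] > model$in_hi[1] |
           X_raw[, 2] < model$in_lo[2] | X_raw[, 2] > model$in_hi[2]
  X <- sapply(seq_len(2), function(j) {
    scale_minmax(X_raw[, j], model$in_lo[j], model$in_hi[j])
  })
  if (length(soil_cd) == 1) X <- matrix(X, nrow = 1)
  A <- nn_forward(model$W, model$B, X)
  pred <- unscale_minmax(drop(A[[length(A)]]), model$out_lo, model$out_hi,
                         to = c(0.1, 0.9))
  structure(unname(pred), extrapolated = unname(extra))
}

#' Training-set fit metrics of the network
#'
#' @param model a trained [train_nn()] model.
#' @param samples sample data frame, >= 3 rows.
#' @return list with Pearson `R` between observed and predicted grain Cd
#'   (flagged `NA` if predictions are constant) and `RMSE` in mg/kg.
#' @export
evaluate_nn <- function(model, samples) {
  validate_samples(samples)
  stopifnot(nrow(samples) >= 3)
  pred <- as.numeric(predict_nn(model, samples$soil_cd, samples$soil_ph))
  obs <- samples$soybean_cd
  list(R = pearson_corr(obs, pred),
       RMSE = sqrt(mean((pred - obs)^2)))
}

#' Serialize a trained network to JSON
#'
#' The document records architecture, weights, biases, scaling bounds,
#' training configuration and metrics; [nn_from_json()] restores a model
#' whose predictions equal the original's.
#'
#' @param model a trained `nn_model`.
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
nn_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "nn_model"))
  doc <- list(
    sizes = model$sizes,
    W = lapply(model$W, unclass),
    B = model$B,
    in_lo = as.list(model$in_lo), in_hi = as.list(model$in_hi),
    out_lo = model$out_lo, out_hi = model$out_hi,
    config = unclass(model$config),
    metrics = list(initial_loss = model$initial_loss,
                   final_loss = model$final_loss,
                   iterations = model$iterations)
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE))
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a trained network from JSON
#'
#' @param path file path or JSON string produced by [nn_to_json()].
#' @return an `nn_model`.
#' @export
nn_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  sizes <- as.integer(doc$sizes)
  L <- length(sizes) - 1
  structure(list(
    sizes = sizes,
    W = lapply(doc$W, function(w) matrix(unlist(w), nrow = nrow(w))),
    B = lapply(doc$B, as.numeric),
    in_lo = unlist(doc$in_lo), in_hi = unlist(doc$in_hi),
    out_lo = doc$out_lo, out_hi = doc$out_hi,
    config = do.call(nn_config, doc$config[c("hidden_sizes",
                                             "learning_rate",
                                             "max_iterations", "seed",
                                             "tolerance")]),
    initial_loss = doc$metrics$initial_loss,
    final_loss = doc$metrics$final_loss,
    iterations = doc$metrics$iterations
  ), class = "nn_model")
}
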