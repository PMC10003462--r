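# run code with a private RNG stream, leaving the caller's untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Train / validation / test split
#'
#' Reproducible stratified split following the study design: a class-balanced
#' train+validation pool (at the study's 143-case / 119-control size this is
#' 100 cases + 100 controls), of which 10% (stratified) becomes the
#' validation set; everything else is the test set. For other sample sizes
#' the pool is scaled proportionally, keeping the class balance:
#' per-class pool size m = min(floor((200/262) n / 2), n_cases - 1,
#' n_controls - 1).
#'
#' @param phenotypes binary 0/1 vector, or a [genotype_dataset()].
#' @param seed integer seed; the same seed always yields the same split.
#' @param val_fraction fraction of the pool held out for validation
#'   (default 0.1).
#' @return list with integer index vectors `train`, `val`, `test`
#'   (disjoint, union = all samples) and, when a dataset was given,
#'   `train_ids`, `val_ids`, `test_ids`.
#' @export
make_split <- function(phenotypes, seed, val_fraction = 0.1) {
  dataset <- NULL
  if (inherits(phenotypes, "genotype_dataset")) {
    dataset <- phenotypes
    phenotypes <- dataset$phenotypes
  }
  phenotypes <- as.integer(phenotypes)
  n <- length(phenotypes)
  cases <- which(phenotypes == 1L)
  controls <- which(phenotypes == 0L)
  if (length(cases) < 2 || length(controls) < 2)
    stop("need at least 2 samples per class; have ",
         length(cases), " cases and ", length(controls), " controls")
  m <- min(floor((200 / 262) * n / 2), length(cases) - 1L, length(controls) - 1L)
  if (m < 2)
    stop("too few samples for a split; need at least 3 per class")
  v_per_class <- max(1L, round(val_fraction * m))
  with_seed(seed, {
    pool_cases <- sample(cases, m)
    pool_controls <- sample(controls, m)
    val <- c(sample(pool_cases, v_per_class), sample(pool_controls, v_per_class))
  })
  pool <- c(pool_cases, pool_controls)
  train <- sort(setdiff(pool, val))
  val <- sort(val)
  test <- sort(setdiff(seq_len(n), pool))
  out <- list(train = train, val = val, test = test, seed = seed)
  if (!is.null(dataset)) {
    out$train_ids <- dataset$sample_ids[train]
    out$val_ids <- dataset$sample_ids[val]
    out$test_ids <- dataset$sample_ids[test]
  }
  out
}

#' Hidden-layer width for a given SNP count
#'
#' The architecture uses one width per model size: 8, 16, 32 and 64 neurons
#' for the 3-, 10-, 16- and 92-SNP models. Other SNP counts (an extension)
#' get the width of the nearest listed size, ties toward the larger size.
#'
#' @param n_snps number of input SNPs.
#' @return Hidden width, one of 8, 16, 32, 64.
#' @export
ann_width <- function(n_snps) {
  stopifnot(n_snps >= 1)
  sizes <- c(3, 10, 16, 92)
  widths <- c(8L, 16L, 32L, 64L)
  d <- abs(sizes - n_snps)
  candidates <- which(d == min(d))
  widths[max(candidates)]   # tie -> larger listed size
}

#' Train the feed-forward network
#'
#' Two ReLU hidden layers of equal width and a sigmoid output unit, trained
#' with mean binary cross-entropy and Adam (initial step size `lr`,
#' per-update decay `lr / (1 + decay t)`) for `epochs` epochs in mini-batches
#' of `batch_size`. After every epoch the full-train and validation losses
#' are evaluated; the returned weights are the checkpoint with minimum
#' validation loss (ties broken toward higher training accuracy, then the
#' earlier epoch). Fully reproducible for a fixed seed.
#'
#' @param x_train,x_val numeric matrices of additive genotypes (no missing
#'   values), samples x SNPs.
#' @param y_train,y_val binary 0/1 labels.
#' @param hidden hidden width; default [ann_width()] of the input dimension.
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param epochs,batch_size,lr,decay training protocol (defaults 100, 32,
#'   5e-3, 1e-5).
#' @return A `trained_ann`: weights at the restored checkpoint, per-epoch
#'   `history` (train_loss, val_loss, train_acc), `best_epoch`, and the
#'   restored `train_loss`, `val_loss`, `train_accuracy`.
#' @export
train_ann <- function(x_train, y_train, x_val, y_val, hidden = NULL,
                      seed = 1L, epochs = 100L, batch_size = 32L,
                      lr = 5e-3, decay = 1e-5) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  if (anyNA(x_train) || anyNA(x_val))
    stop("inputs must be imputed before training")
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2)
    stop("both classes must be present in the training labels")
  if (is.null(hidden)) hidden <- ann_width(ncol(x_train))
  fit <- .ann_train_cpp(x_train, y_train, x_val, y_val,
                        as.integer(hidden), as.integer(epochs),
                        as.integer(batch_size), lr, decay, as.integer(seed))
  if (isTRUE(fit$diverged))
    stop(sprintf("training diverged (non-finite loss) at epoch %d, step size %.3g",
                 fit$epoch_at_failure, fit$lr_at_failure))
  structure(list(
    spec = list(n_inputs = ncol(x_train), hidden = hidden, epochs = epochs,
                batch_size = batch_size, lr = lr, decay = decay, seed = seed),
    weights = fit[c("W1", "b1", "W2", "b2", "W3", "b3")],
    history = data.frame(epoch = seq_len(epochs),
                         train_loss = as.numeric(fit$train_loss),
                         val_loss = as.numeric(fit$val_loss),
                         train_acc = as.numeric(fit$train_acc)),
    best_epoch = fit$best_epoch,
    train_loss = fit$best_train_loss,
    val_loss = fit$best_val_loss,
    train_accuracy = fit$best_train_acc),
    class = "trained_ann")
}

#' @param object a `trained_ann`.
#' @param x matrix of additive genotypes to score.
#' @param ... unused.
#' @return Case probabilities.
#' @rdname train_ann
#' @export
predict.trained_ann <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$spec$n_inputs)
    stop("input has ", ncol(x), " columns; network expects ",
         object$spec$n_inputs)
  w <- object$weights
  as.numeric(.ann_forward_cpp(x, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3))
}

#' Number of trainable parameters of a trained network
#'
#' @param object a `trained_ann`.
#' @return Integer parameter count over all weight matrices and biases.
#' @export
ann_n_params <- function(object) {
  sum(vapply(object$weights, length, numeric(1)))
}

BASELINE_ALGORITHMS <- c("svm", "random_forest", "extreme_gradient_boosting",
                         "logistic_regression", "light_gradient_boosting",
                         "adaptive_boosting")

#' Train a conventional baseline classifier
#'
#' Six standard algorithms at conventional defaults, each seeded and
#' returning a case-probability scorer via `predict()`:
#' \describe{
#'   \item{svm}{radial-kernel support vector machine with Platt probability
#'     calibration (`e1071::svm`).}
#'   \item{random_forest}{500 trees (`randomForest`).}
#'   \item{extreme_gradient_boosting}{gradient-boosted trees, 100 rounds,
#'     learning rate 0.3, depth 6 (`xgboost`).}
#'   \item{logistic_regression}{unpenalized logistic regression
#'     (`stats::glm`).}
#'   \item{light_gradient_boosting}{leaf-wise-grown histogram gradient
#'     boosting in the LightGBM style, expressed through `xgboost`
#'     (`grow_policy = "lossguide"`, 31 leaves, learning rate 0.1,
#'     100 rounds).}
#'   \item{adaptive_boosting}{AdaBoost (SAMME) over depth-1 decision stumps,
#'     50 rounds (`rpart` weak learners); the score is the
#'     weight-normalized vote for the case class.}
#' }
#'
#' @param algorithm one of the six names above.
#' @param x numeric matrix of additive genotypes, samples x SNPs.
#' @param y binary 0/1 labels.
#' @param seed integer seed.
#' @return A `baseline_model`.
#' @export
train_baseline <- function(algorithm, x, y, seed = 1L) {
  if (!algorithm %in% BASELINE_ALGORITHMS)
    stop("unknown algorithm '", algorithm, "'; valid: ",
         paste(BASELINE_ALGORITHMS, collapse = ", "))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training labels")
  model <- switch(algorithm,
    svm = with_seed(seed,
      e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE)),
    random_forest = with_seed(seed,
      randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 500)),
    extreme_gradient_boosting = xgboost::xgboost(
      x, factor(y, levels = c(0, 1)), nrounds = 100,
      learning_rate = 0.3, max_depth = 6, nthreads = 1, seed = seed,
      verbosity = 0),
    logistic_regression = {
      df <- data.frame(y = y, x)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    light_gradient_boosting = xgboost::xgboost(
      x, factor(y, levels = c(0, 1)), nrounds = 100,
      learning_rate = 0.1, tree_method = "hist", grow_policy = "lossguide",
      max_leaves = 31, max_depth = 0, nthreads = 1, seed = seed,
      verbosity = 0),
    adaptive_boosting = ada_boost_stumps(x, y, n_rounds = 50, seed = seed))
  structure(list(algorithm = algorithm, model = model,
                 feature_names = colnames(x), seed = seed),
            class = "baseline_model")
}

#' @param object a `baseline_model`.
#' @param x matrix to score.
#' @param ... unused.
#' @return Case probabilities.
#' @rdname train_baseline
#' @export
predict.baseline_model <- function(object, x, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  colnames(x) <- object$feature_names
  alg <- object$algorithm
  if (alg == "svm") {
    pr <- attr(predict(object$model, x, probability = TRUE), "probabilities")
    return(as.numeric(pr[, "1"]))
  }
  if (alg == "random_forest")
    return(as.numeric(predict(object$model, x, type = "prob")[, "1"]))
  if (alg %in% c("extreme_gradient_boosting", "light_gradient_boosting")) {
    pr <- predict(object$model, x, type = "response")
    if (is.matrix(pr)) pr <- pr[, "1"]
    return(as.numeric(pr))
  }
  if (alg == "logistic_regression")
    return(as.numeric(predict(object$model, newdata = as.data.frame(x),
                              type = "response")))
  predict_ada(object$model, x)
}

# AdaBoost (discrete SAMME) with depth-1 rpart stumps.
ada_boost_stumps <- function(x, y, n_rounds = 50, seed = 1L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yf <- factor(y, levels = c(0, 1))
  df <- data.frame(y = yf, x)
  stumps <- list()
  alphas <- numeric(0)
  with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      fit <- rpart::rpart(y ~ ., data = df, weights = w,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1, cp = -1, minsplit = 2,
                            minbucket = 1, xval = 0))
      pred <- as.integer(as.character(predict(fit, df, type = "class")))
      err <- sum(w * (pred != y))
      if (err <= 0) {
        stumps[[length(stumps) + 1]] <- fit
        alphas <- c(alphas, log((1 - 1e-10) / 1e-10))
        break
      }
      if (err >= 0.5) break
      alpha <- log((1 - err) / err)
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0) {
    # no stump beats chance: fall back to the class prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_ada <- function(model, x) {
  if (length(model$stumps) == 0)
    return(rep(model$prior, nrow(x)))
  df <- as.data.frame(x)
  votes <- matrix(0, nrow(x), length(model$stumps))
  for (r in seq_along(model$stumps)) {
    votes[, r] <- as.integer(as.character(
      predict(model$stumps[[r]], df, type = "class")))
  }
  as.numeric(votes %*% model$alphas / sum(model$alphas))
}
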