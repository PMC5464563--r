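# False-positive reduction: a three-layer feed-forward network (30
# inputs, one hidden layer, 2 softmax outputs for metastasis / not)
# trained by back-propagation with the scaled hyperbolic tangent
# activation 1.7159 * tanh(2x/3) in the hidden layer.

#' Scaled hyperbolic tangent activation
#'
#' `y = 1.7159 * tanh(2x/3)`: odd, bounded by 1.7159, with gain close to 1
#' around the origin so standardized inputs stay in the responsive range.
#'
#' @param x numeric.
#' @return numeric of the same shape.
#' @export
activation <- function(x) 1.7159 * tanh(2 * x / 3)

activation_grad <- function(x) 1.7159 * (2 / 3) * (1 - tanh(2 * x / 3)^2)

#' ANN configuration
#'
#' @param n_hidden hidden-layer width (default 15, midway between the 30
#'   inputs and 2 outputs).
#' @param learning_rate,momentum SGD step size and momentum coefficient.
#' @param max_epochs,patience epoch cap and early-stopping patience on the
#'   validation loss.
#' @param batch_size mini-batch size.
#' @param val_fraction fraction of the training data held out for early
#'   stopping.
#' @param class_weights `"balanced"` (inverse class frequency) or a named
#'   vector `c(TP = , FP = )`; candidate sets are heavily FP-dominated, so
#'   unweighted training collapses to the majority class.
#' @param seed RNG seed for weight initialization and shuffling.
#' @return list of class `ann_config`.
#' @export
ann_config <- function(n_hidden = 15, learning_rate = 0.01, momentum = 0.9,
                       max_epochs = 1000, patience = 50, batch_size = 32,
                       val_fraction = 0.2, class_weights = "balanced",
                       seed = 1) {
  stopifnot(n_hidden >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1, batch_size >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(n_input = 30L, n_hidden = as.integer(n_hidden),
                 n_output = 2L, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "ann_config")
}

# Forward pass + class-weighted cross-entropy loss and analytic gradients.
# X: n x p (standardized), Y: n x 2 one-hot, w: per-sample weights.
ann_forward_backward <- function(par, X, Y, w, grad = TRUE) {
  n <- nrow(X)
  Z1 <- sweep(X %*% par$W1, 2, par$b1, `+`)
  H <- activation(Z1)
  Z2 <- sweep(H %*% par$W2, 2, par$b2, `+`)
  Z2 <- Z2 - apply(Z2, 1, max)  # softmax stabilization
  E <- exp(Z2)
  P <- E / rowSums(E)
  eps <- 1e-12
  loss <- -sum(w * rowSums(Y * log(P + eps))) / sum(w)
  if (!grad) return(list(loss = loss, prob = P))
  D2 <- (P - Y) * w / sum(w)          # n x 2
  gW2 <- t(H) %*% D2
  gb2 <- colSums(D2)
  D1 <- (D2 %*% t(par$W2)) * activation_grad(Z1)
  gW1 <- t(X) %*% D1
  gb1 <- colSums(D1)
  list(loss = loss, prob = P,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Train the false-positive reduction network
#'
#' Features are z-scored with training-set statistics (stored in the
#' model), labels one-hot encoded, and the network fit by mini-batch
#' gradient descent with momentum on class-weighted cross-entropy after a
#' softmax over the two output units.  A validation split drives early
#' stopping; the best-validation weights are returned.  A fixed seed gives
#' an identical model.
#'
#' @param features numeric matrix or data frame, one row per candidate, 30
#'   columns (canonical order).
#' @param labels logical or factor/character: `TRUE`/`"TP"` for true
#'   metastases, `FALSE`/`"FP"` otherwise.  Both classes must be present.
#' @param config an [ann_config].
#' @return An `ann_model`: weights, activation constants, standardization
#'   statistics, config and per-epoch loss log.
#' @export
ann_train <- function(features, labels, config = ann_config()) {
  X <- as.matrix(features)
  if (ncol(X) != config$n_input)
    stop("expected ", config$n_input, " features, got ", ncol(X))
  bad <- which(!stats::complete.cases(X) | !apply(is.finite(X), 1, all))
  if (length(bad))
    stop("non-finite features for candidate row(s) ",
         paste(head(bad, 5), collapse = ", "))
  y <- if (is.logical(labels)) labels else as.character(labels) %in%
    c("TP", "TRUE", "1", "tp")
  if (length(unique(y)) < 2L)
    stop("both classes (TP and FP) must be present in the training data")
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, function(col) {
    s <- sd(col); if (!is.finite(s) || s == 0) 1 else s
  })
  Xs <- scale(X, center = ctr, scale = scl)
  Y <- cbind(FP = as.numeric(!y), TP = as.numeric(y))
  cw <- config$class_weights
  if (identical(cw, "balanced"))
    cw <- c(TP = n / (2 * sum(y)), FP = n / (2 * sum(!y)))
  w <- ifelse(y, cw[["TP"]], cw[["FP"]])

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  p <- config$n_input; h <- config$n_hidden; o <- config$n_output
  lim1 <- 1 / sqrt(p); lim2 <- 1 / sqrt(h)
  par <- list(W1 = matrix(runif(p * h, -lim1, lim1), p, h),
              b1 = numeric(h),
              W2 = matrix(runif(h * o, -lim2, lim2), h, o),
              b2 = numeric(o))
  vel <- lapply(par, function(m) m * 0)

  n_val <- floor(config$val_fraction * n)
  val_idx <- if (n_val >= 2) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  wtr <- w[tr_idx]
  has_val <- length(val_idx) > 0

  best <- list(loss = Inf, par = par, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(Xtr))
    for (start in seq(1, nrow(Xtr), by = config$batch_size)) {
      b <- ord[start:min(start + config$batch_size - 1, nrow(Xtr))]
      fb <- ann_forward_backward(par, Xtr[b, , drop = FALSE],
                                 Ytr[b, , drop = FALSE], wtr[b])
      for (nm in names(par)) {
        vel[[nm]] <- config$momentum * vel[[nm]] -
          config$learning_rate * fb$grad[[nm]]
        par[[nm]] <- par[[nm]] + vel[[nm]]
      }
    }
    tl <- ann_forward_backward(par, Xtr, Ytr, wtr, grad = FALSE)$loss
    vl <- if (has_val)
      ann_forward_backward(par, Xs[val_idx, , drop = FALSE],
                           Y[val_idx, , drop = FALSE], w[val_idx],
                           grad = FALSE)$loss else tl
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tl,
                                 val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, par = par, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(W1 = best$par$W1, b1 = best$par$b1, W2 = best$par$W2,
                 b2 = best$par$b2, center = ctr, scale = scl,
                 activation = c(a = 1.7159, b = 2 / 3),
                 feature_names = colnames(X), config = config,
                 log = log, best_epoch = best$epoch),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> 30-%d-2, best epoch %d, val loss %.4f\n",
              x$config$n_hidden, x$best_epoch, min(x$log$val_loss)))
  invisible(x)
}

#' Per-candidate probability of being a true metastasis
#'
#' Softmax over the two output units; the two probabilities sum to 1 and
#' the TP unit's probability is returned.
#'
#' @param object an `ann_model`.
#' @param newdata matrix or data frame of 30-column feature vectors.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(dim(X)) || ncol(X) == 1L && length(X) == 30L)
    X <- matrix(X, nrow = 1)
  if (ncol(X) != 30L)
    stop("feature vectors must have length 30, got ", ncol(X))
  Xs <- scale(X, center = object$center, scale = object$scale)
  par <- object[c("W1", "b1", "W2", "b2")]
  ann_forward_backward(par, Xs,
                       matrix(0, nrow(Xs), 2), rep(1, nrow(Xs)),
                       grad = FALSE)$prob[, 2]
}

#' Filter candidates by ANN probability
#'
#' Every candidate is annotated with its TP probability; candidates at or
#' above `cutoff` are retained as final detections, sorted by probability
#' descending.
#'
#' @param candidates candidate data frame.
#' @param model a trained `ann_model`.
#' @param cutoff probability cutoff (default 0.5).
#' @param volume the source [volume3d]; required unless `features` given.
#' @param features precomputed 30-column feature table aligned to
#'   `candidates`.
#' @return list with `detections` (retained candidates, with
#'   `probability`) and `scored` (all candidates with probabilities).
#' @export
filter_candidates <- function(candidates, model, cutoff = 0.5,
                              volume = NULL, features = NULL) {
  if (nrow(candidates) == 0L) {
    candidates$probability <- numeric(0)
    return(list(detections = candidates, scored = candidates))
  }
  if (is.null(features)) {
    if (is.null(volume))
      stop("supply either `features` or `volume`")
    features <- extract_feature_table(volume, candidates)
  }
  prob <- predict(model, features)
  scored <- candidates
  scored$probability <- prob
  scored <- scored[order(-scored$probability), ]
  rownames(scored) <- NULL
  list(detections = scored[scored$probability >= cutoff, ],
       scored = scored)
}

#' Choose a probability cutoff bounding true-positive loss
#'
#' Among cutoffs that keep at least `1 - max_tp_loss` of the true
#' positives (on the data provided, typically the training candidates),
#' returns the one removing the most false positives; ties go to the
#' smallest such cutoff, which risks the least true-positive loss on
#' unseen data for the same false-positive benefit.
#'
#' @param probabilities predicted TP probabilities.
#' @param labels logical, `TRUE` for true positives.
#' @param max_tp_loss maximum fraction of TPs that may be discarded
#'   (default 0.1).
#' @return scalar cutoff.
#' @export
select_cutoff <- function(probabilities, labels, max_tp_loss = 0.1) {
  stopifnot(length(probabilities) == length(labels))
  tp <- probabilities[labels]
  fp <- probabilities[!labels]
  if (!length(tp)) stop("no true positives to calibrate against")
  cuts <- sort(unique(c(0, probabilities, min(1, probabilities + 1e-9))))
  keep <- vapply(cuts, function(ct) mean(tp >= ct), numeric(1))
  removed <- vapply(cuts, function(ct) sum(fp < ct), numeric(1))
  ok <- keep >= 1 - max_tp_loss
  if (!any(ok)) return(0)
  best <- max(removed[ok])
  min(cuts[ok & removed == best])
}

#' Serialize / restore an ANN model as JSON
#'
#' @param model an `ann_model`.
#' @param path output path.
#' @return `path` (write) or the restored `ann_model` (read).
#' @export
write_ann_model <- function(model, path) {
  obj <- list(format = "metcad-ann", version = 1L,
              n_input = 30L, n_hidden = model$config$n_hidden,
              n_output = 2L, activation = as.list(model$activation),
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              center = model$center, scale = model$scale,
              feature_names = model$feature_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "metcad-ann"))
    stop("not a metcad ANN model file: ", path)
  structure(list(W1 = matrix(unlist(obj$W1), 30, obj$n_hidden),
                 b1 = as.numeric(obj$b1),
                 W2 = matrix(unlist(obj$W2), obj$n_hidden, 2),
                 b2 = as.numeric(obj$b2),
                 center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 activation = c(a = obj$activation$a, b = obj$activation$b),
                 feature_names = obj$feature_names,
                 config = ann_config(n_hidden = obj$n_hidden),
                 log = NULL, best_epoch = NA_integer_),
            class = "ann_model")
}
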