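# Convolutional LSTM grasp-type classifier.
#
# Architecture: ConvLSTM(128 filters, 1 x 3 kernel, same padding along the
# 20-column axis) -> dropout 0.5 -> flatten -> dense 200 (ReLU) ->
# dense 50 (ReLU) -> dropout 0.2 -> dense 11 (softmax), trained with
# class-weighted categorical cross-entropy and Adam at default parameters.
# The recurrence runs over the 10 subsequences of each 200-sample window;
# convolutions (input-to-state and state-to-state) slide a length-3 kernel
# along the 20-column spatial axis with the 12 electrodes as channels.

#' Classifier architecture specification
#'
#' @param filters ConvLSTM filters.
#' @param kernel Kernel size, height x width (height fixed at 1).
#' @param dropout1 Dropout rate after the ConvLSTM.
#' @param dense_units Sizes of the two fully connected ReLU layers.
#' @param dropout2 Dropout rate after the second dense layer.
#' @param n_classes Output units (ten grasp types + rest).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(filters = 128L, kernel = c(1L, 3L), dropout1 = 0.5,
                       dense_units = c(200L, 50L), dropout2 = 0.2,
                       n_classes = 11L) {
  if (kernel[1] != 1L) stopf("kernel height must be 1")
  if (length(dense_units) != 2L) stopf("exactly two dense layers expected")
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 dropout1 = dropout1, dense_units = as.integer(dense_units),
                 dropout2 = dropout2, n_classes = as.integer(n_classes)),
            class = "model_spec")
}

#' Training configuration
#'
#' @param epochs Training epochs (fixed budget; best snapshot kept).
#' @param batch_size Minibatch size.
#' @param seed Seed for parameter init fallback, shuffling and dropout.
#' @param lr,beta1,beta2,eps Adam parameters (defaults).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 150L, batch_size = 32L, seed = 1L,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps),
            class = "train_config")
}

glorot <- function(nin, nout, fan_in = nin, fan_out = nout) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build a ConvLSTM grasp classifier
#'
#' Initializes all parameters reproducibly from `seed` (Glorot-uniform
#' weights, zero biases with the forget-gate bias at 1).
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @param n_channels Input channels (electrodes).
#' @param spatial Spatial width of each subsequence (columns).
#' @return Object of class `convlstm_model`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L, n_channels = 12L,
                        spatial = 20L) {
  Fk <- spec$filters
  with_seed(seed, {
    params <- list(
      Wx = glorot(3L * n_channels, 4L * Fk,
                  fan_in = 3L * n_channels, fan_out = 3L * Fk),
      Wh = glorot(3L * Fk, 4L * Fk, fan_in = 3L * Fk, fan_out = 3L * Fk),
      b = c(rep(0, Fk), rep(1, Fk), rep(0, 2L * Fk)),
      W1 = glorot(spatial * Fk, spec$dense_units[1]),
      b1 = rep(0, spec$dense_units[1]),
      W2 = glorot(spec$dense_units[1], spec$dense_units[2]),
      b2 = rep(0, spec$dense_units[2]),
      W3 = glorot(spec$dense_units[2], spec$n_classes),
      b3 = rep(0, spec$n_classes)
    )
  })
  structure(list(spec = spec, params = params, n_channels = as.integer(n_channels),
                 spatial = as.integer(spatial), classes = 0:(spec$n_classes - 1L)),
            class = "convlstm_model")
}

#' @export
print.convlstm_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("convlstm_model: %d filters, %d classes, %s parameters\n",
              x$spec$filters, x$spec$n_classes, format(n_par, big.mark = ",")))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# im2col for a length-3 kernel along the spatial axis, zero padded ("same").
# A: B x P x C array -> (B P) x (3 C) matrix; output position p gathers
# input positions p-1, p, p+1.
im2col3 <- function(A) {
  d <- dim(A); B <- d[1]; P <- d[2]; C <- d[3]
  Ap <- array(0, c(B, P + 2L, C))
  Ap[, 2:(P + 1L), ] <- A
  cbind(matrix(Ap[, 1:P, ], B * P, C),
        matrix(Ap[, 2:(P + 1L), ], B * P, C),
        matrix(Ap[, 3:(P + 2L), ], B * P, C))
}

# Adjoint of im2col3: scatter (B P) x (3 C) gradients back to B x P x C.
col2im3 <- function(dM, B, P, C) {
  dAp <- array(0, c(B, P + 2L, C))
  for (k in 1:3) {
    dAp[, k:(k + P - 1L), ] <- dAp[, k:(k + P - 1L), ] +
      array(dM[, ((k - 1L) * C + 1L):(k * C)], c(B, P, C))
  }
  dAp[, 2:(P + 1L), , drop = FALSE]
}

# Forward pass over a batch tensor X (B x T x 1 x P x C).
# Returns probabilities and, if keep_cache, everything backward needs.
convlstm_forward <- function(model, X, train = FALSE, masks = NULL,
                             keep_cache = FALSE) {
  p <- model$params; spec <- model$spec
  d <- dim(X); B <- d[1]; Tn <- d[2]; P <- d[4]; C <- d[5]
  Fk <- spec$filters
  H <- matrix(0, B * P, Fk); Cs <- matrix(0, B * P, Fk)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  ix <- seq_len(Fk)
  for (t in seq_len(Tn)) {
    Xt <- array(X[, t, 1L, , , drop = FALSE], c(B, P, C))
    Mx <- im2col3(Xt)
    Mh <- im2col3(array(H, c(B, P, Fk)))
    Z <- add_bias(Mx %*% p$Wx + Mh %*% p$Wh, p$b)
    gi <- sigmoid(Z[, ix, drop = FALSE])
    gf <- sigmoid(Z[, Fk + ix, drop = FALSE])
    gg <- tanh(Z[, 2L * Fk + ix, drop = FALSE])
    go <- sigmoid(Z[, 3L * Fk + ix, drop = FALSE])
    Cnew <- gf * Cs + gi * gg
    tC <- tanh(Cnew)
    if (keep_cache) {
      cache[[t]] <- list(Mx = Mx, Mh = Mh, i = gi, f = gf, g = gg, o = go,
                         Cprev = Cs, tC = tC)
    }
    H <- go * tC
    Cs <- Cnew
  }
  Hflat <- array(H, c(B, P, Fk))
  dim(Hflat) <- c(B, P * Fk)
  if (train && spec$dropout1 > 0) Hflat <- Hflat * masks$m1 / (1 - spec$dropout1)
  Z1 <- add_bias(Hflat %*% p$W1, p$b1); A1 <- pmax(Z1, 0)
  Z2 <- add_bias(A1 %*% p$W2, p$b2); A2 <- pmax(Z2, 0)
  A2d <- A2
  if (train && spec$dropout2 > 0) A2d <- A2d * masks$m2 / (1 - spec$dropout2)
  logits <- add_bias(A2d %*% p$W3, p$b3)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(lstm = cache, H = H, Hflat = Hflat, A1 = A1, A2 = A2,
                      A2d = A2d, Z1 = Z1, Z2 = Z2, B = B, P = P, C = C,
                      Tn = Tn, masks = masks)
  }
  out
}

# Backward pass; y one-hot (B x K), w per-sample weights. Returns gradients.
convlstm_backward <- function(model, fw, y, w) {
  p <- model$params; spec <- model$spec
  ch <- fw$cache
  B <- ch$B; P <- ch$P; Fk <- spec$filters
  dlogits <- (fw$probs - y) * (w / B)
  g <- list()
  g$W3 <- crossprod(ch$A2d, dlogits); g$b3 <- colSums(dlogits)
  dA2d <- tcrossprod(dlogits, p$W3)
  dA2 <- if (spec$dropout2 > 0) dA2d * ch$masks$m2 / (1 - spec$dropout2) else dA2d
  dZ2 <- dA2 * (ch$Z2 > 0)
  g$W2 <- crossprod(ch$A1, dZ2); g$b2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, p$W2)
  dZ1 <- dA1 * (ch$Z1 > 0)
  g$W1 <- crossprod(ch$Hflat, dZ1); g$b1 <- colSums(dZ1)
  dHflat <- tcrossprod(dZ1, p$W1)
  if (spec$dropout1 > 0) dHflat <- dHflat * ch$masks$m1 / (1 - spec$dropout1)
  dH <- array(dHflat, c(B, P, Fk))
  dH <- matrix(dH, B * P, Fk)
  dC <- matrix(0, B * P, Fk)
  g$Wx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  g$Wh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  g$b <- numeric(length(p$b))
  ix <- seq_len(Fk)
  for (t in rev(seq_len(ch$Tn))) {
    s <- ch$lstm[[t]]
    dO <- dH * s$tC
    dC <- dC + dH * s$o * (1 - s$tC^2)
    dI <- dC * s$g
    dG <- dC * s$i
    dFg <- dC * s$Cprev
    dCprev <- dC * s$f
    dZ <- cbind(dI * s$i * (1 - s$i),
                dFg * s$f * (1 - s$f),
                dG * (1 - s$g^2),
                dO * s$o * (1 - s$o))
    g$Wx <- g$Wx + crossprod(s$Mx, dZ)
    g$Wh <- g$Wh + crossprod(s$Mh, dZ)
    g$b <- g$b + colSums(dZ)
    dMh <- tcrossprod(dZ, p$Wh)
    dH <- matrix(col2im3(dMh, B, P, Fk), B * P, Fk)
    dC <- dCprev
  }
  g
}

#' Balanced inverse-frequency class weights
#'
#' `weight_c = N / (K * n_c)` over the window labels, so the predominant
#' rest class is down-weighted relative to the grasps.
#'
#' @param window_labels Integer window labels (0 = rest).
#' @param classes Classes the weights must cover; defaults to the classes
#'   present. An absent requested class is an error.
#' @return Named numeric vector of weights (names are class ids).
#' @export
compute_class_weights <- function(window_labels, classes = NULL) {
  present <- sort(unique(as.integer(window_labels)))
  classes <- sort(as.integer(classes %||% present))
  missing_cls <- setdiff(classes, present)
  if (length(missing_cls)) {
    stopf("class(es) absent from training windows: %s",
          paste(missing_cls, collapse = ", "))
  }
  counts <- vapply(classes, function(cl) sum(window_labels == cl), numeric(1))
  w <- length(window_labels) / (length(classes) * counts)
  names(w) <- classes
  w
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Train the ConvLSTM classifier
#'
#' Runs the fixed epoch budget with class-weighted categorical
#' cross-entropy and Adam, evaluating validation accuracy after every epoch
#' and returning the parameter snapshot that maximized it.
#'
#' @param model A [build_model()] object.
#' @param train_tensor,val_tensor lists with `tensor` (N x 10 x 1 x 20 x 12)
#'   and `labels` (integer class ids).
#' @param config A [train_config()].
#' @param class_weights Named weights from [compute_class_weights()];
#'   `NULL` computes them from the training labels.
#' @param verbose Print per-epoch progress.
#' @return list(model = best snapshot, log = per-epoch data.frame,
#'   best_epoch, best_val_accuracy).
#' @export
train_model <- function(model, train_tensor, val_tensor,
                        config = train_config(), class_weights = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "convlstm_model"))
  x <- train_tensor$tensor; yl <- as.integer(train_tensor$labels)
  if (is.null(class_weights)) class_weights <- compute_class_weights(yl)
  wts <- unname(class_weights[as.character(yl)])
  if (anyNA(wts)) stopf("class weight missing for some training label")
  classes <- model$classes
  Y <- one_hot(yl, classes)
  n <- dim(x)[1]
  spec <- model$spec
  hid_flat <- model$spatial * spec$filters

  adam <- lapply(model$params, function(p) {
    list(m = array(0, dim(p) %||% length(p)), v = array(0, dim(p) %||% length(p)))
  })
  step <- 0L
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_acc = numeric(0), val_loss = numeric(0),
                    val_acc = numeric(0))

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        B <- length(idx)
        Xb <- x[idx, , , , , drop = FALSE]
        masks <- list(
          m1 = matrix(stats::runif(B * hid_flat) >= spec$dropout1, B, hid_flat) * 1,
          m2 = matrix(stats::runif(B * spec$dense_units[2]) >= spec$dropout2,
                      B, spec$dense_units[2]) * 1
        )
        fw <- convlstm_forward(model, Xb, train = TRUE, masks = masks,
                               keep_cache = TRUE)
        pb <- fw$probs
        wb <- wts[idx]
        li <- -log(pmax(pb[cbind(seq_len(B), match(yl[idx], classes))], 1e-12))
        loss <- mean(wb * li)
        if (!is.finite(loss)) stopf("non-finite loss at epoch %d; aborting", epoch)
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct + sum(classes[row_argmax(pb)] == yl[idx])
        grads <- convlstm_backward(model, fw, Y[idx, , drop = FALSE], wb)
        step <- step + 1L
        for (nm in names(grads)) {
          st <- adam[[nm]]
          st$m <- config$beta1 * st$m + (1 - config$beta1) * grads[[nm]]
          st$v <- config$beta2 * st$v + (1 - config$beta2) * grads[[nm]]^2
          adam[[nm]] <- st
          mhat <- st$m / (1 - config$beta1^step)
          vhat <- st$v / (1 - config$beta2^step)
          model$params[[nm]] <- model$params[[nm]] -
            config$lr * mhat / (sqrt(vhat) + config$eps)
        }
      }
      val <- evaluate_tensor(model, val_tensor)
      log[epoch, ] <- list(epoch, ep_loss / n, ep_correct / n,
                           val$loss, val$accuracy)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, val$loss, val$accuracy))
      }
      if (val$accuracy > best$acc) {
        best <- list(acc = val$accuracy, params = model$params, epoch = epoch)
      }
    }
  })
  model$params <- best$params
  list(model = model, log = log, best_epoch = best$epoch,
       best_val_accuracy = best$acc)
}

evaluate_tensor <- function(model, tensor_set, batch = 256L) {
  pr <- predict_proba(model, tensor_set$tensor, batch = batch)
  yl <- as.integer(tensor_set$labels)
  li <- -log(pmax(pr[cbind(seq_along(yl), match(yl, model$classes))], 1e-12))
  list(loss = mean(li),
       accuracy = mean(model$classes[row_argmax(pr)] == yl))
}

#' Predict class probabilities for a batch tensor
#'
#' @param model A trained `convlstm_model`.
#' @param tensor N x 10 x 1 x 20 x 12 input tensor.
#' @param batch Internal batch size.
#' @return N x n_classes matrix of posteriors; every row sums to 1.
#'   Column names are class ids (0 = rest).
#' @export
predict_proba <- function(model, tensor, batch = 256L) {
  n <- dim(tensor)[1]
  out <- matrix(NA_real_, n, model$spec$n_classes,
                dimnames = list(NULL, model$classes))
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    fw <- convlstm_forward(model, tensor[idx, , , , , drop = FALSE])
    out[idx, ] <- fw$probs
  }
  out
}

#' Streaming classification of a standardized sEMG stream
#'
#' Emits one 11-class posterior every `stride_inference` samples (about
#' 10 ms): at sample t = 200, 220, 240, ... the trailing 200-sample window
#' ending at t is classified. Identical to batch inference on the same
#' extracted windows.
#'
#' @param model A trained `convlstm_model`.
#' @param emg_std Standardized + rectified stream (samples x 12).
#' @param spec A [window_spec()].
#' @return list of class `prob_stream`: `probs` (steps x n_classes) and `t`
#'   (emitting sample index of each step); empty for streams shorter than
#'   one window.
#' @export
predict_stream <- function(model, emg_std, spec = window_spec()) {
  L <- nrow(emg_std)
  wl <- spec$window_len; st <- spec$stride_inference
  if (L < wl) {
    return(structure(list(probs = matrix(NA_real_, 0, model$spec$n_classes),
                          t = integer(0)), class = "prob_stream"))
  }
  ends <- seq.int(wl, L, by = st)
  n <- length(ends)
  windows <- array(0, c(n, wl, ncol(emg_std)))
  for (i in seq_len(n)) {
    windows[i, , ] <- emg_std[(ends[i] - wl + 1L):ends[i], ]
  }
  probs <- predict_proba(model, tensorize(windows, spec))
  structure(list(probs = probs, t = ends), class = "prob_stream")
}
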