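# Numerical engine: mini-batch forward/backward passes for the layer kinds
# produced by build_model(), plus the Adam optimizer. Activations with
# spatial extent are (H, W, C, B) arrays; flat activations are
# (features, B) matrices. Convolution uses im2col gathers (C++) and BLAS
# matrix products; the patch-matrix row order is (h, w, b) and its column
# order matches the column-major flattening of a (3, 3, Cin, Cout) kernel.

conv_forward <- function(A, par) {
  d <- dim(A)
  P <- cpp_im2col3(A, d[1L], d[2L], d[3L], d[4L])
  Z <- P %*% par$W
  Z <- Z + rep(par$b, each = nrow(P))
  out <- aperm(array(Z, c(d[1L], d[2L], d[4L], ncol(par$W))), c(1L, 2L, 4L, 3L))
  list(out = out, cache = list(P = P, dims = d))
}

conv_backward <- function(dY, par, cache) {
  d <- cache$dims
  dZ <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L])
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- tcrossprod(dZ, par$W)
  dA <- cpp_col2im3(dP, d[1L], d[2L], d[3L], d[4L])
  list(dA = dA, dW = dW, db = db)
}

maxpool_forward <- function(A) {
  d <- dim(A)
  r <- cpp_maxpool2(A, d[1L], d[2L], d[3L], d[4L])
  list(out = r$out, cache = list(argmax = r$argmax, dims = d))
}

maxpool_backward <- function(dY, cache) {
  d <- cache$dims
  cpp_maxpool2_backward(dY, cache$argmax, d[1L], d[2L], d[3L], d[4L])
}

dense_forward <- function(A, par) {
  list(out = par$W %*% A + par$b, cache = list(A = A))
}

dense_backward <- function(dZ, par, cache) {
  list(dA = crossprod(par$W, dZ), dW = tcrossprod(dZ, cache$A),
       db = rowSums(dZ))
}

softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2L, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(Z))
}

# Forward pass. Returns the softmax output (if present), pre-softmax
# logits, and per-layer caches for the backward pass. Dropout masks are
# drawn from the current RNG stream when training = TRUE.
net_forward <- function(model, X, training = FALSE) {
  layers <- model$spec$layers
  caches <- vector("list", length(layers))
  A <- X
  logits <- NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "softmax") logits <- A
    A <- switch(l$kind,
      conv = {
        r <- conv_forward(A, model$params[[i]])
        caches[[i]] <- r$cache
        r$out
      },
      relu = {
        caches[[i]] <- list(mask = A > 0)
        A * (A > 0)
      },
      dropout = {
        if (training && l$rate > 0) {
          keep <- 1 - l$rate
          mask <- (array(runif(length(A)), dim(A) %||% length(A)) < keep) /
            keep
          caches[[i]] <- list(mask = mask)
          A * mask
        } else {
          caches[[i]] <- list(mask = NULL)
          A
        }
      },
      maxpool = {
        r <- maxpool_forward(A)
        caches[[i]] <- r$cache
        r$out
      },
      flatten = {
        caches[[i]] <- list(dims = dim(A))
        matrix(A, prod(dim(A)[1:3]), dim(A)[4L])
      },
      dense = {
        r <- dense_forward(A, model$params[[i]])
        caches[[i]] <- r$cache
        r$out
      },
      softmax = softmax_cols(A))
  }
  list(out = A, logits = logits %||% A, caches = caches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward pass from a gradient on the pre-softmax logits; returns
# per-layer parameter gradients and the gradient w.r.t. the input.
net_backward <- function(model, caches, dlogits) {
  layers <- model$spec$layers
  grads <- vector("list", length(layers))
  dA <- dlogits
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    dA <- switch(l$kind,
      softmax = dA,  # gradient is already on the logits
      dense = {
        r <- dense_backward(dA, model$params[[i]], caches[[i]])
        grads[[i]] <- list(dW = r$dW, db = r$db)
        r$dA
      },
      flatten = array(dA, caches[[i]]$dims),
      dropout = if (is.null(caches[[i]]$mask)) dA else dA * caches[[i]]$mask,
      relu = dA * caches[[i]]$mask,
      maxpool = maxpool_backward(dA, caches[[i]]),
      conv = {
        r <- conv_backward(dA, model$params[[i]], caches[[i]])
        grads[[i]] <- list(dW = r$dW, db = r$db)
        r$dA
      })
  }
  list(grads = grads, dX = dA)
}

# Cross-entropy data loss plus L2 penalty and its gradients for one batch.
# y is an integer class vector (1-based). Returns the penalized loss, the
# data loss, batch accuracy and per-layer gradients.
net_loss_grads <- function(model, X, y, training = TRUE) {
  fwd <- net_forward(model, X, training = training)
  P <- fwd$out
  B <- ncol(P)
  eps <- 1e-12
  data_loss <- -mean(log(pmax(P[cbind(y, seq_len(B))], eps)))
  acc <- mean(max.col(t(P), ties.method = "first") == y)
  dlogits <- P
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  bwd <- net_backward(model, fwd$caches, dlogits)
  lambda <- model$spec$config$l2_lambda
  l2 <- lambda * l2_weight_sum(model)
  for (i in seq_along(bwd$grads)) {
    if (!is.null(bwd$grads[[i]]))
      bwd$grads[[i]]$dW <- bwd$grads[[i]]$dW +
        2 * lambda * model$params[[i]]$W
  }
  list(loss = data_loss + l2, data_loss = data_loss, l2 = l2, accuracy = acc,
       grads = bwd$grads)
}

# Sum of squared weights (not biases) over all parameterized layers.
l2_weight_sum <- function(model) {
  sum(vapply(model$params, function(p)
    if (is.null(p)) 0 else sum(p$W^2), numeric(1L)))
}

adam_init <- function(model) {
  lapply(model$params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(model, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- model$spec$layers
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g) || !layers[[i]]$trainable) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t)
    vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t)
    vhb <- s$vb / (1 - beta2^t)
    model$params[[i]]$W <- model$params[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    model$params[[i]]$b <- model$params[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

# Class probabilities for an (H, W, 1, B) array, evaluated in chunks.
net_predict_probs <- function(model, X, chunk = 64L) {
  B <- dim(X)[4L]
  nc <- model$spec$config$n_classes
  P <- matrix(0, nc, B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    P[, s:e] <- net_forward(model, X[, , , s:e, drop = FALSE])$out
  }
  P
}

# Gradient of the target-class pre-softmax score w.r.t. the input pixels.
net_input_gradient <- function(model, X, class_idx) {
  fwd <- net_forward(model, X, training = FALSE)
  dlogits <- matrix(0, model$spec$config$n_classes, dim(X)[4L])
  dlogits[class_idx, ] <- 1
  net_backward(model, fwd$caches, dlogits)$dX
}

#' Predict classes or probabilities from a trained model
#'
#' @param object a `stagernet_model` (as returned by [train_fold()] /
#'   [run_cross_validation()]).
#' @param newdata an [img_dataset()], a single image matrix, or an
#'   `(H, W, 1, B)` array.
#' @param type `"prob"` for class probabilities (one row per image) or
#'   `"class"` for labels.
#' @param ... unused.
#' @return A matrix of probabilities with one column per class, or a
#'   character (integer, if the model has no class names) vector of labels.
#' @export
predict.stagernet_model <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  if (inherits(newdata, "img_dataset")) {
    cn <- object$class_names %||% sort(unique(dataset_labels(newdata)))
    newdata <- dataset_to_array(newdata, cn)$x
  } else if (is.matrix(newdata)) {
    newdata <- array(newdata, c(dim(newdata), 1L, 1L))
  }
  P <- t(net_predict_probs(object, newdata))
  colnames(P) <- object$class_names
  if (type == "prob") return(P)
  idx <- max.col(P, ties.method = "first")
  if (is.null(object$class_names)) idx else object$class_names[idx]
}
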