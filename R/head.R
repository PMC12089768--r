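# Softmax (multinomial logistic) classification head trained by
# full-batch gradient descent with momentum.  This is the "single
# feedforward layer" sitting on top of span representations; written
# in-package so that per-epoch loss logging, label-space handling and
# determinism are explicit.

# Feature map of the classification head for a marked span: the
# concatenated boundary-marker vectors plus their elementwise product.
# The multiplicative channel lets the (convex, linear) softmax layer
# express start-AND-end conjunctions, which pure concatenation cannot.
span_features <- function(R, width) {
  hs <- R[, seq_len(width), drop = FALSE]
  he <- R[, width + seq_len(width), drop = FALSE]
  cbind(R, hs * he)
}

softmax_probs <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# X: n x d feature matrix; y: character labels; labels: full label space
# (kept even when a class is absent from the data).  class_weight_alpha
# interpolates between unweighted (0) and fully class-balanced (1)
# per-sample weights; a moderate value lifts rare-class recall without
# flooding the frequent classes.  Returns a "softmax_head" with weights,
# scaling, label space and the loss log.
softmax_train <- function(X, y, labels, epochs = 120L, lr = 0.5,
                          momentum = 0.9, l2 = 1e-4, seed = 42L,
                          init_sd = 0.01, class_weight_alpha = 0) {
  stopifnot(nrow(X) == length(y), all(y %in% labels))
  n <- nrow(X); d <- ncol(X); K <- length(labels)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2L, mu), 2L, sdv, "/"))
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), match(y, labels))] <- 1
  cnt <- table(factor(y, levels = labels))
  cw <- (n / (pmax(cnt, 1) * K))^class_weight_alpha
  wv <- as.numeric(cw[match(y, labels)])
  wv <- wv / mean(wv)

  old <- .Random.seed_get()
  set.seed(seed %% 2147483647L)
  W <- matrix(stats::rnorm((d + 1L) * K, sd = init_sd), d + 1L, K)
  .Random.seed_set(old)

  V <- matrix(0, d + 1L, K)
  loss_log <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    P <- softmax_probs(Xs %*% W)
    loss_log[ep] <- -mean(wv * log(pmax(P[Y == 1], 1e-12))) +
      l2 / 2 * sum(W[-1L, ]^2)
    G <- crossprod(Xs, (P - Y) * wv) / n
    G[-1L, ] <- G[-1L, ] + l2 * W[-1L, ]
    V <- momentum * V - lr * G
    W <- W + V
  }
  structure(list(W = W, mu = mu, sd = sdv, labels = labels,
                 loss_log = loss_log),
            class = "softmax_head")
}

softmax_predict <- function(head, X) {
  Xs <- cbind(1, sweep(sweep(X, 2L, head$mu), 2L, head$sd, "/"))
  P <- softmax_probs(Xs %*% head$W)
  colnames(P) <- head$labels
  P
}

#' @export
print.softmax_head <- function(x, ...) {
  cat(sprintf("<softmax_head: %d features -> %d classes, final loss %.4f>\n",
              nrow(x$W) - 1L, ncol(x$W), utils::tail(x$loss_log, 1L)))
  invisible(x)
}

# Argmax decoding with the null-favouring tie policy: if the null label
# ties with the best label (within eps), null wins.
argmax_with_null_ties <- function(P, null_label = "O", eps = 1e-9) {
  labels <- colnames(P)
  null_col <- match(null_label, labels)
  apply(P, 1L, function(p) {
    best <- max(p)
    if (!is.na(null_col) && p[null_col] >= best - eps) return(null_label)
    labels[which.max(p)]
  })
}
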