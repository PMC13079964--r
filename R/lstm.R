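# Stacked LSTM sequence classifier / feature extractor, in vectorised base R.
# Gates are blocked [input | forget | cell | output] in the 4H-wide weight
# matrices; dropout is applied between layers (and before the softmax head)
# during training only, with inverted scaling.

sigm <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(layer_sizes, n_classes, input_dim = 1L) {
  glorot <- function(nin, nout) {
    r <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -r, r), nin, nout)
  }
  n_in <- c(input_dim, layer_sizes[-length(layer_sizes)])
  layers <- lapply(seq_along(layer_sizes), function(l) {
    H <- layer_sizes[l]
    b <- numeric(4 * H)
    b[H + seq_len(H)] <- 1          # forget-gate bias starts open
    list(Wx = glorot(n_in[l], 4 * H), Wh = glorot(H, 4 * H), b = b)
  })
  HL <- layer_sizes[length(layer_sizes)]
  list(layers = layers,
       Wy = glorot(HL, n_classes), by = numeric(n_classes))
}

# forward pass over a batch; X is N x T. Returns final hidden state of the
# top layer plus (optionally) the caches needed for BPTT.
lstm_forward <- function(params, X, layer_sizes, dropout = 0,
                         masks = NULL, keep_cache = FALSE) {
  N <- nrow(X); Tn <- ncol(X); L <- length(layer_sizes)
  H_state <- lapply(layer_sizes, function(h) matrix(0, N, h))
  C_state <- H_state
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    x <- X[, t, drop = FALSE]
    if (keep_cache) cache[[t]] <- vector("list", L)
    for (l in seq_len(L)) {
      p <- params$layers[[l]]
      H <- layer_sizes[l]
      Hprev <- H_state[[l]]; Cprev <- C_state[[l]]
      Z <- x %*% p$Wx + Hprev %*% p$Wh
      Z <- sweep(Z, 2L, p$b, "+")
      I <- sigm(Z[, seq_len(H), drop = FALSE])
      Fg <- sigm(Z[, H + seq_len(H), drop = FALSE])
      G <- tanh(Z[, 2 * H + seq_len(H), drop = FALSE])
      O <- sigm(Z[, 3 * H + seq_len(H), drop = FALSE])
      C <- Fg * Cprev + I * G
      Hh <- O * tanh(C)
      if (keep_cache)
        cache[[t]][[l]] <- list(x = x, Hprev = Hprev, Cprev = Cprev,
                                I = I, Fg = Fg, G = G, O = O, C = C)
      H_state[[l]] <- Hh; C_state[[l]] <- C
      x <- if (!is.null(masks)) Hh * masks[[l]] else Hh
    }
  }
  top <- if (!is.null(masks)) H_state[[L]] * masks[[L]] else H_state[[L]]
  list(features = top, H_state = H_state, cache = cache)
}

lstm_backward <- function(params, fw, X, Y1hot, layer_sizes, masks = NULL) {
  N <- nrow(X); Tn <- ncol(X); L <- length(layer_sizes)
  logits <- fw$features %*% params$Wy
  logits <- sweep(logits, 2L, params$by, "+")
  P <- exp(logits - apply(logits, 1L, max))
  P <- P / rowSums(P)
  loss <- -mean(rowSums(Y1hot * log(pmax(P, 1e-12))))
  dLogits <- (P - Y1hot) / N
  grads <- list(
    layers = lapply(params$layers, function(p)
      list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0)),
    Wy = t(fw$features) %*% dLogits, by = colSums(dLogits))
  dTop <- dLogits %*% t(params$Wy)
  if (!is.null(masks)) dTop <- dTop * masks[[L]]
  dH_rec <- lapply(layer_sizes, function(h) matrix(0, N, h))
  dC_rec <- dH_rec
  dH_from_head <- dTop               # reaches the top layer at t = T only
  for (t in rev(seq_len(Tn))) {
    dX_up <- NULL                    # gradient flowing into layer below
    for (l in rev(seq_len(L))) {
      cc <- fw$cache[[t]][[l]]
      p <- params$layers[[l]]
      H <- layer_sizes[l]
      dHh <- dH_rec[[l]]
      if (l == L && t == Tn) dHh <- dHh + dH_from_head
      if (l < L) {
        d_in <- dX_up
        if (!is.null(masks)) d_in <- d_in * masks[[l]]
        dHh <- dHh + d_in
      }
      tC <- tanh(cc$C)
      dO <- dHh * tC
      dC <- dC_rec[[l]] + dHh * cc$O * (1 - tC^2)
      dI <- dC * cc$G
      dG <- dC * cc$I
      dF <- dC * cc$Cprev
      dC_rec[[l]] <- dC * cc$Fg
      dZ <- cbind(dI * cc$I * (1 - cc$I),
                  dF * cc$Fg * (1 - cc$Fg),
                  dG * (1 - cc$G^2),
                  dO * cc$O * (1 - cc$O))
      g <- grads$layers[[l]]
      g$Wx <- g$Wx + t(cc$x) %*% dZ
      g$Wh <- g$Wh + t(cc$Hprev) %*% dZ
      g$b <- g$b + colSums(dZ)
      grads$layers[[l]] <- g
      dH_rec[[l]] <- dZ %*% t(p$Wh)
      dX_up <- dZ %*% t(p$Wx)
    }
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params) rapply(params, function(w) w * 0, how = "replace")

adam_step <- function(params, grads, m, v, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(w, g, mm, vv) {
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g^2
    mh <- mm / (1 - beta1^t)
    vh <- vv / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = mm, v = vv)
  }
  for (l in seq_along(params$layers)) {
    for (k in c("Wx", "Wh", "b")) {
      u <- upd(params$layers[[l]][[k]], grads$layers[[l]][[k]],
               m$layers[[l]][[k]], v$layers[[l]][[k]])
      params$layers[[l]][[k]] <- u$w
      m$layers[[l]][[k]] <- u$m
      v$layers[[l]][[k]] <- u$v
    }
  }
  for (k in c("Wy", "by")) {
    u <- upd(params[[k]], grads[[k]], m[[k]], v[[k]])
    params[[k]] <- u$w; m[[k]] <- u$m; v[[k]] <- u$v
  }
  list(params = params, m = m, v = v)
}

#' Train the LSTM feature extractor
#'
#' Trains a stacked LSTM end-to-end with a temporary softmax classification
#' head on the window labels (cross-entropy loss, Adam, mini-batches, seeded
#' inverted dropout between layers, early stopping on a held-out validation
#' split). After training the head is kept only for the pure-LSTM baseline;
#' the deep feature vector of a window is the final layer's last-time-step
#' hidden state. Default architectures: 75-50-25-15 units (15 deep features)
#' for the weekly-quality target and 100-80-60-40 units (40 deep features)
#' for the consistency target, tanh cell activation, dropout 0.2, input
#' shape 24 x 1.
#'
#' @param X Numeric matrix, one window per row (24 normalised hourly counts).
#' @param labels Class labels, one per row (>= 2 distinct classes).
#' @param layer_sizes Integer vector of hidden sizes per stacked layer.
#' @param config Configuration list; the `extractor` block supplies dropout,
#'   epochs, batch size, learning rate, validation fraction, patience, seed.
#' @return An object of class `lstm_extractor`.
#' @export
train_extractor <- function(X, labels, layer_sizes = c(75L, 50L, 25L, 15L),
                            config = sleepmos_config()) {
  ex <- config$extractor
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) < 2L) stop("windows must have at least 2 time steps")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stop("parameter error: training labels contain a single class")
  if (ex$dropout < 0 || ex$dropout >= 1)
    stop("parameter error: dropout must lie in [0, 1)")
  y <- match(as.character(labels), classes)
  K <- length(classes)
  N <- nrow(X)
  withr::with_seed(as.integer(ex$seed), {
    params <- init_lstm_params(layer_sizes, K)
    m <- adam_init(params); v <- adam_init(params)
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(N), y), function(ix) {
      nv <- floor(length(ix) * ex$val_fraction)
      if (nv >= 1L) sample(ix, nv) else integer(0)
    }))
    tr_idx <- setdiff(seq_len(N), val_idx)
    if (length(val_idx) == 0L) { val_idx <- tr_idx }
    onehot <- function(idx) {
      Y <- matrix(0, length(idx), K)
      Y[cbind(seq_along(idx), y[idx])] <- 1
      Y
    }
    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- NULL
    step <- 0L
    stall <- 0L
    for (ep in seq_len(ex$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = ex$batch_size)) {
        bi <- ord[b0:min(b0 + ex$batch_size - 1L, length(ord))]
        masks <- if (ex$dropout > 0)
          lapply(layer_sizes, function(h)
            matrix(stats::rbinom(length(bi) * h, 1L, 1 - ex$dropout) /
                     (1 - ex$dropout), length(bi), h))
          else NULL
        fw <- lstm_forward(params, X[bi, , drop = FALSE], layer_sizes,
                           masks = masks, keep_cache = TRUE)
        bw <- lstm_backward(params, fw, X[bi, , drop = FALSE], onehot(bi),
                            layer_sizes, masks = masks)
        step <- step + 1L
        upd <- adam_step(params, bw$grads, m, v, ex$learning_rate, step)
        params <- upd$params; m <- upd$m; v <- upd$v
        ep_loss <- ep_loss + bw$loss; nb <- nb + 1L
      }
      # validation loss / accuracy
      fw <- lstm_forward(params, X[val_idx, , drop = FALSE], layer_sizes)
      logits <- sweep(fw$features %*% params$Wy, 2L, params$by, "+")
      P <- exp(logits - apply(logits, 1L, max)); P <- P / rowSums(P)
      vloss <- -mean(log(pmax(P[cbind(seq_along(val_idx), y[val_idx])], 1e-12)))
      vacc <- mean(max.col(P) == y[val_idx])
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / nb, val_loss = vloss,
        val_accuracy = vacc))
      if (vloss < best$loss - 1e-5) {
        best <- list(loss = vloss, params = params, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= ex$patience) break
      }
    }
    structure(list(params = best$params, layer_sizes = as.integer(layer_sizes),
                   classes = classes, history = history,
                   dropout = ex$dropout, trained = TRUE,
                   input_len = ncol(X), config = ex),
              class = "lstm_extractor")
  })
}

#' @export
print.lstm_extractor <- function(x, ...) {
  cat("<lstm_extractor> stacked LSTM", paste(x$layer_sizes, collapse = "-"),
      "(tanh), dropout", x$dropout, "\n")
  cat("  ", length(x$classes), "classes; trained",
      max(x$history$epoch), "epochs; best val loss",
      sprintf("%.4f", min(x$history$val_loss)), "\n")
  cat("  deep-feature dimension:", x$layer_sizes[length(x$layer_sizes)], "\n")
  invisible(x)
}

#' Extract deep features from trained extractor
#'
#' Deterministic inference pass (dropout disabled): returns the final LSTM
#' layer's last-time-step hidden state, one row per window.
#'
#' @param extractor A trained `lstm_extractor`.
#' @param X Matrix of windows (rows) matching the training window length.
#' @return Numeric matrix, `nrow(X)` rows by last-layer-size columns, with
#'   column names `deep01`, `deep02`, ...
#' @export
extract_deep_features <- function(extractor, X) {
  if (!inherits(extractor, "lstm_extractor") || !isTRUE(extractor$trained))
    stop("state error: extractor is not a trained lstm_extractor")
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != extractor$input_len)
    stop("shape error: windows have ", ncol(X), " time steps; extractor ",
         "was trained on ", extractor$input_len)
  fw <- lstm_forward(extractor$params, X, extractor$layer_sizes)
  feats <- fw$features
  colnames(feats) <- sprintf("deep%02d", seq_len(ncol(feats)))
  feats
}

#' Predict classes with the LSTM's own softmax head
#'
#' Used by the pure-LSTM baseline variant: end-to-end classification without
#' the SVM stage.
#'
#' @param extractor A trained `lstm_extractor`.
#' @param X Matrix of windows.
#' @return List with `class` (character predictions) and `prob`
#'   (N x K matrix of class probabilities).
#' @export
predict_lstm_head <- function(extractor, X) {
  feats <- extract_deep_features(extractor, X)
  logits <- sweep(feats %*% extractor$params$Wy, 2L, extractor$params$by, "+")
  P <- exp(logits - apply(logits, 1L, max)); P <- P / rowSums(P)
  colnames(P) <- extractor$classes
  list(class = extractor$classes[max.col(P)], prob = P)
}
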