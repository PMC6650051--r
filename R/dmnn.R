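#' Configuration for the deep maxout network
#'
#' The architecture is fixed at three hidden maxout blocks followed by a
#' sigmoid output layer with one neuron per vocabulary term. Each hidden
#' block batch-normalizes its inputs, applies `maxout_pieces` parallel
#' affine maps combined through an elementwise maximum, and applies
#' dropout during training.
#'
#' @param hidden_dim width of every hidden layer. The reference protocol
#'   tunes it over 300, 500, 700 and 1000 (see [select_hidden_dim()]);
#'   an input-matched width is also admissible.
#' @param maxout_pieces number of affine pieces per maxout unit.
#' @param dropout_rate dropout probability in \[0, 1).
#' @param learning_rate AdaGrad learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a validated `dmnn_config` list.
#' @export
dmnn_config <- function(hidden_dim = 500, maxout_pieces = 3, dropout_rate = 0.5,
                        learning_rate = 0.05, batch_size = 100, epochs = 150,
                        seed = 1L) {
  problems <- character(0)
  if (hidden_dim <= 0) problems <- c(problems, "hidden_dim must be > 0")
  if (maxout_pieces < 1) problems <- c(problems, "maxout_pieces must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) problems <- c(problems, "dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) problems <- c(problems, "learning_rate must be > 0")
  if (batch_size < 1) problems <- c(problems, "batch_size must be >= 1")
  if (epochs < 1) problems <- c(problems, "epochs must be >= 1")
  if (length(problems) > 0) stop("invalid dmnn_config: ", paste(problems, collapse = "; "))
  structure(list(n_hidden_layers = 3L, hidden_dim = as.integer(hidden_dim),
                 maxout_pieces = as.integer(maxout_pieces),
                 dropout_rate = dropout_rate, optimizer = "adagrad",
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), init = "glorot_uniform",
                 seed = as.integer(seed)),
            class = "dmnn_config")
}

glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Build an untrained deep maxout network
#'
#' @param input_dim dimension of the input embedding.
#' @param vocab_size number of output terms (sigmoid neurons).
#' @param cfg a [dmnn_config()].
#' @return object of class `dmnn_model` with Glorot-uniform initialized
#'   parameters, unit batch-norm running statistics and an empty
#'   training log.
#' @export
build_dmnn <- function(input_dim, vocab_size, cfg = dmnn_config()) {
  stopifnot(inherits(cfg, "dmnn_config"))
  if (input_dim <= 0 || vocab_size <= 0) stop("input_dim and vocab_size must be > 0")
  set.seed(cfg$seed)
  dims_in <- c(input_dim, cfg$hidden_dim, cfg$hidden_dim)
  layers <- vector("list", 3L)
  for (l in 1:3) {
    din <- dims_in[l]; dout <- cfg$hidden_dim
    layers[[l]] <- list(
      gamma = rep(1, din), beta = rep(0, din),
      run_mean = rep(0, din), run_var = rep(1, din),
      W = lapply(seq_len(cfg$maxout_pieces), function(j) glorot_uniform(din, dout)),
      b = lapply(seq_len(cfg$maxout_pieces), function(j) rep(0, dout))
    )
  }
  out <- list(W = glorot_uniform(cfg$hidden_dim, vocab_size), b = rep(0, vocab_size))
  structure(list(layers = layers, out = out, cfg = cfg,
                 input_dim = as.integer(input_dim),
                 vocab_size = as.integer(vocab_size),
                 trained = FALSE, loss_log = numeric(0)),
            class = "dmnn_model")
}

#' @export
print.dmnn_model <- function(x, ...) {
  cat(sprintf("<dmnn_model: %d -> %d/%d/%d (maxout k=%d) -> %d sigmoid, %s>\n",
              x$input_dim, x$cfg$hidden_dim, x$cfg$hidden_dim, x$cfg$hidden_dim,
              x$cfg$maxout_pieces, x$vocab_size,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

bn_eps <- 1e-5

# forward pass; training=TRUE uses batch statistics + dropout and keeps
# the caches needed for backprop.
dmnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$cfg
  caches <- vector("list", 3L)
  H <- X
  for (l in 1:3) {
    ly <- model$layers[[l]]
    if (training) {
      mu <- colMeans(H)
      v <- colMeans(sweep(H, 2, mu)^2)
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    xhat <- sweep(sweep(H, 2, mu), 2, sqrt(v + bn_eps), "/")
    Y <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    Z <- lapply(seq_len(cfg$maxout_pieces), function(j) {
      sweep(Y %*% ly$W[[j]], 2, ly$b[[j]], "+")
    })
    A <- Z[[1L]]
    amax <- matrix(1L, nrow(A), ncol(A))
    if (cfg$maxout_pieces > 1L) {
      for (j in 2:cfg$maxout_pieces) {
        upd <- Z[[j]] > A
        A[upd] <- Z[[j]][upd]
        amax[upd] <- j
      }
    }
    mask <- NULL
    if (training && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      mask <- matrix(stats::rbinom(length(A), 1L, keep), nrow(A)) / keep
      A <- A * mask
    }
    caches[[l]] <- list(x = H, mu = mu, v = v, xhat = xhat, y = Y,
                        amax = amax, mask = mask, act = A)
    H <- A
  }
  Zo <- sweep(H %*% model$out$W, 2, model$out$b, "+")
  P <- 1 / (1 + exp(-Zo))
  list(p = P, h3 = H, caches = caches)
}

#' Train the deep maxout network on embeddings vs multi-label targets
#'
#' Minimizes binary cross-entropy (summed over vocabulary terms, averaged
#' over proteins) with AdaGrad, minibatches and per-epoch loss logging.
#' Batch-norm running statistics are updated with momentum 0.9 for use at
#' inference time.
#'
#' @param model an untrained (or previously trained) [build_dmnn()]
#'   model.
#' @param X [embedding_matrix()] (or plain matrix), one row per protein.
#' @param Y binary matrix of targets restricted to the vocabulary, rows
#'   aligned with `X`.
#' @param cfg optional config overriding `model$cfg`.
#' @return the trained `dmnn_model`, with `loss_log` holding per-epoch
#'   mean loss.
#' @export
train_dmnn <- function(model, X, Y, cfg = model$cfg) {
  stopifnot(inherits(model, "dmnn_model"))
  X <- unclass(X); Y <- unclass(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("X and Y rows are not aligned on the same proteins")
  }
  if (ncol(X) != model$input_dim) stop("X dimension does not match model input_dim")
  if (ncol(Y) != model$vocab_size) stop("Y width does not match vocabulary size")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  model$cfg <- cfg
  n <- nrow(X)
  # AdaGrad accumulators mirror the parameter structure
  acc <- list(layers = lapply(model$layers, function(ly) {
    list(gamma = ly$gamma * 0, beta = ly$beta * 0,
         W = lapply(ly$W, function(w) w * 0), b = lapply(ly$b, function(b) b * 0))
  }), out = list(W = model$out$W * 0, b = model$out$b * 0))
  lr <- cfg$learning_rate
  ada_eps <- 1e-8
  adagrad <- function(param, g, G) {
    G <- G + g^2
    list(param = param - lr * g / (sqrt(G) + ada_eps), G = G)
  }
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (bstart in seq(1L, n, by = cfg$batch_size)) {
      rows <- ord[bstart:min(bstart + cfg$batch_size - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      Yb <- Y[rows, , drop = FALSE]
      m <- length(rows)
      fw <- dmnn_forward(model, Xb, training = TRUE)
      P <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
      loss <- -sum(Yb * log(P) + (1 - Yb) * log(1 - P)) / m
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      batch_losses <- c(batch_losses, loss)
      # output layer
      dZ <- (fw$p - Yb) / m
      gW <- t(fw$h3) %*% dZ
      gb <- colSums(dZ)
      dH <- dZ %*% t(model$out$W)
      st <- adagrad(model$out$W, gW, acc$out$W); model$out$W <- st$param; acc$out$W <- st$G
      st <- adagrad(model$out$b, gb, acc$out$b); model$out$b <- st$param; acc$out$b <- st$G
      # hidden blocks, backwards
      for (l in 3:1) {
        ca <- model$layers[[l]]
        cache <- fw$caches[[l]]
        if (!is.null(cache$mask)) dH <- dH * cache$mask
        dY <- matrix(0, m, length(ca$gamma))
        for (j in seq_len(model$cfg$maxout_pieces)) {
          sel <- cache$amax == j
          if (!any(sel)) {
            gWj <- ca$W[[j]] * 0; gbj <- ca$b[[j]] * 0
          } else {
            dZj <- dH * sel
            gWj <- t(cache$y) %*% dZj
            gbj <- colSums(dZj)
            dY <- dY + dZj %*% t(ca$W[[j]])
          }
          st <- adagrad(ca$W[[j]], gWj, acc$layers[[l]]$W[[j]])
          ca$W[[j]] <- st$param; acc$layers[[l]]$W[[j]] <- st$G
          st <- adagrad(ca$b[[j]], gbj, acc$layers[[l]]$b[[j]])
          ca$b[[j]] <- st$param; acc$layers[[l]]$b[[j]] <- st$G
        }
        # batch-norm backward
        dgamma <- colSums(dY * cache$xhat)
        dbeta <- colSums(dY)
        dxhat <- sweep(dY, 2, ca$gamma, "*")
        inv_sd <- 1 / sqrt(cache$v + bn_eps)
        dX <- sweep(
          dxhat - matrix(colMeans(dxhat), m, ncol(dY), byrow = TRUE) -
            sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*"),
          2, inv_sd, "*")
        st <- adagrad(ca$gamma, dgamma, acc$layers[[l]]$gamma)
        ca$gamma <- st$param; acc$layers[[l]]$gamma <- st$G
        st <- adagrad(ca$beta, dbeta, acc$layers[[l]]$beta)
        ca$beta <- st$param; acc$layers[[l]]$beta <- st$G
        # running statistics (momentum 0.9)
        ca$run_mean <- 0.9 * ca$run_mean + 0.1 * cache$mu
        ca$run_var <- 0.9 * ca$run_var + 0.1 * cache$v
        model$layers[[l]] <- ca
        dH <- dX
      }
    }
    model$loss_log <- c(model$loss_log, mean(batch_losses))
  }
  model$trained <- TRUE
  model
}

#' Extract the third-hidden-layer functional representation
#'
#' Runs the trained network in inference mode (dropout off, batch-norm
#' running statistics) and returns the post-maxout activations of hidden
#' block 3. These activations jointly encode the PPI-derived embedding
#' geometry and the functional co-annotation structure the network was
#' trained against, and serve as features for downstream per-term
#' classifiers.
#'
#' @param model a trained `dmnn_model`.
#' @param X embedding matrix with `model$input_dim` columns.
#' @return an [embedding_matrix()] with method `"string2go"`.
#' @export
extract_representation <- function(model, X) {
  stopifnot(inherits(model, "dmnn_model"))
  Xm <- unclass(X)
  if (ncol(Xm) != model$input_dim) stop("input dimension mismatch")
  H <- dmnn_forward(model, Xm, training = FALSE)$h3
  rownames(H) <- rownames(Xm)
  colnames(H) <- paste0("dim", seq_len(ncol(H)))
  embedding_matrix(H, method = "string2go",
                   network = attr(X, "network") %||% "")
}

#' Sigmoid-head predictions of the maxout network
#'
#' @inheritParams extract_representation
#' @return a `score_matrix` (protein x vocabulary, values in (0, 1)).
#' @export
predict_sigmoid <- function(model, X) {
  stopifnot(inherits(model, "dmnn_model"))
  Xm <- unclass(X)
  if (ncol(Xm) != model$input_dim) stop("input dimension mismatch")
  P <- dmnn_forward(model, Xm, training = FALSE)$p
  rownames(P) <- rownames(Xm)
  score_matrix(P, terms = colnames(P), method = "dmnn_sigmoid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the hidden-layer width by cross-validated median F1
#'
#' For each candidate width, runs seeded k-fold cross-validation, pools
#' the out-of-fold sigmoid predictions, computes per-term F1 at decision
#' threshold 0.5, takes the median over terms and rounds it to two
#' decimal places. The winner is the smallest candidate among those
#' attaining the maximum rounded median (the curse-of-dimensionality
#' tie-break: prefer the lowest width).
#'
#' @param candidates integer vector of candidate widths (the reference
#'   grid is 300, 500, 700, 1000).
#' @param X,Y training embeddings and binary targets (rows aligned).
#' @param cfg a [dmnn_config()] template; its `hidden_dim` is replaced by
#'   each candidate.
#' @param folds number of CV folds.
#' @param seed seed for the random fold assignment.
#' @return list with `hidden_dim` (the chosen width) and `report`
#'   (data frame candidate / median_f1 / rounded).
#' @export
select_hidden_dim <- function(candidates = c(300, 500, 700, 1000), X, Y,
                              cfg = dmnn_config(), folds = 10, seed = 1L) {
  stopifnot(length(candidates) >= 1)
  candidates <- sort(unique(as.integer(candidates)))
  X <- unclass(X); Y <- unclass(Y)
  n <- nrow(X)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  medians <- vapply(candidates, function(hd) {
    cfg_c <- cfg
    cfg_c$hidden_dim <- hd
    pred <- matrix(NA_real_, n, ncol(Y))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      mdl <- build_dmnn(ncol(X), ncol(Y), cfg_c)
      mdl <- train_dmnn(mdl, X[tr, , drop = FALSE], Y[tr, , drop = FALSE], cfg_c)
      pred[!tr, ] <- dmnn_forward(mdl, X[!tr, , drop = FALSE], training = FALSE)$p
    }
    f1s <- vapply(seq_len(ncol(Y)), function(t) {
      cm <- confusion_counts(pred[, t] >= 0.5, Y[, t] == 1)
      confusion_metrics(cm)$f1
    }, numeric(1))
    lower_median(f1s)
  }, numeric(1))
  rounded <- round(medians, 2)
  best <- candidates[rounded == max(rounded)]
  list(hidden_dim = min(best),
       report = data.frame(candidate = candidates, median_f1 = medians,
                           rounded = rounded))
}

#' Pick the winning width from a table of rounded CV medians
#'
#' Pure selection rule, exposed for protocol-level reuse: maximum rounded
#' median wins and ties break toward the smallest width.
#'
#' @param candidates integer widths.
#' @param rounded_medians their rounded median F1 scores.
#' @return the chosen width.
#' @export
pick_hidden_dim <- function(candidates, rounded_medians) {
  stopifnot(length(candidates) == length(rounded_medians), length(candidates) >= 1)
  min(candidates[rounded_medians == max(rounded_medians)])
}
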