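#' Maxout layer activation
#'
#' A maxout layer computes, for each of its m output units, the maximum
#' over k learned affine transformations of the input:
#' `h_i = max_j (x' W[, i, j] + b[i, j])`. With enough pieces a maxout
#' unit approximates arbitrary convex functions, so the network learns its
#' activation functions along with its weights; k = 1 degenerates to a
#' plain affine map.
#'
#' @param x input: numeric vector of length d, or an n x d matrix of rows.
#' @param params list with `W` (d x m x k array) and `b` (m x k matrix).
#' @return numeric vector of length m (or n x m matrix).
#' @export
maxout_forward <- function(x, params) {
  W <- params$W; b <- params$b
  stopifnot(length(dim(W)) == 3, is.matrix(b),
            dim(W)[2] == nrow(b), dim(W)[3] == ncol(b))
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1) else x
  if (ncol(X) != dim(W)[1]) {
    stop("input dimension ", ncol(X), " != weight dimension ", dim(W)[1])
  }
  H <- maxout_piece_forward(X, W, b)$H
  if (vec_in) drop(H) else H
}

# forward over all k pieces with argmax bookkeeping for backprop
maxout_piece_forward <- function(X, W, b) {
  k <- dim(W)[3]
  piece <- function(j) matrix(W[, , j], dim(W)[1], dim(W)[2])
  H <- sweep(X %*% piece(1), 2, b[, 1], "+")
  amax <- matrix(1L, nrow(H), ncol(H))
  if (k > 1) {
    for (j in 2:k) {
      Zj <- sweep(X %*% piece(j), 2, b[, j], "+")
      upd <- Zj > H
      H[upd] <- Zj[upd]
      amax[upd] <- j
    }
  }
  list(H = H, amax = amax)
}

#' Model configuration for the maxout classifier
#'
#' @param hidden_dims integer vector of hidden layer widths (may be empty:
#'   logistic regression on the similarity rows).
#' @param maxout_units k, the number of affine pieces per maxout unit.
#' @param dropout dropout rate in \[0,1).
#' @param batch_norm apply batch normalization after each maxout layer.
#' @param learning_rate AdaGrad learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early stopping: stop once the validation AUPR has failed
#'   to improve for this many consecutive epochs.
#' @param validation_fraction share of training proteins held out for the
#'   early-stopping metric (0 disables early stopping).
#' @param seed RNG seed controlling initialization, the validation split,
#'   shuffling and dropout masks.
#' @return `model_config` list.
#' @export
model_config <- function(hidden_dims = c(500, 800, 800), maxout_units = 3,
                         dropout = 0.2, batch_norm = TRUE,
                         learning_rate = 0.01, batch_size = 16,
                         max_epochs = 100, patience = 30,
                         validation_fraction = 0.2, seed = 1) {
  stopifnot(all(hidden_dims > 0), maxout_units >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 0,
            patience <= max_epochs,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 maxout_units = as.integer(maxout_units),
                 dropout = dropout, batch_norm = batch_norm,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Published architecture presets
#'
#' `preset_bacteria()` and `preset_eukaryote()` are the architectures used
#' for STRING-scale bacterial and eukaryotic proteome collections: hidden
#' dims \[500, 800, 800\], 3 (bacteria) or 4 (eukaryotes) maxout pieces,
#' dropout 0.2, batch normalization, AdaGrad at learning rate 0.01, batch
#' 16/32, at most 100/300 epochs, patience 30. `preset_compact()` is a
#' small architecture suited to the few-hundred-protein fixtures produced
#' by [simulate_multispecies()].
#'
#' @param seed RNG seed.
#' @return `model_config`.
#' @export
preset_bacteria <- function(seed = 1) {
  model_config(hidden_dims = c(500, 800, 800), maxout_units = 3,
               dropout = 0.2, batch_norm = TRUE, learning_rate = 0.01,
               batch_size = 16, max_epochs = 100, patience = 30,
               seed = seed)
}

#' @rdname preset_bacteria
#' @export
preset_eukaryote <- function(seed = 1) {
  model_config(hidden_dims = c(500, 800, 800), maxout_units = 4,
               dropout = 0.2, batch_norm = TRUE, learning_rate = 0.01,
               batch_size = 32, max_epochs = 300, patience = 30,
               seed = seed)
}

#' @rdname preset_bacteria
#' @export
preset_compact <- function(seed = 1) {
  model_config(hidden_dims = c(128), maxout_units = 3, dropout = 0,
               batch_norm = TRUE, learning_rate = 0.1, batch_size = 16,
               max_epochs = 300, patience = 30, seed = seed)
}

#' Build an untrained maxout network
#'
#' Stack of maxout layers (each followed by batch normalization and
#' dropout when enabled) and a final affine layer with logistic outputs,
#' one per label. Hidden weights use uniform fan-in (Glorot) initialization
#' under the config seed; the output layer starts at zero, so an untrained
#' model scores every label 0.5.
#'
#' @param config a [model_config()].
#' @param input_dim feature dimension (a row of the block S matrix).
#' @param n_labels number of GO terms c.
#' @return `maxout_model` (untrained).
#' @export
build_model <- function(config, input_dim, n_labels) {
  stopifnot(inherits(config, "model_config"), input_dim >= 1, n_labels >= 1)
  set.seed(config$seed)
  k <- config$maxout_units
  dims <- c(input_dim, config$hidden_dims)
  layers <- list()
  if (length(config$hidden_dims) > 0) {
    for (l in seq_along(config$hidden_dims)) {
      d <- dims[l]; m <- dims[l + 1]
      lim <- sqrt(6 / (d + m))
      layers[[l]] <- list(
        W = array(stats::runif(d * m * k, -lim, lim), dim = c(d, m, k)),
        b = matrix(0, m, k),
        gamma = rep(1, m), beta = rep(0, m),
        running_mean = rep(0, m), running_var = rep(1, m)
      )
    }
  }
  last <- dims[length(dims)]
  structure(list(
    layers = layers,
    out = list(W = matrix(0, last, n_labels), b = rep(0, n_labels)),
    config = config, input_dim = input_dim, n_labels = n_labels,
    trained = FALSE, history = NULL, best_epoch = NA_integer_
  ), class = "maxout_model")
}

# forward pass; training = TRUE uses batch statistics and samples dropout
model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  caches <- list()
  H <- X
  bn_eps <- 1e-5
  for (l in seq_along(model$layers)) {
    p <- model$layers[[l]]
    cache <- list(X = H)
    mf <- maxout_piece_forward(H, p$W, p$b)
    H <- mf$H
    cache$amax <- mf$amax
    if (cfg$batch_norm) {
      if (training) {
        mu <- colMeans(H)
        v <- colMeans(H^2) - mu^2
        v[v < 0] <- 0
      } else {
        mu <- p$running_mean
        v <- p$running_var
      }
      inv <- 1 / sqrt(v + bn_eps)
      xhat <- sweep(sweep(H, 2, mu, "-"), 2, inv, "*")
      H <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
      cache$xhat <- xhat; cache$inv <- inv
      cache$mu <- mu; cache$v <- v
    }
    if (training && cfg$dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= cfg$dropout,
                     nrow(H), ncol(H)) / (1 - cfg$dropout)
      H <- H * mask
      cache$mask <- mask
    }
    caches[[l]] <- cache
  }
  logits <- sweep(H %*% model$out$W, 2, model$out$b, "+")
  P <- 1 / (1 + exp(-logits))
  list(P = P, H_last = H, caches = caches)
}

bce_loss <- function(P, Y) {
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

# one minibatch of backprop + AdaGrad updates; returns updated model state
model_backward_update <- function(model, X, Y, fw, opt, lr) {
  n <- nrow(X); c <- ncol(Y)
  cfg <- model$config
  dlogits <- (fw$P - Y) / (n * c)
  grads_out <- list(W = crossprod(fw$H_last, dlogits),
                    b = colSums(dlogits))
  dH <- tcrossprod(dlogits, model$out$W)
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    p <- model$layers[[l]]
    cache <- fw$caches[[l]]
    if (!is.null(cache$mask)) dH <- dH * cache$mask
    if (cfg$batch_norm) {
      dgamma <- colSums(dH * cache$xhat)
      dbeta <- colSums(dH)
      dxhat <- sweep(dH, 2, p$gamma, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dH <- sweep(dxhat - rep(s1, each = n) / n -
                    sweep(cache$xhat, 2, s2, "*") / n,
                  2, cache$inv, "*")
    } else {
      dgamma <- NULL; dbeta <- NULL
    }
    k <- dim(p$W)[3]
    dW <- array(0, dim = dim(p$W))
    db <- matrix(0, nrow(p$b), ncol(p$b))
    dX <- matrix(0, n, dim(p$W)[1])
    Xl <- cache$X
    for (j in seq_len(k)) {
      mj <- cache$amax == j
      if (!any(mj)) next
      dZ <- dH * mj
      dW[, , j] <- crossprod(Xl, dZ)
      db[, j] <- colSums(dZ)
      dX <- dX + tcrossprod(dZ, matrix(p$W[, , j], dim(p$W)[1], dim(p$W)[2]))
    }
    grads[[l]] <- list(W = dW, b = db, gamma = dgamma, beta = dbeta)
    dH <- dX
  }
  # AdaGrad: per-parameter accumulated squared gradients
  adagrad <- function(theta, g, G) {
    G <- G + g^2
    list(theta = theta - lr * g / (sqrt(G) + 1e-8), G = G)
  }
  for (l in seq_along(model$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      up <- adagrad(model$layers[[l]][[nm]], g, opt$layers[[l]][[nm]])
      model$layers[[l]][[nm]] <- up$theta
      opt$layers[[l]][[nm]] <- up$G
    }
  }
  for (nm in c("W", "b")) {
    up <- adagrad(model$out[[nm]], grads_out[[nm]], opt$out[[nm]])
    model$out[[nm]] <- up$theta
    opt$out[[nm]] <- up$G
  }
  list(model = model, opt = opt)
}

#' Train the maxout network
#'
#' Minimizes mean binary cross-entropy over all (protein, term) entries
#' with AdaGrad. A fraction of the training proteins (default 20%) is held
#' out; after every epoch the micro-averaged AUPR on that split is
#' computed, and training stops once it has not improved for `patience`
#' consecutive epochs (or at `max_epochs`), restoring the parameters of
#' the best epoch. Batch-normalization running statistics are updated with
#' momentum 0.9 during training and used at prediction time. All
#' randomness (validation split, shuffling, dropout) flows from the config
#' seed, so training is bit-reproducible on one machine.
#'
#' @param model an untrained [build_model()] output (or a config, in which
#'   case the model is built for the data at hand).
#' @param features numeric matrix, one row per training protein (rows of
#'   the block similarity matrix S).
#' @param labels binary matrix, same row count, one column per GO term.
#' @return `maxout_model` with `trained = TRUE`, per-epoch `history`
#'   (`loss` on the fit split, `val_aupr`) and `best_epoch`.
#' @export
train_maxout <- function(model, features, labels) {
  if (inherits(model, "model_config")) {
    model <- build_model(model, ncol(features), ncol(labels))
  }
  stopifnot(inherits(model, "maxout_model"),
            nrow(features) == nrow(labels),
            ncol(features) == model$input_dim,
            ncol(labels) == model$n_labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  cfg <- model$config
  set.seed(cfg$seed)
  n <- nrow(features)
  n_val <- floor(cfg$validation_fraction * n)
  use_val <- n_val >= 1
  val_idx <- if (use_val) sort(sample.int(n, n_val)) else integer(0)
  fit_idx <- setdiff(seq_len(n), val_idx)
  if (length(fit_idx) == 0) stop("no proteins left to fit after split")
  Xf <- features[fit_idx, , drop = FALSE]
  Yf <- labels[fit_idx, , drop = FALSE]
  Xv <- features[val_idx, , drop = FALSE]
  Yv <- labels[val_idx, , drop = FALSE]
  val_cols <- if (use_val) which(colSums(Yv) > 0) else integer(0)
  if (use_val && length(val_cols) < ncol(Yv)) {
    warning(ncol(Yv) - length(val_cols),
            " all-zero label columns excluded from the early-stopping metric")
  }
  if (use_val && length(val_cols) == 0) {
    warning("validation split has no positive labels; early stopping disabled")
    use_val <- FALSE
  }
  # AdaGrad accumulators mirror the parameter shapes
  opt <- list(
    layers = lapply(model$layers, function(p) list(
      W = array(0, dim = dim(p$W)), b = matrix(0, nrow(p$b), ncol(p$b)),
      gamma = rep(0, length(p$gamma)), beta = rep(0, length(p$beta)))),
    out = list(W = matrix(0, nrow(model$out$W), ncol(model$out$W)),
               b = rep(0, length(model$out$b)))
  )
  bn_momentum <- 0.9
  best_metric <- -Inf
  best_state <- NULL
  best_epoch <- NA_integer_
  since_improve <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_aupr = numeric(0))
  nf <- nrow(Xf)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(nf)
    starts <- seq(1, nf, by = cfg$batch_size)
    for (s in starts) {
      ix <- perm[s:min(s + cfg$batch_size - 1, nf)]
      Xb <- Xf[ix, , drop = FALSE]
      Yb <- Yf[ix, , drop = FALSE]
      fw <- model_forward(model, Xb, training = TRUE)
      # update running batch-norm statistics
      if (cfg$batch_norm) {
        for (l in seq_along(model$layers)) {
          cb <- fw$caches[[l]]
          model$layers[[l]]$running_mean <-
            bn_momentum * model$layers[[l]]$running_mean +
            (1 - bn_momentum) * cb$mu
          model$layers[[l]]$running_var <-
            bn_momentum * model$layers[[l]]$running_var +
            (1 - bn_momentum) * cb$v
        }
      }
      st <- model_backward_update(model, Xb, Yb, fw, opt, cfg$learning_rate)
      model <- st$model
      opt <- st$opt
    }
    fit_loss <- bce_loss(model_forward(model, Xf)$P, Yf)
    val_aupr <- NA_real_
    if (use_val) {
      Pv <- model_forward(model, Xv)$P
      val_aupr <- micro_aupr(Yv[, val_cols, drop = FALSE],
                             Pv[, val_cols, drop = FALSE])
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = fit_loss,
                                         val_aupr = val_aupr))
    if (use_val) {
      if (val_aupr > best_metric) {
        best_metric <- val_aupr
        best_state <- list(layers = model$layers, out = model$out)
        best_epoch <- epoch
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
      }
      if (since_improve >= max(cfg$patience, 1L)) break
    }
  }
  if (!is.null(best_state)) {
    model$layers <- best_state$layers
    model$out <- best_state$out
  } else {
    best_epoch <- nrow(history)
  }
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' Predict GO-term scores
#'
#' @param object a `maxout_model`.
#' @param features matrix of rows in the training feature space.
#' @param ... unused.
#' @return matrix of scores in (0, 1), one row per input row, one column
#'   per label.
#' @export
predict.maxout_model <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != object$input_dim) {
    stop("feature dimension ", ncol(features), " != model input dimension ",
         object$input_dim)
  }
  model_forward(object, features)$P
}

#' @export
print.maxout_model <- function(x, ...) {
  cat("maxout_model:", x$input_dim, "->",
      paste(x$config$hidden_dims, collapse = " -> "), "->", x$n_labels,
      " (k =", x$config$maxout_units, ")\n")
  if (x$trained) {
    cat("  trained,", nrow(x$history), "epochs, best epoch", x$best_epoch, "\n")
  } else cat("  untrained\n")
  invisible(x)
}
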