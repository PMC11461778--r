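#' Hyperparameters for the waiting-time metamodel
#'
#' Architecture and training-process settings of the multilayer-perceptron
#' surrogate.  Defaults are sized for datasets of a few hundred design
#' points; the full-scale configuration of the case study (two hidden layers
#' of 90 ReLU units, Adam with learning rate 1e-5, batch size 4, patience 8,
#' up to 574 epochs) is representable by setting the corresponding fields.
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param activation hidden activation; only `"relu"` is implemented.
#' @param learning_rate Adam step size.
#' @param lr_decay multiplicative per-epoch decay of the learning rate
#'   (1 = constant); values like 0.99 let long runs settle to a precise
#'   fit.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param optimizer only `"adam"` is implemented.
#' @param standardize_x,standardize_y standardize features / target to zero
#'   mean and unit variance (statistics from the training split)?
#' @param augment_days if non-`NULL`, the number of days `n` of a
#'   day-symmetric scenario: the training split is augmented with all
#'   cyclic day rotations of each encoded setting (same target), teaching
#'   the network an invariance the scenario actually has.  Leave `NULL`
#'   for scenarios with day-of-week structure.  The validation split is
#'   never augmented.
#' @return an object of class `mlp_hyperparams`.
#' @export
mlp_hyperparams <- function(hidden = c(64L, 64L), activation = "relu",
                            learning_rate = 1e-3, batch_size = 16L,
                            max_epochs = 200L, patience = 8L,
                            optimizer = "adam", standardize_x = TRUE,
                            standardize_y = TRUE, augment_days = NULL,
                            lr_decay = 1) {
  if (!length(hidden) || any(hidden < 1) || !is_wholenumber(hidden))
    stopf("hidden sizes must be positive integers")
  if (!identical(activation, "relu")) stopf("only relu activation supported")
  if (!identical(optimizer, "adam")) stopf("only the adam optimizer supported")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stopf("learning_rate must be positive")
  if (!is_count(batch_size) || batch_size < 1)
    stopf("batch_size must be a positive integer")
  if (!is_count(max_epochs) || max_epochs < 1)
    stopf("max_epochs must be a positive integer")
  if (!is_count(patience) || patience < 1)
    stopf("patience must be a positive integer")
  if (!is.null(augment_days) &&
      (!is_count(augment_days) || augment_days < 2))
    stopf("augment_days must be an integer >= 2 or NULL")
  if (!is.numeric(lr_decay) || lr_decay <= 0 || lr_decay > 1)
    stopf("lr_decay must lie in (0, 1]")
  structure(list(hidden = as.integer(hidden), activation = activation,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 standardize_x = isTRUE(standardize_x),
                 standardize_y = isTRUE(standardize_y),
                 augment_days = if (!is.null(augment_days))
                   as.integer(augment_days),
                 lr_decay = as.double(lr_decay)),
            class = "mlp_hyperparams")
}

mlp_forward <- function(W, b, A) {
  L <- length(W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% W[[l]], 2, b[[l]], "+")
    if (l < L) A <- pmax(A, 0)
  }
  A
}

# forward pass keeping pre-activations, for backprop
mlp_forward_cache <- function(W, b, A) {
  L <- length(W)
  Z <- vector("list", L)
  As <- vector("list", L + 1)
  As[[1]] <- A
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(As[[l]] %*% W[[l]], 2, b[[l]], "+")
    As[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(Z = Z, A = As)
}

#' Train the MLP surrogate of the waiting-time objective
#'
#' Fits a fully-connected ReLU network to the encoded-setting / simulated
#' DTDT pairs of a dataset by mini-batch Adam on the mean squared error,
#' with early stopping on the mean absolute error of a held-out validation
#' split (a seed-derived fraction of the data).  Features and target are
#' standardized with training-split statistics.  Training is fully
#' deterministic given `seed`.
#'
#' @param ds a `miu_dataset` (or any list with matrix `V` and vector `w`).
#' @param hp an [mlp_hyperparams()].
#' @param seed integer seed controlling the split, initialization and batch
#'   shuffling.
#' @param val_fraction fraction of rows held out for early stopping.
#' @return an object of class `mlp_metamodel`: layer weights, scalers, and
#'   a per-epoch training report (`$report`).
#' @seealso [predict_f1()], [grad_f1()], [kfold_random_search()]
#' @export
train_mlp <- function(ds, hp = mlp_hyperparams(), seed = 1L,
                      val_fraction = 0.1) {
  X <- as.matrix(ds$V)
  y <- as.numeric(ds$w)
  p <- nrow(X)
  if (p < 2) stopf("need at least 2 design points to train")
  m <- ncol(X)

  set.seed(mix_seed(seed, 1))
  n_val <- max(1L, floor(p * val_fraction))
  if (n_val >= p) n_val <- p - 1L
  val_idx <- sample.int(p, n_val)
  tr_idx <- setdiff(seq_len(p), val_idx)

  Xtr <- X[tr_idx, , drop = FALSE]
  ytr <- y[tr_idx]
  if (!is.null(hp$augment_days)) {
    nd <- hp$augment_days
    if (m < 2L * nd)
      stopf("augment_days = %d needs at least %d features", nd, 2L * nd)
    rots <- lapply(seq_len(nd) - 1L, function(k) {
      pp <- ((seq_len(nd) - 1L + k) %% nd) + 1L
      c(pp, nd + pp, if (m > 2L * nd) (2L * nd + 1L):m)
    })
    Xtr <- do.call(rbind, lapply(rots, function(ix)
      Xtr[, ix, drop = FALSE]))
    ytr <- rep(ytr, nd)
  }

  xc <- if (hp$standardize_x) unname(colMeans(Xtr)) else rep(0, m)
  xs <- if (hp$standardize_x) unname(apply(Xtr, 2, sd)) else rep(1, m)
  xs[!is.finite(xs) | xs == 0] <- 1
  yc <- if (hp$standardize_y) mean(ytr) else 0
  ys <- if (hp$standardize_y) sd(ytr) else 1
  if (!is.finite(ys) || ys == 0) ys <- 1

  Xtr_s <- sweep(sweep(Xtr, 2, xc), 2, xs, "/")
  ytr_s <- (ytr - yc) / ys
  Xval_s <- sweep(sweep(X[val_idx, , drop = FALSE], 2, xc), 2, xs, "/")
  yval_s <- (y[val_idx] - yc) / ys
  dimnames(Xtr_s) <- NULL
  dimnames(Xval_s) <- NULL

  dims <- c(m, hp$hidden, 1L)
  L <- length(dims) - 1L
  set.seed(mix_seed(seed, 2))
  W <- lapply(seq_len(L), function(l)
    matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
           dims[l], dims[l + 1]))
  b <- lapply(seq_len(L), function(l) rep(0, dims[l + 1]))

  # Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0

  mae_tr <- function() {
    pred <- mlp_forward(W, b, Xtr_s)
    mean(abs(pred - ytr_s)) * ys
  }
  mae_val <- function() {
    pred <- mlp_forward(W, b, Xval_s)
    mean(abs(pred - yval_s)) * ys
  }

  best <- list(val = Inf, W = W, b = b, epoch = 0L)
  wait <- 0L
  report <- vector("list", hp$max_epochs)
  n_tr <- nrow(Xtr_s)

  lr <- hp$learning_rate
  for (epoch in seq_len(hp$max_epochs)) {
    set.seed(mix_seed(seed, 100L + epoch))
    ord <- sample.int(n_tr)
    nb <- ceiling(length(ord) / hp$batch_size)
    for (bi in seq_len(nb)) {
      rows <- ord[((bi - 1) * hp$batch_size + 1):min(bi * hp$batch_size,
                                                     length(ord))]
      A0 <- Xtr_s[rows, , drop = FALSE]
      fc <- mlp_forward_cache(W, b, A0)
      err <- fc$A[[L + 1]] - ytr_s[rows]
      if (any(!is.finite(err)))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      delta <- 2 * err / length(rows)      # d MSE / d z_L
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(fc$A[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (fc$Z[[l - 1]] >= 0)
      }
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    lr <- lr * hp$lr_decay
    tm <- mae_tr(); vm <- mae_val()
    if (!is.finite(tm) || !is.finite(vm))
      stopf("training diverged (non-finite loss) at epoch %d", epoch)
    report[[epoch]] <- c(epoch = epoch, train_mae = tm, val_mae = vm)
    if (vm < best$val - 1e-12) {
      best <- list(val = vm, W = W, b = b, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }

  structure(list(
    W = best$W, b = best$b, activation = hp$activation,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    feature_names = colnames(X),
    report = as.data.frame(do.call(rbind, report[!vapply(report, is.null,
                                                         logical(1))])),
    best_epoch = best$epoch, hp = hp, seed = as.integer(seed)
  ), class = "mlp_metamodel")
}

#' Evaluate the surrogate waiting-time objective
#'
#' `predict_f1` computes the surrogate value (minutes) at an encoded
#' setting; `grad_f1` computes its gradient with respect to each decision
#' variable (minutes per hour, or per percentage point for the diversion
#' variables) by backpropagation through the full
#' standardize-network-destandardize map.  At a ReLU kink the right
#' derivative is used.  Both are S3 generics so that stub surrogates (see
#' [fn_surrogate()]) can stand in for a trained network in optimizer tests.
#'
#' @param m a trained surrogate (`mlp_metamodel` or `fn_surrogate`).
#' @param v numeric feature vector (for `predict_f1`, a matrix of row
#'   vectors is also accepted).
#' @return `predict_f1`: value(s) in minutes; `grad_f1`: gradient vector.
#' @export
predict_f1 <- function(m, v) UseMethod("predict_f1")

#' @rdname predict_f1
#' @export
grad_f1 <- function(m, v) UseMethod("grad_f1")

check_feature_length <- function(m, v) {
  if (NCOL(v) != length(m$x_center) && length(v) != length(m$x_center))
    stopf("feature vector has length %d, model expects %d",
          if (is.matrix(v)) ncol(v) else length(v), length(m$x_center))
}

#' @export
predict_f1.mlp_metamodel <- function(m, v) {
  single <- !is.matrix(v)
  if (single) v <- matrix(v, 1)
  if (ncol(v) != length(m$x_center))
    stopf("feature vector has length %d, model expects %d", ncol(v),
          length(m$x_center))
  A <- sweep(sweep(v, 2, m$x_center), 2, m$x_scale, "/")
  out <- mlp_forward(m$W, m$b, A) * m$y_scale + m$y_center
  if (single) drop(out) else drop(out)
}

#' @export
grad_f1.mlp_metamodel <- function(m, v) {
  single <- !is.matrix(v)
  if (single) v <- matrix(v, 1)
  if (ncol(v) != length(m$x_center))
    stopf("feature vector has length %d, model expects %d", ncol(v),
          length(m$x_center))
  A0 <- sweep(sweep(v, 2, m$x_center), 2, m$x_scale, "/")
  fc <- mlp_forward_cache(m$W, m$b, A0)
  L <- length(m$W)
  delta <- matrix(1, nrow(v), 1)
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (fc$Z[[l]] >= 0)
    delta <- delta %*% t(m$W[[l]])
  }
  G <- sweep(delta, 2, m$x_scale, "/") * m$y_scale
  if (single) drop(G) else G
}

#' @export
predict.mlp_metamodel <- function(object, newdata, ...) {
  predict_f1(object, newdata)
}

#' @export
print.mlp_metamodel <- function(x, ...) {
  dims <- c(length(x$x_center), vapply(x$W, ncol, integer(1)))
  cat("MLP waiting-time surrogate:",
      paste(dims, collapse = "-"), "(ReLU)\n")
  if (nrow(x$report)) {
    cat(sprintf("  trained %d epoch(s); best validation MAE %.3f min at epoch %d\n",
                max(x$report$epoch), min(x$report$val_mae), x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.mlp_metamodel <- function(object, ...) {
  list(architecture = c(length(object$x_center),
                        vapply(object$W, ncol, integer(1))),
       n_parameters = sum(vapply(object$W, length, integer(1))) +
         sum(vapply(object$b, length, integer(1))),
       best_epoch = object$best_epoch,
       best_val_mae = if (nrow(object$report)) min(object$report$val_mae)
       else NA_real_,
       hyperparams = object$hp)
}

#' Function-backed surrogate
#'
#' Wraps an analytic function (and optionally its gradient) in the
#' surrogate interface used by the optimizers, for validation against
#' objectives with known minimizers.
#'
#' @param fn function of an encoded setting vector returning a scalar.
#' @param grad optional gradient function; if `NULL`, central finite
#'   differences are used.
#' @return an object of class `fn_surrogate`.
#' @export
fn_surrogate <- function(fn, grad = NULL) {
  structure(list(fn = fn, grad = grad), class = "fn_surrogate")
}

#' @export
predict_f1.fn_surrogate <- function(m, v) {
  if (is.matrix(v)) apply(v, 1, m$fn) else m$fn(v)
}

#' @export
grad_f1.fn_surrogate <- function(m, v) {
  if (!is.null(m$grad)) return(m$grad(v))
  h <- 1e-5
  vapply(seq_along(v), function(i) {
    e <- replace(numeric(length(v)), i, h)
    (m$fn(v + e) - m$fn(v - e)) / (2 * h)
  }, numeric(1))
}

#' Symmetrize a surrogate over cyclic day rotations
#'
#' For scenarios whose arrival profile and room schedules are identical on
#' every day of the week (as in the shipped case-study fixture), the true
#' waiting-time response is invariant under a cyclic rotation of the days
#' of a setting.  Averaging the surrogate over all rotations of its input
#' is then an exact-in-expectation variance reduction: it cancels
#' day-pattern fitting noise without touching the trained network.  Use it
#' only when the scenario actually has this symmetry.
#'
#' @param m a trained surrogate for encodings of the form
#'   `(x_1..x_n, y_1..y_n, z_1..z_k)` (fixed rooms).
#' @param n_days number of days in the planning period.
#' @return an [fn_surrogate()] evaluating the rotation-averaged value and
#'   gradient.
#' @export
symmetrize_surrogate <- function(m, n_days = 7L) {
  n <- as.integer(n_days)
  rots_for <- function(len) {
    if (len < 2L * n)
      stopf("feature vector of length %d cannot hold 2 x %d day variables",
            len, n)
    lapply(seq_len(n) - 1L, function(k) {
      p <- ((seq_len(n) - 1L + k) %% n) + 1L
      c(p, n + p, if (len > 2L * n) (2L * n + 1L):len)
    })
  }
  rot_matrix <- function(v, rots)
    do.call(rbind, lapply(rots, function(ix) v[ix]))
  fn_surrogate(
    fn = function(v) {
      rots <- rots_for(length(v))
      mean(predict_f1(m, rot_matrix(v, rots)))
    },
    grad = function(v) {
      rots <- rots_for(length(v))
      G <- grad_f1(m, rot_matrix(v, rots))
      g <- numeric(length(v))
      for (i in seq_along(rots)) g[rots[[i]]] <- g[rots[[i]]] + G[i, ]
      g / length(rots)
    })
}

#' K-fold random hyperparameter search
#'
#' Samples `n_candidates` hyperparameter configurations uniformly from a
#' discrete search space and scores each by K-fold cross-validated mean
#' absolute error, returning the configuration with the minimum mean MAE.
#'
#' @param ds a `miu_dataset`.
#' @param space named list; each entry is a list of candidate values for
#'   the corresponding [mlp_hyperparams()] argument.
#' @param K number of folds (default 5).
#' @param n_candidates number of sampled configurations.
#' @param seed integer seed.
#' @return list with `best` (an `mlp_hyperparams`), `scores` (per-candidate
#'   mean CV MAE) and `candidates`.
#' @export
kfold_random_search <- function(ds, space, K = 5L, n_candidates = 10L,
                                seed = 1L) {
  if (!length(space)) stopf("empty hyperparameter search space")
  if (!is_count(K) || K < 2) stopf("K must be an integer >= 2")
  if (!is_count(n_candidates) || n_candidates < 1)
    stopf("n_candidates must be a positive integer")
  bad <- names(space)[!vapply(space, function(x)
    is.list(x) && length(x) > 0, logical(1))]
  if (length(bad))
    stopf("search-space entries must be non-empty lists of values: %s",
          paste(bad, collapse = ", "))
  p <- nrow(ds$V)
  if (p < K) stopf("need at least K = %d design points", K)

  set.seed(mix_seed(seed, 1))
  candidates <- lapply(seq_len(n_candidates), function(i)
    lapply(space, function(vals) vals[[sample.int(length(vals), 1)]]))
  fold <- sample(rep_len(seq_len(K), p))

  scores <- vapply(seq_along(candidates), function(ci) {
    hp <- do.call(mlp_hyperparams, candidates[[ci]])
    fold_mae <- vapply(seq_len(K), function(k) {
      tr <- fold != k
      sub <- list(V = ds$V[tr, , drop = FALSE], w = ds$w[tr])
      fit <- train_mlp(sub, hp, seed = mix_seed(seed, 1000L + ci * K + k))
      pred <- predict_f1(fit, ds$V[!tr, , drop = FALSE])
      mean(abs(pred - ds$w[!tr]))
    }, numeric(1))
    mean(fold_mae)
  }, numeric(1))

  best_i <- which.min(scores)
  list(best = do.call(mlp_hyperparams, candidates[[best_i]]),
       scores = scores, candidates = candidates)
}

#' Persist and load a trained surrogate
#'
#' The model is stored as a flat JSON document (architecture, weights,
#' scalers) and can be reloaded without the training code path.
#'
#' @param m an `mlp_metamodel`.
#' @param path JSON file path.
#' @return `load_metamodel` returns the `mlp_metamodel`; the writer returns
#'   `path` invisibly.
#' @export
save_metamodel <- function(m, path) {
  doc <- list(
    type = "mlp_metamodel",
    activation = m$activation,
    dims = c(length(m$x_center), vapply(m$W, ncol, integer(1))),
    W = lapply(m$W, function(w) list(nrow = nrow(w), ncol = ncol(w),
                                     data = as.vector(w))),
    b = m$b,
    x_center = m$x_center, x_scale = m$x_scale,
    y_center = m$y_center, y_scale = m$y_scale,
    feature_names = m$feature_names,
    best_epoch = m$best_epoch
  )
  write_json_file(doc, path)
  invisible(path)
}

#' @rdname save_metamodel
#' @export
load_metamodel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$type, "mlp_metamodel"))
    stopf("'%s' is not a saved metamodel", path)
  W <- lapply(doc$W, function(w)
    matrix(as.numeric(unlist(w$data)), w$nrow, w$ncol))
  structure(list(
    W = W, b = lapply(doc$b, function(x) as.numeric(unlist(x))),
    activation = doc$activation,
    x_center = as.numeric(unlist(doc$x_center)),
    x_scale = as.numeric(unlist(doc$x_scale)),
    y_center = doc$y_center, y_scale = doc$y_scale,
    feature_names = as.character(unlist(doc$feature_names)),
    report = data.frame(epoch = integer(), train_mae = numeric(),
                        val_mae = numeric()),
    best_epoch = doc$best_epoch, hp = NULL, seed = NA_integer_
  ), class = "mlp_metamodel")
}
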