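#' Training configuration
#'
#' Hyperparameters of the stochastic-gradient-descent training recipe: the
#' initial learning rate is 0.1 and is halved whenever the epoch loss fails
#' to improve for `halve_patience` consecutive epochs (see [lr_schedule()]).
#' Batch normalization precedes every nonlinearity and dropout (p = 0.5 by
#' default, set on the network spec) regularizes the dense layers.
#'
#' @param lr0 Initial learning rate.
#' @param halve_patience Epochs without improvement before halving.
#' @param batch_size Minibatch size.
#' @param max_epochs Number of training epochs.
#' @param seed RNG seed controlling initialization, shuffling and dropout;
#'   fixing it makes training exactly reproducible.
#' @param bn_momentum Running-statistics momentum of batch normalization.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr0 = 0.1, halve_patience = 10L, batch_size = 32L,
                            max_epochs = 30L, seed = 1L, bn_momentum = 0.9) {
  stopifnot(lr0 > 0, halve_patience >= 1)
  structure(list(lr0 = lr0, halve_patience = as.integer(halve_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 bn_momentum = bn_momentum),
            class = "training_config")
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

init_params <- function(spec) {
  shp <- c(spec$input_shape, 1L)
  flat <- FALSE
  params <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      fan_in <- prod(ly$kernel) * shp[4]
      params[[i]] <- list(W = he_uniform(c(ly$kernel, shp[4], ly$n), fan_in),
                          b = numeric(ly$n))
      shp[1:3] <- shp[1:3] + 2L * ly$pad - ly$kernel + 1L
      shp[4] <- ly$n
    } else if (ly$type == "pool") {
      shp[1] <- as.integer(ceiling(shp[1] / ly$s))
    } else if (ly$type == "flatten") {
      shp <- prod(shp); flat <- TRUE
    } else if (ly$type == "dense") {
      n_in <- shp
      params[[i]] <- list(W = matrix(runif(ly$n * n_in, -sqrt(6 / n_in), sqrt(6 / n_in)),
                                     ly$n, n_in),
                          b = numeric(ly$n))
      shp <- ly$n
    } else if (ly$type == "batchnorm") {
      nch <- if (flat) shp else shp[4]
      params[[i]] <- list(gamma = rep(1, nch), beta = numeric(nch),
                          run_mean = numeric(nch), run_var = rep(1, nch))
    }
  }
  params
}

# batchnorm over a channels x m matrix (channels are rows)
bn_fwd_mat <- function(xm, p, training, momentum, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * v
  } else {
    mu <- p$run_mean; v <- p$run_var
    xc <- xm - mu
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- xc * ivar
  list(y = xhat * p$gamma + p$beta, xhat = xhat, ivar = ivar, p = p)
}

bn_bwd_mat <- function(gy, cache, gamma) {
  m <- ncol(gy)
  ggamma <- rowSums(gy * cache$xhat)
  gbeta <- rowSums(gy)
  gxhat <- gy * gamma
  gx <- (cache$ivar / m) * (m * gxhat - rowSums(gxhat) - cache$xhat * rowSums(gxhat * cache$xhat))
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

net_forward <- function(spec, params, x5, training, momentum = 0.9) {
  caches <- vector("list", length(spec$layers))
  a <- x5  # 5D array until flatten, then (features x batch) matrix
  flat <- FALSE
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      caches[[i]] <- list(x = a)
      a <- conv3d_forward_cpp(a, params[[i]]$W, params[[i]]$b, ly$pad)
    } else if (ly$type == "batchnorm") {
      if (flat) {
        r <- bn_fwd_mat(a, params[[i]], training, momentum)
        params[[i]] <- r$p
        caches[[i]] <- r
        a <- r$y
      } else {
        r <- bn5d_forward_cpp(a, params[[i]]$gamma, params[[i]]$beta,
                              params[[i]]$run_mean, params[[i]]$run_var,
                              training, momentum, 1e-5)
        if (training) {
          params[[i]]$run_mean <- r$run_mean
          params[[i]]$run_var <- r$run_var
        }
        caches[[i]] <- list(xhat = r$xhat, ivar = r$ivar)
        a <- r$y
      }
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = a > 0)
      a <- a * caches[[i]]$mask
    } else if (ly$type == "pool") {
      r <- pool_t_forward_cpp(a, ly$s)
      caches[[i]] <- list(idx = r$idx, l_in = dim(a)[1])
      a <- r$y
    } else if (ly$type == "flatten") {
      d <- dim(a)
      caches[[i]] <- list(d = d)
      a <- matrix(a, nrow = prod(d[1:4]))
      flat <- TRUE
    } else if (ly$type == "dense") {
      caches[[i]] <- list(x = a)
      a <- params[[i]]$W %*% a + params[[i]]$b
    } else if (ly$type == "dropout") {
      if (training) {
        mask <- matrix((runif(length(a)) >= ly$p) / (1 - ly$p), nrow = nrow(a))
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      }
    } else if (ly$type == "softmax") {
      z <- a - rep(apply(a, 2, max), each = nrow(a))
      e <- exp(z)
      a <- e / rep(colSums(e), each = nrow(a))
    }
  }
  list(probs = a, caches = caches, params = params)
}

net_backward <- function(spec, params, caches, probs, labels1) {
  n <- ncol(probs)
  g <- probs
  g[cbind(labels1, seq_len(n))] <- g[cbind(labels1, seq_len(n))] - 1
  g <- g / n
  grads <- vector("list", length(spec$layers))
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$type == "softmax") {
      # gradient of cross-entropy wrt logits already formed
    } else if (ly$type == "dense") {
      grads[[i]] <- list(W = g %*% t(caches[[i]]$x), b = rowSums(g))
      g <- t(params[[i]]$W) %*% g
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) g <- g * caches[[i]]$mask
    } else if (ly$type == "flatten") {
      g <- array(g, dim = caches[[i]]$d)
    } else if (ly$type == "pool") {
      g <- pool_t_backward_cpp(caches[[i]]$idx, g, caches[[i]]$l_in)
    } else if (ly$type == "relu") {
      g <- g * caches[[i]]$mask
    } else if (ly$type == "batchnorm") {
      if (is.matrix(g)) {
        r <- bn_bwd_mat(g, caches[[i]], params[[i]]$gamma)
        g <- r$gx
      } else {
        r <- bn5d_backward_cpp(g, caches[[i]]$xhat, caches[[i]]$ivar,
                               params[[i]]$gamma)
        g <- r$gx
      }
      grads[[i]] <- list(gamma = r$ggamma, beta = r$gbeta)
    } else if (ly$type == "conv") {
      r <- conv3d_backward_cpp(caches[[i]]$x, params[[i]]$W, g, ly$pad)
      grads[[i]] <- list(W = r$gw, b = r$gb)
      g <- r$gx
    }
  }
  grads
}

sgd_update <- function(params, grads, lr) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]]))
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * grads[[i]][[nm]]
  }
  params
}

as_input5 <- function(cubes) {
  d <- dim(cubes)
  dim(cubes) <- c(d[1], d[2], d[3], 1L, d[4])
  cubes
}

#' Train a gesture-classification network
#'
#' Minibatch stochastic gradient descent on the categorical cross-entropy of
#' the G-way softmax output. Weights use variance-scaled uniform
#' initialization; batch normalization precedes each ReLU; dropout is applied
#' where the spec places it; the learning rate follows the plateau-halving
#' schedule. Training is exactly reproducible given `cfg$seed`.
#'
#' @param spec A `network_spec` from [build_3d_cnn()] or [build_2d_cnn()].
#' @param train_set A [cube_dataset()] whose cube shape matches
#'   `spec$input_shape` and whose labels lie in `[0, G)`.
#' @param cfg A [training_config()].
#' @param verbose Print per-epoch loss.
#' @return An object of class `emg_model` with the trained parameters, the
#'   per-epoch `loss_history` and `lr_history`, and any training warnings.
#' @export
fit_network <- function(spec, train_set, cfg = training_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(train_set, "cube_dataset"))
  d <- dim(train_set$cubes)
  if (!all(d[1:3] == spec$input_shape))
    stop(sprintf("cube shape %s does not match spec input %s",
                 paste(d[1:3], collapse = "x"),
                 paste(spec$input_shape, collapse = "x")))
  labels <- train_set$labels
  if (any(labels < 0L | labels >= spec$G))
    stop("labels must lie in [0, G)")
  run_log <- character(0)
  missing_cls <- setdiff(0:(spec$G - 1L), unique(labels))
  if (length(missing_cls)) {
    msg <- paste("class absent from training data:",
                 paste(missing_cls, collapse = ", "))
    warning(msg)
    run_log <- c(run_log, msg)
  }
  set.seed(cfg$seed)
  params <- init_params(spec)
  x5 <- as_input5(train_set$cubes)
  n <- d[4]
  lr <- cfg$lr0
  best <- Inf; wait <- 0L
  loss_history <- numeric(0)
  lr_history <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      xb <- x5[, , , , b, drop = FALSE]
      fw <- net_forward(spec, params, xb, training = TRUE, momentum = cfg$bn_momentum)
      params <- fw$params
      lab1 <- labels[b] + 1L
      p_true <- fw$probs[cbind(lab1, seq_along(b))]
      loss <- -mean(log(pmax(p_true, 1e-12)))
      ep_loss <- ep_loss + loss * length(b)
      grads <- net_backward(spec, params, fw$caches, fw$probs, lab1)
      params <- sgd_update(params, grads, lr)
    }
    ep_loss <- ep_loss / n
    loss_history <- c(loss_history, ep_loss)
    lr_history <- c(lr_history, lr)
    if (verbose) cat(sprintf("epoch %3d  loss %.4f  lr %.4g\n", epoch, ep_loss, lr))
    # plateau halving with reset, matching lr_schedule() on the window since
    # the last improvement or halving
    if (ep_loss < best) { best <- ep_loss; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= cfg$halve_patience) { lr <- lr / 2; wait <- 0L; best <- ep_loss }
    }
  }
  structure(list(spec = spec, params = params, cfg = cfg,
                 loss_history = loss_history, lr_history = lr_history,
                 run_log = run_log),
            class = "emg_model")
}

#' @export
print.emg_model <- function(x, ...) {
  cat(sprintf("<emg_model> %dD CNN, %d classes, %d epochs, final loss %.4f\n",
              x$spec$dims, x$spec$G, length(x$loss_history),
              tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict gesture classes for cubes
#'
#' Runs the network in inference mode (batch-normalization running statistics,
#' no dropout). Each cube receives a probability vector over the G classes
#' (nonnegative, summing to one) and the label of maximal probability; exact
#' ties resolve to the smallest class index.
#'
#' @param object A trained `emg_model`.
#' @param cubes A [cube_dataset()] or bare `l x h x w x n` array matching the
#'   spec input shape.
#' @param batch Internal evaluation batch size.
#' @param ... Unused.
#' @return List with `labels` (0-based integer vector) and `probs`
#'   (`n x G` matrix).
#' @export
predict.emg_model <- function(object, cubes, batch = 256L, ...) {
  arr <- if (inherits(cubes, "cube_dataset")) cubes$cubes else cubes
  d <- dim(arr)
  if (length(d) == 3) dim(arr) <- c(d, 1L)
  d <- dim(arr)
  if (!all(d[1:3] == object$spec$input_shape))
    stop(sprintf("cube shape %s does not match model input %s",
                 paste(d[1:3], collapse = "x"),
                 paste(object$spec$input_shape, collapse = "x")))
  x5 <- as_input5(arr)
  n <- d[4]
  probs <- matrix(0, n, object$spec$G)
  for (s in seq(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    fw <- net_forward(object$spec, object$params, x5[, , , , s:e, drop = FALSE],
                      training = FALSE)
    probs[s:e, ] <- t(fw$probs)
  }
  labels <- max.col(probs, ties.method = "first") - 1L
  list(labels = labels, probs = probs)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file of the model object plus a JSON metadata
#' sidecar recording the input shape, class count, seed and epoch count.
#'
#' @param model An `emg_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or an `emg_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(input_shape = model$spec$input_shape, G = model$spec$G,
               dims = model$spec$dims, seed = model$cfg$seed,
               epochs = length(model$loss_history))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
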