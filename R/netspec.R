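#' Declarative network specification
#'
#' A `network_spec` is an ordered layer list from which both the trainable
#' model ([fit_network()]) and the analytic parameter count
#' ([count_parameters()]) are derived. Layers are plain lists with a `type`
#' field; supported types are `conv` (3D convolution, stride 1x1x1, zero
#' padding triple), `batchnorm`, `relu`, `pool` (temporal max pooling
#' `s x 1 x 1`), `flatten`, `dense`, `dropout`, `softmax`. 2D networks are
#' represented as degenerate 3D networks with a singleton temporal dimension.
#'
#' @name network_spec
NULL

new_network_spec <- function(input_shape, layers, G, dims = 3L) {
  spec <- structure(list(input_shape = as.integer(input_shape),
                         layers = layers, G = as.integer(G),
                         dims = as.integer(dims)),
                    class = "network_spec")
  propagate_shapes(spec)  # validates
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %dD input %s -> %d classes, %d layers, %s parameters\n",
              x$dims, paste(x$input_shape, collapse = " x "), x$G,
              length(x$layers), format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Propagate activation shapes through a network spec
#'
#' Computes the `(l, h, w, channels)` shape after every layer. Valid-mode
#' convolution shrinks each dimension by `kernel - 1` less twice the padding;
#' temporal pooling uses ceiling semantics with a boundary-truncated final
#' window (so a temporal extent of 1 survives a pooling layer).
#'
#' @param spec A `network_spec`.
#' @return List of integer shape vectors, one per layer; an error if any
#'   dimension collapses below 1.
#' @export
propagate_shapes <- function(spec) {
  shp <- c(spec$input_shape, 1L)  # (l, h, w, channels)
  flat <- FALSE
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      if (flat) stop("conv after flatten")
      shp[1:3] <- shp[1:3] + 2L * ly$pad - ly$kernel + 1L
      if (any(shp[1:3] < 1L))
        stop(sprintf("layer %d (conv): dimension collapses to %s",
                     i, paste(shp[1:3], collapse = " x ")))
      shp[4] <- ly$n
    } else if (ly$type == "pool") {
      shp[1] <- as.integer(ceiling(shp[1] / ly$s))
    } else if (ly$type == "flatten") {
      shp <- prod(shp); flat <- TRUE
    } else if (ly$type == "dense") {
      if (!flat) stop("dense before flatten")
      shp <- ly$n
    }
    out[[i]] <- shp
  }
  out
}

conv_layer <- function(n, kernel, pad) {
  list(type = "conv", n = as.integer(n), kernel = as.integer(kernel),
       pad = as.integer(pad))
}

bn_relu <- function() list(list(type = "batchnorm"), list(type = "relu"))

#' Build the 3D CNN gesture classifier
#'
#' Constructs the spatiotemporal classifier: three 3D convolutional layers of
#' 3 x 3 x 3 kernels (32, 64, 64 kernels by default) with stride 1 x 1 x 1,
#' zero padding 0 x 1 x 1 on the second and third convolutions each followed
#' by a temporal pooling layer of size `pool_s` x 1 x 1, then two fully
#' connected layers (512 and 128 units by default) and a G-way softmax. Every
#' convolution and dense layer is followed by batch normalization and ReLU,
#' except the output layer; dropout (p = 0.5) follows both hidden dense
#' layers.
#'
#' @param input_shape Integer `(l, h, w)`: cube length and image size, e.g.
#'   `c(10, 8, 16)` for CapgMyo-style data or `c(20, 7, 24)` for CSL-style.
#' @param pool_s Temporal pooling size (2 for 1000 Hz grids, 4 for 2048 Hz).
#' @param G Number of gesture classes.
#' @param n_kernels Kernel counts of the three convolutions.
#' @param fc Unit counts of the two hidden dense layers.
#' @param dropout_p Dropout probability on the hidden dense layers.
#' @return A `network_spec`; an error if the temporal dimension collapses.
#' @examples
#' spec <- build_3d_cnn(c(10, 8, 16), pool_s = 2, G = 8)
#' count_parameters(spec)
#' @export
build_3d_cnn <- function(input_shape, pool_s, G, n_kernels = c(32, 64, 64),
                         fc = c(512, 128), dropout_p = 0.5) {
  stopifnot(length(input_shape) == 3, length(n_kernels) == 3, length(fc) == 2)
  layers <- c(
    list(conv_layer(n_kernels[1], c(3, 3, 3), c(0, 0, 0))), bn_relu(),
    list(conv_layer(n_kernels[2], c(3, 3, 3), c(0, 1, 1))), bn_relu(),
    list(list(type = "pool", s = as.integer(pool_s))),
    list(conv_layer(n_kernels[3], c(3, 3, 3), c(0, 1, 1))), bn_relu(),
    list(list(type = "pool", s = as.integer(pool_s))),
    list(list(type = "flatten")),
    list(list(type = "dense", n = as.integer(fc[1]))), bn_relu(),
    list(list(type = "dropout", p = dropout_p)),
    list(list(type = "dense", n = as.integer(fc[2]))), bn_relu(),
    list(list(type = "dropout", p = dropout_p)),
    list(list(type = "dense", n = as.integer(G))),
    list(list(type = "softmax"))
  )
  new_network_spec(input_shape, layers, G, dims = 3L)
}

#' Build the 2D CNN ablation
#'
#' The same architecture as [build_3d_cnn()] with the temporal dimension of
#' kernels, padding and pooling removed: three 3 x 3 convolutions over a
#' single instantaneous image, spatial padding 1 x 1 on the second and third,
#' pooling degenerate (omitted), then the same dense stack. It classifies
#' individual frames; temporal context is recovered only through majority
#' voting over consecutive frame predictions.
#'
#' @param input_shape Integer `(h, w)` image size.
#' @inheritParams build_3d_cnn
#' @return A `network_spec` with a singleton temporal dimension.
#' @export
build_2d_cnn <- function(input_shape, G, n_kernels = c(32, 64, 64),
                         fc = c(512, 128), dropout_p = 0.5) {
  stopifnot(length(input_shape) == 2)
  layers <- c(
    list(conv_layer(n_kernels[1], c(1, 3, 3), c(0, 0, 0))), bn_relu(),
    list(conv_layer(n_kernels[2], c(1, 3, 3), c(0, 1, 1))), bn_relu(),
    list(conv_layer(n_kernels[3], c(1, 3, 3), c(0, 1, 1))), bn_relu(),
    list(list(type = "flatten")),
    list(list(type = "dense", n = as.integer(fc[1]))), bn_relu(),
    list(list(type = "dropout", p = dropout_p)),
    list(list(type = "dense", n = as.integer(fc[2]))), bn_relu(),
    list(list(type = "dropout", p = dropout_p)),
    list(list(type = "dense", n = as.integer(G))),
    list(list(type = "softmax"))
  )
  spec <- new_network_spec(c(1L, input_shape), layers, G, dims = 2L)
  spec
}

#' Analytic count of network parameters
#'
#' Counts learnable parameters layer by layer: a convolution with `n` kernels
#' of volume `v` over `m` input maps contributes `n * (v * m + 1)`; a dense
#' layer `n_in * n_out + n_out`. Batch normalization contributes according to
#' the convention tag: `"trainable"` counts the scale and shift (2 per
#' channel), `"with-statistics"` also counts the running mean and variance
#' (4 per channel, what a Keras total-parameter summary reports), `"none"`
#' ignores batch normalization.
#'
#' @param spec A `network_spec`.
#' @param convention `"trainable"` (default), `"with-statistics"`, or `"none"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, convention = c("trainable", "with-statistics", "none")) {
  convention <- match.arg(convention)
  bn_per <- switch(convention, trainable = 2, `with-statistics` = 4, none = 0)
  shp <- c(spec$input_shape, 1L)
  flat <- FALSE
  total <- 0
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      total <- total + ly$n * (prod(ly$kernel) * shp[4] + 1)
      shp[1:3] <- shp[1:3] + 2L * ly$pad - ly$kernel + 1L
      shp[4] <- ly$n
    } else if (ly$type == "pool") {
      shp[1] <- as.integer(ceiling(shp[1] / ly$s))
    } else if (ly$type == "flatten") {
      shp <- prod(shp); flat <- TRUE
    } else if (ly$type == "dense") {
      total <- total + shp * ly$n + ly$n
      shp <- ly$n
    } else if (ly$type == "batchnorm") {
      total <- total + bn_per * (if (flat) shp else shp[4])
    }
  }
  total
}

#' Reference 3D convolution by direct summation
#'
#' Nested-loop evaluation of the defining 3D convolution: the output value of
#' kernel `j` at position `(x, y, z)` is the activation of the bias plus the
#' sum over input maps `m` and kernel offsets `(p, q, r)` of
#' `w[j, m, p, q, r] * v[m, x + p, y + q, z + r]`. Valid mode unless an
#' explicit zero-padding triple is supplied; stride 1 x 1 x 1. This is the
#' independent oracle against which the fast im2col/GEMM layer is verified.
#'
#' @param input `l x h x w x m` array of input cubes (an `l x h x w` array is
#'   treated as `m = 1`).
#' @param kernels `d x k x k x m x n_out` array of kernel weights.
#' @param bias Numeric vector of length `n_out`.
#' @param activation Function applied elementwise to the result (default
#'   identity).
#' @param pad Zero-padding triple `(temporal, rows, cols)`.
#' @return `lo x ho x wo x n_out` array of output cubes.
#' @export
conv3d_reference <- function(input, kernels, bias = NULL, activation = identity,
                             pad = c(0L, 0L, 0L)) {
  if (length(dim(input)) == 3) dim(input) <- c(dim(input), 1L)
  dk <- dim(kernels)
  stopifnot(length(dk) == 5, dk[4] == dim(input)[4])
  if (is.null(bias)) bias <- numeric(dk[5])
  di <- dim(input)
  # zero padding
  if (any(pad > 0)) {
    padded <- array(0, dim = c(di[1:3] + 2L * pad, di[4]))
    padded[pad[1] + seq_len(di[1]), pad[2] + seq_len(di[2]),
           pad[3] + seq_len(di[3]), ] <- input
    input <- padded
    di <- dim(input)
  }
  lo <- di[1] - dk[1] + 1L; ho <- di[2] - dk[2] + 1L; wo <- di[3] - dk[3] + 1L
  if (lo < 1 || ho < 1 || wo < 1) stop("kernel larger than padded input")
  out <- array(0, dim = c(lo, ho, wo, dk[5]))
  for (j in seq_len(dk[5])) {
    for (x in seq_len(lo)) for (y in seq_len(ho)) for (z in seq_len(wo)) {
      acc <- bias[j]
      for (m in seq_len(dk[4]))
        acc <- acc + sum(kernels[, , , m, j] *
                         input[x:(x + dk[1] - 1L), y:(y + dk[2] - 1L),
                               z:(z + dk[3] - 1L), m])
      out[x, y, z, j] <- acc
    }
  }
  activation(out)
}

#' Plateau-halving learning-rate schedule
#'
#' The learning rate is divided by two when the loss has stopped improving:
#' given the loss history, if the minimum of the last `patience` entries is
#' no better than the minimum of the earlier entries, the current rate is
#' halved; otherwise it is returned unchanged. [fit_network()] applies this
#' rule with a counter that resets after each halving, so `k` consecutive
#' plateaus of `patience` epochs yield a rate of `lr0 / 2^k`.
#'
#' @param loss_history Numeric vector of per-iteration losses (oldest first).
#' @param current_lr Current learning rate.
#' @param patience Number of iterations without improvement that triggers a
#'   halving (default 10).
#' @return The updated learning rate.
#' @export
lr_schedule <- function(loss_history, current_lr, patience = 10L) {
  if (length(loss_history) == 0) stop("empty loss history")
  stopifnot(patience >= 1)
  if (length(loss_history) <= patience) return(current_lr)
  recent <- tail(loss_history, patience)
  prior <- head(loss_history, length(loss_history) - patience)
  if (min(recent) >= min(prior)) current_lr / 2 else current_lr
}

#' Binary cross-entropy
#'
#' Two-class form of the training loss,
#' `-mean(y * log(p) + (1 - y) * log(1 - p))`. The network itself is trained
#' with the categorical generalization over the G-way softmax; this utility
#' covers the G = 2 case.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities of class 1.
#' @param eps Clamp for numerical safety.
#' @return Scalar loss.
#' @export
binary_cross_entropy <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Serialize / restore a network spec as YAML
#' @param spec A `network_spec`.
#' @param path File path.
#' @return `path` (write) or a `network_spec` (read).
#' @export
write_network_spec <- function(spec, path) {
  yaml::write_yaml(list(input_shape = spec$input_shape, G = spec$G,
                        dims = spec$dims, layers = spec$layers), path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  x <- yaml::read_yaml(path)
  layers <- lapply(x$layers, function(ly) {
    for (f in c("n", "kernel", "pad", "s")) if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    ly
  })
  new_network_spec(x$input_shape, layers, x$G, x$dims)
}
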