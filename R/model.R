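# Model factory: multiple-output regression CNNs.
#
# A classification backbone is truncated after its global-average-pooling
# layer and six parallel single-node linear dense heads are attached, one
# per target in the order BW, SW, SH, HW, HH, BL.  The six heads are stored
# as an F x 6 weight matrix plus a length-6 bias, which is exactly six
# independent one-node dense layers evaluated in parallel.

#' Describe a multiple-output regression CNN
#'
#' @param backbone_name one of `"densenet201"`, `"resnet152v2"`,
#'   `"xception"`, `"mobilenetv2"` or `"tinycnn"`.
#' @param input_size input side length in pixels.  The four named backbones
#'   are fixed to their native sizes (299 for the depthwise-separable
#'   backbone, 224 for the others); `tinycnn` accepts any size >= 16.
#' @param pretrained logical; reserved flag for externally supplied backbone
#'   weights.  No pretrained weights ship with this package, so `TRUE` is
#'   rejected; training always starts from random initialisation.
#' @param input_scale,input_offset affine input normalisation applied to the
#'   0-255 gray values before the first convolution: `x * scale + offset`.
#'   The default maps `[0, 255]` to `[-1, 1]`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(backbone_name, input_size = NULL, pretrained = FALSE,
                       input_scale = 1 / 127.5, input_offset = -1) {
  backbone_name <- match.arg(backbone_name, BACKBONE_NAMES)
  if (isTRUE(pretrained))
    stop("no pretrained weights are bundled; build with pretrained = FALSE")
  if (is.null(input_size)) input_size <- backbone_default_input(backbone_name)
  if (backbone_name == "tinycnn" && input_size < 16)
    stop("tinycnn needs input_size >= 16")
  if (backbone_name != "tinycnn" &&
      input_size != backbone_default_input(backbone_name))
    stop("backbone '", backbone_name, "' is defined for input size ",
         backbone_default_input(backbone_name), ", got ", input_size)
  structure(list(backbone_name = backbone_name,
                 input_size = as.integer(input_size),
                 n_outputs = 6L, pretrained = FALSE,
                 input_scale = input_scale, input_offset = input_offset),
            class = "model_spec")
}

#' Build a multiple-output regression CNN
#'
#' Constructs the backbone graph (classifier removed, global average pooling
#' retained) and attaches six parallel single-node linear heads.  Weights
#' are not materialised until [init_model_weights()] is called (parameter
#' counting needs only the graph); [train()] and [predict()] initialise
#' them on demand where a seed is available.
#'
#' @param spec a [model_spec()], or a backbone name which is promoted to the
#'   default spec for that backbone.
#' @param input_size optional input size override (tinycnn only).
#' @return an object of class `pig_regressor`.
#' @export
build_regressor <- function(spec, input_size = NULL) {
  if (is.character(spec)) spec <- model_spec(spec, input_size = input_size)
  stopifnot(inherits(spec, "model_spec"))
  graph <- build_backbone(spec$backbone_name, spec$input_size)
  stopifnot(graph$nodes[[graph$last]]$type == "gap")
  structure(list(spec = spec, graph = graph,
                 feature_width = ly_shape(graph)[3],
                 weights = NULL, head_w = NULL, head_b = NULL),
            class = "pig_regressor")
}

#' Count model parameters
#'
#' Totals every weight, bias and batch-normalisation statistic in the
#' backbone plus the six regression heads.  The trainable count excludes
#' the batch-normalisation moving means and variances, the convention under
#' which the published totals of the four named backbones are reproduced.
#'
#' @param model a `pig_regressor`.
#' @return a list of class `parameter_count` with elements `total` and
#'   `trainable`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "pig_regressor"))
  tab <- graph_param_table(model$graph)
  heads <- model$spec$n_outputs * (model$feature_width + 1)
  total <- sum(tab$n) + heads
  trainable <- sum(tab$n[tab$trainable]) + heads
  structure(list(total = total, trainable = trainable), class = "parameter_count")
}

#' @export
print.parameter_count <- function(x, ...) {
  cat(sprintf("parameters: total %s, trainable %s\n",
              format(x$total, big.mark = ","), format(x$trainable, big.mark = ",")))
  invisible(x)
}

#' @export
print.pig_regressor <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<pig_regressor> %s, input %dx%dx3, %d heads, feature width %d\n",
              x$spec$backbone_name, x$spec$input_size, x$spec$input_size,
              x$spec$n_outputs, x$feature_width))
  cat(sprintf("  weights: %s; ", if (is.null(x$weights)) "not initialised" else "initialised"))
  print(pc)
  invisible(x)
}

#' Materialise model weights
#'
#' He-normal initialisation for convolution kernels, zeros for biases,
#' identity initialisation for batch-normalisation layers, Glorot-uniform
#' (or zero) initialisation for the six linear heads.
#'
#' @param model a `pig_regressor`.
#' @param seed integer RNG seed.
#' @param head_init `"glorot"` or `"zero"`.
#' @return the model with `weights`, `head_w`, `head_b` filled in.
#' @export
init_model_weights <- function(model, seed = 0L, head_init = c("glorot", "zero")) {
  head_init <- match.arg(head_init)
  set.seed(as.integer(seed))
  weights <- list()
  for (i in seq_along(model$graph$nodes)) {
    node <- model$graph$nodes[[i]]
    if (is.null(node$params)) next
    for (pn in names(node$params)) {
      d <- node$params[[pn]]$dim
      nm <- sprintf("n%03d_%s_%s", i, node$type, pn)
      weights[[nm]] <- switch(paste(node$type, pn),
        "conv w" = array(rnorm(prod(d), sd = sqrt(2 / prod(d[1:3]))), dim = d),
        "dwconv w" = array(rnorm(prod(d), sd = sqrt(2 / (d[1] * d[2]))), dim = d),
        "conv b" = numeric(d),
        "bn gamma" = rep(1, d),
        "bn beta" = numeric(d),
        "bn moving_mean" = numeric(d),
        "bn moving_var" = rep(1, d),
        stop("unhandled parameter ", nm))
    }
  }
  f <- model$feature_width
  if (head_init == "zero") {
    model$head_w <- matrix(0, f, model$spec$n_outputs)
  } else {
    lim <- sqrt(6 / (f + 1))
    model$head_w <- matrix(runif(f * model$spec$n_outputs, -lim, lim), f)
  }
  colnames(model$head_w) <- TARGET_NAMES
  model$head_b <- setNames(numeric(model$spec$n_outputs), TARGET_NAMES)
  model$weights <- weights
  model
}

# ---- forward pass -------------------------------------------------------

bn_apply <- function(x, gamma, beta, mean, var, eps) {
  d <- dim(x)
  scale <- gamma / sqrt(var + eps)
  shift <- beta - mean * scale
  per_px <- d[1] * d[2]
  x * rep(scale, each = per_px) + rep(shift, each = per_px)
}

node_weight <- function(weights, i, node, pn) {
  weights[[sprintf("n%03d_%s_%s", i, node$type, pn)]]
}

# Forward through the backbone graph for a 4-d (H, W, C, N) input batch.
# Branch ops (add/concat) are computed per batch directly; R arrays keep the
# (H, W, C, N) layout throughout.
forward_backbone <- function(model, x, keep_acts = FALSE) {
  g <- model$graph
  weights <- model$weights
  if (is.null(weights)) stop("model weights not initialised; call init_model_weights()")
  acts <- vector("list", length(g$nodes))
  acts[[1]] <- x
  n_batch <- dim(x)[4]
  # reference counting so large intermediates can be dropped when no longer needed
  remaining <- integer(length(g$nodes))
  for (node in g$nodes) for (f in node$from) remaining[f] <- remaining[f] + 1L
  remaining[length(g$nodes)] <- remaining[length(g$nodes)] + 1L
  for (i in seq_along(g$nodes)[-1]) {
    node <- g$nodes[[i]]
    inp <- acts[[node$from[1]]]
    out <- switch(node$type,
      conv = .conv2d_fw(inp, node_weight(weights, i, node, "w"),
                        if (node$use_bias) node_weight(weights, i, node, "b") else NULL,
                        node$stride, node$pad),
      dwconv = .dwconv2d_fw(inp, node_weight(weights, i, node, "w"), node$stride, node$pad),
      bn = bn_apply(inp, node_weight(weights, i, node, "gamma"),
                    node_weight(weights, i, node, "beta"),
                    node_weight(weights, i, node, "moving_mean"),
                    node_weight(weights, i, node, "moving_var"), node$eps),
      relu = { inp[inp < 0] <- 0; inp },
      relu6 = { inp[inp < 0] <- 0; inp[inp > 6] <- 6; inp },
      maxpool = .maxpool2d_fw(inp, node$pool, node$stride, node$pad),
      avgpool = .avgpool2d_fw(inp, node$pool, node$stride),
      add = acts[[node$from[1]]] + acts[[node$from[2]]],
      concat = {
        parts <- lapply(node$from, function(j) acts[[j]])
        d1 <- dim(parts[[1]])
        out <- array(0, c(d1[1], d1[2], node$shape[3], n_batch))
        ofs <- 0L
        for (p in parts) {
          cc <- dim(p)[3]
          out[, , ofs + seq_len(cc), ] <- p
          ofs <- ofs + cc
        }
        out
      },
      gap = {
        d <- dim(inp)
        feats <- matrix(colMeans(matrix(inp, d[1] * d[2], d[3] * d[4])), d[3], d[4])
        array(feats, c(1L, 1L, d[3], d[4]))
      },
      stop("no forward rule for node type ", node$type))
    acts[[i]] <- out
    if (!keep_acts) {
      for (f in node$from) {
        remaining[f] <- remaining[f] - 1L
        if (remaining[f] == 0L && f > 1L) acts[f] <- list(NULL)
      }
    }
  }
  feats <- t(matrix(acts[[length(acts)]], model$feature_width, n_batch))
  list(features = feats, acts = if (keep_acts) acts else NULL)
}

# Normalise gray input and replicate the single channel to the 3 input
# channels the backbones expect.
prepare_input_batch <- function(model, images) {
  s <- model$spec$input_size
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3) {
    n <- dim(images)[3]
    images <- lapply(seq_len(n), function(i) images[, , i])
  }
  stopifnot(is.list(images), length(images) >= 1)
  n <- length(images)
  x <- array(0, c(s, s, 3L, n))
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (!is.matrix(im) || nrow(im) != s || ncol(im) != s)
      stop("image ", i, " is not ", s, "x", s, "; preprocess to the model input size first")
    v <- as.numeric(im) * model$spec$input_scale + model$spec$input_offset
    x[, , 1L, i] <- v
    x[, , 2L, i] <- v
    x[, , 3L, i] <- v
  }
  x
}

#' Predict weight and body sizes for gray images
#'
#' @param object a `pig_regressor` with initialised weights.
#' @param images a single gray matrix, a list of gray matrices, or an
#'   `(S, S, N)` array, all at the model input size.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return an `N x 6` matrix with columns BW, SW, SH, HW, HH, BL.
#' @export
predict.pig_regressor <- function(object, images, batch_size = 32L, ...) {
  x <- prepare_input_batch(object, images)
  n <- dim(x)[4]
  out <- matrix(0, n, object$spec$n_outputs, dimnames = list(NULL, TARGET_NAMES))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- forward_backbone(object, x[, , , idx, drop = FALSE])
    out[idx, ] <- fw$features %*% object$head_w +
      matrix(object$head_b, length(idx), object$spec$n_outputs, byrow = TRUE)
  }
  out
}
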