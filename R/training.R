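# Training: 7:3 shuffled split, summed per-target MSE loss, Adam,
# best-on-validation checkpoint retention.

#' Training configuration
#'
#' Defaults are the reference hyper-parameters: Adam with learning rate
#' 0.001, batch size 16, 150 epochs, 7:3 train/validation split.  Adam's
#' remaining constants follow the optimiser's published defaults.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param split_ratio training fraction of the modelling data.
#' @param shuffle_seed RNG seed for the split, weight init and batch order.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L, epochs = 150L,
                         split_ratio = 0.7, shuffle_seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7) {
  stopifnot(split_ratio > 0, split_ratio < 1, batch_size >= 1, epochs >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 split_ratio = split_ratio, shuffle_seed = as.integer(shuffle_seed),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 loss = "summed multi-target MSE"),
            class = "train_config")
}

#' Shuffled train/validation split
#'
#' @param data a `regression_dataset`, or a single integer sample count (in
#'   which case index vectors are returned).
#' @param ratio training fraction; the training set size is
#'   `round(ratio * n)`.
#' @param seed RNG seed for the shuffle.
#' @return a list with elements `train` and `validation`: datasets when
#'   `data` is a dataset, integer index vectors when `data` is a count.
#' @export
split_dataset <- function(data, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- if (is.numeric(data) && length(data) == 1) as.integer(data)
       else if (inherits(data, "regression_dataset")) dim(data$images)[3]
       else stop("data must be a regression_dataset or a sample count")
  if (n < 2) stop("need at least 2 samples to split")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_train <- min(max(round(ratio * n), 1L), n - 1L)
  idx <- list(train = perm[seq_len(n_train)], validation = perm[(n_train + 1L):n])
  if (is.numeric(data)) return(idx)
  subset_ds <- function(i) structure(list(images = data$images[, , i, drop = FALSE],
                                          labels = data$labels[i, , drop = FALSE]),
                                     class = "regression_dataset")
  list(train = subset_ds(idx$train), validation = subset_ds(idx$validation))
}

#' Summed per-target mean squared error
#'
#' The training loss: for each of the six targets the per-target MSE over
#' the batch is computed, and the six MSEs are summed without weighting
#' (mixed kg^2 + cm^2 units, exactly as the loss is defined).
#'
#' @param estimates numeric `M x 6` matrix (or length-6 vector) of model
#'   outputs.
#' @param measured matching matrix/vector of measured labels.
#' @return a single non-negative number; zero iff the estimates equal the
#'   measurements.
#' @export
total_loss <- function(estimates, measured) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, nrow = 1)
  if (is.null(dim(measured))) measured <- matrix(measured, nrow = 1)
  if (!all(dim(estimates) == dim(measured)) || ncol(estimates) != 6)
    stop("estimates and measured must both be M x 6")
  sum(colMeans((measured - estimates)^2))
}

# ---- Adam ---------------------------------------------------------------

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, t, cfg) {
  b1t <- 1 - cfg$beta1^t
  b2t <- 1 - cfg$beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
    st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate * (st$m / b1t) /
      (sqrt(st$v / b2t) + cfg$epsilon)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# ---- backward pass (sequential conv/relu/gap backbones) -----------------

# Gradient support covers chain graphs built from conv, relu and gap — the
# desk-scale tinycnn backbone.  The branched backbones (dense connectivity,
# residual shortcuts) have forward-only support on CPU.
sequential_plan <- function(graph) {
  for (i in seq_along(graph$nodes)[-1]) {
    node <- graph$nodes[[i]]
    if (length(node$from) != 1 || node$from != i - 1L) return(NULL)
    if (!node$type %in% c("conv", "relu", "gap")) return(NULL)
  }
  graph$nodes
}

backward_backbone <- function(model, acts, dfeats) {
  g <- model$graph
  weights <- model$weights
  grads <- list()
  n_nodes <- length(g$nodes)
  dy <- NULL
  for (i in rev(seq_along(g$nodes)[-1])) {
    node <- g$nodes[[i]]
    x_in <- acts[[node$from[1]]]
    if (node$type == "gap") {
      d <- dim(x_in)
      per_px <- d[1] * d[2]
      dy <- array(rep(t(dfeats) / per_px, each = per_px), dim = d)
    } else if (node$type == "relu") {
      dy <- dy * (acts[[i]] > 0)
    } else if (node$type == "conv") {
      w_name <- sprintf("n%03d_conv_w", i)
      bw <- .conv2d_bw(x_in, weights[[w_name]], dy, node$stride, node$pad,
                       isTRUE(node$use_bias))
      grads[[w_name]] <- bw$dw
      if (isTRUE(node$use_bias)) grads[[sprintf("n%03d_conv_b", i)]] <- bw$db
      dy <- bw$dx
    } else stop("no backward rule for node type ", node$type)
  }
  grads
}

#' Train a regression CNN
#'
#' Mini-batch Adam on the summed per-target MSE loss.  The modelling data
#' are shuffled and split 7:3 (configurable); the validation loss is
#' computed on the full validation set after every epoch and the parameters
#' of the best epoch are retained.
#'
#' Gradients are implemented for sequential conv/ReLU/GAP backbones (the
#' `tinycnn` architecture); the four large branched backbones are
#' forward-only on CPU.
#'
#' @param model a `pig_regressor` (weights are initialised from
#'   `config$shuffle_seed` if absent).
#' @param data a `regression_dataset` (already preprocessed, at the model
#'   input size).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return an object of class `train_result`: `model` (with the retained
#'   best parameters), `history` (data frame of per-epoch train and
#'   validation loss), `best_epoch`, `best_val_loss`.
#' @export
train <- function(model, data, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "pig_regressor"), inherits(data, "regression_dataset"))
  if (is.null(sequential_plan(model$graph)))
    stop("training requires a sequential conv/relu/gap backbone (tinycnn); ",
         "the large branched backbones are forward-only on CPU")
  if (is.null(model$weights))
    model <- init_model_weights(model, seed = config$shuffle_seed)

  n <- dim(data$images)[3]
  idx <- split_dataset(n, config$split_ratio, config$shuffle_seed)
  x_all <- prepare_input_batch(model, data$images)
  y_all <- data$labels

  params <- c(model$weights, list(head_w = model$head_w, head_b = model$head_b))
  state <- adam_state(params)
  n_out <- model$spec$n_outputs

  eval_loss <- function(params, ids) {
    m <- model
    m$weights <- params[setdiff(names(params), c("head_w", "head_b"))]
    loss <- 0
    for (start in seq(1L, length(ids), by = 64L)) {
      sub <- ids[start:min(start + 63L, length(ids))]
      fw <- forward_backbone(m, x_all[, , , sub, drop = FALSE])
      pred <- fw$features %*% params$head_w +
        matrix(params$head_b, length(sub), n_out, byrow = TRUE)
      loss <- loss + total_loss(pred, y_all[sub, , drop = FALSE]) * length(sub)
    }
    loss / length(ids)
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  best <- list(epoch = NA_integer_, val_loss = Inf, params = NULL)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    order <- sample(idx$train)
    epoch_loss <- 0
    for (start in seq(1L, length(order), by = config$batch_size)) {
      batch <- order[start:min(start + config$batch_size - 1L, length(order))]
      m_batch <- length(batch)
      mdl <- model
      mdl$weights <- params[setdiff(names(params), c("head_w", "head_b"))]
      fw <- forward_backbone(mdl, x_all[, , , batch, drop = FALSE], keep_acts = TRUE)
      pred <- fw$features %*% params$head_w +
        matrix(params$head_b, m_batch, n_out, byrow = TRUE)
      err <- pred - y_all[batch, , drop = FALSE]
      batch_loss <- sum(colMeans(err^2))
      if (!is.finite(batch_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      epoch_loss <- epoch_loss + batch_loss * m_batch

      dpred <- 2 * err / m_batch
      grads <- list(head_w = t(fw$features) %*% dpred,
                    head_b = colSums(dpred))
      dfeats <- dpred %*% t(params$head_w)
      grads <- c(grads, backward_backbone(mdl, fw$acts, dfeats))

      step <- step + 1L
      upd <- adam_update(params, grads, state, step, config)
      params <- upd$params
      state <- upd$state
    }
    val_loss <- eval_loss(params, idx$validation)
    train_loss <- epoch_loss / length(idx$train)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (val_loss < best$val_loss)
      best <- list(epoch = epoch, val_loss = val_loss, params = params)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch, train_loss,
                      val_loss, if (best$epoch == epoch) "  *" else ""))
  }

  model$weights <- best$params[setdiff(names(best$params), c("head_w", "head_b"))]
  model$head_w <- best$params$head_w
  model$head_b <- best$params$head_b
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 best_val_loss = best$val_loss, config = config,
                 split = idx), class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs, best epoch %d, best validation loss %.4f\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}
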