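# Layer-graph representation used by the model factory.
#
# A graph is a plain list of nodes built in topological order; each node
# carries its type, the indices of its input node(s), the inferred output
# shape (H, W, C) and any hyper-parameters.  Weight-bearing nodes
# additionally get a set of named parameter descriptors (dims + trainable
# flag) from which both parameter counting and weight materialisation work.

ly_graph <- function(input_shape) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  g <- list(nodes = list(list(type = "input", shape = as.integer(input_shape))),
            last = 1L)
  class(g) <- "ly_graph"
  g
}

ly_shape <- function(g, id = g$last) g$nodes[[id]]$shape

ly_append <- function(g, node) {
  g$nodes[[length(g$nodes) + 1L]] <- node
  g$last <- length(g$nodes)
  g
}

# Resolve padding to (top, bottom, left, right).  "same" follows the
# TensorFlow convention (extra padding goes to the bottom/right), "valid" is
# zero padding; an integer vector of length 4 is taken verbatim.
resolve_pad <- function(padding, in_hw, k, stride) {
  if (is.numeric(padding)) {
    stopifnot(length(padding) == 4)
    return(as.integer(padding))
  }
  if (identical(padding, "valid")) return(c(0L, 0L, 0L, 0L))
  if (identical(padding, "same")) {
    pad1 <- function(n) {
      out <- ceiling(n / stride)
      total <- max((out - 1L) * stride + k - n, 0L)
      beg <- total %/% 2L
      c(beg, total - beg)
    }
    return(as.integer(c(pad1(in_hw[1]), pad1(in_hw[2]))))
  }
  stop("unknown padding spec: ", deparse(padding))
}

conv_out_extent <- function(n, k, stride, p0, p1) {
  as.integer((n + p0 + p1 - k) %/% stride + 1L)
}

ly_conv <- function(g, filters, kernel, stride = 1L, padding = "same",
                    use_bias = FALSE, from = g$last) {
  s <- ly_shape(g, from)
  pad <- resolve_pad(padding, s[1:2], kernel, stride)
  out <- c(conv_out_extent(s[1], kernel, stride, pad[1], pad[2]),
           conv_out_extent(s[2], kernel, stride, pad[3], pad[4]),
           as.integer(filters))
  params <- list(w = list(dim = c(kernel, kernel, s[3], filters), trainable = TRUE))
  if (use_bias) params$b <- list(dim = filters, trainable = TRUE)
  ly_append(g, list(type = "conv", from = from, shape = out, kernel = as.integer(kernel),
                    stride = as.integer(stride), pad = pad, use_bias = use_bias,
                    params = params))
}

ly_dwconv <- function(g, kernel = 3L, stride = 1L, padding = "same", from = g$last) {
  s <- ly_shape(g, from)
  pad <- resolve_pad(padding, s[1:2], kernel, stride)
  out <- c(conv_out_extent(s[1], kernel, stride, pad[1], pad[2]),
           conv_out_extent(s[2], kernel, stride, pad[3], pad[4]),
           s[3])
  ly_append(g, list(type = "dwconv", from = from, shape = out, kernel = as.integer(kernel),
                    stride = as.integer(stride), pad = pad,
                    params = list(w = list(dim = c(kernel, kernel, s[3]), trainable = TRUE))))
}

# Batch normalisation carries 4 parameters per channel; the moving mean and
# variance are the non-trainable pair (the convention under which the
# published totals for the four backbones reproduce).
ly_bn <- function(g, from = g$last) {
  s <- ly_shape(g, from)
  c <- s[3]
  ly_append(g, list(type = "bn", from = from, shape = s, eps = 1.001e-5,
                    params = list(gamma = list(dim = c, trainable = TRUE),
                                  beta = list(dim = c, trainable = TRUE),
                                  moving_mean = list(dim = c, trainable = FALSE),
                                  moving_var = list(dim = c, trainable = FALSE))))
}

ly_act <- function(g, fun = c("relu", "relu6"), from = g$last) {
  fun <- match.arg(fun)
  ly_append(g, list(type = fun, from = from, shape = ly_shape(g, from)))
}

ly_maxpool <- function(g, pool = 3L, stride = 2L, padding = "valid", from = g$last) {
  s <- ly_shape(g, from)
  pad <- resolve_pad(padding, s[1:2], pool, stride)
  out <- c(conv_out_extent(s[1], pool, stride, pad[1], pad[2]),
           conv_out_extent(s[2], pool, stride, pad[3], pad[4]), s[3])
  ly_append(g, list(type = "maxpool", from = from, shape = out,
                    pool = as.integer(pool), stride = as.integer(stride), pad = pad))
}

ly_avgpool <- function(g, pool = 2L, stride = 2L, from = g$last) {
  s <- ly_shape(g, from)
  out <- c(conv_out_extent(s[1], pool, stride, 0L, 0L),
           conv_out_extent(s[2], pool, stride, 0L, 0L), s[3])
  ly_append(g, list(type = "avgpool", from = from, shape = out,
                    pool = as.integer(pool), stride = as.integer(stride)))
}

ly_gap <- function(g, from = g$last) {
  s <- ly_shape(g, from)
  ly_append(g, list(type = "gap", from = from, shape = c(1L, 1L, s[3])))
}

ly_dense <- function(g, units, use_bias = TRUE, from = g$last) {
  s <- ly_shape(g, from)
  stopifnot(s[1] == 1L, s[2] == 1L)
  params <- list(w = list(dim = c(s[3], units), trainable = TRUE))
  if (use_bias) params$b <- list(dim = units, trainable = TRUE)
  ly_append(g, list(type = "dense", from = from, shape = c(1L, 1L, as.integer(units)),
                    use_bias = use_bias, params = params))
}

ly_add2 <- function(g, from) {
  stopifnot(length(from) == 2)
  s1 <- ly_shape(g, from[1]); s2 <- ly_shape(g, from[2])
  stopifnot(identical(s1, s2))
  ly_append(g, list(type = "add", from = as.integer(from), shape = s1))
}

ly_concat <- function(g, from) {
  shapes <- lapply(from, function(i) ly_shape(g, i))
  hw <- shapes[[1]][1:2]
  stopifnot(all(vapply(shapes, function(s) identical(s[1:2], hw), logical(1))))
  c_tot <- sum(vapply(shapes, function(s) s[3], integer(1)))
  ly_append(g, list(type = "concat", from = as.integer(from), shape = c(hw, c_tot)))
}

# One descriptor row per parameter tensor across the graph.
graph_param_table <- function(g) {
  rows <- list()
  for (i in seq_along(g$nodes)) {
    node <- g$nodes[[i]]
    if (is.null(node$params)) next
    for (pn in names(node$params)) {
      p <- node$params[[pn]]
      rows[[length(rows) + 1L]] <- data.frame(
        node = i, name = sprintf("n%03d_%s_%s", i, node$type, pn),
        n = prod(p$dim), trainable = p$trainable, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(node = integer(), name = character(),
                                       n = numeric(), trainable = logical()))
  do.call(rbind, rows)
}
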