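# Backbone graph definitions.
#
# The four named backbones follow their published architecture definitions
# layer by layer (dense blocks with growth 32; pre-activation bottleneck
# residual stacks; depthwise-separable entry/middle/exit flows; inverted
# residual bottlenecks), each truncated after global average pooling.  A
# fifth, deliberately small `tinycnn` backbone (four strided conv blocks +
# GAP) is provided for desk-scale training experiments; it is this package's
# own addition and matches nothing published.

BACKBONE_NAMES <- c("densenet201", "resnet152v2", "xception", "mobilenetv2", "tinycnn")

# Native input side length per backbone (tinycnn is free).
backbone_default_input <- function(name) {
  switch(name,
         xception = 299L,
         densenet201 = , resnet152v2 = , mobilenetv2 = 224L,
         tinycnn = 64L,
         stop("unknown backbone '", name, "'; valid names: ",
              paste(BACKBONE_NAMES, collapse = ", ")))
}

backbone_densenet201 <- function(input_size = 224L) {
  g <- ly_graph(c(input_size, input_size, 3L))
  g <- ly_conv(g, 64, 7, stride = 2, padding = c(3, 3, 3, 3))
  g <- ly_bn(g); g <- ly_act(g, "relu")
  g <- ly_maxpool(g, 3, 2, padding = c(1, 1, 1, 1))
  blocks <- c(6L, 12L, 48L, 32L)
  growth <- 32L
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[b])) {
      inp <- g$last
      g <- ly_bn(g, from = inp); g <- ly_act(g, "relu")
      g <- ly_conv(g, 4L * growth, 1, padding = "valid")
      g <- ly_bn(g); g <- ly_act(g, "relu")
      g <- ly_conv(g, growth, 3, padding = "same")
      g <- ly_concat(g, c(inp, g$last))
    }
    if (b < length(blocks)) {
      c_in <- ly_shape(g)[3]
      g <- ly_bn(g); g <- ly_act(g, "relu")
      g <- ly_conv(g, c_in %/% 2L, 1, padding = "valid")
      g <- ly_avgpool(g, 2, 2)
    }
  }
  g <- ly_bn(g); g <- ly_act(g, "relu")
  ly_gap(g)
}

backbone_resnet152v2 <- function(input_size = 224L) {
  g <- ly_graph(c(input_size, input_size, 3L))
  g <- ly_conv(g, 64, 7, stride = 2, padding = c(3, 3, 3, 3), use_bias = TRUE)
  g <- ly_maxpool(g, 3, 2, padding = c(1, 1, 1, 1))
  block <- function(g, f, stride, conv_shortcut) {
    x_in <- g$last
    g <- ly_bn(g, from = x_in); g <- ly_act(g, "relu")
    preact <- g$last
    if (conv_shortcut) {
      g <- ly_conv(g, 4L * f, 1, stride = stride, padding = "valid",
                   use_bias = TRUE, from = preact)
      shortcut <- g$last
    } else if (stride > 1) {
      g <- ly_maxpool(g, 1, stride, padding = "valid", from = x_in)
      shortcut <- g$last
    } else {
      shortcut <- x_in
    }
    g <- ly_conv(g, f, 1, padding = "valid", from = preact)
    g <- ly_bn(g); g <- ly_act(g, "relu")
    g <- ly_conv(g, f, 3, stride = stride, padding = c(1, 1, 1, 1))
    g <- ly_bn(g); g <- ly_act(g, "relu")
    g <- ly_conv(g, 4L * f, 1, padding = "valid", use_bias = TRUE)
    ly_add2(g, c(shortcut, g$last))
  }
  stacks <- list(c(64L, 3L, 2L), c(128L, 8L, 2L), c(256L, 36L, 2L), c(512L, 3L, 1L))
  for (s in stacks) {
    f <- s[1]; nb <- s[2]; stride1 <- s[3]
    g <- block(g, f, 1L, conv_shortcut = TRUE)
    if (nb > 2) for (i in seq_len(nb - 2L)) g <- block(g, f, 1L, conv_shortcut = FALSE)
    g <- block(g, f, stride1, conv_shortcut = FALSE)
  }
  g <- ly_bn(g); g <- ly_act(g, "relu")
  ly_gap(g)
}

backbone_xception <- function(input_size = 299L) {
  sep <- function(g, filters) {
    g <- ly_dwconv(g, 3, 1, padding = "same")
    ly_conv(g, filters, 1, padding = "valid")
  }
  g <- ly_graph(c(input_size, input_size, 3L))
  g <- ly_conv(g, 32, 3, stride = 2, padding = "valid")
  g <- ly_bn(g); g <- ly_act(g, "relu")
  g <- ly_conv(g, 64, 3, padding = "valid")
  g <- ly_bn(g); g <- ly_act(g, "relu")
  first <- TRUE
  for (f in c(128L, 256L, 728L)) {
    x_in <- g$last
    g <- ly_conv(g, f, 1, stride = 2, padding = "same", from = x_in)
    g <- ly_bn(g)
    residual <- g$last
    if (first) g$last <- x_in else g <- ly_act(g, "relu", from = x_in)
    g <- sep(g, f); g <- ly_bn(g); g <- ly_act(g, "relu")
    g <- sep(g, f); g <- ly_bn(g)
    g <- ly_maxpool(g, 3, 2, padding = "same")
    g <- ly_add2(g, c(residual, g$last))
    first <- FALSE
  }
  for (i in 1:8) {
    x_in <- g$last
    for (j in 1:3) {
      g <- ly_act(g, "relu")
      g <- sep(g, 728L); g <- ly_bn(g)
    }
    g <- ly_add2(g, c(x_in, g$last))
  }
  x_in <- g$last
  g <- ly_conv(g, 1024, 1, stride = 2, padding = "same", from = x_in)
  g <- ly_bn(g)
  residual <- g$last
  g <- ly_act(g, "relu", from = x_in)
  g <- sep(g, 728L); g <- ly_bn(g); g <- ly_act(g, "relu")
  g <- sep(g, 1024L); g <- ly_bn(g)
  g <- ly_maxpool(g, 3, 2, padding = "same")
  g <- ly_add2(g, c(residual, g$last))
  g <- sep(g, 1536L); g <- ly_bn(g); g <- ly_act(g, "relu")
  g <- sep(g, 2048L); g <- ly_bn(g); g <- ly_act(g, "relu")
  ly_gap(g)
}

backbone_mobilenetv2 <- function(input_size = 224L) {
  g <- ly_graph(c(input_size, input_size, 3L))
  g <- ly_conv(g, 32, 3, stride = 2, padding = "same")
  g <- ly_bn(g); g <- ly_act(g, "relu6")
  # (expansion, output channels, repeats, first stride)
  spec <- list(c(1L, 16L, 1L, 1L), c(6L, 24L, 2L, 2L), c(6L, 32L, 3L, 2L),
               c(6L, 64L, 4L, 2L), c(6L, 96L, 3L, 1L), c(6L, 160L, 3L, 2L),
               c(6L, 320L, 1L, 1L))
  first_block <- TRUE
  for (s in spec) {
    t <- s[1]; c_out <- s[2]; n <- s[3]; stride0 <- s[4]
    for (i in seq_len(n)) {
      stride <- if (i == 1L) stride0 else 1L
      x_in <- g$last
      c_in <- ly_shape(g, x_in)[3]
      if (!first_block) {
        g <- ly_conv(g, t * c_in, 1, padding = "valid", from = x_in)
        g <- ly_bn(g); g <- ly_act(g, "relu6")
      }
      g <- ly_dwconv(g, 3, stride, padding = "same")
      g <- ly_bn(g); g <- ly_act(g, "relu6")
      g <- ly_conv(g, c_out, 1, padding = "valid")
      g <- ly_bn(g)
      if (stride == 1L && c_in == c_out) g <- ly_add2(g, c(x_in, g$last))
      first_block <- FALSE
    }
  }
  g <- ly_conv(g, 1280, 1, padding = "valid")
  g <- ly_bn(g); g <- ly_act(g, "relu6")
  ly_gap(g)
}

# Desk-scale backbone: four strided conv blocks (bias, no batch norm) + GAP.
backbone_tinycnn <- function(input_size = 64L) {
  g <- ly_graph(c(input_size, input_size, 3L))
  for (f in c(16L, 32L, 64L, 256L)) {
    g <- ly_conv(g, f, 3, stride = 2, padding = "same", use_bias = TRUE)
    g <- ly_act(g, "relu")
  }
  ly_gap(g)
}

build_backbone <- function(name, input_size = NULL) {
  name <- match.arg(name, BACKBONE_NAMES)
  if (is.null(input_size)) input_size <- backbone_default_input(name)
  input_size <- as.integer(input_size)
  fixed <- c(densenet201 = 224L, resnet152v2 = 224L, xception = 299L, mobilenetv2 = 224L)
  if (name %in% names(fixed) && input_size != fixed[[name]])
    stop("backbone '", name, "' is defined for input size ", fixed[[name]],
         ", got ", input_size)
  switch(name,
         densenet201 = backbone_densenet201(input_size),
         resnet152v2 = backbone_resnet152v2(input_size),
         xception = backbone_xception(input_size),
         mobilenetv2 = backbone_mobilenetv2(input_size),
         tinycnn = backbone_tinycnn(input_size))
}
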