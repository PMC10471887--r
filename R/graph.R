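## Layer-graph representation of the network.
##
## A graph is an ordered named list of primitive units ("nodes"): conv, bn,
## relu, maxpool, add, gap (global average pool) and linear, plus one input
## node. Build order is topological by construction. Every trainable node
## reports its own element count; shapes are inferred symbolically without
## allocating tensors.

node_new <- function(name, op, inputs, module = NA_character_,
                     unit = NA_character_, ...) {
  c(list(name = name, op = op, inputs = inputs, module = module, unit = unit),
    list(...))
}

frag <- function(nodes, output) list(nodes = nodes, output = output)

frag_conv_bn_relu <- function(prefix, input, in_ch, out_ch, k, stride, pad,
                              bias, module, unit = NA, relu = TRUE) {
  nodes <- list(
    node_new(paste0(prefix, ".conv"), "conv", input, module,
             kernel = c(k, k), stride = stride, pad = pad,
             in_ch = in_ch, out_ch = out_ch, bias = bias),
    node_new(paste0(prefix, ".bn"), "bn", paste0(prefix, ".conv"), module,
             ch = out_ch)
  )
  out <- paste0(prefix, ".bn")
  if (relu) {
    nodes <- c(nodes, list(node_new(paste0(prefix, ".relu"), "relu", out,
                                    module, unit = unit)))
    out <- paste0(prefix, ".relu")
  }
  frag(nodes, out)
}

# One residual structure: two 3x3 convolutions with a shortcut. `projection`
# inserts a 1x1 convolution (+ BN) on the shortcut; plain structures use the
# identity. Convolutions here carry no bias (each is followed by BN). The
# addition happens before the final activation.
frag_residual <- function(prefix, input, in_ch, out_ch, stride, projection,
                          module) {
  b1 <- frag_conv_bn_relu(paste0(prefix, ".c1"), input, in_ch, out_ch,
                          k = 3, stride = stride, pad = 1, bias = FALSE,
                          module = module)
  nodes <- b1$nodes
  nodes <- c(nodes, list(
    node_new(paste0(prefix, ".c2.conv"), "conv", b1$output, module,
             kernel = c(3, 3), stride = 1, pad = 1,
             in_ch = out_ch, out_ch = out_ch, bias = FALSE),
    node_new(paste0(prefix, ".c2.bn"), "bn", paste0(prefix, ".c2.conv"),
             module, ch = out_ch)
  ))
  if (projection) {
    nodes <- c(nodes, list(
      node_new(paste0(prefix, ".sc.conv"), "conv", input, module,
               kernel = c(1, 1), stride = stride, pad = 0,
               in_ch = in_ch, out_ch = out_ch, bias = FALSE),
      node_new(paste0(prefix, ".sc.bn"), "bn", paste0(prefix, ".sc.conv"),
               module, ch = out_ch)
    ))
    shortcut <- paste0(prefix, ".sc.bn")
  } else {
    shortcut <- input
  }
  nodes <- c(nodes, list(
    node_new(paste0(prefix, ".add"), "add",
             c(paste0(prefix, ".c2.bn"), shortcut), module),
    node_new(paste0(prefix, ".relu"), "relu", paste0(prefix, ".add"), module,
             unit = paste0(prefix, ".out"))
  ))
  frag(nodes, paste0(prefix, ".relu"))
}

frag_rs_layer <- function(prefix, input, index, in_ch, out_ch, first_stride,
                          module) {
  n_structs <- if (index == 5) 3L else 2L
  nodes <- list()
  cur <- input
  for (j in seq_len(n_structs)) {
    f <- if (j == 1) {
      frag_residual(paste0(prefix, ".s1"), cur, in_ch, out_ch,
                    stride = first_stride, projection = TRUE, module)
    } else {
      frag_residual(paste0(prefix, ".s", j), cur, out_ch, out_ch,
                    stride = 1, projection = FALSE, module)
    }
    nodes <- c(nodes, f$nodes)
    cur <- f$output
  }
  frag(nodes, cur)
}

# Multiscale stem: parallel 1x1 / 3x3 / 5x5 / 7x7 convolutions, 64 filters
# each, same-dimension padding. The 3x3/5x5/7x7 paths use stride 2; the 1x1
# path uses stride 1 followed by a 3x3 max-pool of stride 2. The four path
# outputs are fused by element-wise sum. Channel-branch convolutions carry
# bias in addition to BN (see the parameter-count notes in the vignette).
frag_msf <- function(prefix, input, in_ch, module = "MSF") {
  specs <- list(conv1x1 = c(1, 1, 0), conv3x3 = c(3, 2, 1),
                conv5x5 = c(5, 2, 2), conv7x7 = c(7, 2, 3))
  nodes <- list()
  outs <- character(0)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    f <- frag_conv_bn_relu(paste0(prefix, ".", nm), input, in_ch, 64,
                           k = sp[1], stride = sp[2], pad = sp[3], bias = TRUE,
                           module = module,
                           unit = if (nm != "conv1x1") paste0("msf.", nm) else NA)
    nodes <- c(nodes, f$nodes)
    if (nm == "conv1x1") {
      nodes <- c(nodes, list(
        node_new(paste0(prefix, ".conv1x1.pool"), "maxpool", f$output, module,
                 unit = "msf.conv1x1", kernel = c(3, 3), stride = 2, pad = 1)))
      outs <- c(outs, paste0(prefix, ".conv1x1.pool"))
    } else {
      outs <- c(outs, f$output)
    }
  }
  nodes <- c(nodes, list(node_new(paste0(prefix, ".fuse"), "add", outs,
                                  module, unit = "msf.out")))
  frag(nodes, paste0(prefix, ".fuse"))
}

# Multilevel 1x1-convolution block. Conv1 maps in->out, Conv2..Conv4 map
# out->out. With feature reuse the outputs of Conv1..Conv3 are summed before
# Conv4; without it Conv4 sees Conv3 alone. A trailing 3x3 max-pool of
# stride 2 halves the spatial dimensions.
frag_mlf <- function(prefix, input, in_ch, out_ch, feature_reuse,
                     module, unit_prefix = prefix) {
  if (!(out_ch == in_ch || out_ch == 2L * in_ch)) {
    stop_config(
      "MLF output channels must equal or double the input channels (got %d -> %d)",
      in_ch, out_ch, subclass = "fusenet_invalid_channels")
  }
  nodes <- list()
  ins <- c(in_ch, out_ch, out_ch)
  cur <- input
  outs <- character(0)
  for (j in 1:3) {
    f <- frag_conv_bn_relu(paste0(prefix, ".c", j), cur, ins[j], out_ch,
                           k = 1, stride = 1, pad = 0, bias = TRUE,
                           module = module,
                           unit = paste0(unit_prefix, ".conv", j))
    nodes <- c(nodes, f$nodes)
    cur <- f$output
    outs <- c(outs, f$output)
  }
  if (feature_reuse) {
    nodes <- c(nodes, list(node_new(paste0(prefix, ".reuse"), "add", outs,
                                    module)))
    c4_in <- paste0(prefix, ".reuse")
  } else {
    c4_in <- cur
  }
  f4 <- frag_conv_bn_relu(paste0(prefix, ".c4"), c4_in, out_ch, out_ch,
                          k = 1, stride = 1, pad = 0, bias = TRUE,
                          module = module, unit = paste0(unit_prefix, ".conv4"))
  nodes <- c(nodes, f4$nodes)
  nodes <- c(nodes, list(node_new(paste0(prefix, ".pool"), "maxpool",
                                  f4$output, module,
                                  unit = paste0(unit_prefix, ".out"),
                                  kernel = c(3, 3), stride = 2, pad = 1)))
  frag(nodes, paste0(prefix, ".pool"))
}

as_layer_graph <- function(fragment, in_ch, input_name = "input") {
  nodes <- c(list(node_new(input_name, "input", character(0), ch = in_ch)),
             fragment$nodes)
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  structure(list(nodes = nodes, input = input_name, output = fragment$output),
            class = "layer_graph")
}

#' Build a single residual structure
#'
#' Two 3x3 convolutions (each followed by batch normalization) with a
#' shortcut connection; the addition precedes the final ReLU. The plain
#' variant (`downsample = FALSE`) keeps shape and requires equal channel
#' counts; the downsampling variant uses stride 2 in the first convolution
#' and a 1x1 projection convolution on the shortcut, halving the spatial
#' dimensions and mapping `in_channels` to `out_channels`.
#'
#' @param in_channels,out_channels channel counts.
#' @param downsample logical; selects the projection/stride-2 variant.
#' @return a `layer_graph`.
#' @export
build_residual_structure <- function(in_channels, out_channels,
                                     downsample = FALSE) {
  if (in_channels < 1 || out_channels < 1) stop_config("channels must be >= 1")
  if (!downsample && in_channels != out_channels) {
    stop_config(
      "plain residual structure requires equal channels (got %d and %d)",
      in_channels, out_channels, subclass = "fusenet_invalid_channels")
  }
  f <- frag_residual("res", "input", in_channels, out_channels,
                     stride = if (downsample) 2 else 1,
                     projection = downsample, module = "Residual structure")
  as_layer_graph(f, in_channels)
}

#' Build one residual stage (RS layer)
#'
#' Stages 1-4 stack two residual structures, stage 5 stacks three. The first
#' structure of each stage is the downsampling variant (its stride is
#' `first_stride`, normally 2); the remaining structures preserve shape.
#'
#' @param index stage index in 1..5.
#' @param in_channels,out_channels channel counts (plan: 3-32-64-128-256-512).
#' @param first_stride stride of the first structure's first convolution;
#'   set to 1 in the no-multiscale-stem ablation to keep branch shapes
#'   aligned.
#' @return a `layer_graph`.
#' @export
build_rs_layer <- function(index, in_channels, out_channels, first_stride = 2) {
  if (!index %in% 1:5) stop_config("RS index must be in 1..5")
  if (!first_stride %in% 1:2) stop_config("first_stride must be 1 or 2")
  f <- frag_rs_layer("rs", "input", index, in_channels, out_channels,
                     first_stride, module = paste0("RS_", index))
  as_layer_graph(f, in_channels)
}

#' Build the multiscale feature-extraction stem (MSF)
#'
#' @param in_channels input channels (3 for RGB).
#' @return a `layer_graph` producing 64 channels at half resolution.
#' @export
build_msf <- function(in_channels = 3) {
  as_layer_graph(frag_msf("msf", "input", in_channels), in_channels)
}

#' Build one multilevel feature-extraction block (MLF)
#'
#' @param in_channels,out_channels channel counts; `out_channels` must equal
#'   `in_channels` or double it.
#' @param feature_reuse logical; sum the outputs of the first three 1x1
#'   convolutions before the fourth.
#' @return a `layer_graph` halving the spatial dimensions.
#' @export
build_mlf <- function(in_channels, out_channels, feature_reuse = TRUE) {
  f <- frag_mlf("mlf", "input", in_channels, out_channels, feature_reuse,
                module = "MLF")
  as_layer_graph(f, in_channels)
}

#' Architecture configuration
#'
#' All switches defining a dual-branch network variant. `rs1_first_stride`
#' defaults to 2, or to 1 when the multiscale stem is disabled while the
#' channel branch is kept (the stem replacement is a stride-1 1x1
#' convolution, so the spatial branch must skip its first downsampling to
#' keep the fusion shapes aligned).
#'
#' @param n_mlf number of multilevel blocks in the channel branch (1..4).
#' @param feature_reuse logical; wire the reuse summation inside each MLF.
#' @param use_msf logical; use the multiscale stem (otherwise a single 1x1
#'   convolution to 64 channels stands in).
#' @param use_channel_branch logical; disable to run the residual spatial
#'   branch plus head alone.
#' @param rs1_first_stride stride (1 or 2) of the first convolution of the
#'   first residual stage.
#' @param num_classes output classes.
#' @param input_channels image channels.
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(n_mlf = 3, feature_reuse = TRUE, use_msf = TRUE,
                        use_channel_branch = TRUE, rs1_first_stride = NULL,
                        num_classes = 2, input_channels = 3) {
  if (!n_mlf %in% 1:4) stop_config("n_mlf must be in 1..4, got %s", n_mlf)
  if (is.null(rs1_first_stride)) {
    rs1_first_stride <- if (use_channel_branch && !use_msf) 1L else 2L
  }
  if (!rs1_first_stride %in% 1:2) stop_config("rs1_first_stride must be 1 or 2")
  if (num_classes < 2) stop_config("num_classes must be >= 2")
  structure(list(n_mlf = as.integer(n_mlf),
                 feature_reuse = isTRUE(feature_reuse),
                 use_msf = isTRUE(use_msf),
                 use_channel_branch = isTRUE(use_channel_branch),
                 rs1_first_stride = as.integer(rs1_first_stride),
                 num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels)),
            class = "arch_config")
}

#' The five standard ablation variants
#'
#' Named configurations covering the ablation grid: spatial branch only;
#' channel branch without multiscale stem, with and without feature reuse
#' (both with `rs1_first_stride = 1`); and the full model with and without
#' feature reuse.
#'
#' @return named list of [arch_config()] objects.
#' @export
ablation_variants <- function() {
  list(
    spatial_only = arch_config(use_channel_branch = FALSE),
    mlf          = arch_config(use_msf = FALSE, feature_reuse = FALSE),
    mlf_reuse    = arch_config(use_msf = FALSE, feature_reuse = TRUE),
    msf_mlf      = arch_config(feature_reuse = FALSE),
    full         = arch_config()
  )
}

# Channel plan of the channel branch: first MLF keeps 64, later ones double.
mlf_channel_plan <- function(n_mlf) {
  outs <- 64L
  if (n_mlf > 1) for (j in 2:n_mlf) outs <- c(outs, 2L * outs[j - 1])
  ins <- c(64L, outs[-n_mlf])
  list(ins = ins, outs = outs)
}

#' Build the full dual-branch network graph
#'
#' The spatial branch stacks five residual stages (channels
#' 32/64/128/256/512). The channel branch applies the multiscale stem and
#' `n_mlf` multilevel blocks, and its output is fused into the spatial branch
#' by element-wise summation after stage `n_mlf + 1`, the unique stage where
#' the shapes match. The head is a 3x3 convolution to 1024 channels, global
#' average pooling, and a fully connected layer to `num_classes`.
#'
#' @param cfg an [arch_config()].
#' @return a `layer_graph` covering the whole network.
#' @examples
#' g <- build_dcfcnn(arch_config())
#' count_trainable_params(g)
#' @export
build_dcfcnn <- function(cfg = arch_config()) {
  stopifnot(inherits(cfg, "arch_config"))
  nodes <- list()
  cur <- "input"
  spatial_out <- c(32L, 64L, 128L, 256L, 512L)
  spatial_in <- c(cfg$input_channels, spatial_out[-5])

  channel_frag <- NULL
  if (cfg$use_channel_branch) {
    if (cfg$use_msf) {
      stem <- frag_msf("msf", "input", cfg$input_channels)
    } else {
      stem <- frag_conv_bn_relu("stem", "input", cfg$input_channels, 64,
                                k = 1, stride = 1, pad = 0, bias = TRUE,
                                module = "Stem", unit = "stem.conv1x1")
    }
    ch_nodes <- stem$nodes
    ch_cur <- stem$output
    plan <- mlf_channel_plan(cfg$n_mlf)
    for (j in seq_len(cfg$n_mlf)) {
      f <- frag_mlf(sprintf("mlf%d", j), ch_cur, plan$ins[j], plan$outs[j],
                    cfg$feature_reuse, module = sprintf("MLF_%d", j),
                    unit_prefix = sprintf("mlf%d", j))
      ch_nodes <- c(ch_nodes, f$nodes)
      ch_cur <- f$output
    }
    channel_frag <- frag(ch_nodes, ch_cur)
  }

  for (i in 1:5) {
    f <- frag_rs_layer(sprintf("rs%d", i), cur, i, spatial_in[i],
                       spatial_out[i],
                       first_stride = if (i == 1) cfg$rs1_first_stride else 2,
                       module = sprintf("RS_%d", i))
    nodes <- c(nodes, f$nodes)
    cur <- f$output
    if (!is.null(channel_frag) && i == cfg$n_mlf + 1) {
      nodes <- c(nodes, channel_frag$nodes,
                 list(node_new("fusion", "add", c(cur, channel_frag$output))))
      cur <- "fusion"
    }
  }

  head <- frag_conv_bn_relu("head", cur, 512, 1024, k = 3, stride = 1,
                            pad = 1, bias = TRUE, module = "Conv",
                            unit = "head.conv")
  nodes <- c(nodes, head$nodes, list(
    node_new("gap", "gap", head$output, module = "AdaptiveAvgPool"),
    node_new("fc", "linear", "gap", module = "Fully connect",
             in_ch = 1024L, out_ch = cfg$num_classes, bias = TRUE)
  ))
  g <- as_layer_graph(frag(nodes, "fc"), cfg$input_channels)
  g$config <- cfg
  g
}

# Trainable elements of one unit as reported by the builder.
node_params <- function(node) {
  switch(node$op,
         conv = prod(node$kernel) * node$in_ch * node$out_ch +
           if (isTRUE(node$bias)) node$out_ch else 0,
         bn = 2 * node$ch,
         linear = node$in_ch * node$out_ch +
           if (isTRUE(node$bias)) node$out_ch else 0,
         0)
}

#' Count trainable parameters of a layer graph
#'
#' Sums the element counts of every trainable tensor: convolution kernels and
#' biases, batch-normalization scale and shift, fully connected weights and
#' bias. The default full network counts 20,949,378 trainable elements.
#'
#' @param graph a `layer_graph`.
#' @return integer-valued count.
#' @export
count_trainable_params <- function(graph) {
  stopifnot(inherits(graph, "layer_graph"))
  sum(vapply(graph$nodes, node_params, 0))
}

fmt_shape <- function(s) paste(s, collapse = "x")

# Shape propagation for one node given input shapes (lists of dims; spatial
# shapes are c(H, W, C), flattened shapes are c(1, C)).
node_out_shape <- function(node, in_shapes) {
  op <- node$op
  if (op == "input") return(in_shapes[[1]])
  s <- in_shapes[[1]]
  if (op %in% c("conv", "maxpool")) {
    if (length(s) != 3) {
      stop_config("node '%s' needs a spatial H x W x C input, got %s",
                  node$name, fmt_shape(s))
    }
    if (op == "conv" && s[3] != node$in_ch) {
      stop_config("node '%s' expects %d input channels, got %d",
                  node$name, node$in_ch, s[3],
                  subclass = "fusenet_shape_mismatch")
    }
    oh <- (s[1] + 2 * node$pad - node$kernel[1]) %/% node$stride + 1
    ow <- (s[2] + 2 * node$pad - node$kernel[2]) %/% node$stride + 1
    if (oh < 1 || ow < 1) {
      stop_config("node '%s' output would be empty for input %s",
                  node$name, fmt_shape(s))
    }
    return(as.integer(c(oh, ow, if (op == "conv") node$out_ch else s[3])))
  }
  if (op == "add") {
    for (sh in in_shapes) {
      if (!identical(sh, s)) {
        stop_config("fusion node '%s' received mismatched shapes %s and %s",
                    node$name, fmt_shape(s), fmt_shape(sh),
                    subclass = "fusenet_shape_mismatch")
      }
    }
    return(s)
  }
  if (op == "gap") return(c(1L, as.integer(s[3])))
  if (op == "linear") {
    if (s[length(s)] != node$in_ch) {
      stop_config("linear node '%s' expects %d features, got %d",
                  node$name, node$in_ch, s[length(s)],
                  subclass = "fusenet_shape_mismatch")
    }
    return(c(1L, as.integer(node$out_ch)))
  }
  s  # bn, relu
}

# Shapes for every node; used by both the symbolic trace and the executor.
infer_shapes <- function(graph, input_shape) {
  shapes <- list()
  for (node in graph$nodes) {
    ins <- if (node$op == "input") list(input_shape) else shapes[node$inputs]
    shapes[[node$name]] <- node_out_shape(node, ins)
  }
  shapes
}

#' Symbolic shape trace of a layer graph
#'
#' Computes, without touching any tensors, the input and output shape of
#' every named module (MSF, MLF_1..k, RS_1..5, Conv, AdaptiveAvgPool, Fully
#' connect) for a given input shape. Fusion nodes are checked (mismatched
#' shapes raise an error naming both) but are not modules of their own.
#'
#' @param graph a `layer_graph`.
#' @param input_shape length-3 integer vector `c(H, W, C)`.
#' @return a data.frame of class `shape_trace` with columns `module`, `input`
#'   and `output` (strings like `"448x448x3"`).
#' @examples
#' shape_trace(build_dcfcnn(arch_config()), c(448, 448, 3))
#' @export
shape_trace <- function(graph, input_shape = c(448, 448, 3)) {
  stopifnot(inherits(graph, "layer_graph"), length(input_shape) == 3)
  shapes <- infer_shapes(graph, as.integer(input_shape))
  mods <- character(0); ins <- character(0); outs <- character(0)
  for (node in graph$nodes) {
    m <- node$module
    if (is.na(m)) next
    out_s <- fmt_shape(shapes[[node$name]])
    if (length(mods) == 0 || mods[length(mods)] != m) {
      mods <- c(mods, m)
      in_name <- node$inputs[1]
      in_s <- if (node$op == "input") fmt_shape(input_shape) else
        fmt_shape(shapes[[in_name]])
      ins <- c(ins, in_s)
      outs <- c(outs, out_s)
    } else {
      outs[length(outs)] <- out_s
    }
  }
  res <- data.frame(module = mods, input = ins, output = outs,
                    stringsAsFactors = FALSE)
  attr(res, "params_total") <- count_trainable_params(graph)
  class(res) <- c("shape_trace", "data.frame")
  res
}

#' @export
print.shape_trace <- function(x, ...) {
  df <- as.data.frame(x)
  w1 <- max(nchar(c("Module", df$module)))
  w2 <- max(nchar(c("Input size", df$input)))
  cat(sprintf(paste0("%-", w1, "s  %-", w2, "s  %s\n"),
              "Module", "Input size", "Output size"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf(paste0("%-", w1, "s  %-", w2, "s  %s\n"),
                df$module[i], df$input[i], df$output[i]))
  }
  cat(sprintf("Trainable params: %s\n",
              format(attr(x, "params_total"), big.mark = ",")))
  invisible(x)
}

#' @export
print.layer_graph <- function(x, ...) {
  cat(sprintf("layer_graph: %d units, %s trainable parameters\n",
              length(x$nodes),
              format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}
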