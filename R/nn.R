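## Tensor engine over the layer graph.
##
## Internal activation layout is (C, H, W, N) double arrays, channel fastest,
## matching the C++ kernels. Images enter as H x W x C; `as_batch()` converts.

#' Initialize network weights
#'
#' Kaiming fan-out normal initialization for convolution kernels, unit scale
#' and zero shift for batch normalization, and uniform
#' `U(-1/sqrt(in), 1/sqrt(in))` for the fully connected layer. Deterministic
#' given the seed.
#'
#' @param graph a `layer_graph`.
#' @param seed integer seed.
#' @return a `dcfcnn_model`: list with `graph`, `params` and `state`.
#' @export
init_model <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "layer_graph"))
  params <- list()
  state <- list()
  with_seed(seed, {
    for (node in graph$nodes) {
      if (node$op == "conv") {
        k <- prod(node$kernel)
        fan_out <- k * node$out_ch
        w <- matrix(rnorm(k * node$in_ch * node$out_ch,
                          sd = sqrt(2 / fan_out)),
                    nrow = k * node$in_ch, ncol = node$out_ch)
        p <- list(W = w)
        if (isTRUE(node$bias)) p$b <- numeric(node$out_ch)
        params[[node$name]] <- p
      } else if (node$op == "bn") {
        params[[node$name]] <- list(gamma = rep(1, node$ch),
                                    beta = numeric(node$ch))
        state[[node$name]] <- list(mean = numeric(node$ch),
                                   var = rep(1, node$ch))
      } else if (node$op == "linear") {
        r <- 1 / sqrt(node$in_ch)
        params[[node$name]] <- list(
          W = matrix(runif(node$in_ch * node$out_ch, -r, r),
                     node$in_ch, node$out_ch),
          b = runif(node$out_ch, -r, r))
      }
    }
  })
  structure(list(graph = graph, params = params, state = state),
            class = "dcfcnn_model")
}

#' @export
print.dcfcnn_model <- function(x, ...) {
  cat(sprintf("dcfcnn_model: %s trainable parameters\n",
              format(count_trainable_params(x$graph), big.mark = ",")))
  invisible(x)
}

#' Stack preprocessed images into a batch tensor
#'
#' @param images list of H x W x C arrays (all the same shape).
#' @return a (C, H, W, N) array for the forward pass.
#' @export
as_batch <- function(images) {
  stopifnot(length(images) > 0)
  d <- dim(images[[1]])
  out <- array(0, c(d[3], d[1], d[2], length(images)))
  for (i in seq_along(images)) {
    out[, , , i] <- aperm(images[[i]], c(3, 1, 2))
  }
  out
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Forward pass over the graph. Returns activations (named list), the output,
# updated batch-norm state, per-node auxiliary caches (when train = TRUE) and
# any captured unit activations.
nn_forward <- function(model, x, train = FALSE, capture = character(0)) {
  graph <- model$graph
  params <- model$params
  state <- model$state
  acts <- new.env(parent = emptyenv())
  aux <- new.env(parent = emptyenv())
  captured <- list()
  for (node in graph$nodes) {
    nm <- node$name
    y <- switch(
      node$op,
      input = {
        if (dim(x)[1] != node$ch) {
          stop_data("network expects %d input channels, got %d",
                    node$ch, dim(x)[1], subclass = "fusenet_shape_mismatch")
        }
        x
      },
      conv = {
        xin <- get(node$inputs, envir = acts)
        p <- params[[nm]]
        .cpp_conv_fwd(xin, dim(xin), p$W, p$b, node$kernel[1], node$kernel[2],
                      node$stride, node$pad)
      },
      bn = {
        xin <- get(node$inputs, envir = acts)
        p <- params[[nm]]
        st <- state[[nm]]
        r <- .cpp_bn_fwd(xin, dim(xin), p$gamma, p$beta, st$mean, st$var,
                         train, bn_momentum, bn_eps)
        if (train) {
          state[[nm]] <- list(mean = r$run_mean, var = r$run_var)
          assign(nm, list(mu = r$mu, inv = r$inv), envir = aux)
        }
        r$y
      },
      relu = .cpp_relu_fwd(get(node$inputs, envir = acts)),
      maxpool = {
        xin <- get(node$inputs, envir = acts)
        r <- .cpp_maxpool_fwd(xin, dim(xin), node$kernel[1], node$stride,
                              node$pad)
        assign(nm, r$idx, envir = aux)
        r$y
      },
      add = {
        y0 <- get(node$inputs[1], envir = acts)
        for (inp in node$inputs[-1]) {
          yi <- get(inp, envir = acts)
          if (!identical(dim(yi), dim(y0))) {
            stop_config("fusion node '%s' received mismatched shapes %s and %s",
                        nm, fmt_shape(dim(y0)), fmt_shape(dim(yi)),
                        subclass = "fusenet_shape_mismatch")
          }
          y0 <- y0 + yi
        }
        y0
      },
      gap = {
        xin <- get(node$inputs, envir = acts)
        .cpp_gap_fwd(xin, dim(xin))
      },
      linear = {
        xin <- get(node$inputs, envir = acts)  # (C, N)
        p <- params[[nm]]
        crossprod(p$W, xin) + p$b
      },
      stop_numeric("unknown op '%s'", node$op)
    )
    assign(nm, y, envir = acts)
    if (!is.na(node$unit) && node$unit %in% capture) {
      captured[[node$unit]] <- y
    }
  }
  list(out = get(graph$output, envir = acts), acts = acts, aux = aux,
       state = state, captured = captured)
}

# Reverse-mode pass. `dout` is the gradient at the graph output.
nn_backward <- function(model, fwd, dout) {
  graph <- model$graph
  params <- model$params
  acts <- fwd$acts
  aux <- fwd$aux
  dacts <- new.env(parent = emptyenv())
  assign(graph$output, dout, envir = dacts)
  grads <- list()
  rev_nodes <- rev(graph$nodes)
  for (node in rev_nodes) {
    nm <- node$name
    if (!exists(nm, envir = dacts, inherits = FALSE)) next  # dead branch
    dy <- get(nm, envir = dacts)
    rm(list = nm, envir = dacts)
    push <- function(target, g) {
      if (exists(target, envir = dacts, inherits = FALSE)) {
        assign(target, get(target, envir = dacts) + g, envir = dacts)
      } else {
        assign(target, g, envir = dacts)
      }
    }
    switch(
      node$op,
      input = NULL,
      conv = {
        xin <- get(node$inputs, envir = acts)
        need_dx <- node$inputs != graph$input
        r <- .cpp_conv_bwd(xin, dim(xin), params[[nm]]$W, dy,
                           node$kernel[1], node$kernel[2], node$stride,
                           node$pad, isTRUE(node$bias), need_dx)
        grads[[nm]] <- if (isTRUE(node$bias)) list(W = r$dW, b = r$db) else
          list(W = r$dW)
        if (need_dx) push(node$inputs, r$dx)
      },
      bn = {
        xin <- get(node$inputs, envir = acts)
        cache <- get(nm, envir = aux)
        r <- .cpp_bn_bwd(xin, dim(xin), dy, params[[nm]]$gamma,
                         cache$mu, cache$inv)
        grads[[nm]] <- list(gamma = r$dgamma, beta = r$dbeta)
        push(node$inputs, r$dx)
      },
      relu = {
        xin <- get(node$inputs, envir = acts)
        push(node$inputs, .cpp_relu_bwd(xin, dy))
      },
      maxpool = {
        xin <- get(node$inputs, envir = acts)
        push(node$inputs, .cpp_maxpool_bwd(dy, get(nm, envir = aux), dim(xin)))
      },
      add = {
        for (inp in node$inputs) push(inp, dy)
      },
      gap = {
        xin <- get(node$inputs, envir = acts)
        push(node$inputs, .cpp_gap_bwd(dy, dim(xin)))
      },
      linear = {
        xin <- get(node$inputs, envir = acts)
        grads[[nm]] <- list(W = xin %*% t(dy), b = rowSums(dy))
        push(node$inputs, params[[nm]]$W %*% dy)
      },
      NULL
    )
  }
  grads
}

# Softmax cross-entropy over logits (K x N); labels are integers in 1..K.
softmax_xent <- function(logits, labels) {
  K <- nrow(logits)
  N <- ncol(logits)
  m <- apply(logits, 2, max)
  z <- exp(sweep(logits, 2, m))
  p <- sweep(z, 2, colSums(z), "/")
  picked <- p[cbind(labels, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-15)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(N))] <- dlogits[cbind(labels, seq_len(N))] - 1
  dlogits <- dlogits / N
  list(loss = loss, probs = p, dlogits = dlogits)
}

#' Class probabilities for a batch
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' applies the softmax. The malignant score of a sample is the probability of
#' class 2.
#'
#' @param model a `dcfcnn_model`.
#' @param x batch tensor from [as_batch()].
#' @return matrix (num_classes x N) of probabilities.
#' @export
predict_proba <- function(model, x) {
  out <- nn_forward(model, x, train = FALSE)$out
  z <- exp(sweep(out, 2, apply(out, 2, max)))
  sweep(z, 2, colSums(z), "/")
}
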