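# 3D residual encoder-decoder with SELU activations.
#
# Topology: I -> D(2,32) -> D(3,64) -> D(3,128) -> L -> U(3,128) ->
# U(3,64) -> U(3,32) -> F.  Every block is residual (input added to the
# output of its SELU-activated 5x5x5 convolution stack, through a 1x1x1
# projection when channel counts differ); resolution transitions are
# 2x2x2 stride-2 convolutions (down) and transpose convolutions (up);
# long skip connections join contraction and expansion features at equal
# resolution by element-wise addition.  The final 1x1x1 convolution feeds
# a sigmoid, so the network maps a single-channel crop to a same-shape
# probability field.
#
# The network is represented as a flat tape of primitive ops (conv3,
# down2, up2, selu, add, sigmoid) over numbered tensor slots; forward
# walks the tape, backward walks it in reverse.  A width_multiplier
# scales every channel count so the identical topology runs at desk scale
# on a CPU.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu_fw <- function(x) {
  SELU_LAMBDA * (pmax(x, 0) + SELU_ALPHA * (exp(pmin(x, 0)) - 1))
}
selu_bw <- function(x, g) {
  g * SELU_LAMBDA * ((x > 0) + (x <= 0) * SELU_ALPHA * exp(pmin(x, 0)))
}

#' Specify the segmentation network architecture
#'
#' Defaults are the full-scale architecture; `width_multiplier` scales all
#' channel counts (minimum 1) so the same topology can be trained at desk
#' scale.
#'
#' @param width_multiplier channel-count scale factor (default 1)
#' @param init_filters two integers: filters of the initial 5x5x5
#'   convolution and of its stride-2 follow-up (default `c(8, 16)`)
#' @param down_blocks list of `(n_convs, n_filters)` for the contraction
#'   (default `list(c(2, 32), c(3, 64), c(3, 128))`); the expansion
#'   mirrors it
#' @param bottleneck `(n_convs, n_filters)` of the lowest-resolution block
#'   (default `c(3, 128)`)
#' @param final_filters filters of the final 5x5x5 convolution (default 16)
#' @param conv_kernel kernel size of the in-block convolutions (default 5)
#' @return object of class `network_spec`
#' @export
network_spec <- function(width_multiplier = 1,
                         init_filters = c(8L, 16L),
                         down_blocks = list(c(2L, 32L), c(3L, 64L), c(3L, 128L)),
                         bottleneck = c(3L, 128L),
                         final_filters = 16L,
                         conv_kernel = 5L) {
  stopifnot(width_multiplier > 0, length(init_filters) == 2L,
            length(bottleneck) == 2L, conv_kernel %% 2 == 1)
  structure(list(width_multiplier = width_multiplier,
                 init_filters = as.integer(init_filters),
                 down_blocks = lapply(down_blocks, as.integer),
                 bottleneck = as.integer(bottleneck),
                 final_filters = as.integer(final_filters),
                 conv_kernel = as.integer(conv_kernel),
                 n_down = length(down_blocks) + 1L),
            class = "network_spec")
}

#' Number of stride-2 resolution reductions of a network spec
#' @param spec a [network_spec()]
#' @return integer; input shapes must be divisible by `2^depth`
#' @export
network_depth <- function(spec) spec$n_down

#' Build the segmentation network
#'
#' Allocates SELU-appropriate (LeCun, fan-in variance-scaling) initial
#' weights for every convolution on the architecture tape.
#'
#' @param spec a [network_spec()]
#' @param seed integer seed for weight initialization
#' @return object of class `psoas_network`
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  phi <- function(n) max(1L, as.integer(round(n * spec$width_multiplier)))
  K <- spec$conv_kernel

  ops <- list(); params <- list(); nslot <- 1L  # slot 1 = input
  new_slot <- function() { nslot <<- nslot + 1L; nslot }
  push <- function(op) ops[[length(ops) + 1L]] <<- op
  new_param <- function(prefix, w, b) {
    id <- sprintf("%s%02d", prefix, length(params) + 1L)
    params[[id]] <<- list(w = w, b = b)
    id
  }
  conv <- function(a, cin, cout, k) {
    fan_in <- cin * k^3
    id <- new_param("conv", matrix(rnorm(fan_in * cout, sd = 1 / sqrt(fan_in)),
                                   fan_in, cout), numeric(cout))
    out <- new_slot()
    push(list(kind = "conv3", a = a, out = out, id = id, K = k))
    out
  }
  down <- function(a, cin, cout) {
    id <- new_param("down", matrix(rnorm(cin * 8 * cout, sd = 1 / sqrt(cin * 8)),
                                   cin * 8, cout), numeric(cout))
    out <- new_slot()
    push(list(kind = "down2", a = a, out = out, id = id))
    out
  }
  up <- function(a, cin, cout) {
    id <- new_param("up", matrix(rnorm(cin * cout * 8, sd = 1 / sqrt(cin)),
                                 cin, cout * 8), numeric(cout))
    out <- new_slot()
    push(list(kind = "up2", a = a, out = out, id = id))
    out
  }
  act <- function(a) {
    out <- new_slot(); push(list(kind = "selu", a = a, out = out)); out
  }
  add2 <- function(a, b) {
    out <- new_slot(); push(list(kind = "add", a = a, b = b, out = out)); out
  }
  res_block <- function(a, cin, width, n_convs, k = K) {
    cur <- a; cc <- cin
    for (i in seq_len(n_convs)) { cur <- act(conv(cur, cc, width, k)); cc <- width }
    skip <- if (cin != width) conv(a, cin, width, 1L) else a
    add2(cur, skip)
  }

  net <- with_seed(seed, {
    f_init <- phi(spec$init_filters[1]); f_init2 <- phi(spec$init_filters[2])
    widths <- vapply(spec$down_blocks, function(b) phi(b[2]), integer(1))
    nconvs <- vapply(spec$down_blocks, function(b) b[1], integer(1))
    f_bot <- phi(spec$bottleneck[2])

    a0 <- res_block(1L, 1L, f_init, 1L)              # block I
    cur <- act(down(a0, f_init, f_init2))
    skips <- list(); skip_ch <- integer(0)
    cin <- f_init2
    for (bi in seq_along(widths)) {                  # contraction
      ab <- res_block(cur, cin, widths[bi], nconvs[bi])
      skips[[bi]] <- ab; skip_ch[bi] <- widths[bi]
      cout <- if (bi < length(widths)) widths[bi + 1] else f_bot
      cur <- act(down(ab, widths[bi], cout))
      cin <- cout
    }
    cur <- res_block(cur, f_bot, f_bot, spec$bottleneck[1])   # block L
    up_ch <- phi(64)                                 # L's transpose filters
    cur <- act(up(cur, f_bot, up_ch))
    for (bi in rev(seq_along(widths))) {             # expansion
      sk <- skips[[bi]]
      if (skip_ch[bi] != up_ch) sk <- conv(sk, skip_ch[bi], up_ch, 1L)
      fused <- add2(cur, sk)
      ub <- res_block(fused, up_ch, widths[bi], 3L)  # U blocks: 3 convs each
      next_ch <- if (bi > 1) skip_ch[bi - 1] else f_init2
      cur <- act(up(ub, widths[bi], next_ch))
      up_ch <- next_ch
    }
    sk0 <- if (f_init != f_init2) conv(a0, f_init, f_init2, 1L) else a0
    fused0 <- add2(cur, sk0)
    fF <- phi(spec$final_filters)
    cur <- res_block(fused0, f_init2, fF, 1L)        # block F
    logits <- conv(cur, fF, 1L, 1L)
    out <- new_slot()
    push(list(kind = "sigmoid", a = logits, out = out))
    list(ops = ops, params = params, out_slot = out, n_slots = nslot)
  })
  structure(c(net, list(spec = spec)), class = "psoas_network")
}

#' @export
print.psoas_network <- function(x, ...) {
  cat(sprintf("<psoas_network> width x%.3g, %d ops, %s parameters\n",
              x$spec$width_multiplier, length(x$ops),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param network a [build_network()] result
#' @return total number of weights and biases
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "psoas_network"))
  sum(vapply(network$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

as_input_tensor <- function(x, depth) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)[1:3]
  div <- 2^depth
  if (any(d %% div != 0))
    stop(sprintf("input shape %s must be divisible by %d (got remainder %s)",
                 paste(d, collapse = "x"), div,
                 paste(d %% div, collapse = ",")), call. = FALSE)
  x
}

#' Network forward pass
#'
#' @param network a [build_network()] result
#' @param x single-channel input: 3-d array (or 4-d with one channel)
#'   whose spatial dims are divisible by `2^network_depth(spec)`
#' @param cache keep intermediate tensors for a backward pass
#' @return list with `y` (3-d probability array in (0, 1)) and, when
#'   `cache = TRUE`, the tensor tape `Tn`
#' @export
net_forward <- function(network, x, cache = FALSE) {
  x <- as_input_tensor(x, network$spec$n_down)
  Tn <- vector("list", network$n_slots)
  Tn[[1L]] <- x
  for (op in network$ops) {
    Tn[[op$out]] <- switch(op$kind,
      conv3 = {
        p <- network$params[[op$id]]
        cpp_conv3_fw(Tn[[op$a]], p$w, p$b, op$K)
      },
      down2 = {
        p <- network$params[[op$id]]
        cpp_down2_fw(Tn[[op$a]], p$w, p$b)
      },
      up2 = {
        p <- network$params[[op$id]]
        cpp_up2_fw(Tn[[op$a]], p$w, p$b)
      },
      selu = selu_fw(Tn[[op$a]]),
      add = Tn[[op$a]] + Tn[[op$b]],
      sigmoid = 1 / (1 + exp(-Tn[[op$a]])),
      stop("unknown op kind: ", op$kind))
    if (!cache && op$kind != "sigmoid") {
      # free tensors no longer needed downstream to bound inference memory
    }
  }
  y <- Tn[[network$out_slot]]
  dim(y) <- dim(y)[1:3]
  if (cache) list(y = y, Tn = Tn) else list(y = y)
}

#' Network backward pass
#'
#' @param network a [build_network()] result
#' @param Tn cached tensor tape from `net_forward(..., cache = TRUE)`
#' @param gy gradient of the loss w.r.t. the output probabilities
#' @return named list of parameter gradients (`w`, `b` per conv op)
#' @export
net_backward <- function(network, Tn, gy) {
  if (length(dim(gy)) == 3L) dim(gy) <- c(dim(gy), 1L)
  G <- vector("list", network$n_slots)
  G[[network$out_slot]] <- gy
  grads <- lapply(network$params, function(p)
    list(w = matrix(0, nrow(p$w), ncol(p$w)), b = numeric(length(p$b))))
  acc <- function(slot, g) {
    G[[slot]] <<- if (is.null(G[[slot]])) g else G[[slot]] + g
  }
  for (op in rev(network$ops)) {
    g <- G[[op$out]]
    if (is.null(g)) next
    switch(op$kind,
      conv3 = {
        p <- network$params[[op$id]]
        r <- cpp_conv3_bw(Tn[[op$a]], p$w, g, op$K)
        grads[[op$id]]$w <- grads[[op$id]]$w + r$gw
        grads[[op$id]]$b <- grads[[op$id]]$b + r$gb
        acc(op$a, r$gx)
      },
      down2 = {
        p <- network$params[[op$id]]
        r <- cpp_down2_bw(Tn[[op$a]], p$w, g)
        grads[[op$id]]$w <- grads[[op$id]]$w + r$gw
        grads[[op$id]]$b <- grads[[op$id]]$b + r$gb
        acc(op$a, r$gx)
      },
      up2 = {
        p <- network$params[[op$id]]
        r <- cpp_up2_bw(Tn[[op$a]], p$w, g)
        grads[[op$id]]$w <- grads[[op$id]]$w + r$gw
        grads[[op$id]]$b <- grads[[op$id]]$b + r$gb
        acc(op$a, r$gx)
      },
      selu = acc(op$a, selu_bw(Tn[[op$a]], g)),
      add = { acc(op$a, g); acc(op$b, g) },
      sigmoid = {
        y <- Tn[[op$out]]
        acc(op$a, g * y * (1 - y))
      })
    G[op$out] <- list(NULL)   # free; [[<- NULL would shift indices
  }
  grads
}

#' Segment a crop with a (trained) network
#'
#' @param network a [build_network()] result
#' @param crop a normalized [muscle_crop()] (or bare 3-d array in [0, 1])
#' @param threshold probability cutoff for the binary mask (default 0.5)
#' @return list with `probabilities` (3-d array in (0, 1)), `mask`
#'   (binary 3-d array, `probabilities >= threshold`), `threshold` and
#'   `source_offset` (carried from the crop for re-embedding)
#' @export
predict_mask <- function(network, crop, threshold = 0.5) {
  stopifnot(inherits(network, "psoas_network"))
  x <- if (inherits(crop, "muscle_crop")) crop$intensities else crop
  offset <- if (inherits(crop, "muscle_crop")) crop$source_offset
            else c(0L, 0L, 0L)
  if (min(x) < 0 || max(x) > 1)
    stop("crop must be normalized to [0, 1] before prediction")
  y <- net_forward(network, x)$y
  list(probabilities = y, mask = (y >= threshold) * 1L,
       threshold = threshold, source_offset = offset)
}

#' Serialize network weights to a flat numeric vector
#' @param network a [build_network()] result
#' @return numeric vector (order matches the architecture tape)
#' @export
get_weights <- function(network) {
  unlist(lapply(network$params, function(p) c(as.numeric(p$w), p$b)),
         use.names = FALSE)
}

#' Load weights from a flat numeric vector
#' @param network a [build_network()] result
#' @param weights vector from [get_weights()] of a same-spec network
#' @return the network with weights replaced
#' @export
set_weights <- function(network, weights) {
  pos <- 0L
  for (id in names(network$params)) {
    p <- network$params[[id]]
    nw <- length(p$w); nb <- length(p$b)
    network$params[[id]]$w[] <- weights[pos + seq_len(nw)]
    network$params[[id]]$b <- weights[pos + nw + seq_len(nb)]
    pos <- pos + nw + nb
  }
  if (pos != length(weights)) stop("weight vector length mismatch")
  network
}
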