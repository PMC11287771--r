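## Depth-wise spatial feature extractor (DSFE).
##
## Three convolution blocks, each followed by 2x2 max pooling; LeakyReLU
## after every convolution; frames are processed independently. With base
## width c the channel chain is 2 -> c -> c | c -> 2c -> 2c | 2c -> 6c -> 6c
## (the reference width c = 32 gives 2 -> 32/32/64/64/192/192). The second
## layer of block 1 is the composite DS-Conv2d:
##
##   DS-Conv2d(x) = Conv2d_3x3(x) (+) DW-D-Conv2d(DW-Conv2d(x))
##
## where the depth-wise branches convolve each channel independently, the
## dilated depth-wise stage uses dilation 2, and (+) is the elementwise sum.
## Note on padding: the dilated depth-wise stage uses padding 2
## (= dilation * (kernel - 1) / 2) so both branches preserve H x W, a
## requirement of the elementwise sum; every convolution is size-preserving
## and pooling alone downsamples.

#' Convolution-stack specification for the DSFE
#'
#' @param base_channels width of block 1 (reference model: 32; tiny test
#'   models divide this down).
#' @param ds_placement list of logical vectors (`block1`, `block2`, `block3`,
#'   two entries each) flagging which layers use the composite DS-Conv2d
#'   operator; the default places it in the second layer of block 1.
#' @param leaky_slope negative slope of the LeakyReLU activations, in (0, 1).
#' @param dsfe logical ablation switch: `FALSE` replaces every DS-Conv2d by a
#'   plain convolution with the same channel signature.
#' @return object of class `"conv_stack_spec"`.
#' @export
conv_stack_spec <- function(base_channels = 32L,
                            ds_placement = list(block1 = c(FALSE, TRUE),
                                                block2 = c(FALSE, FALSE),
                                                block3 = c(FALSE, FALSE)),
                            leaky_slope = 0.01, dsfe = TRUE) {
  stopifnot_scalar(base_channels, "base_channels", positive = TRUE)
  if (!(leaky_slope > 0 && leaky_slope < 1))
    stop("leaky_slope must lie in (0, 1)")
  c1 <- as.integer(base_channels)
  chain <- list(c(2L, c1), c(c1, c1),
                c(c1, 2L * c1), c(2L * c1, 2L * c1),
                c(2L * c1, 6L * c1), c(6L * c1, 6L * c1))
  kern <- c(5L, 3L, 3L, 3L, 3L, 3L)
  ds <- unlist(ds_placement[c("block1", "block2", "block3")])
  layers <- lapply(seq_len(6), function(i) {
    list(in_c = chain[[i]][1], out_c = chain[[i]][2], kernel = kern[i],
         pad = (kern[i] - 1L) %/% 2L,
         ds = isTRUE(dsfe) && isTRUE(ds[i]) && chain[[i]][1] == chain[[i]][2])
  })
  structure(list(base_channels = c1, layers = layers,
                 leaky_slope = leaky_slope, out_channels = 6L * c1),
            class = "conv_stack_spec")
}

#' Layer table of a convolution-stack specification
#'
#' @param spec a [conv_stack_spec()].
#' @return data frame with one row per layer (block, layer type, channels,
#'   kernel, dilation, padding), suitable for printing.
#' @export
describe_conv_stack <- function(spec) {
  blocks <- rep(paste0("Block", 1:3), each = 2)
  rows <- lapply(seq_len(6), function(i) {
    l <- spec$layers[[i]]
    data.frame(block = blocks[i],
               layer = if (l$ds) "DS-Conv2d" else "Conv2d",
               in_c = l$in_c, out_c = l$out_c, kernel = l$kernel,
               dilation = if (l$ds) 2L else 1L, padding = l$pad,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

dsfe_init <- function(spec, seed = 1L) {
  with_seed(seed, lapply(spec$layers, function(l) {
    if (l$ds) {
      list(plain = init_conv(3, 3, l$in_c, l$out_c),
           dw = init_dwconv(3, l$in_c),
           dwd = init_dwconv(3, l$in_c))
    } else {
      init_conv(l$kernel, l$kernel, l$in_c, l$out_c)
    }
  }))
}

#' Composite depth-wise convolution operator
#'
#' `DS-Conv2d(x) = Conv2d(x) + DW-D-Conv2d(DW-Conv2d(x))`: a plain 3x3
#' convolution summed elementwise with a per-channel (depth-wise) 3x3
#' convolution followed by a per-channel dilated 3x3 convolution
#' (dilation 2). All stages preserve the spatial size; the composed
#' depth-wise path has a 7x7 receptive field.
#'
#' @param x input array `(H, W, C)` or `(H, W, C, N)`.
#' @param weights list with components `plain` (`list(W, b)`, `W` of shape
#'   `3 x 3 x C x C`), `dw` and `dwd` (`list(W, b)`, `W` of shape `3 x 3 x C`).
#' @return array of the same spatial size and channel count as `x`.
#' @export
ds_conv2d <- function(x, weights) {
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  y <- conv_fwd(x, weights$plain$W, weights$plain$b, pad = 1L) +
    dwconv_fwd(dwconv_fwd(x, weights$dw$W, weights$dw$b, pad = 1L),
               weights$dwd$W, weights$dwd$b, pad = 2L, dil = 2L)
  if (squeeze) dim(y) <- dim(y)[1:3]
  y
}

## cached forward through the full stack; x is (H, W, 2, N)
dsfe_fwd_cached <- function(par, x, spec) {
  a <- spec$leaky_slope
  cache <- list()
  cur <- x
  li <- 0L
  for (b in 1:3) {
    for (j in 1:2) {
      li <- li + 1L
      l <- spec$layers[[li]]; p <- par[[li]]
      if (l$ds) {
        mid <- dwconv_fwd(cur, p$dw$W, p$dw$b, pad = 1L)
        cf <- conv_fwd_keep(cur, p$plain$W, p$plain$b, pad = 1L)
        pre <- cf$y + dwconv_fwd(mid, p$dwd$W, p$dwd$b, pad = 2L, dil = 2L)
        cache[[paste0("L", li)]] <- list(x = cur, mid = mid, pre = pre,
                                         col = cf$col, ds = TRUE)
      } else {
        cf <- conv_fwd_keep(cur, p$W, p$b, pad = l$pad)
        pre <- cf$y
        cache[[paste0("L", li)]] <- list(x = cur, pre = pre, col = cf$col,
                                         ds = FALSE)
      }
      cur <- leaky_relu(pre, a)
    }
    pl <- maxpool_fwd(cur)
    cache[[paste0("pool", b)]] <- list(idx = pl$idx, xdim = dim(cur))
    cur <- pl$y
  }
  list(y = cur, cache = cache)
}

dsfe_bwd <- function(par, cache, spec, dy, need_dx = FALSE) {
  a <- spec$leaky_slope
  grads <- vector("list", 6L)
  cur <- dy
  li <- 6L
  for (b in 3:1) {
    pc <- cache[[paste0("pool", b)]]
    cur <- maxpool_bwd(pc$idx, cur, pc$xdim)
    for (j in 2:1) {
      cc <- cache[[paste0("L", li)]]; p <- par[[li]]
      cur <- lrelu_bwd(cc$pre, cur, a)
      first <- li == 1L
      if (cc$ds) {
        gd <- dwconv_bwd(cc$mid, p$dwd$W, cur, pad = 2L, dil = 2L, need_dx = TRUE)
        g1 <- dwconv_bwd(cc$x, p$dw$W, gd$dx, pad = 1L,
                         need_dx = !first || need_dx)
        gp <- conv_bwd_cached(cc$col, cc$x, p$plain$W, cur, pad = 1L,
                              need_dx = !first || need_dx)
        grads[[li]] <- list(plain = list(W = gp$dw, b = gp$db),
                            dw = list(W = g1$dw, b = g1$db),
                            dwd = list(W = gd$dw, b = gd$db))
        cur <- if (!first || need_dx) gp$dx + g1$dx else NULL
      } else {
        l <- spec$layers[[li]]
        g <- conv_bwd_cached(cc$col, cc$x, p$W, cur, pad = l$pad,
                             need_dx = !first || need_dx)
        grads[[li]] <- list(W = g$dw, b = g$db)
        cur <- if (!first || need_dx) g$dx else NULL
      }
      li <- li - 1L
    }
  }
  list(grads = grads, dx = cur)
}

#' DSFE forward pass
#'
#' Runs a stack of dual-channel frames through the three convolution blocks.
#' Frames are processed independently (no cross-frame mixing): an input of T
#' frames at 2 x 128 x 128 yields T frame-wise feature maps of
#' `6 * base_channels` channels at 16 x 16.
#'
#' @param x array `(H, W, 2, T)` (or `(H, W, 2)` for a single frame) with
#'   `H = W = 128` for the reference geometry.
#' @param params parameter list from an initialised or trained model; if
#'   `NULL`, parameters are drawn with `seed`.
#' @param spec a [conv_stack_spec()].
#' @param seed seed for parameter initialisation when `params` is `NULL`.
#' @return array `(H/8, W/8, out_channels, T)`.
#' @export
dsfe_forward <- function(x, params = NULL, spec = conv_stack_spec(), seed = 1L) {
  squeeze <- length(dim(x)) == 3L
  if (squeeze) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != spec$layers[[1]]$in_c)
    stop(sprintf("input has %d channels; expected %d", dim(x)[3],
                 spec$layers[[1]]$in_c))
  params <- params %||% dsfe_init(spec, seed)
  y <- dsfe_fwd_cached(params, x, spec)$y
  if (squeeze) dim(y) <- dim(y)[1:3]
  y
}

## ---- horizontal partition pooling ---------------------------------------

## internal: fmap (H, W, C, N) -> F (C, p, N) with max+mean strip descriptors
hp_fwd <- function(fmap, p) {
  d <- dim(fmap); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (H %% p != 0) stop(sprintf("p = %d does not divide feature height %d", p, H))
  sh <- H %/% p
  FF <- array(0, c(C, p, N))
  amax <- vector("list", p)
  for (j in seq_len(p)) {
    strip <- fmap[(j - 1) * sh + seq_len(sh), , , , drop = FALSE]
    m <- matrix(strip, sh * W, C * N)
    am <- max.col(t(m), ties.method = "first")
    mx <- m[cbind(am, seq_len(C * N))]
    FF[, j, ] <- mx + colMeans(m)
    amax[[j]] <- am
  }
  list(F = FF, cache = list(amax = amax, dim = d, p = p, sh = sh))
}

hp_bwd <- function(cache, dF) {
  d <- cache$dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  p <- cache$p; sh <- cache$sh
  dmap <- array(0, d)
  for (j in seq_len(p)) {
    g <- as.vector(dF[, j, ])                    # length C*N
    dm <- matrix(rep(g / (sh * W), each = sh * W), sh * W, C * N)
    dm[cbind(cache$amax[[j]], seq_len(C * N))] <-
      dm[cbind(cache$amax[[j]], seq_len(C * N))] + g
    dmap[(j - 1) * sh + seq_len(sh), , , ] <- array(dm, c(sh, W, C, N))
  }
  dmap
}

#' Horizontal partition pooling
#'
#' Splits the feature-map height into `p` equal strips and pools every strip
#' into a per-part channel descriptor: elementwise (max over strip pixels) +
#' (mean over strip pixels).
#'
#' @param fmap array `(H, W, C, T)` of frame-wise feature maps.
#' @param p number of horizontal parts; must divide `H`.
#' @return array `(T, C, p)`: the part feature tensor F_HP.
#' @export
horizontal_partition <- function(fmap, p) {
  if (length(dim(fmap)) == 3L) dim(fmap) <- c(dim(fmap), 1L)
  aperm(hp_fwd(fmap, p)$F, c(3, 1, 2))
}
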