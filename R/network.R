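#' Configuration of the calcification segmentation network
#'
#' An encoder-decoder in the UNet family, specialised for tiny bright
#' lesions. The encoder is one stride-1 convolutional block (so
#' micro-calcifications are never downsampled away at the input), four
#' fused-MBConv blocks (each preceded by 2x2 max pooling) and two
#' tokenized-MLP blocks (each with a stride-2 patch embedding); the decoder
#' mirrors it with two tokenized-MLP blocks and four convolutional blocks,
#' each upsampling by a learnable 2x2 transposed convolution, with skip
#' connections merged by concatenation at every resolution, and a
#' single-channel sigmoid head.
#'
#' @param input_size tile side in px; must be divisible by 64 (six
#'   halvings). Default 512.
#' @param encoder_channels 7 channel widths, default
#'   `c(64, 64, 128, 256, 512, 1024, 2048)`.
#' @param decoder_channels 6 channel widths, default
#'   `c(2048, 1024, 512, 256, 128, 64)` (first entry is the bottleneck
#'   input).
#' @param width_divisor integer >= 1 dividing every channel width, so the
#'   same architecture can be exercised at desk scale; 1 reproduces the full
#'   schedule.
#' @param se_reduction squeeze-and-excitation reduction ratio (default 4).
#' @param expansion fused-MBConv expansion factor (default 4).
#' @param token_dim_ratio tokenized-MLP hidden width as a fraction of the
#'   block channels (default 1).
#' @param shift_size spatial shift of the tokenized-MLP shifted projections
#'   in px (default 5).
#' @param skip_merge only `"concat"` (concatenation + convolution) is
#'   implemented; `"add"` is rejected at build time.
#' @return a `network_config` list.
#' @export
network_config <- function(input_size = 512,
                           encoder_channels = c(64, 64, 128, 256, 512,
                                                1024, 2048),
                           decoder_channels = c(2048, 1024, 512, 256,
                                                128, 64),
                           width_divisor = 1,
                           se_reduction = 4,
                           expansion = 4,
                           token_dim_ratio = 1,
                           shift_size = 5,
                           skip_merge = "concat") {
  if (length(encoder_channels) != 7)
    stop("network_config: encoder_channels must have 7 entries")
  if (length(decoder_channels) != 6)
    stop("network_config: decoder_channels must have 6 entries")
  if (input_size %% 64 != 0)
    stop("network_config: input_size must be divisible by 64")
  if (any(c(encoder_channels, decoder_channels) %% width_divisor != 0))
    stop("network_config: all channels must be divisible by width_divisor")
  if (!identical(skip_merge, "concat"))
    stop("network_config: only skip_merge = 'concat' is implemented")
  structure(list(input_size = as.integer(input_size),
                 encoder_channels = as.integer(encoder_channels),
                 decoder_channels = as.integer(decoder_channels),
                 width_divisor = as.integer(width_divisor),
                 se_reduction = se_reduction, expansion = expansion,
                 token_dim_ratio = token_dim_ratio,
                 shift_size = as.integer(shift_size),
                 skip_merge = skip_merge),
            class = "network_config")
}

new_conv_block <- function(cin, cout) {
  list(type = "conv", conv = init_conv(3, 3, cin, cout), bn = init_bn(cout))
}

new_fmb_block <- function(cin, cout, expansion, se_reduction) {
  e <- max(1L, as.integer(cin * expansion))
  list(type = "fmb", cin = cin, cout = cout,
       expand = init_conv(3, 3, cin, e), bn1 = init_bn(e),
       se = init_se(e, se_reduction),
       proj = init_conv(1, 1, e, cout), bn2 = init_bn(cout))
}

new_mixer <- function(c, token_dim_ratio, shift_size) {
  t <- max(4L, as.integer(round(c * token_dim_ratio)))
  list(tok = init_conv(1, 1, c, t), dw = init_dwconv(t),
       untok = init_conv(1, 1, t, c), ln = init_ln(c),
       shift_size = shift_size)
}

new_tok_block <- function(cin, cout, cfg) {
  list(type = "tok", embed = init_conv(3, 3, cin, cout),
       mixer = new_mixer(cout, cfg$token_dim_ratio, cfg$shift_size))
}

new_dec_block <- function(cin, cout, kind, cfg) {
  b <- list(type = paste0("dec_", kind),
            up = init_convt(cin, cout),
            merge = if (kind == "conv") init_conv(3, 3, 2 * cout, cout)
                    else init_conv(1, 1, 2 * cout, cout),
            bn = init_bn(cout))
  if (kind == "tok")
    b$mixer <- new_mixer(cout, cfg$token_dim_ratio, cfg$shift_size)
  b
}

#' Build the segmentation network
#'
#' @param config a [network_config()].
#' @param seed seed for weight initialisation.
#' @return a `seg_model`: config, parameter blocks, and training metadata.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  ec <- config$encoder_channels %/% config$width_divisor
  dc <- config$decoder_channels %/% config$width_divisor
  dout <- c(dc[-1], dc[6])   # per-decoder-block output channels
  with_seed(seed, {
    blocks <- list(
      b0 = new_conv_block(1, ec[1]),
      b1 = new_fmb_block(ec[1], ec[2], config$expansion, config$se_reduction),
      b2 = new_fmb_block(ec[2], ec[3], config$expansion, config$se_reduction),
      b3 = new_fmb_block(ec[3], ec[4], config$expansion, config$se_reduction),
      b4 = new_fmb_block(ec[4], ec[5], config$expansion, config$se_reduction),
      b5 = new_tok_block(ec[5], ec[6], config),
      b6 = new_tok_block(ec[6], ec[7], config),
      d1 = new_dec_block(dc[1], dout[1], "tok", config),
      d2 = new_dec_block(dout[1], dout[2], "tok", config),
      d3 = new_dec_block(dout[2], dout[3], "conv", config),
      d4 = new_dec_block(dout[3], dout[4], "conv", config),
      d5 = new_dec_block(dout[4], dout[5], "conv", config),
      d6 = new_dec_block(dout[5], dout[6], "conv", config),
      head = list(type = "head", conv = init_conv(1, 1, dout[6], 1))
    )
    # bias the sigmoid head towards the ~1% lesion prior so early training
    # is not spent unlearning a uniform p = 0.5 (standard focal-loss
    # initialisation for rare-foreground detection)
    blocks$head$conv$b[1] <- log(0.01 / 0.99)
    structure(list(config = config, blocks = blocks,
                   meta = list(phase = "untrained", epochs = 0L,
                               seed = as.integer(seed))),
              class = "seg_model")
  })
}

# ---- block forward/backward ------------------------------------------------

conv_block_fw <- function(b, x, training) {
  c1 <- conv_fw(x, b$conv)
  n1 <- bn_fw(c1$y, b$bn, training)
  if (!is.null(n1$update)) { b$bn$rm <- n1$update$rm; b$bn$rv <- n1$update$rv }
  r1 <- relu_fw(n1$y)
  list(y = r1$y, cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache),
       block = b)
}

conv_block_bw <- function(b, cache, gy) {
  g <- relu_bw(cache$r1, gy)
  nb <- bn_bw(b$bn, cache$n1, g)
  cb <- conv_bw(b$conv, cache$c1, nb$gx)
  list(gx = cb$gx,
       grads = list(conv = list(w = cb$gw, b = cb$gb),
                    bn = list(gamma = nb$ggamma, beta = nb$gbeta)))
}

fmb_block_fw <- function(b, x, training) {
  e1 <- conv_fw(x, b$expand)
  n1 <- bn_fw(e1$y, b$bn1, training)
  if (!is.null(n1$update)) { b$bn1$rm <- n1$update$rm; b$bn1$rv <- n1$update$rv }
  a1 <- silu_fw(n1$y)
  s1 <- se_fw(a1$y, b$se)
  p1 <- conv_fw(s1$y, b$proj, kh = 1, kw = 1, pad = 0)
  n2 <- bn_fw(p1$y, b$bn2, training)
  if (!is.null(n2$update)) { b$bn2$rm <- n2$update$rm; b$bn2$rv <- n2$update$rv }
  res <- b$cin == b$cout
  y <- if (res) n2$y + x else n2$y
  list(y = y, cache = list(e1 = e1$cache, n1 = n1$cache, a1 = a1$cache,
                           s1 = s1$cache, p1 = p1$cache, n2 = n2$cache,
                           res = res),
       block = b)
}

fmb_block_bw <- function(b, cache, gy) {
  n2 <- bn_bw(b$bn2, cache$n2, gy)
  p1 <- conv_bw(b$proj, cache$p1, n2$gx)
  s1 <- se_bw(b$se, cache$s1, p1$gx)
  a1 <- silu_bw(cache$a1, s1$gx)
  n1 <- bn_bw(b$bn1, cache$n1, a1)
  e1 <- conv_bw(b$expand, cache$e1, n1$gx)
  gx <- if (cache$res) e1$gx + gy else e1$gx
  list(gx = gx,
       grads = list(expand = list(w = e1$gw, b = e1$gb),
                    bn1 = list(gamma = n1$ggamma, beta = n1$gbeta),
                    se = list(w1 = s1$gw1, b1 = s1$gb1,
                              w2 = s1$gw2, b2 = s1$gb2),
                    proj = list(w = p1$gw, b = p1$gb),
                    bn2 = list(gamma = n2$ggamma, beta = n2$gbeta)))
}

mixer_fw <- function(m, x) {
  sw <- shift_fw(x, axis = 2, size = m$shift_size)
  t1 <- conv_fw(sw$y, m$tok, kh = 1, kw = 1, pad = 0)
  dw <- dwconv_fw(t1$y, m$dw)
  g1 <- gelu_fw(dw$y)
  sh <- shift_fw(g1$y, axis = 1, size = m$shift_size)
  t2 <- conv_fw(sh$y, m$untok, kh = 1, kw = 1, pad = 0)
  ln <- ln_fw(t2$y + x, m$ln)
  list(y = ln$y, cache = list(sw = sw$cache, t1 = t1$cache, dw = dw$cache,
                              g1 = g1$cache, sh = sh$cache, t2 = t2$cache,
                              ln = ln$cache))
}

mixer_bw <- function(m, cache, gy) {
  ln <- ln_bw(m$ln, cache$ln, gy)
  t2 <- conv_bw(m$untok, cache$t2, ln$gx)
  sh <- shift_bw(cache$sh, t2$gx)
  g1 <- gelu_bw(cache$g1, sh)
  dw <- dwconv_bw(m$dw, cache$dw, g1)
  t1 <- conv_bw(m$tok, cache$t1, dw$gx)
  sw <- shift_bw(cache$sw, t1$gx)
  list(gx = sw + ln$gx,   # residual path
       grads = list(tok = list(w = t1$gw, b = t1$gb),
                    dw = list(w = dw$gw, b = dw$gb),
                    untok = list(w = t2$gw, b = t2$gb),
                    ln = list(gamma = ln$ggamma, beta = ln$gbeta)))
}

tok_block_fw <- function(b, x, training) {
  em <- conv_fw(x, b$embed, stride = 2, pad = 1)
  mx <- mixer_fw(b$mixer, em$y)
  list(y = mx$y, cache = list(em = em$cache, mx = mx$cache), block = b)
}

tok_block_bw <- function(b, cache, gy) {
  mx <- mixer_bw(b$mixer, cache$mx, gy)
  em <- conv_bw(b$embed, cache$em, mx$gx)
  list(gx = em$gx,
       grads = list(embed = list(w = em$gw, b = em$gb), mixer = mx$grads))
}

dec_block_fw <- function(b, x, skip, training) {
  up <- convt_fw(x, b$up)
  z <- abind4(up$y, skip)
  mg <- if (b$type == "dec_conv") conv_fw(z, b$merge)
        else conv_fw(z, b$merge, kh = 1, kw = 1, pad = 0)
  n1 <- bn_fw(mg$y, b$bn, training)
  if (!is.null(n1$update)) { b$bn$rm <- n1$update$rm; b$bn$rv <- n1$update$rv }
  r1 <- relu_fw(n1$y)
  y <- r1$y
  mx_cache <- NULL
  if (b$type == "dec_tok") {
    mx <- mixer_fw(b$mixer, y)
    y <- mx$y
    mx_cache <- mx$cache
  }
  list(y = y, cache = list(up = up$cache, mg = mg$cache, n1 = n1$cache,
                           r1 = r1$cache, mx = mx_cache,
                           c_up = dim(up$y)[3]),
       block = b)
}

dec_block_bw <- function(b, cache, gy) {
  grads <- list()
  if (b$type == "dec_tok") {
    mx <- mixer_bw(b$mixer, cache$mx, gy)
    gy <- mx$gx
    grads$mixer <- mx$grads
  }
  g <- relu_bw(cache$r1, gy)
  n1 <- bn_bw(b$bn, cache$n1, g)
  mg <- conv_bw(b$merge, cache$mg, n1$gx)
  cu <- cache$c_up
  gup <- mg$gx[, , seq_len(cu), , drop = FALSE]
  gskip <- mg$gx[, , -seq_len(cu), , drop = FALSE]
  up <- convt_bw(b$up, cache$up, gup)
  grads$up <- list(w = up$gw, b = up$gb)
  grads$merge <- list(w = mg$gw, b = mg$gb)
  grads$bn <- list(gamma = n1$ggamma, beta = n1$gbeta)
  list(gx = up$gx, gskip = gskip, grads = grads)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- whole-network forward/backward ---------------------------------------

net_forward_full <- function(model, x, training = FALSE) {
  b <- model$blocks
  caches <- list()
  f0 <- conv_block_fw(b$b0, x, training); b$b0 <- f0$block
  caches$b0 <- f0$cache
  enc <- list(f0$y)
  xin <- f0$y
  for (i in 1:4) {
    nm <- paste0("b", i)
    pl <- maxpool_fw(xin)
    fb <- fmb_block_fw(b[[nm]], pl$y, training); b[[nm]] <- fb$block
    caches[[nm]] <- list(pool = pl$cache, fmb = fb$cache)
    enc[[i + 1]] <- fb$y
    xin <- fb$y
  }
  for (i in 5:6) {
    nm <- paste0("b", i)
    tb <- tok_block_fw(b[[nm]], xin, training); b[[nm]] <- tb$block
    caches[[nm]] <- tb$cache
    enc[[i + 1]] <- tb$y
    xin <- tb$y
  }
  dec_shapes <- vector("list", 6)
  for (i in 1:6) {
    nm <- paste0("d", i)
    db <- dec_block_fw(b[[nm]], xin, enc[[7 - i]], training)
    b[[nm]] <- db$block
    caches[[nm]] <- db$cache
    xin <- db$y
    dec_shapes[[i]] <- dim(xin)
  }
  hc <- conv_fw(xin, b$head$conv, kh = 1, kw = 1, pad = 0)
  sg <- sigmoid_fw(hc$y)
  caches$head <- list(conv = hc$cache, sg = sg$cache)
  model$blocks <- b
  list(y = sg$y, caches = if (training) caches else NULL,
       enc_shapes = lapply(enc, dim), dec_shapes = dec_shapes,
       model = model)
}

net_backward_full <- function(model, caches, gy) {
  b <- model$blocks
  grads <- list()
  g <- sigmoid_bw(caches$head$sg, gy)
  hc <- conv_bw(b$head$conv, caches$head$conv, g)
  grads$head <- list(conv = list(w = hc$gw, b = hc$gb))
  g <- hc$gx
  gskips <- vector("list", 7)
  for (i in 6:1) {
    nm <- paste0("d", i)
    db <- dec_block_bw(b[[nm]], caches[[nm]], g)
    grads[[nm]] <- db$grads
    gskips[[7 - i]] <- db$gskip
    g <- db$gx
  }
  for (i in 6:5) {
    nm <- paste0("b", i)
    if (!is.null(gskips[[i + 1]])) g <- g + gskips[[i + 1]]
    tb <- tok_block_bw(b[[nm]], caches[[nm]], g)
    grads[[nm]] <- tb$grads
    g <- tb$gx
  }
  for (i in 4:1) {
    nm <- paste0("b", i)
    g <- g + gskips[[i + 1]]
    fb <- fmb_block_bw(b[[nm]], caches[[nm]]$fmb, g)
    g <- maxpool_bw(caches[[nm]]$pool, fb$gx)
    grads[[nm]] <- fb$grads
  }
  g <- g + gskips[[1]]
  f0 <- conv_block_bw(b$b0, caches$b0, g)
  grads$b0 <- f0$grads
  grads
}

#' Run the network on a batch of tiles
#'
#' Inference-mode forward pass (batch-norm running statistics, no caching),
#' deterministic for fixed weights.
#'
#' @param model a `seg_model`.
#' @param tiles a single matrix, a list of matrices, or an (H, W, N) array;
#'   every tile must be `input_size` square with intensities in \[0,1\].
#' @param batch_size tiles per forward chunk (memory control).
#' @return list of probability matrices, one per tile, values in \[0,1\].
#' @export
net_forward <- function(model, tiles, batch_size = 4L) {
  if (is.matrix(tiles)) tiles <- list(tiles)
  if (is.array(tiles) && length(dim(tiles)) == 3)
    tiles <- lapply(seq_len(dim(tiles)[3]), function(i) tiles[, , i])
  sz <- model$config$input_size
  for (t in tiles)
    if (!all(dim(t) == c(sz, sz)))
      stop("net_forward: tiles must be ", sz, "x", sz)
  out <- vector("list", length(tiles))
  i <- 1L
  while (i <= length(tiles)) {
    j <- min(length(tiles), i + batch_size - 1L)
    x <- array(unlist(tiles[i:j]), dim = c(sz, sz, 1, j - i + 1))
    r <- net_forward_full(model, x, training = FALSE)
    for (k in i:j) out[[k]] <- r$y[, , 1, k - i + 1]
    i <- j + 1L
  }
  out
}

#' Number of trainable parameters of a model
#' @param model a `seg_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  cnt <- 0L
  walk <- function(x) {
    for (v in x) {
      if (is.list(v)) walk(v)
      else if (is.numeric(v)) cnt <<- cnt + length(v)
    }
  }
  for (b in model$blocks) {
    pb <- b[setdiff(names(b), c("type", "cin", "cout"))]
    walk(pb)
  }
  cnt
}

#' @export
print.seg_model <- function(x, ...) {
  cat("seg_model: input", x$config$input_size, "px, width_divisor",
      x$config$width_divisor, "|", format(n_params(x), big.mark = ","),
      "parameters | phase:", x$meta$phase, "\n")
  invisible(x)
}
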