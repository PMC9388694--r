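# R-side layer plumbing around the compiled kernels: batch normalisation,
# leaky rectifier, channel concatenation, softmax/sigmoid, parameter
# initialisation and Adam. Activations are (H, W, C, B) arrays.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# reshape (H,W,C,B) -> (H*W*B, C) matrix with channels as columns
.chmat <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  xp
}

.unchmat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1L, 2L, 4L, 3L))
}

.bn_fwd <- function(x, g, b, run, training) {
  fw <- cpp_bn_fwd(x, g, b, run$mean, run$var, training, .BN_EPS)
  if (training) {
    run$mean <- (1 - .BN_MOMENTUM) * run$mean + .BN_MOMENTUM * fw$mean
    run$var <- (1 - .BN_MOMENTUM) * run$var + .BN_MOMENTUM * fw$var
  }
  list(y = fw$y,
       cache = list(xhat = fw$xhat, istd = fw$istd, g = g,
                    batch = training),
       run = run)
}

.bn_bwd <- function(gy, cache) {
  bw <- cpp_bn_bwd(gy, cache$xhat, cache$g, cache$istd, cache$batch)
  list(gx = bw$gx, gg = bw$gg, gb = bw$gb)
}

.lrelu_fwd <- function(x, slope) {
  y <- cpp_lrelu_fwd(x, slope)
  list(y = y, neg = y)
}

.lrelu_bwd <- function(gy, neg, slope) {
  cpp_lrelu_bwd(gy, neg, slope)
}

.cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# softmax over the channel dimension of (H,W,C,B)
.softmax_ch <- function(z) {
  d <- dim(z)
  zm <- .chmat(z)
  zm <- zm - apply(zm, 1L, max)
  ez <- exp(zm)
  .unchmat(ez / rowSums(ez), d)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- parameters ----------------------------------------------------------

.conv_init <- function(ci, co) {
  array(rnorm(9 * ci * co, sd = sqrt(2 / (9 * ci))), c(3L, 3L, ci, co))
}
.deconv_init <- function(ci, co) {
  array(rnorm(4 * ci * co, sd = sqrt(2 / ci)), c(2L, 2L, ci, co))
}

.enc_channels <- function(depth, base) {
  cin <- c(1L, base * 2^(seq_len(depth) - 1L))
  list(cin = cin[seq_len(depth)], cout = base * 2^(seq_len(depth) - 1L))
}

# flat named parameter list; names starting enc/bott are the shared encoder
.init_params <- function(depth, base, seed) {
  set.seed(seed)
  p <- list()
  s <- list()
  addblock <- function(pfx, ci, co) {
    p[[paste0(pfx, "_conv1_w")]] <<- .conv_init(ci, co)
    p[[paste0(pfx, "_conv1_b")]] <<- numeric(co)
    p[[paste0(pfx, "_bn1_g")]] <<- rep(1, co)
    p[[paste0(pfx, "_bn1_b")]] <<- numeric(co)
    p[[paste0(pfx, "_conv2_w")]] <<- .conv_init(co, co)
    p[[paste0(pfx, "_conv2_b")]] <<- numeric(co)
    p[[paste0(pfx, "_bn2_g")]] <<- rep(1, co)
    p[[paste0(pfx, "_bn2_b")]] <<- numeric(co)
    s[[paste0(pfx, "_bn1")]] <<- list(mean = numeric(co), var = rep(1, co))
    s[[paste0(pfx, "_bn2")]] <<- list(mean = numeric(co), var = rep(1, co))
  }
  ch <- .enc_channels(depth, base)
  for (i in seq_len(depth)) addblock(paste0("enc", i), ch$cin[i], ch$cout[i])
  addblock("bott", base * 2^(depth - 1L), base * 2^depth)
  for (head in c("obj", "ctr")) {
    for (i in rev(seq_len(depth))) {
      ci <- base * 2^i          # channels arriving from below
      co <- base * 2^(i - 1L)   # channels at this scale
      p[[paste0(head, "_up", i, "_w")]] <- .deconv_init(ci, co)
      p[[paste0(head, "_up", i, "_b")]] <- numeric(co)
      addblock(paste0(head, "_dec", i), 2L * co, co)
    }
    nout <- if (head == "obj") 3L else 1L
    p[[paste0(head, "_out_w")]] <- matrix(rnorm(base * nout,
                                                sd = sqrt(2 / base)),
                                          base, nout)
    p[[paste0(head, "_out_b")]] <- numeric(nout)
  }
  list(params = p, state = s)
}

# convolution-type weight arrays (targets of L2 regularisation)
.weight_names <- function(params) {
  nm <- names(params)
  nm[grepl("_(conv[12]|up[0-9]+|out)_w$", nm)]
}

# sum of squared convolution weights: the psi(theta) of the total loss
.psi <- function(params) {
  sum(vapply(.weight_names(params), function(n) sum(params[[n]]^2),
             numeric(1)))
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function() list(m = list(), v = list(), t = 0L)

# updates only the parameters named in grads; untouched parameters are
# bit-identical afterwards
.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (n in names(grads)) {
    g <- grads[[n]]
    if (is.null(opt$m[[n]])) {
      opt$m[[n]] <- g * 0
      opt$v[[n]] <- g * 0
    }
    opt$m[[n]] <- beta1 * opt$m[[n]] + (1 - beta1) * g
    opt$v[[n]] <- beta2 * opt$v[[n]] + (1 - beta2) * g * g
    params[[n]] <- params[[n]] -
      lr * (opt$m[[n]] / c1) / (sqrt(opt$v[[n]] / c2) + eps)
  }
  list(params = params, opt = opt)
}
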