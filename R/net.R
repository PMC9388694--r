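# The multitask U-Net: a shared down-sampling encoder and two decoder
# heads. Every scale uses two 3x3 convolutions, batch normalisation and a
# leaky rectifier; down-sampling is 2x2 max-pooling (stride 2) and
# up-sampling a 2x2 transposed convolution (stride 2) with skip
# concatenation from the encoder at the matching scale. The object head
# ends in a 1x1 convolution with 3-class softmax, the contour head in a
# single-channel sigmoid.

.PROB_CLAMP <- 1e-12  # probabilities are clamped here before logarithms

#' Build a multitask U-Net
#'
#' Parameters are initialised deterministically from `seed` (He-scaled
#' normal weights, zero biases, unit batch-norm gain).
#'
#' @param depth number of down-samplings; the input size must be divisible
#'   by `2^depth`.
#' @param baseChannels channel count at the first scale; doubled per scale.
#' @param slope negative slope of the leaky rectifier.
#' @param lambda L2 regularisation weight on convolution weights.
#' @param seed RNG seed for the initialisation.
#' @return a [MultitaskUNet-class] object.
#' @export
buildModel <- function(depth = 3L, baseChannels = 12L, slope = 0.01,
                       lambda = 1e-4, seed = 1L) {
  depth <- as.integer(depth)
  baseChannels <- as.integer(baseChannels)
  init <- .init_params(depth, baseChannels, seed)
  cfg <- list(depth = depth, baseChannels = baseChannels, slope = slope,
              lambda = lambda, seed = as.integer(seed))
  new("MultitaskUNet", config = cfg, params = init$params,
      state = init$state, archHash = .arch_hash(cfg))
}

.arch_hash <- function(cfg) {
  sprintf("unet-d%d-c%d-s%g", cfg$depth, cfg$baseChannels, cfg$slope)
}

# ---- forward / backward --------------------------------------------------

.block_fwd <- function(x, p, s, pfx, training, slope) {
  c1 <- cpp_conv3x3_fwd(x, p[[paste0(pfx, "_conv1_w")]],
                        p[[paste0(pfx, "_conv1_b")]])
  bn1 <- .bn_fwd(c1, p[[paste0(pfx, "_bn1_g")]], p[[paste0(pfx, "_bn1_b")]],
                 s[[paste0(pfx, "_bn1")]], training)
  s[[paste0(pfx, "_bn1")]] <- bn1$run
  a1 <- .lrelu_fwd(bn1$y, slope)
  c2 <- cpp_conv3x3_fwd(a1$y, p[[paste0(pfx, "_conv2_w")]],
                        p[[paste0(pfx, "_conv2_b")]])
  bn2 <- .bn_fwd(c2, p[[paste0(pfx, "_bn2_g")]], p[[paste0(pfx, "_bn2_b")]],
                 s[[paste0(pfx, "_bn2")]], training)
  s[[paste0(pfx, "_bn2")]] <- bn2$run
  a2 <- .lrelu_fwd(bn2$y, slope)
  cache <- if (training)
    list(x = x, a1 = a1$y, neg1 = a1$neg, neg2 = a2$neg,
         bn1 = bn1$cache, bn2 = bn2$cache)
  list(y = a2$y, cache = cache, state = s)
}

.block_bwd <- function(gy, cache, p, pfx, slope) {
  g <- list()
  gy <- .lrelu_bwd(gy, cache$neg2, slope)
  b2 <- .bn_bwd(gy, cache$bn2)
  g[[paste0(pfx, "_bn2_g")]] <- b2$gg
  g[[paste0(pfx, "_bn2_b")]] <- b2$gb
  c2 <- cpp_conv3x3_bwd(cache$a1, p[[paste0(pfx, "_conv2_w")]], b2$gx)
  g[[paste0(pfx, "_conv2_w")]] <- c2$gw
  g[[paste0(pfx, "_conv2_b")]] <- c2$gb
  gy <- .lrelu_bwd(c2$gx, cache$neg1, slope)
  b1 <- .bn_bwd(gy, cache$bn1)
  g[[paste0(pfx, "_bn1_g")]] <- b1$gg
  g[[paste0(pfx, "_bn1_b")]] <- b1$gb
  c1 <- cpp_conv3x3_bwd(cache$x, p[[paste0(pfx, "_conv1_w")]], b1$gx)
  g[[paste0(pfx, "_conv1_w")]] <- c1$gw
  g[[paste0(pfx, "_conv1_b")]] <- c1$gb
  list(gx = c1$gx, grads = g)
}

# forward pass over a (H,W,1,B) batch; returns logits per requested head
.net_fwd <- function(params, state, x4, config, training,
                     heads = c("obj", "ctr")) {
  d <- config$depth
  H <- dim(x4)[1]; W <- dim(x4)[2]
  if (H %% 2^d != 0L || W %% 2^d != 0L)
    stop(sprintf("input size %dx%d must be divisible by 2^depth = %d",
                 H, W, 2^d))
  cache <- list(); skips <- vector("list", d)
  a <- x4
  for (i in seq_len(d)) {
    bf <- .block_fwd(a, params, state, paste0("enc", i), training,
                     config$slope)
    state <- bf$state
    skips[[i]] <- bf$y
    cache[[paste0("enc", i)]] <- bf$cache
    mp <- cpp_maxpool2_fwd(bf$y)
    cache[[paste0("pool", i)]] <- mp$idx
    cache[[paste0("pooldim", i)]] <- dim(bf$y)
    a <- mp$y
  }
  bf <- .block_fwd(a, params, state, "bott", training, config$slope)
  state <- bf$state
  cache$bott <- bf$cache
  bott <- bf$y
  out <- list()
  for (head in heads) {
    hx <- bott
    for (i in rev(seq_len(d))) {
      cache[[paste0(head, "_upin", i)]] <- hx
      up <- cpp_convT2x2_fwd(hx, params[[paste0(head, "_up", i, "_w")]],
                             params[[paste0(head, "_up", i, "_b")]])
      cc <- .cat_ch(up, skips[[i]])
      bf <- .block_fwd(cc, params, state, paste0(head, "_dec", i), training,
                       config$slope)
      state <- bf$state
      cache[[paste0(head, "_dec", i)]] <- bf$cache
      hx <- bf$y
    }
    cache[[paste0(head, "_outin")]] <- hx
    out[[head]] <- cpp_conv1x1_fwd(hx, params[[paste0(head, "_out_w")]],
                                   params[[paste0(head, "_out_b")]])
  }
  list(obj = out$obj, ctr = out$ctr, cache = cache, state = state,
       skipdims = lapply(skips, dim))
}

# backpropagation from logits gradients; returns grads only for parameters
# on an active path (object-only gradients never touch ctr_* parameters)
.net_bwd <- function(params, fw, config, gObj = NULL, gCtr = NULL) {
  d <- config$depth
  cache <- fw$cache
  grads <- list()
  gskips <- vector("list", d)
  gbott <- NULL
  for (head in c("obj", "ctr")) {
    ghead <- if (head == "obj") gObj else gCtr
    if (is.null(ghead)) next
    ob <- cpp_conv1x1_bwd(cache[[paste0(head, "_outin")]],
                          params[[paste0(head, "_out_w")]], ghead)
    grads[[paste0(head, "_out_w")]] <- ob$gw
    grads[[paste0(head, "_out_b")]] <- ob$gb
    g <- ob$gx
    for (i in seq_len(d)) {
      bb <- .block_bwd(g, cache[[paste0(head, "_dec", i)]], params,
                       paste0(head, "_dec", i), config$slope)
      grads <- c(grads, bb$grads)
      co <- dim(bb$gx)[3] %/% 2L
      gup <- bb$gx[, , seq_len(co), , drop = FALSE]
      gsk <- bb$gx[, , co + seq_len(co), , drop = FALSE]
      gskips[[i]] <- if (is.null(gskips[[i]])) gsk else gskips[[i]] + gsk
      ub <- cpp_convT2x2_bwd(cache[[paste0(head, "_upin", i)]],
                             params[[paste0(head, "_up", i, "_w")]], gup)
      grads[[paste0(head, "_up", i, "_w")]] <- ub$gw
      grads[[paste0(head, "_up", i, "_b")]] <- ub$gb
      g <- ub$gx
    }
    gbott <- if (is.null(gbott)) g else gbott + g
  }
  bb <- .block_bwd(gbott, cache$bott, params, "bott", config$slope)
  grads <- .acc_grads(grads, bb$grads)
  g <- bb$gx
  for (i in rev(seq_len(d))) {
    dimi <- cache[[paste0("pooldim", i)]]
    g <- cpp_maxpool2_bwd(cache[[paste0("pool", i)]], g, dimi[1], dimi[2])
    if (!is.null(gskips[[i]])) g <- g + gskips[[i]]
    bb <- .block_bwd(g, cache[[paste0("enc", i)]], params, paste0("enc", i),
                     config$slope)
    grads <- .acc_grads(grads, bb$grads)
    g <- bb$gx
  }
  grads
}

.acc_grads <- function(a, b) {
  for (n in names(b)) a[[n]] <- if (is.null(a[[n]])) b[[n]] else a[[n]] + b[[n]]
  a
}

# one-hot (H,W,3,B) from an integer (H,W,B) label array
.onehot4 <- function(y) {
  d <- dim(y)
  out <- array(0, c(d[1], d[2], 3L, d[3]))
  for (k in 0:2) out[, , k + 1L, ] <- as.numeric(y == k)
  out
}

# total pretraining objective on a batch: lambda*psi + pixel-summed
# cross-entropies of both heads; returns loss, grads and updated BN state
.loss_grad_total <- function(params, state, x4, yObj, yCtr, config) {
  fw <- .net_fwd(params, state, x4, config, training = TRUE)
  Po <- .softmax_ch(fw$obj)
  Pc <- .sigmoid(fw$ctr)
  Y <- .onehot4(yObj)
  pTrue <- Po[, , 1, ] * Y[, , 1, ] + Po[, , 2, ] * Y[, , 2, ] +
    Po[, , 3, ] * Y[, , 3, ]
  pc <- Pc[, , 1, ]
  pTrueC <- ifelse(array(yCtr, dim(pc)) == 1, pc, 1 - pc)
  lam <- config$lambda
  loss <- lam * .psi(params) - sum(log(pmax(pTrue, .PROB_CLAMP))) -
    sum(log(pmax(pTrueC, .PROB_CLAMP)))
  gCtr <- Pc
  gCtr[, , 1, ] <- pc - array(yCtr, dim(pc))
  grads <- .net_bwd(params, fw, config, gObj = Po - Y, gCtr = gCtr)
  if (lam > 0)
    for (n in .weight_names(params))
      grads[[n]] <- grads[[n]] + 2 * lam * params[[n]]
  list(loss = loss, grads = grads, state = fw$state)
}

# transfer objective: per-pixel mean 3-class cross-entropy on the object
# head; the contour head receives no gradient unless includeContour
.loss_grad_transfer <- function(params, state, x4, yObj, config,
                                includeContour = FALSE, yCtr = NULL,
                                freezeEncoder = FALSE) {
  heads <- if (includeContour) c("obj", "ctr") else "obj"
  fw <- .net_fwd(params, state, x4, config, training = TRUE, heads = heads)
  Po <- .softmax_ch(fw$obj)
  Y <- .onehot4(yObj)
  N <- prod(dim(yObj))
  pTrue <- Po[, , 1, ] * Y[, , 1, ] + Po[, , 2, ] * Y[, , 2, ] +
    Po[, , 3, ] * Y[, , 3, ]
  loss <- -sum(log(pmax(pTrue, .PROB_CLAMP))) / N
  gObj <- (Po - Y) / N
  gCtr <- NULL
  if (includeContour) {
    Pc <- .sigmoid(fw$ctr)
    pc <- Pc[, , 1, ]
    pTrueC <- ifelse(array(yCtr, dim(pc)) == 1, pc, 1 - pc)
    loss <- loss - sum(log(pmax(pTrueC, .PROB_CLAMP))) / N
    gCtr <- Pc
    gCtr[, , 1, ] <- (pc - array(yCtr, dim(pc))) / N
  }
  grads <- .net_bwd(params, fw, config, gObj = gObj, gCtr = gCtr)
  if (freezeEncoder)
    grads <- grads[!grepl("^(enc|bott)", names(grads))]
  list(loss = loss, grads = grads, state = fw$state)
}

# ---- inference -----------------------------------------------------------

# batched eval-mode forward returning probability arrays
.predict_batch <- function(model, x4) {
  fw <- .net_fwd(model@params, model@state, x4, model@config,
                 training = FALSE)
  list(object = .softmax_ch(fw$obj), contour = .sigmoid(fw$ctr))
}

#' Network probability maps for one B-scan
#'
#' Runs the model in inference mode (batch-norm running statistics) on a
#' single B-scan.
#'
#' @param model a [MultitaskUNet-class] object.
#' @param image numeric matrix `(depth, width)`; both sizes must be
#'   divisible by `2^depth`.
#' @return a [ProbMaps-class] object.
#' @export
predictProbs <- function(model, image) {
  stopifnot(is(model, "MultitaskUNet"), is.matrix(image))
  x4 <- array(image, c(dim(image), 1L, 1L))
  pr <- .predict_batch(model, x4)
  new("ProbMaps", object = pr$object[, , , 1],
      contour = pr$contour[, , 1, 1])
}

# ---- user-facing losses --------------------------------------------------

#' Total multitask loss
#'
#' `lambda * psi(theta) - sum_x log N_o(x, l_o(x)) - sum_x log N_c(x,
#' l_c(x))`: an L2 penalty on the convolution weights plus pixel-summed
#' cross-entropies of the object and contour heads. `N_c(x, 0)` is taken as
#' `1 - N_c(x, 1)`. Probabilities are clamped at `1e-12` before the
#' logarithm.
#'
#' @param probs a [ProbMaps-class] object.
#' @param classMask integer matrix of labels in `{0, 1, 2}`.
#' @param contourMask binary integer matrix.
#' @param model optional [MultitaskUNet-class] supplying the weights for the
#'   L2 term; required when `lambda > 0`.
#' @param lambda L2 weight (defaults to the model's configured value, or 0
#'   without a model).
#' @return scalar loss.
#' @export
lossTotal <- function(probs, classMask, contourMask, model = NULL,
                      lambda = NULL) {
  stopifnot(is(probs, "ProbMaps"))
  if (is.null(lambda))
    lambda <- if (!is.null(model)) model@config$lambda else 0
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda > 0 && is.null(model))
    stop("a model is required to evaluate the L2 term when lambda > 0")
  Po <- probs@object
  if (!identical(dim(Po)[1:2], dim(classMask)) ||
      !identical(dim(classMask), dim(contourMask)))
    stop("probability maps and masks must share spatial shape")
  oh <- oneHot(classMask)
  pTrue <- Po[, , 1] * oh[, , 1] + Po[, , 2] * oh[, , 2] +
    Po[, , 3] * oh[, , 3]
  pc <- probs@contour
  pTrueC <- ifelse(contourMask == 1L, pc, 1 - pc)
  reg <- if (!is.null(model)) lambda * .psi(model@params) else 0
  reg - sum(log(pmax(pTrue, .PROB_CLAMP))) -
    sum(log(pmax(pTrueC, .PROB_CLAMP)))
}

#' Transfer (fine-tuning) loss
#'
#' Per-pixel mean of the 3-class cross-entropy `-sum_c y_c log p_c` between
#' the object probability map and the one-hot encoded labels.
#'
#' @param probObj 3-channel probability array `(depth, width, 3)` or a
#'   [ProbMaps-class] object.
#' @param classMask integer matrix of labels in `{0, 1, 2}`.
#' @return scalar loss.
#' @export
lossTransfer <- function(probObj, classMask) {
  if (is(probObj, "ProbMaps")) probObj <- probObj@object
  if (!identical(dim(probObj)[1:2], dim(classMask)))
    stop("probability map and mask must share spatial shape")
  oh <- oneHot(classMask)
  pTrue <- probObj[, , 1] * oh[, , 1] + probObj[, , 2] * oh[, , 2] +
    probObj[, , 3] * oh[, , 3]
  -sum(log(pmax(pTrue, .PROB_CLAMP))) / length(classMask)
}
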