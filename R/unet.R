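## 1D U-net for dense arousal-probability prediction.
##
## The network maps a 3 x T input (EEG, EOG, EMG at 50 Hz) to a length-T
## probability track. Architecture: `depth` encoder double-convolution
## blocks, each followed by max-pooling by `poolFactor`, and `depth`
## symmetric decoder double-convolution blocks, each preceded by
## nearest-neighbour upsampling and concatenation with the matching encoder
## skip; a final 1x1 convolution plus sigmoid produces the probability.
## Every convolution is same-padded so length is preserved at each scale.
## Forward and backward passes are written directly on BLAS matrix
## operations (im2col convolutions); optimization is Adam on binary
## cross-entropy.

#' U-net model object
#'
#' @slot spec list with `depth`, `baseFilters`, `kernel`, `poolFactor`,
#'   `filterCap`, `inChannels`.
#' @slot params list of convolution parameter pairs (`W`, `b`) in network
#'   order.
#' @slot plan internal layer plan (channel arithmetic).
#' @export
setClass("UNetModel",
  representation(spec = "list", params = "list", plan = "list"))

#' U-net architecture specification
#'
#' @param depth number of encoder levels (the network has `2 * depth`
#'   double-convolution blocks; default 4, i.e. eight blocks).
#' @param baseFilters filters in the first encoder block (default 16);
#'   doubled per level, capped at `filterCap`.
#' @param kernel convolution kernel size in taps (default 21; odd).
#' @param poolFactor pooling/upsampling factor per level (default 4).
#' @param filterCap maximum filters per layer (default 256).
#' @param inChannels input channels (default 3: EEG, EOG, EMG).
#' @return A validated spec list.
#' @export
unetSpec <- function(depth = 4, baseFilters = 16, kernel = 21,
                     poolFactor = 4, filterCap = 256, inChannels = 3) {
  stopifnot(depth >= 1, baseFilters >= 1, kernel %% 2 == 1, poolFactor >= 2)
  list(depth = depth, baseFilters = baseFilters, kernel = kernel,
       poolFactor = poolFactor, filterCap = filterCap, inChannels = inChannels)
}

.unetPlan <- function(spec) {
  d <- spec$depth
  f <- pmin(spec$baseFilters * 2^(seq_len(d) - 1), spec$filterCap)
  convs <- list()
  add <- function(convs, cin, cout, k) {
    convs[[length(convs) + 1]] <- list(cin = cin, cout = cout, k = k)
    convs
  }
  prev <- spec$inChannels
  for (i in seq_len(d)) {          # encoder double conv blocks
    convs <- add(convs, prev, f[i], spec$kernel)
    convs <- add(convs, f[i], f[i], spec$kernel)
    prev <- f[i]
  }
  for (j in seq_len(d)) {          # decoder double conv blocks
    i <- d - j + 1
    convs <- add(convs, prev + f[i], f[i], spec$kernel)
    convs <- add(convs, f[i], f[i], spec$kernel)
    prev <- f[i]
  }
  convs <- add(convs, prev, 1L, 1L)  # 1x1 output conv
  list(depth = d, pool = spec$poolFactor, kernel = spec$kernel,
       filters = f, convs = convs)
}

#' Build a U-net model
#'
#' Initializes all convolution weights (He-scaled Gaussian) and biases
#' (zero). With a fixed RNG seed the initial parameters are reproducible.
#'
#' @param spec a spec from [unetSpec()].
#' @param seed optional integer seed for weight initialization.
#' @return A [UNetModel-class].
#' @examples
#' m <- buildUNet(unetSpec(depth = 2, baseFilters = 4), seed = 1)
#' parameterCount(m)
#' @export
buildUNet <- function(spec = unetSpec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- .unetPlan(spec)
  params <- lapply(plan$convs, function(cv) {
    fanIn <- cv$cin * cv$k
    list(W = matrix(rnorm(cv$cout * fanIn, sd = sqrt(2 / fanIn)),
                    nrow = cv$cout),
         b = numeric(cv$cout))
  })
  new("UNetModel", spec = spec, params = params, plan = plan)
}

#' Number of trainable parameters
#'
#' Closed-form count from the layer plan: each convolution contributes
#' `cout * (cin * k + 1)` weights and biases.
#'
#' @param x a [UNetModel-class] or a spec list from [unetSpec()].
#' @return Integer parameter count.
#' @export
parameterCount <- function(x) {
  plan <- if (is(x, "UNetModel")) x@plan else .unetPlan(x)
  sum(vapply(plan$convs, function(cv) cv$cout * (cv$cin * cv$k + 1), 0))
}

#' @export
setMethod("show", "UNetModel", function(object) {
  s <- object@spec
  cat(sprintf(
    "UNetModel: depth %d (%d double-conv blocks), k=%d, pool=%d, base=%d\n",
    s$depth, 2 * s$depth, s$kernel, s$poolFactor, s$baseFilters))
  cat(sprintf("  %d convolutions, %d parameters; input length must be a multiple of %d\n",
              length(object@params), parameterCount(object),
              s$poolFactor^s$depth))
  invisible(object)
})

## --- primitive layers -------------------------------------------------

.im2col <- function(x, k) {
  C <- nrow(x); Tn <- ncol(x)
  if (k == 1L) return(x)
  p <- (k - 1L) %/% 2L
  xp <- cbind(matrix(0, C, p), x, matrix(0, C, p))
  Xc <- matrix(0, C * k, Tn)
  for (j in seq_len(k))
    Xc[(seq_len(C) - 1L) * k + j, ] <- xp[, j:(j + Tn - 1L), drop = FALSE]
  Xc
}

.col2im <- function(dXc, C, Tn, k) {
  if (k == 1L) return(dXc)
  p <- (k - 1L) %/% 2L
  dxp <- matrix(0, C, Tn + 2L * p)
  for (j in seq_len(k)) {
    cols <- j:(j + Tn - 1L)
    dxp[, cols] <- dxp[, cols] + dXc[(seq_len(C) - 1L) * k + j, , drop = FALSE]
  }
  dxp[, (p + 1L):(p + Tn), drop = FALSE]
}

.poolForward <- function(x, m) {
  To <- ncol(x) %/% m
  y <- x[, seq.int(1L, by = m, length.out = To), drop = FALSE]
  arg <- matrix(1L, nrow(x), To)
  if (m > 1) for (j in 2:m) {
    cand <- x[, seq.int(j, by = m, length.out = To), drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]; arg[upd] <- j
  }
  list(y = y, arg = arg)
}

.poolBackward <- function(dY, arg, m) {
  C <- nrow(dY); To <- ncol(dY)
  dx <- matrix(0, C, To * m)
  for (j in seq_len(m)) {
    sel <- arg == j
    if (!any(sel)) next
    tmp <- matrix(0, C, To); tmp[sel] <- dY[sel]
    dx[, seq.int(j, by = m, length.out = To)] <- tmp
  }
  dx
}

.upForward <- function(x, m) x[, rep(seq_len(ncol(x)), each = m), drop = FALSE]

.upBackward <- function(dY, m) {
  To <- ncol(dY) %/% m
  dx <- dY[, seq.int(1L, by = m, length.out = To), drop = FALSE]
  if (m > 1) for (j in 2:m)
    dx <- dx + dY[, seq.int(j, by = m, length.out = To), drop = FALSE]
  dx
}

## --- forward / backward ------------------------------------------------

.unetForward <- function(model, x, keepCache = FALSE) {
  plan <- model@plan; params <- model@params
  d <- plan$depth; m <- plan$pool
  Tn <- ncol(x)
  if (Tn %% m^d != 0)
    stop(sprintf(
      "input length %d is not divisible by poolFactor^depth = %d; pad the chunk or pick a chunk length that is a multiple of %d",
      Tn, m^d, m^d))
  caches <- if (keepCache) vector("list", length(params)) else NULL
  pools <- skips <- vector("list", d)
  h <- x; li <- 0L
  convRelu <- function(h, li) {
    cv <- plan$convs[[li]]
    Xc <- .im2col(h, cv$k)
    z <- params[[li]]$W %*% Xc + params[[li]]$b
    a <- z * (z > 0)
    if (keepCache) caches[[li]] <<- list(Xc = Xc, mask = z > 0, Cin = nrow(h))
    a
  }
  for (i in seq_len(d)) {
    h <- convRelu(h, li <- li + 1L)
    h <- convRelu(h, li <- li + 1L)
    skips[[i]] <- h
    pl <- .poolForward(h, m)
    pools[[i]] <- pl$arg
    h <- pl$y
  }
  for (j in seq_len(d)) {
    i <- d - j + 1L
    h <- .upForward(h, m)
    h <- rbind(skips[[i]], h)
    h <- convRelu(h, li <- li + 1L)
    h <- convRelu(h, li <- li + 1L)
  }
  li <- li + 1L
  Xc <- h   # k = 1
  z <- params[[li]]$W %*% Xc + params[[li]]$b
  if (keepCache) caches[[li]] <- list(Xc = Xc, mask = NULL, Cin = nrow(h))
  p <- 1 / (1 + exp(-as.vector(z)))
  list(p = p, caches = caches, pools = pools,
       skipChannels = vapply(skips, nrow, 0L))
}

# Gradients of mean binary cross-entropy wrt all parameters for one sample.
.unetBackward <- function(model, fwd, y) {
  plan <- model@plan; params <- model@params
  d <- plan$depth; m <- plan$pool
  Tn <- length(fwd$p)
  grads <- vector("list", length(params))
  dz <- matrix((fwd$p - y) / Tn, nrow = 1)   # sigmoid + BCE combined
  li <- length(params)
  cv <- plan$convs[[li]]; cache <- fwd$caches[[li]]
  grads[[li]] <- list(W = dz %*% t(cache$Xc), b = sum(dz))
  dh <- crossprod(params[[li]]$W, dz)
  convBack <- function(dh, li) {
    cv <- plan$convs[[li]]; cache <- fwd$caches[[li]]
    dzc <- dh * cache$mask
    grads[[li]] <<- list(W = dzc %*% t(cache$Xc), b = rowSums(dzc))
    dXc <- crossprod(params[[li]]$W, dzc)
    .col2im(dXc, cache$Cin, ncol(dh), cv$k)
  }
  li <- li - 1L
  dskips <- vector("list", d)
  for (j in rev(seq_len(d))) {   # decoder blocks, deepest index first
    # params order: decoder block j occupies conv indices 2d + 2j-1, 2j
    base <- 2L * d + 2L * (j - 1L)
    dh <- convBack(dh, base + 2L)
    dh <- convBack(dh, base + 1L)
    i <- d - j + 1L
    nskip <- fwd$skipChannels[i]
    dskips[[i]] <- dh[seq_len(nskip), , drop = FALSE]
    dh <- .upBackward(dh[-seq_len(nskip), , drop = FALSE], m)
  }
  for (i in rev(seq_len(d))) {   # encoder blocks
    dh <- .poolBackward(dh, fwd$pools[[i]], m)
    dh <- dh + dskips[[i]]
    base <- 2L * (i - 1L)
    dh <- convBack(dh, base + 2L)
    dh <- convBack(dh, base + 1L)
  }
  grads
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict an arousal-probability track for a full record
#'
#' Runs the network over the record in fixed-length chunks with 50%
#' overlap and stitches the central half of each chunk (record edges keep
#' the full chunk), so every output sample is predicted with symmetric
#' context wherever possible. Output length always equals input length.
#'
#' @param model a [UNetModel-class].
#' @param x numeric matrix, channels x samples (finite values).
#' @param chunkLength chunk length in samples (default 4096); rounded up
#'   to a multiple of `poolFactor^depth`.
#' @return Numeric vector of probabilities in `[0, 1]`, length `ncol(x)`.
#' @export
predictProbabilities <- function(model, x, chunkLength = 4096) {
  stopifnot(is(model, "UNetModel"), is.matrix(x))
  if (!all(is.finite(x))) stop("input contains non-finite values")
  unit <- model@spec$poolFactor^model@spec$depth
  L <- unit * ceiling(chunkLength / unit)
  Tn <- ncol(x)
  if (Tn <= L) {
    Lp <- unit * ceiling(Tn / unit)
    xp <- cbind(x, matrix(0, nrow(x), Lp - Tn))
    return(.unetForward(model, xp)$p[seq_len(Tn)])
  }
  stride <- L %/% 2L
  q <- L %/% 4L
  starts <- seq.int(0L, Tn - L, by = stride)
  if (tail(starts, 1) + L < Tn) starts <- c(starts, Tn - L)
  p <- numeric(Tn)
  ptr <- 0L  # next unfilled sample (0-based)
  for (s in starts) {
    pc <- .unetForward(model, x[, (s + 1L):(s + L), drop = FALSE])$p
    a <- if (s == 0L) 0L else max(s + q, ptr)
    b <- if (s == tail(starts, 1)) Tn - 1L else s + L - q - 1L
    if (b >= a) p[(a:b) + 1L] <- pc[(a:b) - s + 1L]
    ptr <- b + 1L
  }
  p
}
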