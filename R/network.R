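#' Native tensor backend
#'
#' The realization backend contract: given a stacked 4-channel patch the
#' realized network must return a `Cl`-channel score map of identical spatial
#' extent.  The native backend executes the blueprint's layer graph with
#' Rcpp convolution kernels; normalization layers standardize each channel
#' over the spatial field of the sample (so inference at batch size one is
#' identical to training behavior), and activations are per-channel PReLU.
#'
#' @return backend descriptor used by [realize()].
#' @export
native_backend <- function() {
  structure(list(name = "native"), class = "aniso_backend")
}

#' Realize a blueprint as a callable network
#'
#' Instantiates parameters for every layer of the blueprint (He-normal
#' convolution weights, PReLU slope 0.25, unit-gain normalization),
#' deterministically for a given seed.
#'
#' @param blueprint a [make_blueprint()] object.
#' @param backend a [native_backend()] descriptor.
#' @param seed integer; same seed gives bitwise-identical parameters.
#' @param probe_mode logical; if `TRUE` all convolution weights are set to a
#'   positive constant, normalization layers become the identity and PReLU
#'   slopes are 1, so the network is linear with nonnegative sensitivity
#'   (the regime required by [probe_receptive_field()]).
#' @return object of class `aniso_net`.
#' @export
realize <- function(blueprint, backend = native_backend(), seed = 1L,
                    probe_mode = FALSE) {
  if (!inherits(backend, "aniso_backend"))
    aniso_stop("realization", "backend does not satisfy the backend contract")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 17L))
  params <- vector("list", length(blueprint$graph))
  for (nd in blueprint$graph) {
    if (nd$op == "conv") {
      fan_in <- prod(nd$k) * nd$cin
      W <- if (probe_mode) array(0.5 / fan_in, dim = c(nd$k, nd$cin, nd$cout))
           else array(rnorm(prod(nd$k) * nd$cin * nd$cout, 0, sqrt(2 / fan_in)),
                      dim = c(nd$k, nd$cin, nd$cout))
      params[[nd$id]] <- list(W = W, b = numeric(nd$cout))
    } else if (nd$op == "deconv") {
      fan_in <- prod(nd$k) * nd$cin
      W <- if (probe_mode) array(0.5 / fan_in, dim = c(nd$k, nd$cin, nd$cout))
           else array(rnorm(prod(nd$k) * nd$cin * nd$cout, 0, sqrt(2 / fan_in)),
                      dim = c(nd$k, nd$cin, nd$cout))
      params[[nd$id]] <- list(W = W, b = numeric(nd$cout))
    } else if (nd$op == "norm") {
      params[[nd$id]] <- list(gamma = rep(1, nd$cout), beta = numeric(nd$cout))
    } else if (nd$op == "prelu") {
      params[[nd$id]] <- list(a = rep(if (probe_mode) 1 else 0.25, nd$cout))
    }
  }
  net <- structure(list(blueprint = blueprint, params = params,
                        backend = backend, probe_mode = probe_mode,
                        seed = as.integer(seed)),
                   class = "aniso_net")
  net
}

#' @export
print.aniso_net <- function(x, ...) {
  cat(sprintf("<aniso_net %s> %d parameter tensors%s\n", x$blueprint$variant,
              sum(!vapply(x$params, is.null, logical(1))),
              if (x$probe_mode) " (probe mode)" else ""))
  invisible(x)
}

n_downsamples <- function(bp) sum(vapply(bp$graph, function(n)
  identical(n$kind, "downsample2d"), logical(1)))

# Channel-wise spatial standardization (the realization's normalization layer).
norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); nvox <- prod(d[1:3]); C <- d[4]
  m <- matrix(x, nvox, C)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, dim = d), xhat = xhat, istd = istd)
}

norm_bwd <- function(cache, gamma, gout) {
  d <- dim(gout); nvox <- prod(d[1:3]); C <- d[4]
  g <- matrix(gout, nvox, C)
  dgamma <- colSums(g * cache$xhat)
  dbeta <- colSums(g)
  dxhat <- sweep(g, 2, gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(gx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

prelu_fwd <- function(x, a) {
  d <- dim(x); nvox <- prod(d[1:3])
  m <- matrix(x, nvox, d[4])
  neg <- m < 0
  y <- m
  y[neg] <- (sweep(m, 2, a, `*`))[neg]
  array(y, dim = d)
}

prelu_bwd <- function(x, a, gout) {
  d <- dim(x); nvox <- prod(d[1:3])
  m <- matrix(x, nvox, d[4]); g <- matrix(gout, nvox, d[4])
  neg <- m < 0
  slope <- matrix(1, nvox, d[4]); slope[neg] <- sweep(neg + 0, 2, a, `*`)[neg]
  da <- colSums(g * m * neg)
  list(gx = array(g * slope, dim = d), da = da)
}

concat_channels <- function(vals) {
  d <- dim(vals[[1]])[1:3]
  cs <- vapply(vals, function(v) dim(v)[4], integer(1))
  out <- array(0, dim = c(d, sum(cs)))
  at <- 0L
  for (v in vals) {
    out[, , , at + seq_len(dim(v)[4])] <- v
    at <- at + dim(v)[4]
  }
  out
}

# Forward pass over the layer graph.  Returns the raw score map; with
# keep_cache the per-node activations needed for the backward pass.
net_forward <- function(net, x, keep_cache = FALSE) {
  bp <- net$blueprint
  nodes <- bp$graph
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[4] != bp$in_channels)
    aniso_stop("realization", "input has %d channels, blueprint expects %d",
               dim(x)[4], bp$in_channels)
  vals <- vector("list", length(nodes))
  caches <- if (keep_cache) vector("list", length(nodes)) else NULL
  for (nd in nodes) {
    vals[[nd$id]] <- switch(nd$op,
      input = x,
      conv = {
        xin <- vals[[nd$from]]
        conv3d_fwd(xin, dim(xin), net$params[[nd$id]]$W,
                   dim(net$params[[nd$id]]$W), net$params[[nd$id]]$b,
                   nd$d, nd$stride, nd$pad)
      },
      deconv = {
        xin <- vals[[nd$from]]
        deconv2x_fwd(xin, dim(xin), net$params[[nd$id]]$W,
                     dim(net$params[[nd$id]]$W), net$params[[nd$id]]$b)
      },
      norm = {
        if (net$probe_mode) vals[[nd$from]]
        else {
          nf <- norm_fwd(vals[[nd$from]], net$params[[nd$id]]$gamma,
                         net$params[[nd$id]]$beta)
          if (keep_cache) caches[[nd$id]] <- nf[c("xhat", "istd")]
          nf$y
        }
      },
      prelu = prelu_fwd(vals[[nd$from]], net$params[[nd$id]]$a),
      add = {
        # identity shortcut; widths reconciled by zero-padding / truncation
        main <- vals[[nd$from[1]]]; short <- vals[[nd$from[2]]]
        cs <- dim(short)[4]; cm <- dim(main)[4]
        if (cs == cm) main + short
        else if (cs < cm) {
          out <- main
          out[, , , seq_len(cs)] <- out[, , , seq_len(cs), drop = FALSE] + short
          out
        } else main + short[, , , seq_len(cm), drop = FALSE]
      },
      concat = concat_channels(vals[nd$from]),
      aniso_stop("graph", "unknown op %s", nd$op))
  }
  list(out = vals[[length(nodes)]], vals = if (keep_cache) vals else NULL,
       caches = caches)
}

# Backward pass; returns gradient w.r.t. the input and per-node parameter
# gradients.  `fw` is the structure returned by net_forward(keep_cache=TRUE).
net_backward <- function(net, fw, gout, need_param_grads = TRUE) {
  nodes <- net$blueprint$graph
  n <- length(nodes)
  grads <- vector("list", n)
  pgrads <- vector("list", n)
  grads[[n]] <- gout
  acc <- function(id, g) {
    grads[[id]] <<- if (is.null(grads[[id]])) g else grads[[id]] + g
  }
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- nodes[[id]]
    switch(nd$op,
      input = NULL,
      conv = {
        xin <- fw$vals[[nd$from]]
        bw <- conv3d_bwd(xin, dim(xin), net$params[[id]]$W,
                         dim(net$params[[id]]$W), g, nd$d, nd$stride, nd$pad,
                         TRUE)
        if (need_param_grads) pgrads[[id]] <- list(W = bw$gW, b = bw$gb)
        acc(nd$from, bw$gx)
      },
      deconv = {
        xin <- fw$vals[[nd$from]]
        bw <- deconv2x_bwd(xin, dim(xin), net$params[[id]]$W,
                           dim(net$params[[id]]$W), g, TRUE)
        if (need_param_grads) pgrads[[id]] <- list(W = bw$gW, b = bw$gb)
        acc(nd$from, bw$gx)
      },
      norm = {
        if (net$probe_mode) acc(nd$from, g)
        else {
          bw <- norm_bwd(fw$caches[[id]], net$params[[id]]$gamma, g)
          if (need_param_grads)
            pgrads[[id]] <- list(gamma = bw$dgamma, beta = bw$dbeta)
          acc(nd$from, bw$gx)
        }
      },
      prelu = {
        bw <- prelu_bwd(fw$vals[[nd$from]], net$params[[id]]$a, g)
        if (need_param_grads) pgrads[[id]] <- list(a = bw$da)
        acc(nd$from, bw$gx)
      },
      add = {
        acc(nd$from[1], g)
        cs <- dim(fw$vals[[nd$from[2]]])[4]; cm <- dim(g)[4]
        gs <- if (cs <= cm) g[, , , seq_len(cs), drop = FALSE] else {
          gp <- array(0, dim = c(dim(g)[1:3], cs))
          gp[, , , seq_len(cm)] <- g
          gp
        }
        acc(nd$from[2], gs)
      },
      concat = {
        at <- 0L
        for (src in nd$from) {
          cs <- dim(fw$vals[[src]])[4]
          acc(src, g[, , , at + seq_len(cs), drop = FALSE])
          at <- at + cs
        }
      })
    if (nd$op != "input") grads[[id]] <- NA  # free consumed gradients
  }
  list(gx = grads[[1]], pgrads = pgrads)
}

softmax_channels <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, prod(d[1:3]), d[4])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), dim = d)
}

pad_inplane <- function(x, mult) {
  d <- dim(x)
  tx <- ceiling(d[1] / mult) * mult
  ty <- ceiling(d[2] / mult) * mult
  if (tx == d[1] && ty == d[2]) return(list(x = x, orig = d[1:2]))
  out <- array(0, dim = c(tx, ty, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = out, orig = d[1:2])
}

#' Run a realized network on a patch
#'
#' Pads the in-plane extent to a multiple of the network's total
#' downsampling factor, executes the layer graph, crops back, and optionally
#' applies a channel softmax.  Output spatial extent equals the input's
#' (realization contract).
#'
#' @param net an [realize()]d network.
#' @param x 4D array `(x, y, z, channel)` (or a [multimodal_volume()]).
#' @param softmax return class probabilities instead of raw scores.
#' @return 4D array `(x, y, z, Cl)`.
#' @export
net_predict <- function(net, x, softmax = TRUE) {
  if (inherits(x, "multimodal_volume")) x <- stack_channels(x)
  mult <- 2^n_downsamples(net$blueprint)
  pd <- pad_inplane(x, mult)
  out <- net_forward(net, pd$x, keep_cache = FALSE)$out
  if (!identical(dim(out)[1:3], dim(pd$x)[1:3]))
    aniso_stop("realization",
               "backend contract violation: spatial extent changed (%s -> %s)",
               paste(dim(pd$x)[1:3], collapse = "x"),
               paste(dim(out)[1:3], collapse = "x"))
  out <- out[seq_len(dim(x)[1]), seq_len(dim(x)[2]), , , drop = FALSE]
  if (softmax) softmax_channels(out) else out
}

#' Stack the four modality channels into one 4D array
#' @param volume a [multimodal_volume()].
#' @export
stack_channels <- function(volume) {
  d <- volume$shape
  out <- array(0, dim = c(d, 4L))
  for (i in seq_along(MODALITIES)) out[, , , i] <- volume$channels[[MODALITIES[i]]]
  out
}

#' Empirically probe the receptive field of a realized network
#'
#' Measures the extent of input voxels that influence one central output
#' voxel by backpropagating a unit sensitivity from that voxel through a
#' probe-mode (linear, nonnegative) realization of the network.  Because the
#' footprint does not depend on channel width, wide blueprints are probed
#' with a channel-reduced twin by default.
#'
#' @param predictor an `aniso_net` (any mode) or a `network_blueprint`.
#' @param input_extent 3-vector of voxel extents of the probe grid; the
#'   in-plane extents must be multiples of the network's downsampling factor
#'   and large enough to contain the footprint, otherwise a probe-underflow
#'   error is raised.
#' @param C0 channel width used for the probe realization.
#' @return a `receptive_field`.
#' @export
probe_receptive_field <- function(predictor, input_extent, C0 = 2L) {
  bp <- if (inherits(predictor, "aniso_net")) predictor$blueprint
        else predictor
  if (!inherits(bp, "network_blueprint"))
    aniso_stop("realization", "predictor must be a realized network or blueprint")
  use_as_is <- inherits(predictor, "aniso_net") && predictor$probe_mode &&
    bp$C0 <= max(C0, 4L)
  net <- if (use_as_is) predictor else {
    bp2 <- make_blueprint("custom", C0 = C0, Cl = bp$Cl,
                          dilation_schedule = bp$dilation_schedule,
                          n_blocks = bp$n_blocks, ds_after = bp$ds_after,
                          inter_after = bp$inter_after, taps = bp$taps,
                          in_channels = bp$in_channels)
    realize(bp2, seed = 1L, probe_mode = TRUE)
  }
  mult <- 2^n_downsamples(net$blueprint)
  ext <- as.integer(input_extent)
  if (any(ext[1:2] %% mult != 0))
    aniso_stop("config", "in-plane input extent must be a multiple of %d", mult)
  x <- array(0, dim = c(ext, net$blueprint$in_channels))
  fw <- net_forward(net, x, keep_cache = TRUE)
  od <- dim(fw$out)
  ctr <- pmax((od[1:3] %/% 2L) %/% mult * mult, 0L)  # aligned central voxel
  ctr[3] <- od[3] %/% 2L
  gout <- array(0, dim = od)
  gout[ctr[1] + 1L, ctr[2] + 1L, ctr[3] + 1L, 1L] <- 1
  bw <- net_backward(net, fw, gout, need_param_grads = FALSE)
  sens <- apply(abs(bw$gx), 1:3, sum)
  nz <- which(sens > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) aniso_stop("graph", "no input sensitivity found")
  lo <- apply(nz, 2, min); hi <- apply(nz, 2, max)
  if (any(lo == 1L) || any(hi == dim(sens)))
    aniso_stop("probe_underflow",
               "input extent %s is smaller than the receptive field",
               paste(ext, collapse = "x"))
  structure(list(extents = as.integer(hi - lo + 1L)), class = "receptive_field")
}
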