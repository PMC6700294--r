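#' Anisotropic network blueprints
#'
#' Declarative layer graphs for the three cascade networks.  The backbone of
#' every variant holds 20 intra-slice (3x3x1) convolutions grouped as 10
#' residual blocks of two, interleaved with 4 inter-slice (1x1x3)
#' convolutions; WNet/TNet downsample the in-plane resolution twice, ENet
#' once.  Three intermediate prediction heads (3x3x1) tap the backbone at
#' different depths, are upsampled in-plane by transposed convolutions to the
#' input resolution and concatenated, and one final 3x3x1 prediction layer
#' maps the concatenation to `Cl` class scores.  Every backbone convolution
#' is followed by a normalization layer and a PReLU activation.
#'
#' Downsampling uses 5x5x1 stride-2 convolutions and upsampling 3x3x1
#' factor-2 transposed convolutions; together with the per-block dilation
#' schedule these make the analytic receptive field of the default WNet/TNet
#' exactly 217x217x9 voxels and that of ENet 113x113x9.  The shipped default
#' schedules were found by [find_dilation_schedule()], which performs the
#' constraint search reproducibly.
#'
#' @name net_blueprint
NULL

default_dilation_schedule <- function(variant) {
  switch(variant,
         WNet = c(1, 1, 1, 1, 2, 2, 2, 1, 1, 1),
         TNet = c(1, 1, 1, 1, 2, 2, 2, 1, 1, 1),
         ENet = c(1, 1, 1, 2, 2, 2, 1, 1, 1, 1),
         tiny = c(1, 1, 1, 1),
         NULL)
}

EXPECTED_RF_INPLANE <- c(WNet = 217, TNet = 217, ENet = 113)

#' Construct a network blueprint
#'
#' @param variant `"WNet"`, `"TNet"`, `"ENet"` (the full architectures),
#'   `"tiny"` (a 4-block, `C0 = 4` variant for fast tests; exempt from the
#'   receptive-field invariant), or `"custom"`.
#' @param C0 backbone channel count (default 32; 4 for tiny).
#' @param Cl prediction channel count (default 2).
#' @param dilation_schedule per-residual-block in-plane dilation factors;
#'   length must equal the block count.
#' @param n_blocks,ds_after,inter_after,taps structure overrides for
#'   `"custom"`: residual block count, blocks followed by a downsampling
#'   layer, blocks followed by an inter-slice convolution, and the three
#'   blocks tapped by prediction heads.
#' @param in_channels input channel count (4 modalities).
#' @return object of class `network_blueprint` holding the layer graph and
#'   structural metadata.
#' @export
make_blueprint <- function(variant = c("WNet", "TNet", "ENet", "tiny", "custom"),
                           C0 = NULL, Cl = 2L,
                           dilation_schedule = NULL,
                           n_blocks = NULL, ds_after = NULL,
                           inter_after = NULL, taps = NULL,
                           in_channels = 4L) {
  variant <- match.arg(variant)
  std <- variant %in% c("WNet", "TNet", "ENet")
  if (std) {
    n_blocks <- 10L
    ds_after <- if (variant == "ENet") c(1L, 2L)[1] else c(1L, 2L)
    inter_after <- c(2L, 4L, 6L, 8L)
    taps <- c(4L, 7L, 10L)
    C0 <- C0 %||% 32L
  } else if (variant == "tiny") {
    n_blocks <- n_blocks %||% 4L
    ds_after <- ds_after %||% 1L
    inter_after <- inter_after %||% c(1L, 3L)
    taps <- taps %||% c(2L, 3L, 4L)
    C0 <- C0 %||% 4L
  } else {
    if (is.null(n_blocks)) aniso_stop("blueprint", "custom variant needs n_blocks")
    ds_after <- ds_after %||% integer(0)
    inter_after <- inter_after %||% integer(0)
    taps <- taps %||% n_blocks
    C0 <- C0 %||% 8L
  }
  sched <- dilation_schedule %||% default_dilation_schedule(variant) %||%
    rep(1, n_blocks)
  if (length(sched) != n_blocks)
    aniso_stop("blueprint",
               "dilation schedule has length %d but the backbone has %d residual blocks",
               length(sched), n_blocks)
  if (any(sched < 1)) aniso_stop("blueprint", "dilations must be >= 1")
  bp <- structure(list(variant = variant, C0 = as.integer(C0), Cl = as.integer(Cl),
                       dilation_schedule = as.numeric(sched),
                       n_blocks = as.integer(n_blocks),
                       ds_after = as.integer(ds_after),
                       inter_after = as.integer(inter_after),
                       taps = as.integer(taps),
                       in_channels = as.integer(in_channels)),
                  class = "network_blueprint")
  bp$graph <- build_graph(bp)
  if (std) validate_standard_blueprint(bp)
  bp
}

#' @export
print.network_blueprint <- function(x, ...) {
  cnt <- layer_kind_counts(x)
  rf <- compute_receptive_field(x)
  cat(sprintf("<network_blueprint %s> C0=%d Cl=%d blocks=%d dilations=[%s]\n",
              x$variant, x$C0, x$Cl, x$n_blocks,
              paste(x$dilation_schedule, collapse = ",")))
  cat("  layers:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
  cat("  receptive field:", paste(rf$extents, collapse = "x"), "\n")
  invisible(x)
}

# ---- graph construction -----------------------------------------------------

new_node <- function(id, op, from, kind = NA_character_, k = c(1L, 1L, 1L),
                     d = c(1L, 1L, 1L), stride = 1L, pad = c(0L, 0L, 0L),
                     cin = NA_integer_, cout = NA_integer_) {
  list(id = id, op = op, from = from, kind = kind, k = as.integer(k),
       d = as.integer(d), stride = as.integer(stride), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout))
}

build_graph <- function(bp) {
  nodes <- list()
  nid <- 0L
  add <- function(...) {
    nid <<- nid + 1L
    nodes[[nid]] <<- new_node(nid, ...)
    nid
  }
  conv_bn_act <- function(from, kind, k, d, cin, cout, stride = 1L, pad = NULL) {
    pad <- pad %||% as.integer((k - 1) / 2 * d)
    cv <- add("conv", from, kind = kind, k = k, d = d, stride = stride,
              pad = pad, cin = cin, cout = cout)
    bn <- add("norm", cv, cin = cout, cout = cout)
    add("prelu", bn, cin = cout, cout = cout)
  }
  inp <- add("input", integer(0), cout = bp$in_channels)
  cur <- inp; cur_ch <- bp$in_channels
  tap_nodes <- integer(0); tap_res <- integer(0)
  res <- 1L
  for (b in seq_len(bp$n_blocks)) {
    d <- bp$dilation_schedule[b]
    block_in <- cur; block_in_ch <- cur_ch
    h <- conv_bn_act(cur, "intra_conv", c(3L, 3L, 1L), c(d, d, 1L), cur_ch, bp$C0)
    cv2 <- add("conv", h, kind = "intra_conv", k = c(3L, 3L, 1L),
               d = c(d, d, 1L), pad = as.integer(c(d, d, 0)),
               cin = bp$C0, cout = bp$C0)
    bn2 <- add("norm", cv2, cin = bp$C0, cout = bp$C0)
    # residual shortcut; channel-padded identity when widths differ
    ad <- add("add", c(bn2, block_in), kind = "residual_add",
              cin = bp$C0, cout = bp$C0)
    cur <- add("prelu", ad, cin = bp$C0, cout = bp$C0)
    cur_ch <- bp$C0
    if (b %in% bp$taps) { tap_nodes <- c(tap_nodes, cur); tap_res <- c(tap_res, res) }
    if (b %in% bp$inter_after)
      cur <- conv_bn_act(cur, "inter_conv", c(1L, 1L, 3L), c(1L, 1L, 1L),
                         cur_ch, bp$C0)
    if (b %in% bp$ds_after) {
      cur <- conv_bn_act(cur, "downsample2d", c(5L, 5L, 1L), c(1L, 1L, 1L),
                         cur_ch, bp$C0, stride = 2L, pad = c(2L, 2L, 0L))
      res <- res * 2L
    }
  }
  heads <- integer(0)
  for (i in seq_along(tap_nodes)) {
    h <- add("conv", tap_nodes[i], kind = "prediction_head", k = c(3L, 3L, 1L),
             d = c(1L, 1L, 1L), pad = c(1L, 1L, 0L),
             cin = bp$C0, cout = bp$Cl)
    r <- tap_res[i]
    while (r > 1L) {
      h <- add("deconv", h, kind = "upsample2d", k = c(3L, 3L, 1L),
               cin = bp$Cl, cout = bp$Cl)
      r <- r %/% 2L
    }
    heads <- c(heads, h)
  }
  cc <- add("concat", heads, kind = "concat",
            cin = bp$Cl * length(heads), cout = bp$Cl * length(heads))
  add("conv", cc, kind = "prediction_head", k = c(3L, 3L, 1L),
      d = c(1L, 1L, 1L), pad = c(1L, 1L, 0L),
      cin = bp$Cl * length(heads), cout = bp$Cl)
  for (nd in nodes)
    if (any(nd$from >= nd$id))
      aniso_stop("graph", "layer graph is cyclic at node %d", nd$id)
  nodes
}

layer_kind_counts <- function(bp) {
  kinds <- vapply(bp$graph, function(n) n$kind %||% NA_character_, character(1))
  c(intra_conv = sum(kinds == "intra_conv", na.rm = TRUE),
    inter_conv = sum(kinds == "inter_conv", na.rm = TRUE),
    downsample2d = sum(kinds == "downsample2d", na.rm = TRUE),
    upsample2d = sum(kinds == "upsample2d", na.rm = TRUE),
    prediction_head = sum(kinds == "prediction_head", na.rm = TRUE),
    residual_add = sum(kinds == "residual_add", na.rm = TRUE))
}

validate_standard_blueprint <- function(bp) {
  cnt <- layer_kind_counts(bp)
  want_ds <- if (bp$variant == "ENet") 1L else 2L
  checks <- c(intra_conv = 20L, inter_conv = 4L, downsample2d = want_ds,
              prediction_head = 4L, residual_add = 10L)
  for (k in names(checks))
    if (cnt[[k]] != checks[[k]])
      aniso_stop("blueprint", "variant %s must contain %d %s layers, found %d",
                 bp$variant, checks[[k]], k, cnt[[k]])
  rf <- compute_receptive_field(bp)
  want <- EXPECTED_RF_INPLANE[[bp$variant]]
  if (rf$extents[1] != want || rf$extents[2] != want || rf$extents[3] != 9)
    aniso_stop("blueprint",
               "dilation schedule yields receptive field %s, expected %dx%dx9",
               paste(rf$extents, collapse = "x"), want, want)
  invisible(bp)
}

# ---- receptive field --------------------------------------------------------

#' Analytic receptive field of a blueprint
#'
#' Propagates, per axis, the half-open index interval of input voxels that can
#' influence one central output voxel backwards through the layer graph (the
#' standard receptive-field recurrence over kernel extent, dilation and
#' stride, applied as exact interval arithmetic so that strided and
#' transposed layers are handled without approximation).  Multi-head graphs
#' take the union over paths, i.e. the maximum extent.
#'
#' @param bp a `network_blueprint` (or any object with a compatible `$graph`).
#' @return object of class `receptive_field` with integer `extents`
#'   `(x, y, z)` in voxels.
#' @export
compute_receptive_field <- function(bp) {
  nodes <- if (inherits(bp, "network_blueprint") || !is.null(bp$graph)) bp$graph else bp
  n <- length(nodes)
  for (nd in nodes)
    if (any(nd$from >= nd$id)) aniso_stop("graph", "layer graph is cyclic")
  # demand[[id]] = 3x2 matrix (axis x lo/hi) or NULL
  demand <- vector("list", n)
  demand[[n]] <- matrix(0L, 3, 2)
  merge_demand <- function(id, iv) {
    cur <- demand[[id]]
    demand[[id]] <<- if (is.null(cur)) iv
      else cbind(pmin(cur[, 1], iv[, 1]), pmax(cur[, 2], iv[, 2]))
  }
  for (id in rev(seq_len(n))) {
    iv <- demand[[id]]
    if (is.null(iv)) next
    nd <- nodes[[id]]
    if (nd$op == "input") next
    req <- switch(nd$op,
      conv = {
        out <- iv
        for (ax in 1:3) {
          reach <- (nd$k[ax] - 1L) %/% 2L * nd$d[ax]
          if (nd$stride == 2L && ax <= 2) {
            # stride-2 conv, kernel k, symmetric padding: out m <- in [2m-r, 2m+r]
            r <- (nd$k[ax] - 1L) %/% 2L
            out[ax, ] <- c(2L * iv[ax, 1] - r, 2L * iv[ax, 2] + r)
          } else {
            out[ax, ] <- c(iv[ax, 1] - reach, iv[ax, 2] + reach)
          }
        }
        out
      },
      deconv = {
        out <- iv
        for (ax in 1:2)
          out[ax, ] <- c(floor(iv[ax, 1] / 2), ceiling(iv[ax, 2] / 2))
        out
      },
      iv)  # norm / prelu / add / concat: index-preserving
    for (src in nd$from) merge_demand(src, req)
  }
  hull <- demand[[1]]
  if (is.null(hull)) aniso_stop("graph", "output is disconnected from the input")
  structure(list(extents = as.integer(hull[, 2] - hull[, 1] + 1L)),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat("<receptive_field>", paste(x$extents, collapse = " x "), "voxels\n")
  invisible(x)
}

#' Search a dilation schedule reproducing a target receptive field
#'
#' The per-block dilations of the backbone are not uniquely determined by the
#' layer counts; this constraint search finds a schedule whose analytic
#' in-plane receptive field equals `target`.  The extent is affine in the
#' schedule, so the search measures each block's coefficient once and then
#' distributes the remaining deficit greedily from the deepest block upwards.
#'
#' @param variant blueprint variant whose structure is searched.
#' @param target desired in-plane extent in voxels.
#' @param max_dilation largest allowed dilation per block.
#' @return integer schedule, or an error if the target is unreachable.
#' @export
find_dilation_schedule <- function(variant = c("WNet", "TNet", "ENet"),
                                   target = NULL, max_dilation = 3L) {
  variant <- match.arg(variant)
  target <- target %||% EXPECTED_RF_INPLANE[[variant]]
  nb <- 10L
  rf_of <- function(sched) {
    bp <- make_blueprint("custom", C0 = 2L, Cl = 2L, dilation_schedule = sched,
                         n_blocks = nb,
                         ds_after = if (variant == "ENet") 1L else c(1L, 2L),
                         inter_after = c(2L, 4L, 6L, 8L), taps = c(4L, 7L, 10L))
    compute_receptive_field(bp)$extents[1]
  }
  base <- rep(1L, nb)
  base_rf <- rf_of(base)
  coef <- vapply(seq_len(nb), function(b) {
    s <- base; s[b] <- 2L
    rf_of(s) - base_rf
  }, numeric(1))
  deficit <- target - base_rf
  if (deficit < 0) aniso_stop("blueprint", "target smaller than minimal receptive field")
  sched <- base
  for (b in order(coef, decreasing = TRUE)) {
    while (sched[b] < max_dilation && deficit >= coef[b] && coef[b] > 0) {
      sched[b] <- sched[b] + 1L
      deficit <- deficit - coef[b]
    }
  }
  if (deficit != 0)
    aniso_stop("blueprint",
               "no dilation schedule with max dilation %d reaches extent %d (off by %d)",
               max_dilation, target, deficit)
  stopifnot(rf_of(sched) == target)
  sched
}
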