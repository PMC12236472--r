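#' Network configuration
#'
#' Architecture hyperparameters for the multimodal voxel network. The
#' defaults mirror the published architecture (64^3 windows, 128-channel
#' multi-scale density branch with kernels 3/5/7/9, 64-channel fusion,
#' encoder stack of 128/256/512 filters, 64-channel-per-scale FPN giving 192
#' concatenated channels, task decoders with 4/4/21 output channels, dropout
#' 0.01). Reduced configurations (fewer channels, smaller windows) train and
#' evaluate on a single CPU; see [model_config_tiny()].
#'
#' @param window processing window edge, voxels.
#' @param fusion_channels channels after modality fusion.
#' @param encoder_channels integer vector of three encoder widths.
#' @param fpn_channels per-scale FPN channels (concatenated over 3 scales).
#' @param decoder_out output channels of the three decoders (fixed 4, 4, 21).
#' @param multiscale_kernels kernel sizes of the density branch.
#' @param multiscale_channels total channels of the multi-scale density
#'   branch (split evenly across kernels).
#' @param decoder_hidden hidden channels inside each decoder head.
#' @param attention_reduction channel reduction inside squeeze-excitation /
#'   global-attention blocks.
#' @param dropout dropout probability used during training.
#' @param downsample_encoders if TRUE each encoder block halves the spatial
#'   resolution (stride-2 average pooling) and the FPN upsamples back with
#'   trilinear interpolation; default keeps full resolution.
#' @return A `model_config` list.
#' @export
model_config <- function(window = 64L,
                         fusion_channels = 64L,
                         encoder_channels = c(128L, 256L, 512L),
                         fpn_channels = 64L,
                         decoder_out = c(4L, 4L, 21L),
                         multiscale_kernels = c(3L, 5L, 7L, 9L),
                         multiscale_channels = 128L,
                         decoder_hidden = 32L,
                         attention_reduction = 4L,
                         dropout = 0.01,
                         downsample_encoders = FALSE) {
  stopifnot(length(encoder_channels) == 3L,
            identical(as.integer(decoder_out), c(4L, 4L, 21L)),
            multiscale_channels %% length(multiscale_kernels) == 0L)
  structure(list(
    window = as.integer(window),
    fusion_channels = as.integer(fusion_channels),
    encoder_channels = as.integer(encoder_channels),
    fpn_channels = as.integer(fpn_channels),
    decoder_out = as.integer(decoder_out),
    multiscale_kernels = as.integer(multiscale_kernels),
    multiscale_channels = as.integer(multiscale_channels),
    decoder_hidden = as.integer(decoder_hidden),
    attention_reduction = as.integer(attention_reduction),
    dropout = dropout,
    downsample_encoders = isTRUE(downsample_encoders)),
    class = "model_config")
}

#' Reduced configuration for CPU-scale experiments
#'
#' Same topology as [model_config()] with small channel counts and window,
#' suitable for overfitting a handful of synthetic windows on one CPU.
#'
#' @param window window edge, voxels (default 16).
#' @return A `model_config`.
#' @export
model_config_tiny <- function(window = 16L) {
  model_config(window = window, fusion_channels = 8L,
               encoder_channels = c(8L, 12L, 16L), fpn_channels = 8L,
               multiscale_kernels = c(3L, 5L), multiscale_channels = 8L,
               decoder_hidden = 8L, attention_reduction = 2L)
}

he_init <- function(cout, cin, k) {
  matrix(stats::rnorm(cout * cin * k^3, sd = sqrt(2 / (cin * k^3))),
         nrow = cout)
}

new_conv_param <- function(cout, cin, k) {
  list(W = he_init(cout, cin, k), b = matrix(0, cout, 1L), k = k, cin = cin)
}

new_dense_param <- function(cout, cin) {
  list(W = matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin),
       b = matrix(0, cout, 1L))
}

# squeeze-excitation / global-attention parameter pair (two 1x1 convs on the
# pooled channel vector: C -> C/r -> C, sigmoid at the end)
new_se_param <- function(C, r) {
  mid <- max(1L, C %/% r)
  list(fc1 = new_dense_param(mid, C), fc2 = new_dense_param(C, mid))
}

#' Build the multimodal network
#'
#' Instantiates all parameters of the two-branch fusion network: a
#' multi-scale density branch with channel self-attention, a gated branch
#' for the 24-channel predicted-structure encoding, a fusion convolution,
#' three encoder blocks (residual dense block + squeeze-excitation + dual
#' local/global attention + transition), an FPN with learnable
#' softmax-normalized scale weights, and three cascaded decoders (backbone
#' -> C-alpha -> amino acid). Initialization is He-normal; pass a seed for
#' reproducible parameter draws.
#'
#' @param config a [model_config()].
#' @param seed optional integer seed for parameter initialization.
#' @return An object of class `voxel_model` (environment holding `params`,
#'   `config`, and Adam state).
#' @export
build_model <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  nk <- length(cf$multiscale_kernels)
  msc <- cf$multiscale_channels %/% nk
  M <- cf$multiscale_channels
  Fc <- cf$fusion_channels
  r <- cf$attention_reduction
  p <- list()
  # density branch
  p$ms <- lapply(cf$multiscale_kernels, function(k) new_conv_param(msc, 1L, k))
  p$ms_att <- new_se_param(M, r)
  # AF3 branch
  p$af_feat <- new_conv_param(Fc, 24L, 3L)
  p$af_gate1 <- new_conv_param(Fc, Fc, 3L)
  p$af_gate2 <- new_conv_param(Fc, Fc, 3L)
  # fusion
  p$fuse <- new_conv_param(Fc, M + Fc, 3L)
  # encoders
  cprev <- Fc
  p$enc <- list()
  for (e in 1:3) {
    C <- cf$encoder_channels[e]
    p$enc[[e]] <- list(
      rdb1 = new_conv_param(C, cprev, 3L),
      rdb2 = new_conv_param(C, cprev + C, 3L),
      rdb3 = new_conv_param(C, cprev + 2L * C, 3L),
      se = new_se_param(C, r),
      proj = new_conv_param(C, cprev, 1L),
      local = new_conv_param(C, C, 3L),
      glob = new_se_param(C, r),
      trans = new_conv_param(C, 2L * C, 3L))
    cprev <- C
  }
  # FPN
  p$lateral <- lapply(1:3, function(e)
    new_conv_param(cf$fpn_channels, cf$encoder_channels[e], 1L))
  p$smooth <- lapply(1:3, function(e)
    lapply(1:3, function(s) new_conv_param(cf$fpn_channels, cf$fpn_channels, 3L)))
  p$scale_w <- list(W = matrix(0, 3L, 1L))   # softmax-normalized scale weights
  # decoders (cascade)
  fpn_cat <- 3L * cf$fpn_channels
  h <- cf$decoder_hidden
  p$dec_bb1 <- new_conv_param(h, fpn_cat, 3L)
  p$dec_bb2 <- new_conv_param(4L, h, 1L)
  p$dec_ca1 <- new_conv_param(h, fpn_cat + 4L, 3L)
  p$dec_ca2 <- new_conv_param(4L, h, 1L)
  p$dec_aa1 <- new_conv_param(h, fpn_cat + 8L, 3L)
  p$dec_aa2 <- new_conv_param(21L, h, 1L)

  m <- new.env(parent = emptyenv())
  m$params <- p
  m$config <- cf
  m$adam <- NULL
  m$step <- 0L
  class(m) <- "voxel_model"
  m
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("<voxel_model> %s windows, %d parameters\n",
              paste(rep(x$config$window, 3), collapse = "x"),
              n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `voxel_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  n <- 0L
  walk <- function(p) {
    for (q in p) {
      if (is.list(q) && !is.null(q$W)) {
        n <<- n + length(q$W) + if (!is.null(q$b)) length(q$b) else 0L
      } else if (is.list(q)) walk(q)
    }
  }
  walk(model$params)
  n
}

# flatten params into a list of (path, field) references for the optimizer
param_refs <- function(p, path = character()) {
  out <- list()
  for (nm in names(p)) {
    q <- p[[nm]]
    if (is.list(q) && !is.null(q$W)) {
      out[[length(out) + 1L]] <- c(path, nm, "W")
      if (!is.null(q$b)) out[[length(out) + 1L]] <- c(path, nm, "b")
    } else if (is.list(q)) {
      out <- c(out, param_refs(q, c(path, nm)))
    }
  }
  out
}

get_by_path <- function(p, path) { for (k in path) p <- p[[k]]; p }
set_by_path <- function(p, path, value) {
  if (length(path) == 1L) { p[[path]] <- value; return(p) }
  p[[path[1]]] <- set_by_path(p[[path[1]]], path[-1], value)
  p
}

## ---- forward pass -----------------------------------------------------

# replace every parameter matrix in the params tree with a leaf node on the
# tape (req = training so eval passes skip gradient bookkeeping)
make_leaves <- function(p, tape, training) {
  lapply(p, function(q) {
    if (is.list(q) && !is.null(q$W)) {
      q$W <- t_leaf(q$W, c(1L, 1L, 1L), tape = tape, req = training)
      if (!is.null(q$b))
        q$b <- t_leaf(q$b, c(1L, 1L, 1L), tape = tape, req = training)
      q
    } else if (is.list(q)) make_leaves(q, tape, training)
    else q
  })
}

conv_apply <- function(x, lp, tape) t_conv(x, lp$W, lp$b, lp$k, tape)

se_apply <- function(x, lp, tape) {
  g <- t_gap(x, tape)
  h1 <- t_relu(t_dense(g, lp$fc1$W, lp$fc1$b, tape), tape)
  w <- t_sigmoid(t_dense(h1, lp$fc2$W, lp$fc2$b, tape), tape)
  t_cmul(x, w, tape)
}

# Forward pass. density: window^3 array; af3: 24-channel array
# (24 x window^3) or NULL for the density-only fallback. Returns the three
# logit tensors plus the tape and the leaf-node tree (used by the trainer to
# collect parameter gradients).
model_forward <- function(model, density, af3 = NULL, training = FALSE,
                          tape = NULL) {
  cf <- model$config
  if (is.array(density) && length(dim(density)) == 3L) {
    sp <- dim(density)
    density <- matrix(as.numeric(density), nrow = 1L)
  } else stop("model_forward: density must be a 3-D array")
  V <- prod(sp)
  if (is.null(tape)) tape <- new_tape()
  p <- make_leaves(model$params, tape, training)

  xd <- t_leaf(density, sp, tape = tape, req = FALSE)
  # multi-scale density features
  ms <- lapply(p$ms, function(prm) t_relu(conv_apply(xd, prm, tape), tape))
  dens <- t_concat(ms, tape)
  dens <- se_apply(dens, p$ms_att, tape)         # channel self-attention

  # AF3 branch (zero channels when absent)
  if (is.null(af3)) {
    af3m <- matrix(0, 24L, V)
  } else {
    if (length(dim(af3)) == 4L) af3m <- matrix(as.numeric(af3), nrow = 24L)
    else af3m <- af3
    if (ncol(af3m) != V) stop("model_forward: AF3 encoding shape mismatch")
  }
  xa <- t_leaf(af3m, sp, tape = tape, req = FALSE)
  af <- t_relu(conv_apply(xa, p$af_feat, tape), tape)
  gate <- t_sigmoid(conv_apply(
    t_relu(conv_apply(af, p$af_gate1, tape), tape), p$af_gate2, tape), tape)
  af <- t_mul(af, gate, tape)

  # fusion
  x <- t_relu(conv_apply(t_concat(list(dens, af), tape), p$fuse, tape), tape)
  if (training) x <- t_dropout(x, cf$dropout, tape)

  # encoder stack
  enc_out <- vector("list", 3L)
  for (e in 1:3) {
    pe <- p$enc[[e]]
    c1 <- t_relu(conv_apply(x, pe$rdb1, tape), tape)
    c2 <- t_relu(conv_apply(t_concat(list(x, c1), tape), pe$rdb2, tape), tape)
    c3 <- t_relu(conv_apply(t_concat(list(x, c1, c2), tape), pe$rdb3, tape),
                 tape)
    c3 <- se_apply(c3, pe$se, tape)
    res <- t_add(conv_apply(x, pe$proj, tape), c3, tape)
    loc <- t_relu(conv_apply(res, pe$local, tape), tape)
    glo <- se_apply(res, pe$glob, tape)
    x <- t_relu(conv_apply(t_concat(list(loc, glo), tape), pe$trans, tape),
                tape)
    if (training) x <- t_dropout(x, cf$dropout, tape)
    if (cf$downsample_encoders) x <- t_pool2(x, tape)
    enc_out[[e]] <- x
  }

  # FPN: lateral 1x1 convs, upsample to the finest scale, smooth, weight
  fine_sp <- enc_out[[1]]$sp
  pyr <- vector("list", 3L)
  for (e in 1:3) {
    f <- conv_apply(enc_out[[e]], p$lateral[[e]], tape)
    f <- t_upsample(f, fine_sp, tape)
    for (s in 1:3) f <- t_relu(conv_apply(f, p$smooth[[e]][[s]], tape), tape)
    pyr[[e]] <- f
  }
  sw <- t_softmax_vec(p$scale_w$W, tape)
  weighted <- lapply(1:3, function(e)
    t_scale_mix(list(pyr[[e]]), slice_weight(sw, e, tape), tape))
  fpn <- t_concat(weighted, tape)
  if (cf$downsample_encoders) fpn <- t_upsample(fpn, sp, tape)

  # cascaded decoders
  h_bb <- t_relu(conv_apply(fpn, p$dec_bb1, tape), tape)
  bb <- conv_apply(h_bb, p$dec_bb2, tape)
  h_ca <- t_relu(conv_apply(t_concat(list(fpn, bb), tape), p$dec_ca1, tape),
                 tape)
  ca <- conv_apply(h_ca, p$dec_ca2, tape)
  h_aa <- t_relu(conv_apply(t_concat(list(fpn, bb, ca), tape), p$dec_aa1,
                            tape), tape)
  aa <- conv_apply(h_aa, p$dec_aa2, tape)

  list(backbone = bb, calpha = ca, amino = aa, tape = tape, leaves = p,
       sp = sp)
}

# 1 x 1 view of one component of the scale-weight vector (keeps gradient
# flowing back into the softmax weights)
slice_weight <- function(w, s, tape) {
  tnsr(w$val[s, , drop = FALSE], c(1L, 1L, 1L), parents = list(w),
       tape = tape, bw = function(g) {
         gw <- matrix(0, nrow(w$val), 1L); gw[s, 1] <- as.numeric(g)
         acc_grad(w, gw)
       })
}

#' Run the network on one window
#'
#' Deterministic (eval-mode) forward pass; useful for tests and inference.
#'
#' @param model a `voxel_model`.
#' @param density `window^3` numeric array.
#' @param af3 optional 24-channel encoding for the same window
#'   (`24 x window^3` array), or NULL for the density-only fallback.
#' @return List of three logit arrays: `backbone` and `calpha`
#'   (`4 x window^3`) and `amino` (`21 x window^3`).
#' @export
forward_window <- function(model, density, af3 = NULL) {
  out <- model_forward(model, density, af3, training = FALSE)
  sp <- out$sp
  list(backbone = array(out$backbone$val, c(4L, sp)),
       calpha = array(out$calpha$val, c(4L, sp)),
       amino = array(out$amino$val, c(21L, sp)))
}
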