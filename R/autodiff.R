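# Minimal reverse-mode automatic differentiation over channels-first voxel
# tensors. A tensor is an environment holding `val` (C x V matrix), `sp`
# (spatial dims, length 3), `grad`, `parents`, a backward closure `bw`, and
# `req` (whether any upstream parameter needs this node's gradient). In
# training mode every op records itself on a tape (creation order =
# topological order); in eval mode nothing is recorded and intermediates are
# garbage-collected as the forward pass proceeds.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

tnsr <- function(val, sp, parents = list(), bw = NULL, tape = NULL,
                 req = NULL) {
  e <- new.env(parent = emptyenv())
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  e$val <- val
  e$sp <- as.integer(sp)
  e$grad <- NULL
  if (is.null(req)) req <- any(vapply(parents, function(p) p$req, logical(1)))
  e$req <- req
  if (!is.null(tape) && req) {
    e$parents <- parents
    e$bw <- bw
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- e
  } else {
    e$parents <- list()
    e$bw <- NULL
  }
  class(e) <- "tnsr"
  e
}

t_leaf <- function(val, sp, tape = NULL, req = FALSE) {
  tnsr(val, sp, tape = tape, req = req)
}

acc_grad <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# run reverse pass from a scalar loss node
backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (idx in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[idx]]
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

nvox <- function(x) prod(x$sp)

## ---- ops --------------------------------------------------------------

t_conv <- function(x, W, b, k, tape) {
  y <- conv3d_fw(x$val, x$sp, W$val, as.numeric(b$val), k)
  cin <- nrow(x$val)
  tnsr(y, x$sp, parents = list(x, W, b), tape = tape, bw = function(g) {
    if (x$req) acc_grad(x, conv3d_bw_x(g, x$sp, W$val, cin, k))
    gwb <- conv3d_bw_w(g, x$val, x$sp, k)
    acc_grad(W, gwb$gw)
    acc_grad(b, matrix(gwb$gb, nrow = nrow(b$val)))
  })
}

t_relu <- function(x, tape) {
  m <- x$val > 0
  tnsr(x$val * m, x$sp, parents = list(x), tape = tape,
       bw = function(g) acc_grad(x, g * m))
}

t_sigmoid <- function(x, tape) {
  s <- 1 / (1 + exp(-x$val))
  tnsr(s, x$sp, parents = list(x), tape = tape,
       bw = function(g) acc_grad(x, g * s * (1 - s)))
}

t_add <- function(x, y, tape) {
  tnsr(x$val + y$val, x$sp, parents = list(x, y), tape = tape,
       bw = function(g) { acc_grad(x, g); acc_grad(y, g) })
}

t_mul <- function(x, y, tape) {
  tnsr(x$val * y$val, x$sp, parents = list(x, y), tape = tape,
       bw = function(g) { acc_grad(x, g * y$val); acc_grad(y, g * x$val) })
}

# channel-wise scale: w is C x 1 (e.g. squeeze-excitation weights)
t_cmul <- function(x, w, tape) {
  wv <- as.numeric(w$val)
  tnsr(x$val * wv, x$sp, parents = list(x, w), tape = tape, bw = function(g) {
    acc_grad(x, g * wv)
    acc_grad(w, matrix(rowSums(g * x$val), ncol = 1L))
  })
}

t_concat <- function(xs, tape) {
  v <- do.call(rbind, lapply(xs, function(x) x$val))
  rows <- vapply(xs, function(x) nrow(x$val), integer(1))
  ends <- cumsum(rows)
  starts <- c(1L, head(ends, -1L) + 1L)
  tnsr(v, xs[[1]]$sp, parents = xs, tape = tape, bw = function(g) {
    for (s in seq_along(xs))
      acc_grad(xs[[s]], g[starts[s]:ends[s], , drop = FALSE])
  })
}

# global average pool: C x V -> C x 1 (spatial 1,1,1)
t_gap <- function(x, tape) {
  V <- ncol(x$val)
  tnsr(matrix(rowMeans(x$val), ncol = 1L), c(1L, 1L, 1L),
       parents = list(x), tape = tape, bw = function(g) {
         acc_grad(x, matrix(as.numeric(g) / V, nrow(x$val), V))
       })
}

# dense layer on C x 1 vectors (1x1 conv on pooled features)
t_dense <- function(x, W, b, tape) {
  y <- W$val %*% x$val + b$val
  tnsr(y, c(1L, 1L, 1L), parents = list(x, W, b), tape = tape,
       bw = function(g) {
         if (x$req) acc_grad(x, crossprod(W$val, g))
         acc_grad(W, g %*% t(x$val))
         acc_grad(b, g)
       })
}

# softmax over the rows of a column vector (learnable scale weights)
t_softmax_vec <- function(x, tape) {
  v <- as.numeric(x$val)
  p <- exp(v - max(v)); p <- p / sum(p)
  tnsr(matrix(p, ncol = 1L), x$sp, parents = list(x), tape = tape,
       bw = function(g) {
         gv <- as.numeric(g)
         acc_grad(x, matrix(p * (gv - sum(gv * p)), ncol = 1L))
       })
}

# weighted sum of S same-shape tensors with weights from an S x 1 node
t_scale_mix <- function(xs, w, tape) {
  wv <- as.numeric(w$val)
  v <- Reduce(`+`, Map(function(x, s) x$val * wv[s], xs, seq_along(xs)))
  tnsr(v, xs[[1]]$sp, parents = c(xs, list(w)), tape = tape,
       bw = function(g) {
         gw <- numeric(length(xs))
         for (s in seq_along(xs)) {
           acc_grad(xs[[s]], g * wv[s])
           gw[s] <- sum(g * xs[[s]]$val)
         }
         acc_grad(w, matrix(gw, ncol = 1L))
       })
}

t_dropout <- function(x, p, tape, rng_on = TRUE) {
  if (!rng_on || p <= 0) return(x)
  keep <- matrix(stats::rbinom(length(x$val), 1L, 1 - p), nrow(x$val)) / (1 - p)
  tnsr(x$val * keep, x$sp, parents = list(x), tape = tape,
       bw = function(g) acc_grad(x, g * keep))
}

# stride-2 average pooling (used by the optional encoder downsampling path)
t_pool2 <- function(x, tape) {
  sp <- x$sp
  out_sp <- pmax(1L, sp %/% 2L)
  map <- pool2_index(sp, out_sp)            # V_in -> V_out assignment
  cnt <- tabulate(map, nbins = prod(out_sp))
  y <- t(rowsum(t(x$val), group = map)) / rep(cnt, each = nrow(x$val))
  tnsr(y, out_sp, parents = list(x), tape = tape, bw = function(g) {
    acc_grad(x, g[, map, drop = FALSE] / rep(cnt[map], each = nrow(x$val)))
  })
}

pool2_index <- function(sp, out_sp) {
  i1 <- pmin((seq_len(sp[1]) - 1L) %/% 2L, out_sp[1] - 1L)
  i2 <- pmin((seq_len(sp[2]) - 1L) %/% 2L, out_sp[2] - 1L)
  i3 <- pmin((seq_len(sp[3]) - 1L) %/% 2L, out_sp[3] - 1L)
  g <- expand.grid(a = i1, b = i2, c = i3)
  as.integer(g$a + out_sp[1] * (g$b + out_sp[2] * g$c)) + 1L
}

# trilinear upsampling to the given spatial dims
t_upsample <- function(x, out_sp, tape) {
  if (all(x$sp == out_sp)) return(x)
  ip <- trilin_plan(x$sp, out_sp)
  C <- nrow(x$val)
  y <- matrix(0, C, prod(out_sp))
  for (c8 in seq_len(8L))
    y <- y + x$val[, ip$idx[, c8], drop = FALSE] *
      rep(ip$w[, c8], each = C)
  tnsr(y, out_sp, parents = list(x), tape = tape, bw = function(g) {
    gx <- matrix(0, C, prod(x$sp))
    for (c8 in seq_len(8L)) {
      part <- rowsum(t(g * rep(ip$w[, c8], each = C)), group = ip$idx[, c8])
      gx[, as.integer(rownames(part))] <-
        gx[, as.integer(rownames(part)), drop = FALSE] + t(part)
    }
    acc_grad(x, gx)
  })
}

# per-output-voxel corner indices (V_out x 8) and weights for trilinear
# interpolation from in_sp to out_sp (align-corners convention)
trilin_plan <- function(in_sp, out_sp) {
  axpos <- function(n_out, n_in) {
    if (n_out == 1L) return(list(lo = 1L, fr = 0))
    pos <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    lo <- pmin(floor(pos), n_in - 2L + (n_in == 1L)) + 1L
    list(lo = as.integer(pmax(lo, 1L)), fr = pos - (lo - 1L))
  }
  a1 <- axpos(out_sp[1], in_sp[1]); a2 <- axpos(out_sp[2], in_sp[2])
  a3 <- axpos(out_sp[3], in_sp[3])
  g <- expand.grid(i = seq_len(out_sp[1]), j = seq_len(out_sp[2]),
                   k = seq_len(out_sp[3]))
  l1 <- a1$lo[g$i]; f1 <- a1$fr[g$i]
  l2 <- a2$lo[g$j]; f2 <- a2$fr[g$j]
  l3 <- a3$lo[g$k]; f3 <- a3$fr[g$k]
  h1 <- pmin(l1 + 1L, in_sp[1]); h2 <- pmin(l2 + 1L, in_sp[2])
  h3 <- pmin(l3 + 1L, in_sp[3])
  lin <- function(a, b, c) a + in_sp[1] * (b - 1L) + in_sp[1] * in_sp[2] * (c - 1L)
  idx <- cbind(lin(l1, l2, l3), lin(h1, l2, l3), lin(l1, h2, l3),
               lin(l1, l2, h3), lin(h1, h2, l3), lin(h1, l2, h3),
               lin(l1, h2, h3), lin(h1, h2, h3))
  w <- cbind((1 - f1) * (1 - f2) * (1 - f3), f1 * (1 - f2) * (1 - f3),
             (1 - f1) * f2 * (1 - f3), (1 - f1) * (1 - f2) * f3,
             f1 * f2 * (1 - f3), f1 * (1 - f2) * f3,
             (1 - f1) * f2 * f3, f1 * f2 * f3)
  list(idx = idx, w = w)
}

# fused weighted cross-entropy over voxels (Eq.-style: mean over voxels of
# -w_class * log softmax at the true class). labels: integer vector of
# 0-based classes, one per voxel; w: numeric class weights (length K).
t_wce <- function(logits, labels, w, tape) {
  K <- nrow(logits$val)
  if (any(labels < 0L | labels >= K))
    stop("weighted_cross_entropy: label out of range [0, ", K - 1L, "]")
  V <- ncol(logits$val)
  m <- apply(logits$val, 2L, max)
  ex <- exp(sweep(logits$val, 2L, m))
  p <- sweep(ex, 2L, colSums(ex), `/`)
  li <- cbind(labels + 1L, seq_len(V))
  wv <- w[labels + 1L]
  loss <- -mean(wv * log(pmax(p[li], 1e-300)))
  tnsr(matrix(loss, 1L, 1L), c(1L, 1L, 1L), parents = list(logits),
       tape = tape, bw = function(g) {
         gl <- sweep(p, 2L, wv, `*`)
         gl[li] <- gl[li] - wv
         acc_grad(logits, gl * (as.numeric(g) / V))
       })
}
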