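# Reverse-mode automatic differentiation on plain R arrays.
#
# A tensor is an environment holding a value (`v`, numeric array), an
# accumulated gradient (`grad`), its parents in the computation graph and a
# backward closure mapping the output gradient to parent gradients. Graphs
# are rebuilt every forward pass (define-by-run); `ad_backward()` walks the
# tape in reverse topological order. Sized for desk-scale networks: all ops
# are vectorized array operations, convolutions go through im2col + matmul.

#' Array autodiff engine primitives
#'
#' Low-level reverse-mode operations of the package's array autodiff engine.
#' Each operation takes `ad_tensor` objects (create them with `ad_const()`
#' for data and `ad_param()` for trainables), builds the backward closure as
#' a side effect, and returns a new tensor; `ad_backward()` on a scalar loss
#' accumulates gradients into the `grad` fields of all reachable parameters.
#' Feature maps are `(H, W, C, N)` arrays; matrices are `(rows, cols)`.
#' These primitives power every trainable block in the package and are
#' exposed for extension and testing.
#'
#' @param ... operation arguments; see the function signatures
#' @name engine_ops
#' @keywords internal
NULL

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

#' @rdname engine_ops
#' @export
new_tensor <- function(v, parents = list(), backward = NULL,
                       param = FALSE, req = NULL) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$grad <- NULL
  t$parents <- parents
  t$backward <- backward
  t$param <- param
  if (is.null(req)) {
    req <- param
    for (p in parents) if (p$req) { req <- TRUE; break }
  }
  t$req <- req
  .ad$id <- .ad$id + 1L
  t$id <- .ad$id
  class(t) <- "ad_tensor"
  t
}

#' @export
print.ad_tensor <- function(x, ...) {
  cat("<ad_tensor", paste(dim(x$v) %||% length(x$v), collapse = "x"),
      if (x$param) "param" else "", ">\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname engine_ops
#' @export
ad_const <- function(v) new_tensor(v, req = FALSE)
#' @rdname engine_ops
#' @export
ad_param <- function(v) new_tensor(v, param = TRUE)

#' Detach a tensor from the graph
#' @param x an `ad_tensor`
#' @return a constant tensor sharing `x`'s value
#' @export
ad_detach <- function(x) ad_const(x$v)

#' @rdname engine_ops
#' @export
as_tensor <- function(x) if (inherits(x, "ad_tensor")) x else ad_const(x)

ad_topo <- function(root) {
  visited <- new.env(parent = emptyenv())
  out <- new.env(parent = emptyenv())
  out$l <- vector("list", 512L)
  out$n <- 0L
  visit <- function(node) {
    key <- as.character(node$id)
    if (!is.null(visited[[key]])) return(invisible(NULL))
    visited[[key]] <- TRUE
    for (p in node$parents) visit(p)
    out$n <- out$n + 1L
    if (out$n > length(out$l)) out$l <- c(out$l, vector("list", length(out$l)))
    out$l[[out$n]] <- node
    invisible(NULL)
  }
  visit(root)
  out$l[seq_len(out$n)]
}

#' Run backpropagation from a scalar loss tensor
#' @param loss scalar `ad_tensor`
#' @export
ad_backward <- function(loss) {
  stopifnot(length(loss$v) == 1L)
  order <- ad_topo(loss)
  loss$grad <- array(1, dim = dim(loss$v) %||% 1L)
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$req) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# ---- elementwise ops --------------------------------------------------------

#' @rdname engine_ops
#' @export
ad_add <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  new_tensor(a$v + b$v, list(a, b), function(g) list(g, g))
}

#' @rdname engine_ops
#' @export
ad_sub <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  new_tensor(a$v - b$v, list(a, b), function(g) list(g, -g))
}

#' @rdname engine_ops
#' @export
ad_emul <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  new_tensor(a$v * b$v, list(a, b),
             function(g) list(if (a$req) g * b$v else NULL,
                              if (b$req) g * a$v else NULL))
}

#' @rdname engine_ops
#' @export
ad_scale <- function(x, s) {
  # s: plain numeric scalar
  new_tensor(x$v * s, list(x), function(g) list(g * s))
}

#' @rdname engine_ops
#' @export
ad_smul <- function(x, s) {
  # s: scalar ad_tensor (e.g. a learnable fusion weight)
  stopifnot(length(s$v) == 1L)
  new_tensor(x$v * as.numeric(s$v), list(x, s),
             function(g) list(if (x$req) g * as.numeric(s$v) else NULL,
                              if (s$req) sum(g * x$v) else NULL))
}

#' @rdname engine_ops
#' @export
ad_relu <- function(x) {
  m <- x$v > 0
  new_tensor(x$v * m, list(x), function(g) list(g * m))
}

#' @rdname engine_ops
#' @export
ad_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$v))
  new_tensor(y, list(x), function(g) list(g * y * (1 - y)))
}

#' @rdname engine_ops
#' @export
ad_log <- function(x, eps = 1e-12) {
  vc <- pmax(x$v, eps)
  new_tensor(log(vc), list(x), function(g) list(g / vc))
}

#' @rdname engine_ops
#' @export
ad_pow <- function(x, p) {
  new_tensor(x$v^p, list(x), function(g) list(g * p * x$v^(p - 1)))
}

#' @rdname engine_ops
#' @export
ad_sum <- function(x) {
  d <- dim(x$v) %||% length(x$v)
  new_tensor(sum(x$v), list(x), function(g) list(array(as.numeric(g), d)))
}

#' @rdname engine_ops
#' @export
ad_mean <- function(x) {
  n <- length(x$v)
  d <- dim(x$v) %||% n
  new_tensor(mean(x$v), list(x), function(g) list(array(as.numeric(g) / n, d)))
}

# ---- dense / pooling --------------------------------------------------------

#' @rdname engine_ops
#' @export
ad_linear <- function(x, W, b = NULL) {
  # x: (Din, N); W: (Dout, Din); b: (Dout)
  xv <- if (is.matrix(x$v)) x$v else matrix(x$v, ncol = 1L)
  y <- W$v %*% xv
  if (!is.null(b)) y <- y + as.vector(b$v)
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  new_tensor(y, parents, function(g) {
    g <- matrix(g, nrow = nrow(W$v))
    out <- list(if (x$req) crossprod(W$v, g) else NULL,
                if (W$req) tcrossprod(g, xv) else NULL)
    if (!is.null(b)) out <- c(out, list(if (b$req) rowSums(g) else NULL))
    out
  })
}

#' @rdname engine_ops
#' @export
ad_gap <- function(x) {
  # (H, W, C, N) -> (C, N): spatial mean per channel
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- matrix(colMeans(matrix(x$v, H * W, C * N)), C, N)
  new_tensor(y, list(x), function(g) {
    list(array(rep(as.vector(g), each = H * W) / (H * W), d))
  })
}

#' @rdname engine_ops
#' @export
ad_broadcast_hw <- function(x, H, W) {
  # (C, N) -> (H, W, C, N), spatially constant
  d <- dim(x$v); C <- d[1]; N <- d[2]
  y <- array(rep(as.vector(x$v), each = H * W), c(H, W, C, N))
  new_tensor(y, list(x), function(g) {
    list(matrix(colSums(matrix(g, H * W, C * N)), C, N))
  })
}

#' @rdname engine_ops
#' @export
ad_mul_channel <- function(x, wc) {
  # x: (H, W, C, N); wc: (C, N) per-sample channel weights
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  brd <- array(rep(as.vector(wc$v), each = H * W), d)
  new_tensor(x$v * brd, list(x, wc), function(g) {
    list(if (x$req) g * brd else NULL,
         if (wc$req)
           matrix(colSums(matrix(g * x$v, H * W, C * N)), C, N) else NULL)
  })
}

#' @rdname engine_ops
#' @export
ad_mul_spatial <- function(x, ws) {
  # x: (H, W, C, N); ws: (H, W, 1, N) spatial weight map
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  w3 <- array(ws$v, c(H, W, N))
  brd <- aperm(array(rep(as.vector(w3), times = C), c(H, W, N, C)),
               c(1L, 2L, 4L, 3L))
  new_tensor(x$v * brd, list(x, ws), function(g) {
    list(if (x$req) g * brd else NULL,
         if (ws$req) {
           gx <- g * x$v
           s <- matrix(aperm(gx, c(1L, 2L, 4L, 3L)), H * W * N, C)
           array(rowSums(s), c(H, W, 1L, N))
         } else NULL)
  })
}

#' @rdname engine_ops
#' @export
ad_concat_c <- function(xs) {
  # channel concatenation of (H, W, Ci, N) tensors
  d1 <- dim(xs[[1]]$v)
  cs <- vapply(xs, function(t) dim(t$v)[3], numeric(1))
  Ctot <- sum(cs)
  y <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  at <- 0L
  for (t in xs) {
    ci <- dim(t$v)[3]
    y[, , at + seq_len(ci), ] <- t$v
    at <- at + ci
  }
  new_tensor(y, xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (i in seq_along(xs)) {
      ci <- cs[i]
      if (xs[[i]]$req) out[[i]] <- g[, , at + seq_len(ci), , drop = FALSE]
      at <- at + ci
    }
    out
  })
}

#' @rdname engine_ops
#' @export
ad_slice_c <- function(x, idx) {
  d <- dim(x$v)
  new_tensor(x$v[, , idx, , drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[, , idx, ] <- g
    list(gx)
  })
}

#' @rdname engine_ops
#' @export
ad_chan_maxmean <- function(x) {
  # per-pixel channel max and mean -> (H, W, 2, N)
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  vm <- matrix(aperm(x$v, c(3L, 1L, 2L, 4L)), C, H * W * N)
  mx <- vm[1L, ]; am <- rep(1L, ncol(vm))
  if (C > 1L) for (ci in 2:C) {
    sel <- vm[ci, ] > mx
    mx[sel] <- vm[ci, sel]; am[sel] <- ci
  }
  mn <- colMeans(vm)
  y <- array(0, c(H, W, 2L, N))
  y[, , 1L, ] <- array(mx, c(H, W, N))
  y[, , 2L, ] <- array(mn, c(H, W, N))
  new_tensor(y, list(x), function(g) {
    g1 <- as.vector(array(g[, , 1L, ], c(H, W, N)))
    g2 <- as.vector(array(g[, , 2L, ], c(H, W, N)))
    gm <- matrix(0, C, H * W * N)
    gm[cbind(am, seq_along(am))] <- g1
    gm <- gm + matrix(rep(g2 / C, each = C), C)
    list(aperm(array(gm, c(C, H, W, N)), c(2L, 3L, 1L, 4L)))
  })
}

# ---- convolution ------------------------------------------------------------

# im2col index cache: for a fixed (padded-input shape, kernel, stride,
# dilation) the gather indices are constant, so they are built once and the
# per-call work is a single vectorized gather (forward) / rowsum (backward).
.ad$conv_cache <- new.env(parent = emptyenv())

conv_index_map <- function(dimpad, k, stride, dil, Ho, Wo) {
  key <- paste(c(dimpad, k, stride, dil), collapse = "_")
  hit <- .ad$conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- dimpad[1]; Wp <- dimpad[2]; Cin <- dimpad[3]; N <- dimpad[4]
  r0 <- 1L + (0:(Ho - 1L)) * stride
  c0 <- 1L + (0:(Wo - 1L)) * stride
  hw <- as.vector(outer(r0, (c0 - 1L) * Hp, "+"))
  hwn <- rep(hw, times = N) + rep((0:(N - 1L)) * Hp * Wp * Cin,
                                  each = Ho * Wo)
  offs <- integer(k * k * Cin)
  cc <- 0L
  for (c in seq_len(Cin)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    cc <- cc + 1L
    offs[cc] <- dy * dil + dx * dil * Hp + (c - 1L) * Hp * Wp
  }
  idx <- outer(hwn, offs, "+")
  storage.mode(idx) <- "integer"
  .ad$conv_cache[[key]] <- idx
  idx
}

im2col <- function(xpad, k, stride, dil, Ho, Wo) {
  idx <- conv_index_map(dim(xpad), k, stride, dil, Ho, Wo)
  # linear gather (as.vector guards against matrix-subscript semantics)
  matrix(xpad[as.vector(idx)], nrow(idx), ncol(idx))
}

col2im_add <- function(gcols, dimpad, k, stride, dil, Ho, Wo) {
  gx <- array(0, dimpad)
  Cin <- dimpad[3]
  cc <- 0L
  for (c in seq_len(Cin)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    cc <- cc + 1L
    rows <- seq.int(1L + dy * dil, by = stride, length.out = Ho)
    colx <- seq.int(1L + dx * dil, by = stride, length.out = Wo)
    gx[rows, colx, c, ] <- gx[rows, colx, c, , drop = FALSE] +
      array(gcols[, cc], c(Ho, Wo, 1L, dimpad[4]))
  }
  gx
}

#' @rdname engine_ops
#' @export
ad_conv2d <- function(x, W, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  d <- dim(x$v); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  wd <- dim(W$v); k <- wd[1]; Cout <- wd[4]
  stopifnot(wd[3] == Cin)
  Ho <- (H + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
  Wo <- (Wd + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop("conv2d: output size would be empty")
  if (pad > 0L) {
    xpad <- array(0, c(H + 2L * pad, Wd + 2L * pad, Cin, N))
    xpad[pad + seq_len(H), pad + seq_len(Wd), , ] <- x$v
  } else xpad <- x$v
  cols <- im2col(xpad, k, stride, dil, Ho, Wo)
  Wm <- matrix(W$v, k * k * Cin, Cout)
  y <- cols %*% Wm
  if (!is.null(b)) y <- y + matrix(b$v, nrow(y), Cout, byrow = TRUE)
  yv <- aperm(array(y, c(Ho, Wo, N, Cout)), c(1L, 2L, 4L, 3L))
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  dimpad <- dim(xpad)
  new_tensor(yv, parents, function(g) {
    gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), Ho * Wo * N, Cout)
    gx <- NULL
    if (x$req) {
      gcols <- gm %*% t(Wm)
      gxp <- col2im_add(gcols, dimpad, k, stride, dil, Ho, Wo)
      gx <- if (pad > 0L)
        gxp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE] else gxp
    }
    out <- list(gx,
                if (W$req) array(crossprod(cols, gm), wd) else NULL)
    if (!is.null(b)) out <- c(out, list(if (b$req) colSums(gm) else NULL))
    out
  })
}

#' @rdname engine_ops
#' @export
ad_dwconv2d <- function(x, W, b = NULL, prepadded = FALSE) {
  # depthwise 3x3, stride 1; W: (3, 3, C). With `prepadded = TRUE` the input
  # is already (H+2, W+2, C, N) (e.g. via ad_reflect_pad) and no zero padding
  # is added; gradients then flow back through the padding op.
  dx <- dim(x$v)
  if (prepadded) {
    H <- dx[1] - 2L; Wd <- dx[2] - 2L
  } else {
    H <- dx[1]; Wd <- dx[2]
  }
  C <- dx[3]; N <- dx[4]
  stopifnot(all(dim(W$v)[1:2] == 3L), dim(W$v)[3] == C)
  if (prepadded) {
    xpad <- x$v
  } else {
    xpad <- array(0, c(H + 2L, Wd + 2L, C, N))
    xpad[1L + seq_len(H), 1L + seq_len(Wd), , ] <- x$v
  }
  d <- c(H, Wd, C, N)
  y <- array(0, d)
  shifts <- vector("list", 9L)
  i <- 0L
  for (dxo in 0:2) for (dyo in 0:2) {
    i <- i + 1L
    sh <- xpad[dyo + seq_len(H), dxo + seq_len(Wd), , , drop = FALSE]
    shifts[[i]] <- sh
    wrep <- array(rep(rep(W$v[dyo + 1L, dxo + 1L, ], each = H * Wd),
                      times = N), d)
    y <- y + sh * wrep
  }
  if (!is.null(b))
    y <- y + array(rep(rep(b$v, each = H * Wd), times = N), d)
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  new_tensor(y, parents, function(g) {
    gW <- if (W$req) array(0, dim(W$v)) else NULL
    gxp <- if (x$req) array(0, dim(xpad)) else NULL
    i <- 0L
    for (dxo in 0:2) for (dyo in 0:2) {
      i <- i + 1L
      if (!is.null(gW)) {
        prod <- g * shifts[[i]]
        gW[dyo + 1L, dxo + 1L, ] <-
          colSums(matrix(aperm(prod, c(1L, 2L, 4L, 3L)), H * Wd * N, C))
      }
      if (!is.null(gxp)) {
        wrep <- array(rep(rep(W$v[dyo + 1L, dxo + 1L, ], each = H * Wd),
                          times = N), d)
        gxp[dyo + seq_len(H), dxo + seq_len(Wd), , ] <-
          gxp[dyo + seq_len(H), dxo + seq_len(Wd), , , drop = FALSE] +
          g * wrep
      }
    }
    gx <- NULL
    if (!is.null(gxp)) {
      gx <- if (prepadded) gxp
      else gxp[1L + seq_len(H), 1L + seq_len(Wd), , , drop = FALSE]
    }
    out <- list(gx, gW)
    if (!is.null(b))
      out <- c(out, list(if (b$req)
        colSums(matrix(aperm(g, c(1L, 2L, 4L, 3L)), H * Wd * N, C)) else NULL))
    out
  })
}

# ---- normalization ----------------------------------------------------------

#' @rdname engine_ops
#' @export
ad_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         eps = 1e-5, momentum = 0.1) {
  # per-channel statistics over (H, W, N); `state` holds running moments
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  xm <- matrix(aperm(x$v, c(1L, 2L, 4L, 3L)), m, C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$mu <- (1 - momentum) * state$mu + momentum * mu
    state$va <- (1 - momentum) * state$va + momentum * va
  } else {
    mu <- state$mu; va <- state$va
  }
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, sd_, "/")
  ym <- sweep(sweep(xhat, 2L, gamma$v, "*"), 2L, beta$v, "+")
  y <- aperm(array(ym, c(H, W, N, C)), c(1L, 2L, 4L, 3L))
  new_tensor(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), m, C)
    ggamma <- if (gamma$req) colSums(gm * xhat) else NULL
    gbeta <- if (beta$req) colSums(gm) else NULL
    gx <- NULL
    if (x$req) {
      dxhat <- sweep(gm, 2L, gamma$v, "*")
      if (training) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * xhat)
        gxm <- sweep(dxhat, 2L, sd_, "/") -
          sweep(xhat, 2L, s2 / (m * sd_), "*") -
          matrix(rep(s1 / (m * sd_), each = m), m, C)
        # note: combine means: dx = (dxhat - mean(dxhat) - xhat*mean(dxhat*xhat)) / sd
      } else {
        gxm <- sweep(dxhat, 2L, sd_, "/")
      }
      gx <- aperm(array(gxm, c(H, W, N, C)), c(1L, 2L, 4L, 3L))
    }
    list(gx, ggamma, gbeta)
  })
}

#' @rdname engine_ops
#' @export
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  # x: (Ntok, d, N); normalize over the feature dim per token
  dd <- dim(x$v); Ntok <- dd[1]; dk <- dd[2]; N <- dd[3]
  xm <- matrix(aperm(x$v, c(2L, 1L, 3L)), dk, Ntok * N)  # cols = tokens
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, sd_, "/")
  ym <- sweep(xhat, 1L, gamma$v, "*") + matrix(beta$v, dk, Ntok * N)
  y <- aperm(array(ym, c(dk, Ntok, N)), c(2L, 1L, 3L))
  new_tensor(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(2L, 1L, 3L)), dk, Ntok * N)
    ggamma <- if (gamma$req) rowSums(gm * xhat) else NULL
    gbeta <- if (beta$req) rowSums(gm) else NULL
    gx <- NULL
    if (x$req) {
      dxhat <- gm * gamma$v
      s1 <- colMeans(dxhat)
      s2 <- colMeans(dxhat * xhat)
      gxm <- sweep(dxhat -
                     matrix(rep(s1, each = dk), dk) -
                     sweep(xhat, 2L, s2, "*"),
                   2L, sd_, "/")
      gx <- aperm(array(gxm, c(dk, Ntok, N)), c(2L, 1L, 3L))
    }
    list(gx, ggamma, gbeta)
  })
}

# ---- resampling -------------------------------------------------------------

resize_matrix <- function(n_out, n_in) {
  # bilinear interpolation matrix (n_out x n_in), half-pixel centers
  R <- matrix(0, n_out, n_in)
  if (n_in == 1L) { R[, 1L] <- 1; return(R) }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  w1 <- src - i0
  i0 <- pmin(i0, n_in - 2)
  for (i in seq_len(n_out)) {
    R[i, i0[i] + 1L] <- R[i, i0[i] + 1L] + (1 - w1[i])
    R[i, i0[i] + 2L] <- R[i, i0[i] + 2L] + w1[i]
  }
  R
}

apply_rows <- function(v, R) {
  # v: (H, ...) -> (Ho, ...) multiplying along dim 1
  d <- dim(v)
  y <- R %*% matrix(v, d[1], prod(d[-1]))
  array(y, c(nrow(R), d[-1]))
}

#' @rdname engine_ops
#' @export
ad_resize_bilinear <- function(x, Ho, Wo) {
  d <- dim(x$v); H <- d[1]; W <- d[2]
  Ry <- resize_matrix(Ho, H)
  Rx <- resize_matrix(Wo, W)
  fwd <- function(v) {
    y <- apply_rows(v, Ry)                       # (Ho, W, C, N)
    y <- aperm(y, c(2L, 1L, 3L, 4L))             # (W, Ho, C, N)
    y <- apply_rows(y, Rx)                       # (Wo, Ho, C, N)
    aperm(y, c(2L, 1L, 3L, 4L))
  }
  bwd <- function(g) {
    y <- apply_rows(g, t(Ry))
    y <- aperm(y, c(2L, 1L, 3L, 4L))
    y <- apply_rows(y, t(Rx))
    aperm(y, c(2L, 1L, 3L, 4L))
  }
  new_tensor(fwd(x$v), list(x), function(g) list(bwd(g)))
}

# ---- attention / matrix ops -------------------------------------------------

#' @rdname engine_ops
#' @export
ad_bmm <- function(A, B, transB = FALSE) {
  # batched matmul over the 3rd dim: A (r, k, N), B (k, c, N) [or (c, k, N)]
  dA <- dim(A$v); dB <- dim(B$v); N <- dA[3]
  r <- dA[1]
  cc <- if (transB) dB[1] else dB[2]
  y <- array(0, c(r, cc, N))
  for (n in seq_len(N)) {
    Bn <- if (transB) t(B$v[, , n]) else B$v[, , n]
    y[, , n] <- A$v[, , n] %*% Bn
  }
  new_tensor(y, list(A, B), function(g) {
    gA <- if (A$req) array(0, dA) else NULL
    gB <- if (B$req) array(0, dB) else NULL
    for (n in seq_len(N)) {
      Bn <- if (transB) t(B$v[, , n]) else B$v[, , n]
      if (!is.null(gA)) gA[, , n] <- g[, , n] %*% t(Bn)
      if (!is.null(gB)) {
        gBn <- t(A$v[, , n]) %*% g[, , n]
        gB[, , n] <- if (transB) t(gBn) else gBn
      }
    }
    list(gA, gB)
  })
}

#' @rdname engine_ops
#' @export
ad_row_softmax <- function(A) {
  # softmax along dim 2 of (r, c[, N])
  d <- dim(A$v)
  batched <- length(d) == 3L
  v <- if (batched) A$v else array(A$v, c(d, 1L))
  dd <- dim(v)
  p <- array(0, dd)
  for (n in seq_len(dd[3])) {
    m <- v[, , n, drop = FALSE][, , 1L]
    m <- matrix(m, dd[1], dd[2])
    m <- m - apply(m, 1L, max)
    e <- exp(m)
    p[, , n] <- e / rowSums(e)
  }
  y <- if (batched) p else array(p, d)
  new_tensor(y, list(A), function(g) {
    gv <- if (batched) g else array(g, dd)
    gx <- array(0, dd)
    for (n in seq_len(dd[3])) {
      pn <- matrix(p[, , n], dd[1], dd[2])
      gn <- matrix(gv[, , n], dd[1], dd[2])
      gx[, , n] <- pn * (gn - rowSums(pn * gn))
    }
    list(if (batched) gx else array(gx, d))
  })
}

#' @rdname engine_ops
#' @export
ad_softmax_c <- function(x) {
  # softmax over dim 3 (classes) of (H, W, K, N)
  d <- dim(x$v); K <- d[3]
  vm <- matrix(aperm(x$v, c(3L, 1L, 2L, 4L)), K)
  vm <- sweep(vm, 2L, apply(vm, 2L, max), "-")
  e <- exp(vm)
  pm <- sweep(e, 2L, colSums(e), "/")
  p <- aperm(array(pm, c(K, d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
  new_tensor(p, list(x), function(g) {
    gm <- matrix(aperm(g, c(3L, 1L, 2L, 4L)), K)
    gx <- pm * sweep(gm, 2L, colSums(pm * gm), "-")
    list(aperm(array(gx, c(K, d[1], d[2], d[4])), c(2L, 3L, 1L, 4L)))
  })
}

#' @rdname engine_ops
#' @export
ad_l2normalize_cols <- function(x, eps = 1e-12) {
  # x: (d, B); each column scaled to unit L2 norm
  nrm <- sqrt(colSums(x$v^2)) + eps
  y <- sweep(x$v, 2L, nrm, "/")
  new_tensor(y, list(x), function(g) {
    s <- colSums(g * y)
    list(sweep(g - sweep(y, 2L, s, "*"), 2L, nrm, "/"))
  })
}

# ---- frequency-domain op ----------------------------------------------------

fftshift2 <- function(m) {
  d <- dim(m); h <- floor(d[1] / 2); w <- floor(d[2] / 2)
  ri <- if (h > 0) c((d[1] - h + 1):d[1], 1:(d[1] - h)) else seq_len(d[1])
  ci <- if (w > 0) c((d[2] - w + 1):d[2], 1:(d[2] - w)) else seq_len(d[2])
  m[ri, ci, drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m); h <- floor(d[1] / 2); w <- floor(d[2] / 2)
  ri <- if (h > 0) c((h + 1):d[1], 1:h) else seq_len(d[1])
  ci <- if (w > 0) c((w + 1):d[2], 1:w) else seq_len(d[2])
  m[ri, ci, drop = FALSE]
}

band_filter_channel <- function(ch, mask) {
  # real part of the inverse FFT of the masked, centered spectrum
  sp <- fftshift2(stats::fft(ch))
  Re(stats::fft(ifftshift2(sp * mask), inverse = TRUE)) / length(ch)
}

#' @rdname engine_ops
#' @export
ad_fft_band <- function(x, mult, masks) {
  # x: (H, W, C, N); mult: (3, N) band multipliers; masks: list of 3 (H, W)
  # binary matrices. The per-band filter is self-adjoint on real arrays, so
  # the input gradient is the same filter applied to the output gradient.
  d <- dim(x$v); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(all(is.finite(x$v)))
  comp <- lapply(1:3, function(b) {
    y <- array(0, d)
    for (n in seq_len(N)) for (c in seq_len(C))
      y[, , c, n] <- band_filter_channel(x$v[, , c, n], masks[[b]])
    y
  })
  y <- array(0, d)
  for (b in 1:3)
    y <- y + comp[[b]] *
      array(rep(mult$v[b, ], each = H * W * C), d)
  new_tensor(y, list(x, mult), function(g) {
    gx <- NULL
    if (x$req) {
      gx <- array(0, d)
      for (b in 1:3) {
        gb <- array(0, d)
        for (n in seq_len(N)) for (c in seq_len(C))
          gb[, , c, n] <- band_filter_channel(g[, , c, n], masks[[b]])
        gx <- gx + gb * array(rep(mult$v[b, ], each = H * W * C), d)
      }
    }
    gm <- NULL
    if (mult$req) {
      gm <- matrix(0, 3L, N)
      for (b in 1:3) {
        prod <- g * comp[[b]]
        gm[b, ] <- colSums(matrix(prod, H * W * C, N))
      }
    }
    list(gx, gm)
  })
}

# ---- fused losses -----------------------------------------------------------

#' @rdname engine_ops
#' @export
ad_kl_temp <- function(zs, zt, temp, direction = c("forward", "reverse")) {
  # temperature-softened KL over the class dim of (H, W, K, N), mean over
  # pixels and samples, scaled by temp^2. "forward" = KL(student || teacher).
  # Gradients flow to the student logits only; the teacher side is a target.
  direction <- match.arg(direction)
  if (!identical(dim(zs$v), dim(zt$v))) stop("logit shapes differ")
  if (temp <= 0) stop("temperature must be positive")
  d <- dim(zs$v); K <- d[3]; npix <- d[1] * d[2] * d[4]
  sm <- function(z) {
    m <- matrix(aperm(z, c(3L, 1L, 2L, 4L)), K)
    m <- sweep(m, 2L, apply(m, 2L, max), "-")
    e <- exp(m)
    sweep(e, 2L, colSums(e), "/")
  }
  p <- sm(zs$v / temp)  # student
  q <- sm(zt$v / temp)  # teacher
  lp <- log(pmax(p, 1e-12)); lq <- log(pmax(q, 1e-12))
  if (direction == "forward") {
    klpix <- colSums(p * (lp - lq))
  } else {
    klpix <- colSums(q * (lq - lp))
  }
  val <- mean(klpix) * temp^2
  new_tensor(val, list(zs, zt), function(g) {
    g <- as.numeric(g)
    if (direction == "forward") {
      diffc <- (lp - lq)
      ga <- p * sweep(diffc, 2L, klpix, "-")   # d/d(zs/T)
    } else {
      ga <- p - q
    }
    gm <- ga * (temp / npix) * g               # includes T^2 * (1/T)
    list(aperm(array(gm, c(K, d[1], d[2], d[4])), c(2L, 3L, 1L, 4L)), NULL)
  })
}

# ---- parameters & optimizer -------------------------------------------------

#' @rdname engine_ops
#' @export
collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "ad_tensor")) {
      if (o$param) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) walk(el)
    } else if (is.environment(o) && !is.null(o$params)) {
      walk(o$params)
    }
  }
  walk(x)
  out
}

#' @rdname engine_ops
#' @export
n_params <- function(x) sum(vapply(collect_params(x),
                                   function(p) length(p$v), numeric(1)))

#' @rdname engine_ops
#' @export
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' @rdname engine_ops
#' @export
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  zero_like <- function(p) {
    if (is.null(dim(p$v))) numeric(length(p$v)) else array(0, dim(p$v))
  }
  opt$m <- lapply(params, zero_like)
  opt$s <- lapply(params, zero_like)
  class(opt) <- "adam_opt"
  opt
}

#' @rdname engine_ops
#' @export
adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(dim(p$v))) g <- as.vector(g)
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$s[[i]] <- b2 * opt$s[[i]] + (1 - b2) * g^2
    mhat <- opt$m[[i]] / (1 - b1^opt$t)
    shat <- opt$s[[i]] / (1 - b2^opt$t)
    p$v <- p$v - opt$lr * mhat / (sqrt(shat) + opt$eps)
  }
  zero_grads(opt$params)
  invisible(opt)
}

# ---- seeded streams ---------------------------------------------------------

#' Create a named deterministic random stream
#'
#' Each draw re-seeds base R's generator from `seed + counter`, evaluates,
#' and restores the caller's RNG state, so independently named streams never
#' interfere with each other or with user code.
#' @param seed integer seed (< 2^31)
#' @return an environment of class `rng_stream`
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed %% 2147483629L)
  e$n <- 0L
  class(e) <- "rng_stream"
  e
}

scramble_seed <- function(x) {
  # multiplicative LCG hash so that nearby stream seeds give decorrelated
  # generator states (consecutive raw seeds have correlated first draws)
  x <- (as.numeric(x) * 48271) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

stream_eval <- function(s, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(scramble_seed((s$seed + s$n) %% 2147483629L))
  s$n <- s$n + 1L
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

#' @rdname engine_ops
#' @export
stream_runif <- function(s, n, min = 0, max = 1)
  stream_eval(s, function() stats::runif(n, min, max))
#' @rdname engine_ops
#' @export
stream_rnorm <- function(s, n, mean = 0, sd = 1)
  stream_eval(s, function() stats::rnorm(n, mean, sd))
#' @rdname engine_ops
#' @export
stream_sample <- function(s, x, size = length(x), replace = FALSE)
  stream_eval(s, function() sample(x, size, replace))
#' @rdname engine_ops
#' @export
stream_rint <- function(s, n, max)
  stream_eval(s, function() sample.int(max, n, replace = TRUE))

# ---- layer constructors -----------------------------------------------------

init_conv_w <- function(k, cin, cout, stream, gain = 2) {
  sd_ <- sqrt(gain / (k * k * cin))
  array(stream_rnorm(stream, k * k * cin * cout, sd = sd_), c(k, k, cin, cout))
}

#' @rdname engine_ops
#' @export
nn_conv <- function(cin, cout, k, stream, stride = 1L, pad = NULL, dil = 1L) {
  if (is.null(pad)) pad <- dil * (k - 1L) %/% 2L
  m <- list(W = ad_param(init_conv_w(k, cin, cout, stream)),
            b = ad_param(rep(0, cout)),
            stride = stride, pad = pad, dil = dil)
  m$fwd <- function(x) ad_conv2d(x, m$W, m$b, stride = m$stride,
                                 pad = m$pad, dil = m$dil)
  m
}

#' @rdname engine_ops
#' @export
nn_bn <- function(c) {
  st <- new.env(parent = emptyenv())
  st$mu <- rep(0, c); st$va <- rep(1, c)
  m <- list(gamma = ad_param(rep(1, c)), beta = ad_param(rep(0, c)),
            state = st)
  m$fwd <- function(x, training = TRUE)
    ad_batchnorm(x, m$gamma, m$beta, m$state, training = training)
  m
}

#' @rdname engine_ops
#' @export
nn_linear <- function(din, dout, stream) {
  sd_ <- sqrt(2 / din)
  m <- list(W = ad_param(matrix(stream_rnorm(stream, dout * din, sd = sd_),
                                dout, din)),
            b = ad_param(rep(0, dout)))
  m$fwd <- function(x) ad_linear(x, m$W, m$b)
  m
}

# ---- numerical gradient check ----------------------------------------------

#' Finite-difference gradient check
#'
#' Compares reverse-mode gradients against central differences for a scalar
#' loss function of one or more tensors.
#' @param loss_fn function taking no arguments, returning a scalar
#'   `ad_tensor` built from the tensors in `tensors`
#' @param tensors list of `ad_tensor`s whose gradients are checked
#' @param n_probe number of randomly probed entries per tensor
#' @param eps finite-difference step
#' @param stream `rng_stream` used to pick probe entries
#' @return maximum relative error over all probed entries
#' @export
grad_check <- function(loss_fn, tensors, n_probe = 5L, eps = 1e-5,
                       stream = rng_stream(1L)) {
  loss <- loss_fn()
  for (t in tensors) t$grad <- NULL
  ad_backward(loss)
  worst <- 0
  for (t in tensors) {
    g <- t$grad
    if (is.null(g)) stop("no gradient reached a checked tensor")
    idx <- unique(stream_rint(stream, n_probe, length(t$v)))
    for (i in idx) {
      orig <- t$v[i]
      t$v[i] <- orig + eps
      lp <- as.numeric(loss_fn()$v)
      t$v[i] <- orig - eps
      lm <- as.numeric(loss_fn()$v)
      t$v[i] <- orig
      fd <- (lp - lm) / (2 * eps)
      denom <- max(abs(fd), abs(g[i]), 1e-8)
      worst <- max(worst, abs(fd - g[i]) / denom)
    }
  }
  worst
}
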