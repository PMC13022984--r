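# Additional engine ops: padding, reshapes, per-sample affine maps, plain
# matrix products and index warps used by the texture branch, the attention
# distillation path and the consistency loss.

reflect_index <- function(n, p) {
  # indices of a length-n axis reflected p pixels on each side (no edge repeat
  # when n > 1; degenerate axes repeat the single element)
  if (n == 1L) return(rep(1L, n + 2L * p))
  idx <- seq_len(n)
  pre <- rev(idx[2:min(p + 1L, n)])
  while (length(pre) < p) pre <- c(rev(idx[2:min(p + 1L, n)]), pre)
  pre <- utils::tail(pre, p)
  post <- rev(idx[max(1L, n - p):(n - 1L)])
  while (length(post) < p) post <- c(post, rev(idx[max(1L, n - p):(n - 1L)]))
  post <- utils::head(post, p)
  c(pre, idx, post)
}

#' @rdname engine_ops
#' @export
ad_reflect_pad <- function(x, p) {
  # reflection padding as a pair of selection matrices; the backward pass is
  # their transpose (scatter-add onto the source pixels)
  d <- dim(x$v)
  ri <- reflect_index(d[1], p)
  ci <- reflect_index(d[2], p)
  Sr <- matrix(0, length(ri), d[1]); Sr[cbind(seq_along(ri), ri)] <- 1
  Sc <- matrix(0, length(ci), d[2]); Sc[cbind(seq_along(ci), ci)] <- 1
  y <- x$v[ri, ci, , , drop = FALSE]
  new_tensor(y, list(x), function(g) {
    z <- apply_rows(g, t(Sr))
    z <- aperm(z, c(2L, 1L, 3L, 4L))
    z <- apply_rows(z, t(Sc))
    list(aperm(z, c(2L, 1L, 3L, 4L)))
  })
}

#' @rdname engine_ops
#' @export
ad_reshape <- function(x, newdim) {
  d <- dim(x$v) %||% length(x$v)
  stopifnot(prod(d) == prod(newdim))
  v <- x$v
  dim(v) <- newdim
  new_tensor(v, list(x), function(g) {
    dim(g) <- d
    list(g)
  })
}

ad_rep_cols <- function(x, N) {
  # (k) or (k, 1) vector tensor -> (k, N) by column repetition
  k <- length(x$v)
  new_tensor(matrix(as.vector(x$v), k, N), list(x), function(g) {
    gr <- rowSums(matrix(g, k, N))
    if (!is.null(dim(x$v))) dim(gr) <- dim(x$v)
    list(gr)
  })
}

ad_col_softmax <- function(x) {
  # softmax over rows of each column of a (K, N) matrix
  v <- sweep(x$v, 2L, apply(x$v, 2L, max), "-")
  e <- exp(v)
  p <- sweep(e, 2L, colSums(e), "/")
  new_tensor(p, list(x), function(g) {
    list(p * sweep(g, 2L, colSums(p * g), "-"))
  })
}

ad_matmul <- function(A, B) {
  A <- as_tensor(A); B <- as_tensor(B)
  new_tensor(A$v %*% B$v, list(A, B), function(g) {
    list(if (A$req) g %*% t(B$v) else NULL,
         if (B$req) t(A$v) %*% g else NULL)
  })
}

ad_crossprod_self <- function(x) {
  # t(x) %*% x for a (d, B) matrix tensor
  new_tensor(crossprod(x$v), list(x), function(g) {
    list(x$v %*% (g + t(g)))
  })
}

ad_affine_per_sample <- function(x, a, b) {
  # x: (H, W, C, N); a, b: numeric length N (constants, no gradient path)
  d <- dim(x$v)
  arep <- array(rep(a, each = prod(d[1:3])), d)
  brep <- array(rep(b, each = prod(d[1:3])), d)
  new_tensor(x$v * arep + brep, list(x), function(g) list(g * arep))
}

#' @rdname engine_ops
#' @export
ad_slice_n <- function(x, idx) {
  # subset the sample dimension of (H, W, C, N)
  d <- dim(x$v)
  y <- x$v[, , , idx, drop = FALSE]
  new_tensor(y, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , idx] <- gx[, , , idx, drop = FALSE] + g
    list(gx)
  })
}

ad_slice_cols <- function(x, idx) {
  # subset columns of a (K, N) matrix tensor
  d <- dim(x$v)
  new_tensor(x$v[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[, idx] <- gx[, idx, drop = FALSE] + g
    list(gx)
  })
}

#' @rdname engine_ops
#' @export
ad_gather_hw <- function(x, map) {
  # spatial gather: y[i, j, c, n] = x[map$r[i, j], map$c[i, j], c, n];
  # `map` holds integer source indices (nearest-neighbor inverse warp)
  d <- dim(x$v)
  lin <- cbind(as.vector(map$r), as.vector(map$c))
  flat <- matrix(x$v, d[1] * d[2], d[3] * d[4])
  src <- (lin[, 2L] - 1L) * d[1] + lin[, 1L]
  y <- array(flat[src, ], d)
  new_tensor(y, list(x), function(g) {
    gm <- matrix(g, d[1] * d[2], d[3] * d[4])
    gx <- matrix(0, d[1] * d[2], d[3] * d[4])
    rs <- rowsum(gm, group = src)
    gx[as.integer(rownames(rs)), ] <- rs
    list(array(gx, d))
  })
}

#' @rdname engine_ops
#' @export
ad_div <- function(a, b) {
  # elementwise (typically scalar) division of tensors
  a <- as_tensor(a); b <- as_tensor(b)
  y <- a$v / b$v
  new_tensor(y, list(a, b), function(g) {
    list(if (a$req) g / b$v else NULL,
         if (b$req) -g * a$v / b$v^2 else NULL)
  })
}
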