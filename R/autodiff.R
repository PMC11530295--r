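# Reverse-mode automatic differentiation over dense matrices.
#
# A tape records every operation as a node holding its value, its parent
# nodes and a backward closure.  ad_backward() walks the tape in reverse,
# accumulating gradients.  All network layers in this package (GVP,
# message passing, attention pooling, the losses) are built from these
# primitives, so one engine serves both training and Grad-CAM.
#
# Values are always base-R numeric matrices.  Vector (equivariant)
# features use a stacked layout: a block of v 3-D vector channels over R
# rows is stored as a (3R) x v matrix with spatial axis fastest, i.e.
# row (r-1)*3 + axis.  Channel-wise linear maps are then plain matmuls
# and rotations act by left block multiplication, which keeps every
# equivariance argument elementary.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 1024L)
  t$n <- 0L
  t
}

.ad_push <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$grad <- NULL
  nd$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- n
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_is_node <- function(x) is.environment(x) && !is.null(x$val) && !is.null(x$id)

ad_val <- function(x) if (ad_is_node(x)) x$val else x

# Leaf node; `param = TRUE` marks it as receiving gradients.
ad_leaf <- function(tape, value, param = TRUE) {
  if (!is.matrix(value)) value <- as.matrix(value)
  if (anyNA(value)) stop("non-finite value entering the tape")
  nd <- .ad_push(tape, value)
  nd$param <- param
  nd
}

# Run the backward pass from a scalar (1x1) root.
ad_backward <- function(root, seed = matrix(1, 1, 1)) {
  tape <- root$tape
  root$grad <- seed
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

## ---- primitive operations ------------------------------------------------

# Binary ops accept an untracked constant (plain matrix) in either slot;
# constants receive no gradient.
.ad_parents <- function(...) Filter(ad_is_node, list(...))

ad_matmul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  tape <- if (ad_is_node(a)) a$tape else b$tape
  an <- ad_is_node(a); bn <- ad_is_node(b)
  .ad_push(tape, av %*% bv, .ad_parents(a, b), function(g) {
    out <- list()
    if (an) out <- c(out, list(g %*% t(bv)))
    if (bn) out <- c(out, list(crossprod(av, g)))
    out
  })
}

# a %*% t(b)
ad_matmul_bt <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(a$tape, tcrossprod(av, bv), list(a, b), function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

ad_add <- function(a, b) {
  .ad_push(a$tape, ad_val(a) + ad_val(b), list(a, b),
           function(g) list(g, g))
}

ad_sub <- function(a, b) {
  .ad_push(a$tape, ad_val(a) - ad_val(b), list(a, b),
           function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  tape <- if (ad_is_node(a)) a$tape else b$tape
  an <- ad_is_node(a); bn <- ad_is_node(b)
  .ad_push(tape, av * bv, .ad_parents(a, b), function(g) {
    out <- list()
    if (an) out <- c(out, list(g * bv))
    if (bn) out <- c(out, list(g * av))
    out
  })
}

ad_div <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  .ad_push(a$tape, av / bv, list(a, b),
           function(g) list(g / bv, -g * av / (bv * bv)))
}

# multiply / add by an untracked constant (scalar or matrix)
ad_scale <- function(a, k) {
  .ad_push(a$tape, ad_val(a) * k, list(a), function(g) list(g * k))
}

ad_add_const <- function(a, m) {
  .ad_push(a$tape, ad_val(a) + m, list(a), function(g) list(g))
}

# add a 1 x n bias row to every row of a
ad_add_brow <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  val <- sweep(av, 2L, as.numeric(bv), "+")
  .ad_push(a$tape, val, list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

# multiply every row of a (R x C) by the matching entry of column c (R x 1)
ad_mul_bcol <- function(a, cc) {
  av <- ad_val(a); cv <- as.numeric(ad_val(cc))
  cn <- ad_is_node(cc)
  .ad_push(a$tape, av * cv, .ad_parents(a, cc), function(g) {
    out <- list(g * cv)
    if (cn) out <- c(out, list(matrix(rowSums(g * av), ncol = 1L)))
    out
  })
}

ad_relu <- function(a) {
  av <- ad_val(a)
  mask <- av > 0
  .ad_push(a$tape, av * mask, list(a), function(g) list(g * mask))
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-ad_val(a)))
  .ad_push(a$tape, y, list(a), function(g) list(g * y * (1 - y)))
}

ad_log <- function(a) {
  av <- ad_val(a)
  .ad_push(a$tape, log(av), list(a), function(g) list(g / av))
}

ad_exp <- function(a) {
  y <- exp(ad_val(a))
  .ad_push(a$tape, y, list(a), function(g) list(g * y))
}

ad_sqrt <- function(a, eps = 0) {
  y <- sqrt(ad_val(a) + eps)
  .ad_push(a$tape, y, list(a), function(g) list(g / (2 * pmax(y, 1e-12))))
}

# select rows by index (repeats allowed); backward scatter-adds
ad_gather <- function(a, idx) {
  av <- ad_val(a)
  n <- nrow(av)
  idx <- as.integer(idx)
  .ad_push(a$tape, av[idx, , drop = FALSE], list(a), function(g) {
    agg <- rowsum(g, idx)
    out <- matrix(0, n, ncol(g))
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

ad_cbind <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  na <- ncol(av)
  .ad_push(a$tape, cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  vals <- lapply(nodes, ad_val)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  .ad_push(nodes[[1]]$tape, do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(k) {
      g[starts[k]:ends[k], , drop = FALSE]
    })
  })
}

# per-channel Euclidean norms of stacked vector features:
# (3R) x v -> R x v, n[r,c] = ||x[(3r-2):(3r), c]||
ad_norm3 <- function(a, eps = 1e-8) {
  av <- ad_val(a)
  R <- nrow(av) %/% 3L
  if (R == 0L) {
    return(.ad_push(a$tape, matrix(0, 0L, ncol(av)), list(a),
                    function(g) list(av * 0)))
  }
  sq <- av * av
  ix <- seq(1L, 3L * R, by = 3L)
  ss <- sq[ix, , drop = FALSE] + sq[ix + 1L, , drop = FALSE] +
    sq[ix + 2L, , drop = FALSE]
  nv <- sqrt(ss)
  rep3 <- rep(seq_len(R), each = 3L)
  .ad_push(a$tape, nv, list(a), function(g) {
    denom <- pmax(nv, eps)
    list((g / denom)[rep3, , drop = FALSE] * av)
  })
}

# repeat each row 3x (lift R x C to the stacked (3R) x C layout)
ad_rep3 <- function(a) {
  av <- ad_val(a)
  R <- nrow(av)
  idx <- rep(seq_len(R), each = 3L)
  .ad_push(a$tape, av[idx, , drop = FALSE], list(a), function(g) {
    ix <- seq(1L, 3L * R, by = 3L)
    list(g[ix, , drop = FALSE] + g[ix + 1L, , drop = FALSE] +
           g[ix + 2L, , drop = FALSE])
  })
}

# mean of rows of a grouped by seg (values in 1..n_out); empty groups -> 0
ad_segment_mean <- function(a, seg, n_out) {
  av <- ad_val(a)
  seg <- as.integer(seg)
  cnt <- tabulate(seg, nbins = n_out)
  agg <- rowsum(av, seg)
  out <- matrix(0, n_out, ncol(av))
  got <- as.integer(rownames(agg))
  out[got, ] <- agg / cnt[got]
  .ad_push(a$tape, out, list(a), function(g) {
    list(g[seg, , drop = FALSE] / cnt[seg])
  })
}

# row-wise layer normalization over columns (no affine; see sv_layernorm)
ad_ln_rows <- function(a, eps = 1e-5) {
  av <- ad_val(a)
  n <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  y <- xc / sd
  .ad_push(a$tape, y, list(a), function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list((g - gm - y * gy) / sd)
  })
}

ad_softmax_rows <- function(a) {
  av <- ad_val(a)
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  y <- e / rowSums(e)
  .ad_push(a$tape, y, list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

# multiply every row of a by a 1 x n row vector (learned gain)
ad_mul_brow <- function(a, b) {
  av <- ad_val(a); bv <- as.numeric(ad_val(b))
  val <- sweep(av, 2L, bv, "*")
  .ad_push(a$tape, val, list(a, b), function(g) {
    list(sweep(g, 2L, bv, "*"), matrix(colSums(g * av), 1L))
  })
}

ad_recip <- function(a) {
  av <- ad_val(a)
  y <- 1 / av
  .ad_push(a$tape, y, list(a), function(g) list(-g * y * y))
}

ad_sum <- function(a) {
  av <- ad_val(a)
  .ad_push(a$tape, matrix(sum(av), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L], nrow(av), ncol(av)))
  })
}

ad_mean <- function(a) {
  av <- ad_val(a)
  n <- length(av)
  .ad_push(a$tape, matrix(mean(av), 1L, 1L), list(a), function(g) {
    list(matrix(g[1L] / n, nrow(av), ncol(av)))
  })
}
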