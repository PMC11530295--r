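# Two-stage supernode graph-attention pooling and the sigmoid
# multi-label head.
#
# Stage 1: n trainable supernode queries Q attend over the residues;
# keys and values come from two independent one-pass graph-convolution
# encoders of the collapsed scalar feature map.  Multi-head attention
# matrices are concatenated and mapped row-wise by an MLP to the
# supernode matrix A (n x d).
# Stage 2: a trainable global query attends over the n supernodes,
# giving the protein representation z (1 x d), which the output MLP and
# a sigmoid turn into per-term probabilities.

.gap_params <- function(cfg) {
  d <- cfg$collapse_dim
  H <- cfg$n_heads
  stopifnot(d %% H == 0)
  dh <- d %/% H
  p <- list()
  p[["gcnK.W"]] <- .glorot(d, d); p[["gcnK.b"]] <- matrix(0, 1L, d)
  p[["gcnV.W"]] <- .glorot(d, d); p[["gcnV.b"]] <- matrix(0, 1L, d)
  p[["gap.Q"]] <- matrix(stats::rnorm(cfg$n_super * d, sd = 1 / sqrt(d)),
                         cfg$n_super, d)
  for (h in seq_len(H)) {
    p[[sprintf("gap.WQ%d", h)]] <- .glorot(d, dh)
    p[[sprintf("gap.WK%d", h)]] <- .glorot(d, dh)
    p[[sprintf("gap.WV%d", h)]] <- .glorot(d, dh)
  }
  p[["gap.mlp.W1"]] <- .glorot(d, d); p[["gap.mlp.b1"]] <- matrix(0, 1L, d)
  p[["gap.mlp.W2"]] <- .glorot(d, d); p[["gap.mlp.b2"]] <- matrix(0, 1L, d)
  p[["pool.QP"]] <- matrix(stats::rnorm(d, sd = 1 / sqrt(d)), 1L, d)
  p[["pool.KP"]] <- .glorot(d, d)
  p[["pool.VP"]] <- .glorot(d, d)
  p[["head.W1"]] <- .glorot(d, d); p[["head.b1"]] <- matrix(0, 1L, d)
  p[["head.W2"]] <- .glorot(d, cfg$n_terms)
  p[["head.b2"]] <- matrix(0, 1L, cfg$n_terms)
  p
}

# symmetric-normalized adjacency (self-loops included) from a directed
# edge index; dense L x L
.norm_adjacency <- function(edge_index, L) {
  A <- matrix(0, L, L)
  A[edge_index] <- 1
  A <- pmax(A, t(A))
  diag(A) <- 1
  dd <- 1 / sqrt(rowSums(A))
  A * outer(dd, dd)
}

# one graph-convolution pass: nonlinearity(Ahat X W + b)
.gcn_fwd <- function(pl, prefix, X, Ahat) {
  ad_relu(ad_add_brow(
    ad_matmul(ad_matmul(Ahat, X), pl[[paste0(prefix, ".W")]]),
    pl[[paste0(prefix, ".b")]]))
}

.mlp_fwd <- function(pl, prefix, X) {
  h <- ad_relu(ad_add_brow(ad_matmul(X, pl[[paste0(prefix, ".W1")]]),
                           pl[[paste0(prefix, ".b1")]]))
  ad_add_brow(ad_matmul(h, pl[[paste0(prefix, ".W2")]]),
              pl[[paste0(prefix, ".b2")]])
}

# GAP + head on the tape; Fnode is the L x d collapsed feature map and
# Ahat the graph's normalized adjacency.  Returns z (1 x d), logits
# (1 x C) and yhat (1 x C).
.gap_forward <- function(pl, cfg, Fnode, Ahat, tape) {
  L <- nrow(ad_val(Fnode))
  if (L == 0) stop("empty graph")
  d <- cfg$collapse_dim
  H <- cfg$n_heads
  dh <- d %/% H
  K <- .gcn_fwd(pl, "gcnK", Fnode, Ahat)
  V <- .gcn_fwd(pl, "gcnV", Fnode, Ahat)
  Q <- pl[["gap.Q"]]
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    Qh <- ad_matmul(Q, pl[[sprintf("gap.WQ%d", h)]])
    Kh <- ad_matmul(K, pl[[sprintf("gap.WK%d", h)]])
    Vh <- ad_matmul(V, pl[[sprintf("gap.WV%d", h)]])
    att <- ad_softmax_rows(ad_scale(ad_matmul_bt(Qh, Kh), 1 / sqrt(dh)))
    heads[[h]] <- ad_matmul(att, Vh)
  }
  cat_heads <- Reduce(ad_cbind, heads)
  A <- .mlp_fwd(pl, "gap.mlp", cat_heads)
  KP <- ad_matmul(A, pl[["pool.KP"]])
  VP <- ad_matmul(A, pl[["pool.VP"]])
  watt <- ad_softmax_rows(ad_scale(ad_matmul_bt(pl[["pool.QP"]], KP),
                                   1 / sqrt(d)))
  z <- ad_matmul(watt, VP)
  logits <- .mlp_fwd(pl, "head", z)
  list(z = z, logits = logits, yhat = ad_sigmoid(logits))
}
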