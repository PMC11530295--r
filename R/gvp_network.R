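# The geometric core: geometric vector perceptron (GVP) transforms,
# scalar-vector layer normalization, GVP-based message passing, and the
# final scalar-collapsing GVP.
#
# A GVP maps paired features (s, V) -- an n-channel rotation-invariant
# scalar row and a stack of v rotation-equivariant 3-D vector channels
# -- to new widths (m, mu):
#
#   V' = sigma_plus(||W_mu W_h V||_2 per channel) (*) (W_mu W_h V)
#   s' = sigma(W_m concat(||W_h V||_2 per channel, s) + b)
#
# with sigma = ReLU, sigma_plus = sigmoid gate.  Vector-channel linear
# maps carry no bias (a bias would break rotational equivariance).
#
# Vector stacks use the (3R) x v layout described in autodiff.R.

.glorot <- function(fin, fout) {
  matrix(stats::runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
}

# parameter matrices for one GVP mapping (ns_in, nv_in) -> (ns_out, nv_out)
.gvp_params <- function(prefix, ns_in, nv_in, ns_out, nv_out) {
  h <- max(nv_in, nv_out, 1L)
  p <- list()
  p[[paste0(prefix, ".Wh")]] <- .glorot(nv_in, h)
  p[[paste0(prefix, ".Wm")]] <- .glorot(h + ns_in, ns_out)
  p[[paste0(prefix, ".b")]] <- matrix(0, 1L, ns_out)
  if (nv_out > 0) p[[paste0(prefix, ".Wmu")]] <- .glorot(h, nv_out)
  p
}

.ln_params <- function(prefix, ns) {
  p <- list()
  p[[paste0(prefix, ".gamma")]] <- matrix(1, 1L, ns)
  p[[paste0(prefix, ".beta")]] <- matrix(0, 1L, ns)
  p
}

# GVP forward on the tape.  S: R x ns node, V: (3R) x nv node.
.gvp_fwd <- function(pl, prefix, S, V, nv_out, act = TRUE) {
  Vh <- ad_matmul(V, pl[[paste0(prefix, ".Wh")]])
  nh <- ad_norm3(Vh)
  Sp <- ad_add_brow(ad_matmul(ad_cbind(nh, S), pl[[paste0(prefix, ".Wm")]]),
                    pl[[paste0(prefix, ".b")]])
  if (act) Sp <- ad_relu(Sp)
  Vp <- NULL
  if (nv_out > 0) {
    Vmu <- ad_matmul(Vh, pl[[paste0(prefix, ".Wmu")]])
    gate <- ad_sigmoid(ad_norm3(Vmu))
    Vp <- ad_mul(Vmu, ad_rep3(gate))
  }
  list(S = Sp, V = Vp)
}

# Scalar-vector layer norm: scalars standardized per row with a learned
# affine; vector channels jointly rescaled by the RMS of their norms
# (no recentering, preserving equivariance).
.sv_ln <- function(pl, prefix, S, V) {
  Sn <- ad_add_brow(
    ad_mul_brow(ad_ln_rows(S), pl[[paste0(prefix, ".gamma")]]),
    pl[[paste0(prefix, ".beta")]])
  Vn <- NULL
  if (!is.null(V)) {
    nv <- ncol(ad_val(V))
    n <- ad_norm3(V)
    ms <- ad_matmul(ad_mul(n, n), matrix(1 / nv, nv, 1L))
    scale <- ad_recip(ad_sqrt(ms, eps = 1e-6))
    Vn <- ad_mul_bcol(V, ad_rep3(scale))
  }
  list(S = Sn, V = Vn)
}

# One message-passing layer: per-edge GVP stack on the concatenated
# (source-node, edge) features, mean aggregation over incoming edges,
# residual add and scalar-vector layer norm.
.gnn_layer <- function(pl, cfg, l, S, V, edge) {
  src_node <- if (identical(cfg$message_source, "dest")) edge$dst else edge$src
  Sm <- ad_cbind(ad_gather(S, src_node), edge$Se)
  Vm <- ad_cbind(ad_gather(V, .vec_idx(src_node)), edge$Ve)
  for (d in seq_len(cfg$msg_depth)) {
    o <- .gvp_fwd(pl, sprintf("layer%d.msg%d", l, d), Sm, Vm, cfg$hidden_v)
    Sm <- o$S; Vm <- o$V
  }
  L <- nrow(ad_val(S))
  Sagg <- ad_segment_mean(Sm, edge$dst, L)
  Vagg <- ad_segment_mean(Vm, .vec_idx(edge$dst), 3L * L)
  if (identical(cfg$normalizer, "width")) {
    # literal reading: divide the message sum by the feature width
    cnt <- tabulate(edge$dst, nbins = L)
    w <- cfg$hidden_s
    Sagg <- ad_mul_bcol(Sagg, matrix(cnt / w, ncol = 1L))
    Vagg <- ad_mul_bcol(Vagg, matrix(rep(cnt, each = 3L) / w, ncol = 1L))
  }
  if (isTRUE(cfg$.train) && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    ms <- matrix(stats::rbinom(L * cfg$hidden_s, 1L, keep) / keep,
                 L, cfg$hidden_s)
    mv <- matrix(stats::rbinom(L * cfg$hidden_v, 1L, keep) / keep,
                 L, cfg$hidden_v)
    Sagg <- ad_mul(Sagg, ms)
    Vagg <- ad_mul(Vagg, mv[rep(seq_len(L), each = 3L), , drop = FALSE])
  }
  .sv_ln(pl, sprintf("layer%d.ln", l), ad_add(S, Sagg), ad_add(V, Vagg))
}

# stacked-row indices of residues `r`: rows (r-1)*3 + 1:3
.vec_idx <- function(r) {
  as.integer(t(outer(3L * (as.integer(r) - 1L), 1:3, "+")))
}

# L x nv x 3 array -> (3L) x nv stacked matrix (axis fastest)
.stack_vec <- function(arr) {
  L <- dim(arr)[1]; nv <- dim(arr)[2]
  m <- aperm(arr, c(3L, 1L, 2L))
  dim(m) <- c(3L * L, nv)
  m
}

# per-graph constants (stacked vector features, normalized adjacency),
# memoized in the graph's cache environment
.graph_const <- function(g) {
  ce <- g$cache
  if (is.null(ce)) ce <- new.env(parent = emptyenv())
  if (is.null(ce$vn)) {
    ce$vn <- .stack_vec(g$node_vector)
    ce$ve <- .stack_vec(g$edge_vector)
    ce$Ahat <- .norm_adjacency(g$edge_index, g$n_nodes)
  }
  ce
}

# assemble a block-diagonal composite of several residue graphs
.batch_const <- function(graphs) {
  Ls <- vapply(graphs, function(g) g$n_nodes, 1L)
  off <- c(0L, cumsum(Ls))
  cc <- lapply(graphs, .graph_const)
  list(
    L = sum(Ls), off = off,
    node_scalar = do.call(rbind, lapply(graphs, function(g) g$node_scalar)),
    node_vec = do.call(rbind, lapply(cc, function(x) x$vn)),
    edge_scalar = do.call(rbind, lapply(graphs, function(g) g$edge_scalar)),
    edge_vec = do.call(rbind, lapply(cc, function(x) x$ve)),
    src = unlist(lapply(seq_along(graphs), function(i)
      graphs[[i]]$edge_index[, 1L] + off[i])),
    dst = unlist(lapply(seq_along(graphs), function(i)
      graphs[[i]]$edge_index[, 2L] + off[i])),
    Ahat = lapply(cc, function(x) x$Ahat)
  )
}

# GNN trunk on an assembled (possibly block-diagonal multi-protein)
# graph: lift node and edge features with two separate GVPs, run the
# message-passing layers, collapse to the L x D scalar feature map.
# `perturb` (NULL or eps_max) adds the contrastive sign-preserving
# noise to the lifted node features.  Returns tape nodes.
.trunk_forward <- function(pl, cfg, bc, tape, train = FALSE,
                           perturb = NULL) {
  cfg$.train <- train
  S <- ad_leaf(tape, bc$node_scalar, param = FALSE)
  V <- ad_leaf(tape, bc$node_vec, param = FALSE)
  Se <- ad_leaf(tape, bc$edge_scalar, param = FALSE)
  Ve <- ad_leaf(tape, bc$edge_vec, param = FALSE)

  o <- .gvp_fwd(pl, "lift_n", S, V, cfg$hidden_v)
  S <- o$S; V <- o$V
  o <- .gvp_fwd(pl, "lift_e", Se, Ve, cfg$edge_v)
  Se <- o$S; Ve <- o$V

  if (!is.null(perturb) && perturb > 0) {
    S <- ad_add_const(S, .sign_noise(ad_val(S), perturb))
    V <- ad_add_const(V, .sign_noise(ad_val(V), perturb))
  }

  edge <- list(src = bc$src, dst = bc$dst, Se = Se, Ve = Ve)
  for (l in seq_len(cfg$n_layers)) {
    o <- .gnn_layer(pl, cfg, l, S, V, edge)
    S <- o$S; V <- o$V
  }
  Fmap <- .gvp_fwd(pl, "collapse", S, V, 0L, act = FALSE)$S
  list(F = Fmap, S = S, V = V)
}

# single-graph trunk (kept as the basic entry point)
.gnn_forward <- function(pl, cfg, graph, train = FALSE, perturb = NULL,
                         tape) {
  .trunk_forward(pl, cfg, .batch_const(list(graph)), tape, train, perturb)
}

# |eps| * sign(h) with eps ~ U(0, eps_max), drawn from the ambient RNG
.sign_noise <- function(val, eps_max) {
  abs(stats::runif(length(val), 0, eps_max)) * sign(val)
}

## ---- public numeric surface for the core transforms ----------------------

#' Initialize parameters for a single GVP
#'
#' @param ns_in,nv_in input scalar / vector channel counts.
#' @param ns_out,nv_out output widths (`nv_out = 0` collapses to
#'   scalars only).
#' @param seed initialization seed.
#' @return list of class `gvp_params` (weight matrices `Wh`, `Wm`,
#'   bias `b`, and `Wmu` unless `nv_out = 0`) with the widths attached.
#' @export
gvp_params <- function(ns_in, nv_in, ns_out, nv_out, seed = 1) {
  p <- with_seed(seed, .gvp_params("g", ns_in, nv_in, ns_out, nv_out))
  names(p) <- sub("^g\\.", "", names(p))
  structure(p, widths = c(ns_in = ns_in, nv_in = nv_in, ns_out = ns_out,
                          nv_out = nv_out), class = "gvp_params")
}

#' Apply a geometric vector perceptron
#'
#' Computes `V' = sigmoid(||W_mu W_h V||) (*) (W_mu W_h V)` per vector
#' channel and `s' = relu(W_m concat(||W_h V||, s) + b)` (norms taken
#' rowwise over the 3 spatial components).  Operates on a stack of R
#' feature rows at once.
#'
#' @param s R x ns_in scalar matrix (or a single row vector).
#' @param V R x nv_in x 3 array of vector channels (or nv_in x 3 for a
#'   single row).
#' @param p a [gvp_params()].
#' @param activate apply the scalar nonlinearity (identity if `FALSE`).
#' @return list with `s` (R x ns_out) and `V` (R x nv_out x 3 array, or
#'   `NULL` when `nv_out = 0`).
#' @export
gvp_forward <- function(s, V, p, activate = TRUE) {
  w <- attr(p, "widths")
  if (is.null(dim(s))) s <- matrix(s, 1L)
  if (length(dim(V)) == 2L) V <- array(V, c(1L, dim(V)))
  if (ncol(s) != w["ns_in"] || dim(V)[2] != w["nv_in"]) {
    stop("input widths do not match the GVP parameters")
  }
  tape <- ad_tape()
  pl <- list(`x.Wh` = ad_leaf(tape, p$Wh, FALSE),
             `x.Wm` = ad_leaf(tape, p$Wm, FALSE),
             `x.b` = ad_leaf(tape, p$b, FALSE))
  if (!is.null(p$Wmu)) pl$`x.Wmu` <- ad_leaf(tape, p$Wmu, FALSE)
  out <- .gvp_fwd(pl, "x", ad_leaf(tape, s, FALSE),
                  ad_leaf(tape, .stack_vec(V), FALSE),
                  w["nv_out"], act = activate)
  list(s = ad_val(out$S),
       V = if (w["nv_out"] > 0) .unstack_vec(ad_val(out$V)) else NULL)
}

#' Scalar-vector layer normalization
#'
#' Standardizes scalar channels per row (zero mean, unit variance) and
#' rescales each row's vector channels jointly by the root-mean-square
#' of their norms, with no recentering of vectors (which would break
#' equivariance).
#'
#' @param s R x ns scalar matrix.
#' @param V R x nv x 3 vector array (optional).
#' @return list with normalized `s` and `V`.
#' @export
sv_layernorm <- function(s, V = NULL) {
  if (is.null(dim(s))) s <- matrix(s, 1L)
  tape <- ad_tape()
  pl <- list(`x.gamma` = ad_leaf(tape, matrix(1, 1L, ncol(s)), FALSE),
             `x.beta` = ad_leaf(tape, matrix(0, 1L, ncol(s)), FALSE))
  Vn <- if (is.null(V)) NULL else {
    if (length(dim(V)) == 2L) V <- array(V, c(1L, dim(V)))
    ad_leaf(tape, .stack_vec(V), FALSE)
  }
  out <- .sv_ln(pl, "x", ad_leaf(tape, s, FALSE), Vn)
  list(s = ad_val(out$S),
       V = if (is.null(V)) NULL else .unstack_vec(ad_val(out$V)))
}

# (3R) x nv stacked matrix -> R x nv x 3 array
.unstack_vec <- function(m) {
  R <- nrow(m) %/% 3L
  arr <- array(m, c(3L, R, ncol(m)))
  aperm(arr, c(2L, 3L, 1L))
}
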