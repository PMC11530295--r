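# Model assembly: configuration, parameter initialization, forward
# passes and checkpointing.

#' Construct a geometric graph network model
#'
#' Assembles the full predictor: node/edge feature lifting by two
#' separate GVPs, `n_layers` rounds of GVP message passing with residual
#' scalar-vector layer norm, a scalar-collapsing GVP producing the
#' `L x collapse_dim` feature map, supernode attention pooling, and a
#' sigmoid multi-label head.  All widths are configurable; the defaults
#' are sized for CPU-scale experiments.
#'
#' @param node_scalar_dim input node scalar width (from the feature
#'   manifest).
#' @param n_terms number of GO terms predicted (output width).
#' @param edge_scalar_dim input edge scalar width.
#' @param node_vector_channels,edge_vector_channels input vector widths.
#' @param hidden_s,hidden_v hidden scalar / vector channel counts.
#' @param n_layers message-passing rounds.
#' @param msg_depth GVPs chained inside each message function.
#' @param edge_v lifted edge vector channels.
#' @param collapse_dim width D of the collapsed scalar feature map.
#' @param n_super supernode count of the attention pooling stage.
#' @param n_heads attention heads (`collapse_dim` divisible by it).
#' @param dropout dropout rate on aggregated messages (training only).
#' @param normalizer message normalizer: `"count"` (mean over incoming
#'   messages, default) or `"width"` (sum divided by the scalar feature
#'   width).
#' @param message_source which node enters the message GVP alongside
#'   the edge: `"source"` (default) or `"dest"`.
#' @param seed parameter initialization seed.
#' @return object of class `gvp_model` with elements `cfg` and `params`.
#' @export
gvp_model <- function(node_scalar_dim, n_terms,
                      edge_scalar_dim = 32, node_vector_channels = 3,
                      edge_vector_channels = 1, hidden_s = 32,
                      hidden_v = 8, n_layers = 2, msg_depth = 2,
                      edge_v = 4, collapse_dim = 32, n_super = 16,
                      n_heads = 4, dropout = 0.1,
                      normalizer = c("count", "width"),
                      message_source = c("source", "dest"), seed = 1) {
  stopifnot(n_layers >= 1, msg_depth >= 1, hidden_s > 0, hidden_v > 0,
            n_terms >= 1, collapse_dim %% n_heads == 0)
  cfg <- list(node_scalar_dim = node_scalar_dim,
              edge_scalar_dim = edge_scalar_dim,
              node_vector_channels = node_vector_channels,
              edge_vector_channels = edge_vector_channels,
              hidden_s = hidden_s, hidden_v = hidden_v,
              n_layers = n_layers, msg_depth = msg_depth, edge_v = edge_v,
              collapse_dim = collapse_dim, n_super = n_super,
              n_heads = n_heads, dropout = dropout,
              normalizer = match.arg(normalizer),
              message_source = match.arg(message_source),
              n_terms = n_terms, seed = seed)
  params <- with_seed(seed, .init_params(cfg))
  structure(list(cfg = cfg, params = params), class = "gvp_model")
}

.init_params <- function(cfg) {
  p <- list()
  p <- c(p, .gvp_params("lift_n", cfg$node_scalar_dim,
                        cfg$node_vector_channels, cfg$hidden_s,
                        cfg$hidden_v))
  p <- c(p, .gvp_params("lift_e", cfg$edge_scalar_dim,
                        cfg$edge_vector_channels, cfg$edge_scalar_dim,
                        cfg$edge_v))
  for (l in seq_len(cfg$n_layers)) {
    ns_in <- cfg$hidden_s + cfg$edge_scalar_dim
    nv_in <- cfg$hidden_v + cfg$edge_v
    for (d in seq_len(cfg$msg_depth)) {
      p <- c(p, .gvp_params(sprintf("layer%d.msg%d", l, d),
                            if (d == 1) ns_in else cfg$hidden_s,
                            if (d == 1) nv_in else cfg$hidden_v,
                            cfg$hidden_s, cfg$hidden_v))
    }
    p <- c(p, .ln_params(sprintf("layer%d.ln", l), cfg$hidden_s))
  }
  p <- c(p, .gvp_params("collapse", cfg$hidden_s, cfg$hidden_v,
                        cfg$collapse_dim, 0L))
  c(p, .gap_params(cfg))
}

#' @export
print.gvp_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<gvp_model> %d terms; hidden (%d scalar, %d vector), %d layer(s), %d parameters\n",
    x$cfg$n_terms, x$cfg$hidden_s, x$cfg$hidden_v, x$cfg$n_layers, n_par))
  invisible(x)
}

# wrap every parameter matrix as a tape leaf
.param_leaves <- function(tape, params) {
  lapply(params, function(m) ad_leaf(tape, m, param = TRUE))
}

# full forward for a batch of proteins: one block-diagonal trunk pass,
# then per-graph attention pooling.  Returns a list (one element per
# graph) of tape-node lists (F, z, logits, yhat).
.forward_batch <- function(pl, cfg, graphs, tape, train = FALSE,
                           perturb = NULL) {
  bc <- .batch_const(graphs)
  trunk <- .trunk_forward(pl, cfg, bc, tape, train = train,
                          perturb = perturb)
  out <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    Fg <- if (length(graphs) == 1L) trunk$F else
      ad_gather(trunk$F, (bc$off[i] + 1L):bc$off[i + 1L])
    out[[i]] <- c(list(F = Fg),
                  .gap_forward(pl, cfg, Fg, bc$Ahat[[i]], tape))
  }
  out
}

# full forward for one protein; returns tape nodes (F, z, logits, yhat)
.forward_protein <- function(pl, cfg, graph, tape, train = FALSE,
                             perturb = NULL) {
  .forward_batch(pl, cfg, list(graph), tape, train, perturb)[[1L]]
}

#' Predict GO-term probabilities for residue graphs
#'
#' Runs the model in evaluation mode (deterministic; no dropout, no
#' perturbation) on each graph.
#'
#' @param model a `gvp_model`.
#' @param graphs a `residue_graph` or list of them.
#' @return numeric matrix (proteins x terms) of probabilities in (0, 1),
#'   row names from the graphs' protein ids.
#' @export
model_predict <- function(model, graphs) {
  if (inherits(graphs, "residue_graph")) graphs <- list(graphs)
  out <- matrix(NA_real_, length(graphs), model$cfg$n_terms)
  chunks <- split(seq_along(graphs),
                  ceiling(seq_along(graphs) / 32))
  for (ch in chunks) {
    tape <- ad_tape()
    pl <- .param_leaves(tape, model$params)
    fw <- .forward_batch(pl, model$cfg, graphs[ch], tape)
    for (k in seq_along(ch)) out[ch[k], ] <- ad_val(fw[[k]]$yhat)
  }
  rownames(out) <- vapply(graphs, function(g) g$protein_id, "")
  out
}

#' Pooled protein representations
#'
#' Evaluation-mode forward returning the pooled representation z
#' (one row per protein), the quantity entering the contrastive loss.
#'
#' @inheritParams model_predict
#' @return numeric matrix (proteins x collapse_dim).
#' @export
model_embed <- function(model, graphs) {
  if (inherits(graphs, "residue_graph")) graphs <- list(graphs)
  out <- matrix(NA_real_, length(graphs), model$cfg$collapse_dim)
  chunks <- split(seq_along(graphs), ceiling(seq_along(graphs) / 32))
  for (ch in chunks) {
    tape <- ad_tape()
    pl <- .param_leaves(tape, model$params)
    fw <- .forward_batch(pl, model$cfg, graphs[ch], tape)
    for (k in seq_along(ch)) out[ch[k], ] <- ad_val(fw[[k]]$z)
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS container holding the configuration
#' (also as a JSON header string for external tooling), all parameter
#' matrices, and the package version.
#'
#' @param model a `gvp_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(
    config_json = jsonlite::toJSON(model$cfg, auto_unbox = TRUE,
                                   digits = NA),
    cfg = model$cfg, params = model$params, terms = model$terms,
    version = as.character(utils::packageVersion("structfun"))), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  structure(list(cfg = x$cfg, params = x$params, terms = x$terms),
            class = "gvp_model")
}
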