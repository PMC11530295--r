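# Grad-CAM residue attribution: which residues drive the prediction of
# one GO term for one protein.

#' Grad-CAM residue contribution scores
#'
#' Takes the collapsed scalar feature map `F` (L x D), backpropagates
#' the pre-sigmoid logit of the requested term to obtain per-element
#' weights `W = dy/dF`, and scores residue i as
#' `ReLU(sum_j W[i,j] F[i,j] / D)`.  The logit (rather than the
#' saturating sigmoid output) is differentiated so gradients do not
#' vanish for confident predictions.
#'
#' @param model a `gvp_model`.
#' @param graph a `residue_graph`.
#' @param term term index in `1..n_terms` or a column name used at
#'   training time.
#' @return object of class `cam_scores`: `scores` (nonnegative, one per
#'   residue), `protein_id`, `term`.
#' @export
grad_cam <- function(model, graph, term) {
  C <- model$cfg$n_terms
  if (is.character(term)) term_idx <- match(term, model$terms)
  else term_idx <- as.integer(term)
  if (is.na(term_idx) || term_idx < 1 || term_idx > C) {
    stop("invalid term index: ", term)
  }
  tape <- ad_tape()
  pl <- .param_leaves(tape, model$params)
  fw <- .forward_protein(pl, model$cfg, graph, tape)
  sel <- matrix(0, C, 1L); sel[term_idx, 1L] <- 1
  scores <- .cam_scores(fw$F, ad_matmul(fw$logits, sel))
  structure(list(scores = scores, protein_id = graph$protein_id,
                 term = term), class = "cam_scores")
}

# CAM_i = ReLU(sum_j (droot/dF)[i,j] * F[i,j] / D), root a 1x1 tape node
.cam_scores <- function(Fnode, root) {
  ad_backward(root)
  Fv <- ad_val(Fnode)
  W <- Fnode$grad
  if (is.null(W)) W <- Fv * 0
  pmax(rowSums(W * Fv) / ncol(Fv), 0)
}

#' @export
print.cam_scores <- function(x, ...) {
  cat(sprintf("<cam_scores> %s / term %s: %d residues, max %.4g\n",
              x$protein_id, as.character(x$term), length(x$scores),
              max(x$scores)))
  invisible(x)
}

#' Map residue contribution scores onto a structure
#'
#' Writes a PDB with min-max-normalized scores in the B-factor column
#' (a constant score vector normalizes to all zeros) and a per-residue
#' TSV (`seq_pos`, `aa`, `score`) next to it.
#'
#' @param s the `backbone` the scores belong to.
#' @param cam a `cam_scores` (or bare numeric vector).
#' @param path output PDB path; the TSV gets extension `.tsv`.
#' @return `path`, invisibly.
#' @export
cam_to_structure <- function(s, cam, path) {
  scores <- if (inherits(cam, "cam_scores")) cam$scores else as.numeric(cam)
  if (length(scores) != length(s)) {
    stop("score length does not match protein length")
  }
  rng <- range(scores)
  bf <- if (diff(rng) < 1e-12) rep(0, length(scores)) else
    (scores - rng[1]) / diff(rng)
  write_backbone_pdb(s, path, bfactor = bf)
  utils::write.table(
    data.frame(seq_pos = s$seq_pos, aa = s$aa, score = scores),
    paste0(sub("\\.pdb$", "", path), ".tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ROC curve and AUC for residue-level attribution
#'
#' Standard ROC over score thresholds with trapezoid-rule area,
#' comparing contribution scores against a binary per-residue truth
#' (e.g. known binding-site residues).
#'
#' @param cam a `cam_scores` or numeric score vector.
#' @param truth binary vector of the same length containing both
#'   classes.
#' @return list with `curve` (data.frame fpr, tpr) and `auc`.
#' @export
residue_roc <- function(cam, truth) {
  scores <- if (inherits(cam, "cam_scores")) cam$scores else as.numeric(cam)
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes; AUC undefined")
  }
  r <- pROC::roc(response = truth, predictor = scores, quiet = TRUE,
                 direction = "<")
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  list(curve = curve, auc = as.numeric(r$auc))
}
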