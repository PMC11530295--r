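# GO-DAG label closure, information content, and protein-centric CAFA
# metrics (Fmax, AUPR, Smin).

.THRESH_GRID <- seq(0.01, 1, by = 0.01)

#' Propagate annotations up the GO DAG (true-path rule)
#'
#' Every protein annotated with a term becomes annotated with all of
#' that term's ancestors.  Idempotent; errors on a cyclic graph.
#'
#' @param dag 2-column matrix or data.frame of child -> parent edges.
#' @param labels binary protein x term matrix; column names are term
#'   ids.  Terms absent from the DAG are kept as-is.
#' @return the closed binary label matrix (columns possibly extended by
#'   ancestor terms that gained annotations).
#' @export
propagate_labels <- function(dag, labels) {
  labels <- as.matrix(labels)
  dag <- as.matrix(dag)
  g <- igraph::graph_from_edgelist(dag, directed = TRUE)
  if (!igraph::is_dag(g)) stop("cycle detected in the term DAG")
  terms <- colnames(labels)
  all_terms <- union(terms, igraph::V(g)$name)
  out <- matrix(0L, nrow(labels), length(all_terms),
                dimnames = list(rownames(labels), all_terms))
  out[, terms] <- labels
  for (t in terms) {
    if (!t %in% igraph::V(g)$name) next
    anc <- names(igraph::subcomponent(g, t, mode = "out"))
    have <- labels[, t] == 1L
    if (any(have)) out[have, anc] <- 1L
  }
  out
}

#' Per-term information content from training annotations
#'
#' `ic(t) = -log2(n_t / N)`: the negative log frequency of term t among
#' the N training proteins (after ancestor closure).  Higher IC means a
#' rarer, more specific term.  Terms annotated to no protein get an
#' `Inf` sentinel and are excluded from Smin.
#'
#' @param train_labels closed binary protein x term matrix.
#' @return named nonnegative numeric vector of IC values (bits).
#' @export
information_content <- function(train_labels) {
  train_labels <- as.matrix(train_labels)
  N <- nrow(train_labels)
  if (N == 0) stop("no training proteins")
  n_t <- colSums(train_labels > 0)
  ic <- -log2(n_t / N)
  ic[n_t == 0] <- Inf
  ic
}

#' Protein-centric maximum F-measure (CAFA Fmax)
#'
#' Sweeps thresholds 0.01, 0.02, ..., 1.00.  At each threshold,
#' precision is averaged over proteins making at least one prediction
#' and recall over proteins with at least one true term; Fmax is the
#' best harmonic mean (ties resolved to the smallest threshold).
#'
#' @param y_true binary protein x term matrix.
#' @param y_score matching score matrix in `[0, 1]`.
#' @return list with `fmax` and `threshold`.
#' @export
fmax <- function(y_true, y_score) {
  y_true <- as.matrix(y_true); y_score <- as.matrix(y_score)
  stopifnot(all(dim(y_true) == dim(y_score)))
  has_true <- rowSums(y_true) > 0
  if (!any(has_true)) stop("no protein has a true term")
  best <- 0; best_t <- NA_real_
  for (t in .THRESH_GRID) {
    pred <- y_score >= t
    npred <- rowSums(pred)
    tp <- rowSums(pred & y_true == 1)
    covered <- npred > 0
    if (!any(covered)) next
    pr <- mean(tp[covered] / npred[covered])
    rc <- mean(tp[has_true] / rowSums(y_true)[has_true])
    if (pr + rc == 0) next
    f <- 2 * pr * rc / (pr + rc)
    if (f > best + 1e-15) { best <- f; best_t <- t }
  }
  list(fmax = best, threshold = best_t)
}

#' Micro-averaged area under the precision-recall curve
#'
#' All protein-term pairs are pooled; the area uses step-wise
#' interpolation (precision accumulated at each positive in the score
#' ranking, ties broken by position).
#'
#' @inheritParams fmax
#' @return scalar AUPR.
#' @export
aupr <- function(y_true, y_score) {
  y <- as.numeric(as.matrix(y_true))
  s <- as.numeric(as.matrix(y_score))
  npos <- sum(y == 1)
  if (npos == 0) stop("no positive protein-term pair")
  ord <- order(-s, seq_along(s))
  y <- y[ord]
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / npos
}

#' Minimum semantic distance (CAFA Smin)
#'
#' Over thresholds 0.01, ..., 1.00: remaining uncertainty ru(t) is the
#' mean over proteins of the summed IC of false negatives, and
#' misinformation mi(t) the mean summed IC of false positives;
#' `Smin = min_t sqrt(ru^2 + mi^2)`.
#'
#' @inheritParams fmax
#' @param ic named per-term IC vector (finite for every scored term).
#' @return scalar Smin.
#' @export
smin <- function(y_true, y_score, ic) {
  y_true <- as.matrix(y_true); y_score <- as.matrix(y_score)
  stopifnot(all(dim(y_true) == dim(y_score)))
  if (is.null(colnames(y_true))) {
    stopifnot(length(ic) == ncol(y_true))
  } else {
    if (!all(colnames(y_true) %in% names(ic))) stop("missing ic for terms")
    ic <- ic[colnames(y_true)]
  }
  if (any(!is.finite(ic))) stop("non-finite ic for a scored term")
  icm <- matrix(ic, nrow(y_true), ncol(y_true), byrow = TRUE)
  best <- Inf
  for (t in .THRESH_GRID) {
    pred <- y_score >= t
    ru <- mean(rowSums(icm * (y_true == 1 & !pred)))
    mi <- mean(rowSums(icm * (y_true == 0 & pred)))
    best <- min(best, sqrt(ru^2 + mi^2))
  }
  best
}

#' Evaluate predictions with all three CAFA metrics
#'
#' @inheritParams fmax
#' @param ic optional per-term IC; computed from `y_true` when missing.
#' @return list with `fmax`, `threshold`, `aupr`, `smin`.
#' @export
evaluate_predictions <- function(y_true, y_score, ic = NULL) {
  if (is.null(ic)) ic <- information_content(y_true)
  fm <- fmax(y_true, y_score)
  keep <- is.finite(ic)
  list(fmax = fm$fmax, threshold = fm$threshold,
       aupr = aupr(y_true, y_score),
       smin = smin(y_true[, keep, drop = FALSE],
                   y_score[, keep, drop = FALSE], ic[keep]))
}

#' Read a GO DAG
#'
#' Accepts OBO format (is_a and `relationship: part_of` edges) or a
#' two-column child/parent TSV.
#'
#' @param path file path (`.obo` or TSV).
#' @return list with `edges` (child, parent data.frame) and `terms`
#'   (id, name, namespace data.frame; empty for TSV input).
#' @export
read_go_dag <- function(path) {
  if (grepl("\\.obo$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    ids <- character(0); names_ <- character(0); ns <- character(0)
    child <- parent <- character(0)
    cur <- NULL; obsolete <- FALSE
    for (ln in c(lines, "[Term]")) {
      if (startsWith(ln, "[")) {
        if (!is.null(cur) && !obsolete && nzchar(cur$id)) {
          ids <- c(ids, cur$id); names_ <- c(names_, cur$name)
          ns <- c(ns, cur$ns)
          if (length(cur$parents)) {
            child <- c(child, rep(cur$id, length(cur$parents)))
            parent <- c(parent, cur$parents)
          }
        }
        cur <- list(id = "", name = NA_character_, ns = NA_character_,
                    parents = character(0))
        obsolete <- FALSE
        if (!identical(ln, "[Term]")) cur <- NULL
        next
      }
      if (is.null(cur)) next
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "namespace: ")) {
        cur$ns <- sub("^namespace: ", "", ln)
      } else if (startsWith(ln, "is_a: ")) {
        cur$parents <- c(cur$parents,
                         trimws(sub("!.*$", "", sub("^is_a: ", "", ln))))
      } else if (startsWith(ln, "relationship: part_of ")) {
        cur$parents <- c(cur$parents,
                         trimws(sub("!.*$", "",
                                    sub("^relationship: part_of ", "", ln))))
      } else if (identical(ln, "is_obsolete: true")) obsolete <- TRUE
    }
    list(edges = data.frame(child = child, parent = parent),
         terms = data.frame(id = ids, name = names_, namespace = ns))
  } else {
    e <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("child", "parent"),
                           stringsAsFactors = FALSE)
    list(edges = e, terms = data.frame(id = character(0),
                                       name = character(0),
                                       namespace = character(0)))
  }
}

#' Read protein-term annotations from a 2-column TSV
#'
#' @param path TSV with columns protein, term (no header).
#' @param proteins,terms optional universes fixing row/column order.
#' @return binary protein x term matrix.
#' @export
read_annotations <- function(path, proteins = NULL, terms = NULL) {
  a <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("protein", "term"),
                         stringsAsFactors = FALSE)
  if (is.null(proteins)) proteins <- unique(a$protein)
  if (is.null(terms)) terms <- unique(a$term)
  m <- matrix(0L, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  keep <- a$protein %in% proteins & a$term %in% terms
  m[cbind(a$protein[keep], a$term[keep])] <- 1L
  m
}
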