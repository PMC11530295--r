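# Synthetic fixtures: ideal-geometry backbones built from internal
# coordinates, and a motif-determined multi-label task, so the whole
# pipeline can be trained and evaluated offline.

# Ideal backbone internal coordinates (Angstrom / degrees).
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
.ANGLE <- c(C_N_CA = 121.7, N_CA_C = 111.0, CA_C_N = 116.6, CA_C_O = 120.8)

# Ideal (phi, psi) per secondary-structure type, degrees.
.TORSION <- list(helix = c(phi = -57, psi = -47),
                 strand = c(phi = -135, psi = 135))

# place atom D given previous atoms A, B, C and internal coordinates
# (bond length C-D, bond angle B-C-D, torsion A-B-C-D); angles radians
.nerf <- function(A, B, C, r, theta, chi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc * bc))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n * n))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m2 + d[3] * n
}

#' Generate an ideal-geometry synthetic backbone
#'
#' Builds a protein backbone (N, CA, C, O) from ideal bond lengths and
#' angles with per-residue (phi, psi) torsions set by the requested
#' secondary-structure segments: helix (-57, -47), strand (-135, 135),
#' coil sampled per residue from a polyproline-like region.  Segment
#' junctions receive a randomized hinge (uniform torsions), and optional
#' Gaussian coordinate jitter is added last.  Deterministic under
#' `seed`.
#'
#' @param segments list of `c(type, length)` pairs or a 2-column
#'   data.frame; types are `"helix"`, `"strand"`, `"coil"`.
#' @param seed integer seed.
#' @param jitter standard deviation (Angstrom) of coordinate noise.
#' @return a [new_backbone()] with a seeded random sequence and the
#'   segment table in `attr(, "composition")`.
#' @export
synthetic_backbone <- function(segments, seed = 1, jitter = 0.2) {
  stopifnot(jitter >= 0)
  comp <- .as_composition(segments)
  L <- sum(comp$length)
  if (L < 4) stop("total length must be at least 4")
  with_seed(seed, {
    phi <- psi <- numeric(L)
    pos <- 0L
    for (si in seq_len(nrow(comp))) {
      len <- comp$length[si]
      idx <- pos + seq_len(len)
      tors <- switch(comp$type[si],
        helix = matrix(rep(.TORSION$helix, len), len, 2, byrow = TRUE),
        strand = matrix(rep(.TORSION$strand, len), len, 2, byrow = TRUE),
        coil = cbind(stats::runif(len, -80, -40),
                     stats::runif(len, 100, 160)),
        stop("invalid segment type: ", comp$type[si]))
      phi[idx] <- tors[, 1]; psi[idx] <- tors[, 2]
      if (si > 1L) {
        # randomized hinge at the junction residue
        phi[idx[1L]] <- stats::runif(1, -180, 180)
        psi[idx[1L]] <- stats::runif(1, -180, 180)
      }
      pos <- pos + len
    }
    d2r <- pi / 180
    Nm <- CAm <- Cm <- Om <- matrix(NA_real_, L, 3L)
    Nm[1, ] <- c(0, 0, 0)
    CAm[1, ] <- c(.BOND["N_CA"], 0, 0)
    th <- .ANGLE["N_CA_C"] * d2r
    Cm[1, ] <- CAm[1, ] + .BOND["CA_C"] * c(cos(pi - th), sin(pi - th), 0)
    for (i in seq_len(L)) {
      if (i > 1L) {
        Nm[i, ] <- .nerf(Nm[i - 1, ], CAm[i - 1, ], Cm[i - 1, ],
                         .BOND["C_N"], .ANGLE["CA_C_N"] * d2r,
                         psi[i - 1] * d2r)
        CAm[i, ] <- .nerf(CAm[i - 1, ], Cm[i - 1, ], Nm[i, ],
                          .BOND["N_CA"], .ANGLE["C_N_CA"] * d2r, pi) # omega
        Cm[i, ] <- .nerf(Cm[i - 1, ], Nm[i, ], CAm[i, ],
                         .BOND["CA_C"], .ANGLE["N_CA_C"] * d2r,
                         phi[i] * d2r)
      }
      Om[i, ] <- .nerf(Nm[i, ], CAm[i, ], Cm[i, ], .BOND["C_O"],
                       .ANGLE["CA_C_O"] * d2r, (psi[i] + 180) * d2r)
    }
    if (jitter > 0) {
      Nm <- Nm + stats::rnorm(3 * L, sd = jitter)
      CAm <- CAm + stats::rnorm(3 * L, sd = jitter)
      Cm <- Cm + stats::rnorm(3 * L, sd = jitter)
      Om <- Om + stats::rnorm(3 * L, sd = jitter)
    }
    aa <- sample(.AA_ALPHABET[1:20], L, replace = TRUE)
    s <- new_backbone("A", aa, Nm, CAm, Cm, Om)
    attr(s, "composition") <- comp
    s
  })
}

.as_composition <- function(segments) {
  if (is.data.frame(segments)) {
    comp <- segments
    names(comp) <- c("type", "length")
  } else {
    comp <- data.frame(
      type = vapply(segments, function(x) as.character(x[[1]]), ""),
      length = vapply(segments, function(x) as.integer(x[[2]]), 1L))
  }
  if (!all(comp$type %in% c("helix", "strand", "coil"))) {
    stop("invalid segment type: ",
         paste(setdiff(comp$type, c("helix", "strand", "coil")),
               collapse = ", "))
  }
  comp
}

#' Built-in motif label rules
#'
#' Each rule is a predicate on the generative segment composition of a
#' synthetic backbone; labels are defined on the composition itself, not
#' re-detected from coordinates, so the label oracle is noise-free.
#'
#' @param name one of `"helix_ge_12"` (contains a helix segment of
#'   length >= 12), `"strand_ge_2"` (has >= 2 strand segments),
#'   `"compact"` (CA radius of gyration below `rg_max`).
#' @param rg_max threshold for the `"compact"` rule (Angstrom).
#' @return a function `f(backbone) -> logical` with a `description`
#'   attribute.
#' @export
motif_rule <- function(name = c("helix_ge_12", "strand_ge_2", "compact"),
                       rg_max = 12) {
  name <- match.arg(name)
  f <- switch(name,
    helix_ge_12 = function(s) {
      comp <- attr(s, "composition")
      any(comp$type == "helix" & comp$length >= 12)
    },
    strand_ge_2 = function(s) {
      comp <- attr(s, "composition")
      sum(comp$type == "strand") >= 2
    },
    compact = function(s) {
      mu <- colMeans(s$CA)
      sqrt(mean(rowSums(sweep(s$CA, 2, mu)^2))) < rg_max
    })
  attr(f, "description") <- switch(name,
    helix_ge_12 = "contains a helix segment of length >= 12",
    strand_ge_2 = "has >= 2 strand segments",
    compact = sprintf("CA radius of gyration < %g A", rg_max))
  f
}

.sample_composition <- function() {
  n_seg <- sample(2:4, 1L)
  types <- sample(c("helix", "strand", "coil"), n_seg, replace = TRUE,
                  prob = c(0.4, 0.35, 0.25))
  len <- vapply(types, function(ty) switch(ty,
    helix = sample(6:18, 1L), strand = sample(4:10, 1L),
    coil = sample(3:8, 1L)), 1L)
  data.frame(type = types, length = len)
}

#' Generate a synthetic motif-labelled multi-label task
#'
#' Samples segment compositions, builds ideal-geometry backbones and
#' assigns each term by evaluating its predicate on the true generative
#' composition.  Per-term prevalence is balanced within the given bounds
#' by targeted rejection sampling; the whole task regenerates
#' identically from its seed.
#'
#' @param n_proteins number of proteins.
#' @param n_terms number of terms; defaults rules are `helix_ge_12`,
#'   `strand_ge_2`, then `compact`.
#' @param motif_rules optional named list of predicate functions (see
#'   [motif_rule()]); names become term identifiers.
#' @param seed integer seed.
#' @param jitter coordinate noise passed to [synthetic_backbone()].
#' @param prevalence length-2 prevalence bounds per term.
#' @param max_attempts task-level rejection attempts before erroring.
#' @return an object of class `synthetic_task`: `structures` (list of
#'   backbones), `labels` (binary matrix), `rules` (text), `seed`.
#' @export
make_task <- function(n_proteins = 200, n_terms = 2, motif_rules = NULL,
                      seed = 1, jitter = 0.2,
                      prevalence = c(0.35, 0.65), max_attempts = 20) {
  stopifnot(n_terms >= 1)
  if (is.null(motif_rules)) {
    defaults <- c("helix_ge_12", "strand_ge_2", "compact")
    stopifnot(n_terms <= length(defaults))
    motif_rules <- lapply(defaults[seq_len(n_terms)], motif_rule)
    names(motif_rules) <- paste0("M:", defaults[seq_len(n_terms)])
  }
  stopifnot(length(motif_rules) == n_terms)
  for (attempt in seq_len(max_attempts)) {
    task <- .build_task(n_proteins, motif_rules, seed + 7919L * (attempt - 1L),
                        jitter)
    prev <- colMeans(task$labels)
    if (all(prev >= prevalence[1] & prev <= prevalence[2])) return(task)
  }
  stop("could not satisfy prevalence bounds after ", max_attempts,
       " attempts")
}

.build_task <- function(n_proteins, motif_rules, seed, jitter) {
  n_terms <- length(motif_rules)
  structures <- vector("list", n_proteins)
  labels <- matrix(0L, n_proteins, n_terms,
                   dimnames = list(NULL, names(motif_rules)))
  comps <- with_seed(seed, {
    out <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      target_term <- (i - 1L) %% n_terms + 1L
      target_lab <- ((i - 1L) %/% n_terms) %% 2L == 0L
      for (try in 1:500) {
        comp <- .sample_composition()
        fake <- structure(list(), composition = comp, class = "backbone")
        if (isTRUE(motif_rules[[target_term]](fake)) == target_lab) break
      }
      out[[i]] <- comp
    }
    out
  })
  for (i in seq_len(n_proteins)) {
    s <- synthetic_backbone(comps[[i]], seed = seed + i, jitter = jitter)
    structures[[i]] <- s
    labels[i, ] <- vapply(motif_rules, function(f) as.integer(isTRUE(f(s))),
                          1L)
  }
  names(structures) <- sprintf("syn%04d", seq_len(n_proteins))
  rownames(labels) <- names(structures)
  structure(list(structures = structures, labels = labels,
                 rules = vapply(motif_rules, function(f)
                   attr(f, "description"), ""),
                 seed = seed, jitter = jitter),
            class = "synthetic_task")
}

#' @export
print.synthetic_task <- function(x, ...) {
  cat(sprintf("<synthetic_task> %d proteins x %d terms (seed %d)\n",
              length(x$structures), ncol(x$labels), x$seed))
  for (j in seq_len(ncol(x$labels))) {
    cat(sprintf("  %s [%s]: prevalence %.2f\n", colnames(x$labels)[j],
                x$rules[j], mean(x$labels[, j])))
  }
  invisible(x)
}

#' Write a synthetic task to disk as standard formats
#'
#' Emits one PDB per structure, a 2-column annotation TSV
#' (protein, term) and a parent-edge TSV for the (flat) synthetic term
#' DAG, so the fixtures double as end-to-end pipeline test data.
#'
#' @param task a `synthetic_task`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_task <- function(task, dir) {
  dir.create(file.path(dir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(task$structures)) {
    write_backbone_pdb(task$structures[[nm]],
                       file.path(dir, "pdb", paste0(nm, ".pdb")))
  }
  ann <- which(task$labels == 1L, arr.ind = TRUE)
  utils::write.table(
    data.frame(protein = rownames(task$labels)[ann[, 1]],
               term = colnames(task$labels)[ann[, 2]]),
    file.path(dir, "annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(child = colnames(task$labels),
               parent = rep("M:root", ncol(task$labels))),
    file.path(dir, "dag.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
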