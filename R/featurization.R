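# Multi-scale geometric featurization: per-residue scalar and vector
# node features, RBF/positional edge features, and the directed
# k-nearest-neighbour residue graph.

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1 * n1)) < 1e-9 || sqrt(sum(n2 * n2)) < 1e-9) return(NA_real_)
  m1 <- cross(n1, b2 / sqrt(sum(b2 * b2)))
  atan2(-sum(m1 * n2), sum(n1 * n2))
}

#' Backbone dihedral angles
#'
#' Computes phi(i) from C(i-1), N(i), CA(i), C(i) and psi(i) from N(i),
#' CA(i), C(i), N(i+1).  phi of the first and psi of the last residue
#' are undefined and returned as `NA`; degenerate (collinear) atom
#' quadruples are also flagged `NA` with a warning.
#'
#' @param s a `backbone`.
#' @return list with numeric vectors `phi` and `psi` in radians.
#' @export
backbone_dihedrals <- function(s) {
  L <- length(s)
  stopifnot(L >= 2)
  phi <- psi <- rep(NA_real_, L)
  n_degenerate <- 0L
  for (i in seq_len(L)) {
    if (i > 1L) {
      phi[i] <- .dihedral(s$C[i - 1L, ], s$N[i, ], s$CA[i, ], s$C[i, ])
      if (is.na(phi[i])) n_degenerate <- n_degenerate + 1L
    }
    if (i < L) {
      psi[i] <- .dihedral(s$N[i, ], s$CA[i, ], s$C[i, ], s$N[i + 1L, ])
      if (is.na(psi[i])) n_degenerate <- n_degenerate + 1L
    }
  }
  if (n_degenerate > 0L) {
    warning(sprintf("%d degenerate dihedral(s) flagged undefined",
                    n_degenerate))
  }
  list(phi = phi, psi = psi)
}

# Ramachandran boxes for the 3-state fallback classifier (degrees).
.SS3_HELIX <- c(phi_lo = -120, phi_hi = -30, psi_lo = -90, psi_hi = 10)
.SS3_STRAND <- c(phi_lo = -180, phi_hi = -90, psi_lo = 90, psi_hi = 180)

#' Per-residue secondary structure
#'
#' If a DSSP executable is configured (`options(structfun.dssp = path)`)
#' its 8-state labels are used; otherwise a deterministic 3-state
#' fallback assigns helix (H), strand (E) or coil (C) from Ramachandran
#' boxes on (phi, psi).  Residues with undefined dihedrals are coil.
#'
#' @param s a `backbone`.
#' @param dssp optional path to a DSSP executable.
#' @return character vector of labels with attribute `states` giving the
#'   label alphabet used (3- or 8-state).
#' @export
secondary_structure <- function(s, dssp = getOption("structfun.dssp")) {
  if (!is.null(dssp)) {
    out <- tryCatch(.run_dssp(s, dssp), error = function(e) {
      warning("DSSP invocation failed (", conditionMessage(e),
              "); using dihedral-box fallback")
      NULL
    })
    if (!is.null(out)) return(out)
  }
  if (length(s) < 2) {
    lab <- rep("C", length(s))
    attr(lab, "states") <- c("H", "E", "C")
    return(lab)
  }
  di <- backbone_dihedrals(s)
  phi <- di$phi * 180 / pi
  psi <- di$psi * 180 / pi
  lab <- rep("C", length(s))
  h <- !is.na(phi) & !is.na(psi) &
    phi > .SS3_HELIX["phi_lo"] & phi < .SS3_HELIX["phi_hi"] &
    psi > .SS3_HELIX["psi_lo"] & psi < .SS3_HELIX["psi_hi"]
  e <- !is.na(phi) & !is.na(psi) & !h &
    phi >= .SS3_STRAND["phi_lo"] & phi < .SS3_STRAND["phi_hi"] &
    psi >= .SS3_STRAND["psi_lo"] & psi <= .SS3_STRAND["psi_hi"]
  lab[h] <- "H"
  lab[e] <- "E"
  attr(lab, "states") <- c("H", "E", "C")
  lab
}

.run_dssp <- function(s, dssp) {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_backbone_pdb(s, pdb)
  res <- bio3d::dssp(bio3d::read.pdb(pdb, verbose = FALSE), exefile = dssp)
  lab <- res$sse
  lab[!lab %in% c("H", "G", "I", "E", "B", "T", "S")] <- "-"
  lab <- lab[seq_len(length(s))]
  attr(lab, "states") <- c("H", "G", "I", "E", "B", "T", "S", "-")
  lab
}

# van der Waals radii (Angstrom) by backbone atom name
.VDW <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52, CB = 1.70)

# Theoretical maximum accessible surface areas per residue (Angstrom^2),
# Tien et al. 2013; X uses the 20-residue mean.
.MAX_ACC <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
              E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
              M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
              Y = 263, V = 174, X = 197)

# Orthonormal frame (rows) anchored at atom a, built from the two
# nearest non-collinear neighbouring atoms; rotates exactly with the
# structure.  Falls back to the identity for isolated atoms.
.local_frame <- function(xyz, a, d2a) {
  ord <- order(d2a, seq_along(d2a))
  ord <- ord[ord != a]
  if (length(ord) == 0) return(diag(3))
  u1 <- xyz[ord[1L], ] - xyz[a, ]
  u1 <- u1 / sqrt(sum(u1 * u1))
  for (b in ord[-1L]) {
    w <- xyz[b, ] - xyz[a, ]
    w <- w - sum(w * u1) * u1
    nw <- sqrt(sum(w * w))
    if (nw > 1e-6) {
      u2 <- w / nw
      u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
              u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1])
      return(rbind(u1, u2, u3))
    }
  }
  diag(3)
}

.sphere_points <- function(n) {
  # golden-spiral points on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative solvent accessibility
#'
#' Shrake-Rupley numerical SASA over the stored backbone atoms (probe
#' 1.4 Angstrom), summed per residue, divided by per-residue maximal
#' accessibility constants and clipped to `[0, 1]`.
#'
#' @param s a `backbone`.
#' @param n_points sphere sample points per atom.
#' @param probe probe radius in Angstrom.
#' @return numeric vector in `[0, 1]`, one value per residue.
#' @export
sasa <- function(s, n_points = 92, probe = 1.4) {
  L <- length(s)
  if (L == 0) return(numeric(0))
  coords <- list(); radii <- numeric(0); res_of <- integer(0)
  for (nm in c("N", "CA", "C", "O", "CB")) {
    ok <- stats::complete.cases(s[[nm]])
    if (!any(ok)) next
    coords[[nm]] <- s[[nm]][ok, , drop = FALSE]
    radii <- c(radii, rep(.VDW[[nm]], sum(ok)))
    res_of <- c(res_of, which(ok))
  }
  xyz <- do.call(rbind, coords)
  n_atoms <- nrow(xyz)
  sp <- .sphere_points(n_points)
  er <- radii + probe
  area <- numeric(n_atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (a in seq_len(n_atoms)) {
    # sample directions in a frame built from the atom's own molecular
    # environment, so the numerical SASA is exactly covariant with
    # rigid motions of the structure
    pts <- sweep((sp %*% .local_frame(xyz, a, d2[a, ])) * er[a], 2L,
                 xyz[a, ], "+")
    nbr <- which(d2[a, ] < (er[a] + er)^2 & seq_len(n_atoms) != a)
    free <- rep(TRUE, n_points)
    for (b in nbr) {
      dd <- sweep(pts, 2L, xyz[b, ], "-")
      free <- free & (rowSums(dd * dd) > er[b]^2)
      if (!any(free)) break
    }
    area[a] <- mean(free) * 4 * pi * er[a]^2
  }
  per_res <- as.numeric(rowsum(area, res_of, reorder = TRUE))
  out <- numeric(L)
  out[sort(unique(res_of))] <- per_res
  pmin(pmax(out / .MAX_ACC[s$aa], 0), 1)
}

#' Gaussian radial basis encoding of a distance
#'
#' Component k is `exp(-(d - mu_k)^2 / (2 sigma^2))` with `mu_k` evenly
#' spaced on `[d_min, d_max]` and `sigma` equal to the centre spacing.
#'
#' @param d numeric vector of distances (Angstrom), nonnegative.
#' @param centers number of basis centres K.
#' @param d_min,d_max range spanned by the centres.
#' @return `length(d) x K` matrix of nonnegative values.
#' @export
rbf_encode <- function(d, centers = 16, d_min = 0, d_max = 20) {
  stopifnot(centers >= 2, d_max > d_min)
  if (any(!is.finite(d))) stop("non-finite distance")
  mu <- seq(d_min, d_max, length.out = centers)
  sigma <- mu[2] - mu[1]
  exp(-outer(d, mu, "-")^2 / (2 * sigma^2))
}

#' Sinusoidal encoding of a signed sequence offset
#'
#' Transformer-style interleaved sin/cos of the offset at geometrically
#' spaced frequencies.
#'
#' @param offset signed sequence separation(s) `j - i`.
#' @param dim even output width.
#' @return `length(offset) x dim` matrix.
#' @export
positional_encode <- function(offset, dim = 16) {
  if (dim %% 2 != 0 || dim < 2) stop("positional encoding dim must be even")
  k <- seq_len(dim / 2) - 1
  freq <- 1 / (10000^(2 * k / dim))
  arg <- outer(offset, freq)
  out <- matrix(0, length(offset), dim)
  out[, seq(1, dim, by = 2)] <- sin(arg)
  out[, seq(2, dim, by = 2)] <- cos(arg)
  out
}

#' Directed k-nearest-neighbour residue graph
#'
#' For each residue i, adds directed edges j -> i from its k nearest
#' neighbours by CA-CA Euclidean distance (ties broken by smaller
#' residue index).  With `k >= L - 1` the graph is the complete digraph
#' minus self-loops.
#'
#' @param s a `backbone`.
#' @param k neighbour count.
#' @return integer E x 2 matrix with columns `src`, `dst`.
#' @export
build_graph <- function(s, k = 30) {
  L <- length(s)
  if (L < 2) stop("need at least 2 residues to build a graph")
  stopifnot(k >= 1)
  D <- as.matrix(stats::dist(s$CA))
  kk <- min(k, L - 1L)
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(L)) {
    cand <- setdiff(seq_len(L), i)
    ord <- cand[order(D[i, cand], cand)]
    nb <- ord[seq_len(kk)]
    src <- c(src, nb)
    dst <- c(dst, rep.int(i, kk))
  }
  cbind(src = src, dst = dst)
}

#' Deterministic stand-in for pre-trained sequence embeddings
#'
#' One-hot encodes the 21-letter sequence and multiplies by a fixed
#' seeded random projection, giving an `L x dim` matrix.  This is an
#' offline substitute interface for per-residue language-model
#' embeddings; real embeddings can be supplied to [featurize()]
#' directly as a precomputed matrix.
#'
#' @param sequence amino-acid string over the 21-letter alphabet.
#' @param dim embedding width.
#' @param seed integer seed for the projection.
#' @return `nchar(sequence) x dim` numeric matrix.
#' @export
dummy_embed <- function(sequence, dim = 32, seed = 1) {
  stopifnot(dim > 0)
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, .AA_ALPHABET)
  if (anyNA(idx)) {
    stop("sequence contains characters outside the 21-letter alphabet: ",
         paste(unique(aa[is.na(idx)]), collapse = ""))
  }
  proj <- with_seed(seed, matrix(stats::rnorm(21L * dim), 21L, dim) /
                      sqrt(21))
  onehot <- matrix(0, length(aa), 21L)
  onehot[cbind(seq_along(aa), idx)] <- 1
  onehot %*% proj
}

.unit_rows <- function(m, eps = 1e-6) {
  n <- sqrt(rowSums(m * m))
  out <- m / pmax(n, eps)
  out[n < eps, ] <- 0
  out
}

#' Node scalar and vector features
#'
#' Vector channels per residue: unit backward CA difference
#' (CA(i-1) - CA(i)), unit forward CA difference (CA(i+1) - CA(i)) and
#' the unit CA -> CB direction (virtual CB when no experimental CB is
#' stored).  Channels undefined at the termini are zero vectors.
#' Scalars concatenate the secondary-structure one-hot, sin/cos of
#' (phi, psi) (0 where undefined), relative solvent accessibility and
#' the per-residue embedding rows, in that fixed order.
#'
#' @param s a `backbone`.
#' @param emb `L x dim` embedding matrix (e.g. from [dummy_embed()]).
#' @param ss optional precomputed [secondary_structure()] labels.
#' @return list with `node_scalar` (L x n_s), `node_vector`
#'   (L x 3 x 3 array, channels back/fwd/cb) and a `manifest` recording
#'   the column layout.
#' @export
node_features <- function(s, emb, ss = NULL) {
  L <- length(s)
  emb <- as.matrix(emb)
  if (nrow(emb) != L) stop("embedding row count must equal protein length")
  if (is.null(ss)) ss <- secondary_structure(s)
  states <- attr(ss, "states")

  vec <- array(0, dim = c(L, 3L, 3L),
               dimnames = list(NULL, c("back", "fwd", "cb"), NULL))
  if (L >= 2) {
    vec[2:L, "back", ] <- .unit_rows(s$CA[1:(L - 1), , drop = FALSE] -
                                       s$CA[2:L, , drop = FALSE])
    vec[1:(L - 1), "fwd", ] <- .unit_rows(s$CA[2:L, , drop = FALSE] -
                                            s$CA[1:(L - 1), , drop = FALSE])
  }
  cb <- s$CB
  for (i in seq_len(L)) {
    if (anyNA(cb[i, ])) cb[i, ] <- virtual_cbeta(s$N[i, ], s$CA[i, ], s$C[i, ])
  }
  vec[, "cb", ] <- .unit_rows(cb - s$CA)

  onehot <- matrix(0, L, length(states))
  onehot[cbind(seq_len(L), match(as.character(ss), states))] <- 1
  if (L >= 2) {
    di <- suppressWarnings(backbone_dihedrals(s))
  } else {
    di <- list(phi = NA_real_, psi = NA_real_)
  }
  enc <- function(a) cbind(sin(a), cos(a))
  dih <- cbind(enc(di$phi), enc(di$psi))
  dih[is.na(dih)] <- 0
  rsa <- sasa(s)
  scal <- cbind(onehot, dih, rsa, emb)

  manifest <- list(
    ss_states = states,
    blocks = c(ss = length(states), dihedral = 4L, sasa = 1L,
               embedding = ncol(emb)),
    node_scalar_dim = ncol(scal), node_vector_channels = 3L
  )
  list(node_scalar = unname(scal), node_vector = vec, manifest = manifest)
}

#' Edge scalar and vector features
#'
#' Each directed edge j -> i carries one unit-vector channel along
#' CA(i) - CA(j) and scalars concatenating the Gaussian RBF encoding of
#' the CA-CA distance with the sinusoidal encoding of the signed
#' sequence offset j - i (or, optionally, of the spatial distance).
#'
#' @param s a `backbone`.
#' @param edge_index E x 2 matrix from [build_graph()].
#' @param rbf_centers,rbf_min,rbf_max RBF parameters.
#' @param pos_dim positional-encoding width.
#' @param pos_mode `"offset"` (signed sequence separation, default) or
#'   `"distance"` (spatial CA-CA distance).
#' @return list with `edge_scalar` (E x e_s), `edge_vector`
#'   (E x 1 x 3 array) and a `manifest`.
#' @export
edge_features <- function(s, edge_index, rbf_centers = 16, rbf_min = 0,
                          rbf_max = 20, pos_dim = 16,
                          pos_mode = c("offset", "distance")) {
  pos_mode <- match.arg(pos_mode)
  src <- edge_index[, 1L]; dst <- edge_index[, 2L]
  stopifnot(all(src >= 1), all(src <= length(s)), all(dst >= 1),
            all(dst <= length(s)), all(src != dst))
  diff <- s$CA[dst, , drop = FALSE] - s$CA[src, , drop = FALSE]
  d <- sqrt(rowSums(diff * diff))
  if (any(d < 1e-6)) {
    warning(sprintf("%d coincident CA pair(s); zero edge vector used",
                    sum(d < 1e-6)))
  }
  ev <- array(.unit_rows(diff), dim = c(nrow(diff), 1L, 3L))
  pos_arg <- if (pos_mode == "offset") src - dst else d
  es <- cbind(rbf_encode(d, rbf_centers, rbf_min, rbf_max),
              positional_encode(pos_arg, pos_dim))
  manifest <- list(rbf = c(centers = rbf_centers, d_min = rbf_min,
                           d_max = rbf_max),
                   pos = c(dim = pos_dim), pos_mode = pos_mode,
                   edge_scalar_dim = ncol(es), edge_vector_channels = 1L)
  list(edge_scalar = unname(es), edge_vector = ev, manifest = manifest)
}

#' Build the full residue graph representation of a protein
#'
#' Convenience wrapper running [build_graph()], [node_features()] and
#' [edge_features()] and assembling the model's input representation.
#'
#' @param s a `backbone`.
#' @param emb `L x dim` per-residue embedding matrix; defaults to
#'   [dummy_embed()] of the backbone's sequence.
#' @param k neighbour count for the k-NN graph.
#' @param embed_dim,embed_seed parameters of the default embedder.
#' @param ... further arguments passed to [edge_features()].
#' @return an object of class `residue_graph`.
#' @export
featurize <- function(s, emb = NULL, k = 30, embed_dim = 32,
                      embed_seed = 1, ...) {
  if (is.null(emb)) emb <- dummy_embed(backbone_sequence(s), embed_dim,
                                       embed_seed)
  ei <- build_graph(s, k)
  nf <- node_features(s, emb)
  ef <- edge_features(s, ei, ...)
  residue_graph(
    n_nodes = length(s), edge_index = ei,
    node_scalar = nf$node_scalar, node_vector = nf$node_vector,
    edge_scalar = ef$edge_scalar, edge_vector = ef$edge_vector,
    manifest = c(nf$manifest, ef$manifest, list(k = k)),
    protein_id = paste0("chain_", s$chain_id)
  )
}

#' Residue graph container
#'
#' Validates and wraps the model's input graph representation: node and
#' edge scalar/vector features plus the directed edge index.
#'
#' @param n_nodes residue count L.
#' @param edge_index integer E x 2 matrix (`src`, `dst`), no self-loops.
#' @param node_scalar L x n_s matrix.
#' @param node_vector L x n_v x 3 array; each channel row has norm 1 or
#'   exactly 0.
#' @param edge_scalar E x e_s matrix.
#' @param edge_vector E x e_v x 3 array.
#' @param manifest named list recording the feature layout.
#' @param protein_id identifier carried through prediction output.
#' @return object of class `residue_graph`.
#' @export
residue_graph <- function(n_nodes, edge_index, node_scalar, node_vector,
                          edge_scalar, edge_vector, manifest = list(),
                          protein_id = "protein") {
  edge_index <- cbind(src = as.integer(edge_index[, 1L]),
                      dst = as.integer(edge_index[, 2L]))
  stopifnot(nrow(node_scalar) == n_nodes, dim(node_vector)[1] == n_nodes,
            nrow(edge_scalar) == nrow(edge_index),
            dim(edge_vector)[1] == nrow(edge_index))
  if (any(edge_index < 1L) || any(edge_index > n_nodes)) {
    stop("edge endpoints out of range")
  }
  if (any(edge_index[, 1L] == edge_index[, 2L])) stop("self-loop in graph")
  if (!all(is.finite(node_scalar)) || !all(is.finite(node_vector)) ||
      !all(is.finite(edge_scalar)) || !all(is.finite(edge_vector))) {
    stop("non-finite feature values")
  }
  for (ch in seq_len(dim(node_vector)[2])) {
    n <- sqrt(rowSums(node_vector[, ch, , drop = FALSE]^2, dims = 1))
    if (!all(abs(n - 1) < 1e-5 | n < 1e-8)) {
      stop("node vector channel rows must have norm 1 or exactly 0")
    }
  }
  structure(list(n_nodes = as.integer(n_nodes), edge_index = edge_index,
                 node_scalar = node_scalar, node_vector = node_vector,
                 edge_scalar = edge_scalar, edge_vector = edge_vector,
                 manifest = manifest, protein_id = protein_id,
                 cache = new.env(parent = emptyenv())),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf(
    "<residue_graph> %s: %d nodes, %d edges, scalar %d/%d, vector %d/%d\n",
    x$protein_id, x$n_nodes, nrow(x$edge_index), ncol(x$node_scalar),
    ncol(x$edge_scalar), dim(x$node_vector)[2], dim(x$edge_vector)[2]))
  invisible(x)
}

#' Serialize a residue graph to disk
#'
#' Writes a directory containing `manifest.json` (feature layout and
#' shapes) and `arrays.rds` (the numeric payload).  Round-trips
#' bit-exactly through [read_graph()].
#'
#' @param g a `residue_graph`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_graph <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(protein_id = g$protein_id, n_nodes = g$n_nodes,
         n_edges = nrow(g$edge_index), manifest = g$manifest,
         package_version = as.character(utils::packageVersion("structfun"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(g, file.path(dir, "arrays.rds"))
  invisible(dir)
}

#' Read a residue graph written by [write_graph()]
#' @param dir directory containing `manifest.json` and `arrays.rds`.
#' @return a `residue_graph`.
#' @export
read_graph <- function(dir) {
  g <- readRDS(file.path(dir, "arrays.rds"))
  stopifnot(inherits(g, "residue_graph"))
  g
}

# Evaluate code with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
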