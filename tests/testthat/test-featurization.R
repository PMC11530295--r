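test_that("backbone dihedrals match an independent two-plane oracle", {
  set.seed(3)
  for (rep in 1:20) {
    s <- fixture_backbone(seed = rep, jitter = 0.3)
    di <- backbone_dihedrals(s)
    i <- sample(2:(length(s) - 1), 1)
    expect_equal(di$phi[i],
                 dihedral_oracle(s$C[i - 1, ], s$N[i, ], s$CA[i, ],
                                 s$C[i, ]), tolerance = 1e-9)
    expect_equal(di$psi[i],
                 dihedral_oracle(s$N[i, ], s$CA[i, ], s$C[i, ],
                                 s$N[i + 1, ]), tolerance = 1e-9)
  }
})

test_that("dihedrals: termini are undefined; trans is +/-pi, cis is 0", {
  s <- fixture_backbone()
  di <- backbone_dihedrals(s)
  expect_true(is.na(di$phi[1]))
  expect_true(is.na(di$psi[length(s)]))
  # planar quadruples
  expect_equal(abs(dihedral_oracle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                   c(1, -1, 0))), pi)
  expect_equal(abs(structfun:::.dihedral(c(0, 1, 0), c(0, 0, 0),
                                         c(1, 0, 0), c(1, -1, 0))), pi,
               tolerance = 1e-12)
  expect_equal(structfun:::.dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                     c(1, 1, 0)), 0, tolerance = 1e-12)
})

test_that("fallback secondary structure assigns Ramachandran boxes", {
  hel <- synthetic_backbone(list(c("helix", 12)), seed = 1, jitter = 0)
  ss <- secondary_structure(hel)
  expect_true(all(ss[2:11] == "H"))
  ext <- synthetic_backbone(list(c("strand", 10)), seed = 1, jitter = 0)
  expect_true(all(secondary_structure(ext)[2:9] == "E"))
  # undefined terminal angles give coil
  expect_equal(ss[1], "C")
  expect_equal(ss[12], "C")
})

test_that("relative solvent accessibility is exposed, occluded, bounded", {
  # one isolated residue clips to 1
  iso <- new_backbone("A", "A", matrix(c(0, 0, 0), 1),
                      matrix(c(1.46, 0, 0), 1), matrix(c(2, 1.4, 0), 1))
  expect_equal(sasa(iso), c(A = 1))

  # residue buried at the centre of a dense ball scores low, and the
  # implementation agrees with a brute-force random-direction oracle
  set.seed(4)
  n_shell <- 26
  dirs <- matrix(stats::rnorm(n_shell * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  Ls <- 1 + n_shell
  Nm <- CAm <- Cm <- matrix(0, Ls, 3)
  CAm[1, ] <- c(0, 0, 0); Nm[1, ] <- c(1.46, 0, 0); Cm[1, ] <- c(0, 1.52, 0.6)
  for (i in seq_len(n_shell)) {
    ctr <- dirs[i, ] * 4.5
    CAm[i + 1, ] <- ctr
    Nm[i + 1, ] <- ctr + c(1.46, 0, 0)
    Cm[i + 1, ] <- ctr + c(0, 1.52, 0.6)
  }
  ball <- new_backbone("A", rep("A", Ls), Nm, CAm, Cm)
  rsa <- sasa(ball)
  expect_lt(rsa[1], 0.2)

  # brute-force oracle for the central residue's atoms
  oracle_area <- function(xyz, radii, probe = 1.4, n = 500) {
    total <- 0
    for (a in 1:3) {
      er <- radii[a] + probe
      pts <- matrix(stats::rnorm(n * 3), ncol = 3)
      pts <- pts / sqrt(rowSums(pts^2)) * er
      pts <- sweep(pts, 2, xyz[a, ], "+")
      free <- rep(TRUE, n)
      for (b in seq_len(nrow(xyz))) {
        if (b == a) next
        rb <- radii[b] + probe
        dd <- sweep(pts, 2, xyz[b, ], "-")
        free <- free & rowSums(dd^2) > rb^2
      }
      total <- total + mean(free) * 4 * pi * er^2
    }
    total
  }
  atoms <- rbind(Nm, CAm, Cm)
  radii <- rep(c(1.55, 1.70, 1.70), each = Ls)
  ord <- c(1, Ls + 1, 2 * Ls + 1)  # central residue's N, CA, C first
  xyz <- rbind(atoms[ord, ], atoms[-ord, ])
  rr <- c(radii[ord], radii[-ord])
  expect_equal(unname(rsa[1]), min(oracle_area(xyz, rr) / 129, 1),
               tolerance = 0.05)

  # bounded on random fixtures
  for (i in 1:5) {
    r <- sasa(fixture_backbone(seed = i))
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("RBF encoding matches its closed form", {
  K <- 16; dmin <- 0; dmax <- 20
  mu <- seq(dmin, dmax, length.out = K)
  sig <- mu[2] - mu[1]
  # distance at a centre gives component 1
  expect_equal(rbf_encode(mu[5], K, dmin, dmax)[1, 5], 1)
  # far tail vanishes
  expect_true(all(rbf_encode(dmax + 10 * sig, K, dmin, dmax) < 1e-8))
  set.seed(9)
  d <- stats::runif(100, 0, 25)
  expect_equal(rbf_encode(d, K, dmin, dmax),
               exp(-outer(d, mu, "-")^2 / (2 * sig^2)), tolerance = 1e-12)
  expect_error(rbf_encode(NaN), "finite")
})

test_that("positional encoding has sin/cos structure and parity", {
  e0 <- positional_encode(0, 16)
  expect_equal(e0[1, seq(1, 16, 2)], rep(0, 8))
  expect_equal(e0[1, seq(2, 16, 2)], rep(1, 8))
  ep <- positional_encode(7, 16); em <- positional_encode(-7, 16)
  expect_equal(em[1, seq(1, 16, 2)], -ep[1, seq(1, 16, 2)])
  expect_equal(em[1, seq(2, 16, 2)], ep[1, seq(2, 16, 2)])
  for (d in c(2, 8, 16)) expect_equal(ncol(positional_encode(3, d)), d)
  expect_error(positional_encode(1, 7), "even")
})

test_that("k-NN graph equals exhaustive search, handles ties and edge cases", {
  # L=3, k=2: complete digraph
  s3 <- synthetic_backbone(list(c("coil", 4)), seed = 1, jitter = 0)
  g3 <- build_graph(structfun:::transform_backbone(s3, diag(3)), k = 30)
  expect_equal(nrow(g3), 4 * 3)
  expect_true(all(g3[, 1] != g3[, 2]))

  set.seed(5)
  for (rep in 1:10) {
    s <- fixture_backbone(seed = rep)
    ei <- build_graph(s, k = 3)
    D <- as.matrix(dist(s$CA))
    for (i in sample(length(s), 4)) {
      nb <- sort(ei[ei[, 2] == i, 1])
      cand <- setdiff(seq_len(length(s)), i)
      expected <- sort(cand[order(D[i, cand], cand)][1:3])
      expect_equal(nb, expected)
    }
  }

  # duplicate coordinates: deterministic tie-break by index
  Nm <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(5, 0, 0))
  CAm <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(6, 0, 0))
  Cm <- rbind(c(2, 1, 0), c(2, 1, 0), c(2, 1, 0), c(7, 1, 0))
  dup <- new_backbone("A", rep("A", 4), Nm, CAm, Cm)
  e1 <- build_graph(dup, k = 1)
  e2 <- build_graph(dup, k = 1)
  expect_identical(e1, e2)
  expect_equal(unname(e1[e1[, 2] == 3, 1]), 1L)  # smallest index wins

  one <- new_backbone("A", "A", matrix(0, 1, 3), matrix(1, 1, 3),
                      matrix(2, 1, 3))
  expect_error(build_graph(one), "at least 2")
})

test_that("node features: unit vectors, terminus sentinels, virtual CB for glycine", {
  s <- fixture_backbone()
  nf <- node_features(s, dummy_embed(backbone_sequence(s)))
  L <- length(s)
  for (ch in 1:3) {
    n <- sqrt(rowSums(nf$node_vector[, ch, ]^2))
    expect_true(all(abs(n - 1) < 1e-6 | n == 0))
  }
  expect_equal(nf$node_vector[1, "back", ], c(0, 0, 0))
  expect_equal(nf$node_vector[L, "fwd", ], c(0, 0, 0))
  # glycine channel equals the normalized virtual C-beta direction
  gi <- which(s$aa == "G")[1]
  if (is.na(gi)) gi <- 3L
  vcb <- virtual_cbeta(s$N[gi, ], s$CA[gi, ], s$C[gi, ]) - s$CA[gi, ]
  expect_equal(as.numeric(nf$node_vector[gi, "cb", ]),
               as.numeric(vcb / sqrt(sum(vcb^2))), tolerance = 1e-9)
})

test_that("node scalars are rotation-invariant and vectors rotate exactly", {
  s <- fixture_backbone()
  emb <- dummy_embed(backbone_sequence(s))
  nf0 <- node_features(s, emb)
  set.seed(21)
  R <- random_rotation()
  st <- structfun:::transform_backbone(s, R, stats::rnorm(3) * 8)
  nf1 <- node_features(st, emb)
  expect_equal(nf1$node_scalar, nf0$node_scalar, tolerance = 1e-6)
  for (ch in 1:3) {
    expect_equal(nf1$node_vector[, ch, ],
                 nf0$node_vector[, ch, ] %*% t(R), tolerance = 1e-6)
  }
})

test_that("edge features: antisymmetry, RBF peak, translation invariance", {
  s <- fixture_backbone()
  ei <- build_graph(s, k = 4)
  ef <- edge_features(s, ei)
  # reciprocal edges carry opposite unit vectors
  key <- paste(ei[, 1], ei[, 2])
  rev_idx <- match(paste(ei[, 2], ei[, 1]), key)
  ok <- which(!is.na(rev_idx))[1:5]
  for (e in ok) {
    expect_equal(ef$edge_vector[e, 1, ],
                 -ef$edge_vector[rev_idx[e], 1, ], tolerance = 1e-9)
  }
  # RBF arg-max component sits at the centre nearest the distance
  d <- sqrt(sum((s$CA[ei[1, 2], ] - s$CA[ei[1, 1], ])^2))
  mu <- seq(0, 20, length.out = 16)
  expect_equal(which.max(ef$edge_scalar[1, 1:16]), which.min(abs(mu - d)))
  # pure translation changes nothing
  st <- structfun:::transform_backbone(s, diag(3), c(5, -3, 2))
  ef2 <- edge_features(st, ei)
  expect_equal(ef2$edge_scalar, ef$edge_scalar, tolerance = 1e-9)
  expect_equal(ef2$edge_vector, ef$edge_vector, tolerance = 1e-9)
})

test_that("dummy embedder is deterministic, type-discriminating, shaped", {
  e1 <- dummy_embed("ACDG", 16, seed = 3)
  e2 <- dummy_embed("ACDG", 16, seed = 3)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(4L, 16L))
  expect_false(isTRUE(all.equal(e1[1, ], e1[2, ])))
  expect_error(dummy_embed("ACZ1", 8), "alphabet")
})

test_that("residue graphs validate invariants and round-trip bit-exactly", {
  s <- fixture_backbone()
  g <- featurize(s, k = 6)
  expect_s3_class(g, "residue_graph")
  expect_true(all(g$edge_index[, 1] != g$edge_index[, 2]))
  d <- tempfile()
  write_graph(g, d)
  g2 <- read_graph(d)
  expect_identical(g2$node_scalar, g$node_scalar)
  expect_identical(g2$edge_scalar, g$edge_scalar)
  expect_identical(g2$edge_index, g$edge_index)
  expect_true(file.exists(file.path(d, "manifest.json")))
  # permutation stability: re-featurizing the same backbone is identical
  g3 <- featurize(s, k = 6)
  expect_identical(g3$node_scalar, g$node_scalar)
  expect_identical(g3$edge_index, g$edge_index)
})
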