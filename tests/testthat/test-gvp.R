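test_that("GVP zero-vector input follows the closed-form scalar path", {
  set.seed(1)
  p <- gvp_params(4, 2, 8, 3, seed = 2)
  s <- matrix(stats::rnorm(4), 1)
  V0 <- array(0, c(1, 2, 3))
  out <- gvp_forward(s, V0, p)
  expect_equal(dim(out$s), c(1L, 8L))
  expect_equal(dim(out$V), c(1L, 3L, 3L))
  # V' = 0 exactly and s' = relu(Wm concat(0, s) + b)
  expect_true(all(out$V == 0))
  expected <- pmax(cbind(matrix(0, 1, ncol(p$Wh)), s) %*% p$Wm + p$b, 0)
  expect_equal(out$s, expected, tolerance = 1e-12)
})

test_that("GVP honors declared widths", {
  p <- gvp_params(4, 2, 8, 3, seed = 5)
  out <- gvp_forward(stats::rnorm(4), matrix(stats::rnorm(6), 2, 3), p)
  expect_equal(dim(out$s), c(1L, 8L))
  expect_equal(dim(out$V), c(1L, 3L, 3L))
  pc <- gvp_params(6, 3, 5, 0, seed = 5)
  outc <- gvp_forward(stats::rnorm(6), matrix(stats::rnorm(9), 3, 3), pc)
  expect_null(outc$V)
  expect_equal(dim(outc$s), c(1L, 5L))
  expect_error(gvp_forward(stats::rnorm(3), matrix(stats::rnorm(6), 2, 3),
                           p), "widths")
})

test_that("GVP is rotation-equivariant: scalars invariant, vectors rotate", {
  p <- gvp_params(5, 3, 6, 4, seed = 3)
  set.seed(14)
  for (rep in 1:20) {
    s <- matrix(stats::rnorm(10), 2, 5)
    V <- array(stats::rnorm(2 * 3 * 3), c(2, 3, 3))
    R <- random_rotation()
    VR <- V
    for (i in 1:2) VR[i, , ] <- V[i, , ] %*% t(R)
    o0 <- gvp_forward(s, V, p)
    oR <- gvp_forward(s, VR, p)
    expect_equal(oR$s, o0$s, tolerance = 1e-5)
    for (i in 1:2) {
      expect_equal(oR$V[i, , ], o0$V[i, , ] %*% t(R), tolerance = 1e-6)
    }
  }
})

test_that("scalar-vector layer norm standardizes and commutes with rotation", {
  set.seed(6)
  s <- matrix(stats::rnorm(30, mean = 3, sd = 2), 3, 10)
  V <- array(stats::rnorm(3 * 4 * 3), c(3, 4, 3))
  out <- sv_layernorm(s, V)
  expect_equal(rowMeans(out$s), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(out$s, 1, function(x) mean(x^2)), rep(1, 3),
               tolerance = 1e-4)
  # constant scalar row normalizes to zero (pre-affine)
  cst <- sv_layernorm(matrix(5, 1, 8))
  expect_equal(as.numeric(cst$s), rep(0, 8), tolerance = 1e-2)
  # rotation commutes on the vector part
  R <- random_rotation()
  VR <- V
  for (i in 1:3) VR[i, , ] <- V[i, , ] %*% t(R)
  outR <- sv_layernorm(s, VR)
  for (i in 1:3) {
    expect_equal(outR$V[i, , ], out$V[i, , ] %*% t(R), tolerance = 1e-9)
  }
})

test_that("messages concatenate widths and propagate the zero case", {
  g <- featurize(fixture_backbone(), k = 4)
  m <- small_model(g)
  cfg <- m$cfg
  # concatenation widths: message GVP 1 takes (hidden_s + edge_s,
  # hidden_v + edge_v)
  w1 <- dim(m$params[["layer1.msg1.Wm"]])
  h1 <- dim(m$params[["layer1.msg1.Wh"]])
  expect_equal(h1[1], cfg$hidden_v + cfg$edge_v)
  expect_equal(w1[1], cfg$hidden_s + cfg$edge_scalar_dim + h1[2])
  expect_equal(w1[2], cfg$hidden_s)

  # all-zero node and edge vectors give zero message vectors
  tape <- structfun:::ad_tape()
  pl <- structfun:::.param_leaves(tape, m$params)
  E <- 5L
  Sm <- structfun:::ad_leaf(tape, matrix(0.5, E, cfg$hidden_s +
                                           cfg$edge_scalar_dim), FALSE)
  Vm <- structfun:::ad_leaf(tape, matrix(0, 3 * E, cfg$hidden_v +
                                           cfg$edge_v), FALSE)
  o <- structfun:::.gvp_fwd(pl, "layer1.msg1", Sm, Vm, cfg$hidden_v)
  expect_true(all(structfun:::ad_val(o$V) == 0))
})

test_that("node update: mean aggregation is order-invariant; empty messages reduce to layer norm", {
  # permuting message order leaves segment means bit-identical
  tape <- structfun:::ad_tape()
  set.seed(8)
  M <- matrix(stats::rnorm(12), 6, 2)
  seg <- c(1L, 2L, 1L, 2L, 1L, 2L)
  a <- structfun:::ad_val(structfun:::ad_segment_mean(
    structfun:::ad_leaf(tape, M, FALSE), seg, 2L))
  perm <- c(5L, 3L, 1L, 6L, 4L, 2L)
  b <- structfun:::ad_val(structfun:::ad_segment_mean(
    structfun:::ad_leaf(tape, M[perm, ], FALSE), seg[perm], 2L))
  expect_equal(a, b, tolerance = 1e-12)
  # a single message aggregates to itself
  one <- structfun:::ad_val(structfun:::ad_segment_mean(
    structfun:::ad_leaf(tape, M[1, , drop = FALSE], FALSE), 1L, 1L))
  expect_equal(one, M[1, , drop = FALSE])
  # nodes receiving no message get a zero aggregate
  none <- structfun:::ad_val(structfun:::ad_segment_mean(
    structfun:::ad_leaf(tape, M, FALSE), rep(1L, 6), 3L))
  expect_equal(none[2:3, ], matrix(0, 2, 2))
})

test_that("single-node graph reduces to repeated layer norm of the lifted features", {
  s1 <- new_backbone("A", "A", matrix(c(0, 0, 0), 1),
                     matrix(c(1.46, 0, 0), 1), matrix(c(2, 1.4, 0), 1))
  nf <- node_features(s1, dummy_embed("A", 32))
  g1 <- residue_graph(1L, matrix(integer(0), 0, 2), nf$node_scalar,
                      nf$node_vector, matrix(0, 0, 32),
                      array(0, c(0, 1, 3)))
  m <- small_model(g1)
  tape <- structfun:::ad_tape()
  pl <- structfun:::.param_leaves(tape, m$params)
  tr <- structfun:::.gnn_forward(pl, m$cfg, g1, tape = tape)

  # hand-rolled oracle: lift once, then n_layers plain layer norms
  lift <- m$params[c("lift_n.Wh", "lift_n.Wm", "lift_n.b", "lift_n.Wmu")]
  Vh <- structfun:::.stack_vec(nf$node_vector) %*% lift[["lift_n.Wh"]]
  nh <- sqrt(colSums(Vh^2))  # 1 residue: norms over the 3 stacked rows
  S <- pmax(cbind(matrix(nh, 1), nf$node_scalar) %*% lift[["lift_n.Wm"]] +
              lift[["lift_n.b"]], 0)
  Vmu <- Vh %*% lift[["lift_n.Wmu"]]
  gate <- 1 / (1 + exp(-sqrt(colSums(Vmu^2))))
  V <- Vmu * matrix(gate, 3, length(gate), byrow = TRUE)
  for (l in seq_len(m$cfg$n_layers)) {
    gmma <- m$params[[sprintf("layer%d.ln.gamma", l)]]
    beta <- m$params[[sprintf("layer%d.ln.beta", l)]]
    mu <- mean(S); sd <- sqrt(mean((S - mu)^2) + 1e-5)
    S <- ((S - mu) / sd) * gmma + beta
    rms <- sqrt(mean(colSums(V^2)) + 1e-6)
    V <- V / rms
  }
  expect_equal(structfun:::ad_val(tr$S), S, tolerance = 1e-9)
  expect_equal(structfun:::ad_val(tr$V), V, tolerance = 1e-9)
})

test_that("evaluation-mode forward is deterministic and SE(3)-invariant", {
  s <- fixture_backbone()
  g <- featurize(s, k = 8)
  m <- small_model(g)
  p1 <- model_predict(m, g)
  p2 <- model_predict(m, g)
  expect_identical(p1, p2)

  set.seed(31)
  for (rep in 1:3) {
    R <- random_rotation()
    st <- structfun:::transform_backbone(s, R, stats::rnorm(3) * 10)
    gt <- featurize(st, k = 8)
    pt <- model_predict(m, gt)
    expect_equal(pt, p1, tolerance = 1e-4)
  }
})

test_that("collapsed feature map is rotation-invariant and respects widths", {
  s <- fixture_backbone()
  g <- featurize(s, k = 8)
  m <- small_model(g)
  getF <- function(gg) {
    tape <- structfun:::ad_tape()
    pl <- structfun:::.param_leaves(tape, m$params)
    structfun:::ad_val(structfun:::.gnn_forward(pl, m$cfg, gg,
                                                tape = tape)$F)
  }
  F0 <- getF(g)
  expect_equal(dim(F0), c(length(s), m$cfg$collapse_dim))
  set.seed(7)
  R <- random_rotation()
  F1 <- getF(featurize(structfun:::transform_backbone(s, R, c(3, -1, 2)),
                       k = 8))
  expect_equal(F1, F0, tolerance = 1e-4)
})

test_that("tape gradients agree with central finite differences", {
  g <- featurize(fixture_backbone(), k = 5)
  m <- small_model(g)
  y <- matrix(c(1, 0), 1, 2)
  cfg <- train_config(seed = 3, batch_size = 1)
  base <- withr::with_seed(99, structfun:::.batch_loss(
    m$params, m$cfg, list(g), y, cfg, c(1, 1), FALSE, TRUE))
  set.seed(12)
  for (nm in sample(names(m$params), 6)) {
    pm <- m$params
    i <- sample(length(pm[[nm]]), 1)
    h <- 1e-6
    pm[[nm]][i] <- pm[[nm]][i] + h
    lp <- withr::with_seed(99, structfun:::.batch_loss(
      pm, m$cfg, list(g), y, cfg, c(1, 1), FALSE, FALSE))$loss
    pm[[nm]][i] <- pm[[nm]][i] - 2 * h
    lm <- withr::with_seed(99, structfun:::.batch_loss(
      pm, m$cfg, list(g), y, cfg, c(1, 1), FALSE, FALSE))$loss
    fd <- (lp - lm) / (2 * h)
    expect_equal(base$grads[[nm]][i], fd, tolerance = 1e-4)
  }
})
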