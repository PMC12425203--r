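# Gated fusion, shared encoder, task relation matrix, heads, loss weighting,
# gradient resolution.

test_that("gated fusion obeys sigmoid gating limits", {
  z <- c(1, -2, 3)
  m <- c(0.5, 4)
  p0 <- list(Wz = matrix(0, 3, 3), bz = rep(0, 3),
             Wm = matrix(0, 2, 2), bm = rep(0, 2))
  expect_equal(gated_fuse(z, m, p0), c(0.5 * z, 0.5 * m))
  psat <- list(Wz = matrix(0, 3, 3), bz = rep(50, 3),
               Wm = matrix(0, 2, 2), bm = rep(50, 2))
  expect_equal(gated_fuse(z, m, psat), c(z, m), tolerance = 1e-6)
  set.seed(1)
  prand <- list(Wz = matrix(rnorm(9), 3, 3), bz = rnorm(3),
                Wm = matrix(rnorm(4), 2, 2), bm = rnorm(2))
  expect_equal(gated_fuse(rep(0, 3), rep(0, 2), prand), rep(0, 5))
  expect_error(gated_fuse(c(1, 2), m, p0), "shape")
})

test_that("shared residual layers are identity maps at zero weights", {
  params <- list(`sh.1.W` = matrix(0, 8, 8), `sh.1.b` = rep(0, 8),
                 `sh.2.W` = matrix(0, 8, 8), `sh.2.b` = rep(0, 8))
  h0 <- rnorm(8)
  expect_equal(shared_forward(h0, params, 2), h0)
  # eval mode is deterministic even with a dropout setting
  set.seed(9)
  params$`sh.1.W` <- matrix(rnorm(64), 8, 8)
  a <- shared_forward(h0, params, 2, dropout = 0.5, train = FALSE)
  b <- shared_forward(h0, params, 2, dropout = 0.5, train = FALSE)
  expect_identical(a, b)
  expect_error(shared_forward(rnorm(5), params, 2), "width")
})

test_that("task relation matrix is row-stochastic with hand-checked values", {
  # U = 0 gives the uniform matrix
  U0 <- array(0, dim = c(3, 3, 4))
  R0 <- task_relation(rnorm(4), U0)$R
  expect_equal(R0, matrix(1 / 3, 3, 3))
  # hand softmax: s = [[ln 2, 0], [0, 0]]
  h <- c(1, 0)  # h^2 = (1, 0): s_ij = U[i,j,1]
  U <- array(0, dim = c(2, 2, 2))
  U[1, 1, 1] <- log(2)
  R <- task_relation(h, U)$R
  expect_equal(R[1, ], c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(R[2, ], c(1 / 2, 1 / 2), tolerance = 1e-12)
  # row normalization for random U and h
  set.seed(7)
  for (i in 1:5) {
    Ur <- array(rnorm(2 * 2 * 6), dim = c(2, 2, 6))
    Rr <- task_relation(rnorm(6), Ur)$R
    expect_equal(rowSums(Rr), c(1, 1), tolerance = 1e-6)
    expect_true(all(Rr >= 0))
  }
})

test_that("task heads produce proper distributions with softmax invariances", {
  tasks <- list(task_spec("a", arity = 4L))
  params <- list(`head.1.W` = matrix(0, 4, 6), `head.1.b` = rep(0, 4))
  out <- predict_tasks(rnorm(6), params, tasks)
  expect_equal(out$a, rep(0.25, 4))
  set.seed(5)
  params$`head.1.W` <- matrix(rnorm(24), 4, 6)
  params$`head.1.b` <- rnorm(4)
  h <- rnorm(6)
  p1 <- predict_tasks(h, params, tasks)$a
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  params2 <- params
  params2$`head.1.b` <- params$`head.1.b` + 7  # constant logit shift
  expect_equal(predict_tasks(h, params2, tasks)$a, p1, tolerance = 1e-9)
})

test_that("importance-weighted loss is a scale-invariant convex combination", {
  expect_equal(weighted_loss(c(0.5, 1.5), c(1, 1)), 1.0)
  expect_equal(weighted_loss(c(2, 4), c(3, 1)), 2.5)
  l <- c(1.2, 0.3, 2.2)
  expect_equal(weighted_loss(l, c(5, 5, 5)), mean(l))
  expect_equal(weighted_loss(l, c(2, 1, 7)), weighted_loss(l, 10 * c(2, 1, 7)))
  expect_equal(sum(importance_weights(c(0.2, 5, 1))), 1)
  expect_error(weighted_loss(c(1, 2), c(1, 0)), "positive")
  expect_error(weighted_loss(c(1, 2), c(1, -3)), "positive")
})

test_that("relation-weighted gradient combination matches hand substitution", {
  g1 <- list(W = matrix(1:4, 2, 2), b = c(1, 1))
  g2 <- list(W = matrix(4:1, 2, 2), b = c(3, 5))
  # T = 1: the single gradient passes through
  expect_equal(resolve_gradients(list(g1), matrix(1, 1, 1)), g1)
  # uniform R reduces exactly to the plain average
  Ru <- matrix(0.5, 2, 2)
  avg <- resolve_gradients(list(g1, g2), Ru)
  expect_identical(avg$W, (g1$W + g2$W) / 2)
  expect_identical(avg$b, (g1$b + g2$b) / 2)
  # diagonal weights R_tt as printed
  R <- matrix(c(0.9, 0.1, 0.9, 0.1), 2, 2, byrow = TRUE)
  comb <- resolve_gradients(list(g1, g2), R)
  expect_equal(comb$W, 0.9 * g1$W + 0.1 * g2$W)
  expect_error(resolve_gradients(list(g1, g2), matrix(1, 3, 3)), "T x T")
})

test_that("every parameter tensor receives gradient on a random batch", {
  setup <- tiny_model_setup(n = 16, delta = 1, negation_fraction = 0.9)
  bg <- ehrdx:::batch_grads(setup$model, setup$prep$records[1:8])
  for (nm in names(setup$model$params)) {
    expect_false(is.null(bg$grads[[nm]]), info = nm)
    expect_gt(max(abs(bg$grads[[nm]])), 0, label = paste("grad", nm))
  }
})

test_that("backward pass matches central finite differences", {
  setup <- tiny_model_setup(n = 12, relation = FALSE, negation_fraction = 0.9)
  model <- setup$model
  recs <- setup$prep$records[1:3]
  bg <- ehrdx:::batch_grads(model, recs)
  lossfun <- function(m) ehrdx:::batch_grads(m, recs, want_grads = FALSE)$loss
  eps <- 1e-5
  set.seed(99)
  check_names <- c("token_embedding", "bias_table", "layer1.Wq", "layer1.W1",
                   "layer1.ln2_gamma", "fus.Wz", "sh.1.W", "sh.1.P", "head.1.W")
  for (nm in check_names) {
    for (i in sample(length(model$params[[nm]]), 2)) {
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(bg$grads[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]", nm, i))
    }
  }
})
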