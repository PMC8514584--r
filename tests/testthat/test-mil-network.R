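ns <- asNamespace("admil")

rand_mil_params <- function(spec, D = 8L, seed = 1) {
  set.seed(seed)
  ns$init_mil_params(spec, D)
}

test_that("every backbone maps a patch batch to K x L features", {
  set.seed(1)
  X <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  for (bk in c("lenet_like", "alexnet_like", "inception_like",
               "resnet_like", "densenet_like")) {
    spec <- backbone_spec(bk, 64, feature_dim = 40)
    params <- rand_mil_params(spec)
    H <- backbone_forward(X, spec, params)$H
    expect_equal(dim(H), c(2, 40), label = bk)
    expect_true(all(is.finite(H)), label = bk)
    # deterministic in evaluation: same input, same weights, same output
    expect_identical(H, backbone_forward(X, spec, params)$H, label = bk)
  }
})

test_that("backbones accept all three patch sizes via adaptive pooling", {
  for (sz in c(64L, 96L, 128L)) {
    spec <- backbone_spec("lenet_like", sz, feature_dim = 30)
    X <- array(0.5, c(sz, sz, 3, 1))
    expect_equal(dim(backbone_forward(X, spec, rand_mil_params(spec))$H),
                 c(1, 30))
  }
})

test_that("the reference lenet configuration yields the configured L = 500", {
  spec <- backbone_spec("lenet_like", 64)
  X <- array(0.2, c(64, 64, 3, 1))
  expect_length(backbone_forward(X, spec, rand_mil_params(spec))$H, 500)
})

test_that("a zero image passes through zero-bias ReLU layers to zero features", {
  spec <- backbone_spec("lenet_like", 64, feature_dim = 25)
  params <- rand_mil_params(spec)   # biases initialise to zero
  X <- array(0, c(64, 64, 3, 1))
  expect_equal(as.vector(backbone_forward(X, spec, params)$H), rep(0, 25))
})

test_that("patch size mismatches are input errors", {
  spec <- backbone_spec("lenet_like", 64, feature_dim = 10)
  params <- rand_mil_params(spec)
  expect_error(backbone_forward(array(0, c(96, 96, 3, 1)), spec, params),
               "does not match")
  expect_error(backbone_forward(array(0, c(64, 64, 1)), spec, params),
               "array")
})

test_that("attention pooling reduces correctly for singleton and tied bags", {
  V <- matrix(rnorm(6), 3, 2)
  w <- rnorm(3)
  h <- c(1.5, -2)
  one <- attention_pool(matrix(h, 1), V, w)
  expect_equal(one$a, 1)
  expect_equal(one$z, h)
  same <- attention_pool(matrix(rep(h, each = 5), 5), V, w)
  expect_equal(same$a, rep(0.2, 5))
  expect_equal(same$z, h)
  expect_error(attention_pool(matrix(numeric(0), 0, 2), V, w), "at least one")
})

test_that("zero attention scorer reduces attention pooling to mean pooling", {
  set.seed(2)
  H <- matrix(rnorm(8 * 5), 8, 5)
  V <- matrix(rnorm(3 * 5), 3, 5)
  ap <- attention_pool(H, V, w = rep(0, 3))
  mp <- mean_pool(H)
  expect_equal(ap$a, mp$a)
  expect_equal(ap$z, mp$z)
})

test_that("attention weights follow the softmax of w' tanh(V h)", {
  # hand-derived two-instance case: logits (0, tanh(10))
  V <- matrix(c(1, 0), 1, 2)
  w <- 1
  H <- rbind(c(0, 0), c(10, 0))
  ap <- attention_pool(H, V, w)
  l2 <- tanh(10)
  expect_equal(ap$logits, c(0, l2))
  expect_equal(ap$a, exp(c(0, l2)) / sum(exp(c(0, l2))), tolerance = 1e-12)
  expect_equal(ap$a, c(0.2689, 0.7311), tolerance = 1e-4)
  expect_equal(ap$z, ap$a[2] * c(10, 0))
})

test_that("mean pooling is the elementwise arithmetic mean", {
  H <- rbind(c(1, 3), c(3, 5))
  expect_equal(mean_pool(H)$z, c(2, 4))
  expect_equal(mean_pool(matrix(c(7, 1), 1))$z, c(7, 1))
  expect_error(mean_pool(matrix(numeric(0), 0, 2)), "at least one")
})

test_that("attention weights normalise, stay in (0,1), and z is convex", {
  set.seed(33)
  for (i in 1:20) {
    K <- sample(1:12, 1)
    L <- sample(2:6, 1)
    D <- sample(1:5, 1)
    H <- matrix(rnorm(K * L, sd = 3), K, L)
    V <- matrix(rnorm(D * L), D, L)
    w <- rnorm(D)
    ap <- attention_pool(H, V, w)
    expect_equal(sum(ap$a), 1, tolerance = 1e-6)
    expect_true(all(ap$a > 0 & ap$a < 1 + 1e-12))
    lo <- apply(H, 2, min)
    hi <- apply(H, 2, max)
    expect_true(all(ap$z >= lo - 1e-9 & ap$z <= hi + 1e-9))
  }
})

test_that("bag probability is invariant to instance permutation", {
  set.seed(44)
  spec <- backbone_spec("lenet_like", 64, feature_dim = 15)
  params <- rand_mil_params(spec, D = 6L, seed = 44)
  X <- array(runif(64 * 64 * 3 * 5), c(64, 64, 3, 5))
  fwd <- ns$mil_forward(params, spec, "admil", X)
  for (i in 1:5) {
    perm <- sample(5)
    fwd_p <- ns$mil_forward(params, spec, "admil", X[, , , perm, drop = FALSE])
    expect_equal(fwd_p$p, fwd$p, tolerance = 1e-6)
    expect_equal(fwd_p$a, fwd$a[perm], tolerance = 1e-6)
  }
})

test_that("the sigmoid head behaves as specified", {
  expect_equal(classify_bag(c(1, 2), u = c(0, 0), b = 0), 0.5)
  expect_equal(classify_bag(c(2, 1), u = c(1, -1), b = 0), plogis(1))
  expect_equal(classify_bag(c(2, 1), u = c(1, -1), b = 0), 0.7311, tolerance = 1e-4)
  expect_gt(classify_bag(100, u = 10, b = 0), 1 - 1e-12)
  expect_error(classify_bag(c(1, 2, 3), u = c(1, 2), b = 0), "lengths differ")
})

test_that("attention pooling gradients match finite differences", {
  set.seed(55)
  K <- 6; L <- 4; D <- 3
  H <- matrix(rnorm(K * L), K, L)
  V <- matrix(rnorm(D * L), D, L)
  w <- rnorm(D)
  dz <- rnorm(L)
  pool <- attention_pool(H, V, w)
  gr <- ns$attention_pool_backward(H, V, w, pool, dz)
  fn <- function(H, V, w) sum(attention_pool(H, V, w)$z * dz)
  eps <- 1e-6
  for (i in seq_along(V)) {
    Vp <- V; Vp[i] <- Vp[i] + eps
    Vm <- V; Vm[i] <- Vm[i] - eps
    expect_equal(gr$dV[i], (fn(H, Vp, w) - fn(H, Vm, w)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    expect_equal(gr$dw[i], (fn(H, V, wp) - fn(H, V, wm)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in sample(seq_along(H), 10)) {
    Hp <- H; Hp[i] <- Hp[i] + eps
    Hm <- H; Hm[i] <- Hm[i] - eps
    expect_equal(gr$dH[i], (fn(Hp, V, w) - fn(Hm, V, w)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("end-to-end gradients agree with directional finite differences", {
  set.seed(66)
  for (bk in c("lenet_like", "resnet_like", "densenet_like")) {
    spec <- backbone_spec(bk, 64, feature_dim = 12)
    params <- ns$init_mil_params(spec, 4)
    X <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
    y <- 1
    fwd <- ns$mil_forward(params, spec, "admil", X)
    genv <- new.env(); genv$g <- list()
    ns$mil_backward(params, spec, "admil", X, fwd, y, genv)
    d <- lapply(params, function(p) {
      dd <- rnorm(length(p))
      if (!is.null(dim(p))) dim(dd) <- dim(p)
      dd
    })
    gd <- sum(vapply(names(genv$g), function(n) sum(genv$g[[n]] * d[[n]]), 0))
    eps <- 1e-3
    lossfn <- function(pp) ns$bce_loss(ns$mil_forward(pp, spec, "admil", X)$p, y)
    shift <- function(s) {
      pp <- params
      for (n in names(pp)) pp[[n]] <- pp[[n]] + s * eps * d[[n]]
      pp
    }
    num <- (lossfn(shift(1)) - lossfn(shift(-1))) / (2 * eps)
    # single-precision conv activations + ReLU kinks limit the attainable
    # finite-difference agreement; 5% catches wiring errors, not noise
    expect_equal(gd, num, tolerance = 5e-2, label = bk)
  }
})
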