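test_that("2PL probabilities hit the logistic landmarks and stay stable", {
  expect_equal(prob_dichotomous(0, 1, 0), 0.5)
  expect_equal(prob_dichotomous(log(.62 / .38), 1, 0), 0.62)
  expect_equal(prob_dichotomous(1000, 1, 0), 1)      # no overflow
  expect_equal(prob_dichotomous(-1000, 1, 0), 0)
  expect_error(prob_dichotomous(0, -1, 0), class = "hatcat_domain_error")
  # strictly increasing in theta
  th <- seq(-6, 6, by = 0.1)
  expect_true(all(diff(prob_dichotomous(th, 1.3, 0.4)) > 0))
})

test_that("GPCM category probabilities normalize and reduce to the 2PL", {
  set.seed(11)
  for (rep in 1:20) {
    a <- rlnorm(1, 0, .3); b <- rnorm(1); st <- rnorm(3, 0, .6)
    p <- prob_polytomous(rnorm(1), a, b, st)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  # a 2-category GPCM is a 2PL; note the difficulty scale differs between
  # the two forms: GPCM centers a(theta - b), the 2PL uses a*theta - b
  th <- 0.7
  expect_equal(prob_polytomous(th, 1.3, 0.4, 0)[2],
               prob_dichotomous(th, 1.3, 1.3 * 0.4))
  # symmetric steps around theta = b give a symmetric category profile
  p <- prob_polytomous(0.4, 1.1, 0.4, c(0.5, -0.5))
  expect_equal(p[1], p[3], tolerance = 1e-12)
  expect_error(prob_polytomous(0, 1, 0, numeric(0)),
               class = "hatcat_domain_error")
})

test_that("Fisher information matches its definitions for both models", {
  it <- list(model = "2PL", a = 2, b = 0, steps = numeric(0))
  expect_equal(fisher_information(it, 0), 2^2 * 0.25)  # P = Q = 1/2
  th <- c(-1.3, 0.2, 2)
  p <- prob_dichotomous(th, 1, 0.5)
  expect_equal(fisher_information(list(model = "2PL", a = 1, b = 0.5), th),
               p * (1 - p))
  # polytomous: a^2 Var(X) by explicit category summation
  a <- 1.2; b <- -0.3; st <- c(0.6, -0.2); th <- 0.9
  pr <- prob_polytomous(th, a, b, st)
  ex <- sum(pr * 0:2); ex2 <- sum(pr * (0:2)^2)
  expect_equal(
    fisher_information(list(model = "GPCM", a = a, b = b, steps = st), th),
    a^2 * (ex2 - ex^2))
  # 2PL information peaks at theta = b/a (grid search)
  g <- seq(-4, 4, by = 1e-3)
  inf <- fisher_information(list(model = "2PL", a = 1.6, b = 0.8,
                                 steps = numeric(0)), g)
  expect_equal(g[which.max(inf)], 0.8 / 1.6, tolerance = 1e-6 + 1e-3)
})

test_that("RP shift is the scaled log-odds of the target probability", {
  expect_equal(rp_shift(1, 0.5), 0)
  expect_equal(rp_shift(1, 0.62), log(0.62 / 0.38))   # ~0.4895482
  expect_equal(rp_shift(2, 0.62), rp_shift(1, 0.62) / 2)
  expect_error(rp_shift(1, 1), class = "hatcat_domain_error")
  expect_error(rp_shift(0, 0.62), class = "hatcat_domain_error")
})

test_that("shifted information equals information at the shifted point", {
  set.seed(21)
  pool <- random_pool(6, 2, prop_poly = 0.3)
  th <- 0.3
  for (i in seq_len(nrow(pool$items))) {
    it <- pool$items[i, ]
    expect_equal(shifted_information(it, th, rp_config(0.5)),
                 fisher_information(it, th))
    d <- log(0.62 / 0.38) / it$a
    expect_equal(shifted_information(it, th, rp_config(0.62)),
                 fisher_information(it, th - d))
    expect_gte(shifted_information(it, th, rp_config(0.8)), 0)
  }
  # ranking by shifted information equals grid-evaluated ranking
  infos <- pool_information(pool$items, th, rp = 0.62)
  brute <- sapply(seq_len(nrow(pool$items)), function(i) {
    it <- pool$items[i, ]
    fisher_information(it, th - log(0.62 / 0.38) / it$a)
  })
  expect_equal(order(infos), order(brute))
})

test_that("a 2PL item peaking at the shifted point has RP success at theta-hat", {
  theta_hat <- 0.3; a <- 1.4
  delta <- rp_shift(a, 0.62)
  b <- a * (theta_hat - delta)           # information peak at theta_hat - delta
  expect_equal(prob_dichotomous(theta_hat, a, b), 0.62, tolerance = 1e-12)
})

test_that("EAP reproduces the prior without data and respects the likelihood", {
  e0 <- estimate_theta(NULL, integer(0))
  expect_equal(e0$value, 0, tolerance = 1e-3)
  expect_equal(e0$se, 1, tolerance = 2e-3)   # grid-truncation only
  expect_identical(e0$n_responses, 0L)
  one <- tiny_pool()$items[1, ]
  e1 <- estimate_theta(one, 1L)
  expect_gt(e1$value, 0)
  e1w <- estimate_theta(one, 0L)
  expect_lt(e1w$value, 0)
})

test_that("EAP is invariant to response ordering", {
  set.seed(31)
  pool <- random_pool(10, 2, prop_poly = 0.2)
  items <- pool$items
  scores <- vapply(seq_len(nrow(items)), function(i)
    simulate_response(items[i, ], 0.5), integer(1))
  perm <- sample(nrow(items))
  e1 <- estimate_theta(items, scores)
  e2 <- estimate_theta(items[perm, ], scores[perm])
  expect_equal(e1$value, e2$value, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
})

test_that("MLE flags all-correct patterns; EAP recovers a true ability", {
  pool <- tiny_pool()
  dich <- pool$items[pool$items$model == "2PL", ]
  expect_error(estimate_theta(dich, rep(1L, nrow(dich)), method = "MLE"),
               class = "hatcat_mle_nonfinite")
  m <- estimate_theta(dich, c(1L, 0L, 1L, 0L, 1L), method = "MLE")
  expect_true(is.finite(m$value))
  # recovery: 36 wide-pool responses at true theta = 1, EAP within 3 se
  set.seed(41)
  wide <- random_pool(18, 2)
  hits <- 0L
  for (r in 1:200) {
    scores <- vapply(seq_len(36), function(i)
      simulate_response(wide$items[i, ], 1), integer(1))
    e <- estimate_theta(wide$items, scores)
    if (abs(e$value - 1) <= 3 * e$se) hits <- hits + 1L
  }
  expect_gte(hits, 190)   # ~99.7% nominal coverage, wide margin
})

test_that("EAP bias shrinks toward zero as tests lengthen", {
  set.seed(51)
  pool <- random_pool(30, 2)
  bias_at <- function(n_items, theta_true) {
    err <- replicate(150, {
      idx <- seq_len(n_items)
      sc <- vapply(idx, function(i)
        simulate_response(pool$items[i, ], theta_true), integer(1))
      estimate_theta(pool$items[idx, ], sc)$value - theta_true
    })
    mean(err)
  }
  b12 <- bias_at(12, 2); b36 <- bias_at(36, 2)
  expect_lt(abs(b36), abs(b12))  # shrinkage decreases with test length
})
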