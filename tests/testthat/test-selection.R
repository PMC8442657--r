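test_that("screening finds a perfect marginal association first", {
  set.seed(11)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- 2 * X[, 7]
  sel <- sis_screen(X, y, "gaussian", d = 1)
  expect_identical(sel$selected, 7L)
  # d = p returns everything (subject to no cap binding)
  sel_all <- sis_screen(X, y, "gaussian", d = 12, max_size = 12)
  expect_identical(sel_all$selected, 1:12)
  expect_error(sis_screen(X, y, "gaussian", d = 60), "must be < n2")
})

test_that("selection results are deterministic, capped, and intercept-free", {
  set.seed(12)
  X <- matrix(rnorm(90 * 40), 90, 40)
  y <- rbinom(90, 1, plogis(X[, 3]))
  s1 <- sis_screen(X, y, "binomial")
  s2 <- sis_screen(X, y, "binomial")
  expect_identical(s1$selected, s2$selected)
  expect_true(all(s1$selected >= 1 & s1$selected <= 40))
  expect_lte(length(s1$selected), floor(90 / 3))
  expect_false(any(duplicated(s1$selected)))
  set.seed(5); l1 <- lasso_select(X, y, "binomial")
  set.seed(5); l2 <- lasso_select(X, y, "binomial")
  expect_identical(l1$selected, l2$selected)
})

test_that("penalized selectors capture a strong signal and honour the cap", {
  set.seed(13)
  hits <- 0L
  for (rep in 1:20) {
    X <- matrix(rnorm(150 * 50), 150, 50)
    y <- drop(5 * X[, 17] + rnorm(150))
    # confirm signal strength independently: OLS slope near 5
    expect_gt(abs(oracle_ols(X[, 17, drop = FALSE], y)[2]), 3)
    hits <- hits + (17L %in% lasso_select(X, y, "gaussian")$selected)
  }
  expect_gte(hits, 19L)
  # all-noise response: contract only (bounded size, no crash)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rnorm(80)
  for (f in list(lasso_select, elastic_net_select, scad_select, mcp_select)) {
    s <- suppressWarnings(f(X, y, "gaussian"))
    expect_lte(length(s$selected), floor(80 / 3))
    expect_gte(length(s$selected), 1L)
  }
})

test_that("elastic net at mixing 1 reduces to the lasso on shared folds", {
  set.seed(14)
  X <- matrix(rnorm(100 * 30), 100, 30)
  y <- drop(X[, c(2, 9)] %*% c(2, -1.5) + rnorm(100))
  set.seed(99); a <- lasso_select(X, y, "gaussian")
  set.seed(99); b <- elastic_net_select(X, y, "gaussian", mixing = 1)
  expect_identical(a$selected, b$selected)
})

test_that("all selectors pick up one strong orthogonal-design signal", {
  set.seed(15)
  X <- matrix(rnorm(120 * 25), 120, 25)
  y <- drop(3 * X[, 5] + rnorm(120))
  for (nm in c("sis", "lasso", "elasticnet", "scad", "mcp")) {
    sel <- ssglm:::make_selector(nm)(X, y, "gaussian", 8L)
    expect_true(5L %in% sel$selected)
  }
})

test_that("concave penalties select smaller models than the lasso", {
  set.seed(16)
  d <- realize_design(example_design("example2"), 3)
  sizes <- sapply(1:6, function(k) {
    sim <- simulate_dataset(d, seed = 100 + k)
    idx <- sample(300, 150)
    set.seed(k)
    nl <- length(lasso_select(sim$X[idx, ], sim$y[idx], "poisson",
                              max_size = 400)$selected)
    set.seed(k)
    ns <- length(scad_select(sim$X[idx, ], sim$y[idx], "poisson",
                             max_size = 400)$selected)
    set.seed(k)
    nm <- length(mcp_select(sim$X[idx, ], sim$y[idx], "poisson",
                            max_size = 400)$selected)
    c(nl, ns, nm)
  })
  expect_lt(mean(sizes[2, ]), mean(sizes[1, ]))
  expect_lt(mean(sizes[3, ]), mean(sizes[1, ]))
})

test_that("default screening contains the true poisson active set reliably", {
  # sure-screening proxy on the n = 400, p = 500, s0 = 6 poisson design
  d <- realize_design(example_design("example3", corr = "identity"), 21)
  ok <- sapply(1:60, function(k) {
    sim <- simulate_dataset(d, seed = 7000 + k)
    set.seed(k)
    idx <- sample(400, 200)
    all(d$active_set %in%
          sis_screen(sim$X[idx, ], sim$y[idx], "poisson")$selected)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("strong poisson signals survive conventional-size screening", {
  # predictors with |beta| >= 0.8 in the n = 300 poisson design are kept
  # essentially always at d = floor(n2 / log(n2))
  d <- realize_design(example_design("example2"), 9)
  strong <- d$active_set[d$coef_values >= 0.8]
  caps <- sapply(1:40, function(k) {
    sim <- simulate_dataset(d, seed = 3000 + k)
    set.seed(k)
    idx <- sample(300, 150)
    S <- sis_screen(sim$X[idx, ], sim$y[idx], "poisson",
                    d = floor(150 / log(150)), max_size = 50)$selected
    all(strong %in% S)
  })
  expect_gte(mean(caps), 0.95)
})
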