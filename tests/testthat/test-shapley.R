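# The brute-force coalition enumeration is the module's oracle: its axioms
# are checked on analytic models, and the fast tree pass is checked against
# it on real forests.

test_that("exact Shapley values satisfy the dummy and symmetry axioms", {
  bg <- matrix(runif(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  # dummy: a feature the model ignores gets exactly zero
  f_ignore <- function(X) 2 * X[, "a"] + X[, "b"]
  at <- exact_shapley(f_ignore, c(a = 1, b = 2, c = 3, d = 4), bg)
  expect_equal(unname(at$phi["c"]), 0)
  expect_equal(unname(at$phi["d"]), 0)
  # symmetry: exchangeable features with equal values get equal credit
  bg_sym <- bg; bg_sym[, "b"] <- bg_sym[, "a"]
  f_sym <- function(X) X[, "a"] + X[, "b"] + 0.1 * X[, "c"]
  at2 <- exact_shapley(f_sym, c(a = 2, b = 2, c = 1, d = 0), bg_sym)
  expect_equal(unname(at2$phi["a"]), unname(at2$phi["b"]))
  # efficiency
  expect_equal(at2$base_value + sum(at2$phi), at2$prediction)
})

test_that("exact Shapley matches the closed form for additive models", {
  set.seed(4)
  bg <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  g1 <- function(v) v^2
  g2 <- function(v) 3 * v
  g3 <- function(v) sin(v)
  f <- function(X) g1(X[, 1]) + g2(X[, 2]) + g3(X[, 3])
  inst <- c(x1 = 1.3, x2 = -0.4, x3 = 2)
  at <- exact_shapley(f, inst, bg)
  # for f = sum g_i(x_i) under the interventional value function:
  # phi_i = g_i(instance_i) - mean(g_i over background)
  expect_equal(unname(at$phi["x1"]), g1(1.3) - mean(g1(bg[, 1])))
  expect_equal(unname(at$phi["x2"]), g2(-0.4) - mean(g2(bg[, 2])))
  expect_equal(unname(at$phi["x3"]), g3(2) - mean(g3(bg[, 3])))
})

test_that("tree attribution equals brute-force enumeration on a real forest", {
  set.seed(7)
  n <- 300
  d <- data.frame(a = runif(n), b = runif(n), c = runif(n),
                  d = runif(n), e = sample(0:1, n, TRUE))
  d$y <- 2 * d$a + sin(3 * d$b) + d$c * d$e + rnorm(n, 0, 0.05)
  rf <- ranger::ranger(y = d$y, x = d[, 1:5], num.trees = 30, seed = 1,
                       num.threads = 1)
  X <- d[1:20, 1:5]
  B <- d[51:100, 1:5]
  ts <- tree_shap(rf, X, B)
  pf <- function(M) predict(rf, as.data.frame(M),
                            num.threads = 1)$predictions
  for (i in c(1, 5, 12, 20)) {
    ex <- exact_shapley(pf, unlist(X[i, ]), B)
    expect_lt(max(abs(ex$phi - ts$phi[i, ])), 1e-6)
  }
  # additivity per instance against the ensemble's own predictions
  expect_lt(max(abs(ts$base_value + rowSums(ts$phi) - pf(X))), 1e-6)
  # base value is the mean background prediction
  expect_equal(ts$base_value, mean(pf(B)), tolerance = 1e-9)
})

test_that("grouping sums member attributions and preserves additivity", {
  qm <- quick_model()
  rows <- qm$split$test[1:10, ]
  bg <- qm$split$train[1:40, ]
  shap <- tree_shap(qm$m, rows, bg)
  # singleton groups reproduce the input
  singles <- as.list(shap$feature_names)
  names(singles) <- shap$feature_names
  g1 <- group_attributions(shap, singles)
  expect_equal(unname(g1$phi), unname(shap$phi))
  # one big group carries the whole deviation from the base value
  g2 <- group_attributions(shap, list(all = shap$feature_names))
  expect_equal(as.vector(g2$phi), shap$prediction - shap$base_value,
               tolerance = 1e-9)
  # default grouping: sums match hand-added members, additivity preserved
  g3 <- group_attributions(shap)
  expect_equal(g3$phi[, "charge"],
               shap$phi[, "charge"] + shap$phi[, "delta_charge"])
  expect_equal(g3$base_value + rowSums(g3$phi), shap$prediction,
               tolerance = 1e-9)
  expect_error(group_attributions(shap, list(a = "log_daa")), "missing")
  expect_error(group_attributions(shap, c(singles, list(dup = "log_daa"))),
               "more than one")
})

test_that("importance summaries reduce attributions as documented", {
  fake <- structure(list(
    phi = matrix(c(2, -4, 0.5, 0.1), 2, 2,
                 dimnames = list(NULL, c("g1", "g2"))),
    base_value = 0, prediction = c(1, 1), feature_names = c("g1", "g2")),
    class = "shap_values")
  imp <- importance_summary(fake, c(10, 700))
  expect_equal(imp$global$mean_abs[imp$global$group == "g1"], 3)  # (2+4)/2
  first_bin <- subset(imp$per_interval, bin_lo == 0 & group == "g1")
  expect_equal(first_bin$max_abs, 2)
  third_bin <- subset(imp$per_interval, bin_lo == 500 & group == "g1")
  expect_equal(third_bin$max_abs, 4)
  expect_true(all(is.na(subset(imp$per_interval, bin_lo == 50)$max_abs)))
  # single instance: mean equals max
  imp1 <- importance_summary(structure(list(
    phi = fake$phi[1, , drop = FALSE], base_value = 0, prediction = 1,
    feature_names = c("g1", "g2")), class = "shap_values"), 10)
  expect_equal(imp1$global$mean_abs,
               subset(imp1$per_interval, bin_lo == 0)$max_abs)
})

test_that("explanation sampling is seeded and spans the target range", {
  tbl <- data.frame(delta_t = exp(seq(log(5), log(2500), length.out = 5000)))
  tbl$log_delta_t <- log1p(tbl$delta_t)
  s1 <- sample_for_explanation(tbl, 100, seed = 3)
  expect_equal(nrow(s1), 100)
  expect_identical(s1, sample_for_explanation(tbl, 100, seed = 3))
  # every target decile is represented
  dec <- cut(tbl$log_delta_t, quantile(tbl$log_delta_t, seq(0, 1, 0.1)),
             include.lowest = TRUE)
  got <- cut(s1$log_delta_t, quantile(tbl$log_delta_t, seq(0, 1, 0.1)),
             include.lowest = TRUE)
  expect_setequal(levels(dec), unique(as.character(got)))
  # asking for at least the table size returns the table
  expect_identical(sample_for_explanation(tbl, nrow(tbl), seed = 1), tbl)
  expect_warning(out <- sample_for_explanation(tbl[1:5, ], 10, seed = 1),
                 "fewer")
  expect_equal(nrow(out), 5)
})
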