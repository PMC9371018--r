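test_that("hamming_distance counts differing positions", {
  a <- c(1, 0, 1, 1, 0)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, 1 - a), 5)
  set.seed(6)
  for (i in 1:10) {
    x <- rbinom(24, 1, 0.5); y <- rbinom(24, 1, 0.5)
    expect_equal(hamming_distance(x, y), sum(vapply(1:24, function(p)
      as.integer(x[p] != y[p]), 1L)))
  }
  expect_error(hamming_distance(a, a[-1]), "length")
})

test_that("mode imputation fills the strict mode and breaks ties by domain order", {
  schema <- cat_schema(list(list(name = "A", domain = c("a", "b")),
                            list(name = "cls", domain = c("p", "q"),
                                 role = "class")))
  tab <- discrete_table(data.frame(A = c("a", "a", "b", NA),
                                   cls = c("p", "q", "p", "q")), schema)
  expect_equal(impute_mode(tab)$data$A[4], "a")
  tie <- discrete_table(data.frame(A = c("a", "b", NA),
                                   cls = c("p", "q", "p")), schema)
  expect_equal(impute_mode(tie)$data$A[3], "a")
  # fully missing attribute is unimputable
  allmiss <- discrete_table(data.frame(A = c(NA, NA), cls = c("p", "q")),
                            schema)
  expect_error(impute_mode(allmiss), "no observed values")
})

test_that("random imputation follows the observed frequency law and is seeded", {
  schema <- cat_schema(list(list(name = "A", domain = c("a", "b")),
                            list(name = "cls", domain = c("p", "q"),
                                 role = "class")))
  df <- data.frame(A = c(rep("a", 70), rep("b", 30), rep(NA, 10000)),
                   cls = rep(c("p", "q"), 5050))
  tab <- discrete_table(df, schema)
  f1 <- impute_random(tab, seed = 4)
  f2 <- impute_random(tab, seed = 4)
  expect_identical(f1$data, f2$data)
  fills <- f1$data$A[101:10100]
  expect_equal(mean(fills == "a"), 0.7, tolerance = 0.02)
  # single observed category -> that category always
  one <- discrete_table(data.frame(A = c("b", NA, NA), cls = c("p", "q", "p")),
                        schema)
  expect_true(all(impute_random(one, seed = 1)$data$A == "b"))
})

test_that("hot-deck copies from the nearest complete row, ties to the lowest donor index", {
  schema <- cat_schema(list(
    list(name = "A1", domain = c("a", "b")),
    list(name = "A2", domain = c("x", "y")),
    list(name = "A3", domain = c("s", "t")),
    list(name = "cls", domain = c("p", "q"), role = "class")))
  df <- data.frame(A1 = c("a", "b", "a"), A2 = c("x", "y", "x"),
                   A3 = c("s", "t", NA), cls = c("p", "q", "p"))
  tab <- discrete_table(df, schema)
  # row 3 matches donor row 1 exactly on observed attrs -> copies its A3
  expect_equal(impute_hotdeck(tab)$data$A3[3], "s")
  # two equidistant donors -> the lower-index one
  # row 3 disagrees with donor 1 only on A3 and with donor 2 only on A2,
  # so both donors sit at Hamming distance 2; the tie goes to donor 1
  df2 <- data.frame(A1 = c("a", "b", NA), A2 = c("x", "y", "x"),
                    A3 = c("s", "t", "t"), cls = c("p", "p", "p"))
  tab2 <- discrete_table(df2, schema)
  expect_equal(impute_hotdeck(tab2)$data$A1[3], "a")
})

test_that("mode, hot-deck and knn match brute-force oracles on random tables", {
  for (s in 1:12) {
    tab <- random_table(sample(15:50, 1), sample(3:6, 1), miss_frac = 0.15,
                        seed = 300 + s)
    if (!any(missing_mask(tab))) next
    if (nrow(split_by_completeness(tab)$dcom$data) == 0) next
    expect_identical(impute_mode(tab)$data, oracle_mode(tab)$data)
    expect_identical(impute_hotdeck(tab)$data, oracle_hotdeck(tab)$data)
    expect_identical(impute_knn(tab, k = 5)$data, oracle_knn(tab, 5)$data)
    expect_valid_imputation(impute_knn(tab, k = 3), tab)
  }
})

test_that("knn with k = 1 is hot-deck on every table", {
  for (s in 1:8) {
    tab <- random_table(30, 4, miss_frac = 0.2, seed = 400 + s)
    if (nrow(split_by_completeness(tab)$dcom$data) == 0) next
    expect_identical(impute_knn(tab, k = 1)$data, impute_hotdeck(tab)$data)
  }
})

test_that("knn with all donors at equal distance reduces to the donor mode", {
  schema <- cat_schema(list(
    list(name = "A1", domain = c("a", "b")),
    list(name = "A2", domain = c("x", "y", "z")),
    list(name = "cls", domain = c("p", "q"), role = "class")))
  # the incomplete row observes nothing among features except cls = p;
  # all donors share cls = p, so all distances are 0
  df <- data.frame(A1 = c("a", "a", "b", NA),
                   A2 = c("x", "x", "y", NA),
                   cls = c("p", "p", "p", "p"))
  tab <- discrete_table(df, schema)
  filled <- impute_knn(tab, k = 3)
  expect_equal(filled$data$A1[4], "a")  # donor mode
  expect_equal(filled$data$A2[4], "x")
})

test_that("learner-backed imputation trains one model per (type, attribute)", {
  # constant target column -> any learner fills the constant
  schema <- cat_schema(list(
    list(name = "A1", domain = c("a", "b")),
    list(name = "A2", domain = c("x", "y")),
    list(name = "cls", domain = c("p", "q"), role = "class")))
  df <- data.frame(A1 = c("a", "b", "a", "b", NA),
                   A2 = c("x", "x", "x", "x", "x"),
                   cls = c("p", "q", "p", "q", "p"))
  tab <- discrete_table(df, schema)
  filled <- impute_learner(tab, stub_majority_learner())
  expect_valid_imputation(filled, tab)
  # majority stub learner is mode imputation restricted to the type rows
  tab2 <- random_table(40, 4, miss_frac = 0.15, seed = 77)
  f_stub <- impute_learner(tab2, stub_majority_learner())
  # the stub's majority is computed over complete rows only
  parts <- split_by_completeness(tab2)
  m <- missing_mask(tab2)
  for (j in 1:4) {
    if (!any(m[, j])) next
    dom <- tab2$schema$attributes[[j]]$domain
    counts <- table(factor(parts$dcom$data[[j]], levels = dom))
    expect_true(all(f_stub$data[[j]][m[, j]] == names(counts)[which.max(counts)]))
  }
})

test_that("a tree learner recovers an exactly copied attribute", {
  skip_if_not_installed("rpart")
  set.seed(55)
  schema <- cat_schema(list(
    list(name = "A1", domain = c("a", "b", "c")),
    list(name = "A2", domain = c("x", "y", "z")),
    list(name = "cls", domain = c("p", "q"), role = "class")))
  a1 <- sample(c("a", "b", "c"), 120, TRUE)
  df <- data.frame(A1 = a1, A2 = c("x", "y", "z")[match(a1, c("a", "b", "c"))],
                   cls = sample(c("p", "q"), 120, TRUE))
  df$A2[sample(120, 25)] <- NA
  tab <- discrete_table(df, schema)
  filled <- impute_learner(tab, learner_rpart(seed = 1))
  m <- missing_mask(tab)[, 2]
  expect_true(all(filled$data$A2[m] ==
                    c("x", "y", "z")[match(a1[m], c("a", "b", "c"))]))
})

test_that("autoencoder imputation replaces only the originally missing blocks", {
  tab <- random_table(40, 4, miss_frac = 0.15, seed = 88)
  cfg <- train_config(epochs = 30, seed = 2)
  filled <- impute_autoencoder(tab, cfg)
  expect_valid_imputation(filled, tab)
  # complete table returned unchanged
  comp <- random_table(15, 3, seed = 89)
  expect_identical(impute_autoencoder(comp, cfg)$data, comp$data)
})

test_that("autoencoder exploits attribute redundancy better than the mode", {
  # A2 duplicates A1, so the masked A2 cells are exactly recoverable
  accs <- vapply(1:3, function(s) {
    base <- gen_functional(200, domain_size = 3, noise = 0, seed = s)
    amp <- ampute(base, ampute_config("MCAR", 0.2, targets = 2L,
                                      seed = s + 50))
    cfg <- train_config(epochs = 400, batch_size = 64, seed = s)
    ae <- impute_autoencoder(amp, cfg)
    mode_fill <- impute_mode(amp)
    fill_accuracy(base, amp, ae) - fill_accuracy(base, amp, mode_fill)
  }, 0)
  expect_true(mean(accs) > 0)
})

test_that("all imputers satisfy the closure contract on a shared fixture", {
  tab <- random_table(30, 4, miss_frac = 0.2, seed = 91)
  cfg <- train_config(epochs = 20, seed = 3)
  reg <- imputer_registry(c("mode", "random", "hotdeck", "knn",
                            "autoencoder", "mlp", "imlp"), config = cfg)
  for (nm in names(reg)) {
    filled <- reg[[nm]](tab, "MCAR", 5)
    expect_valid_imputation(filled, tab)
  }
})
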