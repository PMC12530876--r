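test_that("mape and r2 reproduce hand-computed examples and guard their domains", {
  expect_equal(mape(100, 110), 0.10)
  expect_equal(mape(c(200, 400), c(180, 440)), 0.10)
  expect_identical(mape(c(3, 5), c(3, 5)), 0)
  expect_error(mape(c(0, 1), c(1, 1)), "zero")
  expect_error(mape(1:3, 1:2), "equal length")
  expect_identical(r2_score(1:3, 1:3), 1)
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(r2_score(c(1, 2, 3), rep(2, 3)), 0)
  expect_error(r2_score(c(2, 2), c(1, 3)), "constant")
})

test_that("linear and polynomial families recover their own function classes exactly", {
  pts <- make_sobol(feasible_space(), 6)
  X <- as.matrix(pts)
  lin <- toy_dataset(pts, function(X)
    700 + 100 * X[, 1] - 50 * X[, 2] + 20 * X[, 3] + 10 * X[, 4])
  m <- train_surrogate(model_spec("linear"), lin)
  expect_lt(mape(lin$density, predict(m, lin)), 1e-8)
  expect_gt(r2_score(lin$density, predict(m, lin)), 1 - 1e-8)
  quad <- toy_dataset(pts, function(X)
    600 + 50 * X[, 1] + 80 * X[, 2] * X[, 3] + 30 * X[, 4]^2)
  mq <- train_surrogate(model_spec("polynomial", degree = 2), quad)
  expect_lt(max(abs(predict(mq, quad) - quad$density)), 1e-8)
})

test_that("training is deterministic for every stochastic family", {
  ds <- preprocess_dataset(evaluate_samples(make_sobol(feasible_space(), 6),
                                            oracle_config(seed = 8), "d"))
  probe <- make_sobol(feasible_space(), 4, scramble_seed = 3)
  for (spec in list(model_spec("random_forest", ntree = 50, train_seed = 9),
                    model_spec("gaussian_process", kernel = "rq",
                               train_seed = 9),
                    model_spec("fnn", hidden = 8, train_seed = 9))) {
    m1 <- train_surrogate(spec, ds)
    m2 <- train_surrogate(spec, ds)
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
})

test_that("a zero-regularization Gaussian process interpolates its training targets", {
  pts <- make_sobol(feasible_space(), 5)
  smooth <- toy_dataset(pts, function(X)
    100 + 1200 / (1 + exp(6 * ((8 * X[, 1]^3 + 18 * X[, 2]^3) - 0.6) / 0.6)))
  m <- train_surrogate(model_spec("gaussian_process", kernel = "rbf",
                                  gp_noise = 0), smooth)
  rel <- abs(predict(m, smooth) - smooth$density) / abs(smooth$density)
  expect_lt(max(rel), 1e-4)
})

test_that("vectorized prediction equals pointwise prediction and warns off-space", {
  ds <- preprocess_dataset(evaluate_samples(make_sobol(feasible_space(), 6),
                                            oracle_config(seed = 4), "d"))
  m <- train_surrogate(model_spec("random_forest", ntree = 50), ds)
  probe <- make_sobol(feasible_space(), 4, scramble_seed = 1)
  vec <- predict(m, probe)
  pw <- vapply(seq_len(nrow(probe)), function(i)
    predict(m, probe[i, , drop = FALSE]), numeric(1))
  expect_identical(vec, pw)
  outside <- data.frame(sigma_C = 0.4, sigma_H = 0.2, eps_C = 0.5,
                        eps_H = 0.1)
  expect_warning(predict(m, outside), "outside")
})

test_that("forest predictions stay within the training target range", {
  ds <- preprocess_dataset(evaluate_samples(make_sobol(feasible_space(), 7),
                                            oracle_config(seed = 6), "d"))
  m <- train_surrogate(model_spec("random_forest", ntree = 100), ds)
  pr <- predict(m, make_sobol(feasible_space(), 8, scramble_seed = 2))
  expect_gte(min(pr), min(ds$density))
  expect_lte(max(pr), max(ds$density))
})

test_that("polynomial training demands more points than basis functions", {
  pts <- make_sobol(feasible_space(), 4)  # 16 points
  ds <- toy_dataset(pts, function(X) 700 + X[, 1])
  expect_error(train_surrogate(model_spec("polynomial", degree = 4), ds),
               "training points")
})

test_that("every family reaches 2% in-sample error on its own noiseless class at n = 500", {
  sp <- feasible_space()
  pts <- make_sobol(sp, 9)[1:500, ]
  X <- as.matrix(pts)
  smooth_fn <- function(X)
    100 + 1200 / (1 + exp(6 * ((8 * X[, 1]^3 + 18 * X[, 2]^3) - 0.6) / 0.6))
  datasets <- list(
    linear = toy_dataset(pts, function(X)
      700 + 150 * X[, 1] - 90 * X[, 2] + 40 * X[, 3] + 25 * X[, 4]),
    polynomial = toy_dataset(pts, function(X)
      650 + 120 * X[, 1] * X[, 2] - 70 * X[, 3]^2 + 55 * X[, 4]),
    gaussian_process = toy_dataset(pts, smooth_fn),
    fnn = toy_dataset(pts, smooth_fn))
  # forest class: an axis-aligned step function is representable exactly
  datasets$random_forest <- toy_dataset(pts, function(X)
    650 + 150 * (X[, 1] > 0.2) - 80 * (X[, 2] > 0.18) +
      40 * (X[, 3] > 0.65))
  specs <- list(
    linear = model_spec("linear"),
    polynomial = model_spec("polynomial", degree = 2),
    random_forest = model_spec("random_forest", ntree = 250, train_seed = 2),
    gaussian_process = model_spec("gaussian_process", kernel = "rq",
                                  train_seed = 2),
    fnn = model_spec("fnn", hidden = 16, train_seed = 2))
  for (fam in names(specs)) {
    parts <- split_dataset(datasets[[fam]], 0.8, seed = 31)
    m <- train_surrogate(specs[[fam]], parts$train)
    ist <- mape(parts$test$density, predict(m, parts$test))
    expect_lt(ist, 0.02)
  }
})

test_that("over-parameterized polynomials widen the in-to-out-of-sample gap", {
  sp <- feasible_space()
  inner <- parameter_space(sp$names, c(0.0750, 0.0683, 0.2465, 0.0300),
                           c(0.3250, 0.2958, 1.0680, 0.1300))
  pts <- make_sobol(inner, 7)
  X <- as.matrix(pts)
  f <- function(X) 700 + 200 * X[, 1] - 150 * X[, 2] + 90 * X[, 1] * X[, 3] -
    60 * X[, 4]^2
  fresh <- make_sobol(sp, 8, scramble_seed = 5)
  gaps <- vapply(c(2, 3, 4), function(d) {
    mean(vapply(1:10, function(s) {
      y <- f(X) + smaopt:::with_seed(1000 + s, rnorm(nrow(X), 0, 8))
      ds <- density_dataset(data.frame(pts, density = y, valid = TRUE), "t")
      parts <- split_dataset(ds, 0.75, seed = s)
      m <- train_surrogate(model_spec("polynomial", degree = d), parts$train,
                           space = sp)
      yf <- f(as.matrix(fresh)) +
        smaopt:::with_seed(5000 + s, rnorm(nrow(fresh), 0, 8))
      suppressWarnings(
        mape(yf, predict(m, fresh)) -
          mape(parts$test$density, predict(m, parts$test)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("surrogates serialize to a self-describing archive", {
  ds <- preprocess_dataset(evaluate_samples(make_sobol(feasible_space(), 5),
                                            oracle_config(seed = 2), "d"))
  m <- train_surrogate(model_spec("fnn", hidden = 8, train_seed = 4), ds)
  path <- withr::local_tempfile(fileext = ".rds")
  save_surrogate(m, path)
  back <- load_surrogate(path)
  probe <- make_sobol(feasible_space(), 4)
  expect_identical(predict(back, probe), predict(m, probe))
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, junk)
  expect_error(load_surrogate(junk), "surrogate")
})
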