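test_that("ratio enumeration is inclusive with endpoint tolerance", {
  r <- enumerate_ratios(0.05, 0.95, 0.05)
  expect_length(r, 19L)
  expect_equal(r[1], 0.05)
  expect_equal(r[19], 0.95)
  expect_true(all(abs(r / 0.05 - round(r / 0.05)) < 1e-9))
  expect_equal(enumerate_ratios(0.5, 0.5, 0.05), 0.5)
  expect_error(enumerate_ratios(0, 0.9, 0.1), "need 0 <")
  expect_error(enumerate_ratios(0.1, 1.0, 0.1), "need 0 <")
})

test_that("splits partition the dataset reproducibly", {
  ds <- evaluate_samples(make_sobol(feasible_space(), 7)[1:100, ],
                         quiet_oracle(seed = 1), "s")
  parts <- split_dataset(ds, 0.75, seed = 42)
  expect_identical(nrow(parts$train), 75L)
  expect_identical(nrow(parts$test), 25L)
  key <- function(d) paste(d$sigma_C, d$sigma_H, d$eps_C, d$eps_H)
  expect_length(intersect(key(parts$train), key(parts$test)), 0L)
  expect_setequal(c(key(parts$train), key(parts$test)), key(ds))
  expect_identical(split_dataset(ds, 0.75, seed = 42)$train$density,
                   parts$train$density)
  parts2 <- split_dataset(ds, 0.75, seed = 43)
  expect_false(identical(parts$train$density, parts2$train$density))
  expect_error(split_dataset(ds, 0.001, seed = 1), "empty")
})

test_that("IST and OST evaluation respects the partition contracts", {
  sp <- feasible_space()
  cfg <- oracle_config(seed = 9)
  d1 <- preprocess_dataset(evaluate_samples(make_sobol(sp, 6), cfg, "A"))
  d2 <- preprocess_dataset(evaluate_samples(
    make_sobol(sp, 6, scramble_seed = 4), cfg, "B"))
  d3 <- preprocess_dataset(evaluate_samples(
    make_sobol(sp, 6, scramble_seed = 5), cfg, "C"))
  res <- run_ist_ost(model_spec("random_forest", ntree = 50), d1,
                     ratio = 0.75, seed = 3, others = list(d2, d3))
  expect_identical(res$ost$n_eval, nrow(d2) + nrow(d3))
  expect_equal(res$ist$n_eval, nrow(d1) - round(0.75 * nrow(d1)))
  expect_identical(res$ist$mode, "IST")
  expect_identical(res$ost$mode, "OST")
  expect_error(run_ist_ost(model_spec("linear"), d1, 0.75, 3,
                           others = list(d1, d2)), "itself")
})

test_that("a surrogate wrapping the truth keeps OST error at the noise scale", {
  sp <- feasible_space()
  cfg <- oracle_config(noise_sd = 4, failure_prob = 0, rugged_amplitude = 0,
                       seed = 14)
  ds <- preprocess_dataset(evaluate_samples(make_sobol(sp, 7), cfg, "A"))
  other <- preprocess_dataset(evaluate_samples(
    make_sobol(sp, 7, scramble_seed = 8), cfg, "B"))
  # GP with estimated noise recovers the smooth truth; OST MAPE is bounded
  # by a small multiple of the noise-to-signal ratio
  res <- run_ist_ost(model_spec("gaussian_process", kernel = "rq",
                                train_seed = 2),
                     ds, 0.9, 5, others = list(other))
  expect_lt(res$ost$mape, 3 * 4 / 700 + 0.01)
})

test_that("plan counts reproduce the full-scale bookkeeping", {
  plan <- experiment_plan(
    datasets = c("Grid1296", "Grid2401", "Sobol1", "Sobol2"),
    ratios = enumerate_ratios(0.05, 0.95, 0.05),
    seeds_per_ratio = 50,
    family_grids = list(linear = 1, polynomial = 10, random_forest = 6,
                        gaussian_process = 3, fnn = 1))
  counts <- plan_counts(plan)
  expect_identical(counts[["linear"]], 3800L)
  expect_identical(counts[["polynomial"]], 38000L)
  expect_identical(counts[["random_forest"]], 22800L)
  expect_identical(counts[["gaussian_process"]], 11400L)
  expect_identical(counts[["fnn"]], 3800L)
  tiny <- experiment_plan("A", 0.5, 1, list(linear = 1))
  expect_identical(plan_counts(tiny)[["linear"]], 1L)
})

test_that("aggregation matches a brute-force recomputation", {
  set.seed(77)
  res <- expand.grid(family = "linear", hyperparams = "-",
                     dataset = c("A", "B"), ratio = c(0.5, 0.75),
                     seed = 1:5, mode = c("IST", "OST"),
                     stringsAsFactors = FALSE)
  res$mape <- runif(nrow(res), 0.01, 0.2)
  res$r2 <- runif(nrow(res), 0.2, 1)
  agg <- aggregate_metrics(res)
  expect_identical(nrow(agg), 8L)
  expect_true(all(agg$n == 5L))
  for (k in seq_len(nrow(agg))) {
    sel <- res$dataset == agg$dataset[k] & res$ratio == agg$ratio[k] &
      res$mode == agg$mode[k]
    expect_equal(agg$mean_mape[k], mean(res$mape[sel]), tolerance = 1e-12)
    expect_equal(agg$sd_r2[k], sd(res$r2[sel]), tolerance = 1e-12)
  }
  # identical reports collapse to zero spread
  const <- res[res$dataset == "A" & res$ratio == 0.5 & res$mode == "IST", ]
  const$mape <- 0.02; const$r2 <- 0.9
  a2 <- aggregate_metrics(const)
  expect_identical(a2$sd_mape, 0)
  expect_equal(a2$mean_mape, 0.02)
  expect_equal(aggregate_metrics(
    data.frame(const[1:2, 1:6], mape = c(0.01, 0.03),
               r2 = 0.5))$mean_mape, 0.02)
})

test_that("the Welch comparison is symmetric with sane degenerate behavior", {
  a <- c(1.1, 0.9, 1.05, 0.95)
  expect_equal(compare_means(a, a)$p_value, 1, tolerance = 1e-12)
  expect_equal(compare_means(a, a)$statistic, 0, tolerance = 1e-12)
  b <- a + 0.5
  expect_identical(compare_means(a, b)$p_value, compare_means(b, a)$p_value)
  # two n = 50 groups separated by ten standard deviations
  x <- smaopt:::with_seed(5, rnorm(50, 0, 1))
  y <- smaopt:::with_seed(6, rnorm(50, 10, 1))
  expect_lt(compare_means(x, y)$p_value, 1e-6)
  expect_identical(compare_means(rep(2, 3), rep(2, 4))$p_value, 1)
  expect_error(compare_means(1, c(1, 2)), "at least two")
})

test_that("top-k selection handles overlap, ties and duplicates deterministically", {
  # disjoint rankings give 2k, identical rankings give k
  disjoint <- data.frame(id = letters[1:6],
                         mape = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06),
                         r2 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  sel <- select_top(disjoint, 2)
  expect_identical(sel$by_mape, c("a", "b"))
  expect_identical(sel$by_r2, c("f", "e"))
  expect_length(sel$selected, 4L)
  aligned <- data.frame(id = letters[1:6],
                        mape = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06),
                        r2 = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  expect_length(select_top(aligned, 3)$selected, 3L)
  expect_error(select_top(aligned, 7), "between 1")
})

test_that("sobol-trained models degrade less from IST to OST than grid-trained", {
  sp <- feasible_space()
  ocfg <- oracle_config(seed = 1)
  mk <- function(nm, pts) preprocess_dataset(evaluate_samples(pts, ocfg, nm))
  datasets <- list(
    GridA = mk("GridA", make_grid(grid_spec(
      c(0.0750, 0.0683, 0.2465, 0.0300),
      c(0.25, 0.2275, 0.8215, 0.1) / 3,
      c(0.3250, 0.2958, 1.0680, 0.1300)))),
    GridB = mk("GridB", make_grid(grid_spec(
      c(0.0500, 0.0455, 0.1643, 0.0200),
      c(0.30, 0.273, 0.9858, 0.12) / 3,
      c(0.3500, 0.3185, 1.1501, 0.1400)))),
    SobolA = mk("SobolA", make_sobol(sobol1_space(), 8)),
    SobolB = mk("SobolB", make_sobol(sp, 8, scramble_seed = 20)))
  plan <- experiment_plan(
    names(datasets), ratios = seq(0.55, 0.95, 0.1), seeds_per_ratio = 10,
    family_grids = list(polynomial = list(
      model_spec("polynomial", degree = 3),
      model_spec("polynomial", degree = 4))))
  res <- suppressWarnings(run_experiment(plan, datasets, base_seed = 1))
  w <- reshape(res, idvar = c("family", "hyperparams", "dataset", "ratio",
                              "seed"),
               timevar = "mode", direction = "wide")
  w$degr <- w$mape.OST - w$mape.IST
  agg <- aggregate(degr ~ dataset, w, mean)
  sobol_degr <- mean(agg$degr[grepl("Sobol", agg$dataset)])
  grid_degr <- mean(agg$degr[grepl("Grid", agg$dataset)])
  expect_lt(sobol_degr, grid_degr)
})

test_that("flexible nonlinear families out-generalize the linear baseline", {
  sp <- feasible_space()
  cfg <- oracle_config(seed = 9)
  d1 <- preprocess_dataset(evaluate_samples(make_sobol(sp, 7), cfg, "A"))
  d2 <- preprocess_dataset(evaluate_samples(
    make_sobol(sp, 7, scramble_seed = 8), cfg, "B"))
  lin <- run_ist_ost(model_spec("linear"), d1, 0.75, 3, list(d2))
  rf <- run_ist_ost(model_spec("random_forest", ntree = 100, train_seed = 1),
                    d1, 0.75, 3, list(d2))
  gp <- run_ist_ost(model_spec("gaussian_process", kernel = "rq",
                               train_seed = 1), d1, 0.75, 3, list(d2))
  expect_lt(lin$ost$r2, rf$ost$r2)
  expect_lt(lin$ost$r2, gp$ost$r2)
})
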