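test_that("density deviation reproduces table-style signed percentages", {
  expect_equal(err_dens(707.0, 700), 1.0, tolerance = 1e-12)
  expect_identical(err_dens(700, 700), 0)
  expect_equal(round(err_dens(693.2, 700), 1), -1.0)
  expect_error(err_dens(700, 0), "positive")
})

test_that("RCE deviation averages unsigned relative errors and skips zero targets", {
  expect_identical(as.numeric(err_rce(c(1, 2), c(1, 2))), 0)
  expect_equal(as.numeric(err_rce(11, 10)), 10)
  hand <- mean(c(abs(3.3 - 3) / 3, abs(1.8 - 2) / 2, abs(5.5 - 5) / 5)) * 100
  expect_equal(as.numeric(err_rce(c(3.3, 1.8, 5.5), c(3, 2, 5))), hand)
  withzero <- err_rce(c(1, 5), c(0, 4))
  expect_identical(attr(withzero, "n_excluded"), 1L)
  expect_equal(as.numeric(withzero), 25)
  expect_error(err_rce(1, 0), "undefined")
})

test_that("the objective composes its two terms as documented", {
  conf <- make_conformer_fixture(n_conformers = 8, seed = 13)
  targets <- optimization_targets(conf)
  oracle700 <- function(p) 700
  rep0 <- lj_objective(conf$true_params, targets, oracle700)
  expect_equal(rep0$err_dens, 0)
  expect_equal(rep0$err_rce, 0)
  expect_identical(rep0$loss, 0)
  # density-only reduction
  off <- lj_params(0.30, 0.22, 0.5, 0.08)
  d_only <- lj_objective(off, targets, function(p) 710, weights = c(1, 0))
  expect_equal(d_only$loss, (d_only$err_dens / 100)^2, tolerance = 1e-12)
  # the loss recomputes from the report's components
  both <- lj_objective(off, targets, function(p) 710)
  computed <- rce(off, conf)[-1]
  rel <- (computed - target_rce(conf)) / target_rce(conf)
  expect_equal(both$loss, (both$err_dens / 100)^2 + mean(rel^2),
               tolerance = 1e-12)
  expect_error(lj_objective(off, targets, function(p) NaN), "non-finite")
})

test_that("the finite-difference gradient is exact for linear and scales as h^2", {
  f_lin <- function(u) 2 * u[1] - 3 * u[2] + 0.5 * u[3] + u[4]
  g <- num_gradient(f_lin, rep(0.5, 4), 0.01)
  expect_equal(g$grad, c(2, -3, 0.5, 1), tolerance = 1e-8)
  expect_identical(g$n_evals, 8L)
  expect_equal(num_gradient(function(u) 7, rep(0.5, 4))$grad, rep(0, 4))
  # Richardson: halving h quarters the error for a cubic
  f_cub <- function(u) u[1]^3
  err_h <- abs(num_gradient(f_cub, rep(0.5, 4), 0.02)$grad[1] - 3 * 0.25)
  err_h2 <- abs(num_gradient(f_cub, rep(0.5, 4), 0.01)$grad[1] - 3 * 0.25)
  expect_equal(err_h / err_h2, 4, tolerance = 0.05)
  # one-sided fallback near the bounds stays inside the box
  g_edge <- num_gradient(function(u) {
    expect_true(all(u >= 0 & u <= 1)); sum(u)
  }, c(0, 1, 0.5, 0.5), 0.01)
  expect_equal(g_edge$grad, rep(1, 4), tolerance = 1e-6)
})

test_that("optimization terminates immediately at a zero-loss start", {
  conf <- make_conformer_fixture(n_conformers = 8, seed = 13)
  targets <- optimization_targets(conf)
  tr <- optimize_lj(conf$true_params, targets, function(p) 700)
  expect_identical(nrow(tr), 1L)
  expect_identical(attr(tr, "termination"), "already_optimal")
  expect_identical(tr$iter, 0L)
})

test_that("density-only descent on the smooth oracle reaches the target level set", {
  cfg <- quiet_oracle(seed = 1)
  oracle_fn <- function(p) oracle_density(p, cfg, draw_seed = 1)$density
  targets <- optimization_targets(NULL, target_density = 700)
  starts <- perturbed_starts(lj_params(0.34, 0.25, 0.45, 0.09), n = 3,
                             seed = 17)
  for (i in seq_len(3)) {
    tr <- optimize_lj(starts[i, ], targets, oracle_fn,
                      control = opt_control(w_rce = 0, max_iter = 20))
    expect_lte(abs(tr$err_dens[nrow(tr)]), 0.5)
    expect_lte(max(tr$iter), 20)
  }
})

test_that("accepted-iterate losses are non-increasing and evaluations reconcile", {
  cfg <- oracle_config(noise_sd = 0, failure_prob = 0, seed = 2)
  oracle_fn <- function(p) oracle_density(p, cfg, draw_seed = 1)$density
  conf <- make_conformer_fixture(n_conformers = 10, seed = 5)
  targets <- optimization_targets(conf)
  tr <- optimize_lj(perturbed_starts(lj_params(0.34, 0.25, 0.45, 0.09),
                                     n = 1, seed = 3)[1, ],
                    targets, oracle_fn,
                    control = opt_control(max_iter = 40))
  expect_true(all(diff(tr$loss) <= 0))
  expect_true(nrow(tr) >= 2L)
  # per-iteration evaluation counts sum to at most the recorded total
  # (probing iterations that refine the stencil also consume evaluations)
  expect_lte(sum(tr$n_evals), attr(tr, "total_evals"))
  expect_error(optimize_lj(c(sigma_C = 0.5, sigma_H = 0.2, eps_C = 0.5,
                             eps_H = 0.1), targets, oracle_fn),
               "outside")
})

test_that("start perturbation stays inside the box without piling on faces", {
  sp <- feasible_space()
  st <- perturbed_starts(lj_params(0.34, 0.25, 0.45, 0.09), sp, n = 50,
                         seed = 2, spread = 0.2)
  expect_true(all(space_contains(sp, st)))
  expect_identical(st, perturbed_starts(lj_params(0.34, 0.25, 0.45, 0.09),
                                        sp, n = 50, seed = 2, spread = 0.2))
  expect_lt(max(st$sigma_C), sp$upper[1])
  expect_error(perturbed_starts(lj_params(0.45, 0.2, 0.5, 0.1), sp, 3, 1),
               "outside")
})

test_that("verification reports replicate statistics and recomputed errors", {
  conf <- make_conformer_fixture(n_conformers = 8, seed = 13)
  targets <- optimization_targets(conf)
  cfg0 <- quiet_oracle(seed = 6)
  p <- conf$true_params
  vp <- verify_params(p, targets, cfg0, n_rep = 4)
  expect_identical(vp$rho_sim_sd, 0)  # noiseless oracle
  expect_equal(vp$err_rce, 0, tolerance = 1e-12)
  expect_equal(vp$err_dens,
               err_dens(oracle_components(p, cfg0)$smooth, 700),
               tolerance = 1e-9)
  one <- verify_params(p, targets, oracle_config(seed = 6), n_rep = 1)
  expect_identical(one$rho_sim_sd, 0)
  noisy <- verify_params(p, targets, oracle_config(seed = 6), n_rep = 5)
  expect_gt(noisy$rho_sim_sd, 0)
})

test_that("surrogate-assisted and reference optimization agree on the smooth landscape", {
  sp <- feasible_space()
  cfg <- quiet_oracle(seed = 21)
  oracle_fn <- function(p) oracle_density(p, cfg, draw_seed = 1)$density
  ds <- preprocess_dataset(evaluate_samples(make_sobol(sp, 7), cfg, "S"))
  sur <- train_surrogate(model_spec("gaussian_process", kernel = "rq",
                                    train_seed = 3), ds)
  conf <- make_conformer_fixture(n_conformers = 12, seed = 8)
  targets <- optimization_targets(conf)
  p0 <- perturbed_starts(lj_params(0.34, 0.25, 0.45, 0.09), n = 1,
                         seed = 4)[1, ]
  tr_sma <- suppressWarnings(
    optimize_lj(p0, targets, function(p) predict(sur, p), sp))
  tr_ref <- optimize_lj(p0, targets, oracle_fn, sp)
  v_sma <- verify_params(final_params(tr_sma), targets, cfg, n_rep = 1)
  v_ref <- verify_params(final_params(tr_ref), targets, cfg, n_rep = 1)
  expect_lt(abs(v_sma$rho_sim_mean - v_ref$rho_sim_mean) /
              v_ref$rho_sim_mean, 0.02)
})
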