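# Regression surrogates for the density landscape
#
# Five families behind one train/predict contract: linear, polynomial
# (full multivariate monomial basis of total degree d), random forest
# (randomForest), Gaussian process (in-house: RBF / Matern-5/2 / rational-
# quadratic kernels with restarted marginal-likelihood maximization), and
# a feed-forward network (nnet, single hidden layer).  Inputs are
# standardized per dimension for the polynomial, Gaussian-process and
# network families; forests and plain linear fits consume raw values.

#' Mean absolute percentage error
#'
#' `(1/n) * sum(|y - yhat| / |y|)`, reported as a fraction (0.013 means
#' 1.3%).
#'
#' @param y vector of reference values; all entries must be nonzero.
#' @param yhat vector of predictions, same length.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' mape(c(200, 400), c(180, 440))  # 0.10
mape <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L)
    stop("'y' and 'yhat' must have equal length >= 1", call. = FALSE)
  if (any(y == 0))
    stop("MAPE is undefined for zero reference values", call. = FALSE)
  mean(abs(y - yhat) / abs(y))
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @inheritParams mape
#' @return A scalar `<= 1`; negative when predictions are worse than the
#'   mean of `y`.
#' @export
#' @examples
#' r2_score(c(1, 2, 3), c(1, 2, 4))  # 0.5
r2_score <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("'y' and 'yhat' must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("R^2 is undefined for constant reference values", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Specify a surrogate model
#'
#' @param family one of `"linear"`, `"polynomial"`, `"random_forest"`,
#'   `"gaussian_process"`, `"fnn"`.
#' @param degree polynomial total degree, in 1..10.
#' @param ntree forest size; the benchmark grid is
#'   `c(10, 100, 250, 500, 750, 1000)`.
#' @param kernel Gaussian-process kernel: `"rbf"`, `"matern"`
#'   (smoothness 5/2) or `"rq"` (rational quadratic).
#' @param gp_noise observation-noise handling for the Gaussian process:
#'   `NULL` (default) estimates the noise variance by marginal likelihood
#'   together with the kernel hyperparameters; a fixed nonnegative value
#'   (in units of the standardized response variance) pins it, with `0`
#'   giving a near-interpolating fit stabilized by a 1e-6 relative
#'   jitter.
#' @param hidden hidden-layer width of the network.
#' @param decay,maxit network weight decay and optimizer iteration cap.
#' @param train_seed integer seed making stochastic fits (forest
#'   bootstrap, network initialization, Gaussian-process restarts)
#'   reproducible.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("linear", "polynomial", "random_forest",
                                  "gaussian_process", "fnn"),
                       degree = 3L, ntree = 100L, kernel = c("rq", "rbf",
                                                             "matern"),
                       gp_noise = NULL,
                       hidden = 16L, decay = 1e-4, maxit = 2000L,
                       train_seed = 1L) {
  family <- match.arg(family)
  hp <- switch(family,
    linear = list(),
    polynomial = {
      if (degree < 1L || degree != floor(degree))
        stop("polynomial degree must be a positive integer", call. = FALSE)
      list(degree = as.integer(degree))
    },
    random_forest = {
      if (ntree < 1L) stop("'ntree' must be positive", call. = FALSE)
      list(ntree = as.integer(ntree))
    },
    gaussian_process = list(kernel = match.arg(kernel), gp_noise = gp_noise),
    fnn = list(hidden = as.integer(hidden), decay = decay,
               maxit = as.integer(maxit)))
  structure(list(family = family, hyperparameters = hp,
                 train_seed = as.integer(train_seed)),
            class = "model_spec")
}

# compact hyperparameter label for bookkeeping tables
spec_label <- function(spec) {
  hp <- spec$hyperparameters
  switch(spec$family,
    linear = "-",
    polynomial = paste0("d=", hp$degree),
    random_forest = paste0("t=", hp$ntree),
    gaussian_process = paste0("kernel=", hp$kernel),
    fnn = paste0("h=", hp$hidden))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s), train_seed=%d\n", x$family,
              spec_label(x), x$train_seed))
  invisible(x)
}

.param_cols <- c("sigma_C", "sigma_H", "eps_C", "eps_H")

# exponent table of all monomials with 1 <= total degree <= d
monomial_exponents <- function(d, n_var) {
  ex <- as.matrix(expand.grid(rep(list(0:d), n_var)))
  ex <- ex[rowSums(ex) >= 1 & rowSums(ex) <= d, , drop = FALSE]
  ex[order(rowSums(ex)), , drop = FALSE]
}

monomial_design <- function(X, expo) {
  Phi <- matrix(1, nrow(X), nrow(expo))
  for (j in seq_len(ncol(X))) {
    pw <- expo[, j]
    nz <- pw > 0
    if (any(nz))
      Phi[, nz] <- Phi[, nz, drop = FALSE] *
        outer(X[, j], pw[nz], `^`)
  }
  Phi
}

# --- Gaussian process internals --------------------------------------------

# squared distances after per-dimension (ARD) lengthscale weighting
gp_sqdist <- function(A, B, ell = 1) {
  A <- sweep(A, 2L, ell, `/`)
  B <- sweep(B, 2L, ell, `/`)
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, `+`) - 2 * tcrossprod(A, B), 0)
}

# kernels on lengthscale-weighted squared distance
gp_kernel <- function(D2, kernel, sf2, alpha = 1) {
  switch(kernel,
    rbf = sf2 * exp(-D2 / 2),
    matern = {
      r <- sqrt(D2)
      sf2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
    },
    rq = sf2 * (1 + D2 / (2 * alpha))^(-alpha))
}

# hyperparameters: one ARD lengthscale per input dimension, a signal
# variance, the RQ mixture parameter where applicable, and the
# observation-noise variance.  sn2_fixed = NULL (default) estimates the
# noise by marginal likelihood — pseudo-simulated densities are noisy; a
# fixed sn2 (0 for a pure interpolant) falls back to a 1e-6 relative
# jitter for stability.
gp_unpack <- function(theta, d, kernel, sn2_fixed) {
  list(ell = exp(theta[seq_len(d)]),
       sf2 = exp(theta[d + 1L])^2,
       alpha = if (kernel == "rq") exp(theta[d + 2L]) else 1,
       sn2 = if (is.null(sn2_fixed)) exp(theta[length(theta)])^2
             else sn2_fixed)
}

# DK: per-dimension squared-difference matrices, cached across the
# marginal-likelihood evaluations of one fit
gp_weighted_D2 <- function(DK, ell) {
  D2 <- DK[[1]] / ell[1]^2
  for (k in seq_along(DK)[-1]) D2 <- D2 + DK[[k]] / ell[k]^2
  D2
}

gp_neg_loglik <- function(theta, DK, d, y, kernel, sn2_fixed) {
  hp <- gp_unpack(theta, d, kernel, sn2_fixed)
  K <- gp_kernel(gp_weighted_D2(DK, hp$ell), kernel, hp$sf2, hp$alpha)
  diag(K) <- diag(K) + max(hp$sn2, 0) + 1e-6 * hp$sf2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * length(y) * log(2 * pi)
}

gp_fit <- function(X, y, kernel, train_seed, sn2_fixed = NULL,
                   n_restarts = 5L) {
  d <- ncol(X)
  # universal-kriging style linear trend: the stationary kernel then only
  # has to model the residual surface, which extrapolates less badly at
  # the edges of the sampled box
  trend <- stats::lm.fit(cbind(1, X), y)$coefficients
  trend[is.na(trend)] <- 0
  y <- y - drop(cbind(1, X) %*% trend)
  DK <- lapply(seq_len(d), function(k) outer(X[, k], X[, k], `-`)^2)
  n_par <- d + 1L + (kernel == "rq") + is.null(sn2_fixed)
  lower <- c(rep(log(0.05), d), log(0.05),
             if (kernel == "rq") log(0.05),
             if (is.null(sn2_fixed)) log(1e-4))
  upper <- c(rep(log(50), d), log(10),
             if (kernel == "rq") log(20),
             if (is.null(sn2_fixed)) log(1))
  starts <- with_seed(train_seed, {
    s <- matrix(stats::runif(n_restarts * n_par, rep(lower, each = n_restarts),
                             rep(upper, each = n_restarts)),
                nrow = n_restarts)
    s[1, ] <- c(rep(0, d), 0, if (kernel == "rq") 0,
                if (is.null(sn2_fixed)) log(0.1))
    s
  })
  best <- NULL
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], gp_neg_loglik, method = "L-BFGS-B",
                   lower = lower, upper = upper, DK = DK, d = d, y = y,
                   kernel = kernel, sn2_fixed = sn2_fixed,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  hp <- gp_unpack(best$par, d, kernel, sn2_fixed)
  K <- gp_kernel(gp_sqdist(X, X, hp$ell), kernel, hp$sf2, hp$alpha)
  diag(K) <- diag(K) + max(hp$sn2, 0) + 1e-6 * hp$sf2
  L <- chol(K)
  list(X = X, alpha_vec = backsolve(L, forwardsolve(t(L), y)),
       trend = trend, ell = hp$ell, sf2 = hp$sf2, alpha = hp$alpha,
       sn2 = hp$sn2, kernel = kernel)
}

gp_predict <- function(fit, Xnew) {
  D2 <- gp_sqdist(Xnew, fit$X, fit$ell)
  Ks <- gp_kernel(D2, fit$kernel, fit$sf2, fit$alpha)
  drop(Ks %*% fit$alpha_vec) + drop(cbind(1, Xnew) %*% fit$trend)
}

# ----------------------------------------------------------------------------

#' Train a surrogate model
#'
#' Fits the family described by `spec` to a preprocessed density dataset.
#' Training is deterministic given `(spec, data)`: the spec's `train_seed`
#' drives every stochastic ingredient.
#'
#' @param spec a [model_spec()].
#' @param data a `density_dataset` containing only valid records (run
#'   [preprocess_dataset()] first).
#' @param space the feasible [parameter_space()] the model is meant to
#'   cover; predictions outside it trigger a warning.
#' @return An object of class `surrogate_model` with a [predict()] method.
#' @export
train_surrogate <- function(spec, data, space = feasible_space()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("training data must be a nonempty dataset", call. = FALSE)
  if (!is.null(data$valid) && any(!data$valid))
    stop("training data contains invalid records; run preprocess_dataset()",
         call. = FALSE)
  X <- as.matrix(data[, .param_cols, drop = FALSE])
  y <- data$density
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, `-`), 2, scale, `/`)
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mu) / y_sd
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    linear = {
      Q <- cbind(1, X)
      stats::lm.fit(Q, y)[c("coefficients")]
    },
    polynomial = {
      expo <- monomial_exponents(hp$degree, ncol(X))
      if (nrow(X) < nrow(expo) + 1L)
        stop(sprintf(paste0("polynomial degree %d needs more than %d ",
                            "training points (got %d)"),
                     hp$degree, nrow(expo), nrow(X)), call. = FALSE)
      Phi <- cbind(1, monomial_design(Xs, expo))
      co <- stats::lm.fit(Phi, ys)$coefficients
      co[is.na(co)] <- 0
      list(coefficients = co, exponents = expo)
    },
    random_forest = with_seed(spec$train_seed,
      randomForest::randomForest(x = X, y = y, ntree = hp$ntree)),
    gaussian_process = gp_fit(Xs, ys, hp$kernel, spec$train_seed,
                              sn2_fixed = hp$gp_noise),
    fnn = with_seed(spec$train_seed,
      nnet::nnet(Xs, ys, size = hp$hidden, linout = TRUE, decay = hp$decay,
                 maxit = hp$maxit, trace = FALSE, MaxNWts = 5000)))
  structure(list(spec = spec, fit = fit, space = space,
                 center = center, scale = scale, y_mu = y_mu, y_sd = y_sd,
                 fingerprint = list(dataset = dataset_name(data),
                                    n_train = nrow(data)),
                 y_range = range(y)),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> %s (%s) trained on '%s' (n=%d)\n",
              x$spec$family, spec_label(x$spec), x$fingerprint$dataset,
              x$fingerprint$n_train))
  invisible(x)
}

#' Predict densities from a trained surrogate
#'
#' @param object a `surrogate_model` from [train_surrogate()].
#' @param newdata a data frame of parameter points, a numeric matrix with
#'   the four parameter columns, or a single point ([lj_params()] / named
#'   vector).
#' @param ... unused.
#' @return Numeric vector of predicted densities (kg/m^3), in row order.
#'   Points outside the model's input space are still evaluated but raise
#'   a warning (callers performing optimization are expected to clamp
#'   first).
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  if (!is.data.frame(newdata) && is.null(dim(newdata)))
    newdata <- as.data.frame(as.list(as_param_vector(newdata, .param_cols)),
                             col.names = .param_cols)
  newdata <- as.data.frame(newdata)
  X <- as.matrix(newdata[, .param_cols, drop = FALSE])
  n_out <- sum(!space_contains(object$space, newdata[, .param_cols,
                                                     drop = FALSE]))
  if (n_out > 0)
    warning(n_out, " point(s) outside the model's input space",
            call. = FALSE)
  Xs <- sweep(sweep(X, 2, object$center, `-`), 2, object$scale, `/`)
  spec <- object$spec
  out <- switch(spec$family,
    linear = drop(cbind(1, X) %*% object$fit$coefficients),
    polynomial = {
      Phi <- cbind(1, monomial_design(Xs, object$fit$exponents))
      drop(Phi %*% object$fit$coefficients) * object$y_sd + object$y_mu
    },
    random_forest = unname(stats::predict(object$fit, X)),
    gaussian_process = gp_predict(object$fit, Xs) * object$y_sd + object$y_mu,
    fnn = drop(stats::predict(object$fit, Xs)) * object$y_sd + object$y_mu)
  unname(out)
}

#' Save / load a trained surrogate
#'
#' Serializes the full model state (spec, scaler state, fitted
#' parameters, input space) to a single archive file.
#'
#' @param model a `surrogate_model`.
#' @param path archive path.
#' @return `save_surrogate` returns `path` invisibly; `load_surrogate`
#'   returns the restored model.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "surrogate_model"))
    stop("'", path, "' does not contain a surrogate model", call. = FALSE)
  model
}
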