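# Benchmarking protocol for the surrogate comparison
#
# Seeded split-ratio sweeps over the sampling datasets.  A model trained
# on one dataset's training split is scored twice: on that dataset's
# held-out part (in-sample test, IST) and on the concatenation of all
# records of every *other* dataset (out-of-sample test, OST), probing
# generalization beyond the originating sampling strategy.

#' Enumerate split ratios
#'
#' Inclusive arithmetic sequence with a relative endpoint tolerance, e.g.
#' `enumerate_ratios(0.05, 0.95, 0.05)` yields the canonical 19 ratios.
#'
#' @param start,stop,step reals with `0 < start <= stop < 1`, `step > 0`.
#' @return Numeric vector of ratios.
#' @export
enumerate_ratios <- function(start = 0.05, stop = 0.95, step = 0.05) {
  if (!(start > 0 && start <= stop && stop < 1) || step <= 0)
    stop("need 0 < start <= stop < 1 and step > 0", call. = FALSE)
  k <- floor((stop - start) / step + 1e-9)
  start + step * (0:k)
}

#' Split a dataset into training and testing parts
#'
#' Pseudo-random partition determined entirely by the seed; the training
#' part holds `round(ratio * n)` records.
#'
#' @param ds a `density_dataset` (preprocessed).
#' @param ratio training fraction in (0, 1).
#' @param seed integer split seed.
#' @return A list with `density_dataset` elements `train` and `test`.
#' @export
split_dataset <- function(ds, ratio, seed) {
  n <- nrow(ds)
  n_train <- round(ratio * n)
  if (n_train < 1L || n_train > n - 1L)
    stop(sprintf("split of %d records at ratio %g leaves an empty part",
                 n, ratio), call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_train))
  relabel <- function(part) {
    rownames(part) <- NULL
    attr(part, "name") <- dataset_name(ds)
    class(part) <- class(ds)
    part
  }
  list(train = relabel(ds[idx, , drop = FALSE]),
       test = relabel(ds[-idx, , drop = FALSE]))
}

metric_report <- function(y, yhat, mode) {
  list(mape = mape(y, yhat), r2 = r2_score(y, yhat), mode = mode,
       n_eval = length(y))
}

#' Train one model and score it in-sample and out-of-sample
#'
#' @param spec a [model_spec()].
#' @param ds the originating `density_dataset`.
#' @param ratio,seed split parameters (see [split_dataset()]).
#' @param others list of the remaining datasets, forming the combined OST
#'   evaluation set; must not include `ds` itself.
#' @param space feasible space passed to [train_surrogate()].
#' @return A list with elements `ist` and `ost`, each holding `mape`,
#'   `r2`, `mode` and `n_eval`, plus the fitted `model`.
#' @export
run_ist_ost <- function(spec, ds, ratio, seed, others,
                        space = feasible_space()) {
  if (any(vapply(others, dataset_name, character(1)) == dataset_name(ds)))
    stop("'others' must not contain the training dataset itself",
         call. = FALSE)
  parts <- split_dataset(ds, ratio, seed)
  model <- train_surrogate(spec, parts$train, space = space)
  ist <- metric_report(parts$test$density,
                       predict(model, parts$test), "IST")
  ost_df <- do.call(rbind, lapply(others, as.data.frame))
  ost <- metric_report(ost_df$density,
                       predict(model, ost_df), "OST")
  list(ist = ist, ost = ost, model = model)
}

#' Define an experiment plan
#'
#' @param datasets character vector of dataset names.
#' @param ratios numeric vector of split ratios.
#' @param seeds_per_ratio number of seeded splits per ratio.
#' @param family_grids named list mapping each family to its
#'   hyperparameter grid size or to the grid itself (a list/vector whose
#'   length is used); families with no tunable grid count as 1.
#' @return An object of class `experiment_plan`.
#' @export
#' @examples
#' plan <- experiment_plan(
#'   datasets = c("Grid1296", "Grid2401", "Sobol1", "Sobol2"),
#'   ratios = enumerate_ratios(0.05, 0.95, 0.05),
#'   seeds_per_ratio = 50,
#'   family_grids = list(linear = 1, polynomial = 10, random_forest = 6,
#'                       gaussian_process = 3, fnn = 1))
#' plan_counts(plan)
experiment_plan <- function(datasets, ratios, seeds_per_ratio, family_grids) {
  stopifnot(length(datasets) >= 1L, length(ratios) >= 1L,
            seeds_per_ratio >= 1L, length(family_grids) >= 1L)
  structure(list(datasets = as.character(datasets),
                 ratios = as.numeric(ratios),
                 seeds_per_ratio = as.integer(seeds_per_ratio),
                 family_grids = family_grids),
            class = "experiment_plan")
}

#' Planned model counts per family
#'
#' Per family: `|ratios| * seeds_per_ratio * |datasets| * |grid|`.
#'
#' @param plan an [experiment_plan()].
#' @return Named integer vector of planned trainings per family.
#' @export
plan_counts <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  base <- length(plan$ratios) * plan$seeds_per_ratio * length(plan$datasets)
  vapply(plan$family_grids, function(g) {
    size <- if (length(g) == 1L && is.numeric(g)) as.integer(g)
            else length(g)
    as.integer(base * max(1L, size))
  }, integer(1))
}

#' Execute an experiment plan on concrete datasets
#'
#' Runs every (family, hyperparameter, dataset, ratio, seed) combination
#' of the plan through [run_ist_ost()].  Split seeds are derived
#' deterministically from `base_seed` and the run coordinates, so the
#' whole table is reproducible bit-for-bit.
#'
#' @param plan an [experiment_plan()] whose `family_grids` entries are
#'   lists of [model_spec()] objects (one per hyperparameter setting).
#' @param datasets named list of preprocessed `density_dataset`s matching
#'   `plan$datasets`.
#' @param base_seed integer master seed for split generation.
#' @param space feasible space for training.
#' @return A data frame with columns `family`, `hyperparams`, `dataset`,
#'   `ratio`, `seed`, `mode`, `mape`, `r2`.
#' @export
run_experiment <- function(plan, datasets, base_seed = 1L,
                           space = feasible_space()) {
  stopifnot(inherits(plan, "experiment_plan"))
  missing <- setdiff(plan$datasets, names(datasets))
  if (length(missing))
    stop("missing dataset(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- list()
  run_id <- 0L
  for (fam in names(plan$family_grids)) {
    grid <- plan$family_grids[[fam]]
    if (!is.list(grid))
      stop("run_experiment() needs model_spec grids; got a count for '",
           fam, "'", call. = FALSE)
    for (spec in grid) {
      for (ds_name in plan$datasets) {
        ds <- datasets[[ds_name]]
        others <- datasets[setdiff(plan$datasets, ds_name)]
        for (ratio in plan$ratios) {
          for (s in seq_len(plan$seeds_per_ratio)) {
            run_id <- run_id + 1L
            split_seed <- derive_seed(base_seed, run_id)
            spec_s <- spec
            spec_s$train_seed <- derive_seed(split_seed, 1L)
            res <- run_ist_ost(spec_s, ds, ratio, split_seed, others,
                               space = space)
            for (mode in c("ist", "ost")) {
              m <- res[[mode]]
              rows[[length(rows) + 1L]] <- data.frame(
                family = fam, hyperparams = spec_label(spec),
                dataset = ds_name, ratio = ratio, seed = split_seed,
                mode = m$mode, mape = m$mape, r2 = m$r2,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-run metrics
#'
#' Groups a results table by (family, hyperparams, dataset, ratio, mode)
#' and reports the mean and sample (n-1) standard deviation of MAPE and
#' R^2, averaging the seeded splits.
#'
#' @param results a data frame as returned by [run_experiment()].
#' @return A data frame with columns `family`, `hyperparams`, `dataset`,
#'   `ratio`, `mode`, `mean_mape`, `sd_mape`, `mean_r2`, `sd_r2`, `n`.
#' @export
aggregate_metrics <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("'results' must be a nonempty data frame", call. = FALSE)
  key <- interaction(results$family, results$hyperparams, results$dataset,
                     results$ratio, results$mode, drop = TRUE, sep = "\r")
  groups <- split(results, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(family = g$family[1], hyperparams = g$hyperparams[1],
               dataset = g$dataset[1], ratio = g$ratio[1], mode = g$mode[1],
               mean_mape = mean(g$mape),
               sd_mape = if (nrow(g) > 1L) stats::sd(g$mape) else 0,
               mean_r2 = mean(g$r2),
               sd_r2 = if (nrow(g) > 1L) stats::sd(g$r2) else 0,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$family, out$hyperparams, out$dataset, out$ratio, out$mode), ]
}

#' Welch two-sample comparison of score groups
#'
#' Two-sided unequal-variance t-test of the null hypothesis that the two
#' groups share a mean.  When both groups are constant and equal, the
#' hypothesis is trivially satisfied and `p = 1` is returned by
#' convention.
#'
#' @param a,b numeric vectors of per-model scores, each of length >= 2.
#' @return A list with `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_means <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least two values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                p_value = if (mean(a) == mean(b)) 1 else 0,
                n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Select the top models by MAPE and by R^2
#'
#' Returns the union of the `k` lowest-MAPE and the `k` highest-R^2
#' models, duplicates counted once.  Rows carrying an identical
#' (MAPE, R^2) pair are treated as the same underlying model (the
#' convention used when a selection table lists one model under two
#' ranks).  Ties are broken by the secondary metric, then by id, so the
#' selection is deterministic.
#'
#' @param models a data frame with columns `id`, `mape`, `r2`.
#' @param k number of models per ranking, `1 <= k <=` number of distinct
#'   models.
#' @return A list with the ranked id vectors `by_mape` and `by_r2` and
#'   their deduplicated union `selected`.
#' @export
select_top <- function(models, k) {
  stopifnot(is.data.frame(models),
            all(c("id", "mape", "r2") %in% names(models)))
  uniq <- models[!duplicated(models[, c("mape", "r2")]), , drop = FALSE]
  if (k < 1L || k > nrow(uniq))
    stop("'k' must be between 1 and the number of distinct models",
         call. = FALSE)
  by_mape <- uniq[order(uniq$mape, -uniq$r2, uniq$id), "id"][seq_len(k)]
  by_r2 <- uniq[order(-uniq$r2, uniq$mape, uniq$id), "id"][seq_len(k)]
  list(by_mape = by_mape, by_r2 = by_r2,
       selected = union(by_mape, by_r2))
}
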