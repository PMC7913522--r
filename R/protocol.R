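# Grouped split protocol, cross-database evaluation, and the Wilcoxon
# significance score matrix.

#' Split a dataset into disjoint train/test sets at group granularity
#'
#' `round(train_fraction * n_groups)` randomly chosen acquisition groups
#' (round-half-up) form the training set; the remaining groups form the
#' test set. No group ever appears on both sides, mirroring protocols in
#' which train and test must be disjoint with respect to the experiment
#' that acquired the images.
#'
#' @param ds An `mriqa_dataset` with at least 2 groups.
#' @param train_fraction Fraction of groups assigned to training, in (0,1).
#' @param seed Seed for the group shuffle.
#' @return List with `train` and `test` datasets.
#' @export
group_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_mriqa("`train_fraction` must be in (0, 1)")
  groups <- dataset_groups(ds)
  G <- length(groups)
  if (G < 2L) stop_mriqa("grouped split needs at least 2 groups")
  n_train <- floor(train_fraction * G + 0.5)  # round half up
  if (n_train < 1L || n_train >= G)
    stop_mriqa("split would leave an empty side (", n_train, " of ", G,
               " groups to train)")
  shuffled <- with_seed(seed, sample(groups))
  tr_groups <- shuffled[seq_len(n_train)]
  gid <- vapply(ds$images, `[[`, character(1), "group_id")
  ids <- names(ds$images)
  list(train = subset_dataset(ds, ids[gid %in% tr_groups],
                              paste0(ds$name, "_train")),
       test = subset_dataset(ds, ids[!gid %in% tr_groups],
                             paste0(ds$name, "_test")))
}

# All four criteria for one (objective, subjective) pair: SRCC/KRCC on the
# raw scores, PLCC/RMSE after the logistic mapping fitted on these pairs.
eval_metrics <- function(qo, qs) {
  if (stats::sd(qo) == 0)
    stop_mriqa("degenerate prediction: constant objective scores; ",
               "rank correlation is undefined")
  fit <- fit_logistic_mapping(qo, qs)
  mapped <- apply_mapping(fit, qo)
  list(srcc = srcc(qo, qs), krcc = krcc(qo, qs),
       plcc = plcc(mapped, qs), rmse = rmse(mapped, qs),
       beta = fit$beta, converged = fit$converged)
}

new_iqa_eval <- function(per_iter, head_per_iter, betas, seed, split_seeds) {
  med <- vapply(per_iter[c("srcc", "krcc", "plcc", "rmse")], stats::median,
                numeric(1))
  head_med <- if (!is.null(head_per_iter))
    vapply(head_per_iter[c("srcc", "krcc", "plcc", "rmse")], stats::median,
           numeric(1))
  structure(list(per_iteration = per_iter, medians = med,
                 head_per_iteration = head_per_iter, head_medians = head_med,
                 beta = betas, n_iterations = nrow(per_iter),
                 seed = seed, split_seeds = split_seeds),
            class = "iqa_eval")
}

#' @export
print.iqa_eval <- function(x, ...) {
  cat(sprintf("<iqa_eval> %d iteration(s); medians: SRCC %.4f, KRCC %.4f, PLCC %.4f, RMSE %.4f\n",
              x$n_iterations, x$medians["srcc"], x$medians["krcc"],
              x$medians["plcc"], x$medians["rmse"]))
  if (!is.null(x$head_medians))
    cat(sprintf("  network head:        SRCC %.4f, KRCC %.4f, PLCC %.4f, RMSE %.4f\n",
                x$head_medians["srcc"], x$head_medians["krcc"],
                x$head_medians["plcc"], x$head_medians["rmse"]))
  invisible(x)
}

# One full pipeline pass on a fixed train/test split: augment (train only)
# -> joint fine-tuning -> feature extraction -> SVR with CV-selected
# hyperparameters -> predictions for both the SVR model and the network
# head on the test set.
pipeline_iteration <- function(split, fusion, train_cfg, grid, folds,
                               augment, augment_step, it_seed) {
  train <- split$train
  do_aug <- switch(augment, on = TRUE, off = FALSE,
                   auto = length(train) < 100L)
  if (do_aug) train <- rotation_augment(train, augment_step)
  net <- build_fusion(fusion, seed = it_seed)
  cfg <- train_cfg
  cfg$seed <- it_seed
  net <- fine_tune(net, train, cfg)$net
  qs_tr <- unname(dataset_mos(train))
  f_tr <- extract_features(net, train)
  hp <- select_hyperparams(f_tr, qs_tr, grid = grid, folds = folds,
                           seed = it_seed)
  model <- svr_fit(f_tr, qs_tr, C = hp$C, gamma = hp$gamma,
                   epsilon = hp$epsilon)
  f_te <- extract_features(net, split$test, scaler = f_tr$scaler)
  list(svr = svr_predict(model, f_te),
       head = unname(forward(net, split$test)$scores),
       model = model, net = net)
}

#' Run the grouped train/test evaluation protocol
#'
#' For each iteration: draw a grouped 80/20 split, optionally rotation-
#' augment the training fold, jointly fine-tune a freshly initialized
#' fusion, train the SVR quality model on its concatenated features
#' (hyperparameters selected by cross-validation on the training fold
#' only), predict the test fold, and compute SRCC/KRCC plus PLCC/RMSE
#' after the logistic mapping fitted on the test pairs. Medians over the
#' iterations summarize the run.
#'
#' @param ds An `mriqa_dataset`.
#' @param fusion Backbone specification accepted by [build_fusion()].
#' @param n_iterations Number of train/test iterations (default 10).
#' @param train_fraction Fraction of groups used for training.
#' @param seed Master seed; per-iteration seeds derive from it.
#' @param train_cfg A [training_config()]; default uses the desk-scale
#'   from-scratch learning rate 0.02.
#' @param grid,folds SVR search grid ([svr_grid()]) and CV folds.
#' @param augment `"auto"` (rotation-augment training folds of datasets
#'   with fewer than 100 images), `"on"`, or `"off"`.
#' @param augment_step Rotation step in degrees.
#' @param predictor Optional function `(train, test, seed) -> numeric`
#'   returning objective test-fold scores, replacing the fusion+SVR
#'   pipeline (used to benchmark reference predictors).
#' @return An `iqa_eval` with per-iteration criteria, medians, and -- when
#'   the built-in pipeline is used -- the network head's criteria alongside
#'   the SVR model's.
#' @export
run_protocol <- function(ds, fusion = list(tiny_backbone(16L, 1L),
                                           tiny_backbone(32L, 2L)),
                         n_iterations = 10L, train_fraction = 0.8,
                         seed = 1L,
                         train_cfg = training_config(learning_rate = 0.02),
                         grid = svr_grid(), folds = 5L,
                         augment = c("auto", "on", "off"),
                         augment_step = 3, predictor = NULL) {
  augment <- match.arg(augment)
  if (n_iterations < 1L) stop_mriqa("`n_iterations` must be >= 1")
  rows <- head_rows <- vector("list", n_iterations)
  betas <- vector("list", n_iterations)
  split_seeds <- integer(n_iterations)
  for (i in seq_len(n_iterations)) {
    it_seed <- child_seed(seed, i)
    split_seeds[i] <- it_seed
    split <- group_split(ds, train_fraction, it_seed)
    qs_te <- unname(dataset_mos(split$test))
    if (is.null(predictor)) {
      pred <- pipeline_iteration(split, fusion, train_cfg, grid, folds,
                                 augment, augment_step, it_seed)
      m <- eval_metrics(pred$svr, qs_te)
      mh <- eval_metrics(pred$head, qs_te)
      head_rows[[i]] <- data.frame(iteration = i, srcc = mh$srcc,
                                   krcc = mh$krcc, plcc = mh$plcc,
                                   rmse = mh$rmse)
    } else {
      qo <- predictor(split$train, split$test, it_seed)
      m <- eval_metrics(qo, qs_te)
    }
    rows[[i]] <- data.frame(iteration = i, srcc = m$srcc, krcc = m$krcc,
                            plcc = m$plcc, rmse = m$rmse)
    betas[[i]] <- m$beta
  }
  new_iqa_eval(do.call(rbind, rows),
               if (is.null(predictor)) do.call(rbind, head_rows),
               betas, seed, split_seeds)
}

#' Cross-database evaluation
#'
#' Trains the pipeline once on the full first dataset and evaluates it once
#' on the full second dataset, the protocol used to probe whether a learned
#' quality model generalizes across acquisitions.
#'
#' @param train_ds,test_ds Disjoint `mriqa_dataset`s.
#' @inheritParams run_protocol
#' @return An `iqa_eval` with a single iteration.
#' @export
cross_database <- function(train_ds, test_ds,
                           fusion = list(tiny_backbone(16L, 1L),
                                         tiny_backbone(32L, 2L)),
                           seed = 1L,
                           train_cfg = training_config(learning_rate = 0.02),
                           grid = svr_grid(), folds = 5L,
                           augment = c("auto", "on", "off"),
                           augment_step = 3, predictor = NULL) {
  augment <- match.arg(augment)
  split <- list(train = train_ds, test = test_ds)
  qs_te <- unname(dataset_mos(test_ds))
  if (is.null(predictor)) {
    pred <- pipeline_iteration(split, fusion, train_cfg, grid, folds,
                               augment, augment_step, seed)
    m <- eval_metrics(pred$svr, qs_te)
    mh <- eval_metrics(pred$head, qs_te)
    head_row <- data.frame(iteration = 1L, srcc = mh$srcc, krcc = mh$krcc,
                           plcc = mh$plcc, rmse = mh$rmse)
  } else {
    qo <- predictor(train_ds, test_ds, seed)
    m <- eval_metrics(qo, qs_te)
    head_row <- NULL
  }
  new_iqa_eval(data.frame(iteration = 1L, srcc = m$srcc, krcc = m$krcc,
                          plcc = m$plcc, rmse = m$rmse),
               head_row, list(m$beta), seed, seed)
}

#' Wilcoxon rank-sum significance score matrix
#'
#' Compares methods by their per-iteration SRCC samples: entry (i, j) is
#' +1 when method i's sample is significantly greater than method j's
#' (one-sided rank-sum test at level `alpha`), -1 when significantly
#' smaller, and 0 when the two are statistically indistinguishable. The
#' matrix is antisymmetric with zero diagonal; row sums rank the methods
#' globally.
#'
#' @param srcc_samples Named list (`>= 2` methods) of numeric vectors of
#'   per-iteration SRCC values (each of length `>= 3`).
#' @param alpha Significance level, default 0.05.
#' @return A `significance_matrix`: list with `scores` and `row_sums`.
#' @export
wilcoxon_score_matrix <- function(srcc_samples, alpha = 0.05) {
  if (length(srcc_samples) < 2L) stop_mriqa("need at least 2 methods")
  if (is.null(names(srcc_samples)) || any(!nzchar(names(srcc_samples))))
    stop_mriqa("`srcc_samples` must be a named list")
  if (any(vapply(srcc_samples, length, integer(1)) < 3L))
    stop_mriqa("each SRCC sample needs at least 3 values")
  if (alpha <= 0 || alpha >= 1) stop_mriqa("`alpha` must be in (0, 1)")
  k <- length(srcc_samples)
  scores <- matrix(0L, k, k,
                   dimnames = list(names(srcc_samples), names(srcc_samples)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      x <- srcc_samples[[i]]; y <- srcc_samples[[j]]
      p_gt <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = "greater", exact = FALSE)$p.value)
      p_lt <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = "less", exact = FALSE)$p.value)
      s <- if (is.finite(p_gt) && p_gt < alpha) 1L
           else if (is.finite(p_lt) && p_lt < alpha) -1L else 0L
      scores[i, j] <- s
      scores[j, i] <- -s
    }
  }
  structure(list(scores = scores, row_sums = rowSums(scores), alpha = alpha),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("<significance_matrix> %d methods, alpha = %g\n",
              nrow(x$scores), x$alpha))
  print(cbind(x$scores, sum = x$row_sums))
  invisible(x)
}

# ---- report writers --------------------------------------------------------

#' Write evaluation reports
#'
#' `write_eval_csv` writes the per-iteration criteria as
#' `method,iteration,srcc,krcc,plcc,rmse`; `write_eval_json` writes a JSON
#' summary with the medians and fitted logistic parameters;
#' `write_significance_csv` writes a score matrix with its row sums.
#'
#' @param res An `iqa_eval`.
#' @param path Output path.
#' @param method Method label used in the CSV.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(res, path, method = "fusion_svr") {
  tab <- cbind(method = method, res$per_iteration)
  if (!is.null(res$head_per_iteration))
    tab <- rbind(tab, cbind(method = paste0(method, "_head"),
                            res$head_per_iteration))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_csv
#' @export
write_eval_json <- function(res, path) {
  obj <- list(n_iterations = res$n_iterations, seed = res$seed,
              medians = as.list(res$medians),
              head_medians = if (!is.null(res$head_medians))
                as.list(res$head_medians),
              logistic_beta = res$beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_eval_csv
#' @param sm A `significance_matrix`.
#' @export
write_significance_csv <- function(sm, path) {
  utils::write.csv(cbind(as.data.frame(sm$scores), sum = sm$row_sums), path,
                   row.names = TRUE)
  invisible(path)
}
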