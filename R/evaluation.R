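#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, the evaluation metric used
#' throughout: activity predictions are interpreted by rank, not scale.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA_real_` (with a warning) if either vector
#'   is constant, for which rank correlation is undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  rx <- rank(x); ry <- rank(y)
  if (identical(rx, ry)) return(1.0)            # exact at the extremes
  if (identical(rx, max(ry) + 1 - ry)) return(-1.0)
  cor(rx, ry)
}

make_folds <- function(n, k, seed) {
  if (n < k) stop("fewer observations than folds")
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  with_seed(seed, {
    idx <- sample.int(n)
    rep(seq_len(k), times = sizes)[order(idx)]
  })
}

#' k-fold cross-validation by Spearman rank correlation
#'
#' Shuffles with `seed`, partitions into `k` folds of sizes within one of
#' each other, and per fold trains on the remainder and scores the held-out
#' fold by [spearman_rho()]. With `base` supplied the per-fold model is the
#' base model fine-tuned under `plan` ([default_freeze_plan()] if NULL);
#' without it, a fresh model is trained from scratch (the no-transfer
#' baseline). Dataset-level uniqueness of guide sequences (enforced by
#' [labeled_dataset()]) guarantees no train/test leakage.
#'
#' @param data a [labeled_dataset()].
#' @param k number of folds (default 5: 80/20 splits).
#' @param spec [model_spec()] used when training from scratch (ignored when
#'   `base` is given).
#' @param base optional trained `sgnn` to fine-tune per fold.
#' @param plan [freeze_plan()] for fine-tuning.
#' @param cfg [train_config()] for the per-fold fits.
#' @param seed fold-assignment seed; per-fold training seeds derive from it.
#' @return list of class `cv_result`: `fold_rhos`, `mean_rho`,
#'   `fold_assignments`, `seed`.
#' @export
kfold_cv <- function(data, k = 5L, spec = NULL, base = NULL, plan = NULL,
                     cfg, seed) {
  n <- length(data)
  folds <- make_folds(n, k, seed)
  if (!is.null(base) && is.null(plan)) {
    plan <- default_freeze_plan(base$spec)
  }
  fold_rhos <- vapply(seq_len(k), function(f) {
    test_idx <- which(folds == f)
    train <- subset_dataset(data, -test_idx)
    test <- subset_dataset(data, test_idx)
    if (length(intersect(train$sequences, test$sequences)) > 0) {
      stop("guide sequence leakage between train and test folds")
    }
    fcfg <- cfg
    fcfg$seed <- cfg$seed + f
    m <- if (is.null(base)) {
      fit_layers(build_model(spec, seed = seed + f), train, fcfg,
                 layer_names(spec))
    } else {
      transfer_train(base, plan, train, fcfg)
    }
    spearman_rho(predict(m, test), test$targets)
  }, numeric(1))
  structure(list(fold_rhos = fold_rhos, mean_rho = mean(fold_rhos),
                 fold_assignments = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cross-validation:", length(x$fold_rhos), "folds, mean rho =",
      round(x$mean_rho, 3), "\n")
  cat("per fold:", paste(round(x$fold_rhos, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Input-window length sweep
#'
#' Re-encodes a dataset of full 43-nt target contexts (10 nt upstream,
#' 20-nt protospacer, 3-nt PAM, 10 nt downstream) at a series of window
#' settings and records the mean CV rank correlation for each. Settings are
#' the bare 20-nt protospacer once, upstream extensions `(u, 0)` for `u` in
#' `u_range`, and downstream extensions `(0, d)` for `d` in `d_range` —
#' downstream starts at 3 because the first downstream increment is the
#' whole PAM.
#'
#' @param data [labeled_dataset()] whose sequences are 43-nt contexts.
#' @param spec_template [model_spec()] whose `input_len` is replaced per
#'   setting.
#' @param u_range upstream extensions to test (default 1:10).
#' @param d_range downstream extensions to test (default 3:13).
#' @param k,cfg,seed passed to [kfold_cv()].
#' @return data.frame of class `sweep_result`: `upstream_nt`,
#'   `downstream_nt`, `input_len`, `mean_rho`.
#' @export
length_sweep <- function(data, spec_template, u_range = 1:10,
                         d_range = 3:13, k = 5L, cfg, seed) {
  ctx_len <- nchar(data$sequences[1])
  if (ctx_len != 43) stop("length_sweep needs 43-nt contexts, got ", ctx_len)
  settings <- rbind(data.frame(u = 0L, d = 0L),
                    data.frame(u = u_range, d = 0L),
                    data.frame(u = 0L, d = d_range))
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    u <- settings$u[i]; d <- settings$d[i]
    len <- 20L + u + d
    win <- substr(data$sequences, 11L - u, 30L + d)
    sp <- spec_template
    sp$input_len <- len
    sp <- do.call(model_spec, unclass(sp))
    ds <- labeled_dataset(win, data$targets, name = data$name,
                          nuclease = data$nuclease)
    cv <- kfold_cv(ds, k = k, spec = sp, cfg = cfg, seed = seed)
    data.frame(upstream_nt = u, downstream_nt = d, input_len = len,
               mean_rho = cv$mean_rho)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Remove test entries overlapping a reference dataset
#'
#' Deduplication used to build untouched generalization sets: any test entry
#' whose guide appears in the reference is dropped. By default the key is
#' the 20-nt guide (the first 20 characters of the stored sequence, which by
#' convention starts at the protospacer); `key = "full"` matches the whole
#' stored sequence.
#'
#' @param reference,test [labeled_dataset()]s.
#' @param key "guide" (first 20 nt) or "full".
#' @return the deduplicated test dataset with attribute `removed` (count).
#' @export
dedupe_against <- function(reference, test, key = c("guide", "full")) {
  key <- match.arg(key)
  kf <- function(s) if (key == "guide") substr(toupper(s), 1, 20) else
    toupper(s)
  drop <- kf(test$sequences) %in% kf(reference$sequences)
  out <- subset_dataset(test, !drop)
  attr(out, "removed") <- sum(drop)
  out
}

#' Evaluate a model on an external dataset
#'
#' @param model an `sgnn`.
#' @param dataset a [labeled_dataset()] encoded at the model's input length.
#' @return Spearman rank correlation between predictions and targets.
#' @export
evaluate_external <- function(model, dataset) {
  spearman_rho(predict(model, dataset), dataset$targets)
}
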