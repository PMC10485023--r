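#' Centred log-ratio transform
#'
#' Per-sample CLR in log2 units: `log2(x_i) - mean(log2(x))` computed on
#' proportions, so it is exactly invariant to the sample's sequencing depth
#' (multiplying a column by any positive constant changes nothing).
#'
#' @param x positive numeric vector, or matrix with samples in columns.
#' @return CLR values, same shape as `x`.
#' @export
clr_transform <- function(x) {
  if (is.matrix(x)) {
    lg <- log2(x)
    sweep(lg, 2, colMeans(lg))
  } else {
    lg <- log2(x)
    lg - mean(lg)
  }
}

row_medians <- function(m) apply(m, 1, median)

row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Compositional activity scores by Dirichlet Monte-Carlo CLR
#'
#' Guide read counts from pooled screens are compositional: only relative
#' abundances are observed. For each Monte-Carlo instance this draws
#' per-sample guide proportions from Dirichlet(counts + prior), applies the
#' centred log-ratio (log2), and computes per guide:
#'
#' * `diff_btw` — median over all between-group sample pairs of
#'   CLR(group_b) - CLR(group_a);
#' * `diff_win` — the larger of the two within-group median absolute
#'   pairwise CLR differences;
#' * `rab_all` — median CLR over all samples (relative abundance);
#' * `effect` — `diff_btw / max(diff_win, eps)` (standardized effect);
#' * a Welch t (or Wilcoxon) p-value between groups, BH-adjusted across
#'   guides.
#'
#' Reported values are expectations (means) over instances; `q_value` is the
#' expected BH-adjusted p. Deterministic given `seed`.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b condition labels; `diff_btw` is oriented b minus a
#'   (for an enrichment screen: a = repressed, b = induced).
#' @param n_instances Monte-Carlo instances (default 128).
#' @param prior Dirichlet prior pseudo-count (default 0.5).
#' @param seed integer seed (required: scores are Monte-Carlo estimates).
#' @param test "welch" or "wilcoxon" for the per-instance group test.
#' @return data.frame of class `score_table` with columns `guide`,
#'   `diff_btw`, `diff_win`, `rab_all`, `effect`, `q_value`.
#' @export
clr_mc_scores <- function(cm, group_a, group_b, n_instances = 128L,
                          prior = 0.5, seed, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (missing(seed)) stop("seed is required")
  ia <- which(cm$condition == group_a)
  ib <- which(cm$condition == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need at least 2 samples per group (see depletion_scores() for ",
         "single initial-pool designs)")
  }
  counts <- cm$counts
  G <- nrow(counts)
  if (G < 2) stop("need at least 2 guides")
  nA <- length(ia); nB <- length(ib)
  pairsAB_a <- rep(seq_len(nA), times = nB)
  pairsAB_b <- rep(seq_len(nB), each = nA)
  wpairs <- function(n) {
    if (n < 2) return(NULL)
    idx <- utils::combn(n, 2)
    idx
  }
  pA <- wpairs(nA); pB <- wpairs(nB)

  acc <- matrix(0, nrow = G, ncol = 5,
                dimnames = list(NULL, c("diff_btw", "diff_win", "rab_all",
                                        "effect", "q_value")))
  with_seed(seed, {
    for (inst in seq_len(n_instances)) {
      # log of Dirichlet draws: unnormalized gamma draws, CLR centres them
      lgam <- matrix(0, nrow = G, ncol = ncol(counts))
      for (j in seq_len(ncol(counts))) {
        g <- rgamma(G, shape = counts[, j] + prior, rate = 1)
        lg <- log2(g)
        lgam[, j] <- lg - mean(lg)
      }
      clrA <- lgam[, ia, drop = FALSE]
      clrB <- lgam[, ib, drop = FALSE]
      D <- clrB[, pairsAB_b, drop = FALSE] - clrA[, pairsAB_a, drop = FALSE]
      diff_btw <- row_medians(D)
      winA <- if (is.null(pA)) rep(0, G) else
        row_medians(abs(clrA[, pA[1, ], drop = FALSE] -
                        clrA[, pA[2, ], drop = FALSE]))
      winB <- if (is.null(pB)) rep(0, G) else
        row_medians(abs(clrB[, pB[1, ], drop = FALSE] -
                        clrB[, pB[2, ], drop = FALSE]))
      diff_win <- pmax(winA, winB)
      rab <- row_medians(lgam[, c(ia, ib), drop = FALSE])
      eff <- diff_btw / pmax(diff_win, 1e-8)
      p <- if (test == "welch") {
        mA <- rowMeans(clrA); mB <- rowMeans(clrB)
        vA <- row_vars(clrA); vB <- row_vars(clrB)
        se2 <- vA / nA + vB / nB
        tt <- (mB - mA) / sqrt(se2)
        df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
        pv <- 2 * pt(-abs(tt), df)
        pv[!is.finite(pv)] <- 1
        pv
      } else {
        vapply(seq_len(G), function(g) {
          stats::wilcox.test(clrB[g, ], clrA[g, ], exact = FALSE)$p.value
        }, numeric(1))
      }
      q <- p.adjust(p, method = "BH")
      acc <- acc + cbind(diff_btw, diff_win, rab, eff, q)
    }
  })
  acc <- acc / n_instances
  out <- data.frame(guide = rownames(counts), diff_btw = acc[, 1],
                    diff_win = acc[, 2], rab_all = acc[, 3],
                    effect = acc[, 4], q_value = acc[, 5],
                    stringsAsFactors = FALSE)
  structure(out, class = c("score_table", "data.frame"),
            n_instances = n_instances, prior = prior, seed = seed,
            test = test, groups = c(a = group_a, b = group_b))
}

#' Standardize activity scores to unit variance
#'
#' Adds `std_score = diff_btw / sd(diff_btw)`, the dimensionless regression
#' target. Datasets from different screens have different dynamic ranges;
#' dividing by the dataset standard deviation puts them on one scale.
#' Monotone, rank-preserving, and idempotent in `std_score`.
#'
#' @param scores a `score_table`.
#' @return the table with a `std_score` column and attribute `dataset_sd`.
#' @export
standardize_scores <- function(scores) {
  if (nrow(scores) < 2) stop("need at least 2 guides")
  s <- sd(scores$diff_btw)
  if (s == 0) stop("zero variance in diff_btw; cannot standardize")
  scores$std_score <- scores$diff_btw / s
  attr(scores, "dataset_sd") <- s
  scores
}

#' Score a depletion screen against an initial pool
#'
#' Genome-targeting (depletion) screens have no repressed replicates; the
#' initial sequencing of the plasmid pool prior to transformation stands in
#' for them. A single initial-pool sample is replicated to meet the
#' two-sample minimum (flagged in the output metadata). Active guides vanish
#' from the endpoint, so raw `diff_btw` is negative for active guides;
#' `flip_sign = TRUE` (default) negates `diff_btw` and `effect` so that
#' larger means more active, matching the enrichment orientation.
#'
#' @param cm_endpoint [count_matrix()] of post-selection samples.
#' @param initial_pool [count_matrix()] of the pre-transformation pool
#'   (1 or more samples).
#' @param flip_sign orient scores activity-increasing (default TRUE).
#' @inheritParams clr_mc_scores
#' @return a `score_table` (attributes record the depletion design).
#' @export
depletion_scores <- function(cm_endpoint, initial_pool, n_instances = 128L,
                             prior = 0.5, seed, flip_sign = TRUE,
                             test = "welch") {
  ge <- rownames(cm_endpoint$counts)
  gp <- rownames(initial_pool$counts)
  if (!setequal(ge, gp)) {
    off <- c(setdiff(ge, gp), setdiff(gp, ge))
    stop("guide sets differ between endpoint and pool: ",
         paste(head(off, 10), collapse = ", "),
         if (length(off) > 10) " ..." else "")
  }
  pool_counts <- initial_pool$counts[ge, , drop = FALSE]
  replicated <- FALSE
  if (ncol(pool_counts) < 2) {
    pool_counts <- cbind(pool_counts, pool_counts)
    colnames(pool_counts) <- paste0("initial_pool_", 1:2)
    replicated <- TRUE
  }
  comb <- count_matrix(
    cbind(pool_counts, cm_endpoint$counts),
    condition = c(rep("initial_pool", ncol(pool_counts)),
                  rep("endpoint", ncol(cm_endpoint$counts))),
    replicate = c(seq_len(ncol(pool_counts)),
                  seq_len(ncol(cm_endpoint$counts))))
  sc <- clr_mc_scores(comb, group_a = "initial_pool", group_b = "endpoint",
                      n_instances = n_instances, prior = prior, seed = seed,
                      test = test)
  if (flip_sign) {
    sc$diff_btw <- -sc$diff_btw
    sc$effect <- -sc$effect
  }
  attr(sc, "depletion_mode") <- TRUE
  attr(sc, "pool_replicated") <- replicated
  attr(sc, "flip_sign") <- flip_sign
  sc
}

#' Drop highly variable guides
#'
#' Removes guides whose within-condition dispersion `diff_win` exceeds
#' `diff_win_max` (strict: `diff_win` exactly 1.0 is retained at the
#' default).
#'
#' @param scores a `score_table`.
#' @param diff_win_max threshold (default 1.0).
#' @return filtered table with attribute `removed` (guide names).
#' @export
filter_high_variance <- function(scores, diff_win_max = 1.0) {
  drop <- scores$diff_win > diff_win_max
  out <- scores[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- scores$guide[drop]
  out
}

#' Guides with significant activity at an FDR threshold
#'
#' @param scores a `score_table` (q_value populated).
#' @param fdr false-discovery-rate cutoff (default 0.01, strict `<`).
#' @param direction "positive" restricts to `diff_btw > 0`; "any" does not.
#' @return character vector of guide names.
#' @export
significant_guides <- function(scores, fdr = 0.01,
                               direction = c("positive", "any")) {
  direction <- match.arg(direction)
  hit <- scores$q_value < fdr
  if (direction == "positive") hit <- hit & scores$diff_btw > 0
  scores$guide[hit]
}
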