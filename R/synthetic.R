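# Synthetic world generators. These emulate the statistical structure the
# scoring and modeling methods assume -- a planted sequence->activity
# function with PAM-proximal (seed-region) dominance, paired-condition
# multinomial count tables whose enrichment is monotone in activity, a
# minority of toxic guides depleted under both conditions, logistic growth
# curves, and a large/small transfer-learning dataset pair -- so every
# module is testable without downloads. They are pure functions of their
# seeds.

CTX_LEN <- 43L          # 10 up + 20 protospacer + 3 PAM + 10 down
CTX_PROTO <- 11:30      # protospacer positions within the context
CTX_SEED_REGION <- 21:30  # PAM-proximal protospacer positions 1..10

#' Create a planted sequence-to-activity function
#'
#' Activity over a 43-nt target context is a sum of per-position additive
#' weights (centred over the four bases at each position) plus sparse
#' pairwise interaction terms built from centred indicator products, so the
#' main, pairwise, and noise variance components are orthogonal and the
#' declared decomposition sums to the total. Weights in the PAM-proximal
#' seed region (protospacer positions 1-10) are scaled by
#' `seed_region_boost`, mirroring the dominance of seed mismatches;
#' positions outside `active_span` get zero weight (the default span covers
#' protospacer + PAM only, so downstream or upstream context carries no
#' signal unless requested).
#'
#' @param seed integer seed; same seed, same function.
#' @param seed_region_boost multiplier on seed-region weights (default 2).
#' @param weight_sd per-position weight scale (default 0.5).
#' @param n_pairwise number of pairwise interaction terms (default 20).
#' @param pairwise_sd pairwise weight scale (default 0.3).
#' @param noise_sd measurement noise added when datasets are scored
#'   (default 0.25; the activity function itself is deterministic).
#' @param active_span context positions carrying signal (default 11..33,
#'   protospacer + PAM).
#' @return object of class `planted_model`.
#' @export
make_planted_model <- function(seed, seed_region_boost = 2,
                               weight_sd = 0.5, n_pairwise = 20L,
                               pairwise_sd = 0.3, noise_sd = 0.25,
                               active_span = 11:33) {
  with_seed(seed, {
    w <- matrix(rnorm(4 * CTX_LEN, sd = weight_sd), nrow = 4,
                dimnames = list(BASES, NULL))
    w <- sweep(w, 2, colMeans(w))          # centre over bases per position
    mask <- rep(0, CTX_LEN)
    mask[active_span] <- 1
    boost <- rep(1, CTX_LEN)
    boost[CTX_SEED_REGION] <- seed_region_boost
    w <- sweep(w, 2, mask * boost, `*`)
    pw <- NULL
    if (n_pairwise > 0) {
      pos <- replicate(n_pairwise,
                       sort(sample(active_span, 2, replace = FALSE)))
      pw <- data.frame(pos_i = pos[1, ], pos_j = pos[2, ],
                       base_i = sample(BASES, n_pairwise, replace = TRUE),
                       base_j = sample(BASES, n_pairwise, replace = TRUE),
                       weight = rnorm(n_pairwise, sd = pairwise_sd),
                       stringsAsFactors = FALSE)
    }
    var_main <- sum(colMeans(w^2))      # E over uniform base per position
    var_pair <- if (is.null(pw)) 0 else sum(pw$weight^2) * (3 / 16)^2
    structure(list(weights = w, pairwise = pw, noise_sd = noise_sd,
                   seed = seed,
                   variance = c(main = var_main, pairwise = var_pair,
                                noise = noise_sd^2,
                                total = var_main + var_pair + noise_sd^2)),
              class = "planted_model")
  })
}

#' Evaluate the planted activity function (noise-free)
#'
#' @param model a [planted_model][make_planted_model()].
#' @param contexts character vector of 43-nt contexts.
#' @return numeric activities, deterministic.
#' @export
planted_activity <- function(model, contexts) {
  n <- length(contexts)
  ch <- matrix(unlist(strsplit(contexts, ""), use.names = FALSE),
               nrow = n, byrow = TRUE)
  if (ncol(ch) != CTX_LEN) stop("contexts must be ", CTX_LEN, " nt")
  bi <- matrix(match(ch, BASES), nrow = n)
  act <- rowSums(matrix(model$weights[cbind(as.vector(bi),
                                            rep(seq_len(CTX_LEN),
                                                each = n))], nrow = n))
  if (!is.null(model$pairwise)) {
    for (t in seq_len(nrow(model$pairwise))) {
      p <- model$pairwise[t, ]
      xi <- (ch[, p$pos_i] == p$base_i) - 0.25
      xj <- (ch[, p$pos_j] == p$base_j) - 0.25
      act <- act + p$weight * xi * xj
    }
  }
  act
}

#' Random target contexts
#' @param n number of contexts.
#' @param seed seed.
#' @param len context length (default 43).
#' @return character vector of uniform random DNA strings.
#' @export
random_contexts <- function(n, seed, len = CTX_LEN) {
  with_seed(seed, {
    m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
    apply(m, 1, paste, collapse = "")
  })
}

#' Simulate a paired-condition enrichment screen
#'
#' Emulates the two-plasmid experiment: every guide has a log-normal library
#' composition bias; repressed-condition expected proportions follow the
#' bias; induced-condition proportions are the repressed ones multiplied by
#' `exp(gain * activity)` (so enrichment is monotone in true activity among
#' non-toxic guides); toxic guides have their proportions multiplied by
#' `(1 - toxicity)` under *both* conditions. Per-sample counts are
#' multinomial at exactly `depth` reads, so compositional closure holds
#' exactly.
#'
#' @param model a [planted_model][make_planted_model()].
#' @param n_guides number of guides (random contexts).
#' @param n_toxic number of toxic guides (toxicity drawn in 0.7..1).
#' @param depth reads per sample (default 1e6).
#' @param reps replicates per condition (default 10).
#' @param gain selection gain on activity (default 0.3, calibrated so the
#'   activity-score range spans roughly 10 log2 units).
#' @param bias_sd log-normal library-bias sd in log units (default 0.5).
#' @param seed seed.
#' @return list of class `sim_screen`: `contexts`, `true_activity`,
#'   `toxicity`, and `counts` (a [count_matrix()] with `reps` repressed and
#'   `reps` induced samples).
#' @export
simulate_screen <- function(model, n_guides = 1000L, n_toxic = 120L,
                            depth = 1e6, reps = 10L, gain = 0.3,
                            bias_sd = 0.5, seed) {
  if (n_toxic >= n_guides) stop("n_toxic must be < n_guides")
  contexts <- random_contexts(n_guides, seed)
  activity <- planted_activity(model, contexts)
  with_seed(seed + 1L, {
    toxicity <- rep(0, n_guides)
    tox_idx <- sample.int(n_guides, n_toxic)
    toxicity[tox_idx] <- runif(n_toxic, 0.7, 1)
    bias <- rlnorm(n_guides, meanlog = 0, sdlog = bias_sd)
    p_rep <- bias * (1 - toxicity)
    p_ind <- p_rep * exp(gain * activity)
    p_rep <- p_rep / sum(p_rep)
    p_ind <- p_ind / sum(p_ind)
    if (depth < 10 * n_guides) {
      warning("depth may be too low to represent all guides")
    }
    guides <- sprintf("g%05d", seq_len(n_guides))
    cm <- cbind(
      matrix(unlist(lapply(seq_len(reps),
                           function(i) rmultinom(1, depth, p_rep))),
             ncol = reps),
      matrix(unlist(lapply(seq_len(reps),
                           function(i) rmultinom(1, depth, p_ind))),
             ncol = reps))
    rownames(cm) <- guides
    colnames(cm) <- c(paste0("rep_", seq_len(reps)),
                      paste0("ind_", seq_len(reps)))
    counts <- count_matrix(cm,
                           condition = rep(c("repressed", "induced"),
                                           each = reps),
                           replicate = rep(seq_len(reps), 2))
    structure(list(contexts = setNames(contexts, guides),
                   true_activity = setNames(activity, guides),
                   toxicity = setNames(toxicity, guides), counts = counts),
              class = "sim_screen")
  })
}

#' Build a transfer-learning dataset pair
#'
#' A large, noisy dataset scored by the base planted function (emulating a
#' big depletion screen) and a small, clean dataset scored by a function
#' whose weights are interpolated toward an independent draw by `shift`
#' (same underlying biology, shifted nuclease/assay). Both are standardized
#' to unit target variance. Sequences are the default 28-nt windows
#' (protospacer + PAM + 5 nt) of independently drawn random contexts.
#'
#' @param model base [planted_model][make_planted_model()].
#' @param shift interpolation toward the independent function, in `[0, 1]`.
#' @param n_large,n_small dataset sizes (defaults 40000 and 300, mirroring a
#'   large published depletion set and a small high-quality set).
#' @param noise_large,noise_small target noise as multiples of the signal
#'   sd (defaults 0.75 and 0.15).
#' @param seed seed.
#' @return list with [labeled_dataset()]s `large` and `small`.
#' @export
make_transfer_scenario <- function(model, shift = 0.3, n_large = 40000L,
                                   n_small = 300L, noise_large = 0.75,
                                   noise_small = 0.15, seed) {
  if (shift < 0 || shift > 1) stop("shift must be in [0, 1]")
  other <- make_planted_model(seed = model$seed + 1000003L,
                              noise_sd = model$noise_sd)
  shifted <- model
  shifted$weights <- (1 - shift) * model$weights + shift * other$weights
  if (!is.null(model$pairwise) && !is.null(other$pairwise)) {
    shifted$pairwise$weight <- (1 - shift) * model$pairwise$weight +
      shift * other$pairwise$weight
  }
  ctx_l <- random_contexts(n_large, seed + 1L)
  ctx_s <- random_contexts(n_small, seed + 2L)
  a_l <- planted_activity(model, ctx_l)
  a_s <- planted_activity(shifted, ctx_s)
  with_seed(seed + 3L, {
    y_l <- a_l + rnorm(n_large, sd = noise_large * sd(a_l))
    y_s <- a_s + rnorm(n_small, sd = noise_small * sd(a_s))
  })
  win <- function(ctx) substr(ctx, 11, 38)   # (u=0, d=8): 28 nt
  mk <- function(ctx, y, nm) {
    w <- win(ctx)
    keep <- !duplicated(w)
    labeled_dataset(w[keep], y[keep] / sd(y[keep]), name = nm)
  }
  list(large = mk(ctx_l, y_l, "synthetic_large"),
       small = mk(ctx_s, y_s, "synthetic_small"))
}

#' Simulate growth curves for a cohort of guides
#'
#' Logistic OD600 curves: the induced-condition carrying capacity increases
#' with guide activity (active guides cleave the toxin plasmid and grow);
#' toxicity suppresses growth in both conditions; small additive
#' measurement noise.
#'
#' @param activity numeric vector of guide activities.
#' @param toxicity numeric vector in `[0, 1]`.
#' @param time timepoints in minutes (default 0..1080 by 10, i.e. 18 h).
#' @param seed seed for measurement noise.
#' @param noise_sd additive OD noise (default 0.02).
#' @return list with `time`, `od_induced`, `od_repressed` (guides x
#'   timepoints matrices), `activity`, `toxicity`.
#' @export
simulate_growth <- function(activity, toxicity, time = seq(0, 1080, by = 10),
                            seed = 1L, noise_sd = 0.02) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  n <- length(activity)
  stopifnot(length(toxicity) == n)
  od0 <- 0.02; r <- 0.012
  logistic <- function(K) {
    t(vapply(K, function(k) {
      k <- max(k, od0 * 1.5)
      k / (1 + ((k - od0) / od0) * exp(-r * time))
    }, numeric(length(time))))
  }
  K_ind <- (0.08 + 0.92 * plogis(1.5 * activity)) * (1 - 0.95 * toxicity)
  K_rep <- 1.0 * (1 - 0.95 * toxicity)
  with_seed(seed, {
    noise <- function(m) pmax(m + matrix(rnorm(length(m), sd = noise_sd),
                                         nrow = nrow(m)), 0.001)
    gn <- sprintf("g%03d", seq_len(n))
    oi <- noise(logistic(K_ind)); rownames(oi) <- gn
    or <- noise(logistic(K_rep)); rownames(or) <- gn
    list(time = time, od_induced = oi, od_repressed = or,
         activity = activity, toxicity = toxicity)
  })
}
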