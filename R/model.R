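MODEL_FORMAT_VERSION <- 1L

#' Specification of the dual-branch sequence regression network
#'
#' The network consumes a one-hot 4xN input through one shared convolution,
#' then splits: branch A stacks further convolutions, max-pools, flattens,
#' and applies a dense layer (the "multi-layer CNN"); branch B feeds the
#' shared convolution's output through a bidirectional GRU and a dense layer
#' (the "CNN-BGRU" hybrid). The branches concatenate into a dense head
#' ending in a single linear output. Defaults stand in for tuned values that
#' were never published; every size is configurable.
#'
#' @param input_len input sequence length (default 28: protospacer + PAM +
#'   5 nt downstream).
#' @param conv_filters,conv_kernel shared convolution (128 filters, width 5,
#'   ReLU).
#' @param branch_filters,branch_kernel branch-A convolution stack
#'   (64/32/32, width 3).
#' @param pool max-pool width after branch A (2).
#' @param dense_a branch-A dense units (64).
#' @param gru_units GRU units per direction (64).
#' @param dense_b branch-B dense units (64).
#' @param merge_dense dense head sizes before the linear output (128, 64).
#' @param dropout dropout rate after each dense block during training (0.3).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(input_len = 28L, conv_filters = 128L, conv_kernel = 5L,
                       branch_filters = c(64L, 32L, 32L), branch_kernel = 3L,
                       pool = 2L, dense_a = 64L, gru_units = 64L,
                       dense_b = 64L, merge_dense = c(128L, 64L),
                       dropout = 0.3) {
  sp <- list(input_len = as.integer(input_len),
             conv_filters = as.integer(conv_filters),
             conv_kernel = as.integer(conv_kernel),
             branch_filters = as.integer(branch_filters),
             branch_kernel = as.integer(branch_kernel),
             pool = as.integer(pool), dense_a = as.integer(dense_a),
             gru_units = as.integer(gru_units), dense_b = as.integer(dense_b),
             merge_dense = as.integer(merge_dense), dropout = dropout)
  L <- sp$input_len - sp$conv_kernel + 1
  for (f in sp$branch_filters) L <- L - sp$branch_kernel + 1
  if (L < sp$pool) {
    stop("branch-A output length ", L, " too short for pooling; ",
         "reduce kernels or layers")
  }
  class(sp) <- "model_spec"
  sp
}

#' Layer names of a model (freeze-plan granularity)
#' @param spec a [model_spec()].
#' @return character vector of stable layer names.
#' @export
layer_names <- function(spec) {
  c("conv_shared",
    paste0("conv_a", seq_along(spec$branch_filters)),
    "dense_a", "bigru", "dense_b",
    paste0("dense_merge", seq_along(spec$merge_dense)),
    "output")
}

#' Build (initialize) a model
#'
#' @param spec a [model_spec()].
#' @param seed initialization seed; two builds with the same seed produce
#'   identical weights.
#' @return object of class `sgnn` (spec + weights + training history).
#' @export
build_model <- function(spec, seed) {
  stopifnot(inherits(spec, "model_spec"))
  w <- nn_init_cpp(unclass(spec), as.integer(seed))
  structure(list(spec = spec, weights = w, history = NULL,
                 provenance = list(init_seed = seed)),
            class = "sgnn")
}

#' Count trainable parameters
#' @param model an `sgnn` model.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' Training configuration
#'
#' @param lr Adam learning rate (base 1e-3; transfer 1e-4).
#' @param epochs training epochs (base models are tuned in increments of 5,
#'   transfer in single-epoch increments).
#' @param batch_size minibatch size (base 128; transfer 16).
#' @param seed seed fixing shuffling and dropout.
#' @param use_dropout apply dropout during this training run.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, epochs = 25L, batch_size = 128L, seed,
                         use_dropout = TRUE) {
  if (missing(seed)) stop("seed is required")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), use_dropout = use_dropout),
            class = "train_config")
}

#' Labeled sequence-activity dataset
#'
#' @param sequences equal-length DNA strings (model inputs).
#' @param targets standardized activity scores, one per sequence.
#' @param name dataset label.
#' @param nuclease nuclease the scores were measured with (free text, e.g.
#'   "SpCas9", "eSpCas9", "TevSpCas9").
#' @return list of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sequences, targets, name = "dataset",
                            nuclease = "SpCas9") {
  if (length(sequences) != length(targets)) {
    stop("sequences and targets must have equal length")
  }
  if (anyDuplicated(sequences)) {
    stop("duplicate guide sequences within a dataset")
  }
  check_dna(sequences, what = "sequences")
  structure(list(sequences = toupper(sequences), targets = as.numeric(targets),
                 name = name, nuclease = nuclease),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$sequences)

subset_dataset <- function(data, idx) {
  labeled_dataset(data$sequences[idx], data$targets[idx],
                  name = data$name, nuclease = data$nuclease)
}

dataset_array <- function(data, input_len) {
  n <- nchar(data$sequences[1])
  if (n != input_len) {
    stop("dataset sequences have length ", n,
         " but the model expects ", input_len)
  }
  encode_dataset(data$sequences)
}

#' Train a base model on a large dataset
#'
#' Fits all layers with Adam on mean squared error. Warns if the dataset is
#' small relative to the network (below 5000 examples a base model will
#' usually overfit; use [transfer_train()] on such data instead), and if the
#' training loss did not decrease.
#'
#' @param model an `sgnn` from [build_model()].
#' @param data a [labeled_dataset()].
#' @param cfg a [train_config()].
#' @return the trained model; `$history` holds per-epoch training loss.
#' @export
train_base <- function(model, data, cfg) {
  if (length(data) < 5000) {
    warning("base training on ", length(data),
            " examples; consider transfer learning for small datasets")
  }
  fit_layers(model, data, cfg, layer_names(model$spec))
}

fit_layers <- function(model, data, cfg, trainable) {
  x <- dataset_array(data, model$spec$input_len)
  res <- nn_train_cpp(model$weights, unclass(model$spec), x, data$targets,
                      cfg$epochs, cfg$batch_size, cfg$lr, cfg$seed,
                      trainable, cfg$use_dropout)
  model$weights <- res$weights
  h <- as.numeric(res$history)
  if (length(h) > 1 && h[length(h)] > h[1] * 1.05) {
    warning("training loss increased over training (",
            signif(h[1], 4), " -> ", signif(h[length(h)], 4), ")")
  }
  model$history <- c(model$history, list(h))
  model
}

#' Default transfer-learning freeze plan
#'
#' During fine-tuning, the multi-layer CNN branch and the post-concatenation
#' dense layers are frozen; the shared initial convolution, the whole
#' CNN-BGRU branch, and the final output layer remain trainable.
#'
#' @param spec a [model_spec()].
#' @param preset "default" as above; "rnn_only" additionally freezes the
#'   shared convolution and output; "none" freezes nothing.
#' @return list of class `freeze_plan` with `trainable` and `frozen`
#'   character vectors partitioning [layer_names()].
#' @export
default_freeze_plan <- function(spec, preset = c("default", "rnn_only",
                                                 "none")) {
  preset <- match.arg(preset)
  all_layers <- layer_names(spec)
  trainable <- switch(preset,
    default = c("conv_shared", "bigru", "dense_b", "output"),
    rnn_only = c("bigru", "dense_b"),
    none = all_layers)
  freeze_plan(trainable, setdiff(all_layers, trainable))
}

#' Construct a freeze plan
#' @param trainable,frozen character vectors of layer names; together they
#'   must partition the model's layers (checked at [transfer_train()] time).
#' @return list of class `freeze_plan`.
#' @export
freeze_plan <- function(trainable, frozen = character()) {
  if (length(intersect(trainable, frozen)) > 0) {
    stop("layers cannot be both trainable and frozen")
  }
  structure(list(trainable = trainable, frozen = frozen),
            class = "freeze_plan")
}

#' Fine-tune a trained model under a freeze plan
#'
#' Updates only `plan$trainable` layers; frozen parameters are bit-identical
#' before and after (the optimizer never touches them, though gradients
#' still flow through them).
#'
#' @param base a trained `sgnn`.
#' @param plan a [freeze_plan()].
#' @param data small high-quality [labeled_dataset()].
#' @param cfg a [train_config()] (typically lower lr, small batches,
#'   single-epoch-tuned epochs).
#' @return the fine-tuned model.
#' @export
transfer_train <- function(base, plan, data, cfg) {
  all_layers <- layer_names(base$spec)
  known <- union(plan$trainable, plan$frozen)
  if (!setequal(known, all_layers)) {
    bad <- c(setdiff(known, all_layers), setdiff(all_layers, known))
    stop("freeze plan does not partition the model layers: ",
         paste(bad, collapse = ", "))
  }
  fit_layers(base, data, cfg, plan$trainable)
}

#' Predict activity scores
#'
#' @param object an `sgnn` model.
#' @param newdata a [labeled_dataset()], character vector of sequences, or a
#'   pre-encoded `c(n, 4, N)` array.
#' @param ... unused.
#' @return numeric vector of predicted (standardized-score scale)
#'   activities; deterministic, one value per input.
#' @export
predict.sgnn <- function(object, newdata, ...) {
  x <- if (is.array(newdata) && length(dim(newdata)) == 3) {
    newdata
  } else if (inherits(newdata, "labeled_dataset")) {
    dataset_array(newdata, object$spec$input_len)
  } else {
    encode_dataset(newdata)
  }
  if (dim(x)[3] != object$spec$input_len) {
    stop("input length ", dim(x)[3], " does not match model input_len ",
         object$spec$input_len)
  }
  as.numeric(nn_forward_cpp(object$weights, unclass(object$spec), x))
}

spec_hash <- function(spec) {
  # tiny FNV-1a over the canonical JSON of the spec; guards load-time mismatch
  s <- as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Save a model to a portable text file
#'
#' JSON with the spec, a spec checksum, the format version, and all weights
#' printed at 17 significant digits, which round-trips IEEE doubles exactly:
#' save -> load -> predict is bit-identical to predict.
#'
#' @param model an `sgnn`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  ws <- lapply(model$weights, function(m) {
    list(dim = dim(m), data = sprintf("%.17g", as.numeric(m)))
  })
  obj <- list(format_version = MODEL_FORMAT_VERSION,
              spec = unclass(model$spec), spec_hash = spec_hash(model$spec),
              provenance = model$provenance, weights = ws)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE)), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path model file.
#' @return an `sgnn`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(readLines(path), simplifyVector = FALSE),
                  error = function(e) stop("corrupt model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$format_version) ||
      obj$format_version > MODEL_FORMAT_VERSION) {
    stop("unsupported model format version")
  }
  spec <- obj$spec
  spec$branch_filters <- as.integer(unlist(spec$branch_filters))
  spec$merge_dense <- as.integer(unlist(spec$merge_dense))
  for (f in c("input_len", "conv_filters", "conv_kernel", "branch_kernel",
              "pool", "dense_a", "gru_units", "dense_b")) {
    spec[[f]] <- as.integer(spec[[f]])
  }
  spec$dropout <- as.numeric(spec$dropout)
  class(spec) <- "model_spec"
  if (!identical(spec_hash(spec), obj$spec_hash)) {
    stop("model file spec hash mismatch; file corrupt or edited")
  }
  ws <- lapply(obj$weights, function(w) {
    matrix(as.numeric(unlist(w$data)), nrow = w$dim[[1]], ncol = w$dim[[2]])
  })
  names(ws) <- names(obj$weights)
  structure(list(spec = spec, weights = ws, history = NULL,
                 provenance = obj$provenance),
            class = "sgnn")
}

#' @export
print.sgnn <- function(x, ...) {
  cat("dual-branch CNN / CNN-BGRU regression model\n")
  cat("  input: 4 x", x$spec$input_len, " one-hot\n")
  cat("  parameters:", n_parameters(x), "\n")
  invisible(x)
}
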