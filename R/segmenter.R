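#' Annotation oracle backed by simulation truth
#'
#' Emulates the hand-annotation of selected areas: for a requested channel it
#' can label any voxel as confident signal, confident background, or decline
#' (uncertain region at the blurred structure's fringe). Derived from the
#' annotation-code volumes the renderer attaches to simulated stacks.
#'
#' @param stacks list of simulated `exm_stack` objects (with annotation
#'   codes).
#' @return a function `oracle(stack_index, channel)` returning a list with
#'   integer voxel indices `signal` and `background`.
#' @export
truth_oracle <- function(stacks) {
  codes <- lapply(stacks, attr, "annotation_codes")
  if (any(vapply(codes, is.null, TRUE)))
    stop_exm("all stacks must carry annotation codes (simulated stacks do)",
             "exmloc_config")
  function(stack_index, channel) {
    code <- codes[[stack_index]][[channel]]
    list(signal = which(code == 1L), background = which(code == -1L))
  }
}

# deterministic canonical order: by stack, voxel index, then label
canonical_sort <- function(ann) {
  ann[order(ann$stack, ann$voxel, ann$label), , drop = FALSE]
}

fit_logistic <- function(X, y) {
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- scale(X, ctr, scl)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Xs), y,
                                         family = stats::binomial(),
                                         control = list(maxit = 100)))
  list(coef = fit$coefficients, center = ctr, scale = scl)
}

predict_logistic <- function(model, X) {
  Xs <- scale(X, model$center, model$scale)
  eta <- drop(cbind(1, Xs) %*% model$coef)
  1 / (1 + exp(-eta))
}

#' Train a pixel segmenter in iterative annotation rounds
#'
#' Supervised pixel classification replacing the commercial deep-learning
#' spot segmenter: a logistic classifier over multiscale features, trained in
#' (by default) twelve rounds of an active-learning loop. Each round the
#' oracle contributes a fixed number of annotated voxels per class; from the
#' second round on, annotations are drawn preferentially where the current
#' model disagrees with the oracle (corrective annotation), mirroring
#' iterative hand-training. The fit is made order-invariant by canonically
#' sorting the accumulated annotations before fitting.
#'
#' @param stacks list of `exm_stack` training stacks.
#' @param oracle an annotation provider as returned by [truth_oracle()].
#' @param channel channel to segment (`"receptor"` or `"collagen"`); each
#'   channel is segmented independently from its own channel's features.
#' @param rounds number of training rounds (>= 1), default 12.
#' @param n_per_class annotated voxels per class per round.
#' @param scales_nm feature scales passed to [extract_features()].
#' @param seed integer seed for the annotation substream.
#' @param features optional precomputed list of feature matrices (one per
#'   stack) to avoid recomputation.
#' @return object of class `exm_segmenter` with the fitted coefficients,
#'   feature configuration, `training_rounds_completed` and per-round
#'   history (annotation counts, training error).
#' @export
train_segmenter <- function(stacks, oracle, channel = "receptor",
                            rounds = 12, n_per_class = 200,
                            scales_nm = c(150, 300, 600), seed = 1L,
                            features = NULL) {
  stopifnot(rounds >= 1, n_per_class >= 2)
  if (is.null(features))
    features <- lapply(stacks, extract_features, channel = channel,
                       scales_nm = scales_nm)
  pools <- lapply(seq_along(stacks), function(i) oracle(i, channel))
  if (all(vapply(pools, function(p) length(p$signal), 1L) == 0) ||
      all(vapply(pools, function(p) length(p$background), 1L) == 0))
    stop_exm("a class is absent from all annotations; cannot train",
             "exmloc_degenerate_training")

  ann <- data.frame(stack = integer(0), voxel = integer(0), label = integer(0))
  model <- NULL
  history <- data.frame(round = integer(0), n_annotations = integer(0),
                        training_error = numeric(0))

  with_seed(seed_stream(seed, "annotation"), {
    for (r in seq_len(rounds)) {
      for (i in seq_along(stacks)) {
        for (lab in c(1L, 0L)) {
          pool <- if (lab == 1L) pools[[i]]$signal else pools[[i]]$background
          if (!length(pool)) next
          take <- min(n_per_class, length(pool))
          if (r == 1 || is.null(model)) {
            pick <- pool[sample.int(length(pool), take)]
          } else {
            # corrective annotation: prefer voxels the model gets wrong
            # (screened on a bounded candidate subsample for large pools)
            cand <- if (length(pool) > 20000)
              pool[sample.int(length(pool), 20000)] else pool
            p <- predict_logistic(model, features[[i]][cand, , drop = FALSE])
            wrong <- cand[(p > 0.5) != (lab == 1L)]
            pick <- if (length(wrong) >= take)
              wrong[sample.int(length(wrong), take)]
            else c(wrong, cand[sample.int(length(cand), take - length(wrong))])
          }
          ann <- rbind(ann, data.frame(stack = i, voxel = pick, label = lab))
        }
      }
      ann <- unique(canonical_sort(ann))
      X <- do.call(rbind, lapply(split(ann, ann$stack), function(a)
        features[[a$stack[1]]][a$voxel, , drop = FALSE]))
      y <- unlist(lapply(split(ann, ann$stack), function(a) a$label),
                  use.names = FALSE)
      if (length(unique(y)) < 2)
        stop_exm("a class is absent from the accumulated annotations",
                 "exmloc_degenerate_training")
      model <- fit_logistic(X, y)
      err <- mean((predict_logistic(model, X) > 0.5) != (y == 1))
      history <- rbind(history, data.frame(round = r,
                                           n_annotations = nrow(ann),
                                           training_error = err))
    }
  })
  structure(list(channel = channel, scales_nm = scales_nm,
                 model = model,
                 training_rounds_completed = as.integer(rounds),
                 n_per_class = n_per_class, history = history,
                 seed = as.integer(seed)),
            class = "exm_segmenter")
}

#' @export
print.exm_segmenter <- function(x, ...) {
  cat(sprintf("Pixel segmenter for channel '%s' (%d training rounds)\n",
              x$channel, x$training_rounds_completed))
  cat(sprintf("  features: intensity + smooth/gradient/Laplacian at %s nm\n",
              paste(x$scales_nm, collapse = ", ")))
  cat(sprintf("  final training error: %.4f (%d annotations)\n",
              utils::tail(x$history$training_error, 1),
              utils::tail(x$history$n_annotations, 1)))
  invisible(x)
}

#' Per-voxel class probabilities for one channel
#'
#' @param segmenter an `exm_segmenter`.
#' @param stack an `exm_stack`.
#' @param features optional precomputed feature matrix.
#' @return matrix with columns `signal` and `background`, rows summing to 1.
#' @export
predict_probabilities <- function(segmenter, stack, features = NULL) {
  if (is.null(features))
    features <- extract_features(stack, segmenter$channel,
                                 segmenter$scales_nm)
  if (ncol(features) != length(segmenter$model$center))
    stop_exm("feature configuration does not match the trained model",
             "exmloc_model_incompatibility")
  p <- predict_logistic(segmenter$model, features)
  cbind(signal = p, background = 1 - p)
}

#' Predict binary signal masks for the receptor and collagen channels
#'
#' Applies each channel's independently trained segmenter; a voxel is signal
#' when its signal probability strictly exceeds 1/2 (at exact ties background
#' wins, the conservative choice in low SNR).
#'
#' @param models named list with elements `receptor` and/or `collagen`, each
#'   an `exm_segmenter`.
#' @param stack an `exm_stack`.
#' @return named list of logical mask arrays, one per supplied model.
#' @export
predict_masks <- function(models, stack) {
  if (inherits(models, "exm_segmenter"))
    models <- stats::setNames(list(models), models$channel)
  out <- list()
  for (nm in names(models)) {
    p <- predict_probabilities(models[[nm]], stack)
    out[[nm]] <- array(p[, "signal"] > 0.5, stack$dim)
  }
  out
}

#' Classical spot segmentation baseline
#'
#' The conventional methods the trained segmenter is benchmarked against on
#' low-SNR stacks: global Otsu thresholding, or thresholded
#' Laplacian-of-Gaussian blob response.
#'
#' @param stack an `exm_stack`.
#' @param channel channel name.
#' @param method `"otsu"` or `"log_blobs"`.
#' @param scale_nm LoG scale in gel nm (log_blobs only).
#' @param k LoG threshold in robust sd units of the response (log_blobs only).
#' @return logical mask array.
#' @export
blob_fallback <- function(stack, channel, method = c("otsu", "log_blobs"),
                          scale_nm = 300, k = 4) {
  method <- match.arg(method)
  if (!channel %in% names(stack$channels))
    stop_exm(paste0("unknown channel: ", channel), "exmloc_channel")
  img <- stack$channels[[channel]]
  if (max(img) == min(img)) return(array(FALSE, dim(img)))
  if (method == "otsu") {
    norm <- (img - min(img)) / (max(img) - min(img))
    # one global threshold over the whole volume (EBImage's otsu is
    # per-frame on 3D images, so hand it a single flat frame)
    flat <- EBImage::Image(matrix(as.numeric(norm), ncol = 1))
    thr <- EBImage::otsu(flat, range = c(0, 1))
    array(norm > thr, dim(img))
  } else {
    sm <- blur_volume(img, scale_nm / stack$voxel_size_gel)
    resp <- -laplacian(sm, stack$voxel_size_gel)
    thr <- stats::median(resp) + k * stats::mad(resp)
    array(resp > thr & img > stats::median(img), dim(img))
  }
}
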