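# Patch classification: preprocessing, a trainable softmax network with an
# Adam/cross-entropy harness, and the deterministic oracle used to verify the
# severity and mapping stages independently of any trained model.

#' Bilinearly resize a square patch
#'
#' Patches enter the classifier at 224x224; this converts the native 128x128
#' windows with bilinear interpolation, clipping to \[0, 255\].
#'
#' @param patch S x S x 3 array, values 0..255.
#' @param target_side Output side in pixels (default 224).
#' @return target_side x target_side x 3 array, values in \[0, 255\].
#' @export
resize_patch <- function(patch, target_side = 224L) {
  assert_rgb_array(patch, "patch")
  d <- dim(patch)
  if (d[1] != d[2]) stop("patch must be square", call. = FALSE)
  if (d[1] == target_side) return(patch)
  img <- EBImage::Image(aperm(patch / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = target_side, h = target_side,
                         filter = "bilinear")
  pmin(pmax(aperm(as.array(out), c(2, 1, 3)) * 255, 0), 255)
}

#' Training configuration
#'
#' Hyperparameters of the patch-classifier training harness. Defaults: Adam,
#' learning rate 2.5e-4, 50 epochs, batch size 256, cross-entropy loss, six
#' output classes, 224-pixel input side. The seed is explicit: a fixed seed
#' with fixed data ordering gives bit-identical training runs.
#'
#' @param optimizer Optimizer name; only `"adam"` is provided.
#' @param learning_rate Step size (default 2.5e-4).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 256).
#' @param loss Loss name; only `"cross-entropy"` is provided.
#' @param n_classes Output classes (default 6).
#' @param input_side Input side after resize (default 224).
#' @param seed Integer RNG seed (required for training).
#' @param hidden Hidden-layer width of the network (default 64).
#' @param pool_grid Side of the average-pooling grid applied after resize
#'   (default 8, i.e. 8x8x3 = 192 pooled features).
#' @param class_weights `"none"` (default) or `"inverse-frequency"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 2.5e-4,
                         epochs = 50L, batch_size = 256L,
                         loss = "cross-entropy", n_classes = 6L,
                         input_side = 224L, seed = 1L, hidden = 64L,
                         pool_grid = 8L,
                         class_weights = c("none", "inverse-frequency")) {
  stopifnot(optimizer == "adam", loss == "cross-entropy",
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            n_classes >= 2, input_side >= pool_grid)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 loss = loss, n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side), seed = as.integer(seed),
                 hidden = as.integer(hidden), pool_grid = as.integer(pool_grid),
                 class_weights = match.arg(class_weights)),
            class = "train_config")
}

# Preprocessing shared by training and prediction: resize to input_side,
# scale to [0,1], average-pool to pool_grid x pool_grid per channel, flatten.
patch_features <- function(patch, config) {
  x <- resize_patch(patch, config$input_side) / 255
  side <- dim(x)[1]
  grp <- rep(seq_len(config$pool_grid), each = ceiling(side / config$pool_grid),
             length.out = side)
  pooled <- vapply(1:3, function(ch) {
    m <- rowsum(x[, , ch], grp)
    m <- t(rowsum(t(m), grp))
    as.vector(m / tabulate(grp)[row(m)] / tabulate(grp)[col(m)])
  }, numeric(config$pool_grid^2))
  as.numeric(pooled)
}

feature_matrix <- function(patches, config) {
  t(vapply(patches, patch_features, numeric(3 * config$pool_grid^2), config))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the patch classifier
#'
#' Fits a compact feed-forward network (average-pooled RGB features, one
#' ReLU hidden layer, softmax output) with minibatch Adam on the
#' cross-entropy loss. The model handle satisfies the same predict contract
#' as the oracle classifier, records its preprocessing (scale to \[0, 1\]
#' after bilinear resize) and returns a per-epoch loss/accuracy log.
#'
#' @param data A labeled patch set: list with `x` (list of S x S x 3 arrays)
#'   and `y` (integer class labels 0..5), e.g. the `train` element of
#'   [generate_labeled_patchset()].
#' @param config A [train_config()].
#' @return A model handle of class `ccemap_model` with elements `type`
#'   (`"mlp"`), `weights`, `config` and `log` (data.frame `epoch`, `loss`,
#'   `accuracy`).
#' @export
train_classifier <- function(data, config = train_config()) {
  if (length(data$x) == 0L) stop("training set is empty", call. = FALSE)
  y <- assert_label(data$y)
  if (length(unique(y)) < 2L) {
    stop("training set must contain at least two classes (cross-entropy is ",
         "degenerate on a single class)", call. = FALSE)
  }
  stopifnot(length(data$x) == length(y))
  X <- feature_matrix(data$x, config)
  n <- nrow(X); p <- ncol(X); k <- config$n_classes; h <- config$hidden
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), y + 1L)] <- 1
  w <- rep(1, n)
  if (config$class_weights == "inverse-frequency") {
    freq <- tabulate(y + 1L, nbins = k)
    cw <- ifelse(freq > 0, mean(freq[freq > 0]) / freq, 0)
    w <- cw[y + 1L]
  }

  withr::with_seed(config$seed, {
    W1 <- matrix(stats::rnorm(p * h, sd = sqrt(2 / p)), p, h)
    b1 <- numeric(h)
    W2 <- matrix(0, h, k)
    b2 <- numeric(k)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    m <- lapply(params, function(q) q * 0)
    v <- lapply(params, function(q) q * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      accuracy = numeric(0))

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0; epoch_correct <- 0
      for (b in batches) {
        Xb <- X[b, , drop = FALSE]; Yb <- Y[b, , drop = FALSE]
        wb <- w[b]
        H <- sweep(Xb %*% params$W1, 2, params$b1, "+")
        A <- pmax(H, 0)
        Z <- sweep(A %*% params$W2, 2, params$b2, "+")
        P <- softmax_rows(Z)
        li <- -log(pmax(rowSums(P * Yb), 1e-12))
        epoch_loss <- epoch_loss + sum(wb * li)
        epoch_correct <- epoch_correct +
          sum(max.col(P, ties.method = "first") == max.col(Yb))
        # backprop
        dZ <- (P - Yb) * wb / sum(wb)
        gW2 <- t(A) %*% dZ; gb2 <- colSums(dZ)
        dA <- dZ %*% t(params$W2)
        dH <- dA * (H > 0)
        gW1 <- t(Xb) %*% dH; gb1 <- colSums(dH)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        t_step <- t_step + 1
        for (nm in names(params)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - beta1^t_step)
          vhat <- v[[nm]] / (1 - beta2^t_step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   loss = epoch_loss / sum(w),
                                   accuracy = epoch_correct / n))
    }
    structure(list(type = "mlp", weights = params, config = config,
                   normalization = "scale-255-to-unit", log = log),
              class = "ccemap_model")
  })
}

#' @export
print.ccemap_model <- function(x, ...) {
  cat(sprintf("<ccemap_model type=%s>\n", x$type))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epochs, final loss %.4f, train accuracy %.3f\n",
                nrow(x$log), x$log$loss[nrow(x$log)],
                x$log$accuracy[nrow(x$log)]))
  }
  invisible(x)
}

#' Classify patches
#'
#' Runs the model on a list of patches and returns, for each, the predicted
#' class label (argmax of the six scores, ties broken to the lowest class
#' index) and the score vector (normalised to sum to 1). Input order is
#' preserved; prediction is pure (repeated calls agree exactly).
#'
#' @param model A `ccemap_model` handle from [train_classifier()] or
#'   [make_oracle_classifier()].
#' @param patches List of S x S x 3 arrays (resized internally), or a single
#'   such array.
#' @return data.frame with `label` (integer 0..5), `class` (name) and score
#'   columns `score_MES0` .. `score_ileal`.
#' @export
predict_patches <- function(model, patches) {
  stopifnot(inherits(model, "ccemap_model"))
  if (is.array(patches)) patches <- list(patches)
  for (p in patches) {
    if (!is.array(p) || length(dim(p)) != 3L || dim(p)[3] != 3L ||
        dim(p)[1] != dim(p)[2]) {
      stop("each patch must be a square S x S x 3 array", call. = FALSE)
    }
  }
  scores <- if (model$type == "oracle") {
    t(vapply(patches, oracle_scores, numeric(6), model))
  } else {
    X <- feature_matrix(patches, model$config)
    H <- pmax(sweep(X %*% model$weights$W1, 2, model$weights$b1, "+"), 0)
    Z <- sweep(H %*% model$weights$W2, 2, model$weights$b2, "+")
    softmax_rows(Z)
  }
  scores <- scores / rowSums(scores)
  label <- max.col(scores, ties.method = "first") - 1L
  out <- data.frame(label = label, class = CLASS_NAMES[label + 1L])
  colnames(scores) <- paste0("score_", CLASS_NAMES)
  cbind(out, as.data.frame(scores))
}

#' Texture signature key of the synthetic stills
#'
#' Synthetic textures encode their class in the red-minus-blue channel
#' offset: a pixel of class k has R = g + delta_k, B = g - delta_k for a
#' shared luminance field g. This key maps each class to its offset.
#'
#' @return data.frame with columns `label` (0..5) and `delta`.
#' @export
#' @seealso [generate_synthetic_still()], [make_oracle_classifier()]
synth_texture_key <- function() {
  data.frame(label = 0:5, delta = c(-25, -15, -5, 5, 15, 25))
}

#' Oracle classifier for synthetic textures
#'
#' A deterministic model handle honouring the [predict_patches()] contract.
#' It decodes the per-pixel texture signature (half the red-minus-blue
#' difference), assigns each pixel to the nearest key entry within
#' `tolerance`, and labels the patch by majority vote. Patches in which
#' fewer than half of the pixels carry a decodable signature are labelled
#' `inadequate` with a warning — the fallback for unknown content. The score
#' vector reports per-class pixel vote shares.
#'
#' @param texture_key Mapping from signature offset to class label; must
#'   cover all six classes (default [synth_texture_key()]).
#' @param tolerance Maximum |signature - key offset| for a pixel to vote
#'   (default 4; key offsets are 10 apart).
#' @return A model handle of class `ccemap_model` with `type = "oracle"`.
#' @export
make_oracle_classifier <- function(texture_key = synth_texture_key(),
                                   tolerance = 4) {
  stopifnot(all(0:5 %in% texture_key$label))
  structure(list(type = "oracle", key = texture_key, tolerance = tolerance),
            class = "ccemap_model")
}

# Vote shares of one patch under the oracle; warns on undecodable patches.
oracle_scores <- function(patch, model) {
  d <- (patch[, , 1] - patch[, , 3]) / 2
  centers <- model$key$delta
  labels <- model$key$label
  dist <- abs(outer(as.vector(d), centers, "-"))
  nearest <- max.col(-dist, ties.method = "first")
  decodable <- dist[cbind(seq_along(nearest), nearest)] <= model$tolerance
  votes <- numeric(6)
  if (any(decodable)) {
    tab <- tabulate(labels[nearest[decodable]] + 1L, nbins = 6)
    votes[seq_len(6)] <- tab
  }
  if (sum(decodable) < length(nearest) / 2) {
    warning("patch carries no decodable texture signature; ",
            "labelling as inadequate", call. = FALSE)
    votes <- c(0, 0, 0, 0, 1, 0)
    return(votes)
  }
  votes / sum(votes)
}
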