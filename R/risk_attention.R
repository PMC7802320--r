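#' Hyperparameters for the attention-weighted classifier
#'
#' @param embed_size Embedding dimension `e`.
#' @param hidden Integer vector of MLP hidden layer widths (ReLU).
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); set `Inf` to disable.
#' @param val_frac Fraction of samples held out (stratified) for early
#'   stopping.
#' @param class_weights `"balanced"` for inverse-frequency weights or a
#'   named numeric vector over classes.
#' @return List of class `attention_hyper`.
#' @export
attention_hyper <- function(embed_size = 32, hidden = c(64, 16), lr = 1e-3,
                            epochs = 200, batch_size = 32, patience = 20,
                            val_frac = 0.1, class_weights = "balanced") {
  structure(list(embed_size = as.integer(embed_size), hidden = as.integer(hidden),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), patience = patience,
                 val_frac = val_frac, class_weights = class_weights),
            class = "attention_hyper")
}

#' Construct an attention model from explicit parameters
#'
#' Mainly for testing and serialization round-trips; [train_attention()] is
#' the normal entry point. The forward pass is
#' `r = sum_j x_j * W_j * E_j` (an `e`-vector), followed by the MLP layers
#' and a softmax over the two class logits (column 1 = non-cancer,
#' column 2 = cancer).
#'
#' @param W Per-deletion scalar weight vector (length `m`).
#' @param E Embedding table, `m` x `e`.
#' @param layers List of layers, each `list(W = <matrix>, b = <vector>,
#'   act = "relu"|"identity")`; the last layer must output 2 logits.
#' @param dsv_ids Optional deletion ids (defaults to names of `W`).
#' @return List of class `attention_model`.
#' @export
attention_model <- function(W, E, layers, dsv_ids = names(W)) {
  E <- as.matrix(E)
  if (length(W) != nrow(E)) stop("length(W) must equal nrow(E)")
  if (is.null(dsv_ids)) dsv_ids <- sprintf("DSV%04d", seq_along(W))
  structure(list(W = stats::setNames(as.numeric(W), dsv_ids), E = E,
                 layers = layers, dsv_ids = dsv_ids),
            class = "attention_model")
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Forward pass of the attention-weighted model
#'
#' @param model An `attention_model`.
#' @param x Binary deletion vector of length `m`, or an `n x m` matrix.
#' @return Matrix of class probabilities (`n x 2`, columns `non-cancer`,
#'   `cancer`), rows summing to 1.
#' @export
attention_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$W))
    stop("input has ", ncol(x), " deletions; model expects ", length(model$W))
  h <- (x %*% (model$W * model$E))   # r_{n,e} = sum_j x_j W_j E_j
  for (ly in model$layers) {
    h <- sweep(h %*% ly$W, 2, ly$b, "+")
    if (identical(ly$act, "relu")) h <- relu(h)
  }
  if (ncol(h) != 2) stop("final layer must produce 2 logits")
  p <- softmax_rows(h)
  colnames(p) <- c("non-cancer", "cancer")
  p
}

#' Predict cancer probabilities
#' @param object An `attention_model`.
#' @param newdata Carrier matrix (`carrier_matrix` or plain binary matrix).
#' @param ... Unused.
#' @return Numeric vector of cancer-class probabilities.
#' @export
predict.attention_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "carrier_matrix")) newdata$carriers else newdata
  attention_forward(object, X)[, "cancer"]
}

# One Adam step for a list of parameter matrices; state carries m/v moments.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Forward + loss + gradients for one batch. Parameters are a flat named
# list: W, E, L1.W, L1.b, ..., with ReLU on all but the last layer.
attention_batch <- function(params, n_hidden, xb, yb, wb, want_grad = TRUE) {
  xw <- sweep(xb, 2, params$W, "*")
  acts <- list(xw %*% params$E)
  n_layers <- n_hidden + 1L
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% params[[paste0("L", l, ".W")]], 2,
               params[[paste0("L", l, ".b")]], "+")
    acts[[l + 1L]] <- if (l < n_layers) relu(z) else z
  }
  p <- softmax_rows(acts[[n_layers + 1L]])
  eps <- 1e-12
  ll <- -log(ifelse(yb == 1L, p[, 2], p[, 1]) + eps)
  loss <- sum(wb * ll) / length(yb)
  if (!want_grad) return(list(loss = loss, p = p))

  Y <- cbind(1 - yb, yb)
  dlogit <- (p - Y) * wb / length(yb)
  grads <- list()
  dh <- dlogit
  for (l in rev(seq_len(n_layers))) {
    grads[[paste0("L", l, ".W")]] <- t(acts[[l]]) %*% dh
    grads[[paste0("L", l, ".b")]] <- colSums(dh)
    dh <- dh %*% t(params[[paste0("L", l, ".W")]])
    if (l > 1L) dh <- dh * (acts[[l]] > 0)
  }
  dr <- dh  # gradient at the embedding sum r
  grads$E <- t(xw) %*% dr
  grads$W <- colSums(xb * (dr %*% t(params$E)))
  list(loss = loss, p = p, grads = grads)
}

#' Train the attention-weighted cancer risk classifier
#'
#' Minimizes class-weighted binary cross-entropy by mini-batch Adam. The
#' per-deletion weight vector is initialized to small positive values
#' (uniform on \[0, 0.1\]) and left unconstrained during training; the
#' embedding table is Gaussian with sd `1/sqrt(e)`. A stratified validation
#' split drives early stopping. Deterministic given the seed.
#'
#' @param carriers A `carrier_matrix` or plain binary matrix (samples x
#'   deletions).
#' @param labels Per-sample labels; `"cancer"` is the positive class.
#' @param hyper An [attention_hyper()].
#' @param seed Integer seed.
#' @return A trained `attention_model` with `loss_history` (per-epoch train
#'   and validation loss) attached.
#' @export
train_attention <- function(carriers, labels, hyper = attention_hyper(),
                            seed = 1L) {
  X <- if (inherits(carriers, "carrier_matrix")) carriers$carriers else carriers
  y <- as.integer(labels == "cancer")
  if (length(unique(y)) < 2) stop("both classes must be present")
  set.seed(as.integer(seed))
  n <- nrow(X); m <- ncol(X); e <- hyper$embed_size

  if (identical(hyper$class_weights, "balanced")) {
    w_class <- n / (2 * c(`0` = sum(y == 0), `1` = sum(y == 1)))
  } else {
    w_class <- c(`0` = hyper$class_weights[["non-cancer"]],
                 `1` = hyper$class_weights[["cancer"]])
  }
  wts <- unname(w_class[as.character(y)])

  # stratified validation split
  val_idx <- integer(0)
  if (hyper$val_frac > 0) {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      nv <- floor(length(idx) * hyper$val_frac)
      if (nv >= 1) val_idx <- c(val_idx, sample(idx, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  sizes <- c(e, hyper$hidden, 2L)
  params <- list(W = stats::runif(m, 0, 0.1),
                 E = matrix(stats::rnorm(m * e, 0, 1 / sqrt(e)), m, e))
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    params[[paste0("L", l, ".W")]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                                          0, sqrt(2 / fan_in)),
                                             fan_in, sizes[l + 1L])
    params[[paste0("L", l, ".b")]] <- rep(0, sizes[l + 1L])
  }
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))

  n_hidden <- length(hyper$hidden)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  t_step <- 0L
  for (ep in seq_len(hyper$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
    ep_loss <- 0
    for (b in batches) {
      res <- attention_batch(params, n_hidden, X[b, , drop = FALSE], y[b], wts[b])
      t_step <- t_step + 1L
      upd <- adam_step(params, res$grads, state, hyper$lr, t_step)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + res$loss * length(b)
    }
    ep_loss <- ep_loss / length(ord)
    val_loss <- if (length(val_idx) > 0)
      attention_batch(params, n_hidden, X[val_idx, , drop = FALSE],
                      y[val_idx], wts[val_idx], want_grad = FALSE)$loss
    else ep_loss
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                         val_loss = val_loss))
    if (val_loss < best$loss - 1e-9) best <- list(loss = val_loss, params = params, epoch = ep)
    if (is.finite(hyper$patience) && ep - best$epoch >= hyper$patience) break
  }
  params <- best$params

  layers <- lapply(seq_len(n_hidden + 1L), function(l)
    list(W = params[[paste0("L", l, ".W")]], b = params[[paste0("L", l, ".b")]],
         act = if (l <= n_hidden) "relu" else "identity"))
  model <- attention_model(params$W, params$E, layers,
                           dsv_ids = colnames(X) %||% sprintf("DSV%04d", seq_len(m)))
  model$hyper <- hyper
  model$seed <- as.integer(seed)
  model$loss_history <- history
  model$final_loss <- utils::tail(history$train_loss, 1)
  model
}

#' Select deletions with strictly positive attention weights
#'
#' The risk-feature selection rule: deletions whose learned scalar weight
#' `W_j` is strictly > 0, in original column order.
#'
#' @param model A trained `attention_model`.
#' @return Character vector of deletion ids (possibly empty, with a
#'   warning).
#' @export
select_positive_weight_dsvs <- function(model) {
  stopifnot(inherits(model, "attention_model"))
  sel <- model$dsv_ids[model$W > 0]
  if (length(sel) == 0) warning("no deletions with positive weight")
  sel
}

#' Stratified k-fold cross-validation of risk classifiers
#'
#' Benchmarks the attention-weighted model against a plain MLP, a linear
#' SVM, logistic regression and a random forest under stratified k-fold
#' cross-validation. Reports rank-based AUC plus sensitivity and
#' specificity at the 0.5 probability cutoff ("cancer" positive).
#'
#' @param carriers A `carrier_matrix` or binary matrix.
#' @param labels Per-sample labels ("cancer" / "non-cancer").
#' @param models Subset of `c("attention", "mlp", "svm", "logistic", "rf")`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and model training.
#' @param hyper [attention_hyper()] for the attention model.
#' @return List of class `cv_report`: `metrics` (per model and fold),
#'   `summary` (per-model means), `folds`, `seed`.
#' @export
crossvalidate <- function(carriers, labels,
                          models = c("attention", "mlp", "svm", "logistic", "rf"),
                          k = 5, seed = 1L, hyper = attention_hyper()) {
  X <- if (inherits(carriers, "carrier_matrix")) carriers$carriers else carriers
  y <- factor(ifelse(labels == "cancer", "cancer", "non-cancer"),
              levels = c("non-cancer", "cancer"))
  n <- nrow(X)
  if (n < k) stop("need at least k samples")
  if (min(table(y)) < k) stop("each class needs at least k samples for stratified folds")
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }

  metrics <- list()
  for (f in seq_len(k)) {
    te <- fold == f; tr <- !te
    xtr <- X[tr, , drop = FALSE]; xte <- X[te, , drop = FALSE]
    ytr <- y[tr]; yte <- y[te]
    for (mod in models) {
      prob <- switch(mod,
        attention = {
          fit <- train_attention(xtr, as.character(ytr), hyper,
                                 seed = substream_seed(seed, 100L + f))
          predict(fit, xte)
        },
        mlp = {
          fit <- nnet::nnet(xtr, stats::model.matrix(~ ytr - 1)[, 2],
                            size = 16, decay = 0.01, maxit = 200,
                            entropy = TRUE, trace = FALSE)
          as.numeric(stats::predict(fit, xte))
        },
        svm = {
          fit <- e1071::svm(xtr, ytr, kernel = "linear", probability = TRUE)
          pr <- attr(stats::predict(fit, xte, probability = TRUE), "probabilities")
          pr[, "cancer"]
        },
        logistic = {
          df_tr <- data.frame(y = as.integer(ytr == "cancer"), xtr)
          fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                             family = stats::binomial()))
          as.numeric(suppressWarnings(stats::predict(fit, data.frame(xte),
                                                     type = "response")))
        },
        rf = {
          fit <- randomForest::randomForest(xtr, ytr, ntree = 300)
          stats::predict(fit, xte, type = "prob")[, "cancer"]
        },
        stop("unknown model: ", mod))
      pos <- yte == "cancer"
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = mod, fold = f,
        auc = auc_rank(prob, pos),
        sensitivity = mean(prob[pos] >= 0.5),
        specificity = mean(prob[!pos] < 0.5),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  summ <- do.call(rbind, lapply(split(metrics, metrics$model), function(d)
    data.frame(model = d$model[1], auc = mean(d$auc),
               sensitivity = mean(d$sensitivity),
               specificity = mean(d$specificity), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(metrics = metrics, summary = summ, folds = fold,
                 seed = as.integer(seed)), class = "cv_report")
}

#' PCA projection of samples on selected deletions
#'
#' Centers the carrier submatrix and projects samples on the top principal
#' axes.
#'
#' @param carriers A `carrier_matrix` or binary matrix.
#' @param dsv_ids Columns to use (default: all).
#' @param n_components Number of components (default 2).
#' @return List with `scores` (samples x components), `sdev`, and
#'   `var_explained`.
#' @export
pca_projection <- function(carriers, dsv_ids = NULL, n_components = 2) {
  X <- if (inherits(carriers, "carrier_matrix")) carriers$carriers else carriers
  if (!is.null(dsv_ids)) X <- X[, dsv_ids, drop = FALSE]
  if (ncol(X) < 2) stop("need >= 2 deletions for PCA")
  if (all(apply(X, 2, stats::var) == 0)) stop("zero-variance input; PCA undefined")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       sdev = pc$sdev,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Hierarchical clustering of deletion carrier profiles
#'
#' Agglomerative clustering of deletions (columns) on the Jaccard distance
#' between their binary carrier profiles, average linkage by default, with
#' the tree cut at `k` clusters.
#'
#' @param carriers A `carrier_matrix` or binary matrix.
#' @param dsv_ids Columns to cluster (default: all).
#' @param k Number of clusters (default 2).
#' @param linkage Linkage method for [stats::hclust()].
#' @return List with `clusters` (named integer vector per deletion) and
#'   `tree` (the `hclust` object).
#' @export
cluster_dsvs <- function(carriers, dsv_ids = NULL, k = 2, linkage = "average") {
  X <- if (inherits(carriers, "carrier_matrix")) carriers$carriers else carriers
  if (!is.null(dsv_ids)) X <- X[, dsv_ids, drop = FALSE]
  if (k > ncol(X)) stop("k exceeds the number of deletions")
  d <- stats::dist(t(X), method = "binary")  # Jaccard distance on 0/1 profiles
  tree <- stats::hclust(d, method = linkage)
  list(clusters = stats::cutree(tree, k = k), tree = tree)
}
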