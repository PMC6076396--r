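#' Majority vote over per-frame predictions
#'
#' @param preds integer vector of 0-based per-frame class predictions.
#' @param n_classes number of classes.
#' @return the winning 0-based class; ties resolve to the lowest index.
#' @export
majority_vote <- function(preds, n_classes) {
  counts <- tabulate(preds + 1L, nbins = n_classes)
  which.max(counts) - 1L
}

#' Hand-crafted-features + SVM baseline
#'
#' The temporal-information-free baseline: a radial-basis support vector
#' machine on standardized per-frame hand-crafted features predicts an
#' accession for every frame, and a plant's sequence label is the majority
#' vote over its frames (ties to the lowest class index). Training and test
#' sets must always be split by plant, never by frame.
#'
#' @param features feature tibble as returned by [extract_features_table()]
#'   (columns `plant_id`, `genotype`, `day`, then feature columns).
#' @param n_classes number of genotype classes; defaults to the number of
#'   distinct training genotypes.
#' @param cost SVM cost parameter.
#' @return a `phenoseq_svm` object.
#' @export
svm_baseline <- function(features, n_classes = NULL, cost = 1) {
  meta <- c("plant_id", "genotype", "day")
  stopifnot(all(meta %in% names(features)))
  y <- features$genotype
  if (is.null(n_classes)) n_classes <- length(unique(y))
  if (length(unique(y)) < n_classes)
    stop("a class is absent from training data", call. = FALSE)
  x <- as.matrix(features[, setdiff(names(features), meta)])
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("all features are constant", call. = FALSE)
  fit <- e1071::svm(x = x[, keep, drop = FALSE],
                    y = factor(y, levels = sort(unique(y))),
                    kernel = "radial", cost = cost, scale = TRUE)
  structure(list(fit = fit, keep = keep, n_classes = as.integer(n_classes),
                 feature_names = colnames(x)),
            class = "phenoseq_svm")
}

#' @rdname svm_baseline
#' @param object a `phenoseq_svm`.
#' @param ... unused.
#' @return for `predict()`: tibble with one row per plant (`plant_id`,
#'   `genotype` if present, frame-vote prediction `pred`).
#' @export
predict.phenoseq_svm <- function(object, features, ...) {
  x <- as.matrix(features[, object$feature_names, drop = FALSE])
  frame_pred <- as.integer(as.character(
    stats::predict(object$fit, x[, object$keep, drop = FALSE])))
  tb <- tibble::tibble(plant_id = features$plant_id, frame_pred = frame_pred)
  if ("genotype" %in% names(features)) tb$genotype <- features$genotype
  out <- dplyr::summarise(
    dplyr::group_by(tb, .data$plant_id),
    genotype = if ("genotype" %in% names(tb)) .data$genotype[1] else NA_integer_,
    pred = majority_vote(.data$frame_pred, object$n_classes),
    .groups = "drop")
  out
}

#' Linear-chain CRF sequence baseline
#'
#' A conditional random field over a plant's frame sequence in which all
#' frames share one accession label: per-frame unary scores are a linear map
#' of the frame features to the L classes, plus an L x L transition matrix
#' whose diagonal rewards label persistence along the chain. Under the
#' shared-label constraint the total path score of class y for a T-frame
#' sequence is `sum_t u_t(y) + (T-1) A[y, y]`, and maximum-likelihood fitting
#' reduces to a convex problem solved by BFGS with an L2 penalty.
#'
#' @param sequences list of T x D feature matrices (deep features).
#' @param labels 0-based genotype labels.
#' @param n_classes number of classes L.
#' @param lambda L2 regularisation weight on W and A.
#' @param maxit BFGS iteration cap.
#' @param standardize z-score features with training statistics.
#' @return a `phenoseq_crf` model.
#' @export
crf_baseline <- function(sequences, labels, n_classes = NULL, lambda = 1e-3,
                         maxit = 200, standardize = TRUE) {
  stopifnot(length(sequences) == length(labels))
  if (any(vapply(sequences, nrow, integer(1)) < 1L)) stop("empty sequence", call. = FALSE)
  labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- length(unique(labels))
  L <- n_classes
  D <- ncol(sequences[[1]])
  if (standardize) {
    allx <- do.call(rbind, sequences)
    ctr <- colMeans(allx); scl <- pmax(apply(allx, 2, sd), 1e-8)
  } else { ctr <- numeric(D); scl <- rep(1, D) }
  seqs <- lapply(sequences, function(s) sweep(sweep(s, 2, ctr), 2, scl, `/`))
  S <- t(vapply(seqs, colSums, numeric(D)))        # N x D summed features
  Tv <- vapply(seqs, nrow, integer(1))
  N <- length(seqs)
  Y <- cbind(seq_len(N), labels + 1L)

  unpack <- function(par) {
    W <- matrix(par[seq_len(D * L)], D, L)
    b <- par[D * L + seq_len(L)]
    A <- matrix(par[D * L + L + seq_len(L * L)], L, L)
    list(W = W, b = b, A = A)
  }
  scores_of <- function(p) S %*% p$W + outer(Tv, p$b) + outer(Tv - 1, diag(p$A))
  fn <- function(par) {
    p <- unpack(par)
    sc <- scores_of(p)
    m <- apply(sc, 1, max)
    nll <- sum(m + log(rowSums(exp(sc - m))) - sc[Y])
    nll + lambda * (sum(p$W^2) + sum(p$A^2))
  }
  gr <- function(par) {
    p <- unpack(par)
    sc <- scores_of(p)
    P <- softmax_rows(sc)
    G <- P; G[Y] <- G[Y] - 1
    dW <- crossprod(S, G) + 2 * lambda * p$W
    db <- colSums(G * Tv)
    dA <- 2 * lambda * p$A
    diag(dA) <- diag(dA) + colSums(G * (Tv - 1))
    c(as.vector(dW), db, as.vector(dA))
  }
  par0 <- numeric(D * L + L + L * L)
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  p <- unpack(opt$par)
  crf_model(p$W, p$b, p$A, center = ctr, scale = scl, value = opt$value)
}

#' @rdname crf_baseline
#' @param W D x L unary weight matrix.
#' @param b length-L unary bias.
#' @param A L x L transition matrix.
#' @param center,scale feature standardisation applied before scoring.
#' @param value training objective value (optional bookkeeping).
#' @export
crf_model <- function(W, b, A, center = numeric(nrow(W)), scale = rep(1, nrow(W)),
                      value = NA_real_) {
  stopifnot(ncol(W) == length(b), all(dim(A) == length(b)))
  structure(list(W = W, b = b, A = A, center = center, scale = scale,
                 n_classes = length(b), value = value),
            class = "phenoseq_crf")
}

#' @rdname crf_baseline
#' @param model a `phenoseq_crf`.
#' @param sequence one T x D feature matrix.
#' @return `crf_sequence_scores()`: normalised class scores (softmax of the
#'   shared-label path scores).
#' @export
crf_sequence_scores <- function(model, sequence) {
  stopifnot(inherits(model, "phenoseq_crf"))
  s <- sweep(sweep(sequence, 2, model$center), 2, model$scale, `/`)
  TT <- nrow(s)
  sc <- colSums(s %*% model$W) + TT * model$b + (TT - 1) * diag(model$A)
  drop(softmax_rows(matrix(sc, 1)))
}

#' @rdname crf_baseline
#' @param object a `phenoseq_crf`.
#' @param ... unused.
#' @export
predict.phenoseq_crf <- function(object, sequences, ...) {
  t(vapply(sequences, function(s) crf_sequence_scores(object, s),
           numeric(object$n_classes)))
}
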