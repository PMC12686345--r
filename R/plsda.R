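#' One-hot encode class labels
#'
#' Standard PLS-DA response coding: an `n x K` indicator matrix with a single
#' 1 per row, in the column of the spectrum's class.
#'
#' @param labels Character vector of class labels.
#' @param class_order Ordered class set; every label must appear in it.
#' @return Numeric `n x K` indicator matrix with `class_order` as column
#'   names.
#' @export
encode_onehot <- function(labels, class_order) {
  labels <- as.character(labels)
  idx <- match(labels, class_order)
  if (anyNA(idx)) {
    stop("encoding error: unknown label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  Y <- matrix(0, nrow = length(labels), ncol = length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(labels), idx)] <- 1
  Y
}

#' Fit a PLS-DA model by NIPALS
#'
#' PLS2 regression of a one-hot class indicator matrix on mean-centered
#' spectra, extracted component by component with the NIPALS algorithm:
#' starting from the first response column, the weight/score/loading updates
#' are iterated to convergence, then both blocks are deflated by the
#' extracted component. No variance scaling of the bands is applied by
#' default: after internal-standard normalization all bands share a physical
#' intensity scale, and autoscaling would inflate pure-noise channels.
#'
#' The per-component explained response sum of squares
#' \eqn{SSY_a = \|t_a\|^2 \sum_k q_{ka}^2} is stored for VIP scoring, and the
#' regression coefficient matrix \eqn{B = W (P'W)^{-1} Q'} for direct
#' prediction. Each weight column's sign is fixed so its largest-magnitude
#' entry is positive, making fits reproducible across platforms.
#'
#' @param X Numeric `n x p` predictor matrix (spectra in rows).
#' @param Y Numeric `n x K` response indicator matrix (see [encode_onehot()]).
#' @param ncomp Number of latent components `A` (default 2);
#'   `A <= min(n - 1, p)`.
#' @param scale Logical; if `TRUE`, bands are additionally scaled to unit
#'   variance (off by default, see above).
#' @param tol,max_iter NIPALS convergence tolerance on the score vector and
#'   iteration cap.
#' @return An object of class `plsda_model` with fields `class_order`,
#'   `x_mean`, `y_mean`, `x_scale`, `weights` (W, `p x A`), `loadings`
#'   (P, `p x A`), `y_loadings` (Q, `K x A`), `scores` (T, `n x A`),
#'   `coefficients` (B, `p x K`), `ssy` (length-`A` explained response sums
#'   of squares) and `ncomp`.
#' @export
fit_plsda <- function(X, Y, ncomp = 2, scale = FALSE,
                      tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); K <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("X and Y must be finite", call. = FALSE)
  }
  if (ncomp > min(n - 1, p)) {
    stop("ncomp (", ncomp, ") exceeds min(n - 1, p) = ", min(n - 1, p),
         call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean)
  if (scale) {
    x_scale <- apply(Xc, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2L, x_scale, `/`)
  } else {
    x_scale <- rep(1, p)
  }
  if (all(abs(Xc) < .Machine$double.eps * 100)) {
    stop("degenerate input: X has zero variance", call. = FALSE)
  }
  Yc <- sweep(Y, 2L, y_mean)

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, K, ncomp); Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, 1L]                    # deterministic start: first Y column
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1L]
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt)[, 1L] / sum(tt^2)
      u <- (Yd %*% q)[, 1L] / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    # sign convention: largest-|.| weight entry positive
    s <- sign(w[which.max(abs(w))])
    if (s < 0) { w <- -w; tt <- -tt; q <- -q }
    pvec <- crossprod(Xd, tt)[, 1L] / sum(tt^2)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; Tm[, a] <- tt
    ssy[a] <- sum(tt^2) * sum(q^2)
    Xd <- Xd - tcrossprod(tt, pvec)
    Yd <- Yd - tcrossprod(tt, q)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  rownames(B) <- colnames(X); colnames(B) <- colnames(Y)
  structure(list(class_order = colnames(Y), x_mean = x_mean, y_mean = y_mean,
                 x_scale = x_scale, weights = W, loadings = P, y_loadings = Q,
                 scores = Tm, coefficients = B, ssy = ssy, ncomp = ncomp,
                 scaled = scale),
            class = "plsda_model")
}

#' Fit a PLS-DA model to a spectral dataset
#'
#' Convenience wrapper: one-hot encodes the dataset labels in the dataset's
#' declared class order and calls [fit_plsda()] on the intensity matrix.
#' The model is fitted on the entire spectrum as stored (crop beforehand
#' with [crop_range()] if a window is wanted).
#'
#' @param dataset A preprocessed [spectral_dataset()].
#' @param ncomp Number of latent components (default 2).
#' @param ... Further arguments to [fit_plsda()].
#' @return A `plsda_model`.
#' @export
fit_plsda_dataset <- function(dataset, ncomp = 2, ...) {
  Y <- encode_onehot(dataset$labels, dataset$class_order)
  X <- dataset$intensities
  colnames(X) <- format(dataset$grid, trim = TRUE, scientific = FALSE)
  model <- fit_plsda(X, Y, ncomp = ncomp, ...)
  model$grid <- dataset$grid
  model
}

#' Predict continuous class responses
#'
#' \eqn{\hat Y = (X - \bar x) B + \bar y}: the continuous PLS regression
#' response used both for the argmax class decision and as the score input
#' to one-vs-rest ROC analysis.
#'
#' @param model A fitted `plsda_model`.
#' @param X Numeric `m x p` matrix on the same band grid as the training
#'   data, or a `spectral_dataset`.
#' @return Numeric `m x K` matrix of continuous scores.
#' @export
predict_response <- function(model, X) {
  if (inherits(X, "spectral_dataset")) X <- X$intensities
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("dimension mismatch: model expects ", length(model$x_mean),
         " bands, got ", ncol(X), call. = FALSE)
  }
  Xc <- sweep(X, 2L, model$x_mean)
  if (model$scaled) Xc <- sweep(Xc, 2L, model$x_scale, `/`)
  Yhat <- Xc %*% model$coefficients
  Yhat <- sweep(Yhat, 2L, model$y_mean, `+`)
  colnames(Yhat) <- model$class_order
  Yhat
}

#' Hard class assignment
#'
#' Assigns each spectrum to the class whose continuous response is largest;
#' exact ties go to the earliest class in the model's class order.
#'
#' @inheritParams predict_response
#' @return Character vector of predicted class labels.
#' @export
classify <- function(model, X) {
  Yhat <- predict_response(model, X)
  model$class_order[apply(Yhat, 1L, which.max)]
}

#' Variable importance in projection
#'
#' Wold's VIP for multi-response PLS:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with \eqn{SSY_a} the per-component explained response sum of squares
#' summed over all response columns. The squared scores average to 1 across
#' bands, so VIP > 1 marks bands contributing more than an average band to
#' the class separation.
#'
#' @param model A fitted `plsda_model`.
#' @param threshold Selection threshold (default 1.0).
#' @return An object of class `vip_result` with fields `vip` (one score per
#'   band, named by band when the model was fitted through
#'   [fit_plsda_dataset()]), `threshold` and `selected_bands` (wavenumbers
#'   with VIP strictly above threshold, sorted by descending VIP).
#' @export
compute_vip <- function(model, threshold = 1.0) {
  stopifnot(inherits(model, "plsda_model"))
  if (all(model$ssy == 0)) {
    stop("degenerate model: no explained response variance", call. = FALSE)
  }
  W <- model$weights
  wnorm2 <- colSums(W^2)
  p <- nrow(W)
  num <- (W^2 %*% (model$ssy / wnorm2))[, 1L]
  vip <- sqrt(p * num / sum(model$ssy))
  if (!is.null(model$grid)) names(vip) <- format(model$grid, trim = TRUE,
                                                 scientific = FALSE)
  structure(list(vip = vip, threshold = threshold,
                 grid = model$grid,
                 selected_bands = select_bands_internal(vip, model$grid,
                                                       threshold)),
            class = "vip_result")
}

select_bands_internal <- function(vip, grid, threshold) {
  keep <- which(vip > threshold)
  keep <- keep[order(vip[keep], decreasing = TRUE)]
  if (is.null(grid)) keep else grid[keep]
}

#' Threshold a VIP result into a discriminant band set
#'
#' @param vip A `vip_result`.
#' @param threshold Selection threshold (>= 0); bands with VIP strictly
#'   greater are kept.
#' @return Wavenumbers (or band indices when the model carried no grid)
#'   sorted by descending VIP.
#' @export
select_bands <- function(vip, threshold = vip$threshold) {
  stopifnot(inherits(vip, "vip_result"), threshold >= 0)
  select_bands_internal(vip$vip, vip$grid, threshold)
}

#' Serialize a PLS-DA model to JSON
#'
#' Stores class order, centering vectors, weights, loadings, coefficients
#' and explained response variance; [read_plsda_model()] restores a model
#' usable for prediction and VIP scoring.
#'
#' @param model A `plsda_model`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_plsda_model <- function(model, path) {
  payload <- list(
    class_order = model$class_order, x_mean = model$x_mean,
    y_mean = model$y_mean, x_scale = model$x_scale,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, coefficients = model$coefficients,
    ssy = model$ssy, ncomp = model$ncomp, scaled = model$scaled,
    grid = model$grid
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a PLS-DA model written by [write_plsda_model()]
#'
#' @param path JSON path.
#' @return A `plsda_model` (without training scores).
#' @export
read_plsda_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "loadings", "y_loadings", "coefficients")) {
    m[[f]] <- as.matrix(m[[f]])
  }
  m$coefficients <- matrix(as.numeric(m$coefficients),
                           nrow = length(m$x_mean),
                           dimnames = list(NULL, m$class_order))
  structure(m, class = "plsda_model")
}
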