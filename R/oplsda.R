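## Orthogonal PLS discriminant analysis (OPLS-DA), implemented from scratch.
##
## For a single coded class response y the model splits the scaled predictor
## matrix X into one predictive latent component and n_orth components
## orthogonal to y:
##   w  prop X'y (unit norm);  t = X w;  p = X't / t't
##   w_o = p - (w'p) w (unit norm);  t_o = X w_o;  p_o = X't_o / t_o't_o
##   X <- X - t_o p_o'   (repeat n_orth times, then refit the predictive
##   component on the filtered X and regress y on its score)
## Orthogonal scores satisfy t_o'y = 0 by construction because w_o is
## orthogonal to w prop X'y.

#' Unit-variance scale a descriptor matrix
#'
#' Mean-centres each column and divides by its sample standard deviation
#' (n - 1 denominator), the conventional preprocessing for chemometric
#' discriminant models.
#'
#' @param x Numeric matrix, data frame, or `descriptor_matrix`.
#' @return List with `x` (scaled matrix), `center` and `scale` (named).
#' @export
uv_scale <- function(x) {
  m <- if (inherits(x, "descriptor_matrix")) as.matrix(x) else as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric", call. = FALSE)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, sd)
  zero <- sdv < .Machine$double.eps^0.5
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  list(x = scale(m, mu, sdv), center = mu, scale = sdv)
}

## y as named numeric codes; levels taken from names(y_codes)
code_response <- function(y, y_codes) {
  lev <- names(y_codes)
  y <- as.character(y)
  bad <- setdiff(unique(y), lev)
  if (length(bad))
    stop("class labels not covered by y_codes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  unname(y_codes[y])
}

decode_class <- function(yhat, y_codes, threshold) {
  ## positive class = the label with the larger code; ties classify positive
  pos <- names(y_codes)[which.max(y_codes)]
  neg <- names(y_codes)[which.min(y_codes)]
  ifelse(yhat >= threshold, pos, neg)
}

## one pass of the component extraction on already-scaled data
opls_components <- function(xs, yc, n_orth) {
  xd <- xs
  w_o <- p_o <- t_o <- NULL
  if (n_orth > 0) {
    for (k in seq_len(n_orth)) {
      w <- drop(crossprod(xd, yc))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-10)
        stop("predictive weight degenerate; reduce n_orth", call. = FALSE)
      w <- w / nw
      tt <- drop(xd %*% w)
      p <- drop(crossprod(xd, tt)) / sum(tt^2)
      wo <- p - sum(w * p) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-10)
        stop("orthogonal component ", k,
             " has norm below 1e-10; use a smaller n_orth", call. = FALSE)
      wo <- wo / nwo
      to <- drop(xd %*% wo)
      po <- drop(crossprod(xd, to)) / sum(to^2)
      xd <- xd - tcrossprod(to, po)
      w_o <- cbind(w_o, wo); p_o <- cbind(p_o, po); t_o <- cbind(t_o, to)
    }
  }
  w <- drop(crossprod(xd, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-10)
    stop("predictive weight degenerate; reduce n_orth", call. = FALSE)
  w <- w / nw
  tt <- drop(xd %*% w)
  p <- drop(crossprod(xd, tt)) / sum(tt^2)
  b <- sum(tt * yc) / sum(tt^2)
  list(w = w, p = p, t = tt, b = b, W_o = w_o, P_o = p_o, T_o = t_o,
       x_deflated = xd)
}

## strip stored orthogonal components from new scaled data, return scores
strip_orthogonal <- function(xs, W_o, P_o) {
  t_o <- NULL
  if (!is.null(W_o)) {
    for (k in seq_len(ncol(W_o))) {
      to <- drop(xs %*% W_o[, k])
      xs <- xs - tcrossprod(to, P_o[, k])
      t_o <- cbind(t_o, to)
    }
  }
  list(xs = xs, t_o = t_o)
}

#' Fit an OPLS-DA classifier
#'
#' `oplsda()` is the formula front end (`group ~ .` on a data frame holding
#' the descriptor columns); `fit_oplsda()` takes a predictor matrix and a
#' label vector directly.  Predictors are unit-variance scaled; class labels
#' are coded numerically (default A = 0, B = 1), centred, and regressed on
#' the predictive latent score after removal of the y-orthogonal components.
#'
#' The number of orthogonal components defaults to `"auto"`: starting from
#' none, a component is added only while the cross-validated Q2 improves by
#' more than 0.01 — the usual chemometric stopping rule.  R2Y is
#' `1 - SS_res/SS_tot` on the coded response; Q2 comes from
#' [cross_validate_q2()] with the same settings.
#'
#' @param x Predictor matrix, data frame or `descriptor_matrix` (one row per
#'   compound, the 13 canonical descriptors as columns).
#' @param y Class labels matching `names(y_codes)`.
#' @param n_orth Number of orthogonal components, or `"auto"`.
#' @param folds Cross-validation folds (round-robin by row order).
#' @param y_codes Named class coding, default `c(A = 0, B = 1)`.
#' @param threshold Classification threshold on the decoded response scale;
#'   ties classify as the positive (larger-coded) class.
#' @param cv_refit_scaling Logical; if `TRUE` the cross-validation
#'   re-estimates the column scaling inside every training fold.  The
#'   default `FALSE` treats scaling as a fixed property of the assembled
#'   data set, matching how chemometrics packages report Q2.
#' @param max_orth Upper limit for `"auto"` selection.
#' @return An object of class `"oplsda"`; see [export_scores_loadings()],
#'   [predict.oplsda()].
#' @export
#' @examples
#' tab1 <- load_descriptor_table("table1")
#' fit <- fit_oplsda(tab1, tab1$group)
#' fit
fit_oplsda <- function(x, y, n_orth = "auto", folds = 7,
                       y_codes = c(A = 0, B = 1), threshold = 0.5,
                       cv_refit_scaling = FALSE, max_orth = 5L) {
  labels <- as.character(y)
  ycode <- code_response(labels, y_codes)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("need at least 2 samples in each class", call. = FALSE)
  sc <- uv_scale(x)
  n <- nrow(sc$x)
  if (folds < 2L || folds > n)
    stop("folds must lie in [2, n_samples]", call. = FALSE)
  names_x <- rownames(sc$x)
  if (is.null(names_x)) names_x <- as.character(seq_len(n))

  if (identical(n_orth, "auto")) {
    q_prev <- cross_validate_q2(x, labels, n_orth = 0L, folds = folds,
                                y_codes = y_codes,
                                refit_scaling = cv_refit_scaling)
    n_sel <- 0L
    for (k in seq_len(max_orth)) {
      q_k <- tryCatch(
        cross_validate_q2(x, labels, n_orth = k, folds = folds,
                          y_codes = y_codes,
                          refit_scaling = cv_refit_scaling),
        error = function(e) -Inf)
      if (q_k > q_prev + 0.01) { n_sel <- k; q_prev <- q_k } else break
    }
    n_orth <- n_sel
  }
  n_orth <- as.integer(n_orth)

  y_center <- mean(ycode)
  yc <- ycode - y_center
  cmp <- opls_components(sc$x, yc, n_orth)

  ## orientation: positive class scores to the right of the scores plot
  pos <- names(y_codes)[which.max(y_codes)]
  if (mean(cmp$t[labels == pos]) < 0) {
    cmp$w <- -cmp$w; cmp$t <- -cmp$t; cmp$p <- -cmp$p; cmp$b <- -cmp$b
  }

  fitted_y <- cmp$b * cmp$t + y_center
  r2y <- 1 - sum((ycode - fitted_y)^2) / sum(yc^2)
  cls <- decode_class(fitted_y, y_codes, threshold)
  mis <- names_x[cls != labels]

  q2 <- cross_validate_q2(x, labels, n_orth = n_orth, folds = folds,
                          y_codes = y_codes,
                          refit_scaling = cv_refit_scaling)

  ## orthogonality invariants, asserted on every fit
  if (!is.null(cmp$T_o)) {
    stopifnot(max(abs(crossprod(cmp$T_o, yc))) < 1e-8,
              max(abs(crossprod(cmp$T_o, cmp$t))) < 1e-8)
  }

  structure(list(center = sc$center, scale = sc$scale,
                 y_codes = y_codes, y_center = y_center,
                 threshold = threshold,
                 w = cmp$w, p = cmp$p, t_pred = cmp$t, b = cmp$b,
                 W_o = cmp$W_o, P_o = cmp$P_o, T_o = cmp$T_o,
                 x_deflated = cmp$x_deflated,
                 n_orth = n_orth, folds = folds,
                 cv_refit_scaling = cv_refit_scaling,
                 r2y = r2y, q2 = q2,
                 fitted_y = fitted_y, class_fitted = cls,
                 labels = labels, names = names_x,
                 misclassified = mis),
            class = "oplsda")
}

#' @rdname fit_oplsda
#' @param formula Model formula, e.g. `group ~ .`; the response must name
#'   the class column, all remaining numeric columns are predictors.
#' @param data Data frame holding the response and descriptor columns.
#' @param ... Passed on to `fit_oplsda()`.
#' @export
oplsda <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  terms_x <- attr(stats::terms(formula, data = data), "term.labels")
  xcols <- if (length(terms_x)) terms_x else setdiff(names(data), all.vars(formula[[2L]]))
  xm <- as.matrix(data[, xcols, drop = FALSE])
  if ("name" %in% names(data)) rownames(xm) <- data$name
  fit <- fit_oplsda(xm, y, ...)
  fit$call <- match.call()
  fit
}

#' Cross-validated predictivity (Q2)
#'
#' Rows are assigned to folds round-robin by row order (row i to fold
#' i mod folds); each fold is held out in turn, the orthogonal and
#' predictive components are re-estimated on the remaining rows, and the
#' held-out coded responses are predicted.  `Q2 = 1 - PRESS / SS` with SS
#' the total sum of squares of the centred coded response.  By default the
#' column scaling (and response centring) is the one computed on the full
#' data set; `refit_scaling = TRUE` re-estimates both inside every training
#' fold.
#'
#' @inheritParams fit_oplsda
#' @param refit_scaling Re-estimate scaling per training fold.
#' @return Q2 (at most 1; can be negative).
#' @export
cross_validate_q2 <- function(x, y, n_orth = 0L, folds = 7,
                              y_codes = c(A = 0, B = 1),
                              refit_scaling = FALSE) {
  labels <- as.character(y)
  ycode <- code_response(labels, y_codes)
  m <- if (inherits(x, "descriptor_matrix")) as.matrix(x) else as.matrix(x)
  n <- nrow(m)
  if (folds > n) stop("folds cannot exceed the number of samples",
                      call. = FALSE)
  fold <- (seq_len(n) - 1L) %% folds
  sc <- uv_scale(m)
  y_center_full <- mean(ycode)
  press <- 0
  for (f in unique(fold)) {
    hold <- fold == f
    if (length(unique(labels[!hold])) < 2L)
      warning("training portion of a fold lacks one class; fold retained")
    if (refit_scaling) {
      sct <- uv_scale(m[!hold, , drop = FALSE])
      xs_tr <- sct$x
      xs_ho <- scale(m[hold, , drop = FALSE], sct$center, sct$scale)
      y_center <- mean(ycode[!hold])
    } else {
      xs_tr <- sc$x[!hold, , drop = FALSE]
      xs_ho <- sc$x[hold, , drop = FALSE]
      y_center <- y_center_full
    }
    cmp <- opls_components(xs_tr, ycode[!hold] - y_center, n_orth)
    st <- strip_orthogonal(xs_ho, cmp$W_o, cmp$P_o)
    yhat <- cmp$b * drop(st$xs %*% cmp$w) + y_center
    press <- press + sum((ycode[hold] - yhat)^2)
  }
  1 - press / sum((ycode - y_center_full)^2)
}

#' Predict classes for new compounds
#'
#' New descriptors are scaled with the training parameters, the stored
#' orthogonal components are stripped, and the predictive score is decoded
#' to a class (ties classify as the positive class).
#'
#' @param object A fitted `"oplsda"` model.
#' @param newdata Matrix, data frame or `descriptor_matrix` with the
#'   training descriptor columns (matched by name when available).
#' @param ... Unused.
#' @return Data frame with `name`, `y_pred`, `class`, `t_pred` and the
#'   orthogonal scores (`t_orth1`, ...).
#' @export
predict.oplsda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    out <- data.frame(name = object$names, y_pred = object$fitted_y,
                      class = object$class_fitted, t_pred = object$t_pred,
                      stringsAsFactors = FALSE)
    if (!is.null(object$T_o)) {
      colnames(object$T_o) <- paste0("t_orth", seq_len(ncol(object$T_o)))
      out <- cbind(out, object$T_o)
    }
    rownames(out) <- NULL
    return(out)
  }
  m <- if (inherits(newdata, "descriptor_matrix")) as.matrix(newdata)
       else as.matrix(newdata)
  wanted <- names(object$center)
  if (!is.null(colnames(m))) {
    missing <- setdiff(wanted, colnames(m))
    if (length(missing))
      stop("newdata lacks descriptor column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    m <- m[, wanted, drop = FALSE]
  } else if (ncol(m) != length(wanted)) {
    stop("newdata must have ", length(wanted), " descriptor columns",
         call. = FALSE)
  }
  xs <- scale(m, object$center, object$scale)
  st <- strip_orthogonal(xs, object$W_o, object$P_o)
  t_pred <- drop(st$xs %*% object$w)
  y_pred <- object$b * t_pred + object$y_center
  cls <- decode_class(y_pred, object$y_codes, object$threshold)
  nm <- rownames(m)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(m)))
  out <- data.frame(name = nm, y_pred = y_pred, class = cls,
                    t_pred = t_pred, stringsAsFactors = FALSE)
  if (!is.null(st$t_o)) {
    colnames(st$t_o) <- paste0("t_orth", seq_len(ncol(st$t_o)))
    out <- cbind(out, st$t_o)
  }
  rownames(out) <- NULL
  out
}

#' Plot-ready scores and loadings tables
#'
#' Scores pair the predictive score `t_pred` with the first orthogonal
#' score per compound; loadings pair the predictive weight/loading with the
#' first orthogonal loading per descriptor.  The predictive axis is
#' oriented so that the positive (larger-coded) class has positive mean
#' score, i.e. plots to the right.  For a model with no orthogonal
#' component the orthogonal axis shown is the leading principal component
#' of the X residual after the predictive component (a display axis only,
#' not part of the regression).
#'
#' @param model A fitted `"oplsda"` object.
#' @return List with data frames `scores` (`name`, `group`, `t_pred`,
#'   `t_orth`) and `loadings` (`descriptor`, `w`, `p`, `p_orth`).
#' @export
export_scores_loadings <- function(model) {
  stopifnot(inherits(model, "oplsda"))
  if (!is.null(model$T_o)) {
    t_orth <- model$T_o[, 1L]
    p_orth <- model$P_o[, 1L]
  } else {
    resid <- model$x_deflated - tcrossprod(model$t_pred, model$p)
    sv <- svd(resid, nu = 1L, nv = 1L)
    t_orth <- sv$u[, 1L] * sv$d[1L]
    p_orth <- sv$v[, 1L]
  }
  scores <- data.frame(name = model$names, group = model$labels,
                       t_pred = model$t_pred, t_orth = t_orth,
                       stringsAsFactors = FALSE)
  loadings <- data.frame(descriptor = names(model$center),
                         w = model$w, p = model$p, p_orth = p_orth,
                         stringsAsFactors = FALSE)
  rownames(scores) <- rownames(loadings) <- NULL
  list(scores = scores, loadings = loadings)
}

#' @export
coef.oplsda <- function(object, ...) {
  ## regression coefficients on the scaled descriptor scale:
  ## yhat = b * t = b * (filtered X) w
  setNames(object$b * object$w, names(object$center))
}

#' @export
fitted.oplsda <- function(object, ...) object$fitted_y

#' @export
residuals.oplsda <- function(object, ...) {
  code_response(object$labels, object$y_codes) - object$fitted_y
}

#' @export
print.oplsda <- function(x, ...) {
  cat("OPLS-DA model\n")
  cat(sprintf("  %d compounds, %d descriptors; 1 predictive + %d orthogonal component(s)\n",
              length(x$labels), length(x$w), x$n_orth))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f (%d-fold CV)\n", x$r2y, x$q2, x$folds))
  if (length(x$misclassified))
    cat("  misclassified:", paste(x$misclassified, collapse = ", "), "\n")
  else cat("  no training compounds misclassified\n")
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  tab <- table(observed = object$labels, predicted = object$class_fitted)
  structure(list(model = object, confusion = tab), class = "summary.oplsda")
}

#' @export
print.summary.oplsda <- function(x, ...) {
  print(x$model)
  cat("\nConfusion (training):\n")
  print(x$confusion)
  invisible(x)
}

#' Scores plot for an OPLS-DA model
#'
#' Predictive score against the first orthogonal score, coloured by class
#' label, mirroring the conventional chemometric scores plot.
#'
#' @param x A fitted `"oplsda"` model.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.oplsda <- function(x, ...) {
  ex <- export_scores_loadings(x)
  cls <- factor(ex$scores$group)
  plot(ex$scores$t_pred, ex$scores$t_orth, col = as.integer(cls),
       pch = as.integer(cls) + 15L,
       xlab = "t (predictive)", ylab = "t (orthogonal)", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topleft", legend = levels(cls),
                   col = seq_along(levels(cls)),
                   pch = seq_along(levels(cls)) + 15L, bty = "n")
  invisible(x)
}
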