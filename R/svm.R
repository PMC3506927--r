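# Soft-margin RBF-SVM comparator.
#
# Kernel fixed at exp(-|x - x'|^2 / 3) (gamma = 1/3 for the 3 features);
# only the slack/margin trade-off C is swept. Features are z-score
# standardized with training-set statistics before fitting (their orders
# of magnitude differ wildly); the KDE classifier needs no such step
# because its bandwidths already scale each component. The quadratic
# program itself is delegated to libsvm via e1071.

#' Train the RBF support vector machine comparator
#'
#' @param train Data.frame with columns `f1`, `f2`, `f3` and `label`
#'   (`"N"` / `"S"`; both must be present).
#' @param C Slack/margin trade-off (> 0).
#' @param gamma RBF width parameter (default 1/3).
#' @param tolerance Solver termination tolerance (default 1e-3).
#' @return An object of class `"st_svm"` holding the fitted model and the
#'   standardization statistics.
#' @export
train_svm <- function(train, C = 1, gamma = 1 / 3, tolerance = 1e-3) {
  if (length(unique(train$label)) < 2L)
    stop_fit("train_svm: both classes must be present in the training set")
  if (C <= 0) stop_config("train_svm: C must be positive")
  x <- .feature_matrix(train)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  y <- factor(train$label, levels = c("N", "S"))
  fit <- e1071::svm(xs, y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = C, scale = FALSE,
                    tolerance = tolerance)
  structure(list(fit = fit, center = center, scale = scale,
                 gamma = gamma, C = C),
            class = "st_svm")
}

#' @export
predict.st_svm <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) .feature_matrix(newdata)
       else as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  as.character(stats::predict(object$fit, xs))
}

#' Dual objective of a fitted SVM
#'
#' Evaluates `sum(alpha) - 0.5 * alpha' H alpha` at the solver's solution,
#' with `H_ij = t_i t_j K(x_i, x_j)`; used to check the delegated solver
#' against an independent quadratic-program solution.
#'
#' @param object An `"st_svm"` fit.
#' @return The dual objective value.
#' @export
svm_dual_objective <- function(object) {
  co <- as.numeric(object$fit$coefs)       # t_j * alpha_j over SVs
  sv <- object$fit$SV
  K <- exp(-object$gamma * as.matrix(stats::dist(sv))^2)
  sum(abs(co)) - 0.5 * drop(t(co) %*% K %*% co)
}

#' Sweep the SVM trade-off parameter C
#'
#' Trains at each C in the grid and returns the value maximizing
#' sensitivity + specificity on the test split; ties break to the
#' smallest C.
#'
#' @param train,test Data.frames with `f1`, `f2`, `f3`, `label`.
#' @param grid C grid (default `seq(0.1, 300, by = 0.1)`; pass a coarser
#'   grid for quick runs).
#' @param ... Passed to [train_svm()].
#' @return List with `best_C` and `metrics` (data.frame: `C`, `se`, `sp`,
#'   `sum`).
#' @export
sweep_C <- function(train, test, grid = seq(0.1, 300, by = 0.1), ...) {
  res <- lapply(grid, function(C) {
    fit <- train_svm(train, C = C, ...)
    cm <- confusion(predict(fit, test), test$label)
    data.frame(C = C, se = cm$Se, sp = cm$Sp, sum = cm$Se + cm$Sp)
  })
  metrics <- do.call(rbind, res)
  list(best_C = metrics$C[which.max(metrics$sum)], metrics = metrics)
}
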