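# Product-bandwidth kernel density Bayes classifier.
#
# Each class density is a sum of radially symmetric kernels in the scaled
# coordinates u_j = (y_j - x_ij) / b_j, with per-class, per-component
# bandwidths b_i set automatically to factor * (mean absolute pairwise
# component difference); factor defaults to 1/2. The 3-D normalization
# constants below make each kernel integrate to one, though they cancel in
# the posterior and so never change a decision.

.kernels <- list(
  gaussian = list(
    constant = (2 * pi)^(-3 / 2),
    profile = function(u) exp(-u^2 / 2),
    support = Inf),
  rectangular = list(
    constant = 3 / (4 * pi),
    profile = function(u) as.numeric(u <= 1),
    support = 1),
  epanechnikov = list(
    constant = 15 / (8 * pi),
    profile = function(u) ifelse(u <= 1, 1 - u^2, 0),
    support = 1),
  biweight = list(
    constant = 105 / (32 * pi),
    profile = function(u) ifelse(u <= 1, (1 - u^2)^2, 0),
    support = 1),
  triweight = list(
    constant = 315 / (64 * pi),
    profile = function(u) ifelse(u <= 1, (1 - u^2)^3, 0),
    support = 1),
  triangular = list(
    constant = 3 / pi,
    profile = function(u) ifelse(u <= 1, 1 - u, 0),
    support = 1)
)

#' Supported kernel profiles
#'
#' @return Character vector of the six supported kernel names.
#' @export
kde_kernels <- function() names(.kernels)

#' Kernel specification
#'
#' @param name One of [kde_kernels()].
#' @return List with `name`, the radial `profile` function of `u >= 0`,
#'   the 3-D normalization `constant`, and `support` (1 for compactly
#'   supported kernels, `Inf` for the Gaussian).
#' @export
kernel_spec <- function(name) {
  name <- match.arg(tolower(name), kde_kernels())
  c(list(name = name), .kernels[[name]])
}

#' Mean absolute pairwise difference of one feature component
#'
#' `(2 / (m (m - 1))) * sum_{j < k} |x_j - x_k|`, evaluated via the sorted
#' order statistics in O(m log m); permutation-invariant.
#'
#' @param points Numeric matrix (rows = points) or vector.
#' @param i Column index when `points` is a matrix.
#' @return The mean absolute pairwise difference.
#' @export
mean_component_diff <- function(points, i = 1L) {
  v <- if (is.matrix(points)) points[, i] else points
  m <- length(v)
  if (m < 2L)
    stop_fit("mean_component_diff: need at least 2 points (got %d)", m)
  s <- sort(v)
  # sum_{j<k}(s_k - s_j) = sum_r (2r - m - 1) s_(r)
  tot <- sum((2 * seq_len(m) - m - 1) * s)
  tot / (m * (m - 1) / 2)
}

#' Fit the kernel density classifier
#'
#' Bandwidths are set per class and component to
#' `factor * mean_component_diff`; class priors are the class proportions.
#'
#' @param points_S,points_N Numeric matrices (rows = feature windows,
#'   3 columns) of ischemic (`S`) and normal (`N`) training points.
#' @param kernel Kernel name or [kernel_spec()] (default `"gaussian"`).
#' @param factor Bandwidth factor (> 0, default 0.5 — half the mean
#'   pairwise difference).
#' @return An object of class `"kde_model"`.
#' @export
kde_fit <- function(points_S, points_N, kernel = "gaussian", factor = 0.5) {
  ks <- if (is.list(kernel)) kernel else kernel_spec(kernel)
  points_S <- as.matrix(points_S); points_N <- as.matrix(points_N)
  if (ncol(points_S) != ncol(points_N))
    stop_fit("kde_fit: class point sets have different dimensions")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop_config("kde_fit: bandwidth factor must be positive")
  if (nrow(points_S) < 2L || nrow(points_N) < 2L)
    stop_fit("kde_fit: each class needs at least 2 training points")
  d <- ncol(points_S)
  bw <- function(pts, cl) {
    b <- vapply(seq_len(d), function(i) {
      factor * mean_component_diff(pts, i)
    }, numeric(1))
    zero <- which(b <= 0)
    if (length(zero) > 0L)
      stop_fit("kde_fit: degenerate component %s in class %s (zero bandwidth)",
               paste(zero, collapse = ","), cl)
    b
  }
  n_s <- nrow(points_S); n_n <- nrow(points_N)
  structure(
    list(points_S = points_S, points_N = points_N,
         bandwidths = list(S = bw(points_S, "S"), N = bw(points_N, "N")),
         factor = factor, kernel = ks,
         priors = c(N = n_n / (n_n + n_s), S = n_s / (n_n + n_s))),
    class = "kde_model")
}

#' @export
print.kde_model <- function(x, ...) {
  cat(sprintf("<kde_model> kernel %s, factor %g; n_N = %d, n_S = %d\n",
              x$kernel$name, x$factor, nrow(x$points_N), nrow(x$points_S)))
  cat("  b(N):", signif(x$bandwidths$N, 4),
      " b(S):", signif(x$bandwidths$S, 4), "\n")
  invisible(x)
}

#' Class-conditional kernel density at a test point
#'
#' `(1/n_cl) sum_i constant / prod(b) * profile(u_i)` with
#' `u_i^2 = sum_j ((y_j - x_ij)/b_j)^2`. The Gaussian sum is evaluated with
#' max-exponent factoring so far-away points underflow gracefully; the
#' result equals the naive formula wherever that is representable.
#'
#' @param model A [kde_fit()] model.
#' @param y Numeric feature vector (length 3).
#' @param cl `"S"` or `"N"`.
#' @return Non-negative density value.
#' @export
kde_likelihood <- function(model, y, cl = c("S", "N")) {
  cl <- match.arg(cl)
  pts <- if (cl == "S") model$points_S else model$points_N
  b <- model$bandwidths[[cl]]
  n <- nrow(pts)
  u2 <- rep(0, n)
  for (j in seq_along(y))
    u2 <- u2 + ((y[j] - pts[, j]) / b[j])^2
  ks <- model$kernel
  scale <- ks$constant / prod(b)
  if (ks$name == "gaussian") {
    e <- -u2 / 2
    mx <- max(e)
    if (!is.finite(mx)) return(0)
    return(scale * exp(mx) * sum(exp(e - mx)) / n)
  }
  scale * sum(ks$profile(sqrt(u2))) / n
}

#' Posterior class probabilities
#'
#' Bayes' rule with prior-weighted class likelihoods. If both likelihoods
#' are exactly zero (possible with compactly supported kernels far from
#' all training points) the posterior falls back to the priors.
#'
#' @param model A [kde_fit()] model.
#' @param y Numeric feature vector.
#' @return Named numeric `c(N = , S = )` summing to one.
#' @export
kde_posterior <- function(model, y) {
  ln <- kde_likelihood(model, y, "N") * model$priors[["N"]]
  ls <- kde_likelihood(model, y, "S") * model$priors[["S"]]
  tot <- ln + ls
  if (tot == 0) return(c(N = model$priors[["N"]], S = model$priors[["S"]]))
  c(N = ln / tot, S = ls / tot)
}

#' Classify feature windows
#'
#' Assigns each row of `y` the class with the larger posterior; an exact
#' tie goes to `"N"`.
#'
#' @param model A [kde_fit()] model.
#' @param y Numeric vector (one point) or matrix (rows = points).
#' @return Character vector of `"N"` / `"S"` labels.
#' @export
kde_classify <- function(model, y) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  apply(y, 1, function(row) {
    p <- kde_posterior(model, row)
    if (p[["S"]] > p[["N"]]) "S" else "N"
  })
}

#' Episode-level majority decision
#'
#' An annotated interval is declared an ischemic ST episode when strictly
#' more than half of its window labels are `"S"`.
#'
#' @param labels Character vector of per-window labels over one episode.
#' @return Logical: detected or not.
#' @export
classify_episode <- function(labels) {
  n <- length(labels)
  if (n < 1L) stop_input("classify_episode: empty interval")
  sum(labels == "S") > n / 2
}

#' Sweep the bandwidth factor
#'
#' Fits and evaluates the classifier over a grid of bandwidth factors and
#' returns the factor maximizing sensitivity + specificity on the test
#' split (ties break to the smallest factor).
#'
#' @param train,test Data.frames with columns `f1`, `f2`, `f3`, `label`.
#' @param factors Factor grid (default `seq(0.1, 3.0, by = 0.1)`).
#' @param kernel Kernel name.
#' @return List with `best_factor` and `metrics` (data.frame: `factor`,
#'   `se`, `sp`, `sum`).
#' @export
kde_sweep_factor <- function(train, test, factors = seq(0.1, 3, by = 0.1),
                             kernel = "gaussian") {
  res <- lapply(factors, function(fac) {
    m <- kde_fit(.feature_matrix(train[train$label == "S", ]),
                 .feature_matrix(train[train$label == "N", ]),
                 kernel, fac)
    pred <- kde_classify(m, .feature_matrix(test))
    cm <- confusion(pred, test$label)
    data.frame(factor = fac, se = cm$Se, sp = cm$Sp, sum = cm$Se + cm$Sp)
  })
  metrics <- do.call(rbind, res)
  list(best_factor = metrics$factor[which.max(metrics$sum)],
       metrics = metrics)
}

.feature_matrix <- function(df) {
  as.matrix(df[, c("f1", "f2", "f3"), drop = FALSE])
}
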