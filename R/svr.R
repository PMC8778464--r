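# Epsilon-insensitive support vector regression.
#
# The dual problem is solved with quadprog: variables (alpha, alpha*) in
# [0, C]^2n with the balance constraint sum(alpha - alpha*) = 0, objective
# -1/2 (a-a*)' K (a-a*) + y'(a-a*) - eps * sum(a+a*). A tiny ridge keeps the
# (rank-deficient) dual Hessian positive definite for the QP solver. Cohort
# sizes here are tens of subjects, so the 2n-dimensional QP is cheap.

svr_kernel <- function(X, Y, kernel, kernel_scale) {
  switch(kernel,
    linear    = X %*% t(Y),
    quadratic = (1 + X %*% t(Y))^2,
    cubic     = (1 + X %*% t(Y))^3,
    gaussian  = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-pmax(d2, 0) / kernel_scale^2)
    },
    stop("unknown kernel: ", kernel))
}

#' Fit an epsilon-insensitive support vector regression
#'
#' @param X Numeric training matrix (rows = subjects).
#' @param y Numeric target (normalized scale).
#' @param kernel One of `"linear"`, `"quadratic"`, `"cubic"`, `"gaussian"`.
#' @param kernel_scale Gaussian kernel width (ignored for the polynomial /
#'   linear kernels, as in the optimization grid convention).
#' @param box_constraint Regularization cost C.
#' @param epsilon Tube half-width; default a tenth of `sd(y)`.
#' @return Object of class `pigd_svr`.
#' @export
svr_fit <- function(X, y, kernel = "linear", kernel_scale = 1,
                    box_constraint = 1, epsilon = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  if (!(kernel_scale > 0 && box_constraint > 0)) {
    stop("kernel_scale and box_constraint must be positive")
  }
  if (is.null(epsilon)) epsilon <- 0.1 * stats::sd(y)
  if (!is.finite(epsilon) || epsilon < 0) epsilon <- 0
  K <- svr_kernel(X, X, kernel, kernel_scale)
  C <- box_constraint

  D0 <- rbind(cbind(K, -K), cbind(-K, K))
  d <- c(y - epsilon, -y - epsilon)
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- NULL
  jitter <- 1e-8 * max(1, mean(diag(K)))
  for (attempt in 1:4) {
    sol <- tryCatch(
      quadprog::solve.QP(D0 + diag(jitter, 2 * n), d, Amat, bvec, meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    jitter <- jitter * 100
  }
  if (is.null(sol)) {
    stop(sprintf("SVR solver failed (kernel=%s, scale=%g, C=%g)",
                 kernel, kernel_scale, box_constraint))
  }
  beta <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  f0 <- as.vector(K %*% beta)
  # offset: exact minimizer of the epsilon-insensitive loss in b given f0
  # (piecewise linear and convex; evaluated at its breakpoints, midpoint of
  # the flat argmin interval). Robust where KKT-based free-SV averaging is
  # fragile under degenerate duals.
  r0 <- y - f0
  cand <- sort(unique(c(r0 - epsilon, r0 + epsilon)))
  loss <- vapply(cand, function(b0) sum(pmax(0, abs(r0 - b0) - epsilon)),
                 numeric(1))
  best <- which(loss <= min(loss) + 1e-12 * (1 + min(loss)))
  b <- mean(range(cand[best]))
  structure(list(X = X, beta = beta, b = b, kernel = kernel,
                 kernel_scale = kernel_scale, box_constraint = C,
                 epsilon = epsilon), class = "pigd_svr")
}

#' @export
predict.pigd_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.vector(svr_kernel(newdata, object$X, object$kernel,
                       object$kernel_scale) %*% object$beta) + object$b
}

#' @export
print.pigd_svr <- function(x, ...) {
  cat(sprintf("<pigd_svr> kernel=%s scale=%g C=%g eps=%.4g, %d SVs of %d\n",
              x$kernel, x$kernel_scale, x$box_constraint, x$epsilon,
              sum(abs(x$beta) > 1e-8), nrow(x$X)))
  invisible(x)
}

#' Hyperparameter grid for the nested optimization
#'
#' Kernel scale and box constraint span the stated 0.001-1000 range on a
#' log10 grid; kernel scale applies to the gaussian kernel only. The row
#' order (kernel as listed, then box constraint, then kernel scale) is the
#' deterministic tie-break order of the inner-loop arg-min.
#'
#' @param kernels Kernel subset, in tie-break order.
#' @param kernel_scale,box_constraint Grid values.
#' @return data.frame with columns `kernel`, `kernel_scale`,
#'   `box_constraint`.
#' @export
svr_grid <- function(kernels = c("linear", "quadratic", "cubic", "gaussian"),
                     kernel_scale = 10^(-3:3), box_constraint = 10^(-3:3)) {
  rows <- list()
  for (k in kernels) {
    ks <- if (k == "gaussian") kernel_scale else 1
    for (C in sort(box_constraint)) {
      for (s in sort(ks)) {
        rows[[length(rows) + 1]] <- data.frame(kernel = k, kernel_scale = s,
                                               box_constraint = C)
      }
    }
  }
  do.call(rbind, rows)
}
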