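#' Closed-form ridge regression
#'
#' Solves `W = (X'X + lambda I)^-1 X'Y` per target column, without
#' intercept. For numerical stability the solution is obtained by Cholesky
#' factorization rather than explicit inversion; when the feature dimension
#' exceeds the sample count the mathematically identical dual form
#' `W = X'(XX' + lambda I)^-1 Y` is used, so very wide feature maps (large
#' Random Fourier expansions) cost `O(n^3)` instead of `O(p^3)`.
#'
#' @param X `n x p` design matrix.
#' @param Y `n x q` target matrix (a vector is treated as one column).
#' @param lambda ridge coefficient, `>= 0`; the pipeline default is 1.
#' @return `p x q` weight matrix.
#' @export
#' @examples
#' X <- diag(4); Y <- c(1, 0, 0, 0)
#' ridge_fit(X, Y, lambda = 1)  # (I + I)^-1 Y = Y / 2
ridge_fit <- function(X, Y, lambda = 1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) < 1L || nrow(X) != nrow(Y)) {
    stop("`X` and `Y` must have the same positive number of rows.",
         call. = FALSE)
  }
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("`X` and `Y` must be finite with no missing values.", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative number.", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  solve_spd <- function(A, B) {
    # at lambda = 0 a numerically singular system must not pass silently
    if (lambda == 0 && rcond(A) < 1e-12) {
      stop("System is singular; use lambda > 0.", call. = FALSE)
    }
    R <- tryCatch(chol(A), error = function(e) {
      stop("System is singular; use lambda > 0.", call. = FALSE)
    })
    backsolve(R, backsolve(R, B, transpose = TRUE))
  }
  if (p <= n) {
    W <- solve_spd(crossprod(X) + diag(lambda, p), crossprod(X, Y))
  } else {
    alpha <- solve_spd(tcrossprod(X) + diag(lambda, n), Y)
    W <- crossprod(X, alpha)
  }
  if (any(!is.finite(W))) {
    stop("System is singular; use lambda > 0.", call. = FALSE)
  }
  rownames(W) <- colnames(X)
  colnames(W) <- colnames(Y)
  W
}

#' Sample a Random Fourier Feature map
#'
#' Draws the randomized cosine feature map whose inner products approximate
#' the radial-basis-function kernel `k(x, x') = exp(-||x - x'||^2 /
#' (2 sigma^2))`: frequencies `Omega` (`D x d`) i.i.d. Gaussian with
#' standard deviation `1/sigma` per coordinate, phases `b` uniform on
#' `[0, 2 pi)`.
#'
#' @param d input dimension.
#' @param D number of random features; the pipeline default is 300.
#' @param sigma kernel bandwidth (length-scale), `> 0`.
#' @param seed integer seed; the same seed reproduces the map exactly.
#' @return an object of class `rff_map` with fields `Omega`, `b`, `d`,
#'   `D`, `sigma`, `seed`.
#' @export
rff_sample <- function(d, D = 300L, sigma, seed) {
  if (d < 1 || D < 1) stop("`d` and `D` must be >= 1.", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  draws <- with_seed(seed, list(
    Omega = matrix(rnorm(D * d, 0, 1 / sigma), D, d),
    b = runif(D, 0, 2 * pi)))
  structure(list(Omega = draws$Omega, b = draws$b, d = as.integer(d),
                 D = as.integer(D), sigma = sigma, seed = seed),
            class = "rff_map")
}

#' Evaluate a Random Fourier Feature map
#'
#' `phi(x) = sqrt(2/D) * cos(Omega x + b)`, applied row-wise.
#'
#' @param map an [rff_sample()] map.
#' @param X `n x d` matrix (or length-`d` vector).
#' @return `n x D` feature matrix; every entry lies in
#'   `[-sqrt(2/D), sqrt(2/D)]`.
#' @export
rff_transform <- function(map, X) {
  stopifnot(inherits(map, "rff_map"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != map$d) {
    stop(sprintf("`X` has %d columns; the map expects %d.", ncol(X), map$d),
         call. = FALSE)
  }
  proj <- X %*% t(map$Omega)
  sqrt(2 / map$D) * cos(sweep(proj, 2, map$b, "+"))
}

#' Fit a force-regression model (linear ridge or RFF ridge)
#'
#' The linear model is `f(x) = W' x` with the closed-form ridge solution;
#' the nonlinear model first maps inputs through a Random Fourier Feature
#' approximation of the RBF kernel, `f(x) = W' phi(x)`, sharing a single
#' feature map across all six target DOFs. `sigma = NULL` triggers a grid
#' search via [grid_search_sigma()].
#'
#' @param X `n x d` training samples (preprocessed stream values).
#' @param Y `n x q` training targets (forces, N).
#' @param lambda ridge coefficient (default 1).
#' @param feature_map "identity" for linear ridge, "rff" for RFF ridge.
#' @param D number of random features (RFF only, default 300).
#' @param sigma RFF bandwidth; `NULL` = grid search.
#' @param sigma_grid candidate bandwidths for the search (`NULL` = median
#'   heuristic grid, see [median_heuristic_grid()]).
#' @param seed integer seed for the feature map draw and the search folds.
#' @return an object of class `hmi_model`.
#' @export
fit_model <- function(X, Y, lambda = 1, feature_map = c("identity", "rff"),
                      D = 300L, sigma = NULL, sigma_grid = NULL, seed = 1L) {
  feature_map <- match.arg(feature_map)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (feature_map == "identity") {
    W <- ridge_fit(X, Y, lambda)
    map <- NULL
  } else {
    if (is.null(sigma)) {
      if (is.null(sigma_grid)) sigma_grid <- median_heuristic_grid(X, seed = seed)
      sigma <- grid_search_sigma(X, Y, lambda = lambda, D = D,
                                 sigma_grid = sigma_grid, seed = seed)
    }
    map <- rff_sample(ncol(X), D, sigma, derive_seed(seed, "rff"))
    W <- ridge_fit(rff_transform(map, X), Y, lambda)
  }
  structure(list(feature_map = feature_map, map = map, weights = W,
                 lambda = lambda, input_dim = ncol(X),
                 target_names = colnames(Y)),
            class = "hmi_model")
}

#' Convenience wrapper: RFF ridge with an explicit bandwidth
#'
#' @inheritParams fit_model
#' @return an `hmi_model`.
#' @export
rff_ridge_fit <- function(X, Y, lambda = 1, sigma, D = 300L, seed = 1L) {
  fit_model(X, Y, lambda = lambda, feature_map = "rff", D = D, sigma = sigma,
            seed = seed)
}

#' @export
predict.hmi_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    stop(sprintf("`newdata` has %d columns; the model expects %d.",
                 ncol(X), object$input_dim), call. = FALSE)
  }
  Phi <- if (object$feature_map == "rff") rff_transform(object$map, X) else X
  Phi %*% object$weights
}

#' @export
print.hmi_model <- function(x, ...) {
  cat(sprintf("<hmi_model> %s ridge (lambda = %g%s), input dim %d, %d targets\n",
              x$feature_map, x$lambda,
              if (x$feature_map == "rff")
                sprintf(", D = %d, sigma = %.4g", x$map$D, x$map$sigma) else "",
              x$input_dim, ncol(x$weights)))
  invisible(x)
}

#' Candidate bandwidth grid from the median heuristic
#'
#' Ten logarithmically spaced values spanning 0.1x to 10x the median
#' pairwise Euclidean distance of a training subsample — a standard
#' starting grid for RBF length-scales.
#'
#' @param X training samples.
#' @param n_grid grid size (default 10).
#' @param max_n subsample size for the pairwise distances (default 500).
#' @param seed seed for the subsample draw.
#' @return numeric vector of candidate `sigma` values, increasing.
#' @export
median_heuristic_grid <- function(X, n_grid = 10L, max_n = 500L, seed = 1L) {
  X <- as.matrix(X)
  idx <- if (nrow(X) > max_n) {
    with_seed(derive_seed(seed, "medheur"), sample.int(nrow(X), max_n))
  } else seq_len(nrow(X))
  med <- median(dist(X[idx, , drop = FALSE]))
  if (!is.finite(med) || med <= 0) med <- 1
  exp(seq(log(0.1 * med), log(10 * med), length.out = n_grid))
}

#' Grid search for the RFF bandwidth
#'
#' Selects the `sigma` minimizing the mean cross-validated nRMSE of an RFF
#' ridge model over the candidate grid. Fold assignment and the per-fit RFF
#' seeds are deterministic functions of `seed`; ties are broken toward the
#' larger (smoother) bandwidth.
#'
#' @param X,Y training samples and targets.
#' @param lambda ridge coefficient.
#' @param D number of random features.
#' @param sigma_grid non-empty vector of candidate bandwidths.
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer seed.
#' @return the selected `sigma`.
#' @export
grid_search_sigma <- function(X, Y, lambda = 1, D = 300L, sigma_grid,
                              n_folds = 5L, seed = 1L) {
  if (length(sigma_grid) == 0) stop("`sigma_grid` must be non-empty.", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (length(sigma_grid) == 1L) return(sigma_grid)
  n <- nrow(X)
  folds <- with_seed(derive_seed(seed, "cvfolds"),
                     sample(rep_len(seq_len(n_folds), n)))
  score <- vapply(sigma_grid, function(s) {
    errs <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      m <- rff_ridge_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                         lambda = lambda, sigma = s, D = D,
                         seed = derive_seed(seed, "gridfit", k))
      pred <- predict(m, X[!tr, , drop = FALSE])
      truth <- Y[!tr, , drop = FALSE]
      rng <- apply(truth, 2, function(v) diff(range(v)))
      rng[rng <= 0] <- 1  # degenerate fold target: score unnormalized RMSE
      mean(sqrt(colMeans((pred - truth)^2)) / rng)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # ties (within numerical noise) go to the larger, smoother sigma
  best <- max(which(score <= min(score) + 1e-12))
  sigma_grid[best]
}

#' Exact RBF kernel ridge regression (test oracle)
#'
#' The dual closed form `pred = K* (K + lambda I)^-1 Y` with the RBF kernel
#' `exp(-||x - x'||^2 / (2 sigma^2))`. `O(n^3)` — intended as the exact
#' reference that Random Fourier Feature models converge to as `D` grows,
#' not for production fitting.
#'
#' @param X,Y training samples and targets.
#' @param lambda ridge coefficient.
#' @param sigma RBF bandwidth.
#' @param X_test test samples.
#' @return `n_test x q` prediction matrix.
#' @export
krr_rbf_oracle <- function(X, Y, lambda, sigma, X_test) {
  X <- as.matrix(X); Y <- as.matrix(Y); X_test <- as.matrix(X_test)
  stopifnot(ncol(X_test) == ncol(X), sigma > 0, lambda >= 0)
  sq <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  }
  K <- exp(-pmax(sq(X, X), 0) / (2 * sigma^2))
  Kt <- exp(-pmax(sq(X_test, X), 0) / (2 * sigma^2))
  alpha <- solve(K + diag(lambda, nrow(K)), Y)
  Kt %*% alpha
}
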