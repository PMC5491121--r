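#' Least-angle regression (LAR)
#'
#' From-scratch implementation of the least-angle regression path (Efron,
#' Hastie, Johnstone & Tibshirani's LAR, without the lasso modification).
#' At each step the variable most correlated with the current residual joins
#' the active set, and the coefficients of all active variables move together
#' in the equiangular direction -- the direction keeping every active
#' variable at equal absolute correlation with the residual -- until an
#' inactive variable catches up.  Compared with plain forward selection the
#' coefficients are adjusted more smoothly, which is why the path's
#' breakpoints give usable models at every sparsity level.
#'
#' A documented `method` flag exists for a future lasso-modified path; only
#' `"lar"` is implemented.
#'
#' @name lars
NULL

#' Standardize a design matrix and response for LAR
#'
#' Centres each column and scales it to unit Euclidean norm; centres the
#' response.  Centres and scales are retained so coefficients can be
#' back-transformed to the original scale.
#'
#' @param X numeric matrix, no missing values, n >= 3 rows.
#' @param y numeric response of length n.
#' @return an object of class `standardized_design` with elements `Xs`, `ys`,
#'   `x_center`, `x_scale`, `y_center`, `labels`.
#' @export
standardize <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), is.numeric(y), nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response",
                                 call. = FALSE)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows to standardize", call. = FALSE)
  labels <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- sqrt(colSums(Xc^2))
  zero <- scl < .Machine$double.eps^0.5 * sqrt(n)
  if (any(zero))
    stop("zero-variance column(s): ", paste(labels[zero], collapse = ", "),
         call. = FALSE)
  structure(list(Xs = sweep(Xc, 2L, scl, "/"),
                 ys = y - mean(y),
                 x_center = ctr, x_scale = scl, y_center = mean(y),
                 labels = labels),
            class = "standardized_design")
}

#' Compute the LAR path
#'
#' @param d a [standardize()]d design.
#' @param max_steps maximum number of variables on the path; capped at
#'   `min(p, n - 1)`.
#' @param method `"lar"` (the implemented algorithm).
#' @return an object of class `lars_path`: `order` (entering column indices),
#'   `beta` (matrix of breakpoint coefficients in standardized space, row k+1
#'   = active set of size k), `cors` (common absolute residual correlation at
#'   each breakpoint, non-increasing), `truncated` (TRUE if a rank-deficient
#'   active set stopped the path early), `labels`.
#' @export
lars_path <- function(d, max_steps = NULL, method = c("lar")) {
  stopifnot(inherits(d, "standardized_design"))
  method <- match.arg(method)
  Xs <- d$Xs; ys <- d$ys
  n <- nrow(Xs); p <- ncol(Xs)
  kmax <- min(p, n - 1L, max_steps %||% p)
  tol <- 1e-12
  # work entirely in the Gram space: every step needs only X'X and X'y
  G <- crossprod(Xs)
  c0 <- as.double(crossprod(Xs, ys))
  beta <- numeric(p)
  active <- integer(0)
  B <- matrix(0, nrow = 1L, ncol = p, dimnames = list(NULL, d$labels))
  cors <- max(abs(c0))
  truncated <- FALSE
  cvec <- c0
  while (length(active) < kmax) {
    inactive <- setdiff(seq_len(p), active)
    Cmax <- max(abs(cvec[inactive]), if (length(active)) abs(cvec[active]) else NULL)
    if (Cmax < tol) break
    # entering variable: largest |correlation| among inactive, ties -> lowest index
    j <- inactive[which(abs(cvec[inactive]) >= Cmax - tol)][1L]
    active <- c(active, j)
    s <- sign(cvec[active])
    s[s == 0] <- 1
    Ga <- G[active, active, drop = FALSE] * tcrossprod(s)
    w <- tryCatch(solve(Ga, rep(1, length(active))),
                  error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w)) || sum(w) <= 0) {
      truncated <- TRUE
      active <- active[-length(active)]
      break
    }
    A <- 1 / sqrt(sum(w))
    w <- A * w
    # a = X' u where u = Xa w is the unit equiangular direction
    a <- as.double(G[, active, drop = FALSE] %*% (w * s))
    C <- max(abs(cvec[active]))
    if (length(active) == min(p, n - 1L)) {
      # saturated: no further variable can enter; jump to the least-squares
      # fit of the active set (for full-rank p < n this is the OLS endpoint)
      gamma <- C / A
    } else {
      rest <- setdiff(seq_len(p), active)
      cand <- c((C - cvec[rest]) / (A - a[rest]),
                (C + cvec[rest]) / (A + a[rest]))
      cand <- cand[is.finite(cand) & cand > tol]
      gamma <- if (length(cand)) min(cand, C / A) else C / A
    }
    beta[active] <- beta[active] + gamma * s * w
    cvec <- cvec - gamma * a
    B <- rbind(B, beta)
    cors <- c(cors, max(0, C - gamma * A))
  }
  structure(list(order = active, beta = B, cors = cors,
                 truncated = truncated, labels = d$labels),
            class = "lars_path")
}

#' @export
print.lars_path <- function(x, ...) {
  cat(sprintf("<lars_path: %d step(s)%s>\n", length(x$order),
              if (x$truncated) ", truncated (rank-deficient)" else ""))
  if (length(x$order))
    cat("  entry order:", paste(x$labels[x$order], collapse = " -> "), "\n")
  invisible(x)
}

#' Extract the model at a given sparsity from a LAR path
#'
#' Returns the model at the breakpoint where the active set first reaches
#' size `k`, back-transformed to the original variable scale with an
#' intercept.  `k = 0` is the intercept-only model (the training mean).
#'
#' @param path a [lars_path].
#' @param k number of variables, `0 <= k <= length(path$order)`.
#' @param design the [standardize()]d design the path was computed on.
#' @return an object of class `fitted_model` with `coef` (named, original
#'   scale, the k selected variables), `intercept`, `k`, `variables`.
#' @export
coefficients_at <- function(path, k, design) {
  stopifnot(inherits(path, "lars_path"), inherits(design, "standardized_design"))
  if (k < 0L || k > length(path$order))
    stop("k = ", k, " exceeds the path length ", length(path$order),
         call. = FALSE)
  bs <- path$beta[k + 1L, ]
  b <- bs / design$x_scale
  sel <- if (k == 0L) integer(0) else path$order[seq_len(k)]
  intercept <- design$y_center - sum(b[sel] * design$x_center[sel])
  structure(list(coef = stats::setNames(b[sel], design$labels[sel]),
                 intercept = intercept,
                 k = as.integer(k),
                 variables = design$labels[sel]),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model: k = %d, intercept = %.4g>\n", x$k, x$intercept))
  if (x$k > 0L) print(round(x$coef, 6))
  invisible(x)
}

#' @export
coef.fitted_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coef)
}

#' Predict from a fitted model
#'
#' @param object a `fitted_model`.
#' @param newdata a numeric matrix (or data frame) whose columns include the
#'   model's variables.  Rows with a missing value in any model variable get
#'   `NA` (complete-case prediction).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$k == 0L) return(rep(object$intercept, nrow(newdata)))
  miss <- setdiff(object$variables, colnames(newdata))
  if (length(miss))
    stop("newdata lacks model variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  Xm <- newdata[, object$variables, drop = FALSE]
  as.double(object$intercept + Xm %*% object$coef)
}

# OLS as a fitted_model over the given columns (used for single / fixed-set
# model specifications).  Rank deficiency is handled by lm.fit's pivoting;
# aliased coefficients are set to 0.
ols_model <- function(X, y, variables) {
  Xm <- cbind(`(Intercept)` = 1, X[, variables, drop = FALSE])
  fit <- stats::lm.fit(Xm, y)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  structure(list(coef = b[-1L], intercept = unname(b[1L]),
                 k = length(variables), variables = variables),
            class = "fitted_model")
}
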