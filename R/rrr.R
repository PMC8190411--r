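#' Column-wise z-standardization
#'
#' Centres every column to mean 0 and scales to sample SD 1 (n - 1
#' denominator). Constant columns cannot be scaled; they are dropped with a
#' warning and recorded in the parameter set.
#'
#' @param mat Numeric matrix or data frame, n >= 2 rows.
#' @return List with `z` (standardized matrix) and `params` (list of `means`,
#'   `sds`, `dropped` column names).
#' @export
standardize_columns <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows")
  sds <- apply(mat, 2, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (all(constant)) stop("all columns are constant")
  if (any(constant))
    warning("dropping constant column(s): ",
            paste(colnames(mat)[constant], collapse = ", "))
  keep <- !constant
  means <- colMeans(mat[, keep, drop = FALSE])
  z <- scale(mat[, keep, drop = FALSE])
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(z = z,
       params = list(means = means, sds = sds[keep],
                     dropped = colnames(mat)[constant]))
}

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix via eigen
pinv_sym <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) return(matrix(0, nrow(S), ncol(S)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Fit a reduced rank regression dietary-pattern model
#'
#' Extracts K successive factors: linear combinations of the (standardized)
#' predictors that maximize the explained variation in the (standardized)
#' responses. Writing P for the projection onto the predictor column space,
#' the fitted responses are Yhat = P Y; the response weights v_k are the
#' eigenvectors of crossprod(Yhat) (eigenvalues descending), the response
#' score is t_k = Y v_k, the predictor weights a_k map it into predictor
#' space (a_k = (X'X)^+ X'Y v_k), and the factor score f_k = X a_k is the
#' least-squares projection of t_k onto the predictors. Factor scores are
#' mutually orthogonal. Sign convention: each factor is flipped, if
#' necessary, so that it correlates non-negatively with the reference
#' response (by default the first response column, intended to be Zn
#' intake); an exact zero falls through to the second response.
#'
#' @param X n x p standardized predictor matrix (food groups).
#' @param Y n x m standardized response matrix (nutrients); column names are
#'   kept in the output.
#' @param K Number of factors, at most m.
#' @param sign_ref Column (index or name) of `Y` anchoring the sign
#'   convention.
#' @param loading_type `"correlation"` (default; loading = Pearson
#'   correlation of predictor with factor score) or `"regression"`
#'   (X-loadings as the regression of each predictor on the factor score,
#'   the convention some PLS software prints).
#' @return An object of class `rrr_fit`: list with `predictor_weights`
#'   (p x K), `response_weights` (m x K, unit norm), `factor_scores` (n x K),
#'   `response_scores` (n x K), `loadings` (p x K), `eigenvalues`,
#'   `explained` (see [explained_variation()]), `rank_deficient` (logical
#'   K-vector), `loading_type`, and the training `X`, `Y`.
#' @examples
#' set.seed(1)
#' X <- standardize_columns(matrix(rnorm(300), 100, 3))$z
#' colnames(X) <- c("a", "b", "c")
#' Y <- cbind(zn = X[, 1], pufa = X[, 2] + rnorm(100, 0, 0.2))
#' fit <- fit_rrr(X, standardize_columns(Y)$z, K = 2)
#' fit$explained
#' @export
fit_rrr <- function(X, Y, K = 2, sign_ref = 1,
                    loading_type = c("correlation", "regression")) {
  loading_type <- match.arg(loading_type)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 3) stop("need at least 3 observations")
  if (K > m) stop("K cannot exceed the number of responses")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(m))
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))

  XtX <- crossprod(X)
  B <- pinv_sym(XtX) %*% crossprod(X, Y)        # p x m coefficient matrix
  Yhat <- X %*% B
  S <- crossprod(Yhat)
  e <- eigen(S, symmetric = TRUE)               # values already descending
  lambda <- pmax(e$values[seq_len(K)], 0)
  V <- e$vectors[, seq_len(K), drop = FALSE]
  rank_deficient <- lambda <= 1e-10 * max(e$values[1], 1e-300)

  A <- B %*% V                                   # predictor weights a_k
  Fsc <- X %*% A                                 # factor scores f_k
  Tsc <- Y %*% V                                 # response scores t_k

  # sign convention: corr(f_k, reference response) >= 0
  ref <- Y[, sign_ref]
  ref2 <- if (m >= 2) Y[, if (is.numeric(sign_ref) && sign_ref == 1) 2 else 1]
          else ref
  for (k in seq_len(K)) {
    if (rank_deficient[k] || stats::sd(Fsc[, k]) == 0) next
    r <- stats::cor(Fsc[, k], ref)
    if (r == 0) r <- stats::cor(Fsc[, k], ref2)
    if (!is.na(r) && r < 0) {
      A[, k] <- -A[, k]; V[, k] <- -V[, k]
      Fsc[, k] <- -Fsc[, k]; Tsc[, k] <- -Tsc[, k]
    }
  }
  kn <- paste0("factor", seq_len(K))
  dimnames(A) <- list(colnames(X), kn)
  dimnames(V) <- list(colnames(Y), kn)
  dimnames(Fsc) <- list(rownames(X), kn)
  dimnames(Tsc) <- list(rownames(X), kn)

  fit <- structure(list(
    predictor_weights = A, response_weights = V,
    factor_scores = Fsc, response_scores = Tsc,
    eigenvalues = lambda, rank_deficient = rank_deficient,
    loading_type = loading_type, X = X, Y = Y, K = K
  ), class = "rrr_fit")
  fit$loadings <- factor_loadings(fit, X, loading_type)
  fit$explained <- explained_variation(fit, Y)
  fit
}

#' @export
print.rrr_fit <- function(x, ...) {
  cat(sprintf("Reduced rank regression fit: %d factor(s), %d predictors, %d responses, n = %d\n",
              x$K, ncol(x$X), ncol(x$Y), nrow(x$X)))
  ev <- x$explained
  cat("Explained variation (fraction of response variance):\n")
  print(round(ev, 4))
  invisible(x)
}

#' Factor loadings
#'
#' @param model An [fit_rrr()] object.
#' @param X Standardized predictor matrix the model was fitted on (defaults
#'   to the stored training matrix).
#' @param type `"correlation"` or `"regression"` (see [fit_rrr()]).
#' @return p x K loading matrix.
#' @export
factor_loadings <- function(model, X = model$X,
                            type = c("correlation", "regression")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (nrow(X) != nrow(model$factor_scores)) stop("dimension mismatch")
  L <- matrix(NA_real_, ncol(X), model$K,
              dimnames = list(colnames(X), colnames(model$factor_scores)))
  for (k in seq_len(model$K)) {
    f <- model$factor_scores[, k]
    if (model$rank_deficient[k] || stats::sd(f) == 0) {
      L[, k] <- 0
      next
    }
    L[, k] <- if (type == "correlation") {
      drop(stats::cor(X, f))
    } else {
      fc <- f - mean(f)
      drop(crossprod(scale(X, scale = FALSE), fc)) / sum(fc^2)
    }
  }
  L
}

#' Explained variation table
#'
#' For each factor and response, the squared Pearson correlation between the
#' response and the factor score — the fraction of that response's variance
#' the factor explains. Because factor scores are mutually orthogonal, the
#' cumulative explained variation is the running sum across factors. The
#' overall column averages across the responses.
#'
#' @param model An [fit_rrr()] object.
#' @param Y Standardized response matrix (defaults to the stored one).
#' @return K x (m + 2) matrix: one column per response, `overall`, and
#'   `cumulative_overall`.
#' @export
explained_variation <- function(model, Y = model$Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(model$factor_scores)) stop("dimension mismatch")
  m <- ncol(Y)
  out <- matrix(0, model$K, m,
                dimnames = list(colnames(model$factor_scores), colnames(Y)))
  for (k in seq_len(model$K)) {
    f <- model$factor_scores[, k]
    if (model$rank_deficient[k] || stats::sd(f) == 0) next
    out[k, ] <- drop(stats::cor(Y, f))^2
  }
  overall <- rowMeans(out)
  cbind(out, overall = overall, cumulative_overall = cumsum(overall))
}

#' Simplified dietary pattern
#'
#' Reduces a factor to its high-loading food groups: every group with
#' absolute loading at or above the threshold (boundary included) becomes a
#' contributor with the sign of its loading, and the simplified score is the
#' signed sum of the contributors' z-standardized intakes.
#'
#' @param model An [fit_rrr()] object.
#' @param k Factor index.
#' @param threshold Absolute-loading cut-off, default 0.20.
#' @param X Standardized predictor matrix (defaults to the stored one).
#' @return Object of class `simplified_pattern`: list with `factor_index`,
#'   `contributing_groups` (data frame: group_id, sign, loading), `score`
#'   (n-vector) and `quintile` (1..5, from [assign_quintiles()]).
#' @export
simplify_pattern <- function(model, k, threshold = 0.20, X = model$X) {
  if (k > model$K) stop("model has no factor ", k)
  load_k <- model$loadings[, k]
  sel <- !is.na(load_k) & abs(load_k) >= threshold
  if (!any(sel)) stop("empty simplified pattern: no loading reaches ", threshold)
  sgn <- sign(load_k[sel])
  score <- drop(as.matrix(X)[, sel, drop = FALSE] %*% sgn)
  structure(list(
    factor_index = k,
    contributing_groups = data.frame(
      group_id = names(load_k)[sel], sign = unname(sgn),
      loading = unname(load_k[sel]), stringsAsFactors = FALSE),
    score = score,
    quintile = if (length(score) >= 5) assign_quintiles(score) else NULL
  ), class = "simplified_pattern")
}

#' @export
print.simplified_pattern <- function(x, ...) {
  cat(sprintf("Simplified pattern (factor %d): %d contributing group(s)\n",
              x$factor_index, nrow(x$contributing_groups)))
  print(x$contributing_groups)
  invisible(x)
}

#' Quintile assignment
#'
#' Rank-based split of a score into five near-equal groups (sizes differ by
#' at most one). Ties are broken by stable input order. Quintile 1 holds the
#' lowest scores (low adherence), quintile 5 the highest.
#'
#' @param score Numeric n-vector, n >= 5.
#' @return Integer vector of labels 1..5.
#' @examples
#' assign_quintiles(1:10)
#' @export
assign_quintiles <- function(score) {
  n <- length(score)
  if (n < 5) stop("need at least 5 observations for quintiles")
  r <- rank(score, ties.method = "first")
  as.integer(ceiling(5 * r / n))
}

#' Serialize a fitted RRR model to delimited text
#'
#' Writes `predictor_weights.csv`, `response_weights.csv`, `loadings.csv`
#' and `explained_variation.csv` into a directory, rows labelled by group /
#' response in deterministic order.
#'
#' @param model An [fit_rrr()] object.
#' @param dir Output directory (created if needed).
#' @export
write_rrr_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.csv(as.data.frame(m),
                                        file.path(dir, f), row.names = TRUE)
  wr(model$predictor_weights, "predictor_weights.csv")
  wr(model$response_weights, "response_weights.csv")
  wr(model$loadings, "loadings.csv")
  wr(model$explained, "explained_variation.csv")
  invisible(dir)
}
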