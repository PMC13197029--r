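#' Replace below-detection zeros in daily behavior compositions
#'
#' Accelerometer processing occasionally records 0 minutes for a behavior
#' (in practice MVPA) that was merely below the detection limit. Log-ratio
#' methods need strictly positive parts, so zeros are imputed before the ilr
#' transformation.
#'
#' Two methods are provided:
#' * `"multiplicative"` (default): every zero cell is set to
#'   `delta_frac * detection_limit` minutes and the positive cells of that
#'   row are scaled by `(total - imputed_mass) / total`, which preserves all
#'   pairwise ratios among the observed parts.
#' * `"lrEM"`: expectation-maximization on the additive log-ratio scale.
#'   Censored cells are replaced by their conditional expectation (below the
#'   detection limit) given the observed log ratios, iterating mean and
#'   covariance until the parameter change drops under `tol`. Initialised at
#'   the multiplicative solution.
#'
#' With only a handful of zero cells the two methods are numerically
#' indistinguishable downstream; multiplicative has an exact closed form.
#'
#' @param x Matrix or data frame of daily compositions in minutes (columns
#'   `sleep`, `sb`, `lpa`, `mvpa`), each row closed to `total`.
#' @param method `"multiplicative"` or `"lrEM"`.
#' @param detection_limit Detection limit in minutes (default 1): imputed
#'   values lie below it.
#' @param delta_frac Fraction of the detection limit used by the
#'   multiplicative rule (default 0.65).
#' @param total Row total in minutes (default 1440).
#' @param tol,max_iter Convergence controls for `"lrEM"`.
#' @return Matrix of the same dimensions with all parts strictly positive,
#'   rows still summing to `total`. Attribute `"n_replaced"` records the
#'   number of imputed cells.
#' @export
replace_zeros <- function(x, method = c("multiplicative", "lrEM"),
                          detection_limit = 1, delta_frac = 0.65,
                          total = 1440, tol = 1e-6, max_iter = 50L) {
  method <- match.arg(method)
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  if (any(m < 0) || any(!is.finite(m))) {
    stop("composition parts must be finite and non-negative", call. = FALSE)
  }
  zero <- m == 0
  npos <- rowSums(!zero)
  if (any(npos < 2L)) {
    stop("zero replacement needs at least 2 positive parts per day",
         call. = FALSE)
  }
  n_replaced <- sum(zero)
  if (n_replaced > 0L) {
    delta <- delta_frac * detection_limit
    m <- .mult_replace(m, zero, delta, total)
    if (method == "lrEM") {
      m <- .lrem_replace(m, zero, detection_limit, total, tol, max_iter)
    }
  }
  attr(m, "n_replaced") <- n_replaced
  if (vec) {
    out <- m[1L, ]
    attr(out, "n_replaced") <- n_replaced
    return(out)
  }
  m
}

.mult_replace <- function(m, zero, delta, total) {
  for (i in which(rowSums(zero) > 0L)) {
    z <- zero[i, ]
    imputed <- delta * sum(z)
    m[i, z] <- delta
    m[i, !z] <- m[i, !z] * (total - imputed) / total
  }
  m
}

# EM on the alr scale w.r.t. a reference part that is never zero.
# m arrives with zeros already multiplicatively imputed (starting values);
# `zero` marks the originally censored cells, bounded above by the limit.
.lrem_replace <- function(m, zero, detection_limit, total, tol, max_iter) {
  ref <- which.min(colSums(zero))
  if (any(zero[, ref])) {
    stop("lrEM needs one part with no zeros to serve as alr reference",
         call. = FALSE)
  }
  other <- setdiff(seq_len(ncol(m)), ref)
  Y <- log(m[, other, drop = FALSE] / m[, ref])
  cens <- zero[, other, drop = FALSE]
  # censoring threshold on the alr scale, row specific
  psi <- log(detection_limit / m[, ref])
  old <- c(colMeans(Y), stats::cov(Y))
  for (iter in seq_len(max_iter)) {
    mu <- colMeans(Y)
    S <- stats::cov(Y)
    for (i in which(rowSums(cens) > 0L)) {
      for (j in which(cens[i, ])) {
        obs <- which(!cens[i, ])
        if (length(obs)) {
          Soo <- S[obs, obs, drop = FALSE]
          cm <- mu[j] + S[j, obs, drop = FALSE] %*%
            solve(Soo, Y[i, obs] - mu[obs])
          cv <- S[j, j] - S[j, obs, drop = FALSE] %*%
            solve(Soo, S[obs, j, drop = FALSE])
        } else {
          cm <- mu[j]
          cv <- S[j, j]
        }
        s <- sqrt(max(as.numeric(cv), 1e-12))
        a <- (psi[i] - as.numeric(cm)) / s
        # E[X | X < psi] for X ~ N(cm, s^2)
        Y[i, j] <- as.numeric(cm) - s * stats::dnorm(a) /
          pmax(stats::pnorm(a), 1e-12)
      }
    }
    new <- c(colMeans(Y), stats::cov(Y))
    if (max(abs(new - old)) < tol) break
    old <- new
  }
  x <- cbind(exp(Y), 1)  # alr inverse up to closure
  perm <- order(c(other, ref))
  x <- x[, perm, drop = FALSE]
  # only censored rows were touched; rebuild them, keep the rest exact
  redone <- which(rowSums(zero) > 0L)
  for (i in redone) m[i, ] <- x[i, ] / sum(x[i, ]) * total
  m
}
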