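#' Canonical behavior parts of the 24-hour day
#'
#' The four mutually exclusive and exhaustive behavior categories making up a
#' 1440-minute day: sleep, sedentary behavior (SB), light physical activity
#' (LPA) and moderate-to-vigorous physical activity (MVPA). All composition
#' functions in the package accept and return parts in this canonical order.
#'
#' @format Character vector of length 4.
#' @export
behavior_parts <- c("sleep", "sb", "lpa", "mvpa")

#' Named pivot-coordinate rotations for the four-part day
#'
#' Each rotation is a permutation of the four behaviors defining a sequential
#' binary partition: the first listed part is pivoted against the geometric
#' mean of the rest in the first ilr coordinate, the second against the
#' remaining two, and the third against the last. Fitting the same model under
#' all four rotations makes every behavior's balance against the others appear
#' once as an interpretable coordinate:
#'
#' * `H1`: SB vs (LPA, MVPA, sleep); LPA vs (MVPA, sleep); MVPA vs sleep
#' * `H2`: LPA vs (sleep, MVPA, SB); sleep vs (MVPA, SB); MVPA vs SB
#' * `H3`: sleep vs (MVPA, LPA, SB); MVPA vs (LPA, SB); LPA vs SB
#' * `H4`: MVPA vs (LPA, sleep, SB); LPA vs (sleep, SB); sleep vs SB
#'
#' @format Named list of length-4 character vectors.
#' @export
ilr_orderings <- list(
  H1 = c("sb", "lpa", "mvpa", "sleep"),
  H2 = c("lpa", "sleep", "mvpa", "sb"),
  H3 = c("sleep", "mvpa", "lpa", "sb"),
  H4 = c("mvpa", "lpa", "sleep", "sb")
)

# Orthonormal pivot (sequential binary partition) basis for D = 4:
# column k contrasts part k against the geometric mean of parts k+1..D.
pivot_basis <- function() {
  D <- 4L
  V <- matrix(0, D, D - 1L)
  for (k in seq_len(D - 1L)) {
    r <- D - k
    V[k, k] <- sqrt(r / (r + 1))
    V[(k + 1L):D, k] <- -sqrt(r / (r + 1)) / r
  }
  V
}

.resolve_ordering <- function(ordering) {
  if (is.character(ordering) && length(ordering) == 1L) {
    if (!ordering %in% names(ilr_orderings)) {
      stop("unknown ordering '", ordering, "'; use one of ",
           paste(names(ilr_orderings), collapse = ", "), call. = FALSE)
    }
    return(ilr_orderings[[ordering]])
  }
  if (is.character(ordering) && length(ordering) == 4L &&
      setequal(ordering, behavior_parts)) {
    return(ordering)
  }
  stop("'ordering' must be an ordering name (\"H1\"..\"H4\") or a permutation of ",
       paste(behavior_parts, collapse = ", "), call. = FALSE)
}

# Coerce a vector / matrix / data frame to an n x 4 matrix in canonical
# part order, using names when present.
.as_part_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, intersect(colnames(x), behavior_parts), drop = FALSE])
  if (is.null(dim(x))) {
    if (length(x) != 4L) stop("a composition needs exactly 4 parts", call. = FALSE)
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  }
  if (ncol(x) != 4L) stop("a composition needs exactly 4 parts", call. = FALSE)
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), behavior_parts)) {
      stop("composition columns must be ", paste(behavior_parts, collapse = ", "),
           call. = FALSE)
    }
    x <- x[, behavior_parts, drop = FALSE]
  } else {
    colnames(x) <- behavior_parts
  }
  storage.mode(x) <- "double"
  x
}

#' Close a behavior composition to a fixed day total
#'
#' Rescales the four parts so they sum to `total` minutes without changing
#' their ratios. Zeros are preserved as zeros; closure is the identity on a
#' row already summing to `total`.
#'
#' @param x Numeric vector of 4 parts, or a matrix/data frame with columns
#'   `sleep`, `sb`, `lpa`, `mvpa` (rows are days).
#' @param total Day total in minutes (default 1440).
#' @return Object of the same shape as `x`, closed to `total`, with parts in
#'   canonical order.
#' @examples
#' close_composition(c(sleep = 1, sb = 1, lpa = 1, mvpa = 1))
#' @export
close_composition <- function(x, total = 1440) {
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  if (any(m < 0) || any(!is.finite(m))) {
    stop("composition parts must be finite and non-negative", call. = FALSE)
  }
  s <- rowSums(m)
  if (any(s <= 0)) stop("cannot close an all-zero composition", call. = FALSE)
  out <- m * (total / s)
  if (vec) out[1L, ] else out
}

#' Geometric-mean composition of a set of days
#'
#' The compositional center: per-part geometric means across days, re-closed
#' to the day total. This is the "geometric average day" reported in
#' time-use studies.
#'
#' @param x Matrix or data frame of daily compositions (columns `sleep`,
#'   `sb`, `lpa`, `mvpa`), all parts strictly positive.
#' @param total Day total in minutes (default 1440).
#' @return Named numeric vector: the geometric-mean day in minutes.
#' @export
geometric_mean_composition <- function(x, total = 1440) {
  m <- .as_part_matrix(x)
  if (any(m <= 0)) {
    stop("geometric mean requires strictly positive parts; replace zeros first",
         call. = FALSE)
  }
  close_composition(exp(colMeans(log(m))), total = total)
}

#' Isometric log-ratio (pivot) coordinates of a behavior composition
#'
#' Maps a four-part composition to three orthonormal balance coordinates
#' under the chosen rotation. With ordered parts \eqn{(x_1, x_2, x_3, x_4)}:
#' \deqn{z_1 = \sqrt{3/4}\,\ln\frac{x_1}{(x_2 x_3 x_4)^{1/3}},\quad
#'       z_2 = \sqrt{2/3}\,\ln\frac{x_2}{\sqrt{x_3 x_4}},\quad
#'       z_3 = \sqrt{1/2}\,\ln\frac{x_3}{x_4}.}
#' The map is scale invariant, so closed and unclosed inputs give identical
#' coordinates.
#'
#' @param x Composition(s): vector, matrix or data frame as in
#'   [close_composition()]; all parts strictly positive.
#' @param ordering Rotation name (`"H1"`..`"H4"`, see [ilr_orderings]) or an
#'   explicit permutation of the part names.
#' @return For a single composition, a named numeric vector `ilr1..ilr3`;
#'   for n rows, an n x 3 matrix. The rotation is attached as attribute
#'   `"ordering"`.
#' @examples
#' ilr_transform(c(sleep = 240, sb = 720, lpa = 240, mvpa = 240), "H1")
#' @export
ilr_transform <- function(x, ordering = "H1") {
  ord <- .resolve_ordering(ordering)
  vec <- is.null(dim(x))
  m <- .as_part_matrix(x)
  if (any(m <= 0)) {
    stop("ilr requires strictly positive parts; replace zeros first",
         call. = FALSE)
  }
  z <- log(m[, ord, drop = FALSE]) %*% pivot_basis()
  colnames(z) <- c("ilr1", "ilr2", "ilr3")
  out <- if (vec) z[1L, ] else z
  attr(out, "ordering") <- if (is.character(ordering) && length(ordering) == 1L) ordering else ord
  out
}

#' Inverse ilr: recover a composition from pivot coordinates
#'
#' Exact inverse of [ilr_transform()] under the same rotation, closed to
#' `total` minutes. `ilr_inverse(c(0, 0, 0))` is the neutral element, the
#' uniform day.
#'
#' @param z Numeric vector of 3 coordinates or an n x 3 matrix.
#' @param ordering Rotation, as in [ilr_transform()].
#' @param total Day total in minutes (default 1440).
#' @return Composition(s) in canonical part order, closed to `total`.
#' @export
ilr_inverse <- function(z, ordering = "H1", total = 1440) {
  ord <- .resolve_ordering(ordering)
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1L)
  if (ncol(z) != 3L) stop("ilr coordinates have 3 columns", call. = FALSE)
  if (any(!is.finite(z))) stop("ilr coordinates must be finite", call. = FALSE)
  lx <- z %*% t(pivot_basis())
  x <- exp(lx)
  x <- x / rowSums(x) * total
  colnames(x) <- ord
  x <- x[, behavior_parts, drop = FALSE]
  if (vec) x[1L, ] else x
}

#' Within-person centering of daily ilr coordinates
#'
#' Subtracts each participant's own arithmetic mean (over their retained
#' days) from the daily coordinates, so the centered predictors carry pure
#' day-to-day (within-person) variation. On the ilr scale this equals
#' compositional perturbation by the inverse of the person's geometric-mean
#' composition.
#'
#' @param data Data frame with an id column and the coordinate columns.
#' @param cols Columns to center (default `ilr1`, `ilr2`, `ilr3`).
#' @param id Participant id column name (default `"pid"`).
#' @param suffix Suffix for the new centered columns (default `"_c"`).
#' @return List with `data` (input plus centered columns) and
#'   `person_means` (one row per participant).
#' @export
center_within_person <- function(data, cols = c("ilr1", "ilr2", "ilr3"),
                                 id = "pid", suffix = "_c") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(id, cols), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pm <- aggregate(data[cols], by = data[id], FUN = mean)
  idx <- match(data[[id]], pm[[id]])
  for (cl in cols) {
    data[[paste0(cl, suffix)]] <- data[[cl]] - pm[[cl]][idx]
  }
  list(data = data, person_means = pm)
}
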