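#' Cost matrix with dummy padding
#'
#' Workers (rows) are predicted tracker positions, jobs (columns) are
#' detections, entries are Euclidean distances in pixels. When tracker and
#' detection counts differ — or some pair is implausibly far — dummy rows and
#' columns at a constant `dummy_cost` make the matrix square, so every
#' worker/job can be explicitly unmatched. The dummy-dummy block costs zero.
#'
#' @param costs Numeric matrix (n_workers x n_jobs), nonnegative.
#' @param dummy_cost Constant cost of matching to a dummy; `NULL` for no
#'   padding.
#' @return A `cost_matrix` object.
#' @export
cost_matrix <- function(costs, dummy_cost = NULL) {
  costs <- as.matrix(costs)
  if (any(costs < 0)) stop("costs must be nonnegative")
  nr <- nrow(costs); nc <- ncol(costs)
  m <- costs
  if (!is.null(dummy_cost)) {
    n <- nr + nc
    m <- matrix(dummy_cost, n, n)
    if (nr > 0 && nc > 0) m[seq_len(nr), seq_len(nc)] <- costs
    if (nr > 0 && nc > 0) m[nr + seq_len(nc), nc + seq_len(nr)] <- 0
  }
  structure(list(costs = m, n_rows = nr, n_cols = nc,
                 dummy_cost = dummy_cost), class = "cost_matrix")
}

as_cost_matrix <- function(x) {
  if (inherits(x, "cost_matrix")) x else cost_matrix(x)
}

# Hungarian algorithm (potentials + shortest augmenting paths) for an
# n x m matrix with n <= m; returns, per row, the assigned column.
hungarian_solve <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- cols[!used[cols + 1]]
      cur <- a[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1] <- j0
      }
      k <- which.min(minv[free])
      delta <- minv[free][k]
      j1 <- free[k]
      usedj <- which(used) - 1L          # columns (and sentinel 0) in tree
      u[p[usedj + 1] + 1] <- u[p[usedj + 1] + 1] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}

new_assignment <- function(cm, rows, cols) {
  real <- rows <= cm$n_rows & cols <= cm$n_cols
  pairs <- tibble::tibble(worker = rows[real], job = cols[real],
                          cost = cm$costs[cbind(rows[real], cols[real])])
  structure(list(
    pairs = pairs,
    unmatched_workers = setdiff(seq_len(cm$n_rows), pairs$worker),
    unmatched_jobs = setdiff(seq_len(cm$n_cols), pairs$job),
    total_cost = sum(pairs$cost)), class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("<assignment: %d pairs, total cost %.3f, %d/%d unmatched>\n",
              nrow(x$pairs), x$total_cost, length(x$unmatched_workers),
              length(x$unmatched_jobs)))
  invisible(x)
}

#' Optimal assignment (Hungarian algorithm)
#'
#' Globally minimizes the total cost of a one-to-one worker/job matching.
#' Pairs involving a dummy row or column are reported as unmatched.
#'
#' @param c A [cost_matrix()] or plain numeric matrix.
#' @return An `assignment`: tibble `pairs` (`worker`, `job`, `cost`),
#'   `unmatched_workers`, `unmatched_jobs`, `total_cost` (over real pairs).
#' @export
#' @examples
#' hungarian_assign(matrix(c(1, 2, 2, 1), 2))$total_cost  # 2
hungarian_assign <- function(c) {
  cm <- as_cost_matrix(c)
  a <- cm$costs
  if (nrow(a) == 0 || ncol(a) == 0)
    return(new_assignment(cm, integer(), integer()))
  if (nrow(a) <= ncol(a)) {
    ans <- hungarian_solve(a)
    rows <- seq_len(nrow(a)); cols <- ans
  } else {
    ans <- hungarian_solve(t(a))
    cols <- seq_len(ncol(a)); rows <- ans
  }
  keep <- cols > 0 & rows > 0
  new_assignment(cm, rows[keep], cols[keep])
}

#' Greedy closest-neighbor assignment
#'
#' Repeatedly takes the globally smallest remaining cost, fixes that pair,
#' and deletes its row and column, until no rows or columns remain. Locally
#' optimal only: each pair is the best still available, but the total cost
#' can exceed the Hungarian optimum. Ties break toward the lowest row, then
#' the lowest column.
#'
#' @inheritParams hungarian_assign
#' @return An `assignment` (see [hungarian_assign()]).
#' @export
#' @examples
#' closest_neighbor_assign(matrix(c(1, 1.5, 2, 10), 2))$total_cost  # 11
closest_neighbor_assign <- function(c) {
  cm <- as_cost_matrix(c)
  a <- cm$costs
  nr <- nrow(a); nc <- ncol(a)
  rows <- integer(); cols <- integer()
  row_alive <- rep(TRUE, nr); col_alive <- rep(TRUE, nc)
  while (any(row_alive) && any(col_alive)) {
    sub <- a[row_alive, col_alive, drop = FALSE]
    mn <- min(sub)
    hit <- which(sub == mn, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    ri <- which(row_alive)[hit[1, 1]]
    ci <- which(col_alive)[hit[1, 2]]
    rows <- c(rows, ri); cols <- c(cols, ci)
    row_alive[ri] <- FALSE; col_alive[ci] <- FALSE
  }
  new_assignment(cm, rows, cols)
}
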