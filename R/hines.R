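# Tree-specialized Gaussian elimination for the sparse quasi-tridiagonal
# cable system.
#
# Each compartment n contributes one row of
#     b_n V_p(n) + d_n V_n + sum_{c: p(c)=n} a_c V_c = rhs_n
# where a_n = b_n = -1/r_n couple row n to its parent (the matrix is
# symmetric) and the system is solved for the voltage increment dV.  Because
# every row has a single sub-diagonal entry, elimination leaves-to-root
# (backward triangulation) followed by a root-to-leaves back-solve (forward
# substitution) solves the system without fill-in.

#' Construct solver arrays for a (sub)tree system
#'
#' @param parent 1-based parent index per row; `NA` for the first row (the
#'   local root).
#' @param a,b Child/parent coupling coefficients (uS); `a[i]` appears in row
#'   `parent[i]`, `b[i]` in row `i`.  The root entries hold the cross-boundary
#'   coupling when the arrays describe a subtree that hangs below a parent
#'   subtree, and 0 otherwise.
#' @param d Main diagonal (uS).
#' @param rhs Right-hand side (nA; holds dV in mV after substitution).
#' @param v Membrane voltage (mV), optional bookkeeping.
#' @return A `solver_arrays` list.
#' @export
solver_arrays <- function(parent, a, b, d, rhs, v = numeric(length(d))) {
  n <- length(d)
  stopifnot(length(parent) == n, length(a) == n, length(b) == n,
            length(rhs) == n, length(v) == n)
  if (n > 1L && any(parent[-1] >= seq(2L, n), na.rm = TRUE)) {
    stop("solver_arrays: parent index must be smaller than row index")
  }
  structure(list(n = n, parent = parent, a = a, b = b, d = d,
                 rhs = rhs, v = v),
            class = "solver_arrays")
}

#' Per-step matrix set-up
#'
#' Fills the diagonal and right-hand side of the dV system for one subtree:
#' `d_n = C_n/dt + G_n + sum_children 1/r_c + 1/r_n` (the `1/r_n` term only
#' for rows with a parent, including a subtree root coupled across the
#' boundary) and `rhs_n` = injected minus ionic current plus the axial terms
#' `sum_c (v_c - v_n)/r_c - (v_n - v_p)/r_n`, where a subtree root reads
#' `v_p` from the cached parent boundary voltage.
#'
#' @param arrays A `solver_arrays` whose `a`, `b` encode `-1/r`.
#' @param G Summed mechanism conductance per row (uS).
#' @param i_total Summed mechanism current per row (nA; injected stimuli
#'   enter negatively).
#' @param C Membrane capacitance per row (nF).
#' @param dt Timestep (ms).
#' @param parent_boundary_v Cached voltage of the parent-subtree connecting
#'   compartment (mV), or `NULL` for a whole-neuron root.
#' @param boundary_children Optional list of `list(row =, ga =, v =)` for
#'   child subtrees attached below leaf `row` with coupling `ga` (uS) and
#'   cached child-root voltage `v`.
#' @return The updated `solver_arrays`.
#' @export
setup_matrix <- function(arrays, G, i_total, C, dt,
                         parent_boundary_v = NULL,
                         boundary_children = list()) {
  stopifnot(inherits(arrays, "solver_arrays"), dt > 0)
  n <- arrays$n
  v <- arrays$v
  has_boundary_root <- arrays$a[1] != 0
  if (has_boundary_root && is.null(parent_boundary_v)) {
    stop("setup_matrix: missing parent boundary voltage for a non-root subtree")
  }
  ga_self <- -arrays$b            # 1/r_n for each row (0 where no parent)
  d <- C / dt + G + ga_self
  rhs <- -i_total
  if (n > 1L) {
    idx <- 2:n
    p <- arrays$parent[idx]
    e <- ga_self[idx] * (v[p] - v[idx])
    rhs[idx] <- rhs[idx] + e
    acc <- rowsum_ordered(cbind(-e, ga_self[idx]), p)
    d[acc$group] <- d[acc$group] + acc$sums[, 2]
    rhs[acc$group] <- rhs[acc$group] + acc$sums[, 1]
  }
  if (has_boundary_root) {
    rhs[1] <- rhs[1] + ga_self[1] * (parent_boundary_v - v[1])
  }
  for (bc in boundary_children) {
    d[bc$row] <- d[bc$row] + bc$ga
    rhs[bc$row] <- rhs[bc$row] + bc$ga * (bc$v - v[bc$row])
  }
  arrays$d <- d
  arrays$rhs <- rhs
  arrays
}

#' Backward triangulation (leaves-to-root elimination)
#'
#' Folds every row into its parent's diagonal and right-hand side in
#' descending index order (a valid leaves-to-root topological order).  When
#' the arrays describe a subtree hanging below a parent subtree, the
#' eliminated root row emits its contribution to the parent-subtree
#' connecting compartment instead of being folded locally.
#'
#' @param arrays A `solver_arrays` after [setup_matrix()]; boundary-child
#'   contributions must already be folded into the leaf rows.
#' @return `list(arrays =, boundary =)` where `boundary` is
#'   `list(delta_d =, delta_rhs =)` for the parent's connecting row, or
#'   `NULL` for a whole-neuron root.
#' @export
backward_triangulate <- function(arrays) {
  stopifnot(inherits(arrays, "solver_arrays"))
  n <- arrays$n
  a <- arrays$a; b <- arrays$b; d <- arrays$d; rhs <- arrays$rhs
  p <- arrays$parent
  if (n > 1L) {
    for (i in n:2) {
      if (d[i] == 0) stop(sprintf("backward_triangulate: singular pivot at row %d", i))
      f <- a[i] / d[i]
      pi_ <- p[i]
      d[pi_] <- d[pi_] - f * b[i]
      rhs[pi_] <- rhs[pi_] - f * rhs[i]
    }
  }
  arrays$d <- d; arrays$rhs <- rhs
  boundary <- NULL
  if (a[1] != 0) {
    if (d[1] == 0) stop("backward_triangulate: singular pivot at subtree root")
    f <- a[1] / d[1]
    boundary <- list(delta_d = -f * b[1], delta_rhs = -f * rhs[1])
  }
  list(arrays = arrays, boundary = boundary)
}

#' Forward substitution (root-to-leaves back-solve)
#'
#' Turns the triangulated right-hand side into the voltage increment dV.
#' A whole-neuron root solves its own row; a subtree root first absorbs the
#' parent connecting compartment's dV received across the boundary.
#'
#' @param arrays Triangulated `solver_arrays`.
#' @param parent_delta_v dV of the parent-subtree connecting compartment
#'   (mV), or `NULL` for a whole-neuron root.
#' @return The arrays with `rhs` holding dV.
#' @export
forward_substitute <- function(arrays, parent_delta_v = NULL) {
  stopifnot(inherits(arrays, "solver_arrays"))
  n <- arrays$n
  b <- arrays$b; d <- arrays$d; rhs <- arrays$rhs; p <- arrays$parent
  if (arrays$a[1] != 0) {
    if (is.null(parent_delta_v)) {
      stop("forward_substitute: missing parent dV for a non-root subtree")
    }
    rhs[1] <- (rhs[1] - b[1] * parent_delta_v) / d[1]
  } else {
    rhs[1] <- rhs[1] / d[1]
  }
  if (n > 1L) {
    for (i in 2:n) {
      rhs[i] <- (rhs[i] - b[i] * rhs[p[i]]) / d[i]
    }
  }
  arrays$rhs <- rhs
  arrays
}

#' Solve a whole-neuron tree system
#'
#' Composition of [backward_triangulate()] and [forward_substitute()] on a
#' system with no subtree boundaries; equal (to rounding) to a dense solve of
#' the assembled matrix.
#'
#' @param arrays A `solver_arrays` with `a[1] = b[1] = 0`.
#' @return The dV vector (mV).
#' @export
solve_tree <- function(arrays) {
  if (arrays$a[1] != 0) stop("solve_tree: expected a whole-neuron system")
  tri <- backward_triangulate(arrays)
  forward_substitute(tri$arrays)$rhs
}

#' Assemble the dense matrix of a tree system
#'
#' Bookkeeping helper used to cross-check the tree solver against a dense
#' solve: `A[i, i] = d_i`, `A[i, p(i)] = b_i`, `A[p(i), i] = a_i`.
#'
#' @param arrays A `solver_arrays`.
#' @return The dense `n x n` matrix.
#' @export
as_dense_matrix <- function(arrays) {
  n <- arrays$n
  A <- matrix(0, n, n)
  diag(A) <- arrays$d
  if (n > 1L) {
    for (i in 2:n) {
      A[i, arrays$parent[i]] <- arrays$b[i]
      A[arrays$parent[i], i] <- arrays$a[i]
    }
  }
  A
}

# one-shot sanity check used at t = 0: the cable system should be strictly
# diagonally dominant for the implicit step to be well-conditioned
check_diagonal_dominance <- function(arrays) {
  n <- arrays$n
  off <- abs(arrays$b)
  if (n > 1L) {
    acc <- rowsum_ordered(cbind(abs(arrays$a[2:n])), arrays$parent[2:n])
    off[acc$group] <- off[acc$group] + acc$sums[, 1]
  }
  if (any(arrays$d <= off)) {
    warning("cable matrix is not strictly diagonally dominant at t = 0")
  }
  invisible(all(arrays$d > off))
}

#' Dump solver arrays to CSV for fixture diffing
#' @param arrays A `solver_arrays`.
#' @param path Output CSV path.
#' @export
dump_solver_arrays <- function(arrays, path) {
  df <- data.frame(row = seq_len(arrays$n),
                   parent = ifelse(is.na(arrays$parent), 0L, arrays$parent),
                   a = arrays$a, b = arrays$b, d = arrays$d,
                   rhs = arrays$rhs, v = arrays$v)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
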