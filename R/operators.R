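# Sparse operator assembly for the linearised system ---------------------
#
# The linearised right-hand side is linear in the stacked state
# u = (a, b, c), so the whole spatial+reaction operator is one sparse
# matrix A with u' = A u.  Both spatial blocks are multiples of a single
# scalar operator S (interior 5-point Laplacian + one-sided no-flux
# boundary divergence), because each equation's flux is the gradient of a
# single potential: w_a = D_a a and w_b = D_b b - chi_a a.  S is assembled
# once per (grid, div_mode) by applying the field-level operator to basis
# vectors, which keeps the matrix provably identical to rhs_linearized().

.ps_op_cache <- new.env(parent = emptyenv())

grid_signature <- function(grid, div_mode) {
  paste(grid$m, grid$n, signif(grid$tau_ext, 15), signif(grid$tau_int, 15),
        signif(grid$d, 15), div_mode, sep = "|")
}

# scalar spatial operator S(w): interior Laplacian, boundary flux divergence
apply_scalar_operator <- function(w, grid, div_mode) {
  out <- laplacian(w, grid)
  dv <- divergence_boundary(flux_tau(w, grid), flux_sigma(w, grid),
                            grid, div_mode)
  out[1, ] <- dv$row1
  out[grid$m, ] <- dv$rowm
  out
}

#' Sparse matrix of the scalar spatial operator
#'
#' Assembles the `m*n x m*n` sparse matrix of the discrete diffusion
#' operator (interior 5-point Laplacian scaled by \eqn{1/h^2}, one-sided
#' no-flux flux-divergence at the two tau boundary rows).  Cached per grid
#' and divergence mode.
#'
#' @param grid A `ps_grid`.
#' @param div_mode `"faithful"` or `"consistent"`.
#' @return A `dgCMatrix`.
#' @export
spatial_operator_matrix <- function(grid, div_mode = "faithful") {
  key <- grid_signature(grid, div_mode)
  hit <- .ps_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- grid$m; n <- grid$n; mn <- m * n
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  w <- matrix(0, m, n)
  for (k in seq_len(mn)) {
    w[k] <- 1
    col <- apply_scalar_operator(w, grid, div_mode)
    w[k] <- 0
    nz <- which(col != 0)
    ii <- c(ii, nz); jj <- c(jj, rep.int(k, length(nz))); xx <- c(xx, col[nz])
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(mn, mn))
  .ps_op_cache[[key]] <- S
  S
}

#' Full linearised system matrix
#'
#' The `3mn x 3mn` sparse matrix A with \eqn{u' = A u} for the stacked
#' perturbation vector `(a, b, c)`:
#' \deqn{A = \begin{pmatrix} D_a S - k_1 I & -k_2 I & 0 \\
#'  -\chi_a S - k_3 I & D_b S - k_4 I & 0 \\
#'   k_6 I & k_4 I & -k_5 I \end{pmatrix}.}
#'
#' @param lc A `ps_lincoef`.
#' @param grid A `ps_grid`.
#' @param div_mode `"faithful"` or `"consistent"`.
#' @return A `dgCMatrix`.
#' @export
linearized_system_matrix <- function(lc, grid, div_mode = "faithful") {
  S <- spatial_operator_matrix(grid, div_mode)
  mn <- nrow(S)
  I <- Matrix::Diagonal(mn)
  Z <- Matrix::Matrix(0, mn, mn, sparse = TRUE)
  A <- rbind(
    cbind(lc$D_a * S - lc$k1 * I, -lc$k2 * I, Z),
    cbind(-lc$chi_a * S - lc$k3 * I, lc$D_b * S - lc$k4 * I, Z),
    cbind(lc$k6 * I, lc$k4 * I, -lc$k5 * I)
  )
  methods::as(A, "CsparseMatrix")
}

# ------------------------------------------------------------------
# Sparse finite-difference Jacobian of the nonlinear right-hand side,
# with conservative structural colouring.  Column (i, j, s) can affect
# rows with i' in {i-1, i, i+1}, plus row 1 when i <= 4 and row m when
# i >= m-3 (the one-sided boundary stencil), sigma offsets within +-2
# (periodic), any species.  Columns share a colour only when their row
# sets are provably disjoint.

jac_row_set <- function(i, j, m, n) {
  is <- unique(pmax(1L, pmin(m, c(i - 1L, i, i + 1L))))
  if (i <= 4L) is <- union(is, 1L)
  if (i >= m - 3L) is <- union(is, m)
  js <- ((j - 1L + c(-2L, -1L, 0L, 1L, 2L)) %% n) + 1L
  list(is = is, js = unique(js))
}

nonlinear_jacobian <- function(ufun, u, fu, m, n) {
  mn <- m * n
  gi <- min(m, 7L)
  divs <- which(n %% seq_len(n) == 0L)
  pj <- if (any(divs >= 5L)) min(divs[divs >= 5L]) else n
  idx <- seq_len(3L * mn)
  s <- ((idx - 1L) %/% mn)
  within <- ((idx - 1L) %% mn)
  ic <- (within %% m)                      # 0-based row in grid
  jc <- (within %/% m)                     # 0-based column in grid
  color <- s + 3L * (ic %% gi) + 3L * gi * (jc %% pj)
  scale_u <- 1e-7 * pmax(abs(u), 1e-3)
  trip_i <- vector("list", length(unique(color)))
  trip_j <- trip_i; trip_x <- trip_i
  cix <- 0L
  for (cl in unique(color)) {
    cols <- idx[color == cl]
    du <- numeric(3L * mn)
    du[cols] <- scale_u[cols]
    fd <- ufun(u + du) - fu
    li <- integer(0); lj <- integer(0); lx <- numeric(0)
    for (k in cols) {
      kk <- ((k - 1L) %% mn)
      rs <- jac_row_set((kk %% m) + 1L, (kk %/% m) + 1L, m, n)
      rows <- as.vector(outer(rs$is, (rs$js - 1L) * m, `+`))
      rows <- c(rows, rows + mn, rows + 2L * mn)
      vals <- fd[rows] / scale_u[k]
      nz <- vals != 0
      li <- c(li, rows[nz]); lj <- c(lj, rep.int(k, sum(nz)))
      lx <- c(lx, vals[nz])
    }
    cix <- cix + 1L
    trip_i[[cix]] <- li; trip_j[[cix]] <- lj; trip_x[[cix]] <- lx
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(3L * mn, 3L * mn))
}
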