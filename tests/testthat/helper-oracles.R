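# Independent oracle paths, deliberately written without reusing the
# package's implementations.

# Closed-form eigendecomposition of a symmetric 2x2 matrix via the
# quadratic formula on the characteristic polynomial.
oracle_eigen2 <- function(S) {
  a <- S[1, 1]; b <- S[1, 2]; d <- S[2, 2]
  tr <- a + d
  disc <- sqrt((a - d)^2 + 4 * b^2)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  vec_for <- function(l) {
    if (abs(b) > 1e-14) {
      v <- c(l - d, b)
    } else if (a >= d) {
      v <- if (abs(l - a) < abs(l - d)) c(1, 0) else c(0, 1)
    } else {
      v <- if (abs(l - a) < abs(l - d)) c(1, 0) else c(0, 1)
    }
    v / sqrt(sum(v^2))
  }
  list(values = c(l1, l2), vectors = cbind(vec_for(l1), vec_for(l2)))
}

# Component scores by direct projection using the closed-form eigensolver,
# with the same sign convention as the main path.
oracle_decompose <- function(imd, ald) {
  X <- cbind(imd - mean(imd), ald - mean(ald))
  S <- stats::cov(X)
  e <- oracle_eigen2(S)
  v1 <- e$vectors[, 1]; v2 <- e$vectors[, 2]
  if (sum(v1) < 0) v1 <- -v1
  if (v2[1] < 0) v2 <- -v2
  list(pc1 = as.vector(X %*% v1), pc2 = as.vector(X %*% v2),
       values = e$values, v1 = v1, v2 = v2)
}

# Brute-force standardized OLS: z-score by hand, solve the normal
# equations directly.
oracle_std_ols <- function(y, X) {
  z <- function(v) (v - mean(v)) / sd(v)
  zy <- z(y)
  zX <- apply(as.matrix(X), 2, z)
  A <- cbind(1, zX)
  beta <- solve(t(A) %*% A, t(A) %*% zy)
  as.vector(beta[-1])
}

# Mean Pearson correlation over adjacent pairs of a field on a graph.
oracle_neighbour_pair_cor <- function(field, graph) {
  a <- c(); b <- c()
  for (i in seq_along(graph$ids)) {
    for (j in graph$nb[[i]]) {
      if (j > i) { a <- c(a, field[i]); b <- c(b, field[j]) }
    }
  }
  cor(a, b)
}

# Minimal component object for tests that construct scores directly.
fake_components <- function(ids, pc1, pc2) {
  structure(list(
    target_deprivation = stats::setNames(pc1, ids),
    deprivation_differential = stats::setNames(pc2, ids),
    loadings = rbind(PC1 = c(imd = 1, ald = 0), PC2 = c(imd = 0, ald = -1)),
    variance_explained = c(PC1 = var(pc1), PC2 = var(pc2)),
    means = c(imd = 0, ald = 0), scales = c(imd = 1, ald = 1),
    mode = "covariance", ids = ids
  ), class = "deprivation_components")
}

# Unit-square polygon for grid cell (r, c), rows counted downward.
unit_square <- function(r, c) {
  cbind(x = c(c - 1, c, c, c - 1), y = c(r - 1, r - 1, r, r))
}

grid_polygons <- function(rows, cols, ids = NULL) {
  rc <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  polys <- mapply(function(r, c) unit_square(r, c), rc$row, rc$col,
                  SIMPLIFY = FALSE)
  names(polys) <- if (is.null(ids)) sprintf("g%d_%d", rc$row, rc$col) else ids
  polys
}
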