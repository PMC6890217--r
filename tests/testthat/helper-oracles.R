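# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths: the Gram-Schmidt oracle orthonormalizes from
# scratch, the Kabsch oracle solves the least-squares rigid fit by SVD, and
# the edge/triangle brute forces recompute everything from raw coordinates.

norm3 <- function(v) sqrt(sum(v^2))

# Gram-Schmidt orthonormalization of (AB, AC, AB x AC): the reference for
# the tri-point frame construction.
gram_schmidt_frame <- function(A, B, C) {
  u1 <- B - A
  e1 <- u1 / norm3(u1)
  u2 <- (C - A) - sum((C - A) * e1) * e1
  e2 <- u2 / norm3(u2)
  n <- c(u1[2] * (C - A)[3] - u1[3] * (C - A)[2],
         u1[3] * (C - A)[1] - u1[1] * (C - A)[3],
         u1[1] * (C - A)[2] - u1[2] * (C - A)[1])
  e3 <- n / norm3(n)
  rbind(x = e1, y = e2, z = e3)
}

# Optimal least-squares rigid superposition (Kabsch, SVD): returns the
# rotation R and translation t minimizing sum |R x_i + t - y_i|^2.
kabsch_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(X - matrix(cx, nrow(X), 3, byrow = TRUE)) %*%
    (Y - matrix(cy, nrow(Y), 3, byrow = TRUE))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cy - as.numeric(R %*% cx))
}

# Random proper rotation matrix.
rand_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# Random noncollinear triple in a ~50 mm cube (rejects flat ones).
rand_triple <- function() {
  repeat {
    A <- runif(3, 0, 50); B <- runif(3, 0, 50); C <- runif(3, 0, 50)
    ab <- B - A; ac <- C - A
    n <- c(ab[2] * ac[3] - ab[3] * ac[2],
           ab[3] * ac[1] - ab[1] * ac[3],
           ab[1] * ac[2] - ab[2] * ac[1])
    s <- norm3(n) / (norm3(ab) * norm3(ac))
    if (norm3(ab) > 1 && norm3(ac) > 1 && s > 0.05) {
      return(list(A = A, B = B, C = C))
    }
  }
}

apply_rigid <- function(pts, R, t) {
  if (is.matrix(pts)) t(R %*% t(pts)) + matrix(t, nrow(pts), 3, byrow = TRUE)
  else as.numeric(R %*% pts + t)
}

# Landmark table whose real space is an exact rigid copy of planned space.
rigid_copy_pairs <- function(P, R = rand_rotation(), t = runif(3, -30, 30)) {
  Rm <- apply_rigid(P, R, t)
  landmark_pairs(data.frame(
    label = sprintf("L%02d", seq_len(nrow(P))),
    px = P[, 1], py = P[, 2], pz = P[, 3],
    rx = Rm[, 1], ry = Rm[, 2], rz = Rm[, 3]))
}

# Well-spread planned-space landmark cloud (no near-collinear pathologies).
spread_cloud <- function(n) {
  base <- rbind(c(0, 0, 0), c(40, 5, 2), c(18, 30, 4), c(30, 12, 18),
                c(5, 25, 15), c(45, 28, 10), c(12, 8, 12), c(38, 35, 16),
                c(25, 2, 8), c(2, 38, 6), c(48, 15, 3), c(20, 20, 20),
                c(8, 15, 2), c(33, 25, 1), c(15, 35, 18), c(42, 3, 14))
  stopifnot(n <= nrow(base))
  base[seq_len(n), , drop = FALSE]
}

# Brute-force point error: enumerate all triangles containing i from raw
# coordinates, recomputing edge discrepancies from scratch.
brute_point_error <- function(pairs, i) {
  P <- as.matrix(pairs[, c("px", "py", "pz")])
  R <- as.matrix(pairs[, c("rx", "ry", "rz")])
  edge <- function(a, b) {
    dp <- norm3(P[a, ] - P[b, ]); dr <- norm3(R[a, ] - R[b, ])
    abs(dp - dr) / (0.5 * (dp + dr))
  }
  tri <- function(a, b, c) {
    e <- c(edge(a, b), edge(a, c), edge(b, c))
    sum(e) + max(e) - min(e)
  }
  others <- setdiff(seq_len(nrow(pairs)), i)
  uv <- combn(others, 2)
  sum(apply(uv, 2, function(p) tri(i, p[1], p[2])))
}
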