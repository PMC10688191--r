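# Independent oracles used across test files.

# Angle at the vertex from the three pairwise distances (law of cosines).
law_of_cosines_angle <- function(p_a, p_v, p_b) {
  d_ab <- sqrt(sum((p_a - p_b)^2))
  d_av <- sqrt(sum((p_a - p_v)^2))
  d_bv <- sqrt(sum((p_b - p_v)^2))
  acos(pmin(1, pmax(-1, (d_av^2 + d_bv^2 - d_ab^2) / (2 * d_av * d_bv))))
}

# Kabsch superposition RMSD via SVD, independent of bio3d.
kabsch_rmsd <- function(ref, mob) {
  ref <- matrix(ref, ncol = 3L, byrow = TRUE)
  mob <- matrix(mob, ncol = 3L, byrow = TRUE)
  rc <- colMeans(ref); mc <- colMeans(mob)
  P <- sweep(mob, 2L, mc); Q <- sweep(ref, 2L, rc)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- P %*% t(R)
  sqrt(mean(rowSums((fit - Q)^2)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3L, 3L, byrow = TRUE)
}
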