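# Independent oracles used to freeze expected values.  These deliberately do
# NOT share code with the implementation paths they check.

# Horn's quaternion method for optimal superposition RMSD: build the 4x4 key
# matrix from the correlation matrix of centered point sets and take its
# largest eigenvalue.  Independent of the SVD (Kabsch) route in the package.
oracle_quaternion_rmsd <- function(A, B) {
  a <- sweep(A, 2, colMeans(A))
  b <- sweep(B, 2, colMeans(B))
  M <- crossprod(b, a)  # sum over points of b_i a_i^T
  K <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2], M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3], M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1], -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3], M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(a^2) + sum(b^2) - 2 * lambda) / nrow(A))
}

# Brute-force minimax path value between two cells of a small free-energy
# grid: depth-first enumeration of all simple paths (8-connected over finite
# cells), tracking the lowest possible maximum cell value.
oracle_minimax_path <- function(fe, a, b) {
  n1 <- nrow(fe); n2 <- ncol(fe)
  best <- Inf
  visited <- matrix(FALSE, n1, n2)
  dfs <- function(i, j, path_max) {
    if (path_max >= best) return(invisible())
    if (i == b[1] && j == b[2]) { best <<- path_max; return(invisible()) }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- i + di; vj <- j + dj
      if (vi < 1 || vi > n1 || vj < 1 || vj > n2) next
      if (visited[vi, vj] || !is.finite(fe[vi, vj])) next
      dfs(vi, vj, max(path_max, fe[vi, vj]))
    }
    visited[i, j] <<- FALSE
  }
  dfs(a[1], a[2], fe[a[1], a[2]])
  best
}

# Recovery metric shared by assignment tests: fraction of distinct truth
# atom pairs present among correctly assigned unambiguous restraints, plus
# the count of unambiguous pairs that are not truth pairs.
oracle_recovery <- function(rset, truth) {
  pk <- function(r1, a1, r2, a2)
    paste(pmin(paste(r1, a1), paste(r2, a2)),
          pmax(paste(r1, a1), paste(r2, a2)), sep = "|")
  truth_keys <- unique(pk(truth$res_a, truth$atom_a, truth$res_b, truth$atom_b))
  un <- as.data.frame(rset)[!rset$ambiguous, , drop = FALSE]
  un_keys <- unique(pk(un$res_a, un$atom_a, un$res_b, un$atom_b))
  list(recovered = mean(truth_keys %in% un_keys),
       false_unambiguous = sum(!un_keys %in% truth_keys))
}
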