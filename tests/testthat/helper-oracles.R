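## Independent brute-force oracles. These deliberately re-derive every
## quantity from first principles (explicit hat matrices, exhaustive
## enumeration, naive tail minima) and share no code with the package
## internals they check.

## all permutations of 1..n, one per row (plain recursion)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## Gower-centered matrix via the explicit projector J = I - 11'/n
oracle_gower <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% (D^2) %*% J
}

## sequential PERMANOVA pseudo-F values for all terms, hat matrices built
## with solve() on explicit model matrices
oracle_permanova_F <- function(D, M_list, perm = seq_len(nrow(D))) {
  G <- oracle_gower(D)
  n <- nrow(D)
  hat <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  M_prev <- matrix(1, n, 1)
  ss <- numeric(length(M_list))
  df <- numeric(length(M_list))
  for (j in seq_along(M_list)) {
    M_cur <- cbind(M_prev, M_list[[j]][perm, , drop = FALSE])
    ss[j] <- sum(diag(hat(M_cur) %*% G)) - sum(diag(hat(M_prev) %*% G))
    df[j] <- ncol(M_list[[j]])
    M_prev <- M_cur
  }
  ss_total <- sum(diag(G))
  df_res <- n - 1 - sum(df)
  ss_res <- ss_total - sum(ss)
  list(ss = ss, F = (ss / df) / (ss_res / df_res), R2 = ss / ss_total,
       ss_res = ss_res)
}

## exact PERMANOVA p-value for the last term by enumerating all n! label
## permutations (proportion with F >= observed, identity included)
oracle_permanova_exact_p <- function(D, M_list) {
  f_obs <- oracle_permanova_F(D, M_list)$F
  j <- length(M_list)
  perms <- oracle_perms(nrow(D))
  f_all <- apply(perms, 1, function(p) oracle_permanova_F(D, M_list, p)$F[j])
  mean(f_all >= f_obs[j] - 1e-8)
}

## ANOSIM R from scratch: rank off-diagonal distances, contrast mean ranks
oracle_anosim_R <- function(D, groups) {
  n <- nrow(D)
  rb <- c(); rw <- c()
  r <- matrix(0, n, n)
  idx <- which(lower.tri(D))
  r[idx] <- rank(D[idx])
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (groups[i] == groups[j]) rw <- c(rw, r[i, j]) else rb <- c(rb, r[i, j])
  }
  (mean(rb) - mean(rw)) / (n * (n - 1) / 4)
}

oracle_anosim_exact_p <- function(D, groups) {
  r_obs <- oracle_anosim_R(D, groups)
  perms <- oracle_perms(nrow(D))
  r_all <- apply(perms, 1, function(p) oracle_anosim_R(D, groups[p]))
  mean(r_all >= r_obs - 1e-12)
}

## BH step-up by the "minimum over the tail" definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## random valid distance matrix (Euclidean, hence metric) on n points
random_euclidean_D <- function(n, d = 3) {
  Y <- matrix(rnorm(n * d), n, d)
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  D
}

## small relative-abundance matrix
random_relabund <- function(n, t) {
  X <- matrix(rexp(n * t), n, t,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:t)))
  X / rowSums(X)
}
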