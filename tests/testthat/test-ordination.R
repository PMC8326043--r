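test_that("Gower centering matches the explicit projector form", {
  D0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(gower_center(D0)), matrix(0, 3, 3))
  ## two points at distance d: the single positive eigenvalue is d^2/2
  d <- 1.7
  D2 <- matrix(c(0, d, d, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(max(eigen(gower_center(D2))$values), d^2 / 2)
  ## 3 x 3 with unit off-diagonals: trace of G is 1
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  G <- gower_center(D3)
  expect_equal(sum(diag(G)), 1)
  expect_equal(G, oracle_gower(D3), ignore_attr = TRUE)
  expect_equal(max(abs(rowSums(G))), 0, tolerance = 1e-9)
  bad <- D3; bad[1, 2] <- 2
  expect_error(gower_center(bad), "symmetric")
})

test_that("PCoA recovers geometry and matches an independent eigensolver", {
  ## collinear points: one positive axis reproducing the line up to sign
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x)); dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit <- pcoa(D)
  expect_equal(sum(fit$eigenvalues > 1e-8), 1)
  got <- fit$coordinates[, 1]
  expect_equal(sort(abs(outer(got, got, `-`))[lower.tri(D)]),
               sort(D[lower.tri(D)]))
  ## equilateral triangle at distance 1: G = J/2, so two eigenvalues of 1/2
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  ev <- pcoa(D3)$eigenvalues
  expect_equal(ev, c(0.5, 0.5, 0))
  ## against ape on a non-Euclidean Bray-Curtis matrix
  set.seed(81)
  Db <- bray_curtis_matrix(random_relabund(10, 12))
  expect_equal(pcoa(Db)$eigenvalues,
               ape::pcoa(as.dist(unclass(Db)))$values$Eigenvalues,
               tolerance = 1e-8)
})

test_that("PCoA corrections remove negative eigenvalues while keeping order", {
  set.seed(82)
  Db <- bray_curtis_matrix(random_relabund(12, 8))
  expect_lt(min(pcoa(Db)$eigenvalues), -1e-8)   # genuinely non-Euclidean
  for (corr in c("lingoes", "cailliez")) {
    fit <- pcoa(Db, correction = corr)
    expect_gt(fit$correction_constant, 0)
    expect_gt(min(fit$eigenvalues), -1e-6)
    ## the embedding reproduces the corrected distances
    cc <- fit$correction_constant
    target <- if (corr == "lingoes") sqrt(unclass(Db)^2 + 2 * cc)
              else unclass(Db) + cc
    diag(target) <- 0
    expect_equal(as.matrix(dist(fit$coordinates)), target,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("PERMANOVA partitioning matches vegan::adonis2 exactly", {
  set.seed(83)
  X <- random_relabund(30, 25)
  D <- bray_curtis_matrix(X)
  dat <- data.frame(sample_id = rownames(X),
                    age = rnorm(30), grp = rep(c("u", "v", "w"), 10),
                    diet = rnorm(30))
  fit <- permanova(D, dat, c("age", "grp", "diet"), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(unclass(D)) ~ age + grp + diet, data = dat,
                        permutations = 99, by = "terms")
  expect_equal(fit$aov_tab$SS, ref$SumOfSqs, tolerance = 1e-9)
  expect_equal(fit$aov_tab$R2, ref$R2, tolerance = 1e-9)
  expect_equal(fit$aov_tab$F[1:3], ref$F[1:3], tolerance = 1e-9)
  expect_equal(fit$aov_tab$df[1:3], c(1, 2, 1))
  ## R2 partition sums to one
  expect_equal(sum(fit$aov_tab$R2[1:4]), 1, tolerance = 1e-9)
})

test_that("PERMANOVA p-values agree with exhaustive enumeration on small n", {
  set.seed(84)
  D <- random_euclidean_D(6)
  grp <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)
  dat <- data.frame(sample_id = rownames(D), grp = grp[, 1])
  exact <- oracle_permanova_exact_p(D, list(grp))
  fit_ex <- permanova(D, dat, "grp", seed = 1, exhaustive = TRUE)
  expect_equal(fit_ex$aov_tab$p[1], exact, tolerance = 1e-12)
  ## sampled p lands within Monte-Carlo error of the exact value
  fit_mc <- permanova(D, dat, "grp", n_perm = 999, seed = 1)
  tol <- 3 * sqrt(exact * (1 - exact) / 999)
  expect_lt(abs(fit_mc$aov_tab$p[1] - exact), tol + 2 / 999)
})

test_that("separated groups and equidistant designs give the closed-form answers", {
  ## two tight clusters far apart: group term explains almost everything
  pts <- c(0, 0.01, 0.02, 10, 10.01, 10.02)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  dat <- data.frame(sample_id = rownames(D), grp = rep(c("a", "b"), each = 3))
  fit <- permanova(D, dat, "grp", exhaustive = TRUE)
  expect_gt(fit$aov_tab$R2[1], 0.999)
  ## exactly 1/C(6,3) * 2 orderings preserve the split under relabelling
  expect_equal(fit$aov_tab$p[1], 2 * 36 / 720)
  ## all pairwise distances equal: R2 equals the df share and F is ~1
  De <- matrix(1, 6, 6) - diag(6)
  dimnames(De) <- dimnames(D)
  fe <- permanova(De, dat, "grp", n_perm = 9, seed = 1)
  expect_equal(fe$aov_tab$R2[1], 1 / 5, tolerance = 1e-9)
  expect_equal(fe$aov_tab$F[1], 1, tolerance = 1e-9)
})

test_that("PERMANOVA on Euclidean distances equals raw-space RDA partitioning", {
  set.seed(85)
  n <- 24
  Y <- matrix(rnorm(n * 6), n, 6)
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  age <- rnorm(n); diet <- rnorm(n)
  dat <- data.frame(sample_id = rownames(D), age = age, diet = diet)
  fit <- permanova(D, dat, c("age", "diet"), n_perm = 9, seed = 1)
  ## oracle: classical sequential sums of squares on the centred response
  Yc <- scale(Y, scale = FALSE)
  hat <- function(M) M %*% solve(crossprod(M)) %*% t(M)
  H1 <- hat(cbind(1, age)); H12 <- hat(cbind(1, age, diet))
  ss_age <- sum(diag(H1 %*% tcrossprod(Yc)))
  ss_diet <- sum(diag(H12 %*% tcrossprod(Yc))) - ss_age
  expect_equal(fit$aov_tab$SS[1], ss_age, tolerance = 1e-6)
  expect_equal(fit$aov_tab$SS[2], ss_diet, tolerance = 1e-6)
  expect_equal(fit$aov_tab$SS[4], sum(Yc^2), tolerance = 1e-6)
})

test_that("rank-deficient or over-saturated designs are refused with names", {
  set.seed(86)
  D <- random_euclidean_D(8)
  dat <- data.frame(sample_id = rownames(D), a = rnorm(8))
  dat$b <- 2 * dat$a
  expect_error(permanova(D, dat, c("a", "b"), n_perm = 9), "collinear")
  small <- random_euclidean_D(4)
  dats <- data.frame(sample_id = rownames(small), a = rnorm(4), b = rnorm(4),
                     c = rnorm(4))
  expect_error(permanova(small, dats, c("a", "b", "c"), n_perm = 9),
               "too few samples")
})

test_that("ANOSIM matches its definition, vegan, and exhaustive enumeration", {
  ## complete separation: R = 1
  pts <- c(0, 1, 2, 50, 51, 52)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim(D, g, n_perm = 9, seed = 1)$statistic, 1)
  ## all distances tied: R = 0
  De <- matrix(1, 6, 6) - diag(6); dimnames(De) <- dimnames(D)
  expect_equal(anosim(De, g, n_perm = 9, seed = 1)$statistic, 0)
  ## random instances: equality with the brute-force oracle and with vegan
  set.seed(87)
  for (rep in 1:5) {
    Dr <- random_euclidean_D(8)
    gr <- sample(rep(c("a", "b"), 4))
    r <- anosim(Dr, gr, n_perm = 9, seed = 1)$statistic
    expect_equal(r, oracle_anosim_R(Dr, gr), tolerance = 1e-12)
    ref <- vegan::anosim(as.dist(Dr), gr, permutations = 0)
    expect_equal(r, unname(ref$statistic), tolerance = 1e-12)
  }
  ## n = 4, two groups of two: exact p over all 24 relabellings
  set.seed(88)
  D4 <- random_euclidean_D(4)
  g4 <- c("a", "a", "b", "b")
  expect_equal(anosim(D4, g4, seed = 1, exhaustive = TRUE)$p,
               oracle_anosim_exact_p(D4, g4), tolerance = 1e-12)
  expect_error(anosim(D4, c("a", "b", "b", "b"), n_perm = 9), ">= 2 members")
})

test_that("extreme-decile grouping selects the score tails", {
  g <- extreme_decile_groups(setNames(1:100, paste0("s", 1:100)))
  expect_equal(table(g$group)[["low"]], 10)
  expect_equal(table(g$group)[["high"]], 10)
  expect_true(all(paste0("s", 1:10) %in% g$sample_id[g$group == "low"]))
  g20 <- extreme_decile_groups(setNames(rnorm(20), paste0("s", 1:20)))
  expect_equal(sum(g20$group == "low"), 2L)
  expect_equal(sum(g20$group == "high"), 2L)
  ## heavy ties at the boundary widen a group, with a message
  tied <- setNames(c(rep(1, 5), 2:15, rep(16, 1)), paste0("s", 1:20))
  expect_message(gt <- extreme_decile_groups(tied), "tied")
  expect_gt(sum(gt$group == "low"), sum(gt$group == "high"))
  expect_error(extreme_decile_groups(1:5), "at least 10")
})

test_that("dbRDA constrained variance reduces to known projections", {
  set.seed(89)
  D <- random_euclidean_D(20)
  fit0 <- pcoa(D)
  ## constraining on the first PCoA axis recovers exactly its variance share
  dat <- data.frame(sample_id = rownames(D), ax1 = fit0$coordinates[, 1])
  fit <- dbrda(D, dat, "ax1", n_perm = 9, seed = 1)
  expect_equal(fit$constrained_prop,
               fit0$eigenvalues[1] / sum(fit0$eigenvalues), tolerance = 1e-9)
  expect_equal(fit$constrained_eig[1], fit0$eigenvalues[1], tolerance = 1e-9)
  ## biplot score of the constraining variable on its own axis is +/-1
  expect_equal(abs(fit$biplot_scores[1, 1]), 1, tolerance = 1e-9)
  ## a saturated design constrains everything
  dats <- data.frame(sample_id = rownames(D), fit0$coordinates)
  fits <- dbrda(D, dats, colnames(fit0$coordinates), n_perm = 9, seed = 1)
  expect_equal(fits$constrained_prop, 1, tolerance = 1e-9)
  ## constant constraint is refused
  datc <- data.frame(sample_id = rownames(D), k = rep(1, 20))
  expect_error(dbrda(D, datc, "k", n_perm = 9), "constant")
})

test_that("dbRDA agrees with vegan on constrained inertia for Euclidean input", {
  set.seed(90)
  Y <- matrix(rnorm(18 * 5), 18, 5)
  D <- as.matrix(dist(Y)); dimnames(D) <- list(paste0("s", 1:18), paste0("s", 1:18))
  x1 <- rnorm(18); x2 <- rnorm(18)
  dat <- data.frame(sample_id = rownames(D), x1 = x1, x2 = x2)
  fit <- dbrda(D, dat, c("x1", "x2"), n_perm = 9, seed = 1)
  ref <- vegan::dbrda(as.dist(D) ~ x1 + x2, data = dat)
  expect_equal(fit$constrained_prop,
               ref$CCA$tot.chi / ref$tot.chi, tolerance = 1e-9)
  ## vegan scales inertia by n - 1
  expect_equal(unname(fit$constrained_eig) / (18 - 1), unname(ref$CCA$eig),
               tolerance = 1e-8)
})

test_that("permutation streams are reproducible and operation-specific", {
  set.seed(91)
  D <- random_euclidean_D(12)
  dat <- data.frame(sample_id = rownames(D), x = rnorm(12))
  p1 <- permanova(D, dat, "x", n_perm = 199, seed = 7)$aov_tab$p[1]
  p2 <- permanova(D, dat, "x", n_perm = 199, seed = 7)$aov_tab$p[1]
  expect_identical(p1, p2)
  p3 <- permanova(D, dat, "x", n_perm = 199, seed = 8)$aov_tab$p[1]
  g <- rep(c("a", "b"), 6)
  a1 <- anosim(D, g, n_perm = 199, seed = 7)$p
  a2 <- anosim(D, g, n_perm = 199, seed = 7)$p
  expect_identical(a1, a2)
  ## the global RNG state is untouched by seeded operations
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(permanova(D, dat, "x", n_perm = 19, seed = 7))
  expect_identical(rnorm(1), before)
})
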