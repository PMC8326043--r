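test_that("core filter applies detection-then-prevalence with >= conventions", {
  set.seed(21)
  X <- random_relabund(200, 5)
  X[, 2] <- 0                       # all-zero taxon
  X[, 3] <- 1e-5                    # present but always below detection
  ## taxon 4: detected in exactly ceiling(0.01 * 200) = 2 samples
  X[, 4] <- 1e-6; X[1:2, 4] <- 0.002
  X <- X / rowSums(X)
  kept <- core_filter(X)
  expect_false("t2" %in% kept)
  expect_false("t3" %in% kept)
  expect_true("t4" %in% kept)       # boundary prevalence counts as in
  expect_true(all(c("t1", "t5") %in% kept))
  expect_error(core_filter(X, detection = 0), "strictly")
  expect_error(core_filter(X, detection = 1.2), "detection")
})

test_that("arcsine-sqrt transform hits the closed-form anchors", {
  expect_equal(arcsine_sqrt(c(0, 0.25, 0.5, 1)),
               c(0, pi / 6, pi / 4, pi / 2))
  expect_equal(arcsine_sqrt(1 + 1e-13), pi / 2)   # tolerance clip
  expect_error(arcsine_sqrt(1.001), "0, 1")
  expect_error(arcsine_sqrt(-0.1), "0, 1")
  m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(dimnames(arcsine_sqrt(m)), dimnames(m))
  expect_true(all(diff(arcsine_sqrt(seq(0, 1, 0.01))) > 0))   # monotone
})

test_that("linear association reproduces hand-computed OLS", {
  ## exact linear relation
  x <- c(1, 2, 3, 5, 8)
  f <- suppressWarnings(fit_linear_association(3 * x, x, standardize = FALSE))
  expect_equal(f$beta_per_sd, 3)
  expect_equal(f$p, 2.2e-308)       # perfect fit floors the p-value
  ## orthogonal outcome
  xo <- c(-1, 0, 1, 2, -2)
  yo <- c(1, -2, 1, 0, 0)           # centred x, sum(x*y) = 0
  expect_equal(sum(xo * yo), 0)
  expect_equal(fit_linear_association(yo, xo, standardize = FALSE)$beta_per_sd,
               0, tolerance = 1e-12)
  ## 4-point hand case: slope 0.9, intercept 0.9
  f4 <- fit_linear_association(c(1, 2, 2, 4), 0:3, standardize = FALSE)
  expect_equal(f4$beta_per_sd, 0.9)
  ## standardisation multiplies slope and SE by sd(x)
  set.seed(22)
  y <- rnorm(40); x <- rnorm(40, sd = 3)
  raw <- fit_linear_association(y, x, standardize = FALSE)
  std <- fit_linear_association(y, x)
  expect_equal(std$beta_per_sd, raw$beta_per_sd * sd(x))
  expect_equal(std$se, raw$se * sd(x))
  expect_equal(std$p, raw$p)
  ## closed-form simple-regression slope
  expect_equal(raw$beta_per_sd,
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2),
               tolerance = 1e-10)
  expect_error(fit_linear_association(y, rep(1, 40)), "zero variance")
  expect_error(fit_linear_association(y, x, data.frame(x2 = 2 * x)),
               "collinear")
})

test_that("the vectorised scan equals per-feature lm fits", {
  set.seed(23)
  n <- 60
  X <- random_relabund(n, 8)
  diet <- rnorm(n)
  C <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  scan <- per_taxon_scan(X, diet, C, detection = 1e-6, prevalence = 0.01)
  for (t in c("t1", "t5", "t8")) {
    single <- fit_linear_association(arcsine_sqrt(X[, t]), diet, C)
    row <- scan[scan$feature_id == t, ]
    expect_equal(row$beta_per_sd, single$beta_per_sd, tolerance = 1e-10)
    expect_equal(row$se, single$se, tolerance = 1e-10)
    expect_equal(row$p, single$p, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force tail-minimum oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(24)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    ## q is monotone in the p-ranking
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("per-taxon scans are invariant to sample order and find planted taxa", {
  set.seed(25)
  co <- simulate_cohort(cohort_spec(n_participants = 400), seed = 25)
  eff <- effect_spec(planted_taxa = data.frame(taxon_id = "g003", beta = 0.2))
  X <- simulate_abundances(co, eff, seed = 25)
  diet <- hfc_named(co)
  C <- cohort_covariates(co)
  scan <- per_taxon_scan(X, diet, C)
  expect_equal(nrow(scan), 91)
  top <- scan$feature_id[1]
  expect_equal(top, "g003")
  expect_true(scan$significant[1])
  expect_gt(scan$beta_per_sd[scan$feature_id == "g003"], 0.1)
  ## shuffling all inputs by the same sample permutation changes nothing
  perm <- sample(nrow(X))
  scan2 <- per_taxon_scan(X[perm, ], diet[perm], C[perm, ])
  expect_equal(scan2, scan)
})

test_that("KO scan splits significant hits by sign and validates its input", {
  set.seed(26)
  co <- simulate_cohort(cohort_spec(n_participants = 400), seed = 26)
  eff <- effect_spec(planted_kos = data.frame(
    ko_id = c("K00010", "K00040"), beta = c(0.15, -0.15)))
  K <- simulate_ko_table(co, eff, seed = 26)
  res <- ko_scan(K, hfc_named(co), cohort_covariates(co))
  expect_true("K00010" %in% res$positive$feature_id)
  expect_true("K00040" %in% res$negative$feature_id)
  ## the sign split partitions the significant set
  expect_equal(sort(c(res$positive$feature_id, res$negative$feature_id)),
               sort(res$all$feature_id[res$all$significant]))
  expect_length(intersect(res$positive$feature_id, res$negative$feature_id), 0)
  ## constant KO column is an error
  Kc <- K; Kc[, 5] <- 0.001
  expect_error(ko_scan(Kc, hfc_named(co), cohort_covariates(co)), "constant")
  Kn <- K; Kn[1, 1] <- -1
  expect_error(ko_scan(Kn, hfc_named(co)), "non-negative")
  ## node aggregation averages significant estimates per node
  map <- data.frame(ko = c("K00010", "K00040", "K00010"),
                    node = c("pathA", "pathB", "pathC"))
  res2 <- ko_scan(K, hfc_named(co), cohort_covariates(co), ko_map = map)
  expect_true(all(c("pathA", "pathB", "pathC") %in% res2$nodes$node))
  expect_equal(res2$nodes$mean_estimate[res2$nodes$node == "pathA"],
               res$all$beta_per_sd[res$all$feature_id == "K00010"])
})
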