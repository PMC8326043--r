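## Covariate-adjusted linear association scans: alpha diversity vs diet
## scores, per-taxon scans on arcsine-sqrt transformed core abundances with
## BH FDR control, and KO-group scans on log10 abundances with sign-split
## outputs.

#' Core-microbiota filter
#'
#' Keeps taxon `t` iff it reaches the detection threshold (relative
#' abundance, default 0.1%) in at least the prevalence fraction of samples
#' (default 1%). The comparison is `>=` on both sides, the convention of
#' standard core-microbiota tooling.
#'
#' @param X Relative-abundance samples-by-taxa matrix (rows sum to 1).
#' @param detection Relative-abundance detection threshold in (0, 1).
#' @param prevalence Fraction-of-samples threshold in (0, 1).
#' @return Character vector of retained taxon IDs.
#' @export
core_filter <- function(X, detection = 0.001, prevalence = 0.01) {
  check_abundance_matrix(X, relative = TRUE)
  assert_scalar_number(detection, "detection", 0, 1)
  assert_scalar_number(prevalence, "prevalence", 0, 1)
  if (detection <= 0 || detection >= 1 || prevalence <= 0 || prevalence >= 1)
    stop_dietbiome("detection and prevalence must lie strictly in (0, 1)")
  prev <- colMeans(X >= detection)
  colnames(X)[prev >= prevalence]
}

#' Arcsine-square-root transform
#'
#' Variance-stabilising transform `y = asin(sqrt(x))` for proportions,
#' applied to relative abundances before linear modelling; monotone, with
#' range \[0, pi/2\]. Values in `(1, 1 + 1e-12]` are clipped to 1; anything
#' further outside \[0, 1\] is an error.
#'
#' @param X Numeric vector or matrix of proportions.
#' @return Transformed object of the same shape.
#' @export
#' @examples
#' arcsine_sqrt(c(0, 0.25, 1))  # 0, pi/6, pi/2
arcsine_sqrt <- function(X) {
  if (any(X < -1e-12 | X > 1 + 1e-12, na.rm = TRUE))
    stop_dietbiome("proportions must lie in [0, 1]")
  X <- pmin(pmax(X, 0), 1)
  out <- asin(sqrt(X))
  if (is.matrix(X)) dim(out) <- dim(X)
  dimnames(out) <- dimnames(X)
  out
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of an outcome on a predictor plus covariates,
#' reporting the predictor effect per 1 SD of the predictor
#' (predictor-only standardisation, `beta_per_sd = beta * sd(x)`; the
#' outcome stays on its native scale), its standard error on the same
#' scale, and a two-sided t-test p-value.
#'
#' @param y Outcome vector.
#' @param x Predictor vector.
#' @param C Optional data.frame (or matrix) of covariate columns.
#' @param standardize Report the effect per 1 SD of `x` (default TRUE).
#' @param feature_id Optional label carried into the result.
#' @return One-row data.frame: `feature_id`, `beta_per_sd`, `se`, `p`, `n`.
#' @export
fit_linear_association <- function(y, x, C = NULL, standardize = TRUE,
                                   feature_id = NA_character_) {
  if (length(y) != length(x)) stop_dietbiome("y and x lengths differ")
  n <- length(y)
  if (stats::sd(x) == 0) stop_dietbiome("predictor has zero variance")
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(C)) {
    C <- as.data.frame(C)
    if (nrow(C) != n) stop_dietbiome("covariate rows do not match samples")
    dat <- cbind(dat, C)
  }
  if (n <= ncol(dat) + 1L) stop_dietbiome("too few samples for the model")
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_dietbiome("collinear design; aliased: ",
                   paste(aliased, collapse = ", "))
  }
  cf <- summary(fit)$coefficients[".x", ]
  scale <- if (standardize) stats::sd(x) else 1
  data.frame(feature_id = feature_id,
             beta_per_sd = unname(cf[1] * scale),
             se = unname(cf[2] * scale),
             p = max(unname(cf[4]), 2.2e-308),
             n = n,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_(i) = min_(j>=i) p_(j) * m / j`, mapped back
#' to input order), delegated to [stats::p.adjust()] after validating the
#' inputs lie in (0, 1].
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, `q >= p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_dietbiome("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Fast vectorised OLS across many outcome columns sharing one design.
## Returns beta, se, p for the predictor of interest (last design column).
## Cross-checked against fit_linear_association() in the test suite.
ols_scan <- function(Y, x, C = NULL) {
  n <- length(x)
  Xd <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(C)) {
    C <- as.data.frame(C)
    for (nm in names(C)) {
      v <- C[[nm]]
      if (is.character(v)) v <- factor(v)
      if (is.factor(v)) {
        Xd <- cbind(Xd, stats::model.matrix(~v)[, -1, drop = FALSE])
      } else Xd <- cbind(Xd, as.numeric(v))
    }
  }
  Xd <- cbind(Xd, x = as.numeric(x))
  k <- ncol(Xd)
  qrx <- qr(Xd)
  if (qrx$rank < k) stop_dietbiome("collinear scan design")
  coefs <- qr.coef(qrx, Y)
  res <- Y - Xd %*% coefs
  sigma2 <- colSums(res^2) / (n - k)
  xtx_inv_kk <- chol2inv(qr.R(qrx))[k, k]
  beta <- coefs[k, ]
  se <- sqrt(sigma2 * xtx_inv_kk)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - k, lower.tail = FALSE)
  ## extreme t statistics underflow to p = 0; floor at the smallest normal
  ## double so downstream BH adjustment keeps p in (0, 1]
  p <- pmax(p, 2.2e-308)
  list(beta = beta, se = se, p = p, df = n - k)
}

#' Per-taxon association scan
#'
#' MaAsLin-style scan: core-filters the relative abundances, arcsine-sqrt
#' transforms them, regresses each taxon on the diet variable plus
#' covariates, and BH-adjusts the p-values across the taxa of the scan.
#' Effects are reported per 1 SD of the diet variable.
#'
#' @param X Relative-abundance samples-by-taxa matrix (rows sum to 1),
#'   sample IDs as rownames.
#' @param diet Named (by sample ID) or aligned numeric diet variable.
#' @param C Covariate data.frame aligned to the samples (or with rownames /
#'   `sample_id` column for ID alignment).
#' @param detection,prevalence Core-filter thresholds, see [core_filter()].
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @return data.frame with one row per core taxon: `feature_id`,
#'   `beta_per_sd`, `se`, `p`, `q`, `n`, `significant`, sorted by q.
#' @export
per_taxon_scan <- function(X, diet, C = NULL, detection = 0.001,
                           prevalence = 0.01, fdr = 0.05) {
  check_abundance_matrix(X, relative = TRUE)
  al <- align_scan_inputs(X, diet, C)
  keep <- core_filter(al$X, detection, prevalence)
  if (!length(keep)) stop_dietbiome("core filter removed every taxon")
  Y <- arcsine_sqrt(al$X[, keep, drop = FALSE])
  fit <- ols_scan(Y, al$diet, al$C)
  sdx <- stats::sd(al$diet)
  out <- data.frame(feature_id = keep,
                    beta_per_sd = unname(fit$beta * sdx),
                    se = unname(fit$se * sdx),
                    p = unname(fit$p),
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$n <- nrow(Y)
  out$significant <- out$q < fdr
  out[order(out$q, out$p), ]
}

## Align abundance rows, the diet vector and covariates by sample ID where
## names are available; otherwise positional with length checks.
align_scan_inputs <- function(X, diet, C) {
  ids <- rownames(X)
  if (!is.null(names(diet))) {
    missing <- setdiff(ids, names(diet))
    if (length(missing))
      stop_dietbiome("diet variable lacks samples: ",
                     paste(utils::head(missing, 5), collapse = ", "))
    diet <- diet[ids]
  } else if (length(diet) != nrow(X)) {
    stop_dietbiome("diet variable length does not match samples")
  }
  if (!is.null(C)) {
    C <- as.data.frame(C)
    key <- if ("sample_id" %in% names(C)) as.character(C$sample_id)
           else rownames(C)
    if (!is.null(key) && !identical(key, as.character(seq_len(nrow(C))))) {
      missing <- setdiff(ids, key)
      if (length(missing))
        stop_dietbiome("covariates lack samples: ",
                       paste(utils::head(missing, 5), collapse = ", "))
      C <- C[match(ids, key), setdiff(names(C), "sample_id"), drop = FALSE]
    } else if (nrow(C) != nrow(X)) {
      stop_dietbiome("covariate rows do not match samples")
    }
  }
  list(X = X, diet = as.numeric(diet), C = C)
}

#' KO-group functional association scan
#'
#' Regresses `log10(abundance + pseudocount)` of each KEGG-orthology (KO)
#' group on the HFC score plus covariates, keeps the associations with
#' `p < p_threshold` (raw p by default, mirroring common practice for
#' functional profiles; set `fdr = TRUE` to threshold on BH q-values
#' instead), and splits them by effect sign. The default pseudocount is
#' half the smallest non-zero value of each KO across samples.
#'
#' @param K Non-negative KO relative-abundance samples-by-KO matrix.
#' @param score Diet score vector (named by sample ID or aligned).
#' @param C Covariate data.frame.
#' @param pseudocount Single value, or `NULL` for the per-feature default.
#' @param p_threshold Significance threshold (default 0.05).
#' @param fdr Threshold on q-values instead of raw p-values.
#' @param ko_map Optional data.frame with columns `ko` and `node` mapping KO
#'   IDs to functional-hierarchy nodes; when given, a `nodes` table with the
#'   mean significant estimate per node is added.
#' @return List with `all`, `positive`, `negative` association tables and
#'   optionally `nodes`.
#' @export
ko_scan <- function(K, score, C = NULL, pseudocount = NULL,
                    p_threshold = 0.05, fdr = FALSE, ko_map = NULL) {
  if (any(K < 0)) stop_dietbiome("KO abundances must be non-negative")
  if (is.null(rownames(K))) stop_dietbiome("KO matrix needs sample rownames")
  al <- align_scan_inputs(K, score, C)
  K <- al$X
  const <- apply(K, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    stop_dietbiome("KO group(s) constant across samples: ",
                   paste(utils::head(colnames(K)[const], 5), collapse = ", "))
  if (is.null(pseudocount)) {
    pc <- apply(K, 2, function(v) {
      nz <- v[v > 0]
      if (!length(nz)) 1e-12 else min(nz) / 2
    })
  } else {
    assert_scalar_number(pseudocount, "pseudocount", lower = 0)
    pc <- rep(pseudocount, ncol(K))
  }
  Y <- log10(sweep(K, 2, pc, `+`))
  fit <- ols_scan(Y, al$diet, al$C)
  sdx <- stats::sd(al$diet)
  tab <- data.frame(feature_id = colnames(K),
                    beta_per_sd = unname(fit$beta * sdx),
                    se = unname(fit$se * sdx),
                    p = unname(fit$p),
                    stringsAsFactors = FALSE)
  tab$q <- bh_adjust(tab$p)
  tab$n <- nrow(K)
  crit <- if (fdr) tab$q else tab$p
  tab$significant <- crit < p_threshold
  sig <- tab[tab$significant, ]
  out <- list(all = tab[order(tab$p), ],
              positive = sig[sig$beta_per_sd > 0, ],
              negative = sig[sig$beta_per_sd < 0, ])
  if (!is.null(ko_map)) {
    if (!all(c("ko", "node") %in% names(ko_map)))
      stop_dietbiome("ko_map needs 'ko' and 'node' columns")
    m <- merge(sig, ko_map, by.x = "feature_id", by.y = "ko")
    if (nrow(m)) {
      agg <- stats::aggregate(beta_per_sd ~ node, data = m, FUN = mean)
      names(agg) <- c("node", "mean_estimate")
      agg$n_ko <- stats::aggregate(beta_per_sd ~ node, data = m,
                                   FUN = length)$beta_per_sd
      out$nodes <- agg
    } else {
      out$nodes <- data.frame(node = character(), mean_estimate = numeric(),
                              n_ko = integer())
    }
  }
  out
}
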