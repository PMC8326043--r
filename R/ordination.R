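## Distance-matrix inference: Gower centering, PCoA, PERMANOVA, ANOSIM and
## distance-based RDA, all with seeded permutation nulls. Permutation
## substreams are derived from one master seed and the operation name, so
## adding one analysis to a run never shifts another's stream.

#' Gower-center a distance matrix
#'
#' Returns `G = -1/2 * J A J` with `A_ij = D_ij^2` and `J = I - 11'/n`, the
#' doubly centered inner-product matrix underlying principal coordinate
#' analysis and distance-based sum-of-squares partitioning. Row and column
#' sums of `G` are zero and `trace(G)` equals the total sum of squares
#' `sum(D^2)/n`.
#'
#' @param D Symmetric distance matrix (or `dist`) with zero diagonal.
#' @return Symmetric centered matrix `G`.
#' @export
gower_center <- function(D) {
  D <- check_distance_matrix(D)
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A)
  G <- A - matrix(rm_, n, n) - matrix(rm_, n, n, byrow = TRUE) + mean(A)
  (G + t(G)) / 2
}

## ---- design-matrix handling -------------------------------------------

## Expand the named terms of a data.frame into numeric indicator columns.
## Returns the column matrix (no intercept), the term index of each column,
## and term degrees of freedom. Errors on rank deficiency, naming the terms
## involved.
build_design <- function(data, terms) {
  if (!is.data.frame(data)) stop_dietbiome("design data must be a data.frame")
  missing <- setdiff(terms, names(data))
  if (length(missing))
    stop_dietbiome("design terms not found in data: ",
                   paste(missing, collapse = ", "))
  cols <- list()
  assign <- integer(0)
  for (j in seq_along(terms)) {
    v <- data[[terms[j]]]
    if (anyNA(v)) stop_dietbiome("design term '", terms[j], "' contains NA")
    if (is.character(v)) v <- factor(v)
    if (is.logical(v)) v <- as.numeric(v)
    if (is.factor(v)) {
      if (nlevels(droplevels(v)) < 2L)
        stop_dietbiome("design term '", terms[j], "' is constant")
      m <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(m) <- paste0(terms[j], levels(droplevels(v))[-1])
    } else {
      if (stats::sd(v) == 0)
        stop_dietbiome("design term '", terms[j], "' is constant")
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, terms[j]))
    }
    cols[[j]] <- m
    assign <- c(assign, rep(j, ncol(m)))
  }
  M <- do.call(cbind, cols)
  qrx <- qr(cbind(1, M))
  if (qrx$rank < ncol(M) + 1L) {
    kept <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- setdiff(seq_len(ncol(M) + 1L), kept) - 1L
    stop_dietbiome("design is rank deficient; collinear term(s): ",
                   paste(unique(terms[assign[dropped]]), collapse = ", "))
  }
  list(M = M, assign = assign, terms = terms,
       df = as.integer(table(factor(assign, levels = seq_along(terms)))))
}

## Reorder the rows of `data` to the sample order of D. Alignment is by ID
## (a `sample_id` column or rownames), never by row order.
align_design <- function(D, data) {
  ids <- rownames(D)
  if (is.null(ids)) stop_dietbiome("distance matrix needs sample IDs as dimnames")
  key <- if ("sample_id" %in% names(data)) as.character(data$sample_id)
         else rownames(data)
  if (is.null(key) || anyDuplicated(key))
    stop_dietbiome("design data needs unique sample IDs (a 'sample_id' ",
                   "column or rownames)")
  missing <- setdiff(ids, key)
  if (length(missing))
    stop_dietbiome("design data lacks samples: ",
                   paste(utils::head(missing, 5), collapse = ", "))
  data[match(ids, key), , drop = FALSE]
}

## All permutations of 1..n as rows (exhaustive null; guarded to n <= 8).
all_permutations <- function(n) {
  if (n > 8L) stop_dietbiome("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

permutation_set <- function(n, n_perm, seed, op, exhaustive) {
  if (exhaustive) return(all_permutations(n))
  if (n_perm < 1L) stop_dietbiome("n_perm must be >= 1")
  with_seed(substream_seed(seed, op), {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  })
}

## ---- PERMANOVA ---------------------------------------------------------

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix by the terms of
#' a design, using hat-matrix projections on the Gower-centered matrix.
#' Terms are entered sequentially in the order given (covariates first, the
#' diet variable last, by default semantics of the caller); marginal sums of
#' squares are available with `by = "margin"`. The p-value per term is the
#' add-one estimator `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under free
#' permutation of sample labels, so with 999 permutations the smallest
#' attainable p is 1e-3. With `exhaustive = TRUE` all `n!` label
#' permutations are enumerated instead (small n only) and the p-value is the
#' exact proportion.
#'
#' @param D Distance matrix (or `dist`) with sample IDs as dimnames.
#' @param data data.frame of predictors, aligned to `D` by a `sample_id`
#'   column or rownames.
#' @param terms Character vector naming the model terms, in entry order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Master seed for the permutation stream.
#' @param by `"terms"` for sequential sums of squares, `"margin"` for
#'   marginal.
#' @param exhaustive Enumerate all label permutations (n <= 8).
#' @return An object of class `permanova` with an `aov_tab` data.frame
#'   (term, df, SS, R2, F, p) including residual and total rows.
#' @export
permanova <- function(D, data, terms, n_perm = 999L, seed = 1L,
                      by = c("terms", "margin"), exhaustive = FALSE) {
  by <- match.arg(by)
  D <- check_distance_matrix(D)
  data <- align_design(D, data)
  des <- build_design(data, terms)
  n <- nrow(D)
  k <- ncol(des$M)
  if (n <= k + 1L)
    stop_dietbiome("too few samples (", n, ") for ", k, " design columns")
  G <- gower_center(D)
  qrx <- qr(cbind(`(Intercept)` = 1, des$M))
  Q <- qr.Q(qrx)                       # n x (k+1); prefix columns span
  col_term <- c(0L, des$assign)        # nested sequential subspaces
  ss_total <- sum(diag(G))
  df_res <- n - 1L - k

  term_ss <- function(Qm) {
    ## per-column SS q_c' G q_c, grouped by term (intercept column drops out
    ## because G is doubly centered)
    contrib <- colSums(Qm * (G %*% Qm))
    vapply(seq_along(terms), function(j) sum(contrib[col_term == j]),
           numeric(1))
  }
  margin_ss <- function(perm) {
    Qp <- Q[perm, , drop = FALSE]
    full <- sum(colSums(Qp * (G %*% Qp)))
    vapply(seq_along(terms), function(j) {
      keep <- col_term != j
      Mj <- cbind(1, des$M[, des$assign != j, drop = FALSE])
      Qj <- qr.Q(qr(Mj))[perm, , drop = FALSE]
      full - sum(colSums(Qj * (G %*% Qj)))
    }, numeric(1))
  }
  ss_fun <- if (by == "terms") function(p) term_ss(Q[p, , drop = FALSE])
            else margin_ss

  idp <- seq_len(n)
  ss_obs <- ss_fun(idp)
  ss_model <- sum(term_ss(Q))          # sequential model SS (= tr(HG))
  ss_res <- ss_total - ss_model
  f_obs <- (ss_obs / des$df) / (ss_res / df_res)

  perms <- permutation_set(n, n_perm, seed, "permanova", exhaustive)
  f_perm <- matrix(0, nrow(perms), length(terms))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    ssp <- ss_fun(p)
    Qp <- Q[p, , drop = FALSE]
    res_p <- ss_total - sum(colSums(Qp * (G %*% Qp)))
    f_perm[i, ] <- (ssp / des$df) / (res_p / df_res)
  }
  hits <- colSums(sweep(f_perm, 2, f_obs - 1e-8, `>=`))
  pval <- if (exhaustive) hits / nrow(perms) else (1 + hits) / (1 + nrow(perms))

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(des$df, df_res, n - 1L),
    SS = c(ss_obs, ss_res, ss_total),
    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(aov_tab = tab, n = n, n_perm = nrow(perms), seed = seed,
                 by = by, exhaustive = exhaustive),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s SS, %d permutations%s, seed %s)\n",
              x$by, x$n_perm, if (x$exhaustive) ", exhaustive" else "",
              format(x$seed)))
  print(transform(x$aov_tab, SS = signif(SS, 5), R2 = signif(R2, 4),
                  F = signif(F, 4)), row.names = FALSE)
  invisible(x)
}

## ---- ANOSIM ------------------------------------------------------------

anosim_stat <- function(rank_d, within) {
  ## R = (mean between-group rank - mean within-group rank) / (n(n-1)/4);
  ## ranks are over all n(n-1)/2 off-diagonal distances, M = n(n-1)/2, and
  ## the divisor M/2 bounds R in [-1, 1] (Clarke's definition)
  m <- length(rank_d)
  (mean(rank_d[!within]) - mean(rank_d[within])) / (m / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between-group versus within-group distances.
#' `R` lies in \[-1, 1\]; values near 0 mean no separation and 1 means every
#' between-group distance exceeds every within-group one. The p-value uses
#' the same seeded add-one permutation scheme as [permanova()].
#'
#' @param D Distance matrix with sample IDs as dimnames.
#' @param groups Group labels, one per sample (named vector or aligned to
#'   `D`'s row order; at least two groups with two members each).
#' @inheritParams permanova
#' @return An object of class `anosim_result` with `statistic`, `p`,
#'   `n_perm`, `seed`.
#' @export
anosim <- function(D, groups, n_perm = 999L, seed = 1L, exhaustive = FALSE) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(D), names(groups))
    if (length(missing))
      stop_dietbiome("group labels lack samples: ",
                     paste(utils::head(missing, 5), collapse = ", "))
    groups <- groups[rownames(D)]
  } else if (length(groups) != n) {
    stop_dietbiome("groups must have one label per sample")
  }
  groups <- factor(groups)
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop_dietbiome("ANOSIM needs at least two groups")
  if (any(sizes < 2L))
    stop_dietbiome("every group needs >= 2 members; too small: ",
                   paste(names(sizes)[sizes < 2], collapse = ", "))
  lower <- lower.tri(D)
  rank_d <- rank(D[lower])             # average ranks on ties
  gi <- as.integer(groups)
  same <- outer(gi, gi, `==`)[lower]
  r_obs <- anosim_stat(rank_d, same)
  perms <- permutation_set(n, n_perm, seed, "anosim", exhaustive)
  r_perm <- vapply(seq_len(nrow(perms)), function(i) {
    gp <- gi[perms[i, ]]
    anosim_stat(rank_d, outer(gp, gp, `==`)[lower])
  }, numeric(1))
  hits <- sum(r_perm >= r_obs - 1e-12)
  p <- if (exhaustive) hits / length(r_perm) else (1 + hits) / (1 + length(r_perm))
  structure(list(statistic = r_obs, p = p, n_perm = length(r_perm),
                 seed = seed, exhaustive = exhaustive, groups = sizes),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%d permutations%s, seed %s)\n",
              x$statistic, x$p, x$n_perm,
              if (x$exhaustive) ", exhaustive" else "", format(x$seed)))
  invisible(x)
}

## ---- PCoA --------------------------------------------------------------

#' Principal coordinate analysis
#'
#' Eigendecomposition of the Gower-centered distance matrix; coordinates are
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Negative eigenvalues (possible for semimetrics such as Bray-Curtis) are
#' reported; the Lingoes correction adds a constant to the squared
#' off-diagonal distances and the Cailliez correction a constant to the
#' distances themselves, each the smallest making the configuration
#' Euclidean.
#'
#' @param D Distance matrix with sample IDs as dimnames.
#' @param correction `"none"` (default), `"lingoes"` or `"cailliez"`.
#' @return Object of class `dietbiome_pcoa`: `eigenvalues` (descending),
#'   `coordinates` (samples x positive axes), `negative_eigenvalues`,
#'   `correction`, `correction_constant`.
#' @export
pcoa <- function(D, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  D <- check_distance_matrix(D)
  n <- nrow(D)
  cconst <- 0
  if (correction != "none") {
    ev <- eigen(gower_center(D), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      if (correction == "lingoes") {
        cconst <- -min(ev)
        D2 <- D^2 + 2 * cconst
        diag(D2) <- 0
        D <- sqrt(D2)
      } else {
        ## Cailliez: largest eigenvalue of the 2n x 2n companion problem
        A1 <- -0.5 * D^2
        A2 <- -0.5 * D
        B <- rbind(cbind(matrix(0, n, n), 2 * A1),
                   cbind(-diag(n), -4 * A2))
        cconst <- max(Re(eigen(B, only.values = TRUE)$values))
        D <- D + cconst
        diag(D) <- 0
      }
    }
  }
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  pos <- which(vals > max(vals) * 1e-10 & vals > 0)
  coords <- sweep(vecs[, pos, drop = FALSE], 2, sqrt(vals[pos]), `*`)
  dimnames(coords) <- list(rownames(D), paste0("PCo", seq_along(pos)))
  structure(list(eigenvalues = vals, coordinates = coords,
                 negative_eigenvalues = vals[vals < 0],
                 correction = correction, correction_constant = cconst),
            class = "dietbiome_pcoa")
}

#' @export
print.dietbiome_pcoa <- function(x, ...) {
  npos <- ncol(x$coordinates)
  cat(sprintf("PCoA: %d positive axes, %d negative eigenvalue(s), correction '%s'\n",
              npos, length(x$negative_eigenvalues), x$correction))
  rel <- x$eigenvalues[seq_len(min(5, npos))] / sum(x$eigenvalues[x$eigenvalues > 0])
  cat("first axes (share of positive-eigenvalue variance):",
      paste(sprintf("%.3f", rel), collapse = " "), "\n")
  invisible(x)
}

## ---- extreme deciles ---------------------------------------------------

#' Bottom- and top-decile group labels for a score
#'
#' Returns group membership for the first and tenth deciles of a per-sample
#' score (samples in deciles 2-9 are excluded), as used for contrasting the
#' microbiotas of the most and least health-consciously eating participants.
#' Decile bounds come from [stats::quantile()]; heavy ties at a boundary can
#' make the groups unequal, which is reported via a message.
#'
#' @param scores Named numeric vector (names are sample IDs) or plain vector.
#' @return data.frame with `sample_id` and `group` (`"low"`/`"high"`).
#' @export
extreme_decile_groups <- function(scores) {
  if (length(scores) < 10L) stop_dietbiome("need at least 10 samples")
  ids <- names(scores) %||% as.character(seq_along(scores))
  q <- stats::quantile(scores, c(0.1, 0.9), names = FALSE)
  low <- scores <= q[1]
  high <- scores >= q[2]
  if (sum(low) < 2L || sum(high) < 2L)
    stop_dietbiome("fewer than 2 samples in an extreme decile")
  n10 <- floor(length(scores) / 10)
  if (sum(low) != sum(high) || sum(low) != n10)
    message(sprintf("extreme_decile_groups: tied scores give groups of %d and %d",
                    sum(low), sum(high)))
  data.frame(sample_id = c(ids[low], ids[high]),
             group = rep(c("low", "high"), c(sum(low), sum(high))),
             stringsAsFactors = FALSE)
}

## ---- dbRDA -------------------------------------------------------------

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a distance matrix: the Gower-centered matrix is
#' projected onto the span of the predictors, and the fitted part is
#' eigendecomposed into constrained axes. The constrained proportion is
#' `trace(H G H) / trace(G)`; biplot scores are correlations of the
#' predictor columns with the constrained sample scores; the overall-model
#' p-value uses a seeded pseudo-F permutation test as in [permanova()].
#' Negative-eigenvalue axes are dropped from coordinates but retained in the
#' sums-of-squares totals.
#'
#' @inheritParams permanova
#' @return Object of class `dbrda_result`: `constrained_eig`,
#'   `unconstrained_eig`, `constrained_prop`, `coordinates` (samples x
#'   constrained axes), `biplot_scores`, `F`, `p`, `n_perm`, `seed`.
#' @export
dbrda <- function(D, data, terms, n_perm = 999L, seed = 1L,
                  exhaustive = FALSE) {
  D <- check_distance_matrix(D)
  data <- align_design(D, data)
  des <- build_design(data, terms)
  n <- nrow(D)
  q <- ncol(des$M)
  if (n <= q + 1L)
    stop_dietbiome("too few samples (", n, ") for ", q, " design columns")
  G <- gower_center(D)
  Q <- qr.Q(qr(cbind(1, des$M)))[, -1, drop = FALSE]   # constraint basis
  W <- G %*% Q
  ss_total <- sum(diag(G))
  ss_con <- sum(colSums(Q * W))                         # tr(HGH) = tr(HG)
  ss_res <- ss_total - ss_con
  df_res <- n - 1L - q
  f_obs <- (ss_con / q) / (ss_res / df_res)

  ## constrained axes: eigen of Q'GQ lifted back to sample space
  small <- crossprod(Q, W)
  es <- eigen((small + t(small)) / 2, symmetric = TRUE)
  keep <- es$values > max(abs(es$values)) * 1e-10 & es$values > 0
  axes <- Q %*% es$vectors[, keep, drop = FALSE]
  coords <- sweep(axes, 2, sqrt(es$values[keep]), `*`)
  dimnames(coords) <- list(rownames(D),
                           paste0("dbRDA", seq_len(sum(keep))))
  ## residual structure
  R <- G - W %*% t(Q) - Q %*% t(W) + Q %*% (small %*% t(Q))
  un_eig <- sort(eigen((R + t(R)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  biplot <- stats::cor(des$M, coords)

  perms <- permutation_set(n, n_perm, seed, "dbrda", exhaustive)
  f_perm <- vapply(seq_len(nrow(perms)), function(i) {
    Qp <- Q[perms[i, ], , drop = FALSE]
    ssc <- sum(colSums(Qp * (G %*% Qp)))
    (ssc / q) / ((ss_total - ssc) / df_res)
  }, numeric(1))
  hits <- sum(f_perm >= f_obs - 1e-8)
  p <- if (exhaustive) hits / length(f_perm) else (1 + hits) / (1 + length(f_perm))

  structure(list(constrained_eig = es$values[keep],
                 all_constrained_eig = es$values,
                 unconstrained_eig = un_eig,
                 constrained_prop = ss_con / ss_total,
                 coordinates = coords, biplot_scores = biplot,
                 F = f_obs, p = p, n_perm = length(f_perm), seed = seed),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: %.3f%% of total variance constrained; F = %.3f, p = %.4g (%d permutations)\n",
              100 * x$constrained_prop, x$F, x$p, x$n_perm))
  if (length(x$constrained_eig)) {
    sh <- x$constrained_eig / sum(x$constrained_eig)
    cat("constrained-axis shares:",
        paste(sprintf("%.3f", utils::head(sh, 5)), collapse = " "), "\n")
  }
  invisible(x)
}
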