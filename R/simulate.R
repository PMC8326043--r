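## Synthetic cohort, abundance and KO-table generators with known planted
## effects. Everything is a pure function of (spec, seed), so every pipeline
## stage is testable without access-restricted data.

## Calibrated default parameters of the ordinal FPQ model (see the methods
## vignette): per-item offsets on the logistic latent scale chosen so the
## simulated component means track the study-sample means and the HFC score
## distribution its mean/SD target; the factor loading sets the inter-item
## correlation that produces the HFC SD.
FPQ_CUTPOINTS <- c(-3, -1.5, 0, 1.5, 3)
FPQ_ITEM_OFFSETS <- c(
  bread_rye = 2.744, bread_graham = 2.744, veg_fresh = 0.990,
  veg_cooked = 0.625, veg_dishes = 0.625, fruits = 2.044, berries = 0.134,
  juices = 1.259, fish = -1.074, poultry = -1.298, cheese_lowfat = 1.127,
  dressings_oils = -0.594, nuts = -3.718, seeds = -3.718,
  meat_dishes = 0.002, sausages = 0.002, cold_cuts = -0.182,
  charcuterie = -0.182)
FPQ_LOADING <- 0.880
FPQ_FEMALE_SHIFT <- 0.717
FPQ_MEAT_LOADING <- -0.60   # loading multiplier for meat-consumption items

## Taxon panel shape: core shares follow a power law in rank (exponent set
## so the mean Shannon index of the default panel is ~3.43 nats with SD
## ~0.39 at 91 core genera); the two low-dispersion "stable" genera make
## clean effect planting possible.
PANEL_EXPONENT <- 0.95
PANEL_SIGMA_CORE <- 1.0
PANEL_SIGMA_STABLE <- 0.4
PANEL_SIGMA_RARE <- 1.0
STABLE_TAXA <- c("g003", "g005")
## The Shannon response to log-share compression is measured numerically on
## the generated data itself (a two-point probe), so the evenness channel
## delivers the configured Shannon-units effect under any panel.

#' Synthetic cohort specification
#'
#' Bundles the sample size, covariate targets (study-sample means/SDs for
#' age and BMI, proportions for sex, smoking and medication use), the
#' HFC-score calibration targets, and the ordinal FPQ model parameters
#' (latent-factor loading, female factor shift, cut-points, per-item
#' offsets).
#'
#' @param n_participants Cohort size (default 500; the source study scale is
#'   4930).
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate targets.
#' @param hfc_mean,hfc_sd HFC-score calibration targets (times/month).
#' @param p_female Proportion of women.
#' @param smoking_by_sex,medication_by_sex Named proportions for
#'   `c(male=, female=)`.
#' @param loading Latent health-consciousness factor loading; 0 makes the
#'   FPQ items mutually independent.
#' @param female_shift Latent-factor shift for women (drives the Table-style
#'   sex differences in diet).
#' @param meat_loading Multiplier on `loading` for meat-consumption items
#'   (negative: health-conscious participants eat less meat).
#' @param cutpoints Five increasing cut-points on the logistic latent scale.
#' @param item_offsets Named per-item offsets; defaults are calibrated to
#'   the study-sample item means.
#' @param items Food item configuration.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 500L,
                        age_mean = 48, age_sd = 12.8,
                        bmi_mean = 26.9, bmi_sd = 4.6,
                        hfc_mean = 250.0, hfc_sd = 103.2,
                        p_female = 0.531,
                        smoking_by_sex = c(male = 0.285, female = 0.195),
                        medication_by_sex = c(male = 0.294, female = 0.439),
                        loading = FPQ_LOADING,
                        female_shift = FPQ_FEMALE_SHIFT,
                        meat_loading = FPQ_MEAT_LOADING,
                        cutpoints = FPQ_CUTPOINTS,
                        item_offsets = FPQ_ITEM_OFFSETS,
                        items = default_food_items()) {
  if (age_sd <= 0 || bmi_sd <= 0 || hfc_sd <= 0)
    stop_dietbiome("SD targets must be positive")
  for (p in c(p_female, smoking_by_sex, medication_by_sex))
    assert_scalar_number(p, "proportion", 0, 1)
  if (is.unsorted(cutpoints, strictly = TRUE) || length(cutpoints) != 5L)
    stop_dietbiome("cutpoints must be 5 strictly increasing values")
  items <- validate_food_items(items)
  missing <- setdiff(items$item_id, names(item_offsets))
  if (length(missing))
    stop_dietbiome("item_offsets lacks items: ", paste(missing, collapse = ", "))
  structure(list(n_participants = as.integer(n_participants),
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 hfc_mean = hfc_mean, hfc_sd = hfc_sd,
                 p_female = p_female,
                 smoking_by_sex = smoking_by_sex,
                 medication_by_sex = medication_by_sex,
                 loading = loading, female_shift = female_shift,
                 meat_loading = meat_loading,
                 cutpoints = cutpoints, item_offsets = item_offsets,
                 items = items),
            class = "cohort_spec")
}

#' Planted-effect specification for the generators
#'
#' Defines the ground truth the synthetic data carry: per-taxon diet effects
#' on the arcsine-sqrt scale (per 1 SD of the HFC score), the
#' alpha-diversity effect (Shannon units per SD), covariate effects on
#' alpha diversity, and planted KO effects on the log10 scale. Defaults
#' follow the magnitudes reported for a Finnish population cohort (alpha
#' 0.044 per SD; taxon effects of order 0.1).
#'
#' @param alpha_beta Shannon-units-per-SD effect of the HFC score.
#' @param covariate_alpha_betas Named Shannon-unit effects for
#'   age/sex/bmi/smoking/medication (per 1 SD of each).
#' @param planted_taxa data.frame with `taxon_id`, `beta` (arcsine-sqrt
#'   units per SD of HFC).
#' @param planted_kos data.frame with `ko_id`, `beta` (log10 units per SD).
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(alpha_beta = 0.044,
                        covariate_alpha_betas = c(age = 0.054, sex = -0.039,
                                                  bmi = -0.082,
                                                  smoking = -0.049,
                                                  medication = -0.039),
                        planted_taxa = data.frame(
                          taxon_id = c("g003", "g005"),
                          beta = c(0.10, -0.07),
                          stringsAsFactors = FALSE),
                        planted_kos = data.frame(
                          ko_id = c("K00010", "K00025", "K00040"),
                          beta = c(0.06, 0.05, -0.06),
                          stringsAsFactors = FALSE)) {
  stopifnot(is.data.frame(planted_taxa), is.data.frame(planted_kos))
  if (nrow(planted_taxa) && !all(is.finite(planted_taxa$beta)))
    stop_dietbiome("planted taxon effects must be finite")
  if (nrow(planted_kos) && !all(is.finite(planted_kos$beta)))
    stop_dietbiome("planted KO effects must be finite")
  structure(list(alpha_beta = alpha_beta,
                 covariate_alpha_betas = covariate_alpha_betas,
                 planted_taxa = planted_taxa, planted_kos = planted_kos),
            class = "effect_spec")
}

#' Null (no-effect) specification
#'
#' Convenience constructor for global-null simulations: no diet, covariate,
#' taxon or KO effects.
#' @return An `effect_spec` with every effect zero/empty.
#' @export
null_effect_spec <- function() {
  effect_spec(alpha_beta = 0,
              covariate_alpha_betas = c(age = 0, sex = 0, bmi = 0,
                                        smoking = 0, medication = 0),
              planted_taxa = data.frame(taxon_id = character(),
                                        beta = numeric()),
              planted_kos = data.frame(ko_id = character(),
                                       beta = numeric()))
}

#' Simulate a cohort: covariates and FPQ responses
#'
#' Draws a latent health-consciousness factor per participant (with a
#' female shift), then ordinal FPQ categories from a cut-point model on a
#' logistic latent scale in which healthy items load positively and
#' meat-consumption items negatively on the factor. With the calibrated
#' defaults the simulated HFC score distribution tracks the configured
#' mean/SD and the sex differences point in the study directions (women
#' higher on vegetables, fruits, berries and low-fat cheeses; men higher on
#' meat consumption).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical (spec, seed) gives identical output.
#' @return List of class `dietbiome_cohort`: `covariates` (sample_id, age,
#'   sex with males coded 1, bmi, smoking, medication), `responses` (FPQ
#'   categories), `scores` (from [score_fpq()]), `latent` factor values and
#'   the `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(substream_seed(seed, "simulate_cohort"), {
    ids <- sprintf("S%05d", seq_len(n))
    female <- stats::rbinom(n, 1, spec$p_female)
    age <- round(stats::rnorm(n, spec$age_mean, spec$age_sd))
    age <- pmin(pmax(age, 24), 74)
    bmi <- round(pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), 15), 1)
    smoking <- stats::rbinom(n, 1, ifelse(female == 1,
                                          spec$smoking_by_sex[["female"]],
                                          spec$smoking_by_sex[["male"]]))
    medication <- stats::rbinom(n, 1, ifelse(female == 1,
                                             spec$medication_by_sex[["female"]],
                                             spec$medication_by_sex[["male"]]))
    h <- stats::rnorm(n) + spec$female_shift * (female - spec$p_female)
    items <- spec$items
    resp <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(items))) {
      id <- items$item_id[i]
      w <- if (items$inverse_scored[i]) spec$meat_loading else 1
      u <- spec$item_offsets[[id]] + spec$loading * w * h +
        stats::rlogis(n)
      resp[[id]] <- findInterval(u, spec$cutpoints) + 1L
    }
    covariates <- data.frame(sample_id = ids, age = age,
                             sex = 1L - female, bmi = bmi,
                             smoking = smoking, medication = medication,
                             stringsAsFactors = FALSE)
    scores <- suppressMessages(score_fpq(resp, items))
    structure(list(covariates = covariates, responses = resp,
                   scores = scores, latent = h, spec = spec, seed = seed),
              class = "dietbiome_cohort")
  })
}

## Default taxon panel: `n_core` genera whose mean shares follow a rank
## power law (these survive the core filter) plus `n_rare` genera with tiny
## shares that the filter should remove.
taxon_panel <- function(n_taxa = 191L, n_core = 91L) {
  if (n_taxa < n_core) stop_dietbiome("n_taxa must be >= ", n_core)
  n_rare <- n_taxa - n_core
  ids <- sprintf("g%03d", seq_len(n_taxa))
  core_share <- seq_len(n_core)^(-PANEL_EXPONENT)
  rare_share <- if (n_rare > 0)
    10^(seq(-4.5, -5.5, length.out = n_rare)) else numeric(0)
  share <- c(core_share / sum(core_share) * (1 - sum(rare_share)), rare_share)
  sigma <- c(rep(PANEL_SIGMA_CORE, n_core), rep(PANEL_SIGMA_RARE, n_rare))
  sigma[ids %in% STABLE_TAXA] <- PANEL_SIGMA_STABLE
  data.frame(taxon_id = ids, mean_log = log(share), sigma = sigma,
             core = rep(c(TRUE, FALSE), c(n_core, n_rare)),
             stringsAsFactors = FALSE)
}

standardize <- function(v) {
  s <- stats::sd(v)
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

## Per-sample evenness signal in Shannon units: diet effect plus covariate
## effects, each per 1 SD of the (standardised) variable.
evenness_signal <- function(cohort, effects) {
  z_hfc <- standardize(cohort$scores$hfc_score)
  cb <- effects$covariate_alpha_betas
  cov <- cohort$covariates
  eta <- effects$alpha_beta * z_hfc
  if (!is.null(cb) && length(cb)) {
    get_z <- function(nm) standardize(as.numeric(cov[[nm]]))
    for (nm in intersect(names(cb), names(cov)))
      eta <- eta + cb[[nm]] * get_z(nm)
  }
  eta
}

#' Simulate a genus-level relative-abundance matrix
#'
#' Baseline log-normal taxon intensities around a heavy-tailed mean
#' spectrum; diet and covariate effects on alpha diversity enter as an
#' HFC-dependent compression of the log intensities (more compression =
#' more even = higher Shannon), and per-taxon effects are planted exactly on
#' the arcsine-sqrt scale (`asin(sqrt(p))` shifted by `beta * z_HFC`, the
#' non-planted taxa rescaled to the remaining row mass), so association
#' scans recover the planted `beta` without transform bias.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param effects An [effect_spec()].
#' @param n_taxa Panel size (91 core + rare genera; default 191).
#' @param seed Integer seed.
#' @return Relative-abundance matrix (samples x taxa, rows sum to 1) with a
#'   `truth` attribute recording the planted effects and panel.
#' @export
simulate_abundances <- function(cohort, effects = effect_spec(),
                                n_taxa = 191L, seed = 1L) {
  stopifnot(inherits(cohort, "dietbiome_cohort"),
            inherits(effects, "effect_spec"))
  panel <- taxon_panel(n_taxa)
  unknown <- setdiff(effects$planted_taxa$taxon_id, panel$taxon_id)
  if (length(unknown))
    stop_dietbiome("planted effect on unknown taxon: ",
                   paste(unknown, collapse = ", "))
  n <- nrow(cohort$covariates)
  with_seed(substream_seed(seed, "simulate_abundances"), {
    eps <- matrix(stats::rnorm(n * n_taxa), n, n_taxa)
    L <- matrix(panel$mean_log, n, n_taxa, byrow = TRUE) +
      sweep(eps, 2, panel$sigma, `*`)
    P <- exp(L)
    P <- P / rowSums(P)
    dimnames(P) <- list(cohort$covariates$sample_id, panel$taxon_id)
    z <- standardize(cohort$scores$hfc_score)
    ## plant per-taxon effects first, exactly on the arcsine-sqrt scale
    ## (the other taxa absorb the mass difference), so association scans
    ## recover beta without transform bias
    idx <- integer(0)
    implicit_slope <- 0
    if (nrow(effects$planted_taxa)) {
      idx <- match(effects$planted_taxa$taxon_id, panel$taxon_id)
      planted_new <- P[, idx, drop = FALSE]
      for (j in seq_along(idx)) {
        y <- asin(sqrt(planted_new[, j])) + effects$planted_taxa$beta[j] * z
        planted_new[, j] <- sin(pmin(pmax(y, 0), pi / 2))^2
      }
      rest <- 1 - rowSums(planted_new)
      if (any(rest <= 0))
        stop_dietbiome("planted effects exhaust the composition")
      P <- P * (rest / (1 - rowSums(P[, idx, drop = FALSE])))
      P[, idx] <- planted_new
      ## abundance shifts in a dominant taxon drag the Shannon index with
      ## them; measure that implicit diversity drift so the evenness
      ## channel below carries only the *net* configured alpha effect
      H1 <- -rowSums(ifelse(P > 0, P * log(P), 0))
      implicit_slope <- stats::cov(H1, z) / max(stats::var(z), 1e-12)
    }
    ## evenness channel: compress the log shares of the non-planted taxa
    ## (more compression = more even = higher Shannon), leaving planted
    ## columns untouched
    eta <- evenness_signal(cohort, effects) - implicit_slope * z
    if (any(eta != 0)) {
      rest_idx <- setdiff(seq_len(n_taxa), idx)
      rest_mass <- 1 - (if (length(idx)) rowSums(P[, idx, drop = FALSE]) else 0)
      Lr0 <- log(pmax(P[, rest_idx, drop = FALSE], 1e-300))
      compress_rest <- function(cs) {
        Lr <- Lr0 * cs
        Pr <- exp(Lr - apply(Lr, 1, max))
        Pr / rowSums(Pr) * rest_mass
      }
      shannon_rest <- function(Pr)
        -rowSums(ifelse(Pr > 0, Pr * log(Pr), 0))
      ## probe d(Shannon)/d(compression) on this very data set
      gain <- mean(shannon_rest(compress_rest(0.98)) -
                   shannon_rest(compress_rest(1.02))) / 0.04
      compress <- 1 - pmin(pmax(eta / gain, -0.9), 0.9)
      P[, rest_idx] <- compress_rest(compress)
    }
    attr(P, "truth") <- list(effects = effects, panel = panel, seed = seed)
    P
  })
}

#' Simulate a KO-group relative-abundance matrix
#'
#' Analogous to [simulate_abundances()] but on the log10 scale: baseline
#' log-normal KO intensities, planted effects multiply a KO's share by
#' `10^(beta * z_HFC)` exactly (non-planted KOs rescaled to the remaining
#' mass), rows normalised to 1.
#'
#' @inheritParams simulate_abundances
#' @param n_kos Number of KO groups (default 200).
#' @return Relative-abundance matrix (samples x KO) with a `truth`
#'   attribute.
#' @export
simulate_ko_table <- function(cohort, effects = effect_spec(),
                              n_kos = 200L, seed = 1L) {
  stopifnot(inherits(cohort, "dietbiome_cohort"),
            inherits(effects, "effect_spec"))
  ids <- sprintf("K%05d", seq_len(n_kos))
  unknown <- setdiff(effects$planted_kos$ko_id, ids)
  if (length(unknown))
    stop_dietbiome("planted effect on unknown KO: ",
                   paste(unknown, collapse = ", "))
  n <- nrow(cohort$covariates)
  with_seed(substream_seed(seed, "simulate_ko_table"), {
    share <- seq_len(n_kos)^(-0.9)
    share <- share / sum(share)
    eps <- matrix(stats::rnorm(n * n_kos, sd = 0.8), n, n_kos)
    K <- exp(matrix(log(share), n, n_kos, byrow = TRUE) + eps)
    K <- K / rowSums(K)
    dimnames(K) <- list(cohort$covariates$sample_id, ids)
    if (nrow(effects$planted_kos)) {
      z <- standardize(cohort$scores$hfc_score)
      idx <- match(effects$planted_kos$ko_id, ids)
      old <- K[, idx, drop = FALSE]
      new <- old * 10^(outer(z, effects$planted_kos$beta))
      rest <- 1 - rowSums(new)
      if (any(rest <= 0))
        stop_dietbiome("planted KO effects exhaust the composition")
      K <- K * (rest / (1 - rowSums(old)))
      K[, idx] <- new
    }
    attr(K, "truth") <- list(effects = effects, seed = seed)
    K
  })
}
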