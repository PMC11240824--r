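#' Default regime-specific covariate prevalences
#'
#' Named list mapping each binary covariate to its prevalence in the
#' heterogeneous (`het`) and homogeneous (`hom`) visual-ITH regimes.
#' Defaults reproduce the prevalence contrasts observed between the two
#' groups in a large population-based breast cancer cohort (younger age,
#' Black race, high grade, high risk-of-recurrence score, basal-like
#' subtype, ER negativity and adaptive immune response are all more common
#' in the visually homogeneous group).
#'
#' @return Named list of length-2 numeric vectors `c(het = , hom = )`.
#' @export
default_covariate_effects <- function() {
  list(
    age_young    = c(het = 0.431, hom = 0.486),
    race_black   = c(het = 0.429, hom = 0.530),
    grade_high   = c(het = 0.450, hom = 0.600),
    ror_high     = c(het = 0.364, hom = 0.628),
    pam50_basal  = c(het = 0.189, hom = 0.261),
    er_neg       = c(het = 0.203, hom = 0.291),
    node_pos     = c(het = 0.350, hom = 0.400),
    size_large   = c(het = 0.400, hom = 0.450),
    immune_high  = c(het = 0.247, hom = 0.391)
  )
}

#' Configuration for the synthetic visual-ITH cohort generator
#'
#' Bundles every parameter of the generator: cohort size, cores-per-patient
#' distribution, the two within-patient feature-variance regimes that create
#' visually homogeneous vs heterogeneous patients, regime-specific covariate
#' prevalences, and the planted effect sizes (recurrence hazard ratio and
#' clonality/TP53 odds ratios, homogeneous vs heterogeneous referent).
#'
#' @param n_patients Number of patients (>= 2).
#' @param cores_per_patient Named probability vector over core counts;
#'   names are integer core counts (all >= 2, mirroring the inclusion rule
#'   that every patient contributes at least two cores).
#' @param feature_dim Dimension of the per-core feature vectors.
#' @param sigma_between Spread of patient centers in feature space.
#' @param sigma_within_low Core spread around the patient center for the
#'   homogeneous regime; must be < `sigma_within_high`.
#' @param sigma_within_high Core spread for the heterogeneous regime.
#' @param prop_heterogeneous Fraction of patients in the heterogeneous
#'   regime (default 0.44).
#' @param covariate_effects See [default_covariate_effects()].
#' @param true_hr Planted recurrence hazard ratio, homogeneous vs
#'   heterogeneous (default 1.62).
#' @param true_or_clonal,true_or_tp53 Planted odds ratios for single-clone
#'   status and TP53 mutation, homogeneous vs heterogeneous.
#' @param prev_clonal_het,prev_tp53_het Outcome prevalence in the
#'   heterogeneous regime; the homogeneous prevalence follows from the
#'   planted odds ratio.
#' @param baseline_hazard Exponential recurrence hazard (per year) in the
#'   heterogeneous regime.
#' @param censor_rate Fraction of records independently censored.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 50,
                             cores_per_patient = c("2" = 0.2, "3" = 0.6, "4" = 0.2),
                             feature_dim = 512,
                             sigma_between = 1,
                             sigma_within_low = 0.1,
                             sigma_within_high = 3,
                             prop_heterogeneous = 0.44,
                             covariate_effects = default_covariate_effects(),
                             true_hr = 1.62,
                             true_or_clonal = 1.54,
                             true_or_tp53 = 1.98,
                             prev_clonal_het = 0.55,
                             prev_tp53_het = 0.27,
                             baseline_hazard = 0.15,
                             censor_rate = 0.2,
                             seed = 1L) {
  if (n_patients < 2) {
    stop("n_patients must be >= 2: clustering is undefined for a single patient")
  }
  kk <- as.integer(names(cores_per_patient))
  if (anyNA(kk) || any(kk < 2)) {
    stop("cores_per_patient names must be integer core counts >= 2")
  }
  if (any(cores_per_patient < 0) || sum(cores_per_patient) <= 0) {
    stop("cores_per_patient must be a non-negative weight vector")
  }
  if (!(sigma_within_low < sigma_within_high)) {
    stop("sigma_within_low must be strictly smaller than sigma_within_high")
  }
  probs <- c(prop_heterogeneous, censor_rate,
             unlist(covariate_effects, use.names = FALSE),
             prev_clonal_het, prev_tp53_het)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (any(c(sigma_between, true_hr, true_or_clonal, true_or_tp53,
            baseline_hazard) <= 0) || sigma_within_low < 0) {
    stop("scale and ratio parameters must be positive")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    cores_per_patient = cores_per_patient / sum(cores_per_patient),
    feature_dim = as.integer(feature_dim),
    sigma_between = sigma_between,
    sigma_within_low = sigma_within_low,
    sigma_within_high = sigma_within_high,
    prop_heterogeneous = prop_heterogeneous,
    covariate_effects = covariate_effects,
    true_hr = true_hr,
    true_or_clonal = true_or_clonal,
    true_or_tp53 = true_or_tp53,
    prev_clonal_het = prev_clonal_het,
    prev_tp53_het = prev_tp53_het,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# exact-count planting: round(n*p) positives, assigned to random rows
plant_binary <- function(n, p) {
  pos <- logical(n)
  n_pos <- min(n, round(n * p))
  if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
  pos
}

# shift a prevalence by a planted odds ratio
shift_by_or <- function(p, or) stats::plogis(stats::qlogis(p) + log(or))

#' Generate patient-clustered core feature vectors
#'
#' Patient centers are isotropic Gaussian with spread `sigma_between`; each
#' core is the center plus isotropic noise whose scale depends on the
#' patient's regime (`sigma_within_low` for homogeneous patients,
#' `sigma_within_high` for heterogeneous ones). High within-patient spread
#' is exactly what the NML score is designed to detect.
#'
#' @param config A [synthetic_config()].
#' @return List with `features` (a [feature_matrix()]) and `truth`, a
#'   data.frame with one row per patient (`patient_id`, `regime`,
#'   `n_cores`).
#' @export
gen_features <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  d <- config$feature_dim
  patient_id <- sprintf("P%04d", seq_len(n))
  regime <- rep("heterogeneous", n)
  n_het <- round(n * config$prop_heterogeneous)
  regime[seq_len(n) > n_het] <- "homogeneous"
  regime <- sample(regime)  # random order, exact regime counts
  kk <- as.integer(names(config$cores_per_patient))
  n_cores <- kk[sample.int(length(kk), n, replace = TRUE,
                           prob = config$cores_per_patient)]

  centers <- matrix(stats::rnorm(n * d, sd = config$sigma_between), n, d)
  total <- sum(n_cores)
  feat <- matrix(0, total, d)
  pid <- character(total)
  cid <- character(total)
  row <- 1L
  for (i in seq_len(n)) {
    sw <- if (regime[i] == "heterogeneous") config$sigma_within_high else config$sigma_within_low
    k <- n_cores[i]
    idx <- row:(row + k - 1L)
    noise <- if (sw > 0) matrix(stats::rnorm(k * d, sd = sw), k, d) else matrix(0, k, d)
    feat[idx, ] <- matrix(centers[i, ], k, d, byrow = TRUE) + noise
    pid[idx] <- patient_id[i]
    cid[idx] <- sprintf("%s_C%d", patient_id[i], seq_len(k))
    row <- row + k
  }
  truth <- data.frame(patient_id = patient_id, regime = regime,
                      n_cores = n_cores, stringsAsFactors = FALSE)
  list(features = feature_matrix(feat, pid, cid, variant = "original"),
       truth = truth)
}

#' Generate clinical records with planted effect sizes
#'
#' Binary covariates are planted with exact marginal counts per regime
#' (`round(n * p)` positives assigned to randomly chosen patients), so the
#' regime-specific prevalences in [default_covariate_effects()] hold up to
#' integer rounding in every realization. Recurrence times are exponential
#' with the homogeneous-regime hazard multiplied by `true_hr`; censoring is
#' independent of regime at rate `censor_rate` (censored records observe a
#' uniform fraction of their latent event time). Clonality and TP53 status
#' are planted so the homogeneous-vs-heterogeneous odds ratio equals
#' `true_or_clonal` / `true_or_tp53`.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth table from [gen_features()].
#' @return List with `records` (clinical data.frame, one row per patient)
#'   and `truth` augmented with the latent event time.
#' @export
gen_clinical <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(c("patient_id", "regime") %in% names(truth))) {
    stop("truth must be the table returned by gen_features()")
  }
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  hom <- truth$regime == "homogeneous"

  draw_cov <- function(prev, or = NULL) {
    if (length(prev) != 2 || !all(c("het", "hom") %in% names(prev))) {
      stop("each covariate effect must be c(het = , hom = )")
    }
    p_hom <- if (is.null(or)) prev[["hom"]] else shift_by_or(prev[["het"]], or)
    out <- logical(n)
    out[!hom] <- plant_binary(sum(!hom), prev[["het"]])
    out[hom] <- plant_binary(sum(hom), p_hom)
    out
  }
  ce <- config$covariate_effects
  known <- names(default_covariate_effects())
  if (!all(names(ce) %in% known)) {
    stop("unknown covariate name(s): ",
         paste(setdiff(names(ce), known), collapse = ", "))
  }

  lvl <- function(flag, yes, no) factor(ifelse(flag, yes, no), levels = c(no, yes))
  rec <- data.frame(patient_id = truth$patient_id, stringsAsFactors = FALSE)
  rec$age_group <- lvl(draw_cov(ce$age_young), "<50", ">=50")
  rec$race <- lvl(draw_cov(ce$race_black), "Black", "non-Black")
  rec$grade <- lvl(draw_cov(ce$grade_high), "high", "low")
  rec$ror <- lvl(draw_cov(ce$ror_high), "high", "low")
  rec$pam50 <- lvl(draw_cov(ce$pam50_basal), "Basal", "LumA")
  rec$er <- lvl(draw_cov(ce$er_neg), "neg", "pos")
  rec$node <- lvl(draw_cov(ce$node_pos), "pos", "neg")
  rec$size <- lvl(draw_cov(ce$size_large), ">2cm", "<=2cm")
  rec$immune_class <- lvl(draw_cov(ce$immune_high), "high", "low")
  rec$subclones <- lvl(draw_cov(c(het = config$prev_clonal_het, hom = NA),
                                or = config$true_or_clonal), "1", ">1")
  rec$tp53 <- lvl(draw_cov(c(het = config$prev_tp53_het, hom = NA),
                           or = config$true_or_tp53), "mutation", "none")

  rate <- config$baseline_hazard * ifelse(hom, config$true_hr, 1)
  time_true <- stats::rexp(n, rate = rate)
  censored <- plant_binary(n, config$censor_rate)
  rec$time <- ifelse(censored, stats::runif(n) * time_true, time_true)
  rec$event <- as.integer(!censored)

  truth$time_true <- time_true
  list(records = rec, truth = truth)
}

# canonical H&E stain matrix (columns = unit optical-density vectors)
he_stain_matrix <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  cbind(hematoxylin = h / sqrt(sum(h^2)), eosin = e / sqrt(sum(e^2)))
}

#' Render one toy H&E core image with ground truth
#'
#' Draws a circular "tissue" disc on a white background: eosin-dominant
#' stroma containing hematoxylin-dominant elliptical epithelium nests.
#' Pixel intensities follow the Beer-Lambert stain model
#' `I = exp(-(c_h * H + c_e * E))` with multiplicative concentration noise,
#' so the image lies exactly in the two-stain subspace assumed by the
#' normalization step. Optionally injects a known artifact (uniform grey
#' bubble or blurred region) into one named tile.
#'
#' @param patient_id,core_id Identifiers carried on the image.
#' @param size Side length in pixels (square image).
#' @param n_nests Number of epithelium nests.
#' @param nest_scale Mean nest radius in pixels.
#' @param background_only If TRUE, render a pure-white core.
#' @param artifact One of "none", "bubble", "blur".
#' @param artifact_tile Integer `c(row0, col0)` 0-based pixel origin of the
#'   tile receiving the artifact (required when `artifact != "none"`).
#' @param patch_size Tile side used to size the artifact region.
#' @param noise_sd Log-scale sd of the concentration noise.
#' @return List with `image` (a [core_image()]) and `mask` (the
#'   ground-truth [segmentation_mask()]).
#' @export
gen_core_image <- function(patient_id = "P0001", core_id = "P0001_C1",
                           size = 600, n_nests = 12, nest_scale = 45,
                           background_only = FALSE,
                           artifact = c("none", "bubble", "blur"),
                           artifact_tile = NULL, patch_size = 200,
                           noise_sd = 0.1) {
  artifact <- match.arg(artifact)
  if (size < patch_size) {
    stop("requested image side (", size, ") is smaller than one patch side (",
         patch_size, ")")
  }
  S <- he_stain_matrix()
  lab <- matrix(0L, size, size)  # 0 background, 1 epithelium, 2 stroma
  ch <- matrix(0, size, size)
  cecc <- matrix(0, size, size)
  if (!background_only) {
    ctr <- (size + 1) / 2
    rr <- row(lab) - ctr
    cc <- col(lab) - ctr
    disc <- (rr^2 + cc^2) <= (0.45 * size)^2
    lab[disc] <- 2L
    if (n_nests > 0) {
      for (j in seq_len(n_nests)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.33 * size)
        cy <- ctr + rad * sin(ang)
        cx <- ctr + rad * cos(ang)
        a <- nest_scale * stats::runif(1, 0.6, 1.4)
        b <- nest_scale * stats::runif(1, 0.6, 1.4)
        th <- stats::runif(1, 0, pi)
        u <- (rr + ctr - cy) * cos(th) + (cc + ctr - cx) * sin(th)
        v <- -(rr + ctr - cy) * sin(th) + (cc + ctr - cx) * cos(th)
        nest <- ((u / a)^2 + (v / b)^2) <= 1 & disc
        lab[nest] <- 1L
      }
    }
    epi <- lab == 1L
    str <- lab == 2L
    ch[epi] <- 1.0
    cecc[epi] <- 0.30
    ch[str] <- 0.12
    cecc[str] <- 0.70
    tissue <- epi | str
    nz <- sum(tissue)
    if (nz > 0 && noise_sd > 0) {
      ch[tissue] <- ch[tissue] * exp(stats::rnorm(nz, sd = noise_sd))
      cecc[tissue] <- cecc[tissue] * exp(stats::rnorm(nz, sd = noise_sd))
    }
  }
  px <- array(1, dim = c(size, size, 3))
  for (b in 1:3) px[, , b] <- exp(-(ch * S[b, 1] + cecc * S[b, 2]))

  if (artifact != "none") {
    if (is.null(artifact_tile) || length(artifact_tile) != 2) {
      stop("artifact_tile = c(row0, col0) is required when injecting an artifact")
    }
    ri <- artifact_tile[1] + seq_len(patch_size)
    ci <- artifact_tile[2] + seq_len(patch_size)
    if (max(ri) > size || max(ci) > size) stop("artifact_tile outside the image")
    if (artifact == "bubble") {
      for (b in 1:3) px[ri, ci, b] <- 0.82
    } else {  # heavy local box blur
      g <- px[ri, ci, ]
      w <- 15
      for (b in 1:3) {
        m <- g[, , b]
        m <- t(apply(m, 1, function(x) stats::filter(x, rep(1 / w, w), circular = TRUE)))
        m <- apply(m, 2, function(x) stats::filter(x, rep(1 / w, w), circular = TRUE))
        g[, , b] <- m
      }
      px[ri, ci, ] <- g
    }
  }
  list(image = core_image(px, patient_id, core_id, variant = "original"),
       mask = segmentation_mask(lab))
}

#' Generate a toy image cohort
#'
#' One call to [gen_core_image()] per core, with nest geometry shared
#' within homogeneous patients (cores look alike) and re-drawn per core for
#' heterogeneous patients (cores look different). Intended for small
#' cohorts: images are dense arrays, so keep `n_patients` modest.
#'
#' @param config A [synthetic_config()].
#' @param size,patch_size Image and tile side lengths in pixels.
#' @return List with `cores` (list of `list(image, mask)`) and the `truth`
#'   table from [gen_features()].
#' @export
gen_images <- function(config, size = 600, patch_size = 200) {
  stopifnot(inherits(config, "synthetic_config"))
  if (size < patch_size) {
    stop("requested image side (", size, ") is smaller than one patch side (",
         patch_size, ")")
  }
  set.seed(config$seed + 2L)
  n <- config$n_patients
  regime <- rep("heterogeneous", n)
  regime[seq_len(n) > round(n * config$prop_heterogeneous)] <- "homogeneous"
  regime <- sample(regime)
  kk <- as.integer(names(config$cores_per_patient))
  n_cores <- kk[sample.int(length(kk), n, replace = TRUE,
                           prob = config$cores_per_patient)]
  patient_id <- sprintf("P%04d", seq_len(n))
  cores <- list()
  for (i in seq_len(n)) {
    base_nests <- sample(6:18, 1)
    base_scale <- stats::runif(1, 25, 60)
    for (k in seq_len(n_cores[i])) {
      if (regime[i] == "heterogeneous") {
        nn <- sample(c(2:6, 14:24), 1)
        sc <- stats::runif(1, 15, 80)
      } else {
        nn <- base_nests
        sc <- base_scale
      }
      cores[[length(cores) + 1L]] <- gen_core_image(
        patient_id = patient_id[i],
        core_id = sprintf("%s_C%d", patient_id[i], k),
        size = size, n_nests = nn, nest_scale = sc, patch_size = patch_size)
    }
  }
  truth <- data.frame(patient_id = patient_id, regime = regime,
                      n_cores = n_cores, stringsAsFactors = FALSE)
  list(cores = cores, truth = truth)
}
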