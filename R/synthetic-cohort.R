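#' Specification of a synthetic multimodal survival cohort
#'
#' Collects the knobs of the synthetic-cohort generator: cohort size,
#' gene panel, patch-bag geometry, per-modality log-hazard effect sizes
#' and the censoring target.  Defaults describe a mid-sized cohort with
#' moderate signal in all three modalities.
#'
#' @param n_patients Number of patients.
#' @param n_genes Number of genes in the expression matrix.
#' @param n_prognostic_genes Number of genes carrying planted signal
#'   (`<= n_genes`).
#' @param feature_dim Patch-feature dimension D (default 1024, matching
#'   the truncated-ResNet50 feature contract).
#' @param bag_size_range Integer interval `[K_min, K_max]` of patches
#'   per slide bag.
#' @param signal_fraction Upper bound on the per-bag proportion of
#'   instances carrying the signal direction; each patient draws a
#'   fraction uniformly from `[0, signal_fraction]`.
#' @param beta_image,beta_gene,beta_clinical Log-hazard effect sizes of
#'   the image, gene and clinical components of the linear predictor.
#' @param baseline_scale Baseline mean survival time in months (the
#'   exponential baseline hazard is `1 / baseline_scale`).
#' @param censoring_rate Target censored proportion in `[0, 1)`.
#' @param seed Integer RNG seed; identical spec + seed reproduces the
#'   cohort bit-for-bit.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L, n_genes = 100L,
                        n_prognostic_genes = 5L, feature_dim = 1024L,
                        bag_size_range = c(16L, 64L),
                        signal_fraction = 0.5,
                        beta_image = 1, beta_gene = 1, beta_clinical = 0.5,
                        baseline_scale = 60, censoring_rate = 0.3,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients <= 0L) stop("n_patients must be positive")
  if (n_prognostic_genes > n_genes) stop("n_prognostic_genes must be <= n_genes")
  if (signal_fraction < 0 || signal_fraction > 1) {
    stop("signal_fraction must lie in [0, 1]")
  }
  if (bag_size_range[1] < 1L || bag_size_range[2] < bag_size_range[1]) {
    stop("bag_size_range must satisfy 1 <= K_min <= K_max")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0, 1)")
  }
  if (baseline_scale <= 0) stop("baseline_scale must be positive")
  out <- list(n_patients = n_patients, n_genes = as.integer(n_genes),
              n_prognostic_genes = as.integer(n_prognostic_genes),
              feature_dim = as.integer(feature_dim),
              bag_size_range = as.integer(bag_size_range),
              signal_fraction = signal_fraction,
              beta_image = beta_image, beta_gene = beta_gene,
              beta_clinical = beta_clinical,
              baseline_scale = baseline_scale,
              censoring_rate = censoring_rate, seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

# amplitude of the planted instance-level signal along the unit direction
SIGNAL_AMPLITUDE <- 2.0
N_IMMUNE_SCORES <- 23L  # with age + cT + cN + cTNM + 5 PAM50 -> 32 covariates

#' Generate a synthetic multimodal cohort with planted survival signal
#'
#' Draws, per patient, a patch-feature bag in which a known subset of
#' instances carries a fixed unit "signal direction", a gene-expression
#' vector with planted prognostic genes, and clinical covariates (age,
#' cT/cN/cTNM stage, PAM50 one-hot, immune-cell scores; 32 in total).
#' Survival times follow an exponential proportional-hazards model with
#' linear predictor
#' `eta = beta_image * f + beta_gene * g + beta_clinical * c`,
#' where `f` is the bag's realized signal-instance fraction, `g` the
#' standardized planted-gene aggregate and `c` the z-scored ordinal cTNM
#' stage.  Censoring is independent exponential with its rate solved by
#' bisection so the expected censored proportion matches
#' `censoring_rate`.
#'
#' @param spec A [cohort_spec].
#' @return An object of class `synthetic_cohort`: list with
#'   `patients` (a [surv_data] with clinical columns), `bags` (list of
#'   `patch_bag`s), `expression` (genes x patients matrix),
#'   `clinical` (patients x 32 numeric matrix), and `truth`
#'   (planted linear predictor and its components, planted gene ids,
#'   per-bag signal-instance index sets).
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 20, feature_dim = 8,
#'                                   bag_size_range = c(4, 8)))
#' nrow(co$patients)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_patients
  D <- spec$feature_dim
  ids <- sprintf("PT%04d", seq_len(n))

  # fixed unit signal direction in feature space
  u <- rep(1 / sqrt(D), D)

  # --- image modality: bags with planted signal instances ---
  Ks <- sample(seq(spec$bag_size_range[1], spec$bag_size_range[2]),
               n, replace = TRUE)
  frac <- spec$signal_fraction * stats::runif(n)
  bags <- vector("list", n)
  signal_idx <- vector("list", n)
  realized_frac <- numeric(n)
  for (i in seq_len(n)) {
    K <- Ks[i]
    X <- matrix(stats::rnorm(K * D), K, D)
    m <- round(frac[i] * K)
    idx <- if (m > 0) sort(sample.int(K, m)) else integer(0)
    if (m > 0) X[idx, ] <- X[idx, , drop = FALSE] +
        matrix(SIGNAL_AMPLITUDE * u, m, D, byrow = TRUE)
    realized_frac[i] <- m / K
    coords <- cbind(x = 256L * ((seq_len(K) - 1L) %% 16L),
                    y = 256L * ((seq_len(K) - 1L) %/% 16L))
    bags[[i]] <- patch_bag(slide_id = ids[i], features = X,
                           coords = coords, extractor_id = "synthetic")
    signal_idx[[i]] <- idx
  }

  # --- gene modality ---
  G <- spec$n_genes
  gene_ids <- sprintf("GENE%04d", seq_len(G))
  expr <- matrix(stats::rnorm(G * n), G, n,
                 dimnames = list(gene_ids, ids))
  p <- spec$n_prognostic_genes
  planted <- gene_ids[seq_len(p)]
  gene_agg <- if (p > 0) {
    unname(colSums(expr[seq_len(p), , drop = FALSE])) / sqrt(p)
  } else numeric(n)

  # --- clinical modality (32 covariates) ---
  age <- stats::rnorm(n, 55, 10)
  cT <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
  cN <- sample(0:3, n, replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
  cTNM <- pmin(4L, pmax(1L, cT + (cN > 0)))
  pam50 <- sample(c("LumA", "LumB", "HER2", "Basal", "Normal"),
                  n, replace = TRUE, prob = c(0.4, 0.2, 0.15, 0.15, 0.1))
  pam_onehot <- outer(pam50, c("LumA", "LumB", "HER2", "Basal", "Normal"),
                      "==") * 1
  colnames(pam_onehot) <- paste0("PAM50_", c("LumA", "LumB", "HER2",
                                             "Basal", "Normal"))
  immune <- matrix(stats::rbeta(n * N_IMMUNE_SCORES, 2, 5),
                   n, N_IMMUNE_SCORES,
                   dimnames = list(NULL, sprintf("immune%02d",
                                                 seq_len(N_IMMUNE_SCORES))))
  clinical <- cbind(age = (age - 55) / 10, cT = cT, cN = cN, cTNM = cTNM,
                    pam_onehot, immune)
  rownames(clinical) <- ids
  clin_score <- as.numeric(scale(cTNM))
  if (any(!is.finite(clin_score))) clin_score <- rep(0, n)

  # --- survival ---
  eta <- spec$beta_image * realized_frac + spec$beta_gene * gene_agg +
    spec$beta_clinical * clin_score
  lambda <- exp(eta) / spec$baseline_scale
  t_true <- stats::rexp(n, rate = lambda)
  if (spec$censoring_rate > 0) {
    crate <- solve_censor_rate(lambda, spec$censoring_rate)
    c_time <- stats::rexp(n, rate = crate)
    time <- pmin(t_true, c_time)
    event <- as.integer(t_true <= c_time)
  } else {
    time <- t_true
    event <- rep(1L, n)
  }
  patients <- surv_data(time, event, ids)

  out <- list(patients = patients, bags = bags, expression = expr,
              clinical = clinical,
              truth = list(eta = eta, image_fraction = realized_frac,
                           gene_aggregate = gene_agg,
                           clinical_score = clin_score,
                           planted_genes = planted,
                           signal_direction = u,
                           signal_idx = signal_idx),
              spec = spec)
  class(out) <- "synthetic_cohort"
  out
}

# bisection for the exponential censoring rate c such that the expected
# censored proportion mean(c / (c + lambda_i)) hits the target
solve_censor_rate <- function(lambda, target, tol = 1e-10) {
  f <- function(cc) mean(cc / (cc + lambda)) - target
  lo <- 1e-12; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * hi) break
  }
  (lo + hi) / 2
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic multimodal cohort: %d patients, %d genes ",
                     "(%d planted), %d-d patch features\n"),
              x$spec$n_patients, x$spec$n_genes,
              x$spec$n_prognostic_genes, x$spec$feature_dim))
  cat(sprintf("  events: %d / %d (censored %.1f%%)\n",
              sum(x$patients$event), nrow(x$patients),
              100 * mean(1 - x$patients$event)))
  invisible(x)
}

# save/restore the global RNG so seeded generators do not disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
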