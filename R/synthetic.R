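# Synthetic paired-omics generator: log-normal latent-factor layers, two
# clinical-marker vectors with planted couplings, injected degenerate
# features, MCAR missingness, and analytic ground truth.
#
# All structure lives on the natural-log scale, where everything is jointly
# Gaussian; abundances are exponentials, so the population correlation of
# any pair of (non-degenerate) abundances has the closed bivariate-lognormal
# form r_ab = (exp(s_ij) - 1) / sqrt((exp(s_ii) - 1) (exp(s_jj) - 1)).
# Planted marker couplings invert this form so that the target correlation
# rho* holds exactly on the abundance scale the pipeline analyses.

#' Simulation configuration for the synthetic paired-omics study
#'
#' Defaults emulate the shape of a 20-patient serum study: 551 protein and
#' 719 metabolite features, markers CEA and CA 19-9 on their clinical
#' scales, a metabolite layer with stronger shared latent factors than the
#' protein layer (serum metabolites co-vary more tightly than proteins),
#' sparse completely-at-random missingness, a handful of degenerate
#' features per layer, and five features per marker coupled at rho* = 0.9.
#'
#' @param n_samples number of samples (default 20).
#' @param n_proteins,n_metabolites features per layer (defaults 551, 719).
#' @param n_factors_protein,n_factors_metabolite latent factors per layer.
#' @param loading_sd_protein,loading_sd_metabolite sd of the factor
#'   loadings on the log scale; the metabolite default is larger, giving
#'   that layer stronger inter-feature correlation.
#' @param noise_sd idiosyncratic log-scale noise sd for ordinary features.
#' @param baseline_log_mean,baseline_log_sd distribution of per-feature
#'   baseline log-intensities (arbitrary intensity units).
#' @param missing_rate MCAR missingness rate in \[0, 1).
#' @param n_degenerate degenerate (low-information) features injected per
#'   layer; each repeats a constant in `floor(n_samples/2) + 2` samples.
#' @param n_planted_biomarkers features coupled to each marker (split
#'   between the two layers).
#' @param rho_star planted abundance-scale population correlation between a
#'   marker and each of its planted features, `|rho_star| < 1`.
#' @param sigma_planted log-scale sd of planted features and markers.
#' @param marker_names,marker_scales marker ids and multiplicative scales
#'   (defaults mimic CEA ~ 500 and CA 19-9 ~ 2000 ng/ml; cosmetic, since
#'   Pearson r is scale-invariant).
#' @param seed RNG seed fixing the whole stream.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 20L,
                              n_proteins = 551L,
                              n_metabolites = 719L,
                              n_factors_protein = 3L,
                              n_factors_metabolite = 3L,
                              loading_sd_protein = 0.3,
                              loading_sd_metabolite = 0.6,
                              noise_sd = 0.5,
                              baseline_log_mean = 10,
                              baseline_log_sd = 1,
                              missing_rate = 0.05,
                              n_degenerate = 10L,
                              n_planted_biomarkers = 5L,
                              rho_star = 0.9,
                              sigma_planted = 0.3,
                              marker_names = c("CEA", "CA19-9"),
                              marker_scales = c(500, 2000),
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              n_factors_protein = as.integer(n_factors_protein),
              n_factors_metabolite = as.integer(n_factors_metabolite),
              loading_sd_protein = loading_sd_protein,
              loading_sd_metabolite = loading_sd_metabolite,
              noise_sd = noise_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              missing_rate = missing_rate,
              n_degenerate = as.integer(n_degenerate),
              n_planted_biomarkers = as.integer(n_planted_biomarkers),
              rho_star = rho_star, sigma_planted = sigma_planted,
              marker_names = marker_names, marker_scales = marker_scales,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_samples >= 3L, n_proteins >= 0L, n_metabolites >= 0L,
              n_factors_protein >= 0L, n_factors_metabolite >= 0L,
              loading_sd_protein >= 0, loading_sd_metabolite >= 0,
              noise_sd > 0, missing_rate >= 0, missing_rate < 1,
              n_degenerate >= 0L, n_planted_biomarkers >= 0L,
              abs(rho_star) < 1, sigma_planted > 0,
              length(marker_names) == length(marker_scales))
    n_planted_total <- 2L * n_planted_biomarkers * length(marker_names) # generous bound
    if (n_planted_biomarkers > 0L &&
        n_planted_total + 2L * n_degenerate > n_proteins + n_metabolites)
      stop("not enough features for the requested planted/degenerate sets",
           call. = FALSE)
  })
  rl <- planted_log_correlation(cfg$rho_star, cfg$sigma_planted)
  if (!is.finite(rl) || abs(rl) >= 1)
    stop("rho_star unattainable at sigma_planted = ", cfg$sigma_planted,
         call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

# Log-scale correlation that induces abundance-scale correlation rho_star
# between two lognormals with common log-sd sigma.
planted_log_correlation <- function(rho_star, sigma) {
  c_ <- expm1(sigma^2)
  log1p(rho_star * c_) / sigma^2
}

padded_ids <- function(prefix, n)
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))

#' Generate a synthetic paired-omics study
#'
#' Draws the two abundance layers, the marker table and the ground truth
#' implied by a [simulation_config()]. Identical seeds give bit-identical
#' output.
#'
#' The generated objects per layer: ordinary features follow the layer's
#' latent-factor log-normal model; each marker's planted features load on a
#' dedicated marker factor so their abundance-scale population correlation
#' with the marker is exactly `rho_star`; degenerate features repeat a
#' constant in a majority of samples (so the default degenerate filter
#' removes them); missingness is MCAR at `missing_rate`, with one observed
#' cell per feature guaranteed.
#'
#' @param config a `SimulationConfig`.
#' @return list with `proteins`, `metabolites` (`AbundanceMatrix`),
#'   `markers` (`MarkerTable`) and `truth` (`SyntheticTruth`: element ids,
#'   layers, factor loadings, idiosyncratic sds, planted couplings,
#'   degenerate ids).
#' @export
synthesize_study <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- paste0("N", seq_len(n))
  prot_ids <- padded_ids("P", cfg$n_proteins)
  met_ids <- padded_ids("M", cfg$n_metabolites)
  ids <- c(prot_ids, met_ids, cfg$marker_names)
  layers <- c(rep("protein", cfg$n_proteins),
              rep("metabolite", cfg$n_metabolites),
              rep("marker", length(cfg$marker_names)))
  n_feat <- cfg$n_proteins + cfg$n_metabolites
  n_el <- length(ids)

  # ---- assign roles ------------------------------------------------------
  planted <- assign_planted(cfg, prot_ids, met_ids)
  degen_ids <- c(utils::tail(prot_ids, min(cfg$n_degenerate, cfg$n_proteins)),
                 utils::tail(met_ids, min(cfg$n_degenerate, cfg$n_metabolites)))
  if (length(intersect(planted$feature, degen_ids)))
    stop("planted and degenerate feature sets overlap; reduce counts",
         call. = FALSE)

  # ---- loadings on log scale --------------------------------------------
  n_marker_factors <- length(cfg$marker_names)
  K <- cfg$n_factors_protein + cfg$n_factors_metabolite + n_marker_factors
  L <- matrix(0, n_el, K, dimnames = list(ids, NULL))
  psi <- rep(cfg$noise_sd, n_el)  # idiosyncratic log-sd
  names(psi) <- ids
  pf <- seq_len(cfg$n_factors_protein)
  mf <- cfg$n_factors_protein + seq_len(cfg$n_factors_metabolite)
  hf <- cfg$n_factors_protein + cfg$n_factors_metabolite +
    seq_len(n_marker_factors)
  if (cfg$n_proteins && length(pf))
    L[prot_ids, pf] <- rnorm(cfg$n_proteins * length(pf),
                             sd = cfg$loading_sd_protein)
  if (cfg$n_metabolites && length(mf))
    L[met_ids, mf] <- rnorm(cfg$n_metabolites * length(mf),
                            sd = cfg$loading_sd_metabolite)
  rho_log <- planted_log_correlation(cfg$rho_star, cfg$sigma_planted)
  s <- cfg$sigma_planted
  for (m in seq_along(cfg$marker_names)) {
    mk <- cfg$marker_names[m]
    L[mk, ] <- 0; L[mk, hf[m]] <- s; psi[mk] <- 0
    feats <- planted$feature[planted$marker == mk]
    if (length(feats)) {
      L[feats, ] <- 0
      L[feats, hf[m]] <- s * rho_log
      psi[feats] <- s * sqrt(1 - rho_log^2)
    }
  }
  psi[cfg$marker_names] <- 1e-12  # numerically zero idiosyncratic noise

  # ---- draw log values ---------------------------------------------------
  FF <- matrix(rnorm(K * n), K, n)
  E <- matrix(rnorm(n_el * n), n_el, n) * psi
  Z <- L %*% FF + E
  mu <- c(rnorm(n_feat, cfg$baseline_log_mean, cfg$baseline_log_sd),
          log(cfg$marker_scales))
  X <- exp(mu + Z)
  dimnames(X) <- list(ids, samples)

  # ---- degenerate features: constant in a majority of samples -----------
  n_rep <- min(n, n %/% 2L + 2L)
  for (f in degen_ids) {
    pos <- sample.int(n, n_rep)
    X[f, pos] <- min(X[f, ]) * 0.9
  }

  # ---- MCAR missingness on the feature layers ---------------------------
  feat_rows <- seq_len(n_feat)
  if (cfg$missing_rate > 0 && n_feat > 0L) {
    mask <- matrix(runif(n_feat * n) < cfg$missing_rate, n_feat, n)
    for (i in which(rowSums(!mask) == 0L)) mask[i, sample.int(n, 1L)] <- FALSE
    Xf <- X[feat_rows, , drop = FALSE]
    Xf[mask] <- NA_real_
    X[feat_rows, ] <- Xf
  }

  truth <- structure(list(
    ids = ids, layers = layers, loadings = L, idio_sd = psi,
    planted = planted, degenerate_ids = degen_ids,
    rho_star = cfg$rho_star, config = cfg
  ), class = "SyntheticTruth")

  list(
    proteins = if (cfg$n_proteins)
      abundance_matrix(X[prot_ids, , drop = FALSE], "protein") else NULL,
    metabolites = if (cfg$n_metabolites)
      abundance_matrix(X[met_ids, , drop = FALSE], "metabolite") else NULL,
    markers = marker_table(X[cfg$marker_names, , drop = FALSE]),
    truth = truth
  )
}

# Split each marker's planted features across the two layers, walking the
# head of each layer so markers get disjoint sets.
assign_planted <- function(cfg, prot_ids, met_ids) {
  k <- cfg$n_planted_biomarkers
  out <- data.frame(marker = character(0), feature = character(0),
                    rho_star = numeric(0), stringsAsFactors = FALSE)
  if (k == 0L) return(out)
  pi_ <- mi_ <- 0L
  for (m in seq_along(cfg$marker_names)) {
    n_p <- min(ceiling(k / 2), cfg$n_proteins - pi_)
    n_m <- min(k - n_p, cfg$n_metabolites - mi_)
    if (n_p + n_m < k)
      stop("not enough features to plant ", k, " biomarkers per marker",
           call. = FALSE)
    feats <- c(prot_ids[pi_ + seq_len(n_p)], met_ids[mi_ + seq_len(n_m)])
    pi_ <- pi_ + n_p; mi_ <- mi_ + n_m
    out <- rbind(out, data.frame(marker = cfg$marker_names[m],
                                 feature = feats, rho_star = cfg$rho_star,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Population abundance-scale correlation matrix implied by the truth
#'
#' Computed from the log-scale covariance `S = L L' + diag(psi^2)` via the
#' bivariate-lognormal correlation form. Degenerate features are not
#' lognormal; their rows/columns are `NA`.
#'
#' @param truth a `SyntheticTruth`.
#' @return symmetric matrix of population correlations (unit diagonal).
#' @export
population_correlations <- function(truth) {
  S <- tcrossprod(truth$loadings) + diag(truth$idio_sd^2)
  v <- expm1(diag(S))
  R <- expm1(S) / sqrt(outer(v, v))
  diag(R) <- 1
  dimnames(R) <- list(truth$ids, truth$ids)
  if (length(truth$degenerate_ids)) {
    R[truth$degenerate_ids, ] <- NA_real_
    R[, truth$degenerate_ids] <- NA_real_
    diag(R) <- 1
  }
  R
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' True strongly-correlated pairs under the synthetic model
#'
#' @param truth a `SyntheticTruth`.
#' @param rho_threshold population |rho| cut-off defining a true positive.
#' @return data.frame `id1, id2, rho` of unordered pairs with
#'   `|rho| >= rho_threshold` (degenerate features excluded).
#' @export
true_pairs <- function(truth, rho_threshold) {
  R <- population_correlations(truth)
  idx <- which(upper.tri(R) & !is.na(R) & abs(R) >= rho_threshold,
               arr.ind = TRUE)
  data.frame(id1 = truth$ids[idx[, 1L]], id2 = truth$ids[idx[, 2L]],
             rho = R[idx], stringsAsFactors = FALSE)
}

#' Score called edges against the planted truth
#'
#' Standard confusion-matrix rates over unordered pairs: positives are the
#' pairs whose population `|rho|` meets `rho_threshold`.
#'
#' @param called data.frame with `id1`, `id2` columns (e.g. the edges of a
#'   built network, or the significant rows of a correlation table).
#' @param truth a `SyntheticTruth`.
#' @param rho_threshold population |rho| defining truth positives (use the
#'   pipeline's `sqrt(r2_min)` for a like-for-like comparison).
#' @return list `precision`, `recall`, `fdp`, `tp`, `fp`, `fn`; `recall` is
#'   `NA` when the truth positive set is empty, `precision`/`fdp` are `NA`
#'   when nothing was called.
#' @export
evaluate_recovery <- function(called, truth, rho_threshold) {
  pos <- true_pairs(truth, rho_threshold)
  pos_keys <- pair_key(pos$id1, pos$id2)
  called_keys <- unique(pair_key(called$id1, called$id2))
  tp <- sum(called_keys %in% pos_keys)
  fp <- length(called_keys) - tp
  fn <- length(pos_keys) - tp
  list(
    precision = if (length(called_keys)) tp / length(called_keys) else NA_real_,
    recall = if (length(pos_keys)) tp / length(pos_keys) else NA_real_,
    fdp = if (length(called_keys)) fp / length(called_keys) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}
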