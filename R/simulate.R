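#' Configuration for the synthetic multi-batch generator
#'
#' Builds the parameter list consumed by [simulate_table()]. The defaults
#' emulate a 9-month wastewater monitoring campaign: 56 wastewater samples
#' (7 months x 6 trunkline sites A-E and G, plus WWTP influent and
#' effluent each month), analysed in 4 analytical batches
#' (May | June | July-September | November+January), with one method blank
#' per month and 10 isotopically labelled internal-standard (ISTD)
#' channels.
#'
#' The batch-effect model, on the log2 scale, for analyte feature g in
#' sample j of batch b is
#' \deqn{s_g c_b + \gamma_{gb} + e_j}
#' where `c_b` is a batch-wide response drift shared across compounds,
#' `s_g ~ N(1, sensitivity_sd)` is how strongly feature g responds to that
#' drift, `gamma_gb ~ N(0, idio_sd)` is a compound-idiosyncratic batch
#' shift, and `e_j ~ N(0, efficiency_sd)` is a per-sample injection/
#' ionization efficiency shared by all channels of the sample. ISTD
#' channels experience `c_b + e_j` only (sensitivity 1, no idiosyncratic
#' term), so median-ISTD scaling removes the shared components but not the
#' compound-specific ones. Residual noise is `N(0, noise_sd * delta_gb)`
#' with `log(delta_gb) ~ N(0, scale_log_sd)` giving each batch a
#' multiplicative (variance) effect. The magnitudes are free parameters
#' of the generator, not estimates from any real acquisition.
#'
#' @param n_features number of analyte features (before planted split
#'   twins and ISTD channels are appended)
#' @param months,sites sampling-month and sampling-location labels; every
#'   month x site combination yields exactly one wastewater sample
#' @param design optional data.frame with columns `month`, `site`
#'   overriding the full `months` x `sites` grid; duplicate rows are an
#'   error
#' @param batch_map named integer vector month -> analytical batch
#' @param n_blanks_per_month method blanks per month
#' @param n_istd number of ISTD channels
#' @param base_log2_range range of baseline log2 abundance for
#'   "background" features; together with the sporadic range the default
#'   spans more than six orders of magnitude on the raw scale
#' @param noise_sd residual log2 noise standard deviation
#' @param noise_df degrees of freedom of the (unit-variance scaled) t
#'   noise; the default 4 gives the occasional large matrix effect seen
#'   in environmental acquisitions, `Inf` gives Gaussian noise
#' @param sparsity list controlling zero inflation: `frac_sporadic`
#'   (share of features whose baseline sits near the detection limit, so
#'   their occurrence is sparse and response-dependent),
#'   `sporadic_log2_range` (their baseline range),
#'   `detection_threshold` (counts; realized heights below it are
#'   censored to 0, so low-response batches and samples lose
#'   detections), and `dropout` (additional unconditional per-cell miss
#'   probability, emulating alignment losses)
#' @param batch_effect list: `common` (per-batch drift c_b, log2),
#'   `sensitivity_sd`, `idio_sd`, `scale_log_sd` (see Details)
#' @param efficiency_sd sd of the per-sample efficiency shift (log2)
#' @param istd_noise_sd sd of ISTD channel measurement noise (log2)
#' @param month_effect_frac,month_effect_size fraction of features with a
#'   planted single-month abundance shift and its log2 magnitude
#' @param site_effect_frac,site_effect_size ditto for a single site
#' @param split_frac_duplicate,split_frac_alternating fractions of
#'   features emitted twice as planted split pairs (duplicate form:
#'   identical values with a few extra dropouts; alternating form:
#'   complementary nonzero patterns)
#' @param contaminant_frac fraction of features planted as blank
#'   contaminants (high method-blank background, so the blank filter
#'   should remove them)
#' @param lowrt_frac,lowsnr_frac fractions of features planted with
#'   retention time < 4.5 min or S/N < 10, to exercise those filters
#' @param seed random seed; a fixed seed makes the output bit-reproducible
#'
#' @return a `SimulationConfig` list
#' @export
sim_config <- function(n_features = 800,
                       months = c("May", "June", "July", "August",
                                  "September", "November", "January"),
                       sites = c("A", "B", "C", "D", "E", "G",
                                 "influent", "effluent"),
                       design = NULL,
                       batch_map = c(May = 1L, June = 2L, July = 3L,
                                     August = 3L, September = 3L,
                                     November = 4L, January = 4L),
                       n_blanks_per_month = 1L,
                       n_istd = 10L,
                       base_log2_range = c(12, 30),
                       noise_sd = 0.45,
                       noise_df = 4,
                       sparsity = list(frac_sporadic = 0.35,
                                       sporadic_log2_range = c(8.5, 12.5),
                                       detection_threshold = 500,
                                       dropout = 0.03),
                       batch_effect = list(common = c(0, 1.2, -1.0, 1.6),
                                           sensitivity_sd = 0.3,
                                           idio_sd = 0.8,
                                           scale_log_sd = 0.25),
                       efficiency_sd = 0.25,
                       istd_noise_sd = 0.05,
                       month_effect_frac = 0.10, month_effect_size = 1.5,
                       site_effect_frac = 0.10, site_effect_size = 1.5,
                       split_frac_duplicate = 0.05,
                       split_frac_alternating = 0.05,
                       contaminant_frac = 0.03,
                       lowrt_frac = 0.08, lowsnr_frac = 0.08,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$design))
    cfg$design <- expand.grid(site = sites, month = months,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)[, c("month", "site")]
  if (anyDuplicated(cfg$design))
    stop("design has duplicate (month, site) cells")
  miss <- setdiff(unique(cfg$design$month), names(batch_map))
  if (length(miss))
    stop("batch_map does not cover month(s): ", paste(miss, collapse = ", "))
  fr <- c(month_effect_frac, site_effect_frac, split_frac_duplicate,
          split_frac_alternating, contaminant_frac, lowrt_frac, lowsnr_frac,
          sparsity$frac_sporadic, sparsity$dropout)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  n_batches <- length(unique(batch_map[unique(cfg$design$month)]))
  if (length(batch_effect$common) < n_batches)
    stop("batch_effect$common must give a drift for each of the ",
         n_batches, " batches")
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

# Do any two of rows i, j satisfy all three joining criteria? Vectorized
# over equal-length vectors.
meets_all_criteria <- function(mz1, mz2, rt1, rt2, iso1, iso2,
                               rt_tol_min = 0.25, mz_tol_ppm = 10,
                               iso_cv_max = 0.20) {
  ppm <- abs(mz1 - mz2) / ((mz1 + mz2) / 2) * 1e6
  cv <- pair_cv(iso1, iso2)
  abs(rt1 - rt2) <= rt_tol_min & ppm <= mz_tol_ppm &
    !is.na(cv) & cv <= iso_cv_max
}

#' Simulate a multi-batch nontarget feature table with ground truth
#'
#' Generates a raw-scale `FeatureTable` with the statistical structure the
#' downstream analysis assumes (see [sim_config()]): a wide baseline
#' abundance distribution, planted additive/multiplicative batch effects,
#' planted month/site effects, class-specific zero inflation, per-month
#' method blanks with low-level background, ISTD channels, and planted
#' duplicate/alternating split-feature pairs whose metadata satisfy the
#' three joining criteria. Features that are not planted pairs are
#' guaranteed (by rejection sampling of m/z) to violate at least one
#' criterion, so joining precision/recall can be scored exactly.
#'
#' @param config a [sim_config()] list
#' @return list with elements `table` (`FeatureTable`, `scale_tag` "raw")
#'   and `truth` (list recording every planted effect: per-batch drifts,
#'   sensitivities, idiosyncratic shifts, per-sample efficiencies, month/
#'   site effects, split pairs, ISTD / contaminant / low-RT / low-SNR
#'   feature ids, and feature classes)
#' @export
simulate_table <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  cfg <- config

  ## ---- samples -------------------------------------------------------
  des <- cfg$design
  months_present <- intersect(cfg$months, unique(des$month))
  ww <- data.frame(sample_id = paste(des$month, des$site, sep = "_"),
                   role = "wastewater", site = des$site, month = des$month,
                   batch = as.integer(cfg$batch_map[des$month]),
                   stringsAsFactors = FALSE)
  blanks <- do.call(rbind, lapply(months_present, function(m) {
    k <- seq_len(cfg$n_blanks_per_month)
    data.frame(sample_id = paste0("Blank_", m, ifelse(k > 1, paste0("_", k), "")),
               role = "method_blank", site = NA_character_, month = m,
               batch = as.integer(cfg$batch_map[[m]]),
               stringsAsFactors = FALSE)
  }))
  samples <- rbind(ww, blanks)
  ns <- nrow(samples)
  batches <- sort(unique(samples$batch))
  bidx <- match(samples$batch, batches)

  ## ---- analyte feature metadata -------------------------------------
  G <- cfg$n_features
  cls <- ifelse(stats::runif(G) < cfg$sparsity$frac_sporadic,
                "sporadic", "background")
  mu <- stats::runif(G, cfg$base_log2_range[1], cfg$base_log2_range[2])
  spor <- cls == "sporadic"
  mu[spor] <- stats::runif(sum(spor), cfg$sparsity$sporadic_log2_range[1],
                           cfg$sparsity$sporadic_log2_range[2])
  mz <- stats::runif(G, 85, 950)
  rt <- stats::runif(G, 4.6, 28)
  low_rt <- sort(sample.int(G, round(cfg$lowrt_frac * G)))
  rt[low_rt] <- stats::runif(length(low_rt), 0.8, 4.4)
  snr <- 10^stats::runif(G, 1.1, 2.7)
  low_snr <- sort(sample.int(G, round(cfg$lowsnr_frac * G)))
  snr[low_snr] <- stats::runif(length(low_snr), 2, 9.5)
  iso <- stats::runif(G, 0.02, 0.24)
  contaminants <- sort(sample.int(G, round(cfg$contaminant_frac * G)))

  ## ---- planted effects ----------------------------------------------
  be <- cfg$batch_effect
  common <- be$common[seq_along(batches)]
  sens <- stats::rnorm(G, 1, be$sensitivity_sd)
  idio <- matrix(stats::rnorm(G * length(batches), 0, be$idio_sd),
                 G, length(batches))
  delta <- matrix(exp(stats::rnorm(G * length(batches), 0, be$scale_log_sd)),
                  G, length(batches))
  eff <- stats::rnorm(ns, 0, cfg$efficiency_sd)
  names(eff) <- samples$sample_id

  pick_effects <- function(frac, size, levels) {
    idx <- sort(sample.int(G, round(frac * G)))
    if (!length(idx))
      return(data.frame(feature = integer(), level = character(),
                        effect = numeric(), stringsAsFactors = FALSE))
    data.frame(feature = idx,
               level = sample(levels, length(idx), replace = TRUE),
               effect = size * sample(c(-1, 1), length(idx), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  month_eff <- pick_effects(cfg$month_effect_frac, cfg$month_effect_size,
                            months_present)
  site_eff <- pick_effects(cfg$site_effect_frac, cfg$site_effect_size,
                           unique(des$site))

  ## ---- analyte abundances (log2 scale) ------------------------------
  ## residual noise is heavy-tailed by default (unit-variance t):
  ## sporadic ion suppression/enhancement produces occasional large
  ## matrix effects on individual peaks
  eps <- if (is.finite(cfg$noise_df)) {
    stats::rt(G * ns, df = cfg$noise_df) /
      sqrt(cfg$noise_df / (cfg$noise_df - 2))
  } else stats::rnorm(G * ns)
  L <- matrix(mu, G, ns) +
    outer(sens, common)[, bidx] + idio[, bidx] +
    matrix(eff, G, ns, byrow = TRUE) +
    matrix(eps * cfg$noise_sd, G, ns) * sqrt(delta)[, bidx]
  is_ww <- samples$role == "wastewater"
  for (r in seq_len(nrow(month_eff))) {
    j <- which(is_ww & samples$month == month_eff$level[r])
    L[month_eff$feature[r], j] <- L[month_eff$feature[r], j] +
      month_eff$effect[r]
  }
  for (r in seq_len(nrow(site_eff))) {
    j <- which(is_ww & !is.na(samples$site) &
                 samples$site == site_eff$level[r])
    L[site_eff$feature[r], j] <- L[site_eff$feature[r], j] +
      site_eff$effect[r]
  }

  ## blanks: low-level carryover background, except planted contaminants
  ## which sit well above one tenth of the wastewater maximum
  jb <- which(samples$role == "method_blank")
  L[, jb] <- matrix(mu - 8, G, length(jb)) +
    matrix(eff[jb], G, length(jb), byrow = TRUE) +
    matrix(stats::rnorm(G * length(jb), 0, cfg$noise_sd), G, length(jb))
  if (length(contaminants))
    L[contaminants, jb] <- matrix(mu[contaminants] + 4,
                                  length(contaminants), length(jb)) +
      matrix(stats::rnorm(length(contaminants) * length(jb), 0, 0.2),
             length(contaminants), length(jb))

  raw <- round(2^L)
  ## zero inflation: detection-limit censoring (response-dependent, so
  ## low-response batches and samples lose detections of near-threshold
  ## features) plus a small unconditional alignment-miss dropout
  raw[raw < cfg$sparsity$detection_threshold] <- 0
  if (cfg$sparsity$dropout > 0) {
    miss <- matrix(stats::runif(G * ns), G, ns) < cfg$sparsity$dropout
    raw[miss] <- 0
  }

  ## ---- ISTD channels -------------------------------------------------
  nI <- cfg$n_istd
  mu_istd <- stats::runif(nI, 18, 22)
  L_istd <- matrix(mu_istd, nI, ns) +
    matrix(common[bidx], nI, ns, byrow = TRUE) +
    matrix(eff, nI, ns, byrow = TRUE) +
    matrix(stats::rnorm(nI * ns, 0, cfg$istd_noise_sd), nI, ns)
  raw_istd <- 2^L_istd          # not rounded: exact efficiency recovery
  meta_istd <- data.frame(mz = stats::runif(nI, 100, 900),
                          rt = stats::runif(nI, 5, 26),
                          snr = rep(1000, nI),
                          iso = stats::runif(nI, 0.02, 0.24))

  ## ---- planted split pairs ------------------------------------------
  eligible <- setdiff(which(!is.na(iso)), c(contaminants, low_rt, low_snr))
  n_dup <- round(cfg$split_frac_duplicate * G)
  n_alt <- round(cfg$split_frac_alternating * G)
  if (n_dup + n_alt > length(eligible))
    stop("not enough eligible features for the requested split fractions")
  parents <- sample(eligible, n_dup + n_alt)
  dup_parents <- sort(parents[seq_len(n_dup)])
  alt_parents <- sort(parents[n_dup + seq_len(n_alt)])

  twin_meta <- function(p) {
    list(mz = mz[p] * (1 + stats::runif(length(p), -6, 6) * 1e-6),
         rt = pmax(0, rt[p] + stats::runif(length(p), -12, 12) / 60),
         iso = iso[p] * (1 + stats::runif(length(p), -0.15, 0.15)),
         snr = snr[p] * stats::runif(length(p), 0.9, 1.1))
  }
  dup_tm <- twin_meta(dup_parents)
  alt_tm <- twin_meta(alt_parents)

  twin_rows <- matrix(0, n_dup + n_alt, ns)
  for (k in seq_along(dup_parents)) {
    p <- dup_parents[k]
    v <- raw[p, ]
    nz <- intersect(which(v > 0), which(is_ww))
    holes <- sample(nz, min(length(nz), sample.int(3L, 1)))
    v[holes] <- 0               # duplicate: identical values, a few dropouts
    twin_rows[k, ] <- v
  }
  for (k in seq_along(alt_parents)) {
    p <- alt_parents[k]
    full <- raw[p, ]
    m <- stats::rbinom(ns, 1, 0.5)
    shared <- sample.int(ns, 1)  # one sample reported by both members
    twin <- full * (1 - m)
    twin[shared] <- full[shared]
    parent_kept <- full * m
    parent_kept[shared] <- full[shared]
    raw[p, ] <- parent_kept
    twin_rows[n_dup + k, ] <- twin
  }

  ## ---- assemble rows: analytes, ISTDs, twins -------------------------
  features <- data.frame(
    feature_id = seq_len(G + nI + n_dup + n_alt),
    mz = c(mz, meta_istd$mz, dup_tm$mz, alt_tm$mz),
    rt_min = c(rt, meta_istd$rt, dup_tm$rt, alt_tm$rt),
    snr = c(snr, meta_istd$snr, dup_tm$snr, alt_tm$snr),
    isotope_ratio = c(iso, meta_istd$iso, dup_tm$iso, alt_tm$iso))
  ## a small share of non-twin analytes lack an isotope ratio
  iso_na <- sample(setdiff(seq_len(G), c(dup_parents, alt_parents)),
                   round(0.05 * G))
  features$isotope_ratio[iso_na] <- NA_real_

  abundance <- rbind(raw, raw_istd, twin_rows)
  istd_ids <- G + seq_len(nI)
  split_pairs <- data.frame(
    parent_id = c(dup_parents, alt_parents),
    twin_id = G + nI + seq_len(n_dup + n_alt),
    type = rep(c("duplicate", "alternating"), c(n_dup, n_alt)))

  ## ---- separation guarantee ------------------------------------------
  ## redraw m/z until no unplanted pair satisfies all three criteria
  planted_key <- paste(split_pairs$parent_id, split_pairs$twin_id)
  for (iter in 1:60) {
    prs <- candidate_pairs_core(features$mz, features$rt_min,
                                features$isotope_ratio)
    if (nrow(prs)) {
      key <- paste(prs$i, prs$j)
      bad <- prs[!key %in% planted_key, , drop = FALSE]
    } else bad <- prs
    if (!nrow(bad)) break
    ## move the second member of each offending pair (and its twin, so
    ## planted pairs stay intact) to a fresh m/z
    redo <- unique(bad$j)
    for (id in redo) {
      newmz <- stats::runif(1, 85, 950)
      features$mz[id] <- newmz
      hit <- which(split_pairs$parent_id == id)
      if (length(hit))
        features$mz[split_pairs$twin_id[hit]] <-
          newmz * (1 + stats::runif(1, -6, 6) * 1e-6)
      hit <- which(split_pairs$twin_id == id)
      if (length(hit))
        features$mz[id] <- features$mz[split_pairs$parent_id[hit]] *
          (1 + stats::runif(1, -6, 6) * 1e-6)
    }
    if (iter == 60)
      stop("could not separate unplanted feature pairs; ",
           "lower the split fractions or n_features")
  }

  table <- feature_table(features, samples, abundance, scale_tag = "raw")
  truth <- list(
    batch = list(levels = batches, common = common, sensitivity = sens,
                 idiosyncratic = idio, delta = delta,
                 total_additive = outer(sens, common) + idio),
    efficiency = eff,
    month_effects = month_eff,
    site_effects = site_eff,
    split_pairs = split_pairs,
    istd_ids = istd_ids,
    contaminant_ids = contaminants,
    low_rt_ids = low_rt,
    low_snr_ids = low_snr,
    class = cls,
    base_log2 = mu)
  list(table = table, truth = truth)
}
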