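# Independent oracle implementations used to validate the package's
# computational paths. These deliberately use the most literal, brute
# force formulation of each definition.

# --- tiny FeatureTable builders --------------------------------------

tiny_table <- function(abundance, mz = NULL, rt = NULL, snr = NULL,
                       iso = NULL, roles = NULL, months = NULL,
                       sites = NULL, batches = NULL, scale_tag = "raw") {
  G <- nrow(abundance); S <- ncol(abundance)
  if (is.null(roles)) roles <- rep("wastewater", S)
  if (is.null(months)) {
    mo <- c("May", "June", "July", "August", "September", "November",
            "January")
    months <- ifelse(roles == "wastewater", rep_len(mo, S), NA)
  }
  if (is.null(sites))
    sites <- ifelse(roles == "wastewater",
                    paste0("S", cumsum(roles == "wastewater")), NA)
  if (is.null(batches)) batches <- rep(NA_integer_, S)
  features <- data.frame(
    feature_id = seq_len(G),
    mz = if (is.null(mz)) 100 + seq_len(G) else mz,
    rt_min = if (is.null(rt)) 5 + seq_len(G) / 10 else rt,
    snr = if (is.null(snr)) rep(100, G) else snr,
    isotope_ratio = if (is.null(iso)) rep(0.1, G) else iso)
  samples <- data.frame(
    sample_id = paste0("smp", seq_len(S)), role = roles,
    site = sites, month = months, batch = batches)
  feature_table(features, samples, abundance, scale_tag = scale_tag)
}

table2_path <- function() {
  system.file("extdata", "table2_example.tsv", package = "ntabatch")
}
table2_ann_path <- function() {
  system.file("extdata", "table2_annotation.tsv", package = "ntabatch")
}

# --- brute-force candidate pairs -------------------------------------

oracle_pairs <- function(features, rt_tol_s = 15, mz_ppm = 10,
                         iso_cv = 0.20) {
  n <- nrow(features)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    f1 <- features[i, ]; f2 <- features[j, ]
    if (is.na(f1$isotope_ratio) || is.na(f2$isotope_ratio)) next
    ppm <- abs(f1$mz - f2$mz) / mean(c(f1$mz, f2$mz)) * 1e6
    cv <- sd(c(f1$isotope_ratio, f2$isotope_ratio)) /
      mean(c(f1$isotope_ratio, f2$isotope_ratio))
    if (abs(f1$rt_min - f2$rt_min) * 60 <= rt_tol_s && ppm <= mz_ppm &&
        is.finite(cv) && cv <= iso_cv)
      out <- rbind(out, data.frame(id_a = f1$feature_id,
                                   id_b = f2$feature_id))
  }
  if (is.null(out)) data.frame(id_a = integer(), id_b = integer()) else out
}

# --- brute-force BH step-up ------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (k in (n - 1):1) adj[k] <- min(adj[k], adj[k + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# --- balanced one-way ANOVA closed form ------------------------------

oracle_anova_vc <- function(y, g) {
  g <- factor(g)
  n_per <- as.vector(table(g))
  stopifnot(length(unique(n_per)) == 1)
  n <- n_per[1]
  means <- tapply(y, g, mean)
  msb <- n * sum((means - mean(y))^2) / (nlevels(g) - 1)
  msw <- sum((y - means[g])^2) / (length(y) - nlevels(g))
  c(factor = max(0, (msb - msw) / n), residual = msw, msb = msb)
}

# --- brute-force silhouette ------------------------------------------

oracle_silhouette <- function(X, cl) {
  D <- as.matrix(dist(X))
  s <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# --- brute-force Ward (D2) agglomeration -----------------------------
# Lance-Williams update on distances; returns merge heights in order and
# the partition after each merge (as canonical label vectors).

oracle_ward <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(n - 1)
  partitions <- list()
  cl <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      if (D[a, b] < best[1] - 1e-12) best <- c(D[a, b], a, b)
    }
    a <- best[2]; b <- best[3]
    heights[step] <- best[1]
    for (k in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nk <- sizes[k]
      D[a, k] <- D[k, a] <- sqrt(
        ((na + nk) * D[a, k]^2 + (nb + nk) * D[b, k]^2 -
           nk * D[a, b]^2) / (na + nb + nk))
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
    cl[members[[a]]] <- min(members[[a]])
    partitions[[step]] <- canonical_labels(cl)
  }
  list(heights = heights, partitions = partitions)
}

canonical_labels <- function(cl) as.integer(factor(cl, levels = unique(cl)))

same_partition <- function(a, b) {
  all(canonical_labels(a) == canonical_labels(b))
}

# --- independent moment-matching eBayes oracle -----------------------
# Estimates the prior df d0 and prior variance s02 from the ensemble of
# residual variances by matching moments of log s^2 under the scaled-F
# model (digamma/trigamma equations), then forms posterior variances and
# moderated t for a two-group contrast.

oracle_trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (k in 1:100) {
    f <- trigamma(x) - y
    x_new <- x - f / psigamma(x, 2)
    if (abs(x_new - x) < 1e-12 * x) { x <- x_new; break }
    x <- x_new
  }
  x
}

oracle_moderated_t <- function(Y, g, level_a, level_b) {
  g <- factor(g)
  G <- nrow(Y)
  d <- ncol(Y) - nlevels(g)
  means <- t(apply(Y, 1, function(y) tapply(y, g, mean)))
  s2 <- vapply(seq_len(G), function(i)
    sum((Y[i, ] - means[i, g])^2) / d, numeric(1))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * oracle_trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else
    rep(s02, G)
  na <- sum(g == level_a); nb <- sum(g == level_b)
  est <- means[, level_a] - means[, level_b]
  tmod <- est / sqrt(s2post * (1 / na + 1 / nb))
  df_total <- min(d0 + d, G * d)
  list(d0 = d0, s02 = s02, s2post = s2post, t = tmod,
       p = 2 * pt(-abs(tmod), df_total))
}
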