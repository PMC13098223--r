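# Community-level statistics over an abundance matrix (rows = samples,
# columns = vOTUs). Presence means abundance strictly > 0 after breadth
# filtering.

as_sample_matrix <- function(x, slot = "composition") {
  if (inherits(x, "abundance_matrix")) return(x[[slot]])
  if (is.matrix(x)) return(x)
  stop2("expected an abundance_matrix or a samples x vOTU matrix")
}

#' Observed vOTU richness per sample
#'
#' @param x An `abundance_matrix` or samples x vOTU matrix.
#' @return Named integer vector of per-sample counts of vOTUs with
#'   abundance > 0.
#' @export
richness <- function(x) {
  m <- as_sample_matrix(x)
  rowSums(m > 0)
}

#' Core virome size per group and prevalence threshold
#'
#' Prevalence of each vOTU is computed within each group only (samples of
#' other groups are excluded); the core count at a threshold is the number
#' of vOTUs present in at least that fraction of the group's samples.
#'
#' @param x An `abundance_matrix` or samples x vOTU matrix.
#' @param groups Per-sample group labels (e.g. gut region).
#' @param thresholds Prevalence fractions.
#' @return A `data.table` with `group`, `threshold`, `n_core`.
#' @export
core_virome <- function(x, groups, thresholds = c(0.25, 0.50, 0.75)) {
  m <- as_sample_matrix(x)
  if (length(groups) != nrow(m))
    stop2("groups must have one label per sample")
  rows <- list()
  for (g in unique(groups)) {
    prev <- colMeans(m[groups == g, , drop = FALSE] > 0)
    for (thr in thresholds)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        group = g, threshold = thr, n_core = sum(prev >= thr))
  }
  data.table::rbindlist(rows)
}

#' Prevalence of each vOTU within groups
#'
#' Presence is at least one detection (abundance > 0) in the sample.
#'
#' @param x An `abundance_matrix` or samples x vOTU matrix.
#' @param groups Per-sample group labels.
#' @return A `data.table` with `group`, `votu`, `n_present`, `n_samples`,
#'   `prevalence`.
#' @export
prevalence_table <- function(x, groups) {
  m <- as_sample_matrix(x)
  rows <- lapply(unique(groups), function(g) {
    sub <- m[groups == g, , drop = FALSE] > 0
    data.table::data.table(group = g, votu = colnames(m),
                           n_present = colSums(sub),
                           n_samples = nrow(sub),
                           prevalence = colMeans(sub))
  })
  data.table::rbindlist(rows)
}

#' Species accumulation curve (random permutations)
#'
#' For each of `n_perm` random orderings of the samples, counts the
#' cumulative number of distinct vOTUs after each added sample; reports
#' the mean and standard deviation across permutations at each step. The
#' final value always equals the total number of distinct vOTUs.
#'
#' @param x An `abundance_matrix` or samples x vOTU matrix.
#' @param n_perm Number of sample-order permutations (default 1000).
#' @param seed Integer seed.
#' @return An `accumulation_curve` data.table with `sites`, `mean`, `sd`.
#' @export
accumulation_curve <- function(x, n_perm = 1000L, seed = 1L) {
  m <- as_sample_matrix(x) > 0
  n <- nrow(m)
  if (n < 2L) stop2("accumulation needs at least 2 samples")
  with_seed(seed, {
    acc <- matrix(0L, n_perm, n)
    for (p in seq_len(n_perm)) {
      o <- sample.int(n)
      seen <- matrixStats_colCummax(m[o, , drop = FALSE])
      acc[p, ] <- rowSums(seen)
    }
    out <- data.table::data.table(
      sites = seq_len(n),
      mean = colMeans(acc),
      sd = apply(acc, 2L, sd))
    data.table::setattr(out, "class",
                        c("accumulation_curve", class(out)))
    out
  })
}

# cumulative "any seen so far" per column, returned as the same matrix
matrixStats_colCummax <- function(m) {
  apply(m, 2L, cummax) > 0
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over vOTUs. Two samples
#' with disjoint support are at distance 1; a pair of all-zero samples is
#' defined to be at distance 0.
#'
#' @param x An `abundance_matrix` or samples x vOTU matrix (nonnegative).
#' @return A symmetric samples x samples distance matrix.
#' @export
bray_curtis <- function(x) {
  m <- as_sample_matrix(x)
  if (any(m < 0)) stop2("Bray-Curtis requires nonnegative abundances")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
  }
  d
}

#' One-way PERMANOVA on a distance matrix
#'
#' Distance-based multivariate ANOVA: with squared distances `d2`,
#' `SS_total = sum_{i<j} d2_ij / n`, `SS_within` sums within-group pairs
#' scaled by group size, `SS_between = SS_total - SS_within`,
#' `pseudo-F = (SS_B / (k - 1)) / (SS_W / (n - k))` and
#' `R^2 = SS_B / SS_total`. The p-value is the permutation tail
#' probability `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under free
#' permutation of group labels, so the minimum attainable p is
#' `1 / (1 + n_perm)`.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param groups Per-sample labels; at least 2 groups with >= 2 samples.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return A `permanova_result` list: `pseudo_F`, `R2`, `p`, `n_perm`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(groups) != n) stop2("one group label per sample required")
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop2("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2L))
    stop2("every group needs at least 2 samples (group '",
          names(sizes)[sizes < 2L][1L], "' has ", min(sizes), ")")
  d2 <- d^2
  k <- length(sizes)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_w <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) / length(idx)
    }
    s
  }
  f_stat <- function(lab) {
    ssw <- ss_w(lab)
    ssb <- ss_total - ssw
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_stat(groups)
  ssw_obs <- ss_w(groups)
  with_seed(seed, {
    exceed <- 0L
    for (p in seq_len(n_perm))
      if (f_stat(sample(groups)) >= f_obs) exceed <- exceed + 1L
    structure(list(pseudo_F = f_obs,
                   R2 = (ss_total - ssw_obs) / ss_total,
                   p = (1 + exceed) / (1 + n_perm),
                   n_perm = n_perm,
                   ss_between = ss_total - ssw_obs,
                   ss_within = ssw_obs,
                   ss_total = ss_total),
              class = "permanova_result")
  })
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix (Gower centring) and
#' eigendecomposes it. Axes are ordered by eigenvalue; negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported, and coordinates are returned for positive
#' axes only.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return A list with `points` (samples x axes) and `eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  G <- -0.5 * d^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))   # second sweep restores the grand mean
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > sqrt(.Machine$double.eps) * max(abs(e$values))
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = e$values)
}

#' Pairwise Wilcoxon and Kruskal-Wallis rank tests
#'
#' Kruskal-Wallis across all groups and two-sided Wilcoxon rank-sum tests
#' for every group pair, reported raw and Holm-adjusted.
#'
#' @param values Numeric vector.
#' @param groups Per-value group labels (>= 2 groups).
#' @return A list with `kruskal` (statistic, df, p) and `pairwise`
#'   (`data.table` of group pairs with `W`, `p`, `p_holm`).
#' @export
rank_tests <- function(values, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) < 2L) stop2("rank tests need at least 2 groups")
  kw <- stats::kruskal.test(values, factor(groups))
  pairs <- utils::combn(gl, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    wt <- suppressWarnings(stats::wilcox.test(values[groups == a],
                                              values[groups == b]))
    data.table::data.table(group_a = a, group_b = b,
                           W = unname(wt$statistic), p = wt$p.value)
  })
  tab <- data.table::rbindlist(rows)
  tab[, p_holm := stats::p.adjust(p, method = "holm")]
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = tab[])
}

#' Aggregate vOTU abundances by predicted host taxon
#'
#' Sums per-sample abundances over vOTUs sharing a host taxon at the
#' requested rank; vOTUs without a prediction are pooled as `no_host`.
#' Per-sample totals are conserved.
#'
#' @param x An `abundance_matrix` or samples x vOTU matrix.
#' @param host_table Host table (`genome_id`, `host_family`, `host_genus`).
#' @param rank `"family"` or `"genus"`.
#' @return A samples x host-taxon matrix.
#' @export
host_group_abundance <- function(x, host_table, rank = c("family", "genus")) {
  rank <- match.arg(rank)
  m <- as_sample_matrix(x)
  host <- data.table::as.data.table(host_table)
  col <- paste0("host_", rank)
  tax <- setNames(host[[col]], host$genome_id)[colnames(m)]
  tax[is.na(tax)] <- "no_host"
  t(rowsum(t(m), group = tax))
}

#' Drop vOTUs detected in fewer than a minimum number of samples
#'
#' Optional pre-step before ordination or PERMANOVA to remove very rare
#' vOTUs (e.g. present in fewer than 10 samples) whose presence noise can
#' dominate a dissimilarity.
#'
#' @param x A samples x vOTU matrix.
#' @param min_samples Minimum number of samples a vOTU must be present in.
#' @return The filtered matrix.
#' @export
filter_by_prevalence <- function(x, min_samples = 10L) {
  m <- as_sample_matrix(x)
  m[, colSums(m > 0) >= min_samples, drop = FALSE]
}

#' Negative binomial richness model (breed x diet)
#'
#' Fits `richness ~ breed * diet` with a negative binomial GLM (log link,
#' dispersion estimated by maximum likelihood via [MASS::glm.nb]);
#' reports Wald tests per coefficient. If the dispersion estimate
#' diverges (counts effectively Poisson), the model falls back to a
#' Poisson GLM with a warning.
#'
#' @param richness Integer per-sample richness counts.
#' @param breed,diet Factors (>= 2 levels each).
#' @return A list with `coefficients` (`data.table`: term, estimate, se,
#'   z, p), `theta`, `family` and the fitted `model`.
#' @export
nb_richness_model <- function(richness, breed, diet) {
  if (any(richness < 0) || any(richness != round(richness)))
    stop2("richness must be nonnegative integer counts")
  breed <- factor(breed); diet <- factor(diet)
  if (nlevels(breed) < 2L || nlevels(diet) < 2L)
    stop2("breed and diet each need at least 2 levels")
  df <- data.frame(richness = as.integer(richness), breed = breed,
                   diet = diet)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(richness ~ breed * diet, data = df)),
    error = function(e) NULL)
  fam <- "negative_binomial"
  theta <- NA_real_
  if (is.null(fit) || !fit$converged || fit$theta > 1e5) {
    if (!is.null(fit) && fit$theta > 1e5)
      warning("dispersion estimate diverged; falling back to Poisson")
    if (is.null(fit)) {
      warning("negative binomial fit failed; falling back to Poisson")
    }
    fit <- stats::glm(richness ~ breed * diet, data = df,
                      family = stats::poisson())
    fam <- "poisson"
  } else {
    theta <- fit$theta
  }
  cf <- summary(fit)$coefficients
  list(coefficients = data.table::data.table(
    term = rownames(cf), estimate = cf[, 1L], se = cf[, 2L],
    z = cf[, 3L], p = cf[, 4L]),
    theta = theta, family = fam, model = fit)
}
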