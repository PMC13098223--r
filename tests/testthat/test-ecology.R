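pm <- function(v, nr) matrix(v, nrow = nr,
                             dimnames = list(paste0("s", seq_len(nr)), NULL))

test_that("richness counts vOTUs with nonzero abundance", {
  m <- rbind(s1 = c(0, 0, 0), s2 = c(0.1, 0.2, 0.3), s3 = c(0.5, 0, 0))
  expect_identical(unname(richness(m)), c(0, 3, 1))
})

test_that("core virome counts per group and threshold", {
  m <- rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 0), s3 = c(1, 0, 0),
             s4 = c(0, 0, 1))
  colnames(m) <- c("v1", "v2", "v3")
  groups <- c("ileum", "ileum", "ileum", "caeca")
  cv <- core_virome(m, groups)
  ileum <- cv[cv$group == "ileum"]
  # vOTU1 prevalence 1 (all thresholds), vOTU2 1/3, vOTU3 0
  expect_identical(ileum$n_core, c(2L, 1L, 1L))
  caeca <- cv[cv$group == "caeca"]
  expect_identical(caeca$n_core, c(1L, 1L, 1L))

  pt <- prevalence_table(m, groups)
  expect_equal(pt[pt$group == "ileum" & pt$votu == "v1"]$prevalence, 1)
  expect_equal(pt[pt$group == "ileum" & pt$votu == "v2"]$prevalence, 1 / 3)
  expect_true(all(pt$prevalence >= 0 & pt$prevalence <= 1))
})

test_that("planted core prevalence lands at the right thresholds", {
  set.seed(19)
  n <- 40
  m <- matrix(rbinom(n * 30, 1, 0.05), n, 30)
  m[, 1] <- rbinom(n, 1, 0.6)   # planted core vOTU at prevalence 0.6
  colnames(m) <- paste0("v", 1:30)
  rownames(m) <- paste0("s", 1:n)
  cv <- core_virome(m, rep("ileum", n))
  at <- function(thr) cv$n_core[cv$threshold == thr]
  expect_gte(at(0.25), 1L)
  expect_gte(at(0.50), 1L)
  expect_identical(at(0.75), 0L)
})

test_that("accumulation curve matches closed forms and the exact mean", {
  # identical samples: flat after the first step
  ident <- pm(rep(1, 4 * 5), 4)
  ac <- accumulation_curve(ident, n_perm = 20, seed = 1)
  expect_equal(ac$mean, rep(5, 4))
  expect_equal(ac$sd, rep(0, 4))

  # disjoint samples of 5 vOTUs each: exactly 5k at step k
  disj <- matrix(0, 4, 20, dimnames = list(paste0("s", 1:4), NULL))
  for (i in 1:4) disj[i, ((i - 1) * 5 + 1):(i * 5)] <- 1
  ac2 <- accumulation_curve(disj, n_perm = 50, seed = 2)
  expect_equal(ac2$mean, c(5, 10, 15, 20))
  expect_equal(ac2$sd, rep(0, 4))

  # exact expectation by permutation enumeration (4 samples, 24 orders)
  set.seed(20)
  pres <- matrix(rbinom(4 * 15, 1, 0.4) > 0, 4, 15)
  rownames(pres) <- paste0("s", 1:4)
  exact <- exact_accumulation(pres)
  ac3 <- accumulation_curve(pres, n_perm = 3000, seed = 3)
  expect_true(all(abs(ac3$mean - exact) < 0.15))
  expect_equal(ac3$mean[4], sum(colSums(pres) > 0))
  expect_error(accumulation_curve(pres[1, , drop = FALSE]), "2 samples")
})

test_that("accumulation final value equals total distinct vOTUs per seed", {
  set.seed(21)
  for (s in 1:5) {
    m <- matrix(rbinom(6 * 40, 1, 0.2), 6, 40)
    rownames(m) <- paste0("s", 1:6)
    ac <- accumulation_curve(m, n_perm = 30, seed = s)
    expect_equal(ac$mean[6], sum(colSums(m) > 0))
    expect_equal(ac$sd[6], 0)
  }
})

test_that("Bray-Curtis matches closed forms and the vegan oracle", {
  m <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0.5, 0), s3 = c(0, 0, 1))
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  expect_equal(d, t(d))
  set.seed(22)
  r <- pm(runif(10 * 25), 10)
  expect_lt(max(abs(bray_curtis(r) -
                      as.matrix(vegan::vegdist(r, "bray")))), 1e-12)
  expect_error(bray_curtis(pm(c(-1, rep(1, 19)), 4)), "nonnegative")
})

test_that("PERMANOVA matches the vegan oracle on F and R2", {
  set.seed(23)
  m <- pm(runif(15 * 30), 15)
  grp <- rep(c("A", "B", "C"), each = 5)
  d <- bray_curtis(m)
  mine <- permanova(d, grp, n_perm = 99, seed = 4)
  ref <- vegan::adonis2(stats::as.dist(d) ~ grp, permutations = 99)
  expect_lt(abs(mine$pseudo_F - ref$F[1]), 1e-10)
  expect_lt(abs(mine$R2 - ref$R2[1]), 1e-10)
  expect_true(mine$R2 >= 0 && mine$R2 <= 1)
})

test_that("maximal separation attains the minimum permutation p", {
  m <- matrix(0, 20, 20, dimnames = list(paste0("s", 1:20), NULL))
  m[1:10, 1:10] <- matrix(runif(100, 0.5, 1), 10)
  m[11:20, 11:20] <- matrix(runif(100, 0.5, 1), 10)
  d <- bray_curtis(m)
  r <- permanova(d, rep(c("A", "B"), each = 10), n_perm = 999, seed = 5)
  expect_equal(r$p, 0.001)
  expect_gt(r$R2, 0.5)
})

test_that("PERMANOVA errors on degenerate group structure", {
  d <- bray_curtis(pm(runif(4 * 6), 4))
  expect_error(permanova(d, c("A", "A", "A", "B")), "at least 2 samples")
  expect_error(permanova(d, rep("A", 4)), "at least 2 groups")
})

test_that("PERMANOVA p is invariant to consistent sample reordering", {
  set.seed(24)
  m <- pm(runif(12 * 20), 12)
  grp <- rep(c("A", "B"), each = 6)
  d <- bray_curtis(m)
  r1 <- permanova(d, grp, n_perm = 199, seed = 6)
  o <- sample(12)
  r2 <- permanova(d[o, o], grp[o], n_perm = 199, seed = 6)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$R2, r2$R2)
})

test_that("PCoA recovers planted geometry up to rotation", {
  set.seed(25)
  X <- matrix(rnorm(8 * 2), 8, 2)
  d <- as.matrix(stats::dist(X))
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  p <- pcoa(d)
  expect_identical(ncol(p$points), 2L)
  Y <- p$points
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sv <- svd(t(Yc) %*% Xc)
  rot <- sv$u %*% t(sv$v)
  expect_lt(max(abs(Yc %*% rot - Xc)), 1e-8)
  # eigenvalues match classical scaling
  cs <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  expect_lt(max(abs(p$eigenvalues - cs$eig)), 1e-10)
})

test_that("PCoA handles symmetry and duplicates", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- paste0("s", 1:3)
  p3 <- pcoa(d3)
  pos <- p3$eigenvalues[p3$eigenvalues > 1e-12]
  expect_equal(pos[1], pos[2])
  # duplicated sample lands on identical coordinates
  set.seed(26)
  m <- pm(runif(5 * 10), 5)
  m <- rbind(m, s6 = m["s3", ])
  p <- pcoa(bray_curtis(m))
  expect_lt(max(abs(p$points["s3", ] - p$points["s6", ])), 1e-10)
})

test_that("rank tests flag separation and behave under ties", {
  v <- c(1:5, 10:14)
  g <- rep(c("lo", "hi"), each = 5)
  r <- rank_tests(v, g)
  expect_identical(nrow(r$pairwise), 1L)
  expect_identical(unname(r$pairwise$W), 25)  # hi entirely above lo
  expect_equal(r$pairwise$p, 2 / choose(10, 5))  # exact two-sided tail
  expect_lt(r$kruskal$p, 0.05)

  # identical distributions in both groups: no evidence of a shift
  same <- rank_tests(rep(c(1, 2, 3), 4), rep(c("a", "b"), each = 6))
  expect_equal(same$pairwise$p, 1)

  set.seed(27)
  v3 <- sample(1:4, 30, TRUE)
  g3 <- rep(c("a", "b", "c"), each = 10)
  r3 <- rank_tests(v3, g3)
  expect_identical(nrow(r3$pairwise), 3L)
  expect_true(all(r3$pairwise$p_holm >= r3$pairwise$p))
  expect_error(rank_tests(1:5, rep("a", 5)), "2 groups")
})

test_that("host-group aggregation conserves totals and pools no_host", {
  m <- rbind(s1 = c(0.1, 0.2, 0.3), s2 = c(0.4, 0, 0.1))
  colnames(m) <- c("v1", "v2", "v3")
  host <- data.frame(genome_id = c("v1", "v2", "v3"),
                     host_family = c("Lactobacillaceae",
                                     "Lactobacillaceae", NA),
                     host_genus = c("Lactobacillus", "Ligilactobacillus",
                                    NA))
  hg <- host_group_abundance(m, host, "family")
  expect_equal(unname(hg[, "Lactobacillaceae"]), c(0.3, 0.4))
  expect_equal(unname(hg[, "no_host"]), c(0.3, 0.1))
  expect_equal(rowSums(hg), rowSums(m))
  hgg <- host_group_abundance(m, host, "genus")
  expect_identical(ncol(hgg), 3L)

  all_na <- host; all_na$host_family <- NA
  hg2 <- host_group_abundance(m, all_na, "family")
  expect_identical(colnames(hg2), "no_host")
  expect_equal(unname(hg2[, 1]), unname(rowSums(m)))
})

test_that("planted richness gradients are detected by rank tests", {
  set.seed(28)
  detected <- 0L
  for (r in 1:40) {
    rich_a <- rpois(12, 40)    # high-richness region
    rich_b <- rpois(12, 25)    # low-richness region
    p <- rank_tests(c(rich_a, rich_b),
                    rep(c("caeca", "ileum"), each = 12))$pairwise$p
    if (p < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 38L)
})

test_that("negative binomial richness model recovers planted effects", {
  sim <- simulate_richness_design(n_per_group = 50, rr_breed = 1.5,
                                  dispersion = 0.2, seed = 29)
  fit <- nb_richness_model(sim$richness, sim$breed, sim$diet)
  expect_identical(fit$family, "negative_binomial")
  b <- fit$coefficients
  expect_lt(b$p[b$term == "breedLSL"], 0.01)
  expect_gt(b$p[b$term == "dietsupp"], 0.05)
  expect_true(is.finite(fit$theta))
  expect_error(nb_richness_model(c(1.5, 2, 3), c("a", "b", "a"),
                                 c("x", "y", "x")), "integer")
})

test_that("prevalence filter drops rare vOTUs only", {
  set.seed(30)
  m <- matrix(rbinom(20 * 50, 1, 0.2), 20, 50)
  colnames(m) <- paste0("v", 1:50)
  rownames(m) <- paste0("s", 1:20)
  f <- filter_by_prevalence(m, min_samples = 5)
  expect_true(all(colSums(f > 0) >= 5))
  expect_true(all(colnames(f) %in% colnames(m)))
})
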