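test_that("grain yield follows the moisture-corrected area formula", {
  expect_equal(grain_yield(312, 3.12, 14), 1.00)
  expect_equal(grain_yield(100, 1, 57) / grain_yield(100, 1, 14), 0.5)
  expect_equal(grain_yield(0, 3.12, 14), 0)
  expect_error(grain_yield(100, 3.12, 100), "moisture")
  expect_error(grain_yield(100, 0, 14), "area")
})

test_that("heritability formula is exact and monotone", {
  expect_equal(heritability(2, var_gy = 2, var_e = 4, t = 2, r = 2), 0.5)
  expect_equal(heritability(3, var_gy = 0, var_e = 0, t = 2, r = 2), 1)
  h <- sapply(c(1, 2, 4), heritability, var_gy = 1, var_e = 2, t = 2, r = 2)
  expect_true(all(diff(h) > 0))                       # increasing in var_g
  h2 <- sapply(c(1, 2, 4), function(e)
    heritability(2, var_gy = 1, var_e = e, t = 2, r = 2))
  expect_true(all(diff(h2) < 0))                      # decreasing in var_e
})

test_that("BLUEs equal genotype means in a noiseless balanced design", {
  plots <- tidyr::expand_grid(genotype = paste0("g", 1:6),
                              trial = c("T1", "T2"), rep = c("1", "2"))
  g_eff <- stats::setNames(1:6, paste0("g", 1:6))
  plots$value <- 10 + g_eff[plots$genotype]
  fit <- suppressWarnings(fit_mixed(plots, "fixed"))
  est <- stats::setNames(fit$estimates$value, fit$estimates$genotype)
  expect_equal(est[paste0("g", 1:6)], 10 + g_eff, tolerance = 1e-6)
})

test_that("BLUPs shrink toward the mean relative to BLUEs", {
  panel <- simulate_panel(300, seed = 1)
  sim <- simulate_breeding_program(panel, n_families = 8, n_lines = 60,
                                   arch = trait_architecture(h2 = 0.5),
                                   n_trials = 2, replication = 1.5, seed = 2)
  blue <- fit_mixed(sim$phenotypes, "fixed")
  blup <- fit_mixed(sim$phenotypes, "random")
  b1 <- stats::setNames(blue$estimates$value, blue$estimates$genotype)
  b2 <- stats::setNames(blup$estimates$value, blup$estimates$genotype)
  ids <- intersect(names(b1), names(b2))
  mu <- mean(b1[ids])
  expect_true(mean(abs(b2[ids] - mu) <= abs(b1[ids] - mu) + 1e-8) > 0.95)
  expect_gt(stats::cor(b1[ids], b2[ids]), 0.9)
})

test_that("variance components are recovered from a sized simulation", {
  panel <- simulate_panel(400, seed = 5)
  sim <- simulate_breeding_program(panel, n_families = 20, n_lines = 200,
                                   arch = trait_architecture(h2 = 0.7),
                                   n_trials = 6, replication = 1.5, seed = 6)
  fit <- fit_mixed(sim$phenotypes, "random")
  vg <- fit$varcomp$variance[fit$varcomp$component == "var_g"]
  ve <- fit$varcomp$variance[fit$varcomp$component == "var_e"]
  expect_lt(abs(vg - sim$truth$var_g) / sim$truth$var_g, 0.35)
  expect_lt(abs(ve - sim$truth$var_e) / sim$truth$var_e, 0.35)
})

test_that("G has unit mean diagonal under HWE and duplicates are identical", {
  set.seed(7)
  p <- stats::runif(800, 0.1, 0.9)
  D <- sapply(p, function(pj) stats::rbinom(120, 2, pj))
  rownames(D) <- sprintf("s%03d", 1:120)
  G <- grm(D)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  D2 <- rbind(D, dup = D[1, ])
  G2 <- grm(D2)
  expect_equal(G2["dup", "dup"], G2["s001", "s001"], tolerance = 1e-12)
  expect_equal(G2["dup", "s001"], G2["s001", "s001"], tolerance = 1e-12)
})

test_that("A-matrix reproduces textbook relationships", {
  ped <- as_pedigree(tibble::tibble(
    id = c("P1", "P2", "S1", "S2", "O"),
    sire = c(NA, NA, "P1", "P1", "S1"),
    dam = c(NA, NA, "P2", "P2", "S2")
  ))
  A <- a_matrix(ped)
  expect_equal(A["P1", "S1"], 0.5)       # parent-offspring
  expect_equal(A["S1", "S2"], 0.5)       # full sibs
  expect_equal(A["O", "O"], 1.25)        # offspring of full sibs is inbred
  founders <- as_pedigree(tibble::tibble(id = c("a", "b", "c"),
                                         sire = NA, dam = NA))
  expect_equal(a_matrix(founders), diag(3), ignore_attr = TRUE)
})

test_that("A-matrix agrees with an independent recursive-kinship oracle", {
  # kinship recursion: phi(i,i) = (1 + phi(s_i, d_i)) / 2,
  # phi(i,j) = (phi(s_i, j) + phi(d_i, j)) / 2 for i later than j; A = 2 phi
  ped <- as_pedigree(tibble::tibble(
    id = c("F1", "F2", "F3", "X", "Y", "Z", "W", "Q"),
    sire = c(NA, NA, NA, "F1", "F1", "X", "Z", "Z"),
    dam = c(NA, NA, NA, "F2", "F2", "Y", "F3", "Y")
  ))
  phi <- function(i, j, s, d) {
    if (is.na(i) || is.na(j)) return(0)
    oi <- match(i, ped$id); oj <- match(j, ped$id)
    if (oi < oj) return(phi(j, i, s, d))
    if (i == j) return((1 + phi(s[[i]], d[[i]], s, d)) / 2)
    (phi(s[[i]], j, s, d) + phi(d[[i]], j, s, d)) / 2
  }
  s <- stats::setNames(as.list(ped$sire), ped$id)
  d <- stats::setNames(as.list(ped$dam), ped$id)
  A <- a_matrix(ped)
  for (i in ped$id) {
    for (j in ped$id) {
      expect_equal(A[i, j], 2 * phi(i, j, s, d), tolerance = 1e-12)
    }
  }
})

test_that("spectral REML matches a grid-search restricted likelihood oracle", {
  set.seed(8)
  n <- 12
  D <- sapply(stats::runif(40, 0.2, 0.8), function(p) stats::rbinom(n, 2, p))
  rownames(D) <- paste0("s", 1:n)
  K <- grm(D)
  u <- drop(chol(K + diag(1e-6, n)) %*% stats::rnorm(n))
  y <- stats::setNames(5 + u + stats::rnorm(n, 0, 0.7), rownames(K))
  fit <- fit_ridge(y, K)
  # oracle: dense grid on log(lambda) with generic matrix algebra
  X1 <- matrix(1, n, 1)
  rll <- function(lam) {
    H <- lam * K + diag(n)
    Hi <- solve(H)
    XtHiX <- drop(t(X1) %*% Hi %*% X1)
    beta <- drop(t(X1) %*% Hi %*% y) / XtHiX
    r <- y - beta
    q <- drop(t(r) %*% Hi %*% r)
    -0.5 * ((n - 1) * log(q) + determinant(H)$modulus + log(XtHiX))
  }
  grid <- exp(seq(-12, 12, length.out = 20001))
  best <- grid[which.max(vapply(grid, rll, 0))]
  expect_equal(log(fit$lambda), log(best), tolerance = 5e-3)
  ratio_fit <- fit$var_u / (fit$var_u + fit$var_e)
  ratio_grid <- best / (best + 1)
  expect_equal(ratio_fit, ratio_grid, tolerance = 1e-3)
})

test_that("ridge GEBVs equal a direct mixed-model-equation solve", {
  set.seed(9)
  n <- 20
  D <- sapply(stats::runif(50, 0.2, 0.8), function(p) stats::rbinom(n, 2, p))
  rownames(D) <- paste0("s", 1:n)
  K <- grm(D)
  y <- stats::setNames(stats::rnorm(n, 10), rownames(K))
  fit <- fit_ridge(y, K)
  lam <- fit$lambda
  V <- lam * K + diag(n)
  alpha <- solve(V, y - fit$mu)
  u_direct <- drop(lam * K %*% alpha)
  expect_equal(unname(fit$gebv - fit$mu), unname(u_direct), tolerance = 1e-6)
})

test_that("ridge recovers breeding values in the noiseless limit and permutes", {
  panel <- simulate_panel(200, seed = 10)
  sim <- simulate_breeding_program(panel, n_families = 6, n_lines = 60,
                                   arch = trait_architecture(h2 = 0.999,
                                                             trial_var = 0,
                                                             rep_var = 0),
                                   n_trials = 1, replication = 1,
                                   pop_model = population_model(
                                     residual_het_rate = 0, missing_rate = 0,
                                     failed_marker_rate = 0),
                                   seed = 11)
  y <- with(sim$phenotypes, stats::setNames(value, genotype))
  y <- y[sim$geno$samples$sample_id]
  G <- grm(sim$geno)
  fit <- fit_ridge(y, G)
  expect_gt(stats::cor(fit$gebv, sim$truth$breeding_values[names(y)]), 0.99)
  perm <- sample(length(y))
  fit2 <- fit_ridge(y[perm], G[names(y)[perm], names(y)[perm]])
  expect_equal(fit2$gebv[names(y)], fit$gebv, tolerance = 1e-6)
})

test_that("Bayesian shrinkage collapses null effects and matches OLS at scale", {
  # pure-noise trait with many more markers than lines: posterior effects
  # must be shrunk far below the per-marker least-squares estimates
  set.seed(12)
  n <- 100; m <- 1000
  X <- matrix(stats::rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(paste0("s", 1:n), paste0("m", 1:m)))
  y <- stats::setNames(stats::rnorm(n), rownames(X))   # pure noise
  Xc <- scale(X, scale = FALSE)
  ols <- drop(crossprod(Xc, y - mean(y))) / colSums(Xc^2)
  for (fam in c("bayes_a", "bayes_b", "bayes_c", "bayes_l")) {
    fit <- fit_bayes(y, X, fam, niter = 2000, burn = 500, seed = 13)
    expect_lt(mean(abs(fit$effects$effect)), 0.1 * mean(abs(ols)))
  }
  # single informative marker: posterior within 2 posterior SDs of OLS
  X1 <- X[, 1, drop = FALSE]
  y1 <- stats::setNames(0.8 * X1[, 1] + stats::rnorm(n, 0, 0.5), rownames(X))
  fit1 <- fit_bayes(y1, X1, "bayes_a", niter = 4000, burn = 1000, seed = 14)
  ols1 <- stats::coef(stats::lm(y1 ~ X1[, 1]))[2]
  expect_lt(abs(fit1$effects$effect - ols1), 2 * fit1$effects$sd + 0.05)
  # seeded chains are reproducible
  f_a <- fit_bayes(y1, X1, "bayes_l", niter = 500, burn = 100, seed = 15)
  f_b <- fit_bayes(y1, X1, "bayes_l", niter = 500, burn = 100, seed = 15)
  expect_identical(f_a$effects$effect, f_b$effects$effect)
  expect_identical(f_a$varE_trace, f_b$varE_trace)
})

test_that("two-kernel RKHS predicts held-out lines and is seed-stable", {
  panel <- simulate_panel(400, seed = 16)
  sim <- simulate_breeding_program(panel, n_families = 15, n_lines = 150,
                                   arch = trait_architecture(h2 = 0.8),
                                   seed = 17)
  fitB <- fit_mixed(sim$phenotypes, "fixed")
  y <- stats::setNames(fitB$estimates$value, fitB$estimates$genotype)
  y <- y[sim$geno$samples$sample_id]
  G <- grm(sim$geno)
  A <- a_matrix(sim$pedigree)[names(y), names(y)]
  # hold out lines spread across families (whole-family holdout would have
  # no informative relatives in training)
  set.seed(99)
  held <- sample(names(y), 30)
  y_tr <- y; y_tr[held] <- NA
  fit <- fit_rkhs(y_tr, list(G = G, A = A), niter = 1500, burn = 500,
                  seed = 18)
  expect_gt(stats::cor(fit$gebv[held], y[held]), 0.4)
  fit2 <- fit_rkhs(y_tr, list(G = G, A = A), niter = 1500, burn = 500,
                   seed = 18)
  expect_identical(fit$gebv, fit2$gebv)
  # with identical kernels the summed fit matches single-kernel GBLUP
  fitGG <- fit_rkhs(y_tr, list(G = G, G2 = G), niter = 3000, burn = 1000,
                    seed = 19)
  fitG <- fit_ridge(y_tr, G)
  expect_gt(stats::cor(fitGG$gebv, fitG$gebv), 0.95)
})

test_that("stratified folds partition samples and balance sizes", {
  set.seed(20)
  fams <- rep(sprintf("F%02d", 1:12), times = sample(1:8, 12, replace = TRUE))
  ids <- sprintf("s%03d", seq_along(fams))
  folds <- stratified_cv(ids, fams, k = 5, repeats = 4, seed = 21)
  for (r in 1:4) {
    fr <- folds[folds$repeat_no == r, ]
    expect_setequal(fr$sample_id, ids)            # partition, no repeats
    expect_equal(anyDuplicated(fr$sample_id), 0)
    sizes <- table(fr$fold)
    expect_lte(max(sizes) - min(sizes), ceiling(12 / 5))
  }
  # family of 5 with k = 5: one member per fold
  f5 <- stratified_cv(paste0("x", 1:5), rep("fam", 5), k = 5, repeats = 1,
                      seed = 2)
  expect_setequal(f5$fold, 1:5)
  expect_identical(stratified_cv(ids, fams, 5, 2, seed = 3),
                   stratified_cv(ids, fams, 5, 2, seed = 3))
  expect_error(stratified_cv(ids[1:3], fams[1:3], k = 5), "exceeds")
})

test_that("predictive ability pools folds per repeat and flags degeneracy", {
  df <- tibble::tibble(observed = rep(stats::rnorm(30), 2),
                       predicted = rep(NA_real_, 60),
                       repeat_no = rep(1:2, each = 30))
  df$predicted <- df$observed                      # oracle model
  pa <- predictive_ability(df)
  expect_equal(pa$mean_r, 1)
  expect_equal(pa$n_repeats, 2)
  df$predicted <- 1
  expect_error(predictive_ability(df), "zero-variance")
})

test_that("ridge and RKHS G+A agree when the pedigree adds nothing", {
  # marker-driven trait with an uninformative pedigree (all lines founders,
  # so A = I): the second kernel carries no signal beyond the residual and
  # the two models' predictive abilities coincide up to MCMC error
  panel <- simulate_panel(300, seed = 22)
  sim <- simulate_breeding_program(panel, n_families = 8, n_lines = 100,
                                   arch = trait_architecture(h2 = 0.8),
                                   seed = 23)
  fitB <- fit_mixed(sim$phenotypes, "fixed")
  y <- stats::setNames(fitB$estimates$value, fitB$estimates$genotype)
  y <- y[sim$geno$samples$sample_id]
  flat_ped <- as_pedigree(tibble::tibble(id = names(y), sire = NA, dam = NA))
  A <- a_matrix(flat_ped)[names(y), names(y)]
  G <- grm(sim$geno)
  # full-data GEBVs of the two families agree when only G carries signal
  fit_r <- fit_ridge(y, G)
  fit_k <- fit_rkhs(y, list(G = G, A = A), niter = 2000, burn = 500,
                    seed = 25)
  expect_gt(stats::cor(fit_r$gebv, fit_k$gebv), 0.95)
  # and cross-validated abilities stay close (the uninformative kernel keeps
  # some prior variance mass, so exact equality is not expected)
  cv <- gs_cross_validate(sim$geno, y, sim$geno$samples$family,
                          models = c("ridge", "rkhs_ga"), ped = flat_ped,
                          k = 5, repeats = 2, niter = 2000, burn = 500,
                          seed = 24)
  r <- stats::setNames(cv$summary$mean_r, cv$summary$model)
  expect_lt(abs(r["ridge"] - r["rkhs_ga"]), 0.1)
})
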