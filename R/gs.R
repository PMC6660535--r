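#' Grain yield in t/ha from plot harvest data
#'
#' `GY = ((100 - MC) / 86) * (weight_g / area_m2) * 0.01`: grain weight is
#' normalized to the harvested area, corrected to 14% moisture (the factor
#' is 1 at MC = 14), and scaled to tonnes per hectare.
#'
#' @param weight_g grain weight (g)
#' @param area_m2 harvested plot area (m^2), default the common 3.12 m^2
#'   sampling area
#' @param mc_pct grain moisture content (percent), must be `< 100`
#' @return yield in t/ha.
#' @export
grain_yield <- function(weight_g, area_m2 = 3.12, mc_pct) {
  if (any(mc_pct >= 100)) stop("moisture content must be < 100%")
  if (any(area_m2 <= 0)) stop("harvested area must be positive")
  ((100 - mc_pct) / 86) * (weight_g / area_m2) * 0.01
}

#' Fit the plot-level mixed model and extract BLUEs or BLUPs
#'
#' Fits `Y_ijk = mu + g_i + t_j + r(t)_jk + e_ijk` by REML. With
#' `genotype_as = "fixed"` the overall mean and genotypes are fixed effects
#' and the per-genotype estimates are BLUEs (adjusted means); with
#' `"random"` all effects except the mean are random and the estimates are
#' BLUPs. `gxt = TRUE` adds a random genotype-by-trial interaction so its
#' variance enters the heritability denominator.
#'
#' @param plots tibble with columns `genotype`, `trial`, `rep`, `value`
#' @param genotype_as `"random"` (BLUPs) or `"fixed"` (BLUEs)
#' @param gxt also fit a genotype-by-trial variance component
#' @return a list of class `mixed_fit`: `estimates` tibble (`genotype`,
#'   `value`), `varcomp` tibble (`component`, `variance`), design means
#'   `t` (trials per genotype) and `r` (plots per genotype per trial), and
#'   the underlying `lme4` fit.
#' @export
fit_mixed <- function(plots, genotype_as = c("random", "fixed"), gxt = FALSE) {
  genotype_as <- match.arg(genotype_as)
  plots <- tibble::as_tibble(plots)
  stopifnot(all(c("genotype", "trial", "rep", "value") %in% names(plots)))
  if (length(unique(plots$genotype)) < 2) stop("need >= 2 genotypes")
  if (any(table(plots$trial) == 0)) stop("empty trial")
  rhs <- "(1 | trial) + (1 | trial:rep)"
  if (gxt) rhs <- paste(rhs, "+ (1 | genotype:trial)")
  if (genotype_as == "random") {
    form <- stats::as.formula(paste("value ~", rhs, "+ (1 | genotype)"))
    fit <- lme4::lmer(form, data = plots, REML = TRUE)
    re <- lme4::ranef(fit)$genotype
    est <- tibble::tibble(genotype = rownames(re),
                          value = lme4::fixef(fit)[["(Intercept)"]] + re[, 1])
  } else {
    form <- stats::as.formula(paste("value ~ 0 + genotype +", rhs))
    fit <- lme4::lmer(form, data = plots, REML = TRUE)
    fe <- lme4::fixef(fit)
    est <- tibble::tibble(genotype = sub("^genotype", "", names(fe)),
                          value = unname(fe))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(
    component = vc$grp, variance = vc$vcov
  ) |>
    dplyr::mutate(component = dplyr::recode(.data$component,
      genotype = "var_g", trial = "var_t", `trial:rep` = "var_rt",
      `genotype:trial` = "var_gt", Residual = "var_e"))
  design <- plots |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(t = dplyr::n_distinct(.data$trial),
                     r = dplyr::n() / dplyr::n_distinct(.data$trial),
                     .groups = "drop")
  structure(
    list(estimates = est, varcomp = varcomp,
         t = mean(design$t), r = mean(design$r),
         genotype_as = genotype_as, fit = fit),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> ", nrow(x$estimates), " genotypes (",
      if (x$genotype_as == "fixed") "BLUEs" else "BLUPs",
      "); t = ", round(x$t, 2), ", r = ", round(x$r, 2), "\n", sep = "")
  print(x$varcomp)
  invisible(x)
}

#' Broad-sense heritability of accession means
#'
#' `H2 = var_g / (var_g + var_gy / t + var_e / (t * r))`, with `t` the mean
#' number of trials per accession and `r` the mean number of plots per
#' accession per trial. When the fitted model omits the genotype-by-trial
#' interaction, `var_gy` defaults to 0.
#'
#' @param x a `mixed_fit` with random genotypes, or the genetic variance
#'   `var_g` (then supply the remaining components explicitly)
#' @param var_gy,var_e,t,r variance components and design means (numeric
#'   interface)
#' @param ... unused
#' @return H-squared in `[0, 1]` (`NA` on a zero denominator).
#' @export
heritability <- function(x, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.default <- function(x, var_gy = 0, var_e, t, r, ...) {
  denom <- x + var_gy / t + var_e / (t * r)
  if (denom <= 0) return(NA_real_)
  x / denom
}

#' @rdname heritability
#' @export
heritability.mixed_fit <- function(x, ...) {
  if (x$genotype_as != "random") {
    stop("heritability needs a fit with random genotypes")
  }
  get_vc <- function(name) {
    v <- x$varcomp$variance[x$varcomp$component == name]
    if (length(v)) v else 0
  }
  heritability.default(get_vc("var_g"), var_gy = get_vc("var_gt"),
                       var_e = get_vc("var_e"), t = x$t, r = x$r)
}

#' Genomic relationship matrix
#'
#' `G = W W' / (2 * sum(p_j (1 - p_j)))` with `W` the column-centered
#' dosage matrix and `p_j` the observed alternate-allele frequencies
#' (VanRaden's first method). Missing dosages are mean-imputed with a
#' message; run [impute_ld_knn()] first for LD-aware imputation.
#' Monomorphic markers are dropped.
#'
#' @param gm a [geno_matrix()] or a numeric dosage matrix
#' @return symmetric positive semidefinite matrix with sample ids as
#'   dimnames.
#' @export
grm <- function(gm) {
  D <- if (inherits(gm, "geno_matrix")) dosage(gm) else as.matrix(gm)
  if (anyNA(D)) {
    message("mean-imputing ", sum(is.na(D)), " missing dosage(s) for G")
    mu <- colMeans(D, na.rm = TRUE)
    for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- mu[j]
  }
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; G undefined")
  D <- D[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(D, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  (G + t(G)) / 2
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' `A_ii = 1 + A_sd / 2` (inbreeding from parental relationship) and
#' `A_ij = (A_js + A_jd) / 2` for `j` preceding `i`; founders are
#' unrelated and non-inbred.
#'
#' @param ped a [as_pedigree()] (topologically ordered)
#' @return symmetric matrix with individual ids as dimnames.
#' @export
a_matrix <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        aij <- 0
        if (!is.na(s)) aij <- aij + A[j, s] / 2
        if (!is.na(d)) aij <- aij + A[j, d] / 2
        A[i, j] <- A[j, i] <- aij
      }
    }
  }
  A
}

#' Ridge-regression GBLUP via spectral REML
#'
#' Fits `y = 1 mu + u + e`, `u ~ N(0, K sigma_u^2)`, by restricted maximum
#' likelihood: after an eigendecomposition of the training kernel the
#' restricted log-likelihood is a one-dimensional function of the variance
#' ratio `lambda = sigma_u^2 / sigma_e^2`, maximized by golden-section
#' search (tolerance 1e-8 on log-lambda). Samples with missing `y` are
#' predicted through the kernel cross-block.
#'
#' @param y named numeric vector; `NA` entries are predicted
#' @param K relationship kernel (e.g. [grm()] or [a_matrix()]) covering all
#'   names of `y`
#' @return a list of class `gblup_fit`: `mu`, `gebv` (named, all samples),
#'   `var_u`, `var_e`, `lambda`, `loglik`.
#' @export
fit_ridge <- function(y, K) {
  stopifnot(!is.null(names(y)), all(names(y) %in% rownames(K)))
  train <- names(y)[!is.na(y)]
  if (length(train) < 3) stop("need >= 3 training observations")
  Kt <- K[train, train]
  eg <- eigen(Kt, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop("kernel is not positive semidefinite")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y[train]))
  ot <- drop(crossprod(U, rep(1, length(train))))
  n <- length(train)
  rll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    o2 <- sum(ot^2 / w)
    beta <- sum(ot * yt / w) / o2
    r <- yt - ot * beta
    q <- sum(r^2 / w)
    -0.5 * ((n - 1) * log(q) + sum(log(w)) + log(o2))
  }
  opt <- stats::optimize(rll, c(-12, 12), maximum = TRUE, tol = 1e-8)
  lam <- exp(opt$maximum)
  w <- lam * d + 1
  o2 <- sum(ot^2 / w)
  beta <- sum(ot * yt / w) / o2
  r <- yt - ot * beta
  var_e <- sum(r^2 / w) / (n - 1)
  var_u <- lam * var_e
  # BLUP(u) on training; predictions via kernel cross-block
  alpha <- U %*% (r * (lam / w))          # = (K + I/lam)^{-1} (y - 1 mu)
  u_train <- drop(Kt %*% alpha)
  gebv <- stats::setNames(rep(NA_real_, length(y)), names(y))
  gebv[train] <- beta + u_train
  test <- setdiff(names(y), train)
  if (length(test)) {
    gebv[test] <- beta + drop(K[test, train, drop = FALSE] %*% alpha)
  }
  structure(list(mu = beta, gebv = gebv, var_u = var_u, var_e = var_e,
                 lambda = lam, loglik = opt$objective),
            class = "gblup_fit")
}

#' Bayesian whole-genome regression
#'
#' Single-site Gibbs samplers for four shrinkage families on marker
#' effects: `"bayes_a"` (per-marker scaled-t via scaled-inverse-chi-squared
#' marker variances), `"bayes_b"` (point-mass/Gaussian-slab mixture with a
#' common slab variance and sampled inclusion probability), `"bayes_c"`
#' (point-mass/scaled-t mixture with per-marker slab variances), and
#' `"bayes_l"` (Bayesian lasso, double-exponential prior via per-marker
#' exponential mixing). Hyperprior defaults: 5 prior degrees of freedom,
#' with scales set from the phenotypic variance under a prior R-squared
#' of 0.5.
#'
#' @param y named numeric vector; `NA` entries are predicted
#' @param X dosage matrix (no missing values), rows covering all names of
#'   `y`
#' @param family one of `"bayes_a"`, `"bayes_b"`, `"bayes_c"`, `"bayes_l"`
#' @param niter,burn,thin chain settings (defaults 12000 / 2000 / 5)
#' @param df0 prior degrees of freedom for the effect-variance hyperpriors
#' @param R2 prior proportion of variance attributed to markers
#' @param pi_init initial (and prior-scale) inclusion probability for the
#'   mixture families
#' @param seed integer seed for the chain
#' @return a list of class `bayes_fit`: `mu`, `effects` tibble
#'   (`marker`, `effect`), `gebv` (named, all samples), `varE`, `pi`,
#'   and `varE_trace` (one value per iteration, for convergence checks;
#'   write it to a text file to inspect it like a residual-variance trace).
#' @export
fit_bayes <- function(y, X, family = c("bayes_a", "bayes_b", "bayes_c", "bayes_l"),
                      niter = 12000, burn = 2000, thin = 5,
                      df0 = 5, R2 = 0.5, pi_init = 0.1, seed = 1L) {
  family <- match.arg(family)
  stopifnot(burn < niter, !is.null(names(y)), all(names(y) %in% rownames(X)))
  if (anyNA(X)) stop("X must be fully imputed")
  train <- names(y)[!is.na(y)]
  set.seed(seed)
  res <- bayes_gibbs_cpp(X[train, , drop = FALSE], y[train],
                         match(family, c("bayes_a", "bayes_b", "bayes_c", "bayes_l")) - 1L,
                         as.integer(niter), as.integer(burn), as.integer(thin),
                         df0, R2, pi_init, 5, 1e-10)
  gebv <- drop(res$mu + X[names(y), , drop = FALSE] %*% res$b)
  names(gebv) <- names(y)
  structure(
    list(mu = res$mu,
         effects = tibble::tibble(marker = colnames(X), effect = res$b,
                                  sd = res$b_sd),
         gebv = gebv, varE = res$varE, pi = res$pi,
         varE_trace = res$varE_trace, family = family,
         settings = list(niter = niter, burn = burn, thin = thin, seed = seed)),
    class = "bayes_fit"
  )
}

#' Two-kernel RKHS regression (e.g. G + A)
#'
#' Gibbs sampler for `y = 1 mu + sum_k u_k + e` with `u_k ~ N(0, K_k
#' sigma_k^2)`: each kernel is eigendecomposed once and its effects updated
#' in the rotated basis, with scaled-inverse-chi-squared priors on all
#' variances (5 prior df, scales from the phenotypic variance at prior
#' R-squared 0.5 split equally across kernels). The genomic-plus-pedigree
#' model passes `list(G = grm(...), A = a_matrix(...))`.
#'
#' @param y named numeric vector; `NA` entries are predicted
#' @param kernels named list of PSD kernels covering all names of `y`
#' @param niter,burn,thin chain settings
#' @param df0,R2 hyperprior df and prior R-squared
#' @param seed integer seed
#' @return a list of class `rkhs_fit`: `mu`, `gebv` (named, sum of kernel
#'   effects plus intercept), `var_k` (posterior-mean kernel variances),
#'   `varE`, `varE_trace`.
#' @export
fit_rkhs <- function(y, kernels, niter = 12000, burn = 2000, thin = 5,
                     df0 = 5, R2 = 0.5, seed = 1L) {
  stopifnot(burn < niter, length(kernels) >= 1, !is.null(names(y)))
  train <- names(y)[!is.na(y)]
  n <- length(train)
  set.seed(seed)
  eig <- lapply(kernels, function(K) {
    stopifnot(all(names(y) %in% rownames(K)))
    eg <- eigen(K[train, train], symmetric = TRUE)
    keep <- eg$values > 1e-8 * max(eg$values)
    list(V = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
  })
  vy <- stats::var(y[train])
  dfE <- 5
  SE <- vy * (1 - R2) * (dfE + 2)
  Sk <- vapply(kernels, function(K) {
    vy * (R2 / length(kernels)) * (df0 + 2) / mean(diag(K[train, train]))
  }, 0)
  alpha <- lapply(eig, function(e) rep(0, length(e$d)))
  var_k <- Sk / (df0 + 2)
  varE <- vy * (1 - R2)
  mu <- mean(y[train])
  u <- lapply(eig, function(e) rep(0, n))
  e_res <- y[train] - mu
  nsave <- 0
  alpha_mean <- lapply(alpha, function(a) a * 0)
  mu_mean <- 0; var_k_mean <- var_k * 0; varE_mean <- 0
  varE_trace <- numeric(niter)
  for (it in seq_len(niter)) {
    mu_new <- stats::rnorm(1, mean(e_res) + mu, sqrt(varE / n))
    e_res <- e_res - (mu_new - mu)
    mu <- mu_new
    for (k in seq_along(eig)) {
      Vk <- eig[[k]]$V; dk <- eig[[k]]$d
      ek <- e_res + u[[k]]
      z <- drop(crossprod(Vk, ek))
      prec <- 1 / varE + 1 / (var_k[k] * dk)
      mean_a <- (z / varE) / prec
      alpha[[k]] <- stats::rnorm(length(dk), mean_a, sqrt(1 / prec))
      u_new <- drop(Vk %*% alpha[[k]])
      e_res <- ek - u_new
      u[[k]] <- u_new
      var_k[k] <- (Sk[k] * df0 + sum(alpha[[k]]^2 / dk)) /
        stats::rchisq(1, df0 + length(dk))
    }
    varE <- (sum(e_res^2) + SE * dfE) / stats::rchisq(1, n + dfE)
    varE_trace[it] <- varE
    if (it > burn && ((it - burn - 1) %% thin == 0)) {
      nsave <- nsave + 1
      mu_mean <- mu_mean + mu
      varE_mean <- varE_mean + varE
      var_k_mean <- var_k_mean + var_k
      for (k in seq_along(alpha)) {
        alpha_mean[[k]] <- alpha_mean[[k]] + alpha[[k]]
      }
    }
  }
  mu_hat <- mu_mean / nsave
  gebv <- stats::setNames(rep(mu_hat, length(y)), names(y))
  for (k in seq_along(kernels)) {
    a_hat <- alpha_mean[[k]] / nsave
    u_train <- drop(eig[[k]]$V %*% a_hat)
    gebv[train] <- gebv[train] + u_train
    test <- setdiff(names(y), train)
    if (length(test)) {
      # project through the kernel cross-block: u_test = K_st K_tt^+ u_train
      Kinv_u <- eig[[k]]$V %*% (a_hat / eig[[k]]$d)
      gebv[test] <- gebv[test] +
        drop(kernels[[k]][test, train, drop = FALSE] %*% Kinv_u)
    }
  }
  structure(list(mu = mu_hat, gebv = gebv,
                 var_k = var_k_mean / nsave, varE = varE_mean / nsave,
                 varE_trace = varE_trace),
            class = "rkhs_fit")
}

#' Family-stratified k-fold assignments
#'
#' Within each family the members are shuffled and dealt round-robin to
#' folds, with the dealing start rotated from family to family so fold
#' sizes stay balanced; every sample lands in exactly one fold per repeat.
#'
#' @param sample_ids character vector
#' @param families family label per sample
#' @param k number of folds (>= 2)
#' @param repeats independent repeats
#' @param seed integer seed
#' @return tibble: `repeat_no`, `fold`, `sample_id`, `family`.
#' @export
stratified_cv <- function(sample_ids, families, k = 5, repeats = 10, seed = 1L) {
  stopifnot(k >= 2, length(sample_ids) == length(families),
            !anyNA(families))
  if (k > length(sample_ids)) stop("k exceeds the number of samples")
  set.seed(seed)
  purrr::map(seq_len(repeats), function(rep_i) {
    start <- 0L
    out <- purrr::map(unique(families), function(fam) {
      members <- sample(sample_ids[families == fam])
      fold <- ((start + seq_along(members) - 1L) %% k) + 1L
      start <<- (start + length(members)) %% k
      tibble::tibble(fold = fold, sample_id = members, family = fam)
    }) |> dplyr::bind_rows()
    dplyr::mutate(out, repeat_no = rep_i, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Predictive ability from pooled cross-validated predictions
#'
#' Per repeat, the predictions of all validation folds are pooled and
#' Pearson-correlated against the observed values; the mean correlation
#' over repeats is the predictive ability.
#'
#' @param df tibble with columns `observed`, `predicted`, `repeat_no`
#' @return a one-row tibble: `mean_r`, `sd_r`, `n_repeats`.
#' @export
predictive_ability <- function(df) {
  rs <- df |>
    dplyr::group_by(.data$repeat_no) |>
    dplyr::summarise(r = {
      if (stats::sd(.data$observed) == 0 || stats::sd(.data$predicted) == 0) {
        stop("zero-variance observations or predictions; correlation undefined")
      }
      stats::cor(.data$observed, .data$predicted)
    }, .groups = "drop")
  tibble::tibble(mean_r = mean(rs$r), sd_r = stats::sd(rs$r),
                 n_repeats = nrow(rs))
}

#' Genomic-prediction cross-validation over a model panel
#'
#' Runs family-stratified k-fold cross-validation for any subset of seven
#' prediction models: `"ridge"` (GBLUP on G), `"bayes_a"`, `"bayes_b"`,
#' `"bayes_c"`, `"bayes_l"` (whole-genome regression on dosages),
#' `"rkhs_ga"` (two-kernel G + A) and `"pedigree_blup"` (BLUP on A).
#' Predictive ability per model is the mean over repeats of the Pearson
#' correlation between observed phenotypes and pooled cross-validated
#' GEBVs.
#'
#' @param gm a [geno_matrix()] (imputed; remaining missing dosages are
#'   mean-imputed) or a complete dosage matrix
#' @param y named numeric phenotype vector (e.g. BLUEs), names matching
#'   sample ids
#' @param families family label per entry of `y`
#' @param models character subset of the seven model names
#' @param ped [as_pedigree()] covering the samples (required for
#'   `rkhs_ga` / `pedigree_blup`)
#' @param k,repeats cross-validation design
#' @param niter,burn,thin chain settings for the Bayesian families
#' @param seed integer seed driving fold assignment and all chains
#' @return a list of class `gs_cv`: `results` tibble (`model`,
#'   `repeat_no`, `r`), `summary` tibble (`model`, `mean_r`, `sd_r`),
#'   `folds` (the assignment tibble).
#' @export
gs_cross_validate <- function(gm, y, families,
                              models = c("ridge", "bayes_a", "bayes_b",
                                         "bayes_c", "bayes_l", "rkhs_ga",
                                         "pedigree_blup"),
                              ped = NULL, k = 5, repeats = 10,
                              niter = 12000, burn = 2000, thin = 5,
                              seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  ids <- names(y)
  stopifnot(!is.null(ids), length(families) == length(y))
  X <- if (inherits(gm, "geno_matrix")) dosage(gm) else as.matrix(gm)
  X <- X[ids, , drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  }
  G <- grm(X)
  A <- NULL
  if (any(models %in% c("rkhs_ga", "pedigree_blup"))) {
    if (is.null(ped)) stop("ped is required for rkhs_ga / pedigree_blup")
    A <- a_matrix(ped)[ids, ids]
  }
  folds <- stratified_cv(ids, families, k = k, repeats = repeats, seed = seed)
  results <- purrr::map(seq_len(repeats), function(rep_i) {
    f_rep <- dplyr::filter(folds, .data$repeat_no == rep_i)
    purrr::map(models, function(mod) {
      pred <- stats::setNames(rep(NA_real_, length(y)), ids)
      for (fold_i in sort(unique(f_rep$fold))) {
        test <- f_rep$sample_id[f_rep$fold == fold_i]
        y_train <- y
        y_train[test] <- NA
        fit_seed <- seed + 1000L * rep_i + 10L * fold_i +
          match(mod, models)
        fit <- switch(
          mod,
          ridge = fit_ridge(y_train, G),
          pedigree_blup = fit_ridge(y_train, A),
          rkhs_ga = fit_rkhs(y_train, list(G = G, A = A), niter = niter,
                             burn = burn, thin = thin, seed = fit_seed),
          fit_bayes(y_train, X, family = mod, niter = niter, burn = burn,
                    thin = thin, seed = fit_seed)
        )
        pred[test] <- fit$gebv[test]
      }
      tibble::tibble(model = mod, repeat_no = rep_i,
                     r = stats::cor(y, pred))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- results |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = stats::sd(.data$r),
                     .groups = "drop")
  structure(list(results = results, summary = summary, folds = folds,
                 settings = list(k = k, repeats = repeats, niter = niter,
                                 burn = burn, thin = thin, seed = seed)),
            class = "gs_cv")
}

#' @export
print.gs_cv <- function(x, ...) {
  cat("<gs_cv> ", x$settings$k, "-fold x ", x$settings$repeats,
      " repeats\n", sep = "")
  print(x$summary)
  invisible(x)
}
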