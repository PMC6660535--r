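#' Pairwise polymorphic-SNP counts and gap statistics
#'
#' For every pair of samples, counts loci where both are non-missing
#' homozygotes with different alleles (the marker set usable in a cross
#' between the pair), and optionally summarises the physical spacing of
#' those loci: median/min/max adjacent gap (bp, within chromosomes) among
#' each pair's polymorphic positions.
#'
#' @param gm a [geno_matrix()]
#' @param groups optional character vector of group labels per sample
#'   (defaults to `sample_info()$subpop`); used for the group-pair summary
#' @param gap_stats compute per-pair gap summaries (quadratic in samples;
#'   disable for very large panels)
#' @return a list of class `pairwise_poly`: `counts` (symmetric matrix,
#'   zero diagonal), `pairs` tibble (`sample_a`, `sample_b`, `group_pair`,
#'   `n_polymorphic`, and when requested `median_gap_bp`, `min_gap_bp`,
#'   `max_gap_bp`), and `by_group` summary tibble.
#' @export
pairwise_polymorphism <- function(gm, groups = NULL, gap_stats = TRUE) {
  if (n_samples(gm) < 2) stop("need >= 2 samples")
  if (is.null(groups)) groups <- gm$samples$subpop
  D <- dosage(gm)
  hom_alt <- (!is.na(D)) & D == 2
  hom_ref <- (!is.na(D)) & D == 0
  counts <- hom_alt %*% t(hom_ref) + hom_ref %*% t(hom_alt)  # symmetric
  diag(counts) <- 0
  storage.mode(counts) <- "double"
  ids <- gm$samples$sample_id
  dimnames(counts) <- list(ids, ids)
  idx <- which(upper.tri(counts), arr.ind = TRUE)
  pairs <- tibble::tibble(
    sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
    group_pair = pair_label(groups[idx[, 1]], groups[idx[, 2]]),
    n_polymorphic = counts[idx]
  )
  if (gap_stats) {
    ord <- order(gm$markers$chrom, gm$markers$pos_bp)
    pos <- gm$markers$pos_bp[ord]
    chrom <- gm$markers$chrom[ord]
    gaps <- matrix(NA_real_, nrow(idx), 3)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      poly <- (hom_alt[i, ord] & hom_ref[j, ord]) |
        (hom_ref[i, ord] & hom_alt[j, ord])
      if (!any(poly)) next
      g <- diff_within_chrom(pos[poly], chrom[poly])
      if (length(g)) {
        gaps[k, ] <- c(stats::median(g), min(g), max(g))
      }
    }
    pairs$median_gap_bp <- gaps[, 1]
    pairs$min_gap_bp <- gaps[, 2]
    pairs$max_gap_bp <- gaps[, 3]
  }
  by_group <- pairs |>
    dplyr::group_by(.data$group_pair) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_polymorphic = mean(.data$n_polymorphic),
      median_polymorphic = stats::median(.data$n_polymorphic),
      q25 = stats::quantile(.data$n_polymorphic, 0.25),
      q75 = stats::quantile(.data$n_polymorphic, 0.75),
      mean_median_gap_bp = if (gap_stats) mean(.data$median_gap_bp, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  structure(list(counts = counts, pairs = pairs, by_group = by_group),
            class = "pairwise_poly")
}

pair_label <- function(a, b) {
  a <- ifelse(is.na(a), "NA", a); b <- ifelse(is.na(b), "NA", b)
  paste(pmin(a, b), pmax(a, b), sep = "x")
}

diff_within_chrom <- function(pos, chrom) {
  unlist(lapply(split(pos, chrom), function(p) if (length(p) > 1) diff(sort(p))),
         use.names = FALSE)
}

#' @export
print.pairwise_poly <- function(x, ...) {
  cat("<pairwise_poly> ", nrow(x$pairs), " pairs\n", sep = "")
  print(x$by_group)
  invisible(x)
}

#' Principal component analysis of genotypes
#'
#' Dosage coding (0/1/2 alternate-allele count), per-marker mean imputation
#' of missing calls, column centering (optional unit scaling), then an
#' eigendecomposition of the sample covariance via [stats::prcomp()].
#' Monomorphic (zero-variance) markers are dropped. A deterministic sign
#' convention is applied: the largest-magnitude loading of each component
#' is positive.
#'
#' @param gm a [geno_matrix()]
#' @param scale. unit-scale markers before decomposition
#' @return a list of class `geno_pca`: `scores` tibble (sample metadata +
#'   `PC1..PCk`), `var_explained` (fractions summing to 1), `loadings`
#'   matrix, `center`, and `preprocessing` record.
#' @export
pca_genotypes <- function(gm, scale. = FALSE) {
  if (n_samples(gm) < 2 || n_markers(gm) < 2) stop("need >= 2 samples and markers")
  D <- dosage(gm)
  mono <- apply(D, 2, function(x) stats::var(x, na.rm = TRUE)) %in% c(0, NA)
  D <- D[, !mono, drop = FALSE]
  if (ncol(D) == 0) stop("no variable markers after removing monomorphic columns")
  mu <- colMeans(D, na.rm = TRUE)
  for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- mu[j]
  pc <- stats::prcomp(D, center = TRUE, scale. = scale.)
  # sign convention: largest |loading| positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(gm$samples, tibble::as_tibble(pc$x))
  structure(
    list(scores = scores, var_explained = ve, loadings = pc$rotation,
         center = pc$center,
         preprocessing = list(coding = "alt-allele dosage 0/1/2",
                              imputation = "per-marker mean",
                              centered = TRUE, scaled = scale.,
                              n_markers_used = ncol(D))),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  ve <- round(100 * x$var_explained[1:min(3, length(x$var_explained))], 1)
  cat("<geno_pca> ", nrow(x$scores), " samples, ",
      x$preprocessing$n_markers_used, " markers | PC1-",
      length(ve), ": ", paste0(ve, "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ward hierarchical clustering of genotypes
#'
#' Agglomerative clustering with Euclidean distances and Ward's
#' minimum-variance criterion, with dissimilarities squared before cluster
#' updating (the Lance-Williams form of the Ward objective). Accepts a
#' genotype matrix (clustered on mean-imputed dosages) or a score matrix.
#'
#' @param x a [geno_matrix()], a `geno_pca`, or a numeric matrix
#' @param n_pcs number of components used when `x` is a `geno_pca`
#' @return an [stats::hclust()] tree with sample labels.
#' @export
ward_cluster <- function(x, n_pcs = 10) {
  M <- cluster_input(x, n_pcs)
  if (anyNA(M)) stop("input contains NA; impute first")
  stats::hclust(stats::dist(M), method = "ward.D2")
}

cluster_input <- function(x, n_pcs = 10) {
  if (inherits(x, "geno_matrix")) {
    D <- dosage(x)
    mu <- colMeans(D, na.rm = TRUE)
    for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- mu[j]
    return(D)
  }
  if (inherits(x, "geno_pca")) {
    k <- min(n_pcs, sum(grepl("^PC", names(x$scores))))
    M <- as.matrix(x$scores[paste0("PC", seq_len(k))])
    rownames(M) <- x$scores$sample_id
    return(M)
  }
  as.matrix(x)
}

#' Export a dendrogram as Newick
#'
#' @param tree an [stats::hclust()] tree
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Pick the number of clusters by average silhouette width
#'
#' Runs k-means (fixed seed, `n_init` restarts) on PCA scores for each
#' candidate `k` and scores the average silhouette width; the best `k` is
#' the argmax, with ties resolved towards the smaller `k`. Scores use the
#' leading components capturing at least `var_cap` of the variance (capped
#' at 10 components). Singleton clusters contribute silhouette 0.
#'
#' @param pca a `geno_pca` (or numeric score matrix)
#' @param k_range integer candidates, all `>= 2` and `< n`
#' @param n_init k-means restarts
#' @param var_cap variance fraction determining how many PCs are used
#' @param seed seed for the k-means restarts
#' @return a list of class `silhouette_scan`: `best_k` and `by_k` tibble
#'   (`k`, `avg_sil_width`).
#' @export
pick_k_silhouette <- function(pca, k_range = 2:10, n_init = 10,
                              var_cap = 0.8, seed = 1L) {
  M <- if (inherits(pca, "geno_pca")) {
    k_use <- min(10, max(2, which(cumsum(pca$var_explained) >= var_cap)[1]))
    cluster_input(pca, n_pcs = k_use)
  } else as.matrix(pca)
  stopifnot(all(k_range >= 2), max(k_range) < nrow(M))
  d <- stats::dist(M)
  widths <- purrr::map_dbl(k_range, function(k) {
    set.seed(seed)
    km <- stats::kmeans(M, centers = k, nstart = n_init)
    sil <- cluster::silhouette(km$cluster, d)
    mean(sil[, "sil_width"])
  })
  by_k <- tibble::tibble(k = k_range, avg_sil_width = widths)
  structure(list(best_k = k_range[which.max(widths)], by_k = by_k),
            class = "silhouette_scan")
}

#' @export
print.silhouette_scan <- function(x, ...) {
  cat("<silhouette_scan> best k =", x$best_k, "\n")
  print(x$by_k)
  invisible(x)
}

#' Classify unlabeled samples from PC coordinates
#'
#' Nearest-centroid assignment in the first two principal components:
#' centroids are computed from the labeled samples of each target group and
#' every unlabeled sample is assigned to the nearer centroid; exact
#' distance ties stay unassigned (`NA`).
#'
#' @param pca a `geno_pca`
#' @param labels named character vector (or `sample_id`-named) of known
#'   group labels for a subset of samples
#' @param groups the target groups (each must have labeled samples)
#' @return tibble: `sample_id`, `group` (existing label or assignment),
#'   `assigned` (logical).
#' @export
classify_undetermined <- function(pca, labels,
                                  groups = unique(stats::na.omit(labels))) {
  sc <- pca$scores
  lab <- labels[sc$sample_id]
  if (any(!groups %in% lab)) {
    stop("no labeled samples for group(s): ",
         paste(setdiff(groups, lab), collapse = ", "))
  }
  M <- as.matrix(sc[c("PC1", "PC2")])
  centroids <- vapply(groups,
                      function(g) colMeans(M[which(lab == g), , drop = FALSE]),
                      numeric(2))
  assigned <- rep(NA_character_, nrow(sc))
  for (i in seq_len(nrow(sc))) {
    if (!is.na(lab[i])) { assigned[i] <- lab[i]; next }
    d <- sqrt(colSums((centroids - M[i, ])^2))
    nearest <- which(d == min(d))
    if (length(nearest) == 1) assigned[i] <- groups[nearest]
  }
  tibble::tibble(sample_id = sc$sample_id, group = assigned,
                 assigned = is.na(lab) & !is.na(assigned))
}
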