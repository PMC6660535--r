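#' Per-marker quality-control statistics
#'
#' For each marker: call rate (called / total samples), heterozygosity
#' (heterozygous calls among successfully called genotypes), and minor
#' allele frequency (over called allele counts). A marker fails when
#' `maf <= min_maf` (LOW_MAF), `het >= max_het` (HIGH_HET) or
#' `call_rate <= min_call_rate` (LOW_CR) — all boundaries inclusive.
#' A marker with zero called samples has `call_rate = 0`, undefined
#' `het`/`maf`, and fails LOW_CR.
#'
#' @param gm a [geno_matrix()]
#' @param min_maf MAF filter boundary (fail at or below)
#' @param max_het heterozygosity boundary (fail at or above)
#' @param min_call_rate call-rate boundary (fail at or below)
#' @return tibble: `marker_id`, `chrom`, `pos_bp`, `call_rate`, `het`,
#'   `maf`, `pass`, `fail_reasons` (comma-separated).
#' @export
marker_qc <- function(gm, min_maf = 0.01, max_het = 0.10,
                      min_call_rate = 0.75) {
  if (n_samples(gm) < 1) stop("need at least one sample")
  D <- dosage(gm)
  n <- n_samples(gm)
  called <- colSums(!is.na(D))
  cr <- called / n
  het <- colSums(D == 1, na.rm = TRUE) / called
  p_alt <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  het[called == 0] <- NA_real_
  maf[called == 0] <- NA_real_
  low_cr <- cr <= min_call_rate
  high_het <- !is.na(het) & het >= max_het
  low_maf <- !is.na(maf) & maf <= min_maf
  reasons <- purrr::pmap_chr(
    list(unname(low_cr), unname(high_het), unname(low_maf)),
    function(a, b, c) paste(c("LOW_CR", "HIGH_HET", "LOW_MAF")[c(a, b, c)],
                            collapse = ",")
  )
  tibble::tibble(
    marker_id = gm$markers$marker_id,
    chrom = gm$markers$chrom,
    pos_bp = gm$markers$pos_bp,
    call_rate = unname(cr), het = unname(het), maf = unname(maf),
    pass = unname(!(low_cr | high_het | low_maf)),
    fail_reasons = reasons
  )
}

#' Drop markers failing QC
#'
#' @param gm a [geno_matrix()]
#' @param qc result of [marker_qc()] on `gm` (recomputed if omitted)
#' @return `gm` restricted to passing markers. Idempotent. When all markers
#'   fail, a valid empty matrix is returned with a warning.
#' @export
filter_markers <- function(gm, qc = marker_qc(gm)) {
  if (!identical(qc$marker_id, gm$markers$marker_id)) {
    stop("qc table is not aligned to the genotype matrix")
  }
  drop <- qc |>
    dplyr::filter(!.data$pass) |>
    tidyr::separate_rows("fail_reasons", sep = ",") |>
    dplyr::count(.data$fail_reasons)
  if (nrow(drop)) {
    message("removing ", sum(!qc$pass), " marker(s): ",
            paste(drop$fail_reasons, drop$n, collapse = ", "))
  }
  if (!any(qc$pass)) warning("all markers failed QC; returning empty matrix")
  gm[, which(qc$pass)]
}

#' Consensus genotypes across replicate runs
#'
#' Collapses replicates of the same accession to one row: at each locus the
#' strict-majority genotype among non-missing replicate calls; ties and
#' all-missing loci give a missing consensus call.
#'
#' @param gm a [geno_matrix()] whose `sample_info()$accession` groups
#'   replicates
#' @return a [geno_matrix()] with one row per accession.
#' @export
consensus_genotype <- function(gm) {
  acc <- gm$samples$accession
  accs <- unique(acc)
  out <- matrix(NA_character_, length(accs), n_markers(gm))
  for (i in seq_along(accs)) {
    rows <- gm$calls[acc == accs[i], , drop = FALSE]
    out[i, ] <- apply(rows, 2, majority_call)
  }
  geno_matrix(out, gm$markers,
              tibble::tibble(sample_id = accs, accession = accs))
}

majority_call <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_character_)
  tab <- table(v)
  top <- tab[tab == max(tab)]
  if (length(top) > 1) return(NA_character_)   # tie
  if (max(tab) * 2 <= length(v)) return(NA_character_)  # not strict majority
  names(top)
}

#' Replicate repeatability
#'
#' Repeatability is `R = 100 - mean(e_l)` in percent, where the per-locus
#' error rate `e_l = m_l / n_l` counts replicate-locus genotypes with at
#' least one allelic mismatch (`m_l`) among all non-missing replicate-locus
#' comparisons (`n_l`) against the accession's reference genotype. The
#' reference genotype is the within-accession consensus ([consensus_genotype()]).
#' Missing calls on either side are excluded from `n_l`; a heterozygote
#' compared to a homozygote counts as a mismatch even though one allele is
#' shared.
#'
#' @param gm replicate [geno_matrix()] (replicates grouped by
#'   `sample_info()$accession`)
#' @param min_reps only accessions with at least this many replicates enter
#' @param drop_hets set replicate heterozygous calls to missing before
#'   comparison (mirrors recomputing repeatability after removing and
#'   imputing heterozygous calls)
#' @return a list of class `repeatability`: `overall_R` (percent),
#'   `mean_e_l` (percent), `per_locus` tibble (`marker_id`, `m_l`, `n_l`,
#'   `e_l`), `per_accession` tibble, `n_accessions`.
#' @export
repeatability <- function(gm, min_reps = 4, drop_hets = FALSE) {
  counts <- table(gm$samples$accession)
  keep <- names(counts)[counts >= min_reps]
  if (!length(keep)) stop("no accession has >= ", min_reps, " replicates")
  gm <- gm[gm$samples$accession %in% keep, ]
  calls <- gm$calls
  if (drop_hets) calls[is_het(calls)] <- NA_character_
  ref_gm <- consensus_genotype(
    geno_matrix(calls, gm$markers, gm$samples)
  )
  ref <- ref_gm$calls[match(gm$samples$accession, ref_gm$samples$sample_id), ,
                      drop = FALSE]
  comp <- !is.na(calls) & !is.na(ref)
  mism <- comp & calls != ref
  m_l <- colSums(mism); n_l <- colSums(comp)
  per_locus <- tibble::tibble(
    marker_id = gm$markers$marker_id,
    m_l = unname(m_l), n_l = unname(n_l),
    e_l = unname(ifelse(n_l > 0, m_l / n_l, NA_real_))
  )
  mean_e <- mean(per_locus$e_l, na.rm = TRUE)
  per_acc <- tibble::tibble(accession = gm$samples$accession,
                            mismatch = rowSums(mism), compared = rowSums(comp)) |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(e = sum(.data$mismatch) / sum(.data$compared),
                     R = 100 * (1 - .data$e), .groups = "drop")
  structure(
    list(overall_R = 100 * (1 - mean_e), mean_e_l = 100 * mean_e,
         per_locus = per_locus, per_accession = per_acc,
         n_accessions = length(keep)),
    class = "repeatability"
  )
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> R = %.2f%% (mean per-locus error %.2f%%) over %d accessions\n",
              x$overall_R, x$mean_e_l, x$n_accessions))
  invisible(x)
}

#' Cross-platform genotype concordance
#'
#' Compares canonical genotype calls at markers shared by `(chrom, pos_bp)`
#' between two platforms. When a shared marker's allele pairs disagree but
#' platform B's pair is the reverse-complement of A's, B's calls are
#' complemented before comparison (opposite-strand reporting).
#' Strand-ambiguous markers (A/T and C/G pairs), where an opposite-strand
#' report is indistinguishable from an allele swap, are flagged and
#' excluded by default, as are markers whose declared pairs are genuinely
#' discordant. Calls missing on either side are excluded from the
#' comparison.
#'
#' @param gm_a,gm_b [geno_matrix()] objects from the two platforms
#' @param sample_map tibble with columns `sample_a`, `sample_b` pairing the
#'   ids; defaults to samples with identical ids in both matrices
#' @param include_ambiguous keep strand-ambiguous (A/T, C/G) markers in the
#'   comparison instead of excluding them
#' @return a list of class `concordance`: `overall` (percent),
#'   `n_overlap_markers`, `n_compared`, `n_matches`, `per_sample` tibble,
#'   `excluded_markers` (ambiguous, flagged).
#' @export
concordance <- function(gm_a, gm_b, sample_map = NULL,
                        include_ambiguous = FALSE) {
  if (is.null(sample_map)) {
    shared <- intersect(gm_a$samples$sample_id, gm_b$samples$sample_id)
    if (!length(shared)) stop("no shared sample ids; provide sample_map")
    sample_map <- tibble::tibble(sample_a = shared, sample_b = shared)
  }
  ka <- paste(gm_a$markers$chrom, gm_a$markers$pos_bp)
  kb <- paste(gm_b$markers$chrom, gm_b$markers$pos_bp)
  common <- intersect(ka, kb)
  if (!length(common)) stop("no shared markers by (chrom, pos)")
  ia <- match(common, ka); ib <- match(common, kb)
  pair_a <- paste0(pmin(gm_a$markers$allele_ref, gm_a$markers$allele_alt),
                   pmax(gm_a$markers$allele_ref, gm_a$markers$allele_alt))[ia]
  pair_b <- paste0(pmin(gm_b$markers$allele_ref, gm_b$markers$allele_alt),
                   pmax(gm_b$markers$allele_ref, gm_b$markers$allele_alt))[ib]
  comp_pair_b <- vapply(pair_b, function(p) {
    cc <- chartr("ACGT", "TGCA", p)
    paste0(min(substr(cc, 1, 1), substr(cc, 2, 2)),
           max(substr(cc, 1, 1), substr(cc, 2, 2)))
  }, "")
  same <- pair_a == pair_b
  flip <- !same & pair_a == comp_pair_b & !pair_a %in% c("AT", "CG")
  ambiguous <- (!same & !flip) |
    (!include_ambiguous & pair_a %in% c("AT", "CG"))
  A <- gm_a$calls[sample_map$sample_a, ia, drop = FALSE]
  B <- gm_b$calls[sample_map$sample_b, ib, drop = FALSE]
  if (any(flip)) {
    B[, flip] <- canonicalize_calls(
      matrix(chartr("ACGT", "TGCA", B[, flip]), nrow(B))
    )
  }
  A <- A[, !ambiguous, drop = FALSE]
  B <- B[, !ambiguous, drop = FALSE]
  comp <- !is.na(A) & !is.na(B)
  match_ <- comp & A == B
  per_sample <- tibble::tibble(
    sample_a = sample_map$sample_a, sample_b = sample_map$sample_b,
    n_compared = rowSums(comp), n_matches = rowSums(match_),
    concordance = 100 * rowSums(match_) / rowSums(comp)
  )
  structure(
    list(overall = 100 * sum(match_) / sum(comp),
         n_overlap_markers = sum(!ambiguous),
         n_compared = sum(comp), n_matches = sum(match_),
         per_sample = per_sample,
         excluded_markers = common[ambiguous]),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %.2f%% over %d calls at %d shared markers (%d samples)\n",
              x$overall, x$n_compared, x$n_overlap_markers,
              nrow(x$per_sample)))
  if (length(x$excluded_markers)) {
    cat("  excluded strand-ambiguous markers: ",
        length(x$excluded_markers), "\n")
  }
  invisible(x)
}

#' Set heterozygous calls missing
#'
#' In fully inbred material residual heterozygous calls are predominantly
#' miscalls; the usual preprocessing before imputation and genomic
#' prediction is to remove them and let the imputer refill the locus.
#'
#' @param gm a [geno_matrix()]
#' @return a [geno_matrix()] with heterozygous calls set to missing.
#' @export
drop_het_calls <- function(gm) {
  calls <- gm$calls
  calls[is_het(calls)] <- NA_character_
  geno_matrix(calls, gm$markers, gm$samples)
}

#' LD-kNN genotype imputation
#'
#' Imputes missing calls with the LD-kNNi scheme: for each marker with
#' missing data, take the `l_sites` markers in highest LD (squared Pearson
#' correlation of dosages on pairwise-complete observations); the distance
#' between two samples is the mean absolute dosage difference over those
#' sites (pairs missing at a site are skipped); the predicted dosage is a
#' `1/(distance + 1e-6)`-weighted vote of the `k_neighbors` nearest
#' neighbours with a non-missing call, rounded to the nearest of 0/1/2
#' (exact half-way ties resolved to the single nearest neighbour's
#' genotype). Non-missing calls are never altered; calls with no usable
#' neighbour stay missing.
#'
#' @param gm a [geno_matrix()]
#' @param l_sites number of high-LD sites defining the local distance
#' @param k_neighbors number of nearest neighbours in the vote
#' @return a [geno_matrix()] with imputed calls.
#' @export
impute_ld_knn <- function(gm, l_sites = 30, k_neighbors = 30) {
  if (n_markers(gm) < 2 || n_samples(gm) < 2) {
    stop("need at least 2 samples and 2 markers")
  }
  D <- dosage(gm)
  R2 <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))^2
  diag(R2) <- NA
  out <- D
  for (j in which(colSums(is.na(D)) > 0)) {
    r2j <- R2[, j]
    sites <- order(r2j, decreasing = TRUE, na.last = NA)
    sites <- utils::head(sites[!is.na(r2j[sites])], l_sites)
    if (!length(sites)) next
    Dj <- D[, sites, drop = FALSE]
    for (s in which(is.na(D[, j]))) {
      diffs <- abs(sweep(Dj, 2, Dj[s, ], `-`))
      dist <- rowMeans(diffs, na.rm = TRUE)
      dist[s] <- NA                              # not its own neighbour
      dist[rowSums(!is.na(diffs)) == 0] <- NA    # no shared sites
      dist[is.na(D[, j])] <- NA                  # neighbour must be called
      if (all(is.na(dist))) next
      nb <- order(dist, na.last = NA)[seq_len(min(k_neighbors, sum(!is.na(dist))))]
      w <- 1 / (dist[nb] + 1e-6)
      pred <- sum(w * D[nb, j]) / sum(w)
      lo <- floor(pred); hi <- ceiling(pred)
      out[s, j] <- if (hi - pred == pred - lo && lo != hi) {
        D[nb[1], j]                              # exact tie -> nearest neighbour
      } else {
        round(pred)
      }
    }
  }
  geno_matrix(calls_from_dosage(out, gm$markers), gm$markers, gm$samples)
}
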