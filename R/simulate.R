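#' Rice chromosome lengths (MSU7 pseudomolecules)
#'
#' Physical lengths of the 12 rice chromosomes; they sum to 373,245,519 bp.
#'
#' @return named integer vector `chr01`..`chr12` (bp).
#' @export
rice_chrom_lengths <- function() {
  c(chr01 = 43270923L, chr02 = 35937250L, chr03 = 36413819L,
    chr04 = 35502694L, chr05 = 29958434L, chr06 = 31248787L,
    chr07 = 29697621L, chr08 = 28443022L, chr09 = 23012720L,
    chr10 = 23207287L, chr11 = 29021106L, chr12 = 27531856L)
}

#' Population model for synthetic rice germplasm
#'
#' Describes the subpopulation structure the generators emulate: a common
#' ancestral allele-frequency spectrum (symmetric Beta on the alternate
#' allele, folded to the panel's minor-allele-frequency spectrum) and a
#' drift divergence per subpopulation. Subpopulation frequencies are drawn
#' as `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`
#' (the Balding-Nichols model); `F = 0` keeps the ancestral frequency.
#'
#' Defaults emulate an indica-ascertained panel: indica draws straight from
#' the panel spectrum, japonica is strongly drifted (many markers near
#' fixation), aus intermediate. The error model reflects a well-behaved
#' amplicon assay: 1.5% residual heterozygosity in inbreds, and a bimodal
#' missingness structure — most markers drop ~2% of calls while a
#' `failed_marker_rate` fraction amplify poorly and lose
#' `failed_marker_missing` of theirs. The defaults give a panel-wide mean
#' call rate of ~95% with roughly a tenth of markers falling under the 75%
#' call-rate filter, the typical fate of a fixed-content amplicon design.
#'
#' @param divergence named numeric vector of per-subpopulation drift
#'   divergences in `[0, 1)`
#' @param residual_het_rate probability a truly homozygous call is rendered
#'   heterozygous
#' @param missing_rate per-call missing probability at well-behaved markers
#' @param failed_marker_rate fraction of markers with poor amplification
#' @param failed_marker_missing per-call missing probability at failed
#'   markers
#' @return a list of class `population_model`.
#' @export
population_model <- function(divergence = c(indica = 0, japonica = 0.75, aus = 0.45),
                             residual_het_rate = 0.015,
                             missing_rate = 0.02,
                             failed_marker_rate = 0.10,
                             failed_marker_missing = 0.32) {
  stopifnot(all(divergence >= 0), all(divergence < 1),
            residual_het_rate >= 0, residual_het_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            failed_marker_rate >= 0, failed_marker_rate < 1,
            failed_marker_missing >= 0, failed_marker_missing < 1)
  structure(list(divergence = divergence,
                 residual_het_rate = residual_het_rate,
                 missing_rate = missing_rate,
                 failed_marker_rate = failed_marker_rate,
                 failed_marker_missing = failed_marker_missing),
            class = "population_model")
}

# per-marker missing probabilities under the bimodal amplification model
marker_missing_rates <- function(pop_model, m) {
  failed <- stats::runif(m) < pop_model$failed_marker_rate
  ifelse(failed, pop_model$failed_marker_missing, pop_model$missing_rate)
}

#' Simulate a genome-wide SNP panel
#'
#' Places `n_markers` biallelic SNPs across the 12 rice chromosomes,
#' allocated proportionally to physical length and uniformly spaced within
#' each chromosome with random jitter. Each marker gets an ancestral
#' alternate-allele frequency drawn from a symmetric `Beta(shape, shape)`
#' truncated to the requested minor-allele-frequency interval; the default
#' shape (3.25) yields a MAF spectrum with median ~0.36 and interquartile
#' range ~0.28-0.44, the spectrum of a high-MAF indica-ascertained panel.
#'
#' @param n_markers number of SNPs (>= 1)
#' @param chrom_lengths named vector of chromosome lengths in bp
#' @param maf_target interval of admissible minor allele frequencies,
#'   within (0, 0.5]
#' @param maf_shape Beta shape parameter of the frequency spectrum
#' @param seed integer seed; the panel is a pure function of the arguments
#' @return tibble of markers: `marker_id` (chrNN:pos), `chrom`, `pos_bp`,
#'   `allele_ref`, `allele_alt`, `source`, `maf`, `alt_freq`.
#' @export
simulate_panel <- function(n_markers = 995,
                           chrom_lengths = rice_chrom_lengths(),
                           maf_target = c(0.01, 0.5),
                           maf_shape = 3.25,
                           seed = 1L) {
  stopifnot(n_markers >= 1, all(chrom_lengths > 0))
  if (maf_target[1] <= 0 || maf_target[2] > 0.5 || maf_target[1] >= maf_target[2]) {
    stop("maf_target must be an interval inside (0, 0.5]")
  }
  set.seed(seed)
  # proportional allocation with largest-remainder rounding, >=1 per chrom
  share <- n_markers * chrom_lengths / sum(chrom_lengths)
  n_per <- floor(share)
  rem <- n_markers - sum(n_per)
  if (rem > 0) {
    top <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[top] <- n_per[top] + 1
  }
  if (n_markers >= length(chrom_lengths)) n_per <- pmax(n_per, 1L)
  while (sum(n_per) > n_markers) {        # repair if the floor forced extras
    i <- which.max(n_per)
    n_per[i] <- n_per[i] - 1L
  }
  rows <- purrr::map(seq_along(chrom_lengths), function(i) {
    k <- n_per[i]
    if (k == 0) return(NULL)
    L <- chrom_lengths[i]
    spacing <- L / k
    pos <- (seq_len(k) - 0.5) * spacing +
      stats::runif(k, -0.3 * spacing, 0.3 * spacing)
    pos <- sort(unique(pmin(pmax(round(pos), 1), L)))
    while (length(pos) < k) {  # de-duplicate collisions (tiny chromosomes)
      pos <- sort(unique(c(pos, sample.int(L, k - length(pos)))))
    }
    tibble::tibble(chrom = names(chrom_lengths)[i], pos_bp = as.integer(pos))
  })
  panel <- dplyr::bind_rows(rows)
  n <- nrow(panel)
  pair <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
  maf <- rbeta_maf(n, maf_shape, maf_target)
  # orientation of the minor allele is random
  alt_freq <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
  src <- rep(c("C6AIR", "3KRG", "TRAIT"),
             times = round(n * c(604, 363, 28) / 995))
  src <- c(src, rep("3KRG", max(0, n - length(src))))[seq_len(n)]
  panel |>
    dplyr::mutate(
      marker_id = paste0(chrom, ":", pos_bp),
      allele_ref = pair[, 1], allele_alt = pair[, 2],
      source = sample(src), maf = maf, alt_freq = alt_freq
    ) |>
    dplyr::select(marker_id, chrom, pos_bp, allele_ref, allele_alt,
                  source, maf, alt_freq) |>
    dplyr::arrange(chrom, pos_bp)
}

# draw minor allele frequencies from folded Beta(shape, shape) truncated to
# the target interval (rejection; the default interval accepts ~everything)
rbeta_maf <- function(n, shape, maf_target) {
  out <- numeric(0)
  while (length(out) < n) {
    p <- stats::rbeta(2 * n, shape, shape)
    m <- pmin(p, 1 - p)
    out <- c(out, m[m >= maf_target[1] & m <= maf_target[2]])
  }
  out[seq_len(n)]
}

balding_nichols <- function(p, f) {
  if (f < 1e-12) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate inbred lines from a panel and population model
#'
#' Each line is fully homozygous in truth: at every marker the line carries
#' the alternate allele with its subpopulation's frequency. Calls are then
#' corrupted by the model's residual heterozygosity and missing rates.
#'
#' @param panel marker tibble from [simulate_panel()] (needs `alt_freq`)
#' @param pop_model a [population_model()]
#' @param n_per_subpop named integer vector, samples per subpopulation
#'   (names must be a subset of the model's subpopulations)
#' @param ld_blocks optional integer block size `b`: markers are grouped in
#'   consecutive blocks of `b` sharing a latent haplotype, giving within-
#'   block r-squared of ~0.8 (for exercising LD-based imputation); default
#'   `NULL` simulates linkage equilibrium
#' @param seed integer seed
#' @return a [geno_matrix()] whose `sample_info()` carries the true
#'   subpopulation labels.
#' @export
simulate_inbreds <- function(panel, pop_model = population_model(),
                             n_per_subpop = c(indica = 50, japonica = 20),
                             ld_blocks = NULL, seed = 1L) {
  stopifnot(all(names(n_per_subpop) %in% names(pop_model$divergence)))
  set.seed(seed)
  m <- nrow(panel)
  subpop_freq <- lapply(names(n_per_subpop), function(sp) {
    balding_nichols(panel$alt_freq, pop_model$divergence[[sp]])
  })
  names(subpop_freq) <- names(n_per_subpop)
  n_total <- sum(n_per_subpop)
  D <- matrix(NA_real_, n_total, m)
  labs <- character(n_total)
  row <- 1L
  for (sp in names(n_per_subpop)) {
    p <- subpop_freq[[sp]]
    for (i in seq_len(n_per_subpop[[sp]])) {
      if (is.null(ld_blocks)) {
        D[row, ] <- 2 * (stats::runif(m) < p)
      } else {
        D[row, ] <- draw_ld_blocks(p, ld_blocks)
      }
      labs[row] <- sp
      row <- row + 1L
    }
  }
  # residual heterozygosity then marker-specific missingness
  het <- stats::runif(length(D)) < pop_model$residual_het_rate
  D[het] <- 1
  miss_rate <- marker_missing_rates(pop_model, m)
  miss <- sweep(matrix(stats::runif(n_total * m), n_total, m), 2,
                miss_rate, `<`)
  D[miss] <- NA
  ids <- sprintf("%s_%03d", labs, stats::ave(seq_len(n_total), labs, FUN = seq_along))
  geno_matrix(
    calls = calls_from_dosage(D, panel),
    markers = panel,
    samples = tibble::tibble(sample_id = ids, accession = ids, subpop = labs)
  )
}

# one inbred line with correlated blocks: consecutive markers in a block
# copy a latent allele with probability c (c^4 ~ r^2 >= 0.8)
draw_ld_blocks <- function(p, b, copy_prob = 0.95) {
  m <- length(p)
  block <- (seq_len(m) - 1L) %/% b
  p_block <- stats::ave(p, block, FUN = function(x) x[1])
  z <- stats::runif(m) < p_block            # latent haplotype allele, by block
  z <- stats::ave(as.numeric(z), block, FUN = function(x) x[1])
  fresh <- stats::runif(m) >= copy_prob
  a <- ifelse(fresh, stats::runif(m) < p_block, z == 1)
  2 * as.numeric(a)
}

#' Simulate independent replicate genotyping runs
#'
#' Produces `n_reps` replicate call sets per accession; every replicate-locus
#' call is independently replaced with probability `per_locus_error`.
#' Replacement errors are biased towards heterozygous miscalls (the dominant
#' error mode of amplicon assays on inbred material): with probability
#' `het_bias` the erroneous call is the marker's heterozygote, otherwise a
#' random different genotype.
#'
#' @param truth a [geno_matrix()] of true genotypes (one row per accession)
#' @param n_reps replicates per accession
#' @param per_locus_error per-call error probability in `[0, 1)`
#' @param het_bias fraction of errors rendered heterozygous
#' @param seed integer seed
#' @return a [geno_matrix()] with `n_reps * n_samples(truth)` rows;
#'   `sample_info()$accession` groups replicates and `rep_group` indexes them.
#' @export
simulate_replicates <- function(truth, n_reps = 4, per_locus_error = 0.01,
                                het_bias = 0.7, seed = 1L) {
  stopifnot(per_locus_error >= 0, per_locus_error < 1)
  set.seed(seed)
  m <- n_markers(truth); n <- n_samples(truth)
  ref <- truth$markers$allele_ref; alt <- truth$markers$allele_alt
  hom_ref <- paste0(ref, ref)
  hom_alt <- paste0(alt, alt)
  het <- paste0(pmin(ref, alt), pmax(ref, alt))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    calls <- truth$calls
    err <- matrix(stats::runif(n * m) < per_locus_error, n, m)
    err[is.na(calls)] <- FALSE
    if (any(err)) {
      idx <- which(err, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1]; j <- idx[k, 2]
        cur <- calls[i, j]
        opts <- setdiff(c(hom_ref[j], het[j], hom_alt[j]), cur)
        if (stats::runif(1) < het_bias && het[j] %in% opts) {
          calls[i, j] <- het[j]
        } else {
          calls[i, j] <- sample(opts, 1)
        }
      }
    }
    reps[[r]] <- geno_matrix(
      calls, truth$markers,
      truth$samples |>
        dplyr::mutate(sample_id = paste0(sample_id, "_rep", r),
                      rep_group = as.character(r))
    )
  }
  do.call(bind_geno, reps)
}

#' Simulate a bi-parental cross
#'
#' F1 plants are heterozygous wherever the homozygous parents differ,
#' homozygous where they agree, and missing where either parent is missing.
#' With `f2 = TRUE` each plant is an F2 instead: every marker segregates
#' independently 1:2:1 from the F1 (the generators do not model linkage).
#'
#' @param gm a [geno_matrix()] containing both parents
#' @param parent1,parent2 sample ids of the parents (must be homozygous or
#'   missing at every marker)
#' @param n_progeny number of F1 (or F2) plants
#' @param f2 simulate F2 instead of F1
#' @param seed integer seed
#' @return a [geno_matrix()] of the progeny; `family` records the cross.
#' @export
simulate_cross <- function(gm, parent1, parent2, n_progeny = 10,
                           f2 = FALSE, seed = 1L) {
  set.seed(seed)
  c1 <- gm$calls[parent1, ]; c2 <- gm$calls[parent2, ]
  if (any(is_het(c1), na.rm = TRUE) || any(is_het(c2), na.rm = TRUE)) {
    stop("parents must be homozygous (or missing) at every marker")
  }
  f1 <- predict_f1_calls(c1, c2)
  cross_id <- paste0(parent1, "x", parent2)
  if (!f2) {
    calls <- matrix(rep(f1, each = n_progeny), n_progeny, length(f1))
  } else {
    m <- length(f1)
    calls <- matrix(NA_character_, n_progeny, m)
    a1 <- substr(f1, 1, 1); a2 <- substr(f1, 2, 2)
    for (j in seq_len(m)) {
      if (is.na(f1[j])) next
      if (a1[j] == a2[j]) { calls[, j] <- f1[j]; next }
      g1 <- sample(c(a1[j], a2[j]), n_progeny, replace = TRUE)
      g2 <- sample(c(a1[j], a2[j]), n_progeny, replace = TRUE)
      calls[, j] <- paste0(pmin(g1, g2), pmax(g1, g2))
    }
  }
  gen <- if (f2) "F2" else "F1"
  ids <- sprintf("%s_%s_%02d", gen, cross_id, seq_len(n_progeny))
  geno_matrix(calls, gm$markers,
              tibble::tibble(sample_id = ids, family = cross_id))
}

kb_per_cM_default <- function() 244

# parental origin of each marker for one RIL: per chromosome, crossover
# breakpoints ~ Poisson(2 x cM length / 100), alternating origin
ril_origin <- function(chrom_idx, pos_cM) {
  out <- logical(length(pos_cM))
  for (idx in chrom_idx) {
    span <- max(pos_cM[idx])
    n_x <- stats::rpois(1, 2 * span / 100)
    breaks <- sort(stats::runif(n_x, 0, span))
    seg <- findInterval(pos_cM[idx], breaks)
    out[idx] <- (seg + stats::rbinom(1, 1, 0.5)) %% 2 == 0
  }
  out
}

is_het <- function(calls) {
  !is.na(calls) & substr(calls, 1, 1) != substr(calls, 2, 2)
}

#' Additive trait architecture
#'
#' @param n_qtl number of causal markers
#' @param effect_distribution `"gaussian"` or `"scaled_t"` marker effects
#' @param h2 broad-sense heritability of accession means (0, 1]
#' @param trial_var,rep_var trial and replicate-within-trial variances,
#'   expressed as multiples of the genetic variance
#' @return a list of class `trait_architecture`.
#' @export
trait_architecture <- function(n_qtl = 300,
                               effect_distribution = c("gaussian", "scaled_t"),
                               h2 = 0.85, trial_var = 2, rep_var = 0.2) {
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(h2 > 0, h2 <= 1, trial_var >= 0, rep_var >= 0)
  structure(list(n_qtl = n_qtl, effect_distribution = effect_distribution,
                 h2 = h2, trial_var = trial_var, rep_var = rep_var),
            class = "trait_architecture")
}

#' Simulate an elite breeding program dataset
#'
#' Emulates a genomic-selection training set: recombinant inbred lines from
#' bi-parental families between elite parents of one subpopulation, a
#' pedigree, and plot-level phenotypes generated from the additive model
#' `Y = mu + g_i + t_j + r(t)_jk + e_ijk`. The residual variance is set from
#' the architecture's target heritability of accession means,
#' `H2 = var_g / (var_g + var_e / (t * r))`, so realized heritability at the
#' simulated scale matches the requested value in expectation.
#'
#' @param panel marker tibble from [simulate_panel()]
#' @param n_families number of bi-parental families
#' @param n_lines total number of lines (family sizes drawn to sum to this)
#' @param arch a [trait_architecture()]
#' @param n_trials number of trials (environments)
#' @param replication mean plots per line per trial (1.2 = a p-rep design
#'   where 20% of lines get a second plot)
#' @param pop_model a [population_model()] for the parent pool
#' @param n_parents size of the elite parent pool
#' @param mu trait mean on the simulated scale
#' @param seed integer seed
#' @return a list with elements `geno` ([geno_matrix()] of the lines),
#'   `pedigree` ([as_pedigree()]), `phenotypes` (tibble: `genotype`,
#'   `trial`, `rep`, `value`), and `truth` (marker `effects`, true
#'   `breeding_values`, the drawn variance components).
#' @export
simulate_breeding_program <- function(panel, n_families = 30, n_lines = 353,
                                      arch = trait_architecture(),
                                      n_trials = 3, replication = 1.2,
                                      pop_model = population_model(),
                                      n_parents = 25, mu = 100, seed = 1L) {
  set.seed(seed)
  m <- nrow(panel)
  parents <- simulate_inbreds(
    panel,
    population_model(divergence = pop_model$divergence,
                     residual_het_rate = 0, missing_rate = 0, failed_marker_rate = 0),
    n_per_subpop = c(indica = n_parents),
    seed = seed + 1L
  )
  Dp <- dosage(parents)
  # family sizes: multinomial around equal shares, min 1 per family
  sizes <- as.vector(stats::rmultinom(1, n_lines - n_families,
                                      rep(1, n_families))) + 1L
  pairs <- t(replicate(n_families, sample(parents$samples$sample_id, 2)))
  # RILs inherit parental chromosome segments: breakpoints are Poisson on
  # the genetic map (244 kb/cM, doubled for the RIL map expansion under
  # repeated selfing), and each segment is homozygous for one parent
  chrom_f <- factor(panel$chrom, levels = unique(panel$chrom))
  pos_cM <- panel$pos_bp / (kb_per_cM_default() * 1000)
  chrom_idx <- split(seq_len(m), chrom_f)
  lines_d <- matrix(NA_real_, n_lines, m)
  fam <- character(n_lines); sire <- character(n_lines); dam <- character(n_lines)
  ids <- sprintf("L%03d", seq_len(n_lines))
  row <- 1L
  for (f in seq_len(n_families)) {
    p1 <- Dp[pairs[f, 1], ]; p2 <- Dp[pairs[f, 2], ]
    for (i in seq_len(sizes[f])) {
      pick <- ril_origin(chrom_idx, pos_cM)   # TRUE = parent 1 segment
      lines_d[row, ] <- ifelse(pick, p1, p2)
      fam[row] <- sprintf("FAM%02d", f)
      sire[row] <- pairs[f, 1]; dam[row] <- pairs[f, 2]
      row <- row + 1L
    }
  }
  # observed genotypes pass through the assay's error model; breeding
  # values below use the true dosages
  obs_d <- lines_d
  het <- stats::runif(length(obs_d)) < pop_model$residual_het_rate
  obs_d[het] <- 1
  miss_rate <- marker_missing_rates(pop_model, m)
  miss <- sweep(matrix(stats::runif(length(obs_d)), n_lines, m), 2,
                miss_rate, `<`)
  obs_d[miss] <- NA
  geno <- geno_matrix(
    calls_from_dosage(obs_d, panel), panel,
    tibble::tibble(sample_id = ids, family = fam)
  )
  ped <- as_pedigree(dplyr::bind_rows(
    tibble::tibble(id = parents$samples$sample_id,
                   sire = NA_character_, dam = NA_character_),
    tibble::tibble(id = ids, sire = sire, dam = dam)
  ))
  # additive architecture
  qtl <- sample.int(m, min(arch$n_qtl, m))
  beta <- if (arch$effect_distribution == "gaussian") {
    stats::rnorm(length(qtl))
  } else {
    stats::rt(length(qtl), df = 5) / sqrt(5 / 3)
  }
  bv <- drop(lines_d[, qtl, drop = FALSE] %*% beta)
  bv <- bv - mean(bv)
  var_g <- stats::var(bv)
  t_n <- n_trials
  r_n <- replication
  var_e <- var_g * t_n * r_n * (1 - arch$h2) / arch$h2
  var_t <- arch$trial_var * var_g
  var_r <- arch$rep_var * var_g
  t_eff <- stats::rnorm(n_trials, 0, sqrt(var_t))
  plots <- purrr::map(seq_len(n_trials), function(tj) {
    extra <- sample(ids, round((replication - 1) * n_lines))
    reps <- list(`1` = ids, `2` = extra)
    purrr::imap(reps, function(who, rk) {
      if (!length(who)) return(NULL)
      r_eff <- stats::rnorm(1, 0, sqrt(var_r))
      tibble::tibble(
        genotype = who, trial = sprintf("T%d", tj), rep = rk,
        value = mu + bv[match(who, ids)] + t_eff[tj] + r_eff +
          stats::rnorm(length(who), 0, sqrt(var_e))
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  list(
    geno = geno, pedigree = ped, phenotypes = plots,
    truth = list(qtl = panel$marker_id[qtl], effects = beta,
                 breeding_values = stats::setNames(bv, ids),
                 var_g = var_g, var_e = var_e, var_t = var_t, var_r = var_r)
  )
}
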