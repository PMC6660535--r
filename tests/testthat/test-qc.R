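test_that("per-marker statistics count calls exactly", {
  panel <- tiny_markers()[1, ]
  calls <- matrix(c("AA", "AA", "AG", "GG"), 4, 1)
  gm <- geno_matrix(calls, panel, tibble::tibble(sample_id = paste0("s", 1:4)))
  qc <- marker_qc(gm)
  expect_equal(qc$call_rate, 1)
  expect_equal(qc$het, 0.25)
  expect_equal(qc$maf, 0.375)                  # 3 G of 8 alleles: minor = G
  # 25% heterozygosity trips the 10% boundary; the counts stand on their own
  expect_false(qc$pass)
  expect_equal(qc$fail_reasons, "HIGH_HET")
})

test_that("filter boundaries are inclusive as printed", {
  panel <- tiny_markers()
  # marker 1: CR exactly 0.75 -> fail; marker 2: het exactly 10% -> fail;
  # marker 3: clean
  calls <- rbind(
    c("AA", "CC", "GG"), c("AA", "CC", "GG"), c("AA", "CC", "TT"),
    c("AA", "CC", "GG"), c("AA", "CT", "GG"), c("GG", "CC", "GG"),
    c("GG", "TT", "TT"), c("GG", "TT", "TT"), c(NA, "TT", "GG"),
    c(NA, "TT", "TT")
  )
  gm <- geno_matrix(calls, panel,
                    tibble::tibble(sample_id = sprintf("s%02d", 1:10)))
  qc <- marker_qc(gm)
  expect_equal(qc$call_rate[1], 0.8)
  qc2 <- marker_qc(gm, min_call_rate = 0.8)    # boundary: 0.8 <= 0.8 fails
  expect_false(qc2$pass[1])
  expect_match(qc2$fail_reasons[1], "LOW_CR")
  expect_equal(qc$het[2], 0.1)
  expect_false(qc$pass[2])                     # het >= 10% inclusive
  expect_match(qc$fail_reasons[2], "HIGH_HET")
  expect_true(qc$pass[3])
})

test_that("a marker with no calls fails LOW_CR with undefined het and maf", {
  panel <- tiny_markers()[1, ]
  gm <- geno_matrix(matrix(NA_character_, 3, 1), panel,
                    tibble::tibble(sample_id = paste0("s", 1:3)))
  qc <- marker_qc(gm)
  expect_equal(qc$call_rate, 0)
  expect_true(is.na(qc$het) && is.na(qc$maf))
  expect_match(qc$fail_reasons, "LOW_CR")
})

test_that("an engineered 97 + 5 failure fixture removes exactly those markers", {
  # 995 clean markers; corrupt 97 to low call rate and 5 more to high het
  gm <- clean_gm(n_samples = 40, n_markers = 995, seed = 10)
  set.seed(11)
  low_cr <- sample(n_markers(gm), 97)
  high_het <- sample(setdiff(seq_len(n_markers(gm)), low_cr), 5)
  calls <- gm$calls
  calls[1:11, low_cr] <- NA                    # CR = 29/40 = 0.725 <= 0.75
  for (j in high_het) {
    het <- paste0(pmin(gm$markers$allele_ref[j], gm$markers$allele_alt[j]),
                  pmax(gm$markers$allele_ref[j], gm$markers$allele_alt[j]))
    calls[1:6, j] <- het                       # 15% het
  }
  gm2 <- geno_matrix(calls, gm$markers, gm$samples)
  qc <- marker_qc(gm2)
  expect_equal(sum(grepl("LOW_CR", qc$fail_reasons)), 97)
  # two-stage removal: call-rate filter first, then heterozygosity
  after_cr <- gm2[, !grepl("LOW_CR", qc$fail_reasons)]
  expect_equal(n_markers(after_cr), 995 - 97)
  qc2 <- marker_qc(after_cr)
  after_het <- filter_markers(after_cr, qc2)
  expect_equal(n_markers(after_het), 995 - 97 - 5)
  # filtering is idempotent
  expect_equal(n_markers(filter_markers(after_het)), n_markers(after_het))
})

test_that("consensus genotypes follow strict majority with ties missing", {
  expect_equal(ricepanel:::majority_call(c("AA", "AA", "AG")), "AA")
  expect_equal(ricepanel:::majority_call(c("AA", "GG")), NA_character_)
  expect_equal(ricepanel:::majority_call("AG"), "AG")
  expect_equal(ricepanel:::majority_call(c(NA, NA)), NA_character_)
  expect_equal(ricepanel:::majority_call(c("AA", "AA", "AG", "AG")), NA_character_)
})

test_that("repeatability reproduces the per-locus error formula", {
  # 1 accession, 4 reps, 10 loci; one replicate mismatches at locus 3
  panel <- simulate_panel(10, seed = 1)
  D <- matrix(0, 4, 10)
  D[4, 3] <- 2
  gm <- geno_matrix(calls_from_dosage(D, panel), panel,
                    tibble::tibble(sample_id = paste0("r", 1:4),
                                   accession = "acc1"))
  r <- repeatability(gm, min_reps = 4)
  expect_equal(r$per_locus$e_l[3], 0.25)
  expect_equal(r$mean_e_l, 2.5)
  expect_equal(r$overall_R, 97.5)
  expect_error(repeatability(gm, min_reps = 5), "replicates")
})

test_that("dropping heterozygous calls removes het-driven mismatches", {
  panel <- simulate_panel(400, seed = 1)
  truth <- simulate_inbreds(panel,
                            population_model(residual_het_rate = 0,
                                             missing_rate = 0, failed_marker_rate = 0),
                            c(indica = 10), seed = 2)
  reps <- simulate_replicates(truth, 4, per_locus_error = 0.01,
                              het_bias = 1, seed = 3)
  r_all <- repeatability(reps)
  r_drop <- repeatability(reps, drop_hets = TRUE)
  expect_gt(r_drop$overall_R, r_all$overall_R)
  expect_gt(r_drop$overall_R, 99.9)  # every error was a het miscall
})

test_that("concordance matches exact calls and excludes missing", {
  panel <- tibble::tibble(
    marker_id = paste0("chr01:", 1:10 * 1000),
    chrom = "chr01", pos_bp = 1:10 * 1000L,
    allele_ref = "A", allele_alt = "G"          # no strand-ambiguous pairs
  )
  D <- matrix(rep_len(c(0, 2), 200), 20, 10)
  gm <- geno_matrix(calls_from_dosage(D, panel), panel,
                    tibble::tibble(sample_id = sprintf("s%02d", 1:20)))
  cc <- concordance(gm, gm)
  expect_equal(cc$overall, 100)
  gm2 <- gm
  calls <- gm2$calls
  calls[1, 1] <- if (calls[1, 1] == paste0(gm$markers$allele_ref[1],
                                           gm$markers$allele_ref[1])) {
    paste0(gm$markers$allele_alt[1], gm$markers$allele_alt[1])
  } else paste0(gm$markers$allele_ref[1], gm$markers$allele_ref[1])
  calls[2, 1] <- NA                             # removed from comparison
  gm2 <- geno_matrix(calls, gm$markers, gm$samples)
  cc2 <- concordance(gm, gm2)
  expect_equal(cc2$n_compared, 199)
  expect_equal(cc2$n_matches, 198)
  expect_equal(cc2$overall, 100 * 198 / 199)
})

test_that("opposite-strand platforms are reconciled, ambiguous pairs excluded", {
  panel <- tibble::tibble(
    marker_id = c("chr01:100", "chr01:200"),
    chrom = "chr01", pos_bp = c(100L, 200L),
    allele_ref = c("A", "A"), allele_alt = c("G", "T")
  )
  calls <- rbind(s1 = c("AG", "AA"), s2 = c("GG", "TT"))
  gm_a <- geno_matrix(calls, panel, tibble::tibble(sample_id = c("s1", "s2")))
  # platform B reports marker 1 on the opposite strand (T/C), marker 2 is
  # strand-ambiguous A/T with a discordant declared pair
  panel_b <- panel
  panel_b$allele_ref <- c("T", "T"); panel_b$allele_alt <- c("C", "A")
  calls_b <- rbind(s1 = c("CT", "TT"), s2 = c("CC", "AA"))
  gm_b <- geno_matrix(calls_b, panel_b,
                      tibble::tibble(sample_id = c("s1", "s2")))
  cc <- concordance(gm_a, gm_b)
  expect_equal(cc$n_overlap_markers, 1)
  expect_equal(length(cc$excluded_markers), 1)
  expect_equal(cc$overall, 100)                # complemented calls match
  panel_c <- panel
  panel_c$pos_bp <- c(900L, 950L)
  panel_c$marker_id <- paste0("chr01:", panel_c$pos_bp)
  gm_c <- geno_matrix(calls, panel_c, tibble::tibble(sample_id = c("s1", "s2")))
  expect_error(concordance(gm_a, gm_c), "shared markers")
})

test_that("LD-kNN imputation copies a duplicate sample's call", {
  panel <- simulate_panel(30, seed = 5)
  base <- simulate_inbreds(panel,
                           population_model(residual_het_rate = 0,
                                            missing_rate = 0, failed_marker_rate = 0),
                           c(indica = 8), seed = 6)
  calls <- rbind(base$calls, dup = base$calls[1, ])
  calls["dup", 4] <- NA
  gm <- geno_matrix(calls, base$markers,
                    tibble::tibble(sample_id = c(base$samples$sample_id, "dup")))
  imp <- impute_ld_knn(gm, l_sites = 10, k_neighbors = 3)
  expect_equal(imp$calls["dup", 4], base$calls[1, 4])
  # non-missing calls never altered
  known <- !is.na(gm$calls)
  expect_identical(imp$calls[known], gm$calls[known])
  expect_lte(sum(is.na(imp$calls)), sum(is.na(gm$calls)))
  expect_error(impute_ld_knn(gm[, 1]), "at least 2")
})

test_that("LD-kNN beats column-mode imputation on correlated blocks", {
  panel <- simulate_panel(400, seed = 3)
  truth <- simulate_inbreds(panel,
                            population_model(residual_het_rate = 0,
                                             missing_rate = 0, failed_marker_rate = 0),
                            c(indica = 80), ld_blocks = 8, seed = 21)
  D0 <- dosage(truth)
  set.seed(22)
  miss <- matrix(stats::runif(length(truth$calls)) < 0.05,
                 nrow(truth$calls))
  calls <- truth$calls
  calls[miss] <- NA
  gm <- geno_matrix(calls, truth$markers, truth$samples)
  Di <- dosage(impute_ld_knn(gm))
  acc_knn <- mean(Di[miss] == D0[miss])
  Dm <- dosage(gm)
  modes <- apply(Dm, 2, function(x) {
    t <- table(x)
    as.numeric(names(t)[which.max(t)])
  })
  acc_mode <- mean(matrix(modes, nrow(Dm), ncol(Dm), byrow = TRUE)[miss] ==
                     D0[miss])
  expect_gt(acc_knn, acc_mode)
})
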