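#' Packaged trait-marker definitions
#'
#' The 21 marker-assisted-selection SNPs shipped with the package: 11 loci
#' (grain size GS3, bacterial-leaf-blight resistance xa5/Xa7/xa13/Xa4/Xa21/
#' Xa23, tungro resistance rstv, submergence tolerance sub1, gelatinization
#' temperature ALK, and the Waxy amylose-content haplotype), each used
#' either as a single diagnostic SNP or as a multi-SNP haplotype. The Waxy
#' locus maps haplotypes to amylose classes (high / intermediate / low);
#' both reported spellings of the high-class haplotype (GAC and GAT) are
#' encoded, with the conflict noted in the `note` column.
#'
#' @return tibble with one row per trait SNP: `trait`, `gene`, `marker_id`,
#'   `chrom`, `pos_bp`, `negative_allele`, `positive_allele`,
#'   `negative_trait`, `positive_trait`, `use` ("single"/"haplotype"),
#'   `hap_index`, `favorable_haplotypes`, `unfavorable_haplotypes`,
#'   `class_map`, `note`.
#' @export
trait_marker_defs <- function() {
  path <- system.file("extdata", "trait_markers.csv", package = "ricepanel")
  readr::read_csv(path, col_types = readr::cols(
    pos_bp = "i", hap_index = "i", .default = "c"
  ), progress = FALSE, show_col_types = FALSE)
}

#' Call trait status from genotypes
#'
#' Applies one trait-marker definition (a single locus: one row in single
#' mode, the ordered marker rows of one gene in haplotype mode) to every
#' sample.
#'
#' Single mode: a sample homozygous for the positive allele is `favorable`,
#' homozygous negative is `unfavorable`, heterozygous is `het` (reported as
#' carrying the favorable allele), missing is `unknown`.
#'
#' Haplotype mode: the sample's alleles are concatenated across the locus'
#' markers in `hap_index` order. A heterozygous or missing component makes
#' the haplotype ambiguous; every completion consistent with the observed
#' alleles (missing components range over the marker's declared pair) is
#' classified, and the sample gets a determinate label only if all
#' completions agree. Loci with a `class_map` label samples with the mapped
#' class ("high"/"intermediate"/"low"); otherwise labels are
#' `favorable`/`unfavorable`/`unknown`.
#'
#' @param gm a [geno_matrix()]
#' @param def rows of [trait_marker_defs()] for one gene
#' @return tibble: `sample_id`, `gene`, `trait`, `call`,
#'   `carrier` (favorable allele / haplotype present; `NA` when
#'   undeterminable), `unfav_carrier`.
#' @export
call_trait <- function(gm, def) {
  def <- dplyr::arrange(tibble::as_tibble(def), .data$hap_index)
  if (length(unique(def$gene)) != 1) stop("def must describe a single gene")
  missing_ids <- setdiff(def$marker_id, gm$markers$marker_id)
  if (length(missing_ids)) {
    stop("trait markers absent from genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  calls <- gm$calls[, def$marker_id, drop = FALSE]
  n <- n_samples(gm)
  if (def$use[1] == "single") {
    pos <- def$positive_allele[1]; neg <- def$negative_allele[1]
    a1 <- substr(calls[, 1], 1, 1); a2 <- substr(calls[, 1], 2, 2)
    has_pos <- !is.na(calls[, 1]) & (a1 == pos | a2 == pos)
    has_neg <- !is.na(calls[, 1]) & (a1 == neg | a2 == neg)
    call <- dplyr::case_when(
      has_pos & has_neg ~ "het",
      has_pos ~ "favorable",
      has_neg ~ "unfavorable",
      .default = "unknown"
    )
    carrier <- ifelse(call == "unknown", NA, has_pos)
    unfav <- ifelse(call == "unknown", NA, has_neg)
  } else {
    class_map <- parse_class_map(def$class_map[1])
    fav <- strsplit(def$favorable_haplotypes[1] %||% "", "/")[[1]]
    unf <- strsplit(def$unfavorable_haplotypes[1] %||% "", "/")[[1]]
    marker_rows <- match(def$marker_id, gm$markers$marker_id)
    pairs <- Map(c, gm$markers$allele_ref[marker_rows],
                 gm$markers$allele_alt[marker_rows])
    call <- character(n); carrier <- rep(NA, n); unfav <- rep(NA, n)
    for (s in seq_len(n)) {
      completions <- hap_completions(calls[s, ], pairs)
      labels <- vapply(completions, function(h) {
        if (length(class_map)) {
          class_map[h] %||% NA_character_
        } else if (h %in% fav) "favorable"
        else if (h %in% unf) "unfavorable"
        else NA_character_
      }, "")
      labels_u <- unique(labels)
      if (length(labels_u) == 1 && !is.na(labels_u)) {
        call[s] <- labels_u
      } else {
        call[s] <- "unknown"
      }
      if (length(fav)) {
        carrier[s] <- if (call[s] == "unknown") NA else call[s] == "favorable"
      }
      if (length(unf)) {
        unfav[s] <- if (call[s] == "unknown") NA else call[s] == "unfavorable"
      }
    }
  }
  tibble::tibble(
    sample_id = gm$samples$sample_id,
    gene = def$gene[1], trait = def$trait[1],
    call = call, carrier = as.logical(carrier),
    unfav_carrier = as.logical(unfav)
  )
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

parse_class_map <- function(x) {
  if (is.na(x %||% NA) || !nzchar(x %||% "")) return(character(0))
  kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

# all haplotype strings consistent with the observed calls; a het component
# contributes both alleles, a missing one the marker's declared pair
hap_completions <- function(call_row, pairs) {
  alleles <- lapply(seq_along(call_row), function(j) {
    cj <- call_row[j]
    if (is.na(cj)) pairs[[j]] else unique(c(substr(cj, 1, 1), substr(cj, 2, 2)))
  })
  grid <- expand.grid(alleles, stringsAsFactors = FALSE)
  unique(apply(grid, 1, paste, collapse = ""))
}

#' Trait-marker utility
#'
#' The proportion of an assessed pool across which a marker can be used to
#' introgress the favorable allele: 100 x (samples NOT carrying the
#' favorable allele) / (samples assessed). Samples with an `unknown` call
#' are excluded from both numerator and denominator (utility measures pool
#' composition, not marker performance).
#'
#' @param calls result of [call_trait()]
#' @return utility percentage (`NA` when no call is determinate).
#' @export
marker_utility <- function(calls) {
  det <- !is.na(calls$carrier)
  if (!any(det)) return(NA_real_)
  100 * sum(!calls$carrier[det]) / sum(det)
}

#' False positive and false negative rates of a trait marker
#'
#' Computed against known donor and recipient panels:
#' FPR = 100 x (recipients WITHOUT the unfavorable allele) / (recipients);
#' FNR = 100 x (donors WITHOUT the favorable allele) / (donors).
#' Unknown calls count in the totals and in the numerators — a marker that
#' cannot classify a known donor or recipient has failed for that sample.
#'
#' @param calls result of [call_trait()]
#' @param donors,recipients disjoint, non-empty character vectors of sample
#'   ids known to carry (donors) / lack (recipients) the favorable allele
#' @return a one-row tibble: `fpr`, `fnr` (percent) and the counts behind
#'   them (`n_donors`, `n_donors_without_fav`, `n_recipients`,
#'   `n_recipients_without_unfav`).
#' @export
fpr_fnr <- function(calls, donors, recipients) {
  if (!length(donors)) stop("donor set is empty")
  if (!length(recipients)) stop("recipient set is empty")
  if (length(intersect(donors, recipients))) {
    stop("donor and recipient sets must be disjoint")
  }
  dc <- calls[match(donors, calls$sample_id), ]
  rc <- calls[match(recipients, calls$sample_id), ]
  d_without_fav <- sum(is.na(dc$carrier) | !dc$carrier)
  r_without_unfav <- sum(is.na(rc$unfav_carrier) | !rc$unfav_carrier)
  tibble::tibble(
    fpr = 100 * r_without_unfav / length(recipients),
    fnr = 100 * d_without_fav / length(donors),
    n_donors = length(donors),
    n_donors_without_fav = d_without_fav,
    n_recipients = length(recipients),
    n_recipients_without_unfav = r_without_unfav
  )
}
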