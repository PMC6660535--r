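#' Filter candidate SNPs by reference call rate and MAF
#'
#' Keeps candidates with call rate strictly above `min_call_rate` and minor
#' allele frequency at or above `min_maf` — the asymmetry (strict vs
#' inclusive) mirrors the usual panel-design rule of "call rate > 95%, MAF
#' >= 0.4" measured on a reference germplasm collection.
#'
#' @param cands tibble of candidate SNPs with numeric columns `call_rate`
#'   and `maf`
#' @param min_call_rate call-rate threshold (exclusive)
#' @param min_maf MAF threshold (inclusive)
#' @return the retained rows of `cands`.
#' @export
filter_candidates <- function(cands, min_call_rate = 0.95, min_maf = 0.4) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  dplyr::filter(tibble::as_tibble(cands),
                .data$call_rate > min_call_rate, .data$maf >= min_maf)
}

#' Fill physical gaps in a marker panel from a candidate pool
#'
#' Greedy gap filling: repeatedly find the largest remaining gap — adjacent
#' same-chromosome marker intervals, plus the half-open intervals from
#' position 1 to the first marker and from the last marker to the
#' chromosome end — and add the pool candidate closest to that gap's
#' midpoint (ties broken towards the lower position). Stops early when no
#' candidate lies inside any gap.
#'
#' @param selected tibble of selected markers (`marker_id`, `chrom`,
#'   `pos_bp`, ...)
#' @param pool tibble of candidate markers with the same columns, disjoint
#'   from `selected` by `(chrom, pos_bp)`
#' @param n_to_add number of markers to add
#' @param chrom_lengths named chromosome lengths in bp (for end gaps)
#' @return the augmented marker tibble, sorted by `(chrom, pos_bp)`.
#' @export
fill_gaps <- function(selected, pool, n_to_add,
                      chrom_lengths = rice_chrom_lengths()) {
  selected <- tibble::as_tibble(selected)
  pool <- tibble::as_tibble(pool)
  if (nrow(pool) == 0) {
    warning("empty candidate pool; panel returned unchanged")
    return(selected)
  }
  key <- function(df) paste(df$chrom, df$pos_bp)
  if (any(key(pool) %in% key(selected))) {
    stop("pool and selected markers overlap by (chrom, pos_bp)")
  }
  for (step in seq_len(n_to_add)) {
    gaps <- current_gaps(selected, chrom_lengths)
    added <- FALSE
    for (g in seq_len(nrow(gaps))) {            # largest gap first
      inside <- pool$chrom == gaps$chrom[g] &
        pool$pos_bp > gaps$start[g] & pool$pos_bp < gaps$end[g]
      if (!any(inside)) next
      mid <- (gaps$start[g] + gaps$end[g]) / 2
      cand <- pool[inside, ]
      d <- abs(cand$pos_bp - mid)
      pick <- which(d == min(d))
      pick <- pick[which.min(cand$pos_bp[pick])]  # tie -> lower position
      selected <- dplyr::bind_rows(selected, cand[pick, ])
      pool <- dplyr::anti_join(pool, cand[pick, c("chrom", "pos_bp")],
                               by = c("chrom", "pos_bp"))
      added <- TRUE
      break
    }
    if (!added) break                            # no candidate in any gap
  }
  dplyr::arrange(selected, chrom, pos_bp)
}

# all gaps (including chromosome ends), largest first
current_gaps <- function(markers, chrom_lengths) {
  purrr::map(names(chrom_lengths), function(ch) {
    pos <- sort(markers$pos_bp[markers$chrom == ch])
    bounds <- c(1, pos, chrom_lengths[[ch]])
    tibble::tibble(chrom = ch,
                   start = bounds[-length(bounds)],
                   end = bounds[-1])
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(width = .data$end - .data$start) |>
    dplyr::filter(.data$width > 0) |>
    dplyr::arrange(dplyr::desc(.data$width))
}

#' Physical and genetic spacing statistics of a marker panel
#'
#' Gaps are computed between adjacent markers within chromosomes only.
#' Genetic distances use a single genome-wide constant (default 244 kb per
#' cM); the theoretical uniform spacing `genome_length_bp / n_markers` is
#' reported alongside for comparison.
#'
#' @param panel marker tibble (`chrom`, `pos_bp`); input order is irrelevant
#' @param kb_per_cM physical-to-genetic conversion constant
#' @param genome_length_bp total genome length in bp
#' @return a list of class `spacing_stats`: `summary` (one-row tibble with
#'   `n_markers`, `mean_gap_bp`, `median_gap_bp`, `mean_gap_cM`,
#'   `sd_gap_cM`, `uniform_spacing_bp`, `uniform_spacing_cM`), `gaps`
#'   (per-gap tibble) and `largest_gaps` (gaps ranked by width).
#' @export
spacing_stats <- function(panel, kb_per_cM = 244,
                          genome_length_bp = 373245519) {
  stopifnot(kb_per_cM > 0, genome_length_bp > 0)
  panel <- dplyr::arrange(tibble::as_tibble(panel), chrom, pos_bp)
  gaps <- panel |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(start = .data$pos_bp[-dplyr::n()],
                   end = .data$pos_bp[-1]) |>
    dplyr::mutate(gap_bp = .data$end - .data$start,
                  gap_cM = .data$gap_bp / (kb_per_cM * 1000))
  if (nrow(gaps) == 0) stop("need >= 2 markers on at least one chromosome")
  single <- setdiff(unique(panel$chrom),
                    unique(panel$chrom[duplicated(panel$chrom)]))
  if (length(single)) {
    message("chromosome(s) with a single marker contribute no gaps: ",
            paste(single, collapse = ", "))
  }
  n <- nrow(panel)
  summary <- tibble::tibble(
    n_markers = n,
    mean_gap_bp = mean(gaps$gap_bp),
    median_gap_bp = stats::median(gaps$gap_bp),
    mean_gap_cM = mean(gaps$gap_cM),
    sd_gap_cM = stats::sd(gaps$gap_cM),
    uniform_spacing_bp = genome_length_bp / n,
    uniform_spacing_cM = genome_length_bp / n / (kb_per_cM * 1000)
  )
  structure(list(summary = summary, gaps = gaps,
                 largest_gaps = dplyr::arrange(gaps, dplyr::desc(gap_bp))),
            class = "spacing_stats")
}

#' @export
print.spacing_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<spacing_stats> %d markers | mean gap %.0f bp (%.3f cM, SD %.2f) | uniform %.0f bp (%.3f cM)\n",
              s$n_markers, s$mean_gap_bp, s$mean_gap_cM, s$sd_gap_cM,
              s$uniform_spacing_bp, s$uniform_spacing_cM))
  invisible(x)
}
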