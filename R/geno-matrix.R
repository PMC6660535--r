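#' Genotype matrix container
#'
#' A `geno_matrix` holds unordered diploid allele-pair calls for a set of
#' samples at a set of biallelic SNP markers, together with a marker map and
#' sample metadata. Calls are stored canonically: the two alleles of a call
#' are sorted alphabetically ("AG", never "GA"), missing is `NA`.
#'
#' @param calls character matrix (samples x markers) of two-letter genotype
#'   calls ("AA", "AG", ...) or `NA` for missing. Row and column names are
#'   taken from `samples` and `markers` if absent.
#' @param markers tibble with at least `marker_id`, `chrom`, `pos_bp`,
#'   `allele_ref`, `allele_alt`. Extra columns (e.g. `source`, `gene`,
#'   `maf`) are carried along. Markers are sorted by `(chrom, pos_bp)`.
#' @param samples tibble with at least `sample_id`; optional metadata columns
#'   `accession`, `subpop`, `rep_group`, `family` are created (as `NA`) when
#'   absent.
#'
#' @details Calls whose alleles fall outside the marker's declared allele
#' pair are not dropped: they are retained and recorded in the violations
#' report available through [allele_violations()].
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers, samples) {
  markers <- tibble::as_tibble(markers)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("marker_id", "chrom", "pos_bp", "allele_ref", "allele_alt") %in% names(markers)),
    "sample_id" %in% names(samples)
  )
  if (anyDuplicated(markers[c("chrom", "pos_bp")])) {
    dup <- markers[duplicated(markers[c("chrom", "pos_bp")]), ]
    stop("duplicate (chrom, pos_bp) markers: ",
         paste(dup$chrom, dup$pos_bp, sep = ":", collapse = ", "))
  }
  if (any(markers$allele_ref == markers$allele_alt)) {
    stop("marker alleles must be distinct")
  }
  if (any(markers$pos_bp < 1)) stop("positions are 1-based: pos_bp >= 1")
  for (col in c("accession", "subpop", "rep_group", "family")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  if (is.na(samples$accession[1]) && nrow(samples) > 0) {
    samples$accession <- dplyr::coalesce(samples$accession, samples$sample_id)
  }
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers)) {
    stop("calls must be ", nrow(samples), " x ", nrow(markers),
         ", got ", nrow(calls), " x ", ncol(calls))
  }
  ord <- order(markers$chrom, markers$pos_bp)
  markers <- markers[ord, ]
  calls <- calls[, ord, drop = FALSE]
  calls <- canonicalize_calls(calls)
  rownames(calls) <- samples$sample_id
  colnames(calls) <- markers$marker_id
  gm <- structure(
    list(calls = calls, markers = markers, samples = samples),
    class = "geno_matrix"
  )
  attr(gm, "violations") <- find_violations(gm)
  gm
}

# sort each two-letter call's alleles alphabetically; normalize missing codes
canonicalize_calls <- function(calls) {
  x <- calls
  x[x %in% c("NN", "N", "--", "")] <- NA_character_
  idx <- which(!is.na(x))
  if (length(idx)) {
    v <- x[idx]
    a <- substr(v, 1L, 1L)
    b <- substr(v, 2L, 2L)
    swap <- b < a
    v[swap] <- paste0(b[swap], a[swap])
    x[idx] <- v
  }
  x
}

find_violations <- function(gm) {
  out <- vector("list", n_markers(gm))
  for (j in seq_len(n_markers(gm))) {
    ok <- c(gm$markers$allele_ref[j], gm$markers$allele_alt[j])
    cj <- gm$calls[, j]
    bad <- !is.na(cj) &
      !(substr(cj, 1, 1) %in% ok & substr(cj, 2, 2) %in% ok)
    if (any(bad)) {
      out[[j]] <- tibble::tibble(
        marker_id = gm$markers$marker_id[j],
        sample_id = gm$samples$sample_id[bad],
        call = cj[bad]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Report calls whose alleles fall outside the marker's declared pair
#'
#' @param gm a [geno_matrix()]
#' @return tibble with columns `marker_id`, `sample_id`, `call` (zero rows
#'   when the matrix is clean).
#' @export
allele_violations <- function(gm) {
  v <- attr(gm, "violations")
  if (is.null(v)) v <- find_violations(gm)
  v
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", n_samples(x), " samples x ", n_markers(x),
      " markers\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing: ", sprintf("%.2f%%", 100 * miss), sep = "")
  nv <- nrow(allele_violations(x))
  if (nv > 0) cat("  | ", nv, " allele violations", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of markers / samples in a genotype matrix
#' @param gm a [geno_matrix()]
#' @return integer count.
#' @export
n_markers <- function(gm) nrow(gm$markers)

#' @rdname n_markers
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' Marker map and sample metadata as tibbles
#' @param gm a [geno_matrix()]
#' @return a tibble (one row per marker, resp. per sample).
#' @export
marker_info <- function(gm) gm$markers

#' @rdname marker_info
#' @export
sample_info <- function(gm) gm$samples

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()]
#' @param i sample selector (indices, logical, or sample ids)
#' @param j marker selector (indices, logical, or marker ids)
#' @param ... unused
#' @return a [geno_matrix()] restricted to the selection.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_markers(x))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$markers$marker_id)
  if (anyNA(i) || anyNA(j)) stop("unknown sample or marker id in subset")
  geno_matrix(
    calls = x$calls[i, j, drop = FALSE],
    markers = x$markers[j, ],
    samples = x$samples[i, ]
  )
}

#' Dosage coding of a genotype matrix
#'
#' Counts the marker's alternate allele per call: homozygous reference = 0,
#' heterozygous = 1, homozygous alternate = 2, missing (or a call outside
#' the declared allele pair) = `NA`.
#'
#' @param gm a [geno_matrix()]
#' @return numeric matrix (samples x markers).
#' @export
dosage <- function(gm) {
  D <- matrix(NA_real_, n_samples(gm), n_markers(gm),
              dimnames = dimnames(gm$calls))
  for (j in seq_len(n_markers(gm))) {
    alt <- gm$markers$allele_alt[j]
    ref <- gm$markers$allele_ref[j]
    cj <- gm$calls[, j]
    d <- (substr(cj, 1, 1) == alt) + (substr(cj, 2, 2) == alt)
    ok <- substr(cj, 1, 1) %in% c(ref, alt) & substr(cj, 2, 2) %in% c(ref, alt)
    d[!ok] <- NA_real_
    D[, j] <- d
  }
  D
}

#' Rebuild two-letter calls from a dosage matrix
#'
#' Inverse of [dosage()] for complete biallelic data; used by the imputation
#' routines to write predicted dosages back as genotype calls.
#'
#' @param D numeric matrix of dosages in \{0, 1, 2\} (NA allowed)
#' @param markers marker tibble aligned to the columns of `D`
#' @return character matrix of canonical calls.
#' @export
calls_from_dosage <- function(D, markers) {
  out <- matrix(NA_character_, nrow(D), ncol(D), dimnames = dimnames(D))
  for (j in seq_len(ncol(D))) {
    ref <- markers$allele_ref[j]
    alt <- markers$allele_alt[j]
    g <- c(paste0(ref, ref),
           paste0(min(ref, alt), max(ref, alt)),
           paste0(alt, alt))
    dj <- D[, j]
    ok <- !is.na(dj)
    out[ok, j] <- g[dj[ok] + 1L]
  }
  out
}

#' Combine genotype matrices by stacking samples
#'
#' All inputs must share an identical marker map.
#' @param ... two or more [geno_matrix()] objects
#' @return a [geno_matrix()] with the samples of all inputs.
#' @export
bind_geno <- function(...) {
  gms <- list(...)
  m0 <- gms[[1]]$markers
  for (g in gms[-1]) {
    if (!identical(g$markers[c("marker_id", "chrom", "pos_bp")],
                   m0[c("marker_id", "chrom", "pos_bp")])) {
      stop("genotype matrices have different marker maps")
    }
  }
  geno_matrix(
    calls = do.call(rbind, lapply(gms, function(g) g$calls)),
    markers = m0,
    samples = dplyr::bind_rows(lapply(gms, function(g) g$samples))
  )
}
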