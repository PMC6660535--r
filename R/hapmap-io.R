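#' Read a HapMap genotype table
#'
#' Parses the standard tab-delimited HapMap layout: 11 header columns
#' (`rs#, alleles, chrom, pos, strand, assembly#, center, protLSID,
#' assayLSID, panel, QCcode`) followed by one column per sample. Two
#' genotype dialects are supported: `"two-letter"` ("AA", "AG", "NN") and
#' `"iupac"` single-letter codes (hets R/Y/S/W/K/M, missing "N").
#'
#' @param path file path
#' @param dialect one of `"auto"`, `"two-letter"`, `"iupac"`. `"auto"`
#'   inspects call widths.
#' @return a [geno_matrix()], markers sorted by `(chrom, pos_bp)`. Missing
#'   codes `"NN"`, `"N"` and `"--"` all decode to `NA`. Calls with alleles
#'   outside the declared pair are kept and reported via
#'   [allele_violations()] with a warning.
#' @export
read_hapmap <- function(path, dialect = c("auto", "two-letter", "iupac")) {
  dialect <- match.arg(dialect)
  hd <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hd) < 11L || hd[1] != "rs#" || hd[2] != "alleles" ||
      hd[3] != "chrom" || hd[4] != "pos") {
    stop("malformed HapMap header: expected 'rs#', 'alleles', 'chrom', 'pos', ... got: ",
         paste(utils::head(hd, 4), collapse = ", "))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  sample_ids <- names(raw)[-(1:11)]
  al <- strsplit(raw$alleles, "/", fixed = TRUE)
  if (any(lengths(al) != 2L)) stop("alleles column must be of the form 'A/G'")
  markers <- tibble::tibble(
    marker_id = raw$`rs#`,
    chrom = raw$chrom,
    pos_bp = as.integer(raw$pos),
    allele_ref = vapply(al, `[`, "", 1L),
    allele_alt = vapply(al, `[`, "", 2L)
  )
  if (anyNA(markers$pos_bp)) stop("non-integer positions in HapMap 'pos' column")
  calls_raw <- t(as.matrix(raw[, sample_ids, drop = FALSE]))  # samples x markers
  if (dialect == "auto") {
    w <- nchar(calls_raw)
    dialect <- if (any(w == 2L & calls_raw != "NN" & calls_raw != "--", na.rm = TRUE))
      "two-letter" else "iupac"
  }
  calls <- if (dialect == "iupac") decode_iupac(calls_raw) else calls_raw
  gm <- geno_matrix(calls, markers,
                    tibble::tibble(sample_id = sample_ids))
  nv <- nrow(allele_violations(gm))
  if (nv > 0) {
    warning(nv, " call(s) outside the declared allele pair; see allele_violations()")
  }
  gm
}

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

decode_iupac <- function(x) {
  out <- x
  out[x %in% c("N", "-", "--", "NN", "")] <- NA_character_
  for (code in names(IUPAC_HET)) out[x == code] <- IUPAC_HET[[code]]
  hom <- x %in% c("A", "C", "G", "T")
  out[hom] <- paste0(x[hom], x[hom])
  out
}

encode_iupac <- function(x) {
  out <- x
  out[is.na(x)] <- "N"
  for (code in names(IUPAC_HET)) out[x == IUPAC_HET[[code]]] <- code
  hom <- !is.na(x) & substr(x, 1, 1) == substr(x, 2, 2)
  out[hom] <- substr(x[hom], 1, 1)
  out
}

#' Write a genotype matrix as a HapMap table
#'
#' Output is bit-stable for a fixed input: markers are written in canonical
#' `(chrom, pos_bp)` order and samples in their stored order. Missing calls
#' are written as `"NN"` (two-letter dialect) or `"N"` (IUPAC).
#'
#' @param gm a [geno_matrix()]
#' @param path output file path
#' @param dialect `"two-letter"` or `"iupac"`
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path, dialect = c("two-letter", "iupac")) {
  dialect <- match.arg(dialect)
  calls <- gm$calls
  enc <- if (dialect == "iupac") encode_iupac(calls) else {
    calls[is.na(calls)] <- "NN"
    calls
  }
  header <- tibble::tibble(
    `rs#` = gm$markers$marker_id,
    alleles = paste(gm$markers$allele_ref, gm$markers$allele_alt, sep = "/"),
    chrom = gm$markers$chrom,
    pos = gm$markers$pos_bp,
    strand = "+", `assembly#` = "MSU7", center = NA_character_,
    protLSID = NA_character_, assayLSID = NA_character_,
    panel = NA_character_, QCcode = NA_character_
  )
  body <- tibble::as_tibble(t(enc), .name_repair = "minimal")
  names(body) <- gm$samples$sample_id
  readr::write_tsv(dplyr::bind_cols(header, body), path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Read (or coerce) a pedigree
#'
#' A pedigree is a tibble of `(id, sire, dam)` rows; founders have `NA`
#' parents. The result is topologically ordered (parents before offspring).
#' Parents referenced but never listed as individuals are added as founders
#' with a warning; cycles are an error.
#'
#' @param path CSV file with columns `id`, `sire`, `dam` (missing parents as
#'   empty fields, `NA`, `"-"` or `"0"`).
#' @return a tibble of class `pedigree`, topologically sorted.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  names(df)[1:3] <- c("id", "sire", "dam")
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param df data frame with columns `id`, `sire`, `dam`
#' @export
as_pedigree <- function(df) {
  df <- tibble::as_tibble(df)[, c("id", "sire", "dam")]
  for (col in c("sire", "dam")) {
    df[[col]][df[[col]] %in% c("", "-", "0", "NA")] <- NA_character_
  }
  if (anyDuplicated(df$id)) stop("duplicate individual ids in pedigree")
  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(parents)) {
    warning("unknown parent id(s) added as founders: ",
            paste(parents, collapse = ", "))
    df <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_),
      df
    )
  }
  # Kahn's algorithm: repeatedly emit individuals whose parents are emitted
  emitted <- character(0)
  remaining <- df
  out <- df[0, ]
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% emitted) &
      (is.na(remaining$dam) | remaining$dam %in% emitted)
    if (!any(ready)) {
      stop("pedigree contains a cycle involving: ",
           paste(utils::head(remaining$id, 5), collapse = ", "))
    }
    out <- dplyr::bind_rows(out, remaining[ready, ])
    emitted <- c(emitted, remaining$id[ready])
    remaining <- remaining[!ready, ]
  }
  class(out) <- c("pedigree", class(out))
  out
}
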