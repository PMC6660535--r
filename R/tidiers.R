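#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for ricepanel result objects
#'
#' `tidy()` returns the per-unit records of a result (per sample, marker,
#' pair, or model repeat); `glance()` returns a one-row summary.
#'
#' @param x a ricepanel result object
#' @param ... unused
#' @return a tibble.
#' @name ricepanel-tidiers
NULL

#' @rdname ricepanel-tidiers
#' @export
tidy.geno_pca <- function(x, ...) x$scores

#' @rdname ricepanel-tidiers
#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_markers = x$preprocessing$n_markers_used,
    pc1_var = x$var_explained[1],
    pc2_var = x$var_explained[2],
    scaled = x$preprocessing$scaled
  )
}

#' @rdname ricepanel-tidiers
#' @export
tidy.gs_cv <- function(x, ...) x$results

#' @rdname ricepanel-tidiers
#' @export
glance.gs_cv <- function(x, ...) {
  tibble::tibble(
    k = x$settings$k, repeats = x$settings$repeats,
    n_models = nrow(x$summary),
    mean_r_across_models = mean(x$summary$mean_r)
  )
}

#' @rdname ricepanel-tidiers
#' @export
tidy.repeatability <- function(x, ...) x$per_locus

#' @rdname ricepanel-tidiers
#' @export
glance.repeatability <- function(x, ...) {
  tibble::tibble(R = x$overall_R, mean_e_l = x$mean_e_l,
                 n_accessions = x$n_accessions)
}

#' @rdname ricepanel-tidiers
#' @export
tidy.concordance <- function(x, ...) x$per_sample

#' @rdname ricepanel-tidiers
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(concordance = x$overall,
                 n_overlap_markers = x$n_overlap_markers,
                 n_compared = x$n_compared, n_matches = x$n_matches)
}

#' @rdname ricepanel-tidiers
#' @export
tidy.pairwise_poly <- function(x, ...) x$pairs

#' @rdname ricepanel-tidiers
#' @export
glance.pairwise_poly <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 mean_polymorphic = mean(x$pairs$n_polymorphic),
                 median_polymorphic = stats::median(x$pairs$n_polymorphic))
}

#' @rdname ricepanel-tidiers
#' @export
tidy.mixed_fit <- function(x, ...) x$estimates

#' @rdname ricepanel-tidiers
#' @export
glance.mixed_fit <- function(x, ...) {
  out <- tidyr::pivot_wider(x$varcomp, names_from = "component",
                            values_from = "variance")
  out$t <- x$t
  out$r <- x$r
  if (x$genotype_as == "random") out$H2 <- heritability(x)
  tibble::as_tibble(out)
}

#' @rdname ricepanel-tidiers
#' @export
tidy.spacing_stats <- function(x, ...) x$gaps

#' @rdname ricepanel-tidiers
#' @export
glance.spacing_stats <- function(x, ...) x$summary

#' @rdname ricepanel-tidiers
#' @export
tidy.f1_result <- function(x, ...) x$per_f1

#' @rdname ricepanel-tidiers
#' @export
glance.f1_result <- function(x, ...) {
  tibble::tibble(n_f1 = nrow(x$per_f1), n_crosses = nrow(x$per_cross),
                 mean_similarity = x$mean_similarity)
}
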