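#' Predict the F1 genotype of a cross
#'
#' Per locus: two homozygous parents with different alleles give the
#' heterozygote, identical homozygotes give that homozygote, and a locus
#' where either parent is heterozygous or missing is set missing (the
#' prediction is only defined from homozygous parental haplotypes).
#'
#' @param gm a [geno_matrix()] containing both parents
#' @param parent1,parent2 parental sample ids
#' @return a one-row [geno_matrix()] for the predicted F1.
#' @export
predict_f1 <- function(gm, parent1, parent2) {
  f1 <- predict_f1_calls(gm$calls[parent1, ], gm$calls[parent2, ])
  geno_matrix(matrix(f1, 1), gm$markers,
              tibble::tibble(sample_id = paste0("predF1_", parent1, "x", parent2),
                             family = paste0(parent1, "x", parent2)))
}

predict_f1_calls <- function(c1, c2) {
  out <- rep(NA_character_, length(c1))
  ok <- !is.na(c1) & !is.na(c2) & !is_het(c1) & !is_het(c2)
  a1 <- substr(c1, 1, 1); a2 <- substr(c2, 1, 1)
  out[ok] <- paste0(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]))
  out
}

#' Concordance between predicted and observed F1 genotypes
#'
#' Exact-match percentage over loci where both the predicted and the
#' observed call are non-missing.
#'
#' @param predicted,observed genotype call vectors (or one-row
#'   [geno_matrix()] objects) over the same markers
#' @return percentage in `[0, 100]`; `NA` if no locus is comparable.
#' @export
f1_concordance <- function(predicted, observed) {
  p <- as_call_vector(predicted)
  o <- as_call_vector(observed)
  stopifnot(length(p) == length(o))
  comp <- !is.na(p) & !is.na(o)
  if (!any(comp)) return(NA_real_)
  100 * sum(p[comp] == o[comp]) / sum(comp)
}

as_call_vector <- function(x) {
  if (inherits(x, "geno_matrix")) {
    stopifnot(n_samples(x) == 1)
    return(x$calls[1, ])
  }
  x
}

#' Count markers polymorphic between two parents
#'
#' Loci where both parents carry non-missing, homozygous, and different
#' genotypes. Equal to the number of heterozygous loci in the predicted F1.
#'
#' @param gm a [geno_matrix()]
#' @param parent1,parent2 parental sample ids
#' @return integer count.
#' @export
count_polymorphic <- function(gm, parent1, parent2) {
  c1 <- gm$calls[parent1, ]; c2 <- gm$calls[parent2, ]
  ok <- !is.na(c1) & !is.na(c2) & !is_het(c1) & !is_het(c2)
  sum(ok & c1 != c2)
}

#' Validate F1 plants against their predicted genotypes
#'
#' For every cross: builds the predicted F1 from the parents, scores each
#' F1 plant's concordance with it, and counts the cross' polymorphic
#' markers. Per-cross similarity is the macro-average over that cross' F1
#' plants.
#'
#' @param gm a [geno_matrix()] containing parents and F1 plants
#' @param crosses tibble with columns `cross_id`, `parent1`, `parent2`,
#'   `f1_ids` (list-column of F1 sample ids)
#' @return a list of class `f1_result`: `per_f1` tibble (`cross_id`,
#'   `sample_id`, `similarity`), `per_cross` tibble (`cross_id`,
#'   `parent1`, `parent2`, `n_polymorphic`, `n_f1`, `mean_similarity`),
#'   and the overall `mean_similarity` across all F1 plants.
#' @export
f1_validation <- function(gm, crosses) {
  crosses <- tibble::as_tibble(crosses)
  per_f1 <- purrr::pmap(crosses, function(cross_id, parent1, parent2, f1_ids) {
    pred <- predict_f1_calls(gm$calls[parent1, ], gm$calls[parent2, ])
    tibble::tibble(
      cross_id = cross_id,
      sample_id = f1_ids,
      similarity = vapply(f1_ids,
                          function(id) f1_concordance(pred, gm$calls[id, ]),
                          numeric(1))
    )
  }) |> dplyr::bind_rows()
  per_cross <- crosses |>
    dplyr::mutate(
      n_polymorphic = purrr::map2_int(.data$parent1, .data$parent2,
                                      ~count_polymorphic(gm, .x, .y)),
      n_f1 = lengths(.data$f1_ids)
    ) |>
    dplyr::select(-"f1_ids") |>
    dplyr::left_join(
      per_f1 |>
        dplyr::group_by(.data$cross_id) |>
        dplyr::summarise(mean_similarity = mean(.data$similarity, na.rm = TRUE),
                         .groups = "drop"),
      by = "cross_id"
    )
  structure(list(per_f1 = per_f1, per_cross = per_cross,
                 mean_similarity = mean(per_f1$similarity, na.rm = TRUE)),
            class = "f1_result")
}

#' @export
print.f1_result <- function(x, ...) {
  cat(sprintf("<f1_result> %d F1 plants in %d crosses | mean similarity %.2f%%\n",
              nrow(x$per_f1), nrow(x$per_cross), x$mean_similarity))
  print(x$per_cross)
  invisible(x)
}
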