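#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a MORPH result into its ranked candidate table
#'
#' @param x A `morph_result`.
#' @param ... Unused.
#' @return Tibble with `term_id`, `config_id`, `gene_id`, `module_id`,
#'   `raw_score`, `z`, `rank`.
#' @method tidy morph_result
#' @export
tidy.morph_result <- function(x, ...) {
  dplyr::mutate(x$candidates, term_id = x$term_id,
                config_id = x$chosen_config_id, .before = 1L)
}

#' One-row summary of a MORPH result
#'
#' @param x A `morph_result`.
#' @param ... Unused.
#' @return Tibble with `term_id`, `chosen_config_id`, `n_baits_used`,
#'   `n_scored` (baits with a self-rank), `n_candidates`, `ausr`.
#' @export
glance.morph_result <- function(x, ...) {
  tibble(term_id = x$term_id, chosen_config_id = x$chosen_config_id,
         n_baits_used = x$n_baits_used,
         n_scored = sum(!is.na(x$self_ranks)),
         n_candidates = nrow(x$candidates),
         ausr = x$ausr)
}

#' @method tidy bulk_result
#' @export
tidy.bulk_result <- function(x, ...) x$summary

#' @method glance bulk_result
#' @export
glance.bulk_result <- function(x, ...) {
  tibble(n_terms = nrow(x$summary),
         n_ok = sum(x$summary$status == "ok"),
         n_failed = sum(x$summary$status != "ok"),
         n_p_lt_0.05 = sum(x$summary$p_value < 0.05, na.rm = TRUE),
         n_q_lt_0.05 = sum(x$summary$q_value < 0.05, na.rm = TRUE))
}

#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tidyr::unnest(tibble(size = x$sizes, ausr = x$values), "ausr")
}

#' Self-rank curve of a MORPH result
#'
#' Plots, for increasing rank threshold t, the fraction of bait genes whose
#' LOOCV self-rank is at most t; the area under this curve is the AUSR.
#'
#' @param object A `morph_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot morph_result
#' @export
autoplot.morph_result <- function(object, ...) {
  t <- seq_len(object$r_max)
  r <- object$self_ranks
  frac <- vapply(t, function(tt) mean(!is.na(r) & r <= tt), numeric(1))
  ggplot2::ggplot(tibble(threshold = t, fraction = frac),
                  ggplot2::aes(x = .data$threshold, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "rank threshold", y = "fraction of baits recovered",
                  title = sprintf("%s  (AUSR = %.3f, config %s)", object$term_id,
                                  object$ausr, object$chosen_config_id))
}

#' AUSR null distributions per bait-set size
#'
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @return A ggplot object (histograms faceted by size).
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy.null_distribution(object),
                  ggplot2::aes(x = .data$ausr)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~size) +
    ggplot2::labs(x = "AUSR under random bait sets", y = "count")
}

#' Histogram of AUSR values from a bulk run
#'
#' @param object A `bulk_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bulk_result
#' @export
autoplot.bulk_result <- function(object, ...) {
  ok <- object$summary[object$summary$status == "ok", , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$ausr,
                                   fill = .data$p_value < 0.05)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "AUSR", y = "terms", fill = "p < 0.05")
}
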