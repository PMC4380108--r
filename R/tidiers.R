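# broom-style accessors and ggplot2 autoplot methods for result objects.

#' Tidy the per-iteration trace of an assembly run
#'
#' @param x A `genefish_result` from [run_genefish()].
#' @param ... Unused.
#' @return One row per iteration: `iteration`, `n_hits`, `n_pairs_in_pool`,
#'   `n_contigs`, `n_kept`, `best_score`, `best_length`, `status`.
#' @export
tidy.genefish_result <- function(x, ...) {
  bind_rows(lapply(x$trace, function(r) {
    kept <- r$kept_contigs
    tibble(iteration = r$iteration, n_hits = r$n_hits,
           n_pairs_in_pool = r$n_pairs_in_pool,
           n_contigs = nrow(r$contigs), n_kept = nrow(kept),
           best_score = if (nrow(kept)) max(kept$score) else NA_integer_,
           best_length = if (nrow(kept)) kept$length[which.max(kept$score)]
                         else NA_integer_,
           status = r$status)
  }))
}

#' One-row summary of an assembly run
#'
#' @param x A `genefish_result`.
#' @param ... Unused.
#' @return A one-row tibble: `target_id`, `termination`, `iterations`,
#'   `n_final_contigs`, `best_length`, `best_score`.
#' @export
glance.genefish_result <- function(x, ...) {
  tibble(target_id = x$target_id, termination = x$termination,
         iterations = length(x$trace),
         n_final_contigs = if (is.null(x$final_contigs)) 0L else nrow(x$final_contigs),
         best_length = x$best_contig$length %||% NA_integer_,
         best_score = x$best_contig$score %||% NA_integer_)
}

#' Plot contig growth across iterations
#'
#' Best kept-contig length and score per iteration of one assembly run.
#' @param object A `genefish_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genefish_result <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$best_length)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2.5) +
    ggplot2::labs(x = "iteration", y = "best kept contig length (bp)",
                  title = paste0("target ", object$target_id, " (",
                                 object$termination, ")")) +
    ggplot2::theme_minimal()
}

#' Plot an assembly grid as a status tile map
#'
#' @param object A `genefish_grid` from [assembly_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genefish_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$target_id, y = .data$sample_id,
                                       fill = .data$termination)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "target", y = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
glance.genefish_grid <- function(x, ...) {
  tibble(n_samples = length(unique(x$sample_id)),
         n_targets = length(unique(x$target_id)),
         n_cells = nrow(x),
         n_complete = sum(x$termination %in% c("autocomplete", "converged")),
         n_no_hits = sum(x$termination == "no_hits"),
         n_errors = sum(x$termination == "error"))
}
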