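#' Compare Jaccard-index distributions across cell groups
#'
#' Non-parametric comparison of genomic-imbalance (JI) values between CTC
#' groups: a Kruskal-Wallis test when more than two groups are present, and
#' a two-sided Mann-Whitney U test for every unordered group pair. The
#' Mann-Whitney p-value is exact (complete enumeration, ties included) when
#' both groups have at most 8 cells, otherwise the tie-corrected normal
#' approximation.
#'
#' @param ji Tibble with a `summary_ji` column plus the grouping columns
#'   (as from [ji_table()]).
#' @param grouping One of `"time_point"`, `"outcome"`,
#'   `"time_point_outcome"` (the interaction).
#' @param value Name of the value column (default `"summary_ji"`).
#' @return An object of class `ji_comparison` with elements `grouping`,
#'   `groups` (tibble `group`, `n`, `median`, `iqr`), `kw_p` (`NA` unless
#'   more than two groups) and `pairwise` (tibble `group_a`, `group_b`,
#'   `mw_p`).
#' @export
compare_groups <- function(ji, grouping = c("time_point", "outcome",
                                            "time_point_outcome"),
                           value = "summary_ji") {
  grouping <- match.arg(grouping)
  g <- if (grouping == "time_point_outcome") {
    paste(ji$time_point, ji$outcome, sep = ".")
  } else {
    ji[[grouping]]
  }
  x <- ji[[value]]
  keep <- !is.na(g) & !is.na(x)
  g <- g[keep]
  x <- x[keep]
  sizes <- table(g)
  if (any(sizes == 0)) {
    warn(paste("dropping empty group(s):",
               paste(names(sizes)[sizes == 0], collapse = ", ")))
  }
  levels <- names(sizes)[sizes > 0]
  if (length(levels) < 2) stop_ctcna("need at least 2 non-empty groups")

  groups <- tibble(
    group = levels,
    n = as.integer(sizes[levels]),
    median = purrr::map_dbl(levels, ~ stats::median(x[g == .x])),
    iqr = purrr::map_dbl(levels, ~ stats::IQR(x[g == .x]))
  )
  kw_p <- if (length(levels) > 2) {
    stats::kruskal.test(x, factor(g))$p.value
  } else {
    NA_real_
  }
  pairs <- utils::combn(levels, 2)
  pairwise <- tibble(
    group_a = pairs[1, ],
    group_b = pairs[2, ],
    mw_p = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                           ~ rank_sum_p(x[g == .x], x[g == .y]))
  )
  structure(
    list(grouping = grouping, groups = groups, kw_p = kw_p,
         pairwise = pairwise),
    class = "ji_comparison"
  )
}

#' @export
print.ji_comparison <- function(x, ...) {
  cat("<ji_comparison> by ", x$grouping, "\n", sep = "")
  print(x$groups)
  if (!is.na(x$kw_p)) cat("Kruskal-Wallis p =", signif(x$kw_p, 3), "\n")
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `ji_comparison` object.
#' @param ... Unused.
#' @method tidy ji_comparison
#' @export
tidy.ji_comparison <- function(x, ...) {
  mutate(x$pairwise, grouping = x$grouping, .before = 1)
}

#' @rdname compare_groups
#' @method glance ji_comparison
#' @export
glance.ji_comparison <- function(x, ...) {
  tibble(grouping = x$grouping, n_groups = nrow(x$groups),
         n_cells = sum(x$groups$n), kw_p = x$kw_p,
         min_pairwise_p = min(x$pairwise$mw_p))
}

#' Summarize JI distributions per group, optionally exporting a violin plot
#'
#' @param ji JI tibble (see [compare_groups()]).
#' @param grouping Grouping column, as in [compare_groups()].
#' @param value Value column (default `"summary_ji"`).
#' @param plot_file Optional path (`.svg` or `.png`) to write a violin plot.
#' @return Tibble `group`, `n`, `median`, `iqr` (empty for empty input; no
#'   plot is written then).
#' @export
summarize_distribution <- function(ji, grouping = "time_point",
                                   value = "summary_ji", plot_file = NULL) {
  if (nrow(ji) == 0) {
    return(tibble(group = character(), n = integer(), median = numeric(),
                  iqr = numeric()))
  }
  g <- if (grouping == "time_point_outcome") {
    paste(ji$time_point, ji$outcome, sep = ".")
  } else {
    ji[[grouping]]
  }
  x <- ji[[value]]
  keep <- !is.na(g) & !is.na(x)
  df <- tibble(group = g[keep], value = x[keep])
  out <- df |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), median = stats::median(.data$value),
              iqr = stats::IQR(.data$value), .groups = "drop")
  if (!is.null(plot_file)) {
    p <- ji_violin(df)
    save_plot(p, plot_file)
  }
  out
}

ji_violin <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_violin(scale = "width", trim = TRUE, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.08, size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Jaccard index (1 = diploid-like)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

save_plot <- function(p, path, width = 6, height = 4) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    svg = grDevices::svg,
    png = function(filename, width, height)
      grDevices::png(filename, width = width, height = height,
                     units = "in", res = 150),
    pdf = grDevices::pdf,
    stop_ctcna("unsupported plot format: .", ext)
  )
  dev(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Violin plot of JI distributions
#'
#' @param object A JI tibble (e.g. from [ji_table()]).
#' @param grouping Grouping column, as in [compare_groups()].
#' @param value Value column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ji <- function(object, grouping = "time_point", value = "summary_ji",
                    ...) {
  g <- if (grouping == "time_point_outcome") {
    paste(object$time_point, object$outcome, sep = ".")
  } else {
    object[[grouping]]
  }
  keep <- !is.na(g) & !is.na(object[[value]])
  ji_violin(tibble(group = g[keep], value = object[[value]][keep]))
}
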