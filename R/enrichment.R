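#' Enrichment trend: regression slope of abundance over cycles
#'
#' The screen's ranking statistic: the ordinary least-squares slope of a
#' variant's percentage abundance against the cycle index 0, 1, ..., C-1
#' (cycle 0 = unsorted input library). Cycles where the variant went
#' undetected contribute abundance 0 — no pseudocounts, since this is a
#' slope on the percentage scale, not a log fold change.
#'
#' @param abundances Numeric vector of per-cycle percentage abundances in
#'   cycle order (length >= 2).
#' @return The OLS slope, in percentage points per cycle.
#' @examples
#' enrichment_trend(c(10, 20, 30))  # 10
#' @export
enrichment_trend <- function(abundances) {
  n <- length(abundances)
  if (n < 2) abort("Need at least 2 cycles to compute a trend.")
  x <- seq_len(n) - 1
  xc <- x - mean(x)
  sum(xc * (abundances - mean(abundances))) / sum(xc^2)
}

#' Rank variants by enrichment trend
#'
#' Computes every variant's enrichment-trend slope from a long abundance
#' table and ranks them in descending slope order. Ties are broken by larger
#' final-cycle abundance, then lexicographic variant id, so the ranking is
#' deterministic. OFF-screens use the same descending order: enrichment of
#' the desired behavior is always "up".
#'
#' @param abundance Long tibble `variant_id`, `cycle`, `abundance` from
#'   [abundance_matrix()] (cycle a factor in screen order, or sortable
#'   labels); missing (variant, cycle) pairs count as abundance 0.
#' @return An `enrichment_ranking` tibble: `variant_id`, `slope`,
#'   `cycles_detected`, `final_abundance`, `rank` (1 = steepest).
#' @export
rank_variants <- function(abundance) {
  stopifnot(all(c("variant_id", "cycle", "abundance") %in% names(abundance)))
  cyc <- if (is.factor(abundance$cycle)) abundance$cycle else
    factor(abundance$cycle, levels = sort(unique(abundance$cycle)))
  n_cycles <- nlevels(cyc)
  if (n_cycles < 2) abort("Need at least 2 cycles to rank variants.")
  x <- seq_len(n_cycles) - 1
  xc <- x - mean(x)
  sxx <- sum(xc^2)

  # dense variant x cycle matrix of abundances (absent pairs = 0)
  vid <- factor(abundance$variant_id)
  m <- matrix(0, nlevels(vid), n_cycles,
              dimnames = list(levels(vid), levels(cyc)))
  m[cbind(as.integer(vid), as.integer(cyc))] <- abundance$abundance

  slope <- as.vector(m %*% xc) / sxx
  res <- tibble(
    variant_id = rownames(m),
    slope = slope,
    cycles_detected = as.integer(rowSums(m > 0)),
    final_abundance = m[, n_cycles]
  ) |>
    arrange(desc(.data$slope), desc(.data$final_abundance),
            .data$variant_id) |>
    mutate(rank = dplyr::row_number())
  class(res) <- c("enrichment_ranking", class(res))
  res
}

#' Per-cycle detection coverage and dropout
#'
#' Reports how many variants are detected (count >= 1) in each cycle, and
#' which variants disappear as sorting proceeds: for a complete initial
#' library all variants are detected in cycle 0, and stringent sorting then
#' drives losers out of later cycles.
#'
#' @param counts Long count table from [count_variants()].
#' @param design Optional [library_design()]; adds the design-space size so
#'   completeness is visible.
#' @return A list with `detected` (tibble `cycle`, `n_detected`, and
#'   `design_space` if a design is given) and `dropouts` (tibble
#'   `variant_id`, `last_seen`: variants absent from the final cycle that
#'   were seen earlier).
#' @export
coverage_report <- function(counts, design = NULL) {
  detected <- counts |>
    group_by(.data$cycle) |>
    summarise(n_detected = sum(.data$count > 0), .groups = "drop")
  if (!is.null(design)) detected$design_space <- design_space_size(design)

  cyc_levels <- levels(factor(counts$cycle))
  last <- counts |>
    dplyr::filter(.data$count > 0) |>
    mutate(cycle_idx = as.integer(factor(.data$cycle, levels = cyc_levels))) |>
    group_by(.data$variant_id) |>
    summarise(last_seen = cyc_levels[max(.data$cycle_idx)],
              last_idx = max(.data$cycle_idx), .groups = "drop")
  dropouts <- last |>
    dplyr::filter(.data$last_idx < length(cyc_levels)) |>
    select("variant_id", "last_seen") |>
    arrange(.data$variant_id)
  list(detected = detected, dropouts = dropouts)
}

#' Plot abundance trajectories of top-ranked variants
#'
#' @param abundance Long abundance tibble (as for [rank_variants()]).
#' @param ranking Optional [rank_variants()] result (recomputed otherwise).
#' @param top Number of top-ranked variants to highlight.
#' @return A ggplot: abundance vs cycle, top variants coloured.
#' @export
plot_enrichment <- function(abundance, ranking = NULL, top = 10) {
  if (is.null(ranking)) ranking <- rank_variants(abundance)
  keep <- ranking$variant_id[seq_len(min(top, nrow(ranking)))]
  df <- abundance |>
    mutate(
      cycle_idx = as.integer(factor(.data$cycle)) - 1L,
      highlight = ifelse(.data$variant_id %in% keep, .data$variant_id, NA)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle_idx, y = .data$abundance,
                                   group = .data$variant_id)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, is.na(.data$highlight)),
                       colour = "grey80", linewidth = 0.2) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, !is.na(.data$highlight)),
                       ggplot2::aes(colour = .data$highlight),
                       linewidth = 0.6) +
    ggplot2::labs(x = "sorting cycle", y = "abundance (%)",
                  colour = "variant",
                  title = sprintf("Top %d variants by enrichment trend",
                                  length(keep)))
}

#' @method autoplot enrichment_ranking
#' @export
autoplot.enrichment_ranking <- function(object, top = 20, ...) {
  df <- object[seq_len(min(top, nrow(object))), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variant_id, -.data$rank), y = .data$slope
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "enrichment trend (%/cycle)")
}

#' Plot a droplet population with its sorting gate
#'
#' @param events Droplet tibble with `rox`, `gfp` (and optionally
#'   `in_gate`).
#' @param gate Optional [build_gate()] result; draws the thresholds.
#' @param sample_n Down-sample to this many droplets for plotting.
#' @return A ggplot of GFP vs ROX on log scales.
#' @export
plot_droplets <- function(events, gate = NULL, sample_n = 2e4) {
  if (nrow(events) > sample_n) {
    events <- events[sample.int(nrow(events), sample_n), ]
  }
  p <- ggplot2::ggplot(events, ggplot2::aes(x = .data$gfp, y = .data$rox)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "GFP signal", y = "ROX signal")
  if (!is.null(gate)) {
    p <- p +
      ggplot2::geom_hline(yintercept = gate$rox_min, colour = "firebrick",
                          linetype = 2) +
      ggplot2::geom_vline(xintercept = gate$gfp_bound, colour = "firebrick",
                          linetype = 2)
  }
  p
}
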