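#' Build a motif-count dataset over a length grid
#'
#' For each length in the grid, generates `n_per_length` random sequences
#' from the given composition, folds them, counts motifs and emits one row
#' per structure per motif (long format), tagged with the ensemble name.
#'
#' @param engine A [folding_engine()].
#' @param lengths Integer vector of sequence lengths.
#' @param n_per_length Sequences per length.
#' @param comp A [composition_spec()].
#' @param seed Run seed; each length draws from its own substream.
#' @param ensemble Label recorded in the output (default `"random"`).
#' @return A tibble with columns `id`, `length`, `motif`, `count`,
#'   `ensemble`; motifs are `bulges`, `loops`, `junctions`, `helices`,
#'   `bonds`.
#' @export
build_length_grid_dataset <- function(engine, lengths, n_per_length,
                                      comp = composition_spec(), seed = 1L,
                                      ensemble = "random") {
  stopifnot(inherits(engine, "folding_engine"), n_per_length >= 1)
  purrr::map_dfr(lengths, function(L) {
    seqs <- random_sequences(n_per_length, L, comp,
                             seed = substream_seed(seed, paste0("grid", L)))
    folded <- fold(seqs, engine)
    motif_points(folded, ensemble = ensemble)
  })
}

#' Convert folded structures to long-format motif points
#'
#' @param structures Tibble with columns `id` and `db` (e.g. from [fold()]).
#' @param ensemble Ensemble label.
#' @return Long tibble of per-structure motif counts (`id`, `length`,
#'   `motif`, `count`, `ensemble`).
#' @export
motif_points <- function(structures, ensemble = "random") {
  stopifnot(is.data.frame(structures), all(c("id", "db") %in% names(structures)))
  counts <- motif_counts(structures$db)
  counts$id <- structures$id
  long <- tidyr::pivot_longer(
    counts[c("id", "length", "bulges", "loops", "junctions", "helices", "bonds")],
    cols = c("bulges", "loops", "junctions", "helices", "bonds"),
    names_to = "motif", values_to = "count"
  )
  long$ensemble <- ensemble
  long
}

# OLS fit of count on length for one motif/ensemble group of points.
.fit_line <- function(L, count) {
  if (length(L) < 3L) stop("need at least 3 points to fit a trend", call. = FALSE)
  if (length(unique(L)) < 2L) {
    stop("degenerate design: all points share one length", call. = FALSE)
  }
  fit <- stats::lm(count ~ L)
  stats::coef(fit)
}

#' Fit linear length trends of motif counts
#'
#' Fits `count = a * L + b` by ordinary least squares over per-structure
#' points, separately for every motif-by-ensemble group, and (optionally)
#' attaches nonparametric bootstrap 95% confidence intervals obtained by
#' resampling points with replacement (percentile method).
#'
#' @param points Long tibble from [build_length_grid_dataset()] /
#'   [motif_points()] with columns `length`, `motif`, `count`, `ensemble`.
#' @param B Bootstrap replicates for the confidence intervals; `B = 0`
#'   skips the bootstrap.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `motif_trend_fit`: a tibble with one row per
#'   motif-by-ensemble group and columns `motif`, `ensemble`, `slope`,
#'   `intercept`, `n_points`, plus `slope_lo`, `slope_hi`, `intercept_lo`,
#'   `intercept_hi` when `B > 0`. The raw points are attached as attribute
#'   `points` for plotting.
#' @examples
#' pts <- tibble::tibble(length = rep(c(100, 200, 300), each = 2),
#'                       motif = "bonds", ensemble = "random",
#'                       count = c(33, 35, 65, 67, 97, 99))
#' motif_trend_fit(pts)
#' @export
motif_trend_fit <- function(points, B = 0L, seed = 1L) {
  stopifnot(is.data.frame(points),
            all(c("length", "motif", "count", "ensemble") %in% names(points)))
  fits <- points |>
    dplyr::group_by(.data$motif, .data$ensemble) |>
    dplyr::group_modify(function(g, key) {
      cf <- .fit_line(g$length, g$count)
      row <- tibble::tibble(slope = unname(cf[2]), intercept = unname(cf[1]),
                            n_points = nrow(g))
      if (B > 0L) {
        ci <- bootstrap_fit_ci(g, B = B,
                               seed = substream_seed(seed, paste(key$motif, key$ensemble)))
        row <- dplyr::bind_cols(row, ci)
      }
      row
    }) |>
    dplyr::ungroup()
  structure(fits, class = c("motif_trend_fit", class(fits)),
            points = tibble::as_tibble(points))
}

#' Bootstrap confidence intervals for a linear trend
#'
#' Resamples the points of one motif/ensemble group with replacement `B`
#' times, refits the line, and returns percentile 2.5%/97.5% intervals for
#' slope and intercept.
#'
#' @param points Tibble with columns `length` and `count` (one group).
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Seed.
#' @return One-row tibble: `slope_lo`, `slope_hi`, `intercept_lo`,
#'   `intercept_hi`.
#' @export
bootstrap_fit_ci <- function(points, B = 1000L, seed = 1L) {
  stopifnot(is.data.frame(points), all(c("length", "count") %in% names(points)),
            B >= 100L)
  set.seed(seed)
  n <- nrow(points)
  reps <- vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(points$length[idx])) >= 2L) break
    }
    .fit_line(points$length[idx], points$count[idx])
  }, numeric(2))
  qs_b <- stats::quantile(reps[1, ], c(0.025, 0.975), names = FALSE)
  qs_a <- stats::quantile(reps[2, ], c(0.025, 0.975), names = FALSE)
  tibble::tibble(slope_lo = qs_a[1], slope_hi = qs_a[2],
                 intercept_lo = qs_b[1], intercept_hi = qs_b[2])
}

#' @export
tidy.motif_trend_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.motif_trend_fit <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x), n_points = sum(x$n_points),
                 bootstrapped = "slope_lo" %in% names(x))
}

#' @export
autoplot.motif_trend_fit <- function(object, ...) {
  pts <- attr(object, "points")
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$length, y = .data$count,
                                         colour = .data$ensemble)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(
      data = tidy.motif_trend_fit(object),
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$ensemble)
    ) +
    ggplot2::facet_wrap(~motif, scales = "free_y") +
    ggplot2::labs(x = "sequence length (nt)", y = "motif count") +
    ggplot2::theme_minimal()
  p
}
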