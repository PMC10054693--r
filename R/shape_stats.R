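#' Tabulate shape frequencies for one ensemble
#'
#' Counts each distinct abstract shape in a sample, converts counts to
#' probabilities (count / sample size) and assigns ranks by descending
#' probability; ties are broken lexicographically on the shape string so the
#' ranking is deterministic.
#'
#' @param shapes Character vector of shape strings (one per structure; a
#'   multiset).
#' @return A tibble with columns `shape`, `count`, `probability`, `rank`,
#'   ordered by rank. The sample size is attached as attribute `total`.
#' @examples
#' shape_frequency_table(c("[]", "[]", "[][]", "_"))
#' @export
shape_frequency_table <- function(shapes) {
  stopifnot(is.character(shapes))
  if (length(shapes) == 0L) stop("empty shape sample", call. = FALSE)
  tab <- table(shapes)
  out <- tibble::tibble(shape = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$shape), ]
  out$probability <- out$count / length(shapes)
  out$rank <- seq_len(nrow(out))
  attr(out, "total") <- length(shapes)
  out
}

#' Fraction of one ensemble's shapes recovered by another
#'
#' The fraction of the unique shapes of a reference ensemble (e.g. natural
#' structures) that also occur in a comparison ensemble (e.g. structures of
#' randomly sampled sequences).
#'
#' @param reference,sampled Shape frequency tables from
#'   [shape_frequency_table()] (any data frame with a `shape` column works).
#' @return A single fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(reference, sampled) {
  stopifnot(is.data.frame(reference), is.data.frame(sampled),
            nrow(reference) > 0L, nrow(sampled) > 0L)
  mean(unique(reference$shape) %in% sampled$shape)
}

#' Correlate log shape probabilities across two ensembles
#'
#' Pearson correlation of log10 shape probabilities over the shapes common
#' to both tables (shapes absent from either have no defined log
#' probability; optionally, add-one pseudocounts over the union can be used
#' instead). The two-sided p-value comes from the usual t transform of r.
#'
#' @param table_a,table_b Shape frequency tables.
#' @param pseudocount If `TRUE`, compare over the union of shapes with
#'   count + 1 pseudocounts instead of the intersection. Default `FALSE`.
#' @return A one-row tibble with columns `r`, `p_value`, `n_common`.
#' @export
log_log_correlation <- function(table_a, table_b, pseudocount = FALSE) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b))
  if (isTRUE(pseudocount)) {
    all_shapes <- union(table_a$shape, table_b$shape)
    ca <- table_a$count[match(all_shapes, table_a$shape)]
    cb <- table_b$count[match(all_shapes, table_b$shape)]
    ca[is.na(ca)] <- 0L; cb[is.na(cb)] <- 0L
    pa <- (ca + 1) / sum(ca + 1)
    pb <- (cb + 1) / sum(cb + 1)
  } else {
    common <- intersect(table_a$shape, table_b$shape)
    if (length(common) < 3L) {
      stop("fewer than 3 shapes shared between the two tables", call. = FALSE)
    }
    pa <- table_a$probability[match(common, table_a$shape)]
    pb <- table_b$probability[match(common, table_b$shape)]
  }
  ct <- stats::cor.test(log10(pa), log10(pb), method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_common = length(pa))
}

#' Asymptotic size of the level-5 shape space
#'
#' Analytic estimate of the number of distinct level-5 abstract shapes of
#' length `L` (minimum hairpin size 3, minimal ladder length — the
#' convention matching MFE folding): `2.44 * 1.32^L * L^(-3/2)`. The count
#' grows exponentially in `L`: about 1e9 shapes at L = 100 and 1e45 at
#' L = 400, which is why random sampling recovering most natural shapes is
#' evidence of strong phenotype bias.
#'
#' @param L Integer vector of lengths (nt).
#' @param level Abstraction level; only level 5 is supported.
#' @return A tibble with columns `length`, `level`, `estimate`.
#' @examples
#' shape_space_size(c(100, 200, 300, 400))
#' @export
shape_space_size <- function(L, level = 5L) {
  stopifnot(all(L >= 1))
  if (!identical(as.integer(level), 5L)) {
    stop("only the level-5 shape-space estimate is implemented", call. = FALSE)
  }
  tibble::tibble(length = as.integer(L), level = 5L,
                 estimate = 2.44 * 1.32^L * L^(-3 / 2))
}

#' Rank plot of shape frequencies
#'
#' Frequency versus rank on log axes, optionally overlaying several
#' ensembles.
#'
#' @param ... Named shape frequency tables (names become the legend).
#' @return A ggplot object.
#' @export
plot_shape_rank <- function(...) {
  tables <- list(...)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("ensemble", seq_along(tables))
  }
  df <- dplyr::bind_rows(lapply(tables, function(t) t[c("rank", "probability")]),
                         .id = "ensemble")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$probability,
                                   colour = .data$ensemble)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "shape rank", y = "shape probability") +
    ggplot2::theme_minimal()
}
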