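#' Specification for a pseudo-natural versus random dataset
#'
#' Defines the generative conditions for a labelled two-class benchmark that
#' emulates the statistical signatures that distinguish natural non-coding
#' RNA from random RNA: per-sequence GC-content heterogeneity (natural
#' sequences are composition-biased, random ones are not) and small shifts
#' in the mean motif counts of the folded structures (natural structures
#' show slightly fewer bulges and slightly more hairpin loops than random
#' ones of the same length).
#'
#' The default `shift` points in the direction of those observed contrasts
#' (fewer bulges, more loops, slightly fewer bonds); its magnitude is a
#' tunable effect size, not an empirical claim.
#'
#' @param L Sequence length (nt).
#' @param n Sequences per class.
#' @param gc_alpha,gc_beta Shape parameters of the Beta law from which each
#'   pseudo-natural sequence draws its GC fraction. The default
#'   `Beta(12, 12)` gives mean 0.5 with s.d. ≈ 0.1, a realistic spread of
#'   per-molecule GC content; `gc_alpha = gc_beta` keeps the classes
#'   composition-balanced on average.
#' @param shift Named effect-size vector over the five motifs (target
#'   direction of the pseudo-natural mean shift, in count units).
#' @param candidates_per_accept Oversampling factor of the
#'   selection-by-resampling step; 1 disables selection.
#' @return A list of class `pseudo_natural_spec`.
#' @export
pseudo_natural_spec <- function(L = 100L, n = 200L,
                                gc_alpha = 12, gc_beta = 12,
                                shift = c(bulges = -1, loops = 1, junctions = 0,
                                          helices = 0, bonds = -0.5),
                                candidates_per_accept = 3L) {
  stopifnot(n >= 1, L >= 1, candidates_per_accept >= 1,
            gc_alpha > 0, gc_beta > 0, all(is.finite(shift)))
  motifs <- c("bulges", "loops", "junctions", "helices", "bonds")
  full <- stats::setNames(numeric(5), motifs)
  full[names(shift)] <- shift
  structure(list(L = as.integer(L), n = as.integer(n),
                 gc_alpha = gc_alpha, gc_beta = gc_beta, shift = full,
                 candidates_per_accept = as.integer(candidates_per_accept)),
            class = "pseudo_natural_spec")
}

#' Generate a labelled pseudo-natural versus random dataset
#'
#' The `"random"` class consists of uniform-composition random sequences
#' folded with the given engine. The `"pseudo-natural"` class draws each
#' sequence's GC fraction from `Beta(gc_alpha, gc_beta)`, folds
#' `candidates_per_accept` candidate sequences per slot, and keeps the
#' candidate whose motif-count vector has the largest inner product with the
#' effect-size vector `shift` (selection-by-resampling: selection acts on
#' fold outcomes, so kept sequences remain genuinely foldable). With
#' `shift = 0` and `gc_alpha == gc_beta == Inf`-like symmetric, tight GC
#' laws the classes are exchangeable and any downstream classifier should
#' sit at AUC 0.5.
#'
#' @param spec A [pseudo_natural_spec()].
#' @param engine A [folding_engine()].
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `seq`, `length`, `db`, `class`
#'   (`"random"` / `"pseudo-natural"`).
#' @export
generate_pseudo_natural <- function(spec, engine = folding_engine("nussinov"),
                                    seed = 1L) {
  stopifnot(inherits(spec, "pseudo_natural_spec"),
            inherits(engine, "folding_engine"))
  rand <- random_sequences(spec$n, spec$L,
                           seed = substream_seed(seed, "random_class"))
  rand <- fold(rand, engine)
  rand$class <- "random"

  m <- spec$candidates_per_accept
  set.seed(substream_seed(seed, "pseudo_gc"))
  gc <- stats::rbeta(spec$n, spec$gc_alpha, spec$gc_beta)
  cand <- purrr::map_dfr(seq_len(spec$n), function(i) {
    s <- random_sequences(m, spec$L, composition_spec(gc = gc[i]),
                          seed = substream_seed(seed, paste0("pseudo", i)))
    s$slot <- i
    s
  })
  cand <- fold(cand, engine)
  score <- as.matrix(motif_counts(cand$db)[, names(spec$shift)]) %*% spec$shift
  cand$selection_score <- as.numeric(score)
  kept <- cand |>
    dplyr::group_by(.data$slot) |>
    dplyr::slice_max(.data$selection_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  kept$id <- sprintf("pseudo_%d", kept$slot)
  kept$class <- "pseudo-natural"
  keep_cols <- intersect(c("id", "seq", "length", "db", "energy", "class"),
                         names(kept))
  dplyr::bind_rows(rand[intersect(names(rand), keep_cols)],
                   kept[keep_cols])
}

#' Turn labelled structures into a classifier feature table
#'
#' One row per structure; the columns are exactly the five motif counts
#' (in the fixed order bulges, loops, junctions, helices, bonds) plus a
#' binary `label` column (1 for the pseudo-natural / natural-like class).
#'
#' @param structures Tibble with columns `db` and `class` (as from
#'   [generate_pseudo_natural()]), or `db` and `label`.
#' @param positive Class value mapped to label 1 (default
#'   `"pseudo-natural"`).
#' @return A tibble with columns `bulges`, `loops`, `junctions`, `helices`,
#'   `bonds`, `label`.
#' @export
make_feature_dataset <- function(structures, positive = "pseudo-natural") {
  stopifnot(is.data.frame(structures), "db" %in% names(structures))
  counts <- motif_counts(structures$db)
  out <- counts[c("bulges", "loops", "junctions", "helices", "bonds")]
  if ("label" %in% names(structures)) {
    out$label <- .check_binary(structures$label)
  } else if ("class" %in% names(structures)) {
    out$label <- as.integer(structures$class == positive)
  } else {
    stop("`structures` needs a `class` or `label` column", call. = FALSE)
  }
  out
}
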