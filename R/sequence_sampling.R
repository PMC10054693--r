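# Derive a reproducible sub-seed for a named pipeline stage from a run seed.
# Keeps all randomness funnelled through one user-visible seed while letting
# stages draw from independent streams.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Specify a nucleotide composition
#'
#' Either explicit probabilities for A, C, G, U, or a GC fraction with the
#' AU and GC mass split evenly within each pair class.
#'
#' @param a,c,g,u Probabilities summing to 1.
#' @param gc Alternatively, a GC fraction in `[0, 1]`.
#' @return A named numeric vector of class `composition_spec`.
#' @examples
#' composition_spec()            # uniform
#' composition_spec(gc = 0.6)
#' @export
composition_spec <- function(a = 0.25, c = 0.25, g = 0.25, u = 0.25, gc = NULL) {
  if (!is.null(gc)) {
    stopifnot(gc >= 0, gc <= 1)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  } else {
    p <- c(A = a, C = c, G = g, U = u)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("composition probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(p, class = "composition_spec")
}

#' Generate random RNA sequences
#'
#' Draws `n` i.i.d. sequences of length `L`, each residue sampled
#' independently from the given composition. Fully reproducible from `seed`.
#'
#' @param n Number of sequences.
#' @param L Sequence length in nucleotides.
#' @param comp A [composition_spec()]; uniform by default.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @examples
#' random_sequences(3, 20, seed = 1)
#' @export
random_sequences <- function(n, L, comp = composition_spec(), seed = 1L) {
  stopifnot(n >= 1, L >= 1)
  if (!inherits(comp, "composition_spec")) comp <- do.call(composition_spec, as.list(comp))
  set.seed(seed)
  mat <- matrix(sample(names(comp), n * L, replace = TRUE, prob = comp),
                nrow = n)
  seqs <- apply(mat, 1L, paste, collapse = "")
  tibble::tibble(id = sprintf("rand_%d", seq_len(n)), seq = seqs,
                 length = rep(as.integer(L), n))
}

#' Scramble sequences by random permutation
#'
#' Randomly permutes the residues of each sequence, preserving its exact
#' nucleotide multiset (and hence its GC content). This is the standard
#' composition-matched control for comparisons against natural sequences.
#'
#' @param seqs Tibble with columns `id`, `seq`, or a character vector.
#' @param seed Integer seed.
#' @return A tibble with the same columns, `seq` replaced by its scrambled
#'   version and `id` suffixed with `"_scr"`.
#' @examples
#' scramble_sequences(tibble::tibble(id = "x", seq = "AACCGGUU"), seed = 1)
#' @export
scramble_sequences <- function(seqs, seed = 1L) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = paste0("seq", seq_along(seqs)), seq = seqs)
  }
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)),
            all(nzchar(seqs$seq)))
  out <- tibble::as_tibble(seqs)
  set.seed(seed)
  out$seq <- vapply(out$seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(ch[sample.int(length(ch))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out$id <- paste0(out$id, "_scr")
  out
}

#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file into a tibble, normalising
#' `T` to `U` and raising lower case. Records containing ambiguity codes
#' (N, R, Y, ...) are skipped with a warning, since their fold would be
#' undefined.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header), `seq`,
#'   `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[1], ">")) {
    stop(sprintf("not a FASTA file (no records): %s", path), call. = FALSE)
  }
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1), collapse = "")
  seqs <- .normalize_rna(trimws(seqs))
  keep <- !grepl("[^ACGU]", seqs)
  if (any(!keep)) {
    warning(sprintf("skipped %d record(s) with ambiguity codes: %s",
                    sum(!keep), paste(utils::head(ids[!keep], 5), collapse = ", ")),
            call. = FALSE)
  }
  tibble::tibble(id = ids[keep], seq = unname(seqs[keep]),
                 length = nchar(unname(seqs[keep])))
}

#' Filter sequences to a target length
#'
#' Keeps sequences whose length is within `tol` of `L`; the default `tol = 0`
#' keeps exact matches only, matching the fixed-length strata used in the
#' package's analyses.
#'
#' @param seqs Tibble with columns `seq` (and optionally `length`).
#' @param L Target length in nt.
#' @param tol Half-width of the accepted length window.
#' @param dedupe Drop duplicated sequences first (default `FALSE`).
#' @return Filtered tibble.
#' @export
filter_by_length <- function(seqs, L, tol = 0L, dedupe = FALSE) {
  stopifnot(is.data.frame(seqs), "seq" %in% names(seqs))
  out <- tibble::as_tibble(seqs)
  if (isTRUE(dedupe)) out <- out[!duplicated(out$seq), ]
  len <- nchar(out$seq)
  out$length <- len
  out[abs(len - L) <= tol, ]
}
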