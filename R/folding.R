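#' Construct a folding engine
#'
#' A folding engine maps an RNA sequence to a single predicted secondary
#' structure. Two engines are provided:
#'
#' * `"vienna"` — an adapter over the `RNAfold` program of the ViennaRNA
#'   suite, returning the minimum-free-energy structure at the package's
#'   default settings (37 °C, default dangles, no constraints). This is the
#'   engine used for all headline analyses.
#' * `"nussinov"` — a built-in base-pair-maximisation fold (Watson–Crick
#'   pairs plus GU wobble, minimum hairpin size 3 by default) with a
#'   deterministic traceback. A fast, dependency-free baseline used for unit
#'   testing and small simulated datasets; it is not an energy model.
#'
#' Both engines are pure: the same engine, parameters and sequence always
#' give byte-identical structures.
#'
#' @param name `"vienna"` or `"nussinov"`.
#' @param temperature Folding temperature in °C (vienna only).
#' @param min_hairpin Minimum unpaired bases in a hairpin (nussinov only).
#' @param wobble Allow GU wobble pairs (nussinov only).
#' @return An object of class `folding_engine` with fields `name`, `params`
#'   and a `version` provenance string.
#' @examples
#' folding_engine("nussinov")
#' @export
folding_engine <- function(name = c("vienna", "nussinov"),
                           temperature = 37,
                           min_hairpin = 3L,
                           wobble = TRUE) {
  name <- match.arg(name)
  if (name == "vienna") {
    version <- .rnafold_version()
    params <- list(temperature = temperature)
  } else {
    version <- "rnamotifs built-in nussinov"
    params <- list(min_hairpin = as.integer(min_hairpin), wobble = isTRUE(wobble))
  }
  structure(list(name = name, params = params, version = version),
            class = "folding_engine")
}

#' @export
print.folding_engine <- function(x, ...) {
  cat("<folding_engine> ", x$name, "\n  version: ", x$version, "\n  params: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.rnafold_path <- function() {
  path <- Sys.which("RNAfold")
  if (!nzchar(path)) {
    stop("the vienna folding engine requires the RNAfold program on PATH",
         call. = FALSE)
  }
  path
}

.rnafold_version <- function() {
  out <- tryCatch(system2(.rnafold_path(), "--version", stdout = TRUE),
                  error = function(e) conditionMessage(e))
  paste(out, collapse = " ")
}

.normalize_rna <- function(seq) {
  chartr("acgutT", "ACGUUU", seq)
}

.check_alphabet <- function(seq) {
  bad <- grepl("[^ACGU]", seq)
  if (any(bad)) {
    stop(sprintf("%d sequence(s) contain residues outside {A,C,G,U}",
                 sum(bad)), call. = FALSE)
  }
}

# Batch-fold sequences with RNAfold, one process for the whole batch.
# Input and output are plain sequence/structure line pairs (no FASTA ids),
# which keeps parsing unambiguous.
.vienna_fold <- function(seqs, temperature = 37) {
  path <- .rnafold_path()
  args <- c("--noPS")
  if (!identical(temperature, 37) && !identical(temperature, 37L)) {
    args <- c(args, paste0("--temp=", temperature))
  }
  out <- system2(path, args, stdout = TRUE, input = paste(seqs, collapse = "\n"))
  struct_lines <- out[seq(2L, length(out), by = 2L)]
  if (length(struct_lines) != length(seqs)) {
    stop("RNAfold returned an unexpected number of records", call. = FALSE)
  }
  db <- sub("^([.()]+).*$", "\\1", struct_lines)
  energy <- as.numeric(sub("^[.()]+\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1",
                           struct_lines))
  list(db = db, energy = energy)
}

#' Fold RNA sequences into secondary structures
#'
#' Predicts one dot-bracket structure per sequence with the chosen engine.
#' Sequences are normalised first (lower case raised, `T` read as `U`).
#'
#' @param seqs A tibble/data frame with columns `id` and `seq` (as produced
#'   by [random_sequences()] or [read_fasta()]), or a bare character vector
#'   of sequences.
#' @param engine A [folding_engine()]; defaults to the vienna engine.
#' @return The input table with columns `db` (dot-bracket string, same
#'   length as the sequence) and, for the vienna engine, `energy`
#'   (kcal/mol) appended.
#' @examples
#' fold(c("GGGAAACCC"), folding_engine("nussinov"))
#' @export
fold <- function(seqs, engine = folding_engine("vienna")) {
  stopifnot(inherits(engine, "folding_engine"))
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = paste0("seq", seq_along(seqs)), seq = seqs)
  }
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  out <- tibble::as_tibble(seqs)
  out$seq <- .normalize_rna(out$seq)
  .check_alphabet(out$seq)
  if (nrow(out) == 0L) {
    out$db <- character(0)
    return(out)
  }
  if (engine$name == "vienna") {
    res <- .vienna_fold(out$seq, engine$params$temperature)
    out$db <- res$db
    out$energy <- res$energy
  } else {
    out$db <- nussinov_fold(out$seq,
                            min_hairpin = engine$params$min_hairpin,
                            wobble = engine$params$wobble)
  }
  stopifnot(nchar(out$db) == nchar(out$seq))
  out
}

#' Maximum base-pairing fold (Nussinov algorithm)
#'
#' Maximises the number of allowed base pairs (Watson–Crick AU/GC, plus GU
#' wobble unless disabled) subject to nesting and a minimum hairpin size.
#' The traceback is deterministic: at every step the algorithm prefers
#' leaving the leftmost base unpaired and, among optimal pairings, pairs it
#' with the smallest possible partner.
#'
#' @param seqs Character vector of RNA sequences (A/C/G/U after
#'   normalisation).
#' @param min_hairpin Minimum unpaired bases enclosed by a pair.
#' @param wobble Allow GU pairs.
#' @return Character vector of dot-bracket strings.
#' @examples
#' nussinov_fold("GGGAAACCC")
#' @export
nussinov_fold <- function(seqs, min_hairpin = 3L, wobble = TRUE) {
  stopifnot(is.character(seqs), min_hairpin >= 0L)
  seqs <- .normalize_rna(seqs)
  .check_alphabet(seqs)
  vapply(seqs, .nussinov_cpp, character(1),
         min_hairpin = as.integer(min_hairpin), wobble = isTRUE(wobble),
         USE.NAMES = FALSE)
}
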