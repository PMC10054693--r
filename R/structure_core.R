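#' Parse a dot-bracket string into a pair table
#'
#' A dot-bracket string encodes a nested (pseudoknot-free) RNA secondary
#' structure: `.` is an unpaired base, matched `(` `)` a base pair. The pair
#' table is the standard array representation: entry `i` holds the 1-based
#' index of the partner of base `i`, or `NA` when base `i` is unpaired.
#'
#' @param text A single non-empty string over the alphabet `.`, `(`, `)`.
#' @return An integer vector of length `nchar(text)` (class `pair_table`);
#'   `pt[i] == j` iff bases `i` and `j` are paired, `NA` where unpaired.
#' @examples
#' parse_dot_bracket("(((...)))")
#' @export
parse_dot_bracket <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty dot-bracket string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character(s) in dot-bracket string: %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        stop(sprintf("unbalanced brackets: unmatched ')' at position %d", i),
             call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack) > 0L) {
    stop(sprintf("unbalanced brackets: %d unmatched '('", length(stack)),
         call. = FALSE)
  }
  structure(pt, class = "pair_table")
}

#' Serialize a pair table back to dot-bracket text
#'
#' Inverse of [parse_dot_bracket()]; `pair_table_to_text(parse_dot_bracket(x))`
#' round-trips `x` exactly for any valid nested structure.
#'
#' @param pt A pair table as returned by [parse_dot_bracket()].
#' @return A dot-bracket string.
#' @export
pair_table_to_text <- function(pt) {
  idx <- seq_along(pt)
  out <- rep(".", length(pt))
  out[!is.na(pt) & pt > idx] <- "("
  out[!is.na(pt) & pt < idx] <- ")"
  paste(out, collapse = "")
}

# Recursively decompose the region enclosed by helices starting at (i, j).
# Assumes pt[i] == j. Returns a helix node.
.helix_node <- function(pt, i, j) {
  bp <- 1L
  while (i + 1L < j - 1L && !is.na(pt[i + 1L]) && pt[i + 1L] == j - 1L) {
    i <- i + 1L
    j <- j - 1L
    bp <- bp + 1L
  }
  # interior face of the maximal helix: region (i+1) .. (j-1)
  child <- .face_node(pt, i + 1L, j - 1L)
  list(type = "helix", bp = bp, child = child)
}

# Classify the loop face spanning positions lo..hi (both inclusive; may be
# empty when lo > hi). Returns a hairpin / bulge / internal / multiloop node.
.face_node <- function(pt, lo, hi) {
  elements <- list()   # ordered unpaired runs and enclosed helices
  helices <- list()
  unpaired <- 0L
  run <- 0L
  runs <- integer(0)   # unpaired run lengths in order, incl. trailing
  k <- lo
  while (k <= hi) {
    if (is.na(pt[k])) {
      run <- run + 1L
      unpaired <- unpaired + 1L
      k <- k + 1L
    } else {
      runs <- c(runs, run)
      if (run > 0L) elements[[length(elements) + 1L]] <- list(type = "unpaired", n = run)
      run <- 0L
      h <- .helix_node(pt, k, pt[k])
      elements[[length(elements) + 1L]] <- h
      helices[[length(helices) + 1L]] <- h
      k <- pt[k] + 1L
    }
  }
  runs <- c(runs, run)
  if (run > 0L) elements[[length(elements) + 1L]] <- list(type = "unpaired", n = run)

  nh <- length(helices)
  if (nh == 0L) {
    return(list(type = "hairpin", unpaired = unpaired))
  }
  if (nh == 1L) {
    u5 <- runs[1]
    u3 <- runs[2]
    # a face with no unpaired bases on either side would be a stacked pair,
    # which the helix builder has already merged
    stopifnot(u5 > 0L || u3 > 0L)
    if (u5 > 0L && u3 > 0L) {
      return(list(type = "internal", unpaired5 = u5, unpaired3 = u3,
                  child = helices[[1]]))
    }
    side <- if (u5 > 0L) "5'" else "3'"
    return(list(type = "bulge", side = side, unpaired = u5 + u3,
                child = helices[[1]]))
  }
  list(type = "multiloop", branches = nh, unpaired = unpaired,
       elements = elements)
}

#' Build the loop-decomposition tree of a secondary structure
#'
#' Decomposes a nested structure into its unique tree of faces: maximal
#' helices (runs of stacked pairs), hairpin loops, one-sided bulges,
#' two-sided internal loops, multiloops (junctions), and the exterior region.
#' Every maximal helix has exactly one loop-type child (the face its
#' innermost pair closes); every bulge/internal loop has exactly one helix
#' child; every multiloop encloses two or more helices.
#'
#' @param x A dot-bracket string or a `pair_table`.
#' @return A nested list with node `type` one of `"exterior"`, `"helix"`,
#'   `"hairpin"`, `"bulge"`, `"internal"`, `"multiloop"`.
#' @examples
#' str(build_structure_tree("((..((...))..))"), max.level = 3)
#' @export
build_structure_tree <- function(x) {
  pt <- if (inherits(x, "pair_table")) x else parse_dot_bracket(x)
  elements <- list()
  unpaired <- 0L
  branches <- 0L
  run <- 0L
  k <- 1L
  n <- length(pt)
  while (k <= n) {
    if (is.na(pt[k])) {
      run <- run + 1L
      unpaired <- unpaired + 1L
      k <- k + 1L
    } else {
      if (pt[k] < k) stop("invalid pair table: crossing or inverted pair", call. = FALSE)
      if (run > 0L) elements[[length(elements) + 1L]] <- list(type = "unpaired", n = run)
      run <- 0L
      elements[[length(elements) + 1L]] <- .helix_node(pt, k, pt[k])
      branches <- branches + 1L
      k <- pt[k] + 1L
    }
  }
  if (run > 0L) elements[[length(elements) + 1L]] <- list(type = "unpaired", n = run)
  list(type = "exterior", branches = branches, unpaired = unpaired,
       elements = elements)
}

# Fold a function over all nodes of a structure tree.
.tree_walk <- function(node, f) {
  f(node)
  kids <- switch(node$type,
    exterior  = ,
    multiloop = Filter(function(e) e$type == "helix", node$elements),
    helix     = list(node$child),
    bulge     = ,
    internal  = list(node$child),
    list()
  )
  for (k in kids) .tree_walk(k, f)
  invisible(NULL)
}

.count_motifs_one <- function(db) {
  tree <- build_structure_tree(db)
  env <- new.env(parent = emptyenv())
  env$bulges <- env$loops <- env$junctions <- env$helices <- env$bonds <- env$internals <- 0L
  .tree_walk(tree, function(nd) {
    switch(nd$type,
      helix     = { env$helices <- env$helices + 1L; env$bonds <- env$bonds + nd$bp },
      hairpin   = env$loops     <- env$loops + 1L,
      bulge     = env$bulges    <- env$bulges + 1L,
      multiloop = env$junctions <- env$junctions + 1L,
      internal  = env$internals <- env$internals + 1L,
      NULL
    )
  })
  c(bulges = env$bulges, loops = env$loops, junctions = env$junctions,
    helices = env$helices, bonds = env$bonds, internals = env$internals)
}

#' Count structural motifs in dot-bracket structures
#'
#' For each structure, counts the five classical motifs used throughout the
#' package — bonds (base pairs), helices (maximal runs of stacked pairs),
#' loops (hairpin loops), bulges (one-sided interior faces) and junctions
#' (multiloops) — plus the auxiliary count of two-sided internal loops.
#' Counts are read off the loop-decomposition tree
#' ([build_structure_tree()]); the exterior region contributes to none of
#' them.
#'
#' @param db Character vector of dot-bracket strings.
#' @return A tibble with one row per structure and columns `structure`,
#'   `length`, `bulges`, `loops`, `junctions`, `helices`, `bonds`,
#'   `internals`.
#' @examples
#' motif_counts(c("(((...)))", "((..((...))..((...))..))"))
#' @export
motif_counts <- function(db) {
  stopifnot(is.character(db))
  counts <- vapply(db, .count_motifs_one, integer(6), USE.NAMES = FALSE)
  tibble::tibble(
    structure = db,
    length    = nchar(db),
    bulges    = counts[1, ],
    loops     = counts[2, ],
    junctions = counts[3, ],
    helices   = counts[4, ],
    bonds     = counts[5, ],
    internals = counts[6, ]
  )
}

#' Count structural motifs by direct pair-table scanning
#'
#' Independent implementation of [motif_counts()] that classifies each loop
#' face by walking the pair table directly, without building a tree. The two
#' routes agree on every valid structure; this one exists as a test oracle.
#'
#' @inheritParams motif_counts
#' @return Same shape as [motif_counts()].
#' @export
motif_counts_scan <- function(db) {
  stopifnot(is.character(db))
  one <- function(s) {
    pt <- parse_dot_bracket(s)
    n <- length(pt)
    opens <- which(!is.na(pt) & pt > seq_len(n))
    bonds <- length(opens)
    # helix starts: an opening pair not stacked under another pair
    helices <- sum(vapply(opens, function(i) {
      i == 1L || is.na(pt[i - 1L]) || pt[i - 1L] != pt[i] + 1L
    }, logical(1)))
    loops <- bulges <- junctions <- internals <- 0L
    for (i in opens) {
      j <- pt[i]
      # only faces closed by the innermost pair of a stack are loop faces
      if (i + 1L <= j - 1L && !is.na(pt[i + 1L]) && pt[i + 1L] == j - 1L) next
      # walk the face i+1 .. j-1
      nh <- 0L; runs <- integer(0); run <- 0L; k <- i + 1L
      while (k <= j - 1L) {
        if (is.na(pt[k])) { run <- run + 1L; k <- k + 1L }
        else { runs <- c(runs, run); run <- 0L; nh <- nh + 1L; k <- pt[k] + 1L }
      }
      runs <- c(runs, run)
      if (nh == 0L) loops <- loops + 1L
      else if (nh >= 2L) junctions <- junctions + 1L
      else if (runs[1] > 0L && runs[2] > 0L) internals <- internals + 1L
      else bulges <- bulges + 1L
    }
    c(bulges, loops, junctions, helices, bonds, internals)
  }
  counts <- vapply(db, one, integer(6), USE.NAMES = FALSE)
  tibble::tibble(
    structure = db,
    length    = nchar(db),
    bulges    = counts[1, ],
    loops     = counts[2, ],
    junctions = counts[3, ],
    helices   = counts[4, ],
    bonds     = counts[5, ],
    internals = counts[6, ]
  )
}

#' Enumerate all valid dot-bracket structures of a given length
#'
#' Exhaustively generates every balanced dot-bracket string of length `L`
#' whose hairpin loops all contain at least `min_hairpin` unpaired bases.
#' Intended as a brute-force oracle for property tests; guarded against
#' combinatorial explosion.
#'
#' @param L Structure length in nucleotides; must be at most 16.
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop.
#' @return Character vector of dot-bracket strings (no duplicates).
#' @examples
#' enumerate_structures(5)  # ".....", "(...)"
#' @export
enumerate_structures <- function(L, min_hairpin = 3L) {
  stopifnot(L >= 0L, min_hairpin >= 0L)
  if (L > 16L) stop("enumeration limited to L <= 16", call. = FALSE)
  memo <- vector("list", L + 1L)
  gen <- function(n) {
    if (n == 0L) return("")
    if (!is.null(memo[[n + 1L]])) return(memo[[n + 1L]])
    out <- paste0(".", gen(n - 1L))
    if (n >= 2L) {
      for (k in 0:(n - 2L)) {
        inner <- gen(k)
        inner <- inner[grepl("\\(", inner) | k >= min_hairpin]
        if (length(inner) == 0L) next
        rest <- gen(n - k - 2L)
        out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest, paste0)))
      }
    }
    memo[[n + 1L]] <<- out
    out
  }
  gen(as.integer(L))
}
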