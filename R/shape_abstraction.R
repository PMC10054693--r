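# Render one tree node as an abstract shape string at a given level.
#
# Level semantics (RNAshapes-style, most to least detailed):
#   1  every helix a bracket pair; every maximal unpaired run an '_'
#   2  helices as in 3; '_' kept only inside bulges and internal loops
#   3  every maximal helix its own bracket pair, no '_'
#   4  helix chains connected through bulges merge into one bracket;
#      internal loops keep separate nesting
#   5  helix chains connected through bulges OR internal loops merge
#      (the maximal abstraction; the normative, fully tested level)
.shape_render <- function(node, level) {
  if (node$type %in% c("exterior", "multiloop")) {
    parts <- vapply(node$elements, function(e) {
      if (e$type == "unpaired") {
        if (level == 1L) "_" else ""
      } else {
        .shape_render(e, level)
      }
    }, character(1))
    return(paste(parts, collapse = ""))
  }
  if (node$type == "helix") {
    cur <- node$child
    pre <- ""; post <- ""
    repeat {
      if (cur$type == "hairpin") {
        inner <- if (level == 1L) "_" else ""
        return(paste0("[", pre, inner, post, "]"))
      }
      if (cur$type %in% c("bulge", "internal")) {
        merge <- level == 5L || (level == 4L && cur$type == "bulge")
        if (merge) {
          cur <- cur$child$child  # skip the loop face and descend past its helix
        } else if (level %in% c(1L, 2L)) {
          u5 <- if (cur$type == "internal") cur$unpaired5 > 0L else cur$side == "5'"
          u3 <- if (cur$type == "internal") cur$unpaired3 > 0L else cur$side == "3'"
          pre <- paste0(pre, if (u5) "_" else "", "[")
          post <- paste0("]", if (u3) "_" else "", post)
          cur <- cur$child$child
        } else {
          return(paste0("[", pre, .shape_render(cur$child, level), post, "]"))
        }
      } else if (cur$type == "multiloop") {
        return(paste0("[", pre, .shape_render(cur, level), post, "]"))
      } else {
        stop("unexpected node type in shape rendering", call. = FALSE)
      }
    }
  }
  stop("unexpected node type in shape rendering", call. = FALSE)
}

#' Abstract a dot-bracket structure to an RNAshapes-style shape string
#'
#' Coarse-grains each structure to its abstract shape at one of five levels
#' of abstraction. Level 5, the level used throughout the package's analyses,
#' retains only helix nesting and adjacency: every maximal chain of helices
#' connected through bulges or internal loops collapses to a single `[` `]`
#' pair, a chain ending in a hairpin renders `[]`, a chain ending in a
#' multiloop wraps the concatenated shapes of its branches, and the exterior
#' region concatenates its branches. A structure with no base pairs renders
#' the sentinel `"_"`. Levels 1–4 are provided for illustration of the
#' abstraction ladder and follow the published RNAshapes scheme on a
#' best-effort basis.
#'
#' @param db Character vector of dot-bracket strings.
#' @param level Abstraction level, integer 1–5 (default 5).
#' @return Character vector of shape strings.
#' @examples
#' abstract_shape(c("((..((...))..((...))..))", "((...))((...))", "....."))
#' @export
abstract_shape <- function(db, level = 5L) {
  stopifnot(is.character(db))
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 5L) {
    stop("`level` must be an integer between 1 and 5", call. = FALSE)
  }
  vapply(db, function(s) {
    tree <- build_structure_tree(s)
    if (tree$branches == 0L) return("_")
    .shape_render(tree, level)
  }, character(1), USE.NAMES = FALSE)
}

#' Count the opening brackets of a shape string
#'
#' For a level-5 shape this equals the number of hairpin loops plus
#' multiloops of the underlying structure (each `[` closes either a hairpin
#' chain or a junction).
#'
#' @param s Character vector of shape strings.
#' @return Integer vector of `[` counts.
#' @examples
#' shape_bracket_count(c("[[][]]", "[][]", "_"))
#' @export
shape_bracket_count <- function(s) {
  stopifnot(is.character(s))
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) sum(ch == "["), integer(1))
}
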