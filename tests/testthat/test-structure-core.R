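test_that("parse_dot_bracket matches brackets and rejects malformed input", {
  pt <- parse_dot_bracket("(((...)))")
  expect_equal(as.integer(pt), c(9L, 8L, 7L, NA, NA, NA, 3L, 2L, 1L))
  expect_true(all(is.na(parse_dot_bracket("....."))))
  expect_error(parse_dot_bracket("(()"), "unbalanced")
  expect_error(parse_dot_bracket("())"), "unbalanced")
  expect_error(parse_dot_bracket("(a)"), "invalid character")
  expect_error(parse_dot_bracket(""), "non-empty")
})

test_that("pair table is an involution and round-trips to text", {
  for (db in all_structures_up_to(10)) {
    if (!nzchar(db)) next
    pt <- parse_dot_bracket(db)
    paired <- which(!is.na(pt))
    expect_identical(as.integer(pt[pt[paired]]), paired)
    expect_identical(pair_table_to_text(pt), db)
  }
})

test_that("loop decomposition identifies helices, bulges and multiloops", {
  tree <- build_structure_tree("(((...)))")
  h <- tree$elements[[1]]
  expect_equal(h$type, "helix")
  expect_equal(h$bp, 3L)
  expect_equal(h$child$type, "hairpin")
  expect_equal(h$child$unpaired, 3L)

  tree <- build_structure_tree("(((..(((...))))))")
  h <- tree$elements[[1]]
  expect_equal(h$bp, 3L)
  expect_equal(h$child$type, "bulge")
  expect_equal(h$child$side, "5'")
  expect_equal(h$child$unpaired, 2L)
  expect_equal(h$child$child$bp, 3L)
  expect_equal(h$child$child$child$type, "hairpin")

  tree <- build_structure_tree("((..((...))..((...))..))")
  h <- tree$elements[[1]]
  expect_equal(h$bp, 2L)
  expect_equal(h$child$type, "multiloop")
  expect_equal(h$child$branches, 2L)
  branches <- Filter(function(e) e$type == "helix", h$child$elements)
  expect_length(branches, 2L)
  expect_true(all(vapply(branches, function(b) b$child$type, "") == "hairpin"))
})

test_that("motif counts match hand-derived values", {
  counts <- motif_counts(c("(((...)))", ".....", "((..((...))..))",
                           "((..((...))..((...))..))", "((...))((...))"))
  expect_equal(counts$bonds, c(3L, 0L, 4L, 6L, 4L))
  expect_equal(counts$helices, c(1L, 0L, 2L, 3L, 2L))
  expect_equal(counts$loops, c(1L, 0L, 1L, 2L, 2L))
  expect_equal(counts$bulges, c(0L, 0L, 0L, 0L, 0L))
  expect_equal(counts$junctions, c(0L, 0L, 0L, 1L, 0L))
  expect_equal(counts$internals, c(0L, 0L, 1L, 0L, 0L))
})

test_that("tree identity and scan-oracle equivalence hold on the exhaustive enumeration", {
  pool <- all_structures_up_to(14)
  pool <- pool[nzchar(pool)]
  a <- motif_counts(pool)
  b <- motif_counts_scan(pool)
  expect_equal(a, b)
  # each helix closes exactly one loop-type face
  expect_equal(a$helices, a$loops + a$bulges + a$junctions + a$internals)
  # bonds equal the number of opening brackets
  expect_equal(a$bonds, vapply(strsplit(pool, "", fixed = TRUE),
                               function(ch) sum(ch == "("), integer(1)))
})

test_that("motif counts are additive over exterior-level concatenation", {
  pool <- enumerate_structures(8)
  set.seed(11)
  left <- sample(pool, 40, replace = TRUE)
  right <- sample(pool, 40, replace = TRUE)
  combo <- motif_counts(paste0(left, right))
  parts <- motif_counts(left)[-(1:2)] + motif_counts(right)[-(1:2)]
  expect_equal(as.data.frame(combo[-(1:2)]), as.data.frame(parts))
})

test_that("enumeration matches brute force over all strings at small L", {
  # independent oracle: generate every string over {., (, )} and filter
  brute <- function(L, min_hairpin = 3L) {
    grid <- do.call(expand.grid, rep(list(c(".", "(", ")")), L))
    cand <- apply(grid, 1, paste, collapse = "")
    ok <- vapply(cand, function(s) {
      pt <- tryCatch(parse_dot_bracket(s), error = function(e) NULL)
      if (is.null(pt)) return(FALSE)
      cnt <- motif_counts_scan(s)
      # hairpin sizes: every innermost pair must enclose >= min_hairpin dots
      opens <- which(!is.na(pt) & pt > seq_along(pt))
      for (i in opens) {
        j <- pt[i]
        if (all(is.na(pt[seq(i + 1L, length.out = j - i - 1L)])) &&
            j - i - 1L < min_hairpin) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    sort(cand[ok])
  }
  for (L in c(3L, 4L, 5L, 7L)) {
    expect_identical(sort(enumerate_structures(L)), brute(L))
  }
  expect_identical(enumerate_structures(4), "....")
  expect_setequal(enumerate_structures(5), c(".....", "(...)"))
  expect_error(enumerate_structures(17), "L <= 16")
})
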