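test_that("UniMoG parsing handles linear, circular and duplicated families", {
  gs <- parse_unimog(">A\n1 -2 |")
  expect_length(gs, 1L)
  ch <- gs[[1]]$chromosomes[[1]]
  expect_equal(ch$fams, c("1", "2"))
  expect_equal(ch$signs, c(1L, -1L))
  expect_false(ch$circular)

  gs <- parse_unimog(">A\n1 )\n>B\n1 )")
  expect_length(gs, 2L)
  expect_true(all(vapply(gs, function(g) g$chromosomes[[1]]$circular, logical(1))))

  gs <- parse_unimog(">A\n2 1 2 |")
  ch <- gs[[1]]$chromosomes[[1]]
  expect_equal(ch$fams, c("2", "1", "2"))
  expect_equal(ch$occ, 1:3)   # duplicated family, distinct occurrence ids

  # several chromosomes on one line
  gs <- parse_unimog(">A\n1 | 2 )")
  expect_length(gs[[1]]$chromosomes, 2L)
  expect_true(gs[[1]]$chromosomes[[2]]$circular)
})

test_that("malformed UniMoG input is rejected with a line number", {
  expect_error(parse_unimog(">A\n1 2"), "line 2.*terminator")
  expect_error(parse_unimog(">A\n1 | |"), "line 2.*empty chromosome")
  expect_error(parse_unimog("1 2 |"), "before any")
  expect_error(parse_unimog(">\n1 |"), "malformed header")
  expect_error(parse_unimog("no headers at all"), "terminator|header")
})

test_that("write/parse round-trips on canonical text and random genomes", {
  txt <- ">A\n1 -2 |"
  expect_equal(write_unimog(parse_unimog(txt)), txt)
  g <- genome("A", list(chromosome("1", 1L, circular = TRUE)))
  expect_equal(write_unimog(list(g)), ">A\n1 )")
  # canonical text puts one chromosome per line
  txt2 <- ">A\n1 -2 |\n>B\n2 ) 1 |"
  expect_equal(write_unimog(parse_unimog(txt2)), ">A\n1 -2 |\n>B\n2 )\n1 |")

  set.seed(101)
  for (i in 1:25) {
    gs <- rand_pair(max_markers = 4L, fams = c("1", "2", "x"))
    round <- parse_unimog(write_unimog(gs))
    expect_equal(vapply(round, canonical_genome_key, character(1)),
                 vapply(gs, canonical_genome_key, character(1)))
  }
})

test_that("occurrence ids follow reading order across the pair", {
  gs <- pair_from_text(">A\n1 2 |\n>B\n2 1 |")
  expect_equal(genome_occs(gs[[1]]), 1:2)
  expect_equal(genome_occs(gs[[2]]), 3:4)
})

test_that("adjacency derivation follows the head/tail convention", {
  gs <- parse_unimog(">A\n1 2 |")
  aj <- genome_adjacencies(gs[[1]])
  # head of occurrence 1 (code 2) adjacent to tail of occurrence 2 (code 3)
  expect_equal(sort(aj$adjacencies[, 1]), c(2L, 3L))
  expect_equal(sort(aj$telomeres), c(1L, 4L))   # tail1, head2

  gs <- parse_unimog(">A\n1 )")
  aj <- genome_adjacencies(gs[[1]])
  expect_equal(sort(aj$adjacencies[, 1]), c(1L, 2L))
  expect_length(aj$telomeres, 0L)

  gs <- parse_unimog(">A\n1 |")
  aj <- genome_adjacencies(gs[[1]])
  expect_equal(ncol(aj$adjacencies), 0L)
  expect_equal(sort(aj$telomeres), c(1L, 2L))

  # reverse-oriented marker swaps the roles of head and tail
  gs <- parse_unimog(">A\n-1 2 |")
  aj <- genome_adjacencies(gs[[1]])
  expect_equal(sort(aj$adjacencies[, 1]), c(1L, 3L))  # tail1 ~ tail2
})

test_that("every extremity is in exactly one adjacency or a telomere", {
  set.seed(77)
  for (i in 1:30) {
    g <- rand_genome("G", max_markers = 5L, fams = c("1", "2", "3"))
    g <- assign_occurrences(list(g))[[1]]
    expect_true(validate_genome(g))
    aj <- genome_adjacencies(g)
    covered <- c(aj$adjacencies[1, ], aj$adjacencies[2, ], aj$telomeres)
    occs <- genome_occs(g)
    expect_setequal(covered, c(2L * occs - 1L, 2L * occs))
  }
})

test_that("family derivation flags singular and ambiguous families", {
  gs <- pair_from_text(">A\n1 2 |\n>B\n1 |")
  s <- attr(derive_families(gs[[1]], gs[[2]]), "summary")
  expect_true(s$singular[s$fam == "2"])
  expect_false(s$ambiguous[s$fam == "2"])

  gs <- pair_from_text(">A\n1 1 |\n>B\n1 |")
  s <- attr(derive_families(gs[[1]], gs[[2]]), "summary")
  expect_true(s$ambiguous[s$fam == "1"])

  gs <- pair_from_text(">A\n1 |\n>B\n2 |")
  s <- attr(derive_families(gs[[1]], gs[[2]]), "summary")
  expect_true(all(s$singular))
})

test_that("chromosome keys are invariant under reversal and rotation", {
  lin1 <- chromosome(c("1", "2", "3"), c(1L, -1L, 1L))
  lin2 <- chromosome(c("3", "2", "1"), c(-1L, 1L, -1L))   # full reversal
  expect_equal(canonical_chromosome_key(lin1), canonical_chromosome_key(lin2))

  circ1 <- chromosome(c("1", "2", "3"), c(1L, 1L, -1L), circular = TRUE)
  circ2 <- chromosome(c("2", "3", "1"), c(1L, -1L, 1L), circular = TRUE)
  circ3 <- chromosome(c("3", "2", "1"), c(1L, -1L, -1L), circular = TRUE)
  expect_equal(canonical_chromosome_key(circ1), canonical_chromosome_key(circ2))
  expect_equal(canonical_chromosome_key(circ1), canonical_chromosome_key(circ3))

  # linear and circular never collide
  expect_false(canonical_chromosome_key(chromosome("1")) ==
                 canonical_chromosome_key(chromosome("1", circular = TRUE)))
})

test_that("matchings validate injectivity and family membership", {
  gs <- pair_from_text(">A\n1 2 |\n>B\n1 2 |")
  fams <- derive_families(gs[[1]], gs[[2]])
  m <- identity_matching(gs[[1]], gs[[2]])
  expect_equal(nrow(m), 2L)
  expect_true(is_maximal_matching(m, fams))
  expect_error(resolved_matching(c(1L, 1L), c(3L, 4L)), "injective")
  expect_error(resolved_matching(1L, 4L, fams), "different families")
  expect_false(is_maximal_matching(resolved_matching(1L, 3L, fams), fams))
  # ambiguous homologies have no identity matching
  gs2 <- pair_from_text(">A\n1 1 |\n>B\n1 |")
  expect_error(identity_matching(gs2[[1]], gs2[[2]]), "not resolved")
})

test_that("genome equality under a matching matches canonical relabeling", {
  gs <- pair_from_text(">A\n1 -2 |\n>B\n2 -1 |")
  m <- identity_matching(gs[[1]], gs[[2]])
  expect_true(genomes_equal(gs[[1]], gs[[2]], m))   # reversal of the whole
  gs2 <- pair_from_text(">A\n1 2 |\n>B\n1 -2 |")
  m2 <- identity_matching(gs2[[1]], gs2[[2]])
  expect_false(genomes_equal(gs2[[1]], gs2[[2]], m2))
})
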