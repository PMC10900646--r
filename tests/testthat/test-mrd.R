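test_that("MRD construction counts vertices and extremity edges", {
  gs <- pair_from_text(">A\n1 |\n>B\n1 |")
  m <- build_mrd(gs[[1]], gs[[2]])
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$edges_adj), 0L)
  expect_equal(nrow(m$edges_ext), 2L)

  gs <- pair_from_text(">A\n1 1 |\n>B\n1 |")
  m <- build_mrd(gs[[1]], gs[[2]])
  expect_equal(nrow(m$edges_ext), 4L)   # 2 pairs x head+tail

  gs <- pair_from_text(">A\n1 2 |\n>B\n1 |")
  m <- build_mrd(gs[[1]], gs[[2]])
  expect_equal(nrow(m$edges_ext), 2L)   # family 2 contributes none

  # |extremity edges| = sum over families of 2 |f_A| |f_B|
  set.seed(5)
  for (i in 1:10) {
    gs <- rand_pair(max_markers = 4L)
    fams <- derive_families(gs[[1]], gs[[2]])
    s <- attr(fams, "summary")
    m <- build_mrd(gs[[1]], gs[[2]], fams)
    expect_equal(nrow(m$edges_ext), sum(2L * s$n_a * s$n_b))
  }
})

test_that("augmentation adds pseudo-caps, cap edges and indel edges", {
  gs <- pair_from_text(">A\n1 |\n>B\n1 |")
  m <- augment_mrd(build_mrd(gs[[1]], gs[[2]]))
  expect_equal(sum(m$vertices$cap), 4L)
  expect_equal(sum(m$edges_adj$cap), 4L)
  expect_equal(nrow(m$edges_indel), 2L)

  gs <- pair_from_text(">A\n1 2 )\n>B\n1 )")
  m <- augment_mrd(build_mrd(gs[[1]], gs[[2]]))
  expect_equal(sum(m$vertices$cap), 0L)

  # every marker is incident to exactly one indel edge
  set.seed(6)
  gs <- rand_pair(max_markers = 5L)
  m <- augment_mrd(build_mrd(gs[[1]], gs[[2]]))
  expect_setequal(m$edges_indel$occ, c(genome_occs(gs[[1]]), genome_occs(gs[[2]])))
  expect_error(augment_mrd(m), "already augmented")
})

test_that("pseudo-caps take the lowest ix, A before B, before extremities", {
  gs <- pair_from_text(">A\n1 2 |\n>B\n1 | 2 |")
  m <- augment_mrd(build_mrd(gs[[1]], gs[[2]]))
  V <- m$vertices
  caps_a <- V$ix[V$cap & V$genome == "A"]
  caps_b <- V$ix[V$cap & V$genome == "B"]
  rest <- V$ix[!V$cap]
  expect_true(max(caps_a) < min(caps_b))
  expect_true(max(caps_b) < min(rest))
  expect_equal(sort(V$ix), seq_len(nrow(V)))
})

test_that("decompositions select sibling pairs and indel edges consistently", {
  gs <- pair_from_text(">A\n1 |\n>B\n1 |")
  m <- build_mrd(gs[[1]], gs[[2]])
  d <- decomposition_from_matching(m, identity_matching(gs[[1]], gs[[2]]))
  expect_true(all(d$ext_sel))
  expect_length(d$lava_occs, 0L)

  d0 <- decomposition_from_matching(m, resolved_matching(integer(0), integer(0)))
  expect_false(any(d0$ext_sel))
  expect_setequal(d0$lava_occs, 1:2)

  gs <- pair_from_text(">A\n1 1 |\n>B\n1 |")
  m <- build_mrd(gs[[1]], gs[[2]])
  d1 <- decomposition_from_matching(m, resolved_matching(1L, 3L))
  expect_equal(sum(d1$ext_sel), 2L)      # head and tail of the matched pair
  expect_setequal(d1$lava_occs, 2L)
  # cross-family pairs are rejected
  gs2 <- pair_from_text(">A\n1 2 |\n>B\n1 2 |")
  m2 <- build_mrd(gs2[[1]], gs2[[2]])
  expect_error(decomposition_from_matching(m2, resolved_matching(1L, 4L)),
               "different families")
})

test_that("component classification reproduces worked examples", {
  gs <- pair_from_text(">A\n1 |\n>B\n1 |")
  m <- build_mrd(gs[[1]], gs[[2]])
  r <- classify_components(m, decomposition_from_matching(
    m, identity_matching(gs[[1]], gs[[2]])))
  expect_equal(unclass(r)[["n"]], 1L)
  expect_equal(unclass(r)[["p_AB"]], 2L)
  expect_equal(sum(unclass(r)) - 1L - 2L, 0L)

  gs <- pair_from_text(">A\n1 2 |\n>B\n1 |")
  fams <- derive_families(gs[[1]], gs[[2]])
  m <- build_mrd(gs[[1]], gs[[2]], fams)
  r <- classify_components(m, decomposition_from_matching(
    m, resolved_matching(1L, 3L, fams)))
  expect_equal(unclass(r)[["p_AB"]], 1L)
  expect_equal(unclass(r)[["p_Ba"]], 1L)
  expect_equal(unclass(r)[["p_Aoa"]], 1L)

  gs <- pair_from_text(">A\n1 )\n>B\n1 )")
  m <- build_mrd(gs[[1]], gs[[2]])
  r <- classify_components(m, decomposition_from_matching(
    m, identity_matching(gs[[1]], gs[[2]])))
  expect_equal(unclass(r)[["c"]], 1L)
  expect_equal(unclass(r)[["n"]], 1L)
})

test_that("circular singletons are detected per genome", {
  gs <- pair_from_text(">A\n1 ) 2 |\n>B\n2 |")
  fams <- derive_families(gs[[1]], gs[[2]])
  m <- resolved_matching(2L, 3L, fams)
  expect_equal(detect_circular_singletons(gs[[1]], m), 1L)
  expect_equal(detect_circular_singletons(gs[[2]], m), 0L)

  gs2 <- pair_from_text(">A\n1 2 |\n>B\n2 |")
  m2 <- resolved_matching(2L, 3L, derive_families(gs2[[1]], gs2[[2]]))
  expect_equal(detect_circular_singletons(gs2[[1]], m2), 0L)

  # circular chromosome containing one matched marker is no singleton
  gs3 <- pair_from_text(">A\n1 2 )\n>B\n2 |")
  m3 <- resolved_matching(2L, 3L, derive_families(gs3[[1]], gs3[[2]]))
  expect_equal(detect_circular_singletons(gs3[[1]], m3), 0L)
})

test_that("report invariants hold on random decompositions", {
  set.seed(404)
  for (i in 1:40) {
    gs <- rand_pair(max_markers = 4L, fams = c("1", "2", "3"))
    a <- gs[[1]]; b <- gs[[2]]
    fams <- derive_families(a, b)
    mm <- enumerate_maximal_matchings(fams)
    matching <- mm[[sample.int(length(mm), 1L)]]
    r <- unclass(dcjindel:::classify_pair(a, b, matching))

    tel_a <- length(genome_adjacencies(a)$telomeres)
    tel_b <- length(genome_adjacencies(b)$telomeres)
    expect_equal(2L * r[["p_AoA"]] + r[["p_AB"]] + r[["p_Aoa"]] + r[["p_Ab"]],
                 tel_a)
    expect_equal(2L * r[["p_BoB"]] + r[["p_AB"]] + r[["p_Ba"]] + r[["p_Bob"]],
                 tel_b)
    # lava endpoints count the unmatched markers' extremities
    unmatched_a <- length(genome_occs(a)) - nrow(matching)
    unmatched_b <- length(genome_occs(b)) - nrow(matching)
    expect_equal(2L * r[["p_aoa"]] + r[["p_ab"]] + r[["p_Aoa"]] + r[["p_Ba"]],
                 2L * unmatched_a)
    expect_equal(2L * r[["p_bob"]] + r[["p_ab"]] + r[["p_Ab"]] + r[["p_Bob"]],
                 2L * unmatched_b)

    # A<->B swap maps the report by the mirror symmetry
    r_sw <- dcjindel:::classify_pair(b, a, swap_pair_matching(matching))
    expect_equal(unclass(swap_report(r)), unclass(r_sw))
  }
})
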