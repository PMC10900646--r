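test_that("distance formula evaluates worked component reports", {
  expect_equal(formula_distance(component_report(n = 1, c = 1)), 0L)
  expect_equal(formula_distance(component_report(n = 1, p_AB = 2)), 0L)
  expect_equal(formula_distance(component_report(n = 1, p_AB = 1, p_Ba = 1,
                                                 p_Aoa = 1)), 1L)
  expect_equal(formula_distance(component_report(n = 2, p_AB = 2, p_BoB = 1)), 1L)
  # mathematical ceiling on negative numerators (equal genomes)
  expect_equal(formula_distance(component_report(n = 2, p_AB = 4)), 0L)
  # circular singletons add one indel each
  expect_equal(formula_distance(component_report(s = 2)), 2L)
})

test_that("resolved distances match scenario oracles on worked pairs", {
  gs <- pair_from_text(">A\n1 -2 |\n>B\n1 2 |")
  m <- identity_matching(gs[[1]], gs[[2]])
  expect_equal(resolved_distance(gs[[1]], gs[[2]], m)$distance, 1L)

  gs <- pair_from_text(">A\n1 )\n>B\n2 )")
  m <- resolved_matching(integer(0), integer(0))
  rd <- resolved_distance(gs[[1]], gs[[2]], m)
  expect_equal(rd$distance, 2L)
  expect_equal(unclass(rd$report)[["s"]], 2L)

  gs <- pair_from_text(">A\n1 2 |\n>B\n1 | 2 |")
  m <- identity_matching(gs[[1]], gs[[2]])
  expect_equal(resolved_distance(gs[[1]], gs[[2]], m)$distance, 1L)
})

test_that("identity and symmetry hold on random resolved fixtures", {
  set.seed(99)
  for (i in 1:30) {
    gs <- rand_resolved_pair(max_markers = 5L, n_fams = 6L)
    a <- gs[[1]]; b <- gs[[2]]
    m <- identity_matching(a, b)
    # identity: a genome against itself is at distance zero
    self <- as_pair(a, a)
    expect_equal(resolved_distance(
      self[[1]], self[[2]], identity_matching(self[[1]], self[[2]]))$distance, 0L)
    # symmetry under swapping the pair
    d_ab <- resolved_distance(a, b, m)$distance
    d_ba <- resolved_distance(b, a, swap_pair_matching(m))$distance
    expect_equal(d_ab, d_ba)
  }
})

test_that("formula equals the scenario BFS on exhaustive tiny pairs", {
  # fast version of the exhaustive property: every canonical pair with at
  # most 2 markers per genome over two families, every maximal matching
  genomes <- all_canonical_genomes(max_markers = 2L)
  n_checked <- 0L
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    if (j < i) next
    pair <- as_pair(genomes[[i]], genomes[[j]])
    fams <- derive_families(pair[[1]], pair[[2]])
    mm <- enumerate_maximal_matchings(fams)
    mm[[length(mm) + 1L]] <- resolved_matching(integer(0), integer(0))
    for (m in mm) {
      d_f <- resolved_distance(pair[[1]], pair[[2]], m)$distance
      d_o <- cached_bfs_distance(pair[[1]], pair[[2]], m)
      expect_false(is.na(d_o))
      if (d_f != d_o) {
        fail(sprintf("formula %d != oracle %d on:\n%s", d_f, d_o,
                     write_unimog(pair)))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 400L)
})

test_that("formula equals the BFS on non-maximal partial matchings", {
  set.seed(2024)
  for (i in 1:60) {
    gs <- rand_pair(max_markers = 3L)
    fams <- derive_families(gs[[1]], gs[[2]])
    mm <- enumerate_maximal_matchings(fams)
    full <- mm[[sample.int(length(mm), 1)]]
    keep <- if (nrow(full) > 0) sample(c(TRUE, FALSE), nrow(full), TRUE)
      else logical(0)
    part <- resolved_matching(full$occ_a[keep], full$occ_b[keep], fams)
    d_f <- resolved_distance(gs[[1]], gs[[2]], part)$distance
    d_o <- cached_bfs_distance(gs[[1]], gs[[2]], part)
    expect_equal(d_f, d_o)
  }
})

test_that("delta_F reproduces the tabulated operation effects", {
  extraction <- op_signature("K", c("K", "C"), generic = TRUE)
  ctx <- component_report(n = 3, p_Aoa = 2, p_ab = 1, c = 1)
  expect_equal(delta_F(extraction, ctx), -1L)
  expect_equal(delta_F(op_signature("AoA", c("AB", "AB")),
                       component_report(p_AoA = 1, p_ab = 3)), -1L)
  # the even-pier recombination is optimal only in some contexts
  op <- op_signature(c("Aoa", "Aoa"), c("AoA", "aoa"))
  expect_equal(delta_F(op, component_report(p_Aoa = 2)), -1L)
  expect_equal(delta_F(op, component_report(p_Aoa = 2, p_Ba = 2)), 0L)
  # sources must be present
  expect_error(delta_F(op, component_report(p_Aoa = 1)), "absent")
})

test_that("exactly seven operation types are safe", {
  cat <- safe_catalogue()
  expect_length(cat, 7L)
  keys <- vapply(cat, dcjindel:::op_key, character(1))
  expect_true("ab,ab -> aoa,bob" %in% keys)
  expect_true("Aoa,Ba -> AB,aoa" %in% keys)
  expect_true("Ab,Bob -> AB,bob" %in% keys)
  expect_true("AoA -> AB,AB" %in% keys)
  expect_true("BoB -> AB,AB" %in% keys)
  expect_true("AoA,BoB -> AB,AB" %in% keys)
  expect_false("Aoa,Aoa -> AoA,aoa" %in% keys)
  expect_true(any(vapply(cat, function(x) x$generic, logical(1))))
})

test_that("the safe catalogue is closed under swapping the genomes", {
  swap_type <- function(t) {
    out <- chartr("ABab", "BAba", t)
    # the unordered endpoint pairs {A,B} and {a,b} are fixed points
    out[out == "BA"] <- "AB"
    out[out == "ba"] <- "ab"
    out
  }
  cat <- safe_catalogue()
  keys <- sort(vapply(cat, dcjindel:::op_key, character(1)))
  swapped <- sort(vapply(cat, function(op) {
    if (op$generic) return(dcjindel:::op_key(op))
    dcjindel:::op_key(op_signature(swap_type(op$sources),
                                   swap_type(op$resultants)))
  }, character(1)))
  expect_equal(keys, swapped)
})

test_that("operation signatures conserve lava endpoints", {
  expect_error(op_signature("Aoa", "AoA"), "lava")
  expect_error(op_signature(c("ab", "ab"), c("aoa", "aoa")), "lava")
  for (op in safe_catalogue()) {
    if (op$generic) next
    lava_of <- function(tys) {
      ep <- unlist(lapply(tys, dcjindel:::type_endpoints))
      c(sum(ep == "a"), sum(ep == "b"))
    }
    expect_equal(lava_of(op$sources), lava_of(op$resultants))
  }
})

test_that("there are ten reduced bridge types with consistent lava genomes", {
  bridges <- reduced_bridge_types()
  expect_length(bridges, 10L)
  keys <- vapply(bridges, dcjindel:::bridge_key, character(1))
  expect_true("Aoa+Bob+ab" %in% keys)         # pier - odd pontoon - pier
  expect_true("Aoa+Ba" %in% keys)             # same lava genome, no pontoon
  expect_false("Aoa+Ab" %in% keys)            # differing lava, no pontoon
  expect_error(reduced_bridge(c("Aoa", "Ab")), "share the lava genome")
  expect_error(reduced_bridge(c("Aoa", "Ba"), "ab"), "different lava genomes")
  # six pairs, four triples
  expect_equal(sum(vapply(bridges, function(b) is.null(b$pontoon), logical(1))), 6L)
})

test_that("recombination counts match the catalogued enumeration", {
  expect_equal(count_recombinations(op_signature(c("Aoa", "Ba"), c("AB", "aoa"))), 9L)
  expect_equal(count_recombinations(op_signature(c("Ab", "Bob"), c("AB", "bob"))), 9L)
  expect_equal(count_recombinations(op_signature(c("ab", "ab"), c("aoa", "bob"))), 10L)
  expect_error(count_recombinations(op_signature("AoA", c("AB", "AB"))),
               "recombination-enabling")
})
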