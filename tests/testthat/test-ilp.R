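test_that("family bounds implement the three matching models", {
  gs <- pair_from_text(">A\n1 1 1 2 |\n>B\n1 1 3 |")
  fams <- derive_families(gs[[1]], gs[[2]])

  b <- family_bounds(fams, "maximum")
  expect_equal(b$L[b$fam == "1"], 2L)
  expect_equal(b$U[b$fam == "1"], 2L)

  b <- family_bounds(fams, "exemplar")
  expect_equal(b$L[b$fam == "1"], 1L)
  expect_equal(b$U[b$fam == "1"], 1L)

  b <- family_bounds(fams, "intermediate")
  expect_equal(b$L[b$fam == "1"], 1L)
  expect_equal(b$U[b$fam == "1"], 2L)

  # families present in only one genome are never matched
  for (mod in c("maximum", "intermediate", "exemplar")) {
    b <- family_bounds(fams, mod)
    expect_equal(b$L[b$fam %in% c("2", "3")], c(0L, 0L))
    expect_equal(b$U[b$fam %in% c("2", "3")], c(0L, 0L))
  }
  expect_error(family_bounds(fams, "bogus"))
})

test_that("the ILP solves worked examples to their known optima", {
  gs <- pair_from_text(">A\n1 |\n>B\n1 |")
  res <- dcj_indel_ilp(gs[[1]], gs[[2]])
  expect_equal(res$distance, 0L)
  expect_equal(res$solution$status, "optimal")
  expect_equal(res$solution$objective, 0)

  gs <- pair_from_text(">A\n1 1 |\n>B\n1 |")
  res <- dcj_indel_ilp(gs[[1]], gs[[2]])
  expect_equal(res$distance, 1L)
  expect_equal(res$solution$bound, 1)
  expect_equal(nrow(res$matching), 1L)          # exactly one copy matched

  gs <- pair_from_text(">A\n1 )\n>B\n2 )")
  expect_equal(dcj_indel_ilp(gs[[1]], gs[[2]])$distance, 2L)
})

test_that("extraction returns the homology itself on resolved fixtures", {
  gs <- pair_from_text(">A\n1 -3 2 |\n>B\n1 2 3 |")
  res <- dcj_indel_ilp(gs[[1]], gs[[2]])
  m_id <- identity_matching(gs[[1]], gs[[2]])
  expect_equal(res$matching[order(res$matching$occ_a), c("occ_a", "occ_b")],
               m_id[order(m_id$occ_a), c("occ_a", "occ_b")],
               ignore_attr = TRUE)
  expect_equal(res$distance,
               resolved_distance(gs[[1]], gs[[2]], m_id)$distance)
})

test_that("ILP optimum equals the closed form on random resolved pairs", {
  set.seed(314)
  for (i in 1:15) {
    gs <- rand_resolved_pair(max_markers = 5L, n_fams = 6L)
    m <- identity_matching(gs[[1]], gs[[2]])
    d_formula <- resolved_distance(gs[[1]], gs[[2]], m)$distance
    res <- dcj_indel_ilp(gs[[1]], gs[[2]])
    expect_equal(res$distance, d_formula)
    expect_equal(round(res$solution$objective), d_formula)
  }
})

test_that("ILP optimum equals the matching-enumeration minimum", {
  set.seed(271)
  for (i in 1:25) {
    gs <- rand_pair(max_markers = 5L, fams = c("1", "2", "3"))
    d_enum <- as.integer(min_distance_by_enumeration(gs[[1]], gs[[2]]))
    res <- dcj_indel_ilp(gs[[1]], gs[[2]])
    expect_equal(res$distance, d_enum)
    expect_equal(round(res$solution$objective), d_enum)
    # extracted matching is maximal under the maximum model
    fams <- derive_families(gs[[1]], gs[[2]])
    expect_true(is_maximal_matching(res$matching, fams))
  }
})

test_that("matched-pair counts respect the family bounds in every model", {
  gs <- pair_from_text(">A\n1 1 2 2 -1 |\n>B\n1 -2 2 |")
  fams <- derive_families(gs[[1]], gs[[2]])
  for (mod in c("maximum", "intermediate", "exemplar")) {
    b <- family_bounds(fams, mod)
    res <- dcj_indel_ilp(gs[[1]], gs[[2]], model = mod)
    cnt <- table(factor(res$matching$fam, levels = b$fam))
    expect_true(all(as.integer(cnt) >= b$L & as.integer(cnt) <= b$U))
  }
  # exemplar keeps one pair per shared family
  res <- dcj_indel_ilp(gs[[1]], gs[[2]], model = "exemplar")
  expect_equal(nrow(res$matching), 2L)
})

test_that("both solver backends agree and model export is solvable", {
  gs <- pair_from_text(">A\n1 1 2 |\n>B\n2 -1 |")
  fams <- derive_families(gs[[1]], gs[[2]])
  mrd <- augment_mrd(build_mrd(gs[[1]], gs[[2]], fams))
  model <- build_model(mrd, family_bounds(fams, "maximum"))

  sol_scipy <- solve_ilp(model, solver = "scipy")
  expect_equal(sol_scipy$status, "optimal")
  sol_glpk <- solve_ilp(model, solver = "glpk")
  expect_equal(sol_glpk$status, "optimal")
  expect_equal(sol_glpk$objective, sol_scipy$objective)
  d_enum <- as.integer(min_distance_by_enumeration(gs[[1]], gs[[2]]))
  expect_equal(round(sol_glpk$objective), d_enum)

  lp <- tempfile(fileext = ".lp"); mps <- tempfile(fileext = ".mps")
  write_lp(model, lp); write_mps(model, mps)
  expect_true(file.exists(lp) && file.exists(mps))
  # the free-MPS export feeds any exact MIP solver; check with glpsol
  out <- tempfile()
  system2("glpsol", c("--freemps", shQuote(mps), "-o", shQuote(out)),
          stdout = NULL, stderr = NULL)
  sol_lines <- readLines(out, warn = FALSE)
  expect_true(any(grepl("INTEGER OPTIMAL", sol_lines)))
  obj_line <- grep("^Objective", sol_lines, value = TRUE)[1]
  expect_equal(as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*\\(.*", "\\1", obj_line)),
               sol_scipy$objective)
})

test_that("batch solving matches one-by-one solving", {
  set.seed(8)
  models <- list()
  answers <- integer(0)
  for (i in 1:4) {
    gs <- rand_pair(max_markers = 4L)
    fams <- derive_families(gs[[1]], gs[[2]])
    mrd <- augment_mrd(build_mrd(gs[[1]], gs[[2]], fams))
    models[[i]] <- build_model(mrd, family_bounds(fams, "maximum"))
    answers[i] <- as.integer(min_distance_by_enumeration(gs[[1]], gs[[2]]))
  }
  sols <- solve_scipy_batch(models)
  expect_equal(vapply(sols, function(s) round(s$objective), numeric(1)),
               as.numeric(answers))
})
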