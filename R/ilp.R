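#' Capping-free ILP for the DCJ-indel distance of natural genomes
#'
#' The program minimizes the restricted DCJ-indel distance over consistent
#' decompositions of the augmented MRD, i.e. over matchings within the
#' selected matching model. Instead of capping (joining linear chromosome
#' ends into circular structures at solve time), telomeres are anchored by
#' inert pseudo-cap vertices, and the component types of the distance
#' formula are detected by report variables on adjacency edges.
#'
#' @name ilp
#' @keywords internal
NULL

#' Per-family matching bounds for a matching model
#'
#' * `maximum`: `L_f = U_f = min(|f_A|, |f_B|)` (maximal matchings);
#' * `intermediate`: `L_f = 1`, `U_f = min(|f_A|, |f_B|)`;
#' * `exemplar`: `L_f = U_f = 1`.
#'
#' Families present in only one genome get `L_f = U_f = 0` in every model.
#'
#' @param fams A [derive_families()] result.
#' @param model One of `"maximum"`, `"intermediate"`, `"exemplar"`.
#' @return Data frame with columns `fam`, `L`, `U`.
#' @export
family_bounds <- function(fams, model = c("maximum", "intermediate", "exemplar")) {
  model <- match.arg(model)
  s <- attr(fams, "summary")
  mins <- pmin(s$n_a, s$n_b)
  both <- mins > 0L
  L <- U <- integer(length(mins))
  if (model == "maximum") {
    L[both] <- mins[both]; U[both] <- mins[both]
  } else if (model == "intermediate") {
    L[both] <- 1L; U[both] <- mins[both]
  } else {
    L[both] <- 1L; U[both] <- 1L
  }
  data.frame(fam = s$fam, L = L, U = U, stringsAsFactors = FALSE)
}

# ---- model builder infrastructure ----------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$vname <- character(0); env$vtype <- character(0)
  env$vlb <- numeric(0); env$vub <- numeric(0); env$vobj <- numeric(0)
  env$rows <- list()   # each: list(name, idx, coef, sense, rhs)
  env
}

bld_var <- function(env, name, type, lb, ub, obj = 0) {
  env$vname <- c(env$vname, name)
  env$vtype <- c(env$vtype, type)
  env$vlb <- c(env$vlb, lb); env$vub <- c(env$vub, ub)
  env$vobj <- c(env$vobj, obj)
  length(env$vname)
}

bld_con <- function(env, name, idx, coef, sense, rhs) {
  keep <- coef != 0
  env$rows[[length(env$rows) + 1L]] <-
    list(name = name, idx = idx[keep], coef = coef[keep], sense = sense, rhs = rhs)
  invisible(NULL)
}

#' Build the capping-free ILP model
#'
#' Encodes, over an augmented MRD: the consistent-decomposition constraints
#' (every extremity covered by one extremity edge or its marker's indel
#' edge; sibling head/tail edges equal), the per-family matching bounds,
#' the component-labeling machinery (`y` equal along decomposition edges
#' and zero in components with lava vertices, `z` marking the minimum-id
#' vertex of lava-free components), endpoint label variables `l` (0 for
#' genome A, 1 for genome B, pinned at pseudo-caps and lava vertices and
#' constant along edges except where an odd-path report licenses a change),
#' report variables for cycles, `A|B` viaducts, the four pier types and odd
#' pontoons, counter definitions, the four inequalities realizing the
#' ceiled fraction of the distance formula, and circular-singleton
#' indicators. Objective: minimize `n - c + q + s`.
#'
#' @param m An augmented MRD ([augment_mrd()]).
#' @param bounds A [family_bounds()] data frame.
#' @return Object of class `ilp_model` with the variable table, sparse
#'   constraint rows, objective offset 0 and extraction metadata.
#' @export
build_model <- function(m, bounds) {
  if (!isTRUE(m$augmented)) stop("build_model() needs an augmented MRD")
  env <- new_builder()
  V <- m$vertices
  N <- nrow(V)
  bigM <- N

  occ_all <- c(m$occs$A, m$occs$B)
  occ_genome <- stats::setNames(
    rep(c("A", "B"), c(length(m$occs$A), length(m$occs$B))),
    as.character(occ_all))

  # -- variables -----------------------------------------------------------
  # extremity-edge selection x, one per edge row (tail and head siblings)
  ne <- nrow(m$edges_ext)
  x_idx <- integer(ne)
  for (i in seq_len(ne))
    x_idx[i] <- bld_var(env, paste0("x", i), "B", 0, 1)
  # indel-edge selection, one per marker occurrence
  w_idx <- stats::setNames(integer(length(occ_all)), as.character(occ_all))
  for (o in occ_all)
    w_idx[as.character(o)] <- bld_var(env, paste0("w", o), "B", 0, 1)
  # y, z per vertex; l per vertex with pseudo-cap pinning
  y_idx <- integer(N); z_idx <- integer(N); l_idx <- integer(N)
  for (v in seq_len(N)) {
    y_idx[v] <- bld_var(env, paste0("y", v), "I", 0, V$ix[v])
    z_idx[v] <- bld_var(env, paste0("z", v), "B", 0, 1)
    if (V$cap[v]) {
      if (V$genome[v] == "A") l_idx[v] <- bld_var(env, paste0("l", v), "B", 0, 0)
      else l_idx[v] <- bld_var(env, paste0("l", v), "B", 1, 1)
    } else {
      l_idx[v] <- bld_var(env, paste0("l", v), "B", 0, 1)
    }
  }

  # report variables on adjacency edges
  EA <- m$edges_adj
  na_e <- nrow(EA)
  cap_of_edge <- ifelse(EA$cap, ifelse(V$cap[EA$u], EA$u, EA$v), NA_integer_)
  cap_genome <- ifelse(is.na(cap_of_edge), NA_character_, V$genome[cap_of_edge])
  r_c <- rep(NA_integer_, na_e); r_AB <- rep(NA_integer_, na_e)
  r_Aoa <- rep(NA_integer_, na_e); r_Ab <- rep(NA_integer_, na_e)
  r_Ba <- rep(NA_integer_, na_e); r_Bob <- rep(NA_integer_, na_e)
  r_ab <- integer(na_e)
  for (e in seq_len(na_e)) {
    if (!EA$cap[e]) {
      r_c[e] <- bld_var(env, paste0("rc", e), "B", 0, 1)
    } else if (cap_genome[e] == "A") {
      r_AB[e] <- bld_var(env, paste0("rAB", e), "B", 0, 1)
      r_Aoa[e] <- bld_var(env, paste0("rAa", e), "B", 0, 1)
      r_Ab[e] <- bld_var(env, paste0("rAb", e), "B", 0, 1)
    } else {
      r_Ba[e] <- bld_var(env, paste0("rBa", e), "B", 0, 1)
      r_Bob[e] <- bld_var(env, paste0("rBb", e), "B", 0, 1)
    }
    r_ab[e] <- bld_var(env, paste0("rab", e), "B", 0, 1)
  }

  # counters and objective variables
  n_idx <- bld_var(env, "n", "I", 0, ne / 2, obj = 1)
  c_idx <- bld_var(env, "cN", "I", 0, max(na_e, 1), obj = -1)
  q_idx <- bld_var(env, "q", "I", -N, N, obj = 1)
  s_idx <- bld_var(env, "sN", "I", 0, length(occ_all), obj = 1)
  p_idx <- c(
    AB = bld_var(env, "pAB", "I", 0, max(na_e, 1)),
    Aoa = bld_var(env, "pAa", "I", 0, max(na_e, 1)),
    Ab = bld_var(env, "pAb", "I", 0, max(na_e, 1)),
    Ba = bld_var(env, "pBa", "I", 0, max(na_e, 1)),
    Bob = bld_var(env, "pBb", "I", 0, max(na_e, 1)),
    ab = bld_var(env, "pab", "I", 0, max(na_e, 1)))

  # circular-singleton indicators, one per circular chromosome
  circ_chroms <- list()
  for (g in list(m$a, m$b))
    for (ch in g$chromosomes)
      if (ch$circular) circ_chroms[[length(circ_chroms) + 1L]] <- ch$occ
  sK_idx <- integer(length(circ_chroms))
  for (k in seq_along(circ_chroms))
    sK_idx[k] <- bld_var(env, paste0("sK", k), "B", 0, 1)

  # -- constraints ---------------------------------------------------------
  # C.01: each extremity vertex covered exactly once
  ext_vs <- which(!V$cap)
  edges_at <- vector("list", N)
  for (i in seq_len(ne)) {
    edges_at[[m$edges_ext$u[i]]] <- c(edges_at[[m$edges_ext$u[i]]], i)
    edges_at[[m$edges_ext$v[i]]] <- c(edges_at[[m$edges_ext$v[i]]], i)
  }
  for (v in ext_vs) {
    ii <- edges_at[[v]]
    bld_con(env, paste0("C01_", v),
            c(x_idx[ii], w_idx[[as.character(V$occ[v])]]),
            c(rep(1, length(ii)), 1), "=", 1)
  }
  # C.02/C.03: sibling consistency (tail edge selected iff head edge is)
  sib_rows <- split(seq_len(ne), m$edges_ext$sib)
  pair_rep <- integer(length(sib_rows))   # tail-edge x index per sibling pair
  pair_occ <- matrix(0L, length(sib_rows), 2)
  for (p in seq_along(sib_rows)) {
    rows <- sib_rows[[p]]
    stopifnot(length(rows) == 2L)
    bld_con(env, paste0("C02_", p), x_idx[rows], c(1, -1), "=", 0)
    tail_row <- rows[m$edges_ext$side[rows] == "t"]
    pair_rep[p] <- x_idx[tail_row]
    pair_occ[p, ] <- c(m$edges_ext$occ_a[tail_row], m$edges_ext$occ_b[tail_row])
  }
  # C.04: y bounded by ix (variable bound), zero at lava vertices, equal
  # along decomposition edges
  for (v in ext_vs) {
    bld_con(env, paste0("C04l_", v),
            c(y_idx[v], w_idx[[as.character(V$occ[v])]]),
            c(1, V$ix[v]), "<=", V$ix[v])
  }
  for (e in seq_len(na_e)) {
    bld_con(env, paste0("C04a_", e), c(y_idx[EA$u[e]], y_idx[EA$v[e]]),
            c(1, -1), "=", 0)
  }
  for (i in seq_len(ne)) {
    u <- m$edges_ext$u[i]; v <- m$edges_ext$v[i]
    bld_con(env, paste0("C04x_", i, "a"), c(y_idx[u], y_idx[v], x_idx[i]),
            c(1, -1, bigM), "<=", bigM)
    bld_con(env, paste0("C04x_", i, "b"), c(y_idx[v], y_idx[u], x_idx[i]),
            c(1, -1, bigM), "<=", bigM)
  }
  EI <- m$edges_indel
  for (i in seq_len(nrow(EI))) {
    u <- EI$u[i]; v <- EI$v[i]; wv <- w_idx[[as.character(EI$occ[i])]]
    bld_con(env, paste0("C04i_", i, "a"), c(y_idx[u], y_idx[v], wv),
            c(1, -1, bigM), "<=", bigM)
    bld_con(env, paste0("C04i_", i, "b"), c(y_idx[v], y_idx[u], wv),
            c(1, -1, bigM), "<=", bigM)
  }
  # C.05: z marks the minimum-id vertex of a lava-free component
  for (v in seq_len(N))
    bld_con(env, paste0("C05_", v), c(z_idx[v], y_idx[v]),
            c(V$ix[v], -1), "<=", 0)
  # C.06: family bounds on matched pairs
  pair_fams <- fam_of_pairs(m, pair_occ)
  for (fi in seq_len(nrow(bounds))) {
    f <- bounds$fam[fi]
    pp <- which(pair_fams == f)
    if (length(pp) == 0L) next
    bld_con(env, paste0("C06l_", fi), pair_rep[pp], rep(1, length(pp)),
            ">=", bounds$L[fi])
    bld_con(env, paste0("C06u_", fi), pair_rep[pp], rep(1, length(pp)),
            "<=", bounds$U[fi])
  }
  # C.07 is static (l bounds at pseudo-caps). C.08: l pinned at lava vertices
  for (v in ext_vs) {
    wv <- w_idx[[as.character(V$occ[v])]]
    if (V$genome[v] == "A")
      bld_con(env, paste0("C08_", v), c(l_idx[v], wv), c(1, 1), "<=", 1)
    else
      bld_con(env, paste0("C08_", v), c(l_idx[v], wv), c(1, -1), ">=", 0)
  }
  # C.09: l equal across decomposition edges, relaxed by odd reports
  odd_at_edge <- function(e) {
    idx <- c(r_AB[e], r_Ab[e], r_Ba[e], r_ab[e])
    idx[!is.na(idx)]
  }
  for (e in seq_len(na_e)) {
    odd <- odd_at_edge(e)
    u <- EA$u[e]; v <- EA$v[e]
    bld_con(env, paste0("C09a_", e), c(l_idx[u], l_idx[v], odd),
            c(1, -1, rep(-1, length(odd))), "<=", 0)
    bld_con(env, paste0("C09b_", e), c(l_idx[v], l_idx[u], odd),
            c(1, -1, rep(-1, length(odd))), "<=", 0)
  }
  for (i in seq_len(ne)) {
    u <- m$edges_ext$u[i]; v <- m$edges_ext$v[i]
    bld_con(env, paste0("C09x_", i, "a"), c(l_idx[u], l_idx[v], x_idx[i]),
            c(1, -1, 1), "<=", 1)
    bld_con(env, paste0("C09x_", i, "b"), c(l_idx[v], l_idx[u], x_idx[i]),
            c(1, -1, 1), "<=", 1)
  }
  # C.10: cycle and A|B reports licensed (once) by an adjacent z at the
  # lower-id endpoint
  lic <- vector("list", N)
  for (e in seq_len(na_e)) {
    lo <- if (V$ix[EA$u[e]] < V$ix[EA$v[e]]) EA$u[e] else EA$v[e]
    rr <- c(r_c[e], r_AB[e])
    rr <- rr[!is.na(rr)]
    if (length(rr)) lic[[lo]] <- c(lic[[lo]], rr)
  }
  for (v in seq_len(N)) {
    if (length(lic[[v]]))
      bld_con(env, paste0("C10_", v), c(lic[[v]], z_idx[v]),
              c(rep(1, length(lic[[v]])), -1), "<=", 0)
  }
  # C.11: a pier report zeroes the component's y (via its pseudo-cap);
  # C.12: a pseudo-cap with y = 0 must report a pier
  for (e in seq_len(na_e)) {
    if (!EA$cap[e]) next
    w <- cap_of_edge[e]
    piers <- c(r_Aoa[e], r_Ab[e], r_Ba[e], r_Bob[e])
    piers <- piers[!is.na(piers)]
    for (r in piers)
      bld_con(env, paste0("C11_", e, "_", r), c(y_idx[w], r),
              c(1, V$ix[w]), "<=", V$ix[w])
    bld_con(env, paste0("C12_", e), c(piers, y_idx[w]),
            c(rep(1, length(piers)), 1), ">=", 1)
  }
  # C.13: odd reports need a label change at the reporting edge
  for (e in seq_len(na_e)) {
    u <- EA$u[e]; v <- EA$v[e]
    for (r in odd_at_edge(e)) {
      bld_con(env, paste0("C13a_", r), c(r, l_idx[u], l_idx[v]),
              c(1, -1, -1), "<=", 0)
      bld_con(env, paste0("C13b_", r), c(r, l_idx[u], l_idx[v]),
              c(1, 1, 1), "<=", 2)
    }
  }
  # C.14: odd-pontoon reports need a neighboring selected indel edge
  for (e in seq_len(na_e)) {
    wvs <- integer(0)
    for (vv in c(EA$u[e], EA$v[e]))
      if (!V$cap[vv]) wvs <- c(wvs, w_idx[[as.character(V$occ[vv])]])
    bld_con(env, paste0("C14_", e), c(r_ab[e], unique(wvs)),
            c(1, rep(-1, length(unique(wvs)))), "<=", 0)
  }
  # C.15: n = number of selected sibling pairs
  bld_con(env, "C15", c(n_idx, pair_rep), c(1, rep(-1, length(pair_rep))),
          "=", 0)
  # C.16-C.27: counters are sums of their reports; q >= each ceiled-max combo
  sum_def <- function(name, counter, rvars) {
    rvars <- rvars[!is.na(rvars)]
    bld_con(env, name, c(counter, rvars), c(1, rep(-1, length(rvars))), "=", 0)
  }
  sum_def("C16", c_idx, r_c)
  sum_def("C17", p_idx[["AB"]], r_AB)
  sum_def("C18", p_idx[["Aoa"]], r_Aoa)
  sum_def("C19", p_idx[["Ab"]], r_Ab)
  sum_def("C20", p_idx[["Ba"]], r_Ba)
  sum_def("C21", p_idx[["Bob"]], r_Bob)
  sum_def("C22", p_idx[["ab"]], r_ab)
  combo <- 0L
  for (alpha in c("Aoa", "Ba")) for (beta in c("Ab", "Bob")) {
    combo <- combo + 1L
    bld_con(env, paste0("C23_", combo),
            c(q_idx, p_idx[["ab"]], p_idx[[alpha]], p_idx[[beta]], p_idx[["AB"]]),
            c(2, -1, -1, -1, 1), ">=", 0)
  }
  # C.28/C.29: circular singletons
  for (k in seq_along(circ_chroms)) {
    ws <- w_idx[as.character(circ_chroms[[k]])]
    bld_con(env, paste0("C28_", k), c(ws, sK_idx[k]),
            c(rep(1, length(ws)), -1), "<=", length(ws) - 1L)
  }
  bld_con(env, "C29", c(s_idx, sK_idx),
          c(1, rep(-1, length(sK_idx))), "=", 0)

  structure(list(
    vars = data.frame(name = env$vname, type = env$vtype, lb = env$vlb,
                      ub = env$vub, obj = env$vobj, stringsAsFactors = FALSE),
    rows = env$rows,
    meta = list(pair_rep = pair_rep, pair_occ = pair_occ,
                w_idx = w_idx, n_idx = n_idx, c_idx = c_idx, q_idx = q_idx,
                s_idx = s_idx, p_idx = p_idx, mrd_n_vertices = N)),
    class = "ilp_model")
}

# family token of each sibling pair (helper for C.06)
fam_of_pairs <- function(m, pair_occ) {
  fam_of_a <- fam_lookup(m$fams, "A")
  unname(fam_of_a[as.character(pair_occ[, 1])])
}

#' @export
print.ilp_model <- function(x, ...) {
  cat("ILP model:", nrow(x$vars), "variables,", length(x$rows), "constraints\n")
  invisible(x)
}

# ---- LP / MPS export -----------------------------------------------------

lp_terms <- function(idx, coef, vnames) {
  paste(sprintf("%+g %s", coef, vnames[idx]), collapse = " ")
}

#' Write an ILP model in CPLEX LP text format
#'
#' @param model An [build_model()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_lp <- function(model, path) {
  v <- model$vars
  out <- c("Minimize")
  obj_i <- which(v$obj != 0)
  out <- c(out, paste(" obj:", lp_terms(obj_i, v$obj[obj_i], v$name)))
  out <- c(out, "Subject To")
  for (r in model$rows) {
    sense <- switch(r$sense, "<=" = "<=", ">=" = ">=", "=" = "=")
    out <- c(out, sprintf(" %s: %s %s %g", r$name,
                          lp_terms(r$idx, r$coef, v$name), sense, r$rhs))
  }
  out <- c(out, "Bounds")
  for (i in seq_len(nrow(v)))
    out <- c(out, sprintf(" %g <= %s <= %g", v$lb[i], v$name[i], v$ub[i]))
  gen <- which(v$type %in% c("I", "B"))
  out <- c(out, "Generals", paste(" ", v$name[gen]), "End")
  writeLines(out, path)
  invisible(path)
}

#' Write an ILP model in free MPS text format
#'
#' @param model An [build_model()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mps <- function(model, path) {
  v <- model$vars
  out <- c("NAME dcjindel", "ROWS", " N obj")
  for (r in model$rows) {
    tag <- switch(r$sense, "<=" = "L", ">=" = "G", "=" = "E")
    out <- c(out, paste("", tag, r$name))
  }
  # column-major coefficient lists
  col_terms <- vector("list", nrow(v))
  for (i in which(v$obj != 0))
    col_terms[[i]] <- c(col_terms[[i]], sprintf("obj %g", v$obj[i]))
  for (r in model$rows)
    for (k in seq_along(r$idx))
      col_terms[[r$idx[k]]] <- c(col_terms[[r$idx[k]]],
                                 sprintf("%s %g", r$name, r$coef[k]))
  out <- c(out, "COLUMNS", " M1 'MARKER' 'INTORG'")
  for (i in seq_len(nrow(v)))
    for (t in col_terms[[i]])
      out <- c(out, paste("", v$name[i], t))
  out <- c(out, " M2 'MARKER' 'INTEND'", "RHS")
  for (r in model$rows)
    if (r$rhs != 0) out <- c(out, sprintf(" RHS %s %g", r$name, r$rhs))
  out <- c(out, "BOUNDS")
  for (i in seq_len(nrow(v))) {
    out <- c(out, sprintf(" LO BND %s %g", v$name[i], v$lb[i]),
             sprintf(" UP BND %s %g", v$name[i], v$ub[i]))
  }
  out <- c(out, "ENDATA")
  writeLines(out, path)
  invisible(path)
}
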