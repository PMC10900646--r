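#' Restricted DCJ-indel distance under a resolved homology
#'
#' The closed-form distance reads off the component report of the simple
#' MRD:
#' \deqn{d = n - c + \lceil (p_{ab} + \max(p_{Aoa}, p_{Ba}) +
#'   \max(p_{Ab}, p_{Bob}) - p_{AB}) / 2 \rceil + s}
#' with `n` matched markers, `c` cycles, the six path counts, and `s`
#' circular singletons (each pre-paid with one indel). The ceiling is the
#' mathematical one, so a negative numerator rounds towards zero from
#' below (e.g. equal genomes give `ceil(-2/2) = -1`).
#'
#' @param r A [component_report()].
#' @return Integer distance value of the formula.
#' @examples
#' formula_distance(component_report(n = 1, c = 1))       # equal circular
#' formula_distance(component_report(n = 1, p_AB = 2))    # equal linear
#' @export
formula_distance <- function(r) {
  r <- unclass(r)
  num <- r[["p_ab"]] + max(r[["p_Aoa"]], r[["p_Ba"]]) +
    max(r[["p_Ab"]], r[["p_Bob"]]) - r[["p_AB"]]
  as.integer(r[["n"]] - r[["c"]] + ceiling(num / 2) + r[["s"]])
}

#' Distance of a genome pair under a resolved matching
#'
#' Circular singletons are counted and removed first (adding `s` to the
#' distance), then the remaining pair is decomposed along the matching,
#' components are classified and the distance formula applied.
#'
#' @param a,b `dcj_genome` objects with occurrence ids.
#' @param match A [resolved_matching()].
#' @return List with elements `distance` (integer) and `report`
#'   (a [component_report()] including `n` and `s`).
#' @examples
#' gs <- parse_unimog(">A\n1 -2 |\n>B\n1 2 |")
#' m <- identity_matching(gs[[1]], gs[[2]])
#' resolved_distance(gs[[1]], gs[[2]], m)$distance  # one inversion
#' @export
resolved_distance <- function(a, b, match) {
  s <- detect_circular_singletons(a, match) + detect_circular_singletons(b, match)
  a2 <- drop_circular_singletons(a, match)
  b2 <- drop_circular_singletons(b, match)
  if (length(a2$chromosomes) == 0L && length(b2$chromosomes) == 0L) {
    rep <- component_report(s = s)
    return(list(distance = formula_distance(rep), report = rep))
  }
  rep <- classify_pair(a2, b2, match)
  rep["s"] <- s
  list(distance = formula_distance(rep), report = rep)
}

# ---- Abstract DCJ operation signatures -----------------------------------

component_types <- c("C", "AoA", "AB", "BoB", "Aoa", "Ab", "Ba", "Bob",
                     "aoa", "ab", "bob")

type_endpoints <- function(type) {
  switch(type,
         C = character(0),
         AoA = c("A", "A"), AB = c("A", "B"), BoB = c("B", "B"),
         Aoa = c("A", "a"), Ab = c("A", "b"), Ba = c("B", "a"), Bob = c("B", "b"),
         aoa = c("a", "a"), ab = c("a", "b"), bob = c("b", "b"),
         stop("unknown component type: ", type))
}

#' Construct an abstract DCJ operation signature
#'
#' Operations are written on component types, e.g.
#' `op_signature(c("Aoa", "Ba"), c("AB", "aoa"))` for the safe pier
#' recombination. Lava endpoints are conserved between sources and
#' resultants; telomeres may be created or destroyed in same-genome pairs
#' (a cut or join). The generic cycle-extraction family `K -> K' + C`
#' (with `K'` possibly empty, i.e. whole-component circularization) is
#' represented with `generic = TRUE`.
#'
#' @param sources,resultants Character vectors of component type names
#'   (from `C`, `AoA`, `AB`, `BoB`, `Aoa`, `Ab`, `Ba`, `Bob`, `aoa`, `ab`,
#'   `bob`), or `"K"` placeholders for the generic signature.
#' @param generic Logical; marks the cycle-extraction family.
#' @return Object of class `op_signature`.
#' @export
op_signature <- function(sources, resultants, generic = FALSE) {
  if (!generic) {
    stopifnot(all(sources %in% component_types),
              all(resultants %in% component_types))
    lava <- function(tys) {
      ep <- unlist(lapply(tys, type_endpoints))
      c(a = sum(ep == "a"), b = sum(ep == "b"))
    }
    if (!identical(lava(sources), lava(resultants)))
      stop("signature does not conserve lava endpoints")
  }
  structure(list(sources = sort(sources, method = "radix"),
                 resultants = sort(resultants, method = "radix"),
                 generic = isTRUE(generic)),
            class = "op_signature")
}

#' @export
print.op_signature <- function(x, ...) {
  cat(paste(x$sources, collapse = ","), "->",
      paste(x$resultants, collapse = ","),
      if (x$generic) "(generic cycle extraction)", "\n")
  invisible(x)
}

op_key <- function(op) {
  paste(paste(op$sources, collapse = ","), paste(op$resultants, collapse = ","),
        sep = " -> ")
}

report_counts_of_types <- function(tys) {
  key <- ifelse(tys == "C", "c", paste0("p_", tys))
  tab <- table(key)
  out <- stats::setNames(as.integer(tab), names(tab))
  out
}

apply_op_to_report <- function(op, r) {
  r <- unclass(r)
  if (op$generic) {
    r["c"] <- r["c"] + 1L
    return(structure(r, class = "component_report"))
  }
  dec <- report_counts_of_types(op$sources)
  inc <- report_counts_of_types(op$resultants)
  r[names(dec)] <- r[names(dec)] - dec
  r[names(inc)] <- r[names(inc)] + inc
  if (any(r < 0L)) stop("operation sources absent from context")
  structure(r, class = "component_report")
}

#' Change of the distance formula under an abstract operation
#'
#' Evaluates `F(context after op) - F(context)` where `F` is the value of
#' [formula_distance()] (with `n` and `s` unchanged). The generic
#' cycle-extraction signature adds one cycle and leaves everything else in
#' place, which is its effect on `F` for every concrete instantiation.
#'
#' @param op An [op_signature()].
#' @param context A [component_report()] containing the sources.
#' @return Integer change in `F` (safe operations give -1).
#' @export
delta_F <- function(op, context) {
  if (!op$generic) {
    dec <- report_counts_of_types(op$sources)
    ctx <- unclass(context)
    if (any(ctx[names(dec)] < dec))
      stop("operation sources absent from context")
  } else if (sum(unclass(context)[c("c", paste0("p_", path_type_names))]) < 1L) {
    stop("generic extraction needs at least one component in the context")
  }
  formula_distance(apply_op_to_report(op, context)) - formula_distance(context)
}

# ---- Candidate universe of realizable signatures -------------------------

# All signatures realizable by a single DCJ at the component-type level:
# recombinations (two cuts in two components, both repairings), fissions
# (one cut, creating a same-genome telomere pair), fusions (one join,
# consuming a same-genome telomere pair), cycle absorption, and the
# extraction family. Path parity is determined by the endpoint classes, so
# types are identified with endpoint multisets here.
enumerate_signatures <- function() {
  paths <- setdiff(component_types, "C")
  sigs <- list()
  add <- function(sources, resultants) {
    op <- op_signature(sources, resultants)
    sigs[[op_key(op)]] <<- op
  }
  ep_type <- function(e1, e2) endpoint_pair_to_type(e1, e2)

  for (i in seq_along(paths)) for (j in i:length(paths)) {
    x <- paths[i]; y <- paths[j]
    e1 <- type_endpoints(x); e2 <- type_endpoints(y)
    # recombination: both repairings of the four endpoints
    add(c(x, y), c(ep_type(e1[1], e2[1]), ep_type(e1[2], e2[2])))
    add(c(x, y), c(ep_type(e1[1], e2[2]), ep_type(e1[2], e2[1])))
    # fusion: consume one same-genome telomere from each
    for (t1 in which(e1 %in% c("A", "B"))) for (t2 in which(e2 %in% c("A", "B"))) {
      if (e1[t1] == e2[t2])
        add(c(x, y), ep_type(e1[-t1], e2[-t2]))
    }
  }
  for (x in paths) {
    e <- type_endpoints(x)
    # fission: cut an adjacency of genome g inside the path
    for (g in c("A", "B"))
      add(x, c(ep_type(e[1], g), ep_type(g, e[2])))
    # cycle absorption into a path
    add(c("C", x), x)
  }
  for (g in c("A", "B")) add("C", ep_type(g, g))  # cycle fission
  add(c("C", "C"), "C")                            # cycle merge
  # extraction family: K -> K' + C with K' = K or empty (circularization of
  # a two-same-genome-telomere path); collapsed to one generic signature
  extraction <- op_signature("K", c("K", "C"), generic = TRUE)
  list(specific = sigs, generic = extraction)
}

# Instantiations of the generic extraction family, used to verify its
# safety concretely.
extraction_instances <- function() {
  out <- list()
  for (k in component_types)
    out[[length(out) + 1L]] <- op_signature(k, c(k, "C"))
  out[[length(out) + 1L]] <- op_signature("AoA", "C")
  out[[length(out) + 1L]] <- op_signature("BoB", "C")
  out
}

# Evaluate dF over every context with 0..max_copies extra copies of each
# formula-relevant component type (other types never change dF). Vectorized
# over the context grid.
is_safe_signature <- function(op, max_copies = 4L) {
  rel <- c("p_ab", "p_Aoa", "p_Ba", "p_Ab", "p_Bob", "p_AB")
  grid <- expand.grid(rep(list(0:max_copies), length(rel)))
  names(grid) <- rel
  base <- report_counts_of_types(op$sources)
  for (f in intersect(names(base), rel)) grid[[f]] <- grid[[f]] + base[[f]]
  dc <- 0L
  delta <- stats::setNames(integer(length(rel)), rel)
  if (op$generic) {
    dc <- 1L
  } else {
    dec <- report_counts_of_types(op$sources)
    inc <- report_counts_of_types(op$resultants)
    for (f in names(dec)) {
      if (f == "c") dc <- dc - dec[[f]]
      else if (f %in% rel) delta[f] <- delta[f] - dec[[f]]
    }
    for (f in names(inc)) {
      if (f == "c") dc <- dc + inc[[f]]
      else if (f %in% rel) delta[f] <- delta[f] + inc[[f]]
    }
  }
  num_before <- grid$p_ab + pmax(grid$p_Aoa, grid$p_Ba) +
    pmax(grid$p_Ab, grid$p_Bob) - grid$p_AB
  num_after <- (grid$p_ab + delta[["p_ab"]]) +
    pmax(grid$p_Aoa + delta[["p_Aoa"]], grid$p_Ba + delta[["p_Ba"]]) +
    pmax(grid$p_Ab + delta[["p_Ab"]], grid$p_Bob + delta[["p_Bob"]]) -
    (grid$p_AB + delta[["p_AB"]])
  dF <- -dc + ceiling(num_after / 2) - ceiling(num_before / 2)
  all(dF == -1L)
}

#' Catalogue of safe DCJ operation types
#'
#' Enumerates every abstract operation signature realizable by a single
#' DCJ on the component types (recombinations, fissions, fusions, cycle
#' moves and the extraction family) and keeps those whose effect on the
#' distance formula is exactly -1 in *every* surrounding context
#' (0..`max_copies` extra copies of each formula-relevant component type).
#' The cycle-extraction family counts once, as a generic signature; its
#' safety is verified on every concrete instantiation, including
#' whole-component circularization.
#'
#' @param max_copies Context enumeration bound per component type.
#' @return List of [op_signature()] objects (length 7).
#' @export
safe_catalogue <- function(max_copies = 4L) {
  univ <- enumerate_signatures()
  safe <- Filter(function(op) is_safe_signature(op, max_copies), univ$specific)
  # remove concrete members of the extraction family; they are represented
  # by the single generic entry
  extr_keys <- vapply(extraction_instances(), op_key, character(1))
  safe <- safe[setdiff(names(safe), extr_keys)]
  generic_ok <- all(vapply(extraction_instances(), is_safe_signature,
                           logical(1), max_copies = max_copies))
  out <- unname(safe)
  if (generic_ok) out <- c(list(univ$generic), out)
  out
}

# ---- Reduced bridges and recombination counts ----------------------------

pier_types <- c("Aoa", "Ab", "Ba", "Bob")
pier_lava <- c(Aoa = "a", Ab = "b", Ba = "a", Bob = "b")

#' Construct a reduced bridge
#'
#' A reduced bridge is the unsaturated remainder of a bridge after all
#' internal safe operations: its two piers, separated by one odd pontoon
#' when the bridge holds an odd number of odd pontoons. Consecutive
#' components must agree on the genome of the lava vertices joining them.
#'
#' @param piers Character vector of two pier types.
#' @param pontoon `"ab"` or `NULL`.
#' @return Object of class `reduced_bridge`.
#' @export
reduced_bridge <- function(piers, pontoon = NULL) {
  stopifnot(length(piers) == 2L, all(piers %in% pier_types))
  lv <- unname(pier_lava[piers])
  if (is.null(pontoon)) {
    if (lv[1] != lv[2])
      stop("pier pair without pontoon must share the lava genome")
  } else {
    stopifnot(identical(pontoon, "ab"))
    if (lv[1] == lv[2])
      stop("piers flanking an odd pontoon must have different lava genomes")
  }
  structure(list(piers = sort(piers, method = "radix"), pontoon = pontoon),
            class = "reduced_bridge")
}

#' @export
print.reduced_bridge <- function(x, ...) {
  comps <- if (is.null(x$pontoon)) x$piers else c(x$piers[1], x$pontoon, x$piers[2])
  cat("(", paste(paste0("P_", comps), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

bridge_key <- function(b) {
  paste(c(b$piers, if (!is.null(b$pontoon)) b$pontoon), collapse = "+")
}

bridge_components <- function(b) c(b$piers, if (!is.null(b$pontoon)) b$pontoon)

#' Enumerate the reduced bridge types
#'
#' Pier pairs sharing the lava genome, plus pier / odd-pontoon / pier
#' triples whose lava genomes are consistent along the chain: ten types.
#'
#' @return List of [reduced_bridge()] objects (length 10).
#' @export
reduced_bridge_types <- function() {
  out <- list()
  for (i in seq_along(pier_types)) for (j in i:length(pier_types)) {
    p1 <- pier_types[i]; p2 <- pier_types[j]
    if (pier_lava[[p1]] == pier_lava[[p2]]) {
      out[[length(out) + 1L]] <- reduced_bridge(c(p1, p2))
    } else {
      out[[length(out) + 1L]] <- reduced_bridge(c(p1, p2), "ab")
    }
  }
  out
}

#' Count path recombinations enabled by a safe operation
#'
#' For the three safe operations that can recombine two bridges —
#' (i) `Aoa,Ba -> AB,aoa`, (ii) `Ab,Bob -> AB,bob`,
#' (iii) `ab,ab -> aoa,bob` — counts the reduced-bridge pairings supplying
#' the operation's sources, after excluding the internally sortable bridge
#' types (those equal to a safe operation's source pair, which sort without
#' recombination). For (i) and (ii) this is (bridges containing the first
#' source) x (bridges containing the second); for (iii) it is same-type
#' selections plus unordered distinct-type pairs over the bridges holding
#' an odd pontoon.
#'
#' @param op An [op_signature()] equal to one of the three operations.
#' @return Integer count (9, 9 and 10 respectively).
#' @export
count_recombinations <- function(op) {
  bridges <- reduced_bridge_types()
  safe_pairs <- list(c("Aoa", "Ba"), c("Ab", "Bob"))
  internally_sortable <- vapply(bridges, function(b) {
    is.null(b$pontoon) &&
      any(vapply(safe_pairs, function(sp)
        identical(sort(sp, method = "radix"), b$piers), logical(1)))
  }, logical(1))
  bridges <- bridges[!internally_sortable]
  contains <- function(b, comp) comp %in% bridge_components(b)

  srt <- function(x) sort(x, method = "radix")
  src <- op$sources
  if (identical(src, srt(c("Aoa", "Ba"))) &&
      identical(op$resultants, srt(c("AB", "aoa")))) {
    return(sum(vapply(bridges, contains, logical(1), comp = "Aoa")) *
             sum(vapply(bridges, contains, logical(1), comp = "Ba")))
  }
  if (identical(src, srt(c("Ab", "Bob"))) &&
      identical(op$resultants, srt(c("AB", "bob")))) {
    return(sum(vapply(bridges, contains, logical(1), comp = "Ab")) *
             sum(vapply(bridges, contains, logical(1), comp = "Bob")))
  }
  if (identical(src, c("ab", "ab")) &&
      identical(op$resultants, srt(c("aoa", "bob")))) {
    k <- sum(vapply(bridges, contains, logical(1), comp = "ab"))
    return(as.integer(k + choose(k, 2)))
  }
  stop("not one of the three recombination-enabling safe operations")
}
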