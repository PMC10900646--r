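#' Multi-relational diagram (MRD) of a genome pair
#'
#' The MRD has one vertex per marker extremity of both genomes. Adjacency
#' edges are the adjacencies of both genomes; extremity edges connect
#' equivalent extremities (head-head, tail-tail) across genomes. The
#' augmented MRD used by the ILP additionally carries one *pseudo-cap*
#' vertex and pseudo-cap adjacency edge per telomere, and one *indel edge*
#' per marker joining its head and tail.
#'
#' @name mrd
#' @keywords internal
NULL

#' Build the MRD of a genome pair
#'
#' @param a,b `dcj_genome` objects with occurrence ids assigned.
#' @param fams Family assignment from [derive_families()]; derived when
#'   `NULL`.
#' @return Object of class `mrd`: vertex table, adjacency / extremity edge
#'   tables, and lookups from extremity code to vertex id (`ix`).
#' @export
build_mrd <- function(a, b, fams = NULL) {
  if (is.null(fams)) fams <- derive_families(a, b)
  occ_a <- genome_occs(a); occ_b <- genome_occs(b)
  ord_a <- sort(occ_a); ord_b <- sort(occ_b)
  # extremities in occurrence order, tail before head, genome A before B
  ext_codes <- c(rbind(ext_tail(ord_a), ext_head(ord_a)),
                 rbind(ext_tail(ord_b), ext_head(ord_b)))
  n_v <- length(ext_codes)
  ix_of_ext <- integer(max(ext_codes))
  ix_of_ext[ext_codes] <- seq_len(n_v)
  vertices <- data.frame(
    ix = seq_len(n_v),
    ext = ext_codes,
    occ = ext_occ(ext_codes),
    side = ifelse(ext_is_head(ext_codes), "h", "t"),
    genome = rep(c("A", "B"), c(2L * length(ord_a), 2L * length(ord_b))),
    cap = FALSE,
    stringsAsFactors = FALSE)

  aj_a <- genome_adjacencies(a); aj_b <- genome_adjacencies(b)
  adj_ext <- cbind(aj_a$adjacencies, aj_b$adjacencies)
  edges_adj <- data.frame(
    u = if (ncol(adj_ext)) ix_of_ext[adj_ext[1, ]] else integer(0),
    v = if (ncol(adj_ext)) ix_of_ext[adj_ext[2, ]] else integer(0),
    cap = logical(ncol(adj_ext)))

  eo_a <- integer(0); eo_b <- integer(0)
  for (f in names(fams)) {
    fa <- fams[[f]]$A; fb <- fams[[f]]$B
    if (length(fa) && length(fb)) {
      grid <- expand.grid(oa = fa, ob = fb)
      eo_a <- c(eo_a, grid$oa); eo_b <- c(eo_b, grid$ob)
    }
  }
  n_pair <- length(eo_a)
  edges_ext <- data.frame(
    u = c(if (n_pair) ix_of_ext[ext_tail(eo_a)], if (n_pair) ix_of_ext[ext_head(eo_a)]),
    v = c(if (n_pair) ix_of_ext[ext_tail(eo_b)], if (n_pair) ix_of_ext[ext_head(eo_b)]),
    occ_a = rep(eo_a, 2L), occ_b = rep(eo_b, 2L),
    sib = rep(seq_len(n_pair), 2L),
    side = rep(c("t", "h"), each = n_pair),
    stringsAsFactors = FALSE)

  structure(list(
    vertices = vertices, edges_adj = edges_adj, edges_ext = edges_ext,
    edges_indel = NULL, ix_of_ext = ix_of_ext,
    telomeres = list(A = aj_a$telomeres, B = aj_b$telomeres),
    occs = list(A = ord_a, B = ord_b),
    a = a, b = b, fams = fams, augmented = FALSE),
    class = "mrd")
}

#' Augment an MRD with pseudo-caps and indel edges
#'
#' Adds one pseudo-cap vertex plus pseudo-cap adjacency edge per telomere
#' and one indel edge per marker of either genome, then reassigns vertex
#' ids so that A pseudo-caps take the lowest `ix`, followed by B
#' pseudo-caps, then A extremities, then B extremities (required by the
#' ILP's component-labeling constraints).
#'
#' @param m An un-augmented [build_mrd()] result.
#' @return The augmented `mrd`.
#' @export
augment_mrd <- function(m) {
  if (isTRUE(m$augmented)) stop("MRD is already augmented")
  tel_a <- m$telomeres$A; tel_b <- m$telomeres$B
  n_cap <- length(tel_a) + length(tel_b)
  n_ext_v <- nrow(m$vertices)

  # new ix: caps first (A then B, in telomere order), then old extremity order
  cap_ix <- seq_len(n_cap)
  old_to_new <- n_cap + seq_len(n_ext_v)
  vertices <- data.frame(
    ix = c(cap_ix, old_to_new),
    ext = c(rep(NA_integer_, n_cap), m$vertices$ext),
    occ = c(rep(NA_integer_, n_cap), m$vertices$occ),
    side = c(rep("cap", n_cap), m$vertices$side),
    genome = c(rep(c("A", "B"), c(length(tel_a), length(tel_b))), m$vertices$genome),
    cap = c(rep(TRUE, n_cap), rep(FALSE, n_ext_v)),
    stringsAsFactors = FALSE)
  ix_of_ext <- integer(length(m$ix_of_ext))
  ix_of_ext[m$vertices$ext] <- old_to_new

  cap_edges <- data.frame(
    u = cap_ix,
    v = ix_of_ext[c(tel_a, tel_b)],
    cap = rep(TRUE, n_cap))
  edges_adj <- rbind(
    data.frame(u = old_to_new[m$edges_adj$u], v = old_to_new[m$edges_adj$v],
               cap = rep(FALSE, nrow(m$edges_adj))),
    cap_edges)

  edges_ext <- m$edges_ext
  edges_ext$u <- old_to_new[edges_ext$u]
  edges_ext$v <- old_to_new[edges_ext$v]

  occ_all <- c(m$occs$A, m$occs$B)
  edges_indel <- data.frame(
    u = ix_of_ext[ext_tail(occ_all)],
    v = ix_of_ext[ext_head(occ_all)],
    occ = occ_all,
    genome = rep(c("A", "B"), c(length(m$occs$A), length(m$occs$B))),
    stringsAsFactors = FALSE)

  m$vertices <- vertices
  m$edges_adj <- edges_adj
  m$edges_ext <- edges_ext
  m$edges_indel <- edges_indel
  m$ix_of_ext <- ix_of_ext
  m$augmented <- TRUE
  m
}

#' Derive a decomposition from a resolved matching
#'
#' Selects the extremity-edge sibling pairs of matched occurrence pairs and
#' the indel edges of all unmatched markers, yielding a consistent
#' decomposition in which every extremity is covered exactly once.
#'
#' @param m An `mrd` (augmented or not).
#' @param match A [resolved_matching()].
#' @return Object of class `decomposition`: logical vector `ext_sel` over
#'   the rows of `m$edges_ext` and integer vector `lava_occs` of unmatched
#'   occurrence ids.
#' @export
decomposition_from_matching <- function(m, match) {
  fam_of_a <- fam_lookup(m$fams, "A"); fam_of_b <- fam_lookup(m$fams, "B")
  fa <- fam_of_a[as.character(match$occ_a)]
  fb <- fam_of_b[as.character(match$occ_b)]
  if (any(is.na(fa)) || any(is.na(fb)) || any(fa != fb))
    stop("matching pairs occurrences of different families")
  key <- paste(m$edges_ext$occ_a, m$edges_ext$occ_b)
  sel_key <- paste(match$occ_a, match$occ_b)
  ext_sel <- key %in% sel_key
  matched <- c(match$occ_a, match$occ_b)
  lava_occs <- setdiff(c(m$occs$A, m$occs$B), matched)
  structure(list(ext_sel = ext_sel, lava_occs = lava_occs, match = match),
            class = "decomposition")
}

#' An empty (all counts zero) component report
#'
#' Fields: cycle count `c`, the ten path-type counts (`p_AoA`, `p_AB`,
#' `p_BoB`, `p_Aoa`, `p_Ab`, `p_Ba`, `p_Bob`, `p_aoa`, `p_ab`, `p_bob`;
#' `o` marks even, the bare two-letter forms odd paths), the matched-marker
#' count `n` and the circular-singleton count `s`.
#'
#' @param ... Named counts to set, e.g. `component_report(n = 1, p_AB = 2)`.
#' @return Object of class `component_report` (named integer vector).
#' @export
component_report <- function(...) {
  r <- c(c = 0L, p_AoA = 0L, p_AB = 0L, p_BoB = 0L,
         p_Aoa = 0L, p_Ab = 0L, p_Ba = 0L, p_Bob = 0L,
         p_aoa = 0L, p_ab = 0L, p_bob = 0L, n = 0L, s = 0L)
  upd <- list(...)
  if (length(upd)) {
    if (is.null(names(upd)) || any(!nzchar(names(upd))))
      stop("component_report() takes named counts")
    bad <- setdiff(names(upd), names(r))
    if (length(bad)) stop("unknown report fields: ", paste(bad, collapse = ", "))
    r[names(upd)] <- as.integer(unlist(upd))
  }
  structure(r, class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  nz <- x[x != 0L | names(x) %in% c("n", "c", "s")]
  cat("component report:",
      paste(names(nz), unclass(nz), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.component_report <- function(x, ...) {
  as.data.frame(as.list(unclass(x)), ...)
}

path_type_names <- c("AoA", "AB", "BoB", "Aoa", "Ab", "Ba", "Bob", "aoa", "ab", "bob")

endpoint_pair_to_type <- function(e1, e2) {
  key <- paste(sort(c(e1, e2)), collapse = "")
  # sort() puts uppercase before lowercase in the C locale; make explicit
  ord <- c("A", "B", "a", "b")
  pr <- c(e1, e2)[order(match(c(e1, e2), ord))]
  switch(paste(pr, collapse = ""),
         AA = "AoA", AB = "AB", BB = "BoB",
         Aa = "Aoa", Ab = "Ab", Ba = "Ba", Bb = "Bob",
         aa = "aoa", ab = "ab", bb = "bob",
         stop("unclassifiable endpoint pair: ", key))
}

# Core classifier working directly on a pair plus selected extremity edges.
# Operates on the simple (un-augmented, indel-free) view: vertices are
# extremities, edges are both genomes' adjacencies plus the matched
# extremity edges. Single extremities that are both telomere and lava form
# one-vertex paths with a telomere end and a lava end (even piers).
classify_pair <- function(a, b, matching) {
  aj_a <- genome_adjacencies(a); aj_b <- genome_adjacencies(b)
  occ_a <- genome_occs(a); occ_b <- genome_occs(b)
  exts <- c(ext_tail(occ_a), ext_head(occ_a), ext_tail(occ_b), ext_head(occ_b))
  genome_of_ext <- rep(c("A", "B"), c(2L * length(occ_a), 2L * length(occ_b)))
  names(genome_of_ext) <- as.character(exts)

  adj_u <- c(aj_a$adjacencies[1, ], aj_b$adjacencies[1, ])
  adj_v <- c(aj_a$adjacencies[2, ], aj_b$adjacencies[2, ])
  sel_u <- c(ext_tail(matching$occ_a), ext_head(matching$occ_a))
  sel_v <- c(ext_tail(matching$occ_b), ext_head(matching$occ_b))

  vid <- stats::setNames(seq_along(exts), as.character(exts))
  eu <- vid[as.character(c(adj_u, sel_u))]
  ev <- vid[as.character(c(adj_v, sel_v))]
  is_ext_edge <- c(rep(FALSE, length(adj_u)), rep(TRUE, length(sel_u)))

  deg <- tabulate(c(eu, ev), nbins = length(exts))
  if (any(deg > 2L)) stop("decomposition has a vertex of degree > 2")
  has_adj <- logical(length(exts)); has_sel <- logical(length(exts))
  has_adj[vid[as.character(c(adj_u, adj_v))]] <- TRUE
  has_sel[vid[as.character(c(sel_u, sel_v))]] <- TRUE

  if (length(eu)) {
    gr <- igraph::graph_from_edgelist(cbind(eu, ev), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, length(exts) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
  } else {
    comp <- seq_along(exts)
  }
  edge_comp <- comp[eu]

  counts <- unclass(component_report(n = nrow(matching)))
  n_comp <- max(comp)
  nxe_of_comp <- integer(n_comp)
  if (length(edge_comp)) {
    agg <- tapply(is_ext_edge, edge_comp, sum)
    nxe_of_comp[as.integer(names(agg))] <- as.integer(agg)
  }
  edge_count <- tabulate(edge_comp, nbins = n_comp)

  for (ci in seq_len(n_comp)) {
    members <- which(comp == ci)
    if (edge_count[ci] == length(members) && all(deg[members] == 2L)) {
      if (nxe_of_comp[ci] %% 2L != 0L) stop("cycle with odd extremity-edge count")
      counts["c"] <- counts["c"] + 1L
      next
    }
    ends <- members[deg[members] < 2L]
    ep <- character(0)
    for (v in ends) {
      if (deg[v] == 0L) {
        # isolated extremity: telomere that is also lava
        ep <- c(ep, genome_of_ext[[v]], tolower(genome_of_ext[[v]]))
      } else if (!has_adj[v]) {
        ep <- c(ep, genome_of_ext[[v]])            # telomere endpoint
      } else if (!has_sel[v]) {
        ep <- c(ep, tolower(genome_of_ext[[v]]))   # lava endpoint
      } else stop("endpoint with both edge kinds present")
    }
    if (length(ep) != 2L) stop("path without exactly two endpoints")
    type <- endpoint_pair_to_type(ep[1], ep[2])
    odd_expected <- type %in% c("AB", "Ab", "Ba", "ab")
    if ((nxe_of_comp[ci] %% 2L == 1L) != odd_expected)
      stop("path parity inconsistent with endpoint classes")
    counts[paste0("p_", type)] <- counts[paste0("p_", type)] + 1L
  }
  structure(counts, class = "component_report")
}

#' Classify the components of a decomposition
#'
#' Partitions the simple MRD induced by a decomposition into cycles and the
#' ten path types distinguished by endpoint classes: `A`/`B` for telomeres
#' and `a`/`b` for lava vertices of genome A/B, with parity counted in
#' extremity edges. A vertex that is both telomere and lava contributes one
#' telomere endpoint and one lava endpoint (an even pier).
#'
#' @param m An `mrd`.
#' @param d A [decomposition_from_matching()] result.
#' @return A [component_report()] with `n` set; `s` is left 0 (circular
#'   singletons are handled by [resolved_distance()]).
#' @export
classify_components <- function(m, d) {
  classify_pair(m$a, m$b, d$match)
}

#' Dump an MRD as an edge-list table
#'
#' Debug view: one row per edge with vertex ids and edge type
#' (`adjacency`, `pseudo-cap`, `extremity`, `indel`).
#'
#' @param m An `mrd`.
#' @param path Optional TSV output path.
#' @return Data frame (invisibly when written to a file).
#' @export
mrd_edge_table <- function(m, path = NULL) {
  tab <- rbind(
    data.frame(u = m$edges_adj$u, v = m$edges_adj$v,
               type = ifelse(m$edges_adj$cap, "pseudo-cap", "adjacency")),
    data.frame(u = m$edges_ext$u, v = m$edges_ext$v, type = "extremity"),
    if (!is.null(m$edges_indel))
      data.frame(u = m$edges_indel$u, v = m$edges_indel$v, type = "indel"))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Count circular singletons of a genome under a matching
#'
#' A circular singleton is a circular chromosome all of whose occurrences
#' are unmatched; each one costs exactly one indel and is handled before
#' the distance formula is applied.
#'
#' @param g A `dcj_genome`.
#' @param match A [resolved_matching()].
#' @return Integer count.
#' @export
detect_circular_singletons <- function(g, match) {
  matched <- c(match$occ_a, match$occ_b)
  sum(vapply(g$chromosomes, function(ch)
    ch$circular && !any(ch$occ %in% matched), logical(1)))
}

drop_circular_singletons <- function(g, match) {
  matched <- c(match$occ_a, match$occ_b)
  keep <- vapply(g$chromosomes, function(ch)
    !(ch$circular && !any(ch$occ %in% matched)), logical(1))
  g$chromosomes <- g$chromosomes[keep]
  g
}
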