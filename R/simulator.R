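#' Genome-pair evolution simulator
#'
#' Evolves two genomes from a common root by rate-weighted DCJ,
#' insertion, deletion and duplication operations, with Zipf-distributed
#' indel and duplication lengths, and records the ground-truth matching
#' between markers descending from the same root marker.
#'
#' @name simulator
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Defaults follow the reference simulation protocol: operation rates are
#' relative to a DCJ rate of 1 (so a type is drawn with probability
#' `rate / (1 + sum(rates))`), Zipf shape 4 for indel lengths and 6 for
#' duplication lengths.
#'
#' @param n_markers Root genome size in markers.
#' @param n_chromosomes Number of linear chromosomes in the root.
#' @param n_ops Total operations, split evenly between the two lineages.
#' @param rates Named numeric: `insertion`, `deletion`, `duplication`
#'   rates relative to DCJ rate 1.
#' @param zipf_indel,zipf_dup Zipf shape parameters (> 1) for indel and
#'   duplication segment lengths.
#' @param seed Integer seed for the single PRNG stream.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_markers = 20000L, n_chromosomes = 1L,
                              n_ops = 10000L,
                              rates = c(insertion = 0.1, deletion = 0.2,
                                        duplication = 0.4),
                              zipf_indel = 4, zipf_dup = 6, seed = 1L) {
  rates <- rates[c("insertion", "deletion", "duplication")]
  rates[is.na(rates)] <- 0
  names(rates) <- c("insertion", "deletion", "duplication")
  stopifnot(all(rates >= 0), zipf_indel > 1, zipf_dup > 1,
            n_markers >= n_chromosomes, n_chromosomes >= 1)
  structure(list(n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_ops = as.integer(n_ops), rates = rates,
                 zipf_indel = zipf_indel, zipf_dup = zipf_dup,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Root genome for a simulation
#'
#' Families `1..n_markers`, all forward, spread over `n_chromosomes`
#' linear chromosomes as evenly as possible. Construction is
#' deterministic; `seed` is accepted for interface symmetry only.
#'
#' @param n_markers,n_chromosomes Size and chromosome count.
#' @param seed Ignored (the root is deterministic).
#' @return A `dcj_genome` named `"root"`.
#' @export
make_root <- function(n_markers, n_chromosomes = 1L, seed = NULL) {
  if (n_chromosomes > n_markers) stop("more chromosomes than markers")
  sizes <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  chs <- lapply(seq_len(n_chromosomes), function(i)
    chromosome(as.character(off[i] + seq_len(sizes[i])), 1L, circular = FALSE))
  genome("root", chs)
}

#' Expected operation counts by type
#'
#' Each operation's type is drawn with probability `rate / (1 + sum(rates))`
#' (DCJ rate 1), so the expectation for type `t` over `n_ops` draws is
#' `n_ops * rate_t / (1 + sum(rates))`.
#'
#' @param n_ops Total number of operations.
#' @param rates Named rates relative to DCJ = 1 (missing types count 0).
#' @return Named numeric vector with components `dcj`, `insertion`,
#'   `deletion`, `duplication`.
#' @examples
#' floor(expected_op_counts(10000, c(insertion = .1, deletion = .2,
#'                                   duplication = .4))[["dcj"]])  # 5882
#' @export
expected_op_counts <- function(n_ops, rates = numeric(0)) {
  full <- c(insertion = 0, deletion = 0, duplication = 0)
  full[names(rates)] <- rates
  tot <- 1 + sum(full)
  c(dcj = n_ops / tot, n_ops * full / tot)
}

# cached truncated-support Zipf tables per shape
.zipf_cache <- new.env(parent = emptyenv())

#' Sample Zipf-distributed positive integers
#'
#' `P(k)` proportional to `k^-shape`, `k >= 1`, sampled by inversion on a
#' truncated support of `1..10^6` (the truncated tail mass is negligible
#' for the shapes used here).
#'
#' @param n Number of draws.
#' @param shape Shape parameter (> 1).
#' @return Integer vector of length `n`.
#' @export
sample_zipf <- function(n, shape) {
  stopifnot(shape > 1)
  key <- format(shape, digits = 12)
  cdf <- .zipf_cache[[key]]
  if (is.null(cdf)) {
    support <- 1e6
    w <- seq_len(support)^(-shape)
    cdf <- cumsum(w) / sum(w)
    .zipf_cache[[key]] <- cdf
  }
  findInterval(stats::runif(n), cdf) + 1L
}

# operation types drawn independently with P(type) = rate / (1 + sum(rates)),
# DCJ rate 1; factored out so the sampling distribution is testable
draw_op_types <- function(n, rates) {
  probs <- c(dcj = 1, rates) / (1 + sum(rates))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# ---- internal lineage state ----------------------------------------------

lineage_state <- function(root) {
  st <- new.env(parent = emptyenv())
  st$chroms <- list(); st$circ <- logical(0)
  st$fam <- integer(0); st$origin <- integer(0)
  nxt <- 1L
  for (ch in root$chromosomes) {
    k <- length(ch$fams)
    ids <- seq.int(nxt, length.out = k)
    nxt <- nxt + k
    st$chroms[[length(st$chroms) + 1L]] <- ids * ch$signs
    st$circ <- c(st$circ, ch$circular)
    st$fam[ids] <- as.integer(ch$fams)
    st$origin[ids] <- as.integer(ch$fams)
  }
  st$next_id <- nxt
  st
}

state_marker_count <- function(st) sum(lengths(st$chroms))

# extremity codes on instance ids: tail = 2id-1, head = 2id
state_adjacencies <- function(st) {
  adj_u <- integer(0); adj_v <- integer(0); tel <- integer(0)
  for (ci in seq_along(st$chroms)) {
    v <- st$chroms[[ci]]
    id <- abs(v); k <- length(v)
    left <- ifelse(v > 0L, 2L * id - 1L, 2L * id)
    right <- ifelse(v > 0L, 2L * id, 2L * id - 1L)
    if (k > 1L) { adj_u <- c(adj_u, right[-k]); adj_v <- c(adj_v, left[-1L]) }
    if (st$circ[ci]) { adj_u <- c(adj_u, right[k]); adj_v <- c(adj_v, left[1L]) }
    else tel <- c(tel, left[1L], right[k])
  }
  list(u = adj_u, v = adj_v, tel = tel)
}

state_rebuild_from_adj <- function(st, adjvec, ids) {
  chroms <- list(); circ <- logical(0)
  seen <- logical(length(adjvec))
  exts <- sort(c(2L * ids - 1L, 2L * ids))
  for (e in exts) {
    if (seen[e] || adjvec[e] != 0L) next
    seq_ <- integer(0); cur <- e
    repeat {
      id <- (cur + 1L) %/% 2L
      tail_ <- cur %% 2L == 1L
      seq_ <- c(seq_, if (tail_) id else -id)
      seen[cur] <- TRUE
      other <- if (tail_) cur + 1L else cur - 1L
      seen[other] <- TRUE
      nxt <- adjvec[other]
      if (nxt == 0L) break
      cur <- nxt
    }
    chroms[[length(chroms) + 1L]] <- seq_
    circ <- c(circ, FALSE)
  }
  for (e in exts) {
    if (seen[e]) next
    seq_ <- integer(0); cur <- e
    while (!seen[cur]) {
      id <- (cur + 1L) %/% 2L
      tail_ <- cur %% 2L == 1L
      seq_ <- c(seq_, if (tail_) id else -id)
      seen[cur] <- TRUE
      other <- if (tail_) cur + 1L else cur - 1L
      seen[other] <- TRUE
      cur <- adjvec[other]
    }
    chroms[[length(chroms) + 1L]] <- seq_
    circ <- c(circ, TRUE)
  }
  st$chroms <- chroms
  st$circ <- circ
  invisible(st)
}

# one DCJ: two cut sites drawn uniformly (with replacement) from
# adjacencies and telomeres; a reconnection variant drawn uniformly among
# the cases valid for the drawn sites; drawing one telomere twice is
# rejected and redrawn
apply_dcj <- function(st) {
  aj <- state_adjacencies(st)
  K <- length(aj$u); Tn <- length(aj$tel)
  if (K + Tn == 0L) return(invisible(st))
  ids <- unlist(lapply(st$chroms, abs), use.names = FALSE)
  adjvec <- integer(2L * max(ids))
  adjvec[aj$u] <- aj$v; adjvec[aj$v] <- aj$u
  repeat {
    s1 <- sample.int(K + Tn, 1L); s2 <- sample.int(K + Tn, 1L)
    if (!(s1 == s2 && s1 > K)) break
  }
  if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
  cut <- function(u, v) { adjvec[u] <<- 0L; adjvec[v] <<- 0L }
  join <- function(u, v) { adjvec[u] <<- v; adjvec[v] <<- u }
  if (s1 <= K && s2 <= K) {
    a <- aj$u[s1]; b <- aj$v[s1]
    if (s1 == s2) {
      cut(a, b)                                     # ab -> a, b
    } else {
      c_ <- aj$u[s2]; d <- aj$v[s2]
      cut(a, b); cut(c_, d)
      if (stats::runif(1) < 0.5) { join(a, c_); join(b, d) }
      else { join(a, d); join(b, c_) }
    }
  } else if (s1 <= K) {
    a <- aj$u[s1]; b <- aj$v[s1]; s <- aj$tel[s2 - K]
    cut(a, b)
    if (stats::runif(1) < 0.5) join(a, s) else join(b, s)
  } else {
    join(aj$tel[s1 - K], aj$tel[s2 - K])            # s, t -> st
  }
  state_rebuild_from_adj(st, adjvec, ids)
}

# insertion sites: one per adjacency, one per telomere, plus "new circular
# chromosome"; returns function applying the splice
insert_segment <- function(st, seg) {
  sites <- list()
  for (ci in seq_along(st$chroms)) {
    k <- length(st$chroms[[ci]])
    gaps <- if (st$circ[ci]) seq_len(k) else 0:k
    for (g in gaps) sites[[length(sites) + 1L]] <- c(ci, g)
  }
  pick <- sample.int(length(sites) + 1L, 1L)
  if (pick > length(sites)) {
    st$chroms[[length(st$chroms) + 1L]] <- seg
    st$circ <- c(st$circ, TRUE)
  } else {
    ci <- sites[[pick]][1]; g <- sites[[pick]][2]
    v <- st$chroms[[ci]]
    st$chroms[[ci]] <- append(v, seg, after = g)
  }
  invisible(st)
}

apply_insertion <- function(st, shared, len) {
  ids <- seq.int(st$next_id, length.out = len)
  st$next_id <- st$next_id + len
  fams <- seq.int(shared$next_fam, length.out = len)
  shared$next_fam <- shared$next_fam + len
  st$fam[ids] <- fams
  st$origin[ids] <- 0L
  insert_segment(st, ids)
}

# pick a uniform start marker; the segment extends rightwards, capped at
# the chromosome (wrapping on circulars)
pick_segment <- function(st, len) {
  sizes <- lengths(st$chroms)
  p <- sample.int(sum(sizes), 1L)
  cs <- cumsum(sizes)
  ci <- which(p <= cs)[1]
  pos <- p - c(0L, cs)[ci]
  k <- sizes[ci]
  len_eff <- if (st$circ[ci]) min(len, k) else min(len, k - pos + 1L)
  idx <- ((pos - 1L + seq_len(len_eff) - 1L) %% k) + 1L
  list(ci = ci, idx = idx)
}

apply_deletion <- function(st, len) {
  total <- state_marker_count(st)
  if (total <= 1L) return(invisible(st))
  # a deletion must never empty the genome: cap the length when only one
  # chromosome remains (the resampled-length equivalent)
  if (length(st$chroms) == 1L) len <- min(len, total - 1L)
  sg <- pick_segment(st, len)
  v <- st$chroms[[sg$ci]]
  if (length(sg$idx) == length(v)) {
    st$chroms[[sg$ci]] <- NULL
    st$circ <- st$circ[-sg$ci]
  } else if (st$circ[sg$ci]) {
    keep <- setdiff(seq_along(v), sg$idx)
    # keep order starting after the removed run so the repair adjacency
    # closes the circle correctly
    start <- max(sg$idx) %% length(v) + 1L
    ord <- ((start - 1L + seq_len(length(v))) - 1L) %% length(v) + 1L
    st$chroms[[sg$ci]] <- v[ord[ord %in% keep]]
  } else {
    st$chroms[[sg$ci]] <- v[-sg$idx]
  }
  invisible(st)
}

apply_duplication <- function(st, len) {
  sg <- pick_segment(st, len)
  v <- st$chroms[[sg$ci]][sg$idx]
  src <- abs(v)
  ids <- seq.int(st$next_id, length.out = length(v))
  st$next_id <- st$next_id + length(v)
  st$fam[ids] <- st$fam[src]
  st$origin[ids] <- st$origin[src]
  insert_segment(st, ids * sign(v))
}

state_to_genome <- function(st, name) {
  chs <- lapply(seq_along(st$chroms), function(ci) {
    v <- st$chroms[[ci]]
    chromosome(as.character(st$fam[abs(v)]), sign(v), circular = st$circ[ci])
  })
  g <- genome(name, chs)
  attr(g, "origin") <- lapply(st$chroms, function(v) st$origin[abs(v)])
  g
}

#' Evolve a genome pair from a common root
#'
#' Applies `n_ops` operations, split evenly between the two lineages, each
#' operation's type drawn with probability `rate / (1 + sum(rates))` (DCJ
#' rate 1). DCJs draw two cut sites uniformly from adjacencies and
#' telomeres and a valid reconnection uniformly; insertions add fresh
#' families at a uniformly chosen site (adjacency, telomere or new
#' circular chromosome); deletions remove a uniformly chosen segment of
#' Zipf length capped at its chromosome (never emptying the genome);
#' duplications copy a Zipf-length segment, retaining families, to a
#' uniformly chosen insertion site. A single seeded PRNG stream makes the
#' pair reproducible.
#'
#' @param root A root genome, e.g. [make_root()].
#' @param cfg A [simulation_config()].
#' @return List of class `evolved_pair`: genomes `a` and `b` (with
#'   occurrence ids assigned), `matching` (ground-truth
#'   [resolved_matching()] pairing descendants of the same root marker),
#'   and `op_counts` (applied operations per type and lineage).
#' @param validate When `TRUE`, every intermediate genome is checked
#'   against the genome invariants after every operation (slow; meant for
#'   property tests).
#' @export
evolve_pair <- function(root, cfg, validate = FALSE) {
  set.seed(cfg$seed)
  shared <- new.env(parent = emptyenv())
  shared$next_fam <- cfg$n_markers + 1L
  n_a <- ceiling(cfg$n_ops / 2); n_b <- cfg$n_ops - n_a
  counts <- matrix(0L, 2, 4, dimnames = list(c("a", "b"),
                                             c("dcj", names(cfg$rates))))
  run_lineage <- function(n_ops, row, name) {
    st <- lineage_state(root)
    types <- draw_op_types(n_ops, cfg$rates)
    for (ty in types) {
      counts[row, ty] <<- counts[row, ty] + 1L
      switch(ty,
             dcj = apply_dcj(st),
             insertion = apply_insertion(st, shared, sample_zipf(1, cfg$zipf_indel)),
             deletion = apply_deletion(st, sample_zipf(1, cfg$zipf_indel)),
             duplication = apply_duplication(st, sample_zipf(1, cfg$zipf_dup)))
      if (validate)
        validate_genome(assign_occurrences(list(state_to_genome(st, name)))[[1]])
    }
    st
  }
  st_a <- run_lineage(n_a, 1L, "A")
  st_b <- run_lineage(n_b, 2L, "B")
  ga <- state_to_genome(st_a, "A")
  gb <- state_to_genome(st_b, "B")
  pair <- assign_occurrences(list(ga, gb))
  matching <- truth_matching(pair[[1]], pair[[2]])
  structure(list(a = pair[[1]], b = pair[[2]], matching = matching,
                 op_counts = counts),
            class = "evolved_pair")
}

# pair surviving descendants of each root marker (descent is tracked by the
# origin attribute); injective, at most min(count) pairs per origin
truth_matching <- function(a, b) {
  tab <- function(g) {
    occ <- genome_occs(g)
    ori <- unlist(attr(g, "origin"), use.names = FALSE)
    data.frame(occ = occ, origin = ori)[ori > 0L, , drop = FALSE]
  }
  ta <- tab(a); tb <- tab(b)
  occ_a <- integer(0); occ_b <- integer(0)
  for (r in intersect(unique(ta$origin), unique(tb$origin))) {
    xa <- sort(ta$occ[ta$origin == r]); xb <- sort(tb$occ[tb$origin == r])
    k <- min(length(xa), length(xb))
    occ_a <- c(occ_a, xa[seq_len(k)]); occ_b <- c(occ_b, xb[seq_len(k)])
  }
  fams <- derive_families(a, b)
  resolved_matching(occ_a, occ_b, fams)
}
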