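# Fixture builders shared across the test files. Everything is generated
# in code; no stored data.

pair_from_text <- function(text) {
  gs <- parse_unimog(text)
  stopifnot(length(gs) == 2L)
  gs
}

# random genome over a small family pool, mixed topologies
rand_genome <- function(name, max_markers = 3L, fams = c("1", "2"),
                        p_circular = 0.3, min_markers = 1L) {
  k <- sample(min_markers:max_markers, 1L)
  f <- sample(fams, k, replace = TRUE)
  s <- sample(c(-1L, 1L), k, replace = TRUE)
  nchr <- sample(seq_len(k), 1L)
  brk <- sort(sample(seq_len(k), nchr - 1L))
  idx <- split(seq_len(k), findInterval(seq_len(k), c(0L, brk) + 1L))
  chs <- lapply(idx, function(ii)
    chromosome(f[ii], s[ii], circular = stats::runif(1) < p_circular))
  genome(name, unname(chs))
}

rand_pair <- function(max_markers = 3L, fams = c("1", "2"), p_circular = 0.3) {
  gs <- assign_occurrences(list(
    rand_genome("A", max_markers, fams, p_circular),
    rand_genome("B", max_markers, fams, p_circular)))
  gs
}

# random genome pair with a resolved homology (every family at most once
# per genome): sample distinct families per genome
rand_resolved_pair <- function(max_markers = 4L, n_fams = 5L,
                               p_circular = 0.25) {
  pool <- as.character(seq_len(n_fams))
  one <- function(name) {
    k <- sample(seq_len(max_markers), 1L)
    f <- sample(pool, k)
    s <- sample(c(-1L, 1L), k, replace = TRUE)
    nchr <- sample(seq_len(k), 1L)
    brk <- sort(sample(seq_len(k), nchr - 1L))
    idx <- split(seq_len(k), findInterval(seq_len(k), c(0L, brk) + 1L))
    genome(name, unname(lapply(idx, function(ii)
      chromosome(f[ii], s[ii], circular = stats::runif(1) < p_circular))))
  }
  assign_occurrences(list(one("A"), one("B")))
}

compositions_of <- function(k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(remaining, acc) {
    if (remaining == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (first in seq_len(remaining)) recurse(remaining - first, c(acc, first))
  }
  recurse(k, integer(0))
  out
}

# every canonical genome with 1..max_markers markers over the family pool:
# all family/sign sequences, all contiguous chromosome splits, all
# linear/circular flags, deduplicated by canonical key
all_canonical_genomes <- function(max_markers = 3L, fams = c("1", "2")) {
  res <- list()
  seen <- new.env(parent = emptyenv())
  for (k in seq_len(max_markers)) {
    fam_grid <- as.matrix(do.call(expand.grid,
                                  c(rep(list(fams), k),
                                    stringsAsFactors = FALSE)))
    sign_grid <- as.matrix(do.call(expand.grid, rep(list(c(1L, -1L)), k)))
    comps <- compositions_of(k)
    for (fi in seq_len(nrow(fam_grid))) {
      f <- fam_grid[fi, ]
      for (si in seq_len(nrow(sign_grid))) {
        s <- sign_grid[si, ]
        for (cp in comps) {
          ends <- cumsum(cp)
          starts <- c(1L, ends[-length(ends)] + 1L)
          nch <- length(cp)
          for (mask in 0:(2^nch - 1L)) {
            circ <- bitwAnd(mask, 2^(seq_len(nch) - 1L)) > 0
            chs <- lapply(seq_len(nch), function(i)
              chromosome(f[starts[i]:ends[i]], s[starts[i]:ends[i]], circ[i]))
            g <- genome("g", chs)
            key <- canonical_genome_key(g)
            if (is.null(seen[[key]])) {
              seen[[key]] <- TRUE
              res[[length(res) + 1L]] <- g
            }
          }
        }
      }
    }
  }
  res
}

# rebuild a pair with shared occurrence numbering
as_pair <- function(ga, gb) {
  ga$name <- "A"; gb$name <- "B"
  assign_occurrences(list(ga, gb))
}

# cached bidirectional-BFS distance keyed on the relabeled canonical pair
bfs_cache <- new.env(parent = emptyenv())

cached_bfs_distance <- function(a, b, matching, ...) {
  lab <- dcjindel:::relabel_pair(a, b, matching)
  key <- paste(canonical_genome_key(lab$a), canonical_genome_key(lab$b),
               sep = " || ")
  hit <- bfs_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- bfs_restricted_distance(a, b, matching, ...)
  bfs_cache[[key]] <- d
  d
}

swap_pair_matching <- function(matching) {
  resolved_matching(matching$occ_b, matching$occ_a)
}

# A<->B swap of a component report (used by the symmetry invariant)
swap_report <- function(r) {
  r <- unclass(r)
  sw <- c(c = "c", p_AoA = "p_BoB", p_AB = "p_AB", p_BoB = "p_AoA",
          p_Aoa = "p_Bob", p_Ab = "p_Ba", p_Ba = "p_Ab", p_Bob = "p_Aoa",
          p_aoa = "p_bob", p_ab = "p_ab", p_bob = "p_aoa",
          n = "n", s = "s")
  out <- r
  out[sw[names(r)]] <- r
  structure(out, class = "component_report")
}
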