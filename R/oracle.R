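#' Brute-force reference computations
#'
#' Independent oracles used to verify the closed-form distance and the ILP:
#' a breadth-first search over restricted DCJ-indel scenarios for tiny
#' genome pairs, and exhaustive enumeration of maximal matchings.
#'
#' @name oracle
#' @keywords internal
NULL

# Relabel a pair into integer marker ids for the search core: matched pairs
# share an id, unmatched occurrences get fresh unique ids.
relabel_for_search <- function(a, b, matching) {
  n_pairs <- nrow(matching)
  id_of_a <- stats::setNames(seq_len(n_pairs), as.character(matching$occ_a))
  id_of_b <- stats::setNames(seq_len(n_pairs), as.character(matching$occ_b))
  nxt <- n_pairs
  to_int <- function(g, id_map) {
    seqs <- list(); circ <- logical(0); sing <- integer(0)
    for (ch in g$chromosomes) {
      ids <- id_map[as.character(ch$occ)]
      fresh <- is.na(ids)
      if (any(fresh)) {
        ids[fresh] <- nxt + seq_len(sum(fresh))
        nxt <<- nxt + sum(fresh)
        sing <- c(sing, as.integer(ids[fresh]))
      }
      seqs[[length(seqs) + 1L]] <- as.integer(ids) * ch$signs
      circ <- c(circ, ch$circular)
    }
    list(seqs = seqs, circ = circ, sing = sing)
  }
  ra <- to_int(a, id_of_a)
  rb <- to_int(b, id_of_b)
  list(a = ra, b = rb, singular = c(ra$sing, rb$sing))
}

#' Restricted DCJ-indel distance by breadth-first search
#'
#' Finds the length of a shortest sequence of DCJ operations and restricted
#' indels (indels touch only singular, i.e. unmatched, markers)
#' transforming `a` into a genome equal to `b` under the given matching.
#' The search runs bidirectionally: an optimal scenario can be reordered so
#' that every deletion precedes every insertion, so scenarios decompose
#' into a deletion-plus-DCJ prefix from `a` and (read backwards) a
#' deletion-plus-DCJ prefix from `b`, meeting at a genome over the matched
#' markers. Intended for tiny instances; the state space is canonicalized
#' and capped.
#'
#' @param a,b `dcj_genome` objects with occurrence ids.
#' @param match A [resolved_matching()].
#' @param max_states Cap on visited canonical states; past it the search
#'   reports an undecided result instead of a possibly wrong number.
#' @param max_depth Cap on per-direction search depth.
#' @return Integer distance, or `NA` with attribute `undecided = TRUE` when
#'   a cap was hit.
#' @export
bfs_restricted_distance <- function(a, b, match, max_states = 500000L,
                                    max_depth = 16L) {
  rl <- relabel_for_search(a, b, match)
  d <- .bfs_core(rl$a$seqs, rl$a$circ, rl$b$seqs, rl$b$circ,
                 as.integer(rl$a$sing), as.integer(rl$b$sing),
                 as.integer(max_states), as.integer(max_depth))
  if (d < 0L) {
    out <- NA_integer_
    attr(out, "undecided") <- TRUE
    return(out)
  }
  d
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Enumerate all maximal matchings of a family assignment
#'
#' A maximal matching pairs exactly `min(|f_A|, |f_B|)` occurrences per
#' family; the number of choices per family is `choose(max, min) * min!`.
#'
#' @param fams A [derive_families()] result.
#' @param limit Abort (with the computed count) when the total number of
#'   matchings exceeds this bound.
#' @return List of [resolved_matching()] objects.
#' @export
enumerate_maximal_matchings <- function(fams, limit = 1e5) {
  per_family <- lapply(fams, function(f) {
    na <- length(f$A); nb <- length(f$B); m <- min(na, nb)
    if (m == 0L)
      return(list(data.frame(occ_a = integer(0), occ_b = integer(0))))
    opts <- list()
    if (na <= nb) {
      sel <- utils::combn(seq_len(nb), m, simplify = FALSE)
      for (ss in sel) for (p in perms(f$B[ss]))
        opts[[length(opts) + 1L]] <- data.frame(occ_a = f$A, occ_b = p)
    } else {
      sel <- utils::combn(seq_len(na), m, simplify = FALSE)
      for (ss in sel) for (p in perms(f$A[ss]))
        opts[[length(opts) + 1L]] <- data.frame(occ_a = p, occ_b = f$B)
    }
    opts
  })
  total <- prod(vapply(per_family, length, integer(1)))
  if (total > limit)
    stop(sprintf("matching enumeration would produce %.0f matchings (limit %g)",
                 total, limit))
  combos <- list(data.frame(occ_a = integer(0), occ_b = integer(0)))
  for (opts in per_family) {
    combos <- unlist(lapply(combos, function(acc)
      lapply(opts, function(o) rbind(acc, o))), recursive = FALSE)
  }
  lapply(combos, function(df) resolved_matching(df$occ_a, df$occ_b, fams))
}

#' Minimum distance over all maximal matchings, by enumeration
#'
#' The exhaustive reference for the natural-genome problem: evaluates
#' [resolved_distance()] on every maximal matching and returns the minimum.
#'
#' @param a,b `dcj_genome` objects with occurrence ids.
#' @param fams Optional family assignment (derived when `NULL`).
#' @param limit Passed to [enumerate_maximal_matchings()].
#' @return Integer minimum distance, with the optimal matching attached as
#'   attribute `matching`.
#' @export
min_distance_by_enumeration <- function(a, b, fams = NULL, limit = 1e5) {
  if (is.null(fams)) fams <- derive_families(a, b)
  ms <- enumerate_maximal_matchings(fams, limit)
  best <- Inf; best_m <- NULL
  for (m in ms) {
    d <- resolved_distance(a, b, m)$distance
    if (d < best) { best <- d; best_m <- m }
  }
  out <- as.integer(best)
  attr(out, "matching") <- best_m
  out
}
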