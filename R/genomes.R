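#' Genome data model and UniMoG input/output
#'
#' A genome is an ordered collection of chromosomes; a chromosome is an
#' ordered run of oriented marker occurrences and is either linear or
#' circular. Marker *families* are the homology classes implied by shared
#' token names across the two genomes of a comparison. Every occurrence
#' carries a pair-wide unique integer id so that extremities (tail/head)
#' can be addressed as `2*occ - 1` and `2*occ`.
#'
#' @name genomes
#' @keywords internal
NULL

#' Construct a chromosome
#'
#' @param fams Character vector of family tokens, in chromosomal order.
#' @param signs Integer vector of +1 (forward) / -1 (reverse), recycled if
#'   length 1.
#' @param circular Logical scalar; `FALSE` for a linear chromosome.
#' @return An object of class `dcj_chromosome`.
#' @examples
#' chromosome(c("1", "2"), c(1, -1))
#' @export
chromosome <- function(fams, signs = 1L, circular = FALSE) {
  fams <- as.character(fams)
  if (length(fams) == 0L) stop("empty chromosomes are not allowed")
  signs <- rep_len(as.integer(signs), length(fams))
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  structure(list(fams = fams, signs = signs, circular = isTRUE(circular),
                 occ = rep(NA_integer_, length(fams))),
            class = "dcj_chromosome")
}

#' Construct a genome
#'
#' @param name Genome name (the text after `>` in UniMoG files).
#' @param chromosomes List of [chromosome()] objects.
#' @return An object of class `dcj_genome`.
#' @examples
#' genome("A", list(chromosome(c("1", "2"))))
#' @export
genome <- function(name, chromosomes) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(chromosomes) ||
      !all(vapply(chromosomes, inherits, logical(1), "dcj_chromosome")))
    stop("chromosomes must be a list of dcj_chromosome objects")
  structure(list(name = name, chromosomes = chromosomes), class = "dcj_genome")
}

#' @export
print.dcj_genome <- function(x, ...) {
  cat(">", x$name, " (", length(x$chromosomes), " chromosome",
      if (length(x$chromosomes) != 1L) "s", ")\n", sep = "")
  for (ch in x$chromosomes) {
    toks <- ifelse(ch$signs < 0L, paste0("-", ch$fams), ch$fams)
    cat(" ", paste(toks, collapse = " "), if (ch$circular) ")" else "|", "\n")
  }
  invisible(x)
}

n_markers <- function(g) sum(vapply(g$chromosomes, function(ch) length(ch$fams), integer(1)))

genome_occs <- function(g) unlist(lapply(g$chromosomes, `[[`, "occ"), use.names = FALSE)

#' Assign pair-wide occurrence ids
#'
#' Ids are assigned deterministically in reading order: genome A before
#' genome B, chromosomes in order, positions left to right, starting at 1.
#' This ordering also fixes the vertex id (`ix`) assignment used by the ILP.
#'
#' @param genomes List of `dcj_genome` objects (usually a pair).
#' @return The list with `occ` fields filled in.
#' @export
assign_occurrences <- function(genomes) {
  nxt <- 1L
  for (gi in seq_along(genomes)) {
    for (ci in seq_along(genomes[[gi]]$chromosomes)) {
      k <- length(genomes[[gi]]$chromosomes[[ci]]$fams)
      genomes[[gi]]$chromosomes[[ci]]$occ <- seq.int(nxt, length.out = k)
      nxt <- nxt + k
    }
  }
  genomes
}

# ---- UniMoG parsing -------------------------------------------------------

#' Parse genomes from UniMoG text
#'
#' The dialect accepted: `>name` header lines; chromosomes are maximal
#' whitespace-separated token runs terminated by `|` (linear) or `)`
#' (circular); several chromosomes may share a line; a `-` prefix marks
#' reverse orientation. Occurrence ids are assigned in reading order
#' across all genomes (see [assign_occurrences()]).
#'
#' @param text A single string, character vector of lines, or a file path
#'   (when `is_path = TRUE`).
#' @param is_path Treat `text` as a file path.
#' @return List of `dcj_genome` objects with occurrence ids assigned.
#' @examples
#' parse_unimog(">A\n1 -2 |\n>B\n1 2 |")
#' @export
parse_unimog <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  flush_genome <- function() {
    if (!is.null(cur_name)) {
      genomes[[length(genomes) + 1L]] <<- genome(cur_name, cur_chroms)
      cur_chroms <<- list()
    }
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_name <- trimws(sub("^>", "", line))
      if (!nzchar(cur_name))
        stop(sprintf("line %d: malformed header (empty genome name)", ln))
      next
    }
    if (is.null(cur_name))
      stop(sprintf("line %d: chromosome data before any '>' header", ln))
    toks <- strsplit(line, "\\s+")[[1]]
    run <- character(0)
    for (tok in toks) {
      if (tok %in% c("|", ")")) {
        if (length(run) == 0L)
          stop(sprintf("line %d: empty chromosome", ln))
        signs <- ifelse(startsWith(run, "-"), -1L, 1L)
        fams <- sub("^-", "", run)
        if (any(!nzchar(fams)))
          stop(sprintf("line %d: bare '-' token", ln))
        cur_chroms[[length(cur_chroms) + 1L]] <-
          chromosome(fams, signs, circular = tok == ")")
        run <- character(0)
      } else {
        run <- c(run, tok)
      }
    }
    if (length(run) > 0L)
      stop(sprintf("line %d: chromosome missing terminator '|' or ')'", ln))
  }
  flush_genome()
  if (length(genomes) == 0L) stop("no '>' headers found in input")
  assign_occurrences(genomes)
}

#' Write genomes in UniMoG text format
#'
#' Inverse of [parse_unimog()]: `parse_unimog(write_unimog(gs))` reproduces
#' the genomes up to chromosome canonicalization.
#'
#' @param genomes List of `dcj_genome` objects.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The UniMoG text (invisibly when written to a file).
#' @export
write_unimog <- function(genomes, path = NULL) {
  if (inherits(genomes, "dcj_genome")) genomes <- list(genomes)
  out <- character(0)
  for (g in genomes) {
    out <- c(out, paste0(">", g$name))
    for (ch in g$chromosomes) {
      toks <- ifelse(ch$signs < 0L, paste0("-", ch$fams), ch$fams)
      out <- c(out, paste(c(toks, if (ch$circular) ")" else "|"), collapse = " "))
    }
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# ---- Extremities and adjacencies -----------------------------------------

ext_tail <- function(occ) 2L * occ - 1L
ext_head <- function(occ) 2L * occ
ext_occ <- function(e) (e + 1L) %/% 2L
ext_is_head <- function(e) e %% 2L == 0L

#' Adjacencies and telomeres of a genome
#'
#' Extremities are encoded as integers: tail of occurrence `k` is `2k - 1`,
#' head is `2k`. For consecutive occurrences the right extremity of the
#' left marker (head if forward, tail if reverse) is adjacent to the left
#' extremity of the right marker; circular chromosomes close the wrap-around
#' adjacency; the outer extremities of linear chromosomes are telomeres.
#'
#' @param g A `dcj_genome` with occurrence ids assigned.
#' @return List with `adjacencies` (2-row integer matrix, one column per
#'   adjacency) and `telomeres` (integer vector of extremity codes).
#' @export
genome_adjacencies <- function(g) {
  adj_u <- integer(0); adj_v <- integer(0); tel <- integer(0)
  for (ch in g$chromosomes) {
    occ <- ch$occ
    if (anyNA(occ)) stop("occurrence ids not assigned; see assign_occurrences()")
    left <- ifelse(ch$signs > 0L, ext_tail(occ), ext_head(occ))
    right <- ifelse(ch$signs > 0L, ext_head(occ), ext_tail(occ))
    k <- length(occ)
    if (k > 1L) {
      adj_u <- c(adj_u, right[-k])
      adj_v <- c(adj_v, left[-1L])
    }
    if (ch$circular) {
      adj_u <- c(adj_u, right[k])
      adj_v <- c(adj_v, left[1L])
    } else {
      tel <- c(tel, left[1L], right[k])
    }
  }
  list(adjacencies = rbind(adj_u, adj_v, deparse.level = 0),
       telomeres = tel)
}

# ---- Families and matchings ----------------------------------------------

occurrence_table <- function(g, genome_tag) {
  fams <- unlist(lapply(g$chromosomes, `[[`, "fams"), use.names = FALSE)
  occs <- genome_occs(g)
  data.frame(occ = occs, fam = fams, genome = rep(genome_tag, length(occs)),
             stringsAsFactors = FALSE)
}

#' Derive the family assignment of a genome pair
#'
#' Families are keyed by token. A family is *singular* when it has
#' occurrences in only one genome, and *ambiguous* when some genome holds
#' more than one of its occurrences.
#'
#' @param a,b `dcj_genome` objects with occurrence ids assigned.
#' @return Object of class `family_assignment`: a list mapping family token
#'   to `list(A = <occ ids>, B = <occ ids>)`, with a `summary` attribute
#'   data frame (columns `fam`, `n_a`, `n_b`, `singular`, `ambiguous`).
#' @export
derive_families <- function(a, b) {
  ta <- occurrence_table(a, "A"); tb <- occurrence_table(b, "B")
  fams <- sort(unique(c(ta$fam, tb$fam)))
  out <- lapply(fams, function(f) {
    list(A = ta$occ[ta$fam == f], B = tb$occ[tb$fam == f])
  })
  names(out) <- fams
  n_a <- vapply(out, function(x) length(x$A), integer(1))
  n_b <- vapply(out, function(x) length(x$B), integer(1))
  attr(out, "summary") <- data.frame(
    fam = fams, n_a = n_a, n_b = n_b,
    singular = n_a == 0L | n_b == 0L,
    ambiguous = n_a > 1L | n_b > 1L,
    stringsAsFactors = FALSE)
  class(out) <- "family_assignment"
  out
}

#' @export
print.family_assignment <- function(x, ...) {
  print(attr(x, "summary"))
  invisible(x)
}

#' Construct a resolved matching
#'
#' A resolved matching pairs occurrences of genome A with occurrences of
#' genome B, injectively on both sides, within families.
#'
#' @param occ_a,occ_b Equal-length integer vectors of occurrence ids.
#' @param fams Optional `family_assignment` to validate against.
#' @return Object of class `resolved_matching`: a data frame with columns
#'   `occ_a`, `occ_b`.
#' @export
resolved_matching <- function(occ_a, occ_b, fams = NULL) {
  occ_a <- as.integer(occ_a); occ_b <- as.integer(occ_b)
  if (length(occ_a) != length(occ_b)) stop("occ_a and occ_b differ in length")
  if (anyDuplicated(occ_a) || anyDuplicated(occ_b))
    stop("matching must be injective on both sides")
  m <- data.frame(occ_a = occ_a, occ_b = occ_b)
  if (!is.null(fams)) {
    fam_of_a <- fam_lookup(fams, "A"); fam_of_b <- fam_lookup(fams, "B")
    fa <- fam_of_a[as.character(occ_a)]; fb <- fam_of_b[as.character(occ_b)]
    if (any(is.na(fa)) || any(is.na(fb)) || any(fa != fb))
      stop("matching pairs occurrences of different families")
    m$fam <- unname(fa)
  }
  class(m) <- c("resolved_matching", "data.frame")
  m
}

fam_lookup <- function(fams, tag) {
  occ <- unlist(lapply(fams, `[[`, tag), use.names = FALSE)
  rep_fam <- rep(names(fams), vapply(fams, function(x) length(x[[tag]]), integer(1)))
  stats::setNames(rep_fam, as.character(occ))
}

#' Identity matching of a pair under a resolved homology
#'
#' Requires every family to have at most one occurrence per genome; pairs
#' each family's A occurrence with its B occurrence.
#'
#' @param a,b `dcj_genome` objects.
#' @return A [resolved_matching()].
#' @export
identity_matching <- function(a, b) {
  fams <- derive_families(a, b)
  s <- attr(fams, "summary")
  if (any(s$ambiguous))
    stop("homology is not resolved; ambiguous families: ",
         paste(s$fam[s$ambiguous], collapse = ", "))
  keep <- s$n_a == 1L & s$n_b == 1L
  resolved_matching(
    vapply(fams[s$fam[keep]], function(x) x$A, integer(1)),
    vapply(fams[s$fam[keep]], function(x) x$B, integer(1)),
    fams)
}

#' Is a matching maximal for a family assignment?
#'
#' Maximal means `min(|f_A|, |f_B|)` pairs are present for every family,
#' so that each family retains singular markers in at most one genome.
#'
#' @param match A [resolved_matching()].
#' @param fams A [derive_families()] result.
#' @return Logical scalar.
#' @export
is_maximal_matching <- function(match, fams) {
  fam_of_a <- fam_lookup(fams, "A")
  cnt <- table(factor(fam_of_a[as.character(match$occ_a)], levels = names(fams)))
  s <- attr(fams, "summary")
  all(as.integer(cnt) == pmin(s$n_a, s$n_b))
}

# ---- Canonicalization and equality ---------------------------------------

signed_tokens <- function(fams, signs) ifelse(signs < 0L, paste0("-", fams), fams)

rev_comp <- function(fams, signs) list(fams = rev(fams), signs = -rev(signs))

#' Canonical key of a chromosome
#'
#' Linear chromosomes are canonical under full reversal; circular ones
#' under rotation and reversal. The key is the lexicographically smallest
#' token string among the equivalent readings.
#'
#' @param ch A `dcj_chromosome`.
#' @return A single string (prefixed `L:` or `C:`).
#' @export
canonical_chromosome_key <- function(ch) {
  cand <- character(0)
  if (ch$circular) {
    k <- length(ch$fams)
    for (r in seq_len(k)) {
      idx <- c(seq.int(r, k), if (r > 1L) seq_len(r - 1L))
      cand <- c(cand, paste(signed_tokens(ch$fams[idx], ch$signs[idx]), collapse = " "))
      rc <- rev_comp(ch$fams[idx], ch$signs[idx])
      cand <- c(cand, paste(signed_tokens(rc$fams, rc$signs), collapse = " "))
    }
    paste0("C:", min(cand))
  } else {
    fwd <- paste(signed_tokens(ch$fams, ch$signs), collapse = " ")
    rc <- rev_comp(ch$fams, ch$signs)
    bwd <- paste(signed_tokens(rc$fams, rc$signs), collapse = " ")
    paste0("L:", min(fwd, bwd))
  }
}

#' Canonical key of a genome
#'
#' The sorted multiset of canonical chromosome keys; two genomes over the
#' same marker labels are equal as marker/adjacency sets iff their keys are
#' equal.
#'
#' @param g A `dcj_genome`.
#' @return A single string.
#' @export
canonical_genome_key <- function(g) {
  paste(sort(vapply(g$chromosomes, canonical_chromosome_key, character(1))),
        collapse = " ; ")
}

#' Test genome equality under a matching
#'
#' Relabels the pair by the matching (matched pairs get a shared label,
#' unmatched occurrences per-genome labels) and compares canonical
#' chromosome multisets, so equality holds iff each marker and adjacency of
#' one genome has exactly one counterpart in the other.
#'
#' @param a,b `dcj_genome` objects with occurrence ids.
#' @param match A [resolved_matching()].
#' @return Logical scalar.
#' @export
genomes_equal <- function(a, b, match) {
  lab <- relabel_pair(a, b, match)
  identical(canonical_genome_key(lab$a), canonical_genome_key(lab$b))
}

# Relabel a pair so matched occurrences share a token and unmatched ones get
# unique per-occurrence tokens; used by the oracle and equality test.
relabel_pair <- function(a, b, match) {
  map_a <- stats::setNames(paste0("m", seq_len(nrow(match))), as.character(match$occ_a))
  map_b <- stats::setNames(paste0("m", seq_len(nrow(match))), as.character(match$occ_b))
  relab <- function(g, map, tag) {
    g$chromosomes <- lapply(g$chromosomes, function(ch) {
      key <- as.character(ch$occ)
      hit <- map[key]
      ch$fams <- ifelse(is.na(hit), paste0(tag, key), unname(hit))
      ch
    })
    g
  }
  list(a = relab(a, map_a, "uA"), b = relab(b, map_b, "uB"))
}

#' Validate genome invariants
#'
#' Checks that the derived adjacency set is a matching on extremities and
#' that every extremity is either in exactly one adjacency or a telomere.
#'
#' @param g A `dcj_genome` with occurrence ids.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_genome <- function(g) {
  occs <- genome_occs(g)
  if (anyDuplicated(occs)) stop("duplicate occurrence ids")
  aj <- genome_adjacencies(g)
  touched <- c(aj$adjacencies[1, ], aj$adjacencies[2, ])
  if (anyDuplicated(touched)) stop("adjacencies do not form a matching")
  if (length(intersect(touched, aj$telomeres)) > 0L)
    stop("telomere listed in an adjacency")
  all_ext <- c(ext_tail(occs), ext_head(occs))
  if (!setequal(c(touched, aj$telomeres), all_ext))
    stop("extremity neither in an adjacency nor a telomere")
  invisible(TRUE)
}
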