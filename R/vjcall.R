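#' Local alignment of mates against germline segments
#'
#' Ungapped local alignment (substitution-oriented, both strands) with an
#' identity floor and a minimum aligned length; the best-scoring placement
#' per (mate, segment) is retained.  Score is matches minus mismatches.
#' The defaults (identity 0.95, length 20 nt) are chosen so that ranking
#' by score distinguishes segments at 99 percent similarity.
#'
#' @param mates character vector of mate sequences.
#' @param segments segment data.frame (see [germline_set()]) or named
#'   character vector of segment sequences.
#' @param min_identity minimum matched fraction of the aligned span.
#' @param min_length minimum aligned length in nt.
#' @return data.frame with columns `mate` (index), `segment`, `subgroup`,
#'   `strand`, `read_start`, `read_end` (0-based half-open on the original
#'   mate), `seg_start`, `seg_end`, `matches`, `length`, `score`,
#'   `identity`.
#' @export
align_local <- function(mates, segments, min_identity = 0.95,
                        min_length = 20) {
  if (is.character(segments)) {
    segments <- data.frame(name = names(segments), seq = unname(segments),
                           subgroup = NA_character_,
                           stringsAsFactors = FALSE)
  }
  if (nrow(segments) == 0L) stop("empty segment set", call. = FALSE)
  k <- run_guarantee_local(min_length, min_identity,
                           max(nchar(mates), min_length))
  k <- if (k < 4L) 0L else min(31L, k)
  h <- cpp_local_align(unname(mates), segments$seq, min_identity,
                       as.integer(min_length), as.integer(k))
  h$segment <- segments$name[h$seg]
  h$subgroup <- segments$subgroup[h$seg]
  h$strand <- ifelse(h$strand > 0, "+", "-")
  h$identity <- h$matches / h$length
  h$seg <- NULL
  h
}

#' Detect VJ-encompassing read pairs
#'
#' A read pair is VJ-encompassing when one mate aligns locally to at least
#' one V segment and the other mate to at least one J segment; mates may
#' be covered totally or partially.  A pair for which both orientations
#' are simultaneously possible (each mate hits both a V and a J in the
#' complementary arrangement) is ambiguous and excluded with a flag.
#'
#' @param reads data.frame with `read_id`, `mate1_seq`, `mate2_seq`.
#' @param v_set,j_set segment data.frames (elements of a `germline_set`).
#' @param min_identity,min_length see [align_local()].
#' @return object of class `encompassing_reads`: list with `hits`
#'   (data.frame of V hits of the V mate and J hits of the J mate, with a
#'   `role` column), `v_mate` (data.frame `read_id`, `v_mate`), and
#'   `ambiguous` (excluded read ids).
#' @export
find_encompassing_reads <- function(reads, v_set, j_set,
                                    min_identity = 0.95, min_length = 20) {
  if (nrow(v_set) == 0L || nrow(j_set) == 0L) {
    stop("empty germline set", call. = FALSE)
  }
  n <- nrow(reads)
  mates <- c(reads$mate1_seq, reads$mate2_seq)
  vh <- align_local(mates, v_set, min_identity, min_length)
  jh <- align_local(mates, j_set, min_identity, min_length)

  has_v <- matrix(FALSE, n, 2)
  has_j <- matrix(FALSE, n, 2)
  has_v[cbind((vh$mate - 1L) %% n + 1L, (vh$mate - 1L) %/% n + 1L)] <- TRUE
  has_j[cbind((jh$mate - 1L) %% n + 1L, (jh$mate - 1L) %/% n + 1L)] <- TRUE

  or1 <- has_v[, 1] & has_j[, 2]  # mate1 = V mate
  or2 <- has_v[, 2] & has_j[, 1]  # mate2 = V mate
  ambiguous <- or1 & or2
  keep1 <- or1 & !ambiguous
  keep2 <- or2 & !ambiguous

  v_mate <- integer(n)
  v_mate[keep1] <- 1L
  v_mate[keep2] <- 2L
  sel <- v_mate > 0L

  decorate <- function(h, role) {
    ridx <- (h$mate - 1L) %% n + 1L
    midx <- (h$mate - 1L) %/% n + 1L
    want_mate <- if (role == "V") v_mate[ridx] else 3L - v_mate[ridx]
    keep <- sel[ridx] & midx == want_mate
    h <- h[keep, , drop = FALSE]
    if (nrow(h)) {
      h$read_id <- reads$read_id[(h$mate - 1L) %% n + 1L]
      h$mate <- (h$mate - 1L) %/% n + 1L
      h$role <- role
    } else {
      h$read_id <- character(0)
      h$role <- character(0)
    }
    h
  }
  hits <- rbind(decorate(vh, "V"), decorate(jh, "J"))
  rownames(hits) <- NULL
  res <- list(hits = hits,
              v_mate = data.frame(read_id = reads$read_id[sel],
                                  v_mate = v_mate[sel],
                                  stringsAsFactors = FALSE),
              ambiguous = reads$read_id[ambiguous])
  class(res) <- "encompassing_reads"
  res
}

#' @export
print.encompassing_reads <- function(x, ...) {
  cat(sprintf(
    "encompassing_reads: %d reads (%d ambiguous excluded), %d hits\n",
    nrow(x$v_mate), length(x$ambiguous), nrow(x$hits)))
  invisible(x)
}

#' Library-size-normalised clone score
#'
#' `score = count / total_reads * 1e9`.  Unlike conventional RPKM there is
#' deliberately no per-length normalisation: V, D and J regions are
#' comparable to or shorter than a single mate, and encompassing reads do
#' not tile the V region, so dividing by segment length would distort the
#' comparison between clones.
#'
#' @param count supporting-read count (must not exceed `total_reads`).
#' @param total_reads library size (input read pairs); must be > 0.
#' @return numeric score(s).
#' @export
rpkm_like <- function(count, total_reads) {
  if (any(total_reads <= 0)) stop("`total_reads` must be > 0",
                                  call. = FALSE)
  if (any(count < 0) || any(count > total_reads)) {
    stop("`count` must be in [0, total_reads]", call. = FALSE)
  }
  count / total_reads * 1e9
}

#' Count and rank VJ couples
#'
#' For each (V, J) couple implied by any encompassing read, the supporting
#' reads are counted with set semantics: a read supporting the same couple
#' at several positions counts once for that couple, while a read
#' supporting several couples counts once for each of them (no decision is
#' possible at this stage).  Couples are sorted by count descending, ties
#' broken lexicographically on (v_name, j_name) and flagged.
#'
#' @param enc an `encompassing_reads` object.
#' @param total_reads optional library size for [rpkm_like()] scores.
#' @return data.frame of class `vj_couples`: `v_name`, `j_name`,
#'   `v_subgroup`, `j_subgroup`, `count`, `tie`, optional `rpkm`, and a
#'   list column `supporting_reads`.
#' @export
count_vj_couples <- function(enc, total_reads = NULL) {
  h <- enc$hits
  empty <- data.frame(v_name = character(), j_name = character(),
                      v_subgroup = character(), j_subgroup = character(),
                      count = integer(), tie = logical())
  empty$supporting_reads <- list()
  if (is.null(h) || nrow(h) == 0L) {
    class(empty) <- c("vj_couples", "data.frame")
    return(empty)
  }
  vv <- unique(h[h$role == "V", c("read_id", "segment", "subgroup")])
  jj <- unique(h[h$role == "J", c("read_id", "segment", "subgroup")])
  m <- merge(vv, jj, by = "read_id", suffixes = c("_v", "_j"))
  if (nrow(m) == 0L) {
    class(empty) <- c("vj_couples", "data.frame")
    return(empty)
  }
  key <- paste(m$segment_v, m$segment_j, sep = "\r")
  sets <- split(m$read_id, key)
  sets <- lapply(sets, unique)
  parts <- strsplit(names(sets), "\r", fixed = TRUE)
  sub_v <- m$subgroup_v[match(names(sets), key)]
  sub_j <- m$subgroup_j[match(names(sets), key)]
  out <- data.frame(v_name = vapply(parts, `[`, "", 1L),
                    j_name = vapply(parts, `[`, "", 2L),
                    v_subgroup = sub_v, j_subgroup = sub_j,
                    count = vapply(sets, length, 0L),
                    stringsAsFactors = FALSE)
  out$supporting_reads <- lapply(sets, sort)
  out <- out[order(-out$count, out$v_name, out$j_name), , drop = FALSE]
  rownames(out) <- NULL
  out$tie <- duplicated(out$count) | duplicated(out$count, fromLast = TRUE)
  if (!is.null(total_reads)) out$rpkm <- rpkm_like(out$count, total_reads)
  class(out) <- c("vj_couples", "data.frame")
  out
}

#' Aggregate VJ couples to subgroup level
#'
#' Couples sharing the (V subgroup, J subgroup) pair are merged; with
#' `method = "union"` (default) the supporting-read sets are unioned so a
#' read multimapping across alleles of a subgroup is not double-counted;
#' `method = "sum"` adds the allele-level counts instead, for comparison.
#'
#' @param couples a `vj_couples` data.frame.
#' @param total_reads optional library size for scores.
#' @param method `"union"` or `"sum"`.
#' @return `vj_couples`-like data.frame keyed by `v_subgroup`,
#'   `j_subgroup`.
#' @export
aggregate_by_subgroup <- function(couples, total_reads = NULL,
                                  method = c("union", "sum")) {
  method <- match.arg(method)
  empty <- data.frame(v_subgroup = character(), j_subgroup = character(),
                      count = integer(), tie = logical())
  if (nrow(couples) == 0L) return(empty)
  key <- paste(couples$v_subgroup, couples$j_subgroup, sep = "\r")
  groups <- split(seq_len(nrow(couples)), key)
  count <- vapply(groups, function(i) {
    if (method == "union") {
      length(unique(unlist(couples$supporting_reads[i])))
    } else sum(couples$count[i])
  }, 0L)
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(v_subgroup = vapply(parts, `[`, "", 1L),
                    j_subgroup = vapply(parts, `[`, "", 2L),
                    count = unname(count), stringsAsFactors = FALSE)
  out$supporting_reads <- lapply(groups, function(i) {
    sort(unique(unlist(couples$supporting_reads[i])))
  })
  out <- out[order(-out$count, out$v_subgroup, out$j_subgroup), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$tie <- duplicated(out$count) | duplicated(out$count, fromLast = TRUE)
  if (!is.null(total_reads)) out$rpkm <- rpkm_like(out$count, total_reads)
  out
}

#' Main clone and monoclonality ratio
#'
#' Returns the top-ranked couple together with the top-1/top-2
#' supporting-read ratio — the statistic used to assess whether a single
#' clone dominates a polyclonal background.
#'
#' @param couples a sorted `vj_couples` (or subgroup-level) data.frame.
#' @return list with `couple` (first row), `ratio` (`Inf` when only one
#'   couple exists) and `tie` (logical: the top count is shared).
#' @export
main_clone <- function(couples) {
  if (nrow(couples) == 0L) {
    stop("no rearrangement detected", call. = FALSE)
  }
  ratio <- if (nrow(couples) >= 2L) {
    couples$count[1L] / couples$count[2L]
  } else Inf
  list(couple = couples[1L, , drop = FALSE], ratio = ratio,
       tie = isTRUE(couples$tie[1L]))
}
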