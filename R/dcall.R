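#' Select mates not fully explained by their V or J alignment
#'
#' From the encompassing reads, returns the mates whose best V/J local
#' alignment covers strictly less than the full mate length (an uncovered
#' flank of at least 1 nt remains): these are the mates that may carry D
#' and junction sequence.
#'
#' @param enc an `encompassing_reads` object.
#' @param reads data.frame with `read_id`, `mate1_seq`, `mate2_seq`.
#' @return data.frame with `read_id`, `mate`, `seq`.
#' @export
select_partial_mates <- function(enc, reads) {
  h <- enc$hits
  if (is.null(h) || nrow(h) == 0L) {
    return(data.frame(read_id = character(), mate = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  key <- paste(h$read_id, h$mate)
  best <- tapply(seq_len(nrow(h)), key, function(i) {
    i[which.max(h$score[i])]
  })
  b <- h[unlist(best), , drop = FALSE]
  ridx <- match(b$read_id, reads$read_id)
  mlen <- ifelse(b$mate == 1L, nchar(reads$mate1_seq[ridx]),
                 nchar(reads$mate2_seq[ridx]))
  covered <- b$read_end - b$read_start
  keep <- covered < mlen
  out <- data.frame(
    read_id = b$read_id[keep], mate = b$mate[keep],
    seq = ifelse(b$mate[keep] == 1L, reads$mate1_seq[ridx][keep],
                 reads$mate2_seq[ridx][keep]),
    stringsAsFactors = FALSE)
  out[order(out$read_id, out$mate), , drop = FALSE]
}

#' Seeded local alignment on D segments
#'
#' A mate receives a hit only if it shares an exact common substring of at
#' least `min_seed` nt with a D segment (either strand).  Among all
#' candidate seeds the highest-scoring ungapped extension (+1 match, -1
#' mismatch) is returned — at most one reported alignment per mate, ties
#' broken lexicographically on segment name and flagged.
#'
#' @param mates character vector of mate sequences.
#' @param d_set D-segment data.frame (element `d` of a `germline_set`).
#' @param min_seed minimum exact seed length in nt (default 10).
#' @return data.frame with one row per mate that has a hit: `mate`
#'   (index), `segment`, `strand`, `read_start`, `read_end`, `seg_start`,
#'   `seg_end`, `matches`, `length`, `score`, `tie`.
#' @export
align_seeded <- function(mates, d_set, min_seed = 10) {
  if (nrow(d_set) == 0L) stop("empty D segment set", call. = FALSE)
  # segment tables are kept sorted by name, so index order = name order
  stopifnot(!is.unsorted(d_set$name))
  h <- cpp_seeded_align(unname(mates), d_set$seq, as.integer(min_seed))
  h$segment <- d_set$name[h$seg]
  h$strand <- ifelse(h$strand > 0, "+", "-")
  h$tie <- h$tie > 0
  h$seg <- NULL
  h
}

#' Assign the rearranged D segment to a VJ couple
#'
#' Tallies, over the selected partial mates of the couple's supporting
#' reads, one unit per mate per reported seeded D hit; the most supported
#' D segment is assigned.  Ties are broken lexicographically and flagged;
#' absence of any D evidence is flagged.
#'
#' @param couple one-row slice of a `vj_couples` data.frame.
#' @param partial_mates output of [select_partial_mates()].
#' @param d_hits output of [align_seeded()] on `partial_mates$seq`.
#' @return list (`clone`): `v_name`, `j_name`, `d_name` (`NA` without
#'   evidence), `d_support` (named tally), `d_support_top`, `d_flag`
#'   (`"assigned"`, `"no_d_evidence"` or `"tie"`).
#' @export
assign_d <- function(couple, partial_mates, d_hits) {
  support_ids <- couple$supporting_reads[[1L]]
  midx <- which(partial_mates$read_id %in% support_ids)
  hh <- d_hits[d_hits$mate %in% midx, , drop = FALSE]
  if (nrow(hh) == 0L) {
    return(list(v_name = couple$v_name, j_name = couple$j_name,
                d_name = NA_character_, d_support = integer(0),
                d_support_top = 0L, d_flag = "no_d_evidence"))
  }
  tally <- sort(table(hh$segment), decreasing = TRUE)
  top <- max(tally)
  winners <- sort(names(tally)[tally == top])
  list(v_name = couple$v_name, j_name = couple$j_name,
       d_name = winners[1L], d_support = c(tally),
       d_support_top = as.integer(top),
       d_flag = if (length(winners) > 1L) "tie" else "assigned")
}

#' Identify D alleles for the most supported VJ couples
#'
#' Runs [select_partial_mates()] + [align_seeded()] once, then assigns a D
#' segment to each of the top `top_n` couples.  A mate belonging to
#' several couples' supporting reads contributes to each of them.
#'
#' @param couples a `vj_couples` data.frame (sorted).
#' @param enc the `encompassing_reads` object the couples came from.
#' @param reads read table.
#' @param d_set D-segment data.frame.
#' @param top_n number of couples to process (default 5).
#' @param min_seed see [align_seeded()].
#' @return data.frame of class `clone_table`: couple columns plus
#'   `d_name`, `d_support_top`, `d_flag`; attribute `d_hits` carries the
#'   per-mate seeded alignments and `partial_mates` the mate table.
#' @export
call_d_alleles <- function(couples, enc, reads, d_set, top_n = 5,
                           min_seed = 10) {
  n <- min(top_n, nrow(couples))
  if (n == 0L) stop("no rearrangement detected", call. = FALSE)
  pm <- select_partial_mates(enc, reads)
  dh <- if (nrow(pm)) align_seeded(pm$seq, d_set, min_seed) else
    data.frame(mate = integer(), segment = character())
  rows <- lapply(seq_len(n), function(i) {
    cl <- assign_d(couples[i, , drop = FALSE], pm, dh)
    data.frame(rank = i, v_name = cl$v_name, j_name = cl$j_name,
               count = couples$count[i],
               rpkm = if ("rpkm" %in% names(couples))
                 couples$rpkm[i] else NA_real_,
               d_name = cl$d_name, d_support_top = cl$d_support_top,
               d_flag = cl$d_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "d_hits") <- dh
  attr(out, "partial_mates") <- pm
  class(out) <- c("clone_table", "data.frame")
  out
}
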