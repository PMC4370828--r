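# longest common prefix / suffix lengths between two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

common_suffix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(substr(a, nchar(a) - n + 1L, nchar(a))))
  bv <- rev(utf8ToInt(substr(b, nchar(b) - n + 1L, nchar(b))))
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

# flip a hit's read coordinates into sense (hit-strand) orientation
orient_hit <- function(hit, mate_len) {
  if (hit$strand == "+") {
    list(rs = hit$read_start, re = hit$read_end,
         ss = hit$seg_start, se = hit$seg_end)
  } else {
    list(rs = mate_len - hit$read_end, re = mate_len - hit$read_start,
         ss = hit$seg_start, se = hit$seg_end)
  }
}

#' Select junction-bridging read pairs
#'
#' From a couple's supporting reads, returns those for which each mate
#' carries a seeded D hit on the same D segment — the reads eligible for
#' virtual-reference construction.  Pairs whose two mates' D segment
#' intervals intersect are the overlap case; otherwise the D interior must
#' be germline-filled (non-overlap case).
#'
#' @param couple one-row slice of a `vj_couples` data.frame.
#' @param partial_mates,d_hits outputs of [select_partial_mates()] /
#'   [align_seeded()].
#' @return data.frame with `read_id`, `d_name`, `case` (`"overlap"` or
#'   `"non_overlap"`).
#' @export
select_bridging_reads <- function(couple, partial_mates, d_hits) {
  empty <- data.frame(read_id = character(), d_name = character(),
                      case = character(), stringsAsFactors = FALSE)
  if (nrow(d_hits) == 0L) return(empty)
  support <- couple$supporting_reads[[1L]]
  dh <- d_hits
  dh$read_id <- partial_mates$read_id[dh$mate]
  dh$mate_no <- partial_mates$mate[dh$mate]
  dh <- dh[dh$read_id %in% support, , drop = FALSE]
  out <- lapply(split(dh, dh$read_id), function(g) {
    if (length(unique(g$mate_no)) != 2L) return(NULL)
    if (length(unique(g$segment)) != 1L) return(NULL)
    a <- g[1L, ]; b <- g[2L, ]
    over <- a$seg_start < b$seg_end && b$seg_start < a$seg_end
    data.frame(read_id = g$read_id[1L], d_name = g$segment[1L],
               case = if (over) "overlap" else "non_overlap",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$read_id), , drop = FALSE]
}

# best hit of a given role for one read (hits already restricted to the
# correct mate by find_encompassing_reads); deterministic tie-break
best_role_hit <- function(enc_hits, read_id, role) {
  h <- enc_hits[enc_hits$read_id == read_id & enc_hits$role == role, ,
                drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(-h$score, h$length, h$segment, h$seg_start), , drop = FALSE]
  h[1L, , drop = FALSE]
}

#' Build a virtual reference from one bridging read pair
#'
#' The candidate main-clone sequence is assembled from the read pair's
#' best-scoring placements: the germline V up to the read-supported V end
#' (read bases where the mate is aligned, germline extension to the V 5'
#' end), the VD-junction bases read between the V- and D-aligned
#' intervals, the D-covered bases (germline-filled between the two mates
#' in the non-overlap case), the DJ-junction bases, and the germline J
#' from the read-supported J start through the J 3' end.  Returns `NULL`
#' (with a `reason` attribute) for reads with inconsistent orientations or
#' negative junction intervals.
#'
#' @param read_id read to build from.
#' @param reads read table.
#' @param enc `encompassing_reads` object.
#' @param partial_mates,d_hits outputs of the D-calling stage.
#' @param germline a `germline_set`.
#' @return object of class `virtual_reference`: list with `source_read_id`,
#'   `sequence`, `v_name`, `d_name`, `j_name`, `spans` (named widths of
#'   `V_part`, `VD_junction`, `D_part`, `DJ_junction`, `J_part`),
#'   `core_start`/`core_end` (read-evidenced span, 0-based half-open); or
#'   an object of class `skipped_read` carrying the skip `reason`.
#' @export
build_virtual_reference <- function(read_id, reads, enc, partial_mates,
                                    d_hits, germline) {
  fail <- function(reason) {
    structure(list(reason = reason), class = "skipped_read")
  }
  v_hit <- best_role_hit(enc$hits, read_id, "V")
  j_hit <- best_role_hit(enc$hits, read_id, "J")
  if (is.null(v_hit) || is.null(j_hit)) return(fail("missing V or J hit"))

  dh <- d_hits
  dh$read_id <- partial_mates$read_id[dh$mate]
  dh$mate_no <- partial_mates$mate[dh$mate]
  dh <- dh[dh$read_id == read_id, , drop = FALSE]
  if (length(unique(dh$mate_no)) != 2L) return(fail("missing D hit"))
  if (length(unique(dh$segment)) != 1L) return(fail("discordant D hits"))

  ridx <- match(read_id, reads$read_id)
  vm <- enc$v_mate$v_mate[match(read_id, enc$v_mate$read_id)]
  mate_seq <- c(reads$mate1_seq[ridx], reads$mate2_seq[ridx])
  v_seq_m <- mate_seq[vm]
  j_seq_m <- mate_seq[3L - vm]
  d1 <- dh[dh$mate_no == vm, , drop = FALSE]
  d2 <- dh[dh$mate_no == 3L - vm, , drop = FALSE]
  if (nrow(d1) != 1L || nrow(d2) != 1L) return(fail("missing D hit"))

  # orientation consistency: the D hit on each mate must be on the same
  # strand as that mate's V (resp. J) hit
  if (d1$strand != v_hit$strand || d2$strand != j_hit$strand) {
    return(fail("inconsistent orientations"))
  }
  lv <- nchar(v_seq_m)
  lj <- nchar(j_seq_m)
  sense_v <- if (v_hit$strand == "+") v_seq_m else revcomp(v_seq_m)
  sense_j <- if (j_hit$strand == "+") j_seq_m else revcomp(j_seq_m)
  vh <- orient_hit(v_hit, lv)
  jh <- orient_hit(j_hit, lj)
  d1h <- orient_hit(d1, lv)
  d2h <- orient_hit(d2, lj)

  # a V (or J) local alignment may creep a few bases across the junction
  # when junction bases chance-match the germline continuation; clip it at
  # the D hit boundary (hits are ungapped, so clipping is coordinate-
  # consistent and the clipped bases are read-derived either way)
  if (d1h$rs < vh$re) {
    if (d1h$rs <= vh$rs) return(fail("negative VD junction interval"))
    vh$se <- vh$ss + (d1h$rs - vh$rs)
    vh$re <- d1h$rs
  }
  if (jh$rs < d2h$re) {
    if (jh$re <= d2h$re) return(fail("negative DJ junction interval"))
    jh$ss <- jh$se - (jh$re - d2h$re)
    jh$rs <- d2h$re
  }

  v_germ <- germline$v$seq[match(v_hit$segment, germline$v$name)]
  j_germ <- germline$j$seq[match(j_hit$segment, germline$j$name)]
  d_germ <- germline$d$seq[match(d1$segment, germline$d$name)]

  sub0 <- function(s, a, b) if (b <= a) "" else substr(s, a + 1L, b)

  v_part <- paste0(sub0(v_germ, 0L, vh$ss), sub0(sense_v, vh$rs, vh$re))
  vd_jun <- sub0(sense_v, vh$re, d1h$rs)

  if (d2h$ss < d1h$ss || d2h$se < d1h$se) {
    return(fail("D intervals out of order"))
  }
  if (d2h$ss < d1h$se) {  # overlap case
    extra <- if (d2h$se > d1h$se) {
      off <- d1h$se - d2h$ss
      sub0(sense_j, d2h$rs + off, d2h$re)
    } else ""
    d_part <- paste0(sub0(sense_v, d1h$rs, d1h$re), extra)
    case <- "overlap"
  } else {  # non-overlap: fill the interior from the germline D
    d_part <- paste0(sub0(sense_v, d1h$rs, d1h$re),
                     sub0(d_germ, d1h$se, d2h$ss),
                     sub0(sense_j, d2h$rs, d2h$re))
    case <- "non_overlap"
  }
  dj_jun <- sub0(sense_j, d2h$re, jh$rs)
  j_part <- paste0(sub0(sense_j, jh$rs, jh$re),
                   sub0(j_germ, jh$se, nchar(j_germ)))

  spans <- c(V_part = nchar(v_part), VD_junction = nchar(vd_jun),
             D_part = nchar(d_part), DJ_junction = nchar(dj_jun),
             J_part = nchar(j_part))
  sequence <- paste0(v_part, vd_jun, d_part, dj_jun, j_part)
  ref <- list(source_read_id = read_id, sequence = sequence,
              v_name = v_hit$segment, d_name = d1$segment,
              j_name = j_hit$segment, spans = spans, case = case,
              core_start = vh$ss,
              core_end = nchar(sequence) - (nchar(j_germ) - jh$se))
  class(ref) <- "virtual_reference"
  validate_reference(ref)
  ref
}

# span-tiling invariant, asserted on every constructed reference
validate_reference <- function(ref) {
  if (sum(ref$spans) != nchar(ref$sequence)) {
    stop("internal error: reference spans do not tile the sequence",
         call. = FALSE)
  }
  invisible(ref)
}

#' Build the candidate reference set for a clone
#'
#' Builds one virtual reference per bridging read, dropping reads that
#' fail consistency checks, and deduplicates identical sequences (the
#' lexicographically smallest source read id is kept as representative).
#'
#' @param bridging output of [select_bridging_reads()].
#' @param reads,enc,partial_mates,d_hits,germline see
#'   [build_virtual_reference()].
#' @return list of `virtual_reference` objects; attribute `skipped` maps
#'   read ids to skip reasons.
#' @export
build_references <- function(bridging, reads, enc, partial_mates, d_hits,
                             germline) {
  refs <- list()
  skipped <- character(0)
  for (rid in bridging$read_id) {
    r <- build_virtual_reference(rid, reads, enc, partial_mates, d_hits,
                                 germline)
    if (inherits(r, "skipped_read")) {
      skipped[rid] <- r$reason
    } else {
      refs[[rid]] <- r
    }
  }
  if (length(refs)) {
    refs <- refs[order(names(refs))]
    seqs <- vapply(refs, `[[`, "", "sequence")
    refs <- refs[!duplicated(seqs)]
  }
  attr(refs, "skipped") <- skipped
  refs
}

#' Score virtual references by re-mapping unmapped reads
#'
#' Each reference is supported by the read pairs of the scoring set with
#' at least one mate locally aligning to it (identity and length floors as
#' in [align_local()]); the score is the library-size-normalised
#' [rpkm_like()] value of the support.  References are sorted by score
#' descending, ties broken lexicographically on source read id and
#' flagged.
#'
#' @param refs list of `virtual_reference` objects.
#' @param scoring_mates data.frame with `read_id`, `seq` — the mates of
#'   the initially VDJ-unmapped reads.
#' @param total_reads library size.
#' @param min_identity,min_length see [align_local()].
#' @return data.frame of class `reference_table`: `source_read_id`,
#'   `v_name`, `d_name`, `j_name`, `support`, `score`, `tie`, span
#'   columns, `sequence`; attribute `alignments` holds the supporting
#'   local alignments (with a `ref` column).
#' @export
score_references <- function(refs, scoring_mates, total_reads,
                             min_identity = 0.95, min_length = 20) {
  if (length(refs) == 0L) stop("no references to score", call. = FALSE)
  seg <- data.frame(name = vapply(refs, `[[`, "", "source_read_id"),
                    seq = vapply(refs, `[[`, "", "sequence"),
                    subgroup = NA_character_, stringsAsFactors = FALSE)
  hits <- if (nrow(scoring_mates)) {
    align_local(scoring_mates$seq, seg, min_identity, min_length)
  } else {
    data.frame(mate = integer(), segment = character())
  }
  support <- vapply(seg$name, function(nm) {
    length(unique(scoring_mates$read_id[hits$mate[hits$segment == nm]]))
  }, 0L)
  out <- data.frame(
    source_read_id = seg$name,
    v_name = vapply(refs, `[[`, "", "v_name"),
    d_name = vapply(refs, `[[`, "", "d_name"),
    j_name = vapply(refs, `[[`, "", "j_name"),
    support = unname(support),
    score = rpkm_like(unname(support), total_reads),
    do.call(rbind, lapply(refs, function(r) as.data.frame(t(r$spans)))),
    core_start = vapply(refs, `[[`, 0L, "core_start"),
    core_end = vapply(refs, `[[`, 0L, "core_end"),
    sequence = seg$seq, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$source_read_id), , drop = FALSE]
  rownames(out) <- NULL
  out$tie <- duplicated(out$support) | duplicated(out$support,
                                                  fromLast = TRUE)
  if (nrow(hits)) hits$ref <- hits$segment
  attr(out, "alignments") <- hits
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Select the main-clone sequence
#'
#' @param scored a `reference_table` from [score_references()].
#' @return list with `reference` (top row) and `tie`.
#' @export
reconstruct_main_clone <- function(scored) {
  if (is.null(scored) || nrow(scored) == 0L) {
    stop("reconstruction impossible: no scored references", call. = FALSE)
  }
  list(reference = scored[1L, , drop = FALSE],
       tie = isTRUE(scored$tie[1L]))
}

#' Annotate junction insertions and deletions
#'
#' Compares a reconstructed sequence against the naive concatenation of
#' its germline V, D and J segments: deletions are the germline bases
#' missing at each recombining end (maximal-match convention), insertions
#' the junction bases not attributable to any of the three segments.
#' P nucleotides are part of the inserted strings (not distinguished from
#' N additions).
#'
#' @param sequence reconstructed nucleotide string.
#' @param v_seq,d_seq,j_seq germline segment sequences.
#' @param min_anchor minimum recognizable V prefix / J suffix (nt).
#' @return list with `inserted_vd`, `inserted_dj`, `deleted_v3`,
#'   `deleted_d5`, `deleted_d3`, `deleted_j5`.
#' @export
annotate_junctions <- function(sequence, v_seq, d_seq, j_seq,
                               min_anchor = 15) {
  vlen <- common_prefix_len(sequence, v_seq)
  jlen <- common_suffix_len(sequence, j_seq)
  if (vlen < min_anchor) {
    stop("V prefix unrecognizable (matched ", vlen, " < ", min_anchor,
         " nt)", call. = FALSE)
  }
  if (jlen < min_anchor) {
    stop("J suffix unrecognizable (matched ", jlen, " < ", min_anchor,
         " nt)", call. = FALSE)
  }
  # prefix and suffix claims must not overlap on short sequences
  jlen <- min(jlen, nchar(sequence) - vlen)
  middle <- substr(sequence, vlen + 1L, nchar(sequence) - jlen)
  lm <- nchar(middle)
  ld <- nchar(d_seq)
  # best placement of a contiguous D substring within the middle region
  best <- list(len = 0L, pos = 0L, off = 0L)
  if (lm > 0L) {
    mv <- utf8ToInt(middle)
    dv <- utf8ToInt(d_seq)
    for (diag in (-lm + 1L):(ld - 1L)) {
      lo <- max(0L, -diag)
      hi <- min(lm, ld - diag)
      if (hi - lo <= best$len) next
      run <- 0L
      for (x in lo:(hi - 1L)) {
        if (mv[x + 1L] == dv[x + diag + 1L]) {
          run <- run + 1L
          if (run > best$len) {
            best <- list(len = run, pos = x - run + 1L,
                         off = x + diag - run + 1L)
          }
        } else {
          run <- 0L
        }
      }
    }
  }
  res <- list(
    inserted_vd = substr(middle, 1L, best$pos),
    inserted_dj = substr(middle, best$pos + best$len + 1L, lm),
    deleted_v3 = nchar(v_seq) - vlen,
    deleted_d5 = if (best$len > 0L) best$off else ld,
    deleted_d3 = if (best$len > 0L) ld - best$off - best$len else 0L,
    deleted_j5 = nchar(j_seq) - jlen)
  reassembled <- paste0(
    substr(v_seq, 1L, nchar(v_seq) - res$deleted_v3), res$inserted_vd,
    substr(d_seq, res$deleted_d5 + 1L, ld - res$deleted_d3),
    res$inserted_dj, substr(j_seq, res$deleted_j5 + 1L, nchar(j_seq)))
  if (!identical(reassembled, sequence)) {
    stop("internal error: junction annotation invariant violated",
         call. = FALSE)
  }
  res
}

#' Per-base coverage of a reference by its supporting alignments
#'
#' @param ref one-row slice of a `reference_table`.
#' @param alignments alignment data.frame (attribute `alignments` of the
#'   table) with `ref`, `read_start`, `read_end`, `seg_start`, `seg_end`.
#' @return integer vector of per-base depth over the reference.
#' @export
coverage_profile <- function(ref, alignments) {
  L <- nchar(ref$sequence)
  depth <- integer(L)
  h <- alignments[alignments$ref == ref$source_read_id, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    idx <- (h$seg_start[i] + 1L):h$seg_end[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

#' Write a depth track as BedGraph
#'
#' @param depth integer vector from [coverage_profile()].
#' @param name reference name (BedGraph chrom field).
#' @param path output file.
#' @export
write_bedgraph <- function(depth, name, path) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = name, start = starts, end = ends,
                   value = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the main-clone sequence as FASTA
#'
#' The header carries the V/D/J assignment and the junction annotation.
#'
#' @param ref one-row slice of a `reference_table`.
#' @param annotation output of [annotate_junctions()].
#' @param path output FASTA file.
#' @export
write_main_clone_fasta <- function(ref, annotation, path) {
  hdr <- sprintf(
    "main_clone %s|%s|%s del_v3=%d del_d5=%d del_d3=%d del_j5=%d ins_vd=%s ins_dj=%s src=%s",
    ref$v_name, ref$d_name, ref$j_name, annotation$deleted_v3,
    annotation$deleted_d5, annotation$deleted_d3, annotation$deleted_j5,
    ifelse(nzchar(annotation$inserted_vd), annotation$inserted_vd, "-"),
    ifelse(nzchar(annotation$inserted_dj), annotation$inserted_dj, "-"),
    ref$source_read_id)
  ss <- Biostrings::DNAStringSet(ref$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
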