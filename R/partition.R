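#' Mismatch-bounded end-to-end alignment of mates
#'
#' Places whole mates on reference contigs (both strands) allowing at most
#' `max_mismatches` mismatches.  Only placements in the best observed
#' mismatch stratum are reported, at most `max_report` of them; a mate
#' with more than `max_report` placements in its best stratum receives
#' the suppression marker and is treated as unaligned downstream.  Contigs
#' shorter than a mate are skipped for that mate.
#'
#' @param mates character vector of mate sequences (optionally named).
#' @param reference named character vector of reference contig sequences.
#' @param max_mismatches maximum mismatches per placement (default 2).
#' @param max_report maximum reported placements per mate (default 10).
#' @return list with `status` (integer per mate: 0 = no placement,
#'   1 = reported, 2 = suppressed) and `hits` (data.frame `mate`,
#'   `target`, `start` (0-based), `strand`, `mismatches`).
#' @export
align_ungapped <- function(mates, reference, max_mismatches = 2,
                           max_report = 10) {
  if (length(reference) == 0L) stop("empty reference", call. = FALSE)
  if (is.null(names(reference))) {
    names(reference) <- paste0("contig", seq_along(reference))
  }
  k <- run_guarantee_endtoend(min(nchar(mates)), max_mismatches)
  k <- max(1L, min(31L, k))
  res <- cpp_ungapped_scan(unname(mates), unname(reference),
                           as.integer(max_mismatches),
                           as.integer(max_report), as.integer(k))
  hits <- res$hits
  hits$target <- names(reference)[hits$ref]
  hits$strand <- ifelse(hits$strand > 0, "+", "-")
  if (!is.null(names(mates))) hits$mate_id <- names(mates)[hits$mate]
  list(status = res$status, hits = hits)
}

#' Partition read pairs into VDJ-unmapped / VDJ-mapped / discarded
#'
#' Reproduces the two input datasets of the clone-identification stage: a
#' pair is `vdj_unmapped` iff neither mate receives a reported end-to-end
#' placement (suppressed multimappers count as unaligned); otherwise it is
#' `vdj_mapped` iff at least one reported placement overlaps a locus
#' interval, else `discarded`.  The three sets are disjoint and cover the
#' input.  With `unmapped_mode = "either"` a pair with at least one
#' unaligned mate joins `vdj_unmapped` (takes precedence over the mapped
#' test).
#'
#' @param reads data.frame with `read_id`, `mate1_seq`, `mate2_seq`.
#' @param reference named character vector of contigs (a genome slice, or
#'   simply the germline segment sequences standing in for the locus).
#' @param locus optional data.frame (`contig`, `start`, `end`; 0-based
#'   half-open) of IGH V(D)J locus intervals; `NULL` treats every whole
#'   contig as locus.
#' @param max_mismatches,max_report see [align_ungapped()].
#' @param unmapped_mode `"both"` (default: both mates unaligned) or
#'   `"either"`.
#' @return object of class `partition_result`: list of read-id vectors
#'   `vdj_unmapped`, `vdj_mapped`, `discarded`, with attribute
#'   `unmapped_mates` (data.frame `read_id`, `mate` of individually
#'   unaligned mates).
#' @export
partition_reads <- function(reads, reference, locus = NULL,
                            max_mismatches = 2, max_report = 10,
                            unmapped_mode = c("both", "either")) {
  unmapped_mode <- match.arg(unmapped_mode)
  n <- nrow(reads)
  mates <- c(reads$mate1_seq, reads$mate2_seq)
  al <- align_ungapped(mates, reference, max_mismatches, max_report)
  aligned <- al$status == 1L
  m1 <- aligned[seq_len(n)]
  m2 <- aligned[n + seq_len(n)]

  in_locus <- rep(FALSE, 2L * n)
  if (nrow(al$hits)) {
    h <- al$hits
    if (is.null(locus)) {
      ok <- rep(TRUE, nrow(h))
    } else {
      len <- nchar(mates)[h$mate]
      ok <- rep(FALSE, nrow(h))
      for (i in seq_len(nrow(locus))) {
        ok <- ok | (h$target == locus$contig[i] &
                    h$start < locus$end[i] &
                    h$start + len > locus$start[i])
      }
    }
    in_locus[unique(h$mate[ok])] <- TRUE
  }
  pair_locus <- in_locus[seq_len(n)] | in_locus[n + seq_len(n)]

  unmapped <- if (unmapped_mode == "both") !m1 & !m2 else !m1 | !m2
  mapped <- !unmapped & pair_locus
  discarded <- !unmapped & !mapped

  res <- list(vdj_unmapped = reads$read_id[unmapped],
              vdj_mapped = reads$read_id[mapped],
              discarded = reads$read_id[discarded])
  class(res) <- "partition_result"
  attr(res, "unmapped_mates") <- data.frame(
    read_id = c(reads$read_id[!m1], reads$read_id[!m2]),
    mate = c(rep(1L, sum(!m1)), rep(2L, sum(!m2))),
    stringsAsFactors = FALSE)
  validate_partition(res, reads$read_id)
  res
}

# disjoint-cover invariant, asserted on every run
validate_partition <- function(res, input_ids) {
  all_ids <- c(res$vdj_unmapped, res$vdj_mapped, res$discarded)
  if (anyDuplicated(all_ids) || !setequal(all_ids, input_ids) ||
      length(all_ids) != length(input_ids)) {
    stop("internal error: partition is not a disjoint cover of the input",
         call. = FALSE)
  }
  invisible(res)
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "partition_result: %d vdj_unmapped, %d vdj_mapped, %d discarded\n",
    length(x$vdj_unmapped), length(x$vdj_mapped), length(x$discarded)))
  invisible(x)
}

# reference-space width of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Ingest externally produced alignments (SAM/BAM)
#'
#' Substitute for the internal partitioning aligner: classifies pairs with
#' the same contract as [partition_reads()] using the file's alignment
#' flags.  The locus overlap test is half-open interval intersection.
#' Unpaired records are discarded with a warning.
#'
#' @param path SAM or BAM file (SAM text is converted on the fly).
#' @param locus data.frame (`contig`, `start`, `end`; 0-based half-open).
#' @param unmapped_mode see [partition_reads()].
#' @return a `partition_result`.
#' @export
ingest_sam <- function(path, locus, unmapped_mode = c("both", "either")) {
  unmapped_mode <- match.arg(unmapped_mode)
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  if (length(rec$qname) == 0L) stop("no records in ", path, call. = FALSE)
  flag <- rec$flag
  primary <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  df <- data.frame(qname = rec$qname[primary],
                   flag = flag[primary],
                   rname = as.character(rec$rname)[primary],
                   pos = rec$pos[primary],
                   cigar = rec$cigar[primary], stringsAsFactors = FALSE)
  df$mate <- ifelse(bitwAnd(df$flag, 0x80) > 0, 2L, 1L)
  df$unmapped <- bitwAnd(df$flag, 0x4) > 0
  df$paired <- bitwAnd(df$flag, 0x1) > 0

  cnt <- table(df$qname)
  complete <- names(cnt)[cnt == 2L]
  orphans <- setdiff(unique(df$qname), complete)
  bad_pairing <- !df$paired
  if (length(orphans) || any(bad_pairing)) {
    orphans <- union(orphans, unique(df$qname[bad_pairing]))
    complete <- setdiff(complete, orphans)
    warning(length(orphans), " read(s) without a resolvable mate pair ",
            "were discarded", call. = FALSE)
  }
  df <- df[df$qname %in% complete, , drop = FALSE]

  overlap <- rep(FALSE, nrow(df))
  idx <- which(!df$unmapped & !is.na(df$pos))
  if (length(idx)) {
    st <- df$pos[idx] - 1L
    en <- st + cigar_ref_width(df$cigar[idx])
    for (i in seq_len(nrow(locus))) {
      overlap[idx] <- overlap[idx] |
        (df$rname[idx] == locus$contig[i] & st < locus$end[i] &
         en > locus$start[i])
    }
  }
  unmapped_by <- tapply(df$unmapped, df$qname, all)
  any_unmapped_by <- tapply(df$unmapped, df$qname, any)
  locus_by <- tapply(overlap, df$qname, any)
  qn <- names(unmapped_by)

  unm <- if (unmapped_mode == "both") unmapped_by else any_unmapped_by
  mapped <- !unm & locus_by
  disc <- !unm & !mapped

  res <- list(vdj_unmapped = qn[unm],
              vdj_mapped = qn[mapped],
              discarded = c(qn[disc], orphans))
  class(res) <- "partition_result"
  um <- df[df$unmapped, c("qname", "mate")]
  attr(res, "unmapped_mates") <- data.frame(
    read_id = um$qname, mate = um$mate, stringsAsFactors = FALSE)
  validate_partition(res, union(qn, orphans))
  res
}

#' Load locus intervals from BED
#'
#' @param path BED file (0-based half-open, as BED always is).
#' @return data.frame with `contig`, `start`, `end`.
#' @export
load_locus_bed <- function(path) {
  d <- as.data.frame(rtracklayer::import(path, format = "BED"))
  data.frame(contig = as.character(d$seqnames), start = d$start - 1L,
             end = d$end, stringsAsFactors = FALSE)
}

#' Write a partition result as id-list files plus a summary TSV
#'
#' @param res a `partition_result`.
#' @param dir output directory.
#' @export
write_partition <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (set in c("vdj_unmapped", "vdj_mapped", "discarded")) {
    writeLines(res[[set]], file.path(dir, paste0(set, ".ids")))
  }
  summary <- data.frame(
    set = c("vdj_unmapped", "vdj_mapped", "discarded"),
    n = c(length(res$vdj_unmapped), length(res$vdj_mapped),
          length(res$discarded)))
  write.table(summary, file.path(dir, "partition_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
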