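#' Pipeline configuration
#'
#' Collects the stage parameters: the end-to-end aligner's mismatch cap
#' (2) and placement cap (10), the D-seed length (10 nt), the number of
#' top couples taken into D calling (5), the local-alignment identity and
#' length floors, and the library size used by the normalised scores.
#'
#' @param max_mismatches end-to-end mismatch cap.
#' @param max_report end-to-end placement cap (suppression above).
#' @param min_seed exact D seed length in nt.
#' @param top_n_couples couples taken forward to D identification.
#' @param min_identity,min_length local-alignment floors.
#' @param total_reads library size (input read pairs); filled from the
#'   input when `NULL`.
#' @param unmapped_mode pair-level unmapped rule, see [partition_reads()].
#' @param score_reads which reads score virtual references:
#'   `"unmapped_mates"` (pairs with at least one individually unaligned
#'   mate; the unaligned mates are re-mapped) or `"unmapped_pairs"`
#'   (pairs of the `vdj_unmapped` partition class only).
#' @param seed integer seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(max_mismatches = 2, max_report = 10,
                            min_seed = 10, top_n_couples = 5,
                            min_identity = 0.95, min_length = 20,
                            total_reads = NULL,
                            unmapped_mode = c("both", "either"),
                            score_reads = c("unmapped_mates",
                                            "unmapped_pairs"),
                            seed = 1) {
  cfg <- list(max_mismatches = as.integer(max_mismatches),
              max_report = as.integer(max_report),
              min_seed = as.integer(min_seed),
              top_n_couples = as.integer(top_n_couples),
              min_identity = min_identity,
              min_length = as.integer(min_length),
              total_reads = total_reads,
              unmapped_mode = match.arg(unmapped_mode),
              score_reads = match.arg(score_reads),
              seed = as.integer(seed))
  stopifnot(cfg$max_mismatches >= 0, cfg$max_report >= 1,
            cfg$min_seed >= 1, cfg$top_n_couples >= 1,
            cfg$min_identity > 0, cfg$min_identity <= 1,
            cfg$min_length >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Monoclonality summary
#'
#' Emits the top-1/top-2 supporting-read ratio at allele and subgroup
#' level plus the top-5 table — the per-sample statistic used to decide
#' whether one clone dominates the lymphocyte population.
#'
#' @param couples allele-level `vj_couples`.
#' @param subgroup_couples subgroup-level table from
#'   [aggregate_by_subgroup()].
#' @return list with `ratio_allele`, `ratio_subgroup` (`Inf` when a
#'   single couple exists), `tie_allele`, `tie_subgroup`, `top5`.
#' @export
report_monoclonality <- function(couples, subgroup_couples) {
  ma <- main_clone(couples)
  ms <- main_clone(subgroup_couples)
  list(ratio_allele = ma$ratio, ratio_subgroup = ms$ratio,
       tie_allele = ma$tie, tie_subgroup = ms$tie,
       top5 = utils::head(couples[, setdiff(names(couples),
                                            "supporting_reads")], 5L))
}

#' Run the full clone-identification and reconstruction pipeline
#'
#' Executes partition (or SAM ingestion), VJ-encompassing detection,
#' couple counting and ranking, D identification, virtual-reference
#' construction and scoring, main-clone selection and junction
#' annotation; optionally writes the report bundle (clone and subgroup
#' TSVs, main-clone FASTA, references TSV, depth BedGraph, partition id
#' lists, JSON manifest) to `outdir`.
#'
#' @param reads read table (`read_id`, `mate1_seq`, `mate2_seq`) or
#'   `NULL` when `mate1_fastq`/`mate2_fastq` are given.
#' @param germline a `germline_set` or `list(v=, d=, j=)` of FASTA paths.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for the report bundle.
#' @param mate1_fastq,mate2_fastq optional FASTQ inputs.
#' @param sam optional SAM/BAM file replacing the internal partition
#'   aligner (requires `locus`).
#' @param locus optional locus intervals (data.frame or BED path).
#' @param reference optional named character vector of contigs for the
#'   internal partitioner; defaults to the germline segment sequences
#'   standing in for the locus.
#' @return list of class `ighclone_result` with elements `partition`,
#'   `encompassing`, `couples`, `subgroup_couples`, `clones`,
#'   `monoclonality`, `references`, `main`, `annotation`, `manifest`.
#' @export
run_pipeline <- function(reads = NULL, germline, config = pipeline_config(),
                         outdir = NULL, mate1_fastq = NULL,
                         mate2_fastq = NULL, sam = NULL, locus = NULL,
                         reference = NULL) {
  t0 <- proc.time()[["elapsed"]]
  # --- inputs -------------------------------------------------------------
  digests <- list()
  if (is.list(germline) && !inherits(germline, "germline_set")) {
    for (p in unlist(germline)) {
      if (!file.exists(p)) {
        stop("configuration error: germline file not found: ", p,
             call. = FALSE)
      }
    }
    digests$germline <- unname(tools::md5sum(unlist(germline)))
    germline <- load_germline_set(germline$v, germline$d, germline$j)
  }
  if (!inherits(germline, "germline_set")) {
    stop("configuration error: `germline` must be a germline_set or a ",
         "list of FASTA paths", call. = FALSE)
  }
  if (is.null(reads)) {
    if (is.null(mate1_fastq) || is.null(mate2_fastq)) {
      stop("configuration error: provide `reads` or both FASTQ paths",
           call. = FALSE)
    }
    digests$fastq <- unname(tools::md5sum(c(mate1_fastq, mate2_fastq)))
    reads <- read_fastq_pair(mate1_fastq, mate2_fastq)
  }
  if (is.character(locus)) locus <- load_locus_bed(locus)
  total_reads <- config$total_reads %||% nrow(reads)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- partition ----------------------------------------------------------
  part <- stage("partition", {
    if (!is.null(sam)) {
      if (is.null(locus)) {
        stop("SAM ingestion requires locus intervals", call. = FALSE)
      }
      ingest_sam(sam, locus, config$unmapped_mode)
    } else {
      ref <- reference %||% with(
        rbind(germline$v, germline$d, germline$j),
        stats::setNames(seq, name))
      partition_reads(reads, ref, locus, config$max_mismatches,
                      config$max_report, config$unmapped_mode)
    }
  })

  # --- VJ couples (mapped + unmapped datasets feed the detection) ---------
  vdj_ids <- c(part$vdj_unmapped, part$vdj_mapped)
  sub <- reads[reads$read_id %in% vdj_ids, , drop = FALSE]
  enc <- stage("vjcall", find_encompassing_reads(
    sub, germline$v, germline$j, config$min_identity, config$min_length))
  couples <- stage("vjcall", count_vj_couples(enc, total_reads))
  if (nrow(couples) == 0L) {
    stop("no rearrangement detected", call. = FALSE)
  }
  subgroup <- aggregate_by_subgroup(couples, total_reads)
  mono <- report_monoclonality(couples, subgroup)

  # --- D identification ---------------------------------------------------
  clones <- stage("dcall", call_d_alleles(
    couples, enc, sub, germline$d, config$top_n_couples, config$min_seed))
  pm <- attr(clones, "partial_mates")
  dh <- attr(clones, "d_hits")

  # --- reconstruction -----------------------------------------------------
  bridging <- stage("reconstruct", select_bridging_reads(
    couples[1L, , drop = FALSE], pm, dh))
  scoring_mates <- scoring_mate_table(reads, part, config$score_reads)
  refs <- stage("reconstruct", build_references(
    bridging, sub, enc, pm, dh, germline))
  main <- NULL
  scored <- NULL
  annotation <- NULL
  if (length(refs)) {
    scored <- stage("reconstruct", score_references(
      refs, scoring_mates, total_reads, config$min_identity,
      config$min_length))
    main <- reconstruct_main_clone(scored)
    annotation <- stage("reconstruct", annotate_junctions(
      main$reference$sequence,
      germline$v$seq[match(main$reference$v_name, germline$v$name)],
      germline$d$seq[match(main$reference$d_name, germline$d$name)],
      germline$j$seq[match(main$reference$j_name, germline$j$name)]))
  }

  manifest <- list(
    package = "ighclone",
    version = as.character(packageVersion("ighclone")),
    seed = config$seed,
    total_reads = total_reads,
    config = config[setdiff(names(config), "total_reads")],
    input_digests = digests,
    counters = list(
      n_pairs = nrow(reads),
      vdj_unmapped = length(part$vdj_unmapped),
      vdj_mapped = length(part$vdj_mapped),
      discarded = length(part$discarded),
      encompassing = nrow(enc$v_mate),
      ambiguous = length(enc$ambiguous),
      couples = nrow(couples),
      bridging = nrow(bridging),
      references = length(refs),
      scoring_mates = nrow(scoring_mates)))

  res <- list(partition = part, encompassing = enc, couples = couples,
              subgroup_couples = subgroup, clones = clones,
              monoclonality = mono, references = scored, main = main,
              annotation = annotation, manifest = manifest,
              elapsed = proc.time()[["elapsed"]] - t0)
  class(res) <- "ighclone_result"
  if (!is.null(outdir)) write_report_bundle(res, outdir)
  res
}

# mates scoring the virtual references; see pipeline_config(score_reads=)
scoring_mate_table <- function(reads, part, score_reads) {
  if (score_reads == "unmapped_pairs") {
    sel <- reads[reads$read_id %in% part$vdj_unmapped, , drop = FALSE]
    data.frame(read_id = rep(sel$read_id, 2L),
               seq = c(sel$mate1_seq, sel$mate2_seq),
               stringsAsFactors = FALSE)
  } else {
    um <- attr(part, "unmapped_mates")
    ridx <- match(um$read_id, reads$read_id)
    data.frame(read_id = um$read_id,
               seq = ifelse(um$mate == 1L, reads$mate1_seq[ridx],
                            reads$mate2_seq[ridx]),
               stringsAsFactors = FALSE)
  }
}

#' @export
print.ighclone_result <- function(x, ...) {
  cat("ighclone result\n")
  cat(sprintf("  pairs: %d (unmapped %d / mapped %d / discarded %d)\n",
              x$manifest$counters$n_pairs,
              x$manifest$counters$vdj_unmapped,
              x$manifest$counters$vdj_mapped,
              x$manifest$counters$discarded))
  cat(sprintf("  encompassing reads: %d, couples: %d\n",
              x$manifest$counters$encompassing,
              x$manifest$counters$couples))
  top <- x$clones[1L, ]
  cat(sprintf("  main clone: %s / %s / %s (count %d, ratio %.2f)\n",
              top$v_name, ifelse(is.na(top$d_name), "?", top$d_name),
              top$j_name, top$count, x$monoclonality$ratio_allele))
  if (!is.null(x$main)) {
    cat(sprintf("  reconstructed sequence: %d nt (support %d)\n",
                nchar(x$main$reference$sequence),
                x$main$reference$support))
  }
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' @param res an `ighclone_result`.
#' @param outdir output directory (created if needed).
#' @export
write_report_bundle <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_partition(res$partition, outdir)

  ct <- res$clones
  write.table(ct, file.path(outdir, "clone_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sg <- res$subgroup_couples[, setdiff(names(res$subgroup_couples),
                                       "supporting_reads")]
  write.table(sg, file.path(outdir, "subgroup_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(res$references)) {
    rt <- res$references[, setdiff(names(res$references), "sequence")]
    write.table(rt, file.path(outdir, "references.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$main)) {
    write_main_clone_fasta(res$main$reference, res$annotation,
                           file.path(outdir, "main_clone.fasta"))
    depth <- coverage_profile(res$main$reference,
                              attr(res$references, "alignments"))
    write_bedgraph(depth, res$main$reference$source_read_id,
                   file.path(outdir, "coverage.bedgraph"))
  }
  jsonlite::write_json(res$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(outdir)
}
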