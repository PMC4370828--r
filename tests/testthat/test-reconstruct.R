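# Hand-built hit tables exercise the assembly arithmetic on toy germline
# segments with known truth (coordinates composed by hand).

toy_enc <- function(hits, v_mate_df) {
  res <- list(hits = hits, v_mate = v_mate_df, ambiguous = character(0))
  class(res) <- "encompassing_reads"
  res
}

hit_row <- function(read_id, mate, role, segment, strand, rs, re, ss, se) {
  data.frame(read_id = read_id, mate = mate, role = role,
             segment = segment, subgroup = sub("[-*].*$", "", segment),
             strand = strand, read_start = rs, read_end = re,
             seg_start = ss, seg_end = se, score = re - rs,
             length = re - rs, matches = re - rs, identity = 1,
             stringsAsFactors = FALSE)
}

d_hit_row <- function(mate_idx, segment, strand, rs, re, ss, se) {
  data.frame(mate = mate_idx, segment = segment, strand = strand,
             read_start = rs, read_end = re, seg_start = ss, seg_end = se,
             matches = re - rs, length = re - rs, score = re - rs,
             tie = FALSE, stringsAsFactors = FALSE)
}

test_that("bridging reads split into overlap and non-overlap cases", {
  pm <- data.frame(read_id = c("r1", "r1", "r2", "r2", "r3"),
                   mate = c(1L, 2L, 1L, 2L, 1L), seq = "N",
                   stringsAsFactors = FALSE)
  dh <- rbind(
    d_hit_row(1L, "IGHD1-1*01", "+", 0, 6, 0, 6),    # r1 mates overlap in D
    d_hit_row(2L, "IGHD1-1*01", "-", 0, 5, 4, 9),
    d_hit_row(3L, "IGHD1-1*01", "+", 0, 4, 0, 4),    # r2 gap [4, 6)
    d_hit_row(4L, "IGHD1-1*01", "-", 0, 4, 6, 10),
    d_hit_row(5L, "IGHD1-1*01", "+", 0, 4, 0, 4))    # r3: one mate only
  couple <- data.frame(v_name = "IGHV1-1*01", j_name = "IGHJ1*01",
                       stringsAsFactors = FALSE)
  couple$supporting_reads <- list(c("r1", "r2", "r3"))
  br <- select_bridging_reads(couple, pm, dh)
  expect_equal(br$read_id, c("r1", "r2"))
  expect_equal(br$case, c("overlap", "non_overlap"))
})

test_that("overlap-case references reproduce the composed transcript", {
  # V=ACGTACGT, D=TGAT, J=CCCCCC; an identifiable composition: junction
  # bases differ from the adjacent germline continuation bases
  gl <- germline_set(v = c("IGHV1-1*01" = "ACGTACGT"),
                     d = c("IGHD1-1*01" = "TGAT"),
                     j = c("IGHJ1*01" = "CCCCCC"))
  # event: trims (2,1,1,2), n1=AA, n2=A -> transcript ACGTACAAGAACCCC
  reads <- data.frame(read_id = "r1", mate1_seq = "ACGTACAAGAAC",
                      mate2_seq = revcomp("TACAAGAACCCC"),
                      stringsAsFactors = FALSE)
  enc <- toy_enc(rbind(
    hit_row("r1", 1L, "V", "IGHV1-1*01", "+", 0, 6, 0, 6),
    hit_row("r1", 2L, "J", "IGHJ1*01", "-", 0, 4, 2, 6)),
    data.frame(read_id = "r1", v_mate = 1L, stringsAsFactors = FALSE))
  pm <- data.frame(read_id = c("r1", "r1"), mate = c(1L, 2L),
                   seq = c(reads$mate1_seq, reads$mate2_seq),
                   stringsAsFactors = FALSE)
  dh <- rbind(d_hit_row(1L, "IGHD1-1*01", "+", 8, 10, 1, 3),
              d_hit_row(2L, "IGHD1-1*01", "-", 5, 7, 1, 3))
  ref <- build_virtual_reference("r1", reads, enc, pm, dh, gl)
  expect_s3_class(ref, "virtual_reference")
  expect_equal(ref$sequence, "ACGTACAAGAACCCC")
  expect_equal(unname(ref$spans),
               c(6L, 2L, 2L, 1L, 4L))  # V | AA | GA | A | CCCC
  expect_equal(sum(ref$spans), nchar(ref$sequence))
  expect_equal(c(ref$core_start, ref$core_end), c(0L, 15L))
  # junction annotation recovers the event exactly
  ann <- annotate_junctions(ref$sequence, "ACGTACGT", "TGAT", "CCCCCC",
                            min_anchor = 4)
  expect_equal(ann[c("deleted_v3", "deleted_d5", "deleted_d3",
                     "deleted_j5")],
               list(deleted_v3 = 2L, deleted_d5 = 1L, deleted_d3 = 1L,
                    deleted_j5 = 2L))
  expect_equal(ann$inserted_vd, "AA")
  expect_equal(ann$inserted_dj, "A")
})

test_that("non-overlap references germline-fill the uncovered D interior", {
  gl <- germline_set(v = c("IGHV1-1*01" = "ACGTACGT"),
                     d = c("IGHD1-1*01" = "TTATT"),
                     j = c("IGHJ1*01" = "CCCCCC"))
  # transcript ACGTAC|GG|TTATT|A|CCCC; mate1 sees D[0,2), mate2 D[3,5)
  reads <- data.frame(read_id = "r1", mate1_seq = "ACGTACGGTT",
                      mate2_seq = revcomp("TTACCCC"),
                      stringsAsFactors = FALSE)
  enc <- toy_enc(rbind(
    hit_row("r1", 1L, "V", "IGHV1-1*01", "+", 0, 6, 0, 6),
    hit_row("r1", 2L, "J", "IGHJ1*01", "-", 0, 4, 2, 6)),
    data.frame(read_id = "r1", v_mate = 1L, stringsAsFactors = FALSE))
  pm <- data.frame(read_id = c("r1", "r1"), mate = c(1L, 2L),
                   seq = c(reads$mate1_seq, reads$mate2_seq),
                   stringsAsFactors = FALSE)
  dh <- rbind(d_hit_row(1L, "IGHD1-1*01", "+", 8, 10, 0, 2),
              d_hit_row(2L, "IGHD1-1*01", "-", 5, 7, 3, 5))
  ref <- build_virtual_reference("r1", reads, enc, pm, dh, gl)
  expect_equal(ref$sequence, "ACGTACGGTTATTACCCC")
  expect_equal(ref$case, "non_overlap")
  # the interior base D[2,3) = "A" came from the germline, not a read
  expect_equal(substr(ref$sequence, 11, 11), "A")
})

test_that("zero-length junctions reduce to the V+D+J concatenation", {
  gl <- toy_germline()
  reads <- data.frame(read_id = "r1", mate1_seq = "ACGTACGTTT",
                      mate2_seq = revcomp("TTTTCCCCCC"),
                      stringsAsFactors = FALSE)
  enc <- toy_enc(rbind(
    hit_row("r1", 1L, "V", "IGHV1-1*01", "+", 0, 8, 0, 8),
    hit_row("r1", 2L, "J", "IGHJ1*01", "-", 0, 6, 0, 6)),
    data.frame(read_id = "r1", v_mate = 1L, stringsAsFactors = FALSE))
  pm <- data.frame(read_id = c("r1", "r1"), mate = c(1L, 2L),
                   seq = c(reads$mate1_seq, reads$mate2_seq),
                   stringsAsFactors = FALSE)
  dh <- rbind(d_hit_row(1L, "IGHD1-1*01", "+", 8, 10, 0, 2),
              d_hit_row(2L, "IGHD1-1*01", "-", 6, 10, 0, 4))
  ref <- build_virtual_reference("r1", reads, enc, pm, dh, gl)
  expect_equal(ref$sequence, "ACGTACGTTTTTCCCCCC")
  expect_equal(unname(ref$spans), c(8L, 0L, 4L, 0L, 6L))
  ann <- annotate_junctions(ref$sequence, "ACGTACGT", "TTTT", "CCCCCC",
                            min_anchor = 4)
  expect_equal(unlist(ann[3:6], use.names = FALSE), c(0L, 0L, 0L, 0L))
  expect_equal(ann$inserted_vd, "")
  expect_equal(ann$inserted_dj, "")
})

test_that("inconsistent reads are skipped with a reason", {
  gl <- toy_germline()
  reads <- data.frame(read_id = "r1", mate1_seq = "ACGTACGGTTAC",
                      mate2_seq = revcomp("TACGGTTACCCC"),
                      stringsAsFactors = FALSE)
  enc <- toy_enc(rbind(
    hit_row("r1", 1L, "V", "IGHV1-1*01", "+", 0, 6, 0, 6),
    hit_row("r1", 2L, "J", "IGHJ1*01", "-", 0, 4, 2, 6)),
    data.frame(read_id = "r1", v_mate = 1L, stringsAsFactors = FALSE))
  pm <- data.frame(read_id = c("r1", "r1"), mate = c(1L, 2L),
                   seq = c(reads$mate1_seq, reads$mate2_seq),
                   stringsAsFactors = FALSE)
  # D hit on the V mate in the opposite orientation -> skip
  dh_bad <- rbind(d_hit_row(1L, "IGHD1-1*01", "-", 8, 10, 1, 3),
                  d_hit_row(2L, "IGHD1-1*01", "-", 5, 7, 1, 3))
  r <- build_virtual_reference("r1", reads, enc, pm, dh_bad, gl)
  expect_s3_class(r, "skipped_read")
  expect_match(r$reason, "orientation")
  # a small V/D overlap on the read is clipped at the D boundary and the
  # overlapping bases stay read-derived
  dh_clip <- rbind(d_hit_row(1L, "IGHD1-1*01", "+", 5, 7, 1, 3),
                   d_hit_row(2L, "IGHD1-1*01", "-", 5, 7, 1, 3))
  r2 <- build_virtual_reference("r1", reads, enc, pm, dh_clip, gl)
  expect_s3_class(r2, "virtual_reference")
  expect_equal(unname(r2$spans[["VD_junction"]]), 0L)
  # a D hit swallowing the whole V alignment is a negative junction
  dh_neg <- rbind(d_hit_row(1L, "IGHD1-1*01", "+", 0, 2, 1, 3),
                  d_hit_row(2L, "IGHD1-1*01", "-", 5, 7, 1, 3))
  r3 <- build_virtual_reference("r1", reads, enc, pm, dh_neg, gl)
  expect_s3_class(r3, "skipped_read")
  expect_match(r3$reason, "junction")
})

test_that("simulated truth round-trips through junction annotation", {
  for (seed in c(5, 9, 13)) {
    s <- simulate_sample(seed, n_pairs = 10, n_background = 0,
                         error_rate = 0)
    ev <- s$main_event
    gl <- s$germline
    ann <- annotate_junctions(
      ev$transcript,
      gl$v$seq[match(ev$v_name, gl$v$name)],
      gl$d$seq[match(ev$d_name, gl$d$name)],
      gl$j$seq[match(ev$j_name, gl$j$name)])
    expect_equal(ann$deleted_v3, ev$trim_v3)
    expect_equal(ann$deleted_d5, ev$trim_d5)
    expect_equal(ann$deleted_d3, ev$trim_d3)
    expect_equal(ann$deleted_j5, ev$trim_j5)
    expect_equal(ann$inserted_vd, paste0(ev$p_v, ev$n1_seq, ev$p_d5))
    expect_equal(ann$inserted_dj, paste0(ev$p_d3, ev$n2_seq, ev$p_j))
  }
})

test_that("reference scoring counts supporting pairs and breaks ties", {
  set.seed(40)
  seqs <- c(random_dna(200), random_dna(200))
  refs <- lapply(1:2, function(i) {
    r <- list(source_read_id = c("r2", "r1")[i], sequence = seqs[i],
              v_name = "IGHV1-1*01", d_name = "IGHD1-1*01",
              j_name = "IGHJ1*01",
              spans = c(V_part = 200L, VD_junction = 0L, D_part = 0L,
                        DJ_junction = 0L, J_part = 0L),
              core_start = 0L, core_end = 200L)
    class(r) <- "virtual_reference"
    r
  })
  mates <- data.frame(
    read_id = c("a", "a", "b", "c"),
    seq = c(substr(seqs[1], 1, 60), substr(seqs[1], 100, 160),
            substr(seqs[1], 50, 120), random_dna(60)),
    stringsAsFactors = FALSE)
  sc <- score_references(refs, mates, total_reads = 1000)
  expect_equal(sc$support, c(2L, 0L))           # pairs a and b; c aligns nowhere
  expect_equal(sc$score, c(2e6, 0))
  expect_equal(sc$source_read_id[1], "r2")
  # equal-support ties resolve by source read id and are flagged
  mates0 <- mates[4, , drop = FALSE]
  sc0 <- score_references(refs, mates0, total_reads = 1000)
  expect_equal(sc0$support, c(0L, 0L))
  expect_equal(sc0$source_read_id, c("r1", "r2"))
  expect_true(all(sc0$tie))
  top <- reconstruct_main_clone(sc0)
  expect_equal(top$reference$source_read_id, "r1")
  expect_true(top$tie)
})

test_that("coverage depth conserves the total aligned bases", {
  set.seed(41)
  seqs <- random_dna(150)
  r <- list(source_read_id = "r1", sequence = seqs,
            v_name = "IGHV1-1*01", d_name = "IGHD1-1*01",
            j_name = "IGHJ1*01",
            spans = c(V_part = 150L, VD_junction = 0L, D_part = 0L,
                      DJ_junction = 0L, J_part = 0L),
            core_start = 0L, core_end = 150L)
  class(r) <- "virtual_reference"
  mates <- data.frame(read_id = c("a", "b"),
                      seq = c(substr(seqs, 11, 60), substr(seqs, 41, 100)),
                      stringsAsFactors = FALSE)
  sc <- score_references(list(r), mates, total_reads = 100)
  al <- attr(sc, "alignments")
  depth <- coverage_profile(sc[1, ], al)
  expect_length(depth, 150)
  expect_equal(sum(depth), sum(al$seg_end - al$seg_start))
  # no reads -> all-zero track
  sc0 <- score_references(list(r), mates[0, ], total_reads = 100)
  d0 <- coverage_profile(sc0[1, ], attr(sc0, "alignments"))
  expect_true(all(d0 == 0))
  # bedgraph round-trip of the run-length encoding
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(depth, "r1", bg)
  tab <- read.delim(bg, header = FALSE)
  expect_equal(sum((tab$V3 - tab$V2) * tab$V4), sum(depth))
})

test_that("in a 90/10 mixture the top reference comes from the majority", {
  s <- simulate_sample(16, n_pairs = 2000, main_fraction = 0.9,
                       n_background = 1, error_rate = 0)
  res <- run_pipeline(s$reads, s$germline,
                      pipeline_config(total_reads = 2000))
  expect_false(is.null(res$main))
  r <- res$main$reference
  expect_equal(substr(r$sequence, r$core_start + 1, r$core_end),
               substr(s$main_event$transcript, r$core_start + 1,
                      r$core_end))
  # the majority-clone references outscore any background reference
  truth_ids <- s$truth$read_id[s$truth$clone_label == "main"]
  expect_true(r$source_read_id %in% truth_ids)
})
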