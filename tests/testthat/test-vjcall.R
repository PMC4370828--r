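test_that("local alignment honours identity and length floors", {
  set.seed(20)
  v <- random_dna(300)
  segs <- data.frame(name = "IGHV1-1*01", subgroup = "IGHV1", seq = v,
                     stringsAsFactors = FALSE)
  # mate equal to a 100-nt prefix: full-identity hit on [0, 100)
  h <- align_local(substr(v, 1, 100), segs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(c(h$seg_start, h$seg_end), c(0L, 100L))
  expect_equal(c(h$read_start, h$read_end), c(0L, 100L))
  expect_equal(h$strand, "+")

  # reverse-complemented mate: same segment interval, minus strand
  hr <- align_local(revcomp(substr(v, 41, 140)), segs)
  expect_equal(hr$strand, "-")
  expect_equal(c(hr$seg_start, hr$seg_end), c(40L, 140L))

  # a common stretch of 15 nt fails a 20-nt length floor
  m <- paste0(random_dna(40), substr(v, 101, 115), random_dna(45))
  expect_equal(nrow(align_local(m, segs, min_length = 20)), 0L)
  expect_equal(nrow(align_local(m, segs, min_length = 15))  , 1L)
})

test_that("alleles differing by one base in the span are both reported", {
  set.seed(21)
  a <- random_dna(300)
  b <- a
  substr(b, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, 150, 150))[1]
  segs <- data.frame(name = c("IGHV1-1*01", "IGHV1-1*02"),
                     subgroup = "IGHV1", seq = c(a, b),
                     stringsAsFactors = FALSE)
  mate <- substr(a, 101, 200)
  h <- align_local(mate, segs, min_identity = 0.95)
  expect_setequal(h$segment, c("IGHV1-1*01", "IGHV1-1*02"))
  # direct mismatch count: the second allele's best window keeps >= 0.95
  expect_true(all(h$identity >= 0.95))
  # the true source allele scores strictly higher
  expect_gt(h$score[h$segment == "IGHV1-1*01"],
            h$score[h$segment == "IGHV1-1*02"])
})

test_that("score ranking distinguishes segments at 99 percent similarity", {
  set.seed(22)
  a <- random_dna(300)
  b <- a
  for (p in c(50, 150, 250)) {  # 99% identity pair
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  }
  segs <- data.frame(name = c("IGHV9-1*01", "IGHV9-2*01"),
                     subgroup = "IGHV9", seq = c(a, b),
                     stringsAsFactors = FALSE)
  for (start in c(1, 81, 161, 201)) {
    mate <- substr(a, start, start + 99)
    h <- align_local(mate, segs)
    ha <- h[h$segment == "IGHV9-1*01", ]
    hb <- h[h$segment == "IGHV9-2*01", ]
    expect_gt(ha$score, if (nrow(hb)) max(hb$score) else -Inf)
  }
})

test_that("encompassing pairs need a V mate and a J mate on opposite mates", {
  set.seed(23)
  gl <- generate_synthetic_germline(n_v = 4, n_d = 2, n_j = 2, seed = 23)
  vseq <- gl$v$seq[1]
  jseq <- gl$j$seq[1]
  reads <- data.frame(
    read_id = c("enc", "vv", "jonly"),
    mate1_seq = c(substr(vseq, 1, 100), substr(vseq, 1, 100),
                  random_dna(100)),
    mate2_seq = c(revcomp(paste0(random_dna(50), jseq)),
                  revcomp(substr(vseq, 150, 249)),
                  revcomp(paste0(random_dna(50), jseq))),
    stringsAsFactors = FALSE)
  enc <- find_encompassing_reads(reads, gl$v, gl$j)
  expect_equal(enc$v_mate$read_id, "enc")
  expect_equal(enc$v_mate$v_mate, 1L)
  expect_setequal(unique(enc$hits$role), c("V", "J"))

  # a mate hitting two V alleles carries both hits into the record
  h <- enc$hits[enc$hits$role == "V", ]
  expect_true(all(c("01", "02") %in%
                  parse_segment_name(h$segment)$allele))
})

test_that("pairs supporting both orientations are ambiguous and excluded", {
  set.seed(24)
  v <- random_dna(300); j <- random_dna(60)
  gl <- germline_set(v = c("IGHV1-1*01" = v), d = c("IGHD1-1*01" = "TTTTTTTTTTTT"),
                     j = c("IGHJ1*01" = j))
  chimera <- paste0(substr(v, 1, 50), substr(j, 1, 30), random_dna(20))
  reads <- data.frame(read_id = "amb", mate1_seq = chimera,
                      mate2_seq = revcomp(chimera),
                      stringsAsFactors = FALSE)
  enc <- find_encompassing_reads(reads, gl$v, gl$j, min_length = 20)
  expect_equal(enc$ambiguous, "amb")
  expect_equal(nrow(enc$v_mate), 0L)
})

test_that("couple counting follows the once-per-read set semantics", {
  mk_hits <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      data.frame(read_id = r[[1]], role = r[[2]], segment = r[[3]],
                 subgroup = sub("-.*$", "", sub("\\*.*$", "", r[[3]])),
                 score = 10, stringsAsFactors = FALSE)
    }))
  }
  # one read supporting the same couple at two position pairs counts once
  enc1 <- list(hits = rbind(
    cbind(mk_hits(list("r1", "V", "IGHV1-1*01")), seg_start = 0),
    cbind(mk_hits(list("r1", "V", "IGHV1-1*01")), seg_start = 37),
    cbind(mk_hits(list("r1", "J", "IGHJ1*01")), seg_start = 0)))
  c1 <- count_vj_couples(enc1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$count, 1L)

  # a read supporting two couples counts once in each
  enc2 <- list(hits = mk_hits(list("r1", "V", "IGHV1-1*01"),
                              list("r1", "V", "IGHV2-1*01"),
                              list("r1", "J", "IGHJ1*01")))
  c2 <- count_vj_couples(enc2)
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$count, c(1L, 1L))
  expect_true(all(c2$tie))

  # empty input gives an empty table
  expect_equal(nrow(count_vj_couples(list(hits = NULL))), 0L)
})

test_that("couple counting equals the brute-force triple enumeration", {
  set.seed(25)
  v_names <- sprintf("IGHV%d-%d*01", rep(1:3, each = 3), rep(1:3, 3))
  j_names <- sprintf("IGHJ%d*01", 1:4)
  hits <- do.call(rbind, lapply(sprintf("r%03d", 1:300), function(rid) {
    nv <- sample(0:3, 1); nj <- sample(0:2, 1)
    if (nv == 0 || nj == 0) return(NULL)
    rbind(
      data.frame(read_id = rid, role = "V",
                 segment = sample(v_names, nv),
                 subgroup = "x", score = 1, stringsAsFactors = FALSE),
      data.frame(read_id = rid, role = "J",
                 segment = sample(j_names, nj),
                 subgroup = "x", score = 1, stringsAsFactors = FALSE))
  }))
  got <- count_vj_couples(list(hits = hits))
  want <- oracle_couples(hits)
  expect_equal(paste(got$v_name, got$j_name, sep = "|"), want$couple)
  expect_equal(got$count, want$count)
  # counts never exceed the number of contributing reads
  expect_true(all(got$count <= length(unique(hits$read_id))))
})

test_that("the normalised score follows count / total * 1e9 exactly", {
  expect_identical(rpkm_like(0, 1e6), 0)
  expect_identical(rpkm_like(2, 1e6), 2000)
  expect_error(rpkm_like(1, 0), "total_reads")
  expect_error(rpkm_like(5, 4), "count")
  # doubling the library halves every score; the ranking is unchanged
  counts <- c(50, 20, 7, 1)
  s1 <- rpkm_like(counts, 1e5)
  s2 <- rpkm_like(counts, 2e5)
  expect_equal(s1, 2 * s2)
  expect_equal(order(s1), order(s2))
  expect_equal(order(-s1), order(-counts))
})

test_that("subgroup aggregation unions supporting-read sets", {
  couples <- data.frame(
    v_name = c("IGHV2-70*11", "IGHV2-70*01", "IGHV3-1*01"),
    j_name = c("IGHJ4*02", "IGHJ4*02", "IGHJ4*02"),
    v_subgroup = c("IGHV2", "IGHV2", "IGHV3"),
    j_subgroup = "IGHJ4",
    count = c(2L, 2L, 1L), stringsAsFactors = FALSE)
  couples$supporting_reads <- list(c("a", "b"), c("b", "c"), "z")
  agg <- aggregate_by_subgroup(couples)
  expect_equal(agg$count[agg$v_subgroup == "IGHV2"], 3L)   # |{a,b,c}|
  expect_equal(agg$count[agg$v_subgroup == "IGHV3"], 1L)
  expect_equal(nrow(agg), 2L)
  # union never exceeds the number of encompassing reads (union bound)
  expect_true(all(agg$count <= length(unique(unlist(
    couples$supporting_reads)))))
  # the sum variant double-counts the shared read
  agg2 <- aggregate_by_subgroup(couples, method = "sum")
  expect_equal(agg2$count[agg2$v_subgroup == "IGHV2"], 4L)
})

test_that("the main clone is the top couple with its fold ratio", {
  couples <- data.frame(
    v_name = c("IGHV1-1*01", "IGHV2-1*01", "IGHV3-1*01"),
    j_name = "IGHJ1*01", v_subgroup = c("IGHV1", "IGHV2", "IGHV3"),
    j_subgroup = "IGHJ1", count = c(10L, 4L, 1L), tie = FALSE,
    stringsAsFactors = FALSE)
  mc <- main_clone(couples)
  expect_equal(mc$couple$v_name, "IGHV1-1*01")
  expect_equal(mc$ratio, 2.5)
  expect_false(mc$tie)

  expect_equal(main_clone(couples[1, ])$ratio, Inf)
  expect_error(main_clone(couples[0, ]), "no rearrangement")

  # a tie at the top surfaces the lexicographically smaller couple, flagged
  enc <- list(hits = data.frame(
    read_id = c("r1", "r1", "r1"), role = c("V", "V", "J"),
    segment = c("IGHV2-1*01", "IGHV1-1*01", "IGHJ1*01"),
    subgroup = c("IGHV2", "IGHV1", "IGHJ1"), score = 1,
    stringsAsFactors = FALSE))
  tied <- count_vj_couples(enc)
  mct <- main_clone(tied)
  expect_equal(mct$couple$v_name, "IGHV1-1*01")
  expect_true(mct$tie)
})
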