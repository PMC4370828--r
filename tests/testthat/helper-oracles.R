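# Independent oracles used by unit and acceptance tests.  These re-derive
# expected results by brute force or via Biostrings, independently of the
# package's alignment kernels.

# exhaustive end-to-end placement scan: every start position on every
# contig, both strands, mismatch-counted with Biostrings
oracle_endtoend <- function(mate, refs, max_mm, max_report) {
  hits <- data.frame(target = character(), start = integer(),
                     strand = character(), mismatches = integer(),
                     stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") mate else revcomp(mate)
    qs <- Biostrings::DNAString(q)
    for (nm in names(refs)) {
      subj <- Biostrings::DNAString(refs[[nm]])
      L <- nchar(q)
      if (length(subj) < L) next
      starts <- seq_len(length(subj) - L + 1L)
      mm <- Biostrings::neditStartingAt(qs, subj, starting.at = starts,
                                        with.indels = FALSE)
      ok <- which(mm <= max_mm)
      if (length(ok)) {
        hits <- rbind(hits, data.frame(
          target = nm, start = ok - 1L, strand = strand,
          mismatches = mm[ok], stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(hits) == 0L) return(list(status = 0L, hits = hits))
  best <- min(hits$mismatches)
  hits <- hits[hits$mismatches == best, , drop = FALSE]
  if (nrow(hits) > max_report) return(list(status = 2L, hits = hits[0, ]))
  hits <- hits[order(hits$target, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(status = 1L, hits = hits)
}

# brute-force longest common substring (both strands) via dynamic
# programming, vectorised over one dimension
oracle_lcs <- function(a, b) {
  lcs1 <- function(x, y) {
    xv <- utf8ToInt(x); yv <- utf8ToInt(y)
    best <- 0L
    prev <- integer(length(yv))
    for (i in seq_along(xv)) {
      cur <- integer(length(yv))
      m <- which(yv == xv[i])
      if (length(m)) {
        cur[m] <- 1L
        m2 <- m[m > 1L]
        cur[m2] <- prev[m2 - 1L] + 1L
        best <- max(best, cur)
      }
      prev <- cur
    }
    best
  }
  max(lcs1(a, b), lcs1(revcomp(a), b))
}

# brute-force VJ couple table: enumerate all (read, V hit, J hit) triples
# and count distinct read ids per couple
oracle_couples <- function(hits) {
  v <- hits[hits$role == "V", c("read_id", "segment")]
  j <- hits[hits$role == "J", c("read_id", "segment")]
  m <- merge(v, j, by = "read_id")
  if (nrow(m) == 0L) return(m)
  key <- paste(m$segment.x, m$segment.y, sep = "|")
  tab <- tapply(m$read_id, key, function(r) length(unique(r)))
  out <- data.frame(couple = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$couple), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny hand-built germline set for toy cases
toy_germline <- function() {
  germline_set(
    v = c("IGHV1-1*01" = "ACGTACGT"),
    d = c("IGHD1-1*01" = "TTTT"),
    j = c("IGHJ1*01" = "CCCCCC"))
}

# count mismatches between two equal-length strings
count_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}
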