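#' Simulation configuration
#'
#' Defaults emulate the data the method targets: 100 bp paired-end reads
#' from a short-insert cDNA library, exonucleolytic trimming of up to 6 nt
#' per segment end, non-templated (TdT) N insertions of up to 6 nt per
#' junction, and palindromic (P) nucleotides at untrimmed ends.  The
#' fragment-length distribution (truncated normal, default 240 +/- 60 nt,
#' clipped to `[read_length, transcript length]`) deliberately carries a
#' left tail below twice the read length: fragments short enough for the
#' two mates to overlap are exactly the ones whose pairs bridge the short
#' D region, and sequence reconstruction depends on them.
#'
#' @param n_pairs number of read pairs to simulate.
#' @param read_length mate length in nt.
#' @param fragment_length_mean,fragment_length_sd fragment length
#'   distribution (truncated normal) in nt.
#' @param substitution_error_rate per-base substitution probability.
#' @param trim_max maximum trimming (uniform on `0:trim_max`) at each
#'   recombining segment end.
#' @param n_ins_max maximum N-insertion length (uniform on `0:n_ins_max`)
#'   per junction.
#' @param p_probability probability of a palindromic addition (length
#'   uniform on 1–3 nt) at each untrimmed segment end.
#' @param clone_fractions optional named numeric vector of clone fractions
#'   summing to 1; usually supplied via the transcript pool instead.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 5000, read_length = 100,
                       fragment_length_mean = 240,
                       fragment_length_sd = 60,
                       substitution_error_rate = 0.005,
                       trim_max = 6, n_ins_max = 6, p_probability = 0.5,
                       clone_fractions = NULL, seed = 1) {
  if (!is.null(clone_fractions)) {
    if (abs(sum(clone_fractions) - 1) > 1e-9) {
      stop("clone fractions must sum to 1", call. = FALSE)
    }
  }
  if (read_length > fragment_length_mean) {
    stop("`read_length` must not exceed the fragment length mean",
         call. = FALSE)
  }
  cfg <- list(n_pairs = as.integer(n_pairs),
              read_length = as.integer(read_length),
              fragment_length_mean = fragment_length_mean,
              fragment_length_sd = fragment_length_sd,
              substitution_error_rate = substitution_error_rate,
              trim_max = as.integer(trim_max),
              n_ins_max = as.integer(n_ins_max),
              p_probability = p_probability,
              clone_fractions = clone_fractions,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# palindromic addition: reverse complement of the terminal `len` bases of
# the retained segment end
p_nucleotides <- function(seq, end, len) {
  n <- nchar(seq)
  if (end == "3p") revcomp(substr(seq, n - len + 1L, n))
  else revcomp(substr(seq, 1L, len))
}

draw_p <- function(seq, end, p_probability) {
  if (runif(1) < p_probability) {
    p_nucleotides(seq, end, 1L + floor(runif(1) * 3))
  } else ""
}

# One attempt at composing an event; junction bases adjacent to a trimmed
# germline boundary must differ from the germline continuation base so
# that the trim/insertion decomposition of the transcript is identifiable
# (the event is redrawn otherwise).
compose_event <- function(v, d, j, config) {
  tmax <- config$trim_max
  if (tmax >= min(nchar(c(v$seq, d$seq, j$seq)))) {
    stop("trim distribution support reaches a segment length; ",
         "reduce `trim_max`", call. = FALSE)
  }
  ld <- nchar(d$seq)
  trim_v3 <- as.integer(floor(runif(1) * (tmax + 1)))
  trim_j5 <- as.integer(floor(runif(1) * (tmax + 1)))
  repeat {
    trim_d5 <- as.integer(floor(runif(1) * (tmax + 1)))
    trim_d3 <- as.integer(floor(runif(1) * (tmax + 1)))
    if (trim_d5 + trim_d3 < ld) break
  }
  tv <- substr(v$seq, 1L, nchar(v$seq) - trim_v3)
  td <- substr(d$seq, trim_d5 + 1L, ld - trim_d3)
  tj <- substr(j$seq, trim_j5 + 1L, nchar(j$seq))
  p_v <- if (trim_v3 == 0L) draw_p(v$seq, "3p", config$p_probability) else ""
  p_d5 <- if (trim_d5 == 0L) draw_p(d$seq, "5p", config$p_probability) else ""
  p_d3 <- if (trim_d3 == 0L) draw_p(d$seq, "3p", config$p_probability) else ""
  p_j <- if (trim_j5 == 0L) draw_p(j$seq, "5p", config$p_probability) else ""
  n1 <- random_seq(floor(runif(1) * (config$n_ins_max + 1)))
  n2 <- random_seq(floor(runif(1) * (config$n_ins_max + 1)))
  jun1 <- paste0(p_v, n1, p_d5)
  jun2 <- paste0(p_d3, n2, p_j)

  last1 <- function(s) substr(s, nchar(s), nchar(s))
  ok <- TRUE
  if (trim_v3 > 0L) {
    cont <- substr(v$seq, nchar(v$seq) - trim_v3 + 1L,
                   nchar(v$seq) - trim_v3 + 1L)
    nxt <- if (nzchar(jun1)) substr(jun1, 1L, 1L) else substr(td, 1L, 1L)
    if (nxt == cont) ok <- FALSE
  }
  if (ok && trim_d5 > 0L) {
    cont <- substr(d$seq, trim_d5, trim_d5)
    prv <- if (nzchar(jun1)) last1(jun1) else last1(tv)
    if (prv == cont) ok <- FALSE
  }
  if (ok && trim_d3 > 0L) {
    cont <- substr(d$seq, ld - trim_d3 + 1L, ld - trim_d3 + 1L)
    nxt <- if (nzchar(jun2)) substr(jun2, 1L, 1L) else substr(tj, 1L, 1L)
    if (nxt == cont) ok <- FALSE
  }
  if (ok && trim_j5 > 0L) {
    cont <- substr(j$seq, trim_j5, trim_j5)
    prv <- if (nzchar(jun2)) last1(jun2) else last1(td)
    if (prv == cont) ok <- FALSE
  }
  if (!ok) return(NULL)

  ev <- list(v_name = v$name, d_name = d$name, j_name = j$name,
             trim_v3 = trim_v3, trim_d5 = trim_d5, trim_d3 = trim_d3,
             trim_j5 = trim_j5, n1_seq = n1, n2_seq = n2,
             p_v = p_v, p_d5 = p_d5, p_d3 = p_d3, p_j = p_j,
             transcript = paste0(tv, jun1, td, jun2, tj))
  class(ev) <- "recomb_event"
  validate_event(ev, v$seq, d$seq, j$seq)
  ev
}

# transcript-composition invariant: reassemble from the parts
validate_event <- function(ev, v_seq, d_seq, j_seq) {
  tv <- substr(v_seq, 1L, nchar(v_seq) - ev$trim_v3)
  td <- substr(d_seq, ev$trim_d5 + 1L, nchar(d_seq) - ev$trim_d3)
  tj <- substr(j_seq, ev$trim_j5 + 1L, nchar(j_seq))
  expect <- paste0(tv, ev$p_v, ev$n1_seq, ev$p_d5, td, ev$p_d3, ev$n2_seq,
                   ev$p_j, tj)
  if (!identical(expect, ev$transcript)) {
    stop("internal error: transcript composition invariant violated",
         call. = FALSE)
  }
  invisible(ev)
}

#' Simulate one V(D)J recombination event
#'
#' Draws V, D and J segments uniformly from the germline set, trims the
#' recombining ends, adds N nucleotides at the VD and DJ junctions, and
#' adds P (palindromic) nucleotides at untrimmed ends.  The transcript is
#' `trimmedV + p_v + n1 + p_d5 + trimmedD + p_d3 + n2 + p_j + trimmedJ`.
#' Consumes the current RNG stream (seed via [with_seed] wrappers such as
#' [simulate_sample()], or `set.seed()`).
#'
#' @param germline a `germline_set`.
#' @param config a [sim_config()].
#' @return object of class `recomb_event`.
#' @export
simulate_rearrangement <- function(germline, config = sim_config()) {
  pick <- function(df) df[1L + floor(runif(1) * nrow(df)), , drop = FALSE]
  for (attempt in 1:200) {
    ev <- compose_event(pick(germline$v), pick(germline$d),
                        pick(germline$j), config)
    if (!is.null(ev)) return(ev)
  }
  stop("failed to draw an identifiable recombination event", call. = FALSE)
}

#' Simulate a polyclonal background
#'
#' Draws `n_clones` recombination events with distinct (V, D, J) triples
#' when the germline set allows it.
#'
#' @param germline a `germline_set`.
#' @param n_clones number of background clones (>= 1).
#' @param config a [sim_config()].
#' @return list of `recomb_event`s named `bg001`, `bg002`, ...
#' @export
simulate_background <- function(germline, n_clones, config = sim_config()) {
  stopifnot_scalar_count(n_clones, "n_clones")
  if (n_clones < 1) stop("`n_clones` must be >= 1", call. = FALSE)
  max_triples <- nrow(germline$v) * nrow(germline$d) * nrow(germline$j)
  events <- vector("list", n_clones)
  seen <- character(0)
  for (i in seq_len(n_clones)) {
    for (attempt in 1:100) {
      ev <- simulate_rearrangement(germline, config)
      key <- paste(ev$v_name, ev$d_name, ev$j_name)
      if (!(key %in% seen) || length(seen) >= max_triples) break
    }
    seen <- c(seen, key)
    events[[i]] <- ev
  }
  names(events) <- sprintf("bg%03d", seq_len(n_clones))
  events
}

#' Assemble a labeled transcript pool
#'
#' @param main_event the main-clone `recomb_event`.
#' @param background list of background `recomb_event`s (may be empty).
#' @param main_fraction fraction of read pairs drawn from the main clone;
#'   the remainder is split near-uniformly over the background clones.
#' @return data.frame with columns `label`, `sequence`, `fraction`,
#'   `v_name`, `d_name`, `j_name`.
#' @export
transcript_pool <- function(main_event, background = list(),
                            main_fraction = 0.7) {
  if (length(background) == 0L) main_fraction <- 1
  evs <- c(list(main = main_event), background)
  fr <- if (length(background)) {
    c(main_fraction, rep((1 - main_fraction) / length(background),
                         length(background)))
  } else 1
  data.frame(label = names(evs),
             sequence = vapply(evs, `[[`, "", "transcript"),
             fraction = fr,
             v_name = vapply(evs, `[[`, "", "v_name"),
             d_name = vapply(evs, `[[`, "", "d_name"),
             j_name = vapply(evs, `[[`, "", "j_name"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# exact largest-remainder apportionment of n into fractions
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# truncated-normal integer draw via inverse CDF, vectorised
rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  plo <- pnorm((lo - 0.5 - mean) / sd)
  phi <- pnorm((hi + 0.5 - mean) / sd)
  x <- round(qnorm(runif(n, plo, phi)) * sd + mean)
  pmin(pmax(as.integer(x), as.integer(lo)), as.integer(hi))
}

#' Simulate paired-end reads from a transcript pool
#'
#' Pairs are allocated to transcripts by exact largest-remainder rounding
#' of the pool fractions (no sampling noise in the allocation).  Fragments
#' are drawn from a truncated normal clipped to
#' `[read_length, transcript length]` (mates overlap when the fragment is
#' shorter than two read lengths); mate 1
#' is the fragment 5' end in sense orientation, mate 2 the reverse
#' complement of the fragment 3' end.  Substitution errors are injected
#' per base and recorded in the truth table.  Consumes the current RNG
#' stream.
#'
#' @param pool data.frame from [transcript_pool()] (or any data.frame with
#'   `label`, `sequence`, `fraction` and optional `v_name`/`d_name`/
#'   `j_name` columns).
#' @param config a [sim_config()].
#' @return list with `reads` (data.frame `read_id`, `mate1_seq`,
#'   `mate2_seq`) and `truth` (data.frame `read_id`, `clone_label`,
#'   `v_name`, `d_name`, `j_name`, `frag_start`, `frag_end`, `errors1`,
#'   `errors2`; coordinates 0-based half-open on the source transcript,
#'   error offsets 0-based on the mate, comma-separated).
#' @export
simulate_reads <- function(pool, config = sim_config()) {
  rl <- config$read_length
  short <- nchar(pool$sequence) < rl
  if (any(short)) {
    stop("transcript(s) shorter than the read length: ",
         paste(sQuote(pool$label[short]), collapse = ", "), call. = FALSE)
  }
  fr <- if (!is.null(config$clone_fractions)) {
    unname(config$clone_fractions[pool$label])
  } else pool$fraction
  if (anyNA(fr)) stop("clone fractions do not cover all pool labels",
                      call. = FALSE)
  counts <- largest_remainder(fr, config$n_pairs)

  out <- vector("list", nrow(pool))
  idx0 <- 0L
  for (k in seq_len(nrow(pool))) {
    n <- counts[k]
    if (n == 0L) { out[[k]] <- NULL; next }
    tr <- pool$sequence[k]
    L <- nchar(tr)
    lo <- rl
    frag <- rtruncnorm_int(n, config$fragment_length_mean,
                           config$fragment_length_sd, lo, L)
    start <- floor(runif(n) * (L - frag + 1))
    m1 <- substring(tr, start + 1L, start + rl)
    m2 <- revcomp(substring(tr, start + frag - rl + 1L, start + frag))
    e1 <- inject_errors(m1, config$substitution_error_rate)
    e2 <- inject_errors(m2, config$substitution_error_rate)
    out[[k]] <- data.frame(
      read_id = sprintf("r%06d", idx0 + seq_len(n)),
      clone_label = pool$label[k],
      v_name = if ("v_name" %in% names(pool)) pool$v_name[k] else NA,
      d_name = if ("d_name" %in% names(pool)) pool$d_name[k] else NA,
      j_name = if ("j_name" %in% names(pool)) pool$j_name[k] else NA,
      frag_start = start, frag_end = start + frag,
      mate1_seq = e1$seqs, mate2_seq = e2$seqs,
      errors1 = e1$offsets, errors2 = e2$offsets,
      stringsAsFactors = FALSE)
    idx0 <- idx0 + n
  }
  all <- do.call(rbind, out)
  rownames(all) <- NULL
  list(reads = all[, c("read_id", "mate1_seq", "mate2_seq")],
       truth = all[, c("read_id", "clone_label", "v_name", "d_name",
                       "j_name", "frag_start", "frag_end", "errors1",
                       "errors2")])
}

# substitution errors at per-base rate; returns mutated sequences and
# 0-based offsets (comma separated) per sequence
inject_errors <- function(seqs, rate) {
  offsets <- rep("", length(seqs))
  if (rate > 0 && length(seqs)) {
    rl <- nchar(seqs[1L])
    hit <- matrix(runif(length(seqs) * rl) < rate, nrow = length(seqs))
    which_seq <- which(rowSums(hit) > 0)
    alts <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACGT")
    for (i in which_seq) {
      pos <- which(hit[i, ])
      s <- seqs[i]
      for (p in pos) {
        orig <- substr(s, p, p)
        alt <- alts[[orig]]
        r <- ceiling(runif(1) * nchar(alt))
        substr(s, p, p) <- substr(alt, r, r)
      }
      seqs[i] <- s
      offsets[i] <- paste(pos - 1L, collapse = ",")
    }
  }
  list(seqs = seqs, offsets = offsets)
}

#' Simulate a complete sample (germline, events, reads, truth)
#'
#' Convenience wrapper reproducing the package's standard study condition:
#' one dominant clone over a polyclonal background, synthetic germline
#' with allele pairs.  Fully determined by `seed`.
#'
#' @param seed integer seed.
#' @param n_pairs read pairs to simulate.
#' @param main_fraction fraction of pairs from the main clone.
#' @param n_background number of background clones.
#' @param error_rate per-base substitution error rate.
#' @param germline optional pre-built `germline_set`; generated from
#'   `seed` when `NULL`.
#' @param n_v,n_d,n_j germline sizes when generating.
#' @param divergence allele-pair divergence when generating.
#' @param config optional [sim_config()]; `n_pairs` and `error_rate`
#'   override its fields.
#' @return list with `germline`, `main_event`, `background`, `pool`,
#'   `reads`, `truth`, `config`.
#' @export
simulate_sample <- function(seed, n_pairs = 5000, main_fraction = 0.7,
                            n_background = 50, error_rate = 0.005,
                            germline = NULL, n_v = 30, n_d = 10, n_j = 6,
                            divergence = 0.015, config = NULL) {
  config <- config %||% sim_config()
  config$n_pairs <- as.integer(n_pairs)
  config$substitution_error_rate <- error_rate
  config$seed <- as.integer(seed)
  with_seed(seed, {
    if (is.null(germline)) {
      germline <- generate_germline_impl(
        n_v, n_d, n_j,
        list(v = c(280, 310), d = c(16, 37), j = c(45, 60)), divergence)
    }
    main_event <- simulate_rearrangement(germline, config)
    background <- if (n_background > 0) {
      simulate_background(germline, n_background, config)
    } else list()
    pool <- transcript_pool(main_event, background, main_fraction)
    sim <- simulate_reads(pool, config)
    list(germline = germline, main_event = main_event,
         background = background, pool = pool, reads = sim$reads,
         truth = sim$truth, config = config)
  })
}

#' Write simulated reads as paired FASTQ files
#'
#' Mate ids carry `/1` and `/2` suffixes; qualities are a constant
#' placeholder (`I`).
#'
#' @param reads data.frame with `read_id`, `mate1_seq`, `mate2_seq`.
#' @param mate1_path,mate2_path output FASTQ paths.
#' @export
write_fastq_pair <- function(reads, mate1_path, mate2_path) {
  wr <- function(seqs, ids, suffix, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- paste0(ids, suffix)
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  }
  wr(reads$mate1_seq, reads$read_id, "/1", mate1_path)
  wr(reads$mate2_seq, reads$read_id, "/2", mate2_path)
  invisible(c(mate1_path, mate2_path))
}

#' Read paired FASTQ files into a read table
#'
#' @param mate1_path,mate2_path FASTQ paths (ids must pair up after
#'   stripping `/1`/`/2` suffixes).
#' @return data.frame with `read_id`, `mate1_seq`, `mate2_seq`.
#' @export
read_fastq_pair <- function(mate1_path, mate2_path) {
  s1 <- Biostrings::readDNAStringSet(mate1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(mate2_path, format = "fastq")
  id1 <- sub("/1$", "", sub("\\s.*$", "", names(s1)))
  id2 <- sub("/2$", "", sub("\\s.*$", "", names(s2)))
  if (!identical(id1, id2)) {
    stop("mate FASTQ files do not pair up record-by-record", call. = FALSE)
  }
  data.frame(read_id = id1, mate1_seq = as.character(s1),
             mate2_seq = as.character(s2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write / read the simulation truth table (TSV)
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
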