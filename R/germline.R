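#' Parse IMGT-style IGH allele labels
#'
#' IGH segment names follow the hierarchy `subgroup[-gene]*allele`:
#' V and D segments carry a gene token (`IGHV2-70*11`, `IGHD1-26*01`),
#' J segments do not (`IGHJ4*02`).  Gene tokens are kept as opaque strings
#' because IMGT genes are not numeric in general (e.g. `3-16` relatives,
#' letter suffixes).
#'
#' @param text character vector of allele labels.
#' @return data.frame with columns `text`, `chain` (`"IGH"`), `type`
#'   (`"V"`, `"D"` or `"J"`), `subgroup` (e.g. `"IGHV2"`), `gene`
#'   (`NA` for J segments) and `allele`.
#' @examples
#' parse_segment_name(c("IGHV2-70*11", "IGHJ4*02", "IGHD1-26*01"))
#' @export
parse_segment_name <- function(text) {
  if (length(text) == 0L) {
    return(data.frame(text = character(), chain = character(),
                      type = character(), subgroup = character(),
                      gene = character(), allele = character(),
                      stringsAsFactors = FALSE))
  }
  if (!is.character(text) || anyNA(text) || any(!nzchar(text))) {
    stop("allele labels must be non-empty strings", call. = FALSE)
  }
  rx <- "^(IGH)([VDJ])([0-9A-Za-z.]+?)(?:-([0-9A-Za-z.]+))?\\*([0-9A-Za-z]+)$"
  ok <- grepl(rx, text, perl = TRUE)
  if (any(!ok)) {
    stop("cannot parse segment name(s): ",
         paste(sQuote(text[!ok]), collapse = ", "), call. = FALSE)
  }
  m <- regmatches(text, regexec(rx, text, perl = TRUE))
  m <- do.call(rbind, m)
  type <- m[, 3L]
  gene <- m[, 5L]
  gene[gene == ""] <- NA_character_
  bad_j <- type == "J" & !is.na(gene)
  bad_vd <- type != "J" & is.na(gene)
  if (any(bad_j | bad_vd)) {
    stop("malformed segment name(s) (gene token must be absent for J, ",
         "present for V and D): ",
         paste(sQuote(text[bad_j | bad_vd]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(text = text, chain = m[, 2L], type = type,
             subgroup = paste0(m[, 2L], type, m[, 4L]), gene = gene,
             allele = m[, 6L], stringsAsFactors = FALSE)
}

#' Format parsed segment names back to allele labels
#'
#' Inverse of [parse_segment_name()]: `subgroup[-gene]*allele`.
#'
#' @param x data.frame with columns `subgroup`, `gene`, `allele`.
#' @return character vector of labels.
#' @export
format_segment_name <- function(x) {
  gene <- ifelse(is.na(x$gene), "", paste0("-", x$gene))
  paste0(x$subgroup, gene, "*", x$allele)
}

# internal constructor for a segment table: name columns + sequence
make_segment_table <- function(names, seqs) {
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) stop("empty germline sequence", call. = FALSE)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("germline sequences must be over {A,C,G,T}: ",
         paste(sQuote(names[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("duplicate segment name(s): ",
         paste(sQuote(unique(names[duplicated(names)])), collapse = ", "),
         call. = FALSE)
  }
  p <- parse_segment_name(names)
  df <- data.frame(name = names, type = p$type, subgroup = p$subgroup,
                   gene = p$gene, allele = p$allele, seq = seqs,
                   stringsAsFactors = FALSE)
  df <- df[order(df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble a germline segment set
#'
#' @param v,d,j data.frames as returned by [load_germline()] (columns
#'   `name`, `type`, `subgroup`, `gene`, `allele`, `seq`), or named
#'   character vectors of sequences.
#' @return object of class `germline_set` with elements `v`, `d`, `j`.
#' @export
germline_set <- function(v, d, j) {
  norm <- function(x, type) {
    if (is.character(x)) x <- make_segment_table(names(x), unname(x))
    if (nrow(x) == 0L) stop("empty ", type, " segment set", call. = FALSE)
    if (any(x$type != type)) {
      stop("segment(s) of wrong type in ", type, " set: ",
           paste(sQuote(x$name[x$type != type]), collapse = ", "),
           call. = FALSE)
    }
    x
  }
  gs <- list(v = norm(v, "V"), d = norm(d, "D"), j = norm(j, "J"))
  class(gs) <- "germline_set"
  gs
}

#' @export
print.germline_set <- function(x, ...) {
  cat(sprintf("germline_set: %d V, %d D, %d J segments\n",
              nrow(x$v), nrow(x$d), nrow(x$j)))
  invisible(x)
}

#' Load germline segments from FASTA
#'
#' Headers must start with a parseable allele label (free text after the
#' first whitespace is ignored).  Sequences are uppercased and U is
#' normalised to T.
#'
#' @param path FASTA file.
#' @param segment_type `"V"`, `"D"` or `"J"`; all records must be of this
#'   type.
#' @return segment data.frame (see [germline_set()]).
#' @export
load_germline <- function(path, segment_type = c("V", "D", "J")) {
  segment_type <- match.arg(segment_type)
  if (!file.exists(path)) stop("germline file not found: ", path,
                               call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  df <- make_segment_table(nm, as.character(ss))
  if (any(df$type != segment_type)) {
    stop("record(s) of unexpected type in ", path, ": ",
         paste(sQuote(df$name[df$type != segment_type]), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write germline segments to FASTA
#'
#' @param segments segment data.frame or `germline_set` element.
#' @param path output FASTA file.
#' @export
write_germline <- function(segments, path) {
  ss <- Biostrings::DNAStringSet(segments$seq)
  names(ss) <- segments$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Load a complete germline set from three FASTA files
#'
#' @param v_path,d_path,j_path FASTA files for the V, D and J segments.
#' @return a `germline_set`.
#' @export
load_germline_set <- function(v_path, d_path, j_path) {
  germline_set(load_germline(v_path, "V"), load_germline(d_path, "D"),
               load_germline(j_path, "J"))
}

# mutate each base independently with probability `rate` to one of the
# other three bases (uses the current RNG stream)
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(b)) < rate
  if (any(hit)) {
    alts <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    pick <- ceiling(runif(sum(hit)) * 3)
    b[hit] <- vapply(seq_along(pick), function(i) {
      substr(alts[[b[hit][i]]], pick[i], pick[i])
    }, character(1))
  }
  paste(b, collapse = "")
}

random_seq <- function(len) {
  paste(c("A", "C", "G", "T")[ceiling(runif(len) * 4)], collapse = "")
}

#' Generate a synthetic germline segment set
#'
#' Segments are organised in the IMGT hierarchy: genes carry allele pairs
#' (`*01` plus a `*02` derived from it by per-base substitution at rate
#' `divergence`), genes are distributed over subgroups, and J segments
#' carry alleles directly under the subgroup.  Allele pairs exercise the
#' multimapping behaviour that homologous and polymorphic IGH segments
#' cause in real data.
#'
#' @param n_v,n_d,n_j number of V, D and J segments (alleles) to generate.
#' @param length_ranges list with elements `v`, `d`, `j`, each `c(min,
#'   max)` nucleotides.  Defaults reflect human IGH segment sizes.
#' @param divergence per-base substitution probability between the two
#'   alleles of a gene; default 0.015 (98.5 percent allele-pair identity).
#' @param seed integer seed; the result is a pure function of the
#'   arguments including the seed.
#' @return a `germline_set`.
#' @export
generate_synthetic_germline <- function(n_v = 30, n_d = 10, n_j = 6,
                                        length_ranges = list(
                                          v = c(280, 310),
                                          d = c(16, 37),
                                          j = c(45, 60)),
                                        divergence = 0.015, seed = 1) {
  stopifnot_scalar_count(n_v, "n_v")
  stopifnot_scalar_count(n_d, "n_d")
  stopifnot_scalar_count(n_j, "n_j")
  if (n_v < 1 || n_d < 1 || n_j < 1) {
    stop("segment counts must be >= 1", call. = FALSE)
  }
  if (divergence < 0 || divergence > 1) {
    stop("`divergence` must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    generate_germline_impl(n_v, n_d, n_j, length_ranges, divergence)
  })
}

# generator body; consumes the current RNG stream
generate_germline_impl <- function(n_v, n_d, n_j, length_ranges,
                                   divergence) {
  draw_len <- function(rng) {
    rng[1] + floor(runif(1) * (rng[2] - rng[1] + 1))
  }
  gene_family <- function(n, type, rng) {
    # allele pairs: gene g gets *01 (base) and *02 (mutated copy)
    n_genes <- ceiling(n / 2)
    n_sub <- max(2L, ceiling(n_genes / 3))
    nm <- character(0); sq <- character(0)
    made <- 0L
    for (g in seq_len(n_genes)) {
      sub <- ((g - 1L) %% n_sub) + 1L
      base <- random_seq(draw_len(rng))
      for (a in 1:2) {
        if (made >= n) break
        made <- made + 1L
        nm <- c(nm, sprintf("IGH%s%d-%d*%02d", type, sub, g, a))
        sq <- c(sq, if (a == 1L) base else mutate_seq(base, divergence))
      }
    }
    make_segment_table(nm, sq)
  }
  j_family <- function(n, rng) {
    n_sub <- ceiling(n / 2)
    nm <- character(0); sq <- character(0)
    made <- 0L
    for (s in seq_len(n_sub)) {
      base <- random_seq(draw_len(rng))
      for (a in 1:2) {
        if (made >= n) break
        made <- made + 1L
        nm <- c(nm, sprintf("IGHJ%d*%02d", s, a))
        sq <- c(sq, if (a == 1L) base else mutate_seq(base, divergence))
      }
    }
    make_segment_table(nm, sq)
  }
  germline_set(gene_family(n_v, "V", length_ranges$v),
               gene_family(n_d, "D", length_ranges$d),
               j_family(n_j, length_ranges$j))
}
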