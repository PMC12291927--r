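#' Gene feature table constructor
#'
#' Builds the validated feature table used by [circular_genome()]. Features
#' are rows of a data frame with 1-based inclusive coordinates on a circle
#' of length `genome_length`; a feature whose `stop` is smaller than its
#' `start` wraps across the sequence origin (runs `start..L` then
#' `1..stop`), which is how the control region of a vertebrate mitogenome
#' that spans the origin is represented.
#'
#' @param name character vector of unique gene symbols (e.g. "atp8",
#'   "trnF", "rrnS", "control").
#' @param start,stop 1-based inclusive coordinates, each in `[1, L]`.
#' @param strand "+" (heavy) or "-" (light).
#' @param gene_class one of "PCG", "tRNA", "rRNA", "control".
#' @param genome_length circle length L in bp.
#' @return a `data.frame` of class `mito_features`, sorted by `start`, with
#'   columns name, gene_class, start, stop, strand, wraps, length.
#' @export
gene_features <- function(name, start, stop, strand, gene_class, genome_length) {
  L <- as.integer(genome_length)
  start <- as.integer(start)
  stop <- as.integer(stop)
  n <- length(name)
  stopifnot(
    n >= 1L,
    length(start) == n, length(stop) == n,
    length(strand) == n, length(gene_class) == n
  )
  if (anyDuplicated(name)) {
    stop("duplicate gene name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  bad <- which(start < 1L | start > L | stop < 1L | stop > L)
  if (length(bad)) {
    stop("coordinate out of [1, ", L, "] for feature(s): ",
         paste(name[bad], collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(gene_class %in% c("PCG", "tRNA", "rRNA", "control"))) {
    stop("gene_class must be PCG, tRNA, rRNA or control")
  }
  wraps <- stop < start
  df <- data.frame(
    name = as.character(name), gene_class = as.character(gene_class),
    start = start, stop = stop, strand = as.character(strand),
    wraps = wraps, stringsAsFactors = FALSE
  )
  df <- df[order(df$start), , drop = FALSE]
  if (anyDuplicated(df$start)) stop("features may not share a start coordinate")
  df$length <- feature_length(df$start, df$stop, df$wraps, L)
  rownames(df) <- NULL
  attr(df, "genome_length") <- L
  class(df) <- c("mito_features", "data.frame")
  df
}

#' Circular genome container
#'
#' Bundles a circular nucleotide sequence with its ordered feature table.
#' The sequence may be omitted (`seq = NULL`) for annotation-only work such
#' as gene-organization accounting, in which case `length` must be given.
#'
#' @param seq uppercase nucleotide string over `{A,C,G,T,N}` or `NULL`.
#' @param features a `mito_features` table (see [gene_features()]).
#' @param length circle length; defaults to `nchar(seq)`.
#' @return an object of class `circular_genome`.
#' @export
circular_genome <- function(seq = NULL, features = NULL, length = NULL) {
  if (is.null(seq) && is.null(length)) {
    stop("either seq or length must be supplied")
  }
  if (!is.null(seq)) {
    stopifnot(is.character(seq), base::length(seq) == 1L)
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters")
    L <- nchar(seq)
    if (!is.null(length) && as.integer(length) != L) {
      stop("length does not match nchar(seq)")
    }
  } else {
    L <- as.integer(length)
  }
  if (!is.null(features)) {
    if (!inherits(features, "mito_features")) stop("features must be a mito_features table")
    if (attr(features, "genome_length") != L) {
      stop("feature table genome_length (", attr(features, "genome_length"),
           ") does not match genome length (", L, ")")
    }
  }
  structure(list(seq = seq, length = L, features = features),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome> ", x$length, " bp",
      if (is.null(x$seq)) " (annotation only)" else "", "\n", sep = "")
  if (!is.null(x$features)) {
    tab <- table(x$features$gene_class)
    cat("  features: ", nrow(x$features), " (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Length of a (possibly wrapping) feature
#'
#' Vectorized over features. A non-wrapping feature has length
#' `stop - start + 1`; a wrapping one `(L - start + 1) + stop`.
#'
#' @param start,stop 1-based inclusive coordinates.
#' @param wraps logical; TRUE when the feature crosses the origin.
#' @param genome_length circle length L.
#' @return integer length(s) in bp.
#' @export
feature_length <- function(start, stop, wraps, genome_length) {
  L <- as.integer(genome_length)
  ifelse(wraps, (L - as.integer(start) + 1L) + as.integer(stop),
         as.integer(stop) - as.integer(start) + 1L)
}

#' Intergenic nucleotides between two consecutive features
#'
#' The signed gap printed in gene-organization tables:
#' `next.start - prev.stop - 1`. Negative values denote overlap with the
#' previous listed feature. When `next` starts at or before `prev` stops in
#' linear coordinates because the pair straddles the origin (and `prev`
#' does not itself wrap), the gap is measured around the circle.
#'
#' @param prev,nxt single-row feature data frames (or lists) with `start`,
#'   `stop`, `wraps` fields; `prev` precedes `nxt` in start order.
#' @param genome_length circle length L.
#' @return signed integer gap in bp.
#' @export
intergenic_nt <- function(prev, nxt, genome_length) {
  L <- as.integer(genome_length)
  gap <- as.integer(nxt$start) - as.integer(prev$stop) - 1L
  # circuit-closure pair: prev is the last feature, nxt the first. If prev
  # wraps, its stop already lies just before nxt in linear coordinates.
  if (!isTRUE(prev$wraps) && as.integer(nxt$start) <= as.integer(prev$start)) {
    gap <- gap + L
  }
  gap
}

#' Gene-organization report for a circular genome
#'
#' Walks the features in start order (the order a gene-organization table
#' prints them), computes the signed intergenic gap of every consecutive
#' pair including the circuit-closure pair, and aggregates the overlap and
#' spacer censuses plus the per-strand gene counts. The control region is
#' excluded from the strand census (it is not a gene) but participates in
#' the adjacency walk, so the gap printed for the first gene is measured
#' against it.
#'
#' @param g a [circular_genome()] with at least 2 features.
#' @return a list of class `organization_report` with elements `rows`
#'   (per-feature table with `intergenic_nt` vs the previous feature on the
#'   circle), `overlap_count`, `overlap_total_bp`, `overlap_max_bp`,
#'   `spacer_count`, `spacer_total_bp`, `spacer_max_bp`,
#'   `h_strand_gene_count`, `l_strand_gene_count`, `gene_count`.
#' @export
organization_report <- function(g) {
  stopifnot(inherits(g, "circular_genome"), !is.null(g$features))
  f <- g$features
  n <- nrow(f)
  if (n < 2L) stop("organization_report needs at least 2 features")
  L <- g$length
  prev_idx <- c(n, seq_len(n - 1L))
  gaps <- vapply(seq_len(n), function(i) {
    intergenic_nt(f[prev_idx[i], ], f[i, ], L)
  }, integer(1))
  rows <- data.frame(
    name = f$name, gene_class = f$gene_class, strand = f$strand,
    start = f$start, stop = f$stop, length = f$length,
    intergenic_nt = gaps, stringsAsFactors = FALSE
  )
  neg <- gaps[gaps < 0L]
  pos <- gaps[gaps > 0L]
  is_gene <- f$gene_class != "control"
  structure(list(
    rows = rows,
    overlap_count = length(neg),
    overlap_total_bp = -sum(neg),
    overlap_max_bp = if (length(neg)) max(-neg) else 0L,
    spacer_count = length(pos),
    spacer_total_bp = sum(pos),
    spacer_max_bp = if (length(pos)) max(pos) else 0L,
    h_strand_gene_count = sum(is_gene & f$strand == "+"),
    l_strand_gene_count = sum(is_gene & f$strand == "-"),
    gene_count = sum(is_gene)
  ), class = "organization_report")
}

#' @export
print.organization_report <- function(x, ...) {
  cat("<organization_report> ", x$gene_count, " genes (",
      x$h_strand_gene_count, " H / ", x$l_strand_gene_count, " L)\n",
      "  overlaps: ", x$overlap_count, " (", x$overlap_total_bp,
      " bp total, max ", x$overlap_max_bp, ")\n",
      "  spacers:  ", x$spacer_count, " (", x$spacer_total_bp,
      " bp total, max ", x$spacer_max_bp, ")\n", sep = "")
  invisible(x)
}

# Genome positions covered by a feature, in coding (5'->3' on the H strand
# reading) order before any strand flip.
feature_positions <- function(start, stop, wraps, L) {
  if (wraps) c(start:L, 1:stop) else start:stop
}

#' Length of the union of all protein-coding gene intervals
#'
#' Positions covered by two overlapping PCGs are counted once, so the
#' result can be smaller than the sum of PCG lengths (in the pig skeleton
#' the intra-PCG overlaps reduce 11,410 summed bp to an 11,342 bp union).
#' Implemented by interval merging on the circle (wrapping features are
#' split in two); a brute-force position-set oracle backs it in the tests.
#'
#' @param g a [circular_genome()] with at least one PCG feature.
#' @return union length in bp.
#' @export
pcg_union_length <- function(g) {
  stopifnot(inherits(g, "circular_genome"), !is.null(g$features))
  f <- g$features[g$features$gene_class == "PCG", , drop = FALSE]
  if (nrow(f) < 1L) stop("no PCG features")
  L <- g$length
  iv <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    if (f$wraps[i]) {
      rbind(c(f$start[i], L), c(1L, f$stop[i]))
    } else {
      c(f$start[i], f$stop[i])
    }
  }))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  total <- 0L
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= cur_e) {
      cur_e <- max(cur_e, iv[i, 2])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- iv[i, 1]; cur_e <- iv[i, 2]
    }
  }
  total <- total + (cur_e - cur_s + 1L)
  as.integer(total)
}

#' Read a gene-annotation TSV
#'
#' Expects a tab-separated file with header columns `name`, `start`,
#' `stop`, `strand` and optionally `class`; extra columns (such as a
#' printed length or intergenic column) are ignored and lengths are always
#' recomputed from the coordinates, because published organization tables
#' occasionally carry transcription errors in derived columns. Lines
#' starting with `#` are comments. When `class` is absent it is inferred
#' from the gene symbol prefix (`trn*` tRNA, `rrn*` rRNA, `control`
#' control, otherwise PCG).
#'
#' @param path TSV path.
#' @param genome_length circle length L used for validation.
#' @return a `mito_features` table.
#' @export
read_annotation_table <- function(path, genome_length) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "start", "stop", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  strand <- df$strand
  strand[strand %in% c("−", "–")] <- "-" # unicode minus/en-dash
  cls <- if ("class" %in% names(df)) df$class else infer_gene_class(df$name)
  gene_features(df$name, df$start, df$stop, strand, cls, genome_length)
}

infer_gene_class <- function(name) {
  ifelse(grepl("^trn", name, ignore.case = TRUE), "tRNA",
  ifelse(grepl("^rrn", name, ignore.case = TRUE), "rRNA",
  ifelse(grepl("^(control|d-?loop)$", name, ignore.case = TRUE), "control",
         "PCG")))
}

#' Write an organization report as TSV
#'
#' Emits the per-feature table followed by a `#`-commented summary block
#' (overlap/spacer censuses and strand counts), mirroring the shape of a
#' published gene-organization table.
#'
#' @param rep an [organization_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_organization_tsv <- function(rep, path) {
  stopifnot(inherits(rep, "organization_report"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(rep$rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- rep
  writeLines(sprintf(
    "# genes\t%d\n# h_strand\t%d\n# l_strand\t%d\n# overlaps\t%d\t%d bp total\t%d bp max\n# spacers\t%d\t%d bp total\t%d bp max",
    s$gene_count, s$h_strand_gene_count, s$l_strand_gene_count,
    s$overlap_count, s$overlap_total_bp, s$overlap_max_bp,
    s$spacer_count, s$spacer_total_bp, s$spacer_max_bp), con)
  invisible(path)
}

#' Packaged pig-like mitogenome gene skeleton
#'
#' The 37-gene coordinate/strand layout of a 16,581 bp *Sus scrofa*
#' mitogenome plus its origin-spanning control region, shipped as a text
#' fixture so that gene-organization accounting and the synthetic
#' generator need no downloads.
#'
#' @param genome_length circle length the skeleton is laid out on.
#' @return a `mito_features` table.
#' @export
mito_gene_skeleton <- function(genome_length = 16581L) {
  path <- system.file("extdata", "sus_scrofa_mito_genes.tsv",
                      package = "mitochar", mustWork = TRUE)
  read_annotation_table(path, genome_length)
}
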