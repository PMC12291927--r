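#' Build a characterization run configuration
#'
#' Merges defaults, an optional JSON config file and programmatic
#' overrides (overrides win, then the file, then defaults). The
#' configuration is the single artifact that makes a run reproducible:
#' outputs are a pure function of (inputs, config, seeds).
#'
#' @param path optional JSON file with configuration fields.
#' @param ... override fields: `genome_fasta`, `annotation_tsv`,
#'   `alignment_fasta`, `stages` (subset of `organize`, `composition`,
#'   `rscu`, `repeats`, `variation`, `haplotype`, `phylo`),
#'   `repeat_motif`, `max_mismatch`, `reference_row`, `outgroup`,
#'   `replicates`, `seed`, `genome_length`, `outdir`.
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    genome_fasta = NULL, annotation_tsv = NULL, alignment_fasta = NULL,
    stages = c("organize", "composition", "rscu", "repeats"),
    repeat_motif = "CGTACACGTG", max_mismatch = 0L,
    reference_row = NULL, outgroup = NULL,
    replicates = 100L, seed = 1L,
    genome_length = NULL, outdir = "mitochar_out"
  )
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg$replicates <- as.integer(cfg$replicates)
  if (cfg$replicates < 1L) stop("replicates must be >= 1")
  known <- c("organize", "composition", "rscu", "repeats", "variation",
             "haplotype", "phylo")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

# Fingerprint over the fields that determine output *content*; the output
# directory is excluded so identical runs into different directories stamp
# identically (the byte-reproducibility contract).
config_fingerprint <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"))
}

#' Run the end-to-end mitogenome characterization
#'
#' Wires the stages together the way a mitogenome paper reports them:
#' gene organization (table + overlap/spacer/strand summary), per-region
#' composition and skews, codon usage and RSCU with start/stop
#' classification, control-region tandem repeats, alignment variation and
#' haplotype calls, and the TN93 + neighbor-joining + bootstrap tree with
#' optional outgroup rooting. Each output file carries a header with the
#' package version and a config fingerprint. Configuration errors (e.g.
#' the phylo stage without an alignment) are raised before any work.
#'
#' @param cfg a [run_config()].
#' @return invisible named list of written paths.
#' @export
run_characterization <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  needs_aln <- any(c("variation", "haplotype", "phylo") %in% cfg$stages)
  if (needs_aln && is.null(cfg$alignment_fasta)) {
    stop("stages ", paste(intersect(cfg$stages,
                                    c("variation", "haplotype", "phylo")),
                          collapse = "/"),
         " require alignment_fasta")
  }
  needs_genome <- any(c("organize", "composition", "rscu", "repeats")
                      %in% cfg$stages)
  if (needs_genome && is.null(cfg$annotation_tsv)) {
    stop("genome stages require annotation_tsv")
  }
  for (p in c(cfg$genome_fasta, cfg$annotation_tsv, cfg$alignment_fasta)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# mitochar %s\tconfig %s",
                   as.character(utils::packageVersion("mitochar")),
                   config_fingerprint(cfg))
  written <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$outdir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    writer(con)
    close(con)
    written[[name]] <<- path
  }
  write_df <- function(df) function(con) {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  g <- NULL
  if (needs_genome) {
    seq <- if (!is.null(cfg$genome_fasta)) {
      unname(read_genome_fasta(cfg$genome_fasta))
    } else NULL
    L <- if (!is.null(seq)) nchar(seq) else cfg$genome_length
    if (is.null(L)) stop("genome_length required when no genome FASTA is given")
    feats <- read_annotation_table(cfg$annotation_tsv, L)
    g <- circular_genome(seq = seq, features = feats, length = L)
  }

  if ("organize" %in% cfg$stages) {
    rep <- organization_report(g)
    path <- file.path(cfg$outdir, "organization.tsv")
    con <- file(path, "w")
    writeLines(stamp, con)
    close(con)
    con <- file(path, "a")
    utils::write.table(rep$rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(sprintf(
      "# genes\t%d\n# h_strand\t%d\n# l_strand\t%d\n# overlaps\t%d\t%d\t%d\n# spacers\t%d\t%d\t%d",
      rep$gene_count, rep$h_strand_gene_count, rep$l_strand_gene_count,
      rep$overlap_count, rep$overlap_total_bp, rep$overlap_max_bp,
      rep$spacer_count, rep$spacer_total_bp, rep$spacer_max_bp), con)
    close(con)
    written[["organization.tsv"]] <- path
  }
  if ("composition" %in% cfg$stages) {
    if (is.null(g$seq)) stop("composition stage requires a genome FASTA")
    emit("composition.tsv", write_df(composition_table(g)))
  }
  if ("rscu" %in% cfg$stages) {
    if (is.null(g$seq)) stop("rscu stage requires a genome FASTA")
    prof <- codon_profile(g)
    r <- prof$rscu
    emit("codon_rscu.tsv", write_df(data.frame(
      codon = names(r), aa = attr(r, "aa"),
      count = prof$codon_counts[names(r)],
      rscu = round(unname(r), 4), stringsAsFactors = FALSE)))
    emit("pcg_codons.tsv", write_df(prof$genes))
    aa <- prof$aa_percent
    emit("aa_distribution.tsv", write_df(data.frame(
      aa = names(aa), percent = round(as.numeric(aa), 4))))
  }
  if ("repeats" %in% cfg$stages) {
    if (is.null(g$seq)) stop("repeats stage requires a genome FASTA")
    ctrl <- g$features[g$features$gene_class == "control", , drop = FALSE]
    if (!nrow(ctrl)) stop("repeats stage requires a control feature")
    region <- extract_region(g, ctrl[1, ])
    rr <- count_tandem_copies(region, cfg$repeat_motif,
                              max_mismatch_per_copy = cfg$max_mismatch)
    occ <- find_motif_occurrences(region, cfg$repeat_motif)
    emit("repeats.tsv", write_df(data.frame(
      motif = rr$motif, copy_number = rr$copy_number,
      run_start_local = rr$run_start,
      run_start_genome = if (is.na(rr$run_start)) NA_integer_ else
        local_to_genome(rr$run_start, ctrl[1, ], g$length),
      occurrences = length(occ$positions),
      duplication = occ$duplication, stringsAsFactors = FALSE)))
  }

  aln <- NULL
  if (needs_aln) aln <- read_aligned_fasta(cfg$alignment_fasta)
  if ("variation" %in% cfg$stages) {
    sites <- polymorphic_sites(aln)
    m <- unclass(aln)
    site_tab <- data.frame(
      column = sites,
      states = vapply(sites, function(j) {
        b <- m[, j]; b <- b[b %in% MITO_BASES]
        paste(sort(unique(b)), collapse = "/")
      }, character(1)))
    emit("polymorphic_sites.tsv", write_df(site_tab))
    emit("variation_summary.tsv", write_df(data.frame(
      alignment_columns = ncol(aln), samples = nrow(aln),
      polymorphic_sites = length(sites),
      variable_percent = round(variable_fraction(aln), 2))))
  }
  if ("haplotype" %in% cfg$stages) {
    emit("haplotypes.tsv", write_df(classify_haplotypes(aln)))
  }
  if ("phylo" %in% cfg$stages) {
    tree <- bootstrap_support(aln, replicates = cfg$replicates,
                              seed = cfg$seed)
    if (!is.null(cfg$outgroup)) tree <- root_with_outgroup(tree, cfg$outgroup)
    path <- file.path(cfg$outdir, "tree.nwk")
    write_newick(tree, path)
    written[["tree.nwk"]] <- path
    emit("distances.tsv", function(con) {
      D <- tn93_distance_matrix(aln)
      utils::write.table(
        cbind(taxon = rownames(D), as.data.frame(round(unclass(D), 6))),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  invisible(written)
}
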