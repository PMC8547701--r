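# Serialization of a synthetic dataset to standard formats (GFF3, FASTA,
# BED, newick, TSV, JSON) and the matching readers. GFF3 is 1-based
# inclusive, BED 0-based half-open; in-memory tables are 0-based half-open.

#' Write a gene annotation to GFF3
#' @param genes Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @export
write_gene_gff <- function(genes, path) {
  gr <- as_granges0(genes)
  S4Vectors::mcols(gr)$source <- "teecology"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#' @param path GFF3 path.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_gene_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) %>% arrange(.data$chrom, .data$start, .data$gene_id)
}

write_bed0 <- function(df, path, name_col = NULL) {
  out <- df %>% select("chrom", "start", "end")
  if (!is.null(name_col)) out$name <- df[[name_col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

read_bed0 <- function(path, name_col = NULL) {
  cols <- c("chrom", "start", "end", if (!is.null(name_col)) name_col)
  readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
}

#' Write all layers of a synthetic dataset to a directory
#'
#' Emits `te.gff3`, `genes.gff3`, `genome.fa`, `trees/<superfamily>.nwk`,
#' `ltr_alignments.fa` (records `<copy_id>_5LTR` / `<copy_id>_3LTR`),
#' `methylation_windows.tsv`, `te_counts.tsv`, `gene_counts.tsv`,
#' `library_sizes.tsv`, `genetic_map.tsv`, `mnase_<tissue>.bed`,
#' `variants.tsv`, `subgenomes.bed`, `domain_hits.tsv`,
#' `syntenic_genes.txt` and `truth.json` (true ages and the generator
#' config).
#'
#' @param dataset A `synthetic_te_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_te_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  write_te_gff(dataset$te_copies, p("te.gff3"))
  write_gene_gff(dataset$genes, p("genes.gff3"))
  writeLines(dataset$syntenic_ids, p("syntenic_genes.txt"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$genome), p("genome.fa")
  )
  for (sf in names(dataset$trees)) {
    writeLines(dataset$trees[[sf]], p("trees", paste0(sf, ".nwk")))
  }
  if (length(dataset$ltr_alignments) > 0) {
    seqs <- unlist(lapply(names(dataset$ltr_alignments), function(id) {
      setNames(
        dataset$ltr_alignments[[id]],
        paste0(id, c("_5LTR", "_3LTR"))
      )
    }))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), p("ltr_alignments.fa"))
  }
  readr::write_tsv(dataset$methylation, p("methylation_windows.tsv"))
  readr::write_tsv(dataset$expression$te_counts, p("te_counts.tsv"))
  readr::write_tsv(dataset$expression$gene_counts, p("gene_counts.tsv"))
  readr::write_tsv(dataset$expression$library_sizes, p("library_sizes.tsv"))
  readr::write_tsv(dataset$genetic_map, p("genetic_map.tsv"))
  for (t in names(dataset$mnase)) {
    write_bed0(dataset$mnase[[t]], p(paste0("mnase_", t, ".bed")))
  }
  readr::write_tsv(dataset$variants, p("variants.tsv"))
  write_bed0(dataset$subgenomes, p("subgenomes.bed"), name_col = "subgenome")
  readr::write_tsv(dataset$domain_hits, p("domain_hits.tsv"))
  jsonlite::write_json(
    list(
      config = unclass(dataset$config),
      true_ages = dataset$true_ages,
      family_truth = dataset$family_truth
    ),
    p("truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Read back a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list with the same layer names as a `synthetic_te_dataset`
#'   (reconstructed from the serialized files; the generator config and
#'   truth come from `truth.json`).
#' @export
read_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  tissues <- truth$config$tissue_names
  genome_ss <- Biostrings::readDNAStringSet(p("genome.fa"))
  genome <- setNames(as.character(genome_ss), names(genome_ss))
  tree_files <- list.files(p("trees"), pattern = "\\.nwk$", full.names = TRUE)
  trees <- setNames(
    lapply(tree_files, function(f) readLines(f, warn = FALSE)[1]),
    sub("\\.nwk$", "", basename(tree_files))
  )
  mnase_files <- list.files(dir, pattern = "^mnase_.*\\.bed$", full.names = TRUE)
  mnase <- setNames(
    lapply(mnase_files, read_bed0),
    sub("^mnase_(.*)\\.bed$", "\\1", basename(mnase_files))
  )
  list(
    config = truth$config,
    te_copies = read_te_gff(p("te.gff3")),
    genes = read_gene_gff(p("genes.gff3")),
    syntenic_ids = readLines(p("syntenic_genes.txt"), warn = FALSE),
    genome = genome,
    true_ages = as_tibble(truth$true_ages),
    trees = trees,
    ltr_alignments = if (file.exists(p("ltr_alignments.fa"))) {
      read_ltr_alignments(p("ltr_alignments.fa"))
    } else {
      list()
    },
    methylation = readr::read_tsv(p("methylation_windows.tsv"),
                                  show_col_types = FALSE),
    expression = list(
      te_counts = readr::read_tsv(p("te_counts.tsv"), show_col_types = FALSE),
      gene_counts = readr::read_tsv(p("gene_counts.tsv"), show_col_types = FALSE),
      library_sizes = readr::read_tsv(p("library_sizes.tsv"), show_col_types = FALSE)
    ),
    genetic_map = readr::read_tsv(p("genetic_map.tsv"), show_col_types = FALSE),
    mnase = mnase,
    variants = readr::read_tsv(p("variants.tsv"), show_col_types = FALSE),
    subgenomes = read_bed0(p("subgenomes.bed"), name_col = "subgenome"),
    domain_hits = readr::read_tsv(p("domain_hits.tsv"), show_col_types = FALSE)
  )
}
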