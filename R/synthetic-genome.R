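#' Generate a synthetic multi-exon genome and annotation
#'
#' Builds a random but seed-reproducible genome with multi-exon gene models —
#' the fixture substrate for panel design and assay simulation.  Genes are
#' laid out along a single chromosome, separated by intergenic gaps, with
#' random exon and intron lengths and strands; base composition is uniform
#' (GC ~ 0.5) so k-mers are effectively unique at the scales used here.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene (one transcript per gene).
#' @param exon_length_range Integer length-2 vector, inclusive range of exon
#'   lengths in nucleotides.
#' @param intron_length_range Inclusive range of intron lengths.
#' @param intergenic_range Inclusive range of gaps between genes.
#' @param gc GC fraction of the random sequence.
#' @param seed Integer seed; identical arguments and seed give byte-identical
#'   written fixtures.
#' @param chrom Chromosome name.
#'
#' @return An object of class `spet_genome`: list with `genome` (named
#'   character vector of one chromosome), `annotation` (tibble of exon rows:
#'   `gene_id`, `transcript_id`, `exon_index`, `chrom`, `start`, `end`
#'   0-based half-open, `genomic_strand`), and the generation parameters.
#'
#' @seealso [write_synthetic_genome()] to serialize to FASTA + GTF.
#' @examples
#' gx <- generate_synthetic_genome(n_genes = 3, seed = 42)
#' gx$annotation
#' @export
generate_synthetic_genome <- function(n_genes = 5,
                                      exons_per_gene = 4,
                                      exon_length_range = c(100, 200),
                                      intron_length_range = c(100, 500),
                                      intergenic_range = c(200, 500),
                                      gc = 0.5,
                                      seed = 1,
                                      chrom = "chr1") {
  stopifnot(
    n_genes >= 1, exons_per_gene >= 1,
    all(exon_length_range > 0), all(intron_length_range > 0),
    all(intergenic_range > 0)
  )
  set.seed(derive_seed(seed, "genome"))

  rint <- function(r, n = 1L) {
    if (r[1] == r[2]) rep(r[1], n) else sample(seq(r[1], r[2]), n, replace = TRUE)
  }

  rows <- list()
  cursor <- 0L
  for (g in seq_len(n_genes)) {
    cursor <- cursor + rint(intergenic_range)
    strand <- sample(c("+", "-"), 1L)
    ex_len <- rint(exon_length_range, exons_per_gene)
    in_len <- if (exons_per_gene > 1) rint(intron_length_range, exons_per_gene - 1) else integer()
    starts <- integer(exons_per_gene)
    ends <- integer(exons_per_gene)
    p <- cursor
    for (e in seq_len(exons_per_gene)) {
      starts[e] <- p
      ends[e] <- p + ex_len[e]
      p <- ends[e] + if (e < exons_per_gene) in_len[e] else 0L
    }
    cursor <- p
    gid <- sprintf("GENE%03d", g)
    # exon_index runs 5'->3' along the transcript
    idx <- if (strand == "+") seq_len(exons_per_gene) else rev(seq_len(exons_per_gene))
    rows[[g]] <- tibble(
      gene_id = gid,
      transcript_id = paste0(gid, ".t1"),
      exon_index = idx,
      chrom = chrom,
      start = starts,
      end = ends,
      genomic_strand = strand
    )
  }
  ann <- bind_rows(rows)
  total_len <- max(ann$end) + rint(intergenic_range)
  genome <- setNames(random_dna(total_len, gc = gc), chrom)

  structure(
    list(
      genome = genome,
      annotation = arrange(ann, .data$gene_id, .data$exon_index),
      params = list(
        n_genes = n_genes, exons_per_gene = exons_per_gene,
        exon_length_range = exon_length_range,
        intron_length_range = intron_length_range,
        intergenic_range = intergenic_range, gc = gc, seed = seed
      )
    ),
    class = "spet_genome"
  )
}

#' Write a synthetic genome fixture to FASTA + GTF
#'
#' @param x A `spet_genome` from [generate_synthetic_genome()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the `genome` (FASTA) and `annotation`
#'   (GTF) file paths.
#' @export
write_synthetic_genome <- function(x, dir) {
  stopifnot(inherits(x, "spet_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "genes.gtf")

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x$genome), fa, width = 70L
  )

  a <- arrange(x$annotation, .data$start)
  lines <- sprintf(
    '%s\tspetseq\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number "%d";',
    a$chrom, a$start + 1L, a$end, a$genomic_strand,
    a$gene_id, a$transcript_id, a$exon_index
  )
  writeLines(lines, gtf)
  invisible(list(genome = fa, annotation = gtf))
}

#' @export
print.spet_genome <- function(x, ...) {
  cat(
    "<spet_genome> ", x$params$n_genes, " genes x ", x$params$exons_per_gene,
    " exons, chromosome length ", nchar(x$genome[[1]]), " nt\n",
    sep = ""
  )
  invisible(x)
}
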