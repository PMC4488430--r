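#' Parse a gene annotation and splice transcript sequences
#'
#' Reads exon records from a GTF/GFF3 file, orients them 5'→3' along each
#' transcript, and splices per-transcript cDNA sequences from a genome FASTA.
#' Minus-strand transcripts are reverse-complemented so that every spliced
#' sequence reads in the sense (mRNA) direction.  Coordinates are converted to
#' 0-based half-open internally; `exon_index` is 1-based along the transcript.
#'
#' @param annotation_file Path to a GTF or GFF3 file containing `exon`
#'   features with `gene_id` and `transcript_id` attributes.
#' @param sequence_file Path to the genome FASTA. Every chromosome referenced
#'   by the annotation must be present (a missing chromosome is an error).
#' @param gene_list Optional character vector of gene ids to keep. Genes in
#'   the list that are absent from the annotation trigger a warning and are
#'   recorded in the returned object's `missing_genes` field.
#'
#' @return An object of class `spet_annotation`: a list with
#'   * `exons` — tibble of exon records (`gene_id`, `transcript_id`,
#'     `exon_index`, `chrom`, `start`, `end`, `genomic_strand`, `length`,
#'     `tx_start`, `tx_end`), genomic coordinates 0-based half-open,
#'     `tx_start`/`tx_end` the exon's interval in transcript coordinates;
#'   * `transcripts` — tibble (`transcript_id`, `gene_id`, `chrom`,
#'     `genomic_strand`, `seq`, `tx_length`) with spliced sense-strand cDNA;
#'   * `genome` — named character vector of chromosome sequences;
#'   * `missing_genes` — requested gene ids not found.
#'
#' @examples
#' gx <- generate_synthetic_genome(n_genes = 2, seed = 1)
#' paths <- write_synthetic_genome(gx, tempfile("gx"))
#' ann <- parse_annotation(paths$annotation, paths$genome)
#' ann$transcripts
#' @export
parse_annotation <- function(annotation_file, sequence_file, gene_list = NULL) {
  gr <- rtracklayer::import(annotation_file)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) abort("annotation contains no exon features")

  tx_id <- as.character(S4Vectors::mcols(gr)$transcript_id)
  gene_id <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (anyNA(tx_id) || anyNA(gene_id)) {
    abort("every exon needs gene_id and transcript_id attributes")
  }

  ex <- tibble(
    gene_id = gene_id,
    transcript_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    genomic_strand = as.character(GenomicRanges::strand(gr))
  )

  missing_genes <- character()
  if (!is.null(gene_list)) {
    missing_genes <- setdiff(gene_list, unique(ex$gene_id))
    if (length(missing_genes) > 0L) {
      warn(paste0(
        "genes not found in annotation: ",
        paste(missing_genes, collapse = ", ")
      ))
    }
    ex <- filter(ex, .data$gene_id %in% gene_list)
  }

  genome_set <- Biostrings::readDNAStringSet(sequence_file)
  names(genome_set) <- sub("\\s.*$", "", names(genome_set))
  genome <- setNames(as.character(genome_set), names(genome_set))

  missing_chrom <- setdiff(unique(ex$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    abort(paste0(
      "chromosome(s) referenced by annotation but absent from FASTA: ",
      paste(missing_chrom, collapse = ", ")
    ))
  }

  if (nrow(ex) == 0L) {
    return(structure(
      list(
        exons = mutate(ex, exon_index = integer(), length = integer(),
                       tx_start = integer(), tx_end = integer()),
        transcripts = tibble(
          transcript_id = character(), gene_id = character(),
          chrom = character(), genomic_strand = character(),
          seq = character(), tx_length = integer()
        ),
        genome = genome,
        missing_genes = missing_genes
      ),
      class = "spet_annotation"
    ))
  }

  # Orient exons along the transcript (5'->3'): genomic order for + strand,
  # reverse genomic order for - strand; assign exon_index and tx coordinates.
  ex <- ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(ord = if (first(.data$genomic_strand) == "-") rev(row_number()) else row_number()) |>
    ungroup() |>
    arrange(.data$gene_id, .data$transcript_id, .data$ord) |>
    rename(exon_index = "ord") |>
    mutate(length = .data$end - .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(tx_end = cumsum(.data$length), tx_start = .data$tx_end - .data$length) |>
    ungroup()

  exon_seq <- substr(unname(genome[ex$chrom]), ex$start + 1L, ex$end)
  minus <- ex$genomic_strand == "-"
  exon_seq[minus] <- revcomp(exon_seq[minus])

  tx <- ex |>
    mutate(.seq = exon_seq) |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      genomic_strand = first(.data$genomic_strand),
      seq = paste(.seq[order(.data$exon_index)], collapse = ""),
      tx_length = sum(.data$length),
      .groups = "drop"
    ) |>
    arrange(.data$gene_id, .data$transcript_id)

  structure(
    list(
      exons = select(ex, -any_of(".seq")),
      transcripts = tx,
      genome = genome,
      missing_genes = missing_genes
    ),
    class = "spet_annotation"
  )
}

#' @export
print.spet_annotation <- function(x, ...) {
  cat(
    "<spet_annotation> ", length(unique(x$exons$gene_id)), " genes, ",
    length(unique(x$exons$transcript_id)), " transcripts, ",
    nrow(x$exons), " exons on ", length(x$genome), " sequence(s)\n",
    sep = ""
  )
  invisible(x)
}

# Map a transcript coordinate (0-based) of `transcript_id` to its genomic
# coordinate, using the exon table.  Vectorised over `pos`.
transcript_to_genomic <- function(annotation, transcript_id, pos) {
  ex <- filter(annotation$exons, .data$transcript_id == !!transcript_id) |>
    arrange(.data$exon_index)
  if (nrow(ex) == 0L) abort(paste0("unknown transcript: ", transcript_id))
  vapply(pos, function(p) {
    i <- which(p >= ex$tx_start & p < ex$tx_end)
    if (length(i) == 0L) return(NA_real_)
    off <- p - ex$tx_start[i]
    if (ex$genomic_strand[i] == "+") ex$start[i] + off else ex$end[i] - 1L - off
  }, numeric(1))
}
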