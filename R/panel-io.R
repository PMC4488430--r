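#' Write a probe panel to disk
#'
#' Serializes a [design_panel()] manifest to a directory:
#' `probes.fasta` (full probe sequences, tail included), `probes.bed`
#' (0-based half-open probe footprints; strand column is the genome strand
#' the probe sequence matches; score 0), `targets.bed` (per-gene union of
#' probed exon intervals), `targets_tx.tsv` (the same union in transcript
#' coordinates), `panel.tsv` (all probe fields, with design parameters and
#' stats in `#`-prefixed header lines), and `design_report.txt`.
#'
#' @param panel A `spet_panel`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, named vector of written file paths.
#' @seealso [read_panel()] — `read_panel(write_panel(p))` reproduces `p`.
#' @export
write_panel <- function(panel, out_dir) {
  stopifnot(inherits(panel, "spet_panel"))
  if (nrow(panel$probes) == 0L) abort("refusing to write an empty panel")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))

  pr <- panel$probes
  fa <- file.path(out_dir, "probes.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(pr$full_seq, pr$probe_id)), fa, width = 80L
  )

  bed <- file.path(out_dir, "probes.bed")
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    pr$chrom, pr$g_start, pr$g_end, pr$probe_id, pr$genomic_strand
  ), bed)

  tbed <- file.path(out_dir, "targets.bed")
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t0\t.",
    panel$targets$chrom, panel$targets$start, panel$targets$end,
    panel$targets$gene_id
  ), tbed)

  ttx <- file.path(out_dir, "targets_tx.tsv")
  readr::write_tsv(panel$targets_tx, ttx)

  tsv <- file.path(out_dir, "panel.tsv")
  hdr <- c(
    sprintf("# tile_interval=%d", panel$params$tile_interval),
    sprintf("# min_probes_per_exon=%d", panel$params$min_probes_per_exon),
    sprintf("# probe_length=%d", panel$params$probe_length),
    sprintf("# tail_sequence=%s", panel$params$tail_sequence),
    sprintf("# min_exon_length_for_probe=%d", panel$params$min_exon_length_for_probe)
  )
  writeLines(hdr, tsv)
  suppressMessages(readr::write_tsv(pr, tsv, append = TRUE, col_names = TRUE))

  rpt <- file.path(out_dir, "design_report.txt")
  writeLines(c(
    "SPET panel design report",
    sprintf("probes_total: %d", panel$stats$probes_total),
    sprintf("exons_covered: %d", panel$stats$exons_covered),
    sprintf("genes_covered: %d", panel$stats$genes_covered),
    sprintf("undesignable_exons: %d", nrow(panel$undesignable)),
    if (nrow(panel$undesignable) > 0) {
      c("undesignable (gene transcript exon_index length):",
        sprintf(
          "  %s %s %d %d",
          panel$undesignable$gene_id, panel$undesignable$transcript_id,
          panel$undesignable$exon_index, panel$undesignable$length
        ))
    }
  ), rpt)

  invisible(c(
    probes_fasta = fa, probes_bed = bed, targets_bed = tbed,
    targets_tx = ttx, panel_tsv = tsv, report = rpt
  ))
}

#' Read a probe panel written by [write_panel()]
#'
#' @param dir Directory containing `panel.tsv`, `targets.bed` and
#'   `targets_tx.tsv`.
#' @return A `spet_panel` equal (probes, targets, params, stats) to the one
#'   written.
#' @export
read_panel <- function(dir) {
  tsv <- file.path(dir, "panel.tsv")
  if (!file.exists(tsv)) abort(paste0("not a panel directory (no panel.tsv): ", dir))
  hdr <- grep("^# ", readLines(tsv, n = 20L), value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  params <- panel_design_params(
    tile_interval = as.integer(vals[["tile_interval"]]),
    min_probes_per_exon = as.integer(vals[["min_probes_per_exon"]]),
    probe_length = as.integer(vals[["probe_length"]]),
    tail_sequence = vals[["tail_sequence"]],
    min_exon_length_for_probe = as.integer(vals[["min_exon_length_for_probe"]])
  )
  probes <- readr::read_tsv(
    tsv, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      exon_index = readr::col_integer(), anchor_pos = readr::col_integer(),
      fp_start = readr::col_integer(), fp_end = readr::col_integer(),
      g_start = readr::col_integer(), g_end = readr::col_integer(),
      genomic_anchor = readr::col_integer(), .default = readr::col_character()
    )
  )
  tb <- readr::read_tsv(
    file.path(dir, "targets.bed"), col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    show_col_types = FALSE
  )
  targets <- tb |>
    transmute(
      gene_id = .data$gene_id, chrom = .data$chrom,
      start = as.integer(.data$start), end = as.integer(.data$end)
    ) |>
    arrange(.data$gene_id, .data$start)
  targets_tx <- readr::read_tsv(
    file.path(dir, "targets_tx.tsv"), show_col_types = FALSE,
    col_types = readr::cols(
      tx_start = readr::col_integer(), tx_end = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  new_spet_panel(probes, targets, targets_tx, params, empty_undesignable_tbl())
}

empty_undesignable_tbl <- function() {
  tibble(
    gene_id = character(), transcript_id = character(),
    exon_index = integer(), length = integer()
  )
}
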