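#' Panel design parameters
#'
#' Parameters controlling SPET probe placement.  The design rules are:
#' every designable exon receives two boundary probes — one per strand of the
#' double-stranded cDNA, each with its 3' end at an exon edge so that
#' polymerase extension crosses the adjacent exon-exon (or fusion) junction —
#' and exons longer than `tile_interval` additionally receive probes tiled at
#' `tile_interval` anchor spacing on both strands.
#'
#' @param tile_interval Anchor spacing for interior tiling, nucleotides.
#' @param min_probes_per_exon Minimum probes per designable exon.
#' @param probe_length Exonic probe footprint length, nucleotides.
#' @param tail_sequence Constant tail prepended to every probe (a universal
#'   priming site for library amplification).
#' @param min_exon_length_for_probe Exons shorter than this get no probes and
#'   are recorded as undesignable; defaults to `probe_length`.
#' @return A list of class `spet_design_params`.
#' @export
panel_design_params <- function(tile_interval = 300L,
                                min_probes_per_exon = 2L,
                                probe_length = 40L,
                                tail_sequence = "ACACGACGCTCTTCCGATCT",
                                min_exon_length_for_probe = probe_length) {
  stopifnot(
    tile_interval > 0, probe_length > 0, min_probes_per_exon >= 1,
    grepl("^[ACGT]+$", tail_sequence)
  )
  structure(
    list(
      tile_interval = as.integer(tile_interval),
      min_probes_per_exon = as.integer(min_probes_per_exon),
      probe_length = as.integer(probe_length),
      tail_sequence = tail_sequence,
      min_exon_length_for_probe = as.integer(min_exon_length_for_probe)
    ),
    class = "spet_design_params"
  )
}

# Map a transcript-coordinate interval inside one exon to genomic coordinates.
exon_tx_to_genomic <- function(exon, fs, fe) {
  if (exon$genomic_strand == "+") {
    c(exon$start + (fs - exon$tx_start), exon$start + (fe - exon$tx_start))
  } else {
    c(exon$end - (fe - exon$tx_start), exon$end - (fs - exon$tx_start))
  }
}

exon_tx_pos_to_genomic <- function(exon, pos) {
  if (exon$genomic_strand == "+") {
    exon$start + (pos - exon$tx_start)
  } else {
    exon$end - 1L - (pos - exon$tx_start)
  }
}

#' Design probes for a single exon
#'
#' Emits the two outward-pointing boundary probes (one on each strand of the
#' ds-cDNA) and, for exons longer than the tile interval, additional tile
#' probes at `tile_interval` anchor offsets from the exon's transcript-5' end
#' on both strands.  A tile whose footprint would leave the exon, or which
#' duplicates a boundary probe, is skipped.  An exon shorter than the probe
#' footprint yields zero rows (the caller records it as undesignable).
#'
#' Probe orientation convention: a probe hybridizing to the *antisense*
#' strand of the ds-cDNA reads as the sense (mRNA) sequence and its
#' polymerase extension runs toward the transcript 3' end; a probe
#' hybridizing to the *sense* strand is the reverse complement and extends
#' toward the transcript 5' end.  `anchor_pos` is the 0-based transcript
#' coordinate of the probe's 3'-terminal base.
#'
#' @param exon One exon row as produced by [parse_annotation()] (needs
#'   `tx_start`, `tx_end`, genomic coordinates and strand).
#' @param transcript_seq Spliced sense-strand transcript sequence.
#' @param params A [panel_design_params()] object.
#' @return Tibble of probe specifications (possibly 0 rows).
#' @export
design_probes_for_exon <- function(exon, transcript_seq, params = panel_design_params()) {
  if (is_tibble(exon)) exon <- as.list(exon[1, ])
  cand <- probe_candidates(exon$tx_start, exon$tx_end, params)
  if (length(cand$anchor) == 0L) {
    return(empty_probe_tbl())
  }
  assemble_probes(exon_rows = as_tibble(exon[c(
    "gene_id", "transcript_id", "exon_index", "chrom", "start", "end",
    "genomic_strand", "tx_start"
  )])[rep(1L, length(cand$anchor)), ], cand = cand,
  transcript_seq = rep(transcript_seq, length(cand$anchor)), params = params)
}

# Anchor/footprint candidates for one exon [ts, te) in transcript
# coordinates: the two boundary probes plus tile probes on both strands,
# minus tiles whose footprint leaves the exon or that duplicate a boundary
# probe.  Returns parallel vectors.
probe_candidates <- function(ts, te, params) {
  L <- params$probe_length
  exon_len <- te - ts
  if (exon_len < max(L, params$min_exon_length_for_probe)) {
    return(list(strand = character(), anchor = integer(), fs = integer(),
                fe = integer(), origin = character()))
  }
  strand <- c("antisense", "sense")
  anchor <- c(te - 1L, ts)
  fs <- c(te - L, ts)
  fe <- c(te, ts + L)
  origin <- c("boundary_3prime", "boundary_5prime")
  if (exon_len > params$tile_interval) {
    d <- seq.int(params$tile_interval, exon_len - 1L, by = params$tile_interval)
    p <- ts + d
    ka <- p - L + 1L >= ts
    ks <- p + L <= te
    strand <- c(strand, rep("antisense", sum(ka)), rep("sense", sum(ks)))
    anchor <- c(anchor, p[ka], p[ks])
    fs <- c(fs, p[ka] - L + 1L, p[ks])
    fe <- c(fe, p[ka] + 1L, p[ks] + L)
    origin <- c(origin, rep("tile", sum(ka) + sum(ks)))
  }
  keep <- !duplicated(paste0(strand, ":", anchor))
  list(strand = strand[keep], anchor = as.integer(anchor[keep]),
       fs = as.integer(fs[keep]), fe = as.integer(fe[keep]),
       origin = origin[keep])
}

# Vectorized probe-record assembly; `exon_rows` has one row per candidate.
assemble_probes <- function(exon_rows, cand, transcript_seq, params) {
  L <- params$probe_length
  sense_seq <- unname(substr(transcript_seq, cand$fs + 1L, cand$fe))
  anti <- cand$strand == "antisense"
  probe_seq <- sense_seq
  if (any(!anti)) probe_seq[!anti] <- revcomp(sense_seq[!anti])

  plus <- exon_rows$genomic_strand == "+"
  off_s <- cand$fs - exon_rows$tx_start
  off_e <- cand$fe - exon_rows$tx_start
  g_start <- ifelse(plus, exon_rows$start + off_s, exon_rows$end - off_e)
  genomic_anchor <- ifelse(
    plus,
    exon_rows$start + (cand$anchor - exon_rows$tx_start),
    exon_rows$end - 1L - (cand$anchor - exon_rows$tx_start)
  )
  tibble(
    probe_id = sprintf("%s_%s_%d", exon_rows$gene_id,
                       ifelse(anti, "A", "S"), genomic_anchor),
    gene_id = exon_rows$gene_id,
    transcript_id = exon_rows$transcript_id,
    exon_index = exon_rows$exon_index,
    chrom = exon_rows$chrom,
    cdna_strand = cand$strand,
    origin = cand$origin,
    anchor_pos = cand$anchor,
    fp_start = cand$fs,
    fp_end = cand$fe,
    g_start = as.integer(g_start),
    g_end = as.integer(g_start + L),
    genomic_anchor = as.integer(genomic_anchor),
    genomic_strand = ifelse(xor(anti, exon_rows$genomic_strand == "-"), "+", "-"),
    probe_seq = probe_seq,
    full_seq = paste0(params$tail_sequence, probe_seq)
  )
}

empty_probe_tbl <- function() {
  tibble(
    probe_id = character(), gene_id = character(), transcript_id = character(),
    exon_index = integer(), chrom = character(), cdna_strand = character(),
    origin = character(), anchor_pos = integer(), fp_start = integer(),
    fp_end = integer(), g_start = integer(), g_end = integer(),
    genomic_anchor = integer(), genomic_strand = character(),
    probe_seq = character(), full_seq = character()
  )
}

#' Design a SPET probe panel from an annotation
#'
#' Runs [design_probes_for_exon()] over every exon of the annotation (or of a
#' gene subset), deduplicates probes shared between isoforms on their full
#' sequence (tail + footprint), and assembles the panel manifest with target
#' intervals and design statistics.  Output ordering is deterministic
#' (`gene_id`, `genomic_anchor`, `cdna_strand`).
#'
#' @param annotation A `spet_annotation` from [parse_annotation()].
#' @param params A [panel_design_params()] object.
#' @param genes Optional gene subset to design against.
#' @return An object of class `spet_panel`: list with `probes` (tibble),
#'   `targeted_genes`, `targets` (per-gene union of probed exon genomic
#'   intervals), `targets_tx` (the same union in transcript coordinates,
#'   used by the on-target metric), `params`, `stats` and `undesignable`
#'   (exons too short to carry a probe).
#' @export
design_panel <- function(annotation, params = panel_design_params(), genes = NULL) {
  stopifnot(inherits(annotation, "spet_annotation"))
  ex <- annotation$exons
  if (!is.null(genes)) ex <- filter(ex, .data$gene_id %in% genes)
  if (nrow(ex) == 0L) abort("no exons to design against")
  txseq <- setNames(annotation$transcripts$seq, annotation$transcripts$transcript_id)

  min_len <- max(params$probe_length, params$min_exon_length_for_probe)
  designable <- ex$length >= min_len
  undesignable <- ex[!designable, c("gene_id", "transcript_id", "exon_index", "length")]

  des <- ex[designable, ]
  cands <- lapply(seq_len(nrow(des)), function(i) {
    probe_candidates(des$tx_start[i], des$tx_end[i], params)
  })
  nc <- vapply(cands, function(x) length(x$anchor), 0L)
  cand <- list(
    strand = unlist(lapply(cands, `[[`, "strand")),
    anchor = unlist(lapply(cands, `[[`, "anchor")),
    fs = unlist(lapply(cands, `[[`, "fs")),
    fe = unlist(lapply(cands, `[[`, "fe")),
    origin = unlist(lapply(cands, `[[`, "origin"))
  )
  rows <- rep(seq_len(nrow(des)), nc)
  probes <- assemble_probes(
    exon_rows = des[rows, ], cand = cand,
    transcript_seq = txseq[des$transcript_id[rows]], params = params
  )

  if (nrow(probes) == 0L) abort("no designable exons: every exon is shorter than the probe footprint")

  probes <- probes |>
    arrange(.data$gene_id, .data$genomic_anchor, .data$cdna_strand) |>
    distinct(.data$full_seq, .keep_all = TRUE)

  probed_exons <- semi_join(
    mutate(ex[designable, ], exon_key = paste(.data$transcript_id, .data$exon_index)),
    mutate(probes, exon_key = paste(.data$transcript_id, .data$exon_index)),
    by = "exon_key"
  )

  targets <- probed_exons |>
    group_by(.data$gene_id, .data$chrom) |>
    reframe({
      r <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1L, end = .data$end))
      tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    arrange(.data$gene_id, .data$start)

  targets_tx <- probed_exons |>
    group_by(.data$transcript_id, .data$gene_id) |>
    reframe({
      r <- IRanges::reduce(IRanges::IRanges(start = .data$tx_start + 1L, end = .data$tx_end))
      tibble(tx_start = IRanges::start(r) - 1L, tx_end = IRanges::end(r))
    }) |>
    arrange(.data$transcript_id, .data$tx_start)

  new_spet_panel(probes, targets, targets_tx, params, as_tibble(undesignable))
}

new_spet_panel <- function(probes, targets, targets_tx, params, undesignable) {
  structure(
    list(
      probes = probes,
      targeted_genes = sort(unique(probes$gene_id)),
      targets = targets,
      targets_tx = targets_tx,
      params = params,
      stats = list(
        probes_total = nrow(probes),
        exons_covered = nrow(distinct(probes, .data$transcript_id, .data$exon_index)),
        genes_covered = length(unique(probes$gene_id))
      ),
      undesignable = undesignable
    ),
    class = "spet_panel"
  )
}

#' @export
print.spet_panel <- function(x, ...) {
  cat(
    "<spet_panel> ", x$stats$probes_total, " probes over ",
    x$stats$exons_covered, " exons in ", x$stats$genes_covered, " genes",
    if (nrow(x$undesignable) > 0) paste0(" (", nrow(x$undesignable), " undesignable exons)"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname design_panel
#' @param x A `spet_panel`.
#' @param ... Unused.
#' @export
tidy.spet_panel <- function(x, ...) x$probes

#' @rdname design_panel
#' @export
glance.spet_panel <- function(x, ...) {
  tibble(
    probes_total = x$stats$probes_total,
    exons_covered = x$stats$exons_covered,
    genes_covered = x$stats$genes_covered,
    undesignable_exons = nrow(x$undesignable),
    probe_length = x$params$probe_length,
    tile_interval = x$params$tile_interval
  )
}

#' Probe map plot for a designed panel
#'
#' Draws each probe as an arrow at its transcript-coordinate anchor, pointing
#' in its extension direction, one facet per gene.
#'
#' @param object A `spet_panel`.
#' @param ... Unused.
#' @export
autoplot.spet_panel <- function(object, ...) {
  pr <- object$probes |>
    mutate(
      y = ifelse(.data$cdna_strand == "antisense", 1, -1),
      xend = .data$anchor_pos + ifelse(.data$cdna_strand == "antisense", 15, -15)
    )
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$anchor_pos, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$y, colour = .data$origin),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(~gene_id, scales = "free_x") +
    ggplot2::scale_y_continuous(
      breaks = c(-1, 1), labels = c("sense", "antisense"), limits = c(-2, 2)
    ) +
    ggplot2::labs(
      x = "transcript coordinate (nt)", y = "cDNA strand hybridized",
      colour = "probe origin"
    ) +
    ggplot2::theme_minimal()
}
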