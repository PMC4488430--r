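#' Library simulation configuration
#'
#' Collects the knobs of the in-silico SPET library: input molecule count
#' (the abstraction of RNA mass), per-transcript abundances, fragment-length
#' distribution, FFPE mode, read geometry and sequencing error.
#'
#' Fragment lengths are log-normal with the given arithmetic mean/sd,
#' truncated to the transcript.  Fresh-tissue defaults are mean 400 sd 100;
#' `ffpe_mode = TRUE` switches the defaults to mean 200 sd 80, emulating the
#' shorter inserts of formalin-fixed, paraffin-embedded RNA.  Explicitly
#' supplied mean/sd override the mode defaults.
#'
#' @param n_molecules Number of ds-cDNA molecules fragmented into the library.
#' @param abundances Optional named numeric vector of per-transcript weights
#'   (default: equal). Weights are multiplied by transcript length when
#'   allocating fragments.
#' @param fragment_length_mean,fragment_length_sd Fragment length moments in
#'   nucleotides, or `NULL` for the mode default.
#' @param ffpe_mode Logical; use FFPE-style short-fragment defaults.
#' @param read_length Read length of both mates (the assay uses 75 or 100).
#' @param error_rate Per-base substitution probability applied i.i.d. at
#'   sequencing.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param adapter Adapter sequence; ligated (abstractly) to fragment ends and
#'   used to 3'-pad reads from molecules shorter than `read_length`.
#' @param probe_in_read If `TRUE`, R1 starts at the probe's 5' end so the
#'   probe footprint itself is sequenced; the default places the sequencing
#'   primer at the probe/insert junction so R1 begins immediately 3' of the
#'   probe.
#' @return A list of class `spet_library_config`.
#' @export
library_config <- function(n_molecules = 20000,
                           abundances = NULL,
                           fragment_length_mean = NULL,
                           fragment_length_sd = NULL,
                           ffpe_mode = FALSE,
                           read_length = 100L,
                           error_rate = 0,
                           seed = 1L,
                           adapter = "AGATCGGAAGAGC",
                           probe_in_read = FALSE) {
  stopifnot(
    n_molecules >= 0, read_length > 0, error_rate >= 0, error_rate < 1,
    grepl("^[ACGT]+$", adapter)
  )
  if (!is.null(abundances)) {
    stopifnot(all(abundances >= 0), any(abundances > 0), !is.null(names(abundances)))
  }
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      abundances = abundances,
      fragment_length_mean = fragment_length_mean %||% (if (ffpe_mode) 200 else 400),
      fragment_length_sd = fragment_length_sd %||% (if (ffpe_mode) 80 else 100),
      ffpe_mode = isTRUE(ffpe_mode),
      read_length = as.integer(read_length),
      error_rate = error_rate,
      seed = as.integer(seed),
      adapter = adapter,
      probe_in_read = isTRUE(probe_in_read)
    ),
    class = "spet_library_config"
  )
}

#' Build simulation transcript models from an annotation
#'
#' One row per transcript: spliced sequence, exon boundaries in transcript
#' coordinates, and a segment map from the model's coordinates back to the
#' reference transcript it was built from (the identity map for non-fusion
#' transcripts).  Fusion rows created by [build_fusion_transcript()] can be
#' appended with `bind_rows()`.
#'
#' @param annotation A `spet_annotation`.
#' @return Tibble of transcript models.
#' @export
transcript_models <- function(annotation) {
  stopifnot(inherits(annotation, "spet_annotation"))
  tx <- annotation$transcripts
  bounds <- annotation$exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$exon_index, .by_group = TRUE) |>
    summarise(exon_boundaries = list(cumsum(.data$length)), .groups = "drop")
  tx |>
    left_join(bounds, by = "transcript_id") |>
    transmute(
      transcript_id = .data$transcript_id,
      gene_id = .data$gene_id,
      seq = .data$seq,
      tx_length = .data$tx_length,
      exon_boundaries = .data$exon_boundaries,
      is_fusion = FALSE,
      gene5_id = NA_character_,
      gene3_id = NA_character_,
      junction_pos = NA_integer_,
      junction_left = NA_integer_,
      in_frame = NA,
      segments = map2(.data$transcript_id, .data$tx_length, function(id, len) {
        tibble(
          src_transcript_id = id, src_start = 0L, src_end = as.integer(len),
          dst_start = 0L, dst_end = as.integer(len)
        )
      })
    )
}

#' Build a fusion transcript joining two transcript models
#'
#' The fused transcript keeps exons 1..`exon5` of the 5' partner and exons
#' `exon3`..end of the 3' partner; the breakpoint transcript coordinate
#' (`junction_pos`) equals the summed length of the retained 5'-partner
#' exons.  Without CDS metadata the reading-frame status is unknown
#' (`in_frame = NA`).
#'
#' @param models Transcript model tibble from [transcript_models()].
#' @param transcript5 Transcript id of the 5' partner.
#' @param exon5 Last exon index retained from the 5' partner.
#' @param transcript3 Transcript id of the 3' partner.
#' @param exon3 First exon index retained from the 3' partner.
#' @param fusion_id Id for the fused transcript (also used as its gene id).
#' @return A one-row transcript model tibble (`is_fusion = TRUE`).
#' @export
build_fusion_transcript <- function(models, transcript5, exon5, transcript3, exon3,
                                    fusion_id = NULL) {
  m5 <- filter(models, .data$transcript_id == transcript5, !.data$is_fusion)
  m3 <- filter(models, .data$transcript_id == transcript3, !.data$is_fusion)
  if (nrow(m5) != 1L) abort(paste0("unknown 5' transcript: ", transcript5))
  if (nrow(m3) != 1L) abort(paste0("unknown 3' transcript: ", transcript3))
  b5 <- m5$exon_boundaries[[1]]
  b3 <- m3$exon_boundaries[[1]]
  if (exon5 < 1 || exon5 > length(b5)) abort("exon5 out of range")
  if (exon3 < 1 || exon3 > length(b3)) abort("exon3 out of range")

  junction <- b5[exon5]
  off3 <- if (exon3 == 1L) 0L else b3[exon3 - 1L]
  # leftmost-equivalent representation of the junction: when the bases just
  # 5' of the breakpoint are shared between the partners the junction can
  # slide; the canonical (5'-most) position is what split-read evidence
  # resolves to
  jl <- junction
  ql <- off3
  while (jl > 0L && ql > 0L &&
         substr(m5$seq, jl, jl) == substr(m3$seq, ql, ql)) {
    jl <- jl - 1L
    ql <- ql - 1L
  }
  len3 <- m3$tx_length - off3
  seq <- paste0(
    subseq0(m5$seq, 0L, junction),
    subseq0(m3$seq, off3, m3$tx_length)
  )
  fusion_id <- fusion_id %||% paste0(m5$gene_id, "-", m3$gene_id)

  tibble(
    transcript_id = fusion_id,
    gene_id = fusion_id,
    seq = seq,
    tx_length = junction + len3,
    exon_boundaries = list(c(b5[seq_len(exon5)], junction + (b3[exon3:length(b3)] - off3))),
    is_fusion = TRUE,
    gene5_id = m5$gene_id,
    gene3_id = m3$gene_id,
    junction_pos = as.integer(junction),
    junction_left = as.integer(jl),
    in_frame = NA,
    segments = list(tibble(
      src_transcript_id = c(transcript5, transcript3),
      src_start = c(0L, as.integer(off3)),
      src_end = c(as.integer(junction), as.integer(m3$tx_length)),
      dst_start = c(0L, as.integer(junction)),
      dst_end = c(as.integer(junction), as.integer(junction + len3))
    ))
  )
}

#' Fragment transcripts into adapter-ligated ds-cDNA
#'
#' Allocates `n_molecules` fragments across transcripts by a multinomial in
#' abundance x length, draws log-normal fragment lengths truncated to the
#' transcript, and places each fragment uniformly.  Both fragment ends are
#' considered adapter-ligated.
#'
#' @param models Transcript model tibble (may include fusion rows).
#' @param config A [library_config()].
#' @return Tibble of fragments (`fragment_id`, `transcript_id`, `start`,
#'   `end`), coordinates 0-based half-open on the model transcript.
#' @export
simulate_fragments <- function(models, config) {
  stopifnot(inherits(config, "spet_library_config"))
  set.seed(derive_seed(config$seed, "fragments"))
  if (config$n_molecules == 0L || nrow(models) == 0L) {
    return(tibble(
      fragment_id = integer(), transcript_id = character(),
      start = integer(), end = integer()
    ))
  }
  ab <- rep(1, nrow(models))
  if (!is.null(config$abundances)) {
    ab <- config$abundances[models$transcript_id]
    ab[is.na(ab)] <- 0
  }
  w <- ab * models$tx_length
  if (all(w == 0)) abort("all transcript weights are zero")
  counts <- as.vector(rmultinom(1L, config$n_molecules, w))

  idx <- rep(seq_len(nrow(models)), counts)
  n <- length(idx)
  m <- config$fragment_length_mean
  s <- config$fragment_length_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  flen <- pmin(pmax(round(rlnorm(n, meanlog, sdlog)), 1L), models$tx_length[idx])
  start <- floor(runif(n) * (models$tx_length[idx] - flen + 1L))
  tibble(
    fragment_id = seq_len(n),
    transcript_id = models$transcript_id[idx],
    start = as.integer(start),
    end = as.integer(start + flen)
  )
}

# Map panel probes onto each model transcript via its segment map: a probe
# instance is the probe footprint expressed in model coordinates.
probe_instances <- function(models, panel) {
  segs <- models |>
    select("transcript_id", "segments") |>
    tidyr::unnest("segments") |>
    rename(model_transcript_id = "transcript_id")
  pr <- panel$probes |>
    select("probe_id", src_transcript_id = "transcript_id", "cdna_strand",
           "fp_start", "fp_end")
  inner_join(segs, pr, by = "src_transcript_id", relationship = "many-to-many") |>
    filter(.data$fp_start >= .data$src_start, .data$fp_end <= .data$src_end) |>
    mutate(
      m_fp_start = .data$fp_start - .data$src_start + .data$dst_start,
      m_fp_end = .data$fp_end - .data$src_start + .data$dst_start
    ) |>
    select("model_transcript_id", "probe_id", "cdna_strand", "m_fp_start", "m_fp_end")
}

#' Probe capture and polymerase extension
#'
#' A fragment is captured iff it fully contains the footprint of at least
#' one panel probe (error-free hybridization); when several probes are
#' eligible one is chosen uniformly at random.  The captured molecule is the
#' extension product running from the probe's 3' end to the fragment's
#' adapter-ligated end: downstream (transcript 3') of the anchor for
#' antisense-strand probes, upstream for sense-strand probes.  Uncaptured
#' fragments are discarded (perfect washing).
#'
#' @param fragments Fragment tibble from [simulate_fragments()].
#' @param models Transcript model tibble.
#' @param panel A `spet_panel`.
#' @param config A [library_config()].
#' @return Tibble of captured molecules: provenance plus the insert interval
#'   `ins_start`/`ins_end` (model transcript coordinates, probe footprint
#'   excluded unless `probe_in_read`) and `direction` (`+` when the read
#'   runs toward the transcript 3' end).
#' @export
capture_and_extend <- function(fragments, models, panel, config) {
  stopifnot(inherits(panel, "spet_panel"), inherits(config, "spet_library_config"))
  if (nrow(panel$probes) == 0L) abort("panel has no probes")
  set.seed(derive_seed(config$seed, "capture"))
  inst <- probe_instances(models, panel)
  hits <- inner_join(
    fragments, inst,
    by = c(transcript_id = "model_transcript_id"),
    relationship = "many-to-many"
  ) |>
    filter(.data$m_fp_start >= .data$start, .data$m_fp_end <= .data$end)
  if (nrow(hits) == 0L) {
    return(empty_captured_tbl())
  }
  chosen <- hits |>
    group_by(.data$fragment_id) |>
    slice_sample(n = 1L) |>
    ungroup() |>
    arrange(.data$fragment_id)

  out <- chosen |>
    mutate(
      direction = ifelse(.data$cdna_strand == "antisense", "+", "-"),
      ins_start = ifelse(
        .data$cdna_strand == "antisense",
        if (config$probe_in_read) .data$m_fp_start else .data$m_fp_end,
        .data$start
      ),
      ins_end = ifelse(
        .data$cdna_strand == "antisense",
        .data$end,
        if (config$probe_in_read) .data$m_fp_end else .data$m_fp_start
      )
    ) |>
    filter(.data$ins_end > .data$ins_start) |>
    mutate(molecule_id = row_number()) |>
    select(
      "molecule_id", "fragment_id", "transcript_id", frag_start = "start",
      frag_end = "end", "probe_id", "cdna_strand", "direction",
      "ins_start", "ins_end"
    )
  out
}

empty_captured_tbl <- function() {
  tibble(
    molecule_id = integer(), fragment_id = integer(), transcript_id = character(),
    frag_start = integer(), frag_end = integer(), probe_id = character(),
    cdna_strand = character(), direction = character(),
    ins_start = integer(), ins_end = integer()
  )
}

pad_to_length <- function(x, len, adapter) {
  need <- len - nchar(x)
  pad_src <- strrep(adapter, ceiling(len / nchar(adapter)) + 1L)
  ifelse(need > 0, paste0(x, substr(rep(pad_src, length(x)), 1L, need)), x)
}

# Junction overhang observable from a read: insert overhang extended by any
# 3'-padding adapter bases that coincidentally match the reference
# continuation past the open (padded) end of the insert.
observed_overhang <- function(seq, J, a, b, open, read_length, adapter) {
  # a,b: covered insert interval; open: "upper"/"lower"/"none"
  pad <- read_length - (b - a)
  if (pad > 0 && open != "none") {
    pad_src <- strrep(adapter, ceiling(read_length / nchar(adapter)) + 1L)
    if (open == "upper") {
      lim <- min(pad, nchar(seq) - b)
      i <- 0L
      while (i < lim &&
             substr(pad_src, i + 1L, i + 1L) == substr(seq, b + i + 1L, b + i + 1L)) {
        i <- i + 1L
      }
      b <- b + i
    } else {
      comp <- chartr("ACGT", "TGCA", pad_src)
      lim <- min(pad, a)
      i <- 0L
      while (i < lim &&
             substr(comp, i + 1L, i + 1L) == substr(seq, a - i, a - i)) {
        i <- i + 1L
      }
      a <- a - i
    }
  }
  if (a < J && J < b) min(J - a, b - J) else 0L
}

#' Emit paired-end FASTQ with ground-truth provenance
#'
#' R1 begins at the probe's 3'-end position and reads in the extension
#' direction (the probe footprint itself is not sequenced unless the library
#' was configured with `probe_in_read`); R2 reads inward from the
#' adapter-ligated fragment end.  Substitution errors are applied i.i.d. at
#' `error_rate`; molecules shorter than the read length are 3'-padded with
#' adapter sequence; base qualities are constant.  The truth table (also
#' written as TSV) records, per read pair, the source molecule, probe, and —
#' for fusion molecules — the junction overhang observable in each mate
#' (insert overhang plus any padding bases that match the reference
#' continuation), all computed before sequencing errors.
#'
#' @param captured Captured molecules from [capture_and_extend()].
#' @param models Transcript model tibble.
#' @param config A [library_config()].
#' @param out_dir Directory for `reads_1.fastq`, `reads_2.fastq`, `truth.tsv`.
#' @return Invisibly, list with file paths and the truth tibble.
#' @export
emit_fastq <- function(captured, models, config, out_dir) {
  stopifnot(inherits(config, "spet_library_config"))
  if (nrow(captured) == 0L) {
    abort(paste0(
      "no captured molecules to sequence: either no fragment contained a ",
      "full probe footprint or the panel does not target the expressed ",
      "transcripts"
    ))
  }
  set.seed(derive_seed(config$seed, "emit"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  RL <- config$read_length

  mrow <- match(captured$transcript_id, models$transcript_id)
  seqs <- models$seq[mrow]
  is_fus <- models$is_fusion[mrow]
  # junction overhangs are measured at the leftmost-equivalent breakpoint,
  # the canonical position split-read evidence resolves to
  Js <- if ("junction_left" %in% names(models)) {
    dplyr::coalesce(models$junction_left[mrow], models$junction_pos[mrow])
  } else {
    models$junction_pos[mrow]
  }
  genes <- models$gene_id[mrow]

  a <- captured$ins_start
  b <- captured$ins_end
  fwd <- captured$direction == "+"

  # covered insert intervals per mate
  r1_a <- ifelse(fwd, a, pmax(a, b - RL))
  r1_b <- ifelse(fwd, pmin(b, a + RL), b)
  r2_a <- ifelse(fwd, pmax(a, b - RL), a)
  r2_b <- ifelse(fwd, b, pmin(b, a + RL))

  r1_raw <- ifelse(fwd,
    subseq0(seqs, r1_a, r1_b),
    revcomp(subseq0(seqs, r1_a, r1_b))
  )
  r2_raw <- ifelse(fwd,
    revcomp(subseq0(seqs, r2_a, r2_b)),
    subseq0(seqs, r2_a, r2_b)
  )
  r1 <- pad_to_length(r1_raw, RL, config$adapter)
  r2 <- pad_to_length(r2_raw, RL, config$adapter)

  r1_ov <- integer(nrow(captured))
  r2_ov <- integer(nrow(captured))
  fi <- which(is_fus & !is.na(Js))
  for (i in fi) {
    r1_ov[i] <- observed_overhang(
      seqs[i], Js[i], r1_a[i], r1_b[i],
      open = if (fwd[i]) "upper" else "lower", RL, config$adapter
    )
    r2_ov[i] <- observed_overhang(
      seqs[i], Js[i], r2_a[i], r2_b[i],
      open = if (fwd[i]) "lower" else "upper", RL, config$adapter
    )
  }
  spans <- r1_ov > 0L | r2_ov > 0L

  ids <- sprintf(
    "M%06d|tx=%s|pb=%s|fs=%d|fe=%d|sj=%d",
    captured$molecule_id, captured$transcript_id, captured$probe_id,
    captured$frag_start, captured$frag_end, as.integer(spans)
  )

  if (config$error_rate > 0) {
    r1 <- add_substitution_errors(r1, config$error_rate)
    r2 <- add_substitution_errors(r2, config$error_rate)
  }

  qual <- strrep("I", RL)
  r1_path <- file.path(out_dir, "reads_1.fastq")
  r2_path <- file.path(out_dir, "reads_2.fastq")
  writeLines(as.vector(rbind(paste0("@", ids), r1, "+", qual)), r1_path)
  writeLines(as.vector(rbind(paste0("@", ids), r2, "+", qual)), r2_path)

  truth <- tibble(
    read_id = ids,
    transcript_id = captured$transcript_id,
    gene_id = genes,
    is_fusion = is_fus,
    probe_id = captured$probe_id,
    cdna_strand = captured$cdna_strand,
    frag_start = captured$frag_start,
    frag_end = captured$frag_end,
    ins_start = captured$ins_start,
    ins_end = captured$ins_end,
    junction_pos = Js,
    r1_overhang = r1_ov,
    r2_overhang = r2_ov,
    spans_junction = spans
  )
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(truth, truth_path)
  invisible(list(r1 = r1_path, r2 = r2_path, truth_path = truth_path, truth = truth))
}

add_substitution_errors <- function(reads, rate) {
  n <- length(reads)
  L <- nchar(reads[1])
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)), nrow = L)
  hit <- which(runif(n * L) < rate)
  if (length(hit) > 0L) {
    alt <- matrix(c(
      "C", "G", "T",  # A ->
      "A", "G", "T",  # C ->
      "A", "C", "T",  # G ->
      "A", "C", "G"   # T ->
    ), nrow = 3L)
    base_idx <- match(mat[hit], c("A", "C", "G", "T"))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    mat[hit] <- alt[cbind(pick, base_idx)]
  }
  apply(mat, 2L, paste, collapse = "")
}

#' Decode simulator read ids back to their provenance fields
#'
#' @param ids Character vector of read ids as written by [emit_fastq()].
#' @return Tibble with `molecule`, `transcript_id`, `probe_id`,
#'   `frag_start`, `frag_end`, `spans_junction`.
#' @export
parse_read_ids <- function(ids) {
  parts <- stringr::str_match(
    ids, "^M(\\d+)\\|tx=([^|]+)\\|pb=([^|]+)\\|fs=(\\d+)\\|fe=(\\d+)\\|sj=([01])$"
  )
  if (anyNA(parts[, 1])) abort("read id does not follow the simulator encoding")
  tibble(
    molecule = as.integer(parts[, 2]),
    transcript_id = parts[, 3],
    probe_id = parts[, 4],
    frag_start = as.integer(parts[, 5]),
    frag_end = as.integer(parts[, 6]),
    spans_junction = parts[, 7] == "1"
  )
}

#' Write the reference transcriptome used by the caller
#'
#' Non-fusion transcript models are written as FASTA with headers
#' `transcript_id gene_id`, the format [read_reference_fasta()] expects.
#'
#' @param models Transcript model tibble.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(models, path) {
  m <- filter(models, !.data$is_fusion)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(m$seq, paste(m$transcript_id, m$gene_id))),
    path, width = 70L
  )
  invisible(path)
}

#' Read a reference transcriptome FASTA written by [write_reference_fasta()]
#'
#' @param path FASTA path; headers are `transcript_id gene_id` (a header
#'   without a gene token uses the transcript id as gene id).
#' @return Tibble (`transcript_id`, `gene_id`, `seq`).
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(x), "\\s+")
  tibble(
    transcript_id = vapply(hdr, `[`, "", 1L),
    gene_id = vapply(hdr, function(h) if (length(h) > 1L) h[2L] else h[1L], ""),
    seq = unname(as.character(x))
  )
}
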