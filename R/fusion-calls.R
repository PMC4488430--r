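# Normalize a junction representation (p, q) -- fused = A[1..p] + B[q+1..] in
# 1-based terms -- to its leftmost (5'-most on the 5' partner) equivalent, and
# measure the homology interval over which it can slide.
normalize_junction <- function(seqA, seqB, p, q) {
  while (p > 0L && q > 0L &&
         substr(seqA, p, p) == substr(seqB, q, q)) {
    p <- p - 1L
    q <- q - 1L
  }
  amb <- 0L
  lenA <- nchar(seqA)
  lenB <- nchar(seqB)
  while (p + amb + 1L <= lenA && q + amb + 1L <= lenB &&
         substr(seqA, p + amb + 1L, p + amb + 1L) ==
         substr(seqB, q + amb + 1L, q + amb + 1L)) {
    amb <- amb + 1L
  }
  list(p = p, q = q, ambiguity = amb)
}

# Count matching characters of `read` against `contig` starting at contig
# offset `o` (0-based), stopping at the first mismatch.
prefix_match_run <- function(read, contig, o) {
  m <- min(nchar(read), nchar(contig) - o)
  if (m <= 0L) return(0L)
  a <- utf8ToInt(substr(read, 1L, m))
  b <- utf8ToInt(substr(contig, o + 1L, o + m))
  d <- which(a != b)
  if (length(d) == 0L) m else d[1L] - 1L
}

# Matching run counting backwards from the read's last base aligned to
# contig position `o_last` (0-based), stopping at the first mismatch.
suffix_match_run <- function(read, contig, o_last) {
  L <- nchar(read)
  m <- min(L, o_last + 1L)
  if (m <= 0L) return(0L)
  a <- utf8ToInt(substr(read, L - m + 1L, L))
  b <- utf8ToInt(substr(contig, o_last - m + 2L, o_last + 1L))
  d <- which(a != b)
  if (length(d) == 0L) m else m - d[length(d)]
}

# Does `read` (one orientation) support the junction at contig offset `jo`
# with >= min_ov matching bases on both sides?  The read is anchored either
# on its first or its last 12-mer, so adapter padding at either read end
# (which aligns only where it coincidentally matches the reference) is
# handled symmetrically.
read_supports_junction <- function(read, contig, jo, min_ov) {
  L <- nchar(read)
  occ <- gregexpr(substr(read, 1L, 12L), contig, fixed = TRUE)[[1L]]
  if (occ[1L] != -1L) {
    for (o in as.integer(occ) - 1L) {
      m <- prefix_match_run(read, contig, o)
      if (o < jo && jo < o + m && jo - o >= min_ov && o + m - jo >= min_ov) {
        return(TRUE)
      }
    }
  }
  occ <- gregexpr(substr(read, L - 11L, L), contig, fixed = TRUE)[[1L]]
  if (occ[1L] != -1L) {
    for (oe in as.integer(occ) - 1L) {
      o_last <- oe + 11L
      m <- suffix_match_run(read, contig, o_last)
      lo <- o_last + 1L - m
      if (lo < jo && jo < o_last + 1L &&
          jo - lo >= min_ov && o_last + 1L - jo >= min_ov) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Call gene fusions from split-read alignments
#'
#' Split reads nominate candidate junctions; each junction is normalized to
#' its leftmost representation (with the homology interval reported as
#' `ambiguity`), a junction contig is assembled from the two reference
#' transcripts, and every read without a full-length single-gene alignment
#' is re-evaluated against the contig.  A read pair supports a junction when
#' a mate matches the contig across the breakpoint with at least
#' `min_overhang` matching bases on both sides.  Calls require
#' `min_supporting_reads` supporting pairs, two distinct genes, and at least
#' one partner with probes in the panel; `partners_in_panel` records whether
#' both, only the 5', or only the 3' gene is targeted.  `spanning_pairs`
#' counts non-split pairs whose mates map uniquely to the two partners.
#'
#' @param alignments A `spet_alignments` from [align_reads()].
#' @param panel A `spet_panel` (used for the targeted-gene labels).
#' @param params A [caller_params()].
#' @param annotation Optional `spet_annotation`; when supplied, breakpoints
#'   are also projected to genomic coordinates.
#' @return A tibble of fusion calls (class `spet_fusion_calls`), sorted by
#'   supporting reads, descending.
#' @export
call_fusions <- function(alignments, panel, params = caller_params(),
                         annotation = NULL) {
  stopifnot(inherits(alignments, "spet_alignments"), inherits(panel, "spet_panel"))
  aln <- alignments$alignments
  ref <- alignments$reference
  RL <- alignments$read_length
  refseq <- setNames(ref$seq, ref$transcript_id)

  splits <- filter(aln, .data$status == "split")
  if (nrow(splits) == 0L) {
    return(empty_fusion_calls(params))
  }

  # candidate junctions, leftmost-normalized
  cand <- splits |>
    distinct(.data$tx, .data$gene, .data$tx2, .data$gene2, .data$t_end, .data$t_start2) |>
    rowwise() |>
    mutate(norm = list(normalize_junction(
      refseq[[.data$tx]], refseq[[.data$tx2]], .data$t_end, .data$t_start2
    ))) |>
    ungroup() |>
    mutate(
      bp5 = map_int(.data$norm, function(z) as.integer(z$p)),
      bp3 = map_int(.data$norm, function(z) as.integer(z$q)),
      ambiguity = map_int(.data$norm, function(z) as.integer(z$ambiguity))
    ) |>
    distinct(.data$tx, .data$gene, .data$tx2, .data$gene2,
             .data$bp5, .data$bp3, .data$ambiguity) |>
    filter(.data$gene != .data$gene2)
  if (nrow(cand) == 0L) {
    return(empty_fusion_calls(params))
  }

  # reads eligible to support a junction: anything except a (near) full-length
  # single-gene alignment
  full_single <- aln$status == "unique" & (aln$r_end - aln$r_start) >= RL - 2L
  elig <- which(!full_single & aln$status != "ambiguous")
  reads_fwd <- alignments$reads$seq
  reads_rev <- revcomp(reads_fwd)
  pair_id <- alignments$reads$read_id

  calls <- vector("list", nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    A <- refseq[[cand$tx[ci]]]
    B <- refseq[[cand$tx2[ci]]]
    p <- cand$bp5[ci]
    q <- cand$bp3[ci]
    a_from <- max(0L, p - RL)
    contig <- paste0(subseq0(A, a_from, p), subseq0(B, q, min(nchar(B), q + RL)))
    jo <- p - a_from                    # junction offset within contig

    supp <- character(0)
    for (ri in elig) {
      found <- read_supports_junction(reads_fwd[ri], contig, jo, params$min_overhang) ||
        read_supports_junction(reads_rev[ri], contig, jo, params$min_overhang)
      if (found) supp <- c(supp, pair_id[ri])
    }
    n_supp <- length(unique(supp))

    # spanning pairs: both mates uniquely on the two partners, pair not
    # already counted as junction-supporting
    uni <- filter(aln, .data$status == "unique",
                  .data$gene %in% c(cand$gene[ci], cand$gene2[ci]))
    span <- uni |>
      group_by(.data$read_id) |>
      summarise(n_genes = n_distinct(.data$gene), .groups = "drop") |>
      filter(.data$n_genes == 2L, !.data$read_id %in% supp)

    calls[[ci]] <- tibble(
      gene5_id = cand$gene[ci],
      gene3_id = cand$gene2[ci],
      transcript5 = cand$tx[ci],
      transcript3 = cand$tx2[ci],
      breakpoint5 = p,
      breakpoint3 = q,
      supporting_reads = n_supp,
      spanning_pairs = nrow(span),
      ambiguity = cand$ambiguity[ci],
      junction_seq = paste0(
        subseq0(A, max(0L, p - 25L), p), "|",
        subseq0(B, q, min(nchar(B), q + 25L))
      )
    )
  }

  out <- bind_rows(calls) |>
    filter(.data$supporting_reads >= params$min_supporting_reads) |>
    mutate(
      partners_in_panel = case_when(
        .data$gene5_id %in% panel$targeted_genes &
          .data$gene3_id %in% panel$targeted_genes ~ "both",
        .data$gene5_id %in% panel$targeted_genes ~ "five_only",
        .data$gene3_id %in% panel$targeted_genes ~ "three_only",
        TRUE ~ "none"
      )
    ) |>
    filter(.data$partners_in_panel != "none") |>
    arrange(desc(.data$supporting_reads), .data$gene5_id, .data$gene3_id)

  if (!is.null(annotation)) {
    out <- out |>
      rowwise() |>
      mutate(
        breakpoint5_genomic = transcript_to_genomic(
          annotation, .data$transcript5, max(.data$breakpoint5 - 1L, 0L)
        ),
        breakpoint3_genomic = transcript_to_genomic(
          annotation, .data$transcript3, .data$breakpoint3
        )
      ) |>
      ungroup()
  } else {
    out$breakpoint5_genomic <- NA_real_
    out$breakpoint3_genomic <- NA_real_
  }

  structure(out, class = c("spet_fusion_calls", class(out)), params = params)
}

empty_fusion_calls <- function(params) {
  structure(
    tibble(
      gene5_id = character(), gene3_id = character(),
      transcript5 = character(), transcript3 = character(),
      breakpoint5 = integer(), breakpoint3 = integer(),
      supporting_reads = integer(), spanning_pairs = integer(),
      ambiguity = integer(), junction_seq = character(),
      partners_in_panel = character(),
      breakpoint5_genomic = numeric(), breakpoint3_genomic = numeric()
    ),
    class = c("spet_fusion_calls", class(tibble())), params = params
  )
}

#' @rdname call_fusions
#' @param x A `spet_fusion_calls` tibble.
#' @param ... Unused.
#' @export
tidy.spet_fusion_calls <- function(x, ...) as_tibble(x)

#' @rdname call_fusions
#' @export
glance.spet_fusion_calls <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_calls = nrow(x),
    total_supporting_reads = sum(x$supporting_reads),
    min_overhang = p$min_overhang,
    min_supporting_reads = p$min_supporting_reads,
    k = p$k
  )
}

#' Supporting-read barplot for fusion calls
#'
#' @param object A `spet_fusion_calls` tibble.
#' @param ... Unused.
#' @export
autoplot.spet_fusion_calls <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(fusion = paste0(.data$gene5_id, "-", .data$gene3_id))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$fusion, -.data$supporting_reads),
    y = .data$supporting_reads, fill = .data$partners_in_panel
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "supporting read pairs", fill = "partners targeted") +
    ggplot2::theme_minimal()
}

#' Mapping and on-target enrichment rates
#'
#' Computes, over forward (R1) reads only, the fraction of reads with an
#' accepted alignment and the fraction of those overlapping the panel's
#' target intervals by at least one base (transcript-space intervals of the
#' probed exons).
#'
#' @param alignments A `spet_alignments`.
#' @param panel A `spet_panel`.
#' @return One-row tibble: `mapped_fraction`, `on_target_fraction` (`NA`
#'   when nothing maps), `n_total`, `n_mapped`, `n_on_target`.
#' @export
on_target_rate <- function(alignments, panel) {
  stopifnot(inherits(alignments, "spet_alignments"), inherits(panel, "spet_panel"))
  a <- filter(alignments$alignments, .data$mate == "R1")
  if (nrow(a) == 0L) abort("no forward reads")
  mapped <- filter(a, .data$status %in% c("unique", "split"))

  overlaps_target <- function(tx, s, e) {
    if (is.na(tx)) return(FALSE)
    tt <- panel$targets_tx
    any(tt$transcript_id == tx & tt$tx_start < e & tt$tx_end > s)
  }
  on_t <- pmap(
    list(mapped$tx, mapped$t_start, mapped$t_end,
         mapped$tx2, mapped$t_start2, mapped$t_end2),
    function(tx, s, e, tx2, s2, e2) {
      overlaps_target(tx, s, e) || overlaps_target(tx2, s2, e2)
    }
  ) |> unlist()

  tibble(
    mapped_fraction = nrow(mapped) / nrow(a),
    on_target_fraction = if (nrow(mapped) == 0L) NA_real_ else mean(on_t),
    n_total = nrow(a),
    n_mapped = nrow(mapped),
    n_on_target = sum(on_t)
  )
}

#' Sequencing-efficiency comparison between targeted and untargeted runs
#'
#' Expresses a targeted run's read budget as a percentage of the untargeted
#' run it is compared against (1 decimal place) and as a fold reduction
#' (nearest integer).
#'
#' @param fusion_reads_targeted,fusion_reads_untargeted Fusion-supporting
#'   read counts (carried through for reporting; may be `NA`).
#' @param total_reads_targeted,total_reads_untargeted Total read counts of
#'   the two runs; both must be positive.
#' @return One-row tibble with `percent_of_reads` and `fold_reduction`.
#' @examples
#' compare_efficiency(
#'   total_reads_targeted = 1.6e6,
#'   total_reads_untargeted = 125e6
#' )
#' @export
compare_efficiency <- function(fusion_reads_targeted = NA_real_,
                               total_reads_targeted,
                               fusion_reads_untargeted = NA_real_,
                               total_reads_untargeted) {
  if (total_reads_targeted <= 0) abort("total_reads_targeted must be positive")
  if (total_reads_untargeted <= 0) abort("total_reads_untargeted must be positive")
  tibble(
    fusion_reads_targeted = fusion_reads_targeted,
    total_reads_targeted = total_reads_targeted,
    fusion_reads_untargeted = fusion_reads_untargeted,
    total_reads_untargeted = total_reads_untargeted,
    percent_of_reads = round(100 * total_reads_targeted / total_reads_untargeted, 1L),
    fold_reduction = round(total_reads_untargeted / total_reads_targeted)
  )
}
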