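ref_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("the k-mer index counts, flags ambiguity, and rejects duplicates", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  idx <- build_reference_index(
    ref_tbl(transcript_id = "t1", gene_id = "g1", seq = s), k = 21
  )
  expect_equal(nrow(idx$kmers), 100 - 21 + 1)
  expect_false(any(idx$kmers$ambiguous))

  # identical transcripts under different genes: everything ambiguous
  idx2 <- build_reference_index(
    ref_tbl(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"), seq = c(s, s)),
    k = 21
  )
  expect_true(all(idx2$kmers$ambiguous))

  expect_error(
    build_reference_index(
      ref_tbl(transcript_id = c("t1", "t1"), gene_id = c("g1", "g2"), seq = c(s, s))
    ),
    "duplicate"
  )
})

test_that("reads align uniquely, split across genes, or stay unmapped", {
  set.seed(7)
  a <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  # remove chance homology at the constructed A[..200] | B[301..] junction so
  # the expected split coordinates are unambiguous
  pick_other <- function(base) setdiff(c("A", "C", "G", "T"), base)[1]
  substr(b, 300, 300) <- pick_other(substr(a, 200, 200))
  substr(b, 301, 301) <- pick_other(substr(a, 201, 201))
  idx <- build_reference_index(
    ref_tbl(transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"), seq = c(a, b))
  )
  params <- caller_params()

  reads <- tibble::tibble(
    read_id = c("inside", "split", "random", "rc"),
    seq = c(
      substr(a, 101, 200),
      paste0(substr(a, 151, 200), substr(b, 301, 350)),  # 50 nt A + 50 nt B
      paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
      oracle_revcomp(substr(b, 51, 150))
    )
  )
  aln <- align_reads(reads, NULL, idx, params)$alignments

  inside <- aln[aln$read_id == "inside", ]
  expect_equal(inside$status, "unique")
  expect_equal(c(inside$r_start, inside$r_end), c(0L, 100L))
  expect_equal(c(inside$t_start, inside$t_end), c(100L, 200L))

  sp <- aln[aln$read_id == "split", ]
  expect_equal(sp$status, "split")
  expect_equal(sp$gene, "gA")
  expect_equal(sp$gene2, "gB")
  expect_equal(c(sp$r_start, sp$r_end), c(0L, 50L))
  expect_equal(c(sp$r_start2, sp$r_end2), c(50L, 100L))
  expect_equal(sp$t_end, 200L)
  expect_equal(sp$t_start2, 300L)

  expect_equal(aln$status[aln$read_id == "random"], "unmapped")

  rc <- aln[aln$read_id == "rc", ]
  expect_equal(rc$status, "unique")
  expect_equal(rc$orientation, "-")
  expect_equal(c(rc$t_start, rc$t_end), c(50L, 150L))
})

test_that("reads matching two genes equally well are dropped as non-unique", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  idx <- build_reference_index(
    ref_tbl(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"), seq = c(s, s))
  )
  reads <- tibble::tibble(read_id = "dup", seq = substr(s, 51, 150))
  aln <- align_reads(reads, NULL, idx, caller_params())$alignments
  expect_equal(aln$status, "ambiguous")
})

test_that("malformed FASTQ fails with a line number", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(align_reads(bad, NULL,
    build_reference_index(ref_tbl(transcript_id = "t", gene_id = "g",
                                  seq = strrep("ACGT", 30)))),
    "lines")
})

test_that("caller support equals simulator truth and breakpoints are leftmost-exact", {
  sim <- make_sim(seed = 101, n_molecules = 1500)
  params <- caller_params()
  idx <- build_reference_index(sim$ref_fa, k = params$k)
  aln <- align_reads(sim$fq$r1, sim$fq$r2, idx, params)
  calls <- call_fusions(aln, sim$panel, params, annotation = sim$ann)

  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene5_id, "GENE001")
  expect_equal(calls$gene3_id, "GENE002")
  expect_equal(calls$partners_in_panel, "both")
  expect_equal(calls$supporting_reads, truth_junction_pairs(sim$fq$truth))

  # expected breakpoints: planted junction, leftmost-normalized by an
  # independent oracle on the reference sequences
  tA <- sim$models$seq[sim$models$transcript_id == "GENE001.t1"]
  tB <- sim$models$seq[sim$models$transcript_id == "GENE002.t1"]
  b3 <- sim$models$exon_boundaries[sim$models$transcript_id == "GENE002.t1"][[1]]
  planted <- oracle_leftmost_junction(tA, tB, sim$fusion$junction_pos, b3[1])
  expect_equal(c(calls$breakpoint5, calls$breakpoint3), planted)

  # genomic projections land on real coordinates
  expect_false(is.na(calls$breakpoint5_genomic))
  expect_false(is.na(calls$breakpoint3_genomic))

  # junction context matches the reference
  halves <- strsplit(calls$junction_seq, "|", fixed = TRUE)[[1]]
  expect_identical(halves[1], substr(tA, calls$breakpoint5 - 24, calls$breakpoint5))
  expect_identical(halves[2], substr(tB, calls$breakpoint3 + 1, calls$breakpoint3 + 25))
})

test_that("removing the 3' partner from the panel preserves the call and breakpoints", {
  both <- make_sim(seed = 77, n_molecules = 1500)
  params <- caller_params()
  idx <- build_reference_index(both$ref_fa, k = params$k)
  aln <- align_reads(both$fq$r1, both$fq$r2, idx, params)
  calls_both <- call_fusions(aln, both$panel, params)

  five <- make_sim(seed = 77, n_molecules = 1500,
                   panel_genes = c("GENE001", "GENE003", "GENE004"))
  aln5 <- align_reads(five$fq$r1, five$fq$r2, idx, params)
  calls_five <- call_fusions(aln5, five$panel, params)

  expect_equal(nrow(calls_five), 1L)
  expect_equal(calls_five$partners_in_panel, "five_only")
  expect_equal(calls_five$gene5_id, calls_both$gene5_id)
  expect_equal(calls_five$breakpoint5, calls_both$breakpoint5)
  expect_equal(calls_five$breakpoint3, calls_both$breakpoint3)
  expect_equal(calls_five$supporting_reads, truth_junction_pairs(five$fq$truth))
})

test_that("fusion-free data yields no calls", {
  sim <- make_sim(seed = 55, n_molecules = 1000, fusion = FALSE)
  params <- caller_params()
  idx <- build_reference_index(sim$ref_fa, k = params$k)
  aln <- align_reads(sim$fq$r1, sim$fq$r2, idx, params)
  calls <- call_fusions(aln, sim$panel, params)
  expect_equal(nrow(calls), 0L)
})

test_that("supporting reads grow with fusion transcript abundance", {
  support_at <- function(ab) {
    dir <- tempfile("ab")
    gx <- generate_synthetic_genome(n_genes = 4, exons_per_gene = 3, seed = 303)
    paths <- write_synthetic_genome(gx, dir)
    ann <- parse_annotation(paths$annotation, paths$genome)
    panel <- design_panel(ann)
    models <- transcript_models(ann)
    fus <- build_fusion_transcript(models, "GENE001.t1", 2, "GENE002.t1", 2, "FUS1")
    models <- dplyr::bind_rows(models, fus)
    ab_vec <- setNames(rep(1, nrow(models)), models$transcript_id)
    ab_vec["FUS1"] <- ab
    lib <- library_config(n_molecules = 1500, seed = 303, abundances = ab_vec)
    frags <- simulate_fragments(models, lib)
    cap <- capture_and_extend(frags, models, panel, lib)
    fq <- emit_fastq(cap, models, lib, file.path(dir, "sim"))
    ref <- file.path(dir, "ref.fa")
    write_reference_fasta(models, ref)
    params <- caller_params()
    idx <- build_reference_index(ref, k = params$k)
    aln <- align_reads(fq$r1, fq$r2, idx, params)
    calls <- call_fusions(aln, panel, params)
    if (nrow(calls) == 0L) 0L else calls$supporting_reads[1]
  }
  s <- vapply(c(0.5, 2, 8), support_at, 0L)
  expect_true(all(diff(s) >= 0))
  expect_gt(s[3], s[1])
})

test_that("on-target metrics are exact on pure target reads and NA when nothing maps", {
  sim <- make_sim(seed = 19, n_molecules = 600, fusion = FALSE)
  params <- caller_params()
  idx <- build_reference_index(sim$ref_fa, k = params$k)

  # construct long-insert captures so every read aligns end to end
  models <- sim$models
  pr <- sim$panel$probes[sim$panel$probes$cdna_strand == "antisense", ]
  pr <- pr[!duplicated(pr$transcript_id), ]
  keep <- (models$tx_length[match(pr$transcript_id, models$transcript_id)] -
             pr$fp_end) >= 120
  pr <- pr[keep, ]
  cap <- tibble::tibble(
    molecule_id = seq_len(nrow(pr)), fragment_id = seq_len(nrow(pr)),
    transcript_id = pr$transcript_id,
    frag_start = pr$fp_start,
    frag_end = pr$fp_end + 120L,
    probe_id = pr$probe_id, cdna_strand = pr$cdna_strand, direction = "+",
    ins_start = pr$fp_end, ins_end = pr$fp_end + 120L
  )
  fq <- emit_fastq(cap, models, sim$lib, tempfile("ot"))
  aln <- align_reads(fq$r1, fq$r2, idx, params)
  ot <- on_target_rate(aln, sim$panel)
  expect_equal(ot$mapped_fraction, 1.0)
  expect_equal(ot$on_target_fraction, 1.0)

  # junk reads: nothing maps, rate undefined
  set.seed(77)
  junk <- tibble::tibble(
    read_id = paste0("j", 1:20),
    seq = vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    }, "")
  )
  aj <- align_reads(junk, NULL, idx, params)
  oj <- on_target_rate(aj, sim$panel)
  expect_equal(oj$mapped_fraction, 0)
  expect_true(is.na(oj$on_target_fraction))
})

test_that("efficiency arithmetic reduces read budgets as printed", {
  eff <- compare_efficiency(total_reads_targeted = 1e6, total_reads_untargeted = 1e6)
  expect_equal(eff$percent_of_reads, 100.0)
  expect_equal(eff$fold_reduction, 1)
  expect_error(compare_efficiency(total_reads_targeted = 0,
                                  total_reads_untargeted = 1), "positive")
  expect_error(compare_efficiency(total_reads_targeted = 1,
                                  total_reads_untargeted = 0), "positive")
})
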