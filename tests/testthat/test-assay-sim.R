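test_that("synthetic genomes are byte-identical under one seed and parse cleanly", {
  d1 <- tempfile("g1"); d2 <- tempfile("g2")
  p1 <- write_synthetic_genome(generate_synthetic_genome(seed = 42), d1)
  p2 <- write_synthetic_genome(generate_synthetic_genome(seed = 42), d2)
  expect_identical(readLines(p1$genome), readLines(p2$genome))
  expect_identical(readLines(p1$annotation), readLines(p2$annotation))
  expect_false(identical(
    readLines(write_synthetic_genome(generate_synthetic_genome(seed = 43), tempfile())$genome),
    readLines(p1$genome)
  ))

  expect_no_warning(ann <- parse_annotation(p1$annotation, p1$genome))
  # transcript length equals the sum of exon lengths recomputed from the GTF
  gtf <- read.delim(p1$annotation, header = FALSE, quote = "")
  lens <- tapply(gtf$V5 - gtf$V4 + 1L, sub('.*transcript_id "([^"]+)".*', "\\1", gtf$V9), sum)
  expect_equal(
    ann$transcripts$tx_length,
    as.integer(lens[ann$transcripts$transcript_id]),
    ignore_attr = TRUE
  )
})

test_that("fusion transcripts are exact prefix+suffix concatenations", {
  gx <- generate_synthetic_genome(n_genes = 3, exons_per_gene = 3,
                                  exon_length_range = c(100, 100), seed = 2)
  paths <- write_synthetic_genome(gx, tempfile("fus"))
  ann <- parse_annotation(paths$annotation, paths$genome)
  models <- transcript_models(ann)

  f <- build_fusion_transcript(models, "GENE001.t1", 2, "GENE002.t1", 1, "F")
  expect_equal(f$junction_pos, 200L)
  tA <- models$seq[models$transcript_id == "GENE001.t1"]
  tB <- models$seq[models$transcript_id == "GENE002.t1"]
  expect_identical(f$seq, paste0(substr(tA, 1, 200), tB))
  expect_equal(f$tx_length, 200L + nchar(tB))

  # fusing a transcript to itself at its own exon boundary is the identity
  self <- build_fusion_transcript(models, "GENE001.t1", 2, "GENE001.t1", 3, "S")
  expect_identical(self$seq, tA)

  # the junction 20-mer is novel with respect to both parents
  j <- f$junction_pos
  jmer <- substr(f$seq, j - 9, j + 10)
  expect_false(grepl(jmer, tA, fixed = TRUE))
  expect_false(grepl(jmer, tB, fixed = TRUE))

  expect_error(build_fusion_transcript(models, "GENE001.t1", 7, "GENE002.t1", 1),
               "out of range")
  expect_error(build_fusion_transcript(models, "NOPE.t1", 1, "GENE002.t1", 1),
               "unknown")
})

test_that("fragment allocation follows abundance x length and FFPE shortens fragments", {
  gx <- generate_synthetic_genome(n_genes = 2, exons_per_gene = 3,
                                  exon_length_range = c(150, 150), seed = 6)
  paths <- write_synthetic_genome(gx, tempfile("fr"))
  ann <- parse_annotation(paths$annotation, paths$genome)
  models <- transcript_models(ann)

  n <- 40000
  lib <- library_config(
    n_molecules = n, seed = 10,
    abundances = c(GENE001.t1 = 1, GENE002.t1 = 3)
  )
  fr <- simulate_fragments(models, lib)
  expect_equal(nrow(fr), n)
  n2 <- sum(fr$transcript_id == "GENE002.t1")
  p <- 0.75  # equal lengths, abundance 1:3
  expect_lt(abs(n2 - n * p), 3 * sqrt(n * p * (1 - p)))
  expect_true(all(fr$end > fr$start))
  expect_true(all(fr$start >= 0))

  fresh <- simulate_fragments(models, library_config(n_molecules = 5000, seed = 4))
  ffpe <- simulate_fragments(models, library_config(n_molecules = 5000, seed = 4,
                                                    ffpe_mode = TRUE))
  expect_lt(mean(ffpe$end - ffpe$start), mean(fresh$end - fresh$start))

  expect_equal(nrow(simulate_fragments(models, library_config(n_molecules = 0))), 0L)
})

test_that("capture requires a fully contained probe footprint on the matching strand", {
  gx <- generate_synthetic_genome(n_genes = 3, exons_per_gene = 3, seed = 12)
  paths <- write_synthetic_genome(gx, tempfile("cap"))
  ann <- parse_annotation(paths$annotation, paths$genome)
  models <- transcript_models(ann)
  panel <- design_panel(ann, genes = c("GENE001", "GENE002"))
  lib <- library_config(seed = 1)

  prs <- panel$probes[panel$probes$cdna_strand == "sense" &
                        panel$probes$transcript_id == "GENE001.t1" &
                        panel$probes$fp_start >= 50, ]
  pr <- prs[1, ]
  frag <- tibble::tibble(
    fragment_id = 1L, transcript_id = "GENE001.t1",
    start = max(0L, pr$fp_start - 30L), end = pr$fp_end + 10L
  )
  cap <- capture_and_extend(frag, models, panel, lib)
  expect_equal(nrow(cap), 1L)
  expect_equal(cap$direction, "-")  # sense probes extend toward the 5' end
  expect_equal(cap$ins_start, frag$start)
  expect_equal(cap$ins_end, pr$fp_start)

  # a fragment that only partially contains the footprint (and is too small
  # to contain any other probe) is washed away
  frag2 <- frag
  frag2$start <- pr$fp_start - 2L
  frag2$end <- pr$fp_end - 1L
  expect_equal(nrow(capture_and_extend(frag2, models, panel, lib)), 0L)

  # untargeted gene: never captured
  frag3 <- tibble::tibble(fragment_id = 1L, transcript_id = "GENE003.t1",
                          start = 0L, end = 300L)
  expect_equal(nrow(capture_and_extend(frag3, models, panel, lib)), 0L)
})

test_that("a single-anchored fragment carries untargeted partner sequence past the junction", {
  sim <- make_sim(seed = 31, panel_genes = c("GENE001", "GENE003", "GENE004"))
  J <- sim$fusion$junction_pos
  fus_cap <- sim$captured[sim$captured$transcript_id == "FUS1", ]
  expect_gt(nrow(fus_cap), 0L)
  # all capturing probes belong to the 5' partner, yet extension products
  # reach into the untargeted 3' partner
  expect_true(all(grepl("^GENE001", fus_cap$probe_id)))
  expect_gt(sum(fus_cap$ins_end > J), 0L)
})

test_that("emitted reads are faithful at zero error and carry valid FASTQ structure", {
  sim <- make_sim(seed = 5, n_molecules = 800)
  r1 <- readLines(sim$fq$r1)
  r2 <- readLines(sim$fq$r2)
  expect_equal(length(r1) %% 4, 0)
  seqs1 <- r1[seq(2, length(r1), by = 4)]
  quals1 <- r1[seq(4, length(r1), by = 4)]
  expect_true(all(nchar(seqs1) == sim$lib$read_length))
  expect_true(all(nchar(quals1) == nchar(seqs1)))
  expect_true(all(startsWith(r1[seq(1, length(r1), by = 4)], "@")))

  # R1 equals the extension product starting at the probe anchor
  truth <- sim$fq$truth
  mseq <- setNames(sim$models$seq, sim$models$transcript_id)
  for (i in sample(nrow(truth), 50)) {
    src <- mseq[[truth$transcript_id[i]]]
    a <- truth$ins_start[i]; b <- truth$ins_end[i]
    fwd <- sim$captured$direction[i] == "+"
    ins <- substr(src, a + 1, b)
    if (!fwd) ins <- oracle_revcomp(ins)
    expect_identical(
      substr(seqs1[i], 1, min(nchar(ins), sim$lib$read_length)),
      substr(ins, 1, sim$lib$read_length)
    )
  }
})

test_that("substitution errors match the configured binomial rate", {
  gx <- generate_synthetic_genome(n_genes = 2, exons_per_gene = 3, seed = 3)
  paths <- write_synthetic_genome(gx, tempfile("err"))
  ann <- parse_annotation(paths$annotation, paths$genome)
  models <- transcript_models(ann)
  panel <- design_panel(ann)

  run_sim <- function(err) {
    lib <- library_config(n_molecules = 3000, seed = 44, error_rate = err)
    frags <- simulate_fragments(models, lib)
    cap <- capture_and_extend(frags, models, panel, lib)
    fq <- emit_fastq(cap, models, lib, tempfile("fq"))
    readLines(fq$r1)[seq(2, 4 * nrow(cap), by = 4)]
  }
  clean <- run_sim(0)
  noisy <- run_sim(0.01)
  expect_equal(length(clean), length(noisy))
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean, noisy)
  n_bases <- length(clean) * 100
  expect_lt(abs(mean(mism) - 1.0), 3 * sqrt(100 * 0.01 * 0.99 / length(clean)))
})

test_that("read ids round-trip the ground-truth provenance", {
  sim <- make_sim(seed = 13, n_molecules = 600)
  truth <- sim$fq$truth
  ids1 <- sub("^@", "", readLines(sim$fq$r1)[seq(1, 4 * nrow(truth), by = 4)])
  expect_identical(ids1, truth$read_id)
  dec <- parse_read_ids(truth$read_id)
  expect_identical(dec$transcript_id, truth$transcript_id)
  expect_identical(dec$probe_id, truth$probe_id)
  expect_identical(dec$frag_start, truth$frag_start)
  expect_identical(dec$frag_end, truth$frag_end)
  expect_identical(dec$spans_junction, truth$spans_junction)
})

test_that("empty capture sets are a hard error at sequencing", {
  gx <- generate_synthetic_genome(n_genes = 2, seed = 3)
  paths <- write_synthetic_genome(gx, tempfile("ec"))
  ann <- parse_annotation(paths$annotation, paths$genome)
  models <- transcript_models(ann)
  lib <- library_config(seed = 1)
  expect_error(
    emit_fastq(capture_and_extend(
      tibble::tibble(fragment_id = integer(), transcript_id = character(),
                     start = integer(), end = integer()),
      models, design_panel(ann), lib
    ), models, lib, tempfile()),
    "no captured molecules"
  )
})
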