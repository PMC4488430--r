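`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixture builders.  Everything is generated in code at test time;
# nothing is stored on disk between runs.

# Independent reverse complement (kept separate from the package's helper so
# sequence-oracle tests do not depend on the code path they check).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Hand-written two-exon toy annotation on a 300-nt genome.
write_toy_gene <- function(dir, strand = "+", genome_len = 300,
                           exon1 = c(0, 100), exon2 = c(200, 300)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(99)
  g <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
             collapse = "")
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", g), fa)
  idx <- if (strand == "+") 1:2 else 2:1
  gtf <- file.path(dir, "toy.gtf")
  writeLines(sprintf(
    'chrT\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "TOY1"; transcript_id "TOY1.t1"; exon_number "%d";',
    c(exon1[1], exon2[1]) + 1L, c(exon1[2], exon2[2]), strand, idx
  ), gtf)
  list(genome = fa, annotation = gtf, seq = g)
}

# A small simulated dataset with an optional planted fusion, used by the
# caller and acceptance tests.
make_sim <- function(seed,
                     n_genes = 4,
                     exons_per_gene = 3,
                     exon_length_range = c(120, 200),
                     n_molecules = 1200,
                     fusion = TRUE,
                     panel_genes = NULL,
                     error_rate = 0,
                     read_length = 100) {
  dir <- tempfile("spetsim")
  gx <- generate_synthetic_genome(
    n_genes = n_genes, exons_per_gene = exons_per_gene,
    exon_length_range = exon_length_range, seed = seed
  )
  paths <- write_synthetic_genome(gx, dir)
  ann <- parse_annotation(paths$annotation, paths$genome)
  panel <- design_panel(ann, genes = panel_genes)
  models <- transcript_models(ann)
  fus <- NULL
  if (fusion) {
    fus <- build_fusion_transcript(models, "GENE001.t1", 2, "GENE002.t1", 2, "FUS1")
    models <- dplyr::bind_rows(models, fus)
  }
  lib <- library_config(
    n_molecules = n_molecules, seed = seed,
    error_rate = error_rate, read_length = read_length
  )
  frags <- simulate_fragments(models, lib)
  captured <- capture_and_extend(frags, models, panel, lib)
  fq <- emit_fastq(captured, models, lib, file.path(dir, "sim"))
  ref_fa <- file.path(dir, "reference.fa")
  write_reference_fasta(models, ref_fa)
  list(
    dir = dir, ann = ann, panel = panel, models = models, fusion = fus,
    lib = lib, frags = frags, captured = captured, fq = fq, ref_fa = ref_fa
  )
}

# Independent leftmost normalization of a junction (p, q) between two
# reference sequences: fused = A[1..p] + B[q+1..] (1-based).
oracle_leftmost_junction <- function(seqA, seqB, p, q) {
  while (p > 0 && q > 0 && substr(seqA, p, p) == substr(seqB, q, q)) {
    p <- p - 1
    q <- q - 1
  }
  c(p, q)
}

# Truth-side supporting-pair count at the caller's overhang threshold.
truth_junction_pairs <- function(truth, min_overhang = 10) {
  sum(pmax(truth$r1_overhang, truth$r2_overhang) >= min_overhang)
}

# Annotation of n single-exon genes with prescribed exon lengths, used by
# the design-rule property suites.
single_exon_annotation <- function(lengths, seed = 11) {
  gx <- generate_synthetic_genome(
    n_genes = length(lengths), exons_per_gene = 1,
    exon_length_range = c(1, 1), seed = seed
  )
  # rewrite exon ends to the requested lengths, then regenerate the genome
  # string long enough to cover them
  ann <- gx$annotation
  starts <- cumsum(c(100, head(lengths, -1) + 100))
  ann$start <- starts
  ann$end <- starts + lengths
  set.seed(seed)
  genome <- paste(sample(c("A", "C", "G", "T"), max(ann$end) + 100, replace = TRUE),
                  collapse = "")
  dir <- tempfile("sx")
  dir.create(dir)
  writeLines(c(">chr1", genome), file.path(dir, "g.fa"))
  writeLines(sprintf(
    'chr1\tspetseq\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
    ann$start + 1L, ann$end, ann$gene_id, ann$transcript_id
  ), file.path(dir, "g.gtf"))
  parse_annotation(file.path(dir, "g.gtf"), file.path(dir, "g.fa"))
}

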