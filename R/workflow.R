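#' Build a workflow run configuration
#'
#' One flat, YAML-serializable configuration driving the full
#' design → simulate → call workflow.  A single global seed fans out to
#' per-stage derived seeds, so identical configurations give byte-identical
#' run artifacts.
#'
#' The genome is either synthetic (`genome = NULL`, generated from
#' `genome_params`) or given as `annotation`/`genome` file paths.  Fusions
#' are planted from a manifest tibble with columns `transcript5`, `exon5`,
#' `transcript3`, `exon3`, and optionally `fusion_id` and `abundance`
#' (relative weight of the fusion transcript; background transcripts have
#' weight 1).
#'
#' @param seed Global integer seed.
#' @param annotation,genome Optional input file paths (GTF + FASTA). When
#'   `NULL` a synthetic genome is generated inside the run directory.
#' @param genome_params Arguments for [generate_synthetic_genome()] (used
#'   only when no annotation is supplied).
#' @param panel_genes Optional gene subset the panel is designed against;
#'   genes left out are expressed but untargeted.
#' @param design Arguments for [panel_design_params()].
#' @param fusions Fusion manifest tibble/data frame (or `NULL` for a
#'   fusion-free run).
#' @param library Arguments for [library_config()] (its `seed` is derived
#'   from the global seed).
#' @param caller Arguments for [caller_params()].
#' @return A list of class `spet_run_config`.
#' @export
run_config <- function(seed = 1L,
                       annotation = NULL,
                       genome = NULL,
                       genome_params = list(),
                       panel_genes = NULL,
                       design = list(),
                       fusions = NULL,
                       library = list(),
                       caller = list()) {
  cfg <- structure(
    list(
      seed = as.integer(seed),
      annotation = annotation,
      genome = genome,
      genome_params = genome_params,
      panel_genes = panel_genes,
      design = design,
      fusions = if (!is.null(fusions)) as_tibble(fusions),
      library = library,
      caller = caller
    ),
    class = "spet_run_config"
  )
  cfg
}

#' Demo configuration: five genes, one planted fusion
#'
#' A small synthetic run: 5 four-exon genes, a fusion joining exon 2 of the
#' first gene to exon 2 of the second, 20,000 input molecules.  With
#' `target_both = FALSE` the 3' partner is left out of the panel, so the
#' fusion must be recovered through single-partner (5'-anchored) evidence
#' alone.
#'
#' @param seed Global seed.
#' @param target_both Include both fusion partners in the panel?
#' @param n_molecules Library size.
#' @return A `spet_run_config`.
#' @export
demo_config <- function(seed = 1L, target_both = TRUE, n_molecules = 20000) {
  genes <- sprintf("GENE%03d", 1:5)
  run_config(
    seed = seed,
    genome_params = list(
      n_genes = 5, exons_per_gene = 4, exon_length_range = c(120, 220),
      intron_length_range = c(100, 400)
    ),
    panel_genes = if (target_both) genes else setdiff(genes, "GENE002"),
    fusions = tibble(
      transcript5 = "GENE001.t1", exon5 = 2L,
      transcript3 = "GENE002.t1", exon3 = 2L,
      fusion_id = "FUS1", abundance = 1
    ),
    library = list(n_molecules = n_molecules)
  )
}

validation_error <- function(msg) {
  abort(msg, class = "spet_validation_error")
}

#' Validate a run configuration
#'
#' Checks referenced input paths and parameter ranges before any compute.
#'
#' @param config A `spet_run_config`.
#' @return Invisibly `TRUE`; otherwise an error of class
#'   `spet_validation_error`.
#' @export
validate_run_config <- function(config) {
  if (!inherits(config, "spet_run_config")) validation_error("not a run configuration")
  if (is.null(config$annotation) != is.null(config$genome)) {
    validation_error("annotation and genome paths must be given together")
  }
  for (p in c(config$annotation, config$genome)) {
    if (!file.exists(p)) validation_error(paste0("input path does not exist: ", p))
  }
  if (!is.null(config$fusions)) {
    need <- c("transcript5", "exon5", "transcript3", "exon3")
    miss <- setdiff(need, names(config$fusions))
    if (length(miss) > 0L) {
      validation_error(paste0("fusion manifest lacks columns: ", paste(miss, collapse = ", ")))
    }
  }
  # materialize parameter objects so bad values fail here, not mid-run
  do.call(panel_design_params, config$design)
  do.call(library_config, c(config$library, list(seed = config$seed)))
  do.call(caller_params, config$caller)
  invisible(TRUE)
}

#' Serialize / deserialize a run configuration
#'
#' @param config A `spet_run_config`.
#' @param path YAML file path.
#' @return `write_run_config()`: invisibly `path`; `read_run_config()`: the
#'   configuration (lossless round-trip).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$fusions)) x$fusions <- as.list(as.data.frame(x$fusions))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$fusions)) x$fusions <- as_tibble(x$fusions)
  do.call(run_config, x[c(
    "seed", "annotation", "genome", "genome_params", "panel_genes",
    "design", "fusions", "library", "caller"
  )])
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = "spet_stage_error"
    )
  })
}

#' Run the full design → simulate → call workflow
#'
#' Executes panel design, library simulation and fusion calling under one
#' configuration, writing every artifact plus an md5 manifest into
#' `run_dir`.  Identical configuration and seed give identical checksums.
#'
#' @param config A `spet_run_config`.
#' @param run_dir Output directory for the run.
#' @return Invisibly, a list with the run directory, panel, calls and
#'   metrics.
#' @export
run_end_to_end <- function(config, run_dir) {
  run_stage("validate", validate_run_config(config))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- run_stage("genome", {
    if (is.null(config$annotation)) {
      gx <- do.call(generate_synthetic_genome,
                    c(config$genome_params, list(seed = config$seed)))
      write_synthetic_genome(gx, file.path(run_dir, "genome"))
    } else {
      list(genome = config$genome, annotation = config$annotation)
    }
  })

  ann <- run_stage("parse_annotation",
                   parse_annotation(paths$annotation, paths$genome))

  dparams <- do.call(panel_design_params, config$design)
  panel <- run_stage("design_panel",
                     design_panel(ann, dparams, genes = config$panel_genes))
  run_stage("write_panel", write_panel(panel, file.path(run_dir, "panel")))

  lib <- do.call(library_config, c(config$library, list(seed = config$seed)))
  sim <- run_stage("simulate", {
    models <- transcript_models(ann)
    ab <- setNames(rep(1, nrow(models)), models$transcript_id)
    if (!is.null(config$fusions)) {
      f <- config$fusions
      for (i in seq_len(nrow(f))) {
        fid <- if ("fusion_id" %in% names(f)) f$fusion_id[i] else NULL
        fm <- build_fusion_transcript(
          models, f$transcript5[i], f$exon5[i], f$transcript3[i], f$exon3[i],
          fusion_id = fid
        )
        models <- bind_rows(models, fm)
        ab[fm$transcript_id] <- if ("abundance" %in% names(f)) f$abundance[i] else 1
      }
    }
    lib$abundances <- ab
    frags <- simulate_fragments(models, lib)
    captured <- capture_and_extend(frags, models, panel, lib)
    sim_dir <- file.path(run_dir, "sim")
    fq <- emit_fastq(captured, models, lib, sim_dir)
    write_reference_fasta(models, file.path(sim_dir, "reference.fa"))
    c(fq, list(models = models, reference = file.path(sim_dir, "reference.fa")))
  })

  cparams <- do.call(caller_params, config$caller)
  res <- run_stage("call", {
    index <- build_reference_index(sim$reference, k = cparams$k)
    aln <- align_reads(sim$r1, sim$r2, index, cparams)
    calls <- call_fusions(aln, panel, cparams, annotation = ann)
    metrics <- on_target_rate(aln, panel)
    call_dir <- file.path(run_dir, "calls")
    dir.create(call_dir, showWarnings = FALSE)
    write_fusion_calls(calls, file.path(call_dir, "fusions.tsv"))
    readr::write_tsv(metrics, file.path(call_dir, "metrics.tsv"))
    write_truth_comparison(calls, sim$truth, cparams,
                           file.path(call_dir, "truth_comparison.tsv"))
    list(calls = calls, metrics = metrics)
  })

  write_run_config(config, file.path(run_dir, "config.yaml"))
  report <- run_stage("report", make_report(run_dir))

  files <- sort(setdiff(
    list.files(run_dir, recursive = TRUE),
    c("manifest.tsv")
  ))
  sums <- tools::md5sum(file.path(run_dir, files))
  readr::write_tsv(tibble(file = files, md5 = unname(sums)),
                   file.path(run_dir, "manifest.tsv"))

  invisible(list(
    run_dir = run_dir, panel = panel, calls = res$calls,
    metrics = res$metrics, report = report
  ))
}

#' Write / read a fusion call table
#'
#' The TSV carries the caller thresholds as `#`-prefixed header lines.
#'
#' @param calls A `spet_fusion_calls` tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_fusion_calls <- function(calls, path) {
  p <- attr(calls, "params") %||% caller_params()
  writeLines(c(
    sprintf("# min_overhang=%d", p$min_overhang),
    sprintf("# min_supporting_reads=%d", p$min_supporting_reads),
    sprintf("# k=%d", p$k),
    sprintf("# max_mismatches_per_segment=%d", p$max_mismatches_per_segment)
  ), path)
  suppressMessages(readr::write_tsv(as_tibble(calls), path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname write_fusion_calls
#' @export
read_fusion_calls <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

write_truth_comparison <- function(calls, truth, cparams, path) {
  tr <- truth |>
    filter(.data$is_fusion) |>
    group_by(.data$transcript_id, .data$junction_pos) |>
    summarise(
      truth_junction_pairs = sum(pmax(.data$r1_overhang, .data$r2_overhang) >=
                                   cparams$min_overhang),
      .groups = "drop"
    )
  cmp <- as_tibble(calls) |>
    mutate(fusion = paste0(.data$gene5_id, "-", .data$gene3_id)) |>
    select("fusion", "breakpoint5", "breakpoint3", "supporting_reads")
  readr::write_tsv(
    bind_rows(
      cmp |> mutate(source = "called"),
      tr |> transmute(
        fusion = .data$transcript_id,
        breakpoint5 = .data$junction_pos,
        breakpoint3 = NA_integer_,
        supporting_reads = .data$truth_junction_pairs,
        source = "truth"
      )
    ),
    path
  )
  invisible(path)
}

#' Summarize a completed run
#'
#' Collects the run's mapping/enrichment metrics and fusion calls into
#' `report.txt` (human-readable) and `report.json` (machine-readable,
#' checked by [validate_report()]).  When a companion untargeted run
#' directory is given, the targeted/untargeted efficiency comparison is
#' included.
#'
#' @param run_dir A directory produced by [run_end_to_end()].
#' @param companion_run Optional run directory of an untargeted companion
#'   simulation, used for the read-efficiency comparison.
#' @return Invisibly, the report as a list.
#' @export
make_report <- function(run_dir, companion_run = NULL) {
  need <- c(
    file.path("calls", "fusions.tsv"),
    file.path("calls", "metrics.tsv"),
    file.path("sim", "truth.tsv")
  )
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0L) {
    abort(paste0(
      "incomplete run directory ", run_dir, "; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  metrics <- readr::read_tsv(file.path(run_dir, "calls", "metrics.tsv"),
                             show_col_types = FALSE)
  calls <- read_fusion_calls(file.path(run_dir, "calls", "fusions.tsv"))

  report <- list(
    run_dir = run_dir,
    n_reads = metrics$n_total,
    mapped_fraction = metrics$mapped_fraction,
    on_target_fraction = metrics$on_target_fraction,
    fusions = if (nrow(calls) == 0L) list() else {
      lapply(seq_len(nrow(calls)), function(i) {
        list(
          gene5_id = calls$gene5_id[i], gene3_id = calls$gene3_id[i],
          breakpoint5 = calls$breakpoint5[i], breakpoint3 = calls$breakpoint3[i],
          supporting_reads = calls$supporting_reads[i],
          spanning_pairs = calls$spanning_pairs[i],
          partners_in_panel = calls$partners_in_panel[i]
        )
      })
    }
  )
  if (!is.null(companion_run)) {
    comp_metrics <- readr::read_tsv(
      file.path(companion_run, "calls", "metrics.tsv"), show_col_types = FALSE
    )
    eff <- compare_efficiency(
      total_reads_targeted = metrics$n_total,
      total_reads_untargeted = comp_metrics$n_total
    )
    report$efficiency <- list(
      percent_of_reads = eff$percent_of_reads,
      fold_reduction = eff$fold_reduction
    )
  }

  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c(
    "SPET workflow report",
    sprintf("reads: %d", report$n_reads),
    sprintf("mapped_fraction: %.4f", report$mapped_fraction),
    sprintf("on_target_fraction: %.4f", report$on_target_fraction),
    sprintf("fusion calls: %d", length(report$fusions)),
    vapply(report$fusions, function(f) {
      sprintf(
        "  %s-%s bp5=%d bp3=%d supporting=%d spanning=%d partners=%s",
        f$gene5_id, f$gene3_id, f$breakpoint5, f$breakpoint3,
        f$supporting_reads, f$spanning_pairs, f$partners_in_panel
      )
    }, ""),
    if (!is.null(report$efficiency)) {
      sprintf(
        "efficiency vs untargeted companion: %.1f%% of reads (%dx fewer)",
        report$efficiency$percent_of_reads, report$efficiency$fold_reduction
      )
    }
  )
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(report)
}

#' Validate a workflow report against its schema
#'
#' @param x A report list, or a path to `report.json`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_report <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x)
  need <- c("run_dir", "n_reads", "mapped_fraction", "on_target_fraction", "fusions")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    abort(paste0("report lacks fields: ", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(x$n_reads) || !is.numeric(x$mapped_fraction)) {
    abort("report numeric fields have wrong types")
  }
  for (f in x$fusions) {
    fm <- setdiff(
      c("gene5_id", "gene3_id", "breakpoint5", "breakpoint3",
        "supporting_reads", "partners_in_panel"),
      names(f)
    )
    if (length(fm) > 0L) {
      abort(paste0("fusion record lacks fields: ", paste(fm, collapse = ", ")))
    }
  }
  invisible(TRUE)
}
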