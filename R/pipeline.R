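# End-to-end orchestration: partition -> (orthology) -> reference -> rank
# -> select -> minimize -> validate, with persisted artifacts and a
# machine-readable run report. Identical config + seed gives a
# byte-identical report (no timestamps in report.json).

#' Pipeline configuration
#'
#' Exactly one input mode is used: `"simulated"` (a benchmark generated by
#' [synthesize_benchmark()]), or `"alignments"` (a directory of aligned
#' FASTA files, one per gene). The training:validation split defaults to
#' 2:1; a 1:1 split tends to select marker sets that fail validation more
#' often, since fewer species constrain the selection and more must be
#' predicted.
#'
#' @param mode `"simulated"` or `"alignments"`.
#' @param sim A [simulation_config()] (simulated mode).
#' @param alignments_dir Directory of aligned FASTA files (alignments
#'   mode).
#' @param reference_newick Optional path to a Newick reference topology
#'   honored verbatim instead of building one from the concatenation.
#' @param tv_split Either a fraction in (0, 1) giving the training share,
#'   or a list with explicit `t` and `v` species vectors.
#' @param selection A [selection_config()].
#' @param search `"random"`, `"exhaustive"` or `"none"`.
#' @param exhaustive_sizes Optional sizes for exhaustive search.
#' @param builder_engine `"nj"` (built-in) or `"external"`.
#' @param builder_correction Distance correction for the built-in builder.
#' @param external_command Command template for [external_builder()].
#' @param validation_mode `"cross"`, `"one_species"` or `"both"`.
#' @param cross_threshold Maximum normalized RF for the cross-validation
#'   pass (default 0).
#' @param max_retries If validation fails, rerun selection up to this many
#'   times with the selection seed incremented (default 0: no retry loop).
#' @param rng_seed Master seed for data partitioning / simulation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulated", "alignments"),
                            sim = simulation_config(),
                            alignments_dir = NULL,
                            reference_newick = NULL,
                            tv_split = 2 / 3,
                            selection = selection_config(),
                            search = "random",
                            exhaustive_sizes = NULL,
                            builder_engine = c("nj", "external"),
                            builder_correction = "poisson",
                            external_command = NULL,
                            validation_mode = c("both", "cross",
                                                "one_species"),
                            cross_threshold = 0,
                            max_retries = 0L,
                            rng_seed = 1L) {
  mode <- match.arg(mode)
  builder_engine <- match.arg(builder_engine)
  validation_mode <- match.arg(validation_mode)
  if (mode == "alignments" && is.null(alignments_dir)) {
    stop("alignments mode requires 'alignments_dir'")
  }
  structure(list(mode = mode, sim = sim, alignments_dir = alignments_dir,
                 reference_newick = reference_newick, tv_split = tv_split,
                 selection = selection, search = search,
                 exhaustive_sizes = exhaustive_sizes,
                 builder_engine = builder_engine,
                 builder_correction = builder_correction,
                 external_command = external_command,
                 validation_mode = validation_mode,
                 cross_threshold = cross_threshold,
                 max_retries = as.integer(max_retries),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Nested keys `sim` and `selection` are passed to [simulation_config()]
#' and [selection_config()]; all other keys map to [pipeline_config()]
#' arguments.
#'
#' @param path Path to a JSON configuration file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$sim)) args$sim <- do.call(simulation_config, raw$sim)
  if (!is.null(raw$selection)) {
    args$selection <- do.call(selection_config, raw$selection)
  }
  do.call(pipeline_config, args)
}

restrict_alignment <- function(aln, species) {
  keep <- intersect(names(aln$seqs), species)
  if (length(keep) == 0L) return(NULL)
  gene_alignment(aln$gene_id, aln$seqs[keep])
}

pipeline_builder <- function(cfg) {
  if (cfg$builder_engine == "nj") {
    nj_builder(correction = cfg$builder_correction)
  } else {
    if (is.null(cfg$external_command)) {
      stop("external engine requires 'external_command'")
    }
    external_builder(cfg$external_command)
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full marker-selection pipeline
#'
#' Executes, in order: input loading or simulation, training/validation
#' partitioning, reference construction, gene ranking, progressive
#' concatenation, subset minimization and validation, persisting every
#' intermediate artifact under `out_dir` (`reference.nwk`, `ranking.tsv`,
#' `initial_set.txt`, `final_set.txt`, `trace.tsv`, `validation.json`,
#' `report.json`). Rerunning with the same config and seed reproduces the
#' report byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run report (a list), invisibly readable from
#'   `report.json`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$mode == "alignments" && !dir.exists(cfg$alignments_dir)) {
    stop(sprintf("alignment directory does not exist: %s",
                 cfg$alignments_dir))
  }
  if (!is.null(cfg$reference_newick) && !file.exists(cfg$reference_newick)) {
    stop(sprintf("reference tree file does not exist: %s",
                 cfg$reference_newick))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  builder <- pipeline_builder(cfg)

  input <- run_stage("input", {
    if (cfg$mode == "simulated") {
      ds <- synthesize_benchmark(cfg$sim, seed = cfg$rng_seed)
      list(alignments = ds$alignments, t_set = ds$t_set, v_set = ds$v_set)
    } else {
      files <- sort(list.files(cfg$alignments_dir,
                               pattern = "\\.(fa|fasta|faa|afa|aln)$",
                               full.names = TRUE, ignore.case = TRUE))
      if (length(files) == 0L) stop("no FASTA files found")
      alns <- lapply(files, read_fasta_alignment)
      names(alns) <- vapply(alns, `[[`, character(1), "gene_id")
      species <- sort(unique(unlist(lapply(alns, function(a) names(a$seqs)))))
      if (is.list(cfg$tv_split)) {
        t_set <- sort(intersect(cfg$tv_split$t, species))
        v_set <- sort(intersect(cfg$tv_split$v, species))
      } else {
        n_t <- max(4L, round(cfg$tv_split * length(species)))
        t_set <- withr::with_seed(cfg$rng_seed,
                                  sort(sample(species, n_t)))
        v_set <- sort(setdiff(species, t_set))
      }
      list(alignments = alns, t_set = t_set, v_set = v_set)
    }
  })

  t_alns <- run_stage("partition", {
    out <- lapply(input$alignments, restrict_alignment, input$t_set)
    out <- Filter(function(a) !is.null(a) && length(a$seqs) >= 4L, out)
    if (length(out) == 0L) stop("no genes cover the training species")
    out
  })

  reference <- run_stage("reference", {
    if (!is.null(cfg$reference_newick)) {
      parse_newick(paste(readLines(cfg$reference_newick), collapse = ""))
    } else {
      build_reference(t_alns, builder)
    }
  })
  writeLines(write_newick(reference), file.path(out_dir, "reference.nwk"))

  sel <- run_stage("selection", {
    select_minimal_set(t_alns, reference = reference, cfg = cfg$selection,
                       builder = builder, search = cfg$search,
                       exhaustive_sizes = cfg$exhaustive_sizes)
  })
  retries_used <- 0L
  validation <- NULL

  evaluate_validation <- function(final_set) {
    run_stage("validation", {
      out <- list()
      if (length(input$v_set) >= 4L &&
          cfg$validation_mode %in% c("cross", "both")) {
        v_alns <- lapply(input$alignments, restrict_alignment, input$v_set)
        v_alns <- Filter(Negate(is.null), v_alns)
        out$cross <- cross_validate(final_set, v_alns, builder,
                                    threshold = cfg$cross_threshold)
      }
      if (length(input$v_set) >= 1L &&
          cfg$validation_mode %in% c("one_species", "both")) {
        vh <- holdout_homologs(input$alignments, input$v_set)
        out$one_species <- one_species_at_a_time(final_set, t_alns, vh,
                                                 builder)
      }
      out$pass <- all(vapply(out[c("cross", "one_species")],
                             function(r) is.null(r) || isTRUE(r$pass),
                             logical(1)))
      out
    })
  }

  validation <- evaluate_validation(sel$final_set)
  while (!validation$pass && retries_used < cfg$max_retries) {
    retries_used <- retries_used + 1L
    cfg2 <- cfg$selection
    cfg2$rng_seed <- cfg2$rng_seed + retries_used
    sel <- run_stage("selection", {
      select_minimal_set(t_alns, reference = reference, cfg = cfg2,
                         builder = builder, search = cfg$search,
                         exhaustive_sizes = cfg$exhaustive_sizes)
    })
    validation <- evaluate_validation(sel$final_set)
  }

  run_stage("report", {
    utils::write.table(as.data.frame(sel$ranking),
                       file.path(out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sel$initial_set, file.path(out_dir, "initial_set.txt"))
    writeLines(sel$final_set, file.path(out_dir, "final_set.txt"))
    trace <- if (!is.null(sel$selection)) sel$selection$trace else empty_trace()
    utils::write.table(trace, file.path(out_dir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    val_json <- list(
      pass = validation$pass,
      cross = if (!is.null(validation$cross)) {
        list(rf = validation$cross$rf,
             normalized_rf = validation$cross$normalized_rf,
             markers_used = validation$cross$markers_used,
             pass = validation$cross$pass)
      },
      one_species = if (!is.null(validation$one_species)) {
        list(per_species = validation$one_species$per_species,
             pass = validation$one_species$pass)
      })
    jsonlite::write_json(val_json, file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    report <- list(
      mode = cfg$mode,
      seed = cfg$rng_seed,
      measure = cfg$selection$measure,
      cutoff = cfg$selection$cutoff,
      selection_seed = cfg$selection$rng_seed,
      n_species = length(input$t_set) + length(input$v_set),
      t_set = input$t_set,
      v_set = input$v_set,
      n_genes = length(t_alns),
      initial_set = sel$initial_set,
      converged = sel$converged,
      final_set = sel$final_set,
      final_distance = sel$final_distance,
      termination = if (!is.null(sel$selection)) {
        sel$selection$termination
      } else if (sel$converged) "skipped" else "not_converged",
      retries_used = retries_used,
      validation_pass = validation$pass)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(report)
  })
}
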