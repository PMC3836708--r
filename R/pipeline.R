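#' Pipeline run configuration
#'
#' Bundles the per-stage configurations under one seed. Unknown keys in any
#' section are rejected, so misspelled options fail loudly.
#'
#' @param seed Top-level seed; all randomness flows from it.
#' @param out_dir Output directory for artifact files (NULL for none).
#' @param synth Named list of [synthetic_config()] overrides.
#' @param align Named list of [align_config()] overrides.
#' @param filter Named list of [filter_config()] overrides.
#' @param enrich Named list: `min_genes` (rarity threshold), `method`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, synth = list(),
                       align = list(), filter = list(), enrich = list()) {
  check_keys <- function(given, allowed, section) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown) > 0L) {
      stop("unknown key(s) in ", section, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  check_keys(synth, setdiff(names(formals(synthetic_config)), "seed"),
             "synth")
  check_keys(align, names(formals(align_config)), "align")
  check_keys(filter, names(formals(filter_config)), "filter")
  check_keys(enrich, c("min_genes", "method"), "enrich")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synth = synth, align = align, filter = filter,
                 enrich = enrich),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with optional sections `seed`, `out_dir`,
#'   `synth`, `align`, `filter`, `enrich`.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "synth", "align", "filter", "enrich")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "))
  }
  run_config(seed = if (is.null(y$seed)) 1L else y$seed,
             out_dir = y$out_dir,
             synth = if (is.null(y$synth)) list() else y$synth,
             align = if (is.null(y$align)) list() else y$align,
             filter = if (is.null(y$filter)) list() else y$filter,
             enrich = if (is.null(y$enrich)) list() else y$enrich)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

#' Run the full discovery pipeline on a synthetic genome pair
#'
#' Orchestrates simulate, align, filter-cascade, gene assignment and
#' domain enrichment, returning a machine-readable run report. All stage
#' outputs are also written under `cfg$out_dir` when set.
#'
#' @param cfg [run_config()].
#' @param quiet Suppress the funnel log lines.
#' @return List of class `run_report` with elements `funnel`, `retained`
#'   (count), `evidence_class_counts`, `per_gene`, `recovery`,
#'   `enrichment` (table), `decoys` (stage report), `config_hash`,
#'   `package_version`, plus the full tables under `tables`.
#' @export
run_all <- function(cfg = run_config(), quiet = FALSE) {
  set.seed(cfg$seed)
  scfg <- do.call(synthetic_config, c(list(seed = cfg$seed), cfg$synth))
  acfg <- do.call(align_config, cfg$align)
  fcfg <- do.call(filter_config, cfg$filter)
  min_genes <- if (is.null(cfg$enrich$min_genes)) 10L else cfg$enrich$min_genes
  method <- if (is.null(cfg$enrich$method)) "fisher" else cfg$enrich$method

  sim_dir <- if (!is.null(cfg$out_dir)) file.path(cfg$out_dir, "sim") else NULL
  sim <- generate_pair(scfg, sim_dir)

  hits <- run_search(sim$genome_a, sim$genome_b, acfg)
  cascade <- run_cascade(hits,
                         list(exons = sim$exons, ncrna = sim$ncrna,
                              ests = sim$ests),
                         sim$genome_a, fcfg, acfg)
  if (!quiet) {
    for (i in seq_len(nrow(cascade$funnel))) {
      message(sprintf("funnel %-15s %6d -> %6d",
                      cascade$funnel$stage[i], cascade$funnel$n_in[i],
                      cascade$funnel$n_out[i]))
    }
  }

  retained <- cascade$retained
  assignments <- assign_nearest_tss(retained, sim$genes)
  per_gene <- if (any(!is.na(assignments$gene_id))) {
    per_gene_stats(assignments)
  } else {
    list(n_assigned = 0L, n_unassigned = nrow(assignments),
         n_genes = 0L, mean_per_gene = NA_real_)
  }
  cne_gene_ids <- unique(assignments$gene_id[!is.na(assignments$gene_id)])
  enrichment <- enrich_all(cne_gene_ids, sim$genes$gene_id, sim$domains,
                           hierarchy = sim$hierarchy,
                           min_genes = min_genes, method = method)
  recovery <- score_recovery(sim$truth, retained)
  decoys <- decoy_stage_report(sim$truth, cascade$elements)

  evidence <- c(none = sum(retained$evidence_class == "none"),
                weak = sum(retained$evidence_class == "weak"))

  report <- structure(list(
    funnel = cascade$funnel,
    retained = nrow(retained),
    evidence_class_counts = evidence,
    per_gene = per_gene,
    recovery = list(recall = recovery$recall,
                    precision = recovery$precision),
    decoys_all_ok = all(decoys$ok),
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("cneforge")),
    tables = list(hits = hits, elements = cascade$elements,
                  retained = retained, assignments = assignments,
                  enrichment = enrichment, decoys = decoys,
                  confusion = recovery$confusion,
                  truth = sim$truth),
    sim = sim
  ), class = "run_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_file(hits[, setdiff(names(hits), "ops")],
                   file.path(cfg$out_dir, "hits.tsv"))
    write_tsv_file(cascade$funnel, file.path(cfg$out_dir, "funnel.tsv"))
    write_tsv_file(cascade$elements,
                   file.path(cfg$out_dir, "elements.tsv"))
    if (nrow(retained) > 0L) {
      bed <- data.frame(seq_id = retained$a_seq, start = retained$a_start,
                        end = retained$a_end, name = retained$element_id,
                        stringsAsFactors = FALSE)
      write_bed(bed, file.path(cfg$out_dir, "cnes.bed"))
    } else {
      writeLines(character(0), file.path(cfg$out_dir, "cnes.bed"))
    }
    write_tsv_file(assignments, file.path(cfg$out_dir, "assignments.tsv"))
    write_tsv_file(enrichment, file.path(cfg$out_dir, "enrichment.tsv"))
    write_run_report(report, file.path(cfg$out_dir, "report.json"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report` from [run_all()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- list(
    funnel = report$funnel,
    retained = report$retained,
    evidence_class_counts = as.list(report$evidence_class_counts),
    per_gene = report$per_gene,
    recovery = report$recovery,
    decoys_all_ok = report$decoys_all_ok,
    config_hash = report$config_hash,
    package_version = report$package_version
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("cneforge run report\n")
  cat("  retained elements:", x$retained, "\n")
  cat("  evidence classes: none =", x$evidence_class_counts[["none"]],
      ", weak =", x$evidence_class_counts[["weak"]], "\n")
  if (!is.null(x$per_gene$mean_per_gene)) {
    cat("  associated genes:", x$per_gene$n_genes,
        sprintf("(%.1f elements per gene)", x$per_gene$mean_per_gene), "\n")
  }
  cat(sprintf("  recovery: recall %.3f, precision %.3f\n",
              x$recovery$recall, x$recovery$precision))
  cat("  funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("    %-15s %6d -> %6d\n", x$funnel$stage[i],
                x$funnel$n_in[i], x$funnel$n_out[i]))
  }
  invisible(x)
}
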