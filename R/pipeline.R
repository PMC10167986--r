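# End-to-end pipeline driver and flat key=value configuration.

pipeline_defaults <- function() {
  list(genes = NULL, blast = NULL, out_dir = "paleosynteny_out",
       gene_dialect = "tsv", species = NULL,
       cip_min = 50, calp_min = 50, direction = "either",
       tandem_window = 5L, min_anchors = 6L, max_gap = 15,
       reference = "median", multiplicity = NULL,
       dataset_name = "dataset", dataset_version = 1L,
       contact_name = "unknown", contact_email = "unknown@example.org",
       seed = 1L)
}

#' Read a flat key = value pipeline configuration file
#'
#' One `key = value` per line; `#` starts a comment; unknown keys are
#' rejected. `multiplicity` is a comma-separated list of `A>B:n` entries.
#'
#' @param path config file.
#' @return named list merged over the documented defaults.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- pipeline_defaults()
  numeric_keys <- c("cip_min", "calp_min", "tandem_window", "min_anchors",
                    "max_gap", "dataset_version", "seed")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    if (key %in% numeric_keys) val <- as.numeric(val)
    cfg[[key]] <- val
  }
  cfg
}

parse_multiplicity <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(NULL)
  entries <- strsplit(spec, ",", fixed = TRUE)[[1]]
  parts <- strsplit(entries, "[>:]")
  multiplicity_map(
    species_a = vapply(parts, `[`, character(1), 1),
    species_b = vapply(parts, `[`, character(1), 2),
    n = as.integer(vapply(parts, `[`, character(1), 3)))
}

#' Run the four-step reconstruction pipeline
#'
#' Reads gene positions and BLAST tabular input, runs Steps 1-4, and writes
#' one tabular file per step plus the karyotype tables, the submission
#' workbook and a JSON run manifest (parameters, package version, input
#' checksums). Any stage failure aborts with an error naming the stage.
#' Re-running with identical inputs and configuration reproduces identical
#' outputs.
#'
#' @param config a config list (see [read_pipeline_config()]) or the path of
#'   a config file.
#' @param ... individual keys overriding the config file values.
#' @return Invisibly, a list with output paths and per-stage record counts.
#' @export
run_pipeline <- function(config = list(), ...) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg <- utils::modifyList(cfg, list(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  genes <- stage("io_formats", {
    if (is.null(cfg$genes)) stop("no gene table configured")
    read_gene_table(cfg$genes, dialect = cfg$gene_dialect, species = cfg$species)
  })
  hsps <- stage("io_formats", {
    if (is.null(cfg$blast)) stop("no BLAST table configured")
    read_blast_tabular(cfg$blast)
  })
  qlen <- stage("io_formats", {
    if (!"protein_length" %in% names(genes)) {
      stop("gene table lacks a protein_length column (needed for CALP)")
    }
    setNames(as.numeric(genes$protein_length), genes$gene_id)
  })
  message(sprintf("[io_formats] %d genes (%d species), %d HSPs",
                  nrow(genes), length(unique(genes$species)), nrow(hsps)))

  step1 <- stage("homology", {
    summ <- summarize_hsps(hsps, qlen)
    filter_conserved_pairs(summ, cip_min = cfg$cip_min, calp_min = cfg$calp_min,
                           direction = cfg$direction, genes = genes)
  })
  counts$conserved_pairs <- nrow(step1)
  fwrite(step1, file.path(cfg$out_dir, "step1_conserved_pairs.tsv"), sep = "\t")
  message(sprintf("[homology] %d conserved pairs", nrow(step1)))

  step2 <- stage("orthology", {
    collapsed <- collapse_tandem_duplicates(step1, genes, window = cfg$tandem_window)
    fwrite(collapsed$report, file.path(cfg$out_dir, "step2_tandem_report.tsv"), sep = "\t")
    mult <- if (is.character(cfg$multiplicity)) parse_multiplicity(cfg$multiplicity)
            else cfg$multiplicity
    assign_orthologs(collapsed$pairs, mult)
  })
  counts$orthologs <- nrow(step2)
  fwrite(step2, file.path(cfg$out_dir, "step2_orthologs.tsv"), sep = "\t")
  message(sprintf("[orthology] %d ortholog relationships", nrow(step2)))

  blocks <- stage("synteny", {
    anchors <- build_anchors(step2, genes)
    chain_all_blocks(anchors, min_anchors = cfg$min_anchors, max_gap = cfg$max_gap)
  })
  counts$blocks <- nrow(blocks$blocks)
  fwrite(blocks$anchors, file.path(cfg$out_dir, "step3_anchors.tsv"), sep = "\t")
  fwrite(blocks$blocks, file.path(cfg$out_dir, "step3_blocks.tsv"), sep = "\t")
  message(sprintf("[synteny] %d blocks from %d anchors",
                  nrow(blocks$blocks), nrow(blocks$anchors)))

  kary <- stage("karyotype", {
    k <- group_blocks_into_cars(blocks)
    k <- order_protogenes(k, genes, reference = cfg$reference)
    k <- backfill_conserved_genes(k, step1)
    classify_protogenes(k)
  })
  counts$cars <- nrow(kary$cars)
  counts$protogenes <- nrow(kary$protogenes)
  fwrite(merge(kary$protogenes, kary$members, by = "pg_id"),
         file.path(cfg$out_dir, "step4_protogenes.tsv"), sep = "\t")
  fwrite(kary$segments, file.path(cfg$out_dir, "step4_derivation.tsv"), sep = "\t")
  message(sprintf("[karyotype] %d CARs, %d protogenes (%d core)",
                  nrow(kary$cars), nrow(kary$protogenes),
                  sum(kary$protogenes$status == "core", na.rm = TRUE)))

  wb_path <- stage("io_formats", {
    contact <- data.table(name = cfg$contact_name, email = cfg$contact_email,
                          role = "submitter")
    wb <- build_submission_workbook(kary, genes, contact,
                                    dataset_name = cfg$dataset_name,
                                    version = cfg$dataset_version)
    write_submission_workbook(wb, file.path(cfg$out_dir, "workbook"))
  })

  manifest <- list(
    package = "paleosynteny",
    version = as.character(utils::packageVersion("paleosynteny")),
    parameters = cfg[setdiff(names(cfg), c("genes", "blast"))],
    inputs = list(genes = unname(tools::md5sum(cfg$genes)),
                  blast = unname(tools::md5sum(cfg$blast))),
    counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = cfg$out_dir, counts = counts, karyotype = kary,
                 workbook = wb_path))
}

#' Run the in-memory pipeline on a simulated dataset
#'
#' Convenience wrapper chaining Steps 1-4 on the output of
#' [simulate_synteny_dataset()] without touching disk; used throughout the
#' test-suite and handy for parameter exploration.
#'
#' @param sim simulator output.
#' @param cip_min,calp_min,direction Step-1 thresholds.
#' @param tandem_window Step-2 tandem collapse window.
#' @param mult multiplicity map (see [multiplicity_map()]).
#' @param min_anchors,max_gap Step-3 chaining parameters.
#' @param reference ordering reference species (or `"median"`).
#' @param backfill attach Step-1 conserved genes beyond 1:1 relations.
#' @return list: `pairs`, `orthologs`, `blocks`, `karyotype`.
#' @export
reconstruct_from_simulation <- function(sim, cip_min = 50, calp_min = 50,
                                        direction = "either",
                                        tandem_window = 5L, mult = NULL,
                                        min_anchors = 6L, max_gap = 15,
                                        reference = "median",
                                        backfill = TRUE) {
  summ <- summarize_hsps(sim$hsps, sim$query_lengths)
  pairs <- filter_conserved_pairs(summ, cip_min, calp_min, direction, genes = sim$genes)
  collapsed <- collapse_tandem_duplicates(pairs, sim$genes, window = tandem_window)
  orth <- assign_orthologs(collapsed$pairs, mult)
  anchors <- build_anchors(orth, sim$genes)
  blocks <- chain_all_blocks(anchors, min_anchors = min_anchors, max_gap = max_gap)
  kary <- group_blocks_into_cars(blocks)
  kary <- order_protogenes(kary, sim$genes, reference = reference)
  if (backfill) kary <- backfill_conserved_genes(kary, pairs)
  kary <- classify_protogenes(kary)
  list(pairs = pairs, orthologs = orth, blocks = blocks, karyotype = kary)
}
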