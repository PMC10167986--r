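# Readers/writers for gene-position tables, BLAST tabular output and the
# four-sheet submission workbook, plus dataset-consistency validation.

#' Assign dense gene ranks along each chromosome
#'
#' Sorts gene records by `(species, chromosome, start, end, gene_id)` and
#' assigns a 0-based `rank` column densely (0..n-1) within each
#' `(species, chromosome)`. Rank, not base-pair position, is the coordinate
#' used by every downstream step: the method is gene-order based.
#'
#' @param genes data.table with at least `gene_id`, `species`, `chromosome`,
#'   `start`, `end` columns.
#' @return A new data.table with a dense 0-based `rank` column.
#' @export
assign_gene_ranks <- function(genes) {
  genes <- as.data.table(genes)
  if (nrow(genes) == 0L) {
    genes[, rank := integer(0)]
    return(genes[])
  }
  setorder(genes, species, chromosome, start, end, gene_id)
  genes[, rank := seq_len(.N) - 1L, by = .(species, chromosome)]
  genes[]
}

gene_table_cols <- c("gene_id", "species", "chromosome", "start", "end",
                     "strand", "rank")

empty_gene_table <- function() {
  data.table(gene_id = character(0), species = character(0),
             chromosome = character(0), start = integer(0), end = integer(0),
             strand = character(0), rank = integer(0))
}

check_gene_table <- function(genes) {
  bad <- which(genes$start > genes$end)
  if (length(bad)) {
    stop("start > end for gene(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         " (first gene_id: ", genes$gene_id[bad[1]], ")")
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id(s): ", paste(head(dup, 10), collapse = ", "))
  }
  invisible(genes)
}

#' Read a gene-position table
#'
#' Reads gene placements from either a simple TSV dialect (columns `gene_id`,
#' `species`, `chromosome`, `start`, `end`, optional `strand`, optional
#' `protein_length`) or a GFF3 file (features of type `gene`, identified by
#' their `ID` attribute; GFF3 files describe a single genome, so `species`
#' must be supplied). Coordinates are 1-based inclusive. Records are sorted by
#' `(species, chromosome, start)` and dense 0-based ranks are assigned per
#' chromosome.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param species species name, required for `dialect = "gff3"`.
#' @return data.table of gene records with a dense `rank` column.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"), species = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    if (file.size(path) == 0L) return(empty_gene_table())
    dt <- fread(path, sep = "\t", header = TRUE)
    for (cc in intersect(c("gene_id", "species", "chromosome", "strand"), names(dt))) {
      dt[[cc]] <- as.character(dt[[cc]])
    }
    need <- c("gene_id", "species", "chromosome", "start", "end")
    miss <- setdiff(need, names(dt))
    if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(dt) == 0L) return(empty_gene_table())
    if (!"strand" %in% names(dt)) dt[, strand := "+"]
    if (!is.numeric(dt$start) || !is.numeric(dt$end)) {
      stop("non-numeric start/end in gene table: ", path)
    }
    keep_cols <- intersect(c(gene_table_cols[gene_table_cols != "rank"],
                             "protein_length"), names(dt))
    dt <- dt[, keep_cols, with = FALSE]
  } else {
    if (is.null(species)) stop("species must be given for GFF3 input")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene feature(s) without an ID attribute in ", path)
    dt <- data.table(
      gene_id = as.character(ids),
      species = species,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
    dt[strand == "*", strand := "+"]
  }
  check_gene_table(dt)
  assign_gene_ranks(dt)
}

#' Default BLAST tabular columns (outfmt 6 extended with nident)
#'
#' The default column layout matches
#' `-outfmt "6 std nident"`: the 12 standard fields followed by the number of
#' identical matches, which CIP needs and percent identity alone cannot give.
#' @export
blast_outfmt6_nident <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                          "gapopen", "qstart", "qend", "sstart", "send",
                          "evalue", "bitscore", "nident")

#' Read all-vs-all BLAST tabular output
#'
#' One row per HSP. Self hits (`qseqid == sseqid`) are dropped. Column order
#' is configurable; names `qseqid`, `sseqid`, `length`, `nident`, `qstart`,
#' `qend`, `sstart`, `send`, `bitscore` must be present in `columns`.
#'
#' @param path file path (tab-separated, no header).
#' @param columns character vector naming the columns, in file order.
#' @return data.table of HSP records: `query_id`, `subject_id`, `hsp_length`,
#'   `n_identities`, `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `score`.
#' @export
read_blast_tabular <- function(path, columns = blast_outfmt6_nident) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("qseqid", "sseqid", "length", "nident", "qstart", "qend",
            "sstart", "send", "bitscore")
  miss <- setdiff(need, columns)
  if (length(miss)) stop("columns must include: ", paste(miss, collapse = ", "))
  if (file.size(path) == 0L) {
    return(data.table(query_id = character(0), subject_id = character(0),
                      hsp_length = integer(0), n_identities = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      subject_start = integer(0), subject_end = integer(0),
                      score = numeric(0)))
  }
  dt <- fread(path, sep = "\t", header = FALSE, col.names = columns)
  num_cols <- c("length", "nident", "qstart", "qend", "sstart", "send", "bitscore")
  for (cc in num_cols) {
    v <- dt[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) stop("non-numeric value in column '", cc, "' at row ", bad[1])
      dt[[cc]] <- vn
    }
  }
  bad <- which(dt$nident > dt$length | dt$length < 1)
  if (length(bad)) {
    stop("invalid HSP at row ", bad[1],
         ": nident (", dt$nident[bad[1]], ") > length (", dt$length[bad[1]],
         ") or length < 1")
  }
  out <- dt[qseqid != sseqid, .(
    query_id = as.character(qseqid), subject_id = as.character(sseqid),
    hsp_length = as.integer(length), n_identities = as.integer(nident),
    query_start = as.integer(qstart), query_end = as.integer(qend),
    subject_start = as.integer(sstart), subject_end = as.integer(send),
    score = as.numeric(bitscore))]
  out[]
}

# ---------------------------------------------------------------------------
# Submission workbook (four sheets + dataset descriptor)
# ---------------------------------------------------------------------------

#' Build a submission workbook from a reconstructed karyotype
#'
#' Assembles the four-sheet data-exchange object: (i) contact/author records,
#' (ii) genome features, (iii) chromosome phylogeny (modern chromosome to
#' ancestral CAR relations), and (iv) homology groups (one row per protogene
#' with its member genes). Column headers are this package's documented
#' dialect; the public template's exact headers are not standardized.
#'
#' @param karyotype an `ancestral_karyotype` (see [group_blocks_into_cars()]).
#' @param genes gene table covering every member gene.
#' @param contact data.frame/data.table with columns `name`, `email`, `role`.
#' @param dataset_name dataset identifier.
#' @param version integer dataset version (>= 1).
#' @param genome_versions optional named character vector, species -> assembly
#'   version string.
#' @return A `submission_workbook` object (list of four sheets + descriptor).
#' @export
build_submission_workbook <- function(karyotype, genes, contact,
                                      dataset_name = "dataset",
                                      version = 1L,
                                      genome_versions = NULL) {
  stopifnot(inherits(karyotype, "ancestral_karyotype"))
  genes <- as.data.table(genes)
  contact <- as.data.table(contact)
  if (!all(c("name", "email", "role") %in% names(contact))) {
    stop("contact sheet needs columns name, email, role")
  }
  missing_genes <- setdiff(karyotype$members$gene_id, genes$gene_id)
  if (length(missing_genes)) {
    stop("protogene member gene(s) absent from gene table: ",
         paste(head(missing_genes, 10), collapse = ", "))
  }
  genome <- genes[, .(gene_id, species, chromosome, start, end, strand, rank)]
  gv <- if (is.null(genome_versions)) "unversioned" else genome_versions[genome$species]
  gv <- as.character(gv)
  gv[is.na(gv)] <- "unversioned"
  genome[, genome_version := gv]

  phylogeny <- unique(karyotype$segments[, .(species, chromosome, car_id)])
  setorder(phylogeny, species, chromosome, car_id)

  mem <- merge(karyotype$members, karyotype$protogenes[, .(pg_id, car_id, ancestral_rank, status)],
               by = "pg_id")
  setorder(mem, pg_id, species, gene_id)
  serialize_members <- function(gene_id, backfilled, species) {
    tagged <- paste0(gene_id, ifelse(backfilled, "*", ""))
    per_sp <- vapply(split(tagged, species), paste, character(1), collapse = ",")
    paste(paste0(names(per_sp), ":", per_sp), collapse = ";")
  }
  homology <- mem[, .(members = serialize_members(gene_id, backfilled, species)),
                  by = .(pg_id, car_id, ancestral_rank, status)]
  setorder(homology, car_id, ancestral_rank, pg_id)

  wb <- list(contact = contact[, .(name, email, role)],
             genome = genome, phylogeny = phylogeny, homology = homology,
             dataset_name = dataset_name, version = as.integer(version))
  class(wb) <- "submission_workbook"
  wb
}

#' Write a submission workbook
#'
#' Writes the canonical tab-delimited dialect: a directory containing
#' `contact.tsv`, `genome.tsv`, `phylogeny.tsv`, `homology_group.tsv` and a
#' `dataset.tsv` descriptor (name, version). Refuses to write a workbook whose
#' homology sheet references genes absent from the genome sheet.
#'
#' @param wb a `submission_workbook`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_submission_workbook <- function(wb, path) {
  stopifnot(inherits(wb, "submission_workbook"))
  member_ids <- workbook_member_genes(wb)
  missing_genes <- setdiff(member_ids, wb$genome$gene_id)
  if (length(missing_genes)) {
    stop("refusing to write: homology sheet references unknown gene(s): ",
         paste(head(missing_genes, 10), collapse = ", "))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fwrite(wb$contact, file.path(path, "contact.tsv"), sep = "\t")
  fwrite(wb$genome, file.path(path, "genome.tsv"), sep = "\t")
  fwrite(wb$phylogeny, file.path(path, "phylogeny.tsv"), sep = "\t")
  fwrite(wb$homology, file.path(path, "homology_group.tsv"), sep = "\t")
  fwrite(data.table(dataset = wb$dataset_name, version = wb$version),
         file.path(path, "dataset.tsv"), sep = "\t")
  invisible(path)
}

#' Read a submission workbook written by [write_submission_workbook()]
#' @param path workbook directory.
#' @return A `submission_workbook`.
#' @export
read_submission_workbook <- function(path) {
  rd <- function(f, chr_cols) {
    dt <- fread(file.path(path, f), sep = "\t", header = TRUE)
    for (cc in intersect(chr_cols, names(dt))) dt[[cc]] <- as.character(dt[[cc]])
    dt
  }
  ds <- rd("dataset.tsv", "dataset")
  wb <- list(
    contact = rd("contact.tsv", c("name", "email", "role")),
    genome = rd("genome.tsv", c("gene_id", "species", "chromosome", "strand",
                                "genome_version")),
    phylogeny = rd("phylogeny.tsv", c("species", "chromosome", "car_id")),
    homology = rd("homology_group.tsv", c("pg_id", "car_id", "status", "members")),
    dataset_name = ds$dataset[1], version = as.integer(ds$version[1]))
  class(wb) <- "submission_workbook"
  wb
}

# member gene ids referenced by the homology sheet ("*" marks back-filled)
workbook_member_genes <- function(wb) {
  if (nrow(wb$homology) == 0L) return(character(0))
  specs <- unlist(strsplit(wb$homology$members, ";", fixed = TRUE))
  genes <- unlist(lapply(strsplit(specs, ":", fixed = TRUE), function(x) {
    strsplit(x[2], ",", fixed = TRUE)[[1]]
  }))
  sub("\\*$", "", genes)
}

#' Validate a submission workbook
#'
#' Enumerates every violation of the workbook consistency rules: identifier
#' unicity in the genome and homology sheets, dangling gene references from
#' the homology sheet, phylogeny rows naming chromosomes absent from the
#' genome sheet, and (when a `registry` of already-loaded datasets is given)
#' dataset name/version conflicts. Violations are data, not errors: an empty
#' report means the workbook is loadable.
#'
#' @param wb a `submission_workbook`.
#' @param registry optional dataset registry (see [register_dataset()]).
#' @return data.table with columns `rule`, `entity`, `message`.
#' @export
validate_workbook <- function(wb, registry = NULL) {
  v <- list()
  add <- function(rule, entity, message) {
    v[[length(v) + 1L]] <<- data.table(rule = rule, entity = entity, message = message)
  }
  dup <- unique(wb$genome$gene_id[duplicated(wb$genome$gene_id)])
  for (g in dup) add("unicity.gene_id", g, paste0("gene_id '", g, "' appears more than once in genome sheet"))
  dupg <- unique(wb$homology$pg_id[duplicated(wb$homology$pg_id)])
  for (g in dupg) add("unicity.pg_id", g, paste0("pg_id '", g, "' appears more than once in homology sheet"))
  dangling <- setdiff(workbook_member_genes(wb), wb$genome$gene_id)
  for (g in dangling) add("reference.homology_gene", g,
                          paste0("homology sheet references unknown gene '", g, "'"))
  if (nrow(wb$phylogeny)) {
    known <- unique(wb$genome[, paste(species, chromosome)])
    ph <- wb$phylogeny[!paste(species, chromosome) %in% known]
    for (i in seq_len(nrow(ph))) {
      add("reference.phylogeny_chromosome", paste(ph$species[i], ph$chromosome[i]),
          paste0("phylogeny sheet names unknown chromosome '", ph$chromosome[i],
                 "' of species '", ph$species[i], "'"))
    }
  }
  if (is.na(wb$version) || wb$version < 1L) {
    add("version.invalid", as.character(wb$version), "dataset version must be a positive integer")
  }
  if (!is.null(registry) && nrow(registry)) {
    hit <- registry[dataset == wb$dataset_name & version == wb$version]
    if (nrow(hit)) add("version.conflict", paste0(wb$dataset_name, " v", wb$version),
                       "this (dataset, version) is already loaded")
  }
  if (!length(v)) {
    return(data.table(rule = character(0), entity = character(0), message = character(0)))
  }
  rbindlist(v)
}

#' Register a dataset version
#'
#' Maintains the append-only dataset registry: loading version v of a dataset
#' marks every earlier version obsolete; loading an already-present
#' `(dataset, version)` is an error (unicity).
#'
#' @param registry data.table(`dataset`, `version`, `obsolete`) or `NULL`.
#' @param dataset_name dataset identifier.
#' @param version integer version.
#' @return Updated registry.
#' @export
register_dataset <- function(registry, dataset_name, version) {
  if (is.null(registry)) {
    registry <- data.table(dataset = character(0), version = integer(0),
                           obsolete = logical(0))
  }
  ver <- as.integer(version)
  if (any(registry$dataset == dataset_name & registry$version == ver)) {
    stop("dataset '", dataset_name, "' version ", ver, " already registered")
  }
  registry <- copy(registry)
  registry[dataset == dataset_name, obsolete := TRUE]
  rbind(registry, data.table(dataset = dataset_name, version = ver,
                             obsolete = FALSE))
}
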