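# Plain-text serialisation: gene tables as TSV (genes x samples), catalogs
# and ground truth as JSON, gene->KO maps as 2-column TSV, module
# definitions in a line-based dialect of KEGG-module step logic.

#' Read / write an abundance table as TSV
#'
#' Tables are stored genes-in-rows, samples-in-columns, with the feature id
#' in the first column (`feature`).
#'
#' @param x numeric matrix, features x samples.
#' @param path file path.
#' @return `read_table_tsv` returns a numeric matrix with dimnames.
#' @export
write_table_tsv <- function(x, path) {
  check_table(x)
  dt <- data.table::data.table(feature = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(x))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Read / write an MGS catalog as JSON
#'
#' The JSON layout maps each MGS id to its gene list, marker subset and
#' genus/species labels, alongside the gene-to-KO map, module definitions
#' and planted producer/degrader membership.
#'
#' @param catalog an `mgs_catalog`.
#' @param path file path.
#' @return `read_catalog_json` returns an `mgs_catalog`.
#' @export
write_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "mgs_catalog"))
  out <- list(mgs = catalog$mgs,
              gene_ko = catalog$gene_ko,
              modules = unname(lapply(catalog$modules, function(m) {
                m$steps <- lapply(m$steps, as.list); m
              })),
              amino_acids = catalog$amino_acids,
              producers = catalog$producers,
              degraders = catalog$degraders)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  raw <- jsonlite::read_json(path)
  mods <- lapply(raw$modules, function(m) {
    list(id = m$id, name = m$name, source = m$source, category = m$category,
         amino_acid = if (is.null(m$amino_acid)) NA_character_ else m$amino_acid,
         steps = lapply(m$steps, function(s) unlist(s, use.names = FALSE)))
  })
  names(mods) <- vapply(mods, `[[`, "", "id")
  structure(list(
    mgs = lapply(raw$mgs, function(m)
      list(genes = unlist(m$genes), markers = unlist(m$markers),
           genus = m$genus, species = m$species)),
    gene_ko = data.frame(gene = vapply(raw$gene_ko, `[[`, "", "gene"),
                         ko = vapply(raw$gene_ko, `[[`, "", "ko"),
                         stringsAsFactors = FALSE),
    modules = mods,
    amino_acids = unlist(raw$amino_acids),
    producers = lapply(raw$producers, function(x) unlist(x)),
    degraders = lapply(raw$degraders, function(x) unlist(x))),
    class = "mgs_catalog")
}

#' Read / write module definitions as structured text
#'
#' One module per block: a header line
#' `MODULE<tab>id<tab>name<tab>category<tab>source<tab>amino_acid` followed
#' by one line per ordered step listing its alternative KO ids separated by
#' commas. `amino_acid` is `-` for modules outside amino-acid metabolism.
#'
#' @param modules a named list of module definitions.
#' @param path file path.
#' @return `read_modules_txt` returns the named module list.
#' @export
write_modules_txt <- function(modules, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in modules) {
    writeLines(paste("MODULE", m$id, m$name, m$category, m$source,
                     ifelse(is.na(m$amino_acid), "-", m$amino_acid),
                     sep = "\t"), con)
    for (s in m$steps) writeLines(paste(s, collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_modules_txt
#' @export
read_modules_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  modules <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      if (length(cur$steps) == 0)
        fail("module '%s' has no steps", cur$id)
      modules[[cur$id]] <<- cur
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "MODULE\t")) {
      flush()
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 6) fail("malformed MODULE header: %s", ln)
      cur <- list(id = f[2], name = f[3], category = f[4], source = f[5],
                  amino_acid = if (f[6] == "-") NA_character_ else f[6],
                  steps = list())
    } else {
      if (is.null(cur)) fail("step line before any MODULE header")
      kos <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (!length(kos)) fail("empty step in module '%s'", cur$id)
      cur$steps[[length(cur$steps) + 1L]] <- kos
    }
  }
  flush()
  modules
}

#' Write a full synthetic cohort to a directory
#'
#' Emits `genes.tsv` (integer counts, genes x samples), `catalog.json`,
#' `gene_ko.tsv`, `modules.txt`, `metadata.tsv` and `truth.json`.
#'
#' @param cohort output of [generate_cohort()].
#' @param catalog the matching [generate_catalog()] output.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(cohort$genes, file.path(dir, "genes.tsv"))
  write_catalog_json(catalog, file.path(dir, "catalog.json"))
  data.table::fwrite(catalog$gene_ko, file.path(dir, "gene_ko.tsv"), sep = "\t")
  write_modules_txt(catalog$modules, file.path(dir, "modules.txt"))
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t")
  truth <- cohort$truth
  truth$abundance <- cbind(data.frame(mgs = rownames(truth$abundance)),
                           as.data.frame(truth$abundance))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
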