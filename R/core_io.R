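# Domain containers and delimited-text IO shared by every pipeline stage.

#' Measurement platforms recognized for metabolite features
#'
#' Five mass-spectrometry platforms commonly combined in broad plasma
#' metabolomics panels: gas chromatography (primary metabolites), HILIC
#' (biogenic amines), CSH lipidomics (complex lipids), and targeted assays
#' for bile acids/steroids and oxylipins.
#'
#' @export
MD_PLATFORMS <- c("GC", "HILIC", "CSH-lipidomics", "bile-steroids", "oxylipins")

#' Construct an abundance table
#'
#' The central data container: a samples-by-features matrix of non-negative
#' abundances (arbitrary intensity units) with `NA` marking values below the
#' detection limit, plus one platform label per feature.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids). Entries must be `NA` or
#'   finite and >= 0.
#' @param platform Character vector of platform labels, one per feature
#'   (recycled if length 1). Must be drawn from [MD_PLATFORMS].
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, platform = "GC") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in abundance matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in abundance matrix")
  v <- values[!is.na(values)]
  if (any(!is.finite(v)) || any(v < 0))
    stop("abundances must be missing (NA) or finite and non-negative")
  platform <- rep_len(as.character(platform), ncol(values))
  if (!all(platform %in% MD_PLATFORMS))
    stop("unknown platform label(s): ",
         paste(setdiff(platform, MD_PLATFORMS), collapse = ", "))
  names(platform) <- colnames(values)
  structure(list(values = values, platform = platform),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d features (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("platforms:", paste(sprintf("%s=%d", names(table(x$platform)),
                                  table(x$platform)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table by feature or sample ids
#'
#' @param table An [abundance_table()].
#' @param features,samples Character vectors of ids to keep (NULL = all).
#' @return An `abundance_table`.
#' @export
subset_abundance <- function(table, features = NULL, samples = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  abundance_table(v, table$platform[colnames(v)])
}

# ---- sample metadata ------------------------------------------------------

.normalize_sex <- function(x) {
  out <- c(f = "F", female = "F", m = "M", male = "M")[tolower(as.character(x))]
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    stop("unknown sex token(s): ", paste(unique(x[bad]), collapse = ", "))
  unname(out)
}

.normalize_role <- function(x) {
  out <- c(study = "study", qc = "QC", blank = "blank")[tolower(as.character(x))]
  bad <- is.na(out)
  if (any(bad))
    stop("unknown role token(s): ", paste(unique(x[bad]), collapse = ", "))
  unname(out)
}

#' Validate a sample metadata table
#'
#' Checks the contract every statistical stage relies on: unique sample ids,
#' normalized sex (`F`/`M`) and role (`study`/`QC`/`blank`) tokens, and a sex
#' and genotype for every study sample. `WT` is the reserved genotype label
#' for wildtype controls.
#'
#' @param meta Data frame with columns `sample_id`, `sex`, `genotype`,
#'   `zygosity`, `role`, `batch` and optionally `body_weight` (grams).
#' @return The validated metadata as a tibble (sex/role tokens normalized).
#' @export
validate_sample_meta <- function(meta) {
  meta <- tibble::as_tibble(meta)
  for (col in intersect(c("sample_id", "sex", "genotype", "zygosity",
                          "role", "batch"), names(meta)))
    meta[[col]] <- as.character(meta[[col]])
  if ("body_weight" %in% names(meta))
    meta$body_weight <- as.numeric(meta$body_weight)
  need <- c("sample_id", "sex", "genotype", "role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  meta$role <- .normalize_role(meta$role)
  study <- meta$role == "study"
  if (any(study & (is.na(meta$sex) | meta$sex == "")))
    stop("every study sample must have a sex")
  meta$sex[!is.na(meta$sex) & meta$sex != ""] <-
    .normalize_sex(meta$sex[!is.na(meta$sex) & meta$sex != ""])
  if (any(study & (is.na(meta$genotype) | meta$genotype == "")))
    stop("every study sample must have a genotype")
  if (!"zygosity" %in% names(meta)) meta$zygosity <- NA_character_
  if (!"batch" %in% names(meta)) meta$batch <- "B1"
  if (!"body_weight" %in% names(meta)) meta$body_weight <- NA_real_
  meta
}

#' Study samples of a metadata table
#'
#' @param meta Validated sample metadata.
#' @return Tibble of rows with role `study` (QC and blank injections are
#'   excluded from all statistics).
#' @export
study_samples <- function(meta) meta[meta$role == "study", , drop = FALSE]

# ---- readers --------------------------------------------------------------

.read_delim_auto <- function(path, all_character = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    colClasses = if (all_character) "character" else NA)
}

#' Read an abundance matrix with sample metadata and feature annotation
#'
#' Expects delimited text (TSV or CSV by extension): the matrix has feature
#' ids in the header and sample ids in the first column; missing values are
#' empty cells or the token `NA`. Every sample in the matrix must appear in
#' the metadata and vice versa -- silent dropping is never allowed.
#'
#' @param path Abundance matrix file.
#' @param meta_path Sample metadata file (see [validate_sample_meta()]).
#' @param annot_path Feature annotation file with columns `feature_id`,
#'   `name`, `chemical_cluster`, `platform`, optional `compound_id` and
#'   `is_internal_standard`.
#' @return List with elements `abundance` ([abundance_table()]), `meta`
#'   (tibble) and `annotation` (tibble).
#' @export
read_abundance <- function(path, meta_path, annot_path) {
  raw <- .read_delim_auto(path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in abundance matrix")
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  meta <- validate_sample_meta(.read_delim_auto(meta_path,
                                                all_character = TRUE))
  extra <- setdiff(rownames(m), meta$sample_id)
  if (length(extra))
    stop("samples present in abundance matrix but absent from metadata: ",
         paste(utils::head(extra, 5), collapse = ", "))
  orphan <- setdiff(meta$sample_id, rownames(m))
  if (length(orphan))
    stop("samples present in metadata but absent from abundance matrix: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  annot <- read_feature_annotation(annot_path, feature_ids = colnames(m))
  platform <- annot$platform[match(colnames(m), annot$feature_id)]
  list(abundance = abundance_table(m, platform), meta = meta, annotation = annot)
}

#' Read a feature annotation table
#'
#' @param path Delimited annotation file.
#' @param feature_ids Optional ids the annotation must cover exactly.
#' @return Tibble with `feature_id`, `name`, `chemical_cluster`, `platform`,
#'   `compound_id`, `is_internal_standard`.
#' @export
read_feature_annotation <- function(path, feature_ids = NULL) {
  annot <- tibble::as_tibble(.read_delim_auto(path, all_character = TRUE))
  if (!"feature_id" %in% names(annot)) stop("annotation lacks `feature_id`")
  if (anyDuplicated(annot$feature_id)) stop("duplicate feature ids in annotation")
  if (!"name" %in% names(annot)) annot$name <- annot$feature_id
  if (!"chemical_cluster" %in% names(annot)) annot$chemical_cluster <- NA_character_
  if (!"platform" %in% names(annot)) annot$platform <- "GC"
  if (!"compound_id" %in% names(annot)) annot$compound_id <- NA_character_
  if (!"is_internal_standard" %in% names(annot)) annot$is_internal_standard <- FALSE
  annot$is_internal_standard <- as.logical(annot$is_internal_standard)
  if (!is.null(feature_ids)) {
    miss <- setdiff(feature_ids, annot$feature_id)
    if (length(miss))
      stop("features lacking annotation: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  annot
}

#' Read a continuous phenotype table
#'
#' Samples in rows (first column = sample id), phenotypes in columns.
#'
#' @param path Delimited file.
#' @return Numeric matrix with sample ids as rownames.
#' @export
read_phenotypes <- function(path) {
  raw <- .read_delim_auto(path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in phenotype table")
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# ---- writers --------------------------------------------------------------

#' Write a result table as TSV
#'
#' Deterministic output: columns in their given order, rows sorted by
#' `feature_id` then `ko_line` (when present), missing values written as the
#' token `NA`, numbers at full `as.character()` precision (>= 15 significant
#' digits, so p-values survive a write/read round trip).
#'
#' @param rows Data frame of homogeneous result records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  key <- intersect(c("feature_id", "ko_line", "phenotype_id", "cluster", "sex"),
                   names(rows))
  if (length(key))
    rows <- rows[do.call(order, rows[key]), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a samples-by-features matrix as TSV
#'
#' Missing values are written as empty cells, matching common metabolomics
#' exports (and what [read_abundance()] parses back).
#'
#' @param m Numeric matrix with dimnames, or an [abundance_table()].
#' @param path Output file.
#' @param id_col Header of the sample-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "sample_id") {
  if (inherits(m, "abundance_table")) m <- m$values
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated or imported cohort to a directory
#'
#' Emits `abundance.tsv`, `samples.tsv`, `features.tsv` and (when present)
#' `phenotypes.tsv` and `truth.tsv`, in the formats [read_abundance()] and
#' [read_phenotypes()] accept.
#'
#' @param cohort List with elements `abundance`, `meta`, `annotation` and
#'   optionally `phenotypes`, `truth` (as returned by [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_table(cohort$meta, file.path(dir, "samples.tsv"))
  write_table(cohort$annotation, file.path(dir, "features.tsv"))
  if (!is.null(cohort$phenotypes))
    write_matrix(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  if (!is.null(cohort$truth))
    write_table(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
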