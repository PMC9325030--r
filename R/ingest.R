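#' Read a genes x samples expression matrix from TSV
#'
#' Expects gene identifiers in the first column and sample identifiers in the
#' header.  Duplicate gene identifiers are collapsed by the elementwise mean
#' of their rows; negative values are rejected.  Gzip-compressed files are
#' read transparently.
#'
#' @param path path to a tab-separated file (optionally `.gz`).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  cf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(cf)) != 1L) {
    bad <- which(cf != cf[1])[1]
    stop_stage("ingest", "line %d of '%s' has %d fields, expected %d",
               bad, path, cf[bad], cf[1])
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (ncol(df) < 2)
    stop_stage("ingest", "expression file '%s' has no sample columns", path)
  gene <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    stop_stage("ingest", "non-numeric expression values in '%s'", path)
  if (anyNA(vals))
    stop_stage("ingest", "missing expression values in '%s'", path)
  if (any(vals < 0))
    stop_stage("ingest", "negative expression values in '%s'", path)
  if (anyDuplicated(colnames(vals)))
    stop_stage("ingest", "duplicate sample identifiers in '%s'", path)
  if (anyDuplicated(gene)) {
    n_dup <- sum(duplicated(gene))
    vals <- rowsum(vals, group = gene, reorder = FALSE) /
      as.vector(table(factor(gene, levels = unique(gene))))
    gene <- unique(gene)
    message("read_expression_matrix: collapsed ", n_dup,
            " duplicate gene row(s) by elementwise mean")
  }
  rownames(vals) <- gene
  vals
}

#' Write an expression matrix as TSV
#'
#' Full-precision counterpart of [read_expression_matrix()]; the round trip
#' reproduces values exactly.
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Classify samples as tumour or normal
#'
#' TCGA-style barcodes are classified from the sample-type field (positions
#' 14-15 of the barcode, i.e. the leading digits of the fourth dash-separated
#' field): codes 01-09 are tumour, 10-19 normal.  An explicit class table
#' overrides the barcode rule and is required for identifiers that do not
#' parse as barcodes.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param class optional override: a named character vector
#'   (`sample -> "tumor"/"normal"`), a two-column data.frame
#'   (`sample_id`, `class`), or a path to a TSV with those columns.
#' @return named character vector mapping each sample to `"tumor"` or
#'   `"normal"`.
#' @export
classify_samples <- function(sample_ids, class = NULL) {
  override <- NULL
  if (!is.null(class)) {
    if (is.character(class) && length(class) == 1L && file.exists(class))
      class <- read.delim(class, header = TRUE, stringsAsFactors = FALSE)
    if (is.data.frame(class)) {
      if (!all(c("sample_id", "class") %in% names(class)))
        stop_stage("ingest", "class file needs columns 'sample_id', 'class'")
      override <- setNames(as.character(class$class),
                           as.character(class$sample_id))
    } else if (!is.null(names(class))) {
      override <- class
    } else {
      stop_stage("ingest", "'class' must be a named vector, data.frame or path")
    }
    bad <- setdiff(unique(override), c("tumor", "normal"))
    if (length(bad) > 0)
      stop_stage("ingest", "unknown sample classes: %s",
                 paste(bad, collapse = ", "))
  }

  code <- function(id) {
    parts <- strsplit(id, "-", fixed = TRUE)[[1]]
    if (length(parts) < 4) return(NA_integer_)
    m <- regmatches(parts[4], regexpr("^[0-9]{2}", parts[4]))
    if (length(m) == 0) return(NA_integer_)
    as.integer(m)
  }
  out <- vapply(sample_ids, function(id) {
    if (!is.null(override) && id %in% names(override))
      return(unname(override[id]))
    cd <- code(id)
    if (is.na(cd)) return(NA_character_)
    if (cd >= 1 && cd <= 9) "tumor" else if (cd >= 10 && cd <= 19) "normal"
    else NA_character_
  }, character(1))
  if (anyNA(out))
    stop_stage("ingest", "cannot classify sample(s): %s",
               paste(sample_ids[is.na(out)], collapse = ", "))
  setNames(out, sample_ids)
}

#' Read gene annotation from an Ensembl-style GTF
#'
#' Parses `gene` records and maps Ensembl biotypes onto the three classes the
#' pipeline uses: `lncRNA` (including the legacy aliases `lincRNA`,
#' `antisense`, `sense_intronic`, `sense_overlapping`, `processed_transcript`
#' is *not* included), `protein_coding`, and `other`.  Both `gene_biotype`
#' and `gene_type` attribute keys are accepted.
#'
#' @param path path to a GTF file (optionally gzip-compressed).
#' @return data.frame with columns `gene_id`, `symbol`, `biotype`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path))
    stop_stage("ingest", "annotation file '%s' not found", path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (!"gene_id" %in% names(meta))
    stop_stage("ingest", "GTF '%s' has no gene_id attribute", path)
  if ("type" %in% names(meta) && any(meta$type == "gene"))
    meta <- meta[meta$type == "gene", , drop = FALSE]
  bio <- if ("gene_biotype" %in% names(meta)) meta$gene_biotype
         else if ("gene_type" %in% names(meta)) meta$gene_type
         else stop_stage("ingest", "GTF '%s' has no gene_biotype/gene_type", path)
  symbol <- if ("gene_name" %in% names(meta)) meta$gene_name else meta$gene_id
  lnc_aliases <- c("lncRNA", "lincRNA", "antisense", "sense_intronic",
                   "sense_overlapping", "3prime_overlapping_ncRNA",
                   "macro_lncRNA", "bidirectional_promoter_lncRNA")
  cls <- ifelse(bio %in% lnc_aliases, "lncRNA",
                ifelse(bio == "protein_coding", "protein_coding", "other"))
  ann <- data.frame(gene_id = meta$gene_id, symbol = symbol, biotype = cls,
                    stringsAsFactors = FALSE)
  ann[!duplicated(ann$gene_id), , drop = FALSE]
}

#' Partition an expression matrix by gene biotype
#'
#' Splits the matrix into the lncRNA and protein-coding submatrices using a
#' gene annotation; rows whose identifier (matched against both `gene_id`
#' and `symbol`) is missing from the annotation, or annotated `other`, are
#' dropped with a message.
#'
#' @param expr numeric matrix, genes x samples.
#' @param annotation data.frame from [read_gene_annotation()].
#' @return list with elements `lnc` and `coding` (matrices).
#' @export
partition_by_biotype <- function(expr, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0)
    stop_stage("ingest", "no gene annotation available")
  bt <- setNames(annotation$biotype, annotation$gene_id)
  by_sym <- setNames(annotation$biotype, annotation$symbol)
  ids <- rownames(expr)
  cls <- bt[ids]
  cls[is.na(cls)] <- by_sym[ids[is.na(cls)]]
  dropped <- sum(is.na(cls)) + sum(cls == "other", na.rm = TRUE)
  if (dropped > 0)
    message("partition_by_biotype: dropped ", dropped,
            " gene(s) unannotated or of other biotype")
  lnc <- expr[which(cls == "lncRNA"), , drop = FALSE]
  coding <- expr[which(cls == "protein_coding"), , drop = FALSE]
  if (nrow(lnc) == 0)
    stop_stage("ingest", "lncRNA partition is empty; nothing to screen")
  if (nrow(coding) == 0)
    warning("partition_by_biotype: protein-coding partition is empty")
  list(lnc = lnc, coding = coding)
}

#' Read an immune gene symbol list
#'
#' Accepts either a plain one-symbol-per-line file or a TSV with a `Symbol`
#' (or `symbol`/`gene`) column, as in ImmPort GeneList exports.  Symbols are
#' de-duplicated with case preserved.
#'
#' @param path path to the list.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0)
    stop_stage("ingest", "gene list '%s' is empty", path)
  if (grepl("\t", first) || tolower(trimws(first)) %in% c("symbol", "gene")) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    col <- intersect(c("Symbol", "symbol", "gene", "Gene"), names(df))
    if (length(col) == 0) col <- names(df)[1]
    syms <- as.character(df[[col[1]]])
  } else {
    syms <- readLines(path)
  }
  syms <- unique(trimws(syms))
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0)
    stop_stage("ingest", "gene list '%s' contains no symbols", path)
  syms
}

#' Clean a clinical table
#'
#' Applies the standard cleaning rules to an in-memory clinical table:
#' records with a follow-up time of 0 (or negative) days are removed,
#' duplicate sample identifiers keep their first record, and the event status
#' must be 0/1.  Idempotent.
#'
#' @param clinical data.frame with at least `sample_id`, `futime`, `fustat`.
#' @return the cleaned data.frame.
#' @export
clean_clinical <- function(clinical) {
  req <- c("sample_id", "futime", "fustat")
  miss <- setdiff(req, names(clinical))
  if (length(miss) > 0)
    stop_stage("ingest", "clinical table lacks column(s): %s",
               paste(miss, collapse = ", "))
  if (!all(clinical$fustat %in% c(0, 1)))
    stop_stage("ingest", "fustat values outside {0, 1}")
  n0 <- nrow(clinical)
  clinical <- clinical[clinical$futime > 0, , drop = FALSE]
  n_time <- n0 - nrow(clinical)
  dup <- duplicated(clinical$sample_id)
  clinical <- clinical[!dup, , drop = FALSE]
  if (n_time + sum(dup) > 0)
    message("clean_clinical: removed ", n_time, " record(s) with futime <= 0 and ",
            sum(dup), " duplicate(s)")
  rownames(clinical) <- NULL
  clinical
}

#' Read and clean a clinical TSV
#'
#' Requires columns `sample_id`, `futime` (days) and `fustat` (0/1); any
#' additional covariate columns (age, gender, grade, stage, T, N, M, ...) are
#' carried through.  Cleaning follows [clean_clinical()].
#'
#' @param path path to the TSV (optionally gzip-compressed).
#' @return cleaned clinical data.frame.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  clean_clinical(df)
}
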