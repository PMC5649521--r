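#' Read an expression matrix from TSV or GCT 1.2
#'
#' Plain TSV: first column gene id, header row of sample ids. GCT 1.2: a
#' `#1.2` version line, a dimensions line, then `NAME`/`Description` columns
#' followed by one column per sample. Input row order is preserved and
#' duplicate gene ids are allowed (aggregate them with
#' [aggregate_duplicate_genes()]).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return numeric matrix, genes x samples (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || trimws(header[1L]) != "#1.2") {
      stop("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
    if (length(dims) < 2L || any(is.na(dims[1:2]))) {
      stop("malformed GCT dimensions line in ", path)
    }
    df <- utils::read.delim(path, skip = 2L, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L]) {
      stop("GCT header declares ", dims[1L], " genes x ", dims[2L],
           " samples but file has ", nrow(df), " x ", ncol(df) - 2L)
    }
    gene_ids <- df[[1L]]
    value_df <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) stop("TSV matrix needs a gene column plus >=1 sample")
    gene_ids <- df[[1L]]
    value_df <- df[, -1L, drop = FALSE]
  }
  values <- matrix(NA_real_, nrow = nrow(value_df), ncol = ncol(value_df))
  for (j in seq_len(ncol(value_df))) {
    v <- suppressWarnings(as.numeric(value_df[[j]]))
    bad <- is.na(v) & !(value_df[[j]] %in% c("NA", "", "nan", "NaN"))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric cell at gene '", gene_ids[i], "', sample '",
           colnames(value_df)[j], "': '", value_df[[j]][i], "'")
    }
    values[, j] <- v
  }
  dimnames(values) <- list(gene_ids, colnames(value_df))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in ", path)
  }
  values
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' Values are serialized with 17 significant digits so a write/read round trip
#' reproduces doubles exactly.
#'
#' @param m numeric matrix (genes x samples).
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression_matrix <- function(m, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  .check_expression_matrix(m)
  val <- format(m, digits = 17, scientific = TRUE, trim = TRUE)
  rows <- apply(val, 1L, paste, collapse = "\t")
  if (format == "gct") {
    lines <- c("#1.2",
               paste(nrow(m), ncol(m), sep = "\t"),
               paste(c("NAME", "Description", colnames(m)), collapse = "\t"),
               paste(rownames(m), "na", rows, sep = "\t"))
  } else {
    lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), rows, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample clinical table from CSV
#'
#' Requires columns `sample_id` and `group`; lung-function percent columns
#' (`fev1_pct`, `fvc_pct`, `dlco_pct`), `age`, `sex` and `smoking` are
#' optional. Unparseable percent cells become missing values; the number of
#' such cells is reported in a warning.
#'
#' @param path CSV file path.
#' @return clinical `data.frame` (see [clinical_table()]).
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("sample_id", "group")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  }
  n_bad <- 0L
  parse_pct <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    n_bad <<- n_bad + sum(is.na(v) & !is.na(raw) & raw != "" & raw != "NA")
    v
  }
  fev1 <- parse_pct("fev1_pct")
  fvc <- parse_pct("fvc_pct")
  dlco <- parse_pct("dlco_pct")
  if (n_bad > 0L) {
    warning(n_bad, " unparseable percent value(s) recorded as missing")
  }
  clinical_table(
    sample_id = df$sample_id,
    group = df$group,
    fev1_pct = fev1, fvc_pct = fvc, dlco_pct = dlco,
    age = if ("age" %in% names(df))
      suppressWarnings(as.numeric(df$age)) else NA_real_,
    sex = if ("sex" %in% names(df)) df$sex else "unknown",
    smoking = if ("smoking" %in% names(df)) df$smoking else NA_character_
  )
}

#' Write a clinical table to CSV
#' @param cl clinical `data.frame`.
#' @param path output path.
#' @export
write_clinical_table <- function(cl, path) {
  .check_clinical(cl)
  utils::write.csv(cl, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`. Gene
#' order is preserved; duplicate genes within a line are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields (name, description, ",
           ">=1 gene)")
    }
    sets[[fields[1L]]] <- list(description = fields[2L],
                               genes = fields[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc), function(nm) {
    s <- gsc[[nm]]
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(nm, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential-expression result table to TSV
#' @param de DE result `data.frame` as returned by [run_de_contrast()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' Used for classifier evaluation reports and panel-search results.
#' @param x a list (scalars are unboxed).
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
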