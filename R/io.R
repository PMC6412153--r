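# Readers and writers for expression matrices, annotation, clinical metadata
# and result tables. All formats are plain TSV; GCT 1.2 is supported read-only
# for expression.

#' Read a TPM expression matrix
#'
#' Reads a genes-by-samples matrix of non-negative TPM values from a TSV file
#' (first column gene identifiers, one column per sample) or a GCT 1.2 file
#' (two-line preamble, `Name` and `Description` columns). The reader rejects
#' malformed input rather than repairing it: duplicate gene or sample
#' identifiers, non-numeric cells, and negative or non-finite values are all
#' errors naming the offending row or column.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"gct"`.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G2\t0\t5"), tf)
#' read_expression(tf)
read_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (dialect == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1L], "#1.2")) {
      stop("malformed GCT preamble in ", path, ": expected '#1.2' on line 1")
    }
    shape <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
    if (length(shape) < 2L || anyNA(shape[1:2])) {
      stop("malformed GCT shape line in ", path)
    }
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             colClasses = "character")
    if (!all(c("Name", "Description") %in% names(tab)[1:2])) {
      stop("malformed GCT header in ", path,
           ": expected 'Name' and 'Description' columns")
    }
    ids <- tab[["Name"]]
    tab <- tab[, -(1:2), drop = FALSE]
    if (nrow(tab) != shape[1L] || ncol(tab) != shape[2L]) {
      stop("GCT shape line (", shape[1L], " x ", shape[2L],
           ") does not match table (", nrow(tab), " x ", ncol(tab), ")")
    }
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L) stop("malformed header in ", path,
                             ": need a gene id column plus >=1 sample column")
    ids <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(names(tab))) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = length(ids), ncol = ncol(tab),
                dimnames = list(ids, names(tab)))
  for (j in seq_len(ncol(tab))) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v) & !(tab[[j]] %in% c("NA", "NaN")))
    if (length(bad)) {
      stop("non-numeric TPM cell in ", path, " at gene '", ids[bad[1L]],
           "', sample '", names(tab)[j], "'")
    }
    mat[, j] <- v
  }
  validate_expression(mat, context = path)
  mat
}

#' @rdname read_expression
#' @param mat a validated expression matrix.
#' @param digits significant digits written for TPM values; round-trips
#'   through [read_expression()] are exact to this precision (default 15,
#'   i.e. full double precision).
#' @export
write_expression <- function(mat, path, digits = 15L) {
  validate_expression(mat)
  tab <- data.frame(gene_id = rownames(mat),
                    signif(mat, digits),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the invariants of the expression container: a numeric matrix with
#' unique gene row names and unique sample column names, all values finite
#' and non-negative. Called by every function that consumes a matrix.
#'
#' @param mat matrix to check.
#' @param context label used in error messages (e.g. a file path).
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(mat, context = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop(context, ": expected a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop(context, ": gene row names and sample column names are required")
  }
  if (anyDuplicated(rownames(mat))) stop(context, ": duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop(context, ": duplicate sample ids")
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(context, ": negative or non-finite TPM at gene '",
         rownames(mat)[bad[1L, 1L]], "', sample '",
         colnames(mat)[bad[1L, 2L]], "'")
  }
  invisible(mat)
}

# Clinical flag vocabulary: history flags are yes/no/unknown, the HIV serology
# result is positive/negative/not performed. Matching is case-insensitive.
.flag_cols <- c("MHT1D", "MHT2D", "MHARTHTS", "MHRA", "MHSEPSIS", "MHLUPUS",
                "MHCLLULTS", "MHSCLRDRM", "MHSRCDSS")
.mandatory_meta <- c("SAMPID", "SEX", "AGE", "MHT1D", "MHT2D", "MHARTHTS",
                     "MHRA", "MHSEPSIS", "LBHIV1NT")

.normalize_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("yes", "y", "true", "1")] <- "yes"
  out[x %in% c("no", "n", "false", "0")] <- "no"
  out
}

.normalize_hiv <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("not_performed", "notperformed", "np")] <- "not performed"
  out <- rep("not performed", length(x))
  out[x == "positive"] <- "positive"
  out[x == "negative"] <- "negative"
  out[!(x %in% c("positive", "negative", "not performed"))] <- "not performed"
  out
}

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  if (anyNA(out)) stop("unrecognized SEX value(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read donor clinical metadata
#'
#' Reads a per-donor metadata table with GTEx-style variable names (SAMPID,
#' SEX, AGE, RACE, BMI, HGHT, WGHT, medical-history flags such as MHT2D or
#' MHSEPSIS, and the HIV serology outcome LBHIV1NT). Flag strings are matched
#' case-insensitively and stored normalized as "yes"/"no"/"unknown"
#' (LBHIV1NT: "positive"/"negative"/"not performed"); unknown values are
#' preserved as "unknown", never coerced to a known level. Sex accepts
#' "male"/"female", "M"/"F" or the 1/2 coding.
#'
#' @param path path to a TSV file whose header contains at least the
#'   mandatory columns SAMPID, SEX, AGE and the cohort-defining flags
#'   (MHT1D, MHT2D, MHARTHTS, MHRA, MHSEPSIS, LBHIV1NT).
#' @param age_range plausible donor age range; ages outside it are an error.
#' @return A data.frame with one row per sample, normalized flag columns, and
#'   numeric AGE/BMI/HGHT/WGHT where present.
#' @export
read_metadata <- function(path, age_range = c(21, 70)) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  names(tab) <- toupper(names(tab))
  missing <- setdiff(.mandatory_meta, names(tab))
  if (length(missing)) {
    stop("metadata schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$SAMPID)) {
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(tab$SAMPID[duplicated(tab$SAMPID)]), collapse = ", "))
  }
  tab$SEX <- .normalize_sex(tab$SEX)
  tab$AGE <- suppressWarnings(as.numeric(tab$AGE))
  if (anyNA(tab$AGE)) stop("non-numeric AGE value(s) in metadata")
  out_of_range <- tab$AGE < age_range[1] | tab$AGE > age_range[2]
  if (any(out_of_range)) {
    stop("AGE outside plausible range [", age_range[1], ", ", age_range[2],
         "] for sample(s): ",
         paste(tab$SAMPID[out_of_range], collapse = ", "))
  }
  for (col in intersect(.flag_cols, names(tab))) {
    tab[[col]] <- .normalize_flag(tab[[col]])
  }
  for (col in setdiff(.flag_cols, names(tab))) {
    tab[[col]] <- "unknown"
  }
  tab$LBHIV1NT <- .normalize_hiv(tab$LBHIV1NT)
  for (col in intersect(c("BMI", "HGHT", "WGHT"), names(tab))) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  if (!"RACE" %in% names(tab)) tab$RACE <- "Unknown"
  rownames(tab) <- NULL
  tab
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `symbol`, `chromosome`,
#'   `is_coding` (logical or "coding"/"noncoding").
#' @return A data.frame with those four columns, `is_coding` logical.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "symbol", "chromosome", "is_coding")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("annotation schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene id(s) in annotation")
  ic <- tolower(trimws(tab$is_coding))
  coding <- ic %in% c("true", "t", "1", "yes", "coding")
  noncoding <- ic %in% c("false", "f", "0", "no", "noncoding", "non-coding")
  if (!all(coding | noncoding)) {
    stop("unrecognized is_coding value(s): ",
         paste(unique(tab$is_coding[!(coding | noncoding)]), collapse = ", "))
  }
  tab$is_coding <- coding
  tab[, need]
}

#' Write and re-read differential-expression result tables
#'
#' Results are written as TSV with a fixed, deterministic column order and
#' full double precision, so that write-then-read recovers the table exactly
#' (to 15 significant digits). An empty result set yields a header-only file.
#'
#' @param de a DE result data.frame from [run_de()].
#' @param path output path.
#' @return `write_results()` returns the path invisibly; `read_results()`
#'   returns the data.frame.
#' @export
write_results <- function(de, path) {
  stopifnot(is.data.frame(de))
  num <- vapply(de, is.numeric, logical(1L))
  de[num] <- lapply(de[num], function(x) signif(x, 15L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(de, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  utils::read.delim(path, check.names = FALSE)
}

#' Read a gene list for annotation
#'
#' A gene list is a TSV with a `symbol` column and an optional numeric
#' `score` column (e.g. a neural proportion score in \[0, 1\]). Symbols are
#' uppercased; duplicates are removed with a warning (the first occurrence
#' wins).
#'
#' @param path TSV path.
#' @param name label for the list; defaults to the file name without
#'   extension.
#' @return An object of class `gene_list`: a list with `name`, `symbols`
#'   (character) and `scores` (named numeric or NULL).
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"symbol" %in% names(tab)) stop("gene list needs a 'symbol' column")
  gene_list(toupper(trimws(as.character(tab$symbol))),
            scores = if ("score" %in% names(tab)) as.numeric(tab$score),
            name = name)
}

#' @rdname read_gene_list
#' @param symbols character vector of gene symbols.
#' @param scores optional numeric vector parallel to `symbols`.
#' @export
gene_list <- function(symbols, scores = NULL, name = "list") {
  symbols <- toupper(trimws(as.character(symbols)))
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(symbols))
    scores <- as.numeric(scores)
  }
  if (anyDuplicated(symbols)) {
    warning("gene list '", name, "': ",
            sum(duplicated(symbols)), " duplicate symbol(s) removed")
    keep <- !duplicated(symbols)
    symbols <- symbols[keep]
    if (!is.null(scores)) scores <- scores[keep]
  }
  if (!is.null(scores)) names(scores) <- symbols
  structure(list(name = name, symbols = symbols, scores = scores),
            class = "gene_list")
}
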