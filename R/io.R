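# Readers and writers for the plain-text formats the pipeline touches:
# expression TSV (genes x samples), Broad-dialect GMT signature files,
# clinical TSV, and undirected edge lists.

MISSING_TOKENS <- c("", "NA", "na", "N/A", "n/a", ".", "NULL", "null", "unknown")

#' Read a log-scale expression matrix
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose first row holds sample identifiers.  Rows with any missing value are
#' dropped; rows sharing a gene identifier are collapsed to their mean (the
#' usual rule for collapsed probes/transcripts).  Both actions are logged.
#'
#' @param path Path to a tab-separated genes-by-samples table.
#' @return A numeric matrix (genes x samples) with unique row and column
#'   names, no missing values, and at least 2 genes and 2 samples.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) stop("expression matrix needs >= 2 samples, found ",
                           ncol(tab) - 1L)
  gene_ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(trimws(vals) %in% MISSING_TOKENS), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric expression value '%s' for gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  rownames(num) <- gene_ids
  keep <- stats::complete.cases(num)
  if (any(!keep))
    is_log("read_expression_matrix: dropped %d row(s) with missing values",
           sum(!keep))
  num <- num[keep, , drop = FALSE]
  if (anyDuplicated(rownames(num))) {
    dups <- unique(rownames(num)[duplicated(rownames(num))])
    is_log("read_expression_matrix: collapsing %d duplicated gene id(s) by mean",
           length(dups))
    num <- collapse_duplicate_rows(num)
  }
  validate_expression_matrix(num)
  is_log("read_expression_matrix: %d genes x %d samples", nrow(num), ncol(num))
  num
}

collapse_duplicate_rows <- function(mat) {
  f <- factor(rownames(mat), levels = unique(rownames(mat)))
  out <- rowsum(mat, f) / as.vector(table(f))
  rownames(out) <- levels(f)
  out
}

validate_expression_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (nrow(mat) < 2L) stop("expression matrix needs >= 2 genes")
  if (ncol(mat) < 2L) stop("expression matrix needs >= 2 samples")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  invisible(mat)
}

#' Read a GMT gene-set file
#'
#' Broad dialect: each line is `name TAB description TAB gene TAB gene ...`.
#' Genes repeated within a set are kept once; duplicated set names are an
#' error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                   i, length(fields)))
    nms[i] <- fields[1L]
    desc[i] <- fields[2L]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("GMT line %d ('%s') has no genes", i, nms[i]))
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(desc, nms)
  sets
}

#' Read a clinical table
#'
#' Tab-separated with a header; requires columns `sample_id`, `pfs_time`
#' (months, strictly positive) and `pfs_event` (0 = censored,
#' 1 = progressed).  Recognized optional columns: `gleason`, `n_status`
#' (`N-`/`N+`), `hormone_therapy`, `radiation_therapy` (0/1), `t_stage`
#' (`T1`..`T4`).  Unknown tokens become `NA` and are counted in the log.
#'
#' @param path Path to the clinical TSV.
#' @return A data.frame with typed columns, one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  req <- c("sample_id", "pfs_time", "pfs_event")
  missing_cols <- setdiff(req, colnames(tab))
  if (length(missing_cols))
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(sample_id = tab$sample_id, stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample_id in clinical table")
  out$pfs_time <- as.numeric(tab$pfs_time)
  out$pfs_event <- as.integer(tab$pfs_event)
  if (anyNA(out$pfs_time) || anyNA(out$pfs_event))
    stop("non-numeric pfs_time/pfs_event for sample ",
         out$sample_id[which(is.na(out$pfs_time) | is.na(out$pfs_event))[1L]])
  if (any(out$pfs_time <= 0))
    stop("non-positive pfs_time for sample ",
         out$sample_id[which(out$pfs_time <= 0)[1L]])
  if (!all(out$pfs_event %in% c(0L, 1L)))
    stop("pfs_event must be 0 or 1; offending sample ",
         out$sample_id[which(!out$pfs_event %in% c(0L, 1L))[1L]])

  n_mapped <- 0L
  grab_int <- function(col, allowed) {
    if (!col %in% colnames(tab)) return(rep(NA_integer_, nrow(tab)))
    raw <- trimws(tab[[col]])
    val <- suppressWarnings(as.integer(raw))
    val[!(val %in% allowed)] <- NA_integer_
    n_mapped <<- n_mapped + sum(is.na(val) & !(raw %in% MISSING_TOKENS))
    val
  }
  grab_factor <- function(col, levels) {
    if (!col %in% colnames(tab)) return(factor(rep(NA_character_, nrow(tab)), levels = levels))
    raw <- trimws(tab[[col]])
    val <- ifelse(raw %in% levels, raw, NA_character_)
    n_mapped <<- n_mapped + sum(is.na(val) & !(raw %in% MISSING_TOKENS))
    factor(val, levels = levels)
  }
  out$gleason <- grab_int("gleason", 2:10)
  out$n_status <- grab_factor("n_status", c("N-", "N+"))
  out$hormone_therapy <- grab_int("hormone_therapy", 0:1)
  out$radiation_therapy <- grab_int("radiation_therapy", 0:1)
  out$t_stage <- grab_factor("t_stage", paste0("T", 1:4))
  if (n_mapped > 0L)
    is_log("read_clinical: %d unrecognized token(s) mapped to missing", n_mapped)
  is_log("read_clinical: %d samples, %d events", nrow(out), sum(out$pfs_event))
  out
}

#' Read an undirected edge list
#'
#' Two id columns plus an optional numeric weight.  Self-loops are dropped
#' (and counted), duplicate edges collapsed regardless of orientation.
#'
#' @param path Path to a tab- or whitespace-separated edge list (no header).
#' @return A data.frame with columns `from`, `to`, `weight`; zero rows for an
#'   empty file.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stop("malformed edge list line ", which(nf < 2L | nf > 3L)[1L])
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  weight <- vapply(parts, function(p) {
    if (length(p) < 3L) return(1)
    w <- suppressWarnings(as.numeric(p[[3L]]))
    if (is.na(w)) stop("non-numeric edge weight: ", p[[3L]])
    w
  }, numeric(1L))
  loops <- from == to
  if (any(loops)) is_log("read_edge_list: dropped %d self-loop(s)", sum(loops))
  from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  a <- pmin(from, to); b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  if (any(dup)) is_log("read_edge_list: collapsed %d duplicate edge(s)", sum(dup))
  data.frame(from = a[!dup], to = b[!dup], weight = weight[!dup],
             stringsAsFactors = FALSE)
}

#' Write an expression matrix (or any numeric matrix) as TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips values through
#' full-precision decimal text.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Header of the first (identifier) column.
#' @export
write_matrix_tsv <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), format(mat, digits = 17, trim = TRUE,
                                         scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
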