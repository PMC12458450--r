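#' Read a raw count matrix
#'
#' Accepts either a delimited text file (tab or comma, sniffed from the
#' header line) with a header row of sample ids and gene ids in the first
#' column, or a Matrix Market `.mtx` file with sidecar `genes.tsv` /
#' `barcodes.tsv` files in the same directory (first column used as ids).
#'
#' @param path Path to the `.tsv`/`.csv`/`.txt` or `.mtx` file.
#' @return Integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv"); bf <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gf) || !file.exists(bf))
      stop("sidecar genes.tsv / barcodes.tsv not found next to ", path)
    genes <- utils::read.delim(gf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("sidecar lengths do not match matrix dimensions")
    dimnames(m) <- list(genes, cells)
  } else {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(df[, -1, drop = FALSE], 1,
                         function(r) any(is.na(suppressWarnings(as.numeric(r))))))
      stop("non-numeric count value at data line ",
           if (length(bad)) bad[1] else "?")
    }
    rownames(m) <- ids
  }
  ids <- rownames(m)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  m
}

#' Read a per-gene prior-effect table
#'
#' Two-column delimited file (gene id, prior effect value, e.g. log fold
#' changes estimated on another platform or species). Values are aligned
#' to `gene_ids`; genes absent from the table receive 0 (an uninformative
#' center, shrinking toward "no change") with a message reporting the
#' count; table rows for unknown genes are ignored.
#'
#' @param path Path to the table (TSV or CSV; optional header detected).
#' @param gene_ids Gene identifiers of the analysis dataset, in order.
#' @return Numeric vector `h` aligned to `gene_ids`.
#' @export
read_prior_table <- function(path, gene_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  first <- strsplit(header, sep, fixed = TRUE)[[1]]
  has_header <- length(first) >= 2 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("prior table must have two columns (gene id, value)")
  val <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(val)) stop("non-numeric prior value at row ", which(is.na(val))[1])
  idx <- match(gene_ids, as.character(df[[1]]))
  h <- ifelse(is.na(idx), 0, val[idx])
  n_missing <- sum(is.na(idx))
  if (n_missing > 0)
    message(n_missing, " gene(s) without prior; centered at 0")
  n_extra <- sum(!(as.character(df[[1]]) %in% gene_ids))
  if (n_extra > 0)
    message(n_extra, " prior table row(s) for genes not in the dataset; ignored")
  h
}

#' Write the per-gene results table
#'
#' Tab-separated output with one row per gene (posterior mean effect,
#' posterior mean local scale, region probabilities, BCR, q-value,
#' decision, sign-set membership) preceded by `#`-comment lines recording
#' the run metadata.
#'
#' @param decisions A `DecisionTable` from [decide()].
#' @param summaries The matching `GeneTestSummary`.
#' @param path Output file path.
#' @param metadata Named list echoed into the comment header (e.g. seed,
#'   alpha, epsilon).
#' @return The path, invisibly.
#' @export
write_results <- function(decisions, summaries, path, metadata = list()) {
  stopifnot(inherits(decisions, "DecisionTable"))
  meta <- c(list(alpha = attr(decisions, "alpha"),
                 lambda_star = attr(decisions, "lambda_star"),
                 version = as.character(utils::packageVersion("bishot"))),
            metadata)
  omcols <- grep("^omega", names(summaries), value = TRUE)
  extra <- intersect(c("beta_postmean", "betaD_postmean", "betaC_postmean",
                       "lambda_postmean"), names(summaries))
  tab <- cbind(summaries[, c("gene_id", extra, omcols, "bcr")],
               decisions[, c("qvalue", "decision", "in_S")])
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the file.
#' @return List with `table` (data.frame) and `metadata` (named character).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  metaln <- grep("^#", lines)
  meta <- character(0)
  if (length(metaln)) {
    kv <- sub("^# ", "", lines[metaln])
    meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  }
  tab <- utils::read.table(text = lines[setdiff(seq_along(lines), metaln)],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(table = tab, metadata = meta)
}
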