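#' Read a cytosine count table
#'
#' Reads the tab-separated per-cytosine count dialect used throughout the
#' pipeline: one strand-specific cytosine per line with columns
#' \code{chrom}, \code{pos} (0-based), \code{strand} (+/-), \code{context}
#' (only "CpG" is used downstream), \code{meth_reads} (reads supporting
#' methylation, the k of the beta-binomial model) and \code{total_reads}
#' (reads covering the position, N). Lines starting with \code{#} are
#' comments. Zero-coverage cytosines are not representable: absence from the
#' file means "not profiled", and \code{total_reads >= 1} is enforced.
#'
#' @param path Path to a tab-separated count file.
#' @return A data.frame with columns chrom (character), pos (integer),
#'   strand (character), context (character), meth_reads (integer),
#'   total_reads (integer), in file order.
#' @export
read_cytosine_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0L) {
    return(empty_cytosine_counts())
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop("malformed count line ", line_no[bad], " in ", path,
         ": expected 6 tab-separated fields, got ", nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 5L]))
  total <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(total))
  if (length(bad)) {
    stop("malformed count line ", line_no[bad[1L]], " in ", path,
         ": non-integer pos/meth/total field")
  }
  rec <- data.frame(chrom = m[, 1L], pos = pos, strand = m[, 3L],
                    context = m[, 4L], meth_reads = meth,
                    total_reads = total, stringsAsFactors = FALSE)
  v <- validate_cytosine_counts(rec)
  if (!is.null(v)) {
    stop("invalid count record at line ", line_no[v$row], " in ", path,
         ": ", v$msg)
  }
  rec
}

empty_cytosine_counts <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             context = character(), meth_reads = integer(),
             total_reads = integer(), stringsAsFactors = FALSE)
}

# Returns NULL when valid, else list(row, msg) for the first violation.
validate_cytosine_counts <- function(rec) {
  checks <- list(
    list(bad = rec$pos < 0L, msg = "pos < 0"),
    list(bad = !(rec$strand %in% c("+", "-")), msg = "strand not in {+,-}"),
    list(bad = rec$meth_reads < 0L, msg = "meth_reads < 0"),
    list(bad = rec$total_reads < 1L, msg = "total_reads < 1"),
    list(bad = rec$meth_reads > rec$total_reads,
         msg = "meth_reads > total_reads")
  )
  for (ch in checks) {
    if (any(ch$bad)) return(list(row = which(ch$bad)[1L], msg = ch$msg))
  }
  NULL
}

#' Write a cytosine count table
#'
#' Inverse of \code{\link{read_cytosine_counts}}; the written file round-trips
#' exactly. A header comment documents the column layout.
#'
#' @param records data.frame as returned by \code{read_cytosine_counts}.
#' @param path Output path.
#' @export
write_cytosine_counts <- function(records, path) {
  v <- validate_cytosine_counts(records)
  if (!is.null(v)) stop("invalid record ", v$row, ": ", v$msg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cytosine counts: chrom\tpos\tstrand\tcontext\tmeth_reads\ttotal_reads",
               "# pos is 0-based; strand-specific; CpG context only is tested"),
             con)
  if (nrow(records)) {
    writeLines(paste(records$chrom, records$pos, records$strand,
                     records$context, records$meth_reads,
                     records$total_reads, sep = "\t"), con)
  }
  invisible(NULL)
}

#' Read a BED interval file
#'
#' Accepts BED3+ (0-based half-open); the name is taken from column 4 when
#' present. \code{track} and \code{browser} lines and \code{#} comments are
#' skipped.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns chrom, start, end, name (NA when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (!length(data_lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1L]
    stop("malformed BED line ", line_no[bad], " in ", path,
         ": fewer than 3 fields")
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  name <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, "")
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop("malformed BED line ", line_no[bad], " in ", path,
         ": non-integer coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("invalid BED interval at line ", line_no[bad[1L]], " in ", path,
         ": start >= end")
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param intervals data.frame with chrom, start, end and optional name.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(intervals$start < intervals$end))
  has_name <- "name" %in% names(intervals) && !all(is.na(intervals$name))
  lines <- if (has_name) {
    paste(intervals$chrom, intervals$start, intervals$end, intervals$name,
          sep = "\t")
  } else {
    paste(intervals$chrom, intervals$start, intervals$end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a TSS annotation table
#'
#' Tab-separated with columns gene_id, chrom, tss (0-based), strand.
#'
#' @param path Path to the table.
#' @return data.frame with those four columns.
#' @export
read_tss <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("gene_id", "chrom", "tss", "strand"))
  if (any(tab$tss < 0)) stop("TSS position < 0 in ", path)
  if (!all(tab$strand %in% c("+", "-"))) stop("TSS strand not in {+,-} in ", path)
  tab$tss <- as.integer(tab$tss)
  tab
}

#' Read a sample design (sample-to-group) file
#'
#' Two tab-separated columns: sample id, group label.
#'
#' @param path Path to the design file.
#' @return Named character vector mapping sample id to group label.
#' @export
read_design <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("sample", "group"))
  if (anyDuplicated(tab$sample)) stop("duplicate sample id in design file")
  stats::setNames(tab$group, tab$sample)
}

#' Read an array-style beta-value matrix
#'
#' CSV with the probe id in the first column and one column per sample;
#' values are methylation beta values in [0,1], with missing cells allowed
#' (empty or NA). Group labels come from a separate two-column design file.
#'
#' @param path CSV path.
#' @param design_path Two-column sample-to-group file
#'   (see \code{\link{read_design}}).
#' @return List of class \code{beta_matrix} with elements \code{values}
#'   (numeric matrix, probes x samples, NA for missing), \code{probe_ids},
#'   \code{sample_ids} and \code{group_labels}.
#' @export
read_beta_matrix <- function(path, design_path) {
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("beta matrix needs a probe column and >=1 sample")
  probe_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    stop("beta value outside [0,1] in ", path, " (first offending probe: ",
         probe_ids[(bad[1L] - 1L) %% nrow(values) + 1L], ")")
  }
  design <- read_design(design_path)
  missing_samples <- setdiff(colnames(values), names(design))
  if (length(missing_samples)) {
    stop("samples absent from group file: ",
         paste(missing_samples, collapse = ", "))
  }
  structure(list(values = values, probe_ids = probe_ids,
                 sample_ids = colnames(values),
                 group_labels = unname(design[colnames(values)])),
            class = "beta_matrix")
}

#' Write a beta-value matrix as CSV
#'
#' @param beta \code{beta_matrix} object or plain numeric matrix with probe
#'   rownames and sample colnames.
#' @param path Output CSV path.
#' @export
write_beta_matrix <- function(beta, path) {
  values <- if (inherits(beta, "beta_matrix")) beta$values else beta
  out <- data.frame(probe_id = rownames(values), values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a gene count matrix
#'
#' Tab-separated: gene_id column followed by one integer column per sample.
#'
#' @param path Path to the table.
#' @param design_path Two-column sample-to-group file.
#' @return List of class \code{count_matrix} with elements \code{counts}
#'   (integer matrix, genes x samples), \code{gene_ids}, \code{sample_ids},
#'   \code{group_labels}.
#' @export
read_count_matrix <- function(path, design_path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  gene_ids <- as.character(tab[[1L]])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers in ", path)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  design <- read_design(design_path)
  missing_samples <- setdiff(colnames(counts), names(design))
  if (length(missing_samples)) {
    stop("samples absent from group file: ",
         paste(missing_samples, collapse = ", "))
  }
  structure(list(counts = counts, gene_ids = gene_ids,
                 sample_ids = colnames(counts),
                 group_labels = unname(design[colnames(counts)])),
            class = "count_matrix")
}

#' Write a gene count matrix
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  out <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a position weight matrix
#'
#' Plain text: optional \code{#} comment header (the first comment supplies
#' the motif name), then one row per motif position with 4 whitespace
#' separated log-odds weights in A C G T order.
#'
#' @param path Path to the matrix file.
#' @return List of class \code{pwm} with elements \code{name} and
#'   \code{matrix} (positions x 4, columns A,C,G,T).
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  name <- if (length(comments)) {
    trimws(sub("^#+\\s*", "", comments[1L]))
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(data_lines)) stop("PWM file has no weight rows: ", path)
  rows <- lapply(strsplit(trimws(data_lines), "\\s+"), as.numeric)
  if (any(lengths(rows) != 4L) || anyNA(unlist(rows))) {
    stop("each PWM row needs exactly 4 numeric weights (A C G T): ", path)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = mat), class = "pwm")
}
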