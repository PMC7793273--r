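#' Construct a peak set
#'
#' A peak set is the unit of all overlap computation: a named, sorted
#' collection of peaks with single-base summits. Coordinates are 0-based
#' half-open throughout; the summit is an absolute 0-based position inside
#' the peak interval. Peaks are unstranded.
#'
#' @param peaks data.frame with columns chrom, start, end, name, signal,
#'   summit.
#' @param factor Factor (TF/cofactor) name.
#' @param cell_line Cell-line name.
#' @param experiment_id Dataset identifier.
#' @param is_tagged Logical; experiment performed with a tagged protein.
#' @return An object of class \code{PeakSet}.
#' @export
peak_set <- function(peaks, factor, cell_line,
                     experiment_id = NA_character_, is_tagged = FALSE) {
  stopifnot(is.data.frame(peaks))
  required <- c("chrom", "start", "end", "summit")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) stop("peaks lacks columns: ", paste(missing, collapse = ", "))
  if (!nzchar(factor) || !nzchar(cell_line)) stop("factor and cell_line must be non-empty")
  if (is.null(peaks$name)) peaks$name <- sprintf("%s_peak%d", factor, seq_len(nrow(peaks)))
  if (is.null(peaks$signal)) peaks$signal <- 0
  if (nrow(peaks)) {
    if (any(peaks$start < 0)) stop("negative start coordinate")
    if (any(peaks$end <= peaks$start)) stop("end must exceed start (0-based half-open)")
    if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
      stop("summit must lie within [start, end)")
    }
    if (any(peaks$signal < 0)) stop("signal must be non-negative")
    peaks <- peaks[order(peaks$chrom, peaks$summit), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(
    list(factor = factor, cell_line = cell_line,
         experiment_id = experiment_id, is_tagged = isTRUE(is_tagged),
         peaks = peaks[, c("chrom", "start", "end", "name", "signal", "summit")]),
    class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("<PeakSet> %s in %s: %d peaks on %d chromosome(s)%s\n",
              x$factor, x$cell_line, nrow(x$peaks),
              length(unique(x$peaks$chrom)),
              if (x$is_tagged) " [tagged]" else ""))
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$peaks)

#' Read an ENCODE narrowPeak file
#'
#' Parses a BED6+4 narrowPeak file into a \code{\link{peak_set}}. The summit
#' is \code{chromStart + column 10}; when the offset is -1 (summit not
#' called) the interval midpoint (floor) is used instead.
#'
#' @param path Path to a narrowPeak file (>= 10 tab-separated columns).
#' @inheritParams peak_set
#' @return A \code{PeakSet}, sorted by (chrom, summit).
#' @export
read_narrowpeak <- function(path, factor, cell_line,
                            experiment_id = NA_character_, is_tagged = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 10L)
  if (length(bad)) {
    stop(sprintf("malformed narrowPeak line %d in %s: expected >= 10 fields, got %d",
                 bad[1], path, nf[bad[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:10))
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  offset <- as.integer(m[, 10])
  summit <- ifelse(offset < 0L, (start + end) %/% 2L, start + offset)
  peak_set(data.frame(chrom = m[, 1], start = start, end = end,
                      name = m[, 4], signal = as.numeric(m[, 7]),
                      summit = summit, stringsAsFactors = FALSE),
           factor = factor, cell_line = cell_line,
           experiment_id = experiment_id, is_tagged = is_tagged)
}

#' Write a peak set as narrowPeak
#'
#' Inverse of \code{\link{read_narrowpeak}}: summits are written as offsets
#' from chromStart, so a write/read round trip reproduces intervals and
#' summits exactly.
#'
#' @param ps A \code{PeakSet}.
#' @param path Output path.
#' @export
write_narrowpeak <- function(ps, path) {
  stopifnot(inherits(ps, "PeakSet"))
  p <- ps$peaks
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%g\t-1\t-1\t%d",
                   p$chrom, p$start, p$end, p$name, p$signal,
                   p$summit - p$start)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a position frequency matrix
#'
#' @param matrix_id Identifier (e.g. a JASPAR accession).
#' @param name Factor name associated with the matrix.
#' @param counts 4 x L numeric matrix with rownames A, C, G, T; per-position
#'   nucleotide counts (or frequencies), all non-negative, every column with
#'   at least one positive entry; L >= 4.
#' @return An object of class \code{PWM}.
#' @export
pwm <- function(matrix_id, name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(counts) < 4L) stop("motif width must be >= 4")
  if (any(counts < 0)) stop("negative count in matrix ", matrix_id)
  if (any(colSums(counts) <= 0)) stop("all-zero column in matrix ", matrix_id)
  structure(list(matrix_id = matrix_id, name = name,
                 counts = counts, length = ncol(counts)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("<PWM> %s (%s), width %d, consensus %s\n",
              x$matrix_id, x$name, x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PFM (highest count per column, ties to the
#' alphabetically first base).
#' @param x A \code{PWM}.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' Read a JASPAR-format PFM file
#'
#' Accepts the plain JASPAR text layout: a header line \code{>ID name}
#' followed by four base rows, either bracketed
#' (\code{A [ 1 2 3 ]}) or bare whitespace-separated numbers.
#'
#' @param path Path to the file.
#' @return Named list of \code{\link{pwm}} objects (names = matrix ids).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    header <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    nm <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    if (length(block) != 4L) {
      stop(sprintf("record %s: expected 4 base rows, found %d", id, length(block)))
    }
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      stop(sprintf("record %s: base rows of unequal width (%s)",
                   id, paste(widths, collapse = ", ")))
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- pwm(id, nm, counts)
  }
  out
}

#' Write PFMs in JASPAR text format
#' @param pwms List of \code{PWM} objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms) {
    writeLines(sprintf(">%s %s", m$matrix_id, m$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a chromatin-state segmentation (BED4)
#'
#' Four-column BED with the state mnemonic in column 4, as in the 18-state
#' chromHMM segmentations. Segments must be non-overlapping within each
#' chromosome.
#'
#' @param path Path to the BED file.
#' @return Object of class \code{ChromatinSegmentation}: a list with
#'   \code{segments} (data.frame chrom/start/end/state, sorted) and
#'   \code{state_labels}.
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seg <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "state"),
                           colClasses = c("character", "integer", "integer", "character"))
  chromatin_segmentation(seg)
}

#' @rdname read_segmentation
#' @param segments data.frame with chrom, start, end, state.
#' @export
chromatin_segmentation <- function(segments) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(segments)))
  if (any(segments$end <= segments$start)) stop("segment end must exceed start")
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch)
    }
  }
  structure(list(segments = segments,
                 state_labels = sort(unique(segments$state))),
            class = "ChromatinSegmentation")
}

#' Read a TSV gene annotation (gene_id, chrom, tss, strand)
#'
#' @param path Path to a headered TSV.
#' @return data.frame with unique gene_id; strand limited to +/-; tss is a
#'   0-based position.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be + or -")
  ann
}

#' Read a DESeq2-shaped differential-expression table
#'
#' Headered TSV with columns gene_id, log2FoldChange (or log2FC) and padj
#' (or FDR). Rows with missing FDR are kept with NA and treated as
#' non-significant downstream.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns gene_id, log2FoldChange, padj.
#' @export
read_deg_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (is.null(d$log2FoldChange) && !is.null(d$log2FC)) d$log2FoldChange <- d$log2FC
  if (is.null(d$padj) && !is.null(d$FDR)) d$padj <- d$FDR
  stopifnot(all(c("gene_id", "log2FoldChange", "padj") %in% names(d)))
  if (anyDuplicated(d$gene_id)) stop("duplicate gene_id in DEG table")
  if (any(d$padj < 0 | d$padj > 1, na.rm = TRUE)) stop("FDR outside [0, 1]")
  d[, c("gene_id", "log2FoldChange", "padj")]
}

#' Read a GMT gene-set file
#' @param path Path to a GMT file (set id, description, then member genes).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write a FASTA file from a named character vector of sequences
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path Path to the FASTA file.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no FASTA records in ", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- vapply(seq_along(heads), function(i) {
    paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
  }, "")
  names(out) <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads])
  out
}
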