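#' Read and write Cell Ranger-style MatrixMarket triplets
#'
#' A directory with `matrix.mtx` (MatrixMarket sparse, genes x cells),
#' `features.tsv` (gene ids) and `barcodes.tsv` (cell barcodes). The
#' reader validates the header against the feature/barcode files and
#' against the listed entry count before delegating the parse to
#' [Matrix::readMM()]; write then read is the identity.
#'
#' @param dir Directory holding (or to hold) the three files.
#' @param counts Sparse or dense genes x cells matrix with dimnames.
#' @return `read_mtx_triplet()`: a `dgCMatrix` with gene ids as rownames
#'   and barcodes as colnames. `write_mtx_triplet()`: `dir`, invisibly.
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 3),
#'                           dims = c(2, 2),
#'                           dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' write_mtx_triplet(m, d)
#' all.equal(as.matrix(read_mtx_triplet(d)), as.matrix(m))
read_mtx_triplet <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  feat_path <- file.path(dir, "features.tsv")
  bc_path <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path))
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)

  lines <- readLines(mtx_path)
  body <- lines[!startsWith(lines, "%")]
  body <- body[nzchar(trimws(body))]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  if (length(hdr) != 3 || any(!is.finite(hdr)))
    stop("malformed MatrixMarket size header", call. = FALSE)
  if (length(body) - 1L != hdr[3])
    stop("MatrixMarket header declares ", hdr[3], " entries but ",
         length(body) - 1L, " are listed", call. = FALSE)

  features <- readLines(feat_path)
  barcodes <- readLines(bc_path)
  features <- features[nzchar(features)]
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(features) != hdr[1] || length(barcodes) != hdr[2])
    stop("matrix dimensions (", hdr[1], " x ", hdr[2], ") do not match ",
         length(features), " features / ", length(barcodes), " barcodes",
         call. = FALSE)

  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  dimnames(m) <- list(sub("\t.*", "", features), sub("\t.*", "", barcodes))
  m
}

#' @rdname read_mtx_triplet
#' @export
write_mtx_triplet <- function(counts, dir) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry gene and barcode dimnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or barcode identifiers", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(if (is.null(rownames(counts))) character(0) else
    rownames(counts), file.path(dir, "features.tsv"))
  writeLines(if (is.null(colnames(counts))) character(0) else
    colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read or write a bulk count matrix as TSV
#'
#' Genes in rows (first column `gene`), samples in columns.
#'
#' @param path File path.
#' @param counts Integer genes x samples matrix with dimnames.
#' @return `read_counts_tsv()`: an integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses exon records (via [rtracklayer::import()], GTF is 1-based
#' inclusive), collapses transcripts to one union-exon model per gene,
#' and derives the TSS: span start on `+`, span end on `-`. Records whose
#' start exceeds their end, or with negative coordinates, are dropped
#' with a warning.
#'
#' @param path GTF file path.
#' @return A list with `genes` (GRanges, one span per gene with `gene_id`)
#'   and `exons` (GRangesList keyed by gene, reduced/union exons).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  bad <- GenomicRanges::start(gr) < 1
  if (any(bad)) {
    warning(sum(bad), " GTF records with invalid coordinates dropped")
    gr <- gr[!bad]
  }
  if (!length(gr)) stop("no usable exon records in ", path, call. = FALSE)
  exl <- GenomicRanges::reduce(S4Vectors::split(gr, gr$gene_id))
  spans <- unlist(range(exl))
  spans$gene_id <- names(spans)
  names(spans) <- NULL
  list(genes = spans, exons = exl)
}

#' Write toy gene models as GTF
#'
#' Emits one transcript per gene plus its exon records (1-based
#' inclusive), with `gene_id` and `transcript_id` attributes.
#'
#' @param models A list with `genes` (GRanges with `gene_id`) and `exons`
#'   (GRangesList), as from [simulate_atac()] or [read_gtf()].
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  genes <- models$genes
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(genes)) {
    gid <- genes$gene_id[i]
    st <- as.character(GenomicRanges::strand(genes))[i]
    chr <- as.character(GenomeInfoDb::seqnames(genes))[i]
    attr <- sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
    writeLines(sprintf("%s\tsynthio\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       chr, GenomicRanges::start(genes)[i],
                       GenomicRanges::end(genes)[i], st, attr), con)
    ex <- models$exons[[gid]]
    for (j in seq_along(ex)) {
      writeLines(sprintf("%s\tsynthio\texon\t%d\t%d\t.\t%s\t.\t%s",
                         chr, GenomicRanges::start(ex)[j],
                         GenomicRanges::end(ex)[j], st, attr), con)
    }
  }
  invisible(path)
}

#' Read or write ATAC fragments as BED
#'
#' BED is 0-based half-open on disk; in memory fragments are GRanges
#' (1-based closed). [rtracklayer] handles the conversion. Records with
#' non-positive width or negative coordinates are rejected.
#'
#' @param path BED file path.
#' @param fragments A GRanges of fragments.
#' @return `read_bed()`: a GRanges.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED records with non-positive width", call. = FALSE)
  gr
}

#' @rdname read_bed
#' @export
write_bed <- function(fragments, path) {
  rtracklayer::export(fragments, path, format = "bed")
  invisible(path)
}

#' Read or write peaks in ENCODE narrowPeak format
#'
#' narrowPeak is BED6+4: signalValue, pValue, qValue and the summit
#' offset relative to the peak start (0-based on disk). Internally peaks
#' are GRanges with a `score` and a 1-based `summit_offset` such that
#' `start + summit_offset - 1` is the summit position.
#'
#' @param path narrowPeak file path.
#' @param peaks GRanges with `score` and `summit_offset` (and optionally
#'   `peak_id`) metadata columns.
#' @return `read_narrowpeak()`: a GRanges with `peak_id`, `score`,
#'   `signalValue`, `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  df <- read.table(path, sep = "\t", col.names = cols,
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("invalid narrowPeak coordinates", call. = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  gr$peak_id <- df$name
  gr$score <- df$signalValue
  gr$signalValue <- df$signalValue
  gr$summit_offset <- df$peak + 1L
  gr
}

#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(peaks, path) {
  name <- if (!is.null(peaks$peak_id)) peaks$peak_id else
    sprintf("peak%04d", seq_along(peaks))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = name,
    score = pmin(1000L, as.integer(round(peaks$score * 10))),
    strand = ".",
    signalValue = peaks$score,
    pValue = -1,
    qValue = -1,
    peak = peaks$summit_offset - 1L)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read cell-cycle phase gene sets from TSV
#'
#' Two columns (`phase`, `gene`), one row per marker gene. Phases must be
#' a subset of the five canonical labels ([cc_phases()]); the result is
#' ordered cyclically and every set must be non-empty.
#'
#' @param path TSV path.
#' @return Named list of gene-id vectors, one per phase in cyclic order.
#' @export
read_phase_sets <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("phase", "gene") %in% names(df)))
    stop("phase set file needs columns 'phase' and 'gene'", call. = FALSE)
  unknown <- setdiff(unique(df$phase), CC_PHASES)
  if (length(unknown))
    stop("unknown phase labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sets <- lapply(CC_PHASES, function(p) unique(df$gene[df$phase == p]))
  names(sets) <- CC_PHASES
  if (any(lengths(sets) == 0))
    stop("every phase needs at least one gene", call. = FALSE)
  sets
}

#' @rdname read_phase_sets
#' @param sets Named list of gene-id vectors keyed by phase.
#' @export
write_phase_sets <- function(sets, path) {
  df <- data.frame(phase = rep(names(sets), lengths(sets)),
                   gene = unlist(sets, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write peak sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
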