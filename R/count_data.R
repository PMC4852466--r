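#' Contig size table
#'
#' An ordered table of contig names and lengths.  The order is fixed and
#' defines the genome-wide bin order used by [bin_reads()] and
#' [genome_bins()].
#'
#' @param names character vector of unique contig names.
#' @param lengths positive integer lengths in base pairs.
#' @return A `contig_table` data frame with columns `name` and `length`.
#' @export
contig_table <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths))
    stop("names and lengths must have equal length")
  if (anyDuplicated(names))
    stop("duplicate contig names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("contig lengths must be positive")
  out <- data.frame(name = names, length = lengths, stringsAsFactors = FALSE)
  class(out) <- c("contig_table", "data.frame")
  out
}

#' Read a two-column contig size table (name, length)
#'
#' @param path TSV file with two columns and no header (seqname, length),
#'   the `samtools faidx`-style chrom.sizes convention.
#' @return A [contig_table()].
#' @export
read_contig_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("contig table needs two columns: name, length")
  contig_table(tab[[1]], tab[[2]])
}

#' Genome-wide bin coordinates for a contig table
#'
#' Bins are 0-based half-open `[start, end)` intervals of width `bin_size`
#' tiling each contig in order; the last bin of a contig may be short.
#'
#' @param contigs a [contig_table()].
#' @param bin_size bin width in base pairs.
#' @return data frame with columns `contig`, `start`, `end`.
#' @export
genome_bins <- function(contigs, bin_size = 1000L) {
  stopifnot(bin_size >= 1)
  pieces <- lapply(seq_len(nrow(contigs)), function(i) {
    len <- contigs$length[i]
    nb <- ceiling(len / bin_size)
    start <- (seq_len(nb) - 1) * bin_size
    data.frame(contig = contigs$name[i], start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Binned count matrix container
#'
#' @param counts non-negative numeric matrix, bins in rows, data sets in
#'   columns.
#' @param bins data frame of bin coordinates (`contig`, `start`, `end`) with
#'   one row per matrix row.
#' @param dataset_ids unique character ids, one per column.
#' @param bin_size bin width in base pairs.
#' @return A `binned_counts` object (list with elements `counts`, `bins`,
#'   `dataset_ids`, `bin_size`).
#' @export
binned_counts <- function(counts, bins, dataset_ids, bin_size = 1000L) {
  counts <- as.matrix(counts)
  if (nrow(bins) != nrow(counts))
    stop("bins and counts disagree on the number of bins")
  if (length(dataset_ids) != ncol(counts))
    stop("dataset_ids and counts disagree on the number of data sets")
  if (anyDuplicated(dataset_ids))
    stop("dataset ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  colnames(counts) <- dataset_ids
  structure(list(counts = counts, bins = bins,
                 dataset_ids = as.character(dataset_ids),
                 bin_size = as.integer(bin_size)),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts: %d bins x %d data sets (bin size %d bp)\n",
              nrow(x$counts), ncol(x$counts), x$bin_size))
  invisible(x)
}

#' @export
dim.binned_counts <- function(x) dim(x$counts)

#' Load read start positions from a BAM or BED file
#'
#' The "read start" is the leftmost mapped coordinate for both strands
#' (0-based).  Unmapped records are dropped.  An optional `five_prime = TRUE`
#' switches to the strand-aware 5' end (rightmost base for minus-strand
#' reads).
#'
#' @param path BAM or BED (3+ columns) file.
#' @param format `"auto"` (by extension), `"bam"` or `"bed"`.
#' @param five_prime use the strand-specific 5' end instead of the leftmost
#'   coordinate.
#' @return data frame with columns `contig` and `pos` (0-based).
#' @export
read_read_starts <- function(path, format = c("auto", "bam", "bed"),
                             five_prime = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (format == "bam") {
    param <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(b$pos)
    contig <- as.character(b$rname[keep])
    pos <- b$pos[keep] - 1L             # BAM pos is 1-based
    if (five_prime) {
      minus <- b$strand[keep] == "-"
      w <- b$qwidth[keep]
      pos[minus] <- pos[minus] + w[minus] - 1L
    }
    data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    pos <- GenomicRanges::start(gr) - 1L  # back to BED 0-based starts
    if (five_prime) {
      minus <- as.character(GenomicRanges::strand(gr)) == "-"
      pos[minus] <- GenomicRanges::end(gr)[minus] - 1L
    }
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               pos = pos, stringsAsFactors = FALSE)
  }
}

#' Bin read starts into fixed-width genomic bins
#'
#' Counts the number of read starts falling into each `bin_size`-bp bin of
#' the genome defined by `contigs`.  The bin index within a contig is
#' `floor(pos / bin_size)` on 0-based positions, so a read at position 1000
#' with 1000-bp bins falls into the second bin.  Reads on contigs absent from
#' the table are skipped, counted, and reported via a warning and the
#' `"skipped"` attribute.
#'
#' @param reads data frame with columns `contig` and `pos` (0-based leftmost
#'   mapped coordinate), as returned by [read_read_starts()], or a path to a
#'   BAM/BED file.
#' @param contigs a [contig_table()].
#' @param bin_size bin width in base pairs (default 1000).
#' @param id column id for the resulting single data set.
#' @return single-column [binned_counts()] with attribute `skipped` (number
#'   of reads on unknown contigs).
#' @export
bin_reads <- function(reads, contigs, bin_size = 1000L, id = "dataset1") {
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_read_starts(reads)
  if (!all(c("contig", "pos") %in% names(reads)))
    stop("reads must have columns 'contig' and 'pos'")
  bins <- genome_bins(contigs, bin_size)
  nb_per <- ceiling(contigs$length / bin_size)
  offset <- c(0, cumsum(nb_per))[seq_len(nrow(contigs))]
  names(offset) <- contigs$name
  names(nb_per) <- contigs$name

  n_reads <- nrow(reads)
  counts <- integer(nrow(bins))
  skipped <- 0L
  if (n_reads == 0L) {
    warning("no reads supplied; returning zero counts")
  } else {
    bad <- !is.finite(reads$pos) | reads$pos < 0
    if (any(bad))
      stop("malformed read record(s) at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    known <- reads$contig %in% contigs$name
    skipped <- sum(!known)
    if (skipped > 0)
      warning(sprintf("%d read(s) on contigs absent from the contig table were skipped",
                      skipped))
    r <- reads[known, , drop = FALSE]
    if (nrow(r) > 0) {
      idx_in <- r$pos %/% bin_size
      over <- idx_in >= nb_per[r$contig]
      if (any(over))
        stop("read position beyond contig end at row(s): ",
             paste(utils::head(which(known)[over], 5), collapse = ", "))
      idx <- offset[r$contig] + idx_in + 1
      tab <- tabulate(idx, nbins = nrow(bins))
      counts <- tab
    }
  }
  out <- binned_counts(matrix(counts, ncol = 1), bins, id, bin_size)
  attr(out, "skipped") <- skipped
  out
}

#' Experiment metadata table
#'
#' One row per data set: `id`, `factor` (ChIP target, matched
#' case-insensitively everywhere), `cell_type`, `lab`, `treatment`, and
#' `target_class` (`"transcription_factor"` or `"histone_mark"`).
#'
#' @param df data frame with at least columns `id` and `factor`; missing
#'   optional columns are filled with `""` / `"transcription_factor"`.
#' @return an `experiment_metadata` data frame.
#' @export
experiment_metadata <- function(df) {
  if (!all(c("id", "factor") %in% names(df)))
    stop("metadata needs at least columns 'id' and 'factor'")
  if (anyDuplicated(df$id))
    stop("duplicate dataset ids in metadata: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(!nzchar(df$factor))) stop("empty factor names in metadata")
  for (col in c("cell_type", "lab", "treatment"))
    if (is.null(df[[col]])) df[[col]] <- ""
  if (is.null(df$target_class)) df$target_class <- "transcription_factor"
  bad <- !df$target_class %in% c("transcription_factor", "histone_mark")
  if (any(bad))
    stop("target_class must be 'transcription_factor' or 'histone_mark'")
  out <- df[c("id", "factor", "cell_type", "lab", "treatment", "target_class")]
  class(out) <- c("experiment_metadata", "data.frame")
  out
}

#' Read an experiment metadata TSV
#' @param path TSV with header columns id, factor, cell_type, lab,
#'   treatment, target_class.
#' @return an [experiment_metadata()] table.
#' @export
read_metadata <- function(path) {
  experiment_metadata(utils::read.delim(path, stringsAsFactors = FALSE,
                                        colClasses = "character"))
}

#' Save a binned count matrix (and optional metadata) as TSV
#'
#' Columns are `contig`, `start`, `end` followed by one integer column per
#' data set.  Round-trips bit-exactly with [load_counts()] for integer
#' counts.
#'
#' @param x a [binned_counts()].
#' @param path output TSV path.
#' @param metadata optional [experiment_metadata()]; written to
#'   `metadata_path`.
#' @param metadata_path where to write the metadata TSV (default:
#'   `path` with a `.meta.tsv` suffix).
#' @export
save_counts <- function(x, path, metadata = NULL,
                        metadata_path = paste0(path, ".meta.tsv")) {
  tab <- data.table::as.data.table(x$bins)
  cnt <- data.table::as.data.table(x$counts)
  data.table::setnames(cnt, x$dataset_ids)
  data.table::fwrite(cbind(tab, cnt), path, sep = "\t")
  if (!is.null(metadata)) {
    if (!setequal(metadata$id, x$dataset_ids))
      stop("metadata ids do not match dataset ids")
    data.table::fwrite(metadata, metadata_path, sep = "\t")
  }
  invisible(path)
}

#' Load a binned count matrix TSV (and optional metadata)
#'
#' @param path TSV written by [save_counts()] (columns contig, start, end,
#'   then one column per data set).
#' @param metadata_path optional metadata TSV; validated against the matrix
#'   column ids.
#' @return list with elements `counts` ([binned_counts()]) and `metadata`
#'   (or `NULL`).
#' @export
load_counts <- function(path, metadata_path = NULL) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("contig", "start", "end")
  if (!all(need %in% names(tab)))
    stop("count TSV must start with columns contig, start, end")
  ids <- setdiff(names(tab), need)
  if (length(ids) == 0) stop("count TSV has no data set columns")
  mat <- as.matrix(tab[ids])
  nonint <- which(is.na(mat) | mat != floor(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop(sprintf("non-integer or negative count at row %d, data set '%s'",
                 nonint[1, 1], ids[nonint[1, 2]]))
  bin_size <- max(tab$end - tab$start)
  bc <- binned_counts(mat, tab[need], ids, bin_size)
  md <- NULL
  if (!is.null(metadata_path)) {
    md <- read_metadata(metadata_path)
    if (!setequal(md$id, ids)) {
      off <- c(setdiff(md$id, ids), setdiff(ids, md$id))
      stop("metadata/matrix id mismatch: ", paste(off, collapse = ", "))
    }
    md <- md[match(ids, md$id), ]
  }
  list(counts = bc, metadata = md)
}
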