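# Per-bin barcode tallying from FASTQ with a minimum Phred quality filter,
# plus assembly of per-(replicate, bin) tables into a count tensor.

#' Count barcodes of one (replicate, bin) FASTQ file
#'
#' Applies the minimum-quality filter to the barcode span of each read: a
#' read is discarded when any base of its barcode has Phred quality below
#' `min_quality` (default 20). Surviving barcodes must match a map entry
#' exactly (no mismatch rescue); matched counts are summed per variant.
#'
#' @param fastq Path to a Phred+33 FASTQ file (one file = one replicate/bin).
#' @param barcode_map Data.frame with `barcode` and `variant` columns (see
#'   [read_barcode_map()]).
#' @param min_quality Minimum per-base Phred quality over the barcode span
#'   (default 20).
#' @param barcode_start 1-based offset of the barcode within the read
#'   (default 1).
#' @param barcode_length Barcode length; defaults to the (constant) length
#'   of the mapped barcodes.
#' @param replicate,bin Labels recorded on the output table.
#' @return A list of class `bin_count_table`: `replicate`, `bin`, `counts`
#'   (named integer vector over the map's variants), `total_reads`,
#'   `n_filtered_quality`, `n_unmapped_barcodes`.
#' @export
count_barcodes <- function(fastq, barcode_map, min_quality = 20L,
                           barcode_start = 1L, barcode_length = NULL,
                           replicate = "R1", bin = 1L) {
  stopifnot(is.data.frame(barcode_map),
            all(c("barcode", "variant") %in% names(barcode_map)))
  widths <- unique(nchar(barcode_map$barcode))
  if (length(widths) != 1L)
    stop("barcode length must be constant within a map")
  if (is.null(barcode_length)) barcode_length <- widths
  variants <- unique(barcode_map$variant)
  counts <- stats::setNames(integer(length(variants)), variants)
  bin <- as.integer(bin)
  if (!bin %in% 1:4) stop("bin must be in 1..4")

  parsed <- tryCatch({
    reads <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                          with.qualities = TRUE)
    list(seqs = as.character(reads),
         quals = as.character(S4Vectors::mcols(reads)$qualities),
         widths = Biostrings::width(reads))
  }, error = function(e) {
    n_lines <- length(readLines(fastq, warn = FALSE))
    if (n_lines %% 4L != 0L)
      stop("truncated FASTQ record at record ", n_lines %/% 4L + 1L,
           " of ", fastq, call. = FALSE)
    stop(e)
  })
  mk <- function(total = 0L, nq = 0L, nu = 0L) {
    structure(list(replicate = replicate, bin = bin, counts = counts,
                   total_reads = total, n_filtered_quality = nq,
                   n_unmapped_barcodes = nu),
              class = "bin_count_table")
  }
  n_reads <- length(parsed$seqs)
  if (n_reads == 0L) {
    warning("empty FASTQ file: ", fastq)
    return(mk())
  }
  span_end <- barcode_start + barcode_length - 1L
  if (any(parsed$widths < span_end))
    stop("barcode span [", barcode_start, ", ", span_end,
         "] exceeds read length")
  seqs <- substr(parsed$seqs, barcode_start, span_end)
  quals <- substr(parsed$quals, barcode_start, span_end)
  # minimum Phred over the barcode span: lowest ASCII character - 33
  min_phred <- vapply(quals, function(q) {
    min(as.integer(charToRaw(q))) - 33L
  }, 0L, USE.NAMES = FALSE)
  pass <- min_phred >= min_quality
  n_quality <- sum(!pass)
  hits <- match(seqs[pass], barcode_map$barcode)
  n_unmapped <- sum(is.na(hits))
  mapped <- barcode_map$variant[hits[!is.na(hits)]]
  if (length(mapped) > 0L) {
    tab <- table(mapped)
    counts[names(tab)] <- as.integer(tab)
  }
  mk(n_reads, n_quality, n_unmapped)
}

#' @export
print.bin_count_table <- function(x, ...) {
  cat("bin_count_table: replicate ", x$replicate, ", bin ", x$bin, "; ",
      sum(x$counts), " mapped reads over ", length(x$counts), " variants (",
      x$n_filtered_quality, " quality-filtered, ", x$n_unmapped_barcodes,
      " unmapped)\n", sep = "")
  invisible(x)
}

#' Write a bin count table plus a JSON sidecar of totals
#'
#' @param table A `bin_count_table` from [count_barcodes()].
#' @param path Output TSV path (`variant  count`); a `.json` sidecar with
#'   the totals and filter counters is written next to it.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(table, path) {
  stopifnot(inherits(table, "bin_count_table"))
  utils::write.table(data.frame(variant = names(table$counts),
                                count = as.integer(table$counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(replicate = table$replicate, bin = table$bin,
               total_reads = table$total_reads,
               n_filtered_quality = table$n_filtered_quality,
               n_unmapped_barcodes = table$n_unmapped_barcodes)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Merge per-(replicate, bin) count tables into a count tensor
#'
#' @param tables Either a list of `bin_count_table` objects or a long
#'   data.frame with columns `replicate`, `bin`, `variant`, `count`.
#' @return An integer array with dimensions replicate x bin x variant
#'   (bins 1..4; the variant axis is the union over inputs, missing entries
#'   imputed as 0).
#' @export
merge_counts <- function(tables) {
  if (is.data.frame(tables)) {
    long <- tables[, c("replicate", "bin", "variant", "count")]
  } else {
    stopifnot(all(vapply(tables, inherits, TRUE, "bin_count_table")))
    key <- vapply(tables, function(t) paste(t$replicate, t$bin), "")
    if (anyDuplicated(key))
      stop("duplicate (replicate, bin) tables: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    long <- do.call(rbind, lapply(tables, function(t) {
      data.frame(replicate = t$replicate, bin = t$bin,
                 variant = names(t$counts), count = as.integer(t$counts),
                 stringsAsFactors = FALSE)
    }))
  }
  reps <- sort(unique(as.character(long$replicate)))
  variants <- unique(long$variant)
  arr <- array(0L, dim = c(length(reps), 4L, length(variants)),
               dimnames = list(replicate = reps, bin = as.character(1:4),
                               variant = variants))
  idx <- cbind(match(long$replicate, reps), as.integer(long$bin),
               match(long$variant, variants))
  if (is.data.frame(tables) &&
      anyDuplicated(paste(idx[, 1], idx[, 2], idx[, 3])))
    stop("duplicate (replicate, bin, variant) rows in count input")
  arr[idx] <- arr[idx] + as.integer(long$count)
  arr
}
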