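# Variant identity, consensus calling from reads sharing a barcode, and
# barcode-map construction (the subassembly stage of a barcoded library).

REJECTION_STATUSES <- c("rejected_indel", "rejected_multi_aa",
                        "rejected_ambiguous", "rejected_wt_identical")
BARCODE_STATUSES <- c("accepted", REJECTION_STATUSES)
MUT_CLASSES <- c("missense", "synonymous", "nonsense")

#' Format a variant as a compact token
#'
#' Tokens take the form `<wt><position><alt>`, e.g. `R98W`, `W5*` for a
#' nonsense variant and `L27L` for a synonymous variant.
#'
#' @param position Integer residue position(s).
#' @param wt_aa,alt_aa One-letter amino acid codes (`*` for stop).
#' @return Character vector of tokens.
#' @export
format_variant_token <- function(position, wt_aa, alt_aa) {
  paste0(wt_aa, position, alt_aa)
}

#' Parse compact variant tokens
#'
#' @param tokens Character vector of tokens such as `R98W`, `W5*`, `L27L`.
#' @return A data.frame with columns `variant`, `position`, `wt_aa`,
#'   `alt_aa`, `mut_class` and logical `valid`. Malformed tokens are flagged
#'   rather than raising an error.
#' @export
parse_variant_token <- function(tokens) {
  tokens <- as.character(tokens)
  m <- regmatches(tokens, regexec("^([A-Y])([0-9]+)([A-Y*])$", tokens))
  ok <- vapply(m, length, 1L) == 4L
  wt <- alt <- rep(NA_character_, length(tokens))
  pos <- rep(NA_integer_, length(tokens))
  wt[ok] <- vapply(m[ok], `[`, "", 2L)
  pos[ok] <- as.integer(vapply(m[ok], `[`, "", 3L))
  alt[ok] <- vapply(m[ok], `[`, "", 4L)
  cls <- ifelse(alt == AA_STOP, "nonsense",
                ifelse(alt == wt, "synonymous", "missense"))
  data.frame(variant = tokens, position = pos, wt_aa = wt, alt_aa = alt,
             mut_class = cls, valid = ok, stringsAsFactors = FALSE)
}

variant_key <- function(position, wt_aa, alt_aa, alt_codon, mut_class) {
  data.frame(variant = format_variant_token(position, wt_aa, alt_aa),
             position = as.integer(position), wt_aa = wt_aa, alt_aa = alt_aa,
             alt_codon = alt_codon, mut_class = mut_class,
             stringsAsFactors = FALSE)
}

#' Call a variant from an observed coding sequence
#'
#' Compares a frame-registered observed coding sequence against the
#' reference, codon by codon. Exactly one differing codon encoding at most
#' one amino-acid change yields an accepted variant call; anything else is
#' rejected with a reason. No alignment is attempted: a length mismatch is
#' treated as an insertion/deletion.
#'
#' @param observed Observed coding DNA string (same frame as the reference).
#' @param reference A [protein_reference()].
#' @return A list with `status` (one of `accepted`, `rejected_indel`,
#'   `rejected_multi_aa`, `rejected_ambiguous`, `rejected_wt_identical`) and,
#'   when accepted, `variant`: a one-row data.frame with columns `variant`,
#'   `position`, `wt_aa`, `alt_aa`, `alt_codon`, `mut_class`.
#' @details Sequences containing non-ACGT characters (e.g. `N`) in a
#'   differing codon are rejected as ambiguous, not raised as errors. Edits
#'   outside the mutagenized range are also rejected as ambiguous since they
#'   cannot arise from the library design.
#' @examples
#' ref <- protein_reference("toy", "ATGCGGTGGAAA")
#' obs <- sub("CGG", "TGG", ref$coding_sequence)
#' call_variant(obs, ref)
#' @export
call_variant <- function(observed, reference) {
  if (!inherits(reference, "protein_reference"))
    stop("reference must be a protein_reference")
  observed <- toupper(as.character(observed))
  if (nchar(observed) != nchar(reference$coding_sequence))
    return(list(status = "rejected_indel", variant = NULL))
  if (identical(observed, reference$coding_sequence))
    return(list(status = "rejected_wt_identical", variant = NULL))
  obs_codons <- split_codons(observed)
  ref_codons <- split_codons(reference$coding_sequence)
  diff <- which(obs_codons != ref_codons)
  if (length(diff) > 1L) {
    # more than one codon edited: a multi-change sequence, unless the extra
    # difference is just ambiguity noise -- an N-containing codon is
    # ambiguous either way
    if (any(grepl("[^ACGT]", obs_codons[diff])))
      return(list(status = "rejected_ambiguous", variant = NULL))
    return(list(status = "rejected_multi_aa", variant = NULL))
  }
  pos <- diff[1L]
  alt_codon <- obs_codons[pos]
  if (grepl("[^ACGT]", alt_codon))
    return(list(status = "rejected_ambiguous", variant = NULL))
  if (pos < reference$mutagenized_range[1] ||
      pos > reference$mutagenized_range[2])
    return(list(status = "rejected_ambiguous", variant = NULL))
  wt <- wt_aa_at(reference, pos)
  alt <- translate_codons(alt_codon)
  cls <- if (alt == AA_STOP) "nonsense" else if (alt == wt) "synonymous" else "missense"
  list(status = "accepted",
       variant = variant_key(pos, wt, alt, alt_codon, cls))
}

#' Collapse reads sharing a barcode into a consensus variant call
#'
#' All subassembly reads carrying one barcode are collapsed by per-base
#' majority vote; the consensus sequence is then passed to [call_variant()].
#' A tie at any base, or fewer than `min_reads` supporting reads, rejects the
#' barcode as ambiguous: reproducibility is preferred over yield.
#'
#' @param reads Character vector of frame-registered reads (same length).
#' @param reference A [protein_reference()].
#' @param barcode Barcode sequence tagging these reads (recorded verbatim).
#' @param min_reads Minimum number of supporting reads (default 1).
#' @return A one-row data.frame (a barcode record) with columns `barcode`,
#'   `variant`, `position`, `wt_aa`, `alt_aa`, `alt_codon`, `mut_class`,
#'   `n_supporting_reads`, `status`.
#' @export
collapse_barcode_reads <- function(reads, reference, barcode = NA_character_,
                                   min_reads = 1L) {
  if (length(reads) == 0L) stop("no reads supplied for barcode ", barcode)
  reads <- toupper(as.character(reads))
  if (length(unique(nchar(reads))) != 1L)
    stop("reads sharing barcode ", barcode, " differ in length")
  rec <- function(status, variant = NULL) {
    v <- if (is.null(variant))
      variant_key(NA_integer_, NA_character_, NA_character_, NA_character_,
                  NA_character_)
    else variant
    if (is.null(variant)) v$variant <- NA_character_
    cbind(data.frame(barcode = barcode, stringsAsFactors = FALSE), v,
          data.frame(n_supporting_reads = length(reads), status = status,
                     stringsAsFactors = FALSE))
  }
  if (length(reads) < min_reads) return(rec("rejected_ambiguous"))
  if (length(reads) == 1L) {
    consensus <- reads
  } else {
    chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(reads), byrow = TRUE)
    cons <- character(ncol(chars))
    for (j in seq_len(ncol(chars))) {
      tab <- table(chars[, j])
      top <- tab[tab == max(tab)]
      if (length(top) > 1L) return(rec("rejected_ambiguous"))
      cons[j] <- names(top)
    }
    consensus <- paste(cons, collapse = "")
  }
  res <- call_variant(consensus, reference)
  rec(res$status, res$variant)
}

#' Build a barcode-to-variant map from barcode records
#'
#' Retains accepted records only, resolves duplicate barcodes (records with
#' the same barcode and identical variant are merged; a barcode claiming two
#' different variants is dropped entirely), and returns the map in
#' deterministic lexicographic barcode order alongside summary counts.
#'
#' @param records A data.frame of barcode records as produced by
#'   [collapse_barcode_reads()] (row-bound).
#' @return A list with `map` (accepted, de-duplicated records) and `summary`
#'   (counts per status, per mutation class, and of barcodes dropped for
#'   conflicting variant assignments).
#' @export
build_barcode_map <- function(records) {
  empty <- records[0, , drop = FALSE]
  if (nrow(records) == 0L) {
    return(list(map = empty,
                summary = list(n_input = 0L, accepted = 0L, rejected = 0L,
                               by_status = integer(0), by_class = integer(0),
                               dropped_conflicting = 0L)))
  }
  stopifnot(all(records$status %in% BARCODE_STATUSES))
  by_status <- table(factor(records$status, levels = BARCODE_STATUSES))
  acc <- records[records$status == "accepted", , drop = FALSE]
  dropped <- 0L
  if (nrow(acc) > 0L && anyDuplicated(acc$barcode)) {
    split_idx <- split(seq_len(nrow(acc)), acc$barcode)
    keep <- logical(nrow(acc))
    merged <- list()
    for (idx in split_idx) {
      ids <- unique(paste(acc$variant[idx], acc$alt_codon[idx]))
      if (length(ids) == 1L) {
        first <- idx[1L]
        acc$n_supporting_reads[first] <- sum(acc$n_supporting_reads[idx])
        keep[first] <- TRUE
      } else {
        dropped <- dropped + length(idx)
        message("dropping barcode ", acc$barcode[idx[1L]],
                ": conflicting variant assignments")
      }
    }
    acc <- acc[keep, , drop = FALSE]
  }
  acc <- acc[order(acc$barcode, method = "radix"), , drop = FALSE]
  rownames(acc) <- NULL
  by_class <- table(factor(acc$mut_class, levels = MUT_CLASSES))
  list(map = acc,
       summary = list(n_input = nrow(records),
                      accepted = nrow(acc),
                      rejected = nrow(records) - sum(records$status == "accepted"),
                      by_status = c(by_status),
                      by_class = c(by_class),
                      dropped_conflicting = dropped))
}

#' Write / read a barcode map as TSV
#'
#' The on-disk format has columns `barcode`, `variant`, `mut_class`,
#' `alt_codon`, `n_reads`.
#'
#' @param map Data.frame with at least `barcode`, `variant`, `mut_class`,
#'   `alt_codon` columns (`n_supporting_reads` used for `n_reads` if present).
#' @param path Output/input file path.
#' @return `write_barcode_map` returns `path` invisibly; `read_barcode_map`
#'   returns a data.frame with parsed `position`, `wt_aa`, `alt_aa` columns.
#' @export
write_barcode_map <- function(map, path) {
  n_reads <- if ("n_supporting_reads" %in% names(map)) map$n_supporting_reads
             else if ("n_reads" %in% names(map)) map$n_reads else NA_integer_
  out <- data.frame(barcode = map$barcode, variant = map$variant,
                    mut_class = map$mut_class, alt_codon = map$alt_codon,
                    n_reads = n_reads, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_map
#' @export
read_barcode_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(barcode = "character",
                                          variant = "character",
                                          mut_class = "character",
                                          alt_codon = "character"))
  parsed <- parse_variant_token(map$variant)
  if (any(!parsed$valid))
    stop("malformed variant tokens in ", path, ": ",
         paste(utils::head(map$variant[!parsed$valid], 5), collapse = ", "))
  map$position <- parsed$position
  map$wt_aa <- parsed$wt_aa
  map$alt_aa <- parsed$alt_aa
  map
}
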