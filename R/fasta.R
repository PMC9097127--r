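#' Read a FASTA file into a sequence table
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file and returns one
#' row per record. Sequences are uppercased on read so that downstream
#' candidate matching is case-insensitive; stable integer ids are assigned in
#' file order and act as the join key for every downstream table (headers may
#' collide, ids never do).
#'
#' Only DNA is accepted: the IUPAC nucleotide alphabet
#' (`A C G T` plus the ambiguity letters `R Y S W K M B D H V N`). `U` is
#' rejected rather than silently converted, as are alignment gaps.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id` (integer, 1..n in file order),
#'   `header` (the full header line without the leading `>`) and `sequence`
#'   (uppercased DNA).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "acg", "t"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "oligocover_input_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("Could not parse '", path, "' as FASTA: ", conditionMessage(e)),
            class = "oligocover_input_error")
    }
  )
  if (length(set) == 0) {
    abort(paste0("FASTA file '", path, "' contains no records."),
          class = "oligocover_input_error")
  }
  headers <- names(set) %||% rep("", length(set))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  records <- tibble(
    seq_id = seq_along(seqs),
    header = unname(headers),
    sequence = unname(seqs)
  )
  validate_records(records)
  if (anyDuplicated(records$header)) {
    dups <- unique(records$header[duplicated(records$header)])
    warn(paste0("Duplicate FASTA header(s): ",
                paste(utils::head(dups, 5), collapse = ", "),
                ". Records are kept; seq_id disambiguates."))
  }
  records
}

validate_records <- function(records) {
  empty <- !nzchar(records$sequence)
  if (any(empty)) {
    abort(paste0("Record '", records$header[which(empty)[1]],
                 "' has an empty sequence."),
          class = "oligocover_input_error")
  }
  bad_pattern <- paste0("[^", paste(IUPAC_DNA, collapse = ""), "]")
  bad <- stringr::str_detect(records$sequence, bad_pattern)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- stringr::str_extract(records$sequence[i], bad_pattern)
    abort(paste0("Record '", records$header[i], "' (seq_id ", records$seq_id[i],
                 ") contains non-IUPAC DNA character '", ch, "'."),
          class = "oligocover_input_error")
  }
  invisible(records)
}

#' Build the id/header/sequence conversion table
#'
#' The conversion table records, for every input sequence, its stable integer
#' id together with the original FASTA header and the full DNA sequence. It is
#' the lookup needed to translate the integer `seq_id`s used in every other
#' output back to the input records.
#'
#' @param records A sequence table as returned by [read_fasta()].
#' @return A tibble with columns `seq_id`, `header`, `sequence`, one row per
#'   record in id order.
#' @export
conversion_table <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  records |>
    dplyr::select("seq_id", "header", "sequence") |>
    dplyr::arrange(.data$seq_id) |>
    as_tibble()
}

#' Write a sequence table back to FASTA
#'
#' Inverse of [read_fasta()] up to line wrapping: re-reading the written file
#' reproduces the `(header, sequence)` pairs exactly.
#'
#' @param records A sequence table with `header` and `sequence` columns.
#' @param path Output file path.
#' @param width Sequence line width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  lines <- purrr::map2(records$header, records$sequence, function(h, s) {
    body <- if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1, nchar(s)))
    } else {
      s
    }
    c(paste0(">", h), body)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}
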