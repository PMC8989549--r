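#' Read and write FASTQ (Sanger Phred+33)
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] converting to and from the tibble
#' representation used by the pipeline (`id`, `sequence`, `quality`).
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: a tibble `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fastq
#' @param reads Tibble with `id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read and write a cycle-barcode map
#'
#' A two-column TSV (`cycle`, `barcode`) mapping each sorting cycle to the
#' custom DNA barcode (6-8 nt) prepended to its reads. Barcodes must be
#' unique; a pairwise Hamming distance of at least 2 between equal-length
#' barcodes is recommended and a warning is issued when it is violated.
#'
#' @param path TSV file path.
#' @return A tibble `cycle` (character), `barcode`.
#' @export
read_barcode_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    cycle = readr::col_character(), barcode = readr::col_character()
  ))
  validate_barcode_map(map)
}

#' @rdname read_barcode_map
#' @param map Tibble with `cycle`, `barcode`.
#' @export
write_barcode_map <- function(map, path) {
  readr::write_tsv(validate_barcode_map(map), path)
  invisible(path)
}

#' @rdname read_barcode_map
#' @export
validate_barcode_map <- function(map) {
  if (!all(c("cycle", "barcode") %in% names(map))) {
    abort("Barcode map needs `cycle` and `barcode` columns.")
  }
  map$cycle <- as.character(map$cycle)
  map$barcode <- toupper(map$barcode)
  if (anyDuplicated(map$cycle)) abort("Cycle labels must be unique.")
  if (anyDuplicated(map$barcode)) abort("Barcodes must be unique.")
  if (!all(grepl("^[ACGT]{6,8}$", map$barcode))) {
    abort("Barcodes must be 6-8 nt over A, C, G, T.")
  }
  bc <- map$barcode
  for (i in seq_along(bc)) {
    for (j in seq_len(i - 1)) {
      if (nchar(bc[i]) == nchar(bc[j])) {
        d <- sum(strsplit(bc[i], "")[[1]] != strsplit(bc[j], "")[[1]])
        if (d < 2) {
          warn(sprintf(
            "Barcodes %s and %s have Hamming distance %d (< 2).",
            bc[j], bc[i], d
          ))
        }
      }
    }
  }
  as_tibble(map)
}

#' Default barcode map for a screen history
#'
#' Assigns one 8-nt barcode per cycle, pairwise Hamming distance >= 2.
#'
#' @param cycles Character or integer vector of cycle labels (<= 12).
#' @return A barcode-map tibble.
#' @export
default_barcode_map <- function(cycles) {
  pool <- c("AACCGGTT", "CCAATTGG", "GGTTAACC", "TTGGCCAA",
            "ACACGTGT", "CACATGTG", "GTGTACAC", "TGTGCATA",
            "AAGGCCTT", "CCTTGGAA", "GGAATTCC", "TTCCAAGG")
  if (length(cycles) > length(pool)) {
    abort("At most 12 cycles are supported by the built-in barcode pool.")
  }
  validate_barcode_map(tibble(cycle = as.character(cycles),
                              barcode = pool[seq_along(cycles)]))
}

#' Write a variant-by-cycle table as TSV
#'
#' Variants as rows, cycles as ordered columns — the on-disk layout for
#' count tables and abundance matrices.
#'
#' @param x Long tibble `variant_id`, `cycle`, and a value column.
#' @param path Output TSV.
#' @param value Name of the value column (`"count"` or `"abundance"`).
#' @return `path`, invisibly.
#' @export
write_cycle_table <- function(x, path, value = "count") {
  wide <- tidyr::pivot_wider(
    x[c("variant_id", "cycle", value)],
    names_from = "cycle", values_from = dplyr::all_of(value), values_fill = 0
  )
  readr::write_tsv(wide, path)
  invisible(path)
}
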