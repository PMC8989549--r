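#' Define a degenerate riboswitch library
#'
#' A library design consists of two constant DNA flanks and a set of allowed
#' lengths for the fully degenerate (N) region inserted between them. The
#' design space is every sequence over \{A, C, G, T\} at every allowed length,
#' so its size is \eqn{\sum_L 4^L}. Sequences are stored as DNA (T, not U);
#' rendering as RNA is a display concern only.
#'
#' @param upstream_constant DNA string 5' of the randomized region (e.g. the
#'   region carrying the T7 promoter).
#' @param degenerate_lengths Integer vector of allowed randomized-region
#'   lengths (non-negative, non-empty, deduplicated and sorted).
#' @param downstream_constant DNA string 3' of the randomized region (aptamer,
#'   RBS and reporter context).
#' @param name Label for the design.
#' @return An object of class `library_design`.
#' @examples
#' d <- library_design("ACGT", 4:6, "GGAA", name = "demo")
#' design_space_size(d)
#' @export
library_design <- function(upstream_constant, degenerate_lengths,
                           downstream_constant, name = "library") {
  upstream_constant <- toupper(upstream_constant)
  downstream_constant <- toupper(downstream_constant)
  for (s in c(upstream_constant, downstream_constant)) {
    if (!grepl("^[ACGT]*$", s)) {
      abort("Constant regions must contain only A, C, G, T.")
    }
  }
  lens <- sort(unique(as.integer(degenerate_lengths)))
  if (length(lens) == 0 || anyNA(lens) || any(lens < 0)) {
    abort("`degenerate_lengths` must be a non-empty set of integers >= 0.")
  }
  structure(
    list(
      upstream_constant = upstream_constant,
      degenerate_lengths = lens,
      downstream_constant = downstream_constant,
      name = name
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design> ", x$name, "\n", sep = "")
  cat("  upstream   (", nchar(x$upstream_constant), " nt): ",
      x$upstream_constant, "\n", sep = "")
  cat("  degenerate lengths: {", paste(x$degenerate_lengths, collapse = ", "),
      "}\n", sep = "")
  cat("  downstream (", nchar(x$downstream_constant), " nt): ",
      x$downstream_constant, "\n", sep = "")
  cat("  design space: ", format(design_space_size(x), big.mark = ","),
      " variants\n", sep = "")
  invisible(x)
}

#' Built-in library designs
#'
#' Three ready-made designs matching the screened riboswitch libraries: a
#' histamine-activated (ON) library with 4-6 randomized nucleotides directly
#' upstream of the aptamer (up to 5376 variants), a histamine-repressed (OFF)
#' library with 3-6 randomized nucleotides (up to 5440 variants), and a
#' ciprofloxacin library with 6 randomized nucleotides (4096 variants).
#'
#' The constant flanks used here are synthetic stand-ins of realistic length
#' and composition (a T7-promoter-carrying upstream region; an
#' aptamer + RBS + reporter-like downstream region); only their exact match to
#' reads, not their biology, matters to the pipeline.
#'
#' @return A `library_design`.
#' @export
design_histamine_on <- function() {
  library_design(
    upstream_constant = "GCGTAATACGACTCACTATAGGGAGA",
    degenerate_lengths = 4:6,
    downstream_constant = paste0(
      "GGACCGTCACCTGGGTGTCGGTCCTTCGCGGTCA",   # aptamer-like sensing domain
      "TAAGGAGGTGACTACT",                     # RBS + spacer
      "ATGCGTGACCACATGGTCCTTCATGAGTACGTAAATGCTGCTGGGATTACAGGTGGCGGC"
    ),
    name = "histamine_on_N4-6"
  )
}

#' @rdname design_histamine_on
#' @export
design_histamine_off <- function() {
  d <- design_histamine_on()
  library_design(d$upstream_constant, 3:6, d$downstream_constant,
                 name = "histamine_off_N3-6")
}

#' @rdname design_histamine_on
#' @export
design_ciprofloxacin <- function() {
  d <- design_histamine_on()
  library_design(d$upstream_constant, 6, d$downstream_constant,
                 name = "ciprofloxacin_N6")
}

#' Number of distinct variants in a library design
#'
#' @param design A [library_design()].
#' @return `sum(4^L)` over the allowed degenerate-region lengths, as a double
#'   (exact for any desk-scale design).
#' @examples
#' design_space_size(design_histamine_on())   # 5376
#' design_space_size(design_histamine_off())  # 5440
#' design_space_size(design_ciprofloxacin())  # 4096
#' @export
design_space_size <- function(design) {
  stopifnot(inherits(design, "library_design"))
  sum(4^design$degenerate_lengths)
}

#' Enumerate every variant of a library design
#'
#' Yields each variable-region sequence exactly once: lengths ascending,
#' lexicographic (A < C < G < T) within each length. The variant id is the
#' variable-region sequence itself; ids from different lengths cannot collide
#' because their lengths differ.
#'
#' @param design A [library_design()].
#' @param max_variants Refuse to enumerate beyond this many variants.
#' @param full_sequence Also return the full template sequence
#'   (upstream + variable + downstream)?
#' @return A tibble with column `variant_id` (and optionally `full_sequence`).
#' @export
enumerate_design_space <- function(design, max_variants = 1e7,
                                   full_sequence = FALSE) {
  stopifnot(inherits(design, "library_design"))
  n <- design_space_size(design)
  if (n > max_variants) {
    abort(sprintf(
      "Design space has %.0f variants, above the enumeration cap of %.0f.",
      n, max_variants
    ))
  }
  ids <- unlist(lapply(design$degenerate_lengths, all_kmers), use.names = FALSE)
  out <- tibble(variant_id = ids)
  if (full_sequence) {
    out$full_sequence <- paste0(design$upstream_constant, out$variant_id,
                                design$downstream_constant)
  }
  out
}

# All 4^k DNA k-mers in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  if (k == 0) return("")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reversing the column order
  # makes the last character vary fastest, i.e. lexicographic order
  do.call(paste0, rev(grid))
}

#' Sample an initial template pool from a library design
#'
#' Models library synthesis as a multinomial draw of `n_templates` molecules
#' over the design space. Per-variant weights are i.i.d. Gamma with shape
#' `1/skew` (mean 1), so `skew = 0` gives a uniform library and larger values
#' give increasing synthesis bias.
#'
#' @param design A [library_design()].
#' @param n_templates Total number of template molecules to draw.
#' @param skew Non-negative synthesis-bias parameter; 0 = uniform.
#' @param seed Optional integer seed for reproducibility.
#' @param max_variants Enumeration cap, as in [enumerate_design_space()].
#' @return A tibble `variant_id`, `count` (all variants, zeros included);
#'   counts sum to `n_templates`.
#' @export
sample_library <- function(design, n_templates, skew = 0, seed = NULL,
                           max_variants = 1e7) {
  stopifnot(n_templates >= 1)
  variants <- enumerate_design_space(design, max_variants = max_variants)
  nv <- nrow(variants)
  with_seed_if(seed, {
    w <- if (skew <= 0) rep(1, nv) else stats::rgamma(nv, shape = 1 / skew)
    if (all(w == 0)) w <- rep(1, nv)
    counts <- as.vector(rmultinom(1, size = n_templates, prob = w / sum(w)))
    tibble(variant_id = variants$variant_id, count = counts)
  })
}

#' Convert a template count table to a relative-abundance pool
#'
#' @param counts A tibble with `variant_id` and `count` columns.
#' @param drop_zero Drop variants with zero count?
#' @return A tibble `variant_id`, `abundance` summing to 1.
#' @export
as_pool <- function(counts, drop_zero = TRUE) {
  stopifnot(all(c("variant_id", "count") %in% names(counts)))
  total <- sum(counts$count)
  if (total <= 0) abort("Pool has no templates.")
  out <- tibble(variant_id = counts$variant_id,
                abundance = counts$count / total)
  if (drop_zero) out <- dplyr::filter(out, .data$abundance > 0)
  out
}

# Minimal IUPAC code covering each observed base set, keyed by the sorted
# concatenation of the bases present.
iupac_from_bases <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  inv <- setNames(names(map), vapply(strsplit(map, ""), function(b)
    paste(sort(b), collapse = ""), ""))
  inv
})

#' IUPAC consensus of equal-length variable regions
#'
#' Per position, returns the minimal IUPAC degeneracy code covering all bases
#' observed at that position. The enriched histamine ON variants, for example,
#' share the consensus GYGT (GYGU as RNA; Y = C or T/U) proximal to the
#' aptamer.
#'
#' @param variable_regions Character vector of equal-length DNA strings.
#' @return A single IUPAC string.
#' @examples
#' consensus_sequence(c("GCGT", "GTGT"))  # "GYGT"
#' @export
consensus_sequence <- function(variable_regions) {
  if (length(variable_regions) == 0) abort("Need at least one sequence.")
  variable_regions <- toupper(variable_regions)
  lens <- unique(nchar(variable_regions))
  if (length(lens) != 1) abort("Sequences must all have the same length.")
  if (!all(grepl("^[ACGT]*$", variable_regions))) {
    abort("Sequences must contain only A, C, G, T.")
  }
  if (lens == 0) return("")
  m <- do.call(rbind, strsplit(variable_regions, ""))
  codes <- apply(m, 2, function(col) {
    key <- paste(sort(unique(col)), collapse = "")
    iupac_from_bases[[key]]
  })
  paste(codes, collapse = "")
}

#' Write variants to FASTA
#'
#' Headers are the variant ids; sequences are the full templates when a
#' design is supplied, otherwise the variable regions themselves.
#'
#' @param variants Tibble with a `variant_id` column.
#' @param path Output file.
#' @param design Optional [library_design()] supplying the constant flanks.
#' @return `path`, invisibly.
#' @export
write_variant_fasta <- function(variants, path, design = NULL) {
  seqs <- variants$variant_id
  if (!is.null(design)) {
    seqs <- paste0(design$upstream_constant, seqs, design$downstream_constant)
  }
  x <- Biostrings::DNAStringSet(setNames(seqs, variants$variant_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
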