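#' Simulate barcoded sequencing reads from screen pools
#'
#' Each cycle's pool is sequenced to `depth` reads. A read is the cycle
#' barcode, the upstream constant, a variable region drawn in proportion to
#' pool abundance, and the downstream constant, truncated to `read_length`
#' nt. Substitution errors are applied i.i.d. per base at `per_base_error`;
#' base qualities are constant at the Phred score implied by that error rate
#' (Q40 for error-free reads).
#'
#' @param pools Long pool tibble `cycle`, `variant_id`, `abundance` (e.g.
#'   `simulate_screen(...)$pools`).
#' @param design The [library_design()] supplying the constant flanks.
#' @param barcode_map Tibble `cycle`, `barcode` covering every cycle in
#'   `pools`.
#' @param depth Reads per cycle.
#' @param per_base_error Substitution probability per base.
#' @param read_length Read truncation length (150 nt single-end).
#' @param seed Optional integer seed.
#' @return A tibble `id`, `cycle` (true cycle of origin), `sequence`,
#'   `quality`. Write to disk with [write_fastq()].
#' @export
simulate_reads <- function(pools, design, barcode_map, depth = 1e5,
                           per_base_error = 0.001, read_length = 150,
                           seed = NULL) {
  stopifnot(inherits(design, "library_design"))
  barcode_map <- validate_barcode_map(barcode_map)
  cycles <- unique(as.character(pools$cycle))
  missing <- setdiff(cycles, barcode_map$cycle)
  if (length(missing) > 0) {
    abort(paste("No barcode for cycle(s):", paste(missing, collapse = ", ")))
  }
  if (depth == 0) {
    return(tibble(id = character(), cycle = character(),
                  sequence = character(), quality = character()))
  }
  qchar <- if (per_base_error <= 0) "I" else
    intToUtf8(33 + min(40, round(-10 * log10(per_base_error))))
  with_seed_if(seed, {
    per_cycle <- lapply(cycles, function(cy) {
      p <- pools[as.character(pools$cycle) == cy, ]
      bc <- barcode_map$barcode[barcode_map$cycle == cy]
      vid <- sample(p$variant_id, depth, replace = TRUE, prob = p$abundance)
      seqs <- strtrim(
        paste0(bc, design$upstream_constant, vid, design$downstream_constant),
        read_length
      )
      seqs <- add_read_errors(seqs, per_base_error)
      tibble(
        id = sprintf("%s_read%d", cy, seq_len(depth)),
        cycle = cy,
        sequence = seqs,
        quality = strrep(qchar, nchar(seqs))
      )
    })
    bind_rows(per_cycle)
  })
}

# i.i.d. substitution errors at rate e, vectorized over reads.
add_read_errors <- function(seqs, e) {
  if (e <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  widths <- nchar(seqs)
  k <- rbinom(length(seqs), widths, e)
  while (any(k > 0)) {
    i <- which(k > 0)
    pos <- ceiling(runif(length(i)) * widths[i])
    old <- substring(seqs[i], pos, pos)
    new <- bases[(match(old, bases) - 1 + sample(3, length(i),
                                                replace = TRUE)) %% 4 + 1]
    substring(seqs[i], pos, pos) <- new
    k[i] <- k[i] - 1
  }
  seqs
}

#' Demultiplex reads by cycle barcode
#'
#' Exact-match on the barcode prefix (no error correction): a read is
#' assigned to the cycle whose barcode exactly prefixes it; reads matching
#' no barcode are tallied as unassigned (`cycle = NA`). When one barcode is
#' a prefix of another, the longer match wins.
#'
#' @param reads Tibble with a `sequence` column (any other columns are
#'   preserved; an existing `cycle` column is renamed `cycle_true`).
#' @param barcode_map Tibble `cycle`, `barcode`.
#' @return `reads` with columns `cycle` (assigned cycle, NA = unassigned)
#'   and `payload` (sequence with the barcode removed), plus
#'   `payload_quality` when a `quality` column is present.
#' @export
demultiplex <- function(reads, barcode_map) {
  barcode_map <- validate_barcode_map(barcode_map)
  if ("cycle" %in% names(reads)) {
    reads <- dplyr::rename(reads, cycle_true = "cycle")
  }
  assigned <- rep(NA_character_, nrow(reads))
  bclen <- integer(nrow(reads))
  ord <- order(nchar(barcode_map$barcode), decreasing = TRUE)
  for (i in ord) {
    hit <- is.na(assigned) &
      startsWith(reads$sequence, barcode_map$barcode[i])
    assigned[hit] <- barcode_map$cycle[i]
    bclen[hit] <- nchar(barcode_map$barcode[i])
  }
  reads$cycle <- factor(assigned, levels = barcode_map$cycle)
  reads$payload <- ifelse(is.na(assigned), NA_character_,
                          substring(reads$sequence, bclen + 1))
  if ("quality" %in% names(reads)) {
    reads$payload_quality <- ifelse(is.na(assigned), NA_character_,
                                    substring(reads$quality, bclen + 1))
  }
  reads
}

#' Filter demultiplexed reads
#'
#' A read is discarded if (in this order of reported reasons):
#' * `quality`: any base quality is below `min_q`;
#' * `constant_mismatch`: the constant flanks do not match the design
#'   exactly (errors in unintended positions — this also catches indels,
#'   since the variable region is located by fixed offsets, not alignment);
#' * `length`: the flanks match but the variable region's length is not an
#'   allowed degenerate length.
#'
#' @param reads Demultiplexed tibble (from [demultiplex()]); unassigned
#'   reads are dropped first.
#' @param design The [library_design()].
#' @param min_q Minimum per-base Phred quality (default 20).
#' @return `reads` with columns `pass`, `discard_reason` (NA when passing)
#'   and `variant_id` (the extracted variable region; NA unless passing).
#' @export
filter_reads <- function(reads, design, min_q = 20) {
  stopifnot(inherits(design, "library_design"))
  reads <- reads[!is.na(reads$cycle), ]
  n <- nrow(reads)
  if (n == 0) {
    return(mutate(reads, pass = logical(), discard_reason = character(),
                  variant_id = character()))
  }
  payload <- reads$payload

  bad_q <- rep(FALSE, n)
  if (min_q > 0 && "quality" %in% names(reads)) {
    # any quality character below the Phred+33 threshold
    pat <- sprintf("[\\x{21}-\\x{%x}]", 32 + min_q)
    bad_q <- stringr::str_detect(reads$quality, stringr::regex(pat))
  }

  up <- design$upstream_constant
  nu <- nchar(up)
  down <- design$downstream_constant
  plen <- nchar(payload)
  up_ok <- substr(payload, 1, nu) == up & plen >= nu

  # locate the downstream flank at fixed offsets past the upstream flank;
  # smallest matching offset wins
  max_scan <- max(design$degenerate_lengths) + 8
  var_len <- rep(NA_integer_, n)
  unresolved <- up_ok
  for (j in 0:max_scan) {
    if (!any(unresolved)) break
    idx <- which(unresolved)
    avail <- pmax(plen[idx] - nu - j, 0)
    cand <- substring(payload[idx], nu + j + 1)
    ok <- avail > 0 & cand == substring(down, 1, avail)
    var_len[idx[ok]] <- j
    unresolved[idx[ok]] <- FALSE
  }
  len_ok <- !is.na(var_len) & var_len %in% design$degenerate_lengths

  reason <- rep(NA_character_, n)
  reason[!up_ok | is.na(var_len)] <- "constant_mismatch"
  reason[up_ok & !is.na(var_len) & !len_ok] <- "length"
  reason[bad_q] <- "quality"
  pass <- is.na(reason)

  reads$pass <- pass
  reads$discard_reason <- reason
  reads$variant_id <- ifelse(pass, substr(payload, nu + 1, nu + var_len),
                             NA_character_)
  reads
}

#' Per-cycle discard tallies
#'
#' @param filtered Output of [filter_reads()].
#' @return Tibble `cycle`, `discard_reason` (`"pass"` for retained reads),
#'   `n`.
#' @export
discard_summary <- function(filtered) {
  filtered |>
    mutate(discard_reason = ifelse(.data$pass, "pass",
                                   .data$discard_reason)) |>
    count(.data$cycle, .data$discard_reason, .drop = FALSE, name = "n") |>
    dplyr::filter(!is.na(.data$discard_reason))
}

#' Count variant reads per cycle
#'
#' @param filtered Output of [filter_reads()]; only passing reads are
#'   counted.
#' @param design The [library_design()].
#' @param dense `TRUE` registers every design-space variant as a row (zeros
#'   included); `FALSE` keeps only observed variants. Default: dense when
#'   the design space has at most `1e5` variants.
#' @return A long count table: tibble `variant_id`, `cycle`, `count`, with
#'   every (variant, cycle) pair present.
#' @export
count_variants <- function(filtered, design, dense = NULL) {
  stopifnot(inherits(design, "library_design"))
  if (is.null(dense)) dense <- design_space_size(design) <= 1e5
  obs <- filtered |>
    dplyr::filter(.data$pass) |>
    count(.data$variant_id, .data$cycle, name = "count")
  ids <- if (dense) enumerate_design_space(design)$variant_id else
    sort(unique(obs$variant_id))
  grid <- tidyr::expand_grid(
    variant_id = ids,
    cycle = factor(levels(filtered$cycle), levels = levels(filtered$cycle))
  )
  grid |>
    left_join(obs, by = c("variant_id", "cycle")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L))
}

#' Percentage abundance per cycle
#'
#' Each variant's count expressed as a percentage of the total reads in its
#' cycle; columns (cycles) sum to 100.
#'
#' @param counts Long count table from [count_variants()].
#' @return `counts` with an `abundance` column (percent).
#' @export
abundance_matrix <- function(counts) {
  totals <- counts |>
    group_by(.data$cycle) |>
    summarise(total = sum(.data$count), .groups = "drop")
  empty <- totals$cycle[totals$total == 0]
  if (length(empty) > 0) {
    abort(paste("Cycle(s) with zero reads:",
                paste(as.character(empty), collapse = ", ")))
  }
  counts |>
    left_join(totals, by = "cycle") |>
    mutate(abundance = 100 * .data$count / .data$total) |>
    select(-"total")
}
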