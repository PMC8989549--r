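test_that("read simulation follows pool proportions and is seed-stable", {
  d <- tiny_design(2)
  pools <- tibble::tibble(cycle = "c1", variant_id = c("AA", "CC"),
                          abundance = c(0.9, 0.1))
  bm <- default_barcode_map("c1")
  reads <- simulate_reads(pools, d, bm, depth = 1e4, per_base_error = 0,
                          seed = 5)
  expect_equal(nrow(reads), 1e4)
  n_aa <- sum(grepl(paste0("^", bm$barcode[1], d$upstream_constant, "AA"),
                    reads$sequence))
  expect_lt(abs(n_aa - 9000), 4 * sqrt(1e4 * 0.9 * 0.1))

  expect_identical(reads, simulate_reads(pools, d, bm, depth = 1e4,
                                         per_base_error = 0, seed = 5))
  expect_equal(nrow(simulate_reads(pools, d, bm, depth = 0, seed = 5)), 0)
  expect_error(
    simulate_reads(dplyr::mutate(pools, cycle = "zzz"), d, bm, 10),
    "No barcode"
  )

  # substitution errors appear at roughly the requested rate
  noisy <- simulate_reads(pools[1, ] |>
                            dplyr::mutate(abundance = 1), d, bm,
                          depth = 2000, per_base_error = 0.01, seed = 6)
  clean <- paste0(bm$barcode[1], d$upstream_constant, "AA",
                  d$downstream_constant)
  mism <- vapply(strsplit(noisy$sequence, ""), function(x)
    sum(x != strsplit(clean, "")[[1]]), integer(1))
  expect_equal(mean(mism) / nchar(clean), 0.01, tolerance = 0.15)
})

test_that("FASTQ writing and reading round-trips through Biostrings", {
  d <- tiny_design(1)
  reads <- make_reads(d, c("A", "C", "G"), "AACCGGTT")
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
  expect_equal(back$id, reads$id)
})

test_that("demultiplexing is exact-match with a conserved unassigned tally", {
  d <- tiny_design(1)
  bm <- default_barcode_map(c("c0", "c1"))
  reads <- dplyr::bind_rows(
    make_reads(d, c("A", "C"), bm$barcode[1]),
    make_reads(d, "G", bm$barcode[2]),
    make_reads(d, "T", "AAAAAAAA")  # matches no barcode
  )
  dm <- demultiplex(reads, bm)
  expect_equal(sum(dm$cycle == "c0", na.rm = TRUE), 2)
  expect_equal(sum(dm$cycle == "c1", na.rm = TRUE), 1)
  expect_equal(sum(is.na(dm$cycle)), 1)
  # conservation: assigned + unassigned = total
  expect_equal(sum(!is.na(dm$cycle)) + sum(is.na(dm$cycle)), nrow(reads))
  # barcode is stripped from the payload
  expect_equal(dm$payload[1], paste0(d$upstream_constant, "A",
                                     d$downstream_constant))

  # one mismatch in the barcode leaves the read unassigned
  mm <- make_reads(d, "A", bm$barcode[1])
  substr(mm$sequence, 1, 1) <- "T"
  expect_true(is.na(demultiplex(mm, bm)$cycle[1]))
})

test_that("read filtering discards by quality, flank mismatch, and length", {
  d <- tiny_design(c(1, 2))
  bm <- default_barcode_map("c0")
  good <- make_reads(d, c("A", "CC"), bm$barcode)

  bad_constant <- make_reads(d, "A", bm$barcode)
  pos <- nchar(bm$barcode) + 2  # inside the upstream flank
  substr(bad_constant$sequence, pos, pos) <- "T"

  bad_length <- make_reads(d, "AAA", bm$barcode)  # 3 nt not allowed

  bad_quality <- make_reads(d, "C", bm$barcode)
  substr(bad_quality$quality, 3, 3) <- "+"  # Phred 10 < 20

  fl <- filter_reads(
    demultiplex(dplyr::bind_rows(good, bad_constant, bad_length,
                                 bad_quality), bm),
    d, min_q = 20
  )
  expect_equal(fl$pass, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(fl$discard_reason[3:5],
               c("constant_mismatch", "length", "quality"))
  expect_equal(fl$variant_id[1:2], c("A", "CC"))

  # conservation: passed + discarded = assigned
  expect_equal(sum(fl$pass) + sum(!fl$pass), 5)

  # raising min_q never increases the passing count
  passes <- vapply(c(0, 10, 20, 30, 41), function(q)
    sum(filter_reads(demultiplex(dplyr::bind_rows(good, bad_quality), bm),
                     d, min_q = q)$pass), integer(1))
  expect_true(all(diff(passes) <= 0))
})

test_that("variant counting and abundance preserve composition", {
  d <- tiny_design(1)
  bm <- default_barcode_map("c0")
  reads <- make_reads(d, rep(c("A", "C"), c(10, 30)), bm$barcode)
  fl <- filter_reads(demultiplex(reads, bm), d)
  ct <- count_variants(fl, d)
  expect_equal(ct$count[ct$variant_id == "A"], 10)
  expect_equal(ct$count[ct$variant_id == "C"], 30)
  # dense table registers unseen design variants at zero
  expect_equal(ct$count[ct$variant_id == "G"], 0)

  am <- abundance_matrix(ct)
  expect_equal(am$abundance[am$variant_id == "A"], 25)
  expect_equal(sum(am$abundance), 100, tolerance = 1e-6)

  empty <- dplyr::mutate(ct, count = 0L)
  expect_error(abundance_matrix(empty), "zero reads")

  # single-variant cycle is 100%
  one <- count_variants(
    filter_reads(demultiplex(make_reads(d, "T", bm$barcode), bm), d),
    d, dense = FALSE
  )
  expect_equal(abundance_matrix(one)$abundance, 100)
})

test_that("error-free pipeline reproduces pool composition end to end", {
  d <- tiny_design(2)
  pool <- enumerate_design_space(d) |>
    dplyr::mutate(abundance = (1:16) / sum(1:16), cycle = "c0")
  bm <- default_barcode_map("c0")
  depth <- 5e4
  reads <- simulate_reads(pool, d, bm, depth = depth, per_base_error = 0,
                          seed = 31)
  fl <- filter_reads(demultiplex(reads, bm), d)
  expect_equal(sum(is.na(fl$cycle)), 0)
  expect_true(all(fl$pass))
  am <- abundance_matrix(count_variants(fl, d))
  merged <- dplyr::inner_join(am, pool, by = "variant_id")
  p <- merged$abundance.y
  sigma <- 100 * sqrt(p * (1 - p) / depth)
  expect_true(all(abs(merged$abundance.x - 100 * p) < 4 * sigma))

  # discard report shows all reads passing
  ds <- discard_summary(fl)
  expect_equal(ds$n[ds$discard_reason == "pass"], depth)
})

test_that("barcode maps validate uniqueness and Hamming separation", {
  expect_error(validate_barcode_map(
    tibble::tibble(cycle = c("a", "a"), barcode = c("AAAAAA", "CCCCCC"))
  ), "unique")
  expect_error(validate_barcode_map(
    tibble::tibble(cycle = c("a", "b"), barcode = c("AAAA", "CCCCCC"))
  ), "6-8")
  expect_warning(validate_barcode_map(
    tibble::tibble(cycle = c("a", "b"), barcode = c("AAAAAA", "AAAAAC"))
  ), "Hamming")

  path <- withr::local_tempfile(fileext = ".tsv")
  bm <- default_barcode_map(c("c0", "c1", "c2"))
  write_barcode_map(bm, path)
  expect_equal(read_barcode_map(path), bm)
})
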