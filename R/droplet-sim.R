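#' Specification of one sorting round
#'
#' @param sort_target `"ON"` keeps the ROX-positive droplets with the highest
#'   GFP; `"OFF"` keeps those with the lowest GFP.
#' @param ligand_conc Ligand concentration (mM) in the droplets of this round.
#' @param n_droplets Number of droplets generated (>= 1000 so quantile gates
#'   are meaningful).
#' @param loading A [loading_model()]; default targets 30% occupancy.
#' @param gate_cap Maximum fraction of all droplets admitted to the gate
#'   (protocol cap 0.10; typical working range 0.001-0.03).
#' @param sorter_false_sort Probability that an out-of-gate droplet is sorted
#'   anyway (dispensing error).
#' @param sorter_miss Probability that an in-gate droplet is missed.
#' @return A `round_spec` object.
#' @export
round_spec <- function(sort_target = c("ON", "OFF"),
                       ligand_conc = 0,
                       n_droplets = 1e5,
                       loading = loading_model(lambda_for_occupancy(0.30)),
                       gate_cap = 0.03,
                       sorter_false_sort = 0.0025,
                       sorter_miss = 0.02) {
  sort_target <- match.arg(sort_target)
  if (n_droplets < 1000) abort("`n_droplets` must be >= 1000.")
  if (gate_cap <= 0 || gate_cap > 0.10) abort("`gate_cap` must be in (0, 0.10].")
  if (sorter_false_sort < 0 || sorter_false_sort >= 1 ||
      sorter_miss < 0 || sorter_miss >= 1) {
    abort("Sorter error rates must be in [0, 1).")
  }
  structure(
    list(sort_target = sort_target, ligand_conc = ligand_conc,
         n_droplets = as.integer(n_droplets), loading = loading,
         gate_cap = gate_cap, sorter_false_sort = sorter_false_sort,
         sorter_miss = sorter_miss),
    class = "round_spec"
  )
}

#' The default alternating ON/OFF sorting schedule
#'
#' Two rounds each of ON-sorting in the presence of ligand and OFF-sorting
#' without ligand, alternating — the schedule used to isolate
#' ligand-activated switches.
#'
#' @param ligand_conc Ligand concentration (mM) in the ON-sorting rounds.
#' @param ... Passed on to every [round_spec()].
#' @return A list of four `round_spec`s: ON, OFF, ON, OFF.
#' @export
alternating_schedule <- function(ligand_conc = 5, ...) {
  list(
    round_spec("ON", ligand_conc = ligand_conc, ...),
    round_spec("OFF", ligand_conc = 0, ...),
    round_spec("ON", ligand_conc = ligand_conc, ...),
    round_spec("OFF", ligand_conc = 0, ...)
  )
}

#' Construct a sorting gate from a droplet population
#'
#' Follows the bench procedure: the empty droplets (ROX- GFP-) form the
#' dominant low-ROX cluster (they are at least 70% of all droplets at
#' protocol loading) and set the baseline. The ROX threshold is the 99.9th
#' percentile of that empty cluster; droplets above it are ROX-positive. The
#' GFP bound is then the quantile of GFP among ROX-positive droplets such
#' that the gate (ROX-positive AND GFP beyond the bound) contains at most
#' `cap_fraction` of *all* droplets.
#'
#' @param events A tibble with `rox` and `gfp` columns (one row per droplet).
#' @param mode `"high_gfp"` (gate keeps gfp >= bound; ON-sorting) or
#'   `"low_gfp"` (gate keeps gfp <= bound; OFF-sorting).
#' @param cap_fraction Maximum in-gate fraction of all droplets, <= 0.10.
#' @return A `gate` object with `rox_min`, `gfp_bound`, `mode`,
#'   `cap_fraction`.
#' @export
build_gate <- function(events, mode = c("high_gfp", "low_gfp"),
                       cap_fraction = 0.03) {
  mode <- match.arg(mode)
  if (cap_fraction <= 0 || cap_fraction > 0.10) {
    abort("`cap_fraction` must be in (0, 0.10].")
  }
  n <- nrow(events)
  if (n < 1000) abort("Need at least 1000 droplets to place quantile gates.")
  rox <- events$rox
  # Empty droplets are the dominant low-ROX mode; locate it robustly via the
  # median (valid while occupancy < 50%) and take everything within a wide
  # band around it as the empty cluster.
  lr <- log(rox)
  ctr <- median(lr)
  spread <- max(mad(lr[lr <= ctr]), 1e-3)
  empty <- lr <= ctr + 6 * spread
  rox_min <- as.numeric(exp(quantile(lr[empty], 0.999, names = FALSE)))
  rox_pos <- rox > rox_min
  if (!any(rox_pos)) abort("No ROX-positive droplets; cannot place a gate.")

  gfp_pos <- events$gfp[rox_pos]
  k <- floor(cap_fraction * n)
  if (k < 1) abort("`cap_fraction` admits fewer than one droplet.")
  if (length(gfp_pos) <= k) {
    # every ROX-positive droplet fits under the cap
    bound <- if (mode == "high_gfp") min(gfp_pos) else max(gfp_pos)
  } else if (mode == "high_gfp") {
    s <- sort(gfp_pos, decreasing = TRUE)
    bound <- s[k]
    if (sum(gfp_pos >= bound) > k) bound <- bound + .Machine$double.eps * bound
  } else {
    s <- sort(gfp_pos)
    bound <- s[k]
    if (sum(gfp_pos <= bound) > k) bound <- bound - .Machine$double.eps * bound
  }
  structure(
    list(rox_min = rox_min, gfp_bound = as.numeric(bound), mode = mode,
         cap_fraction = cap_fraction),
    class = "gate"
  )
}

#' @export
print.gate <- function(x, ...) {
  cat(sprintf("<gate> %s: rox > %.3g, gfp %s %.3g (cap %.2g%%)\n",
              x$mode, x$rox_min,
              if (x$mode == "high_gfp") ">=" else "<=",
              x$gfp_bound, 100 * x$cap_fraction))
  invisible(x)
}

#' Apply a gate to droplets
#'
#' @param events Tibble with `rox`, `gfp`.
#' @param gate A [build_gate()] result.
#' @return Logical vector: in-gate flag per droplet.
#' @export
in_gate <- function(events, gate) {
  stopifnot(inherits(gate, "gate"))
  rox_pos <- events$rox > gate$rox_min
  if (gate$mode == "high_gfp") {
    rox_pos & events$gfp >= gate$gfp_bound
  } else {
    rox_pos & events$gfp <= gate$gfp_bound
  }
}

#' Sort droplets through a gate with an imperfect sorter
#'
#' In-gate droplets are dispensed with probability `1 - miss`; out-of-gate
#' droplets are dispensed anyway with probability `false_sort` (this is how
#' empty droplets end up contaminating the sorted output).
#'
#' @param events Tibble with `rox`, `gfp` (and any other per-droplet
#'   columns, which are preserved).
#' @param gate A [build_gate()] result.
#' @param false_sort,miss Sorter error rates in [0, 1).
#' @param seed Optional integer seed.
#' @return `events` with logical columns `in_gate` and `sorted` added.
#' @export
sort_droplets <- function(events, gate, false_sort = 0.0025, miss = 0.02,
                          seed = NULL) {
  if (false_sort < 0 || false_sort >= 1 || miss < 0 || miss >= 1) {
    abort("Sorter error rates must be in [0, 1).")
  }
  ig <- in_gate(events, gate)
  with_seed_if(seed, {
    u <- runif(nrow(events))
    events$in_gate <- ig
    events$sorted <- ifelse(ig, u >= miss, u < false_sort)
    events
  })
}

#' Regenerate a template pool from sorted droplets
#'
#' Every bead in a sorted droplet seeds one template lineage for the next
#' round; lineages are amplified by PCR with an optional lognormal
#' per-lineage bias and renormalized to relative abundances.
#'
#' @param sorted_variants Character vector of variant ids, one per bead
#'   recovered from the sorted droplets.
#' @param pcr_bias_cv Coefficient of variation of the lognormal amplification
#'   factor (0 = faithful amplification).
#' @param seed Optional integer seed.
#' @return A pool tibble `variant_id`, `abundance` summing to 1.
#' @export
regenerate_pool <- function(sorted_variants, pcr_bias_cv = 0, seed = NULL) {
  if (length(sorted_variants) == 0) {
    abort("No beads recovered from sorting; the campaign cannot continue.",
          class = "dropswitch_empty_pool")
  }
  counts <- table(sorted_variants)
  with_seed_if(seed, {
    w <- as.numeric(counts) * lognoise(length(counts), pcr_bias_cv)
    tibble(variant_id = names(counts), abundance = w / sum(w)) |>
      arrange(.data$variant_id)
  })
}

#' Simulate one full sorting round
#'
#' Encapsulation (Poisson or clumped bead loading; bead variants drawn from
#' the pool), cell-free expression and optics, gate construction, sorting
#' with sorter errors, and pool regeneration.
#'
#' @param pool Tibble `variant_id`, `abundance` (summing to 1).
#' @param spec A [round_spec()].
#' @param phenotypes Phenotype table from [assign_phenotypes()] (must cover
#'   every pool variant).
#' @param optics An [optics_model()].
#' @param pcr_bias_cv Passed to [regenerate_pool()].
#' @param seed Optional integer seed (controls the whole round).
#' @return A list with `pool` (the regenerated next-round pool), `events`
#'   (per-droplet tibble: `droplet`, `bead_count`, `ligand_conc`, `rox`,
#'   `gfp`, `in_gate`, `sorted`), `beads` (per-bead tibble: `droplet`,
#'   `variant_id`, `sorted`), and `gate`.
#' @export
simulate_round <- function(pool, spec, phenotypes, optics = optics_model(),
                           pcr_bias_cv = 0, seed = NULL) {
  stopifnot(inherits(spec, "round_spec"))
  if (abs(sum(pool$abundance) - 1) > 1e-6) {
    abort("`pool` abundances must sum to 1.")
  }
  with_seed_if(seed, {
    n <- spec$n_droplets
    bead_count <- sample_bead_counts(n, spec$loading)
    total_beads <- sum(bead_count)
    if (total_beads == 0) {
      abort("No beads were encapsulated.", class = "dropswitch_empty_pool")
    }
    bead_variant <- sample(pool$variant_id, total_beads, replace = TRUE,
                           prob = pool$abundance)
    droplet_of_bead <- rep.int(seq_len(n), bead_count)

    # per-bead expression at this round's ligand concentration, summed per
    # droplet (multi-bead droplets pool their output and share one fate)
    ph <- phenotypes[match(bead_variant, phenotypes$variant_id), ]
    if (anyNA(ph$off_level)) {
      abort("`phenotypes` does not cover every variant in the pool.")
    }
    expr_bead <- expression_level(ph, spec$ligand_conc)
    total_expr <- numeric(n)
    agg <- rowsum(expr_bead, droplet_of_bead)
    total_expr[as.integer(rownames(agg))] <- agg[, 1]

    events <- droplet_signals(bead_count, total_expr, optics)
    events <- tibble(droplet = seq_len(n), bead_count = bead_count,
                     ligand_conc = spec$ligand_conc, events)
    gate <- build_gate(events,
                       mode = if (spec$sort_target == "ON") "high_gfp"
                              else "low_gfp",
                       cap_fraction = spec$gate_cap)
    events <- sort_droplets(events, gate,
                            false_sort = spec$sorter_false_sort,
                            miss = spec$sorter_miss)
    beads <- tibble(droplet = droplet_of_bead, variant_id = bead_variant,
                    sorted = events$sorted[droplet_of_bead])
    next_pool <- regenerate_pool(beads$variant_id[beads$sorted],
                                 pcr_bias_cv = pcr_bias_cv)
    list(pool = next_pool, events = events, beads = beads, gate = gate)
  })
}

#' Simulate a multi-round sorting screen
#'
#' Runs the rounds of `schedule` sequentially, regenerating the pool after
#' each. Cycle 0 is the unsorted input library; cycle `r` is the pool after
#' round `r`. If a round recovers no beads the campaign halts there and the
#' remaining rounds are skipped (recorded in the summary).
#'
#' @param pool Initial pool tibble (`variant_id`, `abundance`).
#' @param schedule List of [round_spec()]s.
#' @param phenotypes,optics,pcr_bias_cv As in [simulate_round()].
#' @param seed Optional campaign seed; round `r` runs under `seed + r`.
#' @return A `screen_history` list: `pools` (long tibble `cycle`,
#'   `variant_id`, `abundance`), `rounds` (per-round summary tibble: cycle,
#'   sort target, ligand, droplet/gate/sort tallies, halted flag), and
#'   `gates`.
#' @export
simulate_screen <- function(pool, schedule, phenotypes,
                            optics = optics_model(), pcr_bias_cv = 0,
                            seed = NULL) {
  stopifnot(length(schedule) >= 1)
  pools <- list(tibble(cycle = 0L, pool))
  rounds <- list()
  gates <- list()
  for (r in seq_along(schedule)) {
    spec <- schedule[[r]]
    round_seed <- if (is.null(seed)) NULL else as.integer(seed) + r
    res <- tryCatch(
      simulate_round(pool, spec, phenotypes, optics, pcr_bias_cv,
                     seed = round_seed),
      dropswitch_empty_pool = function(e) NULL
    )
    if (is.null(res)) {
      rounds[[r]] <- tibble(
        cycle = r, sort_target = spec$sort_target,
        ligand_conc = spec$ligand_conc, n_droplets = spec$n_droplets,
        n_occupied = NA_integer_, n_in_gate = NA_integer_,
        n_sorted = NA_integer_, gate_fraction = NA_real_, halted = TRUE
      )
      warn(sprintf("Round %d recovered no beads; campaign halted.", r))
      break
    }
    pool <- res$pool
    pools[[r + 1]] <- tibble(cycle = r, pool)
    gates[[r]] <- res$gate
    rounds[[r]] <- tibble(
      cycle = r, sort_target = spec$sort_target,
      ligand_conc = spec$ligand_conc, n_droplets = spec$n_droplets,
      n_occupied = sum(res$events$bead_count > 0),
      n_in_gate = sum(res$events$in_gate),
      n_sorted = sum(res$events$sorted),
      gate_fraction = mean(res$events$in_gate),
      halted = FALSE
    )
  }
  structure(
    list(pools = bind_rows(pools), rounds = bind_rows(rounds), gates = gates),
    class = "screen_history"
  )
}

#' @export
print.screen_history <- function(x, ...) {
  n_cycles <- max(x$pools$cycle)
  cat(sprintf("<screen_history> %d sorting cycle(s) + initial library\n",
              n_cycles))
  print(x$rounds)
  invisible(x)
}

#' Export screen pools as per-cycle TSV files
#'
#' @param history A [simulate_screen()] result.
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_screen_pools <- function(history, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(history$pools, history$pools$cycle), function(p) {
    path <- file.path(dir, sprintf("pool_cycle%d.tsv", p$cycle[1]))
    readr::write_tsv(p[c("variant_id", "abundance")], path)
    path
  }, character(1))
  invisible(paths)
}
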