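#' ROX- and control-normalized expression
#'
#' Bulk cell-free expression measurements are first normalized within each
#' well by the ROX transcription signal (GFP/ROX), then by the same ratio of
#' the no-riboswitch positive control measured without ligand. A value of 1
#' therefore means "expresses like the unregulated control".
#'
#' @param data Tibble of measurements with columns `construct`,
#'   `ligand_conc`, `gfp`, `rox` (a `replicate` column is preserved if
#'   present).
#' @param control Label (in `construct`) of the no-riboswitch control; its
#'   mean GFP/ROX at `ligand_conc == 0` is the normalizer.
#' @return `data` with a `norm_expression` column added.
#' @export
normalize_expression <- function(data, control) {
  needed <- c("construct", "ligand_conc", "gfp", "rox")
  if (!all(needed %in% names(data))) {
    abort(paste("`data` must have columns:", paste(needed, collapse = ", ")))
  }
  if (any(data$rox <= 0)) abort("All ROX values must be > 0.")
  ctrl <- dplyr::filter(data, .data$construct == control,
                        .data$ligand_conc == 0)
  if (nrow(ctrl) == 0) {
    abort("No measurements of `control` at ligand_conc == 0.")
  }
  ctrl_ratio <- mean(ctrl$gfp / ctrl$rox)
  mutate(data, norm_expression = (.data$gfp / .data$rox) / ctrl_ratio)
}

#' Fold change corrected for nonspecific ligand effects
#'
#' The ligand itself can nonspecifically perturb cell-free expression (e.g.
#' up to ~36% activation of the aptamer-free control at 10 mM histamine), so
#' raw fold changes overstate switching. The corrected ratio divides the
#' variant's fold change by the control's fold change at the same
#' concentration:
#' \deqn{(v_c / v_0) / (k_c / k_0)}
#'
#' @param variant_c,variant_0 Variant expression with and without ligand.
#' @param control_c,control_0 Control expression with and without ligand.
#' @return Corrected fold change (vectorized over concentrations).
#' @examples
#' corrected_fold_change(26.8, 1, 1.36, 1)  # 19.7
#' @export
corrected_fold_change <- function(variant_c, variant_0, control_c,
                                  control_0) {
  vals <- c(variant_c, variant_0, control_c, control_0)
  if (any(vals <= 0)) abort("All expression levels must be > 0.")
  (variant_c / variant_0) / (control_c / control_0)
}

#' Corrected dose response of a construct relative to a control
#'
#' Convenience wrapper: averages replicates of `data` per concentration for
#' the chosen construct and the no-riboswitch control, and returns the
#' control-corrected fold change at every nonzero concentration (plus 1 at
#' concentration 0 by definition).
#'
#' @param data Measurement tibble as in [normalize_expression()].
#' @param construct Label of the riboswitch variant.
#' @param control Label of the no-riboswitch control.
#' @return Tibble `ligand_conc`, `response` (corrected fold change).
#' @export
corrected_dose_response <- function(data, construct, control) {
  mean_level <- function(label) {
    data |>
      dplyr::filter(.data$construct == label) |>
      group_by(.data$ligand_conc) |>
      summarise(level = mean(.data$gfp / .data$rox), .groups = "drop")
  }
  v <- mean_level(construct)
  k <- mean_level(control)
  joined <- inner_join(v, k, by = "ligand_conc", suffix = c("_v", "_k"))
  if (!any(joined$ligand_conc == 0)) {
    abort("Measurements at ligand_conc == 0 are required.")
  }
  v0 <- joined$level_v[joined$ligand_conc == 0]
  k0 <- joined$level_k[joined$ligand_conc == 0]
  transmute(
    joined,
    ligand_conc = .data$ligand_conc,
    response = corrected_fold_change(.data$level_v, v0, .data$level_k, k0)
  )
}

#' Sorting efficiency, purity, and enrichment metrics
#'
#' Definitions follow the droplet-sorter bookkeeping:
#' * efficiency (recovery): 100 x (desired droplets sorted) / (droplets
#'   detected within the gate);
#' * purity: 100 x (desired droplets among sorted) / (droplets sorted);
#' * droplet-level fold enrichment: desired-droplet fraction among all
#'   droplets after sorting / before sorting (empties included before);
#' * template-level fold enrichment: desired-template fraction in the
#'   regenerated pool / in the input pool (requires pools and the desired
#'   variant set).
#'
#' @param events Droplet tibble with logical columns `in_gate`, `sorted`,
#'   `desired`.
#' @param pool_before,pool_after Optional pools (`variant_id`, `abundance`)
#'   for the template-level metric.
#' @param desired_variants Optional character vector of desired variant ids.
#' @return One-row tibble: `efficiency`, `purity`,
#'   `droplet_enrichment_fold`, `template_enrichment_fold` (NA when pools
#'   are not supplied).
#' @export
sort_metrics <- function(events, pool_before = NULL, pool_after = NULL,
                         desired_variants = NULL) {
  needed <- c("in_gate", "sorted", "desired")
  if (!all(needed %in% names(events))) {
    abort(paste("`events` must have columns:", paste(needed, collapse = ", ")))
  }
  n_gate <- sum(events$in_gate)
  if (n_gate == 0) abort("The gate contains no droplets.")
  n_sorted <- sum(events$sorted)
  efficiency <- 100 * sum(events$desired & events$sorted & events$in_gate) /
    n_gate
  purity <- if (n_sorted == 0) NA_real_ else
    100 * sum(events$desired & events$sorted) / n_sorted

  frac_before <- mean(events$desired)
  frac_after <- if (n_sorted == 0) NA_real_ else
    mean(events$desired[events$sorted])
  droplet_enrichment <- frac_after / frac_before

  template_enrichment <- NA_real_
  if (!is.null(pool_before) && !is.null(pool_after) &&
      !is.null(desired_variants)) {
    before <- sum(pool_before$abundance[
      pool_before$variant_id %in% desired_variants])
    after <- sum(pool_after$abundance[
      pool_after$variant_id %in% desired_variants])
    template_enrichment <- after / before
  }
  tibble(
    efficiency = efficiency,
    purity = purity,
    droplet_enrichment_fold = droplet_enrichment,
    template_enrichment_fold = template_enrichment
  )
}

#' Template composition from restriction-digest band intensities
#'
#' The two mock templates carry different restriction sites, so digesting the
#' recovered PCR product with both enzymes yields species-specific cut
#' bands. After the caller subtracts background, the composition is the
#' ratio of the cut-band intensities.
#'
#' @param cut_a,cut_b Cut-band intensity for species A and B (>= 0).
#' @param uncut_a,uncut_b Residual uncut-band intensities (recorded in the
#'   output as digestion-completeness diagnostics; not used in the
#'   composition estimate).
#' @return Tibble `species`, `cut`, `uncut`, `fraction`; fractions sum to 1.
#' @export
digest_ratio <- function(cut_a, cut_b, uncut_a = 0, uncut_b = 0) {
  vals <- c(cut_a, cut_b, uncut_a, uncut_b)
  if (any(vals < 0)) abort("Band intensities must be >= 0.")
  if (cut_a + cut_b <= 0) abort("Both cut bands are zero; cannot estimate.")
  tibble(
    species = c("A", "B"),
    cut = c(cut_a, cut_b),
    uncut = c(uncut_a, uncut_b),
    fraction = c(cut_a, cut_b) / (cut_a + cut_b)
  )
}
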