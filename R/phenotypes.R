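#' Assign ground-truth dose-response phenotypes to library variants
#'
#' The synthetic-data layer plants a small fraction of true switches in the
#' library and makes the rest constitutive or dead, mirroring an
#' inhibitory-stem-loop library in which most variants keep the reporter
#' repressed, some break repression constitutively, and a few couple it to
#' ligand binding. Each variant gets a Hill dose-response:
#' \deqn{E(c) = off + (on - off) \cdot c^h / (EC_{50}^h + c^h)}
#'
#' Defaults (expression in arbitrary units roughly commensurate with the
#' ~26-unit split-GFP saturation ceiling):
#' * dead variants: the leaky repressed baseline, lognormal around 0.5 at
#'   all concentrations — in a stem-loop-repression library a non-functional
#'   variant is *repressed*, not silent, so it is indistinguishable from a
#'   switch's OFF state (this is what makes the alternating ON/OFF schedule
#'   selective for switches rather than for any fixed expression level);
#' * switches: repressed-state level drawn from the same distribution as the
#'   dead baseline, ON/OFF ratio uniform in `effect_range` (default 5-20x,
#'   bracketing the strongest observed ratio of 19.7), `ec50` lognormal
#'   around 1.6 mM, `hill = 1`;
#' * constitutive variants: a single lognormal level around 5 at all
#'   concentrations (repression broken regardless of ligand).
#'
#' @param design A [library_design()] (or a tibble with `variant_id`).
#' @param planted_fraction Fraction of variants made true switches.
#' @param direction `"on"` (ligand activates) or `"off"` (ligand represses)
#'   for the planted switches.
#' @param effect_range Length-2 range of ON/OFF ratios for planted switches.
#' @param constitutive_fraction Fraction of the *non-switch* variants that
#'   express constitutively; the rest are dead.
#' @param ec50_meanlog,ec50_sdlog Lognormal parameters of planted EC50 (mM).
#' @param repressed_meanlog,repressed_sdlog Lognormal parameters of the
#'   repressed baseline shared by dead variants and the switches' low state.
#' @param hill Hill coefficient for planted switches.
#' @param seed Optional integer seed.
#' @return A tibble with `variant_id`, `class_label` (one of `on_switch`,
#'   `off_switch`, `constitutive`, `dead`), `off_level`, `on_level`, `ec50`,
#'   `hill`. For every phenotype `off_level` is the no-ligand output and
#'   `on_level` the saturating-ligand output.
#' @export
assign_phenotypes <- function(design,
                              planted_fraction = 0.01,
                              direction = c("on", "off"),
                              effect_range = c(5, 20),
                              constitutive_fraction = 0.2,
                              ec50_meanlog = log(1.6),
                              ec50_sdlog = 0.5,
                              repressed_meanlog = log(0.5),
                              repressed_sdlog = 0.3,
                              hill = 1,
                              seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(planted_fraction >= 0, planted_fraction <= 1)
  variants <- if (inherits(design, "library_design")) {
    enumerate_design_space(design)
  } else {
    tibble(variant_id = design$variant_id)
  }
  nv <- nrow(variants)
  with_seed_if(seed, {
    n_switch <- round(planted_fraction * nv)
    idx <- sample.int(nv)
    switch_idx <- idx[seq_len(n_switch)]
    rest <- idx[-seq_len(n_switch)]
    n_const <- round(constitutive_fraction * length(rest))
    const_idx <- rest[seq_len(n_const)]

    class_label <- rep("dead", nv)
    class_label[const_idx] <- "constitutive"
    class_label[switch_idx] <-
      if (direction == "on") "on_switch" else "off_switch"

    base <- rlnorm(nv, repressed_meanlog, repressed_sdlog)
    off_level <- base
    on_level <- base
    ec50 <- rep(1, nv)
    hill_v <- rep(1, nv)

    lv <- rlnorm(n_const, meanlog = log(5), sdlog = 0.5)
    off_level[const_idx] <- lv
    on_level[const_idx] <- lv

    low <- rlnorm(n_switch, repressed_meanlog, repressed_sdlog)
    ratio <- runif(n_switch, effect_range[1], effect_range[2])
    high <- low * ratio
    if (direction == "on") {
      off_level[switch_idx] <- low
      on_level[switch_idx] <- high
    } else {
      off_level[switch_idx] <- high
      on_level[switch_idx] <- low
    }
    ec50[switch_idx] <- rlnorm(n_switch, ec50_meanlog, ec50_sdlog)
    hill_v[switch_idx] <- hill

    tibble(
      variant_id = variants$variant_id,
      class_label = class_label,
      off_level = off_level,
      on_level = on_level,
      ec50 = ec50,
      hill = hill_v
    )
  })
}

#' Hill dose-response expression level
#'
#' @param phenotypes A tibble with `off_level`, `on_level`, `ec50`, `hill`
#'   (one row per variant), or a single-row phenotype.
#' @param conc Ligand concentration in mM (scalar or one per row), >= 0.
#' @return Numeric vector of expression levels:
#'   `off + (on - off) * conc^hill / (ec50^hill + conc^hill)`.
#' @examples
#' ph <- tibble::tibble(off_level = 1, on_level = 20, ec50 = 1.6, hill = 1)
#' expression_level(ph, 0)     # 1
#' expression_level(ph, 1.6)   # 10.5 (midpoint)
#' @export
expression_level <- function(phenotypes, conc) {
  if (any(conc < 0)) abort("`conc` must be >= 0.")
  off <- phenotypes$off_level
  on <- phenotypes$on_level
  ec50 <- phenotypes$ec50
  h <- phenotypes$hill
  frac <- ifelse(conc == 0, 0, conc^h / (ec50^h + conc^h))
  off + (on - off) * frac
}

#' Optics model for droplet fluorescence readout
#'
#' Maps droplet content to ROX and GFP signals. ROX is a transcription
#' indicator: any droplet with at least one bead lights up
#' (`rox_baseline + rox_scale`, times lognormal noise); empty droplets show
#' baseline autofluorescence only. GFP reports the summed expression of all
#' beads in the droplet, capped at `gfp_cap` — the saturation ceiling imposed
#' by the limiting split-GFP detector fragment (GFP1-10) — then scaled and
#' subjected to the same multiplicative lognormal noise.
#'
#' @param gfp_cap Expression ceiling (same units as phenotype levels).
#' @param gfp_scale,rox_scale Signal units per source unit.
#' @param gfp_baseline,rox_baseline Autofluorescence baselines.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (must be < 1; 0 = deterministic optics).
#' @return An `optics_model` object.
#' @export
optics_model <- function(gfp_cap = 26, gfp_scale = 1, rox_scale = 50,
                         gfp_baseline = 1, rox_baseline = 1,
                         noise_cv = 0.2) {
  vals <- c(gfp_cap, gfp_scale, rox_scale, gfp_baseline, rox_baseline, noise_cv)
  if (any(vals < 0)) abort("Optics parameters must be non-negative.")
  if (noise_cv >= 1) abort("`noise_cv` must be < 1.")
  structure(
    list(gfp_cap = gfp_cap, gfp_scale = gfp_scale, rox_scale = rox_scale,
         gfp_baseline = gfp_baseline, rox_baseline = rox_baseline,
         noise_cv = noise_cv),
    class = "optics_model"
  )
}

# Multiplicative lognormal noise with mean 1 and the requested CV.
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Compute ROX/GFP signals for droplets
#'
#' @param bead_count Integer vector: beads per droplet.
#' @param total_expression Numeric vector: summed expression of the beads in
#'   each droplet (ignored for empty droplets).
#' @param optics An [optics_model()].
#' @param seed Optional integer seed.
#' @return A tibble with `rox` and `gfp` columns (one row per droplet).
#'   Empty droplets cluster at the baseline (bottom-left) corner of the
#'   GFP x ROX plane.
#' @export
droplet_signals <- function(bead_count, total_expression, optics,
                            seed = NULL) {
  stopifnot(inherits(optics, "optics_model"),
            length(bead_count) == length(total_expression))
  n <- length(bead_count)
  with_seed_if(seed, {
    occupied <- bead_count > 0
    nz_rox <- lognoise(n, optics$noise_cv)
    nz_gfp <- lognoise(n, optics$noise_cv)
    gfp_src <- optics$gfp_scale *
      pmin(ifelse(occupied, total_expression, 0), optics$gfp_cap)
    tibble(
      # occupied droplets: baseline + noisy signal; empties: noisy baseline
      rox = ifelse(occupied,
                   optics$rox_baseline + optics$rox_scale * nz_rox,
                   optics$rox_baseline * nz_rox),
      gfp = ifelse(occupied,
                   optics$gfp_baseline + gfp_src * nz_gfp,
                   optics$gfp_baseline * nz_gfp)
    )
  })
}
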