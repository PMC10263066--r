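# Marker panel and population intensity templates for the synthetic
# cytometry generator.  Intensities are log10 arbitrary units; modes are
# placed so that "positive" sits >= 3 sd above the positive threshold and
# "lo" modes sit between the negative and positive thresholds, which makes
# gate recovery testable.

#' Default 26-marker cytometry panel
#'
#' The lineage / functional markers plus the scatter and viability channels
#' every event table must carry.  Not every panel marker is a gate
#' dimension; the extras mirror the dump/backbone channels of a real panel.
#'
#' @return list with elements `markers` (26 marker names), `scatter`
#'   (`FSC`, `SSC`) and `viability` (`Viability`).
#' @export
default_panel <- function() {
  list(
    markers = c(
      "CD45", "CD326", "CD3", "CD4", "CD8", "CD56", "CD19",
      "CD45RA", "CD197", "FOXP3", "CD25", "HLA-DR", "CD11c", "CD123",
      "CD68", "CD14", "CD11b", "CD33", "CD16", "CD127", "CD1c", "CD141",
      "Ki67", "PD1", "PDL1", "CTLA4"
    ),
    scatter = c("FSC", "SSC"),
    viability = "Viability"
  )
}

# intensity modes (log10 a.u.)
.lvl <- list(
  neg   = c(mean = 1.00, sd = 0.15),
  lo    = c(mean = 2.05, sd = 0.15),
  pos   = c(mean = 3.40, sd = 0.25),
  scat  = c(mean = 2.00, sd = 0.20),
  sschi = c(mean = 3.40, sd = 0.20)
)

# markers on which mixture-fraction functional overlays are drawn
.overlay_markers <- c("Ki67", "PD1", "PDL1", "CTLA4")

# per-leaf-population marker patterns: positives, "lo" levels, high side
# scatter, and overlay-positive fractions.  Anything unlisted is negative.
.leaf_profiles <- list(
  cd4_naive  = list(pos = c("CD45", "CD3", "CD4", "CD45RA", "CD197", "CD127"),
                    ov = c(Ki67 = 0.03, PD1 = 0.05, PDL1 = 0.03, CTLA4 = 0.01)),
  cd4_cm     = list(pos = c("CD45", "CD3", "CD4", "CD197", "CD127"),
                    ov = c(Ki67 = 0.15, PD1 = 0.35, PDL1 = 0.05, CTLA4 = 0.02)),
  cd4_em     = list(pos = c("CD45", "CD3", "CD4", "CD127"),
                    ov = c(Ki67 = 0.25, PD1 = 0.40, PDL1 = 0.05, CTLA4 = 0.02)),
  cd4_emra   = list(pos = c("CD45", "CD3", "CD4", "CD45RA"),
                    ov = c(Ki67 = 0.10, PD1 = 0.20, PDL1 = 0.05, CTLA4 = 0.01)),
  treg_fr1   = list(pos = c("CD45", "CD3", "CD4", "CD45RA", "CD197", "CD25"),
                    lo = "FOXP3",
                    ov = c(Ki67 = 0.05, PD1 = 0.10, PDL1 = 0.03, CTLA4 = 0.10)),
  treg_fr2   = list(pos = c("CD45", "CD3", "CD4", "CD25", "FOXP3"),
                    ov = c(Ki67 = 0.25, PD1 = 0.30, PDL1 = 0.05, CTLA4 = 0.60)),
  treg_fr3   = list(pos = c("CD45", "CD3", "CD4", "CD25"),
                    lo = "FOXP3",
                    ov = c(Ki67 = 0.15, PD1 = 0.25, PDL1 = 0.05, CTLA4 = 0.10)),
  cd8_naive  = list(pos = c("CD45", "CD3", "CD8", "CD45RA", "CD197", "CD127"),
                    ov = c(Ki67 = 0.03, PD1 = 0.05, PDL1 = 0.03, CTLA4 = 0.01)),
  cd8_cm     = list(pos = c("CD45", "CD3", "CD8", "CD197", "CD127"),
                    ov = c(Ki67 = 0.15, PD1 = 0.35, PDL1 = 0.10, CTLA4 = 0.02)),
  cd8_em     = list(pos = c("CD45", "CD3", "CD8"),
                    ov = c(Ki67 = 0.30, PD1 = 0.45, PDL1 = 0.15, CTLA4 = 0.02)),
  cd8_emra   = list(pos = c("CD45", "CD3", "CD8", "CD45RA"),
                    ov = c(Ki67 = 0.12, PD1 = 0.25, PDL1 = 0.10, CTLA4 = 0.01)),
  nkt_cd4    = list(pos = c("CD45", "CD3", "CD56", "CD4"),
                    ov = c(Ki67 = 0.10, PD1 = 0.15, PDL1 = 0.05, CTLA4 = 0.02)),
  nkt_cd8    = list(pos = c("CD45", "CD3", "CD56", "CD8"),
                    ov = c(Ki67 = 0.10, PD1 = 0.15, PDL1 = 0.05, CTLA4 = 0.02)),
  b_cell     = list(pos = c("CD45", "CD19", "HLA-DR"),
                    ov = c(Ki67 = 0.08, PD1 = 0.05, PDL1 = 0.05, CTLA4 = 0.01)),
  nk         = list(pos = c("CD45", "CD56", "CD16"),
                    ov = c(Ki67 = 0.10, PD1 = 0.05, PDL1 = 0.05, CTLA4 = 0.01)),
  cdc        = list(pos = c("CD45", "HLA-DR", "CD11c", "CD11b", "CD33", "CD1c"),
                    ov = c(Ki67 = 0.05, PD1 = 0.02, PDL1 = 0.20, CTLA4 = 0.01)),
  pdc        = list(pos = c("CD45", "HLA-DR", "CD123"),
                    ov = c(Ki67 = 0.05, PD1 = 0.02, PDL1 = 0.10, CTLA4 = 0.01)),
  macrophage = list(pos = c("CD45", "CD68", "HLA-DR", "CD14", "CD11b", "CD33"),
                    sschi = TRUE,
                    ov = c(Ki67 = 0.08, PD1 = 0.02, PDL1 = 0.35, CTLA4 = 0.01)),
  mmdsc      = list(pos = c("CD45", "CD14", "CD11b", "CD33"),
                    lo = "HLA-DR",
                    ov = c(Ki67 = 0.15, PD1 = 0.02, PDL1 = 0.50, CTLA4 = 0.01)),
  cd14_mono  = list(pos = c("CD45", "CD14", "HLA-DR", "CD11b", "CD33"),
                    ov = c(Ki67 = 0.08, PD1 = 0.02, PDL1 = 0.25, CTLA4 = 0.01))
)

# planted composition of CD45+ leukocytes per study condition.  Tumour
# templates share an effector-dominant shape (high EM subsets, effector
# Tregs, myeloid lineage); the NAT template is naive / NK dominant, which
# is what drives the tumour-vs-NAT clade split.
.composition_templates <- list(
  Cold = c(
    cd8_naive = 0.02, cd8_cm = 0.04, cd8_em = 0.06, cd8_emra = 0.02,
    cd4_naive = 0.03, cd4_cm = 0.05, cd4_em = 0.06, cd4_emra = 0.02,
    treg_fr1 = 0.01, treg_fr2 = 0.03, treg_fr3 = 0.02,
    nkt_cd4 = 0.01, nkt_cd8 = 0.01,
    b_cell = 0.10, nk = 0.16,
    macrophage = 0.16, mmdsc = 0.08, cd14_mono = 0.08, cdc = 0.03, pdc = 0.01
  ),
  Myeloid = c(
    cd8_naive = 0.02, cd8_cm = 0.03, cd8_em = 0.04, cd8_emra = 0.02,
    cd4_naive = 0.03, cd4_cm = 0.04, cd4_em = 0.04, cd4_emra = 0.02,
    treg_fr1 = 0.01, treg_fr2 = 0.03, treg_fr3 = 0.02,
    nkt_cd4 = 0.01, nkt_cd8 = 0.01,
    b_cell = 0.06, nk = 0.08,
    macrophage = 0.22, mmdsc = 0.14, cd14_mono = 0.12, cdc = 0.04, pdc = 0.02
  ),
  CD8 = c(
    cd8_naive = 0.05, cd8_cm = 0.10, cd8_em = 0.18, cd8_emra = 0.05,
    cd4_naive = 0.05, cd4_cm = 0.08, cd4_em = 0.09, cd4_emra = 0.03,
    treg_fr1 = 0.01, treg_fr2 = 0.03, treg_fr3 = 0.02,
    nkt_cd4 = 0.01, nkt_cd8 = 0.02,
    b_cell = 0.08, nk = 0.05,
    macrophage = 0.06, mmdsc = 0.03, cd14_mono = 0.03, cdc = 0.02, pdc = 0.01
  ),
  NAT = c(
    cd8_naive = 0.12, cd8_cm = 0.06, cd8_em = 0.04, cd8_emra = 0.02,
    cd4_naive = 0.14, cd4_cm = 0.07, cd4_em = 0.04, cd4_emra = 0.02,
    treg_fr1 = 0.01, treg_fr2 = 0.01, treg_fr3 = 0.01,
    nkt_cd4 = 0.02, nkt_cd8 = 0.02,
    b_cell = 0.10, nk = 0.20,
    macrophage = 0.04, mmdsc = 0.01, cd14_mono = 0.04, cdc = 0.02, pdc = 0.01
  )
)

# relative leukocyte yield (drives planted cell-density differences):
# Cold tumours are immune deserts, NAT sits in between.
.density_factors <- c(Cold = 0.12, Myeloid = 1.0, CD8 = 1.0, NAT = 0.45)

#' Population intensity specifications for one study condition
#'
#' Expands the packaged marker patterns and composition template of a study
#' condition into full per-population specifications: a lognormal mean / sd
#' per channel, an expected fraction of CD45+ events, and
#' overlay-positive mixture fractions for Ki67 / PD1 / PDL1 / CTLA4.
#'
#' @param condition `"Cold"`, `"Myeloid"`, `"CD8"` or `"NAT"`.
#' @param fractions optional named numeric vector overriding the template
#'   composition (must cover the same populations and sum to 1).
#' @return list of population specs (class `population_spec`).
#' @export
default_population_specs <- function(condition = "CD8", fractions = NULL) {
  if (!condition %in% names(.composition_templates)) {
    stop("unknown condition '", condition, "'; available: ",
         paste(names(.composition_templates), collapse = ", "))
  }
  fr <- fractions %||% .composition_templates[[condition]]
  if (!setequal(names(fr), names(.leaf_profiles))) {
    stop("fractions must be named by the ", length(.leaf_profiles),
         " leaf populations")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", format(sum(fr)), ")")
  }
  panel <- default_panel()
  channels <- c(panel$scatter, panel$viability, panel$markers)
  lapply(names(.leaf_profiles), function(id) {
    prof <- .leaf_profiles[[id]]
    mu <- stats::setNames(rep(.lvl$neg["mean"], length(channels)), channels)
    sd <- stats::setNames(rep(.lvl$neg["sd"], length(channels)), channels)
    mu[panel$scatter] <- .lvl$scat["mean"]
    sd[panel$scatter] <- .lvl$scat["sd"]
    if (isTRUE(prof$sschi)) {
      mu["SSC"] <- .lvl$sschi["mean"]
      sd["SSC"] <- .lvl$sschi["sd"]
    }
    mu[prof$pos] <- .lvl$pos["mean"]
    sd[prof$pos] <- .lvl$pos["sd"]
    if (!is.null(prof$lo)) {
      mu[prof$lo] <- .lvl$lo["mean"]
      sd[prof$lo] <- .lvl$lo["sd"]
    }
    structure(list(
      population_id = id,
      mean_log_intensity = mu,
      sd_log_intensity = sd,
      expected_fraction = unname(fr[[id]]),
      overlay_fractions = prof$ov
    ), class = "population_spec")
  })
}

#' Leaf population identifiers of the synthetic generator
#' @return character vector of the 20 mutually exclusive leaf populations.
#' @export
leaf_population_ids <- function() names(.leaf_profiles)
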