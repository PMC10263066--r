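# Synthetic cohort generator.  Emulates the statistical structure the
# analysis assumes -- per-population lognormal marker mixtures with planted
# subtype compositions, subtype-shifted expression, Dirichlet clonotype
# abundances and censored survival -- so every downstream stage can be
# exercised and validated without controlled-access patient data.

#' Built-in cohort templates
#'
#' `"study_luad"` encodes an adenocarcinoma cohort of 85 tumors split
#' 19/36/30 across the Cold/Myeloid/CD8 subtypes; `"study_lusq"` a
#' squamous cohort of 50 split 14/19/17; `"study_full"` combines both and
#' adds 157 normal-adjacent-tissue (NAT) samples; `"mini"` is a small
#' template (20 samples) for fast checks.
#'
#' @param template_name one of `"study_luad"`, `"study_lusq"`,
#'   `"study_full"`, `"mini"`.
#' @return a `cohort_spec` list: `groups` (data.frame with `histology`,
#'   `subtype`, `n`), `events_per_sample`, `mass_mean_g`, `mass_sd_g`,
#'   `contamination` (dead / epithelial fractions), `seed`.
#' @export
default_cohort_spec <- function(template_name) {
  templates <- c("study_luad", "study_lusq", "study_full", "mini")
  if (length(template_name) != 1 || !template_name %in% templates) {
    stop("unknown template '", paste(template_name, collapse = ","),
         "'; available: ", paste(templates, collapse = ", "))
  }
  luad <- data.frame(histology = "LUAD",
                     subtype = c("Cold", "Myeloid", "CD8"),
                     n = c(19L, 36L, 30L))
  lusq <- data.frame(histology = "LUSQ",
                     subtype = c("Cold", "Myeloid", "CD8"),
                     n = c(14L, 19L, 17L))
  nat <- data.frame(histology = "NAT", subtype = "none", n = 157L)
  groups <- switch(template_name,
    study_luad = luad,
    study_lusq = lusq,
    study_full = rbind(luad, lusq, nat),
    mini = data.frame(histology = c("LUAD", "LUAD", "LUAD", "NAT"),
                      subtype = c("Cold", "Myeloid", "CD8", "none"),
                      n = c(4L, 5L, 5L, 6L))
  )
  structure(list(
    template = template_name,
    groups = groups,
    events_per_sample = if (template_name == "mini") 2000L else 4000L,
    mass_mean_g = 0.5,
    mass_sd_g = 0.2,
    contamination = c(dead = 0.08, epithelial = 0.15),
    seed = 1L
  ), class = "cohort_spec")
}

#' Simulate one cytometry sample
#'
#' Draws events population-by-population from independent lognormal marker
#' intensities (on the log10 scale the gates operate on), adds dead-cell
#' and CD45-negative epithelial contaminants, and returns the drawn
#' per-population event numbers as ground truth.
#'
#' @param populations list of `population_spec` objects (see
#'   [default_population_specs()]); expected fractions must sum to 1.
#' @param n_events number of leukocyte events to draw (>= 1).
#' @param mass_g tissue mass in grams (> 0).
#' @param seed integer seed.
#' @param contamination named numeric: `dead` and `epithelial` fractions in
#'   \[0, 1); contaminant events are added on top of `n_events`.
#' @return list with `events` (numeric matrix, one row per event, columns =
#'   scatter + viability + markers), `true_counts` (named integer),
#'   `mass_g`.
#' @export
simulate_fcm_sample <- function(populations, n_events, mass_g, seed = 1L,
                                contamination = c(dead = 0, epithelial = 0)) {
  if (!is.numeric(n_events) || n_events < 1) stop("n_events must be >= 1")
  if (!is.numeric(mass_g) || mass_g <= 0) stop("mass_g must be > 0")
  panel <- default_panel()
  channels <- c(panel$scatter, panel$viability, panel$markers)
  fr <- vapply(populations, function(p) p$expected_fraction, numeric(1))
  ids <- vapply(populations, function(p) p$population_id, character(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", format(sum(fr)), ")")
  }
  for (p in populations) {
    if (!all(names(p$mean_log_intensity) %in% channels) ||
        !all(channels %in% names(p$mean_log_intensity))) {
      stop("population '", p$population_id,
           "' does not match the panel channel set")
    }
    if (any(p$sd_log_intensity <= 0)) {
      stop("population '", p$population_id, "' has non-positive sd")
    }
  }
  dead_fr <- contamination[["dead"]] %||% 0
  epi_fr <- contamination[["epithelial"]] %||% 0
  if (dead_fr < 0 || dead_fr >= 1 || epi_fr < 0 || epi_fr >= 1) {
    stop("contamination fractions must be in [0, 1)")
  }

  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, size = n_events, prob = fr))
    names(counts) <- ids
    blocks <- vector("list", length(populations) + 2L)
    for (i in seq_along(populations)) {
      p <- populations[[i]]
      ni <- counts[[i]]
      if (ni == 0) next
      m <- matrix(
        stats::rnorm(ni * length(channels),
                     mean = rep(p$mean_log_intensity[channels], each = ni),
                     sd = rep(p$sd_log_intensity[channels], each = ni)),
        nrow = ni, dimnames = list(NULL, channels)
      )
      # functional overlay markers are two-component mixtures: a planted
      # fraction of the population is shifted to the positive mode
      for (mk in names(p$overlay_fractions)) {
        pf <- p$overlay_fractions[[mk]]
        hit <- stats::runif(ni) < pf
        if (any(hit)) {
          m[hit, mk] <- stats::rnorm(sum(hit), .lvl$pos["mean"], .lvl$pos["sd"])
        }
      }
      blocks[[i]] <- m
    }
    n_dead <- round(n_events * dead_fr)
    if (n_dead > 0) {
      m <- matrix(
        stats::rnorm(n_dead * length(channels), .lvl$neg["mean"], .lvl$neg["sd"]),
        nrow = n_dead, dimnames = list(NULL, channels)
      )
      m[, panel$scatter] <- stats::rnorm(n_dead * 2, .lvl$scat["mean"], .lvl$scat["sd"])
      m[, panel$viability] <- stats::rnorm(n_dead, .lvl$pos["mean"], .lvl$pos["sd"])
      m[, "CD45"] <- stats::rnorm(n_dead, .lvl$pos["mean"], .lvl$pos["sd"])
      blocks[[length(populations) + 1L]] <- m
    }
    n_epi <- round(n_events * epi_fr)
    if (n_epi > 0) {
      m <- matrix(
        stats::rnorm(n_epi * length(channels), .lvl$neg["mean"], .lvl$neg["sd"]),
        nrow = n_epi, dimnames = list(NULL, channels)
      )
      m[, panel$scatter] <- stats::rnorm(n_epi * 2, .lvl$scat["mean"], .lvl$scat["sd"])
      m[, "CD326"] <- stats::rnorm(n_epi, .lvl$pos["mean"], .lvl$pos["sd"])
      blocks[[length(populations) + 2L]] <- m
    }
    events <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
    list(events = events, true_counts = counts, mass_g = mass_g)
  })
}

#' Simulate a full cohort with planted subtype structure
#'
#' Applies subtype-conditional composition and leukocyte-yield templates
#' (Cold = scant infiltration, Myeloid = macrophage/mMDSC-dominant, CD8 =
#' T-cell-dominant; NAT from its own naive/NK-dominant template), with
#' per-sample Dirichlet composition jitter and lognormal yield jitter.
#'
#' @param spec a `cohort_spec` from [default_cohort_spec()].
#' @param seed integer seed; defaults to the seed stored in `spec`.
#' @return list with `samples` (named list of event matrices), `masses`
#'   (named numeric, grams), `meta` (data.frame `sample_id`, `histology`),
#'   and `truth` (per-sample subtype labels and true population counts;
#'   never consumed by the analysis path).
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  grp <- spec$groups
  if (any(grp$n < 1)) stop("each cohort group needs n >= 1")
  n_total <- sum(grp$n)
  histology <- rep(grp$histology, grp$n)
  subtype <- rep(grp$subtype, grp$n)
  sample_id <- sprintf("S%03d", seq_len(n_total))

  # lognormal mass with the requested arithmetic mean / sd
  m <- spec$mass_mean_g; s <- spec$mass_sd_g
  sdlog <- sqrt(log(1 + s^2 / m^2))
  meanlog <- log(m) - sdlog^2 / 2

  samples <- vector("list", n_total)
  true_counts <- vector("list", n_total)
  masses <- numeric(n_total)
  dens_jitter_sdlog <- 0.30
  comp_concentration <- 150

  for (i in seq_len(n_total)) {
    cond <- if (histology[i] == "NAT") "NAT" else subtype[i]
    si <- child_seed(seed, i)
    draw <- with_seed(si, {
      mass <- stats::rlnorm(1, meanlog, sdlog)
      base <- .composition_templates[[cond]]
      a <- base * comp_concentration
      g <- stats::rgamma(length(a), shape = a, rate = 1)
      frac <- stats::setNames(g / sum(g), names(base))
      yield <- .density_factors[[cond]] * stats::rlnorm(1, 0, dens_jitter_sdlog)
      n_ev <- max(50L, as.integer(round(spec$events_per_sample * yield)))
      list(mass = mass, frac = frac, n_ev = n_ev)
    })
    sim <- simulate_fcm_sample(
      default_population_specs(cond, fractions = draw$frac),
      n_events = draw$n_ev, mass_g = draw$mass,
      seed = child_seed(si, 1L), contamination = spec$contamination
    )
    samples[[i]] <- sim$events
    true_counts[[i]] <- sim$true_counts
    masses[i] <- draw$mass
  }
  names(samples) <- sample_id
  names(true_counts) <- sample_id
  names(masses) <- sample_id
  list(
    samples = samples,
    masses = masses,
    meta = data.frame(sample_id = sample_id, histology = histology,
                      stringsAsFactors = FALSE),
    truth = list(
      subtype = stats::setNames(subtype, sample_id),
      condition = stats::setNames(ifelse(histology == "NAT", "NAT", subtype),
                                  sample_id),
      true_counts = true_counts
    )
  )
}

#' Default gene configuration for the expression simulator
#'
#' Signature, checkpoint and immunogram-axis genes with planted per-subtype
#' log2 shifts (CD8-attractant chemokines, effector and interferon genes up
#' in the CD8 subtype; suppressive myeloid genes up in Myeloid), plus
#' exchangeable background genes.
#'
#' @param n_background number of null background genes.
#' @return data.frame with columns `gene`, `base_log2`, `sd_log2`,
#'   `effect_Cold`, `effect_Myeloid`, `effect_CD8`.
#' @export
default_gene_config <- function(n_background = 150L) {
  up_cd8 <- c("CCL5", "CXCL9", "CXCL10", "CXCL11", "IFNG", "GZMA", "GZMB",
              "PRF1", "CD8A", "CD8B", "PDCD1", "CD274", "HAVCR2", "LAG3",
              "CTLA4", "ISG15", "MX1", "OAS1", "IFIT1", "IFIT3", "IRF7",
              "STAT1", "IDO1", "CD80", "CD86", "CD28", "ICOS",
              "HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2", "HLA-DRA")
  up_myeloid <- c("CD163", "MRC1", "CCL22", "TGFB1", "IL10", "VEGFA",
                  "FOXP3", "CD14", "CD68", "ITGAM")
  core <- data.frame(
    gene = c(up_cd8, up_myeloid),
    base_log2 = 4,
    sd_log2 = 1,
    effect_Cold = 0,
    effect_Myeloid = c(rep(0, length(up_cd8)), rep(1.2, length(up_myeloid))),
    effect_CD8 = c(rep(1.8, length(up_cd8)), rep(0, length(up_myeloid))),
    stringsAsFactors = FALSE
  )
  bg <- data.frame(
    gene = sprintf("BG%04d", seq_len(n_background)),
    base_log2 = 4, sd_log2 = 1,
    effect_Cold = 0, effect_Myeloid = 0, effect_CD8 = 0,
    stringsAsFactors = FALSE
  )
  rbind(core, bg)
}

#' Simulate a TPM expression matrix with planted subtype effects
#'
#' Log-normal TPM: `log2(TPM) ~ N(base + effect[subtype], sd)` per gene.
#'
#' @param labels per-sample subtype labels (`Cold`, `Myeloid`, `CD8`, or
#'   `none` for NAT samples, which receive no planted effect); names are
#'   used as sample identifiers.
#' @param gene_config data.frame as from [default_gene_config()].
#' @param seed integer seed.
#' @return numeric genes x samples matrix of TPM values (all >= 0).
#' @export
simulate_expression <- function(labels, gene_config = default_gene_config(),
                                seed = 1L) {
  if (length(labels) == 0) stop("labels must be nonempty")
  ok <- c("Cold", "Myeloid", "CD8", "none")
  if (!all(labels %in% ok)) {
    stop("unknown subtype label(s): ",
         paste(unique(labels[!labels %in% ok]), collapse = ", "))
  }
  ids <- names(labels) %||% sprintf("S%03d", seq_along(labels))
  with_seed(seed, {
    eff <- matrix(0, nrow(gene_config), length(labels))
    for (s in c("Cold", "Myeloid", "CD8")) {
      idx <- which(labels == s)
      if (length(idx)) {
        eff[, idx] <- gene_config[[paste0("effect_", s)]]
      }
    }
    mu <- gene_config$base_log2 + eff
    x <- matrix(
      stats::rnorm(length(mu), mean = mu, sd = gene_config$sd_log2),
      nrow = nrow(gene_config),
      dimnames = list(gene_config$gene, ids)
    )
    2^x
  })
}

#' Default TCR repertoire configuration
#'
#' Clonotype richness and symmetric-Dirichlet concentration per study
#' condition.  The CD8 subtype is planted with the most diverse repertoire.
#'
#' @return data.frame with `condition`, `richness`, `concentration`.
#' @export
default_tcr_config <- function() {
  data.frame(
    condition = c("Cold", "Myeloid", "CD8", "none"),
    richness = c(120L, 100L, 250L, 200L),
    concentration = c(0.35, 0.35, 0.55, 0.50),
    stringsAsFactors = FALSE
  )
}

#' Expected Shannon entropy of a symmetric Dirichlet repertoire
#'
#' Closed form for abundances `p ~ Dirichlet(alpha, ..., alpha)` over
#' `richness` clonotypes: `E[H] = digamma(R*alpha + 1) - digamma(alpha + 1)`
#' (nats).  Used to calibrate planted diversity gaps.
#'
#' @param richness number of clonotypes.
#' @param concentration Dirichlet concentration per clonotype.
#' @return expected entropy in nats.
#' @export
expected_repertoire_entropy <- function(richness, concentration) {
  digamma(richness * concentration + 1) - digamma(concentration + 1)
}

#' Simulate clonotype tables per TCR chain
#'
#' Per sample and chain, clonotype abundances are drawn from a symmetric
#' Dirichlet and UMI counts from a multinomial at the given depth.
#'
#' @param labels per-sample subtype labels (names = sample ids).
#' @param tcr_config data.frame as [default_tcr_config()].
#' @param umi_depth total UMIs per (sample, chain) (>= 1).
#' @param chains TCR chains to emit.
#' @param seed integer seed.
#' @return data.frame `sample_id`, `chain`, `cdr3`, `umi_count` (class
#'   `clonotype_table`); rows with zero drawn UMIs are omitted.
#' @export
simulate_tcr <- function(labels, tcr_config = default_tcr_config(),
                         umi_depth = 10000L,
                         chains = c("TRA", "TRB", "TRD", "TRG"), seed = 1L) {
  if (umi_depth < 1) stop("umi_depth must be >= 1")
  ids <- names(labels) %||% sprintf("S%03d", seq_along(labels))
  rows <- list()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in seq_along(labels)) {
    cfg <- tcr_config[tcr_config$condition == labels[[i]], ]
    if (nrow(cfg) != 1) stop("no TCR config for label '", labels[[i]], "'")
    for (ci in seq_along(chains)) {
      sc <- child_seed(seed, i * 101L + ci)
      part <- with_seed(sc, {
        r <- cfg$richness
        if (r == 1) {
          p <- 1
        } else {
          g <- stats::rgamma(r, shape = cfg$concentration, rate = 1)
          # guard against all-zero gamma draws at tiny concentrations
          if (sum(g) == 0) g[1] <- 1
          p <- g / sum(g)
        }
        cnt <- as.vector(stats::rmultinom(1, umi_depth, p))
        keep <- cnt > 0
        n_keep <- sum(keep)
        cdr3 <- vapply(seq_len(n_keep), function(k) {
          paste0("CASS", paste(sample(aa, 8, replace = TRUE), collapse = ""),
                 "F")
        }, character(1))
        # de-duplicate the rare CDR3 collisions by an index suffix
        dup <- duplicated(cdr3)
        if (any(dup)) cdr3[dup] <- paste0(cdr3[dup], seq_len(sum(dup)))
        data.frame(sample_id = ids[i], chain = chains[ci], cdr3 = cdr3,
                   umi_count = cnt[keep], stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- part
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("clonotype_table", "data.frame")
  out
}

#' Simulate clinical outcomes with planted subtype hazards
#'
#' Exponential event-free survival times with per-subtype hazard
#' multipliers (default Myeloid > Cold > CD8) and independent uniform
#' administrative censoring, plus categorical clinicopathologic factors
#' with planted subtype associations.
#'
#' @param labels per-sample subtype labels (names = sample ids).
#' @param hazard_config named numeric hazard multipliers per subtype.
#' @param censor_config list with `min` and `max` censoring times (months);
#'   `rate` in \[0,1\] optionally forces that fraction of samples censored at
#'   time of draw (1 = everything censored).
#' @param baseline_rate baseline exponential hazard (per month).
#' @param seed integer seed.
#' @return data.frame `sample_id`, `efs_months`, `event`, `subtype`, and
#'   planted categorical factors (`differentiation`, `stage`, `pT`, `N`,
#'   `TLS_grade`, `STAS`).
#' @export
simulate_clinical <- function(labels,
                              hazard_config = c(Cold = 1.8, Myeloid = 3.0,
                                                CD8 = 1.0, none = 1.2),
                              censor_config = list(min = 36, max = 84,
                                                   rate = NULL),
                              baseline_rate = log(2) / 60,
                              seed = 1L) {
  if (any(hazard_config <= 0)) stop("hazard multipliers must be positive")
  ids <- names(labels) %||% sprintf("S%03d", seq_along(labels))
  if (!all(labels %in% names(hazard_config))) {
    stop("missing hazard multiplier for label(s): ",
         paste(setdiff(unique(labels), names(hazard_config)), collapse = ", "))
  }
  with_seed(seed, {
    n <- length(labels)
    rate <- baseline_rate * unname(hazard_config[labels])
    t_event <- stats::rexp(n, rate = rate)
    t_cens <- stats::runif(n, censor_config$min, censor_config$max)
    if (!is.null(censor_config$rate)) {
      forced <- stats::runif(n) < censor_config$rate
      t_cens[forced] <- pmin(t_cens[forced], t_event[forced] * 0.99)
    }
    efs <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    pick <- function(probs) {
      # probs: named list by subtype -> probability vector over levels
      vapply(labels, function(s) {
        p <- probs[[s]] %||% probs[["none"]]
        sample(seq_along(p), 1, prob = p)
      }, integer(1))
    }
    diff_lv <- c("well-moderate", "poor")
    differentiation <- diff_lv[pick(list(
      Cold = c(0.85, 0.15), Myeloid = c(0.55, 0.45), CD8 = c(0.60, 0.40),
      none = c(0.90, 0.10)))]
    stage_lv <- c("I-II", "III-IV")
    stage <- stage_lv[pick(list(
      Cold = c(0.85, 0.15), Myeloid = c(0.65, 0.35), CD8 = c(0.80, 0.20),
      none = c(1.00, 0.00)))]
    pt_lv <- c("pT1-2", "pT3-4")
    pT <- pt_lv[pick(list(
      Cold = c(0.85, 0.15), Myeloid = c(0.60, 0.40), CD8 = c(0.80, 0.20),
      none = c(0.95, 0.05)))]
    n_lv <- c("N0", "N1-3")
    N <- n_lv[pick(list(
      Cold = c(0.80, 0.20), Myeloid = c(0.65, 0.35), CD8 = c(0.75, 0.25),
      none = c(0.95, 0.05)))]
    tls_lv <- c("0", "1", "2")
    TLS_grade <- tls_lv[pick(list(
      Cold = c(0.60, 0.30, 0.10), Myeloid = c(0.45, 0.40, 0.15),
      CD8 = c(0.15, 0.35, 0.50), none = c(0.70, 0.25, 0.05)))]
    stas_lv <- c("0", "1")
    STAS <- stas_lv[pick(list(
      Cold = c(0.75, 0.25), Myeloid = c(0.60, 0.40), CD8 = c(0.70, 0.30),
      none = c(0.95, 0.05)))]
    data.frame(
      sample_id = ids, efs_months = efs, event = event,
      subtype = unname(labels), differentiation = differentiation,
      stage = stage, pT = pT, N = N, TLS_grade = TLS_grade, STAS = STAS,
      stringsAsFactors = FALSE
    )
  })
}

#' Expected gated counts from simulated leaf truth
#'
#' Maps the generator's 20 mutually exclusive leaf populations onto the
#' populations of the default gating hierarchy (e.g. the CD45RA/CD197
#' memory quadrant partitions all CD4+ T cells, so effector and non-Treg
#' FOXP3lo fractions fall in the EM quadrant).  Used to validate gating
#' recovery against planted truth.
#'
#' @param true_counts named numeric vector of leaf population counts (as
#'   returned by [simulate_fcm_sample()]).
#' @return named numeric vector over the default config's cell-type
#'   populations.
#' @export
expected_gated_counts <- function(true_counts) {
  g <- function(...) sum(true_counts[c(...)])
  c(
    cd4_t = g("cd4_naive", "cd4_cm", "cd4_em", "cd4_emra",
              "treg_fr1", "treg_fr2", "treg_fr3"),
    cd4_naive = g("cd4_naive", "treg_fr1"),
    cd4_cm = g("cd4_cm"),
    cd4_em = g("cd4_em", "treg_fr2", "treg_fr3"),
    cd4_emra = g("cd4_emra"),
    treg = g("treg_fr1", "treg_fr2", "treg_fr3"),
    treg_fr1 = g("treg_fr1"), treg_fr2 = g("treg_fr2"),
    treg_fr3 = g("treg_fr3"),
    cd8_t = g("cd8_naive", "cd8_cm", "cd8_em", "cd8_emra"),
    cd8_naive = g("cd8_naive"), cd8_cm = g("cd8_cm"),
    cd8_em = g("cd8_em"), cd8_emra = g("cd8_emra"),
    nkt_cd4 = g("nkt_cd4"), nkt_cd8 = g("nkt_cd8"),
    b_cell = g("b_cell"), nk = g("nk"),
    cdc = g("cdc"), pdc = g("pdc"),
    macrophage = g("macrophage"), mmdsc = g("mmdsc"),
    cd14_mono = g("cd14_mono")
  )
}
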