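#' Generate the factorial sample design
#'
#' Produces the warming-by-clipping factorial layout of the field experiment:
#' four treatments (CC clipped control, UC unclipped control, CW clipped
#' warming, UW unclipped warming) with `n_reps` replicates each, replicates
#' assigned to blocks round-robin. The default (6 blocks, 6 replicates)
#' reproduces the 24-sample layout of the study system.
#'
#' @param n_blocks Number of blocks (>= 1).
#' @param n_reps Replicates per treatment (>= 1).
#' @return data.frame with columns `sample_id`, `treatment`, `warming`,
#'   `clipping` (0/1 flags), `block`, `replicate`.
#' @export
gen_design <- function(n_blocks = 6L, n_reps = 6L) {
  assert_positive_int(n_blocks, "n_blocks")
  assert_positive_int(n_reps, "n_reps")
  treatments <- data.frame(
    treatment = c("CC", "UC", "CW", "UW"),
    warming   = c(0L, 0L, 1L, 1L),
    clipping  = c(1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  design <- do.call(rbind, lapply(seq_len(n_reps), function(rep) {
    cbind(treatments,
          block = ((rep - 1L) %% n_blocks) + 1L,
          replicate = rep)
  }))
  design$sample_id <- sprintf("%s_r%02d", design$treatment, design$replicate)
  rownames(design) <- NULL
  design[, c("sample_id", "treatment", "warming", "clipping", "block", "replicate")]
}

#' Parameters for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic test bed with defaults that emulate
#' the study conditions: a FACS-sorted community of `n_taxa` OTUs of which
#' `n_pao_taxa` are planted PAOs, a warming effect of +0.536 on PAO Shannon
#' diversity (the printed taxonomic effect size), a modest negative warming
#' effect on bulk evenness, stronger positive within-guild associations under
#' warming (the stress-gradient direction), and sign-anchored multiplicative
#' warming shifts on Raman biomarkers (glycogen and PHA up, polyP and fatty
#' acids down).
#'
#' @param n_taxa Total number of OTUs.
#' @param n_pao_taxa Number of planted PAO OTUs (<= `n_taxa`).
#' @param depth Sequencing depth per sample (multinomial total).
#' @param seed Root seed; all generators derive named substreams from it.
#' @param eff_warming_pao_shannon,eff_clipping_pao_shannon,eff_interaction_pao_shannon
#'   Additive planted effects on per-sample PAO Shannon diversity (natural-log
#'   units).
#' @param eff_warming_pao_abund Planted warming effect on the PAO fraction of
#'   the community, on the log-odds scale.
#' @param bulk_tilt_warming Warming exponent tilt on bulk taxa abundances
#'   (> 0 lowers bulk evenness and hence bulk Shannon).
#' @param h_base Baseline PAO Shannon diversity (natural-log units).
#' @param block_sd,noise_sd SDs of the block intercept and residual noise on
#'   the per-sample Shannon target.
#' @param conc Dirichlet concentration controlling compositional
#'   overdispersion (smaller = noisier).
#' @param sdlog_pao,sdlog_bulk Log-normal SD of baseline mean abundances.
#' @param n_guilds Number of PAO co-occurrence guilds (blocks of positively
#'   associated taxa) under ambient conditions.
#' @param n_guilds_warming Number of coarser association blocks the ambient
#'   guilds coalesce into under warming (facilitation broadens partner
#'   range, integrating the warmed network); must be <= `n_guilds`.
#' @param guild_loading,guild_loading_warming Loading of the shared
#'   within-guild log-abundance factor for ambient samples and the additional
#'   loading under warming.
#' @param frac_competitors Fraction of PAO taxa that respond *negatively* to
#'   their guild factor under ambient conditions (competitive exclusion) and
#'   switch to the cooperative positive loading under warming, following the
#'   stress-gradient hypothesis: warming relaxes competition, so networks
#'   gain positive associations.
#' @param comp_loading Magnitude of the negative ambient loading of
#'   competitor taxa.
#' @param frac_antagonists Fraction of PAO taxa that keep a residual
#'   antagonistic association under warming: besides their cooperative block
#'   loading they load *negatively* on the neighbouring association block,
#'   so the warmed network retains a minority of dispersed negative links
#'   knitting the blocks together.
#' @param antagonist_loading Magnitude of the negative secondary loading of
#'   antagonist taxa on the neighbouring block factor.
#' @param antagonist_gain Amplitude multiplier on the antagonists' combined
#'   loading; larger values strengthen both their within-block and their
#'   antagonistic associations relative to idiosyncratic noise.
#' @param taxon_noise_sd SD of idiosyncratic per-taxon log-abundance noise.
#' @param pao_frac Baseline PAO fraction of total reads (FACS-sorted
#'   communities are PAO-dominated).
#' @param pao_frac_sd SD of log-odds noise on the PAO fraction.
#' @param frac_no_genus,frac_low_escore Fractions of bulk taxa lacking a
#'   genus-level assignment / carrying an e-score below 99 (exercise the
#'   filtering rules; planted PAOs are always clean).
#' @param fun_b,fun_sd Slope and noise of the planted logarithmic
#'   functionality-biodiversity relation (functional Shannon =
#'   `fun_b * log(taxonomic Shannon) + noise`), emulating functional
#'   redundancy saturation.
#' @param n_categories Number of function categories in the function table.
#' @param redundancy Functional redundancy dial in \[0, 1\]: fraction of taxa
#'   contributing to each category (0 = one taxon per category, 1 = all taxa
#'   share every category).
#' @param cells_per_drop,n_drops Single-cell Raman sampling: cells measured
#'   per drop replicate and drop replicates per sample. Defaults (100, 2)
#'   yield 4 treatments x 6 replicates x 2 drops x 100 cells = 4800 cells.
#' @param spectra_noise_sd SD of additive Gaussian noise on spectra.
#' @param baseline_scale Scale of the smooth polynomial baseline added to raw
#'   spectra.
#' @param eff_warming_glycogen,eff_warming_pha,eff_warming_polyp,eff_warming_fa
#'   Multiplicative warming shifts on biomarker band intensities (> 1 up,
#'   < 1 down).
#' @param env_noise Global multiplier on environment-table noise SDs (0 gives
#'   exact linear functions of the treatment flags).
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_taxa = 300L,
                         n_pao_taxa = 150L,
                         depth = 20000L,
                         seed = 1L,
                         eff_warming_pao_shannon = 0.536,
                         eff_clipping_pao_shannon = 0,
                         eff_interaction_pao_shannon = 0,
                         eff_warming_pao_abund = 0.3,
                         bulk_tilt_warming = 0.15,
                         h_base = 3.2,
                         block_sd = 0.15,
                         noise_sd = 0.05,
                         conc = 20000,
                         sdlog_pao = 0.8,
                         sdlog_bulk = 1.0,
                         n_guilds = 9L,
                         n_guilds_warming = 3L,
                         guild_loading = 0.50,
                         guild_loading_warming = 0.55,
                         frac_competitors = 0.30,
                         comp_loading = 1.8,
                         frac_antagonists = 0.25,
                         antagonist_loading = 0.55,
                         antagonist_gain = 1,
                         taxon_noise_sd = 0.35,
                         pao_frac = 0.75,
                         pao_frac_sd = 0.2,
                         frac_no_genus = 0.06,
                         frac_low_escore = 0.06,
                         fun_b = 4.0,
                         fun_sd = 0.01,
                         n_categories = 20L,
                         redundancy = 0.7,
                         cells_per_drop = 100L,
                         n_drops = 2L,
                         spectra_noise_sd = 0.02,
                         baseline_scale = 0.3,
                         eff_warming_glycogen = 1.6,
                         eff_warming_pha = 1.3,
                         eff_warming_polyp = 0.75,
                         eff_warming_fa = 0.5,
                         env_noise = 1) {
  p <- as.list(environment())
  if (p$n_pao_taxa > p$n_taxa) {
    stop_invalid("n_pao_taxa (", p$n_pao_taxa, ") must be <= n_taxa (", p$n_taxa, ")")
  }
  sds <- c(block_sd, noise_sd, sdlog_pao, sdlog_bulk, taxon_noise_sd,
           pao_frac_sd, fun_sd, spectra_noise_sd)
  if (any(sds < 0)) stop_invalid("all SDs must be >= 0")
  if (redundancy < 0 || redundancy > 1) stop_invalid("redundancy must be in [0, 1]")
  if (frac_competitors < 0 || frac_competitors > 1) {
    stop_invalid("frac_competitors must be in [0, 1]")
  }
  if (comp_loading < 0) stop_invalid("comp_loading must be >= 0")
  if (frac_antagonists < 0 || frac_antagonists > 1) {
    stop_invalid("frac_antagonists must be in [0, 1]")
  }
  if (antagonist_loading < 0) stop_invalid("antagonist_loading must be >= 0")
  if (antagonist_gain <= 0) stop_invalid("antagonist_gain must be > 0")
  assert_positive_int(n_guilds_warming, "n_guilds_warming")
  if (n_guilds_warming > n_guilds) {
    stop_invalid("n_guilds_warming must be <= n_guilds")
  }
  assert_positive_int(n_taxa, "n_taxa")
  class(p) <- "synth_params"
  p
}

# Pool of genus names used for synthetic lineages; includes genera reported as
# soil PAOs or phosphate solubilisers.
.genus_pool <- c(
  "Sphingomonas", "Cupriavidus", "Azospirillum", "Dechloromonas",
  "Pseudomonas", "Accumulibacter", "Tetrasphaera", "Rhodoplanes",
  "Bradyrhizobium", "Streptomyces", "Bacillus", "Gemmatimonas",
  "Nitrospira", "Massilia", "Flavobacterium", "Arthrobacter"
)

# Solve for the tilt exponent t such that the composition p_i(t) ~ w_i^(1-t)
# has Shannon diversity equal to `target` (natural log). t = 1 gives the
# uniform composition (maximal H); decreasing t makes it more uneven.
.solve_tilt_composition <- function(w, target) {
  w <- w / sum(w)
  h_of <- function(t) {
    lp <- (1 - t) * log(w)
    lp <- lp - max(lp)
    p <- exp(lp) / sum(exp(lp))
    -sum(p[p > 0] * log(p[p > 0]))
  }
  hmax <- log(length(w))
  target <- min(max(target, 0.05), hmax - 1e-6)
  lo <- -6
  if (h_of(lo) > target) lo <- -20
  t <- tryCatch(uniroot(function(t) h_of(t) - target, c(lo, 1))$root,
                error = function(e) 1)
  lp <- (1 - t) * log(w)
  lp <- lp - max(lp)
  exp(lp) / sum(exp(lp))
}

#' Generate a synthetic OTU table with planted treatment effects
#'
#' Counts follow a log-normal / Dirichlet-multinomial scheme: taxon mean
#' abundances are log-normal, each sample's composition is perturbed by shared
#' within-guild factors (positive co-occurrence, stronger in warming samples)
#' and idiosyncratic log-normal noise, PAO evenness is tilted so the planted
#' per-sample Shannon target (baseline + treatment effects + block + noise) is
#' hit exactly before sampling, and counts are drawn
#' Dirichlet-multinomially for compositional overdispersion.
#'
#' @param design Output of [gen_design()].
#' @param params A [synth_params()] list.
#' @return A list with elements `table` (a `pao_otu_table` whose first
#'   `n_pao_taxa` taxa are the planted PAOs, flagged `pao_candidate`) and
#'   `truth` (planted effect sizes, per-sample Shannon targets, the planted
#'   functional-diversity values, and guild assignments).
#' @export
gen_otu_table <- function(design, params = synth_params()) {
  stopifnot(is.data.frame(design), all(c("warming", "clipping", "block") %in% names(design)))
  p <- params
  if (p$n_pao_taxa > p$n_taxa) stop_invalid("n_pao_taxa must be <= n_taxa")
  with_seed(substream_seed(p$seed, "otu"), {
    n_bulk <- p$n_taxa - p$n_pao_taxa
    m_pao <- exp(rnorm(p$n_pao_taxa, 0, p$sdlog_pao))
    m_bulk <- exp(rnorm(n_bulk, 0, p$sdlog_bulk))
    guild <- rep_len(seq_len(p$n_guilds), p$n_pao_taxa)
    competitor <- runif(p$n_pao_taxa) < p$frac_competitors
    antagonist <- runif(p$n_pao_taxa) < p$frac_antagonists

    n <- nrow(design)
    blocks <- sort(unique(design$block))
    block_eff <- setNames(rnorm(length(blocks), 0, p$block_sd), blocks)

    h_target <- p$h_base +
      p$eff_warming_pao_shannon * design$warming +
      p$eff_clipping_pao_shannon * design$clipping +
      p$eff_interaction_pao_shannon * design$warming * design$clipping +
      block_eff[as.character(design$block)] +
      rnorm(n, 0, p$noise_sd)

    # Under warming the fine-grained ambient guilds coalesce into coarser
    # association blocks (facilitation broadens partner range).
    guild_warm <- ((guild - 1L) %% p$n_guilds_warming) + 1L

    counts <- matrix(0L, p$n_taxa, n)
    for (s in seq_len(n)) {
      warm <- design$warming[s] == 1
      lam_coop <- p$guild_loading + p$guild_loading_warming * design$warming[s]
      # Competitors load negatively on their guild factor under ambient
      # conditions and cooperatively under warming (stress-gradient shift).
      lam <- ifelse(competitor & !warm, -p$comp_loading, lam_coop)
      f <- rnorm(p$n_guilds)
      g_use <- if (warm) guild_warm else guild
      eta <- lam * f[g_use]
      if (warm) {
        # Residual antagonism: antagonists also load negatively on the
        # neighbouring block, planting dispersed negative warming links.
        g_next <- (guild_warm %% p$n_guilds_warming) + 1L
        eta <- ifelse(antagonist,
                      p$antagonist_gain *
                        (eta - p$antagonist_loading * f[g_next]),
                      eta)
      }
      w_pao <- m_pao *
        exp(eta + rnorm(p$n_pao_taxa, 0, p$taxon_noise_sd))
      p_pao <- .solve_tilt_composition(w_pao, h_target[s])

      tilt <- 1 + p$bulk_tilt_warming * design$warming[s]
      w_bulk <- m_bulk^tilt * exp(rnorm(n_bulk, 0, p$taxon_noise_sd))
      p_bulk <- w_bulk / sum(w_bulk)

      phi <- stats::plogis(stats::qlogis(p$pao_frac) +
                             p$eff_warming_pao_abund * design$warming[s] +
                             rnorm(1, 0, p$pao_frac_sd))
      prob <- c(phi * p_pao, (1 - phi) * p_bulk)
      alpha <- p$conc * prob
      g <- rgamma(length(alpha), shape = alpha, rate = 1)
      if (sum(g) == 0) g <- prob
      counts[, s] <- rmultinom(1, p$depth, g / sum(g))[, 1]
    }

    taxa_ids <- c(sprintf("PAO%03d", seq_len(p$n_pao_taxa)),
                  sprintf("OTU%03d", seq_len(n_bulk)))
    rownames(counts) <- taxa_ids
    colnames(counts) <- design$sample_id

    genus <- sample(.genus_pool, p$n_taxa, replace = TRUE)
    taxonomy <- sprintf(
      "d__Bacteria;p__Pseudomonadota;c__C;o__O;f__F;g__%s;s__", genus)
    e_score <- runif(p$n_taxa, 99, 100)
    if (n_bulk > 0) {
      idx_bulk <- p$n_pao_taxa + seq_len(n_bulk)
      no_genus <- sample(idx_bulk, round(p$frac_no_genus * n_bulk))
      taxonomy[no_genus] <- sub("g__[^;]*", "g__", taxonomy[no_genus])
      low_e <- sample(setdiff(idx_bulk, no_genus),
                      round(p$frac_low_escore * n_bulk))
      e_score[low_e] <- runif(length(low_e), 95, 99 - 1e-6)
    }

    flags <- data.frame(pao_candidate = seq_len(p$n_taxa) <= p$n_pao_taxa,
                        row.names = taxa_ids)
    table <- otu_table(counts, taxonomy, e_score, flags)

    h_fun <- p$fun_b * log(h_target) + rnorm(n, 0, p$fun_sd)
    truth <- list(
      pao_taxa = taxa_ids[seq_len(p$n_pao_taxa)],
      guild = setNames(guild, taxa_ids[seq_len(p$n_pao_taxa)]),
      competitor = setNames(competitor, taxa_ids[seq_len(p$n_pao_taxa)]),
      antagonist = setNames(antagonist, taxa_ids[seq_len(p$n_pao_taxa)]),
      h_target = setNames(h_target, design$sample_id),
      h_fun_target = setNames(h_fun, design$sample_id),
      block_effects = block_eff,
      effects = list(
        warming_pao_shannon = p$eff_warming_pao_shannon,
        clipping_pao_shannon = p$eff_clipping_pao_shannon,
        interaction_pao_shannon = p$eff_interaction_pao_shannon,
        warming_pao_abund = p$eff_warming_pao_abund
      )
    )
    list(table = table, truth = truth)
  })
}

#' Generate a taxon-by-function contribution table
#'
#' Emulates 16S-based functional prediction output: binary presence of the
#' four PAO marker genes (ppk1, ppx, phaZ, phaC; all four set for planted
#' PAOs, at least one missing for every other taxon) plus nonnegative
#' contributions of taxa to function categories with tunable redundancy.
#'
#' @param otu A `pao_otu_table` (or the list returned by [gen_otu_table()]).
#' @param params A [synth_params()] list.
#' @return A list of class `function_table` with elements `genes` (logical
#'   taxa x 4 matrix) and `contrib` (nonnegative taxa x category matrix).
#' @export
gen_function_table <- function(otu, params = synth_params()) {
  if (!inherits(otu, "pao_otu_table") && is.list(otu) && !is.null(otu$table)) {
    otu <- otu$table
  }
  stopifnot(inherits(otu, "pao_otu_table"))
  p <- params
  taxa <- rownames(otu$counts)
  nt <- length(taxa)
  with_seed(substream_seed(p$seed, "function"), {
    is_pao <- if (!is.null(otu$flags$pao_candidate)) {
      otu$flags$pao_candidate
    } else {
      rep(FALSE, nt)
    }
    genes <- matrix(FALSE, nt, 4,
                    dimnames = list(taxa, c("ppk1", "ppx", "phaZ", "phaC")))
    genes[is_pao, ] <- TRUE
    for (i in which(!is_pao)) {
      k <- sample(0:3, 1)             # never all four
      if (k > 0) genes[i, sample(4, k)] <- TRUE
    }

    n_cat <- p$n_categories
    n_contrib <- max(1L, round(p$redundancy * nt))
    contrib <- matrix(0, nt, n_cat,
                      dimnames = list(taxa, sprintf("K%05d", seq_len(n_cat))))
    for (k in seq_len(n_cat)) {
      idx <- ((k - 1L) + seq_len(n_contrib) - 1L) %% nt + 1L
      contrib[idx, k] <- rgamma(n_contrib, shape = 2, rate = 1)
    }
    structure(list(genes = genes, contrib = contrib), class = "function_table")
  })
}

#' Default Raman spectral archetypes
#'
#' Seven archetype band tables sharing the PAO biomarker bands (polyP at 695
#' and 1174 cm-1, PHA at 840 and 1725, peptidoglycan at 726/1421/1578, amide
#' at 1002/1220/1657, glycogen at 481, fatty acids at 1450) but differing in
#' signature bands and biomarker ratios so they are separable as operational
#' phenotypic units. Archetypes 1-3 are fatty-acid-rich (control-associated),
#' archetypes 4-7 glycogen-rich (warming-associated).
#'
#' @param n Number of archetypes (1..7).
#' @return A list of data.frames with columns `center`, `width`, `intensity`,
#'   `biomarker`.
#' @export
default_archetypes <- function(n = 7L) {
  stopifnot(n >= 1, n <= 7)
  common <- data.frame(
    center   = c(695, 1174, 840, 1725, 726, 1421, 1578, 1002, 1220, 1657, 481, 1450),
    width    = c(5,   6,    5,   6,    5,   5,    5,    4,    6,    7,    4,   8),
    intensity = c(0.35, 0.3, 0.3, 0.25, 0.3, 0.25, 0.25, 0.35, 0.25, 0.3, 0.3, 0.35),
    biomarker = c("polyp", "polyp", "pha", "pha", "peptidoglycan", "peptidoglycan",
                  "peptidoglycan", "amide", "amide", "amide", "glycogen", "fa"),
    stringsAsFactors = FALSE
  )
  sig_centers <- list(c(520, 905), c(560, 1310), c(610, 1085),
                      c(875, 1520), c(935, 1360), c(965, 1125), c(1045, 1760))
  lapply(seq_len(n), function(i) {
    a <- common
    # archetype-specific biomarker weighting: low i -> FA-rich, high i -> glycogen-rich
    wfa <- 1.6 - 0.18 * (i - 1)
    wgly <- 0.6 + 0.2 * (i - 1)
    a$intensity[a$biomarker == "fa"] <- a$intensity[a$biomarker == "fa"] * wfa
    a$intensity[a$biomarker == "glycogen"] <- a$intensity[a$biomarker == "glycogen"] * wgly
    rbind(a, data.frame(center = sig_centers[[i]], width = c(6, 6),
                        intensity = c(3, 2.6), biomarker = "signature",
                        stringsAsFactors = FALSE))
  })
}

#' Generate synthetic single-cell Raman spectra
#'
#' Per cell, intensity on a 1 cm-1 grid from 400 to 2000 (1601 points) is a
#' sum of Gaussian bands from the cell's archetype, a smooth low-order
#' polynomial baseline with small random coefficients, and Gaussian noise.
#' Warming shifts biomarker band intensities multiplicatively (glycogen and
#' PHA up, polyP and fatty acids down by default). With the default design
#' and sampling parameters the set contains 4 x 6 x 2 x 100 = 4800 cells.
#'
#' @param design Output of [gen_design()].
#' @param archetypes List of archetype band tables, see [default_archetypes()].
#' @param params A [synth_params()] list.
#' @return A `spectra_set`: list with `wavenumbers` (1601-point grid),
#'   `intensities` (wavenumber x cell matrix), `meta` (per-cell data.frame
#'   with `cell_id`, `sample_id`, `treatment`, `replicate`, `drop`,
#'   `archetype`).
#' @export
gen_spectra <- function(design, archetypes = default_archetypes(),
                        params = synth_params()) {
  p <- params
  wn <- seq(400, 2000, by = 1)
  for (a in archetypes) {
    if (any(a$center < 400 | a$center > 2000)) {
      stop_invalid("archetype band centre outside the 400-2000 cm-1 grid")
    }
    if (any(a$width <= 0) || any(a$intensity < 0)) {
      stop_invalid("archetype widths must be > 0 and intensities >= 0")
    }
  }
  n_arch <- length(archetypes)
  with_seed(substream_seed(p$seed, "spectra"), {
    # archetype mixture weights: warming tilts towards glycogen-rich archetypes
    rank <- seq_len(n_arch)
    w_ambient <- rev(rank)^1.2
    w_warm <- rank^1.2
    w_ambient <- w_ambient / sum(w_ambient)
    w_warm <- w_warm / sum(w_warm)

    cells_per_sample <- p$n_drops * p$cells_per_drop
    n_cells <- nrow(design) * cells_per_sample
    intens <- matrix(0, length(wn), n_cells)
    meta <- vector("list", nrow(design))
    col <- 0L
    for (s in seq_len(nrow(design))) {
      warm <- design$warming[s] == 1
      wts <- if (warm) w_warm else w_ambient
      arch_idx <- sample.int(n_arch, cells_per_sample, replace = TRUE, prob = wts)
      shift <- c(
        glycogen = if (warm) p$eff_warming_glycogen else 1,
        pha      = if (warm) p$eff_warming_pha else 1,
        polyp    = if (warm) p$eff_warming_polyp else 1,
        fa       = if (warm) p$eff_warming_fa else 1
      )
      for (j in seq_len(cells_per_sample)) {
        col <- col + 1L
        a <- archetypes[[arch_idx[j]]]
        amp <- a$intensity
        mult <- shift[a$biomarker]
        mult[is.na(mult)] <- 1
        amp <- amp * mult * exp(rnorm(nrow(a), 0, 0.1))
        spec <- rep(0, length(wn))
        for (b in seq_len(nrow(a))) {
          spec <- spec + amp[b] * exp(-0.5 * ((wn - a$center[b]) / a$width[b])^2)
        }
        x01 <- (wn - 400) / 1600
        base <- p$baseline_scale *
          (runif(1, 0.5, 1) + runif(1, -0.5, 0.5) * x01 +
             runif(1, -0.3, 0.3) * x01^2 + runif(1, -0.2, 0.2) * x01^3)
        intens[, col] <- spec + base + rnorm(length(wn), 0, p$spectra_noise_sd)
      }
      meta[[s]] <- data.frame(
        sample_id = design$sample_id[s],
        treatment = design$treatment[s],
        replicate = design$replicate[s],
        drop = rep(seq_len(p$n_drops), each = p$cells_per_drop),
        archetype = arch_idx,
        stringsAsFactors = FALSE
      )
    }
    meta <- do.call(rbind, meta)
    meta$cell_id <- sprintf("cell%05d", seq_len(n_cells))
    colnames(intens) <- meta$cell_id
    spectra_set(wn, intens, meta)
  })
}

#' Generate the environment / ecosystem-functioning table
#'
#' A linear Gaussian system whose default path signs match the study's
#' structural model: warming raises soil temperature (+2 degC) and alkaline
#' phosphatase activity, lowers moisture, pH and total phosphorus; clipping
#' lowers C4 biomass. Carbon fluxes (NEE, ER, Rs, Rh) respond to warming and
#' GPP is derivable as ER - NEE.
#'
#' @param design Output of [gen_design()].
#' @param params A [synth_params()] list; `env_noise = 0` yields exact linear
#'   functions of the treatment flags.
#' @return data.frame with one row per sample: `sample_id`, treatment flags,
#'   `soil_t`, `moisture`, `ph`, `tp`, `ap`, `loi`, `c3_biomass`,
#'   `c4_biomass`, `nee`, `er`, `rs`, `rh`.
#' @export
gen_env <- function(design, params = synth_params()) {
  p <- params
  with_seed(substream_seed(p$seed, "env"), {
    n <- nrow(design)
    W <- design$warming
    C <- design$clipping
    s <- p$env_noise
    env <- data.frame(
      sample_id = design$sample_id,
      warming = W, clipping = C,
      soil_t   = 14 + 2.0 * W + rnorm(n, 0, 0.3 * s),
      moisture = 22 - 4.0 * W - 1.0 * C + rnorm(n, 0, 1.0 * s),
      ph       = 6.8 - 0.15 * W + rnorm(n, 0, 0.05 * s),
      tp       = 420 - 35 * W + rnorm(n, 0, 10 * s),
      ap       = 55 + 12 * W + rnorm(n, 0, 3 * s),
      loi      = 6.5 + 0.3 * W + rnorm(n, 0, 0.3 * s),
      c3_biomass = 120 - 10 * W + rnorm(n, 0, 8 * s),
      c4_biomass = 180 + 15 * W - 20 * C + rnorm(n, 0, 10 * s),
      nee = -1.0 + 0.3 * W + rnorm(n, 0, 0.15 * s),
      er  = 4.0 + 0.8 * W + rnorm(n, 0, 0.2 * s),
      rs  = 2.5 + 0.5 * W + rnorm(n, 0, 0.15 * s),
      rh  = 1.5 + 0.3 * W + rnorm(n, 0, 0.1 * s),
      stringsAsFactors = FALSE
    )
    env$loi <- pmin(pmax(env$loi, 0), 100)
    env
  })
}

#' Generate a coupled complexity/stability metric panel
#'
#' Simulates per-unit network complexity and stability metric tables that
#' share a single latent axis: every complexity metric loads on the latent
#' factor with unit weight, and every stability metric loads with weight
#' `coupling`. Larger `coupling` therefore yields stronger pairwise
#' complexity-stability correlations and more pairs flagged by
#' [correlation_screen()]. Emulates the warmed-versus-ambient contrast in
#' flagged metric pairs: warming couples network complexity to stability
#' tightly, ambient only weakly.
#'
#' @param n_units Number of observational units (rows).
#' @param coupling Latent loading of the stability metrics (>= 0); the
#'   complexity metrics always load with weight 1.
#' @param n_complexity,n_stability Number of metric columns per table.
#' @param noise_sd SD of the idiosyncratic noise on each metric.
#' @param seed Seed for the panel substream.
#' @return List with data.frames `complexity` and `stability` (matched rows)
#'   and the latent scores `latent`.
#' @export
gen_coupling_panel <- function(n_units = 24L, coupling = 1,
                               n_complexity = 6L, n_stability = 5L,
                               noise_sd = 0.6, seed = 1L) {
  assert_positive_int(n_units, "n_units")
  assert_positive_int(n_complexity, "n_complexity")
  assert_positive_int(n_stability, "n_stability")
  if (coupling < 0) stop_invalid("coupling must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  with_seed(substream_seed(seed, "coupling_panel"), {
    s <- rnorm(n_units)
    cx <- vapply(seq_len(n_complexity), function(j) {
      s + rnorm(n_units, 0, noise_sd)
    }, numeric(n_units))
    st <- vapply(seq_len(n_stability), function(j) {
      coupling * s + rnorm(n_units, 0, noise_sd)
    }, numeric(n_units))
    colnames(cx) <- sprintf("complexity_%02d", seq_len(n_complexity))
    colnames(st) <- sprintf("stability_%02d", seq_len(n_stability))
    list(complexity = as.data.frame(cx), stability = as.data.frame(st),
         latent = s)
  })
}

#' Write all synthetic tables to TSV/JSON
#'
#' Convenience writer for the full synthetic bundle: design, OTU table,
#' function table, spectra (wide TSV, first column wavenumber), cell
#' metadata, environment table, and the truth record as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param design,otu,fn,spectra,env,truth Generator outputs; any may be NULL
#'   to skip.
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic <- function(dir, design = NULL, otu = NULL, fn = NULL,
                            spectra = NULL, env = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- path
  }
  if (!is.null(design)) wr(design, "design.tsv")
  if (!is.null(otu)) {
    paths[["otu_table.tsv"]] <- write_otu_tsv(otu, file.path(dir, "otu_table.tsv"))
  }
  if (!is.null(fn)) {
    wr(data.frame(taxon = rownames(fn$genes), fn$genes, fn$contrib,
                  check.names = FALSE), "function_table.tsv")
  }
  if (!is.null(spectra)) {
    wide <- data.frame(wavenumber = spectra$wavenumbers, spectra$intensities,
                       check.names = FALSE)
    wr(wide, "spectra.tsv")
    wr(spectra$meta, "cells.tsv")
  }
  if (!is.null(env)) wr(env, "env.tsv")
  if (!is.null(truth)) {
    path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
    paths[["truth.json"]] <- path
  }
  invisible(unlist(paths))
}
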