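#' Default pipeline configuration
#'
#' A full end-to-end run on synthetic defaults: synthesize -> filter ->
#' diversity/functional redundancy -> OPU -> network -> linkage, driven by a
#' single root seed from which every stage derives a named substream.
#'
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @param ... Overrides for [synth_params()] entries or top-level config
#'   fields (`stages`, `k_pools`, `corr_threshold`, `n_null`, `n_rep`,
#'   `r_min`, `alpha`, `opu_cutoff`, `bin_width`, `use_rmt`).
#' @return Named list, serializable losslessly to YAML.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("paoscope_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(synth = TRUE, filter = TRUE, diversity = TRUE,
                  opu = TRUE, network = TRUE, linkage = TRUE),
    params = list(),           # synth_params overrides
    k_pools = 3L,
    use_rmt = FALSE,           # RMT scan optional; fixed threshold by default
    corr_threshold = 0.78,
    alpha = 0.05,
    n_null = 30L,
    n_rep = 100L,
    r_min = 0.6,
    opu_cutoff = 0.6,
    bin_width = 6
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(formals(synth_params))) {
      cfg$params[[nm]] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [default_config()].
#' @return Config list with defaults filled in.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (nm == "stages") {
      for (s in names(user$stages)) cfg$stages[[s]] <- isTRUE(user$stages[[s]])
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

.stage_error <- function(stage, e) {
  stop_invalid("pipeline stage '", stage, "' failed: ", conditionMessage(e))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic inputs:
#' synthesize the design-structured tables, apply the PAO identification
#' filters, compute diversity and treatment effect sizes, cluster Raman
#' spectra into OPUs, build per-condition co-occurrence networks with the
#' complexity/stability metric suite, and screen metric-functioning
#' correlations. Every output is written under `out_dir` and listed in a
#' manifest with parameters, seeds and md5 hashes; rerunning with an
#' identical config reproduces identical hashes.
#'
#' @param config A config list from [default_config()]/[read_config()], or a
#'   path to a YAML config.
#' @return The manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  st <- cfg$stages
  # dependency checks up front
  if (isTRUE(st$filter) && !isTRUE(st$synth)) {
    stop_invalid("stage dependency error: 'filter' requires 'synth'")
  }
  if (isTRUE(st$diversity) && !isTRUE(st$filter)) {
    stop_invalid("stage dependency error: 'diversity' requires 'filter'")
  }
  if (isTRUE(st$opu) && !isTRUE(st$synth)) {
    stop_invalid("stage dependency error: 'opu' requires 'synth'")
  }
  if (isTRUE(st$network) && !isTRUE(st$filter)) {
    stop_invalid("stage dependency error: 'network' requires 'filter'")
  }
  if (isTRUE(st$linkage) && !(isTRUE(st$network) && isTRUE(st$diversity))) {
    stop_invalid("stage dependency error: 'linkage' requires 'network' and 'diversity'")
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  wr_tsv <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- path
    path
  }
  wr_json <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs[[name]] <<- path
    path
  }

  params <- do.call(synth_params, c(list(seed = cfg$seed), cfg$params))
  state <- list()

  if (isTRUE(st$synth)) {
    tryCatch({
      design <- gen_design()
      otu <- gen_otu_table(design, params)
      fn <- gen_function_table(otu$table, params)
      spectra <- if (isTRUE(st$opu)) gen_spectra(design, params = params) else NULL
      env <- gen_env(design, params)
      state <- list(design = design, otu = otu$table, truth = otu$truth,
                    fn = fn, spectra = spectra, env = env)
      wr_tsv(design, "design.tsv")
      outputs[["otu_table.tsv"]] <- write_otu_tsv(otu$table,
                                                  file.path(cfg$out_dir, "otu_table.tsv"))
      wr_tsv(env, "env.tsv")
    }, error = function(e) .stage_error("synth", e))
  }

  if (isTRUE(st$filter)) {
    tryCatch({
      filtered <- filter_otus(state$otu)
      pao <- require_pao_genes(filtered, state$fn)
      state$filtered <- filtered
      state$pao <- pao
      wr_tsv(attr(filtered, "removed"), "removed_taxa.tsv")
      outputs[["pao_table.tsv"]] <- write_otu_tsv(pao,
                                                  file.path(cfg$out_dir, "pao_table.tsv"))
    }, error = function(e) .stage_error("filter", e))
  }

  if (isTRUE(st$diversity)) {
    tryCatch({
      h_tax <- apply(relative_abundance(state$pao), 2, shannon)
      eff <- fit_lmm(h_tax[state$design$sample_id], state$design)
      eff$beta_norm <- renormalize_effects(eff$beta)
      fr <- functional_redundancy(state$fn)
      fitcmp <- compare_fits(h_tax[state$design$sample_id],
                             state$truth$h_fun_target[state$design$sample_id])
      state$h_tax <- h_tax
      wr_tsv(data.frame(sample_id = names(h_tax), shannon = unname(h_tax)),
             "pao_shannon.tsv")
      wr_tsv(eff, "effect_sizes.tsv")
      wr_json(list(fr = fr$fr, fit_comparison = fitcmp), "diversity_summary.json")
    }, error = function(e) .stage_error("diversity", e))
  }

  if (isTRUE(st$opu)) {
    tryCatch({
      pre <- preprocess_spectra(state$spectra, bin_width = cfg$bin_width)
      levels <- quantify_biomarkers(pre)
      confirmed <- confirm_pao(levels, noise = estimate_noise(pre))
      opus <- cluster_opus(pre, cutoff = cfg$opu_cutoff)
      comp <- opu_abundance(opus, state$design)
      h_fun <- apply(comp, 1, shannon)
      eff_fun <- fit_lmm(h_fun[state$design$sample_id], state$design)
      state$opus <- opus
      state$h_fun <- h_fun
      wr_tsv(data.frame(cell_id = names(opus$assignments),
                        opu = unname(opus$assignments),
                        confirmed_pao = unname(confirmed)),
             "opu_assignments.tsv")
      wr_tsv(data.frame(sample_id = rownames(comp), comp, check.names = FALSE),
             "opu_composition.tsv")
      wr_tsv(eff_fun, "opu_effect_sizes.tsv")
    }, error = function(e) .stage_error("opu", e))
  }

  if (isTRUE(st$network)) {
    tryCatch({
      metrics <- list()
      for (cond in c("warming", "ambient")) {
        ids <- state$design$sample_id[
          if (cond == "warming") state$design$warming == 1 else state$design$warming == 0]
        sub <- state$pao$counts[, ids, drop = FALSE]
        corr <- correlation_matrix(sub)
        s_star <- if (isTRUE(cfg$use_rmt)) rmt_threshold(corr) else cfg$corr_threshold
        net <- build_network(corr, s_star, alpha = cfg$alpha, treatment = cond)
        m <- network_metrics(net, n_null = cfg$n_null, n_rep = cfg$n_rep,
                             seed = substream_seed(cfg$seed, cond))
        coh <- cohesion(sub, seed = substream_seed(cfg$seed, paste0("coh_", cond)))
        m$Cohesion_pos <- mean(coh$cohesion$pos)
        m$Cohesion_neg <- mean(coh$cohesion$neg)
        metrics[[cond]] <- m
        outputs[[paste0("network_", cond, ".tsv")]] <-
          write_edgelist_tsv(net, file.path(cfg$out_dir, paste0("network_", cond, ".tsv")))
      }
      state$net_metrics <- metrics
      mt <- do.call(rbind, lapply(names(metrics), function(cond) {
        data.frame(condition = cond,
                   metric = names(metrics[[cond]]),
                   value = unlist(lapply(metrics[[cond]], function(v) {
                     if (is.numeric(v)) v[1] else NA_real_
                   })),
                   stringsAsFactors = FALSE)
      }))
      wr_tsv(mt, "network_metrics.tsv")
    }, error = function(e) .stage_error("network", e))
  }

  if (isTRUE(st$linkage)) {
    tryCatch({
      env <- state$env
      env$om <- percent_om(env$loi)
      env$gpp <- gpp(env$nee, env$er)
      func <- env[, c("nee", "er", "gpp", "rs", "rh")]
      pao_metrics <- data.frame(
        shannon_tax = state$h_tax[env$sample_id],
        shannon_fun = if (!is.null(state$h_fun)) state$h_fun[env$sample_id] else NULL
      )
      screen <- correlation_screen(pao_metrics, func,
                                   r_min = cfg$r_min, alpha = cfg$alpha)
      wr_tsv(screen$pairs, "linkage_screen.tsv")
      wr_tsv(env, "env_derived.tsv")
      wr_json(list(n_significant = screen$n_significant), "linkage_summary.json")
    }, error = function(e) .stage_error("linkage", e))
  }

  manifest <- list(
    package = "paoscope",
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  wr_json(manifest, "manifest.json")
  invisible(manifest)
}
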