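#' Run the full comparative hydraulics pipeline
#'
#' Orchestrates: data acquisition (synthetic generation or user CSV/newick
#' inputs) -> vulnerability-curve fits -> anatomy trait derivation ->
#' species trait table -> Pearson and contrast correlation matrices,
#' phylogenetic signal table, PCA, group ANOVA with Tukey letters, VIF
#' screening plus AICc multimodel selection for embolism resistance and
#' conductivity, and recursive path models. All stages are deterministic
#' under the configured seed; every emitted file is listed with its MD5 in a
#' machine-readable manifest.
#'
#' @param config A list. Either `synth` (a [synth_config()] or `TRUE` for
#'   defaults) or `inputs` (list of paths: `curves`, `pits`, `tracheids`,
#'   `wood`, `tree`) — not both. Optional: `out_dir` (default a fresh
#'   tempdir), `seed` (default 42, overrides the synth config seed),
#'   `ks_mode`, `rpa_convention`, `delta_aicc` (2), `n_perm` (999),
#'   `n_groups` (8, for the tree-derived grouping ANOVA), `trim_outliers`
#'   (`FALSE`: beyond-3-SD values are logged, never silently removed),
#'   toggles `do_phylo`, `do_modelsel`, `do_sem`, `do_anova` (all `TRUE`).
#' @return Invisibly, a list with all in-memory results (`traits`,
#'   `vc_fits`, `correlations`, `pic`, `signal`, `pca`, `anova`,
#'   `model_selection`, `sem`, `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    synth = TRUE, inputs = NULL, out_dir = NULL, seed = 42L,
    ks_mode = "standard", rpa_convention = "as_printed",
    delta_aicc = 2, n_perm = 999L, n_groups = 8L, trim_outliers = FALSE,
    do_phylo = TRUE, do_modelsel = TRUE, do_sem = TRUE, do_anova = TRUE),
    config)
  if (!is.null(config$inputs) && !is.null(config$synth)) {
    stop("give either 'synth' or 'inputs', not both", call. = FALSE)
  }
  if (!is.null(cfg$inputs)) cfg$synth <- NULL
  out_dir <- cfg$out_dir %||% tempfile("xylemcomp_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  results <- list(out_dir = out_dir)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    tree <- parse_newick(paste(readLines(inp$tree), collapse = ""))
    curves <- utils::read.csv(inp$curves)
    pits <- utils::read.csv(inp$pits)
    tracheids <- utils::read.csv(inp$tracheids)
    wood <- utils::read.csv(inp$wood)
    truth <- NULL
  } else {
    scfg <- if (isTRUE(cfg$synth)) synth_config(seed = cfg$seed)
            else utils::modifyList(cfg$synth, list(seed = cfg$seed))
    if (!inherits(scfg, "synth_config")) class(scfg) <- "synth_config"
    tree <- simulate_tree(scfg$n_species, scfg$birth,
                          substream_seed(scfg$seed, "tree"))
    cav <- generate_cavitron_dataset(tree, scfg)
    ana <- generate_anatomy_table(tree, scfg)
    curves <- cav$curves
    pits <- ana$pits; tracheids <- ana$tracheids; wood <- ana$wood
    truth <- list(cavitron = cav$truth, anatomy = ana$truth)
    writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
    emit(curves, "curves.csv"); emit(pits, "pits.csv")
    emit(tracheids, "tracheids.csv"); emit(wood, "wood.csv")
    jsonlite::write_json(
      list(species = truth$cavitron$species, anatomy = truth$anatomy,
           cv = scfg$cv, seed = scfg$seed,
           note = truth$cavitron$note),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- stage: vulnerability curves ----------------------------------------
  vc <- fit_vc_table(curves, ks_mode = cfg$ks_mode)
  vc_species <- species_vc_means(vc)
  emit(vc, "vc_fits_branch.csv"); emit(vc_species, "vc_fits_species.csv")
  results$vc_fits <- list(branch = vc, species = vc_species)

  # --- stage: anatomy ------------------------------------------------------
  ana_tab <- anatomy_trait_table(pits, tracheids, wood,
                                 rpa_convention = cfg$rpa_convention)
  traits <- merge(vc_species[, c("species", "P50_abs_MPa",
                                 "Ks_kg_m_s_MPa")],
                  ana_tab$species, by = "species")
  emit(ana_tab$branch, "anatomy_branch.csv")
  emit(traits, "traits_species.csv")
  results$traits <- traits

  trait_cols <- c("P50_abs_MPa", "Ks_kg_m_s_MPa", "Dh_um", "TD_per_mm2",
                  "Tw_um", "TSR", "DPM_um", "DT_um", "DPA_um", "TO", "MF",
                  "VE", "RPA_MPa_s_m3", "WD_g_cm3")
  trait_cols <- intersect(trait_cols, names(traits))

  # outliers are logged, never silently removed; trimming is opt-in
  ol <- flag_outliers(traits, trait_cols, trim = isTRUE(cfg$trim_outliers))
  if (nrow(ol$flagged)) {
    emit(ol$flagged, "outliers_flagged.csv")
    message(nrow(ol$flagged), " trait value(s) beyond 3 SD (",
            if (isTRUE(cfg$trim_outliers)) "trimmed to NA" else "kept", ")")
    if (isTRUE(cfg$trim_outliers)) traits <- ol$table
  }
  results$outliers <- ol$flagged

  # --- stage: correlations / PCA ------------------------------------------
  cors <- pearson_matrix(traits, trait_cols)
  emit(as.data.frame(cors$r), "correlations_pearson.csv")
  results$correlations <- cors
  if (nrow(traits) >= length(trait_cols) + 1L) {
    pca <- pca_traits(traits, trait_cols)
    emit(as.data.frame(pca$loadings), "pca_loadings.csv")
    results$pca <- pca
  } else {
    message("skipping PCA: fewer species than traits + 1")
  }

  # --- stage: phylogenetic tests ------------------------------------------
  if (cfg$do_phylo) {
    picm <- pic_matrix(tree, traits, trait_cols)
    emit(as.data.frame(picm$r), "correlations_pic.csv")
    results$pic <- picm
    sig <- signal_table(tree, traits, trait_cols, n_perm = cfg$n_perm,
                        seed = substream_seed(cfg$seed, "signal"))
    emit(sig, "signal_table.csv")
    results$signal <- sig
  }

  # --- stage: group ANOVA --------------------------------------------------
  if (cfg$do_anova) {
    groups <- tree_groups(tree, cfg$n_groups)
    gl <- groups[traits$species]
    anov <- lapply(stats::setNames(trait_cols, trait_cols), function(tr) {
      anova_tukey(traits[[tr]], gl)
    })
    letter_tab <- do.call(rbind, lapply(names(anov), function(tr) {
      a <- anov[[tr]]
      data.frame(trait = tr, F = a$F, df1 = a$df[1], df2 = a$df[2],
                 p = a$p, letters = paste(
                   paste0(names(a$letters), ":", a$letters),
                   collapse = " "), stringsAsFactors = FALSE)
    }))
    emit(letter_tab, "anova_letters.csv")
    results$anova <- anov
    results$groups <- groups
  }

  # --- stage: multimodel selection ----------------------------------------
  if (cfg$do_modelsel) {
    specs <- list(
      P50_abs_MPa = c("DPA_um", "MF", "VE"),
      Ks_kg_m_s_MPa = c("Dh_um", "TD_per_mm2", "RPA_MPa_s_m3"))
    ms <- lapply(names(specs), function(resp) {
      cand <- intersect(specs[[resp]], names(traits))
      list(response = resp,
           vif = vif_screen(traits, cand),
           selection = aicc_model_selection(traits, resp, cand,
                                            delta_threshold = cfg$delta_aicc))
    })
    names(ms) <- names(specs)
    sel_tab <- do.call(rbind, lapply(ms, function(m) {
      cbind(response = m$response,
            m$selection$models[m$selection$models$selected,
                               c("model", "k", "logLik", "AICc", "delta",
                                 "weight")])
    }))
    emit(sel_tab, "model_selection.csv")
    results$model_selection <- ms
  }

  # --- stage: path models --------------------------------------------------
  if (cfg$do_sem) {
    sem <- lapply(c(p50 = "p50", ks = "ks"), function(w) {
      spec <- path_preset(w)
      if (!all(spec$variables %in% names(traits))) return(NULL)
      if (nrow(traits) < length(spec$variables) + 2L) {
        message("skipping '", w, "' path model: fewer species than ",
                "variables + 2")
        return(NULL)
      }
      fit <- fit_path_model(traits, spec)
      outcome <- if (w == "p50") "P50_abs_MPa" else "Ks_kg_m_s_MPa"
      list(fit = fit, effects = effects_decomposition(fit, outcome))
    })
    sem_tab <- do.call(rbind, lapply(names(sem), function(w) {
      if (is.null(sem[[w]])) return(NULL)
      cbind(model = w, sem[[w]]$fit$coefficients,
            chisq = sem[[w]]$fit$chisq, df = sem[[w]]$fit$df,
            p_model = sem[[w]]$fit$p)
    }))
    if (!is.null(sem_tab)) emit(sem_tab, "path_models.csv")
    results$sem <- sem
  }

  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "xylemcomp",
    version = as.character(utils::packageVersion("xylemcomp")),
    seed = cfg$seed, ks_mode = cfg$ks_mode,
    rpa_convention = cfg$rpa_convention,
    n_perm = cfg$n_perm, delta_aicc = cfg$delta_aicc,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Partition tips into clade-based groups
#'
#' Stand-in for taxonomic subfamilies when only a tree is available: cuts
#' the cophenetic-distance dendrogram into `n_groups` clusters (a clade
#' partition on an ultrametric tree).
#'
#' @param tree A `phylo`.
#' @param n_groups Number of groups.
#' @return Named character vector (tip -> group label `G1`, `G2`, ...).
#' @export
tree_groups <- function(tree, n_groups = 8L) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = n_groups)
  stats::setNames(paste0("G", cl), names(cl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
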