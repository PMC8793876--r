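#' Synthetic-study configuration
#'
#' Defaults mirror the sampling design the analysis assumes: 28 species in an
#' ultrametric phylogeny, 5 branches per species for vulnerability curves,
#' pit and tracheid anatomy on 3 of those branches with 10 pits each,
#' centrifuge pressure steps starting at -0.8 MPa, and species trait values
#' evolved under Brownian motion with a tunable non-phylogenetic noise
#' fraction. Bounded traits are evolved on a logistic scale so the Brownian
#' covariance structure survives the range constraint. Trait ranges default
#' to the published subfamily extremes (pit membrane diameter 9-15 um, torus
#' overlap 0.27-0.41, margo flexibility 0.45-0.57, wall thickness
#' 2.3-3.0 um, P50 -7.8 to -3.0 MPa, Ks 0.15-0.68 kg m-1 s-1 MPa-1).
#'
#' @param n_species Number of species (tips).
#' @param n_branches_vc Branches per species for vulnerability curves.
#' @param n_branches_anatomy Branches per species for anatomy.
#' @param n_pits Pits measured per anatomy branch.
#' @param birth Yule birth rate for the simulated tree.
#' @param lambda White-noise fraction in [0, 1] for evolved traits (0 = pure
#'   Brownian motion).
#' @param sigma_logit Brownian standard deviation on the logistic scale for
#'   bounded traits.
#' @param cv Multiplicative noise coefficient of variation for conductance
#'   replicates (default 0.05).
#' @param cv_branch Between-branch coefficient of variation on species-level
#'   anatomical dimensions (default 0.02).
#' @param cv_pit Pit-to-pit coefficient of variation (default 0.02).
#' @param p50_range,s_range,ks_range,dpm_range,to_range,mf_range,tw_range,wd_range
#'   Species-level trait ranges (length-2 numeric).
#' @param p50_branch_sd Between-branch standard deviation of P50 (MPa).
#' @param pressure_step `"auto"` (-0.3 MPa decrements for vulnerable species
#'   with P50 above -4 MPa, -0.8 MPa for resistant ones) or a fixed negative
#'   decrement.
#' @param length_m,area_m2 Sample length and sapwood area for the centrifuge
#'   samples.
#' @param td_constant Tracheid density-diameter trade-off constant `c` in
#'   `TD = c / D^2` (um^2 mm^-2).
#' @param seed Master seed (mandatory for dataset emission).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_species = 28L, n_branches_vc = 5L,
                         n_branches_anatomy = 3L, n_pits = 10L,
                         birth = 1, lambda = 0, sigma_logit = 1.2,
                         cv = 0.05, cv_branch = 0.02, cv_pit = 0.02,
                         p50_range = c(-7.8, -3.0), s_range = c(20, 60),
                         ks_range = c(0.15, 0.68),
                         dpm_range = c(9, 15), to_range = c(0.27, 0.41),
                         mf_range = c(0.45, 0.57), tw_range = c(2.3, 3.0),
                         wd_range = c(0.46, 0.60),
                         p50_branch_sd = 0.2, pressure_step = "auto",
                         length_m = 0.27, area_m2 = 1e-5,
                         td_constant = 4.3e5, seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 2L, cfg$n_branches_vc >= 2L,
            cfg$n_branches_anatomy >= 2L, cfg$n_pits >= 2L,
            cfg$lambda >= 0, cfg$lambda <= 1, !is.null(cfg$seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with the requested number of tips, rescaled to unit root
#' depth. Deterministic under the seed.
#'
#' @param n_species Number of tips.
#' @param birth Birth rate.
#' @param seed Integer seed.
#' @return A `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species = 28L, birth = 1, seed = 42L) {
  stopifnot(n_species >= 2L)
  local_rng()
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth, death = 0)
  depth <- mean(tip_depths(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

# one Brownian-motion draw on the tree: MVN(0, sigma2 * V)
simulate_bm <- function(tree, sigma2 = 1) {
  V <- phylo_vcv(tree)
  L <- chol(V + diag(1e-12, nrow(V)))
  drop(sqrt(sigma2) * t(L) %*% stats::rnorm(nrow(V)))
}

#' Simulate species trait values with tunable phylogenetic signal
#'
#' `x = mean + sqrt(1 - lambda) * BM(sigma2) + sqrt(lambda) * iid noise`,
#' with the iid component scaled to the Brownian tip variance so that total
#' variance is `sigma2 * depth` regardless of `lambda`. `lambda = 0` is pure
#' Brownian motion (Blomberg's K near 1 in expectation), `lambda = 1` pure
#' white noise (K near 0).
#'
#' @param tree A rooted `phylo`.
#' @param sigma2 Brownian rate.
#' @param lambda White-noise fraction in [0, 1].
#' @param mean Trait grand mean.
#' @param seed Integer seed.
#' @return Named numeric vector in tip order.
#' @export
simulate_traits <- function(tree, sigma2 = 1, lambda = 0, mean = 0,
                            seed = 42L) {
  stopifnot(lambda >= 0, lambda <= 1)
  local_rng()
  set.seed(seed)
  depth <- base::mean(tip_depths(tree))
  bm <- simulate_bm(tree, sigma2)
  noise <- stats::rnorm(length(bm), sd = sqrt(sigma2 * depth))
  stats::setNames(mean + sqrt(1 - lambda) * bm + sqrt(lambda) * noise,
                  tree$tip.label)
}

# evolve a range-bounded trait: Brownian motion on the logistic scale mapped
# into (lo, hi), preserving phylogenetic covariance without truncation
simulate_bounded_trait <- function(tree, range, sigma_logit = 1.2,
                                   lambda = 0, seed = 42L) {
  z <- simulate_traits(tree, sigma2 = sigma_logit^2, lambda = lambda,
                       mean = 0, seed = seed)
  stats::setNames(range[1L] + diff(range) * stats::plogis(z),
                  tree$tip.label)
}

#' Generate a synthetic centrifuge conductance dataset
#'
#' Species P50 (and sigmoid slope, and target specific conductivity) are
#' evolved on the tree within the configured ranges; each branch gets a
#' jittered P50, pressure steps run from -0.8 MPa in fixed decrements until
#' the true curve passes 99% loss (at least 4 steps), and each step yields 3
#' replicate conductances `kmax * (1 - PLC/100) * (1 + eps)` with
#' multiplicative Gaussian noise of coefficient of variation `cv`.
#'
#' @param tree A `phylo` (typically [simulate_tree()]).
#' @param config A [synth_config()].
#' @return list with `curves` (long data.frame: `branch_id`, `species`,
#'   `pressure_MPa`, `k_rep1..3`, `length_m`, `sapwood_area_m2`) and `truth`
#'   (list with species- and branch-level generating values).
#' @export
generate_cavitron_dataset <- function(tree, config = synth_config()) {
  cfg <- config
  local_rng()
  p50_sp <- simulate_bounded_trait(tree, cfg$p50_range, cfg$sigma_logit,
                                   cfg$lambda,
                                   substream_seed(cfg$seed, "p50"))
  s_sp <- simulate_bounded_trait(tree, cfg$s_range, cfg$sigma_logit,
                                 cfg$lambda, substream_seed(cfg$seed, "slope"))
  ks_sp <- simulate_bounded_trait(tree, cfg$ks_range, cfg$sigma_logit,
                                  cfg$lambda, substream_seed(cfg$seed, "ks"))
  set.seed(substream_seed(cfg$seed, "cavitron-noise"))
  rows <- list()
  branch_truth <- list()
  for (sp in tree$tip.label) {
    step <- if (identical(cfg$pressure_step, "auto")) {
      if (p50_sp[[sp]] > -4) -0.3 else -0.8
    } else as.numeric(cfg$pressure_step)
    for (b in seq_len(cfg$n_branches_vc)) {
      bid <- sprintf("%s_b%d", sp, b)
      p50_b <- p50_sp[[sp]] + stats::rnorm(1, sd = cfg$p50_branch_sd)
      kmax <- cfg$area_m2 * ks_sp[[sp]] / cfg$length_m *
        exp(stats::rnorm(1, sd = 0.1))
      pressures <- -0.8
      repeat {
        last <- utils::tail(pressures, 1)
        if (length(pressures) >= 4L &&
            vc_sigmoid(last, p50_b, s_sp[[sp]]) > 99) break
        if (length(pressures) >= 40L) break
        pressures <- c(pressures, last + step)
      }
      plc_true <- vc_sigmoid(pressures, p50_b, s_sp[[sp]])
      k_true <- kmax * (1 - plc_true / 100)
      reps <- vapply(1:3, function(r) {
        pmax(k_true * (1 + stats::rnorm(length(k_true), sd = cfg$cv)), 0)
      }, numeric(length(k_true)))
      rows[[bid]] <- data.frame(
        branch_id = bid, species = sp, pressure_MPa = pressures,
        k_rep1 = reps[, 1L], k_rep2 = reps[, 2L], k_rep3 = reps[, 3L],
        length_m = cfg$length_m, sapwood_area_m2 = cfg$area_m2,
        stringsAsFactors = FALSE)
      branch_truth[[bid]] <- data.frame(
        branch_id = bid, species = sp, P50_true = p50_b,
        S_true = s_sp[[sp]], kmax_true = kmax, stringsAsFactors = FALSE)
    }
  }
  list(
    curves = do.call(rbind, c(rows, make.row.names = FALSE)),
    truth = list(
      species = data.frame(species = tree$tip.label,
                           P50_true = unname(p50_sp),
                           S_true = unname(s_sp), Ks_true = unname(ks_sp),
                           stringsAsFactors = FALSE),
      branch = do.call(rbind, c(branch_truth, make.row.names = FALSE)),
      cv = cfg$cv, seed = cfg$seed,
      note = "within-species noise levels are synthetic placeholders"))
}

#' Generate synthetic pit, tracheid and wood-density tables
#'
#' Species-level pit membrane diameter, torus overlap, margo flexibility,
#' wall thickness, wood density and earlywood lumen diameter are evolved on
#' the tree within the configured ranges; torus and aperture diameters are
#' built as `DT = DPM * (1 - MF)` and `DPA = DT * (1 - TO)` so the geometric
#' ordering `DPA < DT < DPM` holds by construction. Branch replicates add
#' multiplicative noise (`cv_branch`), pits add pit-level noise (`cv_pit`).
#' Tracheid lumen areas are lognormal; tracheid density follows the
#' `TD = c / D^2` packing trade-off.
#'
#' @param tree A `phylo`.
#' @param config A [synth_config()].
#' @return list with `pits`, `tracheids`, `wood` data.frames (the anatomy
#'   input contract) and `truth` (species-level generating values).
#' @export
generate_anatomy_table <- function(tree, config = synth_config()) {
  cfg <- config
  local_rng()
  if (cfg$to_range[2L] >= 1 || cfg$mf_range[2L] >= 1) {
    stop("TO and MF ranges must stay below 1", call. = FALSE)
  }
  dpm_sp <- simulate_bounded_trait(tree, cfg$dpm_range, cfg$sigma_logit,
                                   cfg$lambda, substream_seed(cfg$seed, "dpm"))
  to_sp <- simulate_bounded_trait(tree, cfg$to_range, cfg$sigma_logit,
                                  cfg$lambda, substream_seed(cfg$seed, "to"))
  mf_sp <- simulate_bounded_trait(tree, cfg$mf_range, cfg$sigma_logit,
                                  cfg$lambda, substream_seed(cfg$seed, "mf"))
  tw_sp <- simulate_bounded_trait(tree, cfg$tw_range, cfg$sigma_logit,
                                  cfg$lambda, substream_seed(cfg$seed, "tw"))
  wd_sp <- simulate_bounded_trait(tree, cfg$wd_range, cfg$sigma_logit,
                                  cfg$lambda, substream_seed(cfg$seed, "wd"))
  dew_sp <- simulate_bounded_trait(tree, c(12, 18), cfg$sigma_logit,
                                   cfg$lambda, substream_seed(cfg$seed, "dew"))
  set.seed(substream_seed(cfg$seed, "anatomy-noise"))
  mnoise <- function(n, cv) 1 + stats::rnorm(n, sd = cv)
  pit_rows <- trach_rows <- list()
  for (sp in tree$tip.label) {
    for (b in seq_len(cfg$n_branches_anatomy)) {
      bid <- sprintf("%s_b%d", sp, b)
      dpm_b <- dpm_sp[[sp]] * mnoise(1, cfg$cv_branch)
      to_b <- to_sp[[sp]] * mnoise(1, cfg$cv_branch)
      mf_b <- mf_sp[[sp]] * mnoise(1, cfg$cv_branch)
      tw_b <- tw_sp[[sp]] * mnoise(1, cfg$cv_branch)
      dpm <- dpm_b * mnoise(cfg$n_pits, cfg$cv_pit)
      dt <- dpm * (1 - mf_b) * mnoise(cfg$n_pits, cfg$cv_pit)
      dpa <- dt * (1 - to_b) * mnoise(cfg$n_pits, cfg$cv_pit)
      pit_rows[[bid]] <- data.frame(
        branch_id = bid, species = sp, DPM_um = dpm, DT_um = dt,
        DPA_um = dpa, stringsAsFactors = FALSE)
      # tracheids: wide earlywood, narrow latewood, plus pooled section
      d_ew <- dew_sp[[sp]] * mnoise(1, cfg$cv_branch)
      d_lw <- 0.55 * d_ew
      zones <- list(
        earlywood = list(n = 220L, d = d_ew, tw = 0.85 * tw_b),
        latewood = list(n = 200L, d = d_lw, tw = 1.30 * tw_b))
      diam <- lapply(zones, function(z) {
        z$d * stats::rlnorm(z$n, meanlog = -0.25^2 / 2, sdlog = 0.25)
      })
      area <- lapply(diam, function(d) pi * d^2 / 4)
      zone_row <- function(zone, areas, tw) {
        d_mean <- mean(diameter_from_area(areas))
        td <- cfg$td_constant / d_mean^2
        data.frame(branch_id = bid, species = sp, zone = zone,
                   lumen_area_um2 = paste(signif(areas, 8), collapse = ";"),
                   section_area_mm2 = length(areas) / td, Tw_um = tw,
                   stringsAsFactors = FALSE)
      }
      trach_rows[[paste0(bid, "_ew")]] <-
        zone_row("earlywood", area$earlywood, zones$earlywood$tw)
      trach_rows[[paste0(bid, "_lw")]] <-
        zone_row("latewood", area$latewood, zones$latewood$tw)
      n_ew <- zones$earlywood$n
      tw_whole <- (n_ew * zones$earlywood$tw +
                     zones$latewood$n * zones$latewood$tw) /
        (n_ew + zones$latewood$n)
      trach_rows[[paste0(bid, "_wh")]] <-
        zone_row("whole", c(area$earlywood, area$latewood), tw_whole)
    }
  }
  wood <- do.call(rbind, lapply(tree$tip.label, function(sp) {
    vol <- stats::runif(5, 8, 12)
    data.frame(species = sp, mass_g = wd_sp[[sp]] * vol * mnoise(5, 0.02),
               volume_cm3 = vol, stringsAsFactors = FALSE)
  }))
  list(
    pits = do.call(rbind, c(pit_rows, make.row.names = FALSE)),
    tracheids = do.call(rbind, c(trach_rows, make.row.names = FALSE)),
    wood = wood,
    truth = data.frame(
      species = tree$tip.label, DPM_true = unname(dpm_sp),
      TO_true = unname(to_sp), MF_true = unname(mf_sp),
      VE_true = unname(to_sp * mf_sp), Tw_true = unname(tw_sp),
      WD_true = unname(wd_sp), D_EW_true = unname(dew_sp),
      stringsAsFactors = FALSE))
}
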