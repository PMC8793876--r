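#' Torus overlap, margo flexibility and valve effect
#'
#' Dimensionless bordered-pit sealing traits from pit membrane (DPM), torus
#' (DT) and aperture (DPA) diameters:
#' `TO = (DT - DPA) / DT`, `MF = (DPM - DT) / DPM`, `VE = TO * MF`.
#' All vectorised.
#'
#' @param DT,DPA,DPM,TO,MF Diameters in micrometres / computed ratios.
#' @return Numeric vector.
#' @name pit_ratios
NULL

#' @rdname pit_ratios
#' @export
torus_overlap <- function(DT, DPA) (DT - DPA) / DT

#' @rdname pit_ratios
#' @export
margo_flexibility <- function(DPM, DT) (DPM - DT) / DPM

#' @rdname pit_ratios
#' @export
valve_effect <- function(TO, MF) TO * MF

#' Pit aperture resistance
#'
#' Hydraulic resistance of the pit aperture: a Poiseuille channel term for
#' flow through the aperture canal of length `T_pa = 0.81 * 2 * Tw` (81% of
#' the double wall thickness) plus an orifice entry term,
#' \deqn{R_{PA} = 128 \, T_{pa} \, \eta / (\pi D_{PA})^4 + 24 \eta / D_{PA}^3}
#' with lengths in m and viscosity in MPa s, so the result is in MPa s m^-3.
#'
#' The default `convention = "as_printed"` raises the *product* `pi * DPA` to
#' the fourth power in the channel term, which is the form that reproduces
#' published species-mean values; the hydrodynamically conventional
#' `pi * DPA^4` denominator (channel term larger by `pi^3`, about 31x) is
#' available as `convention = "conventional"` and does **not** match those
#' published values.
#'
#' @param DPA_um Pit aperture diameter, micrometres (> 0).
#' @param Tw_um Single wall thickness, micrometres (> 0).
#' @param eta_Pa_s Dynamic viscosity of water, Pa s (default 0.001, 20 C).
#' @param convention `"as_printed"` (default) or `"conventional"`.
#' @return Resistance in MPa s m^-3. Vectorised over `DPA_um` and `Tw_um`.
#' @examples
#' pit_aperture_resistance(2.69, 2.57)  # ~1.34e9 MPa s m^-3
#' @export
pit_aperture_resistance <- function(DPA_um, Tw_um, eta_Pa_s = 0.001,
                                    convention = c("as_printed",
                                                   "conventional")) {
  convention <- match.arg(convention)
  if (any(DPA_um <= 0) || any(Tw_um <= 0) || eta_Pa_s < 0) {
    stop("DPA and Tw must be > 0 and eta >= 0", call. = FALSE)
  }
  dpa <- DPA_um * 1e-6             # m
  tpa <- 0.81 * 2 * Tw_um * 1e-6   # m, canal length through one pit border
  eta <- eta_Pa_s * 1e-6           # MPa s
  channel <- if (convention == "as_printed") {
    128 * tpa * eta / (pi * dpa)^4
  } else {
    128 * tpa * eta / (pi * dpa^4)
  }
  channel + 24 * eta / dpa^3
}

#' Derive pit-sealing traits from raw pit geometry
#'
#' Computes TO, MF, VE and pit aperture resistance per pit, flags rows that
#' violate the geometric ordering `DPA < DT < DPM` (these yield TO <= 0 or
#' MF <= 0 and are excluded from means rather than aborting the branch), and
#' averages valid pits per branch.
#'
#' @param pits data.frame with columns `branch_id`, `species`, `DPM_um`,
#'   `DT_um`, `DPA_um` (one row per measured pit; typically 10 per branch).
#' @param Tw_um Single wall thickness per branch: named vector (names =
#'   branch ids) or single value recycled to all branches.
#' @param convention Passed to [pit_aperture_resistance()].
#' @return data.frame with one row per branch: trait means over valid pits,
#'   `n_pits`, `n_excluded`.
#' @export
derive_pit_traits <- function(pits, Tw_um,
                              convention = c("as_printed", "conventional")) {
  convention <- match.arg(convention)
  need <- c("branch_id", "species", "DPM_um", "DT_um", "DPA_um")
  if (!all(need %in% names(pits))) {
    stop("missing columns: ", paste(setdiff(need, names(pits)),
                                    collapse = ", "), call. = FALSE)
  }
  valid <- pits$DPA_um > 0 & pits$DPA_um < pits$DT_um &
    pits$DT_um < pits$DPM_um
  rows <- lapply(split(seq_len(nrow(pits)), pits$branch_id), function(idx) {
    ok <- idx[valid[idx]]
    bid <- pits$branch_id[idx[1L]]
    tw <- if (length(Tw_um) == 1L && is.null(names(Tw_um))) Tw_um
          else unname(Tw_um[as.character(bid)])
    if (is.na(tw)) stop("no wall thickness for branch ", bid, call. = FALSE)
    if (!length(ok)) {
      return(data.frame(branch_id = bid, species = pits$species[idx[1L]],
                        DPM_um = NA_real_, DT_um = NA_real_,
                        DPA_um = NA_real_, TO = NA_real_, MF = NA_real_,
                        VE = NA_real_, RPA_MPa_s_m3 = NA_real_,
                        n_pits = length(idx), n_excluded = length(idx)))
    }
    to <- torus_overlap(pits$DT_um[ok], pits$DPA_um[ok])
    mf <- margo_flexibility(pits$DPM_um[ok], pits$DT_um[ok])
    data.frame(
      branch_id = bid, species = pits$species[idx[1L]],
      DPM_um = mean(pits$DPM_um[ok]), DT_um = mean(pits$DT_um[ok]),
      DPA_um = mean(pits$DPA_um[ok]),
      TO = mean(to), MF = mean(mf), VE = mean(valve_effect(to, mf)),
      RPA_MPa_s_m3 = mean(pit_aperture_resistance(
        pits$DPA_um[ok], tw, convention = convention)),
      n_pits = length(idx), n_excluded = length(idx) - length(ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_excluded > 0)) {
    warning(sum(out$n_excluded),
            " pit(s) violated DPA < DT < DPM and were excluded from means",
            call. = FALSE)
  }
  out
}

#' Hydraulic diameter of a set of tracheids
#'
#' Fourth-root of the mean fourth power of lumen diameters — the
#' Hagen-Poiseuille-weighted mean that reflects conductive capacity. By
#' power-mean inequality, always at least the arithmetic mean diameter.
#'
#' @param diameters_um Lumen diameters, micrometres (> 0), non-empty.
#' @return Dh in micrometres.
#' @examples
#' hydraulic_diameter(c(10, 20))  # 17.07
#' @export
hydraulic_diameter <- function(diameters_um) {
  if (!length(diameters_um)) stop("empty diameter list", call. = FALSE)
  if (any(diameters_um <= 0)) stop("diameters must be > 0", call. = FALSE)
  mean(diameters_um^4)^0.25
}

#' Thickness-to-span ratio
#'
#' Cell-wall reinforcement against implosion: the squared ratio of double
#' wall thickness to lumen diameter, `TSR = (2 * Tw / D)^2`.
#'
#' @param Tw_um Single wall thickness, micrometres (> 0).
#' @param D_um Lumen diameter, micrometres (> 0).
#' @return Dimensionless TSR. Vectorised.
#' @export
thickness_to_span <- function(Tw_um, D_um) {
  if (any(Tw_um <= 0) || any(D_um <= 0)) {
    stop("Tw and D must be > 0", call. = FALSE)
  }
  (2 * Tw_um / D_um)^2
}

#' Lumen diameter from area, assuming a circular section
#'
#' @param area_um2 Lumen areas, square micrometres (> 0).
#' @return Equivalent circular diameters, micrometres.
#' @export
diameter_from_area <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("areas must be > 0", call. = FALSE)
  2 * sqrt(area_um2 / pi)
}

#' Summaries of one tracheid section
#'
#' Mean lumen diameter `D` (from areas, assuming circular sections),
#' tracheid density `TD` (count per mm^2 of section), hydraulic diameter
#' `Dh` and thickness-to-span ratio for one zone of a cross-section
#' (earlywood, latewood or the whole radial section). Trait averaging
#' conventionally requires at least 200 tracheids; smaller sections are
#' summarised but flagged.
#'
#' @param area_um2 Per-tracheid lumen areas (um^2); alternatively give
#'   `diameter_um`.
#' @param diameter_um Per-tracheid lumen diameters (um); ignored when areas
#'   are supplied.
#' @param section_area_mm2 Measured section area, mm^2 (> 0).
#' @param Tw_um Mean single wall thickness for the zone, micrometres.
#' @param zone `"earlywood"`, `"latewood"` or `"whole"`.
#' @param min_count Count below which the summary is flagged (default 200).
#' @return One-row data.frame: `zone`, `D_um`, `Dh_um`, `TD_per_mm2`,
#'   `Tw_um`, `TSR`, `n_tracheids`, `undersampled`.
#' @export
tracheid_summaries <- function(area_um2 = NULL, diameter_um = NULL,
                               section_area_mm2, Tw_um,
                               zone = c("whole", "earlywood", "latewood"),
                               min_count = 200L) {
  zone <- match.arg(zone)
  if (is.null(diameter_um)) {
    if (is.null(area_um2)) stop("need areas or diameters", call. = FALSE)
    diameter_um <- diameter_from_area(area_um2)
  }
  if (section_area_mm2 <= 0) stop("section area must be > 0", call. = FALSE)
  n <- length(diameter_um)
  out <- data.frame(
    zone = zone,
    D_um = mean(diameter_um),
    Dh_um = hydraulic_diameter(diameter_um),
    TD_per_mm2 = n / section_area_mm2,
    Tw_um = Tw_um,
    TSR = thickness_to_span(Tw_um, mean(diameter_um)),
    n_tracheids = n,
    undersampled = n < min_count,
    stringsAsFactors = FALSE
  )
  if (out$undersampled) {
    warning("only ", n, " tracheids in ", zone,
            " section (minimum for averaging is ", min_count, ")",
            call. = FALSE)
  }
  out
}

#' Wood density
#'
#' Oven-dry mass over fresh volume. Values outside the (0.2, 1.2) g cm^-3
#' band that brackets softwoods draw a warning, not an error.
#'
#' @param mass_g Dry mass in grams (> 0).
#' @param volume_cm3 Fresh volume in cm^3 (> 0).
#' @return WD in g cm^-3. Vectorised.
#' @export
wood_density <- function(mass_g, volume_cm3) {
  if (any(mass_g <= 0) || any(volume_cm3 <= 0)) {
    stop("mass and volume must be > 0", call. = FALSE)
  }
  wd <- mass_g / volume_cm3
  if (any(wd <= 0.2 | wd >= 1.2)) {
    warning("wood density outside the (0.2, 1.2) g cm^-3 sanity band",
            call. = FALSE)
  }
  wd
}

#' Build a species trait table from raw anatomy inputs
#'
#' Full anatomy pass: pit traits per branch via [derive_pit_traits()]
#' (earlywood wall thickness feeds the aperture resistance), tracheid
#' summaries per branch and zone via [tracheid_summaries()], wood density per
#' species, then means per species. Aggregation is per-unit trait first, then
#' branch, then species. Columns are unit-suffixed. Whole-section tracheid
#' values (`D_um`, `Dh_um`, `TD_per_mm2`, `Tw_um`, `TSR`) are the headline
#' traits; earlywood and latewood appear with `_E` / `_L` suffixes.
#'
#' @param pits data.frame per pit: `branch_id`, `species`, `DPM_um`,
#'   `DT_um`, `DPA_um`.
#' @param tracheids data.frame per branch x zone: `branch_id`, `species`,
#'   `zone` ("earlywood"/"latewood"/"whole"), `lumen_area_um2`
#'   (semicolon-packed list or one row per tracheid), `section_area_mm2`,
#'   `Tw_um`.
#' @param wood data.frame per sample: `species`, `mass_g`, `volume_cm3`.
#' @param rpa_convention Passed to [pit_aperture_resistance()].
#' @param rpa_tw_zone Which zone's wall thickness enters the aperture
#'   resistance canal length (default `"earlywood"`, where pits are
#'   measured).
#' @return list with `branch` (branch-level table) and `species`
#'   (species-mean trait table ready for the comparative statistics).
#' @export
anatomy_trait_table <- function(pits, tracheids, wood,
                                rpa_convention = c("as_printed",
                                                   "conventional"),
                                rpa_tw_zone = "earlywood") {
  rpa_convention <- match.arg(rpa_convention)
  # per-branch, per-zone tracheid summaries
  key <- interaction(tracheids$branch_id, tracheids$zone, drop = TRUE)
  tsum <- do.call(rbind, lapply(split(tracheids, key), function(tz) {
    areas <- tz$lumen_area_um2
    if (is.character(areas)) {
      areas <- as.numeric(unlist(strsplit(areas, ";", fixed = TRUE)))
    }
    cbind(branch_id = tz$branch_id[1L], species = tz$species[1L],
          tracheid_summaries(area_um2 = areas,
                             section_area_mm2 = tz$section_area_mm2[1L],
                             Tw_um = tz$Tw_um[1L], zone = tz$zone[1L]))
  }))
  rownames(tsum) <- NULL

  tw_zone <- tsum[tsum$zone == rpa_tw_zone, ]
  tw_by_branch <- stats::setNames(tw_zone$Tw_um, tw_zone$branch_id)
  pit_branch <- derive_pit_traits(pits, tw_by_branch,
                                  convention = rpa_convention)

  wide <- function(zone, suffix) {
    z <- tsum[tsum$zone == zone,
              c("branch_id", "D_um", "Dh_um", "TD_per_mm2", "Tw_um", "TSR")]
    names(z)[-1L] <- paste0(names(z)[-1L], suffix)
    z
  }
  branch <- Reduce(function(a, b) merge(a, b, by = "branch_id", all = TRUE),
                   list(pit_branch, wide("whole", ""),
                        wide("earlywood", "_E"), wide("latewood", "_L")))

  sp_traits <- setdiff(names(branch),
                       c("branch_id", "species", "n_pits", "n_excluded"))
  species <- stats::aggregate(branch[, sp_traits],
                              by = list(species = branch$species),
                              FUN = mean, na.rm = TRUE)
  wd <- stats::aggregate(
    list(WD_g_cm3 = wood_density(wood$mass_g, wood$volume_cm3)),
    by = list(species = wood$species), FUN = mean)
  species <- merge(species, wd, by = "species", all.x = TRUE)
  list(branch = branch, species = species)
}
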