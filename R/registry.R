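# Synthetic calibration registry: a literature-style corpus of normalized
# time-course and single-timepoint measurement series covering the
# IFN-gamma, IL-4 and hypoxia arms of the network. The catalog of
# conditions (observable, stimulus, dose, oxygen, sampling grid,
# normalization mode) mirrors the kind of measurement series a literature
# calibration assembles; the values are synthetic, generated from the
# model plus multiplicative lognormal noise, and stand in for digitized
# experimental data.

MW_IFNG <- 17000   # g/mol, dimeric cytokine, rounded
MW_IL4 <- 14000

.tc_grid <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
.tc_long <- c(0, 2, 4, 8, 12, 24, 36, 48)

#' Catalog of calibration conditions for the macrophage model
#'
#' Returns the scenario descriptors (without data values) of the synthetic
#' calibration registry: per dataset an observable, a stimulation scenario
#' (IFN-gamma, IL-4, hypoxia, miR mimics, and combinations at several
#' doses), a sampling grid and a normalization mode. Time-course series
#' cover receptor engagement, STAT phosphorylation, transcription-factor
#' induction and marker expression; single-timepoint series cover
#' endpoint fold changes.
#'
#' @return list of scenario descriptors consumable by
#'   [make_synthetic_datasets()].
#' @export
macrophage_calibration_catalog <- function() {
  ifng <- function(dose, t = 0) mp_stimulus("IFNg", dose, MW_IFNG, time = t)
  il4 <- function(dose, t = 0) mp_stimulus("IL4", dose, MW_IL4, time = t)
  mir93 <- function(copies) mp_stimulus("miR93", copies = copies)
  tcn <- mp_norm("to_max"); t0n <- mp_norm("to_t0")
  entry <- function(id, obs, times, events = list(), oxygen = NULL,
                    norm = tcn, lvl = "protein")
    list(id = id, observable = obs, times = times, events = events,
         oxygen = oxygen, normalization = norm, level = lvl,
         horizon = max(times, 1))
  cat1 <- list()
  add <- function(e) cat1[[length(cat1) + 1L]] <<- e

  ## IFN-gamma arm: time courses at several doses ----------------------
  for (d in c(1, 10, 50)) {
    add(entry(sprintf("ifng%02d_boundlig", d), "R_I_lig", .tc_grid,
              list(ifng(d))))
    add(entry(sprintf("ifng%02d_pjak", d), "R_I_act", .tc_grid,
              list(ifng(d))))
    add(entry(sprintf("ifng%02d_pstat1", d), "pSTAT1d_n", .tc_grid,
              list(ifng(d))))
    add(entry(sprintf("ifng%02d_irf1", d), "IRF1", .tc_long,
              list(ifng(d))))
    add(entry(sprintf("ifng%02d_inos", d), "iNOS", .tc_long,
              list(ifng(d))))
  }
  add(entry("ifng10_tnfa", "TNFa", .tc_long, list(ifng(10)), norm = t0n))
  add(entry("ifng10_il12", "IL12", .tc_long, list(ifng(10))))
  add(entry("ifng10_cxcl9", "CXCL9", .tc_long, list(ifng(10))))
  add(entry("ifng10_cxcl10", "CXCL10_mRNA", .tc_grid, list(ifng(10)),
            lvl = "mRNA"))
  add(entry("ifng10_mir3473b", "miR3473b", .tc_long, list(ifng(10)),
            lvl = "miR"))
  add(entry("ifng10_socs1", "SOCS1", .tc_grid, list(ifng(10))))
  add(entry("ifng10_socs3", "SOCS3", .tc_grid, list(ifng(10))))
  add(entry("ifng10_irf9", "IRF9", .tc_long, list(ifng(10))))
  add(entry("ifng10_itaconate18h", "ITA", c(0, 18), list(ifng(10)),
            norm = mp_norm("to_reference_time", 18), lvl = "metabolite"))
  add(entry("ifng10_pten36h", "PTEN", c(0, 36), list(ifng(10)),
            norm = t0n))
  add(entry("mir3473bmimic_pten36h", "PTEN", c(0, 36),
            list(mp_stimulus("miR3473b", copies = 2e4)), norm = t0n))
  add(entry("ifng10_hif1a", "HIF1a", .tc_long, list(ifng(10)), norm = t0n))
  add(entry("ifng10hyp_hif1a", "HIF1a", .tc_long, list(ifng(10)),
            oxygen = mp_oxygen(2)))
  add(entry("ifng10_pakt24h", "pAKT", c(0, 24), list(ifng(10)),
            norm = t0n))

  ## IL-4 arm -----------------------------------------------------------
  for (d in c(5, 10, 20)) {
    add(entry(sprintf("il4%02d_pstat6", d), "pSTAT6d_n", .tc_grid,
              list(il4(d))))
    add(entry(sprintf("il4%02d_arg1", d), "Arg1", .tc_long,
              list(il4(d))))
  }
  add(entry("il410_irf4", "IRF4", .tc_long, list(il4(10))))
  add(entry("il410_irf4_24h", "IRF4", c(0, 24), list(il4(10)), norm = t0n))
  add(entry("il410_pakt", "pAKT", .tc_grid, list(il4(10))))
  add(entry("il410_pparg18h", "PPARg", c(0, 18), list(il4(10)),
            norm = t0n))
  add(entry("il410_arg1_24h", "Arg1", c(0, 24), list(il4(10)), norm = t0n))
  add(entry("il410_il10_24h", "IL10", c(0, 24), list(il4(10)), norm = t0n))
  add(entry("il410_vegf_24h", "VEGF", c(0, 24), list(il4(10)), norm = t0n))
  add(entry("il410_tnfa_24h", "TNFa", c(0, 24), list(il4(10)), norm = t0n))
  add(entry("il410_socs1", "SOCS1", .tc_grid, list(il4(10))))
  add(entry("il410_hif2a", "HIF2a", .tc_long, list(il4(10)), norm = t0n))
  add(entry("il410hyp_hif2a", "HIF2a", .tc_long, list(il4(10)),
            oxygen = mp_oxygen(2)))
  add(entry("il410_irf1_24h", "IRF1", c(0, 24), list(il4(10)), norm = t0n))

  ## hypoxia arm ---------------------------------------------------------
  add(entry("hyp3_hif1a", "HIF1a", .tc_grid, oxygen = mp_oxygen(3)))
  add(entry("hyp3_hif2a", "HIF2a", .tc_grid, oxygen = mp_oxygen(3)))
  add(entry("hyp05_hif1a_24h", "HIF1a", c(0, 24),
            oxygen = mp_oxygen(0.5),
            norm = mp_norm("to_reference_time", 24)))
  add(entry("hyp05_hif2a_24h", "HIF2a", c(0, 24),
            oxygen = mp_oxygen(0.5),
            norm = mp_norm("to_reference_time", 24)))
  add(entry("hyp1_inos_8h", "iNOS", c(0, 8), oxygen = mp_oxygen(1),
            norm = t0n))
  add(entry("hyp1_arg1_8h", "Arg1", c(0, 8), oxygen = mp_oxygen(1),
            norm = t0n))
  add(entry("hyp03_tnfa_24h", "TNFa", c(0, 24), oxygen = mp_oxygen(0.3),
            norm = t0n))
  add(entry("hyp1_ifng", "IFNg", .tc_long, oxygen = mp_oxygen(1),
            norm = t0n))
  add(entry("hyp1_vegf_24h", "VEGF", c(0, 24), oxygen = mp_oxygen(1),
            norm = t0n))
  add(entry("hyp2_mir93_12h", "miR93", c(0, 12), oxygen = mp_oxygen(2),
            norm = t0n, lvl = "miR"))
  add(entry("hyp2mimic_ifng_12h", "IFNg", c(0, 12),
            list(mir93(2e4)), oxygen = mp_oxygen(2), norm = t0n))
  add(entry("hyp2mimic_tnfa_12h", "TNFa", c(0, 12),
            list(mir93(2e4)), oxygen = mp_oxygen(2), norm = t0n))
  add(entry("hyp2mimic_irf9", "IRF9", .tc_long, list(mir93(2e4)),
            oxygen = mp_oxygen(2), norm = t0n))
  add(entry("hyp2mimic_irg1", "IRG1", .tc_long, list(mir93(2e4)),
            oxygen = mp_oxygen(2), norm = t0n))
  add(entry("hyp2_irf1", "IRF1", .tc_long, oxygen = mp_oxygen(2),
            norm = t0n))
  add(entry("hyp2_irf9", "IRF9", .tc_long, oxygen = mp_oxygen(2),
            norm = t0n))
  add(entry("hyp2_irg1", "IRG1", .tc_long, oxygen = mp_oxygen(2),
            norm = t0n))
  add(entry("hyp2_phd", "PHD", .tc_long, oxygen = mp_oxygen(2),
            norm = t0n))
  add(entry("hyp2_ita", "ITA", .tc_long, oxygen = mp_oxygen(2),
            norm = t0n, lvl = "metabolite"))

  ## combined stimulation ------------------------------------------------
  add(entry("ifng10_il4_20_4h_irf1", "IRF1", .tc_long,
            list(ifng(10), il4(20, 4)), norm = t0n))
  add(entry("il410_ifng20_1h_pakt", "pAKT", .tc_long,
            list(il4(10), ifng(20, 1)), norm = t0n))
  add(entry("costim_inos", "iNOS", .tc_long,
            list(ifng(10), il4(5)), norm = t0n))
  add(entry("costim_arg1", "Arg1", .tc_long,
            list(ifng(10), il4(5)), norm = t0n))
  add(entry("costim_tnfa", "TNFa", .tc_long,
            list(ifng(10), il4(5)), norm = t0n))
  add(entry("costim_il10", "IL10", .tc_long,
            list(ifng(10), il4(5)), norm = t0n))
  cat1
}

#' Build the synthetic calibration registry
#'
#' Generates the full registry from the condition catalog by simulating
#' the model and applying multiplicative lognormal measurement noise. The
#' corpus covers all three pathway arms with more than 70 datasets and
#' more than 300 data points.
#'
#' @param model the model to sample from (default [macrophage_model()]).
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param seed integer seed.
#' @return list of `mp_dataset` objects (attribute `levels` records each
#'   dataset's reported level: protein, mRNA, miR or metabolite).
#' @export
macrophage_registry <- function(model = macrophage_model(),
                                noise_cv = 0.1, seed = 42) {
  cat1 <- macrophage_calibration_catalog()
  ds <- make_synthetic_datasets(model, cat1, noise_cv = noise_cv,
                                seed = seed)
  for (i in seq_along(ds)) ds[[i]]$source <- "synthetic"
  attr(ds, "levels") <- vapply(cat1, `[[`, "", "level")
  ds
}

#' Tabulate a dataset registry (one row per point)
#'
#' @param datasets list of `mp_dataset` objects.
#' @return `data.frame` with dataset metadata and point values, suitable
#'   for TSV export (mirrors a calibration-source summary table).
#' @export
registry_table <- function(datasets) {
  do.call(rbind, lapply(datasets, function(d) {
    ev <- if (length(d$events))
      paste(vapply(d$events, function(e)
        sprintf("%s:%g@%gh", e$ligand, e$copies, e$time), ""),
        collapse = ";") else ""
    data.frame(dataset = d$id, observable = d$observable,
               stimulus = ev,
               oxygen_pct = if (!is.null(d$oxygen)) d$oxygen$percent else 21,
               normalization = d$normalization$mode,
               weight = d$weight, source = d$source,
               time = d$points$time, value = d$points$value,
               stringsAsFactors = FALSE)
  }))
}
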