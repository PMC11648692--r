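#' Default 40-predictor volume schema
#'
#' The analysis-ready feature table carries 40 regional brain-volume
#' predictors: 39 bilateral (left+right merged) volumes -- the 34 Desikan
#' cortical parcels plus five subcortical segmentation structures -- and the
#' whole-brain segmentation volume without ventricles (BrainSegVolNotVent).
#' Subcortical (aseg) names keep their hyphenated FreeSurfer spelling;
#' cortical (aparc) names are lower-case without hemisphere prefix.
#'
#' @return Character vector of the 40 canonical region names.
#' @export
default_schema <- function() {
  c(
    # aseg structures (merged left+right)
    "Lateral-Ventricle", "Inf-Lat-Vent", "Hippocampus", "Amygdala",
    "Accumbens-area",
    # Desikan cortical parcels (merged lh+rh)
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal",
    # global measure, passed through unmerged
    "BrainSegVolNotVent"
  )
}

#' Regions carrying a group (atrophy/enlargement) effect by default
#'
#' The eight regions that discriminate stable from converting healthy elders
#' in the reference cohort analysis: ventricular enlargement (Lateral
#' Ventricle, Inf-Lat-Vent) and atrophy of the hippocampus, accumbens area,
#' entorhinal, lateral orbitofrontal and middle temporal cortex, plus global
#' brain-volume loss (BrainSegVolNotVent).
#'
#' @return Character vector of 8 region names.
#' @export
default_effect_regions <- function() {
  c("Lateral-Ventricle", "Inf-Lat-Vent", "Hippocampus", "Accumbens-area",
    "entorhinal", "lateralorbitofrontal", "middletemporal",
    "BrainSegVolNotVent")
}

# Reference marginal moments (mm^3) per region in stable healthy elders aged
# 60-86, and the additive group effect (converter minus stable mean) planted
# in the eight effect regions. The eight effect rows use the published
# ADNI-cohort means/SDs; remaining rows are typical FreeSurfer bilateral
# volumes for this age band.
#
# resid_frac is the fraction of marginal variance left after removing age,
# sex and ICV. For the effect regions it is derived from the reference
# cohort's harmonized one-way-ANOVA p-values at n = (97, 24), which pin
# down the post-harmonization effect size d = t * sqrt(1/97 + 1/24) and
# hence the residual SD = |effect| / d; regions whose implied residual SD
# exceeds what the marginal SD allows are capped so the ICV correlation
# stays >= 0.2. Non-effect regions get the generic split (NA here).
region_effect_resid_frac <- function() {
  c("Lateral-Ventricle" = 0.66,     # capped: implied d exceeds marginal
    "Inf-Lat-Vent" = 0.66,          # capped
    "Hippocampus" = 0.4820,         # p = 0.005
    "Accumbens-area" = 0.86,        # capped (implied frac > 1)
    "entorhinal" = 0.2524,          # p = 0.007
    "lateralorbitofrontal" = 0.2336, # p = 0.002
    "middletemporal" = 0.1779,      # p = 0.012
    "BrainSegVolNotVent" = 0.0330)  # p < 0.001
}

region_reference_stats <- function() {
  s <- rbind(
    data.frame(region = "Lateral-Ventricle", hc_mean = 32077.74, hc_sd = 15998.18, uhc_effect = 50914.57 - 32077.74),
    data.frame(region = "Inf-Lat-Vent",      hc_mean = 1165.48,  hc_sd = 672.08,   uhc_effect = 2163.08 - 1165.48),
    data.frame(region = "Hippocampus",       hc_mean = 7592.62,  hc_sd = 837.74,   uhc_effect = 7213.36 - 7592.62),
    data.frame(region = "Amygdala",          hc_mean = 3122.47,  hc_sd = 430.58,   uhc_effect = 0),
    data.frame(region = "Accumbens-area",    hc_mean = 900.29,   hc_sd = 165.10,   uhc_effect = 761.66 - 900.29),
    data.frame(region = "bankssts",          hc_mean = 5100,     hc_sd = 750,      uhc_effect = 0),
    data.frame(region = "caudalanteriorcingulate", hc_mean = 3900, hc_sd = 700,    uhc_effect = 0),
    data.frame(region = "caudalmiddlefrontal", hc_mean = 12500,  hc_sd = 1900,     uhc_effect = 0),
    data.frame(region = "cuneus",            hc_mean = 6600,     hc_sd = 950,      uhc_effect = 0),
    data.frame(region = "entorhinal",        hc_mean = 3582.20,  hc_sd = 648.10,   uhc_effect = 3378.46 - 3582.20),
    data.frame(region = "frontalpole",       hc_mean = 1600,     hc_sd = 280,      uhc_effect = 0),
    data.frame(region = "fusiform",          hc_mean = 17451.08, hc_sd = 2175.02,  uhc_effect = 0),
    data.frame(region = "inferiorparietal",  hc_mean = 24800,    hc_sd = 3000,     uhc_effect = 0),
    data.frame(region = "inferiortemporal",  hc_mean = 19404.56, hc_sd = 2752.38,  uhc_effect = 0),
    data.frame(region = "insula",            hc_mean = 13042.72, hc_sd = 1545.59,  uhc_effect = 0),
    data.frame(region = "isthmuscingulate",  hc_mean = 4657.37,  hc_sd = 687.63,   uhc_effect = 0),
    data.frame(region = "lateraloccipital",  hc_mean = 22500,    hc_sd = 2800,     uhc_effect = 0),
    data.frame(region = "lateralorbitofrontal", hc_mean = 13717.41, hc_sd = 1373.75, uhc_effect = 13239.04 - 13717.41),
    data.frame(region = "lingual",           hc_mean = 12500,    hc_sd = 1700,     uhc_effect = 0),
    data.frame(region = "medialorbitofrontal", hc_mean = 10102.50, hc_sd = 1158.77, uhc_effect = 0),
    data.frame(region = "middletemporal",    hc_mean = 20807.65, hc_sd = 2386.15,  uhc_effect = 20222.25 - 20807.65),
    data.frame(region = "paracentral",       hc_mean = 7100,     hc_sd = 950,      uhc_effect = 0),
    data.frame(region = "parahippocampal",   hc_mean = 3791.19,  hc_sd = 516.83,   uhc_effect = 0),
    data.frame(region = "parsopercularis",   hc_mean = 8900,     hc_sd = 1200,     uhc_effect = 0),
    data.frame(region = "parsorbitalis",     hc_mean = 4500,     hc_sd = 650,      uhc_effect = 0),
    data.frame(region = "parstriangularis",  hc_mean = 7400,     hc_sd = 1100,     uhc_effect = 0),
    data.frame(region = "pericalcarine",     hc_mean = 4300,     hc_sd = 700,      uhc_effect = 0),
    data.frame(region = "postcentral",       hc_mean = 20300,    hc_sd = 2400,     uhc_effect = 0),
    data.frame(region = "posteriorcingulate", hc_mean = 6100,    hc_sd = 800,      uhc_effect = 0),
    data.frame(region = "precentral",        hc_mean = 26000,    hc_sd = 2900,     uhc_effect = 0),
    data.frame(region = "precuneus",         hc_mean = 18600,    hc_sd = 2100,     uhc_effect = 0),
    data.frame(region = "rostralanteriorcingulate", hc_mean = 5000, hc_sd = 800,   uhc_effect = 0),
    data.frame(region = "rostralmiddlefrontal", hc_mean = 31500, hc_sd = 4000,     uhc_effect = 0),
    data.frame(region = "superiorfrontal",   hc_mean = 44000,    hc_sd = 4800,     uhc_effect = 0),
    data.frame(region = "superiorparietal",  hc_mean = 25800,    hc_sd = 3000,     uhc_effect = 0),
    data.frame(region = "superiortemporal",  hc_mean = 21659.54, hc_sd = 2508.39,  uhc_effect = 0),
    data.frame(region = "supramarginal",     hc_mean = 20900,    hc_sd = 2600,     uhc_effect = 0),
    data.frame(region = "temporalpole",      hc_mean = 4400,     hc_sd = 600,      uhc_effect = 0),
    data.frame(region = "transversetemporal", hc_mean = 2300,    hc_sd = 350,      uhc_effect = 0),
    data.frame(region = "BrainSegVolNotVent", hc_mean = 1025466.82, hc_sd = 103015.64, uhc_effect = 1011076.79 - 1025466.82)
  )
  rownames(s) <- NULL
  s
}
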