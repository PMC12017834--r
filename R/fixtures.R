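# Published summary values for the Mt Etna caves study region, packaged as
# fixtures: the dating summary table for the two sediment samples, the
# open-system U-Th transect ages for the fossil teeth, and the printed
# vegetation-baseline and specimen 87Sr/86Sr means. Only published numbers
# appear here; synthetic scenarios that flesh these out live in synthetic.R.

#' Mt Etna TT-OSL dating summary (published values)
#'
#' Dose-rate components (Gy/ka, +/- 1 sigma), grain counts, overdispersion,
#' CAM equivalent doses and ages for the two dated sediment samples.
#'
#' @return Data frame, one row per sample.
#' @export
mt_etna_dose_rates <- function() {
  data.frame(
    sample = c("MTE17-1", "MTE17-4"),
    unit = c("QML1311C/D", "QML1311H"),
    grain_um_min = c(180, 180), grain_um_max = c(250, 250),
    water_present = c(5, 16), water_longterm = c(20, 16),
    beta = c(0.50, 0.71), beta_se = c(0.03, 0.04),
    gamma = c(0.42, 0.49), gamma_se = c(0.02, 0.02),
    cosmic = c(0.01, 0.01), cosmic_se = c(0.01, 0.01),
    internal = c(0.03, 0.03), internal_se = c(0.01, 0.01),
    total = c(0.95, 1.23), total_se = c(0.06, 0.07),
    n_accepted = c(40, 27), n_measured = c(500, 500),
    od_pct = c(30, 3), od_pct_se = c(7, 3),
    de_gy = c(277.4, 375.5), de_se_gy = c(19.3, 23.2),
    age_ka = c(291.5, 304.2), age_se_ka = c(28.3, 26.1)
  )
}

#' Mt Etna open-system U-Th transect ages (published values)
#'
#' Per-transect open-system ages (ka) with asymmetric 2SD bounds; the
#' WIGL8546_1 transect is flagged excluded (anomalously old with a large
#' error).
#'
#' @return Data frame, one row per transect.
#' @export
mt_etna_useries_ages <- function() {
  data.frame(
    tooth = c("WIGL8543", "WIGL8543", "WIGL8544", "WIGL8544", "WIGL8545",
              "WIGL8545", "WIGL8546", "WIGL8546", "WIGL8547", "WIGL8547",
              "WIGL8548", "WIGL8548", "WIGL8549", "WIGL8549", "WIGL8550",
              "WIGL8550"),
    transect = rep(1:2, 8),
    unit = c(rep("QML1311H", 8), rep("QML1384LU", 4), rep("QML1311C/D", 4)),
    tooth_type = c(rep("Molar", 12), "Incisor", "Incisor", "Molar", "Molar"),
    age_ka = c(234, 255, 212, 208, 230, 245, 480, 260,
               264, 291, 228, 213, 240, 211, 271, 285),
    plus_2sd = c(9, 50, 19, 17, 20, 23, 190, 5, 12, 29, 29, 13, 5, 6, 35, 27),
    minus_2sd = c(6, 15, 21, 16, 17, 18, 140, 20, 14, 30, 25, 9, 6, 4, 30, 23),
    excluded = c(rep(FALSE, 6), TRUE, rep(FALSE, 9))
  )
}

#' Mt Etna bioavailable-Sr vegetation baseline (published means)
#'
#' Mean 87Sr/86Sr (+/- 2SE) of plant samples per geological unit around the
#' site; 24 samples over 11 units. The Mount Alma Formation limestone and
#' the broader Mount Alma Formation are the local units.
#'
#' @return Baseline data frame in the [build_baseline()] layout.
#' @export
mt_etna_sr_baseline <- function() {
  b <- data.frame(
    unit = c("Mount Alma Formation limestone", "Mount Alma Formation",
             "Mount Hedlow Trachyte", "Serpentinite", "Ellrott Rhyolite",
             "Lakes Creek Formation", "Rockhampton Group",
             "Alton Downs Basalt", "Chalmers Formation",
             "Quaternary Alluvium", "Permian to Triassic Gabbro"),
    mean_87_86 = c(0.708514, 0.708138, 0.709240, 0.709102, 0.708443,
                   0.709549, 0.705858, 0.706728, 0.706395, 0.706292,
                   0.706839),
    two_se = c(0.000348, 0.000572, 0.000311, 0.000014, 0.000007,
               0.000006, 0.000081, 0.000022, 0.000014, 0.000883,
               0.000008),
    n = c(4, 6, 2, 1, 1, 1, 2, 1, 1, 4, 1)
  )
  b$local <- b$unit %in% c("Mount Alma Formation limestone", "Mount Alma Formation")
  b$range_unknown <- b$n == 1
  b
}

#' Mt Etna specimen 87Sr/86Sr summaries (published means)
#'
#' Overall mean 87Sr/86Sr (+/- 2SE) for the four fossil teeth whose
#' specimen-level means are published, with their stratigraphic units.
#'
#' @return Data frame, one row per specimen.
#' @export
mt_etna_specimens <- function() {
  data.frame(
    tooth = c("WIGL8547", "WIGL8548", "WIGL8549", "WIGL8550"),
    unit = c("QML1384LU", "QML1384LU", "QML1311C/D", "QML1311C/D"),
    mean_87_86 = c(0.707841, 0.708105, 0.707820, 0.706855),
    two_se = c(0.000136, 0.000058, 0.000113, 0.000020)
  )
}
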