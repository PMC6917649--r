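#' Default analyte catalogue
#'
#' One row per quantified analyte: hop cone prenylchalcones (370 nm channel),
#' cone alpha and beta bitter acids (320 nm), and leaf flavonol glycosides
#' (350 nm). Flavonol retention times and absorbance maxima are the published
#' values for this chromatographic method; cone-compound retention times
#' follow the elution order seen on the 8-minute gradient (DXH < XGA < XHU <
#' MXH at 370 nm; COH < n+ADH < COL < n+ADL at 320 nm), since exact values
#' are method constants rather than results.
#'
#' Compound codes: XHU xanthohumol, DXH desmethylxanthohumol, XGA
#' xanthogalenol, MXH 4'-O-methylxanthohumol; COH cohumulone, nADH
#' humulone + adhumulone, COL colupulone, nADL lupulone + adlupulone;
#' Qrut/Qglc/Qmal quercetin-3-O-rutinoside/-glucoside/-(6''-O-malonyl)-
#' glucoside, Krut/Kglc/Kmal the kaempferol analogues.
#'
#' @return A data.frame with columns `compound_id`, `compound`, `tissue`,
#'   `class`, `channel_nm`, `rt_min`, `lambda_max_nm`.
#' @export
default_catalog <- function() {
  data.frame(
    compound_id = c("DXH", "XGA", "XHU", "MXH",
                    "COH", "nADH", "COL", "nADL",
                    "Qrut", "Qglc", "Krut", "Qmal", "Kglc", "Kmal"),
    compound = c("desmethylxanthohumol", "xanthogalenol", "xanthohumol",
                 "4'-O-methylxanthohumol",
                 "cohumulone", "humulone+adhumulone",
                 "colupulone", "lupulone+adlupulone",
                 "quercetin-3-O-rutinoside", "quercetin-3-O-glucoside",
                 "kaempferol-3-O-rutinoside",
                 "quercetin-3-O-(6''-O-malonyl)-glucoside",
                 "kaempferol-3-O-glucoside",
                 "kaempferol-3-O-(6''-O-malonyl)-glucoside"),
    tissue = c(rep("cone", 8), rep("leaf", 6)),
    class = c(rep("prenylchalcone", 4), "alpha_acid", "alpha_acid",
              "beta_acid", "beta_acid", rep("flavonol", 6)),
    channel_nm = c(rep(370, 4), rep(320, 4), rep(350, 6)),
    rt_min = c(2.10, 2.60, 3.10, 3.60,
               4.40, 4.80, 5.40, 5.80,
               3.83, 3.96, 4.18, 4.20, 4.30, 4.60),
    lambda_max_nm = c(rep(368, 4), rep(325, 4),
                      354, 354, 347, 354, 348, 348),
    stringsAsFactors = FALSE
  )
}

#' Detector response factor for a quantitation channel
#'
#' Single response factor per channel (area in mAU min per mg/ml), matching
#' the equivalents convention: all prenylchalcones are quantified as
#' xanthohumol equivalents and all flavonols as quercetin-3-O-rutinoside
#' equivalents, so compounds sharing a channel share a response factor.
#'
#' @param channel_nm Quantitation wavelength (320, 350 or 370 nm).
#' @return Response factor, mAU min per (mg/ml).
#' @export
channel_response_factor <- function(channel_nm) {
  rf <- c("320" = 1400, "350" = 1600, "370" = 1500)
  key <- as.character(channel_nm)
  if (!key %in% names(rf)) {
    stop("no response factor defined for channel ", channel_nm, " nm")
  }
  unname(rf[key])
}

#' ICE-3 bitter-acid calibration standard
#'
#' International Calibration Extract 3: a reference hop extract with defined
#' mass fractions (w/w) of the four quantified bitter-acid analytes, used for
#' single-point response-factor calibration at 320 nm.
#'
#' @param total_mg_ml Total concentration the standard is prepared at (mg/ml).
#' @return List with `fractions` (named, w/w) and `total_mg_ml`.
#' @export
ice3_composition <- function(total_mg_ml = 1) {
  stopifnot(is.finite(total_mg_ml), total_mg_ml > 0)
  list(
    fractions = c(COH = 0.1388, nADH = 0.3076, COL = 0.1344, nADL = 0.1084),
    total_mg_ml = total_mg_ml
  )
}

#' Default extraction record for a tissue and channel
#'
#' Cones: 0.5 g powdered cones extracted twice into 25 ml (50 ml pooled).
#' The abundant bitter acids (320 nm) are read from a 4-fold dilution so
#' they stay on scale, while the prenylchalcone channel (370 nm) uses the
#' neat extract so the trace markers XGA/MXH fall inside the calibrated
#' range. Leaves: ~200 mg extracted twice into 5 ml (10 ml pooled), neat.
#'
#' @param tissue "cone" or "leaf".
#' @param channel_nm Quantitation channel (decides the cone dilution).
#' @return List with `sample_mass_mg`, `extract_volume_ml`, `dilution_factor`.
#' @export
default_extraction <- function(tissue = c("cone", "leaf"), channel_nm = NA) {
  tissue <- match.arg(tissue)
  if (tissue == "cone") {
    dil <- if (!is.na(channel_nm) && channel_nm == 320) 4 else 1
    extraction_record(500, 50, dil)
  } else {
    extraction_record(200, 10, 1)
  }
}

#' Construct an extraction record
#'
#' @param sample_mass_mg Dry sample mass extracted, mg.
#' @param extract_volume_ml Total pooled extract volume, ml.
#' @param dilution_factor Dilution applied before injection (>= 1 typical).
#' @return List of the three validated fields.
#' @export
extraction_record <- function(sample_mass_mg, extract_volume_ml,
                              dilution_factor = 1) {
  vals <- c(sample_mass_mg, extract_volume_ml, dilution_factor)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("extraction record fields must all be strictly positive")
  }
  list(sample_mass_mg = sample_mass_mg,
       extract_volume_ml = extract_volume_ml,
       dilution_factor = dilution_factor)
}
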