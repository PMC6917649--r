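# Peak detection, baseline-aware integration, calibration and conversion of
# areas to percent dry weight.

#' Construct a chromatogram object
#'
#' @param time_min Strictly increasing time axis, minutes (>= 2 samples).
#' @param absorbance_mau Finite absorbance values, mAU.
#' @param channel_nm Detection wavelength.
#' @param metadata Named character metadata.
#' @return A list of class `hop_chromatogram`.
#' @export
as_chromatogram <- function(time_min, absorbance_mau, channel_nm = NA,
                            metadata = character()) {
  if (length(time_min) < 2 || length(time_min) != length(absorbance_mau)) {
    stop("a chromatogram needs >= 2 (time, absorbance) samples")
  }
  if (any(diff(time_min) <= 0)) stop("time axis must be strictly increasing")
  if (any(!is.finite(absorbance_mau))) stop("absorbances must be finite")
  structure(list(time_min = as.numeric(time_min),
                 absorbance_mau = as.numeric(absorbance_mau),
                 channel_nm = channel_nm, metadata = metadata),
            class = "hop_chromatogram")
}

moving_average <- function(y, k) {
  if (k <= 1) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- y[is.na(s)]  # keep raw values at the edges
  s
}

#' Detect peaks in a chromatogram
#'
#' Local maxima of the (lightly smoothed) trace rising at least `min_height`
#' above the baseline estimate (trace median) with topographic prominence of
#' at least `min_prominence`. Each peak gets an integration window delimited
#' by the flanking signal minima (valley between neighbouring peaks, or the
#' minimum towards the trace end), clipped to `max_halfwidth_min` around the
#' apex so windows stay tight on flat baseline stretches. Windows are
#' disjoint and peaks are ordered by apex time.
#'
#' @param chrom A `hop_chromatogram` with >= 3 samples.
#' @param min_height Minimum apex height above baseline, mAU.
#' @param min_prominence Minimum topographic prominence, mAU.
#' @param smooth_pts Moving-average width in samples (odd; 1 = none).
#' @param max_halfwidth_min Maximum window half-width, minutes.
#' @return data.frame: `apex_time`, `apex_index`, `height`, `prominence`,
#'   `window_start`, `window_end` (one row per peak; empty if none).
#' @export
detect_peaks <- function(chrom, min_height = 5, min_prominence = 3,
                         smooth_pts = 9, max_halfwidth_min = 0.15) {
  stopifnot(inherits(chrom, "hop_chromatogram"))
  t <- chrom$time_min
  y <- chrom$absorbance_mau
  if (length(t) < 3) stop("peak detection needs at least 3 samples")
  s <- moving_average(y, smooth_pts)
  base <- median(s)
  n <- length(s)
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  cand <- cand[s[cand] - base >= min_height]
  if (length(cand) == 0) return(empty_peaks())

  prom <- vapply(cand, function(i) {
    left <- s[seq_len(i - 1)]
    higher_l <- which(left > s[i])
    lmin <- if (length(higher_l) > 0) {
      min(s[(max(higher_l) + 1):(i - 1)])
    } else min(left)
    right <- s[(i + 1):n]
    higher_r <- which(right > s[i])
    rmin <- if (length(higher_r) > 0) {
      min(s[(i + 1):(i + min(higher_r) - 1)])
    } else min(right)
    s[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0) return(empty_peaks())

  ord <- order(cand)
  cand <- cand[ord]
  prom <- prom[ord]
  k <- length(cand)
  lo <- integer(k)
  hi <- integer(k)
  for (j in seq_len(k)) {
    left_lim <- if (j == 1) 1L else cand[j - 1]
    right_lim <- if (j == k) n else cand[j + 1]
    seg_l <- left_lim:cand[j]
    seg_r <- cand[j]:right_lim
    lo[j] <- seg_l[which.min(s[seg_l])]
    hi[j] <- seg_r[which.min(s[seg_r])]
    # clip long flat stretches to a fixed half-width around the apex
    lo[j] <- max(lo[j], which.min(abs(t - (t[cand[j]] - max_halfwidth_min))))
    hi[j] <- min(hi[j], which.min(abs(t - (t[cand[j]] + max_halfwidth_min))))
  }
  # partially-resolved neighbours share an (unclipped) valley boundary;
  # chain them into clusters so integration can drop-line from cluster edges
  cluster <- integer(k)
  cluster[1] <- 1L
  if (k > 1) {
    for (j in 2:k) {
      linked <- hi[j - 1] == lo[j]
      cluster[j] <- if (linked) cluster[j - 1] else cluster[j - 1] + 1L
    }
  }
  data.frame(apex_time = t[cand], apex_index = cand,
             height = s[cand] - base, prominence = prom,
             window_start = t[lo], window_end = t[hi], cluster = cluster)
}

empty_peaks <- function() {
  data.frame(apex_time = numeric(), apex_index = integer(),
             height = numeric(), prominence = numeric(),
             window_start = numeric(), window_end = numeric(),
             cluster = integer())
}

#' Integrate a peak window
#'
#' Trapezoidal integral of (signal - baseline) over the window. Baseline is
#' either zero or the straight line joining the signal values at the window
#' endpoints (`linear_endpoints`, the default elsewhere in the pipeline,
#' which removes constant offsets exactly). Negative results are clipped to
#' zero.
#'
#' For peaks that are part of a partially-resolved cluster, `anchor` places
#' the baseline anchor points at the cluster edges instead of the peak's own
#' valley boundaries (drop-line integration: the valley splits the area but
#' does not anchor the baseline). `anchor_span` averages the signal over a
#' small symmetric neighbourhood of each anchor to suppress single-sample
#' noise.
#'
#' @param chrom A `hop_chromatogram`.
#' @param window Numeric length-2 `(start, end)` in minutes, inside the
#'   time range.
#' @param baseline `"linear_endpoints"` or `"zero"`.
#' @param anchor Optional length-2 times at which the linear baseline is
#'   anchored (defaults to the window endpoints).
#' @param anchor_span Half-width (minutes) of the averaging neighbourhood
#'   around each anchor (0 = single sample).
#' @return Area in mAU min (>= 0).
#' @export
integrate_peak <- function(chrom, window,
                           baseline = c("linear_endpoints", "zero"),
                           anchor = NULL, anchor_span = 0) {
  stopifnot(inherits(chrom, "hop_chromatogram"))
  baseline <- match.arg(baseline)
  if (length(window) != 2 || !all(is.finite(window)) ||
      window[1] >= window[2]) {
    stop("window must be a finite (start, end) pair with start < end")
  }
  t <- chrom$time_min
  if (window[1] < t[1] || window[2] > t[length(t)]) {
    stop("window lies outside the chromatogram time range")
  }
  idx <- which(t >= window[1] & t <= window[2])
  if (length(idx) < 2) stop("window contains fewer than 2 samples")
  ti <- t[idx]
  yi <- chrom$absorbance_mau[idx]
  if (baseline == "zero") {
    b <- rep(0, length(idx))
  } else {
    if (is.null(anchor)) anchor <- c(ti[1], ti[length(ti)])
    av <- vapply(anchor, function(a) {
      near <- which(abs(t - a) <= max(anchor_span, 0))
      if (length(near) == 0) near <- which.min(abs(t - a))
      mean(chrom$absorbance_mau[near])
    }, numeric(1))
    b <- av[1] + (av[2] - av[1]) * (ti - anchor[1]) / (anchor[2] - anchor[1])
  }
  max(0, pracma::trapz(ti, yi - b))
}

#' Assign detected peaks to catalogue compounds
#'
#' Nearest-retention-time matching within `rt_tol`. A peak matching more
#' than one catalogue entry (the co-eluting kaempferol-rutinoside /
#' quercetin-malonyl-glucoside pair at unit peak widths) is assigned jointly
#' with compound ids joined by `+` and flagged `coeluting`.
#'
#' @param peaks Output of [detect_peaks()].
#' @param catalog Analyte catalogue.
#' @param channel_nm Channel whose catalogue entries are candidates.
#' @param tissue Restrict candidates to one tissue (optional).
#' @param rt_tol Assignment tolerance, minutes.
#' @return `peaks` with added `compound_id` (NA if unassigned) and `flag`.
#' @export
assign_peaks <- function(peaks, catalog = default_catalog(), channel_nm,
                         tissue = NULL, rt_tol = 0.05) {
  cat_c <- catalog[catalog$channel_nm == channel_nm, ]
  if (!is.null(tissue)) cat_c <- cat_c[cat_c$tissue == tissue, ]
  peaks$compound_id <- NA_character_
  peaks$flag <- ""
  if (nrow(peaks) == 0) return(peaks)
  for (i in seq_len(nrow(peaks))) {
    d <- abs(cat_c$rt_min - peaks$apex_time[i])
    hit <- which(d <= rt_tol)
    if (length(hit) == 1) {
      peaks$compound_id[i] <- cat_c$compound_id[hit]
    } else if (length(hit) > 1) {
      peaks$compound_id[i] <- paste(cat_c$compound_id[hit][order(d[hit])],
                                    collapse = "+")
      peaks$flag[i] <- "coeluting"
    } else {
      peaks$flag[i] <- "unassigned"
    }
  }
  peaks
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of integrated area on concentration
#' (`area = m * conc + b`), with the coefficient of determination and the
#' calibrated concentration range.
#'
#' @param points data.frame with columns `concentration_mg_ml` (or first
#'   column) and `area` (or second column).
#' @param compound_id Analyte label stored with the curve.
#' @return A list of class `hop_calibration`: `compound_id`, `slope`,
#'   `intercept`, `r_squared`, `valid_range`.
#' @export
fit_calibration <- function(points, compound_id = NA_character_) {
  conc <- if ("concentration_mg_ml" %in% names(points)) {
    points$concentration_mg_ml
  } else points[[1]]
  area <- if ("area" %in% names(points)) points$area else points[[2]]
  if (length(unique(conc)) < 2) {
    stop("degenerate calibration design: need >= 2 distinct concentrations")
  }
  fit <- lm(area ~ conc)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  structure(list(
    compound_id = compound_id,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    valid_range = range(conc)
  ), class = "hop_calibration")
}

#' Convert a peak area to percent dry weight
#'
#' `conc = (area - intercept) / slope * dilution_factor` (mg/ml), then
#' `pct_dw = 100 * conc * extract_volume / sample_mass`. Areas implying a
#' concentration above the calibrated range raise an error (re-run diluted);
#' below the lowest calibrant the value is reported as-is with a
#' `below_lowest_calibrant` flag (trace marker detection matters for
#' classification). Negative implied concentrations clip to zero.
#'
#' @param area Peak area(s), mAU min.
#' @param curve A `hop_calibration`.
#' @param extraction An extraction record ([extraction_record()]).
#' @return data.frame: `area`, `concentration_mg_ml`, `percent_dw`, `flag`.
#' @export
quantify <- function(area, curve, extraction) {
  stopifnot(inherits(curve, "hop_calibration"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("calibration slope must be positive")
  }
  raw <- (area - curve$intercept) / curve$slope
  if (any(raw > curve$valid_range[2] * (1 + 1e-9))) {
    stop("area implies concentration above the calibrated range (",
         signif(max(raw), 4), " > ", curve$valid_range[2],
         " mg/ml); dilute the extract and re-run")
  }
  flag <- ifelse(raw < curve$valid_range[1], "below_lowest_calibrant", "")
  raw <- pmax(0, raw)
  conc <- raw * extraction$dilution_factor
  pct <- 100 * conc * extraction$extract_volume_ml / extraction$sample_mass_mg
  data.frame(area = area, concentration_mg_ml = conc, percent_dw = pct,
             flag = flag, stringsAsFactors = FALSE)
}

#' Quantify bitter acids against the ICE-3 standard
#'
#' Per-analyte response factor from a run of the standard:
#' `rf = ice3_area / (fraction * total_mg_ml)`; sample concentration is
#' `area / rf`, then dilution/extraction bookkeeping as in [quantify()].
#'
#' @param areas Named sample areas for COH, nADH, COL, nADL (mAU min).
#' @param ice3 An [ice3_composition()].
#' @param ice3_areas Named areas measured for the standard at 320 nm; all
#'   four analytes must be present.
#' @param extraction Extraction record for the sample.
#' @return Named numeric vector of percent dry weight.
#' @export
quantify_bitter_acids <- function(areas, ice3 = ice3_composition(),
                                  ice3_areas, extraction) {
  analytes <- names(ice3$fractions)
  missing <- setdiff(analytes, names(ice3_areas))
  if (length(missing) > 0) {
    stop("ICE-3 standard areas missing analyte(s): ",
         paste(missing, collapse = ", "))
  }
  rf <- ice3_areas[analytes] / (ice3$fractions * ice3$total_mg_ml)
  a <- areas[analytes]
  a[is.na(a)] <- 0
  conc <- pmax(0, a / rf) * extraction$dilution_factor
  pct <- 100 * conc * extraction$extract_volume_ml / extraction$sample_mass_mg
  stats::setNames(as.numeric(pct), analytes)
}

#' Quantify one channel of a chromatogram
#'
#' detect -> assign -> integrate -> convert. Bitter-acid channels pass an
#' `ice3_areas` standard instead of a calibration curve.
#'
#' @param chrom A `hop_chromatogram`.
#' @param catalog Analyte catalogue.
#' @param tissue Tissue of the sample.
#' @param curve `hop_calibration` for equivalents-quantified channels.
#' @param ice3,ice3_areas Standard composition and areas for the 320 nm
#'   bitter-acid channel.
#' @param extraction Extraction record.
#' @param ... Passed to [detect_peaks()].
#' @return data.frame: `compound_id`, `area`, `concentration_mg_ml`,
#'   `percent_dw`, `flag`.
#' @export
quantify_channel <- function(chrom, catalog = default_catalog(), tissue,
                             curve = NULL, ice3 = NULL, ice3_areas = NULL,
                             extraction = NULL, ...) {
  if (is.null(extraction)) {
    extraction <- default_extraction(tissue, chrom$channel_nm)
  }
  peaks <- detect_peaks(chrom, ...)
  peaks <- assign_peaks(peaks, catalog, chrom$channel_nm, tissue = tissue)
  keep <- !is.na(peaks$compound_id)
  # cluster edges computed before dropping unassigned peaks, so the
  # drop-line baseline stays anchored where the signal reaches baseline
  edges <- lapply(split(seq_len(nrow(peaks)), peaks$cluster), function(i) {
    c(min(peaks$window_start[i]), max(peaks$window_end[i]))
  })
  peaks <- peaks[keep, , drop = FALSE]
  dt <- stats::median(diff(chrom$time_min))
  areas <- vapply(seq_len(nrow(peaks)), function(i) {
    integrate_peak(chrom, c(peaks$window_start[i], peaks$window_end[i]),
                   anchor = edges[[as.character(peaks$cluster[i])]],
                   anchor_span = 2 * dt)
  }, numeric(1))
  if (!is.null(curve)) {
    out <- quantify(areas, curve, extraction)
    out <- cbind(compound_id = peaks$compound_id, out,
                 stringsAsFactors = FALSE)
    out$flag <- ifelse(peaks$flag != "",
                       trimws(paste(peaks$flag, out$flag)), out$flag)
  } else if (!is.null(ice3) && !is.null(ice3_areas)) {
    named <- stats::setNames(areas, peaks$compound_id)
    pct <- quantify_bitter_acids(named, ice3, ice3_areas, extraction)
    out <- data.frame(compound_id = names(pct),
                      area = as.numeric(named[names(pct)]),
                      concentration_mg_ml = NA_real_,
                      percent_dw = as.numeric(pct), flag = "",
                      stringsAsFactors = FALSE)
    out$area[is.na(out$area)] <- 0
  } else {
    stop("provide either a calibration curve or an ICE-3 standard")
  }
  # compounds of the channel with no detected peak are reported as zero
  expected <- catalog$compound_id[catalog$tissue == tissue &
                                    catalog$channel_nm == chrom$channel_nm]
  seen <- unlist(strsplit(out$compound_id, "+", fixed = TRUE))
  absent <- setdiff(expected, seen)
  if (length(absent) > 0) {
    out <- rbind(out, data.frame(compound_id = absent, area = 0,
                                 concentration_mg_ml = 0, percent_dw = 0,
                                 flag = "not_detected",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Apportion the co-eluting kaempferol-rutinoside / quercetin-malonyl pair
#'
#' The 4.18/4.20 min pair is quantified as one joint peak. The quercetin
#' malonyl ester is estimated from the chromatographically resolved
#' kaempferol malonyl ester divided by the kaempferol:quercetin malonyl
#' abundance ratio (about 5 in hop leaves); the rutinoside takes the
#' remainder. A flagged heuristic, exact when the configured ratio holds.
#'
#' @param pct Named percent-dry-weight vector that may contain a joint
#'   `"Krut+Qmal"` (or `"Qmal+Krut"`) entry and a `Kmal` entry.
#' @param ratio Kaempferol:quercetin malonyl-ester abundance ratio.
#' @return Named vector with `Krut` and `Qmal` resolved.
#' @export
apportion_coeluting <- function(pct, ratio = 5) {
  joint <- intersect(c("Krut+Qmal", "Qmal+Krut"), names(pct))
  if (length(joint) == 0) return(pct)
  total <- sum(pct[joint])
  qmal <- if ("Kmal" %in% names(pct)) min(pct[["Kmal"]] / ratio, total) else 0
  out <- pct[setdiff(names(pct), joint)]
  out[["Qmal"]] <- qmal
  out[["Krut"]] <- total - qmal
  out
}
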