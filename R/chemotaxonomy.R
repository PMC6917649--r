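# Subspecies chemotype classification rules and concordance analysis.

#' Cone chemotype call from the XGA/MXH marker rule
#'
#' Native North American *lupuloides* cones carry both methylated
#' prenylchalcone markers, xanthogalenol (XGA) and 4'-O-methylxanthohumol
#' (MXH); European *lupulus* cones carry neither. Both above the presence
#' threshold -> `lupuloides`; both at or below -> `lupulus`; exactly one
#' above -> `atypical` (the rule is not extrapolated to single-marker
#' profiles); missing values -> `unavailable`.
#'
#' @param xga,mxh Marker concentrations, percent dry weight (vectorized).
#' @param presence_threshold Concentration floor for calling a marker
#'   present; defaults to the lowest calibration level (0.001 % dw scale).
#' @return Character vector of calls.
#' @export
classify_cone <- function(xga, mxh, presence_threshold = 0.001) {
  if (!is.finite(presence_threshold) || presence_threshold < 0) {
    stop("presence_threshold must be finite and non-negative")
  }
  has_x <- xga > presence_threshold
  has_m <- mxh > presence_threshold
  out <- ifelse(has_x & has_m, "lupuloides",
         ifelse(!has_x & !has_m, "lupulus", "atypical"))
  out[is.na(xga) | is.na(mxh)] <- "unavailable"
  out
}

#' Leaf chemotype call from the malonyl-ester proportion
#'
#' Leaves depleted in malonylated flavonol glycosides (< `low` of total
#' flavonols) are `lupuloides_type`; leaves rich in them (> `high`) are
#' `lupulus_type`. Proportions inside the published gray zone [0.10, 0.20]
#' are `indeterminate` (neither chemotype was observed there); missing
#' values -> `unavailable`.
#'
#' @param malonyl_proportion Malonyl-flavonol proportion(s), in \[0, 1\].
#' @param low,high Decision thresholds, `0 <= low < high <= 1`.
#' @return Character vector of calls.
#' @export
classify_leaf <- function(malonyl_proportion, low = 0.10, high = 0.20) {
  if (!is.finite(low) || !is.finite(high) || low < 0 || high > 1 ||
      low >= high) {
    stop("thresholds must satisfy 0 <= low < high <= 1")
  }
  out <- ifelse(malonyl_proportion < low, "lupuloides_type",
         ifelse(malonyl_proportion > high, "lupulus_type", "indeterminate"))
  out[is.na(malonyl_proportion)] <- "unavailable"
  out
}

#' Combine cone and leaf calls per accession
#'
#' Concordance is defined only where both calls are available and neither is
#' atypical/indeterminate; it holds when the two rules agree on the
#' subspecies.
#'
#' @param site_code Accession identifiers.
#' @param cone_call,leaf_call Calls from [classify_cone()] /
#'   [classify_leaf()].
#' @return data.frame of class `hop_chemotype_calls` with a logical
#'   `concordant` column (NA where undefined).
#' @export
chemotype_calls <- function(site_code, cone_call, leaf_call) {
  stopifnot(length(site_code) == length(cone_call),
            length(cone_call) == length(leaf_call))
  cone_ok <- cone_call %in% c("lupuloides", "lupulus")
  leaf_ok <- leaf_call %in% c("lupuloides_type", "lupulus_type")
  concordant <- ifelse(cone_ok & leaf_ok,
    (cone_call == "lupuloides" & leaf_call == "lupuloides_type") |
      (cone_call == "lupulus" & leaf_call == "lupulus_type"),
    NA)
  out <- data.frame(site_code = site_code, cone_call = cone_call,
                    leaf_call = leaf_call, concordant = concordant,
                    stringsAsFactors = FALSE)
  class(out) <- c("hop_chemotype_calls", class(out))
  out
}

#' Cone/leaf classification concordance
#'
#' Fraction of evaluable accessions (concordance defined) where the two
#' rules agree; non-evaluable calls are excluded from the denominator and
#' counted separately.
#'
#' @param calls A [chemotype_calls()] data.frame (>= 1 row).
#' @return List: `fraction_concordant` (NA if nothing evaluable),
#'   `n_evaluable`, `n_excluded`.
#' @export
concordance <- function(calls) {
  if (nrow(calls) == 0) stop("concordance requires at least one call")
  eval_idx <- !is.na(calls$concordant)
  n_eval <- sum(eval_idx)
  list(
    fraction_concordant = if (n_eval > 0) {
      mean(calls$concordant[eval_idx])
    } else NA_real_,
    n_evaluable = n_eval,
    n_excluded = nrow(calls) - n_eval
  )
}

#' Proportions of cone chemotype calls
#'
#' @param cone_call Character vector of cone calls (>= 1).
#' @return Named proportions over all calls; sums to 1.
#' @export
subspecies_fractions <- function(cone_call) {
  if (length(cone_call) == 0) stop("no calls supplied")
  tab <- table(cone_call)
  prop <- as.numeric(tab) / length(cone_call)
  stats::setNames(prop, names(tab))
}
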