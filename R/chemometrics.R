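# Per-accession trait statistics and group summaries.

CONE_COMPOUNDS <- c("XHU", "DXH", "XGA", "MXH", "COH", "nADH", "COL", "nADL")
LEAF_COMPOUNDS <- c("Qrut", "Qglc", "Krut", "Qmal", "Kglc", "Kmal")

#' Derived cone trait profile
#'
#' Totals and ratios from the eight quantified cone compounds: total
#' prenylchalcones (XHU + DXH + XGA + MXH), total alpha acids (COH + nADH),
#' total beta acids (COL + nADL), the cohumulone proportion
#' COH / total alpha, and the alpha ratio P_alpha = alpha / (alpha + beta).
#' 0/0 ratios are returned as NA (undefined), not 0.
#'
#' @param quantified Named percent-dry-weight vector containing all eight
#'   cone compounds (zeros allowed, negatives are an error).
#' @return List of class `hop_cone_profile`.
#' @export
cone_profile <- function(quantified) {
  missing <- setdiff(CONE_COMPOUNDS, names(quantified))
  if (length(missing) > 0) {
    stop("cone profile missing compound(s): ", paste(missing, collapse = ", "))
  }
  x <- quantified[CONE_COMPOUNDS]
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("cone concentrations must be finite and non-negative")
  }
  total_alpha <- x[["COH"]] + x[["nADH"]]
  total_beta <- x[["COL"]] + x[["nADL"]]
  structure(list(
    compounds = x,
    total_prenylchalcones = x[["XHU"]] + x[["DXH"]] + x[["XGA"]] + x[["MXH"]],
    total_alpha = total_alpha,
    total_beta = total_beta,
    coh_proportion = if (total_alpha > 0) x[["COH"]] / total_alpha else NA_real_,
    alpha_ratio = if (total_alpha + total_beta > 0) {
      total_alpha / (total_alpha + total_beta)
    } else NA_real_
  ), class = "hop_cone_profile")
}

#' Derived leaf flavonol profile
#'
#' Total flavonols (sum of the six glycosides, quercetin-rutinoside
#' equivalents) and the malonyl-ester proportion
#' (Qmal + Kmal) / total flavonols — the leaf chemotaxonomic trait.
#'
#' @param quantified Named vector with all six leaf flavonols (zeros
#'   allowed, negatives are an error).
#' @return List of class `hop_leaf_profile`.
#' @export
leaf_profile <- function(quantified) {
  missing <- setdiff(LEAF_COMPOUNDS, names(quantified))
  if (length(missing) > 0) {
    stop("leaf profile missing compound(s): ", paste(missing, collapse = ", "))
  }
  x <- quantified[LEAF_COMPOUNDS]
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("leaf abundances must be finite and non-negative")
  }
  total <- sum(x)
  structure(list(
    compounds = x,
    total_flavonols = total,
    malonyl_proportion = if (total > 0) {
      (x[["Qmal"]] + x[["Kmal"]]) / total
    } else NA_real_
  ), class = "hop_leaf_profile")
}

#' Mean and standard error over analytical replicates
#'
#' Arithmetic mean and SE = sd(n-1 denominator) / sqrt(n); SE is NA
#' (undefined) for a single replicate.
#'
#' @param values Numeric vector, length >= 1.
#' @return Named numeric `c(mean, se)`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0) stop("no replicate values supplied")
  if (any(!is.finite(values))) stop("replicate values must be finite")
  c(mean = mean(values),
    se = if (length(values) >= 2) sd(values) / sqrt(length(values)) else
      NA_real_)
}

#' Group summaries of per-accession trait means
#'
#' Unweighted mean over accessions per group (matching how the printed class
#' averages reproduce from per-accession values) with SE = sd of accession
#' means / sqrt(n); plus an "entire collection" row over the union.
#'
#' @param records data.frame with one row per accession: an id column, a
#'   group column and numeric trait columns.
#' @param traits Trait column names (default: every numeric column).
#' @param group_col,id_col Column names holding the group label and id.
#' @param all_label Label for the union group (`NULL` to skip it).
#' @return Long data.frame: `group`, `trait`, `n`, `mean`, `se`.
#' @export
group_summary <- function(records, traits = NULL, group_col = "subspecies",
                          id_col = "site_code", all_label = "all") {
  if (nrow(records) == 0) stop("cannot summarise an empty set of records")
  if (any(is.na(records[[group_col]]))) {
    stop("every record must carry a group label")
  }
  if (is.null(traits)) {
    traits <- names(records)[vapply(records, is.numeric, logical(1))]
    traits <- setdiff(traits, c(group_col, id_col))
  }
  groups <- split(records, records[[group_col]])
  if (!is.null(all_label)) groups[[all_label]] <- records
  out <- do.call(rbind, lapply(names(groups), function(g) {
    gr <- groups[[g]]
    do.call(rbind, lapply(traits, function(tr) {
      v <- gr[[tr]]
      v <- v[is.finite(v)]
      if (length(v) == 0) stop("group '", g, "' has no values for ", tr)
      ms <- aggregate_replicates(v)
      data.frame(group = g, trait = tr, n = length(v),
                 mean = unname(ms["mean"]), se = unname(ms["se"]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
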