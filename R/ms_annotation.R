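# Theoretical masses and ESI ion series for flavonol glycoside candidates,
# and annotation of observed (m/z, mode) ion lists.

# monoisotopic constants (Da)
MS_CONST <- list(
  aglycone = c(kaempferol = 286.0477, quercetin = 302.0427),
  sugar = c(glucoside = 162.0528, rutinoside = 308.1107),
  acyl = c(none = 0, malonyl = 86.0004),
  proton = 1.00728,
  co2 = 43.9898
)

#' Construct a flavonol glycoside candidate
#'
#' @param aglycone "kaempferol" or "quercetin".
#' @param sugar "glucoside" or "rutinoside".
#' @param acyl "none" or "malonyl" (6''-O-malonyl ester on the sugar).
#' @param id Candidate identifier (auto-built when NULL).
#' @param rt_min,lambda_max_nm Optional retention time and absorbance
#'   maximum used as annotation tie-breakers.
#' @return List of class `hop_glycoside`.
#' @export
glycoside_candidate <- function(aglycone = c("kaempferol", "quercetin"),
                                sugar = c("glucoside", "rutinoside"),
                                acyl = c("none", "malonyl"), id = NULL,
                                rt_min = NA_real_,
                                lambda_max_nm = NA_real_) {
  aglycone <- match.arg(aglycone)
  sugar <- match.arg(sugar)
  acyl <- match.arg(acyl)
  if (is.null(id)) {
    id <- paste0(aglycone, "-3-O-",
                 if (acyl == "malonyl") "malonyl" else "", sugar)
  }
  structure(list(id = id, aglycone = aglycone, sugar = sugar, acyl = acyl,
                 rt_min = rt_min, lambda_max_nm = lambda_max_nm),
            class = "hop_glycoside")
}

#' The six leaf flavonol glycosides
#'
#' Candidate catalogue matching the leaf analyte list, with published
#' retention times and absorbance maxima (kaempferol glycosides 347-348 nm,
#' quercetin glycosides 354 nm).
#'
#' @return Named list of `hop_glycoside` candidates keyed by compound code.
#' @export
flavonol_candidates <- function() {
  list(
    Qrut = glycoside_candidate("quercetin", "rutinoside", "none",
                               id = "Qrut", rt_min = 3.83,
                               lambda_max_nm = 354),
    Qglc = glycoside_candidate("quercetin", "glucoside", "none",
                               id = "Qglc", rt_min = 3.96,
                               lambda_max_nm = 354),
    Krut = glycoside_candidate("kaempferol", "rutinoside", "none",
                               id = "Krut", rt_min = 4.18,
                               lambda_max_nm = 347),
    Qmal = glycoside_candidate("quercetin", "glucoside", "malonyl",
                               id = "Qmal", rt_min = 4.20,
                               lambda_max_nm = 354),
    Kglc = glycoside_candidate("kaempferol", "glucoside", "none",
                               id = "Kglc", rt_min = 4.30,
                               lambda_max_nm = 348),
    Kmal = glycoside_candidate("kaempferol", "glucoside", "malonyl",
                               id = "Kmal", rt_min = 4.60,
                               lambda_max_nm = 348)
  )
}

#' Theoretical monoisotopic mass of a glycoside candidate
#'
#' Aglycone mass plus the glycosylation increment plus the acyl increment
#' (monoisotopic constants: kaempferol 286.0477, quercetin 302.0427,
#' +hexose 162.0528, +rutinose 308.1107, +malonyl 86.0004 Da).
#'
#' @param candidate A `hop_glycoside`.
#' @return Mass in daltons.
#' @export
theoretical_mass <- function(candidate) {
  stopifnot(inherits(candidate, "hop_glycoside"))
  MS_CONST$aglycone[[candidate$aglycone]] +
    MS_CONST$sugar[[candidate$sugar]] +
    MS_CONST$acyl[[candidate$acyl]]
}

#' Predicted ESI ion series for a candidate
#'
#' Positive mode: the quasimolecular \[M+H\]+ for every candidate, plus the
#' \[aglycone+H\]+ in-source fragment for non-acylated glycosides. Negative
#' mode: \[M-H\]- and the proton-bound dimer \[2M-H\]-, plus the diagnostic
#' decarboxylation fragment \[M-CO2-H\]- (deprotonated molecule minus
#' neutral CO2, loss of the terminal malonyl carboxyl) for malonyl esters.
#' Proton 1.00728 Da, CO2 43.9898 Da.
#'
#' @param candidate A `hop_glycoside`.
#' @param mode "positive" or "negative".
#' @return data.frame: `species`, `mz`, `mode`.
#' @export
predict_ions <- function(candidate, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  m <- theoretical_mass(candidate)
  p <- MS_CONST$proton
  if (mode == "positive") {
    species <- "M+H"
    mz <- m + p
    if (candidate$acyl == "none") {
      species <- c(species, "aglycone+H")
      mz <- c(mz, MS_CONST$aglycone[[candidate$aglycone]] + p)
    }
  } else {
    species <- c("M-H", "2M-H")
    mz <- c(m - p, 2 * m - p)
    if (candidate$acyl == "malonyl") {
      species <- c(species, "M-CO2-H")
      mz <- c(mz, m - p - MS_CONST$co2)
    }
  }
  data.frame(species = species, mz = as.numeric(mz), mode = mode,
             stringsAsFactors = FALSE)
}

#' Annotate an observed ion list against candidate glycosides
#'
#' Each candidate is scored as the fraction of its predicted ions (over the
#' ionization modes present in the observation) matched by an observed ion
#' of the same mode within `tolerance`. Ties break by absorbance-maximum
#' proximity, then retention-time proximity, then candidate id, so the
#' ranking is deterministic and permutation-invariant in the ion list.
#' Candidates matching nothing are excluded.
#'
#' @param observed data.frame with columns `mz` and `mode`
#'   ("positive"/"negative"); an `abundance` column is carried but not
#'   scored (matrix- and tune-dependent).
#' @param candidates List of `hop_glycoside` (>= 1, else an error).
#' @param tolerance Match tolerance in Da (0.5 = unit resolution).
#' @param lambda_max_nm,rt_min Optional observed values for tie-breaking.
#' @return data.frame ranked best-first: `candidate_id`, `score`,
#'   `n_predicted`, `n_matched`, `dlambda_nm`, `drt_min`.
#' @export
annotate_spectrum <- function(observed, candidates = flavonol_candidates(),
                              tolerance = 0.5, lambda_max_nm = NA_real_,
                              rt_min = NA_real_) {
  if (length(candidates) == 0) stop("candidate catalogue is empty")
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive")
  }
  if (nrow(observed) == 0) stop("need at least one observed ion")
  if (!all(c("mz", "mode") %in% names(observed))) {
    stop("observed ions need `mz` and `mode` columns")
  }
  modes <- intersect(c("positive", "negative"), unique(observed$mode))
  rows <- lapply(candidates, function(cand) {
    preds <- do.call(rbind, lapply(modes, predict_ions, candidate = cand))
    matched <- vapply(seq_len(nrow(preds)), function(i) {
      obs <- observed$mz[observed$mode == preds$mode[i]]
      any(abs(obs - preds$mz[i]) <= tolerance)
    }, logical(1))
    data.frame(
      candidate_id = cand$id,
      score = mean(matched),
      n_predicted = nrow(preds),
      n_matched = sum(matched),
      dlambda_nm = if (is.finite(lambda_max_nm) &&
                       is.finite(cand$lambda_max_nm)) {
        abs(lambda_max_nm - cand$lambda_max_nm)
      } else Inf,
      drt_min = if (is.finite(rt_min) && is.finite(cand$rt_min)) {
        abs(rt_min - cand$rt_min)
      } else Inf,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_matched > 0, , drop = FALSE]
  out <- out[order(-out$score, out$dlambda_nm, out$drt_min,
                   out$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the packaged leaf flavonol ion catalogue
#'
#' Observed retention times, absorbance maxima and ESI+/ESI- ion lists for
#' the six leaf flavonol glycosides, as printed for this chromatographic
#' method.
#'
#' @param path CSV path (defaults to the packaged file).
#' @return data.frame, one row per observed ion.
#' @export
load_table3_fixture <- function(path = system.file(
  "extdata", "table3_flavonol_ions.csv", package = "hopchem")) {
  if (!nzchar(path) || !file.exists(path)) stop("ion catalogue not found")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "rt_min", "lambda_max_nm", "mode", "mz",
            "rel_abundance", "species")
  if (!all(need %in% names(x))) stop("ion catalogue is missing columns")
  if (length(unique(x$compound_id)) != 6) {
    stop("ion catalogue must describe exactly 6 compounds")
  }
  x
}
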