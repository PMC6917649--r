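# Seeded synthetic germplasm panels and DAD chromatograms.
# Every generator is a pure function of its arguments including the seed;
# per-call streams are derived from (seed, accession, tissue, replicate) so
# no global RNG state leaks between calls.

#' Derive a reproducible sub-seed from a base seed and string labels
#'
#' Polynomial string hash folded into the base seed modulo 2^31 - 1, so each
#' (accession, tissue, replicate, ...) combination gets its own independent
#' stream while staying a valid 32-bit integer seed.
#'
#' @param seed Base integer seed.
#' @param ... Character/numeric labels identifying the stream.
#' @return An integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(paste(..., sep = "|"))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(((abs(seed) + h) %% (m - 1)) + 1)
}

# mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# location parameter such that the truncated-normal mean equals `target`
truncnorm_center <- function(target, sd, lo, hi) {
  stopifnot(target >= lo, target <= hi)
  uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target,
          lower = lo - 6 * sd, upper = hi + 6 * sd, tol = 1e-10)$root
}

# rejection sampler; mu is the location, not the mean
rtruncnorm <- function(n, mu, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mu, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a truncated normal whose empirical mean targets a given value
#'
#' The location parameter is re-centred (closed-form truncated-normal mean,
#' solved by [stats::uniroot]) so that the distribution mean equals
#' `target_mean` despite asymmetric truncation at the trait's printed range.
#'
#' @param n Number of draws.
#' @param target_mean Desired distribution mean (must lie inside the range).
#' @param sd Spread before truncation.
#' @param lo,hi Admissible trait range.
#' @return Numeric vector of length `n` inside `[lo, hi]`.
#' @export
rtruncnorm_target <- function(n, target_mean, sd, lo, hi) {
  if (sd <= 0) {
    stopifnot(target_mean >= lo, target_mean <= hi)
    return(rep(target_mean, n))
  }
  rtruncnorm(n, truncnorm_center(target_mean, sd, lo, hi), sd, lo, hi)
}

#' Per-class trait distribution parameters
#'
#' Class means and admissible ranges for every generated trait, taken from
#' the printed per-accession summary of the 30-accession survey: traits are
#' truncated normal with mean equal to the class mean and truncation at the
#' printed min/max of each column. Spread defaults to (hi - lo)/6. The total
#' leaf flavonol pool is not summarised per class in print; both classes use
#' the published collection range (0.28-2.77 % dw) with a mid-range mean.
#'
#' @return data.frame with columns `trait`, `class`, `mean`, `lo`, `hi`, `sd`.
#' @export
default_trait_params <- function() {
  p <- rbind(
    data.frame(trait = "total_prenylchalcones", class = "lupuloides",
               mean = 0.67, lo = 0.47, hi = 1.15),
    data.frame(trait = "total_prenylchalcones", class = "lupulus",
               mean = 0.51, lo = 0.29, hi = 0.65),
    data.frame(trait = "xga", class = "lupuloides",
               mean = 0.050, lo = 0.0295, hi = 0.111),
    data.frame(trait = "mxh", class = "lupuloides",
               mean = 0.044, lo = 0.0254, hi = 0.0868),
    data.frame(trait = "total_alpha", class = "lupuloides",
               mean = 6.65, lo = 2.53, hi = 9.38),
    data.frame(trait = "total_alpha", class = "lupulus",
               mean = 4.58, lo = 1.70, hi = 8.31),
    data.frame(trait = "prop_coh", class = "lupuloides",
               mean = 0.41, lo = 0.36, hi = 0.47),
    data.frame(trait = "prop_coh", class = "lupulus",
               mean = 0.26, lo = 0.17, hi = 0.36),
    data.frame(trait = "total_beta", class = "lupuloides",
               mean = 6.27, lo = 3.97, hi = 12.0),
    data.frame(trait = "total_beta", class = "lupulus",
               mean = 4.36, lo = 2.12, hi = 6.55),
    data.frame(trait = "prop_malonyl", class = "lupuloides",
               mean = 0.0343, lo = 0.021, hi = 0.063),
    data.frame(trait = "prop_malonyl", class = "lupulus",
               mean = 0.391, lo = 0.221, hi = 0.536),
    data.frame(trait = "total_flavonols", class = "lupuloides",
               mean = 1.20, lo = 0.28, hi = 2.77),
    data.frame(trait = "total_flavonols", class = "lupulus",
               mean = 1.20, lo = 0.28, hi = 2.77)
  )
  p$sd <- (p$hi - p$lo) / 6
  p
}

#' Panel generation configuration
#'
#' @param n_lupuloides,n_lupulus Accessions per subspecies class; defaults
#'   match the 19 + 11 composition of the surveyed collection.
#' @param replicates Analytical replicates per accession (triplicate).
#' @param replicate_noise_cv Multiplicative (log-normal) coefficient of
#'   variation of a single replicate measurement; 5% reproduces the order of
#'   the printed standard errors (2-10% of trait means).
#' @param kaempferol_quercetin_malonyl_ratio Abundance ratio of the
#'   kaempferol to the quercetin malonyl-glucoside (about five in leaves).
#' @param trait_params Per-class trait distributions, see
#'   [default_trait_params()].
#' @param seed Integer seed; the panel is a pure function of the config.
#' @return A validated list of class `hop_panel_config`.
#' @export
panel_config <- function(n_lupuloides = 19, n_lupulus = 11, replicates = 3,
                         replicate_noise_cv = 0.05,
                         kaempferol_quercetin_malonyl_ratio = 5,
                         trait_params = default_trait_params(), seed = 1) {
  counts <- c(n_lupuloides, n_lupulus, replicates)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (!is.finite(replicate_noise_cv) || replicate_noise_cv < 0) {
    stop("replicate_noise_cv must be finite and non-negative")
  }
  if (!is.finite(kaempferol_quercetin_malonyl_ratio) ||
      kaempferol_quercetin_malonyl_ratio <= 0) {
    stop("kaempferol_quercetin_malonyl_ratio must be positive")
  }
  bad <- !is.finite(trait_params$mean) | !is.finite(trait_params$sd) |
    trait_params$sd < 0 | trait_params$mean < trait_params$lo |
    trait_params$mean > trait_params$hi
  if (any(bad)) {
    stop("invalid trait parameters for: ",
         paste(trait_params$trait[bad], collapse = ", "))
  }
  structure(list(n_lupuloides = n_lupuloides, n_lupulus = n_lupulus,
                 replicates = replicates,
                 replicate_noise_cv = replicate_noise_cv,
                 kaempferol_quercetin_malonyl_ratio =
                   kaempferol_quercetin_malonyl_ratio,
                 trait_params = trait_params, seed = seed),
            class = "hop_panel_config")
}

trait_row <- function(params, trait, class) {
  r <- params[params$trait == trait & params$class == class, ]
  if (nrow(r) != 1) stop("no trait parameters for ", trait, "/", class)
  r
}

sample_trait <- function(n, params, trait, class) {
  r <- trait_row(params, trait, class)
  rtruncnorm_target(n, r$mean, r$sd, r$lo, r$hi)
}

# fixed within-class composition splits (no published per-compound values)
XHU_SHARE <- 0.72   # xanthohumol share of the non-marker prenylchalcone pool
NONMAL_WEIGHTS <- c(Qrut = 0.40, Qglc = 0.25, Krut = 0.15, Kglc = 0.20)

#' Generate a synthetic germplasm panel
#'
#' Draws per-accession ground-truth cone and leaf compositions for the two
#' chemotype classes. *lupuloides* truths carry both cone markers (XGA and
#' MXH strictly positive) and a low leaf malonyl-ester proportion; *lupulus*
#' truths have exactly zero XGA and MXH and a high malonyl proportion.
#' Deterministic for a fixed config (including seed).
#'
#' @param config A [panel_config()].
#' @return List of `hop_truth` objects, lupuloides first.
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "hop_panel_config"))
  n <- config$n_lupuloides + config$n_lupulus
  if (n == 0) return(list())
  labels <- c(rep("lupuloides", config$n_lupuloides),
              rep("lupulus", config$n_lupulus))
  ids <- sprintf("WLD-%02d", seq_len(n))
  k <- config$kaempferol_quercetin_malonyl_ratio
  withr::with_seed(derive_seed(config$seed, "panel"), {
    truths <- vector("list", n)
    for (cls in c("lupuloides", "lupulus")) {
      idx <- which(labels == cls)
      m <- length(idx)
      if (m == 0) next
      t_pc <- sample_trait(m, config$trait_params, "total_prenylchalcones", cls)
      xga <- if (cls == "lupuloides") {
        sample_trait(m, config$trait_params, "xga", cls)
      } else rep(0, m)
      mxh <- if (cls == "lupuloides") {
        sample_trait(m, config$trait_params, "mxh", cls)
      } else rep(0, m)
      t_a <- sample_trait(m, config$trait_params, "total_alpha", cls)
      p_coh <- sample_trait(m, config$trait_params, "prop_coh", cls)
      t_b <- sample_trait(m, config$trait_params, "total_beta", cls)
      t_f <- sample_trait(m, config$trait_params, "total_flavonols", cls)
      p_mal <- sample_trait(m, config$trait_params, "prop_malonyl", cls)
      for (j in seq_len(m)) {
        i <- idx[j]
        rest <- t_pc[j] - xga[j] - mxh[j]
        cone <- c(
          XHU = XHU_SHARE * rest, DXH = (1 - XHU_SHARE) * rest,
          XGA = xga[j], MXH = mxh[j],
          COH = p_coh[j] * t_a[j], nADH = (1 - p_coh[j]) * t_a[j],
          # colupulone share of beta acids tracks the cohumulone share
          # (co-analogs draw on the same branched acyl precursor pool)
          COL = p_coh[j] * t_b[j], nADL = (1 - p_coh[j]) * t_b[j]
        )
        mal <- p_mal[j] * t_f[j]
        leaf <- c(
          NONMAL_WEIGHTS * (t_f[j] - mal),
          Qmal = mal / (k + 1),
          Kmal = mal * k / (k + 1)
        )
        truths[[i]] <- structure(list(
          accession_id = ids[i], subspecies = labels[i],
          cone = cone, leaf = leaf,
          replicate_noise_cv = config$replicate_noise_cv,
          seed = derive_seed(config$seed, ids[i])
        ), class = "hop_truth")
      }
    }
    truths
  })
}

#' Measured (replicate-noised) concentrations for one truth
#'
#' Applies multiplicative log-normal measurement noise with the truth's CV,
#' mean-corrected so the expectation equals the generating value. The noise
#' stream is derived from (truth seed, tissue, replicate), so a given cone
#' replicate sees the same realization whether it is read at 320 or 370 nm.
#'
#' @param truth A `hop_truth`.
#' @param tissue "cone" or "leaf".
#' @param replicate Replicate index (1-based).
#' @return Named numeric vector of measured percent dry weight.
#' @export
measure_truth <- function(truth, tissue = c("cone", "leaf"), replicate = 1) {
  tissue <- match.arg(tissue)
  x <- truth[[tissue]]
  cv <- truth$replicate_noise_cv
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(derive_seed(truth$seed, tissue, replicate), {
    x * exp(rnorm(length(x), -sdlog^2 / 2, sdlog))
  })
}

#' Tabulate measured concentrations for a whole panel
#'
#' @param truths List of `hop_truth` (from [generate_panel()]).
#' @param replicates Replicates per accession and tissue.
#' @return Tidy data.frame: accession_id, subspecies, tissue, replicate,
#'   compound_id, true_pct_dw, measured_pct_dw.
#' @export
measure_panel <- function(truths, replicates = 3) {
  rows <- list()
  for (truth in truths) {
    for (tissue in c("cone", "leaf")) {
      for (rep_i in seq_len(replicates)) {
        meas <- measure_truth(truth, tissue, rep_i)
        rows[[length(rows) + 1]] <- data.frame(
          accession_id = truth$accession_id, subspecies = truth$subspecies,
          tissue = tissue, replicate = rep_i,
          compound_id = names(meas),
          true_pct_dw = unname(truth[[tissue]]),
          measured_pct_dw = unname(meas),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(accession_id = character(), subspecies = character(),
                      tissue = character(), replicate = integer(),
                      compound_id = character(), true_pct_dw = numeric(),
                      measured_pct_dw = numeric()))
  }
  do.call(rbind, rows)
}

#' Simulate a DAD trace from extract concentrations
#'
#' Forward model: sum of Gaussian peaks (apex at the catalogue retention
#' time, common width) on a constant baseline, plus optional white noise.
#' Each peak's true area is `response_factor * concentration`, so the
#' Gaussian amplitude is `rf * c / (sigma * sqrt(2*pi))`.
#'
#' @param conc_mg_ml Named vector of extract concentrations (mg/ml).
#' @param rt_min Named vector of retention times covering every compound
#'   with nonzero concentration (missing entry is a catalogue error).
#' @param response_factor Area per (mg/ml), common to the channel.
#' @param times Time axis (min), strictly increasing; defaults to an 8-min
#'   run sampled at 20 Hz.
#' @param peak_sd_min Gaussian peak sigma in minutes.
#' @param baseline_mau Constant baseline (mAU).
#' @param noise_sd Additive white-noise standard deviation (mAU).
#' @param channel_nm Wavelength recorded in the metadata.
#' @param seed Optional seed for the noise stream.
#' @param metadata Named character metadata stored with the trace.
#' @return A `hop_chromatogram` (see [as_chromatogram()]).
#' @export
simulate_trace <- function(conc_mg_ml, rt_min, response_factor,
                           times = seq(0, 8, by = 1 / 1200),
                           peak_sd_min = 0.02, baseline_mau = 2,
                           noise_sd = 0, channel_nm = NA, seed = NULL,
                           metadata = character()) {
  nz <- names(conc_mg_ml)[conc_mg_ml > 0]
  missing_rt <- setdiff(nz, names(rt_min)[is.finite(rt_min)])
  if (length(missing_rt) > 0) {
    stop("no catalogue retention time for compound(s): ",
         paste(missing_rt, collapse = ", "))
  }
  y <- rep(baseline_mau, length(times))
  for (id in nz) {
    amp <- response_factor * conc_mg_ml[[id]] / (peak_sd_min * sqrt(2 * pi))
    y <- y + amp * exp(-0.5 * ((times - rt_min[[id]]) / peak_sd_min)^2)
  }
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(length(times), 0, noise_sd) else {
      withr::with_seed(seed, rnorm(length(times), 0, noise_sd))
    }
    y <- y + eps
  }
  as_chromatogram(times, y, channel_nm = channel_nm, metadata = metadata)
}

#' Simulate a chromatogram for one accession replicate
#'
#' Converts the truth's percent-dry-weight composition to injected extract
#' concentrations via the extraction record (`c = pct * mass /
#' (100 * volume * dilution)`), applies replicate measurement noise (see
#' [measure_truth()]), and renders the channel's catalogue compounds as a
#' Gaussian-peak trace.
#'
#' @param truth A `hop_truth`.
#' @param tissue "cone" or "leaf".
#' @param channel_nm Quantitation channel (370/320 for cones, 350 for leaf).
#' @param catalog Analyte catalogue, see [default_catalog()].
#' @param replicate Replicate index; 0 disables replicate noise.
#' @param noise_sd Trace white-noise sd (mAU).
#' @param extraction Extraction record; defaults to
#'   [default_extraction()] for the tissue/channel.
#' @param peak_sd_min,baseline_mau Forward-model constants.
#' @return A `hop_chromatogram`.
#' @export
simulate_chromatogram <- function(truth, tissue = c("cone", "leaf"),
                                  channel_nm, catalog = default_catalog(),
                                  replicate = 1, noise_sd = 0.2,
                                  extraction = NULL,
                                  peak_sd_min = 0.02, baseline_mau = 2) {
  tissue <- match.arg(tissue)
  if (is.null(extraction)) {
    extraction <- default_extraction(tissue, channel_nm)
  }
  pct <- if (replicate >= 1) measure_truth(truth, tissue, replicate) else
    truth[[tissue]]
  cat_t <- catalog[catalog$tissue == tissue & catalog$channel_nm == channel_nm, ]
  if (nrow(cat_t) == 0) {
    stop("catalogue has no ", tissue, " compounds at ", channel_nm, " nm")
  }
  pct <- pct[names(pct) %in% cat_t$compound_id]
  conc <- pct * extraction$sample_mass_mg /
    (100 * extraction$extract_volume_ml * extraction$dilution_factor)
  rt <- stats::setNames(cat_t$rt_min, cat_t$compound_id)
  simulate_trace(
    conc, rt, channel_response_factor(channel_nm),
    peak_sd_min = peak_sd_min, baseline_mau = baseline_mau,
    noise_sd = noise_sd, channel_nm = channel_nm,
    seed = derive_seed(truth$seed, tissue, replicate, "ch", channel_nm),
    metadata = c(sample_id = truth$accession_id, tissue = tissue,
                 replicate = as.character(replicate))
  )
}

#' Simulate a multi-level calibration series
#'
#' Seven geometrically spaced levels across 0.001-0.5 mg/ml by default, in
#' three independent serial-dilution series, with seeded proportional noise
#' on the response: `area = rf * conc * (1 + eps)`, `eps ~ N(0, noise_cv)`.
#'
#' @param compound_id Analyte being calibrated (sets the channel response
#'   factor via the catalogue unless `response_factor` is given).
#' @param n_levels Calibration levels (>= 2).
#' @param low,high Concentration range, mg/ml, `0 < low < high`.
#' @param n_series Independent dilution series.
#' @param noise_cv Proportional response noise, default 0.5% (UPLC injection
#'   precision class; 0 = exact line).
#' @param response_factor Override the catalogue response factor.
#' @param catalog Analyte catalogue.
#' @param seed Seed for the noise stream.
#' @return data.frame with columns `series`, `concentration_mg_ml`, `area`.
#' @export
generate_calibration_series <- function(compound_id = "XHU", n_levels = 7,
                                        low = 0.001, high = 0.5,
                                        n_series = 3, noise_cv = 0.005,
                                        response_factor = NULL,
                                        catalog = default_catalog(),
                                        seed = 1) {
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high) {
    stop("calibration range requires 0 < low < high")
  }
  stopifnot(n_levels >= 2, n_series >= 1)
  if (is.null(response_factor)) {
    row <- catalog[catalog$compound_id == compound_id, ]
    if (nrow(row) != 1) stop("unknown compound_id: ", compound_id)
    response_factor <- channel_response_factor(row$channel_nm)
  }
  levels <- exp(seq(log(low), log(high), length.out = n_levels))
  conc <- rep(levels, times = n_series)
  series <- rep(seq_len(n_series), each = n_levels)
  eps <- if (noise_cv > 0) {
    withr::with_seed(derive_seed(seed, "calib", compound_id),
                     rnorm(length(conc), 0, noise_cv))
  } else rep(0, length(conc))
  data.frame(series = series, concentration_mg_ml = conc,
             area = response_factor * conc * (1 + eps))
}

#' Write / read a chromatogram as plain tabular text
#'
#' Two tab-separated columns (`time_min`, `absorbance_mAU`) preceded by
#' `# key: value` comment lines carrying the channel and sample metadata.
#'
#' @param chrom A `hop_chromatogram`.
#' @param path File path.
#' @return `read_chromatogram` returns a `hop_chromatogram`;
#'   `write_chromatogram` returns `path` invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "hop_chromatogram"))
  meta <- c(channel_nm = as.character(chrom$channel_nm), chrom$metadata)
  header <- sprintf("# %s: %s", names(meta), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("time_min\tabsorbance_mAU", con)
  writeLines(sprintf("%.10g\t%.10g", chrom$time_min, chrom$absorbance_mau),
             con)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- character()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[trimws(key)] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- utils::read.delim(text = lines[!grepl("^#", lines)])
  channel <- suppressWarnings(as.numeric(meta[["channel_nm"]]))
  as_chromatogram(body$time_min, body$absorbance_mAU, channel_nm = channel,
                  metadata = meta[setdiff(names(meta), "channel_nm")])
}

#' Write panel ground truth as tabular text
#'
#' One row per accession x tissue x compound, plus a companion label file
#' (`<path>.labels.csv`) mapping accessions to generating subspecies.
#'
#' @param truths List of `hop_truth`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_truths <- function(truths, path) {
  rows <- do.call(rbind, lapply(truths, function(tr) {
    do.call(rbind, lapply(c("cone", "leaf"), function(tissue) {
      data.frame(accession_id = tr$accession_id, subspecies = tr$subspecies,
                 tissue = tissue, compound_id = names(tr[[tissue]]),
                 pct_dw = unname(tr[[tissue]]), stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  labels <- data.frame(
    accession_id = vapply(truths, `[[`, "", "accession_id"),
    subspecies = vapply(truths, `[[`, "", "subspecies")
  )
  utils::write.csv(labels, paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}
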