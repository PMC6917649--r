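# Fixture loading, the end-to-end synthetic study, and the report pipeline.

#' Load the packaged 30-accession trait table
#'
#' Per-accession chemical traits (means and standard errors over analytical
#' triplicates) for the 30 wild-collected accessions: total prenylchalcones,
#' XGA, MXH, total alpha acids, cohumulone proportion, total beta acids,
#' alpha ratio and the leaf malonyl-flavonol proportion, with subspecies
#' identification and habitat.
#'
#' Integrity checks: exactly 30 rows, 19 labelled lupuloides and 11
#' lupulus; lupulus rows carry exactly zero XGA and MXH; all proportions in
#' \[0, 1\]. Violations raise an error naming the offending rows.
#'
#' @param path CSV path (defaults to the packaged file).
#' @return data.frame of class `hop_table2`.
#' @export
load_table2_fixture <- function(path = system.file(
  "extdata", "table2_accessions.csv", package = "hopchem")) {
  if (!nzchar(path) || !file.exists(path)) stop("trait table not found")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_code", "subspecies", "habitat", "total_prenylchalcones",
            "total_prenylchalcones_se", "xga", "mxh", "total_alpha",
            "total_alpha_se", "prop_coh", "total_beta", "total_beta_se",
            "alpha_ratio", "prop_malonyl")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("trait table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) != 30) {
    stop("trait table integrity: expected 30 accessions, found ", nrow(x))
  }
  n_oid <- sum(x$subspecies == "lupuloides")
  n_ulus <- sum(x$subspecies == "lupulus")
  if (n_oid != 19 || n_ulus != 11) {
    stop("trait table integrity: expected 19 lupuloides + 11 lupulus, found ",
         n_oid, " + ", n_ulus)
  }
  bad_marker <- x$subspecies == "lupulus" & (x$xga != 0 | x$mxh != 0)
  if (any(bad_marker)) {
    stop("trait table integrity: lupulus rows with nonzero markers: ",
         paste(x$site_code[bad_marker], collapse = ", "))
  }
  props <- cbind(x$prop_coh, x$alpha_ratio, x$prop_malonyl)
  bad_prop <- apply(props < 0 | props > 1 | !is.finite(props), 1, any)
  if (any(bad_prop)) {
    stop("trait table integrity: proportions outside [0, 1] in row(s): ",
         paste(x$site_code[bad_prop], collapse = ", "))
  }
  class(x) <- c("hop_table2", class(x))
  x
}

#' Chemotype analysis of a per-accession trait table
#'
#' Applies the cone XGA/MXH rule and the leaf malonyl-ester rule to each
#' row, combines the calls and computes concordance and cone-call
#' fractions.
#'
#' @param tab A trait table (see [load_table2_fixture()]).
#' @param presence_threshold Cone marker presence floor, percent dry weight.
#' @param leaf_low,leaf_high Leaf rule thresholds.
#' @return List: `calls` (a [chemotype_calls()] frame with the marker
#'   values and malonyl proportion attached), `concordance`, `fractions`.
#' @export
chemotype_analysis <- function(tab, presence_threshold = 0.001,
                               leaf_low = 0.10, leaf_high = 0.20) {
  cone <- classify_cone(tab$xga, tab$mxh, presence_threshold)
  leaf <- classify_leaf(tab$prop_malonyl, leaf_low, leaf_high)
  calls <- chemotype_calls(tab$site_code, cone, leaf)
  calls$xga <- tab$xga
  calls$mxh <- tab$mxh
  calls$malonyl_proportion <- tab$prop_malonyl
  list(calls = calls,
       concordance = concordance(calls),
       fractions = subspecies_fractions(calls$cone_call))
}

#' Group summaries of a trait table by cone chemotype call
#'
#' Groups accessions by the cone marker rule (not by the stored label) and
#' summarises the printed traits as unweighted means over accessions, plus
#' the entire-collection row.
#'
#' @param tab A trait table.
#' @param presence_threshold Cone marker presence floor.
#' @return Long data.frame from [group_summary()].
#' @export
trait_group_summary <- function(tab, presence_threshold = 0.001) {
  tab$group <- classify_cone(tab$xga, tab$mxh, presence_threshold)
  group_summary(
    tab,
    traits = c("total_prenylchalcones", "total_alpha", "prop_coh",
               "total_beta", "alpha_ratio", "prop_malonyl"),
    group_col = "group", id_col = "site_code", all_label = "entire_collection"
  )
}

quantify_accession_replicate <- function(truth, rep_i, curves, ice3,
                                         ice3_areas, catalog, noise_sd,
                                         mal_ratio) {
  # cone prenylchalcones at 370 nm (neat), xanthohumol-equivalents curve
  ch370 <- simulate_chromatogram(truth, "cone", 370, catalog, rep_i, noise_sd)
  q370 <- quantify_channel(ch370, catalog, "cone", curve = curves$XHU,
                           extraction = default_extraction("cone", 370))
  # cone bitter acids at 320 nm (4x dilution) against ICE-3
  ch320 <- simulate_chromatogram(truth, "cone", 320, catalog, rep_i, noise_sd)
  q320 <- quantify_channel(ch320, catalog, "cone", ice3 = ice3,
                           ice3_areas = ice3_areas,
                           extraction = default_extraction("cone", 320))
  # leaf flavonols at 350 nm, rutinoside-equivalents curve
  ch350 <- simulate_chromatogram(truth, "leaf", 350, catalog, rep_i, noise_sd)
  q350 <- quantify_channel(ch350, catalog, "leaf", curve = curves$Qrut,
                           extraction = default_extraction("leaf", 350))
  cone_pct <- stats::setNames(c(q370$percent_dw, q320$percent_dw),
                              c(q370$compound_id, q320$compound_id))
  leaf_raw <- stats::setNames(q350$percent_dw, q350$compound_id)
  leaf_pct <- apportion_coeluting(leaf_raw, ratio = mal_ratio)
  flags <- c(stats::setNames(q370$flag, q370$compound_id),
             stats::setNames(q350$flag, q350$compound_id))
  list(cone = cone_pct, leaf = leaf_pct, flags = flags)
}

#' Run the full synthetic study
#'
#' Generates a seeded germplasm panel, simulates every replicate's DAD
#' chromatograms on all three quantitation channels, fits the calibration
#' curves (xanthohumol and quercetin-rutinoside equivalents) and the ICE-3
#' response factors from simulated standard runs, quantifies each trace,
#' derives per-replicate cone/leaf profiles, aggregates to accession means,
#' classifies both tissues and computes concordance against the generating
#' labels.
#'
#' @param seed Integer seed controlling panel, noise and calibration draws.
#' @param n_lupuloides,n_lupulus,replicates Panel dimensions.
#' @param replicate_noise_cv Replicate measurement CV (0 for noiseless).
#' @param trace_noise_sd Trace white-noise sd in mAU (0 for noiseless).
#' @param calibration_noise_cv Proportional calibration response noise.
#' @param catalog Analyte catalogue.
#' @return List: `panel`, `curves`, `accession_traits` (per-accession trait
#'   means/SEs), `calls`, `concordance`, `fractions`, `label_agreement`
#'   (fraction of cone calls matching generating labels), `recovery`
#'   (per-compound quantified vs true percent dry weight, with the
#'   co-eluting pair apportioned), `quant` (per-replicate quantified table).
#' @export
run_synthetic_study <- function(seed = 1, n_lupuloides = 19, n_lupulus = 11,
                                replicates = 3, replicate_noise_cv = 0.05,
                                trace_noise_sd = 0.2,
                                calibration_noise_cv = 0.005,
                                catalog = default_catalog()) {
  cfg <- panel_config(n_lupuloides = n_lupuloides, n_lupulus = n_lupulus,
                      replicates = replicates,
                      replicate_noise_cv = replicate_noise_cv, seed = seed)
  panel <- generate_panel(cfg)
  mal_ratio <- cfg$kaempferol_quercetin_malonyl_ratio

  curves <- list(
    XHU = fit_calibration(
      generate_calibration_series("XHU", noise_cv = calibration_noise_cv,
                                  seed = seed), "XHU"),
    Qrut = fit_calibration(
      generate_calibration_series("Qrut", noise_cv = calibration_noise_cv,
                                  seed = seed), "Qrut")
  )
  # ICE-3 standard run at 320 nm: defined composition, known total
  ice3 <- ice3_composition()
  cat320 <- catalog[catalog$channel_nm == 320, ]
  std_trace <- simulate_trace(
    ice3$fractions * ice3$total_mg_ml,
    stats::setNames(cat320$rt_min, cat320$compound_id),
    channel_response_factor(320), channel_nm = 320,
    noise_sd = trace_noise_sd, seed = derive_seed(seed, "ice3")
  )
  std_peaks <- assign_peaks(detect_peaks(std_trace), catalog, 320, "cone")
  ice3_areas <- stats::setNames(
    vapply(seq_len(nrow(std_peaks)), function(i) {
      integrate_peak(std_trace,
                     c(std_peaks$window_start[i], std_peaks$window_end[i]))
    }, numeric(1)),
    std_peaks$compound_id)

  quant_rows <- list()
  trait_rows <- list()
  recovery_rows <- list()
  for (truth in panel) {
    rep_traits <- list()
    for (rep_i in seq_len(replicates)) {
      q <- quantify_accession_replicate(truth, rep_i, curves, ice3,
                                        ice3_areas, catalog, trace_noise_sd,
                                        mal_ratio)
      cp <- cone_profile(q$cone)
      lp <- leaf_profile(q$leaf)
      rep_traits[[rep_i]] <- c(
        total_prenylchalcones = cp$total_prenylchalcones,
        xga = unname(cp$compounds["XGA"]), mxh = unname(cp$compounds["MXH"]),
        total_alpha = cp$total_alpha, prop_coh = cp$coh_proportion,
        total_beta = cp$total_beta, alpha_ratio = cp$alpha_ratio,
        total_flavonols = lp$total_flavonols,
        prop_malonyl = lp$malonyl_proportion
      )
      meas <- c(q$cone, q$leaf)
      quant_rows[[length(quant_rows) + 1]] <- data.frame(
        accession_id = truth$accession_id, subspecies = truth$subspecies,
        replicate = rep_i, compound_id = names(meas),
        percent_dw = unname(meas),
        flag = unname(q$flags[names(meas)]),
        stringsAsFactors = FALSE
      )
      truth_all <- c(truth$cone, truth$leaf)
      recovery_rows[[length(recovery_rows) + 1]] <- data.frame(
        accession_id = truth$accession_id, replicate = rep_i,
        compound_id = names(meas),
        true_pct_dw = unname(truth_all[names(meas)]),
        quantified_pct_dw = unname(meas), stringsAsFactors = FALSE
      )
    }
    mat <- do.call(rbind, rep_traits)
    agg <- apply(mat, 2, aggregate_replicates)
    trait_rows[[length(trait_rows) + 1]] <- data.frame(
      site_code = truth$accession_id, subspecies = truth$subspecies,
      as.list(stats::setNames(agg["mean", ], colnames(mat))),
      stringsAsFactors = FALSE
    )
  }
  accession_traits <- do.call(rbind, trait_rows)
  quant <- do.call(rbind, quant_rows)
  recovery <- do.call(rbind, recovery_rows)

  cone_call <- classify_cone(accession_traits$xga, accession_traits$mxh)
  leaf_call <- classify_leaf(accession_traits$prop_malonyl)
  calls <- chemotype_calls(accession_traits$site_code, cone_call, leaf_call)
  calls$generating_label <- accession_traits$subspecies
  list(
    panel = panel, curves = curves, accession_traits = accession_traits,
    calls = calls, concordance = concordance(calls),
    fractions = subspecies_fractions(cone_call),
    label_agreement = mean(cone_call == accession_traits$subspecies),
    recovery = recovery, quant = quant
  )
}

pipeline_keys <- c("mode", "outdir", "seed", "n_lupuloides", "n_lupulus",
                   "replicates", "replicate_noise_cv", "trace_noise_sd",
                   "presence_threshold", "leaf_low", "leaf_high",
                   "fixture_path")

#' Run the end-to-end analysis and write the report bundle
#'
#' Two modes. `"fixture"` loads the packaged 30-accession trait table,
#' classifies every accession with both rules, and summarises traits by
#' chemotype group. `"synthetic"` runs [run_synthetic_study()]:
#' simulate -> calibrate -> quantify -> profile -> classify -> summarise.
#' Both write a calls CSV, a group-summary CSV, a flavonol annotation CSV
#' (observed ion lists annotated against the candidate catalogue) and a log
#' recording the seed and every threshold used.
#'
#' @param config Named list; required keys `mode` and `outdir`, optional
#'   `seed`, `n_lupuloides`, `n_lupulus`, `replicates`,
#'   `replicate_noise_cv`, `trace_noise_sd`, `presence_threshold`,
#'   `leaf_low`, `leaf_high`, `fixture_path`. An empty or keyless config is
#'   a usage error listing the documented keys.
#' @return Invisibly, the list of computed results.
#' @export
run_pipeline <- function(config) {
  if (!is.list(config) || is.null(config$mode) || is.null(config$outdir)) {
    stop("config must be a named list with at least `mode` and `outdir`; ",
         "documented keys: ", paste(pipeline_keys, collapse = ", "))
  }
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; documented keys: ", paste(pipeline_keys, collapse = ", "))
  }
  mode <- match.arg(config$mode, c("fixture", "synthetic"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  thr <- config$presence_threshold %||% 0.001
  lo <- config$leaf_low %||% 0.10
  hi <- config$leaf_high %||% 0.20

  if (mode == "fixture") {
    tab <- if (is.null(config$fixture_path)) load_table2_fixture() else
      load_table2_fixture(config$fixture_path)
    chem <- chemotype_analysis(tab, thr, lo, hi)
    summ <- trait_group_summary(tab, thr)
    results <- c(chem, list(summary = summ))
  } else {
    study <- run_synthetic_study(
      seed = seed,
      n_lupuloides = config$n_lupuloides %||% 19,
      n_lupulus = config$n_lupulus %||% 11,
      replicates = config$replicates %||% 3,
      replicate_noise_cv = config$replicate_noise_cv %||% 0.05,
      trace_noise_sd = config$trace_noise_sd %||% 0.2
    )
    at <- study$accession_traits
    at$group <- study$calls$cone_call
    summ <- group_summary(
      at, traits = c("total_prenylchalcones", "total_alpha", "prop_coh",
                     "total_beta", "alpha_ratio", "prop_malonyl"),
      group_col = "group", all_label = "entire_collection")
    utils::write.csv(study$quant, file.path(outdir, "quantitation.csv"),
                     row.names = FALSE)
    results <- list(calls = study$calls, concordance = study$concordance,
                    fractions = study$fractions, summary = summ,
                    label_agreement = study$label_agreement, study = study)
  }

  # flavonol annotation report from the packaged observed ion lists
  ions <- load_table3_fixture()
  ann <- do.call(rbind, lapply(split(ions, ions$compound_id), function(g) {
    top <- annotate_spectrum(data.frame(mz = g$mz, mode = g$mode),
                             lambda_max_nm = g$lambda_max_nm[1],
                             rt_min = g$rt_min[1])[1, ]
    data.frame(observed_compound = g$compound_id[1],
               top_candidate = top$candidate_id, score = top$score,
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL

  utils::write.csv(results$calls, file.path(outdir, "calls.csv"),
                   row.names = FALSE)
  utils::write.csv(results$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(ann, file.path(outdir, "annotation.csv"),
                   row.names = FALSE)
  conc <- results$concordance
  log_lines <- c(
    paste("timestamp:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("hopchem version:",
          as.character(utils::packageVersion("hopchem"))),
    paste("mode:", mode), paste("seed:", seed),
    paste("presence_threshold_pct_dw:", thr),
    paste("leaf_low:", lo), paste("leaf_high:", hi),
    paste("concordance:", format(conc$fraction_concordant)),
    paste("n_evaluable:", conc$n_evaluable),
    paste("n_excluded:", conc$n_excluded),
    paste("fractions:", paste(names(results$fractions),
                              format(results$fractions), sep = "=",
                              collapse = " "))
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  results$annotation <- ann
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
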