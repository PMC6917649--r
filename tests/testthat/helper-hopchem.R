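# shared fixtures built in code

# a single Gaussian of known area on a constant baseline
gaussian_chrom <- function(area = 1, rt = 1, sd = 0.02, baseline = 0,
                           t_end = 2, rate = 1200, channel = 350) {
  times <- seq(0, t_end, by = 1 / rate)
  y <- baseline + area / (sd * sqrt(2 * pi)) *
    exp(-0.5 * ((times - rt) / sd)^2)
  as_chromatogram(times, y, channel_nm = channel)
}

flat_chrom <- function(level = 2, t_end = 2, rate = 1200) {
  times <- seq(0, t_end, by = 1 / rate)
  as_chromatogram(times, rep(level, length(times)), channel_nm = 350)
}

# one lupuloides and one lupulus truth under default conditions
demo_truths <- function(seed = 301) {
  p <- generate_panel(panel_config(n_lupuloides = 1, n_lupulus = 1,
                                   seed = seed))
  stats::setNames(p, vapply(p, `[[`, "", "subspecies"))
}
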