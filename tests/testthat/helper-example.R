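# Worked-example data used across test files: one subject, four fitness
# items, ten trials each.  `printed_summaries` carries the published
# summary-table statistics, which for jump/flex disagree with the raw
# lists (that discrepancy is itself asserted in the io tests).

example_values <- list(
  cardio = c(589, 593, 590, 591, 589, 590, 589, 589, 592, 594),
  situps = c(39, 38, 37, 38, 37, 39, 38, 37, 37, 38),
  jump   = c(191, 190, 191, 190, 191, 189, 188, 192, 191, 190),
  flex   = c(18.5, 18.6, 18.4, 18.7, 18.6, 18.5, 18.6, 18.7, 18.6, 18.9))

example_specs <- function(k = 6, alpha = 0.05, phi1 = 0.4, phi2 = 0.8) {
  list(
    cardio = fitness_spec("cardio", 598, "smaller_better",
                          k = k, alpha = alpha, phi1 = phi1, phi2 = phi2),
    situps = fitness_spec("situps", 33, "larger_better",
                          k = k, alpha = alpha, phi1 = phi1, phi2 = phi2),
    jump   = fitness_spec("jump", 185, "larger_better",
                          k = k, alpha = alpha, phi1 = phi1, phi2 = phi2),
    flex   = fitness_spec("flex", 18, "larger_better",
                          k = k, alpha = alpha, phi1 = phi1, phi2 = phi2))
}

# summary-table statistics and 2-dp index estimates as published
printed_summaries <- data.frame(
  item_id = c("cardio", "situps", "jump", "flex"),
  n = 10L,
  mean = c(590.6, 37.8, 192, 18.59),
  sd = c(1.838, 0.789, 1.160, 0.099),
  stringsAsFactors = FALSE)
printed_estimates <- c(cardio = 4.03, situps = 6.09, jump = 6.04,
                       flex = 5.93)

# independent forward map for the fuzzy alpha-cut equation, written out
# from the confidence-limit definition rather than calling package code
fwd_cut <- function(a, pf_star, n) {
  pf_star * sqrt(qchisq(1 - a / 2, df = n - 1) / n) +
    qnorm(1 - a / 2) / sqrt(n)
}
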