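# small scenario for fast unit tests: fewer background genes, same design
smallScenario <- function(seed = 11L, nBackgroundGenes = 300L, ...) {
    scenarioConfig(seed = seed, nBackgroundGenes = nBackgroundGenes, ...)
}

# noise-free scenario: deterministic designed values everywhere
noiselessScenario <- function(seed = 11L, ...) {
    g <- scenarioConfig(seed = seed)@growth
    g$cv <- 0
    scenarioConfig(seed = seed, nBackgroundGenes = 300L, exprNoiseSd = 0,
                   growth = g, doseCV = 0,
                   qpcr = within(scenarioConfig(seed = seed)@qpcr,
                                 ct_sd <- 0),
                   ...)
}

# truth-curve responses for a hand-specified 4PL
responses4PL <- function(dose, bottom, top, ec50, hill) {
    bottom + (top - bottom) / (1 + 10^((log10(ec50) - log10(dose)) * hill))
}

# brute-force Pearson r from sum formulas (independent of stats::cor)
bruteforceR <- function(x, s) {
    n <- length(x)
    num <- sum(x * s) - n * mean(x) * mean(s)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(s^2) - n * mean(s)^2))
    num / den
}
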