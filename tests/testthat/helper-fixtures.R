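# Shared fixtures for the test suite: a moderate-resolution axis keeps the
# forward simulations fast; the component cache inside the package makes
# repeated fits on the same axis cheap.

testAxis <- function(n = 2048) defaultFieldAxis(n)

fabp3Lib <- function() fabpComponents("FABP3", "5-DSA")

# render a noisy mixture trace from a library and weights
noisyMixture <- function(lib, w, snr, seed, fieldMT = testAxis()) {
  tr <- simulateMixture(lib, w, fieldMT)
  y <- intensity(tr)
  pp <- max(y) - min(y)
  set.seed(seed)
  spectrumTrace(fieldMT, y + rnorm(length(y), 0, pp / snr))
}

# decompose a synthetic temperature series and classify it
classifyPreset <- function(preset, seed, probe = "5-DSA", snr = 50) {
  p <- truthParams(preset = preset, noiseSnr = snr, seed = seed, probe = probe)
  ser <- synthTemperatureSeries(p, fieldMT = testAxis())
  lib <- fabpComponents(p$protein, p$probe)
  entries <- lapply(ser, function(s) {
    f <- fitWeights(s$trace, lib)
    list(temperatureK = s$temperatureK, result = f,
         totalDI = fittedDoubleIntegral(f, fieldAxis(s$trace)))
  })
  classifyHighT(buildTemperatureSeries(entries))@classification
}
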