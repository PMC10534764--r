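# shared fixtures built in code; everything is deterministic under the
# seeds fixed here

quietNoise <- function() synthNoise(0, 0, 0)

# a tiny noiseless session: background / walking / background
fixtureSession <- function(seed = 3, durations = c(12, 20, 12)) {
  makeSession(sessionScript(
    c("none_of_the_above", "walking", "none_of_the_above"),
    durations, noise = quietNoise(), seed = seed))
}

randomDepthSeq <- function(h, w, T, seed = 1, maxmm = 3000L) {
  set.seed(seed)
  DepthSequence(array(sample.int(maxmm, h * w * T, replace = TRUE),
                      dim = c(h, w, T)))
}

bgTrack <- function(runs) {
  FrameLabelTrack(rep(names(runs), unname(runs)))
}
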