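# Shared fixtures: the default basis is memoized inside the package; the
# body model and a coil sampler are cheap to rebuild.

fixtureBasis <- function() defaultBasis()
fixtureBody <- function() wormBodyModel()

# a rasterized disc of radius r centered on an odd canvas
discImage <- function(r = 20, pad = 20) {
  c0 <- r + pad
  n <- 2 * c0 + 1
  outer(seq_len(n) - 1, seq_len(n) - 1,
        function(y, x) (x - c0)^2 + (y - c0)^2 <= r^2)
}

# draw a curvature-feasible coiled posture: a3 in [12, 30], uniform
# body-wave phase at the default wave amplitude, a4 in [-5, 5], a5 = 0
drawCoil <- function(basis, waveAmp = 4.5) {
  repeat {
    u <- runif(1, 0, 2 * pi)
    p <- c(waveAmp * cos(u), -waveAmp * sin(u), runif(1, 12, 30),
           runif(1, -5, 5), 0, runif(1, 0, 2 * pi))
    if (curvatureOk(reconstructProfile(p, basis))) return(p)
  }
}

# max per-mode deviation, taking the better of a candidate and its swap
coilDeviation <- function(p, truth, basis) {
  s <- swapHeadTail(p, basis)
  min(max(abs(p[1:5] - truth[1:5])), max(abs(s[1:5] - truth[1:5])))
}
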