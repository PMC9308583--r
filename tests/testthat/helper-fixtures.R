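## shared fixtures: the acquisition schedule and one synthetic arterial
## input built through the full input-construction pipeline (fixed seed)
fixtureSchedule <- defaultSchedule()
fixtureSystem <- makeSyntheticInput(seed = 20260901)
fixtureInput <- fixtureSystem$input

## a noiseless irreversible (2T3K) white-matter-like TAC used across tests
fixtureParams2t3k <- c(K1 = 0.12, k2 = 0.14, k3 = 0.11, vB = 0)
fixtureKi2t3k <- 0.12 * 0.11 / (0.14 + 0.11)
fixtureTac2t3k <- modelTissueCurve("2T3K", fixtureParams2t3k,
                                   fixtureInput, fixtureSchedule)

relErr <- function(x, ref) abs(x - ref) / abs(ref)
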