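Package: chirpfi
Title: Feature-Invariant Midbrain Responses to Electrocommunication Chirps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how midbrain (torus semicircularis) electrosensory
    neurons of weakly electric fish achieve selective yet invariant responses to
    heterogeneous electrocommunication ("chirp") stimuli. Provides synthesis of
    two-fish beat/chirp amplitude-modulation stimuli and quantification of chirp
    attributes; a synthetic generator of hindbrain (ELL) ON/OFF population input;
    conversion of firing rates to synaptic conductances; a stochastic
    Hodgkin-Huxley model of a torus semicircularis neuron integrated with the
    Euler-Maruyama scheme; selectivity and invariance metrics (chirp selectivity
    index, Victor-Purpura spike-train distance, aligned root-mean-square error,
    feature-invariance score, bimodality index); a constrained differential
    evolution parameter search; and pairwise parameter-sweep robustness analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
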