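Curated fixtures (synthetic emulations, not verbatim published data):

xi_o1.csv  - emulation of the implemented laboratory design for the arrest
             endpoint: 11 distinct trimethoprim levels on [0, 1000] uM
             (control plus log-then-linear spacing), equal weights because
             the per-level replicate flask counts are not reliably
             recoverable from the publication.
xi_o2.csv  - the same design restricted to [0, 450] uM (the aboral
             endpoint cannot be scored above 450 uM), weights renormalized.
priors_arrest.json / priors_aboral.json
           - the six published nominal parameter sets per endpoint with
             equal probabilities 1/6.
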