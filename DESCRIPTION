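Package: rscdigest
Title: Ileal Digestibility and Prediction Equations for Rapeseed Cake Fed to Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Marker-based evaluation of rapeseed cake as a protein feed for
    growing-finishing pigs. Computes apparent ileal digestibility (AID) of
    crude protein and amino acids from titanium-dioxide marker ratios,
    estimates basal endogenous losses from a nitrogen-free diet, corrects AID
    to standardized ileal digestibility (SID), screens multi-sample chemical
    composition for high variability (CV > 10%), and builds stepwise
    least-squares prediction equations for SID from chemical composition and
    processing temperature. Ships the published composition, diet,
    digestibility and endogenous-loss tables as plain-text fixtures, and a
    synthetic two-square 11 x 3 incomplete Latin square trial generator for
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
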