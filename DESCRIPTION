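Package: meicoc
Title: Crossover Interference Statistics from Cytological Focus Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of meiotic crossover patterning from cytological
    focus data (e.g. Zip3 foci mapped along synaptonemal-complex axes).
    Implements coefficient-of-coincidence (CoC) interference curves over
    equal-size chromosome intervals, maximum-likelihood gamma-distribution
    estimation of interference strength from inter-adjacent focus
    distances with bootstrap confidence intervals, per-nucleus focus and
    axis-length summaries including obligatory-crossover (zero-focus)
    frequencies, multiplicative independence expectations for double
    mutants, tetrad-fluorescence missegregation scoring, and
    immunofluorescence intensity quantification with line-profile
    background estimation. A seeded stationary gamma-renewal simulator
    generates focus datasets, tetrad colour patterns and spot-on-background
    nucleus images so every analysis stage can be exercised and validated
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, tiff
Suggests: testthat (>= 3.0.0), MASS, jsonlite, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
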