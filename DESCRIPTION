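Package: cdlcodec
Title: Composite DNA Letter Storage Codec with Soft-Decision Reed-Solomon
    Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encode arbitrary byte payloads into sequences of composite DNA
    letters (position-level mixtures of the four nucleotides in fixed integer
    ratios), protect them with Reed-Solomon blocks and CRC32 checksums,
    simulate the synthesis/sampling/sequencing channel, infer letters from
    observed base counts by maximum a posteriori estimation, and recover data
    beyond the hard-decision Reed-Solomon bound with transition-probability
    guided iterative soft-decision decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
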