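Package: pegforge
Title: Prime-Editing pegRNA Design, Nicking-Guide Selection and Golden-Gate Cloning Kits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs prime-editing reagents from a wild-type DNA sequence and a
    desired edit written in parenthesis notation. Enumerates and ranks candidate
    pegRNA spacers by PAM-to-edit distance, builds primer-binding-site (PBS) and
    reverse-transcriptase-template (RTT) options with efficiency warnings,
    selects PE3/PE3b secondary nicking guides (PE3b guides match only the edited
    allele), and emits golden-gate-ready oligonucleotides verified by simulated
    Type IIS digestion and ligation. Every emitted design is checked in silico
    by reconstructing the edited locus from the RT template.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    yaml,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
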