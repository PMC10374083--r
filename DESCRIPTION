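Package: introsel
Title: Selection on Introgressing Haplotypes and Genome-Scan Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the effective selection coefficient of a non-recombining
    haplotype introgressing from a donor into a diverged recipient population,
    accounting for direct fitness effects and pairwise epistasis within and
    between genetic backgrounds. Provides exact multiplicative-fitness forms
    and small-effect approximations for haploid and diploid carriers
    (including dominance of direct effects and of epistasis), a brute-force
    explicit-genome oracle for validation, parameter-sweep engines over
    haplotype size and composition, and a windowed genome-scan toolkit
    (Hudson F_ST, population branch statistic, normalized branch scores, f_D)
    with a four-population synthetic window generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
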