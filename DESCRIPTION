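Package: peatlipid
Title: Lipid Biomarker Analysis of Peat Cores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for depth-resolved lipid biomarker analysis of peatland
    cores. Reads long-format GC-MS concentration tables (ug/g dry weight),
    computes n-alkane molecular indices (carbon preference index, average
    chain length, the Paq aquatic macrophyte proxy, chain-length ratios and
    class sums), classifies organic-matter sources from threshold bands,
    summarizes sterol, pentacyclic triterpenoid, hopanoid and archaeol
    markers (stanol/sterol degradation ratios, alpha-beta hopane dominance,
    archaeol vs. water-table consistency), and contrasts degraded, restored
    and near-natural sites against a reference condition. A seeded
    end-member mixing simulator generates realistic synthetic datasets for
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
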