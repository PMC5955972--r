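Package: denatens
Title: Denatured-State Ensemble Analysis of Protein Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Analysis of protein conformational ensembles from molecular
    dynamics style trajectories, aimed at characterizing heat-denatured
    states. Detects salt bridges by a side-chain carbon-carbon distance
    criterion and reports per-pair occupancies and salt-bridge count
    series; computes solvent-accessible surface area (Shrake-Rupley) with
    hydrophobic/hydrophilic partitioning and the hydrophobic transfer
    energy estimated from ensemble-average ASA differences; assigns
    secondary structure from Kabsch-Sander backbone hydrogen bonds;
    and provides Kabsch-superposition RMSD and radius-of-gyration series.
    A seeded synthetic-trajectory generator with known ground truth
    (per-pair contact occupancy, per-residue helicity, radius-of-gyration
    drift) supports parameter-recovery testing without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
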