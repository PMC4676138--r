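# shared helpers: build records/libraries from SMILES in code

rec <- function(smiles, id = "r1") {
  r <- screenrank:::new_record(id, smiles)
  if (is.null(r)) stop("helper: SMILES failed to parse: ", smiles)
  r
}

lib_from_smiles <- function(smiles, name = "test") {
  records <- lapply(seq_along(smiles), function(i) rec(smiles[i], sprintf("%s_%02d", name, i)))
  screenrank:::new_library(name, records)
}

# a tight homologous series of catechol-bearing oligosaccharides: every
# member fails Lipinski and Veber, is predicted BBB-impermeable, matches the
# catechol alert, and the series has high internal similarity - so a clean
# drug-like library dominates it on every workflow criterion
DOMINATED_SMILES <- c(
  "Oc1ccc(OC2OC(COC3OC(COC4OC(CO)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)cc1O",
  "Oc1cc(C)c(OC2OC(COC3OC(COC4OC(CO)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)cc1O",
  "Oc1ccc(OC2OC(COC3OC(COC4OC(CO)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)c(C)c1O",
  "Oc1ccc(CC2OC(COC3OC(COC4OC(CO)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)cc1O",
  "Oc1cc(CC)c(OC2OC(COC3OC(COC4OC(CO)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)cc1O",
  "Oc1ccc(OC2OC(COC3OC(COC4OC(COC)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)cc1O",
  "Oc1ccc(OC2OC(COC3OC(COC4OC(CO)C(O)CC4O)C(O)C3O)C(O)C(O)C2O)cc1O",
  "Oc1ccc(OC2OC(COC3OC(COC4OC(CCO)C(O)C(O)C4O)C(O)C3O)C(O)C(O)C2O)cc1O"
)

# small, structurally varied set reused across fingerprint/divsim tests
VARIED_SMILES <- c(
  "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2c(c1)cccn2", "CCN(CC)C(=O)c1cccnc1",
  "CN1CCN(CC1)c1ccccc1", "OCC1CCCN1Cc1ccccc1", "Cc1nc2ccccc2s1",
  "CC(C)Oc1ccccc1C#N", "c1ccc(cc1)S(=O)(=O)NC", "CCCCCCCC", "C1CCCCC1"
)
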