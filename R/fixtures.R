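## Embedded drug-like SMILES used by the synthetic activity-library
## generator. Families span several ring systems (quinazoline, pyrazole,
## 7-azaindole, benzimidazole, indole, pyridine, saturated carbocycles,
## thiophene, furan) so scaffold statistics operate on chemically
## meaningful groups; one entry is acyclic.

fixtureSmilesTable <- function() {
  tab <- rbind(
    c("c1ccc2ncncc2c1",                         "quinazoline"),
    c("Nc1ncnc2ccccc12",                        "quinazoline"),
    c("CNc1ncnc2ccccc12",                       "quinazoline"),
    c("c1ccc(Nc2ncnc3ccccc23)cc1",              "quinazoline"),
    c("COc1ccc2ncnc(N)c2c1",                    "quinazoline"),
    c("Cc1ccc2ncnc(NCC(O)CO)c2c1",              "quinazoline"),
    c("Oc1ncnc2ccccc12",                        "quinazoline"),
    c("Clc1ccc2ncnc(Nc3ccccc3)c2c1",            "quinazoline"),
    c("Cc1cc(C)[nH]n1",                         "pyrazole"),
    c("Cc1cc(-c2ccccc2)[nH]n1",                 "pyrazole"),
    c("NC(=O)c1cc(-c2ccccc2)[nH]n1",            "pyrazole"),
    c("Cc1n[nH]c(C)c1CC(=O)O",                  "pyrazole"),
    c("c1cc2cc[nH]c2nc1",                       "azaindole"),
    c("Cc1cc2cc[nH]c2nc1",                      "azaindole"),
    c("O=C(N)c1cc2cc[nH]c2nc1",                 "azaindole"),
    c("c1ccc2[nH]c(N)nc2c1",                    "benzimidazole"),
    c("Cc1ccc2[nH]c(C)nc2c1",                   "benzimidazole"),
    c("OCCn1c(C)nc2ccccc21",                    "benzimidazole"),
    c("c1ccc2[nH]ccc2c1",                       "indole"),
    c("CC(N)Cc1c[nH]c2ccccc12",                 "indole"),
    c("O=C(O)Cc1c[nH]c2ccccc12",                "indole"),
    c("Cc1ccncc1",                              "pyridine"),
    c("NC(=O)c1ccncc1",                         "pyridine"),
    c("OCc1ccccn1",                             "pyridine"),
    c("Clc1ccc(CN2CCNCC2)cn1",                  "pyridine"),
    c("OC1CCCCC1",                              "cyclohexane"),
    c("NC1CCC(O)CC1",                           "cyclohexane"),
    c("CC1CCC(C(=O)O)CC1",                      "cyclohexane"),
    c("Cc1ccc(C)s1",                            "thiophene"),
    c("NC(=O)c1cccs1",                          "thiophene"),
    c("Cc1ccc(C(=O)O)o1",                       "furan"),
    c("NCc1ccco1",                              "furan"),
    c("CC(C)CC(N)C(=O)O",                       "acyclic"),
    c("CCOC(=O)CC(C)C",                         "acyclic"),
    c("OCC(O)C(O)CO",                           "acyclic"),
    c("CN1CCN(Cc2ccccc2)CC1",                   "piperazine"),
    c("O=C(O)C1CCN(C)CC1",                      "piperidine"),
    c("OC(=O)c1ccc(N2CCOCC2)cc1",               "morpholine")
  )
  data.frame(smiles = tab[, 1], family = tab[, 2], stringsAsFactors = FALSE)
}
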