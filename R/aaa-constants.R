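# package-wide constants (file named to load before the modules using
# them at build time)

backbone_atoms <- c("N", "CA", "C", "O")

aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

standard_aa <- names(aa_three_to_one)[names(aa_three_to_one) != "MSE"]
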